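## Read-side tag handling: extract raw tags from tag reads, count them,
## and apply the three cleaning rules (N-containing tags, adaptor-derived
## tags, copy number below a minimum) that turn a raw library into a
## clean-tag library.

#' Filtering configuration
#'
#' @param min_copy minimum copy number for a tag to be kept (default 2:
#'   singletons are presumed sequencing-error artifacts).
#' @param adaptor_sequences character vector of adaptor sequences; a tag is
#'   removed when it equals an adaptor or is a prefix-length slice of one.
#'   The default is the Illumina DGE 3' adaptor; the sequence is
#'   kit-specific and should be supplied to match the library chemistry.
#' @param drop_n drop tags containing any non-A/C/G/T character (default TRUE).
#' @return object of class `FilterConfig`.
#' @export
filter_config <- function(min_copy = 2L,
                          adaptor_sequences = dge_default_adaptor(),
                          drop_n = TRUE) {
  assert_scalar_number(min_copy, "min_copy", min = 1, integer = TRUE)
  structure(list(min_copy = as.integer(min_copy),
                 adaptor_sequences = toupper(adaptor_sequences),
                 drop_n = isTRUE(drop_n)),
            class = "FilterConfig")
}

#' Default adaptor sequence
#'
#' Illumina small-RNA/DGE 3' adaptor prefix; override to match the kit.
#' @return character scalar.
#' @export
dge_default_adaptor <- function() "TCGTATGCCGTCTTCTGCTTG"

#' Extract raw tags from tag reads
#'
#' Tag reads are expected to begin with the anchor site (`CATG` after
#' adaptor-1 trimming); the `tag_length` bases following the anchor are the
#' tag. Reads not starting with the anchor are counted as discarded unless
#' `scan_anchor` is set, in which case the first anchor occurrence with a
#' full tag downstream is used.
#'
#' @param reads character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTQ file
#'   (gzip-transparent).
#' @param anchor anchor sequence at the read start (default `"CATG"`).
#' @param tag_length tag length (default 17).
#' @param scan_anchor if TRUE, rescue reads by searching for the anchor
#'   internally instead of requiring it at position 1.
#' @return list with `counts` (named integer vector, tag to raw count;
#'   N-containing tags are retained at this stage), `raw_reads`,
#'   `discarded_no_anchor` and `discarded_short`.
#' @export
extract_read_tags <- function(reads, anchor = "CATG", tag_length = 17L,
                              scan_anchor = FALSE) {
  if (is.character(reads) && length(reads) == 1L && !is.null(reads) &&
      file.exists(reads) && grepl("\\.(fq|fastq)(\\.gz)?$", reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  n_reads <- length(reads)
  min_len <- nchar(anchor) + tag_length

  short <- nchar(reads) < min_len
  usable <- reads[!short]
  if (scan_anchor) {
    pos <- regexpr(anchor, usable, fixed = TRUE)
    pos[pos > 0 & pos + min_len - 1L > nchar(usable)] <- -1L
  } else {
    pos <- ifelse(startsWith(usable, anchor), 1L, -1L)
  }
  anchored <- pos > 0
  tags <- substr(usable[anchored], pos[anchored] + nchar(anchor),
                 pos[anchored] + min_len - 1L)
  list(counts = tabulate_tags(tags),
       raw_reads = n_reads,
       discarded_no_anchor = sum(!anchored),
       discarded_short = sum(short))
}

#' Clean a raw tag-count table
#'
#' Applies, in order: (1) removal of tags containing characters outside
#' A/C/G/T (N calls) when `drop_n`; (2) removal of adaptor-derived tags
#' (equal to a configured adaptor or to its tag-length prefix); (3) removal
#' of tags with copy number below `min_copy`. The order is fixed so the
#' per-rule removal counts in the report are reproducible.
#'
#' @param raw named integer vector of raw tag counts.
#' @param cfg a [filter_config()].
#' @return list with `clean` (named integer vector of surviving counts,
#'   unchanged values) and `report`: per-rule removed distinct-tag counts
#'   (`n_removed`, `adaptor_removed`, `low_copy_removed`), reads removed
#'   (`reads_removed`), and input/output summaries.
#' @export
filter_tags <- function(raw, cfg = filter_config()) {
  stopifnot(inherits(cfg, "FilterConfig"))
  raw <- sort_tag_counts(raw)
  keep <- raw
  n_removed <- 0L
  if (cfg$drop_n && length(keep)) {
    is_n <- grepl("[^ACGT]", names(keep))
    n_removed <- sum(is_n)
    keep <- keep[!is_n]
  }
  adaptor_removed <- 0L
  if (length(cfg$adaptor_sequences) && length(keep)) {
    bad <- rep(FALSE, length(keep))
    for (a in cfg$adaptor_sequences) {
      bad <- bad | names(keep) == a |
        vapply(names(keep), function(t) startsWith(a, t), logical(1L))
    }
    adaptor_removed <- sum(bad)
    keep <- keep[!bad]
  }
  low <- keep < cfg$min_copy
  low_copy_removed <- sum(low)
  keep <- keep[!low]
  list(clean = keep,
       report = list(
         distinct_in = length(raw),
         distinct_out = length(keep),
         n_removed = n_removed,
         adaptor_removed = adaptor_removed,
         low_copy_removed = as.integer(low_copy_removed),
         reads_in = sum(raw),
         reads_out = sum(keep),
         reads_removed = sum(raw) - sum(keep)))
}

#' Singleton statistics of a raw tag distribution
#'
#' Singletons (distinct tags seen exactly once) are reported on the
#' pre-filter distribution: the copy-number filter removes them from clean
#' libraries by construction, so a singleton fraction is only meaningful on
#' raw counts.
#'
#' @param raw named integer vector of raw tag counts.
#' @return list with `singleton_count`, `distinct_raw` and
#'   `singleton_fraction` (0 when the library is empty).
#' @export
singleton_stats <- function(raw) {
  distinct_raw <- length(raw)
  singleton_count <- sum(raw == 1L)
  list(singleton_count = as.integer(singleton_count),
       distinct_raw = as.integer(distinct_raw),
       singleton_fraction =
         if (distinct_raw == 0L) 0 else singleton_count / distinct_raw)
}

#' Assemble a per-library tag object
#'
#' Bundles the raw and clean count tables of one (species, stage) library
#' with its totals, the shape consumed by mapping and summaries.
#'
#' @param species,stage library identity.
#' @param raw named integer vector of raw tag counts.
#' @param cfg a [filter_config()].
#' @param raw_reads total reads the raw counts came from (defaults to the
#'   raw count sum, i.e. every read yielded a tag).
#' @return object of class `TagLibrary`.
#' @export
tag_library <- function(species, stage, raw, cfg = filter_config(),
                        raw_reads = sum(raw)) {
  f <- filter_tags(raw, cfg)
  s <- singleton_stats(raw)
  structure(list(
    species = species, stage = stage,
    raw_counts = sort_tag_counts(raw),
    clean_counts = f$clean,
    filter_report = f$report,
    raw_reads = as.integer(raw_reads),
    raw_tag_total = sum(raw),
    clean_tag_total = sum(f$clean),
    distinct_raw = length(raw),
    distinct_clean = length(f$clean),
    singleton_fraction = s$singleton_fraction
  ), class = "TagLibrary")
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf(
    "TagLibrary %s/%s: %d raw reads, %d raw tags (%d distinct), %d clean tags (%d distinct)\n",
    x$species, x$stage, x$raw_reads, x$raw_tag_total, x$distinct_raw,
    x$clean_tag_total, x$distinct_clean))
  invisible(x)
}
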