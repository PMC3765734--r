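## Virtual tag extraction: the reference-side half of tag-to-gene
## assignment. NlaIII recognizes CATG; MmeI cuts 17 bp downstream of the
## recognition junction, so every qualifying CATG site defines a 17 nt tag
## immediately 3' of the anchor. The oligo-dT bead protocol retains the
## 3'-most restriction fragment of each cDNA, so the 3'-most qualifying
## site yields the canonical tag.

#' Extract virtual DGE tags from one transcript
#'
#' Scans the sense strand for anchor sites (default `CATG`, the NlaIII
#' recognition sequence) with at least `tag_length` non-N nucleotides
#' downstream. Each qualifying site yields a virtual tag: the
#' `tag_length` bases immediately 3' of the anchor.
#'
#' @param transcript_id transcript identifier.
#' @param sequence nucleotide string over A/C/G/T/N (case-insensitive).
#' @param mode `"canonical"` (default) returns only the 3'-most qualifying
#'   site, the fragment retained by the oligo-dT bead chemistry;
#'   `"all_sites"` returns every qualifying site 5' to 3' with
#'   `is_canonical` set on the 3'-most.
#' @param anchor anchor site sequence; `"GATC"` selects DpnII-style anchoring.
#' @param tag_length tag length in nt downstream of the anchor (default 17,
#'   the MmeI cut distance).
#' @return data.frame with columns `transcript_id`, `tag17`, `anchored21`
#'   (anchor + tag), `site_offset` (0-based offset of the anchor's first
#'   base on the sense strand) and `is_canonical`. Zero rows when no site
#'   qualifies.
#' @examples
#' extract_virtual_tags("t1", paste0("AAACATG", strrep("ACGT", 5)))
#' @export
extract_virtual_tags <- function(transcript_id, sequence,
                                 mode = c("canonical", "all_sites"),
                                 anchor = "CATG", tag_length = 17L) {
  mode <- match.arg(mode)
  if (!nzchar(sequence)) {
    dge_error("empty sequence", "dgetag_input_error")
  }
  sequence <- toupper(sequence)
  check_nucleotides(sequence, allow_n = TRUE)

  empty <- data.frame(transcript_id = character(0), tag17 = character(0),
                      anchored21 = character(0), site_offset = integer(0),
                      is_canonical = logical(0), stringsAsFactors = FALSE)

  hits <- gregexpr(anchor, sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(empty)
  an <- nchar(anchor)
  tag_start <- hits + an                            # 1-based first tag base
  ok <- tag_start + tag_length - 1L <= nchar(sequence)
  hits <- hits[ok]
  if (!length(hits)) return(empty)
  tags <- substr(rep(sequence, length(hits)), hits + an,
                 hits + an + tag_length - 1L)
  ok <- !grepl("N", tags, fixed = TRUE)             # read-side N filter mirror
  hits <- hits[ok]; tags <- tags[ok]
  if (!length(hits)) return(empty)

  canonical <- seq_along(hits) == length(hits)      # 3'-most qualifying site
  if (mode == "canonical") {
    hits <- hits[canonical]; tags <- tags[canonical]; canonical <- TRUE
  }
  data.frame(transcript_id = transcript_id, tag17 = tags,
             anchored21 = paste0(anchor, tags),
             site_offset = as.integer(hits - 1L),
             is_canonical = canonical, stringsAsFactors = FALSE)
}

#' Build a virtual tag index over a transcript reference
#'
#' @param reference named character vector of transcript sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @inheritParams extract_virtual_tags
#' @return object of class `TagIndex`: a hash-style exact lookup from tag
#'   sequence to the set of transcripts bearing it, plus `reference_size`
#'   (transcripts indexed) and `taggable_count` (transcripts contributing
#'   at least one virtual tag). `tag_table` holds the per-site records.
#' @export
build_tag_index <- function(reference, mode = c("canonical", "all_sites"),
                            anchor = "CATG", tag_length = 17L) {
  mode <- match.arg(mode)
  sequences <- as_reference_vector(reference)
  ids <- names(sequences)
  if (anyDuplicated(ids)) {
    dge_error(sprintf("duplicate transcript id '%s'",
                      ids[anyDuplicated(ids)]),
              "dgetag_input_error")
  }
  per_tx <- lapply(seq_along(sequences), function(i) {
    extract_virtual_tags(ids[i], sequences[[i]], mode = mode,
                         anchor = anchor, tag_length = tag_length)
  })
  tag_table <- if (length(per_tx)) {
    do.call(rbind, c(per_tx, list(make.row.names = FALSE)))
  } else {
    extract_virtual_tags("x", "CATG")                   # typed empty frame
  }
  exact <- split(tag_table$transcript_id, tag_table$tag17)
  exact <- lapply(exact, unique)
  structure(list(
    tags = names(exact),
    transcripts = unname(exact),
    tag_table = tag_table,
    reference_size = length(sequences),
    taggable_count = length(unique(tag_table$transcript_id)),
    anchor = anchor,
    tag_length = as.integer(tag_length),
    mode = mode
  ), class = "TagIndex")
}

#' @export
print.TagIndex <- function(x, ...) {
  cat(sprintf(
    "TagIndex: %d distinct %d nt tags (%s anchor, %s mode)\n  %d/%d transcripts taggable\n",
    length(x$tags), x$tag_length, x$anchor, x$mode,
    x$taggable_count, x$reference_size))
  invisible(x)
}

## Accept a FASTA path, DNAStringSet or named character vector.
as_reference_vector <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (!is.character(reference)) {
    dge_error("reference must be a named character vector, DNAStringSet or FASTA path",
              "dgetag_input_error")
  }
  if (length(reference) && is.null(names(reference))) {
    dge_error("reference sequences must be named", "dgetag_input_error")
  }
  ## FASTA headers may carry descriptions; the id is the first word
  names(reference) <- sub("\\s.*$", "", names(reference))
  toupper(reference)
}

#' Write a virtual tag table
#'
#' @param index `TagIndex` from [build_tag_index()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_virtual_tags <- function(index, path) {
  stopifnot(inherits(index, "TagIndex"))
  write.table(index$tag_table[, c("transcript_id", "tag17", "site_offset",
                                  "is_canonical")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
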