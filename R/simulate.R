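## Synthetic-data generator: reference transcriptomes with NlaIII tag
## sites, per-transcript expression profiles across species x stage
## conditions, and simulated tag libraries with per-base substitution / N
## errors and adaptor contamination, all with recorded ground truth.

#' Simulation configuration
#'
#' Defaults emulate a two-species, four-developmental-stage DGE-tag study:
#' per-library depths in the millions of tags are scaled to what a test or
#' example needs via `depth_per_library`.
#'
#' @param n_transcripts number of reference transcripts.
#' @param transcript_length_range integer pair (min, max) in nt; minimum
#'   >= 25 so a CATG site and 17 nt tag fit.
#' @param gc_content GC fraction of generated sequence in \[0, 1\].
#' @param n_species,n_stages condition grid (defaults 2 species, 4 stages).
#' @param depth_per_library total tag reads per library.
#' @param substitution_rate per-base substitution probability within the
#'   17 nt tag.
#' @param n_rate per-base probability of an N call within the tag.
#' @param adaptor_read_fraction fraction of reads that are adaptor-derived
#'   contaminants rather than transcript tags.
#' @param adaptor_sequence contaminant adaptor sequence.
#' @param de_fraction fraction of transcripts given a between-species
#'   expression difference. DE transcripts are created in matched pairs
#'   whose weights are swapped between the species, so every DE transcript
#'   changes by exactly `de_log2fc` (half up, half down) while library
#'   composition is preserved and non-DE transcripts remain exact
#'   between-species nulls — the structure a normalization-based exact
#'   test assumes.
#' @param de_log2fc absolute log2 fold change of each DE transcript.
#' @param expression_meanlog,expression_sdlog log-normal parameters of the
#'   baseline per-transcript expression weights.
#' @param stage_sdlog log-sd of per-transcript multiplicative stage
#'   effects (shared between species, so stages differ but non-DE genes
#'   obey the between-species null exactly).
#' @param seed master seed; every library derives its own stream from it.
#' @return object of class `SimulationConfig`.
#' @export
sim_config <- function(n_transcripts = 500L,
                       transcript_length_range = c(200L, 400L),
                       gc_content = 0.42,
                       n_species = 2L,
                       n_stages = 4L,
                       depth_per_library = 1e5,
                       substitution_rate = 0.002,
                       n_rate = 0.002,
                       adaptor_read_fraction = 0.01,
                       adaptor_sequence = dge_default_adaptor(),
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       expression_meanlog = 0,
                       expression_sdlog = 1.2,
                       stage_sdlog = 0.5,
                       seed = 1L) {
  assert_scalar_number(n_transcripts, "n_transcripts", min = 0,
                       integer = TRUE)
  if (length(transcript_length_range) != 2L ||
      transcript_length_range[1L] > transcript_length_range[2L]) {
    dge_error("field 'transcript_length_range' must be an increasing pair",
              "dgetag_config_error")
  }
  assert_scalar_number(transcript_length_range[1L],
                       "transcript_length_range", min = 25)
  assert_scalar_number(gc_content, "gc_content", min = 0, max = 1)
  assert_scalar_number(n_species, "n_species", min = 1, integer = TRUE)
  assert_scalar_number(n_stages, "n_stages", min = 1, integer = TRUE)
  assert_scalar_number(depth_per_library, "depth_per_library", min = 1)
  assert_scalar_number(substitution_rate, "substitution_rate",
                       min = 0, max = 1 - 1e-9)
  assert_scalar_number(n_rate, "n_rate", min = 0, max = 1 - 1e-9)
  if (substitution_rate + n_rate >= 1) {
    dge_error("field 'substitution_rate' + 'n_rate' must be < 1",
              "dgetag_config_error")
  }
  assert_scalar_number(adaptor_read_fraction, "adaptor_read_fraction",
                       min = 0, max = 1 - 1e-9)
  assert_scalar_number(de_fraction, "de_fraction", min = 0, max = 1)
  assert_scalar_number(de_log2fc, "de_log2fc", min = 0)
  assert_scalar_number(seed, "seed", integer = TRUE)
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length_range = as.integer(transcript_length_range),
    gc_content = gc_content, n_species = as.integer(n_species),
    n_stages = as.integer(n_stages),
    depth_per_library = as.integer(depth_per_library),
    substitution_rate = substitution_rate, n_rate = n_rate,
    adaptor_read_fraction = adaptor_read_fraction,
    adaptor_sequence = toupper(adaptor_sequence),
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog, stage_sdlog = stage_sdlog,
    seed = as.integer(seed)
  ), class = "SimulationConfig")
}

sim_species_names <- function(config) {
  if (config$n_species == 2L) c("species_A", "species_B")
  else paste0("species_", LETTERS[seq_len(config$n_species)])
}

sim_stage_names <- function(config) {
  if (config$n_stages == 4L) STAGE_ORDER
  else paste0("stage", seq_len(config$n_stages))
}

#' Simulate a reference transcriptome
#'
#' Generates random transcripts at the configured GC content. A CATG site
#' with a full 17 nt downstream window is inserted into any transcript
#' lacking one, so essentially all transcripts are taggable; the
#' `taggable` attribute records the per-transcript status found by a scan
#' of the final sequence.
#'
#' @param config a [sim_config()].
#' @return object of class `SimulatedReference`: list with `sequences`
#'   (named character vector, ids `tx0001`...), `taggable` (logical) and
#'   `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_transcripts
  if (n == 0L) {
    return(structure(list(sequences = setNames(character(0), character(0)),
                          taggable = logical(0), config = config),
                     class = "SimulatedReference"))
  }
  lens <- sample(seq(config$transcript_length_range[1L],
                     config$transcript_length_range[2L]), n, replace = TRUE)
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = "")
  }, character(1L))
  ## guarantee a usable site: insert CATG (overwriting 4 bases) where the
  ## random sequence has no CATG with >= 17 nt downstream
  has_site <- function(s) {
    h <- gregexpr("CATG", s, fixed = TRUE)[[1L]]
    h[1L] != -1L && any(h + 20L <= nchar(s))
  }
  for (i in seq_len(n)) {
    if (!has_site(seqs[i])) {
      L <- nchar(seqs[i])
      at <- sample(seq_len(L - 20L), 1L)        # leaves >= 17 nt downstream
      substr(seqs[i], at, at + 3L) <- "CATG"
    }
  }
  names(seqs) <- sprintf("tx%04d", seq_len(n))
  structure(list(sequences = seqs,
                 taggable = vapply(seqs, has_site, logical(1L)),
                 config = config),
            class = "SimulatedReference")
}

#' @export
print.SimulatedReference <- function(x, ...) {
  cat(sprintf("SimulatedReference: %d transcripts (%d taggable)\n",
              length(x$sequences), sum(x$taggable)))
  invisible(x)
}

#' Write a simulated reference as FASTA
#'
#' @param reference a `SimulatedReference` (or named character vector).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  seqs <- if (inherits(reference, "SimulatedReference"))
    reference$sequences else reference
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

## Ground-truth expression grid: baseline weight per transcript, shared
## per-transcript stage effects, and between-species differential
## expression injected as weight swaps within matched transcript pairs.
## Pairing keeps every library's composition identical across species, so
## non-DE transcripts are exact between-species nulls while each DE
## transcript changes by exactly de_log2fc. Drawn from the master seed
## before any per-library stream is opened.
sim_expression_truth <- function(reference, config) {
  taggable_ids <- names(reference$sequences)[reference$taggable]
  n <- length(taggable_ids)
  set.seed((config$seed + 777L) %% .Machine$integer.max)
  base <- rlnorm(n, config$expression_meanlog, config$expression_sdlog)
  stage_eff <- matrix(rlnorm(n * config$n_stages, 0, config$stage_sdlog),
                      nrow = n)
  n_pairs <- floor(round(config$de_fraction * n) / 2)
  de_ids <- character(0)
  de_sign <- numeric(0)
  if (n_pairs > 0 && n >= 2 * n_pairs && config$n_species >= 2L) {
    picked <- sample.int(n, 2L * n_pairs)
    up <- picked[seq_len(n_pairs)]           # higher in the second species
    down <- picked[n_pairs + seq_len(n_pairs)]
    f <- 2^config$de_log2fc
    base[down] <- base[up] * f               # matched-pair weights b, b*f
    stage_eff[down, ] <- stage_eff[up, ]     # shared within a pair
    de_ids <- taggable_ids[c(up, down)]
    de_sign <- setNames(rep(c(1, -1), each = n_pairs), de_ids)
  }
  species <- sim_species_names(config)
  stages <- sim_stage_names(config)
  weights <- array(0, dim = c(n, config$n_species, config$n_stages),
                   dimnames = list(taggable_ids, species, stages))
  for (sp in seq_len(config$n_species)) {
    b <- base
    if (sp == 2L && length(de_ids)) {        # swap pair weights in species 2
      up <- match(de_ids[de_sign == 1], taggable_ids)
      down <- match(de_ids[de_sign == -1], taggable_ids)
      b[up] <- base[down]
      b[down] <- base[up]
    }
    for (st in seq_len(config$n_stages)) {
      weights[, sp, st] <- b * stage_eff[, st]
    }
  }
  list(weights = weights, de_ids = de_ids, de_sign = de_sign,
       taggable_ids = taggable_ids)
}

## Mutate reads carrying >= 1 erroneous base. `tags` are the canonical
## 17-mers of the affected reads; returns the mutated sequences.
mutate_tags <- function(tags, n_errors, n_rate, substitution_rate) {
  tag_len <- nchar(tags[1L])
  p_n <- n_rate / (n_rate + substitution_rate)
  one <- n_errors == 1L
  ## single-error reads (the vast majority): vectorized
  if (any(one)) {
    t1 <- tags[one]
    pos <- sample.int(tag_len, length(t1), replace = TRUE)
    to_n <- runif(length(t1)) < p_n
    orig <- substr(t1, pos, pos)
    new <- vapply(seq_along(t1), function(i) {
      if (to_n[i]) "N" else sample(setdiff(DNA_BASES, orig[i]), 1L)
    }, character(1L))
    substr(t1, pos, pos) <- new
    tags[one] <- t1
  }
  multi <- which(n_errors > 1L)
  for (i in multi) {
    ch <- strsplit(tags[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(tag_len, n_errors[i])
    for (p in pos) {
      ch[p] <- if (runif(1) < p_n) "N" else sample(setdiff(DNA_BASES, ch[p]), 1L)
    }
    tags[i] <- paste(ch, collapse = "")
  }
  tags
}

#' Simulate tag libraries over a species x stage grid
#'
#' Each library draws `depth_per_library` tag reads: a fixed
#' `adaptor_read_fraction` share of adaptor-derived contaminants (the
#' anchor followed by the adaptor's first 17 nt), and the rest drawn
#' multinomially over taggable transcripts with log-normal baseline
#' weights, per-transcript stage effects shared between species, and a
#' `de_log2fc` species fold change on a `de_fraction` subset. Each
#' transcript read is its canonical tag with i.i.d. per-base substitution
#' and N-call errors. Each library uses its own RNG stream derived from
#' the master seed by a stable hash of (species, stage), so results do not
#' depend on simulation order.
#'
#' @param reference a `SimulatedReference` from [simulate_reference()], or
#'   a named character vector of transcript sequences.
#' @param config the [sim_config()] used (taken from `reference` when
#'   absent there is none).
#' @return object of class `SimulatedLibraries`: `libraries` — list of
#'   `TagLibrary`-shaped raw components, one per species x stage, each
#'   with `species`, `stage`, `raw_counts` and `raw_reads`; `truth` — list
#'   with `expected_counts` data.frame (transcript_id, species, stage,
#'   expected_count), `transcript_tags` (canonical tag per taggable
#'   transcript), `de_ids`, `de_sign`, `contaminant_reads` per library.
#' @export
simulate_libraries <- function(reference, config = reference$config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!inherits(reference, "SimulatedReference")) {
    seqs <- as_reference_vector(reference)
    reference <- structure(
      list(sequences = seqs,
           taggable = vapply(seqs, function(s) {
             nrow(extract_virtual_tags("x", s)) > 0L
           }, logical(1L)),
           config = config),
      class = "SimulatedReference")
  }
  if (length(reference$sequences) == 0L || !any(reference$taggable)) {
    dge_error("reference contains no taggable transcript",
              "dgetag_simulation_error")
  }
  truth <- sim_expression_truth(reference, config)
  ids <- truth$taggable_ids
  canonical <- vapply(reference$sequences[ids], function(s) {
    extract_virtual_tags("x", s)$tag17
  }, character(1L))
  names(canonical) <- ids

  species <- sim_species_names(config)
  stages <- sim_stage_names(config)
  depth <- config$depth_per_library
  n_adaptor <- as.integer(round(config$adaptor_read_fraction * depth))
  adaptor_tag <- substr(config$adaptor_sequence, 1L, 17L)
  p_base <- config$substitution_rate + config$n_rate

  libraries <- list()
  expected <- list()
  contaminants <- integer(0)
  for (sp in species) {
    for (st in stages) {
      lib_id <- paste(sp, st, sep = ".")
      set.seed((config$seed + stable_hash(lib_id)) %% .Machine$integer.max)
      w <- truth$weights[, sp, st]
      n_tx_reads <- depth - n_adaptor
      draws <- as.integer(rmultinom(1L, n_tx_reads, w))
      names(draws) <- ids
      ## split each transcript's reads into error-free and erroneous
      err_per_read <- rbinom(sum(draws), 17L, p_base)
      read_tx <- rep.int(seq_along(ids), draws)
      erroneous <- err_per_read > 0L
      clean_part <- tabulate(read_tx[!erroneous], nbins = length(ids))
      ## two transcripts can share a canonical tag: aggregate by tag
      agg <- tapply(clean_part, canonical, sum)
      counts <- setNames(as.integer(agg), names(agg))
      counts <- counts[counts > 0L]
      if (any(erroneous)) {
        mut <- mutate_tags(canonical[read_tx[erroneous]],
                           err_per_read[erroneous],
                           config$n_rate, config$substitution_rate)
        mut_tab <- tabulate_tags(mut)
        all_tags <- union(names(counts), names(mut_tab))
        merged <- setNames(integer(length(all_tags)), all_tags)
        merged[names(counts)] <- counts
        merged[names(mut_tab)] <- merged[names(mut_tab)] + mut_tab
        counts <- merged
      }
      if (n_adaptor > 0L) {
        counts[adaptor_tag] <- as.integer(
          (if (adaptor_tag %in% names(counts)) counts[[adaptor_tag]] else 0L) +
            n_adaptor)
      }
      libraries[[lib_id]] <- list(species = sp, stage = st,
                                  raw_counts = sort_tag_counts(counts),
                                  raw_reads = depth)
      expected[[lib_id]] <- data.frame(
        transcript_id = ids, species = sp, stage = st,
        expected_count = n_tx_reads * w / sum(w),
        stringsAsFactors = FALSE)
      contaminants[lib_id] <- n_adaptor
    }
  }
  structure(list(
    libraries = libraries,
    truth = list(expected_counts = do.call(rbind,
                                           c(expected,
                                             list(make.row.names = FALSE))),
                 transcript_tags = canonical,
                 de_ids = truth$de_ids, de_sign = truth$de_sign,
                 contaminant_reads = contaminants),
    config = config
  ), class = "SimulatedLibraries")
}

#' @export
print.SimulatedLibraries <- function(x, ...) {
  cat(sprintf("SimulatedLibraries: %d libraries, depth %d each\n",
              length(x$libraries), x$config$depth_per_library))
  invisible(x)
}

#' Expand a simulated library to reads and write FASTQ
#'
#' Emits one record per tag read: the anchor plus the (possibly
#' error-bearing) tag, optionally padded with adaptor sequence to a fixed
#' read length to exercise adaptor handling, with constant Q30 qualities.
#' Intended for small test-scale depths.
#'
#' @param library one element of `SimulatedLibraries$libraries`.
#' @param path output FASTQ path (`.gz` transparently compressed).
#' @param anchor anchor prepended to each tag (default `"CATG"`).
#' @param read_length pad reads to this length with adaptor bases
#'   (default 21 = no padding).
#' @param adaptor_sequence padding source when `read_length` > 21.
#' @return `path`, invisibly.
#' @export
write_library_fastq <- function(library, path, anchor = "CATG",
                                read_length = 21L,
                                adaptor_sequence = dge_default_adaptor()) {
  counts <- library$raw_counts
  reads <- paste0(anchor, rep.int(names(counts), counts))
  if (read_length > nchar(reads[1L])) {
    pad <- read_length - nchar(reads[1L])
    reads <- paste0(reads, substr(strrep(adaptor_sequence, 3L), 1L, pad))
  }
  names(reads) <- sprintf("read%07d", seq_along(reads))
  ## DNAStringSet drops N-free assumptions transparently; qualities constant
  x <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::PhredQuality(
    Biostrings::BStringSet(rep(strrep("?", read_length), length(reads))))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write ground-truth expected counts
#'
#' @param sim a `SimulatedLibraries` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  write.table(sim$truth$expected_counts, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
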