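## Set-overlap (Venn) analysis of expressed tags or genes across libraries,
## and Table-style per-library summaries with species totals and mapping
## ratios.

#' Expressed-set constructor
#'
#' The membership universe is either `tags` (distinct clean tag sequences)
#' or `genes` (transcript ids with unambiguously assigned counts).
#'
#' @param library_id label for the library (e.g. `"armigera.embryo"`).
#' @param members character vector of members, or a named count vector from
#'   which members with count >= `threshold` are taken.
#' @param universe `"tags"` or `"genes"`.
#' @param threshold minimum count for membership when `members` is a count
#'   vector (default 1: presence in the clean library).
#' @return object of class `ExpressedSet`.
#' @export
expressed_set <- function(library_id, members, universe = c("tags", "genes"),
                          threshold = 1) {
  universe <- match.arg(universe)
  if (!is.null(names(members)) && is.numeric(members)) {
    members <- names(members)[members >= threshold]
  }
  structure(list(library_id = library_id, universe = universe,
                 members = unique(as.character(members)),
                 threshold = threshold),
            class = "ExpressedSet")
}

check_same_universe <- function(sets) {
  u <- unique(vapply(sets, function(s) s$universe, character(1L)))
  if (length(u) != 1L) {
    dge_error(paste0("sets mix universes: ", paste(u, collapse = ", ")),
              "dgetag_input_error")
  }
  invisible(TRUE)
}

#' Venn partition of 2-4 expressed sets
#'
#' Partitions the union of the sets into its 2^k - 1 exclusive regions.
#' Region labels are the sorted library ids of the sets containing the
#' region, joined with `&`.
#'
#' @param sets list of 2 to 4 [expressed_set()] objects sharing a universe.
#' @return named integer vector: region label to element count, covering
#'   all 2^k - 1 regions (zeros included). Counts sum to the union size.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) {
    dge_error("venn_partition takes 2 to 4 sets", "dgetag_input_error")
  }
  check_same_universe(sets)
  ids <- vapply(sets, function(s) s$library_id, character(1L))
  if (anyDuplicated(ids)) {
    dge_error("duplicate library ids among sets", "dgetag_input_error")
  }
  universe <- unique(unlist(lapply(sets, function(s) s$members),
                            use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s$members,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  ## membership signature of every element -> region
  sig <- if (length(universe)) {
    apply(member, 1L, function(m) paste(sort(ids[m]), collapse = "&"))
  } else character(0)
  regions <- unlist(lapply(seq_len(k), function(r) {
    apply(utils::combn(sort(ids), r), 2L, paste, collapse = "&")
  }), use.names = FALSE)
  counts <- setNames(integer(length(regions)), regions)
  tab <- table(sig)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Coexpression overlap between two expressed sets
#'
#' For cross-species tag-universe comparisons, membership is by identical
#' tag sequence; for gene universes, by shared transcript id.
#'
#' @param set_a,set_b [expressed_set()] objects sharing a universe.
#' @return list with `intersection` (size), `fraction_of_a`,
#'   `fraction_of_b` (0 for empty sets).
#' @export
coexpression_fraction <- function(set_a, set_b) {
  check_same_universe(list(set_a, set_b))
  n <- length(intersect(set_a$members, set_b$members))
  frac <- function(m) if (length(m) == 0L) 0 else n / length(m)
  list(intersection = n,
       fraction_of_a = frac(set_a$members),
       fraction_of_b = frac(set_b$members))
}

STAGE_ORDER <- c("embryo", "larva", "pupa", "adult")

#' Table-style library summary with species totals and mapping ratios
#'
#' Assembles per-(species, stage) counts into a summary with per-species
#' totals (each total is the sum of its stage values) and mapping tag
#' ratios, `100 * mapped_unique_tags / unique_clean_tags`, rounded half-up
#' to 2 decimals. The mapping gene ratio `100 * genes_hit /
#' reference_size` is reported only when `reference_size` is supplied; its
#' denominator is a property of the reference the user mapped against.
#'
#' @param stats data.frame with columns `species`, `stage`, `raw_reads`,
#'   `clean_tags`, `unique_clean_tags`, `mapped_unique_tags`, `genes_hit`.
#'   Alternatively built from pipeline objects via
#'   [library_stats_from_results()].
#' @param reference_size optional number of transcripts in the mapped
#'   reference.
#' @return object of class `LibrarySummary`: `per_stage` (input rows with
#'   `mapping_tag_ratio` and optionally `mapping_gene_ratio` columns,
#'   stages ordered embryo/larva/pupa/adult where applicable) and `totals`
#'   (one row per species).
#' @export
summarize_libraries <- function(stats, reference_size = NULL) {
  needed <- c("species", "stage", "raw_reads", "clean_tags",
              "unique_clean_tags", "mapped_unique_tags", "genes_hit")
  missing <- setdiff(needed, names(stats))
  if (length(missing)) {
    dge_error(paste0("missing columns: ", paste(missing, collapse = ", ")),
              "dgetag_input_error")
  }
  count_cols <- needed[-(1:2)]
  per_species <- split(stats, stats$species)
  for (sp in names(per_species)) {
    absent <- setdiff(STAGE_ORDER, per_species[[sp]]$stage)
    if (length(absent) && all(per_species[[sp]]$stage %in% STAGE_ORDER)) {
      warning(sprintf("species %s missing stage(s): %s; totals cover present stages",
                      sp, paste(absent, collapse = ", ")))
    }
  }
  ord <- order(stats$species,
               match(stats$stage, STAGE_ORDER, nomatch = NA))
  per_stage <- stats[ord, , drop = FALSE]
  per_stage$mapping_tag_ratio <- round_half_up(
    100 * per_stage$mapped_unique_tags /
      pmax(per_stage$unique_clean_tags, 1) *
      (per_stage$unique_clean_tags > 0), 2)
  totals <- do.call(rbind, lapply(split(per_stage, per_stage$species),
                                  function(d) {
    tot <- as.data.frame(lapply(d[count_cols], sum))
    cbind(data.frame(species = d$species[1L], stringsAsFactors = FALSE), tot)
  }))
  rownames(totals) <- NULL
  totals$mapping_tag_ratio <- round_half_up(
    100 * totals$mapped_unique_tags /
      pmax(totals$unique_clean_tags, 1) *
      (totals$unique_clean_tags > 0), 2)
  if (!is.null(reference_size)) {
    per_stage$mapping_gene_ratio <- round_half_up(
      100 * per_stage$genes_hit / reference_size, 2)
  }
  rownames(per_stage) <- NULL
  structure(list(per_stage = per_stage, totals = totals,
                 reference_size = reference_size),
            class = "LibrarySummary")
}

#' @export
print.LibrarySummary <- function(x, ...) {
  cat("Per-library statistics:\n")
  print(x$per_stage, row.names = FALSE)
  cat("\nSpecies totals:\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Assemble per-library statistics from pipeline objects
#'
#' @param libraries list of `TagLibrary` objects.
#' @param mappings list of `MappingResult` objects, aligned with
#'   `libraries`.
#' @return data.frame in the shape [summarize_libraries()] consumes.
#' @export
library_stats_from_results <- function(libraries, mappings) {
  stopifnot(length(libraries) == length(mappings))
  do.call(rbind, lapply(seq_along(libraries), function(i) {
    lib <- libraries[[i]]; mp <- mappings[[i]]
    data.frame(species = lib$species, stage = lib$stage,
               raw_reads = lib$raw_reads,
               clean_tags = lib$clean_tag_total,
               unique_clean_tags = lib$distinct_clean,
               mapped_unique_tags = mp$mapped_unique_tags,
               genes_hit = mp$genes_hit, stringsAsFactors = FALSE)
  }))
}

#' Published Helicoverpa developmental DGE library statistics
#'
#' Per-stage library statistics (raw reads, clean tags, unique clean tags,
#' mapped unique tags, genes hit) for the four developmental stages of
#' *Helicoverpa armigera* and *H. assulta* from a published developmental
#' DGE-tag experiment, shipped as a worked example and regression fixture
#' for [summarize_libraries()].
#'
#' @return data.frame of 8 rows in [summarize_libraries()] input shape.
#' @export
helicoverpa_library_stats <- function() {
  path <- system.file("extdata", "helicoverpa_library_stats.tsv",
                      package = "dgetag", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Published Helicoverpa cross-species tag-count profiles
#'
#' Per-stage tag copy numbers in both species for 20 digestion/
#' detoxification/olfaction-related transcripts, with the similar (S) /
#' different (D) pattern labels assigned in the source study. Used as a
#' worked example for [classify_pattern()]; the study's own S/D thresholds
#' were not published, so beyond the exemplar rows the labels are context,
#' not ground truth.
#'
#' @return data.frame with `pattern_label`, `gene_id`, `seq_id`,
#'   `<species>_<stage>` count columns and `annotation`.
#' @export
helicoverpa_pattern_profiles <- function() {
  path <- system.file("extdata", "helicoverpa_pattern_profiles.tsv",
                      package = "dgetag", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
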