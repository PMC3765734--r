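## End-to-end driver: reference -> tag index -> per-library extraction,
## cleaning, mapping -> expression matrix -> DE / patterns -> overlaps ->
## summary, with every stage handing the next one plain TSV files and a
## manifest recording checksums so reruns are verifiably identical.

#' Pipeline configuration
#'
#' Two entry modes: `simulation` (a [sim_config()]; the pipeline generates
#' its own reference and libraries) or `reference` + `libraries` (a FASTA
#' path plus a data.frame with columns `species`, `stage`, `path` pointing
#' at FASTQ or tag-count TSV inputs).
#'
#' @param out_dir output directory, created if needed.
#' @param simulation optional [sim_config()].
#' @param reference optional FASTA path.
#' @param libraries optional data.frame (`species`, `stage`, `path`).
#' @param filter a [filter_config()].
#' @param mapping_mode virtual tag extraction mode (`"canonical"` or
#'   `"all_sites"`).
#' @param ambiguous ambiguous-tag policy, see [map_library()].
#' @param alpha,lfc_min DE thresholds, see [call_de()].
#' @return object of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir,
                            simulation = NULL,
                            reference = NULL,
                            libraries = NULL,
                            filter = filter_config(),
                            mapping_mode = "canonical",
                            ambiguous = "count",
                            alpha = 0.05, lfc_min = 1.0) {
  if (is.null(simulation)) {
    if (is.null(reference) || is.null(libraries)) {
      dge_error("either 'simulation' or 'reference' + 'libraries' required",
                "dgetag_config_error")
    }
    if (!file.exists(reference)) {
      dge_error(paste0("reference FASTA not found: ", reference),
                "dgetag_config_error")
    }
    missing <- libraries$path[!file.exists(libraries$path)]
    if (length(missing)) {
      dge_error(paste0("library input(s) not found: ",
                       paste(missing, collapse = ", ")),
                "dgetag_config_error")
    }
  } else {
    stopifnot(inherits(simulation, "SimulationConfig"))
  }
  structure(list(out_dir = out_dir, simulation = simulation,
                 reference = reference, libraries = libraries,
                 filter = filter, mapping_mode = mapping_mode,
                 ambiguous = ambiguous, alpha = alpha, lfc_min = lfc_min),
            class = "PipelineConfig")
}

#' Run the DGE-tag pipeline
#'
#' Executes reference indexing, per-library tag extraction and cleaning,
#' 1-mismatch mapping, quantification, pairwise cross-species DE within
#' each stage (when exactly two species are present), S/D pattern
#' classification, per-species Venn partitions of expressed tags across
#' stages, and the library summary table. All tables are written under
#' `config$out_dir`; the returned manifest records paths, md5 checksums
#' and row counts.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (data.frame: stage, path, md5, rows),
#'   `summary` (a `LibrarySummary`), `matrix` (an `ExpressionMatrix`),
#'   `mappings`, `libraries`, `patterns`, `venn` and, for simulation runs,
#'   `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, path = path,
      md5 = unname(tools::md5sum(path)), rows = rows,
      stringsAsFactors = FALSE)
  }

  ## stage 1: reference
  truth <- NULL
  if (!is.null(config$simulation)) {
    ref <- simulate_reference(config$simulation)
    ref_path <- file.path(config$out_dir, "reference.fa")
    write_reference_fasta(ref, ref_path)
    sim <- simulate_libraries(ref, config$simulation)
    truth <- sim$truth
    raw_inputs <- lapply(sim$libraries, function(l) {
      list(species = l$species, stage = l$stage, counts = l$raw_counts,
           raw_reads = l$raw_reads)
    })
    gt_path <- file.path(config$out_dir, "ground_truth.tsv")
    write_ground_truth(sim, gt_path)
    note("ground_truth", gt_path, nrow(truth$expected_counts))
  } else {
    ref_path <- config$reference
    raw_inputs <- lapply(seq_len(nrow(config$libraries)), function(i) {
      row <- config$libraries[i, ]
      counts <- if (grepl("\\.(fq|fastq)(\\.gz)?$", row$path)) {
        ex <- extract_read_tags(row$path)
        attr(ex$counts, "raw_reads") <- ex$raw_reads
        ex$counts
      } else {
        read_tag_counts(row$path)
      }
      rr <- attr(counts, "raw_reads")
      list(species = row$species, stage = row$stage,
           counts = counts,
           raw_reads = if (is.null(rr)) sum(counts) else rr)
    })
    names(raw_inputs) <- vapply(raw_inputs, function(l) {
      paste(l$species, l$stage, sep = ".")
    }, character(1L))
  }
  index <- build_tag_index(ref_path, mode = config$mapping_mode)
  tags_path <- file.path(config$out_dir, "virtual_tags.tsv")
  write_virtual_tags(index, tags_path)
  note("build_ref", tags_path, nrow(index$tag_table))

  ## stage 2: clean + map each library
  libraries <- list(); mappings <- list()
  for (lib_id in names(raw_inputs)) {
    li <- raw_inputs[[lib_id]]
    lib <- tag_library(li$species, li$stage, li$counts, config$filter,
                       raw_reads = li$raw_reads)
    clean_path <- file.path(config$out_dir,
                            paste0("clean_", lib_id, ".tsv"))
    write_tag_counts(lib$clean_counts, clean_path)
    note("clean", clean_path, lib$distinct_clean)
    mp <- map_library(lib$clean_counts, index, ambiguous = config$ambiguous)
    map_path <- file.path(config$out_dir, paste0("mapped_", lib_id, ".tsv"))
    write.table(mp$assignments, map_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("map", map_path, nrow(mp$assignments))
    libraries[[lib_id]] <- lib
    mappings[[lib_id]] <- mp
  }

  ## stage 3: quantify
  genes <- sort(unique(unlist(lapply(mappings, function(m) {
    names(m$transcript_counts)
  }), use.names = FALSE)))
  counts <- sapply(names(mappings), function(lib_id) {
    v <- mappings[[lib_id]]$transcript_counts
    out <- setNames(numeric(length(genes)), genes)
    out[names(v)] <- v
    out
  })
  if (length(genes) == 1L) {
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list(genes, names(mappings)))
  }
  depths <- vapply(libraries, function(l) l$clean_tag_total, numeric(1L))
  mat <- expression_matrix(counts, depths)
  mat_path <- file.path(config$out_dir, "expression_counts.tsv")
  write.table(data.frame(gene = rownames(mat$counts), mat$counts,
                         check.names = FALSE),
              mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  note("quant", mat_path, nrow(mat$counts))

  ## stage 4: DE + patterns (two-species designs)
  species <- unique(vapply(libraries, function(l) l$species, character(1L)))
  stages <- unique(vapply(libraries, function(l) l$stage, character(1L)))
  patterns <- NULL
  if (length(species) == 2L &&
      all(paste(rep(species, each = length(stages)), stages,
                sep = ".") %in% colnames(mat$counts))) {
    patterns <- classify_patterns(mat, species, stages,
                                  alpha = config$alpha,
                                  lfc_min = config$lfc_min)
    pat_path <- file.path(config$out_dir, "patterns.tsv")
    write.table(patterns, pat_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("patterns", pat_path, nrow(patterns))
  }

  ## stage 5: per-species Venn of expressed tags across stages
  venn <- lapply(setNames(species, species), function(sp) {
    sets <- lapply(stages, function(st) {
      lib <- libraries[[paste(sp, st, sep = ".")]]
      expressed_set(paste(sp, st, sep = "."), lib$clean_counts, "tags")
    })
    if (length(sets) >= 2L && length(sets) <= 4L) venn_partition(sets)
    else NULL
  })
  venn_rows <- do.call(rbind, lapply(names(venn), function(sp) {
    if (is.null(venn[[sp]])) return(NULL)
    data.frame(species = sp, region = names(venn[[sp]]),
               count = as.integer(venn[[sp]]), stringsAsFactors = FALSE)
  }))
  if (!is.null(venn_rows)) {
    venn_path <- file.path(config$out_dir, "venn_tags.tsv")
    write.table(venn_rows, venn_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("venn", venn_path, nrow(venn_rows))
  }

  ## stage 6: summary
  stats <- library_stats_from_results(libraries, mappings)
  summary <- summarize_libraries(stats,
                                 reference_size = index$reference_size)
  sum_path <- file.path(config$out_dir, "library_summary.tsv")
  write.table(summary$per_stage, sum_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("summarize", sum_path, nrow(summary$per_stage))

  list(manifest = do.call(rbind, manifest), summary = summary,
       matrix = mat, mappings = mappings, libraries = libraries,
       patterns = patterns, venn = venn, truth = truth, index = index)
}
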