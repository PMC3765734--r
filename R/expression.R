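## Quantification and differential expression for tag-count data without
## replicates: tags-per-million / RPKM normalization, the exact
## Audic-Claverie test for comparing one count between two libraries of
## known depth, BH-corrected pairwise DE calls, and the two-way S/D
## classification of a gene's cross-species developmental profile.

#' Build a gene-by-library expression matrix
#'
#' @param counts gene x library matrix (or coercible) of nonnegative
#'   integer tag counts, with row and column names.
#' @param library_depths named numeric vector of clean-tag totals, one per
#'   column of `counts`. These are the normalization denominators and can
#'   exceed the column sums (clean tags that did not map to any gene still
#'   contribute to sequencing depth).
#' @param transcript_lengths optional named numeric vector (nt) for RPKM.
#' @return object of class `ExpressionMatrix` with `counts`, `tpm`,
#'   optionally `rpkm`, and `library_depths`.
#' @export
expression_matrix <- function(counts, library_depths,
                              transcript_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    dge_error("counts must have gene row names and library column names",
              "dgetag_input_error")
  }
  if (!all(colnames(counts) %in% names(library_depths))) {
    dge_error("every library needs a depth", "dgetag_input_error")
  }
  depths <- library_depths[colnames(counts)]
  norm <- normalize_counts(counts, depths, transcript_lengths)
  structure(list(counts = counts, tpm = norm$tpm, rpkm = norm$rpkm,
                 library_depths = depths),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d libraries (depths %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(format(x$library_depths, big.mark = ","),
                    collapse = ", ")))
  invisible(x)
}

#' Tags-per-million and RPKM normalization
#'
#' `tpm[g,l] = 1e6 * counts[g,l] / depth[l]`;
#' `rpkm[g,l] = 1e9 * counts[g,l] / (depth[l] * length[g])`. RPKM divides
#' by transcript length even though a DGE protocol yields a single tag per
#' transcript regardless of its length, so TPM is the recommended unit;
#' RPKM is provided because it is the unit this class of study reports.
#'
#' @param counts gene x library matrix.
#' @param library_depths numeric vector, one depth per column, all > 0.
#' @param transcript_lengths named numeric vector of lengths (nt) covering
#'   every gene, or NULL to skip RPKM.
#' @return list with `tpm` and `rpkm` (NULL when lengths not given).
#' @export
normalize_counts <- function(counts, library_depths,
                             transcript_lengths = NULL) {
  counts <- as.matrix(counts)
  if (any(library_depths <= 0)) {
    dge_error("library depths must be positive", "dgetag_input_error")
  }
  tpm <- sweep(counts, 2L, library_depths, "/") * 1e6
  rpkm <- NULL
  if (!is.null(transcript_lengths)) {
    missing <- setdiff(rownames(counts), names(transcript_lengths))
    if (length(missing)) {
      dge_error(paste0("no transcript length for: ",
                       paste(missing, collapse = ", ")),
                "dgetag_input_error")
    }
    len <- transcript_lengths[rownames(counts)]
    if (any(len <= 0)) {
      dge_error("transcript lengths must be positive", "dgetag_input_error")
    }
    rpkm <- sweep(tpm, 1L, len / 1e3, "/")
  }
  list(tpm = tpm, rpkm = rpkm)
}

#' Audic-Claverie exact test for two tag counts
#'
#' Exact test for whether a tag's counts `x` (depth `N1`) and `y` (depth
#' `N2`) are consistent with equal underlying expression. Conditional on
#' the pooled count `t = x + y`, `y` follows `Binomial(t, N2/(N1+N2))`
#' under the null; the two-sided p-value doubles the smaller of the lower
#' and upper tail sums (capped at 1). The upper tail equals the classic
#' Audic-Claverie predictive tail
#' `sum over y' >= y of (N2/N1)^y' C(x+y', y') / (1+N2/N1)^(x+y'+1)`
#' term for term, and conditioning on the pooled count makes the test
#' exactly symmetric under swapping the two libraries. Tail terms are
#' accumulated in log space, so depths in the millions and counts in the
#' hundreds of thousands are handled without underflow.
#'
#' @param x,y observed tag counts (nonnegative, vectorized).
#' @param N1,N2 library depths (positive).
#' @return two-sided p-values in (0, 1].
#' @examples
#' ac_test(5, 1e6, 50, 1e6)
#' @export
ac_test <- function(x, N1, y, N2) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  if (any(N1 <= 0 | N2 <= 0)) {
    dge_error("depths must be positive", "dgetag_input_error")
  }
  if (any(x < 0 | y < 0)) {
    dge_error("counts must be nonnegative", "dgetag_input_error")
  }
  vapply(seq_len(n), function(i) {
    ac_test_one(x[i], N1[i], y[i], N2[i])
  }, numeric(1L))
}

ac_test_one <- function(x, N1, y, N2) {
  t <- x + y
  if (t == 0) return(1)
  ## canonical argument order: the test is symmetric under swapping the
  ## libraries, and a fixed order makes that hold to the last bit
  if (x > y || (x == y && N1 > N2)) {
    tmp <- x; x <- y; y <- tmp
    tmp <- N1; N1 <- N2; N2 <- tmp
  }
  q <- N2 / (N1 + N2)
  lt <- stats::dbinom(0:t, t, q, log = TRUE)
  lower <- exp(logsumexp(lt[seq_len(y + 1L)]))        # P(Y <= y)
  upper <- exp(logsumexp(lt[seq.int(y + 1L, t + 1L)])) # P(Y >= y)
  min(1, 2 * min(lower, upper))
}

#' Pairwise differential expression calls
#'
#' For each gene, the Audic-Claverie p-value between two libraries,
#' Benjamini-Hochberg FDR across the genes detected in the pair (>= 1
#' count in either library), and a direction call: `up` / `down` (in
#' library B relative to library A, by the sign of the log2 fold change of
#' pseudocounted TPM) when `fdr <= alpha` and `|lfc| >= lfc_min`, else
#' `unchanged`.
#'
#' @param mat an `ExpressionMatrix`.
#' @param pair character vector of two library (column) names, c(A, B).
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @return data.frame with `gene`, `count_a`, `count_b`, `tpm_a`, `tpm_b`,
#'   `log2_fold_change`, `p_value`, `fdr`, `direction`.
#' @export
call_de <- function(mat, pair, alpha = 0.05, lfc_min = 1.0) {
  stopifnot(inherits(mat, "ExpressionMatrix"), length(pair) == 2L)
  if (!all(pair %in% colnames(mat$counts))) {
    dge_error(paste0("libraries not in matrix: ",
                     paste(setdiff(pair, colnames(mat$counts)),
                           collapse = ", ")),
              "dgetag_input_error")
  }
  a <- mat$counts[, pair[1L]]; b <- mat$counts[, pair[2L]]
  Na <- mat$library_depths[[pair[1L]]]; Nb <- mat$library_depths[[pair[2L]]]
  tpm_a <- mat$tpm[, pair[1L]]; tpm_b <- mat$tpm[, pair[2L]]
  lfc <- log2((tpm_b + 1) / (tpm_a + 1))

  detected <- a + b > 0
  p <- rep(1, length(a))
  p[detected] <- ac_test(a[detected], Na, b[detected], Nb)
  fdr <- rep(1, length(a))
  fdr[detected] <- p.adjust(p[detected], method = "BH")

  direction <- rep("unchanged", length(a))
  sig <- fdr <= alpha & abs(lfc) >= lfc_min
  direction[sig & lfc > 0] <- "up"
  direction[sig & lfc < 0] <- "down"
  data.frame(gene = rownames(mat$counts), count_a = a, count_b = b,
             tpm_a = tpm_a, tpm_b = tpm_b, log2_fold_change = lfc,
             p_value = p, fdr = fdr, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a gene's cross-species developmental pattern as S or D
#'
#' Runs the between-species comparison within each developmental stage and
#' classifies the gene `"D"` (different) if any stage shows a significant
#' direction call, else `"S"` (similar). This formalizes the two-way
#' similar/different split of cross-species tag-copy-number profiles.
#'
#' @param counts_a,counts_b per-stage tag counts for the gene in species A
#'   and B (same length, stage order aligned).
#' @param depths_a,depths_b per-stage clean-tag library depths.
#' @param stages optional stage names (default `embryo`, `larva`, `pupa`,
#'   `adult` when 4 stages are given).
#' @param alpha,lfc_min thresholds as in [call_de()]. With a single gene
#'   there is no multiplicity to correct, so `alpha` applies to the raw
#'   Audic-Claverie p-value; to classify many genes jointly with FDR
#'   control, see [classify_patterns()].
#' @return list with `pattern` (`"S"` or `"D"`) and `stage_calls`
#'   data.frame (stage, counts, lfc, p_value, direction).
#' @export
classify_pattern <- function(counts_a, counts_b, depths_a, depths_b,
                             stages = NULL, alpha = 0.05, lfc_min = 1.0) {
  k <- length(counts_a)
  stopifnot(length(counts_b) == k, length(depths_a) == k,
            length(depths_b) == k)
  if (is.null(stages)) {
    stages <- if (k == 4L) c("embryo", "larva", "pupa", "adult")
              else paste0("stage", seq_len(k))
  }
  p <- ac_test(counts_a, depths_a, counts_b, depths_b)
  tpm_a <- 1e6 * counts_a / depths_a
  tpm_b <- 1e6 * counts_b / depths_b
  lfc <- log2((tpm_b + 1) / (tpm_a + 1))
  direction <- rep("unchanged", k)
  sig <- p <= alpha & abs(lfc) >= lfc_min
  direction[sig & lfc > 0] <- "up"
  direction[sig & lfc < 0] <- "down"
  list(pattern = if (any(direction != "unchanged")) "D" else "S",
       stage_calls = data.frame(stage = stages, count_a = counts_a,
                                count_b = counts_b,
                                log2_fold_change = lfc, p_value = p,
                                direction = direction,
                                stringsAsFactors = FALSE))
}

#' Classify many genes' cross-species patterns with joint FDR control
#'
#' Applies [call_de()] between species within each stage (BH correction
#' across genes per stage) and labels each gene `"D"` if any stage yields a
#' significant direction call, else `"S"`.
#'
#' @param mat an `ExpressionMatrix` whose columns are named
#'   `<species>.<stage>` for exactly two species sharing the same stages.
#' @param species character vector of the two species prefixes.
#' @param stages character vector of stage names.
#' @inheritParams call_de
#' @return data.frame with `gene`, one `direction.<stage>` column per
#'   stage, and `pattern`.
#' @export
classify_patterns <- function(mat, species, stages, alpha = 0.05,
                              lfc_min = 1.0) {
  stopifnot(length(species) == 2L)
  dir_cols <- lapply(stages, function(st) {
    de <- call_de(mat, paste(species, st, sep = "."),
                  alpha = alpha, lfc_min = lfc_min)
    de$direction
  })
  dirs <- do.call(cbind, dir_cols)
  colnames(dirs) <- paste0("direction.", stages)
  data.frame(gene = rownames(mat$counts), dirs,
             pattern = ifelse(rowSums(dirs != "unchanged") > 0, "D", "S"),
             row.names = NULL, stringsAsFactors = FALSE)
}
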