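## Tag-to-gene assignment permitting at most 1 bp mismatch. Resolution is
## two-tier: an exact hit always beats any 1-mismatch hit; within a tier a
## tag hitting a single transcript is assigned, a tag hitting two or more
## is ambiguous. The candidate set at the mismatch tier is found by hashed
## lookup of the full Hamming-1 neighborhood (tag_length x 3 variants).

#' All Hamming-distance-1 neighbors of a tag
#'
#' @param tag nucleotide string over A/C/G/T.
#' @return data.frame with `neighbor`, `position` (1-based mutated
#'   position) and `base`; `3 * nchar(tag)` rows.
#' @export
hamming1_neighbors <- function(tag) {
  n <- nchar(tag)
  chars <- strsplit(tag, "", fixed = TRUE)[[1L]]
  pos <- rep(seq_len(n), each = 3L)
  base <- unlist(lapply(chars, function(ch) setdiff(DNA_BASES, ch)),
                 use.names = FALSE)
  neighbor <- paste0(substr(rep(tag, length(pos)), 1L, pos - 1L), base,
                     substr(rep(tag, length(pos)), pos + 1L, n))
  data.frame(neighbor = neighbor, position = pos, base = base,
             stringsAsFactors = FALSE)
}

#' Assign one tag to the reference
#'
#' @param tag17 tag sequence over A/C/G/T, length matching the index.
#' @param index a `TagIndex` from [build_tag_index()].
#' @return list with `match_class` (`"exact"`, `"one_mismatch"`,
#'   `"ambiguous"`, `"unmapped"`), `transcript_ids` (character vector;
#'   length 1 for exact/one_mismatch, >= 2 for ambiguous, 0 for unmapped)
#'   and `mismatch_position` (1-based position in the tag, `NA` unless
#'   one_mismatch).
#' @export
map_tag <- function(tag17, index) {
  stopifnot(inherits(index, "TagIndex"))
  if (!is.character(tag17) || length(tag17) != 1L ||
      nchar(tag17) != index$tag_length || grepl("[^ACGT]", tag17)) {
    dge_error(sprintf("malformed tag '%s': expected %d nt over A/C/G/T",
                      tag17, index$tag_length),
              "dgetag_input_error")
  }
  i <- match(tag17, index$tags)
  if (!is.na(i)) {
    tx <- index$transcripts[[i]]
    return(list(
      match_class = if (length(tx) == 1L) "exact" else "ambiguous",
      transcript_ids = tx, mismatch_position = NA_integer_))
  }
  nb <- hamming1_neighbors(tag17)
  hit <- match(nb$neighbor, index$tags)
  found <- which(!is.na(hit))
  if (!length(found)) {
    return(list(match_class = "unmapped", transcript_ids = character(0),
                mismatch_position = NA_integer_))
  }
  tx <- unique(unlist(index$transcripts[hit[found]], use.names = FALSE))
  if (length(tx) == 1L) {
    list(match_class = "one_mismatch", transcript_ids = tx,
         mismatch_position = nb$position[found[1L]])
  } else {
    list(match_class = "ambiguous", transcript_ids = sort(tx),
         mismatch_position = NA_integer_)
  }
}

#' Map a clean tag library to the reference
#'
#' Applies [map_tag()] to every distinct clean tag (vectorized over the
#' hashed neighborhood lookups) and aggregates per-transcript counts from
#' unambiguously assigned tags.
#'
#' @param clean named integer vector of clean tag counts.
#' @param index a `TagIndex`.
#' @param ambiguous policy for ambiguous tags in the `mapped_unique_tags`
#'   statistic and per-transcript counts: `"count"` (default; counted as
#'   mapped but excluded from per-transcript counts), `"drop"` (excluded
#'   from both), or `"distribute"` (counted as mapped; clean count split
#'   equally over the candidate transcripts).
#' @return object of class `MappingResult`: `assignments` data.frame (tag,
#'   count, match_class, transcript_ids comma-joined, mismatch_position),
#'   `transcript_counts` named numeric vector, `mapped_unique_tags`,
#'   `genes_hit` (distinct transcripts receiving >= 1 unambiguous tag),
#'   `distinct_clean`, `mapping_ratio`, and per-class distinct-tag counts.
#' @export
map_library <- function(clean, index,
                        ambiguous = c("count", "drop", "distribute")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(inherits(index, "TagIndex"))
  if (length(index$tags) == 0L) {
    warning("empty tag index: all tags unmapped")
  }
  tags <- names(clean)
  cls <- rep("unmapped", length(tags))
  tx_join <- rep("", length(tags))
  mm_pos <- rep(NA_integer_, length(tags))
  tx_sets <- vector("list", length(tags))

  ## exact tier
  ex <- match(tags, index$tags)
  hit_ex <- which(!is.na(ex))
  for (i in hit_ex) {
    tx <- index$transcripts[[ex[i]]]
    tx_sets[[i]] <- tx
    cls[i] <- if (length(tx) == 1L) "exact" else "ambiguous"
  }

  ## 1-mismatch tier, batched: build all neighbors of all unmatched tags
  miss <- which(is.na(ex))
  if (length(miss) && length(index$tags)) {
    n <- index$tag_length
    mtags <- tags[miss]
    for (p in seq_len(n)) {
      left <- substr(mtags, 1L, p - 1L)
      right <- substr(mtags, p + 1L, n)
      orig <- substr(mtags, p, p)
      for (b in DNA_BASES) {
        rel <- which(orig != b)
        if (!length(rel)) next
        hit <- match(paste0(left[rel], b, right[rel]), index$tags)
        ok <- which(!is.na(hit))
        for (k in ok) {
          i <- miss[rel[k]]
          tx_sets[[i]] <- c(tx_sets[[i]], index$transcripts[[hit[k]]])
          if (is.na(mm_pos[i])) mm_pos[i] <- p
        }
      }
    }
    for (i in miss) {
      if (is.null(tx_sets[[i]])) next
      tx <- unique(tx_sets[[i]])
      tx_sets[[i]] <- tx
      if (length(tx) == 1L) {
        cls[i] <- "one_mismatch"
      } else {
        cls[i] <- "ambiguous"
        mm_pos[i] <- NA_integer_
        tx_sets[[i]] <- sort(tx)
      }
    }
  }

  has_tx <- !vapply(tx_sets, is.null, logical(1L))
  tx_join[has_tx] <- vapply(tx_sets[has_tx], paste, character(1L),
                            collapse = ",")

  unambig <- cls %in% c("exact", "one_mismatch")
  tx_counts <- numeric(0)
  if (any(unambig)) {
    tx_counts <- vapply(split(as.numeric(clean[unambig]),
                              unlist(tx_sets[unambig], use.names = FALSE)),
                        sum, numeric(1L))
  }
  if (ambiguous == "distribute") {
    amb <- which(cls == "ambiguous")
    if (length(amb)) {
      share_tx <- unlist(tx_sets[amb], use.names = FALSE)
      share_ct <- rep(as.numeric(clean[amb]) /
                        lengths(tx_sets[amb]), lengths(tx_sets[amb]))
      add <- vapply(split(share_ct, share_tx), sum, numeric(1L))
      all_tx <- union(names(tx_counts), names(add))
      tx_counts <- setNames(
        ifelse(is.na(tx_counts[all_tx]), 0, tx_counts[all_tx]) +
          ifelse(is.na(add[all_tx]), 0, add[all_tx]), all_tx)
    }
  }

  n_amb <- sum(cls == "ambiguous")
  mapped <- sum(unambig) + if (ambiguous == "drop") 0L else n_amb
  structure(list(
    assignments = data.frame(tag = tags, count = as.integer(clean),
                             match_class = cls, transcript_ids = tx_join,
                             mismatch_position = mm_pos,
                             stringsAsFactors = FALSE),
    transcript_counts = tx_counts,
    mapped_unique_tags = as.integer(mapped),
    genes_hit = length(unique(unlist(tx_sets[unambig], use.names = FALSE))),
    distinct_clean = length(tags),
    mapping_ratio = if (length(tags)) mapped / length(tags) else 0,
    class_counts = c(exact = sum(cls == "exact"),
                     one_mismatch = sum(cls == "one_mismatch"),
                     ambiguous = n_amb,
                     unmapped = sum(cls == "unmapped")),
    ambiguous_policy = ambiguous
  ), class = "MappingResult")
}

#' @export
print.MappingResult <- function(x, ...) {
  cat(sprintf(
    "MappingResult: %d/%d uni-tags mapped (%.2f%%), %d genes hit\n  exact %d | one_mismatch %d | ambiguous %d | unmapped %d\n",
    x$mapped_unique_tags, x$distinct_clean, 100 * x$mapping_ratio,
    x$genes_hit, x$class_counts[["exact"]], x$class_counts[["one_mismatch"]],
    x$class_counts[["ambiguous"]], x$class_counts[["unmapped"]]))
  invisible(x)
}
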