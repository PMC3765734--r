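# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (linear scans, direct summation) so it cannot share a
# defect with the vectorized implementations it checks.

random_tags <- function(n, len = 17L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

## A minimal transcript whose only qualifying site is offset 0: any CATG
## inside the 17 nt tag has fewer than 17 nt downstream.
ref_from_tags <- function(tags, ids = sprintf("g%03d", seq_along(tags))) {
  stats::setNames(paste0("CATG", tags), ids)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Brute-force tag-site scan: every position tested directly.
oracle_scan_tags <- function(sequence, tag_length = 17L) {
  n <- nchar(sequence)
  sites <- integer(0)
  tags <- character(0)
  for (i in seq_len(max(n - 3L, 0L))) {
    if (substr(sequence, i, i + 3L) != "CATG") next
    if (i + 3L + tag_length > n) next
    tag <- substr(sequence, i + 4L, i + 3L + tag_length)
    if (grepl("N", tag, fixed = TRUE)) next
    sites <- c(sites, i - 1L)            # 0-based
    tags <- c(tags, tag)
  }
  list(site_offsets = sites, tags = tags,
       canonical = if (length(sites)) length(sites) else NA_integer_)
}

## Brute-force Hamming<=1 assignment over the full reference.
oracle_map_tag <- function(tag, ref_tags, ref_ids) {
  d <- vapply(ref_tags, hamming, integer(1L), a = tag)
  exact <- unique(ref_ids[d == 0L])
  if (length(exact) == 1L) return(list(class = "exact", tx = exact))
  if (length(exact) >= 2L) return(list(class = "ambiguous", tx = sort(exact)))
  near <- unique(ref_ids[d == 1L])
  if (length(near) == 0L) return(list(class = "unmapped", tx = character(0)))
  if (length(near) == 1L) return(list(class = "one_mismatch", tx = near))
  list(class = "ambiguous", tx = sort(near))
}

## Matrix-based brute-force Hamming<=1 classification of many queries
## against a full reference (independent of the hashed neighborhood path).
oracle_map_bulk <- function(queries, ref_tags, ref_ids) {
  refm <- do.call(rbind, strsplit(ref_tags, "", fixed = TRUE))
  cls <- character(length(queries))
  tx <- vector("list", length(queries))
  for (j in seq_along(queries)) {
    qc <- strsplit(queries[j], "", fixed = TRUE)[[1]]
    d <- rowSums(refm != matrix(qc, nrow(refm), length(qc), byrow = TRUE))
    exact <- unique(ref_ids[d == 0])
    if (length(exact)) {
      cls[j] <- if (length(exact) == 1L) "exact" else "ambiguous"
      tx[[j]] <- exact
      next
    }
    near <- unique(ref_ids[d == 1])
    if (length(near) == 0L) {
      cls[j] <- "unmapped"; tx[[j]] <- character(0)
    } else if (length(near) == 1L) {
      cls[j] <- "one_mismatch"; tx[[j]] <- near
    } else {
      cls[j] <- "ambiguous"; tx[[j]] <- near
    }
  }
  list(class = cls, tx = tx)
}

## High-precision conditional tail sums by term recurrence (no dbinom, no
## log-sum-exp): p-value = min(1, 2 * min(P(Y<=y), P(Y>=y))) for
## Y ~ Binomial(x+y, N2/(N1+N2)).
oracle_ac <- function(x, N1, y, N2) {
  t <- x + y
  if (t == 0) return(1)
  q <- N2 / (N1 + N2)
  terms <- numeric(t + 1L)
  terms[1L] <- (1 - q)^t
  for (k in seq_len(t)) {
    terms[k + 1L] <- terms[k] * (q / (1 - q)) * (t - k + 1) / k
  }
  lower <- sum(terms[seq_len(y + 1L)])
  upper <- sum(terms[seq.int(y + 1L, t + 1L)])
  min(1, 2 * min(lower, upper))
}

## order-insensitive comparison of named count vectors
canon_counts <- function(x) x[order(names(x))]

study_depths <- function(species) {
  stats <- helicoverpa_library_stats()
  d <- stats$clean_tags[stats$species == species]
  names(d) <- stats$stage[stats$species == species]
  d[c("embryo", "larva", "pupa", "adult")]
}
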