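#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rlnorm rmultinom runif setNames p.adjust dbinom
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Round half up to a fixed number of decimals
#'
#' Commercial ("round half away from zero") rounding, used for percentage
#' cells in library summary tables so that printed ratios are reproducible
#' independent of the platform's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## log(sum(exp(lx))) without overflow; -Inf-safe
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

## stop() with a classed condition so callers can test error types
dge_error <- function(msg, class) {
  stop(structure(
    class = c(class, "dgetag_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    dge_error(sprintf("field '%s' must be a single number", name),
              "dgetag_config_error")
  }
  if (integer && x != floor(x)) {
    dge_error(sprintf("field '%s' must be an integer", name),
              "dgetag_config_error")
  }
  if (x < min || x > max) {
    dge_error(sprintf("field '%s' = %g out of range [%g, %g]",
                      name, x, min, max),
              "dgetag_config_error")
  }
  invisible(TRUE)
}

## Stable, platform-independent string hash (polynomial rolling, 31-bit).
## Used to derive per-library RNG streams from a master seed so that the
## result does not depend on the order in which libraries are simulated.
stable_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483629
  as.integer(h)
}

## Sequence validation shared by extraction entry points: the allowed
## alphabet is A/C/G/T/N; anything else is reported with its position.
check_nucleotides <- function(sequence, allow_n = TRUE) {
  alphabet <- if (allow_n) c(DNA_BASES, "N") else DNA_BASES
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    dge_error(sprintf("invalid character '%s' at position %d",
                      chars[bad[1L]], bad[1L]),
              "dgetag_input_error")
  }
  invisible(TRUE)
}

## Named-count helpers -------------------------------------------------------

## Collapse a character vector of tags into a named integer count vector,
## sorted by decreasing count then tag (deterministic serialization order).
tabulate_tags <- function(tags) {
  if (!length(tags)) return(setNames(integer(0), character(0)))
  tab <- table(tags)
  counts <- setNames(as.integer(tab), names(tab))
  sort_tag_counts(counts)
}

sort_tag_counts <- function(counts) {
  counts[order(-counts, names(counts), method = "radix")]
}

#' Read a two-column tag-count table
#'
#' @param path TSV with header columns `tag` and `count`.
#' @return named integer vector of counts.
#' @export
read_tag_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer"))
  if (!all(c("tag", "count") %in% names(df))) {
    dge_error("tag-count table must have columns 'tag' and 'count'",
              "dgetag_input_error")
  }
  setNames(df$count, df$tag)
}

#' Write a two-column tag-count table
#'
#' @param counts named integer vector (names are tag sequences).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_tag_counts <- function(counts, path) {
  counts <- sort_tag_counts(counts)
  df <- data.frame(tag = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
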