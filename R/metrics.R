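# Repertoire summary metrics on clonotype frequencies.  All metrics
# depend only on relative frequencies, so they are invariant under any
# uniform rescaling of counts; primer-pair normalization changes them
# only by shifting weight between pairs.

#' Clonotype relative frequencies from counts
#'
#' @param counts non-negative counts (raw or normalized); zero-count
#'   clones are dropped.
#' @return a frequency vector summing to 1.
#' @export
clone_frequencies <- function(counts) {
  if (length(counts) == 0) stop("empty repertoire")
  if (any(counts < 0)) stop("counts must be >= 0")
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all counts are zero")
  counts / sum(counts)
}

.check_freqs <- function(freqs) {
  if (length(freqs) == 0) stop("empty frequency vector")
  if (any(freqs <= 0)) stop("frequencies must be > 0")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  freqs
}

#' Shannon diversity index
#'
#' `H = -sum p_k log(p_k)` (natural log); ranges from 0 (monoclonal) to
#' `log(S)` (uniform over `S` clonotypes).
#'
#' @param freqs clonotype frequencies (positive, summing to 1).
#' @return `H` in nats.
#' @examples
#' shannon_diversity(c(0.5, 0.25, 0.25))  # 1.0397
#' @export
shannon_diversity <- function(freqs) {
  freqs <- .check_freqs(freqs)
  -sum(freqs * log(freqs))
}

#' Clonality (normalized evenness complement)
#'
#' `1 - H / log(S)`: 0 for a perfectly even repertoire, approaching 1 as
#' a single clone dominates.  Defined as 1 (with a warning) for the
#' degenerate single-clone repertoire.
#'
#' @param freqs clonotype frequencies.
#' @return clonality in `[0, 1]`.
#' @export
clonality <- function(freqs) {
  freqs <- .check_freqs(freqs)
  S <- length(freqs)
  if (S == 1) {
    warning("single-clone repertoire: clonality defined as 1")
    return(1)
  }
  1 - shannon_diversity(freqs) / log(S)
}

#' Maximum clonal frequency
#'
#' @param freqs clonotype frequencies.
#' @return `max(p_k)`.
#' @export
max_clonal_frequency <- function(freqs) {
  max(.check_freqs(freqs))
}

#' Total frequency of hyperexpanded clones
#'
#' Sum of the frequencies of clones with `p_k > threshold`.
#'
#' @param freqs clonotype frequencies.
#' @param threshold frequency cutoff in (0, 1); default 0.01.
#' @return the hyperexpanded fraction in `[0, 1]`.
#' @export
hyperexpanded_fraction <- function(freqs, threshold = 0.01) {
  freqs <- .check_freqs(freqs)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  sum(freqs[freqs > threshold])
}

#' All repertoire metrics for a clonotype table
#'
#' Computes frequencies from `normalized_count` when present (falling
#' back to `count`) and returns the four summary metrics plus richness.
#'
#' @param table a clonotype data.frame.
#' @param hyper_threshold cutoff for [hyperexpanded_fraction()].
#' @param use either `"auto"` (normalized counts if available), `"raw"`
#'   or `"normalized"`.
#' @return a one-row data.frame: `n_clonotypes`, `shannon_diversity`,
#'   `clonality`, `max_clonal_frequency`, `hyperexpanded_fraction`.
#' @export
repertoire_metrics <- function(table, hyper_threshold = 0.01,
                               use = c("auto", "raw", "normalized")) {
  use <- match.arg(use)
  counts <- switch(use,
    auto = if ("normalized_count" %in% names(table))
      table$normalized_count else table$count,
    raw = table$count,
    normalized = table$normalized_count)
  if (is.null(counts)) stop("requested counts column absent from table")
  counts <- counts[!is.na(counts)]
  p <- clone_frequencies(counts)
  data.frame(
    n_clonotypes = length(p),
    shannon_diversity = shannon_diversity(p),
    clonality = if (length(p) == 1) 1 else clonality(p),
    max_clonal_frequency = max_clonal_frequency(p),
    hyperexpanded_fraction = hyperexpanded_fraction(p, hyper_threshold)
  )
}
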