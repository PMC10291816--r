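# Per-primer-pair scaling factors.  Batch-mean: SF_i = C_i. / C_.. where
# C_i. is template i's mean count over the batch and C_.. the mean of the
# 260 row means.  NB-mean: m_i / m. from per-template NB fits.  The two
# coincide exactly when the fits come from the same matrix, because the
# NB mean MLE is the arithmetic mean.  Both sets average to 1 by
# construction.

new_scaling_factors <- function(factors, method, batches = NA_character_) {
  vj <- template_vj()
  out <- cbind(vj, data.frame(factor = as.numeric(factors)))
  rownames(out) <- template_labels()
  structure(out, method = method, batches = batches,
            class = c("scaling_factors", "data.frame"))
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat(sprintf("Scaling factor set (%s): %d templates, range [%.3g, %.3g]\n",
              attr(x, "method"), nrow(x),
              min(x$factor, na.rm = TRUE), max(x$factor, na.rm = TRUE)))
  if (any(is.na(x$factor)))
    cat(" ", sum(is.na(x$factor)), "template(s) flagged unusable (zero mean)\n")
  invisible(x)
}

#' Batch-mean scaling factors from an ST count matrix
#'
#' `factor_i = C_i. / C_..` with `C_i.` the mean count of template `i`
#' across the batch and `C_..` the mean of the 260 template means.  The
#' factors average to exactly 1.
#'
#' @param matrix an `st_counts` matrix (>= 1 sample column).
#' @return a `scaling_factors` data.frame (columns `v_index`, `j_index`,
#'   `factor`; templates with zero mean get `NA` and are flagged).
#' @examples
#' m <- st_count_matrix(matrix(rep(c(12L, 24L, 36L), length.out = 260),
#'                             ncol = 1))
#' head(batch_mean_scaling_factors(m))
#' @export
batch_mean_scaling_factors <- function(matrix) {
  if (ncol(matrix) < 1) stop("need at least one sample column")
  row_means <- rowMeans(matrix)
  grand <- mean(row_means)
  if (grand == 0) stop("all-zero count matrix: no scale defined")
  f <- row_means / grand
  f[row_means == 0] <- NA_real_
  new_scaling_factors(f, "batch_mean")
}

#' NB-mean scaling factors from per-template fits
#'
#' `factor_i = m_i / m.` with `m.` the average of the 260 fitted means.
#' Numerically identical to [batch_mean_scaling_factors()] on the matrix
#' the fits came from, but usable when the means were estimated on
#' independent ST-only data and the samples to normalize contain no ST.
#'
#' @param fits a data.frame from [fit_nb_matrix()] (260 rows, column `m`),
#'   or a numeric vector of 260 fitted means.
#' @return a `scaling_factors` data.frame; zero-mean templates get `NA`.
#' @export
nb_mean_scaling_factors <- function(fits) {
  m <- if (is.data.frame(fits)) fits$m else as.numeric(fits)
  if (length(m) != N_TEMPLATES)
    stop("need ", N_TEMPLATES, " fitted means, got ", length(m))
  grand <- mean(m)
  if (grand == 0) stop("all fitted means are zero: no scale defined")
  f <- m / grand
  f[m == 0] <- NA_real_
  new_scaling_factors(f, "nb_mean")
}

#' Pool per-template mean estimates across batches
#'
#' Batches sequenced at different ST concentrations (or depths) cannot be
#' averaged directly.  Each batch's mean vector is first reduced to
#' relative frequencies (divided by its own sum), removing the overall
#' concentration; the frequency vectors are then averaged with weights
#' proportional to the batches' sample counts; finally the result is
#' rescaled so its grand mean equals the weighted mean of the batch grand
#' means.  Multiplying any batch by a positive constant leaves the
#' combined scaling factors unchanged.
#'
#' @param mean_vectors list of numeric vectors (equal length, one mean per
#'   template) — typically the `m` columns of [fit_nb_matrix()] results.
#' @param weights per-batch sample counts (same length as the list).
#' @return the combined mean vector (same length as the inputs).
#' @export
combine_batches <- function(mean_vectors, weights = NULL) {
  stopifnot(length(mean_vectors) >= 1)
  if (is.null(weights)) weights <- rep(1, length(mean_vectors))
  stopifnot(length(weights) == length(mean_vectors), all(weights > 0))
  len <- unique(vapply(mean_vectors, length, integer(1)))
  if (length(len) != 1) stop("batch mean vectors must have equal length")
  sums <- vapply(mean_vectors, sum, numeric(1))
  if (any(sums == 0)) stop("zero-sum batch mean vector")
  freq <- mapply(function(v, s) v / s, mean_vectors, sums, SIMPLIFY = FALSE)
  w <- weights / sum(weights)
  combined_freq <- Reduce(`+`, mapply(function(f, wi) f * wi, freq, w,
                                      SIMPLIFY = FALSE))
  grand_means <- vapply(mean_vectors, mean, numeric(1))
  target_mean <- sum(w * grand_means)
  combined_freq * target_mean / mean(combined_freq)
}

#' Log-scale concordance between two scaling factor sets
#'
#' Pearson correlation between the natural-log factors of two sets -- the
#' standard stability check between calibration batches (published
#' calibrations report r in the 0.83-0.97 range between independent
#' ST-only batches).
#'
#' @param a,b `scaling_factors` objects (or numeric vectors) of equal
#'   length with strictly positive factors.
#' @return the Pearson correlation of the log factors.
#' @export
scaling_concordance <- function(a, b) {
  fa <- if (is.data.frame(a)) a$factor else as.numeric(a)
  fb <- if (is.data.frame(b)) b$factor else as.numeric(b)
  stopifnot(length(fa) == length(fb))
  if (any(!is.finite(fa)) || any(!is.finite(fb)) ||
      any(fa <= 0) || any(fb <= 0))
    stop("scaling factors must be positive and finite for log concordance")
  cor(log(fa), log(fb))
}

#' Read / write scaling factor sets as TSV
#'
#' Columns `v_index`, `j_index`, `factor`, `method`.
#'
#' @param path file path.
#' @param x a `scaling_factors` object (for writing).
#' @return `read_scaling_factors` returns a `scaling_factors` object.
#' @export
read_scaling_factors <- function(path) {
  df <- read.delim(path)
  df <- df[order(template_index(df$v_index, df$j_index)), , drop = FALSE]
  new_scaling_factors(df$factor, method = df$method[1])
}

#' @rdname read_scaling_factors
#' @export
write_scaling_factors <- function(x, path) {
  out <- data.frame(v_index = x$v_index, j_index = x$j_index,
                    factor = x$factor, method = attr(x, "method"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
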