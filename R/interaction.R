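# V x J primer dependence.  ST counts pooled over samples form a 20 x 13
# contingency table; deviations from row-column independence are scored
# as signed Pearson residuals (O - E) / sqrt(E) with
# E = row total x column total / grand total.  Patches of same-sign
# residuals mean groups of V primers and groups of J primers become over-
# or under-represented together -- the dependence that lets normalization
# beat the iid lower bound.

#' Pool an ST count matrix into a 20 x 13 V x J table
#'
#' @param matrix an `st_counts` matrix.
#' @return a 20 x 13 numeric matrix `O`; `O[v, j]` is the total count of
#'   template (v, j) over all samples.
#' @export
pooled_vj_table <- function(matrix) {
  stopifnot(nrow(matrix) == N_TEMPLATES)
  O <- matrix(rowSums(matrix), nrow = N_V, ncol = N_J, byrow = TRUE)
  dimnames(O) <- list(sprintf("V%02d", seq_len(N_V)),
                      sprintf("J%02d", seq_len(N_J)))
  O
}

#' Signed Pearson residuals of a V x J table
#'
#' `R[v, j] = (O - E) / sqrt(E)` with `E = row total * column total /
#' grand total`.  The sum of `R^2` over cells is the chi-squared statistic
#' for independence.  Cells in all-zero rows or columns have no defined
#' expectation and are returned as `NA`.
#'
#' @param table a 20 x 13 (or any 2-d) non-negative count matrix.
#' @return a matrix of residuals, same shape, with attribute
#'   `"chi_squared"` (sum of squared residuals over defined cells).
#' @export
pearson_residuals <- function(table) {
  O <- as.matrix(table)
  if (any(O < 0)) stop("counts must be >= 0")
  total <- sum(O)
  if (total <= 0) stop("grand total must be > 0")
  E <- outer(rowSums(O), colSums(O)) / total
  R <- (O - E) / sqrt(E)
  R[E == 0] <- NA_real_
  attr(R, "chi_squared") <- sum(R[!is.na(R)]^2)
  R
}

#' Row and column orderings for a residual heatmap
#'
#' Average-linkage hierarchical clustering on Euclidean distances between
#' residual rows (and, separately, columns), as used to reveal blocks of
#' jointly over-/under-represented primers.  Deterministic given the
#' input; when all pairwise distances are equal (e.g. an all-zero
#' residual matrix) the input order is kept.
#'
#' @param residuals a residual matrix from [pearson_residuals()].
#' @return a list with integer vectors `rows` and `cols`.
#' @export
cluster_residuals <- function(residuals) {
  R <- as.matrix(residuals)
  if (any(is.na(R))) stop("residual matrix must be complete for clustering")
  ord <- function(m) {
    if (nrow(m) < 3) return(seq_len(nrow(m)))
    dd <- dist(m)
    if (max(dd) - min(dd) < 1e-12) return(seq_len(nrow(m)))
    hclust(dd, method = "average")$order
  }
  list(rows = ord(R), cols = ord(t(R)))
}

#' Heatmap of V x J Pearson residuals
#'
#' Draws the clustered residual matrix with a symmetric blue-white-red
#' palette (white = independence).
#'
#' @param residuals a residual matrix from [pearson_residuals()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, the cluster orderings used.
#' @export
plot_vj_residuals <- function(residuals, ...) {
  ords <- cluster_residuals(residuals)
  R <- as.matrix(residuals)[ords$rows, ords$cols, drop = FALSE]
  lim <- max(abs(R))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  graphics::image(seq_len(ncol(R)), seq_len(nrow(R)), t(R),
                  zlim = c(-lim, lim), col = pal,
                  xlab = "J primer", ylab = "V primer", axes = FALSE, ...)
  graphics::axis(1, seq_len(ncol(R)), colnames(R), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(R)), rownames(R), las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(ords)
}

#' Monte-Carlo independence null for the normalized-count spread
#'
#' How much residual spread would remain after self-normalization if the
#' 260 templates were truly independent, identically distributed
#' NB(m, d) counts?  Each replicate draws an iid count matrix,
#' self-normalizes it with its own batch-mean factors, and records two
#' within-sample spread statistics of the normalized counts: the
#' log-ratio of the maximum to the minimum, and the IQR of the logs.
#' The empirical distribution is a lower bound on the spread achievable
#' by normalization under independence; observed spreads below it imply
#' dependence between templates.
#'
#' @param m common NB mean.
#' @param d common NB overdispersion (variance `m + d m^2`).
#' @param n_templates number of templates (260 for the full panel).
#' @param n_samples samples per replicate batch.
#' @param reps number of Monte-Carlo replicates.
#' @param seed integer seed (mandatory: the distribution is reproducible).
#' @return a data.frame with one row per (replicate, sample):
#'   `rep`, `sample`, `log_max_min_ratio`, `log_iqr`.  Zero normalized
#'   counts (possible at small `m`) are excluded from the logs.
#' @export
independence_null_spread <- function(m, d, n_templates = 260L,
                                     n_samples = 20L, reps = 100L,
                                     seed) {
  stopifnot(reps >= 1, m > 0, d >= 0, n_templates >= 2, n_samples >= 1)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    C <- matrix(if (d == 0) rpois(n_templates * n_samples, m)
                else rnbinom(n_templates * n_samples, size = 1 / d, mu = m),
                nrow = n_templates)
    C <- C[rowMeans(C) > 0, , drop = FALSE]  # all-zero rows carry no scale
    f <- rowMeans(C) / mean(rowMeans(C))
    norm <- C / f
    stats <- t(apply(norm, 2L, function(x) {
      x <- x[x > 0]
      lx <- log(x)
      c(log(max(x) / min(x)), IQR(lx))
    }))
    out[[r]] <- data.frame(rep = r, sample = seq_len(n_samples),
                           log_max_min_ratio = stats[, 1],
                           log_iqr = stats[, 2])
  }
  do.call(rbind, out)
}
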