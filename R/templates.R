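# Template indexing: the 260 synthetic templates are laid out in a fixed
# row order i = (v - 1) * N_J + j, v = 1..20, j = 1..13, used everywhere a
# length-260 vector or a 260-row matrix appears.

N_V <- 20L
N_J <- 13L
N_TEMPLATES <- N_V * N_J

#' Template index and labels for the 20 x 13 primer-pair grid
#'
#' The 260 synthetic templates are ordered by V primer, then J primer:
#' template \eqn{i = (v - 1) \cdot 13 + j}.  All count matrices, scaling
#' factor sets and pooled tables in the package follow this order.
#'
#' @param v,j integer vectors of V (1..20) and J (1..13) primer indices.
#' @return `template_index` returns the row index 1..260;
#'   `template_labels` returns the canonical row labels
#'   (`"V01J01"` ... `"V20J13"`); `template_vj` returns a two-column
#'   data.frame of (v_index, j_index) for rows 1..260.
#' @examples
#' template_index(1, 1)   # 1
#' template_index(20, 13) # 260
#' @export
template_index <- function(v, j) {
  stopifnot(all(v >= 1L & v <= N_V), all(j >= 1L & j <= N_J))
  (as.integer(v) - 1L) * N_J + as.integer(j)
}

#' @rdname template_index
#' @export
template_labels <- function() {
  vj <- template_vj()
  sprintf("V%02dJ%02d", vj$v_index, vj$j_index)
}

#' @rdname template_index
#' @export
template_vj <- function() {
  data.frame(
    v_index = rep(seq_len(N_V), each = N_J),
    j_index = rep(seq_len(N_J), times = N_V)
  )
}

#' Construct and validate an ST count matrix
#'
#' An ST count matrix holds non-negative integer counts for the 260
#' templates (rows, canonical order) across `n` samples (columns).
#'
#' @param counts numeric matrix, 260 rows, counts >= 0.
#' @param sample_ids optional character vector of column labels.
#' @return an integer matrix of class `st_counts` with canonical rownames.
#' @export
st_count_matrix <- function(counts, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != N_TEMPLATES)
    stop("ST count matrix must have ", N_TEMPLATES, " rows, got ", nrow(counts))
  if (any(is.na(counts)) || any(counts < 0))
    stop("ST counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("ST counts must be integers")
  storage.mode(counts) <- "integer"
  rownames(counts) <- template_labels()
  if (!is.null(sample_ids)) {
    stopifnot(length(sample_ids) == ncol(counts))
    colnames(counts) <- sample_ids
  } else if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  }
  class(counts) <- c("st_counts", class(counts))
  counts
}

#' Read / write ST count matrices as TSV
#'
#' The on-disk layout has columns `v_index`, `j_index`, then one column per
#' sample; rows in canonical template order.
#'
#' @param path file path.
#' @param x an `st_counts` matrix (for writing).
#' @return `read_st_counts` returns an `st_counts` matrix.
#' @export
read_st_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("v_index", "j_index")
  if (!all(need %in% names(df)))
    stop("count matrix TSV must have v_index and j_index columns")
  ord <- order(template_index(df$v_index, df$j_index))
  df <- df[ord, , drop = FALSE]
  m <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  st_count_matrix(m, sample_ids = colnames(m))
}

#' @rdname read_st_counts
#' @export
write_st_counts <- function(x, path) {
  vj <- template_vj()
  out <- cbind(vj, as.data.frame(unclass(x)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
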