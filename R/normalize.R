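# Normalization of clonotype tables.  Clonotype counts are aggregated to
# primer-pair totals C_i, each total is divided by its scaling factor
# (C_i' = C_i / SF_i for batch-mean factors, C_i'' = (m. / m_i) C_i for
# NB-mean factors), and each clonotype receives the same proportion of
# the normalized total as it held of the raw total -- so within-pair
# ratios and ranks are untouched and only pair-to-pair weights change.

#' Read / write a gene-to-primer map
#'
#' Multiplex panels are many-to-one: several V (or J) gene segments can be
#' amplified by the same primer.  The map is a TSV with columns `gene`,
#' `segment` (`"V"` or `"J"`) and `primer_index` (1..20 for V, 1..13 for
#' J).
#'
#' @param path file path.
#' @param map a primer-map data.frame (for writing).
#' @return `read_primer_map` returns the validated data.frame.
#' @export
read_primer_map <- function(path) {
  map <- read.delim(path, colClasses = c("character", "character", "integer"))
  validate_primer_map(map)
}

#' @rdname read_primer_map
#' @export
write_primer_map <- function(map, path) {
  validate_primer_map(map)
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_primer_map <- function(map) {
  stopifnot(all(c("gene", "segment", "primer_index") %in% names(map)))
  if (!all(map$segment %in% c("V", "J"))) stop("segment must be 'V' or 'J'")
  if (anyDuplicated(map$gene[map$segment == "V"]) ||
      anyDuplicated(map$gene[map$segment == "J"]))
    stop("each gene may map to only one primer")
  v <- map$primer_index[map$segment == "V"]
  j <- map$primer_index[map$segment == "J"]
  if (length(v) && (min(v) < 1 || max(v) > N_V))
    stop("V primer indices must lie in 1..", N_V)
  if (length(j) && (min(j) < 1 || max(j) > N_J))
    stop("J primer indices must lie in 1..", N_J)
  map
}

# Resolve each record's (v_gene, j_gene) to a template row index; NA for
# unmapped genes.
.pair_index <- function(table, map) {
  vmap <- setNames(map$primer_index[map$segment == "V"],
                   map$gene[map$segment == "V"])
  jmap <- setNames(map$primer_index[map$segment == "J"],
                   map$gene[map$segment == "J"])
  v <- vmap[as.character(table$v_gene)]
  j <- jmap[as.character(table$j_gene)]
  ifelse(is.na(v) | is.na(j), NA_integer_, (v - 1L) * N_J + j)
}

#' Read a clonotype table
#'
#' Native dialect: TSV with columns `count`, `v_gene`, `j_gene`,
#' `cdr3_nt` (a `clonotype_id` column is added if absent).  The
#' `"mixcr"` dialect accepts a clonotype-caller export with columns
#' `cloneCount`, `allVHitsWithScore`, `allJHitsWithScore`, `nSeqCDR3`;
#' the top hit is taken and its alignment score stripped.
#'
#' @param path file path.
#' @param dialect `"otsp"` (native) or `"mixcr"`.
#' @return a clonotype data.frame with columns `clonotype_id`, `cdr3_nt`,
#'   `v_gene`, `j_gene`, `count` (plus `normalized_count` if present in
#'   the file).
#' @export
read_clonotypes <- function(path, dialect = c("otsp", "mixcr")) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, check.names = FALSE)
  if (dialect == "mixcr") {
    top_hit <- function(x) sub("\\*.*$", "", sub(",.*$", "", x))
    df <- data.frame(
      cdr3_nt = df$nSeqCDR3,
      v_gene = top_hit(df$allVHitsWithScore),
      j_gene = top_hit(df$allJHitsWithScore),
      count = df$cloneCount
    )
  }
  need <- c("count", "v_gene", "j_gene", "cdr3_nt")
  if (!all(need %in% names(df)))
    stop("clonotype table needs columns: ", paste(need, collapse = ", "))
  if (!"clonotype_id" %in% names(df))
    df$clonotype_id <- sprintf("clone%04d", seq_len(nrow(df)))
  if (any(df$count < 0)) stop("clonotype counts must be >= 0")
  key <- paste(df$cdr3_nt, df$v_gene, df$j_gene)
  if (anyDuplicated(key))
    stop("(cdr3_nt, v_gene, j_gene) must be unique per table")
  keep <- c("clonotype_id", "cdr3_nt", "v_gene", "j_gene", "count",
            intersect("normalized_count", names(df)))
  df[, keep]
}

#' @rdname read_clonotypes
#' @param table a clonotype data.frame (for writing).
#' @export
write_clonotypes <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate clonotype counts to primer-pair totals
#'
#' `C_i` = total count of all clonotypes amplified by primer pair `i`.
#' Records whose V or J gene is absent from the map are excluded and
#' reported via the `"unmapped"` attribute (count of records and total
#' reads routed to the bucket).
#'
#' @param table a clonotype data.frame (see [read_clonotypes()]).
#' @param map a primer map (see [read_primer_map()]).
#' @return a named numeric vector of length 260 in canonical template
#'   order, summing to the table total over mapped records.
#' @export
primer_pair_totals <- function(table, map) {
  validate_primer_map(map)
  totals <- setNames(numeric(N_TEMPLATES), template_labels())
  if (nrow(table) == 0) return(totals)
  idx <- .pair_index(table, map)
  unmapped <- is.na(idx)
  if (any(unmapped))
    warning(sum(unmapped), " record(s) with unmapped genes excluded (",
            sum(table$count[unmapped]), " reads)")
  agg <- tapply(table$count[!unmapped], idx[!unmapped], sum)
  totals[as.integer(names(agg))] <- as.numeric(agg)
  attr(totals, "unmapped") <- c(records = sum(unmapped),
                                reads = sum(table$count[unmapped]))
  totals
}

#' Rescale primer-pair totals by scaling factors
#'
#' Elementwise division `C_i / factor_i`.  A nonzero total at a template
#' whose factor is flagged unusable (zero estimated mean) is an error:
#' silently imputing a factor would fabricate counts.
#'
#' @param totals numeric vector of length 260 (from
#'   [primer_pair_totals()] or an ST count column).
#' @param factors a `scaling_factors` object.
#' @return the normalized totals (length 260).
#' @export
normalize_totals <- function(totals, factors) {
  f <- factors$factor
  stopifnot(length(totals) == N_TEMPLATES, length(f) == N_TEMPLATES)
  bad <- is.na(f) & totals != 0
  if (any(bad))
    stop("no usable scaling factor for pair(s) with nonzero totals: ",
         paste(template_labels()[bad], collapse = ", "))
  out <- ifelse(is.na(f), 0, as.numeric(totals) / f)
  names(out) <- template_labels()
  out
}

#' Reallocate normalized pair totals to clonotypes
#'
#' A clonotype holding proportion `p` of its pair's raw total receives
#' `p` times the normalized pair total.  Per-pair sums of normalized
#' counts equal the normalized totals exactly, and within-pair ratios
#' are preserved.
#'
#' @param table a clonotype data.frame.
#' @param normalized_totals length-260 vector from [normalize_totals()].
#' @param map a primer map.
#' @return `table` with a `normalized_count` column (`NA` for unmapped
#'   records).
#' @export
reallocate_clonotypes <- function(table, normalized_totals, map) {
  idx <- .pair_index(table, map)
  raw_totals <- primer_pair_totals(table, map)
  norm <- rep(NA_real_, nrow(table))
  mapped <- !is.na(idx)
  p <- table$count[mapped] / raw_totals[idx[mapped]]
  norm[mapped] <- p * normalized_totals[idx[mapped]]
  norm[mapped][table$count[mapped] == 0] <- 0  # 0/0 guard for zero-count rows
  table$normalized_count <- norm
  table
}

#' Normalize a clonotype table in one step
#'
#' Convenience wrapper: [primer_pair_totals()] then [normalize_totals()]
#' then [reallocate_clonotypes()].
#'
#' @param table a clonotype data.frame.
#' @param factors a `scaling_factors` object.
#' @param map a primer map.
#' @return `table` with a `normalized_count` column.
#' @export
normalize_clonotypes <- function(table, factors, map) {
  totals <- primer_pair_totals(table, map)
  reallocate_clonotypes(table, normalize_totals(totals, factors), map)
}

#' Normalize an ST count matrix
#'
#' Divides each count column elementwise by the scaling factors.  When
#' the factors are the batch-mean factors of the very matrix being
#' normalized, the grand total is preserved exactly; with independently
#' estimated NB-mean factors it is preserved in expectation.
#'
#' @param matrix an `st_counts` matrix.
#' @param factors a `scaling_factors` object.
#' @return a numeric matrix (not re-rounded to integers) of normalized
#'   counts, same dimensions and labels.
#' @export
normalize_st_counts <- function(matrix, factors) {
  f <- factors$factor
  stopifnot(nrow(matrix) == N_TEMPLATES, length(f) == N_TEMPLATES)
  bad <- is.na(f) & rowSums(matrix) != 0
  if (any(bad))
    stop("no usable scaling factor for template(s) with nonzero counts: ",
         paste(template_labels()[bad], collapse = ", "))
  fdiv <- ifelse(is.na(f), Inf, f)
  out <- unclass(matrix) / fdiv
  dimnames(out) <- dimnames(matrix)
  out
}
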