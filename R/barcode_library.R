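# ST barcode library: one 9-nt barcode shared by all 260 templates plus a
# 16-nt barcode unique to each V x J pair.  Pairwise edit distance between
# the unique barcodes must be >= 3 so that single-edit matching can never
# hit two templates at once (triangle inequality).

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n_seq, len) {
  len <- rep_len(len, n_seq)
  vapply(seq_len(n_seq), function(i)
    paste(sample(DNA_BASES, len[i], replace = TRUE), collapse = ""),
    character(1))
}

#' Generate an ST barcode library
#'
#' Draws a shared 9-nt barcode and 260 unique 16-nt barcodes (one per
#' V x J primer pair) uniformly at random, rejecting candidates that come
#' within edit distance 2 of an already accepted barcode or of the shared
#' barcode, so the library satisfies the minimum-distance-3 design rule.
#'
#' @param seed integer seed; the library is deterministic given the seed.
#' @return an object of class `st_barcode_library`: a list with
#'   `universal_barcode` (9-nt string) and `entries` (data.frame with
#'   columns `v_index`, `j_index`, `unique_barcode`, 260 rows in canonical
#'   template order).
#' @examples
#' lib <- st_barcode_library(seed = 1)
#' nrow(lib$entries)  # 260
#' @export
st_barcode_library <- function(seed = 1L) {
  set.seed(seed)
  universal <- random_dna(1, 9)
  accepted <- character(0)
  while (length(accepted) < N_TEMPLATES) {
    batch <- random_dna(2 * (N_TEMPLATES - length(accepted)), 16)
    for (b in batch) {
      if (length(accepted) == N_TEMPLATES) break
      ok <- all(adist(b, accepted) >= 3) && adist(b, universal) >= 3
      if (ok) accepted <- c(accepted, b)
    }
  }
  lib <- structure(
    list(universal_barcode = universal,
         entries = cbind(template_vj(), unique_barcode = accepted)),
    class = "st_barcode_library")
  validate_barcode_library(lib)
  lib
}

#' Validate an ST barcode library
#'
#' Checks the design invariants: exactly 260 entries covering each
#' (v, j) pair once, all barcodes distinct, and pairwise edit distance
#' >= 3 among unique barcodes (so distance-1 matching is unambiguous).
#'
#' @param lib an `st_barcode_library`.
#' @return `lib`, invisibly; errors if any invariant fails.
#' @export
validate_barcode_library <- function(lib) {
  stopifnot(is.list(lib), !is.null(lib$universal_barcode), !is.null(lib$entries))
  if (nchar(lib$universal_barcode) != 9)
    stop("universal barcode must be 9 nt")
  e <- lib$entries
  if (nrow(e) != N_TEMPLATES)
    stop("library must have exactly ", N_TEMPLATES, " entries")
  if (any(nchar(e$unique_barcode) != 16))
    stop("unique barcodes must be 16 nt")
  idx <- template_index(e$v_index, e$j_index)
  if (any(sort(idx) != seq_len(N_TEMPLATES)))
    stop("every (v_index, j_index) pair must appear exactly once")
  dm <- adist(e$unique_barcode)
  if (min(dm[upper.tri(dm)]) < 3)
    stop("pairwise edit distance between unique barcodes must be >= 3")
  invisible(lib)
}

#' Read / write barcode libraries as TSV
#'
#' The first line is a comment header `# universal_barcode=XXXXXXXXX`,
#' followed by a TSV with columns `v_index`, `j_index`, `unique_barcode`.
#'
#' @param path file path.
#' @param lib an `st_barcode_library` (for writing).
#' @return `read_barcode_library` returns a validated library.
#' @export
read_barcode_library <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# universal_barcode=", first))
    stop("missing '# universal_barcode=' header line in ", path)
  universal <- sub("^# universal_barcode=", "", first)
  e <- read.delim(path, comment.char = "#")
  e <- e[order(template_index(e$v_index, e$j_index)), , drop = FALSE]
  rownames(e) <- NULL
  lib <- structure(list(universal_barcode = universal, entries = e),
                   class = "st_barcode_library")
  validate_barcode_library(lib)
  lib
}

#' @rdname read_barcode_library
#' @export
write_barcode_library <- function(lib, path) {
  validate_barcode_library(lib)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# universal_barcode=%s", lib$universal_barcode), con)
  write.table(lib$entries, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.st_barcode_library <- function(x, ...) {
  cat("ST barcode library:", nrow(x$entries), "templates,",
      "universal barcode", x$universal_barcode, "\n")
  invisible(x)
}
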