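# Demultiplexing merged reads into synthetic-template (ST) and clonotype
# streams.  A read is an ST iff the shared 9-nt barcode occurs somewhere
# in it (either orientation) within `max_edits` Levenshtein edits; the
# template identity is the 16-nt barcode with the minimal edit distance
# over all windows of the read (both orientations), provided that
# minimum is <= `max_edits` and a single template attains it.  Reads
# whose universal barcode matches but whose 16-nt region resolves to no
# template -- or ties between templates -- are dropped as ambiguous.
# The inner scans are C++ (src/edit_scan.cpp).

.check_dna <- function(x, what) {
  if (!nzchar(x)) stop("empty ", what)
  if (grepl("[^ACGTN]", x)) stop(what, " contains letters outside {A,C,G,T,N}")
  x
}

#' Locate a barcode in a sequence by approximate matching
#'
#' Finds the leftmost window of `sequence` whose Levenshtein distance
#' (substitution, insertion and deletion each cost 1) to `barcode` is at
#' most `max_edits`.  `N` bases never match and therefore count as
#' substitutions.
#'
#' @param sequence DNA string to search (alphabet A,C,G,T,N).
#' @param barcode DNA string to search for.
#' @param max_edits maximum edit distance (default 1, the protocol's
#'   "one-nucleotide mismatch or indel" rule).
#' @return a list with elements `start`, `end` (1-based, inclusive) and
#'   `dist` for the leftmost qualifying window, or `NULL` if there is
#'   none.
#' @examples
#' match_barcode("TTACGTACGTATT", "ACGTACGTA", 1)$start  # 3
#' @export
match_barcode <- function(sequence, barcode, max_edits = 1L) {
  .check_dna(sequence, "sequence")
  .check_dna(barcode, "barcode")
  if (max_edits < 0) stop("max_edits must be >= 0")
  hit <- .cpp_infix_find(sequence, barcode, as.integer(max_edits))
  if (hit[["found"]] == 0L) return(NULL)
  end <- hit[["end"]]
  # recover the leftmost window start compatible with that end
  m <- nchar(barcode)
  s0 <- end - m + 1L
  starts <- max(1L, s0 - max_edits):min(end, s0 + max_edits)
  wins <- substring(sequence, starts, end)
  # full-window edit distance ('N' translated so it can never match)
  dists <- drop(adist(chartr("N", "?", wins), barcode))
  # minimal distance wins; ties broken by the leftmost start
  list(start = starts[which.min(dists)], end = end, dist = hit[["dist"]])
}

# Best template for one read: minimal infix edit distance of each 16-nt
# barcode over the given sequences (typically read + reverse complement).
# Returns c(template, dist); template 0 on no-hit or tie between
# distinct templates.
.best_template <- function(seqs, barcodes, max_edits) {
  d <- rep.int(.Machine$integer.max, length(barcodes))
  for (s in seqs) d <- pmin(d, .cpp_infix_dists(s, barcodes))
  dmin <- min(d)
  if (dmin > max_edits) return(c(0L, dmin))
  hits <- which(d == dmin)
  if (length(hits) > 1L) return(c(0L, dmin))
  c(hits, dmin)
}

#' Classify a merged read as ST, clonotype or ambiguous
#'
#' Searches the read and its reverse complement for the library's
#' universal 9-nt barcode within `max_edits` edits.  Reads without it
#' are clonotype reads.  For ST candidates the 16-nt template barcode is
#' looked up first in a window of +/- 4 nt after the position implied by
#' the universal-barcode match (accepting only a unique exact hit
#' there), then by a full scan of both orientations taking the template
#' with the minimal edit distance; no qualifying template, or a tie
#' between distinct templates, makes the read ambiguous.  ST and
#' ambiguous reads are excluded from the clonotype stream.
#'
#' @param sequence DNA string of the merged read.
#' @param library an `st_barcode_library`.
#' @param max_edits maximum edit distance for both barcode searches.
#' @return a list with `class` (one of `"st"`, `"clonotype"`,
#'   `"ambiguous"`) and `template` (row index 1..260, or `NA`).
#' @export
classify_read <- function(sequence, library, max_edits = 1L) {
  .check_dna(sequence, "sequence")
  r <- .classify(sequence, .cpp_revcomp(sequence),
                 library$universal_barcode,
                 library$entries$unique_barcode, as.integer(max_edits))
  list(class = c("st", "clonotype", "ambiguous")[r[1]],
       template = if (r[1] == 1L) r[2] else NA_integer_)
}

# core classification, shared by classify_read and demux_sample
.classify <- function(fwd, rc, universal, barcodes, max_edits) {
  hf <- .cpp_infix_find(fwd, universal, max_edits)
  hr <- .cpp_infix_find(rc, universal, max_edits)
  if (hf[["found"]] == 0L && hr[["found"]] == 0L) return(c(2L, 0L))
  # fast path: unique exact barcode right after the universal barcode,
  # tried in the orientation(s) with a universal hit, best distance first
  ords <- list(c(hf[["found"]], hf[["dist"]], 1L),
               c(hr[["found"]], hr[["dist"]], 2L))
  ords <- Filter(function(o) o[1] == 1L, ords)
  if (length(ords) == 2L && ords[[2]][2] < ords[[1]][2])
    ords <- rev(ords)
  for (o in ords) {
    seq <- if (o[3] == 1L) fwd else rc
    end <- if (o[3] == 1L) hf[["end"]] else hr[["end"]]
    region <- substr(seq, max(1L, end - 3L), min(nchar(seq), end + 21L))
    d <- .cpp_infix_dists(region, barcodes)
    if (min(d) == 0L && sum(d == 0L) == 1L)
      return(c(1L, which.min(d)))
  }
  # slow path: full scan of both orientations, minimal-distance rule
  bt <- .best_template(c(fwd, rc), barcodes, max_edits)
  if (bt[1] == 0L) c(3L, 0L) else c(1L, bt[1])
}

#' Demultiplex one sample's merged reads
#'
#' Applies the classification of [classify_read()] to every read,
#' accumulating per-template ST counts and the clonotype read stream.
#' The three classification totals always sum to the number of input
#' reads.
#'
#' @param reads character vector (or `DNAStringSet`) of merged reads.
#' @param library an `st_barcode_library`.
#' @param max_edits maximum edit distance for barcode matching.
#' @return a list with `counts` (named integer vector, length 260, in
#'   canonical template order), `clonotype_idx` (indices of clonotype
#'   reads in the input), and `summary` (totals for st / clonotype /
#'   ambiguous / input).
#' @export
demux_sample <- function(reads, library, max_edits = 1L) {
  validate_barcode_library(library)
  reads <- as.character(reads)
  max_edits <- as.integer(max_edits)
  uni <- library$universal_barcode
  barcodes <- library$entries$unique_barcode
  rcs <- .cpp_revcomp(reads)
  counts <- setNames(integer(N_TEMPLATES), template_labels())
  cls <- integer(length(reads))
  for (k in seq_along(reads)) {
    r <- .classify(reads[k], rcs[k], uni, barcodes, max_edits)
    cls[k] <- r[1]
    if (r[1] == 1L) counts[r[2]] <- counts[r[2]] + 1L
  }
  summary <- data.frame(
    st = sum(cls == 1L),
    clonotype = sum(cls == 2L),
    ambiguous = sum(cls == 3L),
    input = length(reads)
  )
  list(counts = counts, clonotype_idx = which(cls == 2L),
       summary = summary)
}

#' Demultiplex a FASTQ file on disk
#'
#' File-level wrapper around [demux_sample()]: reads merged reads from a
#' FASTQ file, writes the ST count vector as a one-sample count-matrix
#' TSV, the clonotype stream as FASTQ, and a demux summary TSV.
#'
#' @param fastq path to a FASTQ file (optionally gzipped).
#' @param library an `st_barcode_library` (or path to a library TSV).
#' @param out_prefix prefix for the three output files
#'   (`<prefix>.st_counts.tsv`, `<prefix>.clonotypes.fastq`,
#'   `<prefix>.summary.tsv`).
#' @param sample_id column label for the count vector; defaults to the
#'   FASTQ basename.
#' @param max_edits maximum edit distance for barcode matching.
#' @return invisibly, the [demux_sample()] result.
#' @export
demux_fastq <- function(fastq, library, out_prefix,
                        sample_id = NULL, max_edits = 1L) {
  if (is.character(library)) library <- read_barcode_library(library)
  if (is.null(sample_id))
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  # Biostrings warns about dropped metadata columns on plain FASTQ; benign
  reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq))
  res <- demux_sample(as.character(reads), library, max_edits)
  write_st_counts(
    st_count_matrix(matrix(res$counts, ncol = 1), sample_ids = sample_id),
    paste0(out_prefix, ".st_counts.tsv"))
  Biostrings::writeXStringSet(
    reads[res$clonotype_idx], paste0(out_prefix, ".clonotypes.fastq"),
    format = "fastq", qualities = Biostrings::quality(reads[res$clonotype_idx]))
  write.table(res$summary, paste0(out_prefix, ".summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
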