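# Shared fixtures and independent oracles.  The oracles deliberately use
# utils::adist over exhaustively enumerated windows (pure brute force),
# a different route from the package's C++ scanner.

# one barcode library / bias model reused across test files
TEST_LIB <- st_barcode_library(seed = 101)
TEST_MODEL <- make_bias_model(seed = 202)

rnd_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# all substrings of the given lengths
oracle_windows <- function(seq, lens) {
  n <- nchar(seq)
  unlist(lapply(lens, function(L) {
    if (n < L) return(character(0))
    substring(seq, 1:(n - L + 1), L:n)
  }))
}

# minimum Levenshtein distance between `pattern` and any substring of
# `seq`, exact for all values <= slack (windows of length m +/- slack
# suffice for edit distance <= slack); 'N' translated so it never matches
oracle_min_infix <- function(seq, pattern, slack = 1) {
  m <- nchar(pattern)
  wins <- oracle_windows(seq, max(1, m - slack):(m + slack))
  min(adist(chartr("N", "?", wins), pattern))
}

# brute-force read classification: universal barcode within max_edits in
# either orientation => ST candidate; template = unique barcode with the
# minimal window distance over both orientations
oracle_classify <- function(seq, lib, max_edits = 1) {
  rc <- oracle_revcomp(seq)
  u <- min(oracle_min_infix(seq, lib$universal_barcode, max_edits),
           oracle_min_infix(rc, lib$universal_barcode, max_edits))
  if (u > max_edits) return(list(class = "clonotype", template = NA_integer_))
  wins <- chartr("N", "?", c(oracle_windows(seq, (16 - max_edits):(16 + max_edits)),
                             oracle_windows(rc, (16 - max_edits):(16 + max_edits))))
  d <- apply(adist(wins, lib$entries$unique_barcode), 2, min)
  dmin <- min(d)
  if (dmin > max_edits) return(list(class = "ambiguous", template = NA_integer_))
  hits <- which(d == dmin)
  if (length(hits) > 1) return(list(class = "ambiguous", template = NA_integer_))
  list(class = "st", template = hits)
}

# a 260-row count matrix with prescribed row patterns (recycled)
toy_st_matrix <- function(rows) {
  st_count_matrix(do.call(rbind, rep(rows, length.out = 260)))
}

# hand ST read: 40-nt flank + universal + template barcode + 20-nt flank
hand_st_read <- function(lib, template) {
  paste0(rnd_dna(1, 40), lib$universal_barcode,
         lib$entries$unique_barcode[template], rnd_dna(1, 20))
}

# a random read guaranteed (by the oracle) to contain no universal hit
hand_clonotype_read <- function(lib, len = 150) {
  repeat {
    s <- rnd_dna(1, len)
    if (oracle_min_infix(s, lib$universal_barcode) > 1 &&
        oracle_min_infix(oracle_revcomp(s), lib$universal_barcode) > 1)
      return(s)
  }
}

# small clonotype fixture with a many-to-one V map (V1 and V1alt share
# primer 1)
toy_clonotypes <- function() {
  map <- rbind(
    data.frame(gene = c("V1", "V1alt", "V2"), segment = "V",
               primer_index = c(1L, 1L, 2L)),
    data.frame(gene = c("J1", "J2"), segment = "J",
               primer_index = c(1L, 2L))
  )
  table <- data.frame(
    clonotype_id = c("c1", "c2", "c3"),
    cdr3_nt = c("TGTGCAAGC", "TGTGCAAGG", "TGTGCAAGT"),
    v_gene = c("V1", "V1alt", "V2"),
    j_gene = c("J1", "J1", "J1"),
    count = c(10, 20, 5)
  )
  list(table = table, map = map)
}
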