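test_that("match_barcode implements single-edit Levenshtein window search", {
  bc <- "ACGTACGTA"
  exact <- paste0("TTTT", bc, "GGGG")
  hit <- match_barcode(exact, bc, 1)
  expect_equal(hit$start, 5)
  expect_equal(hit$end, 13)
  expect_equal(hit$dist, 0)

  sub1 <- paste0("TTTT", "ACGTACCTA", "GGGG")
  expect_equal(match_barcode(sub1, bc, 1)$dist, 1)

  # one deletion inside the barcode still matches at max_edits = 1
  del1 <- paste0("TTTT", "ACGTCGTA", "GGGG")
  expect_equal(match_barcode(del1, bc, 1)$dist, 1)

  # two substitutions: no match at 1 edit; oracle confirms distance 2
  sub2 <- paste0("TTTT", "ACGTAATTA", "GGGG")
  expect_null(match_barcode(sub2, bc, 1))
  expect_equal(oracle_min_infix(sub2, bc, slack = 2), 2)

  # N never matches: counts as a substitution
  withN <- paste0("TTTT", "ACGTNCGTA", "GGGG")
  expect_equal(match_barcode(withN, bc, 1)$dist, 1)
  expect_null(match_barcode(withN, bc, 0))

  # leftmost of two exact occurrences
  twice <- paste0("AA", bc, "TTTT", bc)
  expect_equal(match_barcode(twice, bc, 1)$start, 3)

  expect_error(match_barcode("", bc, 1), "empty")
  expect_error(match_barcode("ACGT", "", 1), "empty")
  expect_error(match_barcode("ACGT", bc, -1), "max_edits")
})

test_that("classify_read assigns templates, flags corrupt barcodes, passes clonotypes", {
  set.seed(31)
  for (tpl in c(1L, 137L, 260L)) {
    r <- classify_read(hand_st_read(TEST_LIB, tpl), TEST_LIB)
    expect_equal(r$class, "st")
    expect_equal(r$template, tpl)
    # reverse-complement orientation classifies identically
    r2 <- classify_read(oracle_revcomp(hand_st_read(TEST_LIB, tpl)), TEST_LIB)
    expect_equal(r2$template, tpl)
  }

  # universal barcode present but 16-nt region >= 2 edits from every
  # template barcode -> ambiguous
  junk16 <- strrep("A", 16)
  expect_true(min(adist(junk16, TEST_LIB$entries$unique_barcode)) >= 2)
  amb <- paste0(rnd_dna(1, 40), TEST_LIB$universal_barcode, junk16, rnd_dna(1, 20))
  expect_equal(classify_read(amb, TEST_LIB)$class, "ambiguous")

  r <- classify_read(hand_clonotype_read(TEST_LIB), TEST_LIB)
  expect_equal(r$class, "clonotype")
  expect_true(is.na(r$template))
})

test_that("demux_sample counts a constructed fixture and conserves reads", {
  set.seed(32)
  i11 <- template_index(1, 1)
  i22 <- template_index(2, 2)
  reads <- c(replicate(3, hand_st_read(TEST_LIB, i11)),
             replicate(2, hand_st_read(TEST_LIB, i22)),
             replicate(4, hand_clonotype_read(TEST_LIB)))
  res <- demux_sample(reads, TEST_LIB)
  expect_equal(unname(res$counts[i11]), 3L)
  expect_equal(unname(res$counts[i22]), 2L)
  expect_equal(sum(res$counts), 5L)
  expect_length(res$clonotype_idx, 4)
  expect_equal(res$summary$st + res$summary$clonotype + res$summary$ambiguous,
               res$summary$input)

  empty <- demux_sample(character(0), TEST_LIB)
  expect_equal(sum(empty$counts), 0L)
  expect_length(empty$clonotype_idx, 0)
})

test_that("classification agrees with the brute-force Levenshtein oracle", {
  set.seed(33)
  # random reads plus error- and indel-laden ST reads to hit every branch
  st_counts <- setNames(integer(260), template_labels())
  st_counts[sample(260, 60)] <- 2L
  emitted <- emit_reads(st_counts, NULL, TEST_LIB, error_rate = 0.02,
                        indel_rate = 0.05, seed = 34)
  reads <- c(emitted$sequence, rnd_dna(280, 150))
  for (s in reads) {
    got <- classify_read(s, TEST_LIB)
    want <- oracle_classify(s, TEST_LIB)
    expect_equal(got$class, want$class, info = s)
    if (want$class == "st") expect_equal(got$template, want$template, info = s)
  }
})

test_that("error-free emission round-trips counts exactly", {
  set.seed(35)
  st_counts <- setNames(integer(260), template_labels())
  st_counts[sample(260, 80)] <- sample(1:6, 80, replace = TRUE)
  clones <- data.frame(clonotype_id = c("cA", "cB"),
                       cdr3_nt = rnd_dna(2, 39),
                       v_gene = "TRBV3", j_gene = "TRBJ2",
                       count = c(7L, 3L))
  reads <- emit_reads(st_counts, clones, TEST_LIB, error_rate = 0, seed = 36)
  res <- demux_sample(reads$sequence, TEST_LIB)
  expect_identical(unname(res$counts), unname(as.integer(st_counts)))
  expect_equal(res$summary$clonotype, 10)
  expect_equal(res$summary$ambiguous, 0)

  # seeded emission is reproducible
  again <- emit_reads(st_counts, clones, TEST_LIB, error_rate = 0, seed = 36)
  expect_identical(reads, again)
})

test_that("demux_fastq writes count, clonotype and summary files", {
  set.seed(37)
  st_counts <- setNames(integer(260), template_labels())
  st_counts[1:5] <- 3L
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "s1.fastq")
  emit_reads(st_counts, NULL, TEST_LIB, error_rate = 0, seed = 38, path = fq)
  res <- demux_fastq(fq, TEST_LIB, file.path(dir, "s1"))
  expect_identical(unname(res$counts), unname(as.integer(st_counts)))
  mat <- read_st_counts(file.path(dir, "s1.st_counts.tsv"))
  expect_equal(unname(mat[, 1]), unname(as.integer(st_counts)))
  expect_true(file.exists(file.path(dir, "s1.clonotypes.fastq")))
  expect_true(file.exists(file.path(dir, "s1.summary.tsv")))
})
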