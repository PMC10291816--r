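test_that("primer-pair totals aggregate through the many-to-one gene map", {
  fix <- toy_clonotypes()
  totals <- primer_pair_totals(fix$table, fix$map)
  expect_equal(unname(totals[template_index(1, 1)]), 30)  # V1 + V1alt
  expect_equal(unname(totals[template_index(2, 1)]), 5)
  expect_equal(sum(totals), sum(fix$table$count))

  empty <- primer_pair_totals(fix$table[0, ], fix$map)
  expect_equal(sum(empty), 0)

  single <- fix$table[3, ]
  single$count <- 7
  t1 <- primer_pair_totals(single, fix$map)
  expect_equal(unname(t1[template_index(2, 1)]), 7)
  expect_equal(sum(t1), 7)

  stray <- fix$table
  stray$v_gene[3] <- "V-unknown"
  expect_warning(t2 <- primer_pair_totals(stray, fix$map), "unmapped")
  expect_equal(sum(t2), 30)
  expect_equal(unname(attr(t2, "unmapped")["reads"]), 5)
})

test_that("normalize_totals divides by factors and refuses flagged pairs", {
  # counts engineered so C_.. = 24 exactly: factors (0.5, 1, 1.5) at the
  # first three templates, 1 elsewhere
  counts <- c(12L, 24L, 36L, rep(24L, 257))
  sf <- batch_mean_scaling_factors(st_count_matrix(matrix(counts, ncol = 1)))
  expect_equal(unname(sf$factor[1:3]), c(0.5, 1, 1.5))

  totals <- setNames(numeric(260), template_labels())
  totals[1:3] <- c(12, 24, 36)
  norm <- normalize_totals(totals, sf)
  expect_equal(unname(norm[1:3]), c(24, 24, 24))

  ones <- batch_mean_scaling_factors(toy_st_matrix(list(c(24L, 24L))))
  expect_equal(unname(normalize_totals(totals, ones)), unname(totals))

  # zero-mean template -> NA factor -> loud error if its total is nonzero
  zero_row <- c(0L, rep(24L, 259))
  sf0 <- batch_mean_scaling_factors(st_count_matrix(matrix(zero_row, ncol = 1)))
  expect_true(is.na(sf0$factor[1]))
  expect_error(normalize_totals(totals, sf0), "V01J01")
})

test_that("reallocation gives each clonotype its raw within-pair proportion", {
  fix <- toy_clonotypes()
  # pair (1,1) raw total 30, normalized to 40; pair (2,1) total 5 -> 10
  norm_totals <- setNames(numeric(260), template_labels())
  norm_totals[template_index(1, 1)] <- 40
  norm_totals[template_index(2, 1)] <- 10
  out <- reallocate_clonotypes(fix$table, norm_totals, fix$map)
  expect_equal(out$normalized_count, c(10 / 30 * 40, 20 / 30 * 40, 10))
  # c1 holds p = 1/3 of its pair; 1/3 * 40
  expect_equal(out$normalized_count[1] / sum(out$normalized_count[1:2]),
               fix$table$count[1] / sum(fix$table$count[1:2]))

  # single clone in its pair inherits the full normalized total
  expect_equal(out$normalized_count[3], 10)

  # 30/10 pair scaled by factor 0.5 -> 60/20, ratio 3:1 preserved
  two <- data.frame(clonotype_id = c("a", "b"), cdr3_nt = c("TGTA", "TGTC"),
                    v_gene = "V1", j_gene = "J1", count = c(30, 10))
  nt <- setNames(numeric(260), template_labels())
  nt[template_index(1, 1)] <- 40 / 0.5
  out2 <- reallocate_clonotypes(two, nt, fix$map)
  expect_equal(out2$normalized_count, c(60, 20))
})

test_that("batch-mean self-normalization preserves the ST grand total exactly", {
  m <- toy_st_matrix(list(c(10L, 14L), c(30L, 42L)))
  sf <- batch_mean_scaling_factors(m)
  norm <- normalize_st_counts(m, sf)
  expect_equal(sum(norm), sum(m), tolerance = 1e-9)
  expect_equal(unname(rowMeans(norm)), rep(24, 260))

  set.seed(61)
  r <- st_count_matrix(matrix(rpois(260 * 4, 40), nrow = 260))
  normr <- normalize_st_counts(r, batch_mean_scaling_factors(r))
  expect_equal(sum(normr) / sum(r), 1, tolerance = 1e-9)

  ones <- batch_mean_scaling_factors(toy_st_matrix(list(c(24L, 24L))))
  expect_equal(unname(normalize_st_counts(m, ones)), unname(unclass(m)) * 1)
})

test_that("normalization with true factors preserves totals in expectation and flattens bias", {
  # 200 small batches: mean relative change of the grand total under
  # true-factor normalization is centred at 0
  set.seed(62)
  rel <- replicate(200, {
    st <- simulate_st_matrix(TEST_MODEL, n_samples = 2, depth = 13000,
                             seed = sample.int(1e6, 1))
    sum(normalize_st_counts(st, attr(st, "true_factors"))) / sum(st) - 1
  })
  expect_lt(abs(mean(rel)), 3 * sd(rel) / sqrt(length(rel)) + 0.005)

  # normalized row means are flat within NB sampling tolerance
  st <- simulate_st_matrix(TEST_MODEL, n_samples = 20, depth = 260000, seed = 63)
  norm <- normalize_st_counts(st, attr(st, "true_factors"))
  cv_before <- sd(rowMeans(st)) / mean(rowMeans(st))
  cv_after <- sd(rowMeans(norm)) / mean(rowMeans(norm))
  expect_lt(cv_after, 0.2)
  expect_lt(cv_after, cv_before / 3)
})

test_that("within-pair proportions are invariant under normalization", {
  set.seed(64)
  truth <- simulate_repertoire(40, sigma = 1, seed = 65)
  ex <- simulate_experiment(truth, TEST_MODEL, depth = 2e4, st_mass = 0,
                            gdna_mass = 1, seed = 66)
  sf <- nb_mean_scaling_factors(
    rowMeans(simulate_st_matrix(TEST_MODEL, 10, 130000, seed = 67)))
  out <- normalize_clonotypes(ex$table, sf, truth$map)
  pair <- paste(out$v_gene, out$j_gene)
  for (p in unique(pair)) {
    sel <- pair == p
    if (sum(out$count[sel]) == 0) next
    expect_equal(out$normalized_count[sel] / sum(out$normalized_count[sel]),
                 out$count[sel] / sum(out$count[sel]),
                 tolerance = 1e-12)
  }
  # rank order within the table's pairs is unchanged
  expect_equal(order(out$normalized_count[sel]), order(out$count[sel]))
})

test_that("clonotype readers handle both dialects", {
  dir <- withr::local_tempdir()
  native <- file.path(dir, "native.tsv")
  fix <- toy_clonotypes()
  write_clonotypes(fix$table, native)
  back <- read_clonotypes(native)
  expect_equal(back$count, fix$table$count)
  expect_equal(back$cdr3_nt, fix$table$cdr3_nt)

  mixcr <- file.path(dir, "mixcr.tsv")
  writeLines(c(
    "cloneCount\tallVHitsWithScore\tallJHitsWithScore\tnSeqCDR3",
    "120\tTRBV12-1*00(932.1),TRBV12-2*00(880.0)\tTRBJ2-7*00(211.0)\tTGTGCCAGC",
    "30\tTRBV19*00(700.2)\tTRBJ1-1*00(190.5),TRBJ1-2*00(100)\tTGTGCCAGT"
  ), mixcr)
  mx <- read_clonotypes(mixcr, dialect = "mixcr")
  expect_equal(mx$v_gene, c("TRBV12-1", "TRBV19"))
  expect_equal(mx$j_gene, c("TRBJ2-7", "TRBJ1-1"))
  expect_equal(mx$count, c(120, 30))

  dup <- rbind(fix$table, fix$table[1, ])
  dupf <- file.path(dir, "dup.tsv")
  write_clonotypes(dup, dupf)
  expect_error(read_clonotypes(dupf), "unique")
})
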