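test_that("bias models are seeded, centred, and degenerate correctly", {
  m <- make_bias_model(seed = 5)
  expect_identical(m, make_bias_model(seed = 5))
  expect_lt(abs(mean(m$v_effects)), 1e-12)
  expect_lt(abs(mean(m$j_effects)), 1e-12)

  flat <- make_bias_model(seed = 5, v_sd = 0, j_sd = 0, interaction_sd = 0)
  expect_true(all(bias_model_weights(flat) == 1))
  expect_true(all(true_scaling_factors(flat)$factor == 1))

  # no interaction -> multiplicative efficiencies (rank-1 weight grid)
  mult <- make_bias_model(seed = 6, interaction_sd = 0)
  w <- matrix(bias_model_weights(mult), nrow = 13)  # j fastest in canonical order
  expect_equal(w[2, 2] * w[1, 1], w[2, 1] * w[1, 2], tolerance = 1e-12)

  tf <- true_scaling_factors(make_bias_model(seed = 7))
  expect_lt(abs(mean(tf$factor) - 1), 1e-12)
})

test_that("simulated ST matrices track the requested means and dispersion", {
  st <- simulate_st_matrix(TEST_MODEL, n_samples = 4, depth = 2.6e6, d = 0,
                           seed = 91)
  expect_equal(dim(unclass(st)), c(260, 4))
  w <- bias_model_weights(TEST_MODEL)
  expect_gt(cor(rowMeans(st), w), 0.999)          # means proportional to bias
  cv <- apply(unclass(st), 1, sd) / rowMeans(st)  # Poisson concentration
  expect_lt(median(cv), 0.05)

  # library allocation: same NB marginals, common-mode within samples
  lib_alloc <- simulate_st_matrix(TEST_MODEL, n_samples = 4, depth = 2.6e5,
                                  seed = 92, allocation = "library")
  expect_gt(cor(rowMeans(lib_alloc), w), 0.99)
  expect_identical(st, simulate_st_matrix(TEST_MODEL, n_samples = 4,
                                          depth = 2.6e6, d = 0, seed = 91))
})

test_that("simulated repertoires are valid clonotype tables", {
  mono <- simulate_repertoire(1, sigma = 1, seed = 93)
  expect_equal(nrow(mono$table), 1)
  expect_equal(mono$table$count, 1)

  pair <- simulate_repertoire(2, sigma = 0, seed = 94)
  expect_equal(pair$table$count, c(0.5, 0.5))  # the 50:50 two-clone design

  rep50 <- simulate_repertoire(50, sigma = 1.2, seed = 95)
  tab <- rep50$table
  expect_equal(sum(tab$count), 1)
  expect_false(anyDuplicated(paste(tab$cdr3_nt, tab$v_gene, tab$j_gene)) > 0)
  expect_true(all(grepl("^[ACGT]+$", tab$cdr3_nt)))
  expect_silent(otsp:::validate_primer_map(rep50$map))
  # the map is many-to-one on V genes (21 genes on 20 primers)
  expect_equal(sum(rep50$map$segment == "V"), 21)
  expect_equal(length(unique(rep50$map$primer_index[rep50$map$segment == "V"])), 20)
})

test_that("ST / gDNA competition reduces detected clonotypes monotonically", {
  truth <- simulate_repertoire(300, sigma = 1.5, seed = 96)
  detected <- function(st_mass) {
    mean(vapply(1:6, function(r) {
      ex <- simulate_experiment(truth, TEST_MODEL, depth = 2e4,
                                st_mass = st_mass, gdna_mass = 1,
                                seed = 97 * 100 + r * 7 + round(1000 * st_mass))
      sum(ex$table$count > 0)
    }, numeric(1)))
  }
  ladder <- vapply(c(1, 10, 50, 200), detected, numeric(1))
  expect_true(all(diff(ladder) < 0))

  # st_mass 0: every read is a clonotype read
  ex0 <- simulate_experiment(truth, TEST_MODEL, depth = 1e4, st_mass = 0,
                             gdna_mass = 1, seed = 98)
  expect_equal(sum(ex0$st_counts), 0)
  expect_gt(sum(ex0$table$count), 0)
})

test_that("a bias-free model leaves clone proportions unbiased", {
  flat <- make_bias_model(seed = 8, v_sd = 0, j_sd = 0, interaction_sd = 0)
  truth <- simulate_repertoire(2, sigma = 0, seed = 99)
  ex <- simulate_experiment(truth, flat, depth = 2e5, st_mass = 0.1,
                            gdna_mass = 1, seed = 100)
  p <- ex$table$count[1] / sum(ex$table$count)
  expect_lt(abs(p - 0.5), 0.02)
})

test_that("read emission is seeded and degrades with error rate", {
  set.seed(101)
  st_counts <- setNames(integer(260), template_labels())
  st_counts[sample(260, 40)] <- 3L
  clean <- demux_sample(
    emit_reads(st_counts, NULL, TEST_LIB, error_rate = 0, seed = 102)$sequence,
    TEST_LIB)
  noisy <- demux_sample(
    emit_reads(st_counts, NULL, TEST_LIB, error_rate = 0.3, seed = 102)$sequence,
    TEST_LIB)
  expect_equal(clean$summary$st, sum(st_counts))
  expect_lt(noisy$summary$st, clean$summary$st)
  expect_gt(noisy$summary$ambiguous + noisy$summary$clonotype, 0)
})
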