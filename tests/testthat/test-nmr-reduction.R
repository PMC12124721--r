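test_that("logd_from_nmr implements the double-ratio identity", {
  # identical analyte/standard ratios in both phases -> logD = standard's
  m <- partition_measurement(2, 4, 1, 2, standard_logd = 1.37)
  expect_equal(logd_from_nmr(m), 1.37)
  # octanol ratio 10x the aqueous ratio adds exactly one log unit
  m <- partition_measurement(10, 1, 1, 1, standard_logd = 1.0)
  expect_equal(logd_from_nmr(m), 2.0)
  expect_error(partition_measurement(-1, 1, 1, 1, 1), "strictly positive")
})

test_that("logd_from_nmr is gauge invariant and phase-antisymmetric", {
  set.seed(42)
  for (k in 1:20) {
    v <- runif(4, 0.1, 10)
    sl <- runif(1, -1, 3)
    base <- logd_from_nmr(partition_measurement(v[1], v[2], v[3], v[4], sl))
    # common rescaling of all four integrals changes nothing
    s <- runif(1, 0.01, 100)
    expect_equal(
      logd_from_nmr(partition_measurement(s * v[1], s * v[2], s * v[3],
                                          s * v[4], sl)),
      base)
    # swapping the phases negates (logD - standard_logd)
    swapped <- logd_from_nmr(partition_measurement(v[3], v[4], v[1], v[2], sl))
    expect_equal(swapped - sl, -(base - sl))
  }
})

test_that("replicate aggregation returns mean and sample SD", {
  ms <- gen_partition(2.26, 1.0, noise_cv = 0.01, n_replicates = 3, seed = 11)
  agg <- logd_from_nmr(ms)
  expect_length(agg$logd, 3)
  expect_equal(agg$mean, mean(agg$logd))
  expect_equal(agg$sd, sd(agg$logd))
  expect_warning(logd_from_nmr(ms[1]), "fewer than 2 replicates")
})

test_that("synthetic partitions with 1% noise recover logD to 0.02", {
  agg <- logd_from_nmr(gen_partition(2.26, 1.0, noise_cv = 0.01,
                                     n_replicates = 3, seed = 1))
  expect_lt(abs(agg$mean - 2.26), 0.02)
})

test_that("logd_from_hplc implements the mass-balance volume-ratio formula", {
  expect_equal(logd_from_hplc(100, 50, 1, 1), 0)       # D = 1
  expect_equal(logd_from_hplc(100, 10, 1, 1), log10(9))
  expect_equal(logd_from_hplc(100, 50, 10, 1), 1.0)    # D = 1 x 10
  expect_error(logd_from_hplc(50, 100, 1, 1), "no partitioning")
  expect_error(logd_from_hplc(100, 100, 1, 1), "no partitioning")
})

test_that("fit_titration recovers a noiseless sigmoid to 1e-6", {
  ts <- gen_titration(3.69, shift_acid = -63.2, shift_base = -61.4,
                      ph_grid = seq(0, 8, length.out = 15), noise_sd = 0)
  f <- fit_titration(ts)
  expect_lt(abs(f$pka - 3.69), 1e-6)
  # midpoint property: fitted shift at pH = pKa is the plateau average
  mid <- f$shift_acid + (f$shift_base - f$shift_acid) /
    (1 + 10^(f$pka - f$pka))
  expect_equal(mid, (f$shift_acid + f$shift_base) / 2)
})

test_that("fit_titration is invariant to shift offset and negation", {
  ts <- gen_titration(2.05, -70, -68, noise_sd = 0.01, seed = 5)
  f0 <- fit_titration(ts)
  up <- titration_series(ts$points$ph, ts$points$shift + 100)
  expect_equal(fit_titration(up)$pka, f0$pka, tolerance = 1e-6)
  neg <- titration_series(ts$points$ph, -ts$points$shift)
  expect_equal(fit_titration(neg)$pka, f0$pka, tolerance = 1e-6)
})

test_that("degenerate titrations (no transition) are rejected", {
  flat <- titration_series(seq(0, 8, length.out = 12),
                           rep(-63, 12) + 1e-4 * sin(1:12))
  expect_error(fit_titration(flat), "degenerate")
})

test_that("noisy Monte-Carlo pKa recovery stays within 0.05 on average", {
  errs <- vapply(1:20, function(s) {
    ts <- gen_titration(0.97, -64, -62, ph_grid = seq(-1.5, 3.5, length.out = 15),
                        noise_sd = 0.02, seed = 100 + s)
    abs(fit_titration(ts)$pka - 0.97)
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("second_derivative_pka finds the inflection of a dense sigmoid", {
  ts <- gen_titration(2.43, -63.5, -61.5, ph_grid = seq(0, 6, by = 0.1),
                      noise_sd = 0)
  expect_lt(abs(second_derivative_pka(ts) - 2.43), 0.05)
  # agreement with the parametric fit within 0.15 on noiseless grids
  expect_lt(abs(second_derivative_pka(ts) - fit_titration(ts)$pka), 0.15)
})

test_that("second_derivative_pka rejects series without an inflection", {
  lin <- titration_series(seq(0, 6, by = 0.5), seq(-63, -61, length.out = 13))
  expect_error(second_derivative_pka(lin), "no inflection")
})

test_that("second-derivative route tracks the sigmoid fit under noise", {
  ts <- gen_titration(2.43, -63.5, -61.5, ph_grid = seq(0, 6, by = 0.25),
                      noise_sd = 0.02, seed = 9)
  pka_sd <- suppressWarnings(second_derivative_pka(ts))
  expect_lt(abs(pka_sd - fit_titration(ts)$pka), 0.2)
})

test_that("CSV reduction round-trips partitions and titrations", {
  tmp <- withr::local_tempdir()
  ms <- list(cmp_a = gen_partition(2.26, 1.0, noise_cv = 0, seed = 1),
             cmp_b = gen_partition(0.55, 1.0, noise_cv = 0, seed = 2))
  pp <- file.path(tmp, "p.csv"); sp <- file.path(tmp, "s.csv")
  write_partition_csv(ms, pp, sp)
  red <- reduce_partition_table(pp, sp)
  expect_equal(red$logd_mean[match("cmp_a", red$compound_id)], 2.26)
  expect_equal(red$logd_mean[match("cmp_b", red$compound_id)], 0.55)
  expect_equal(red$n_replicates, c(3L, 3L))

  tser <- list(cmp_a = gen_titration(3.69, -63, -61.5, noise_sd = 0),
               cmp_b = gen_titration(1.49, -70, -68,
                                     ph_grid = seq(-1, 4, length.out = 14),
                                     noise_sd = 0))
  tp <- file.path(tmp, "t.csv")
  write_titration_csv(tser, tp)
  fit <- reduce_titration_table(tp, method = "sigmoid")
  expect_equal(fit$pka[match("cmp_a", fit$compound_id)], 3.69,
               tolerance = 1e-6)
  expect_equal(fit$pka[match("cmp_b", fit$compound_id)], 1.49,
               tolerance = 1e-6)
})
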