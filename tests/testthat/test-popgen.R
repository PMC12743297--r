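test_that("harmonic numbers match hand arithmetic", {
  expect_equal(harmonic_number(2), 1)
  expect_equal(harmonic_number(4), 1 + 1 / 2 + 1 / 3)
  expect_equal(harmonic_number(11), sum(1 / 1:10), tolerance = 1e-12)
  expect_error(harmonic_number(1), ">= 2")
  # digamma variant agrees with the exact sum at integers
  expect_equal(harmonic_number(11, "digamma"), sum(1 / 1:10),
               tolerance = 1e-10)
})

test_that("Watterson's theta scales as K / a_n / L", {
  expect_equal(watterson_theta(0, 20, 1000), 0)
  expect_equal(watterson_theta(10, 11, 1000), 10 / sum(1 / 1:10) / 1000)
  expect_equal(watterson_theta(10, 11, 2000),
               watterson_theta(10, 11, 1000) / 2)
  expect_error(watterson_theta(10, 11, 0), "L must be > 0")
})

test_that("effective population size is theta over twice the mutation rate", {
  expect_equal(effective_population_size(0, 2e-10), 0)
  # the study's printed median theta and mutation rate
  expect_equal(effective_population_size(4.5e-6, 2.0e-10), 11250)
  expect_equal(effective_population_size(4.5e-6, 4.0e-10), 11250 / 2)
  expect_error(effective_population_size(1e-6, 0), "m must be > 0")
})

test_that("temporal F statistic matches its definition and flags x in {0,1}", {
  expect_equal(f_statistic(0.5, 0.5), 0)
  expect_equal(f_statistic(0.5, 0.6), 0.04)
  expect_equal(f_statistic(0.5, 0.4), f_statistic(0.5, 0.6))  # symmetry
  expect_true(is.na(f_statistic(0, 0.3)))
  expect_true(is.na(f_statistic(1, 0.3)))
  expect_error(f_statistic(0.5, 1.2), "\\[0, 1\\]")
})

test_that("generations from F invert the drift expectation", {
  expect_equal(generations_from_f(0, 1000), 0)
  expect_equal(generations_from_f(0.04, 1000), -2000 * log(0.96))
  # small-F limit t ~ 2 ne f
  for (f in c(0.001, 0.005, 0.01)) {
    t <- generations_from_f(f, 500)
    expect_lt(abs(t - 2 * 500 * f) / t, 0.02)
  }
  expect_error(generations_from_f(1, 1000), "\\[0, 1\\)")
  # monotone increasing in f
  fs <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(sapply(fs, generations_from_f, ne = 1000)) > 0))
})

test_that("generation time converts generations to days and hours", {
  # 70 generations over 12 weeks -> ~28.8 hours
  expect_equal(unname(generation_time(70, 84)["hours"]), 28.8)
  expect_equal(unname(generation_time(56, 56)["days"]), 1)
  expect_equal(unname(generation_time(28, 56)["days"]),
               2 * unname(generation_time(56, 56)["days"]))
  expect_true(all(is.na(generation_time(0, 56))))
})

test_that("calibrate_mag equals the manual composition of its atomic steps", {
  d <- simulate_snv_trajectories(drift_sim_config(
    n_snvs = 400, ne_true = 800, gen_time_days_true = 2, elapsed_days = 56,
    depth = 500, seed = 13))
  snvs <- d$snvs
  sm <- mag_summary("SIM_MAG", L = 2e6, n = 501.2, K = 37, elapsed_days = 56)
  got <- calibrate_mag(snvs, sm, m = 2e-10)
  theta <- watterson_theta(37, 501.2, 2e6)
  ne <- effective_population_size(theta, 2e-10)
  keep <- snvs$class == "synonymous" & snvs$x > 0 & snvs$x < 1
  f <- pmin(f_statistic(snvs$x[keep], snvs$y[keep]), 0.95)
  t <- generations_from_f(mean(f, na.rm = TRUE), ne)
  expect_equal(got$theta, theta)
  expect_equal(got$ne, ne)
  expect_equal(got$f_mean, mean(f, na.rm = TRUE))
  expect_equal(got$t_generations, t)
  expect_equal(got$gen_time_days, unname(generation_time(t, 56)["days"]))
})

test_that("calibration degenerate cases behave", {
  snvs <- data.frame(mag_id = "M", contig = "c", pos = 1:10,
                     class = "synonymous", x = seq(0.1, 0.9, length.out = 10),
                     y = seq(0.1, 0.9, length.out = 10),
                     depth_t1 = 100, depth_t2 = 100)
  sm <- mag_summary("M", L = 1e6, n = 100, K = 10)
  got <- calibrate_mag(snvs, sm)
  expect_equal(got$t_generations, 0)          # x = y everywhere
  # doubling elapsed days doubles generation time at fixed t
  snvs$y <- snvs$x + 0.05
  sm112 <- mag_summary("M", L = 1e6, n = 100, K = 10, elapsed_days = 112)
  expect_equal(calibrate_mag(snvs, sm112)$gen_time_days,
               2 * calibrate_mag(snvs, sm)$gen_time_days)
  # no usable silent SNV -> flagged unavailable
  snvs$class <- "nonsynonymous"
  got2 <- calibrate_mag(snvs, sm)
  expect_true(is.na(got2$f_mean) && is.na(got2$t_generations))
  expect_false(is.na(got2$ne))
})

test_that("variant classification equals the brute-force rule on the grid", {
  g <- expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1))
  snvs <- data.frame(mag_id = "M", contig = "c", pos = seq_len(nrow(g)),
                     class = "nonsynonymous", x = g$x, y = g$y,
                     depth_t1 = 50, depth_t2 = 50)
  cls <- classify_variants(snvs)
  for (r in seq_len(nrow(g))) {
    oracle <- bf_classify(g$x[r], g$y[r])
    expect_identical(cls$per_snv$is_new[r], oracle$is_new)
    expect_identical(cls$per_snv$is_sweeping[r], oracle$is_sweeping)
  }
  # sweeping is a subset of new, spot definitions
  expect_true(all(!cls$per_snv$is_sweeping | cls$per_snv$is_new))
  one <- function(x, y) classify_variants(data.frame(
    mag_id = "M", contig = "c", pos = 1, class = "nonsynonymous",
    x = x, y = y, depth_t1 = 50, depth_t2 = 50))$per_snv
  expect_true(one(0, 0.8)$is_new && one(0, 0.8)$is_sweeping)
  expect_true(one(0, 0.5)$is_new && !one(0, 0.5)$is_sweeping)
  expect_false(one(0.1, 0.9)$is_new)
})

test_that("sorting comparison handles identical and noiseless inputs", {
  vals <- c(0.01, 0.03, 0.1, 0.2, 0.5)
  mags <- data.frame(mag_id = letters[1:5], delta_abund = vals)
  snvs <- data.frame(mag_id = letters[1:5], abs_delta_freq = vals)
  sc <- suppressWarnings(sorting_comparison(mags, snvs))
  expect_gt(sc$rank_sum$p, 0.9)  # identical tied samples
  # exact linear relation recovered: |dSNV| = 0.31 * dMAG + 0.13
  x <- seq(-0.3, 0.5, length.out = 9)
  mags2 <- data.frame(mag_id = letters[1:9], delta_abund = x)
  snvs2 <- data.frame(mag_id = letters[1:9],
                      abs_delta_freq = 0.31 * x + 0.13)
  sc2 <- suppressWarnings(sorting_comparison(mags2, snvs2))
  expect_equal(sc2$regression_abund$slope, 0.31, tolerance = 1e-10)
  expect_equal(sc2$regression_abund$intercept, 0.13, tolerance = 1e-10)
  expect_equal(sc2$regression_abund$r_squared, 1, tolerance = 1e-10)
  # same regression against PTR change when provided
  ptr <- data.frame(mag_id = letters[1:9], delta_log2_ptr = 2 * x)
  sc3 <- suppressWarnings(sorting_comparison(mags2, snvs2, ptr))
  expect_equal(sc3$regression_ptr$slope, 0.31 / 2, tolerance = 1e-10)
  # constant predictor flagged undefined
  mags3 <- data.frame(mag_id = letters[1:5], delta_abund = rep(0.1, 5))
  sc4 <- sorting_comparison(mags3, snvs)
  expect_true(sc4$regression_abund$undefined)
})

test_that("relative abundance changes derive from normalised coverages", {
  cov <- data.frame(mag_id = c("a", "b"), cov_t1 = c(10, 30),
                    cov_t2 = c(30, 10))
  ch <- mag_abundance_change(cov)
  expect_equal(ch$delta_abund, c(0.5, -0.5))
  expect_equal(ch$abs_delta_abund, c(0.5, 0.5))
})
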