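test_that("simulated samples conserve reads and obey the seed", {
  cfg <- community_sim_config(n_taxa = 50, n_holes = 2,
                              reads_per_sample = 10000,
                              coloniser_rate = 1, coloniser_freq = 2e-3,
                              seed = 11)
  sim <- simulate_asv_table(cfg)
  expect_true(all(colSums(sim$table) == 10000))
  # bit-identical rerun with the same config + seed
  sim2 <- simulate_asv_table(cfg)
  expect_identical(unclass(sim$table), unclass(sim2$table))
  expect_identical(sim$truth, sim2$truth)
  # different seed changes the draw
  sim3 <- simulate_asv_table(community_sim_config(
    n_taxa = 50, n_holes = 2, reads_per_sample = 10000, coloniser_rate = 1,
    coloniser_freq = 2e-3, seed = 12))
  expect_false(identical(unclass(sim$table), unclass(sim3$table)))
})

test_that("zero colonisation rate plants nothing and residents persist", {
  sim <- simulate_asv_table(community_sim_config(
    n_taxa = 40, n_holes = 2, reads_per_sample = 20000, coloniser_rate = 0,
    seed = 4))
  expect_equal(nrow(sim$truth), 0)
  # residents have expected count >= 5, so none should look like a coloniser
  rep <- coloniser_report(sim$table)
  expect_equal(nrow(rep$colonisers), 0)
})

test_that("planted coloniser count per hole is Poisson with mean rate x duration", {
  # rate 1/week over weeks 0..12 -> mean 12 per hole; 200 seeds x 2 holes
  counts <- unlist(lapply(1:200, function(s) {
    sim <- simulate_asv_table(community_sim_config(
      n_taxa = 20, n_holes = 2, weeks = c(0L, 1L, 2L, 4L, 8L, 12L),
      coloniser_rate = 1, coloniser_freq = 5e-3, reads_per_sample = 3000,
      seed = s))
    tabulate(factor(sim$truth$hole_id, levels = c("H01", "H02")), 2)
  }))
  se <- sqrt(12 / length(counts))
  expect_lt(abs(mean(counts) - 12), 3 * se)
})

test_that("nonsensical coloniser load is rejected", {
  expect_error(community_sim_config(coloniser_rate = 11, coloniser_freq = 0.05),
               "50%")
  expect_error(community_sim_config(weeks = c(0L, 2L, 1L)), "increasing")
})

test_that("drift is negligible in the infinite-population limit", {
  d <- simulate_snv_trajectories(drift_sim_config(
    n_snvs = 1000, ne_true = 1e9, gen_time_days_true = 56, elapsed_days = 56,
    depth = 1e6, init_freq = c(0.2, 0.8), seed = 2))
  expect_lt(mean(abs(d$snvs$y - d$snvs$x)), 0.002)
})

test_that("zero elapsed time leaves only resampling noise", {
  d <- simulate_snv_trajectories(drift_sim_config(
    n_snvs = 500, ne_true = 100, gen_time_days_true = 1, elapsed_days = 0,
    depth = 100, init_freq = c(0.5, 0.5), seed = 3))
  expect_identical(d$truth$wf_steps, 0L)
  f <- f_statistic(d$snvs$x, d$snvs$y)
  expect_gt(mean(f, na.rm = TRUE), 0)
})

test_that("drift matches the closed-form expectation at moderate scale", {
  d <- simulate_snv_trajectories(drift_sim_config(
    n_snvs = 5000, ne_true = 100, gen_time_days_true = 1, elapsed_days = 56,
    depth = 1e5, init_freq = c(0.5, 0.5), seed = 7))
  f <- f_statistic(d$snvs$x, d$snvs$y)
  expected <- 1 - (1 - 1 / (2 * 100))^56
  expect_lt(abs(mean(f, na.rm = TRUE) - expected) / expected, 0.10)
})

test_that("coverage gradient halves expected depth at the terminus for log2 PTR 1", {
  # ori placed on a bin midpoint so both extremes are hit exactly
  cv <- simulate_coverage(coverage_sim_config(
    genome_length = 1e6, ori_position = 5000, log2_ptr_true = 1,
    mean_depth = 100, bin_size = 1e4, seed = 1))
  mu <- cv$truth$expected_depth
  expect_equal(max(mu) / min(mu), 2, tolerance = 1e-12)
  # argmax of the expected profile sits in the bin containing the ori
  mids <- (cv$track$start + cv$track$end) / 2
  expect_equal(mids[which.max(mu)], 5000)
})

test_that("shifting the ori shifts the expected-coverage argmax", {
  for (ori in c(0, 250000, 731000)) {
    cv <- simulate_coverage(coverage_sim_config(
      genome_length = 1e6, ori_position = ori, log2_ptr_true = 1.2,
      mean_depth = 50, bin_size = 1e4, seed = 9))
    mids <- (cv$track$start + cv$track$end) / 2
    d <- pmin(abs(mids[which.max(cv$truth$expected_depth)] - ori),
              1e6 - abs(mids[which.max(cv$truth$expected_depth)] - ori))
    expect_lte(d, 5000)  # within half a bin
  }
})

test_that("flat-genome coverage yields a near-zero fitted PTR", {
  cv <- simulate_coverage(coverage_sim_config(
    genome_length = 1e6, log2_ptr_true = 0, mean_depth = 100,
    bin_size = 1e4, seed = 5))
  est <- estimate_ptr(cv$track, n_bins = 100)
  expect_lt(est$log2_ptr, 0.05)
})

test_that("noiseless time-shift assays invert to the planted interactions", {
  A <- matrix(c(-0.9, -0.1, -0.1,
                -0.2, -0.5, -0.3,
                 0.1, -0.4, -0.6), 3, 3, byrow = TRUE)
  sim <- simulate_timeshift(timeshift_sim_config(
    interaction_true = A, noise_sd = 0, n_holes = 2, seed = 6))
  co <- interaction_coefficient(sim$assays$x_i, sim$assays$x_j,
                                sim$assays$x_ij)
  labs <- sim$truth$timepoints
  rec <- A * NA
  for (r in seq_len(nrow(sim$assays))) {
    rec[match(sim$assays$i[r], labs), match(sim$assays$j[r], labs)] <- co[r]
  }
  expect_equal(rec, A, tolerance = 1e-12)
})

test_that("a planted strongest-inhibition column wins the tally", {
  A <- matrix(-0.1, 3, 3); A[, 2] <- -0.9
  sim <- simulate_timeshift(timeshift_sim_config(
    interaction_true = A, noise_sd = 0.01, n_holes = 1, seed = 8))
  tal <- strongest_reduction_tally(sim$assays)
  expect_equal(unname(tal$column_sums), c(0L, 3L, 0L))
})
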