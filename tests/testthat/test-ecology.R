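test_that("CLR transform centres log counts and handles hand-computed cases", {
  expect_equal(clr_transform(c(5, 5, 5, 5), 0.5), rep(0, 4))
  # (1, 0) with pseudocount 1: +-(log 2)/2
  expect_equal(clr_transform(c(1, 0), 1), c(log(2) / 2, -log(2) / 2),
               tolerance = 1e-12)
  set.seed(1)
  for (k in 1:20) {
    v <- rpois(sample(2:40, 1), lambda = 5)
    expect_lt(abs(sum(clr_transform(v))), 1e-9)
  }
  expect_error(clr_transform(c(3)), "at least 2")
})

test_that("Shannon index matches hand values, bounds and vegan", {
  expect_equal(shannon_index(rep(10, 4)), log(4))
  expect_equal(shannon_index(c(0, 7, 0)), 0)
  expect_equal(shannon_index(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  set.seed(2)
  for (k in 1:10) {
    v <- rmultinom(1, 5000, prop.table(rgamma(30, 0.5)))[, 1]
    # maximal at uniform composition, order-invariant, vegan agreement
    expect_lte(shannon_index(v), log(sum(v > 0)) + 1e-12)
    expect_equal(shannon_index(v), shannon_index(rev(v)))
    skip_if_not_installed("vegan")
    expect_equal(shannon_index(v), unname(vegan::diversity(v)),
                 tolerance = 1e-12)
  }
})

test_that("observed richness counts positive taxa", {
  expect_equal(observed_richness(c(0, 0, 0)), 0)
  expect_equal(observed_richness(c(1, 2, 0)), 2)
  # multinomial with all expected counts >= 5 retains every taxon
  set.seed(3)
  hits <- sapply(1:50, function(k) {
    observed_richness(rmultinom(1, 10000, rep(1 / 50, 50))[, 1]) == 50
  })
  expect_gt(mean(hits), 0.99 - 3 * sqrt(0.01 * 0.99 / 50))
})

test_that("coloniser detection applies the appear-then-persist rule", {
  weeks <- c(0, 1, 2, 4, 8, 12)
  counts <- rbind(
    a = c(0, 0, 3, 1, 2, 5),   # coloniser, first week 2
    b = c(0, 3, 0, 2, 5, 5),   # lapsed after appearance -> not
    c = c(1, 0, 3, 1, 2, 5),   # present at baseline -> not
    d = c(0, 0, 0, 0, 0, 4))   # appears only at the end -> coloniser
  tab <- make_table(counts, weeks)
  got <- detect_colonisers(tab, "H1")
  expect_equal(got$taxon, c("a", "d"))
  expect_equal(got$first_week, c(2, 12))
  # no post-baseline samples rejected
  tab0 <- make_table(counts[, 1, drop = FALSE], 0)
  expect_error(detect_colonisers(tab0, "H1"), "post-baseline")
})

test_that("coloniser detection equals the brute-force oracle", {
  # exhaustively: all presence/absence patterns over six sampled weeks
  weeks <- c(0, 1, 2, 4, 8, 12)
  pats <- as.matrix(expand.grid(rep(list(0:1), 6)))
  rownames(pats) <- sprintf("p%02d", seq_len(nrow(pats)))
  tab <- make_table(pats, weeks)
  got <- detect_colonisers(tab, "H1")
  for (r in seq_len(nrow(pats))) {
    oracle <- bf_is_coloniser(pats[r, ], weeks)
    hit <- rownames(pats)[r] %in% got$taxon
    expect_identical(hit, oracle$coloniser)
    if (oracle$coloniser) {
      expect_equal(got$first_week[got$taxon == rownames(pats)[r]],
                   oracle$first_week)
    }
  }
  # and on random 8-week x 12-taxon tables with a week -7 baseline sample
  weeks8 <- c(-7, 0, 1, 2, 4, 6, 8, 12)
  set.seed(11)
  for (k in 1:20) {
    counts <- matrix(rbinom(12 * 8, 1, 0.45) * rpois(12 * 8, 3), nrow = 12,
                     dimnames = list(sprintf("t%02d", 1:12), NULL))
    tab <- make_table(counts, weeks8)
    got <- detect_colonisers(tab, "H1")
    for (r in seq_len(12)) {
      oracle <- bf_is_coloniser(counts[r, ], weeks8)
      expect_identical(rownames(counts)[r] %in% got$taxon, oracle$coloniser)
    }
  }
})

test_that("coloniser frequency is the coloniser read share, with truth recovery", {
  weeks <- c(0, 2, 4)
  counts <- rbind(a = c(0, 4, 6), b = c(10, 6, 4), c = c(10, 10, 10))
  tab <- make_table(counts, weeks)
  rep <- coloniser_report(tab)
  fr <- coloniser_frequency(tab, rep)
  expect_equal(fr$frequency, c(0, 4 / 20, 6 / 20))
  # all reads from colonisers -> 1; none -> 0 (already covered by week 0)
  counts2 <- rbind(a = c(0, 5), b = c(3, 0))
  # b lapses so only a is a coloniser; second sample is all-coloniser
  tab2 <- make_table(counts2, c(0, 4))
  fr2 <- coloniser_frequency(tab2, coloniser_report(tab2))
  expect_equal(fr2$frequency, c(0, 1))
  # planted simulation truth recovered within binomial error
  sim <- simulate_asv_table(community_sim_config(
    n_taxa = 40, n_holes = 2, coloniser_rate = 2, coloniser_freq = 5e-3,
    reads_per_sample = 50000, seed = 21))
  repS <- coloniser_report(sim$table)
  frS <- coloniser_frequency(sim$table, repS)
  meta <- sample_meta(sim$table)
  for (h in unique(meta$hole_id)) {
    n_active <- sum(sim$truth$hole_id == h & sim$truth$first_week <= 12)
    got <- frS$frequency[frS$hole_id == h & frS$week == 12]
    expected <- n_active * 5e-3
    expect_lt(abs(got - expected), 4 * sqrt(expected / 50000) + 1e-3)
  }
})

test_that("colonisation rate divides by duration", {
  expect_equal(unname(colonisation_rate(133.1, 12)["taxa_per_week"]),
               133.1 / 12)
  expect_equal(unname(colonisation_rate(24, 12)["taxa_per_week"]), 2)
  expect_equal(unname(colonisation_rate(0, 12, 0)),
               c(0, 0))
  expect_error(colonisation_rate(5, 0), "> 0")
})

test_that("pairwise sharing pools reads of jointly present taxa", {
  weeks <- c(0, 4)
  counts <- cbind(c(10, 10, 0), c(0, 0, 0),   # hole A pooled (10, 10, 0)
                  c(0, 10, 10), c(0, 0, 0))   # hole B pooled (0, 10, 10)
  rownames(counts) <- c("x", "y", "z")
  meta <- data.frame(sample_id = c("A0", "A4", "B0", "B4"),
                     hole_id = c("A", "A", "B", "B"), week = c(0, 4, 0, 4),
                     treatment = "control")
  colnames(counts) <- meta$sample_id
  tab <- asv_table(counts, meta)
  M <- pairwise_sharing(tab)
  expect_equal(M["A", "B"], 0.5)
  expect_equal(M, t(M))
  expect_equal(diag(M), c(A = 1, B = 1))
  # identical pooled profiles -> 1; disjoint -> 0
  counts2 <- cbind(c(5, 5), c(5, 5))
  rownames(counts2) <- c("x", "y")
  meta2 <- data.frame(sample_id = c("A0", "B0"), hole_id = c("A", "B"),
                      week = 0, treatment = "control")
  colnames(counts2) <- meta2$sample_id
  expect_equal(pairwise_sharing(asv_table(counts2, meta2))["A", "B"], 1)
  counts3 <- cbind(c(5, 0), c(0, 5))
  rownames(counts3) <- c("x", "y")
  colnames(counts3) <- meta2$sample_id
  expect_equal(pairwise_sharing(asv_table(counts3, meta2))["A", "B"], 0)
})

test_that("mantel test recovers perfect and affine association", {
  set.seed(5)
  pts <- matrix(rnorm(16), 8, 2)
  d1 <- as.matrix(dist(pts))
  m <- mantel_test(d1, d1, n_perm = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 200)
  # affine transform of the distances leaves r = 1
  m2 <- mantel_test(d1, 3 * d1 + 2, n_perm = 99, seed = 1)
  expect_equal(m2$r, 1)
  # agreement of r with vegan's statistic
  skip_if_not_installed("vegan")
  d2 <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
  expect_equal(mantel_test(d1, d2, n_perm = 9, seed = 1)$r,
               unname(vegan::mantel(d1, d2, permutations = 9)$statistic),
               tolerance = 1e-12)
  expect_error(mantel_test(d1, matrix(1, 8, 8), n_perm = 9), "constant")
})
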