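## ---- configuration constructors -------------------------------------------

#' Configuration for simulating an ASV/genus count table with planted colonisers
#'
#' Emulates a tree-hole style sampling design: `n_holes` habitat patches each
#' sampled once per week in `weeks`, with uneven resident relative abundances
#' drawn from a Dirichlet-like distribution and new taxa ("colonisers")
#' arriving at a Poisson rate per hole per week after the baseline week.
#'
#' @param n_taxa number of resident taxa shared by all holes.
#' @param n_holes number of habitat patches (holes).
#' @param weeks strictly increasing integer sampling weeks; weeks `<= 0` are
#'   the pre-perturbation baseline.
#' @param base_abundance_shape gamma/Dirichlet concentration controlling
#'   unevenness of resident abundances (smaller = more uneven).
#' @param coloniser_rate expected number of new persistent taxa arriving per
#'   hole per week after week 0.
#' @param coloniser_freq expected relative frequency of each coloniser once
#'   present, in (0, 1).
#' @param reads_per_sample sequencing reads drawn per sample (multinomial
#'   total).
#' @param seed integer seed; all randomness in [simulate_asv_table()] flows
#'   from it.
#' @return a list of class `community_sim_config`.
#' @export
community_sim_config <- function(n_taxa = 300L,
                                 n_holes = 17L,
                                 weeks = c(0L, 1L, 2L, 4L, 8L, 12L),
                                 base_abundance_shape = 0.3,
                                 coloniser_rate = 11,
                                 coloniser_freq = 2.6e-4,
                                 reads_per_sample = 50000L,
                                 seed = 1L) {
  stopifnot(n_taxa >= 1, n_holes >= 1, reads_per_sample >= 1)
  if (is.unsorted(weeks, strictly = TRUE)) {
    stop("`weeks` must be strictly increasing")
  }
  if (coloniser_rate < 0) stop("`coloniser_rate` must be >= 0")
  if (coloniser_freq <= 0 || coloniser_freq >= 1) {
    stop("`coloniser_freq` must be in (0, 1)")
  }
  if (base_abundance_shape <= 0) stop("`base_abundance_shape` must be > 0")
  duration <- max(max(weeks), 0)
  if (coloniser_freq * coloniser_rate * duration > 0.5) {
    stop("nonsensical config: expected colonisers would occupy > 50% of the community")
  }
  structure(list(n_taxa = as.integer(n_taxa), n_holes = as.integer(n_holes),
                 weeks = as.integer(weeks),
                 base_abundance_shape = base_abundance_shape,
                 coloniser_rate = coloniser_rate,
                 coloniser_freq = coloniser_freq,
                 reads_per_sample = as.integer(reads_per_sample),
                 seed = as.integer(seed)),
            class = "community_sim_config")
}

#' Configuration for neutral SNV trajectories under Wright-Fisher drift
#'
#' The population is haploid with `2 * ne_true` allele copies per generation,
#' so that the diploid-form drift formulas (the factor `2 N_e` in both the
#' Watterson and temporal-F expressions) hold verbatim for the simulated data.
#'
#' @param n_snvs number of independent (unlinked) SNVs.
#' @param ne_true true effective population size (individuals).
#' @param gen_time_days_true true generation time in days.
#' @param elapsed_days days between the two observation timepoints (study
#'   value 56).
#' @param depth read depth per SNV per timepoint; observed frequencies are
#'   binomial draws of this size.
#' @param init_freq numeric of length 2, `c(lo, hi)`: initial allele
#'   frequencies are uniform on this interval (use `lo == hi` for a point
#'   mass).
#' @param class class label to attach to every SNV (default "synonymous").
#' @param seed integer seed.
#' @return a list of class `drift_sim_config`.
#' @export
drift_sim_config <- function(n_snvs = 2000L,
                             ne_true = 5000,
                             gen_time_days_true = 1,
                             elapsed_days = 56,
                             depth = 200L,
                             init_freq = c(0.05, 0.95),
                             class = "synonymous",
                             seed = 1L) {
  stopifnot(n_snvs >= 1, elapsed_days >= 0, depth >= 1,
            gen_time_days_true > 0, length(init_freq) == 2)
  if (ne_true < 2) stop("`ne_true` must be >= 2")
  if (init_freq[1] < 0 || init_freq[2] > 1 || init_freq[1] > init_freq[2]) {
    stop("`init_freq` must satisfy 0 <= lo <= hi <= 1")
  }
  structure(list(n_snvs = as.integer(n_snvs), ne_true = ne_true,
                 gen_time_days_true = gen_time_days_true,
                 elapsed_days = elapsed_days, depth = as.integer(depth),
                 init_freq = init_freq, class = class,
                 seed = as.integer(seed)),
            class = "drift_sim_config")
}

#' Configuration for circular-genome coverage with a replication gradient
#'
#' Expected log2 coverage declines linearly from the replication origin down
#' both circular arcs to the antipodal terminus (a symmetric triangle wave in
#' log2 space, matching bidirectional replication); the peak-to-trough span
#' equals `log2_ptr_true`.
#'
#' @param genome_length genome size in bp (single circular contig).
#' @param ori_position position of the replication origin in bp, in
#'   `[0, genome_length)`.
#' @param log2_ptr_true true log2 peak-to-trough ratio, `>= 0`.
#' @param mean_depth genome-wide mean per-base depth.
#' @param bin_size bp per coverage bin; the last bin is truncated if
#'   `genome_length` is not a multiple.
#' @param seed integer seed.
#' @return a list of class `coverage_sim_config`.
#' @export
coverage_sim_config <- function(genome_length = 1e6,
                                ori_position = 0,
                                log2_ptr_true = 1,
                                mean_depth = 100,
                                bin_size = 1e4,
                                seed = 1L) {
  stopifnot(genome_length >= 2, bin_size >= 1, mean_depth > 0,
            log2_ptr_true >= 0)
  if (ori_position < 0 || ori_position >= genome_length) {
    stop("`ori_position` must lie in [0, genome_length)")
  }
  structure(list(genome_length = genome_length, ori_position = ori_position,
                 log2_ptr_true = log2_ptr_true, mean_depth = mean_depth,
                 bin_size = bin_size, seed = as.integer(seed)),
            class = "coverage_sim_config")
}

#' Configuration for simulating time-shift spent-media assays
#'
#' Emulates the fully factorial design in which community inocula from each
#' timepoint are grown on spent media conditioned by communities from each
#' timepoint (3 x 3 combinations per hole). Growth summaries are areas under
#' OD curves (AUC, OD x days).
#'
#' @param timepoints ordered timepoint labels (weeks relative to
#'   perturbation onset).
#' @param fresh_growth_means named per-timepoint mean AUC on fresh medium.
#' @param interaction_true square matrix (rows = focal community `i`,
#'   columns = spent-media source `j`) of true interaction coefficients.
#' @param noise_sd gaussian noise SD added to every AUC measurement.
#' @param n_holes number of replicate holes (assays).
#' @param seed integer seed.
#' @return a list of class `timeshift_sim_config`.
#' @export
timeshift_sim_config <- function(timepoints = c(-7, 0, 8),
                                 fresh_growth_means = c(2.5, 2.5, 2.5),
                                 interaction_true = matrix(-0.5, 3, 3),
                                 noise_sd = 0.1,
                                 n_holes = 8L,
                                 seed = 1L) {
  k <- length(timepoints)
  stopifnot(k >= 2, length(fresh_growth_means) == k, noise_sd >= 0,
            n_holes >= 1)
  if (any(fresh_growth_means <= 0)) stop("`fresh_growth_means` must be > 0")
  if (!is.matrix(interaction_true) || any(dim(interaction_true) != k)) {
    stop("`interaction_true` must be a square matrix over `timepoints`")
  }
  structure(list(timepoints = timepoints,
                 fresh_growth_means = fresh_growth_means,
                 interaction_true = interaction_true, noise_sd = noise_sd,
                 n_holes = as.integer(n_holes), seed = as.integer(seed)),
            class = "timeshift_sim_config")
}

## ---- ASV table simulation --------------------------------------------------

#' Simulate an ASV/genus count table with planted colonisation events
#'
#' Per hole, resident relative abundances are drawn once from a
#' gamma-normalised (Dirichlet) distribution, floored so every resident's
#' expected count per sample is at least 5 reads (which keeps the planted
#' coloniser truth exact: residents cannot masquerade as colonisers through
#' sampling zeros at realistic depths). The number of colonisers per hole is
#' Poisson with mean `coloniser_rate * duration`, where duration is the span
#' of post-baseline weeks; each coloniser has a uniform arrival time mapped to
#' the first sampled week at or after it, is absent before, and holds expected
#' relative frequency `coloniser_freq` from then on. Sample counts are
#' multinomial draws of `reads_per_sample`.
#'
#' @param cfg a [community_sim_config()].
#' @return list with `table` (an `asv_table`: integer count matrix
#'   taxa x samples with `sample_meta`) and `truth` (data frame of planted
#'   colonisers: `hole_id`, `taxon`, `first_week`).
#' @export
simulate_asv_table <- function(cfg) {
  stopifnot(inherits(cfg, "community_sim_config"))
  set.seed(cfg$seed)
  weeks <- cfg$weeks
  later <- weeks[weeks > 0]
  duration <- if (length(later)) max(later) else 0

  holes <- sprintf("H%02d", seq_len(cfg$n_holes))
  treatments <- rep(c("control", "limed"), length.out = cfg$n_holes)

  resident_ids <- sprintf("taxon_%04d", seq_len(cfg$n_taxa))
  floor_freq <- 5 / cfg$reads_per_sample
  if (floor_freq * cfg$n_taxa >= 1) {
    stop("reads_per_sample too low to give every resident an expected count >= 5")
  }

  ## per-hole coloniser draws
  truth <- list()
  col_ids <- character(0)
  n_col_per_hole <- integer(cfg$n_holes)
  first_weeks <- list()
  for (h in seq_len(cfg$n_holes)) {
    n_col <- if (duration > 0) stats::rpois(1, cfg$coloniser_rate * duration) else 0L
    n_col_per_hole[h] <- n_col
    if (n_col > 0) {
      arrival <- stats::runif(n_col, 0, duration)
      fw <- vapply(arrival, function(a) min(later[later >= a]), numeric(1))
      ids <- sprintf("%s_col_%03d", holes[h], seq_len(n_col))
      col_ids <- c(col_ids, ids)
      first_weeks[[h]] <- fw
      truth[[h]] <- data.frame(hole_id = holes[h], taxon = ids,
                               first_week = fw, stringsAsFactors = FALSE)
    } else {
      first_weeks[[h]] <- numeric(0)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(hole_id = character(0), taxon = character(0),
               first_week = numeric(0))

  taxa <- c(resident_ids, col_ids)
  sample_meta <- expand.grid(week = weeks, hole_id = holes,
                             stringsAsFactors = FALSE)[, c("hole_id", "week")]
  sample_meta$treatment <- treatments[match(sample_meta$hole_id, holes)]
  sample_meta$sample_id <- sprintf("%s_W%03d", sample_meta$hole_id,
                                   sample_meta$week)
  sample_meta <- sample_meta[, c("sample_id", "hole_id", "week", "treatment")]

  counts <- matrix(0L, nrow = length(taxa), ncol = nrow(sample_meta),
                   dimnames = list(taxa, sample_meta$sample_id))
  col_offset <- cumsum(c(0L, n_col_per_hole))
  for (h in seq_len(cfg$n_holes)) {
    g <- stats::rgamma(cfg$n_taxa, shape = cfg$base_abundance_shape)
    p <- g / sum(g)
    ## water-fill so every resident keeps expected count >= 5 after rescaling
    low <- p < floor_freq
    p[low] <- floor_freq
    p[!low] <- p[!low] * (1 - sum(p[low])) / sum(p[!low])
    hole_cols <- which(sample_meta$hole_id == holes[h])
    fw <- first_weeks[[h]]
    col_eff <- max(cfg$coloniser_freq, floor_freq)
    for (s in hole_cols) {
      wk <- sample_meta$week[s]
      active <- which(fw <= wk)
      freq <- numeric(length(taxa))
      if (length(active)) {
        idx <- cfg$n_taxa + col_offset[h] + active
        freq[idx] <- col_eff
      }
      freq[seq_len(cfg$n_taxa)] <- p * (1 - sum(freq))
      counts[, s] <- as.integer(stats::rmultinom(1, cfg$reads_per_sample, freq))
    }
  }

  table <- asv_table(counts, sample_meta)
  list(table = table, truth = truth)
}

## ---- SNV trajectory simulation ---------------------------------------------

#' Simulate neutral SNV frequency trajectories under Wright-Fisher drift
#'
#' Each SNV starts at a frequency drawn from the configured uniform interval
#' and is propagated for `round(elapsed_days / gen_time_days_true)` discrete
#' Wright-Fisher generations of `2 * ne_true` allele copies (haploid
#' convention with a diploid-style factor of two, so downstream formulas using
#' `2 N_e` apply verbatim). Observed frequencies at the two timepoints are
#' independent binomial read draws at the configured depth. For populations
#' with more than 2^31 allele copies the binomial generation step uses its
#' gaussian limit (drift there is numerically negligible anyway).
#'
#' @param cfg a [drift_sim_config()].
#' @return list with `snvs` (a SNV table data frame: `mag_id`, `contig`,
#'   `pos`, `class`, `x`, `y`, `depth_t1`, `depth_t2`) and `truth` (list with
#'   `ne_true`, `generations_true`, `wf_steps`, `p_init`, `p_final`).
#' @export
simulate_snv_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "drift_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_snvs
  generations_true <- cfg$elapsed_days / cfg$gen_time_days_true
  steps <- as.integer(round(generations_true))
  alleles <- 2 * cfg$ne_true

  p0 <- stats::runif(n, cfg$init_freq[1], cfg$init_freq[2])
  p <- p0
  if (steps > 0) {
    for (g in seq_len(steps)) {
      if (alleles <= .Machine$integer.max) {
        p <- stats::rbinom(n, alleles, p) / alleles
      } else {
        p <- pmin(pmax(p + stats::rnorm(n, 0, sqrt(p * (1 - p) / alleles)), 0), 1)
      }
    }
  }
  x <- stats::rbinom(n, cfg$depth, p0) / cfg$depth
  y <- stats::rbinom(n, cfg$depth, p) / cfg$depth

  snvs <- data.frame(mag_id = "SIM_MAG", contig = "contig_1", pos = seq_len(n),
                     class = cfg$class, x = x, y = y,
                     depth_t1 = cfg$depth, depth_t2 = cfg$depth,
                     stringsAsFactors = FALSE)
  list(snvs = snvs,
       truth = list(ne_true = cfg$ne_true, generations_true = generations_true,
                    wf_steps = steps, p_init = p0, p_final = p))
}

## ---- coverage simulation ----------------------------------------------------

#' Simulate a circular-genome coverage track with an ori->ter gradient
#'
#' Expected log2 depth is a symmetric triangle wave: maximal at the origin of
#' replication, declining linearly along both circular arcs to the antipodal
#' terminus with total span `log2_ptr_true`; the level is normalised so the
#' length-weighted mean expected depth equals `mean_depth`. Observed per-bin
#' depth is a Poisson count over the bin divided by bin width.
#'
#' @param cfg a [coverage_sim_config()].
#' @return list with `track` (a `coverage_track` data frame: `contig`,
#'   `start`, `end`, `depth`; 0-based half-open, with attribute
#'   `genome_length`) and `truth` (list with `log2_ptr_true`, `ori_position`,
#'   `expected_depth` per bin).
#' @export
simulate_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "coverage_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$genome_length
  starts <- seq(0, G - 1, by = cfg$bin_size)
  ends <- pmin(starts + cfg$bin_size, G)
  widths <- ends - starts
  mids <- (starts + ends) / 2

  d <- pmin(abs(mids - cfg$ori_position), G - abs(mids - cfg$ori_position))
  frac <- d / (G / 2)                       # 0 at ori, 1 at terminus
  rel <- 2^(-cfg$log2_ptr_true * frac)
  mu <- cfg$mean_depth * rel / stats::weighted.mean(rel, widths)
  depth <- stats::rpois(length(mu), mu * widths) / widths

  track <- coverage_track(data.frame(contig = "genome", start = starts,
                                     end = ends, depth = depth,
                                     stringsAsFactors = FALSE),
                          genome_length = G)
  list(track = track,
       truth = list(log2_ptr_true = cfg$log2_ptr_true,
                    ori_position = cfg$ori_position, expected_depth = mu))
}

## ---- time-shift assay simulation --------------------------------------------

#' Simulate time-shift spent-media assay measurements
#'
#' Per hole, one fresh-medium AUC is drawn per timepoint around its configured
#' mean (shared between its roles as `x_i` and `x_j`), and each spent-media
#' growth is `x_ij = x_i + interaction_true[i, j] * x_j + noise`, so that the
#' interaction coefficient `(x_ij - x_i) / x_j` recovers the planted matrix
#' exactly when `noise_sd = 0`.
#'
#' @param cfg a [timeshift_sim_config()].
#' @return list with `assays` (long data frame: `hole_id`, `treatment`, `i`,
#'   `j`, `x_i`, `x_j`, `x_ij`) and `truth` (list with `interaction_true`,
#'   `timepoints`).
#' @export
simulate_timeshift <- function(cfg) {
  stopifnot(inherits(cfg, "timeshift_sim_config"))
  set.seed(cfg$seed)
  k <- length(cfg$timepoints)
  out <- vector("list", cfg$n_holes)
  for (h in seq_len(cfg$n_holes)) {
    fresh <- pmax(stats::rnorm(k, cfg$fresh_growth_means, cfg$noise_sd), 1e-6)
    grid <- expand.grid(i = seq_len(k), j = seq_len(k))
    x_i <- fresh[grid$i]
    x_j <- fresh[grid$j]
    x_ij <- x_i + cfg$interaction_true[cbind(grid$i, grid$j)] * x_j +
      stats::rnorm(nrow(grid), 0, cfg$noise_sd)
    out[[h]] <- data.frame(hole_id = sprintf("H%02d", h),
                           treatment = rep(c("control", "limed"),
                                           length.out = cfg$n_holes)[h],
                           i = cfg$timepoints[grid$i],
                           j = cfg$timepoints[grid$j],
                           x_i = x_i, x_j = x_j, x_ij = x_ij,
                           stringsAsFactors = FALSE)
  }
  list(assays = do.call(rbind, out),
       truth = list(interaction_true = cfg$interaction_true,
                    timepoints = cfg$timepoints))
}
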