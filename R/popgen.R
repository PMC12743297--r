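## Drift calibration chain: segregating-site polymorphism -> Watterson's
## theta -> effective population size; paired-timepoint allele-frequency
## change -> temporal F -> elapsed generations -> generation time. Plus
## new/sweeping variant classification and the inter- vs intra-specific
## sorting comparison.

#' Harmonic number used by the Watterson estimator
#'
#' Returns `a_n = sum_{k=1}^{n-1} 1/k`, the (n-1)-th harmonic number, where
#' the number of sampled sequences `n` is taken from the average read depth.
#' A continuous variant based on the digamma function is available for
#' non-integer depths.
#'
#' @param n number of sequences (>= 2); rounded when `method = "exact"`.
#' @param method "exact" (integer sum, default) or "digamma"
#'   (`digamma(n) - digamma(1)`, continuous in n).
#' @return the harmonic number `a_n`.
#' @export
harmonic_number <- function(n, method = c("exact", "digamma")) {
  method <- match.arg(method)
  if (n < 2) stop("n must be >= 2")
  if (method == "exact") {
    sum(1 / seq_len(round(n) - 1))
  } else {
    digamma(n) - digamma(1)
  }
}

#' Watterson's theta per site from SNV count, read depth and genome length
#'
#' `theta = K / a_n / L`, with the average read depth `n` (rounded to the
#' nearest integer, floored at 2) standing in as the number of sampled
#' sequences.
#'
#' @param K number of SNVs segregating at the first timepoint (>= 0).
#' @param n average read depth of the genome.
#' @param L genome length in nucleotides (> 0).
#' @param method harmonic-number variant, see [harmonic_number()].
#' @return per-site Watterson's theta.
#' @export
watterson_theta <- function(K, n, L, method = c("exact", "digamma")) {
  method <- match.arg(method)
  if (L <= 0) stop("L must be > 0")
  if (K < 0) stop("K must be >= 0")
  n_eff <- max(2, if (method == "exact") round(n) else n)
  K / harmonic_number(n_eff, method) / L
}

#' Effective population size from theta and the mutation rate
#'
#' `N_e = theta / (2 m)` under the haploid-with-2N-alleles drift convention
#' used throughout this package.
#'
#' @param theta per-site Watterson's theta (>= 0).
#' @param m mutation rate per nucleotide per generation (> 0); the study
#'   value is 2.0e-10, the median across sixteen bacterial species.
#' @return effective population size.
#' @export
effective_population_size <- function(theta, m) {
  if (m <= 0) stop("mutation rate m must be > 0")
  if (theta < 0) stop("theta must be >= 0")
  theta / (2 * m)
}

#' Temporal F statistic of allele-frequency change
#'
#' Standardised variance of the change between two timepoints,
#' `F = (x - y)^2 / (x (1 - x))`. Vectorised; sites with an uninformative
#' baseline frequency (`x` equal to 0 or 1) return `NA` (excluded, not an
#' error).
#'
#' @param x allele frequency at timepoint 1, in `[0, 1]`.
#' @param y allele frequency at timepoint 2, in `[0, 1]`.
#' @return numeric vector of F values with `NA` where `x` is 0 or 1.
#' @export
f_statistic <- function(x, y) {
  if (any(x < 0 | x > 1 | y < 0 | y > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  out <- (x - y)^2 / (x * (1 - x))
  out[x <= 0 | x >= 1] <- NA_real_
  out
}

#' Expected elapsed generations from mean temporal F
#'
#' Inverts the Wright-Fisher drift expectation
#' `E[F] = 1 - (1 - 1/(2 N_e))^t ~= 1 - exp(-t/(2 N_e))`:
#' `t = -2 N_e ln(1 - F)`.
#'
#' @param f_mean aggregated F over silent sites, in `[0, 1)`.
#' @param ne effective population size (> 0).
#' @return expected number of generations between the two timepoints.
#' @export
generations_from_f <- function(f_mean, ne) {
  if (is.na(f_mean)) return(NA_real_)
  if (f_mean < 0 || f_mean >= 1) stop("f_mean must lie in [0, 1)")
  if (ne <= 0) stop("ne must be > 0")
  -2 * ne * log(1 - f_mean)
}

#' Generation time from elapsed generations and elapsed days
#'
#' @param t generations elapsed between the two timepoints (> 0; `t = 0` or
#'   `NA` yields `NA`, flagged undefined).
#' @param elapsed_days days between the timepoints (study value 56).
#' @return named numeric: `days` and `hours`.
#' @export
generation_time <- function(t, elapsed_days = 56) {
  if (elapsed_days <= 0) stop("elapsed_days must be > 0")
  if (is.na(t) || t <= 0) return(c(days = NA_real_, hours = NA_real_))
  days <- elapsed_days / t
  c(days = days, hours = 24 * days)
}

#' Per-genome summary feeding the drift calibration
#'
#' @param mag_id genome (MAG) identifier.
#' @param L genome length in nucleotides.
#' @param n average read depth.
#' @param K number of SNVs at timepoint 1; computed from `snvs` as the number
#'   of sites with `x > 0` when a SNV table is supplied.
#' @param snvs optional SNV table (see [simulate_snv_trajectories()] for the
#'   schema) used to derive `K`.
#' @param elapsed_days days between timepoints (default 56).
#' @param theta optional externally estimated per-site theta; when supplied
#'   it overrides the `K / a_n / L` computation in [calibrate_mag()].
#' @param rel_abundance_t1,rel_abundance_t2 optional coverage-based relative
#'   abundances at the two timepoints.
#' @return list of class `mag_summary`.
#' @export
mag_summary <- function(mag_id, L, n, K = NULL, snvs = NULL,
                        elapsed_days = 56, theta = NULL,
                        rel_abundance_t1 = NA_real_,
                        rel_abundance_t2 = NA_real_) {
  if (L <= 0) stop("L must be > 0")
  if (n < 1) stop("average depth n must be >= 1")
  if (is.null(K)) {
    if (is.null(snvs)) stop("supply K or an SNV table to derive it from")
    K <- sum(snvs$x > 0 & snvs$mag_id == mag_id)
  }
  structure(list(mag_id = mag_id, K = K, L = L, n = n,
                 elapsed_days = elapsed_days, theta = theta,
                 rel_abundance_t1 = rel_abundance_t1,
                 rel_abundance_t2 = rel_abundance_t2),
            class = "mag_summary")
}

#' Full drift calibration for one genome
#'
#' Composes the atomic steps: Watterson's theta from (K, n, L); `N_e` from
#' theta and the mutation rate; per-SNV temporal F over synonymous (silent)
#' sites with informative baseline (`0 < x < 1`), each capped at `f_cap`;
#' aggregation (mean by default); elapsed generations
#' `t = -2 N_e ln(1 - F)`; and generation time `elapsed_days / t`.
#'
#' At low read depth the binomial sampling of reads inflates F by roughly
#' `1/d1 + 1/d2` relative to the drift signal, biasing `t` upward;
#' `noise_correction = "binomial"` subtracts the per-SNV plug-in expectation
#' of that contribution, `1/d1 + y(1-y) / (x(1-x) d2)` (floored at 0). The
#' default applies no correction, mirroring the raw estimator.
#'
#' @param snvs SNV table data frame (`mag_id`, `contig`, `pos`, `class`, `x`,
#'   `y`, `depth_t1`, `depth_t2`).
#' @param summary a [mag_summary()] for the same `mag_id`.
#' @param m mutation rate per nucleotide per generation (default 2e-10).
#' @param f_agg aggregate per-SNV F by "mean" (default; the drift expectation
#'   E[F] is what the inversion assumes) or "median".
#' @param f_cap cap applied to each per-SNV F before aggregation (default
#'   0.95); keeps `ln(1 - F)` finite when sites drift to fixation, which is
#'   off-model for the approximation.
#' @param noise_correction "none" (default) or "binomial" (see Details).
#' @param harmonic harmonic-number variant, see [harmonic_number()].
#' @return one-row data frame of class `calibration_result` with all
#'   intermediates: `mag_id`, `K`, `L`, `n`, `a_n`, `theta`, `m`, `ne`,
#'   `n_silent_used`, `f_mean`, `t_generations`, `gen_time_days`,
#'   `gen_time_hours`. F-dependent fields are `NA` when no usable silent SNV
#'   exists.
#' @export
calibrate_mag <- function(snvs, summary, m = 2e-10,
                          f_agg = c("mean", "median"), f_cap = 0.95,
                          noise_correction = c("none", "binomial"),
                          harmonic = c("exact", "digamma")) {
  f_agg <- match.arg(f_agg)
  noise_correction <- match.arg(noise_correction)
  harmonic <- match.arg(harmonic)
  stopifnot(inherits(summary, "mag_summary"))
  snvs <- snvs[snvs$mag_id == summary$mag_id, , drop = FALSE]
  if (!is.null(summary$theta)) {
    theta <- summary$theta
    a_n <- NA_real_
  } else {
    a_n <- harmonic_number(max(2, if (harmonic == "exact") round(summary$n)
                               else summary$n), harmonic)
    theta <- watterson_theta(summary$K, summary$n, summary$L, harmonic)
  }
  ne <- effective_population_size(theta, m)

  silent <- snvs$class == "synonymous" & snvs$x > 0 & snvs$x < 1
  f <- f_statistic(snvs$x[silent], snvs$y[silent])
  if (noise_correction == "binomial") {
    ## per-SNV values stay signed (flooring each at 0 would re-inflate the
    ## mean exactly where noise dominates); only the aggregate is floored
    noise <- 1 / snvs$depth_t1[silent] +
      snvs$y[silent] * (1 - snvs$y[silent]) /
        (snvs$x[silent] * (1 - snvs$x[silent]) * snvs$depth_t2[silent])
    f <- f - noise
  }
  f <- pmin(f, f_cap)
  if (length(f) == 0 || all(is.na(f))) {
    f_mean <- NA_real_
  } else {
    f_mean <- if (f_agg == "mean") mean(f, na.rm = TRUE) else
      stats::median(f, na.rm = TRUE)
    f_mean <- max(f_mean, 0)
  }
  t_gen <- if (is.na(f_mean) || ne <= 0) NA_real_ else
    generations_from_f(f_mean, ne)
  gt <- if (is.na(t_gen)) c(days = NA_real_, hours = NA_real_) else
    generation_time(t_gen, summary$elapsed_days)

  structure(data.frame(mag_id = summary$mag_id, K = summary$K, L = summary$L,
                       n = summary$n, a_n = a_n, theta = theta, m = m,
                       ne = ne, n_silent_used = sum(!is.na(f)),
                       f_mean = f_mean, t_generations = t_gen,
                       gen_time_days = unname(gt["days"]),
                       gen_time_hours = unname(gt["hours"]),
                       stringsAsFactors = FALSE),
            class = c("calibration_result", "data.frame"))
}

#' Classify SNVs as new and sweeping
#'
#' A variant is *new* when absent at the first timepoint (`x <= presence_eps`)
#' and present at the second (`y > presence_eps`); a new variant is *sweeping*
#' when its second-timepoint frequency exceeds `sweep_threshold`. An
#' alternative reading of "changed above the threshold" as `|y - x| >
#' sweep_threshold` is exposed via `sweep_mode = "delta"`.
#'
#' @param snvs SNV table data frame.
#' @param sweep_threshold frequency threshold for sweeping variants
#'   (default 0.75).
#' @param presence_eps detection threshold below which a frequency counts as
#'   absent (default 0: exactly absent from the call set).
#' @param sweep_mode "endpoint" (`y > sweep_threshold`, default) or "delta"
#'   (`|y - x| > sweep_threshold`).
#' @return list of class `variant_classification`: `per_snv` (input plus
#'   logical `is_new`, `is_sweeping`), `per_mag` (counts and `prop_new` per
#'   genome), `overall` (totals).
#' @export
classify_variants <- function(snvs, sweep_threshold = 0.75, presence_eps = 0,
                              sweep_mode = c("endpoint", "delta")) {
  sweep_mode <- match.arg(sweep_mode)
  is_new <- snvs$x <= presence_eps & snvs$y > presence_eps
  swept <- if (sweep_mode == "endpoint") snvs$y > sweep_threshold else
    abs(snvs$y - snvs$x) > sweep_threshold
  is_sweeping <- is_new & swept
  per_snv <- cbind(snvs, is_new = is_new, is_sweeping = is_sweeping)
  mags <- unique(snvs$mag_id)
  per_mag <- do.call(rbind, lapply(mags, function(mg) {
    sel <- snvs$mag_id == mg
    data.frame(mag_id = mg, n_snvs = sum(sel), n_new = sum(is_new[sel]),
               n_sweeping = sum(is_sweeping[sel]),
               prop_new = if (sum(sel)) sum(is_new[sel]) / sum(sel) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  overall <- data.frame(n_snvs = nrow(snvs), n_new = sum(is_new),
                        n_sweeping = sum(is_sweeping),
                        prop_new = if (nrow(snvs)) sum(is_new) / nrow(snvs)
                                   else NA_real_)
  structure(list(per_snv = per_snv, per_mag = per_mag, overall = overall),
            class = "variant_classification")
}

#' Signed and absolute relative-abundance change of genomes from coverages
#'
#' Relative abundance at each timepoint is each genome's coverage divided by
#' the summed coverage of all genomes at that timepoint; the change is the
#' timepoint-2 minus timepoint-1 value.
#'
#' @param coverages data frame with columns `mag_id`, `cov_t1`, `cov_t2`.
#' @return data frame `mag_id`, `delta_abund` (signed), `abs_delta_abund`.
#' @export
mag_abundance_change <- function(coverages) {
  stopifnot(all(c("mag_id", "cov_t1", "cov_t2") %in% names(coverages)))
  if (any(coverages$cov_t1 < 0 | coverages$cov_t2 < 0)) stop("negative coverage")
  r1 <- coverages$cov_t1 / sum(coverages$cov_t1)
  r2 <- coverages$cov_t2 / sum(coverages$cov_t2)
  data.frame(mag_id = coverages$mag_id, delta_abund = r2 - r1,
             abs_delta_abund = abs(r2 - r1), stringsAsFactors = FALSE)
}

#' Compare inter-specific (genome abundance) and intra-specific (SNV) sorting
#'
#' (a) Two-sided Wilcoxon rank-sum test comparing the distribution of
#' absolute genome relative-abundance changes with the distribution of
#' absolute non-synonymous SNV frequency changes; (b) ordinary least-squares
#' regression of each SNV's absolute frequency change on the signed abundance
#' change of its genome; (c) optionally, the same regression against the
#' change in log2 peak-to-trough ratio.
#'
#' @param mag_changes data frame `mag_id`, `delta_abund` (signed); see
#'   [mag_abundance_change()].
#' @param snv_changes data frame `mag_id`, `abs_delta_freq` (per ns-SNV).
#' @param ptr_changes optional data frame `mag_id`, `delta_log2_ptr`.
#' @return list of class `sorting_comparison`: `rank_sum` (statistic, p),
#'   `regression_abund` and (optionally) `regression_ptr`, each with `slope`,
#'   `intercept`, `r_squared`, `p`, or flagged `undefined` for constant
#'   predictors.
#' @export
sorting_comparison <- function(mag_changes, snv_changes, ptr_changes = NULL) {
  stopifnot(all(c("mag_id", "delta_abund") %in% names(mag_changes)),
            all(c("mag_id", "abs_delta_freq") %in% names(snv_changes)))
  a <- abs(mag_changes$delta_abund)
  b <- snv_changes$abs_delta_freq
  if (length(a) < 2 || length(b) < 2) {
    stop("need >= 2 values per group for the rank-sum comparison")
  }
  w <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  run_reg <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(list(undefined = TRUE, slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, p = NA_real_, n = length(x)))
    }
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    list(undefined = FALSE, slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared, p = sm$coefficients[2, 4], n = length(x))
  }
  x_ab <- mag_changes$delta_abund[match(snv_changes$mag_id, mag_changes$mag_id)]
  reg_ab <- run_reg(x_ab, snv_changes$abs_delta_freq)
  out <- list(rank_sum = list(statistic = unname(w$statistic), p = w$p.value),
              regression_abund = reg_ab)
  if (!is.null(ptr_changes)) {
    x_ptr <- ptr_changes$delta_log2_ptr[match(snv_changes$mag_id,
                                              ptr_changes$mag_id)]
    out$regression_ptr <- run_reg(x_ptr, snv_changes$abs_delta_freq)
  }
  structure(out, class = "sorting_comparison")
}
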