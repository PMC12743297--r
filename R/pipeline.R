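## Run configuration and the umbrella pipeline binding all stages, with
## deterministic per-stage seed derivation and JSON provenance alongside
## every output.

.default_run_config <- function() {
  list(
    stages = c("simulate", "ecology", "popgen", "ptr", "timeshift"),
    out_dir = "ecoevotrack_out",
    seed = 1L,
    ## file paths (filled by the simulate stage when it runs first)
    asv_table = NULL, asv_meta = NULL, snv_table = NULL, mag_csv = NULL,
    coverage = NULL, assays = NULL,
    ## tunables, defaults equal to each module's documented choice
    pseudocount = 0.5, baseline_week = 0,
    mutation_rate = 2e-10, elapsed_days = 56, f_agg = "mean", f_cap = 0.95,
    noise_correction = "none", sweep_threshold = 0.75, presence_eps = 0,
    n_bins = 100, grid_step = 1, genome_length = NULL,
    n_perm = 999,
    ## simulate-stage generator settings
    sim = list(n_taxa = 120L, n_holes = 4L, weeks = c(0L, 1L, 2L, 4L, 8L, 12L),
               base_abundance_shape = 0.3, coloniser_rate = 2,
               coloniser_freq = 1e-3, reads_per_sample = 20000L,
               n_snvs = 500L, ne_true = 5000, gen_time_days_true = 1,
               depth = 200L, cov_genome_length = 5e5, cov_bin_size = 5e3,
               log2_ptr_true = 1, mean_depth = 150,
               timeshift_noise_sd = 0.05)
  )
}

#' Build a run configuration
#'
#' Every tunable defaults to the value documented in its module; unknown
#' names are rejected. The configuration round-trips through YAML
#' ([read_run_config()] / [write_run_config()]) identically.
#'
#' @param ... named overrides of the defaults (see
#'   `ecoevotrack:::.default_run_config()` for the full list; the `sim`
#'   entry is itself a list of generator settings merged element-wise).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .default_run_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(over$sim)) {
    unknown_sim <- setdiff(names(over$sim), names(cfg$sim))
    if (length(unknown_sim)) {
      stop(sprintf("unknown config key(s): sim$%s",
                   paste(unknown_sim, collapse = ", sim$")))
    }
    cfg$sim <- utils::modifyList(cfg$sim, over$sim)
    over$sim <- NULL
  }
  cfg <- utils::modifyList(cfg, over, keep.null = TRUE)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a [run_config()].
#' @return `read_run_config()`: a validated [run_config()];
#'   `write_run_config()`: invisibly the path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## one global seed fans out to per-stage streams via a stage-name hash, so
## adding a stage does not shift another stage's stream
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

write_provenance <- function(out_dir, stage, cfg, outputs) {
  prov <- list(stage = stage, seed = cfg$seed,
               stage_seed = stage_seed(cfg$seed, stage),
               config = unclass(cfg), outputs = outputs,
               package = "ecoevotrack",
               version = as.character(utils::packageVersion("ecoevotrack")),
               r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(prov, file.path(out_dir,
                                       sprintf("%s_provenance.json", stage)),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order. The `simulate` stage
#' writes synthetic inputs (and their ground truth) into the output
#' directory and wires the downstream stages to them; otherwise the file
#' paths in the config are used. Every stage writes its outputs plus a JSON
#' provenance block (config, seeds, package version). Outputs are
#' deterministic given the config: reruns are byte-identical.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  known <- c("simulate", "ecology", "popgen", "ptr", "timeshift")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop(sprintf("unknown stage(s): %s",
                                paste(bad, collapse = ", ")))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if ("simulate" %in% cfg$stages) {
    s <- cfg$sim
    seed <- stage_seed(cfg$seed, "simulate")
    asv <- simulate_asv_table(community_sim_config(
      n_taxa = s$n_taxa, n_holes = s$n_holes, weeks = s$weeks,
      base_abundance_shape = s$base_abundance_shape,
      coloniser_rate = s$coloniser_rate, coloniser_freq = s$coloniser_freq,
      reads_per_sample = s$reads_per_sample, seed = seed))
    drift <- simulate_snv_trajectories(drift_sim_config(
      n_snvs = s$n_snvs, ne_true = s$ne_true,
      gen_time_days_true = s$gen_time_days_true,
      elapsed_days = cfg$elapsed_days, depth = s$depth, seed = seed + 1L))
    cov <- simulate_coverage(coverage_sim_config(
      genome_length = s$cov_genome_length, log2_ptr_true = s$log2_ptr_true,
      mean_depth = s$mean_depth, bin_size = s$cov_bin_size, seed = seed + 2L))
    ts <- simulate_timeshift(timeshift_sim_config(
      noise_sd = s$timeshift_noise_sd, n_holes = s$n_holes, seed = seed + 3L))

    cfg$asv_table <- file.path(cfg$out_dir, "asv_counts.tsv")
    cfg$asv_meta <- file.path(cfg$out_dir, "asv_meta.csv")
    cfg$snv_table <- file.path(cfg$out_dir, "snvs.tsv")
    cfg$mag_csv <- file.path(cfg$out_dir, "mags.csv")
    cfg$coverage <- file.path(cfg$out_dir, "coverage.bedgraph")
    cfg$assays <- file.path(cfg$out_dir, "timeshift.csv")
    cfg$genome_length <- s$cov_genome_length
    write_asv_table(asv$table, cfg$asv_table, cfg$asv_meta)
    write_snv_table(drift$snvs, cfg$snv_table)
    ## MAG summary carrying the simulation's truth-implied theta, so the
    ## popgen stage demonstrates the full calibration chain with ne = ne_true
    utils::write.csv(data.frame(mag_id = "SIM_MAG",
                                K = sum(drift$snvs$x > 0),
                                L = 1e6, n = s$depth,
                                theta = 2 * cfg$mutation_rate * s$ne_true),
                     cfg$mag_csv, row.names = FALSE, quote = FALSE)
    write_bedgraph(cov$track, cfg$coverage)
    write_timeshift_csv(ts$assays, cfg$assays)
    truth <- list(colonisers = asv$truth,
                  drift = drift$truth[c("ne_true", "generations_true",
                                        "wf_steps")],
                  coverage = cov$truth[c("log2_ptr_true", "ori_position")],
                  timeshift = ts$truth)
    jsonlite::write_json(truth, file.path(cfg$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_provenance(cfg$out_dir, "simulate", cfg,
                     c(cfg$asv_table, cfg$asv_meta, cfg$snv_table,
                       cfg$coverage, cfg$assays))
    res$simulate <- truth
  }

  if ("ecology" %in% cfg$stages) {
    if (is.null(cfg$asv_table)) stop("stage 'ecology' failed: no ASV table configured")
    tab <- read_asv_table(cfg$asv_table, cfg$asv_meta)
    rep <- coloniser_report(tab, cfg$baseline_week)
    freq <- coloniser_frequency(tab, rep)
    weeks <- sample_meta(tab)$week
    duration <- max(weeks) - max(0, cfg$baseline_week)
    final <- freq$frequency[freq$week == max(weeks)]
    rate <- colonisation_rate(rep, duration, mean(final))
    sharing <- pairwise_sharing(tab)
    meta <- sample_meta(tab)
    div <- data.frame(sample_id = meta$sample_id,
                      shannon = apply(tab, 2, shannon_index),
                      richness = apply(tab, 2, observed_richness))
    utils::write.table(rep$colonisers,
                       file.path(cfg$out_dir, "colonisers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(freq, row.names = NULL),
                       file.path(cfg$out_dir, "coloniser_frequency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(hole_id = rownames(sharing), sharing,
                                  check.names = FALSE),
                       file.path(cfg$out_dir, "sharing_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(div, file.path(cfg$out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- list(per_hole_coloniser_counts = as.list(rep$counts),
                 colonisation_rate = as.list(rate),
                 mean_sharing = mean(sharing[upper.tri(sharing)]))
    jsonlite::write_json(summ, file.path(cfg$out_dir, "ecology_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_provenance(cfg$out_dir, "ecology", cfg,
                     file.path(cfg$out_dir, c("colonisers.tsv",
                                              "coloniser_frequency.tsv",
                                              "sharing_matrix.tsv",
                                              "diversity.tsv",
                                              "ecology_summary.json")))
    res$ecology <- summ
  }

  if ("popgen" %in% cfg$stages) {
    if (is.null(cfg$snv_table)) stop("stage 'popgen' failed: no SNV table configured")
    snvs <- read_snv_table(cfg$snv_table)
    if (is.null(cfg$mag_csv)) stop("stage 'popgen' failed: no MAG summary CSV configured")
    magdf <- utils::read.csv(cfg$mag_csv, stringsAsFactors = FALSE)
    calib <- do.call(rbind, lapply(unique(snvs$mag_id), function(mg) {
      row <- magdf[magdf$mag_id == mg, , drop = FALSE]
      if (!nrow(row)) {
        stop(sprintf("stage 'popgen' failed: MAG '%s' missing from %s",
                     mg, cfg$mag_csv))
      }
      sm <- mag_summary(mg, L = row$L[1], n = row$n[1], K = row$K[1],
                        elapsed_days = cfg$elapsed_days,
                        theta = if ("theta" %in% names(row) &&
                                    !is.na(row$theta[1])) row$theta[1]
                                else NULL)
      calibrate_mag(snvs, sm, m = cfg$mutation_rate, f_agg = cfg$f_agg,
                    f_cap = cfg$f_cap,
                    noise_correction = cfg$noise_correction)
    }))
    cls <- classify_variants(snvs, cfg$sweep_threshold, cfg$presence_eps)
    utils::write.table(calib, file.path(cfg$out_dir, "calibration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
    utils::write.table(cls$per_mag,
                       file.path(cfg$out_dir, "variant_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(cfg$out_dir, "popgen", cfg,
                     file.path(cfg$out_dir, c("calibration.tsv",
                                              "variant_classes.tsv")))
    res$popgen <- list(calibration = calib, classification = cls$overall)
  }

  if ("ptr" %in% cfg$stages) {
    if (is.null(cfg$coverage)) stop("stage 'ptr' failed: no coverage configured")
    track <- read_bedgraph(cfg$coverage, genome_length = cfg$genome_length)
    est <- estimate_ptr(track, n_bins = cfg$n_bins, grid_step = cfg$grid_step)
    out <- data.frame(contig = track$contig[1], ptr = est$ptr,
                      log2_ptr = est$log2_ptr, ori_hat = est$ori_hat,
                      ter_hat = est$ter_hat, fit_r2 = est$fit_r2)
    utils::write.table(out, file.path(cfg$out_dir, "ptr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = ".")
    write_provenance(cfg$out_dir, "ptr", cfg, file.path(cfg$out_dir, "ptr.tsv"))
    res$ptr <- est
  }

  if ("timeshift" %in% cfg$stages) {
    if (is.null(cfg$assays)) stop("stage 'timeshift' failed: no assays configured")
    assays <- read_timeshift_csv(cfg$assays)
    assays$coefficient <- interaction_coefficient(assays$x_i, assays$x_j,
                                                  assays$x_ij)
    tally <- strongest_reduction_tally(assays)
    p <- multinomial_column_test(tally$column_sums)
    utils::write.table(assays, file.path(cfg$out_dir, "coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
    utils::write.table(data.frame(i = rownames(tally$tally), tally$tally,
                                  check.names = FALSE),
                       file.path(cfg$out_dir, "tally.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(column_sums = as.list(tally$column_sums),
                              n_ties = tally$n_ties, p_value = p),
                         file.path(cfg$out_dir, "timeshift_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_provenance(cfg$out_dir, "timeshift", cfg,
                     file.path(cfg$out_dir, c("coefficients.tsv", "tally.tsv",
                                              "timeshift_summary.json")))
    res$timeshift <- list(tally = tally, p_value = p)
  }

  invisible(res)
}
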