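## Community-ecology statistics on ASV/genus count tables: compositional
## transform, diversity, coloniser detection, hole-to-hole connectivity and
## the distance-association permutation test.

#' Centred log-ratio (CLR) transform of one sample's counts
#'
#' `log(count + pseudocount)` centred by its mean across taxa, so the output
#' sums to zero. The pseudocount keeps zero counts finite while perturbing the
#' composition minimally.
#'
#' @param counts non-negative numeric vector of counts for one sample
#'   (length >= 2).
#' @param pseudocount positive value added to every count (default 0.5).
#' @return numeric vector of CLR values summing to zero.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  if (length(counts) < 2) stop("CLR needs at least 2 taxa")
  if (any(counts < 0)) stop("negative counts")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  lx <- log(counts + pseudocount)
  lx - mean(lx)
}

#' Shannon diversity index (natural log) of one sample
#'
#' @param counts non-negative numeric vector; total must be positive.
#' @return `-sum(p * log(p))` over taxa with positive count, in nats.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("all-zero sample: Shannon index undefined")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Observed richness of one sample
#'
#' @param counts non-negative numeric vector.
#' @return number of taxa with count > 0.
#' @export
observed_richness <- function(counts) {
  sum(counts > 0)
}

#' Detect coloniser taxa in one hole
#'
#' A taxon is a coloniser of a hole iff it has zero counts in all of the
#' hole's samples at weeks `<= baseline_week`, a positive count at some later
#' sampled week `w*`, and positive counts in every sampled week after `w*`
#' through the last sample (appear once, then persist).
#'
#' @param table an [asv_table()].
#' @param hole_id hole to scan.
#' @param baseline_week last pre-perturbation week (default 0); all sampled
#'   weeks at or before it form the baseline.
#' @return data frame with columns `taxon`, `first_week` (one row per
#'   coloniser).
#' @export
detect_colonisers <- function(table, hole_id, baseline_week = 0) {
  meta <- sample_meta(table)
  sel <- meta$hole_id == hole_id
  if (!any(sel)) stop(sprintf("unknown hole '%s'", hole_id))
  weeks <- meta$week[sel]
  if (!any(weeks <= baseline_week)) {
    stop(sprintf("hole '%s' has no sample at or before baseline week %s",
                 hole_id, baseline_week))
  }
  if (!any(weeks > baseline_week)) {
    stop(sprintf("hole '%s' has no post-baseline samples", hole_id))
  }
  sub <- table[, sel, drop = FALSE][, order(weeks), drop = FALSE]
  weeks <- sort(weeks)
  base <- weeks <= baseline_week
  later <- !base

  base_zero <- rowSums(sub[, base, drop = FALSE] > 0) == 0
  present_later <- sub[, later, drop = FALSE] > 0
  later_weeks <- weeks[later]

  first_week <- apply(present_later, 1, function(pr) {
    if (!any(pr)) return(NA_real_)
    later_weeks[which(pr)[1]]
  })
  persists <- apply(present_later, 1, function(pr) {
    if (!any(pr)) return(FALSE)
    all(pr[which(pr)[1]:length(pr)])
  })
  is_col <- base_zero & !is.na(first_week) & persists
  data.frame(taxon = rownames(sub)[is_col],
             first_week = unname(first_week[is_col]),
             stringsAsFactors = FALSE)
}

#' Coloniser report across all holes of a table
#'
#' Runs [detect_colonisers()] on every hole and collects per-hole coloniser
#' lists and counts.
#'
#' @inheritParams detect_colonisers
#' @return list of class `coloniser_report`: `colonisers` (data frame
#'   `hole_id`, `taxon`, `first_week`), `counts` (named per-hole coloniser
#'   count), `baseline_week`.
#' @export
coloniser_report <- function(table, baseline_week = 0) {
  meta <- sample_meta(table)
  holes <- unique(meta$hole_id)
  per_hole <- lapply(holes, function(h) {
    d <- detect_colonisers(table, h, baseline_week)
    if (nrow(d)) cbind(hole_id = h, d, stringsAsFactors = FALSE) else NULL
  })
  colonisers <- do.call(rbind, c(per_hole, list(
    data.frame(hole_id = character(0), taxon = character(0),
               first_week = numeric(0)))))
  counts <- vapply(holes, function(h) sum(colonisers$hole_id == h), integer(1))
  structure(list(colonisers = colonisers, counts = counts,
                 baseline_week = baseline_week),
            class = "coloniser_report")
}

#' Per-sample coloniser read frequency
#'
#' Fraction of each sample's reads belonging to that hole's coloniser taxa,
#' plus per-week treatment means.
#'
#' @param table an [asv_table()].
#' @param report a [coloniser_report()] computed from the same table.
#' @return data frame `sample_id`, `hole_id`, `week`, `treatment`,
#'   `frequency`, with attribute `week_treatment_means` (data frame `week`,
#'   `treatment`, `mean_frequency`).
#' @export
coloniser_frequency <- function(table, report) {
  stopifnot(inherits(report, "coloniser_report"))
  meta <- sample_meta(table)
  freq <- vapply(seq_len(ncol(table)), function(s) {
    cols <- report$colonisers$taxon[report$colonisers$hole_id == meta$hole_id[s]]
    tot <- sum(table[, s])
    if (tot == 0) return(0)
    sum(table[cols, s]) / tot
  }, numeric(1))
  out <- cbind(meta, frequency = freq)
  means <- stats::aggregate(frequency ~ week + treatment, out, mean)
  names(means)[names(means) == "frequency"] <- "mean_frequency"
  attr(out, "week_treatment_means") <- means
  out
}

#' Colonisation rate per week
#'
#' Mean per-hole coloniser count divided by the experiment duration, and
#' (optionally) the mean final coloniser frequency divided by duration.
#'
#' @param report a [coloniser_report()], or directly the mean per-hole
#'   coloniser count as a single number.
#' @param duration_weeks experiment duration in weeks (> 0).
#' @param mean_final_frequency optional mean coloniser read frequency at the
#'   final sample across holes.
#' @return named numeric: `taxa_per_week` and `freq_per_week` (NA when no
#'   frequency supplied).
#' @export
colonisation_rate <- function(report, duration_weeks,
                              mean_final_frequency = NULL) {
  if (duration_weeks <= 0) stop("duration_weeks must be > 0")
  mean_count <- if (inherits(report, "coloniser_report")) {
    if (length(report$counts)) mean(report$counts) else 0
  } else {
    as.numeric(report)
  }
  c(taxa_per_week = mean_count / duration_weeks,
    freq_per_week = if (is.null(mean_final_frequency)) NA_real_ else
      mean_final_frequency / duration_weeks)
}

#' Pairwise read-sharing matrix between holes
#'
#' For each pair of holes the counts are pooled across each hole's samples
#' (or compared per matched week when `per_week = TRUE` and averaged); the
#' sharing value is the fraction of the two holes' combined reads that belong
#' to taxa present in both:
#' `(reads_A[shared] + reads_B[shared]) / (total_A + total_B)`.
#'
#' @param table an [asv_table()] with at least 2 holes.
#' @param per_week compare week-matched samples and average instead of
#'   pooling all timepoints (default FALSE, the connectivity reading).
#' @return symmetric holes x holes matrix in `[0, 1]` with unit diagonal.
#' @export
pairwise_sharing <- function(table, per_week = FALSE) {
  meta <- sample_meta(table)
  holes <- unique(meta$hole_id)
  if (length(holes) < 2) stop("need at least 2 holes")
  share_pair <- function(a, b) {
    shared <- a > 0 & b > 0
    tot <- sum(a) + sum(b)
    if (tot == 0) return(0)
    (sum(a[shared]) + sum(b[shared])) / tot
  }
  M <- diag(1, length(holes))
  dimnames(M) <- list(holes, holes)
  for (i in seq_along(holes)[-length(holes)]) {
    for (j in (i + 1):length(holes)) {
      si <- meta$hole_id == holes[i]
      sj <- meta$hole_id == holes[j]
      if (per_week) {
        wk <- intersect(meta$week[si], meta$week[sj])
        if (!length(wk)) stop("per_week sharing: holes share no sampled week")
        vals <- vapply(wk, function(w) {
          share_pair(table[, si & meta$week == w], table[, sj & meta$week == w])
        }, numeric(1))
        v <- mean(vals)
      } else {
        v <- share_pair(rowSums(table[, si, drop = FALSE]),
                        rowSums(table[, sj, drop = FALSE]))
      }
      M[i, j] <- M[j, i] <- v
    }
  }
  M
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a two-sided
#' permutation p-value obtained by simultaneously permuting rows and columns
#' of the second matrix: `p = (1 + #{|r*| >= |r|}) / (1 + n_perm)`.
#'
#' @param d1,d2 square symmetric matrices (or `dist` objects) of equal size
#'   >= 4.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return list with `r` (observed correlation), `p` (two-sided permutation
#'   p-value) and `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  as_mat <- function(d) if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  m1 <- as_mat(d1); m2 <- as_mat(d2)
  n <- nrow(m1)
  if (n < 4 || any(dim(m1) != n) || any(dim(m2) != n)) {
    stop("matrices must be square, of equal size >= 4")
  }
  if (max(abs(m1 - t(m1))) > 1e-8 || max(abs(m2 - t(m2))) > 1e-8) {
    stop("matrices must be symmetric")
  }
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (stats::sd(v1) == 0 || stats::sd(m2[ut]) == 0) {
    stop("constant distance matrix: correlation undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(v1, m2[ut])
  hits <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    rp <- stats::cor(v1, m2[idx, idx][ut])
    if (abs(rp) >= abs(r) - 1e-12) hits <- hits + 1L
  }
  list(r = r, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}
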