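## Time-shift spent-media assay analysis: AUC growth summaries, interaction
## coefficients, strongest-reduction tallies and an exact multinomial test on
## the tally column sums.

#' Area under a growth curve by the trapezoid rule
#'
#' @param times observation times in days, strictly increasing, length >= 2.
#' @param od optical-density readings (>= 0), same length as `times`.
#' @return the trapezoidal integral in OD x days.
#' @export
auc_trapezoid <- function(times, od) {
  if (length(times) < 2) stop("need at least 2 timepoints")
  if (length(times) != length(od)) stop("times and od lengths differ")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (any(od < 0)) stop("negative OD readings")
  pracma::trapz(times, od)
}

#' Interaction coefficient of a spent-media assay
#'
#' `(x_ij - x_i) / x_j`: the effect of community `j`'s spent media on
#' community `i`, scaled by how well community `j` grew on fresh medium.
#' Negative values indicate inhibition on spent media (e.g. shared resources
#' depleted), positive values stimulation. Vectorised; `x_j = 0` (community
#' `j` failed to grow on fresh medium) yields `NA`, flagged undefined.
#'
#' @param x_i AUC of community `i` on fresh medium.
#' @param x_j AUC of community `j` on fresh medium.
#' @param x_ij AUC of community `i` on spent media of community `j`.
#' @return numeric vector of interaction coefficients.
#' @export
interaction_coefficient <- function(x_i, x_j, x_ij) {
  if (any(c(x_i, x_j, x_ij) < 0, na.rm = TRUE)) stop("AUCs must be >= 0")
  out <- (x_ij - x_i) / x_j
  out[x_j == 0] <- NA_real_
  out
}

#' Tally which spent media reduced growth most
#'
#' For every assay (hole) and focal community timepoint `i`, the spent-media
#' source `j` with the minimum interaction coefficient is tallied. Exact ties
#' (within `tie_tol`) are broken deterministically in favour of the earliest
#' timepoint label, and the number of tied cases is reported. Rows with fewer
#' than two defined coefficients are skipped (recorded in `skipped`).
#'
#' @param assays long data frame with columns `hole_id`, `i`, `j`, `x_i`,
#'   `x_j`, `x_ij` (a `coefficient` column is used directly if present).
#' @param tie_tol absolute tolerance within which coefficients count as tied
#'   (default 1e-9).
#' @return list of class `tally_table`: `tally` (matrix, rows = focal `i`,
#'   columns = spent media `j`), `column_sums`, `row_assays` (assays
#'   contributing per row), `n_ties`, `skipped`.
#' @export
strongest_reduction_tally <- function(assays, tie_tol = 1e-9) {
  need <- c("hole_id", "i", "j")
  stopifnot(all(need %in% names(assays)))
  if (!"coefficient" %in% names(assays)) {
    assays$coefficient <- interaction_coefficient(assays$x_i, assays$x_j,
                                                  assays$x_ij)
  }
  labs <- sort(unique(c(assays$i, assays$j)))
  k <- length(labs)
  tally <- matrix(0L, k, k, dimnames = list(i = as.character(labs),
                                            j = as.character(labs)))
  n_ties <- 0L
  skipped <- character(0)
  for (h in unique(assays$hole_id)) {
    for (ii in sort(unique(assays$i[assays$hole_id == h]))) {
      rows <- assays$hole_id == h & assays$i == ii
      co <- assays$coefficient[rows]
      jj <- assays$j[rows]
      ok <- !is.na(co)
      if (sum(ok) < 2) {
        skipped <- c(skipped, sprintf("%s:i=%s", h, ii))
        next
      }
      co <- co[ok]; jj <- jj[ok]
      lo <- min(co)
      tied <- which(co <= lo + tie_tol)
      if (length(tied) > 1) n_ties <- n_ties + 1L
      winner <- jj[tied][order(jj[tied])][1]     # earliest timepoint label
      tally[as.character(ii), as.character(winner)] <-
        tally[as.character(ii), as.character(winner)] + 1L
    }
  }
  structure(list(tally = tally, column_sums = colSums(tally),
                 row_assays = rowSums(tally), n_ties = n_ties,
                 skipped = skipped),
            class = "tally_table")
}

#' Exact multinomial test on tally column sums
#'
#' Tests the null that each assay's strongest-reduction column is uniform
#' over the `n_categories` spent-media sources, using the maximum column
#' count as the statistic: `p = P(max count >= observed max)` under the
#' symmetric multinomial. Computed by exact enumeration of all count
#' configurations for totals up to 30, and by the Bonferroni-corrected exact
#' binomial tail `min(1, k * P[Bin(total, 1/k) >= max])` above that. The
#' p-value is exact-conservative: under the null `P(p <= alpha) <= alpha`.
#'
#' @param column_sums non-negative integer vector of tally column sums.
#' @param n_categories number of categories (default: length of
#'   `column_sums`).
#' @return the p-value.
#' @export
multinomial_column_test <- function(column_sums,
                                    n_categories = length(column_sums)) {
  if (any(column_sums < 0)) stop("negative column sums")
  total <- sum(column_sums)
  if (total < 1) stop("zero total: no assays tallied")
  k <- n_categories
  obs_max <- max(column_sums)
  if (total <= 30) {
    ## enumerate all compositions of `total` into k parts
    compositions <- function(total, k) {
      if (k == 1) return(matrix(total, 1, 1))
      out <- lapply(0:total, function(first) {
        rest <- compositions(total - first, k - 1)
        cbind(first, rest)
      })
      do.call(rbind, out)
    }
    comp <- compositions(total, k)
    probs <- apply(comp, 1, function(cc) {
      stats::dmultinom(cc, prob = rep(1 / k, k))
    })
    p <- sum(probs[apply(comp, 1, max) >= obs_max])
    min(1, p)
  } else {
    min(1, k * stats::pbinom(obs_max - 1, total, 1 / k, lower.tail = FALSE))
  }
}
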