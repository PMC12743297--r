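# Independent brute-force oracles used to validate the vectorised rules.
# Deliberately naive: literal loops over definitions, no shared code with the
# implementations they check.

# coloniser rule: zero in all baseline weeks, first appearance at some later
# week, present in every sampled week from then on
bf_is_coloniser <- function(counts, weeks, baseline_week = 0) {
  base <- counts[weeks <= baseline_week]
  if (any(base > 0)) return(list(coloniser = FALSE, first_week = NA))
  later_weeks <- weeks[weeks > baseline_week]
  later <- counts[weeks > baseline_week]
  first <- NA
  for (k in seq_along(later)) {
    if (later[k] > 0) { first <- k; break }
  }
  if (is.na(first)) return(list(coloniser = FALSE, first_week = NA))
  for (k in first:length(later)) {
    if (later[k] == 0) return(list(coloniser = FALSE, first_week = NA))
  }
  list(coloniser = TRUE, first_week = later_weeks[first])
}

# new/sweeping variant rule
bf_classify <- function(x, y, eps = 0, thr = 0.75) {
  new <- (x <= eps) && (y > eps)
  list(is_new = new, is_sweeping = new && (y > thr))
}

# strongest-reduction winner with earliest-label tie-break
bf_winner <- function(coefs, labels, tol = 1e-9) {
  lo <- min(coefs)
  cand <- labels[coefs <= lo + tol]
  sort(cand)[1]
}

# small ASV table fixture: explicit counts for one or more holes
make_table <- function(counts, weeks, holes = "H1", treatment = "control") {
  n_samp <- length(weeks) * length(holes)
  stopifnot(ncol(counts) == n_samp)
  meta <- expand.grid(week = weeks, hole_id = holes,
                      stringsAsFactors = FALSE)
  meta$treatment <- treatment
  meta$sample_id <- sprintf("%s_w%d", meta$hole_id, meta$week)
  colnames(counts) <- meta$sample_id
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("t%03d", seq_len(nrow(counts)))
  }
  asv_table(counts, meta[, c("sample_id", "hole_id", "week", "treatment")])
}
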