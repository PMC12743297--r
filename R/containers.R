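## Core data containers. Deliberately light-weight: plain matrices and data
## frames with validated structure, the way vegan and picante treat community
## tables.

#' Construct a validated ASV/genus count table
#'
#' @param counts integer matrix, taxa in rows, samples in columns; rownames
#'   are taxon IDs and colnames sample IDs.
#' @param sample_meta data frame with columns `sample_id`, `hole_id`,
#'   `week` (integer), `treatment`; must cover every sample column exactly.
#' @return an object of class `asv_table`: the count matrix with the metadata
#'   attached as attribute `sample_meta`.
#' @export
asv_table <- function(counts, sample_meta) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count for taxon '%s' in sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  need <- c("sample_id", "hole_id", "week", "treatment")
  if (!all(need %in% names(sample_meta))) {
    stop("sample_meta must have columns sample_id, hole_id, week, treatment")
  }
  missing <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(missing)) {
    stop(sprintf("metadata missing for sample(s): %s",
                 paste(missing, collapse = ", ")))
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  dup <- stats::aggregate(week ~ hole_id, sample_meta,
                          function(w) anyDuplicated(w) > 0)
  if (any(dup$week)) {
    stop(sprintf("duplicate sampling week within hole(s): %s",
                 paste(dup$hole_id[dup$week], collapse = ", ")))
  }
  structure(counts, sample_meta = sample_meta, class = c("asv_table", "matrix"))
}

#' Sample metadata of an ASV table
#' @param table an `asv_table`.
#' @return the per-sample metadata data frame.
#' @export
sample_meta <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  attr(table, "sample_meta")
}

#' Construct a validated circular coverage track
#'
#' @param bins data frame with columns `contig`, `start`, `end`, `depth`
#'   (0-based half-open intervals on a single circular contig, ordered,
#'   non-overlapping).
#' @param genome_length total circular genome length in bp; defaults to
#'   `max(bins$end)`.
#' @return data frame of class `coverage_track` with attribute
#'   `genome_length`.
#' @export
coverage_track <- function(bins, genome_length = NULL) {
  need <- c("contig", "start", "end", "depth")
  if (!all(need %in% names(bins))) {
    stop("coverage bins need columns contig, start, end, depth")
  }
  if (length(unique(bins$contig)) > 1) {
    stop("coverage_track holds a single circular contig; concatenate multi-contig assemblies explicitly (bin order is then arbitrary)")
  }
  o <- order(bins$start)
  bins <- bins[o, , drop = FALSE]
  if (any(bins$end <= bins$start)) stop("empty or inverted bins")
  if (any(bins$start[-1] < bins$end[-nrow(bins)])) stop("overlapping bins")
  if (any(bins$depth < 0)) stop("negative depths")
  if (is.null(genome_length)) genome_length <- max(bins$end)
  if (genome_length < max(bins$end)) stop("genome_length shorter than bins")
  rownames(bins) <- NULL
  structure(bins, genome_length = genome_length,
            class = c("coverage_track", "data.frame"))
}
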