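## Format readers and writers. Conventions: tab-separated tables with '#'
## comment headers and '.' for missing values; SNV positions are 1-based
## (VCF convention); bedGraph intervals are 0-based half-open. Numbers are
## written in C locale formatting throughout.

#' Write / read an ASV count table (TSV) with its sample metadata (CSV)
#'
#' The TSV has taxa as rows and samples as columns, with the taxon ID in the
#' first column; the CSV has columns `sample_id`, `hole_id`, `week`,
#' `treatment`.
#'
#' @param table an [asv_table()].
#' @param path TSV path for the counts.
#' @param meta_path CSV path for the sample metadata.
#' @return `write_asv_table()`: invisibly, the paths. `read_asv_table()`: a
#'   validated [asv_table()].
#' @export
write_asv_table <- function(table, path, meta_path) {
  stopifnot(inherits(table, "asv_table"))
  con <- file(path, "w")
  writeLines("# ASV/genus count table: taxa rows x sample columns", con)
  df <- data.frame(taxon_id = rownames(table), unclass(table)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  utils::write.csv(sample_meta(table), meta_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(path, meta_path))
}

#' @rdname write_asv_table
#' @export
read_asv_table <- function(path, meta_path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df) || names(df)[1] != "taxon_id") {
    stop("expected a header row starting with 'taxon_id'")
  }
  if (anyDuplicated(df$taxon_id)) {
    stop(sprintf("duplicate taxon ID(s): %s",
                 paste(unique(df$taxon_id[duplicated(df$taxon_id)]),
                       collapse = ", ")))
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric counts in table")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("fractional count for taxon '%s' in sample '%s'",
                 df$taxon_id[bad[1]], colnames(counts)[bad[2]]))
  }
  rownames(counts) <- df$taxon_id
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  asv_table(counts, meta)
}

#' Write / read a two-timepoint SNV table (TSV)
#'
#' Columns: `mag_id`, `contig`, `pos` (1-based), `class` (synonymous /
#' nonsynonymous / noncoding), `x`, `y` (allele frequencies at the two
#' timepoints), `depth_t1`, `depth_t2`.
#'
#' @param snvs SNV table data frame.
#' @param path TSV path.
#' @return `write_snv_table()`: invisibly the path; `read_snv_table()`: the
#'   validated data frame.
#' @export
write_snv_table <- function(snvs, path) {
  con <- file(path, "w")
  writeLines("# SNV table; pos is 1-based; x,y = allele freq at t1,t2", con)
  utils::write.table(snvs, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  close(con)
  invisible(path)
}

#' @rdname write_snv_table
#' @export
read_snv_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          na.strings = ".", stringsAsFactors = FALSE)
  need <- c("mag_id", "contig", "pos", "class", "x", "y", "depth_t1",
            "depth_t2")
  if (!all(need %in% names(df))) {
    stop(sprintf("SNV table missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  bad <- which(df$x < 0 | df$x > 1 | df$y < 0 | df$y > 1)
  if (length(bad)) {
    stop(sprintf("allele frequency outside [0, 1] at line %d of the table",
                 bad[1]))
  }
  key <- paste(df$mag_id, df$contig, df$pos)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate site: %s", key[duplicated(key)][1]))
  }
  df
}

#' Build an SNV table from two single-timepoint VCF files
#'
#' Reads a minimal VCF subset (CHROM, POS, and INFO fields `AF` for allele
#' frequency and `DP` for depth; optional `CLASS` for the annotation class)
#' from each timepoint and merges on (contig, position). Sites present at
#' only one timepoint get frequency 0 and depth 0 at the other, which is
#' exactly the detected/not-detected semantics feeding the new-variant rule.
#'
#' @param path_t1,path_t2 VCF paths for the first and second timepoint.
#' @param mag_id genome identifier to attach.
#' @return SNV table data frame (schema of [read_snv_table()]).
#' @export
read_snv_vcf_pair <- function(path_t1, path_t2, mag_id = "MAG") {
  read_one <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
    dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
    cls <- tryCatch(vcfR::extract.info(v, "CLASS"),
                    error = function(e) rep(NA_character_, nrow(fix)))
    if (any(is.na(af))) stop(sprintf("missing/invalid AF in %s", path))
    if (any(af < 0 | af > 1)) {
      stop(sprintf("allele frequency outside [0, 1] at line %d of %s",
                   which(af < 0 | af > 1)[1], path))
    }
    d <- data.frame(contig = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), af = af,
                    dp = ifelse(is.na(dp), 0, dp),
                    class = ifelse(is.na(cls), "noncoding", cls),
                    stringsAsFactors = FALSE)
    key <- paste(d$contig, d$pos)
    if (anyDuplicated(key)) {
      stop(sprintf("conflicting duplicate site in %s: %s", path,
                   key[duplicated(key)][1]))
    }
    d
  }
  t1 <- read_one(path_t1)
  t2 <- read_one(path_t2)
  merged <- merge(t1, t2, by = c("contig", "pos"), all = TRUE,
                  suffixes = c("_t1", "_t2"))
  data.frame(mag_id = mag_id, contig = merged$contig, pos = merged$pos,
             class = ifelse(!is.na(merged$class_t1), merged$class_t1,
                            merged$class_t2),
             x = ifelse(is.na(merged$af_t1), 0, merged$af_t1),
             y = ifelse(is.na(merged$af_t2), 0, merged$af_t2),
             depth_t1 = ifelse(is.na(merged$dp_t1), 0, merged$dp_t1),
             depth_t2 = ifelse(is.na(merged$dp_t2), 0, merged$dp_t2),
             stringsAsFactors = FALSE)
}

#' Write / read a coverage track as bedGraph
#'
#' Four tab-separated columns (contig, start, end, depth) with 0-based
#' half-open intervals.
#'
#' @param track a [coverage_track()].
#' @param path bedGraph path.
#' @param genome_length circular genome length for the track read back;
#'   defaults to `max(end)`.
#' @return `write_bedgraph()`: invisibly the path; `read_bedgraph()`: a
#'   [coverage_track()].
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  writeLines("# bedGraph coverage: contig start end depth (0-based half-open)",
             con)
  utils::write.table(as.data.frame(track)[, c("contig", "start", "end",
                                              "depth")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, genome_length = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("bedGraph needs 4 columns: contig start end depth")
  names(df)[1:4] <- c("contig", "start", "end", "depth")
  coverage_track(df[, 1:4], genome_length = genome_length)
}

#' Write / read time-shift assay measurements (long-format CSV)
#'
#' Columns: `hole_id`, `treatment`, `i`, `j`, `x_i`, `x_j`, `x_ij`.
#'
#' @param assays assay data frame.
#' @param path CSV path.
#' @return `write_timeshift_csv()`: invisibly the path;
#'   `read_timeshift_csv()`: the validated data frame.
#' @export
write_timeshift_csv <- function(assays, path) {
  utils::write.csv(assays, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeshift_csv
#' @export
read_timeshift_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hole_id", "i", "j", "x_i", "x_j", "x_ij")
  if (!all(need %in% names(df))) {
    stop(sprintf("assay file missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df
}
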