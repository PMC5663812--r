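# Readers and writers for the pipeline's on-disk formats. All genomic
# intervals are 0-based half-open internally; variant positions are
# 1-based on disk (VCF convention) and converted on read/write.

check_columns <- function(df, need, path) {
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  }
}

#' Read a capture-region depth table
#'
#' Tab-separated with columns `chrom`, `start`, `end` (0-based half-open),
#' `gc_fraction`, `depth_tumor`, `depth_normal`.
#'
#' @param path File path.
#' @return A tibble of regions.
#' @export
read_region_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("chrom", "start", "end", "gc_fraction",
                      "depth_tumor", "depth_normal"), path)
  bad <- which(df$start >= df$end)
  if (length(bad) > 0) {
    stop("start >= end at line(s) ", paste(bad + 1, collapse = ", "),
         " of ", path)
  }
  if (any(df$gc_fraction < 0 | df$gc_fraction > 1)) {
    stop("gc_fraction outside [0, 1] in ", path)
  }
  df
}

#' Read a heterozygous-SNP allele-count table
#'
#' Tab-separated with `chrom`, `pos` (1-based on disk), tumor/normal
#' ref/alt counts; positions are converted to 0-based.
#'
#' @param path File path.
#' @return A tibble with 0-based `pos`.
#' @export
read_snp_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("chrom", "pos", "ref_count_tumor", "alt_count_tumor",
                      "ref_count_normal", "alt_count_normal"), path)
  df$pos <- df$pos - 1L
  df
}

#' Read a somatic-variant candidate table
#'
#' VCF-subset TSV: `chrom`, `pos` (1-based on disk), `ref_allele`,
#' `alt_allele`, tumor/normal alt/ref counts and per-strand alt counts.
#' Positions convert to 0-based.
#'
#' @param path File path.
#' @return A tibble with 0-based `pos`.
#' @export
read_variant_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("chrom", "pos", "ref_allele", "alt_allele",
                      "tumor_alt", "tumor_ref", "normal_alt", "normal_ref"),
                path)
  bad <- which(df$pos < 1)
  if (length(bad) > 0) {
    stop("non-positive position at line(s) ", paste(bad + 1, collapse = ", "),
         " of ", path)
  }
  df$pos <- df$pos - 1L
  df
}

#' Read a probes-by-samples beta matrix from CSV
#'
#' First column `probe_id`, remaining columns one per sample.
#'
#' @param path File path.
#' @return A tibble with `probe_id` and sample columns.
#' @export
read_beta_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "probe_id") {
    stop("first column of ", path, " must be probe_id")
  }
  vals <- as.matrix(df[, -1])
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    stop("beta values outside [0, 1] in ", path)
  }
  df
}

#' Read a sample-to-group assignment file
#'
#' Tab-separated with columns `sample`, `group`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_group_file <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("sample", "group"), path)
  df
}

#' Write copy-number segments as a SEG file
#'
#' Columns: `sample`, `chrom`, `start`, `end`, `num_mark`,
#' `seg_mean` (log2 of the mean depth ratio).
#'
#' @param segments Segment tibble with `chrom`, `start`, `end`,
#'   `n_regions`, `mean_ratio`.
#' @param sample Sample identifier.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_seg <- function(segments, sample, path) {
  out <- tibble::tibble(
    sample = sample,
    chrom = segments$chrom,
    start = segments$start,
    end = segments$end,
    num_mark = segments$n_regions,
    seg_mean = log2(segments$mean_ratio)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write intervals as a BED file
#'
#' 0-based half-open, no header.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional name
#'   column(s).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(intervals, path, col_names = FALSE)
  invisible(path)
}

#' Write a purity estimate as key-value text
#'
#' @param purity One-row purity tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_purity_report <- function(purity, path) {
  writeLines(c(
    paste0("alpha\t", format(purity$alpha, digits = 6)),
    paste0("method\t", purity$method),
    paste0("support\t", purity$support)
  ), path)
  invisible(path)
}

#' Read a purity report written by [write_purity_report()]
#'
#' @param path File path.
#' @return A one-row purity tibble.
#' @export
read_purity_report <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, col.names = c("key", "value"))
  purity_estimate(
    as.numeric(kv$value[kv$key == "alpha"]),
    kv$value[kv$key == "method"],
    as.integer(kv$value[kv$key == "support"])
  )
}
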