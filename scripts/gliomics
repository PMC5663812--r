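#!/usr/bin/env Rscript

# Thin command-line wrapper over the gliomics package.
#
#   gliomics simulate --seed N --out DIR     write one synthetic data set
#   gliomics run      --seed N --out DIR     run the full synthetic pipeline

suppressMessages({
  library(optparse)
  library(gliomics)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "run")) {
  stop("usage: gliomics <simulate|run> --seed N --out DIR", call. = FALSE)
}
cmd <- args[1]
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 17L),
  make_option("--out", type = "character", default = "gliomics_out"),
  make_option("--alpha", type = "double", default = 0.7),
  make_option("--n-regions", type = "integer", default = 2000L,
              dest = "n_regions")
)), args = args[-1])

dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)

if (cmd == "simulate") {
  ex <- simulate_tumor_exome(seed = opts$seed, alpha = opts$alpha,
                             n_regions = opts$n_regions)
  readr::write_tsv(ex$regions, file.path(opts$out, "regions.tsv"))
  snps <- dplyr::mutate(ex$het_snps, pos = pos + 1L)  # 1-based on disk
  readr::write_tsv(snps, file.path(opts$out, "het_snps.tsv"))
  readr::write_tsv(ex$truth$region_cn, file.path(opts$out, "truth_region_cn.tsv"))
  sv <- simulate_somatic_candidates(seed = opts$seed + 1L, alpha = opts$alpha)
  readr::write_tsv(sv$candidates, file.path(opts$out, "somatic_candidates.tsv"))
  readr::write_tsv(sv$truth, file.path(opts$out, "truth_somatic.tsv"))
  meth <- simulate_beta_matrix(seed = opts$seed + 2L)
  readr::write_csv(meth$beta, file.path(opts$out, "beta.csv"))
  readr::write_tsv(meth$annotation, file.path(opts$out, "probe_annotation.tsv"))
  readr::write_tsv(meth$tss_links, file.path(opts$out, "tss_links.tsv"))
  readr::write_tsv(meth$groups, file.path(opts$out, "groups.tsv"))
  fus <- simulate_junction_reads(seed = opts$seed + 4L)
  readr::write_tsv(fus$junction_reads, file.path(opts$out, "junction_reads.tsv"))
  readr::write_tsv(fus$truth, file.path(opts$out, "truth_fusions.tsv"))
  surv <- simulate_survival(seed = opts$seed + 5L)
  readr::write_tsv(surv$records, file.path(opts$out, "survival.tsv"))
  cat("simulated data written to", opts$out, "\n")
} else {
  run_pipeline(list(seed = opts$seed, alpha_true = opts$alpha,
                    n_regions = opts$n_regions), out_dir = opts$out)
  cat("pipeline outputs written to", opts$out, "\n")
}
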