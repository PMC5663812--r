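test_that("tumor-vs-normal Fisher filter separates somatic from germline", {
  cand <- tibble::tibble(
    tumor_alt = c(20, 1, 10), tumor_ref = c(20, 39, 40),
    normal_alt = c(0, 1, 10), normal_ref = c(40, 39, 40)
  )
  out <- somatic_fisher_filter(cand, p_threshold = 0.01)
  expect_true(out$fisher_pass[1])
  expect_false(out$fisher_pass[2])  # identical proportions, p = 1
  expect_equal(out$fisher_flag[3], "germline_evidence")  # normal VAF 0.2
  zero <- somatic_fisher_filter(tibble::tibble(
    tumor_alt = 0, tumor_ref = 0, normal_alt = 5, normal_ref = 5))
  expect_equal(zero$fisher_flag, "no_depth")
})

test_that("heuristic filters flag strand bias, low depth and few alt reads", {
  cand <- tibble::tibble(
    tumor_alt = c(20, 20, 2, 10), tumor_ref = c(40, 40, 3, 40),
    strand_fwd_alt = c(10, 20, 1, 5), strand_rev_alt = c(10, 0, 1, 5)
  )
  out <- heuristic_filters(cand)
  expect_length(out$filter_flags[[1]], 0)
  expect_true("strand_bias" %in% out$filter_flags[[2]])
  expect_true(all(c("low_depth", "few_alt_reads") %in% out$filter_flags[[3]]))
  expect_true(out$heuristic_pass[4])
})

test_that("VAF adjustment applies the 15 percent retention boundary exactly", {
  out <- adjust_vaf(c(0.075, 0.0749, 0.5), 0.5)
  expect_equal(out$vaf_adjusted[1], 0.15)
  expect_true(out$retained[1])
  expect_false(out$retained[2])
  expect_true(out$retained[3])
  # default purity 0.2: vaf 0.029 adjusts to 0.145 and is dropped
  low <- adjust_vaf(0.029, purity_fallback_chain(NULL, NULL))
  expect_equal(low$vaf_adjusted, 0.145)
  expect_false(low$retained)
  expect_equal(adjust_vaf(0.5, 1)$vaf_adjusted, 0.5)
  expect_error(adjust_vaf(0.1, 0), "positive")
})

test_that("VAF adjustment is monotone and the pure-tumor set is a subset", {
  set.seed(61)
  vafs <- sort(runif(100))
  adj <- adjust_vaf(vafs, 0.6)
  expect_true(all(diff(adj$vaf_adjusted) >= 0))
  kept_full <- adjust_vaf(vafs, 1)$retained
  for (a in c(0.8, 0.5, 0.3)) {
    expect_true(all(adjust_vaf(vafs, a)$retained[kept_full]))
  }
})

test_that("filter verdict does not depend on rule application order", {
  sim <- simulate_somatic_candidates(seed = 67, n_true = 60,
                                     n_strand_bias = 20, n_germline = 20,
                                     n_low_depth = 20)
  cand <- sim$candidates
  cand$vaf_raw <- ifelse(cand$tumor_alt + cand$tumor_ref > 0,
                         cand$tumor_alt / (cand$tumor_alt + cand$tumor_ref), 0)
  purity <- purity_estimate_for_tests <- tibble::tibble(
    alpha = 0.7, method = "loh_allelic_imbalance", support = 10L)
  v1 <- filter_somatic_candidates(cand, purity)$somatic_call
  # reversed order of stages
  c2 <- adjust_vaf(cand, purity)
  c2 <- heuristic_filters(c2)
  c2 <- somatic_fisher_filter(c2)
  v2 <- c2$fisher_pass & c2$heuristic_pass & c2$retained
  expect_equal(v1, v2)
})

test_that("planted somatic/artifact mixture is filtered accurately", {
  sim <- simulate_somatic_candidates(seed = 71, alpha = 0.7, n_true = 1000,
                                     n_strand_bias = 330, n_germline = 330,
                                     n_low_depth = 340)
  out <- filter_somatic_candidates(sim$candidates, 0.7)
  sens <- mean(out$somatic_call[!sim$truth$is_artifact])
  false_rate <- mean(out$somatic_call[sim$truth$is_artifact])
  expect_gte(sens, 0.95)
  expect_lte(false_rate, 0.02)
})

test_that("consequence classification translates codons strand-aware", {
  # gene: ATG GAA CAA GGG TAA coded at positions 6..20 on the plus strand
  cds_seq <- "ATGGAACAAGGGTAA"
  genome <- list(chr1 = paste0("AAAAAA", cds_seq, "GTAAGTTTTTTTTTTTTAG",
                               "GGGCCC", strrep("T", 30)))
  tx <- list(gene = "G1", chrom = "chr1", strand = "+",
             exons = data.frame(start = c(0, 40), end = c(21, 50)),
             cds = data.frame(start = 6, end = 21))
  # GAA -> GAG at third codon position: still Glu
  expect_equal(classify_consequence("chr1", 11, "A", "G", tx, genome),
               "synonymous")
  # CAA -> TAA: stop gained
  expect_equal(classify_consequence("chr1", 12, "C", "T", tx, genome),
               "nonsense")
  # GAA -> GTA: Glu -> Val
  expect_equal(classify_consequence("chr1", 10, "A", "T", tx, genome),
               "missense")
  # first two intron bases are splice site
  expect_equal(classify_consequence("chr1", 21, "G", "A", tx, genome),
               "splice_site")
  expect_equal(classify_consequence("chr1", 22, "T", "A", tx, genome),
               "splice_site")
  expect_equal(classify_consequence("chr1", 30, "T", "A", tx, genome),
               "noncoding")
  # 2 bp deletion in CDS shifts the frame; 3 bp deletion does not
  expect_equal(classify_consequence("chr1", 9, "AAC", "A", tx, genome),
               "frameshift")
  expect_equal(classify_consequence("chr1", 9, "AACA", "A", tx, genome),
               "inframe_indel")
  expect_error(classify_consequence("chr2", 11, "A", "G", tx, genome),
               "mismatch")
})

test_that("minus-strand classification equals the reverse-complement case", {
  # same CDS presented on the minus strand of a reverse-complemented genome
  cds_seq <- "ATGGAACAAGGGTAA"
  fwd <- paste0("AAAAAA", cds_seq, strrep("G", 9))
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, NULL)[[1]]), collapse = ""))
  genome_fwd <- list(chr1 = fwd)
  genome_rev <- list(chr1 = rc(fwd))
  n <- nchar(fwd)
  tx_fwd <- list(gene = "G1", chrom = "chr1", strand = "+",
                 exons = data.frame(start = 0, end = n),
                 cds = data.frame(start = 6, end = 21))
  tx_rev <- list(gene = "G1", chrom = "chr1", strand = "-",
                 exons = data.frame(start = 0, end = n),
                 cds = data.frame(start = n - 21, end = n - 6))
  for (case in list(c(12, "C", "T"), c(10, "A", "T"), c(11, "A", "G"))) {
    pos <- as.integer(case[1])
    cons_fwd <- classify_consequence("chr1", pos, case[2], case[3],
                                     tx_fwd, genome_fwd)
    cons_rev <- classify_consequence("chr1", n - 1 - pos,
                                     chartr("ACGT", "TGCA", case[2]),
                                     chartr("ACGT", "TGCA", case[3]),
                                     tx_rev, genome_rev)
    expect_equal(cons_rev, cons_fwd)
  }
})

test_that("codon table matches the standard genetic code", {
  skip_if_not_installed("Biostrings")
  ref <- Biostrings::GENETIC_CODE
  mine <- gliomics:::CODON_TABLE
  expect_equal(unname(mine[names(ref)]), unname(as.character(ref)))
})

test_that("RNA validation counts assessable and concordant positions", {
  cand <- tibble::tibble(chrom = "chr1", pos = 1:10)
  rna <- tibble::tibble(chrom = "chr1", pos = 1:10,
                        rna_depth = c(rep(50, 10)),
                        rna_alt_reads = c(rep(3, 8), 0, 0))
  out <- rna_validate(cand, rna)
  expect_equal(out$n_assessable, 10)
  expect_equal(out$concordance_fraction, 0.8)
  none <- rna_validate(cand, dplyr::mutate(rna, rna_depth = 5))
  expect_equal(none$n_assessable, 0)
  expect_true(is.na(none$concordance_fraction))
  # depth threshold is strict (more than 10 reads)
  edge <- rna_validate(cand[1, ], tibble::tibble(
    chrom = "chr1", pos = 1, rna_depth = 10, rna_alt_reads = 5))
  expect_equal(edge$n_assessable, 0)
  # binomial dropout simulation: concordance tracks 1 - dropout rate
  set.seed(73)
  drop <- 0.12
  big <- tibble::tibble(chrom = "chr1", pos = 1:500)
  rna_big <- tibble::tibble(
    chrom = "chr1", pos = 1:500, rna_depth = 60,
    rna_alt_reads = rbinom(500, 1, 1 - drop) * rbinom(500, 60, 0.4))
  frac <- rna_validate(big, rna_big)$concordance_fraction
  expect_lt(abs(frac - (1 - drop)), 0.03)
})

test_that("hypermutators are flagged against the cohort median", {
  out <- flag_hypermutator(c(s1 = 50, s2 = 60, s3 = 55, s4 = 2000))
  expect_equal(out$hypermutator, c(FALSE, FALSE, FALSE, TRUE))
  eq <- flag_hypermutator(c(a = 100, b = 100, c = 100))
  expect_false(any(eq$hypermutator))
  set.seed(79)
  cohort <- c(pmax(5, round(rnorm(15, 55, 30))), 1040, 2100)
  names(cohort) <- sprintf("t%02d", seq_along(cohort))
  out2 <- flag_hypermutator(cohort)
  expect_equal(sum(out2$hypermutator), 2)
  expect_error(flag_hypermutator(c(a = 1, b = 2)), "3 samples")
})

test_that("mutual exclusivity counts co-occurrence and tests the 2x2 table", {
  st <- tibble::tibble(gene_a = c(rep(TRUE, 4), rep(FALSE, 13)),
                       gene_b = c(rep(FALSE, 4), rep(TRUE, 3), rep(FALSE, 10)))
  out <- mutual_exclusivity(st)
  expect_equal(out$n_both, 0)
  expect_equal(out$n_a_only, 4)
  expect_equal(out$n_b_only, 3)
  same <- mutual_exclusivity(tibble::tibble(gene_a = c(TRUE, TRUE, FALSE),
                                            gene_b = c(TRUE, TRUE, FALSE)))
  expect_equal(same$n_both, 2)
  # null calibration: independent mutation vectors give a valid test
  set.seed(83)
  rej <- mean(replicate(400, {
    mutual_exclusivity(tibble::tibble(gene_a = rbinom(17, 1, 0.3),
                                      gene_b = rbinom(17, 1, 0.3)))$p_value < 0.05
  }))
  expect_lte(rej, 0.07)  # exact test is conservative on small discrete tables
})
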