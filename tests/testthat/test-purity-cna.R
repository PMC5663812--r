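make_regions <- function(n = 200, depth_t = 100, depth_n = 100,
                         gc = NULL, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom,
    start = seq_len(n) * 1000,
    end = seq_len(n) * 1000 + 200,
    gc_fraction = if (is.null(gc)) rep(0.5, n) else gc,
    depth_tumor = rep_len(depth_t, n),
    depth_normal = rep_len(depth_n, n)
  )
}

test_that("depth ratio is 1 for identical samples and scale-invariant", {
  tr <- compute_depth_ratio(make_regions())
  expect_true(all(abs(tr$smoothed_ratio - 1) < 1e-9))
  # doubling tumor depth after library normalization still gives ratio 1;
  # a uniform factor cancels entirely
  set.seed(1)
  reg <- make_regions(300, depth_t = rpois(300, 100), depth_n = rpois(300, 100))
  tr1 <- compute_depth_ratio(reg)
  reg2 <- dplyr::mutate(reg, depth_tumor = depth_tumor * 7.3)
  tr2 <- compute_depth_ratio(reg2)
  expect_equal(tr1$smoothed_ratio, tr2$smoothed_ratio, tolerance = 1e-12)
})

test_that("uniform doubling of tumor copy yields ratio 2 before recentring", {
  reg <- make_regions(100, depth_t = 200, depth_n = 100)
  tr <- compute_depth_ratio(reg)
  # raw ratio is library-normalized, so a genome-wide doubling is absorbed;
  # the relative structure (flat track) is what remains
  expect_true(all(abs(tr$smoothed_ratio - 1) < 1e-9))
  # a focal doubling (half the genome) is preserved relative to baseline
  reg2 <- make_regions(400, depth_t = c(rep(100, 200), rep(200, 200)),
                       depth_n = 100)
  tr2 <- compute_depth_ratio(reg2)
  ratio_hi <- mean(tr2$smoothed_ratio[201:400])
  ratio_lo <- mean(tr2$smoothed_ratio[1:200])
  expect_equal(ratio_hi / ratio_lo, 2, tolerance = 0.01)
})

test_that("GC bias of known shape is removed by the bin-median correction", {
  set.seed(13)
  n <- 4000
  gc <- runif(n, 0.3, 0.7)
  bias <- 1 + 0.3 * sin(2 * pi * (gc - 0.3) / 0.4)
  reg <- make_regions(n, gc = gc)
  reg$depth_tumor <- rpois(n, 100 * bias)
  reg$depth_normal <- rpois(n, 100)
  tr <- compute_depth_ratio(reg)
  bins <- cut(gc, seq(0, 1, by = 0.05))
  bin_medians <- tapply(tr$gc_corrected_ratio, bins, median, na.rm = TRUE)
  bin_medians <- bin_medians[!is.na(bin_medians)]
  expect_true(all(abs(bin_medians - 1) < 0.02))
})

test_that("regions below the minimum normal depth are masked", {
  reg <- make_regions(100)
  reg$depth_normal[5:10] <- 3
  tr <- compute_depth_ratio(reg)
  expect_true(all(tr$masked[5:10]))
  expect_true(all(is.na(tr$raw_ratio[5:10])))
  reg$depth_normal <- 0
  expect_error(compute_depth_ratio(reg), "masked")
})

test_that("wavelet peak detection finds planted density modes", {
  set.seed(17)
  one <- tibble::tibble(smoothed_ratio = rnorm(1000, 1, 0.02))
  p1 <- detect_peaks_wavelet(one)
  expect_length(p1, 1)
  expect_lt(abs(p1 - 1), 0.02)
  mix <- tibble::tibble(smoothed_ratio = c(rnorm(400, 0.7, 0.03),
                                           rnorm(1200, 1.0, 0.03),
                                           rnorm(400, 1.3, 0.03)))
  p3 <- detect_peaks_wavelet(mix)
  expect_length(p3, 3)
  expect_true(all(abs(p3 - c(0.7, 1.0, 1.3)) < 0.03))
  expect_true(all(diff(p3) > 0))
  expect_error(detect_peaks_wavelet(tibble::tibble(smoothed_ratio = rnorm(10))),
               "50")
})

test_that("Gaussian mixture EM recovers planted components monotonically", {
  set.seed(19)
  x <- rnorm(2000, 1.2, 0.05)
  fit1 <- fit_gaussian_peaks(x, 1.1)
  expect_lt(abs(fit1$mean_ratio - 1.2), 2 * 0.05 / sqrt(2000) * 2)
  x3 <- c(rnorm(400, 0.7, 0.03), rnorm(1200, 1.0, 0.03), rnorm(400, 1.3, 0.03))
  fit3 <- fit_gaussian_peaks(x3, c(0.7, 1.0, 1.3))
  expect_equal(fit3$weight, c(0.2, 0.6, 0.2), tolerance = 0.05)
  ll <- attr(fit3, "loglik")
  expect_true(all(diff(ll) >= -1e-6))
  expect_equal(sum(fit3$weight), 1, tolerance = 1e-9)
})

test_that("Viterbi equals exhaustive best-path search on small instances", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    k <- sample(2:3, 1)
    means <- sort(runif(k, 0.5, 2))
    sigmas <- runif(k, 0.05, 0.2)
    w <- as.numeric(rmultinom(1, 20, rep(1, k)) + 1)
    w <- w / sum(w)
    obs <- runif(n, 0.4, 2.1)
    expect_equal(viterbi_path(obs, means, sigmas, w),
                 brute_force_viterbi(obs, means, sigmas, w))
  }
})

test_that("segmentation recovers planted breakpoints", {
  # single-peak model: one segment per chromosome
  reg <- make_regions(120, chrom = rep(c("chrA", "chrB"), each = 60))
  tr <- compute_depth_ratio(reg)
  pk <- tibble::tibble(peak_id = 1L, mean_ratio = 1, sigma = 0.05, weight = 1)
  segs <- segment_hmm(tr, pk)
  expect_equal(nrow(segs), 2)
  # six true segments over 2000 regions, steps >= 0.25, noise sd 0.05
  set.seed(29)
  levels <- c(1, 1.3, 1, 0.7, 1, 1.5)
  true_state <- rep(seq_along(levels), c(400, 300, 300, 300, 300, 400))
  track <- tibble::tibble(
    chrom = "chr1",
    start = seq_along(true_state) * 1000,
    end = seq_along(true_state) * 1000 + 200,
    masked = FALSE,
    smoothed_ratio = rnorm(length(true_state), levels[true_state], 0.05)
  )
  peaks <- tibble::tibble(peak_id = 1:4,
                          mean_ratio = c(0.7, 1.0, 1.3, 1.5),
                          sigma = 0.05, weight = c(0.15, 0.5, 0.2, 0.15))
  segs <- segment_hmm(track, peaks)
  called <- rep(segs$peak_id, segs$n_regions)
  truth_peak <- c(2, 3, 2, 1, 2, 4)[true_state]
  expect_gt(mean(called == truth_peak), 0.95)
  bp_true <- cumsum(c(400, 300, 300, 300, 300))
  bp_called <- cumsum(segs$n_regions)
  for (b in bp_true) expect_lte(min(abs(bp_called - b)), 2)
})

test_that("allelic imbalance algebra matches the two-population model", {
  # alpha = 1 hemizygous deletion: only one allele remains
  mk_snps <- function(p, n = 50, depth = 2000) {
    tibble::tibble(chrom = "chr1", pos = seq_len(n) * 100,
                   ref_count_tumor = round(depth * (1 - p)),
                   alt_count_tumor = round(depth * p),
                   ref_count_normal = depth / 2, alt_count_normal = depth / 2)
  }
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, peak_id = 1,
                        mean_ratio = 0.75, n_regions = 100)
  a1 <- allelic_imbalance(seg, mk_snps(1))
  expect_equal(a1$mirrored_baf, 1)
  expect_equal(a1$allelic_state, "LOH")
  a2 <- allelic_imbalance(seg, mk_snps(1 / (2 - 0.5)))
  expect_equal(a2$mirrored_baf, 1 / 1.5, tolerance = 1e-3)
  seg_cn <- dplyr::mutate(seg, mean_ratio = 1)
  a3 <- allelic_imbalance(seg_cn, mk_snps((1 + 0.5) / 2))
  expect_equal(a3$mirrored_baf, 0.75, tolerance = 1e-3)
  # segments without SNPs keep an absent mirrored BAF
  far <- dplyr::mutate(seg, chrom = "chr9")
  expect_true(is.na(allelic_imbalance(far, mk_snps(0.5))$mirrored_baf))
})

test_that("purity from LOH inverts the mirrored-BAF relations", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, peak_id = 1,
                        mean_ratio = 0.75, n_regions = 100,
                        mirrored_baf = 1.0, n_het_snps = 50,
                        allelic_state = "LOH")
  expect_equal(estimate_purity_from_loh(seg)$alpha, 1)
  seg$mirrored_baf <- 1 / 1.5
  expect_equal(estimate_purity_from_loh(seg)$alpha, 0.5, tolerance = 0.01)
  cn <- dplyr::mutate(seg, mean_ratio = 1, mirrored_baf = 0.75)
  expect_equal(estimate_purity_from_loh(cn)$alpha, 0.5, tolerance = 1e-9)
  expect_null(estimate_purity_from_loh(dplyr::mutate(seg, allelic_state = "balanced")))
  # simulated recovery from binomial reads
  set.seed(37)
  ex <- simulate_tumor_exome(seed = 37, alpha = 0.6, n_regions = 1000)
  fit <- call_copy_number(ex$regions, ex$het_snps)
  expect_lt(abs(fit$purity$alpha - 0.6), 0.05)
})

test_that("purity from the VAF distribution doubles the density mode", {
  set.seed(43)
  v5 <- rnorm(80, 0.5, 0.005)
  expect_equal(estimate_purity_from_vaf(v5)$alpha, 1, tolerance = 0.02)
  v25 <- rnorm(80, 0.25, 0.005)
  expect_equal(estimate_purity_from_vaf(v25)$alpha, 0.5, tolerance = 0.02)
  vafs <- rbinom(80, 120, 0.4 / 2) / 120
  est <- estimate_purity_from_vaf(vafs)
  expect_lt(abs(est$alpha - 0.4), 0.08)
  expect_null(estimate_purity_from_vaf(c(0.2, 0.3)))
})

test_that("purity fallback chain tries LOH, then VAF, then the 0.2 default", {
  def <- purity_fallback_chain(NULL, NULL)
  expect_equal(def$alpha, 0.2)
  expect_equal(def$method, "default_constant")
  loh_seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6, peak_id = 1,
                            mean_ratio = 0.75, n_regions = 100,
                            mirrored_baf = 0.8, n_het_snps = 40,
                            allelic_state = "LOH")
  expect_equal(purity_fallback_chain(loh_seg, rep(0.25, 100))$method,
               "loh_allelic_imbalance")
  expect_equal(purity_fallback_chain(NULL, rnorm(100, 0.25, 0.01))$method,
               "vaf_distribution")
})

test_that("integer-CN fitting solves the exact lattice examples", {
  mk_peaks <- function(m) tibble::tibble(peak_id = seq_along(m),
                                         mean_ratio = m, sigma = 0.03,
                                         weight = rep(1 / length(m), length(m)))
  f1 <- fit_integer_cn(mk_peaks(c(1.0, 1.5)))
  expect_equal(f1$purity$alpha, 1)
  expect_equal(f1$peaks$assigned_cn, c(2L, 3L))
  f2 <- fit_integer_cn(mk_peaks(c(1.0, 1.25)))
  expect_equal(f2$purity$alpha, 0.5)
  expect_equal(f2$peaks$assigned_cn, c(2L, 3L))
  # at alpha = 1 ratios map to n = 2 r for integer 2 r
  f3 <- fit_integer_cn(mk_peaks(c(0.5, 1.0, 1.5, 2.0)), alpha_hint = 1)
  expect_equal(f3$purity$alpha, 1)
  expect_equal(f3$peaks$assigned_cn, c(1L, 2L, 3L, 4L))
})

test_that("end-to-end recovery on a simulated exome", {
  ex <- simulate_tumor_exome(seed = 101, alpha = 0.7)
  fit <- call_copy_number(ex$regions, ex$het_snps)
  expect_lt(abs(fit$purity$alpha - 0.7), 0.05)
  expect_gte(cn_concordance(fit, ex$truth$region_cn), 0.95)
  # cnLOH chromosome is labeled as such
  chr5 <- fit$segments[fit$segments$chrom == "chr5", ]
  expect_true(any(chr5$allelic_state == "cnLOH", na.rm = TRUE))
})

test_that("very low purity never crashes and returns a valid estimate", {
  ex <- simulate_tumor_exome(seed = 53, alpha = 0.12, n_regions = 1000)
  fit <- call_copy_number(ex$regions, ex$het_snps)
  expect_true(fit$purity$alpha > 0 && fit$purity$alpha <= 1)
  expect_true(fit$purity$method %in%
                c("loh_allelic_imbalance", "vaf_distribution",
                  "default_constant"))
})

test_that("cohort gain/loss frequencies count cnLOH as loss", {
  bins <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(100, 200))
  segs <- tibble::tibble(
    sample = c("s1", "s2", "s3", "s4"),
    chrom = "chr1", start = 0, end = 100,
    integer_cn = c(1, 1, 2, 2),
    allelic_state = c("LOH", "LOH", "balanced", "balanced")
  )
  fr <- cna_frequency(segs, bins)
  expect_equal(fr$loss_freq, c(0.5, 0))
  expect_equal(fr$gain_freq, c(0, 0))
  # diploid balanced genome: all frequencies zero
  dip <- tibble::tibble(sample = "s1", chrom = "chr1", start = 0, end = 200,
                        integer_cn = 2, allelic_state = "balanced")
  fr0 <- cna_frequency(dip, bins)
  expect_true(all(fr0$gain_freq == 0) && all(fr0$loss_freq == 0))
  # cnLOH counts as loss, not gain
  cnl <- dplyr::mutate(dip, allelic_state = "cnLOH")
  fr1 <- cna_frequency(cnl, bins)
  expect_equal(fr1$loss_freq, c(1, 1))
  expect_equal(fr1$gain_freq, c(0, 0))
})
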