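# Seeded generators for every input class the pipeline consumes, each
# emitting a machine-readable truth object so downstream stages can be
# scored without re-deriving anything.

#' Default copy-number profile for exome simulation
#'
#' Five chromosomes of equal region counts: a diploid balanced baseline,
#' a hemizygous deletion (CN 1, LOH), a single-copy gain (CN 3), a
#' two-copy gain (CN 4) and a whole-chromosome copy-neutral LOH
#' (uniparental disomy: CN 2, one parental allele lost).
#'
#' @param n_regions Total number of capture regions.
#' @return A tibble `chrom`, `first_region`, `last_region` (1-based,
#'   inclusive, within-genome indices), `cn`, `loh`.
#' @export
default_cn_profile <- function(n_regions = 2000) {
  per <- n_regions %/% 5
  tibble::tibble(
    chrom = c("chr1", "chr2", "chr2", "chr3", "chr4", "chr4", "chr5"),
    first_region = c(1, per + 1, per + per %/% 2 + 1, 2 * per + 1,
                     3 * per + 1, 3 * per + per %/% 2 + 1, 4 * per + 1),
    last_region = c(per, per + per %/% 2, 2 * per, 3 * per,
                    3 * per + per %/% 2, 4 * per, n_regions),
    cn = c(2, 1, 2, 3, 4, 2, 2),
    loh = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

nb_draw <- function(n, mean, overdispersion) {
  # extra-Poisson noise: var = mean + (overdispersion * mean)^2
  if (overdispersion <= 0) return(stats::rpois(n, mean))
  size <- 1 / overdispersion^2
  stats::rnbinom(n, mu = mean, size = size)
}

#' Simulate a tumor/normal exome depth table with known truth
#'
#' Normal fragment counts per capture region are negative-binomial around
#' `depth_mean` (scaled by region length over read length) and modulated
#' by a smooth GC bias; tumor counts are additionally scaled by the
#' expected depth ratio `(2(1 - alpha) + n alpha)/2` of the region's true
#' copy number. Heterozygous SNP alt counts are binomial with success
#' probability from the two-population allele mixture implied by the
#' region's copy number and allelic state.
#'
#' @param seed Random seed (mandatory).
#' @param alpha True tumor purity in (0, 1].
#' @param cn_profile Copy-number profile tibble (see
#'   [default_cn_profile()]); regions are distributed over its chromosome
#'   blocks.
#' @param n_regions Number of capture regions.
#' @param depth_mean Mean per-region coverage.
#' @param overdispersion Extra-Poisson coefficient of variation of the
#'   fragment counts.
#' @param region_length,read_length Used to convert coverage to fragment
#'   counts (`depth * region_length / read_length`).
#' @param gc_amplitude Amplitude of the sinusoidal GC bias on depth.
#' @param snps_per_region Expected heterozygous SNPs per region.
#' @param snp_depth Mean depth at SNP positions.
#' @return A list with `regions` (depth table), `het_snps`, and `truth`
#'   (list: `alpha_true`, `region_cn`, `segments`).
#' @export
simulate_tumor_exome <- function(seed, alpha = 0.7,
                                 cn_profile = NULL, n_regions = 2000,
                                 depth_mean = 100, overdispersion = 0.05,
                                 region_length = 200, read_length = 100,
                                 gc_amplitude = 0.15,
                                 snps_per_region = 0.25, snp_depth = 100) {
  stopifnot(alpha > 0, alpha <= 1)
  if (is.null(cn_profile)) cn_profile <- default_cn_profile(n_regions)
  if (any(cn_profile$cn < 0) || any(cn_profile$first_region > cn_profile$last_region) ||
      max(cn_profile$last_region) != n_regions) {
    stop("invalid copy-number profile")
  }
  set.seed(seed)
  region_cn <- integer(n_regions)
  region_loh <- logical(n_regions)
  region_chrom <- character(n_regions)
  for (i in seq_len(nrow(cn_profile))) {
    idx <- cn_profile$first_region[i]:cn_profile$last_region[i]
    region_cn[idx] <- cn_profile$cn[i]
    region_loh[idx] <- cn_profile$loh[i]
    region_chrom[idx] <- cn_profile$chrom[i]
  }
  pos_in_chrom <- stats::ave(seq_len(n_regions), region_chrom,
                             FUN = seq_along)
  start <- (pos_in_chrom - 1) * 1000
  gc <- 0.35 + 0.3 * stats::runif(n_regions)
  gc_bias <- 1 + gc_amplitude * sin(2 * pi * (gc - 0.35) / 0.3)
  frag_factor <- region_length / read_length
  mu_n <- depth_mean * frag_factor * gc_bias
  ratio_true <- expected_ratio(region_cn, alpha)
  mu_t <- mu_n * ratio_true
  depth_normal <- nb_draw(n_regions, mu_n, overdispersion) / frag_factor
  depth_tumor <- nb_draw(n_regions, mu_t, overdispersion) / frag_factor
  regions <- tibble::tibble(
    chrom = region_chrom,
    start = start,
    end = start + region_length,
    gc_fraction = gc,
    depth_tumor = depth_tumor,
    depth_normal = depth_normal
  )
  # heterozygous SNPs: B allele on the lost/kept haplotype at random
  n_snps <- stats::rpois(1, snps_per_region * n_regions)
  snp_region <- sample.int(n_regions, n_snps, replace = TRUE)
  b_on_major <- stats::runif(n_snps) < 0.5
  n_cn <- region_cn[snp_region]
  major <- ifelse(region_loh[snp_region], n_cn, ceiling(n_cn / 2))
  b_copies <- ifelse(b_on_major, major, n_cn - major)
  p_b <- (b_copies * alpha + (1 - alpha)) /
    pmax(1e-9, n_cn * alpha + 2 * (1 - alpha))
  dp_t <- pmax(1, stats::rpois(n_snps, snp_depth))
  dp_n <- pmax(1, stats::rpois(n_snps, snp_depth))
  alt_t <- stats::rbinom(n_snps, dp_t, p_b)
  alt_n <- stats::rbinom(n_snps, dp_n, 0.5)
  het_snps <- tibble::tibble(
    chrom = region_chrom[snp_region],
    pos = start[snp_region] + sample.int(region_length, n_snps, replace = TRUE) - 1L,
    ref_count_tumor = dp_t - alt_t,
    alt_count_tumor = alt_t,
    ref_count_normal = dp_n - alt_n,
    alt_count_normal = alt_n
  )
  truth_segments <- cn_profile
  truth_segments$start <- start[cn_profile$first_region]
  truth_segments$end <- start[cn_profile$last_region] + region_length
  list(
    regions = regions,
    het_snps = het_snps,
    truth = list(
      alpha_true = alpha,
      region_cn = tibble::tibble(chrom = region_chrom, start = start,
                                 cn = region_cn, loh = region_loh),
      segments = truth_segments
    )
  )
}

#' Simulate a somatic-candidate table with planted artifacts
#'
#' True somatic variants receive tumor alt counts binomial at
#' `vaf = ccf * alpha / 2` and normal alt counts at the sequencing error
#' rate; artifact classes are planted per the design: strand-biased (all
#' alt reads on one strand), germline leak (normal VAF near 0.5) and
#' low-depth candidates.
#'
#' @param seed Random seed.
#' @param alpha Tumor purity.
#' @param n_true,n_strand_bias,n_germline,n_low_depth Class sizes.
#' @param depth_mean Mean sequencing depth.
#' @param ccf Clonal cell fraction of the true variants.
#' @param error_rate Per-read sequencing error rate.
#' @return A list with `candidates` (tibble) and `truth` (tibble with
#'   `is_artifact`, `artifact_class`).
#' @export
simulate_somatic_candidates <- function(seed, alpha = 0.7, n_true = 100,
                                        n_strand_bias = 20, n_germline = 20,
                                        n_low_depth = 10, depth_mean = 80,
                                        ccf = 1, error_rate = 0.001) {
  stopifnot(alpha > 0, alpha <= 1)
  set.seed(seed)
  make <- function(n, class) {
    if (n == 0) return(NULL)
    dp_t <- pmax(2, stats::rpois(n, depth_mean))
    dp_n <- pmax(2, stats::rpois(n, depth_mean))
    vaf <- ccf * alpha / 2
    alt_t <- stats::rbinom(n, dp_t, vaf)
    alt_n <- stats::rbinom(n, dp_n, error_rate)
    fwd_frac <- 0.5
    if (class == "strand_bias") fwd_frac <- 1
    if (class == "germline") alt_n <- stats::rbinom(n, dp_n, 0.5)
    if (class == "germline") alt_t <- stats::rbinom(n, dp_t, 0.5)
    if (class == "low_depth") {
      dp_t <- pmax(1, pmin(7, stats::rpois(n, 4)))
      alt_t <- stats::rbinom(n, dp_t, vaf)
    }
    fwd <- stats::rbinom(n, alt_t, fwd_frac)
    tibble::tibble(
      chrom = "chr1",
      pos = NA_integer_,
      ref_allele = "A", alt_allele = "T",
      tumor_alt = alt_t, tumor_ref = dp_t - alt_t,
      normal_alt = alt_n, normal_ref = dp_n - alt_n,
      strand_fwd_alt = fwd, strand_rev_alt = alt_t - fwd,
      artifact_class = if (class == "true") NA_character_ else class
    )
  }
  cand <- dplyr::bind_rows(
    make(n_true, "true"),
    make(n_strand_bias, "strand_bias"),
    make(n_germline, "germline"),
    make(n_low_depth, "low_depth")
  )
  cand$pos <- seq_len(nrow(cand)) * 1000L
  truth <- tibble::tibble(
    pos = cand$pos,
    is_artifact = !is.na(cand$artifact_class),
    artifact_class = cand$artifact_class
  )
  list(candidates = dplyr::select(cand, -"artifact_class"), truth = truth)
}

rtrunc_norm <- function(n, mean, sd) pmin(1, pmax(0, stats::rnorm(n, mean, sd)))

#' Simulate a beta-value matrix with planted clusters and promoters
#'
#' Per-cluster probe archetypes are drawn from a two-component Beta
#' mixture (hypomethylated ~ Beta(2, 10), hypermethylated ~ Beta(10, 2));
#' informative probes redraw their archetype per cluster, background
#' probes share one archetype. Sample values add truncated Gaussian
#' noise. Promoter probes carry TSS links; the first `n_diff_genes` genes
#' get a planted group-1-vs-group-2 promoter shift of `diff_delta`.
#' X/Y-chromosome and SNP-flagged decoy probes are appended.
#'
#' @param seed Random seed.
#' @param samples_per_group Integer vector; one group of samples per entry.
#' @param n_genes Number of promoter genes.
#' @param probes_per_promoter Probes within the promoter window per gene.
#' @param n_distal_probes Distal (enhancer-territory) probes.
#' @param frac_informative Fraction of probes that differ across groups.
#' @param noise_sd SD of the truncated Gaussian sample noise.
#' @param n_diff_genes Genes with a planted group1-group2 difference.
#' @param diff_delta Planted promoter beta difference (group1 - group2).
#' @param n_decoy_xy,n_decoy_snp Decoy probe counts.
#' @return A list with `beta` (tibble with `probe_id` + sample columns),
#'   `annotation`, `tss_links`, `groups` (tibble sample/group) and
#'   `truth` (cluster labels, differential genes).
#' @export
simulate_beta_matrix <- function(seed, samples_per_group = rep(10, 6),
                                 n_genes = 100, probes_per_promoter = 3,
                                 n_distal_probes = 200,
                                 frac_informative = 0.5, noise_sd = 0.05,
                                 n_diff_genes = 0, diff_delta = 0.35,
                                 n_decoy_xy = 20, n_decoy_snp = 10) {
  set.seed(seed)
  n_groups <- length(samples_per_group)
  group_of <- rep(seq_len(n_groups), samples_per_group)
  n_samples <- length(group_of)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  n_prom <- n_genes * probes_per_promoter
  n_main <- n_prom + n_distal_probes
  probe_ids <- sprintf("cg%06d", seq_len(n_main + n_decoy_xy + n_decoy_snp))
  draw_archetype <- function(n) {
    hyper <- stats::runif(n) < 0.5
    ifelse(hyper, stats::rbeta(n, 10, 2), stats::rbeta(n, 2, 10))
  }
  base_arch <- draw_archetype(n_main)
  informative <- stats::runif(n_main) < frac_informative
  arch <- matrix(rep(base_arch, n_groups), ncol = n_groups)
  for (g in seq_len(n_groups)) {
    arch[informative, g] <- draw_archetype(sum(informative))
  }
  # planted differential promoter genes: group 1 shifted by diff_delta
  diff_gene_idx <- seq_len(min(n_diff_genes, n_genes))
  if (length(diff_gene_idx) > 0 && n_diff_genes > 0) {
    probe_rows <- rep((diff_gene_idx - 1) * probes_per_promoter,
                      each = probes_per_promoter) +
      seq_len(probes_per_promoter)
    base <- stats::rbeta(length(probe_rows), 2, 10) * 0.3 + 0.1
    for (g in seq_len(n_groups)) {
      arch[probe_rows, g] <- if (g == 1) pmin(1, base + diff_delta) else base
    }
  }
  beta <- matrix(NA_real_, n_main, n_samples)
  for (s in seq_len(n_samples)) {
    beta[, s] <- rtrunc_norm(n_main, arch[, group_of[s]], noise_sd)
  }
  decoys <- matrix(rtrunc_norm((n_decoy_xy + n_decoy_snp) * n_samples,
                               0.5, 0.2),
                   n_decoy_xy + n_decoy_snp, n_samples)
  full <- rbind(beta, decoys)
  rownames(full) <- probe_ids
  colnames(full) <- sample_ids
  annotation <- tibble::tibble(
    probe_id = probe_ids,
    chrom = c(rep("chr1", n_main),
              rep(c("chrX", "chrY"), length.out = n_decoy_xy),
              rep("chr2", n_decoy_snp)),
    pos = c(seq_len(n_main) * 2000L,
            seq_len(n_decoy_xy) * 2000L,
            seq_len(n_decoy_snp) * 2000L),
    snp_associated = c(rep(FALSE, n_main + n_decoy_xy),
                       rep(TRUE, n_decoy_snp))
  )
  tss_links <- tibble::tibble(
    probe_id = probe_ids[seq_len(n_prom)],
    gene = rep(sprintf("G%04d", seq_len(n_genes)), each = probes_per_promoter),
    tss_distance = rep(
      seq(-1500, 1500, length.out = probes_per_promoter + 2)[
        2:(probes_per_promoter + 1)],
      n_genes) |> round()
  )
  if (n_distal_probes > 0) {
    tss_links <- dplyr::bind_rows(tss_links, tibble::tibble(
      probe_id = probe_ids[n_prom + seq_len(n_distal_probes)],
      gene = sprintf("G%04d", sample.int(n_genes, n_distal_probes,
                                         replace = TRUE)),
      tss_distance = sample(5000:50000, n_distal_probes, replace = TRUE) *
        sample(c(-1L, 1L), n_distal_probes, replace = TRUE)
    ))
  }
  beta_tbl <- dplyr::bind_cols(tibble::tibble(probe_id = probe_ids),
                               tibble::as_tibble(full))
  list(
    beta = beta_tbl,
    annotation = annotation,
    tss_links = tss_links,
    groups = tibble::tibble(sample = sample_ids,
                            group = paste0("grp", group_of)),
    truth = list(
      cluster_labels = stats::setNames(group_of, sample_ids),
      differential_genes = tibble::tibble(
        gene = sprintf("G%04d", diff_gene_idx),
        delta_beta = if (length(diff_gene_idx)) diff_delta else numeric(0)
      )
    )
  )
}

#' Simulate junction reads for true fusions and designed decoys
#'
#' Each true fusion gets at least five supporting reads with both flanks
#' of at least 12 bases; decoys are constructed to fail exactly one stated
#' rule (too few reads, short flanks, or same-chromosome distance below
#' 100 kb), recorded in the truth table.
#'
#' @param seed Random seed.
#' @param n_true Number of true fusions.
#' @param n_decoys Number of decoy candidates.
#' @param reads_range Range of supporting-read counts for true fusions.
#' @return A list with `junction_reads` and `truth` (one row per
#'   candidate: breakpoints, `is_true`, `failing_rule`).
#' @export
simulate_junction_reads <- function(seed, n_true = 3, n_decoys = 20,
                                    reads_range = c(5, 12)) {
  set.seed(seed)
  mk_reads <- function(id, chrom_l, pos_l, chrom_r, pos_r, n_reads,
                       flank_min) {
    tibble::tibble(
      read_id = sprintf("%s_r%02d", id, seq_len(n_reads)),
      chrom_left = chrom_l,
      pos_left = pos_l + sample(-2:2, n_reads, replace = TRUE),
      chrom_right = chrom_r,
      pos_right = pos_r + sample(-2:2, n_reads, replace = TRUE),
      left_match_len = sample(flank_min:40, n_reads, replace = TRUE),
      right_match_len = sample(flank_min:40, n_reads, replace = TRUE)
    )
  }
  reads <- list()
  truth <- list()
  spacing <- 1e7
  for (i in seq_len(n_true)) {
    id <- sprintf("fus%02d", i)
    n_reads <- sample(reads_range[1]:reads_range[2], 1)
    reads[[id]] <- mk_reads(id, "chr1", i * spacing, "chr9",
                            i * spacing + 5e6, n_reads, 12)
    truth[[id]] <- tibble::tibble(candidate = id, is_true = TRUE,
                                  failing_rule = NA_character_)
  }
  rules <- rep(c("too_few_reads", "short_flank", "read_through"),
               length.out = n_decoys)
  for (i in seq_len(n_decoys)) {
    id <- sprintf("dec%02d", i)
    base <- (n_true + i) * spacing
    rule <- rules[i]
    if (rule == "too_few_reads") {
      r <- mk_reads(id, "chr2", base, "chr10", base + 5e6,
                    sample(1:4, 1), 12)
    } else if (rule == "short_flank") {
      r <- mk_reads(id, "chr3", base, "chr11", base + 5e6,
                    sample(5:8, 1), 12)
      r$left_match_len <- sample(5:11, nrow(r), replace = TRUE)
    } else {
      r <- mk_reads(id, "chr4", base, "chr4",
                    base + sample(10000:99000, 1), sample(5:8, 1), 12)
    }
    reads[[id]] <- r
    truth[[id]] <- tibble::tibble(candidate = id, is_true = FALSE,
                                  failing_rule = rule)
  }
  list(junction_reads = dplyr::bind_rows(reads),
       truth = dplyr::bind_rows(truth))
}

#' Simulate two-group survival data
#'
#' Exponential event times per group (group 2's hazard is
#' `hazard * hazard_ratio`) with uniform censoring.
#'
#' @param seed Random seed.
#' @param n_per_group Samples per group (length-2 vector or scalar).
#' @param hazard Baseline hazard of group 1 (events per month).
#' @param hazard_ratio Group 2 vs group 1 hazard ratio.
#' @param censor_max Upper bound of the uniform censoring time.
#' @return A list with `records` (tibble `time`, `event`, `group`) and
#'   `truth` (the generating parameters).
#' @export
simulate_survival <- function(seed, n_per_group = c(30, 30), hazard = 0.05,
                              hazard_ratio = 1, censor_max = 60) {
  stopifnot(hazard_ratio > 0)
  set.seed(seed)
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 2)
  n1 <- n_per_group[1]
  n2 <- n_per_group[2]
  t_event <- c(stats::rexp(n1, hazard), stats::rexp(n2, hazard * hazard_ratio))
  t_cens <- stats::runif(n1 + n2, 0, censor_max)
  records <- tibble::tibble(
    time = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    group = rep(c("group1", "group2"), c(n1, n2))
  )
  list(records = records,
       truth = list(hazard = hazard, hazard_ratio = hazard_ratio,
                    n_per_group = n_per_group))
}

#' Region-level copy-number concordance against simulation truth
#'
#' Fraction of (unmasked) regions whose called integer copy number equals
#' the simulated truth.
#'
#' @param fit A `cna_fit` object.
#' @param region_truth The `truth$region_cn` tibble of
#'   [simulate_tumor_exome()] (`chrom`, `start`, `cn`).
#' @return A single fraction in \[0, 1\].
#' @export
cn_concordance <- function(fit, region_truth) {
  tr <- fit$track[!fit$track$masked, ]
  called <- rep(NA_integer_, nrow(tr))
  for (i in seq_len(nrow(fit$segments))) {
    s <- fit$segments[i, ]
    sel <- tr$chrom == s$chrom & tr$start >= s$start & tr$start < s$end
    called[sel] <- s$integer_cn
  }
  truth_cn <- region_truth$cn[match(paste(tr$chrom, tr$start),
                                    paste(region_truth$chrom,
                                          region_truth$start))]
  mean(called == truth_cn, na.rm = TRUE)
}
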