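# Infinium-style methylation processing: beta-values, probe filtering,
# consensus k-means clustering, promoter-level differential methylation,
# promoter stratification and distal hypomethylated-probe selection.

#' Beta-value from methylated/unmethylated intensities
#'
#' `beta = M / (U + M + 100)`; the +100 offset stabilizes low-intensity
#' probes and bounds the value in \[0, 1).
#'
#' @param methylated,unmethylated Non-negative intensity vectors.
#' @return Beta-values in \[0, 1).
#' @export
beta_from_intensities <- function(methylated, unmethylated) {
  if (any(methylated < 0) || any(unmethylated < 0)) {
    stop("intensities must be non-negative")
  }
  methylated / (unmethylated + methylated + 100)
}

#' Filter probes for clustering and differential analysis
#'
#' Removes probes on the X and Y chromosomes and SNP-associated probes,
#' then intersects the remaining probe ids across the supplied platform
#' probe sets (e.g. EPIC and 450K manifests). Output rows are in genomic
#' order.
#'
#' @param beta Probes-by-samples beta matrix (rownames are probe ids) or a
#'   tibble with a `probe_id` column.
#' @param annotation Data frame with `probe_id`, `chrom`, `pos`,
#'   `snp_associated`.
#' @param platform_sets Optional list of character vectors of probe ids;
#'   only probes present in every set are kept.
#' @return The filtered beta matrix (same representation as the input).
#' @export
filter_probes <- function(beta, annotation, platform_sets = NULL) {
  ann <- tibble::as_tibble(annotation)
  keep <- ann[!(ann$chrom %in% c("chrX", "chrY", "X", "Y")) &
                !ann$snp_associated, ]
  if (!is.null(platform_sets)) {
    common <- Reduce(intersect, platform_sets)
    keep <- keep[keep$probe_id %in% common, ]
  }
  keep <- keep[order(chrom_order(keep$chrom), keep$pos), ]
  if (nrow(keep) == 0) stop("no probes survive filtering")
  if (is.data.frame(beta)) {
    out <- beta[match(keep$probe_id, beta$probe_id), , drop = FALSE]
    out <- out[!is.na(out$probe_id), , drop = FALSE]
    if (nrow(out) == 0) stop("no probes survive filtering")
    return(tibble::as_tibble(out))
  }
  ids <- intersect(keep$probe_id, rownames(beta))
  if (length(ids) == 0) stop("no probes survive filtering")
  beta[ids, , drop = FALSE]
}

beta_as_matrix <- function(beta) {
  if (is.data.frame(beta)) {
    m <- as.matrix(beta[, setdiff(names(beta), "probe_id"), drop = FALSE])
    rownames(m) <- beta$probe_id
    m
  } else {
    as.matrix(beta)
  }
}

#' Select the most variable probes
#'
#' Ranks probes by across-sample standard deviation (denominator n - 1;
#' missing entries dropped pairwise) and keeps the top `k`; ties broken by
#' probe id. Probes missing in more than `max_missing` of samples are
#' excluded before ranking.
#'
#' @param beta Probes-by-samples matrix or tibble with `probe_id`.
#' @param k Number of probes to keep.
#' @param max_missing Maximum tolerated missing fraction per probe.
#' @return The submatrix of the `k` most variable probes (input order of
#'   representation preserved).
#' @export
select_top_variable <- function(beta, k, max_missing = 0.2) {
  if (k <= 0) stop("k must be positive")
  m <- beta_as_matrix(beta)
  if (k > nrow(m)) stop("k exceeds probe count")
  ok <- rowMeans(is.na(m)) <= max_missing
  m_ok <- m[ok, , drop = FALSE]
  sds <- apply(m_ok, 1, stats::sd, na.rm = TRUE)
  ord <- order(-sds, rownames(m_ok))
  ids <- rownames(m_ok)[ord[seq_len(min(k, nrow(m_ok)))]]
  if (is.data.frame(beta)) {
    return(beta[match(ids, beta$probe_id), , drop = FALSE])
  }
  beta[ids, , drop = FALSE]
}

#' Consensus k-means clustering of samples
#'
#' Repeatedly subsamples the samples, runs k-means (samples as points in
#' probe space), and accumulates a consensus matrix: the fraction of
#' co-sampled runs in which two samples share a cluster. Final labels come
#' from average-linkage hierarchical clustering of `1 - consensus` cut at
#' `k`.
#'
#' @param beta Probes-by-samples matrix or tibble with `probe_id`.
#' @param k Number of clusters.
#' @param n_start,max_iter k-means restarts and iteration cap.
#' @param resample_reps Number of subsampling repetitions.
#' @param resample_frac Fraction of samples drawn per repetition.
#' @param seed Random seed (mandatory for reproducibility).
#' @return An object of class `consensus_clust`: list with `consensus`
#'   (samples-by-samples matrix), `labels` (named integer vector), `k`.
#' @export
consensus_kmeans <- function(beta, k = 6, n_start = 10, max_iter = 1000,
                             resample_reps = 100, resample_frac = 0.8,
                             seed = 17) {
  m <- beta_as_matrix(beta)
  x <- t(m)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of samples")
  set.seed(seed)
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  n_sub <- max(k, floor(resample_frac * n))
  for (rep in seq_len(resample_reps)) {
    idx <- sort(sample.int(n, n_sub))
    cl <- stats::kmeans(x[idx, , drop = FALSE], centers = min(k, n_sub),
                        nstart = n_start, iter.max = max_iter)$cluster
    same <- outer(cl, cl, "==") * 1
    tog[idx, idx] <- tog[idx, idx] + 1
    co[idx, idx] <- co[idx, idx] + same
  }
  consensus <- ifelse(tog > 0, co / tog, 0)
  diag(consensus) <- 1
  consensus <- (consensus + t(consensus)) / 2
  rownames(consensus) <- colnames(consensus) <- rownames(x)
  labels <- stats::cutree(stats::hclust(stats::as.dist(1 - consensus),
                                        method = "average"), k = k)
  structure(list(consensus = consensus, labels = labels, k = k),
            class = "consensus_clust")
}

#' @export
print.consensus_clust <- function(x, ...) {
  cat("<consensus_clust> k =", x$k, "over", ncol(x$consensus), "samples;",
      "cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Gene-level promoter methylation
#'
#' Averages, per gene and sample, the beta-values of all probes whose TSS
#' distance is within `window` bp (inclusive). A probe linked to several
#' genes contributes to each of their promoter means.
#'
#' @param beta Probes-by-samples matrix or tibble with `probe_id`.
#' @param tss_links Data frame with `probe_id`, `gene`, `tss_distance`
#'   (signed bp).
#' @param window Promoter half-width in bp.
#' @return A tibble: `gene` plus one column per sample.
#' @export
promoter_beta <- function(beta, tss_links, window = 1500) {
  m <- beta_as_matrix(beta)
  links <- tibble::as_tibble(tss_links)
  links <- links[abs(links$tss_distance) <= window, ]
  links <- links[links$probe_id %in% rownames(m), ]
  if (nrow(links) == 0) stop("no probe within the promoter window of any gene")
  mm <- m[links$probe_id, , drop = FALSE]
  sums <- rowsum(ifelse(is.na(mm), 0, mm), group = links$gene)
  counts <- rowsum((!is.na(mm)) * 1, group = links$gene)
  avg <- sums / counts
  avg[counts == 0] <- NA_real_
  dplyr::bind_cols(
    tibble::tibble(gene = rownames(avg)),
    tibble::as_tibble(avg)
  )
}

#' Differential promoter methylation between two sample groups
#'
#' Welch's t test per gene on promoter beta-values, Benjamini-Hochberg
#' adjustment across all tested genes; a gene is significant when
#' `q < q_max` and `|difference| > diff_min` (difference = group1 mean
#' minus group2 mean).
#'
#' @param promoter_betas Output of [promoter_beta()].
#' @param group1,group2 Character vectors of sample (column) names.
#' @param q_max,diff_min Significance thresholds.
#' @return A tibble sorted by q then |difference|: `gene`,
#'   `mean_beta_group1`, `mean_beta_group2`, `difference`, `p_value`,
#'   `q_value`, `significant`.
#' @export
differential_promoters <- function(promoter_betas, group1, group2,
                                   q_max = 0.01, diff_min = 0.2) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  g1 <- as.matrix(promoter_betas[, group1, drop = FALSE])
  g2 <- as.matrix(promoter_betas[, group2, drop = FALSE])
  res <- purrr::map_dfr(seq_len(nrow(promoter_betas)), function(i) {
    a <- g1[i, ]
    b <- g2[i, ]
    tt <- welch_t(a, b)
    tibble::tibble(
      gene = promoter_betas$gene[i],
      mean_beta_group1 = mean(a, na.rm = TRUE),
      mean_beta_group2 = mean(b, na.rm = TRUE),
      p_value = tt$p_value
    )
  })
  res$difference <- res$mean_beta_group1 - res$mean_beta_group2
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < q_max & abs(res$difference) > diff_min
  res[order(res$q_value, -abs(res$difference)), ]
}

#' Stratify samples by an anchor gene's promoter methylation
#'
#' Hypomethylated below 0.5, intermediate in \[0.5, 0.7), hypermethylated
#' at or above 0.7.
#'
#' @param promoter_betas Output of [promoter_beta()].
#' @param anchor_gene Gene whose promoter beta stratifies the samples.
#' @param hypo_cut,hyper_cut Stratum boundaries.
#' @return A tibble: `sample`, `beta`, `stratum`.
#' @export
stratify_by_promoter <- function(promoter_betas, anchor_gene,
                                 hypo_cut = 0.5, hyper_cut = 0.7) {
  row <- promoter_betas[promoter_betas$gene == anchor_gene, ]
  if (nrow(row) == 0) stop("anchor gene not found: ", anchor_gene)
  betas <- unlist(row[1, setdiff(names(row), "gene")])
  tibble::tibble(
    sample = names(betas),
    beta = as.numeric(betas),
    stratum = dplyr::case_when(
      betas < hypo_cut ~ "hypo",
      betas < hyper_cut ~ "intermediate",
      TRUE ~ "hyper"
    )
  )
}

#' Select significantly hypomethylated distal probes and export windows
#'
#' Restricts to probes whose minimum |TSS distance| exceeds the promoter
#' window (distal elements), tests hypo vs hyper strata per probe with
#' Welch's t, adjusts with Benjamini-Hochberg, and keeps probes with
#' `q < q_max` and mean difference (hypo - hyper) below `diff_max`.
#' Returns the selected probes and 1000 bp BED windows around them
#' (clamped at the chromosome start).
#'
#' @param beta Probes-by-samples matrix or tibble with `probe_id`.
#' @param annotation Probe annotation (`probe_id`, `chrom`, `pos`).
#' @param tss_links Probe-to-TSS links (`probe_id`, `gene`, `tss_distance`).
#' @param hypo_samples,hyper_samples Sample name vectors (>= 2 each).
#' @param q_max,diff_max Selection thresholds.
#' @param promoter_window Distal means min |TSS distance| strictly above
#'   this.
#' @param window_half Half-width of the exported windows.
#' @return A list with `probes` (tibble incl. p/q/difference) and `bed`
#'   (tibble `chrom`, `start`, `end`, `probe_id`).
#' @export
select_distal_hypo_probes <- function(beta, annotation, tss_links,
                                      hypo_samples, hyper_samples,
                                      q_max = 1e-10, diff_max = -0.25,
                                      promoter_window = 1500,
                                      window_half = 500) {
  stopifnot(length(hypo_samples) >= 2, length(hyper_samples) >= 2)
  m <- beta_as_matrix(beta)
  links <- tibble::as_tibble(tss_links)
  min_dist <- links |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(min_dist = min(abs(.data$tss_distance)), .groups = "drop")
  distal_ids <- min_dist$probe_id[min_dist$min_dist > promoter_window]
  # probes with no TSS link at all are distal by definition
  distal_ids <- c(distal_ids, setdiff(rownames(m), links$probe_id))
  m <- m[rownames(m) %in% distal_ids, , drop = FALSE]
  if (nrow(m) == 0) {
    return(list(probes = tibble::tibble(), bed = tibble::tibble()))
  }
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    a <- m[i, hypo_samples]
    b <- m[i, hyper_samples]
    tibble::tibble(
      probe_id = rownames(m)[i],
      mean_hypo = mean(a, na.rm = TRUE),
      mean_hyper = mean(b, na.rm = TRUE),
      p_value = welch_t(a, b)$p_value
    )
  })
  res$difference <- res$mean_hypo - res$mean_hyper
  res$q_value <- bh_adjust(res$p_value)
  sel <- res[res$q_value < q_max & res$difference < diff_max, ]
  ann <- tibble::as_tibble(annotation)
  sel <- dplyr::left_join(sel, ann[, c("probe_id", "chrom", "pos")],
                          by = "probe_id")
  bed <- tibble::tibble(
    chrom = sel$chrom,
    start = pmax(0, sel$pos - window_half),
    end = sel$pos + window_half,
    probe_id = sel$probe_id
  )
  list(probes = sel, bed = bed)
}
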