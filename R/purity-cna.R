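# Exome depth-ratio copy-number engine: library/GC normalization, moving
# average smoothing, wavelet peak detection on the ratio density, Gaussian
# mixture refinement, Viterbi segmentation, allelic-imbalance analysis and
# joint purity / integer-copy-number fitting.
#
# Model: with tumor purity alpha and diploid normal cells, a region at
# integer copy number n has expected tumor/normal depth ratio
#   r(n) = (2 (1 - alpha) + n alpha) / 2.

expected_ratio <- function(n, alpha) (2 * (1 - alpha) + n * alpha) / 2

chrom_order <- function(chrom) factor(chrom, levels = unique(chrom))

#' Normalized, GC-corrected, smoothed tumor/normal depth ratio
#'
#' Per capture region: the raw ratio is the library-size-normalized
#' tumor/normal depth ratio; GC correction divides each raw ratio by the
#' median raw ratio of its GC-content bin, then the whole track is
#' recentered at its density mode (anchoring the dominant, normally
#' diploid, state at ratio 1); smoothing is a centered moving average
#' within each chromosome. Regions whose normal depth falls below
#' `min_normal_depth` are masked (ratios `NA`).
#'
#' @param regions Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gc_fraction`, `depth_tumor`, `depth_normal`.
#' @param min_normal_depth Minimum normal depth for a region to be used.
#' @param gc_bins Number of equal-width GC bins for the median correction.
#' @param smooth_window Moving-average window (regions), centered and
#'   chromosome-bounded.
#' @return A tibble: the input plus `raw_ratio`, `gc_corrected_ratio`,
#'   `smoothed_ratio`, `masked`; library sizes in attributes
#'   `library_size_tumor` / `library_size_normal`.
#' @export
compute_depth_ratio <- function(regions, min_normal_depth = 10, gc_bins = 40,
                                smooth_window = 5) {
  need <- c("chrom", "start", "end", "gc_fraction", "depth_tumor", "depth_normal")
  stopifnot(all(need %in% names(regions)))
  track <- tibble::as_tibble(regions) |>
    dplyr::arrange(chrom_order(.data$chrom), .data$start)
  lib_t <- sum(track$depth_tumor)
  lib_n <- sum(track$depth_normal)
  track$masked <- track$depth_normal < min_normal_depth
  if (all(track$masked)) stop("all regions masked by the minimum-depth filter")
  track$raw_ratio <- ifelse(track$masked, NA_real_,
                            (track$depth_tumor / lib_t) / (track$depth_normal / lib_n))
  bin <- pmin(gc_bins, pmax(1, ceiling(track$gc_fraction * gc_bins)))
  med <- tapply(track$raw_ratio, bin, stats::median, na.rm = TRUE)
  bin_med <- as.numeric(med[as.character(bin)])
  bin_med[is.na(bin_med) | bin_med <= 0] <- 1
  track$gc_corrected_ratio <- track$raw_ratio / bin_med
  # recenter at the density mode so the dominant (diploid) state sits at 1
  ok <- track$gc_corrected_ratio[!is.na(track$gc_corrected_ratio)]
  if (length(ok) >= 10) {
    anchor <- if (stats::sd(ok) < 1e-8) {
      stats::median(ok)
    } else {
      dens <- stats::density(ok, n = 512)
      dens$x[which.max(dens$y)]
    }
    if (is.finite(anchor) && anchor > 0) {
      track$gc_corrected_ratio <- track$gc_corrected_ratio / anchor
    }
  }
  half <- floor(smooth_window / 2)
  track <- track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(smoothed_ratio = moving_average(.data$gc_corrected_ratio, half)) |>
    dplyr::ungroup()
  track <- track[, unique(c(need, "masked", "raw_ratio", "gc_corrected_ratio",
                            "smoothed_ratio", names(track)))]
  attr(track, "library_size_tumor") <- lib_t
  attr(track, "library_size_normal") <- lib_n
  track
}

moving_average <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

ricker <- function(t, a) {
  (2 / (sqrt(3 * a) * pi^0.25)) * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Wavelet-based detection of copy-number peaks in the ratio density
#'
#' Builds a kernel-density estimate of the smoothed depth ratios on a fixed
#' grid, convolves it with a Mexican-hat (Ricker) wavelet across a range of
#' scales, and links per-scale maxima into ridge lines. Ridges persisting
#' over at least `min_scales` scales with sufficient amplitude are reported
#' as peak candidates (ratio values, ascending). If no ridge qualifies the
#' global density mode is returned, so at least one peak is always found.
#'
#' @param track Output of [compute_depth_ratio()], or any data frame with a
#'   `smoothed_ratio` column.
#' @param grid_n Number of density grid points.
#' @param grid_range Ratio range covered by the grid.
#' @param scales Integer wavelet scales (in grid cells).
#' @param min_scales Minimum ridge length (number of scales).
#' @param min_amplitude Minimum density height at the ridge position,
#'   relative to the density maximum.
#' @return Numeric vector of candidate peak ratios, ascending.
#' @export
detect_peaks_wavelet <- function(track, grid_n = 512, grid_range = c(0, 3),
                                 scales = 2:32, min_scales = 3,
                                 min_amplitude = 0.05) {
  ratios <- track$smoothed_ratio
  ratios <- ratios[!is.na(ratios) & ratios >= grid_range[1] & ratios <= grid_range[2]]
  if (length(ratios) < 50) stop("need at least 50 usable ratios")
  dens <- stats::density(ratios, n = grid_n, from = grid_range[1], to = grid_range[2])
  grid <- dens$x
  y <- dens$y
  scales <- sort(scales, decreasing = TRUE)
  cwt <- lapply(scales, function(a) {
    half <- min(4L * a, (grid_n - 1L) %/% 2L)
    kern <- ricker(seq(-half, half), a)
    as.numeric(stats::filter(y, kern, sides = 2))
  })
  maxima <- lapply(cwt, function(v) {
    m <- local_maxima(ifelse(is.na(v), -Inf, v))
    m[v[m] > 0]
  })
  # ridge linking from coarse to fine scales
  ridges <- lapply(maxima[[1]], function(i) list(pos = i, len = 1L, amp = cwt[[1]][i], gap = 0L))
  for (s in seq_along(scales)[-1]) {
    cand <- maxima[[s]]
    used <- logical(length(cand))
    tol <- max(4L, scales[s])
    for (j in seq_along(ridges)) {
      if (ridges[[j]]$gap > 2L) next
      if (length(cand) == 0) { ridges[[j]]$gap <- ridges[[j]]$gap + 1L; next }
      d <- abs(cand - ridges[[j]]$pos)
      k <- which.min(ifelse(used, Inf, d))
      if (length(k) && !used[k] && d[k] <= tol) {
        used[k] <- TRUE
        ridges[[j]]$pos <- cand[k]
        ridges[[j]]$len <- ridges[[j]]$len + 1L
        ridges[[j]]$amp <- max(ridges[[j]]$amp, cwt[[s]][cand[k]])
        ridges[[j]]$gap <- 0L
      } else {
        ridges[[j]]$gap <- ridges[[j]]$gap + 1L
      }
    }
    for (k in which(!used)) {
      ridges[[length(ridges) + 1L]] <- list(pos = cand[k], len = 1L,
                                            amp = cwt[[s]][cand[k]], gap = 0L)
    }
  }
  y_max <- max(y)
  keep <- vapply(ridges, function(r) {
    r$len >= min_scales && y[r$pos] >= min_amplitude * y_max
  }, logical(1))
  peaks <- sort(unique(grid[vapply(ridges[keep], function(r) r$pos, integer(1))]))
  # deduplicate within grid resolution
  if (length(peaks) > 1) {
    res <- diff(grid[1:2]) * 1.5
    peaks <- peaks[c(TRUE, diff(peaks) > res)]
  }
  if (length(peaks) == 0) peaks <- grid[which.max(y)]
  peaks
}

#' Gaussian-mixture refinement of copy-number peaks
#'
#' Expectation-maximization for a univariate Gaussian mixture seeded at the
#' wavelet peak locations. Component standard deviations are floored at
#' `sigma_floor`; components whose weight drops below `min_weight` are
#' pruned (weights renormalized). The log-likelihood trace is attached as
#' attribute `loglik`.
#'
#' @param ratios Numeric vector of (smoothed) depth ratios.
#' @param initial_peaks Numeric vector of starting means.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence delta.
#' @param min_weight Pruning threshold for component weights.
#' @param sigma_floor Lower bound for component standard deviations.
#' @return A tibble of peaks: `peak_id`, `mean_ratio`, `sigma`, `weight`,
#'   sorted by mean; weights sum to 1.
#' @export
fit_gaussian_peaks <- function(ratios, initial_peaks, max_iter = 500,
                               tol = 1e-6, min_weight = 0.02,
                               sigma_floor = 0.01) {
  ratios <- ratios[!is.na(ratios)]
  if (length(initial_peaks) < 1) stop("at least one initial peak required")
  k <- length(initial_peaks)
  mu <- sort(initial_peaks)
  sigma <- rep(max(sigma_floor, stats::sd(ratios) / max(1, k)), k)
  w <- rep(1 / k, k)
  n <- length(ratios)
  loglik <- numeric(0)
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      w[j] * stats::dnorm(ratios, mu[j], sigma[j])
    }, numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    loglik <- c(loglik, sum(log(tot)))
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * ratios) / nk
    sigma <- sqrt(colSums(resp * (ratios - rep(mu, each = n))^2) / nk)
    sigma <- pmax(sigma, sigma_floor)
    if (iter > 1 && abs(loglik[iter] - loglik[iter - 1]) < tol) break
  }
  keep <- w >= min_weight
  if (!any(keep)) keep <- w == max(w)
  mu <- mu[keep]; sigma <- sigma[keep]; w <- w[keep] / sum(w[keep])
  ord <- order(mu)
  out <- tibble::tibble(
    peak_id = seq_along(mu),
    mean_ratio = mu[ord],
    sigma = sigma[ord],
    weight = w[ord]
  )
  attr(out, "loglik") <- loglik
  out
}

#' Viterbi path for the Gaussian-emission copy-number HMM
#'
#' States are copy-number peaks with Gaussian emissions; the transition
#' matrix has stay probability `1 - tau` and switch probability
#' `tau / (K - 1)`; initial state probabilities are the mixture weights.
#'
#' @param obs Numeric observations (one chromosome's ratios).
#' @param means,sigmas,weights Per-state emission parameters and initial
#'   probabilities.
#' @param tau Total switch probability per step.
#' @return Integer vector of most-probable state indices.
#' @export
viterbi_path <- function(obs, means, sigmas, weights, tau = 1e-4) {
  k <- length(means)
  n <- length(obs)
  if (k == 1) return(rep(1L, n))
  log_emit <- vapply(seq_len(k), function(j) {
    stats::dnorm(obs, means[j], sigmas[j], log = TRUE)
  }, numeric(n))
  log_emit <- matrix(log_emit, nrow = n)
  log_stay <- log(1 - tau)
  log_switch <- log(tau / (k - 1))
  delta <- log(weights) + log_emit[1, ]
  psi <- matrix(0L, n, k)
  for (t in seq_len(n)[-1]) {
    for (j in seq_len(k)) {
      cand <- delta + ifelse(seq_len(k) == j, log_stay, log_switch)
      psi[t, j] <- which.max(cand)
      log_emit[t, j] <- log_emit[t, j] + cand[psi[t, j]]
    }
    delta <- log_emit[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in rev(seq_len(n - 1))) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' HMM segmentation of the depth-ratio track
#'
#' Runs the Viterbi algorithm per chromosome over unmasked regions and
#' merges consecutive same-state regions into segments.
#'
#' @param track Output of [compute_depth_ratio()].
#' @param peaks Output of [fit_gaussian_peaks()].
#' @param tau Per-step switch probability of the HMM.
#' @return A tibble of segments: `chrom`, `start`, `end`, `peak_id`,
#'   `mean_ratio` (recomputed from member regions), `n_regions`.
#' @export
segment_hmm <- function(track, peaks, tau = 1e-4) {
  stopifnot(nrow(peaks) >= 1)
  usable <- track[!track$masked & !is.na(track$smoothed_ratio), ]
  segs <- split(usable, chrom_order(usable$chrom)) |>
    purrr::map(function(df) {
      path <- viterbi_path(df$smoothed_ratio, peaks$mean_ratio, peaks$sigma,
                           peaks$weight, tau = tau)
      runs <- rle(path)
      idx_end <- cumsum(runs$lengths)
      idx_start <- idx_end - runs$lengths + 1L
      tibble::tibble(
        chrom = df$chrom[1],
        start = df$start[idx_start],
        end = df$end[idx_end],
        peak_id = runs$values,
        mean_ratio = vapply(seq_along(runs$values), function(i) {
          mean(df$smoothed_ratio[idx_start[i]:idx_end[i]])
        }, numeric(1)),
        n_regions = runs$lengths
      )
    }) |>
    dplyr::bind_rows()
  segs
}

#' Annotate segments with mirrored B-allele fraction and allelic state
#'
#' For each segment the mirrored BAF is the mean of `max(f, 1 - f)` over
#' the tumor alt fractions `f` of member heterozygous SNPs. Segments with
#' fewer than `min_snps` informative SNPs keep an absent mirrored BAF.
#' The state is `imbalanced` above `0.5 + imbalance_margin` and `LOH` at or
#' above `loh_threshold`; copy-neutral LOH is finalized once integer copy
#' numbers are known (see [fit_integer_cn()]).
#'
#' @param segments Segment tibble ([segment_hmm()]).
#' @param het_snps Data frame with `chrom`, `pos`, `ref_count_tumor`,
#'   `alt_count_tumor` (counts in the tumor at normal-heterozygous sites).
#' @param min_snps Minimum SNPs per segment for a BAF call.
#' @param imbalance_margin Margin above 0.5 for the `imbalanced` state.
#' @param loh_threshold Mirrored BAF at or above which `LOH` is called.
#' @return The segments with `mirrored_baf`, `n_het_snps`, `allelic_state`.
#' @export
allelic_imbalance <- function(segments, het_snps, min_snps = 10,
                              imbalance_margin = 0.08, loh_threshold = 0.70) {
  segments <- tibble::as_tibble(segments)
  if (is.null(het_snps) || nrow(het_snps) == 0) {
    segments$mirrored_baf <- NA_real_
    segments$n_het_snps <- 0L
    segments$allelic_state <- NA_character_
    return(segments)
  }
  snp <- tibble::as_tibble(het_snps)
  dp <- snp$ref_count_tumor + snp$alt_count_tumor
  snp$f <- ifelse(dp > 0, snp$alt_count_tumor / dp, NA_real_)
  snp$mirrored <- pmax(snp$f, 1 - snp$f)
  stats_per_seg <- purrr::map(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    sel <- snp$chrom == seg$chrom & snp$pos >= seg$start & snp$pos < seg$end &
      !is.na(snp$mirrored)
    c(n = sum(sel),
      baf = if (sum(sel) > 0) mean(snp$mirrored[sel]) else NA_real_,
      depth = if (sum(sel) > 0) mean(dp[sel]) else NA_real_)
  })
  segments$n_het_snps <- vapply(stats_per_seg, function(x) as.integer(x["n"]), integer(1))
  baf <- vapply(stats_per_seg, function(x) x[["baf"]], numeric(1))
  baf[segments$n_het_snps < min_snps] <- NA_real_
  segments$mirrored_baf <- baf
  segments$mean_snp_depth <- vapply(stats_per_seg, function(x) x[["depth"]],
                                    numeric(1))
  segments$allelic_state <- dplyr::case_when(
    is.na(baf) ~ NA_character_,
    baf >= loh_threshold ~ "LOH",
    baf > 0.5 + imbalance_margin ~ "imbalanced",
    TRUE ~ "balanced"
  )
  segments
}

# expected mirrored BAF when the underlying B-allele fraction is p and the
# observed fraction carries binomial noise at the given depth: folding
# max(f, 1 - f) inflates values near 0.5 (folded-normal expectation)
expected_mirrored_baf <- function(p, depth) {
  p <- pmax(p, 1 - p)
  if (!is.finite(depth) || depth <= 0) return(p)
  sigma <- sqrt(p * (1 - p) / depth)
  if (sigma == 0) return(p)
  mu <- p - 0.5
  0.5 + sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sigma))
}

purity_estimate <- function(alpha, method, support) {
  tibble::tibble(alpha = alpha, method = method, support = as.integer(support))
}

weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Tumor purity from allelic imbalance in LOH segments
#'
#' In a hemizygous-deletion LOH segment (depth ratio below 1) the pooled
#' mirrored BAF is `m = 1 / (2 - alpha)`, so `alpha = 2 - 1/m`; in a
#' copy-neutral LOH segment (ratio near 1), `m = (1 + alpha)/2`, so
#' `alpha = 2 m - 1`. Per-segment estimates are combined by a
#' SNP-count-weighted median and clipped to (0.01, 1].
#'
#' @param segments Segments annotated by [allelic_imbalance()].
#' @param min_snps Minimum informative SNPs per LOH segment.
#' @param neutral_band Half-width of the ratio band treated as copy-neutral.
#' @return A one-row purity tibble (`alpha`, `method`, `support`), or
#'   `NULL` when no qualifying LOH segment exists.
#' @export
estimate_purity_from_loh <- function(segments, min_snps = 10,
                                     neutral_band = 0.05) {
  loh <- segments[!is.na(segments$allelic_state) &
                    segments$allelic_state %in% c("LOH", "cnLOH") &
                    segments$n_het_snps >= min_snps, ]
  if (nrow(loh) == 0) return(NULL)
  est <- purrr::pmap_dfr(loh[, c("mean_ratio", "mirrored_baf", "n_het_snps")],
    function(mean_ratio, mirrored_baf, n_het_snps) {
      m <- mirrored_baf
      if (mean_ratio < 1 - neutral_band) {
        a <- 2 - 1 / m
      } else if (mean_ratio <= 1 + neutral_band) {
        a <- 2 * m - 1
      } else {
        return(NULL)
      }
      tibble::tibble(alpha = a, w = n_het_snps)
    })
  est <- est[!is.na(est$alpha) & est$alpha > 0, ]
  if (nrow(est) == 0) return(NULL)
  alpha <- min(1, max(0.01, weighted_median(est$alpha, est$w)))
  purity_estimate(alpha, "loh_allelic_imbalance", sum(est$w))
}

#' Tumor purity from the somatic VAF distribution
#'
#' Takes twice the mode of a kernel-density estimate of the somatic variant
#' allele frequencies (clonal heterozygous variants in a pure tumor sit at
#' VAF 0.5), clipped to (0.01, 1].
#'
#' @param somatic_vafs Numeric vector of raw somatic VAFs.
#' @param min_variants Minimum number of VAFs required.
#' @return A one-row purity tibble, or `NULL` when too few variants.
#' @export
estimate_purity_from_vaf <- function(somatic_vafs, min_variants = 20) {
  somatic_vafs <- somatic_vafs[!is.na(somatic_vafs) & somatic_vafs > 0]
  if (length(somatic_vafs) < min_variants) return(NULL)
  dens <- stats::density(somatic_vafs, from = 0, to = 1, n = 512)
  mode <- dens$x[which.max(dens$y)]
  purity_estimate(min(1, max(0.01, 2 * mode)), "vaf_distribution",
                  length(somatic_vafs))
}

#' Purity estimation fallback chain
#'
#' Tries allelic-imbalance (LOH) estimation, then the VAF-distribution
#' estimate, and finally falls back to the constant 0.2.
#'
#' @param segments Segments annotated by [allelic_imbalance()] (or `NULL`).
#' @param somatic_vafs Numeric vector of somatic VAFs (or `NULL`).
#' @param ... Passed to the two estimators.
#' @return A one-row purity tibble; `method` records the provenance.
#' @export
purity_fallback_chain <- function(segments = NULL, somatic_vafs = NULL, ...) {
  if (!is.null(segments)) {
    est <- estimate_purity_from_loh(segments, ...)
    if (!is.null(est)) return(est)
  }
  if (!is.null(somatic_vafs)) {
    est <- estimate_purity_from_vaf(somatic_vafs)
    if (!is.null(est)) return(est)
  }
  purity_estimate(0.2, "default_constant", 0L)
}

#' Joint fit of integer copy numbers and tumor purity
#'
#' Grid search over purity: for each candidate `alpha`, every peak is
#' assigned the integer copy number `n` minimizing the squared distance of
#' its mean ratio to the lattice `r(n) = (2(1-alpha) + n alpha)/2`; the
#' score is the weight-averaged squared lattice distance plus penalties
#' for (i) inconsistency between observed segment mirrored BAFs and the
#' BAF expected under the assigned copy number, (ii) non-parsimonious
#' copy-number assignments (weighted squared deviation from the diploid
#' state; keeps a half-purity lattice, which fits any peak set, from
#' winning on noise) and (iii) baseline scales away from 1. Remaining
#' exact ties resolve by parsimony, scale nearest 1, proximity to
#' `alpha_hint`, then the smaller alpha. When a non-default hint is given
#' the purity grid is restricted to `hint +/- 0.2`.
#'
#' @param peaks Peak tibble ([fit_gaussian_peaks()]).
#' @param segments Segment tibble annotated by [allelic_imbalance()]; may
#'   be `NULL` to fit from peak positions alone.
#' @param alpha_hint Optional one-row purity tibble (fallback chain output)
#'   or a bare numeric.
#' @param alpha_grid Candidate purities.
#' @param scale_grid Candidate baseline scales (residual mis-centering of
#'   the diploid anchor absorbed jointly with the purity).
#' @param max_cn Largest copy number considered.
#' @param min_snps Minimum informative SNPs for a segment to enter the
#'   BAF-consistency penalty.
#' @param baf_weight Relative weight of the BAF-consistency penalty.
#' @param parsimony_weight Weight of the copy-number parsimony penalty.
#' @param scale_weight Weight of the baseline-scale penalty.
#' @return A list with `purity` (one-row tibble), `peaks` (with
#'   `assigned_cn`), `segments` (with `integer_cn` and final
#'   `allelic_state`, `cnLOH` where LOH coincides with copy number 2) and
#'   `scale` (the fitted baseline scale).
#' @export
fit_integer_cn <- function(peaks, segments = NULL, alpha_hint = NULL,
                           alpha_grid = seq(0.05, 1, by = 0.01),
                           scale_grid = seq(0.95, 1.05, by = 0.005),
                           max_cn = 8, baf_weight = 1,
                           parsimony_weight = 3e-4, scale_weight = 0.05,
                           min_snps = 10) {
  stopifnot(nrow(peaks) >= 1)
  hint_alpha <- NA_real_
  hint_method <- NA_character_
  hint_support <- 0L
  if (is.data.frame(alpha_hint)) {
    hint_method <- alpha_hint$method[1]
    hint_support <- alpha_hint$support[1]
    if (hint_method != "default_constant") hint_alpha <- alpha_hint$alpha[1]
  } else if (is.numeric(alpha_hint) && length(alpha_hint) == 1) {
    hint_alpha <- alpha_hint
  }
  if (!is.na(hint_alpha)) {
    alpha_grid <- alpha_grid[alpha_grid >= hint_alpha - 0.2 &
                               alpha_grid <= hint_alpha + 0.2]
  }
  baf_segs <- NULL
  if (!is.null(segments) && "mirrored_baf" %in% names(segments)) {
    baf_segs <- segments[!is.na(segments$mirrored_baf) &
                           segments$n_het_snps >= min_snps, ]
  }
  cn_values <- 0:max_cn
  nearest_cn <- function(r, a, s) {
    lattice <- s * expected_ratio(cn_values, a)
    vapply(r, function(x) cn_values[which.min((x - lattice)^2)], numeric(1))
  }
  eval_candidate <- function(a, s) {
    assign_n <- nearest_cn(peaks$mean_ratio, a, s)
    fit <- sum(peaks$weight * (peaks$mean_ratio -
                                 s * expected_ratio(assign_n, a))^2)
    pen <- 0
    if (!is.null(baf_segs) && nrow(baf_segs) > 0) {
      wtot <- sum(baf_segs$n_het_snps)
      n_seg <- nearest_cn(baf_segs$mean_ratio, a, s)
      depths <- if ("mean_snp_depth" %in% names(baf_segs)) {
        baf_segs$mean_snp_depth
      } else {
        rep(Inf, nrow(baf_segs))
      }
      for (i in seq_len(nrow(baf_segs))) {
        n <- n_seg[i]
        majors <- seq(ceiling(n / 2), max(n, ceiling(n / 2)))
        denom <- n * a + 2 * (1 - a)
        p_major <- if (denom > 0) (majors * a + (1 - a)) / denom else 0.5
        m_exp <- vapply(p_major, expected_mirrored_baf, numeric(1),
                        depth = depths[i])
        pen <- pen + baf_segs$n_het_snps[i] / wtot *
          min((baf_segs$mirrored_baf[i] - m_exp)^2)
      }
    }
    parsimony <- sum(peaks$weight * (assign_n - 2)^2)
    list(score = fit + baf_weight * pen + parsimony_weight * parsimony +
           scale_weight * (s - 1)^2,
         assign = assign_n, parsimony = parsimony)
  }
  grid <- expand.grid(alpha = alpha_grid, scale = scale_grid)
  fits <- lapply(seq_len(nrow(grid)),
                 function(i) eval_candidate(grid$alpha[i], grid$scale[i]))
  scores <- vapply(fits, `[[`, numeric(1), "score")
  best <- which(scores <= min(scores) + 1e-10)
  if (length(best) > 1) {
    pars <- vapply(fits[best], `[[`, numeric(1), "parsimony")
    best <- best[pars <= min(pars) + 1e-10]
  }
  if (length(best) > 1) {
    d <- abs(grid$scale[best] - 1)
    best <- best[d <= min(d) + 1e-12]
  }
  if (length(best) > 1 && !is.na(hint_alpha)) {
    d <- abs(grid$alpha[best] - hint_alpha)
    best <- best[d <= min(d) + 1e-12]
  }
  best <- best[which.min(grid$alpha[best])]
  alpha <- grid$alpha[best]
  scale <- grid$scale[best]
  assign_n <- fits[[best]]$assign
  peaks$assigned_cn <- as.integer(assign_n)
  method <- if (!is.na(hint_method)) hint_method else "loh_allelic_imbalance"
  out_purity <- purity_estimate(alpha, method, hint_support)
  if (!is.null(segments)) {
    segments$integer_cn <- peaks$assigned_cn[match(segments$peak_id, peaks$peak_id)]
    if ("allelic_state" %in% names(segments)) {
      segments$allelic_state <- ifelse(
        !is.na(segments$allelic_state) & segments$allelic_state == "LOH" &
          segments$integer_cn == 2,
        "cnLOH", segments$allelic_state)
    }
  }
  list(purity = out_purity, peaks = peaks, segments = segments,
       scale = scale)
}

#' Cohort gain/loss frequencies over genomic bins
#'
#' Per bin, the fraction of samples with integer copy number above 2
#' (gain) and the fraction with copy number below 2 or copy-neutral LOH
#' (loss); a sample contributes at most one category per bin, loss taking
#' precedence for cnLOH.
#'
#' @param segment_sets Data frame of segments from all samples, with a
#'   `sample` column plus `chrom`, `start`, `end`, `integer_cn`,
#'   `allelic_state`.
#' @param bins Data frame of genomic bins (`chrom`, `start`, `end`).
#' @return The bins with `gain_freq` and `loss_freq` columns.
#' @export
cna_frequency <- function(segment_sets, bins) {
  samples <- unique(segment_sets$sample)
  n <- length(samples)
  if (n == 0) stop("at least one sample required")
  bins <- tibble::as_tibble(bins)
  bins$gain_freq <- 0
  bins$loss_freq <- 0
  for (i in seq_len(nrow(bins))) {
    ov <- segment_sets[segment_sets$chrom == bins$chrom[i] &
                         segment_sets$start < bins$end[i] &
                         segment_sets$end > bins$start[i], ]
    gain <- loss <- character(0)
    if (nrow(ov) > 0) {
      is_loss <- ov$integer_cn < 2 |
        (!is.na(ov$allelic_state) & ov$allelic_state == "cnLOH")
      loss <- unique(ov$sample[is_loss])
      gain <- setdiff(unique(ov$sample[ov$integer_cn > 2]), loss)
    }
    bins$gain_freq[i] <- length(gain) / n
    bins$loss_freq[i] <- length(loss) / n
  }
  bins
}

#' End-to-end copy-number and purity calling
#'
#' Chains depth-ratio computation, wavelet peak detection, Gaussian-mixture
#' refinement, HMM segmentation, allelic-imbalance annotation, the purity
#' fallback chain and the joint integer-CN/purity fit.
#'
#' @param regions Region depth table (see [compute_depth_ratio()]).
#' @param het_snps Heterozygous-SNP table (see [allelic_imbalance()]), or
#'   `NULL`.
#' @param somatic_vafs Optional somatic VAFs for the purity fallback.
#' @param alpha_override Optional fixed purity (skips estimation).
#' @param refine Re-segment against the fitted integer-CN lattice in a
#'   second pass (recommended; prevents spurious mixture components from
#'   fragmenting constant-CN blocks).
#' @param max_cn Largest copy number modeled.
#' @param ... Passed through to [fit_integer_cn()].
#' @return An object of class `cna_fit`: a list with `track`, `peaks`,
#'   `segments`, `purity`.
#' @export
call_copy_number <- function(regions, het_snps = NULL, somatic_vafs = NULL,
                             alpha_override = NULL, refine = TRUE,
                             max_cn = 8, ...) {
  track <- compute_depth_ratio(regions)
  peak_pos <- detect_peaks_wavelet(track)
  peaks <- fit_gaussian_peaks(track$smoothed_ratio, peak_pos)
  segments <- segment_hmm(track, peaks)
  segments <- allelic_imbalance(segments, het_snps)
  hint <- if (!is.null(alpha_override)) {
    purity_estimate(alpha_override, "loh_allelic_imbalance", 0L)
  } else {
    purity_fallback_chain(segments, somatic_vafs)
  }
  fit <- fit_integer_cn(peaks, segments, alpha_hint = hint, max_cn = max_cn,
                        ...)
  out_peaks <- fit$peaks
  out_segments <- fit$segments
  purity <- fit$purity
  if (refine) {
    # alternate re-segmentation against the fitted integer-CN lattice with
    # re-fitting on the (precise) segment block means: spurious mixture
    # components cannot fragment a constant-CN block, and the lattice is
    # re-anchored on segment-level evidence
    cn_states <- 0:max_cn
    resegment <- function(alpha, scale, sigma) {
      w <- vapply(cn_states, function(n) {
        sum(out_peaks$weight[out_peaks$assigned_cn == n])
      }, numeric(1))
      w <- (w + 0.01) / sum(w + 0.01)
      lattice_peaks <- tibble::tibble(
        peak_id = cn_states + 1L,
        mean_ratio = scale * expected_ratio(cn_states, alpha),
        sigma = sigma,
        weight = w
      )
      segs <- segment_hmm(track, lattice_peaks)
      segs$integer_cn <- segs$peak_id - 1L
      allelic_imbalance(segs, het_snps)
    }
    sigma0 <- max(0.01, stats::median(out_peaks$sigma))
    # second fit on first-pass segment block means (weights = region
    # counts); first-pass segments are not conditioned on any lattice
    segs1 <- out_segments
    seg_peaks <- tibble::tibble(
      peak_id = seq_len(nrow(segs1)),
      mean_ratio = segs1$mean_ratio,
      sigma = sigma0,
      weight = segs1$n_regions / sum(segs1$n_regions)
    )
    hint2 <- purity
    if (hint2$method == "default_constant") {
      hint2 <- purity_estimate(purity$alpha, "cn_model_fit", 0L)
    }
    fit2 <- fit_integer_cn(seg_peaks, segs1, alpha_hint = hint2,
                           max_cn = max_cn, ...)
    purity <- purity_estimate(fit2$purity$alpha, purity$method,
                              purity$support)
    out_segments <- resegment(purity$alpha, fit2$scale, sigma0)
    out_segments$allelic_state <- ifelse(
      !is.na(out_segments$allelic_state) &
        out_segments$allelic_state == "LOH" & out_segments$integer_cn == 2,
      "cnLOH", out_segments$allelic_state)
  }
  structure(
    list(track = track, peaks = out_peaks, segments = out_segments,
         purity = fit$purity),
    class = "cna_fit"
  )
}

#' @export
print.cna_fit <- function(x, ...) {
  cat("<cna_fit> ", nrow(x$segments), " segments, ",
      nrow(x$peaks), " peaks, purity alpha = ",
      signif(x$purity$alpha, 3), " (", x$purity$method, ")\n", sep = "")
  invisible(x)
}
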