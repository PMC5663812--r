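# ggplot2 graphics for each result type.

#' Plot the depth-ratio track with its segmentation
#'
#' Smoothed tumor/normal depth ratios per region, colored by chromosome,
#' with fitted segment means overlaid.
#'
#' @param fit A `cna_fit` object.
#' @return A ggplot.
#' @export
plot_depth_ratio <- function(fit) {
  track <- fit$track[!fit$track$masked, ]
  track$index <- seq_len(nrow(track))
  seg <- fit$segments
  seg$index_start <- match(paste(seg$chrom, seg$start),
                           paste(track$chrom, track$start))
  offsets <- vapply(seq_len(nrow(seg)), function(i) {
    sum(track$chrom == seg$chrom[i] & track$start >= seg$start[i] &
          track$start < seg$end[i])
  }, numeric(1))
  seg$index_end <- seg$index_start + offsets - 1
  ggplot2::ggplot(track, ggplot2::aes(x = .data$index,
                                      y = .data$smoothed_ratio)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$chrom), size = 0.4,
                        alpha = 0.6) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$index_start, xend = .data$index_end,
                   y = .data$mean_ratio, yend = .data$mean_ratio),
      inherit.aes = FALSE, linewidth = 1
    ) +
    ggplot2::labs(x = "capture region", y = "tumor/normal depth ratio",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential promoter methylation
#'
#' @param diffmeth Output of [differential_promoters()].
#' @return A ggplot (difference vs -log10 q, significant genes
#'   highlighted).
#' @export
plot_volcano <- function(diffmeth) {
  df <- diffmeth
  df$neg_log_q <- -log10(pmax(df$q_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference,
                                   y = .data$neg_log_q,
                                   color = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "promoter beta difference", y = "-log10(q)",
                  color = "significant") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier survival curves per group
#'
#' @param records Survival records (`time`, `event`, `group`).
#' @return A ggplot of step survival curves.
#' @export
plot_survival <- function(records) {
  curves <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(df, key) {
      km <- km_estimate(df)
      tibble::tibble(group = key$group[[1]],
                     time = c(0, km$time),
                     survival = c(1, km$survival))
    }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_depth_ratio autoplot method for `cna_fit`.
#' @param object A `cna_fit` object.
#' @param ... Unused.
#' @export
autoplot.cna_fit <- function(object, ...) plot_depth_ratio(object)

#' Running-sum plot of a GSEA result
#'
#' @param object A `gsea_result` object.
#' @param ... Unused.
#' @return A ggplot of the running enrichment score.
#' @export
autoplot.gsea_result <- function(object, ...) {
  ggplot2::ggplot(object$running_sum,
                  ggplot2::aes(x = .data$rank, y = .data$running_es)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "gene rank", y = "running enrichment score") +
    ggplot2::theme_minimal()
}

#' Consensus-matrix heatmap
#'
#' @param object A `consensus_clust` object.
#' @param ... Unused.
#' @return A ggplot heatmap of the consensus matrix, samples ordered by
#'   cluster.
#' @export
autoplot.consensus_clust <- function(object, ...) {
  ord <- names(sort(object$labels))
  df <- tibble::as_tibble(object$consensus, rownames = "sample_i") |>
    tidyr::pivot_longer(-"sample_i", names_to = "sample_j",
                        values_to = "consensus")
  df$sample_i <- factor(df$sample_i, levels = ord)
  df$sample_j <- factor(df$sample_j, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_i, y = .data$sample_j,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
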