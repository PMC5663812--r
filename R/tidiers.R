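# Broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a copy-number fit into its segment table
#'
#' @param x A `cna_fit` object.
#' @param ... Unused.
#' @return The segment tibble (one row per segment).
#' @export
tidy.cna_fit <- function(x, ...) tibble::as_tibble(x$segments)

#' One-row summary of a copy-number fit
#'
#' @param x A `cna_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: purity, method, peak and segment counts.
#' @export
glance.cna_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$purity$alpha,
    purity_method = x$purity$method,
    n_peaks = nrow(x$peaks),
    n_segments = nrow(x$segments),
    n_regions = sum(x$segments$n_regions)
  )
}

#' Tidy a consensus clustering into sample labels
#'
#' @param x A `consensus_clust` object.
#' @param ... Unused.
#' @return A tibble `sample`, `cluster`.
#' @export
tidy.consensus_clust <- function(x, ...) {
  tibble::tibble(sample = names(x$labels), cluster = as.integer(x$labels))
}

#' One-row summary of a consensus clustering
#'
#' @param x A `consensus_clust` object.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n_samples`, `mean_consensus`.
#' @export
glance.consensus_clust <- function(x, ...) {
  off_diag <- x$consensus[lower.tri(x$consensus)]
  tibble::tibble(
    k = x$k,
    n_samples = ncol(x$consensus),
    mean_consensus = mean(off_diag)
  )
}

#' Tidy a GSEA result into its running-sum table
#'
#' @param x A `gsea_result` object.
#' @param ... Unused.
#' @return The running-sum tibble (`rank`, `gene`, `running_es`).
#' @export
tidy.gsea_result <- function(x, ...) x$running_sum

#' One-row summary of a GSEA result
#'
#' @param x A `gsea_result` object.
#' @param ... Unused.
#' @return A one-row tibble: `es`, `nes`, `q_value`, `n_hits`,
#'   `n_leading_edge`.
#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(
    es = x$es,
    nes = x$nes,
    q_value = x$q_value,
    n_hits = x$n_hits,
    n_leading_edge = length(x$leading_edge)
  )
}
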