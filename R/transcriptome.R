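# Expression quantification (FPKM, longest-isoform rule), gene-set
# enrichment with permutation NES/FDR, group comparisons and
# fusion-junction filtering.

#' Select the longest isoform per gene
#'
#' The representative isoform is the one with the largest summed exon
#' length; ties break lexicographically by isoform id.
#'
#' @param gene_models Data frame with `gene`, `isoform`, `exon_start`,
#'   `exon_end` (one row per exon).
#' @return A tibble `gene`, `isoform`, `exonic_length` with one row per
#'   gene (the selected isoform).
#' @export
select_longest_isoform <- function(gene_models) {
  tibble::as_tibble(gene_models) |>
    dplyr::group_by(.data$gene, .data$isoform) |>
    dplyr::summarise(exonic_length = sum(.data$exon_end - .data$exon_start),
                     .groups = "drop") |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(dplyr::desc(.data$exonic_length), .data$isoform,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' FPKM expression values
#'
#' `FPKM = counts * 1e9 / (exonic_length * total_mapped_fragments)`, using
#' the selected (longest) isoform's exonic length per gene.
#'
#' @param counts Data frame with `gene`, `sample`, `count`.
#' @param gene_lengths Data frame with `gene`, `exonic_length` (e.g. from
#'   [select_longest_isoform()]).
#' @param totals Optional data frame `sample`, `total_mapped_fragments`;
#'   defaults to per-sample count sums.
#' @return A tibble `gene`, `sample`, `fpkm`.
#' @export
fpkm <- function(counts, gene_lengths, totals = NULL) {
  cnt <- tibble::as_tibble(counts)
  if (is.null(totals)) {
    totals <- cnt |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(total_mapped_fragments = sum(.data$count),
                       .groups = "drop")
  }
  if (any(totals$total_mapped_fragments <= 0)) stop("totals must be positive")
  if (any(gene_lengths$exonic_length <= 0)) stop("zero-length gene model")
  cnt |>
    dplyr::inner_join(gene_lengths[, c("gene", "exonic_length")], by = "gene") |>
    dplyr::inner_join(totals, by = "sample") |>
    dplyr::mutate(fpkm = .data$count * 1e9 /
                    (.data$exonic_length * .data$total_mapped_fragments)) |>
    dplyr::select("gene", "sample", "fpkm")
}

#' Signal-to-noise gene ranking between two groups
#'
#' `score = (mean_a - mean_b) / (sd_a + sd_b)` with each standard
#' deviation floored at `sd_floor_frac` times the absolute group mean (and
#' a small absolute floor), the convention of the canonical enrichment
#' tool. Genes are returned in descending score order.
#'
#' @param expression Data frame `gene`, `sample`, `fpkm` (or a value
#'   column named by `value_col`).
#' @param group_a,group_b Sample name vectors (>= 2 each).
#' @param sd_floor_frac Relative variance floor.
#' @param value_col Name of the value column.
#' @return A tibble `gene`, `score`, descending.
#' @export
rank_by_signal_to_noise <- function(expression, group_a, group_b,
                                    sd_floor_frac = 0.2,
                                    value_col = "fpkm") {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  expr <- tibble::as_tibble(expression)
  expr$value <- expr[[value_col]]
  stat <- function(v) {
    m <- mean(v)
    s <- stats::sd(v)
    s <- max(s, sd_floor_frac * abs(m), sd_floor_frac * 1e-3)
    c(m, s)
  }
  expr |>
    dplyr::filter(.data$sample %in% c(group_a, group_b)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      score = {
        a <- stat(.data$value[.data$sample %in% group_a])
        b <- stat(.data$value[.data$sample %in% group_b])
        (a[1] - b[1]) / (a[2] + b[2])
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$score))
}

gsea_running_sum <- function(ranked_genes, scores, gene_set, exponent = 1) {
  hit <- ranked_genes %in% gene_set
  n <- length(ranked_genes)
  nh <- sum(hit)
  w <- abs(scores)^exponent
  p_hit <- ifelse(hit, w, 0)
  denom <- sum(p_hit)
  if (denom == 0) p_hit[hit] <- 1 / nh else p_hit <- p_hit / denom
  p_miss <- ifelse(hit, 0, 1 / (n - nh))
  cumsum(p_hit - p_miss)
}

#' Gene-set enrichment analysis (weighted Kolmogorov-Smirnov)
#'
#' Running-sum enrichment score with weight exponent 1 on the absolute
#' ranking scores; the null is gene-set permutation (random sets of
#' matching size). NES divides the observed ES by the mean |permuted ES|
#' of the same sign; the q-value is the same-sign tail fraction of the
#' permuted NES distribution.
#'
#' @param ranking Data frame `gene`, `score`, ordered or not (it is sorted
#'   descending internally); duplicate genes are an error.
#' @param gene_set Character vector of member genes.
#' @param n_permutations Number of gene-set permutations.
#' @param seed Random seed.
#' @param exponent Weight exponent on |score| (1 = weighted, 0 = classic).
#' @return An object of class `gsea_result`: list with `es`, `nes`,
#'   `q_value`, `leading_edge`, `running_sum` (tibble), `n_hits`.
#' @export
gsea <- function(ranking, gene_set, n_permutations = 1000, seed = 17,
                 exponent = 1) {
  rk <- tibble::as_tibble(ranking)
  if (anyDuplicated(rk$gene)) stop("duplicate genes in the ranking")
  rk <- rk[order(-rk$score), ]
  genes <- rk$gene
  scores <- rk$score
  hits <- intersect(gene_set, genes)
  if (length(hits) == 0) stop("gene set does not intersect the ranking")
  rs <- gsea_running_sum(genes, scores, hits, exponent)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  set.seed(seed)
  n <- length(genes)
  nh <- length(hits)
  es_perm <- vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(n, nh)
    r <- gsea_running_sum(genes, scores, genes[idx], exponent)
    r[which.max(abs(r))]
  }, numeric(1))
  same_sign <- es_perm[sign(es_perm) == sign(es)]
  nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
  q <- if (length(same_sign) > 0) {
    mean(abs(same_sign) >= abs(es))
  } else {
    NA_real_
  }
  hit_pos <- which(genes %in% hits)
  leading <- if (es >= 0) genes[hit_pos[hit_pos <= i_ext]] else
    genes[hit_pos[hit_pos >= i_ext]]
  structure(
    list(es = es, nes = nes, q_value = q, leading_edge = leading,
         running_sum = tibble::tibble(rank = seq_len(n), gene = genes,
                                      running_es = rs),
         n_hits = nh, n_permutations = n_permutations),
    class = "gsea_result"
  )
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("<gsea_result> ES =", signif(x$es, 3), " NES =", signif(x$nes, 3),
      " q =", signif(x$q_value, 3), " (", x$n_hits, "genes in set)\n")
  invisible(x)
}

#' Compare one gene's expression between two groups
#'
#' Wilcoxon rank-sum test on the expression values of `gene`.
#'
#' @param expression Data frame `gene`, `sample`, `fpkm`.
#' @param gene Gene to test.
#' @param group_a,group_b Sample name vectors.
#' @param value_col Name of the value column.
#' @return One-row test tibble (see [wilcoxon_rank_sum()]).
#' @export
compare_gene_expression <- function(expression, gene, group_a, group_b,
                                    value_col = "fpkm") {
  expr <- expression[expression$gene == gene, ]
  if (nrow(expr) == 0) stop("gene not found: ", gene)
  a <- expr[[value_col]][expr$sample %in% group_a]
  b <- expr[[value_col]][expr$sample %in% group_b]
  wilcoxon_rank_sum(a, b)
}

#' Group junction reads into fusion candidates and apply the call filters
#'
#' Reads are grouped by breakpoint pair within `breakpoint_tolerance`. A
#' read qualifies when at least `min_flank` bases align on both sides of
#' the junction; a candidate survives when it has at least `min_reads`
#' qualifying reads (strictly more than four under the defaults) and its
#' breakpoints are on different chromosomes or at least `min_distance`
#' apart.
#'
#' @param junction_reads Data frame with `read_id`, `chrom_left`,
#'   `pos_left`, `chrom_right`, `pos_right`, `left_match_len`,
#'   `right_match_len`.
#' @param min_flank Minimum aligned bases on each side of the junction.
#' @param min_reads Minimum qualifying spanning reads.
#' @param min_distance Minimum same-chromosome breakpoint distance (bp).
#' @param breakpoint_tolerance Grouping tolerance (bp).
#' @return A tibble of candidates: breakpoints, `n_reads`,
#'   `n_qualifying`, `same_chromosome`, `distance`, `pass`,
#'   `reject_reason`.
#' @export
fusion_filter <- function(junction_reads, min_flank = 12, min_reads = 5,
                          min_distance = 1e5, breakpoint_tolerance = 5) {
  jr <- tibble::as_tibble(junction_reads) |>
    dplyr::arrange(.data$chrom_left, .data$chrom_right, .data$pos_left,
                   .data$pos_right)
  if (nrow(jr) == 0) {
    return(tibble::tibble())
  }
  # chain reads into breakpoint groups
  grp <- integer(nrow(jr))
  grp[1] <- 1L
  for (i in seq_len(nrow(jr))[-1]) {
    prev <- i - 1L
    same <- jr$chrom_left[i] == jr$chrom_left[prev] &&
      jr$chrom_right[i] == jr$chrom_right[prev] &&
      abs(jr$pos_left[i] - jr$pos_left[prev]) <= breakpoint_tolerance &&
      abs(jr$pos_right[i] - jr$pos_right[prev]) <= breakpoint_tolerance
    grp[i] <- if (same) grp[prev] else grp[prev] + 1L
  }
  jr$group <- grp
  jr |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      chrom_left = .data$chrom_left[1],
      pos_left = stats::median(.data$pos_left),
      chrom_right = .data$chrom_right[1],
      pos_right = stats::median(.data$pos_right),
      n_reads = dplyr::n(),
      n_qualifying = sum(.data$left_match_len >= min_flank &
                           .data$right_match_len >= min_flank),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      same_chromosome = .data$chrom_left == .data$chrom_right,
      distance = ifelse(.data$same_chromosome,
                        abs(.data$pos_right - .data$pos_left), NA_real_),
      reject_reason = dplyr::case_when(
        .data$n_qualifying < min_reads ~ "too_few_spanning_reads",
        .data$same_chromosome & .data$distance < min_distance ~ "read_through",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$reject_reason)
    ) |>
    dplyr::select(-"group")
}

#' Correlation of promoter methylation with expression for one gene
#'
#' Pearson correlation over samples present in both tables.
#'
#' @param promoter_betas Output of [promoter_beta()].
#' @param expression Data frame `gene`, `sample`, `fpkm`.
#' @param gene Gene of interest.
#' @param value_col Name of the expression value column.
#' @return A one-row tibble `gene`, `n`, `r`, `r_squared`.
#' @export
correlate_promoter_expression <- function(promoter_betas, expression, gene,
                                          value_col = "fpkm") {
  brow <- promoter_betas[promoter_betas$gene == gene, ]
  erow <- expression[expression$gene == gene, ]
  if (nrow(brow) == 0 || nrow(erow) == 0) stop("gene not found: ", gene)
  betas <- unlist(brow[1, setdiff(names(brow), "gene")])
  common <- intersect(names(betas), erow$sample)
  if (length(common) < 3) stop("need at least 3 paired samples")
  x <- as.numeric(betas[common])
  y <- erow[[value_col]][match(common, erow$sample)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- stats::cor(x, y)
  tibble::tibble(gene = gene, n = length(common), r = r, r_squared = r^2)
}
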