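# Somatic candidate filtering: tumor-vs-normal Fisher test, heuristic
# artifact filters, purity-adjusted VAF thresholding, consequence
# classification, RNA concordance validation and cohort summaries.

#' Tumor-vs-normal Fisher filter for a somatic candidate table
#'
#' Two-sided Fisher's exact test on (tumor alt, tumor ref, normal alt,
#' normal ref). A candidate fails when the p-value is at or above
#' `p_threshold`, when the normal alt fraction exceeds `max_normal_vaf`
#' (flag `germline_evidence`), or when either sample has zero depth (flag
#' `no_depth`).
#'
#' @param candidates Data frame with columns `tumor_alt`, `tumor_ref`,
#'   `normal_alt`, `normal_ref`.
#' @param p_threshold Fisher p-value cutoff (pass requires p below it).
#' @param max_normal_vaf Maximum tolerated normal alt fraction.
#' @return The input with `fisher_p`, `fisher_pass` and a `fisher_flag`
#'   column (`NA` when clean).
#' @export
somatic_fisher_filter <- function(candidates, p_threshold = 0.01,
                                  max_normal_vaf = 0.03) {
  cand <- tibble::as_tibble(candidates)
  n <- nrow(cand)
  p <- rep(NA_real_, n)
  flag <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    dt <- cand$tumor_alt[i] + cand$tumor_ref[i]
    dn <- cand$normal_alt[i] + cand$normal_ref[i]
    if (dt == 0 || dn == 0) {
      flag[i] <- "no_depth"
      next
    }
    p[i] <- fisher_exact_2x2(cand$tumor_alt[i], cand$tumor_ref[i],
                             cand$normal_alt[i], cand$normal_ref[i])$p_value
    if (cand$normal_alt[i] / dn > max_normal_vaf) {
      flag[i] <- "germline_evidence"
    } else if (p[i] >= p_threshold) {
      flag[i] <- "fisher_fail"
    }
  }
  cand$fisher_p <- p
  cand$fisher_flag <- flag
  cand$fisher_pass <- is.na(flag)
  cand
}

binom_two_sided <- function(k, n, prob = 0.5) {
  if (n == 0) return(1)
  d <- stats::dbinom(0:n, n, prob)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

#' Heuristic artifact filters
#'
#' Adds named flags per rule: `low_depth` (tumor depth below `min_depth`),
#' `few_alt_reads` (alt reads below `min_alt_reads`), `strand_bias`
#' (two-sided binomial test of forward vs reverse alt reads with
#' `p < strand_p` and minor-strand fraction below `min_minor_frac`) and
#' `homopolymer_indel` for indels flagged adjacent to a homopolymer run
#' (requires a logical `homopolymer` column; skipped otherwise). A
#' candidate passes when its flag set is empty.
#'
#' @param candidates Data frame with `tumor_alt`, `tumor_ref`,
#'   `strand_fwd_alt`, `strand_rev_alt` and optionally `homopolymer`.
#' @param min_depth,min_alt_reads,strand_p,min_minor_frac Rule parameters.
#' @return The input with a `filter_flags` list-column and `heuristic_pass`.
#' @export
heuristic_filters <- function(candidates, min_depth = 8, min_alt_reads = 3,
                              strand_p = 0.01, min_minor_frac = 0.05) {
  cand <- tibble::as_tibble(candidates)
  flags <- purrr::map(seq_len(nrow(cand)), function(i) {
    f <- character(0)
    depth <- cand$tumor_alt[i] + cand$tumor_ref[i]
    if (depth < min_depth) f <- c(f, "low_depth")
    if (cand$tumor_alt[i] < min_alt_reads) f <- c(f, "few_alt_reads")
    fwd <- cand$strand_fwd_alt[i]
    rev <- cand$strand_rev_alt[i]
    tot <- fwd + rev
    if (tot > 0) {
      pb <- binom_two_sided(fwd, tot)
      minor <- min(fwd, rev) / tot
      if (pb < strand_p && minor < min_minor_frac) f <- c(f, "strand_bias")
    }
    if ("homopolymer" %in% names(cand) && isTRUE(cand$homopolymer[i]) &&
        nchar(cand$ref_allele[i]) != nchar(cand$alt_allele[i])) {
      f <- c(f, "homopolymer_indel")
    }
    f
  })
  cand$filter_flags <- flags
  cand$heuristic_pass <- lengths(flags) == 0
  cand
}

#' Purity-adjusted VAF with the retention rule
#'
#' The adjusted VAF rescales the raw allele frequency to the tumor-cell
#' compartment, `min(1, vaf_raw / alpha)`; candidates are retained when
#' the adjusted VAF is at least 0.15.
#'
#' @param candidates Data frame with a `vaf_raw` column, or a bare numeric
#'   vector of raw VAFs.
#' @param purity One-row purity tibble (see [purity_fallback_chain()]) or
#'   a single numeric alpha in (0, 1].
#' @param min_adjusted_vaf Retention threshold on the adjusted VAF.
#' @return The input with `vaf_adjusted` and `retained` columns (a tibble
#'   when a bare vector was given).
#' @export
adjust_vaf <- function(candidates, purity, min_adjusted_vaf = 0.15) {
  alpha <- if (is.data.frame(purity)) purity$alpha[1] else purity
  if (!is.numeric(alpha) || is.na(alpha) || alpha <= 0) {
    stop("purity alpha must be positive")
  }
  if (!is.data.frame(candidates)) {
    candidates <- tibble::tibble(vaf_raw = as.numeric(candidates))
  }
  cand <- tibble::as_tibble(candidates)
  cand$vaf_adjusted <- pmin(1, cand$vaf_raw / alpha)
  cand$retained <- cand$vaf_adjusted >= min_adjusted_vaf
  cand
}

CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", vapply(strsplit(s, NULL), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}

#' Classify the coding consequence of a variant against a transcript model
#'
#' SNVs inside the CDS are translated through the standard genetic code
#' before and after substitution (strand-aware); SNVs in an intron within
#' 2 bp of an exon boundary are splice-site; indels in the CDS are
#' frameshift when the length change is not divisible by 3, otherwise
#' in-frame; everything else is noncoding.
#'
#' @param chrom,pos 0-based variant position.
#' @param ref_allele,alt_allele Explicit alleles (plus-strand, as in a VCF).
#' @param transcript A list/one-row data frame with `gene`, `chrom`,
#'   `strand` ("+"/"-"), `exons` (data frame `start`,`end`), `cds`
#'   (data frame `start`,`end`).
#' @param genome A named character vector of chromosome sequences
#'   (plus strand).
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`,
#'   `"splice_site"`, `"frameshift"`, `"inframe_indel"`, `"noncoding"`.
#' @export
classify_consequence <- function(chrom, pos, ref_allele, alt_allele,
                                 transcript, genome) {
  if (chrom != transcript$chrom) stop("chromosome mismatch")
  exons <- as.data.frame(transcript$exons)
  cds <- as.data.frame(transcript$cds)
  exons <- exons[order(exons$start), ]
  cds <- cds[order(cds$start), ]
  in_exon <- any(pos >= exons$start & pos < exons$end)
  is_indel <- nchar(ref_allele) != nchar(alt_allele)
  if (!in_exon) {
    # 2 intronic bases flanking each internal exon boundary
    donors <- exons$end[-nrow(exons)]      # first intron base = exon end
    acceptors <- exons$start[-1]           # last intron base = start - 1
    splice_pos <- c(donors, donors + 1, acceptors - 1, acceptors - 2)
    if (pos %in% splice_pos) return("splice_site")
    return("noncoding")
  }
  in_cds <- any(pos >= cds$start & pos < cds$end)
  if (!in_cds) return("noncoding")
  if (is_indel) {
    shift <- abs(nchar(ref_allele) - nchar(alt_allele))
    return(if (shift %% 3 != 0) "frameshift" else "inframe_indel")
  }
  seqchr <- genome[[chrom]]
  # genomic coordinates of CDS bases, 5' to 3' on the coding strand
  cds_pos <- unlist(lapply(seq_len(nrow(cds)), function(i) {
    seq(cds$start[i], cds$end[i] - 1)
  }))
  if (transcript$strand == "-") cds_pos <- rev(cds_pos)
  idx <- match(pos, cds_pos)
  if (is.na(idx)) return("noncoding")
  codon_i <- (idx - 1) %/% 3
  codon_pos <- cds_pos[(codon_i * 3 + 1):(codon_i * 3 + 3)]
  base_at <- function(p) substr(seqchr, p + 1, p + 1)
  codon_ref <- vapply(codon_pos, base_at, character(1))
  codon_alt <- codon_ref
  codon_alt[match(pos, codon_pos)] <- alt_allele
  if (transcript$strand == "-") {
    codon_ref <- chartr("ACGT", "TGCA", codon_ref)
    codon_alt <- chartr("ACGT", "TGCA", codon_alt)
  }
  aa_ref <- CODON_TABLE[[paste(toupper(codon_ref), collapse = "")]]
  aa_alt <- CODON_TABLE[[paste(toupper(codon_alt), collapse = "")]]
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_alt == "*") return("nonsense")
  "missense"
}

#' RNA-read concordance validation of somatic calls
#'
#' A position is assessable when its RNA depth exceeds `depth_threshold`
#' (strictly more than 10 reads by default); an assessable position is
#' concordant when at least `min_support` RNA reads carry the alt allele.
#'
#' @param candidates Data frame with `chrom`, `pos`.
#' @param rna_counts Data frame with `chrom`, `pos`, `rna_depth`,
#'   `rna_alt_reads`.
#' @param depth_threshold RNA depth must exceed this value.
#' @param min_support Minimum alt-supporting RNA reads for concordance.
#' @return A one-row tibble: `n_assessable`, `n_concordant`,
#'   `concordance_fraction` (`NA` when nothing is assessable).
#' @export
rna_validate <- function(candidates, rna_counts, depth_threshold = 10,
                         min_support = 1) {
  merged <- dplyr::inner_join(
    tibble::as_tibble(candidates)[, c("chrom", "pos")],
    tibble::as_tibble(rna_counts),
    by = c("chrom", "pos")
  )
  assessable <- merged[merged$rna_depth > depth_threshold, ]
  n_a <- nrow(assessable)
  n_c <- sum(assessable$rna_alt_reads >= min_support)
  tibble::tibble(
    n_assessable = n_a,
    n_concordant = n_c,
    concordance_fraction = if (n_a > 0) n_c / n_a else NA_real_
  )
}

#' Flag hypermutator samples
#'
#' A sample is flagged when its nonsynonymous mutation count exceeds
#' `factor` times the cohort median.
#'
#' @param counts Data frame with `sample` and `n_nonsynonymous`, or a
#'   named numeric vector.
#' @param factor Multiple of the cohort median marking a hypermutator.
#' @return A tibble with `sample`, `n_nonsynonymous`, `hypermutator`.
#' @export
flag_hypermutator <- function(counts, factor = 5) {
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(sample = names(counts),
                             n_nonsynonymous = as.numeric(counts))
  }
  cand <- tibble::as_tibble(counts)
  if (nrow(cand) < 3) stop("at least 3 samples required")
  med <- stats::median(cand$n_nonsynonymous)
  cand$hypermutator <- cand$n_nonsynonymous > factor * med
  cand
}

#' Mutual exclusivity of two gene mutations across a cohort
#'
#' Counts co-occurrences and tests the 2x2 mutation-status table with the
#' exact Fisher test.
#'
#' @param status Data frame with logical/0-1 columns `gene_a` and `gene_b`,
#'   one row per sample.
#' @return A one-row tibble: `n_both`, `n_a_only`, `n_b_only`, `n_neither`,
#'   `p_value`.
#' @export
mutual_exclusivity <- function(status) {
  a <- as.logical(status$gene_a)
  b <- as.logical(status$gene_b)
  if (length(a) == 0) stop("at least one sample required")
  n_both <- sum(a & b)
  n_a <- sum(a & !b)
  n_b <- sum(!a & b)
  n_no <- sum(!a & !b)
  p <- fisher_exact_2x2(n_both, n_a, n_b, n_no)$p_value
  tibble::tibble(n_both = n_both, n_a_only = n_a, n_b_only = n_b,
                 n_neither = n_no, p_value = p)
}

#' Full somatic filtering pipeline for a candidate table
#'
#' Applies the Fisher filter, the heuristic filters and the
#' purity-adjusted VAF rule; the verdict is the conjunction of the three
#' and is independent of application order (flags only accumulate).
#'
#' @param candidates Candidate table (see [somatic_fisher_filter()] and
#'   [heuristic_filters()]; `vaf_raw` is computed when absent).
#' @param purity One-row purity tibble or numeric alpha.
#' @param ... Passed to the individual filters.
#' @return The annotated table with a final logical `somatic_call`.
#' @export
filter_somatic_candidates <- function(candidates, purity, ...) {
  cand <- tibble::as_tibble(candidates)
  if (!"vaf_raw" %in% names(cand)) {
    depth <- cand$tumor_alt + cand$tumor_ref
    cand$vaf_raw <- ifelse(depth > 0, cand$tumor_alt / depth, 0)
  }
  cand <- somatic_fisher_filter(cand)
  cand <- heuristic_filters(cand)
  cand <- adjust_vaf(cand, purity)
  cand$somatic_call <- cand$fisher_pass & cand$heuristic_pass & cand$retained
  cand
}
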