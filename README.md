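# gliomics

Integrated tumor/normal multi-omics analysis for diffuse gliomas, built as
a reusable, simulation-tested R pipeline. The package is aimed at
computational cancer-genomics researchers who need the complete analysis
chain of a tumor/normal profiling study — exome copy-number calling with
tumor-purity estimation, somatic variant filtering, Infinium-style
methylation analysis, expression/enrichment comparison and fusion
filtering — with every stage runnable and verifiable on synthetic data
with known ground truth, no external cohorts required.

## The models at the core

**Purity and copy number.** A specimen is modeled as a mixture of a
fraction α of tumor cells and 1−α of diploid normal cells. A region at
integer tumor copy number *n* has expected tumor/normal depth ratio

    r(n) = (2(1−α) + nα) / 2

and a heterozygous SNP with *b* of *n* tumor copies carrying the B allele
has expected B-allele fraction (bα + (1−α)) / (nα + 2(1−α)). The engine
normalizes and GC-corrects read depth, finds copy-number peaks in the
ratio density with a Mexican-hat continuous wavelet transform, refines
them with a Gaussian-mixture EM, links them to the genome with a
Viterbi-decoded HMM, and jointly fits α and integer copy numbers by grid
search against the lattice r(n), scored with an allelic-imbalance
consistency penalty. Purity falls back from allelic imbalance in LOH
segments (α = 2 − 1/m for deletions, α = 2m − 1 for copy-neutral LOH,
with m the mirrored B-allele fraction) to the doubled mode of the somatic
VAF density, to a constant 0.2.

**Somatic filtering.** Candidates pass a tumor-vs-normal Fisher exact
test, heuristic artifact filters (depth, alt reads, strand bias), and the
purity rule: adjusted VAF = min(1, VAF/α) must be ≥ 0.15.

**Methylation.** Beta = M/(U + M + 100); X/Y and SNP probes excluded;
consensus k-means (10 starts, 1000 iterations, k = 6) over the 8000 most
variable probes; promoter = mean beta within ±1500 bp of the TSS;
differential promoters by Welch's *t* + Benjamini–Hochberg, significant
at q < 0.01 and |Δβ| > 0.2; strata at promoter beta 0.5/0.7; distal
hypomethylated probes at q < 1e−10 and Δβ < −0.25 with 1000 bp windows
exported as BED.

**Expression and fusions.** FPKM on the longest isoform; signal-to-noise
ranking; gene-set enrichment with a weighted running sum and
gene-set-permutation NES/FDR; fusion candidates need ≥ 12 bp aligned on
both sides of the junction, more than four spanning reads, and ≥ 100 kb
separation on the same chromosome.

All statistical primitives (Fisher exact, Welch *t*, Benjamini–Hochberg,
Wilcoxon rank-sum, Kaplan–Meier, log-rank) are implemented natively in
the package and cross-checked against independent oracles in the tests.

## Worked example

Simulate a tumor exome with known truth (purity 0.6; a deletion, two
gains and a copy-neutral LOH chromosome), call copy number and purity,
then filter somatic candidates with the estimated purity:

```r
library(gliomics)

ex  <- simulate_tumor_exome(seed = 42, alpha = 0.6)
fit <- call_copy_number(ex$regions, ex$het_snps)
fit
#> <cna_fit> 8 segments, 4 peaks, purity alpha = 0.62 (loh_allelic_imbalance)

tidy(fit)[, c("chrom", "start", "end", "mean_ratio", "integer_cn", "allelic_state")]
#> # A tibble: 8 × 6
#>   chrom  start    end mean_ratio integer_cn allelic_state
#> 1 chr1       0 399200      0.995          2 balanced
#> 2 chr2       0 198200      0.691          1 LOH
#> 3 chr2  199000 399200      0.978          2 balanced
#> 4 chr3       0 399200      1.31           3 imbalanced
#> 5 chr4       0 198200      1.61           4 balanced
#> 6 chr4  199000 200200      1.33           3 <NA>
#> 7 chr4  201000 399200      0.999          2 balanced
#> 8 chr5       0 399200      0.993          2 cnLOH
```

The estimated purity (0.62 vs true 0.6) comes from the mirrored B-allele
fraction of the chr2 deletion and the chr5 copy-neutral LOH, refined by
the lattice fit; the segment table recovers the planted profile,
including the cnLOH chromosome that is invisible in depth alone. Somatic
candidates are then filtered with that purity:

```r
sv  <- simulate_somatic_candidates(seed = 43, alpha = 0.6, n_true = 50)
flt <- filter_somatic_candidates(sv$candidates, fit$purity)
table(flt$somatic_call)
#> FALSE  TRUE
#>    50    50   # the 50 planted artifacts fail, the 50 true somatics pass
```

The native Fisher test reproduces cohort-level mutation-frequency
comparisons, e.g. 4 mutated of 17 versus 5 of 292:

```r
fisher_exact_2x2(4, 13, 5, 287)
#> # A tibble: 1 × 4
#>   method statistic    df  p_value
#> 1 fisher      17.7    NA 0.000676
```

`run_pipeline()` chains all stages over one seed and writes SEG, TSV and
BED outputs plus the resolved configuration; `autoplot()` methods and
`plot_volcano()` / `plot_survival()` provide the standard graphics.

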