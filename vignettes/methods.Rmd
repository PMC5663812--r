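---
title: "Models and methods behind gliomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gliomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomics)
```

gliomics reimplements, as a reusable and fully simulation-tested pipeline,
the integrated tumor/normal multi-omics analysis used to characterize
diffuse cerebellar gliomas: exome copy-number segmentation with tumor-purity
estimation, purity-adjusted somatic-variant filtering, Infinium-style
methylation clustering and differential promoter analysis, expression
comparison with gene-set enrichment, and fusion-junction filtering. This
vignette explains the underlying models, the tunable parameters and the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The two-population read-mixture model

Everything in the copy-number engine follows from one model. A tumor
specimen is a mixture of a fraction $\alpha$ (the tumor purity) of tumor
cells and $1-\alpha$ of diploid normal cells. A genomic region at integer
tumor copy number $n$ then has expected tumor/normal depth ratio

$$r(n) = \frac{2(1-\alpha) + n\,\alpha}{2},$$

and a heterozygous SNP whose B allele is present in $b$ of the $n$ tumor
copies has expected B-allele fraction
$(b\,\alpha + (1-\alpha)) / (n\,\alpha + 2(1-\alpha))$. Two special cases
drive purity estimation: in a hemizygous deletion the retained allele sits
at $m = 1/(2-\alpha)$, and in copy-neutral LOH (both copies from one
parent) the major allele sits at $m = (1+\alpha)/2$. Solving for $\alpha$
gives the two inversion formulas used by `estimate_purity_from_loh()`.

Because the magnitude of every copy-number signal scales with $\alpha$,
low-purity specimens are intrinsically hard: at $\alpha = 0.12$ a
single-copy change moves the depth ratio by only 0.06. The engine is
required to return a valid estimate (possibly the fallback constant)
rather than fail in that regime.

## Depth-ratio track

`compute_depth_ratio()` normalizes tumor and normal depths by their library
totals, divides each raw ratio by the median of its GC-content bin (40
equal-width bins), recenters the whole track at its kernel-density mode and
smooths with a centered 5-region moving average per chromosome. Regions
with normal depth below 10 are masked. Two of these choices deserve
comment:

* **Mode recentring.** Library-size normalization anchors the *average*
  ratio at 1, so in an aneuploid genome the diploid state lands somewhere
  else (with 30% of the exome gained, diploid regions sit near 0.93). The
  density mode of the corrected ratios is the most common state, which in
  tumor exomes is almost always the diploid one; dividing by it puts copy
  number 2 at ratio 1. The mode of a finite sample still carries a percent
  or two of error, which is why the model fit below retains a residual
  scale freedom.
* **Window of 5 regions.** Exome capture regions are short and numerous; a
  5-region centered average suppresses counting noise by roughly
  $\sqrt 5$ while blurring breakpoints by at most 2 regions, matching the
  breakpoint tolerance used in the tests.

## Peak detection, mixture refinement and segmentation

Copy-number states appear as modes of the ratio density.
`detect_peaks_wavelet()` estimates the density of the smoothed ratios on a
fixed 512-point grid over ratios 0–3, convolves it with a Mexican-hat
(Ricker) wavelet at integer scales 2–32, and links the per-scale maxima
into ridge lines from coarse to fine. A ridge must persist over at least 3
scales and sit where the density is at least 5% of its maximum; the
position of a surviving ridge at its finest scale is the peak candidate.
The density-height criterion (rather than wavelet amplitude) keeps minor
but real states — a focal amplification covering 10% of the exome —
from being drowned out by the coarse-scale response of the diploid peak.
If nothing qualifies the global mode is returned, so there is always at
least one peak.

`fit_gaussian_peaks()` refines the candidates by expectation–maximization
of a univariate Gaussian mixture seeded at the wavelet peaks. Component
standard deviations are floored at 0.01 (preventing the classic
degenerate-likelihood collapse), components below 2% weight are pruned,
and convergence is declared when the log-likelihood improves by less than
$10^{-6}$ (cap 500 iterations). The log-likelihood trace is attached so
the monotonicity property can be asserted in tests.

`segment_hmm()` links states to the genome with a hidden Markov model:
one state per peak, Gaussian emissions, stay probability $1-\tau$ with
$\tau = 10^{-4}$, and the exact most-probable path by the Viterbi
algorithm per chromosome. The small $\tau$ encodes the prior that copy
number changes are rare (tens of breakpoints per genome, not thousands);
the test suite verifies the dynamic program against exhaustive path
enumeration on all instances up to 12 regions and 3 states.

## Joint purity and integer copy-number fitting

`fit_integer_cn()` grid-searches $\alpha \in [0.05, 1]$ in steps of 0.01
(restricted to $\pm 0.2$ around a non-default hint) jointly with a
baseline scale $s \in [0.95, 1.05]$ in steps of 0.005. For each candidate
pair every peak is assigned the copy number minimizing its distance to the
lattice $s \cdot r(n)$, and the score combines four terms:

1. the weight-averaged squared lattice distance of the peaks;
2. a BAF-consistency penalty: each segment with at least 10 informative
   SNPs contributes the squared gap between its observed mirrored BAF and
   the closest BAF expected under its assigned copy number — with the
   expectation corrected for *folding bias* (averaging
   $\max(f, 1-f)$ over binomially noisy fractions inflates values near
   0.5; at depth 100 a balanced locus reads ≈ 0.54, not 0.50, and
   ignoring this actively favors wrong odd-copy assignments);
3. a parsimony penalty ($3 \times 10^{-4}$ times the weighted squared
   deviation of assigned copy numbers from 2) — necessary because a
   half-purity lattice is twice as fine and can fit *any* peak set, so
   without parsimony the fit at $\alpha/2$ ties the fit at $\alpha$
   exactly and wins on noise;
4. a scale penalty ($0.05\,(s-1)^2$) expressing that the mode anchor is
   approximately right.

Remaining exact ties resolve toward parsimony, scale closest to 1,
proximity to the hint, then the smaller purity. The scale dimension and
the two soft penalties are this package's resolution of the genuinely
open part of the design: purity, ploidy-lattice assignment and baseline
are only jointly identifiable, and the stated combination reproduces the
textbook cases (peaks at 1.0/1.5 give $\alpha = 1$ with copy numbers
2 and 3; peaks at 1.0/1.25 give $\alpha = 0.5$, not the equally exact
$\alpha = 0.25$ with a copy-4 assignment) while remaining stable on
noisy simulated exomes.

`call_copy_number()` then alternates once: it re-segments the track
against the fitted integer lattice (so a spurious mixture component can no
longer fragment a constant-copy block), re-fits the purity on the
resulting block means — which average hundreds of regions and are far more
precise than mixture peaks — and re-segments with the final estimate.
Copy-neutral LOH is assigned where a segment is LOH by BAF
(mirrored BAF ≥ 0.70, ≥ 10 SNPs) and lands at copy number 2; in the
cohort gain/loss summary (`cna_frequency()`) such segments count as loss.

The purity fallback chain mirrors the analysis procedure: allelic
imbalance in LOH segments first, the doubled mode of the somatic VAF
density second, and the constant 0.2 when both fail. The 0.70 LOH
threshold means BAF-based estimation is only possible above roughly
$\alpha = 0.57$ for deletions and $\alpha = 0.40$ for copy-neutral LOH;
below that the joint lattice fit carries the estimate, which is exactly
what the recovery tests at $\alpha = 0.3$ exercise.

## Somatic variant filtering

Candidates pass three independent, order-invariant groups of rules: a
two-sided Fisher exact test of tumor versus normal allele counts
($p < 0.01$ and normal VAF ≤ 0.03), heuristic artifact filters (tumor
depth ≥ 8, alt reads ≥ 3, strand bias called when a two-sided binomial
test of forward/reverse alt reads gives $p < 0.01$ with minor-strand
fraction < 0.05, and an optional homopolymer-indel flag), and the purity
rule: the adjusted VAF $\min(1, \mathrm{VAF}/\alpha)$ must reach 0.15.
The adjustment rescales the allele frequency to the tumor-cell
compartment under a copy-number-neutral assumption; the alternative
cancer-cell-fraction scaling $2\,\mathrm{VAF}/\alpha$ is deliberately not
used because the retention threshold is stated on an allele frequency.
Consequence classification translates affected codons through the
standard genetic code, strand-aware, with the two intronic bases at each
exon boundary called splice-site and in-CDS indels split by length
divisibility into frameshift versus in-frame.

## Methylation processing

Beta-values are $M/(U+M+100)$ — bounded in $[0,1)$ by the +100 offset.
Probe filtering removes X/Y and SNP-associated probes and intersects
platform manifests; the most variable probes are ranked by across-sample
standard deviation (ties broken by probe id so the selection is
deterministic). Consensus clustering subsamples 80% of samples 100 times,
runs k-means (10 random starts, up to 1000 iterations, samples as points
in probe space) on each draw, accumulates the co-clustering frequency
over co-sampled pairs, and cuts an average-linkage dendrogram of
1 − consensus at $k$; $k = 6$ is the default. Resampling fraction, the
number of repetitions and the final-label rule are not externally fixed
anywhere, so they are package choices: 100 × 0.8 subsampling is the
common default of consensus class discovery, and the average-linkage cut
is the conventional way to turn a consensus matrix into labels.

Promoter methylation is the mean beta of all probes within ±1500 bp
(inclusive) of a TSS, a probe contributing to every gene it is linked to.
Differential promoters use Welch's *t* per gene with Benjamini–Hochberg
adjustment across genes; a gene is called when $q < 0.01$ **and**
$|\Delta\beta| > 0.2$ (the difference is signed in the output so both
hypo- and hypermethylation are visible in the volcano plot). Sample
stratification by an anchor gene's promoter (the SOX10 use case) cuts at
beta 0.5 and 0.7 with half-open intervals. Distal-probe selection
restricts to probes farther than 1500 bp from every linked TSS, tests
hypo- versus hypermethylated strata, and keeps probes with
$q < 10^{-10}$ and difference < −0.25, exporting 1000 bp windows clamped
at the chromosome start for external motif discovery. The $10^{-10}$
default reads an obviously slipped exponent sign in the original
criterion ("$10^{10}$") as the strict threshold it was described to be; a
q-value cannot exceed 1.

## Expression, enrichment and fusions

FPKM is $c \cdot 10^9 / (L \cdot N)$ with $L$ the exonic length of the
longest isoform (ties broken lexicographically) and $N$ the mapped
fragment total. Group ranking uses the signal-to-noise ratio
$(\mu_a-\mu_b)/(\sigma_a+\sigma_b)$ with each $\sigma$ floored at 20% of
the absolute group mean, the convention of the canonical enrichment tool.
The enrichment score is the extremum of the weighted Kolmogorov–Smirnov
running sum (weight exponent 1 on |score|); the null is gene-set
permutation — 1000 random same-size sets — because with a dozen samples
per group phenotype permutation would have too few distinct relabelings.
NES divides the observed ES by the mean |permuted ES| of the same sign,
and the q-value is the same-sign tail fraction. Published NES/q values
from the original expression cohorts are therefore not exact targets of
this implementation — the ranking metric and permutation scheme of the
original runs are unknown — but the ES itself is checked bit-for-bit
against an independent reference implementation in the tests.

Fusion calling applies three rules to junction reads grouped within 5 bp:
a read qualifies only if at least 12 bases align on *both* sides of the
junction; a candidate survives with strictly more than four qualifying
reads; and same-chromosome candidates need breakpoints at least
100,000 bp apart to exclude read-through transcripts.

## Statistical primitives

All test procedures the pipeline uses are implemented natively in
`stats-core.R`: Fisher's exact test by point-probability summation of the
hypergeometric support (with a $10^{-7}$ relative tie tolerance so
floating-point noise cannot exclude a tied table), Welch's *t* with
Satterthwaite degrees of freedom, Benjamini–Hochberg as the step-up
minimum, the Wilcoxon rank-sum with midranks (exact enumeration up to
combined $n = 12$, then a tie-corrected normal approximation with
continuity correction), the Kaplan–Meier product-limit estimator and the
unweighted Mantel–Haenszel log-rank test. Base-R distribution functions
(`pt`, `pnorm`, `pchisq`, `dnorm`) serve as numerical primitives. The
corresponding base-R and survival-package procedures appear in the test
suite only, as independent oracles.

One calibration subtlety: Fisher's exact test is conservative on small
discrete tables — under an independent-mutation null with 17 samples its
rejection rate at level 0.05 is nearer 0.01 than 0.05, a property of the
test itself, not of this implementation. Null-calibration checks
therefore assert the one-sided validity bound at cohort size 17 and the
two-sided 0.05 ± 0.02 band at cohort sizes (hundreds of samples) where
the exact test approaches its nominal level.

## Synthetic data: what it does and does not emulate

The generators produce every input class with recorded ground truth.
The exome generator draws per-region fragment counts from a negative
binomial (extra-Poisson coefficient of variation 0.05) around a mean set
by coverage 100×, 200 bp regions and 100 bp reads, modulated by a smooth
sinusoidal GC bias shared between tumor and normal; tumor means scale by
$r(n)$ over a default profile containing a diploid chromosome, a
hemizygous deletion, copy-4 and copy-3 gains and a whole-chromosome
copy-neutral LOH (uniparental disomy — deliberately whole-chromosome,
since a cnLOH arm adjacent to diploid sequence is invisible to
depth-based segmentation and would contaminate the pooled BAF of the
merged segment). Het-SNP counts are binomial with the mixture
probabilities above; somatic candidates plant strand-bias, germline-leak
and low-depth artifact classes, each designed to fail exactly one filter;
the beta-matrix generator draws per-cluster probe archetypes from a
bimodal Beta mixture (Beta(2,10)/Beta(10,2)) with truncated Gaussian
sample noise (sd 0.05), planted differential promoter shifts, TSS-linked
and distal probes and X/Y/SNP decoys; junction-read and survival
generators follow the module rules directly.

What passing these tests shows is that each stage implements its stated
model correctly and recovers known truth under that model. What they do
not show: real exomes have correlated capture noise, mappability
artifacts and subclonal structure; real methylation arrays have probe
chemistry effects and batch structure; real fusion callers see alignment
ambiguity. The generators emulate the statistical structure the methods
assume, not those nuisances.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed (default 17) and is
bit-reproducible given one. The shipped test-and-acceptance problem sizes
— 2000 capture regions at depth 100 over 20 seeds and four purities, 2000
promoter genes at cohort sizes 18 versus 123, 60 samples by 800 probes
with six planted classes over 10 seeds, 2000-replicate null calibrations
— were chosen as the smallest sizes at which the recovery criteria are
statistically comfortable, and run in a few minutes on one core.

## Known limitations

* Subclonal copy number and tumor ploidy renormalization are out of
  scope; the lattice is anchored at normal diploidy.
* cnLOH regions sharing a chromosome with diploid sequence cannot be
  separated by depth segmentation alone (BAF-based segmentation would be
  the extension).
* The GSEA q-value follows the single-set gene-permutation convention;
  multi-set FDR pooling is not implemented.
* The heuristic artifact filter set is configurable but minimal; it is a
  stand-in for the richer unpublished filter stacks of production
  callers.
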