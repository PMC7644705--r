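---
title: "Pooled variant calling from simulated NIPT cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled variant calling from simulated NIPT cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptpool)
```

# The problem

Non-invasive prenatal testing sequences cell-free DNA from maternal plasma
at an ultra-low depth (≈ 0.17× per sample from ~3.6 million 2 × 75 bp read
pairs). Per sample this supports no genotyping, but pooled across a cohort
of thousands of pregnancies the aggregate depth reaches hundreds-fold, and
the fraction of reads carrying an alternate allele at a site estimates the
population allele frequency — provided every read at a position comes from
a different individual. `niptpool` is a laboratory for that idea: it
simulates the whole data-generating process with recorded truth, applies
the filtering and pooled-calling procedure, and measures how faithfully
the population genetics is recovered.

# The generative model

## Population allele frequencies

Sites are placed uniformly without collision on non-Y chromosomes. Each
site draws an ancestral alternate-allele frequency $p$ from a truncated
Beta$(0.5, 0.5)$ spectrum (bounds $[0.01, 0.99]$). The U-shape is the
standard neutral-like choice and reproduces the empirical excess of
low-frequency alleles in large call sets; both shape and bounds are
configurable. Each population with divergence parameter $F \in [0,1)$
then draws its frequency from the Balding–Nichols distribution

$$ p_{\text{pop}} \sim \mathrm{Beta}\!\left(p\,\tfrac{1-F}{F},\;
   (1-p)\,\tfrac{1-F}{F}\right), $$

which has mean $p$ and variance $F\,p(1-p)$; $F = 0$ returns $p$ exactly
and $F = 1$ is rejected as degenerate. This is the minimal standard model
that produces PCA-separable populations with a single interpretable knob.
Reference and alternate bases are drawn so the truth
transition/transversion ratio is configurable, default 2.0 — the
genome-wide value expected for true human SNPs, against which the 0.5
ratio of uniform sequencing errors provides a diagnostic contrast.

## Families and plasma

Maternal and paternal genotypes are drawn from the population frequencies
as phased haplotypes (Hardy–Weinberg: autosomal dosage
$\sim \mathrm{Binomial}(2, p)$, male X $\sim \mathrm{Binomial}(1, p)$).
The fetus receives one maternal and one paternal gamete per site; fathers
are then discarded, since only maternal and fetal DNA appear in plasma.
A male fetus carries one maternal X and one Y; mothers carry no Y.

Plasma is a mixture: each chromosome copy is sampled with probability
proportional to its length times its mixture weight — $(1-\mathit{ff})$
per maternal copy and $\mathit{ff}$ per fetal copy, where the fetal
fraction $\mathit{ff}$ is drawn per sample. The study population this
package emulates reports fetal fractions of 8–10%, so the default
`fetal_fraction_dist` is Uniform(0.08, 0.10); the distribution is a
parameter because no more detailed shape is established. Fragment length
follows Normal(166, 40) truncated to $[\text{read\_len}+1, 500]$ — 166 bp
is the modal cfDNA fragment size — and two 75 bp mates are read from the
fragment ends, so mates of short fragments overlap, which is exactly the
phenomenon the overlap filter exists for. At every covered position the
emitted base is the source haplotype's allele, substituted uniformly to
one of the other three bases with probability 0.003 (the error rate
estimated for this kind of data). MAPQ is 60, or a low value inside
designated low-mappability intervals (the downstream pipeline only uses
MAPQ as a threshold, so a binary model suffices). Per-sample depth
defaults to a constant 0.17×; depth variability across samples is
real but unparameterized, and can be injected through `depth_dist`.

Reads are emitted as alignments (SAM) directly: alignment itself is
upstream of the questions this package asks. Base calls are stored
sparsely as deviations from the reference, which is lossless and keeps a
million-read cohort in memory.

# Filtering

Two rules, in this order:

1. **MAPQ filter** — discard alignments with MAPQ < 30.
2. **Overlap deduplication** — within each sample and chromosome, keep a
   maximal set of pairwise non-overlapping reads, so every position gets
   at most one read per sample and the pooled counts are draws from
   distinct individuals. Which overlapping read survives is not specified
   by the procedure this emulates; we use a deterministic greedy sweep
   (sort by start, end, read id; keep a read iff it clears the last kept
   read). It is idempotent, order-independent, and treats overlapping
   mates of one pair the same as any other overlap — the depth-2
   positions that motivate the filter are mostly overlapping mates.

`coverage_summary()` does exact per-position accounting (per-sample and
pooled coverage, mean depth, depth histogram); the package asserts the
max-one-read-per-sample-per-position postcondition machine-checkably on
every simulated dataset.

# The pooled caller

The reference analysis used a somatic caller in pooled mode; its internal
model is not part of the record, so the caller here is a specified,
minimal stand-in documented as such: at a pooled pileup column with depth
$n$, alternate base $b$ with count $k$ is called iff

$$ P(X \ge k) \le \alpha_{\text{site}}, \qquad
   X \sim \mathrm{Binomial}(n, e/3), $$

with $e = 0.003$ and the $/3$ from errors substituting uniformly across
the three non-reference bases (matching the simulator; a full error
matrix would slot in here). $\alpha_{\text{site}}$ defaults to a
Bonferroni bound $0.05/L$ over the $L$ genome positions — conservative by
construction, so the type-I properties are provable and testable. The AF
estimate is $k/n$; its conditional bias at the calling threshold (sites
whose $k$ barely clears the bar are upward-biased) is visible at low
pooled depth and fades as depth grows. Each alternate at a site is tested
independently (multi-allelics emit split VCF records). Two flags mirror
the post-calling filters named in the emulated workflow: `weak_evidence`
($k <$ 3 by default) and `strand_bias` (two-sided Fisher exact
$p < 10^{-3}$ *and* ≥ 90% of alternate reads on one strand). A
contamination flag name is reserved but unimplemented — the simulator has
no contamination model to detect.

# Validation analyses

* **Panel partition** — each called site is assigned to the first
  matching panel in precedence order (exact chrom/pos/ref/alt match —
  the strictest identity, chosen to avoid inflating overlap), else
  novel; percentages are relative to the call set.
* **Common-SNP sensitivity** — fraction of truth sites carried by ≥ 2
  panel individuals (ties count: "at least two") present in the calls.
* **AF correlation** — Pearson r between pooled estimates and reference
  frequencies over matched sites only.
* **Ti/Tv contrast** — calls at truth sites inherit the truth ratio
  (≈ 2.0); error-driven calls fall to ≈ 0.5.
* **Sex-chromosome accounting** — only male fetuses contribute Y DNA
  (one copy vs two autosomal), so chrY depth ≈
  $\mathit{ff} \cdot P(\text{male})/2$ of genome-wide depth, ≈ 2.1% at
  $\mathit{ff} = 0.084$; similarly ~5% of pooled data is male at a 10%
  fetal fraction. The closed form assumes chrY is a small share of the
  genome, so the simulated genome keeps human-like proportions (chrY
  ≈ 1.8%, chrX ≈ 5% of total length).
* **Carrier frequency** — Hardy–Weinberg heterozygote rate $2p(1-p)$,
  e.g. 0.232 ("about 1 in 4–5") at $p = 0.134$.
* **PCA** — pooled calling yields no individual genotypes, so genotypes
  are simulated from the estimated AF vector (100 pseudo-individuals by
  default) and analysed jointly with panel individuals:
  PLINK-convention standardization (center $2\hat p$, scale
  $\sqrt{2\hat p(1-\hat p)}$, pooled $\hat p$, monomorphic sites
  dropped), scores from the top-$k$ singular vectors. Pseudo-individuals
  land with their source population when the estimates are good — and
  measurably off it when they are not, which is the diagnostic value.

# Numerical and design choices

* Coordinates are 1-based inclusive throughout (SAM/VCF convention).
* Every stochastic operation takes an explicit seed; cohort operations
  derive per-sample seeds by counter, so results are independent of
  evaluation order and reruns are byte-identical.
* Truncated-normal fragment lengths use rejection sampling with a
  clamped fallback; fragments longer than a toy chromosome are clamped
  to it.
* Truth VCFs store frequencies at full double precision (`%.17g`) so
  write/read round-trips are exact.
* Zero-transversion call sets, zero-variance AF vectors, empty common
  site sets and zero genome-wide depth all signal "undefined" explicitly
  (`NA` with a warning) rather than returning a number.
* Panel precedence follows the order panels are supplied; the pipeline
  orders primary population, superpopulation, then database, mirroring
  the conventional reporting order.

# Study scales and what the tests show

The test suite runs three profiles: `tiny` (3 samples, 10 kb), `small`
(50 samples, 100 kb) and `paper_like_scaled` (500 samples × 0.15×, 1 Mb,
5000 sites — pooled ≈ 57× after filtering). Properties checked at scale:
AF recovery r ≥ 0.95 on the large profile, type-I control on 10⁶
simulated null columns at 100×, sensitivity/correlation monotone in
cohort size, PCA separation at $F = 0.1$ and none at $F = 0$, and the
chrY ratio within ±0.3 percentage points of 2.1% on a 600-sample
simulation. These sizes were chosen as the smallest at which the
sampling error of each property is comfortably below its assertion
margin.

Passing them shows the estimator and filters behave as designed under
the stated generative model. Real cohorts differ in ways the simulator
deliberately omits: GC and mappability bias beyond a binary MAPQ model,
PCR duplicates, contamination, index hopping, related individuals,
linkage disequilibrium (sites are independent here), and empirically
shaped fetal-fraction and insert-size distributions. Conclusions about
absolute sensitivity or error rates on real data should not be read off
these simulations; the package's value is the controlled comparison —
how each violation, once added, degrades the pooled estimates.

# Limitations

No indels, CNVs or aneuploidy (the screening purpose of the assay is not
modelled); no chromosome-Y variant calling (depth accounting only); no
contamination model; no real reference panels — synthetic panels stand in
for them and are labelled as such.
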