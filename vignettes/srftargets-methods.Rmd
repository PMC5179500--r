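---
title: "Methods: integrated classification of TCF-SRF target genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated classification of TCF-SRF target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind each pipeline stage,
the tunable parameters and their defaults, the design decisions taken where
the problem was genuinely open, and what the synthetic test-bed does and
does not establish about real data.

## Invariant-gene normalization

Sequencing libraries differ in depth; the normalization model assumes that
the majority of genes do not change between any two libraries, and that
their per-gene log2 count differences are approximately normal around the
library-scale offset. For sample *s* against the reference,

$$d_g = \log_2(n_{g,s} + 0.5) - \log_2(n_{g,\mathrm{ref}} + 0.5),$$

the invariant set is $\{g : |d_g - \mu_d| \le \sigma_d\}$ with $\mu_d$ the
mean and $\sigma_d$ the *population* standard deviation of $d$, and the
size factor is $2^{\overline{d}}$ over the invariant set.

Choices worth recording:

* **Log2 scale with pseudocount 0.5.** On the raw-count scale the
  difference distribution is dominated by expression level and far from
  normal; the log scale makes the quasi-normality assumption plausible and
  the one-sigma rule symmetric. A `diff_scale = "linear"` switch exists for
  comparison.
* **One pass, population SD.** The selection is applied once, not
  iterated; at transcriptome scale the sample/population SD distinction is
  immaterial, and the population form is fixed for determinism.
* **Degenerate cases.** Genes with zero counts in both libraries carry no
  scale information and are excluded before selection; if every difference
  is identical ($\sigma_d = 0$), all genes are kept.
* Differentially expressed genes contaminate $\mu_d$ upward before
  selection. With ~10% induced genes the one-sigma rule excludes
  essentially all of them and the residual bias on the factors is a few
  percent; the test suite measures this on tables with planted factors.

## The induction test

Differential induction per gene and read class uses a conditional
negative-binomial test: with raw condition totals $K_A, K_B$ and size
factors $s_j$, the null fits a common abundance
$q_0 = (K_A + K_B)/(\sum_A s_j + \sum_B s_j)$ and models each condition
total as (approximately) NB with mean $q_0 \sum s_j$ and variance
$\sum_j (q_0 s_j + \alpha q_0^2 s_j^2)$ — exact when size factors within a
condition are equal. The two-sided p value sums, over all splits
$a + b = K_A + K_B$, the probabilities no larger than that of the observed
split. Totals above $2 \times 10^6$ switch to a normal approximation of the
conditional law.

**Dispersion.** With two or three replicates per condition the per-gene
method-of-moments estimator is noise-dominated: roughly half the genes get
an underestimate (often hitting the numerical floor of $10^{-8}$), which
makes an exact test anticonservative, while keeping the overestimates
destroys power. The default therefore applies a robust *common* dispersion
— the 5% trimmed mean of the per-gene moment estimates, which is unbiased
under the $\chi^2_2$ sampling noise of a two-replicate variance (the
median, by contrast, is biased low by the factor $\ln 2$) — to every gene.
`dispersion_method = "per-gene"` restores raw per-gene estimation, and any
externally known dispersion can be supplied directly. Trended or
empirical-Bayes shrinkage across genes is deliberately out of scope.

**Calls.** A gene is *induced* when BH-adjusted p ≤ `alpha` (0.01) and fold
change ≥ `1 + min_change` (1.10) in at least one read class, with no
significant opposite call in the other; *downregulated* symmetrically. The
either-class rule maximizes sensitivity (intronic reads proxy ongoing
transcription and respond faster than total RNA) while the no-contradiction
clause protects against artefacts; requiring both classes is available by
filtering the per-class columns the call table retains.

**A power ceiling worth knowing about.** At 2+2 replicates and dispersion
0.02, the biological coefficient of variation alone puts the standard
deviation of an estimated log2 fold change near 0.21; at the BH cutoffs
realized in a 2,000-gene experiment, the detection probability of a 2-fold
induction is ≈ 0.95 for base means around 500 but only ≈ 0.80 near base
mean 100. Aggregate "power" for 2-fold changes therefore sits near 0.89 for
realistic expression distributions — a property of the design, not of the
test (a likelihood-ratio test with *known* dispersion does slightly worse
than the exact test in the same simulation).

## The dependence partition

For genes induced in the reference background, each gene contributes points
$(x, y)$ — log2 induction in the reference and comparison backgrounds — for
both read classes. The model is a single attenuated relation $y = \beta x$
through the origin for the dependent set, with everything else near
$y = x$. The iteration:

1. initialise the dependent set with genes attenuated in *both* classes
   ($y < x$);
2. fit $\beta$ by least absolute deviations through the origin on the
   pooled (total + intronic) points of the current set — the minimiser is
   the weighted median of $y_i/x_i$ with weights $|x_i|$, with the first
   ratio whose cumulative weight reaches half as tie-break;
3. reassign every gene: dependent iff $|y - \beta x| \le \tau$ in both
   classes, provided $\beta < 1 - \delta_{\min}$;
4. repeat until the label set is a fixed point (convergence is reported;
   the final relabelling is idempotent by construction).

Defaults: $\tau = 0.5$ log2 units (about twice the fold-change noise of a
well-measured gene, so the residual rule tests membership of the relation
rather than measurement luck) and $\delta_{\min} = 0.2$ (an attenuation of
less than 20% is not distinguishable from none at this noise level; when
the fitted slope reaches $1 - \delta_{\min}$ the dependent set empties,
which makes the null case — no attenuation anywhere — return zero dependent
genes rather than an arbitrary subset). Genes with non-positive reference
induction in either class are excluded before fitting: a ratio $y/x$ with
$x \le 0$ carries no attenuation information. Reassignment each round is
from the full induced set (not pruning-only), so early mistakes can be
repaired; the fixed point is insensitive to this choice in simulation.

The fitted slope and the Spearman correlation over the dependent cloud are
the two reported fit statistics. Note the Spearman value is driven by the
attenuation-to-noise ratio: with a planted slope of 0.15 and residual noise
of similar magnitude it is expected to be moderate (~0.3–0.5) even when the
labels are > 95% correct.

**Rescue.** The same machinery, applied to (reference induction, rescue
induction) over the dependent set, labels genes *rescued* when they rejoin
a systematic relation with slope above `beta_min` (0.5); the candidate set
initialises near full restoration ($|y - x| \le \tau$ in both classes), so
a rescue background identical to the knockout yields zero rescued genes.

## Peak consensus and coincidence

Pseudo-replicate peak calls are clustered by single-linkage 1-bp overlap
(via IRanges); a cluster is retained when ≥ `min_support` (3) distinct
pseudo-replicates contribute a peak with p < `p_threshold` (1e-4; scores
are −log10 p, so the rule is score > 4). The cluster is reported as the
union interval — conservative for downstream distance rules — with summit
the mean of qualifying member summits. Differential occupancy against a
control keeps peaks with normalized fold ≥ 1.5 at NB-test p ≤ 0.05.
Elk-1 peaks are *SRF-associated* when their summit falls inside an SRF
interval ± 100 bp (the same window used for motif analysis around peaks),
else *solo*; the partition is exhaustive and exclusive.

## Hi-C: expected model, interactions, compartments

The background model multiplies a per-distance mean by per-bin coverage
factors, $\mathrm{exp}(i,j) = m(|i-j|)\, c_i c_j$ with
$c_i = \mathrm{cov}_i / \overline{\mathrm{cov}}$, accounting for genomic
distance and sequencing depth without matrix balancing. Distance means are
raw up to 20 bins and pooled over quarter-octave log-spaced groups beyond
(pooling totals, not averaging means, so sparse far diagonals are
stabilised without reweighting). Zero-coverage bins are masked everywhere.

Interaction calls evaluate stored pairs at distance ≥ 2 bins (self and
adjacent bins are dominated by self-ligation): $Z = (o - e)/\sqrt{e}$ and
an upper-tail Poisson p at mean $e$; significance requires both p ≤ 0.05
and Z ≥ 2. Poisson is the natural law for the product-form expectation; a
pair with zero observed count can never be significant under an upper tail,
so unstored pairs are skipped. Note the calibration consequence: at these
fixed thresholds roughly 2–4% of null pairs are flagged (the Z ≥ 2 tail of
a Poisson), which is the intended "universe" behaviour — downstream rules
must treat a significant link as evidence, not proof, and the Indirect
class (defined by *absence* of links to site-bearing bins) inherits this
false-link rate as a recall bound.

Compartments: the observed/expected matrix over covered bins is turned into
a Pearson correlation matrix, whose first eigenvector is the compartment
score. Two conventions close the gaps the eigen-decomposition leaves open:
the sign is oriented so the score correlates positively with a per-bin
activity track (gene or active-TSS density — the A compartment is the
gene-rich one), and scores are scaled so the 95th percentile of |score| is
1,000, making the ± 100 assignment threshold a 10%-of-typical-amplitude
rule. Bins between the thresholds stay unassigned. On maps without block
structure the PC1 direction is arbitrary; scores are still emitted but
labels carry no spatial coherence (the test suite checks exactly this,
rather than asserting that such maps produce mostly unassigned bins, which
the scaling convention does not guarantee).

## Target classification

A gene is **Direct** when induced, dependent, and its TSS is within 10 kb
of a retained site *or* linked to a site-bearing bin by a significant
interaction at any distance (the "or" matters: proximity suffices even
where the map misses short-range contacts). **Indirect** requires > 100 kb
from every site *and* no link. The 10–100 kb band is a deliberate evidence
gap: such genes stay Unassigned and are reported separately rather than
silently merged. Multi-TSS genes use the TSS minimising site distance, and
any linked TSS makes the gene linked. "Linked to a site" means the partner
bin contains at least one retained peak *summit* — edge-only overlap of a
peak with a bin does not count, keeping the bin assignment unambiguous.
Direct targets whose nearest site is beyond 10 kb are flagged
*remote-controlled*. TSS-to-bin assignment uses the single TSS base
(start for + strand, end − 1 for −); peaks use their summit.

Gene-set enrichment is the upper-tail hypergeometric test with Bonferroni
adjustment over the number of sets tested (BH remains the adjustment for
DE testing; the two are never mixed).

## The synthetic test-bed

The generator emulates, per stage: NB counts with per-library size factors
and a majority of non-changing genes; a planted induced set (log2 fold
changes uniform in 1–3) of which a fraction is TCF-dependent with induction
multiplied by `attenuation` (0.15) in the knockout; down-regulated genes
planted symmetrically; intronic counts by binomial thinning (0.2) of the
same latent transcript draw, so both read classes share fold-change
structure as a transcription-rate proxy would; peak sets with
per-pseudo-replicate detection probability 0.9 and ≤ 50 bp jitter plus
single-replicate decoys; contact maps with power-law distance decay
(scale 200 at one bin, exponent 1), optional alternating A/B blocks
(enrichment 1.5× within, 1/1.5 across) and planted loops (10× local
expectation). Defaults: 2,000 genes, 400 induced, 60% dependent, dispersion
0.02, 2 replicates, one 5-Mb chromosome of 500 10-kb bins — desk-scale
sizes that keep the full suite to minutes while leaving every estimator in
its intended regime.

The coordinated study scenario places two clusters of three SRF sites,
dependent genes in four geometric roles (TSS within 5 kb of a site; > 100 kb
with a planted loop to a site bin; > 100 kb unlooped; and the 30–80 kb
evidence gap), and everything else uniformly. Its contact map is generated
*without* compartment blocks: the interaction caller's expected model is
deliberately compartment-blind (as the field-standard one is), so
superimposing strong blocks would convert compartment enrichment into
spurious loop calls; compartment recovery is exercised separately on
dedicated block maps. Gene density on the synthetic chromosome is far above
mouse average — a compression that correlates errors within shared bins but
does not change per-gene calibration.

What passing tests do **not** show about real data: no read-level effects
(mappability, GC, duplication), no dispersion heterogeneity across genes
(so the common-dispersion default is exactly right here and only
approximately right in practice), no TAD-scale structure or matrix
balancing, no inter-chromosomal contacts, single-TSS genes only in the
planted scenario, and peak FDR driven solely by the reproducibility model.

## Problem sizes and runtime choices

Unit tests run on 100–600-gene tables and 20–200-bin maps. Recovery suites
use the full default scenario (2,000 genes, 500 bins) over 10 seeds for the
partition, compartment and end-to-end checks, 500 replicates for the
consensus-retention expectation, and 20 random ≤ 100-bin maps for exact
oracle equivalence of the interaction caller; the acceptance script scales
the seed counts down (3 study seeds, 200 consensus replicates) to stay
within a few minutes on one CPU.

## Known limitations

* The exact NB test conditions on totals with an NB approximation to the
  sum when size factors differ within a condition; for strongly unequal
  factors the approximation is only moment-matched.
* The LAD slope assumes a single shared attenuation; genuinely heterogeneous
  attenuation would be averaged, not detected.
* Compartment scores from a single chromosome arm can flip sign in the
  orientation step when the activity track is nearly uncorrelated with the
  leading eigenvector.
* The Indirect class inherits the interaction caller's per-pair false-link
  rate; with many site-bearing bins its recall degrades geometrically.
* No support for inter-chromosomal links, `.hic`/`.cool` inputs, or BAM
  parsing — text formats only.
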