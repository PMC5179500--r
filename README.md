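# srftargets

Integrated RNA-seq / ChIP-seq / Hi-C classification of TCF–SRF target genes.

Serum response factor (SRF) drives immediate-early transcription after
mitogen stimulation through its ternary complex factor (TCF) cofactors
(Elk-1, Net, SAP-1). Deciding which phorbol-ester (TPA) inducible genes are
*direct* TCF–SRF targets — as opposed to downstream consequences of the
response — requires combining three genome-scale measurements:

* **RNA-seq** (total and intronic read counts) in wild-type and TCF
  triple-knockout (TKO) fibroblasts, to find TPA-induced genes and decide
  which of them lose induction without TCFs;
* **ChIP-seq** pseudo-replicate peak calls, to define high-confidence SRF
  (and Elk-1) binding sites;
* **Hi-C** contact maps at 10-kb resolution, to link transcription start
  sites (TSSs) to remote binding sites through significant chromatin
  interactions.

`srftargets` implements that analysis as a tested, tidyverse-style R
pipeline, together with a synthetic-data generator that plants known truth
at every stage so each statistical step has a recovery test. All user-facing
functions take data frames and return tibbles; fitted objects have
`tidy()`/`glance()` methods and ggplot2 `autoplot()`/`plot_*()` displays.

## The method

1. **Invariant-gene normalization.** For each library against a reference,
   per-gene differences `d_g = log2(n_g,s + 0.5) − log2(n_g,ref + 0.5)` are
   computed; the *invariant* set is `{g : |d_g − μ_diff| ≤ σ_diff}` (mean and
   population SD of `d`, one pass), and the size factor is `2^mean(d)` over
   that set.

2. **Induction testing.** Per gene, a conditional negative-binomial test
   compares condition totals given their pooled sum (the classical exact NB
   test computed from fitted means); dispersion is a robust common
   method-of-moments estimate. A gene is *induced* when, in at least one
   read class, BH-adjusted p ≤ 0.01 with fold change ≥ 1.10 and no
   significant opposite call in the other class (*downregulated*
   symmetrically).

3. **Dependence partition.** For genes induced in the reference background,
   the points `(x, y)` = (log2 induction in WT, log2 induction in TKO) for
   both read classes are partitioned iteratively: fit a
   least-absolute-deviation slope `β` through the origin on the current
   dependent set, reassign every gene by `|y − βx| ≤ τ` in both read classes
   (τ = 0.5 log2 units), repeat to a fixed point. The same machinery labels
   dependent genes *rescued* in a reconstituted (e.g. TKO + Elk-1)
   background.

4. **Peak consensus.** Peaks from pseudo-replicates are clustered by
   single-linkage overlap; a cluster is retained when called at p < 1e-4 in
   at least 3 pseudo-replicates, with optional differential-occupancy
   filtering against a control (fold ≥ 1.5, p ≤ 0.05). Elk-1 peaks whose
   summit falls within an SRF peak ± 100 bp are *SRF-associated*, the rest
   *solo*.

5. **Interaction calling.** A distance- and coverage-aware expected model
   (`expected(i,j) = distance_mean(|i−j|) · c_i · c_j`) yields per-pair
   `Z = (obs − exp)/√exp` and an upper-tail Poisson p; a pair is significant
   when `p ≤ 0.05` and `Z ≥ 2`. PC1 of the observed/expected correlation
   matrix, sign-oriented by gene activity and scaled so the 95th percentile
   of |score| is 1,000, assigns A (score > 100) and B (score < −100)
   compartments.

6. **Target classification.** An induced, dependent gene is **Direct** when
   its TSS lies within 10 kb of a retained SRF site *or* its TSS bin forms a
   significant interaction with a site-bearing bin at any distance;
   **Indirect** when it is > 100 kb from every site with no such link; genes
   in the 10–100 kb evidence gap stay **Unassigned** and are reported
   separately. Gene-set enrichment uses the upper-tail hypergeometric test
   with Bonferroni adjustment.

## Worked example

Simulate a coordinated study (2,000 genes, 400 TPA-induced of which 60% are
TCF-dependent with induction attenuated to 15% in TKO; two clusters of SRF
sites, planted TSS–site loops on a 5-Mb chromosome) and run the whole
pipeline:

```r
library(srftargets)

study <- simulate_study(sim_config(seed = 1))
res   <- run_study(study)

res$partition
#> Dependence partition: 229/402 genes dependent; slope 0.124, Spearman r 0.333 (5 iterations)

res$summary
#> Integrated target analysis summary
#>   n_genes                      2000
#>   n_induced                    402
#>   n_dependent                  229
#>   pct_dependent_of_induced     56.97
#>   n_direct                     90
#>   n_indirect                   92
#>   n_unassigned_dependent       47
#>   n_direct_remote              44
#>   pct_direct_remote            48.89
#>   n_elk_sites                  6
#>   n_elk_srf_associated         3
#>   n_elk_solo                   3
#>   pct_elk_srf_associated       50

res$metrics            # recovery against the planted truth
#> # A tibble: 3 × 3
#>   quantity  precision recall
#>   <chr>         <dbl>  <dbl>
#> 1 dependent     0.983  0.938
#> 2 direct        0.944  0.944
#> 3 indirect      0.957  0.88
```

The fitted slope 0.124 estimates the planted attenuation (0.15): dependent
genes retain ~12% of their wild-type induction in the knockout. 402 genes
are called induced (400 planted); 90 classify Direct and 92 Indirect, with
precision and recall ≥ 0.88 against the planted classes. About half the
Direct targets are "remote-controlled" — linked to their nearest SRF site
only through a significant Hi-C interaction beyond 10 kb.

`autoplot(res$partition)` draws the two-background induction scatter with
the fitted relation; `plot_contact_map()` and `plot_compartment_track()`
display the Hi-C side.

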