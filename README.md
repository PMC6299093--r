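# dsbquant

Quantification of repair-factor and DNA:RNA hybrid signals at DNA
double-strand breaks (DSBs), for groups analyzing super-resolution
colocalization imaging and break-proximal enrichment sequencing.

DSBs recruit repair factors (γH2AX, BRCA1, RNase H2, ...) and accumulate
DNA:RNA hybrids nearby. `dsbquant` implements the two quantifications such
studies lean on, plus the qPCR arithmetic behind their companion panels:

1. **SMLM colocalization with a Monte-Carlo cluster-randomization null.**
   Per nucleus, clusters of localizations are detected per channel
   (DBSCAN), two-channel overlaps are counted by disc intersection
   (centroid distance ≤ sum of effective radii), and the count is
   normalized by the mean overlap count across *n*<sub>sim</sub> = 20
   simulations in which every cluster is independently translated to a
   uniformly random admissible position within the nucleus ROI:

   *R* = *N*<sub>real</sub> / *N̄*<sub>random</sub>.

   *R* ≈ 1 under no association; cohorts are summarized as mean ± s.e.m.
   with Welch *t*-tests between groups.

2. **DSB-proximal enrichment profile.** Cut and uncut coverage in 50-bp
   bins is RPKM-normalized, combined into per-bin
   log₂((cut + 1)/(uncut + 1)), and aggregated around the top-50
   cleavage-ranked cut sites into five two-sided distance windows (0–0.5,
   0.5–1, 1–1.5, 1.5–2, 2–2.5 kb), assigning a bin to a window only when
   ≥ 90% of the bin overlaps the window footprint. Per-window medians of
   per-site means are tested against 0 with a one-sample Wilcoxon
   signed-rank test, overall and stratified by genic context.

3. **qPCR arithmetic.** Percent input 100·IP/(input/*f*), per-replicate
   cut/uncut fold induction averaged across replicates, and ΔΔCq relative
   expression against a normalizer.

Synthetic-data generators emulate each assay (clustered two-channel point
patterns in a nucleus mask; negative-binomial bin counts with a
distance-dependent enrichment amplitude; replicated qPCR tables with
log-normal IP noise), so the entire pipeline is testable offline. See the
methods vignette (`vignettes/dsb-signal-quantification.Rmd`) for the
models, conventions and numerical choices.

## Worked example

```r
library(dsbquant)

# --- colocalization: 20 nuclei, half of the B clusters seeded on A ------
nuclei <- simulate_smlm_cohort(20, smlm_sim_spec(coloc_fraction = 0.5),
                               seed = 1)
tab <- coloc_cohort(nuclei, n_sim = 20, seed = 2)
head(tab[, c("nucleus_id", "n_real", "mean_random", "ratio", "flag")])
#>    nucleus_id n_real mean_random     ratio flag
#> 1 nucleus_001     17        1.95  8.717949   ok
#> 2 nucleus_002     26        2.55 10.196078   ok
#> 3 nucleus_003     21        2.00 10.500000   ok
#> 4 nucleus_004     24        1.45 16.551724   ok
#> 5 nucleus_005     19        1.85 10.270270   ok
#> 6 nucleus_006     17        1.85  9.189189   ok
mean(tab$ratio[tab$flag == "ok"])
#> [1] 11.65066
```

Each row is one nucleus: ~17–26 real overlaps against ~2 expected by
chance gives normalized ratios around 10 — strong colocalization, as
designed (`coloc_fraction = 0.5`). With independent channels
(`coloc_fraction = 0`) the cohort mean sits near 1.

```r
# --- enrichment profile: 50 sites, amplitude peaking 3x at 1.5 kb -------
sim <- simulate_drip_experiment(drip_sim_spec(), seed = 3)
prof <- drip_profile(sim$cut, sim$uncut, sim$sites,
                     total_reads_cut = sim$library_size_cut,
                     total_reads_uncut = sim$library_size_uncut)
subset(prof$summary, stratum == "all")
#>   stratum interval  n median   q25  q75        p
#> 1     all    0-0.5 50  0.367 0.277 0.42 7.79e-10
#> 2     all    0.5-1 50  0.976 0.901 1.04 7.79e-10
#> 3     all    1-1.5 50  1.402 1.335 1.46 7.79e-10
#> 4     all    1.5-2 50  1.408 1.361 1.51 7.79e-10
#> 5     all    2-2.5 50  0.978 0.888 1.04 7.79e-10
```

The per-window medians of the per-site mean log₂ ratios reproduce the
simulated amplitude: rising from the cut, maximal in the 1–1.5/1.5–2 kb
windows, declining beyond — with the signed-rank test rejecting 0 in
every window.

```r
# --- qPCR: true fold 4, 15% IP noise, 4 replicates ----------------------
qp <- simulate_qpcr_table(c(locus = 4), cv = 0.15, n_replicates = 4,
                          seed = 4)
fold_induction_table(qp)$summary
#>   region n mean_fold   sem
#> 1  locus 4     4.047 0.497
```

`run_pipeline()` drives the same stages from a single YAML/list config and
writes TSV outputs plus a reproducible JSON run manifest.

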