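---
title: "Quantifying repair-factor and DNA:RNA hybrid signals at double-strand breaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repair-factor and DNA:RNA hybrid signals at double-strand breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

DNA double-strand breaks (DSBs) recruit repair factors and accumulate
DNA:RNA hybrids in their vicinity. Two very different assays probe this:
two-colour single-molecule localization microscopy (SMLM/STORM), which asks
whether two markers — say the damage mark γH2AX and S9.6-detected DNA:RNA
hybrids — colocalize in individual nuclei beyond chance; and DRIP-seq-style
binned coverage, which asks how hybrid signal is distributed as a function
of genomic distance from nuclease-induced cut sites. `dsbquant` implements
both quantifications, the percent-input arithmetic behind the companion
qPCR panels, and synthetic-data generators that make every stage testable
without any external data.

```{r setup}
library(dsbquant)
```

## 1. The colocalization statistic

### Model

A nucleus contributes a region of interest (ROI) and, per channel, a set of
clusters of single-molecule localizations. Each cluster is summarized by
its centroid and an *effective radius* — the maximum distance of any member
localization from the centroid, so the disc covers every member. Two
clusters from different channels *overlap* when their centroid distance is
at most the sum of their radii (disc intersection), and the per-nucleus
signal is the number of unordered overlapping pairs.

A raw overlap count is meaningless on its own: nuclei differ in cluster
number, size and nuclear area, all of which change how many overlaps occur
by chance. The statistic therefore normalizes against a Monte-Carlo null:
in each of `n_sim = 20` simulations every cluster is independently
translated — without rotation or reshaping — to a uniformly random
admissible position in the ROI, and overlaps are re-counted. The
*normalized overlap ratio* is

$$R \;=\; \frac{N_\text{real}}{\overline{N}_\text{random}},$$

the real count divided by the mean of the 20 random counts from the same
nucleus. Under no association, $R \approx 1$; values above 1 quantify
colocalization in units of "fold over chance".

### Design choices

Several details of this statistic are genuinely open, and the package pins
them as follows (alternatives stay available behind arguments):

* **Clustering.** Localization lists carry no cluster labels, so clusters
  are found by density-based clustering (DBSCAN; defaults
  `eps = 75` nm, `min_pts = 5`, an SMLM-typical scale between localization
  precision and focus size). The clustering is implemented in the package
  (grid-hashed neighbour search, exact labels).
* **Overlap unit.** Unordered intersecting *pairs*, because the disc
  criterion admits an exact analytic null for testing (see below);
  `count_overlaps(unit = "matched")` counts clusters with at least one
  partner instead.
* **Both channels are randomized** in every simulation. A symmetric null
  propagates both channels' cluster numbers and sizes into the baseline —
  this is how the broader spatial spread of one marker (e.g. γH2AX) than
  the other is absorbed rather than mistaken for signal.
  `normalized_overlap_ratio(randomize = "a")` restricts rearrangement to
  one channel.
* **Erosion constraint.** A randomized centroid is drawn uniformly from
  the ROI eroded by the cluster's radius, so the whole disc stays inside
  the nucleus (asserted per simulation). For rectangles and discs the
  eroded region is sampled analytically; for masks and polygons by
  rejection sampling. This constraint shrinks the admissible area slightly
  — about 2% for 100-nm clusters in a 10 µm nucleus — which is the main
  deviation of the realized null from the naive closed form
  $n_A n_B \pi (2r)^2 / \text{Area}$.
* **Degenerate nuclei.** If all 20 random counts are zero while real
  overlaps exist, no finite ratio is defined; the nucleus is flagged
  `null-degenerate`, excluded from cohort summaries and counted. A nucleus
  with zero real *and* random overlaps gets ratio 0 with flag `both-zero`
  and is likewise excluded.
* **Reproducibility.** Each nucleus derives a child seed from the run's
  root seed by hashing its identifier ([nucleus_seed()]), so adding or
  removing a nucleus never perturbs the others. The hash is passed through
  three Lehmer (MINSTD) scrambling steps because R's Mersenne-Twister
  seeding can yield weakly correlated streams for *adjacent* integer
  seeds; scrambling keeps nearby ids and roots on well-separated streams.

Cohorts of nuclei are summarized as mean ± s.e.m. of the valid ratios and
compared between two groups with a Welch two-sample two-tailed *t*-test
(`cohort_summary()`).

### What the simulator emulates — and what it does not

`simulate_smlm_nucleus()` draws channel-A cluster centroids uniformly in
the ROI; with probability `coloc_fraction` a channel-B cluster is seeded at
a randomly chosen A centroid plus Gaussian jitter, otherwise placed
uniformly. Member localizations are Gaussian around the centroid, truncated
at the drawn radius; uniform background localizations are appended.
Colocalization is modelled at the *cluster* level because clusters are
what the statistic randomizes and counts.

The reference condition used throughout the tests is 40 + 40 clusters of
fixed 100 nm radius in a 10 × 10 µm square nucleus with 20 randomizations —
scales at which the analytic Poisson-disc expectation
$n_A n_B \pi (2r)^2 / \text{Area} \approx 2.0$ overlaps per nucleus makes a
sharp oracle. The simulator does **not** model camera or PSF physics,
drift, chromatic aberration, localization blinking/recounting, or
non-uniform chromatin density; passing tests therefore certify the
*statistic*, not robustness to those instrumental effects.

Two cohort-level properties tie simulator and statistic together (both are
asserted in the test suite): with independent channels the cohort mean
ratio lies in [0.9, 1.1] over 200 nuclei, and the mean ratio increases
strictly with the simulated colocalized fraction. At these fixed
conditions the cohort mean under the null is approximately
$\mathcal{N}(1.025,\,0.052)$ — the +2.5% reflecting the Jensen bias of
$E[1/\overline{N}_\text{random}]$ at a null mean of only ~2 overlaps — so
the [0.9, 1.1] band is a ~1.5–2σ statement, and the packaged checks use
fixed seeds.

## 2. The DSB-proximal enrichment profile

### Pipeline

Counts per fixed-width bin (50 bp by default) for a *cut* and an *uncut*
condition are each RPKM-normalized,

$$v' = \frac{\text{count}}{(\text{width}/1000)\,(\text{total reads}/10^6)},$$

and combined into a per-bin log2 ratio with a pseudocount (default 1 on
the normalized scale):
$\log_2(v'_\text{cut} + 1) - \log_2(v'_\text{uncut} + 1)$. The subtraction
form makes swapping the conditions negate every bin bitwise-exactly.

Cut sites carry a cleavage-rank score (e.g. from genome-wide break
mapping) and a genic/nongenic flag; the `top_k = 50` highest-scoring sites
are analyzed, with score ties broken deterministically by (chrom,
position). Around each site, five half-open windows of absolute distance —
0–0.5, 0.5–1, 1–1.5, 1.5–2, 2–2.5 kb — pool the left and right flanks. A
bin is assigned to a (site, window) pair iff its total overlap with the
two-sided footprint is at least `min_overlap_frac = 0.9` of the nominal
bin width (a 45-bp overlap of a 50-bp bin passes; 44 bp does not). Sites
are treated independently, so one bin may serve several sites; it can
satisfy the rule for at most one window of a given site because the
windows are disjoint and 0.9 > 0.5 (asserted in tests, not assumed).

Per (site, window) the assigned bin values are averaged; per window —
overall and stratified genic/nongenic — the per-site means are summarized
by median and quartiles and tested against 0 with a two-sided one-sample
Wilcoxon signed-rank test. Zero differences are dropped (standard
convention); the exact distribution is used for n ≤ 25 tie-free samples
and the normal approximation with continuity correction otherwise. Windows
with fewer than 5 contributing sites, or with no nonzero values, keep
their summary but withhold the test. No multiple-testing correction is
applied by default, mirroring per-window significance stars;
`bonferroni = TRUE` multiplies by the number of windows.

Open conventions pinned here: the test is one-sample against 0 on per-site
means of the log2 ratio track (a paired cut-vs-uncut variant can be built
by profiling each condition's normalized track separately); left and right
flanks are pooled at the *bin* level before averaging; distance is
absolute (unsigned).

### The simulator and its noise scale

`simulate_drip_experiment()` places `n_sites = 50` cut sites on a 3 Mb
chromosome with a minimum separation of twice the profile extent, so
footprints never overlap (positions are drawn uniformly conditional on the
separation via the exact spacing construction). Uncut bin counts are
negative-binomial around a flat baseline; cut counts are negative-binomial
around baseline × *a(d)*, where *a* is a piecewise-linear amplitude rising
from 1 at the cut to a peak (default 3-fold) at 1.5 kb and decaying to 1
by 3 kb — the enrichment-with-distance shape the profile pipeline is meant
to resolve, used purely as a simulation design. A `"flat"` amplitude shape
and a Poisson limit (`dispersion = Inf`) are provided for calibration
checks against closed-form expectations.

Two numerical choices deserve justification:

* **Count noise** defaults to baseline 100 reads/bin with NB size 20
  (per-bin log2-ratio noise ≈ 0.5) — a deeply sequenced library with mild
  overdispersion. With 50 sites × ~20 pooled bins per window this resolves
  per-window medians to ≈ 0.02, which is what makes a ±0.05 null band on
  control medians a meaningful (≈ 2.5σ) statement. A markedly noisier
  default would leave the control band dominated by sampling error
  regardless of correctness.
* **RPKM totals.** The simulator reports nominal library sizes
  (`n_bins × baseline`, per condition) and the profile should normalize by
  them rather than by the realized sums of the simulated chromosome: on a
  real genome the DSB-proximal enriched fraction is a negligible share of
  the library, but on a 3 Mb toy chromosome it is not, and normalizing by
  the realized sum would push background bins visibly below zero.

`scramble_sites()` provides the matched negative control: same number of
sites, same separation rule, forced at least the profile extent away from
every real site, so scrambled footprints sample only baseline noise.

## 3. qPCR arithmetic

Percent input is $100 \cdot \text{IP} / (\text{input}/f)$ with $f$ the
input chromatin fraction — required configuration with no canonical
default, since dilution schemes vary between experiments. Fold induction
is the ratio of cut to uncut percent input, computed *per replicate and
then averaged* (never a ratio of means), so the reported s.e.m. reflects
between-experiment variability. Relative expression follows the
ΔΔCq convention, $E^{-\Delta\Delta C_q}$, with amplification efficiency
fixed at 2.0 per cycle by default (no standard curves assumed) and
configurable per target.

`simulate_qpcr_table()` applies multiplicative log-normal noise (mean 1,
stated CV) to the IP quantities and treats the input quantities as exact:
inputs are dilutions of the same chromatin pool measured in the same run,
so replicate variability is dominated by IP recovery. This placement
matters for calibration — the per-replicate fold estimator is then biased
only by $E[\varepsilon_c/\varepsilon_u] = e^{\sigma^2} \approx 1 + cv^2$
(+4% at CV 0.2), whereas independent noise on all four quantities would
double that. At CV 0.2 the fold-3 recovery lands within 5% of truth, as
the tests assert.

## 4. Data formats, containers and degenerate inputs

Localizations are CSV with a configurable column mapping
(`loc_dialect()`; defaults match ThunderSTORM-style headers `"x [nm]"`,
`"y [nm]"`, `"frame"`, with optional camera-pixel units converted on
read). ROIs are binary raster TIFF/PNG (any nonzero pixel is foreground)
or GeoJSON-style polygon JSON; rendered images are 16-bit count TIFFs at
20 nm/pixel by default — rendering is QC only, the statistic runs on
continuous coordinates. Genomic tracks are bedGraph and cut sites BED
(score = cleavage rank, name tag `genic`/`nongenic`), read and written
through `rtracklayer`; all genomic coordinates are 0-based half-open
internally. Pipeline outputs are TSV plus a JSON run manifest.

Degenerate inputs are handled explicitly rather than silently: non-finite
localization rows are dropped and counted; localizations exactly on a
pixel edge belong to the floor pixel and polygon boundaries are inclusive,
so in/out decisions are deterministic; an all-zero mask or zero-area
polygon is an error; a cluster that cannot fit in the ROI names itself in
the placement error; an ROI that exactly fits a cluster pins its centroid
to the unique admissible point; mismatched bin grids report the first
mismatching bin; `k` larger than the site table warns and keeps all sites;
sites near chromosome ends simply collect fewer bins, and (site, window)
pairs with no assigned bins are omitted and counted.

The run manifest records command, parameters, seed, package version and
output digests. It omits wall-clock timestamps by default so that reruns
with the same config and seed are byte-identical — reproducibility is
favoured over provenance timestamps (`include_timestamp = TRUE` restores
them).

## 5. Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on synthetic data at
the configuration stated above: 200-nucleus null cohorts and 50-nucleus
dose-response cohorts for the colocalization statistic; 10⁴ draws for the
randomization-uniformity check; a 3 Mb chromosome (6 × 10⁴ bins) with 50
sites for the enrichment profile; 10⁴ bins × 20 sites for the
bin-assignment oracle; 200 replicate runs for the qPCR recovery. These
sizes keep every closed-form or brute-force oracle sharp while the whole
suite completes in well under a minute on one core.

## 6. Worked example

A minimal end-to-end run on simulated data:

```{r example}
# --- colocalization ------------------------------------------------------
nuclei <- simulate_smlm_cohort(20, smlm_sim_spec(coloc_fraction = 0.5),
                               seed = 1)
tab <- coloc_cohort(nuclei, n_sim = 20, seed = 2)
head(tab[, c("nucleus_id", "n_real", "mean_random", "ratio", "flag")])
mean(tab$ratio[tab$flag == "ok"])

# --- enrichment profile --------------------------------------------------
sim <- simulate_drip_experiment(drip_sim_spec(), seed = 3)
prof <- drip_profile(sim$cut, sim$uncut, sim$sites,
                     total_reads_cut = sim$library_size_cut,
                     total_reads_uncut = sim$library_size_uncut)
subset(prof$summary, stratum == "all")

# --- qPCR ----------------------------------------------------------------
qp <- simulate_qpcr_table(c(locus = 4), cv = 0.15, n_replicates = 4,
                          seed = 4)
fold_induction_table(qp)$summary
```

## 7. Known limitations

* The colocalization statistic is strictly two-channel and disc-based; no
  rendering-based cross-correlation (Pearson/Manders) or >2-colour
  statistics are provided, and no drift or chromatic-aberration
  correction is attempted.
* Clusters may overlap each other after randomization — no hard-core
  exclusion is imposed, so the null slightly over-counts configurations a
  crowded nucleus could not realize.
* The enrichment stage starts from binned counts; alignment, duplicate
  removal and peak calling are upstream concerns, and cleavage ranks are
  taken as given.
* The Wilcoxon exact branch requires tie-free absolute values; tied
  samples silently use the corrected normal approximation, which is
  anti-conservative for very small n with heavy ties.
* Amplification efficiency in the qPCR module is a configured constant,
  not estimated from standard curves.
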