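---
title: "Layered deconvolution of bulk tumor methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered deconvolution of bulk tumor methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilayers)
```

## The problem

Bulk tumor methylation profiles are mixtures. The DNA in a biopsy comes from
tumor cells, infiltrating immune cells, and cancer-associated fibroblasts
(CAFs), so the measured methylation fraction at a locus is a purity-weighted
average of cell-type-specific methylomes. Any unsupervised analysis of raw
bulk methylomes therefore rediscovers tumor microenvironment (TME)
composition before it discovers tumor biology. On top of that, the
tumor-intrinsic signal is itself dominated by a small number of global,
highly correlated "layers": a replication-timing-graded loss of methylation
that behaves like a mitotic clock (late-replicating domains lose most), a
gain layer at normally unmethylated CpG-island-like loci (MG), and a loss
layer at partially methylated loci (ML). Locus-level regulatory signal —
promoter or enhancer methylation repressing its own gene — is a thin residual
on top of these trans-acting structures.

`epilayers` separates these strata explicitly:

1. **TME module discovery** (`build_cross_correlation`,
   `cluster_cross_correlation`, `identify_tme_modules`): Pearson
   cross-correlation of log expression against raw promoter methylation,
   clustered (Euclidean distance, Ward "ward.D2", 30 clusters), with immune
   and CAF gene modules identified by anchor markers (CD3D..., CAV1...).
2. **K-nn normalization** (`knn_normalize`): each tumor's K nearest
   neighbors (K = 30 for ER+; 15 for the smaller ER− and normal groups) in
   the 2D (immune signature, CAF signature) plane define a composition-matched
   reference; subtracting the neighborhood-mean methylation removes the
   compositional signal.
3. **Layer inference** (`fit_layers`): up to 50,000 normalized signatures
   are sampled, filtered (at least one |r| > 0.25 partner), and Ward-clustered
   into three clusters; per-sample layer scores are the mean normalized
   methylation over each cluster's loci.
4. **Cis-regulation screens** (`promoter_cis_screen`, `distal_cis_screen`):
   rank-based detection of promoters whose methylation correlates with their
   own gene beyond trans effects (empirical FDR = k/m), and distal-element
   pairing within 500 kb with a shuffled-control FDR.
5. **Read-level epialleles** (`homogenize_fragment`, `downsample_patterns`,
   `epipolymorphism`): 5-CpG patterns per restriction fragment at fixed depth
   30, summarized by Gini–Simpson diversity.
6. **Genetic integration** (`associate_scores`, `dosage_compensation`,
   `math_score`).

The whole model is exposed as a single fitting function:

```{r, eval = FALSE}
coh <- simulate_cohort(sim_config())
fit <- epilayer_fit(coh$meth, coh$expr, coh$metadata, group = "ER+")
summary(fit)
head(signature_table(fit, coh$metadata))
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `promoter_upstream/downstream` | 500 / 50 bp | promoter window around the TSS |
| `meth_mean_bounds` | [0.1, 0.9] | loci admitted to cross-correlation |
| `corr_floor` | 0.25 | row/column retention and layer-eligibility partner threshold |
| `tme_corr_threshold` | −0.3 | promoters entering the TME methylation scores |
| `knn_K` / `knn_K_small` | 30 / 15 | neighborhood sizes (ER+ / ER− and normals) |
| `n_cross_clusters` | 30 | cross-correlation clusters |
| `n_layer_clusters` | 3 | methylation layers |
| `layer_sample_size` | 50,000 | loci sampled for layer inference |
| `min_corr_samples` | 50 | minimum paired samples per correlation |
| `distal_window` | 500 kb | distal pairing distance |
| `epipoly_ncpg` / `epipoly_depth` | 5 / 30 | epiallele length and fixed depth |
| `enhancer_top_quantile` | 3% | H3K4me1 coverage cut for enhancer calling |
| `tor_bins` | 20% / 60% | late / intermediate / early replication bins |

Smaller K makes neighborhood means noisier; larger K makes neighborhoods less
homogeneous in TME composition and the normalization less effective. The
layer-eligibility mean-methylation filter acts on **normalized** values by
default (|mean| < 0.1): applying it to raw means would exclude the
raw-hypermethylated clock loci entirely, which is why the raw variant is
available only behind `layer_eligibility = "raw"`.

## Design choices where the procedure was genuinely open

* **Ward semantics.** "ward.D2" squares Euclidean distances internally; we
  call `stats::hclust(method = "ward.D2")` and relabel clusters in dendrogram
  order so identical inputs give identical labels.
* **Missing correlations** are imputed as 0 before clustering — neutral under
  Euclidean distance.
* **Layer auto-labeling.** Clusters are labeled from the raw methylation of
  normal samples: highest → clock (normally hypermethylated, loses in
  tumors), lowest → MG (normally unmethylated, gains), middle → ML. A
  replication-timing cross-check warns if the clock cluster is not
  late-enriched. Manual inspection would also work; a deterministic rule is
  testable.
* **Self-exclusion** in K-nn: including a sample in its own neighborhood
  biases residuals toward zero.
* **Signature axes are z-scored** before neighbor search (flag
  `zscore_axes = FALSE` for raw axes): the two signatures need not share a
  dynamic range.
* **Missing-data rule**: a normalized cell is reported only when at least
  K/2 neighbors are observed, capping the variance of the neighborhood mean.
* **Promoter aggregation** pools reads (coverage-weighted) rather than
  averaging per-CpG fractions; a flag switches to the unweighted mean. The
  choice matches coverage-weighted practice for sparse reduced-representation
  data.
* **Rank direction** in the promoter screen: ascending (rank 1 = strongest
  negative correlation) for repression, with a mirrored descending pass for
  induction; both passes are emitted, labeled by sign.
* **Shuffle unit** in the distal screen: sample labels of the expression
  matrix, keeping the locus/gene genomic geometry intact.
* **Downsampling without replacement** for epialleles (flag available),
  preserving multiset semantics; coverage ties in CpG selection break to the
  leftmost genomic position.
* **Tie-breaks** throughout (promoter resolution: 5′-most; best distal gene:
  lexicographic gene id; neighbor ties: stable sample index) make every stage
  deterministic under a fixed seed.

## The synthetic cohort

Controlled-access data cannot ship with a package, so every stage is tested
against `simulate_cohort()`, which generates the statistical structure the
method assumes:

* per-sample immune and CAF fractions `f_imm`, `f_caf` ~ Beta(2, 8)
  (mean 0.2 — realistic infiltration spreads), with tumor latents
  `c_s`, `g_s`, `l_s` ~ U(0, 1) (zero in normals);
* observed methylation = `(1 − f_imm − f_caf)·tumor + f_imm·immune +
  f_caf·CAF + noise`, clipped to [0, 1];
* cell-type baselines from a bimodal beta mixture (the familiar
  hypo/hemi/hyper methylome shape), clamped to [0.08, 0.92];
* clock loci lose `c_s × loading`, with loading proportional to the locus's
  replication-timing lateness rank and clock membership drawn
  lateness-weighted (late domains concentrate the loss);
* MG loci start at 0.08 and gain `g_s × U(0.4, 0.8)`; ML loci start
  partially methylated and lose `l_s × U(0.3, 0.6)`;
* measurement noise is heteroscedastic: binomial read-sampling variance
  `m(1−m)/depth` at depth 60 plus a flat sd-0.02 technical floor. This keeps
  boundary loci quiet (clipping < 1% of entries) while interior loci carry
  the sd ≈ 0.05–0.09 noise real reduced-representation data shows;
* expression: module genes rise with their fraction; most background genes
  carry a small compartment-mixture drift with the fractions and a weak
  coupling to one latent (bulk expression is a mixture too — without this
  pervasive trans structure, 30-way clustering over-fragments the tight
  modules, which is not how cohort-scale data behaves);
* 50 planted cis promoter–gene pairs (coupling −0.6 against the observed
  promoter methylation) and 30 planted enhancer–gene pairs within 10–400 kb;
* 5% of calls missing at random; read-level epialleles drawn multinomially
  with per-CpG dropout.

What the simulator does **not** emulate: genomic sequence context, CNA-driven
methylation shifts, clonal heterogeneity, batch effects, and spatially
correlated coverage. Passing recovery tests therefore demonstrates that the
algorithms recover the structure they model — not that real tumors contain
only that structure.

## Reference measurements and problem sizes

The bundled tests and `scripts/acceptance.R` run, at fixed seed:

* the default cohort (500 ER+ tumors, 60 normals, 5,420 loci, 2,120 genes)
  for TME normalization, layer recovery (assignment accuracy ≈ 97%, score
  |cor| ≈ 0.93 for each latent, clock TOR KS p ≈ 0) and the cis screen
  (sensitivity 100% of 50 planted pairs at FDR ≤ 0.05);
* 20 null replicates of a 500-gene independent screen (mean rank-1 diagonal
  count ≈ 1, essentially no declarations at nominal FDR 0.05). Under a pure
  global null the k/m rule declares nothing, so calibration is reported as
  the rank-1 Poisson check plus the declared fraction, and the realized
  false-discovery proportion is additionally checked in the planted cohort;
* 20 permutation cohorts (150 samples, 1,000 loci, 600 genes at 50 kb
  spacing) for the distal-pairing null, where the shuffled:real ratio
  averages ≈ 1;
* 1,000 random 30-read pattern compositions against a brute-force
  Gini–Simpson oracle (agreement to 1e−12);
* a 200-gene copy-number cohort for dosage-compensation classification
  (accuracy ≈ 98%);
* two identical end-to-end pipeline runs compared byte for byte.

Unit tests use smaller cohorts (120–300 tumors). One caveat discovered there
is worth knowing: below roughly 250 samples the |r| > 0.25 eligibility filter
no longer prunes null loci (the null correlation ceiling over thousands of
candidate partners exceeds 0.25), so layer clusters absorb background loci
and the MG score degrades first. The method is a cohort-scale tool.

## Known limitations

* **Residual TME correlation after K-nn normalization.** The neighborhood
  residual `f − mean(f over K neighbors)` retains correlation ≈ 0.7 with `f`
  itself — a shrinkage bias intrinsic to nearest-neighbor smoothing (it
  persists, ≈ 0.5, even with exact 1D matching on the true fraction). At
  strong-contrast immune-specific loci with realistic noise this leaves a
  residual |cor| ≈ 0.15–0.25 with the infiltrating fraction at n = 500,
  K = 30 — normalization flattens the raw |cor| ≈ 0.85 by about 75%, but does
  not nullify it. Downstream analyses should treat normalized methylation at
  known TME loci with care.
* Layer labels are only as good as the normal-sample reference; without
  normals a tumor-mean heuristic is used, with a warning.
* The empirical k/m FDR assumes independence between expression and
  methylation under the null; pervasive trans structure makes it
  conservative rather than anti-conservative (m grows with k).
* Epi-polymorphism at fixed depth 30 cannot distinguish diversity beyond
  1 − 1/30, and fragments under 30 homogenized reads are dropped, biasing
  toward well-covered (CpG-dense) fragments.
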