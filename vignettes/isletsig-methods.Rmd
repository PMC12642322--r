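---
title: "Methods: single-islet proteomics signatures of islet immune response and beta-cell state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-islet proteomics signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

In presymptomatic (stage 1) type 1 diabetes, islets within a single pancreas
are heterogeneous: some are infiltrated and inflamed, others quiescent; some
have lost insulin expression, others are intact. Because pancreas specimens
are single snapshots, this *intra-donor* heterogeneity is the only available
window onto disease progression — islets at different molecular states can be
read as positions along a pseudo-temporal trajectory. `isletsig` implements
an analysis pipeline for label-free proteomics of individual laser-dissected
islet sections that turns a protein-group abundance matrix from a handful of
donors (~50-100 islets each) into:

1. per-donor co-expression modules tested against islet phenotypes (binary
   CD3 T-cell status, proteomic insulin intensity);
2. a 40-protein **Islet Immune Response Signature (IIRS)** selected by
   machine learning, whose per-islet median abundance serves as a
   pseudo-temporal coordinate of immune activation;
3. a 41-protein **Beta-Cell Profile (BCP)** ranked by correlation with the
   beta-cell anchors INS and ENTPD3, summarizing beta-cell mass/function/
   identity per islet;
4. per-donor moderated linear models of every protein against these
   centroids, and correlation-adjusted competitive gene-set tests
   (CAMERA-PR) on the resulting z-scores.

A seeded synthetic-data generator with known ground truth accompanies the
pipeline so that every stage is testable end to end without access to the
original tissue data.

# Preprocessing model

Raw intensities are log2-transformed and each protein is zero-centered over
its observed values. Sample-to-sample loading differences are removed by
**Tukey median polish**: the additive decomposition
`x[g, j] = overall + row[g] + col[j] + resid[g, j]` is fit by alternating
row- and column-median sweeps on the complete-case protein rows (classical
relative stopping rule 0.01, hard cap of 20 sweeps with a warning), and the
fitted column effects are subtracted from *all* proteins of those samples —
fit on complete cases, apply to everything, so proteins with missing values
are normalized too.

Tissue-block batch effects within each donor are removed by a parametric
empirical-Bayes location/scale adjustment (the ComBat model): proteins are
standardized on their grand mean and pooled residual variance, per-block
means are shrunk toward a normal prior and per-block variances toward an
inverse-gamma prior (method-of-moments hyperparameters, iterated conditional
updates to 1e-4), and the standardization is inverted. Our implementation
keeps the fit (`combat_fit()`) and the transform (`combat_apply()`)
separate, and tolerates missing entries by taking every moment over observed
cells — a requirement here, since correction happens before imputation.
Degenerate inputs are handled conservatively: constant proteins are skipped
with a warning, and proteins with no within-block residual variance receive
a location-only adjustment.

Donors are then combined on the intersection of their feature universes and
proteins are kept only when *strictly more than half* of each donor's islets
observe them (50.0% exactly is removed; the threshold is configurable).

**Missing values are never zeros.** They are carried as absent cells through
every transform (zeros would corrupt the median polish), and only the steps
that require complete data impute:

* clustering runs on matrices completed by **iterative SVD imputation**
  (z-score proteins, initialize missing cells at 0, repeatedly replace them
  with their rank-k reconstruction until the relative change drops below
  1e-5, restore scales and observed values), applied within disease-status
  groups so imputation cannot blend the two class structures. The default
  rank is 20 — the number of latent co-regulation factors the synthetic
  design contains, and a sensible order of magnitude for a fine-grained
  module analysis; a rank that is too small demonstrably attenuates
  within-module correlations because imputed cells are projected onto too
  few axes.
* the random-forest stage uses per-protein, per-donor median imputation
  (forests need complete inputs; the median is neutral within donor).
* moderated linear models use no imputation at all — each protein is fit on
  its observed samples (listwise deletion per feature).

# Co-expression modules

Protein similarity is the **biweight midcorrelation**: with `med` and the
(unscaled) median absolute deviation `mad` of each vector,
`u_i = (x_i - med) / (9 mad)`, weights `w_i = (1 - u_i^2)^2` inside
`|u_i| < 1` and zero outside, and the correlation of the weighted centered
vectors. It behaves like Pearson on clean data (empirically within a few
hundredths on Gaussian draws) while discounting outlying islets. Vectors
with zero `mad` fall back to the Pearson standardization.

The signed adjacency raises correlations to a **soft power** of 12
(`a = sign(r) |r|^beta`), and similarity is the **signed-Nowick topological
overlap**

```
T[i, j] = (sum_u a[i, u] a[u, j] + a[i, j]) / (D[i, j] + 1 - |a[i, j]|)
```

with connectivity `k_i = sum |a[i, u]|`. The default variant
(`signed_nowick_2`) uses the modified denominator `D = (k_i + k_j) / 2`; the
base form (`D = min(k_i, k_j)`) is available via `tom_type =
"signed_nowick"`. The exact algebra of the "2" variant is documented only in
its reference implementation, which we could not consult; we implement the
mean-denominator modification and verify both variants against brute-force
per-pair evaluation on small graphs. Both keep `|T| <= 1`, preserve the
numerator's sign, and the downstream distance is `1 - T`. Results in our
tests are insensitive to the choice.

Clustering is agglomerative with **Ward's D** linkage (on the distance
itself; a flag switches to Ward's D2) and the dendrogram is cut to a fixed
number of clusters: K = 75 for the fine-grained cross-donor run, K = 20 per
donor by default. Dynamic-height cutting is deliberately not implemented —
fixed cuts keep module granularity identical across runs and donors, which
the downstream module bookkeeping relies on. A scale-free-fit power scan
(`pick_soft_power()`, target R^2 0.8, fallback 12) is available for
per-donor runs.

Each module is summarized by its **eigenprotein** — the first right-singular
vector of the standardized member submatrix, sign-fixed so its mean
correlation with members is positive — and tested against phenotypes with
the moderated statistics below, sharing variance information across modules.
Module annotation is a hypergeometric upper-tail over-representation test
against a flat gene-set collection (GMT), Benjamini-Hochberg adjusted per
module, sets tested only when at least 5 members are measured.

# The statistical kernel

Per-protein models are ordinary least squares on `[intercept, covariate]`
over the protein's observed samples. The ensemble of residual variances is
shrunk by fitting a scaled-F distribution via moment matching on log
variances (digamma/trigamma equations), giving a prior variance `s0^2` and
prior df `d0` (`Inf` — carried as a genuine infinity, not a large number —
when the observed spread of log-variances does not exceed its expected
sampling noise). The moderated statistic is

```
s2_post = (d0 s0^2 + d s^2) / (d0 + d),   t = b / (u sqrt(s2_post))
```

on `d0 + d` degrees of freedom; `d0 = 0` recovers the ordinary t-test and
`d0 = Inf` the normal score. Moderated t-statistics are mapped to
standard-normal equivalents tail-symmetrically in log space
(`z = sign(t) qnorm(pt(|t|, df, lower = FALSE, log = TRUE), ...)`), which
survives |t| deep into the tails.

**CAMERA-PR** compares a gene set's z-scores against all others with a
pooled two-sample t whose set-mean variance is inflated by
`VIF = 1 + (m - 1) rho` with the inter-gene correlation fixed at rho = 0.01
— never estimated from data. At rho = 0 the statistic is exactly the pooled
two-sample t-test, the identity our tests assert to 1e-12. Set-level
z-scores use the same t-to-z transform as the gene level (the choice is ours
to make; we use one transform for both for coherence). P-values are adjusted
per donor, reflecting that each donor is a separate family of tests.

# Signature selection

**Candidate pool.** Members of every per-donor module whose ORA flags the
configured immune gene sets at adjusted p < 0.05 are unioned across the
stage-1 donors, filtered to < 50% missing within every donor, and the pooled
matrix is batch-corrected at the donor level.

**Nested cross-validated RFE.** Ten stratified outer folds; within each
outer-training set, the loop alternates (i) random-search tuning of `mtry`
and `min.node.size` (10 draws, log-uniform, scored by stratified 5-fold
inner-CV AUROC), (ii) fitting a 1000-tree probability forest with
permutation importance, and (iii) dropping the lowest `floor(0.10 n)`
features (at least one), until 60 features remain (the last drop trims to
exactly 60). The final tuned forest's importance ordering is the fold's
ranked list, and its AUROC on the held-out outer fold is recorded — reported
for transparency, but not used for selection. Labels are the donor's disease
status applied to each islet; a config override allows CD3 instead.

**Robust rank aggregation.** Each feature's normalized ranks across the 10
lists (rank / pool size; features missing from a list get worst rank 1) are
compared against the uniform order-statistic null:
`rho = min_k P(Beta(k, n - k + 1) <= r_(k))`, Bonferroni-corrected over k.
The 40 lowest-scoring proteins form the IIRS. Ties break by mean normalized
rank, then symbol — selection is fully deterministic under a fixed seed.

**Centroids.** A panel's per-islet value is the sample-wise median of its
member abundances over observed values; islets with no observed member get a
missing centroid and are dropped from downstream fits with a note. The BCP
is the 41 proteins with the highest mean Pearson correlation against INS and
ENTPD3 (pairwise-complete; the anchors score 1 against themselves and are
eligible). For cross-donor displays, `baseline_center()` centers each
protein on the median over ND islets pooled with the lower-half (by
centroid) stage-1 islets — an interpretive anchoring choice, flagged as
such, resting on the assumption that un-inflamed stage-1 islets are
comparable to controls.

**Islet-level calls.** An islet is *low-insulin* when its donor-median-
centered log2 INS value is strictly below -2 (4-fold below the median; -2.0
exactly is not flagged). Pseudo-temporal ordering sorts islets by IIRS
centroid and labels empirical tertiles low / moderate / high; ties resolve
stably by sample ID (with a rank-based fallback when ties collapse the
quantile breaks). Marker-based composition estimates are normalized sums of
linear-scale marker intensities per cell type.

# The synthetic study

The generator emulates the study design rather than the instrument: three
stage-1 donors with 100 islet sections each and three ND controls with 50,
three tissue blocks per donor, and 1000 protein groups. Its defaults are the
study conditions, chosen once:

* **Latents.** Stage-1 islets draw an immune pseudo-time `u ~ U(0, 1)`; ND
  islets have `u = 0` exactly (an optional jitter exists for robustness
  experiments). The beta-cell latent `v` is drawn independently of `u`
  (depressed to `U(0, 0.3)` in 25% of stage-1 and 8% of ND islets per donor,
  otherwise `U(0.5, 1)`); independence mirrors the observed weak coupling
  between inflammation and beta-cell state, and the ND fraction is a free
  parameter because no reference value exists. The binary CD3 call follows
  `P(CD3+) = plogis(-2 + 4u)` — a noisy, saturating readout of the latent.
* **Structure.** One immune module (100 proteins, shifted by
  `2 * lambda * u` log2 units), one beta-cell module (80 proteins including
  INS and ENTPD3, shifted by `2 * lambda * v`; GCG deliberately sits in an
  alpha-cell-like background module), 18 background modules driven by
  N(0, 1) factors, and 30% unstructured proteins — real proteomes are not
  wholly co-regulated. Baselines are N(22, 4.5^2) log2 units (the label-free
  dynamic range) and loadings U(1.5, 2.5), which puts within-module
  correlations in the 0.85-0.95 band reported for tight fine-grained
  clusters; modules with only moderate internal correlation are invisible at
  soft power 12 (0.7^12 is about 0.01), so this tightness is a requirement
  of the network settings, not a convenience.
* **Nuisance.** Mean-zero per-feature block offsets (SD 0.5), measurement
  noise SD 0.5, logistic low-intensity censoring (midpoint 18, slope 1) plus
  2% MCAR, and six reference pools that are noisy replicates (SD 0.1) of the
  grand mean profile — replicates correlate above 0.96, islet pairs around
  0.8-0.9, as quality control on real data shows.
* **Reproducibility.** One RNG stream per dataset, split hierarchically per
  donor; a seed is mandatory.

What the generator does **not** emulate: peptide-level quantification, raw
spectra, retention-time structure, iBAQ absolute scaling, nonlinear
intensity distortions, or correlated MNAR between co-eluting peptides.
Passing recovery tests on this generator therefore demonstrates the
pipeline's correctness and its statistical behavior under the modeled
conditions — not performance on any particular real cohort.

# Problem sizes and numerical choices

The test suite runs the complete procedure — every tuning and
cross-validation setting at its default — on cohorts with 30/15 islets per
stage-1/ND donor (three seeds for the recovery checks), which keeps a full
nested-CV selection at about half a minute per fold on one core; the
acceptance script uses the same 30/15 cohort, and the bundled analysis
scripts the full 100/50 design (an end-to-end run at that size is a matter
of hours, not minutes, on one core — the candidate pool, and with it the
number of elimination rounds, grows with cohort size).
Convergence tolerances: median polish 0.01 relative (20-sweep cap), batch
correction EB updates 1e-4, SVD imputation 1e-5 relative Frobenius (100
iterations), eigenprotein SVDs exact. Correlations are clamped to [-1, 1]
before powering; TOM matrices are symmetrized against floating-point drift.
Tie-breaks are deterministic everywhere (score, then mean rank, then
symbol; sample ID for islet orderings).

# A note on normalization-induced coupling

Although the synthetic immune and beta-cell latents are drawn independently,
the recovered IIRS and BCP centroids correlate mildly negatively (around
-0.25 on the default study). The mechanism is compositional: immune
activation raises ~10% of the proteome in an islet, median polish estimates
that islet's column effect partly from those proteins and subtracts it from
*everything*, so strongly inflamed islets are pushed down globally —
including their apparent beta-cell profile. On the raw (un-normalized) data
the two centroids are uncorrelated, which localizes the effect to the
normalization step. This is a generic artifact of global normalization under
one-sided regulation, worth keeping in mind when interpreting weak
cross-signature correlations on real data too.

# Known limitations

* The "2" TOM variant is our transcription of a modified denominator, not a
  line-by-line port of the reference implementation (see above); both
  variants are exposed and give equivalent results on the synthetic study.
* The moderated-model kernel supports intercept + one covariate and
  two-group contrasts — exactly what the analysis needs, nothing more.
* ORA consumes flat gene-set collections; no ontology graph traversal.
* The empirical-Bayes variance squeeze is the plain moment-matching form;
  no robust (outlier-variance) variant.
* Per-donor module discovery reuses the fine-grained network settings by
  default; whether the original per-donor runs used signed or unsigned
  networks is unrecorded, so both are configurable.
* CAMERA-PR's inter-gene correlation is a fixed constant by design; the
  pipeline never estimates it.
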