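# isletsig

Analysis pipeline for **single-islet proteomics of presymptomatic (stage 1)
type 1 diabetes**: from a label-free protein-group abundance matrix of
individual laser-dissected islet sections to co-expression modules, two
machine-learned protein signatures, and pathway-level associations.

Pancreas specimens are snapshots, but islets within one donor span a range
of molecular states — from quiescent to inflamed, from insulin-rich to
insulin-depleted. Ordering islets by a molecular score turns that
*intra-donor heterogeneity* into a pseudo-temporal axis of disease
progression. `isletsig` implements the full analysis:

1. **Preprocessing** — log2 transform and feature centering; per-donor
   sample normalization by Tukey median polish (fit on complete cases,
   applied to all proteins); per-donor empirical-Bayes batch correction
   across tissue blocks (a missing-value-tolerant parametric ComBat with an
   explicit fit/apply split); cross-donor assembly with a strict >50%
   per-donor completeness filter; iterative SVD imputation within disease
   groups for the steps that need complete data.
2. **Co-expression modules** — biweight midcorrelation networks, signed
   soft-threshold adjacency (power 12), signed-Nowick topological overlap
   (base and "2" denominators), Ward's D clustering cut to a fixed number of
   clusters (75 in the fine-grained cross-donor run), module eigenproteins,
   and moderated eigenprotein-phenotype tests (binary CD3, insulin
   intensity) plus hypergeometric over-representation per module.
3. **Signatures** — the 40-protein **Islet Immune Response Signature
   (IIRS)**: candidates from immune-enriched modules are ranked by nested
   cross-validated random-forest recursive feature elimination (10 outer
   folds, 5-fold inner tuning with 10 random-search draws, 1000-tree
   forests, permutation importance, 10% drops to a 60-feature target) and
   consolidated by robust rank aggregation (beta order statistics); and the
   41-protein **Beta-Cell Profile (BCP)** ranked by mean correlation with
   INS and ENTPD3. Panel centroids are per-islet medians, giving each islet
   an immune pseudo-time and a beta-cell state.
4. **Differential abundance & enrichment** — per donor, moderated linear
   models (empirical-Bayes variance shrinkage) with the signature centroid
   as sole predictor; moderated t converted to standard-normal scores;
   CAMERA-PR competitive gene-set tests with fixed inter-gene correlation
   0.01; Benjamini-Hochberg adjustment per donor.

At the core of the moderated models is the shrunken variance
`s2_post = (d0*s0^2 + d*s^2)/(d0 + d)` with moderated statistic
`t = b/(u*sqrt(s2_post))` on `d0 + d` df; CAMERA-PR inflates the set-mean
variance by `VIF = 1 + (m-1)*rho`; robust rank aggregation scores each
protein by `min_k P(Beta(k, n-k+1) <= r_(k))`, Bonferroni-corrected over k.

A seeded **synthetic-data generator** (`synth_config()`,
`generate_dataset()`) emulates the study — 3 stage-1 donors x 100 islets,
3 ND donors x 50, a planted immune gradient present only in stage-1 donors,
planted beta-cell loss, tissue-block shifts, intensity-dependent
missingness, replicate reference pools — with full ground truth, so every
stage is testable without the original tissue data.

## Worked example

```r
library(isletsig)

cfg <- pipeline_config(seed = 101,
                       synth = synth_config(islets_per_donor = 30,
                                            islets_per_donor_nd = 15,
                                            seed = 101))
res <- run_pipeline(cfg)

length(res$iirs$members)            # 40   (IIRS panel size)
length(res$bcp$members)             # 41   (BCP panel size)
length(unique(res$fine_clusters))   # 75   (fine-grained clusters)
lengths(res$rfe$ranked_lists)       # 60 60 ... 60  (10 outer folds)

res$recovery$iirs_pseudotime_spearman
#>     S1_01     S1_02     S1_03
#> 0.9577308 0.9474972 0.9608454
res$recovery$iirs_planted_fraction  # 1     (all 40 are planted immune proteins)
res$recovery$bcp_planted_count      # 41    (of 41 BCP members planted)
res$module_recovery$ari             # 0.968 (planted-module recovery)
round(res$iirs_bcp_cor, 3)          # -0.081 (immune and beta-cell axes decouple)
sum(res$low_insulin, na.rm = TRUE)  # 11    (islets >4-fold below donor median INS)
```

The IIRS centroid tracks the hidden immune pseudo-time within every stage-1
donor (Spearman 0.95-0.96 here), the panels recover the planted features,
and the fine-grained clustering reconstructs the planted modules — on a
reduced 30/15-islet cohort that runs in ~4 minutes on one core. The
`analysis/` directory holds numbered driver scripts (`01_simulate.R` ...
`06_enrichment.R`) that run the same stages on the full 100/50 design and
write their tables under `results/`.

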