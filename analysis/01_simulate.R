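#!/usr/bin/env Rscript

# Stage 1 — simulate the single-islet study.
#
# Generates the default synthetic cohort: three stage-1 donors with 100 islet
# sections each, three ND controls with 50 each, a module-structured
# proteome with a latent immune gradient (stage-1 only), beta-cell loss in a
# subset of islets, tissue-block batch shifts, intensity-dependent
# missingness and replicate reference pools. Writes the abundance matrix,
# metadata, ground truth and a toy gene-set collection (one set per planted
# immune module plus random sets, standing in for GO:BP exports) under
# results/data/.

library(isletsig)

# usage: Rscript analysis/01_simulate.R [seed] [islets_stage1] [islets_nd]
# (the optional islet counts allow smaller trial cohorts; defaults 100/50)
args <- suppressWarnings(as.integer(commandArgs(trailingOnly = TRUE)))
seed <- if (!is.na(args[1])) args[1] else 1L
n1 <- if (!is.na(args[2])) args[2] else 100L
n0 <- if (!is.na(args[3])) args[3] else 50L

cfg <- synth_config(islets_per_donor = n1, islets_per_donor_nd = n0,
                    seed = seed)
ds <- generate_dataset(cfg)
write_dataset(ds, "results/data")

sets <- make_toy_goldset(50L, 40L, ds$truth$planted_immune_members,
                         rownames(ds$abundance), seed = seed + 1L)
write_gmt(sets, "results/data/gene_sets.gmt")

meta <- ds$metadata
cat(sprintf("Simulated %d proteins x %d samples (%d islets + %d reference pools)\n",
            nrow(ds$abundance), ncol(ds$abundance),
            sum(meta$is_reference == 0L), sum(meta$is_reference == 1L)))
cat(sprintf("Missing entries: %.1f%%\n", 100 * mean(is.na(ds$abundance))))
cat("Wrote results/data/{abundance,metadata,truth_samples,truth_features}.tsv and gene_sets.gmt\n")
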