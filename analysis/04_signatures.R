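#!/usr/bin/env Rscript

# Stage 4 — signature selection.
#
# Builds the immune candidate pool (members of immune-enriched modules
# across the stage-1 donors, <50% missing per donor, donor-level batch
# correction), ranks candidates by nested cross-validated random-forest
# recursive feature elimination (10 outer folds, 5-fold inner tuning,
# 1000-tree forests, permutation importance, 10% drops to a target of 60),
# consolidates the 10 fold lists by robust rank aggregation and keeps the
# top 40 as the Islet Immune Response Signature (IIRS). The Beta-Cell
# Profile (BCP) is the 41 proteins with the highest mean correlation with
# INS and ENTPD3. Per-sample centroids are sample-wise medians of the panel
# members. This stage carries the heavy compute (~10-15 min single-core at
# the default study size).

library(isletsig)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

asm <- read_abundance("results/abundance_preprocessed.tsv")
attr(asm, "scale_tag") <- "log2_centered"
meta <- read_metadata("results/data/metadata.tsv")
meta_i <- meta[meta$is_reference == 0L, ]
sets <- read_gmt("results/data/gene_sets.gmt")
dir.create("results/signatures", showWarnings = FALSE, recursive = TRUE)

s1 <- unique(meta_i$donor_id[meta_i$group == "stage1"])
labels_by_donor <- list(); ora_by_donor <- list()
for (d in s1) {
  mtab <- read.delim(sprintf("results/modules/%s_modules.tsv", d))
  labels_by_donor[[d]] <- setNames(mtab$module, mtab$feature)
  otab <- read.delim(sprintf("results/modules/%s_ora.tsv", d))
  ora_by_donor[[d]] <- split(otab[, -1], otab$module)
}

pool <- candidate_pool(labels_by_donor, ora_by_donor, asm, meta_i,
                       immune_sets = "PLANTED_IMMUNE_RESPONSE")
cat(sprintf("Candidate pool: %d proteins from immune-enriched modules\n",
            length(pool$members)))

x <- t(impute_donor_median(pool$matrix, meta_i))
labels <- factor(meta_i$group[match(rownames(x), meta_i$sample_id)],
                 levels = c("nd", "stage1"))
rfe <- rf_rfe_outer(x, labels, rf_config(seed = seed))
cat(sprintf("Outer-fold AUROC: %s (mean %.3f)\n",
            paste(round(rfe$outer_auroc, 3), collapse = " "),
            mean(rfe$outer_auroc)))

agg <- rra(rfe$ranked_lists, universe_size = length(pool$members))
iirs <- select_panel(agg, 40L, pool$matrix, name = "IIRS")
bcp <- bcp_select(asm, k = 41L)

write.table(data.frame(rank = seq_along(iirs$members), feature = iirs$members,
                       rra_score = unname(iirs$scores)),
            "results/signatures/iirs_panel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(rank = seq_along(bcp$members), feature = bcp$members,
                       mean_anchor_cor = unname(bcp$scores)),
            "results/signatures/bcp_panel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ord <- pseudo_temporal_order(iirs$centroid[!is.na(iirs$centroid)])
cen <- data.frame(sample_id = names(iirs$centroid),
                  iirs = unname(iirs$centroid),
                  bcp = unname(bcp$centroid[names(iirs$centroid)]),
                  tertile = ord$tertile[match(names(iirs$centroid), ord$sample)])
ins_row <- asm["INS", meta_i$sample_id]
for (d in unique(meta_i$donor_id)) {
  ids <- meta_i$sample_id[meta_i$donor_id == d]
  ins_row[ids] <- ins_row[ids] - median(ins_row[ids], na.rm = TRUE)
}
cen$low_insulin <- low_insulin_flag(ins_row)[cen$sample_id]
write.table(cen, "results/signatures/centroids.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

s1_ids <- meta_i$sample_id[meta_i$group == "stage1"]
cat(sprintf("IIRS-BCP Pearson correlation (stage-1 islets): %.3f\n",
            cor(cen$iirs[cen$sample_id %in% s1_ids],
                cen$bcp[cen$sample_id %in% s1_ids], use = "complete.obs")))
cat(sprintf("Low-insulin islets (strict -2 log2 rule): %d\n",
            sum(cen$low_insulin, na.rm = TRUE)))
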