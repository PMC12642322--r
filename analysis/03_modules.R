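#!/usr/bin/env Rscript

# Stage 3 — per-donor co-expression modules.
#
# For each donor: SVD-impute the preprocessed matrix, build a biweight
# midcorrelation network at soft power 12, take the signed-Nowick-2
# topological overlap, cut the Ward dendrogram into K = 20 modules, and test
# each module eigenprotein against the CD3 call (group contrast) and the
# proteomic insulin intensity (slope) with moderated statistics. Each module
# is annotated by hypergeometric over-representation against the gene-set
# collection. Writes module assignments, eigenproteins, association tables
# and ORA tables under results/modules/.

library(isletsig)

asm <- read_abundance("results/abundance_preprocessed.tsv")
attr(asm, "scale_tag") <- "log2_centered"
meta <- read_metadata("results/data/metadata.tsv")
meta_i <- meta[meta$is_reference == 0L, ]
sets <- read_gmt("results/data/gene_sets.gmt")
dir.create("results/modules", showWarnings = FALSE, recursive = TRUE)

for (d in unique(meta_i$donor_id)) {
  ids <- meta_i$sample_id[meta_i$donor_id == d]
  md <- asm[, ids]
  attr(md, "scale_tag") <- "log2_centered"
  keep <- rowSums(!is.na(md)) >= 2L & apply(md, 1, sd, na.rm = TRUE) > 0
  md <- md[keep, ]
  attr(md, "scale_tag") <- "log2_centered"
  md <- svd_impute(md, n_components = min(20L, min(dim(md)) - 1L))
  tm <- tom(adjacency(cor_matrix(md), beta = 12), variant = "signed_nowick_2")
  cl <- cluster_fixed_k(1 - tm, K = 20L)

  assign_tab <- data.frame(feature = names(cl$labels),
                           module = paste0("M", cl$labels))
  assign_tab$module_size <- ave(seq_len(nrow(assign_tab)), assign_tab$module,
                                FUN = length)
  write.table(assign_tab, sprintf("results/modules/%s_modules.tsv", d),
              sep = "\t", quote = FALSE, row.names = FALSE)

  mods <- sort(unique(cl$labels))
  E <- t(vapply(mods, function(k)
    module_eigenprotein(md, names(cl$labels)[cl$labels == k])$eigenprotein,
    numeric(ncol(md))))
  rownames(E) <- paste0("M", mods)
  write.table(data.frame(module = rownames(E), E, check.names = FALSE),
              sprintf("results/modules/%s_eigenproteins.tsv", d),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cd3 <- meta_i$cd3[match(ids, meta_i$sample_id)]
  ins <- if ("INS" %in% rownames(md)) md["INS", ] else rep(NA_real_, ncol(md))
  assoc <- module_phenotype_assoc(E, list(cd3 = as.numeric(cd3),
                                          ins_intensity = as.numeric(ins)))
  write.table(assoc, sprintf("results/modules/%s_phenotype_assoc.tsv", d),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ora_all <- do.call(rbind, lapply(mods, function(k) {
    tab <- ora(names(cl$labels)[cl$labels == k], rownames(md), sets)
    if (nrow(tab)) cbind(module = paste0("M", k), tab) else NULL
  }))
  write.table(ora_all, sprintf("results/modules/%s_ora.tsv", d),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sig <- assoc[!assoc$skipped & !is.na(assoc$adj_p) & assoc$adj_p < 0.05, ]
  cat(sprintf("%s: %d modules, %d significant module-phenotype associations\n",
              d, length(mods), nrow(sig)))
}
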