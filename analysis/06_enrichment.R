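#!/usr/bin/env Rscript

# Stage 6 — correlation-adjusted competitive gene-set testing (CAMERA-PR).
#
# For each donor and signature, the per-protein standard-normal scores from
# stage 5 are tested per gene set against the rest of the proteome with the
# inter-gene correlation fixed at 0.01 (sets with fewer than 5 measured
# members are skipped); p-values are adjusted per donor. Writes one table
# per donor plus a set x donor bubble-heatmap input (z and adjusted p)
# under results/enrichment/.

library(isletsig)

meta <- read_metadata("results/data/metadata.tsv")
meta_i <- meta[meta$is_reference == 0L, ]
sets <- read_gmt("results/data/gene_sets.gmt")
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

for (sig in c("IIRS", "BCP")) {
  bubbles_z <- list(); bubbles_p <- list()
  for (d in unique(meta_i$donor_id)) {
    tab <- read.delim(sprintf("results/differential/%s_%s.tsv", sig, d))
    z <- setNames(tab$z, tab$feature)
    z <- z[!is.na(z)]
    cam <- camera_pr(z, sets, inter_gene_cor = 0.01, min_set_size = 5L)
    write.table(cam, sprintf("results/enrichment/%s_%s_camera.tsv", sig, d),
                sep = "\t", quote = FALSE, row.names = FALSE)
    bubbles_z[[d]] <- setNames(cam$z, cam$set)
    bubbles_p[[d]] <- setNames(cam$adj_p, cam$set)
    cat(sprintf("%s ~ %s: %d/%d sets at adjusted p < 0.05\n", d, sig,
                sum(cam$adj_p < 0.05), nrow(cam)))
  }
  all_sets <- sort(unique(unlist(lapply(bubbles_z, names))))
  bub <- data.frame(set = all_sets)
  for (d in names(bubbles_z)) {
    bub[[paste0("z_", d)]] <- unname(bubbles_z[[d]][all_sets])
    bub[[paste0("adj_p_", d)]] <- unname(bubbles_p[[d]][all_sets])
  }
  write.table(bub, sprintf("results/enrichment/%s_bubble_table.tsv", sig),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
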