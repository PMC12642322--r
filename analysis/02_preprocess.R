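#!/usr/bin/env Rscript

# Stage 2 — preprocessing.
#
# Replicate-pool QC, then per donor: log2 transform + feature centering,
# median-polish sample normalization fit on complete cases, and
# empirical-Bayes batch correction across tissue blocks. Donors are then
# combined and features filtered to >50% completeness within every donor.
# Writes the analysis-ready matrix and a QC/count report under results/.

library(isletsig)

m <- read_abundance("results/data/abundance.tsv")
meta <- read_metadata("results/data/metadata.tsv")

qc <- replicate_qc(m, meta)
print(qc$summary)
write.table(qc$summary, "results/qc_replicates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

meta_i <- meta[meta$is_reference == 0L, ]
per <- list()
for (d in unique(meta_i$donor_id)) {
  ids <- meta_i$sample_id[meta_i$donor_id == d]
  md <- m[, ids]
  attr(md, "scale_tag") <- "log2"
  md <- log2_and_center(md)
  md <- median_polish_normalize(md)
  per[[d]] <- combat_correct(md, meta_i$block[match(ids, meta_i$sample_id)])
}
asm <- completeness_filter(assemble_cross_donor(per), meta_i, 0.5)

cat(sprintf("Retained %d of %d features after the per-donor >50%% completeness rule\n",
            nrow(asm), nrow(m)))
write_abundance(asm, "results/abundance_preprocessed.tsv")
report <- data.frame(stage = c("input", "filtered"),
                     n_features = c(nrow(m), nrow(asm)),
                     n_samples = c(ncol(m), ncol(asm)))
write.table(report, "results/preprocess_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
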