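#' Pipeline configuration
#'
#' Bundles every stage's settings with a single master seed. The default
#' analysis runs per-donor median-polish normalization and
#' block-level batch correction, >50% per-donor completeness, biweight
#' midcorrelation networks at soft power 12 with signed-Nowick-2 topological
#' overlap and Ward's D clustering (75 fine-grained clusters), a 40-protein
#' immune signature from nested-CV random-forest RFE consolidated by robust
#' rank aggregation, a 41-protein beta-cell profile ranked by INS/ENTPD3
#' correlation, moderated linear models against the signature centroids, and
#' CAMERA-PR with fixed inter-gene correlation 0.01.
#'
#' @param seed master seed; every stage's randomness derives from it.
#' @param synth a [synth_config()]; defaults to the standard synthetic study
#'   seeded from `seed`.
#' @param gene_sets gene-set collection for ORA/CAMERA-PR; `NULL` builds a
#'   toy collection around the planted immune module.
#' @param min_completeness per-donor completeness threshold (strict `>`).
#' @param polish_tol,polish_max_iter median-polish convergence settings.
#' @param svd_components,svd_tol,svd_max_iter SVD-imputation settings.
#' @param power,tom_type,bicor_c,k_fine,k_donor network settings (soft
#'   power, TOM variant, bicor tuning constant, fine-grained and per-donor
#'   cluster counts).
#' @param donor_power_scan pick the per-donor soft power by scale-free fit
#'   (fallback `power`) instead of using `power` directly.
#' @param rf an [rf_config()]; `NULL` derives one from `seed`.
#' @param inter_gene_cor,min_set_size CAMERA-PR settings.
#' @param iirs_size,bcp_size panel sizes.
#' @param immune_sets gene-set names flagging immune enrichment.
#' @param alpha_enrich adjusted-p cutoff for calling a module
#'   immune-enriched.
#' @param n_gene_sets,gene_set_size toy gene-set collection shape (when
#'   `gene_sets` is `NULL`).
#' @param do_signatures,do_fine,do_differential stage toggles.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            synth = NULL,
                            gene_sets = NULL,
                            min_completeness = 0.5,
                            polish_tol = 0.01, polish_max_iter = 20L,
                            svd_components = 20L, svd_tol = 1e-5, svd_max_iter = 100L,
                            power = 12, tom_type = "signed_nowick_2",
                            bicor_c = 9, k_fine = 75L, k_donor = 20L,
                            donor_power_scan = FALSE,
                            rf = NULL,
                            inter_gene_cor = 0.01, min_set_size = 5L,
                            iirs_size = 40L, bcp_size = 41L,
                            immune_sets = "PLANTED_IMMUNE_RESPONSE",
                            alpha_enrich = 0.05,
                            n_gene_sets = 50L, gene_set_size = 40L,
                            do_signatures = TRUE, do_fine = TRUE,
                            do_differential = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  seeds <- .child_seeds(as.integer(seed), 4L)
  cfg <- as.list(environment())
  cfg$seeds <- NULL
  cfg$synth <- synth %||% synth_config(seed = seeds[1L])
  cfg$rf <- rf %||% rf_config(seed = seeds[2L])
  cfg$goldset_seed <- seeds[3L]
  cfg$stage_seed <- seeds[4L]
  structure(cfg, class = "pipeline_config")
}

#' Run the full single-islet analysis pipeline
#'
#' Orchestrates: data generation (or intake) -> replicate QC -> per-donor
#' preprocessing (log2/center, median polish, block-level batch correction)
#' -> cross-donor assembly and completeness filter -> per-donor module
#' discovery with eigenprotein-phenotype tests and ORA -> immune candidate
#' pool -> RF-RFE + RRA -> IIRS panel -> BCP panel -> fine-grained
#' clustering -> moderated models against both centroids -> CAMERA-PR per
#' donor. Deterministic under a fixed config seed.
#'
#' @param cfg a [pipeline_config()].
#' @param dataset optionally, a pre-built `synthetic_dataset` (or a list
#'   with `abundance` and `metadata`) to analyze instead of generating one.
#' @return list of class `pipeline_result`; see the elements written by each
#'   stage, plus `manifest`.
#' @export
run_pipeline <- function(cfg, dataset = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t_start <- Sys.time()
  manifest <- list()
  note <- function(stage, features, samples, extra = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, n_features = features, n_samples = samples,
      elapsed_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 1),
      note = extra, stringsAsFactors = FALSE)
  }

  ds <- dataset %||% generate_dataset(cfg$synth)
  raw <- ds$abundance
  meta <- .meta_align(ds$metadata, raw)
  truth <- ds$truth
  note("data", nrow(raw), ncol(raw))

  qc <- replicate_qc(raw, meta)
  comp <- .marker_composition(raw, meta)

  islet_ids <- meta$sample_id[meta$is_reference == 0L]
  meta_i <- meta[meta$is_reference == 0L, , drop = FALSE]
  donors <- unique(meta_i$donor_id)

  per_donor <- list()
  for (d in donors) {
    ids <- meta_i$sample_id[meta_i$donor_id == d]
    md <- raw[, ids, drop = FALSE]
    attr(md, "scale_tag") <- scale_tag(raw)
    md <- log2_and_center(md)
    md <- median_polish_normalize(md, tol = cfg$polish_tol,
                                  max_iter = cfg$polish_max_iter)
    blocks <- meta_i$block[match(ids, meta_i$sample_id)]
    md <- combat_correct(md, blocks)
    per_donor[[d]] <- md
  }
  assembled <- assemble_cross_donor(per_donor)
  assembled <- completeness_filter(assembled, meta_i, cfg$min_completeness)
  note("preprocess", nrow(assembled), ncol(assembled),
       paste0(attr(assembled, "n_removed"), " features removed"))

  gene_sets <- cfg$gene_sets
  if (is.null(gene_sets)) {
    if (is.null(truth)) stop("no gene sets supplied and no planted truth to build them from")
    gene_sets <- make_toy_goldset(cfg$n_gene_sets, cfg$gene_set_size,
                                  intersect(truth$planted_immune_members,
                                            rownames(assembled)),
                                  rownames(assembled), seed = cfg$goldset_seed)
  }

  # per-donor module discovery on the assembled feature space
  donor_modules <- list(); donor_assoc <- list(); donor_ora <- list()
  for (d in donors) {
    ids <- meta_i$sample_id[meta_i$donor_id == d]
    md <- assembled[, ids, drop = FALSE]
    attr(md, "scale_tag") <- scale_tag(assembled)
    keep <- rowSums(!is.na(md)) >= 2L & apply(md, 1L, stats::sd, na.rm = TRUE) > 0
    md <- md[keep, , drop = FALSE]
    attr(md, "scale_tag") <- scale_tag(assembled)
    md <- svd_impute(md, n_components = min(cfg$svd_components, min(dim(md)) - 1L),
                     max_iter = cfg$svd_max_iter, tol = cfg$svd_tol)
    corr <- cor_matrix(md, method = "bicor", c = cfg$bicor_c)
    pw <- if (cfg$donor_power_scan) pick_soft_power(corr, fallback = cfg$power)$power
          else cfg$power
    tm <- tom(adjacency(corr, pw), variant = cfg$tom_type)
    cl <- cluster_fixed_k(1 - tm, K = min(cfg$k_donor, nrow(md)))
    mods <- sort(unique(cl$labels))
    E <- t(vapply(mods, function(k)
      module_eigenprotein(md, names(cl$labels)[cl$labels == k])$eigenprotein,
      numeric(ncol(md))))
    rownames(E) <- paste0("M", mods)
    cd3 <- meta_i$cd3[match(ids, meta_i$sample_id)]
    ins <- if ("INS" %in% rownames(md)) md["INS", ] else rep(NA_real_, ncol(md))
    donor_assoc[[d]] <- module_phenotype_assoc(
      E, list(cd3 = as.numeric(cd3), ins_intensity = as.numeric(ins)))
    donor_ora[[d]] <- lapply(stats::setNames(mods, paste0("M", mods)), function(k)
      ora(names(cl$labels)[cl$labels == k], rownames(md), gene_sets,
          min_overlap = cfg$min_set_size))
    donor_modules[[d]] <- stats::setNames(paste0("M", cl$labels), names(cl$labels))
  }
  note("modules_per_donor", nrow(assembled), length(donors))

  result <- list(config = cfg, metadata = meta, qc = qc, composition = comp,
                 abundance = assembled, per_donor_modules = donor_modules,
                 per_donor_assoc = donor_assoc, per_donor_ora = donor_ora,
                 gene_sets = gene_sets, truth = truth)

  if (cfg$do_signatures) {
    s1 <- donors[donors %in% meta_i$donor_id[meta_i$group == "stage1"]]
    pool <- candidate_pool(donor_modules[s1], donor_ora[s1], assembled, meta_i,
                           immune_sets = cfg$immune_sets,
                           alpha = cfg$alpha_enrich,
                           max_missing = 1 - cfg$min_completeness)
    x <- t(impute_donor_median(pool$matrix, meta_i))
    labels <- factor(meta_i$group[match(rownames(x), meta_i$sample_id)],
                     levels = c("nd", "stage1"))
    rfe <- rf_rfe_outer(x, labels, cfg$rf)
    agg <- rra(rfe$ranked_lists, universe_size = length(pool$members))
    iirs <- select_panel(agg, cfg$iirs_size, pool$matrix, name = "IIRS")
    note("iirs", length(pool$members), nrow(x),
         paste0("mean outer AUROC ", round(mean(rfe$outer_auroc), 3)))

    bcp <- bcp_select(assembled, k = cfg$bcp_size)
    note("bcp", nrow(assembled), ncol(assembled))

    result$candidate_pool <- pool
    result$rfe <- rfe
    result$rra <- agg
    result$iirs <- iirs
    result$bcp <- bcp
    ok <- !is.na(iirs$centroid)
    result$pseudo_order <- pseudo_temporal_order(iirs$centroid[ok])
    s1_ids <- meta_i$sample_id[meta_i$group == "stage1"]
    s1_ids <- intersect(s1_ids, names(iirs$centroid)[ok])
    s1_ids <- intersect(s1_ids, names(bcp$centroid)[!is.na(bcp$centroid)])
    result$iirs_bcp_cor <- stats::cor(iirs$centroid[s1_ids], bcp$centroid[s1_ids])
  }

  ins_centered <- .donor_median_center_row(assembled, meta_i, "INS")
  result$low_insulin <- low_insulin_flag(ins_centered)

  if (cfg$do_fine) {
    groups <- split(meta_i$sample_id, meta_i$group)
    imputed <- lapply(groups, function(ids) {
      sub <- assembled[, ids, drop = FALSE]
      attr(sub, "scale_tag") <- scale_tag(assembled)
      svd_impute(sub, n_components = min(cfg$svd_components, min(dim(sub)) - 1L),
                 max_iter = cfg$svd_max_iter, tol = cfg$svd_tol)
    })
    fine_m <- do.call(cbind, imputed)[, colnames(assembled), drop = FALSE]
    attr(fine_m, "scale_tag") <- scale_tag(assembled)
    corr <- cor_matrix(fine_m, method = "bicor", c = cfg$bicor_c)
    tm <- tom(adjacency(corr, cfg$power), variant = cfg$tom_type)
    cl <- cluster_fixed_k(1 - tm, K = cfg$k_fine)
    result$fine_clusters <- cl$labels
    result$fine_dendrogram <- cl$dendrogram
    note("fine_clusters", nrow(fine_m), ncol(fine_m),
         paste0(length(unique(cl$labels)), " clusters"))
    if (!is.null(truth)) {
      tru <- truth$module[names(cl$labels)]
      planted <- tru != "none"
      # the unstructured pool forms a cluster of its own, so the recovery
      # cut allows one extra cluster beyond the planted modules
      k_true <- length(unique(tru[planted])) + as.integer(any(!planted))
      rec <- stats::cutree(cl$dendrogram, k = k_true)
      result$module_recovery <- list(
        k_true = k_true,
        ari = .adjusted_rand(rec[planted], tru[planted]))
    }
  }

  if (cfg$do_differential && cfg$do_signatures) {
    result$differential <- list(
      IIRS = .differential_vs_centroid(assembled, meta_i, result$iirs$centroid,
                                       gene_sets, cfg),
      BCP = .differential_vs_centroid(assembled, meta_i, result$bcp$centroid,
                                      gene_sets, cfg))
    result$camera_bubble <- .bubble_table(result$differential$IIRS)
    note("differential", nrow(assembled), length(donors))
  }

  if (!is.null(truth) && cfg$do_signatures) {
    result$recovery <- .recovery_stats(result, meta_i, truth)
  }

  result$manifest <- do.call(rbind, manifest)
  class(result) <- "pipeline_result"
  result
}

# per-donor moderated models against a signature centroid + CAMERA-PR
.differential_vs_centroid <- function(m, meta, centroid, gene_sets, cfg) {
  out <- list()
  for (d in unique(meta$donor_id)) {
    ids <- meta$sample_id[meta$donor_id == d]
    ids <- ids[!is.na(centroid[ids])]
    md <- m[, ids, drop = FALSE]
    attr(md, "scale_tag") <- scale_tag(m)
    fit <- fit_linear_models(md, centroid[ids])
    sq <- squeeze_variances(fit$s2, fit$df)
    mt <- moderated_t(fit, s02 = sq$s02, d0 = sq$d0)
    z <- t_to_z(mt$t, mt$df)
    tab <- data.frame(feature = mt$feature, logFC = mt$b, t = mt$t, z = z,
                      p = mt$p, adj_p = bh_adjust(mt$p), stringsAsFactors = FALSE)
    zv <- stats::setNames(z, mt$feature)
    zv <- zv[!is.na(zv)]
    camera <- camera_pr(zv, gene_sets, inter_gene_cor = cfg$inter_gene_cor,
                        min_set_size = cfg$min_set_size)
    out[[d]] <- list(table = tab, camera = camera,
                     prior = c(s02 = sq$s02, d0 = sq$d0))
  }
  out
}

# set x donor matrix of CAMERA-PR z and adjusted p (bubble-heatmap input)
.bubble_table <- function(diff_list) {
  sets <- unique(unlist(lapply(diff_list, function(x) x$camera$set)))
  if (!length(sets)) return(NULL)
  z <- adj <- matrix(NA_real_, length(sets), length(diff_list),
                     dimnames = list(sets, names(diff_list)))
  for (d in names(diff_list)) {
    cam <- diff_list[[d]]$camera
    z[cam$set, d] <- cam$z
    adj[cam$set, d] <- cam$adj_p
  }
  list(z = z, adj_p = adj)
}

.donor_median_center_row <- function(m, meta, feature) {
  if (!feature %in% rownames(m)) stop("feature '", feature, "' absent from matrix")
  row <- m[feature, meta$sample_id]
  for (d in unique(meta$donor_id)) {
    ids <- meta$sample_id[meta$donor_id == d]
    row[ids] <- row[ids] - stats::median(row[ids], na.rm = TRUE)
  }
  row
}

# iBAQ-style composition on the synthetic marker trio (INS/ENTPD3 beta,
# GCG alpha) where present; NULL otherwise
.marker_composition <- function(m, meta) {
  beta <- intersect(c("INS", "ENTPD3"), rownames(m))
  alpha <- intersect("GCG", rownames(m))
  if (!length(beta) || !length(alpha)) return(NULL)
  ids <- meta$sample_id[meta$is_reference == 0L]
  lin <- function(f) rowMeans(2^m[f, ids, drop = FALSE], na.rm = TRUE)
  composition_estimate(list(beta = unlist(lapply(beta, function(f) lin(f))),
                            alpha = unlist(lapply(alpha, function(f) lin(f)))))
}

# Adjusted Rand index between two labelings.
.adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

# ground-truth recovery statistics of a completed run
.recovery_stats <- function(result, meta, truth) {
  iirs <- result$iirs
  s1 <- unique(meta$donor_id[meta$group == "stage1"])
  rho <- vapply(s1, function(d) {
    ids <- meta$sample_id[meta$donor_id == d]
    ids <- ids[!is.na(iirs$centroid[ids])]
    stats::cor(iirs$centroid[ids], truth$pseudo_time[ids], method = "spearman")
  }, 0)
  list(
    iirs_pseudotime_spearman = rho,
    iirs_planted_fraction = mean(iirs$members %in% truth$planted_immune_members),
    bcp_planted_count = sum(result$bcp$members %in% truth$planted_bcell_members),
    bcp_size = length(result$bcp$members))
}
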