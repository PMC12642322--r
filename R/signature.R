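#' Random-forest selection configuration
#'
#' Settings of the nested cross-validated recursive feature elimination used
#' to select the islet immune response signature: 1000-tree forests,
#' permutation importance, random-search tuning of `mtry` and
#' `min.node.size` (10 evaluations scored by inner 5-fold CV AUROC), 10
#' outer folds, dropping the lowest 10% of importances per iteration down to
#' a target of 60 features.
#'
#' @param n_trees trees per forest.
#' @param tune_evals random-search evaluations per elimination step.
#' @param inner_folds,outer_folds stratified CV folds.
#' @param drop_fraction fraction of features removed per elimination step
#'   (floor, at least 1).
#' @param rfe_target terminal feature count per fold.
#' @param mtry_range range of `mtry` sampled log-uniformly; `NULL` derives
#'   `[ceiling(sqrt(p))/2, p/2]` from the current feature count.
#' @param min_node_range range of `min.node.size` sampled log-uniformly.
#' @param seed integer seed (required).
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 1000L, tune_evals = 10L, inner_folds = 5L,
                      outer_folds = 10L, drop_fraction = 0.10,
                      rfe_target = 60L, mtry_range = NULL,
                      min_node_range = c(1L, 20L), seed = NULL) {
  if (is.null(seed)) stop("rf_config: a seed is required")
  stopifnot(rfe_target >= 1L, drop_fraction > 0, drop_fraction < 1,
            inner_folds >= 2L, outer_folds >= 2L, n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), tune_evals = as.integer(tune_evals),
                 inner_folds = as.integer(inner_folds),
                 outer_folds = as.integer(outer_folds),
                 drop_fraction = drop_fraction, rfe_target = as.integer(rfe_target),
                 mtry_range = mtry_range, min_node_range = as.integer(min_node_range),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Feature-count sequence of recursive elimination
#'
#' Starting from `start` features, each step removes
#' `max(1, floor(fraction * n))` until the count is at or below `target`;
#' the last step is trimmed to exactly `target`.
#'
#' @param start starting feature count.
#' @param fraction drop fraction per step.
#' @param target terminal count.
#' @return integer vector of feature counts, beginning at `start` and ending
#'   at `target`.
#' @export
rfe_sizes <- function(start, fraction = 0.10, target = 60L) {
  if (start <= target) return(as.integer(start))
  sizes <- as.integer(start)
  n <- start
  while (n > target) {
    n <- n - max(1L, floor(fraction * n))
    if (n < target) n <- target
    sizes <- c(sizes, as.integer(n))
  }
  sizes
}

# Stratified fold assignment: samples of each class are spread evenly.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    if (length(idx) < k) stop("class '", lev, "' has fewer samples (",
                              length(idx), ") than folds (", k, ")")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Random-search tuning by inner stratified CV, scored by AUROC.
.tune_forest <- function(x, y, cfg) {
  p <- ncol(x)
  mtry_range <- cfg$mtry_range %||% c(max(1, ceiling(sqrt(p)) / 2), max(1, p / 2))
  log_unif <- function(lo, hi, n) {
    lo <- max(lo, 1e-9)
    round(exp(stats::runif(n, log(lo), log(max(hi, lo)))))
  }
  mtry <- pmin(pmax(log_unif(mtry_range[1L], mtry_range[2L], cfg$tune_evals), 1L), p)
  mns <- pmin(pmax(log_unif(cfg$min_node_range[1L], cfg$min_node_range[2L],
                            cfg$tune_evals), 1L), nrow(x))
  fold <- .stratified_folds(y, cfg$inner_folds)
  pos <- levels(y)[2L]
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$tune_evals * cfg$inner_folds)
  score <- numeric(cfg$tune_evals)
  for (e in seq_len(cfg$tune_evals)) {
    aucs <- numeric(cfg$inner_folds)
    for (f in seq_len(cfg$inner_folds)) {
      tr <- fold != f
      rf <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                           num.trees = cfg$n_trees, mtry = mtry[e],
                           min.node.size = mns[e], probability = TRUE,
                           num.threads = 1L,
                           seed = seeds[(e - 1L) * cfg$inner_folds + f])
      pr <- stats::predict(rf, data = x[!tr, , drop = FALSE],
                           num.threads = 1L)$predictions[, pos]
      aucs[f] <- .auroc(pr, y[!tr] == pos)
    }
    score[e] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(score)
  list(mtry = mtry[best], min_node = mns[best], auroc = score[best])
}

#' Nested cross-validated recursive feature elimination
#'
#' For each of `outer_folds` stratified outer folds: on the training
#' portion, repeatedly (i) tune `mtry`/`min.node.size` by random search
#' scored with inner stratified CV AUROC, (ii) fit a permutation-importance
#' forest, and (iii) drop the lowest `drop_fraction` of features, until the
#' feature count reaches `rfe_target`; a final tuned forest on the surviving
#' features is evaluated on the held-out outer fold and its
#' importance-ordered feature list emitted.
#'
#' Missing values must be handled upstream (see [candidate_pool()] /
#' [impute_donor_median()]); forests need complete inputs.
#'
#' @param x samples-by-features numeric matrix (no missing values).
#' @param labels two-level factor (or coercible) of per-sample class labels
#'   (islet disease status).
#' @param cfg an [rf_config()].
#' @return list of class `rfe_result`: `ranked_lists` (one importance-ordered
#'   character vector per outer fold), `outer_auroc`, and `sizes` (the
#'   elimination sequence).
#' @export
rf_rfe_outer <- function(x, labels, cfg) {
  stopifnot(inherits(cfg, "rf_config"), is.matrix(x), !is.null(colnames(x)))
  if (anyNA(x)) stop("candidate matrix has missing values; impute first")
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("need exactly two classes, got ", nlevels(y))
  .with_seed(cfg$seed, {
    outer <- .stratified_folds(y, cfg$outer_folds)
    fold_seeds <- sample.int(.Machine$integer.max - 1L, cfg$outer_folds)
    pos <- levels(y)[2L]
    ranked <- vector("list", cfg$outer_folds)
    outer_auc <- numeric(cfg$outer_folds)
    sizes <- rfe_sizes(ncol(x), cfg$drop_fraction, cfg$rfe_target)
    for (of in seq_len(cfg$outer_folds)) {
      set.seed(fold_seeds[of])
      tr <- outer != of
      feats <- colnames(x)
      final <- NULL
      repeat {
        xt <- x[tr, feats, drop = FALSE]
        tuned <- .tune_forest(xt, y[tr], cfg)
        rf <- ranger::ranger(x = xt, y = y[tr], num.trees = cfg$n_trees,
                             mtry = tuned$mtry, min.node.size = tuned$min_node,
                             probability = TRUE, importance = "permutation",
                             num.threads = 1L,
                             seed = sample.int(.Machine$integer.max - 1L, 1L))
        imp <- sort(rf$variable.importance, decreasing = TRUE)
        if (length(feats) <= cfg$rfe_target) {
          final <- rf
          feats <- names(imp)[seq_len(min(cfg$rfe_target, length(imp)))]
          break
        }
        n_drop <- max(1L, floor(cfg$drop_fraction * length(feats)))
        n_keep <- max(cfg$rfe_target, length(feats) - n_drop)
        feats <- names(imp)[seq_len(n_keep)]
      }
      pr <- stats::predict(final, data = x[!tr, final$forest$independent.variable.names,
                                           drop = FALSE],
                           num.threads = 1L)$predictions[, pos]
      outer_auc[of] <- .auroc(pr, y[!tr][seq_along(pr)] == pos)
      ranked[[of]] <- feats
    }
    structure(list(ranked_lists = ranked, outer_auroc = outer_auc,
                   sizes = sizes),
              class = "rfe_result")
  })
}

#' Median-impute missing values per feature within each donor
#'
#' @param m abundance matrix (features x samples).
#' @param meta metadata covering the columns of `m`.
#' @return completed matrix; features still missing everywhere within a
#'   donor fall back to the feature's overall median.
#' @export
impute_donor_median <- function(m, meta) {
  meta <- .meta_align(meta, m)
  out <- m
  for (d in unique(meta$donor_id)) {
    cols <- meta$donor_id == d
    sub <- m[, cols, drop = FALSE]
    med <- apply(sub, 1L, stats::median, na.rm = TRUE)
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx)) sub[idx] <- med[idx[, 1L]]
    out[, cols] <- sub
  }
  still <- which(is.na(out), arr.ind = TRUE)
  if (nrow(still)) {
    overall <- apply(m, 1L, stats::median, na.rm = TRUE)
    out[still] <- overall[still[, 1L]]
  }
  attr(out, "scale_tag") <- scale_tag(m)
  out
}

#' Assemble the immune candidate pool
#'
#' Unions the members of immune-enriched modules across the stage-1 donors,
#' keeps the candidates with fewer than `max_missing` missing values within
#' every donor, and applies donor-level batch correction to the pooled
#' matrix.
#'
#' @param module_labels named list (per stage-1 donor) of feature-to-module
#'   assignments (named vectors as from [cluster_fixed_k()]).
#' @param ora_tables named list (same donors) of [ora()] tables per module:
#'   each element is a list of data.frames keyed by module id.
#' @param m cross-donor abundance matrix (islets only).
#' @param meta metadata covering `m`.
#' @param immune_sets names of the gene sets that flag immune enrichment.
#' @param alpha adjusted-p cutoff declaring a module immune-enriched.
#' @param max_missing per-donor missing-fraction ceiling (strict `<`).
#' @return list with `matrix` (donor-corrected candidates x samples),
#'   `members`, and `enriched_modules` (per donor).
#' @export
candidate_pool <- function(module_labels, ora_tables, m, meta, immune_sets,
                           alpha = 0.05, max_missing = 0.5) {
  meta <- .meta_align(meta, m)
  pool <- character(0)
  enriched <- list()
  for (d in names(module_labels)) {
    labs <- module_labels[[d]]
    hits <- character(0)
    for (mod in names(ora_tables[[d]])) {
      tab <- ora_tables[[d]][[mod]]
      if (!nrow(tab)) next
      sel <- tab$set %in% immune_sets & tab$adj_p < alpha
      if (any(sel)) hits <- c(hits, mod)
    }
    enriched[[d]] <- hits
    pool <- union(pool, names(labs)[as.character(labs) %in% hits])
  }
  if (!length(pool))
    stop("empty candidate pool; no module reached adjusted p < ", alpha,
         " on the immune sets (modules per donor: ",
         paste(vapply(module_labels, function(l) length(unique(l)), 1L),
               collapse = ", "), ")")
  pool <- intersect(pool, rownames(m))
  keep <- rep(TRUE, length(pool))
  for (d in unique(meta$donor_id)) {
    cols <- meta$donor_id == d
    fr_miss <- rowMeans(is.na(m[pool, cols, drop = FALSE]))
    keep <- keep & (fr_miss < max_missing)
  }
  pool <- pool[keep]
  if (!length(pool)) stop("candidate pool emptied by the per-donor missingness rule")
  sub <- m[pool, , drop = FALSE]
  attr(sub, "scale_tag") <- scale_tag(m)
  corrected <- combat_correct(sub, meta$donor_id)
  list(matrix = corrected, members = pool, enriched_modules = enriched)
}

#' Robust rank aggregation
#'
#' Consolidates several importance-ranked feature lists: each feature's
#' normalized ranks (rank / `universe_size`, worst rank 1 when absent from a
#' list) are compared against the uniform order-statistic null — rho =
#' min_k P(Beta(k, n-k+1) <= r_(k)) — and Bonferroni-corrected over k. Lower
#' scores mean more consistently top-ranked features. Ties are broken by
#' mean normalized rank, then symbol.
#'
#' @param lists list of ranked character vectors (best first, no
#'   duplicates).
#' @param universe_size the N that ranks are normalized by (defaults to the
#'   largest list length).
#' @return data.frame ordered by score: feature, `rho`, `score`,
#'   `mean_rank`, `final_rank`.
#' @export
rra <- function(lists, universe_size = NULL) {
  stopifnot(length(lists) >= 1L)
  for (l in lists) if (anyDuplicated(l)) stop("ranked list contains duplicates")
  n <- length(lists)
  N <- universe_size %||% max(lengths(lists))
  if (any(lengths(lists) > N)) stop("a list is longer than the universe size")
  feats <- sort(unique(unlist(lists)))
  rmat <- matrix(1, nrow = length(feats), ncol = n,
                 dimnames = list(feats, NULL))
  for (j in seq_len(n)) {
    l <- lists[[j]]
    rmat[l, j] <- seq_along(l) / N
  }
  rho <- apply(rmat, 1L, function(r) {
    rs <- sort(r)
    min(stats::pbeta(rs, seq_len(n), n - seq_len(n) + 1L))
  })
  score <- pmin(rho * n, 1)
  mean_rank <- rowMeans(rmat)
  ord <- order(score, mean_rank, feats)
  out <- data.frame(feature = feats[ord], rho = rho[ord], score = score[ord],
                    mean_rank = mean_rank[ord],
                    final_rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select a signature panel and its per-sample centroid
#'
#' Takes the top `k` features by aggregation score and aggregates them into
#' one representative per-sample feature: the sample-wise median over the
#' member rows (observed values only). Samples with no observed member get a
#' missing centroid.
#'
#' @param rra_result an [rra()] table (or any data.frame with `feature` and
#'   `score` ordered best-first).
#' @param k panel size.
#' @param m abundance matrix supplying the member rows (log2,
#'   median-centered).
#' @param name panel name, e.g. `"IIRS"`.
#' @return list of class `signature_panel`: `name`, `members` (ordered),
#'   `scores`, `centroid`.
#' @export
select_panel <- function(rra_result, k, m, name = "IIRS") {
  if (k > nrow(rra_result))
    stop("k (", k, ") exceeds the number of scored features (", nrow(rra_result), ")")
  members <- rra_result$feature[seq_len(k)]
  miss <- setdiff(members, rownames(m))
  if (length(miss)) stop("panel member(s) missing from matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  centroid <- apply(m[members, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  centroid[is.nan(centroid)] <- NA_real_
  n_empty <- sum(is.na(centroid))
  if (n_empty) message(n_empty, " sample(s) have no observed panel member")
  structure(list(name = name, members = members,
                 scores = stats::setNames(rra_result$score[seq_len(k)], members),
                 centroid = centroid),
            class = "signature_panel")
}

#' Select the beta-cell profile by anchor correlation
#'
#' Ranks every feature by the mean of its Pearson correlations with the two
#' anchors (INS and ENTPD3 by default) over pairwise-complete samples and
#' keeps the top `k`; the anchors score 1 against themselves and are
#' eligible members. The centroid is the sample-wise median of the members.
#'
#' @param m abundance matrix (log2, median-centered).
#' @param anchors the two anchor features; both must be present with at
#'   least 3 observed values.
#' @param k panel size (41 in the default analysis).
#' @return `signature_panel` (name `"BCP"`) with an extra `mean_cor`
#'   element.
#' @export
bcp_select <- function(m, anchors = c("INS", "ENTPD3"), k = 41L) {
  .check_abundance(m)
  for (a in anchors) {
    if (!a %in% rownames(m)) stop("anchor feature missing from matrix: ", a)
    if (sum(!is.na(m[a, ])) < 3L) stop("anchor '", a, "' has fewer than 3 observed values")
  }
  cors <- sapply(anchors, function(a)
    suppressWarnings(stats::cor(t(m), m[a, ], use = "pairwise.complete.obs"))[, 1L])
  mean_cor <- rowMeans(cors)
  ord <- order(-mean_cor, rownames(m), na.last = TRUE)
  members <- rownames(m)[ord][seq_len(k)]
  centroid <- apply(m[members, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  centroid[is.nan(centroid)] <- NA_real_
  structure(list(name = "BCP", members = members,
                 scores = stats::setNames(mean_cor[ord][seq_len(k)], members),
                 mean_cor = mean_cor, centroid = centroid),
            class = "signature_panel")
}

#' Flag low-insulin islets
#'
#' An islet is low-insulin when its median-centered log2 insulin value is
#' more than 4-fold below the donor median, i.e. strictly below -2 on the
#' log2 scale (-2.0 exactly is not flagged).
#'
#' @param ins_row named numeric vector of median-centered log2 INS values.
#' @param cutoff log2 cutoff (default -2).
#' @return named logical vector (`NA` where INS is unobserved).
#' @export
low_insulin_flag <- function(ins_row, cutoff = -2) {
  if (all(is.na(ins_row))) stop("insulin row is entirely missing")
  ins_row < cutoff
}

#' Marker-based cell-type composition
#'
#' Relative abundance of each cell type as the sum of its (linear-scale)
#' marker intensities over the summed intensity across all cell-type
#' markers.
#'
#' @param marker_intensities named list: cell type -> numeric vector of
#'   non-negative linear intensities.
#' @return named numeric vector of proportions summing to 1.
#' @export
composition_estimate <- function(marker_intensities) {
  stopifnot(length(marker_intensities) >= 1L)
  sums <- vapply(marker_intensities, function(v) {
    if (any(v < 0, na.rm = TRUE)) stop("negative marker intensity")
    sum(v, na.rm = TRUE)
  }, 0)
  total <- sum(sums)
  if (total == 0) stop("all marker intensities are zero")
  sums / total
}

#' Pseudo-temporal ordering with tertile labels
#'
#' Orders samples by their signature centroid (ascending) and labels the
#' empirical tertiles low / moderate / high. Ties are assigned stably by
#' sample ID; ties spanning a tertile boundary are reported via a message.
#'
#' @param centroid named numeric vector (complete).
#' @return data.frame with sample, centroid, rank and tertile.
#' @export
pseudo_temporal_order <- function(centroid) {
  stopifnot(!is.null(names(centroid)))
  if (anyNA(centroid)) stop("centroid must be defined for all samples")
  ord <- order(centroid, names(centroid))
  q <- stats::quantile(centroid, c(1 / 3, 2 / 3), names = FALSE)
  breaks <- c(-Inf, q[1L], q[2L], Inf)
  if (anyDuplicated(breaks)) {
    # ties collapse the quantile breaks: fall back to rank thirds, stable
    # by sample ID
    message("ties span a tertile boundary; assignment is stable by sample ID")
    third <- ceiling(3 * seq_along(ord) / length(ord))
    tert <- factor(c("low", "moderate", "high")[third],
                   levels = c("low", "moderate", "high"))[order(ord)]
  } else {
    tert <- cut(centroid, breaks = breaks, labels = c("low", "moderate", "high"))
    if (any(duplicated(centroid)))
      message("tied centroid values; ordering is stable by sample ID")
  }
  data.frame(sample = names(centroid)[ord], centroid = centroid[ord],
             rank = seq_along(ord), tertile = as.character(tert)[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reference-pool and islet replicate QC
#'
#' Pairwise Pearson correlations over pairwise-complete features, separately
#' for reference-reference and islet-islet sample pairs, with min/median
#' summaries. Replicate pools should correlate more tightly than biological
#' islets.
#'
#' @param m abundance matrix.
#' @param meta metadata covering `m`.
#' @param max_islets islet pairs are summarized on at most this many
#'   randomly positioned islets (the first `max_islets` columns) to keep the
#'   table small.
#' @return list with `reference_cor`, `islet_cor` matrices (possibly `NULL`)
#'   and a `summary` data.frame.
#' @export
replicate_qc <- function(m, meta, max_islets = 50L) {
  meta <- .meta_align(meta, m)
  refs <- meta$sample_id[meta$is_reference == 1L]
  islets <- meta$sample_id[meta$is_reference == 0L]
  ref_cor <- NULL
  if (length(refs) >= 2L) {
    ref_cor <- stats::cor(m[, refs, drop = FALSE], use = "pairwise.complete.obs")
  } else {
    warning("fewer than 2 reference samples; reference QC block skipped")
  }
  isl <- islets[seq_len(min(length(islets), max_islets))]
  islet_cor <- if (length(isl) >= 2L)
    stats::cor(m[, isl, drop = FALSE], use = "pairwise.complete.obs") else NULL
  off <- function(cc) if (is.null(cc)) numeric(0) else cc[lower.tri(cc)]
  summary <- data.frame(
    pair_type = c("reference", "islet"),
    n_pairs = c(length(off(ref_cor)), length(off(islet_cor))),
    min_r = c(suppressWarnings(min(off(ref_cor))), suppressWarnings(min(off(islet_cor)))),
    median_r = c(stats::median(off(ref_cor)), stats::median(off(islet_cor))))
  list(reference_cor = ref_cor, islet_cor = islet_cor, summary = summary)
}

#' Center features on the non-inflamed baseline
#'
#' Cross-donor display centering under the assumption that ND islets and the
#' lower-half (by signature centroid, within donor) stage-1 islets are
#' comparable: each feature is centered on its median over that baseline
#' set.
#'
#' @param m abundance matrix.
#' @param meta metadata covering `m`.
#' @param centroid named per-sample signature centroid.
#' @return centered matrix.
#' @export
baseline_center <- function(m, meta, centroid) {
  meta <- .meta_align(meta, m)
  base <- meta$sample_id[meta$group == "nd" & meta$is_reference == 0L]
  for (d in unique(meta$donor_id[meta$group == "stage1"])) {
    ids <- meta$sample_id[meta$donor_id == d & meta$is_reference == 0L]
    cen <- centroid[ids]
    lower <- ids[!is.na(cen) & cen <= stats::median(cen, na.rm = TRUE)]
    base <- c(base, lower)
  }
  ref <- apply(m[, base, drop = FALSE], 1L, stats::median, na.rm = TRUE)
  out <- m - ref
  attr(out, "scale_tag") <- scale_tag(m)
  out
}
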