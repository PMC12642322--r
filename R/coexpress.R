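#' Biweight midcorrelation
#'
#' Robust correlation that downweights outliers with Tukey biweights:
#' u_i = (x_i - med_x) / (c * mad_x), w_i = (1 - u_i^2)^2 for |u_i| < 1 and 0
#' otherwise (mad is the unscaled median absolute deviation). When a vector
#' has zero mad the correlation falls back to the Pearson standardization for
#' that vector. Only pairwise-complete observations enter.
#'
#' @param x,y numeric vectors of equal length.
#' @param c tuning constant (default 9).
#' @return correlation in `[-1, 1]`; `NA` (with a warning) when fewer than 3
#'   complete pairs remain.
#' @export
bicor <- function(x, y, c = 9) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    warning("fewer than 3 pairwise-complete observations; returning NA")
    return(NA_real_)
  }
  ax <- .bicor_prep(x[ok], c)
  ay <- .bicor_prep(y[ok], c)
  r <- sum(ax * ay)
  max(-1, min(1, r))
}

# weighted, centered, unit-norm transform behind bicor
.bicor_prep <- function(x, c = 9) {
  med <- stats::median(x)
  mad <- stats::median(abs(x - med))
  if (mad == 0) {
    a <- x - mean(x)
  } else {
    u <- (x - med) / (c * mad)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    a <- (x - med) * w
  }
  nrm <- sqrt(sum(a^2))
  if (nrm == 0) stop("degenerate vector (all weights zero or constant input)")
  a / nrm
}

#' All-pairs correlation matrix of feature rows
#'
#' @param m complete (imputed) abundance matrix, features in rows.
#' @param method `"bicor"` (default) or `"pearson"`.
#' @param c bicor tuning constant.
#' @return symmetric feature-by-feature correlation matrix with unit
#'   diagonal.
#' @export
cor_matrix <- function(m, method = c("bicor", "pearson"), c = 9) {
  .check_abundance(m)
  method <- match.arg(method)
  if (anyNA(m)) stop("correlation matrix requires a complete (imputed) matrix")
  if (method == "pearson") {
    r <- stats::cor(t(m))
  } else {
    a <- t(apply(m, 1L, .bicor_prep, c = c))
    r <- tcrossprod(a)
  }
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Signed soft-threshold adjacency
#'
#' a_ij = sign(corr_ij) * |corr_ij|^beta, with unit diagonal. Raising to the
#' soft power beta suppresses weak correlations while keeping the network
#' sign-aware.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param beta soft power (> 0).
#' @return signed adjacency matrix.
#' @export
adjacency <- function(corr, beta) {
  stopifnot(beta > 0)
  if (anyNA(corr)) stop("NA in correlation matrix; impute before adjacency")
  if (!isSymmetric(unname(corr), tol = 1e-8)) stop("correlation matrix not symmetric")
  a <- sign(corr) * abs(corr)^beta
  diag(a) <- 1
  a
}

#' Signed-Nowick topological overlap
#'
#' T_ij = (sum_u a_iu a_uj + a_ij) / (D_ij + 1 - |a_ij|) with connectivity
#' k_i = sum_u |a_iu| (off-diagonal), preserving the sign contributed by the
#' numerator. `variant = "signed_nowick"` uses D_ij = min(k_i, k_j); the
#' `"signed_nowick_2"` variant uses the modified denominator
#' D_ij = (k_i + k_j) / 2. Diagonal is 1 by convention; the dissimilarity
#' used downstream is `1 - T`.
#'
#' @param adj signed adjacency from [adjacency()].
#' @param variant TOM flavor.
#' @return topological overlap matrix with `|T_ij| <= 1`.
#' @export
tom <- function(adj, variant = c("signed_nowick_2", "signed_nowick")) {
  variant <- match.arg(variant)
  if (!isSymmetric(unname(adj), tol = 1e-8)) stop("adjacency not symmetric")
  a <- adj
  diag(a) <- 0
  num <- a %*% a + a
  k <- rowSums(abs(a))
  dmat <- switch(variant,
                 signed_nowick = outer(k, k, pmin),
                 signed_nowick_2 = outer(k, k, `+`) / 2)
  denom <- dmat + 1 - abs(a)
  t_mat <- num / denom
  diag(t_mat) <- 1
  dimnames(t_mat) <- dimnames(adj)
  (t_mat + t(t_mat)) / 2
}

#' Cut a TOM-distance dendrogram into a fixed number of modules
#'
#' Agglomerative clustering with Ward's minimum-variance criterion
#' (`hclust` method `"ward.D"`, i.e. on the distance itself, not its square;
#' set `square = TRUE` for Ward's D2) applied to the TOM dissimilarity, cut
#' to exactly `K` clusters.
#'
#' @param dissim symmetric dissimilarity matrix (e.g. `1 - tom(...)`).
#' @param K number of clusters, `2 <= K <=` number of features (K = 1 is
#'   allowed and puts everything in one module).
#' @param square use Ward's D2 instead of Ward's D.
#' @return list with `labels` (named integer module ids) and `dendrogram`
#'   (the `hclust` object).
#' @export
cluster_fixed_k <- function(dissim, K, square = FALSE) {
  n <- nrow(dissim)
  if (K > n) stop("K (", K, ") exceeds the number of features (", n, ")")
  h <- stats::hclust(stats::as.dist(dissim),
                     method = if (square) "ward.D2" else "ward.D")
  labels <- stats::cutree(h, k = K)
  list(labels = labels, dendrogram = h)
}

#' Pick a soft power by scale-free topology fit
#'
#' For each candidate power, computes the signed-adjacency connectivities and
#' the R-squared of the log-log regression of the binned degree distribution;
#' returns the smallest power reaching `rsq_target`, or `fallback` if none
#' does.
#'
#' @param corr correlation matrix.
#' @param powers candidate powers.
#' @param rsq_target scale-free fit target.
#' @param fallback power used when no candidate reaches the target.
#' @param n_bins histogram bins of the connectivity distribution.
#' @return list with `power` and a table of per-power fits.
#' @export
pick_soft_power <- function(corr, powers = 1:20, rsq_target = 0.8,
                            fallback = 12, n_bins = 10) {
  fits <- vapply(powers, function(b) {
    a <- abs(corr)^b
    diag(a) <- 0
    k <- rowSums(a)
    if (stats::sd(k) == 0) return(c(rsq = NA_real_, slope = NA_real_))
    cut_k <- cut(k, breaks = n_bins)
    tab <- table(cut_k)
    keep <- tab > 0
    kmean <- tapply(k, cut_k, mean)[keep]
    pk <- as.numeric(tab[keep]) / length(k)
    if (sum(keep) < 3L) return(c(rsq = NA_real_, slope = NA_real_))
    fit <- stats::lm(log10(pk) ~ log10(kmean))
    c(rsq = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2L]))
  }, c(rsq = 0, slope = 0))
  tab <- data.frame(power = powers, rsq = fits["rsq", ], slope = fits["slope", ])
  ok <- which(!is.na(tab$rsq) & tab$rsq >= rsq_target & tab$slope < 0)
  list(power = if (length(ok)) powers[ok[1L]] else fallback, fits = tab)
}

#' Module eigenprotein
#'
#' First right-singular vector of the standardized member submatrix — the
#' per-sample summary profile of a module. The sign is fixed so that the
#' mean correlation of the eigenprotein with its member profiles is
#' positive.
#'
#' @param m complete abundance matrix.
#' @param members feature IDs of the module (at least 1, all present in `m`).
#' @return list with `eigenprotein` (unit-norm sample vector) and
#'   `variance_explained` (first singular value squared over the total).
#' @export
module_eigenprotein <- function(m, members) {
  .check_abundance(m)
  if (ncol(m) < 2L) stop("eigenprotein undefined for a single sample")
  miss <- setdiff(members, rownames(m))
  if (length(miss)) stop("member(s) not in matrix: ", paste(utils::head(miss, 5L), collapse = ", "))
  x <- m[members, , drop = FALSE]
  if (anyNA(x)) stop("member rows must be complete (impute first)")
  x <- t(scale(t(x)))
  if (anyNA(x)) stop("constant member row(s); drop before summarizing")
  s <- svd(x)
  e <- s$v[, 1L]
  if (mean(x %*% e) < 0) e <- -e
  names(e) <- colnames(m)
  list(eigenprotein = e, variance_explained = s$d[1L]^2 / sum(s$d^2))
}

#' Eigenprotein-phenotype association with moderated statistics
#'
#' Fits one linear model per module eigenprotein against each phenotype — a
#' two-group contrast for the binary CD3 call, a slope for the continuous
#' insulin intensity — and shares variance information across modules via
#' empirical-Bayes shrinkage ([squeeze_variances()]). P-values are
#' Benjamini-Hochberg adjusted within each phenotype family.
#'
#' @param E eigenprotein matrix, modules in rows, samples in columns.
#' @param phenotypes named list of per-sample numeric vectors (e.g.
#'   `list(cd3 = <0/1>, ins_intensity = <log2>)`); missing entries drop the
#'   sample for that phenotype.
#' @return data.frame with module, phenotype, effect, moderated t, raw and
#'   adjusted p; phenotypes that cannot be tested (e.g. CD3 all one level)
#'   are flagged with `skipped = TRUE`.
#' @export
module_phenotype_assoc <- function(E, phenotypes) {
  stopifnot(is.matrix(E), !is.null(rownames(E)))
  out <- list()
  for (ph in names(phenotypes)) {
    x <- phenotypes[[ph]]
    stopifnot(length(x) == ncol(E))
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L || sum(ok) < 3L) {
      out[[ph]] <- data.frame(module = rownames(E), phenotype = ph,
                              effect = NA_real_, t = NA_real_, p = NA_real_,
                              adj_p = NA_real_, skipped = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    sub <- E[, ok, drop = FALSE]
    attr(sub, "scale_tag") <- "log2_centered"
    fit <- fit_linear_models(sub, x[ok])
    sq <- try(squeeze_variances(fit$s2, fit$df), silent = TRUE)
    if (inherits(sq, "try-error")) sq <- list(s02 = NA_real_, d0 = 0)
    mt <- moderated_t(fit, s02 = sq$s02, d0 = sq$d0)
    out[[ph]] <- data.frame(module = fit$feature, phenotype = ph,
                            effect = fit$b, t = mt$t, p = mt$p,
                            adj_p = bh_adjust(mt$p), skipped = FALSE,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Over-representation analysis (hypergeometric test)
#'
#' Upper-tail hypergeometric p-value of the overlap between a module and
#' each gene set — P(X >= observed) with the universe as population — with
#' Benjamini-Hochberg adjustment across the tested sets. Sets with fewer
#' than `min_overlap` members in the universe are not tested.
#'
#' @param module_members features of the module (subset of `universe`).
#' @param universe all features under consideration.
#' @param sets gene-set collection (named list).
#' @param min_overlap minimum set size within the universe.
#' @return data.frame with set, set size in universe, overlap, raw and
#'   adjusted p.
#' @export
ora <- function(module_members, universe, sets, min_overlap = 5L) {
  if (!length(universe)) stop("empty universe")
  bad <- setdiff(module_members, universe)
  if (length(bad)) stop("module members outside the universe: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  n_univ <- length(universe)
  n_mod <- length(module_members)
  rows <- lapply(names(sets), function(nm) {
    in_univ <- intersect(sets[[nm]], universe)
    k <- length(in_univ)
    if (k < min_overlap) return(NULL)
    ov <- length(intersect(in_univ, module_members))
    p <- stats::phyper(ov - 1L, k, n_univ - k, n_mod, lower.tail = FALSE)
    data.frame(set = nm, set_size = k, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), adj_p = numeric(0)))
  res$adj_p <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}
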