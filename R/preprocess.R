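#' Log2-transform and zero-center protein features
#'
#' Linear-scale matrices are log2-transformed first (all observed values must
#' be strictly positive); every feature row is then centered on its mean over
#' observed entries. The missingness pattern is untouched.
#'
#' @param m abundance matrix (scale `linear` or `log2`).
#' @return matrix with scale tag `log2_centered`.
#' @export
log2_and_center <- function(m) {
  .check_abundance(m)
  tag <- scale_tag(m)
  if (tag == "log2_centered") stop("matrix is already centered")
  if (tag == "linear") {
    bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("non-positive linear intensity at feature '", rownames(m)[bad[1L, 1L]],
           "', sample '", colnames(m)[bad[1L, 2L]], "'")
    m[] <- log2(m)
    attr(m, "scale_tag") <- "log2"
  }
  m <- m - rowMeans(m, na.rm = TRUE)
  scale_tag(m) <- "log2_centered"
  m
}

#' Median-polish sample normalization
#'
#' Fits Tukey's median polish (alternating row- and column-median sweeps) on
#' the complete-case feature rows only, then subtracts the fitted column
#' (sample) effects from every feature, complete or not. Intended to be run
#' per donor.
#'
#' @param m abundance matrix (log2 scale).
#' @param tol convergence tolerance on the relative reduction of the sum of
#'   absolute residuals (the classical median-polish stopping rule).
#' @param max_iter sweep cap; the polish warns if it has not converged by
#'   then.
#' @return the normalized matrix, with the fitted column effects in the
#'   `col_effects` attribute.
#' @export
median_polish_normalize <- function(m, tol = 0.01, max_iter = 20L) {
  .check_abundance(m)
  complete <- rowSums(is.na(m)) == 0L
  if (sum(complete) < 2L)
    stop("fewer than 2 complete-case feature rows; lower the completeness ",
         "requirement or impute before normalizing")
  if (ncol(m) < 2L) stop("median polish needs at least 2 samples")
  fit <- withCallingHandlers(
    stats::medpolish(m[complete, , drop = FALSE], eps = tol,
                     maxiter = max_iter, trace.iter = FALSE),
    warning = function(w) {
      warning("median polish did not converge in ", max_iter, " sweeps",
              call. = FALSE)
      invokeRestart("muffleWarning")
    })
  out <- sweep(m, 2L, fit$col, `-`)
  attr(out, "scale_tag") <- scale_tag(m)
  attr(out, "col_effects") <- fit$col
  out
}

#' Per-donor completeness filter
#'
#' Keeps the features whose observed fraction is strictly greater than
#' `min_fraction` within every donor present in the metadata (a feature at
#' exactly the threshold in any donor is removed). Reference-pool samples are
#' excluded from the fraction.
#'
#' @param m abundance matrix.
#' @param meta sample metadata covering the columns of `m`.
#' @param min_fraction completeness threshold in `[0, 1]`.
#' @return the filtered matrix; the number of removed features is reported in
#'   the `n_removed` attribute.
#' @export
completeness_filter <- function(m, meta, min_fraction = 0.5) {
  .check_abundance(m)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  meta <- .meta_align(meta, m)
  islets <- meta$is_reference == 0L
  if (!any(islets)) stop("no non-reference samples to assess completeness on")
  keep <- rep(TRUE, nrow(m))
  for (d in unique(meta$donor_id[islets])) {
    cols <- islets & meta$donor_id == d
    if (!any(cols)) stop("donor ", d, " has zero samples")
    frac <- rowMeans(!is.na(m[, cols, drop = FALSE]))
    keep <- keep & (frac > min_fraction)
  }
  out <- m[keep, , drop = FALSE]
  attr(out, "scale_tag") <- scale_tag(m)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Combine per-donor matrices across donors
#'
#' Takes the union of samples over the intersection of feature universes.
#' Feature order follows the first donor; sample order follows donor order
#' then input order.
#'
#' @param per_donor non-empty list of abundance matrices with disjoint sample
#'   IDs.
#' @return the combined matrix.
#' @export
assemble_cross_donor <- function(per_donor) {
  if (!length(per_donor)) stop("empty list of per-donor matrices")
  for (m in per_donor) .check_abundance(m)
  if (length(per_donor) == 1L) return(per_donor[[1L]])
  ids <- unlist(lapply(per_donor, colnames))
  if (anyDuplicated(ids))
    stop("duplicated sample ID across donors: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  feats <- Reduce(intersect, lapply(per_donor, rownames))
  if (!length(feats)) stop("no features shared across donors")
  out <- do.call(cbind, lapply(per_donor, function(m) m[feats, , drop = FALSE]))
  attr(out, "scale_tag") <- scale_tag(per_donor[[1L]])
  out
}

#' Iterative SVD imputation
#'
#' Features are z-scored on their observed mean and SD, missing cells start
#' at 0, and the matrix is repeatedly replaced by its rank-`n_components`
#' SVD reconstruction (missing cells only) until the relative Frobenius
#' change of the imputed values drops below `tol`. Observed cells and the
#' original feature scales are restored afterwards. Intended to be run within
#' disease-status groups.
#'
#' @param m abundance matrix.
#' @param n_components rank of the reconstruction; must be below both
#'   dimensions.
#' @param max_iter iteration cap.
#' @param tol relative-change convergence tolerance.
#' @return the completed matrix (no missing entries).
#' @export
svd_impute <- function(m, n_components = 5L, max_iter = 100L, tol = 1e-5) {
  .check_abundance(m)
  if (n_components >= min(dim(m)))
    stop("n_components must be smaller than both matrix dimensions")
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs < 2L))
    stop("feature(s) with fewer than 2 observed values (sd undefined): ",
         paste(utils::head(rownames(m)[n_obs < 2L], 5L), collapse = ", "))
  if (any(colSums(!is.na(m)) == 0L))
    stop("sample(s) with all entries missing")
  mu <- rowMeans(m, na.rm = TRUE)
  sd <- apply(m, 1L, stats::sd, na.rm = TRUE)
  if (any(sd == 0))
    stop("constant feature(s) cannot be z-scored: ",
         paste(utils::head(rownames(m)[sd == 0], 5L), collapse = ", "))
  z <- (m - mu) / sd
  miss <- is.na(z)
  if (!any(miss)) return(m)
  z[miss] <- 0
  prev <- z[miss]
  for (it in seq_len(max_iter)) {
    s <- svd(z, nu = n_components, nv = n_components)
    recon <- s$u %*% (s$d[seq_len(n_components)] * t(s$v))
    z[miss] <- recon[miss]
    delta <- sqrt(sum((z[miss] - prev)^2)) / max(sqrt(sum(prev^2)), .Machine$double.eps)
    prev <- z[miss]
    if (delta < tol) break
  }
  out <- z * sd + mu
  out[!miss] <- m[!miss]
  attr(out, "scale_tag") <- scale_tag(m)
  out
}
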