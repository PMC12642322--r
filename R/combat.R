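#' Fit an empirical-Bayes batch-correction model (parametric ComBat)
#'
#' Location/scale batch adjustment with empirical-Bayes shrinkage: features
#' are standardized on their grand mean and pooled residual variance, batch
#' means are shrunk toward a batch-level normal prior and batch variances
#' toward an inverse-gamma prior (method-of-moments hyperparameters, iterated
#' conditional updates). Unlike textbook implementations this one tolerates
#' missing entries: all moments are taken over observed cells.
#'
#' Degenerate situations are handled conservatively: a feature that is
#' constant across all samples is skipped (returned unchanged by
#' [combat_apply()]) with a warning; a feature with zero within-batch
#' residual variance gets a location-only adjustment.
#'
#' @param m abundance matrix (log2 scale).
#' @param batches batch label per column of `m`.
#' @param conv convergence tolerance of the iterated EB updates.
#' @return object of class `combat_model` holding the grand mean, pooled
#'   variance, shrunken per-batch location (`gamma_star`) and scale
#'   (`delta_star`) estimates, and the prior hyperparameters.
#' @export
combat_fit <- function(m, batches, conv = 1e-4) {
  .check_abundance(m)
  batches <- as.character(batches)
  stopifnot(length(batches) == ncol(m))
  levs <- unique(batches)
  obs <- !is.na(m)
  for (b in levs) {
    nb <- sum(batches == b)
    if (nb < 2L) stop("batch '", b, "' has ", nb, " sample(s); ",
                      "variance is undefined with fewer than 2")
  }

  overall_var <- apply(m, 1L, stats::var, na.rm = TRUE)
  skip <- !is.na(overall_var) & overall_var == 0
  if (any(skip))
    warning(sum(skip), " constant feature(s) skipped by batch correction")

  # observed counts and batch means per feature
  n_bg <- sapply(levs, function(b) rowSums(obs[, batches == b, drop = FALSE]))
  gamma_hat_raw <- sapply(levs, function(b)
    rowMeans(m[, batches == b, drop = FALSE], na.rm = TRUE))
  n_bg <- matrix(n_bg, nrow = nrow(m), dimnames = list(rownames(m), levs))
  gamma_hat_raw <- matrix(gamma_hat_raw, nrow = nrow(m),
                          dimnames = list(rownames(m), levs))
  grand <- rowSums(gamma_hat_raw * n_bg, na.rm = TRUE) / rowSums(n_bg)

  # pooled residual variance about batch means (divisor N, ComBat convention)
  resid <- m - gamma_hat_raw[, match(batches, levs), drop = FALSE]
  pooled <- rowSums(resid^2, na.rm = TRUE) / rowSums(obs)
  pooled_floor <- pmax(pooled, 1e-8)

  model <- list(batches = levs, grand_mean = grand, pooled_var = pooled,
                skip = skip, conv = conv)

  if (length(levs) == 1L) {
    model$gamma_star <- matrix(0, nrow(m), 1L, dimnames = list(rownames(m), levs))
    model$delta_star <- matrix(1, nrow(m), 1L, dimnames = list(rownames(m), levs))
    model$priors <- NULL
    class(model) <- "combat_model"
    return(model)
  }

  z <- (m - grand) / sqrt(pooled_floor)
  gamma_star <- delta_star <- matrix(NA_real_, nrow(m), length(levs),
                                     dimnames = list(rownames(m), levs))
  priors <- list()
  use <- !skip
  for (j in seq_along(levs)) {
    cols <- batches == levs[j]
    zb <- z[, cols, drop = FALSE]
    n <- rowSums(!is.na(zb))
    g_hat <- rowMeans(zb, na.rm = TRUE)
    d_hat <- apply(zb, 1L, stats::var, na.rm = TRUE)
    d_hat[is.na(d_hat)] <- 0
    gbar <- mean(g_hat[use])
    t2 <- stats::var(g_hat[use])
    dm <- mean(d_hat[use]); ds2 <- stats::var(d_hat[use])
    if (is.na(t2) || t2 <= 0 || is.na(ds2) || ds2 <= 0) {
      # no dispersion across features to borrow from: no shrinkage
      g_star <- g_hat
      d_star <- ifelse(d_hat > 0, d_hat, 1)
      priors[[levs[j]]] <- list(gamma_bar = gbar, t2 = t2, a = NA, b = NA)
    } else {
      a <- (2 * ds2 + dm^2) / ds2
      b <- (dm * ds2 + dm^3) / ds2
      g_star <- g_hat
      d_star <- d_hat
      repeat {
        g_new <- (n * t2 * g_hat + d_star * gbar) / (n * t2 + d_star)
        sum2 <- rowSums((zb - g_new)^2, na.rm = TRUE)
        d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
        chg <- max(abs(g_new - g_star) / pmax(abs(g_star), 1e-12),
                   abs(d_new - d_star) / pmax(abs(d_star), 1e-12))
        g_star <- g_new; d_star <- d_new
        if (chg < conv) break
      }
      d_star <- ifelse(d_star > 0, d_star, 1)
      priors[[levs[j]]] <- list(gamma_bar = gbar, t2 = t2, a = a, b = b)
    }
    gamma_star[, j] <- g_star
    delta_star[, j] <- d_star
  }
  gamma_star[skip, ] <- 0
  delta_star[skip, ] <- 1
  model$gamma_star <- gamma_star
  model$delta_star <- delta_star
  model$priors <- priors
  class(model) <- "combat_model"
  model
}

#' Apply a fitted batch-correction model
#'
#' Standardizes on the model's grand mean and pooled variance, removes the
#' shrunken batch location, rescales by the shrunken batch scale, and
#' restores the original feature scale. Missing entries pass through
#' untouched.
#'
#' @param m abundance matrix whose features appear in the model.
#' @param model a [combat_fit()] result.
#' @param batches batch label per column of `m`; all labels must have been
#'   seen at fit time.
#' @return corrected matrix.
#' @export
combat_apply <- function(m, model, batches) {
  stopifnot(inherits(model, "combat_model"))
  .check_abundance(m)
  batches <- as.character(batches)
  stopifnot(length(batches) == ncol(m))
  unseen <- setdiff(unique(batches), model$batches)
  if (length(unseen)) stop("unseen batch label(s): ", paste(unseen, collapse = ", "))
  feats <- rownames(m)
  if (!all(feats %in% names(model$grand_mean)))
    stop("matrix contains features absent from the model")
  grand <- model$grand_mean[feats]
  pooled <- pmax(model$pooled_var[feats], 1e-8)
  j <- match(batches, model$batches)
  g <- model$gamma_star[feats, j, drop = FALSE]
  d <- model$delta_star[feats, j, drop = FALSE]
  z <- (m - grand) / sqrt(pooled)
  out <- (z - g) / sqrt(d) * sqrt(pooled) + grand
  out[model$skip[feats], ] <- m[model$skip[feats], ]
  attr(out, "scale_tag") <- scale_tag(m)
  out
}

#' Fit and apply batch correction in one step
#'
#' @inheritParams combat_fit
#' @return corrected matrix.
#' @export
combat_correct <- function(m, batches, conv = 1e-4) {
  combat_apply(m, combat_fit(m, batches, conv = conv), batches)
}
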