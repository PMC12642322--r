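#' Per-feature simple linear models against a covariate
#'
#' Ordinary least squares of each feature's abundance on
#' `[intercept, covariate]`, fit over the samples where that feature is
#' observed (listwise deletion per feature). Features with fewer than 3
#' observed samples or residual df below 1 get `NA` statistics and are
#' flagged.
#'
#' @param m abundance matrix (log2, typically median-centered).
#' @param covariate complete numeric vector, one value per column of `m`
#'   (e.g. a signature centroid).
#' @return data.frame with per-feature slope `b`, unscaled standard error
#'   `u`, residual variance `s2`, residual df `df`, `n_obs` and `flagged`.
#' @export
fit_linear_models <- function(m, covariate) {
  .check_abundance(m)
  stopifnot(length(covariate) == ncol(m))
  if (anyNA(covariate)) stop("covariate must be complete over samples")
  if (stats::var(covariate) == 0) stop("constant covariate: slope unidentified")
  p <- nrow(m)
  b <- u <- s2 <- rep(NA_real_, p)
  df <- n_obs <- rep(NA_integer_, p)
  for (g in seq_len(p)) {
    y <- m[g, ]
    ok <- !is.na(y)
    n <- sum(ok)
    n_obs[g] <- n
    if (n < 3L) next
    x <- covariate[ok]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) next
    yv <- y[ok]
    bg <- sum(xc * yv) / sxx
    a <- mean(yv) - bg * mean(x)
    rss <- sum((yv - a - bg * x)^2)
    b[g] <- bg
    u[g] <- sqrt(1 / sxx)
    df[g] <- n - 2L
    s2[g] <- rss / (n - 2L)
  }
  res <- data.frame(feature = rownames(m), b = b, u = u, s2 = s2, df = df,
                    n_obs = n_obs, flagged = is.na(b), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
.trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-7
  hi <- y > 1e7
  out[lo] <- 1 / sqrt(y[lo])
  out[hi] <- 1 / y[hi]
  mid <- !lo & !hi & !is.na(y)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes variance shrinkage hyperparameters
#'
#' Fits a scaled-F distribution to the ensemble of per-feature residual
#' variances by moment matching on the log scale (digamma/trigamma
#' equations), yielding the prior variance `s02` and prior df `d0`. When the
#' spread of log variances does not exceed its expected sampling variance the
#' prior df is infinite (every feature shares `s02`).
#'
#' @param s2 per-feature residual variances (at least 2 positive values).
#' @param df per-feature residual degrees of freedom (recycled if scalar).
#' @return list with `s02` and `d0` (`Inf` allowed).
#' @export
squeeze_variances <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  stopifnot(length(df) == length(s2))
  ok <- !is.na(s2) & !is.na(df) & df > 0
  if (all(s2[ok] == 0)) stop("all residual variances are zero")
  pos <- ok & s2 > 0
  if (sum(pos) < 2L) stop("need at least 2 features with positive variance")
  x <- s2[pos]; d <- df[pos]
  z <- log(x)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(s02 = s02, d0 = d0)
}

#' Moderated t-statistics
#'
#' Shrinks each feature's residual variance toward the ensemble prior,
#' s2_post = (d0 * s02 + df * s2) / (d0 + df), and tests b / (u * s_post)
#' against a t distribution with d0 + df degrees of freedom (standard normal
#' when d0 is infinite). With d0 = 0 this is the ordinary t-test.
#'
#' @param fit result of [fit_linear_models()].
#' @param s02,d0 prior variance and df, e.g. from [squeeze_variances()].
#' @return data.frame with feature, b, moderated `t`, total `df`, two-sided
#'   `p` and posterior variance `s2_post`.
#' @export
moderated_t <- function(fit, s02, d0) {
  stopifnot(d0 >= 0)
  s2_post <- if (is.infinite(d0)) rep(s02, nrow(fit)) else
    (d0 * s02 + fit$df * fit$s2) / (d0 + fit$df)
  df_total <- if (is.infinite(d0)) rep(Inf, nrow(fit)) else d0 + fit$df
  t <- fit$b / (fit$u * sqrt(s2_post))
  zero_var <- !is.na(s2_post) & s2_post == 0
  p <- ifelse(is.infinite(df_total),
              2 * stats::pnorm(-abs(t)),
              2 * stats::pt(-abs(t), df_total))
  if (any(zero_var, na.rm = TRUE)) {
    warning(sum(zero_var), " feature(s) with zero posterior variance; p set to 0")
    t[zero_var] <- sign(fit$b[zero_var]) * Inf
    p[zero_var] <- 0
  }
  data.frame(feature = fit$feature, b = fit$b, t = t, df = df_total, p = p,
             s2_post = s2_post, stringsAsFactors = FALSE)
}

#' Map t-statistics to standard-normal equivalents
#'
#' z = qnorm(pt(t; df)), evaluated tail-symmetrically in log space for
#' numerical stability; monotone in t with z(-t) = -z(t). Infinite df gives
#' z = t.
#'
#' @param t t-statistic(s).
#' @param df degrees of freedom (> 0; recycled).
#' @return z-score(s); non-finite t propagates as signed infinity.
#' @export
t_to_z <- function(t, df) {
  stopifnot(all(df > 0))
  if (length(df) == 1L) df <- rep(df, length(t))
  z <- ifelse(is.infinite(df), t,
              sign(t) * stats::qnorm(
                stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE),
                lower.tail = FALSE, log.p = TRUE))
  z[t == 0] <- 0
  z
}

#' Pre-ranked CAMERA competitive gene-set test
#'
#' Two-sample comparison of a set's gene scores against all other scores,
#' with the set-mean variance inflated by VIF = 1 + (m - 1) * rho to account
#' for inter-gene correlation: t = (mean_set - mean_rest) /
#' (s_p * sqrt(VIF/m + 1/(G-m))) on G - 2 df, two-sided. With rho = 0 this
#' is exactly the pooled two-sample t-test. Sets are tested only if at least
#' `min_set_size` members are present among the scores; p-values are
#' Benjamini-Hochberg adjusted across the tested sets.
#'
#' @param z named per-feature scores (e.g. from [t_to_z()]).
#' @param sets gene-set collection.
#' @param inter_gene_cor the fixed inter-gene correlation rho (default 0.01,
#'   never estimated from data).
#' @param min_set_size minimum overlap with the score universe.
#' @return data.frame with set, `n_genes`, `direction` (Up/Down), set-level
#'   `z`, raw and adjusted p.
#' @export
camera_pr <- function(z, sets, inter_gene_cor = 0.01, min_set_size = 5L) {
  stopifnot(!is.null(names(z)))
  z <- z[!is.na(z)]
  G <- length(z)
  rows <- lapply(names(sets), function(nm) {
    idx <- names(z) %in% sets[[nm]]
    m <- sum(idx)
    if (m < min_set_size || G - m == 0L) return(NULL)
    vif <- 1 + (m - 1) * inter_gene_cor
    if (vif <= 0) stop("non-positive VIF for set '", nm, "'")
    zs <- z[idx]; zr <- z[!idx]
    ms <- mean(zs); mr <- mean(zr)
    sp2 <- (sum((zs - ms)^2) + sum((zr - mr)^2)) / (G - 2L)
    if (sp2 == 0) {
      stat <- 0; p <- 1
    } else {
      stat <- (ms - mr) / sqrt(sp2 * (vif / m + 1 / (G - m)))
      p <- 2 * stats::pt(-abs(stat), df = G - 2L)
    }
    data.frame(set = nm, n_genes = m,
               direction = if (ms > mr) "Up" else "Down",
               t = stat, z = t_to_z(stat, G - 2L), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set = character(0), n_genes = integer(0),
                      direction = character(0), t = numeric(0), z = numeric(0),
                      p = numeric(0), adj_p = numeric(0)))
  res$adj_p <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-preserving and
#' never below the raw p.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
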