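mkm <- function(values, nr) {
  m <- matrix(values, nrow = nr, byrow = TRUE)
  dimnames(m) <- list(paste0("f", seq_len(nrow(m))), paste0("s", seq_len(ncol(m))))
  attr(m, "scale_tag") <- "log2_centered"
  m
}

test_that("per-feature OLS matches hand-worked normal equations", {
  x <- c(0, 1, 2, 3)
  m <- mkm(c(1, 2, 2, 4,
             2 * x + 1,
             0, 0, 0, 0), 3)
  fit <- fit_linear_models(m, x)
  # n = 4, y = (1,2,2,4): b = 0.9, d = 2, s2 = RSS/2 = 0.35
  expect_equal(fit$b[1], 0.9, tolerance = 1e-12)
  expect_equal(fit$df[1], 2L)
  expect_equal(fit$s2[1], 0.35, tolerance = 1e-12)
  expect_equal(fit$u[1], sqrt(1 / 5), tolerance = 1e-12)
  # noiseless line
  expect_equal(fit$b[2], 2, tolerance = 1e-12)
  expect_equal(fit$s2[2], 0, tolerance = 1e-12)
  # orthogonal feature
  expect_equal(fit$b[3], 0, tolerance = 1e-12)

  # listwise deletion per feature under missingness
  m2 <- mkm(c(NA, 2, 2, 4), 1)
  fit2 <- fit_linear_models(m2, x)
  xm <- x[-1]; ym <- c(2, 2, 4)
  expect_equal(fit2$b, cov(xm, ym) / var(xm), tolerance = 1e-12)
  expect_equal(fit2$n_obs, 3L)

  expect_error(fit_linear_models(m, rep(1, 4)), "constant covariate")
  expect_error(fit_linear_models(m, c(1, 2, NA, 4)), "complete")
})

test_that("variance squeeze recovers known scaled-F hyperparameters", {
  set.seed(31)
  d0 <- 4; s02 <- 1; d <- 10
  s2 <- s02 * rf(1e4, d, d0)
  sq <- squeeze_variances(s2, d)
  expect_lt(abs(sq$d0 - d0), 1)
  expect_lt(abs(sq$s02 - s02) / s02, 0.1)

  # identical variances with large df: no excess dispersion, infinite prior
  sq2 <- squeeze_variances(rep(2, 100), 1000)
  expect_identical(sq2$d0, Inf)
  expect_equal(sq2$s02, 2, tolerance = 1e-2)

  # minimal ensemble does not crash
  sq3 <- squeeze_variances(c(0.5, 1.5), c(5, 5))
  expect_true(is.finite(sq3$s02))
  expect_error(squeeze_variances(c(0, 0), c(5, 5)), "zero")
})

test_that("variance squeeze agrees with limma::squeezeVar", {
  skip_if_not_installed("limma")
  set.seed(32)
  for (d in c(3, 8, 25)) {
    s2 <- 0.7 * rf(500, d, 6)
    sq <- squeeze_variances(s2, d)
    ref <- limma::squeezeVar(s2, df = d)
    expect_equal(sq$d0, ref$df.prior, tolerance = 1e-6)
    expect_equal(sq$s02, ref$var.prior, tolerance = 1e-6)
  }
})

test_that("moderated t has the documented shrinkage limits", {
  set.seed(33)
  x <- rnorm(12)
  m <- mkm(rnorm(60), 5)
  fit <- fit_linear_models(m, rnorm(12))
  # d0 = 0: ordinary t
  mt0 <- moderated_t(fit, s02 = 123, d0 = 0)
  expect_equal(mt0$t, fit$b / (fit$u * sqrt(fit$s2)), tolerance = 1e-12)
  # d0 = Inf: posterior variance equals the prior everywhere, normal p
  mtI <- moderated_t(fit, s02 = 0.8, d0 = Inf)
  expect_true(all(mtI$s2_post == 0.8))
  expect_equal(mtI$p, 2 * pnorm(-abs(fit$b / (fit$u * sqrt(0.8)))),
               tolerance = 1e-12)
  # intermediate prior keeps s2_post between the prior and the observed
  mth <- moderated_t(fit, s02 = 0.8, d0 = 4)
  expect_true(all(mth$s2_post >= pmin(0.8, fit$s2) - 1e-12 &
                  mth$s2_post <= pmax(0.8, fit$s2) + 1e-12))
})

test_that("moderated pipeline agrees with limma lmFit + eBayes", {
  skip_if_not_installed("limma")
  set.seed(34)
  n <- 20L; p <- 300L
  x <- rnorm(n)
  m <- matrix(rnorm(p * n, sd = rep(sqrt(0.5 * rf(p, 10, 8)), n)), p, n)
  m <- m + outer(rnorm(p, 0, 0.4), x)
  dimnames(m) <- list(paste0("f", 1:p), paste0("s", 1:n))
  attr(m, "scale_tag") <- "log2_centered"
  fit <- fit_linear_models(m, x)
  sq <- squeeze_variances(fit$s2, fit$df)
  mt <- moderated_t(fit, sq$s02, sq$d0)

  lf <- limma::eBayes(limma::lmFit(m, cbind(1, x)))
  expect_equal(sq$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(sq$s02, lf$s2.prior, tolerance = 1e-6)
  expect_equal(mt$t, lf$t[, 2], ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(mt$p, lf$p.value[, 2], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("t to z transform is exact, symmetric and stable", {
  expect_identical(t_to_z(0, 5), 0)
  # 2.228 is the 0.975 t-quantile at 10 df
  expect_equal(t_to_z(qt(0.975, 10), 10), qnorm(0.975), tolerance = 1e-10)
  expect_equal(t_to_z(-3.1, 7), -t_to_z(3.1, 7), tolerance = 1e-12)
  expect_lt(abs(t_to_z(2, 1e6) - 2), 1e-3)
  expect_identical(t_to_z(2, Inf), 2)
  # deep tails survive in log space
  expect_true(is.finite(t_to_z(40, 200)))
  expect_gt(t_to_z(40, 200), 10)
})

test_that("camera_pr reduces to the pooled two-sample t at rho = 0", {
  set.seed(35)
  z <- rnorm(50)
  names(z) <- paste0("g", 1:50)
  sets <- list(A = paste0("g", 1:8), B = paste0("g", 20:45))
  res <- camera_pr(z, sets, inter_gene_cor = 0)
  for (nm in names(sets)) {
    inset <- names(z) %in% sets[[nm]]
    tt <- t.test(z[inset], z[!inset], var.equal = TRUE)
    expect_equal(res$p[res$set == nm], tt$p.value, tolerance = 1e-12)
    expect_equal(abs(res$t[res$set == nm]), abs(unname(tt$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("camera_pr matches limma::cameraPR and the direct formula", {
  skip_if_not_installed("limma")
  set.seed(36)
  z <- rnorm(200)
  names(z) <- paste0("g", 1:200)
  sets <- lapply(1:10, function(i) sample(names(z), 15))
  names(sets) <- paste0("S", 1:10)
  res <- camera_pr(z, sets, inter_gene_cor = 0.01)
  ref <- limma::cameraPR(z, index = lapply(sets, function(s) which(names(z) %in% s)),
                         inter.gene.cor = 0.01, sort = FALSE)
  expect_equal(res$p, ref$PValue[match(res$set, rownames(ref))], tolerance = 1e-9)
  expect_equal(res$adj_p, ref$FDR[match(res$set, rownames(ref))], tolerance = 1e-9)
  expect_identical(res$direction, as.character(ref$Direction[match(res$set, rownames(ref))]))

  # hand evaluation of the statistic for one set
  s <- sets$S1
  inset <- names(z) %in% s
  m <- sum(inset); G <- length(z)
  sp2 <- (sum((z[inset] - mean(z[inset]))^2) + sum((z[!inset] - mean(z[!inset]))^2)) / (G - 2)
  stat <- (mean(z[inset]) - mean(z[!inset])) /
    sqrt(sp2 * ((1 + (m - 1) * 0.01) / m + 1 / (G - m)))
  expect_equal(res$t[res$set == "S1"], stat, tolerance = 1e-9)
})

test_that("degenerate camera inputs behave as documented", {
  z <- rep(1.3, 30)
  names(z) <- paste0("g", 1:30)
  res <- camera_pr(z, list(A = paste0("g", 1:10)))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # sets below the overlap floor are not tested
  res2 <- camera_pr(z, list(A = paste0("g", 1:3)), min_set_size = 5L)
  expect_equal(nrow(res2), 0L)
})

test_that("a positive inter-gene correlation deflates significance", {
  set.seed(37)
  rej0 <- rej1 <- 0L
  n_rep <- 300L
  for (r in seq_len(n_rep)) {
    G <- 100L; m <- 20L
    shared <- rnorm(1)
    z <- rnorm(G)
    z[1:m] <- sqrt(0.9) * rnorm(m) + sqrt(0.1) * shared  # equicorrelated set
    names(z) <- paste0("g", 1:G)
    sets <- list(S = paste0("g", 1:m))
    rej0 <- rej0 + (camera_pr(z, sets, inter_gene_cor = 0)$p < 0.05)
    rej1 <- rej1 + (camera_pr(z, sets, inter_gene_cor = 0.1)$p < 0.05)
  }
  expect_lte(rej1, rej0)
})

test_that("BH adjustment matches brute force on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  brute <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  set.seed(38)
  for (r in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute(p), tolerance = 1e-12)
  }
})
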