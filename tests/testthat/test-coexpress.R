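test_that("bicor handles self, anti and outlier cases", {
  x <- c(1.2, 3.1, 2.4, 5.9, 4.4, 0.3, 2.2, 7.1, 6.6, 1.9)
  expect_equal(bicor(x, x), 1.0)
  expect_equal(bicor(x, -x), -1.0)

  # outlier downweighting: corrupting one point barely moves bicor but
  # drags Pearson far away
  x <- as.numeric(1:20)
  y <- x; y[20] <- 1000
  b <- bicor(x, y)
  p <- cor(x, y)
  expect_gt(abs(b - p), 0.1)
  expect_gt(b, p)
  # direct evaluation of the weight formula as an independent oracle
  w_of <- function(v) {
    med <- median(v); mad <- median(abs(v - med))
    u <- (v - med) / (9 * mad)
    (v - med) * (1 - u^2)^2 * (abs(u) < 1)
  }
  ax <- w_of(x); ay <- w_of(y)
  expect_equal(b, sum(ax * ay) / sqrt(sum(ax^2) * sum(ay^2)), tolerance = 1e-12)

  expect_warning(r <- bicor(c(1, 2, NA), c(1, NA, 3)), "fewer than 3")
  expect_true(is.na(r))
})

test_that("bicor approximates Pearson on clean Gaussian data", {
  set.seed(21)
  d <- numeric(20)
  for (i in 1:20) {
    x <- rnorm(200)
    y <- 0.6 * x + rnorm(200, sd = sqrt(1 - 0.36))
    d[i] <- abs(bicor(x, y) - cor(x, y))
  }
  # the biweight taper leaves a small residual difference even without
  # outliers; it stays a few hundredths at most
  expect_lt(mean(d), 0.02)
  expect_lt(max(d), 0.06)
})

test_that("cor_matrix agrees with pairwise bicor and Pearson", {
  set.seed(22)
  m <- matrix(rnorm(8 * 30), 8, dimnames = list(paste0("f", 1:8), paste0("s", 1:30)))
  attr(m, "scale_tag") <- "log2_centered"
  cm <- cor_matrix(m, method = "bicor")
  expect_true(isSymmetric(cm))
  expect_equal(cm[2, 5], bicor(m[2, ], m[5, ]), tolerance = 1e-12)
  expect_equal(unname(cor_matrix(m, method = "pearson")), unname(cor(t(m))),
               tolerance = 1e-12)
})

test_that("adjacency is a signed soft power with unit diagonal", {
  corr <- diag(3)
  expect_equal(adjacency(corr, 12), diag(3))
  corr <- matrix(c(1, -0.5, -0.5, 1), 2)
  a <- adjacency(corr, 2)
  expect_equal(a[1, 2], -0.25)
  corr2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(adjacency(corr2, 1), corr2)
})

test_that("TOM matches hand evaluation on small graphs", {
  # fully connected triangle: T_12 = (1*1 + 1) / (min(2,2) + 1 - 1) = 1
  a <- matrix(1, 3, 3)
  for (v in c("signed_nowick", "signed_nowick_2")) {
    t3 <- tom(a, variant = v)
    expect_equal(unname(t3), matrix(1, 3, 3))
  }

  # disconnected graph: off-diagonal T = 0
  t0 <- tom(diag(4), variant = "signed_nowick")
  expect_equal(unname(t0), diag(4))

  # brute-force per-pair evaluation on random signed adjacencies
  set.seed(23)
  for (rep in 1:5) {
    n <- 6L
    a <- matrix(runif(n * n, -1, 1), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    k <- sapply(seq_len(n), function(i) sum(abs(a[i, -i])))
    for (v in c("signed_nowick", "signed_nowick_2")) {
      tm <- tom(a, variant = v)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
        dd <- if (v == "signed_nowick") min(k[i], k[j]) else (k[i] + k[j]) / 2
        expect_equal(tm[i, j], num / (dd + 1 - abs(a[i, j])), tolerance = 1e-12)
      }
      expect_true(isSymmetric(tm))
      expect_true(all(abs(tm) <= 1 + 1e-12))
    }
  }
})

test_that("fixed-K Ward clustering recovers separated blocks", {
  d <- matrix(1, 10, 10)
  d[1:5, 1:5] <- 0; d[6:10, 6:10] <- 0
  diag(d) <- 0
  dimnames(d) <- list(paste0("f", 1:10), paste0("f", 1:10))
  cl <- cluster_fixed_k(d, 2)
  expect_length(unique(cl$labels[1:5]), 1L)
  expect_length(unique(cl$labels[6:10]), 1L)
  expect_false(cl$labels[1] == cl$labels[6])

  expect_length(unique(cluster_fixed_k(d, 1)$labels), 1L)
  expect_length(unique(cluster_fixed_k(d, 10)$labels), 10L)
  expect_error(cluster_fixed_k(d, 11), "exceeds")
})

test_that("eigenproteins summarize modules with the documented conventions", {
  set.seed(24)
  base <- rnorm(20)
  m <- rbind(f1 = base, f2 = 2 * base + 3, f3 = -base + 1)
  colnames(m) <- paste0("s", 1:20)
  attr(m, "scale_tag") <- "log2_centered"
  ep <- module_eigenprotein(m, c("f1", "f2"))
  expect_equal(ep$variance_explained, 1.0, tolerance = 1e-12)
  expect_gt(cor(ep$eigenprotein, base), 0.999)

  # two orthogonal equal-variance features split the variance evenly
  x <- scale(cbind(rnorm(50)))[, 1]
  y <- scale(cbind(residuals(lm(rnorm(50) ~ x))))[, 1]
  m2 <- rbind(f1 = x, f2 = y)
  colnames(m2) <- paste0("s", 1:50)
  attr(m2, "scale_tag") <- "log2_centered"
  ep2 <- module_eigenprotein(m2, c("f1", "f2"))
  expect_equal(ep2$variance_explained, 0.5, tolerance = 1e-10)

  # negating the member rows negates the eigenprotein
  m3 <- -m
  attr(m3, "scale_tag") <- "log2_centered"
  ep3 <- module_eigenprotein(m3, c("f1", "f2"))
  expect_equal(ep3$eigenprotein, -ep$eigenprotein, tolerance = 1e-10)
})

test_that("eigenprotein-phenotype association flags and powers correctly", {
  set.seed(25)
  n <- 60L
  cd3 <- rep(c(0, 1), each = n / 2)
  E <- rbind(M1 = rnorm(n), M2 = rnorm(n), M3 = rnorm(n) + 0.8 * cd3)
  colnames(E) <- paste0("s", 1:n)
  res <- module_phenotype_assoc(E, list(cd3 = cd3))
  expect_equal(nrow(res), 3L)
  expect_false(any(res$skipped))
  expect_true(all(res$adj_p >= res$p - 1e-15))

  # constant phenotype is skipped with a flag
  res0 <- module_phenotype_assoc(E, list(cd3 = rep(1, n)))
  expect_true(all(res0$skipped))

  # identical eigenprotein across groups: effect and t at zero
  E2 <- rbind(M1 = rep(c(1, -1), n / 2), M2 = rnorm(n))
  colnames(E2) <- paste0("s", 1:n)
  resn <- module_phenotype_assoc(E2, list(cd3 = cd3))
  expect_lt(abs(resn$effect[1]), 1e-12)
})

test_that("planted CD3-linked module is detected in most seeded replicates", {
  set.seed(26)
  n_rep <- 100L
  ps <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 100L                      # one stage-1 donor's worth of islets
    u <- runif(n)
    cd3 <- rbinom(n, 1, plogis(-2 + 4 * u))
    imm <- scale(u + rnorm(n, sd = 0.25))[, 1]
    E <- rbind(M1 = imm, M2 = rnorm(n), M3 = rnorm(n), M4 = rnorm(n))
    colnames(E) <- paste0("s", 1:n)
    ps[r] <- module_phenotype_assoc(E, list(cd3 = cd3))$adj_p[1]
  }
  expect_gte(mean(ps < 0.05, na.rm = TRUE), 0.95)
})

test_that("ORA matches the exact hypergeometric sum", {
  universe <- paste0("g", 1:20)
  set5 <- paste0("g", 1:5)
  module <- paste0("g", c(1:4, 10))
  res <- ora(module, universe, list(S = set5), min_overlap = 2L)
  manual <- (choose(5, 4) * choose(15, 1) + choose(5, 5) * choose(15, 0)) /
    choose(20, 5)
  expect_equal(res$p, manual, tolerance = 1e-12)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)

  # zero overlap and exhaustive draw both give p = 1
  res0 <- ora(paste0("g", 11:15), universe, list(S = paste0("g", 1:5)),
              min_overlap = 2L)
  expect_equal(res0$p, 1)
  resU <- ora(universe, universe, list(S = set5), min_overlap = 2L)
  expect_equal(resU$p, 1)
  expect_equal(resU$overlap, 5L)

  expect_error(ora("g1", character(0), list(S = set5)), "empty universe")
  expect_error(ora("zz", universe, list(S = set5)), "outside the universe")
})

test_that("scale-free power selection prefers structured networks", {
  set.seed(27)
  # modular correlation structure reaches the fit target at a moderate power
  f <- matrix(rnorm(40 * 3), 3, 40)
  load <- matrix(0, 90, 3)
  for (k in 1:3) load[((k - 1) * 30 + 1):(k * 30), k] <- runif(30, 0.8, 1.2)
  m <- load %*% f + matrix(rnorm(90 * 40, sd = 0.4), 90)
  dimnames(m) <- list(paste0("f", 1:90), paste0("s", 1:40))
  attr(m, "scale_tag") <- "log2_centered"
  corr <- cor_matrix(m, method = "pearson")
  ps <- pick_soft_power(corr, powers = 1:20, fallback = 12)
  expect_true(ps$power %in% 1:20)
  expect_true(is.data.frame(ps$fits))
})
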