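test_that("RFE size sequence follows the floor rule down to the target", {
  expect_identical(rfe_sizes(100, 0.10, 60), c(100L, 90L, 81L, 73L, 66L, 60L))
  expect_identical(rfe_sizes(60, 0.10, 60), 60L)
  expect_identical(rfe_sizes(40, 0.10, 60), 40L)
  # drop is at least one feature per step
  expect_identical(rfe_sizes(8, 0.10, 5), c(8L, 7L, 6L, 5L))
})

test_that("nested RFE finds a perfectly separating feature and is seeded", {
  set.seed(51)
  n <- 60L
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  x[, "f7"] <- ifelse(y == "b", 3, -3) + rnorm(n, sd = 0.1)
  cfg <- rf_config(n_trees = 100L, tune_evals = 2L, inner_folds = 3L,
                   outer_folds = 3L, rfe_target = 5L, seed = 9L)
  res <- rf_rfe_outer(x, y, cfg)
  expect_length(res$ranked_lists, 3L)
  expect_true(all(lengths(res$ranked_lists) == 5L))
  expect_true(all(vapply(res$ranked_lists, function(l) l[1L] == "f7", TRUE)))
  expect_true(all(res$outer_auroc > 0.9))

  res2 <- rf_rfe_outer(x, y, cfg)
  expect_identical(res$ranked_lists, res2$ranked_lists)

  expect_error(rf_rfe_outer(x, rep("a", n), cfg), "two classes")
  x[2, 3] <- NA
  expect_error(rf_rfe_outer(x, y, cfg), "missing")
})

test_that("robust rank aggregation matches closed-form beta order statistics", {
  # single list: rho equals the normalized rank, order preserved
  l1 <- list(c("a", "b", "c"))
  res1 <- rra(l1, universe_size = 3L)
  expect_identical(res1$feature, c("a", "b", "c"))
  expect_equal(res1$rho, c(1, 2, 3) / 3, tolerance = 1e-12)

  # consistently 1st of 100 in 5 lists: rho = 0.01^5, corrected = 5e-10
  lists <- rep(list(c("top", paste0("x", 1:9))), 5L)
  res <- rra(lists, universe_size = 100L)
  top <- res[res$feature == "top", ]
  expect_equal(top$rho, 1e-10, tolerance = 1e-12)
  expect_equal(top$score, 5e-10, tolerance = 1e-12)
  # hand evaluation over all k: min(1-(1-r)^5, ..., r^5) at r = 0.01
  ks <- 1:5
  expect_equal(top$rho, min(pbeta(0.01, ks, 5 - ks + 1)), tolerance = 1e-15)

  # a feature absent everywhere would score 1; last-ranked scores at the
  # worst end and corrected scores stay in (0, 1]
  expect_true(all(res$score > 0 & res$score <= 1))

  # permuting the lists leaves scores unchanged
  set.seed(52)
  rl <- lapply(1:6, function(i) sample(paste0("g", 1:30), 20))
  a <- rra(rl, 30L)
  b <- rra(rev(rl), 30L)
  expect_identical(a, b)

  expect_error(rra(list(c("a", "a", "b"))), "duplicates")
})

test_that("panel selection aggregates by sample-wise median", {
  m <- rbind(g1 = c(1, 2, 10), g2 = c(2, 2, 2), g3 = c(10, 2, 1))
  colnames(m) <- paste0("s", 1:3)
  attr(m, "scale_tag") <- "log2_centered"
  tab <- data.frame(feature = c("g1", "g2", "g3"), score = c(0.1, 0.2, 0.3))
  p1 <- select_panel(tab, 1L, m)
  expect_equal(unname(p1$centroid), unname(m["g1", ]))
  p3 <- select_panel(tab, 3L, m)
  expect_equal(unname(p3$centroid), c(2, 2, 2))
  expect_error(select_panel(tab, 4L, m), "exceeds")

  # medians ignore missing members; all-missing samples get NA
  m2 <- m; m2["g1", 1] <- NA; m2[, 3] <- NA
  attr(m2, "scale_tag") <- "log2_centered"
  p <- suppressMessages(select_panel(tab, 3L, m2))
  expect_equal(unname(p$centroid[1]), median(c(2, 10)))
  expect_true(is.na(p$centroid[3]))
})

test_that("beta-cell profile ranks by mean anchor correlation", {
  set.seed(53)
  n <- 40L
  v <- runif(n)
  ins <- 2 * v + rnorm(n, sd = 0.1)
  entpd3 <- 1.8 * v + rnorm(n, sd = 0.1)
  good <- 1.5 * v + rnorm(n, sd = 0.2)
  noise <- matrix(rnorm(6 * n), 6, dimnames = list(paste0("n", 1:6), NULL))
  m <- rbind(INS = ins, ENTPD3 = entpd3, GOOD = good, noise)
  colnames(m) <- paste0("s", 1:n)
  attr(m, "scale_tag") <- "log2_centered"
  p <- bcp_select(m, k = 3L)
  expect_setequal(p$members, c("INS", "ENTPD3", "GOOD"))
  # anchors score their self-correlation
  expect_equal(unname(p$mean_cor["INS"]),
               mean(c(1, cor(ins, entpd3))), tolerance = 1e-12)
  expect_error(bcp_select(m[-1, ], k = 2L), "INS")
})

test_that("low-insulin rule uses a strict -2 log2 cutoff", {
  x <- c(a = -2.1, b = -2.0, c = -1.9, d = 0, e = -3)
  f <- low_insulin_flag(x)
  expect_identical(unname(f), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(sum(low_insulin_flag(c(-3, -1, 0))), 1L)
  expect_error(low_insulin_flag(c(NA_real_, NA_real_)), "missing")
})

test_that("composition estimates are normalized marker sums", {
  expect_equal(composition_estimate(list(alpha = 1, beta = 3)),
               c(alpha = 0.25, beta = 0.75))
  expect_equal(unname(composition_estimate(list(beta = c(2, 3)))), 1)
  expect_equal(unname(composition_estimate(list(a = c(0, 0), b = 5))["a"]), 0)
  expect_error(composition_estimate(list(a = 0, b = 0)), "zero")
})

test_that("pseudo-temporal ordering is monotone with stable tertiles", {
  cen <- c(s2 = 0, s1 = -1, s3 = 1)
  out <- pseudo_temporal_order(cen)
  expect_identical(out$sample, c("s1", "s2", "s3"))
  expect_identical(out$tertile, c("low", "moderate", "high"))
  rev <- pseudo_temporal_order(-cen)
  expect_identical(rev$sample, c("s3", "s2", "s1"))
  # degenerate constant centroid: stable by sample ID
  const <- c(b = 1, a = 1, c = 1)
  expect_identical(pseudo_temporal_order(const)$sample, c("a", "b", "c"))
})

test_that("replicate QC separates duplicates from orthogonal profiles", {
  set.seed(54)
  prof <- rnorm(200)
  m <- cbind(r1 = prof, r2 = prof, i1 = rnorm(200), i2 = rnorm(200))
  rownames(m) <- paste0("f", 1:200)
  attr(m, "scale_tag") <- "log2"
  meta <- data.frame(sample_id = colnames(m), donor_id = "d1", group = "stage1",
                     block = "b1", cd3 = 0L, is_reference = c(1L, 1L, 0L, 0L))
  qc <- replicate_qc(m, meta)
  expect_equal(qc$reference_cor["r1", "r2"], 1.0, tolerance = 1e-12)
  expect_lt(abs(qc$islet_cor["i1", "i2"]), 0.2)
  meta$is_reference <- c(1L, 0L, 0L, 0L)
  expect_warning(replicate_qc(m, meta), "skipped")
})

test_that("candidate pool unions enriched modules and applies the missing rule", {
  feats <- paste0("g", 1:12)
  m <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(feats, paste0("s", 1:8)))
  m["g3", 1:3] <- NA  # 75% missing in donor A
  attr(m, "scale_tag") <- "log2_centered"
  meta <- data.frame(sample_id = colnames(m),
                     donor_id = rep(c("A", "B"), each = 4L),
                     group = rep(c("stage1", "nd"), each = 4L),
                     block = "b", cd3 = 0L, is_reference = 0L)
  labs <- stats::setNames(rep(c("M1", "M2"), each = 6L), feats)
  oraA <- list(M1 = data.frame(set = "IMMUNE", set_size = 5L, overlap = 4L,
                               p = 1e-4, adj_p = 1e-3),
               M2 = data.frame(set = "IMMUNE", set_size = 5L, overlap = 0L,
                               p = 1, adj_p = 1))
  pool <- candidate_pool(list(A = labs), list(A = oraA), m, meta,
                         immune_sets = "IMMUNE")
  expect_setequal(pool$members, setdiff(paste0("g", 1:6), "g3"))
  expect_identical(pool$enriched_modules$A, "M1")
  oraA$M1$adj_p <- 0.2
  expect_error(candidate_pool(list(A = labs), list(A = oraA), m, meta,
                              immune_sets = "IMMUNE"), "empty candidate pool")
})

test_that("donor-median imputation fills within donors first", {
  m <- rbind(f1 = c(1, 3, NA, 10, 20, NA))
  colnames(m) <- paste0("s", 1:6)
  attr(m, "scale_tag") <- "log2"
  meta <- data.frame(sample_id = colnames(m),
                     donor_id = rep(c("A", "B"), each = 3L),
                     group = "stage1", block = "b", cd3 = 0L, is_reference = 0L)
  out <- impute_donor_median(m, meta)
  expect_equal(unname(out[1, 3]), 2)   # median of donor A
  expect_equal(unname(out[1, 6]), 15)  # median of donor B
})
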