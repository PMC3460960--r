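test_that("ROC endpoints, perfect separation and all-tie behavior", {
  lab <- rep(c("case", "control"), c(5, 5))
  r <- roc_auc(c(6:10, 1:5), lab)
  expect_equal(r$auc, 1)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
  expect_equal(roc_auc(rep(2, 10), lab)$auc, 0.5)
  expect_error(roc_auc(1:5, rep("case", 5)), "both classes")
})

test_that("AUC equals the pairwise Mann-Whitney enumeration", {
  set.seed(41)
  for (trial in 1:10) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    scores <- c(rnorm(n1, 0.5), rnorm(n0))
    scores <- round(scores, 1)  # induce ties
    lab <- rep(c("case", "control"), c(n1, n0))
    u <- 0
    for (i in 1:n1) for (j in 1:n0) {
      xi <- scores[i]; yj <- scores[n1 + j]
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    }
    r <- roc_auc(scores, lab)
    expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-12)
    # trapezoid area under the empirical curve agrees
    trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
  }
})

test_that("DeLong comparison is symmetric, null-consistent, non-negative", {
  set.seed(42)
  lab <- rep(c("case", "control"), c(30, 30))
  a <- c(rnorm(30, 1), rnorm(30))
  b <- 0.5 * a + rnorm(60, sd = 0.8)
  same <- delong_compare(a, a, lab)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  fwd <- delong_compare(a, b, lab)
  rev <- delong_compare(b, a, lab)
  expect_equal(fwd$z, -rev$z)
  expect_equal(fwd$p, rev$p)
  expect_gte(fwd$se, 0)
  expect_error(delong_compare(a, b[1:10], lab), "identical samples")
})

test_that("DeLong agrees with the independent pROC implementation", {
  set.seed(43)
  for (trial in 1:5) {
    lab <- rep(c("case", "control"), c(25, 25))
    a <- c(rnorm(25, 0.8), rnorm(25))
    b <- c(rnorm(25, 0.4), rnorm(25))
    ours <- delong_compare(a, b, lab)
    ref <- pROC::roc.test(
      pROC::roc(lab, a, levels = c("control", "case"), direction = "<",
                quiet = TRUE),
      pROC::roc(lab, b, levels = c("control", "case"), direction = "<",
                quiet = TRUE),
      method = "delong")
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("covariate correlation is flagged and affine-invariant", {
  set.seed(44)
  m <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(paste0("g", 1:20), NULL))
  covariate <- m[7, ]  # identical to one probe
  prof <- correlate_covariate(m, covariate)
  expect_equal(prof$r[7], 1)
  expect_true(prof$flagged[7])
  prof2 <- correlate_covariate(m, 3 * covariate - 10)
  expect_equal(prof$r, prof2$r, tolerance = 1e-12)
  expect_error(correlate_covariate(m, rep(1, 30)), "constant")
  expect_error(correlate_covariate(m, c(covariate[1:2], rep(NA, 28))),
               "at least 3")
  # missing covariate values are excluded pairwise
  cv_na <- covariate; cv_na[1:5] <- NA
  expect_equal(attr(correlate_covariate(m, cv_na), "n_used"), 25)
})

test_that("the resampling null matches the analytic flagged fraction", {
  set.seed(45)
  n <- 39
  m <- matrix(rnorm(395 * n), 395, n,
              dimnames = list(paste0("g", 1:395), NULL))
  covariate <- rnorm(n)
  null <- resample_covariate_null(m, covariate, n_reps = 100, seed = 9)
  r_crit <- 0.4
  t_crit <- r_crit * sqrt((n - 2) / (1 - r_crit^2))
  analytic <- 2 * pt(t_crit, n - 2, lower.tail = FALSE)
  se <- sd(null$fractions) / sqrt(length(null$fractions))
  expect_lt(abs(mean(null$fractions) - analytic), max(2 * se, 0.003))
  # seeded reproducibility
  null2 <- resample_covariate_null(m, covariate, n_reps = 100, seed = 9)
  expect_identical(null$fractions, null2$fractions)
})

test_that("a planted covariate effect exceeds the resampled null", {
  set.seed(46)
  n <- 45
  covariate <- rnorm(n, 65, 9)
  m <- matrix(rnorm(100 * n, 7, 0.6), 100, n,
              dimnames = list(paste0("g", 1:100), NULL))
  for (g in 1:20) m[g, ] <- m[g, ] + 0.08 * (covariate - 65)
  null <- resample_covariate_null(m, covariate, n_reps = 100, seed = 10)
  expect_gt(null$observed, null$q95)
})

test_that("average-linkage heights match a brute-force recomputation", {
  set.seed(47)
  m <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(paste0("g", 1:8),
                                                  paste0("s", 1:6)))
  res <- hierarchical_cluster(m, "samples")
  # naive average-linkage agglomeration on the correlation distance
  D <- 1 - cor(m)
  active <- as.list(1:6)
  heights <- numeric(0)
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- mean(D[active[[i]], active[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    heights <- c(heights, best[1])
    active[[best[2]]] <- c(active[[best[2]]], active[[best[3]]])
    active[[best[3]]] <- NULL
  }
  expect_equal(res$heights, heights, tolerance = 1e-12)
})

test_that("optimal leaf ordering improves on the default order", {
  set.seed(48)
  m <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  res <- hierarchical_cluster(m, "samples")
  D <- 1 - cor(m)
  cost <- function(ord) sum(D[cbind(ord[-length(ord)], ord[-1])])
  default_hc <- hclust(as.dist(D), method = "average")
  expect_lte(res$objective, cost(default_hc$order) + 1e-12)
  expect_equal(res$objective, cost(res$order))
  # duplicated sample merges first at height zero
  m2 <- cbind(m, dup = m[, 3])
  res2 <- hierarchical_cluster(m2, "samples")
  expect_equal(min(res2$heights), 0, tolerance = 1e-12)
  # affine per-item transformations leave the tree unchanged
  m3 <- sweep(sweep(m, 2, runif(12, 0.5, 2), "*"), 2, rnorm(12), "+")
  res3 <- hierarchical_cluster(m3, "samples")
  expect_equal(res3$heights, res$heights, tolerance = 1e-10)
  # constant profile gets maximal distance with a warning
  m4 <- m; m4[, 5] <- 3
  expect_warning(hierarchical_cluster(m4, "samples"), "constant")
})

test_that("newick export is a parseable tree with all leaves", {
  m <- matrix(rnorm(6 * 5), 6, 5,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  res <- hierarchical_cluster(m, "samples")
  tree <- ape::read.tree(text = dendrogram_newick(res$hclust))
  expect_setequal(tree$tip.label, paste0("s", 1:5))
})

test_that("platform concordance statistics behave as defined", {
  sig <- c(5, 6, 7, 8, 9)
  cq <- 30 - 1.5 * sig
  res <- platform_concordance(cq, sig)
  expect_equal(res$r, -1)
  expect_equal(res$amplification, 1.5)
  expect_equal(platform_concordance(sig, sig)$amplification, 1)
  expect_error(platform_concordance(1:2, 1:2), "at least 3")

  # Fisher-z CI: simulation check of its 95% coverage at n = 11
  set.seed(49)
  rho <- -0.7
  hits <- replicate(2000, {
    z <- matrix(rnorm(22), 11, 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
    ci <- platform_concordance(z[, 1], z[, 2])[, c("ci_lo", "ci_hi")]
    ci$ci_lo <= rho && rho <= ci$ci_hi
  })
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)

  # per-molecule grouping returns one row each
  s2 <- rnorm(11, 7, 1)
  cq2 <- 28 - 1.8 * s2 + rnorm(11, 0, 0.8)
  res_g <- platform_concordance(c(cq, cq2), c(sig, s2),
                                rep(c("m1", "m2"), c(5, 11)))
  expect_equal(nrow(res_g), 2)
})
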