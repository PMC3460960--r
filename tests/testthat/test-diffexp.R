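test_that("variance prior handles zero excess dispersion", {
  prior <- fit_moderated_prior(rep(0.05, 100), residual_df = 43)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0_sq, 0.05)
  expect_error(fit_moderated_prior(c(-1, rep(1, 20)), 10), "positive")
  expect_error(fit_moderated_prior(rep(1, 5), 10), "at least 10")
})

test_that("variance prior recovers planted hyperparameters", {
  set.seed(11)
  d0 <- 4; s0 <- 0.05; df <- 43
  # gene variances: s0^2 * F-draws, i.e. scaled chi-square ratio
  s2 <- s0 * stats::rchisq(2000, df) / df /
    (stats::rchisq(2000, d0) / d0)
  prior <- fit_moderated_prior(s2, df)
  expect_lt(abs(prior$d0 - d0), 1)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.1)

  # self-consistency: moments of log s2 implied by the estimate match
  # the empirical moments
  e_mean <- log(prior$s0_sq) + digamma(df / 2) - log(df / 2) -
    digamma(prior$d0 / 2) + log(prior$d0 / 2)
  e_var <- trigamma(df / 2) + trigamma(prior$d0 / 2)
  expect_lt(abs(mean(log(s2)) - e_mean), 3 * sqrt(e_var / 2000))
  expect_lt(abs(var(log(s2)) / e_var - 1), 0.15)
})

test_that("moderated t reduces to the classical pooled t at d0 = 0", {
  set.seed(12)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  cls <- rep(c("case", "control"), each = 6)
  tab <- moderated_t_table(m, cls,
                           prior = structure(list(d0 = 0, s0_sq = 1),
                                             class = "moderated_prior"))
  classic <- apply(m, 1, function(x)
    t.test(x[1:6], x[7:12], var.equal = TRUE)$statistic)
  expect_equal(tab$t, unname(classic), tolerance = 1e-10)
  p_classic <- apply(m, 1, function(x)
    t.test(x[1:6], x[7:12], var.equal = TRUE)$p.value)
  expect_equal(tab$p, unname(p_classic), tolerance = 1e-10)
})

test_that("moderated t at d0 = Inf is the fixed-variance statistic", {
  set.seed(13)
  m <- matrix(rnorm(20 * 10), 20, 10)
  rownames(m) <- paste0("g", 1:20)
  cls <- rep(c("case", "control"), each = 5)
  s0 <- 0.8
  tab <- moderated_t_table(m, cls,
                           prior = structure(list(d0 = Inf, s0_sq = s0),
                                             class = "moderated_prior"))
  d <- rowMeans(m[, 1:5]) - rowMeans(m[, 6:10])
  expect_equal(tab$t, unname(d / sqrt(s0 * (2 / 5))), tolerance = 1e-12)
})

test_that("shrunken variances interpolate monotonically in d0", {
  set.seed(14)
  m <- matrix(rnorm(30 * 10, sd = rep(c(0.2, 2), 15)), 30, 10)
  rownames(m) <- paste0("g", 1:30)
  cls <- rep(c("case", "control"), each = 5)
  s0 <- 1
  grid <- c(0, 0.5, 2, 8, 32, Inf)
  s2t <- sapply(grid, function(d0)
    moderated_t_table(m, cls, structure(list(d0 = d0, s0_sq = s0),
                                        class = "moderated_prior"))$s2_tilde)
  for (g in 1:30) {
    path <- s2t[g, ]
    expect_true(all(diff(path) >= -1e-12) || all(diff(path) <= 1e-12))
    expect_equal(path[length(grid)], s0)
  }
})

test_that("a probe with identical group means gets t = 0, p = 1", {
  set.seed(19)
  m <- rbind(g1 = rep(c(1, 2), 5),
             matrix(rnorm(110), 11, 10,
                    dimnames = list(paste0("g", 2:12), NULL)))
  cls <- rep(c("case", "control"), each = 5)
  m[1, cls == "case"] <- m[1, cls == "control"]
  tab <- moderated_t_table(m, cls)
  expect_equal(tab$t[1], 0)
  expect_equal(tab$p[1], 1)
})

test_that("BH step-up equals hand computation and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(15)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Wilcoxon p-values match exact enumeration and approximation", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  cls <- c("case", "case", "case", "control", "control", "control")
  expect_equal(unname(wilcoxon_table(m, cls)), 0.1)  # 2/20 orderings

  m2 <- rbind(g1 = rep(c(5, 7), 5))
  cls2 <- rep(c("case", "control"), 5)
  m2[1, ] <- rep(4, 10)
  expect_equal(unname(wilcoxon_table(m2, cls2)), 1)

  # approximation against the exact distribution at n1 = n2 = 8; the
  # worst-case deviation of the continuity-corrected normal tail over
  # the W grid at this size is just above 0.01
  set.seed(16)
  deltas <- sapply(1:10, function(i) {
    x <- rnorm(16)
    exact <- wilcox.test(x[1:8], x[9:16], exact = TRUE)$p.value
    approx <- wilcox.test(x[1:8], x[9:16], exact = FALSE,
                          correct = TRUE)$p.value
    abs(exact - approx)
  })
  expect_lt(max(deltas), 0.015)
  expect_lt(median(deltas), 0.01)
})

test_that("fold-changes reproduce printed group-mean arithmetic", {
  # group means set to printed values for the extreme rows
  m <- rbind(mir144 = rep(c(143.57, 267.88), c(4, 4)),
             mirplus = rep(c(211.82, 133.2), c(4, 4)))
  cls <- rep(c("case", "control"), c(4, 4))
  fc <- fold_changes(m, cls)
  expect_equal(fc$fold_change_display, c(0.54, 1.59))
  expect_equal(fc$mean_case, c(143.57, 211.82))

  m_eq <- rbind(g = rep(5, 8))
  expect_equal(fold_changes(m_eq, cls)$fold_change, 1)
  expect_error(fold_changes(rbind(g = c(-1, rep(1, 7))), cls), "positive")
})

test_that("cohort summary tests reproduce the summary-based pooled t", {
  res <- pooled_t_from_summary(22, 6.7, 1.8, 17, 7.7, 2.7)
  expect_equal(round(res$p, 2), 0.17)

  res_eq <- pooled_t_from_summary(10, 5, 1, 10, 5, 1)
  expect_equal(res_eq$t, 0)
  expect_equal(res_eq$p, 1)

  set.seed(17)
  sheet <- sample_sheet(sprintf("s%02d", 1:45),
                        rep(c("case", "control"), c(22, 23)),
                        age = runif(45, 40, 85),
                        gender = sample(c("M", "F"), 45, TRUE),
                        smoking = sample(c(TRUE, FALSE), 45, TRUE),
                        wbc = rnorm(45, 7, 2),
                        platelets = rnorm(45, 250, 70),
                        hemoglobin = rnorm(45, 13.5, 1.3))
  tab <- cohort_summary_tests(sheet)
  expect_true(all(c("age", "wbc", "gender", "smoking") %in% tab$variable))
  # age row equals direct pooled computation
  a <- sheet$age[sheet$class == "case"]; b <- sheet$age[sheet$class == "control"]
  direct <- pooled_t_from_summary(22, mean(a), sd(a), 23, mean(b), sd(b))
  expect_equal(tab$p[tab$variable == "age"], direct$p)
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  tab <- matrix(c(12, 10, 12, 11), 2)
  # enumerate all tables with the observed margins; two-sided p sums the
  # probabilities of tables no more probable than the observed one
  enum_p <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab)
    a_obs <- tab[1, 1]
    a_all <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    pr <- dhyper(a_all, rs[1], rs[2], cs[1])
    sum(pr[pr <= dhyper(a_obs, rs[1], rs[2], cs[1]) * (1 + 1e-7)])
  }
  expect_equal(fisher.test(tab)$p.value, enum_p(tab), tolerance = 1e-10)
})

test_that("moderated-t and Wilcoxon discovery sets overlap on strong effects", {
  lm <- latent_matrix(n_probes = 200, n_case = 22, n_control = 23,
                      lfc = 1.5, n_de = 40, seed = 18, noise = 0.6)
  de <- differential_expression(2^lm$matrix, lm$classes)
  hits_t <- de$probe_id[de$q < 0.05]
  hits_w <- de$probe_id[de$wilcoxon_q < 0.05]
  expect_gt(length(hits_t), 20)
  expect_gt(length(intersect(hits_t, hits_w)) / length(hits_t), 0.9)
})
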