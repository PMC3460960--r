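#' Fit the empirical-Bayes variance prior
#'
#' Gene-wise sample variances are modeled as draws from a scaled
#' F-distribution around a scaled inverse-chi-square prior with
#' hyperparameters (d0, s0^2). The hyperparameters are estimated by
#' matching the first two moments of log sample variances to the
#' theoretical log-F distribution via the digamma/trigamma relations:
#' with e_g = log(s_g^2) - digamma(df/2) + log(df/2),
#' var(e) - trigamma(df/2) estimates trigamma(d0/2), and the mean of e
#' fixes s0^2. When the observed dispersion of log-variances does not
#' exceed the theoretical minimum, d0 is infinite and s0^2 is the
#' geometric mean of the sample variances (equal to the common value when
#' all variances coincide).
#'
#' @param sample_variances positive gene-wise variances (>= 10 of them).
#' @param residual_df residual degrees of freedom of each variance.
#' @return list of class \code{"moderated_prior"} with \code{d0} (possibly
#'   \code{Inf}) and \code{s0_sq}.
#' @export
fit_moderated_prior <- function(sample_variances, residual_df) {
  if (length(sample_variances) < 10)
    stop("need at least 10 variances to fit the prior", call. = FALSE)
  if (any(!is.finite(sample_variances) | sample_variances <= 0))
    stop("content error: variances must be positive and finite",
         call. = FALSE)
  df <- residual_df
  e <- log(sample_variances) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  excess <- stats::var(e) - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(log(sample_variances)))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderated_prior")
}

## solve trigamma(y) = x by Newton iteration on 1/trigamma (convex scale)
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moderated t-statistics for a two-group comparison
#'
#' Per probe: pooled two-group variance s_g^2 with df = n1 + n2 - 2,
#' shrunken variance (d0 s0^2 + df s_g^2) / (d0 + df), moderated
#' t = (mean_case - mean_control) / (s_tilde sqrt(1/n1 + 1/n2)), two-sided
#' p from the t-distribution with d0 + df degrees of freedom, and
#' Benjamini-Hochberg q-values.
#'
#' @param log2_matrix probes x samples matrix of log2 signals.
#' @param classes factor or character vector with levels
#'   \code{"control"}, \code{"case"} (one per column).
#' @param prior a \code{\link{fit_moderated_prior}} result; fitted from
#'   the data when \code{NULL}. \code{d0 = 0} reduces to the ordinary
#'   pooled-variance t; \code{d0 = Inf} uses s0^2 for every probe.
#' @return data.frame with per-probe means, variance, moderated t, p, q.
#' @export
moderated_t_table <- function(log2_matrix, classes, prior = NULL) {
  cls <- as.character(classes)
  if (!all(cls %in% c("case", "control")))
    stop("content error: classes must be 'case'/'control'", call. = FALSE)
  i1 <- which(cls == "case"); i2 <- which(cls == "control")
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2)
    stop("content error: each class needs at least 2 samples",
         call. = FALSE)
  m <- as.matrix(log2_matrix)
  mean1 <- rowMeans(m[, i1, drop = FALSE])
  mean2 <- rowMeans(m[, i2, drop = FALSE])
  v1 <- apply(m[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(m[, i2, drop = FALSE], 1, stats::var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  if (is.null(prior)) prior <- fit_moderated_prior(pmax(s2, 1e-12), df)
  d0 <- prior$d0
  s2_tilde <- if (is.infinite(d0)) rep(prior$s0_sq, length(s2))
  else (d0 * prior$s0_sq + df * s2) / (d0 + df)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, (mean1 - mean2) / se,
                  ifelse(mean1 == mean2, 0, Inf * sign(mean1 - mean2)))
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(probe_id = rownames(m),
             mean_case_log2 = mean1, mean_control_log2 = mean2,
             s2 = s2, s2_tilde = s2_tilde, t = t_mod, p = p,
             q = bh_adjust(p), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1].
#' @return monotone q-values capped at 1: q_(i) = min over j >= i of
#'   p_(j) * n / j.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("content error: p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  if (n == 0) return(numeric())
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * n / seq(n, 1)))
  q[order(o)]
}

#' Per-probe Wilcoxon rank-sum p-values
#'
#' Two-sided Mann-Whitney test per probe: exact enumeration when the
#' smaller group has at most 8 samples and the probe has no ties, the
#' normal approximation with tie correction otherwise.
#'
#' @inheritParams moderated_t_table
#' @param matrix probes x samples matrix (any monotone scale).
#' @return numeric vector of p-values, one per probe row.
#' @export
wilcoxon_table <- function(matrix, classes) {
  cls <- as.character(classes)
  i1 <- which(cls == "case"); i2 <- which(cls == "control")
  if (!length(i1) || !length(i2))
    stop("content error: both classes must be present", call. = FALSE)
  m <- as.matrix(matrix)
  small <- min(length(i1), length(i2))
  apply(m, 1, function(x) {
    x1 <- x[i1]; x2 <- x[i2]
    if (stats::sd(c(x1, x2)) == 0) return(1)  # no information in ranks
    exact <- small <= 8 && !anyDuplicated(c(x1, x2))
    suppressWarnings(stats::wilcox.test(x1, x2, exact = exact,
                                        correct = !exact)$p.value)
  })
}

#' Case/control fold-changes on the linear scale
#'
#' Ratio of the case-group mean to the control-group mean of the
#' summarized linear-scale signals.
#'
#' @param matrix_linear probes x samples matrix of positive linear-scale
#'   signals.
#' @inheritParams moderated_t_table
#' @param digits decimals for the display-rounded column (default 2).
#' @return data.frame with per-probe group means, SDs and fold-change
#'   (full precision plus a column rounded for display).
#' @export
fold_changes <- function(matrix_linear, classes, digits = 2) {
  cls <- as.character(classes)
  m <- as.matrix(matrix_linear)
  if (any(m <= 0))
    stop("content error: linear signals must be positive", call. = FALSE)
  i1 <- which(cls == "case"); i2 <- which(cls == "control")
  mean1 <- rowMeans(m[, i1, drop = FALSE])
  mean2 <- rowMeans(m[, i2, drop = FALSE])
  if (any(mean2 == 0))
    stop("content error: zero control mean", call. = FALSE)
  data.frame(probe_id = rownames(m),
             mean_case = mean1,
             sd_case = apply(m[, i1, drop = FALSE], 1, stats::sd),
             mean_control = mean2,
             sd_control = apply(m[, i2, drop = FALSE], 1, stats::sd),
             fold_change = mean1 / mean2,
             fold_change_display = round(mean1 / mean2, digits),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full differential-expression table
#'
#' Combines linear-scale group means/SDs and fold-changes with the
#' moderated-t statistics (computed on log2 signals) and Wilcoxon
#' rank-sum p-values.
#'
#' @param em an \code{\link{expression_matrix}} (the expressed subset is
#'   used when a mask is present), or a positive linear-scale matrix.
#' @inheritParams moderated_t_table
#' @return data.frame of class \code{"de_table"}.
#' @export
differential_expression <- function(em, classes, prior = NULL) {
  m <- if (inherits(em, "expression_matrix")) {
    if (!is.null(em$expressed)) em$signal[em$expressed, , drop = FALSE]
    else em$signal
  } else as.matrix(em)
  m <- pmax(m, 1e-8)  # guard; cannot occur with a positive offset
  fc <- fold_changes(m, classes)
  mt <- moderated_t_table(log2(m), classes, prior)
  out <- cbind(fc, mt[, c("t", "p", "q")])
  out$wilcoxon_p <- wilcoxon_table(log2(m), classes)
  out$wilcoxon_q <- bh_adjust(out$wilcoxon_p)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Two-sided pooled-variance t-test from group summaries
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 group sizes, means and SDs.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
pooled_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohort-comparison summary tests
#'
#' Case-vs-control tests over the sample sheet: pooled-variance two-sided
#' t-tests for continuous variables (age and the blood parameters,
#' missing values excluded pairwise) and Fisher's exact test for
#' categorical ones (gender, smoking).
#'
#' @param sheet a \code{\link{sample_sheet}}.
#' @return data.frame with one row per variable: test used, statistic,
#'   p-value, and the per-group n actually used.
#' @export
cohort_summary_tests <- function(sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  case <- sheet$class == "case"
  rows <- list()
  for (v in c("age", "wbc", "platelets", "hemoglobin")) {
    x1 <- sheet[[v]][case]; x2 <- sheet[[v]][!case]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) {
      warning("skipping '", v, "': fewer than 2 values per group")
      next
    }
    res <- pooled_t_from_summary(length(x1), mean(x1), stats::sd(x1),
                                 length(x2), mean(x2), stats::sd(x2))
    rows[[v]] <- data.frame(variable = v, test = "pooled_t",
                            statistic = res$t, p = res$p,
                            n_case = length(x1), n_control = length(x2),
                            stringsAsFactors = FALSE)
  }
  for (v in c("gender", "smoking")) {
    x <- sheet[[v]]
    keep <- !is.na(x)
    if (length(unique(x[keep])) < 2 || !any(keep & case) ||
        !any(keep & !case)) next
    tab <- table(factor(case[keep], c(TRUE, FALSE)), x[keep])
    res <- stats::fisher.test(tab)
    rows[[v]] <- data.frame(variable = v, test = "fisher_exact",
                            statistic = NA_real_, p = res$p.value,
                            n_case = sum(keep & case),
                            n_control = sum(keep & !case),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
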