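#' Empirical ROC curve and AUC
#'
#' ROC over all distinct score thresholds (ties contribute diagonal
#' segments); the trapezoid AUC equals the Mann-Whitney probability
#' estimate with ties counted 1/2. Per-sample structural components are
#' kept for the DeLong variance.
#'
#' @param scores numeric scores, larger = more case-like.
#' @param labels \code{"case"}/\code{"control"} per score.
#' @return object of class \code{"roc_result"} with \code{thresholds},
#'   \code{fpr}, \code{tpr}, \code{auc} and structural components
#'   \code{v10} (cases), \code{v01} (controls).
#' @export
roc_auc <- function(scores, labels) {
  lab <- as.character(labels)
  if (any(!is.finite(scores)))
    stop("content error: scores must be finite", call. = FALSE)
  x <- scores[lab == "case"]; y <- scores[lab == "control"]
  if (!length(x) || !length(y))
    stop("content error: both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(x >= t), 0)
  fpr <- vapply(thr, function(t) mean(y >= t), 0)
  ## Mann-Whitney placements: psi = 1 if x > y, 1/2 if tied
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = mean(cmp), v10 = rowMeans(cmp), v01 = colMeans(cmp),
                 n_case = length(x), n_control = length(y)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d cases, %d controls)\n", x$auc,
              x$n_case, x$n_control))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two scores measured on the same samples using
#' the DeLong structural-component covariance estimate; the test is
#' symmetric in its two score arguments.
#'
#' @param scores_a,scores_b paired scores on identical samples.
#' @param labels shared \code{"case"}/\code{"control"} labels.
#' @return list with \code{auc_a}, \code{auc_b}, \code{diff}, \code{se},
#'   \code{z}, two-sided \code{p}, and a 95\% CI for the difference.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("content error: scores and labels must be paired on identical ",
         "samples", call. = FALSE)
  ra <- roc_auc(scores_a, labels)
  rb <- roc_auc(scores_b, labels)
  n1 <- ra$n_case; n0 <- ra$n_control
  s10 <- stats::cov(cbind(ra$v10, rb$v10))
  s01 <- stats::cov(cbind(ra$v01, rb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  v <- max(v, 0)
  d <- ra$auc - rb$auc
  se <- sqrt(v)
  z <- if (se == 0) { if (d == 0) 0 else Inf * sign(d) } else d / se
  list(auc_a = ra$auc, auc_b = rb$auc, diff = d, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       ci = d + c(-1, 1) * 1.96 * se)
}

#' Correlation profile of expression with a covariate
#'
#' Pearson correlation of each probe's log2 signal with a sample-level
#' covariate, over the samples with a non-missing covariate value
#' (pairwise-complete); probes with |r| above the threshold are flagged.
#'
#' @param matrix_log2 probes x samples matrix of log2 signals.
#' @param covariate numeric per-sample covariate (NA allowed).
#' @param threshold flagging threshold on |r| (default 0.4).
#' @return data.frame of class \code{"correlation_profile"} with columns
#'   \code{probe_id}, \code{r}, \code{flagged}; attributes \code{n_used},
#'   \code{threshold}, \code{flagged_fraction}.
#' @export
correlate_covariate <- function(matrix_log2, covariate, threshold = 0.4) {
  m <- as.matrix(matrix_log2)
  keep <- !is.na(covariate)
  if (sum(keep) < 3)
    stop("content error: need at least 3 pairwise-complete observations",
         call. = FALSE)
  cov_used <- covariate[keep]
  if (stats::sd(cov_used) == 0)
    stop("content error: covariate is constant", call. = FALSE)
  r <- as.numeric(stats::cor(t(m[, keep, drop = FALSE]), cov_used))
  out <- data.frame(probe_id = rownames(m), r = r,
                    flagged = abs(r) > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "n_used") <- sum(keep)
  attr(out, "threshold") <- threshold
  attr(out, "flagged_fraction") <- mean(out$flagged)
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Resampling null for the covariate flagged fraction
#'
#' Permutes the covariate values across samples and recomputes the
#' fraction of probes with |r| above the threshold, giving the null
#' distribution against which an observed flagged fraction is judged.
#'
#' @inheritParams correlate_covariate
#' @param n_reps number of permutations (default 200).
#' @param seed optional integer seed.
#' @return list with \code{fractions} (null draws), \code{observed},
#'   \code{q95} and the permutation p-value of the observed fraction.
#' @export
resample_covariate_null <- function(matrix_log2, covariate, threshold = 0.4,
                                    n_reps = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  observed <- attr(correlate_covariate(matrix_log2, covariate, threshold),
                   "flagged_fraction")
  keep <- which(!is.na(covariate))
  fractions <- vapply(seq_len(n_reps), function(i) {
    perm <- covariate
    perm[keep] <- covariate[sample(keep)]
    attr(correlate_covariate(matrix_log2, perm, threshold),
         "flagged_fraction")
  }, 0)
  list(fractions = fractions, observed = observed,
       q95 = stats::quantile(fractions, 0.95, names = FALSE),
       p = (1 + sum(fractions >= observed)) / (1 + n_reps))
}

#' Hierarchical clustering with correlation distance and optimal leaf order
#'
#' Items (samples or probes) are clustered with distance
#' 1 - Pearson r between their profiles and average linkage; items with a
#' constant profile (undefined r) are assigned the maximal distance 2
#' with a warning. The leaf order is then optimized to minimize the sum
#' of adjacent-leaf distances among all orders consistent with the tree
#' (exact dynamic program over subtree endpoint pairs).
#'
#' @param matrix_log2 probes x samples matrix.
#' @param axis cluster \code{"samples"} (columns) or \code{"probes"}
#'   (rows).
#' @return list with the \code{hclust} object (its \code{order} replaced
#'   by the optimized one), \code{labels} in optimized order,
#'   \code{heights}, and the adjacent-distance \code{objective}.
#' @export
hierarchical_cluster <- function(matrix_log2, axis = c("samples", "probes")) {
  axis <- match.arg(axis)
  m <- as.matrix(matrix_log2)
  profiles <- if (axis == "samples") m else t(m)  # columns = items
  if (ncol(profiles) < 2) stop("need at least 2 items", call. = FALSE)
  constant <- apply(profiles, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(profiles))
  D <- 1 - r
  if (any(constant)) {
    warning(sum(constant), " item(s) with constant profile assigned ",
            "maximal correlation distance 2")
    D[constant, ] <- 2; D[, constant] <- 2
  }
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ord <- optimal_leaf_order(hc, D)
  hc$order <- ord
  list(hclust = hc, labels = hc$labels[ord], heights = hc$height,
       order = ord,
       objective = sum(D[cbind(ord[-length(ord)], ord[-1])]))
}

## exact optimal leaf ordering (dynamic program over subtree endpoints):
## for every node, the minimal path cost of its leaf sequence for each
## (first leaf, last leaf) pair; children may be swapped freely.
optimal_leaf_order <- function(hc, D) {
  n <- nrow(D)
  solve_node <- function(v) {
    if (v < 0) {
      leaf <- -v
      M <- matrix(0, 1, 1, dimnames = list(leaf, leaf))
      return(list(leaves = leaf, M = M,
                  bp = array(NA_integer_, c(1, 1, 2))))
    }
    A <- solve_node(hc$merge[v, 1])
    B <- solve_node(hc$merge[v, 2])
    la <- A$leaves; lb <- B$leaves
    M <- matrix(Inf, length(la) + length(lb), length(la) + length(lb),
                dimnames = list(c(la, lb), c(la, lb)))
    bp <- array(NA_integer_, c(nrow(M), nrow(M), 2))
    for (ii in seq_along(la)) for (jj in seq_along(lb)) {
      ## best bridge (k in A, h in B) for a sequence i .. k | h .. j
      inner <- outer(A$M[ii, ], rep(0, length(lb)), "+") +
        D[la, lb, drop = FALSE] +
        outer(rep(0, length(la)), B$M[, jj], "+")
      best <- arrayInd(which.min(inner), dim(inner))
      M[ii, length(la) + jj] <- inner[best]
      M[length(la) + jj, ii] <- inner[best]  # reversal has equal cost
      bp[ii, length(la) + jj, ] <- c(best[1], best[2])
      bp[length(la) + jj, ii, ] <- c(best[1], best[2])
    }
    list(leaves = c(la, lb), M = M, bp = bp,
         A = A, B = B, na = length(la))
  }
  root <- solve_node(nrow(hc$merge))
  reconstruct <- function(node, i, j) {
    if (length(node$leaves) == 1) return(node$leaves)
    na <- node$na
    if (i <= na) {  # starts in A, ends in B
      k <- node$bp[i, j, 1]; h <- node$bp[i, j, 2]
      c(reconstruct(node$A, i, k), reconstruct(node$B, h, j - na))
    } else {        # starts in B: reverse of (j .. i)
      rev(reconstruct(node, j, i))
    }
  }
  best <- arrayInd(which.min(root$M + diag(Inf, nrow(root$M))),
                   dim(root$M))
  ord <- reconstruct(root, best[1], best[2])
  stopifnot(length(ord) == n, !anyDuplicated(ord))
  ord
}

#' Export a clustering as newick text with node heights
#'
#' @param hc an \code{hclust} object (e.g. from
#'   \code{\link{hierarchical_cluster}}).
#' @return single newick string with branch lengths derived from merge
#'   heights.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Cross-platform concordance of RT-PCR and microarray quantification
#'
#' Pearson correlation between RT-PCR quantification-cycle (Cq) values
#' and log2 microarray signals per molecule, with the Fisher-z 95\% CI
#' and the range-amplification ratio (range of Cq over range of log2
#' signal). Cq is inversely related to abundance, so good concordance
#' shows as strongly negative r.
#'
#' @param cq numeric Cq values.
#' @param log2_signal paired log2 microarray signals.
#' @param molecule optional grouping (one value per pair); when given,
#'   one result row per molecule.
#' @return data.frame with \code{n}, \code{r}, \code{ci_lo}, \code{ci_hi},
#'   \code{p}, \code{amplification}.
#' @export
platform_concordance <- function(cq, log2_signal, molecule = NULL) {
  if (is.null(molecule)) molecule <- rep("all", length(cq))
  stopifnot(length(cq) == length(log2_signal),
            length(molecule) == length(cq))
  rows <- lapply(split(seq_along(cq), molecule), function(idx) {
    x <- cq[idx]; y <- log2_signal[idx]
    n <- length(x)
    if (n < 3)
      stop("content error: need at least 3 paired measurements",
           call. = FALSE)
    r <- stats::cor(x, y)
    z <- atanh(r)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
    p <- stats::cor.test(x, y)$p.value
    data.frame(molecule = molecule[idx[1]], n = n, r = r,
               ci_lo = ci[1], ci_hi = ci[2], p = p,
               amplification = diff(range(x)) / diff(range(y)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
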