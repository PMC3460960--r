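#' Binary classification performance metrics
#'
#' Sensitivity is computed on the case class (TP / (TP + FN)),
#' specificity on controls (TN / (TN + FP)). Values are percentages at
#' full precision; a metric whose denominator class is absent is
#' \code{NA}, not 0.
#'
#' @param predictions,truth character vectors of
#'   \code{"case"}/\code{"control"} labels.
#' @return named numeric vector: \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv} (in percent).
#' @export
performance_metrics <- function(predictions, truth) {
  if (length(truth) == 0)
    stop("content error: no predictions to score", call. = FALSE)
  tp <- sum(predictions == "case" & truth == "case")
  fn <- sum(predictions == "control" & truth == "case")
  tn <- sum(predictions == "control" & truth == "control")
  fp <- sum(predictions == "case" & truth == "control")
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(accuracy = pct(tp + tn, tp + tn + fp + fn),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn))
}

check_method <- function(method) {
  method <- method[1]
  if (!method %in% c("tsp", "svm"))
    stop("config error: unknown method '", method,
         "' (use 'tsp' or 'svm')", call. = FALSE)
  method
}

fit_and_predict <- function(matrix, classes, train, test, method, spec) {
  train_m <- matrix[, train, drop = FALSE]
  test_m <- matrix[, test, drop = FALSE]
  if (method == "tsp") {
    model <- tsp_fit(train_m, classes[train])
    list(model = model, features = model$pair,
         predicted = tsp_predict(model, test_m), probability = NA_real_)
  } else if (method == "svm") {
    model <- svm_fit(train_m, classes[train],
                     spec = if (is.null(spec)) svm_spec() else spec)
    pred <- svm_predict(model, test_m)
    list(model = model, features = model$features,
         predicted = pred$label, probability = pred$probability)
  } else stop("config error: unknown method '", method, "'", call. = FALSE)
}

cv_report <- function(method, scheme, iterations, predictions,
                      feature_counts, aggregate, per_iteration = NULL,
                      resampled = 0L, splits = NULL) {
  structure(list(method = method, scheme = scheme,
                 iterations = iterations, predictions = predictions,
                 feature_frequency = feature_counts,
                 aggregate = aggregate, per_iteration = per_iteration,
                 resampled_splits = resampled, splits = splits),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(toupper(x$scheme), "with", toupper(x$method), "-", x$iterations,
      "iterations\n")
  agg <- x$aggregate
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              agg["accuracy"], agg["sensitivity"], agg["specificity"]))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' n iterations, each fitting on n - 1 samples and predicting the
#' held-out one; aggregate metrics come from the pooled confusion matrix
#' over all n single-sample predictions.
#'
#' @param matrix probes x samples matrix (log2 scale recommended).
#' @param classes per-sample \code{"case"}/\code{"control"} labels.
#' @param method \code{"tsp"} or \code{"svm"}.
#' @param spec an \code{\link{svm_spec}} for the SVM method.
#' @param seed optional integer seed (the SVM inner folds are random).
#' @return a \code{cv_report}.
#' @export
loocv <- function(matrix, classes, method = c("tsp", "svm"), spec = NULL,
                  seed = NULL) {
  method <- check_method(method)
  m <- as.matrix(matrix)
  cls <- as.character(classes)
  n <- ncol(m)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  preds <- character(n); probs <- numeric(n)
  feats <- list()
  for (i in seq_len(n)) {
    res <- fit_and_predict(m, cls, setdiff(seq_len(n), i), i, method, spec)
    preds[i] <- res$predicted
    probs[i] <- res$probability[1]
    feats[[i]] <- res$features
  }
  predictions <- data.frame(iteration = seq_len(n),
                            sample_id = colnames(m),
                            truth = cls, predicted = preds,
                            probability = probs, stringsAsFactors = FALSE)
  counts <- table(unlist(feats))
  cv_report(method, "loocv", n, predictions,
            counts[order(-counts)], performance_metrics(preds, cls),
            splits = lapply(seq_len(n), function(i)
              list(train = setdiff(seq_len(n), i), test = i)))
}

#' Monte Carlo cross-validation
#'
#' Repeated unstratified random splits into training and test sets
#' (training draws containing a single class are resampled and counted).
#' Per-iteration metrics are aggregated as mean, range and SD across
#' iterations; a feature-frequency table counts how many of the
#' classifiers contain each probe.
#'
#' @inheritParams loocv
#' @param n_iter number of random splits (default 1000).
#' @param n_train,n_test split sizes (defaults 36 and 9).
#' @param seed integer seed for the splits.
#' @param stratified draw splits stratified by class (default FALSE,
#'   plain random assignment).
#' @return a \code{cv_report} with per-iteration metrics.
#' @export
mccv <- function(matrix, classes, method = c("tsp", "svm"), spec = NULL,
                 n_iter = 1000, n_train = 36, n_test = 9, seed = NULL,
                 stratified = FALSE) {
  method <- check_method(method)
  m <- as.matrix(matrix)
  cls <- as.character(classes)
  n <- ncol(m)
  if (n_train + n_test > n)
    stop("config error: n_train + n_test exceeds the sample count",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  per_iter <- matrix(NA_real_, n_iter, length(metric_names),
                     dimnames = list(NULL, metric_names))
  feats <- vector("list", n_iter)
  pred_rows <- vector("list", n_iter)
  splits <- vector("list", n_iter)
  resampled <- 0L
  for (it in seq_len(n_iter)) {
    repeat {
      if (stratified) {
        train <- unlist(lapply(split(seq_len(n), cls), function(idx)
          sample(idx, round(length(idx) * n_train / n))))
        train <- if (length(train) > n_train)
          sample(train, n_train) else train
        test <- sample(setdiff(seq_len(n), train), n_test)
      } else {
        perm <- sample(n)
        train <- perm[seq_len(n_train)]
        test <- perm[n_train + seq_len(n_test)]
      }
      if (length(unique(cls[train])) == 2) break
      resampled <- resampled + 1L
    }
    splits[[it]] <- list(train = train, test = test)
    res <- fit_and_predict(m, cls, train, test, method, spec)
    per_iter[it, ] <- performance_metrics(res$predicted, cls[test])
    feats[[it]] <- unique(res$features)
    pred_rows[[it]] <- data.frame(iteration = it,
                                  sample_id = colnames(m)[test],
                                  truth = cls[test],
                                  predicted = res$predicted,
                                  probability = res$probability,
                                  stringsAsFactors = FALSE)
  }
  agg <- colMeans(per_iter, na.rm = TRUE)
  summary_tab <- data.frame(
    metric = metric_names, mean = agg,
    min = apply(per_iter, 2, min, na.rm = TRUE),
    max = apply(per_iter, 2, max, na.rm = TRUE),
    sd = apply(per_iter, 2, stats::sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE)
  counts <- table(unlist(feats))
  rep <- cv_report(method, "mccv", n_iter, do.call(rbind, pred_rows),
                   counts[order(-counts)], agg,
                   per_iteration = as.data.frame(per_iter),
                   resampled = resampled, splits = splits)
  rep$summary <- summary_tab
  rep
}

#' Training-set-size sweep under Monte Carlo cross-validation
#'
#' Runs \code{\link{mccv}} at each requested training-set size with the
#' complementary test size (capped at n - size), and reports the mean and
#' normal-approximation 95\% CI of each metric plus the total number of
#' distinct features used.
#'
#' @inheritParams mccv
#' @param sizes training-set sizes to evaluate.
#' @param max_test cap on the complementary test-set size (default: use
#'   all remaining samples).
#' @return data.frame with one row per size.
#' @export
training_size_sweep <- function(matrix, classes, method = c("tsp", "svm"),
                                sizes, spec = NULL, n_iter = 100,
                                seed = NULL, max_test = Inf) {
  method <- check_method(method)
  n <- ncol(as.matrix(matrix))
  if (any(sizes < 2 | sizes > n - 1))
    stop("config error: sizes must lie in [2, n-1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(sizes, function(sz) {
    rep <- mccv(matrix, classes, method, spec, n_iter = n_iter,
                n_train = sz, n_test = min(n - sz, max_test))
    acc <- rep$per_iteration$accuracy
    se <- stats::sd(acc, na.rm = TRUE) / sqrt(sum(!is.na(acc)))
    data.frame(n_train = sz,
               accuracy = mean(acc, na.rm = TRUE),
               ci_lo = mean(acc, na.rm = TRUE) - 1.96 * se,
               ci_hi = mean(acc, na.rm = TRUE) + 1.96 * se,
               sensitivity = rep$aggregate["sensitivity"],
               specificity = rep$aggregate["specificity"],
               n_features = length(rep$feature_frequency),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
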