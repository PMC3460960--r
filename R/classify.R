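#' Fit a top-scoring-pair classifier
#'
#' For every probe pair (i, j) the primary score is
#' Delta_ij = |P(X_i < X_j | case) - P(X_i < X_j | control)|, estimated
#' from within-sample comparisons (rank-based, so any strictly monotone
#' per-sample transformation of the expression scale gives the same
#' result; ties count as "not less-than"). The pair with maximal Delta is
#' selected, ties broken by the largest average rank-difference score
#' gamma = |mean within-class rank difference (case) - (control)|, then
#' lexicographically by probe id. The orientation of the decision rule is
#' fixed from the training class-conditional ordering frequencies.
#'
#' @param train_matrix probes x samples numeric matrix (log2 or linear;
#'   immaterial by rank invariance).
#' @param train_classes per-sample labels, \code{"case"}/\code{"control"}.
#' @return object of class \code{"tsp_model"}.
#' @export
tsp_fit <- function(train_matrix, train_classes) {
  m <- as.matrix(train_matrix)
  if (nrow(m) < 2) stop("need at least 2 probes", call. = FALSE)
  cls <- as.character(train_classes)
  i1 <- which(cls == "case"); i2 <- which(cls == "control")
  if (!length(i1) || !length(i2))
    stop("content error: both classes must be present in training data",
         call. = FALSE)
  p <- nrow(m)
  count_less <- function(cols) {
    acc <- matrix(0, p, p)
    for (s in cols) acc <- acc + outer(m[, s], m[, s], "<")
    acc
  }
  p_case <- count_less(i1) / length(i1)
  p_ctrl <- count_less(i2) / length(i2)
  delta <- abs(p_case - p_ctrl)
  ## gamma from within-sample ranks
  r <- apply(m, 2, rank)
  d_case <- rowMeans(r[, i1, drop = FALSE])
  d_ctrl <- rowMeans(r[, i2, drop = FALSE])
  dd <- d_case - d_ctrl
  gamma <- abs(outer(dd, dd, "-"))

  delta[lower.tri(delta, diag = TRUE)] <- -1  # unordered pairs: keep i < j
  best <- which(delta == max(delta), arr.ind = TRUE)
  if (nrow(best) > 1) {
    g <- gamma[best]
    best <- best[g == max(g), , drop = FALSE]
    if (nrow(best) > 1) {  # lexicographic by probe id
      ids <- cbind(rownames(m)[best[, 1]], rownames(m)[best[, 2]])
      best <- best[order(ids[, 1], ids[, 2])[1], , drop = FALSE]
    }
  }
  i <- best[1, 1]; j <- best[1, 2]
  structure(list(
    pair = c(rownames(m)[i], rownames(m)[j]),
    delta = delta[i, j],
    gamma = gamma[i, j],
    p_less_case = p_case[i, j],
    p_less_control = p_ctrl[i, j],
    majority_class = if (length(i1) >= length(i2)) "case" else "control",
    n_train = ncol(m)), class = "tsp_model")
}

#' @export
print.tsp_model <- function(x, ...) {
  cat("TSP classifier: ", x$pair[1], " vs ", x$pair[2],
      sprintf(" (Delta = %.3f, gamma = %.2f)\n", x$delta, x$gamma),
      sep = "")
  invisible(x)
}

#' Predict with a top-scoring-pair classifier
#'
#' Per sample, evaluates whether the first pair probe is below the second
#' and emits the class whose training-conditional ordering frequency
#' favors the observed ordering; exact ties go to the majority training
#' class.
#'
#' @param model a \code{\link{tsp_fit}} result.
#' @param test_matrix probes x samples matrix containing the pair probes.
#' @return character vector of predicted labels.
#' @export
tsp_predict <- function(model, test_matrix) {
  m <- as.matrix(test_matrix)
  missing <- setdiff(model$pair, rownames(m))
  if (length(missing))
    stop("content error: pair probe(s) missing from test matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  xi <- m[model$pair[1], ]; xj <- m[model$pair[2], ]
  less_votes_case <- model$p_less_case >= model$p_less_control
  out <- ifelse(xi == xj, model$majority_class,
                ifelse((xi < xj) == less_votes_case, "case", "control"))
  unname(out)
}

#' Linear-SVM specification
#'
#' @param cost_grid soft-margin cost values tuned over by nested
#'   cross-validation.
#' @param max_features number of probes kept by the moderated-t variable
#'   filter (default 15).
#' @param inner_folds folds of the nested tuning loop (default 3).
#' @return list of class \code{"svm_spec"}.
#' @export
svm_spec <- function(cost_grid = c(0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 50),
                     max_features = 15, inner_folds = 3) {
  stopifnot(all(cost_grid > 0), max_features >= 1, inner_folds >= 2)
  structure(list(cost_grid = cost_grid, max_features = max_features,
                 inner_folds = inner_folds), class = "svm_spec")
}

stratified_folds <- function(cls, k) {
  fold <- integer(length(cls))
  for (lev in unique(cls)) {
    idx <- which(cls == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

svm_decision_values <- function(fit, x_new) {
  dv <- attr(stats::predict(fit, x_new, decision.values = TRUE),
             "decision.values")
  ## e1071 orients the decision value toward the first label of the
  ## colname "A/B"; flip so that positive always means "case"
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  as.numeric(dv) * (if (first == "case") 1 else -1)
}

#' Fit a linear soft-margin SVM with nested cost tuning
#'
#' (1) Probes are ranked by the absolute moderated t-statistic computed
#' on the training data only and the top \code{max_features} kept;
#' (2) a stratified inner cross-validation over the cost grid picks the
#' cost with the lowest mean misclassification (ties to the smaller
#' cost); (3) the final linear SVM is fitted on all training data at that
#' cost (features are used unscaled); (4) a logistic (Platt) calibration
#' is fitted on the inner-fold held-out decision values.
#'
#' @param train_matrix probes x samples matrix of log2 signals.
#' @param train_classes per-sample labels.
#' @param spec an \code{\link{svm_spec}}.
#' @return object of class \code{"svm_model"} with the selected features,
#'   chosen cost, case-positive hyperplane weights and intercept, the
#'   Platt coefficients, and the inner tuning trace.
#' @export
svm_fit <- function(train_matrix, train_classes, spec = svm_spec()) {
  m <- as.matrix(train_matrix)
  cls <- as.character(train_classes)
  n1 <- sum(cls == "case"); n2 <- sum(cls == "control")
  if (min(n1, n2) < max(4, spec$inner_folds))
    stop("content error: each class needs at least max(4, inner_folds) ",
         "samples", call. = FALSE)
  ## variable filtering on training data only
  mt <- moderated_t_table(m, cls)
  keep <- order(-abs(mt$t))[seq_len(min(spec$max_features, nrow(m)))]
  features <- rownames(m)[keep]
  x <- t(m[keep, , drop = FALSE])
  y <- factor(cls, levels = c("control", "case"))

  ## stratified inner folds; refold if a training part loses a class
  for (attempt in 1:25) {
    fold <- stratified_folds(cls, spec$inner_folds)
    ok <- all(vapply(seq_len(spec$inner_folds), function(f)
      length(unique(cls[fold != f])) == 2, TRUE))
    if (ok) break
    if (attempt == 25)
      stop("could not build inner folds with both classes", call. = FALSE)
  }

  errors <- matrix(NA_real_, length(spec$cost_grid), spec$inner_folds)
  dv_held <- rep(NA_real_, length(cls))
  for (ci in seq_along(spec$cost_grid)) {
    for (f in seq_len(spec$inner_folds)) {
      tr <- fold != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = spec$cost_grid[ci], scale = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      errors[ci, f] <- mean(pred != y[!tr])
    }
  }
  mean_err <- rowMeans(errors)
  cost <- spec$cost_grid[which.min(mean_err)]  # ties -> smaller cost

  ## held-out decision values at the chosen cost, for Platt calibration
  for (f in seq_len(spec$inner_folds)) {
    tr <- fold != f
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    dv_held[!tr] <- svm_decision_values(fit, x[!tr, , drop = FALSE])
  }
  platt <- suppressWarnings(stats::glm((y == "case") ~ dv_held,
                                       family = stats::binomial()))
  platt_coef <- unname(stats::coef(platt))
  if (anyNA(platt_coef)) platt_coef <- c(0, 1)

  final <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(final$coefs, final$SV))
  b <- -final$rho
  ## orient the stored hyperplane so positive = case
  first <- strsplit(colnames(attr(stats::predict(
    final, x[1, , drop = FALSE], decision.values = TRUE),
    "decision.values"))[1], "/", fixed = TRUE)[[1]][1]
  if (first != "case") { w <- -w; b <- -b }

  structure(list(features = features, cost = cost,
                 weights = stats::setNames(w, features), intercept = b,
                 platt = platt_coef,
                 tuning = data.frame(cost = spec$cost_grid,
                                     mean_error = mean_err),
                 folds = fold, fit = final,
                 spec = spec), class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat("Linear SVM:", length(x$features), "features, cost =", x$cost, "\n")
  invisible(x)
}

#' Predict with a fitted linear SVM
#'
#' @param model an \code{\link{svm_fit}} result.
#' @param test_matrix probes x samples matrix containing the model
#'   features.
#' @return data.frame with \code{label} (sign of the decision value) and
#'   the Platt-calibrated \code{probability} of being a case.
#' @export
svm_predict <- function(model, test_matrix) {
  m <- as.matrix(test_matrix)
  missing <- setdiff(model$features, rownames(m))
  if (length(missing))
    stop("content error: feature(s) missing from test matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  dv <- drop(crossprod(m[model$features, , drop = FALSE], model$weights)) +
    model$intercept
  data.frame(sample_id = colnames(m),
             decision_value = as.numeric(dv),
             label = ifelse(dv > 0, "case", "control"),
             probability = stats::plogis(model$platt[1] +
                                           model$platt[2] * as.numeric(dv)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize a classifier to JSON text
#'
#' Writes a \code{tsp_model} or \code{svm_model} to a documented JSON
#' format (pair, scores and orientation frequencies for TSP; features,
#' weights, cost and calibration for SVM) and reads it back.
#'
#' @param model classifier object.
#' @param path file path.
#' @export
write_classifier <- function(model, path) {
  kind <- if (inherits(model, "tsp_model")) "tsp"
  else if (inherits(model, "svm_model")) "svm"
  else stop("unsupported model class", call. = FALSE)
  obj <- unclass(model)
  obj$tuning <- NULL; obj$spec <- NULL; obj$folds <- NULL; obj$fit <- NULL
  obj$kind <- kind
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$kind
  obj$kind <- NULL
  if (kind == "svm") obj$weights <- stats::setNames(
    as.numeric(obj$weights), obj$features)
  structure(obj, class = paste0(kind, "_model"))
}
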