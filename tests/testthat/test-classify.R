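test_that("TSP selects the planted pair with a perfect score", {
  lm <- latent_matrix(seed = 21)
  model <- tsp_fit(lm$matrix, lm$classes)
  expect_setequal(model$pair, lm$pair)
  expect_equal(model$delta, 1)
  expect_equal(sum(tsp_predict(model, lm$matrix) != lm$classes), 0)
})

test_that("TSP agrees with exhaustive pair enumeration", {
  set.seed(22)
  for (trial in 1:10) {
    m <- matrix(rnorm(4 * 6), 4, 6,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
    cls <- sample(rep(c("case", "control"), 3))
    # brute force over all 6 unordered pairs
    best <- NULL
    for (i in 1:3) for (j in (i + 1):4) {
      pc <- mean(m[i, cls == "case"] < m[j, cls == "case"])
      pk <- mean(m[i, cls == "control"] < m[j, cls == "control"])
      d <- abs(pc - pk)
      if (is.null(best) || d > best$d + 1e-12) best <- list(i = i, j = j, d = d)
    }
    model <- tsp_fit(m, cls)
    expect_equal(model$delta, best$d, tolerance = 1e-12)
    # the selected pair must attain the maximal delta (tie-breaks may
    # choose a different pair of equal score)
    pc <- mean(m[model$pair[1], cls == "case"] < m[model$pair[2], cls == "case"])
    pk <- mean(m[model$pair[1], cls == "control"] < m[model$pair[2], cls == "control"])
    expect_equal(abs(pc - pk), best$d, tolerance = 1e-12)
  }
})

test_that("a constant pair scores delta = 0 and ties go to the majority", {
  m <- rbind(a = rep(1, 6), b = rep(1, 6), c = c(1, 2, 3, 6, 5, 4))
  cls <- rep(c("case", "control"), c(2, 4))
  model <- tsp_fit(m[c("a", "b"), ], cls)
  expect_equal(model$delta, 0)
  expect_equal(unique(tsp_predict(model, m[c("a", "b"), ])), "control")
})

test_that("TSP is invariant to monotone per-sample transformations", {
  lm <- latent_matrix(seed = 23)
  m_log <- lm$matrix
  m_lin <- 2^m_log
  f_log <- tsp_fit(m_log, lm$classes)
  f_lin <- tsp_fit(m_lin, lm$classes)
  expect_identical(f_log$pair, f_lin$pair)
  expect_equal(f_log$delta, f_lin$delta)
  expect_identical(tsp_predict(f_log, m_log), tsp_predict(f_lin, m_lin))
})

test_that("TSP prediction validates its inputs", {
  lm <- latent_matrix(seed = 24)
  model <- tsp_fit(lm$matrix, lm$classes)
  expect_error(tsp_predict(model, lm$matrix[1:3, ]), "missing")
  expect_error(tsp_fit(lm$matrix, rep("case", ncol(lm$matrix))),
               "both classes")
})

test_that("SVM respects the feature cap and picks the tied smallest cost", {
  lm <- latent_matrix(n_probes = 50, seed = 25, lfc = 4, n_de = 20)
  set.seed(1)
  model <- svm_fit(lm$matrix, lm$classes)
  expect_lte(length(model$features), 15)
  expect_true(model$cost %in% svm_spec()$cost_grid)
  # linearly separable planted data: every cost achieves zero inner
  # error, so the tie rule selects the smallest cost on the grid
  expect_equal(min(model$tuning$mean_error), 0)
  expect_equal(model$cost, 0.1)
})

test_that("the chosen cost equals exhaustive evaluation on the same folds", {
  lm <- latent_matrix(n_probes = 30, n_case = 9, n_control = 9,
                      lfc = 0.8, n_de = 5, seed = 26, noise = 1)
  set.seed(2)
  model <- svm_fit(lm$matrix, lm$classes)
  x <- t(lm$matrix[model$features, ])
  y <- factor(lm$classes, levels = c("control", "case"))
  grid <- svm_spec()$cost_grid
  err <- sapply(grid, function(cost) {
    mean(sapply(sort(unique(model$folds)), function(f) {
      fit <- e1071::svm(x[model$folds != f, ], y[model$folds != f],
                        kernel = "linear", cost = cost, scale = FALSE)
      mean(predict(fit, x[model$folds == f, ]) != y[model$folds == f])
    }))
  })
  expect_equal(model$cost, grid[which.min(err)])
  expect_equal(model$tuning$mean_error, unname(err), tolerance = 1e-12)
})

test_that("SVM predictions agree with the underlying decision values", {
  lm <- latent_matrix(seed = 27)
  set.seed(3)
  model <- svm_fit(lm$matrix, lm$classes)
  pred <- svm_predict(model, lm$matrix)
  # labels follow the sign of an independently recomputed dot product
  dv <- drop(crossprod(lm$matrix[model$features, ], model$weights)) +
    model$intercept
  expect_equal(pred$decision_value, unname(dv), tolerance = 1e-10)
  expect_identical(pred$label, unname(ifelse(dv > 0, "case", "control")))
  # agreement with the e1071 object's own class predictions
  expect_identical(pred$label,
                   unname(as.character(predict(model$fit,
                                               t(lm$matrix[model$features, ])))))
  # probabilities are monotone in the decision value
  expect_false(is.unsorted(pred$probability[order(pred$decision_value)]))
  # a point projected onto the hyperplane calibrates near one half
  x0 <- lm$matrix[model$features, 1]
  x0 <- x0 - model$weights * (sum(model$weights * x0) + model$intercept) /
    sum(model$weights^2)
  m0 <- matrix(x0, ncol = 1, dimnames = list(model$features, "h"))
  expect_lt(abs(svm_predict(model, m0)$probability - 0.5), 0.25)
  expect_error(svm_predict(model, lm$matrix[1:3, ]), "missing")
})

test_that("classifier serialization round-trips predictions", {
  lm <- latent_matrix(seed = 28)
  tsp <- tsp_fit(lm$matrix, lm$classes)
  set.seed(4)
  svm <- svm_fit(lm$matrix, lm$classes)
  for (model in list(tsp, svm)) {
    path <- withr::local_tempfile(fileext = ".json")
    write_classifier(model, path)
    back <- read_classifier(path)
    if (inherits(model, "tsp_model")) {
      expect_identical(tsp_predict(back, lm$matrix),
                       tsp_predict(model, lm$matrix))
    } else {
      expect_equal(svm_predict(back, lm$matrix)$probability,
                   svm_predict(model, lm$matrix)$probability,
                   tolerance = 1e-12)
    }
  }
})
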