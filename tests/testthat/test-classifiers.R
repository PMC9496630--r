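test_that("every model family separates two well-separated clouds", {
  fx <- toy_separable(n = 30, p = 5, delta = 1.5, seed = 41)
  for (kind in model_kinds()) {
    m <- train_model(kind, fx$x, fx$y, folds = 5, seed = 7)
    expect_s3_class(m, "trained_model")
    expect_gte(m$cv_accuracy, if (kind == "DT") 0.9 else 1.0)
    expect_gte(m$cv_auc, if (kind == "DT") 0.9 else 0.99)
    expect_true(m$cv_accuracy >= 0 && m$cv_accuracy <= 1)
    # the grid winner dominates every grid point it was compared against
    expect_equal(m$cv_accuracy, max(m$grid_cv_accuracy))
    # training is seed-deterministic
    m2 <- train_model(kind, fx$x, fx$y, folds = 5, seed = 7)
    expect_equal(m$cv_accuracy, m2$cv_accuracy)
    expect_equal(predict_confidence(m, fx$x)$score,
                 predict_confidence(m2, fx$x)$score)
  }
})

test_that("a one-point grid is plain cross-validation plus refit", {
  fx <- toy_separable(n = 20, p = 4, seed = 42)
  g1 <- train_model("DT", fx$x, fx$y, grid = data.frame(maxdepth = 4),
                    folds = 4, seed = 3)
  expect_equal(nrow(g1$grid), 1)
  expect_equal(g1$cv_accuracy, g1$grid_cv_accuracy[1])
  expect_error(train_model("DT", fx$x, fx$y, grid = data.frame()[0, ],
                           folds = 4), "empty")
})

test_that("confidence is zero at the boundary, one at certainty, sign-free", {
  fx <- toy_separable(n = 25, p = 4, seed = 43)
  for (kind in model_kinds()) {
    m <- train_model(kind, fx$x, fx$y, folds = 5, seed = 5)
    pr <- predict_confidence(m, fx$x)
    expect_true(all(pr$confidence >= 0 & pr$confidence <= 1))
    if (kind != "PLSDA") {
      # probabilistic kinds: confidence = 2|p - 0.5| exactly
      expect_equal(pr$confidence, 2 * abs(pr$score - 0.5), tolerance = 1e-12)
    }
  }
  # swapping the class names leaves every confidence unchanged
  flipped <- ifelse(fx$y == "EC", "CTRL", "EC")
  for (kind in c("NB", "GLM", "DT", "PLSDA")) {
    m1 <- train_model(kind, fx$x, fx$y, folds = 5, seed = 5)
    m2 <- train_model(kind, fx$x, flipped, folds = 5, seed = 5)
    expect_equal(predict_confidence(m1, fx$x)$confidence,
                 predict_confidence(m2, fx$x)$confidence, tolerance = 1e-8)
  }
  # a sample at a PLS-DA class centroid is called with full confidence
  m <- train_model("PLSDA", fx$x, fx$y, folds = 5, seed = 5)
  centroid_x <- colMeans(fx$x[fx$y == "EC", ])  # near the EC latent centroid
  pr <- predict_confidence(m, matrix(centroid_x, 1,
                                     dimnames = list("c", names(centroid_x))))
  expect_identical(pr$label, "EC")
  expect_gt(pr$confidence, 0.9)

  expect_error(predict_confidence(m, fx$x[, 1:2]), "lacks")
})

test_that("admission applies strict gates and the overfitting guard", {
  fake <- function(acc, auc, train_acc = acc) {
    structure(list(kind = "NB", cv_accuracy = acc, cv_auc = auc,
                   train_accuracy = train_acc), class = "trained_model")
  }
  # accuracy exactly at the gate is rejected (strict inequality)
  expect_length(admit_models(list(fake(0.65, 0.99))), 0)
  # both gates must hold
  expect_length(admit_models(list(fake(0.90, 0.80))), 0)
  expect_length(admit_models(list(fake(0.90, 0.85))), 0)
  expect_length(admit_models(list(fake(0.90, 0.86))), 1)
  # overfitting: train-CV gap of 0.15 or more is rejected
  expect_length(admit_models(list(fake(0.70, 0.9, train_acc = 0.86))), 0)
  # order preserved
  out <- admit_models(list(fake(0.9, 0.9), fake(0.5, 0.5), fake(0.8, 0.9)))
  expect_equal(vapply(out, `[[`, numeric(1), "cv_accuracy"), c(0.9, 0.8))
})

test_that("label-permuted data yields chance-level cross-validation accuracy", {
  accs <- unlist(lapply(1:5, function(s) {
    fx <- toy_null(n = 50, p = 6, seed = 300 + s)
    vapply(c("NB", "GLM", "DT", "PLSDA"), function(k) {
      train_model(k, fx$x, fx$y, folds = 5, seed = s)$cv_accuracy
    }, numeric(1))
  }))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
  expect_true(all(accs < 0.8))
})

test_that("PLS-DA diagnostics satisfy the VIP identity and Q2 <= R2", {
  for (s in 1:3) {
    fx <- toy_separable(n = 20 + 5 * s, p = 4 + 2 * s, delta = 1, seed = s)
    d <- plsda_diagnostics(fx$x, fx$y, max_lv = 3, folds = 5, n_perm = 30,
                           seed = s)
    expect_equal(mean(d$vip^2), 1, tolerance = 1e-6)
    expect_lte(d$q2, d$r2)
    expect_true(d$perm_p > 0 && d$perm_p <= 1)
    expect_equal(length(d$perm_q2), 30)
  }
  # a feature with zero weight in every component has VIP 0
  fx <- toy_separable(n = 20, p = 3, seed = 9)
  x <- cbind(fx$x, dead = 0)
  fit <- emlscreen:::pls_fit(x, as.numeric(fx$y == "EC"), ncomp = 2)
  expect_equal(unname(pls_vip(fit)["dead"]), 0)

  expect_error(plsda_diagnostics(toy_separable(4, 3)$x[1:3, ],
                                 c("EC", "CTRL", "EC"), folds = 2),
               "at least 2")
})

test_that("PLS-DA agrees with an independent implementation on a fixture", {
  skip_if_not_installed("mixOmics")
  fx <- toy_separable(n = 25, p = 6, delta = 1, seed = 44)
  x <- scale(fx$x)  # compare on the autoscaled matrix both expect
  mine <- emlscreen:::pls_fit(x, as.numeric(fx$y == "EC"), ncomp = 1)
  ref <- mixOmics::plsda(x, factor(fx$y), ncomp = 1, scale = FALSE)
  # latent scores agree up to sign and scale
  r <- abs(cor(mine$Tscores[, 1], ref$variates$X[, 1]))
  expect_gt(r, 1 - 1e-9)
})

test_that("the package AUC matches pROC on random score vectors", {
  skip_if_not_installed("pROC")
  withr::with_seed(45, {
    for (i in 1:10) {
      n <- sample(20:80, 1)
      y <- rep(c(TRUE, FALSE), length.out = n)
      s <- rnorm(n) + y
      ref <- pROC::roc(response = y, predictor = s, quiet = TRUE,
                       direction = "<")
      expect_equal(auc_mw(s, y), as.numeric(pROC::auc(ref)),
                   tolerance = 1e-12)
      expect_equal(auc_delong_ci(s, y)$var,
                   as.numeric(pROC::var(ref, method = "delong")),
                   tolerance = 1e-10)
    }
  })
})
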