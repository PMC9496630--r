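test_that("the EML score is the signed weighted-vote sum with its defining zero", {
  # equal weight for and against: score exactly 0
  v <- weighted_vote(c("NB", "GLM"), c("EC", "CTRL"), c(0.7, 0.7), c(0.9, 0.9))
  expect_identical(eml_score(v), 0)

  # seven unanimous certain votes reach the +700 bound
  v7 <- weighted_vote(model_kinds(), rep("EC", 7), rep(1, 7), rep(1, 7))
  expect_identical(eml_score(v7), 700)

  # hand arithmetic: 45 - 20 + 70
  v3 <- weighted_vote(c("NB", "GLM", "DT"), c("EC", "CTRL", "EC"),
                      c(0.5, 0.25, 1.0), c(0.9, 0.8, 0.7))
  expect_equal(eml_score(v3), 95)

  expect_error(eml_score(numeric(0)), "empty")
  expect_error(weighted_vote("NB", "EC", 1.2, 0.9))
})

test_that("random vote sets respect antisymmetry and the score bound", {
  withr::with_seed(51, {
    for (i in 1:1000) {
      k <- sample(1:7, 1)
      lab <- sample(c("EC", "CTRL"), k, replace = TRUE)
      v <- weighted_vote(sample(model_kinds(), k), lab, runif(k), runif(k))
      flipped <- weighted_vote(v$kind, ifelse(lab == "EC", "CTRL", "EC"),
                               v$confidence, v$accuracy)
      expect_identical(eml_score(flipped), -eml_score(v))
      expect_lte(abs(eml_score(v)), 100 * k)
      expect_true(all(abs(v$signed) <= 100))
      expect_true(all(sign(v$signed)[v$signed != 0] ==
                        ifelse(lab == "EC", 1, -1)[v$signed != 0]))
    }
  })
})

test_that("the Youden threshold matches an exhaustive brute-force maximizer", {
  brute_force_j <- function(scores, y) {
    u <- sort(unique(scores))
    cuts <- c(-Inf, if (length(u) > 1) (head(u, -1) + u[-1]) / 2, Inf)
    best <- -Inf
    for (c in cuts) {
      s <- mean(scores[y] > c)
      sp <- mean(scores[!y] <= c)
      best <- max(best, s + sp - 1)
    }
    best
  }
  withr::with_seed(52, {
    for (i in 1:60) {
      n <- sample(10:200, 1)
      y <- runif(n) < runif(1, 0.2, 0.8)
      if (!any(y) || all(y)) next
      scores <- round(rnorm(n) + y * runif(1, 0, 2), sample(0:2, 1))
      labels <- ifelse(y, "EC", "CTRL")
      res <- choose_threshold(scores, labels)
      expect_equal(res$j, brute_force_j(scores, y))
      # the returned threshold attains the reported operating point
      expect_equal(mean(scores[y] > res$threshold), res$sensitivity)
      expect_equal(mean(scores[!y] <= res$threshold), res$specificity)
      # DeLong point estimate is the Mann-Whitney U over n1*n2
      w <- suppressWarnings(stats::wilcox.test(scores[y], scores[!y]))
      expect_equal(res$auc,
                   unname(w$statistic) / (sum(y) * sum(!y)),
                   tolerance = 1e-12)
    }
  })
})

test_that("threshold behaves at the degenerate and textbook cases", {
  # {1,2,3,4} with {-,-,+,+}: threshold 2.5, J = 1, AUC = 1
  res <- choose_threshold(c(1, 2, 3, 4), c("CTRL", "CTRL", "EC", "EC"))
  expect_equal(res$threshold, 2.5)
  expect_equal(res$j, 1)
  expect_equal(res$auc, 1)
  expect_equal(res$ci, c(1, 1))

  # label-independent scores: AUC near 0.5 and the CI covers 0.5
  withr::with_seed(53, {
    n <- 600
    scores <- rnorm(n)
    labels <- rep(c("CTRL", "EC"), n / 2)
    res0 <- choose_threshold(scores, labels)
    expect_lt(abs(res0$auc - 0.5), 0.08)
    expect_true(res0$ci[1] <= 0.5 && res0$ci[2] >= 0.5)
  })
  expect_error(choose_threshold(1:4, rep("EC", 4)), "binary|both")
})

test_that("the diagnostic panel reproduces its defining identities", {
  # printed-rate identities: NLR = (1-S)/Sp
  expect_equal(round(likelihood_ratios(0.74, 0.94)$nlr, 2), 0.28)
  expect_equal(round(likelihood_ratios(0.90, 0.88)$nlr, 2), 0.11)
  expect_equal(round(likelihood_ratios(0.95, 0.88)$nlr, 2), 0.06)
  lr_pls <- likelihood_ratios(0.93, 1.00)
  expect_true(is.na(lr_pls$plr))          # Sp = 1 makes the PLR ND
  expect_equal(round(lr_pls$nlr, 2), 0.07)

  # perfect predictions
  p <- diagnostic_panel(c("EC", "EC", "CTRL"), c("EC", "EC", "CTRL"))
  expect_equal(p$sensitivity, 1)
  expect_equal(p$specificity, 1)
  expect_equal(p$ppv, 1)
  expect_equal(p$npv, 1)
  expect_equal(p$accuracy, 1)
  expect_equal(p$nlr, 0)
  expect_true(is.na(p$plr))

  expect_error(diagnostic_panel(c("EC", "EC"), c("EC", "CTRL", "EC")),
               "equal length")

  # panel identities on random confusion tables
  withr::with_seed(54, {
    for (i in 1:50) {
      n <- sample(20:100, 1)
      truth <- ifelse(runif(n) < 0.5, "EC", "CTRL")
      if (length(unique(truth)) < 2) next
      pred <- ifelse(runif(n) < 0.7, truth,
                     ifelse(truth == "EC", "CTRL", "EC"))
      pan <- diagnostic_panel(pred, truth)
      if (!is.na(pan$plr)) {
        expect_equal(pan$plr * (1 - pan$specificity), pan$sensitivity)
      }
      if (!is.na(pan$nlr)) {
        expect_equal(pan$nlr * pan$specificity, 1 - pan$sensitivity)
      }
      expect_equal(pan$accuracy,
                   (pan$tp + pan$tn) / (pan$tp + pan$fp + pan$tn + pan$fn))
    }
  })
})

test_that("cohort screening reduces to its parts", {
  fx <- toy_separable(n = 25, p = 4, seed = 55)
  m1 <- train_model("GLM", fx$x, fx$y, folds = 5, seed = 2)
  m2 <- train_model("NB", fx$x, fx$y, folds = 5, seed = 2)

  # degenerate cuts
  all_ctrl <- screen_cohort(list(m1, m2), fx$x, threshold = Inf)
  expect_true(all(all_ctrl$samples$class == "CTRL"))
  all_ec <- screen_cohort(list(m1, m2), fx$x, threshold = -Inf)
  expect_true(all(all_ec$samples$class == "EC"))

  # a single-model ensemble classifies exactly like that model
  single <- screen_cohort(list(m1), fx$x, threshold = 0)
  own <- predict_confidence(m1, fx$x)
  expect_identical(single$samples$class, ifelse(own$label == "EC" &
                                                  own$confidence > 0,
                                                "EC", "CTRL"))
  # vote matrix is bounded and sums to the score
  both <- screen_cohort(list(m1, m2), fx$x, threshold = 0)
  expect_true(all(abs(both$votes) <= 100))
  expect_equal(unname(rowSums(both$votes)), both$samples$score)

  # per-class summary has the Table-3 layout
  sm <- summarize_scores(both, fx$y)
  expect_setequal(names(sm),
                  c("class", "n", "mean", "sd", "min", "max", "error_rate"))
  expect_equal(sum(sm$n), nrow(fx$x))

  expect_error(screen_cohort(list(), fx$x))
})
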