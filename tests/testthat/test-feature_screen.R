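test_that("screening tags each feature by its first failing criterion", {
  withr::with_seed(31, {
    n <- 40
    y <- rep(c("CTRL", "EC"), each = n / 2)
    x <- matrix(rnorm(n * 3), n,
                dimnames = list(paste0("s", 1:n), c("ok1", "ok2", "ok3")))
    # make the 'ok' features clearly informative but not leaky
    x[y == "EC", ] <- x[y == "EC", ] + 1.5
    leak <- as.numeric(y == "EC")                    # exact copy of the label
    null_f <- rep(c(-1, 1), n / 2)                   # orthogonal to the label
    unstable <- numeric(n)                           # 85% identical zeros
    unstable[which(y == "EC")[1:6]] <- 3
    missing_f <- rnorm(n) + 2 * (y == "EC")
    missing_f[5] <- NA
    x <- cbind(x, leak = leak, null_f = null_f, unstable = unstable,
               missing_f = missing_f)

    rep <- screen_features(x, y)
    tags <- setNames(rep$excluded$reason, rep$excluded$feature)
    expect_identical(unname(tags["leak"]), "correlation_high")
    expect_identical(unname(tags["null_f"]), "correlation_null")
    expect_identical(unname(tags["unstable"]), "unstable")
    expect_identical(unname(tags["missing_f"]), "missing")
    expect_setequal(rep$retained, c("ok1", "ok2", "ok3"))

    # retained + excluded partition the inputs; screening is idempotent and
    # indifferent to column order
    expect_setequal(c(rep$retained, rep$excluded$feature), colnames(x))
    rep2 <- screen_features(x[, rep$retained, drop = FALSE], y)
    expect_setequal(rep2$retained, rep$retained)
    perm <- sample(ncol(x))
    rep3 <- screen_features(x[, perm, drop = FALSE], y)
    expect_setequal(rep3$retained, rep$retained)

    expect_error(screen_features(x, rep("A", n)), "binary")
  })
})

test_that("the GA finds a jointly-separating feature pair (brute-force check)", {
  withr::with_seed(32, {
    n <- 60
    z1 <- rnorm(n); z2 <- rnorm(n)
    # margin along z1 + z2 so the pair separates cleanly, while each single
    # feature still overlaps between classes
    m <- 0.4 * sign(z1 + z2)
    z1 <- z1 + m; z2 <- z2 + m
    y <- ifelse(z1 + z2 > 0, "EC", "CTRL")
    x <- cbind(z1, z2, matrix(rnorm(n * 18), n))
    colnames(x) <- paste0("f", 1:20)
    rownames(x) <- paste0("s", 1:n)

    # independent CV oracle: logistic regression, fixed fold assignment
    fold <- integer(n)
    for (cl in unique(y)) {
      i <- which(y == cl)
      fold[i] <- rep_len(1:5, length(i))[order(runif(length(i)))]
    }
    oracle_cv <- function(cols) {
      correct <- logical(n)
      for (k in 1:5) {
        df <- data.frame(y = y == "EC", x[, cols, drop = FALSE])
        fit <- suppressWarnings(glm(y ~ ., binomial(), df[fold != k, ]))
        p <- predict(fit, df[fold == k, ], type = "response")
        correct[fold == k] <- (p > 0.5) == df$y[fold == k]
      }
      mean(correct)
    }
    singles <- vapply(1:20, function(j) oracle_cv(j), numeric(1))
    expect_true(all(singles < 1))          # no single feature separates
    expect_equal(oracle_cv(1:2), 1)        # the pair does

    sel <- ga_select(x, y, "GLM",
                     ga_config(population = 20, generations = 15, folds = 5,
                               seed = 4))
    expect_true(all(c("f1", "f2") %in% sel$features))
    expect_equal(sel$fitness, 1)
  })
})

test_that("GA is seed-reproducible and monotone under elitism", {
  fx <- toy_separable(n = 20, p = 8, seed = 33)
  cfg <- ga_config(population = 8, generations = 6, folds = 3, elitism = 2,
                   seed = 9)
  a <- ga_select(fx$x, fx$y, "NB", cfg)
  b <- ga_select(fx$x, fx$y, "NB", cfg)
  expect_identical(a, b)
  expect_false(is.unsorted(a$trace))

  # degenerate GA: one generation, population 2, no mutation or crossover
  tiny <- ga_config(population = 2, generations = 1, crossover_rate = 0,
                    mutation_rate = 0, elitism = 1, folds = 3, seed = 11)
  d1 <- ga_select(fx$x, fx$y, "NB", tiny)
  d2 <- ga_select(fx$x, fx$y, "NB", tiny)
  expect_identical(d1$features, d2$features)

  expect_error(ga_select(fx$x[, 0], fx$y, "NB", cfg), "empty feature set")
})

test_that("on pure noise the GA-selected subset has no out-of-sample signal", {
  correct <- 0
  total <- 0
  for (s in 1:10) {
    tr <- toy_null(n = 40, p = 10, seed = 100 + s)
    te <- toy_null(n = 100, p = 10, seed = 200 + s)
    sel <- ga_select(tr$x, tr$y, "GLM",
                     ga_config(population = 10, generations = 5, folds = 4,
                               seed = s))
    df_tr <- data.frame(y = tr$y == "EC", tr$x[, sel$features, drop = FALSE])
    fit <- suppressWarnings(glm(y ~ ., binomial(), df_tr))
    p <- predict(fit, data.frame(te$x[, sel$features, drop = FALSE]),
                 type = "response")
    correct <- correct + sum((p > 0.5) == (te$y == "EC"))
    total <- total + length(p)
  }
  expect_gt(stats::binom.test(correct, total, 0.5)$p.value, 0.01)
})
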