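test_that("a pristine batch passes all four acceptance conditions", {
  fx <- qc_fixture()
  reports <- validate_batches(fx$batches)
  for (r in reports) {
    expect_true(r$pass)
    expect_equal(nrow(r$conditions), 4)
    expect_identical(r$pass, all(r$conditions$pass))
  }
})

test_that("the standard-mix and duplicate tolerances bite where stated", {
  fx <- qc_fixture()
  b <- fx$batches[[1]]

  # analyte drifted to 1.12x expected fails the 10% standard tolerance
  drift <- corrupt_batch(b, "standard_drift", 0.12)
  r <- validate_batch(drift)
  expect_false(r$conditions$pass[r$conditions$condition == "standard_within_tol"])
  expect_equal(
    r$conditions$statistic[r$conditions$condition == "standard_within_tol"],
    0.12, tolerance = 1e-10)

  # 20% duplicate deviation fails, 5% still passes the 15% tolerance
  dup20 <- validate_batch(corrupt_batch(b, "duplicate_variance", 0.20))
  dup05 <- validate_batch(corrupt_batch(b, "duplicate_variance", 0.05))
  cond <- function(r, name) r$conditions$pass[r$conditions$condition == name]
  expect_false(cond(dup20, "duplicate_within_tol"))
  expect_true(cond(dup05, "duplicate_within_tol"))
  expect_equal(dup20$duplicate_max_deviation, 0.20, tolerance = 1e-10)

  # a batch missing a control profile is rejected
  broken <- b
  broken$pooled <- NULL
  expect_error(validate_batch(broken), "pooled")
})

test_that("batch validation is monotone in its tolerances", {
  fx <- qc_fixture()
  corrupted <- corrupt_batch(fx$batches[[1]], "duplicate_variance", 0.18)
  tols <- seq(0.02, 0.40, by = 0.02)
  passes <- vapply(tols, function(tl) {
    validate_batch(corrupted, tol_duplicate = tl)$conditions$pass[3]
  }, logical(1))
  expect_false(is.unsorted(passes))  # FALSE then TRUE, never back

  drift <- corrupt_batch(fx$batches[[1]], "standard_drift", 0.15)
  passes2 <- vapply(tols, function(tl) {
    validate_batch(drift, tol_standard = tl)$conditions$pass[2]
  }, logical(1))
  expect_false(is.unsorted(passes2))
})

test_that("the presence filter keeps exactly the >= 80% features", {
  withr::with_seed(21, {
    n <- 100
    areas <- matrix(rlnorm(n * 3, 10), n,
                    dimnames = list(sprintf("s%03d", 1:n), c("a79", "b80", "c100")))
    areas[1:21, "a79"] <- NA   # present in 79% of samples
    areas[1:20, "b80"] <- NA   # present in exactly 80%
    pt <- peak_table(areas, rep(1, n), rep(c("CTRL", "EC"), 50))
    out <- filter_features(pt)
    expect_identical(colnames(out$table$areas), c("b80", "c100"))
    expect_identical(out$removed, "a79")
    expect_identical(rownames(out$table$areas), rownames(areas))

    # idempotent
    again <- filter_features(out$table)
    expect_identical(again$table$areas, out$table$areas)
    expect_length(again$removed, 0)

    # threshold 1.0 on a complete table is the identity
    full <- peak_table(areas[, "c100", drop = FALSE], rep(1, n),
                       rep(c("CTRL", "EC"), 50))
    expect_identical(filter_features(full, 1.0)$table$areas, full$areas)
    expect_error(filter_features(pt, 0), "presence_threshold")
    expect_error(filter_features(pt, 1.2), "presence_threshold")
  })
})

test_that("a 273-feature table with 22 sparse features reduces to 251", {
  withr::with_seed(22, {
    n <- 50
    p <- 273
    areas <- matrix(rlnorm(n * p, 10), n,
                    dimnames = list(sprintf("s%03d", 1:n),
                                    sprintf("pk%03d", 1:p)))
    sparse <- sample(p, 22)
    for (j in sparse) areas[sample(n, 11), j] <- NA  # presence 78% < 80%
    pt <- peak_table(areas, rep(1, n), rep(c("CTRL", "EC"), 25))
    out <- filter_features(pt, 0.80)
    expect_equal(ncol(out$table$areas), 251)
    expect_identical(out$removed, sort(colnames(areas)[sparse]))
  })
})
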