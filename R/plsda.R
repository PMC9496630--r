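# NIPALS PLS1 for a binary class response, the basis of the PLS-DA
# classifier and its diagnostics. X is the autoscaled feature matrix; y is
# the 0/1 class indicator (CTRL = 0, EC = 1), centered internally.

pls_fit <- function(x, y01, ncomp = 1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  ncomp <- min(ncomp, p, n - 1)
  x_mean <- colMeans(x)
  y_mean <- mean(y01)
  e <- sweep(x, 2, x_mean)
  f <- y01 - y_mean
  w_mat <- matrix(0, p, ncomp); p_mat <- matrix(0, p, ncomp)
  t_mat <- matrix(0, n, ncomp); q_vec <- numeric(ncomp)
  a_used <- 0
  for (a in seq_len(ncomp)) {
    w <- crossprod(e, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # no residual covariance left to extract
    w <- w / nw
    tt <- e %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pl <- crossprod(e, tt)[, 1] / tt2
    q <- sum(f * tt) / tt2
    e <- e - tcrossprod(tt, pl)
    f <- f - q * tt
    w_mat[, a] <- w; p_mat[, a] <- pl; t_mat[, a] <- tt; q_vec[a] <- q
    a_used <- a
  }
  if (a_used == 0) {
    # degenerate (e.g. permuted labels orthogonal to X): keep one null comp
    a_used <- 1
  }
  w_mat <- w_mat[, seq_len(a_used), drop = FALSE]
  p_mat <- p_mat[, seq_len(a_used), drop = FALSE]
  t_mat <- t_mat[, seq_len(a_used), drop = FALSE]
  q_vec <- q_vec[seq_len(a_used)]
  # direct regression form: scores T = Xc %*% R, yhat = y_mean + Xc %*% (R q)
  r_mat <- tryCatch(
    w_mat %*% solve(crossprod(p_mat, w_mat)),
    error = function(e) w_mat)
  centroids <- rbind(
    CTRL = colMeans(t_mat[y01 == 0, , drop = FALSE]),
    EC = colMeans(t_mat[y01 == 1, , drop = FALSE]))
  if (anyNA(centroids)) centroids[is.na(centroids)] <- 0
  structure(list(x_mean = x_mean, y_mean = y_mean, ncomp = a_used,
                 W = w_mat, P = p_mat, Tscores = t_mat, q = q_vec,
                 R = r_mat, coef = r_mat %*% q_vec,
                 centroids = centroids,
                 ss_comp = q_vec^2 * colSums(t_mat^2),
                 ss_tot = sum((y01 - y_mean)^2),
                 features = colnames(x)),
            class = "pls_model")
}

pls_predict <- function(fit, x) {
  x <- as.matrix(x)[, fit$features, drop = FALSE]
  xc <- sweep(x, 2, fit$x_mean)
  t_new <- xc %*% fit$R
  yhat <- as.numeric(fit$y_mean + xc %*% fit$coef)
  d <- cbind(
    CTRL = sqrt(rowSums(sweep(t_new, 2, fit$centroids["CTRL", ])^2)),
    EC = sqrt(rowSums(sweep(t_new, 2, fit$centroids["EC", ])^2)))
  list(yhat = yhat, scores = t_new, d = d)
}

#' Variable importance in projection (VIP) scores
#'
#' Standard VIP: for feature j,
#' `VIP_j = sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a(SSY_a))`, where `SSY_a` is
#' the class-indicator variance explained by latent variable a and `w_ja` the
#' normalized weight. The mean squared VIP over all features equals 1.
#'
#' @param fit a fitted PLS model (internal class `pls_model`, e.g. the
#'   `object$fit` of a PLS-DA `trained_model` or the `fit` element of
#'   [plsda_diagnostics()]).
#' @return named numeric vector of VIP scores.
#' @export
pls_vip <- function(fit) {
  stopifnot(inherits(fit, "pls_model"))
  p <- nrow(fit$W)
  ss <- fit$ss_comp
  if (sum(ss) == 0) return(setNames(numeric(p), fit$features))
  vip <- sqrt(p * as.numeric(fit$W^2 %*% ss) / sum(ss))
  setNames(vip, fit$features)
}

pls_q2 <- function(x, y01, ncomp, fold_id) {
  press <- 0
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    f <- pls_fit(x[tr, , drop = FALSE], y01[tr], ncomp)
    yhat <- pls_predict(f, x[!tr, , drop = FALSE])$yhat
    press <- press + sum((y01[!tr] - yhat)^2)
  }
  1 - press / sum((y01 - mean(y01))^2)
}

#' PLS-DA diagnostics: latent-variable choice, VIP, R2/Q2, permutation test
#'
#' Fits a PLS-DA model on the class indicator (CTRL = 0, EC = 1). The
#' latent-variable count is chosen as the one maximizing cross-validated
#' classification accuracy (nearest class centroid in score space; ties go to
#' the smaller count). R2 is the in-sample fraction of class-indicator
#' variance explained; Q2 its k-fold cross-validated analogue. The permutation
#' test refits the model on `n_perm` label permutations and reports
#' `p = (1 + #\{Q2_perm >= Q2_obs\}) / (1 + n_perm)`.
#'
#' @param x feature matrix or `processed_matrix`.
#' @param labels class vector (CTRL/EC); taken from `x` if omitted and `x` is
#'   a `processed_matrix`.
#' @param max_lv maximum latent variables tried (default 3).
#' @param folds CV folds (default 7).
#' @param n_perm permutation iterations (default 2000).
#' @param seed integer seed.
#' @return object of class `plsda_diagnostics`: `ncomp`, `vip`, `r2`, `q2`,
#'   `cv_accuracy` (per latent-variable count), `perm_p`, `perm_q2`, `n_perm`,
#'   and the fitted `fit`.
#' @export
plsda_diagnostics <- function(x, labels = NULL, max_lv = 3, folds = 7,
                              n_perm = 2000, seed = 1L) {
  if (inherits(x, "processed_matrix")) {
    if (is.null(labels)) labels <- x$label
    x <- x$x
  }
  y <- as_class_factor(labels)
  y01 <- as.numeric(y == POSITIVE_CLASS)
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  max_lv <- min(max_lv, ncol(x), nrow(x) - 1)
  if (max_lv < 1) stop("max_lv exceeds the data's rank")
  fold_id <- make_folds(y, folds, seed)

  # choose the latent-variable count by CV classification accuracy
  cv_acc <- vapply(seq_len(max_lv), function(a) {
    correct <- logical(length(y))
    for (k in sort(unique(fold_id))) {
      tr <- fold_id != k
      f <- pls_fit(x[tr, , drop = FALSE], y01[tr], a)
      d <- pls_predict(f, x[!tr, , drop = FALSE])$d
      pred <- ifelse(d[, "EC"] < d[, "CTRL"], 1, 0)
      correct[!tr] <- pred == y01[!tr]
    }
    mean(correct)
  }, numeric(1))
  ncomp <- which.max(cv_acc)

  fit <- pls_fit(x, y01, ncomp)
  r2 <- sum(fit$ss_comp) / fit$ss_tot
  q2 <- pls_q2(x, y01, ncomp, fold_id)

  perm_q2 <- withr::with_seed(seed + 1L, {
    vapply(seq_len(n_perm), function(i) {
      yp <- sample(y01)
      pls_q2(x, yp, ncomp, make_folds(yp, folds,
                                      seed = (seed + i) %% .Machine$integer.max))
    }, numeric(1))
  })
  perm_p <- (1 + sum(perm_q2 >= q2)) / (1 + n_perm)

  structure(list(ncomp = ncomp, cv_accuracy = cv_acc,
                 vip = pls_vip(fit), r2 = r2, q2 = q2,
                 perm_p = perm_p, perm_q2 = perm_q2, n_perm = n_perm,
                 fit = fit),
            class = "plsda_diagnostics")
}

#' @export
print.plsda_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<plsda_diagnostics> %d latent variable(s); R2 = %.3f, Q2 = %.3f; permutation p = %.4g (%d iterations)\n",
    x$ncomp, x$r2, x$q2, x$perm_p, x$n_perm))
  cat("  top VIP:", paste(names(sort(x$vip, decreasing = TRUE))[1:min(5, length(x$vip))],
                          collapse = ", "), "\n")
  invisible(x)
}
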