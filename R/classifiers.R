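#' Classifier kinds
#'
#' The seven base model families combined by the ensemble: Naive Bayes (NB),
#' generalized linear model (GLM, ridge-penalized logistic regression), fast
#' large margin (FLM, linear support-vector classifier with Platt-calibrated
#' probabilities), deep learning (DL, a small feed-forward network), decision
#' tree (DT, CART), random forest (RF), and partial least squares discriminant
#' analysis (PLS-DA).
#'
#' @return character vector of kind codes.
#' @export
model_kinds <- function() c("NB", "GLM", "FLM", "DL", "DT", "RF", "PLSDA")

POSITIVE_CLASS <- "EC"
NEGATIVE_CLASS <- "CTRL"

as_class_factor <- function(labels) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (!setequal(lev, c(NEGATIVE_CLASS, POSITIVE_CLASS))) {
    stop("labels must be binary ", NEGATIVE_CLASS, "/", POSITIVE_CLASS,
         "; got: ", paste(lev, collapse = ", "))
  }
  factor(labels, levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))
}

#' Default hyperparameter grids
#'
#' One row per grid point. NB has no tuned hyperparameter (single point);
#' GLM tunes the ridge penalty; FLM the margin cost; DL hidden-layer width
#' and weight decay; DT tree depth; RF the per-split feature subsample;
#' PLS-DA the latent-variable count.
#'
#' @param kind a code from [model_kinds()].
#' @param p number of features (used by RF's mtry and PLS-DA's ncomp caps).
#' @return data.frame of hyperparameter combinations.
#' @export
default_grid <- function(kind, p = 10) {
  switch(match.arg(kind, model_kinds()),
    NB = data.frame(dummy = 0),
    GLM = data.frame(lambda = c(0.01, 0.1, 1)),
    FLM = data.frame(cost = c(0.1, 1, 10)),
    DL = expand.grid(size = c(3, 6), decay = c(0.1, 1)),
    DT = data.frame(maxdepth = c(2, 4, 8)),
    RF = data.frame(mtry = unique(pmax(1, pmin(p, c(floor(sqrt(p)), floor(p / 3)))))),
    PLSDA = data.frame(ncomp = seq_len(max(1, min(3, p))))
  )
}

# Fit one base model. x: numeric matrix (autoscaled), y: CTRL/EC factor,
# hyper: one-row list of hyperparameters. Stochastic learners are seeded by
# the caller.
fit_classifier <- function(kind, x, y, hyper = list()) {
  y <- as_class_factor(y)
  fit <- switch(kind,
    NB = e1071::naiveBayes(as.data.frame(x), y),
    GLM = {
      xx <- if (ncol(x) == 1) cbind(x, .pad = 0) else x
      glmnet::glmnet(xx, y, family = "binomial", alpha = 0,
                     lambda = hyper$lambda %||% 0.1, standardize = FALSE)
    },
    FLM = {
      sv <- e1071::svm(x, y, kernel = "linear", cost = hyper$cost %||% 1,
                       scale = FALSE)
      dvm <- attr(predict(sv, x, decision.values = TRUE), "decision.values")
      # orient decision values so larger = more EC-like; the column name
      # "A/B" means positive values favor class A
      flip <- if (startsWith(colnames(dvm)[1], POSITIVE_CLASS)) 1 else -1
      platt <- suppressWarnings(
        glm((y == POSITIVE_CLASS) ~ dv2, family = binomial(),
            data = data.frame(dv2 = flip * dvm[, 1])))
      list(svm = sv, flip = flip, platt = coef(platt))
    },
    DL = {
      nnet::nnet(x = x, y = as.numeric(y == POSITIVE_CLASS),
                 size = hyper$size %||% 3, decay = hyper$decay %||% 0.1,
                 maxit = hyper$maxit %||% 150, entropy = TRUE, trace = FALSE,
                 MaxNWts = 100000)
    },
    DT = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = hyper$maxdepth %||% 4,
                     minsplit = hyper$minsplit %||% 10,
                     cp = hyper$cp %||% 0.01, xval = 0))
    },
    RF = randomForest::randomForest(
      x, y, ntree = hyper$ntree %||% 300,
      mtry = min(hyper$mtry %||% max(1, floor(sqrt(ncol(x)))), ncol(x))),
    PLSDA = pls_fit(x, as.numeric(y == POSITIVE_CLASS),
                    ncomp = hyper$ncomp %||% 1),
    stop("unknown model kind: ", kind)
  )
  list(kind = kind, fit = fit, features = colnames(x))
}

# Uniform prediction contract: data.frame(label, confidence, score) with one
# row per sample. `score` is a monotone EC-affinity used for ROC ranking
# (the EC probability for probabilistic kinds, the latent-space response for
# PLS-DA); `confidence` is 0 at the decision boundary and 1 at certainty.
classifier_predictions <- function(obj, x) {
  x <- x[, obj$features, drop = FALSE]
  kind <- obj$kind
  if (kind == "PLSDA") {
    pr <- pls_predict(obj$fit, x)
    d_pos <- pr$d[, POSITIVE_CLASS]
    d_neg <- pr$d[, NEGATIVE_CLASS]
    label <- ifelse(d_pos < d_neg, POSITIVE_CLASS, NEGATIVE_CLASS)
    denom <- d_pos + d_neg
    conf <- ifelse(denom > 0, abs(d_neg - d_pos) / denom, 1)
    return(data.frame(label = label, confidence = conf, score = pr$yhat,
                      row.names = rownames(x)))
  }
  p <- switch(kind,
    NB = predict(obj$fit, as.data.frame(x), type = "raw")[, POSITIVE_CLASS],
    GLM = {
      xx <- if (length(obj$features) == 1) cbind(x, .pad = 0) else x
      as.numeric(predict(obj$fit, xx, type = "response"))
    },
    FLM = {
      dv <- attr(predict(obj$fit$svm, x, decision.values = TRUE),
                 "decision.values")[, 1] * obj$fit$flip
      plogis(obj$fit$platt[1] + obj$fit$platt[2] * dv)
    },
    DL = as.numeric(predict(obj$fit, x)),
    DT = predict(obj$fit, data.frame(x, check.names = FALSE),
                 type = "prob")[, POSITIVE_CLASS],
    RF = predict(obj$fit, x, type = "prob")[, POSITIVE_CLASS]
  )
  p <- pmin(pmax(as.numeric(p), 0), 1)
  data.frame(label = ifelse(p > 0.5, POSITIVE_CLASS, NEGATIVE_CLASS),
             confidence = 2 * abs(p - 0.5), score = p,
             row.names = rownames(x))
}

#' Stratified cross-validation folds
#'
#' @param labels class vector.
#' @param folds number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold assignments, stratified by class.
#' @export
make_folds <- function(labels, folds, seed = 1L) {
  stopifnot(folds >= 2)
  y <- as.character(labels)
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      i <- which(y == cl)
      if (length(i) < folds) {
        stop("class ", cl, " has fewer samples (", length(i),
             ") than folds (", folds, ")")
      }
      assign[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
  })
  assign
}

# Cross-validated accuracy and pooled AUC of one kind at one grid point.
cv_evaluate <- function(kind, x, y, hyper, fold_id, seed = 1L) {
  y <- as_class_factor(y)
  folds <- sort(unique(fold_id))
  acc <- numeric(length(folds))
  oof_score <- numeric(length(y))
  for (k in seq_along(folds)) {
    tr <- fold_id != folds[k]
    obj <- withr::with_seed(seed + 7L * k,
      fit_classifier(kind, x[tr, , drop = FALSE], y[tr], hyper))
    pr <- classifier_predictions(obj, x[!tr, , drop = FALSE])
    acc[k] <- mean(pr$label == as.character(y[!tr]))
    oof_score[!tr] <- pr$score
  }
  list(accuracy = mean(acc),
       auc = auc_mw(oof_score, y == POSITIVE_CLASS))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Rank-based AUC: the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`, with ties counted one half. Identical to the DeLong point
#' estimate.
#'
#' @param scores numeric score, larger = more positive-like.
#' @param positive logical (or coercible) indicator of the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, positive) {
  positive <- as.logical(positive)
  m <- sum(positive); n <- sum(!positive)
  if (m == 0 || n == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - m * (m + 1) / 2) / (m * n)
}

#' Train one classifier with grid search
#'
#' Exhaustive grid search: each hyperparameter combination is evaluated by
#' stratified k-fold cross-validation accuracy; the best point (ties: first in
#' grid order) is refit on all training data. The winning point's CV accuracy,
#' pooled out-of-fold CV AUC, and training accuracy are stored.
#'
#' @param kind code from [model_kinds()].
#' @param x numeric matrix (samples x features) of autoscaled log values, or a
#'   `processed_matrix`.
#' @param labels class vector (CTRL/EC).
#' @param grid data.frame of hyperparameter combinations; default
#'   [default_grid()].
#' @param folds CV folds (default 10).
#' @param seed integer seed governing fold assignment and stochastic learners.
#' @return object of class `trained_model`.
#' @export
train_model <- function(kind, x, labels, grid = NULL, folds = 10, seed = 1L) {
  kind <- match.arg(kind, model_kinds())
  if (inherits(x, "processed_matrix")) {
    if (missing(labels) || is.null(labels)) labels <- x$label
    x <- x$x
  }
  y <- as_class_factor(labels)
  grid <- grid %||% default_grid(kind, ncol(x))
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  fold_id <- make_folds(y, folds, seed)
  results <- lapply(seq_len(nrow(grid)), function(g) {
    cv_evaluate(kind, x, y, as.list(grid[g, , drop = FALSE]), fold_id,
                seed = seed + 1000L * g)
  })
  accs <- vapply(results, `[[`, numeric(1), "accuracy")
  best <- which.max(accs)
  hyper <- as.list(grid[best, , drop = FALSE])
  final <- withr::with_seed(seed, fit_classifier(kind, x, y, hyper))
  train_pred <- classifier_predictions(final, x)
  structure(
    list(kind = kind, object = final, features = colnames(x),
         hyper = hyper, grid = grid,
         grid_cv_accuracy = accs,
         cv_accuracy = accs[best], cv_auc = results[[best]]$auc,
         train_accuracy = mean(train_pred$label == as.character(y)),
         folds = folds, seed = seed, n_train = nrow(x)),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s: %d features, CV accuracy %.3f, CV AUC %.3f (train %.3f)\n",
              x$kind, length(x$features), x$cv_accuracy, x$cv_auc,
              x$train_accuracy))
  invisible(x)
}

#' Predict class and confidence for new samples
#'
#' The confidence maps a model's distance from its decision boundary to
#' \[0, 1\]: for probabilistic models it is `2 * |p(EC) - 0.5|`; for PLS-DA it
#' is `|d_CTRL - d_EC| / (d_CTRL + d_EC)` with `d` the euclidean distance to
#' each class centroid in latent-variable space. It is 0 exactly at the
#' boundary and invariant to relabelling the classes.
#'
#' @param model a `trained_model`.
#' @param x matrix of preprocessed samples (must contain the model's
#'   features), or a `processed_matrix`.
#' @return data.frame with `label`, `confidence`, `score` per sample.
#' @export
predict_confidence <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  if (inherits(x, "processed_matrix")) x <- x$x
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list("s1", names(x)))
  missing_feats <- setdiff(model$features, colnames(x))
  if (length(missing_feats)) {
    stop("sample lacks model feature(s): ",
         paste(head(missing_feats, 5), collapse = ", "))
  }
  classifier_predictions(model$object, x[, model$features, drop = FALSE])
}

#' Admit base models into the ensemble
#'
#' A candidate enters the ensemble only if its cross-validation accuracy
#' strictly exceeds `min_accuracy` AND its CV AUC strictly exceeds `min_auc`,
#' and it shows no overfitting: training accuracy minus CV accuracy below
#' `max_overfit`.
#'
#' @param candidates list of `trained_model`.
#' @param min_accuracy,min_auc admission gates (strict inequalities).
#' @param max_overfit maximum tolerated train-minus-CV accuracy gap.
#' @return the admitted sublist, order preserved.
#' @export
admit_models <- function(candidates, min_accuracy = 0.65, min_auc = 0.85,
                         max_overfit = 0.15) {
  keep <- vapply(candidates, function(m) {
    m$cv_accuracy > min_accuracy && m$cv_auc > min_auc &&
      (m$train_accuracy - m$cv_accuracy) < max_overfit
  }, logical(1))
  candidates[keep]
}
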