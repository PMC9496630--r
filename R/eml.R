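#' Construct weighted votes
#'
#' Each admitted model casts one vote per sample: its signed, weighted score
#' `sign * scale * accuracy * confidence`, with sign +1 for an EC prediction
#' and -1 for CTRL, `accuracy` the model's cross-validation accuracy, and
#' `confidence` its distance-from-boundary measure in \[0, 1\]. The scale
#' (default 100) puts single votes on a 0-100 magnitude, so a seven-model
#' ensemble is bounded by +/-700.
#'
#' @param kind model kind code(s).
#' @param label predicted label(s), "EC" or "CTRL".
#' @param confidence confidence(s) in \[0, 1\].
#' @param accuracy model CV accuracy(ies) in \[0, 1\].
#' @param scale vote scale (default 100).
#' @return data.frame of class `eml_votes` with a `signed` column.
#' @export
weighted_vote <- function(kind, label, confidence, accuracy, scale = 100) {
  stopifnot(all(label %in% c(POSITIVE_CLASS, NEGATIVE_CLASS)),
            all(confidence >= 0 & confidence <= 1),
            all(accuracy >= 0 & accuracy <= 1), scale > 0)
  sign <- ifelse(label == POSITIVE_CLASS, 1, -1)
  structure(
    data.frame(kind = kind, label = label, confidence = confidence,
               accuracy = accuracy, scale = scale,
               signed = sign * scale * accuracy * confidence,
               stringsAsFactors = FALSE),
    class = c("eml_votes", "data.frame"))
}

#' Ensemble machine-learning (EML) score
#'
#' The sum of a sample's signed weighted votes. By construction the score is 0
#' for a hypothetical sample whose votes for and against EC are equal in both
#' number and weight, positive when the weighted evidence favors EC, and
#' antisymmetric under flipping every vote's predicted class.
#'
#' @param votes an `eml_votes` data.frame (one vote per admitted model), or a
#'   numeric vector of signed votes.
#' @return the EML score (a single number).
#' @export
eml_score <- function(votes) {
  signed <- if (is.data.frame(votes)) votes$signed else as.numeric(votes)
  if (length(signed) == 0) stop("empty vote list")
  sum(signed)
}

# DeLong structural-components variance of the Mann-Whitney AUC.
delong_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  xs <- scores[positive]; ys <- scores[!positive]
  m <- length(xs); n <- length(ys)
  if (m == 0 || n == 0) stop("both classes must be present")
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  auc <- mean(v10)
  var_auc <- if (m > 1 && n > 1) var(v10) / m + var(v01) / n else 0
  list(auc = auc, var = var_auc)
}

#' AUC with DeLong 95% confidence interval
#'
#' Point estimate = Mann-Whitney AUC; variance by DeLong's
#' structural-components estimator; the interval is formed on the logit-AUC
#' scale and back-transformed (degenerate at AUC 0 or 1, where the DeLong
#' variance is 0).
#'
#' @param scores numeric scores, larger = more EC-like.
#' @param positive indicator of the positive (EC) class.
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `var`, `ci` (length-2 vector).
#' @export
auc_delong_ci <- function(scores, positive, conf_level = 0.95) {
  d <- delong_auc(scores, positive)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- if (d$auc <= 0 || d$auc >= 1 || d$var == 0) {
    c(d$auc, d$auc)
  } else {
    lg <- log(d$auc / (1 - d$auc))
    se_lg <- sqrt(d$var) / (d$auc * (1 - d$auc))
    plogis(lg + c(-z, z) * se_lg)
  }
  list(auc = d$auc, var = d$var, ci = pmin(pmax(ci, 0), 1))
}

#' Youden-index decision threshold
#'
#' Evaluates every midpoint between consecutive sorted unique scores, plus
#' -Inf and +Inf, classifying EC when `score > threshold`, and returns the cut
#' maximizing the Youden index `J = sensitivity + specificity - 1`. Ties are
#' broken toward higher specificity (then toward the higher threshold). Also
#' returns the full ROC curve and the AUC with DeLong 95% CI.
#'
#' @param scores numeric score vector (e.g. EML scores).
#' @param labels class vector (CTRL/EC); both classes required.
#' @return list of class `threshold_result`: `threshold`, `j`, `sensitivity`,
#'   `specificity`, `auc`, `auc_var`, `ci`, and `roc` (data.frame of all cuts).
#' @export
choose_threshold <- function(scores, labels) {
  y <- as_class_factor(labels)
  pos <- y == POSITIVE_CLASS
  if (!any(pos) || all(pos)) stop("both classes must be present")
  u <- sort(unique(scores))
  cuts <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(cuts, function(c) mean(scores[pos] > c), numeric(1))
  sp_ <- vapply(cuts, function(c) mean(scores[!pos] <= c), numeric(1))
  j <- sens + sp_ - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[sp_[best] == max(sp_[best])]
  best <- best[which.max(cuts[best])]
  a <- auc_delong_ci(scores, pos)
  structure(list(threshold = cuts[best], j = j[best],
                 sensitivity = sens[best], specificity = sp_[best],
                 auc = a$auc, auc_var = a$var, ci = a$ci,
                 roc = data.frame(threshold = cuts, sensitivity = sens,
                                  specificity = sp_, j = j)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> threshold %.4g (J = %.3f; S = %.3f, Sp = %.3f); AUC %.3f (95%% CI %.3f-%.3f)\n",
    x$threshold, x$j, x$sensitivity, x$specificity, x$auc, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Likelihood ratios from sensitivity and specificity
#'
#' `PLR = S / (1 - Sp)` and `NLR = (1 - S) / Sp`; a zero denominator makes the
#' ratio not determinable (`NA`, printed as "ND").
#'
#' @param sensitivity,specificity rates in \[0, 1\].
#' @return list with `plr` and `nlr` (`NA` = ND).
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  list(plr = if (specificity < 1) sensitivity / (1 - specificity) else NA_real_,
       nlr = if (specificity > 0) (1 - sensitivity) / specificity else NA_real_)
}

#' Diagnostic-metric panel
#'
#' Confusion counts and the derived screening metrics: sensitivity
#' `S = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, positive / negative
#' likelihood ratios `PLR = S/(1-Sp)`, `NLR = (1-S)/Sp`, predictive values
#' `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`, accuracy `A = (TP+TN)/total`, and
#' (when scores are supplied) the AUC with DeLong 95% CI. Ratios with a zero
#' denominator are not determinable and reported as `NA` (printed "ND").
#'
#' @param predictions predicted class vector (CTRL/EC).
#' @param truth true class vector; both classes required.
#' @param scores optional numeric scores for the AUC.
#' @return object of class `diagnostic_panel`.
#' @export
diagnostic_panel <- function(predictions, truth, scores = NULL) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth must have equal length")
  }
  truth <- as_class_factor(truth)
  predictions <- factor(as.character(predictions),
                        levels = c(NEGATIVE_CLASS, POSITIVE_CLASS))
  tp <- sum(predictions == POSITIVE_CLASS & truth == POSITIVE_CLASS)
  fp <- sum(predictions == POSITIVE_CLASS & truth == NEGATIVE_CLASS)
  tn <- sum(predictions == NEGATIVE_CLASS & truth == NEGATIVE_CLASS)
  fn <- sum(predictions == NEGATIVE_CLASS & truth == POSITIVE_CLASS)
  s <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  lr <- likelihood_ratios(s, sp)
  auc <- if (!is.null(scores)) auc_delong_ci(scores, truth == POSITIVE_CLASS)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = s, specificity = sp,
                 plr = lr$plr, nlr = lr$nlr,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 accuracy = (tp + tn) / length(truth),
                 auc = if (!is.null(auc)) auc$auc,
                 auc_ci = if (!is.null(auc)) auc$ci),
            class = "diagnostic_panel")
}

fmt_nd <- function(v, digits = 2) {
  if (is.null(v) || is.na(v)) "ND" else formatC(v, digits = digits, format = "f")
}

#' @export
print.diagnostic_panel <- function(x, digits = 2, ...) {
  cat("<diagnostic_panel> TP=", x$tp, " FP=", x$fp, " TN=", x$tn,
      " FN=", x$fn, "\n", sep = "")
  cat(sprintf("  S = %s  Sp = %s  PLR = %s  NLR = %s\n",
              fmt_nd(x$sensitivity, digits), fmt_nd(x$specificity, digits),
              fmt_nd(x$plr, digits), fmt_nd(x$nlr, digits)))
  cat(sprintf("  PPV = %s  NPV = %s  A = %s\n",
              fmt_nd(x$ppv, digits), fmt_nd(x$npv, digits),
              fmt_nd(x$accuracy, digits)))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1],
                x$auc_ci[2]))
  }
  invisible(x)
}

#' Screen a cohort with the trained ensemble
#'
#' Each admitted model votes on every sample; votes are summed into per-sample
#' EML scores; a sample is called EC exactly when its score strictly exceeds
#' the threshold.
#'
#' @param models non-empty list of `trained_model` (the admitted ensemble).
#' @param x preprocessed matrix (or `processed_matrix`) on the training
#'   transform.
#' @param threshold decision threshold (default 0, the defining sign
#'   convention; typically the Youden cut from [choose_threshold()]).
#' @param scale vote scale (default 100).
#' @return object of class `eml_result`: `samples` (data.frame with `score`
#'   and `class` per sample), `votes` (samples x models matrix of signed
#'   votes), `threshold`, `scale`.
#' @export
screen_cohort <- function(models, x, threshold = 0, scale = 100) {
  stopifnot(length(models) > 0)
  if (inherits(x, "processed_matrix")) x <- x$x
  votes <- vapply(models, function(m) {
    pr <- predict_confidence(m, x)
    sign <- ifelse(pr$label == POSITIVE_CLASS, 1, -1)
    sign * scale * m$cv_accuracy * pr$confidence
  }, numeric(nrow(x)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(x))
  colnames(votes) <- vapply(models, `[[`, character(1), "kind")
  rownames(votes) <- rownames(x)
  score <- rowSums(votes)
  structure(list(
    samples = data.frame(sample_id = rownames(x), score = score,
                         class = ifelse(score > threshold, POSITIVE_CLASS,
                                        NEGATIVE_CLASS),
                         row.names = NULL, stringsAsFactors = FALSE),
    votes = votes, threshold = threshold, scale = scale),
    class = "eml_result")
}

#' @export
print.eml_result <- function(x, ...) {
  cat("<eml_result> ", nrow(x$samples), " samples, ", ncol(x$votes),
      " models, threshold ", format(x$threshold, digits = 4), "\n", sep = "")
  cat("  called EC: ", sum(x$samples$class == POSITIVE_CLASS), "\n", sep = "")
  invisible(x)
}

#' Per-class EML score summary
#'
#' One row per patient class: N, mean, sd, min, max of the EML score, and the
#' classification error rate at the result's threshold (for the EC class an
#' error is a score at or below threshold; for every other class a score above
#' it).
#'
#' @param result an `eml_result`.
#' @param classes class label per sample (any number of patient classes; "EC"
#'   marks the cancer class).
#' @return data.frame with columns `class`, `n`, `mean`, `sd`, `min`, `max`,
#'   `error_rate`.
#' @export
summarize_scores <- function(result, classes) {
  stopifnot(inherits(result, "eml_result"),
            length(classes) == nrow(result$samples))
  classes <- as.character(classes)
  do.call(rbind, lapply(unique(classes), function(cl) {
    s <- result$samples$score[classes == cl]
    called_ec <- s > result$threshold
    err <- if (cl == POSITIVE_CLASS) mean(!called_ec) else mean(called_ec)
    data.frame(class = cl, n = length(s), mean = mean(s), sd = sd(s),
               min = min(s), max = max(s), error_rate = err,
               stringsAsFactors = FALSE)
  }))
}
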