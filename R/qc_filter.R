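#' Reference for the pooled-sample QC condition
#'
#' The pooled-injection condition compares each batch's pooled profile against
#' the other batches' pooled injections: the centroid of their IS-normalized
#' profiles, with the cohort's total spread as the yardstick. `sd_norm` is the
#' euclidean norm of the per-feature standard deviations of the member
#' samples' IS-normalized profiles (the "total spread" of the data).
#'
#' @param batches list of `batch_record` objects.
#' @return list with `pooled_profiles` (matrix, one normalized pooled profile
#'   per batch), `centroid`, and `sd_norm`.
#' @export
pooled_reference <- function(batches) {
  stopifnot(length(batches) > 0)
  qp <- t(vapply(batches, function(b) b$pooled$areas / b$pooled$is_area,
                 numeric(length(batches[[1]]$pooled$areas))))
  members <- do.call(rbind, lapply(batches, function(b) b$profiles / b$is_area))
  sds <- apply(members, 2, sd, na.rm = TRUE)
  sds[!is.finite(sds)] <- 0
  list(pooled_profiles = qp, centroid = colMeans(qp),
       sd_norm = sqrt(sum(sds^2)))
}

#' Validate an analytical batch against the four QC conditions
#'
#' A batch is accepted only if all four hold:
#' \enumerate{
#'   \item the solvent blank generated no peaks (no area above the detection
#'     floor, i.e. strictly positive);
#'   \item every standard-mix analyte's IS-normalized peak area is within
#'     `tol_standard` (default 10%) of its expected value;
#'   \item over the 100 highest peaks of the duplicated sample, the
#'     IS-normalized areas of the repeat injection deviate from the first
#'     injection by less than `tol_duplicate` (default 15%) on average (the
#'     per-peak maximum is also reported);
#'   \item the pooled injection falls in the same region as the other pooled
#'     injections: its euclidean distance from their centroid, relative to the
#'     data's total standard-deviation norm, is below `tol_pooled` (default
#'     5%). With no reference (a single batch) the condition passes with
#'     statistic 0.
#' }
#'
#' @param batch a `batch_record`.
#' @param tol_standard,tol_duplicate,tol_pooled fractional tolerances.
#' @param reference output of [pooled_reference()] on the prior batches (the
#'   pooled injections already accepted), or `NULL`. With no reference the
#'   condition passes with statistic 0 (there is nothing to deviate from yet).
#' @param top_n number of highest peaks used by the duplicate condition.
#' @return object of class `qc_report`: per-condition statistic and pass flag,
#'   and `pass` = conjunction of the four.
#' @export
validate_batch <- function(batch, tol_standard = 0.10, tol_duplicate = 0.15,
                           tol_pooled = 0.05, reference = NULL, top_n = 100) {
  stopifnot(inherits(batch, "batch_record"))
  for (ctrl in c("blank", "standard", "pooled", "duplicate")) {
    if (is.null(batch[[ctrl]])) stop("batch is missing its ", ctrl, " control profile")
  }
  # 1. blank: no peaks above the detection floor
  n_blank <- sum(batch$blank$areas > 0, na.rm = TRUE)
  # 2. standard mix: max relative deviation of normalized areas from expected
  obs <- batch$standard$areas / batch$standard$is_area
  std_dev <- max(abs(obs / batch$standard$expected - 1))
  # 3. duplicate: mean relative deviation over the top-N original peaks
  orig <- batch$duplicate$original / batch$duplicate$is_area
  rep_inj <- batch$duplicate$areas / batch$duplicate$is_area
  ok <- which(is.finite(orig) & orig > 0 & is.finite(rep_inj))
  top <- ok[order(orig[ok], decreasing = TRUE)][seq_len(min(top_n, length(ok)))]
  rel <- abs(rep_inj[top] - orig[top]) / orig[top]
  dup_mean <- mean(rel)
  dup_max <- max(rel)
  # 4. pooled: normalized euclidean deviation from the reference centroid
  if (!is.null(reference) && nrow(reference$pooled_profiles) > 0 &&
      reference$sd_norm > 0) {
    q <- batch$pooled$areas / batch$pooled$is_area
    pooled_score <- sqrt(sum((q - colMeans(reference$pooled_profiles))^2)) /
      reference$sd_norm
  } else {
    pooled_score <- 0
  }
  conditions <- data.frame(
    condition = c("blank_no_peaks", "standard_within_tol",
                  "duplicate_within_tol", "pooled_within_tol"),
    statistic = c(n_blank, std_dev, dup_mean, pooled_score),
    tolerance = c(0, tol_standard, tol_duplicate, tol_pooled),
    pass = c(n_blank == 0, std_dev <= tol_standard,
             dup_mean < tol_duplicate, pooled_score < tol_pooled)
  )
  structure(list(batch_id = batch$batch_id, conditions = conditions,
                 duplicate_max_deviation = dup_max,
                 pass = all(conditions$pass)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> batch ", x$batch_id, ": ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' Validate every batch of a cohort
#'
#' @param batches list of `batch_record` objects, in acquisition order.
#' @param ... passed to [validate_batch()].
#' @return list of `qc_report`, one per batch. Each batch's pooled condition
#'   uses the running centroid of the prior batches' pooled injections (the
#'   first batch has no reference and passes that condition vacuously), so a
#'   pooled outlier flags its own batch rather than its neighbours.
#' @export
validate_batches <- function(batches, ...) {
  lapply(seq_along(batches), function(i) {
    ref <- if (i > 1) pooled_reference(batches[seq_len(i - 1)])
    validate_batch(batches[[i]], reference = ref, ...)
  })
}

#' Write QC reports as JSON
#'
#' @param reports list of `qc_report` (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_reports <- function(reports, path) {
  if (inherits(reports, "qc_report")) reports <- list(reports)
  out <- lapply(reports, function(r) {
    list(batch_id = r$batch_id, pass = r$pass,
         conditions = r$conditions,
         duplicate_max_deviation = r$duplicate_max_deviation)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Feature presence filter
#'
#' Retains the features consistently found in at least
#' `presence_threshold` of the samples (inclusive bound); everything else is
#' removed. Optionally, features whose median observed raw area falls below
#' `min_median_area` are removed too (off by default; low-intensity peaks with
#' poor spectral quality have no numeric cutoff of record).
#'
#' @param table a [peak_table()].
#' @param presence_threshold required non-missing fraction, in (0, 1].
#' @param min_median_area optional minimum median area (`NULL` = off).
#' @return list with `table` (filtered [peak_table()], samples unchanged) and
#'   `removed` (feature names, sorted).
#' @export
filter_features <- function(table, presence_threshold = 0.80,
                            min_median_area = NULL) {
  stopifnot(inherits(table, "peak_table"), nrow(table$areas) > 0)
  if (presence_threshold <= 0 || presence_threshold > 1) {
    stop("presence_threshold must be in (0, 1]")
  }
  presence <- colMeans(!is.na(table$areas))
  keep <- presence >= presence_threshold
  if (!is.null(min_median_area)) {
    med <- apply(table$areas, 2, median, na.rm = TRUE)
    keep <- keep & !is.na(med) & med >= min_median_area
  }
  removed <- sort(colnames(table$areas)[!keep])
  list(table = subset_peak_table(table, features = which(keep)),
       removed = removed)
}
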