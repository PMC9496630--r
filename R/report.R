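#' Volcano analysis of metabolite abundance
#'
#' Per metabolite, the fold change `FC = GM(EC) / GM(CTRL)` (ratio of
#' geometric means of the IS-normalized areas, consistent with testing on the
#' log scale) and a two-sample t-test p-value on the log values (Welch by
#' default; the classical equal-variance Student's t is available). A
#' metabolite is flagged when `(FC > fc_hi OR FC < fc_lo) AND p < alpha`, both
#' bounds strict. A Benjamini-Hochberg adjusted p-value column is emitted for
#' reference but does not enter the flag.
#'
#' @param table an IS-normalized [peak_table()] (raw tables are normalized
#'   on the fly). Missing cells are ignored per feature.
#' @param labels class vector (CTRL/EC); default the table's labels.
#' @param fc_hi,fc_lo fold-change bounds (defaults 2 and 0.5).
#' @param alpha significance level (default 0.05).
#' @param var_equal use the equal-variance Student's t instead of Welch.
#' @return data.frame of class `volcano_table`: `feature`, `fold_change`,
#'   `p_value`, `p_adj`, `direction` ("up"/"down"/"none"), `flagged`.
#' @export
volcano <- function(table, labels = NULL, fc_hi = 2.0, fc_lo = 0.5,
                    alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(table, "peak_table"), fc_hi > fc_lo, fc_lo > 0)
  if (!table$normalized) table <- normalize_to_is(table)
  labels <- labels %||% table$label
  y <- as_class_factor(labels)
  if (min(table(y)) < 2) stop("each class needs at least 2 samples")
  la <- log(table$areas)
  res <- do.call(rbind, lapply(seq_len(ncol(la)), function(j) {
    v_ec <- la[y == POSITIVE_CLASS, j]
    v_ct <- la[y == NEGATIVE_CLASS, j]
    v_ec <- v_ec[is.finite(v_ec)]
    v_ct <- v_ct[is.finite(v_ct)]
    fc <- exp(mean(v_ec) - mean(v_ct))
    p <- if (length(v_ec) >= 2 && length(v_ct) >= 2 &&
             (sd(v_ec) > 0 || sd(v_ct) > 0)) {
      t.test(v_ec, v_ct, var.equal = var_equal)$p.value
    } else NA_real_
    data.frame(feature = colnames(la)[j], fold_change = fc, p_value = p)
  }))
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  # strict bounds, compared after rounding to 12 significant digits so a
  # fold change sitting exactly on a bound is not flagged by log/exp roundoff
  fc <- signif(res$fold_change, 12)
  res$direction <- ifelse(fc > fc_hi, "up", ifelse(fc < fc_lo, "down", "none"))
  res$flagged <- res$direction != "none" & !is.na(res$p_value) &
    res$p_value < alpha
  class(res) <- c("volcano_table", "data.frame")
  res
}

#' Metabolites above a VIP cutoff
#'
#' @param diag a [plsda_diagnostics()] result (or a named VIP vector).
#' @param cutoff strict VIP cutoff (default 2.0).
#' @return data.frame `feature`, `vip`, ranked by descending VIP.
#' @export
vip_table <- function(diag, cutoff = 2.0) {
  vip <- if (inherits(diag, "plsda_diagnostics")) diag$vip else diag
  vip <- sort(vip[vip > cutoff], decreasing = TRUE)
  data.frame(feature = names(vip), vip = unname(vip),
             stringsAsFactors = FALSE)
}
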