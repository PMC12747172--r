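# Confusion-matrix metrics (low-quality is the positive class), index-based
# baselines, and the statistical comparison suite: McNemar with continuity
# correction, Friedman, Wilcoxon signed-rank with Benjamini-Hochberg
# correction, and Cliff's delta.

#' Confusion-matrix metrics with low-quality as the positive class
#'
#' Computes accuracy, precision, recall (sensitivity), specificity and
#' F1-score, all in percent. Ratios with zero denominators are reported as
#' `NaN` with a warning (degenerate test sets should be visible, not masked).
#'
#' @param truth,pred character vectors of "high"/"low" (low = positive).
#' @param method optional method label stored in the result.
#' @return list of class `eval_report`: counts `tp`, `tn`, `fp`, `fn` and
#'   metrics `accuracy`, `precision`, `recall`, `specificity`, `f1` (percent).
#' @export
confusion_metrics <- function(truth, pred, method = "model") {
  if (length(truth) != length(pred)) stopf("label vectors differ in length")
  if (!all(c(truth, pred) %in% c("high", "low"))) stopf("labels must be 'high'/'low'")
  tp <- sum(truth == "low" & pred == "low")
  tn <- sum(truth == "high" & pred == "high")
  fp <- sum(truth == "high" & pred == "low")
  fn <- sum(truth == "low" & pred == "high")
  ratio <- function(num, den, what) {
    if (den == 0) { warnf("%s undefined (zero denominator)", what); return(NaN) }
    100 * num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
    warnf("F1 undefined"); NaN
  } else 2 * precision * recall / (precision + recall)
  structure(list(method = method, tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = ratio(tp + tn, tp + tn + fp + fn, "accuracy"),
                 precision = precision, recall = recall,
                 specificity = ratio(tn, tn + fp, "specificity"), f1 = f1),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s: acc %.2f%%, prec %.2f%%, rec %.2f%%, F1 %.2f%%, spec %.2f%% (tp %d tn %d fp %d fn %d)>\n",
              x$method, x$accuracy, x$precision, x$recall, x$f1, x$specificity,
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' F1 score from precision and recall (percent)
#' @param precision,recall percent values.
#' @return F1 in percent.
#' @export
f1_from_pr <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' McNemar's test with continuity correction
#'
#' `chi2 = (|b - c| - 1)^2 / (b + c)` on the discordant-pair counts of two
#' paired classifiers, with a chi-square (1 df) p-value.
#'
#' @param b count: method A wrong, method B right.
#' @param c count: method A right, method B wrong.
#' @return list with `b`, `c`, `chi2`, `p`.
#' @export
mcnemar <- function(b, c) {
  if (b < 0 || c < 0) stopf("counts must be nonnegative")
  if (b + c == 0) stopf("no discordant pairs")
  chi2 <- (abs(b - c) - 1)^2 / (b + c)
  list(b = b, c = c, chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Friedman rank test across blocks
#'
#' Mid-rank Friedman chi-square with tie correction (k - 1 df). Degenerate
#' all-tied data yields statistic 0 and p 1.
#'
#' @param m numeric matrix `[blocks x treatments]` (e.g. folds x methods).
#' @return list with `chi2`, `df`, `p`.
#' @export
friedman <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stopf("need >= 2 blocks and >= 2 treatments")
  r <- t(apply(m, 1, rank))
  tie_term <- sum(unlist(apply(r, 1, function(row) {
    tb <- table(row); tb^3 - tb
  })))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) return(list(chi2 = 0, df = k - 1, p = 1))
  chi2 <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  list(chi2 = chi2, df = k - 1, p = stats::pchisq(chi2, k - 1, lower.tail = FALSE))
}

#' Wilcoxon signed-rank test
#'
#' Exact distribution by enumeration of all sign assignments for n <= 12
#' (mid-ranks under ties, correct even with tied magnitudes); the normal
#' approximation with tie-corrected variance and continuity correction above.
#' Zero differences are dropped (Wilcoxon's rule).
#'
#' @param d numeric vector of paired differences.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param exact_n largest n solved exactly (default 12).
#' @return list with `V` (positive-rank sum), `p`, `n`, `exact`.
#' @export
wilcoxon_signed_rank <- function(d, alternative = c("two.sided", "greater", "less"),
                                 exact_n = 12) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stopf("all differences zero")
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  if (n <= exact_n) {
    # enumerate all 2^n sign assignments of the observed rank magnitudes
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.numeric(signs %*% rk)
    p_ge <- mean(Vs >= V)
    p_le <- mean(Vs <= V)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(list(V = V, p = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- 0.5
  z_g <- (V - mu - cc) / sqrt(sigma2)
  z_l <- (V - mu + cc) / sqrt(sigma2)
  p <- switch(alternative,
              greater = stats::pnorm(z_g, lower.tail = FALSE),
              less = stats::pnorm(z_l),
              two.sided = min(1, 2 * min(stats::pnorm(z_g, lower.tail = FALSE),
                                         stats::pnorm(z_l))))
  list(V = V, p = p, n = n, exact = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#' @param p raw p-values.
#' @return adjusted p-values (monotone, >= raw).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Pairwise Wilcoxon signed-rank tests with BH correction
#'
#' @param diffs list of per-pair difference vectors (e.g. per-fold metric
#'   differences between two methods).
#' @param alternative passed to [wilcoxon_signed_rank()].
#' @return data frame with `pair`, `V`, `p`, `p_adj`.
#' @export
wilcoxon_bh <- function(diffs, alternative = "two.sided") {
  res <- lapply(diffs, wilcoxon_signed_rank, alternative = alternative)
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(pair = names(diffs) %||% seq_along(diffs),
             V = vapply(res, `[[`, numeric(1), "V"),
             p = p, p_adj = bh_adjust(p))
}

#' Cliff's delta effect size
#'
#' `(#\{x_i > y_j\} - #\{x_i < y_j\}) / (|x| |y|)`; ties contribute zero.
#'
#' @param x,y numeric vectors.
#' @return delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be nonempty")
  cmp <- outer(x, y, `-`)
  (sum(cmp > 0) - sum(cmp < 0)) / (length(x) * length(y))
}

#' Index-based baseline classification of segments
#'
#' Applies the two conventional index-based rules per segment: coefficient of
#' variation of raw intensity (low-quality when CV of either wavelength
#' exceeds `cv_threshold` percent) and scalp coupling index (low-quality when
#' below `sci_threshold`), and evaluates both against the provided labels.
#'
#' @param rec an `fnirs_recording`.
#' @param segments segment reference data frame (from [segment_channels()]).
#' @param truth character vector of true labels aligned with `segments`.
#' @param cv_threshold CV threshold in percent (default 15).
#' @param sci_threshold SCI threshold (default 0.75).
#' @return list with per-method `eval_report`s (`cv`, `sci`) and the
#'   per-segment predictions (`pred_cv`, `pred_sci`).
#' @export
run_baselines <- function(rec, segments, truth, cv_threshold = 15,
                          sci_threshold = 0.75) {
  stopifnot(nrow(segments) == length(truth))
  pred_cv <- character(nrow(segments))
  pred_sci <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    w1 <- segment_slice(rec, segments$channel_index[i], segments$start_sample[i],
                        segments$end_sample[i], 1)
    w2 <- segment_slice(rec, segments$channel_index[i], segments$start_sample[i],
                        segments$end_sample[i], 2)
    cv <- max(coefficient_of_variation(w1), coefficient_of_variation(w2))
    pred_cv[i] <- cv_classify(cv, cv_threshold)
    s <- suppressWarnings(sci(w1, w2, rec$fs))
    pred_sci[i] <- sci_classify(s, sci_threshold)
  }
  list(cv = confusion_metrics(truth, pred_cv, "cv"),
       sci = confusion_metrics(truth, pred_sci, "sci"),
       pred_cv = pred_cv, pred_sci = pred_sci)
}

#' Class-share arithmetic for annotated datasets
#'
#' Recomputes per-dataset and combined class shares from per-dataset
#' low/high counts, with exact rational arithmetic before rounding.
#'
#' @param counts named list of `c(low = ..., high = ...)` per dataset.
#' @return data frame with one row per dataset plus a `combined` row:
#'   `n`, `low`, `high`, `low_pct`, `high_pct`.
#' @export
summarize_label_counts <- function(counts) {
  rows <- lapply(names(counts), function(nm) {
    lc <- counts[[nm]]
    n <- lc[["low"]] + lc[["high"]]
    data.frame(dataset = nm, n = n, low = lc[["low"]], high = lc[["high"]],
               low_pct = 100 * lc[["low"]] / n, high_pct = 100 * lc[["high"]] / n)
  })
  df <- do.call(rbind, rows)
  tot_low <- sum(df$low); tot_high <- sum(df$high); tot <- tot_low + tot_high
  rbind(df, data.frame(dataset = "combined", n = tot, low = tot_low,
                       high = tot_high, low_pct = 100 * tot_low / tot,
                       high_pct = 100 * tot_high / tot))
}
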