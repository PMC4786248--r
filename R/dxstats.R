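# Evaluation machinery: expert-panel adjudication with image-quality gating,
# confusion matrices, test characteristics with exact (Clopper-Pearson)
# confidence intervals, Cohen's kappa, and stratified accuracy reports.

ptx_labels <- c("positive", "negative", "indeterminate")

#' Adjudicate expert-panel ratings
#'
#' An exam enters the analysis set only when all raters give the same label
#' and — when the quality rule is on — the median ACEP image-quality score is
#' at least 3 (scores of 1-2 are considered non-diagnostic).  Non-unanimous
#' exams are flagged for plenary review rather than resolved.
#'
#' @param ratings Data frame with columns `exam_id`, `rater_id`, `label`,
#'   `quality_score` (one row per exam-rater pair; every exam needs at least
#'   two raters).
#' @param quality_rule Apply the median-quality >= 3 gate (default `TRUE`).
#' @return Tibble with one row per exam: `exam_id`, `n_raters`,
#'   `consensus_label` (`NA` when not unanimous), `median_quality`,
#'   `included`, and `reason` (`"non_unanimous"` or `"quality_below_3"` for
#'   excluded exams, else `NA`).
#' @export
adjudicate <- function(ratings, quality_rule = TRUE) {
  stopifnot(all(c("exam_id", "rater_id", "label", "quality_score") %in% names(ratings)))
  bad <- setdiff(unique(ratings$label), ptx_labels)
  if (length(bad) > 0L) {
    ptx_abort("bad_label", paste("unknown labels:", paste(bad, collapse = ", ")))
  }
  out <- ratings |>
    dplyr::group_by(.data$exam_id) |>
    dplyr::summarise(
      n_raters = dplyr::n(),
      unanimous = dplyr::n_distinct(.data$label) == 1L,
      consensus_label = ifelse(dplyr::n_distinct(.data$label) == 1L,
                               .data$label[1], NA_character_),
      median_quality = median(.data$quality_score),
      .groups = "drop"
    )
  if (any(out$n_raters < 2L)) {
    ptx_abort("single_rater", sprintf(
      "exams with a single rater: %s",
      paste(out$exam_id[out$n_raters < 2L], collapse = ", ")
    ))
  }
  quality_ok <- !quality_rule | (!is.na(out$median_quality) & out$median_quality >= 3)
  out$included <- out$unanimous & quality_ok
  out$reason <- dplyr::case_when(
    !out$unanimous ~ "non_unanimous",
    !quality_ok ~ "quality_below_3",
    TRUE ~ NA_character_
  )
  out$unanimous <- NULL
  out
}

#' Construct a confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative integer counts (positive = pneumothorax).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    ptx_abort("bad_counts", "confusion counts must be non-negative integers")
  }
  structure(lapply(as.list(counts), as.integer), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Cross-tabulate predictions against a reference standard
#'
#' Positive means pneumothorax.  Reference-indeterminate exams are always
#' dropped (they carry no usable truth).  Prediction-indeterminate exams are
#' handled by policy: `"exclude"` drops them; `"as_error"` counts them
#' against the predictor (false negative under a positive reference, false
#' positive under a negative one).
#'
#' @param pred Data frame with `exam_id`, `label` (algorithm calls).
#' @param ref Data frame with `exam_id`, `label` (reference standard).
#' @param indeterminate_policy `"exclude"` or `"as_error"`.
#' @return A `confusion_matrix`.
#' @export
confusion <- function(pred, ref, indeterminate_policy = c("exclude", "as_error")) {
  indeterminate_policy <- match.arg(indeterminate_policy)
  stopifnot(all(c("exam_id", "label") %in% names(pred)),
            all(c("exam_id", "label") %in% names(ref)))
  bad <- setdiff(unique(c(pred$label, ref$label)), ptx_labels)
  if (length(bad) > 0L) {
    ptx_abort("bad_label", paste("unknown labels:", paste(bad, collapse = ", ")))
  }
  ref <- ref[ref$label != "indeterminate", , drop = FALSE]
  pred <- pred[pred$exam_id %in% ref$exam_id, , drop = FALSE]
  if (!setequal(pred$exam_id, ref$exam_id)) {
    ptx_abort("unmatched_exams",
              "prediction and reference exam sets differ after dropping reference-indeterminate exams")
  }
  d <- dplyr::inner_join(
    tibble(exam_id = pred$exam_id, pred = pred$label),
    tibble(exam_id = ref$exam_id, ref = ref$label),
    by = "exam_id"
  )
  if (indeterminate_policy == "exclude") {
    d <- d[d$pred != "indeterminate", , drop = FALSE]
  } else {
    d$pred[d$pred == "indeterminate" & d$ref == "positive"] <- "negative"
    d$pred[d$pred == "indeterminate" & d$ref == "negative"] <- "positive"
  }
  confusion_matrix(
    tp = sum(d$pred == "positive" & d$ref == "positive"),
    fp = sum(d$pred == "positive" & d$ref == "negative"),
    tn = sum(d$pred == "negative" & d$ref == "negative"),
    fn = sum(d$pred == "negative" & d$ref == "positive")
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval from binomial tail inversion; the lower bound is 0 when
#' `k = 0` and the upper bound is 1 when `k = n`.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
exact_binomial_ci <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n) {
    ptx_abort("bad_counts", "need 0 <= k <= n with n >= 1")
  }
  ci <- stats::binom.test(k, n, conf.level = level)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Diagnostic test characteristics with exact CIs
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`, NPV
#' `tn/(tn+fn)`, each with a Clopper-Pearson interval.  A statistic whose
#' denominator is zero is reported explicitly as undefined (`NA`), never
#' as 0.
#'
#' @param cm A [confusion_matrix()].
#' @param level Confidence level (default 0.95).
#' @return Tibble of class `test_characteristics` with columns `metric`, `k`,
#'   `n`, `estimate`, `lower`, `upper`.
#' @export
characteristics <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  spec <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv = c(cm$tp, cm$tp + cm$fp),
    npv = c(cm$tn, cm$tn + cm$fn)
  )
  rows <- purrr::imap(spec, function(kn, metric) {
    k <- kn[1]; n <- kn[2]
    if (n == 0L) {
      tibble(metric = metric, k = k, n = n,
             estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      ci <- exact_binomial_ci(k, n, level)
      tibble(metric = metric, k = k, n = n,
             estimate = k / n, lower = ci[["lower"]], upper = ci[["upper"]])
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "level") <- level
  class(out) <- c("test_characteristics", class(out))
  out
}

#' @export
print.test_characteristics <- function(x, ...) {
  cat(sprintf("Test characteristics (%.0f%% exact CI):\n", 100 * attr(x, "level")))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-12s undefined (denominator 0)\n", x$metric[i]))
    } else {
      cat(sprintf("  %-12s %d%% (%d-%d)  [%d/%d]\n", x$metric[i],
                  percent_round(x$estimate[i]), percent_round(x$lower[i]),
                  percent_round(x$upper[i]), x$k[i], x$n[i]))
    }
  }
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with `p_e` from the
#' marginal products, a large-sample standard-error CI, and the conventional
#' interpretation bands: above 0.75 excellent, 0.40-0.75 fair to good,
#' below 0.40 poor.
#'
#' @param rater_a,rater_b Equal-length label vectors over the same category
#'   set.
#' @param level Confidence level (default 0.95).
#' @return A `cohen_kappa` object: `kappa`, `se`, `lower`, `upper`, `p_o`,
#'   `p_e`, `n`, `band`, `table`.
#' @export
cohen_kappa <- function(rater_a, rater_b, level = 0.95) {
  if (length(rater_a) != length(rater_b) || length(rater_a) == 0L) {
    ptx_abort("bad_ratings", "rater vectors must be non-empty and equal-length")
  }
  lev <- sort(unique(c(as.character(rater_a), as.character(rater_b))))
  tab <- table(factor(rater_a, lev), factor(rater_b, lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < 1e-12) {
    ptx_abort("undefined_kappa",
              "expected agreement is 1 (degenerate marginals): kappa undefined")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- qnorm(1 - (1 - level) / 2)
  eps <- sqrt(.Machine$double.eps)
  band <- if (kappa > 0.75 + eps) "excellent" else {
    if (kappa >= 0.40 - eps) "fair to good" else "poor"
  }
  structure(
    list(kappa = kappa, se = se,
         lower = max(-1, kappa - z * se), upper = min(1, kappa + z * se),
         p_o = p_o, p_e = p_e, n = as.integer(n), band = band, table = tab),
    class = "cohen_kappa"
  )
}

#' @export
print.cohen_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa %.2f (95%% CI %.2f-%.2f), n=%d: %s agreement\n",
              x$kappa, x$lower, x$upper, x$n, x$band))
  invisible(x)
}

#' Stratified diagnostic-accuracy report
#'
#' One confusion matrix plus test characteristics per stratum level and
#' overall.  Levels with zero denominators are reported as undefined, not
#' dropped.
#'
#' @param records Data frame of per-exam predictions with metadata: columns
#'   `exam_id`, `label`, plus any requested stratum columns (e.g.
#'   `quality_score`, `mode`, `transducer`).
#' @param ref Data frame with `exam_id`, `label` (reference standard).
#' @param strata Character vector of stratum column names (default the three
#'   the study reports on).
#' @param indeterminate_policy Passed to [confusion()].
#' @param level Confidence level.
#' @return Tibble with one row per (stratum, level, metric): columns
#'   `stratum`, `level`, `tp`, `fp`, `tn`, `fn`, `metric`, `k`, `n`,
#'   `estimate`, `lower`, `upper`.  Overall rows have
#'   `stratum = level = "overall"`.
#' @export
stratified_report <- function(records, ref,
                              strata = c("quality_score", "mode", "transducer"),
                              indeterminate_policy = c("exclude", "as_error"),
                              level = 0.95) {
  indeterminate_policy <- match.arg(indeterminate_policy)
  stopifnot(all(c("exam_id", "label") %in% names(records)))
  missing <- setdiff(strata, names(records))
  if (length(missing) > 0L) {
    ptx_abort("unknown_stratum",
              paste("stratum columns absent from records:", paste(missing, collapse = ", ")))
  }
  block <- function(stratum, lvl, sub) {
    cm <- confusion(sub[c("exam_id", "label")],
                    ref[ref$exam_id %in% sub$exam_id, , drop = FALSE],
                    indeterminate_policy)
    tc <- characteristics(cm, level)
    tibble(stratum = stratum, level = lvl,
           tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
           metric = tc$metric, k = tc$k, n = tc$n,
           estimate = tc$estimate, lower = tc$lower, upper = tc$upper)
  }
  out <- list(block("overall", "overall", records))
  for (s in strata) {
    vals <- records[[s]]
    lvls <- sort(unique(vals[!is.na(vals)]))
    for (v in lvls) {
      sub <- records[!is.na(vals) & vals == v, , drop = FALSE]
      out[[length(out) + 1L]] <- block(s, as.character(v), sub)
    }
    if (anyNA(vals)) {
      out[[length(out) + 1L]] <- block(s, NA_character_,
                                       records[is.na(vals), , drop = FALSE])
    }
  }
  dplyr::bind_rows(out)
}
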