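# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pneumothorax call
#'
#' @param x A `ptx_call`.
#' @param ... Unused.
#' @return One-row tibble: `exam_id`, `label`, `reason`, and the headline
#'   stage evidence (`line_found`, `sliding_detected`, `amplitude_px`,
#'   `reverberation_detected`, `barcode_fraction` — `NA` where the stage did
#'   not run or does not apply).
#' @export
tidy.ptx_call <- function(x, ...) {
  ev <- x$evidence
  tibble(
    exam_id = x$exam_id,
    label = x$label,
    reason = x$reason,
    line_found = if (!is.null(ev$line)) ev$line$found else NA,
    sliding_detected = if (!is.null(ev$sliding)) ev$sliding$sliding_detected else NA,
    amplitude_px = if (!is.null(ev$sliding)) ev$sliding$amplitude_px else NA_real_,
    reverberation_detected = if (!is.null(ev$reverb)) ev$reverb$reverberation_detected else NA,
    barcode_fraction = if (!is.null(ev$texture)) ev$texture$barcode_fraction else NA_real_
  )
}

#' Tidy a confusion matrix
#'
#' @param x A [confusion_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `cell` (tp/fp/tn/fn) and `count`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble(cell = c("tp", "fp", "tn", "fn"),
         count = c(x$tp, x$fp, x$tn, x$fn))
}

#' One-row summary of a confusion matrix
#'
#' @param x A [confusion_matrix()].
#' @param ... Unused.
#' @return One-row tibble: counts, total, and raw accuracy.
#' @export
glance.confusion_matrix <- function(x, ...) {
  total <- x$tp + x$fp + x$tn + x$fn
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, total = total,
         accuracy = if (total > 0) (x$tp + x$tn) / total else NA_real_)
}

#' Tidy Cohen's kappa
#'
#' @param x A [cohen_kappa()] result.
#' @param ... Unused.
#' @return One-row tibble: `kappa`, `se`, `lower`, `upper`, `p_o`, `p_e`,
#'   `n`, `band`.
#' @export
tidy.cohen_kappa <- function(x, ...) {
  tibble(kappa = x$kappa, se = x$se, lower = x$lower, upper = x$upper,
         p_o = x$p_o, p_e = x$p_e, n = x$n, band = x$band)
}

#' Forest plot of test characteristics
#'
#' @param object A [characteristics()] result.
#' @param ... Unused.
#' @return A ggplot: point estimates with exact CI bars, percent scale.
#' @export
autoplot.test_characteristics <- function(object, ...) {
  d <- as_tibble(object)
  d$metric <- factor(d$metric, levels = rev(c("sensitivity", "specificity", "ppv", "npv")))
  ggplot2::ggplot(d[!is.na(d$estimate), ],
                  ggplot2::aes(x = .data$estimate, y = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.2) +
    ggplot2::scale_x_continuous(labels = function(v) paste0(round(100 * v), "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "estimate (exact 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Raster view of one clip frame
#'
#' @param object A [bmode_clip()].
#' @param frame Frame index (default 1).
#' @param ... Unused.
#' @return A ggplot raster with depth increasing downwards.
#' @export
autoplot.bmode_clip <- function(object, frame = 1, ...) {
  m <- clip_frame(object, frame)
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$intensity <- as.vector(t(m))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (px)", y = "depth (px)",
                  title = sprintf("%s - frame %d", object$exam_id, frame)) +
    ggplot2::theme_minimal()
}

#' Raster view of an M-mode image
#'
#' @param object An [mmode_image()].
#' @param ... Unused.
#' @return A ggplot raster, depth down, time rightwards.
#' @export
autoplot.mmode_image <- function(object, ...) {
  m <- object$pixels
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$intensity <- as.vector(t(m))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::labs(x = "time (px)", y = "depth (px)", title = object$exam_id) +
    ggplot2::theme_minimal()
}

#' Displacement trace of a sliding measurement
#'
#' @param object A `sliding_result` from [measure_sliding()].
#' @param ... Unused.
#' @return A ggplot of the cumulated lateral displacement per frame.
#' @export
autoplot.sliding_result <- function(object, ...) {
  traj <- cumsum(c(0, object$displacements))
  d <- tibble(frame = seq_along(traj), displacement_px = traj)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$displacement_px)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "frame", y = "cumulative lateral displacement (px)") +
    ggplot2::theme_minimal()
}
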