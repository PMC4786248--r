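# Independent oracles used across the suite.

# Brute-force Clopper-Pearson bounds: bisect p on the exact binomial tail
# sums (no qbeta, no binom.test).
cp_bisect <- function(k, n, level = 0.95, tol = 1e-9) {
  alpha <- 1 - level
  upper_tail <- function(p) sum(dbinom(k:n, n, p))     # P(X >= k | p)
  lower_tail <- function(p) sum(dbinom(0:k, n, p))     # P(X <= k | p)
  bisect <- function(f, target, increasing) {
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if ((f(mid) < target) == increasing) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else bisect(upper_tail, alpha / 2, increasing = TRUE)
  upper <- if (k == n) 1 else bisect(lower_tail, alpha / 2, increasing = FALSE)
  c(lower = lower, upper = upper)
}

# Spectral oracle for the M-mode sign: stratosphere iff more than 95% of the
# sub-pleural temporal-frequency energy sits at zero frequency (per-row FFT
# along the sweep, averaged over rows).
spectral_is_stratosphere <- function(image, depth_row, gap = 3) {
  px <- image$pixels
  sub <- px[(depth_row + gap):nrow(px), , drop = FALSE]
  frac <- apply(sub, 1, function(row) {
    sp <- Mod(fft(row))^2
    if (sum(sp) == 0) 1 else sp[1] / sum(sp)
  })
  mean(frac) > 0.95
}

# Hand formula for Cohen's kappa from a square agreement table.
kappa_from_table <- function(tab) {
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  (p_o - p_e) / (1 - p_e)
}

# A default phantom config of either truth label; ... overrides any field.
phantom_for <- function(label, seed, ...) {
  defaults <- list(
    truth_label = label,
    sliding_amplitude_px = if (label == "negative") 4 else 0,
    n_blines = 0,
    mmode_pattern = if (label == "positive") "stratosphere" else "seashore",
    seed = seed
  )
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# Label vectors realising a 2x2 agreement table (a = both positive,
# b = a-positive/b-negative, c = a-negative/b-positive, d = both negative).
ratings_from_2x2 <- function(a, b, c, d) {
  list(
    a = c(rep("positive", a + b), rep("negative", c + d)),
    b = c(rep("positive", a), rep("negative", b), rep("positive", c), rep("negative", d))
  )
}

# Predictions/reference pair realising given confusion counts.
preds_from_counts <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  ids <- sprintf("x%03d", seq_len(n))
  pred <- c(rep("positive", tp), rep("positive", fp), rep("negative", tn), rep("negative", fn))
  ref <- c(rep("positive", tp), rep("negative", fp), rep("negative", tn), rep("positive", fn))
  list(pred = tibble::tibble(exam_id = ids, label = pred),
       ref = tibble::tibble(exam_id = ids, label = ref))
}
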