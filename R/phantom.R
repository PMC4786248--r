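# Seeded synthetic lung-ultrasound phantoms: speckle-textured B-mode cine
# clips with ribs, posterior acoustic shadows, a pleural line, configurable
# pleural sliding and B-line artifacts, and M-mode seashore / stratosphere
# patterns.  Every output is a pure function of (config, seed).

#' Phantom configuration
#'
#' Fully parameterized, seeded description of one synthetic exam with ground
#' truth.  Geometry is rectangular (linear-probe); depths and widths are in
#' pixels, rows are 1-based with row 1 at the skin surface.
#'
#' A `negative` exam (no pneumothorax) must carry at least one
#' negative-indicating sign — sliding (`sliding_amplitude_px > 0`) or B-lines
#' (`n_blines > 0`); a `positive` exam must carry neither.
#'
#' @param height_px,width_px,n_frames Image geometry and clip length.
#' @param rib_centers_px Lateral centers of the rib shadows (>= 2 for a
#'   detectable intercostal space).
#' @param rib_width_px Rib (and shadow) width.
#' @param rib_cap_depth_px Depth row of the bright rib cap.
#' @param shadow_attenuation Multiplier in `[0, 1]` applied below rib caps.
#' @param pleural_depth_px Depth row of the pleural line (must exceed
#'   `rib_cap_depth_px`).
#' @param pleural_brightness Pleural-band intensity in `(0, 1]`.
#' @param pleural_thickness_px Pleural-band thickness (rows).
#' @param sliding_amplitude_px Lateral sliding amplitude A; per-frame shift is
#'   `round(A * sin(2 * pi * t / period))`.
#' @param sliding_period_frames Sliding period in frames.
#' @param n_blines Number of vertical B-line (comet-tail) artifacts.
#' @param bline_width_px B-line width.
#' @param speckle_scale Rayleigh scale of the background speckle.
#' @param mmode_pattern `"seashore"`, `"stratosphere"`, or `"none"`.
#' @param truth_label `"positive"` or `"negative"` (ground truth).
#' @param seed Integer RNG seed.
#' @return A `phantom_config` object (named list).
#' @export
phantom_config <- function(height_px = 128, width_px = 192, n_frames = 20,
                           rib_centers_px = c(40, 152), rib_width_px = 16,
                           rib_cap_depth_px = 20, shadow_attenuation = 0.15,
                           pleural_depth_px = 60, pleural_brightness = 0.95,
                           pleural_thickness_px = 2,
                           sliding_amplitude_px = 4, sliding_period_frames = 20,
                           n_blines = 0, bline_width_px = 4,
                           speckle_scale = 0.15,
                           mmode_pattern = c("seashore", "stratosphere", "none"),
                           truth_label = c("negative", "positive"),
                           seed = 1L) {
  truth_label <- match.arg(truth_label)
  mmode_pattern <- match.arg(mmode_pattern)
  cfg <- list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    n_frames = as.integer(n_frames),
    rib_centers_px = as.numeric(rib_centers_px), rib_width_px = as.integer(rib_width_px),
    rib_cap_depth_px = as.integer(rib_cap_depth_px),
    shadow_attenuation = shadow_attenuation,
    pleural_depth_px = as.integer(pleural_depth_px),
    pleural_brightness = pleural_brightness,
    pleural_thickness_px = as.integer(pleural_thickness_px),
    sliding_amplitude_px = sliding_amplitude_px,
    sliding_period_frames = as.integer(sliding_period_frames),
    n_blines = as.integer(n_blines), bline_width_px = as.integer(bline_width_px),
    speckle_scale = speckle_scale,
    mmode_pattern = mmode_pattern, truth_label = truth_label,
    seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (height_px < 16 || width_px < 16 || n_frames < 1) {
      ptx_abort("bad_config", "phantom geometry too small")
    }
    if (shadow_attenuation < 0 || shadow_attenuation > 1) {
      ptx_abort("bad_config", "shadow_attenuation must be in [0, 1]")
    }
    if (pleural_depth_px <= rib_cap_depth_px) {
      ptx_abort("bad_config", "pleural_depth_px must exceed rib_cap_depth_px")
    }
    if (pleural_depth_px >= height_px) {
      ptx_abort("bad_config", "pleural_depth_px must be less than height_px")
    }
    if (pleural_brightness <= 0 || pleural_brightness > 1) {
      ptx_abort("bad_config", "pleural_brightness must be in (0, 1]")
    }
    if (speckle_scale <= 0) ptx_abort("bad_config", "speckle_scale must be positive")
    if (sliding_amplitude_px < 0 || n_blines < 0) {
      ptx_abort("bad_config", "sliding amplitude and B-line count must be non-negative")
    }
    neg_sign <- sliding_amplitude_px > 0 || n_blines > 0
    if (truth_label == "negative" && !neg_sign) {
      ptx_abort("label_inconsistent",
                "a negative exam needs sliding_amplitude_px > 0 or n_blines > 0")
    }
    if (truth_label == "positive" && neg_sign) {
      ptx_abort("label_inconsistent",
                "a positive exam must have sliding_amplitude_px = 0 and n_blines = 0")
    }
  })
  invisible(cfg)
}

# rib intervals [start, end] (1-based, inclusive) from centers and width
rib_intervals <- function(cfg) {
  half <- cfg$rib_width_px / 2
  ctr <- sort(cfg$rib_centers_px)
  lo <- pmax(1L, as.integer(round(ctr - half + 1)))
  hi <- pmin(cfg$width_px, as.integer(round(ctr + half)))
  data.frame(start = lo, end = hi)
}

#' Per-frame lateral shift table of a phantom
#'
#' The ground-truth sub-pleural shift (px, relative to frame 1) applied in
#' frame t is `round(A * sin(2 * pi * (t - 1) / period))`.
#'
#' @param config A [phantom_config()].
#' @return Integer vector of length `n_frames`.
#' @export
phantom_shift_table <- function(config) {
  t <- seq_len(config$n_frames) - 1
  as.integer(round(config$sliding_amplitude_px *
                     sin(2 * pi * t / config$sliding_period_frames)))
}

#' Generate a synthetic B-mode cine clip
#'
#' Renders, on multiplicative Rayleigh speckle: a superficial muscle band,
#' bright rib caps with posterior acoustic shadowing, a bright pleural band
#' spanning the intercostal gap, rigid lateral sliding of the sub-pleural
#' speckle (sinusoidal time course; supra-pleural tissue static), and
#' optional B-line artifacts that move with the sliding pattern.  Identical
#' `config` (including seed) gives bit-identical output.
#'
#' @param config A [phantom_config()] with at least two rib centers.
#' @param transducer Transducer recorded in metadata.
#' @param quality_score Optional ACEP quality score for the metadata.
#' @param exam_id Identifier.
#' @return A `labeled_exam`: list with `$image` ([bmode_clip()]), `$metadata`
#'   ([exam_metadata()]), `$config`, and `$shifts` (ground-truth shift table).
#' @export
make_bmode_phantom <- function(config, transducer = "linear",
                               quality_score = NA_integer_, exam_id = "phantom") {
  validate_phantom_config(config)
  if (length(config$rib_centers_px) < 2L) {
    ptx_abort("bad_config", "need >= 2 rib centers for a detectable intercostal space")
  }
  H <- config$height_px; W <- config$width_px; T <- config$n_frames
  pd <- config$pleural_depth_px; th <- config$pleural_thickness_px
  shifts <- phantom_shift_table(config)
  buf <- max(abs(shifts)) + 1L
  ribs <- rib_intervals(config)

  frames <- with_rng(config$seed, {
    above <- matrix(rrayleigh((pd - 1) * W, config$speckle_scale), pd - 1, W)
    # superficial muscle band (pectoralis analogue) above the rib caps
    mb <- max(3L, config$rib_cap_depth_px %/% 2L)
    above[mb:(mb + 1L), ] <- pmax(above[mb:(mb + 1L), ], 0.55)

    n_below <- H - (pd + th - 1L)
    below_field <- matrix(rrayleigh(n_below * (W + 2L * buf), config$speckle_scale),
                          n_below, W + 2L * buf)
    if (config$n_blines > 0L) {
      gap_lo <- ribs$end[1] + 1L
      gap_hi <- ribs$start[2] - 1L
      ctrs <- round(seq(gap_lo, gap_hi, length.out = config$n_blines + 2L))
      ctrs <- ctrs[-c(1L, length(ctrs))]
      for (c0 in ctrs) {
        cols <- (c0 - config$bline_width_px %/% 2L):(c0 + (config$bline_width_px - 1L) %/% 2L)
        cols <- cols[cols >= 1 & cols <= W] + buf
        below_field[, cols] <- pmax(below_field[, cols], 0.9 * config$pleural_brightness)
      }
    }

    lapply(seq_len(T), function(t) {
      m <- matrix(0, H, W)
      m[seq_len(pd - 1L), ] <- above
      m[pd:(pd + th - 1L), ] <- config$pleural_brightness
      s <- shifts[t]
      m[(pd + th):H, ] <- below_field[, (buf + 1L + s):(buf + W + s)]
      # posterior acoustic shadows, then the bright rib caps on top
      cap <- config$rib_cap_depth_px
      for (i in seq_len(nrow(ribs))) {
        cols <- ribs$start[i]:ribs$end[i]
        m[(cap + 3L):H, cols] <- m[(cap + 3L):H, cols] * config$shadow_attenuation
        m[cap:(cap + 2L), cols] <- 0.9
      }
      pmin(pmax(m, 0), 1)
    })
  })

  meta <- exam_metadata(exam_id, mode = "B", transducer = transducer,
                        quality_score = quality_score,
                        reference_label = config$truth_label)
  structure(
    list(image = bmode_clip(frames, exam_id = exam_id), metadata = meta,
         config = config, shifts = shifts),
    class = "labeled_exam"
  )
}

#' Generate a synthetic M-mode image
#'
#' Above the pleural line: horizontally banded, time-static layers.  At
#' `pleural_depth_px`: a bright horizontal band.  Below: the seashore pattern
#' draws independent speckle per (row, time) pixel — the granular "sand" of
#' normal sliding lung — while the stratosphere pattern draws one value per
#' row held constant across time, the barcode appearance of pneumothorax.
#'
#' @inheritParams make_bmode_phantom
#' @return A `labeled_exam` whose `$image` is an [mmode_image()].
#' @export
make_mmode_phantom <- function(config, transducer = "linear",
                               quality_score = NA_integer_, exam_id = "phantom") {
  validate_phantom_config(config)
  if (config$mmode_pattern == "none") {
    ptx_abort("bad_config", "mmode_pattern must be seashore or stratosphere")
  }
  H <- config$height_px; W <- config$width_px
  pd <- config$pleural_depth_px; th <- config$pleural_thickness_px

  px <- with_rng(config$seed, {
    m <- matrix(0, H, W)
    # supra-pleural laminar layers: one draw per row, smoothed across depth,
    # constant along the time axis
    rowvals <- rrayleigh(pd - 1L, config$speckle_scale)
    rowvals <- stats::filter(rowvals, rep(1 / 3, 3), sides = 2)
    rowvals[is.na(rowvals)] <- config$speckle_scale
    m[seq_len(pd - 1L), ] <- matrix(rep(as.numeric(rowvals), W), pd - 1L, W)
    m[pd:(pd + th - 1L), ] <- config$pleural_brightness
    sub_rows <- (pd + th):H
    if (config$mmode_pattern == "seashore") {
      m[sub_rows, ] <- matrix(rrayleigh(length(sub_rows) * W, config$speckle_scale),
                              length(sub_rows), W)
    } else {
      m[sub_rows, ] <- matrix(rep(rrayleigh(length(sub_rows), config$speckle_scale), W),
                              length(sub_rows), W)
    }
    pmin(pmax(m, 0), 1)
  })

  meta <- exam_metadata(exam_id, mode = "M", transducer = transducer,
                        quality_score = quality_score,
                        reference_label = config$truth_label)
  structure(
    list(image = mmode_image(px, exam_id = exam_id), metadata = meta,
         config = config, shifts = NULL),
    class = "labeled_exam"
  )
}

#' @export
print.labeled_exam <- function(x, ...) {
  cat(sprintf("<labeled_exam> %s: mode %s, truth %s\n",
              x$metadata$exam_id, x$metadata$mode, x$config$truth_label))
  invisible(x)
}

#' Generate a labeled phantom cohort
#'
#' Draws `n_positive` pneumothorax-positive exams and
#' `round(negative_ratio * n_positive)` negatives (the study design sampled
#' negatives at a 2:1 ratio), each with independently jittered nuisance
#' parameters (rib positions, pleural depth, speckle scale) from one seeded
#' stream, in randomized output order.  Exam modes (B vs M) and transducers
#' are sampled at the mix observed clinically (about 80% B-mode, 60% linear);
#' quality scores are drawn from 3-5.
#'
#' @param n_positive Number of positive exams (>= 1).
#' @param negative_ratio Negatives per positive (default 2).
#' @param base_config Template [phantom_config()]; nuisance fields are
#'   jittered around it.
#' @param seed Integer seed driving the whole cohort.
#' @return List of `labeled_exam` objects.
#' @export
make_cohort <- function(n_positive, negative_ratio = 2, base_config = phantom_config(),
                        seed = 1L) {
  if (n_positive < 1) ptx_abort("bad_config", "n_positive must be >= 1")
  if (negative_ratio <= 0) ptx_abort("bad_config", "negative_ratio must be positive")
  n_negative <- as.integer(round(negative_ratio * n_positive))
  n <- n_positive + n_negative
  labels <- c(rep("positive", n_positive), rep("negative", n_negative))

  with_rng(seed, {
    ord <- sample.int(n)
    labels <- labels[ord]
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    modes <- sample(c("B", "M"), n, replace = TRUE, prob = c(0.8, 0.2))
    transducers <- sample(c("linear", "phased"), n, replace = TRUE, prob = c(0.6, 0.4))
    qualities <- sample(3:5, n, replace = TRUE, prob = c(45, 68, 20))

    purrr::map(seq_len(n), function(i) {
      lab <- labels[i]
      centers <- sort(base_config$rib_centers_px + round(stats::runif(2, -6, 6)))
      cfg <- phantom_config(
        height_px = base_config$height_px, width_px = base_config$width_px,
        n_frames = base_config$n_frames,
        rib_centers_px = centers, rib_width_px = base_config$rib_width_px,
        rib_cap_depth_px = base_config$rib_cap_depth_px,
        shadow_attenuation = base_config$shadow_attenuation,
        pleural_depth_px = base_config$pleural_depth_px + sample(-8:8, 1),
        pleural_brightness = base_config$pleural_brightness,
        pleural_thickness_px = base_config$pleural_thickness_px,
        sliding_amplitude_px = if (lab == "negative") sample(3:6, 1) else 0,
        sliding_period_frames = base_config$sliding_period_frames,
        n_blines = if (lab == "negative") sample(0:2, 1) else 0L,
        bline_width_px = base_config$bline_width_px,
        speckle_scale = base_config$speckle_scale * stats::runif(1, 0.8, 1.2),
        mmode_pattern = if (lab == "positive") "stratosphere" else "seashore",
        truth_label = lab,
        seed = seeds[i]
      )
      id <- sprintf("exam_%03d", i)
      if (modes[i] == "B") {
        make_bmode_phantom(cfg, transducer = transducers[i],
                           quality_score = qualities[i], exam_id = id)
      } else {
        make_mmode_phantom(cfg, transducer = transducers[i],
                           quality_score = qualities[i], exam_id = id)
      }
    })
  })
}

#' Write a cohort to disk
#'
#' One directory per exam (image + JSON metadata sidecar + JSON config) plus
#' a `manifest.csv` (exam_id, truth_label, mode, transducer, quality_score,
#' image path, config path) at the top level.
#'
#' @param exams List of `labeled_exam` objects (from [make_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(exams, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) ptx_abort("io", sprintf("cannot create output directory %s", dir))
  rows <- purrr::map(exams, function(ex) {
    id <- ex$metadata$exam_id
    exdir <- file.path(dir, id)
    dir.create(exdir, showWarnings = FALSE)
    if (ex$metadata$mode == "B") {
      img <- file.path(id, "bmode.tiff")
      write_bmode_clip(ex$image, file.path(dir, img))
    } else {
      img <- file.path(id, "mmode.png")
      write_mmode_image(ex$image, file.path(dir, img))
    }
    write_metadata(ex$metadata, file.path(exdir, "meta.json"))
    cfgp <- file.path(id, "config.json")
    write_phantom_config(ex$config, file.path(dir, cfgp))
    tibble(
      exam_id = id, truth_label = ex$config$truth_label,
      mode = ex$metadata$mode, transducer = ex$metadata$transducer,
      quality_score = ex$metadata$quality_score, image = img, config = cfgp
    )
  })
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(dplyr::bind_rows(rows), manifest)
  invisible(manifest)
}

#' Serialize / read a phantom config as JSON
#' @param config A [phantom_config()].
#' @param path JSON file path.
#' @return `write_phantom_config()`: `path` invisibly;
#'   `read_phantom_config()`: a [phantom_config()].
#' @export
write_phantom_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(phantom_config, j)
}
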