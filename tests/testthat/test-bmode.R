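# B-mode pipeline stages and the three-way decision rule.

# minimal hand-built stage inputs
space_of <- function(start, end) {
  structure(list(found = TRUE, start = as.integer(start), end = as.integer(end)),
            class = "intercostal_space")
}
line_of <- function(depth_row, brightness = 1, start = 1L, end = 1L) {
  structure(list(found = TRUE, depth_row = as.integer(depth_row),
                 span_start = start, span_end = end,
                 brightness = brightness, contiguity = 1),
            class = "pleural_line_fit")
}
uniform_clip <- function(value, T = 5, H = 64, W = 96) {
  bmode_clip(array(value, dim = c(T, H, W)))
}

test_that("rib shadows: contrast-free images yield an empty set", {
  expect_equal(nrow(detect_rib_shadows(uniform_clip(0.5))), 0L)
})

test_that("rib shadows on phantoms overlap the true bands and find the caps", {
  cfg <- phantom_for("negative", seed = 14)
  ex <- make_bmode_phantom(cfg)
  sh <- detect_rib_shadows(ex$image)
  ribs <- ptxcad:::rib_intervals(cfg)
  expect_equal(nrow(sh), 2L)
  for (i in 1:2) {
    ov <- length(intersect(sh$start[i]:sh$end[i], ribs$start[i]:ribs$end[i]))
    expect_gte(ov / (ribs$end[i] - ribs$start[i] + 1), 0.8)
    expect_lt(abs(sh$cap_depth_row[i] - cfg$rib_cap_depth_px), 4)
    expect_gt(sh$shadow_contrast[i], 0.5)
  }
})

test_that("a single rib shadow leaves the intercostal space not found", {
  # one dark column band on speckle: build a frame directly
  set.seed(4)
  frame <- matrix(ptxcad:::rrayleigh(64 * 96, 0.15), 64, 96)
  frame[33:64, 40:55] <- frame[33:64, 40:55] * 0.1
  sh <- detect_rib_shadows(pmin(frame, 1))
  expect_equal(nrow(sh), 1L)
  expect_false(locate_intercostal_space(sh, 96)$found)
})

test_that("intercostal space is the widest inter-shadow gap minus the margin", {
  sh <- tibble::tibble(start = c(21L, 91L), end = c(32L, 102L),
                       cap_depth_row = c(10L, 10L), shadow_contrast = c(0.9, 0.9))
  sp <- locate_intercostal_space(sh, 120, bmode_params(space_margin = 4))
  expect_true(sp$found)
  expect_equal(c(sp$start, sp$end), c(37L, 86L))

  sh3 <- tibble::tibble(start = c(1L, 41L, 101L), end = c(10L, 50L, 110L),
                        cap_depth_row = rep(10L, 3), shadow_contrast = rep(0.9, 3))
  sp3 <- locate_intercostal_space(sh3, 140, bmode_params(space_margin = 0))
  expect_equal(c(sp3$start, sp3$end), c(51L, 100L))  # the 50-px gap wins

  narrow <- locate_intercostal_space(sh, 120, bmode_params(min_space_width = 60))
  expect_false(narrow$found)
})

test_that("pleural line is found at the configured depth, below the rib caps", {
  cfg <- phantom_for("negative", seed = 9)
  ex <- make_bmode_phantom(cfg)
  sh <- detect_rib_shadows(ex$image)
  sp <- locate_intercostal_space(sh, cfg$width_px)
  line <- detect_pleural_line(ex$image, sp, sh)
  expect_true(line$found)
  expect_lte(abs(line$depth_row - cfg$pleural_depth_px), 2)
  # the bright superficial muscle band (above the caps) is never selected
  expect_gt(line$depth_row, max(sh$cap_depth_row))
})

test_that("pleural line search fails cleanly on an empty image", {
  clip <- uniform_clip(0)
  sh <- detect_rib_shadows(clip)
  line <- detect_pleural_line(clip, space_of(10, 80), sh)
  expect_false(line$found)
})

test_that("sliding is detected with amplitude near the configured value", {
  cfg <- phantom_for("negative", seed = 31,
                     sliding_amplitude_px = 4, sliding_period_frames = 10, n_frames = 20)
  ex <- make_bmode_phantom(cfg)
  sh <- detect_rib_shadows(ex$image)
  sp <- locate_intercostal_space(sh, cfg$width_px)
  line <- detect_pleural_line(ex$image, sp, sh)
  sl <- measure_sliding(ex$image, line, sp)
  expect_true(sl$sliding_detected)
  expect_gte(sl$amplitude_px, 3)
  expect_lte(sl$amplitude_px, 5)
  expect_length(sl$displacements, cfg$n_frames - 1L)
  expect_gte(sl$sign_changes, 1L)
})

test_that("identical frames measure zero displacement and no sliding", {
  set.seed(8)
  frame <- matrix(ptxcad:::rrayleigh(64 * 96, 0.15), 64, 96)
  clip <- bmode_clip(lapply(1:6, function(t) pmin(frame, 1)))
  sl <- measure_sliding(clip, line_of(20), space_of(10, 86))
  expect_equal(sl$displacements, rep(0L, 5))
  expect_false(sl$sliding_detected)
})

test_that("a monotone drift has no sign change and is not sliding", {
  set.seed(15)
  field <- matrix(ptxcad:::rrayleigh(64 * 110, 0.15), 64, 110)
  frames <- lapply(0:7, function(s) pmin(field[, (1 + s):(96 + s)], 1))
  clip <- bmode_clip(frames)
  sl <- measure_sliding(clip, line_of(20), space_of(10, 86))
  expect_equal(sl$sign_changes, 0L)
  expect_false(sl$sliding_detected)
  expect_gt(sl$amplitude_px, 1.5)  # amplitude alone would have passed
})

test_that("too few frames raise the dedicated error from measure_sliding", {
  clip <- uniform_clip(0.5, T = 2)
  expect_error(measure_sliding(clip, line_of(20), space_of(10, 80)),
               class = "ptxcad_error_too_few_frames")
})

test_that("reverberation detects B-line bands where the generator put them", {
  cfg <- phantom_for("negative", seed = 27, sliding_amplitude_px = 0, n_blines = 2)
  ex <- make_bmode_phantom(cfg)
  sh <- detect_rib_shadows(ex$image)
  sp <- locate_intercostal_space(sh, cfg$width_px)
  line <- detect_pleural_line(ex$image, sp, sh)
  rv <- detect_reverberation(ex$image, line, sp)
  expect_true(rv$reverberation_detected)
  expect_equal(nrow(rv$artifact_bands), 2L)
  # recompute the generator's B-line centers and require overlap
  ribs <- ptxcad:::rib_intervals(cfg)
  ctrs <- round(seq(ribs$end[1] + 1L, ribs$start[2] - 1L, length.out = 4L))[2:3]
  half <- cfg$bline_width_px %/% 2L
  for (i in 1:2) {
    truth <- (ctrs[i] - half):(ctrs[i] + half)
    expect_gt(length(intersect(rv$artifact_bands$start[i]:rv$artifact_bands$end[i], truth)), 0)
  }
})

test_that("clean positive phantoms show no reverberation", {
  cfg <- phantom_for("positive", seed = 28)
  ex <- make_bmode_phantom(cfg)
  sh <- detect_rib_shadows(ex$image)
  sp <- locate_intercostal_space(sh, cfg$width_px)
  line <- detect_pleural_line(ex$image, sp, sh)
  rv <- detect_reverberation(ex$image, line, sp)
  expect_false(rv$reverberation_detected)
})

test_that("a saturated sub-pleural field scores one full-width band", {
  clip <- uniform_clip(1, T = 3)
  rv <- detect_reverberation(clip, line_of(20, brightness = 1), space_of(10, 80))
  expect_equal(rv$scores, rep(1, 71))
  expect_equal(nrow(rv$artifact_bands), 1L)
  expect_equal(c(rv$artifact_bands$start, rv$artifact_bands$end), c(10L, 80L))
})

test_that("the decision table maps all evidence combinations per the rule", {
  for (found in c(TRUE, FALSE)) {
    for (slide in c(TRUE, FALSE)) {
      for (reverb in c(TRUE, FALSE)) {
        expected <- if (!found) "indeterminate"
                    else if (slide || reverb) "negative"
                    else "positive"
        expect_identical(bmode_decision(found, slide, reverb), expected)
      }
    }
  }
})

test_that("classify_bmode returns indeterminate with a reason, never a crash", {
  # no ribs at all -> no space
  call <- classify_bmode(uniform_clip(0.5))
  expect_identical(call$label, "indeterminate")
  expect_identical(call$reason, "no_intercostal_space")

  # valid anatomy but a 2-frame clip -> too few frames for 'to and fro'
  cfg <- phantom_for("positive", seed = 40, n_frames = 2)
  call2 <- classify_bmode(make_bmode_phantom(cfg)$image)
  expect_identical(call2$label, "indeterminate")
  expect_identical(call2$reason, "too_few_frames")
})

test_that("classify_bmode labels match phantom truth on clean exams", {
  neg <- classify_bmode(make_bmode_phantom(phantom_for("negative", 51))$image)
  expect_identical(neg$label, "negative")
  expect_true(neg$evidence$sliding$sliding_detected)

  pos <- classify_bmode(make_bmode_phantom(phantom_for("positive", 52))$image)
  expect_identical(pos$label, "positive")

  # reverberation alone (B-lines, no sliding) is a negative indicator
  bl <- classify_bmode(make_bmode_phantom(
    phantom_for("negative", 53, sliding_amplitude_px = 0, n_blines = 2))$image)
  expect_identical(bl$label, "negative")
  expect_false(bl$evidence$sliding$sliding_detected)
  expect_true(bl$evidence$reverb$reverberation_detected)
})

test_that("estimated sliding amplitude is monotone in the configured amplitude", {
  amps <- c(0, 1, 2, 4, 8)
  est <- vapply(amps, function(a) {
    cfg <- phantom_for(if (a == 0) "positive" else "negative", seed = 60,
                       sliding_amplitude_px = a)
    ex <- make_bmode_phantom(cfg)
    sh <- detect_rib_shadows(ex$image)
    sp <- locate_intercostal_space(sh, cfg$width_px)
    line <- detect_pleural_line(ex$image, sp, sh)
    measure_sliding(ex$image, line, sp)$amplitude_px
  }, 0)
  expect_true(all(diff(est) >= 0))
})
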