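# Adjudication, confusion matrices, exact CIs, kappa, stratified reports.

test_that("adjudication includes unanimous diagnostic-quality exams only", {
  ratings <- tibble::tibble(
    exam_id = rep(c("e1", "e2", "e3"), each = 3),
    rater_id = rep(c("r1", "r2", "r3"), 3),
    label = c("negative", "negative", "negative",
              "positive", "positive", "positive",
              "positive", "positive", "negative"),
    quality_score = c(4, 4, 5, 2, 2, 2, 4, 4, 4)
  )
  adj <- adjudicate(ratings)
  e1 <- adj[adj$exam_id == "e1", ]
  expect_true(e1$included)
  expect_identical(e1$consensus_label, "negative")

  e2 <- adj[adj$exam_id == "e2", ]
  expect_false(e2$included)
  expect_identical(e2$reason, "quality_below_3")

  e3 <- adj[adj$exam_id == "e3", ]
  expect_false(e3$included)
  expect_identical(e3$reason, "non_unanimous")
  expect_true(is.na(e3$consensus_label))

  # excluded exams carry exactly one reason
  expect_equal(sum(!is.na(adj$reason)), sum(!adj$included))
})

test_that("the quality gate can be switched off and single raters are rejected", {
  ratings <- tibble::tibble(
    exam_id = rep("e1", 3), rater_id = c("r1", "r2", "r3"),
    label = rep("positive", 3), quality_score = c(2, 2, 2)
  )
  adj <- adjudicate(ratings, quality_rule = FALSE)
  expect_true(adj$included)

  solo <- tibble::tibble(exam_id = "e9", rater_id = "r1",
                         label = "positive", quality_score = 4)
  expect_error(adjudicate(solo), class = "ptxcad_error_single_rater")
})

test_that("confusion counts agreement and handles indeterminates by policy", {
  pr <- preds_from_counts(4, 0, 6, 0)
  cm <- confusion(pr$pred, pr$ref)
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(4L, 0L, 6L, 0L))

  # one prediction-indeterminate exam: exclude drops it ...
  pr$pred$label[1] <- "indeterminate"
  cm2 <- confusion(pr$pred, pr$ref, "exclude")
  expect_equal(cm2$tp + cm2$fp + cm2$tn + cm2$fn, 9L)
  expect_equal(cm2$tp, 3L)
  # ... as_error charges it to the predictor (ref positive -> false negative)
  cm3 <- confusion(pr$pred, pr$ref, "as_error")
  expect_equal(c(cm3$tp, cm3$fn), c(3L, 1L))

  # reference-indeterminate exams are always dropped
  pr2 <- preds_from_counts(2, 1, 3, 1)
  pr2$ref$label[3] <- "indeterminate"
  cm4 <- confusion(pr2$pred, pr2$ref)
  expect_equal(cm4$tp + cm4$fp + cm4$tn + cm4$fn, 6L)

  bad_ref <- pr$ref; bad_ref$exam_id[1] <- "zzz"
  expect_error(confusion(pr$pred, bad_ref), class = "ptxcad_error_unmatched_exams")
})

test_that("exact CI hits the boundaries and matches the bisection oracle", {
  expect_equal(exact_binomial_ci(0, 10)[["lower"]], 0)
  expect_equal(exact_binomial_ci(10, 10)[["upper"]], 1)
  expect_error(exact_binomial_ci(5, 0), class = "ptxcad_error_bad_counts")
  expect_error(exact_binomial_ci(11, 10), class = "ptxcad_error_bad_counts")

  oracle <- cp_bisect(33, 42)
  got <- exact_binomial_ci(33, 42)
  expect_lt(max(abs(got - oracle)), 1e-6)
})

test_that("characteristics compute the four ratios with explicit undefineds", {
  cm <- confusion_matrix(tp = 0, fp = 0, tn = 5, fn = 0)
  tc <- characteristics(cm)
  expect_true(is.na(tc$estimate[tc$metric == "sensitivity"]))
  expect_true(is.na(tc$estimate[tc$metric == "ppv"]))
  expect_equal(tc$estimate[tc$metric == "specificity"], 1.0)
  expect_equal(tc$estimate[tc$metric == "npv"], 1.0)

  cm2 <- confusion_matrix(8, 2, 14, 4)
  tc2 <- characteristics(cm2)
  expect_equal(tc2$estimate, c(8 / 12, 14 / 16, 8 / 10, 14 / 18))
  expect_true(all(tc2$lower <= tc2$estimate & tc2$estimate <= tc2$upper))
})

test_that("kappa reproduces hand computation, symmetry, and the bands", {
  r <- ratings_from_2x2(45, 5, 5, 45)
  k <- cohen_kappa(r$a, r$b)
  expect_equal(k$kappa, 0.8)
  expect_equal(k$kappa, kappa_from_table(matrix(c(45, 5, 5, 45), 2)))
  expect_identical(k$band, "excellent")

  # symmetry and kappa <= 1 over random two-rater tables
  set.seed(99)
  for (i in 1:20) {
    a <- sample(c("positive", "negative", "indeterminate"), 40, replace = TRUE)
    b <- sample(c("positive", "negative", "indeterminate"), 40, replace = TRUE)
    kab <- cohen_kappa(a, b)$kappa
    kba <- cohen_kappa(b, a)$kappa
    expect_equal(kab, kba)
    expect_lte(kab, 1)
  }

  ident <- cohen_kappa(r$a, r$a)
  expect_equal(ident$kappa, 1.0)

  # band edges per the conventional interpretation
  expect_identical(cohen_kappa(ratings_from_2x2(40, 5, 5, 50)$a,
                               ratings_from_2x2(40, 5, 5, 50)$b)$band, "excellent")
  mid <- ratings_from_2x2(35, 15, 15, 35)
  expect_identical(cohen_kappa(mid$a, mid$b)$band, "fair to good")

  expect_error(cohen_kappa(rep("positive", 10), rep("positive", 10)),
               class = "ptxcad_error_undefined_kappa")
})

test_that("kappa matches the independent e1071 implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  a <- sample(c("positive", "negative"), 60, replace = TRUE, prob = c(0.4, 0.6))
  b <- ifelse(runif(60) < 0.8, a, sample(c("positive", "negative"), 60, replace = TRUE))
  ours <- cohen_kappa(a, b)$kappa
  theirs <- e1071::classAgreement(table(a, b))$kappa
  expect_equal(ours, theirs)
})

test_that("the exact CI covers the true proportion at its nominal rate", {
  set.seed(1234)
  n <- 42; p <- 0.8
  k <- rbinom(1000, n, p)
  covered <- vapply(k, function(ki) {
    ci <- exact_binomial_ci(ki, n)
    ci[["lower"]] <= p && p <= ci[["upper"]]
  }, TRUE)
  expect_gte(mean(covered), 0.93)
})

test_that("stratified reports are additive over a partition and keep empty denominators", {
  set.seed(7)
  n <- 60
  ids <- sprintf("e%03d", 1:n)
  ref <- tibble::tibble(exam_id = ids,
                        label = sample(c("positive", "negative"), n, TRUE))
  records <- tibble::tibble(
    exam_id = ids,
    label = ifelse(runif(n) < 0.85, ref$label,
                   ifelse(ref$label == "positive", "negative", "positive")),
    mode = sample(c("B", "M"), n, TRUE),
    quality_score = sample(3:5, n, TRUE)
  )
  rep <- stratified_report(records, ref, strata = c("mode", "quality_score"))
  cms <- dplyr::distinct(rep[c("stratum", "level", "tp", "fp", "tn", "fn")])
  overall <- cms[cms$stratum == "overall", ]
  for (s in c("mode", "quality_score")) {
    part <- cms[cms$stratum == s, ]
    expect_equal(sum(part$tp), overall$tp)
    expect_equal(sum(part$fp), overall$fp)
    expect_equal(sum(part$tn), overall$tn)
    expect_equal(sum(part$fn), overall$fn)
  }
  expect_equal(sum(cms$stratum == "quality_score"), 3L)

  # a stratum whose level has no positives reports sensitivity as undefined
  rec2 <- tibble::tibble(exam_id = c("a", "b"), label = c("negative", "negative"),
                         mode = c("B", "B"))
  ref2 <- tibble::tibble(exam_id = c("a", "b"), label = c("negative", "negative"))
  r2 <- stratified_report(rec2, ref2, strata = "mode")
  expect_true(is.na(r2$estimate[r2$stratum == "mode" & r2$metric == "sensitivity"]))

  # single-stratum input equals the overall block
  one <- stratified_report(rec2, ref2, strata = "mode")
  ov <- one[one$stratum == "overall", c("metric", "estimate")]
  md <- one[one$stratum == "mode", c("metric", "estimate")]
  expect_equal(ov, md, ignore_attr = TRUE)

  expect_error(stratified_report(rec2, ref2, strata = "probe_frequency"),
               class = "ptxcad_error_unknown_stratum")
})

test_that("tidiers return the documented shapes", {
  cm <- confusion_matrix(33, 12, 79, 9)
  td <- tidy(cm)
  expect_equal(td$count, c(33L, 12L, 79L, 9L))
  gl <- glance(cm)
  expect_equal(gl$total, 133L)
  expect_equal(gl$accuracy, (33 + 79) / 133)

  k <- cohen_kappa(ratings_from_2x2(45, 5, 5, 45)$a, ratings_from_2x2(45, 5, 5, 45)$b)
  expect_equal(tidy(k)$kappa, 0.8)

  call <- classify_mmode(make_mmode_phantom(phantom_for("negative", 2))$image)
  expect_equal(nrow(tidy(call)), 1L)
  expect_identical(tidy(call)$label, "negative")
})
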