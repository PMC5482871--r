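test_that("patient score is the per-patient correct fraction", {
  ps <- prediction_set(
    patient_id = rep("P1", 10),
    true_subclass = rep("A", 10),
    predicted_subclass = c(rep("A", 8), "F", "DC"))
  expect_equal(patient_score(ps, "P1"), 0.8)
  ps2 <- prediction_set(rep("P2", 4), rep("DC", 4), rep("DC", 4))
  expect_equal(patient_score(ps2, "P2"), 1.0)
  expect_error(patient_score(ps, "nobody"), "unknown patient")
})

test_that("recognition rates follow their defining formulas", {
  # two patients, scores 1.0 and 0.5 -> patient rate 0.75
  ps <- prediction_set(
    patient_id = c(rep("P1", 4), rep("P2", 8)),
    true_subclass = rep("A", 12),
    predicted_subclass = c(rep("A", 4), rep("A", 4), rep("F", 4)))
  expect_equal(patient_recognition_rate(ps), 0.75)
  # image level ignores grouping: 8 of 12 correct
  expect_equal(image_recognition_rate(ps), 8 / 12)
  ps93 <- prediction_set(sprintf("P%d", 1:100), rep("MC", 100),
                         c(rep("MC", 93), rep("PC", 7)))
  expect_equal(image_recognition_rate(ps93), 0.93)
  ps0 <- prediction_set("P1", "A", "F")
  expect_equal(image_recognition_rate(ps0), 0)
})

test_that("metric identities hold on random fixtures", {
  set.seed(7)
  for (i in 1:10) {
    ps <- random_prediction_set(n_patients = 8, n_images = 25)
    # per-patient scores match a naive group-by oracle
    for (p in unique(ps$patient_id)) {
      rows <- ps[ps$patient_id == p, ]
      expect_equal(patient_score(ps, p),
                   sum(rows$true_subclass == rows$predicted_subclass) /
                     nrow(rows))
    }
    # Eq-2-style rate is the unweighted mean of scores
    scores <- vapply(unique(ps$patient_id),
                     function(p) patient_score(ps, p), 1)
    expect_equal(patient_recognition_rate(ps), mean(scores),
                 tolerance = 1e-12)
    # image rate equals trace(confusion)/total and the image-weighted mean
    cm <- confusion_matrix(ps)
    expect_equal(image_recognition_rate(ps), sum(diag(cm)) / sum(cm),
                 tolerance = 1e-12)
    n_img <- table(ps$patient_id)[unique(ps$patient_id)]
    expect_equal(image_recognition_rate(ps),
                 sum(scores * as.numeric(n_img)) / sum(n_img),
                 tolerance = 1e-12)
    # permutation invariance
    shuf <- ps[sample(nrow(ps)), ]
    expect_equal(image_recognition_rate(shuf), image_recognition_rate(ps))
    expect_equal(patient_recognition_rate(shuf), patient_recognition_rate(ps))
  }
})

test_that("metrics report aggregates per magnification with valid confusion", {
  set.seed(8)
  ps <- random_prediction_set(n_patients = 6, n_images = 10)
  rep_ <- metrics_report(ps, default_breakhis_taxonomy())
  expect_equal(rowSums(rep_$confusion),
               vapply(rownames(rep_$confusion),
                      function(l) sum(ps$true_subclass == l), 1),
               ignore_attr = TRUE)
  expect_true(rep_$patient_recognition_rate >= 0 &&
                rep_$patient_recognition_rate <= 1)
  for (mg in names(rep_$per_magnification)) {
    sub <- ps[ps$magnification == mg, ]
    expect_equal(rep_$per_magnification[[mg]]$image_recognition_rate,
                 image_recognition_rate(sub))
  }
})

test_that("cross-validation summary uses the sample sd convention", {
  mk <- function(p, i) structure(list(patient_recognition_rate = p,
                                      image_recognition_rate = i),
                                 class = "metrics_report")
  same <- lapply(1:5, function(i) mk(0.9, 0.9))
  s <- cross_validation_summary(same)
  expect_equal(s$mean, c(0.9, 0.9))
  expect_equal(s$sd, c(0, 0))
  two <- list(mk(0.8, 0.8), mk(1.0, 1.0))
  s2 <- cross_validation_summary(two)
  expect_equal(s2$sd, rep(sqrt(0.02), 2), tolerance = 1e-12)
  expect_equal(s2$sd[1], 0.1414214, tolerance = 1e-6)
  set.seed(9)
  vals_p <- stats::runif(5); vals_i <- stats::runif(5)
  rnd <- lapply(1:5, function(k) mk(vals_p[k], vals_i[k]))
  s3 <- cross_validation_summary(rnd)
  expect_equal(s3$mean, c(mean(vals_p), mean(vals_i)), tolerance = 1e-12)
  expect_equal(s3$sd, c(stats::sd(vals_p), stats::sd(vals_i)),
               tolerance = 1e-12)
  expect_match(s3$formatted[1], "±")
  expect_error(cross_validation_summary(same[1]), "at least 2")
})

test_that("predictions round-trip through CSV and metrics serialise to JSON", {
  set.seed(10)
  ps <- random_prediction_set(n_patients = 4, n_images = 5)
  f <- tempfile(fileext = ".csv")
  write_predictions(ps, f)
  back <- read_predictions(f, default_breakhis_taxonomy())
  expect_equal(as.data.frame(back), as.data.frame(ps))
  j <- tempfile(fileext = ".json")
  write_metrics_json(metrics_report(ps), j)
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$image_recognition_rate, image_recognition_rate(ps),
               tolerance = 1e-9)
})
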