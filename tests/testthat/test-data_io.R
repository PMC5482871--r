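tx <- default_breakhis_taxonomy()

test_that("manifest validation names offending rows", {
  recs <- toy_records(c("A", "DC"), n_patients = 2, n_images = 2)
  expect_s3_class(manifest(recs, tx), "manifest")
  bad <- recs; bad$magnification[3] <- "4000X"
  expect_error(manifest(bad, tx), "row 3.*4000X")
  dup <- recs; dup$path[2] <- dup$path[1]
  expect_error(manifest(dup, tx), "duplicated path")
  wrong <- recs; wrong$subclass[1] <- "ZZ"
  expect_error(manifest(wrong, tx), "row 1.*ZZ")
  mixed <- recs; mixed$subclass[mixed$patient_id == "P_A_01"][1] <- "F"
  expect_error(manifest(mixed, tx), "more than one subclass")
})

test_that("manifest CSV round-trips", {
  recs <- toy_records(c("A", "F", "DC", "LC"), n_patients = 2, n_images = 3)
  m <- manifest(recs, tx)
  f <- tempfile(fileext = ".csv")
  write_manifest(m, f)
  back <- read_manifest(f, tx)
  expect_equal(back$records[, c("path", "patient_id", "subclass",
                                "magnification")],
               m$records[, c("path", "patient_id", "subclass",
                             "magnification")])
})

test_that("directory scanner understands the folder convention", {
  root <- file.path(tempdir(), "scan_fixture")
  unlink(root, recursive = TRUE)
  layout <- list(
    c("benign", "adenosis", "SOB_B_A_1", "40X", 3L),
    c("benign", "fibroadenoma", "SOB_B_F_1", "100X", 2L),
    c("malignant", "ductal_carcinoma", "SOB_M_DC_1", "40X", 4L))
  for (l in layout) {
    d <- file.path(root, l[1], l[2], l[3], l[4])
    dir.create(d, recursive = TRUE)
    for (i in seq_len(as.integer(l[5]))) {
      file.create(file.path(d, sprintf("img%02d.ppm", i)))
    }
  }
  m <- scan_breakhis_dir(root, tx)
  expect_equal(nrow(m$records), 9L)
  expect_equal(sum(m$records$subclass == "A"), 3L)
  expect_equal(sum(m$records$subclass == "DC"), 4L)
  expect_equal(unique(m$records$magnification[m$records$subclass == "F"]),
               "100X")
})

test_that("patient-wise split reproduces the 41/20/21 global allocation", {
  # 82 patients spread unevenly over the 8 subclasses
  per_sub <- c(A = 12, F = 10, PT = 10, TA = 9, DC = 12, LC = 10,
               MC = 10, PC = 9)
  recs <- do.call(rbind, lapply(names(per_sub), function(s) {
    toy_records(s, n_patients = per_sub[[s]], n_images = 2)
  }))
  m <- manifest(recs, tx)
  sp <- patient_wise_split(m, c(0.50, 0.25, 0.25), rng_seed = 1L)
  pat <- unique(sp$records[, c("patient_id", "split")])
  expect_equal(sum(pat$split == "train"), 41L)
  expect_equal(sum(pat$split == "val"), 20L)
  expect_equal(sum(pat$split == "test"), 21L)
})

test_that("splits never share patients and stratify by subclass", {
  recs <- toy_records(subclasses(tx), n_patients = 5, n_images = 3)
  m <- manifest(recs, tx)
  for (s in 1:5) {
    sp <- patient_wise_split(m, rng_seed = s)
    pieces <- split(sp$records$patient_id, sp$records$split)
    expect_equal(length(intersect(pieces$train, pieces$test)), 0L)
    expect_equal(length(intersect(pieces$train, pieces$val)), 0L)
    expect_equal(length(intersect(pieces$val, pieces$test)), 0L)
    # stratification: per-subclass train counts within 1 of 0.5 * 5
    pat <- unique(sp$records[, c("patient_id", "subclass", "split")])
    per <- table(pat$subclass, pat$split)
    expect_true(all(abs(per[, "train"] - 2.5) <= 1))
  }
  # a single-patient subclass is forced into train with a warning
  solo <- rbind(toy_records("A", 1, 2), toy_records("DC", 4, 2))
  expect_warning(sp <- patient_wise_split(manifest(solo, tx), rng_seed = 1L),
                 "single patient")
  pat <- unique(sp$records[, c("patient_id", "subclass", "split")])
  expect_equal(pat$split[pat$subclass == "A"], "train")
})

test_that("cross-validation folds partition patients", {
  recs <- rbind(toy_records("A", 5, 2), toy_records("DC", 5, 2))
  m <- manifest(recs, tx)
  folds <- make_cv_folds(m, n_folds = 5L, rng_seed = 2L)
  expect_length(folds, 5L)
  test_sets <- lapply(folds, function(f) {
    unique(f$records$patient_id[f$records$split == "test"])
  })
  expect_true(all(lengths(test_sets) == 2L))
  expect_setequal(unlist(test_sets), unique(m$records$patient_id))
  expect_equal(anyDuplicated(unlist(test_sets)), 0L)
  # every fold keeps train/val/test all non-empty
  for (f in folds) expect_setequal(unique(f$records$split),
                                   c("train", "val", "test"))
  expect_error(make_cv_folds(m, n_folds = 11L), "exceeds patient count")
})

test_that("stratified folds track subclass counts within one patient", {
  recs <- rbind(toy_records("A", 7, 2), toy_records("F", 4, 2),
                toy_records("DC", 9, 2), toy_records("MC", 5, 2))
  m <- manifest(recs, tx)
  folds <- make_cv_folds(m, n_folds = 5L, rng_seed = 3L)
  for (f in folds) {
    pat <- unique(f$records[, c("patient_id", "subclass", "split")])
    per <- table(factor(pat$subclass, c("A", "F", "DC", "MC")),
                 pat$split)["DC", "test"]
    expect_true(abs(per - 9 / 5) <= 1.2)   # ideal 1.8 -> 1 or 2 per fold
  }
})

test_that("leakage audit fails loudly on augmented hold-out images", {
  recs <- toy_records(c("A", "DC"), n_patients = 3, n_images = 2)
  m <- patient_wise_split(manifest(recs, tx), rng_seed = 4L)
  clean <- m$records
  aug_src <- clean[clean$split == "train", ][1, ]
  aug_row <- aug_src
  aug_row$path <- "aug/copy1.ppm"; aug_row$augmented_from <- aug_src$path
  clean$augmented_from <- NA_character_
  good <- manifest(rbind(clean, aug_row), tx)
  expect_true(audit_no_leakage(good, m))
  test_src <- m$records[m$records$split == "test", ][1, ]
  leak_row <- test_src
  leak_row$path <- "aug/leak.ppm"; leak_row$augmented_from <- test_src$path
  leak_row$split <- "train"   # masquerades as training data
  leaky_rec <- rbind(clean, leak_row)
  leaky_rec$subclass[leaky_rec$patient_id == leak_row$patient_id] <-
    leak_row$subclass
  leaky <- manifest(leaky_rec, tx)
  expect_error(audit_no_leakage(leaky, m), "leakage audit failed")
})
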