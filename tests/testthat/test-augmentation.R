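random_image <- function(s = 24) array(stats::runif(s * s * 3), c(s, s, 3))

test_that("degenerate spec is the identity and flips are involutions", {
  img <- random_image()
  id_spec <- augmentation_spec(intensity_range = c(0, 0),
                               rotation_range_deg = c(0, 0),
                               flip_horizontal = FALSE, flip_vertical = FALSE,
                               translation_px = 0L, combine = FALSE)
  expect_equal(apply_augmentation(img, id_spec, rng_seed = 1L), img)
  flipped2 <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  flipped2 <- flipped2[, rev(seq_len(dim(flipped2)[2])), , drop = FALSE]
  expect_equal(flipped2, img)
  expect_error(apply_augmentation(array(0, c(8, 8, 1)), id_spec), "RGB")
})

test_that("augmentation is deterministic per seed and stays in range", {
  img <- random_image()
  spec <- augmentation_spec()
  a <- apply_augmentation(img, spec, rng_seed = 42L)
  b <- apply_augmentation(img, spec, rng_seed = 42L)
  expect_identical(a, b)
  c_ <- apply_augmentation(img, spec, rng_seed = 43L)
  expect_false(identical(a, c_))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(dim(a), dim(img))
  # byte-identical after a write/read cycle
  f1 <- tempfile(fileext = ".ppm"); f2 <- tempfile(fileext = ".ppm")
  write_image(a, f1); write_image(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("oversampling plan equalises the 40X class counts", {
  counts <- data.frame(
    subclass = c("A", "F", "TA", "PT", "DC", "LC", "MC", "PC"),
    magnification = "40X",
    count = c(114L, 253L, 109L, 149L, 864L, 156L, 205L, 145L))
  plan <- build_oversampling_plan(counts)
  expect_true(all(plan$target == 864L))
  a <- plan[plan$subclass == "A", ]
  expect_equal(a$extra, 750L)
  expect_equal(a$copies_high, 7L)
  expect_equal(a$n_high, 66L)             # 66 x 7 + 48 x 6 = 750
  for (i in seq_len(nrow(plan))) {
    mult <- hiercls:::plan_multiplicities(plan[i, ])
    expect_length(mult, plan$count[i])
    expect_equal(sum(mult) + plan$count[i], plan$target[i])
  }
})

test_that("oversampling plan closed forms and guards", {
  bal <- data.frame(subclass = c("A", "DC"), magnification = "40X",
                    count = c(5L, 5L))
  pb <- build_oversampling_plan(bal)
  expect_true(all(pb$extra == 0L))
  expect_true(all(hiercls:::plan_multiplicities(pb[1, ]) == 0L))
  ab <- build_oversampling_plan(
    data.frame(subclass = c("a", "b"), magnification = "40X",
               count = c(1L, 5L)))
  expect_equal(ab$extra[ab$subclass == "a"], 4L)
  expect_equal(sum(hiercls:::plan_multiplicities(ab[ab$subclass == "a", ])),
               4L)
  expect_error(build_oversampling_plan(
    data.frame(subclass = "a", magnification = "40X", count = 0L)),
    "zero-count")
  # balancing is per magnification, not global
  two <- data.frame(subclass = rep(c("A", "DC"), 2),
                    magnification = rep(c("40X", "100X"), each = 2),
                    count = c(2L, 6L, 10L, 5L))
  pt <- build_oversampling_plan(two)
  expect_equal(pt$target[pt$magnification == "40X"], c(6L, 6L))
  expect_equal(pt$target[pt$magnification == "100X"], c(10L, 10L))
})

test_that("materialised augmented sets balance counts without leakage", {
  sh <- shared_synth()
  m <- patient_wise_split(sh$manifest, rng_seed = 6L)
  train <- m$records[m$records$split == "train", ]
  counts <- stats::aggregate(list(count = train$path),
                             by = list(subclass = train$subclass,
                                       magnification = train$magnification),
                             FUN = length)
  # force imbalance: drop half of one subclass's training images
  drop <- which(m$records$split == "train" & m$records$subclass == "A")
  keep_rec <- m$records[-drop[seq_len(ceiling(length(drop) / 2))], ]
  m2 <- manifest(keep_rec, m$taxonomy)
  train2 <- m2$records[m2$records$split == "train", ]
  counts2 <- stats::aggregate(list(count = train2$path),
                              by = list(subclass = train2$subclass,
                                        magnification = train2$magnification),
                              FUN = length)
  plan <- build_oversampling_plan(counts2)
  out_dir <- file.path(tempdir(), "aug_out")
  unlink(out_dir, recursive = TRUE)
  aug <- materialize_augmented_set(m2, plan, augmentation_spec(),
                                   out_dir = out_dir, root = sh$dir,
                                   rng_seed = 8L)
  post <- table(aug$records$subclass)
  expect_true(length(unique(post)) == 1L)   # all classes equal after plan
  expect_equal(unname(post[1]), max(counts2$count))
  expect_true(audit_no_leakage(aug, m2))
  # augmented files exist and are readable
  aug_rows <- aug$records[!is.na(aug$records$augmented_from), ]
  expect_gt(nrow(aug_rows), 0L)
  img <- read_image(aug_rows$path[1])
  expect_equal(dim(img)[3], 3L)

  # plan built from counts that include test records is refused
  bad_plan <- build_oversampling_plan(counts)  # built pre-drop: mismatch
  expect_error(materialize_augmented_set(m2, bad_plan, augmentation_spec(),
                                         out_dir = out_dir, root = sh$dir),
               "refusing to augment")

  # an empty plan returns exactly the training records
  pb <- build_oversampling_plan(
    data.frame(subclass = counts2$subclass,
               magnification = counts2$magnification,
               count = counts2$count)[counts2$count == max(counts2$count), ,
                                      drop = FALSE])
  sub_m <- manifest(m2$records[m2$records$split != "train" |
                                 m2$records$subclass %in%
                                 pb$subclass, ], m$taxonomy)
  aug0 <- materialize_augmented_set(sub_m, pb, augmentation_spec(),
                                    out_dir = out_dir, root = sh$dir)
  expect_equal(sum(!is.na(aug0$records$augmented_from)), 0L)
})
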