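#' Augmentation specification
#'
#' The four training-set augmentation operators and their parameter ranges:
#' additive intensity variation on normalised `[0, 1]` channels, rotation by
#' a random angle, horizontal/vertical flips, and integer translation —
#' plus a `combine` mode that includes each operator independently with
#' probability 1/2 before composing them in the fixed order intensity ->
#' rotation -> flip -> translation. Rotation and translation fill exposed
#' pixels by mirror reflection and rotation resamples bilinearly.
#'
#' @param intensity_range additive shift range on `[0, 1]` intensities,
#'   default `c(-0.1, 0.1)`.
#' @param rotation_range_deg rotation angle range in degrees, default
#'   `c(-90, 90)`.
#' @param flip_horizontal,flip_vertical enable the two flips (each applied
#'   with probability 1/2 when enabled).
#' @param translation_px maximum absolute translation in pixels per axis,
#'   default 20.
#' @param combine randomly include/exclude each operator (default `TRUE`);
#'   when `FALSE` every enabled operator is applied.
#' @param multiplicative_intensity interpret the intensity draw as a gain
#'   `(1 + s)` instead of an additive shift (ablation variant).
#' @return Object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(intensity_range = c(-0.1, 0.1),
                              rotation_range_deg = c(-90, 90),
                              flip_horizontal = TRUE,
                              flip_vertical = TRUE,
                              translation_px = 20L,
                              combine = TRUE,
                              multiplicative_intensity = FALSE) {
  if (length(intensity_range) != 2L || diff(intensity_range) < 0) {
    stop("augmentation_spec: intensity_range must be an ordered pair")
  }
  if (length(rotation_range_deg) != 2L || diff(rotation_range_deg) < 0) {
    stop("augmentation_spec: rotation_range_deg must be an ordered pair")
  }
  if (translation_px < 0) stop("augmentation_spec: translation_px must be >= 0")
  structure(list(intensity_range = as.numeric(intensity_range),
                 rotation_range_deg = as.numeric(rotation_range_deg),
                 flip_horizontal = isTRUE(flip_horizontal),
                 flip_vertical = isTRUE(flip_vertical),
                 translation_px = as.integer(translation_px),
                 combine = isTRUE(combine),
                 multiplicative_intensity = isTRUE(multiplicative_intensity)),
            class = "augmentation_spec")
}

rotate_image <- function(img, angle_deg) {
  if (angle_deg == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ys <- rep(seq_len(h), times = w) - cy
  xs <- rep(seq_len(w), each = h) - cx
  # inverse map: rotate output coords by -theta to find source coords
  src_y <- cos(th) * ys + sin(th) * xs + cy
  src_x <- -sin(th) * ys + cos(th) * xs + cx
  out <- img
  for (c in 1:3) {
    out[, , c] <- matrix(bilinear_channel(img[, , c], src_y, src_x), h, w)
  }
  out
}

translate_image <- function(img, dy, dx) {
  if (dy == 0 && dx == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  src_y <- reflect_index(seq_len(h) - dy, h)
  src_x <- reflect_index(seq_len(w) - dx, w)
  img[src_y, src_x, , drop = FALSE]
}

#' Apply a random augmentation to one image
#'
#' Draws operator inclusion and parameters from `rng_seed` and applies the
#' composition in the fixed order intensity -> rotation -> flip ->
#' translation. The same seed on the same image reproduces the output
#' exactly. A spec with zero-width ranges, flips off and zero translation is
#' the identity.
#'
#' @param image numeric array `c(H, W, 3)`, intensities in `[0, 1]`.
#' @param spec an [augmentation_spec].
#' @param rng_seed integer seed.
#' @return Augmented image, same shape, intensities clipped to `[0, 1]`.
#' @export
apply_augmentation <- function(image, spec, rng_seed = 1L) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("apply_augmentation: expected an H x W x 3 RGB array")
  }
  with_seed(rng_seed, {
    use <- if (spec$combine) stats::runif(4) < 0.5 else rep(TRUE, 4L)
    if (use[1]) {
      s <- stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
      image <- if (spec$multiplicative_intensity) image * (1 + s) else image + s
      image <- pmin(pmax(image, 0), 1)
    }
    if (use[2]) {
      ang <- stats::runif(1, spec$rotation_range_deg[1],
                          spec$rotation_range_deg[2])
      image <- rotate_image(image, ang)
    }
    if (use[3]) {
      if (spec$flip_horizontal && stats::runif(1) < 0.5) {
        image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
      }
      if (spec$flip_vertical && stats::runif(1) < 0.5) {
        image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
      }
    }
    if (use[4] && spec$translation_px > 0) {
      d <- sample.int(2L * spec$translation_px + 1L, 2L, replace = TRUE) -
        spec$translation_px - 1L
      image <- translate_image(image, d[1], d[2])
    }
    pmin(pmax(image, 0), 1)
  })
}

#' Class-balancing oversampling plan
#'
#' For each magnification factor independently, sets the target count to the
#' largest subclass count at that magnification and plans
#' `ceiling(target / count) - 1` extra augmented copies per source image,
#' then trims: `trim = count * copies - (target - count)` sources receive one
#' copy fewer, so post-plan totals equal the target exactly. E.g. at 40X
#' with A = 114 and the maximum DC = 864, adenosis receives 750 extra images
#' as 7 copies for 66 sources and 6 for the remaining 48.
#'
#' @param counts data.frame with columns `subclass`, `magnification`,
#'   `count` (one row per class/magnification cell, counts >= 1).
#' @return Object of class `oversampling_plan`: the input plus `target`,
#'   `copies_high` (copies for the first `n_high` sources), `n_high`, and
#'   `extra` (total extra images = target - count).
#' @export
build_oversampling_plan <- function(counts) {
  need <- c("subclass", "magnification", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("build_oversampling_plan: missing column(s): ",
                         paste(miss, collapse = ", "))
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  counts$count <- as.integer(counts$count)
  if (any(counts$count < 1L)) {
    bad <- counts[counts$count < 1L, ]
    stop("build_oversampling_plan: zero-count class: ",
         paste(bad$subclass, bad$magnification, sep = "@", collapse = ", "))
  }
  plan <- do.call(rbind, lapply(split(counts, counts$magnification),
                                function(g) {
    g$target <- max(g$count)
    extra <- g$target - g$count
    ch <- as.integer(ceiling(g$target / g$count)) - 1L  # copies, "high" sources
    n_high <- ifelse(extra == 0L, 0L, g$count - (g$count * ch - extra))
    g$copies_high <- ch
    g$n_high <- as.integer(n_high)
    g$extra <- extra
    g
  }))
  rownames(plan) <- NULL
  class(plan) <- c("oversampling_plan", "data.frame")
  plan
}

# Per-source extra-copy multiplicities for one plan row: n_high sources get
# copies_high, the rest copies_high - 1; sums exactly to `extra`.
plan_multiplicities <- function(plan_row) {
  n <- plan_row$count
  ch <- plan_row$copies_high
  if (plan_row$extra == 0L) return(rep(0L, n))
  c(rep(ch, plan_row$n_high), rep(ch - 1L, n - plan_row$n_high))
}

#' Materialise a balanced augmented training set
#'
#' Applies an oversampling plan to the training split of a manifest: each
#' training source image receives its planned number of augmented copies,
#' written to `out_dir` as PPM, and the returned manifest is the training
#' records plus the augmented copies (which inherit patient, subclass,
#' magnification and `split = "train"` and record their source in
#' `augmented_from`). Refuses to run if the plan does not match the training
#' split's counts — the leakage guard against plans built from, or applied
#' to, validation/test records.
#'
#' @param m a [manifest] with split assignments; paths resolved against
#'   `root`.
#' @param plan an [build_oversampling_plan] result built from the training
#'   split of `m`.
#' @param spec an [augmentation_spec].
#' @param out_dir directory for the augmented images (created).
#' @param root directory the manifest paths are relative to.
#' @param rng_seed integer seed; each copy gets a distinct derived seed.
#' @return A [manifest] of train + augmented records (augmented paths are
#'   absolute into `out_dir`).
#' @export
materialize_augmented_set <- function(m, plan, spec, out_dir, root = ".",
                                      rng_seed = 1L) {
  stopifnot(inherits(m, "manifest"), inherits(plan, "oversampling_plan"),
            inherits(spec, "augmentation_spec"))
  rec <- m$records
  if (all(is.na(rec$split))) {
    stop("materialize_augmented_set: manifest has no split assignment")
  }
  train <- rec[!is.na(rec$split) & rec$split == "train", , drop = FALSE]
  # leakage guard: the plan must describe exactly the training split
  for (i in seq_len(nrow(plan))) {
    n_train <- sum(train$subclass == plan$subclass[i] &
                     train$magnification == plan$magnification[i])
    if (n_train != plan$count[i]) {
      stop("materialize_augmented_set: plan count for ", plan$subclass[i],
           "@", plan$magnification[i], " (", plan$count[i], ") does not ",
           "match the training split (", n_train, "); refusing to augment ",
           "records outside the training split")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("materialize_augmented_set: cannot create out_dir: ", out_dir)
  }
  new_rows <- list()
  for (i in seq_len(nrow(plan))) {
    sel <- which(train$subclass == plan$subclass[i] &
                   train$magnification == plan$magnification[i])
    sel <- sel[order(train$path[sel])]   # deterministic source order
    mult <- plan_multiplicities(plan[i, ])
    for (s in seq_along(sel)) {
      if (mult[s] == 0L) next
      src <- train[sel[s], ]
      img <- read_image(file.path(root, src$path))
      for (cpy in seq_len(mult[s])) {
        seed <- derive_seed(rng_seed, paste0(src$path, "#", cpy))
        out <- apply_augmentation(img, spec, rng_seed = seed)
        # flatten the relative path: basenames repeat across patients
        base <- gsub("[^A-Za-z0-9_.-]", "_",
                     sub("\\.[A-Za-z]+$", "", src$path))
        dst <- file.path(out_dir, sprintf("%s_aug%03d.ppm", base, cpy))
        write_image(out, dst)
        row <- src
        row$path <- dst
        row$augmented_from <- src$path
        new_rows[[length(new_rows) + 1L]] <- row
      }
    }
  }
  train$augmented_from <- NA_character_
  out_rec <- if (length(new_rows)) {
    rbind(train, do.call(rbind, new_rows))
  } else train
  res <- manifest(out_rec, m$taxonomy)
  audit_no_leakage(res, m)
  res
}
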