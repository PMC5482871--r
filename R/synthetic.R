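#' Synthetic dataset configuration
#'
#' Describes a fully synthetic, BreaKHis-shaped image dataset: a two-level
#' taxonomy, patients grouped under one subclass each, several images per
#' patient at one or more magnification factors, and configurable class
#' imbalance. Each image is a flat colour field whose per-channel mean
#' encodes the superclass, plus an oriented sinusoidal band-pass texture
#' whose dominant spatial frequency and orientation encode the subclass, a
#' per-patient random colour offset shared by all of that patient's images,
#' and i.i.d. Gaussian pixel noise. Magnification is simulated by rescaling
#' the texture frequency (higher magnification = coarser structure). By
#' construction, pairwise image distances follow the three-tier hierarchy —
#' same subclass < same superclass < different superclass in expectation —
#' which is exactly the ordering the distance-constraint loss is built to
#' enforce, so the generator provides ground truth for it.
#'
#' @param taxonomy a [taxonomy] (default: the 2 x 4 breast-tumour tree).
#' @param patients_per_subclass patients generated per subclass (default 4).
#' @param images_per_patient images per patient per magnification (default 6).
#' @param image_size square image side in pixels (default 64, minimum 16).
#' @param magnifications subset of 40X/100X/200X/400X (default "40X").
#' @param superclass_effect peak-to-peak channel-mean shift separating the
#'   two superclasses, on `[0, 1]` intensities (default 0.25).
#' @param subclass_effect amplitude of the subclass-coding texture; must be
#'   below `superclass_effect` — subclass differences are the subtle ones
#'   (default 0.15).
#' @param patient_effect sd of the per-patient channel offset (default 0.04).
#' @param noise_sd sd of per-pixel Gaussian noise (default 0.05).
#' @param imbalance_ratios optional named per-subclass multipliers on
#'   `images_per_patient` (e.g. `c(DC = 6)` makes ductal carcinoma 6x the
#'   size of the other classes).
#' @param rng_seed integer master seed; all randomness derives from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(taxonomy = default_breakhis_taxonomy(),
                             patients_per_subclass = 4L,
                             images_per_patient = 6L,
                             image_size = 64L,
                             magnifications = "40X",
                             superclass_effect = 0.25,
                             subclass_effect = 0.15,
                             patient_effect = 0.04,
                             noise_sd = 0.05,
                             imbalance_ratios = NULL,
                             rng_seed = 1L) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  if (image_size < 16L) stop("synthetic_config: image_size must be >= 16")
  if (any(c(superclass_effect, subclass_effect, patient_effect, noise_sd) < 0)) {
    stop("synthetic_config: effect sizes must be nonnegative")
  }
  if (superclass_effect > 0 && subclass_effect >= superclass_effect) {
    stop("synthetic_config: require subclass_effect < superclass_effect ",
         "(subclass differences are the subtle ones)")
  }
  if (!all(magnifications %in% VALID_MAGNIFICATIONS)) {
    stop("synthetic_config: magnifications must be among ",
         paste(VALID_MAGNIFICATIONS, collapse = ", "))
  }
  if (!is.null(imbalance_ratios)) {
    bad <- setdiff(names(imbalance_ratios), subclasses(taxonomy))
    if (length(bad)) stop("synthetic_config: imbalance ratio for unknown ",
                          "subclass: ", paste(bad, collapse = ", "))
  }
  structure(list(taxonomy = taxonomy,
                 patients_per_subclass = as.integer(patients_per_subclass),
                 images_per_patient = as.integer(images_per_patient),
                 image_size = as.integer(image_size),
                 magnifications = magnifications,
                 superclass_effect = superclass_effect,
                 subclass_effect = subclass_effect,
                 patient_effect = patient_effect,
                 noise_sd = noise_sd,
                 imbalance_ratios = imbalance_ratios,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

# Texture signature of a subclass: dominant frequency (cycles per image at
# 40X) and orientation. Within a superclass, subclasses step by a factor 1.7
# in frequency and 45 degrees in orientation; the second superclass is
# offset by a factor 1.3 and 22.5 degrees so every subclass pair, including
# cross-superclass pairs, has a distinct signature.
subclass_signature <- function(cfg, sub) {
  tx <- cfg$taxonomy
  sup <- unname(tx$subclass_map[[sub]])
  sup_i <- match(sup, tx$superclasses) - 1L
  sibs <- names(tx$subclass_map)[tx$subclass_map == sup]
  j <- match(sub, sibs) - 1L
  list(freq = 4.0 * 1.7^j * 1.3^sup_i,
       theta = (j * 45 + sup_i * 22.5) * pi / 180,
       color = (1 - 2 * (sup_i %% 2)))   # +1 first superclass, -1 second
}

mag_scale <- function(mag) sqrt(40 / as.numeric(sub("X$", "", mag)))

# Render one synthetic image (deterministic given `seed`).
gen_synth_image <- function(cfg, sub, patient_offset, mag, seed) {
  s <- cfg$image_size
  sig <- subclass_signature(cfg, sub)
  f <- sig$freq * mag_scale(mag)
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    xs <- (seq_len(s) - 0.5) / s
    wave <- outer(xs * sin(sig$theta), xs * cos(sig$theta), "+")
    tex <- cfg$subclass_effect * sin(2 * pi * f * wave + phase)
    base <- 0.5 + sig$color * cfg$superclass_effect / 2 * c(1, 0, -1)
    img <- array(0, dim = c(s, s, 3L))
    for (ch in 1:3) {
      img[, , ch] <- base[ch] + patient_offset[ch] + tex +
        stats::rnorm(s * s, 0, cfg$noise_sd)
    }
    pmin(pmax(img, 0), 1)
  })
}

synth_patient_offset <- function(cfg, patient_id) {
  with_seed(derive_seed(cfg$rng_seed, paste0("patient:", patient_id)),
            stats::rnorm(3L, 0, cfg$patient_effect))
}

# The manifest skeleton (no pixels): one row per image to generate.
synth_layout <- function(cfg) {
  subs <- subclasses(cfg$taxonomy)
  rows <- list()
  for (sub in subs) {
    ratio <- 1
    if (!is.null(cfg$imbalance_ratios) && sub %in% names(cfg$imbalance_ratios)) {
      ratio <- cfg$imbalance_ratios[[sub]]
    }
    n_img <- max(1L, as.integer(round(cfg$images_per_patient * ratio)))
    sup <- unname(cfg$taxonomy$subclass_map[[sub]])
    for (p in seq_len(cfg$patients_per_subclass)) {
      pid <- sprintf("P_%s_%02d", sub, p)
      for (mag in cfg$magnifications) {
        for (i in seq_len(n_img)) {
          rows[[length(rows) + 1L]] <- data.frame(
            path = file.path(sup, sub, pid, mag,
                             sprintf("img_%03d.ppm", i)),
            patient_id = pid, subclass = sub, magnification = mag,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic dataset on disk
#'
#' Writes the images of a [synthetic_config] as PPM files in a
#' BreaKHis-style folder hierarchy
#' (`superclass/subclass/patient/magnification/image.ppm`) under `out_dir`
#' and returns the corresponding manifest. Fully deterministic given the
#' config's `rng_seed`.
#'
#' @param cfg a [synthetic_config].
#' @param out_dir output directory (created; must be writable).
#' @return A [manifest] whose paths are relative to `out_dir`.
#' @export
generate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("generate_dataset: cannot create out_dir: ", out_dir)
  }
  layout <- synth_layout(cfg)
  offsets <- lapply(stats::setNames(nm = unique(layout$patient_id)),
                    function(p) synth_patient_offset(cfg, p))
  for (i in seq_len(nrow(layout))) {
    r <- layout[i, ]
    img <- gen_synth_image(cfg, r$subclass, offsets[[r$patient_id]],
                           r$magnification,
                           seed = derive_seed(cfg$rng_seed, r$path))
    dst <- file.path(out_dir, r$path)
    dir.create(dirname(dst), recursive = TRUE, showWarnings = FALSE)
    write_image(img, dst)
  }
  m <- manifest(layout, cfg$taxonomy)
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  m
}

## ---- separability diagnostics ---------------------------------------------

# Simple image statistics used by the separability report: per-channel means
# (up-weighted x2 so the colour-shift scale is commensurate with unit-sum
# spectral energies), normalised radial spectrum peak, and energy fractions
# in 8 orientation bins of the 2-D power spectrum.
image_features <- function(img) {
  s <- dim(img)[1]
  means <- c(mean(img[, , 1]), mean(img[, , 2]), mean(img[, , 3]))
  grey <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  p <- Mod(stats::fft(grey - mean(grey)))^2
  fr <- c(0:(s %/% 2), -((s - s %/% 2 - 1):1))   # FFT frequency index
  fy <- matrix(fr, s, s); fx <- matrix(fr, s, s, byrow = TRUE)
  rad <- sqrt(fy^2 + fx^2)
  mask <- rad > 0.5 & rad <= s / 2
  pk <- which.max(ifelse(mask, p, -Inf))
  rpeak <- rad[pk] / (s / 2)
  ang <- atan2(fy, fx) %% pi
  bins <- pmin(floor(ang / (pi / 8)) + 1, 8)
  etot <- sum(p[mask])
  orient <- vapply(1:8, function(b) sum(p[mask & bins == b]) / etot, 1)
  c(2 * means, rpeak, orient)
}

#' Separability report for a synthetic configuration
#'
#' Monte-Carlo estimate of how well the generated data realises the
#' three-tier distance hierarchy: draws random image pairs, computes simple
#' image statistics (channel means, radial spectrum peak, orientation
#' energy) and compares mean feature distances for same-subclass,
#' same-superclass and different-superclass pairs. Also contrasts
#' within-patient against between-patient same-subclass distances: when the
#' patient effect rivals or exceeds the subclass effect, image-wise splits
#' would leak patient identity and the report says so.
#'
#' @param cfg a [synthetic_config].
#' @param n_pairs sampled pairs per tier (default 150).
#' @param rng_seed integer seed for the Monte-Carlo draw.
#' @return List with mean tier distances (`d_same_subclass`,
#'   `d_same_superclass`, `d_diff_superclass`), logical `hierarchy_ok`,
#'   `separable`, `patient_split_required`, and the per-tier samples.
#' @export
expected_separability <- function(cfg, n_pairs = 150L, rng_seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$superclass_effect == 0 && cfg$subclass_effect == 0) {
    return(list(separable = FALSE, hierarchy_ok = FALSE,
                patient_split_required = cfg$patient_effect > 0,
                d_same_subclass = NA_real_, d_same_superclass = NA_real_,
                d_diff_superclass = NA_real_,
                message = "degenerate config: zero effects, non-separable"))
  }
  tx <- cfg$taxonomy
  subs <- subclasses(tx)
  mag <- cfg$magnifications[1]
  draw_feat <- function(sub, pid, tag) {
    off <- synth_patient_offset(cfg, pid)
    img <- gen_synth_image(cfg, sub, off, mag,
                           seed = derive_seed(rng_seed, tag))
    image_features(img)
  }
  with_seed(rng_seed, {
    tiers <- list(same_subclass = numeric(0), same_superclass = numeric(0),
                  diff_superclass = numeric(0))
    within_pat <- numeric(0); between_pat <- numeric(0)
    for (i in seq_len(n_pairs)) {
      a <- sample(subs, 1L)
      sup_a <- tx$subclass_map[[a]]
      sibs <- setdiff(subs[tx$subclass_map[subs] == sup_a], a)
      others <- subs[tx$subclass_map[subs] != sup_a]
      pa <- sprintf("P_%s_%02d", a, sample.int(cfg$patients_per_subclass, 1L))
      fa <- draw_feat(a, pa, paste0("a", i))
      # same subclass, different patient
      if (cfg$patients_per_subclass > 1L) {
        other_p <- setdiff(seq_len(cfg$patients_per_subclass),
                           as.integer(sub(".*_", "", pa)))
        pb <- sprintf("P_%s_%02d", a,
                      other_p[sample.int(length(other_p), 1L)])
        d_bp <- sqrt(sum((fa - draw_feat(a, pb, paste0("b", i)))^2))
        tiers$same_subclass <- c(tiers$same_subclass, d_bp)
        between_pat <- c(between_pat, d_bp)
        within_pat <- c(within_pat,
                        sqrt(sum((fa - draw_feat(a, pa, paste0("w", i)))^2)))
      } else {
        tiers$same_subclass <- c(tiers$same_subclass,
                                 sqrt(sum((fa - draw_feat(a, pa,
                                                          paste0("b", i)))^2)))
      }
      if (length(sibs)) {
        b <- sample(sibs, 1L)
        pb <- sprintf("P_%s_%02d", b, sample.int(cfg$patients_per_subclass, 1L))
        tiers$same_superclass <- c(tiers$same_superclass,
                                   sqrt(sum((fa - draw_feat(b, pb,
                                                            paste0("s", i)))^2)))
      }
      if (length(others)) {
        b <- sample(others, 1L)
        pb <- sprintf("P_%s_%02d", b, sample.int(cfg$patients_per_subclass, 1L))
        tiers$diff_superclass <- c(tiers$diff_superclass,
                                   sqrt(sum((fa - draw_feat(b, pb,
                                                            paste0("n", i)))^2)))
      }
    }
    d1 <- mean(tiers$same_subclass)
    d2 <- mean(tiers$same_superclass)
    d3 <- mean(tiers$diff_superclass)
    psr <- cfg$patient_effect >= cfg$subclass_effect ||
      (length(within_pat) > 0 &&
         mean(between_pat) > 2 * mean(within_pat))
    list(separable = TRUE,
         hierarchy_ok = is.finite(d1) && is.finite(d2) && is.finite(d3) &&
           d1 < d2 && d2 < d3,
         patient_split_required = psr,
         d_same_subclass = d1, d_same_superclass = d2, d_diff_superclass = d3,
         d_within_patient = if (length(within_pat)) mean(within_pat) else NA,
         d_between_patient = if (length(between_pat)) mean(between_pat) else NA,
         samples = tiers,
         message = if (psr) {
           "patient effect is material: use patient-wise splits for honest evaluation"
         } else "ok")
  })
}
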