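# Shared fixtures, all generated in code at test time.

# Unit vector in dimension d.
runit <- function(d) {
  v <- stats::rnorm(d)
  v / sqrt(sum(v^2))
}

# Quadruplet whose three anchor distances are exactly d = c(dpp, dpm, dn):
# points on the unit circle at chord-length distances from the anchor.
quad_with_distances <- function(d) {
  ang <- function(x) 2 * asin(x / 2)
  pt <- function(x) c(cos(ang(x)), sin(ang(x)))
  quadruplet_embeddings(c(1, 0), pt(d[1]), pt(d[2]), pt(d[3]))
}

# Random quadruplet of unit vectors in dimension d.
random_quad <- function(d = 8) {
  quadruplet_embeddings(runit(d), runit(d), runit(d), runit(d))
}

# A records data.frame for manifest tests: n_patients per subclass,
# n_images per patient (no pixel data behind the paths).
toy_records <- function(subclasses, n_patients = 3, n_images = 4,
                        magnification = "40X") {
  rows <- list()
  for (s in subclasses) for (p in seq_len(n_patients)) {
    pid <- sprintf("P_%s_%02d", s, p)
    for (i in seq_len(n_images)) for (mg in magnification) {
      rows[[length(rows) + 1L]] <- data.frame(
        path = sprintf("%s/%s/%s/img_%03d.ppm", s, pid, mg, i),
        patient_id = pid, subclass = s, magnification = mg,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Random prediction set over n_patients patients with n_images each.
random_prediction_set <- function(n_patients = 10, n_images = 20,
                                  labels = subclasses(default_breakhis_taxonomy())) {
  pid <- rep(sprintf("P%02d", seq_len(n_patients)),
             each = n_images)
  true <- rep(sample(labels, n_patients, replace = TRUE), each = n_images)
  pred <- ifelse(stats::runif(length(pid)) < 0.7, true,
                 sample(labels, length(pid), replace = TRUE))
  prediction_set(pid, true, pred,
                 sample(c("40X", "100X"), length(pid), replace = TRUE))
}

# One small synthetic dataset on disk, generated once per test session.
shared_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "hiercls_shared_synth")
      cfg <- synthetic_config(patients_per_subclass = 3L,
                              images_per_patient = 4L,
                              image_size = 32L, rng_seed = 2024L)
      m <- generate_dataset(cfg, dir)
      cache <<- list(cfg = cfg, dir = dir, manifest = m)
    }
    cache
  }
})
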