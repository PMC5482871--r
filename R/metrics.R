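#' Per-image prediction set
#'
#' The input to patient-level and image-level recognition rates: one row per
#' image with its patient, true subclass, predicted subclass and
#' magnification factor.
#'
#' @param patient_id character vector.
#' @param true_subclass,predicted_subclass subclass labels; validated
#'   against `taxonomy` when one is supplied.
#' @param magnification magnification factor per image (e.g. "40X").
#' @param taxonomy optional [taxonomy] for label validation.
#' @return A `prediction_set`: a data.frame with the four columns above.
#' @export
prediction_set <- function(patient_id, true_subclass, predicted_subclass,
                           magnification = "40X", taxonomy = NULL) {
  n <- length(patient_id)
  if (n < 1L) stop("prediction_set: empty prediction set")
  df <- data.frame(patient_id = as.character(patient_id),
                   true_subclass = as.character(true_subclass),
                   predicted_subclass = as.character(predicted_subclass),
                   magnification = rep_len(as.character(magnification), n),
                   stringsAsFactors = FALSE)
  if (!is.null(taxonomy)) {
    df$true_subclass <- canonical_label(taxonomy, df$true_subclass)
    df$predicted_subclass <- canonical_label(taxonomy, df$predicted_subclass)
  }
  class(df) <- c("prediction_set", "data.frame")
  df
}

as_prediction_set <- function(df, taxonomy = NULL) {
  need <- c("patient_id", "true_subclass", "predicted_subclass", "magnification")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("prediction set missing column(s): ",
                         paste(miss, collapse = ", "))
  prediction_set(df$patient_id, df$true_subclass, df$predicted_subclass,
                 df$magnification, taxonomy)
}

#' Patient score
#'
#' Fraction of one patient's images classified correctly:
#' Score = N_rp / N_np, with N_np the patient's image count and N_rp the
#' number classified correctly.
#'
#' @param preds a [prediction_set].
#' @param patient_id single patient identifier present in `preds`.
#' @return Real in `[0, 1]`.
#' @export
patient_score <- function(preds, patient_id) {
  rows <- preds$patient_id == patient_id
  if (!any(rows)) stop("patient_score: unknown patient '", patient_id, "'")
  mean(preds$true_subclass[rows] == preds$predicted_subclass[rows])
}

#' Patient-level recognition rate
#'
#' Mean of the per-patient scores over the N_p patients — each patient
#' counts equally regardless of how many images they contributed.
#'
#' @param preds a [prediction_set].
#' @return Real in `[0, 1]`.
#' @export
patient_recognition_rate <- function(preds) {
  if (nrow(preds) < 1L) stop("patient_recognition_rate: empty prediction set")
  correct <- preds$true_subclass == preds$predicted_subclass
  mean(tapply(correct, preds$patient_id, mean))
}

#' Image-level recognition rate
#'
#' N_r / N_all: the fraction of all images classified correctly, ignoring
#' patient grouping.
#'
#' @param preds a [prediction_set].
#' @return Real in `[0, 1]`.
#' @export
image_recognition_rate <- function(preds) {
  if (nrow(preds) < 1L) stop("image_recognition_rate: empty prediction set")
  mean(preds$true_subclass == preds$predicted_subclass)
}

#' Confusion matrix of a prediction set
#'
#' @param preds a [prediction_set].
#' @param labels class label order; defaults to labels observed in `preds`.
#' @return k x k integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(preds, labels = NULL) {
  if (is.null(labels)) {
    labels <- sort(unique(c(preds$true_subclass, preds$predicted_subclass)))
  }
  tt <- table(factor(preds$true_subclass, levels = labels),
              factor(preds$predicted_subclass, levels = labels))
  m <- matrix(as.integer(tt), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  m
}

#' Full metrics report
#'
#' Computes per-patient scores, patient- and image-level recognition rates,
#' the confusion matrix, and the same metrics restricted to each
#' magnification factor present.
#'
#' @param preds a [prediction_set].
#' @param taxonomy optional [taxonomy] fixing confusion-matrix label order.
#' @return Object of class `metrics_report`.
#' @export
metrics_report <- function(preds, taxonomy = NULL) {
  if (nrow(preds) < 1L) stop("metrics_report: empty prediction set")
  labels <- if (!is.null(taxonomy)) subclasses(taxonomy)
  correct <- preds$true_subclass == preds$predicted_subclass
  scores <- tapply(correct, preds$patient_id, mean)
  per_mag <- lapply(split(seq_len(nrow(preds)), preds$magnification),
                    function(ix) {
    sub <- preds[ix, , drop = FALSE]
    list(patient_recognition_rate = patient_recognition_rate(sub),
         image_recognition_rate = image_recognition_rate(sub),
         n_images = nrow(sub),
         n_patients = length(unique(sub$patient_id)))
  })
  structure(
    list(patient_scores = as.list(scores),
         patient_recognition_rate = mean(scores),
         image_recognition_rate = mean(correct),
         confusion = confusion_matrix(preds, labels),
         per_magnification = per_mag,
         n_images = nrow(preds),
         n_patients = length(scores)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report> ", x$n_images, " images / ", x$n_patients,
      " patients\n", sep = "")
  cat(sprintf("  patient-level recognition rate: %.*f\n", digits,
              x$patient_recognition_rate))
  cat(sprintf("  image-level recognition rate:   %.*f\n", digits,
              x$image_recognition_rate))
  for (m in names(x$per_magnification)) {
    pm <- x$per_magnification[[m]]
    cat(sprintf("  [%s] patient %.*f | image %.*f (n=%d)\n", m, digits,
                pm$patient_recognition_rate, digits,
                pm$image_recognition_rate, pm$n_images))
  }
  invisible(x)
}

#' Summarise metrics across cross-validation folds
#'
#' Mean and sample (n-1) standard deviation of each recognition rate over
#' fold reports, in the "mean +/- sd" convention used for cross-validated
#' accuracy tables.
#'
#' @param reports list of [metrics_report] (>= 2).
#' @return Data.frame with columns `metric`, `mean`, `sd`, `formatted`.
#' @export
cross_validation_summary <- function(reports) {
  if (length(reports) < 2L) {
    stop("cross_validation_summary: need at least 2 fold reports")
  }
  pull <- function(field) vapply(reports, function(r) r[[field]], 1)
  metrics <- c(patient_recognition_rate = "patient_recognition_rate",
               image_recognition_rate = "image_recognition_rate")
  rows <- lapply(names(metrics), function(m) {
    v <- pull(metrics[[m]])
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v),
               formatted = sprintf("%.3f ± %.3f", mean(v), stats::sd(v)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read a prediction set as CSV
#'
#' Columns: `patient_id,true_subclass,predicted_subclass,magnification`.
#'
#' @param preds a [prediction_set].
#' @param path CSV file.
#' @param taxonomy optional [taxonomy] for validation on read.
#' @export
write_predictions <- function(preds, path) {
  utils::write.csv(as.data.frame(preds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path, taxonomy = NULL) {
  as_prediction_set(utils::read.csv(path, stringsAsFactors = FALSE), taxonomy)
}

#' Serialise a metrics report to JSON
#'
#' @param report a [metrics_report].
#' @param path output file.
#' @export
write_metrics_json <- function(report, path) {
  out <- report
  out$confusion <- list(labels = rownames(report$confusion),
                        counts = unclass(report$confusion))
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
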