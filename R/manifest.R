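VALID_MAGNIFICATIONS <- c("40X", "100X", "200X", "400X")

#' Image manifest
#'
#' A manifest is the tabular description of an image dataset: one row per
#' image with its file path, patient identifier, subclass label and
#' magnification factor, plus an optional train/val/test split column and an
#' `augmented_from` column on augmented copies. Invariants enforced: paths
#' are unique, labels and magnifications are valid, and each patient carries
#' a single subclass (one tumour per patient).
#'
#' @param records data.frame with columns `path`, `patient_id`, `subclass`,
#'   `magnification` and optionally `split`, `augmented_from`.
#' @param taxonomy a [taxonomy] the labels must belong to.
#' @return Object of class `manifest` with elements `records`, `taxonomy`.
#' @export
manifest <- function(records, taxonomy = default_breakhis_taxonomy()) {
  need <- c("path", "patient_id", "subclass", "magnification")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("manifest: missing column(s): ", paste(miss, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (cc in intersect(names(records),
                       c(need, "split", "augmented_from"))) {
    records[[cc]] <- as.character(records[[cc]])
  }
  if (!"split" %in% names(records)) records$split <- NA_character_
  records$split[!is.na(records$split) & !nzchar(records$split)] <- NA
  if (!is.null(records$augmented_from)) {
    records$augmented_from[!is.na(records$augmented_from) &
                             !nzchar(records$augmented_from)] <- NA
  }
  if (nrow(records) < 1L) stop("manifest: no records")

  problems <- character(0)
  dup <- which(duplicated(records$path))
  if (length(dup)) {
    problems <- c(problems, paste0("row ", dup, ": duplicated path '",
                                   records$path[dup], "'"))
  }
  bad_mag <- which(!records$magnification %in% VALID_MAGNIFICATIONS)
  if (length(bad_mag)) {
    problems <- c(problems, paste0("row ", bad_mag, ": invalid magnification '",
                                   records$magnification[bad_mag], "'"))
  }
  canon <- tryCatch(canonical_label(taxonomy, records$subclass),
                    error = function(e) NULL)
  if (is.null(canon)) {
    known <- c(names(taxonomy$subclass_map), names(taxonomy$aliases))
    bad <- which(!records$subclass %in% known)
    problems <- c(problems, paste0("row ", bad, ": unknown subclass '",
                                   records$subclass[bad], "'"))
  } else {
    records$subclass <- canon
  }
  bad_split <- which(!is.na(records$split) &
                       !records$split %in% c("train", "val", "test"))
  if (length(bad_split)) {
    problems <- c(problems, paste0("row ", bad_split, ": invalid split '",
                                   records$split[bad_split], "'"))
  }
  if (!length(problems)) {
    multi <- tapply(records$subclass, records$patient_id,
                    function(s) length(unique(s)))
    bad_p <- names(multi)[multi > 1]
    if (length(bad_p)) {
      problems <- c(problems,
                    paste0("patient '", bad_p,
                           "' carries more than one subclass"))
    }
  }
  if (length(problems)) {
    stop("manifest validation failed:\n  ",
         paste(utils::head(problems, 20L), collapse = "\n  "))
  }
  rownames(records) <- NULL
  structure(list(records = records, taxonomy = taxonomy), class = "manifest")
}

#' @export
print.manifest <- function(x, ...) {
  r <- x$records
  cat("<manifest> ", nrow(r), " images, ",
      length(unique(r$patient_id)), " patients, ",
      length(unique(r$subclass)), " subclasses\n", sep = "")
  tab <- table(r$subclass, r$magnification)
  print(tab)
  if (any(!is.na(r$split))) print(table(split = r$split, useNA = "ifany"))
  invisible(x)
}

#' Read / write a manifest CSV
#'
#' Schema: `path,patient_id,subclass,magnification[,split][,augmented_from]`.
#' Reading validates every row and reports offending row numbers;
#' write-then-read is an identity on the record set.
#'
#' @param path CSV file.
#' @param taxonomy a [taxonomy] used for validation.
#' @return `read_manifest` returns a [manifest].
#' @export
read_manifest <- function(path, taxonomy = default_breakhis_taxonomy()) {
  if (!file.exists(path)) stop("read_manifest: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  manifest(df, taxonomy)
}

#' @rdname read_manifest
#' @param m a [manifest].
#' @export
write_manifest <- function(m, path) {
  stopifnot(inherits(m, "manifest"))
  utils::write.csv(m$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Scan a BreaKHis-style directory tree into a manifest
#'
#' Expects the folder convention
#' `root/<superclass>/<tumour_type>/<patient_id>/<magnification>/<image>`
#' where `<tumour_type>` may be a long name (resolved through the taxonomy's
#' alias table) or a canonical short code.
#'
#' @param root directory to walk.
#' @param taxonomy a [taxonomy].
#' @return A [manifest] with paths relative to `root`.
#' @export
scan_breakhis_dir <- function(root, taxonomy = default_breakhis_taxonomy()) {
  if (!dir.exists(root)) stop("scan_breakhis_dir: no such directory: ", root)
  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  files <- files[grepl("/", files, fixed = TRUE)]
  parts <- strsplit(files, "/", fixed = TRUE)
  keep <- vapply(parts, length, 1L) == 5L
  if (!any(keep)) stop("scan_breakhis_dir: no files at depth 5 under ", root)
  parts <- parts[keep]; files <- files[keep]
  df <- data.frame(
    path = files,
    patient_id = vapply(parts, `[`, "", 3L),
    subclass = vapply(parts, `[`, "", 2L),
    magnification = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE)
  manifest(df, taxonomy)
}

#' Patient-wise stratified train/val/test split
#'
#' Assigns every patient — and therefore every one of their images — to
#' exactly one of train/validation/test. Global patient counts follow the
#' fractions with round-to-nearest for train and validation and the
#' remainder going to test (so 82 patients at (0.50, 0.25, 0.25) give
#' 41/20/21); the counts are then apportioned across subclasses by largest
#' remainder so each stratum's composition tracks the fractions as closely
#' as integers allow. A subclass with a single patient cannot be stratified
#' and is assigned to train with a warning.
#'
#' @param m a [manifest].
#' @param fractions numeric length-3 vector (train, val, test), positive,
#'   summing to 1.
#' @param rng_seed integer seed controlling which patients land where.
#' @return The manifest with its `split` column filled.
#' @export
patient_wise_split <- function(m, fractions = c(0.50, 0.25, 0.25),
                               rng_seed = 1L) {
  stopifnot(inherits(m, "manifest"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("patient_wise_split: fractions must be 3 positive numbers summing to 1")
  }
  rec <- m$records
  pat <- unique(rec[, c("patient_id", "subclass")])
  singles <- names(which(table(pat$subclass) == 1L))
  if (length(singles)) {
    warning("patient_wise_split: subclass(es) with a single patient assigned ",
            "to train: ", paste(singles, collapse = ", "))
  }
  forced <- pat$patient_id[pat$subclass %in% singles]
  pool <- pat[!pat$subclass %in% singles, , drop = FALSE]
  n <- nrow(pool)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (n_test < 0) { n_val <- n_val + n_test; n_test <- 0 }

  split_of <- stats::setNames(rep("train", length(forced)), forced)
  if (n > 0) {
    subs <- sort(unique(pool$subclass))
    counts <- vapply(subs, function(s) sum(pool$subclass == s), 1L)
    t_alloc <- apportion(n_train, counts, capacity = counts)
    v_alloc <- apportion(n_val, counts, capacity = counts - t_alloc)
    assigned <- with_seed(rng_seed, {
      out <- character(0)
      for (i in seq_along(subs)) {
        ids <- pool$patient_id[pool$subclass == subs[i]]
        ids <- ids[sample.int(length(ids))]
        lab <- rep(c("train", "val", "test"),
                   c(t_alloc[i], v_alloc[i],
                     length(ids) - t_alloc[i] - v_alloc[i]))
        out <- c(out, stats::setNames(lab, ids))
      }
      out
    })
    split_of <- c(split_of, assigned)
  }
  rec$split <- unname(split_of[rec$patient_id])
  manifest(rec, m$taxonomy)
}

#' Patient-wise stratified cross-validation folds
#'
#' Partitions patients into `n_folds` subclass-stratified groups; fold i
#' uses group i as test, group (i mod n_folds) + 1 as validation and the
#' rest as training, so every patient is in the test portion of exactly one
#' fold.
#'
#' @param m a [manifest].
#' @param n_folds number of folds (default 5).
#' @param rng_seed integer seed.
#' @return List of length `n_folds`; each element is a [manifest] with the
#'   fold's split assignment.
#' @export
make_cv_folds <- function(m, n_folds = 5L, rng_seed = 1L) {
  stopifnot(inherits(m, "manifest"), n_folds >= 2L)
  rec <- m$records
  pat <- unique(rec[, c("patient_id", "subclass")])
  if (n_folds > nrow(pat)) {
    stop("make_cv_folds: n_folds (", n_folds, ") exceeds patient count (",
         nrow(pat), ")")
  }
  fold_of <- with_seed(rng_seed, {
    out <- integer(0)
    for (s in sort(unique(pat$subclass))) {
      ids <- pat$patient_id[pat$subclass == s]
      ids <- ids[sample.int(length(ids))]
      # rotate the starting fold per subclass so small strata spread out
      f <- ((seq_along(ids) - 1L + sample.int(n_folds, 1L)) %% n_folds) + 1L
      out <- c(out, stats::setNames(f, ids))
    }
    out
  })
  lapply(seq_len(n_folds), function(i) {
    val_fold <- (i %% n_folds) + 1L
    f <- fold_of[rec$patient_id]
    rec$split <- ifelse(f == i, "test", ifelse(f == val_fold, "val", "train"))
    manifest(rec, m$taxonomy)
  })
}

#' Subset a manifest by split
#' @param m a [manifest].
#' @param split one of "train", "val", "test".
#' @return A [manifest] containing only that split's records.
#' @export
manifest_split <- function(m, split) {
  stopifnot(inherits(m, "manifest"))
  rec <- m$records[!is.na(m$records$split) & m$records$split == split, ,
                   drop = FALSE]
  if (!nrow(rec)) stop("manifest_split: split '", split, "' is empty")
  manifest(rec, m$taxonomy)
}

#' Audit an augmented manifest for patient leakage
#'
#' Verifies that no augmented image stems from a validation or test patient:
#' augmentation is legitimate on the training split only, and any violation
#' means evaluation data leaked into training. Fails loudly on violation.
#'
#' @param augmented a [manifest] that may contain augmented records
#'   (non-empty `augmented_from`).
#' @param reference a [manifest] carrying the split assignment (defaults to
#'   `augmented` itself).
#' @return Invisibly `TRUE` when clean; otherwise an error listing the
#'   leaked patients.
#' @export
audit_no_leakage <- function(augmented, reference = augmented) {
  stopifnot(inherits(augmented, "manifest"), inherits(reference, "manifest"))
  rec <- augmented$records
  if (is.null(rec$augmented_from)) return(invisible(TRUE))
  aug <- rec[!is.na(rec$augmented_from) & nzchar(rec$augmented_from), ,
             drop = FALSE]
  if (!nrow(aug)) return(invisible(TRUE))
  ref <- reference$records
  holdout <- unique(ref$patient_id[!is.na(ref$split) &
                                     ref$split %in% c("val", "test")])
  leaked <- intersect(unique(aug$patient_id), holdout)
  if (length(leaked)) {
    stop("leakage audit failed: augmented images exist for held-out ",
         "patient(s): ", paste(leaked, collapse = ", "))
  }
  invisible(TRUE)
}
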