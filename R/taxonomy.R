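#' Two-level label taxonomy
#'
#' A taxonomy maps each fine-grained subclass (tumour type) to exactly one
#' superclass (benign / malignant). It is the prior knowledge consumed by the
#' hierarchical distance-constraint loss: two images can be of the same
#' subclass, of sibling subclasses under one superclass, or of different
#' superclasses, and the loss demands increasing embedding distance across
#' those three tiers.
#'
#' @param subclass_map named character vector; names are subclass labels,
#'   values the superclass each belongs to.
#' @param superclasses optional character vector fixing superclass order;
#'   defaults to order of first appearance in `subclass_map`.
#' @param aliases optional named character vector mapping long names
#'   (e.g. folder names such as `"ductal_carcinoma"`) to canonical short
#'   subclass codes.
#' @return An object of class `taxonomy` with elements `superclasses`,
#'   `subclass_map`, `k` (number of subclasses) and `aliases`.
#' @examples
#' tx <- taxonomy(c(A = "benign", DC = "malignant"))
#' tx$k
#' @export
taxonomy <- function(subclass_map, superclasses = NULL, aliases = NULL) {
  if (length(subclass_map) < 2 || is.null(names(subclass_map)) ||
      any(!nzchar(names(subclass_map)))) {
    stop("taxonomy: 'subclass_map' must be a named vector with >= 2 subclasses")
  }
  if (anyDuplicated(names(subclass_map))) {
    stop("taxonomy: duplicated subclass label(s): ",
         paste(unique(names(subclass_map)[duplicated(names(subclass_map))]),
               collapse = ", "))
  }
  subclass_map <- vapply(subclass_map, as.character, character(1))
  if (is.null(superclasses)) superclasses <- unique(unname(subclass_map))
  missing_sup <- setdiff(unname(subclass_map), superclasses)
  if (length(missing_sup)) {
    stop("taxonomy: subclass mapped to unknown superclass: ",
         paste(missing_sup, collapse = ", "))
  }
  empty <- setdiff(superclasses, unname(subclass_map))
  if (length(empty)) {
    stop("taxonomy: superclass with no subclass: ", paste(empty, collapse = ", "))
  }
  structure(
    list(superclasses = superclasses,
         subclass_map = subclass_map,
         k = length(subclass_map),
         aliases = aliases),
    class = "taxonomy")
}

#' Default 8-class breast tumour taxonomy
#'
#' The standard BreaKHis-style class structure: four benign tumour types —
#' adenosis (A), fibroadenoma (F), phyllodes tumor (PT), tubular adenoma
#' (TA) — and four malignant types — ductal carcinoma (DC), lobular
#' carcinoma (LC), mucinous carcinoma (MC), papillary carcinoma (PC).
#' Long-name aliases matching BreaKHis folder names are attached so
#' directory scans resolve to the canonical short codes.
#'
#' @return A [taxonomy] with k = 8.
#' @examples
#' tx <- default_breakhis_taxonomy()
#' subclasses(tx)
#' @export
default_breakhis_taxonomy <- function() {
  taxonomy(
    subclass_map = c(
      A  = "benign", F  = "benign", PT = "benign", TA = "benign",
      DC = "malignant", LC = "malignant", MC = "malignant", PC = "malignant"),
    superclasses = c("benign", "malignant"),
    aliases = c(
      adenosis = "A", fibroadenoma = "F", phyllodes_tumor = "PT",
      tubular_adenoma = "TA", ductal_carcinoma = "DC",
      lobular_carcinoma = "LC", mucinous_carcinoma = "MC",
      papillary_carcinoma = "PC"))
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", x$k, " subclasses under ",
      length(x$superclasses), " superclasses\n", sep = "")
  for (sup in x$superclasses) {
    cat("  ", sup, ": ",
        paste(names(x$subclass_map)[x$subclass_map == sup], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Subclass labels of a taxonomy
#' @param t a [taxonomy].
#' @return Character vector of canonical subclass labels.
#' @export
subclasses <- function(t) {
  stopifnot(inherits(t, "taxonomy"))
  names(t$subclass_map)
}

#' Superclass of a subclass label
#' @param t a [taxonomy].
#' @param label subclass label(s); long-name aliases are accepted.
#' @return Character vector of superclass names.
#' @export
superclass_of <- function(t, label) {
  stopifnot(inherits(t, "taxonomy"))
  label <- canonical_label(t, label)
  unname(t$subclass_map[label])
}

#' Resolve labels to canonical subclass codes
#'
#' Long-name aliases (case-insensitive) are translated; canonical codes are
#' matched case-sensitively and passed through.
#' @param t a [taxonomy].
#' @param label character vector of labels.
#' @return Character vector of canonical codes.
#' @export
canonical_label <- function(t, label) {
  stopifnot(inherits(t, "taxonomy"))
  label <- as.character(label)
  out <- label
  if (!is.null(t$aliases)) {
    hit <- match(tolower(label), tolower(names(t$aliases)))
    out[!is.na(hit)] <- unname(t$aliases[hit[!is.na(hit)]])
  }
  bad <- setdiff(unique(out), names(t$subclass_map))
  if (length(bad)) {
    stop("unknown subclass label(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Relation between two subclass labels
#'
#' Classifies an (unordered) pair of subclass labels into one of the three
#' hierarchy tiers the quadruplet loss is built on.
#'
#' @param t a [taxonomy].
#' @param a,b subclass labels (vectors recycle to common length).
#' @return Character vector with values `"SAME_SUBCLASS"`,
#'   `"SAME_SUPERCLASS"` or `"DIFFERENT_SUPERCLASS"`.
#' @examples
#' tx <- default_breakhis_taxonomy()
#' relation(tx, "A", "F")   # SAME_SUPERCLASS: both benign
#' relation(tx, "A", "DC")  # DIFFERENT_SUPERCLASS
#' @export
relation <- function(t, a, b) {
  stopifnot(inherits(t, "taxonomy"))
  a <- canonical_label(t, a)
  b <- canonical_label(t, b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- rep("DIFFERENT_SUPERCLASS", n)
  same_sup <- t$subclass_map[a] == t$subclass_map[b]
  out[same_sup] <- "SAME_SUPERCLASS"
  out[a == b] <- "SAME_SUBCLASS"
  out
}

#' Serialize / deserialize a taxonomy config block
#'
#' The on-disk form is a JSON object with a `superclasses` array and a
#' `subclasses` object mapping subclass to superclass (plus optional
#' `aliases`).
#'
#' @param t a [taxonomy].
#' @param path file to write to / read from.
#' @return `taxonomy_to_config` returns the list form invisibly;
#'   `taxonomy_from_config` returns a [taxonomy].
#' @export
taxonomy_to_config <- function(t, path = NULL) {
  stopifnot(inherits(t, "taxonomy"))
  cfg <- list(superclasses = t$superclasses,
              subclasses = as.list(t$subclass_map))
  if (!is.null(t$aliases)) cfg$aliases <- as.list(t$aliases)
  if (!is.null(path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(cfg)
}

#' @rdname taxonomy_to_config
#' @param cfg list as produced by `taxonomy_to_config` (used when `path` is
#'   `NULL`).
#' @export
taxonomy_from_config <- function(path = NULL, cfg = NULL) {
  if (is.null(cfg)) cfg <- jsonlite::read_json(path)
  taxonomy(subclass_map = unlist(cfg$subclasses),
           superclasses = unlist(cfg$superclasses),
           aliases = if (!is.null(cfg$aliases)) unlist(cfg$aliases))
}
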