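#' Mine quadruplet index tuples from a labelled batch
#'
#' For every anchor position whose label admits all three partner relations
#' within the batch — a same-subclass positive, a sibling-subclass positive
#' (same superclass, different subclass) and a cross-superclass negative —
#' draw up to `per_anchor` random partner combinations. Anchors missing any
#' partner type contribute nothing. Every returned tuple is guaranteed sound
#' with respect to the taxonomy, and is an element of the exhaustive set of
#' valid (anchor, p+, p-, n) combinations.
#'
#' @param labels character vector of subclass labels for the batch.
#' @param t a [taxonomy].
#' @param per_anchor maximum tuples drawn per eligible anchor.
#' @param rng_seed integer seed making the draw reproducible.
#' @return Integer matrix with columns `anchor`, `pos_same_sub`,
#'   `pos_same_super`, `neg` (zero rows, with a warning, when the batch has
#'   no eligible anchor — the training step then falls back to the
#'   softmax-only objective).
#' @export
mine_quadruplets <- function(labels, t, per_anchor = 1L, rng_seed = 1L) {
  stopifnot(inherits(t, "taxonomy"), per_anchor >= 1L)
  if (length(labels) < 4L) {
    stop("mine_quadruplets: need at least 4 labelled images")
  }
  labels <- canonical_label(t, labels)
  sup <- unname(t$subclass_map[labels])
  n <- length(labels)
  out <- with_seed(rng_seed, {
    rows <- list()
    for (a in seq_len(n)) {
      pp <- which(labels == labels[a] & seq_len(n) != a)
      pm <- which(sup == sup[a] & labels != labels[a])
      ng <- which(sup != sup[a])
      if (!length(pp) || !length(pm) || !length(ng)) next
      for (r in seq_len(per_anchor)) {
        rows[[length(rows) + 1L]] <- c(
          a,
          pp[sample.int(length(pp), 1L)],
          pm[sample.int(length(pm), 1L)],
          ng[sample.int(length(ng), 1L)])
      }
    }
    rows
  })
  if (!length(out)) {
    warning("mine_quadruplets: no eligible anchors in batch; ",
            "falling back to softmax-only loss for this step")
    return(matrix(integer(0), ncol = 4L,
                  dimnames = list(NULL, c("anchor", "pos_same_sub",
                                          "pos_same_super", "neg"))))
  }
  m <- do.call(rbind, out)
  # drop duplicate tuples arising when per_anchor exceeds the partner pool
  m <- unique(m)
  colnames(m) <- c("anchor", "pos_same_sub", "pos_same_super", "neg")
  m
}

#' Exhaustively enumerate all valid quadruplets of a batch
#'
#' Brute-force reference for the miner: every index tuple (a, p+, p-, n)
#' whose pairwise relations to the anchor are SAME_SUBCLASS,
#' SAME_SUPERCLASS and DIFFERENT_SUPERCLASS respectively. Intended for
#' small batches (testing and audits).
#'
#' @inheritParams mine_quadruplets
#' @return Integer matrix, one row per valid tuple.
#' @export
enumerate_quadruplets <- function(labels, t) {
  stopifnot(inherits(t, "taxonomy"))
  labels <- canonical_label(t, labels)
  sup <- unname(t$subclass_map[labels])
  n <- length(labels)
  rows <- list()
  for (a in seq_len(n)) {
    pp <- which(labels == labels[a] & seq_len(n) != a)
    pm <- which(sup == sup[a] & labels != labels[a])
    ng <- which(sup != sup[a])
    for (i in pp) for (j in pm) for (l in ng) {
      rows[[length(rows) + 1L]] <- c(a, i, j, l)
    }
  }
  m <- if (length(rows)) do.call(rbind, rows) else matrix(integer(0), ncol = 4L)
  colnames(m) <- c("anchor", "pos_same_sub", "pos_same_super", "neg")
  m
}

#' Draw a quadruplet-feasible mini-batch from a manifest
#'
#' Stratified sampling of record indices such that the resulting batch can
#' feed the quadruplet miner: it contains at least two images of some
#' subclass, at least one of a sibling subclass, and at least one image of
#' the other superclass. Allocation starts from an equal share per subclass
#' present (capped by availability) and, if that leaves no subclass with two
#' slots, one slot is moved onto a subclass that can take a second image —
#' e.g. with batch size 8 on a balanced 8-class manifest one subclass loses
#' its single slot in favour of a feasible composition.
#'
#' @param manifest a [manifest].
#' @param t a [taxonomy] (defaults to the manifest's own).
#' @param batch_size number of records to draw (>= 8).
#' @param rng_seed integer seed.
#' @return Integer vector of row indices into `manifest$records`.
#' @export
hierarchy_balanced_batch <- function(manifest, t = manifest$taxonomy,
                                     batch_size = 32L, rng_seed = 1L) {
  stopifnot(inherits(manifest, "manifest"), inherits(t, "taxonomy"),
            batch_size >= 8L)
  rec <- manifest$records
  labels <- canonical_label(t, rec$subclass)
  sup <- unname(t$subclass_map[labels])
  subs <- sort(unique(labels))
  if (length(unique(sup)) < 2L) {
    stop("hierarchy_balanced_batch: manifest spans a single superclass; ",
         "quadruplet mining is unsatisfiable")
  }
  sib_ok <- vapply(subs, function(s) {
    any(subs != s & t$subclass_map[subs] == t$subclass_map[[s]])
  }, TRUE)
  if (!any(sib_ok)) {
    stop("hierarchy_balanced_batch: no superclass contains two subclasses; ",
         "quadruplet mining is unsatisfiable")
  }
  avail <- vapply(subs, function(s) sum(labels == s), 1L)
  with_seed(rng_seed, {
    alloc <- apportion(min(batch_size, sum(avail)),
                       weights = rep(1, length(subs)), capacity = avail)
    names(alloc) <- subs
    # feasibility: need some subclass with >=2 whose sibling has >=1
    feasible <- function(al) {
      any(vapply(seq_along(subs), function(i) {
        s <- subs[i]
        al[i] >= 2 && sib_ok[i] &&
          sum(al[subs != s & t$subclass_map[subs] == t$subclass_map[[s]]]) >= 1 &&
          sum(al[t$subclass_map[subs] != t$subclass_map[[s]]]) >= 1
      }, TRUE))
    }
    if (!feasible(alloc)) {
      cand <- which(sib_ok & avail >= 2 & alloc >= 1)
      fixed <- FALSE
      for (ci in cand[sample.int(length(cand))]) {
        donors <- which(alloc >= 1 & seq_along(subs) != ci)
        for (di in donors[sample.int(length(donors))]) {
          trial <- alloc
          trial[ci] <- trial[ci] + 1; trial[di] <- trial[di] - 1
          if (trial[ci] <= avail[ci] && feasible(trial)) {
            alloc <- trial; fixed <- TRUE; break
          }
        }
        if (fixed) break
      }
      if (!fixed) {
        stop("hierarchy_balanced_batch: cannot compose a quadruplet-feasible ",
             "batch of size ", batch_size, " from this manifest")
      }
    }
    idx <- unlist(lapply(seq_along(subs), function(i) {
      pool <- which(labels == subs[i])
      pool[sample.int(length(pool), alloc[i])]
    }), use.names = FALSE)
    sample(idx)  # shuffle batch order
  })
}
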