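#' Margin and mixing configuration for the combined loss
#'
#' `m1` and `m2` are the slack constants of the tiered distance constraint
#' D(x, p+) + m1 < D(x, p-) + m2 < D(x, n): `m1` separates same-subclass
#' from sibling-subclass pairs, `m2` separates sibling-subclass from
#' cross-superclass pairs, and `m1 < m2` is required for the three tiers to
#' be ordered. `lam` is the weight of the softmax term in the combined
#' objective E = lam * J + (1 - lam) * E_t; it lives in (0, 1) for joint
#' training, with the boundary values 0 and 1 admitted as diagnostic modes
#' (pure metric loss / pure softmax ablation).
#'
#' Defaults m1 = 0.2, m2 = 0.4 are commensurate with distances between unit
#' vectors (range [0, 2]); lam defaults to 0.5, the value at which the joint
#' objective performs best.
#'
#' @param m1 nonnegative inner margin.
#' @param m2 nonnegative outer margin, strictly greater than `m1`.
#' @param lam softmax weight in `[0, 1]`.
#' @return An object of class `margin_config`.
#' @export
margin_config <- function(m1 = 0.2, m2 = 0.4, lam = 0.5) {
  if (!is.numeric(m1) || !is.numeric(m2) || m1 < 0 || m2 < 0) {
    stop("margin_config: m1 and m2 must be nonnegative reals")
  }
  if (!(m1 < m2)) stop("margin_config: require m1 < m2 (got m1=", m1,
                       ", m2=", m2, ")")
  if (!is.numeric(lam) || lam < 0 || lam > 1) {
    stop("margin_config: lam must lie in [0, 1]")
  }
  structure(list(m1 = m1, m2 = m2, lam = lam), class = "margin_config")
}

#' l2-normalise vectors
#'
#' @param x numeric vector, or matrix whose rows are normalised.
#' @param eps floor added under the norm so zero vectors pass through scaled
#'   by 1/eps rather than producing NaN.
#' @return Same shape as `x`, each (row) vector scaled to unit Euclidean norm.
#' @export
l2_normalize <- function(x, eps = 1e-12) {
  if (is.matrix(x)) {
    nrm <- sqrt(rowSums(x * x))
    x / pmax(nrm, eps)
  } else {
    x / max(sqrt(sum(x * x)), eps)
  }
}

#' Softmax class probabilities
#'
#' Maps raw per-class scores theta_j' x to a probability distribution
#' exp(z_j) / sum_l exp(z_l), computed with max-subtraction for numerical
#' stability.
#'
#' @param logits numeric k-vector, or N x k matrix (rows are samples).
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @export
softmax_probabilities <- function(logits) {
  if (!all(is.finite(logits))) {
    stop("softmax_probabilities: non-finite logits")
  }
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

#' Softmax cross-entropy loss
#'
#' The multi-class classification error
#' J = -(1/N) sum_i sum_j 1\{y_i = j\} log p(y_i = j | x_i),
#' i.e. the mean negative log-probability of the correct subclass. Computed
#' via log-sum-exp rather than through the probabilities.
#'
#' @param logits N x k numeric matrix of class scores.
#' @param labels integer vector of length N, values in `1..k`.
#' @return Nonnegative scalar loss.
#' @export
softmax_loss <- function(logits, labels) {
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1L)
  n <- nrow(logits)
  if (n < 1L) stop("softmax_loss: empty batch")
  if (length(labels) != n) {
    stop("softmax_loss: ", n, " rows of logits but ", length(labels), " labels")
  }
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > ncol(logits))) {
    stop("softmax_loss: label index outside 1..k")
  }
  if (!all(is.finite(logits))) stop("softmax_loss: non-finite logits")
  zmax <- apply(logits, 1L, max)
  lse <- zmax + log(rowSums(exp(logits - zmax)))
  correct <- logits[cbind(seq_len(n), labels)]
  mean(lse - correct)
}

#' Gradient of the softmax loss with respect to the logits
#'
#' @inheritParams softmax_loss
#' @return N x k matrix (softmax probabilities minus one-hot labels, / N).
#' @export
softmax_loss_grad <- function(logits, labels) {
  if (!is.matrix(logits)) logits <- matrix(logits, nrow = 1L)
  n <- nrow(logits)
  p <- softmax_probabilities(logits)
  p[cbind(seq_len(n), as.integer(labels))] <-
    p[cbind(seq_len(n), as.integer(labels))] - 1
  p / n
}

#' Euclidean distance between two feature vectors
#'
#' Plain (non-squared) Euclidean norm of `a - b`, the distance D used in the
#' hierarchical constraint.
#'
#' @param a,b numeric vectors of equal length.
#' @param squared if `TRUE` return the squared distance (ablation variant).
#' @return Nonnegative scalar.
#' @export
euclidean_distance <- function(a, b, squared = FALSE) {
  if (length(a) != length(b)) {
    stop("euclidean_distance: dimension mismatch (", length(a), " vs ",
         length(b), ")")
  }
  d2 <- sum((a - b)^2)
  if (squared) d2 else sqrt(d2)
}

#' Bundle four embeddings into a quadruplet
#'
#' A quadruplet holds the embeddings of an anchor `x`, a same-subclass
#' positive `p_plus`, a sibling-subclass positive `p_minus` (same superclass,
#' different subclass) and a cross-superclass negative `n`. All four must be
#' unit-norm vectors of one dimension; set `normalize = TRUE` to l2-normalise
#' raw vectors on entry.
#'
#' @param x,p_plus,p_minus,n numeric vectors of equal dimension.
#' @param normalize l2-normalise the inputs first.
#' @param tol tolerance on the unit-norm check.
#' @return Object of class `quadruplet_embeddings`.
#' @export
quadruplet_embeddings <- function(x, p_plus, p_minus, n, normalize = FALSE,
                                  tol = 1e-6) {
  vs <- list(x = x, p_plus = p_plus, p_minus = p_minus, n = n)
  d <- length(x)
  if (!all(vapply(vs, length, 1L) == d)) {
    stop("quadruplet_embeddings: all four vectors must share one dimension")
  }
  if (normalize) vs <- lapply(vs, l2_normalize)
  nrm <- vapply(vs, function(v) sqrt(sum(v * v)), 1)
  if (any(abs(nrm - 1) > tol)) {
    stop("quadruplet_embeddings: vectors must be unit-norm (max deviation ",
         format(max(abs(nrm - 1))), "); use normalize = TRUE")
  }
  structure(vs, class = "quadruplet_embeddings")
}

quad_distances <- function(q, squared = FALSE) {
  c(dpp = euclidean_distance(q$x, q$p_plus, squared),
    dpm = euclidean_distance(q$x, q$p_minus, squared),
    dn  = euclidean_distance(q$x, q$n, squared))
}

#' Does a quadruplet satisfy the tiered distance constraint?
#'
#' Evaluates the strict chain
#' D(x, p+) + m1 < D(x, p-) + m2  and  D(x, p-) + m2 < D(x, n).
#' This is the ideal ordering the training loss pushes towards; the hinge
#' loss itself is zero on the closed (non-strict) version of the region.
#'
#' @param q a [quadruplet_embeddings].
#' @param m a [margin_config].
#' @param squared use squared distances.
#' @return Logical scalar.
#' @export
constraint_satisfied <- function(q, m, squared = FALSE) {
  stopifnot(inherits(q, "quadruplet_embeddings"), inherits(m, "margin_config"))
  d <- quad_distances(q, squared)
  (d[["dpp"]] + m$m1 < d[["dpm"]] + m$m2) && (d[["dpm"]] + m$m2 < d[["dn"]])
}

#' Hierarchical quadruplet hinge loss
#'
#' The distance-constraint loss over N quadruplets:
#' E_t = (1/2N) sum_i max\{0, D(x_i,p_i+) - D(x_i,p_i-) + m1 - m2\}
#'     + (1/2N) sum_i max\{0, D(x_i,p_i-) - D(x_i,n_i) + m2\}.
#' It is zero exactly when every quadruplet satisfies both margin
#' inequalities non-strictly.
#'
#' @param quads list of [quadruplet_embeddings] (a single quadruplet is
#'   accepted unwrapped).
#' @param m a [margin_config].
#' @param squared use squared distances.
#' @return Nonnegative scalar.
#' @export
hinge_constraint_loss <- function(quads, m, squared = FALSE) {
  stopifnot(inherits(m, "margin_config"))
  if (inherits(quads, "quadruplet_embeddings")) quads <- list(quads)
  n <- length(quads)
  if (n < 1L) stop("hinge_constraint_loss: empty quadruplet list")
  term1 <- 0; term2 <- 0
  for (q in quads) {
    d <- quad_distances(q, squared)
    term1 <- term1 + max(0, d[["dpp"]] - d[["dpm"]] + m$m1 - m$m2)
    term2 <- term2 + max(0, d[["dpm"]] - d[["dn"]] + m$m2)
  }
  (term1 + term2) / (2 * n)
}

#' Combined classification + distance-constraint objective
#'
#' E = lam * J + (1 - lam) * E_t, the joint objective optimised during
#' training: `lam = 1` reduces to the softmax loss, `lam = 0` to the pure
#' hinge constraint (both diagnostic boundary modes).
#'
#' @param logits N x k matrix of class scores.
#' @param labels integer class labels in `1..k`.
#' @param quads list of [quadruplet_embeddings].
#' @param m a [margin_config] carrying `m1`, `m2` and `lam`.
#' @param squared use squared distances in the hinge term.
#' @return Scalar loss E.
#' @export
combined_loss <- function(logits, labels, quads, m, squared = FALSE) {
  stopifnot(inherits(m, "margin_config"))
  j <- softmax_loss(logits, labels)
  et <- hinge_constraint_loss(quads, m, squared)
  m$lam * j + (1 - m$lam) * et
}

## ---- batch-level gradients (training path) --------------------------------

# dD/da for D = ||u_a - u_b|| on already-normalised rows; returns zero at the
# D = 0 kink (subgradient choice).
dist_grad_pair <- function(ua, ub, eps = 1e-12) {
  diff <- ua - ub
  d <- sqrt(sum(diff * diff))
  if (d < eps) return(list(d = d, ga = diff * 0))
  list(d = d, ga = diff / d)
}

#' Combined loss and gradients on a mini-batch
#'
#' Training-path evaluation of the joint objective: takes raw (unnormalised)
#' embeddings plus logits for a batch, a set of quadruplet index tuples into
#' that batch, and returns the loss together with analytic gradients with
#' respect to the logits and the raw embeddings. Embeddings are
#' l2-normalised internally before distances are measured, and the gradient
#' is propagated back through the normalisation.
#'
#' @param logits N x k matrix.
#' @param labels integer vector length N.
#' @param embeddings N x d matrix of raw embedding-head outputs.
#' @param quads integer matrix with columns `anchor`, `pos_same_sub`,
#'   `pos_same_super`, `neg` indexing rows of `embeddings`; may have zero
#'   rows, in which case the hinge term is dropped and E = lam * J (the
#'   degenerate-batch fallback).
#' @param m a [margin_config].
#' @return List with `value`, `J`, `E_t`, `grad_logits` (N x k) and
#'   `grad_embeddings` (N x d).
#' @export
combined_loss_grad <- function(logits, labels, embeddings, quads, m) {
  stopifnot(inherits(m, "margin_config"), is.matrix(embeddings))
  if (is.null(dim(quads))) quads <- matrix(quads, ncol = 4L)
  j <- softmax_loss(logits, labels)
  gl <- softmax_loss_grad(logits, labels) * m$lam

  nq <- nrow(quads)
  ge_u <- matrix(0, nrow(embeddings), ncol(embeddings))  # grad wrt normalised
  et <- 0
  if (nq > 0L) {
    u <- l2_normalize(embeddings)
    for (i in seq_len(nq)) {
      a <- quads[i, 1L]; pp <- quads[i, 2L]; pm <- quads[i, 3L]; ng <- quads[i, 4L]
      g_pp <- dist_grad_pair(u[a, ], u[pp, ])
      g_pm <- dist_grad_pair(u[a, ], u[pm, ])
      g_n  <- dist_grad_pair(u[a, ], u[ng, ])
      h1 <- g_pp$d - g_pm$d + m$m1 - m$m2
      h2 <- g_pm$d - g_n$d + m$m2
      if (h1 > 0) {
        et <- et + h1
        ge_u[a, ]  <- ge_u[a, ]  + (g_pp$ga - g_pm$ga)
        ge_u[pp, ] <- ge_u[pp, ] - g_pp$ga
        ge_u[pm, ] <- ge_u[pm, ] + g_pm$ga
      }
      if (h2 > 0) {
        et <- et + h2
        ge_u[a, ]  <- ge_u[a, ]  + (g_pm$ga - g_n$ga)
        ge_u[pm, ] <- ge_u[pm, ] - g_pm$ga
        ge_u[ng, ] <- ge_u[ng, ] + g_n$ga
      }
    }
    et <- et / (2 * nq)
    ge_u <- ge_u * ((1 - m$lam) / (2 * nq))
  }

  # back through row-wise l2 normalisation: de = (du - u (u . du)) / ||e||
  ge <- ge_u
  if (nq > 0L) {
    nrm <- pmax(sqrt(rowSums(embeddings^2)), 1e-12)
    u <- embeddings / nrm
    ge <- (ge_u - u * rowSums(u * ge_u)) / nrm
  }

  list(value = m$lam * j + (1 - m$lam) * et, J = j, E_t = et,
       grad_logits = gl, grad_embeddings = ge)
}
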