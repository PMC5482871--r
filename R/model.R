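#' Backbone configuration
#'
#' A small convolutional network: a stack of conv blocks (each filter size
#' in \{3, 5, 7\}, a channel count and a stride, followed by ReLU and — for
#' all but the last block — 3x3 stride-2 max pooling), a global mean pool,
#' a fully connected embedding head whose output is l2-normalised for the
#' distance loss, and a linear classifier head producing the class logits.
#' Inputs are centred per image and channel, so a constant image maps to an
#' all-zero input tensor.
#'
#' Weights are Gaussian-initialised. `init = "he"` (the default) scales the
#' sd by `sqrt(2 / fan_in)`, which keeps activations alive in a from-scratch
#' desk-scale net; `init = "fixed"` uses `init_sd` everywhere and
#' `final_init_sd` for the last conv block, the scheme used for large
#' transfer-learned nets.
#'
#' @param input_size square input side (images are resized to this; >= 32).
#' @param conv_blocks list of `c(filter, channels, stride)` triples.
#' @param embedding_dim embedding dimension d (default 64).
#' @param init `"he"` or `"fixed"`.
#' @param init_sd,final_init_sd Gaussian sds for `init = "fixed"`.
#' @return Object of class `backbone_config`.
#' @export
backbone_config <- function(input_size = 64L,
                            conv_blocks = list(c(5, 8, 2),
                                               c(3, 16, 1),
                                               c(3, 32, 1)),
                            embedding_dim = 64L,
                            init = c("he", "fixed"),
                            init_sd = 0.01,
                            final_init_sd = 1e-4) {
  init <- match.arg(init)
  if (input_size < 32L) stop("backbone_config: input_size must be >= 32")
  if (embedding_dim < 2L) stop("backbone_config: embedding_dim must be >= 2")
  for (b in conv_blocks) {
    if (length(b) != 3L || !b[1] %in% c(3, 5, 7)) {
      stop("backbone_config: each conv block is c(filter in {3,5,7}, ",
           "channels, stride)")
    }
  }
  structure(list(input_size = as.integer(input_size),
                 conv_blocks = conv_blocks,
                 embedding_dim = as.integer(embedding_dim),
                 init = init, init_sd = init_sd,
                 final_init_sd = final_init_sd),
            class = "backbone_config")
}

#' Training configuration
#'
#' @param base_lr SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param iterations number of SGD steps (default 5000).
#' @param batch_size mini-batch size (default 32).
#' @param margins a [margin_config] (carries m1, m2 and the loss weight lam).
#' @param per_anchor quadruplets mined per eligible anchor (default 1).
#' @param rng_seed master seed for batching, mining and initialisation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(base_lr = 0.01, momentum = 0.9, iterations = 5000L,
                         batch_size = 32L, margins = margin_config(),
                         per_anchor = 1L, rng_seed = 1L) {
  stopifnot(base_lr > 0, iterations >= 1L, batch_size >= 8L,
            momentum >= 0, momentum < 1, inherits(margins, "margin_config"))
  structure(list(base_lr = base_lr, momentum = momentum,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 margins = margins, per_anchor = as.integer(per_anchor),
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

## ---- im2col convolution / pooling primitives ------------------------------

conv_out_size <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# Gather-index matrix (P x K) into a zero/pad-extended single image plane
# stack of Cin channels; K enumerates (dy, dx, channel), dy fastest.
make_gather_idx <- function(H, W, Cin, k, stride) {
  pad <- k %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  outH <- conv_out_size(H, k, stride, pad)
  outW <- conv_out_size(W, k, stride, pad)
  y0 <- rep((seq_len(outH) - 1L) * stride, times = outW)
  x0 <- rep((seq_len(outW) - 1L) * stride, each = outH)
  P <- outH * outW
  K <- k * k * Cin
  idx <- matrix(0L, P, K)
  col <- 1L
  for (c in seq_len(Cin)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    idx[, col] <- (y0 + dy) + (x0 + dx - 1L) * Hp + (c - 1L) * Hp * Wp
    col <- col + 1L
  }
  # column order above is (dy, dx, c) with dy fastest within dx within c
  # inverse (col2im) map: for each padded position, which (p, k) cells of the
  # im2col matrix read it; 0 marks an empty slot. Lets the backward pass
  # scatter-add with plain gathers instead of grouped sums.
  npad <- Hp * Wp * Cin
  all_t <- as.vector(idx)
  counts <- tabulate(all_t, nbins = npad)
  maxr <- max(counts)
  o <- order(all_t)
  Rmat <- matrix(0L, npad, maxr)
  Rmat[cbind(all_t[o], sequence(counts[counts > 0L]))] <- o
  list(idx = idx, pad = pad, Hp = Hp, Wp = Wp, outH = outH, outW = outW,
       P = P, K = K, H = H, W = W, Cin = Cin, k = k, stride = stride,
       Rmat = Rmat, scatter_cache = new.env(parent = emptyenv()))
}

# Cached per-batch-size scatter index into the flattened (P, K, N) im2col
# gradient (sentinel = one-past-the-end, pointing at an appended zero).
scatter_index <- function(g, N) {
  key <- as.character(N)
  if (is.null(g$scatter_cache[[key]])) {
    npad <- nrow(g$Rmat)
    base <- g$Rmat[rep(seq_len(npad), times = N), , drop = FALSE]
    Rbig <- base + rep((seq_len(N) - 1L) * (g$P * g$K), each = npad)
    Rbig[base == 0L] <- g$P * g$K * N + 1L
    g$scatter_cache[[key]] <- Rbig
  }
  g$scatter_cache[[key]]
}

conv_fwd <- function(X, ly) {
  N <- dim(X)[4]
  g <- ly$geom
  Xp <- array(0, c(g$Hp, g$Wp, g$Cin, N))
  Xp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , ] <- X
  slab <- g$Hp * g$Wp * g$Cin
  full <- rep(as.vector(g$idx), times = N) +
    rep((seq_len(N) - 1L) * slab, each = g$P * g$K)
  vals <- array(Xp[full], dim = c(g$P, g$K, N))
  M <- matrix(aperm(vals, c(1L, 3L, 2L)), g$P * N, g$K)
  OUT <- sweep(M %*% ly$W, 2L, ly$b, "+")
  Y <- aperm(array(OUT, c(g$outH, g$outW, N, ncol(ly$W))), c(1L, 2L, 4L, 3L))
  list(Y = Y, M = M, full = full, N = N)
}

conv_bwd <- function(dY, cache, ly, need_dx = TRUE) {
  g <- ly$geom
  N <- cache$N
  D <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), g$P * N, ncol(ly$W))
  dW <- crossprod(cache$M, D)
  db <- colSums(D)
  if (!need_dx) return(list(dX = NULL, dW = dW, db = db))
  dM <- tcrossprod(D, ly$W)
  dvals <- aperm(array(dM, c(g$P, N, g$K)), c(1L, 3L, 2L))
  Rbig <- scatter_index(g, N)
  dv <- c(as.vector(dvals), 0)
  acc <- dv[Rbig[, 1L]]
  for (j in seq_len(ncol(Rbig))[-1L]) acc <- acc + dv[Rbig[, j]]
  dXp <- array(acc, c(g$Hp, g$Wp, g$Cin, N))
  dX <- dXp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

pool_fwd <- function(X, g) {
  d <- dim(X)
  CN <- d[3] * d[4]
  Xp <- array(-Inf, c(g$Hp, g$Wp, CN))
  Xp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), ] <- X
  slab <- g$Hp * g$Wp
  full <- rep(as.vector(g$idx), times = CN) +
    rep((seq_len(CN) - 1L) * slab, each = g$P * g$K)
  V <- matrix(aperm(array(Xp[full], c(g$P, g$K, CN)), c(1L, 3L, 2L)),
              g$P * CN, g$K)
  mx <- V[, 1L]
  for (j in 2:ncol(V)) mx <- pmax(mx, V[, j])
  arg <- max.col(V, ties.method = "first")
  Y <- array(mx, c(g$outH, g$outW, d[3], d[4]))
  list(Y = Y, arg = arg, full = full, in_dim = d, CN = CN)
}

pool_bwd <- function(dY, cache, g) {
  CN <- cache$CN
  fullA <- array(cache$full, c(g$P, g$K, CN))
  p_vec <- rep(seq_len(g$P), times = CN)
  cn_vec <- rep(seq_len(CN), each = g$P)
  chosen <- fullA[cbind(p_vec, cache$arg, cn_vec)]
  rs <- rowsum(as.vector(dY), chosen)
  dXp <- numeric(g$Hp * g$Wp * CN)
  dXp[as.integer(rownames(rs))] <- rs
  dXp <- array(dXp, c(g$Hp, g$Wp, CN))
  dX <- dXp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , drop = FALSE]
  array(dX, cache$in_dim)
}

## ---- model assembly -------------------------------------------------------

init_weights <- function(K, Co, cfg, is_final) {
  sd <- if (cfg$init == "he") sqrt(2 / K) else {
    if (is_final) cfg$final_init_sd else cfg$init_sd
  }
  matrix(stats::rnorm(K * Co, 0, sd), K, Co)
}

#' Initialise an untrained model
#'
#' @param backbone_cfg a [backbone_config].
#' @param taxonomy a [taxonomy] (fixes the number of classes k).
#' @param rng_seed integer seed for the Gaussian initialisation.
#' @return Object of class `hiercls_model`.
#' @export
init_model <- function(backbone_cfg, taxonomy = default_breakhis_taxonomy(),
                       rng_seed = 1L) {
  stopifnot(inherits(backbone_cfg, "backbone_config"),
            inherits(taxonomy, "taxonomy"))
  k_classes <- taxonomy$k
  nb <- length(backbone_cfg$conv_blocks)
  with_seed(rng_seed, {
    layers <- list()
    H <- backbone_cfg$input_size; W <- H; C <- 3L
    for (i in seq_len(nb)) {
      b <- backbone_cfg$conv_blocks[[i]]
      g <- make_gather_idx(H, W, C, as.integer(b[1]), as.integer(b[2 + 1]))
      ly <- list(type = "conv", geom = g,
                 W = init_weights(g$K, as.integer(b[2]), backbone_cfg,
                                  is_final = (i == nb)),
                 b = numeric(b[2]))
      layers[[length(layers) + 1L]] <- ly
      H <- g$outH; W <- g$outW; C <- as.integer(b[2])
      if (i < nb) {
        pg <- make_gather_idx(H, W, 1L, 3L, 2L)
        layers[[length(layers) + 1L]] <- list(type = "pool", geom = pg)
        H <- pg$outH; W <- pg$outW
      }
    }
    d <- backbone_cfg$embedding_dim
    fc_sd <- function(fan) if (backbone_cfg$init == "he") sqrt(2 / fan) else
      backbone_cfg$init_sd
    model <- list(layers = layers,
                  We = matrix(stats::rnorm(C * d, 0, fc_sd(C)), C, d),
                  be = numeric(d),
                  Wc = matrix(stats::rnorm(d * k_classes, 0, fc_sd(d)),
                              d, k_classes),
                  bc = numeric(k_classes),
                  backbone_cfg = backbone_cfg, taxonomy = taxonomy,
                  feat_dim = C)
    class(model) <- "hiercls_model"
    model
  })
}

# Centre each image per channel (constant image -> all-zero tensor).
center_images <- function(X) {
  d <- dim(X)
  chm <- colMeans(matrix(X, d[1] * d[2], d[3] * d[4]))
  X - rep(chm, each = d[1] * d[2])
}

net_forward <- function(model, X, keep_cache = FALSE) {
  X <- center_images(X)
  caches <- list()
  h <- X
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_fwd(h, ly)
      mask <- cf$Y > 0
      h <- cf$Y * mask
      if (keep_cache) caches[[i]] <- list(conv = cf, mask = mask)
    } else {
      pf <- pool_fwd(h, ly$geom)
      h <- pf$Y
      if (keep_cache) caches[[i]] <- pf
    }
  }
  d <- dim(h)
  Fm <- t(matrix(colMeans(matrix(h, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
  e <- sweep(Fm %*% model$We, 2L, model$be, "+")
  logits <- sweep(e %*% model$Wc, 2L, model$bc, "+")
  list(embeddings_raw = e, embeddings = l2_normalize(e), logits = logits,
       pooled = Fm, last_dim = d, caches = if (keep_cache) caches)
}

net_backward <- function(model, fw, dlogits, de_raw) {
  grads <- list()
  e <- fw$embeddings_raw
  de <- de_raw + tcrossprod(dlogits, model$Wc)
  grads$Wc <- crossprod(e, dlogits); grads$bc <- colSums(dlogits)
  grads$We <- crossprod(fw$pooled, de); grads$be <- colSums(de)
  dF <- tcrossprod(de, model$We)                      # N x C
  d <- fw$last_dim
  dh <- array(rep(t(dF), each = d[1] * d[2]) / (d[1] * d[2]), d)
  grads$layers <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      dh <- dh * fw$caches[[i]]$mask
      # the first layer's input gradient is never used: skip its col2im
      cb <- conv_bwd(dh, fw$caches[[i]]$conv, ly, need_dx = (i > 1L))
      grads$layers[[i]] <- list(dW = cb$dW, db = cb$db)
      dh <- cb$dX
    } else {
      dh <- pool_bwd(dh, fw$caches[[i]], ly$geom)
    }
  }
  grads
}

#' Forward pass: embeddings and logits
#'
#' Runs images through the backbone in inference mode. Images are resized to
#' the model's input size and centred per channel; the returned embeddings
#' are unit-norm rows.
#'
#' @param model a trained or initialised `hiercls_model`.
#' @param images a single `H x W x 3` array or an `H x W x 3 x N` batch, or
#'   a list of `H x W x 3` arrays.
#' @return List with `embeddings` (N x d, unit rows) and `logits` (N x k).
#' @export
forward <- function(model, images) {
  stopifnot(inherits(model, "hiercls_model"))
  if (is.list(images)) {
    images <- simplify2array(images)
  }
  if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  if (length(dim(images)) != 4L || dim(images)[3] != 3L) {
    stop("forward: expected H x W x 3 [x N] RGB input, got dims ",
         paste(dim(images), collapse = "x"))
  }
  s <- model$backbone_cfg$input_size
  if (dim(images)[1] != s || dim(images)[2] != s) {
    images <- simplify2array(lapply(seq_len(dim(images)[4]), function(i) {
      resize_image(images[, , , i], s)
    }))
    if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  }
  fw <- net_forward(model, images, keep_cache = FALSE)
  list(embeddings = fw$embeddings, logits = fw$logits)
}

## ---- SGD training ---------------------------------------------------------

flatten_params <- function(model) {
  ps <- list()
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$type == "conv") {
      ps[[paste0("W", i)]] <- model$layers[[i]]$W
      ps[[paste0("b", i)]] <- model$layers[[i]]$b
    }
  }
  c(ps, list(We = model$We, be = model$be, Wc = model$Wc, bc = model$bc))
}

sgd_update <- function(model, grads, state, lr, mu) {
  upd <- function(name, w, g) {
    v <- mu * state[[name]] - lr * g
    state[[name]] <<- v
    w + v
  }
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$type == "conv") {
      model$layers[[i]]$W <- upd(paste0("W", i), model$layers[[i]]$W,
                                 grads$layers[[i]]$dW)
      model$layers[[i]]$b <- upd(paste0("b", i), model$layers[[i]]$b,
                                 grads$layers[[i]]$db)
    }
  }
  model$We <- upd("We", model$We, grads$We)
  model$be <- upd("be", model$be, grads$be)
  model$Wc <- upd("Wc", model$Wc, grads$Wc)
  model$bc <- upd("bc", model$bc, grads$bc)
  list(model = model, state = state)
}

# Load all images of a manifest into an input-size tensor (H, W, 3, N).
load_image_tensor <- function(m, root, input_size) {
  rec <- m$records
  X <- array(0, c(input_size, input_size, 3L, nrow(rec)))
  for (i in seq_len(nrow(rec))) {
    p <- rec$path[i]
    fp <- if (file.exists(p)) p else file.path(root, p)
    X[, , , i] <- resize_image(read_image(fp), input_size)
  }
  X
}

#' Train the backbone with the combined loss
#'
#' The training loop of the method: each step draws a quadruplet-feasible
#' mini-batch, runs a single shared-parameter forward pass, mines quadruplet
#' index tuples from the batch labels, evaluates the combined softmax +
#' distance-constraint loss, and applies an SGD-with-momentum update.
#' After each epoch (one nominal pass over the training split) the model is
#' scored on the validation split at the image level and the best-scoring
#' checkpoint is kept. Batches with no valid quadruplet fall back to the
#' softmax-only objective for that step. Fully seeded; a non-finite loss
#' aborts with a diagnostic naming the step.
#'
#' @param manifest a [manifest] with `train` and `val` splits assigned.
#' @param backbone_cfg a [backbone_config].
#' @param train_cfg a [train_config].
#' @param taxonomy a [taxonomy]; defaults to the manifest's.
#' @param root directory manifest paths are relative to.
#' @param verbose print per-epoch progress.
#' @return Object of class `trained_model`: the best-validation parameters
#'   plus `log` (per-step `step, J, E_t, E, lr, n_quads`) and checkpoint
#'   metadata (`best_epoch`, `best_val_rate`).
#' @export
train <- function(manifest, backbone_cfg = backbone_config(),
                  train_cfg = train_config(),
                  taxonomy = manifest$taxonomy, root = ".",
                  verbose = FALSE) {
  stopifnot(inherits(manifest, "manifest"))
  tr_m <- manifest_split(manifest, "train")
  va_m <- manifest_split(manifest, "val")
  labs <- subclasses(taxonomy)
  tr_lab_chr <- tr_m$records$subclass
  tr_lab <- match(tr_lab_chr, labs)
  va_lab <- match(va_m$records$subclass, labs)

  Xtr <- load_image_tensor(tr_m, root, backbone_cfg$input_size)
  Xva <- load_image_tensor(va_m, root, backbone_cfg$input_size)

  model <- init_model(backbone_cfg, taxonomy,
                      rng_seed = derive_seed(train_cfg$rng_seed, "init"))
  state <- lapply(flatten_params(model), function(p) p * 0)
  mcfg <- train_cfg$margins
  n_tr <- nrow(tr_m$records)
  epoch_len <- max(1L, ceiling(n_tr / train_cfg$batch_size))
  log <- vector("list", train_cfg$iterations)
  best <- list(val_rate = -Inf, epoch = NA_integer_, model = model)

  val_rate <- function(mod) {
    nb <- ceiling(nrow(va_m$records) / 64)
    correct <- 0L
    for (b in seq_len(nb)) {
      ix <- ((b - 1L) * 64L + 1L):min(b * 64L, nrow(va_m$records))
      fw <- net_forward(mod, Xva[, , , ix, drop = FALSE])
      correct <- correct + sum(max.col(fw$logits, "first") == va_lab[ix])
    }
    correct / nrow(va_m$records)
  }

  for (step in seq_len(train_cfg$iterations)) {
    bidx <- hierarchy_balanced_batch(
      tr_m, taxonomy, batch_size = min(train_cfg$batch_size, n_tr),
      rng_seed = derive_seed(train_cfg$rng_seed, paste0("batch", step)))
    fw <- net_forward(model, Xtr[, , , bidx, drop = FALSE], keep_cache = TRUE)
    quads <- suppressWarnings(mine_quadruplets(
      tr_lab_chr[bidx], taxonomy, per_anchor = train_cfg$per_anchor,
      rng_seed = derive_seed(train_cfg$rng_seed, paste0("mine", step))))
    lg <- combined_loss_grad(fw$logits, tr_lab[bidx], fw$embeddings_raw,
                             quads, mcfg)
    if (!is.finite(lg$value)) {
      stop("train: non-finite loss at step ", step, " (J=", lg$J,
           ", E_t=", lg$E_t, "); reduce base_lr or check inputs")
    }
    grads <- net_backward(model, fw, lg$grad_logits, lg$grad_embeddings)
    up <- sgd_update(model, grads, state, train_cfg$base_lr,
                     train_cfg$momentum)
    model <- up$model; state <- up$state
    log[[step]] <- data.frame(step = step, J = lg$J, E_t = lg$E_t,
                              E = lg$value, lr = train_cfg$base_lr,
                              n_quads = nrow(quads))
    if (step %% epoch_len == 0L || step == train_cfg$iterations) {
      vr <- val_rate(model)
      if (vr >= best$val_rate) {
        best <- list(val_rate = vr, epoch = step %/% epoch_len, model = model)
      }
      if (verbose) {
        message(sprintf("epoch %d (step %d): E=%.4f val=%.3f",
                        step %/% epoch_len, step, lg$value, vr))
      }
    }
  }

  out <- best$model
  out$log <- do.call(rbind, log)
  out$best_epoch <- best$epoch
  out$best_val_rate <- best$val_rate
  out$train_cfg <- train_cfg
  class(out) <- c("trained_model", "hiercls_model")
  out
}

#' Evaluate a model on one split of a manifest
#'
#' Argmax-of-logits predictions for every image of the split, wrapped into a
#' [prediction_set] and a [metrics_report] (patient-level and image-level
#' rates, confusion matrix, per-magnification breakdown). Deterministic.
#'
#' @param model a `trained_model` (or any `hiercls_model`).
#' @param manifest a [manifest] with split assignments.
#' @param split which split to score (default "test").
#' @param root directory manifest paths are relative to.
#' @return List with `predictions` and `report`.
#' @export
evaluate <- function(model, manifest, split = "test", root = ".") {
  stopifnot(inherits(model, "hiercls_model"))
  sm <- manifest_split(manifest, split)
  labs <- subclasses(model$taxonomy)
  X <- load_image_tensor(sm, root, model$backbone_cfg$input_size)
  n <- nrow(sm$records)
  pred <- integer(n)
  for (b in seq_len(ceiling(n / 64))) {
    ix <- ((b - 1L) * 64L + 1L):min(b * 64L, n)
    fw <- net_forward(model, X[, , , ix, drop = FALSE])
    pred[ix] <- max.col(fw$logits, "first")
  }
  preds <- prediction_set(sm$records$patient_id, sm$records$subclass,
                          labs[pred], sm$records$magnification,
                          taxonomy = model$taxonomy)
  list(predictions = preds, report = metrics_report(preds, model$taxonomy))
}

#' Margin statistics of a model on a split
#'
#' Mines quadruplets from a split, embeds its images, and reports the mean
#' embedding distance per hierarchy tier together with the fraction of
#' quadruplets satisfying the strict tiered constraint — the direct check
#' that training produced the intended feature-space structure.
#'
#' @param model a `hiercls_model`.
#' @param manifest a [manifest] with splits.
#' @param split split name (default "test").
#' @param margins a [margin_config].
#' @param root manifest path root.
#' @param per_anchor quadruplets per eligible anchor.
#' @param rng_seed mining seed.
#' @return List with `mean_d_pos_sub`, `mean_d_pos_super`, `mean_d_neg`,
#'   `satisfied_fraction`, `n_quads`.
#' @export
quadruplet_margin_stats <- function(model, manifest, split = "test",
                                    margins = margin_config(), root = ".",
                                    per_anchor = 2L, rng_seed = 1L) {
  sm <- manifest_split(manifest, split)
  X <- load_image_tensor(sm, root, model$backbone_cfg$input_size)
  n <- nrow(sm$records)
  U <- matrix(0, n, model$backbone_cfg$embedding_dim)
  for (b in seq_len(ceiling(n / 64))) {
    ix <- ((b - 1L) * 64L + 1L):min(b * 64L, n)
    fw <- net_forward(model, X[, , , ix, drop = FALSE])
    U[ix, ] <- fw$embeddings
  }
  quads <- mine_quadruplets(sm$records$subclass, model$taxonomy,
                            per_anchor = per_anchor, rng_seed = rng_seed)
  if (!nrow(quads)) stop("quadruplet_margin_stats: no quadruplets minable")
  dpp <- dpm <- dn <- numeric(nrow(quads))
  for (i in seq_len(nrow(quads))) {
    dpp[i] <- euclidean_distance(U[quads[i, 1], ], U[quads[i, 2], ])
    dpm[i] <- euclidean_distance(U[quads[i, 1], ], U[quads[i, 3], ])
    dn[i] <- euclidean_distance(U[quads[i, 1], ], U[quads[i, 4], ])
  }
  ok <- (dpp + margins$m1 < dpm + margins$m2) & (dpm + margins$m2 < dn)
  list(mean_d_pos_sub = mean(dpp), mean_d_pos_super = mean(dpm),
       mean_d_neg = mean(dn), satisfied_fraction = mean(ok),
       n_quads = nrow(quads))
}

#' Save / load a model checkpoint
#'
#' Single-file container holding parameters, configs, the taxonomy and the
#' training log.
#'
#' @param model a `trained_model`.
#' @param path checkpoint file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "hiercls_model"))
  # drop transient per-batch scatter caches from the serialised object
  for (i in seq_along(model$layers)) {
    if (!is.null(model$layers[[i]]$geom$scatter_cache)) {
      model$layers[[i]]$geom$scatter_cache <- new.env(parent = emptyenv())
    }
  }
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hiercls_model")) {
    stop("load_checkpoint: not a hiercls checkpoint: ", path)
  }
  model
}
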