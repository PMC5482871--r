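test_that("softmax probabilities: closed forms and independent oracle", {
  expect_equal(softmax_probabilities(rep(0, 8)), rep(1 / 8, 8))
  expect_equal(softmax_probabilities(c(log(1), log(3))), c(0.25, 0.75))
  set.seed(11)
  z <- stats::rnorm(8, sd = 3)
  oracle <- exp(z) / sum(exp(z))     # literal definition, no max-subtraction
  expect_equal(softmax_probabilities(z), oracle, tolerance = 1e-12)
  # matrix rows behave like vectors
  zm <- matrix(stats::rnorm(24), 3, 8)
  pm <- softmax_probabilities(zm)
  expect_equal(rowSums(pm), rep(1, 3), tolerance = 1e-12)
  expect_error(softmax_probabilities(c(1, NaN)), "non-finite")
})

test_that("softmax loss: closed forms, zero limit, brute-force oracle", {
  expect_equal(softmax_loss(matrix(0, 1, 8), 1L), log(8))
  # correct-class probability -> 1: loss -> 0
  big <- matrix(c(50, 0, 0, 0, 50, 0), 2, 3, byrow = TRUE)
  expect_lt(softmax_loss(big, c(1L, 2L)), 1e-12)
  set.seed(21)
  z <- matrix(stats::rnorm(32), 4, 8)
  y <- sample(8L, 4L, replace = TRUE)
  oracle <- -mean(vapply(1:4, function(i) {
    p <- exp(z[i, ]) / sum(exp(z[i, ]))
    log(p[y[i]])
  }, 1))
  expect_equal(softmax_loss(z, y), oracle, tolerance = 1e-12)
  expect_error(softmax_loss(matrix(0, 1, 8), 9L), "1..k")
  expect_error(softmax_loss(matrix(numeric(0), 0, 8), integer(0)), "empty")
})

test_that("euclidean distance: identities and oracle", {
  a <- runit(16)
  expect_equal(euclidean_distance(a, a), 0)
  expect_equal(euclidean_distance(c(1, 0), c(0, 1)), sqrt(2))
  set.seed(31)
  b <- runit(16); c_ <- runit(16)
  expect_equal(euclidean_distance(b, c_), sqrt(sum((b - c_)^2)))
  expect_equal(euclidean_distance(b, c_), euclidean_distance(c_, b))
  expect_error(euclidean_distance(1:3, 1:4), "mismatch")
})

test_that("constraint_satisfied evaluates the strict tiered chain", {
  m <- margin_config(0.2, 0.4)
  expect_true(constraint_satisfied(quad_with_distances(c(0.2, 0.5, 1.0)), m))
  expect_false(constraint_satisfied(quad_with_distances(c(0.9, 0.3, 0.4)), m))
  # degenerate: all four embeddings identical -> all distances 0, m2 > 0
  x <- runit(4)
  q0 <- quadruplet_embeddings(x, x, x, x)
  expect_false(constraint_satisfied(q0, m))
})

test_that("hinge loss: hand cases, empty error, random oracle", {
  m <- margin_config(0.2, 0.4)
  expect_equal(hinge_constraint_loss(quad_with_distances(c(0.2, 0.5, 1.0)), m),
               0)
  expect_equal(hinge_constraint_loss(quad_with_distances(c(0.9, 0.3, 0.4)), m),
               0.35)
  expect_error(hinge_constraint_loss(list(), m), "empty")
  set.seed(41)
  quads <- replicate(50, random_quad(8), simplify = FALSE)
  # independent term-by-term evaluation
  oracle <- local({
    n <- length(quads)
    t1 <- t2 <- 0
    for (q in quads) {
      dpp <- sqrt(sum((q$x - q$p_plus)^2))
      dpm <- sqrt(sum((q$x - q$p_minus)^2))
      dn <- sqrt(sum((q$x - q$n)^2))
      t1 <- t1 + max(0, dpp - dpm + m$m1 - m$m2)
      t2 <- t2 + max(0, dpm - dn + m$m2)
    }
    (t1 + t2) / (2 * n)
  })
  expect_equal(hinge_constraint_loss(quads, m), oracle, tolerance = 1e-10)
})

test_that("hinge loss is rotation invariant and monotone in m1", {
  set.seed(51)
  quads <- replicate(10, random_quad(3), simplify = FALSE)
  # random rotation via QR of a Gaussian matrix
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  rot <- lapply(quads, function(q) {
    quadruplet_embeddings(as.vector(R %*% q$x), as.vector(R %*% q$p_plus),
                          as.vector(R %*% q$p_minus), as.vector(R %*% q$n))
  })
  m <- margin_config(0.2, 0.4)
  expect_equal(hinge_constraint_loss(rot, m), hinge_constraint_loss(quads, m),
               tolerance = 1e-12)
  # raising m1 (m2 fixed) never decreases the loss
  vals <- vapply(c(0, 0.1, 0.2, 0.3), function(m1) {
    hinge_constraint_loss(quads, margin_config(m1, 0.4))
  }, 1)
  expect_true(all(diff(vals) >= -1e-15))
})

test_that("combined loss mixes the components and hits its boundaries", {
  m5 <- margin_config(0.2, 0.4, lam = 0.5)
  # E = lam*J + (1-lam)*E_t against independently computed components
  set.seed(61)
  z <- matrix(stats::rnorm(24), 3, 8)
  y <- c(2L, 5L, 8L)
  quads <- replicate(5, random_quad(8), simplify = FALSE)
  J <- softmax_loss(z, y)
  Et <- hinge_constraint_loss(quads, m5)
  expect_equal(combined_loss(z, y, quads, m5), 0.5 * J + 0.5 * Et)
  m3 <- margin_config(0.2, 0.4, lam = 0.3)
  expect_equal(combined_loss(z, y, quads, m3), 0.3 * J + 0.7 * Et,
               tolerance = 1e-12)
  # lam -> 1 collapses to the softmax loss
  m1 <- margin_config(0.2, 0.4, lam = 1 - 1e-9)
  expect_equal(combined_loss(z, y, quads, m1), J, tolerance = 1e-7)
  # a quadruplet at E_t = 0 with J = 2 gives E = 1 at lam = 0.5
  q0 <- quad_with_distances(c(0.2, 0.5, 1.0))
  z2 <- matrix(c(0, log(exp(2) - 1)), 1, 2)   # -log p(class 1) = 2
  expect_equal(combined_loss(z2, 1L, list(q0), m5), 1, tolerance = 1e-12)
})

test_that("margin and quadruplet constructors reject invalid input", {
  expect_error(margin_config(0.4, 0.2), "m1 < m2")
  expect_error(margin_config(0.2, 0.4, lam = 1.5), "lam")
  expect_error(quadruplet_embeddings(c(1, 0), c(1, 0), c(1, 0), c(2, 0)),
               "unit-norm")
  expect_error(quadruplet_embeddings(c(1, 0), c(1, 0, 0), c(1, 0), c(1, 0)),
               "dimension")
  q <- quadruplet_embeddings(c(3, 4), c(0, 2), c(5, 0), c(0, 1),
                             normalize = TRUE)
  expect_equal(sqrt(sum(q$x^2)), 1, tolerance = 1e-12)
})

test_that("batch-level gradients match central finite differences", {
  set.seed(71)
  m <- margin_config(0.2, 0.4, lam = 0.4)
  N <- 8L; k <- 5L; d <- 6L
  logits <- matrix(stats::rnorm(N * k), N, k)
  labels <- sample(k, N, replace = TRUE)
  emb <- matrix(stats::rnorm(N * d), N, d)
  quads <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  g <- combined_loss_grad(logits, labels, emb, quads, m)
  f <- function(lo, em) combined_loss_grad(lo, labels, em, quads, m)$value
  h <- 1e-5
  num_l <- vapply(seq_along(logits), function(i) {
    a <- logits; b <- logits; a[i] <- a[i] + h; b[i] <- b[i] - h
    (f(a, emb) - f(b, emb)) / (2 * h)
  }, 1)
  num_e <- vapply(seq_along(emb), function(i) {
    a <- emb; b <- emb; a[i] <- a[i] + h; b[i] <- b[i] - h
    (f(logits, a) - f(logits, b)) / (2 * h)
  }, 1)
  expect_lt(max(abs(num_l - as.vector(g$grad_logits))), 1e-6)
  expect_lt(max(abs(num_e - as.vector(g$grad_embeddings))), 1e-6)
  # empty quadruplet set falls back to the lam-weighted softmax term
  g0 <- combined_loss_grad(logits, labels, emb,
                           matrix(integer(0), 0, 4), m)
  expect_equal(g0$value, m$lam * softmax_loss(logits, labels))
  expect_true(all(g0$grad_embeddings == 0))
})
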