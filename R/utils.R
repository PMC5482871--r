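# Run expr under a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Derive a child seed from a base seed and a stream tag; keeps distinct
# pipeline stages decorrelated while staying below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Hamilton largest-remainder apportionment of `total` items proportional to
# `weights`, respecting per-cell integer capacities.
apportion <- function(total, weights, capacity = rep(Inf, length(weights))) {
  stopifnot(total >= 0, all(weights >= 0))
  if (total > sum(capacity)) stop("apportion: total exceeds capacity")
  if (sum(weights) == 0) weights <- rep(1, length(weights))
  ideal <- total * weights / sum(weights)
  out <- pmin(floor(ideal), capacity)
  left <- total - sum(out)
  # distribute remainder by largest fractional part among cells with room
  while (left > 0) {
    room <- which(out < capacity)
    frac <- (ideal - out)[room]
    pick <- room[order(frac, decreasing = TRUE)[seq_len(min(left, length(room)))]]
    out[pick] <- out[pick] + 1
    left <- total - sum(out)
  }
  out
}
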