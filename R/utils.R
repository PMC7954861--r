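# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG afterwards so simulations never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

logistic <- function(x) 1 / (1 + exp(-x))

# 3x3 cross-product matrix [a]x such that [a]x %*% b == a x b
cross_mat <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), nrow = 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vec_norm <- function(x) sqrt(sum(x^2))

# Rowwise Euclidean distances between matrix rows of A (n x 3) and B (m x 3)
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Unit vector along an axis tilted `tilt_deg` degrees from +Y, tilting within
# the X-Y plane (convention: tilt toward +X).
tilted_axis <- function(tilt_deg) {
  th <- tilt_deg * pi / 180
  c(sin(th), cos(th), 0)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(unlist(x)))) {
    stop("non-finite value in ", what, call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal union-find used to split candidate link graphs into components.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}
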