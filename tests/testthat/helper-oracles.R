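# Independent reference implementations used to check the package's
# operations. Each is deliberately written in a different formulation from
# the code under test.

# Hysteresis contact oracle: per-frame conditional recurrence
# (below r_start -> in; above r_end -> out; otherwise carry the last state).
oracle_hysteresis <- function(d, r_start, r_end) {
  out <- logical(length(d))
  prev <- FALSE
  for (t in seq_along(d)) {
    out[t] <- if (d[t] < r_start) TRUE else if (d[t] > r_end) FALSE else prev
    prev <- out[t]
  }
  out
}

# Textbook covariance / (sd * sd) Pearson correlation, two-pass centred.
oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) return(0)
  sum(dx * dy) / sqrt(sxx * syy)
}

# Torsion via arccos of the plane normals, signed by the triple product.
oracle_torsion <- function(p1, p2, p3, p4) {
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- xp(b1, b2); n2 <- xp(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  if (sum(xp(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -180 + 1e-9) ang <- ang + 360
  ang
}

# Stack-based flood fill over the strict upper triangle: returns an integer
# label matrix (0 = background), same-sign 8-connectivity.
oracle_flood_fill <- function(m) {
  n <- nrow(m)
  lab <- matrix(0L, n, n)
  next_lab <- 0L
  for (i0 in seq_len(n - 1L)) {
    for (j0 in (i0 + 1L):n) {
      if (m[i0, j0] == 0 || lab[i0, j0] != 0L) next
      next_lab <- next_lab + 1L
      sgn <- sign(m[i0, j0])
      stack <- list(c(i0, j0))
      while (length(stack) > 0L) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (lab[p[1L], p[2L]] != 0L) next
        lab[p[1L], p[2L]] <- next_lab
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1L] + dr; c <- p[2L] + dc
          if (r >= 1L && c >= 1L && r < c && c <= n &&
              m[r, c] != 0 && sign(m[r, c]) == sgn && lab[r, c] == 0L) {
            stack[[length(stack) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# Random sparse symmetric sign matrix for clustering property tests.
random_sign_matrix <- function(n = 15L, density = 0.15) {
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  on <- sample(ut, size = max(1L, round(density * length(ut))))
  m[on] <- stats::runif(length(on), -1, 1)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Cluster partitions as canonical sets of pixel-key strings, for comparing
# two clusterings independent of label order.
partition_keys <- function(pixel_sets) {
  sort(vapply(pixel_sets, function(px) {
    paste(sort(paste(px$i, px$j, sep = ",")), collapse = ";")
  }, character(1L)))
}
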