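# Independent brute-force oracles. These deliberately avoid the package's
# own primitives (C++ labeling, cor(), vectorized MSD) so that agreement
# is a genuine cross-check.

# connected components by plain R BFS over an explicit neighbour list
oracle_count_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8L) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  n <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    n <- n + 1L
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  n
}

# Pearson r from the raw sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Manders split coefficients at explicit thresholds, by scalar loop
oracle_manders <- function(a, b, t_a, t_b) {
  s_a <- 0; s_a_co <- 0; s_b <- 0; s_b_co <- 0
  for (i in seq_along(a)) {
    s_a <- s_a + a[i]
    s_b <- s_b + b[i]
    if (b[i] > t_b) s_a_co <- s_a_co + a[i]
    if (a[i] > t_a) s_b_co <- s_b_co + b[i]
  }
  c(m1 = s_a_co / s_a, m2 = s_b_co / s_b)
}

# time-averaged MSD by explicit double loop
oracle_msd <- function(x, y, lag) {
  tot <- 0; n <- 0L
  for (t in seq_len(length(x) - lag)) {
    tot <- tot + (x[t + lag] - x[t])^2 + (y[t + lag] - y[t])^2
    n <- n + 1L
  }
  tot / n
}

# mean intensity over a set of linear pixel indices
oracle_mask_mean <- function(img, idx) {
  s <- 0
  for (i in idx) s <- s + img[i]
  s / length(idx)
}
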