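# Independent brute-force oracles, kept deliberately naive (explicit loops,
# no shared code with the implementation).

kl_oracle <- function(p, q, base = 2) {
  p <- unname(p); q <- unname(q)
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i], base = base)
  }
  s
}

levitt_oracle <- function(r, c) {
  if (r > c) return(0)
  x <- (r / c)^2
  1 - 0.5 * (7 * x - 9 * x^2 + 5 * x^3 - x^4)
}

# all-pairs observed profile, one term at a time
observed_oracle <- function(xyz, h, cutoff) {
  n <- nrow(xyz)
  o <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r <= cutoff) o[i] <- o[i] + (h[i] + h[j]) * levitt_oracle(r, cutoff)
    }
  }
  o / sum(o)
}

# per-term Gaussian profile in an already-oriented frame
theoretical_oracle <- function(xyz, sig) {
  n <- nrow(xyz)
  t <- numeric(n)
  for (i in seq_len(n)) {
    t[i] <- exp(-xyz[i, 1]^2 / (2 * sig[1]^2)) *
            exp(-xyz[i, 2]^2 / (2 * sig[2]^2)) *
            exp(-xyz[i, 3]^2 / (2 * sig[3]^2))
  }
  t / sum(t)
}

# exhaustive fine-grid K search
optimize_k_oracle <- function(o, t, k_max = 10, step = 0.001) {
  opp <- (max(t) - t) / sum(max(t) - t)
  best_k <- 0; best <- Inf
  for (k in seq(0, k_max, by = step)) {
    m <- t + k * opp
    m <- m / sum(m)
    d <- kl_oracle(o, m)
    if (d < best) { best <- d; best_k <- k }
  }
  list(k_star = best_k, dkl_om = best)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

rigid_move <- function(records, rot, shift) {
  xyz <- as.matrix(records[, c("x", "y", "z")]) %*% t(rot)
  records$x <- xyz[, 1] + shift[1]
  records$y <- xyz[, 2] + shift[2]
  records$z <- xyz[, 3] + shift[3]
  records
}
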