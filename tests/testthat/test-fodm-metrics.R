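# Frozen hand-computed examples (verified with kl_oracle / direct
# arithmetic before the implementation was written):
#   D_KL((.5,.5) || (.25,.75)) = 1 - log2(3)/2 = 0.2075187496...
#   M(T=(0.5,0.3,0.2), K=1)    = (0.25, 0.35, 0.40)

test_that("KL divergence reproduces hand-computed values", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               1 - log2(3) / 2, tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 0.20751875,
               tolerance = 1e-6)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               kl_oracle(c(0.5, 0.5), c(0.25, 0.75)), tolerance = 1e-12)
  # zero-term convention: 0 * log(0/q) = 0
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1.0)
  # identity
  set.seed(1); p <- runif(10); p <- p / sum(p)
  expect_equal(kl_divergence(p, p), 0)
  expect_gte(kl_divergence(p, rev(p)), 0)
  expect_error(kl_divergence(p, p[1:5]), "mismatch")
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "support")
})

test_that("RD hits its boundary values and flags degeneracy", {
  set.seed(2)
  t <- runif(20); t <- t / sum(t)
  r <- uniform_profile(20)
  expect_equal(rd_value(t, t, r), 0)            # O = T
  expect_equal(rd_value(r, t, r), 1)            # O = R
  d <- rd_value(r, r, r)                        # O = T = R
  expect_equal(unclass(d), 0, ignore_attr = TRUE)
  expect_true(attr(d, "degenerate"))
  o <- runif(20); o <- o / sum(o)
  rd <- rd_value(o, t, r)
  expect_true(rd >= 0 && rd <= 1)
})

test_that("opposite distribution inverts the ordering and normalises", {
  t <- c(0.5, 0.3, 0.2)
  expect_equal(opposite_profile(t), c(0, 0.4, 0.6))
  set.seed(3)
  t2 <- runif(30); t2 <- t2 / sum(t2)
  opp <- opposite_profile(t2)
  expect_equal(sum(opp), 1, tolerance = 1e-12)
  expect_equal(opp[which.max(t2)], 0)
  expect_equal(which.max(opp), which.min(t2))
  expect_equal(cor(t2, opp, method = "spearman"), -1)
  expect_error(opposite_profile(rep(0.25, 4)), "constant")
})

test_that("M profile interpolates between T and the opposite field", {
  t <- c(0.5, 0.3, 0.2)
  expect_identical(m_profile(t, 0), t)            # M(0) = T exactly
  expect_equal(m_profile(t, 1), c(0.25, 0.35, 0.40), tolerance = 1e-12)
  expect_equal(max(abs(m_profile(t, 1e6) - opposite_profile(t))), 0,
               tolerance = 1e-3)                  # K -> Inf limit
  for (k in c(0.3, 1.7, 9))
    expect_equal(sum(m_profile(t, k)), 1, tolerance = 1e-9)
  expect_error(m_profile(t, -0.1), "nonnegative")
})

test_that("K optimisation matches an exhaustive fine-grid oracle", {
  set.seed(4)
  for (case in 1:4) {
    t <- runif(25); t <- t / sum(t)
    w <- runif(1)
    o <- (1 - w) * t + w * opposite_profile(t)    # known-mixture target
    got <- optimize_k(o, t)
    oracle <- optimize_k_oracle(o, t, step = 0.001)
    expect_equal(got$k_star, oracle$k_star, tolerance = 0.01)
    expect_lte(got$dkl_om, oracle$dkl_om + 1e-9)
    expect_lte(got$dkl_om, kl_divergence(o, t) + 1e-12)  # never worse than T
  }
  t <- c(0.5, 0.3, 0.2)
  expect_equal(optimize_k(t, t)$k_star, 0)        # O = T: perfect at K = 0
  # O = opposite: optimum pushed to the domain bound
  expect_equal(optimize_k(opposite_profile(t) * 0.999 + t * 0.001, t,
                          k_max = 10)$k_star, 10, tolerance = 0.02)
})

test_that("RD and K are invariant to the divergence logarithm base", {
  set.seed(5)
  t <- runif(40); t <- t / sum(t)
  o <- runif(40); o <- o / sum(o)
  r <- uniform_profile(40)
  rd_bits <- kl_divergence(o, t) / (kl_divergence(o, t) + kl_divergence(o, r))
  rd_nats <- kl_divergence(o, t, base = exp(1)) /
    (kl_divergence(o, t, base = exp(1)) + kl_divergence(o, r, base = exp(1)))
  expect_equal(rd_bits, rd_nats, tolerance = 1e-12)
  # K: minimiser of the natural-log objective equals the bit objective's
  k_bits <- optimize_k(o, t)$k_star
  obj_nats <- function(k) kl_divergence(o, m_profile(t, k), base = exp(1))
  grid <- seq(0, 10, by = 0.001)
  k_nats <- grid[which.min(vapply(grid, obj_nats, numeric(1)))]
  expect_equal(k_bits, k_nats, tolerance = 0.01)
})

test_that("the K objective is continuous and the refinement never loses", {
  set.seed(6)
  t <- runif(30); t <- t / sum(t)
  o <- runif(30); o <- o / sum(o)
  grid <- seq(0, 10, by = 0.01)
  vals <- vapply(grid, function(k) kl_divergence(o, m_profile(t, k)),
                 numeric(1))
  expect_true(all(abs(diff(vals)) < 0.05))        # no jumps on the scan
  got <- optimize_k(o, t)
  expect_lte(got$dkl_om, min(vals) + 1e-12)
})

test_that("fragment status renormalises complex profiles consistently", {
  fx <- make_fixture("ideal_micelle", n = 80, seed = 10)
  st <- unit_status(fx)
  t_cx <- setNames(st$profiles$T, st$profiles$key)
  o_cx <- setNames(st$profiles$O, st$profiles$key)

  # whole complex as the fragment: identical to the unit status
  whole <- fragment_status(t_cx, o_cx, names(t_cx))
  expect_equal(whole$rd, st$status$rd, tolerance = 1e-12)
  expect_equal(whole$k_star, st$status$k_star, tolerance = 1e-9)

  # direct recomputation of a sliced fragment
  idx <- 11:40
  frag <- fragment_status(t_cx, o_cx, idx)
  t_f <- t_cx[idx] / sum(t_cx[idx]); o_f <- o_cx[idx] / sum(o_cx[idx])
  expect_equal(frag$dkl_ot, kl_oracle(o_f, t_f), tolerance = 1e-12)
  expect_equal(frag$rd, kl_oracle(o_f, t_f) /
                 (kl_oracle(o_f, t_f) + kl_oracle(o_f, uniform_profile(30))),
               tolerance = 1e-12)
  expect_error(fragment_status(t_cx, o_cx, c("Z:1")), "selection")
})

test_that("a mismatch-bearing chain scores worse than a conforming one", {
  # chain A conforming, chain B = chain A with a hydrophobicity-inverted
  # assignment: in the joint cloud, B carries the O-vs-T mismatch
  a <- make_fixture("ideal_micelle", n = 60, seed = 11)
  b <- make_fixture("inverted_micelle", n = 60, seed = 12)
  b$chain <- "B"; b$x <- b$x + 70
  cx <- rbind(a, b)
  class(cx) <- c("fod_residues", "data.frame")
  st_a <- unit_status(cx, unit_selection("A", scope = "complex"))
  st_b <- unit_status(cx, unit_selection("B", scope = "complex"))
  expect_gt(st_b$status$rd, st_a$status$rd)
})

test_that("unit scope and complex scope dispatch coherently", {
  fx <- make_fixture("ideal_micelle", n = 60, seed = 13)
  st_unit <- unit_status(fx, unit_selection("A", scope = "unit"))
  st_cx <- unit_status(fx, unit_selection("A", scope = "complex",
                                          complex_members = "*"))
  # the unit IS the whole complex here: both scopes agree
  expect_equal(st_cx$status$rd, st_unit$status$rd, tolerance = 1e-12)
  expect_error(
    unit_status(make_fixture("engineered_dimer", n = 40, seed = 1),
                unit_selection("A,B", scope = "complex",
                               complex_members = "A")),
    "selection")
})
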