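test_that("elimination is a no-op when RD already meets the threshold", {
  fx <- make_fixture("ideal_micelle", n = 50, seed = 1)
  st <- unit_status(fx)
  el <- eliminate_to_threshold(setNames(st$profiles$T, st$profiles$key),
                               setNames(st$profiles$O, st$profiles$key))
  expect_length(el$eliminated, 0)
  expect_true(el$converged)
  expect_equal(el$status$rd, st$status$rd, tolerance = 1e-12)
})

test_that("a single discrepancy-carrying residue is eliminated first", {
  # 6-residue profile where residue 4 carries the entire O-T discrepancy:
  # O equals T except for a large excess on residue 4
  t <- c(0.30, 0.25, 0.20, 0.10, 0.10, 0.05)
  o <- t
  o[4] <- 0.60
  o[-4] <- t[-4] * (1 - o[4]) / sum(t[-4])
  stopifnot(rd_value(o, t) >= 0.5)
  el <- eliminate_to_threshold(setNames(t, letters[1:6]),
                               setNames(o, letters[1:6]))
  expect_equal(el$eliminated[1], "d")
  expect_true(el$converged)
  expect_lt(el$status$rd, 0.5)

  # self-consistency: recomputing from the surviving residues from scratch
  keep <- match(el$remaining, letters[1:6])
  t_k <- t[keep] / sum(t[keep]); o_k <- o[keep] / sum(o[keep])
  expect_equal(el$status$rd, as.numeric(rd_value(o_k, t_k)),
               tolerance = 1e-12)
})

test_that("ties in discrepancy break toward the lower sequence position", {
  t <- c(0.4, 0.1, 0.1, 0.4)
  o <- c(0.1, 0.4, 0.4, 0.1)       # all |O-T| equal
  el <- eliminate_to_threshold(setNames(t, as.character(1:4)),
                               setNames(o, as.character(1:4)))
  if (length(el$eliminated)) expect_equal(el$eliminated[1], "1")
})

test_that("an unmeetable threshold yields a non-convergence report", {
  # O uniform stays uniform under renormalisation, T peaked: RD pinned at 1
  t <- c(0.9, 0.04, 0.03, 0.02, 0.01)
  o <- rep(0.2, 5)
  el <- eliminate_to_threshold(setNames(t, as.character(1:5)),
                               setNames(o, as.character(1:5)))
  expect_false(el$converged)
  expect_length(el$remaining, 3)
  expect_lte(length(el$eliminated), 5 - 3)   # terminates in <= N - 3 steps
})

test_that("one-shot ranking variant is available and differs only in order", {
  fx <- make_fixture("perturbed_micelle", n = 60, seed = 4)
  st <- unit_status(fx)
  t <- setNames(st$profiles$T, st$profiles$key)
  o <- setNames(st$profiles$O, st$profiles$key)
  el1 <- eliminate_to_threshold(t, o, recompute = TRUE)
  el2 <- eliminate_to_threshold(t, o, recompute = FALSE)
  expect_true(el1$converged && el2$converged)
  expect_lt(el2$status$rd, 0.5)
  expect_equal(el1$eliminated[1], el2$eliminated[1])  # same initial argmax
})

test_that("excess/deficit segmentation finds constructed perturbations", {
  n <- 40
  t <- rep(1 / n, n)
  o <- t
  expect_equal(nrow(excess_deficit_segments(t, o)), 0)   # O = T: no segments

  tol <- 1 / (4 * n)
  o2 <- t; o2[10:20] <- o2[10:20] + 3 * tol
  seg <- excess_deficit_segments(t, o2, tol = tol)
  seg_ex <- seg[seg$label == "excess", ]
  expect_equal(nrow(seg_ex), 1)
  expect_equal(c(seg_ex$start, seg_ex$end), c(10, 20))

  # labels only where |O - T| > tol; segments disjoint and ordered
  lab <- attr(seg, "residue_labels")
  flagged <- which(!is.na(lab))
  expect_true(all(abs(o2 - t)[flagged] > tol))
  if (nrow(seg) > 1) expect_true(all(diff(seg$start) > 0))
  expect_true(all(seg$end >= seg$start))

  # deficit side, default tolerance = 1/(4N)
  o3 <- t; o3[5:9] <- o3[5:9] - 2 * tol; o3 <- o3 / sum(o3)
  seg3 <- excess_deficit_segments(t, o3)
  expect_true(any(seg3$label == "deficit" & seg3$start <= 5 & seg3$end >= 9))
  expect_true(all(seg3$length >= 3))
})

test_that("layer classification applies the threshold rules disjointly", {
  t <- c(0.0005, 0.0020, 0.0020, 0.0012, 0.0005)
  o <- c(0.0004, 0.0030, 0.0005, 0.0012, 0.0020)
  lay <- classify_layers(t, o)
  expect_equal(lay$label,
               c("surface_polar", "subsurface_conforming", "core_deficit",
                 NA, NA))
  # uniform profiles inside the (t_low, t_high) gap: nothing labelled
  u <- rep(1 / 800, 800)
  expect_true(all(is.na(classify_layers(u, u)$label)))
  expect_error(classify_layers(t, o, t_low = 0.002, t_high = 0.001),
               "config")
  # predicates are mutually exclusive by construction
  labs <- classify_layers(runif(50) / 25, runif(50) / 25)$label
  expect_true(all(table(labs) >= 0))  # each residue got at most one label
})

test_that("interface extraction finds the engineered contact and only it", {
  d <- make_fixture("engineered_dimer", n = 60, seed = 3)
  path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(d, path)
  model <- read_structure(path)
  contact <- attr(d, "contact")

  ir <- interface_residues(model, "A", "B", contact_cutoff = 5)
  expect_equal(ir, contact[1])
  ir_b <- interface_residues(model, "B", "A", contact_cutoff = 5)
  expect_equal(ir_b, contact[2])

  # effective-atom basis coincides here (single-atom residues), and the
  # heavy-atom set always contains the effective-atom set
  ir_eff <- interface_residues(model, "A", "B", 5, basis = "effective_atom")
  expect_true(all(ir_eff %in% ir))

  # monotone nondecreasing in the cutoff
  sizes <- vapply(c(4, 5, 8, 20, 60),
                  function(cc) length(interface_residues(model, "A", "B",
                                                         cc)), numeric(1))
  expect_true(all(diff(sizes) >= 0))

  # far-apart chains: empty set at small cutoff
  expect_length(interface_residues(model, "A:1-5", "B:1-5", 5), 0)
  expect_error(interface_residues(model, "A", "A"), "overlap")
})

test_that("interface status partitions a chain into P-P and the rest", {
  d <- make_fixture("engineered_dimer", n = 80, seed = 5)
  st <- unit_status(d, unit_selection("A", scope = "complex"))
  t_p <- setNames(st$profiles$T, st$profiles$key)
  o_p <- setNames(st$profiles$O, st$profiles$key)
  iface <- names(t_p)[1:10]

  # interface = whole chain: equals the chain's own fragment status
  whole <- interface_status(t_p, o_p, names(t_p))
  expect_equal(whole$rd, fragment_status(t_p, o_p, names(t_p))$rd)

  pp <- interface_status(t_p, o_p, iface)
  nopp <- interface_status(t_p, o_p, iface, complement = TRUE)
  expect_equal(pp$n + nopp$n, length(t_p))        # disjoint partition
  direct <- fragment_status(t_p, o_p, setdiff(names(t_p), iface))
  expect_equal(nopp$rd, direct$rd, tolerance = 1e-12)
  expect_error(interface_status(t_p, o_p, character(0)), "empty")
})

test_that("segmentation and layer operations are pure and repeatable", {
  fx <- make_fixture("perturbed_micelle", n = 60, seed = 6)
  st <- unit_status(fx)
  t <- setNames(st$profiles$T, st$profiles$key)
  o <- setNames(st$profiles$O, st$profiles$key)
  expect_identical(excess_deficit_segments(t, o),
                   excess_deficit_segments(t, o))
  expect_identical(classify_layers(t, o), classify_layers(t, o))
})
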