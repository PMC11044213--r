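#' Orient a structural unit into its principal frame
#'
#' Centres the effective-atom cloud at its centroid and rotates it onto its
#' principal axes, ordered by descending extent (x is the longest axis).
#' Axis signs are fixed deterministically: for the first two axes the residue
#' of largest absolute coordinate gets a positive coordinate; the third axis
#' sign is then chosen to keep the rotation proper (det = +1), preserving
#' handedness.
#'
#' @param records A `fod_residues` table with >= 3 non-collinear residues.
#' @return List with `records` (coordinates replaced by principal-frame
#'   coordinates) and `envelope`, a `gaussian_envelope`: `center` (original
#'   frame), `rotation` (3x3, input frame -> principal frame), `sigmas`
#'   (named sx/sy/sz, Angstrom, from [estimate_sigmas()]).
#' @export
orient_unit <- function(records) {
  xyz <- as.matrix(records[, c("x", "y", "z")])
  if (nrow(xyz) < 3L) stop("geometry error: need >= 3 residues to orient")
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  rot <- ev$vectors                       # columns: principal axes, desc. var
  proj <- xc %*% rot
  for (a in 1:2) {
    s <- sign(proj[which.max(abs(proj[, a])), a])
    if (s < 0) { rot[, a] <- -rot[, a]; proj[, a] <- -proj[, a] }
  }
  if (det(rot) < 0) { rot[, 3] <- -rot[, 3]; proj[, 3] <- -proj[, 3] }
  sig <- estimate_sigmas(proj)
  records$x <- proj[, 1]; records$y <- proj[, 2]; records$z <- proj[, 3]
  env <- structure(list(center = ctr, rotation = rot, sigmas = sig),
                   class = "gaussian_envelope")
  list(records = records, envelope = env)
}

#' Gaussian envelope widths from an oriented point cloud
#'
#' Per axis, sigma is the maximum absolute coordinate divided by 3 (the
#' three-sigma rule: the molecular boundary sits where ~99.7% of the Gaussian
#' mass is enclosed).
#'
#' @param oriented An n x 3 coordinate matrix in the principal frame (or a
#'   `fod_residues` table already oriented).
#' @return Named numeric `c(sx, sy, sz)`, all strictly positive.
#' @export
estimate_sigmas <- function(oriented) {
  if (is.data.frame(oriented))
    oriented <- as.matrix(oriented[, c("x", "y", "z")])
  ext <- apply(abs(oriented), 2, max)
  if (any(ext <= 0))
    stop("geometry error: zero extent along axis ",
         paste(c("x", "y", "z")[ext <= 0], collapse = ","))
  stats::setNames(ext / 3, c("sx", "sy", "sz"))
}

# shared guard for profile inputs
check_profile_pair <- function(p, q) {
  if (length(p) != length(q)) stop("profile length mismatch")
}

normalize_profile <- function(v) {
  s <- sum(v)
  if (s <= 0) stop("degenerate profile: nonpositive sum")
  v / s
}

#' Theoretical hydrophobicity profile (T)
#'
#' The idealised micelle-like distribution: the value of the 3D Gaussian
#' envelope at each effective atom, normalised to sum 1. The unit is oriented
#' internally, so T is invariant to rigid-body motion of the input.
#'
#' @param records `fod_residues` to profile, in the same coordinate frame
#'   the envelope was fitted in (the original input frame; the envelope's
#'   centring and rotation are applied here).
#' @param envelope Optional: a `gaussian_envelope` from an enclosing complex
#'   (its centre/rotation/sigmas are used and `records` may be any subset of
#'   that complex). Default `NULL` fits the envelope to `records` itself.
#' @return Named numeric profile (names `chain:resno` keys), sum 1, all
#'   values > 0.
#' @export
theoretical_profile <- function(records, envelope = NULL) {
  if (is.null(envelope)) {
    o <- orient_unit(records)
    records <- o$records
    envelope <- o$envelope
  } else {
    xyz <- sweep(as.matrix(records[, c("x", "y", "z")]), 2, envelope$center)
    proj <- xyz %*% envelope$rotation
    records$x <- proj[, 1]; records$y <- proj[, 2]; records$z <- proj[, 3]
  }
  s <- envelope$sigmas
  t_raw <- exp(-records$x^2 / (2 * s[[1]]^2)) *
           exp(-records$y^2 / (2 * s[[2]]^2)) *
           exp(-records$z^2 / (2 * s[[3]]^2))
  stats::setNames(normalize_profile(t_raw), residue_keys(records))
}

residue_keys <- function(records)
  paste0(records$chain, ":", records$resno,
         ifelse(records$ins == "" | is.na(records$ins), "", records$ins))

#' Observed hydrophobicity profile (O)
#'
#' Collected hydrophobicity of each residue from pairwise interactions with
#' its neighbours within `cutoff`, using Levitt's polynomial contact
#' function:
#' \deqn{\tilde O_i = \sum_{j: r_{ij} \le c} (H_i + H_j)\,
#'   \left[1 - \tfrac12\left(7\rho^2 - 9\rho^4 + 5\rho^6 - \rho^8\right)\right],
#'   \quad \rho = r_{ij}/c,}
#' including the self term (j = i, weight 1), then normalised to sum 1.
#'
#' @param records `fod_residues` with `h` assigned
#'   (see [assign_hydrophobicity()]).
#' @param cutoff Interaction cutoff c in Angstrom (default 9).
#' @return Named numeric profile, sum 1.
#' @export
observed_profile <- function(records, cutoff = 9) {
  if (anyNA(records$h))
    stop("intrinsic hydrophobicity not assigned; call assign_hydrophobicity()")
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- as.matrix(records[, c("x", "y", "z")])
  h <- records$h
  d <- as.matrix(stats::dist(xyz))
  w <- levitt_weight(d, cutoff)
  # sum_j (H_i + H_j) w_ij  =  H_i * sum_j w_ij + sum_j H_j w_ij
  o_raw <- h * rowSums(w) + as.vector(w %*% h)
  if (sum(o_raw) <= 0)
    stop("degenerate scale: observed profile sums to zero")
  stats::setNames(o_raw / sum(o_raw), residue_keys(records))
}

#' Levitt contact weight
#'
#' @param r Distance(s), Angstrom. @param cutoff Cutoff c, Angstrom.
#' @return Weight in \[0, 1\]; 1 at r = 0, 0 at r >= c.
#' @keywords internal
levitt_weight <- function(r, cutoff) {
  rho2 <- (r / cutoff)^2
  w <- 1 - 0.5 * (7 * rho2 - 9 * rho2^2 + 5 * rho2^3 - rho2^4)
  w[r > cutoff] <- 0
  w
}

#' Uniform reference profile (R)
#'
#' Every residue carries hydrophobicity 1/N: the structureless reference a
#' distribution is compared against when computing RD.
#'
#' @param n Residue count (>= 1), or a `fod_residues` table / named profile
#'   whose length and names are reused.
#' @return Numeric profile of 1/n values.
#' @export
uniform_profile <- function(n) {
  nm <- NULL
  if (is.data.frame(n)) { nm <- residue_keys(n); n <- nrow(n) }
  else if (length(n) > 1L || !is.null(names(n))) { nm <- names(n); n <- length(n) }
  if (n < 1) stop("empty unit: n must be >= 1")
  stats::setNames(rep(1 / n, n), nm)
}
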