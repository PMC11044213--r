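#' Greedy residue elimination to reach a target RD
#'
#' Repeatedly removes the residue with the largest discrepancy
#' \eqn{|O_i - T_i|} (ties broken toward the lower sequence position),
#' renormalises the surviving T and O, rebuilds the uniform reference, and
#' recomputes RD, until RD drops below `rd_threshold`. The surviving moiety
#' is the part of the unit whose hydrophobicity arrangement is micelle-like.
#'
#' @param t,o Normalised profiles of equal length >= 3 (named by residue
#'   keys).
#' @param rd_threshold RD target (default 0.5, the hydrophobic-core
#'   boundary).
#' @param recompute If `TRUE` (default) the discrepancy ranking is refreshed
#'   after every removal; `FALSE` removes residues in the one-shot initial
#'   ranking order (for comparison).
#' @return List: `eliminated` (residue keys in removal order), `status`
#'   (final [fod_status()] of the surviving moiety), `converged` (`FALSE`
#'   when the unit would shrink below 3 residues before crossing the
#'   threshold -- reported, not an error), `remaining` (surviving keys).
#' @export
eliminate_to_threshold <- function(t, o, rd_threshold = 0.5,
                                   recompute = TRUE) {
  check_profile_pair(t, o)
  if (length(t) < 3L) stop("need >= 3 residues")
  if (is.null(names(t))) names(t) <- names(o) <- as.character(seq_along(t))
  rank0 <- order(-abs(o - t), seq_along(t))   # one-shot ranking
  eliminated <- character(0)
  t_c <- t; o_c <- o
  repeat {
    rd <- rd_value(o_c, t_c)
    if (rd < rd_threshold)
      return(list(eliminated = eliminated,
                  status = fod_status(o_c, t_c),
                  converged = TRUE, remaining = names(t_c)))
    if (length(t_c) <= 3L)
      return(list(eliminated = eliminated,
                  status = fod_status(o_c, t_c),
                  converged = FALSE, remaining = names(t_c)))
    drop <- if (recompute) {
      which.max(abs(o_c - t_c))           # which.max: first max = lower pos
    } else {
      match(names(t)[rank0[length(eliminated) + 1L]], names(t_c))
    }
    eliminated <- c(eliminated, names(t_c)[drop])
    t_c <- normalize_profile(t_c[-drop])
    o_c <- normalize_profile(o_c[-drop])
  }
}

#' Local hydrophobicity excess / deficit segments
#'
#' Labels residue i `excess` when \eqn{O_i - T_i >} `tol` (more collected
#' hydrophobicity than the micelle ideal expects there, typical of
#' complexation surfaces) and `deficit` when \eqn{T_i - O_i >} `tol`
#' (typical of cavities and active sites), then reports maximal runs of
#' identically labelled consecutive residues of length >= `min_len`.
#'
#' @param t,o Normalised profiles of equal length.
#' @param min_len Minimum segment length (default 3).
#' @param tol Discrepancy tolerance; default `1/(4 * N)`, a quarter of the
#'   uniform level, scale-free in profile units.
#' @return Data frame of segments: `label`, `start`, `end` (1-based residue
#'   indices within the unit), `start_key`, `end_key`, `length`,
#'   `mean_discrepancy`. Attribute `residue_labels` holds the per-residue
#'   label vector (`"excess"`, `"deficit"` or `NA`).
#' @export
excess_deficit_segments <- function(t, o, min_len = 3, tol = NULL) {
  check_profile_pair(t, o)
  n <- length(t)
  if (is.null(tol)) tol <- 1 / (4 * n)
  d <- o - t
  lab <- rep(NA_character_, n)
  lab[d > tol] <- "excess"
  lab[-d > tol] <- "deficit"
  runs <- rle(ifelse(is.na(lab), "none", lab))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != "none" & runs$lengths >= min_len
  keys <- if (is.null(names(t))) as.character(seq_len(n)) else names(t)
  seg <- data.frame(
    label = runs$values[keep],
    start = starts[keep], end = ends[keep],
    start_key = keys[starts[keep]], end_key = keys[ends[keep]],
    length = runs$lengths[keep],
    mean_discrepancy = vapply(which(keep), function(i)
      mean(d[starts[i]:ends[i]]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(seg) <- NULL
  attr(seg, "residue_labels") <- stats::setNames(lab, keys)
  attr(seg, "tol") <- tol
  seg
}

#' Classify residues into structural layers by profile thresholds
#'
#' Applies fixed thresholds on the normalised complex-wide profiles:
#' \describe{
#'   \item{`surface_polar`}{\eqn{T_i < t_{low}} and \eqn{O_i < t_{low}}:
#'     polar residues exposed on the surface, as the model expects.}
#'   \item{`subsurface_conforming`}{\eqn{T_i > t_{high}} and
#'     \eqn{O_i > t_{high}}: a subsurface layer whose hydrophobicity matches
#'     expectation.}
#'   \item{`core_deficit`}{\eqn{T_i > t_{high}} and \eqn{O_i < t_{high}}:
#'     expected core hydrophobicity missing, e.g. a polar inner chamber
#'     wall.}
#' }
#' Residues matching none of the predicates are unlabelled. The label sets
#' are pairwise disjoint by construction.
#'
#' @param t,o Normalised profiles of equal length.
#' @param t_low,t_high Thresholds on normalised profile values (defaults
#'   0.001 and 0.0015).
#' @return Data frame: `key`, `T`, `O`, `label` (`NA` when unlabelled).
#' @export
classify_layers <- function(t, o, t_low = 0.001, t_high = 0.0015) {
  check_profile_pair(t, o)
  if (t_low > t_high) stop("config error: t_low > t_high")
  lab <- rep(NA_character_, length(t))
  lab[t < t_low & o < t_low] <- "surface_polar"
  lab[t > t_high & o > t_high] <- "subsurface_conforming"
  lab[t > t_high & o < t_high] <- "core_deficit"
  keys <- if (is.null(names(t))) as.character(seq_along(t)) else names(t)
  data.frame(key = keys, T = unname(t), O = unname(o), label = lab,
             stringsAsFactors = FALSE)
}

#' Residues of one unit in contact with another
#'
#' A residue of `unitA` belongs to the interface when any of its atoms
#' (heavy atoms, or the single effective atom, per `basis`) lies within
#' `contact_cutoff` of any such atom of `unitB`.
#'
#' @param model A `fod_structure`.
#' @param unitA,unitB Disjoint residue selections (strings or indices, see
#'   [select_residues()]).
#' @param contact_cutoff Distance cutoff in Angstrom (default 5).
#' @param basis `"heavy_atom"` (default) or `"effective_atom"`.
#' @return Character vector of residue keys (`chain:resno`) of `unitA` at
#'   the interface, in deposited order.
#' @export
interface_residues <- function(model, unitA, unitB, contact_cutoff = 5,
                               basis = c("heavy_atom", "effective_atom")) {
  basis <- match.arg(basis)
  stopifnot(inherits(model, "fod_structure"))
  res <- effective_atoms(model)
  ra <- select_residues(res, unitA)
  rb <- select_residues(res, unitB)
  ka <- residue_keys(ra); kb <- residue_keys(rb)
  if (length(intersect(ka, kb)))
    stop("selection error: units overlap")
  if (basis == "effective_atom") {
    xa <- as.matrix(ra[, c("x", "y", "z")]); ia <- seq_along(ka)
    xb <- as.matrix(rb[, c("x", "y", "z")])
  } else {
    at <- model$atoms[!(model$atoms$element %in% c("H", "D")), , drop = FALSE]
    kat <- paste0(at$chain, ":", at$resno, ifelse(at$ins == "", "", at$ins))
    aa <- at[kat %in% ka, , drop = FALSE]
    ab <- at[kat %in% kb, , drop = FALSE]
    xa <- as.matrix(aa[, c("x", "y", "z")])
    ia <- match(paste0(aa$chain, ":", aa$resno,
                       ifelse(aa$ins == "", "", aa$ins)), ka)
    xb <- as.matrix(ab[, c("x", "y", "z")])
  }
  # squared-distance test, blocked over A atoms to bound memory
  cut2 <- contact_cutoff^2
  hit <- logical(length(ka))
  bs <- 2048L
  for (s in seq(1L, nrow(xa), by = bs)) {
    e <- min(s + bs - 1L, nrow(xa))
    blk <- xa[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(xb^2), "+") - 2 * blk %*% t(xb)
    close <- rowSums(d2 <= cut2 + 1e-9) > 0
    hit[unique(ia[s:e][close])] <- TRUE
  }
  ka[hit]
}

#' FOD status of an interface (or of its complement)
#'
#' Scores the interface residue set of a chain -- or the part of the chain
#' lacking those residues -- as a fragment of the complex-wide profiles
#' ([fragment_status()]): "P-P" versus "No P-P" status.
#'
#' @param complex_t,complex_o Complex-wide normalised profiles.
#' @param interface Residue keys (or index) of the interface set; must be a
#'   subset of the profile names.
#' @param within Optional residue keys of the chain the complement is taken
#'   within (default: the whole profile).
#' @param complement `FALSE` (default) scores the interface; `TRUE` scores
#'   `within` minus `interface`.
#' @param ... Passed to [fod_status()].
#' @return A `fod_status`.
#' @export
interface_status <- function(complex_t, complex_o, interface,
                             within = names(complex_t), complement = FALSE,
                             ...) {
  if (!is.character(interface))
    interface <- names(complex_t)[interface]
  keys <- if (complement) setdiff(within, interface) else interface
  if (!length(keys)) stop("empty residue set")
  fragment_status(complex_t, complex_o, keys, ...)
}
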