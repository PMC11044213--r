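#' Kullback-Leibler divergence between hydrophobicity profiles
#'
#' \eqn{D_{KL}(P\|Q) = \sum_i P_i \log_2 (P_i / Q_i)}, in bits by default.
#' Terms with \eqn{P_i = 0} contribute 0; \eqn{P_i > 0} with \eqn{Q_i = 0}
#' is a support error. The RD statistic and the optimal K are invariant to
#' the logarithm base (it cancels in the ratio / is a monotone rescaling of
#' the objective), so the base only affects reported divergences.
#'
#' @param p Analysed profile (normalised; the observed O in this model).
#' @param q Reference profile (normalised; T, R or M).
#' @param base Logarithm base (default 2, bits).
#' @return Nonnegative scalar divergence.
#' @export
kl_divergence <- function(p, q, base = 2) {
  check_profile_pair(p, q)
  pos <- p > 0
  if (any(q[pos] == 0))
    stop("support error: P > 0 where Q = 0")
  sum(p[pos] * log(p[pos] / q[pos], base = base))
}

#' Relative distance of the observed profile between T and R
#'
#' \eqn{RD = D_{KL}(O\|T) / (D_{KL}(O\|T) + D_{KL}(O\|R))}. RD < 0.5 means
#' the observed distribution is closer to the micelle-like Gaussian ideal
#' than to the structureless uniform reference, i.e. the unit has a
#' hydrophobic core.
#'
#' @param o,t,r Normalised profiles of equal length (see
#'   [observed_profile()], [theoretical_profile()], [uniform_profile()]).
#' @return Scalar in \[0, 1\]. In the degenerate case O = T = R the value is
#'   defined as 0 and carries attribute `degenerate = TRUE`.
#' @export
rd_value <- function(o, t, r = uniform_profile(length(o))) {
  check_profile_pair(o, t); check_profile_pair(o, r)
  d_ot <- kl_divergence(o, t)
  d_or <- kl_divergence(o, r)
  if (d_ot + d_or == 0)
    return(structure(0, degenerate = TRUE))
  d_ot / (d_ot + d_or)
}

#' Opposite (complementary) hydrophobicity distribution
#'
#' The idealised pattern of a fully nonpolar milieu: hydrophobicity exposed
#' where the Gaussian field is low. Computed as \eqn{(T_{max} - T_i)},
#' normalised; the residue at the Gaussian maximum gets 0.
#'
#' @param t Normalised theoretical profile, not constant.
#' @return Normalised profile anti-ordered to `t`.
#' @export
opposite_profile <- function(t) {
  v <- max(t) - t
  if (sum(v) == 0)
    stop("degenerate profile: T is constant, opposite distribution undefined")
  v / sum(v)
}

#' Environment-modified reference profile M(K)
#'
#' Mixes the aqueous-ideal T with the nonpolar ideal (the normalised
#' opposite distribution), weighted by the environment parameter K, then
#' renormalises: \eqn{M_i(K) = [T_i + K\,(T_{max}-T_i)_n]_n}. M(0) = T
#' exactly; as K grows M approaches the opposite distribution.
#'
#' @param t Normalised theoretical profile, not constant (unless K = 0).
#' @param k Nonnegative environment weight.
#' @return Normalised profile.
#' @export
m_profile <- function(t, k) {
  if (k < 0) stop("K must be nonnegative")
  if (k == 0) return(t)
  v <- t + k * opposite_profile(t)
  v / sum(v)
}

#' Optimal environment parameter K
#'
#' Finds \eqn{K^* = \arg\min_{K \ge 0} D_{KL}(O \| M(K))}: a grid scan over
#' \[0, `k_max`\] at `step`, refined by golden-section search in the
#' bracketing interval. Since M(0) = T, the minimised divergence never
#' exceeds \eqn{D_{KL}(O\|T)}.
#'
#' @param o,t Normalised profiles of equal length; `t` not constant.
#' @param k_max Upper bound of the search domain (default 10; the largest
#'   K observed for chaperonin systems is below 7).
#' @param step Grid step (default 0.01).
#' @return List: `k_star` (the optimum), `dkl_om` (divergence at the
#'   optimum).
#' @export
optimize_k <- function(o, t, k_max = 10, step = 0.01) {
  check_profile_pair(o, t)
  opp <- opposite_profile(t)          # validates non-constant t
  obj <- function(k) {
    m <- if (k == 0) t else { v <- t + k * opp; v / sum(v) }
    kl_divergence(o, m)
  }
  grid <- seq(0, k_max, by = step)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  ref <- stats::optimize(obj, c(lo, hi), tol = 1e-8)
  if (ref$objective <= vals[i]) {
    k_star <- ref$minimum; dkl <- ref$objective
  } else {
    k_star <- grid[i]; dkl <- vals[i]
  }
  if (k_star < step / 2 && obj(0) <= dkl) { k_star <- 0; dkl <- obj(0) }
  list(k_star = k_star, dkl_om = dkl)
}

#' Full FOD / FOD-M status of one profile pair
#'
#' Bundles the divergences, RD and the fitted environment parameter for a
#' structural unit: \eqn{D_{KL}(O\|T)}, \eqn{D_{KL}(O\|R)}, RD, \eqn{K^*}
#' and \eqn{D_{KL}(O\|M(K^*))}.
#'
#' @param o,t Normalised observed and theoretical profiles.
#' @param scope `"unit"` or `"complex"`, recorded for reporting.
#' @param k_max,step Passed to [optimize_k()].
#' @return A `fod_status` list: `n`, `dkl_ot`, `dkl_or`, `rd`, `k_star`,
#'   `dkl_om`, `scope`, `degenerate`.
#' @export
fod_status <- function(o, t, scope = "unit", k_max = 10, step = 0.01) {
  check_profile_pair(o, t)
  r <- uniform_profile(length(o))
  d_ot <- kl_divergence(o, t)
  d_or <- kl_divergence(o, r)
  degenerate <- (d_ot + d_or == 0)
  rd <- if (degenerate) 0 else d_ot / (d_ot + d_or)
  kk <- if (max(t) == min(t)) list(k_star = 0, dkl_om = d_ot)
        else optimize_k(o, t, k_max = k_max, step = step)
  structure(list(n = length(o), dkl_ot = d_ot, dkl_or = d_or, rd = rd,
                 k_star = kk$k_star, dkl_om = kk$dkl_om, scope = scope,
                 degenerate = degenerate),
            class = "fod_status")
}

#' @export
print.fod_status <- function(x, ...) {
  cat(sprintf(
    "FOD status (%s scope, n = %d)\n  D_KL(O|T) = %.4f  D_KL(O|R) = %.4f bits\n  RD = %.3f   K = %.2f   D_KL(O|M(K)) = %.4f%s\n",
    x$scope, x$n, x$dkl_ot, x$dkl_or, x$rd, x$k_star, x$dkl_om,
    if (isTRUE(x$degenerate)) "   [degenerate: O = T = R]" else ""))
  invisible(x)
}

#' @export
as.data.frame.fod_status <- function(x, ...) {
  data.frame(scope = x$scope, n_residues = x$n, dkl_OT = x$dkl_ot,
             dkl_OR = x$dkl_or, RD = x$rd, K = x$k_star, dkl_OM = x$dkl_om,
             stringsAsFactors = FALSE)
}

#' Status of a fragment carved out of complex-wide profiles
#'
#' Extracts the fragment's T and O values from profiles computed over an
#' enclosing complex, renormalises each to sum 1, rebuilds the uniform
#' reference over the fragment length, and scores RD and K on the
#' renormalised triple. This measures the fragment's contribution to the
#' hydrophobicity distribution of the whole complex.
#'
#' @param complex_t,complex_o Complex-wide normalised profiles (equal
#'   length, computed with the Gaussian spanning the complex).
#' @param fragment Logical/integer index into the complex profiles, or a
#'   character vector of residue keys matching the profile names.
#' @param ... Passed to [fod_status()].
#' @return A `fod_status` with `scope = "complex"`.
#' @export
fragment_status <- function(complex_t, complex_o, fragment, ...) {
  check_profile_pair(complex_t, complex_o)
  if (is.character(fragment)) {
    idx <- match(fragment, names(complex_t))
    if (anyNA(idx))
      stop("selection error: fragment residues not in complex: ",
           paste(fragment[is.na(idx)], collapse = ", "))
  } else {
    idx <- seq_along(complex_t)[fragment]
    if (anyNA(idx) || length(idx) == 0L)
      stop("selection error: fragment index out of range")
  }
  t_f <- normalize_profile(complex_t[idx])
  o_f <- normalize_profile(complex_o[idx])
  fod_status(o_f, t_f, scope = "complex", ...)
}

#' FOD status of a structural unit of a model
#'
#' End-to-end dispatch: resolves the unit selection, computes the profiles
#' under the requested Gaussian scope, and returns the status together with
#' the profiles used.
#'
#' With `scope = "unit"` the envelope, T and O are computed over the unit
#' itself. With `scope = "complex"` they are computed over
#' `complex_members`; the unit's values are then extracted and renormalised
#' ([fragment_status()]).
#'
#' @param model A `fod_structure`, or a `fod_residues` table (already
#'   reduced, with or without hydrophobicities).
#' @param unit A [unit_selection()], or a selection string (scope then
#'   defaults to `"unit"`).
#' @param scale,cutoff,k_max,step Model parameters (see
#'   [assign_hydrophobicity()], [observed_profile()], [optimize_k()]).
#' @return List: `status` (`fod_status`), `profiles` (data.frame with keys,
#'   aa, T, O, R, M at the fitted K, over the unit), `envelope`.
#' @export
unit_status <- function(model, unit = unit_selection("*"),
                        scale = "kyte_doolittle", cutoff = 9,
                        k_max = 10, step = 0.01) {
  if (!inherits(unit, "unit_selection")) unit <- unit_selection(unit)
  res <- if (inherits(model, "fod_structure")) effective_atoms(model) else model
  if (anyNA(res$h)) res <- assign_hydrophobicity(res, scale)

  members <- select_residues(res, unit$members)
  if (unit$scope == "unit") {
    oriented <- orient_unit(members)
    t_p <- theoretical_profile(members, oriented$envelope)
    o_p <- observed_profile(members, cutoff = cutoff)
    st <- fod_status(o_p, t_p, scope = "unit", k_max = k_max, step = step)
    env <- oriented$envelope
    t_use <- t_p; o_use <- o_p
  } else {
    cx <- select_residues(res, unit$complex_members)
    miss <- setdiff(residue_keys(members), residue_keys(cx))
    if (length(miss))
      stop("selection error: unit members outside the complex: ",
           paste(miss, collapse = ", "))
    oriented <- orient_unit(cx)
    t_cx <- theoretical_profile(cx, oriented$envelope)
    o_cx <- observed_profile(cx, cutoff = cutoff)
    st <- fragment_status(t_cx, o_cx, residue_keys(members),
                          k_max = k_max, step = step)
    env <- oriented$envelope
    t_use <- normalize_profile(t_cx[residue_keys(members)])
    o_use <- normalize_profile(o_cx[residue_keys(members)])
  }
  m_use <- m_profile(t_use, st$k_star)
  prof <- data.frame(key = names(t_use),
                     chain = members$chain, resno = members$resno,
                     aa = members$aa,
                     T = unname(t_use), O = unname(o_use),
                     R = 1 / length(t_use), M = unname(m_use),
                     stringsAsFactors = FALSE)
  list(status = st, profiles = prof, envelope = env)
}
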