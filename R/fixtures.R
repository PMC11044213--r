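#' Synthetic structures with known hydrophobicity regimes
#'
#' Builds small artificial point-cloud "proteins" whose fuzzy-oil-drop
#' status is known by construction, so every statistic and procedure can be
#' exercised without real structure files. One effective atom per residue is
#' emitted (a single CA), so [effective_atoms()] degenerates to the
#' identity and tests isolate the profile mathematics from atom averaging.
#'
#' Regimes (all seeded, bit-reproducible):
#' \describe{
#'   \item{`ideal_micelle`}{Residues sampled uniformly in a ball; amino-acid
#'     types chosen so intrinsic hydrophobicity tracks the local Gaussian
#'     density (hydrophobic centre, polar surface). Expected: RD < 0.3,
#'     K <= 0.2 -- the aqueous-folding regime.}
#'   \item{`inverted_micelle`}{Same geometry, assignment reversed
#'     (hydrophobic surface, polar centre). Expected: RD > 0.5, K >= 1.0 --
#'     the membrane-like regime.}
#'   \item{`uniform_blob`}{Constant residue type: a structureless reference.}
#'   \item{`perturbed_micelle`}{Ideal micelle with a localised patch of
#'     surface residues forced to maximum hydrophobicity, creating a
#'     contiguous observed-vs-theoretical discrepancy.}
#'   \item{`engineered_dimer`}{Two well-separated micelle chains A and B
#'     with exactly one engineered inter-chain contact pair at 4 Angstrom.}
#' }
#'
#' Within each chain residues are ordered by decreasing Gaussian density
#' (core first), so the perturbation patch -- the tail of the sequence -- is
#' both sequence-contiguous and spatially superficial.
#'
#' @param regime One of the regime names above.
#' @param n Residue count (default 200; >= 8, split over two chains for the
#'   dimer).
#' @param seed Integer seed fixing all randomness.
#' @param radius Ball radius in Angstrom (default 15).
#' @param patch_len Perturbed-micelle patch length (default 8, the scale of a small complexation epitope).
#' @param scale Scale used to pick residue types (default Kyte-Doolittle).
#' @return A `fod_residues` table with `h` assigned, plus attributes
#'   `regime`, `bounds` (declared RD/K bounds where the regime states them)
#'   and, for `perturbed_micelle`, `patch` (the perturbed residue keys).
#' @export
make_fixture <- function(regime = c("ideal_micelle", "inverted_micelle",
                                    "uniform_blob", "perturbed_micelle",
                                    "engineered_dimer"),
                         n = 200, seed = 1, radius = 15, patch_len = 8,
                         scale = "kyte_doolittle") {
  regime <- match.arg(regime)
  if (n < 8) stop("n must be >= 8")
  sc <- resolve_scale(scale)
  res <- switch(
    regime,
    ideal_micelle    = micelle_cloud(n, seed, radius, sc, invert = FALSE),
    inverted_micelle = micelle_cloud(n, seed, radius, sc, invert = TRUE),
    uniform_blob     = {
      r <- micelle_cloud(n, seed, radius, sc, invert = FALSE)
      r$aa <- "ALA"; r$h <- unclass(sc)[["ALA"]]; r
    },
    perturbed_micelle = {
      r <- micelle_cloud(n, seed, radius, sc, invert = FALSE)
      hi <- names(which.max(unclass(sc)))
      # surface patch: the most superficial residue and its nearest surface
      # neighbours, renumbered to the sequence tail (sequence-contiguous)
      # and pulled into a tight clump around the anchor so their mutual
      # Levitt weights are ~1: a strong, spatially localised excess of
      # observed hydrophobicity where the Gaussian field expects little
      surf <- seq(ceiling(n / 2), n)           # lower-density half
      anchor <- n
      d2 <- (r$x[surf] - r$x[anchor])^2 + (r$y[surf] - r$y[anchor])^2 +
            (r$z[surf] - r$z[anchor])^2
      patch <- surf[order(d2)][seq_len(patch_len)]
      r <- rbind(r[-patch, , drop = FALSE], r[patch, , drop = FALSE])
      r$resno <- seq_len(n)
      class(r) <- c("fod_residues", "data.frame")
      patch <- seq(n - patch_len + 1L, n)
      jit <- seq_len(patch_len) - (patch_len + 1) / 2
      r$x[patch] <- r$x[patch[1]] + 0.8 * jit  # clump, 0.8 A spacing
      r$y[patch] <- r$y[patch[1]]
      r$z[patch] <- r$z[patch[1]]
      r$aa[patch] <- hi; r$h[patch] <- unclass(sc)[[hi]]
      attr(r, "patch") <- residue_keys(r)[patch]
      r
    },
    engineered_dimer = {
      na <- n %/% 2L; nb <- n - na
      a <- micelle_cloud(na, seed, radius, sc, invert = FALSE)
      b <- micelle_cloud(nb, seed + 1000L, radius, sc, invert = FALSE)
      b$chain <- "B"
      gap <- 4 * radius            # chains far apart except one contact
      b$x <- b$x + gap
      # engineer one contact: move the outermost B residue to 4 A from the
      # outermost (+x) A residue, along +x
      ia <- which.max(a$x); ib <- which.max(b$x)
      b$x[ib] <- a$x[ia] + 4; b$y[ib] <- a$y[ia]; b$z[ib] <- a$z[ia]
      r <- rbind(a, b)
      class(r) <- c("fod_residues", "data.frame")
      attr(r, "contact") <- c(residue_keys(a)[ia],
                              residue_keys(b[ib, , drop = FALSE]))
      r
    })
  attr(res, "regime") <- regime
  attr(res, "bounds") <- switch(regime,
    ideal_micelle    = c(rd_max = 0.3, k_max = 0.2),
    inverted_micelle = c(rd_min = 0.5, k_min = 1.0),
    NULL)
  res
}

# Uniform ball sample; hydrophobicity mapped from the local Gaussian-envelope
# density (or its complement), discretised to the nearest amino acid on the
# active scale. Residues sorted by decreasing density (core first).
micelle_cloud <- function(n, seed, radius, sc, invert) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * radius * stats::runif(n)^(1 / 3)
  sig <- apply(abs(pts), 2, max) / 3
  dens <- exp(-pts[, 1]^2 / (2 * sig[1]^2) - pts[, 2]^2 / (2 * sig[2]^2) -
              pts[, 3]^2 / (2 * sig[3]^2))
  ord <- order(-dens)
  pts <- pts[ord, , drop = FALSE]; dens <- dens[ord]
  target <- dens / max(dens)
  if (invert) target <- 1 - target
  vals <- unclass(sc)
  aa <- names(vals)[vapply(target, function(d) which.min(abs(vals - d)),
                           integer(1))]
  res <- data.frame(chain = "A", resno = seq_len(n), ins = "", aa = aa,
                    x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    h = unname(vals[aa]), stringsAsFactors = FALSE)
  class(res) <- c("fod_residues", "data.frame")
  res
}

#' Write residue records as a fixed-column PDB file
#'
#' Emits one CA ATOM record per residue (the effective-atom representation),
#' TER records between chains, and END. Output round-trips through
#' [read_structure()] to the PDB coordinate precision (1e-3 Angstrom).
#'
#' @param records A `fod_residues` table (e.g. from [make_fixture()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(records, path) {
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  serial <- 0L
  chains <- unique(records$chain)
  for (ch in chains) {
    sub <- records[records$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, sub$aa[i], ch, sub$resno[i],
        sub$x[i], sub$y[i], sub$z[i], 1, 0), con)
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      %-3s %1s%4d",
                       serial, sub$aa[nrow(sub)], ch,
                       sub$resno[nrow(sub)]), con)
  }
  writeLines("END", con)
  invisible(path)
}
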