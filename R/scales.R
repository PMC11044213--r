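#' Intrinsic hydrophobicity scales
#'
#' Named per-residue hydrophobicity tables, min-max normalised to \[0, 1\] so
#' that the most hydrophilic residue of a scale maps to 0 and the most
#' hydrophobic to 1. Normalisation makes scales interchangeable inside the
#' observed-profile sum, whose output is itself renormalised to a probability
#' distribution, so only the relative ordering and spacing of a scale matter.
#'
#' Available scales:
#' \describe{
#'   \item{`kyte_doolittle`}{Kyte & Doolittle (1982) hydropathy index.}
#'   \item{`eisenberg`}{Eisenberg et al. (1984) consensus scale.}
#'   \item{`fauchere_pliska`}{Fauchere & Pliska (1983) octanol/water pi values.}
#' }
#'
#' @param name Scale name, one of `"kyte_doolittle"`, `"eisenberg"`,
#'   `"fauchere_pliska"`.
#' @return A named numeric vector over the 20 standard three-letter residue
#'   codes, values in \[0, 1\], with attributes `scale_name` and class
#'   `"fod_scale"`.
#' @examples
#' sc <- hydrophobicity_scale("kyte_doolittle")
#' sc["ILE"]  # 1: most hydrophobic on this scale
#' @export
hydrophobicity_scale <- function(name = c("kyte_doolittle", "eisenberg",
                                          "fauchere_pliska")) {
  name <- match.arg(name)
  raw <- .fod_scales[[name]]
  v <- (raw - min(raw)) / (max(raw) - min(raw))
  structure(v, scale_name = name, class = "fod_scale")
}

# Raw published values, indexed by 3-letter code (alphabetical).
.fod_scales <- list(
  kyte_doolittle = c(
    ALA =  1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS =  2.5,
    GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE =  4.5,
    LEU =  3.8, LYS = -3.9, MET =  1.9, PHE =  2.8, PRO = -1.6,
    SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL =  4.2),
  eisenberg = c(
    ALA =  0.62, ARG = -2.53, ASN = -0.78, ASP = -0.90, CYS =  0.29,
    GLN = -0.85, GLU = -0.74, GLY =  0.48, HIS = -0.40, ILE =  1.38,
    LEU =  1.06, LYS = -1.50, MET =  0.64, PHE =  1.19, PRO =  0.12,
    SER = -0.18, THR = -0.05, TRP =  0.81, TYR =  0.26, VAL =  1.08),
  fauchere_pliska = c(
    ALA =  0.31, ARG = -1.01, ASN = -0.60, ASP = -0.77, CYS =  1.54,
    GLN = -0.22, GLU = -0.64, GLY =  0.00, HIS =  0.13, ILE =  1.80,
    LEU =  1.70, LYS = -0.99, MET =  1.23, PHE =  1.79, PRO =  0.72,
    SER = -0.04, THR =  0.26, TRP =  2.25, TYR =  0.96, VAL =  1.22)
)

#' @export
print.fod_scale <- function(x, ...) {
  cat("Intrinsic hydrophobicity scale:", attr(x, "scale_name"),
      "(normalised to [0,1])\n")
  print(round(unclass(x), 3))
  invisible(x)
}

# Resolve a scale argument: a name, a fod_scale, or a user-supplied named
# vector covering the 20 standard residues.
resolve_scale <- function(scale) {
  if (inherits(scale, "fod_scale")) return(scale)
  if (is.character(scale) && length(scale) == 1L)
    return(hydrophobicity_scale(scale))
  if (is.numeric(scale) && !is.null(names(scale))) {
    missing <- setdiff(names(.fod_scales$kyte_doolittle), names(scale))
    if (length(missing))
      stop("custom scale is missing residues: ", paste(missing, collapse = ", "))
    if (any(scale < 0)) stop("scale values must be nonnegative")
    if (all(scale == 0)) stop("degenerate scale: all values are zero")
    return(structure(scale, scale_name = "custom", class = "fod_scale"))
  }
  stop("`scale` must be a scale name, a fod_scale, or a named numeric vector")
}
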