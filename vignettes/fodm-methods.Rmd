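---
title: "The fuzzy-oil-drop model in fodm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fuzzy-oil-drop model in fodm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodm)
```

## The model

The fuzzy-oil-drop picture treats a folded, water-soluble protein as the
product of a micellisation process: hydrophobic residues concentrate in
the centre, polar residues coat the surface, and the resulting density of
hydrophobicity is well described by a 3D Gaussian spanning the molecule.
`fodm` turns that picture into three per-residue probability
distributions and two scalar statistics.

Every residue is represented by its **effective atom**, the unweighted
mean of its heavy-atom coordinates. Hydrogens are excluded because
deposited crystal structures rarely resolve them; including them when
present would make results depend on the refinement protocol rather than
the structure. Waters and non-polymer heteroatoms never enter profiles.

For a unit of $N$ residues:

* the **theoretical profile** $T_i$ is the Gaussian envelope
  $\exp(-x_i^2/2\sigma_x^2)\exp(-y_i^2/2\sigma_y^2)\exp(-z_i^2/2\sigma_z^2)$
  evaluated at the effective atoms and normalised to sum 1;
* the **observed profile** $O_i$ collects pairwise hydrophobicity with
  Levitt's contact polynomial
  $w(r) = 1 - \tfrac12\!\left(7\rho^2 - 9\rho^4 + 5\rho^6 - \rho^8\right)$,
  $\rho = r/c$, zero beyond the cutoff $c$:
  $\tilde O_i = \sum_{j,\; r_{ij}\le c}(H_i + H_j)\,w(r_{ij})$, normalised;
* the **uniform reference** $R_i = 1/N$.

Their disagreement is measured in Kullback–Leibler divergence (base 2),
and summarised by the relative distance
$\mathrm{RD} = D_{KL}(O\|T)\,/\,[D_{KL}(O\|T) + D_{KL}(O\|R)]$:
below 0.5 the observed distribution is closer to the micelle ideal than
to structurelessness, i.e. the unit has a hydrophobic core.

Non-aqueous environments are modelled by the **opposite distribution**
$(T_{max}-T_i)_n$ (the hydrophobicity pattern a fully nonpolar milieu
would favour) and the mixed reference
$M_i(K) = [\,T_i + K\,(T_{max}-T_i)_n\,]_n$. The environment parameter
$K^\ast$ minimises $D_{KL}(O\|M(K))$; since $M(0)=T$ exactly, the
minimised divergence never exceeds $D_{KL}(O\|T)$.

Two analysis scopes exist. With `scope = "unit"` the envelope and both
profiles are fitted to the unit itself. With `scope = "complex"` they are
fitted to an enclosing complex; the unit's slice of each complex-wide
profile is then renormalised and scored (`fragment_status()`). The two
scopes answer different questions — "is this chain a micelle?" versus
"does this chain contribute to the complex's micelle-like order?" — and
give genuinely different numbers for the same residues.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| hydrophobicity scale | `kyte_doolittle` | dimensionless, min–max normalised to [0, 1] | intrinsic $H_i$ in the observed profile |
| Levitt cutoff $c$ | 9 | Å | neighbourhood radius of the observed profile |
| $\sigma$ convention | max-extent / 3 | Å | Gaussian widths per principal axis |
| K search domain | [0, 10], step 0.01 | — | grid for $K^\ast$, refined locally |
| elimination threshold | 0.5 | RD units | greedy residue removal target |
| segment tolerance | $1/(4N)$ | profile units | excess/deficit call, a quarter of the uniform level |
| layer thresholds | 0.001 / 0.0015 | profile units | surface / subsurface / core-deficit classification |
| contact cutoff | 5 | Å | interface membership (any heavy-atom pair) |

Notes on the non-obvious choices:

* **The scale is a logged configuration item, not a constant.** The
  relative-distance statistic is reasonably robust to the choice of a
  monotone hydrophobicity scale because both divergences shift together,
  but reported K values move by a few tenths between scales. Three
  published scales ship with the package; every run manifest records
  which one was used. Min–max normalisation to [0, 1] makes the scales
  interchangeable inside the pairwise sum, whose output is renormalised
  anyway.
* **$\sigma$ = max-|coordinate| / 3 per axis.** The three-sigma rule puts
  the molecular boundary at the radius enclosing ~99.7 % of the Gaussian
  mass. No padding margin is added; padding inflates every $T_i$ near the
  surface and systematically lowers RD, so a fixed, margin-free
  convention is easier to reason about and to reproduce.
* **The Levitt sum includes the self term** ($j=i$, $w(0)=1$,
  contribution $2H_i$). This makes a single-residue unit well defined
  ($O = 1$) and reads the sum as the hydrophobicity *collected at*
  residue $i$, including its own.
* **K is applied to the normalised opposite term** before the final
  renormalisation. The stepwise reading — normalise the complement, mix,
  renormalise — keeps $K$ interpretable as a mixture weight: a target
  built as $(1-w)\,T + w\,(T_{max}-T)_n$ is recovered with
  $K^\ast = w/(1-w)$, which the acceptance script demonstrates
  numerically ($w = 0.5 \Rightarrow K^\ast = 1$).
* **Divergences are reported in bits.** RD and $K^\ast$ are invariant to
  the logarithm base (the base cancels in the ratio and is a monotone
  rescaling of the K objective); the tests verify this identity.

## Numerical choices

* **Orientation is deterministic.** Principal axes come from the
  eigendecomposition of the effective-atom covariance, ordered by
  descending variance. Eigenvector signs are fixed by requiring the
  residue of largest absolute coordinate on each of the first two axes to
  have a positive coordinate; the third axis sign is then set to keep the
  rotation proper (det = +1), preserving handedness. Two runs on the same
  input are bit-identical, and a rigidly moved copy of the input produces
  the same profiles to 1e-9.
* **K optimisation** scans the grid [0, 10] at 0.01, then refines the
  bracketing interval with `stats::optimize`. The refined value is
  accepted only if it does not exceed the best grid value, so the
  reported minimum never loses to the scan. The domain upper bound 10
  comfortably contains the largest K values reported for chaperonin
  systems (< 7); an optimum pinned at the bound signals an observed
  profile essentially equal to the opposite field (the inverted-micelle
  fixture does this by construction).
* **Elimination ties** (equal $|O_i - T_i|$) break toward the lower
  sequence position, and the ranking is recomputed after every removal
  because renormalisation changes all discrepancies. A one-shot ranked
  variant is available (`recompute = FALSE`) for comparison. Shrinking
  below 3 residues without crossing the threshold returns a
  non-convergence report — a result, not an error.
* **Degenerate inputs** are first-class: constant T rejects the opposite
  distribution (zero-sum); an all-zero scale is rejected before any
  profile is built; O = T = R defines RD := 0 with an explicit
  `degenerate` flag (a one-residue fragment triggers this path);
  collinear or sub-3-residue units raise geometry errors.
* **Zero-term convention:** $0\log(0/q) = 0$. T is strictly positive by
  construction, so support errors can only arise from user-supplied
  profiles.

## What the synthetic fixtures emulate

The fixture generator samples residues uniformly in a ball (default
radius 15 Å, 200 residues) and assigns each position the amino acid whose
scale value is nearest to the local Gaussian density (`ideal_micelle`) or
its complement (`inverted_micelle`). This makes the observed profile
track — or oppose — the theoretical one *by construction*, which is
exactly what the two statistics are supposed to detect: across seeds
1–10 the ideal regime stays below RD 0.3 with K ≤ 0.2 and the inverted
regime above RD 0.5 with K ≥ 1. The `perturbed_micelle` adds a
sequence-contiguous clump of maximally hydrophobic residues on the
surface (default 8 residues, the scale of a small complexation epitope),
giving the elimination and segmentation procedures a known target; the
`engineered_dimer` provides exactly one 4 Å inter-chain contact for the
interface extractor.

What the fixtures do **not** emulate: peptide-bond connectivity, secondary
structure, realistic packing densities, side-chain geometry, or chain
breaks. Passing the fixture suite therefore demonstrates the correctness
of the mathematics and the directional behaviour of the statistics, not
agreement with any particular deposited structure. Scoring real entries
(`reference_targets()`) additionally depends on the hydrophobicity scale
and cutoff configuration, which published FOD analyses do not always pin
down; expect configuration sensitivity of roughly ±0.05 in RD and a few
tenths in K, larger for very large complexes.

Problem sizes in the shipped tests: fixtures of 40–200 residues, ten
seeds for the regime properties, fine-grid K oracles at step 0.001. The
full suite runs in well under a minute on one core.

## Known limitations

* Residue-level only: no all-atom hydrophobicity field, no hydrogen
  addition, no structure repair, no biological-assembly expansion.
* Missing residues (chain breaks) are simply absent; profiles index over
  the residues present. Comparing profiles across structures with
  different coverage of the same sequence needs care.
* The published interface residue lists of specific complexes cannot be
  reproduced exactly because the contact criterion behind them is not
  standardised; `interface_residues()` uses the common any-heavy-atom
  5 Å convention and exposes both the cutoff and the atom basis.
* Water-mediated contacts and explicit water ordering are out of scope;
  the environment enters only through the continuum M field.
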