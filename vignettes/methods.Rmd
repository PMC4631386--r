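---
title: "Models and methods behind cspfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cspfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspfold)
```

cspfold implements the computational chain used to characterize a weak,
fast-exchanging peptide–protein interaction by solution NMR and plate
assays, and to solve the bound-state conformation of the peptide from
transferred NOEs.  This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data tests do
and do not demonstrate.

## Chemical-shift-perturbation mapping

Adding an unlabeled ligand to an ¹⁵N-labeled protein shifts the amide
peaks of residues near the binding site.  The per-residue perturbation is
the weighted Euclidean distance

$$d = \sqrt{\tfrac12\left[\delta_H^2 + (\alpha\,\delta_N)^2\right]},$$

with `csp_alpha()` returning the conventional weighting α = 0.14 for all
residues except glycine (α = 0.20), which compensates the larger ¹⁵N
shift range.  `classify_epitope()` computes the standard deviation σ of
all assigned *d* values and reports residues with *d* > σ and *d* > 2σ
(strict inequalities).  We use the population σ (dividing by *n*, not
*n* − 1): the residue set is the complete population of observations, not
a sample from a larger one; the choice is documented here because both
conventions appear in practice, and the difference is below 1 % for
≈ 120 residues.  Unassigned residues — peaks lost to exchange broadening
or overlap — never contribute to σ and are carried as a separate list
(plotted as negative bars by `plot.csp_profile()`).

Peak tracking (`track_peaks()`) links each assigned free-state peak
through the titration by stepwise nearest-neighbour matching in the
scaled (δH, α·δN) plane, mimicking how assignments are transferred by
following peaks between spectra.  A step whose best and second-best
candidates differ by less than a factor 2 in scaled distance is declared
ambiguous and the residue is reported unassigned — the in-silico analogue
of "could not be unambiguously transferred".

## Fast-exchange K_D fitting

In fast exchange the observed position of residue *i* at titration point
*t* is the population average

$$\mathrm{obs}_{it} = c_i + f_\mathrm{bound}(P, L_t, K_D)\, b_i,$$

where `fraction_bound()` is the exact single-site mass balance with
ligand depletion,

$$f = \frac{(P+L+K_D) - \sqrt{(P+L+K_D)^2 - 4PL}}{2P}.$$

The depletion form matters because the default conditions put the
protein concentration (55 µM) on the same order as K_D (60 µM), where
the large-excess approximation $f = L/(L+K_D)$ is badly wrong.

`fit_kd_fast_exchange()` shares one K_D across residues (the data carry
one binding event) with per-residue amplitudes $b_i$, and — importantly —
a per-residue free intercept $c_i$ rather than anchoring trajectories on
the measured zero-ratio peak.  Anchoring subtracts the same noisy
reference from every titration point of a residue, which correlates the
errors across the titration and systematically drags the fitted K_D
low; the free intercept removes that mechanism, and the test suite
asserts the resulting median recovery bias over 100 simulations at the
default noise.  For fixed K_D both $c_i$ and $b_i$
solve in closed form, so the fit is a 1-D profile of the residual sum of
squares over log₁₀ K_D, started from 8 log-spaced points (the surface
can be multimodal when shifts are tiny).  The reported interval is the
F-based profile-likelihood confidence interval.  Degenerate inputs
(zero-shift trajectories, boundary or flat optima) are flagged
`converged = FALSE` rather than raising errors, since they occur
routinely in scripted batch use.  A `min_shift` exclusion guard is
available but defaults to 0 — with the intercept model it is not needed
for unbiasedness.

## Dose–response fitting

`fit_4pl()` fits the four-parameter logistic

$$y = m_1 + \frac{m_2 - m_1}{1 + (x/m_3)^{m_4}}$$

by Levenberg–Marquardt (minpack.lm) with multi-start initialization
(7 log-spaced $m_3$ × slopes {0.5, 1, 2}).  In this parameterization
$y(0) = m_2$ and $y(\infty) = m_1$; note that descriptions of $m_1$ as
the zero-analyte signal and $m_2$ as the saturating signal occasionally
appear alongside this formula — the formula is authoritative here, and
the midpoint identity $y(m_3) = (m_1+m_2)/2$ holds either way.  For a
competition (displacement) assay the curve descends from $m_2$ and
`ic50_from_fit()` returns $m_3$ as the IC₅₀, refusing ascending curves
and fits not declared as competition curves.

## Transferred-NOE distance calibration

Cross-peak intensities from an isotope-filtered transferred NOESY are
converted to bound-state distances under the isolated-spin-pair
approximation $I \propto r^{-6}$, calibrated internally against a
geminal methylene proton pair: idealized sp³ geometry (C–H 1.09 Å,
tetrahedral angle) separates the two protons by
$2 \cdot 1.09 \cdot \sin(109.47°/2) \approx 1.78$ Å
(`geminal_reference_distance()`), a distance fixed by covalent geometry
and therefore usable as an internal ruler.

`build_restraints()` maps calibrated distances onto the standard
three-bin bound classes — upper bounds 2.7, 3.5 or 5.0 Å with a
universal 1.8 Å lower bound — rather than using raw distances: at
250 ms-scale mixing times spin diffusion and differential relaxation
make exact distances unreliable, while class bounds are robust.  Methyl
pseudoatom corrections add +1.0 Å to the ceiling (and +0.7 Å for
explicitly flagged unresolved methylene/aromatic pairs); duplicate pairs
keep the tighter bound.  Rows whose calibrated distance falls below the
1.8 Å lower bound are discarded as calibration-inconsistent: a
cross-peak more intense than the geminal reference would imply a
sub-covalent separation, which for non-bonded protons indicates an
artifact rather than a distance.  Isotope filtering is modelled by
construction: the simulated table only ever contains peptide-internal
pairs.

## Distance geometry

The structure engine converts bounds to coordinates through the classic
EMBED sequence, with the heavy O(N²)–O(N³) kernels in C++:

1. **Bounds matrix** (`build_bounds()`): 1-2 and 1-3 distances fixed
   from ideal covalent geometry; whole rigid groups (aromatic rings with
   their substituents, guanidinium/amide/carboxylate planes, the trans
   peptide unit) fixed pairwise; remaining 1-4 pairs bounded by their
   cis/trans rotation extremes; everything else defaults to scaled van
   der Waals contact below (Bondi-style radii × 0.9) and a 999 Å ceiling
   above.  Experimental restraints intersect these defaults and carry
   penalty weight 5 (vs 1 for the geometric defaults) — conventional
   restraint weighting that keeps the experimental data in charge of the
   fold while the soft-sphere terms absorb packing strain.
2. **Smoothing** (`smooth_bounds()`): Floyd–Warshall shortest paths over
   the uppers; inverse triangle inequality on the lowers iterated to a
   fixed point.  Idempotent by construction and tested against a plain-R
   oracle.
3. **Random metrization** (`metrize_sample()`): a seeded random subset
   of pairs (default 5 %) is fixed one at a time, each drawn uniformly
   within its current bounds with bound propagation through the two
   endpoints after every draw; the remaining pairs are sampled
   independently within the final bounds.  Full metrization
   (`fraction = 1`) is available but the partial default is the usual
   speed/quality compromise; higher fractions cost proportionally more
   smoothing work without improving the 12-mer recovery statistics the
   test suite asserts.
4. **Embedding** (`embed_distances()`): classical metric-matrix
   (double-centring) embedding into four dimensions.
5. **4D refinement** (`refine_conformer()`): minimization of the squared
   bound-violation penalty (Å² units — there is deliberately no physical
   force field in this engine) plus an L-alpha-carbon chirality penalty,
   with the fourth coordinate suppressed by a weight annealed upward
   (×2 per stage from 0.02) until it collapses below 10⁻³ Å.  The extra
   dimension is what lets wrong-handed centres invert smoothly instead
   of being trapped — so the chirality penalty is active *during* the
   anneal.  Each stage runs L-BFGS on the analytic gradient, which
   converges far faster than a fixed-step descent on this stiff,
   piecewise-smooth penalty.  Mirror ambiguity (an embedding is only
   defined up to reflection) is resolved by inverting the conformer
   whenever the majority of centres are wrong-handed.
6. **Minimization** (`minimize_conformer()`): exactly 200 steepest
   descent then 10 conjugate-gradient steps, each displacing no atom by
   more than 0.02 Å, on the same penalty; the energy is non-increasing
   by construction.  This same-count schedule stands in for a
   force-field minimization of the original protocol: the engine is a
   restraint-satisfaction tool and stays in restraint units.
7. **Ensemble protocol** (`generate_ensemble()`, `select_lowest()`):
   *n* independent runs seeded `seed + i − 1`; the *k* lowest-penalty
   structures are kept (ties broken by seed order), the standard counts
   being 97 generated / 21 kept.  Runs that fail are recorded, never
   silently dropped.  A run whose refined penalty stays above 8 Å² is
   rescued once by re-lifting into 4D with a fresh seeded fourth
   coordinate and re-annealing, which raises the fraction of runs
   landing in the native basin well above the kept fraction
   (21/97 ≈ 22 %), so energy selection operates inside the converged
   cluster.

Chirality uses the signed volume of (C, N, Cβ) about Cα (≈ +0.42 ų for
L-residues in ideal geometry); the penalty activates below a 0.25 ų
floor with weight 20.  Glycine has no centre and is skipped.

## Validation

`violation_report()` computes per-restraint one-sided violations
(pseudoatoms at the mean position of their proton group) with AQUA-style
summary counts above 0.1 and 0.5 Å.  `ensemble_rmsd()` reports mean
pairwise backbone RMSD after optimal (Kabsch) superposition and each
conformer's RMSD to the medoid — a medoid, not a mean structure, because
coordinate averaging produces unphysical geometry.  Pairwise
superposition is cross-checked against bio3d in the test suite.
`csp_contact_consistency()` scores a docked two-chain pose by the
Spearman rank correlation between a partner residue's CSP and its
proximity to the peptide; rank rather than linear correlation because
the functional form linking CSP magnitude to distance is unknown, and
only the ordering is interpretable.

## The synthetic-data module

`simulation_config()` encodes the study conditions as defaults: 55 µM
protein, true K_D 60 µM, a six-point titration at ligand:protein ratios
{0, 0.5, 1, 1.5, 2, 5} (five ratios are standard anchors of such a
titration; the set of six with a saturating 5:1 endpoint is this
package's choice and can be overridden), ¹H shift noise 0.002 ppm (¹⁵N
noise scaled by 1/α so both CSP dimensions carry equal noise), NOE
cutoff 5 Å with 2 % relative intensity noise, and 4PL plates with EC₅₀
2 µM (direct) or IC₅₀ 63 µM (competition) and ~1 % additive signal
noise.  Noise models are additive Gaussian on shifts and signals and
relative Gaussian on NOE intensities — the simplest models with the
right first-order statistics.

`make_ideal_helix()` builds the ground-truth bound conformation from
ideal covalent geometry at uniform (φ, ψ) = (−57°, −47°), with fixed
default rotamers (χ₁ gauche⁻, aromatics trans with ring χ₂ ≈ 90°,
planar groups planar) and generic hydrogen placement — so every
methylene reproduces the analytic 1.78 Å geminal separation exactly.
The proton roster contains the amide H and all carbon-bound protons;
exchangeable sidechain protons (hydroxyl, ammonium, guanidinium, amide
NH₂, ring NH) are omitted, as they are not observed in a NOESY of an
exchanging sample.  Proline is unsupported (no amide proton, ring
backbone).

What the generator does *not* emulate: spin diffusion and
relaxation-matrix effects on NOE intensities, exchange broadening and
peak overlap (unassignable residues enter only as an explicit input),
rotamer heterogeneity, and solvent effects.  Passing the recovery tests
therefore demonstrates that the estimators invert their own generative
models correctly at realistic noise — not that they are robust to every
artifact of real spectra.  One consequence of the rigid-rotamer ideal
helix is worth noting: a handful of sidechain–sidechain proton pairs sit
at 1.3–1.5 Å, closer than any real structure would allow; their NOE rows
are exactly the calibration-inconsistent ones the restraint builder
discards, so the planted structure satisfies every restraint it
generates.

## Problem sizes and reproducibility

All tests run on synthetic data generated in code: the 12-mer peptide
(219 atoms) for the structure engine, 118-residue titrations for CSP
and K_D work, 100-seed repeat studies for bias estimates, and the full
97-generated / 21-kept ensemble protocol for fold recovery (a few
minutes on one core).  Every stochastic step takes an explicit seed, and
the whole simulate → restrain → fold → validate chain is bit-reproducible
for a fixed seed; generators restore the caller's RNG state on exit.
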