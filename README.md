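# cspfold

Tools for characterizing weak, fast-exchanging peptide–protein
interactions by solution NMR and plate assays, and for solving the
bound-state conformation of the peptide from transferred NOEs.  The
package is aimed at structural-biology groups who map a binding epitope
by ¹H,¹⁵N-HSQC titration, quantify the affinity from the same data (and
from ELISA-style dose–response plates), and calculate the ligand's bound
structure with distance geometry.

The pipeline covers:

* **CSP epitope mapping** — per-residue chemical-shift perturbations
  `d = sqrt((δH² + (α·δN)²)/2)` with α = 0.14 (0.20 for Gly), peak
  tracking across titration points, and strict σ/2σ tier classification
  of the binding epitope.
* **Fast-exchange K_D fitting** — one global K_D across residues under
  the exact single-site mass balance with ligand depletion,
  `f = ((P+L+K_D) − sqrt((P+L+K_D)² − 4PL)) / 2P`, with per-residue
  free-state intercepts and bound-state amplitudes, multi-start
  profiling and a profile-likelihood confidence interval.
* **4PL dose–response fitting** — `y = m1 + (m2−m1)/(1+(x/m3)^m4)` by
  Levenberg–Marquardt with multi-start initialization; `m3` of a
  descending competition curve is the IC₅₀.
* **Transferred-NOE calibration** — intensities to distances via the
  isolated-spin-pair `r⁻⁶` law against the geminal methylene internal
  reference (2·1.09 Å·sin(109.47°/2) ≈ 1.78 Å), binned into standard
  2.7/3.5/5.0 Å bound classes with pseudoatom corrections.
* **Distance geometry** — triangle-inequality bound smoothing, seeded
  random metrization, metric-matrix embedding, refinement in four
  dimensions with an annealed collapse of the extra coordinate and an
  L-chirality penalty, and a fixed 200-steepest-descent +
  10-conjugate-gradient minimization at 0.02 Å steps; ensembles of 97
  structures with the 21 lowest-penalty kept.
* **Validation** — restraint-violation statistics, ensemble precision
  (pairwise/medoid backbone RMSD), and CSP-contact rank-correlation
  scoring of docked poses.

A synthetic-data module generates titrations, NOESY tables and plate
reads with known ground truth (ideal helical 12-mer, fast-exchange
shifts under ligand depletion, `r⁻⁶` NOE intensities, 4PL plates), so
the whole chain is testable offline.

## Worked example

Simulate a bound helical peptide, derive restraints from its NOESY, and
solve its structure back (a reduced 16-generated / 3-kept run; the full
protocol uses `n = 97, keep = 21`):

```r
library(cspfold)

r4    <- peptide_sequence("VRRFDLLKRILK", first_index = 62)
truth <- make_ideal_helix(r4)
peaks <- simulate_noesy(truth, simulation_config(noe_noise = 0))
rest  <- build_restraints(peaks, NULL, r4)
ens   <- generate_ensemble(build_bounds(r4, rest), n = 16, seed = 1)
kept  <- select_lowest(ens, 3)
kept
#> conformer_ensemble: 3 conformer(s), 219 atoms, energies 1.000-6.662 A^2 [kept 3 of 16]
violation_report(kept, rest)
#> violation_report: 874 restraints; largest violation 0.112 A; > 0.1 A: 3; > 0.5 A: 0
ensemble_rmsd(kept, region = 65:72)$mean_pairwise
#> [1] 0.3375481
```

The kept structures satisfy all 874 synthetic NOE restraints to within
0.12 Å and agree pairwise to ≈ 0.34 Å backbone RMSD over the ordered
residues 65–72 — the engine recovers the planted helix from its own
NOESY.

Fitting the affinity from a simulated titration of a 118-residue
protein at 55 µM with true K_D = 60 µM and 0.002 ppm shift noise:

```r
prof <- simulate_bound_shifts(n_residues = 118, epitope_residues = 5:12)
cfg  <- simulation_config(shift_noise = 0.002, seed = 7)
tabs <- simulate_titration(cfg, prof)
fit_kd_fast_exchange(track_peaks(tabs), P = cfg$protein_conc)
#> kd_fit: K_D = 6.27e-05 M (CI 5.41e-05-7.36e-05), 115 residues, residual RMS 0.0016 ppm
```

The recovered K_D (62.7 µM here) brackets the planted 60 µM within its
confidence interval.

A thin command-line front end over the same functions ships at
`inst/scripts/cspfold.R` with subcommands `simulate`, `csp`, `fitkd`,
`fit4pl`, `calibrate`, `restraints`, `fold` and `validate`.

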