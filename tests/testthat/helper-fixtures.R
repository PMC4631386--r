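# Shared fixtures, built once per test run and memoized.  Everything is
# generated in code from the synthetic-data module; nothing is read from
# disk.

.fx <- new.env(parent = emptyenv())

fx_r4_sequence <- function() {
  if (is.null(.fx$seq)) .fx$seq <- peptide_sequence("VRRFDLLKRILK", 62)
  .fx$seq
}

fx_helix <- function() {
  if (is.null(.fx$helix)) .fx$helix <- make_ideal_helix(fx_r4_sequence())
  .fx$helix
}

fx_noe_peaks <- function() {
  if (is.null(.fx$peaks))
    .fx$peaks <- simulate_noesy(fx_helix(), simulation_config(noe_noise = 0))
  .fx$peaks
}

fx_restraints <- function() {
  if (is.null(.fx$rest))
    .fx$rest <- build_restraints(fx_noe_peaks(), NULL, fx_r4_sequence())
  .fx$rest
}

fx_bounds <- function() {
  if (is.null(.fx$bounds))
    .fx$bounds <- build_bounds(fx_r4_sequence(), fx_restraints())
  .fx$bounds
}

fx_smooth_bounds <- function() {
  if (is.null(.fx$smooth)) .fx$smooth <- smooth_bounds(fx_bounds())
  .fx$smooth
}

# per-residue profile with a planted epitope, matching the titration study
# conditions (118 assigned residues)
fx_shift_profile <- function() {
  if (is.null(.fx$profile))
    .fx$profile <- simulate_bound_shifts(n_residues = 118L,
                                         epitope_residues = 5:12,
                                         seed = 42L)
  .fx$profile
}

# backbone coordinate block of a conformer over a residue range
backbone_coords <- function(conf, region) {
  sel <- conf$atoms$name %in% c("N", "CA", "C") & conf$atoms$resid %in% region
  conf$coords[sel, , drop = FALSE]
}

# reference Floyd-Warshall shortest paths (upper bounds), plain R oracle
fw_oracle <- function(U) {
  n <- nrow(U)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (U[i, k] + U[k, j] < U[i, j]) U[i, j] <- U[i, k] + U[k, j]
  U
}

# random consistent bound matrices for smoothing oracles
random_bounds <- function(n, seed) {
  set.seed(seed)
  P <- matrix(stats::runif(n * 3L, 0, 10), n, 3L)  # points in a box
  D <- as.matrix(stats::dist(P))
  U <- D * matrix(stats::runif(n * n, 1, 2), n, n)
  U <- (U + t(U)) / 2
  L <- D * matrix(stats::runif(n * n, 0.3, 1), n, n)
  L <- (L + t(L)) / 2
  diag(U) <- diag(L) <- 0
  list(lower = L, upper = U)
}
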