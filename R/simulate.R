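# Synthetic-data generators.  Every generator is a pure function of its
# inputs and the seed carried by the simulation config: the RNG state is
# seeded locally and restored on exit, so calls are reproducible and do not
# disturb the caller's random stream.

#' Simulation configuration
#'
#' Bundles the physical and noise parameters of the synthetic-data
#' generators.  Defaults reproduce the study conditions of the analysis the
#' package implements: 55 uM protein observed by HSQC, true K_D 60 uM, a
#' six-point titration at ligand:protein ratios 0 to 5, transferred-NOESY
#' distances calibrated against a 1.78 A geminal reference, and plate reads
#' from a four-parameter logistic with EC50 2 uM (direct) or IC50 63 uM
#' (competition).
#'
#' @param true_kd dissociation constant (molar).
#' @param protein_conc observed-protein concentration (molar).
#' @param ratios ligand:protein molar ratios, ascending and starting at 0.
#' @param shift_noise additive Gaussian noise on chemical shifts (ppm, 1H;
#'   15N noise is scaled by 1/alpha so both dimensions are comparable after
#'   CSP weighting).
#' @param noe_cutoff proton-pair distance cutoff for NOESY cross peaks (A).
#' @param noe_noise relative Gaussian noise on NOE intensities.
#' @param plate_params named vector `c(m1, m2, m3, m4)` of the
#'   dose-response logistic for the direct binding assay: `m2` is the
#'   zero-concentration signal, `m1` the saturating signal, `m3` the
#'   inflection (EC50, molar), `m4` the slope factor.
#' @param ic50 inflection of the competition (descending) assay (molar).
#' @param plate_noise additive Gaussian noise on plate signals
#'   (signal units).
#' @param seed integer RNG seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(true_kd = 60e-6,
                              protein_conc = 55e-6,
                              ratios = c(0, 0.5, 1, 1.5, 2, 5),
                              shift_noise = 0.002,
                              noe_cutoff = 5,
                              noe_noise = 0.02,
                              plate_params = c(m1 = 1000, m2 = 100,
                                               m3 = 2e-6, m4 = 1.5),
                              ic50 = 63e-6,
                              plate_noise = 10,
                              seed = 1L) {
  if (true_kd <= 0) stop("true_kd must be > 0")
  if (protein_conc <= 0) stop("protein_conc must be > 0")
  if (is.unsorted(ratios) || ratios[1L] != 0)
    stop("ratios must be ascending and start at 0")
  if (shift_noise < 0 || noe_noise < 0 || plate_noise < 0)
    stop("noise levels must be >= 0")
  if (noe_cutoff <= 0) stop("noe_cutoff must be > 0")
  p <- as.numeric(plate_params)
  if (length(p) != 4L || p[3L] <= 0)
    stop("plate_params must be c(m1, m2, m3, m4) with m3 > 0")
  structure(list(true_kd = true_kd, protein_conc = protein_conc,
                 ratios = as.numeric(ratios), shift_noise = shift_noise,
                 noe_cutoff = noe_cutoff, noe_noise = noe_noise,
                 plate_params = stats::setNames(p, c("m1", "m2", "m3", "m4")),
                 ic50 = ic50, plate_noise = plate_noise,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: K_D %.3g M, P %.3g M, ratios {%s},\n",
                     "  shift noise %.3g ppm, NOE cutoff %.3g A (noise %.3g),",
                     " seed %d\n"),
              x$true_kd, x$protein_conc, paste(x$ratios, collapse = ", "),
              x$shift_noise, x$noe_cutoff, x$noe_noise, x$seed))
  invisible(x)
}

# evaluate thunk with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' NOESY cross-peak table
#'
#' @param atom_i,atom_j atom identifiers `"<resid>.<name>"`.
#' @param intensity positive cross-peak intensities (arbitrary units).
#' @param is_reference logical; exactly one row, the geminal calibration
#'   reference, should be flagged per calibration.
#' @return a data.frame of class `noe_peak_table`.
#' @export
noe_peak_table <- function(atom_i, atom_j, intensity, is_reference = FALSE) {
  intensity <- as.numeric(intensity)
  if (any(intensity <= 0) || any(!is.finite(intensity)))
    stop("NOE intensities must be finite and > 0")
  df <- data.frame(atom_i = as.character(atom_i),
                   atom_j = as.character(atom_j),
                   intensity = intensity,
                   is_reference = as.logical(is_reference),
                   stringsAsFactors = FALSE)
  class(df) <- c("noe_peak_table", "data.frame")
  df
}

#' @export
print.noe_peak_table <- function(x, ...) {
  cat(sprintf("noe_peak_table: %d cross peaks (%d reference)\n",
              nrow(x), sum(x$is_reference)))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Simulate a transferred-NOESY cross-peak table from a conformer
#'
#' Enumerates all proton pairs of the conformer closer than the cutoff and
#' assigns each the isolated-spin-pair intensity `(r_ref / r)^6`, optionally
#' perturbed by relative Gaussian noise.  Intensities are expressed relative
#' to the geminal methylene reference pair (H-H distance 1.78 A in
#' idealized sp3 geometry), which is included and flagged
#' `is_reference = TRUE`.  Only ligand-internal pairs exist by construction,
#' mirroring the isotope-filtered experiment that suppresses
#' protein-derived cross peaks.
#'
#' @param conf a [conformer()] with hydrogens (e.g. [make_ideal_helix()]).
#' @param config a [simulation_config()]; uses `noe_cutoff`, `noe_noise`,
#'   `seed`.
#' @param reference atom-identifier pair of the calibration reference, or
#'   `NULL` to use the first geminal methylene pair of the first
#'   phenylalanine (falling back to the first methylene found).
#' @return a [noe_peak_table()].
#' @export
simulate_noesy <- function(conf, config = simulation_config(),
                           reference = NULL) {
  stopifnot(inherits(conf, "conformer"))
  hy <- which(conf$atoms$elem == "H")
  if (!length(hy)) stop("conformer carries no protons")
  ids <- atom_ids(conf$atoms)
  co <- conf$coords[hy, , drop = FALSE]
  D <- as.matrix(stats::dist(co))
  pairs <- which(upper.tri(D) & D <= config$noe_cutoff, arr.ind = TRUE)
  if (!nrow(pairs)) stop("no proton pairs within the NOE cutoff")
  r <- D[pairs]
  r_ref <- geminal_reference_distance()
  if (is.null(reference)) {
    cand <- .default_reference_pair(conf)
    reference <- cand
  }
  ai <- ids[hy[pairs[, 1L]]]
  aj <- ids[hy[pairs[, 2L]]]
  is_ref <- (ai == reference[1L] & aj == reference[2L]) |
            (ai == reference[2L] & aj == reference[1L])
  if (!any(is_ref))
    stop("reference pair ", reference[1L], " / ", reference[2L],
         " not among simulated cross peaks")
  intensity <- (r_ref / r)^6
  if (config$noe_noise > 0) {
    eps <- with_seed(config$seed,
                     stats::rnorm(length(intensity), 0, config$noe_noise))
    intensity <- intensity * (1 + eps)
    if (any(intensity <= 0))
      stop("noise level too large: non-positive intensity generated")
  }
  ord <- order(!is_ref, ai, aj)
  noe_peak_table(ai[ord], aj[ord], intensity[ord], is_ref[ord])
}

# geminal methylene of the first Phe if present, else first CH2 found
.default_reference_pair <- function(conf) {
  at <- conf$atoms
  phe <- unique(at$resid[at$reskind == "F"])
  cands <- if (length(phe)) phe[1L] else unique(at$resid)
  for (resi in cands) {
    sel <- at$resid == resi & at$name %in% c("HB2", "HB3")
    if (sum(sel) == 2L)
      return(paste0(resi, ".", c("HB2", "HB3")))
  }
  stop("no geminal methylene (HB2/HB3) found to serve as reference")
}

#' Simulate per-residue free shifts and bound-state shift changes
#'
#' Generates a protein-sized assignment table with a planted binding
#' epitope: every residue receives random free-state amide shifts and a
#' small random bound-state perturbation; the epitope residues' bound-state
#' perturbations are scaled up by `epitope_scale`.
#'
#' @param n_residues number of assigned residues (default 118, the size of
#'   the transferred assignment set the CSP analysis operates on).
#' @param epitope_residues residue indices carrying the planted epitope.
#' @param background_h,background_n standard deviation of background
#'   bound-state shift changes (ppm).
#' @param epitope_scale multiplier applied to epitope residues.
#' @param first_index numbering offset.
#' @param seed RNG seed.
#' @return data.frame with columns `residue_index`, `residue_kind`,
#'   `free_h`, `free_n`, `dh`, `dn` (bound minus free, ppm).
#' @export
simulate_bound_shifts <- function(n_residues = 118L,
                                  epitope_residues = integer(),
                                  background_h = 0.005,
                                  background_n = 0.03,
                                  epitope_scale = 10,
                                  first_index = 1L,
                                  seed = 1L) {
  idx <- seq(first_index, length.out = n_residues)
  if (!all(epitope_residues %in% idx))
    stop("epitope residues outside the residue range")
  with_seed(seed, {
    kinds <- sample(supported_residues(), n_residues, replace = TRUE)
    free_h <- stats::rnorm(n_residues, 8.3, 0.45)
    free_n <- stats::rnorm(n_residues, 119, 4)
    dh <- stats::rnorm(n_residues, 0, background_h)
    dn <- stats::rnorm(n_residues, 0, background_n)
    ep <- idx %in% epitope_residues
    dh[ep] <- dh[ep] * epitope_scale
    dn[ep] <- dn[ep] * epitope_scale
    data.frame(residue_index = idx, residue_kind = kinds,
               free_h = free_h, free_n = free_n, dh = dh, dn = dn,
               stringsAsFactors = FALSE)
  })
}

#' Simulate an HSQC titration series under fast exchange
#'
#' For each ligand:protein ratio the observed peak of every residue is the
#' population-weighted average of its free and bound positions:
#' `obs = free + f_bound * (bound - free) + noise`, with the bound fraction
#' from the single-site mass-balance model with ligand depletion
#' ([fraction_bound()]).  15N noise is `shift_noise / alpha` so that both
#' dimensions carry comparable noise after CSP weighting.
#'
#' @param config a [simulation_config()] (uses `true_kd`, `protein_conc`,
#'   `ratios`, `shift_noise`, `seed`).
#' @param profile per-residue shift table from [simulate_bound_shifts()].
#' @return list of [peak_table()]s, one per ratio, ascending.
#' @export
simulate_titration <- function(config, profile) {
  stopifnot(inherits(config, "simulation_config"))
  if (!all(c("residue_index", "residue_kind", "free_h", "free_n",
             "dh", "dn") %in% names(profile)))
    stop("profile must come from simulate_bound_shifts()")
  if (!any(config$ratios == 0))
    stop("titration must include the zero ratio (free-state reference)")
  P <- config$protein_conc
  n <- nrow(profile)
  with_seed(config$seed, {
    lapply(config$ratios, function(r) {
      f <- fraction_bound(P, r * P, config$true_kd)
      h <- profile$free_h + f * profile$dh
      nn <- profile$free_n + f * profile$dn
      if (config$shift_noise > 0) {
        h <- h + stats::rnorm(n, 0, config$shift_noise)
        nn <- nn + stats::rnorm(n, 0, config$shift_noise / 0.14)
      }
      peak_table(profile$residue_index, profile$residue_kind, h, nn,
                 ratio_label = r)
    })
  })
}

#' Four-parameter logistic dose-response curve
#'
#' `y = m1 + (m2 - m1) / (1 + (x / m3)^m4)`: `m2` is the signal at zero
#' analyte, `m1` the signal at saturating analyte, `m3` the inflection
#' (EC50/IC50) and `m4` the slope factor.  At `x = m3` the curve passes
#' through the midpoint `(m1 + m2) / 2`.
#'
#' @param x concentrations (molar).
#' @param m1,m2,m3,m4 curve parameters (`m3 > 0`).
#' @return signal values.
#' @export
fourpl <- function(x, m1, m2, m3, m4) {
  m1 + (m2 - m1) / (1 + (x / m3)^m4)
}

#' Simulate a dose-response plate read
#'
#' Evaluates the four-parameter logistic on a serial-dilution concentration
#' grid and adds independent Gaussian noise per well.  With
#' `descending = TRUE` the competition design is emulated: the signal starts
#' at the full (bound) level and is driven down by the competitor, with
#' inflection at `config$ic50`.
#'
#' @param config a [simulation_config()].
#' @param descending simulate the competition (displacement) assay.
#' @param concentrations molar concentration grid; default a 12-point
#'   three-fold serial dilution centred on the inflection.
#' @param replicates wells per concentration.
#' @return a [plate_table()].
#' @export
simulate_plate <- function(config, descending = FALSE,
                           concentrations = NULL, replicates = 3L) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$plate_params
  if (descending)
    p <- c(m1 = unname(p["m2"]), m2 = unname(p["m1"]),
           m3 = unname(config$ic50), m4 = unname(p["m4"]))
  if (is.null(concentrations))
    concentrations <- p[["m3"]] * 3^seq(-6, 5)
  if (length(unique(concentrations)) < 5L)
    stop("need at least 5 distinct concentrations")
  if (all(concentrations == 0)) stop("all concentrations are zero")
  x <- rep(concentrations, each = replicates)
  repl <- rep(seq_len(replicates), times = length(concentrations))
  y0 <- fourpl(x, p[["m1"]], p[["m2"]], p[["m3"]], p[["m4"]])
  y <- if (config$plate_noise > 0)
    y0 + with_seed(config$seed,
                   stats::rnorm(length(x), 0, config$plate_noise))
  else y0
  plate_table(x, y, repl)
}
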