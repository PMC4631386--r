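# Chemical-shift-perturbation mapping: per-residue weighted Euclidean shift
# distances, peak tracking across titration points, and sigma-tier epitope
# classification.

#' Amide 15N weighting factor for CSP
#'
#' 0.14 for all residues except glycine, which uses 0.20.
#' @param residue_kind one-letter code(s).
#' @return numeric vector of alpha values.
#' @export
csp_alpha <- function(residue_kind) {
  ifelse(toupper(residue_kind) == "G", 0.20, 0.14)
}

#' Weighted 1H/15N chemical-shift perturbation
#'
#' `d = sqrt((dH^2 + (alpha * dN)^2) / 2)` with `alpha` from [csp_alpha()]:
#' the root-mean-square of the 1H shift change and the down-weighted 15N
#' shift change.
#'
#' @param dh,dn 1H and 15N shift differences (ppm), vectorized.
#' @param residue_kind one-letter code(s) selecting alpha.
#' @return CSP magnitude(s) in ppm.
#' @examples
#' compute_csp(0.05, 0.20, "A")
#' @export
compute_csp <- function(dh, dn, residue_kind = "A") {
  a <- csp_alpha(residue_kind)
  sqrt((dh^2 + (a * dn)^2) / 2)
}

#' CSP profile: per-residue shift distances with sigma tiers
#'
#' @param residue_index integer residue numbers.
#' @param d CSP magnitudes (ppm); `NA` for unassigned residues.
#' @param residue_kind one-letter codes (optional, used for labelling).
#' @param sigma population standard deviation of the assigned `d` values
#'   (computed if not supplied).
#' @return a data.frame of class `csp_profile` with columns
#'   `residue_index`, `residue_kind`, `d`, `tier` and attribute `sigma`.
#'   Tiers are `">=2sigma"`, `">=1sigma"`, `"<sigma"` (strict comparisons)
#'   and `"unassigned"` for residues without a CSP value.
#' @export
csp_profile <- function(residue_index, d, residue_kind = NA_character_,
                        sigma = NULL) {
  residue_index <- as.integer(residue_index)
  d <- as.numeric(d)
  if (any(d < 0, na.rm = TRUE)) stop("CSP distances must be >= 0")
  assigned <- !is.na(d)
  if (is.null(sigma)) {
    if (sum(assigned) < 2L)
      stop("sigma undefined: need at least 2 assigned residues")
    dv <- d[assigned]
    sigma <- sqrt(mean((dv - mean(dv))^2))  # population SD
  }
  tier <- rep("unassigned", length(d))
  tier[assigned] <- ifelse(d[assigned] > 2 * sigma, ">=2sigma",
                    ifelse(d[assigned] > sigma, ">=1sigma", "<sigma"))
  df <- data.frame(residue_index = residue_index,
                   residue_kind = residue_kind,
                   d = d, tier = tier, stringsAsFactors = FALSE)
  attr(df, "sigma") <- sigma
  class(df) <- c("csp_profile", "data.frame")
  df
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf("csp_profile: %d residues, sigma = %.5f ppm\n",
              nrow(x), attr(x, "sigma")))
  tab <- table(factor(x$tier,
                      levels = c(">=2sigma", ">=1sigma", "<sigma",
                                 "unassigned")))
  cat(sprintf("  >2sigma: %d   >sigma: %d   <=sigma: %d   unassigned: %d\n",
              tab[[1L]], tab[[2L]], tab[[3L]], tab[[4L]]))
  invisible(x)
}

#' Bar-plot of a CSP profile (unassigned residues as negative bars)
#'
#' @param x a [csp_profile()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot.csp_profile <- function(x, ...) {
  s <- attr(x, "sigma")
  h <- x$d
  h[is.na(h)] <- -0.25 * s  # negative-bar convention for unassigned
  graphics::barplot(h, names.arg = x$residue_index, border = NA,
                    col = ifelse(x$tier == ">=2sigma", "firebrick",
                          ifelse(x$tier == ">=1sigma", "orange",
                          ifelse(x$tier == "unassigned", "grey40",
                                 "grey75"))),
                    xlab = "residue", ylab = "CSP (ppm)", ...)
  graphics::abline(h = c(s, 2 * s), lty = c(2, 3))
  invisible(x)
}

#' Track peaks across a titration series
#'
#' Links each residue's assigned free-state peak through the titration by
#' stepwise nearest-neighbour matching in CSP-scaled `(dH, alpha * dN)`
#' space: later titration points are treated as unassigned peak positions,
#' as in a real experiment where only the free-state spectrum carries the
#' transferred assignment.  A step is ambiguous when the best and
#' second-best candidate peaks lie within a factor 2 in scaled distance;
#' ambiguous residues are reported as unassigned (the experimental
#' "cannot be unambiguously transferred" case).
#'
#' @param series list of [peak_table()]s ordered by ascending ratio; the
#'   first must be the fully assigned zero-ratio (free state) table.
#' @param ambiguity_factor trajectories whose best/second-best candidate
#'   distance ratio exceeds `1/ambiguity_factor` are marked ambiguous.
#' @return object of class `peak_trajectories`: list with `residue_index`,
#'   `residue_kind`, `ratios`, `h` and `n` (residue x ratio matrices,
#'   `NA` for ambiguous residues) and `ambiguous` (logical).
#' @export
track_peaks <- function(series, ambiguity_factor = 2) {
  if (!length(series)) stop("empty titration series")
  ratios <- vapply(series, attr, numeric(1L), "ratio")
  if (is.unsorted(ratios)) stop("series must be ordered by ascending ratio")
  if (ratios[1L] != 0) stop("series must start with the zero-ratio table")
  free <- series[[1L]]
  nres <- nrow(free)
  a <- csp_alpha(free$residue_kind)
  H <- matrix(NA_real_, nres, length(series))
  N <- matrix(NA_real_, nres, length(series))
  H[, 1L] <- free$h_shift
  N[, 1L] <- free$n_shift
  ambiguous <- rep(FALSE, nres)
  for (t in seq_along(series)[-1L]) {
    tab <- series[[t]]
    for (i in seq_len(nres)) {
      if (ambiguous[i]) next
      dh <- tab$h_shift - H[i, t - 1L]
      dn <- (tab$n_shift - N[i, t - 1L]) * a[i]
      dd <- sqrt(dh^2 + dn^2)
      o <- order(dd)
      best <- o[1L]
      if (length(dd) > 1L && dd[o[2L]] < ambiguity_factor * dd[o[1L]]) {
        ambiguous[i] <- TRUE
        next
      }
      H[i, t] <- tab$h_shift[best]
      N[i, t] <- tab$n_shift[best]
    }
  }
  H[ambiguous, -1L] <- NA
  N[ambiguous, -1L] <- NA
  structure(list(residue_index = free$residue_index,
                 residue_kind = free$residue_kind,
                 ratios = ratios, h = H, n = N, ambiguous = ambiguous),
            class = "peak_trajectories")
}

#' @export
print.peak_trajectories <- function(x, ...) {
  cat(sprintf("peak_trajectories: %d residues x %d titration points (%d ambiguous)\n",
              length(x$residue_index), length(x$ratios), sum(x$ambiguous)))
  invisible(x)
}

#' CSP profile from tracked trajectories
#'
#' CSP of each residue between the free state and the final titration
#' point; ambiguous residues become `NA` (unassigned).
#'
#' @param traj a [track_peaks()] result.
#' @return a [csp_profile()].
#' @export
csp_from_trajectories <- function(traj) {
  stopifnot(inherits(traj, "peak_trajectories"))
  last <- length(traj$ratios)
  dh <- traj$h[, last] - traj$h[, 1L]
  dn <- traj$n[, last] - traj$n[, 1L]
  d <- compute_csp(dh, dn, traj$residue_kind)
  csp_profile(traj$residue_index, d, traj$residue_kind)
}

#' CSP profile between two assigned peak tables
#'
#' Matches residues by index between a free-state and a bound-state (or
#' saturated titration endpoint) table and computes per-residue CSPs.
#' Residues present in the free table but missing from the bound table are
#' reported unassigned.
#'
#' @param free,bound [peak_table()]s sharing residue indices.
#' @return a [csp_profile()].
#' @export
csp_between <- function(free, bound) {
  stopifnot(inherits(free, "peak_table"), inherits(bound, "peak_table"))
  m <- match(free$residue_index, bound$residue_index)
  dh <- bound$h_shift[m] - free$h_shift
  dn <- bound$n_shift[m] - free$n_shift
  d <- compute_csp(dh, dn, free$residue_kind)
  csp_profile(free$residue_index, d, free$residue_kind)
}

#' Classify the binding epitope by sigma tiers
#'
#' Computes the population standard deviation sigma of all assigned CSP
#' values and splits residues into the strict tiers `d > 2 sigma`,
#' `sigma < d <= 2 sigma`, `d <= sigma`, plus the unassigned list.
#'
#' @param profile a [csp_profile()] (sigma is recomputed from its `d`).
#' @return list with `sigma` and integer vectors `over_2sigma`,
#'   `over_1sigma` (exclusive of the 2-sigma tier), `below_sigma`,
#'   `unassigned`.
#' @export
classify_epitope <- function(profile) {
  stopifnot(inherits(profile, "csp_profile"))
  assigned <- !is.na(profile$d)
  if (sum(assigned) < 2L)
    stop("sigma undefined: need at least 2 assigned residues")
  prof <- csp_profile(profile$residue_index, profile$d,
                      profile$residue_kind)
  list(sigma = attr(prof, "sigma"),
       over_2sigma = prof$residue_index[prof$tier == ">=2sigma"],
       over_1sigma = prof$residue_index[prof$tier == ">=1sigma"],
       below_sigma = prof$residue_index[prof$tier == "<sigma"],
       unassigned = prof$residue_index[prof$tier == "unassigned"])
}
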