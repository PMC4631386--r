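# Binding models: single-site fast-exchange K_D fitting of HSQC titration
# trajectories, and four-parameter logistic fitting of plate dose-response
# data.

#' Bound fraction of the observed protein under single-site binding
#'
#' Exact mass-balance solution with ligand depletion,
#' `f = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 P)`,
#' valid when the protein concentration is comparable to K_D (the
#' large-excess approximation `f = L / (L + Kd)` is not).
#'
#' @param P protein concentration (molar, > 0).
#' @param L total ligand concentration (molar, >= 0), vectorized.
#' @param kd dissociation constant (molar, > 0).
#' @return bound fraction(s) in `[0, 1]`.
#' @examples
#' fraction_bound(55e-6, 55e-6, 60e-6)  # ~0.367
#' @export
fraction_bound <- function(P, L, kd) {
  if (any(P <= 0)) stop("P must be > 0")
  if (any(L < 0)) stop("L must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  s <- P + L + kd
  disc <- pmax(s^2 - 4 * P * L, 0)
  f <- (s - sqrt(disc)) / (2 * P)
  pmin(pmax(f, 0), 1)
}

#' Fit a global K_D to fast-exchange titration trajectories
#'
#' Under fast exchange the observed peak position of residue `i` at
#' titration point `t` is the population-weighted average
#' `obs_it = c_i + f_bound(P, L_t, Kd) * b_i` in each shift dimension,
#' with one K_D shared by all residues, a per-residue free-state position
#' `c_i` and a per-residue bound-state displacement `b_i`.  The free-state
#' position is fitted rather than fixed at the zero-ratio measurement:
#' anchoring on the (noisy) reference point would correlate the errors of
#' all later points and bias K_D low.  For fixed K_D both `c_i` and `b_i`
#' solve in closed form, so the fit profiles the residual sum of squares
#' over log10(K_D) from several log-spaced starts.  15N displacements
#' enter scaled by alpha (as in the CSP metric) so both dimensions are
#' commensurate.
#'
#' Residues whose largest scaled displacement is below `min_shift` can be
#' excluded from the fit; with the free-intercept model this guard is not
#' needed for unbiasedness and defaults to 0.  A fit with zero usable
#' residues or a boundary/flat optimum is flagged `converged = FALSE`
#' rather than raising an error.
#'
#' @param traj a [track_peaks()] result (or anything sharing its fields).
#' @param P protein concentration (molar).
#' @param min_shift optional identifiability guard in ppm (0 disables).
#' @param kd_range search interval for K_D (molar).
#' @param n_starts number of log-spaced starting values.
#' @param conf_level confidence level of the profile interval on K_D.
#' @return object of class `kd_fit`: list with `kd`, `kd_ci`,
#'   `bound_shift` (per-residue dH, dN at full saturation), `residual_rms`
#'   (ppm), `converged`, `n_residues`, `profile` (RSS profile data.frame).
#' @export
fit_kd_fast_exchange <- function(traj, P, min_shift = 0,
                                 kd_range = c(1e-9, 1e-1),
                                 n_starts = 8L, conf_level = 0.95) {
  stopifnot(inherits(traj, "peak_trajectories") ||
              all(c("ratios", "h", "n", "residue_kind",
                    "residue_index") %in% names(traj)))
  ratios <- traj$ratios
  if (length(ratios) < 3L) stop("need at least 3 titration points")
  if (P <= 0) stop("P must be > 0")
  L <- ratios * P
  a <- csp_alpha(traj$residue_kind)
  H <- traj$h
  N <- traj$n * a
  span <- pmax(apply(H, 1L, function(x) diff(range(x))),
               apply(N, 1L, function(x) diff(range(x))))
  usable <- stats::complete.cases(H) & stats::complete.cases(N) &
    span > min_shift & span > 0
  empty_fit <- function() {
    structure(list(kd = NA_real_, kd_ci = c(NA_real_, NA_real_),
                   bound_shift = NULL, residual_rms = NA_real_,
                   converged = FALSE, n_residues = 0L, profile = NULL,
                   P = P, ratios = ratios),
              class = "kd_fit")
  }
  if (!any(usable)) return(empty_fit())
  H <- H[usable, , drop = FALSE]
  N <- N[usable, , drop = FALSE]
  nres <- nrow(H)
  nt <- length(ratios)
  Hc <- H - rowMeans(H)
  Nc <- N - rowMeans(N)
  # for fixed kd: per-residue intercept + slope solve by linear regression
  # on the bound-fraction curve
  fit_at <- function(log10kd) {
    f <- fraction_bound(P, L, 10^log10kd)
    fc <- f - mean(f)
    vf <- sum(fc^2)
    if (vf < 1e-30)
      return(list(rss = sum(Hc^2) + sum(Nc^2), bh = rep(0, nres),
                  bn = rep(0, nres), f = f))
    bh <- as.numeric(Hc %*% fc) / vf
    bn <- as.numeric(Nc %*% fc) / vf
    rss <- sum((Hc - bh %*% t(fc))^2) + sum((Nc - bn %*% t(fc))^2)
    list(rss = rss, bh = bh, bn = bn, f = f)
  }
  rss_at <- function(log10kd) fit_at(log10kd)$rss
  lo <- log10(kd_range[1L]); hi <- log10(kd_range[2L])
  starts <- seq(lo, hi, length.out = n_starts)
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, rss_at, method = "L-BFGS-B", lower = lo, upper = hi)
    if (is.null(best) || o$value < best$value) best <- o
  }
  log10kd <- best$par
  kd <- 10^log10kd
  sol <- fit_at(log10kd)
  rss <- best$value
  residual_rms <- sqrt(rss / (2L * nres * nt))
  nobs <- 2L * nres * nt
  npar <- 4L * nres + 1L   # intercept + slope per residue per dimension
  dfree <- max(nobs - npar, 1L)
  probe <- c(rss_at(log10kd - 0.5), rss_at(log10kd + 0.5))
  flat <- all(abs(probe - rss) <= 1e-12 * max(rss, 1e-300)) || !is.finite(rss)
  at_bound <- log10kd <= lo + 1e-6 || log10kd >= hi - 1e-6
  converged <- best$convergence == 0 && !flat && !at_bound
  grid <- seq(lo, hi, length.out = 121L)
  prof <- vapply(grid, rss_at, numeric(1L))
  ci <- c(NA_real_, NA_real_)
  if (converged && rss > 0) {
    thr <- rss * (1 + stats::qf(conf_level, 1L, dfree) / dfree)
    inside <- grid[prof <= thr]
    if (length(inside)) ci <- 10^range(inside)
  }
  bs <- data.frame(residue_index = traj$residue_index[usable],
                   dh = sol$bh, dn = sol$bn / a[usable])
  structure(list(kd = kd, kd_ci = ci, bound_shift = bs,
                 residual_rms = residual_rms, converged = converged,
                 n_residues = nres,
                 profile = data.frame(kd = 10^grid, rss = prof),
                 P = P, ratios = ratios),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (!x$converged && is.na(x$kd)) {
    cat("kd_fit: non-identifiable (no usable residue trajectories)\n")
    return(invisible(x))
  }
  cat(sprintf("kd_fit: K_D = %.3g M%s, %d residues, residual RMS %.2g ppm%s\n",
              x$kd,
              if (all(is.finite(x$kd_ci)))
                sprintf(" (CI %.3g-%.3g)", x$kd_ci[1L], x$kd_ci[2L]) else "",
              x$n_residues, x$residual_rms,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.kd_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$bound_shift)) {
    cat("per-residue saturating displacements (ppm):\n")
    print(utils::head(object$bound_shift, 10L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.kd_fit <- function(object, ...) c(kd = object$kd)

#' Predicted scaled displacement of one residue along the titration
#' @export
predict.kd_fit <- function(object, ratios = object$ratios, ...) {
  f <- fraction_bound(object$P, ratios * object$P, object$kd)
  out <- list()
  if (!is.null(object$bound_shift)) {
    out <- lapply(seq_len(nrow(object$bound_shift)), function(i)
      cbind(dh = f * object$bound_shift$dh[i],
            dn = f * object$bound_shift$dn[i]))
    names(out) <- object$bound_shift$residue_index
  }
  out
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares of `y = m1 + (m2 - m1) / (1 + (x/m3)^m4)`
#' (see [fourpl()]) via Levenberg-Marquardt with multi-start
#' initialization: `m3` starts on a log-spaced grid spanning the observed
#' concentrations, `m2`/`m1` from the low/high-concentration signal means,
#' `m4` from {0.5, 1, 2}.  Flat (constant-signal) data are flagged
#' non-identifiable instead of raising an error.
#'
#' @param plate a [plate_table()] (needs >= 5 distinct concentrations).
#' @param descending declare the curve a competition (displacement) curve;
#'   recorded and validated by [ic50_from_fit()].
#' @return object of class `fourpl_fit`: list with `par` (named m1..m4),
#'   `residual_rms`, `converged`, `descending`, `data`.
#' @export
fit_4pl <- function(plate, descending = FALSE) {
  stopifnot(inherits(plate, "plate_table"))
  x <- plate$concentration
  y <- plate$signal
  if (length(unique(x)) < 5L)
    stop("need at least 5 distinct concentrations to fit a 4PL")
  ylo <- mean(y[x <= stats::quantile(x, 0.2)])
  yhi <- mean(y[x >= stats::quantile(x, 0.8)])
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    return(structure(list(par = c(m1 = NA_real_, m2 = NA_real_,
                                  m3 = NA_real_, m4 = NA_real_),
                          residual_rms = NA_real_, converged = FALSE,
                          descending = descending, data = plate),
                     class = "fourpl_fit"))
  }
  xp <- x[x > 0]
  m3_grid <- exp(seq(log(min(xp)), log(max(xp)), length.out = 7L))
  best <- NULL
  for (m3s in m3_grid) for (m4s in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fourpl(x, m1, m2, m3, m4),
        start = list(m1 = yhi, m2 = ylo, m3 = m3s, m4 = m4s),
        lower = c(-Inf, -Inf, min(xp) / 1e3, 0.05),
        upper = c(Inf, Inf, max(xp) * 1e3, 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(par = c(m1 = NA_real_, m2 = NA_real_,
                                  m3 = NA_real_, m4 = NA_real_),
                          residual_rms = NA_real_, converged = FALSE,
                          descending = descending, data = plate),
                     class = "fourpl_fit"))
  }
  p <- stats::coef(best$fit)
  structure(list(par = c(m1 = unname(p["m1"]), m2 = unname(p["m2"]),
                         m3 = unname(p["m3"]), m4 = unname(p["m4"])),
                 residual_rms = sqrt(best$rss / length(y)),
                 converged = TRUE, descending = descending, data = plate),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("fourpl_fit: non-identifiable (flat or unfittable data)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "fourpl_fit%s: m1 = %.4g, m2 = %.4g, m3 = %.4g M, m4 = %.3g (RMS %.3g)\n",
    if (x$descending) " [competition]" else "",
    x$par["m1"], x$par["m2"], x$par["m3"], x$par["m4"], x$residual_rms))
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) object$par

#' @export
predict.fourpl_fit <- function(object, concentrations = NULL, ...) {
  if (is.null(concentrations)) concentrations <- object$data$concentration
  p <- object$par
  fourpl(concentrations, p["m1"], p["m2"], p["m3"], p["m4"])
}

#' @export
plot.fourpl_fit <- function(x, ...) {
  d <- x$data
  xs <- d$concentration
  graphics::plot(xs, d$signal, log = "x", xlab = "concentration (M)",
                 ylab = "signal", ...)
  if (x$converged) {
    g <- exp(seq(log(min(xs[xs > 0])), log(max(xs)), length.out = 200L))
    graphics::lines(g, predict(x, g), col = "firebrick")
    graphics::abline(v = x$par["m3"], lty = 2)
  }
  invisible(x)
}

#' Half-maximal displacement concentration from a competition fit
#'
#' Returns the inflection `m3` of a fitted descending (competition) curve,
#' i.e. the IC50.  A curve fitted without the competition flag, or one that
#' rises with concentration, is rejected.
#'
#' @param fit a [fit_4pl()] result with `descending = TRUE`.
#' @return IC50 in molar.
#' @export
ic50_from_fit <- function(fit) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) stop("cannot extract IC50 from a non-converged fit")
  if (!fit$descending)
    stop("fit was not declared a competition curve; IC50 undefined")
  if (fit$par["m1"] >= fit$par["m2"])
    stop("curve is ascending (m1 >= m2): not a displacement curve")
  unname(fit$par["m3"])
}
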