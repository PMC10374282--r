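#' Small-angle X-ray scattering curve
#'
#' @param q scattering vector, increasing; unit tagged.
#' @param i intensity I(q).
#' @param sigma positive uncertainties.
#' @param unit `"A-1"` or `"nm-1"` (explicit tagging; conversions via
#'   [convert_q_unit()]).
#' @param conc optional concentration in mg/mL.
#' @export
saxs_curve <- function(q, i, sigma = NULL, unit = c("A-1", "nm-1"),
                       conc = NULL) {
  unit <- match.arg(unit)
  if (any(diff(q) <= 0)) stop("q must be increasing")
  if (!is.null(sigma) && any(sigma <= 0)) stop("sigma must be positive")
  structure(list(q = q, i = i, sigma = sigma, unit = unit, conc = conc),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("saxs_curve: %d points, q = %.4g..%.4g %s%s\n",
              length(x$q), min(x$q), max(x$q), x$unit,
              if (is.null(x$conc)) "" else sprintf(", c = %g mg/mL", x$conc)))
  invisible(x)
}

#' Convert the q unit of a SAXS curve
#' @param curve a [saxs_curve()].
#' @param unit target unit.
#' @export
convert_q_unit <- function(curve, unit = c("A-1", "nm-1")) {
  unit <- match.arg(unit)
  if (unit == curve$unit) return(curve)
  f <- if (unit == "nm-1") 10 else 0.1
  saxs_curve(curve$q * f, curve$i, curve$sigma, unit = unit,
             conc = curve$conc)
}

#' Debye forward scattering of a bead model
#'
#' \eqn{I(q) = \sum_{ij} b_i b_j \, \mathrm{sinc}(q r_{ij})}, the exact
#' orientational average of a point-bead model. `I(0)` equals
#' \eqn{(\sum b_i)^2}.
#'
#' @param structure a [coarse_structure()] (coordinates in Angstrom).
#' @param q scattering vector grid in 1/Angstrom.
#' @return a [saxs_curve()] (unit `"A-1"`).
#' @export
debye_scattering <- function(structure, q) {
  b <- structure$weight
  n <- length(b)
  if (n == 1) return(saxs_curve(q, rep(b^2, length(q)), unit = "A-1"))
  d <- as.vector(stats::dist(structure$xyz))
  bp <- utils::combn(n, 2)
  bpw <- b[bp[1, ]] * b[bp[2, ]]
  saxs_curve(q, cpp_debye(q, d, bpw, sum(b^2)), unit = "A-1")
}

#' Guinier fit and Kratky transform
#'
#' Linear fit of \eqn{\ln I} vs \eqn{q^2} in the Guinier window
#' (\eqn{q R_g < } `qrg_max`, found iteratively), returning the radius of
#' gyration, forward scattering and the Kratky transform \eqn{q^2 I(q)}.
#'
#' @param curve a [saxs_curve()].
#' @param qrg_max Guinier window limit (default 1.3).
#' @return list with `rg`, `i0`, `n_window`, `kratky` (data.frame q,
#'   q2i); radius in the reciprocal of the q unit.
#' @export
guinier_kratky <- function(curve, qrg_max = 1.3) {
  q <- curve$q; i <- curve$i
  ok <- i > 0
  rg <- NA_real_
  sel <- ok
  for (it in 1:20) {
    fit <- stats::lm(log(i[sel]) ~ I(q[sel]^2))
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0) stop("no Guinier decay found")
    rg_new <- sqrt(-3 * slope)
    sel2 <- ok & q * rg_new < qrg_max
    if (sum(sel2) < 5) stop("insufficient points in the Guinier window")
    if (!is.na(rg) && abs(rg_new - rg) < 1e-6 * rg) { rg <- rg_new; break }
    rg <- rg_new; sel <- sel2
  }
  fit <- stats::lm(log(i[sel]) ~ I(q[sel]^2))
  rg <- sqrt(-3 * stats::coef(fit)[[2]])
  list(rg = rg, i0 = exp(stats::coef(fit)[[1]]), n_window = sum(sel),
       kratky = data.frame(q = q, q2i = q^2 * i))
}

#' Extrapolate a SAXS concentration series to infinite dilution
#'
#' Per-q linear extrapolation of `I(q,c)/c` vs `c` to c = 0, removing the
#' interparticle structure factor; following common practice the
#' extrapolated values are kept at low q and replaced by the (scaled)
#' highest-concentration data above `q_merge`, where S(q) ~ 1 but the
#' high-concentration statistics are better.
#'
#' @param series list of [saxs_curve()]s with `conc` set (>= 2, common
#'   unit).
#' @param q_merge merge boundary in the series' q unit (`NULL` = no
#'   merging, pure extrapolation).
#' @return a [saxs_curve()] of the form factor I(q, c -> 0) per unit
#'   concentration.
#' @export
extrapolate_form_factor <- function(series, q_merge = NULL) {
  if (length(series) < 2) stop("need at least two concentrations")
  cs <- vapply(series, function(s) s$conc %||% NA_real_, numeric(1))
  if (anyNA(cs)) stop("every curve needs a concentration")
  units <- vapply(series, function(s) s$unit, character(1))
  if (length(unique(units)) != 1) stop("q units differ across the series")
  qlo <- max(vapply(series, function(s) min(s$q), numeric(1)))
  qhi <- min(vapply(series, function(s) max(s$q), numeric(1)))
  if (qlo >= qhi) stop("q ranges of the series do not overlap")
  qq <- series[[which.max(cs)]]$q
  qq <- qq[qq >= qlo & qq <= qhi]
  Ic <- vapply(series, function(s) stats::approx(s$q, s$i, qq)$y / s$conc,
               numeric(length(qq)))
  # per-q linear extrapolation to c = 0 (rank-deficient designs, e.g.
  # repeated concentrations, fall back to the plain mean: zero slope)
  X <- cbind(1, cs)
  qrX <- qr(X)
  i0 <- if (qrX$rank < 2) rowMeans(Ic)
        else drop(qr.coef(qrX, t(Ic))[1, ])
  if (!is.null(q_merge)) {
    hi <- which.max(cs)
    ih <- stats::approx(series[[hi]]$q, series[[hi]]$i, qq)$y / cs[hi]
    sel <- qq > q_merge
    if (any(sel) && any(!sel)) {
      # scale the high-c data onto the extrapolation in the overlap decade
      ov <- qq > q_merge * 0.7 & qq <= q_merge
      sc <- if (any(ov)) sum(i0[ov] * ih[ov]) / sum(ih[ov]^2) else 1
      i0[sel] <- ih[sel] * sc
    }
  }
  saxs_curve(qq, i0, unit = units[1])
}

#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic solution for monodisperse hard spheres of radius `r_hs` at
#' volume fraction `phi`; optionally applies the decoupling correction
#' for particle asymmetry, \eqn{S'(q) = 1 + \beta(q) (S(q) - 1)}.
#'
#' @param q scattering vector (reciprocal of the unit of `r_hs`).
#' @param r_hs hard-sphere radius.
#' @param phi volume fraction in [0, 0.74).
#' @param beta optional decoupling factor \eqn{\beta(q)} in [0, 1]
#'   (vector over q).
#' @return S(q) values; `S(0) = (1-phi)^4 / (1+2 phi)^2`.
#' @export
py_structure_factor <- function(q, r_hs, phi, beta = NULL) {
  if (r_hs <= 0) stop("hard-sphere radius must be positive")
  if (phi < 0 || phi >= 0.74) stop("phi must lie in [0, 0.74)")
  if (phi == 0) return(rep(1, length(q)))
  al <- (1 + 2 * phi)^2 / (1 - phi)^4
  be <- -6 * phi * (1 + phi / 2)^2 / (1 - phi)^4
  ga <- phi * al / 2
  A <- 2 * q * r_hs
  G <- function(A) {
    al * (sin(A) - A * cos(A)) / A^2 +
      be * (2 * A * sin(A) + (2 - A^2) * cos(A) - 2) / A^3 +
      ga * (-A^4 * cos(A) + 4 * ((3 * A^2 - 6) * cos(A) +
                                   (A^3 - 6 * A) * sin(A) + 6)) / A^5
  }
  GA_over_A <- numeric(length(A))
  big <- A > 0.05
  GA_over_A[big] <- G(A[big]) / A[big]
  # small-A series limit: G(A)/A -> alpha/3 + beta/4 + gamma/6
  GA_over_A[!big] <- al / 3 + be / 4 + ga / 6
  S <- 1 / (1 + 24 * phi * GA_over_A)
  if (!is.null(beta)) S <- 1 + beta * (S - 1)
  S
}

#' Reduced chi-square of a SAXS model against data
#'
#' Interpolates the model onto the data grid, fits scale and constant
#' offset analytically (affine invariance), and divides the residual sum
#' of squares by `N - 2` or by a Shannon-channel-deflated number of
#' degrees of freedom when the particle diameter `dmax` is supplied
#' (\eqn{N_s = \Delta q\, D_{max} / \pi}).
#'
#' @param model,data [saxs_curve()]s in the same q unit; `data` must
#'   carry uncertainties.
#' @param dmax optional maximal particle dimension (reciprocal unit of
#'   q) enabling the Shannon mode.
#' @return list with `chi2r`, `chi2`, `scale`, `offset`, `dof`,
#'   `n_shannon` (NA without `dmax`).
#' @export
chi2_saxs <- function(model, data, dmax = NULL) {
  if (model$unit != data$unit) stop("q units differ; convert first")
  if (is.null(data$sigma)) stop("data uncertainties required")
  if (any(!is.finite(data$sigma)) || any(data$sigma <= 0))
    stop("degenerate sigma")
  m <- stats::approx(model$q, model$i, data$q, rule = 2)$y
  w <- 1 / data$sigma^2
  y <- data$i
  # minimize sum w (s m + b - y)^2 analytically
  sw <- sum(w); swm <- sum(w * m); swy <- sum(w * y)
  swmm <- sum(w * m^2); swmy <- sum(w * m * y)
  det <- swmm * sw - swm^2
  s <- (swmy * sw - swm * swy) / det
  b <- (swmm * swy - swm * swmy) / det
  chi2 <- sum(w * (s * m + b - y)^2)
  n_s <- if (is.null(dmax)) NA_real_
         else (max(data$q) - min(data$q)) * dmax / pi
  dof <- if (is.null(dmax)) length(y) - 2 else max(1, ceiling(n_s) - 2)
  list(chi2r = chi2 / dof, chi2 = chi2, scale = s, offset = b, dof = dof,
       n_shannon = n_s)
}

#' Two-state ensemble fit of a SAXS curve
#'
#' Fits the population fraction `x` of component M1 in a two-state
#' mixture `x I_M1 + (1-x) I_M2` against data, profiling chi-square over
#' a fraction grid with scale/offset refit at each point, and reports the
#' 68 percent confidence interval from the chi-square profile.
#'
#' @param curve_m1,curve_m2 component model [saxs_curve()]s.
#' @param data experimental [saxs_curve()] with uncertainties.
#' @param dmax optional Shannon-channel dof correction (see
#'   [chi2_saxs()]).
#' @param nx fraction grid resolution.
#' @return object of class `ensemble_fit`: `x` (fraction of M1), `chi2r`,
#'   `interval` (68 percent), `profile` (data.frame x, chi2), `boundary`
#'   flag, and the flat-profile flag `degenerate`.
#' @export
two_state_fit <- function(curve_m1, curve_m2, data, dmax = NULL, nx = 201) {
  xs <- seq(0, 1, length.out = nx)
  prof <- vapply(xs, function(x) {
    mix <- saxs_curve(curve_m1$q,
                      x * curve_m1$i + (1 - x) *
                        stats::approx(curve_m2$q, curve_m2$i, curve_m1$q,
                                      rule = 2)$y,
                      unit = curve_m1$unit)
    chi2_saxs(mix, data, dmax = dmax)$chi2
  }, numeric(1))
  best <- which.min(prof)
  degenerate <- diff(range(prof)) < 1e-9 * (max(prof) + 1)
  thresh <- prof[best] + stats::qchisq(0.68, 1)
  inside <- xs[prof <= thresh]
  res <- chi2_saxs(saxs_curve(curve_m1$q,
                              xs[best] * curve_m1$i + (1 - xs[best]) *
                                stats::approx(curve_m2$q, curve_m2$i,
                                              curve_m1$q, rule = 2)$y,
                              unit = curve_m1$unit), data, dmax = dmax)
  structure(list(x = xs[best], chi2r = res$chi2r, chi2 = res$chi2,
                 dof = res$dof,
                 interval = range(inside),
                 profile = data.frame(x = xs, chi2 = prof),
                 boundary = best %in% c(1L, nx),
                 degenerate = degenerate),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("ensemble_fit: x_M1 = %.3f [%.3f, %.3f], chi2_r = %.3f%s%s\n",
              x$x, x$interval[1], x$interval[2], x$chi2r,
              if (x$boundary) " [at boundary]" else "",
              if (x$degenerate) " [flat profile]" else ""))
  invisible(x)
}
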