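#' Time-correlated single photon counting decay histogram
#'
#' @param time time grid in ns, strictly increasing, uniform channel width.
#' @param counts photon counts per channel (non-negative).
#' @param irf optional instrument response on the same grid.
#' @param linearization optional smoothed room-light reference used as a
#'   multiplicative channel-linearization curve.
#' @return object of class `decay_curve`.
#' @export
decay_curve <- function(time, counts, irf = NULL, linearization = NULL) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) stop("channel width must be uniform")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(irf) && length(irf) != length(time))
    stop("IRF must share the decay's time grid")
  if (!is.null(linearization) && length(linearization) != length(time))
    stop("linearization curve must share the decay's time grid")
  structure(list(time = time, counts = counts, dt = dt[1], irf = irf,
                 linearization = linearization,
                 total = sum(counts)),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("decay_curve: %d channels x %.4g ns, %.3g counts%s\n",
              length(x$time), x$dt, x$total,
              if (is.null(x$irf)) "" else ", IRF attached"))
  invisible(x)
}

#' Multi-exponential fluorophore reference decay
#'
#' Species fractions and lifetimes of a donor or acceptor reference sample
#' measured without FRET, describing its (possibly complex) intrinsic decay
#' \eqn{f(t) = \sum_i x_i \exp(-t/\tau_i)}.
#'
#' @param fractions species fractions (non-negative, normalized to 1).
#' @param lifetimes lifetimes in ns (positive).
#' @param role `"donor"` or `"acceptor"`.
#' @export
fluorophore_reference <- function(fractions, lifetimes,
                                  role = c("donor", "acceptor")) {
  role <- match.arg(role)
  if (length(fractions) != length(lifetimes)) stop("length mismatch")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (any(lifetimes <= 0)) stop("lifetimes must be positive")
  structure(list(fractions = fractions / sum(fractions),
                 lifetimes = lifetimes, role = role),
            class = "fluorophore_reference")
}

reference_decay <- function(ref, t) {
  drop(exp(-outer(t, 1 / ref$lifetimes)) %*% ref$fractions)
}

#' Species-averaged lifetime of a reference
#' @param ref a [fluorophore_reference()].
#' @export
species_average_lifetime <- function(ref) sum(ref$fractions * ref$lifetimes)

#' Two-Gaussian donor-acceptor distance model
#'
#' Superposition of two normal distance components with a common width,
#' plus a FRET-inactive fraction. Following the convention of the decay
#' model, the width `w` parameterizes components
#' \eqn{\exp(-2 (R - \bar R)^2 / w^2)}, i.e. a Gaussian SD of `w / 2`.
#'
#' @param mean1,mean2 component mean distances in Angstrom.
#' @param width common width `w` in Angstrom (SD = w/2).
#' @param x1 fraction of the first component, in `[0, 1]`.
#' @param x_donly FRET-inactive (donor-only) fraction, in `[0, 1]`.
#' @param R0 Forster radius in Angstrom (default 52).
#' @param tau0 unquenched fluorescence lifetime in ns (default 4);
#'   `k0 = 1/tau0` is the rate scale of the FRET rate constant.
#' @export
gaussian_mixture_distance <- function(mean1, mean2 = mean1, width = 12,
                                      x1 = 1, x_donly = 0, R0 = 52,
                                      tau0 = 4) {
  if (width <= 0) stop("width must be positive")
  if (x1 < 0 || x1 > 1 || x_donly < 0 || x_donly > 1)
    stop("x1 and x_donly must lie in [0, 1]")
  if (mean1 <= 0 || mean2 <= 0) stop("mean distances must be positive")
  structure(list(mean1 = mean1, mean2 = mean2, width = width, x1 = x1,
                 x_donly = x_donly, R0 = R0, tau0 = tau0),
            class = "gaussian_mixture_distance")
}

#' Default distance quadrature grid (0.5 A steps over 10-150 A)
#' @export
default_distance_grid <- function() seq(10, 150, by = 0.5)

# Eq-13-style density on a grid, truncated below 1 A and renormalized.
mixture_density <- function(model, r) {
  w <- model$width
  p <- model$x1 * exp(-2 * (r - model$mean1)^2 / w^2) +
    (1 - model$x1) * exp(-2 * (r - model$mean2)^2 / w^2)
  p[r <= 1] <- 0
  p / pracma::trapz(r, p)
}

#' FRET-induced donor decay
#'
#' The ratio of the donor decay with and without acceptor,
#' \eqn{\epsilon_D(t) = (1 - x_{DOnly}) \int p(R)\,
#' e^{-t k_0 (R_0/R)^6} dR + x_{DOnly}}, evaluated on a time grid. The
#' distance density is normalized before applying the donor-only offset,
#' so \eqn{\epsilon_D(0) = 1} and \eqn{\epsilon_D \to x_{DOnly}}.
#'
#' @param dist a [gaussian_mixture_distance()] (carries its own R0/tau0 and
#'   x_donly) or a [distance_distribution()].
#' @param t time grid in ns.
#' @param R0,tau0,x_donly used when `dist` is a bare distance distribution.
#' @param r quadrature grid (defaults to [default_distance_grid()]).
#' @return numeric vector \eqn{\epsilon_D(t)}.
#' @export
fret_induced_donor_decay <- function(dist, t, R0 = 52, tau0 = 4,
                                     x_donly = 0,
                                     r = default_distance_grid()) {
  if (inherits(dist, "gaussian_mixture_distance")) {
    R0 <- dist$R0; tau0 <- dist$tau0; x_donly <- dist$x_donly
    p <- mixture_density(dist, r)
  } else if (inherits(dist, "distance_distribution")) {
    if (any(dist$p < 0)) stop("negative density")
    r <- dist$r
    p <- dist$p / pracma::trapz(r, dist$p)
  } else stop("unsupported distance model")
  if (x_donly == 1) return(rep(1, length(t)))
  k <- (1 / tau0) * (R0 / r)^6
  # trapezoid weights on the distance grid
  dr <- c(diff(r) / 2, 0) + c(0, diff(r) / 2)
  eps <- exp(-outer(t, k)) %*% (p * dr)
  drop((1 - x_donly) * eps + x_donly)
}

#' Donor decay quenched by FRET
#'
#' Pointwise product of the multi-exponential donor reference decay and the
#' FRET-induced donor decay (quasi-static homogeneous approximation: every
#' donor species is quenched by the same FRET-rate distribution).
#'
#' @param ref donor [fluorophore_reference()].
#' @param t time grid in ns.
#' @param eps \eqn{\epsilon_D(t)} on the same grid.
#' @export
donor_decay_with_fret <- function(ref, t, eps) {
  if (length(eps) != length(t)) stop("time grid mismatch")
  reference_decay(ref, t) * eps
}

#' Causal linear convolution on a uniform grid
#'
#' FFT-based non-circular (causal) convolution of two signals sampled
#' with channel width `dt`; the channel-width scaling makes the discrete
#' sum a Riemann approximation of the continuous convolution integral.
#' A discrete delta (`1/dt` in the first channel) is the identity.
#'
#' @param f,h signals on the same uniform grid.
#' @param dt channel width (the integral scaling; use 1 for a purely
#'   discrete convolution).
#' @export
convolve_causal <- function(f, h, dt = 1) {
  n <- length(f)
  if (length(h) != n) stop("signals must share the grid")
  convolve_discrete(f, h) * dt
}

#' FRET-sensitized acceptor decay
#'
#' Convolution of the FRET-quenched donor decay with the acceptor
#' reference decay (the acceptor is pumped by the transfer events).
#'
#' @param donor_fret quenched donor decay \eqn{f_{D|D(DA)}(t)} on grid `t`.
#' @param acceptor_ref acceptor [fluorophore_reference()].
#' @param t uniform time grid in ns.
#' @export
acceptor_sensitized_decay <- function(donor_fret, acceptor_ref, t) {
  if (length(donor_fret) != length(t)) stop("time grid mismatch")
  dt <- t[2] - t[1]
  convolve_causal(donor_fret, reference_decay(acceptor_ref, t), dt)
}

#' Instrument model for a measured TCSPC histogram
#'
#' \eqn{g(t) = N_F \, f(t) \otimes IRF(t) + N_{BG} IRF(t) + bg}, with the
#' IRF normalized to unit sum (so \eqn{N_F} counts fluorescence photons and
#' \eqn{N_{BG}} scattered photons), an optional sub-channel IRF time shift,
#' and an optional multiplicative linearization curve applied last.
#'
#' @param f model decay on the channel grid.
#' @param irf instrument response (any scale; normalized internally).
#' @param n_f,n_bg,bg fluorescence photons, scattered photons, constant
#'   offset per channel.
#' @param linearization optional multiplicative curve.
#' @param shift IRF shift in channels (fractional allowed).
#' @export
instrument_model <- function(f, irf, n_f, n_bg = 0, bg = 0,
                             linearization = NULL, shift = 0) {
  if (all(irf == 0)) stop("IRF is identically zero")
  if (shift != 0) irf <- shift_channels(irf, shift)
  irf <- irf / sum(irf)
  g <- n_f * convolve_discrete(f, irf) + n_bg * irf + bg
  if (!is.null(linearization)) g <- g * linearization / mean(linearization)
  g
}

# plain discrete causal convolution (no dt scaling, no end correction):
# with a unit-sum kernel this redistributes counts across channels.
convolve_discrete <- function(f, h) {
  n <- length(f)
  m <- stats::nextn(2L * n)
  ff <- stats::fft(c(f, rep(0, m - n)))
  hh <- stats::fft(c(h, rep(0, m - n)))
  Re(stats::fft(ff * hh, inverse = TRUE))[seq_len(n)] / m
}

shift_channels <- function(x, shift) {
  n <- length(x)
  i <- seq_len(n) - shift
  lo <- floor(i); fr <- i - lo
  get0 <- function(k) ifelse(k >= 1 & k <= n, x[pmax(pmin(k, n), 1)], 0)
  (1 - fr) * get0(lo) + fr * get0(lo + 1)
}

#' Simulate a TCSPC measurement
#'
#' Generates Poisson-distributed counts for a donor or FRET-sensitized
#' acceptor decay under the full instrument model.
#'
#' @param dist a [gaussian_mixture_distance()].
#' @param donor_ref donor [fluorophore_reference()].
#' @param t time grid in ns.
#' @param irf instrument response on `t` (default: delta in channel 1).
#' @param n_photons expected total fluorescence photons.
#' @param acceptor_ref optional acceptor reference; when given the
#'   FRET-sensitized acceptor decay is simulated instead of the donor.
#' @param n_bg,bg scattered photons and constant offset.
#' @param seed RNG seed; `NULL` for no seeding.
#' @return a [decay_curve()] with the IRF attached.
#' @export
simulate_tcspc <- function(dist, donor_ref, t, irf = NULL,
                           n_photons = 2e7, acceptor_ref = NULL,
                           n_bg = 0, bg = 0, seed = NULL) {
  if (is.null(irf)) irf <- c(1, rep(0, length(t) - 1))
  eps <- fret_induced_donor_decay(dist, t)
  f <- donor_decay_with_fret(donor_ref, t, eps)
  if (!is.null(acceptor_ref)) f <- acceptor_sensitized_decay(f, acceptor_ref, t)
  g1 <- instrument_model(f, irf, n_f = 1, n_bg = 0, bg = 0)
  g <- instrument_model(f, irf, n_f = n_photons / sum(g1), n_bg = n_bg,
                        bg = bg)
  if (!is.null(seed)) set.seed(seed)
  decay_curve(t, stats::rpois(length(t), pmax(g, 0)), irf = irf)
}

#' Default TCSPC fit range
#'
#' Channel range covering the full instrument response and 99.9 percent of
#' the cumulative fluorescence signal.
#'
#' @param curve a [decay_curve()].
#' @export
default_fit_range <- function(curve) {
  cs <- cumsum(curve$counts) / max(1, sum(curve$counts))
  last <- which(cs >= 0.999)[1]
  if (is.na(last)) last <- length(curve$counts)
  c(1L, last)
}

## ---------------------------------------------------------------------------
## Global (joint) decay fitting
## ---------------------------------------------------------------------------

tcspc_par_names <- c("mean1", "mean2", "width", "x1", "x_donly")

tcspc_default_bounds <- function() {
  list(lower = c(mean1 = 15, mean2 = 15, width = 3, x1 = 0, x_donly = 0),
       upper = c(mean1 = 130, mean2 = 130, width = 30, x1 = 1, x_donly = 1))
}

# pack/unpack: shared params once ("s.<name>"), per-dataset otherwise
# ("d<i>.<name>"); `fixed` names are excluded from the vector.
pack_tcspc <- function(start, shared, fixed_names) {
  nm <- c()
  val <- c()
  for (p in setdiff(tcspc_par_names, fixed_names)) {
    if (p %in% shared) {
      nm <- c(nm, paste0("s.", p)); val <- c(val, start[[1]][[p]])
    } else {
      for (i in seq_along(start)) {
        nm <- c(nm, sprintf("d%d.%s", i, p)); val <- c(val, start[[i]][[p]])
      }
    }
  }
  stats::setNames(val, nm)
}

unpack_tcspc <- function(par, i, shared, start, fixed) {
  out <- list()
  for (p in tcspc_par_names) {
    out[[p]] <- if (p %in% names(fixed)) {
      v <- fixed[[p]]; if (length(v) > 1) v[[i]] else v
    } else if (p %in% shared) par[[paste0("s.", p)]]
    else par[[sprintf("d%d.%s", i, p)]]
  }
  out
}

#' Joint fit of TCSPC decays with a two-Gaussian distance model
#'
#' Fits one or more decay histograms by iterative reconvolution with a
#' modified Levenberg-Marquardt algorithm, with Poisson weights
#' \eqn{\sigma_k = \sqrt{\max(c_k, 1)}} and a per-dataset analytically
#' profiled fluorescence amplitude. Any subset of the distance-model
#' parameters (`mean1`, `mean2`, `width`, `x1`, `x_donly`) can be shared
#' globally across datasets or held fixed.
#'
#' @param datasets list; each element a list with components `curve`
#'   (a [decay_curve()], IRF attached if reconvolution is wanted),
#'   `donor_ref`, optional `acceptor_ref` (fit the sensitized acceptor
#'   decay), optional `n_bg`, `bg` (known nuisance counts), optional `R0`,
#'   `tau0`.
#' @param start list (one per dataset) of named starting values for the
#'   distance-model parameters.
#' @param shared character vector of parameter names fitted as a single
#'   global value.
#' @param fixed named list of parameters held at fixed values (scalar or
#'   one value per dataset).
#' @param weighting `"counts"` (classical Poisson weights
#'   \eqn{\sqrt{\max(c_k, 1)}} from the data, the field's standard) or
#'   `"model"` (weights from the fitted model, which removes the small
#'   low-count (Neyman) bias of data-based weights in calibration
#'   studies).
#' @param fit_range `"auto"` (full IRF + 99.9 percent of the cumulative
#'   fluorescence, per [default_fit_range()]) or `"full"`.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return object of class `tcspc_fit`: per-dataset parameter table,
#'   shared parameters, reduced chi-square, fitted model curves.
#' @export
fit_decay <- function(datasets, start, shared = character(),
                      fixed = list(), weighting = c("counts", "model"),
                      fit_range = c("auto", "full"),
                      control = list(maxiter = 200)) {
  weighting <- match.arg(weighting)
  fit_range <- match.arg(fit_range)
  nd <- length(datasets)
  if (length(start) == 1L && nd > 1L) start <- rep(start, nd)
  par0 <- pack_tcspc(start, shared, names(fixed))
  bounds <- tcspc_default_bounds()
  bname <- sub("^(s|d[0-9]+)\\.", "", names(par0))
  lower <- bounds$lower[bname]; upper <- bounds$upper[bname]

  prep <- lapply(datasets, function(d) {
    idx <- if (fit_range == "full") seq_along(d$curve$counts) else {
      rng <- default_fit_range(d$curve)
      rng[1]:rng[2]
    }
    y <- d$curve$counts
    list(d = d, idx = idx, y = y, sigma = sqrt(pmax(y, 1)),
         t = d$curve$time)
  })

  model_one <- function(pars, pp) {
    d <- pp$d
    gm <- gaussian_mixture_distance(pars$mean1, pars$mean2, pars$width,
                                    pars$x1, pars$x_donly,
                                    R0 = d$R0 %||% 52, tau0 = d$tau0 %||% 4)
    eps <- fret_induced_donor_decay(gm, pp$t)
    f <- donor_decay_with_fret(d$donor_ref, pp$t, eps)
    if (!is.null(d$acceptor_ref))
      f <- acceptor_sensitized_decay(f, d$acceptor_ref, pp$t)
    irf <- d$curve$irf %||% c(1, rep(0, length(pp$t) - 1))
    base <- instrument_model(f, irf, n_f = 1, n_bg = d$n_bg %||% 0,
                             bg = d$bg %||% 0,
                             linearization = d$curve$linearization)
    conv <- instrument_model(f, irf, n_f = 1)
    # analytic amplitude: minimize sum w (nf*conv + fixedpart - y)^2
    fixedpart <- base - conv
    w <- 1 / pp$sigma[pp$idx]^2
    cc <- conv[pp$idx]
    nf <- sum(w * cc * (pp$y[pp$idx] - fixedpart[pp$idx])) /
      sum(w * cc^2)
    nf * conv + fixedpart
  }

  resid_fn <- function(p) {
    p <- as.list(p)
    unlist(lapply(seq_len(nd), function(i) {
      pars <- unpack_tcspc(p, i, shared, start, fixed)
      g <- model_one(pars, prep[[i]])
      idx <- prep[[i]]$idx
      s <- if (weighting == "model") sqrt(pmax(g[idx], 1))
           else prep[[i]]$sigma[idx]
      (g[idx] - prep[[i]]$y[idx]) / s
    }))
  }

  fit <- minpack.lm::nls.lm(par0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = do.call(minpack.lm::nls.lm.control,
                                              control))
  est <- as.list(stats::coef(fit))
  pars_by_ds <- lapply(seq_len(nd), function(i)
    unpack_tcspc(est, i, shared, start, fixed))
  nres <- length(fit$fvec)
  npar <- length(par0)
  at_bounds <- names(par0)[stats::coef(fit) <= lower + 1e-10 |
                             stats::coef(fit) >= upper - 1e-10]
  structure(list(
    par = stats::coef(fit),
    parameters = pars_by_ds,
    shared = est[grepl("^s\\.", names(est))],
    chi2 = sum(fit$fvec^2),
    chi2r = sum(fit$fvec^2) / (nres - npar),
    dof = nres - npar,
    converged = fit$info %in% 1:4,
    info = fit$info,
    at_bounds = at_bounds,
    resid_fn = resid_fn,
    n_par = npar,
    fitted = lapply(seq_len(nd), function(i)
      model_one(pars_by_ds[[i]], prep[[i]])),
    datasets = datasets, start = start, shared_names = shared,
    fixed = fixed),
    class = "tcspc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tcspc_fit <- function(x, ...) {
  cat(sprintf("tcspc_fit: %d dataset(s), chi2_r = %.4f%s\n",
              length(x$datasets), x$chi2r,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$shared))
    cat("  shared:", paste(sprintf("%s = %.4g", sub("^s\\.", "",
        names(x$shared)), unlist(x$shared)), collapse = ", "), "\n")
  if (length(x$at_bounds))
    cat("  parameters at bounds:", paste(x$at_bounds, collapse = ", "), "\n")
  invisible(x)
}

#' Support-plane confidence interval for one fit parameter
#'
#' Profiles the summed chi-square along one parameter (re-optimizing all
#' others) and returns the interval where the F-test at the requested
#' confidence level does not reject, the classical support-plane error
#' estimate of time-resolved fluorescence.
#'
#' @param fit a `tcspc_fit`.
#' @param param packed parameter name (e.g. `"s.x1"` or `"d1.mean1"`).
#' @param level confidence level (default 0.95).
#' @param rel_width half-width of the scan, relative to the estimate.
#' @param n_steps grid points on each side.
#' @return list with `lower`, `upper`, `grid`, `chi2`.
#' @export
support_plane_ci <- function(fit, param, level = 0.95, rel_width = 0.2,
                             n_steps = 8) {
  p0 <- fit$par
  if (!param %in% names(p0)) stop("unknown parameter ", param)
  dof <- fit$dof
  thresh <- fit$chi2 * (1 + stats::qf(level, 1, dof) / dof)
  bounds <- tcspc_default_bounds()
  bn <- sub("^(s|d[0-9]+)\\.", "", param)
  scan_dir <- function(sign) {
    width <- max(abs(p0[[param]]) * rel_width, 0.02)
    grid <- p0[[param]] + sign * seq_len(n_steps) / n_steps * width
    grid <- pmin(pmax(grid, bounds$lower[[bn]]), bounds$upper[[bn]])
    chi <- numeric(0)
    lim <- p0[[param]]
    for (v in grid) {
      pf <- p0; pf[[param]] <- v
      free <- setdiff(names(p0), param)
      sub <- minpack.lm::nls.lm(pf[free], fn = function(q) {
        full <- pf; full[free] <- q
        fit$resid_fn(full)
      }, control = minpack.lm::nls.lm.control(maxiter = 50))
      c2 <- sum(sub$fvec^2)
      chi <- c(chi, c2)
      if (c2 > thresh) {
        # linear interpolation to the crossing
        prev <- if (length(chi) > 1) chi[length(chi) - 1] else fit$chi2
        vprev <- if (length(chi) > 1) grid[length(chi) - 1] else p0[[param]]
        lim <- vprev + (v - vprev) * (thresh - prev) / (c2 - prev)
        break
      }
      lim <- v
    }
    list(lim = lim, grid = grid[seq_along(chi)], chi2 = chi)
  }
  lo <- scan_dir(-1); hi <- scan_dir(+1)
  list(lower = lo$lim, upper = hi$lim,
       grid = c(rev(lo$grid), p0[[param]], hi$grid),
       chi2 = c(rev(lo$chi2), fit$chi2, hi$chi2))
}

## ---------------------------------------------------------------------------
## Maximum-entropy reconstruction
## ---------------------------------------------------------------------------

#' Maximum-entropy reconstruction of a distance distribution
#'
#' Model-free inversion of a donor (or quenched-donor) decay into a
#' distance distribution on a grid, maximizing
#' \eqn{\alpha S - \chi^2/2} with the extended (Skilling) entropy
#' \eqn{S = \sum_j (p_j - m_j - p_j \ln(p_j/m_j))} against a flat prior
#' `m`. Solved for each regularization weight in `alphas`; the L-curve
#' (log misfit vs log entropy magnitude) and its maximum-curvature corner
#' are returned.
#'
#' @param curve a [decay_curve()] (IRF used if attached).
#' @param donor_ref donor [fluorophore_reference()].
#' @param r distance grid in Angstrom.
#' @param alphas regularization weights (positive, log-spaced).
#' @param R0,tau0 Forster radius (A) and unquenched lifetime (ns).
#' @param n_bg,bg known nuisance counts.
#' @param maxit optimizer iterations per alpha.
#' @return list with `distribution` (at the corner alpha), `alpha_opt`,
#'   `alphas`, `misfit` (chi2 per alpha), `entropy`, `corner` index and
#'   `distributions` (one per alpha).
#' @export
mem_reconstruct <- function(curve, donor_ref, r = seq(20, 100, 1),
                            alphas = 10^seq(2, -3, length.out = 18),
                            R0 = 52, tau0 = 4, n_bg = 0, bg = 0,
                            maxit = 300) {
  if (any(alphas <= 0)) stop("alpha must be positive")
  t <- curve$time
  y <- curve$counts
  sigma <- sqrt(pmax(y, 1))
  irf <- curve$irf %||% c(1, rep(0, length(t) - 1))
  irf <- irf / sum(irf)
  dref <- reference_decay(donor_ref, t)
  k <- (1 / tau0) * (R0 / r)^6
  A <- dref * exp(-outer(t, k))            # nt x nr
  A <- apply(A, 2, function(col) convolve_discrete(col, irf))
  off <- n_bg * irf + bg
  # scale prior so the flat model roughly matches the data magnitude
  ls0 <- sum((y - off) * rowSums(A)) / sum(rowSums(A)^2)
  m <- rep(max(ls0, 1e-12), length(r))
  W <- 1 / sigma^2
  obj <- function(u, alpha) {
    p <- exp(pmin(pmax(u, -700), 700))
    g <- drop(A %*% p) + off
    chi2 <- sum(W * (g - y)^2)
    S <- sum(p - m - p * log(p / m))
    v <- -(alpha * S - chi2 / 2)
    if (!is.finite(v)) 1e300 else v
  }
  grad <- function(u, alpha) {
    p <- exp(pmin(pmax(u, -700), 700))
    g <- drop(A %*% p) + off
    dchi <- drop(crossprod(A, W * (g - y)))
    gr <- -(p * (-alpha * log(p / m) - dchi))
    gr[!is.finite(gr)] <- 0
    pmax(pmin(gr, 1e12), -1e12)
  }
  u <- log(m)
  fits <- vector("list", length(alphas))
  misfit <- entropy <- numeric(length(alphas))
  for (ia in order(alphas, decreasing = TRUE)) {
    alpha <- alphas[ia]
    opt <- stats::optim(u, obj, grad, alpha = alpha, method = "L-BFGS-B",
                        control = list(maxit = maxit))
    u <- opt$par
    p <- exp(u)
    g <- drop(A %*% p) + off
    misfit[ia] <- sum(W * (g - y)^2)
    entropy[ia] <- sum(p - m - p * log(p / m))
    fits[[ia]] <- p
  }
  ord <- order(alphas, decreasing = TRUE)
  corner_rel <- lcurve_corner(log(misfit[ord]),
                              log(pmax(-entropy[ord], 1e-300)))
  corner <- ord[corner_rel]
  dists <- lapply(fits, function(p) distance_distribution(r, p, kind = "FRET"))
  list(distribution = dists[[corner]], alpha_opt = alphas[corner],
       alphas = alphas, misfit = misfit, entropy = entropy,
       corner = corner, distributions = dists)
}

#' Lifetime moments of the donor in the presence of acceptor
#'
#' The species-averaged lifetime \eqn{\langle\tau\rangle_x =
#' (1 - E)\langle\tau_{D(0)}\rangle_x} and the variance
#' \eqn{var(\tau) = \langle\tau\rangle_F \langle\tau\rangle_x -
#' \langle\tau\rangle_x^2} estimated from burst-wise observables; a
#' non-zero variance flags conformational heterogeneity or dynamics.
#'
#' @param E FRET efficiency in `[0, 1]`.
#' @param tau_x_d0 species-averaged donor-only lifetime (ns).
#' @param tau_f fluorescence-weighted donor lifetime with acceptor (ns).
#' @return list with `tau_x` and `var`.
#' @export
lifetime_moments <- function(E, tau_x_d0, tau_f) {
  if (any(E < 0 | E > 1)) stop("E must lie in [0, 1]")
  if (any(tau_x_d0 <= 0) || any(tau_f <= 0)) stop("lifetimes must be positive")
  tau_x <- (1 - E) * tau_x_d0
  list(tau_x = tau_x, var = tau_f * tau_x - tau_x^2)
}

# lifetime moments of a quenched multi-exponential donor at FRET rate kret
quenched_moments <- function(ref, kret) {
  taup <- 1 / (1 / ref$lifetimes + kret)
  m1 <- sum(ref$fractions * taup)
  m2 <- sum(ref$fractions * taup^2)
  c(m1 = m1, m2 = m2)
}

#' Static and dynamic FRET-lines
#'
#' Parametric reference curves in the (fluorescence-weighted lifetime,
#' efficiency) plane. The static line traces single conformational states
#' over distance; the dynamic line traces mixtures of two fixed states
#' under species-weighted photon averaging, and bows away from the static
#' line — the classic signature separating static from exchanging
#' molecules in burst-wise histograms.
#'
#' @param donor_ref donor [fluorophore_reference()].
#' @param R0 Forster radius (A).
#' @param tau0 unquenched lifetime defining `k0` (ns).
#' @param kind `"static"` or `"dynamic"`.
#' @param states for the dynamic line: the two state distances (A);
#'   at least two are required.
#' @param r distance grid for the static line (A).
#' @param frac mixing-fraction grid for the dynamic line.
#' @return data.frame with columns `tau_f` (ns) and `E`, plus the
#'   parameterizing variable (`r` or `frac`); class `fret_line`.
#' @export
fret_lines <- function(donor_ref, R0 = 52, tau0 = 4,
                       kind = c("static", "dynamic"), states = NULL,
                       r = seq(20, 120, 0.5), frac = seq(0, 1, 0.01)) {
  kind <- match.arg(kind)
  tau_d0 <- species_average_lifetime(donor_ref)
  state_moments <- function(dist) quenched_moments(donor_ref,
                                                   (1 / tau0) * (R0 / dist)^6)
  if (kind == "static") {
    mm <- vapply(r, state_moments, numeric(2))
    out <- data.frame(r = r, tau_f = mm[2, ] / mm[1, ],
                      E = 1 - mm[1, ] / tau_d0)
  } else {
    if (length(states) < 2)
      stop("dynamic FRET-line requires two states")
    m1 <- state_moments(states[1]); m2 <- state_moments(states[2])
    mix1 <- frac * m1[1] + (1 - frac) * m2[1]
    mix2 <- frac * m1[2] + (1 - frac) * m2[2]
    out <- data.frame(frac = frac, tau_f = mix2 / mix1,
                      E = 1 - mix1 / tau_d0)
  }
  class(out) <- c("fret_line", "data.frame")
  attr(out, "kind") <- kind
  out
}
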