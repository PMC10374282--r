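#' Species unmixing filters for filtered FCS
#'
#' Weighted least-squares filters over detector x TAC channels that unmix
#' the photon stream into species-specific signals. The filters are
#' unbiased (\eqn{\sum_j w_j^{(n)} p_j^{(m)} = \delta_{nm}}) and have
#' minimal variance among unbiased linear filters under shot noise with
#' mean channel signal `s`.
#'
#' @param patterns matrix (channels x species) of normalized species decay
#'   patterns \eqn{p_j^{(n)}} (columns sum to 1).
#' @param s mean signal per channel (positive), e.g. the measured
#'   channel-wise mean count rate.
#' @return object of class `filter_set` with the weight matrix `w`
#'   (species x channels), the patterns and `s`.
#' @export
species_filters <- function(patterns, s) {
  M <- as.matrix(patterns)
  if (ncol(M) < 2) stop("at least two species patterns required")
  if (any(s <= 0)) stop("mean signal must be positive in every channel")
  if (length(s) != nrow(M)) stop("s must have one entry per channel")
  M <- sweep(M, 2, colSums(M), "/")
  MtD <- t(M / s)                       # t(M) %*% diag(1/s)
  G <- MtD %*% M
  if (rcond(G) < 1e-12)
    stop(sprintf("species patterns are collinear (rank deficient, rcond = %.1e)",
                 rcond(G)))
  W <- solve(G, MtD)
  rownames(W) <- colnames(M)
  structure(list(w = W, patterns = M, s = s), class = "filter_set")
}

#' @export
print.filter_set <- function(x, ...) {
  cat(sprintf("filter_set: %d species x %d channels\n",
              nrow(x$w), ncol(x$w)))
  invisible(x)
}

#' Species correlation curve container
#'
#' @param lag_s lag times in seconds, increasing.
#' @param g correlation values.
#' @param sd optional per-point SD (positive where given).
#' @param kind one of `"sACF_HH"`, `"sACF_LL"`, `"sCCF_HL"`, `"sCCF_LH"`.
#' @param variant sample/variant identifier.
#' @export
corr_curve <- function(lag_s, g, sd = NULL, kind = "sACF_HH",
                       variant = NA_character_) {
  if (any(diff(lag_s) <= 0)) stop("lag grid must be increasing")
  if (!is.null(sd) && any(sd <= 0, na.rm = TRUE))
    stop("per-point SD must be positive")
  structure(list(lag_s = lag_s, g = g, sd = sd, kind = kind,
                 variant = variant),
            class = "corr_curve")
}

#' @export
print.corr_curve <- function(x, ...) {
  cat(sprintf("corr_curve %s (variant %s): %d lags, %.2e..%.2e s\n",
              x$kind, format(x$variant), length(x$lag_s), min(x$lag_s),
              max(x$lag_s)))
  invisible(x)
}

#' Species auto-/cross-correlation of a filtered photon stream
#'
#' Applies species filters to a binned detector x TAC channel signal and
#' computes the normalized correlation
#' \eqn{G^{(n,m)}(t_c) = \langle F^{(n)}(t) F^{(m)}(t+t_c)\rangle /
#' (\langle F^{(n)}\rangle \langle F^{(m)}\rangle)} on a multi-tau lag
#' grid (16 lags per cascade, factor-2 coarsening with averaging).
#'
#' @param signal matrix (channels x time bins) of binned counts.
#' @param filters a [species_filters()] object.
#' @param pair integer or character vector of length 2 selecting the
#'   species (n, m).
#' @param bin_s duration of one time bin in seconds.
#' @param n_casc number of multi-tau cascades.
#' @param n_per lags per cascade.
#' @param variant label carried to the output.
#' @return a [corr_curve()].
#' @export
species_correlate <- function(signal, filters, pair = c(1, 2), bin_s,
                              n_casc = 8, n_per = 16,
                              variant = NA_character_) {
  if (length(signal) == 0 || ncol(signal) < 4) stop("empty signal")
  Fn <- drop(filters$w[pair[1], , drop = FALSE] %*% signal)
  Fm <- drop(filters$w[pair[2], , drop = FALSE] %*% signal)
  cc <- correlate_multitau(Fn, Fm, bin_s, n_casc, n_per)
  kind <- correlation_kind(pair, rownames(filters$w))
  corr_curve(cc$lag_s, cc$g, kind = kind, variant = variant)
}

correlation_kind <- function(pair, species) {
  nm <- if (is.character(pair)) pair else species[pair]
  if (is.null(nm) || anyNA(nm)) nm <- as.character(pair)
  if (nm[1] == nm[2]) paste0("sACF_", nm[1], nm[2])
  else paste0("sCCF_", nm[1], nm[2])
}

correlate_multitau <- function(x, y, bin_s, n_casc = 8, n_per = 16) {
  lag_s <- g <- numeric(0)
  lvl_bin <- bin_s
  mx_all <- mean(x); my_all <- mean(y)
  for (casc in seq_len(n_casc)) {
    lags <- if (casc == 1) 1:n_per else (n_per / 2 + 1):n_per
    Tn <- length(x)
    if (Tn <= n_per + 1) break
    for (l in lags) {
      i1 <- 1:(Tn - l)
      g <- c(g, mean(x[i1] * y[i1 + l]) / (mean(x[i1]) * mean(y[i1 + l])))
      lag_s <- c(lag_s, l * lvl_bin)
    }
    # coarsen by 2 (averaging correction)
    Tn2 <- floor(Tn / 2)
    x <- (x[2 * seq_len(Tn2) - 1] + x[2 * seq_len(Tn2)]) / 2
    y <- (y[2 * seq_len(Tn2) - 1] + y[2 * seq_len(Tn2)]) / 2
    lvl_bin <- lvl_bin * 2
  }
  list(lag_s = lag_s, g = g)
}

#' Diffusion + kinetics model parameters for species correlation functions
#'
#' Bundles the parameters of the factorized correlation model
#' \eqn{G = 1 + N_{eff}^{-1} G_{diff} G_{kin}}: a 3D-Gaussian-focus
#' diffusion term and a three-exponential kinetic term with
#' anti-correlation amplitudes for the cross-correlations and an optional
#' acceptor-bleaching term on curves involving the high-FRET species.
#'
#' @param n_eff named effective numbers of molecules: `HH`, `LL`, `CC`
#'   (the two sCCFs share one value).
#' @param t_diff diffusion time in seconds.
#' @param axial focal aspect ratio \eqn{\omega_0 / z_0}.
#' @param t_c the three relaxation times in seconds (shared globally in a
#'   joint analysis).
#' @param a kinetic amplitudes A1..A3 of the cross-correlation spectrum
#'   (non-negative, sum to 1 -- renormalized here).
#' @param a0_lh,a0_hl anti-correlation amplitudes of the two sCCFs.
#' @param a_hh,a_ll sACF kinetic amplitudes (length 3, local per curve).
#' @param ab_hh,ab_hl acceptor-bleach amplitudes (H-containing curves).
#' @param t_b bleach time in seconds.
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(n_eff = c(HH = 1, LL = 1, CC = 1),
                          t_diff = 1e-3, axial = 0.2,
                          t_c = c(2e-6, 23e-6, 297e-6),
                          a = c(0.6, 0.3, 0.1),
                          a0_lh = 0.5, a0_hl = 0.5,
                          a_hh = c(0.2, 0.1, 0.05),
                          a_ll = c(0.2, 0.1, 0.05),
                          ab_hh = 0, ab_hl = 0, t_b = 5e-3) {
  if (any(t_c <= 0) || t_diff <= 0 || t_b <= 0) stop("times must be positive")
  if (any(a < 0)) stop("kinetic amplitudes must be non-negative")
  a <- a / sum(a)
  structure(list(n_eff = n_eff, t_diff = t_diff, axial = axial, t_c = t_c,
                 a = a, a0_lh = a0_lh, a0_hl = a0_hl, a_hh = a_hh,
                 a_ll = a_ll, ab_hh = ab_hh, ab_hl = ab_hl, t_b = t_b),
            class = "kinetic_model")
}

#' Evaluate the species correlation model
#'
#' @param tc lag times in seconds.
#' @param model a [kinetic_model()].
#' @param kind `"sACF_HH"`, `"sACF_LL"`, `"sCCF_HL"` or `"sCCF_LH"`.
#' @return correlation values G(tc).
#' @export
fcs_model <- function(tc, model, kind) {
  gd <- (1 + tc / model$t_diff)^-1 *
    (1 + model$axial^2 * tc / model$t_diff)^-0.5
  e <- function(i) exp(-tc / model$t_c[i])
  eb <- exp(-tc / model$t_b)
  gk <- switch(kind,
    sCCF_LH = 1 - model$a0_lh *
      (model$a[1] * e(1) + model$a[2] * e(2) + model$a[3] * e(3)),
    sCCF_HL = (1 - model$a0_hl *
      (model$a[1] * e(1) + model$a[2] * e(2) + model$a[3] * e(3))) *
      (1 - model$ab_hl * eb),
    sACF_LL = 1 + model$a_ll[1] * (e(1) - 1) + model$a_ll[2] * (e(2) - 1) +
      model$a_ll[3] * (e(3) - 1),
    sACF_HH = (1 + model$a_hh[1] * (e(1) - 1) + model$a_hh[2] * (e(2) - 1) +
      model$a_hh[3] * (e(3) - 1)) * (1 + model$ab_hh * (eb - 1)),
    stop("unknown curve kind: ", kind))
  n <- switch(kind, sACF_HH = model$n_eff[["HH"]],
              sACF_LL = model$n_eff[["LL"]], model$n_eff[["CC"]])
  1 + gd * gk / n
}

#' Amplitude-weighted mean relaxation time
#'
#' The per-variant scalar summary \eqn{\sum_i A_i t_{c,i}} of a kinetic
#' relaxation spectrum (amplitudes normalized to 1).
#'
#' @param model a [kinetic_model()], or a numeric vector of amplitudes.
#' @param t_c relaxation times when `model` is an amplitude vector.
#' @return time in the units of `t_c`.
#' @export
mean_relaxation_time <- function(model, t_c = NULL) {
  if (inherits(model, "kinetic_model")) {
    a <- model$a; t_c <- model$t_c
  } else a <- model
  a <- a / sum(a)
  sum(a * t_c)
}

#' Simulate a set of species correlation curves
#'
#' Evaluates the model for all four curve kinds of one variant on a
#' quasi-logarithmic lag grid and adds Gaussian noise with a lag-dependent
#' SD (larger at short lags, emulating photon statistics of measurement
#' splits).
#'
#' @param model a [kinetic_model()].
#' @param lag_s lag grid in seconds (default: multi-tau-like 1 us..0.1 s).
#' @param noise relative noise scale (SD of G at the longest lag).
#' @param variant variant label.
#' @param seed RNG seed.
#' @return list of four [corr_curve()]s (HH, LL, HL, LH).
#' @export
simulate_ffcs_curves <- function(model, lag_s = NULL, noise = 2e-3,
                                 variant = "v1", seed = NULL) {
  if (is.null(lag_s)) lag_s <- 10^seq(-6.3, -1, length.out = 64)
  if (!is.null(seed)) set.seed(seed)
  kinds <- c("sACF_HH", "sACF_LL", "sCCF_HL", "sCCF_LH")
  lapply(stats::setNames(kinds, kinds), function(kind) {
    g <- fcs_model(lag_s, model, kind)
    if (noise > 0) {
      sd <- noise * (1 + 3 * (lag_s / min(lag_s))^-0.25)
      g <- g + stats::rnorm(length(g), sd = sd)
    } else sd <- rep(1e-6, length(g))
    corr_curve(lag_s, g, sd = sd, kind = kind, variant = variant)
  })
}

## ---------------------------------------------------------------------------
## Global fit with shared relaxation times
## ---------------------------------------------------------------------------

# parameter vector layout: shared log10 relaxation times "s.lt1..3";
# per variant v: "v<i>.lnd" (log10 n_eff HH/LL/CC), "v<i>.ltd" (log10
# t_diff), "v<i>.a0lh", "v<i>.a0hl", "v<i>.th1/th2" (softmax of kinetic
# amplitudes, third logit fixed at 0), "v<i>.ahh1..3", "v<i>.all1..3".
softmax3 <- function(th1, th2) {
  z <- exp(c(th1, th2, 0))
  z / sum(z)
}

pack_ffcs <- function(models, variants) {
  p <- c(s.lt1 = log10(models[[1]]$t_c[1]), s.lt2 = log10(models[[1]]$t_c[2]),
         s.lt3 = log10(models[[1]]$t_c[3]))
  for (i in seq_along(variants)) {
    m <- models[[i]]
    a <- pmax(m$a, 1e-4)
    v <- c(lnHH = log10(m$n_eff[["HH"]]), lnLL = log10(m$n_eff[["LL"]]),
           lnCC = log10(m$n_eff[["CC"]]), ltd = log10(m$t_diff),
           a0lh = m$a0_lh, a0hl = m$a0_hl,
           th1 = log(a[1] / a[3]), th2 = log(a[2] / a[3]),
           ahh1 = m$a_hh[1], ahh2 = m$a_hh[2], ahh3 = m$a_hh[3],
           all1 = m$a_ll[1], all2 = m$a_ll[2], all3 = m$a_ll[3])
    names(v) <- sprintf("v%d.%s", i, names(v))
    p <- c(p, v)
  }
  p
}

unpack_ffcs <- function(p, i, axial) {
  g <- function(nm) p[[sprintf("v%d.%s", i, nm)]]
  kinetic_model(
    n_eff = c(HH = 10^g("lnHH"), LL = 10^g("lnLL"), CC = 10^g("lnCC")),
    t_diff = 10^g("ltd"), axial = axial,
    t_c = 10^c(p[["s.lt1"]], p[["s.lt2"]], p[["s.lt3"]]),
    a = softmax3(g("th1"), g("th2")),
    a0_lh = g("a0lh"), a0_hl = g("a0hl"),
    a_hh = c(g("ahh1"), g("ahh2"), g("ahh3")),
    a_ll = c(g("all1"), g("all2"), g("all3")))
}

#' Global fit of filtered-FCS curves with shared relaxation times
#'
#' Fits all curves of all variants (four kinds per variant) jointly by
#' weighted least squares: the three relaxation times are global
#' parameters, amplitudes / effective molecule numbers / diffusion times
#' are local, the kinetic cross-correlation amplitudes are constrained to
#' the simplex by a softmax parameterization, and the two sCCFs of each
#' variant share one effective number of molecules.
#'
#' @param curves nested list: one element per variant, each a named list
#'   of [corr_curve()]s (names `sACF_HH`, `sACF_LL`, `sCCF_HL`,
#'   `sCCF_LH`) carrying per-point SDs.
#' @param start list of [kinetic_model()] starting values (one per
#'   variant; relaxation times taken from the first).
#' @param axial fixed focal aspect ratio.
#' @param control [minpack.lm::nls.lm.control()] list.
#' @return object of class `ffcs_fit` with `t_c` (shared times, s),
#'   `models` (fitted [kinetic_model()]s), `chi2r`, plus the raw
#'   `par` vector and a `resid_fn` for profiling.
#' @export
global_fit_ffcs <- function(curves, start, axial = 0.2,
                            control = list(maxiter = 300)) {
  nv <- length(curves)
  if (length(start) != nv) stop("one starting model per variant required")
  p0 <- pack_ffcs(start, seq_len(nv))
  resid_fn <- function(p) {
    p <- as.list(p)
    unlist(lapply(seq_len(nv), function(i) {
      m <- unpack_ffcs(p, i, axial)
      unlist(lapply(curves[[i]], function(cv) {
        sd <- cv$sd %||% rep(stats::sd(cv$g) / 10, length(cv$g))
        (fcs_model(cv$lag_s, m, cv$kind) - cv$g) / sd
      }))
    }))
  }
  fit <- minpack.lm::nls.lm(p0, fn = resid_fn,
                            control = do.call(minpack.lm::nls.lm.control,
                                              control))
  est <- as.list(stats::coef(fit))
  models <- lapply(seq_len(nv), function(i) unpack_ffcs(est, i, axial))
  nres <- length(fit$fvec)
  structure(list(
    t_c = sort(10^c(est$s.lt1, est$s.lt2, est$s.lt3)),
    models = models,
    chi2 = sum(fit$fvec^2),
    chi2r = sum(fit$fvec^2) / (nres - length(p0)),
    converged = fit$info %in% 1:4,
    par = stats::coef(fit), resid_fn = resid_fn),
    class = "ffcs_fit")
}

#' @export
print.ffcs_fit <- function(x, ...) {
  cat(sprintf("ffcs_fit: %d variants, shared times %s us, chi2_r = %.3f\n",
              length(x$models),
              paste(signif(x$t_c * 1e6, 3), collapse = "/"), x$chi2r))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Exchange kinetics from a rate matrix
## ---------------------------------------------------------------------------

#' Stationary distribution of a rate matrix
#'
#' @param Q rate matrix (rows sum to zero, off-diagonal rates
#'   non-negative), units 1/us or any consistent unit.
#' @export
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_ <- drop(qr.solve(A, b))
  if (any(pi_ < -1e-10)) stop("rate matrix has no valid stationary state")
  pmax(pi_, 0) / sum(pmax(pi_, 0))
}

#' Relaxation-time spectrum of an exchange rate matrix
#'
#' Relaxation times of a reversible n-state exchange process: the inverse
#' magnitudes of the non-zero eigenvalues of the rate matrix, computed via
#' the detailed-balance symmetrization
#' \eqn{S = \Pi^{1/2} Q \Pi^{-1/2}} (a symmetric eigenproblem, numerically
#' exact for reversible chains).
#'
#' @param Q rate matrix (rows sum to zero), in 1/time-unit.
#' @return sorted relaxation times (same time unit).
#' @export
rate_matrix_spectrum <- function(Q) {
  if (max(abs(rowSums(Q))) > 1e-8 * max(abs(Q)))
    stop("rate matrix rows must sum to zero")
  pi_ <- stationary_distribution(Q)
  sq <- sqrt(pi_)
  S <- sweep(sweep(Q, 1, sq, `*`), 2, sq, `/`)
  if (max(abs(S - t(S))) > 1e-6 * max(abs(S)))
    stop("rate matrix does not satisfy detailed balance")
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- ev[ev < -1e-12 * max(abs(ev))]
  sort(-1 / lam)
}

#' Species correlation kinetics from a rate matrix
#'
#' Analytic multi-exponential decomposition of the kinetic factor of a
#' species correlation function for a reversible exchange process:
#' amplitudes and relaxation times of
#' \eqn{G^{(n,m)}_{kin}(t_c) \propto w_n^\top \Pi\, e^{Q t_c} w_m}
#' normalized by the product of mean species signals.
#'
#' @param Q rate matrix (rows sum to zero) in 1/us.
#' @param w_n,w_m per-state species weights (e.g. filtered brightness of
#'   each state as seen by species n and m).
#' @return list with `times` (us), `amplitudes` (relative to the plateau),
#'   and `g(tc)` evaluator (tc in us); `g(Inf) = 1`.
#' @export
kinetic_correlation <- function(Q, w_n, w_m) {
  pi_ <- stationary_distribution(Q)
  sq <- sqrt(pi_)
  S <- sweep(sweep(Q, 1, sq, `*`), 2, sq, `/`)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- es$vectors; lam <- es$values
  left <- drop(crossprod(U, (w_n * pi_) / sq))   # U^T Pi^{1/2} w_n
  right <- drop(crossprod(U, sq * w_m))          # U^T Pi^{-1/2}->  D^{1/2} w_m
  cvec <- left * right
  zero <- which.max(lam)
  c0 <- sum(w_n * pi_) * sum(w_m * pi_)
  keep <- setdiff(order(lam), zero)
  times <- -1 / lam[keep]
  amps <- cvec[keep] / c0
  g <- function(tc) 1 + drop(exp(-outer(tc, 1 / times)) %*% amps)
  list(times = times, amplitudes = amps, g = g)
}

#' Telegraph-process simulator for a two/three-state FRET switcher
#'
#' Slow reference simulator: a continuous-time Markov chain sampled on a
#' regular bin grid; per-bin photon counts in each channel are Poisson
#' with state-specific rates. Used as an independent oracle for the
#' analytic kinetics.
#'
#' @param Q rate matrix in 1/us.
#' @param rates matrix (states x channels) of photon rates per bin.
#' @param n_bins number of time bins.
#' @param bin_us bin width in us.
#' @param seed RNG seed.
#' @return list with `signal` (channels x bins) and `states`.
#' @export
simulate_telegraph <- function(Q, rates, n_bins, bin_us, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_states <- nrow(Q)
  P <- transition_matrix(Q, bin_us)
  states <- integer(n_bins)
  states[1] <- sample.int(n_states, 1, prob = stationary_distribution(Q))
  for (i in 2:n_bins)
    states[i] <- sample.int(n_states, 1, prob = P[states[i - 1], ])
  counts <- matrix(stats::rpois(ncol(rates) * n_bins,
                                t(rates[states, , drop = FALSE])),
                   nrow = ncol(rates))
  list(signal = counts, states = states)
}

# matrix exponential exp(Q * t) via the symmetrized eigendecomposition
transition_matrix <- function(Q, t) {
  pi_ <- stationary_distribution(Q)
  sq <- sqrt(pi_)
  S <- (function(M) (M + t(M)) / 2)(sweep(sweep(Q, 1, sq, `*`), 2, sq, `/`))
  es <- eigen(S, symmetric = TRUE)
  P <- sweep(sweep(es$vectors %*% (exp(t * es$values) * t(es$vectors)),
                   1, sq, `/`), 2, sq, `*`)
  P <- pmax(P, 0)
  sweep(P, 1, rowSums(P), "/")
}
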