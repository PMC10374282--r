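t64 <- seq(0, by = 0.25, length.out = 64)

test_that("FRET-induced donor decay has the right limits and oracle", {
  t <- seq(0, 20, 0.05)
  # all donor-only: no quenching at all
  gm <- gaussian_mixture_distance(50, 60, 12, x1 = 0.5, x_donly = 1)
  expect_equal(fret_induced_donor_decay(gm, t), rep(1, length(t)))
  # delta distribution at R0: k_RET = k0
  r <- seq(40, 64, 0.5)
  dd <- distance_distribution(r, as.numeric(r == 52))
  eps <- fret_induced_donor_decay(dd, t, R0 = 52, tau0 = 4)
  expect_equal(eps, exp(-t / 4), tolerance = 1e-12)
  # two-Gaussian mixture vs adaptive quadrature
  gm <- gaussian_mixture_distance(45, 60, 12, x1 = 0.61)
  mine <- fret_induced_donor_decay(gm, c(0.5, 2, 10))
  oracle <- vapply(c(0.5, 2, 10), function(tt) {
    num <- stats::integrate(function(r) {
      p <- 0.61 * exp(-2 * (r - 45)^2 / 144) +
        0.39 * exp(-2 * (r - 60)^2 / 144)
      p * exp(-tt * 0.25 * (52 / r)^6)
    }, 1, 300, rel.tol = 1e-12)$value
    den <- stats::integrate(function(r)
      0.61 * exp(-2 * (r - 45)^2 / 144) + 0.39 * exp(-2 * (r - 60)^2 / 144),
      1, 300, rel.tol = 1e-12)$value
    num / den
  }, numeric(1))
  expect_equal(mine, oracle, tolerance = 1e-6)
  # bounded, monotone non-increasing, limit x_donly
  gm2 <- gaussian_mixture_distance(45, 60, 12, x1 = 0.61, x_donly = 0.2)
  e2 <- fret_induced_donor_decay(gm2, seq(0, 400, 1))
  expect_equal(e2[1], 1, tolerance = 1e-9)
  expect_true(all(diff(e2) <= 1e-12))
  expect_equal(e2[length(e2)], 0.2, tolerance = 1e-5)
  # negative densities rejected
  expect_error(distance_distribution(r, r - 50), "non-negative")
})

test_that("quenched donor decay composes multiplicatively", {
  t <- seq(0, 20, 0.1)
  ref2 <- fluorophore_reference(c(0.6, 0.4), c(4, 1.5), "donor")
  # no quenching: the reference decay itself
  expect_equal(donor_decay_with_fret(ref2, t, rep(1, length(t))),
               0.6 * exp(-t / 4) + 0.4 * exp(-t / 1.5))
  # delta distance at R0 on a 4 ns donor: total rate 2 k0
  r <- seq(40, 64, 0.5)
  eps <- fret_induced_donor_decay(distance_distribution(r,
                                                        as.numeric(r == 52)),
                                  t, R0 = 52, tau0 = 4)
  expect_equal(donor_decay_with_fret(donor_4ns, t, eps), exp(-2 * t / 4),
               tolerance = 1e-12)
  # two-exponential donor x two-Gaussian quenching: term-by-term oracle
  gm <- gaussian_mixture_distance(45, 60, 12, x1 = 0.61)
  eps <- fret_induced_donor_decay(gm, t)
  f <- donor_decay_with_fret(ref2, t, eps)
  oracle <- (0.6 * exp(-t / 4) + 0.4 * exp(-t / 1.5)) * eps
  expect_equal(f, oracle, tolerance = 1e-14)
  expect_error(donor_decay_with_fret(ref2, t, eps[-1]), "grid")
})

test_that("acceptor-sensitized decay is a causal channel-scaled convolution", {
  dt <- t64[2] - t64[1]
  f <- exp(-t64 / 3) * (1 - exp(-t64 / 0.5))
  acc <- fluorophore_reference(1, 1.2, "acceptor")
  out <- acceptor_sensitized_decay(f, acc, t64)
  # O(n^2) double-sum oracle
  h <- exp(-t64 / 1.2)
  oracle <- vapply(seq_along(t64), function(k)
    sum(f[1:k] * h[k:1]) * dt, numeric(1))
  expect_equal(out, oracle, tolerance = 1e-12)
  # discrete delta acceptor is the identity
  expect_equal(convolve_causal(f, c(1 / dt, rep(0, 63)), dt), f,
               tolerance = 1e-12)
  # Fubini: sums multiply when both signals decay inside the window
  tl <- seq(0, by = 0.25, length.out = 256)
  fl <- hl <- rep(0, 256)
  fl[1:64] <- f; hl[1:64] <- h
  out_l <- convolve_causal(fl, hl, dt)
  expect_equal(sum(out_l) * dt, (sum(fl) * dt) * (sum(hl) * dt),
               tolerance = 1e-10)
})

test_that("instrument model reproduces Eq-type composition and closed form", {
  n <- 512
  t <- seq(0, by = 0.05, length.out = n)
  f <- exp(-t / 4)
  delta <- c(1, rep(0, n - 1))
  expect_equal(instrument_model(f, delta, n_f = 3), 3 * f)
  irf <- gaussian_irf(t, 0.254, t0 = 2)
  expect_equal(instrument_model(rep(0, n), irf, n_f = 5, n_bg = 7, bg = 2),
               7 * irf / sum(irf) + 2)
  expect_error(instrument_model(f, rep(0, n), 1), "zero")
  # Gaussian-IRF reconvolution of a 4 ns exponential: beyond the IRF
  # support the result equals the continuous exGaussian closed form
  dt <- 0.004; tt <- seq(0, by = dt, length.out = 4096)
  s <- 0.254 / (2 * sqrt(2 * log(2))); t0 <- 1.27
  irf2 <- stats::dnorm(tt, t0, s)
  g <- instrument_model(exp(-tt / 4), irf2, n_f = 1)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  oracle <- 0.5 * exp(s^2 / 32 - (tt - t0) / 4) *
    (erf((tt - t0 - s^2 / 4) / (s * sqrt(2))) -
       erf((-t0 - s^2 / 4) / (s * sqrt(2))))
  tail_i <- tt > t0 + 8 * s & tt < 12
  expect_equal(g[tail_i], oracle[tail_i], tolerance = 1e-8)
  # linearization curve multiplies (normalized to unit mean)
  lin <- 1 + 0.05 * sin(seq_len(n))
  expect_equal(instrument_model(f, delta, 1, linearization = lin),
               f * lin / mean(lin))
})

test_that("noiseless decays round-trip through the fit", {
  t <- seq(0, by = 0.028, length.out = 2048)
  irf <- gaussian_irf(t, 0.254)
  gm <- gaussian_mixture_distance(45, 62, 12, x1 = 0.55)
  eps <- fret_induced_donor_decay(gm, t)
  f <- donor_decay_with_fret(donor_4ns, t, eps)
  g <- instrument_model(f, irf, n_f = 2e6 / sum(instrument_model(f, irf, 1)))
  cv <- decay_curve(t, pmax(g, 0), irf = irf)
  fit <- fit_decay(list(list(curve = cv, donor_ref = donor_4ns)),
                   list(list(mean1 = 43, mean2 = 65, width = 12,
                             x1 = 0.45, x_donly = 0)),
                   fixed = list(width = 12, x_donly = 0),
                   control = list(maxiter = 400, ftol = 1e-14,
                                  ptol = 1e-14))
  p <- fit$parameters[[1]]
  expect_equal(p$mean1, 45, tolerance = 1e-6)
  expect_equal(p$mean2, 62, tolerance = 1e-6)
  expect_equal(p$x1, 0.55, tolerance = 1e-5)
  expect_lt(fit$chi2r, 1e-10)
})

test_that("support-plane intervals cover the truth in seeded round trips", {
  t <- seq(0, by = 0.056, length.out = 1024)
  irf <- gaussian_irf(t, 0.254)
  cover <- 0
  n_rep <- 10
  for (k in seq_len(n_rep)) {
    gm <- gaussian_mixture_distance(46, 60, 12, x1 = 0.61)
    cv <- simulate_tcspc(gm, donor_4ns, t, irf = irf, n_photons = 1e7,
                         seed = 500 + k)
    # model-based weights: the data-weight (Neyman) estimator carries a
    # small low-count bias that distorts coverage in calibration studies
    fit <- fit_decay(list(list(curve = cv, donor_ref = donor_4ns)),
                     list(list(mean1 = 44, mean2 = 62, width = 12,
                               x1 = 0.5, x_donly = 0)),
                     fixed = list(width = 12, x_donly = 0),
                     weighting = "model")
    ci <- support_plane_ci(fit, "d1.x1", level = 0.95)
    if (ci$lower <= 0.61 && 0.61 <= ci$upper) cover <- cover + 1
  }
  expect_gte(cover, ceiling(0.8 * n_rep))
})

test_that("sharing a global fraction beats independent fits", {
  t <- seq(0, by = 0.056, length.out = 1024)
  irf <- gaussian_irf(t, 0.254)
  n_rep <- 6
  err_joint <- err_indep <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    set.seed(900 + k)
    means <- cbind(stats::runif(3, 40, 50), stats::runif(3, 56, 66))
    ds <- list(); st <- list()
    for (i in 1:3) {
      gm <- gaussian_mixture_distance(means[i, 1], means[i, 2], 12,
                                      x1 = 0.61)
      cv <- simulate_tcspc(gm, donor_4ns, t, irf = irf, n_photons = 3e5,
                           seed = 900 + 10 * k + i)
      ds[[i]] <- list(curve = cv, donor_ref = donor_4ns)
      st[[i]] <- list(mean1 = means[i, 1] - 2, mean2 = means[i, 2] + 2,
                      width = 12, x1 = 0.5, x_donly = 0)
    }
    joint <- fit_decay(ds, st, shared = "x1",
                       fixed = list(width = 12, x_donly = 0))
    err_joint[k] <- joint$shared$s.x1 - 0.61
    x_ind <- vapply(1:3, function(i)
      fit_decay(ds[i], st[i],
                fixed = list(width = 12, x_donly = 0))$parameters[[1]]$x1,
      numeric(1))
    err_indep[k] <- mean(x_ind) - 0.61
  }
  expect_lt(sqrt(mean(err_joint^2)), sqrt(mean(err_indep^2)) + 0.01)
})

test_that("maximum entropy reconstructs distances model-free", {
  t <- seq(0, by = 0.028, length.out = 2048)
  # single distance: unimodal, mode within 2 A at the corner alpha
  gm1 <- gaussian_mixture_distance(55, 55, 6, x1 = 1)
  cv <- simulate_tcspc(gm1, donor_4ns, t, n_photons = 5e6, seed = 31)
  mem <- mem_reconstruct(cv, donor_4ns, r = seq(25, 95, 1))
  expect_lt(abs(mem$distribution$r[which.max(mem$distribution$p)] - 55), 2)
  expect_error(mem_reconstruct(cv, donor_4ns, alphas = c(-1, 1)),
               "positive")
  # very strong regularization returns (almost) the flat prior
  memf <- mem_reconstruct(cv, donor_4ns, r = seq(25, 95, 1), alphas = 1e9)
  pf <- memf$distributions[[1]]$p
  expect_lt(diff(range(pf)) / mean(pf), 0.02)
  # bimodal case: two modes, fractions within 0.1
  gm2 <- gaussian_mixture_distance(45, 60, 12, x1 = 0.61)
  cv2 <- simulate_tcspc(gm2, donor_4ns, t, n_photons = 2e7, seed = 32)
  mem2 <- mem_reconstruct(cv2, donor_4ns, r = seq(20, 100, 1))
  p <- mem2$distribution
  peaks <- which(diff(sign(diff(p$p))) == -2) + 1
  peaks <- peaks[p$p[peaks] > 0.2 * max(p$p)]
  expect_gte(length(peaks), 2)
  x1_hat <- pracma::trapz(p$r[p$r <= 52.5], p$p[p$r <= 52.5])
  expect_lt(abs(x1_hat - 0.61), 0.1)
})

test_that("lifetime moments follow the burst-wise formulas", {
  m <- lifetime_moments(0, 4, 4)
  expect_equal(m$tau_x, 4)
  expect_equal(m$var, 0)
  # single-exponential ensemble: zero variance
  m2 <- lifetime_moments(0.3, 4, 0.7 * 4)
  expect_equal(m2$var, 0, tolerance = 1e-12)
  # two-lifetime mixture vs direct moment oracle
  taus <- c(1, 4); x <- c(0.5, 0.5)
  tau_x <- sum(x * taus)
  tau_f <- sum(x * taus^2) / sum(x * taus)
  tau_d0 <- 4
  E <- 1 - tau_x / tau_d0
  m3 <- lifetime_moments(E, tau_d0, tau_f)
  expect_equal(m3$tau_x, tau_x)
  expect_equal(m3$var, sum(x * taus^2) - tau_x^2, tolerance = 1e-12)
})

test_that("FRET-lines relate lifetimes and efficiencies", {
  # ideal single-exponential donor: E = 1 - tau_F / tau0
  st <- fret_lines(donor_4ns, R0 = 52, tau0 = 4, kind = "static")
  expect_equal(st$E, 1 - st$tau_f / 4, tolerance = 1e-12)
  # dynamic line endpoints coincide with the states' static points
  dyn <- fret_lines(donor_4ns, R0 = 52, tau0 = 4, kind = "dynamic",
                    states = c(42, 65))
  s42 <- fret_lines(donor_4ns, kind = "static", r = c(42, 65))
  expect_equal(dyn$tau_f[dyn$frac == 1], s42$tau_f[1], tolerance = 1e-12)
  expect_equal(dyn$tau_f[dyn$frac == 0], s42$tau_f[2], tolerance = 1e-12)
  expect_error(fret_lines(donor_4ns, kind = "dynamic", states = 42),
               "two states")
  # midpoint vs brute-force photon mixture simulation
  set.seed(12)
  n_ph <- 1e6
  taup <- 1 / (1 / 4 + 0.25 * (52 / c(42, 65))^6)
  Es <- 1 - taup / 4
  species <- sample(1:2, n_ph, replace = TRUE)   # frac = 0.5
  is_acc <- stats::runif(n_ph) < Es[species]
  tmit <- stats::rexp(sum(!is_acc), rate = 1 / taup[species[!is_acc]])
  e_mc <- mean(is_acc)
  tauf_mc <- mean(tmit)
  mid <- dyn[dyn$frac == 0.5, ]
  expect_equal(mid$E, e_mc, tolerance = 0.01)
  expect_equal(mid$tau_f, tauf_mc, tolerance = 0.01)
  # the dynamic line bows to larger lifetimes than the static line
  st_dense <- fret_lines(donor_4ns, kind = "static",
                         r = seq(30, 90, 0.1))
  inner <- dyn$frac > 0.05 & dyn$frac < 0.95
  tau_static_at_E <- stats::approx(st_dense$E, st_dense$tau_f,
                                   dyn$E[inner])$y
  expect_true(all(dyn$tau_f[inner] >= tau_static_at_E - 1e-9))
})
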