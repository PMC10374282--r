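test_that("species filters are unbiased minimal-variance unmixers", {
  # disjoint-support patterns: filters are scaled indicators
  M <- cbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.25, 0.75))
  fs <- species_filters(M, s = c(1, 1, 1, 1))
  expect_equal(unname(fs$w[1, 3:4]), c(0, 0))
  expect_equal(unname(fs$w[2, 1:2]), c(0, 0))
  expect_equal(unname(fs$w %*% fs$patterns), diag(2), tolerance = 1e-12)
  # unbiasedness on random instances
  for (k in 1:10) {
    set.seed(k)
    M <- matrix(stats::runif(64 * 2), 64, 2)
    s <- stats::runif(64, 0.5, 2)
    fs <- species_filters(M, s)
    expect_equal(unname(fs$w %*% fs$patterns), diag(2), tolerance = 1e-9)
  }
  # explicit weighted least-squares matrix oracle, 3 species
  set.seed(5)
  M <- matrix(stats::runif(32 * 3), 32, 3)
  M <- sweep(M, 2, colSums(M), "/")
  s <- stats::runif(32, 0.2, 3)
  fs <- species_filters(M, s)
  oracle <- solve(t(M) %*% diag(1 / s) %*% M) %*% t(M) %*% diag(1 / s)
  expect_lt(max(abs(fs$w - oracle)), 1e-10)
  # collinear patterns rejected
  expect_error(species_filters(cbind(M[, 1], M[, 1]), s), "collinear")
})

test_that("species correlation of featureless signals is flat", {
  set.seed(21)
  # constant signal: G identically 1
  sig <- matrix(5, nrow = 2, ncol = 4096)
  fs <- species_filters(cbind(c(0.7, 0.3), c(0.2, 0.8)), c(1, 1))
  cc <- species_correlate(sig, fs, pair = c(1, 2), bin_s = 1e-5,
                          n_casc = 4)
  expect_equal(cc$g, rep(1, length(cc$g)), tolerance = 1e-12)
  # pure shot noise: G ~ 1 at positive lags (no afterpulsing modeled)
  gbar <- rowMeans(vapply(1:20, function(k) {
    set.seed(k)
    sig <- matrix(stats::rpois(2 * 8192, 3), nrow = 2)
    species_correlate(sig, fs, pair = c(1, 1), bin_s = 1e-5,
                      n_casc = 3)$g
  }, numeric(32)))
  se <- 1 / sqrt(3^2 * 8192 * 20)
  expect_lt(max(abs(gbar - 1)), 3 * se * 3)
  expect_error(species_correlate(matrix(1, 2, 2), fs, c(1, 2), 1e-5),
               "empty|signal")
})

test_that("telegraph switching produces the analytic anti-correlation", {
  # two-state exchange at k_ex = 0.5 /us -> relaxation time 2 us
  Q <- matrix(c(-0.3, 0.3, 0.2, -0.2), 2, 2, byrow = TRUE)
  rates <- rbind(c(8, 2), c(2, 8)) * 0.05   # photons per 0.2 us bin
  sim <- simulate_telegraph(Q, rates, n_bins = 4e5, bin_us = 0.2,
                            seed = 9)
  fs <- species_filters(t(rates) / colSums(t(rates)),
                        s = rowMeans(sim$signal))
  cc <- species_correlate(sim$signal, fs, pair = c(1, 2), bin_s = 0.2e-6,
                          n_casc = 5)
  # fit a single exponential to the anti-correlated dip
  lag_us <- cc$lag_s * 1e6
  sel <- lag_us < 10
  amp <- 1 - cc$g
  f <- stats::nls(a ~ a0 * exp(-l / tc), data = list(a = amp[sel],
                                                     l = lag_us[sel]),
                  start = list(a0 = max(amp), tc = 1.5))
  expect_equal(stats::coef(f)[["tc"]], 2, tolerance = 0.1)
})

test_that("the correlation model follows its closed form", {
  m <- kinetic_model(n_eff = c(HH = 2, LL = 3, CC = 2.5), t_diff = 1e-3,
                     axial = 0.25, t_c = c(2e-6, 23e-6, 297e-6),
                     a = c(0.5, 0.3, 0.2), a0_lh = 0.6, a0_hl = 0.7,
                     a_hh = c(0.3, 0.1, 0.05), a_ll = c(0.2, 0.15, 0.1),
                     ab_hh = 0.1, ab_hl = 0.12, t_b = 6e-3)
  # long-lag limit
  for (kind in c("sACF_HH", "sACF_LL", "sCCF_HL", "sCCF_LH"))
    expect_equal(fcs_model(1e3, m, kind), 1, tolerance = 1e-5)
  # zero-lag algebra for the LH cross-correlation
  expect_equal(fcs_model(0, m, "sCCF_LH"), 1 + (1 - 0.6) / 2.5)
  # independent symbolic evaluation on random draws
  set.seed(2)
  for (k in 1:10) {
    tc <- 10^stats::runif(1, -6.5, -1.5)
    gd <- 1 / (1 + tc / m$t_diff) / sqrt(1 + m$axial^2 * tc / m$t_diff)
    e <- exp(-tc / m$t_c); eb <- exp(-tc / m$t_b)
    sum3 <- sum(m$a * e)
    expect_equal(fcs_model(tc, m, "sCCF_LH"),
                 1 + gd * (1 - 0.6 * sum3) / 2.5, tolerance = 1e-12)
    expect_equal(fcs_model(tc, m, "sCCF_HL"),
                 1 + gd * (1 - 0.7 * sum3) * (1 - 0.12 * eb) / 2.5,
                 tolerance = 1e-12)
    expect_equal(fcs_model(tc, m, "sACF_HH"),
                 1 + gd * (1 + sum(m$a_hh * (e - 1))) *
                   (1 + 0.1 * (eb - 1)) / 2, tolerance = 1e-12)
    expect_equal(fcs_model(tc, m, "sACF_LL"),
                 1 + gd * (1 + sum(m$a_ll * (e - 1))) / 3,
                 tolerance = 1e-12)
  }
  expect_error(fcs_model(1e-4, m, "bogus"), "unknown")
  # amplitude normalization is enforced by construction
  expect_equal(sum(m$a), 1)
  expect_equal(sum(fusedyn:::softmax3(0.3, -1.2)), 1, tolerance = 1e-15)
})

test_that("mean relaxation time is the amplitude-weighted average", {
  expect_equal(mean_relaxation_time(c(1, 0, 0), c(5e-6, 2e-5, 3e-4)), 5e-6)
  expect_equal(mean_relaxation_time(c(0.5, 0.5, 0),
                                    c(2e-6, 23e-6, 297e-6)), 12.5e-6)
  m1 <- mean_relaxation_time(c(0.3, 0.3, 0.4), c(2e-6, 23e-6, 100e-6))
  m2 <- mean_relaxation_time(c(0.3, 0.3, 0.4), c(2e-6, 23e-6, 200e-6))
  expect_gt(m2, m1)
})

test_that("zero-noise curves refit exactly and prune unused components", {
  truth <- kinetic_model(n_eff = c(HH = 2, LL = 2, CC = 2.5),
                         t_diff = 1e-3, t_c = c(2e-6, 23e-6, 297e-6),
                         a = c(0.6, 0.3, 0.1), a0_lh = 0.5, a0_hl = 0.5,
                         a_hh = c(0.2, 0.1, 0.05),
                         a_ll = c(0.2, 0.1, 0.05))
  curves <- list(simulate_ffcs_curves(truth, noise = 0))
  start <- kinetic_model(n_eff = c(HH = 2.4, LL = 1.7, CC = 2.2),
                         t_diff = 1.3e-3, t_c = c(3e-6, 15e-6, 400e-6),
                         a = c(0.5, 0.3, 0.2), a0_lh = 0.4, a0_hl = 0.6,
                         a_hh = c(0.15, 0.12, 0.03),
                         a_ll = c(0.25, 0.08, 0.03))
  fit <- global_fit_ffcs(curves, list(start))
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$t_c, c(2e-6, 23e-6, 297e-6), tolerance = 1e-3)
  expect_equal(fit$models[[1]]$a, truth$a, tolerance = 1e-2)
  # a two-state variant needs only one relaxation: extra amplitudes ~ 0
  truth2 <- kinetic_model(n_eff = c(HH = 2, LL = 2, CC = 2.5),
                          t_diff = 1e-3, t_c = c(2e-6, 23e-6, 297e-6),
                          a = c(1e-6, 0.999998, 1e-6), a0_lh = 0.6,
                          a0_hl = 0.6, a_hh = c(0, 0.25, 0),
                          a_ll = c(0, 0.25, 0))
  curves2 <- list(simulate_ffcs_curves(truth2, noise = 1e-4, seed = 4))
  fit2 <- global_fit_ffcs(curves2, list(start))
  expect_lt(fit2$models[[1]]$a[1] + fit2$models[[1]]$a[3], 0.05)
})

test_that("shared relaxation times beat per-variant fits", {
  truth_tc <- c(2e-6, 23e-6, 297e-6)
  n_rep <- 5
  rmse_joint <- rmse_single <- matrix(0, n_rep, 3)
  for (rep in seq_len(n_rep)) {
    set.seed(400 + rep)
    curves <- list(); start <- list()
    for (i in 1:4) {
      a <- stats::runif(3); a <- a / sum(a)
      m <- kinetic_model(n_eff = c(HH = 2, LL = 2, CC = 2.5),
                         t_diff = 1e-3, t_c = truth_tc, a = a,
                         a0_lh = 0.6, a0_hl = 0.6, a_hh = a * 0.4,
                         a_ll = a * 0.4)
      curves[[i]] <- simulate_ffcs_curves(m, noise = 4e-3,
                                          variant = paste0("v", i),
                                          seed = 400 + 10 * rep + i)
      sa <- pmax(a + stats::rnorm(3, 0, 0.05), 0.05); sa <- sa / sum(sa)
      start[[i]] <- kinetic_model(n_eff = c(HH = 2.2, LL = 1.8, CC = 2.3),
                                  t_diff = 1.2e-3,
                                  t_c = truth_tc * c(1.4, 0.8, 1.3),
                                  a = sa, a0_lh = 0.5, a0_hl = 0.5,
                                  a_hh = sa * 0.35, a_ll = sa * 0.35)
    }
    joint <- global_fit_ffcs(curves, start)
    rmse_joint[rep, ] <- (joint$t_c - truth_tc) / truth_tc
    singles <- vapply(1:4, function(i)
      global_fit_ffcs(curves[i], start[i])$t_c, numeric(3))
    rmse_single[rep, ] <- (rowMeans(singles) - truth_tc) / truth_tc
  }
  expect_lt(sqrt(mean(rmse_joint^2)), sqrt(mean(rmse_single^2)) + 0.02)
  expect_lt(max(abs(rmse_joint)), 0.25)
})

test_that("exchange spectra equal the rate-matrix eigenvalues", {
  # two-state: k12 + k21 = 1/(2 us) -> single 2 us relaxation
  Q2 <- matrix(c(-0.3, 0.3, 0.2, -0.2), 2, 2, byrow = TRUE)
  expect_equal(rate_matrix_spectrum(Q2), 2, tolerance = 1e-12)
  # three-state chain vs the general (non-symmetric) eigen oracle
  Q3 <- matrix(c(-0.5, 0.5, 0,
                 0.3, -0.34, 0.04,
                 0, 0.06, -0.06), 3, 3, byrow = TRUE)
  mine <- rate_matrix_spectrum(Q3)
  ev <- eigen(Q3, only.values = TRUE)$values
  oracle <- sort(-1 / Re(ev[Re(ev) < -1e-12]))
  expect_equal(mine, oracle, tolerance = 1e-10)
  expect_error(rate_matrix_spectrum(matrix(c(1, 0, 0, 1), 2)), "sum")
})

test_that("kinetic correlations decompose onto the exchange spectrum", {
  Q <- fusedyn:::default_rate_matrix()
  E <- c(0.8, 0.3, 0.7, 0.2)
  kc <- kinetic_correlation(Q, E, 1 - E)
  expect_equal(sort(kc$times), rate_matrix_spectrum(Q), tolerance = 1e-10)
  # numeric propagator oracle via Matrix::expm
  pi_ <- stationary_distribution(Q)
  for (tc in c(0.5, 5, 50, 500)) {
    P <- as.matrix(Matrix::expm(Q * tc))
    oracle <- drop((E * pi_) %*% P %*% (1 - E)) /
      (sum(E * pi_) * sum((1 - E) * pi_))
    expect_equal(kc$g(tc), oracle, tolerance = 1e-10)
  }
  # detailed balance: HL and LH cross-correlations coincide
  kc2 <- kinetic_correlation(Q, 1 - E, E)
  expect_equal(kc$g(c(1, 10, 100)), kc2$g(c(1, 10, 100)),
               tolerance = 1e-12)
  # anti-correlation: cross term dips below the plateau
  expect_true(all(kc$g(c(0.1, 1, 10)) < 1))
})
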