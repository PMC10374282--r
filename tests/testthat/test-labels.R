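test_that("free-space accessible volume fills a uniform ball", {
  # site at a lone bead with no obstructions nearby
  s <- coarse_structure(rbind(c(0, 0, 0), c(500, 500, 500)))
  cl <- accessible_volume(s, label_site(resid = 1, linker_length = 20), 1.0)
  d <- sqrt(rowSums(sweep(cl$points, 2, cl$anchor)^2))
  # mean anchor distance of a uniform ball: 3/4 * R
  expect_equal(sum(cl$weights * d), 15, tolerance = 0.01)
  expect_true(all(d <= 20 + 1e-9))
  expect_equal(sum(cl$weights), 1, tolerance = 1e-12)
})

test_that("a fully enclosing bead shell makes the site inaccessible", {
  dirs <- matrix(stats::rnorm(3 * 500), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  shell <- coarse_structure(rbind(c(0, 0, 0), 5 * dirs), radius = 1.5)
  expect_error(
    accessible_volume(shell, label_site(resid = 1, linker_length = 20,
                                        label_radius = 3.5), 1.0),
    "inaccessible site")
})

test_that("a single obstructing bead matches rejection-sampling", {
  s <- coarse_structure(rbind(c(0, 0, 0), c(6, 0, 0)), radius = 2)
  site <- label_site(resid = 1, linker_length = 12, label_radius = 3)
  cl <- accessible_volume(s, site, 0.75)
  set.seed(42)
  pts <- sample_ball(1e6, 12)
  keep <- sqrt(rowSums(sweep(pts, 2, c(6, 0, 0))^2)) > 5  # 2 + 3
  # accessible volume fraction and centroid shift vs the oracle
  vol_frac_mc <- mean(keep)
  ball_cells <- sum(rowSums(sweep(cl$points, 2, cl$anchor)^2) >= 0)
  # count of all in-ball grid cells for the same grid
  free <- coarse_structure(rbind(c(0, 0, 0), c(500, 0, 0)), radius = 2)
  cl_free <- accessible_volume(free, site, 0.75)
  expect_equal(nrow(cl$points) / nrow(cl_free$points), vol_frac_mc,
               tolerance = 0.02)
  expect_equal(mean(cl$points[, 1]), mean(pts[keep, 1]), tolerance = 0.1)
})

test_that("accessible volume is invariant under rigid motion", {
  set.seed(8)
  beads <- cbind(stats::runif(20, -15, 15), stats::runif(20, -15, 15),
                 stats::runif(20, -15, 15))
  s1 <- coarse_structure(rbind(c(0, 0, 0), beads), radius = 2)
  ax <- c(1, 2, 3) / sqrt(14)
  xyz2 <- fusedyn:::rotate_about_axis(s1$xyz, ax, c(0, 0, 0), 1.1)
  xyz2 <- sweep(xyz2, 2, c(30, -12, 7), `+`)
  s2 <- coarse_structure(xyz2, radius = 2)
  site <- label_site(resid = 1, linker_length = 15)
  c1 <- accessible_volume(s1, site, 1.0)
  c2 <- accessible_volume(s2, site, 1.0)
  d1 <- sqrt(rowSums(sweep(c1$points, 2, c1$anchor)^2))
  d2 <- sqrt(rowSums(sweep(c2$points, 2, c2$anchor)^2))
  expect_equal(mean(d1), mean(d2), tolerance = 1.0)  # within grid error
  expect_equal(nrow(c1$points), nrow(c2$points), tolerance = 0.03 *
                 nrow(c1$points))
})

test_that("accessible contact volume reweights the contact shell", {
  s <- coarse_structure(rbind(c(0, 0, 0), c(8, 0, 0)), radius = 2)
  site <- label_site(resid = 1, linker_length = 10, label_radius = 2,
                     contact_distance = 3)
  cl <- accessible_volume(s, site, 1.0)
  # f = 0: identity
  expect_identical(accessible_contact_volume(cl, s, 0), cl)
  # f = 1: all weight within the shell
  c1 <- accessible_contact_volume(cl, s, 1)
  cut <- 2 + 2 + 3
  in_shell <- sqrt(rowSums(sweep(c1$points, 2, c(8, 0, 0))^2)) <= cut |
    sqrt(rowSums(c1$points^2)) <= cut
  expect_equal(sum(c1$weights[in_shell]), 1, tolerance = 1e-12)
  # f = 0.5: shell weight sums to 0.5, per-point ratio matches a direct
  # reweighting oracle
  ch <- accessible_contact_volume(cl, s, 0.5)
  expect_equal(sum(ch$weights[in_shell]), 0.5, tolerance = 1e-12)
  oracle <- cl$weights
  oracle[in_shell] <- oracle[in_shell] / sum(oracle[in_shell]) * 0.5
  oracle[!in_shell] <- oracle[!in_shell] / sum(oracle[!in_shell]) * 0.5
  expect_equal(ch$weights, oracle, tolerance = 1e-12)
  # monotone: larger f -> strictly larger shell weight
  fs <- c(0.1, 0.3, 0.6, 0.9)
  shell_w <- vapply(fs, function(f)
    sum(accessible_contact_volume(cl, s, f)$weights[in_shell]), numeric(1))
  expect_true(all(diff(shell_w) > 0))
  # error when a contact fraction is requested but nothing is in reach
  lone <- coarse_structure(rbind(c(0, 0, 0), c(900, 0, 0)), radius = 2)
  cl2 <- fusedyn:::new_label_cloud(matrix(c(200, 200, 200), 1), 1,
                                   c(200, 200, 200), site)
  expect_error(accessible_contact_volume(cl2, lone, 0.5), "contact shell")
})

test_that("distance distributions integrate to one and locate deltas", {
  c1 <- fusedyn:::new_label_cloud(matrix(c(0, 0, 0), 1), 1, c(0, 0, 0),
                                  label_site(1))
  c2 <- fusedyn:::new_label_cloud(matrix(c(40, 0, 0), 1), 1, c(40, 0, 0),
                                  label_site(2))
  dd <- cloud_distance_distribution(c1, c2, nbins = 64, range = c(30, 50))
  expect_equal(attr(dd, "mean"), 40)
  expect_equal(attr(dd, "sd"), 0)
  expect_lt(abs(dd$r[which.max(dd$p)] - 40), diff(range(dd$r)) / 64)
  expect_equal(pracma::trapz(dd$r, dd$p), 1, tolerance = 1e-9)
})

test_that("ball-to-ball mean distance matches Monte-Carlo", {
  s <- coarse_structure(rbind(c(0, 0, 0), c(40, 0, 0), c(700, 0, 0)),
                        radius = 0.1)
  site <- label_site(1, linker_length = 10, label_radius = 0.05)
  ca <- accessible_volume(s, site, 1.0)
  sb <- label_site(2, linker_length = 10, label_radius = 0.05)
  cb <- accessible_volume(s, sb, 1.0)
  dd <- cloud_distance_distribution(ca, cb, nbins = 200, max_points = 1e5)
  set.seed(99)
  mc <- mean(sqrt(rowSums((sample_ball(1e6, 10) -
                             sample_ball(1e6, 10, c(40, 0, 0)))^2)))
  expect_equal(attr(dd, "mean"), mc, tolerance = 0.1 / mc)
})

test_that("FRET observables follow the efficiency average", {
  mk <- function(x) fusedyn:::new_label_cloud(matrix(x, 1), 1, x,
                                              label_site(1))
  # single points at R0: E = 0.5, apparent distance = R0
  obs <- fret_observables(mk(c(0, 0, 0)), mk(c(52, 0, 0)), R0 = 52)
  expect_equal(obs$mean_efficiency, 0.5, tolerance = 1e-12)
  expect_equal(obs$fret_distance, 52, tolerance = 1e-9)
  # infinite separation limit
  far <- fret_observables(mk(c(0, 0, 0)), mk(c(5000, 0, 0)), R0 = 52)
  expect_lt(far$mean_efficiency, 1e-10)
  # coincident points count as E = 1
  same <- fret_observables(mk(c(0, 0, 0)), mk(c(0, 0, 0)), R0 = 52)
  expect_equal(same$mean_efficiency, 1)
})

test_that("cloud-pair efficiency matches the Monte-Carlo oracle", {
  s <- coarse_structure(rbind(c(0, 0, 0), c(50, 0, 0), c(700, 0, 0)),
                        radius = 0.1)
  ca <- accessible_volume(s, label_site(1, 10, label_radius = 0.05), 1.0)
  cb <- accessible_volume(s, label_site(2, 10, label_radius = 0.05), 1.0)
  obs <- fret_observables(ca, cb, R0 = 52, max_points = 1e5)
  set.seed(7)
  p1 <- sample_ball(1e6, 10); p2 <- sample_ball(1e6, 10, c(50, 0, 0))
  d <- sqrt(rowSums((p1 - p2)^2))
  e_mc <- mean(1 / (1 + (d / 52)^6))
  expect_equal(obs$mean_efficiency, e_mc, tolerance = 0.002)
})

test_that("apparent FRET distance equals the direct oracle on random clouds", {
  for (k in 1:20) {
    c1 <- random_cloud(40, stats::runif(3, -20, 20), 4, seed = k)
    c2 <- random_cloud(35, stats::runif(3, 20, 60), 5, seed = 100 + k)
    obs <- fret_observables(c1, c2, R0 = 52)
    e <- mean_efficiency_r(c1$points, c1$weights, c2$points, c2$weights, 52)
    expect_equal(obs$mean_efficiency, e, tolerance = 1e-10)
    expect_equal(obs$fret_distance, 52 * (1 / e - 1)^(1 / 6),
                 tolerance = 1e-10)
    expect_equal(obs$mean_distance,
                 mean_distance_r(c1$points, c1$weights, c2$points,
                                 c2$weights), tolerance = 1e-10)
  }
})
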