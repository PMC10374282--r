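#' Toy two-conformer system
#'
#' Builds a deterministic coarse C-alpha bead chain (3.8 A spacing) made
#' of rigid bodies joined at junctions, and a second conformer obtained by
#' rotating the distal bodies about a hinge — a minimal stand-in for a
#' multi-domain protein switching between a major (M1) and minor (M2)
#' conformation. FRET and spin-label site pairs across the hinge are
#' selected so the inter-label distance changes span roughly 5-30 A, and
#' a reversible exchange rate matrix defines the kinetics between
#' conformational substates.
#'
#' @param n_bodies number of rigid bodies (>= 2).
#' @param body_length beads per body.
#' @param hinge_angle rotation between the conformers, degrees.
#' @param hinge_body bodies after this index rotate (default: half).
#' @param n_fret_pairs,n_spin_pairs number of label site pairs.
#' @param x_m1 ground-truth population of conformer M1.
#' @param rate_matrix exchange rate matrix in 1/us (rows sum to 0);
#'   default: a reversible 4-state chain whose relaxation times span
#'   roughly 2-300 us.
#' @param seed RNG seed (the system is bit-identical for a fixed seed).
#' @return object of class `toy_system`: structures `m1`, `m2`
#'   ([coarse_structure()]), `fret_pairs`, `spin_pairs` (data.frames of
#'   residue pairs), `x_m1`, `rate_matrix`, `hinge` (pivot info), `seed`.
#' @export
make_toy_system <- function(n_bodies = 4, body_length = 20,
                            hinge_angle = 30, hinge_body = NULL,
                            n_fret_pairs = 6, n_spin_pairs = 4,
                            x_m1 = 0.61, rate_matrix = NULL, seed = 1) {
  if (n_bodies < 2) stop("need at least two rigid bodies")
  if (is.null(hinge_body)) hinge_body <- floor(n_bodies / 2)
  set.seed(seed)
  # chain of bodies with large deterministic turns -> compact fold
  dirs <- matrix(0, n_bodies, 3)
  dirs[1, ] <- c(1, 0, 0)
  for (b in 2:n_bodies) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 100, 150) * pi / 180
    dirs[b, ] <- drop(rotate_about_axis(matrix(dirs[b - 1, ], 1), ax,
                                        c(0, 0, 0), ang))
  }
  xyz <- matrix(0, n_bodies * body_length, 3)
  body <- integer(n_bodies * body_length)
  pos <- c(0, 0, 0)
  k <- 0
  for (b in seq_len(n_bodies)) for (i in seq_len(body_length)) {
    k <- k + 1
    xyz[k, ] <- pos
    body[k] <- b
    pos <- pos + 3.8 * dirs[b, ]
  }
  m1 <- coarse_structure(xyz, radius = 1.9, body = body)
  pivot_idx <- max(which(body == hinge_body))
  pivot <- xyz[pivot_idx, ]
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  moving <- body > hinge_body
  xyz2 <- xyz
  xyz2[moving, ] <- rotate_about_axis(xyz[moving, , drop = FALSE], ax,
                                      pivot, hinge_angle * pi / 180)
  m2 <- coarse_structure(xyz2, radius = 1.9, body = body)

  fret_pairs <- select_label_pairs(m1, m2, body, hinge_body, n_fret_pairs,
                                   d_range = c(28, 78),
                                   change_range = c(4, 32))
  spin_pairs <- select_label_pairs(m1, m2, body, hinge_body, n_spin_pairs,
                                   d_range = c(20, 60),
                                   change_range = c(3, 25))
  if (is.null(rate_matrix)) rate_matrix <- default_rate_matrix()
  structure(list(
    m1 = m1, m2 = m2,
    fret_pairs = fret_pairs,
    spin_pairs = spin_pairs,
    x_m1 = x_m1, rate_matrix = rate_matrix,
    hinge = list(pivot = pivot, axis = ax, angle_deg = hinge_angle,
                 body = hinge_body, pivot_resid = pivot_idx),
    seed = seed), class = "toy_system")
}

# reversible 4-state chain, relaxation times roughly 2 / 25 / 290 us
default_rate_matrix <- function() {
  k <- c(k12 = 0.35, k21 = 0.25, k23 = 0.025, k32 = 0.02,
         k34 = 0.0022, k43 = 0.0018)
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- k["k12"]; Q[2, 1] <- k["k21"]
  Q[2, 3] <- k["k23"]; Q[3, 2] <- k["k32"]
  Q[3, 4] <- k["k34"]; Q[4, 3] <- k["k43"]
  diag(Q) <- -rowSums(Q)
  unname(Q)
}

select_label_pairs <- function(m1, m2, body, hinge_body, n_pairs,
                               d_range, change_range) {
  if (n_pairs < 1) return(data.frame())
  fixed <- which(body <= hinge_body)
  moving <- which(body > hinge_body)
  cand1 <- fixed[fixed %% 2 == 0]
  cand2 <- moving[moving %% 2 == 0]
  grid <- expand.grid(resid1 = cand1, resid2 = cand2)
  d1 <- sqrt(rowSums((m1$xyz[grid$resid1, ] - m1$xyz[grid$resid2, ])^2))
  d2 <- sqrt(rowSums((m2$xyz[grid$resid1, ] - m2$xyz[grid$resid2, ])^2))
  grid$d_m1 <- d1; grid$d_m2 <- d2; grid$change <- abs(d2 - d1)
  # relax the windows stepwise if the geometry offers too few pairs
  for (relax in seq(1, 2, 0.25)) {
    ok <- grid[d1 > d_range[1] / relax & d1 < d_range[2] * relax &
                 grid$change >= change_range[1] / relax &
                 grid$change <= change_range[2] * relax, ]
    if (nrow(ok) >= n_pairs) break
  }
  if (nrow(ok) < n_pairs)
    ok <- grid[order(abs(d1 - mean(d_range)))[seq_len(min(nrow(grid),
                                                          n_pairs))], ]
  # spread the selected pairs over the span of distance changes
  ok <- ok[order(ok$change), ]
  idx <- unique(round(seq(1, nrow(ok), length.out = n_pairs)))
  out <- ok[idx, ]
  rownames(out) <- NULL
  out
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf(paste0("toy_system: %d beads, hinge %g deg at residue %d, ",
                     "%d FRET + %d spin pairs, x_M1 = %.2f\n"),
              n_beads(x$m1), x$hinge$angle_deg, x$hinge$pivot_resid,
              nrow(x$fret_pairs), nrow(x$spin_pairs), x$x_m1))
  invisible(x)
}

#' Simulate all measurement modalities for a toy system
#'
#' Generates a statistically faithful synthetic data bundle: per-FRET-pair
#' TCSPC decays (two-Gaussian distance mixture at the AV-predicted state
#' distances, Poisson counts), DEER traces (Gaussian spin-spin components,
#' exponential background, Gaussian noise), filtered-FCS curves (kinetic
#' amplitudes derived from the system's rate matrix per variant), NSE
#' spectra and SAXS curves of the two-state structure mixture, and a
#' restraint table whose experimental distances are the truth predictions
#' perturbed within the stated uncertainties. Ground truth and all
#' parameters are stored alongside.
#'
#' @param system a [make_toy_system()] result.
#' @param seed RNG seed for all noise draws.
#' @param n_photons TCSPC fluorescence photons per dataset.
#' @param channel_ns TCSPC channel width (ns).
#' @param n_channels TCSPC channels.
#' @param deer_noise Gaussian noise SD on DEER traces.
#' @param saxs_noise relative SAXS noise.
#' @param nse_noise absolute NSE noise (normalized ISF units).
#' @param restraint_sigma quoted restraint uncertainty in Angstrom (the
#'   full error budget: statistical + systematic allowances).
#' @param restraint_scatter SD of the random scatter actually applied to
#'   the restraint distances (default half the quoted sigma, mirroring
#'   conservative experimental error budgets).
#' @param x_mix SAXS/NSE mixture fraction of M1 (the low-temperature
#'   structural population; default 0.31).
#' @param grid_spacing AV grid spacing (A).
#' @return list of class `modality_bundle` with elements `tcspc`, `deer`,
#'   `ffcs`, `nse`, `saxs`, `restraints`, `truth`.
#' @export
simulate_modalities <- function(system, seed = 1, n_photons = 2e6,
                                channel_ns = 0.0141, n_channels = 4096,
                                deer_noise = 0.005, saxs_noise = 0.01,
                                nse_noise = 0.007, restraint_sigma = 3,
                                restraint_scatter = restraint_sigma / 2,
                                x_mix = 0.31, grid_spacing = 1.5) {
  set.seed(seed)
  donor_ref <- fluorophore_reference(1, 4, role = "donor")
  t_ns <- seq(0, by = channel_ns, length.out = n_channels)
  fret_site0 <- label_site(1)
  spin_site0 <- spin_label_site(1)

  av_dist <- function(structure, resid1, resid2, site0, kind) {
    s1 <- site0; s1$resid <- resid1
    s2 <- site0; s2$resid <- resid2
    c1 <- accessible_volume(structure, s1, grid_spacing)
    c2 <- accessible_volume(structure, s2, grid_spacing)
    if (kind == "FRET") fret_observables(c1, c2)$fret_distance
    else attr(cloud_distance_distribution(c1, c2, kind = "spin"), "mean")
  }

  ## --- TCSPC -------------------------------------------------------------
  tcspc <- list()
  fret_truth <- data.frame()
  for (i in seq_len(nrow(system$fret_pairs))) {
    pr <- system$fret_pairs[i, ]
    r1 <- av_dist(system$m1, pr$resid1, pr$resid2, fret_site0, "FRET")
    r2 <- av_dist(system$m2, pr$resid1, pr$resid2, fret_site0, "FRET")
    gm <- gaussian_mixture_distance(r1, r2, width = 12, x1 = system$x_m1)
    irf <- gaussian_irf(t_ns, fwhm_ns = 0.254)
    tcspc[[i]] <- simulate_tcspc(gm, donor_ref, t_ns, irf = irf,
                                 n_photons = n_photons)
    fret_truth <- rbind(fret_truth,
                        data.frame(pair = i, resid1 = pr$resid1,
                                   resid2 = pr$resid2, r_m1 = r1, r_m2 = r2))
  }

  ## --- DEER --------------------------------------------------------------
  r_nm <- seq(1.5, 8, 0.05)
  # long enough to resolve the slowest dipolar period of ~6 nm distances
  t_us <- seq(0, 8, length.out = 256)
  kern <- dipolar_kernel(t_us, r_nm)
  deer <- list()
  spin_truth <- data.frame()
  for (i in seq_len(nrow(system$spin_pairs))) {
    pr <- system$spin_pairs[i, ]
    r1 <- av_dist(system$m1, pr$resid1, pr$resid2, spin_site0, "spin") / 10
    r2 <- av_dist(system$m2, pr$resid1, pr$resid2, spin_site0, "spin") / 10
    p <- distance_distribution(
      r_nm, system$x_m1 * stats::dnorm(r_nm, r1, 0.25) +
        (1 - system$x_m1) * stats::dnorm(r_nm, r2, 0.25),
      kind = "spin", unit = "nm")
    deer[[i]] <- simulate_deer(p, kern, delta = 0.3, k = 0.05,
                               noise_sd = deer_noise)
    spin_truth <- rbind(spin_truth,
                        data.frame(pair = i, resid1 = pr$resid1,
                                   resid2 = pr$resid2, r_m1 = r1 * 10,
                                   r_m2 = r2 * 10))
  }

  ## --- filtered FCS ------------------------------------------------------
  times_us <- rate_matrix_spectrum(system$rate_matrix)
  n_states <- nrow(system$rate_matrix)
  ffcs <- list()
  ffcs_models <- list()
  for (i in seq_len(nrow(system$fret_pairs))) {
    # states alternate between M1-like and M2-like substates
    rr <- c(fret_truth$r_m1[i], fret_truth$r_m2[i])
    st_r <- rr[rep_len(1:2, n_states)] + stats::rnorm(n_states, 0, 1.5)
    E <- 1 / (1 + (st_r / 52)^6)
    kc <- kinetic_correlation(system$rate_matrix, E, 1 - E)
    a_raw <- pmax(-kc$amplitudes, 1e-4)   # anti-correlation amplitudes
    model <- kinetic_model(
      n_eff = c(HH = 2, LL = 2, CC = 2.5), t_diff = 1e-3,
      t_c = times_us * 1e-6,
      a = a_raw / sum(a_raw),
      a0_lh = min(0.9, sum(pmax(-kc$amplitudes, 0))),
      a0_hl = min(0.9, sum(pmax(-kc$amplitudes, 0))),
      a_hh = 0.5 * a_raw / sum(a_raw), a_ll = 0.4 * a_raw / sum(a_raw))
    ffcs_models[[i]] <- model
    ffcs[[i]] <- simulate_ffcs_curves(model, variant = sprintf("v%d", i))
  }

  ## --- NSE ---------------------------------------------------------------
  tens1 <- kirkwood_tensor(system$m1)
  tens2 <- kirkwood_tensor(system$m2)
  qs <- seq(0.4, 2, length.out = 5)
  tf <- seq(0, 120, length.out = 16)
  nse <- lapply(qs, function(qq) {
    hp <- hydro_params(h_t = 1, h_r = 1)
    v <- x_mix * nse_isf(system$m1, tens1, hp, qq, tf) +
      (1 - x_mix) * nse_isf(system$m2, tens2, hp, qq, tf)
    v <- v + stats::rnorm(length(v), sd = nse_noise) * (tf > 0)
    nse_curve(qq, tf, v, sd = rep(nse_noise, length(tf)))
  })

  ## --- SAXS --------------------------------------------------------------
  qA <- seq(0.008, 0.25, length.out = 120)
  i1 <- debye_scattering(system$m1, qA)
  i2 <- debye_scattering(system$m2, qA)
  imix <- x_mix * i1$i + (1 - x_mix) * i2$i
  sig <- saxs_noise * imix * (1 + (qA / max(qA)) * 3)
  # quoted sigma = 2x the applied noise (systematic allowance)
  saxs <- saxs_curve(qA, imix + stats::rnorm(length(qA), sd = sig),
                     2 * sig, unit = "A-1")

  ## --- restraints --------------------------------------------------------
  rows <- rbind(
    data.frame(pair_id = sprintf("F%d", fret_truth$pair),
               resid1 = fret_truth$resid1, resid2 = fret_truth$resid2,
               technique = "FRET",
               state = rep(c("M1", "M2"), each = nrow(fret_truth)),
               distance = c(fret_truth$r_m1, fret_truth$r_m2)),
    if (nrow(spin_truth))
      data.frame(pair_id = sprintf("D%d", spin_truth$pair),
                 resid1 = spin_truth$resid1, resid2 = spin_truth$resid2,
                 technique = "DEER",
                 state = rep(c("M1", "M2"), each = nrow(spin_truth)),
                 distance = c(spin_truth$r_m1, spin_truth$r_m2)))
  rows$distance <- rows$distance + stats::rnorm(nrow(rows),
                                                sd = restraint_scatter)
  rows$sigma_minus <- restraint_sigma
  rows$sigma_plus <- restraint_sigma
  restraints <- restraint_table(rows)

  structure(list(
    tcspc = tcspc, deer = deer, ffcs = ffcs, nse = nse, saxs = saxs,
    restraints = restraints,
    truth = list(x_m1 = system$x_m1, x_mix = x_mix,
                 fret = fret_truth, spin = spin_truth,
                 relaxation_times_us = times_us,
                 ffcs_models = ffcs_models,
                 seed = seed, n_photons = n_photons,
                 channel_ns = channel_ns)),
    class = "modality_bundle")
}

#' Gaussian instrument response on a TCSPC grid
#'
#' @param t time grid (ns).
#' @param fwhm_ns full width at half maximum (default 254 ps).
#' @param t0 peak position (ns).
#' @export
gaussian_irf <- function(t, fwhm_ns = 0.254, t0 = 5 * fwhm_ns) {
  s <- fwhm_ns / (2 * sqrt(2 * log(2)))
  irf <- stats::dnorm(t, t0, s)
  irf / sum(irf)
}

#' Candidate structure ensemble for discrimination tests
#'
#' The truth conformer plus decoys generated by random rigid-body
#' rotations of the distal bodies about the hinge (plus small whole-body
#' rotations), graded so the decoy RMSDs to truth span roughly the
#' requested range; each structure is labelled with its superposed RMSD.
#'
#' @param system a [make_toy_system()].
#' @param which `"M1"` or `"M2"`: which conformer to decoy.
#' @param n_decoys number of decoys (>= 1).
#' @param rmsd_range target decoy RMSD span in Angstrom.
#' @param seed RNG seed.
#' @return list with `structures` (truth first) and `rmsd` (0 for truth).
#' @export
candidate_ensemble <- function(system, which = c("M1", "M2"), n_decoys = 6,
                               rmsd_range = c(5, 40), seed = 1) {
  which <- match.arg(which)
  truth <- if (which == "M1") system$m1 else system$m2
  set.seed(seed + (which == "M2"))
  moving <- truth$body > system$hinge$body
  targets <- seq(rmsd_range[1], rmsd_range[2], length.out = n_decoys)
  structures <- list(truth)
  rmsds <- 0
  make_decoy <- function(ang, ax, shift) {
    xyz <- truth$xyz
    xyz[moving, ] <- rotate_about_axis(xyz[moving, , drop = FALSE], ax,
                                       system$hinge$pivot, ang)
    xyz[moving, ] <- sweep(xyz[moving, , drop = FALSE], 2, shift, `+`)
    coarse_structure(xyz, radius = truth$radius, body = truth$body)
  }
  for (d in seq_len(n_decoys)) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    sh <- stats::rnorm(3); sh <- sh / sqrt(sum(sh^2)) * 0.2 * targets[d]
    if (targets[d] <= 0) {
      structures[[d + 1]] <- truth
      rmsds <- c(rmsds, 0)
      next
    }
    ang <- 20 * pi / 180
    # two secant refinements of the hinge angle toward the target RMSD
    for (it in 1:3) {
      got <- structure_rmsd(make_decoy(ang, ax, sh), truth)
      if (abs(got - targets[d]) < 0.05 * targets[d]) break
      ang <- min(pi, max(0.005, ang * targets[d] / max(got, 1e-6)))
    }
    dec <- make_decoy(ang, ax, sh)
    structures[[d + 1]] <- dec
    rmsds <- c(rmsds, structure_rmsd(dec, truth))
  }
  list(structures = structures, rmsd = rmsds)
}
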