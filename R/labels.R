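#' Describe a label attachment site
#'
#' Parameters of a dye or spin label tethered to a residue: the linker
#' length and width, an effective label radius (a single sphere standing in
#' for the dye), and the accessible-contact-volume (ACV) parameters: the
#' distance from the protein surface that defines the contact shell, and
#' the fraction of the label population residing in it. Defaults are
#' typical for Alexa-type dyes on maleimide linkers.
#'
#' @param resid residue id of the attachment bead.
#' @param linker_length maximal anchor-to-label distance in Angstrom (> 0).
#' @param linker_width linker diameter in Angstrom (geometry bookkeeping
#'   only; the grid search uses the effective label radius).
#' @param label_radius effective label radius in Angstrom.
#' @param contact_distance thickness of the contact shell above the bead
#'   surface, in Angstrom.
#' @param contact_fraction fraction of label density trapped in the contact
#'   shell, in `[0, 1]`.
#' @param seed_radius radius around the anchor within which clash-free grid
#'   cells seed the accessibility flood fill, in Angstrom.
#' @return an object of class `label_site`.
#' @export
label_site <- function(resid, linker_length = 20, linker_width = 4.5,
                       label_radius = 3.5, contact_distance = 4,
                       contact_fraction = 0, seed_radius = 6) {
  if (linker_length <= 0) stop("linker_length must be positive")
  if (contact_fraction < 0 || contact_fraction > 1)
    stop("contact_fraction must lie in [0, 1]")
  structure(list(resid = resid, linker_length = linker_length,
                 linker_width = linker_width, label_radius = label_radius,
                 contact_distance = contact_distance,
                 contact_fraction = contact_fraction,
                 seed_radius = seed_radius),
            class = "label_site")
}

#' Spin-label site with MTSSL-like defaults
#'
#' Same machinery as [label_site()] with the shorter linker of a nitroxide
#' spin label (approx. 8 A length, 4.5 A width, compact head group).
#'
#' @inheritParams label_site
#' @param ... passed to [label_site()].
#' @export
spin_label_site <- function(resid, linker_length = 8, linker_width = 4.5,
                            label_radius = 2.5, ...) {
  label_site(resid, linker_length = linker_length,
             linker_width = linker_width, label_radius = label_radius, ...)
}

#' Accessible volume of a tethered label
#'
#' Simulates the positional distribution of a dye or spin label as the set
#' of grid points within the linker length of its attachment bead that do
#' not clash with any protein bead (point-bead distance greater than bead
#' radius + label radius) and that are reachable from the anchor through
#' clash-free neighbouring cells. Weights are uniform; [accessible_contact_volume()]
#' reweights them for surface-trapped dye populations.
#'
#' The attachment bead itself never obstructs, and the flood fill is seeded
#' from every clash-free cell within `site$seed_radius` of the anchor so
#' that labels on bead chains (where covalently bonded neighbours overlap
#' the anchor cell) can emerge.
#'
#' @param structure a [coarse_structure()].
#' @param site a [label_site()]; `site$resid` must exist in the structure.
#' @param grid_spacing grid resolution in Angstrom (default 1.0).
#' @return an object of class `label_cloud` with fields `points` (n x 3),
#'   `weights` (normalized), `anchor`, and `site`.
#' @export
accessible_volume <- function(structure, site, grid_spacing = 1.0) {
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  idx <- match(site$resid, structure$resid)
  if (is.na(idx)) stop("attachment residue ", site$resid, " not in structure")
  anchor <- structure$xyz[idx, ]
  pts <- cpp_accessible_volume(anchor, structure$xyz, structure$radius,
                               idx - 1L, site$linker_length,
                               site$label_radius, grid_spacing,
                               site$seed_radius)
  if (nrow(pts) == 0L)
    stop("inaccessible site: no sterically allowed label positions at residue ",
         site$resid)
  new_label_cloud(pts, rep(1 / nrow(pts), nrow(pts)), anchor, site)
}

new_label_cloud <- function(points, weights, anchor, site) {
  structure(list(points = points, weights = weights / sum(weights),
                 anchor = anchor, site = site),
            class = "label_cloud")
}

#' @export
print.label_cloud <- function(x, ...) {
  d <- sqrt(rowSums(sweep(x$points, 2, x$anchor)^2))
  cat(sprintf("label_cloud: %d positions, residue %s, <d(anchor)> = %.1f A\n",
              nrow(x$points), format(x$site$resid),
              sum(x$weights * d)))
  invisible(x)
}

#' Accessible contact volume reweighting
#'
#' Splits an accessible volume into a contact shell (points within
#' `contact_distance` of any bead surface) and a free part, assigning total
#' weight `contact_fraction` to the shell and `1 - contact_fraction` to the
#' free part, mimicking dyes that transiently stick to the protein surface.
#'
#' @param cloud a `label_cloud` from [accessible_volume()].
#' @param structure the [coarse_structure()] the cloud was computed on.
#' @param contact_fraction overrides `cloud$site$contact_fraction` if given.
#' @return a reweighted `label_cloud`.
#' @export
accessible_contact_volume <- function(cloud, structure,
                                      contact_fraction = NULL) {
  f <- if (is.null(contact_fraction)) cloud$site$contact_fraction
       else contact_fraction
  if (f < 0 || f > 1) stop("contact fraction must lie in [0, 1]")
  if (f == 0) return(cloud)
  cut <- structure$radius + cloud$site$label_radius + cloud$site$contact_distance
  in_shell <- rep(FALSE, nrow(cloud$points))
  for (b in seq_len(nrow(structure$xyz))) {
    d2 <- rowSums(sweep(cloud$points, 2, structure$xyz[b, ])^2)
    in_shell <- in_shell | d2 <= cut[b]^2
  }
  if (!any(in_shell))
    stop("contact fraction ", f, " requested but no cloud point lies within ",
         "the contact shell; increase contact_distance or check the site")
  w <- cloud$weights
  ws <- sum(w[in_shell]); wf <- sum(w[!in_shell])
  if (wf == 0) {
    w <- w / ws
  } else {
    w[in_shell] <- w[in_shell] / ws * f
    w[!in_shell] <- w[!in_shell] / wf * (1 - f)
  }
  new_label_cloud(cloud$points, w, cloud$anchor, cloud$site)
}

#' Inter-label distance distribution from two label clouds
#'
#' Weighted histogram of all pairwise distances between two clouds,
#' normalized to unit trapezoid integral. Very large clouds can be
#' subsampled (weighted, seeded) to bound the cost.
#'
#' @param cloud1,cloud2 `label_cloud` objects.
#' @param nbins number of histogram bins.
#' @param range distance range in Angstrom; defaults to the data range
#'   padded by one bin.
#' @param kind `"FRET"` or `"spin"` tag carried by the result.
#' @param max_points subsample clouds above this size (default 4000).
#' @param seed RNG seed for the subsample.
#' @return a [distance_distribution()] with attributes `mean` and `sd` (A).
#' @export
cloud_distance_distribution <- function(cloud1, cloud2, nbins = 128,
                                        range = NULL, kind = "FRET",
                                        max_points = 4000, seed = 1) {
  c1 <- subsample_cloud(cloud1, max_points, seed)
  c2 <- subsample_cloud(cloud2, max_points, seed + 1)
  if (is.null(range)) {
    dmid <- sqrt(sum((colSums(c1$points * c1$weights) -
                      colSums(c2$points * c2$weights))^2))
    reach <- cloud1$site$linker_length + cloud2$site$linker_length
    range <- c(max(0, dmid - reach - 2), dmid + reach + 2)
  }
  breaks <- seq(range[1], range[2], length.out = nbins + 1)
  st <- cpp_pair_stats(c1$points, c1$weights, c2$points, c2$weights,
                       52, breaks)
  mids <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  dd <- distance_distribution(mids, st$hist, kind = kind)
  attr(dd, "mean") <- st$sum_r / st$sw
  attr(dd, "sd") <- sqrt(max(0, st$sum_r2 / st$sw - (st$sum_r / st$sw)^2))
  dd
}

subsample_cloud <- function(cloud, max_points, seed) {
  n <- nrow(cloud$points)
  if (n <= max_points) return(cloud)
  set.seed(seed)
  idx <- sample.int(n, max_points, prob = cloud$weights, replace = TRUE)
  new_label_cloud(cloud$points[idx, , drop = FALSE],
                  rep(1 / max_points, max_points), cloud$anchor, cloud$site)
}

#' Probability density over an inter-label distance grid
#'
#' @param r uniform distance grid.
#' @param p non-negative density values; renormalized so the trapezoid
#'   integral is exactly 1 (unless `scale` marks an explicit scaling by a
#'   FRET-inactive fraction).
#' @param kind `"FRET"` or `"spin"`.
#' @param unit `"angstrom"` or `"nm"`.
#' @param scale optional explicit total (flagged, e.g. `1 - x_DOnly`).
#' @export
distance_distribution <- function(r, p, kind = "FRET", unit = "angstrom",
                                  scale = NULL) {
  if (length(r) != length(p)) stop("r and p must have equal length")
  if (any(p < -1e-12)) stop("density values must be non-negative")
  p <- pmax(p, 0)
  dr <- diff(r)
  if (length(dr) && max(abs(dr - dr[1])) > 1e-6 * dr[1])
    stop("distance grid must be uniform")
  tot <- pracma::trapz(r, p)
  if (tot <= 0) stop("density integrates to zero")
  target <- if (is.null(scale)) 1 else scale
  structure(list(r = r, p = p / tot * target,
                 spacing = if (length(dr)) dr[1] else NA_real_,
                 kind = kind, unit = unit, scale = scale),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  m <- distribution_moments(x)
  cat(sprintf("distance_distribution (%s): %d points on [%.2f, %.2f] %s, ",
              x$kind, length(x$r), min(x$r), max(x$r), x$unit))
  cat(sprintf("<R> = %.2f, SD = %.2f\n", m$mean, m$sd))
  invisible(x)
}

#' Mean and standard deviation of a distance distribution
#'
#' Trapezoid moments of the normalized density.
#'
#' @param dist a [distance_distribution()].
#' @return list with `mean` and `sd` in the distribution's unit.
#' @export
distribution_moments <- function(dist) {
  tot <- pracma::trapz(dist$r, dist$p)
  m1 <- pracma::trapz(dist$r, dist$r * dist$p) / tot
  m2 <- pracma::trapz(dist$r, dist$r^2 * dist$p) / tot
  list(mean = m1, sd = sqrt(max(0, m2 - m1^2)))
}

#' FRET observables from two label clouds
#'
#' Cloud-averaged donor-acceptor distance, mean FRET efficiency under the
#' isotropic-averaging regime (kappa^2 = 2/3, efficiencies averaged over
#' the label position pairs), and the FRET-averaged apparent distance
#' \eqn{R0 (1/E - 1)^{1/6}}. Coincident position pairs contribute E = 1.
#'
#' @param cloud1,cloud2 `label_cloud` objects.
#' @param R0 Forster radius in Angstrom.
#' @param max_points,seed cloud subsampling control as in
#'   [cloud_distance_distribution()].
#' @return list with `mean_distance`, `mean_efficiency`,
#'   `fret_distance` (all Angstrom / dimensionless).
#' @export
fret_observables <- function(cloud1, cloud2, R0 = 52,
                             max_points = 4000, seed = 1) {
  if (R0 <= 0) stop("R0 must be positive")
  c1 <- subsample_cloud(cloud1, max_points, seed)
  c2 <- subsample_cloud(cloud2, max_points, seed + 1)
  st <- cpp_pair_stats(c1$points, c1$weights, c2$points, c2$weights,
                       R0, c(0, 1))
  e <- st$sum_e / st$sw
  list(mean_distance = st$sum_r / st$sw,
       mean_efficiency = e,
       fret_distance = R0 * (1 / e - 1)^(1 / 6))
}
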