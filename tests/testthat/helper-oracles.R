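# Shared fixtures and brute-force oracles used across test files.

# uniform ball sampler (rejection-free via radius transform)
sample_ball <- function(n, radius, center = c(0, 0, 0)) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * stats::runif(n)^(1 / 3)
  sweep(u * r, 2, center, `+`)
}

# weighted mean FRET efficiency between two explicit point sets (R route,
# independent of the compiled pair kernel)
mean_efficiency_r <- function(p1, w1, p2, w2, r0) {
  tot <- 0
  for (i in seq_len(nrow(p1))) {
    d <- sqrt(colSums((t(p2) - p1[i, ])^2))
    e <- ifelse(d <= 0, 1, 1 / (1 + (d / r0)^6))
    tot <- tot + w1[i] * sum(w2 * e)
  }
  tot / (sum(w1) * sum(w2))
}

mean_distance_r <- function(p1, w1, p2, w2) {
  tot <- 0
  for (i in seq_len(nrow(p1))) {
    d <- sqrt(colSums((t(p2) - p1[i, ])^2))
    tot <- tot + w1[i] * sum(w2 * d)
  }
  tot / (sum(w1) * sum(w2))
}

# random small label cloud for property tests
random_cloud <- function(n, center, spread, seed) {
  set.seed(seed)
  pts <- sweep(matrix(stats::rnorm(3 * n, sd = spread), ncol = 3), 2,
               center, `+`)
  w <- stats::runif(n); w <- w / sum(w)
  fusedyn:::new_label_cloud(pts, w, center, label_site(1))
}

# solid-sphere bead model (deterministic grid fill)
sphere_structure <- function(radius, spacing = 1.5, bead_radius = 0.8) {
  g <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(g, g, g))
  pts <- pts[rowSums(pts^2) <= radius^2, ]
  coarse_structure(pts, radius = bead_radius)
}

# single-exponential donor used widely
donor_4ns <- fluorophore_reference(1, 4, role = "donor")
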