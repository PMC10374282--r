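#' 6x6 rigid-body diffusion tensor specification
#'
#' Container for the grand mobility/diffusion tensor of a rigid body:
#' translational block (nm^2/ns), rotational block (1/ns) and coupling
#' blocks (nm/ns), about a stated center (the center of diffusion). Such
#' tensors are normally produced by an external hydrodynamic-bead tool;
#' [kirkwood_tensor()] builds approximate ones for synthetic work.
#'
#' @param D 6x6 symmetric positive semidefinite matrix.
#' @param center 3-vector, tensor origin in nm.
#' @return object of class `diffusion_tensor` with scalar traces `d_t`
#'   (nm^2/ns) and `d_r` (1/ns).
#' @export
diffusion_tensor <- function(D, center = c(0, 0, 0)) {
  D <- as.matrix(D)
  if (!all(dim(D) == c(6, 6))) stop("D must be 6x6")
  if (max(abs(D - t(D))) > 1e-8 * max(abs(D))) stop("D must be symmetric")
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("D must be positive semidefinite")
  structure(list(D = D, center = center,
                 d_t = mean(diag(D)[1:3]), d_r = mean(diag(D)[4:6])),
            class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat(sprintf("diffusion_tensor: D_t = %.4g nm^2/ns, D_r = %.4g 1/ns\n",
              x$d_t, x$d_r))
  invisible(x)
}

#' Read a whitespace 6x6 tensor file
#' @param file path to a text file with 6 rows of 6 numbers.
#' @export
read_diffusion_tensor <- function(file) {
  diffusion_tensor(as.matrix(utils::read.table(file)))
}

# product Gauss-Legendre x uniform-phi spherical quadrature, >= 2*n^2 nodes
sphere_quadrature <- function(n = 20) {
  gl <- pracma::gaussLegendre(n, -1, 1)
  nphi <- 2 * n
  phi <- (seq_len(nphi) - 0.5) / nphi * 2 * pi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  u <- cbind(st * cos(phi), st * sin(phi), ct)
  w <- rep(gl$w, each = nphi) / (2 * nphi)
  list(u = u, w = w)   # weights sum to 1
}

# structure coordinates in nm, centred at the b-weighted centroid
structure_nm_centered <- function(structure) {
  r <- structure$xyz / 10
  b <- structure$weight
  sweep(r, 2, colSums(r * b) / sum(b))
}

#' Effective rigid-body diffusion coefficient D0(q)
#'
#' Orientationally averaged first-cumulant diffusion coefficient of a
#' rigid body measured at scattering vector q: amplitude-weighted
#' quadratic forms of \eqn{(\hat q, \hat q \times r_j)} with the 6x6
#' diffusion tensor, normalized by \eqn{q^2 F(q)}. Reduces to the scalar
#' translational coefficient at q -> 0 and picks up rotational
#' contributions as q resolves the particle.
#'
#' @param structure a [coarse_structure()] (coordinates in Angstrom;
#'   converted to nm internally and centred at the scattering-weighted
#'   centroid, which must coincide with the tensor origin).
#' @param tensor a [diffusion_tensor()].
#' @param q scattering vectors in 1/nm (positive).
#' @param n_quad Gauss-Legendre order of the orientational average
#'   (2*n_quad^2 directions; default 18 -> 648 nodes).
#' @return vector D0(q) in nm^2/ns.
#' @export
rigid_body_D0 <- function(structure, tensor, q, n_quad = 18) {
  if (any(q <= 0)) stop("q must be positive")
  r <- structure_nm_centered(structure)
  b <- structure$weight
  quad <- sphere_quadrature(n_quad)
  D <- tensor$D
  vapply(q, function(qq) {
    num <- den <- 0
    for (k in seq_len(nrow(quad$u))) {
      u <- quad$u[k, ]
      phase <- qq * drop(r %*% u)
      cr <- cbind(u[2] * r[, 3] - u[3] * r[, 2],
                  u[3] * r[, 1] - u[1] * r[, 3],
                  u[1] * r[, 2] - u[2] * r[, 1])   # u x r_j
      V <- cbind(matrix(u, nrow(r), 3, byrow = TRUE), cr)  # n x 6
      re <- drop(crossprod(V, b * cos(phase)))
      im <- drop(crossprod(V, b * sin(phase)))
      num <- num + quad$w[k] *
        (drop(crossprod(re, D %*% re)) + drop(crossprod(im, D %*% im)))
      amp_re <- sum(b * cos(phase)); amp_im <- sum(b * sin(phase))
      den <- den + quad$w[k] * (amp_re^2 + amp_im^2)
    }
    if (den <= 0) stop("vanishing form factor at q = ", qq)
    num / den
  }, numeric(1))
}

#' Rotational amplitude spectrum S_l(q) of a bead model
#'
#' \eqn{S_l(q) = \sum_m |\sum_i b_i j_l(q r_i) Y_{lm}(\Omega_i)|^2} with
#' spherical Bessel functions and real spherical harmonics, for the
#' l-expansion of rigid-body rotational diffusion.
#'
#' @param structure a [coarse_structure()] (Angstrom; centred internally).
#' @param q scattering vector in 1/nm (scalar).
#' @param lmax expansion order (default 15).
#' @return numeric vector `S_0..S_lmax`.
#' @export
structure_sl <- function(structure, q, lmax = 15) {
  r <- structure_nm_centered(structure)
  b <- structure$weight
  rad <- sqrt(rowSums(r^2))
  ct <- ifelse(rad > 0, r[, 3] / rad, 1)
  phi <- atan2(r[, 2], r[, 1])
  sl <- numeric(lmax + 1)
  for (l in 0:lmax) {
    jl <- sph_bessel_j(l, q * rad)
    # pracma::legendre returns P_l^m(x), m = 0..l, as (l+1) x n matrix
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    tot <- 0
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      base <- nrm * P[m + 1, ]
      if (m == 0) {
        tot <- tot + sum(b * jl * base)^2
      } else {
        tot <- tot + sum(b * jl * sqrt(2) * base * cos(m * phi))^2 +
          sum(b * jl * sqrt(2) * base * sin(m * phi))^2
      }
    }
    sl[l + 1] <- tot
  }
  sl
}

sph_bessel_j <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-6
  out[small] <- if (l == 0) 1 else 0
  xs <- x[!small]
  if (length(xs))
    out[!small] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  out
}

#' Hydrodynamic interaction parameters
#'
#' @param c protein concentration in mg/mL.
#' @param eta_intr intrinsic viscosity in mL/mg.
#' @return `hydro_ht`: translational correction \eqn{H_t = 1 - c[\eta]};
#'   `hydro_hr`: rotational correction from the spherical-particle
#'   approximation \eqn{1 - H_r = (1 - H_t)/3}.
#' @export
hydro_ht <- function(c, eta_intr) {
  if (any(c * eta_intr >= 1)) stop("c * [eta] must be < 1")
  1 - c * eta_intr
}

#' @rdname hydro_ht
#' @param h_t translational correction factor.
#' @export
hydro_hr <- function(h_t) 1 - (1 - h_t) / 3

#' Debye-Waller bound on the mean-squared displacement of internal motion
#'
#' Internal dynamics changing the normalized intermediate scattering
#' function by at most a fractional deviation `err` at scattering vector
#' `q` correspond to an MSD bounded by \eqn{-u^2 q^2/3 = \ln(1 - err)}.
#'
#' @param err fractional deviation, in (0, 1).
#' @param q scattering vector in 1/nm.
#' @return displacement u in nm.
#' @export
msd_bound <- function(err, q) {
  if (any(err <= 0 | err >= 1)) stop("err must lie in (0, 1)")
  if (any(q <= 0)) stop("q must be positive")
  sqrt(-3 * log(1 - err)) / q
}

#' Hydrodynamic-correction and internal-dynamics parameters for NSE
#'
#' @param h_t,h_r translational / rotational hydrodynamic factors (0, 1].
#' @param s_q structure factor value S(q) (interparticle interference).
#' @param a_q internal-dynamics amplitude A(q) in [0, 1].
#' @param gamma internal relaxation rate in 1/ns.
#' @export
hydro_params <- function(h_t = 1, h_r = 1, s_q = 1, a_q = 0, gamma = 0) {
  if (h_t <= 0 || h_t > 1 || h_r <= 0 || h_r > 1)
    stop("H_t, H_r must lie in (0, 1]")
  if (a_q < 0 || a_q > 1) stop("A(q) must lie in [0, 1]")
  structure(list(h_t = h_t, h_r = h_r, s_q = s_q, a_q = a_q, gamma = gamma),
            class = "hydro_params")
}

#' Intermediate scattering function of a rigid body with internal dynamics
#'
#' \deqn{I(q,t)/I(q,0) = [(1 - A(q)) + A(q) e^{-\Gamma t}]\;
#' e^{-q^2 D_t H_t t / S(q)}\;
#' \frac{\sum_{l=0}^{l_{max}} S_l(q) e^{-l(l+1) D_r H_r t}}{\sum_l S_l(q)}}
#'
#' Translational diffusion is slowed by interparticle interference
#' (\eqn{D_{t,eff} = D_t H_t / S(q)}) and hydrodynamics; rotational
#' diffusion enters through the spherical-harmonic amplitude spectrum of
#' the bead model; internal dynamics add a single-exponential channel with
#' q-dependent amplitude.
#'
#' @param structure a [coarse_structure()].
#' @param tensor a [diffusion_tensor()] providing `d_t`, `d_r`.
#' @param hydro a [hydro_params()].
#' @param q scattering vector in 1/nm (scalar).
#' @param t Fourier times in ns.
#' @param lmax rotational expansion order (default 15).
#' @return I(q,t)/I(q,0); equals 1 at t = 0.
#' @export
nse_isf <- function(structure, tensor, hydro, q, t, lmax = 15) {
  sl <- structure_sl(structure, q, lmax)
  internal <- (1 - hydro$a_q) + hydro$a_q * exp(-hydro$gamma * t)
  trans <- exp(-q^2 * tensor$d_t * hydro$h_t * t / hydro$s_q)
  l <- 0:lmax
  rot <- drop(exp(-outer(t, l * (l + 1) * tensor$d_r * hydro$h_r)) %*% sl) /
    sum(sl)
  internal * trans * rot
}

#' NSE spectrum container
#'
#' @param q scattering vector (1/nm, positive).
#' @param t Fourier times (ns).
#' @param value normalized I(q,t)/I(q,0); must be ~1 at t = 0 if t
#'   contains 0.
#' @param sd optional per-point SD.
#' @export
nse_curve <- function(q, t, value, sd = NULL) {
  if (q <= 0) stop("q must be positive")
  if (any(t < 0)) stop("Fourier times must be non-negative")
  i0 <- which(t == 0)
  if (length(i0) && abs(value[i0[1]] - 1) > 0.05)
    stop("I(q,0) must be normalized to 1")
  structure(list(q = q, t = t, value = value, sd = sd), class = "nse_curve")
}

#' Cumulant analysis of an NSE spectrum
#'
#' Weighted fit of \eqn{\ln I(q,t)/I(q,0) = K_1 t + K_2 t^2 / 2} over the
#' initial decay, returning the effective diffusion coefficient
#' \eqn{D_{eff} = -K_1 / q^2} with its propagated SD.
#'
#' @param curve an [nse_curve()].
#' @param t_max upper end of the fit window (ns).
#' @return list with `K1` (1/ns), `K2` (1/ns^2), `d_eff` (nm^2/ns),
#'   `d_eff_sd`.
#' @export
cumulant_fit <- function(curve, t_max = max(curve$t)) {
  sel <- curve$t <= t_max & curve$t > 0 & curve$value > 0
  if (sum(sel) < 4) stop("need at least 4 points inside the fit window")
  t <- curve$t[sel]; y <- log(curve$value[sel])
  w <- if (is.null(curve$sd)) rep(1, length(t))
       else (curve$value[sel] / curve$sd[sel])^2   # delta(log y) = sd/y
  X <- cbind(t, t^2 / 2)
  fit <- stats::lm.wfit(X, y, w)
  K1 <- fit$coefficients[[1]]; K2 <- fit$coefficients[[2]]
  # with stated uncertainties propagate them directly; otherwise estimate
  # the noise scale from the residuals
  s2 <- if (is.null(curve$sd))
    sum(w * fit$residuals^2) / max(1, length(t) - 2) else 1
  cov1 <- s2 * solve(crossprod(X * sqrt(w)))[1, 1]
  if (K1 > 0) warning("positive K1: growing spectrum is unphysical")
  list(K1 = K1, K2 = K2, d_eff = -K1 / curve$q^2,
       d_eff_sd = sqrt(cov1) / curve$q^2)
}

#' Kirkwood-type bead approximation of a diffusion tensor
#'
#' Builds an isotropic 6x6 diffusion tensor from a bead model: the
#' translational coefficient from the Kirkwood double sum and the
#' rotational coefficient from bead friction with translational lever
#' arms. For a single bead of radius a the Stokes-Einstein results
#' \eqn{D_t = k_B T / (6\pi\eta a)} and \eqn{D_r = k_B T / (8\pi\eta a^3)}
#' are recovered exactly. Intended for constructing synthetic tensors;
#' production tensors come from dedicated hydrodynamics software.
#'
#' @param structure a [coarse_structure()] (Angstrom).
#' @param eta solvent viscosity in Pa s (default water at 20 C).
#' @param temperature in K.
#' @return a [diffusion_tensor()] (nm^2/ns and 1/ns).
#' @export
kirkwood_tensor <- function(structure, eta = 1.002e-3, temperature = 293.15) {
  kT <- 1.380649e-23 * temperature          # J
  r_m <- structure_nm_centered(structure) * 1e-9
  a_m <- structure$radius * 1e-10
  n <- nrow(r_m)
  # Kirkwood: D_t = kT/(6 pi eta) [ 1/(n <a>) + n^-2 sum_{i!=j} 1/r_ij ]
  inv_self <- mean(1 / a_m) / n
  inv_cross <- 0
  if (n > 1) {
    dmat <- as.matrix(stats::dist(r_m))
    inv_cross <- sum(1 / dmat[upper.tri(dmat)]) * 2 / n^2
  }
  d_t <- kT / (6 * pi * eta) * (inv_self + inv_cross)      # m^2/s
  # rotational friction: bead spin + translational lever arms
  s2 <- rowSums(r_m^2)
  zeta_r <- sum(8 * pi * eta * a_m^3 + 6 * pi * eta * a_m * s2)
  d_r <- kT / zeta_r                                        # 1/s
  # m^2/s -> nm^2/ns: x 1e18 / 1e9 ; 1/s -> 1/ns: / 1e9
  diffusion_tensor(diag(c(rep(d_t * 1e9, 3), rep(d_r / 1e9, 3))))
}
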