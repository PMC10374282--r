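#' Dipolar coupling frequency of a spin pair
#'
#' Angle-free magnitude of the electron-electron dipolar frequency,
#' \eqn{\nu_{dip} / R^3}, with the constant computed from physical
#' constants (\eqn{g^2 \mu_B^2 \mu_0 / (4\pi h)}) using the free-electron
#' g-value 2.0023, which reproduces the canonical 52.04 MHz nm^3 of
#' nitroxide spin labels.
#'
#' @param r_nm inter-spin distance in nm (positive).
#' @param g electron g-value.
#' @return frequency in MHz.
#' @export
dipolar_frequency <- function(r_nm, g = 2.0023) {
  if (any(r_nm <= 0)) stop("distance must be positive")
  dipolar_constant(g) / r_nm^3
}

# nu_dip in MHz nm^3 from CODATA constants
dipolar_constant <- function(g = 2.0023) {
  mu_b <- 9.2740100783e-24   # J/T
  h <- 6.62607015e-34        # J s
  mu0_over_4pi <- 1e-7       # T m / A
  # Hz m^3 -> MHz nm^3: x 1e27 / 1e6
  g^2 * mu_b^2 * mu0_over_4pi / h * 1e21
}

#' Dipolar evolution kernel
#'
#' Kernel matrix \eqn{K(t, R) = \int_0^1 \cos[(3x^2 - 1)\,\omega_{DD} t]\,
#' dx} relating a spin-spin distance distribution to the DEER form factor,
#' with \eqn{x = \cos\theta} integrating out the powder average. Evaluated
#' either by the Fresnel-integral closed form or by fixed-order trapezoid
#' quadrature over `x`.
#'
#' @param t_us dipolar evolution times in microseconds (non-negative).
#' @param r_nm distance grid in nm.
#' @param method `"fresnel"` (closed form, default) or `"quadrature"`.
#' @param n_quad quadrature points over `x` for the quadrature method.
#' @return object of class `dipolar_kernel`: list with the matrix `K`
#'   (length(t) x length(r)), `t_us`, and `r_nm`. `K(0, R) = 1`.
#' @export
dipolar_kernel <- function(t_us, r_nm, method = c("fresnel", "quadrature"),
                           n_quad = 5001) {
  method <- match.arg(method)
  if (any(t_us < 0)) stop("times must be non-negative")
  if (any(r_nm <= 0)) stop("distances must be positive")
  # phase in radians: omega = 2 pi nu (nu in MHz, t in us)
  phi <- 2 * pi * outer(t_us, dipolar_frequency(r_nm))
  K <- if (method == "fresnel") kernel_fresnel(phi) else
    kernel_quadrature(phi, n_quad)
  structure(list(K = K, t_us = t_us, r_nm = r_nm, method = method),
            class = "dipolar_kernel")
}

kernel_fresnel <- function(phi) {
  K <- matrix(1, nrow(phi), ncol(phi))
  pos <- phi > 0
  ph <- phi[pos]
  z <- sqrt(6 * ph / pi)
  K[pos] <- sqrt(pi / (6 * ph)) *
    (cos(ph) * pracma::fresnelC(z) + sin(ph) * pracma::fresnelS(z))
  K
}

kernel_quadrature <- function(phi, n_quad) {
  x <- seq(0, 1, length.out = n_quad)
  w <- rep(1, n_quad); w[c(1, n_quad)] <- 0.5
  w <- w / (n_quad - 1)
  b <- 3 * x^2 - 1
  K <- matrix(0, nrow(phi), ncol(phi))
  for (j in seq_len(ncol(phi)))
    K[, j] <- drop(cos(outer(phi[, j], b)) %*% w)
  K
}

#' @export
print.dipolar_kernel <- function(x, ...) {
  cat(sprintf("dipolar_kernel (%s): %d times x %d distances, t <= %.2f us, R in [%.2f, %.2f] nm\n",
              x$method, length(x$t_us), length(x$r_nm), max(x$t_us),
              min(x$r_nm), max(x$r_nm)))
  invisible(x)
}

#' DEER dipolar evolution trace
#'
#' @param t_us evolution times in microseconds, increasing.
#' @param v normalized signal, `V(0) = 1` within tolerance.
#' @param noise_sd optional noise SD estimate.
#' @export
deer_trace <- function(t_us, v, noise_sd = NA_real_) {
  if (any(diff(t_us) <= 0)) stop("t must be increasing")
  if (abs(v[1] - 1) > 0.15)
    stop("V(0) must be close to 1 (normalized trace)")
  structure(list(t_us = t_us, v = v, noise_sd = noise_sd),
            class = "deer_trace")
}

#' @export
print.deer_trace <- function(x, ...) {
  cat(sprintf("deer_trace: %d points, t = %.3f..%.2f us\n",
              length(x$t_us), min(x$t_us), max(x$t_us)))
  invisible(x)
}

#' Simulate a DEER trace from a distance distribution
#'
#' \eqn{V(t) = [1 - \Delta(1 - K p)] e^{-k t} +} Gaussian noise, i.e. a
#' modulated dipolar signal with modulation depth \eqn{\Delta} on a
#' homogeneous 3D exponential background.
#'
#' @param p a [distance_distribution()] in nm (normalized).
#' @param kernel a [dipolar_kernel()] whose distance grid matches `p$r`.
#' @param delta modulation depth in `[0, 1]`.
#' @param k background rate in 1/us.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed (`NULL` = no seeding).
#' @return a [deer_trace()].
#' @export
simulate_deer <- function(p, kernel, delta = 0.3, k = 0.05, noise_sd = 0,
                          seed = NULL) {
  if (delta < 0 || delta > 1) stop("modulation depth must lie in [0, 1]")
  if (!isTRUE(all.equal(p$r, kernel$r_nm)))
    stop("kernel distance grid must match the distribution grid")
  # trapezoid quadrature of K p so that V(0) = 1 exactly even for
  # densities truncated at the grid boundary
  w <- rep(p$spacing, length(p$r))
  w[c(1, length(w))] <- p$spacing / 2
  s <- drop(kernel$K %*% (p$p * w))
  v <- (1 - delta * (1 - s)) * exp(-k * kernel$t_us)
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
  deer_trace(kernel$t_us, v, noise_sd = noise_sd)
}

#' Background correction of a DEER trace
#'
#' Fits the exponential background \eqn{V_{bg}(t) = (1-\Delta) e^{-kt}} on
#' the trace tail (`t >= fit_start`) by a linear fit of the log signal and
#' divides it out, returning the form factor \eqn{F(t) = V(t)/e^{-kt}}
#' which decays from 1 to the plateau \eqn{1 - \Delta}.
#'
#' @param trace a [deer_trace()].
#' @param fit_start start of the background window in microseconds.
#' @return list with `f` (form factor values), `t_us`, `k` (1/us), and
#'   `delta` (modulation depth implied by the tail intercept).
#' @export
background_correct <- function(trace, fit_start) {
  tail_i <- trace$t_us >= fit_start
  if (sum(tail_i) < 3) stop("background window too short")
  if (any(trace$v[tail_i] <= 0))
    stop("non-positive signal in the background window")
  fit <- stats::lm(log(v) ~ t, data = list(v = trace$v[tail_i],
                                           t = trace$t_us[tail_i]))
  k <- -stats::coef(fit)[["t"]]
  delta <- 1 - exp(stats::coef(fit)[["(Intercept)"]])
  list(f = trace$v / exp(-k * trace$t_us), t_us = trace$t_us,
       k = k, delta = delta)
}

#' Tikhonov regularized inversion of a dipolar signal
#'
#' Minimizes \eqn{\|K p - S\|^2 + \alpha \|L p\|^2} with the free-boundary
#' second-difference operator `L`, either as a non-negativity-constrained
#' least-squares problem on the stacked system (default, the standard
#' behaviour of DEER analysis software) or unconstrained through the
#' regularized normal equations (retained for linear-algebra checks).
#'
#' @param s dipolar signal \eqn{S(t) = K p} (form factor rescaled to unit
#'   modulation).
#' @param kernel a [dipolar_kernel()].
#' @param alpha regularization weight (> 0).
#' @param nonneg enforce p >= 0 (default TRUE).
#' @param normalize return a unit-integral [distance_distribution()]
#'   (default) or the raw coefficient vector.
#' @export
tikhonov <- function(s, kernel, alpha, nonneg = TRUE, normalize = TRUE) {
  if (alpha <= 0) stop("alpha must be positive")
  K <- kernel$K
  L <- second_difference(ncol(K))
  A <- rbind(K, sqrt(alpha) * L)
  b <- c(s, rep(0, nrow(L)))
  if (nonneg) {
    p <- pracma::lsqnonneg(A, b)$x
  } else {
    M <- crossprod(K) + alpha * crossprod(L)
    rc <- rcond(M)
    if (rc < 1e-15)
      stop(sprintf("singular stacked system (rcond = %.2e)", rc))
    p <- solve(M, crossprod(K, s))
  }
  if (!normalize) return(p)
  distance_distribution(kernel$r_nm, pmax(p, 0), kind = "spin", unit = "nm")
}

second_difference <- function(n) {
  L <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) L[i, i:(i + 2)] <- c(1, -2, 1)
  L
}

#' L-curve selection of the Tikhonov regularization weight
#'
#' Solves the Tikhonov problem over a log-spaced alpha grid and locates
#' the corner of the (log misfit, log roughness) curve by maximum discrete
#' curvature after enforcing the theoretical monotonicity of both axes.
#'
#' @param s dipolar signal.
#' @param kernel a [dipolar_kernel()].
#' @param alphas log-spaced grid, at least 20 points recommended.
#' @param nonneg passed to [tikhonov()].
#' @return list with `alpha_opt`, `corner` (index), `log_misfit`,
#'   `log_roughness`, `alphas`.
#' @export
l_curve_select <- function(s, kernel,
                           alphas = 10^seq(-4, 2, length.out = 25),
                           nonneg = TRUE) {
  alphas <- sort(alphas, decreasing = TRUE)
  L <- second_difference(length(kernel$r_nm))
  misfit <- rough <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    p <- tikhonov(s, kernel, alphas[i], nonneg = nonneg, normalize = FALSE)
    misfit[i] <- sum((drop(kernel$K %*% p) - s)^2)
    rough[i] <- sum(drop(L %*% p)^2)
  }
  lm_ <- log(pmax(misfit, 1e-300)); lr <- log(pmax(rough, 1e-300))
  # numerical monotonicity repair: misfit decreases, roughness increases
  # as alpha decreases
  lm_ <- rev(cummax(rev(lm_)))
  lr <- cummax(lr)
  corner <- lcurve_corner(lm_, lr)
  list(alpha_opt = alphas[corner], corner = corner, alphas = alphas,
       log_misfit = lm_, log_roughness = lr, misfit = misfit,
       roughness = rough)
}

# maximum Menger curvature corner of a discrete L-curve (x decreasing or
# increasing); returns the index of the corner point
lcurve_corner <- function(x, y) {
  n <- length(x)
  if (n < 3) return(n)
  sx <- diff(range(x)); sy <- diff(range(y))
  if (sx == 0 || sy == 0) return(ceiling(n / 2))
  xs <- (x - min(x)) / sx; ys <- (y - min(y)) / sy
  curv <- rep(-Inf, n)
  for (i in 2:(n - 1)) {
    a <- c(xs[i - 1], ys[i - 1]); b <- c(xs[i], ys[i]); cc <- c(xs[i + 1], ys[i + 1])
    ab <- sqrt(sum((a - b)^2)); bc <- sqrt(sum((b - cc)^2))
    ac <- sqrt(sum((a - cc)^2))
    if (ab * bc * ac == 0) next
    cross <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    curv[i] <- 2 * abs(cross) / (ab * bc * ac)
  }
  which.max(curv)
}

#' Full DEER inversion: background, modulation depth and p(R)
#'
#' Background-corrects the trace, converts the form factor to the
#' intramolecular dipolar signal without committing to a plateau estimate
#' (the modulation depth is absorbed into the non-negative solution via
#' the shifted kernel \eqn{F - 1 = (K - 1)(\Delta p)}), selects alpha on
#' the L-curve and returns the normalized distance distribution.
#'
#' @param trace a [deer_trace()].
#' @param r_nm distance grid (default 1.5-8 nm, 0.05 nm spacing).
#' @param fit_start background window start (us); default: half of the
#'   trace length.
#' @param alphas L-curve grid; a single value skips the L-curve.
#' @return list with `p` (a [distance_distribution()]), `k`, `delta`,
#'   `alpha_opt`, `lcurve` (NULL if alpha was fixed), `f` (form factor).
#' @export
deer_invert <- function(trace, r_nm = seq(1.5, 8, 0.05), fit_start = NULL,
                        alphas = 10^seq(-4, 2, length.out = 25)) {
  if (is.null(fit_start)) fit_start <- max(trace$t_us) / 2
  bg <- background_correct(trace, fit_start)
  kern <- dipolar_kernel(trace$t_us, r_nm)
  dr <- r_nm[2] - r_nm[1]
  # F - 1 = (Kd - 1 rowsum) h with h = delta * p
  Kd <- kern$K * dr
  Kmod <- Kd - matrix(dr, nrow(Kd), ncol(Kd))
  kern_mod <- kern; kern_mod$K <- Kmod
  target <- bg$f - 1
  lc <- NULL
  if (length(alphas) > 1) {
    lc <- l_curve_select(target, kern_mod, alphas)
    alpha <- lc$alpha_opt
  } else alpha <- alphas
  h <- tikhonov(target, kern_mod, alpha, nonneg = TRUE, normalize = FALSE)
  delta <- sum(h) * dr
  if (delta <= 0) stop("no dipolar modulation recovered")
  list(p = distance_distribution(r_nm, h, kind = "spin", unit = "nm"),
       k = bg$k, delta = delta, alpha_opt = alpha, lcurve = lc, f = bg$f)
}
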