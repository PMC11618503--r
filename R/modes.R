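#' Normal-mode spectra at inherent structures
#'
#' `classical_modes()` diagonalizes the mass-weighted Hessian of a classical
#' inherent structure; eigenvalues \eqn{\lambda} become signed frequencies
#' \eqn{\omega = \mathrm{sign}(\lambda)\sqrt{|\lambda|}} in cm\eqn{^{-1}}
#' (imaginary modes are kept as negative entries so non-minima remain
#' diagnosable). Zero modes are classified by \eqn{|\omega|} below
#' `zero_threshold`: a periodic minimum has exactly 3 (centre-of-mass
#' translations), a free cluster 6 (translations plus rotations).
#'
#' @param x An `is_record` or a `water_config` (assumed minimized).
#' @param params Model parameters.
#' @param zero_threshold Zero-mode classification threshold, cm^-1.
#' @param h Finite-difference step for the Hessian, nm.
#' @return A `mode_spectrum`: sorted `frequency_cm1`, `n_zero`, `kind`
#'   ("classical" or "ring-polymer"), `n_b`, `temperature`, the threshold,
#'   and a `not_minimum` flag when imaginary or excess zero modes appear.
#' @examples
#' mono <- build_cluster(1)
#' sp <- classical_modes(minimize_classical(mono))
#' sp$n_zero        # 6 for a free molecule
#' tail(sp$frequency_cm1, 3)  # bend + two stretches
#' @export
classical_modes <- function(x, params = water_params(), zero_threshold = 5,
                            h = params$hessian_h) {
  config <- if (inherits(x, "is_record")) x$config else x
  if (is.null(config)) abort("record holds no classical configuration")
  H <- mass_weighted_hessian(config, params, h = h)
  lam <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  omega_cm1 <- sort(sign(lam) * omega_to_cm1(sqrt(abs(lam))))
  new_mode_spectrum(omega_cm1, kind = "classical", n_b = 1L,
                    temperature = NA_real_, zero_threshold = zero_threshold,
                    periodic = !is.null(config$box))
}

new_mode_spectrum <- function(frequency_cm1, kind, n_b, temperature,
                              zero_threshold, periodic) {
  n_zero <- sum(abs(frequency_cm1) < zero_threshold)
  expected <- if (periodic) 3L else if (kind == "classical") 6L else 6L
  not_minimum <- any(frequency_cm1 < -zero_threshold) || n_zero > expected
  if (not_minimum)
    warn(sprintf(
      "spectrum has %d imaginary and %d near-zero modes: input may not be a minimum",
      sum(frequency_cm1 < -zero_threshold), n_zero))
  structure(list(frequency_cm1 = frequency_cm1, n_zero = n_zero, kind = kind,
                 n_b = n_b, temperature = temperature,
                 zero_threshold = zero_threshold, periodic = periodic,
                 not_minimum = not_minimum),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("%s mode spectrum: %d modes (%d zero at |w| < %g cm^-1), range %.1f .. %.1f cm^-1\n",
              x$kind, length(x$frequency_cm1), x$n_zero, x$zero_threshold,
              min(x$frequency_cm1), max(x$frequency_cm1)))
  if (x$kind == "ring-polymer")
    cat(sprintf("  n_b = %d, T = %g K\n", x$n_b, x$temperature))
  invisible(x)
}

#' @export
tidy.mode_spectrum <- function(x, ...) {
  tibble(mode = seq_along(x$frequency_cm1),
         frequency_cm1 = x$frequency_cm1,
         zero = abs(x$frequency_cm1) < x$zero_threshold)
}

#' Analytic ring-polymer spectrum at a collapsed inherent structure
#'
#' Because ring polymers collapse at inherent structures, the full
#' \eqn{d n_b} spectrum of the ring-polymer system follows analytically from
#' the d classical frequencies:
#' \deqn{\omega_{i,j}^2 = \frac{\omega_{i,0}^2}{n_b^2} -
#'   \frac{2}{(\hbar\beta)^2}\Big[\cos\Big(\frac{2\pi j}{n_b}\Big)-1\Big],
#'   \quad j = 1\ldots n_b.}
#' The j = n_b branch is the classical spectrum rescaled by \eqn{1/n_b};
#' zero modes stay zero only on that branch, so a periodic system keeps
#' exactly 3 zero modes out of \eqn{d n_b}.
#'
#' @param classical A classical `mode_spectrum` (d entries).
#' @param n_b Number of beads (>= 1).
#' @param temperature Temperature, K (> 0); enters through the spring term.
#' @param zero_threshold Zero-mode threshold, cm^-1.
#' @return A ring-polymer `mode_spectrum` with \eqn{d n_b} sorted entries.
#' @export
rp_modes_analytic <- function(classical, n_b, temperature, zero_threshold = 5) {
  stopifnot(inherits(classical, "mode_spectrum"), n_b >= 1)
  if (temperature <= 0) abort("temperature must be positive")
  beta <- 1 / (.kB * temperature)
  w0 <- cm1_to_omega(classical$frequency_cm1)        # rad/ps, signed
  lam0 <- sign(w0) * w0^2
  j <- seq_len(n_b)
  spring <- -(2 / (.hbar * beta)^2) * (cos(2 * pi * j / n_b) - 1)
  lam <- outer(lam0 / n_b^2, spring, `+`)            # d x n_b eigenvalues
  w <- sort(omega_to_cm1(sign(lam) * sqrt(abs(lam))))
  new_mode_spectrum(w, kind = "ring-polymer", n_b = as.integer(n_b),
                    temperature = temperature, zero_threshold = zero_threshold,
                    periodic = classical$periodic)
}

#' Brute-force ring-polymer spectrum (oracle for the analytic formula)
#'
#' Builds the full mass-weighted Hessian of the ring-polymer potential at a
#' collapsed inherent structure -- replica-diagonal blocks
#' \eqn{(1/n_b) \times} the classical Hessian plus bead-bead spring
#' couplings, mass-weighted with the fictitious bead masses
#' \eqn{m' = n_b m} -- and diagonalizes it numerically. Serves as the
#' independent check of [rp_modes_analytic()]; quadratic in memory, so a
#' size guard refuses systems with more than `max_dof` bead coordinates.
#'
#' @param x An `is_record` (classical: beads are collapsed onto it) or a
#'   `water_config` at a minimum.
#' @param n_b Number of beads.
#' @param temperature Temperature, K.
#' @param params Model parameters.
#' @param zero_threshold Zero-mode threshold, cm^-1.
#' @param h Finite-difference step, nm.
#' @param max_dof Size guard on 3 n n_b (default 5000).
#' @return A ring-polymer `mode_spectrum`.
#' @export
rp_modes_numeric <- function(x, n_b, temperature, params = water_params(),
                             zero_threshold = 5, h = params$hessian_h,
                             max_dof = 5000) {
  config <- if (inherits(x, "is_record")) x$config else x
  if (is.null(config)) abort("need a classical configuration (collapsed IS)")
  n <- nrow(config$positions)
  if (3 * n * n_b > max_dof)
    abort(sprintf(
      "3 n n_b = %d exceeds the %d guard: use rp_modes_analytic() for large systems",
      3 * n * n_b, max_dof))
  if (temperature <= 0) abort("temperature must be positive")
  masses <- atom_masses(n / 3, params)
  X <- rep(as.numeric(config$positions), n_b)      # collapsed beads
  ksp <- spring_constant(masses, n_b, temperature)
  box <- if (is.null(config$box)) numeric(0) else config$box
  inv <- rep(rep(1 / sqrt(n_b * masses), 3), n_b)  # fictitious masses
  H <- cpp_rp_hessian(X, n, n_b, box, params, ksp, h, inv)
  lam <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  w <- sort(sign(lam) * omega_to_cm1(sqrt(abs(lam))))
  new_mode_spectrum(w, kind = "ring-polymer", n_b = as.integer(n_b),
                    temperature = temperature, zero_threshold = zero_threshold,
                    periodic = !is.null(config$box))
}

#' Vibrational density of states histogram
#'
#' Normalized histogram of the positive frequencies of a spectrum (zero
#' modes excluded); the integral over frequency equals 1.
#'
#' @param spectrum A `mode_spectrum`.
#' @param bin_width Bin width, cm^-1.
#' @return A tibble with `omega_cm1` (bin midpoint) and `density` (1/cm^-1).
#' @export
vdos_histogram <- function(spectrum, bin_width = 50) {
  w <- spectrum$frequency_cm1
  w <- w[w >= spectrum$zero_threshold]
  if (length(w) == 0) abort("no positive frequencies above the zero threshold")
  breaks <- seq(0, (max(w) %/% bin_width + 1) * bin_width, by = bin_width)
  counts <- tabulate(findInterval(w, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  tibble(omega_cm1 = breaks[-1] - bin_width / 2,
         density = counts / (length(w) * bin_width))
}

#' Validate the analytic ring-polymer spectrum against its Hessian oracle
#'
#' Builds a minimized water cluster, computes the ring-polymer spectrum both
#' analytically and by full Hessian diagonalization, and reports the maximum
#' relative frequency deviation over modes above the zero threshold.
#'
#' @param N Cluster size (1, 2, 4, 8, 16).
#' @param n_b Number of beads.
#' @param temperature Temperature, K.
#' @param params Model parameters.
#' @param tol Pass threshold on the maximum relative deviation.
#' @return list(max_rel_dev, pass, n_modes_compared).
#' @examples
#' \donttest{validate_rp_modes(1, 4, 240)$pass}
#' @export
validate_rp_modes <- function(N, n_b, temperature, params = water_params(),
                                 tol = 1e-6) {
  cl <- build_cluster(N, params)
  rec <- minimize_classical(cl, params)
  spc <- classical_modes(rec, params)
  ana <- rp_modes_analytic(spc, n_b, temperature)
  num <- rp_modes_numeric(rec, n_b, temperature, params)
  keep <- abs(ana$frequency_cm1) >= ana$zero_threshold &
    abs(num$frequency_cm1) >= num$zero_threshold
  dev <- abs(ana$frequency_cm1[keep] - num$frequency_cm1[keep]) /
    abs(num$frequency_cm1[keep])
  list(max_rel_dev = max(dev), pass = max(dev) < tol,
       n_modes_compared = sum(keep))
}
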