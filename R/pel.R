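#' Basin shape function
#'
#' The shape function of an inherent-structure spectrum,
#' \deqn{S = \sum_{i} \ln(\hbar\omega_i / A_0),}
#' summed over the \eqn{d n_b - 3} positive modes (\eqn{d - 6} for a free
#' cluster), with \eqn{A_0 = 1} kJ/mol making the argument dimensionless.
#' It measures the average local curvature of the basin: larger S means
#' thinner basins. Averaging over inherent structures with equal energy is
#' done at the caller level.
#'
#' @param spectrum A `mode_spectrum`.
#' @param A0 Frequency scale, kJ/mol (default 1).
#' @return Dimensionless scalar S.
#' @examples
#' # two modes with hbar*omega/A0 = e and e^2 give S = 3
#' @export
shape_function <- function(spectrum, A0 = 1) {
  w <- spectrum$frequency_cm1
  w <- w[abs(w) >= spectrum$zero_threshold]
  if (any(w <= 0))
    abort("negative (imaginary) modes present: input is not a minimum")
  hw <- .hbar * cm1_to_omega(w)    # kJ/mol
  sum(log(hw / A0))
}

#' Linear shape-function fit
#'
#' Ordinary least squares of the shape function against the
#' inherent-structure energy, \eqn{S = a + b\, e_{IS}}: the linear law that
#' holds on both the classical landscape (a, b functions of N, V) and the
#' ring-polymer landscape (a, b additionally temperature-dependent).
#'
#' @param data A data frame with columns `e_is` (kJ/mol) and `S`.
#' @return A `pel_shape_fit` with `a` (intercept), `b` (slope, mol/kJ), the
#'   underlying `lm` fit, and `r_squared`. Methods: [tidy()], [glance()],
#'   `autoplot()`.
#' @export
fit_shape_linear <- function(data) {
  stopifnot(all(c("e_is", "S") %in% names(data)))
  data <- data[complete.cases(data[c("e_is", "S")]), ]
  if (nrow(data) < 3) abort("need at least 3 (e_is, S) pairs")
  if (diff(range(data$e_is)) < 1e-12)
    abort("degenerate e_is spread: cannot identify a slope")
  fit <- lm(S ~ e_is, data = data)
  # r^2 computed directly (summary.lm warns on noiseless synthetic input)
  sst <- sum((data$S - mean(data$S))^2)
  r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else NA_real_
  structure(list(
    a = unname(coef(fit)[1]), b = unname(coef(fit)[2]), fit = fit,
    r_squared = r2, data = tibble::as_tibble(data)
  ), class = "pel_shape_fit")
}

#' @export
print.pel_shape_fit <- function(x, ...) {
  cat(sprintf("shape-function fit S = a + b e_IS: a = %.6g, b = %.6g mol/kJ (R^2 = %.4f)\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' @export
tidy.pel_shape_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("a", "b"), estimate = c(x$a, x$b),
         std.error = s[, "Std. Error"], statistic = s[, "t value"],
         p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.pel_shape_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = summary(x$fit)$sigma,
         nobs = nrow(x$data))
}

#' Gaussian-landscape fit of the inherent-structure energy
#'
#' On a Gaussian landscape with a linear shape function the equilibrium
#' inherent-structure energy obeys
#' \deqn{E_{IS}(T) = E_0 - \sigma^2\,[\,b(T) + \beta\,],}
#' so a linear regression of \eqn{E_{IS}} against
#' \eqn{x = b(T) + 1/(k_B T)} yields slope \eqn{-\sigma^2} and intercept
#' \eqn{E_0}. Points above `T_max` (default 280 K, the upper end of the
#' Gaussian regime in liquid water) are excluded. A positive slope is
#' flagged -- never silently clipped -- as a non-Gaussian regime.
#'
#' @param data Data frame with columns `temperature` (K), `e_is` (the
#'   equilibrium E_IS, kJ/mol) and `b` (mol/kJ).
#' @param T_max Upper temperature cut for the fit window, K.
#' @return A `pel_gaussian_fit` with `E0`, `sigma2`, `gaussian` (flag), the
#'   `lm` fit and the fit window. Methods: [tidy()], [glance()],
#'   `autoplot()`.
#' @export
fit_gaussian_pel <- function(data, T_max = 280) {
  stopifnot(all(c("temperature", "e_is", "b") %in% names(data)))
  data <- data[data$temperature <= T_max, ]
  if (nrow(data) < 3) abort("need at least 3 temperatures at or below T_max")
  data$x <- data$b + 1 / (.kB * data$temperature)
  fit <- lm(e_is ~ x, data = data)
  slope <- unname(coef(fit)[2])
  structure(list(
    E0 = unname(coef(fit)[1]), sigma2 = -slope, gaussian = slope < 0,
    fit = fit, T_max = T_max, data = tibble::as_tibble(data)
  ), class = "pel_gaussian_fit")
}

#' @export
print.pel_gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian-landscape fit: E_0 = %.6g kJ/mol, sigma^2 = %.6g (kJ/mol)^2%s\n",
              x$E0, x$sigma2,
              if (x$gaussian) "" else "  [WARNING: positive slope, non-Gaussian regime]"))
  invisible(x)
}

#' @export
tidy.pel_gaussian_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("E0", "sigma2"),
         estimate = c(x$E0, x$sigma2),
         std.error = s[, "Std. Error"])
}

#' @export
glance.pel_gaussian_fit <- function(x, ...) {
  tibble(r.squared = summary(x$fit)$r.squared, gaussian = x$gaussian,
         T_max = x$T_max, nobs = nrow(x$data))
}

#' Harmonic vibrational energy from the shape function
#'
#' Within the Gaussian plus harmonic description, and neglecting the
#' temperature dependence of the landscape parameters
#' \eqn{(\alpha, E_0, \sigma^2)}, the vibrational energy is
#' \deqn{E_{vib}^{harm} = d\, n_b k_B T +
#'   (\partial S/\partial \beta)_{N,V,E_{IS}},}
#' with the derivative taken at fixed inherent-structure energy and
#' evaluated by central finite differences on the temperature grid. With
#' `n_b = 1` and a temperature-independent shape function this reduces
#' exactly to the classical equipartition result \eqn{d k_B T}.
#'
#' @param data Data frame with columns `temperature` (K) and `S` (the shape
#'   function evaluated at a common fixed e_IS, e.g. along the fitted linear
#'   law).
#' @param d Degrees of freedom (9N for water).
#' @param n_b Number of beads.
#' @return A tibble `temperature`, `evib_harm` (kJ/mol; NA at the grid ends
#'   where the central difference is undefined), `dS_dbeta`.
#' @export
harmonic_evib <- function(data, d, n_b) {
  stopifnot(all(c("temperature", "S") %in% names(data)))
  data <- data[order(data$temperature), ]
  if (nrow(data) < 3) abort("need S on at least 3 temperatures")
  if (max(diff(data$temperature)) > 40)
    warn("temperature grid coarser than 40 K: the finite-difference dS/dbeta is inaccurate")
  beta <- 1 / (.kB * data$temperature)
  m <- nrow(data)
  dSdb <- rep(NA_real_, m)
  dSdb[2:(m - 1)] <- (data$S[3:m] - data$S[1:(m - 2)]) /
    (beta[3:m] - beta[1:(m - 2)])
  tibble(temperature = data$temperature,
         dS_dbeta = dSdb,
         evib_harm = d * n_b * .kB * data$temperature + dSdb)
}

#' Configurational entropy, vibrational and Helmholtz free energies
#'
#' `config_entropy()` evaluates the Gaussian-landscape configurational
#' entropy \eqn{S_{IS} = k_B[\alpha N - (e_{IS}-E_0)^2/(2\sigma^2)]}. The
#' total number of inherent structures \eqn{e^{\alpha N}} is not measurable
#' from inherent-structure sampling alone, so when `alpha` is omitted the
#' result is reported up to the additive constant \eqn{k_B \alpha N} with an
#' explicit `relative` flag.
#'
#' `f_vib()` is the harmonic vibrational free energy
#' \eqn{F_{vib} = n_{modes} k_B T \ln(\beta A_0) + k_B T\, S}. The default
#' mode count \eqn{d n_b - 3} matches the modes actually summed in the shape
#' function, which keeps the Helmholtz free energy independent of the
#' arbitrary scale \eqn{A_0} (the thermodynamic-limit form uses
#' \eqn{d n_b}; set `n_modes = d * n_b` to recover it).
#'
#' `free_energy()` assembles \eqn{F = E_{IS} - T S_{IS} + F_{vib}}.
#'
#' @param e_is Inherent-structure energy (kJ/mol; vectorized).
#' @param fit A `pel_gaussian_fit` (source of E0 and sigma2).
#' @param N Number of molecules.
#' @param alpha Landscape parameter alpha (per molecule), or NULL.
#' @return `config_entropy()`: tibble (e_is, s_is (kJ/mol/K), relative).
#' @export
config_entropy <- function(e_is, fit, N, alpha = NULL) {
  stopifnot(inherits(fit, "pel_gaussian_fit"))
  base <- if (is.null(alpha)) 0 else alpha * N
  s <- .kB * (base - (e_is - fit$E0)^2 / (2 * fit$sigma2))
  tibble(e_is = e_is, s_is = s, relative = is.null(alpha))
}

#' @rdname config_entropy
#' @param temperature Temperature, K (vectorized).
#' @param S Shape function value(s).
#' @param d Degrees of freedom (9N).
#' @param n_b Number of beads.
#' @param A0 Frequency scale, kJ/mol.
#' @param n_modes Mode count in the harmonic prefactor.
#' @export
f_vib <- function(temperature, S, d, n_b, A0 = 1, n_modes = d * n_b - 3) {
  beta <- 1 / (.kB * temperature)
  n_modes * .kB * temperature * log(beta * A0) + .kB * temperature * S
}

#' @rdname config_entropy
#' @param s_is Configurational entropy, kJ/mol/K.
#' @param fvib Vibrational free energy, kJ/mol.
#' @export
free_energy <- function(e_is, temperature, s_is, fvib) {
  e_is - temperature * s_is + fvib
}

#' Sample a synthetic Gaussian landscape
#'
#' Generates inherent-structure energies and shape-function values from a
#' Gaussian landscape with a linear shape function and known parameters: at
#' each temperature, \eqn{e_{IS} \sim N(E_0 - \sigma^2(b+\beta), \sigma^2)}
#' (the canonical tilt of the Gaussian density of states) and
#' \eqn{S = a + b\, e_{IS}} plus optional Gaussian noise. Used to verify
#' that the fitting pipeline recovers the generating parameters.
#'
#' @param E0,sigma2 Landscape centre (kJ/mol) and variance ((kJ/mol)^2).
#' @param a_fun,b_fun Functions of temperature giving a(T) and b(T).
#' @param temperatures Temperature grid, K.
#' @param n_is Samples per temperature.
#' @param sd_S Optional Gaussian noise on S.
#' @param seed Integer seed.
#' @return Tibble (temperature, e_is, S).
#' @export
simulate_pel_landscape <- function(E0, sigma2, a_fun, b_fun, temperatures,
                                   n_is = 1000, sd_S = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(temperatures, function(T) {
    beta <- 1 / (.kB * T)
    b <- b_fun(T)
    e <- rnorm(n_is, mean = E0 - sigma2 * (b + beta), sd = sqrt(sigma2))
    S <- a_fun(T) + b * e + rnorm(n_is, sd = sd_S)
    tibble(temperature = T, e_is = e, S = S)
  })
}
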