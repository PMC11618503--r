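kB <- pel_constants$kB
hbar <- pel_constants$hbar

spec_from <- function(freq_cm1, n_zero_expected = 3, periodic = TRUE) {
  structure(list(frequency_cm1 = sort(freq_cm1),
                 n_zero = sum(abs(freq_cm1) < 5), kind = "classical", n_b = 1L,
                 temperature = NA_real_, zero_threshold = 5,
                 periodic = periodic, not_minimum = FALSE),
            class = "mode_spectrum")
}
# cm^-1 value whose quantum hbar*omega equals x kJ/mol
cm1_for_energy <- function(x) pelwater:::omega_to_cm1(x / hbar)

test_that("shape function sums log basin curvatures over nonzero modes", {
  # every mode at hbar*omega = A0 -> S = 0
  sp <- spec_from(c(0, 0, 0, rep(cm1_for_energy(1), 7)))
  expect_equal(shape_function(sp), 0, tolerance = 1e-10)
  # two modes at e*A0 and e^2*A0 -> S = 3
  sp2 <- spec_from(c(0, 0, 0, cm1_for_energy(exp(1)), cm1_for_energy(exp(2))))
  expect_equal(shape_function(sp2), 3, tolerance = 1e-10)
  # changing A0 shifts S by -(n_modes) log(A0'/A0)
  expect_equal(shape_function(sp2, A0 = 2), 3 - 2 * log(2), tolerance = 1e-10)
  sp_bad <- spec_from(c(0, 0, 0, -100, 500))
  expect_error(shape_function(sp_bad), "not a minimum")
})

test_that("ring-polymer shape function decreases on cooling at fixed classical input", {
  cl <- classical_modes(fix_box_is())
  nb <- 4
  S_cold <- shape_function(rp_modes_analytic(cl, nb, 220))
  S_warm <- shape_function(rp_modes_analytic(cl, nb, 300))
  expect_lt(S_cold, S_warm)
})

test_that("linear shape fit recovers generating coefficients", {
  # noiseless recovery to 1e-10
  e <- seq(-60, -50, length.out = 20)
  d0 <- tibble::tibble(e_is = e, S = 4.2 + 0.31 * e)
  f0 <- fit_shape_linear(d0)
  expect_equal(f0$a, 4.2, tolerance = 1e-10)
  expect_equal(f0$b, 0.31, tolerance = 1e-10)
  expect_equal(f0$r_squared, 1, tolerance = 1e-10)
  # noisy recovery within 3 standard errors (Monte-Carlo, fixed seed)
  set.seed(8)
  d1 <- tibble::tibble(e_is = rnorm(200, -55, 3))
  d1$S <- 4.2 + 0.31 * d1$e_is + rnorm(200, 0, 0.5)
  f1 <- fit_shape_linear(d1)
  se_b <- tidy(f1)$std.error[2]
  expect_lt(abs(f1$b - 0.31), 3 * se_b)
  # constant S: b = 0, a = S
  f2 <- fit_shape_linear(tibble::tibble(e_is = e, S = rep(7, 20)))
  expect_equal(f2$b, 0, tolerance = 1e-12)
  expect_equal(f2$a, 7, tolerance = 1e-12)
  expect_error(fit_shape_linear(tibble::tibble(e_is = rep(1, 5), S = 1:5)),
               "degenerate")
  expect_s3_class(glance(f1), "tbl_df")
})

test_that("Gaussian-landscape fit inverts the E_IS(T) relation", {
  E0 <- -50; sigma2 <- 8
  b_fun <- function(T) 0.2 + 1e-4 * T
  temps <- seq(200, 280, by = 10)
  d <- tibble::tibble(temperature = temps, b = b_fun(temps))
  d$e_is <- E0 - sigma2 * (d$b + 1 / (kB * d$temperature))
  fit <- fit_gaussian_pel(d)
  expect_equal(fit$E0, E0, tolerance = 1e-9)
  expect_equal(fit$sigma2, sigma2, tolerance = 1e-9)
  expect_true(fit$gaussian)
  # classical limit: b constant reduces to the 1/T law, same estimator
  d2 <- d; d2$b <- 0.2
  d2$e_is <- E0 - sigma2 * (0.2 + 1 / (kB * d2$temperature))
  fit2 <- fit_gaussian_pel(d2)
  expect_equal(fit2$sigma2, sigma2, tolerance = 1e-9)
  # only T <= T_max points enter the window
  expect_equal(nrow(fit$data), sum(temps <= 280))
  # positive slope flags a non-Gaussian regime rather than clipping
  d3 <- d; d3$e_is <- rev(d$e_is)
  fit3 <- fit_gaussian_pel(d3)
  expect_false(fit3$gaussian)
})

test_that("parameter recovery from sampled synthetic landscapes (3 s.e.)", {
  E0 <- -48; sigma2 <- 6
  a_fun <- function(T) 300 - 0.1 * T
  b_fun <- function(T) 0.15 + 2e-4 * T
  temps <- seq(210, 280, by = 10)
  d <- simulate_pel_landscape(E0, sigma2, a_fun, b_fun, temps,
                              n_is = 1000, seed = 99)
  # per-temperature shape fits give b(T); mean E_IS per temperature
  per_T <- dplyr::group_by(d, temperature)
  fits <- dplyr::summarise(per_T,
    b = fit_shape_linear(dplyr::pick(dplyr::everything()))$b,
    e_is = mean(e_is))
  expect_lt(max(abs(fits$b - b_fun(fits$temperature))), 1e-6)
  g <- fit_gaussian_pel(fits)
  se <- tidy(g)$std.error
  # sampling error of mean e_is: sigma/sqrt(n_is)
  expect_lt(abs(g$E0 - E0), 3 * se[1])
  expect_lt(abs(g$sigma2 - sigma2), 3 * se[2])
  # pipeline reproduces E_IS(T) to < 1% relative
  pred <- g$E0 - g$sigma2 * (fits$b + 1 / (kB * fits$temperature))
  expect_lt(max(abs(pred - fits$e_is) / abs(fits$e_is)), 0.01)
})

test_that("harmonic vibrational energy reduces correctly and differentiates S", {
  d <- 72; temps <- seq(220, 300, by = 20)
  # classical limit: n_b = 1, S independent of T -> d kB T exactly
  ev <- harmonic_evib(tibble::tibble(temperature = temps, S = 5), d = d, n_b = 1)
  inner <- !is.na(ev$evib_harm)
  expect_equal(ev$evib_harm[inner], d * kB * temps[inner], tolerance = 1e-12)
  # S = c * beta: central difference recovers c exactly (linear in beta)
  cc <- 40
  S <- cc / (kB * temps)
  ev2 <- harmonic_evib(tibble::tibble(temperature = temps, S = S), d = d, n_b = 4)
  expect_equal(ev2$dS_dbeta[inner], rep(cc, sum(inner)), tolerance = 1e-9)
  expect_equal(ev2$evib_harm[inner], 4 * d * kB * temps[inner] + cc,
               tolerance = 1e-9)
  expect_warning(harmonic_evib(tibble::tibble(temperature = c(100, 200, 300),
                                              S = 1:3), d, 1), "coarser")
})

test_that("harmonic prediction matches simulation for a harmonic toy solid", {
  # classical oscillator lattice: E_vib from MD equals d kB T; the anharmonic
  # correction of a purely harmonic system vanishes
  k <- 1600; Temp <- 250; n_at <- 30
  tr <- pimd_model_run(n_at, 2, 1, Temp, k_harm = k, n_steps = 4000,
                       save_every = 25, seed = 17, gamma = 8)
  est <- energy_estimator(tr, discard = 0.25)
  evib_md <- est$energy[est$estimator == "primitive"]   # e_IS = 0 here
  d <- 3 * n_at
  sem <- d * kB * blocked_sem(tr$log$T_inst[-(1:40)]) / 2 +
    blocked_sem(tr$log$U_phys[-(1:40)])
  expect_lt(abs(evib_md - d * kB * Temp), 4 * sem + 0.02 * d * kB * Temp)
})

test_that("configurational entropy and free energy follow the Gaussian forms", {
  fit <- structure(list(E0 = -50, sigma2 = 8), class = "pel_gaussian_fit")
  N <- 16; alpha <- 1.2
  # peak value k_B alpha N at e_IS = E0
  ce <- config_entropy(-50, fit, N, alpha = alpha)
  expect_equal(ce$s_is, kB * alpha * N, tolerance = 1e-12)
  expect_false(ce$relative)
  # zeros at e_IS = E0 +/- sigma sqrt(2 alpha N)
  e0s <- -50 + c(-1, 1) * sqrt(8) * sqrt(2 * alpha * N)
  expect_equal(config_entropy(e0s, fit, N, alpha = alpha)$s_is, c(0, 0),
               tolerance = 1e-10)
  # without alpha the entropy is relative, flagged
  expect_true(config_entropy(-49, fit, N)$relative)

  # beta A0 = 1: harmonic prefactor vanishes, F_vib = kB T S
  T1 <- 1 / kB          # beta = 1 at A0 = 1
  expect_equal(f_vib(T1, S = 3, d = 9, n_b = 2), kB * T1 * 3, tolerance = 1e-12)
  expect_equal(free_energy(-50, 250, 0.002, 10), -50 - 250 * 0.002 + 10)
})

test_that("the Helmholtz free energy is invariant under the A0 scale", {
  sp <- classical_modes(fix_box_is())
  Temp <- 250
  d_nb <- length(sp$frequency_cm1)
  n_modes <- d_nb - sp$n_zero
  for (A0 in c(0.5, 1, 3)) {
    S <- shape_function(sp, A0 = A0)
    fv <- f_vib(Temp, S, d = d_nb, n_b = 1, A0 = A0, n_modes = n_modes)
    if (A0 == 0.5) ref <- fv
    expect_equal(fv, ref, tolerance = 1e-10)
  }
  # with the thermodynamic-limit prefactor (d n_b) the invariance is broken
  # by exactly 3 kB T log(A0'/A0) -- the zero-mode bookkeeping term
  S1 <- shape_function(sp, A0 = 1); S2 <- shape_function(sp, A0 = 2)
  fv1 <- f_vib(Temp, S1, d = d_nb, n_b = 1, A0 = 1, n_modes = d_nb)
  fv2 <- f_vib(Temp, S2, d = d_nb, n_b = 1, A0 = 2, n_modes = d_nb)
  expect_equal(fv2 - fv1, 3 * kB * Temp * log(2), tolerance = 1e-9)
})
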