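kB <- pel_constants$kB
hbar <- pel_constants$hbar

test_that("ring-polymer spring constant has the m n_b / (hbar beta)^2 form", {
  expect_equal(spring_constant(1.008, 32, 300) / spring_constant(1.008, 16, 300), 2)
  expect_equal(spring_constant(1.008, 16, 600) / spring_constant(1.008, 16, 300), 4)
  expect_equal(spring_constant(1.008, 32, 300), 5.0e4, tolerance = 0.01)
  expect_error(spring_constant(1.008, 32, -10), "positive")
})

test_that("normal-mode transform is orthonormal with the free-ring frequencies", {
  for (nb in c(1, 2, 4, 7, 16)) {
    nm <- pelwater:::rp_normal_modes(nb, 250)
    expect_equal(t(nm$C) %*% nm$C, diag(nb), tolerance = 1e-12)
    beta <- 1 / (kB * 250)
    expect_equal(nm$omega[1], 0)
    expect_equal(max(nm$omega), (2 / (hbar * beta)) * sin(pi * floor(nb / 2) / nb),
                 tolerance = 1e-12)
  }
})

test_that("ring-polymer potential: collapsed and n_b = 1 limits, two-bead springs", {
  cfg <- fix_box_is()$config
  u_cl <- total_energy(cfg)
  # collapsed beads: spring term zero, U_RP = U(classical)
  st <- beads_state(cfg, 4, 250, seed = 1)
  st$R <- array(rep(cfg$positions, 4), dim = dim(st$R))
  ev <- rp_potential(st)
  expect_equal(ev$spring_energy, 0)
  expect_equal(ev$energy, u_cl, tolerance = 1e-10)
  # n_b = 1 identity
  st1 <- beads_state(cfg, 1, 250, seed = 1)
  expect_equal(rp_potential(st1)$energy, u_cl, tolerance = 1e-12)
  # two beads separated by d: each atom contributes k_sp d^2 (two springs)
  mono <- build_cluster(1)
  st2 <- beads_state(mono, 2, 250, seed = 1)
  d <- 0.01
  st2$R <- array(rep(mono$positions, 2), dim = dim(st2$R))
  st2$R[1, 1, 2] <- st2$R[1, 1, 2] + d     # displace the O bead copy only
  ev2 <- rp_potential(st2)
  ksp_O <- spring_constant(water_params()$m_O, 2, 250)
  expect_equal(ev2$spring_energy, ksp_O * d^2, tolerance = 1e-9)
})

test_that("trajectories are reproducible for a fixed seed", {
  cfg <- fix_box_is()$config
  st <- beads_state(cfg, 2, 280, seed = 3)
  t1 <- pimd_run(st, 40, temperature = 280, save_every = 20, seed = 11)
  t2 <- pimd_run(st, 40, temperature = 280, save_every = 20, seed = 11)
  expect_identical(t1$log, t2$log)
  expect_identical(t1$frames, t2$frames)
  t3 <- pimd_run(st, 40, temperature = 280, save_every = 20, seed = 12)
  expect_false(identical(t3$log$U_rp, t1$log$U_rp))
})

test_that("the n_b = 1 engine is bit-identical to a reference Langevin integrator", {
  # independent OBABO velocity-Verlet Langevin written in R, consuming the
  # RNG in the integrator's documented order (atom, component, mode)
  p <- water_params()
  cfg <- fix_box_is()$config
  n <- nrow(cfg$positions)
  m <- pelwater:::atom_masses(n / 3, p)
  dt <- 0.25e-3; Temp <- 280; gamma <- 0.5; nsteps <- 5
  seed_state <- 77
  st <- beads_state(cfg, 1, Temp, seed = seed_state)
  tr <- pimd_run(st, nsteps, dt = dt, temperature = Temp, gamma = gamma,
                 save_every = nsteps, seed = 99)

  # reference: same initial state, same noise stream
  set.seed(seed_state)
  X <- cfg$positions
  P <- array(rnorm(n * 3), dim = c(n, 3)) * sqrt(m * kB * Temp)
  set.seed(99)
  c1 <- exp(-0.5 * gamma * dt); c2 <- sqrt(1 - c1^2)
  draw_noise <- function() {
    xi <- rnorm(3 * n)
    t(matrix(xi, 3, n))    # row i = draws (i, x), (i, y), (i, z)
  }
  Fmat <- forces(configuration(X, box = cfg$box, wrap = FALSE), p)
  for (s in seq_len(nsteps)) {
    P <- c1 * P + c2 * sqrt(m * kB * Temp) * draw_noise()
    P <- P + 0.5 * dt * Fmat
    X <- X + dt * P / m
    Fmat <- forces(configuration(X, box = cfg$box, wrap = FALSE), p)
    P <- P + 0.5 * dt * Fmat
    P <- c1 * P + c2 * sqrt(m * kB * Temp) * draw_noise()
  }
  expect_equal(tr$state$R[, , 1], X, tolerance = 1e-14)
  expect_equal(tr$state$P[, , 1], P, tolerance = 1e-14)
})

test_that("unthermostatted n_b = 1 dynamics conserves energy", {
  cfg <- fix_box_is()$config
  st <- beads_state(cfg, 1, 150, seed = 5)
  tr <- pimd_run(st, 4000, temperature = 150, save_every = 100,
                 thermostat = FALSE, seed = 6)
  n <- nrow(cfg$positions)
  etot <- tr$log$U_rp + 1.5 * n * kB * tr$log$T_inst
  drift <- abs(coef(lm(etot ~ tr$log$time_ps))[2])   # kJ/mol per ps
  expect_lt(drift / (n / 3), 1e-2)
  expect_lt(diff(range(etot)), 0.05 * abs(mean(etot)))
})

test_that("thermostatted classical run samples the target temperature", {
  cfg <- fix_box_is()$config
  st <- beads_state(cfg, 1, 300, seed = 8)
  tr <- pimd_run(st, 3000, temperature = 300, gamma = 5, save_every = 20, seed = 9)
  Ts <- tr$log$T_inst[tr$log$step > 1000]
  expect_equal(mean(Ts), 300, tolerance = 3 * blocked_sem(Ts) / 300 + 0.05)
})

test_that("free ring polymer reproduces the analytic radius of gyration", {
  nb <- 8; m <- 1.008; Temp <- 300
  nm <- pelwater:::rp_normal_modes(nb, Temp)
  rg2_theory <- sum(3 * kB * Temp / (nb * m * nm$omega[-1]^2)) / nb
  tr <- pimd_model_run(40, m, nb, Temp, k_harm = 0, n_steps = 6000,
                       save_every = 40, seed = 21)
  rg2 <- vapply(tr$frames[30:length(tr$frames)], function(f) {
    cen <- apply(f, c(1, 2), mean)
    mean(apply((f - array(rep(cen, nb), dim = dim(f)))^2, 1, sum)) / nb
  }, numeric(1))
  expect_lt(abs(mean(rg2) - rg2_theory), 3 * blocked_sem(rg2) + 0.01 * rg2_theory)
})

test_that("energy estimators recover classical and quantum oscillator limits", {
  # classical reduction: primitive estimator equals d kBT/2 + <U> exactly
  cfg <- fix_box_is()$config
  st <- beads_state(cfg, 1, 280, seed = 31)
  tr <- pimd_run(st, 300, temperature = 280, save_every = 30, seed = 32)
  est <- energy_estimator(tr)
  d <- 3 * nrow(cfg$positions)
  expect_equal(est$energy[est$estimator == "primitive"],
               d * kB * 280 / 2 + mean(tr$log$U_phys), tolerance = 1e-12)
  expect_error(energy_estimator(list(log = tr$log[1, ], state = tr$state)),
               "2 saved samples")

  # quantum harmonic oscillator: centroid-virial estimator matches the exact
  # finite-bead (Trotter) energy within sampling error
  k <- 25600; mass <- 1; nb <- 16; Temp <- 300
  nm <- pelwater:::rp_normal_modes(nb, Temp)
  beta <- 1 / (kB * Temp)
  wt2 <- k / (nb^2 * mass)
  Om2 <- nm$omega^2 + wt2
  E_nb <- (3 / (2 * beta)) * (nb - sum((nm$omega^2 - wt2) / Om2))
  E_cont <- 3 * (hbar * sqrt(k / mass) / 2) / tanh(beta * hbar * sqrt(k / mass) / 2)
  expect_equal(E_nb, E_cont, tolerance = 0.02)   # n_b large enough
  tr <- pimd_model_run(16, mass, nb, Temp, k_harm = k, n_steps = 5000,
                       save_every = 40, seed = 33, gamma = 10)
  est <- energy_estimator(tr, discard = 0.25)
  per_atom <- est$energy[est$estimator == "centroid_virial"] / 16
  expect_equal(per_atom, E_nb, tolerance = 0.05)
  # far above the classical value at this beta*hbar*omega
  expect_gt(per_atom, 1.5 * 3 * kB * Temp)
})

test_that("MSD and equilibration detection behave on closed-form motions", {
  # frozen trajectory
  cfg <- fix_box_is()$config
  st <- beads_state(cfg, 1, 100, seed = 41)
  frames <- replicate(5, st$R, simplify = FALSE)
  traj <- list(frames = frames, state = st,
               log = tibble::tibble(step = 1:5, time_ps = (1:5) * 0.1))
  msd <- msd_curve(traj)
  expect_true(all(msd$msd_nm2 == 0))
  eq <- equilibration_time(msd)
  expect_identical(eq$tau_ps, Inf)
  expect_false(eq$equilibrated)
  # ballistic motion: MSD = v^2 t^2
  v <- c(0.3, 0, 0)
  frames <- lapply(0:4, function(i) {
    R <- st$R
    R[, 1, ] <- R[, 1, ] + v[1] * i * 0.1
    R
  })
  msd <- msd_curve(list(frames = frames, state = st,
                        log = tibble::tibble(step = 0:4, time_ps = (0:4) * 0.1)))
  expect_equal(msd$msd_nm2, (0.3 * msd$time_ps)^2, tolerance = 1e-10)
  # random walk: MSD slope ~ 3 sigma^2 per step (3D), within sampling error
  set.seed(42)
  sig <- 0.02
  nmol <- 200
  base <- array(0, dim = c(3 * nmol, 3, 1))
  steps <- 30
  walks <- list(base)
  for (i in seq_len(steps)) {
    nxt <- walks[[i]]
    jump <- matrix(rnorm(3 * nmol * 3, sd = sig), 3 * nmol, 3)
    walks[[i + 1]] <- nxt + array(jump, dim = dim(nxt))
  }
  stw <- list(R = base, n_b = 1L)
  msd <- msd_curve(list(frames = walks, state = stw,
                        log = tibble::tibble(step = 0:steps, time_ps = 0:steps)))
  slope <- coef(lm(msd_nm2 ~ time_ps, data = msd))[2]
  expect_equal(unname(slope), 3 * sig^2, tolerance = 0.15)
})

test_that("Metropolis volume moves sample the ideal-gas NPT distribution", {
  set.seed(13)
  beta <- 1 / (kB * 300)
  P <- 10 * pel_constants$mpa_to_internal
  N <- 5
  V <- 1
  vs <- numeric(4000)
  for (i in seq_along(vs)) {
    mv <- metropolis_volume(V, function(s) 0, beta, P, N, 0.3)
    V <- mv$V
    vs[i] <- V
  }
  vs <- vs[1001:4000]
  mean_theory <- (N + 1) / (beta * P)    # Gamma(N+1, beta P)
  expect_equal(mean(vs), mean_theory, tolerance = 0.1)
  expect_equal(var(vs), (N + 1) / (beta * P)^2, tolerance = 0.3)
  # zero-temperature limit: uphill moves are never accepted
  set.seed(14)
  accepted <- vapply(1:200, function(i)
    metropolis_volume(1, function(s) 1, 1e9, P, N, 0.1)$accepted, logical(1))
  expect_false(any(accepted))
  expect_error(pimd_run(beads_state(build_cluster(2), 2, 250, seed = 1), 10,
                        pressure = 0.1), "periodic")
})
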