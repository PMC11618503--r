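#' Ring-polymer spring constant
#'
#' The harmonic spring joining adjacent beads of the ring polymer of an atom
#' of mass m is \eqn{k^{sp} = m\, n_b / (\hbar\beta)^2} with
#' \eqn{\beta = 1/(k_B T)}; it grows linearly in the number of beads and
#' quadratically in temperature.
#'
#' @param m Atomic mass, amu.
#' @param n_b Number of beads per ring polymer (>= 1).
#' @param temperature Temperature in K (> 0).
#' @return Spring constant in kJ/mol/nm^2.
#' @examples
#' spring_constant(1.008, 32, 300)   # ~5.0e4 kJ/mol/nm^2
#' @export
spring_constant <- function(m, n_b, temperature) {
  stopifnot(all(m > 0), n_b >= 1)
  if (any(temperature <= 0)) abort("temperature must be positive")
  beta <- 1 / (.kB * temperature)
  m * n_b / (.hbar * beta)^2
}

# Orthonormal ring-polymer normal-mode transform. Column 1 is the centroid;
# omega are the free-ring-polymer frequencies for fictitious masses
# m' = n_b m: omega_k = (2/(hbar beta)) sin(pi k / n_b).
rp_normal_modes <- function(n_b, temperature) {
  C <- matrix(0, n_b, n_b)
  wav <- integer(n_b)
  j <- 0:(n_b - 1)
  C[, 1] <- 1 / sqrt(n_b)
  col <- 2
  if (n_b >= 3 || n_b == 2) {
    for (k in seq_len(floor((n_b - 1) / 2))) {
      C[, col] <- sqrt(2 / n_b) * cos(2 * pi * k * j / n_b); wav[col] <- k; col <- col + 1
      C[, col] <- sqrt(2 / n_b) * sin(2 * pi * k * j / n_b); wav[col] <- k; col <- col + 1
    }
    if (n_b %% 2 == 0) {
      C[, col] <- (-1)^j / sqrt(n_b); wav[col] <- n_b / 2
    }
  }
  beta <- 1 / (.kB * temperature)
  list(C = C, omega = (2 / (.hbar * beta)) * sin(pi * wav / n_b), wavenumber = wav)
}

#' Initialize a ring-polymer (beads) state
#'
#' Beads start collapsed onto the classical positions with a small Gaussian
#' jitter (one tenth of the free-particle radius of gyration at the target
#' temperature), and momenta are drawn from the Maxwell-Boltzmann
#' distribution with the dynamical bead masses. The engine uses physical
#' masses for every normal mode (thermodynamic averages are independent of
#' the bead-mass choice, and physical masses give the centroid the same
#' exploration timescale as classical MD). With `n_b = 1` the state is
#' exactly the classical configuration.
#'
#' @param config A `water_config`.
#' @param n_b Number of beads per ring polymer.
#' @param temperature Temperature, K.
#' @param params Model parameters.
#' @param seed Integer seed for jitter and momenta (NULL leaves the RNG
#'   state alone).
#' @return An object of class `beads_state`: bead positions `R` and momenta
#'   `P` as (n, 3, n_b) arrays, plus topology metadata.
#' @export
beads_state <- function(config, n_b, temperature, params = water_params(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(config$positions)
  masses <- atom_masses(n / 3, params)
  R <- array(rep(config$positions, n_b), dim = c(n, 3, n_b))
  if (n_b > 1) {
    nm <- rp_normal_modes(n_b, temperature)
    for (i in seq_len(n)) {
      rg2_free <- sum(.kB * temperature /
                        (n_b * masses[i] * nm$omega[-1]^2)) / n_b
      R[i, , ] <- R[i, , ] + rnorm(3 * n_b, sd = 0.1 * sqrt(rg2_free))
    }
  }
  # momenta follow the dynamical bead masses; the engine integrates with
  # physical masses per normal mode (mass choice is thermodynamically inert
  # but sets the centroid exploration timescale)
  P <- array(rnorm(n * 3 * n_b), dim = c(n, 3, n_b)) *
    sqrt(rep(masses, 3 * n_b) * .kB * temperature)
  structure(list(R = R, P = P, n_b = n_b, temperature = temperature,
                 box = config$box, masses = masses, step = 0L),
            class = "beads_state")
}

#' @export
print.beads_state <- function(x, ...) {
  n <- dim(x$R)[1]
  cat(sprintf("beads_state: %d molecules x %d beads at T = %g K (%s)\n",
              n / 3, x$n_b, x$temperature,
              if (is.null(x$box)) "open" else "periodic"))
  invisible(x)
}

#' Centroid configuration of a beads state
#'
#' Collapses a ring-polymer state onto its bead-average (centroid)
#' configuration, the natural classical image of the quantum system.
#'
#' @param state A `beads_state`.
#' @param wrap Wrap the centroid coordinates into the box.
#' @return A `water_config`.
#' @export
centroid_config <- function(state, wrap = FALSE) {
  pos <- apply(state$R, c(1, 2), mean)
  configuration(pos, box = state$box, wrap = wrap)
}

beads_flat <- function(state) as.numeric(state$R)

state_from_flat <- function(X, template) {
  template$R <- array(X, dim = dim(template$R))
  template
}

#' Ring-polymer potential energy
#'
#' The potential of the classical isomorph: bead-bead springs plus the
#' physical potential averaged over replicas,
#' \deqn{U_{RP} = \sum_i \sum_k \tfrac12 k_i^{sp} (r_i^{k+1}-r_i^k)^2 +
#'   \tfrac{1}{n_b}\sum_k U(\mathrm{replica}\ k).}
#' For collapsed beads the spring term vanishes and
#' \eqn{U_{RP} = U(\mathrm{classical})}; for `n_b = 1` the identity is exact.
#'
#' @param state A `beads_state`.
#' @param params Model parameters.
#' @param temperature Temperature defining the spring constants; defaults to
#'   the state's temperature.
#' @return A list with `energy` (kJ/mol), `gradient` (flat, kJ/mol/nm),
#'   `U_k` (per-replica physical energies), and `spring_energy`.
#' @export
rp_potential <- function(state, params = water_params(),
                         temperature = state$temperature) {
  n <- dim(state$R)[1]
  ksp <- spring_constant(state$masses, state$n_b, temperature)
  box <- if (is.null(state$box)) numeric(0) else state$box
  cpp_rp_eval(beads_flat(state), n, state$n_b, box, params, ksp, TRUE)
}

#' Run PILE-thermostatted path-integral molecular dynamics
#'
#' Velocity-Verlet integration of the ring-polymer system with exact
#' normal-mode evolution of the free ring polymer and an Ornstein-Uhlenbeck
#' thermostat per normal mode (OBABO splitting). The centroid mode is
#' thermostatted at the collision rate `gamma`; internal modes are critically
#' damped (\eqn{\gamma_k = 2\omega_k}). Classical Langevin MD is the
#' `n_b = 1` special case of the same code path. Trajectories are exactly
#' reproducible for a fixed seed.
#'
#' @param state A `beads_state` (modified copy returned inside the result).
#' @param n_steps Number of MD steps.
#' @param dt Time step, ps (default 0.25 fs).
#' @param temperature Target temperature, K; defaults to the state's.
#' @param gamma Centroid thermostat collision frequency, 1/ps.
#' @param save_every Save a frame and a log row every this many steps.
#' @param thermostat Logical; FALSE gives plain (symplectic) NVE dynamics.
#' @param seed Integer seed (NULL leaves the RNG state alone).
#' @param params Model parameters.
#' @param pressure Target pressure in MPa for the Monte Carlo barostat, or
#'   NULL (default) for NVT. Requires a periodic system.
#' @param barostat_every Attempt one volume move every this many steps.
#' @param dlnV Initial log-volume step of the barostat (auto-tuned towards
#'   40-50\% acceptance).
#' @return A `pimd_trajectory`: `log` (tibble of step, time, instantaneous
#'   temperature, spring/physical/ring-polymer potential energies, virial),
#'   `frames` (list of bead-position arrays), `state` (final `beads_state`),
#'   and metadata. With a barostat, also `volume_log`.
#' @examples
#' cfg <- build_box(8, 1.0, seed = 1)
#' st <- beads_state(cfg, n_b = 1, temperature = 300, seed = 1)
#' tr <- pimd_run(st, n_steps = 20, save_every = 10, seed = 1)
#' tr$log
#' @export
pimd_run <- function(state, n_steps, dt = 0.25e-3, temperature = state$temperature,
                     gamma = 0.1, save_every = 50, thermostat = TRUE,
                     seed = NULL, params = water_params(),
                     pressure = NULL, barostat_every = 25, dlnV = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  n <- dim(state$R)[1]
  n_b <- state$n_b
  masses <- state$masses
  nm <- rp_normal_modes(n_b, temperature)
  ksp <- spring_constant(masses, n_b, temperature)
  boxv <- if (is.null(state$box)) numeric(0) else state$box

  omega_dyn <- nm$omega * sqrt(n_b)   # free-RP frequencies for physical masses
  if (is.null(pressure)) {
    out <- cpp_run_pile(beads_flat(state), as.numeric(state$P), n_b, boxv,
                        params, masses, ksp, nm$C, omega_dyn,
                        dt, temperature, gamma, n_steps, save_every, thermostat)
    res <- assemble_trajectory(out, state, dt, save_every, temperature, params)
    check_blowup(res)
    return(res)
  }

  # isobaric: alternate short NVT segments with MC volume moves
  if (is.null(state$box)) abort("the barostat requires a periodic system")
  p_int <- pressure * pel_constants$mpa_to_internal
  beta <- 1 / (.kB * temperature)
  logs <- list(); frames <- list(); vlog <- list()
  naccept <- 0L; ntry <- 0L
  steps_done <- 0L
  while (steps_done < n_steps) {
    seg <- min(barostat_every, n_steps - steps_done)
    boxv <- state$box
    out <- cpp_run_pile(beads_flat(state), as.numeric(state$P), n_b, boxv,
                        params, masses, ksp, nm$C, omega_dyn,
                        dt, temperature, gamma, seg, seg, thermostat)
    lg <- as.data.frame(out$log)
    lg$step <- lg$step + steps_done
    lg$time_ps <- lg$time_ps + steps_done * dt
    logs[[length(logs) + 1]] <- lg
    frames[[length(frames) + 1]] <- array(out$frames[[length(out$frames)]],
                                          dim = dim(state$R))
    state$R <- array(out$X, dim = dim(state$R))
    state$P <- array(out$P, dim = dim(state$P))
    steps_done <- steps_done + seg

    mv <- mc_barostat_step(state, p_int, beta, params, ksp, dlnV)
    state <- mv$state
    ntry <- ntry + 1L; naccept <- naccept + mv$accepted
    # crude auto-tune towards 40-50% acceptance
    if (ntry %% 20 == 0) {
      acc <- naccept / ntry
      if (acc > 0.5) dlnV <- dlnV * 1.25
      if (acc < 0.4) dlnV <- dlnV / 1.25
    }
    vlog[[length(vlog) + 1]] <- data.frame(step = steps_done,
                                           volume = prod(state$box),
                                           accepted = mv$accepted)
    if (prod(state$box) < 0.02 * n / 3)
      abort("barostat collapse: volume shrinking towards zero")
  }
  log <- tibble::as_tibble(do.call(rbind, logs))
  res <- structure(list(log = log, frames = frames, state = state,
                        dt = dt, save_every = barostat_every,
                        temperature = temperature, n_b = n_b,
                        params = params,
                        volume_log = tibble::as_tibble(do.call(rbind, vlog)),
                        acceptance = naccept / max(ntry, 1)),
                   class = "pimd_trajectory")
  check_blowup(res)
  res
}

assemble_trajectory <- function(out, state, dt, save_every, temperature, params) {
  state$R <- array(out$X, dim = dim(state$R))
  state$P <- array(out$P, dim = dim(state$P))
  frames <- lapply(out$frames, array, dim = dim(state$R))
  structure(list(log = tibble::as_tibble(as.data.frame(out$log)),
                 frames = frames, state = state, dt = dt,
                 save_every = save_every, temperature = temperature,
                 n_b = state$n_b, params = params),
            class = "pimd_trajectory")
}

check_blowup <- function(traj, bound = 1e8) {
  if (nrow(traj$log) > 0 && any(!is.finite(traj$log$U_rp) |
                                abs(traj$log$U_rp) > bound)) {
    bad <- which(!is.finite(traj$log$U_rp) | abs(traj$log$U_rp) > bound)[1]
    abort(sprintf("integration blow-up at step %d (|U_RP| exceeded %g kJ/mol)",
                  traj$log$step[bad], bound))
  }
  invisible(traj)
}

#' @export
print.pimd_trajectory <- function(x, ...) {
  n <- dim(x$state$R)[1]
  cat(sprintf(
    "PIMD trajectory: %d molecules x %d beads, %d saved frames, T = %g K\n",
    n / 3, x$n_b, length(x$frames), x$temperature))
  invisible(x)
}

#' PIMD of model systems: free ring polymer and harmonic oscillator
#'
#' Runs the same PILE integrator on `n_atoms` independent particles in an
#' isotropic harmonic well of stiffness `k_harm` (kJ/mol/nm^2; 0 gives the
#' free ring polymer). These systems have closed-form quantum statistics --
#' the free ring polymer's \eqn{\langle R_g^2\rangle} follows from
#' normal-mode equipartition and the oscillator energy is
#' \eqn{3(\hbar\omega/2)\coth(\beta\hbar\omega/2)} -- so they validate the
#' thermostat and estimators independently of the water potential.
#'
#' @param n_atoms Number of independent particles.
#' @param mass Particle mass, amu.
#' @param n_b Beads per ring polymer.
#' @param temperature Temperature, K.
#' @param k_harm Harmonic stiffness, kJ/mol/nm^2 (0 = free).
#' @param n_steps,dt,gamma,save_every,seed As in [pimd_run()].
#' @return A `pimd_trajectory` (frames hold the bead positions).
#' @export
pimd_model_run <- function(n_atoms, mass, n_b, temperature, k_harm = 0,
                           n_steps = 1000, dt = 0.25e-3, gamma = 1,
                           save_every = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  masses <- rep(mass, n_atoms)
  nm <- rp_normal_modes(n_b, temperature)
  ksp <- spring_constant(masses, n_b, temperature)
  # start from the normal-mode equilibrium Gaussian (the slow centroid mode
  # of a soft well would otherwise take many ps to fill out its variance)
  kBT <- .kB * temperature
  # equilibrium mode variances: kBT / (m' omega_k^2 + k/n_b), mass-invariant
  stiff <- n_b * mass * nm$omega^2 + k_harm / n_b
  q <- array(rnorm(n_atoms * 3 * n_b), dim = c(n_atoms, 3, n_b))
  for (k in seq_len(n_b)) {
    sdk <- if (stiff[k] > 0) sqrt(kBT / stiff[k]) else 0
    q[, , k] <- q[, , k] * sdk
  }
  X0 <- array(0, dim = c(n_atoms, 3, n_b))
  for (j in seq_len(n_b))
    for (k in seq_len(n_b))
      X0[, , j] <- X0[, , j] + nm$C[j, k] * q[, , k]
  X0 <- as.numeric(X0)
  P0 <- rnorm(n_atoms * 3 * n_b) * sqrt(mass * .kB * temperature)
  out <- cpp_run_pile(X0, P0, n_b, numeric(0), water_params(), masses,
                      ksp, nm$C, nm$omega * sqrt(n_b), dt, temperature, gamma,
                      n_steps, save_every, TRUE, k_harm)
  state <- structure(list(R = array(out$X, dim = c(n_atoms, 3, n_b)),
                          P = array(out$P, dim = c(n_atoms, 3, n_b)),
                          n_b = n_b, temperature = temperature, box = NULL,
                          masses = masses, step = n_steps),
                     class = "beads_state")
  frames <- lapply(out$frames, array, dim = c(n_atoms, 3, n_b))
  structure(list(log = tibble::as_tibble(as.data.frame(out$log)),
                 frames = frames, state = state, dt = dt,
                 save_every = save_every, temperature = temperature,
                 n_b = n_b, params = NULL),
            class = "pimd_trajectory")
}

#' Quantum energy estimators from a PIMD trajectory
#'
#' The primitive (thermodynamic) estimator is the \eqn{\beta}-derivative of
#' the ring-polymer partition function:
#' \deqn{E = \frac{d\, n_b}{2\beta} - \langle U_{spring}\rangle +
#'   \Big\langle \tfrac{1}{n_b}\sum_k U_k \Big\rangle,}
#' with d = 3n degrees of freedom. The centroid-virial estimator, reported
#' alongside as a cross-check, replaces the harmonic term by
#' \eqn{d/(2\beta)} plus the bead-centroid virial. For `n_b = 1` both reduce
#' to the classical \eqn{d k_B T/2 + \langle U \rangle}.
#'
#' @param traj A `pimd_trajectory`.
#' @param discard Fraction of initial frames discarded as equilibration
#'   (default 0).
#' @return A tibble with one row per estimator: total energy and energy per
#'   molecule (kJ/mol), plus the standard error of the potential-energy
#'   average.
#' @export
energy_estimator <- function(traj, discard = 0) {
  log <- traj$log
  if (nrow(log) < 2) abort("need at least 2 saved samples")
  keep <- log[log$step > discard * max(log$step), , drop = FALSE]
  n <- dim(traj$state$R)[1]
  d <- 3 * n
  n_b <- traj$n_b
  beta <- 1 / (.kB * traj$temperature)
  N <- n / 3
  uphys <- mean(keep$U_phys)
  sem <- sd(keep$U_phys) / sqrt(nrow(keep))
  e_prim <- d * n_b / (2 * beta) - mean(keep$U_spring) + uphys
  e_cv <- d / (2 * beta) + mean(keep$virial) + uphys
  tibble(
    estimator = c("primitive", "centroid_virial"),
    energy = c(e_prim, e_cv),
    energy_per_molecule = c(e_prim, e_cv) / N,
    sem_U = sem
  )
}

#' Mean-square displacement and equilibration check
#'
#' `msd_curve()` computes the molecular MSD of the ring-polymer centroids of
#' the selected species (oxygen by default, i.e. the molecular position)
#' from the saved frames, which the integrator keeps unwrapped.
#' `equilibration_time()` returns the first time the MSD crosses a
#' threshold; if it never does, `Inf` with an `equilibrated = FALSE` flag.
#' The threshold mirrors the melt-diffusion rule MSD >= 1.0 nm^2 used for
#' bulk runs, rescaled for desk-size boxes (see the package vignette).
#'
#' @param traj A `pimd_trajectory`.
#' @param species "O" or "H".
#' @return `msd_curve()`: tibble (time_ps, msd_nm2). `equilibration_time()`:
#'   list(tau_ps, equilibrated).
#' @param msd A tibble from `msd_curve()`.
#' @param threshold MSD threshold in nm^2 (default 0.01 at toy scale).
#' @export
msd_curve <- function(traj, species = "O") {
  sel <- which(rep(c("O", "H", "H"), dim(traj$state$R)[1] / 3) == species)
  cent <- lapply(traj$frames, function(f) apply(f[sel, , , drop = FALSE], c(1, 2), mean))
  ref <- cent[[1]]
  msd <- vapply(cent, function(x) mean(rowSums((x - ref)^2)), numeric(1))
  tibble(time_ps = traj$log$time_ps - traj$log$time_ps[1], msd_nm2 = msd)
}

#' @rdname msd_curve
#' @export
equilibration_time <- function(msd, threshold = 0.01) {
  idx <- which(msd$msd_nm2 >= threshold)
  if (length(idx) == 0) {
    list(tau_ps = Inf, equilibrated = FALSE)
  } else {
    list(tau_ps = msd$time_ps[idx[1]], equilibrated = TRUE)
  }
}

#' Metropolis volume move (Monte Carlo barostat core)
#'
#' One isotropic log-volume move: \eqn{\ln V' = \ln V + \delta}, accepted
#' with probability
#' \eqn{\min\{1, \exp[-\beta(\Delta U + P\Delta V) + (N+1)\Delta\ln V]\}},
#' where N is the number of scaled objects (molecules). The `(N+1)` term is
#' the Jacobian of molecular scaling plus the log-volume sampling measure.
#' Exposed so the acceptance rule can be exercised on analytically solvable
#' systems (an ideal gas samples \eqn{P(V) \propto V^N e^{-\beta P V}},
#' a Gamma(N+1) distribution).
#'
#' @param V Current volume, nm^3.
#' @param energy_fn Function of the linear scale factor s = (V'/V)^(1/3)
#'   returning the potential-energy change (kJ/mol).
#' @param beta Inverse temperature, mol/kJ.
#' @param pressure Pressure in internal units, kJ/mol/nm^3.
#' @param n_scaled Number of scaled centroids (molecules).
#' @param dlnV Maximum log-volume step.
#' @return list(V, accepted, s).
#' @export
metropolis_volume <- function(V, energy_fn, beta, pressure, n_scaled, dlnV) {
  dln <- runif(1, -dlnV, dlnV)
  Vnew <- V * exp(dln)
  s <- (Vnew / V)^(1 / 3)
  dU <- energy_fn(s)
  arg <- -beta * (dU + pressure * (Vnew - V)) + (n_scaled + 1) * dln
  if (log(runif(1)) < arg) {
    list(V = Vnew, accepted = TRUE, s = s)
  } else {
    list(V = V, accepted = FALSE, s = 1)
  }
}

# One MC barostat step on a beads_state: molecule centroids are scaled,
# intramolecular and intra-ring geometry rigidly translated.
mc_barostat_step <- function(state, p_int, beta, params, ksp, dlnV) {
  n <- dim(state$R)[1]
  N <- n / 3
  box <- state$box
  V <- prod(box)
  mw <- rep(state$masses, times = 3) # per atom within molecule grouping below
  mol <- rep(seq_len(N), each = 3)
  # center of mass of each molecule over atoms and beads
  com <- matrix(0, N, 3)
  mtot <- sum(state$masses[1:3])
  for (m in seq_len(N)) {
    idx <- which(mol == m)
    w <- state$masses[idx] / mtot
    com[m, ] <- apply(state$R[idx, , , drop = FALSE], 2,
                      function(x) sum(sweep(x, 1, w, `*`)) / state$n_b)
  }
  boxv <- box
  e0 <- cpp_rp_eval(as.numeric(state$R), n, state$n_b, boxv, params, ksp, FALSE)$energy

  trial_state <- function(s) {
    shift <- (s - 1) * com            # displacement per molecule
    Rs <- state$R
    for (m in seq_len(N)) {
      idx <- which(mol == m)
      for (c in 1:3) Rs[idx, c, ] <- Rs[idx, c, ] + shift[m, c]
    }
    Rs
  }
  efun <- function(s) {
    Rs <- trial_state(s)
    cpp_rp_eval(as.numeric(Rs), n, state$n_b, box * s, params, ksp,
                FALSE)$energy - e0
  }
  mv <- metropolis_volume(V, efun, beta, p_int, N, dlnV)
  if (mv$accepted) {
    state$R <- trial_state(mv$s)
    state$box <- box * mv$s
  }
  list(state = state, accepted = mv$accepted)
}
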