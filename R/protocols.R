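#' Run one (N, V, T) state point end to end
#'
#' Desk-scale version of the production protocol: build a periodic box at
#' the target density, equilibrate (checked against the molecular MSD
#' criterion), produce, save equally spaced frames, minimize them to
#' inherent structures (the full ring-polymer landscape for `n_b > 1`,
#' the classical landscape for `n_b = 1`), compute the energy estimator and
#' the inherent-structure spectra, and assemble a state-point summary.
#'
#' @param N Number of molecules.
#' @param rho_g_cm3 Density, g/cm^3.
#' @param temperature Temperature, K.
#' @param n_b Beads per ring polymer (1 = classical MD).
#' @param n_steps_eq,n_steps_prod Equilibration / production steps.
#' @param dt Time step, ps.
#' @param n_is_samples Frames minimized to inherent structures (default 25).
#' @param seed Integer seed (controls packing, initial state, dynamics).
#' @param params Model parameters.
#' @param msd_threshold Equilibration MSD threshold, nm^2 (desk-scale
#'   default 0.01; the bulk rule uses 1.0).
#' @param gamma Production thermostat collision frequency, 1/ps. The
#'   desk-scale default 1/ps keeps the thermostat time constant inside a
#'   picosecond-long production window; long (nanosecond) runs should use
#'   the weak liquid-simulation coupling 0.1/ps.
#' @param gamma_eq Equilibration collision frequency, 1/ps. Toy boxes start
#'   from a minimized configuration with Maxwell-Boltzmann velocities, and a
#'   stiffer equilibration coupling removes the packing heat within the
#'   short desk-scale equilibration window.
#' @param compute_spectra Also diagonalize the first converged inherent
#'   structure and attach classical + ring-polymer spectra (default TRUE).
#' @param is_tol Gradient tolerance for the minimizations (NULL = the
#'   per-path defaults of [sample_is()]).
#' @return A `statepoint` object: `summary` (one-row tibble with E, E_IS,
#'   E_vib per molecule, shape function, radii of gyration, equilibration
#'   flag), `is_sample`, `traj`, `spectrum_classical`, `spectrum_rp`.
#' @export
run_statepoint <- function(N = 16, rho_g_cm3 = 1.0, temperature = 260,
                           n_b = 1, n_steps_eq = 2000, n_steps_prod = 4000,
                           dt = 0.25e-3, n_is_samples = 25, seed = 1,
                           params = water_params(), msd_threshold = 0.01,
                           gamma = 1, gamma_eq = 5, compute_spectra = TRUE,
                           is_tol = NULL) {
  cfg <- build_box(N, rho_g_cm3, seed = seed, params = params)
  cfg <- configuration(minimize_classical(cfg, params)$config$positions,
                       box = cfg$box)
  st <- beads_state(cfg, n_b, temperature, params, seed = seed + 1)
  eq <- pimd_run(st, n_steps_eq, dt = dt, temperature = temperature,
                 gamma = gamma_eq, save_every = max(10, n_steps_eq %/% 50),
                 seed = seed + 2, params = params)
  tau <- equilibration_time(msd_curve(eq), threshold = msd_threshold)
  equilibrated <- tau$equilibrated && tau$tau_ps <= n_steps_eq * dt
  prod <- pimd_run(eq$state, n_steps_prod, dt = dt, temperature = temperature,
                   gamma = gamma,
                   save_every = max(1, n_steps_prod %/% n_is_samples),
                   seed = seed + 3, params = params)
  isamp <- sample_is(prod, n_samples = n_is_samples, params = params,
                     tol = is_tol)
  est <- energy_estimator(prod)
  e_per_mol <- est$energy_per_molecule[est$estimator == "primitive"]
  e_is_mol <- isamp$summary$mean_e_is_per_molecule
  rg <- radius_of_gyration(lapply(prod$frames, function(f) {
    s <- prod$state; s$R <- f; s
  }))
  spc <- sprp <- NULL
  S_shape <- NA_real_
  if (compute_spectra) {
    first_ok <- which(vapply(isamp$records, function(r) r$converged, logical(1)))[1]
    rec <- isamp$records[[first_ok]]
    cfg_is <- if (!is.null(rec$config)) rec$config else centroid_config(rec$state)
    spc <- classical_modes(configuration(cfg_is$positions, box = cfg_is$box,
                                         wrap = FALSE), params)
    sprp <- if (n_b > 1) rp_modes_analytic(spc, n_b, temperature) else spc
    S_shape <- shape_function(sprp)
  }
  V <- prod(cfg$box)
  summary <- tibble(
    N = N, V_nm3 = V, rho_g_cm3 = rho_g_cm3, temperature = temperature,
    n_b = n_b, d = 9 * N,
    E_per_molecule = e_per_mol,
    E_IS_per_molecule = e_is_mol,
    E_vib_per_molecule = e_per_mol - e_is_mol,
    S_shape = S_shape,
    rg_O_angstrom = rg$rg_angstrom[rg$species == "O"],
    rg_H_angstrom = rg$rg_angstrom[rg$species == "H"],
    equilibrated = equilibrated,
    tau_ps = tau$tau_ps,
    n_is_failed = isamp$summary$n_failed,
    seed = seed
  )
  structure(list(summary = summary, traj = prod, is_sample = isamp,
                 spectrum_classical = spc, spectrum_rp = sprp,
                 estimators = est),
            class = "statepoint")
}

#' @export
print.statepoint <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "state point N = %d, rho = %.2f g/cm^3, T = %g K, n_b = %d%s\n",
    s$N, s$rho_g_cm3, s$temperature, s$n_b,
    if (s$equilibrated) "" else "  [UNEQUILIBRATED]"))
  cat(sprintf("  E = %.3f, E_IS = %.3f, E_vib = %.3f kJ/mol per molecule\n",
              s$E_per_molecule, s$E_IS_per_molecule, s$E_vib_per_molecule))
  invisible(x)
}

#' @export
tidy.statepoint <- function(x, ...) x$summary

#' Toy isobaric cooling (vitrification) protocol
#'
#' Cools a periodic box stepwise from `T_start` to `T_end` at constant
#' pressure (Monte Carlo barostat), recording at each temperature the
#' density, the inherent-structure energy, and the radii of gyration of the
#' O/H ring polymers in the instantaneous configurations and at the
#' ring-polymer inherent structure. On cooling into the glass, the
#' instantaneous \eqn{R_g(T)} grows monotonically while
#' \eqn{R_g^{IS} \approx 0} at every temperature and \eqn{E_{IS}(T)}
#' flattens below vitrification.
#'
#' @param N Number of molecules.
#' @param rho_init Initial density, g/cm^3.
#' @param T_start,T_end,dT Temperature ramp, K (cooled in steps of `dT`).
#' @param steps_per_T MD steps per temperature stage.
#' @param pressure Pressure, MPa.
#' @param n_b Beads per ring polymer.
#' @param dt Time step, ps.
#' @param seed Integer seed.
#' @param gamma Centroid thermostat rate, 1/ps; the desk-scale default 2/ps
#'   lets the short per-stage runs actually track the ramp.
#' @param params Model parameters.
#' @param minimize_every Minimize inherent structures every this many
#'   stages (the minimizations dominate the cost).
#' @return A tibble of class `cooling_curve`: temperature, rho_g_cm3,
#'   e_is_per_molecule, rg_O, rg_H, rg_is_O, rg_is_H, acceptance.
#' @export
run_cooling <- function(N = 8, rho_init = 1.0, T_start = 240, T_end = 120,
                        dT = 20, steps_per_T = 500, pressure = 0.1,
                        n_b = 8, dt = 0.25e-3, seed = 1, gamma = 2,
                        params = water_params(), minimize_every = 1) {
  cfg <- build_box(N, rho_init, seed = seed, params = params)
  temps <- seq(T_start, T_end, by = -abs(dT))
  st <- beads_state(cfg, n_b, T_start, params, seed = seed + 1)
  mass_g <- N * pel_constants$molar_mass_water / pel_constants$avogadro
  rows <- vector("list", length(temps))
  for (i in seq_along(temps)) {
    T_i <- temps[i]
    st$temperature <- T_i
    tr <- pimd_run(st, steps_per_T, dt = dt, temperature = T_i,
                   gamma = gamma, save_every = steps_per_T,
                   seed = seed + 10 + i, params = params, pressure = pressure)
    st <- tr$state
    rho <- mass_g / (prod(st$box) * 1e-21)
    rg <- radius_of_gyration(st)
    rg_is_O <- rg_is_H <- e_is_mol <- NA_real_
    if ((i - 1) %% minimize_every == 0) {
      rec <- if (n_b > 1) minimize_rp(st, params) else
        minimize_classical(centroid_config(st), params)
      e_is_mol <- rec$e_is_per_molecule
      if (!is.null(rec$rg_is)) {
        rg_is_O <- rec$rg_is$rg_angstrom[rec$rg_is$species == "O"]
        rg_is_H <- rec$rg_is$rg_angstrom[rec$rg_is$species == "H"]
      } else {
        rg_is_O <- rg_is_H <- 0
      }
    }
    rows[[i]] <- tibble(
      temperature = T_i, rho_g_cm3 = rho,
      e_is_per_molecule = e_is_mol,
      rg_O = rg$rg_angstrom[rg$species == "O"],
      rg_H = rg$rg_angstrom[rg$species == "H"],
      rg_is_O = rg_is_O, rg_is_H = rg_is_H,
      acceptance = tr$acceptance
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cooling_curve", class(out))
  out
}

#' Radial distribution function and hydrogen-bond geometry
#'
#' Oxygen-oxygen radial distribution function (bin width 0.002 nm by
#' default) and geometric hydrogen-bond statistics: a donor H of molecule i
#' is bonded to acceptor oxygen j when \eqn{d_{OO} < d_max} and the
#' H-O-(O') angle at the donor oxygen is below `theta_max`. For
#' ring-polymer trajectories both the replica-resolved ("bead") and the
#' centroid representations are reported.
#'
#' @param traj A `pimd_trajectory` of a periodic system.
#' @param bin_width RDF bin width, nm.
#' @param d_oo_max Hydrogen-bond O-O distance cutoff, nm.
#' @param theta_max Hydrogen-bond angular cutoff, degrees.
#' @return list(rdf = tibble(r_nm, g, representation),
#'   hbonds = tibble(representation, mean_d_oo, sem_d_oo, mean_theta_deg,
#'   sem_theta_deg, n_bonds_per_molecule)).
#' @export
structure_analysis <- function(traj, bin_width = 0.002, d_oo_max = 0.35,
                               theta_max = 30) {
  if (is.null(traj$state$box)) abort("structure analysis needs a periodic trajectory")
  box <- traj$state$box
  n <- dim(traj$state$R)[1]
  N <- n / 3
  reps <- if (traj$n_b > 1) c("bead", "centroid") else "centroid"
  rdf_list <- list(); hb_list <- list()
  for (rep_kind in reps) {
    confs <- list()
    for (f in traj$frames) {
      if (rep_kind == "centroid") {
        confs[[length(confs) + 1]] <- apply(f, c(1, 2), mean)
      } else {
        for (k in seq_len(traj$n_b)) confs[[length(confs) + 1]] <- f[, , k]
      }
    }
    rmax <- min(box) / 2
    breaks <- seq(0, rmax, by = bin_width)
    counts <- numeric(length(breaks) - 1)
    hb_d <- c(); hb_t <- c(); nbonds <- 0
    for (pos in confs) {
      o <- pos[seq(1, n, by = 3), , drop = FALSE]
      for (i in 1:(N - 1)) {
        d <- sweep(o[(i + 1):N, , drop = FALSE], 2, o[i, ], `-`)
        d <- d - sweep(round(sweep(d, 2, box, `/`)), 2, box, `*`)
        r <- sqrt(rowSums(d^2))
        counts <- counts + tabulate(findInterval(r[r < rmax], breaks), length(counts))
      }
      # hydrogen bonds (donor H, acceptor O)
      for (i in seq_len(N)) {
        oi <- pos[3 * i - 2, ]
        for (j in seq_len(N)[-i]) {
          doo <- pos[3 * j - 2, ] - oi
          doo <- doo - box * round(doo / box)
          r_oo <- sqrt(sum(doo^2))
          if (r_oo >= d_oo_max) next
          for (hk in 1:2) {
            dh <- pos[3 * i - 2 + hk, ] - oi
            dh <- dh - box * round(dh / box)
            cth <- sum(dh * doo) / (sqrt(sum(dh^2)) * r_oo)
            th <- acos(max(-1, min(1, cth))) * 180 / pi
            if (th < theta_max) {
              hb_d <- c(hb_d, r_oo); hb_t <- c(hb_t, th); nbonds <- nbonds + 1
            }
          }
        }
      }
    }
    nconf <- length(confs)
    mids <- breaks[-1] - bin_width / 2
    shell <- 4 * pi * mids^2 * bin_width
    ideal <- (N * (N - 1) / 2) * shell / prod(box)
    rdf_list[[rep_kind]] <- tibble(r_nm = mids, g = counts / (nconf * ideal),
                                   representation = rep_kind)
    hb_list[[rep_kind]] <- tibble(
      representation = rep_kind,
      mean_d_oo = mean(hb_d), sem_d_oo = sd(hb_d) / sqrt(length(hb_d)),
      mean_theta_deg = mean(hb_t), sem_theta_deg = sd(hb_t) / sqrt(length(hb_t)),
      n_bonds_per_molecule = nbonds / (nconf * N)
    )
  }
  list(rdf = dplyr::bind_rows(rdf_list), hbonds = dplyr::bind_rows(hb_list))
}
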