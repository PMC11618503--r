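#' q-TIP4P/F model parameters
#'
#' Builds the parameter set of the flexible q-TIP4P/F water model: a quartic
#' expansion of a Morse potential for the two OH covalent bonds, a harmonic
#' HOH angle, a Lennard-Jones site on the oxygen, and fixed point charges on
#' the hydrogens and on a massless M site placed on the HOH bisector,
#' \eqn{r_M = \gamma_M r_O + (1-\gamma_M)(r_{H1}+r_{H2})/2}. Long-range
#' electrostatics in periodic boxes use the reaction-field technique with a
#' continuum dielectric beyond the cutoff.
#'
#' Defaults are the published q-TIP4P/F constants (Habershon, Markland &
#' Manolopoulos, J. Chem. Phys. 131, 024501, 2009) converted to internal
#' units (nm, amu, ps, kJ/mol), with the reaction-field dielectric 78.3 and
#' cutoff 1.0 nm used for the liquid simulations this package reproduces at
#' desk scale. A YAML parameter file (see
#' `system.file("extdata", "qtip4pf.yaml", package = "pelwater")`) can
#' override any constant.
#'
#' @param file Optional path to a YAML file whose top-level keys override the
#'   defaults (same names and units as the arguments below).
#' @param D_r Morse well depth, kJ/mol.
#' @param alpha_r Morse range parameter, 1/nm.
#' @param r_eq Equilibrium OH bond length, nm.
#' @param k_theta Harmonic HOH angle force constant, kJ/mol/rad^2.
#' @param theta_eq Equilibrium HOH angle, rad.
#' @param epsilon_LJ,sigma_LJ Oxygen-oxygen Lennard-Jones parameters, kJ/mol
#'   and nm.
#' @param q_H Hydrogen partial charge, e. The M-site charge is always
#'   \eqn{-2 q_H} so the molecule stays neutral.
#' @param gamma_M Dimensionless M-site weight in (0, 1].
#' @param m_O,m_H Atomic masses, amu.
#' @param r_c Nonbonded cutoff, nm. In periodic boxes smaller than
#'   \eqn{2 r_c} the effective cutoff is capped at half the shortest box edge
#'   so the minimum-image convention stays valid.
#' @param eps_rf Reaction-field dielectric constant of the continuum beyond
#'   the cutoff.
#' @param lj_shift Logical; shift the Lennard-Jones pair energy to zero at
#'   the cutoff (default TRUE). The shifted form keeps the total energy
#'   continuous, which gradient-based minimization to tight tolerances
#'   requires; set FALSE for the sharp truncation.
#' @param force_shift Logical; additionally shift the pair *forces* to zero
#'   at the cutoff (default TRUE), making the potential C1-continuous
#'   (shift-force modification of the Lennard-Jones and reaction-field
#'   terms). Quasi-Newton minimization to gradient norms of 1e-6 kJ/mol/nm
#'   requires a continuous gradient; set FALSE for the plain (energy-only
#'   shifted) reaction-field dialect.
#' @param hessian_h Finite-difference step for Hessian construction, nm.
#'
#' @return An object of class `water_params` (a named list).
#' @examples
#' p <- water_params()
#' p$r_eq                      # 0.09419 nm
#' water_params(q_H = 0.60)$q_M  # -1.2
#' @export
water_params <- function(file = NULL,
                         D_r = 116.09 * 4.184,
                         alpha_r = 22.87,
                         r_eq = 0.09419,
                         k_theta = 87.85 * 4.184,
                         theta_eq = 107.4 * pi / 180,
                         epsilon_LJ = 0.1852 * 4.184,
                         sigma_LJ = 0.31589,
                         q_H = 0.5564,
                         gamma_M = 0.73612,
                         m_O = 15.9994,
                         m_H = 1.008,
                         r_c = 1.0,
                         eps_rf = 78.3,
                         lj_shift = TRUE,
                         force_shift = TRUE,
                         hessian_h = 1e-5) {
  p <- list(D_r = D_r, alpha_r = alpha_r, r_eq = r_eq, k_theta = k_theta,
            theta_eq = theta_eq, epsilon_LJ = epsilon_LJ, sigma_LJ = sigma_LJ,
            q_H = q_H, gamma_M = gamma_M, m_O = m_O, m_H = m_H,
            r_c = r_c, eps_rf = eps_rf, lj_shift = lj_shift,
            force_shift = force_shift, hessian_h = hessian_h)
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    unknown <- setdiff(names(y), names(p))
    if (length(unknown) > 0)
      abort(paste0("unknown parameter(s) in file: ", paste(unknown, collapse = ", ")))
    p[names(y)] <- y
  }
  p$q_M <- -2 * p$q_H
  validate_water_params(p)
  structure(p, class = "water_params")
}

validate_water_params <- function(p) {
  stopifnot(p$r_eq > 0, p$theta_eq > 0, p$theta_eq < pi,
            p$gamma_M > 0, p$gamma_M <= 1,
            p$r_c > p$sigma_LJ, p$m_O > 0, p$m_H > 0)
  if (abs(p$q_M + 2 * p$q_H) > 1e-12) abort("molecule is not neutral")
  invisible(p)
}

#' @export
print.water_params <- function(x, ...) {
  cat("q-TIP4P/F parameter set (internal units: nm, amu, ps, kJ/mol)\n")
  for (nm in setdiff(names(x), c("lj_shift", "force_shift")))
    cat(sprintf("  %-10s %.6g\n", nm, x[[nm]]))
  cat(sprintf("  %-10s %s\n", "lj_shift", x$lj_shift))
  cat(sprintf("  %-10s %s\n", "force_shift", x$force_shift))
  invisible(x)
}

# masses per atom (O,H,H ordering), length n
atom_masses <- function(n_molecules, params) {
  rep(c(params$m_O, params$m_H, params$m_H), n_molecules)
}
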