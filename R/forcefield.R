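#' Position of the massless M charge site
#'
#' The q-TIP4P/F M site is a weighted combination of the three atom positions
#' of one molecule, \eqn{r_M = \gamma_M r_O + (1-\gamma_M)(r_{H1}+r_{H2})/2},
#' so it always lies in the HOH plane on the angle bisector of a symmetric
#' molecule.
#'
#' @param o,h1,h2 Numeric length-3 positions of the O and the two H atoms, nm.
#' @param gamma_M M-site weight in (0, 1]; `gamma_M = 1` collapses the M site
#'   onto the oxygen.
#' @return Numeric length-3 position of the M site, nm.
#' @examples
#' msite_position(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 0.5)  # (0.25, 0.25, 0)
#' @export
msite_position <- function(o, h1, h2, gamma_M) {
  stopifnot(length(o) == 3, length(h1) == 3, length(h2) == 3,
            is.finite(gamma_M), gamma_M > 0, gamma_M <= 1)
  if (sqrt(sum((h1 - o)^2)) > 0.2 || sqrt(sum((h2 - o)^2)) > 0.2)
    abort("malformed molecule: O-H distance exceeds 0.2 nm")
  gamma_M * o + (1 - gamma_M) / 2 * (h1 + h2)
}

#' Intramolecular energy of one water molecule
#'
#' Sum over the two OH bonds of the quartic expansion of the Morse potential,
#' \deqn{V(\Delta r) = D_r \alpha_r^2 \Delta r^2 [1 - \alpha_r \Delta r +
#'   \tfrac{7}{12} \alpha_r^2 \Delta r^2],}
#' plus the harmonic angle term \eqn{(k_\theta/2)(\theta-\theta_{eq})^2}.
#' Zero at the equilibrium geometry.
#'
#' @param mol 3 x 3 matrix of positions (rows O, H, H), nm.
#' @param params Model parameters, see [water_params()].
#' @return Energy in kJ/mol.
#' @export
intramolecular_energy <- function(mol, params = water_params()) {
  total_energy(configuration(mol), params)
}

#' Potential energy, forces, and mass-weighted Hessian
#'
#' `total_energy()` evaluates the full q-TIP4P/F potential U of a
#' configuration: intramolecular terms, O-O Lennard-Jones (truncated at the
#' cutoff in periodic boxes), and site-site electrostatics -- plain Coulomb
#' for open clusters, reaction-field with an energy shift (the pair term
#' vanishes continuously at the cutoff) for periodic boxes. `forces()`
#' returns the analytic gradient \eqn{F = -\nabla U} with the M-site force
#' redistributed onto the real atoms by the chain rule.
#' `mass_weighted_hessian()` builds
#' \eqn{H_{ij} = (m_i m_j)^{-1/2} \partial^2 U/\partial x_i \partial x_j}
#' from central finite differences of the analytic forces and symmetrizes it.
#'
#' @param config A `water_config`.
#' @param params Model parameters.
#' @param h Finite-difference step in nm (default `params$hessian_h`).
#' @param masses Optional length-n mass vector (amu); defaults to the
#'   physical atomic masses.
#' @return `total_energy()`: scalar kJ/mol. `forces()`: n x 3 matrix in
#'   kJ/mol/nm. `mass_weighted_hessian()`: symmetric 3n x 3n matrix whose
#'   eigenvalues are squared angular frequencies in ps^-2.
#' @examples
#' cfg <- build_cluster(1)
#' total_energy(cfg)          # 0 at the equilibrium monomer
#' max(abs(forces(cfg)))      # ~0 at a stationary point
#' @export
total_energy <- function(config, params = water_params()) {
  ff_eval(config, params)$energy
}

#' @rdname total_energy
#' @export
forces <- function(config, params = water_params()) {
  ff_eval(config, params)$forces
}

ff_eval <- function(config, params) {
  box <- if (is.null(config$box)) numeric(0) else config$box
  cpp_ff_eval(config$positions, box, params)
}

#' @rdname total_energy
#' @export
mass_weighted_hessian <- function(config, params = water_params(),
                                  h = params$hessian_h, masses = NULL) {
  n <- nrow(config$positions)
  if (is.null(masses)) masses <- atom_masses(n / 3, params)
  stopifnot(length(masses) == n, all(masses > 0))
  box <- if (is.null(config$box)) numeric(0) else config$box
  inv <- rep(1 / sqrt(masses), 3)
  cpp_hessian(config$positions, box, params, h, inv)
}
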