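#' Map a configuration to its inherent structure
#'
#' Minimizes the potential energy with L-BFGS-B until the gradient infinity
#' norm is below `tol`, returning the local minimum (inherent structure, IS)
#' of the classical landscape. `minimize_rp()` does the same for the
#' ring-polymer potential over all 3 n n_b bead coordinates; at a converged
#' ring-polymer IS the beads are collapsed, the spring energy is zero, and
#' the IS energy coincides with the classical IS energy of the collapsed
#' point.
#'
#' @param config A `water_config`.
#' @param params Model parameters.
#' @param tol Gradient tolerance, kJ/mol/nm (infinity norm). Default 1e-6
#'   for the classical minimization, where a Newton polish stage (exact
#'   curvature from the finite-difference Hessian, zero modes projected
#'   out) pushes the gradient below the L-BFGS-B floating-point stall;
#'   1e-3 for the ring-polymer minimization, whose 3 n n_b-dimensional
#'   Hessian makes polishing disproportionate; the L-BFGS-B floating-point
#'   stall grows with system size, and a 1e-3 kJ/mol/nm gradient already
#'   pins bead displacements to ~1e-5 Angstrom on the softest spring mode.
#' @param polish Run Newton polish after L-BFGS-B (classical only,
#'   default TRUE).
#' @param max_iter Iteration cap for L-BFGS-B.
#' @param source_frame Optional frame identifier carried into the record.
#' @return An `is_record`: minimized `config` (or `state`), the IS energy
#'   `e_is` (kJ/mol, plus `e_is_per_molecule`), `grad_norm`, `iterations`,
#'   `converged`, `spring_energy` and per-species `rg_is` (Angstrom, ring
#'   polymer only).
#' @examples
#' cfg <- build_cluster(1)
#' distorted <- configuration(cfg$positions * 1.05)
#' rec <- minimize_classical(distorted)
#' rec$e_is    # back to ~0
#' @export
minimize_classical <- function(config, params = water_params(), tol = 1e-6,
                               polish = TRUE, max_iter = 1e5,
                               source_frame = NA) {
  box <- if (is.null(config$box)) numeric(0) else config$box
  x0 <- as.numeric(config$positions)
  n <- nrow(config$positions)
  fn <- function(x) cpp_ff_eval(matrix(x, n, 3), box, params)$energy
  gr <- function(x) -as.numeric(cpp_ff_eval(matrix(x, n, 3), box, params)$forces)
  opt <- optim(x0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 1, pgtol = 0))
  par <- opt$par
  if (polish) {
    hess <- function(x) cpp_hessian(matrix(x, n, 3), box, params,
                                    params$hessian_h, rep(1, 3 * n))
    par <- newton_polish(par, gr, hess, tol)$x
  }
  g <- gr(par)
  gmax <- max(abs(g))
  cfg_min <- configuration(matrix(par, n, 3), box = config$box, wrap = FALSE)
  new_is_record(
    config = cfg_min, e_is = fn(par), N = n / 3, grad_norm = gmax,
    iterations = opt$counts[["function"]], converged = gmax <= tol,
    spring_energy = 0, rg_is = NULL, source_frame = source_frame,
    message = opt$message
  )
}

# Newton refinement of a near-minimum: solves H dx = -g in the subspace of
# eigenvalues |lambda| > lam_min (projecting out translations/rotations),
# accepting steps only while the gradient norm decreases.
newton_polish <- function(x, gr, hess, tol, max_iter = 8, lam_min = 1) {
  g <- gr(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(g)) <= tol) break
    ed <- eigen(hess(x), symmetric = TRUE)
    keep <- abs(ed$values) > lam_min
    V <- ed$vectors[, keep, drop = FALSE]
    dx <- -as.numeric(V %*% ((t(V) %*% g) / ed$values[keep]))
    gn <- gr(x + dx)
    if (max(abs(gn)) < max(abs(g))) {
      x <- x + dx
      g <- gn
    } else break
  }
  list(x = x, grad = g)
}

#' @rdname minimize_classical
#' @param state A `beads_state`.
#' @export
minimize_rp <- function(state, params = water_params(), tol = 1e-3,
                        max_iter = 1e5, source_frame = NA) {
  n <- dim(state$R)[1]
  n_b <- state$n_b
  box <- if (is.null(state$box)) numeric(0) else state$box
  ksp <- spring_constant(state$masses, n_b, state$temperature)
  fn <- function(x) cpp_rp_eval(x, n, n_b, box, params, ksp, FALSE)$energy
  gr <- function(x) as.numeric(cpp_rp_eval(x, n, n_b, box, params, ksp, TRUE)$gradient)
  opt <- optim(beads_flat(state), fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 1, pgtol = 0))
  g <- gr(opt$par)
  gmax <- max(abs(g))
  st_min <- state_from_flat(opt$par, state)
  ev <- cpp_rp_eval(opt$par, n, n_b, box, params, ksp, FALSE)
  new_is_record(
    state = st_min, e_is = opt$value, N = n / 3, grad_norm = gmax,
    iterations = opt$counts[["function"]], converged = gmax <= tol,
    spring_energy = ev$spring_energy,
    rg_is = radius_of_gyration(st_min), source_frame = source_frame,
    message = opt$message
  )
}

new_is_record <- function(e_is, N, grad_norm, iterations, converged,
                          spring_energy, rg_is, source_frame, message,
                          config = NULL, state = NULL) {
  structure(list(
    config = config, state = state, e_is = e_is,
    e_is_per_molecule = e_is / N, grad_norm = grad_norm,
    iterations = iterations, converged = converged,
    spring_energy = spring_energy, rg_is = rg_is,
    source_frame = source_frame, message = message
  ), class = "is_record")
}

#' @export
print.is_record <- function(x, ...) {
  cat(sprintf(
    "inherent structure: e_IS = %.6f kJ/mol (%.4f per molecule), max|grad| = %.2e, %s\n",
    x$e_is, x$e_is_per_molecule, x$grad_norm,
    if (x$converged) "converged" else "NOT CONVERGED"))
  if (!is.null(x$rg_is)) {
    cat(sprintf("  R_g at IS: O %.3e A, H %.3e A; spring energy %.3e kJ/mol\n",
                x$rg_is$rg_angstrom[x$rg_is$species == "O"],
                x$rg_is$rg_angstrom[x$rg_is$species == "H"],
                x$spring_energy))
  }
  invisible(x)
}

#' Serialize an inherent-structure record to JSON (+ extended XYZ)
#'
#' Writes the scalar diagnostics as JSON; if `xyz_path` is given, the
#' minimized coordinates (the bead centroid for ring-polymer records) go to
#' an extended-XYZ file alongside.
#'
#' @param record An `is_record`.
#' @param path JSON output path.
#' @param xyz_path Optional XYZ output path.
#' @return `path`, invisibly.
#' @export
write_is_record <- function(record, path, xyz_path = NULL) {
  meta <- record[c("e_is", "e_is_per_molecule", "grad_norm", "iterations",
                   "converged", "spring_energy", "source_frame")]
  if (!is.null(record$rg_is))
    meta$rg_is <- as.list(setNames(record$rg_is$rg_angstrom, record$rg_is$species))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(xyz_path)) {
    cfg <- if (!is.null(record$config)) record$config else
      centroid_config(record$state)
    write_xyz(cfg, xyz_path)
  }
  invisible(path)
}

#' Ring-polymer radius of gyration
#'
#' Per-species root-mean-square distance of the beads from their ring
#' centroid,
#' \eqn{R_g = \sqrt{\langle \tfrac{1}{n_b}\sum_j (r_c - r_j)^2 \rangle}},
#' the standard measure of quantum positional delocalization. Identically
#' zero for `n_b = 1`. Reported in Angstrom.
#'
#' @param state A `beads_state`, or a list of them (frames), in which case
#'   the average also runs over frames.
#' @return A tibble with columns `species` and `rg_angstrom`.
#' @export
radius_of_gyration <- function(state) {
  states <- if (inherits(state, "beads_state")) list(state) else state
  n <- dim(states[[1]]$R)[1]
  species <- rep(c("O", "H", "H"), n / 3)
  acc <- c(O = 0, H = 0); cnt <- c(O = 0, H = 0)
  for (st in states) {
    cen <- apply(st$R, c(1, 2), mean)
    dev2 <- (st$R - array(rep(cen, st$n_b), dim = dim(st$R)))^2
    per_atom <- apply(dev2, 1, sum) / st$n_b   # sum over dims & beads / n_b
    for (sp in c("O", "H")) {
      acc[sp] <- acc[sp] + sum(per_atom[species == sp])
      cnt[sp] <- cnt[sp] + sum(species == sp)
    }
  }
  tibble(species = c("O", "H"),
         rg_angstrom = 10 * sqrt(as.numeric(acc / cnt)))
}

#' Minimize equally spaced frames of a trajectory
#'
#' Takes `n_samples` equally spaced frames (default 25, the standard IS
#' sampling protocol) and minimizes each: the ring-polymer potential for
#' multi-bead trajectories, the classical potential for `n_b = 1`.
#' Non-converged minimizations are excluded from the summary with a count.
#'
#' @param traj A `pimd_trajectory`.
#' @param n_samples Number of frames to minimize.
#' @param params Model parameters.
#' @param path "rp" (minimize the full ring-polymer landscape) or
#'   "centroid" (classical minimization started at the bead centroid -- the
#'   documented fast path, which must agree with "rp" when both reach the
#'   same basin).
#' @param tol,max_iter Passed to the minimizer; `tol = NULL` uses 1e-6 for
#'   classical and 1e-3 for ring-polymer minimizations.
#' @return An `is_sample`: list of `is_record`s plus a summary tibble
#'   (mean e_IS per molecule, s.e.m., failure count).
#' @export
sample_is <- function(traj, n_samples = 25, params = traj$params,
                      path = c("rp", "centroid"), tol = NULL, max_iter = 1e5) {
  path <- match.arg(path)
  classical <- traj$n_b == 1 || path == "centroid"
  if (is.null(tol)) tol <- if (classical) 1e-6 else 1e-3
  nf <- length(traj$frames)
  if (nf < 1) abort("trajectory has no saved frames")
  n_samples <- min(n_samples, nf)
  idx <- if (n_samples == 1) nf else unique(round(seq(1, nf, length.out = n_samples)))
  recs <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    st <- traj$state
    st$R <- traj$frames[[idx[i]]]
    if (traj$n_b == 1 || path == "centroid") {
      cfg <- centroid_config(st)
      recs[[i]] <- minimize_classical(cfg, params, tol = tol,
                                      max_iter = max_iter, source_frame = idx[i])
    } else {
      recs[[i]] <- minimize_rp(st, params, tol = tol, max_iter = max_iter,
                               source_frame = idx[i])
    }
  }
  ok <- vapply(recs, function(r) r$converged, logical(1))
  e <- vapply(recs[ok], function(r) r$e_is_per_molecule, numeric(1))
  summary <- tibble(
    n_minimized = length(recs), n_failed = sum(!ok),
    mean_e_is_per_molecule = mean(e),
    sem_e_is_per_molecule = if (length(e) > 1) sd(e) / sqrt(length(e)) else NA_real_
  )
  structure(list(records = recs, summary = summary, path = path),
            class = "is_sample")
}

#' @export
print.is_sample <- function(x, ...) {
  s <- x$summary
  cat(sprintf("IS sample: %d frames minimized (%d failed), e_IS = %.4f +/- %s kJ/mol per molecule\n",
              s$n_minimized, s$n_failed, s$mean_e_is_per_molecule,
              formatC(s$sem_e_is_per_molecule, format = "g", digits = 2)))
  invisible(x)
}

#' @export
tidy.is_sample <- function(x, ...) {
  purrr::map_dfr(seq_along(x$records), function(i) {
    r <- x$records[[i]]
    tibble(frame = r$source_frame, e_is = r$e_is,
           e_is_per_molecule = r$e_is_per_molecule,
           grad_norm = r$grad_norm, converged = r$converged,
           spring_energy = r$spring_energy,
           rg_is_O = if (is.null(r$rg_is)) NA_real_ else
             r$rg_is$rg_angstrom[r$rg_is$species == "O"],
           rg_is_H = if (is.null(r$rg_is)) NA_real_ else
             r$rg_is$rg_angstrom[r$rg_is$species == "H"])
  })
}
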