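#' Water configurations
#'
#' A `water_config` holds one classical configuration of N water molecules:
#' an n x 3 matrix of positions in nm with atoms ordered O,H,H per molecule,
#' and optionally a periodic box (three edge lengths in nm). Coordinates of
#' periodic systems are stored wrapped into `[0, L)`; molecular bonds are
#' resolved by the minimum-image convention, so a wrapped molecule is still
#' whole. The number of degrees of freedom is `d = 3n = 9N`.
#'
#' @param positions Numeric n x 3 matrix, nm. n must be a multiple of 3.
#' @param box Numeric vector of 3 box edge lengths (nm), or NULL for an open
#'   (cluster) system.
#' @param wrap Wrap periodic coordinates into the box (default TRUE).
#' @return An object of class `water_config` with fields `positions`,
#'   `species` ("O"/"H"), `molecule` (1-based molecule index per atom), and
#'   `box` (or NULL).
#' @examples
#' cfg <- build_cluster(1)
#' cfg$species
#' @export
configuration <- function(positions, box = NULL, wrap = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (n %% 3 != 0 || ncol(positions) != 3)
    abort("positions must be an (3N) x 3 matrix with atoms ordered O,H,H per molecule")
  if (!all(is.finite(positions))) abort("non-finite coordinates")
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3, all(box > 0))
    if (wrap) positions <- positions %% matrix(box, n, 3, byrow = TRUE)
  }
  N <- n / 3
  structure(list(
    positions = positions,
    species = rep(c("O", "H", "H"), N),
    molecule = rep(seq_len(N), each = 3),
    box = box
  ), class = "water_config")
}

n_molecules <- function(config) nrow(config$positions) / 3

#' @export
print.water_config <- function(x, ...) {
  N <- n_molecules(x)
  if (is.null(x$box)) {
    cat(sprintf("water cluster: %d molecules (%d atoms), open boundaries\n",
                N, 3 * N))
  } else {
    cat(sprintf("periodic water box: %d molecules, L = %.4f x %.4f x %.4f nm\n",
                N, x$box[1], x$box[2], x$box[3]))
  }
  invisible(x)
}

# one molecule at its equilibrium geometry, O at `center`, HOH in the xy plane
equilibrium_molecule <- function(params, center = c(0, 0, 0)) {
  half <- params$theta_eq / 2
  o <- center
  h1 <- center + params$r_eq * c(sin(half), cos(half), 0)
  h2 <- center + params$r_eq * c(-sin(half), cos(half), 0)
  rbind(o, h1, h2)
}

rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

place_molecules <- function(centers, angles, params) {
  N <- nrow(centers)
  pos <- matrix(0, 3 * N, 3)
  for (m in seq_len(N)) {
    mol <- equilibrium_molecule(params)
    R <- rotation_matrix(angles[m, 1], angles[m, 2], angles[m, 3])
    mol <- t(R %*% t(mol))
    pos[(3 * m - 2):(3 * m), ] <- sweep(mol, 2, centers[m, ], `+`)
  }
  pos
}

#' Build a small hydrogen-bond-friendly water cluster
#'
#' Places N molecules on a compact deterministic seed geometry (nearest
#' neighbours about 0.29 nm apart, alternating orientations) and relaxes it
#' with [minimize_classical()] so the returned cluster sits at a local
#' minimum of the potential. Open (non-periodic) boundaries.
#'
#' @param N Number of molecules: 1, 2, 4, 8, or 16.
#' @param params Model parameters, see [water_params()].
#' @param minimize Relax the seed geometry (default TRUE). `build_cluster(1)`
#'   is always the exact equilibrium monomer with zero energy.
#' @return A `water_config`.
#' @examples
#' cl <- build_cluster(2)
#' total_energy(cl) < 0   # bound dimer
#' @export
build_cluster <- function(N, params = water_params(), minimize = TRUE) {
  if (!N %in% c(1, 2, 4, 8, 16)) abort("supported cluster sizes: 1, 2, 4, 8, 16")
  if (N == 1) return(configuration(equilibrium_molecule(params)))
  a <- 0.29
  grid <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  centers <- switch(as.character(N),
    "2" = rbind(c(0, 0, 0), c(a, 0, 0)),
    "4" = a * rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)) / sqrt(2),
    "8" = a * grid,
    "16" = a * rbind(grid, sweep(grid, 2, c(0.5, 0.5, 0.5), `+`))
  )
  angles <- matrix(0, N, 3)
  for (m in seq_len(N)) {   # deterministic alternating orientations
    angles[m, ] <- c(pi / 2 * (m %% 4), pi / 3 * (m %% 3), pi / 5 * (m %% 5))
  }
  cfg <- configuration(place_molecules(centers, angles, params))
  if (minimize) cfg <- minimize_classical(cfg, params)$config
  cfg
}

#' Build a periodic water box at a target density
#'
#' Molecules are placed on a jittered cubic lattice with random orientations;
#' the box edge follows from the density and the molar mass of water,
#' \eqn{L = (N M_w / (N_A \rho))^{1/3}}.
#'
#' @param N Number of molecules.
#' @param rho_g_cm3 Mass density in g/cm^3 (0.6 to 1.6 supported).
#' @param seed Integer seed for the jitter and orientations.
#' @param params Model parameters.
#' @return A `water_config` with a cubic box.
#' @examples
#' box <- build_box(8, 1.0, seed = 1)
#' box$box[1]   # ~0.620 nm
#' @export
build_box <- function(N, rho_g_cm3, seed = 1, params = water_params()) {
  if (rho_g_cm3 < 0.6 || rho_g_cm3 > 1.6)
    abort("density outside the supported range 0.6-1.6 g/cm^3")
  L <- (N * pel_constants$molar_mass_water /
          (pel_constants$avogadro * rho_g_cm3) * 1e21)^(1 / 3)
  n_side <- ceiling(N^(1 / 3))
  a <- L / n_side
  set.seed(seed)
  for (attempt in 1:25) {
    grid <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                  z = seq_len(n_side))) - 0.5
    centers <- grid[seq_len(N), , drop = FALSE] * a
    centers <- centers + matrix(runif(3 * N, -0.05, 0.05) * a, N, 3)
    angles <- matrix(runif(3 * N, 0, 2 * pi), N, 3)
    cfg <- configuration(place_molecules(centers, angles, params), box = rep(L, 3))
    if (min_oo_distance(cfg) > 0.22) return(cfg)
  }
  abort(sprintf("could not pack %d molecules at %.2f g/cm^3 without overlap",
                N, rho_g_cm3))
}

min_oo_distance <- function(config) {
  o <- config$positions[config$species == "O", , drop = FALSE]
  N <- nrow(o)
  if (N < 2) return(Inf)
  dmin <- Inf
  for (i in 1:(N - 1)) {
    d <- sweep(o[(i + 1):N, , drop = FALSE], 2, o[i, ], `-`)
    if (!is.null(config$box))
      d <- d - sweep(round(sweep(d, 2, config$box, `/`)), 2, config$box, `*`)
    dmin <- min(dmin, sqrt(rowSums(d^2)))
  }
  dmin
}

#' Read and write configurations in extended-XYZ format
#'
#' The extended-XYZ dialect stores the box in a `Lattice="..."` comment-line
#' entry (9 numbers, row-major lattice vectors; only orthorhombic lattices
#' are supported) and one `species x y z` row per atom. Coordinates are in
#' Angstrom in the file (the common convention) and converted to nm.
#'
#' @param path File path.
#' @param config A `water_config`.
#' @return `read_xyz()` returns a `water_config`; `write_xyz()` returns
#'   `path` invisibly.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  comment <- lines[2]
  box <- NULL
  m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
  if (length(m) == 2) {
    lat <- matrix(as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]]), 3, 3, byrow = TRUE)
    offdiag <- lat[row(lat) != col(lat)]
    if (any(abs(offdiag) > 1e-10)) abort("only orthorhombic lattices are supported")
    box <- diag(lat) / 10   # Angstrom -> nm
  }
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  species <- vapply(parts, `[[`, "", 1)
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))) / 10
  cfg <- configuration(pos, box = box, wrap = FALSE)
  if (!identical(cfg$species, species))
    abort("atoms must be ordered O,H,H per molecule")
  cfg
}

#' @rdname read_xyz
#' @export
write_xyz <- function(config, path) {
  pos <- config$positions * 10   # nm -> Angstrom
  n <- nrow(pos)
  if (is.null(config$box)) {
    comment <- 'Properties=species:S:1:pos:R:3'
  } else {
    L <- config$box * 10
    comment <- sprintf('Lattice="%.10f 0 0 0 %.10f 0 0 0 %.10f" Properties=species:S:1:pos:R:3',
                       L[1], L[2], L[3])
  }
  rows <- sprintf("%s %.10f %.10f %.10f", config$species,
                  pos[, 1], pos[, 2], pos[, 3])
  writeLines(c(as.character(n), comment, rows), path)
  invisible(path)
}
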