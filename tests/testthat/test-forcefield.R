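p <- water_params()

test_that("M-site position follows the weighted O/H combination", {
  o <- c(0, 0, 0)
  # weight-1 limit collapses onto the oxygen
  expect_equal(msite_position(o, c(0.1, 0, 0), c(0, 0.1, 0), 1), o)
  # direct arithmetic at gamma = 0.5 (scaled to valid bond lengths)
  expect_equal(msite_position(o, c(0.1, 0, 0), c(0, 0.1, 0), 0.5),
               c(0.025, 0.025, 0))
  # symmetric molecule: M lies on the bisector axis (x = 0 here)
  m <- msite_position(o, 0.09419 * c(sin(0.9), cos(0.9), 0),
                      0.09419 * c(-sin(0.9), cos(0.9), 0), p$gamma_M)
  expect_equal(m[1], 0)
  expect_equal(m[3], 0)
  expect_error(msite_position(o, c(0.5, 0, 0), c(0, 0.1, 0), 0.5), "malformed")
})

test_that("intramolecular terms vanish at equilibrium and have the Morse curvature", {
  eq <- build_cluster(1)$positions
  expect_equal(intramolecular_energy(eq, p), 0)
  # harmonic limit: energy / dr^2 -> D alpha^2 per stretched bond
  for (dr in c(1e-5, 1e-6)) {
    mol <- eq
    u <- (eq[2, ] - eq[1, ]) / sqrt(sum((eq[2, ] - eq[1, ])^2))
    mol[2, ] <- mol[2, ] + dr * u
    expect_equal(intramolecular_energy(mol, p) / dr^2, p$D_r * p$alpha_r^2,
                 tolerance = 1e-3)
  }
  # quartic expansion tracks the full Morse well to < 1e-3 relative at dr = 1e-3 nm
  for (dr in c(1e-3, -1e-3)) {
    mol <- eq
    u <- (eq[2, ] - eq[1, ]) / sqrt(sum((eq[2, ] - eq[1, ])^2))
    mol[2, ] <- mol[2, ] + dr * u
    quartic <- intramolecular_energy(mol, p)
    morse <- p$D_r * (1 - exp(-p$alpha_r * dr))^2
    expect_lt(abs(quartic - morse) / morse, 1e-3)
  }
})

test_that("quartic Morse expansion deviates from full Morse at fifth order", {
  eq <- build_cluster(1)$positions
  u <- (eq[2, ] - eq[1, ]) / sqrt(sum((eq[2, ] - eq[1, ])^2))
  ratio <- vapply(c(4e-3, 2e-3, 1e-3, 5e-4), function(dr) {
    mol <- eq; mol[2, ] <- mol[2, ] + dr * u
    diff <- intramolecular_energy(mol, p) - p$D_r * (1 - exp(-p$alpha_r * dr))^2
    abs(diff) / (p$D_r * (p$alpha_r * dr)^5)
  }, numeric(1))
  # bounded as dr -> 0 (the expansion is exact through fourth order)
  expect_true(all(ratio < 1))
  expect_lt(diff(range(ratio)) / mean(ratio), 0.5)
})

test_that("total energy decomposes into independently recomputed pair terms", {
  cl <- fix_dimer()
  cfg4 <- build_cluster(4)
  for (cfg in list(cl, cfg4)) {
    pos <- cfg$positions
    N <- nrow(pos) / 3
    # independent double-loop evaluator: intramolecular + O-O LJ + site Coulomb
    e <- 0
    for (m in seq_len(N)) e <- e + intramolecular_energy(pos[(3 * m - 2):(3 * m), ], p)
    site_pos <- function(m) {
      o <- pos[3 * m - 2, ]; h1 <- pos[3 * m - 1, ]; h2 <- pos[3 * m, ]
      rbind(h1, h2, msite_position(o, h1, h2, p$gamma_M))
    }
    qs <- c(p$q_H, p$q_H, p$q_M)
    for (mi in seq_len(N - 1)) for (mj in (mi + 1):N) {
      r <- sqrt(sum((pos[3 * mi - 2, ] - pos[3 * mj - 2, ])^2))
      sr6 <- (p$sigma_LJ / r)^6
      e <- e + 4 * p$epsilon_LJ * (sr6^2 - sr6)
      si <- site_pos(mi); sj <- site_pos(mj)
      for (a in 1:3) for (b in 1:3) {
        rr <- sqrt(sum((si[a, ] - sj[b, ])^2))
        e <- e + pel_constants$coulomb * qs[a] * qs[b] / rr
      }
    }
    expect_equal(total_energy(cfg, p), e, tolerance = 1e-10)
  }
})

test_that("periodic cutoff contract: zero interaction beyond r_c, continuous approach", {
  # two molecules in a large box; each site-site pair term is cut at r_c and
  # shifted so it vanishes continuously there (site-resolved cutoff dialect)
  eqm <- build_cluster(1)$positions
  far <- rbind(eqm, sweep(eqm, 2, c(1.35, 0, 0), `+`))
  cfg <- configuration(far, box = c(3, 3, 3), wrap = FALSE)
  expect_equal(total_energy(cfg, p), 0)   # everything beyond cutoff
  # sweep the separation across the cutoff: the energy is continuous (no
  # jumps above curvature scale) and reaches exactly zero once all site
  # pairs are outside r_c
  seps <- seq(0.93 * p$r_c, 1.2 * p$r_c, length.out = 120)
  u <- vapply(seps, function(sp) {
    two <- rbind(eqm, sweep(eqm, 2, c(sp, 0, 0), `+`))
    total_energy(configuration(two, box = c(3, 3, 3), wrap = FALSE), p)
  }, numeric(1))
  expect_equal(u[length(u)], 0)
  # C1 continuity: the second difference stays at curvature scale across
  # every site-pair cutoff crossing (a kink would spike it by |dF| * dr)
  expect_lt(max(abs(diff(diff(u)))), 5e-3)
  # without the force shift the crossing leaves a visible kink
  p_sharp <- water_params(force_shift = FALSE)
  u2 <- vapply(seps, function(sp) {
    two <- rbind(eqm, sweep(eqm, 2, c(sp, 0, 0), `+`))
    total_energy(configuration(two, box = c(3, 3, 3), wrap = FALSE), p_sharp)
  }, numeric(1))
  expect_gt(max(abs(diff(diff(u2)))), max(abs(diff(diff(u)))))
})

test_that("analytic forces match central finite differences and sum to zero", {
  set.seed(7)
  b <- build_box(8, 1.0, seed = 7)
  pos <- b$positions + matrix(rnorm(72, 0, 1e-3), 24, 3)
  cfg <- configuration(pos, box = b$box, wrap = FALSE)
  f <- forces(cfg, p)
  h <- 1e-6
  fn <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) for (c in 1:3) {
    pp <- pos; pp[i, c] <- pp[i, c] + h
    pm <- pos; pm[i, c] <- pm[i, c] - h
    fn[i, c] <- -(total_energy(configuration(pp, box = b$box, wrap = FALSE), p) -
                    total_energy(configuration(pm, box = b$box, wrap = FALSE), p)) / (2 * h)
  }
  expect_lt(max(abs(f - fn)), 1e-4)
  expect_lt(max(abs(colSums(f))), 1e-8)
  expect_equal(forces(build_cluster(1), p), matrix(0, 3, 3), tolerance = 1e-10)
})

test_that("energy-force consistency holds across a displacement sweep", {
  cfg <- fix_box_is()$config
  set.seed(9)
  dir <- matrix(rnorm(72), 24, 3)
  dir <- dir / sqrt(sum(dir^2))
  f <- forces(cfg, p)
  u0 <- total_energy(cfg, p)
  err <- vapply(c(1e-3, 1e-4, 1e-5), function(s) {
    du <- total_energy(configuration(cfg$positions + s * dir, box = cfg$box,
                                     wrap = FALSE), p) - u0
    abs(du - (-sum(f * dir) * s)) / s^2
  }, numeric(1))
  # the residual is O(|delta|^2): err/s^2 stays bounded as s shrinks
  expect_lt(max(err) / min(err), 50)
})

test_that("lattice translations leave the periodic energy unchanged", {
  cfg <- fix_box_is()$config
  u0 <- total_energy(cfg, p)
  for (shift in list(cfg$box * c(1, 0, 0), cfg$box * c(2, -1, 1))) {
    cfg2 <- configuration(sweep(cfg$positions, 2, shift, `+`), box = cfg$box,
                          wrap = FALSE)
    expect_equal(total_energy(cfg2, p), u0, tolerance = 1e-10)
  }
})

test_that("mass-weighted Hessian is symmetric with the free-molecule mode structure", {
  rec <- minimize_classical(build_cluster(1), p)
  H <- mass_weighted_hessian(rec$config, p)
  expect_equal(H, t(H), tolerance = 1e-8)
  lam <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(lam) < 1e-2), 6)   # 3 translations + 3 rotations
  expect_equal(sum(lam > 1e-2), 3)        # bend + 2 stretches
  # acoustic sum rule on the unweighted Hessian: rows sum to ~0 per direction
  Hu <- mass_weighted_hessian(rec$config, p, masses = rep(1, 3))
  n <- 3
  for (d in 0:2) {
    cols <- d * n + seq_len(n)
    # finite-difference truncation bounds the residual (h = 1e-5 nm)
    expect_lt(max(abs(rowSums(Hu[, cols]))), 1e-2)
  }
})
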