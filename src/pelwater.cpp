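// Core numerical kernels: q-TIP4P/F energy/forces, ring-polymer potential,
// finite-difference mass-weighted Hessians, and the PILE-thermostatted
// path-integral MD integrator. All quantities in internal units:
// nm, amu, ps, kJ/mol (then amu*nm^2/ps^2 == kJ/mol exactly).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB   = 0.0083144626;   // kJ/mol/K
static const double KE_C = 138.935458;     // Coulomb constant, kJ mol^-1 nm e^-2

struct FFP {
  double D_r, a_r, r_eq, k_th, th_eq;   // intramolecular
  double eps, sig, qH, qM, gam;         // LJ + charges + M-site weight
  double rc, eps_rf;                    // cutoff + reaction-field dielectric
  bool lj_shift, force_shift;
};

static FFP parse_pars(const List& p) {
  FFP f;
  f.D_r   = p["D_r"];    f.a_r   = p["alpha_r"]; f.r_eq = p["r_eq"];
  f.k_th  = p["k_theta"];f.th_eq = p["theta_eq"];
  f.eps   = p["epsilon_LJ"]; f.sig = p["sigma_LJ"];
  f.qH    = p["q_H"];    f.qM    = p["q_M"];     f.gam  = p["gamma_M"];
  f.rc    = p["r_c"];    f.eps_rf = p["eps_rf"];
  f.lj_shift = as<bool>(p["lj_shift"]);
  f.force_shift = as<bool>(p["force_shift"]);
  return f;
}

static inline void minimg(double* d, const double* L, bool per) {
  if (!per) return;
  for (int c = 0; c < 3; ++c) d[c] -= L[c] * std::round(d[c] / L[c]);
}

// Potential energy and forces of one replica. x, f have layout x[i + n*d]
// (atom-major per Cartesian component, i.e. an R matrix n x 3).
// Atoms are ordered O,H,H per molecule. Forces are accumulated into f.
static double eval_replica(const double* x, int n, const FFP& P,
                           bool per, const double* L, double* f) {
  const int M = n / 3;
  double U = 0.0;
  // effective cutoff: minimum image requires rc <= L/2
  double rc = P.rc;
  if (per) {
    double lmin = std::min(L[0], std::min(L[1], L[2]));
    rc = std::min(rc, 0.5 * lmin);
  }
  const double rc2 = rc * rc;
  const double krf = per ? (P.eps_rf - 1.0) / ((2.0 * P.eps_rf + 1.0) * rc2 * rc) : 0.0;
  const double crf = per ? 1.0 / rc + krf * rc2 : 0.0;
  double s2c = P.sig * P.sig / rc2, s6c = s2c * s2c * s2c;
  const double eshift = P.lj_shift ? 4.0 * P.eps * (s6c * s6c - s6c) : 0.0;
  // force-shift terms (C1-continuous cutoff): dV/dr at rc for LJ and for the
  // unit-charge reaction-field pair term
  const double vp_lj = (P.force_shift && P.lj_shift)
    ? -(24.0 * P.eps / rc) * (2.0 * s6c * s6c - s6c) : 0.0;
  const double vp_c = P.force_shift ? (-1.0 / rc2 + 2.0 * krf * rc) : 0.0;

  // site positions (H1,H2,M per molecule) and site force accumulators
  std::vector<double> S(9 * M), FS(9 * M, 0.0);

  for (int m = 0; m < M; ++m) {
    const int o = 3 * m, h1 = o + 1, h2 = o + 2;
    double d1[3], d2[3];
    for (int c = 0; c < 3; ++c) {
      d1[c] = x[h1 + n * c] - x[o + n * c];
      d2[c] = x[h2 + n * c] - x[o + n * c];
    }
    minimg(d1, L, per); minimg(d2, L, per);
    const double r1 = std::sqrt(d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2]);
    const double r2 = std::sqrt(d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2]);
    // NB: no hard bond-length guard here -- the quartic Morse expansion is
    // globally restoring, and minimizer line searches probe far points;
    // topology validation lives at the R level (msite_position, builders).
    // quartic expansion of the Morse bond, V = D a^2 dr^2 (1 - a dr + 7/12 a^2 dr^2)
    const double A = P.a_r, DA2 = P.D_r * A * A;
    for (int b = 0; b < 2; ++b) {
      const double r = b ? r2 : r1;
      const double* dv = b ? d2 : d1;
      const int h = b ? h2 : h1;
      const double dr = r - P.r_eq;
      U += DA2 * dr * dr * (1.0 - A * dr + (7.0 / 12.0) * A * A * dr * dr);
      const double dEdr = DA2 * dr * (2.0 - 3.0 * A * dr + (7.0 / 3.0) * A * A * dr * dr);
      for (int c = 0; c < 3; ++c) {
        const double g = dEdr * dv[c] / r;   // dU/dr_h
        f[h + n * c] -= g;
        f[o + n * c] += g;
      }
    }
    // harmonic HOH angle
    double cth = (d1[0]*d2[0] + d1[1]*d2[1] + d1[2]*d2[2]) / (r1 * r2);
    cth = std::max(-1.0, std::min(1.0, cth));
    const double th = std::acos(cth);
    const double sth = std::max(std::sqrt(1.0 - cth * cth), 1e-8);
    const double dth = th - P.th_eq;
    U += 0.5 * P.k_th * dth * dth;
    const double kd = P.k_th * dth;
    for (int c = 0; c < 3; ++c) {
      const double u1 = d1[c] / r1, u2 = d2[c] / r2;
      const double g1 = kd * (cth * u1 - u2) / (r1 * sth);  // dU/dr_h1
      const double g2 = kd * (cth * u2 - u1) / (r2 * sth);
      f[h1 + n * c] -= g1;
      f[h2 + n * c] -= g2;
      f[o  + n * c] += g1 + g2;
    }
    // charge sites, built relative to O so the molecule stays whole under PBC;
    // M site on the bisector: r_M = r_O + (1-gam)/2 (d1 + d2)
    for (int c = 0; c < 3; ++c) {
      S[9 * m + 0 * 3 + c] = x[o + n * c] + d1[c];              // H1
      S[9 * m + 1 * 3 + c] = x[o + n * c] + d2[c];              // H2
      S[9 * m + 2 * 3 + c] = x[o + n * c] + 0.5 * (1.0 - P.gam) * (d1[c] + d2[c]); // M
    }
  }

  const double qs[3] = { P.qH, P.qH, P.qM };
  // intermolecular pair loop
  for (int mi = 0; mi < M - 1; ++mi) {
    for (int mj = mi + 1; mj < M; ++mj) {
      // Lennard-Jones between oxygens
      double dx[3];
      for (int c = 0; c < 3; ++c) dx[c] = x[3 * mi + n * c] - x[3 * mj + n * c];
      minimg(dx, L, per);
      double r2 = dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
      if (r2 < 1e-12) stop("overlapping atoms (O-O) in molecules %d and %d", mi + 1, mj + 1);
      if (!per || r2 < rc2) {
        const double s2 = P.sig * P.sig / r2;
        const double s6 = s2 * s2 * s2, s12 = s6 * s6;
        const double r = std::sqrt(r2);
        U += 4.0 * P.eps * (s12 - s6);
        double fr = 24.0 * P.eps * (2.0 * s12 - s6) / r;   // -dV/dr
        if (per) {
          U += -eshift - (r - rc) * vp_lj;
          fr += vp_lj;
        }
        const double fmag = fr / r;
        for (int c = 0; c < 3; ++c) {
          f[3 * mi + n * c] += fmag * dx[c];
          f[3 * mj + n * c] -= fmag * dx[c];
        }
      }
      // electrostatics between H/M sites (reaction field when periodic)
      for (int a = 0; a < 3; ++a) {
        for (int b = 0; b < 3; ++b) {
          double ds[3];
          for (int c = 0; c < 3; ++c)
            ds[c] = S[9 * mi + 3 * a + c] - S[9 * mj + 3 * b + c];
          minimg(ds, L, per);
          const double q2 = ds[0]*ds[0] + ds[1]*ds[1] + ds[2]*ds[2];
          if (q2 < 1e-12) stop("overlapping charge sites in molecules %d and %d", mi + 1, mj + 1);
          if (per && q2 >= rc2) continue;
          const double r = std::sqrt(q2);
          const double qq = KE_C * qs[a] * qs[b];
          double fr;
          if (per) {
            U += qq * (1.0 / r + krf * q2 - crf - (r - rc) * vp_c);
            fr = qq * (1.0 / q2 - 2.0 * krf * r + vp_c) / r;
          } else {
            U += qq / r;
            fr = qq / (q2 * r);
          }
          for (int c = 0; c < 3; ++c) {
            FS[9 * mi + 3 * a + c] += fr * ds[c];
            FS[9 * mj + 3 * b + c] -= fr * ds[c];
          }
        }
      }
    }
  }
  // redistribute site forces onto real atoms (chain rule of the M site)
  for (int m = 0; m < M; ++m) {
    const int o = 3 * m, h1 = o + 1, h2 = o + 2;
    const double w = 0.5 * (1.0 - P.gam);
    for (int c = 0; c < 3; ++c) {
      const double fH1 = FS[9 * m + 0 * 3 + c];
      const double fH2 = FS[9 * m + 1 * 3 + c];
      const double fM  = FS[9 * m + 2 * 3 + c];
      f[h1 + n * c] += fH1 + w * fM;
      f[h2 + n * c] += fH2 + w * fM;
      f[o  + n * c] += P.gam * fM;
    }
  }
  return U;
}

// [[Rcpp::export]]
List cpp_ff_eval(NumericMatrix pos, NumericVector box, List pars) {
  const int n = pos.nrow();
  if (n % 3 != 0) stop("number of atoms must be a multiple of 3 (O,H,H per molecule)");
  const bool per = box.size() == 3;
  FFP P = parse_pars(pars);
  NumericMatrix f(n, 3);
  const double U = eval_replica(REAL(pos), n, P, per, per ? REAL(box) : nullptr, REAL(f));
  return List::create(_["energy"] = U, _["forces"] = f);
}

// Mass-weighted Hessian by central finite differences of analytic forces.
// invsqrt_m has length 3n and holds 1/sqrt(m_i) for each coordinate.
// [[Rcpp::export]]
NumericMatrix cpp_hessian(NumericMatrix pos, NumericVector box, List pars,
                          double h, NumericVector invsqrt_m) {
  const int n = pos.nrow(), d = 3 * n;
  const bool per = box.size() == 3;
  FFP P = parse_pars(pars);
  const double* L = per ? REAL(box) : nullptr;
  std::vector<double> x(REAL(pos), REAL(pos) + d);
  std::vector<double> fp(d), fm(d);
  NumericMatrix H(d, d);
  for (int j = 0; j < d; ++j) {
    const double x0 = x[j];
    std::fill(fp.begin(), fp.end(), 0.0);
    x[j] = x0 + h;
    eval_replica(x.data(), n, P, per, L, fp.data());
    std::fill(fm.begin(), fm.end(), 0.0);
    x[j] = x0 - h;
    eval_replica(x.data(), n, P, per, L, fm.data());
    x[j] = x0;
    for (int i = 0; i < d; ++i) {
      const double hij = -(fp[i] - fm[i]) / (2.0 * h);  // d2U/dxi dxj
      if (!std::isfinite(hij)) stop("non-finite Hessian entry");
      H(i, j) = hij * invsqrt_m[i] * invsqrt_m[j];
    }
  }
  for (int i = 0; i < d; ++i)          // symmetrize
    for (int j = 0; j < i; ++j) {
      const double s = 0.5 * (H(i, j) + H(j, i));
      H(i, j) = s; H(j, i) = s;
    }
  return H;
}

// Ring-polymer potential (springs + replica average) and its gradient.
// X layout: X[i + n*c + 3n*k] for atom i, component c, bead k.
// [[Rcpp::export]]
List cpp_rp_eval(NumericVector X, int n, int nb, NumericVector box, List pars,
                 NumericVector ksp, bool want_grad = true) {
  const bool per = box.size() == 3;
  FFP P = parse_pars(pars);
  const double* L = per ? REAL(box) : nullptr;
  const int d = 3 * n;
  NumericVector grad(want_grad ? d * nb : 0);
  std::vector<double> frep(d);
  NumericVector Uk(nb);
  double Uphys = 0.0;
  for (int k = 0; k < nb; ++k) {
    std::fill(frep.begin(), frep.end(), 0.0);
    Uk[k] = eval_replica(REAL(X) + d * k, n, P, per, L, frep.data());
    Uphys += Uk[k];
    if (want_grad)
      for (int i = 0; i < d; ++i) grad[d * k + i] = -frep[i] / nb;
  }
  Uphys /= nb;
  double Uspr = 0.0;
  if (nb > 1) {
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < nb; ++k) {
        const int k1 = (k + 1) % nb;
        double s2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          const double dd = X[i + n * c + d * k1] - X[i + n * c + d * k];
          s2 += dd * dd;
          if (want_grad) {
            grad[i + n * c + d * k]  -= ksp[i] * dd;
            grad[i + n * c + d * k1] += ksp[i] * dd;
          }
        }
        Uspr += 0.5 * ksp[i] * s2;
      }
    }
  }
  return List::create(_["energy"] = Uspr + Uphys, _["gradient"] = grad,
                      _["U_k"] = Uk, _["spring_energy"] = Uspr);
}

// Full mass-weighted Hessian of the ring-polymer potential by central
// differences of the analytic RP gradient (fictitious masses nb*m).
// [[Rcpp::export]]
NumericMatrix cpp_rp_hessian(NumericVector X, int n, int nb, NumericVector box,
                             List pars, NumericVector ksp, double h,
                             NumericVector invsqrt_m) {
  const int D = 3 * n * nb;
  NumericVector x = clone(X);
  NumericMatrix H(D, D);
  for (int j = 0; j < D; ++j) {
    const double x0 = x[j];
    x[j] = x0 + h;
    List ep = cpp_rp_eval(x, n, nb, box, pars, ksp, true);
    NumericVector gp = ep["gradient"];
    x[j] = x0 - h;
    List em = cpp_rp_eval(x, n, nb, box, pars, ksp, true);
    NumericVector gm = em["gradient"];
    x[j] = x0;
    for (int i = 0; i < D; ++i) {
      const double hij = (gp[i] - gm[i]) / (2.0 * h);
      if (!std::isfinite(hij)) stop("non-finite Hessian entry");
      H(i, j) = hij * invsqrt_m[i] * invsqrt_m[j];
    }
  }
  for (int i = 0; i < D; ++i)
    for (int j = 0; j < i; ++j) {
      const double s = 0.5 * (H(i, j) + H(j, i));
      H(i, j) = s; H(j, i) = s;
    }
  return H;
}

// PILE-thermostatted path-integral MD (velocity Verlet with exact free
// ring-polymer normal-mode drift; OBABO splitting). Classical MD is nb = 1.
// Cmat columns are orthonormal ring-polymer normal modes (column 0 = centroid),
// omegak the corresponding free-RP angular frequencies with fictitious masses.
// Noise draws use the R RNG in the fixed order (atom, component, mode).
// [[Rcpp::export]]
List cpp_run_pile(NumericVector X0, NumericVector P0, int nb, NumericVector box,
                  List pars, NumericVector mass_fict, NumericVector ksp,
                  NumericMatrix Cmat, NumericVector omegak,
                  double dt, double temperature, double gamma0,
                  int nsteps, int save_every, bool thermostat,
                  double external_k = -1.0) {
  // external_k >= 0 replaces the water potential by an isotropic harmonic
  // well U = k/2 sum r^2 per replica (k = 0: free ring polymer) -- used to
  // validate the integrator against closed-form quantum oscillators.
  const int n = mass_fict.size(), d = 3 * n, D = d * nb;
  const bool per = box.size() == 3;
  FFP P = parse_pars(pars);
  const double* L = per ? REAL(box) : nullptr;
  const double kBT = KB * temperature;

  std::vector<double> X(REAL(X0), REAL(X0) + D), Pm(REAL(P0), REAL(P0) + D);
  std::vector<double> F(D), frep(d), Uk(nb), q(nb), p(nb);
  std::vector<double> c1(nb), c2(nb), cw(nb), sw(nb);
  for (int k = 0; k < nb; ++k) {
    const double g = (k == 0) ? gamma0 : 2.0 * omegak[k];
    c1[k] = std::exp(-0.5 * g * dt);
    c2[k] = std::sqrt(std::max(0.0, 1.0 - c1[k] * c1[k]));
    cw[k] = std::cos(omegak[k] * dt);
    sw[k] = std::sin(omegak[k] * dt);
  }

  auto ou_half = [&](void) {
    for (int i = 0; i < n; ++i) {
      const double sq = std::sqrt(mass_fict[i] * kBT);
      for (int c = 0; c < 3; ++c) {
        for (int k = 0; k < nb; ++k) {
          double s = 0.0;
          for (int j = 0; j < nb; ++j) s += Cmat(j, k) * Pm[i + n * c + d * j];
          p[k] = s;
        }
        for (int k = 0; k < nb; ++k)
          p[k] = c1[k] * p[k] + c2[k] * sq * R::norm_rand();
        for (int j = 0; j < nb; ++j) {
          double s = 0.0;
          for (int k = 0; k < nb; ++k) s += Cmat(j, k) * p[k];
          Pm[i + n * c + d * j] = s;
        }
      }
    }
  };

  auto drift = [&](void) {
    for (int i = 0; i < n; ++i) {
      const double m = mass_fict[i];
      for (int c = 0; c < 3; ++c) {
        for (int k = 0; k < nb; ++k) {
          double sx = 0.0, sp = 0.0;
          for (int j = 0; j < nb; ++j) {
            sx += Cmat(j, k) * X[i + n * c + d * j];
            sp += Cmat(j, k) * Pm[i + n * c + d * j];
          }
          q[k] = sx; p[k] = sp;
        }
        for (int k = 0; k < nb; ++k) {
          if (omegak[k] <= 0.0) {
            q[k] += p[k] / m * dt;
          } else {
            const double qn = q[k] * cw[k] + p[k] / (m * omegak[k]) * sw[k];
            const double pn = -m * omegak[k] * q[k] * sw[k] + p[k] * cw[k];
            q[k] = qn; p[k] = pn;
          }
        }
        for (int j = 0; j < nb; ++j) {
          double sx = 0.0, sp = 0.0;
          for (int k = 0; k < nb; ++k) {
            sx += Cmat(j, k) * q[k];
            sp += Cmat(j, k) * p[k];
          }
          X[i + n * c + d * j] = sx;
          Pm[i + n * c + d * j] = sp;
        }
      }
    }
  };

  // springs are integrated exactly in normal modes, so the B sub-step kick
  // uses only the physical (replica) forces; replica forces are also kept
  // unscaled for centroid-virial logging
  std::vector<double> frep_all(D);
  auto phys_forces_full = [&](void) {
    for (int k = 0; k < nb; ++k) {
      std::fill(frep.begin(), frep.end(), 0.0);
      if (external_k >= 0.0) {
        double u = 0.0;
        for (int i = 0; i < d; ++i) {
          const double xx = X[d * k + i];
          u += 0.5 * external_k * xx * xx;
          frep[i] = -external_k * xx;
        }
        Uk[k] = u;
      } else {
        Uk[k] = eval_replica(X.data() + d * k, n, P, per, L, frep.data());
      }
      for (int i = 0; i < d; ++i) {
        F[d * k + i] = frep[i] / nb;
        frep_all[d * k + i] = frep[i];
      }
    }
  };

  const int nframes = save_every > 0 ? nsteps / save_every : 0;
  List frames(nframes);
  NumericMatrix logm(nframes, 7);
  colnames(logm) = CharacterVector::create("step", "time_ps", "T_inst",
                                           "U_spring", "U_phys", "U_rp", "virial");
  int iframe = 0;

  phys_forces_full();
  for (int s = 0; s < nsteps; ++s) {
    if (thermostat) ou_half();
    for (int i = 0; i < D; ++i) Pm[i] += 0.5 * dt * F[i];
    drift();
    phys_forces_full();
    for (int i = 0; i < D; ++i) Pm[i] += 0.5 * dt * F[i];
    if (thermostat) ou_half();

    if (save_every > 0 && (s + 1) % save_every == 0 && iframe < nframes) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          for (int k = 0; k < nb; ++k) {
            const double pp = Pm[i + n * c + d * k];
            ke += pp * pp / (2.0 * mass_fict[i]);
          }
      double uspr = 0.0;
      if (nb > 1)
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < nb; ++k) {
            const int k1 = (k + 1) % nb;
            double s2 = 0.0;
            for (int c = 0; c < 3; ++c) {
              const double dd = X[i + n * c + d * k1] - X[i + n * c + d * k];
              s2 += dd * dd;
            }
            uspr += 0.5 * ksp[i] * s2;
          }
      double uphys = 0.0;
      for (int k = 0; k < nb; ++k) uphys += Uk[k];
      uphys /= nb;
      double W = 0.0;   // centroid-virial term
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) {
          double cen = 0.0;
          for (int k = 0; k < nb; ++k) cen += X[i + n * c + d * k];
          cen /= nb;
          for (int k = 0; k < nb; ++k)
            W -= (X[i + n * c + d * k] - cen) * frep_all[i + n * c + d * k];
        }
      W /= 2.0 * nb;
      logm(iframe, 0) = s + 1;
      logm(iframe, 1) = (s + 1) * dt;
      logm(iframe, 2) = 2.0 * ke / (3.0 * n * nb * KB);
      logm(iframe, 3) = uspr;
      logm(iframe, 4) = uphys;
      logm(iframe, 5) = uspr + uphys;
      logm(iframe, 6) = W;
      frames[iframe] = NumericVector(X.begin(), X.end());
      ++iframe;
    }
  }
  return List::create(_["X"] = NumericVector(X.begin(), X.end()),
                      _["P"] = NumericVector(Pm.begin(), Pm.end()),
                      _["frames"] = frames, _["log"] = logm);
}
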