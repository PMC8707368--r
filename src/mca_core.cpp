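// Bonded-particle (movable cellular automaton) core: many-body elastic pair
// interactions with Biot pore-pressure coupling and Darcy exchange, explicit
// velocity-Verlet integration. All quantities SI, tension-positive stresses.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Find bonded pairs within `cutoff` using a cell list. Positions in meters.
// Returns 0-based pair indices and center distances.
// [[Rcpp::export]]
List find_bonds_cpp(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  double xmin = R_PosInf, ymin = R_PosInf, zmin = R_PosInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, pos(i, 0));
    ymin = std::min(ymin, pos(i, 1));
    zmin = std::min(zmin, pos(i, 2));
  }
  const double h = cutoff * 1.0000001;
  int nx = 1, ny = 1, nz = 1;
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor((pos(i, 0) - xmin) / h);
    cy[i] = (int)std::floor((pos(i, 1) - ymin) / h);
    cz[i] = (int)std::floor((pos(i, 2) - zmin) / h);
    nx = std::max(nx, cx[i] + 1);
    ny = std::max(ny, cy[i] + 1);
    nz = std::max(nz, cz[i] + 1);
  }
  std::vector<std::vector<int> > cells((size_t)nx * ny * nz);
  for (int i = 0; i < n; ++i)
    cells[(size_t)(cz[i] * ny + cy[i]) * nx + cx[i]].push_back(i);
  std::vector<int> bi, bj;
  std::vector<double> br;
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    for (int dz = -1; dz <= 1; ++dz) {
      int z = cz[i] + dz; if (z < 0 || z >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cy[i] + dy; if (y < 0 || y >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int x = cx[i] + dx; if (x < 0 || x >= nx) continue;
          const std::vector<int>& cell = cells[(size_t)(z * ny + y) * nx + x];
          for (size_t k = 0; k < cell.size(); ++k) {
            int j = cell[k];
            if (j <= i) continue;
            double ddx = pos(j, 0) - pos(i, 0);
            double ddy = pos(j, 1) - pos(i, 1);
            double ddz = pos(j, 2) - pos(i, 2);
            double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (r2 < c2) {
              bi.push_back(i); bj.push_back(j); br.push_back(std::sqrt(r2));
            }
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(bi), _["j"] = wrap(bj), _["r0"] = wrap(br));
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Full explicit run. See R wrapper simulate_mca() for argument semantics.
// [[Rcpp::export]]
List mca_run_cpp(NumericMatrix pos0, NumericMatrix vel0, IntegerVector mat_id,
                 double d, IntegerMatrix bonds, NumericVector r0,
                 NumericVector Sarea, List mats, double mu, double dt,
                 int nsteps, double damp, IntegerVector fixed_idx, List driven,
                 bool confine_lateral, bool poro_on, IntegerVector drained_idx,
                 List ext_force, int monitor_every, IntegerVector probe_idx,
                 bool track_max, int n_sub, double surface_comp) {
  const int n = pos0.nrow();
  const int m = bonds.nrow();
  const double V = d * d * d / std::sqrt(2.0);  // FCC Voronoi-cell volume

  NumericVector mG = mats["G"], mK = mats["K"], mrho = mats["rho"],
                malpha = mats["alpha"], mM = mats["M"], mkp = mats["k"];
  LogicalVector mporo = mats["poroelastic"];

  std::vector<double> x(3 * n), v(3 * n), w(3 * n, 0.0), f(3 * n), tq(3 * n),
      acc(3 * n, 0.0), aw(3 * n, 0.0), s6(6 * n, 0.0), epsv(n, 0.0),
      epsv_prev(n, 0.0), p(n, 0.0), zeta(n, 0.0), dz(n, 0.0), eeq(n, 0.0),
      mass(n), inert(n), wsum_qS(n, 0.0), veff(n, V);
  std::vector<double> mxp(n, 0.0), mxpf(n, 0.0), mxe(n, 0.0);  // temporal maxima
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) { x[3 * i + c] = pos0(i, c); v[3 * i + c] = vel0(i, c); }
    int mi = mat_id[i];
    mass[i] = mrho[mi] * V;
    inert[i] = 0.4 * mass[i] * (d / 2.0) * (d / 2.0);
  }

  // constraint bookkeeping: 0 free, 1 fixed, 2+k driven set k
  std::vector<int> ctype(n, 0);
  for (int k = 0; k < fixed_idx.size(); ++k) ctype[fixed_idx[k]] = 1;
  const int nsets = driven.size();
  std::vector<std::vector<int> > set_idx(nsets);
  std::vector<std::vector<double> > set_vel(nsets);
  std::vector<double> set_dir(3 * nsets);
  for (int k = 0; k < nsets; ++k) {
    List st = driven[k];
    IntegerVector ii = st["idx"];
    NumericVector dir = st["dir"], vv = st["vel"];
    set_idx[k].assign(ii.begin(), ii.end());
    set_vel[k].assign(vv.begin(), vv.end());
    for (int c = 0; c < 3; ++c) set_dir[3 * k + c] = dir[c];
    for (size_t q = 0; q < set_idx[k].size(); ++q) ctype[set_idx[k][q]] = 2 + k;
  }
  std::vector<bool> drained(n, false);
  for (int k = 0; k < drained_idx.size(); ++k) drained[drained_idx[k]] = true;

  bool has_ext = ext_force.size() > 0;
  std::vector<int> ext_idx;
  std::vector<double> ext_vec(3, 0.0), ext_scale;
  if (has_ext) {
    IntegerVector ii = ext_force["idx"];
    NumericVector fv = ext_force["fvec"], sc = ext_force["scale"];
    ext_idx.assign(ii.begin(), ii.end());
    for (int c = 0; c < 3; ++c) ext_vec[c] = fv[c];
    ext_scale.assign(sc.begin(), sc.end());
  }

  // per-bond persistent shear strain vector
  std::vector<double> gam(3 * m, 0.0);
  std::vector<int> b_i(m), b_j(m);
  for (int k = 0; k < m; ++k) { b_i[k] = bonds(k, 0); b_j[k] = bonds(k, 1); }

  // monitor storage
  const int nmon = nsteps / monitor_every + 2;
  std::vector<double> mon_t, mon_ke, mon_pe, mon_zeta;
  std::vector<std::vector<double> > mon_F(nsets * 3), mon_u(nsets);
  const int npr = probe_idx.size();
  std::vector<std::vector<double> > pr_pf(npr), pr_ph(npr), pr_szz(npr), pr_eeq(npr);
  mon_t.reserve(nmon);

  std::vector<double> x0(3 * n);
  std::copy(x.begin(), x.end(), x0.begin());

  // scratch per bond (filled in pass A, reused in pass B)
  std::vector<double> sc_n(3 * m), sc_eps(m), sc_r(m);

  double t_now = 0.0;

  // ---- force evaluation ----
  auto forces = [&](int step) {
    std::fill(f.begin(), f.end(), 0.0);
    std::fill(tq.begin(), tq.end(), 0.0);
    std::fill(s6.begin(), s6.end(), 0.0);
    std::fill(epsv.begin(), epsv.end(), 0.0);
    std::fill(wsum_qS.begin(), wsum_qS.end(), 0.0);

    // pass A: geometry, shear accumulation, volumetric strain
    for (int k = 0; k < m; ++k) {
      const int i = b_i[k], j = b_j[k];
      double rv[3];
      for (int c = 0; c < 3; ++c) rv[c] = x[3 * j + c] - x[3 * i + c];
      double r = std::sqrt(rv[0] * rv[0] + rv[1] * rv[1] + rv[2] * rv[2]);
      double nrm[3] = { rv[0] / r, rv[1] / r, rv[2] / r };
      double eps_n = (r - r0[k]) / r0[k];
      sc_r[k] = r; sc_eps[k] = eps_n;
      for (int c = 0; c < 3; ++c) sc_n[3 * k + c] = nrm[c];
      // relative tangential velocity at the contact (includes rotations)
      double q = 0.5 * r;
      double wsum[3] = { w[3 * i] + w[3 * j], w[3 * i + 1] + w[3 * j + 1],
                         w[3 * i + 2] + w[3 * j + 2] };
      double wxn[3];
      cross3(wsum, nrm, wxn);
      double vrel[3], vdotn = 0.0;
      for (int c = 0; c < 3; ++c) {
        vrel[c] = v[3 * j + c] - v[3 * i + c] - q * wxn[c];
        vdotn += vrel[c] * nrm[c];
      }
      double* g = &gam[3 * k];
      double gdotn = 0.0;
      for (int c = 0; c < 3; ++c) {
        g[c] += (vrel[c] - vdotn * nrm[c]) * dt / r0[k];
      }
      for (int c = 0; c < 3; ++c) gdotn += g[c] * nrm[c];
      for (int c = 0; c < 3; ++c) g[c] -= gdotn * nrm[c];
      // per-side strain split by shear-stiffness weights; volumetric strain
      const double Gi = mG[mat_id[i]], Gj = mG[mat_id[j]];
      const double ei = 2.0 * Gj / (Gi + Gj) * eps_n;
      const double ej = 2.0 * Gi / (Gi + Gj) * eps_n;
      const double qS = q * Sarea[k];
      epsv[i] += qS * ei;
      epsv[j] += qS * ej;
      wsum_qS[i] += qS;
      wsum_qS[j] += qS;
    }
    // Truncated-Voronoi effective volume V_eff = (1/3) sum(qS): equal to V
    // for a fully coordinated automaton, smaller at free surfaces. Using it
    // to normalise eps_vol, the stress homogenisation and the fluid storage
    // keeps surface automata consistent (otherwise missing contacts soften
    // the many-body term and dilute surface stress and pore diffusivity).
    for (int i = 0; i < n; ++i) {
      veff[i] = wsum_qS[i] > 0 ? wsum_qS[i] / 3.0 : V;
      epsv[i] = wsum_qS[i] > 0 ? 3.0 * epsv[i] / wsum_qS[i] : 0.0;
    }

    // poro update: Darcy exchange + storage law, substepped so the explicit
    // pore-pressure diffusion stays stable at the mechanical time step
    if (poro_on) {
      const double dt_f = dt / n_sub;
      for (int sub = 0; sub < n_sub; ++sub) {
        std::fill(dz.begin(), dz.end(), 0.0);
        for (int k = 0; k < m; ++k) {
          const int i = b_i[k], j = b_j[k];
          const int mi = mat_id[i], mj = mat_id[j];
          if (!mporo[mi] || !mporo[mj]) continue;
          double kh = 2.0 * mkp[mi] * mkp[mj] / (mkp[mi] + mkp[mj]);
          double Q = kh * Sarea[k] * (p[i] - p[j]) / (mu * sc_r[k]);
          dz[i] -= Q * dt_f / veff[i];
          dz[j] += Q * dt_f / veff[j];
        }
        for (int i = 0; i < n; ++i) {
          const int mi = mat_id[i];
          if (!mporo[mi]) continue;
          double de = (epsv[i] - epsv_prev[i]) / n_sub;
          p[i] += mM[mi] * (dz[i] - malpha[mi] * de);
          zeta[i] += dz[i];
          if (drained[i]) p[i] = 0.0;
        }
      }
    }
    std::copy(epsv.begin(), epsv.end(), epsv_prev.begin());

    // pass B: tractions, forces, torques, averaged stress
    for (int k = 0; k < m; ++k) {
      const int i = b_i[k], j = b_j[k];
      const int mi = mat_id[i], mj = mat_id[j];
      const double Gi = mG[mi], Gj = mG[mj];
      const double lam_i = mK[mi] - 2.0 * Gi / 3.0;
      const double lam_j = mK[mj] - 2.0 * Gj / 3.0;
      const double Li = lam_i * epsv[i] - (mporo[mi] ? malpha[mi] * p[i] : 0.0);
      const double Lj = lam_j * epsv[j] - (mporo[mj] ? malpha[mj] * p[j] : 0.0);
      const double eps_n = sc_eps[k];
      const double ei = (4.0 * Gj * eps_n + Lj - Li) / (2.0 * (Gi + Gj));
      const double sig_n = 2.0 * Gi * ei + Li;
      const double Gh = 2.0 * Gi * Gj / (Gi + Gj);
      const double* nrm = &sc_n[3 * k];
      const double* g = &gam[3 * k];
      // surface compensation: automata with missing contacts (V_eff < V)
      // carry the lost load share on their remaining bonds, so a free
      // surface is not artificially compliant
      const double boost = 1.0 + surface_comp *
          (0.5 * (V / veff[i] + V / veff[j]) - 1.0);
      double tvec[3], fk[3];
      for (int c = 0; c < 3; ++c) {
        tvec[c] = boost * (sig_n * nrm[c] + 2.0 * Gh * g[c]);
        fk[c] = Sarea[k] * tvec[c];
        f[3 * i + c] += fk[c];
        f[3 * j + c] -= fk[c];
      }
      const double q = 0.5 * sc_r[k];
      double ntau[3];
      double tau[3] = { 2.0 * Gh * g[0], 2.0 * Gh * g[1], 2.0 * Gh * g[2] };
      cross3(nrm, tau, ntau);
      for (int c = 0; c < 3; ++c) {
        tq[3 * i + c] += q * Sarea[k] * ntau[c];
        tq[3 * j + c] += q * Sarea[k] * ntau[c];
      }
      for (int pp = 0; pp < 2; ++pp) {
        const int ii = pp == 0 ? i : j;
        const double coef = q * Sarea[k] / veff[ii];
        double* s = &s6[6 * ii];
        s[0] += coef * nrm[0] * tvec[0];
        s[1] += coef * nrm[1] * tvec[1];
        s[2] += coef * nrm[2] * tvec[2];
        s[3] += coef * 0.5 * (nrm[0] * tvec[1] + nrm[1] * tvec[0]);
        s[4] += coef * 0.5 * (nrm[0] * tvec[2] + nrm[2] * tvec[0]);
        s[5] += coef * 0.5 * (nrm[1] * tvec[2] + nrm[2] * tvec[1]);
      }
    }

    if (has_ext) {
      const double sc = ext_scale[std::min<int>(step, (int)ext_scale.size() - 1)];
      for (size_t k = 0; k < ext_idx.size(); ++k)
        for (int c = 0; c < 3; ++c) f[3 * ext_idx[k] + c] += sc * ext_vec[c];
    }

    // equivalent (von Mises) strain from the stress deviator (pore pressure is
    // hydrostatic, so the deviator needs no effective-stress correction)
    for (int i = 0; i < n; ++i) {
      const double* s = &s6[6 * i];
      const double tr3 = (s[0] + s[1] + s[2]) / 3.0;
      const double twoG = 2.0 * mG[mat_id[i]];
      const double exx = (s[0] - tr3) / twoG, eyy = (s[1] - tr3) / twoG,
                   ezz = (s[2] - tr3) / twoG, exy = s[3] / twoG,
                   exz = s[4] / twoG, eyz = s[5] / twoG;
      eeq[i] = std::sqrt(2.0 / 3.0 *
          (exx * exx + eyy * eyy + ezz * ezz +
           2.0 * (exy * exy + exz * exz + eyz * eyz)));
      if (track_max) {
        const double ph = -tr3;
        if (ph > mxp[i]) mxp[i] = ph;
        if (p[i] > mxpf[i]) mxpf[i] = p[i];
        if (eeq[i] > mxe[i]) mxe[i] = eeq[i];
      }
    }
  };

  auto apply_constraints = [&](int step) {
    for (int k = 0; k < fixed_idx.size(); ++k) {
      int i = fixed_idx[k];
      for (int c = 0; c < 3; ++c) { v[3 * i + c] = 0.0; w[3 * i + c] = 0.0; }
    }
    for (int k = 0; k < nsets; ++k) {
      double vk = set_vel[k][std::min<int>(step, (int)set_vel[k].size() - 1)];
      for (size_t q = 0; q < set_idx[k].size(); ++q) {
        int i = set_idx[k][q];
        for (int c = 0; c < 3; ++c) {
          v[3 * i + c] = vk * set_dir[3 * k + c];
          w[3 * i + c] = 0.0;
        }
      }
    }
    if (confine_lateral)
      for (int i = 0; i < n; ++i) { v[3 * i] = 0.0; v[3 * i + 1] = 0.0; }
  };

  auto record = [&](int step) {
    double ke = 0.0, pe = 0.0, ztot = 0.0;
    for (int i = 0; i < n; ++i) {
      double v2 = 0.0, w2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        v2 += v[3 * i + c] * v[3 * i + c];
        w2 += w[3 * i + c] * w[3 * i + c];
      }
      ke += 0.5 * mass[i] * v2 + 0.5 * inert[i] * w2;
      const int mi = mat_id[i];
      const double* s = &s6[6 * i];
      double ap = mporo[mi] ? malpha[mi] * p[i] : 0.0;
      // skeleton energy from effective stress, inverse isotropic Hooke
      double seff[6] = { s[0] + ap, s[1] + ap, s[2] + ap, s[3], s[4], s[5] };
      double mtr = (seff[0] + seff[1] + seff[2]) / 3.0;
      double evol = 3.0 * mtr / (3.0 * mK[mi]);
      double twoG = 2.0 * mG[mi];
      double dev2 = 0.0;
      double dd[6] = { seff[0] - mtr, seff[1] - mtr, seff[2] - mtr,
                       seff[3], seff[4], seff[5] };
      dev2 = dd[0] * dd[0] + dd[1] * dd[1] + dd[2] * dd[2] +
             2.0 * (dd[3] * dd[3] + dd[4] * dd[4] + dd[5] * dd[5]);
      pe += veff[i] * (0.5 * dev2 / twoG + 0.5 * mtr * evol);
      if (poro_on && mporo[mi]) {
        pe += veff[i] * 0.5 * p[i] * p[i] / mM[mi];
        ztot += zeta[i] * veff[i];
      }
      if (!std::isfinite(x[3 * i]))
        stop("NaN/Inf detected at step %d (particle %d); reduce dt or loading rate",
             step, i + 1);
    }
    mon_t.push_back(t_now);
    mon_ke.push_back(ke);
    mon_pe.push_back(pe);
    mon_zeta.push_back(ztot);
    for (int k = 0; k < nsets; ++k) {
      double F[3] = {0, 0, 0}, u = 0.0;
      for (size_t q = 0; q < set_idx[k].size(); ++q) {
        int i = set_idx[k][q];
        for (int c = 0; c < 3; ++c) F[c] += f[3 * i + c];
        for (int c = 0; c < 3; ++c)
          u += (x[3 * i + c] - x0[3 * i + c]) * set_dir[3 * k + c];
      }
      u /= (double)set_idx[k].size();
      for (int c = 0; c < 3; ++c) mon_F[3 * k + c].push_back(F[c]);
      mon_u[k].push_back(u);
    }
    for (int k = 0; k < npr; ++k) {
      int i = probe_idx[k];
      const double* s = &s6[6 * i];
      pr_pf[k].push_back(p[i]);
      pr_ph[k].push_back(-(s[0] + s[1] + s[2]) / 3.0);
      pr_szz[k].push_back(s[2]);
      pr_eeq[k].push_back(eeq[i]);
    }
  };

  apply_constraints(0);
  forces(0);
  for (int i = 0; i < n; ++i) {
    if (ctype[i] != 0) continue;
    for (int c = 0; c < 3; ++c) {
      acc[3 * i + c] = f[3 * i + c] / mass[i] - damp * v[3 * i + c];
      aw[3 * i + c] = tq[3 * i + c] / inert[i] - damp * w[3 * i + c];
    }
  }
  record(0);

  for (int step = 0; step < nsteps; ++step) {
    apply_constraints(step);
    for (int i = 0; i < n; ++i) {
      if (ctype[i] == 0) {
        for (int c = 0; c < 3; ++c) {
          v[3 * i + c] += 0.5 * dt * acc[3 * i + c];
          w[3 * i + c] += 0.5 * dt * aw[3 * i + c];
        }
        if (confine_lateral) { v[3 * i] = 0.0; v[3 * i + 1] = 0.0; }
      }
      for (int c = 0; c < 3; ++c) x[3 * i + c] += dt * v[3 * i + c];
    }
    t_now += dt;
    forces(step);
    for (int i = 0; i < n; ++i) {
      if (ctype[i] != 0) continue;
      for (int c = 0; c < 3; ++c) {
        double a_new = f[3 * i + c] / mass[i] - damp * v[3 * i + c];
        double aw_new = tq[3 * i + c] / inert[i] - damp * w[3 * i + c];
        v[3 * i + c] += 0.5 * dt * a_new;
        w[3 * i + c] += 0.5 * dt * aw_new;
        acc[3 * i + c] = a_new;
        aw[3 * i + c] = aw_new;
      }
      if (confine_lateral) { v[3 * i] = 0.0; v[3 * i + 1] = 0.0; }
    }
    if ((step + 1) % monitor_every == 0 || step == nsteps - 1) record(step);
  }

  NumericMatrix posf(n, 3), velf(n, 3), sig(n, 6);
  NumericVector pv(n), epsvv(n), eeqv(n), zetav(n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) { posf(i, c) = x[3 * i + c]; velf(i, c) = v[3 * i + c]; }
    for (int c = 0; c < 6; ++c) sig(i, c) = s6[6 * i + c];
    pv[i] = p[i]; epsvv[i] = epsv[i]; eeqv[i] = eeq[i]; zetav[i] = zeta[i];
  }
  List mon = List::create(_["t"] = wrap(mon_t), _["ke"] = wrap(mon_ke),
                          _["pe"] = wrap(mon_pe), _["zeta_total"] = wrap(mon_zeta));
  List Fsets(nsets), usets(nsets);
  for (int k = 0; k < nsets; ++k) {
    Fsets[k] = NumericMatrix(mon_t.size(), 3);
    NumericMatrix Fk = Fsets[k];
    for (size_t r = 0; r < mon_t.size(); ++r)
      for (int c = 0; c < 3; ++c) Fk(r, c) = mon_F[3 * k + c][r];
    usets[k] = wrap(mon_u[k]);
  }
  List probes = List::create(
      _["p_fluid"] = wrap(pr_pf), _["p_hydro"] = wrap(pr_ph),
      _["s_zz"] = wrap(pr_szz), _["eps_eq"] = wrap(pr_eeq));
  NumericMatrix mx(n, 3);
  for (int i = 0; i < n; ++i) { mx(i, 0) = mxp[i]; mx(i, 1) = mxpf[i]; mx(i, 2) = mxe[i]; }
  return List::create(
      _["pos"] = posf, _["vel"] = velf, _["sigma"] = sig, _["p"] = pv,
      _["eps_vol"] = epsvv, _["eps_eq"] = eeqv, _["zeta"] = zetav,
      _["monitor"] = mon, _["set_force"] = Fsets, _["set_disp"] = usets,
      _["probes"] = probes, _["maxima"] = mx);
}
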