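// Axisymmetric large-deformation u-p poroelastic finite-element core for the
// fibril-reinforced poroelastic (FRPE) cartilage model.
//
// Units: mm - N - s - MPa; permeability mm^4 N^-1 s^-1.
// Element: 4-node bilinear quad, equal-order displacement / pore pressure
// (CAX4P class), 2x2 Gauss quadrature, updated-coordinate kinematics with
// backward-Euler time integration.  Element Jacobians by central finite
// differences (the tension-only fibril law and strain-dependent permeability
// make the analytic tangent piecewise; FD keeps the residual the single
// source of truth).  The element kernel is written in plain scalar C for
// speed: it sits inside a triple loop (time step x Newton x FD column).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double TWOPI = 6.283185307179586476925286766559;
static const double GPC = 0.57735026918962576450914878050196;
static const double gp_xi[4]  = {-GPC,  GPC, GPC, -GPC};
static const double gp_eta[4] = {-GPC, -GPC, GPC,  GPC};

// shape values/derivatives at the 4 Gauss points (weights all 1)
struct GPTab { double N[4]; double dN[4][2]; };
static GPTab g_tab[4];
static bool g_tab_init = false;
static void init_gp_tab() {
  if (g_tab_init) return;
  for (int g = 0; g < 4; ++g) {
    double xi = gp_xi[g], eta = gp_eta[g];
    g_tab[g].N[0] = 0.25 * (1 - xi) * (1 - eta);
    g_tab[g].N[1] = 0.25 * (1 + xi) * (1 - eta);
    g_tab[g].N[2] = 0.25 * (1 + xi) * (1 + eta);
    g_tab[g].N[3] = 0.25 * (1 - xi) * (1 + eta);
    g_tab[g].dN[0][0] = -0.25 * (1 - eta); g_tab[g].dN[0][1] = -0.25 * (1 - xi);
    g_tab[g].dN[1][0] =  0.25 * (1 - eta); g_tab[g].dN[1][1] = -0.25 * (1 + xi);
    g_tab[g].dN[2][0] =  0.25 * (1 + eta); g_tab[g].dN[2][1] =  0.25 * (1 + xi);
    g_tab[g].dN[3][0] = -0.25 * (1 + eta); g_tab[g].dN[3][1] =  0.25 * (1 - xi);
  }
  g_tab_init = true;
}

// Cauchy stress of the FRPE solid skeleton at a material point.
// F, snf, sf are row-major 3x3; dirs is column-major (leading dim nf).
static inline void frpe_stress_raw(const double F[9], double Knf, double Gnf,
                                   double Ef, const double* dirs,
                                   const double* wv, int nf,
                                   double snf[9], double sf[9], double& J) {
  J = F[0] * (F[4] * F[8] - F[5] * F[7])
    - F[1] * (F[3] * F[8] - F[5] * F[6])
    + F[2] * (F[3] * F[7] - F[4] * F[6]);
  double J23 = std::cbrt(J * J);
  double vol = 0.5 * Knf * (J - 1.0 / J);
  double gj = Gnf / J;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double b = F[3*i] * F[3*j] + F[3*i+1] * F[3*j+1] + F[3*i+2] * F[3*j+2];
      snf[3*i+j] = gj * b + ((i == j) ? (vol - gj * J23) : 0.0);
    }
  for (int i = 0; i < 9; ++i) sf[i] = 0.0;
  for (int i = 0; i < nf; ++i) {
    double d0 = dirs[i], d1 = dirs[i + nf], d2 = dirs[i + 2 * nf];
    double f0 = F[0] * d0 + F[1] * d1 + F[2] * d2;
    double f1 = F[3] * d0 + F[4] * d1 + F[5] * d2;
    double f2 = F[6] * d0 + F[7] * d1 + F[8] * d2;
    double L2 = f0 * f0 + f1 * f1 + f2 * f2;
    double L = std::sqrt(L2);
    double eps = L - 1.0;           // nominal fibril strain along convected dir
    if (eps > 0.0) {                // collagen fibrils support tension only
      // C1 regularization of the tension-only kink: quadratic blend over
      // [0, EPS_REG] keeps the tangent continuous for Newton; exactly zero in
      // compression, stress offset <= E_f*EPS_REG/2 (negligible) in tension.
      const double EPS_REG = 1e-5;
      double ee = (eps < EPS_REG) ? 0.5 * eps * eps / EPS_REG
                                  : eps - 0.5 * EPS_REG;
      double s = wv[i] * Ef * ee / L2;
      sf[0] += s * f0 * f0; sf[1] += s * f0 * f1; sf[2] += s * f0 * f2;
      sf[4] += s * f1 * f1; sf[5] += s * f1 * f2; sf[8] += s * f2 * f2;
    }
  }
  sf[3] = sf[1]; sf[6] = sf[2]; sf[7] = sf[5];
}

struct ElemCtx {
  double Xr[4], Xz[4];   // reference coords
  mat dirs;              // totf x 3 fibril direction unit vectors (r, z, theta)
  vec w;                 // per-fibril density weights
  double Knf, Gnf, Ef, k0, M;
};

// J at the 4 Gauss points for a given element displacement vector.
static bool elem_gp_J(const ElemCtx& c, const double* ue, double* Jgp) {
  double xr[4], xz[4];
  for (int a = 0; a < 4; ++a) {
    xr[a] = c.Xr[a] + ue[3*a]; xz[a] = c.Xz[a] + ue[3*a + 1];
  }
  for (int g = 0; g < 4; ++g) {
    const double* N = g_tab[g].N;
    double a11 = 0, a12 = 0, a21 = 0, a22 = 0, Rref = 0, rdef = 0;
    double F11 = 0, F12 = 0, F21 = 0, F22 = 0;
    for (int a = 0; a < 4; ++a) {
      double d0 = g_tab[g].dN[a][0], d1 = g_tab[g].dN[a][1];
      a11 += c.Xr[a] * d0; a12 += c.Xr[a] * d1;
      a21 += c.Xz[a] * d0; a22 += c.Xz[a] * d1;
      Rref += N[a] * c.Xr[a]; rdef += N[a] * xr[a];
    }
    double detA = a11 * a22 - a12 * a21;
    if (detA <= 0 || Rref <= 0 || rdef <= 0) return false;
    double i11 = a22 / detA, i12 = -a12 / detA, i21 = -a21 / detA, i22 = a11 / detA;
    for (int a = 0; a < 4; ++a) {
      double d0 = g_tab[g].dN[a][0], d1 = g_tab[g].dN[a][1];
      double gX0 = d0 * i11 + d1 * i21, gX1 = d0 * i12 + d1 * i22;
      F11 += xr[a] * gX0; F12 += xr[a] * gX1;
      F21 += xz[a] * gX0; F22 += xz[a] * gX1;
    }
    Jgp[g] = (F11 * F22 - F12 * F21) * (rdef / Rref);
    if (Jgp[g] <= 0) return false;
  }
  return true;
}

// Element residual: 12 entries (ur, uz, p per node).
// Momentum: div(sigma_tot) = 0 in the deformed configuration (axisymmetric
// weak form).  Continuity: skeleton volume rate (backward Euler vs Jprev)
// balanced by Darcy conduction with k = k0 * J^M.
static bool elem_residual(const ElemCtx& c, const double* ue, const double* Jprev,
                          double dt, double* re) {
  for (int i = 0; i < 12; ++i) re[i] = 0.0;
  double xr[4], xz[4], pe[4];
  for (int a = 0; a < 4; ++a) {
    xr[a] = c.Xr[a] + ue[3*a]; xz[a] = c.Xz[a] + ue[3*a + 1]; pe[a] = ue[3*a + 2];
  }
  const double* dirp = c.dirs.memptr();
  const double* wp = c.w.memptr();
  const int nf = (int)c.dirs.n_rows;
  for (int g = 0; g < 4; ++g) {
    const double* N = g_tab[g].N;
    double a11 = 0, a12 = 0, a21 = 0, a22 = 0;
    double b11 = 0, b12 = 0, b21 = 0, b22 = 0, Rref = 0, rdef = 0;
    for (int a = 0; a < 4; ++a) {
      double d0 = g_tab[g].dN[a][0], d1 = g_tab[g].dN[a][1];
      a11 += c.Xr[a] * d0; a12 += c.Xr[a] * d1;
      a21 += c.Xz[a] * d0; a22 += c.Xz[a] * d1;
      b11 += xr[a] * d0;   b12 += xr[a] * d1;
      b21 += xz[a] * d0;   b22 += xz[a] * d1;
      Rref += N[a] * c.Xr[a]; rdef += N[a] * xr[a];
    }
    double detA = a11 * a22 - a12 * a21;
    double detB = b11 * b22 - b12 * b21;
    if (detA <= 0 || detB <= 0 || Rref <= 0 || rdef <= 0) return false;
    double iA11 = a22 / detA, iA12 = -a12 / detA, iA21 = -a21 / detA, iA22 = a11 / detA;
    double iB11 = b22 / detB, iB12 = -b12 / detB, iB21 = -b21 / detB, iB22 = b11 / detB;
    double dNX[4][2], dNx[4][2];
    double F11 = 0, F12 = 0, F21 = 0, F22 = 0, pgp = 0, gp0 = 0, gp1 = 0;
    for (int a = 0; a < 4; ++a) {
      double d0 = g_tab[g].dN[a][0], d1 = g_tab[g].dN[a][1];
      dNX[a][0] = d0 * iA11 + d1 * iA21; dNX[a][1] = d0 * iA12 + d1 * iA22;
      dNx[a][0] = d0 * iB11 + d1 * iB21; dNx[a][1] = d0 * iB12 + d1 * iB22;
      F11 += xr[a] * dNX[a][0]; F12 += xr[a] * dNX[a][1];
      F21 += xz[a] * dNX[a][0]; F22 += xz[a] * dNX[a][1];
      pgp += N[a] * pe[a];
      gp0 += dNx[a][0] * pe[a]; gp1 += dNx[a][1] * pe[a];
    }
    double Ftt = rdef / Rref;
    double F[9] = {F11, F12, 0, F21, F22, 0, 0, 0, Ftt};
    double snf[9], sfib[9], J;
    frpe_stress_raw(F, c.Knf, c.Gnf, c.Ef, dirp, wp, nf, snf, sfib, J);
    if (J <= 0) return false;
    double s00 = snf[0] + sfib[0] - pgp;
    double s01 = snf[1] + sfib[1];
    double s11 = snf[4] + sfib[4] - pgp;
    double s22 = snf[8] + sfib[8] - pgp;
    double k = c.k0 * std::pow(J, c.M);
    double wref = detA * Rref * TWOPI;
    double wdef = detB * rdef * TWOPI;
    double stor = (J - Jprev[g]) / dt * wref;
    for (int a = 0; a < 4; ++a) {
      re[3*a]     += (dNx[a][0] * s00 + dNx[a][1] * s01 + N[a] / rdef * s22) * wdef;
      re[3*a + 1] += (dNx[a][0] * s01 + dNx[a][1] * s11) * wdef;
      re[3*a + 2] += N[a] * stor + (dNx[a][0] * gp0 + dNx[a][1] * gp1) * k * wdef;
    }
  }
  return true;
}

// central-difference element Jacobian (row-major 12x12 in Ke)
static bool elem_jacobian(const ElemCtx& c, const double* ue, const double* Jprev,
                          double dt, double* Ke) {
  double up[12], rp[12], rm[12];
  for (int i = 0; i < 12; ++i) up[i] = ue[i];
  for (int d = 0; d < 12; ++d) {
    double h = 1e-7 * std::max(1.0, std::abs(ue[d]));
    up[d] = ue[d] + h;
    if (!elem_residual(c, up, Jprev, dt, rp)) return false;
    up[d] = ue[d] - h;
    if (!elem_residual(c, up, Jprev, dt, rm)) return false;
    up[d] = ue[d];
    double s = 0.5 / h;
    for (int i = 0; i < 12; ++i) Ke[12*i + d] = (rp[i] - rm[i]) * s;
  }
  return true;
}

struct Problem {
  mat nodes;                 // nnode x 2
  umat elems;                // nelem x 4 (0-based)
  std::vector<ElemCtx> ctx;
  uword nnode, nelem, ndof;  // ndof = 3*nnode
};

static Problem build_problem(const mat& nodes, const imat& elems1,
                             const mat& elem_mat, const cube& fib_dirs,
                             const mat& fib_w) {
  init_gp_tab();
  Problem P;
  P.nodes = nodes;
  P.nnode = nodes.n_rows;
  P.nelem = elems1.n_rows;
  P.ndof = 3 * P.nnode;
  P.elems.set_size(P.nelem, 4);
  P.ctx.resize(P.nelem);
  for (uword e = 0; e < P.nelem; ++e) {
    ElemCtx& c = P.ctx[e];
    for (int a = 0; a < 4; ++a) {
      uword n = (uword)(elems1(e, a) - 1);
      P.elems(e, a) = n;
      c.Xr[a] = nodes(n, 0);
      c.Xz[a] = nodes(n, 1);
    }
    c.dirs = fib_dirs.slice(e);
    c.w = fib_w.col(e);
    c.Knf = elem_mat(e, 0); c.Gnf = elem_mat(e, 1); c.Ef = elem_mat(e, 2);
    c.k0 = elem_mat(e, 3);  c.M = elem_mat(e, 4);
  }
  return P;
}

static void gather(const Problem& P, uword e, const vec& U, double* ue) {
  for (int a = 0; a < 4; ++a) {
    uword n = P.elems(e, a);
    ue[3*a] = U(3*n); ue[3*a + 1] = U(3*n + 1); ue[3*a + 2] = U(3*n + 2);
  }
}

// Assemble internal residual into R (length ndof) and optionally scatter the
// Jacobian into the leading ndof x ndof block of *K (K may be larger).
static bool assemble(const Problem& P, const vec& U, const mat& JprevAll,
                     double dt, vec& R, mat* K) {
  R.zeros(P.ndof);
  double ue[12], re[12], Ke[144], Jprev[4];
  for (uword e = 0; e < P.nelem; ++e) {
    gather(P, e, U, ue);
    for (int g = 0; g < 4; ++g) Jprev[g] = JprevAll(g, e);
    if (!elem_residual(P.ctx[e], ue, Jprev, dt, re)) return false;
    if (K) { if (!elem_jacobian(P.ctx[e], ue, Jprev, dt, Ke)) return false; }
    for (int a = 0; a < 4; ++a) {
      uword na = P.elems(e, a);
      for (int ca = 0; ca < 3; ++ca) {
        uword ga = 3*na + ca;
        R(ga) += re[3*a + ca];
        if (K) {
          for (int b = 0; b < 4; ++b) {
            uword nb = P.elems(e, b);
            for (int cb = 0; cb < 3; ++cb)
              (*K)(ga, 3*nb + cb) += Ke[12 * (3*a + ca) + (3*b + cb)];
          }
        }
      }
    }
  }
  return true;
}

static bool all_gp_J(const Problem& P, const vec& U, mat& JprevAll) {
  JprevAll.set_size(4, P.nelem);
  double ue[12], Jgp[4];
  for (uword e = 0; e < P.nelem; ++e) {
    gather(P, e, U, ue);
    if (!elem_gp_J(P.ctx[e], ue, Jgp)) return false;
    for (int g = 0; g < 4; ++g) JprevAll(g, e) = Jgp[g];
  }
  return true;
}

// Mesh volume change 2*pi*Int (J - 1) R dA_ref.
static double volume_change(const Problem& P, const vec& U) {
  double ue[12], Jgp[4];
  double dV = 0.0;
  for (uword e = 0; e < P.nelem; ++e) {
    gather(P, e, U, ue);
    if (!elem_gp_J(P.ctx[e], ue, Jgp)) return datum::nan;
    const ElemCtx& c = P.ctx[e];
    for (int g = 0; g < 4; ++g) {
      const double* N = g_tab[g].N;
      double a11 = 0, a12 = 0, a21 = 0, a22 = 0, Rref = 0;
      for (int a = 0; a < 4; ++a) {
        double d0 = g_tab[g].dN[a][0], d1 = g_tab[g].dN[a][1];
        a11 += c.Xr[a] * d0; a12 += c.Xr[a] * d1;
        a21 += c.Xz[a] * d0; a22 += c.Xz[a] * d1;
        Rref += N[a] * c.Xr[a];
      }
      dV += (Jgp[g] - 1.0) * (a11 * a22 - a12 * a21) * Rref * TWOPI;
    }
  }
  return dV;
}

struct Contact {
  double Rs;
  double zc;                   // sphere centre height (current)
  std::vector<uword> cand;     // candidate node indices (0-based)
  std::vector<int> active;
  std::vector<double> lambda;
};

// Gap of candidate node ci at state U; > 0 separated.
static double contact_gap(const Problem& P, const Contact& C, uword ci, const vec& U,
                          double* dgdr = nullptr) {
  uword n = C.cand[ci];
  double r = P.nodes(n, 0) + U(3*n);
  double z = P.nodes(n, 1) + U(3*n + 1);
  double lim = 0.95 * C.Rs;
  if (r >= lim) { if (dgdr) *dgdr = 0.0; return 1e6; }
  double s = std::sqrt(C.Rs * C.Rs - r * r);
  if (dgdr) *dgdr = r / s;
  return (C.zc - s) - z;   // sphere surface height minus node height
}

struct BC {
  uvec fixed_u;     // dofs held at zero
  uvec driven_uz;   // uz dofs following -delta(t) (platen modes)
  uvec p_fixed;     // p dofs always prescribed zero (draining)
  uvec p_surface;   // p dofs draining unless the node is sealed by contact
  bool drained;     // prescribe p = 0 everywhere (elastic limit)
};

struct NewtonCtrl {
  double tol;
  int maxit;
  int max_set_iter;
  int max_halve;
  bool verbose = false;
};

// One backward-Euler solve to t+dt with active-set contact.
// Returns 0 success, 1 newton failure, 2 element inversion, 3 set oscillation.
static int solve_substep(const Problem& P, const BC& bc, Contact* C,
                         const mat& JprevAll, double dt, double delta_end,
                         const NewtonCtrl& nc, vec& U, int* iters_out) {
  uword nd = P.ndof;
  int total_iter = 0;
  // geometric pre-activation: nodes the sphere already overlaps at the new
  // depth start active, merging most active-set growth into the first sweep
  if (C)
    for (uword ci = 0; ci < C->cand.size(); ++ci)
      if (!C->active[ci] && contact_gap(P, *C, ci, U) < -1e-9) {
        C->active[ci] = 1; C->lambda[ci] = 0.0;
      }
  for (int sweep = 0; sweep < nc.max_set_iter; ++sweep) {
    std::vector<uword> act_idx;
    if (C)
      for (uword ci = 0; ci < C->cand.size(); ++ci)
        if (C->active[ci]) act_idx.push_back(ci);
    uword nact = act_idx.size();
    uword ntot = nd + nact;
    mat K(ntot, ntot);
    vec R(ntot), Rint(nd);
    bool converged = false;
    for (int it = 0; it < nc.maxit; ++it) {
      ++total_iter;
      K.zeros(); R.zeros();
      if (!assemble(P, U, JprevAll, dt, Rint, &K)) return 2;
      R.subvec(0, nd - 1) = Rint;
      if (C) {
        for (uword a = 0; a < nact; ++a) {
          uword ci = act_idx[a];
          uword n = C->cand[ci];
          double dgdr;
          double g = contact_gap(P, *C, ci, U, &dgdr);
          double lam = C->lambda[ci];
          uword ir = 3*n, iz = 3*n + 1, il = nd + a;
          // lambda >= 0 presses the tissue down/outward along the inward
          // sphere normal ~ (dgdr, -1); residual = Rint - f_ext.
          R(ir) -= lam * dgdr;
          R(iz) += lam;
          R(il) = g;
          double r = P.nodes(n, 0) + U(ir);
          double lim = 0.95 * C->Rs;
          if (r < lim) {
            double s = std::sqrt(C->Rs * C->Rs - r * r);
            K(ir, ir) -= lam * (C->Rs * C->Rs) / (s * s * s);
          }
          K(ir, il) = -dgdr;
          K(iz, il) = 1.0;
          K(il, ir) = dgdr;
          K(il, iz) = -1.0;
        }
      }
      auto prescribe = [&](uword d, double target) {
        K.row(d).zeros(); K(d, d) = 1.0;
        R(d) = U(d) - target;
      };
      for (uword i = 0; i < bc.fixed_u.n_elem; ++i) prescribe(bc.fixed_u(i), 0.0);
      for (uword i = 0; i < bc.driven_uz.n_elem; ++i) prescribe(bc.driven_uz(i), -delta_end);
      if (bc.drained) {
        for (uword n = 0; n < P.nnode; ++n) prescribe(3*n + 2, 0.0);
      } else {
        for (uword i = 0; i < bc.p_fixed.n_elem; ++i) prescribe(bc.p_fixed(i), 0.0);
        for (uword i = 0; i < bc.p_surface.n_elem; ++i) {
          uword d = bc.p_surface(i);
          uword n = d / 3;
          bool sealed = false;
          if (C)
            for (uword a = 0; a < nact; ++a)
              if (C->cand[act_idx[a]] == n) { sealed = true; break; }
          if (!sealed) prescribe(d, 0.0);
        }
      }
      vec du;
      bool ok = solve(du, K, -R, solve_opts::no_approx);
      if (!ok || !du.is_finite()) return 1;
      U += du.subvec(0, nd - 1);
      for (uword a = 0; a < nact; ++a) C->lambda[act_idx[a]] += du(nd + a);
      double dmax = abs(du).max();
      if (nc.verbose)
        Rcpp::Rcout << "  sweep " << sweep << " it " << it << " nact " << nact
                    << " dmax " << dmax << " res " << norm(R, "inf") << "\n";
      if (dmax > 1e4) return 1;
      if (dmax < nc.tol && it >= 1) { converged = true; break; }
    }
    if (!converged) return 1;
    if (!C) { if (iters_out) *iters_out += total_iter; return 0; }
    bool changed = false;
    for (uword ci = 0; ci < C->cand.size(); ++ci) {
      if (C->active[ci]) {
        if (C->lambda[ci] < -1e-12) {            // adhesion -> release
          C->active[ci] = 0; C->lambda[ci] = 0.0; changed = true;
        }
      } else if (contact_gap(P, *C, ci, U) < -1e-9) {  // penetration -> activate
        C->active[ci] = 1; C->lambda[ci] = 0.0; changed = true;
      }
    }
    if (!changed) { if (iters_out) *iters_out += total_iter; return 0; }
  }
  return 3;
}

static double interp_sched(const mat& sched, double t) {
  uword n = sched.n_rows;
  if (t <= sched(0, 0)) return sched(0, 1);
  if (t >= sched(n - 1, 0)) return sched(n - 1, 1);
  for (uword i = 1; i < n; ++i) {
    if (t <= sched(i, 0)) {
      double f = (t - sched(i - 1, 0)) / (sched(i, 0) - sched(i - 1, 0));
      return sched(i - 1, 1) + f * (sched(i, 1) - sched(i - 1, 1));
    }
  }
  return sched(n - 1, 1);
}

static uvec to_uvec0(const Rcpp::IntegerVector& v) {
  uvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (uword)(v[i] - 1);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_point_stress(const arma::mat& F, double p, double Knf, double Gnf,
                            double Ef, const arma::mat& dirs, const arma::vec& w) {
  double Fr[9], snf[9], sf[9], J;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Fr[3*i + j] = F(i, j);
  frpe_stress_raw(Fr, Knf, Gnf, Ef, dirs.memptr(), w.memptr(),
                  (int)dirs.n_rows, snf, sf, J);
  mat snfm(3, 3), sfm(3, 3), stot(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      snfm(i, j) = snf[3*i + j];
      sfm(i, j) = sf[3*i + j];
      stot(i, j) = snf[3*i + j] + sf[3*i + j] - ((i == j) ? p : 0.0);
    }
  return Rcpp::List::create(
    Rcpp::Named("sigma_nf") = snfm,
    Rcpp::Named("sigma_f") = sfm,
    Rcpp::Named("sigma_tot") = stot,
    Rcpp::Named("J") = J);
}

// [[Rcpp::export]]
Rcpp::List cpp_assemble(const arma::mat& nodes, const Rcpp::IntegerMatrix& elems,
                        const arma::mat& elem_mat, const arma::cube& fib_dirs,
                        const arma::mat& fib_w, const arma::vec& U,
                        const arma::vec& Uprev, double dt, bool jacobian) {
  imat el(elems.nrow(), elems.ncol());
  for (int i = 0; i < elems.nrow(); ++i)
    for (int j = 0; j < elems.ncol(); ++j) el(i, j) = elems(i, j);
  Problem P = build_problem(nodes, el, elem_mat, fib_dirs, fib_w);
  mat JprevAll;
  if (!all_gp_J(P, Uprev, JprevAll))
    Rcpp::stop("inverted element in previous state");
  vec R(P.ndof);
  if (jacobian) {
    mat K(P.ndof, P.ndof, fill::zeros);
    if (!assemble(P, U, JprevAll, dt, R, &K))
      Rcpp::stop("inverted element at evaluation state");
    return Rcpp::List::create(Rcpp::Named("residual") = R,
                              Rcpp::Named("jacobian") = K);
  }
  if (!assemble(P, U, JprevAll, dt, R, nullptr))
    Rcpp::stop("inverted element at evaluation state");
  return Rcpp::List::create(Rcpp::Named("residual") = R);
}

// [[Rcpp::export]]
arma::mat cpp_cell_fields(const arma::mat& nodes, const Rcpp::IntegerMatrix& elems,
                          const arma::mat& elem_mat, const arma::cube& fib_dirs,
                          const arma::mat& fib_w, const arma::vec& U) {
  imat el(elems.nrow(), elems.ncol());
  for (int i = 0; i < elems.nrow(); ++i)
    for (int j = 0; j < elems.ncol(); ++j) el(i, j) = elems(i, j);
  Problem P = build_problem(nodes, el, elem_mat, fib_dirs, fib_w);
  mat out(P.nelem, 4);   // J, permeability, p, max principal effective stress
  double ue[12];
  for (uword e = 0; e < P.nelem; ++e) {
    gather(P, e, U, ue);
    const ElemCtx& c = P.ctx[e];
    double xr[4], xz[4], pe[4];
    for (int a = 0; a < 4; ++a) {
      xr[a] = c.Xr[a] + ue[3*a]; xz[a] = c.Xz[a] + ue[3*a + 1]; pe[a] = ue[3*a + 2];
    }
    // element centre: N = 1/4, dN at (0,0)
    double dN0[4] = {-0.25, 0.25, 0.25, -0.25};
    double dN1[4] = {-0.25, -0.25, 0.25, 0.25};
    double a11 = 0, a12 = 0, a21 = 0, a22 = 0, Rref = 0, rdef = 0, pgp = 0;
    for (int a = 0; a < 4; ++a) {
      a11 += c.Xr[a] * dN0[a]; a12 += c.Xr[a] * dN1[a];
      a21 += c.Xz[a] * dN0[a]; a22 += c.Xz[a] * dN1[a];
      Rref += 0.25 * c.Xr[a]; rdef += 0.25 * xr[a]; pgp += 0.25 * pe[a];
    }
    double detA = a11 * a22 - a12 * a21;
    double i11 = a22 / detA, i12 = -a12 / detA, i21 = -a21 / detA, i22 = a11 / detA;
    double F11 = 0, F12 = 0, F21 = 0, F22 = 0;
    for (int a = 0; a < 4; ++a) {
      double g0 = dN0[a] * i11 + dN1[a] * i21, g1 = dN0[a] * i12 + dN1[a] * i22;
      F11 += xr[a] * g0; F12 += xr[a] * g1;
      F21 += xz[a] * g0; F22 += xz[a] * g1;
    }
    double F[9] = {F11, F12, 0, F21, F22, 0, 0, 0, rdef / Rref};
    double snf[9], sfib[9], J;
    frpe_stress_raw(F, c.Knf, c.Gnf, c.Ef, c.dirs.memptr(), c.w.memptr(),
                    (int)c.dirs.n_rows, snf, sfib, J);
    mat se(3, 3);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) se(i, j) = snf[3*i + j] + sfib[3*i + j];
    vec eigval = eig_sym(se);
    out(e, 0) = J;
    out(e, 1) = c.k0 * std::pow(J, c.M);
    out(e, 2) = pgp;
    out(e, 3) = eigval.max();
  }
  return out;
}

// Full time-stepping driver.
// [[Rcpp::export]]
Rcpp::List cpp_simulate(const arma::mat& nodes, const Rcpp::IntegerMatrix& elems,
                        const arma::mat& elem_mat, const arma::cube& fib_dirs,
                        const arma::mat& fib_w, const arma::vec& times,
                        const arma::mat& sched,
                        const Rcpp::IntegerVector& fixed_u_dofs,
                        const Rcpp::IntegerVector& driven_uz_dofs,
                        const Rcpp::IntegerVector& p_fixed_dofs,
                        const Rcpp::IntegerVector& p_surface_dofs,
                        const Rcpp::IntegerVector& contact_nodes,
                        double sphere_r, double surface_z, bool drained,
                        Rcpp::List ctrl, const arma::vec& U0) {
  imat el(elems.nrow(), elems.ncol());
  for (int i = 0; i < elems.nrow(); ++i)
    for (int j = 0; j < elems.ncol(); ++j) el(i, j) = elems(i, j);
  Problem P = build_problem(nodes, el, elem_mat, fib_dirs, fib_w);

  BC bc;
  bc.fixed_u = to_uvec0(fixed_u_dofs);
  bc.driven_uz = to_uvec0(driven_uz_dofs);
  bc.p_fixed = to_uvec0(p_fixed_dofs);
  bc.p_surface = to_uvec0(p_surface_dofs);
  bc.drained = drained;

  NewtonCtrl nc;
  nc.tol = Rcpp::as<double>(ctrl["newton_tol"]);
  nc.maxit = Rcpp::as<int>(ctrl["newton_maxit"]);
  nc.max_set_iter = Rcpp::as<int>(ctrl["max_set_iter"]);
  nc.max_halve = Rcpp::as<int>(ctrl["max_halve"]);
  bool store_states = Rcpp::as<bool>(ctrl["store_states"]);
  if (ctrl.containsElementNamed("verbose"))
    nc.verbose = Rcpp::as<bool>(ctrl["verbose"]);

  bool has_contact = contact_nodes.size() > 0;
  Contact C;
  if (has_contact) {
    C.Rs = sphere_r;
    C.cand.resize(contact_nodes.size());
    C.active.assign(contact_nodes.size(), 0);
    C.lambda.assign(contact_nodes.size(), 0.0);
    for (int i = 0; i < contact_nodes.size(); ++i)
      C.cand[i] = (uword)(contact_nodes[i] - 1);
  }

  uword nt = times.n_elem;
  vec f_contact(nt, fill::zeros), f_top(nt, fill::zeros), f_base(nt, fill::zeros);
  vec p_base(nt, fill::zeros), max_p(nt, fill::zeros), dvol(nt, fill::zeros);
  vec efflux(nt, fill::zeros), cbm(nt, fill::zeros);
  Rcpp::IntegerVector n_iter(nt, 0);
  mat states;
  if (store_states) states.set_size(P.ndof, nt);

  uword base_node = 0; double best = datum::inf;
  for (uword n = 0; n < P.nnode; ++n)
    if (P.nodes(n, 1) <= 1e-12 && P.nodes(n, 0) < best) {
      best = P.nodes(n, 0); base_node = n;
    }

  vec U(P.ndof, fill::zeros);
  if (U0.n_elem == P.ndof) U = U0;
  if (store_states) states.col(0) = U;
  double efflux_cum = 0.0;
  int status = 0, last_rc = 0;
  uword last_ok = 0;

  mat JprevAll;
  all_gp_J(P, U, JprevAll);
  vec Rint_last(P.ndof, fill::zeros);
  vec U_old = U;            // state one substep back, for the predictor
  double dt_old = -1.0;

  for (uword k = 1; k < nt && status == 0; ++k) {
    double t0 = times(k - 1), t1 = times(k);
    int halve = 0;
    bool done = false;
    while (!done) {
      int nsub = 1 << halve;
      vec Usave = U;
      Contact Csave = C;
      mat Jsave = JprevAll;
      double eff_save = efflux_cum;
      bool fail = false;
      int iters_tot = 0;
      for (int s = 0; s < nsub; ++s) {
        double tb = t0 + (t1 - t0) * (s + 1) / (double)nsub;
        double dt = (t1 - t0) / (double)nsub;
        double delta = interp_sched(sched, tb);
        if (has_contact) C.zc = surface_z + C.Rs - delta;
        vec U_before = U;
        if (dt_old > 0) U += (U - U_old) * (dt / dt_old);   // linear predictor
        int rc = solve_substep(P, bc, has_contact ? &C : nullptr, JprevAll, dt,
                               delta, nc, U, &iters_tot);
        if (rc != 0) { last_rc = rc; U = U_before; fail = true; break; }
        U_old = U_before; dt_old = dt;
        // flux bookkeeping with the substep's backward-Euler reference:
        // summed over drained p rows, the continuity residual equals dV/dt,
        // so the outflow rate is its negative.
        if (!drained) {
          if (!assemble(P, U, JprevAll, dt, Rint_last, nullptr)) { fail = true; break; }
          double q = 0.0;
          for (uword i = 0; i < bc.p_fixed.n_elem; ++i) q += Rint_last(bc.p_fixed(i));
          for (uword i = 0; i < bc.p_surface.n_elem; ++i) {
            uword d = bc.p_surface(i);
            uword n = d / 3;
            bool sealed = false;
            if (has_contact)
              for (uword ci = 0; ci < C.cand.size(); ++ci)
                if (C.active[ci] && C.cand[ci] == n) { sealed = true; break; }
            if (!sealed) q += Rint_last(d);
          }
          efflux_cum += (-q) * dt;
        } else {
          if (!assemble(P, U, JprevAll, 1.0, Rint_last, nullptr)) { fail = true; break; }
        }
        if (!all_gp_J(P, U, JprevAll)) { fail = true; break; }
      }
      if (!fail) {
        done = true;
        n_iter[k] = iters_tot;
      } else {
        U = Usave; C = Csave; JprevAll = Jsave; efflux_cum = eff_save;
        dt_old = -1.0;
        ++halve;
        if (halve > nc.max_halve) { status = 1; break; }
      }
    }
    if (status != 0) break;
    last_ok = k;

    if (has_contact) {
      double fc = 0.0;
      for (uword ci = 0; ci < C.cand.size(); ++ci) fc += C.lambda[ci];
      f_contact(k) = fc;
    }
    double ft = 0.0;
    for (uword i = 0; i < bc.driven_uz.n_elem; ++i) ft += Rint_last(bc.driven_uz(i));
    f_top(k) = -ft;
    double fb = 0.0;
    for (uword i = 0; i < bc.fixed_u.n_elem; ++i) {
      uword d = bc.fixed_u(i);
      if (d % 3 == 1 && P.nodes(d / 3, 1) <= 1e-12) fb += Rint_last(d);
    }
    f_base(k) = fb;
    p_base(k) = U(3 * base_node + 2);
    double mp = 0.0;
    for (uword n = 0; n < P.nnode; ++n) mp = std::max(mp, std::abs(U(3*n + 2)));
    max_p(k) = mp;
    double cb = 0.0;
    for (uword e = 0; e < P.nelem; ++e) {
      double alt = U(3*P.elems(e,0)+2) - U(3*P.elems(e,1)+2)
                 + U(3*P.elems(e,2)+2) - U(3*P.elems(e,3)+2);
      cb = std::max(cb, std::abs(alt));
    }
    cbm(k) = (mp > 1e-14) ? cb / (4.0 * mp) : 0.0;
    dvol(k) = volume_change(P, U);
    efflux(k) = efflux_cum;
    if (store_states) states.col(k) = U;
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("time") = times,
    Rcpp::Named("force_contact") = f_contact,
    Rcpp::Named("force_top") = f_top,
    Rcpp::Named("force_base") = f_base,
    Rcpp::Named("p_base") = p_base,
    Rcpp::Named("max_abs_p") = max_p,
    Rcpp::Named("checkerboard") = cbm,
    Rcpp::Named("vol_change") = dvol,
    Rcpp::Named("efflux_cum") = efflux,
    Rcpp::Named("newton_iters") = n_iter,
    Rcpp::Named("U") = U,
    Rcpp::Named("status") = status,
    Rcpp::Named("fail_code") = last_rc,
    Rcpp::Named("last_ok") = (int)last_ok);
  if (store_states) out["states"] = states;
  return out;
}
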