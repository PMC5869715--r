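// Core numerics: RKHS surface evaluation (value + analytic gradient),
// two-state mixing, and the Langevin / velocity-Verlet propagator used by
// the reactive-dynamics module. Units throughout: A, degrees, fs, amu,
// kcal/mol. Conversion kcal/mol -> amu A^2/fs^2 is F2A below.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double F2A = 4.184e-4;           // kcal/mol in amu A^2/fs^2
static const double KB = 0.0019872041;        // kcal/mol/K

// ---------------------------------------------------------------------------
// deterministic RNG (xoshiro256++ seeded by splitmix64), Box-Muller normals
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0xA3C59AC2ULL + stream * 0x9E3779B97F4A7C15ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// RKHS surface
// ---------------------------------------------------------------------------
struct Surface {
  const double *beta;
  std::vector<double> Rn, pn;
  int nl, nR, nphi, n, m;
  double sigma, kdome, phie, asym;
  std::vector<double> coef;   // finite 2F1 polynomial coefficients
  double pref;                // n^2 B(m+1, n)
  double Rfar;                // beyond this the kernel tail is negligible

  // scratch
  mutable std::vector<double> kr, dkr, gam, dgam, A, Ad, Vl, VlR, Vlp, P, dP;

  void init(const NumericVector &beta_, const NumericVector &Rn_,
            const NumericVector &pn_, int n_, int m_, double sigma_,
            double kdome_, double phie_, double asym_) {
    beta = REAL(beta_);
    Rn.assign(Rn_.begin(), Rn_.end());
    pn.assign(pn_.begin(), pn_.end());
    IntegerVector d(((RObject)beta_).attr("dim"));
    nl = d[0]; nR = d[1]; nphi = d[2];
    n = n_; m = m_; sigma = sigma_; kdome = kdome_; phie = phie_; asym = asym_;
    coef.resize(n);
    coef[0] = 1.0;
    for (int k = 1; k < n; ++k) {
      coef[k] = coef[k - 1] * (-(double)n + k) * ((double)m + k) /
                (((double)n + m + k) * k);
    }
    // n^2 * B(m+1, n) with integer args: B = m! (n-1)! / (m+n)!
    double b = 1.0;
    for (int k = 1; k <= n; ++k) b *= (double)k / (m + k);
    b /= (double)n;
    pref = (double)n * (double)n * b;
    Rfar = Rn.back() * 1.15;
    kr.resize(nR); dkr.resize(nR);
    gam.resize(nphi); dgam.resize(nphi);
    A.resize(nl * nR); Ad.resize(nl * nR);
    Vl.resize(nl); VlR.resize(nl); Vlp.resize(nl);
    P.resize(nl); dP.resize(nl);
  }

  inline void radial(double R, double Ri, double &q, double &dq) const {
    double lo = R < Ri ? R : Ri, hi = R < Ri ? Ri : R;
    double z = lo / hi;
    double poly = 0.0, dpoly = 0.0, zpow = 1.0;
    for (int k = 0; k < n; ++k) {
      poly += coef[k] * zpow;
      if (R > Ri || R == Ri) dpoly += coef[k] * (m + 1 + k) * zpow;
      else if (k >= 1) dpoly += coef[k] * k * zpow / z;
      zpow *= z;
    }
    double him = 1.0, inv = 1.0 / hi;
    for (int k = 0; k <= m; ++k) him *= inv;
    q = pref * him * poly;
    dq = (R >= Ri) ? -pref * him * inv * dpoly : pref * him * inv * dpoly;
  }

  // value + gradient (per deg for angles); cheap asymptotic branch far out
  void eval(double R, double th, double phi, double &V, double &gR,
            double &gth, double &gphi) const {
    double dphi0 = phi - phie;
    double vc = 0.5 * kdome * dphi0 * dphi0;
    if (R > Rfar) {
      V = asym + vc; gR = 0.0; gth = 0.0; gphi = kdome * dphi0;
      return;
    }
    for (int i = 0; i < nR; ++i) radial(R, Rn[i], kr[i], dkr[i]);
    double is2 = 1.0 / (sigma * sigma);
    for (int j = 0; j < nphi; ++j) {
      double dp = phi - pn[j];
      gam[j] = std::exp(-0.5 * dp * dp * is2);
      dgam[j] = -dp * is2 * gam[j];
    }
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(Ad.begin(), Ad.end(), 0.0);
    for (int j = 0; j < nphi; ++j) {
      double gj = gam[j], dgj = dgam[j];
      const double *bj = beta + (size_t)nl * nR * j;
      for (int idx = 0; idx < nl * nR; ++idx) {
        A[idx] += bj[idx] * gj;
        Ad[idx] += bj[idx] * dgj;
      }
    }
    std::fill(Vl.begin(), Vl.end(), 0.0);
    std::fill(VlR.begin(), VlR.end(), 0.0);
    std::fill(Vlp.begin(), Vlp.end(), 0.0);
    for (int i = 0; i < nR; ++i) {
      double ki = kr[i], dki = dkr[i];
      const double *Ai = A.data() + (size_t)nl * i;
      const double *Adi = Ad.data() + (size_t)nl * i;
      for (int l = 0; l < nl; ++l) {
        Vl[l] += Ai[l] * ki;
        VlR[l] += Ai[l] * dki;
        Vlp[l] += Adi[l] * ki;
      }
    }
    double thr = th * 0.017453292519943295;
    double x = std::cos(thr), sx = std::sin(thr);
    P[0] = 1.0; dP[0] = 0.0;
    if (nl > 1) { P[1] = x; dP[1] = 1.0; }
    for (int l = 2; l < nl; ++l) {
      P[l] = ((2 * l - 1) * x * P[l - 1] - (l - 1) * P[l - 2]) / l;
      dP[l] = dP[l - 2] + (2 * l - 1) * P[l - 1];
    }
    double dxdth = -sx * 0.017453292519943295;  // d cos(theta) / d theta_deg
    V = asym + vc; gR = 0.0; gth = 0.0; gphi = kdome * dphi0;
    for (int l = 0; l < nl; ++l) {
      V += Vl[l] * P[l];
      gR += VlR[l] * P[l];
      gth += Vl[l] * dP[l] * dxdth;
      gphi += Vlp[l] * P[l];
    }
  }
};

static Surface surface_from_list(const List &s) {
  Surface out;
  out.init(s["beta"], s["R_nodes"], s["phi_nodes"], as<int>(s["n"]),
           as<int>(s["m"]), as<double>(s["sigma_phi"]), as<double>(s["k_dome"]),
           as<double>(s["phi_e"]), as<double>(s["asymptote"]));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_rkhs_eval(NumericVector beta, NumericVector R_nodes,
                            NumericVector phi_nodes, int n, int m,
                            double sigma_phi, double k_dome, double phi_e,
                            double asymptote, NumericVector R,
                            NumericVector theta, NumericVector phi,
                            bool gradient) {
  Surface s;
  s.init(beta, R_nodes, phi_nodes, n, m, sigma_phi, k_dome, phi_e, asymptote);
  // exact evaluation everywhere when called point-wise (no far cutoff)
  s.Rfar = 1e300;
  int np = R.size();
  NumericMatrix out(np, gradient ? 4 : 1);
  double V, gR, gt, gp;
  for (int i = 0; i < np; ++i) {
    s.eval(R[i], theta[i], phi[i], V, gR, gt, gp);
    out(i, 0) = V;
    if (gradient) { out(i, 1) = gR; out(i, 2) = gt; out(i, 3) = gp; }
  }
  return out;
}

// ---------------------------------------------------------------------------
// two-state mixed model
// ---------------------------------------------------------------------------
struct Mixed {
  Surface s2, s4;
  double delta, mixw;
  double eh1, ec1, ew1, eh2, ec2, ew2;   // environment bias bumps
  bool has_env;
  double env_Rsw = 5.0, env_Rw = 0.5;    // radial switch of the bias

  inline void env(double R, double th, double &U, double &dUth,
                  double &dUR) const {
    U = 0.0; dUth = 0.0; dUR = 0.0;
    if (!has_env) return;
    double sw = 1.0 / (1.0 + std::exp((R - env_Rsw) / env_Rw));
    double dsw = -sw * (1.0 - sw) / env_Rw;
    double a1 = (th - ec1) / ew1, a2 = (th - ec2) / ew2;
    double b1 = eh1 * std::exp(-0.5 * a1 * a1);
    double b2 = eh2 * std::exp(-0.5 * a2 * a2);
    double db1 = -b1 * a1 / ew1, db2 = -b2 * a2 / ew2;
    U = sw * (b1 + b2);
    dUth = sw * (db1 + db2);
    dUR = dsw * (b1 + b2);
  }

  // mode 0: doublet only; mode 1: shifted quartet only; mode 2: mixed
  void force(int mode, double R, double th, double phi, double &V,
             double &gR, double &gth, double &gphi, double &w2A) const {
    double V1, g1R, g1t, g1p, V2, g2R, g2t, g2p;
    double U, dUt, dUR;
    env(R, th, U, dUt, dUR);
    if (mode == 0) {
      s2.eval(R, th, phi, V, gR, gth, gphi);
      V += U; gth += dUt; gR += dUR; w2A = 1.0;
      return;
    }
    if (mode == 1) {
      s4.eval(R, th, phi, V, gR, gth, gphi);
      V += delta + U; gth += dUt; gR += dUR; w2A = 0.0;
      return;
    }
    s2.eval(R, th, phi, V1, g1R, g1t, g1p);
    s4.eval(R, th, phi, V2, g2R, g2t, g2p);
    V1 += U; V2 += delta + U;
    g1t += dUt; g2t += dUt; g1R += dUR; g2R += dUR;
    double d = (V1 - V2) / mixw;
    double w1;
    if (d > 37.0) w1 = 0.0;
    else if (d < -37.0) w1 = 1.0;
    else w1 = 1.0 / (1.0 + std::exp(d));
    double w2 = 1.0 - w1;
    V = w1 * V1 + w2 * V2;
    double cc = w1 * w2 * (V1 - V2) / mixw;
    gR = w1 * g1R + w2 * g2R - cc * (g1R - g2R);
    gth = w1 * g1t + w2 * g2t - cc * (g1t - g2t);
    gphi = w1 * g1p + w2 * g2p - cc * (g1p - g2p);
    w2A = w1;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_mixed_eval(List surf2, List surf4, double delta, double mixw,
                             NumericVector env, NumericVector R,
                             NumericVector theta, NumericVector phi, int mode) {
  Mixed mm;
  mm.s2 = surface_from_list(surf2);
  mm.s4 = surface_from_list(surf4);
  mm.s2.Rfar = 1e300; mm.s4.Rfar = 1e300;
  mm.delta = delta; mm.mixw = mixw;
  mm.eh1 = env[0]; mm.ec1 = env[1]; mm.ew1 = env[2];
  mm.eh2 = env[3]; mm.ec2 = env[4]; mm.ew2 = env[5];
  mm.has_env = (mm.eh1 != 0.0 || mm.eh2 != 0.0);
  int np = R.size();
  NumericMatrix out(np, 5);  // V, gR, gth, gphi, w2A
  double V, gR, gt, gp, w;
  for (int i = 0; i < np; ++i) {
    mm.force(mode, R[i], theta[i], phi[i], V, gR, gt, gp, w);
    out(i, 0) = V; out(i, 1) = gR; out(i, 2) = gt; out(i, 3) = gp;
    out(i, 4) = w;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Langevin propagator (BAOAB splitting; velocity Verlet when gamma = 0)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_propagate(List surf2, List surf4, double delta, double mixw,
                   NumericVector env, NumericVector state0, double dt,
                   int nsteps, NumericVector gamma_fs, double TK,
                   NumericVector mass, int mode, NumericVector cage,
                   double Rout, double entropic, NumericVector hot_drag,
                   NumericVector restraint,
                   NumericVector rebind, double seed, double stream,
                   int record_stride) {
  Mixed mm;
  mm.s2 = surface_from_list(surf2);
  mm.s4 = surface_from_list(surf4);
  mm.delta = delta; mm.mixw = mixw;
  mm.eh1 = env[0]; mm.ec1 = env[1]; mm.ew1 = env[2];
  mm.eh2 = env[3]; mm.ec2 = env[4]; mm.ew2 = env[5];
  mm.has_env = (mm.eh1 != 0.0 || mm.eh2 != 0.0);

  double q[3] = {state0[0], state0[1], state0[2]};   // R, theta, phi
  double v[3] = {state0[3], state0[4], state0[5]};   // A/fs, deg/fs, deg/fs
  double mss[3] = {mass[0], mass[1], mass[2]};       // amu, amu A^2 deg^-2 ...
  double c1[3], c2s[3];
  for (int k = 0; k < 3; ++k) {
    c1[k] = std::exp(-gamma_fs[k] * dt);
    c2s[k] = std::sqrt((1.0 - c1[k] * c1[k]) * KB * TK * F2A / mss[k]);
  }
  bool thermostat = gamma_fs[0] > 0 || gamma_fs[1] > 0 || gamma_fs[2] > 0;
  double hot_cut = hot_drag[0];
  double hot_decay = std::exp(-hot_drag[1] * dt);
  double Rcage = cage[0], kwall = cage[1];
  double kRr = restraint[0], Rlo = restraint[1], Rhi = restraint[2];
  double ktr = restraint[3], tlo = restraint[4], thi = restraint[5];
  bool reb_on = rebind[0] > 0;
  double reb_w = rebind[1], reb_R = rebind[2], reb_th = rebind[3];
  int sustain_steps = (int)std::ceil(rebind[4] / dt);

  Rng rng((uint64_t)seed, (uint64_t)stream);

  int nrec = 0;
  NumericMatrix rec;
  if (record_stride > 0) {
    nrec = nsteps / record_stride + 1;
    rec = NumericMatrix(nrec, 9);
  }

  double V, gR, gth, gphi, w2A;
  auto add_extras = [&](double &Vv, double gr[3]) {
    if (entropic > 0) {
      // 3-D radial measure surrogate: free energy -2 kB T ln(R)
      Vv += -2.0 * KB * TK * std::log(q[0]);
      gr[0] += -2.0 * KB * TK / q[0];
    }
    if (kwall > 0 && q[0] > Rcage) {
      double dr = q[0] - Rcage;
      Vv += 0.5 * kwall * dr * dr;
      gr[0] += kwall * dr;
    }
    if (kRr > 0) {
      if (q[0] < Rlo) { double d0 = q[0] - Rlo; Vv += 0.5 * kRr * d0 * d0; gr[0] += kRr * d0; }
      if (q[0] > Rhi) { double d0 = q[0] - Rhi; Vv += 0.5 * kRr * d0 * d0; gr[0] += kRr * d0; }
    }
    if (ktr > 0) {
      if (q[1] < tlo) { double d0 = q[1] - tlo; Vv += 0.5 * ktr * d0 * d0; gr[1] += ktr * d0; }
      if (q[1] > thi) { double d0 = q[1] - thi; Vv += 0.5 * ktr * d0 * d0; gr[1] += ktr * d0; }
    }
  };

  double gr[3];
  mm.force(mode, q[0], q[1], q[2], V, gr[0], gr[1], gr[2], w2A);
  add_extras(V, gr);
  double ke0 = 0.0;
  for (int k = 0; k < 3; ++k) ke0 += 0.5 * mss[k] * v[k] * v[k] / F2A;
  double e0 = V + ke0;

  int streak = 0, irec = 0;
  double rebind_time = NA_REAL, phi_at_rebind = NA_REAL;
  double R_at_rebind = NA_REAL, th_at_rebind = NA_REAL;
  double streak_t = 0.0, streak_phi = 0.0, streak_R = 0.0, streak_th = 0.0;
  bool blown = false;

  auto record = [&](int step) {
    if (record_stride > 0 && step % record_stride == 0 && irec < nrec) {
      double t_ps = step * dt * 1e-3;
      rec(irec, 0) = t_ps; rec(irec, 1) = q[0]; rec(irec, 2) = q[1];
      rec(irec, 3) = q[2]; rec(irec, 4) = v[0]; rec(irec, 5) = v[1];
      rec(irec, 6) = v[2]; rec(irec, 7) = V; rec(irec, 8) = w2A;
      ++irec;
    }
  };
  record(0);

  int step = 0;
  for (step = 1; step <= nsteps; ++step) {
    for (int k = 0; k < 3; ++k) v[k] += -0.5 * dt * gr[k] * F2A / mss[k];
    for (int k = 0; k < 3; ++k) q[k] += 0.5 * dt * v[k];
    if (thermostat) {
      for (int k = 0; k < 3; ++k) v[k] = c1[k] * v[k] + c2s[k] * rng.norm();
      // hot-ligand drag: radial speed in excess of the threshold relaxes
      // fast (collisional energy loss of a ballistic ligand); thermal
      // motion is essentially untouched
      if (hot_cut > 0) {
        double ex = std::fabs(v[0]) - hot_cut;
        if (ex > 0) {
          double sgn = v[0] > 0 ? 1.0 : -1.0;
          v[0] = sgn * (hot_cut + ex * hot_decay);
        }
      }
    }
    for (int k = 0; k < 3; ++k) q[k] += 0.5 * dt * v[k];
    // reflective boundaries: theta poles, optional outer wall, inner guard
    if (q[1] < 0.0) { q[1] = -q[1]; v[1] = -v[1]; }
    if (q[1] > 180.0) { q[1] = 360.0 - q[1]; v[1] = -v[1]; }
    if (Rout > 0 && q[0] > Rout) { q[0] = 2.0 * Rout - q[0]; v[0] = -v[0]; }
    if (q[0] < 0.8) { q[0] = 1.6 - q[0]; v[0] = -v[0]; }
    mm.force(mode, q[0], q[1], q[2], V, gr[0], gr[1], gr[2], w2A);
    add_extras(V, gr);
    for (int k = 0; k < 3; ++k) v[k] += -0.5 * dt * gr[k] * F2A / mss[k];

    record(step);

    if (reb_on) {
      bool hit = (w2A >= reb_w) && (q[0] <= reb_R) && (q[1] >= reb_th);
      if (hit) {
        if (streak == 0) {
          streak_t = step * dt; streak_phi = q[2];
          streak_R = q[0]; streak_th = q[1];
        }
        ++streak;
        if (streak >= sustain_steps) {
          rebind_time = streak_t * 1e-3;  // ps, first frame of the window
          phi_at_rebind = streak_phi;
          R_at_rebind = streak_R; th_at_rebind = streak_th;
          break;
        }
      } else {
        streak = 0;
      }
    }
    if ((step & 1023) == 0) {
      if (!std::isfinite(q[0]) || !std::isfinite(q[1]) || !std::isfinite(V)) {
        blown = true;
        break;
      }
    }
  }

  double ke1 = 0.0;
  for (int k = 0; k < 3; ++k) ke1 += 0.5 * mss[k] * v[k] * v[k] / F2A;

  List out = List::create(
      _["state"] = NumericVector::create(q[0], q[1], q[2], v[0], v[1], v[2]),
      _["rebind_time_ps"] = rebind_time,
      _["phi_at_rebind"] = phi_at_rebind,
      _["R_at_rebind"] = R_at_rebind,
      _["theta_at_rebind"] = th_at_rebind,
      _["energy_initial"] = e0,
      _["energy_final"] = V + ke1,
      _["potential_final"] = V,
      _["kinetic_final"] = ke1,
      _["weight_2A"] = w2A,
      _["blown_up"] = blown,
      _["steps_done"] = (step > nsteps ? nsteps : step));
  if (record_stride > 0) {
    colnames(rec) = CharacterVector::create("t_ps", "R", "theta", "phi", "vR",
                                            "vtheta", "vphi", "epot", "w2A");
    out["records"] = rec;
  }
  return out;
}

// Langevin dynamics in a 1-D harmonic well; used to validate the thermostat
// (position variance must match kB T / k).
// [[Rcpp::export]]
NumericVector cpp_langevin_harmonic(double kspring, double mass_amu,
                                    double gamma_fs, double TK, double dt,
                                    int nsteps, double seed, int stride) {
  Rng rng((uint64_t)seed, 1);
  double x = 0.0, v = 0.0;
  double c1 = std::exp(-gamma_fs * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * KB * TK * F2A / mass_amu);
  int nout = nsteps / stride;
  NumericVector out(nout);
  double a = -kspring * x * F2A / mass_amu;
  int j = 0;
  for (int i = 1; i <= nsteps; ++i) {
    v += 0.5 * dt * a;
    x += 0.5 * dt * v;
    v = c1 * v + c2 * rng.norm();
    x += 0.5 * dt * v;
    a = -kspring * x * F2A / mass_amu;
    v += 0.5 * dt * a;
    if (i % stride == 0 && j < nout) out[j++] = x;
  }
  return out;
}
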