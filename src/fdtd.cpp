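// 2D finite-difference time-domain (Yee) solver, normal-incidence plane
// wave, periodic lateral (x) boundary, CPML absorbing boundaries at both
// ends of the propagation (y) direction.
//
// Normalized units: lengths in nm, c = eps0 = mu0 = 1, so time is in nm
// and impedance is 1. Grid indices: i = 0..nx-1 lateral (periodic),
// j = 0..ny-1 along propagation, j increasing away from the source
// (the "downward"/transmission side); the reflection monitor sits at
// j < j_src, between the source line and the first CPML.
//
// TM polarization: Ez(i,j), Hx(i,j+1/2), Hy(i+1/2,j); downward power flux
// is +Re(Ez conj(Hx))/2.
// TE polarization: Hz(i+1/2,j+1/2), Ex(i+1/2,j), Ey(i,j+1/2); downward
// power flux is -Re(Ex conj(Hz))/2.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

namespace {

struct CpmlY {
  // coefficients at integer rows (E locations) and half rows (H locations)
  std::vector<double> be, ce, ike;  // ike = 1/kappa
  std::vector<double> bh, ch, ikh;
};

// Polynomial-graded CPML conductivity profile, depth 0 at the interface
// rising to sigma_max at the outer edge. kappa is kept at 1 (normal
// incidence, propagating waves) and a small alpha term keeps the
// recursion well conditioned.
CpmlY build_cpml(int ny, int npml, double dx, double dt) {
  const double m = 3.0;
  const double sigma_max = 0.8 * (m + 1.0) / dx;
  const double alpha = 0.02;
  CpmlY p;
  p.be.assign(ny, 0.0); p.ce.assign(ny, 0.0); p.ike.assign(ny, 1.0);
  p.bh.assign(ny - 1, 0.0); p.ch.assign(ny - 1, 0.0); p.ikh.assign(ny - 1, 1.0);
  auto coef = [&](double depth_cells, double &b, double &c) {
    if (depth_cells <= 0) { b = 0.0; c = 0.0; return; }
    double s = sigma_max * std::pow(depth_cells / npml, m);
    b = std::exp(-(s + alpha) * dt);
    c = s * (b - 1.0) / (s + alpha);
  };
  for (int j = 0; j < ny; ++j) {
    double dtop = (double)(npml - j);            // integer row depth, top PML
    double dbot = (double)(j - (ny - 1 - npml)); // bottom PML
    double d = std::max(dtop, dbot);
    coef(d, p.be[j], p.ce[j]);
  }
  for (int j = 0; j < ny - 1; ++j) {
    double dtop = (double)npml - (j + 0.5);
    double dbot = (j + 0.5) - (double)(ny - 1 - npml);
    double d = std::max(dtop, dbot);
    coef(d, p.bh[j], p.ch[j]);
  }
  return p;
}

inline int wrap(int i, int n) { return i < 0 ? i + n : (i >= n ? i - n : i); }

} // namespace

// Pulsed broadband run, TM polarization. Records running DFTs of the
// tangential fields at the reflection and transmission monitor rows for
// each requested angular frequency. Runs until the supplied source
// waveform is exhausted and the grid energy has decayed below
// decay_tol * peak (checked every check_every steps), or max_steps.
// [[Rcpp::export]]
List fdtd_pulse_tm_cpp(NumericMatrix epsr, NumericMatrix sigma, double dx,
                       double dt, int npml, int jsrc, int jrefl, int jtran,
                       NumericVector src, NumericVector omegas,
                       int max_steps, double decay_tol, int check_every) {
  const int nx = epsr.nrow(), ny = epsr.ncol();
  const int nw = omegas.size(), nsrc = src.size();
  std::vector<double> Ez(nx * ny, 0.0), Hy(nx * ny, 0.0);
  std::vector<double> Hx(nx * (ny - 1), 0.0);
  std::vector<double> psiE(nx * ny, 0.0), psiH(nx * (ny - 1), 0.0);
  std::vector<double> Ca(nx * ny), Cb(nx * ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double eps = epsr(i, j), sg = sigma(i, j);
      double a = sg * dt / (2.0 * eps);
      Ca[i + nx * j] = (1.0 - a) / (1.0 + a);
      Cb[i + nx * j] = (dt / eps) / (1.0 + a);
    }
  CpmlY pml = build_cpml(ny, npml, dx, dt);

  std::vector<cplx> Er(nw * nx, 0.0), HrA(nw * nx, 0.0), HrB(nw * nx, 0.0);
  std::vector<cplx> Et(nw * nx, 0.0), HtA(nw * nx, 0.0), HtB(nw * nx, 0.0);
  std::vector<cplx> rot(nw), pE(nw), pH(nw);
  for (int w = 0; w < nw; ++w) {
    rot[w] = std::exp(cplx(0.0, omegas[w] * dt));
    pE[w] = rot[w];                                  // t = dt after first E update
    pH[w] = std::exp(cplx(0.0, omegas[w] * 0.5 * dt)); // t = dt/2
  }

  const double idx = 1.0 / dx;
  double peak_energy = 0.0, energy = 0.0;
  int n = 0;
  bool decayed = false;
  for (n = 0; n < max_steps; ++n) {
    // H updates (t -> t + dt/2)
    for (int j = 0; j < ny - 1; ++j) {
      const double bh = pml.bh[j], ch = pml.ch[j], ikh = pml.ikh[j];
      const bool in_pml = (ch != 0.0);
      double *hx = &Hx[nx * j], *ps = &psiH[nx * j];
      const double *e0 = &Ez[nx * j], *e1 = &Ez[nx * (j + 1)];
      if (in_pml) {
        for (int i = 0; i < nx; ++i) {
          double D = (e1[i] - e0[i]) * idx;
          ps[i] = bh * ps[i] + ch * D;
          hx[i] -= dt * (D * ikh + ps[i]);
        }
      } else {
        for (int i = 0; i < nx; ++i) hx[i] -= dt * (e1[i] - e0[i]) * idx;
      }
    }
    for (int j = 0; j < ny; ++j) {
      double *hy = &Hy[nx * j];
      const double *e = &Ez[nx * j];
      for (int i = 0; i < nx; ++i) {
        int ip = wrap(i + 1, nx);
        hy[i] += dt * (e[ip] - e[i]) * idx;
      }
    }
    // E update (t + dt/2 -> t + dt)
    for (int j = 1; j < ny - 1; ++j) {
      const double be = pml.be[j], ce = pml.ce[j], ike = pml.ike[j];
      const bool in_pml = (ce != 0.0);
      double *ez = &Ez[nx * j], *ps = &psiE[nx * j];
      const double *hxm = &Hx[nx * (j - 1)], *hxp = &Hx[nx * j];
      const double *hy = &Hy[nx * j];
      const double *ca = &Ca[nx * j], *cb = &Cb[nx * j];
      for (int i = 0; i < nx; ++i) {
        int im = wrap(i - 1, nx);
        double curlx = (hy[i] - hy[im]) * idx;
        double De = (hxp[i] - hxm[i]) * idx;
        double dterm;
        if (in_pml) {
          ps[i] = be * ps[i] + ce * De;
          dterm = De * ike + ps[i];
        } else {
          dterm = De;
        }
        ez[i] = ca[i] * ez[i] + cb[i] * (curlx - dterm);
      }
    }
    // soft plane-wave line source
    if (n < nsrc) {
      double s = src[n];
      double *ez = &Ez[nx * jsrc];
      for (int i = 0; i < nx; ++i) ez[i] += s;
    }
    // DFT accumulation at the monitor rows
    {
      const double *er = &Ez[nx * jrefl], *et = &Ez[nx * jtran];
      const double *hra = &Hx[nx * (jrefl - 1)], *hrb = &Hx[nx * jrefl];
      const double *hta = &Hx[nx * (jtran - 1)], *htb = &Hx[nx * jtran];
      for (int w = 0; w < nw; ++w) {
        const cplx pe = pE[w], ph = pH[w];
        cplx *ERw = &Er[nx * w], *HAw = &HrA[nx * w], *HBw = &HrB[nx * w];
        cplx *ETw = &Et[nx * w], *TAw = &HtA[nx * w], *TBw = &HtB[nx * w];
        for (int i = 0; i < nx; ++i) {
          ERw[i] += er[i] * pe;
          ETw[i] += et[i] * pe;
          HAw[i] += hra[i] * ph;
          HBw[i] += hrb[i] * ph;
          TAw[i] += hta[i] * ph;
          TBw[i] += htb[i] * ph;
        }
        pE[w] *= rot[w];
        pH[w] *= rot[w];
      }
    }
    if ((n + 1) % check_every == 0) {
      energy = 0.0;
      for (size_t q = 0; q < Ez.size(); ++q) energy += Ez[q] * Ez[q];
      if (energy > peak_energy) peak_energy = energy;
      if (n >= nsrc && peak_energy > 0.0 && energy < decay_tol * peak_energy) {
        decayed = true;
        ++n;
        break;
      }
    }
  }

  auto pack = [&](std::vector<cplx> &v) {
    ComplexMatrix m(nw, nx);
    for (int w = 0; w < nw; ++w)
      for (int i = 0; i < nx; ++i) {
        m(w, i) = Rcomplex{v[nx * w + i].real() * dt, v[nx * w + i].imag() * dt};
      }
    return m;
  };
  // average the two half-row H DFTs onto the monitor row
  std::vector<cplx> Hr(nw * nx), Ht(nw * nx);
  for (size_t q = 0; q < Hr.size(); ++q) {
    Hr[q] = 0.5 * (HrA[q] + HrB[q]);
    Ht[q] = 0.5 * (HtA[q] + HtB[q]);
  }
  return List::create(_["Er"] = pack(Er), _["Hr"] = pack(Hr),
                      _["Et"] = pack(Et), _["Ht"] = pack(Ht),
                      _["steps"] = n, _["decayed"] = decayed,
                      _["energy_ratio"] =
                          peak_energy > 0 ? energy / peak_energy : 0.0);
}

// Pulsed broadband run, TE polarization (Hz out of plane).
// [[Rcpp::export]]
List fdtd_pulse_te_cpp(NumericMatrix epsr, NumericMatrix sigma, double dx,
                       double dt, int npml, int jsrc, int jrefl, int jtran,
                       NumericVector src, NumericVector omegas,
                       int max_steps, double decay_tol, int check_every) {
  const int nx = epsr.nrow(), ny = epsr.ncol();
  const int nw = omegas.size(), nsrc = src.size();
  // Ex(i+1/2, j): nx * ny ; Ey(i, j+1/2): nx * (ny-1) ; Hz(i+1/2, j+1/2)
  std::vector<double> Ex(nx * ny, 0.0), Ey(nx * (ny - 1), 0.0);
  std::vector<double> Hz(nx * (ny - 1), 0.0);
  std::vector<double> psiH(nx * (ny - 1), 0.0), psiE(nx * ny, 0.0);
  std::vector<double> CaX(nx * ny), CbX(nx * ny);
  std::vector<double> CaY(nx * (ny - 1)), CbY(nx * (ny - 1));
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int ip = wrap(i + 1, nx);
      double eps = 0.5 * (epsr(i, j) + epsr(ip, j));
      double sg = 0.5 * (sigma(i, j) + sigma(ip, j));
      double a = sg * dt / (2.0 * eps);
      CaX[i + nx * j] = (1.0 - a) / (1.0 + a);
      CbX[i + nx * j] = (dt / eps) / (1.0 + a);
    }
  for (int j = 0; j < ny - 1; ++j)
    for (int i = 0; i < nx; ++i) {
      double eps = 0.5 * (epsr(i, j) + epsr(i, j + 1));
      double sg = 0.5 * (sigma(i, j) + sigma(i, j + 1));
      double a = sg * dt / (2.0 * eps);
      CaY[i + nx * j] = (1.0 - a) / (1.0 + a);
      CbY[i + nx * j] = (dt / eps) / (1.0 + a);
    }
  CpmlY pml = build_cpml(ny, npml, dx, dt);

  std::vector<cplx> Er(nw * nx, 0.0), HrA(nw * nx, 0.0), HrB(nw * nx, 0.0);
  std::vector<cplx> Et(nw * nx, 0.0), HtA(nw * nx, 0.0), HtB(nw * nx, 0.0);
  std::vector<cplx> rot(nw), pE(nw), pH(nw);
  for (int w = 0; w < nw; ++w) {
    rot[w] = std::exp(cplx(0.0, omegas[w] * dt));
    pE[w] = rot[w];
    pH[w] = std::exp(cplx(0.0, omegas[w] * 0.5 * dt));
  }

  const double idx = 1.0 / dx;
  double peak_energy = 0.0, energy = 0.0;
  int n = 0;
  bool decayed = false;
  for (n = 0; n < max_steps; ++n) {
    // Hz update: dHz/dt = dEx/dy - dEy/dx   (y-derivative gets CPML)
    for (int j = 0; j < ny - 1; ++j) {
      const double bh = pml.bh[j], ch = pml.ch[j], ikh = pml.ikh[j];
      const bool in_pml = (ch != 0.0);
      double *hz = &Hz[nx * j], *ps = &psiH[nx * j];
      const double *ex0 = &Ex[nx * j], *ex1 = &Ex[nx * (j + 1)];
      const double *ey = &Ey[nx * j];
      for (int i = 0; i < nx; ++i) {
        int ip = wrap(i + 1, nx);
        double Dy = (ex1[i] - ex0[i]) * idx;
        double Dx = (ey[ip] - ey[i]) * idx;
        double dterm;
        if (in_pml) {
          ps[i] = bh * ps[i] + ch * Dy;
          dterm = Dy * ikh + ps[i];
        } else {
          dterm = Dy;
        }
        hz[i] += dt * (dterm - Dx);
      }
    }
    // Ex update: dEx/dt = (1/eps) dHz/dy - (sigma/eps) Ex
    for (int j = 1; j < ny - 1; ++j) {
      const double be = pml.be[j], ce = pml.ce[j], ike = pml.ike[j];
      const bool in_pml = (ce != 0.0);
      double *ex = &Ex[nx * j], *ps = &psiE[nx * j];
      const double *hzm = &Hz[nx * (j - 1)], *hzp = &Hz[nx * j];
      const double *ca = &CaX[nx * j], *cb = &CbX[nx * j];
      for (int i = 0; i < nx; ++i) {
        double De = (hzp[i] - hzm[i]) * idx;
        double dterm;
        if (in_pml) {
          ps[i] = be * ps[i] + ce * De;
          dterm = De * ike + ps[i];
        } else {
          dterm = De;
        }
        ex[i] = ca[i] * ex[i] + cb[i] * dterm;
      }
    }
    // Ey update: dEy/dt = -(1/eps) dHz/dx - (sigma/eps) Ey
    for (int j = 0; j < ny - 1; ++j) {
      double *ey = &Ey[nx * j];
      const double *hz = &Hz[nx * j];
      const double *ca = &CaY[nx * j], *cb = &CbY[nx * j];
      for (int i = 0; i < nx; ++i) {
        int im = wrap(i - 1, nx);
        ey[i] = ca[i] * ey[i] - cb[i] * (hz[i] - hz[im]) * idx;
      }
    }
    if (n < nsrc) {
      double s = src[n];
      double *ex = &Ex[nx * jsrc];
      for (int i = 0; i < nx; ++i) ex[i] += s;
    }
    {
      const double *er = &Ex[nx * jrefl], *et = &Ex[nx * jtran];
      const double *hra = &Hz[nx * (jrefl - 1)], *hrb = &Hz[nx * jrefl];
      const double *hta = &Hz[nx * (jtran - 1)], *htb = &Hz[nx * jtran];
      for (int w = 0; w < nw; ++w) {
        const cplx pe = pE[w], ph = pH[w];
        cplx *ERw = &Er[nx * w], *HAw = &HrA[nx * w], *HBw = &HrB[nx * w];
        cplx *ETw = &Et[nx * w], *TAw = &HtA[nx * w], *TBw = &HtB[nx * w];
        for (int i = 0; i < nx; ++i) {
          ERw[i] += er[i] * pe;
          ETw[i] += et[i] * pe;
          HAw[i] += hra[i] * ph;
          HBw[i] += hrb[i] * ph;
          TAw[i] += hta[i] * ph;
          TBw[i] += htb[i] * ph;
        }
        pE[w] *= rot[w];
        pH[w] *= rot[w];
      }
    }
    if ((n + 1) % check_every == 0) {
      energy = 0.0;
      for (size_t q = 0; q < Hz.size(); ++q) energy += Hz[q] * Hz[q];
      if (energy > peak_energy) peak_energy = energy;
      if (n >= nsrc && peak_energy > 0.0 && energy < decay_tol * peak_energy) {
        decayed = true;
        ++n;
        break;
      }
    }
  }

  auto pack = [&](std::vector<cplx> &v) {
    ComplexMatrix m(nw, nx);
    for (int w = 0; w < nw; ++w)
      for (int i = 0; i < nx; ++i) {
        m(w, i) = Rcomplex{v[nx * w + i].real() * dt, v[nx * w + i].imag() * dt};
      }
    return m;
  };
  std::vector<cplx> Hr(nw * nx), Ht(nw * nx);
  for (size_t q = 0; q < Hr.size(); ++q) {
    Hr[q] = 0.5 * (HrA[q] + HrB[q]);
    Ht[q] = 0.5 * (HtA[q] + HtB[q]);
  }
  return List::create(_["Er"] = pack(Er), _["Hr"] = pack(Hr),
                      _["Et"] = pack(Et), _["Ht"] = pack(Ht),
                      _["steps"] = n, _["decayed"] = decayed,
                      _["energy_ratio"] =
                          peak_energy > 0 ? energy / peak_energy : 0.0);
}

// Continuous-wave run, TM polarization: ramped sinusoid, then block-wise
// single-frequency DFT of the full Ez grid. Two consecutive accumulation
// blocks are returned so the caller can verify steady state.
// [[Rcpp::export]]
List fdtd_cw_tm_cpp(NumericMatrix epsr, NumericMatrix sigma, double dx,
                    double dt, int npml, int jsrc, int jrefl, int jtran,
                    NumericVector src, double omega, int n_settle,
                    int n_block) {
  const int nx = epsr.nrow(), ny = epsr.ncol();
  const int nsrc = src.size();
  const int n_total = n_settle + 2 * n_block;
  std::vector<double> Ez(nx * ny, 0.0), Hy(nx * ny, 0.0);
  std::vector<double> Hx(nx * (ny - 1), 0.0);
  std::vector<double> psiE(nx * ny, 0.0), psiH(nx * (ny - 1), 0.0);
  std::vector<double> Ca(nx * ny), Cb(nx * ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double eps = epsr(i, j), sg = sigma(i, j);
      double a = sg * dt / (2.0 * eps);
      Ca[i + nx * j] = (1.0 - a) / (1.0 + a);
      Cb[i + nx * j] = (dt / eps) / (1.0 + a);
    }
  CpmlY pml = build_cpml(ny, npml, dx, dt);

  std::vector<cplx> map1(nx * ny, 0.0), map2(nx * ny, 0.0);
  const cplx rot = std::exp(cplx(0.0, omega * dt));
  cplx pE = rot;
  const double idx = 1.0 / dx;

  for (int n = 0; n < n_total; ++n) {
    for (int j = 0; j < ny - 1; ++j) {
      const double bh = pml.bh[j], ch = pml.ch[j], ikh = pml.ikh[j];
      const bool in_pml = (ch != 0.0);
      double *hx = &Hx[nx * j], *ps = &psiH[nx * j];
      const double *e0 = &Ez[nx * j], *e1 = &Ez[nx * (j + 1)];
      if (in_pml) {
        for (int i = 0; i < nx; ++i) {
          double D = (e1[i] - e0[i]) * idx;
          ps[i] = bh * ps[i] + ch * D;
          hx[i] -= dt * (D * ikh + ps[i]);
        }
      } else {
        for (int i = 0; i < nx; ++i) hx[i] -= dt * (e1[i] - e0[i]) * idx;
      }
    }
    for (int j = 0; j < ny; ++j) {
      double *hy = &Hy[nx * j];
      const double *e = &Ez[nx * j];
      for (int i = 0; i < nx; ++i) {
        int ip = wrap(i + 1, nx);
        hy[i] += dt * (e[ip] - e[i]) * idx;
      }
    }
    for (int j = 1; j < ny - 1; ++j) {
      const double be = pml.be[j], ce = pml.ce[j], ike = pml.ike[j];
      const bool in_pml = (ce != 0.0);
      double *ez = &Ez[nx * j], *ps = &psiE[nx * j];
      const double *hxm = &Hx[nx * (j - 1)], *hxp = &Hx[nx * j];
      const double *hy = &Hy[nx * j];
      const double *ca = &Ca[nx * j], *cb = &Cb[nx * j];
      for (int i = 0; i < nx; ++i) {
        int im = wrap(i - 1, nx);
        double curlx = (hy[i] - hy[im]) * idx;
        double De = (hxp[i] - hxm[i]) * idx;
        double dterm;
        if (in_pml) {
          ps[i] = be * ps[i] + ce * De;
          dterm = De * ike + ps[i];
        } else {
          dterm = De;
        }
        ez[i] = ca[i] * ez[i] + cb[i] * (curlx - dterm);
      }
    }
    if (n < nsrc) {
      double s = src[n];
      double *ez = &Ez[nx * jsrc];
      for (int i = 0; i < nx; ++i) ez[i] += s;
    }
    if (n >= n_settle) {
      std::vector<cplx> &map = (n < n_settle + n_block) ? map1 : map2;
      for (int q = 0; q < nx * ny; ++q) map[q] += Ez[q] * pE;
    }
    pE *= rot;
  }

  const double norm = dt;
  ComplexMatrix M1(nx, ny), M2(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      cplx a = map1[i + nx * j] * norm, b = map2[i + nx * j] * norm;
      M1(i, j) = Rcomplex{a.real(), a.imag()};
      M2(i, j) = Rcomplex{b.real(), b.imag()};
    }
  return List::create(_["map1"] = M1, _["map2"] = M2);
}

// Continuous-wave run, TE polarization: as fdtd_cw_tm_cpp but returning
// block-wise DFT maps of both in-plane E components.
// [[Rcpp::export]]
List fdtd_cw_te_cpp(NumericMatrix epsr, NumericMatrix sigma, double dx,
                    double dt, int npml, int jsrc, int jrefl, int jtran,
                    NumericVector src, double omega, int n_settle,
                    int n_block) {
  const int nx = epsr.nrow(), ny = epsr.ncol();
  const int nsrc = src.size();
  const int n_total = n_settle + 2 * n_block;
  std::vector<double> Ex(nx * ny, 0.0), Ey(nx * (ny - 1), 0.0);
  std::vector<double> Hz(nx * (ny - 1), 0.0);
  std::vector<double> psiH(nx * (ny - 1), 0.0), psiE(nx * ny, 0.0);
  std::vector<double> CaX(nx * ny), CbX(nx * ny);
  std::vector<double> CaY(nx * (ny - 1)), CbY(nx * (ny - 1));
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int ip = wrap(i + 1, nx);
      double eps = 0.5 * (epsr(i, j) + epsr(ip, j));
      double sg = 0.5 * (sigma(i, j) + sigma(ip, j));
      double a = sg * dt / (2.0 * eps);
      CaX[i + nx * j] = (1.0 - a) / (1.0 + a);
      CbX[i + nx * j] = (dt / eps) / (1.0 + a);
    }
  for (int j = 0; j < ny - 1; ++j)
    for (int i = 0; i < nx; ++i) {
      double eps = 0.5 * (epsr(i, j) + epsr(i, j + 1));
      double sg = 0.5 * (sigma(i, j) + sigma(i, j + 1));
      double a = sg * dt / (2.0 * eps);
      CaY[i + nx * j] = (1.0 - a) / (1.0 + a);
      CbY[i + nx * j] = (dt / eps) / (1.0 + a);
    }
  CpmlY pml = build_cpml(ny, npml, dx, dt);

  std::vector<cplx> ex1(nx * ny, 0.0), ex2(nx * ny, 0.0);
  std::vector<cplx> ey1(nx * (ny - 1), 0.0), ey2(nx * (ny - 1), 0.0);
  const cplx rot = std::exp(cplx(0.0, omega * dt));
  cplx pE = rot;
  const double idx = 1.0 / dx;

  for (int n = 0; n < n_total; ++n) {
    for (int j = 0; j < ny - 1; ++j) {
      const double bh = pml.bh[j], ch = pml.ch[j], ikh = pml.ikh[j];
      const bool in_pml = (ch != 0.0);
      double *hz = &Hz[nx * j], *ps = &psiH[nx * j];
      const double *ex0 = &Ex[nx * j], *exu = &Ex[nx * (j + 1)];
      const double *ey = &Ey[nx * j];
      for (int i = 0; i < nx; ++i) {
        int ip = wrap(i + 1, nx);
        double Dy = (exu[i] - ex0[i]) * idx;
        double Dx = (ey[ip] - ey[i]) * idx;
        double dterm;
        if (in_pml) {
          ps[i] = bh * ps[i] + ch * Dy;
          dterm = Dy * ikh + ps[i];
        } else {
          dterm = Dy;
        }
        hz[i] += dt * (dterm - Dx);
      }
    }
    for (int j = 1; j < ny - 1; ++j) {
      const double be = pml.be[j], ce = pml.ce[j], ike = pml.ike[j];
      const bool in_pml = (ce != 0.0);
      double *ex = &Ex[nx * j], *ps = &psiE[nx * j];
      const double *hzm = &Hz[nx * (j - 1)], *hzp = &Hz[nx * j];
      const double *ca = &CaX[nx * j], *cb = &CbX[nx * j];
      for (int i = 0; i < nx; ++i) {
        double De = (hzp[i] - hzm[i]) * idx;
        double dterm;
        if (in_pml) {
          ps[i] = be * ps[i] + ce * De;
          dterm = De * ike + ps[i];
        } else {
          dterm = De;
        }
        ex[i] = ca[i] * ex[i] + cb[i] * dterm;
      }
    }
    for (int j = 0; j < ny - 1; ++j) {
      double *ey = &Ey[nx * j];
      const double *hz = &Hz[nx * j];
      const double *ca = &CaY[nx * j], *cb = &CbY[nx * j];
      for (int i = 0; i < nx; ++i) {
        int im = wrap(i - 1, nx);
        ey[i] = ca[i] * ey[i] - cb[i] * (hz[i] - hz[im]) * idx;
      }
    }
    if (n < nsrc) {
      double s = src[n];
      double *ex = &Ex[nx * jsrc];
      for (int i = 0; i < nx; ++i) ex[i] += s;
    }
    if (n >= n_settle) {
      bool first = (n < n_settle + n_block);
      std::vector<cplx> &mx = first ? ex1 : ex2;
      std::vector<cplx> &my = first ? ey1 : ey2;
      for (int q = 0; q < nx * ny; ++q) mx[q] += Ex[q] * pE;
      for (int q = 0; q < nx * (ny - 1); ++q) my[q] += Ey[q] * pE;
    }
    pE *= rot;
  }

  auto packE = [&](std::vector<cplx> &v, int ncol) {
    ComplexMatrix m(nx, ncol);
    for (int j = 0; j < ncol; ++j)
      for (int i = 0; i < nx; ++i) {
        cplx a = v[i + nx * j] * dt;
        m(i, j) = Rcomplex{a.real(), a.imag()};
      }
    return m;
  };
  return List::create(_["map1"] = packE(ex1, ny), _["map2"] = packE(ex2, ny),
                      _["ey1"] = packE(ey1, ny - 1),
                      _["ey2"] = packE(ey2, ny - 1));
}
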