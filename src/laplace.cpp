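// Compiled kernel for the Laplace marginal likelihood.
//
// Mirrors the R reference implementation (.laplace_subject): proportional
// residual error with interaction, log-normal random effects, mode located
// by guarded Newton (analytic d(-loglik)/df, Jacobian of f by central
// differences), Hessian for the Laplace determinant by central differences
// of the gradient. The R version remains the documentation and the oracle;
// this one is called per outer-objective evaluation.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = std::log(2.0 * M_PI);

struct Macro {
  double a, b, k21;
  bool degen;
};

static Macro macro(double cl, double v1, double q, double v2) {
  double k10 = cl / v1, k12 = q / v1, k21 = q / v2;
  double s = k10 + k12 + k21;
  double disc2 = s * s - 4.0 * k10 * k21;
  double disc = disc2 > 0 ? std::sqrt(disc2) : 0.0;
  Macro m;
  m.a = (s + disc) / 2.0;
  m.b = (s - disc) / 2.0;
  m.k21 = k21;
  m.degen = (m.a - m.b) < 1e-10 * m.a;
  return m;
}

static double H_u(double u, const Macro& m) {
  if (u <= 0) return 0.0;
  if (!m.degen) {
    double A = (m.a - m.k21) / (m.a - m.b);
    double B = (m.k21 - m.b) / (m.a - m.b);
    return A * (1.0 - std::exp(-m.a * u)) / m.a +
           B * (1.0 - std::exp(-m.b * u)) / m.b;
  }
  double e = std::exp(-m.a * u);
  return (1.0 - e) / m.a -
         (m.a - m.k21) * (1.0 - e * (1.0 + m.a * u)) / (m.a * m.a);
}

struct Subject {
  std::vector<double> t, y;
  double rate, dur, ce_r, lbm_r, wt_c;
};

// th layout: 0 cl, 1 cl_ce, 2 v1, 3 q, 4 q_lbm, 5 v2, 6 v2_wt (NaN = absent)
// iiv: indices into {0 cl, 1 v1, 2 q, 3 v2}, in eta order
static void predict(const Subject& s, const double* th, const int* iiv,
                    int d, const double* eta, std::vector<double>& f) {
  double cl = th[0], v1 = th[2], q = th[3], v2 = th[5];
  if (!ISNAN(th[1])) cl *= std::pow(s.ce_r, th[1]);
  if (!ISNAN(th[4])) q *= std::pow(s.lbm_r, th[4]);
  if (!ISNAN(th[6])) v2 *= std::exp(th[6] * s.wt_c);
  for (int k = 0; k < d; ++k) {
    double e = std::exp(eta[k]);
    switch (iiv[k]) {
      case 0: cl *= e; break;
      case 1: v1 *= e; break;
      case 2: q *= e; break;
      case 3: v2 *= e; break;
    }
  }
  Macro m = macro(cl, v1, q, v2);
  size_t n = s.t.size();
  f.resize(n);
  for (size_t j = 0; j < n; ++j) {
    double t = s.t[j];
    f[j] = t <= 0 ? 0.0
                  : (s.rate / v1) * (H_u(t, m) - H_u(t - s.dur, m));
  }
}

static double nll_data(const std::vector<double>& y,
                       const std::vector<double>& f, double sigma) {
  double out = 0.0;
  for (size_t j = 0; j < y.size(); ++j) {
    if (!(f[j] > 0.0) || !std::isfinite(f[j])) return R_PosInf;
    double v = sigma * sigma * f[j] * f[j];
    double r = y[j] - f[j];
    out += 0.5 * (r * r / v + std::log(v) + LOG2PI);
  }
  return out;
}

struct Inner {
  const Subject* s;
  const double* th;
  const int* iiv;
  int d;
  const double* omega;
  double sigma;
  std::vector<double> fbuf, fp, fm;

  double g(const double* eta) {
    predict(*s, th, iiv, d, eta, fbuf);
    double out = nll_data(s->y, fbuf, sigma);
    if (!std::isfinite(out)) return R_PosInf;
    for (int k = 0; k < d; ++k)
      out += 0.5 * (eta[k] * eta[k] / (omega[k] * omega[k]) +
                    std::log(omega[k] * omega[k]) + LOG2PI);
    return out;
  }

  void grad(const double* eta, double* gr) {
    const double h = 1e-5;
    predict(*s, th, iiv, d, eta, fbuf);
    size_t n = s->y.size();
    std::vector<double> dldf(n);
    for (size_t j = 0; j < n; ++j) {
      double fj = fbuf[j], r = s->y[j] - fj, s2 = sigma * sigma;
      dldf[j] = -r / (s2 * fj * fj) - r * r / (s2 * fj * fj * fj) + 1.0 / fj;
    }
    std::vector<double> ep(eta, eta + d);
    for (int k = 0; k < d; ++k) {
      ep[k] = eta[k] + h;
      predict(*s, th, iiv, d, ep.data(), fp);
      ep[k] = eta[k] - h;
      predict(*s, th, iiv, d, ep.data(), fm);
      ep[k] = eta[k];
      double acc = 0.0;
      for (size_t j = 0; j < n; ++j)
        acc += dldf[j] * (fp[j] - fm[j]) / (2.0 * h);
      gr[k] = acc + eta[k] / (omega[k] * omega[k]);
    }
  }

  void hess(const double* eta, double* Hm) {  // d x d, column major
    const double h = 1e-4;
    std::vector<double> ep(eta, eta + d), gp(d), gm(d);
    for (int k = 0; k < d; ++k) {
      ep[k] = eta[k] + h;
      grad(ep.data(), gp.data());
      ep[k] = eta[k] - h;
      grad(ep.data(), gm.data());
      ep[k] = eta[k];
      for (int i = 0; i < d; ++i)
        Hm[k * d + i] = (gp[i] - gm[i]) / (2.0 * h);
    }
    for (int i = 0; i < d; ++i)
      for (int k = i + 1; k < d; ++k) {
        double v = 0.5 * (Hm[k * d + i] + Hm[i * d + k]);
        Hm[k * d + i] = Hm[i * d + k] = v;
      }
  }
};

// solve A x = b (d x d, column major) by Gaussian elimination with partial
// pivoting; returns false if singular. A and b are overwritten.
static bool solve_d(int d, double* A, double* b) {
  std::vector<int> piv(d);
  for (int i = 0; i < d; ++i) piv[i] = i;
  for (int c = 0; c < d; ++c) {
    int best = c;
    for (int r = c + 1; r < d; ++r)
      if (std::fabs(A[c * d + r]) > std::fabs(A[c * d + best])) best = r;
    if (std::fabs(A[c * d + best]) < 1e-300) return false;
    if (best != c) {
      for (int cc = 0; cc < d; ++cc) std::swap(A[cc * d + c], A[cc * d + best]);
      std::swap(b[c], b[best]);
    }
    for (int r = c + 1; r < d; ++r) {
      double fct = A[c * d + r] / A[c * d + c];
      for (int cc = c; cc < d; ++cc) A[cc * d + r] -= fct * A[cc * d + c];
      b[r] -= fct * b[c];
    }
  }
  for (int r = d - 1; r >= 0; --r) {
    double acc = b[r];
    for (int cc = r + 1; cc < d; ++cc) acc -= A[cc * d + r] * b[cc];
    b[r] = acc / A[r * d + r];
  }
  return true;
}

static double det_d(int d, const double* Ain) {
  std::vector<double> A(Ain, Ain + d * d);
  double det = 1.0;
  for (int c = 0; c < d; ++c) {
    int best = c;
    for (int r = c + 1; r < d; ++r)
      if (std::fabs(A[c * d + r]) > std::fabs(A[c * d + best])) best = r;
    if (std::fabs(A[c * d + best]) < 1e-300) return 0.0;
    if (best != c) {
      for (int cc = 0; cc < d; ++cc) std::swap(A[cc * d + c], A[cc * d + best]);
      det = -det;
    }
    det *= A[c * d + c];
    for (int r = c + 1; r < d; ++r) {
      double fct = A[c * d + r] / A[c * d + c];
      for (int cc = c; cc < d; ++cc) A[cc * d + r] -= fct * A[cc * d + c];
    }
  }
  return det;
}

// guarded Newton from start; returns true on success (gradient ~ 0)
static bool newton(Inner& in, std::vector<double>& eta, double& gval) {
  int d = in.d;
  gval = in.g(eta.data());
  if (!std::isfinite(gval)) return false;
  std::vector<double> gr(d), H(d * d), step(d), cand(d);
  for (int it = 0; it < 25; ++it) {
    in.grad(eta.data(), gr.data());
    double nrm = 0.0;
    for (int k = 0; k < d; ++k) nrm += gr[k] * gr[k];
    if (std::sqrt(nrm) < 1e-10) return true;
    in.hess(eta.data(), H.data());
    step = gr;
    std::vector<double> Hc(H);
    if (!solve_d(d, Hc.data(), step.data())) return false;
    bool ok = false;
    for (int half = 0; half < 8; ++half) {
      double scale = 1.0 / double(1 << half);
      for (int k = 0; k < d; ++k) cand[k] = eta[k] - scale * step[k];
      double gc = in.g(cand.data());
      if (std::isfinite(gc) && gc <= gval + 1e-12) {
        eta = cand;
        gval = gc;
        ok = true;
        break;
      }
    }
    if (!ok) break;
  }
  in.grad(eta.data(), gr.data());
  double nrm = 0.0;
  for (int k = 0; k < in.d; ++k) nrm += gr[k] * gr[k];
  return std::sqrt(nrm) < 1e-6;
}

// [[Rcpp::export(name = ".ofv_all_cpp")]]
List ofv_all_cpp(List subjects, NumericVector th, IntegerVector iiv,
                 NumericVector omega, double sigma, NumericMatrix warm) {
  int nsub = subjects.size();
  int d = iiv.size();
  NumericMatrix eta_out(nsub, d);
  double total = 0.0;
  bool failed = false;

  for (int i = 0; i < nsub && !failed; ++i) {
    List sl = subjects[i];
    Subject s;
    s.t = as<std::vector<double> >(sl["t"]);
    s.y = as<std::vector<double> >(sl["y"]);
    s.rate = as<double>(sl["rate"]);
    s.dur = as<double>(sl["dur"]);
    s.ce_r = as<double>(sl["ce_r"]);
    s.lbm_r = as<double>(sl["lbm_r"]);
    s.wt_c = as<double>(sl["wt_c"]);

    if (d == 0) {
      std::vector<double> f;
      predict(s, th.begin(), nullptr, 0, nullptr, f);
      double nll = nll_data(s.y, f, sigma);
      if (!std::isfinite(nll)) { failed = true; break; }
      total += 2.0 * nll;
      continue;
    }

    Inner in;
    in.s = &s;
    in.th = th.begin();
    in.iiv = iiv.begin();
    in.d = d;
    in.omega = omega.begin();
    in.sigma = sigma;

    std::vector<double> eta(d);
    for (int k = 0; k < d; ++k) eta[k] = warm(i, k);
    double gval;
    bool ok = newton(in, eta, gval);
    if (!ok) {
      std::fill(eta.begin(), eta.end(), 0.0);
      ok = newton(in, eta, gval);
    }
    if (!ok) {
      // coarse grid fall-back around zero, then Newton
      double best = R_PosInf;
      std::vector<double> beta(d, 0.0), cand(d);
      int npts = 9;
      std::vector<int> idx(d, 0);
      bool done = false;
      while (!done) {
        for (int k = 0; k < d; ++k)
          cand[k] = (idx[k] - (npts - 1) / 2.0) * omega[k];
        double gc = in.g(cand.data());
        if (gc < best) { best = gc; beta = cand; }
        int k = 0;
        while (k < d && ++idx[k] == npts) { idx[k] = 0; ++k; }
        done = (k == d);
      }
      eta = beta;
      ok = newton(in, eta, gval);
      if (!ok) { failed = true; break; }
    }
    std::vector<double> H(d * d);
    in.hess(eta.data(), H.data());
    double det = det_d(d, H.data());
    if (!(det > 0.0) || !std::isfinite(det)) {
      det = 1.0;
      for (int k = 0; k < d; ++k) det /= omega[k] * omega[k];
    }
    total += 2.0 * gval + std::log(det) - d * LOG2PI;
    for (int k = 0; k < d; ++k) eta_out(i, k) = eta[k];
  }

  return List::create(_["ofv"] = failed ? R_PosInf : total,
                      _["eta"] = eta_out,
                      _["failed"] = failed);
}
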