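// Fast path for batch-culture simulation: evaluates the packed rate laws
// (mirroring the R reference engine in kinetics.R) and integrates the mass
// balances with an adaptive Dormand-Prince 5(4) scheme. The model arrives
// as flat arrays packed in R (see .pack_model), so this file knows nothing
// about reaction identities.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  int ns, nr;
  std::vector<double> S;          // ns x nr dense, column-major
  std::vector<int> kind, dil;
  std::vector<double> vmax_f, vmax_r;
  int growth;
  double mw;
  // factors
  std::vector<int> fr, fd, ft, fi1, fi2;
  std::vector<double> fc1, fc2;
  // pools
  std::vector<int> pool_off, pool_len, pool_sp;
  // sparse stoichiometry triplets
  std::vector<int> t_s, t_r;
  std::vector<double> t_v;
  // scratch buffers (avoid per-evaluation allocation)
  mutable std::vector<double> buf_fw, buf_rv, buf_xc, buf_acc;

  explicit Model(const List& pack) {
    NumericMatrix Sm = pack["S"];
    ns = Sm.nrow(); nr = Sm.ncol();
    S.assign(Sm.begin(), Sm.end());
    kind = as<std::vector<int> >(pack["kind"]);
    dil = as<std::vector<int> >(pack["dil"]);
    vmax_f = as<std::vector<double> >(pack["vmax_f"]);
    vmax_r = as<std::vector<double> >(pack["vmax_r"]);
    growth = as<int>(pack["growth"]);
    mw = as<double>(pack["mw"]);
    fr = as<std::vector<int> >(pack["fr"]);
    fd = as<std::vector<int> >(pack["fd"]);
    ft = as<std::vector<int> >(pack["ft"]);
    fi1 = as<std::vector<int> >(pack["fi1"]);
    fi2 = as<std::vector<int> >(pack["fi2"]);
    fc1 = as<std::vector<double> >(pack["fc1"]);
    fc2 = as<std::vector<double> >(pack["fc2"]);
    pool_off = as<std::vector<int> >(pack["pool_off"]);
    pool_len = as<std::vector<int> >(pack["pool_len"]);
    pool_sp = as<std::vector<int> >(pack["pool_sp"]);
    for (int r = 0; r < nr; ++r)
      for (int s = 0; s < ns; ++s) {
        double v = S[s + ns * r];
        if (v != 0.0) { t_s.push_back(s); t_r.push_back(r); t_v.push_back(v); }
      }
    buf_fw.resize(nr); buf_rv.resize(nr);
    buf_xc.resize(ns); buf_acc.resize(ns);
  }

  void fluxes(const double* x, double* v) const {
    std::vector<double>& fw = buf_fw;
    std::vector<double>& rv = buf_rv;
    std::copy(vmax_f.begin(), vmax_f.end(), fw.begin());
    std::copy(vmax_r.begin(), vmax_r.end(), rv.begin());
    const size_t nf = fr.size();
    for (size_t k = 0; k < nf; ++k) {
      double f = 1.0;
      switch (ft[k]) {
      case 1: { double c = x[fi1[k]]; f = c / (fc1[k] + c); break; }
      case 2: { double c = 0; int o = pool_off[fi1[k]], L = pool_len[fi1[k]];
                for (int j = 0; j < L; ++j) c += x[pool_sp[o + j]];
                f = c / (fc1[k] + c); break; }
      case 3: { int o = pool_off[fi1[k]], L = pool_len[fi1[k]];
                for (int j = 0; j < L; ++j) {
                  double c = x[pool_sp[o + j]];
                  f *= c / (fc1[k] + c);
                }
                break; }
      case 4: { double r = x[fi1[k]] / std::max(x[fi2[k]], 1e-12);
                f = r / (fc1[k] + r); break; }
      case 5: { double r = x[fi1[k]] / std::max(x[fi2[k]], 1e-12);
                f = r / (1.0 + r); break; }
      case 6: f = 1.0 / (1.0 + x[fi1[k]] / fc1[k]); break;
      case 7: { double c = x[fi1[k]]; f = c / (fc1[k] + c); break; }
      case 8: { double r = x[fi1[k]] / fc1[k];
                double rp = (fc2[k] == 4.0) ? (r * r) * (r * r)
                                            : std::pow(r, fc2[k]);
                f = 1.0 / (1.0 + rp); break; }
      case 9: { double c = std::max(fc2[k] - x[fi1[k]], 0.0);
                f = c / (fc1[k] + c); break; }
      default: Rcpp::stop("unknown factor type");
      }
      if (fd[k] == 0) fw[fr[k]] *= f; else rv[fr[k]] *= f;
    }
    for (int r = 0; r < nr; ++r) v[r] = fw[r] - rv[r];
  }

  void rhs(const double* y, double* dy, double* vbuf) const {
    std::vector<double>& xc = buf_xc;
    for (int i = 0; i < ns; ++i) xc[i] = y[i] > 0.0 ? y[i] : 0.0;
    fluxes(xc.data(), vbuf);
    std::vector<double>& acc = buf_acc;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (size_t k = 0; k < t_s.size(); ++k)
      acc[t_s[k]] += t_v[k] * vbuf[t_r[k]];
    const double Xv = xc[0];
    const double mu = vbuf[growth];
    for (int i = 0; i < ns; ++i) {
      switch (kind[i]) {
      case 0: dy[i] = acc[i] * Xv; break;                 // cell density
      case 1: dy[i] = acc[i] * Xv * 1000.0; break;        // mM extracellular
      case 2: dy[i] = acc[i] * 1e6 - (dil[i] ? mu * xc[i] : 0.0); break;
      case 3: dy[i] = acc[i] * Xv * 1000.0 * mw; break;   // mAb titer, mg/L
      default: Rcpp::stop("unknown species kind");
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_fluxes(List pack, NumericMatrix states) {
  Model m(pack);
  const int nt = states.nrow();
  NumericMatrix out(nt, m.nr);
  std::vector<double> x(m.ns), v(m.nr);
  for (int t = 0; t < nt; ++t) {
    for (int i = 0; i < m.ns; ++i) x[i] = std::max(states(t, i), 0.0);
    m.fluxes(x.data(), v.data());
    for (int r = 0; r < m.nr; ++r) out(t, r) = v[r];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate(List pack, NumericVector y0, NumericVector times,
                  double rtol, double atol, double hmax, int maxsteps) {
  Model m(pack);
  const int ns = m.ns, nt = times.size();
  // Dormand-Prince 5(4) tableau
  static const double
    a21 = 1.0 / 5,
    a31 = 3.0 / 40, a32 = 9.0 / 40,
    a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9,
    a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
    a54 = -212.0 / 729,
    a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
    a64 = 49.0 / 176, a65 = -5103.0 / 18656,
    b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
    b5 = -2187.0 / 6784, b6 = 11.0 / 84,
    e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  NumericMatrix out(nt, ns);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns), k7(ns),
    yt(ns), y5(ns), err(ns), vbuf(m.nr);
  double t = times[0];
  for (int i = 0; i < ns; ++i) out(0, i) = y[i];

  double h = std::min(1e-3, hmax);
  int step = 0, iout = 1;
  bool have_k1 = false, rejected = false;
  double errold = 1e-4;
  while (iout < nt) {
    if (++step > maxsteps)
      return List::create(_["ok"] = false, _["t"] = t,
                          _["msg"] = "maximum step count exceeded",
                          _["states"] = out);
    double tnext = times[iout];
    if (t + h > tnext) h = tnext - t;
    if (!have_k1) { m.rhs(y.data(), k1.data(), vbuf.data()); have_k1 = true; }

    for (int i = 0; i < ns; ++i) yt[i] = y[i] + h * a21 * k1[i];
    m.rhs(yt.data(), k2.data(), vbuf.data());
    for (int i = 0; i < ns; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    m.rhs(yt.data(), k3.data(), vbuf.data());
    for (int i = 0; i < ns; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    m.rhs(yt.data(), k4.data(), vbuf.data());
    for (int i = 0; i < ns; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    m.rhs(yt.data(), k5.data(), vbuf.data());
    for (int i = 0; i < ns; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    m.rhs(yt.data(), k6.data(), vbuf.data());
    for (int i = 0; i < ns; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    m.rhs(y5.data(), k7.data(), vbuf.data());

    double errnorm = 0.0;
    bool bad = false;
    for (int i = 0; i < ns; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double q = e / sc;
      errnorm += q * q;
      if (!std::isfinite(y5[i])) bad = true;
    }
    errnorm = std::sqrt(errnorm / ns);
    if (bad)
      return List::create(_["ok"] = false, _["t"] = t,
                          _["msg"] = "non-finite state during integration",
                          _["states"] = out);
    // PI step control (Gustafsson): damps accept/reject oscillation near
    // the stability boundary of the explicit scheme
    double en = std::max(errnorm, 1e-10);
    double fac = 0.9 * std::pow(en, -0.14) * std::pow(errold, 0.08);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < ns; ++i) y[i] = std::max(y5[i], 0.0);
      k1 = k7;  // FSAL
      have_k1 = true;
      if (t >= tnext - 1e-12) {
        for (int i = 0; i < ns; ++i) out(iout, i) = y[i];
        ++iout;
      }
      if (rejected && fac > 1.0) fac = 1.0;  // cautious growth after reject
      rejected = false;
      errold = en;
    } else {
      have_k1 = true;  // k1 still valid at unchanged (t, y)
      rejected = true;
      if (fac > 1.0) fac = 1.0;
    }
    h *= fac;
    if (h > hmax) h = hmax;
    if (h < 1e-10)
      return List::create(_["ok"] = false, _["t"] = t,
                          _["msg"] = "step size underflow",
                          _["states"] = out);
  }
  return List::create(_["ok"] = true, _["t"] = t, _["msg"] = "",
                      _["steps"] = step, _["states"] = out);
}
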