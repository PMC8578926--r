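// Reduced-order hemodynamic network solver.
//
// Time-varying elastance left ventricle coupled through an ideal-diode aortic
// valve to a lumped-ladder ("Pi"-element) arterial network with three-element
// Windkessel terminal loads.  All quantities here are SI (Pa, m^3, s); unit
// conversion happens in the R wrapper.  Explicit RK4 with fixed step; the run
// stops when the maximum cycle-to-cycle node-pressure change drops below the
// convergence tolerance.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::NumericMatrix;

namespace {

struct Net {
  int N, B, K;                       // nodes, branches, terminals
  std::vector<int> u, v;             // branch endpoints (0-based node ids)
  std::vector<double> R, L;          // branch resistance / inertance
  std::vector<double> Cn;            // node capacitance
  std::vector<int> tnode;            // terminal node ids
  std::vector<double> Rc, Rp, Ct;    // Windkessel elements
  double Pout;                       // distal venous pressure
};

struct Vent {
  double Ees, Eed, Vd, Pfill, tes, tr, Rven, Rvalve, T;
};

// reduce t into [0, T) (portable stand-in for fmod on positive arguments)
inline double cycle_time(double t, double T) {
  double r = t - T * std::floor(t / T);
  return (r >= T) ? r - T : r;
}

// raised-cosine normalized elastance, peak 1 at t = tes, zero after tes + tr
inline double e_norm(double t, double tes, double tr) {
  if (t <= tes) return 0.5 * (1.0 - std::cos(M_PI * t / tes));
  if (t <= tes + tr) return 0.5 * (1.0 + std::cos(M_PI * (t - tes) / tr));
  return 0.0;
}

// state layout: [V, P_node(0..N-1), Q_branch(0..B-1), P_wk(0..K-1)]
inline void deriv(double t, const double* y, double* dy,
                  const Net& net, const Vent& vt,
                  std::vector<double>& net_flow) {
  const int N = net.N, B = net.B, K = net.K;
  const double* P = y + 1;
  const double* Q = y + 1 + N;
  const double* Pw = y + 1 + N + B;
  double* dP = dy + 1;
  double* dQ = dy + 1 + N;
  double* dPw = dy + 1 + N + B;

  const double tc = cycle_time(t, vt.T);
  const double E = vt.Eed + (vt.Ees - vt.Eed) * e_norm(tc, vt.tes, vt.tr);
  const double Plv = E * (y[0] - vt.Vd);
  const double Qin = (vt.Pfill > Plv) ? (vt.Pfill - Plv) / vt.Rven : 0.0;
  const double Qout = (Plv > P[0]) ? (Plv - P[0]) / vt.Rvalve : 0.0;
  dy[0] = Qin - Qout;

  std::fill(net_flow.begin(), net_flow.end(), 0.0);
  net_flow[0] += Qout;
  for (int b = 0; b < B; ++b) {
    const double q = Q[b];
    net_flow[net.u[b]] -= q;
    net_flow[net.v[b]] += q;
    dQ[b] = (P[net.u[b]] - P[net.v[b]] - net.R[b] * q) / net.L[b];
  }
  for (int k = 0; k < K; ++k) {
    const int m = net.tnode[k];
    const double qt = (P[m] - Pw[k]) / net.Rc[k];
    net_flow[m] -= qt;
    dPw[k] = (qt - (Pw[k] - net.Pout) / net.Rp[k]) / net.Ct[k];
  }
  for (int n = 0; n < N; ++n) dP[n] = net_flow[n] / net.Cn[n];
}

// linear interpolation of one periodically recorded series onto nq uniform
// query times over [0, T)
void resample_periodic(const std::vector<double>& rec, double t_step,
                       double T, int nq, double* out) {
  const int m = static_cast<int>(rec.size());
  for (int k = 0; k < nq; ++k) {
    const double tq = T * k / nq;
    const double pos = tq / t_step;
    int i0 = static_cast<int>(std::floor(pos));
    const double w = pos - i0;
    const double y0 = rec[i0 % m];
    const double y1 = rec[(i0 + 1) % m];
    out[k] = y0 * (1.0 - w) + y1 * w;
  }
}

} // namespace

// [[Rcpp::export]]
List hemo_simulate_cpp(List network, List ventricle, List settings,
                       IntegerVector record_nodes,
                       IntegerVector record_branches) {
  Net net;
  {
    IntegerVector u = network["u"], v = network["v"], tn = network["term_node"];
    NumericVector R = network["R"], L = network["L"], Cn = network["Cnode"];
    NumericVector Rc = network["term_Rc"], Rp = network["term_Rp"],
                  Ct = network["term_Ct"];
    net.B = u.size(); net.N = Cn.size(); net.K = tn.size();
    net.u.assign(u.begin(), u.end());
    net.v.assign(v.begin(), v.end());
    net.R.assign(R.begin(), R.end());
    net.L.assign(L.begin(), L.end());
    net.Cn.assign(Cn.begin(), Cn.end());
    net.tnode.assign(tn.begin(), tn.end());
    net.Rc.assign(Rc.begin(), Rc.end());
    net.Rp.assign(Rp.begin(), Rp.end());
    net.Ct.assign(Ct.begin(), Ct.end());
    net.Pout = Rcpp::as<double>(network["P_out"]);
  }
  Vent vt;
  vt.Ees = ventricle["Ees"];   vt.Eed = ventricle["Eed"];
  vt.Vd = ventricle["Vd"];     vt.Pfill = ventricle["Pfill"];
  vt.tes = ventricle["tes"];   vt.tr = ventricle["tr"];
  vt.Rven = ventricle["Rven"]; vt.Rvalve = ventricle["Rvalve"];
  vt.T = ventricle["T"];
  if (vt.tes + vt.tr >= vt.T)
    Rcpp::stop("systole (tes + tes/2) is not shorter than the cardiac cycle");

  const double dt_req = Rcpp::as<double>(settings["dt"]);
  const int n_cycles_max = Rcpp::as<int>(settings["n_cycles_max"]);
  const double tol = Rcpp::as<double>(settings["convergence_tol"]);
  const int nr = Rcpp::as<int>(settings["output_rate"]);
  const double P0 = Rcpp::as<double>(settings["init_pressure"]);

  const int spc = std::max(16, static_cast<int>(std::lround(vt.T / dt_req)));
  const double dt = vt.T / spc;

  const int S = 1 + net.N + net.B + net.K;
  std::vector<double> y(S), k1(S), k2(S), k3(S), k4(S), tmp(S), nf(net.N);
  y[0] = vt.Vd + vt.Pfill / vt.Eed;
  for (int n = 0; n < net.N; ++n) y[1 + n] = P0;
  for (int b = 0; b < net.B; ++b) y[1 + net.N + b] = 0.0;
  for (int k = 0; k < net.K; ++k) y[1 + net.N + net.B + k] = P0;

  // per-cycle recording (overwritten each cycle), stride keeps <= ~1200 pts
  const int stride = std::max(1, spc / 1000);
  const int rec_len = (spc + stride - 1) / stride;
  const int nrn = record_nodes.size(), nrb = record_branches.size();
  std::vector<std::vector<double>> recP(nrn, std::vector<double>(rec_len)),
      recQ(nrb, std::vector<double>(rec_len)),
      recQt(net.K, std::vector<double>(rec_len));
  std::vector<double> recLvP(rec_len), recLvV(rec_len), recQav(rec_len);

  // convergence probe: all node pressures at 64 points per cycle
  const int ncmp = 64;
  std::vector<double> probe(net.N * ncmp, 0.0), probe_prev(net.N * ncmp, 0.0);
  std::vector<int> cmp_step(ncmp);
  for (int j = 0; j < ncmp; ++j) cmp_step[j] = (int)((long long)j * spc / ncmp);

  NumericVector conv_hist(n_cycles_max, NA_REAL);
  bool converged = false, diverged = false;
  int cycles_run = 0;

  for (int cyc = 0; cyc < n_cycles_max && !converged && !diverged; ++cyc) {
    int cmp_i = 0, rec_i = 0;
    for (int s = 0; s < spc; ++s) {
      const double t = cyc * vt.T + s * dt;
      if (s % stride == 0 && rec_i < rec_len) {
        const double tc = cycle_time(t, vt.T);
        const double E = vt.Eed + (vt.Ees - vt.Eed) * e_norm(tc, vt.tes, vt.tr);
        const double Plv = E * (y[0] - vt.Vd);
        for (int i = 0; i < nrn; ++i) recP[i][rec_i] = y[1 + record_nodes[i]];
        for (int i = 0; i < nrb; ++i) recQ[i][rec_i] = y[1 + net.N + record_branches[i]];
        for (int k = 0; k < net.K; ++k)
          recQt[k][rec_i] = (y[1 + net.tnode[k]] - y[1 + net.N + net.B + k]) / net.Rc[k];
        recLvP[rec_i] = Plv;
        recLvV[rec_i] = y[0];
        recQav[rec_i] = (Plv > y[1]) ? (Plv - y[1]) / vt.Rvalve : 0.0;
        ++rec_i;
      }
      if (cmp_i < ncmp && s == cmp_step[cmp_i]) {
        for (int n = 0; n < net.N; ++n) probe[cmp_i * net.N + n] = y[1 + n];
        ++cmp_i;
      }
      // RK4 step
      deriv(t, y.data(), k1.data(), net, vt, nf);
      for (int i = 0; i < S; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
      deriv(t + 0.5 * dt, tmp.data(), k2.data(), net, vt, nf);
      for (int i = 0; i < S; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
      deriv(t + 0.5 * dt, tmp.data(), k3.data(), net, vt, nf);
      for (int i = 0; i < S; ++i) tmp[i] = y[i] + dt * k3[i];
      deriv(t + dt, tmp.data(), k4.data(), net, vt, nf);
      for (int i = 0; i < S; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

      if ((s & 63) == 0) {
        const double pr = y[1];
        if (!std::isfinite(pr) || std::fabs(pr) > 1.0e8 || !std::isfinite(y[0])) {
          diverged = true;
          break;
        }
      }
    }
    cycles_run = cyc + 1;
    if (!diverged && cyc >= 1) {
      double md = 0.0;
      for (size_t i = 0; i < probe.size(); ++i)
        md = std::max(md, std::fabs(probe[i] - probe_prev[i]));
      conv_hist[cyc] = md;
      if (md <= tol) converged = true;
    }
    probe_prev = probe;
  }

  NumericMatrix P_out_m(nr, nrn), Q_out_m(nr, nrb), Qt_out_m(nr, net.K);
  NumericVector lv_p(nr), lv_v(nr), q_valve(nr), time_out(nr);
  if (!diverged) {
    const double t_step = stride * dt;
    for (int i = 0; i < nrn; ++i)
      resample_periodic(recP[i], t_step, vt.T, nr, &P_out_m(0, i));
    for (int i = 0; i < nrb; ++i)
      resample_periodic(recQ[i], t_step, vt.T, nr, &Q_out_m(0, i));
    for (int k = 0; k < net.K; ++k)
      resample_periodic(recQt[k], t_step, vt.T, nr, &Qt_out_m(0, k));
    resample_periodic(recLvP, t_step, vt.T, nr, &lv_p[0]);
    resample_periodic(recLvV, t_step, vt.T, nr, &lv_v[0]);
    resample_periodic(recQav, t_step, vt.T, nr, &q_valve[0]);
  }
  for (int k = 0; k < nr; ++k) time_out[k] = vt.T * k / nr;

  return List::create(
      Rcpp::Named("pressure") = P_out_m, Rcpp::Named("flow") = Q_out_m,
      Rcpp::Named("terminal_flow") = Qt_out_m, Rcpp::Named("lv_pressure") = lv_p,
      Rcpp::Named("lv_volume") = lv_v, Rcpp::Named("valve_flow") = q_valve,
      Rcpp::Named("time") = time_out, Rcpp::Named("converged") = converged,
      Rcpp::Named("diverged") = diverged, Rcpp::Named("cycles_run") = cycles_run,
      Rcpp::Named("conv_history") = conv_hist, Rcpp::Named("dt_used") = dt);
}
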