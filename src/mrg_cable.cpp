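// Implicit (backward-Euler) integrator for an MRG-type double-cable
// myelinated axon under extracellular stimulation.
//
// State per compartment: axolemma membrane potential Vm (mV) and, for
// internodal compartments, the periaxonal potential Vp (mV) between the
// axolemma and the myelin sheath.  Nodes of Ranvier have no myelin; their
// periaxonal variable is pinned to zero (shorted to the extracellular bath).
// Nodal membrane carries fast Na+, persistent Na+, slow K+ and linear leak
// conductances; internodal axolemma is passive; the myelin sheath is an RC
// layer whose specific capacitance and conductance are divided by twice the
// lamella count (two membranes per lamella).
//
// Units: mV, ms, nF, uS, nA, MOhm, um.  The linear system solved each step
// is banded (half-bandwidth 3) with unknowns interleaved as
// [Vm_0, Vp_0, Vm_1, Vp_1, ...]; gating variables are advanced by
// exponential Euler using steady-state / relaxation-factor lookup tables
// precomputed on a voltage grid for the fixed step size.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

static const double V_REST = -80.0;
static const double E_NA = 50.0, E_K = -90.0;
static const double G_NAF = 3.0, G_NAP = 0.01, G_KS = 0.08, G_L = 0.007; // S/cm2
static const double CM = 2.0;          // uF/cm2, axolemma (all section types)
static const double MY_CM = 0.1;       // uF/cm2 per lamella membrane
static const double MY_GM = 0.001;     // S/cm2 per lamella membrane
static const double RHO_A = 0.7;       // MOhm*um axoplasm / periaxonal resistivity

// x / (1 - exp(-x/y)), guarded at x -> 0
static inline double vtrap(double x, double y) {
  double r = x / y;
  if (std::fabs(r) < 1e-6) return y * (1.0 + r / 2.0);
  return x / (1.0 - std::exp(-r));
}

struct Rates { double am, bm, ah, bh, ap, bp, as_, bs; };

static inline Rates rates(double v) {
  Rates r;
  r.am = 6.57 * vtrap(v + 20.4, 10.3);
  r.bm = 0.304 * vtrap(-(v + 25.7), 9.16);
  r.ah = 0.34 * vtrap(-(v + 114.0), 11.0);
  r.bh = 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));
  r.ap = 0.0353 * vtrap(v + 27.0, 10.2);
  r.bp = 0.000883 * vtrap(-(v + 34.0), 10.0);
  r.as_ = 0.3 / (1.0 + std::exp(-(v + 53.0) / 5.0));
  r.bs = 0.03 / (1.0 + std::exp(-(v + 90.0) / 1.0));
  return r;
}

// Gating lookup tables on a voltage grid: steady state xinf and relaxation
// factor exp(-dt / tau) for each of the four nodal gates.
struct GateTables {
  double v0, dv_inv;
  int npts;
  std::vector<double> inf[4], rel[4];
  void build(double dt) {
    v0 = -160.0; double v1 = 120.0, dv = 0.02;
    dv_inv = 1.0 / dv;
    npts = (int)((v1 - v0) / dv) + 1;
    for (int g = 0; g < 4; ++g) { inf[g].resize(npts); rel[g].resize(npts); }
    for (int i = 0; i < npts; ++i) {
      double v = v0 + i / dv_inv;
      Rates r = rates(v);
      double a[4] = { r.am, r.ah, r.ap, r.as_ };
      double b[4] = { r.bm, r.bh, r.bp, r.bs };
      for (int g = 0; g < 4; ++g) {
        double tau = 1.0 / (a[g] + b[g]);
        inf[g][i] = a[g] * tau;
        rel[g][i] = std::exp(-dt / tau);
      }
    }
  }
  inline void lookup(double v, double out_inf[4], double out_rel[4]) const {
    double x = (v - v0) * dv_inv;
    if (x < 0) x = 0;
    if (x > npts - 1.001) x = npts - 1.001;
    int i = (int)x;
    double w = x - i;
    for (int g = 0; g < 4; ++g) {
      out_inf[g] = inf[g][i] + w * (inf[g][i + 1] - inf[g][i]);
      out_rel[g] = rel[g][i] + w * (rel[g][i + 1] - rel[g][i]);
    }
  }
};

// Banded LU (no pivoting; the system is diagonally dominant) with
// half-bandwidth KB.  Row-major storage: band[i * 7 + (j - i + KB)] holds
// A(i, j), keeping each row's seven entries contiguous.
static const int KB = 3;
#define BAND(A, i, j) A[(size_t)(i) * 7 + ((j) - (i) + KB)]

// After factorization the main diagonal stores the *inverse* pivot, so the
// solve needs no divisions.
static void band_factor(std::vector<double>& A, int n) {
  for (int k = 0; k < n; ++k) {
    double pivinv = 1.0 / BAND(A, k, k);
    BAND(A, k, k) = pivinv;
    int imax = std::min(k + KB, n - 1);
    for (int i = k + 1; i <= imax; ++i) {
      double &aik = BAND(A, i, k);
      double l = aik * pivinv;
      aik = l;
      int jmax = std::min(k + KB, n - 1);
      for (int j = k + 1; j <= jmax; ++j)
        BAND(A, i, j) -= l * BAND(A, k, j);
    }
  }
}

static void band_solve(const std::vector<double>& A, int n, std::vector<double>& b) {
  for (int i = 0; i < n; ++i) {
    int kmin = std::max(0, i - KB);
    double s = b[i];
    for (int k = kmin; k < i; ++k) s -= BAND(A, i, k) * b[k];
    b[i] = s;
  }
  for (int i = n - 1; i >= 0; --i) {
    int jmax = std::min(n - 1, i + KB);
    double s = b[i];
    for (int j = i + 1; j <= jmax; ++j) s -= BAND(A, i, j) * b[j];
    b[i] = s * BAND(A, i, i);
  }
}

// [[Rcpp::export(name = ".mrg_simulate_cpp")]]
List mrg_simulate_cpp(IntegerVector type,       // 0 node, 1 MYSA, 2 FLUT, 3 STIN
                      NumericVector len_um,     // compartment length
                      NumericVector diam_um,    // local axolemma diameter
                      double fiber_diam_um,     // outer fiber diameter
                      double n_lamella,
                      NumericVector peri_w_um,  // periaxonal space width
                      NumericVector ve_unit_V,  // unit extracellular potential
                      double amplitude,         // drive amplitude (mA or V)
                      NumericVector envelope,   // pulse envelope in [0, 1]
                      double env_dt_us,
                      double dt_ms,
                      double duration_ms,
                      IntegerVector record_idx, // 0-based compartments: spikes
                      double spike_thresh_mV,
                      bool record_trace,
                      bool early_stop,          // stop when quiescent / spiked
                      double pulse_end_ms,      // end of last pulse (for early_stop)
                      NumericVector onsets_ms,  // pulse onsets (train early stop)
                      bool early_stop_train) {  // stop once 80% criterion decided
  const int n = type.size();
  const int N = 2 * n;
  const double dt = dt_ms;

  // ---- per-compartment electrical constants ----
  std::vector<double> cm(n), cmy(n), gmy(n), gpas(n), ga_half(n), gp_half(n);
  for (int i = 0; i < n; ++i) {
    double A_cm2 = M_PI * diam_um[i] * len_um[i] * 1e-8;
    cm[i] = CM * A_cm2 * 1e3;                       // nF
    if (type[i] == 0) {
      cmy[i] = 0.0; gmy[i] = 0.0; gpas[i] = 0.0;
    } else {
      double Amy = M_PI * fiber_diam_um * len_um[i] * 1e-8;
      double nmemb = 2.0 * n_lamella;
      cmy[i] = (MY_CM / nmemb) * Amy * 1e3;         // nF
      gmy[i] = (MY_GM / nmemb) * Amy * 1e6;         // uS
      double gsp = (type[i] == 1) ? 0.001 : 0.0001; // S/cm2 MYSA vs FLUT/STIN
      gpas[i] = gsp * A_cm2 * 1e6;                  // uS
    }
    double Ra_half = RHO_A * (len_um[i] / 2.0) / (M_PI * diam_um[i] * diam_um[i] / 4.0);
    ga_half[i] = 1.0 / Ra_half;
    double rad = diam_um[i] / 2.0;
    double ann = M_PI * ((rad + peri_w_um[i]) * (rad + peri_w_um[i]) - rad * rad);
    double Rp_half = RHO_A * (len_um[i] / 2.0) / ann;
    gp_half[i] = 1.0 / Rp_half;
  }
  std::vector<double> ga(n > 1 ? n - 1 : 0), gp(n > 1 ? n - 1 : 0);
  for (int i = 0; i + 1 < n; ++i) {
    ga[i] = 1.0 / (1.0 / ga_half[i] + 1.0 / ga_half[i + 1]);
    gp[i] = 1.0 / (1.0 / gp_half[i] + 1.0 / gp_half[i + 1]);
  }

  // nodal conductances (uS) and leak reversal balancing rest exactly
  std::vector<int> node_ids;
  std::vector<double> gnaf(n, 0.0), gnap(n, 0.0), gks(n, 0.0), gl(n, 0.0);
  Rates r0 = rates(V_REST);
  double m0 = r0.am / (r0.am + r0.bm), h0 = r0.ah / (r0.ah + r0.bh);
  double p0 = r0.ap / (r0.ap + r0.bp), s0 = r0.as_ / (r0.as_ + r0.bs);
  double e_leak;
  {
    double ina = G_NAF * m0 * m0 * m0 * h0 * (V_REST - E_NA) +
                 G_NAP * p0 * p0 * p0 * (V_REST - E_NA);
    double ik = G_KS * s0 * (V_REST - E_K);
    e_leak = V_REST + (ina + ik) / G_L;
  }
  for (int i = 0; i < n; ++i) {
    if (type[i] == 0) {
      double A_cm2 = M_PI * diam_um[i] * len_um[i] * 1e-8;
      gnaf[i] = G_NAF * A_cm2 * 1e6;
      gnap[i] = G_NAP * A_cm2 * 1e6;
      gks[i] = G_KS * A_cm2 * 1e6;
      gl[i] = G_L * A_cm2 * 1e6;
      node_ids.push_back(i);
    }
  }
  const int nnode = (int)node_ids.size();

  GateTables tab;
  tab.build(dt);

  // ---- constant part of the banded matrix and field-coupling vectors ----
  // template holds everything except the nodal ionic conductance, which is
  // added to the nodal Vm diagonal each step.
  std::vector<double> band0(7 * (size_t)N, 0.0);
  std::vector<double> fldA(n, 0.0), fldP(n, 0.0); // sum g*(veu_j - veu_i)
  for (int i = 0; i < n; ++i) {
    int rm = 2 * i, rp = 2 * i + 1;
    double gsum_a = 0.0, gsum_p = 0.0;
    for (int d = -1; d <= 1; d += 2) {
      int j = i + d;
      if (j < 0 || j >= n) continue;
      double gaij = ga[std::min(i, j)];
      gsum_a += gaij;
      fldA[i] += gaij * (ve_unit_V[j] - ve_unit_V[i]);
      BAND(band0, rm, 2 * j) -= gaij;
      BAND(band0, rm, 2 * j + 1) -= gaij;
      if (type[i] != 0) {
        double gpij = gp[std::min(i, j)];
        gsum_p += gpij;
        fldP[i] += gpij * (ve_unit_V[j] - ve_unit_V[i]);
        BAND(band0, rp, 2 * j + 1) -= gpij;
      }
    }
    BAND(band0, rm, rm) += cm[i] / dt + gsum_a;   // + gt added per step
    BAND(band0, rm, rp) += gsum_a;
    if (type[i] == 0) {
      BAND(band0, rp, rp) = 1.0;                  // Vp_i = 0
    } else {
      BAND(band0, rm, rm) += gpas[i];
      BAND(band0, rp, rm) -= cm[i] / dt + gpas[i];
      BAND(band0, rp, rp) += cmy[i] / dt + gmy[i] + gsum_p;
    }
  }

  // ---- state ----
  std::vector<double> Vm(n, V_REST), Vp(n, 0.0);
  std::vector<double> m(n, m0), h(n, h0), p(n, p0), s(n, s0);

  const int nt = (int)std::lround(duration_ms / dt);
  const int nrec = record_idx.size();
  std::vector<std::vector<double> > spikes(nrec);
  std::vector<double> last_spike(nrec, -1e9), prevV(nrec, V_REST);
  NumericMatrix trace;
  if (record_trace) {
    trace = NumericMatrix(nt + 1, nrec);
    for (int k = 0; k < nrec; ++k) trace(0, k) = V_REST;
  }

  double max_dev = 0.0;
  bool stopped_early = false;
  // per-pulse bookkeeping for the 80%-of-pulses activation criterion
  const int np = onsets_ms.size();
  std::vector<char> pulse_hit(np, 0);
  int hits = 0, misses = 0, next_close = 0;
  const int need = (int)std::ceil(0.8 * np - 1e-9);
  const int allowed_miss = np - need;
  std::vector<double> band(7 * (size_t)N), rhs(N);
  std::vector<double> gt_node(nnode), geq_node(nnode);
  const int env_len = envelope.size();

  for (int it = 1; it <= nt; ++it) {
    double t_new = it * dt;

    // pulse envelope at t_new
    double env = 0.0;
    if (env_len > 0) {
      double x = (t_new * 1000.0) / env_dt_us;
      int i0 = (int)std::floor(x);
      if (i0 >= 0 && i0 < env_len - 1) {
        double w = x - i0;
        env = envelope[i0] * (1.0 - w) + envelope[i0 + 1] * w;
      } else if (i0 == env_len - 1) {
        env = envelope[env_len - 1];
      }
    }
    double scale = amplitude * env * 1000.0;   // unit field (V) -> mV

    // gating update and nodal conductances
    for (int kk = 0; kk < nnode; ++kk) {
      int i = node_ids[kk];
      double xinf[4], xrel[4];
      tab.lookup(Vm[i], xinf, xrel);
      m[i] = xinf[0] + (m[i] - xinf[0]) * xrel[0];
      h[i] = xinf[1] + (h[i] - xinf[1]) * xrel[1];
      p[i] = xinf[2] + (p[i] - xinf[2]) * xrel[2];
      s[i] = xinf[3] + (s[i] - xinf[3]) * xrel[3];
      double gna = gnaf[i] * m[i] * m[i] * m[i] * h[i];
      double gnp = gnap[i] * p[i] * p[i] * p[i];
      double gk = gks[i] * s[i];
      gt_node[kk] = gna + gnp + gk + gl[i];
      geq_node[kk] = (gna + gnp) * E_NA + gk * E_K + gl[i] * e_leak;
    }

    // assemble: copy template, add nodal ionic terms, build RHS
    std::memcpy(band.data(), band0.data(), sizeof(double) * band0.size());
    for (int i = 0; i < n; ++i) {
      int rm = 2 * i, rp = 2 * i + 1;
      if (type[i] == 0) {
        rhs[rm] = cm[i] / dt * Vm[i] + scale * fldA[i];
        rhs[rp] = 0.0;
      } else {
        double geq = gpas[i] * V_REST;
        rhs[rm] = cm[i] / dt * Vm[i] + geq + scale * fldA[i];
        rhs[rp] = cmy[i] / dt * Vp[i] - cm[i] / dt * Vm[i] - geq +
                  scale * fldP[i];
      }
    }
    for (int kk = 0; kk < nnode; ++kk) {
      int i = node_ids[kk];
      BAND(band, 2 * i, 2 * i) += gt_node[kk];
      rhs[2 * i] += geq_node[kk];
    }

    band_factor(band, N);
    band_solve(band, N, rhs);

    double step_dev = 0.0;
    for (int i = 0; i < n; ++i) {
      Vm[i] = rhs[2 * i];
      Vp[i] = rhs[2 * i + 1];
      double dev = std::fabs(Vm[i] - V_REST);
      if (dev > step_dev) step_dev = dev;
    }
    if (step_dev > max_dev) max_dev = step_dev;

    for (int k = 0; k < nrec; ++k) {
      double v = Vm[record_idx[k]];
      if (prevV[k] < spike_thresh_mV && v >= spike_thresh_mV &&
          t_new - last_spike[k] >= 1.0) {
        spikes[k].push_back(t_new);
        last_spike[k] = t_new;
      }
      prevV[k] = v;
      if (record_trace) trace(it, k) = v;
    }

    if (early_stop) {
      // a spike at the detection compartment settles a 1-pulse activation
      // test; a fully subthreshold, decaying cable after the pulse ends
      // cannot spike later
      if (!spikes.empty() && !spikes[0].empty()) { stopped_early = true; break; }
      if (t_new > pulse_end_ms + 2.0 && step_dev < 20.0) {
        stopped_early = true;
        break;
      }
    }

    if (early_stop_train && np > 0) {
      // mark pulse windows hit by the newest detection-compartment spike
      if (nrec > 0 && !spikes[0].empty() &&
          spikes[0].back() == t_new) {
        for (int j = 0; j < np; ++j) {
          if (!pulse_hit[j] && t_new > onsets_ms[j] &&
              t_new <= onsets_ms[j] + 10.0) {
            pulse_hit[j] = 1;
            ++hits;
          }
        }
      }
      while (next_close < np && t_new > onsets_ms[next_close] + 10.0) {
        if (!pulse_hit[next_close]) ++misses;
        ++next_close;
      }
      // outcome already decided either way: stop integrating
      if (hits >= need || misses > allowed_miss) { stopped_early = true; break; }
    }
  }

  List spk(nrec);
  for (int k = 0; k < nrec; ++k)
    spk[k] = NumericVector(spikes[k].begin(), spikes[k].end());
  List out = List::create(_["spike_times"] = spk,
                          _["max_deviation_mV"] = max_dev,
                          _["vm_final"] = NumericVector(Vm.begin(), Vm.end()),
                          _["dt_ms"] = dt, _["n_steps"] = nt,
                          _["stopped_early"] = stopped_early);
  if (record_trace) out["trace"] = trace;
  return out;
}
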