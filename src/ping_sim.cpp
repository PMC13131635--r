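// Fixed-step exponential-Euler integrator for the heterogeneous E-I network:
// stellate cells (transient Na, delayed-rectifier K, persistent Na, fast+slow
// H current, leak) and fast-spiking PV interneurons (Wang-Buzsaki-type Na/K),
// connected by biexponential GABA synapses (I->I, I->E), single-exponential
// AMPA synapses (E->I), and gap junctions among I cells. Theta drive is a
// half-wave-rectified sinusoidal conductance applied to E cells only.
// Units: mV, ms, nS, pA, pF.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct Edge { int post; double w; int d; };

// CSR-style adjacency: for each presynaptic cell, its outgoing edges
struct Projection {
  std::vector<int> start;        // size npre+1
  std::vector<Edge> edges;
  int maxd = 0;
};

static Projection build_proj(const List& proj, int npre) {
  Projection P;
  IntegerVector pre = proj["pre"], post = proj["post"], d = proj["dsteps"];
  NumericVector w = proj["w"];
  int ne = pre.size();
  std::vector<int> cnt(npre, 0);
  for (int k = 0; k < ne; ++k) cnt[pre[k]]++;
  P.start.assign(npre + 1, 0);
  for (int i = 0; i < npre; ++i) P.start[i + 1] = P.start[i] + cnt[i];
  P.edges.resize(ne);
  std::vector<int> fill(npre, 0);
  for (int k = 0; k < ne; ++k) {
    int p = pre[k];
    P.edges[P.start[p] + fill[p]] = { post[k], w[k], d[k] };
    fill[p]++;
    if (d[k] > P.maxd) P.maxd = d[k];
  }
  return P;
}

// ring buffer of pending conductance increments (one per receptor per target pop)
struct Ring {
  int L, n;
  std::vector<double> buf;
  Ring(int maxd, int n_) : L(maxd + 2), n(n_), buf((size_t)(maxd + 2) * n_, 0.0) {}
  double* slot(long step) { return buf.data() + (size_t)(step % L) * n; }
};

// [[Rcpp::export(name = ".ping_simulate_cpp")]]
List ping_simulate_cpp(List epar, List ipar, List conn, List gap,
                       IntegerVector clamp_idx, NumericVector clamp_v,
                       double drive_freq, double drive_gpeak, double drive_erev,
                       double settle_ms, double stim_ms, double dt,
                       IntegerVector rec_v_idx, double rec_start_ms, int rec_decim,
                       List syn_kin) {
  // population parameter vectors (per cell)
  NumericVector eC = epar["C"], egNa = epar["gNa"], egK = epar["gK"],
                egNaP = epar["gNaP"], egH = epar["gH"], egL = epar["gL"],
                eEL = epar["EL"];
  NumericVector iC = ipar["C"], igNa = ipar["gNa"], igK = ipar["gK"],
                igL = ipar["gL"], iEL = ipar["EL"];
  const double ENa = 55.0, EK = -90.0, EH = -20.0, phi = 5.0;

  const int nE = eC.size(), nI = iC.size(), n = nE + nI;

  // synapse kinetics (ms, mV)
  const double tr_ii = syn_kin["tau_r_ii"], td_ii = syn_kin["tau_d_ii"],
               E_ii = syn_kin["e_gaba_ii"];
  const double tr_ie = syn_kin["tau_r_ie"], td_ie = syn_kin["tau_d_ie"],
               E_ie = syn_kin["e_gaba_ie"];
  const double td_ei = syn_kin["tau_d_ei"], E_ei = syn_kin["e_ampa"];

  Projection Pii = build_proj(conn["ii"], nI);   // pre: I index 0..nI-1, post: I
  Projection Pie = build_proj(conn["ie"], nI);   // pre: I, post: E
  Projection Pei = build_proj(conn["ei"], nE);   // pre: E, post: I

  // gap junctions: per-I-cell neighbor lists
  IntegerVector ga = gap["a"], gb = gap["b"];
  NumericVector gg = gap["g"];
  std::vector<std::vector<std::pair<int, double>>> gapadj(nI);
  for (int k = 0; k < ga.size(); ++k) {
    gapadj[ga[k]].push_back({ gb[k], gg[k] });
    gapadj[gb[k]].push_back({ ga[k], gg[k] });
  }

  // biexponential peak normalization so that weight = peak conductance
  auto biexp_norm = [](double tr, double td) {
    double tp = tr * td / (td - tr) * std::log(td / tr);
    return std::exp(-tp / td) - std::exp(-tp / tr);
  };
  const double nrm_ii = biexp_norm(tr_ii, td_ii), nrm_ie = biexp_norm(tr_ie, td_ie);

  Ring ring_ii(Pii.maxd, nI), ring_ie(Pie.maxd, nE), ring_ei(Pei.maxd, nI);

  // state
  std::vector<double> V(n);
  std::vector<double> em(nE), eh(nE), en(nE), ep(nE), ehf(nE), ehs(nE);
  std::vector<double> ih(nI), in_(nI);
  std::vector<double> Aii(nI, 0), Bii(nI, 0), gei(nI, 0);
  std::vector<double> Aie(nE, 0), Bie(nE, 0);

  std::vector<int> clampmap(n, -1);
  for (int k = 0; k < clamp_idx.size(); ++k) clampmap[clamp_idx[k]] = k;

  // init at leak/holding potential with gating at steady state
  for (int i = 0; i < nE; ++i) {
    double v = (clampmap[i] >= 0) ? clamp_v[clampmap[i]] : eEL[i];
    V[i] = v;
    double am = 0.1 * vtrap(v + 23.0, 10.0), bm = 4.0 * std::exp(-(v + 48.0) / 18.0);
    em[i] = am / (am + bm);
    double ah = 0.07 * std::exp(-(v + 37.0) / 20.0), bh = 1.0 / (std::exp(-0.1 * (v + 7.0)) + 1.0);
    eh[i] = ah / (ah + bh);
    double an = 0.01 * vtrap(v + 27.0, 10.0), bn = 0.125 * std::exp(-(v + 37.0) / 80.0);
    en[i] = an / (an + bn);
    ep[i] = 1.0 / (1.0 + std::exp(-(v + 38.0) / 6.5));
    ehf[i] = 1.0 / (1.0 + std::exp((v + 79.2) / 9.78));
    ehs[i] = 1.0 / (1.0 + std::exp((v + 71.3) / 7.9));
  }
  for (int j = 0; j < nI; ++j) {
    int gi = nE + j;
    double v = (clampmap[gi] >= 0) ? clamp_v[clampmap[gi]] : iEL[j];
    V[gi] = v;
    double ah = 0.07 * std::exp(-(v + 58.0) / 20.0), bh = 1.0 / (std::exp(-0.1 * (v + 28.0)) + 1.0);
    ih[j] = ah / (ah + bh);
    double an = 0.01 * vtrap(v + 34.0, 10.0), bn = 0.125 * std::exp(-(v + 44.0) / 80.0);
    in_[j] = an / (an + bn);
  }

  const double t_total = settle_ms + stim_ms;
  const long nsteps = (long)std::llround(t_total / dt);
  const long rec_start = (long)std::llround(rec_start_ms / dt);
  const long settle_steps = (long)std::llround(settle_ms / dt);
  const int refr_steps = (int)std::llround(1.0 / dt);    // 1 ms refractory for raster
  const int nrec = (nsteps - rec_start) / rec_decim + 1;

  NumericMatrix recV(nrec, rec_v_idx.size());
  NumericMatrix recI(nrec, clamp_idx.size());
  NumericVector recT(nrec);
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<long> lastspk(n, -1000000);
  std::vector<double> Vprev(V);

  const double eii_r = std::exp(-dt / tr_ii), eii_d = std::exp(-dt / td_ii);
  const double eie_r = std::exp(-dt / tr_ie), eie_d = std::exp(-dt / td_ie);
  const double eei_d = std::exp(-dt / td_ei);
  const double w2pi = 2.0 * M_PI * drive_freq / 1000.0;  // rad per ms

  int irec = 0;
  bool blowup = false;

  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;

    // deliver pending synaptic events
    {
      double* s = ring_ii.slot(step);
      for (int j = 0; j < nI; ++j) { Aii[j] += s[j]; Bii[j] += s[j]; s[j] = 0.0; }
    }
    {
      double* s = ring_ei.slot(step);
      for (int j = 0; j < nI; ++j) { gei[j] += s[j]; s[j] = 0.0; }
    }
    {
      double* s = ring_ie.slot(step);
      for (int i = 0; i < nE; ++i) { Aie[i] += s[i]; Bie[i] += s[i]; s[i] = 0.0; }
    }

    // theta drive conductance (E cells only, after settling)
    double gdrive = 0.0;
    if (step >= settle_steps && drive_gpeak > 0.0) {
      double s = std::sin(w2pi * (t - settle_ms));
      gdrive = drive_gpeak * (s > 0.0 ? s : 0.0);
    }

    // record
    if (step >= rec_start && (step - rec_start) % rec_decim == 0 && irec < nrec) {
      recT[irec] = t;
      for (int k = 0; k < rec_v_idx.size(); ++k) recV(irec, k) = V[rec_v_idx[k]];
      for (int k = 0; k < clamp_idx.size(); ++k) {
        int gi = clamp_idx[k];
        double vh = clamp_v[k], cur = 0.0;
        if (gi < nE) {
          cur += (Bie[gi] - Aie[gi]) * (vh - E_ie);
          cur += gdrive * (vh - drive_erev);
        } else {
          int j = gi - nE;
          cur += (Bii[j] - Aii[j]) * (vh - E_ii);
          cur += gei[j] * (vh - E_ei);
          for (auto& nb : gapadj[j]) cur += nb.second * (vh - V[nE + nb.first]);
        }
        recI(irec, k) = cur;   // voltage-clamp convention: outward positive
      }
      irec++;
    }

    if (step == nsteps) break;

    // --- update E cells ---
    for (int i = 0; i < nE; ++i) {
      double v = Vprev[i];
      if (clampmap[i] >= 0) continue;
      // gating
      double am = 0.1 * vtrap(v + 23.0, 10.0), bm = 4.0 * std::exp(-(v + 48.0) / 18.0);
      double ah = 0.07 * std::exp(-(v + 37.0) / 20.0), bh = 1.0 / (std::exp(-0.1 * (v + 7.0)) + 1.0);
      double an = 0.01 * vtrap(v + 27.0, 10.0), bn = 0.125 * std::exp(-(v + 37.0) / 80.0);
      double sm = am + bm, sh = ah + bh, sn = an + bn;
      em[i] += (am / sm - em[i]) * (1.0 - std::exp(-dt * sm));
      eh[i] += (ah / sh - eh[i]) * (1.0 - std::exp(-dt * sh));
      en[i] += (an / sn - en[i]) * (1.0 - std::exp(-dt * sn));
      double pinf = 1.0 / (1.0 + std::exp(-(v + 38.0) / 6.5));
      ep[i] += (pinf - ep[i]) * (1.0 - std::exp(-dt / 0.15));
      double hfinf = 1.0 / (1.0 + std::exp((v + 79.2) / 9.78));
      double thf = 0.51 / (std::exp((v - 1.7) / 10.0) + std::exp(-(v + 340.0) / 52.0)) + 1.0;
      ehf[i] += (hfinf - ehf[i]) * (1.0 - std::exp(-dt / thf));
      double hsinf = 1.0 / (1.0 + std::exp((v + 71.3) / 7.9));
      double ths = 5.6 / (std::exp((v - 1.7) / 14.0) + std::exp(-(v + 260.0) / 43.0)) + 1.0;
      ehs[i] += (hsinf - ehs[i]) * (1.0 - std::exp(-dt / ths));
      // conductances
      double m3h = em[i] * em[i] * em[i] * eh[i];
      double n4 = en[i] * en[i]; n4 *= n4;
      double gna = egNa[i] * m3h, gk = egK[i] * n4, gnap = egNaP[i] * ep[i];
      double ghc = egH[i] * (0.65 * ehf[i] + 0.35 * ehs[i]);
      double gsyn = Bie[i] - Aie[i];
      double G = gna + gk + gnap + ghc + egL[i] + gsyn + gdrive;
      double A = gna * ENa + gk * EK + gnap * ENa + ghc * EH + egL[i] * eEL[i]
               + gsyn * E_ie + gdrive * drive_erev;
      double vinf = A / G;
      double vn = vinf + (v - vinf) * std::exp(-dt * G / eC[i]);
      V[i] = vn;
      if (vn > 200.0 || vn < -200.0) blowup = true;
      // spike: upward crossing of 0 mV, 1 ms refractory
      if (v < 0.0 && vn >= 0.0 && (step - lastspk[i]) > refr_steps) {
        lastspk[i] = step;
        spike_t.push_back(t + dt);
        spike_id.push_back(i);
        const Edge* e0 = Pei.edges.data();
        for (int k = Pei.start[i]; k < Pei.start[i + 1]; ++k) {
          const Edge& e = e0[k];
          ring_ei.slot(step + e.d)[e.post] += e.w;
        }
      }
    }

    // --- update I cells ---
    for (int j = 0; j < nI; ++j) {
      int gi = nE + j;
      double v = Vprev[gi];
      if (clampmap[gi] >= 0) continue;
      double am = 0.1 * vtrap(v + 35.0, 10.0), bm = 4.0 * std::exp(-(v + 60.0) / 18.0);
      double minf = am / (am + bm);
      double ah = 0.07 * std::exp(-(v + 58.0) / 20.0), bh = 1.0 / (std::exp(-0.1 * (v + 28.0)) + 1.0);
      double an = 0.01 * vtrap(v + 34.0, 10.0), bn = 0.125 * std::exp(-(v + 44.0) / 80.0);
      double sh = phi * (ah + bh), sn = phi * (an + bn);
      ih[j] += (ah / (ah + bh) - ih[j]) * (1.0 - std::exp(-dt * sh));
      in_[j] += (an / (an + bn) - in_[j]) * (1.0 - std::exp(-dt * sn));
      double m3h = minf * minf * minf * ih[j];
      double n4 = in_[j] * in_[j]; n4 *= n4;
      double gna = igNa[j] * m3h, gk = igK[j] * n4;
      double gsyn_g = Bii[j] - Aii[j];
      double G = gna + gk + igL[j] + gsyn_g + gei[j];
      double A = gna * ENa + gk * EK + igL[j] * iEL[j] + gsyn_g * E_ii + gei[j] * E_ei;
      for (auto& nb : gapadj[j]) { G += nb.second; A += nb.second * Vprev[nE + nb.first]; }
      double vinf = A / G;
      double vn = vinf + (v - vinf) * std::exp(-dt * G / iC[j]);
      V[gi] = vn;
      if (vn > 200.0 || vn < -200.0) blowup = true;
      if (v < 0.0 && vn >= 0.0 && (step - lastspk[gi]) > refr_steps) {
        lastspk[gi] = step;
        spike_t.push_back(t + dt);
        spike_id.push_back(gi);
        const Edge* e0 = Pii.edges.data();
        for (int k = Pii.start[j]; k < Pii.start[j + 1]; ++k) {
          const Edge& e = e0[k];
          ring_ii.slot(step + e.d)[e.post] += e.w / nrm_ii;
        }
        const Edge* f0 = Pie.edges.data();
        for (int k = Pie.start[j]; k < Pie.start[j + 1]; ++k) {
          const Edge& e = f0[k];
          ring_ie.slot(step + e.d)[e.post] += e.w / nrm_ie;
        }
      }
    }

    // decay synaptic states
    for (int j = 0; j < nI; ++j) { Aii[j] *= eii_r; Bii[j] *= eii_d; gei[j] *= eei_d; }
    for (int i = 0; i < nE; ++i) { Aie[i] *= eie_r; Bie[i] *= eie_d; }

    std::copy(V.begin(), V.end(), Vprev.begin());
    if (blowup) stop("numerical blow-up: |V| exceeded 200 mV at t = %f ms", t);
  }

  return List::create(
    _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["t"] = recT, _["v"] = recV, _["clamp_i"] = recI);
}
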