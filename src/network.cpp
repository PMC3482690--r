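#include <Rcpp.h>
using namespace Rcpp;

// One-timestep update of the layered olfactorimotor circuit.
//
// Stage order within a timestep is arranged so that every layer reads only
// the *previous* timestep's output of its presynaptic layer (written later
// in the same sweep), giving exactly one timestep of latency per stage and
// the five-stage sensor -> motor pipeline:
//   sensor-hold -> mitral -> {interneuron, delayed mitral} -> cortex -> motor.
//
// Synapse classes (index): 0 sensor->mitral, 1 mitral->interneuron,
// 2 mitral->cortex (excitatory), 3 interneuron->cortex (inhibitory),
// 4 cortex->motor. Each class has an additive weight w, box-car PSP
// duration D (timesteps), depression fraction U and recovery rate r_rec.
//
// Depression follows the first-order resource rule: on presynaptic activity
// a in [0,1] the release is a*R and R <- R*(1 - U*a); every timestep
// R <- R + r_rec*(1 - R). PSP persistence is a box-car: the per-synapse
// accumulator P holds the sum of the last D releases (ring buffer).

struct SynClass {
  NumericVector R;     // depression resource per synapse
  NumericVector P;     // box-car PSP accumulator per synapse
  NumericVector ring;  // release history, n_syn x D, slot k*D + cur
  int D;
  double w, U, rrec;
};

// release + PSP + depression update for one class given presynaptic
// activity looked up through src indices. The ring buffer is slot-major
// (slot cur holds the releases of all synapses at one past timestep) so
// each substep touches contiguous memory.
static void syn_update(SynClass &sc, const IntegerVector &src,
                       const NumericVector &pre, int cur) {
  int n = sc.R.size();
  double *ring = &sc.ring[(R_xlen_t)cur * n];
  double *R = sc.R.begin(), *P = sc.P.begin();
  const int *s = src.begin();
  const double *pr = pre.begin();
  double U = sc.U, rrec = sc.rrec;
  for (int k = 0; k < n; ++k) {
    double a = pr[s[k]];
    double rel = a * R[k];
    R[k] -= U * rel;
    P[k] += rel - ring[k];
    ring[k] = rel;
    R[k] += rrec * (1.0 - R[k]);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_net_step(List st, NumericVector input, int n_substeps) {
  List cfg = st["cfg"];
  int n_sensor = cfg["n_sensor"], n_mitral = cfg["n_mitral"];
  int n_inter = cfg["n_inter"], n_cortex = cfg["n_cortex"];
  int B = cfg["branches"], n_motor = cfg["n_motor"];
  int nE = cfg["exc_per_branch"], nI = cfg["inh_per_branch"];
  int inter_fanin = cfg["inter_fanin"], cluster = cfg["cluster_size"];
  int branch_mode = cfg["branch_mode_i"];     // 0 thr, 1 linear, 2 sigmoid
  int n_b = cfg["n_b"];
  double branch_gain = cfg["branch_gain"];
  double theta_int = cfg["theta_int"], theta_m = cfg["theta_m"];
  double eta = cfg["eta"], tau_avg = cfg["tau_avg"];
  double th_min = cfg["theta_min"], th_max = cfg["theta_max"];
  double branch_target = cfg["branch_target"], soma_target = cfg["soma_target"];
  bool homeo_on = cfg["homeo_on"];
  bool align_inh = cfg["align_inhibition"];

  NumericVector w = cfg["w"], U = cfg["U"], rrec = cfg["r_rec"];
  IntegerVector D = cfg["D"];

  List Rl = st["R"], Pl = st["P"], ringl = st["ring"];
  IntegerVector cur = st["cur"];

  SynClass sc[5];
  for (int c = 0; c < 5; ++c) {
    sc[c].R = as<NumericVector>(Rl[c]);
    sc[c].P = as<NumericVector>(Pl[c]);
    sc[c].ring = as<NumericVector>(ringl[c]);
    sc[c].D = D[c];
    sc[c].w = w[c]; sc[c].U = U[c]; sc[c].rrec = rrec[c];
  }

  List wiring = st["wiring"];
  IntegerVector inter_src = wiring["inter_src"];
  IntegerVector cx_e_src = wiring["cx_e_src"];
  IntegerVector cx_i_src = wiring["cx_i_src"];
  IntegerVector mo_src = wiring["mo_src"];
  int mo_aff = mo_src.size() / n_motor;

  NumericVector S = st["S"], M = st["M"], Md = st["Md"];
  NumericVector I = st["I"], Cx = st["Cx"], Mo = st["Mo"];
  NumericVector th_b = st["theta_b"], th_s = st["theta_s"];
  NumericVector avg_b = st["avg_b"], avg_s = st["avg_s"];
  // raw drives of the last substep, read back by threshold calibration
  NumericVector drive_b = st["drive_b"], drive_s = st["drive_s"];

  NumericMatrix out(n_substeps, n_motor);

  for (int t = 0; t < n_substeps; ++t) {
    // ---- motor (reads cortex output of previous timestep) ----
    syn_update(sc[4], mo_src, Cx, cur[4]);
    for (int m = 0; m < n_motor; ++m) {
      double drive = 0.0;
      for (int k = m * mo_aff; k < (m + 1) * mo_aff; ++k) drive += sc[4].P[k];
      drive *= sc[4].w;
      Mo[m] = drive >= theta_m ? 1.0 : 0.0;
      out(t, m) = Mo[m];
    }

    // ---- cortex (reads delayed mitral + interneurons, previous step) ----
    const NumericVector &exc_pre = align_inh ? Md : M;
    syn_update(sc[2], cx_e_src, exc_pre, cur[2]);
    syn_update(sc[3], cx_i_src, I, cur[3]);
    for (int c = 0; c < n_cortex; ++c) {
      double agg = 0.0;
      int fired_branches = 0;
      for (int b = 0; b < B; ++b) {
        int bi = c * B + b;
        double sum = 0.0;
        for (int k = bi * nE; k < (bi + 1) * nE; ++k) sum += sc[2].P[k];
        sum *= sc[2].w;
        double inh = 0.0;
        for (int k = bi * nI; k < (bi + 1) * nI; ++k) inh += sc[3].P[k];
        sum += sc[3].w * inh;   // w is negative for the inhibitory class
        drive_b[bi] = sum;
        double bout, act;
        if (branch_mode == 0) {          // thresholded branch unit
          bout = sum >= th_b[bi] ? 1.0 : 0.0;
          act = bout;
          fired_branches += (int)bout;
        } else if (branch_mode == 1) {   // linear dendrite
          bout = sum;
          act = std::min(1.0, std::max(0.0, sum));
        } else {                         // sigmoidal dendrite
          bout = 1.0 / (1.0 + std::exp(-branch_gain * (sum - th_b[bi])));
          act = bout;
        }
        agg += bout;
        avg_b[bi] += (act - avg_b[bi]) / tau_avg;
        if (homeo_on) {
          th_b[bi] += eta * (avg_b[bi] - branch_target);
          if (th_b[bi] < th_min) th_b[bi] = th_min;
          if (th_b[bi] > th_max) th_b[bi] = th_max;
        }
      }
      drive_s[c] = branch_mode == 0 ? (double)fired_branches : agg;
      double fired;
      if (branch_mode == 0) fired = fired_branches >= n_b ? 1.0 : 0.0;
      else fired = agg >= th_s[c] ? 1.0 : 0.0;
      Cx[c] = fired;
      avg_s[c] += (fired - avg_s[c]) / tau_avg;
      if (homeo_on) {
        th_s[c] += eta * (avg_s[c] - soma_target);
        if (th_s[c] < th_min) th_s[c] = th_min;
        if (th_s[c] > th_max) th_s[c] = th_max;
      }
    }

    // ---- feedforward interneurons (read mitral, previous step) ----
    syn_update(sc[1], inter_src, M, cur[1]);
    for (int i = 0; i < n_inter; ++i) {
      double drive = 0.0;
      for (int k = i * inter_fanin; k < (i + 1) * inter_fanin; ++k)
        drive += sc[1].P[k];
      drive *= sc[1].w / inter_fanin;
      I[i] = drive >= theta_int ? 1.0 : 0.0;
    }

    // ---- delayed mitral buffer (aligns excitation with disynaptic inhibition)
    for (int m = 0; m < n_mitral; ++m) Md[m] = M[m];

    // ---- mitral (reads sensor hold, previous step) ----
    {
      // class 0: one synapse per sensor, presyn = S
      SynClass &c0 = sc[0];
      double *ring0 = &c0.ring[(R_xlen_t)cur[0] * n_sensor];
      for (int k = 0; k < n_sensor; ++k) {
        double a = S[k];
        double rel = a * c0.R[k];
        c0.R[k] -= c0.U * rel;
        c0.P[k] += rel - ring0[k];
        ring0[k] = rel;
        c0.R[k] += c0.rrec * (1.0 - c0.R[k]);
      }
      for (int m = 0; m < n_mitral; ++m) {
        double sum = 0.0;
        for (int k = m * cluster; k < (m + 1) * cluster; ++k) sum += c0.P[k];
        double a = c0.w * sum / cluster;
        M[m] = std::min(1.0, std::max(0.0, a));
      }
    }

    // ---- sensor hold ----
    for (int k = 0; k < n_sensor; ++k) S[k] = input[k];

    for (int c = 0; c < 5; ++c) cur[c] = (cur[c] + 1) % sc[c].D;
  }
  return out;
}
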