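// Spiking network engine: conductance-based LIF neurons with adaptive
// thresholds, short-term plasticity, triplet STDP + heterosynaptic +
// transmitter-induced plasticity, bistable reference-weight consolidation,
// and network activity-based inhibitory plasticity.
//
// Update order per time step (one-step synaptic delay convention):
//   A. decay conductances, deliver previous step's weighted spikes and
//      adaptation increments, update NMDA low-pass from post-update AMPA
//   B. forward-Euler membrane and threshold integration
//   C. spike detection and reset (Poisson populations draw their spikes)
//   D. plasticity: exact-exponential trace/STP/H decays, homeostatic C
//      update, rule evaluation on this step's spikes reading pre-increment
//      (t - eps) trace values, transmission queuing for the next step,
//      then trace/STP/H increments
//   E. every dt_long, an Euler step of the reference-weight double well.
// The pure-R reference engine in R/reference-engine.R follows the same
// order; the two are compared step-for-step in the tests.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
struct Pcg32 {
  uint64_t state = 0x853c49e6748fea9bULL, inc = 0xda3e39cb94b95bdbULL;
  void seed(uint64_t s, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u; next(); state += s; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() { return next() * 2.3283064365386963e-10; } // [0,1)
  int binom(int n, double p) {
    if (n <= 0 || p <= 0) return 0;
    if (p >= 1) return n;
    double pdf = std::exp(n * std::log1p(-p));
    double u = unif(), odds = p / (1 - p);
    int k = 0;
    while (u > pdf && k < n) {
      u -= pdf; ++k;
      pdf *= odds * (double)(n - k + 1) / (double)k;
    }
    return k;
  }
};

// ------------------------------------------------------------- params ----
struct NeurP {
  double tau_m, U_rest, U_exc, U_inh, th_rest, th_spike, tau_thr, alpha,
      tau_ampa, tau_nmda, tau_gaba, tau_a, Delta_a;
};

struct Pop {  // Poisson source population
  std::string name; int n = 0;
  std::vector<double> u, x, zp;
  // current drive (set per run segment)
  std::vector<int> active;           // 0-based
  std::vector<uint8_t> is_active;
  double rate_a = 0, rate_b = 0;
  bool fixed = false;                // fixed spike schedule this segment
  std::vector<int> fs_ptr;           // per-step offsets into fs_id
  std::vector<int> fs_id;
  std::vector<int> spikes;           // this step
  std::vector<double> eff;           // per-neuron delivered efficacy
  // silent populations relax to their fixed point and are then skipped;
  // countdown covers ~35 facilitation time constants before clamping
  bool idle = false;
  long long idle_countdown = -1;
};

struct Region {
  std::string name; int ne = 0, ni = 0; bool enabled = true;
  NeurP np;
  double tau_H = 10.0, H = 0;
  // neuron state, exc then inh (size ne+ni)
  std::vector<double> U, th, ga, gn, gg, gad;
  std::vector<double> exc_in, inh_in, a_in;
  // presynaptic state of excitatory neurons
  std::vector<double> u, x, zp, eff;
  // postsynaptic traces of excitatory neurons
  std::vector<double> zm, zs, zht, C;
  // inhibitory-plasticity traces
  std::vector<double> zi_pre, zi_post;  // sizes ni, ne
  std::vector<int> sp_e, sp_i;          // spikes this step (0-based local)
};

enum ProjType { STATIC = 0, STP_ONLY = 1, STP_LT = 2, INH_PLASTIC = 3 };

struct Proj {
  std::string name;
  int src_kind;  // 0 pop, 1 region-exc, 2 region-inh
  int src_idx, tgt_region;
  int tgt_part;  // 1 exc, 2 inh
  int n_src = 0, n_tgt = 0;
  std::vector<int> rptr, col;        // CSR by source
  std::vector<double> w, wt;
  bool has_wt = false;
  std::vector<int> cptr, csyn, csrc; // CSC by target
  int type = STATIC;
  double eta = 0, A = 0, beta = 0, delta = 0, tau_cons = 0;
  double eta_inh = 0, gamma = 0;
  double wmin = 0, wmax = 1e300;
  std::vector<uint8_t> blocked;
};

struct Engine {
  double dt = 1e-4, dt_long = 1.2;
  long long step_count = 0;
  int long_every = 12000;
  bool exact_decay = false;
  // global plasticity constants
  double tau_plus, tau_minus, tau_slow, tau_ht, tau_hom, tau_istdp;
  double U_stp, tau_d, tau_f;
  double P_dw, w_P;
  std::vector<Pop> pops;
  std::vector<Region> regions;
  std::vector<Proj> projs;
  Pcg32 rng;

  int pop_index(const std::string& nm) const {
    for (size_t i = 0; i < pops.size(); ++i)
      if (pops[i].name == nm) return (int)i;
    return -1;
  }
  int region_index(const std::string& nm) const {
    for (size_t i = 0; i < regions.size(); ++i)
      if (regions[i].name == nm) return (int)i;
    return -1;
  }
  int proj_index(const std::string& nm) const {
    for (size_t i = 0; i < projs.size(); ++i)
      if (projs[i].name == nm) return (int)i;
    stop("unknown projection: " + nm);
    return -1;
  }

  double decf(double tau) const {
    return exact_decay ? std::exp(-dt / tau) : 1.0 - dt / tau;
  }

  // presynaptic arrays of a projection's source
  std::vector<double>& src_zp(Proj& p) {
    return p.src_kind == 0 ? pops[p.src_idx].zp : regions[p.src_idx].zp;
  }
  std::vector<double>& src_eff(Proj& p) {
    return p.src_kind == 0 ? pops[p.src_idx].eff : regions[p.src_idx].eff;
  }
  const std::vector<int>& src_spikes(Proj& p) {
    if (p.src_kind == 0) return pops[p.src_idx].spikes;
    return p.src_kind == 1 ? regions[p.src_idx].sp_e : regions[p.src_idx].sp_i;
  }

  void consolidate() {
    for (auto& p : projs) {
      if (!p.has_wt) continue;
      double r = dt_long / p.tau_cons;
      for (size_t s = 0; s < p.w.size(); ++s) {
        double wt = p.wt[s];
        double drift = p.w[s] - wt -
          P_dw * wt * (w_P / 2.0 - wt) * (w_P - wt);
        wt += r * drift;
        p.wt[s] = wt;
      }
      for (size_t s = 0; s < p.wt.size(); ++s)
        if (!std::isfinite(p.wt[s]) || std::fabs(p.wt[s]) > 1e6)
          stop("reference weights diverging in projection " + p.name +
               ": tau_cons/dt_long too small for a stable Euler step");
    }
  }

  void draw_pop_spikes(Pop& pp, int step_in_seg) {
    pp.spikes.clear();
    if (pp.fixed) {
      if (step_in_seg + 1 < (int)pp.fs_ptr.size()) {
        for (int k = pp.fs_ptr[step_in_seg]; k < pp.fs_ptr[step_in_seg + 1]; ++k)
          pp.spikes.push_back(pp.fs_id[k]);
      }
      return;
    }
    // active subset at rate_a, remainder at rate_b
    int na = (int)pp.active.size();
    int nb = pp.n - na;
    double pa = pp.rate_a * dt, pb = pp.rate_b * dt;
    if (pa >= 1 || pb >= 1) stop("poisson drive: rate*dt >= 1");
    if (na > 0 && pa > 0) {
      int k = rng.binom(na, pa);
      sample_into(pp.spikes, pp.active, k);
    }
    if (nb > 0 && pb > 0) {
      int k = rng.binom(nb, pb);
      // sample from the complement of the active set
      sample_complement(pp, k);
    }
  }

  void sample_into(std::vector<int>& out, const std::vector<int>& group,
                   int k) {
    int m = (int)group.size();
    if (k >= m) { for (int j = 0; j < m; ++j) out.push_back(group[j]); return; }
    size_t start = out.size();
    while ((int)(out.size() - start) < k) {
      int idx = group[(int)(rng.unif() * m)];
      bool dup = false;
      for (size_t j = start; j < out.size(); ++j)
        if (out[j] == idx) { dup = true; break; }
      if (!dup) out.push_back(idx);
    }
  }

  void sample_complement(Pop& pp, int k) {
    int m = pp.n - (int)pp.active.size();
    if (m <= 0 || k <= 0) return;
    if (k >= m) {
      for (int i = 0; i < pp.n; ++i)
        if (!pp.is_active[i]) pp.spikes.push_back(i);
      return;
    }
    size_t start = pp.spikes.size();
    while ((int)(pp.spikes.size() - start) < k) {
      int idx = (int)(rng.unif() * pp.n);
      if (pp.is_active[idx]) continue;
      bool dup = false;
      for (size_t j = start; j < pp.spikes.size(); ++j)
        if (pp.spikes[j] == idx) { dup = true; break; }
      if (!dup) pp.spikes.push_back(idx);
    }
  }

  void step(int step_in_seg) {
    const double fzp = std::exp(-dt / tau_plus), fzm = std::exp(-dt / tau_minus),
        fzs = std::exp(-dt / tau_slow), fzh = std::exp(-dt / tau_ht),
        fzi = std::exp(-dt / tau_istdp),
        fd = std::exp(-dt / tau_d), ff = std::exp(-dt / tau_f);

    // A + B + C for regions
    for (auto& r : regions) {
      if (!r.enabled) { r.sp_e.clear(); r.sp_i.clear(); continue; }
      const NeurP& q = r.np;
      const double fa = decf(q.tau_ampa), fg = decf(q.tau_gaba),
          fad = decf(q.tau_a), dtn = dt / q.tau_nmda,
          dtm = dt / q.tau_m, dtt = dt / q.tau_thr;
      int n = r.ne + r.ni;
      double *U = r.U.data(), *th = r.th.data(), *ga = r.ga.data(),
             *gn = r.gn.data(), *gg = r.gg.data(), *gad = r.gad.data(),
             *ei = r.exc_in.data(), *ii = r.inh_in.data(), *ai = r.a_in.data();
      for (int i = 0; i < n; ++i) {
        double a = ga[i] * fa + ei[i];
        double g = gg[i] * fg + ii[i];
        double ad = gad[i] * fad + ai[i];
        double nm = gn[i] + dtn * (a - gn[i]);
        ga[i] = a; gg[i] = g; gad[i] = ad; gn[i] = nm;
        ei[i] = 0; ii[i] = 0; ai[i] = 0;
        double gexc = q.alpha * a + (1.0 - q.alpha) * nm;
        double Ui = U[i];
        Ui += dtm * ((q.U_rest - Ui) + gexc * (q.U_exc - Ui) +
                     (g + ad) * (q.U_inh - Ui));
        double thi = th[i] + dtt * (q.th_rest - th[i]);
        U[i] = Ui; th[i] = thi;
      }
      r.sp_e.clear(); r.sp_i.clear();
      for (int i = 0; i < n; ++i) {
        if (U[i] > th[i]) {
          U[i] = q.U_rest; th[i] = q.th_spike;
          ai[i] += q.Delta_a;  // adaptation delivered next step
          if (i < r.ne) r.sp_e.push_back(i); else r.sp_i.push_back(i - r.ne);
        }
      }
      if (!std::isfinite(U[0]))
        stop("non-finite membrane state in region " + r.name);
    }
    // C for Poisson populations
    for (auto& pp : pops) draw_pop_spikes(pp, step_in_seg);

    // D1: decays
    for (auto& r : regions) {
      if (!r.enabled) continue;
      for (int i = 0; i < r.ne; ++i) {
        r.zp[i] *= fzp;
        double zh = r.zht[i] * fzh;
        r.zht[i] = zh;
        r.zm[i] *= fzm; r.zs[i] *= fzs;
        r.C[i] += dt * (-r.C[i] / tau_hom + zh * zh);
        r.x[i] = 1.0 + (r.x[i] - 1.0) * fd;
        r.u[i] = U_stp + (r.u[i] - U_stp) * ff;
        r.zi_post[i] *= fzi;
      }
      for (int i = 0; i < r.ni; ++i) r.zi_pre[i] *= fzi;
      r.H *= std::exp(-dt / r.tau_H);
    }
    for (auto& pp : pops) {
      if (pp.idle) continue;
      for (int i = 0; i < pp.n; ++i) {
        pp.x[i] = 1.0 + (pp.x[i] - 1.0) * fd;
        pp.u[i] = U_stp + (pp.u[i] - U_stp) * ff;
        pp.zp[i] *= fzp;
      }
      if (pp.idle_countdown > 0 && --pp.idle_countdown == 0) {
        std::fill(pp.u.begin(), pp.u.end(), U_stp);
        std::fill(pp.x.begin(), pp.x.end(), 1.0);
        std::fill(pp.zp.begin(), pp.zp.end(), 0.0);
        pp.idle = true;
      }
    }

    // D2: delivered efficacies (u*x after relaxation, before jumps)
    for (auto& pp : pops)
      for (int j : pp.spikes) pp.eff[j] = pp.u[j] * pp.x[j];
    for (auto& r : regions)
      for (int j : r.sp_e) r.eff[j] = r.u[j] * r.x[j];

    // D3: plasticity rules (pre-rules then post-rules per projection)
    for (auto& p : projs) {
      Region& tr = regions[p.tgt_region];
      if (!tr.enabled) continue;
      if (p.src_kind != 0 && !regions[p.src_idx].enabled) continue;
      if (p.type == STP_LT) {
        const std::vector<int>& pre = src_spikes(p);
        for (int j : pre) {
          if (p.blocked[j]) continue;
          for (int k = p.rptr[j]; k < p.rptr[j + 1]; ++k) {
            int i = p.col[k];
            double B = p.A * std::min(tr.C[i], 1.0);
            double w = p.w[k] + p.eta * (-B * tr.zm[i]) + p.delta;
            p.w[k] = std::min(std::max(w, p.wmin), p.wmax);
          }
        }
        std::vector<double>& zpsrc = src_zp(p);
        for (int i : tr.sp_e) {
          double zs_i = tr.zs[i];
          double zm3 = tr.zm[i] * tr.zm[i] * tr.zm[i];
          for (int k = p.cptr[i]; k < p.cptr[i + 1]; ++k) {
            int s = p.csyn[k];
            double w = p.w[s];
            w += p.eta * p.A * zpsrc[p.csrc[k]] * zs_i -
                 p.beta * (w - p.wt[s]) * zm3;
            p.w[s] = std::min(std::max(w, p.wmin), p.wmax);
          }
        }
      } else if (p.type == INH_PLASTIC) {
        double G = tr.H - p.gamma;
        for (int j : regions[p.src_idx].sp_i) {
          if (p.blocked[j]) continue;
          for (int k = p.rptr[j]; k < p.rptr[j + 1]; ++k) {
            int i = p.col[k];
            double w = p.w[k] + p.eta_inh * G * (tr.zi_post[i] + 1.0);
            p.w[k] = std::min(std::max(w, p.wmin), p.wmax);
          }
        }
        for (int i : tr.sp_e) {
          for (int k = p.cptr[i]; k < p.cptr[i + 1]; ++k) {
            int s = p.csyn[k];
            double w = p.w[s] + p.eta_inh * G * tr.zi_pre[p.csrc[k]];
            p.w[s] = std::min(std::max(w, p.wmin), p.wmax);
          }
        }
      }
    }

    // D4: transmission for next step (post-update weights)
    for (auto& p : projs) {
      Region& tr = regions[p.tgt_region];
      if (!tr.enabled) continue;
      if (p.src_kind != 0 && !regions[p.src_idx].enabled) continue;
      const std::vector<int>& pre = src_spikes(p);
      if (pre.empty()) continue;
      bool inhibitory = (p.src_kind == 2);
      bool use_stp = (p.type == STP_ONLY || p.type == STP_LT);
      int off = (p.tgt_part == 2) ? tr.ne : 0;
      std::vector<double>& buf = inhibitory ? tr.inh_in : tr.exc_in;
      std::vector<double>& eff = src_eff(p);
      for (int j : pre) {
        if (p.blocked[j]) continue;
        double e = use_stp ? eff[j] : 1.0;
        for (int k = p.rptr[j]; k < p.rptr[j + 1]; ++k)
          buf[off + p.col[k]] += p.w[k] * e;
      }
    }

    // D5: increments
    for (auto& pp : pops) {
      for (int j : pp.spikes) {
        pp.zp[j] += 1.0;
        double un = pp.u[j] + U_stp * (1.0 - pp.u[j]);
        pp.u[j] = un;
        pp.x[j] -= un * pp.x[j];
      }
    }
    for (auto& r : regions) {
      if (!r.enabled) continue;
      for (int j : r.sp_e) {
        r.zp[j] += 1.0; r.zm[j] += 1.0; r.zs[j] += 1.0; r.zht[j] += 1.0;
        r.zi_post[j] += 1.0;
        double un = r.u[j] + U_stp * (1.0 - r.u[j]);
        r.u[j] = un;
        r.x[j] -= un * r.x[j];
      }
      for (int j : r.sp_i) r.zi_pre[j] += 1.0;
      r.H += (double)r.sp_e.size();
    }

    ++step_count;
    if (step_count % long_every == 0) consolidate();
    // flush denormalized values to zero: purely decaying state otherwise
    // lingers in the subnormal range where arithmetic is very slow
    if ((step_count & 0xFF) == 0) flush_denormals();
  }

  static void flush_vec(std::vector<double>& v) {
    for (double& x : v)
      if (x != 0.0 && std::fabs(x) < 1e-30) x = 0.0;
  }
  void flush_denormals() {
    for (auto& r : regions) {
      flush_vec(r.ga); flush_vec(r.gn); flush_vec(r.gg); flush_vec(r.gad);
      flush_vec(r.zp); flush_vec(r.zm); flush_vec(r.zs); flush_vec(r.zht);
      flush_vec(r.C); flush_vec(r.zi_pre); flush_vec(r.zi_post);
      if (r.H != 0.0 && std::fabs(r.H) < 1e-30) r.H = 0.0;
    }
    for (auto& pp : pops) flush_vec(pp.zp);
  }
};

static NeurP neurp_from_list(List np) {
  NeurP q;
  q.tau_m = np["tau_m"]; q.U_rest = np["U_rest"]; q.U_exc = np["U_exc"];
  q.U_inh = np["U_inh"]; q.th_rest = np["theta_rest"];
  q.th_spike = np["theta_spike"]; q.tau_thr = np["tau_thr"];
  q.alpha = np["alpha"]; q.tau_ampa = np["tau_ampa"];
  q.tau_nmda = np["tau_nmda"]; q.tau_gaba = np["tau_gaba"];
  q.tau_a = np["tau_a"]; q.Delta_a = np["Delta_a"];
  return q;
}

// [[Rcpp::export]]
SEXP eng_build(List spec) {
  Engine* e = new Engine();
  e->dt = as<double>(spec["dt"]);
  e->dt_long = as<double>(spec["dt_long"]);
  e->long_every = std::max(1, (int)std::lround(e->dt_long / e->dt));
  e->exact_decay = as<bool>(spec["exact_decay"]);
  List gp = spec["global_plasticity"];
  e->tau_plus = gp["tau_plus"]; e->tau_minus = gp["tau_minus"];
  e->tau_slow = gp["tau_slow"]; e->tau_ht = gp["tau_ht"];
  e->tau_hom = gp["tau_hom"]; e->tau_istdp = gp["tau_istdp"];
  e->U_stp = gp["U_stp"]; e->tau_d = gp["tau_d"]; e->tau_f = gp["tau_f"];
  e->P_dw = gp["P"]; e->w_P = gp["w_P"];
  e->rng.seed(as<double>(spec["seed"]));

  List pops = spec["pops"];
  for (int i = 0; i < pops.size(); ++i) {
    List pl = pops[i];
    Pop pp;
    pp.name = as<std::string>(pl["name"]);
    pp.n = as<int>(pl["n"]);
    pp.u.assign(pp.n, e->U_stp); pp.x.assign(pp.n, 1.0);
    pp.zp.assign(pp.n, 0.0); pp.eff.assign(pp.n, 0.0);
    pp.is_active.assign(pp.n, 0);
    e->pops.push_back(pp);
  }
  List regs = spec["regions"];
  for (int i = 0; i < regs.size(); ++i) {
    List rl = regs[i];
    Region r;
    r.name = as<std::string>(rl["name"]);
    r.ne = as<int>(rl["ne"]); r.ni = as<int>(rl["ni"]);
    r.np = neurp_from_list(rl["neuron"]);
    r.tau_H = as<double>(rl["tau_H"]);
    int n = r.ne + r.ni;
    r.U.assign(n, r.np.U_rest); r.th.assign(n, r.np.th_rest);
    r.ga.assign(n, 0); r.gn.assign(n, 0); r.gg.assign(n, 0); r.gad.assign(n, 0);
    r.exc_in.assign(n, 0); r.inh_in.assign(n, 0); r.a_in.assign(n, 0);
    r.u.assign(r.ne, e->U_stp); r.x.assign(r.ne, 1.0);
    r.zp.assign(r.ne, 0); r.eff.assign(r.ne, 0);
    r.zm.assign(r.ne, 0); r.zs.assign(r.ne, 0); r.zht.assign(r.ne, 0);
    r.C.assign(r.ne, 0);
    r.zi_pre.assign(r.ni, 0); r.zi_post.assign(r.ne, 0);
    e->regions.push_back(r);
  }
  List prjs = spec["projections"];
  for (int i = 0; i < prjs.size(); ++i) {
    List pl = prjs[i];
    Proj p;
    p.name = as<std::string>(pl["name"]);
    p.src_kind = as<int>(pl["src_kind"]);
    std::string srcnm = as<std::string>(pl["src"]);
    std::string tgtnm = as<std::string>(pl["tgt"]);
    p.src_idx = (p.src_kind == 0) ? e->pop_index(srcnm) : e->region_index(srcnm);
    if (p.src_idx < 0) stop("unresolved projection source: " + srcnm);
    p.tgt_region = e->region_index(tgtnm);
    if (p.tgt_region < 0) stop("unresolved projection target: " + tgtnm);
    p.tgt_part = as<int>(pl["tgt_part"]);
    p.n_src = (p.src_kind == 0) ? e->pops[p.src_idx].n
              : (p.src_kind == 1 ? e->regions[p.src_idx].ne
                                 : e->regions[p.src_idx].ni);
    p.n_tgt = (p.tgt_part == 1) ? e->regions[p.tgt_region].ne
                                : e->regions[p.tgt_region].ni;
    IntegerVector src = pl["src_id"], tgt = pl["tgt_id"];
    NumericVector w0 = pl["w"];
    p.type = as<int>(pl["type"]);
    p.eta = as<double>(pl["eta"]); p.A = as<double>(pl["A"]);
    p.beta = as<double>(pl["beta"]); p.delta = as<double>(pl["delta"]);
    p.tau_cons = as<double>(pl["tau_cons"]);
    p.eta_inh = as<double>(pl["eta_inh"]); p.gamma = as<double>(pl["gamma"]);
    p.wmin = as<double>(pl["w_min"]); p.wmax = as<double>(pl["w_max"]);
    p.has_wt = (p.type == STP_LT);
    int m = src.size();
    // CSR build (sources 1-based from R)
    std::vector<int> cnt(p.n_src + 1, 0);
    for (int k = 0; k < m; ++k) cnt[src[k]]++;
    p.rptr.assign(p.n_src + 1, 0);
    for (int j = 0; j < p.n_src; ++j) p.rptr[j + 1] = p.rptr[j] + cnt[j + 1];
    std::vector<int> pos(p.rptr.begin(), p.rptr.end() - 1);
    p.col.assign(m, 0); p.w.assign(m, 0);
    for (int k = 0; k < m; ++k) {
      int j = src[k] - 1;
      int at = pos[j]++;
      p.col[at] = tgt[k] - 1;
      p.w[at] = std::min(std::max((double)w0[k], p.wmin), p.wmax);
    }
    if (p.has_wt) {
      p.wt.assign(m, 0.0);
      if (pl.containsElementNamed("w_tilde") && !Rf_isNull(pl["w_tilde"])) {
        NumericVector wt0 = pl["w_tilde"];
        // reorder to CSR order
        std::vector<int> pos2(p.rptr.begin(), p.rptr.end() - 1);
        for (int k = 0; k < m; ++k) p.wt[pos2[src[k] - 1]++] = wt0[k];
      }
    }
    // CSC build
    std::vector<int> ccnt(p.n_tgt + 1, 0);
    for (int k = 0; k < m; ++k) ccnt[p.col[k] + 1]++;
    p.cptr.assign(p.n_tgt + 1, 0);
    for (int j = 0; j < p.n_tgt; ++j) p.cptr[j + 1] = p.cptr[j] + ccnt[j + 1];
    std::vector<int> cpos(p.cptr.begin(), p.cptr.end() - 1);
    p.csyn.assign(m, 0); p.csrc.assign(m, 0);
    for (int j = 0; j < p.n_src; ++j)
      for (int k = p.rptr[j]; k < p.rptr[j + 1]; ++k) {
        int at = cpos[p.col[k]]++;
        p.csyn[at] = k; p.csrc[at] = j;
      }
    p.blocked.assign(p.n_src, 0);
    e->projs.push_back(p);
  }
  XPtr<Engine> xp(e, true);
  return xp;
}

// [[Rcpp::export]]
SEXP eng_clone(SEXP xp) {
  XPtr<Engine> p(xp);
  Engine* e = new Engine(*p);
  return XPtr<Engine>(e, true);
}

// [[Rcpp::export]]
void eng_seed(SEXP xp, double seed) {
  XPtr<Engine> e(xp);
  e->rng.seed((uint64_t)seed);
}

// [[Rcpp::export]]
double eng_time(SEXP xp) {
  XPtr<Engine> e(xp);
  return e->step_count * e->dt;
}

// locate a population by name for raster/group purposes:
// returns (kind: 0 pop / 1 region-exc / 2 region-inh, index)
static void find_pop(Engine* e, const std::string& nm, int& kind, int& idx) {
  idx = e->pop_index(nm);
  if (idx >= 0) { kind = 0; return; }
  size_t dot = nm.rfind('.');
  if (dot != std::string::npos) {
    std::string base = nm.substr(0, dot), part = nm.substr(dot + 1);
    int ri = e->region_index(base);
    if (ri >= 0 && (part == "e" || part == "i")) {
      kind = (part == "e") ? 1 : 2; idx = ri; return;
    }
  }
  stop("unknown population: " + nm);
}

// [[Rcpp::export]]
List eng_run(SEXP xp, double duration, List drive, List record) {
  XPtr<Engine> e(xp);
  int nsteps = (int)std::lround(duration / e->dt);
  double t0 = e->step_count * e->dt;

  // reset drives
  for (auto& pp : e->pops) {
    pp.active.clear();
    std::fill(pp.is_active.begin(), pp.is_active.end(), 0);
    pp.rate_a = 0; pp.rate_b = 0; pp.fixed = false;
    pp.fs_ptr.clear(); pp.fs_id.clear();
  }
  if (drive.size() > 0) {
    CharacterVector nms = drive.names();
    for (int i = 0; i < drive.size(); ++i) {
      std::string nm = as<std::string>(nms[i]);
      int pi = e->pop_index(nm);
      if (pi < 0) stop("drive names an unknown population: " + nm);
      Pop& pp = e->pops[pi];
      List d = drive[i];
      if (d.containsElementNamed("spike_step")) {
        IntegerVector st = d["spike_step"], id = d["spike_id"];
        pp.fixed = true;
        pp.fs_ptr.assign(nsteps + 1, 0);
        for (int k = 0; k < st.size(); ++k) {
          if (st[k] < 1 || st[k] > nsteps) stop("fixed spike step out of range");
          pp.fs_ptr[st[k]]++;
        }
        for (int k = 0; k < nsteps; ++k) pp.fs_ptr[k + 1] += pp.fs_ptr[k];
        pp.fs_id.assign(st.size(), 0);
        std::vector<int> pos(pp.fs_ptr.begin(), pp.fs_ptr.end() - 1);
        for (int k = 0; k < st.size(); ++k)
          pp.fs_id[pos[st[k] - 1]++] = id[k] - 1;
      } else {
        if (d.containsElementNamed("active")) {
          IntegerVector act = d["active"];
          for (int k = 0; k < act.size(); ++k) {
            int a = act[k] - 1;
            if (a < 0 || a >= pp.n) stop("active index out of range");
            pp.active.push_back(a);
            pp.is_active[a] = 1;
          }
        }
        if (d.containsElementNamed("rate_active"))
          pp.rate_a = as<double>(d["rate_active"]);
        if (d.containsElementNamed("rate_bg"))
          pp.rate_b = as<double>(d["rate_bg"]);
        if (pp.rate_a < 0 || pp.rate_b < 0) stop("negative drive rate");
      }
    }
  }
  // silent-population bookkeeping: a population with no drive this segment
  // relaxes toward its presynaptic fixed point and is clamped there once
  // the residual is below double precision
  for (auto& pp : e->pops) {
    bool silent = !pp.fixed && pp.rate_b <= 0 &&
      (pp.active.empty() || pp.rate_a <= 0);
    if (!silent) { pp.idle = false; pp.idle_countdown = -1; }
    else if (!pp.idle && pp.idle_countdown < 0)
      pp.idle_countdown = (long long)std::llround(35.0 * e->tau_f / e->dt);
  }

  // recording setup
  std::vector<int> ras_kind, ras_idx;
  std::vector<std::string> ras_names;
  if (record.containsElementNamed("raster") && !Rf_isNull(record["raster"])) {
    CharacterVector rs = record["raster"];
    for (int i = 0; i < rs.size(); ++i) {
      int k, ix;
      std::string nm = as<std::string>(rs[i]);
      find_pop(e, nm, k, ix);
      ras_kind.push_back(k); ras_idx.push_back(ix); ras_names.push_back(nm);
    }
  }
  std::vector<std::vector<double>> ras_t(ras_names.size());
  std::vector<std::vector<int>> ras_i(ras_names.size());

  double binw = 0; int nbins = 0, ngroups = 0;
  std::vector<std::vector<uint8_t>> gmask;  // per group: mask over its pop
  std::vector<int> g_kind, g_idx, g_size;
  if (record.containsElementNamed("bin") && !Rf_isNull(record["bin"])) {
    binw = as<double>(record["bin"]);
    if (binw > 0 && record.containsElementNamed("groups")) {
      List gl = record["groups"];
      ngroups = gl.size();
      nbins = (int)std::ceil(nsteps * e->dt / binw - 1e-9);
      for (int g = 0; g < ngroups; ++g) {
        List gg = gl[g];
        int k, ix;
        find_pop(e, as<std::string>(gg["pop"]), k, ix);
        g_kind.push_back(k); g_idx.push_back(ix);
        int n = (k == 0) ? e->pops[ix].n
                : (k == 1 ? e->regions[ix].ne : e->regions[ix].ni);
        std::vector<uint8_t> msk(n, 0);
        IntegerVector id = gg["idx"];
        for (int j = 0; j < id.size(); ++j) {
          if (id[j] < 1 || id[j] > n) stop("group index out of range");
          msk[id[j] - 1] = 1;
        }
        g_size.push_back((int)id.size());
        gmask.push_back(msk);
      }
    }
  }
  IntegerMatrix bin_counts(nbins, ngroups);

  for (int s = 0; s < nsteps; ++s) {
    e->step(s);
    double tsp = t0 + (double)(s + 1) * e->dt;
    int b = (binw > 0) ? std::min((int)((double)s * e->dt / binw), nbins - 1) : 0;
    // record spikes
    for (size_t ri = 0; ri < ras_names.size(); ++ri) {
      const std::vector<int>* sp;
      if (ras_kind[ri] == 0) sp = &e->pops[ras_idx[ri]].spikes;
      else if (ras_kind[ri] == 1) sp = &e->regions[ras_idx[ri]].sp_e;
      else sp = &e->regions[ras_idx[ri]].sp_i;
      for (int id : *sp) { ras_t[ri].push_back(tsp); ras_i[ri].push_back(id + 1); }
    }
    for (int g = 0; g < ngroups; ++g) {
      const std::vector<int>* sp;
      if (g_kind[g] == 0) sp = &e->pops[g_idx[g]].spikes;
      else if (g_kind[g] == 1) sp = &e->regions[g_idx[g]].sp_e;
      else sp = &e->regions[g_idx[g]].sp_i;
      for (int id : *sp)
        if (gmask[g][id]) bin_counts(b, g)++;
    }
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  List rasters(ras_names.size());
  for (size_t ri = 0; ri < ras_names.size(); ++ri)
    rasters[ri] = List::create(_["time"] = wrap(ras_t[ri]),
                               _["neuron"] = wrap(ras_i[ri]));
  if (ras_names.size()) rasters.names() = wrap(ras_names);

  return List::create(
      _["t_start"] = t0,
      _["t_end"] = e->step_count * e->dt,
      _["rasters"] = rasters,
      _["bin_counts"] = bin_counts,
      _["bin_width"] = binw,
      _["group_sizes"] = wrap(g_size));
}

// [[Rcpp::export]]
List eng_get_weights(SEXP xp, std::string proj) {
  XPtr<Engine> e(xp);
  Proj& p = e->projs[e->proj_index(proj)];
  int m = (int)p.w.size();
  IntegerVector src(m), tgt(m);
  NumericVector w(m);
  int at = 0;
  for (int j = 0; j < p.n_src; ++j)
    for (int k = p.rptr[j]; k < p.rptr[j + 1]; ++k) {
      src[at] = j + 1; tgt[at] = p.col[k] + 1; w[at] = p.w[k]; ++at;
    }
  List out = List::create(_["src"] = src, _["tgt"] = tgt, _["w"] = w);
  if (p.has_wt) {
    NumericVector wt(m);
    at = 0;
    for (int j = 0; j < p.n_src; ++j)
      for (int k = p.rptr[j]; k < p.rptr[j + 1]; ++k) wt[at++] = p.wt[k];
    out["w_tilde"] = wt;
  }
  return out;
}

// [[Rcpp::export]]
void eng_set_weights(SEXP xp, std::string proj, NumericVector w,
                     Nullable<NumericVector> w_tilde = R_NilValue) {
  XPtr<Engine> e(xp);
  Proj& p = e->projs[e->proj_index(proj)];
  if ((int)p.w.size() != w.size()) stop("weight vector length mismatch");
  for (int k = 0; k < w.size(); ++k)
    p.w[k] = std::min(std::max((double)w[k], p.wmin), p.wmax);
  if (w_tilde.isNotNull()) {
    if (!p.has_wt) stop("projection has no reference weights");
    NumericVector wt(w_tilde);
    if ((int)p.wt.size() != wt.size()) stop("w_tilde length mismatch");
    for (int k = 0; k < wt.size(); ++k) p.wt[k] = wt[k];
  }
}

// [[Rcpp::export]]
List eng_get_neuron_state(SEXP xp, std::string pop) {
  XPtr<Engine> e(xp);
  int kind, idx;
  find_pop(e, pop, kind, idx);
  if (kind == 0) {
    Pop& pp = e->pops[idx];
    return List::create(_["u"] = wrap(pp.u), _["x"] = wrap(pp.x),
                        _["z_plus"] = wrap(pp.zp));
  }
  Region& r = e->regions[idx];
  int off = (kind == 1) ? 0 : r.ne;
  int n = (kind == 1) ? r.ne : r.ni;
  auto slice = [&](std::vector<double>& v) {
    return NumericVector(v.begin() + off, v.begin() + off + n);
  };
  return List::create(
      _["U"] = slice(r.U), _["theta"] = slice(r.th),
      _["g_ampa"] = slice(r.ga), _["g_nmda"] = slice(r.gn),
      _["g_gaba"] = slice(r.gg), _["g_a"] = slice(r.gad));
}

// [[Rcpp::export]]
List eng_get_traces(SEXP xp, std::string region) {
  XPtr<Engine> e(xp);
  int ri = e->region_index(region);
  if (ri < 0) stop("unknown region: " + region);
  Region& r = e->regions[ri];
  return List::create(
      _["z_plus"] = wrap(r.zp), _["z_minus"] = wrap(r.zm),
      _["z_slow"] = wrap(r.zs), _["z_ht"] = wrap(r.zht),
      _["C"] = wrap(r.C), _["H"] = r.H,
      _["u"] = wrap(r.u), _["x"] = wrap(r.x),
      _["zi_pre"] = wrap(r.zi_pre), _["zi_post"] = wrap(r.zi_post));
}

// [[Rcpp::export]]
void eng_set_block(SEXP xp, std::string proj, LogicalVector blocked) {
  XPtr<Engine> e(xp);
  Proj& p = e->projs[e->proj_index(proj)];
  if (blocked.size() != p.n_src) stop("blocked mask length mismatch");
  for (int j = 0; j < p.n_src; ++j) p.blocked[j] = blocked[j] ? 1 : 0;
}

// [[Rcpp::export]]
LogicalVector eng_get_block(SEXP xp, std::string proj) {
  XPtr<Engine> e(xp);
  Proj& p = e->projs[e->proj_index(proj)];
  LogicalVector out(p.n_src);
  for (int j = 0; j < p.n_src; ++j) out[j] = p.blocked[j] != 0;
  return out;
}

// [[Rcpp::export]]
void eng_set_enabled(SEXP xp, std::string region, bool enabled) {
  XPtr<Engine> e(xp);
  int ri = e->region_index(region);
  if (ri < 0) stop("unknown region: " + region);
  e->regions[ri].enabled = enabled;
}

// [[Rcpp::export]]
void eng_set_proj_param(SEXP xp, std::string proj, std::string param,
                        double value) {
  XPtr<Engine> e(xp);
  Proj& p = e->projs[e->proj_index(proj)];
  if (param == "eta") p.eta = value;
  else if (param == "A") p.A = value;
  else if (param == "beta") p.beta = value;
  else if (param == "delta") p.delta = value;
  else if (param == "eta_inh") p.eta_inh = value;
  else if (param == "gamma") p.gamma = value;
  else if (param == "tau_cons") p.tau_cons = value;
  else stop("unknown projection parameter: " + param);
}

// [[Rcpp::export]]
double eng_get_proj_param(SEXP xp, std::string proj, std::string param) {
  XPtr<Engine> e(xp);
  Proj& p = e->projs[e->proj_index(proj)];
  if (param == "eta") return p.eta;
  if (param == "A") return p.A;
  if (param == "beta") return p.beta;
  if (param == "delta") return p.delta;
  if (param == "eta_inh") return p.eta_inh;
  if (param == "gamma") return p.gamma;
  if (param == "tau_cons") return p.tau_cons;
  stop("unknown projection parameter: " + param);
  return NA_REAL;
}

// [[Rcpp::export]]
CharacterVector eng_proj_names(SEXP xp) {
  XPtr<Engine> e(xp);
  CharacterVector out(e->projs.size());
  for (size_t i = 0; i < e->projs.size(); ++i) out[i] = e->projs[i].name;
  return out;
}

// [[Rcpp::export]]
double eng_saturation(SEXP xp, std::string proj) {
  XPtr<Engine> e(xp);
  Proj& p = e->projs[e->proj_index(proj)];
  if (p.w.empty()) return 0.0;
  int n = 0;
  for (double w : p.w)
    if (w <= p.wmin || w >= p.wmax) ++n;
  return (double)n / (double)p.w.size();
}
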