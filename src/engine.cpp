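// Protocol engine: runs the five agent architectures through task phases
// (exploration, trials, forced single-step probes) at C++ speed. The update
// rules are the same as the R reference implementations in R/sr_core.R and
// R/agents.R; matrices whose rows are updated per step (M, H) are stored
// transposed so each row update touches one contiguous column.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int A_COLLECT = 4;   // 0-based action codes: 0=N,1=E,2=S,3=W,4=collect
static const double TIE_TOL = 1e-9;

enum Kind { ONESTEP = 0, SRTD = 1, SRMB = 2, SRDYNA = 3, DYNAQ = 4 };
enum WMode { W_NORM = 0, W_PLAIN = 1, W_DIRECT = 2 };

struct WorldC {
  int S;
  arma::imat nbr;               // S x 4, 1-based state index or 0
  std::vector<int> open;        // 0/1
  std::vector<int> term;        // reward sites: collect-only, episode ends
  arma::vec rew;

  void load(const List& w) {
    S = as<int>(w["n_states"]);
    IntegerMatrix nb = w["neighbors"];
    nbr.set_size(S, 4);
    for (int s = 0; s < S; ++s)
      for (int a = 0; a < 4; ++a) nbr(s, a) = nb(s, a);
    LogicalVector op = w["open"];
    open.assign(op.begin(), op.end());
    LogicalVector tm = w["terminal"];
    term.assign(tm.begin(), tm.end());
    rew = as<arma::vec>(w["rewards"]);
  }
  // availability bitmask: bits 0..3 cardinal, bit 4 collect
  int avail_mask(int s) const {
    if (!open[s]) return 0;
    if (term[s]) return 1 << A_COLLECT;
    int m = 0;
    for (int a = 0; a < 4; ++a) {
      int nb = nbr(s, a);
      if (nb > 0 && open[nb - 1]) m |= (1 << a);
    }
    return m;
  }
};

static inline int draw_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// exponential rank distribution over 0..n-1: P(j) proportional to exp(-lambda j)
static inline int draw_exp_rank(int n, double lambda) {
  if (n == 1) return 0;
  double q = std::exp(-lambda);
  double qn = std::pow(q, n);
  double u = unif_rand();
  double x = std::log(1.0 - u * (1.0 - qn)) / std::log(q);
  int j = (int)std::floor(x);
  if (j < 0) j = 0;
  if (j >= n) j = n - 1;
  return j;
}

struct Agent {
  int kind;
  int S, SA;
  // parameters
  double gamma, eps, aw, asr, aq, api, lambda, change_tol;
  int n_replay, k_post, wmode;

  arma::vec V;                    // onestep
  arma::mat MT;                   // sr_td: transposed successor matrix
  arma::vec w;                    // sr_td / sr_mb state weights
  arma::mat pi;                   // sr_mb: S x 4 policy
  std::vector<int> Abelief;       // sr_mb: believed availability mask
  arma::mat HT;                   // sr_dyna: transposed state-action SR
  arma::vec wsa;                  // sr_dyna weights
  arma::mat Q;                    // dyna_q: S x 5
  std::vector<int> lastAvail;     // dyna agents: last observed availability
  std::vector<int> samp_s, samp_a, samp_s2;
  std::vector<double> samp_r;     // dyna_q only
  std::vector<std::vector<int> > by_sa;  // sample indices per pair, oldest first
  std::vector<int> seen_sa;              // pairs with at least one sample
  int pend_sa; double pend_r; bool pend_valid;
  bool wnz;                       // any nonzero weight yet

  void load_params(const List& p) {
    gamma = as<double>(p["gamma"]);
    eps = as<double>(p["epsilon"]);
    aw = as<double>(p["alpha_w"]);
    asr = as<double>(p["alpha_sr"]);
    aq = as<double>(p["alpha_q"]);
    api = as<double>(p["alpha_pi"]);
    n_replay = as<int>(p["n_replay_per_step"]);
    k_post = as<int>(p["k_post_change"]);
    lambda = as<double>(p["replay_lambda"]);
    change_tol = as<double>(p["change_tol"]);
    wmode = as<int>(p["weight_mode_code"]);
  }

  void load_state(const List& st) {
    if (kind == ONESTEP) {
      V = as<arma::vec>(st["V"]);
      S = V.n_elem;
    } else if (kind == SRTD) {
      MT = as<arma::mat>(st["MT"]);
      w = as<arma::vec>(st["w"]);
      S = w.n_elem;
    } else if (kind == SRMB) {
      pi = as<arma::mat>(st["pi"]);
      w = as<arma::vec>(st["w"]);
      IntegerVector ab = st["Abelief"];
      Abelief.assign(ab.begin(), ab.end());
      S = w.n_elem;
    } else if (kind == SRDYNA) {
      HT = as<arma::mat>(st["HT"]);
      wsa = as<arma::vec>(st["w"]);
      IntegerVector la = st["lastAvail"];
      lastAvail.assign(la.begin(), la.end());
      S = lastAvail.size();
      IntegerMatrix sm = st["samples"];
      int n = sm.nrow();
      samp_s.reserve(n + 65536); samp_a.reserve(n + 65536); samp_s2.reserve(n + 65536);
      for (int i = 0; i < n; ++i) {
        samp_s.push_back(sm(i, 0)); samp_a.push_back(sm(i, 1)); samp_s2.push_back(sm(i, 2));
      }
      NumericVector pd = st["pending"];
      pend_sa = (int)pd[0]; pend_r = pd[1]; pend_valid = pd[2] != 0;
    } else {
      Q = as<arma::mat>(st["Q"]);
      IntegerVector la = st["lastAvail"];
      lastAvail.assign(la.begin(), la.end());
      S = lastAvail.size();
      IntegerMatrix sm = st["samples"];
      NumericVector sr = st["samp_r"];
      int n = sm.nrow();
      samp_s.reserve(n + 65536); samp_a.reserve(n + 65536);
      samp_s2.reserve(n + 65536); samp_r.reserve(n + 65536);
      for (int i = 0; i < n; ++i) {
        samp_s.push_back(sm(i, 0)); samp_a.push_back(sm(i, 1)); samp_s2.push_back(sm(i, 2));
        samp_r.push_back(sr[i]);
      }
    }
    SA = 5 * S;
    wnz = as<bool>(st["wnz"]);
    if (kind == SRDYNA || kind == DYNAQ) {
      by_sa.assign(SA, std::vector<int>());
      for (size_t i = 0; i < samp_s.size(); ++i)
        index_sample((int)i);
    }
  }

  void index_sample(int i) {
    int sa = samp_s[i] * 5 + samp_a[i];
    if (by_sa[sa].empty()) seen_sa.push_back(sa);
    by_sa[sa].push_back(i);
  }

  List save_state() const {
    List st;
    if (kind == ONESTEP) {
      st["V"] = NumericVector(V.begin(), V.end());
    } else if (kind == SRTD) {
      st["MT"] = wrap(MT);
      st["w"] = NumericVector(w.begin(), w.end());
    } else if (kind == SRMB) {
      st["pi"] = wrap(pi);
      st["w"] = NumericVector(w.begin(), w.end());
      st["Abelief"] = IntegerVector(Abelief.begin(), Abelief.end());
    } else if (kind == SRDYNA) {
      st["HT"] = wrap(HT);
      st["w"] = NumericVector(wsa.begin(), wsa.end());
      st["lastAvail"] = IntegerVector(lastAvail.begin(), lastAvail.end());
      int n = samp_s.size();
      IntegerMatrix sm(n, 3);
      for (int i = 0; i < n; ++i) {
        sm(i, 0) = samp_s[i]; sm(i, 1) = samp_a[i]; sm(i, 2) = samp_s2[i];
      }
      st["samples"] = sm;
      st["pending"] = NumericVector::create((double)pend_sa, pend_r,
                                            pend_valid ? 1.0 : 0.0);
    } else {
      st["Q"] = wrap(Q);
      st["lastAvail"] = IntegerVector(lastAvail.begin(), lastAvail.end());
      int n = samp_s.size();
      IntegerMatrix sm(n, 3);
      NumericVector sr(n);
      for (int i = 0; i < n; ++i) {
        sm(i, 0) = samp_s[i]; sm(i, 1) = samp_a[i]; sm(i, 2) = samp_s2[i];
        sr[i] = samp_r[i];
      }
      st["samples"] = sm;
      st["samp_r"] = sr;
    }
    st["wnz"] = wnz;
    return st;
  }

  // believed availability at x (falls back to ground truth before first visit)
  int believed_mask(const WorldC& W, int x) const {
    int m = lastAvail[x];
    return m >= 0 ? m : W.avail_mask(x);
  }

  double max_q_avail(const WorldC& W, int x) const {
    int bm = believed_mask(W, x);
    if (bm == 0) return 0.0;
    double best = -1e300;
    for (int a = 0; a < 5; ++a)
      if (bm & (1 << a)) best = std::max(best, Q(x, a));
    return best;
  }

  // SR-MB: successor matrix implied by believed availability + cached policy
  arma::mat srmb_inverse(const WorldC& W) const {
    arma::mat Tm(S, S, arma::fill::zeros);
    for (int s = 0; s < S; ++s) {
      int bm = Abelief[s];
      if (bm == 0 || (bm & (1 << A_COLLECT))) continue;  // mass exits to terminal
      double tot = 0;
      for (int a = 0; a < 4; ++a) if (bm & (1 << a)) tot += pi(s, a);
      if (tot <= 0) continue;
      for (int a = 0; a < 4; ++a) {
        if (!(bm & (1 << a))) continue;
        int nb = W.nbr(s, a);
        int dest = (nb > 0) ? nb - 1 : s;   // believed move into a border: bump
        Tm(s, dest) += pi(s, a) / tot;
      }
    }
    return arma::inv(arma::eye(S, S) - gamma * Tm);
  }

  void normalized_w_update(arma::vec& wv, const arma::vec& f, double delta) {
    if (delta == 0) return;
    double scale = aw * delta;
    if (wmode == W_NORM) {
      double n2 = arma::dot(f, f);
      if (n2 <= 0) return;
      scale /= n2;
    }
    wv += scale * f;
    wnz = true;
  }

  // --- SR-Dyna machinery -------------------------------------------------

  int argmax_pair(const WorldC& W, int x) const {
    int bm = believed_mask(W, x);
    if (bm == 0) return -1;
    int best[5]; int bn = 0; double bq = -1e300;
    for (int a = 0; a < 5; ++a) {
      if (!(bm & (1 << a))) continue;
      double qv = wnz ? arma::dot(HT.col(x * 5 + a), wsa) : 0.0;
      if (qv > bq + TIE_TOL) { bq = qv; bn = 0; best[bn++] = a; }
      else if (qv >= bq - TIE_TOL) { best[bn++] = a; if (qv > bq) bq = qv; }
    }
    int a = (bn == 1) ? best[0] : best[draw_int(bn)];
    return x * 5 + a;
  }

  void h_replay(const WorldC& W, int idx) {
    int s = samp_s[idx], a = samp_a[idx], s2 = samp_s2[idx];
    int sa = s * 5 + a;
    int cont = (s2 >= 0) ? argmax_pair(W, s2) : -1;
    HT.col(sa) *= (1.0 - asr);
    HT(sa, sa) += asr;
    if (cont >= 0) HT.col(sa) += (asr * gamma) * HT.col(cont);
  }

  void q_replay(const WorldC& W, int idx) {
    int s = samp_s[idx], a = samp_a[idx], s2 = samp_s2[idx];
    double cont = (s2 >= 0) ? max_q_avail(W, s2) : 0.0;
    double delta = samp_r[idx] + gamma * cont - Q(s, a);
    Q(s, a) += aq * delta;
  }

  // replay draw (used both between decisions and in post-change bursts):
  // a state-action pair is chosen uniformly among experienced pairs, then
  // one of its samples by exponential recency rank (most recent = rank 0)
  void replay_draws(const WorldC& W, int count) {
    if (seen_sa.empty() || count == 0) return;
    int m = seen_sa.size();
    for (int i = 0; i < count; ++i) {
      const std::vector<int>& lst = by_sa[seen_sa[draw_int(m)]];
      int j = draw_exp_rank(lst.size(), lambda);
      int idx = lst[lst.size() - 1 - j];
      if (kind == SRDYNA) h_replay(W, idx); else q_replay(W, idx);
    }
  }

  void drop_pending() { pend_valid = false; }

  // --- one agent-environment step ----------------------------------------
  // returns next state (0-based) or -1 on terminal
  int do_step(const WorldC& W, int s, int* out_a, double* out_r, int* out_s2) {
    int mask = W.avail_mask(s);
    if (mask == 0) stop("agent occupies a state with no available action");

    // observation of the occupied state
    bool avail_trigger = false;
    if (kind == SRMB) Abelief[s] = mask;
    if (kind == SRDYNA || kind == DYNAQ) {
      if (lastAvail[s] >= 0 && lastAvail[s] != mask) avail_trigger = true;
      lastAvail[s] = mask;
    }

    int acts[5]; int m = 0;
    for (int a = 0; a < 5; ++a) if (mask & (1 << a)) acts[m++] = a;

    // action values
    double qv[5];
    arma::mat Minv;  arma::vec Vmb;  bool have_mb = false;
    for (int i = 0; i < m; ++i) qv[i] = 0.0;
    if (m > 1) {
      switch (kind) {
      case ONESTEP:
        for (int i = 0; i < m; ++i)
          qv[i] = (acts[i] == A_COLLECT) ? 0.0 : V[W.nbr(s, acts[i]) - 1];
        break;
      case SRTD:
        if (wnz)
          for (int i = 0; i < m; ++i)
            qv[i] = (acts[i] == A_COLLECT) ? 0.0
                  : arma::dot(MT.col(W.nbr(s, acts[i]) - 1), w);
        break;
      case SRMB:
        if (wnz) {
          Minv = srmb_inverse(W);
          Vmb = Minv * w;
          have_mb = true;
          for (int i = 0; i < m; ++i)
            qv[i] = (acts[i] == A_COLLECT) ? 0.0 : Vmb[W.nbr(s, acts[i]) - 1];
        }
        break;
      case SRDYNA:
        if (wnz)
          for (int i = 0; i < m; ++i)
            qv[i] = arma::dot(HT.col(s * 5 + acts[i]), wsa);
        break;
      case DYNAQ:
        for (int i = 0; i < m; ++i) qv[i] = Q(s, acts[i]);
        break;
      }
    }

    // epsilon-greedy with uniform tie-breaking
    int a;
    if (m == 1) {
      a = acts[0];
    } else if (unif_rand() < eps) {
      a = acts[draw_int(m)];
    } else {
      double mx = qv[0];
      for (int i = 1; i < m; ++i) if (qv[i] > mx) mx = qv[i];
      int best[5]; int bn = 0;
      for (int i = 0; i < m; ++i) if (qv[i] >= mx - TIE_TOL) best[bn++] = acts[i];
      a = (bn == 1) ? best[0] : best[draw_int(bn)];
    }

    // environment transition
    bool term = (a == A_COLLECT);
    double r = term ? W.rew[s] : 0.0;
    int s2 = term ? -1 : W.nbr(s, a) - 1;
    if (out_a) { *out_a = a; *out_r = r; *out_s2 = s2; }

    // learning updates
    switch (kind) {
    case ONESTEP: {
      double vn = term ? 0.0 : V[s2];
      V[s] += aw * (r + gamma * vn - V[s]);
      if (V[s] != 0) wnz = true;
      break;
    }
    case SRTD: {
      double vs = wnz ? arma::dot(MT.col(s), w) : 0.0;
      double vn = (term || !wnz) ? 0.0 : arma::dot(MT.col(s2), w);
      double delta = r + gamma * vn - vs;
      arma::vec f;
      bool need_f = (wmode != W_DIRECT) && (delta != 0);
      if (need_f) f = MT.col(s);
      MT.col(s) *= (1.0 - asr);
      MT(s, s) += asr;
      if (!term) MT.col(s) += (asr * gamma) * MT.col(s2);
      if (wmode == W_DIRECT) {
        w[s] += aw * (r - w[s]);
        if (w[s] != 0) wnz = true;
      } else if (need_f) {
        normalized_w_update(w, f, delta);
      }
      break;
    }
    case SRMB: {
      if (a < 4) {
        pi.row(s) *= (1.0 - api);
        pi(s, a) += api;
      }
      // a forced step skips the choice-time model computation; values are
      // still needed for the weight update whenever a signal can exist
      if (!have_mb && (wnz || r != 0)) {
        Minv = srmb_inverse(W);
        Vmb = Minv * w;
        have_mb = true;
      }
      double vs = have_mb ? Vmb[s] : 0.0;
      double vn = (term || !have_mb) ? 0.0 : Vmb[s2];
      double delta = r + gamma * vn - vs;
      if (delta != 0) {
        arma::vec f = Minv.row(s).t();
        normalized_w_update(w, f, delta);
      }
      break;
    }
    case SRDYNA: {
      int sa = s * 5 + a;
      bool rew_trigger = false;
      if (term) {
        double qsa = wnz ? arma::dot(HT.col(sa), wsa) : 0.0;
        if (std::fabs(r - qsa) > change_tol) rew_trigger = true;
      }
      // complete the pending SARSA pair now that its successor action is known
      if (pend_valid) {
        double qcur = wnz ? arma::dot(HT.col(sa), wsa) : 0.0;
        double qp = wnz ? arma::dot(HT.col(pend_sa), wsa) : 0.0;
        double delta = pend_r + gamma * qcur - qp;
        arma::vec f;
        if (delta != 0) f = HT.col(pend_sa);
        HT.col(pend_sa) *= (1.0 - asr);
        HT(pend_sa, pend_sa) += asr;
        HT.col(pend_sa) += (asr * gamma) * HT.col(sa);
        if (delta != 0) normalized_w_update(wsa, f, delta);
        pend_valid = false;
      }
      if (term) {
        double qsa = wnz ? arma::dot(HT.col(sa), wsa) : 0.0;
        double delta = r - qsa;
        arma::vec f;
        if (delta != 0) f = HT.col(sa);
        HT.col(sa) *= (1.0 - asr);
        HT(sa, sa) += asr;
        if (delta != 0) normalized_w_update(wsa, f, delta);
      } else {
        pend_sa = sa; pend_r = r; pend_valid = true;
      }
      samp_s.push_back(s); samp_a.push_back(a); samp_s2.push_back(s2);
      index_sample((int)samp_s.size() - 1);
      replay_draws(W, n_replay);
      if (avail_trigger || rew_trigger) replay_draws(W, k_post);
      break;
    }
    case DYNAQ: {
      bool rew_trigger = term && (std::fabs(r - Q(s, a)) > change_tol);
      double cont = term ? 0.0 : max_q_avail(W, s2);
      Q(s, a) += aq * (r + gamma * cont - Q(s, a));
      samp_s.push_back(s); samp_a.push_back(a); samp_s2.push_back(s2);
      samp_r.push_back(r);
      index_sample((int)samp_s.size() - 1);
      replay_draws(W, n_replay);
      if (avail_trigger || rew_trigger) replay_draws(W, k_post);
      break;
    }
    }
    return term ? -1 : s2;
  }

  // recorded state-value table: V-agents report V(s); Q-agents the max
  // available action value; walled cells are NA
  NumericVector record_values(const WorldC& W) {
    NumericVector out(S, NA_REAL);
    arma::vec Vv;
    if (kind == SRTD) Vv = MT.t() * w;
    if (kind == SRMB) Vv = srmb_inverse(W) * w;
    for (int s = 0; s < S; ++s) {
      if (!W.open[s]) continue;
      switch (kind) {
      case ONESTEP: out[s] = V[s]; break;
      case SRTD: case SRMB: out[s] = Vv[s]; break;
      case SRDYNA: {
        int bm = W.avail_mask(s);
        double best = 0;
        bool any = false;
        for (int a = 0; a < 5; ++a) {
          if (!(bm & (1 << a))) continue;
          double qv = arma::dot(HT.col(s * 5 + a), wsa);
          if (!any || qv > best) { best = qv; any = true; }
        }
        out[s] = any ? best : 0.0;
        break;
      }
      case DYNAQ: {
        int bm = W.avail_mask(s);
        double best = 0;
        bool any = false;
        for (int a = 0; a < 5; ++a) {
          if (!(bm & (1 << a))) continue;
          if (!any || Q(s, a) > best) { best = Q(s, a); any = true; }
        }
        out[s] = any ? best : 0.0;
        break;
      }
      }
    }
    return out;
  }
};

static int kind_code(const std::string& kind) {
  if (kind == "onestep_td") return ONESTEP;
  if (kind == "sr_td") return SRTD;
  if (kind == "sr_mb") return SRMB;
  if (kind == "sr_dyna") return SRDYNA;
  if (kind == "dyna_q") return DYNAQ;
  stop("unknown agent kind '%s'", kind.c_str());
  return -1;
}

// [[Rcpp::export(name = ".agent_init_cpp")]]
List agent_init_cpp(std::string kind, int S) {
  int k = kind_code(kind);
  List st;
  if (k == ONESTEP) {
    st["V"] = NumericVector(S);
  } else if (k == SRTD) {
    arma::mat M = arma::eye(S, S);
    st["MT"] = wrap(M);
    st["w"] = NumericVector(S);
  } else if (k == SRMB) {
    NumericMatrix pi(S, 4);
    std::fill(pi.begin(), pi.end(), 0.25);
    st["pi"] = pi;
    st["w"] = NumericVector(S);
    st["Abelief"] = IntegerVector(S, 15);  // all four cardinal actions believed
  } else if (k == SRDYNA) {
    arma::mat H = arma::eye(5 * S, 5 * S);
    st["HT"] = wrap(H);
    st["w"] = NumericVector(5 * S);
    st["lastAvail"] = IntegerVector(S, -1);
    st["samples"] = IntegerMatrix(0, 3);
    st["pending"] = NumericVector::create(-1.0, 0.0, 0.0);
  } else {
    st["Q"] = NumericMatrix(S, 5);
    st["lastAvail"] = IntegerVector(S, -1);
    st["samples"] = IntegerMatrix(0, 3);
    st["samp_r"] = NumericVector(0);
  }
  st["wnz"] = false;
  return st;
}

// [[Rcpp::export(name = ".run_protocol_cpp")]]
List run_protocol_cpp(std::string kind, List state, List params, List phases) {
  Agent A;
  A.kind = kind_code(kind);
  A.load_params(params);
  A.load_state(state);

  WorldC W;
  bool have_world = false;

  std::vector<NumericVector> records;
  std::vector<int> trial_lengths;
  bool capped = false;
  int last_a = NA_INTEGER, last_s2 = NA_INTEGER;
  double last_r = NA_REAL;

  int n_phases = phases.size();
  for (int p = 0; p < n_phases; ++p) {
    List ph = phases[p];
    std::string type = as<std::string>(ph["type"]);
    if (type == "world") {
      W.load(ph["world"]);
      have_world = true;
      continue;
    }
    if (!have_world) stop("protocol must set a world before phase '%s'", type.c_str());
    if (type == "explore") {
      int steps = as<int>(ph["steps"]);
      int start = as<int>(ph["start"]) - 1;
      A.drop_pending();
      int s = start;
      for (int i = 0; i < steps; ++i) {
        s = A.do_step(W, s, NULL, NULL, NULL);
        if (s < 0) s = start;
      }
      A.drop_pending();
    } else if (type == "trials") {
      IntegerVector starts = ph["starts"];
      int n_trials = as<int>(ph["n_trials"]);
      int cap = as<int>(ph["cap"]);
      for (int t = 0; t < n_trials; ++t) {
        int s = starts[t % starts.size()] - 1;
        A.drop_pending();
        int len = 0;
        while (true) {
          s = A.do_step(W, s, NULL, NULL, NULL);
          ++len;
          if (s < 0) break;
          if (len >= cap) { capped = true; break; }
        }
        trial_lengths.push_back(len);
      }
      A.drop_pending();
    } else if (type == "probes") {
      int at = as<int>(ph["at"]) - 1;
      int n = as<int>(ph["n"]);
      for (int i = 0; i < n; ++i) {
        A.drop_pending();
        A.do_step(W, at, NULL, NULL, NULL);
      }
      A.drop_pending();
    } else if (type == "step") {
      int at = as<int>(ph["at"]) - 1;
      int a, s2; double r;
      A.do_step(W, at, &a, &r, &s2);
      last_a = a + 1; last_r = r;
      last_s2 = (s2 >= 0) ? s2 + 1 : NA_INTEGER;
    } else if (type == "record") {
      records.push_back(A.record_values(W));
    } else {
      stop("unknown phase type '%s'", type.c_str());
    }
  }

  List recs(records.size());
  for (size_t i = 0; i < records.size(); ++i) recs[i] = records[i];
  return List::create(
    _["state"] = A.save_state(),
    _["values"] = recs,
    _["trial_lengths"] = IntegerVector(trial_lengths.begin(), trial_lengths.end()),
    _["capped"] = capped,
    _["last_action"] = last_a,
    _["last_reward"] = last_r,
    _["last_s_next"] = last_s2);
}
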