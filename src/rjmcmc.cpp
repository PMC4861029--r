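// Reversible-jump MCMC core for pedigree-based bi-allelic QTL mapping.
//
// Model: y = mu + sum_k a_k w_k + e, e ~ N(0, se2). Each QTL k carries a
// map position, an additive effect a_k ~ N(0, s2a_k), a founder allele
// frequency f_k, alleles on every base (founder) homolog, and segregation
// indicators on every tracked meiosis. The genotype code w in {-1,0,1}
// (qq, Qq, QQ) of every pedigree member is implied deterministically by the
// founder alleles and the indicators. The number of QTLs has a Poisson
// prior and is sampled with birth/death reversible jumps whose new
// component is drawn from its prior, so the acceptance ratio reduces to
// the likelihood ratio times the Poisson count ratio.
//
// All randomness comes from R's RNG: callers seed with set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double haldane_r(double d) {
  return 0.5 * (1.0 - std::exp(-2.0 * d / 100.0));
}

struct IoLg {
  std::vector<double> pos;
  std::vector<int> org;  // 0 = parent's homolog 1 (maternal), 1 = homolog 2
};

struct Engine {
  int n, n_base, M, n_lg;
  std::vector<int> par;   // n*2 parent row (-1 unknown); slot i*2+s, s=0 dam
  std::vector<int> base;  // n*2 base homolog id or -1
  std::vector<int> meio;  // n*2 meiosis id or -1
  std::vector<int> base_owner;           // n_base -> slot
  std::vector<int> meio_owner;           // M -> slot
  std::vector<std::vector<std::pair<int, int>>> children;  // (child, side)
  std::vector<double> lg_len;
  std::vector<IoLg> io;  // M * n_lg
};

// P(segregation indicator = 1 | flanking informative origins, position)
static double prob_org1(const Engine& E, int m, int g, double pos) {
  const IoLg& v = E.io[(size_t)m * E.n_lg + g];
  size_t k = v.pos.size();
  if (k == 0) return 0.5;
  size_t lo = std::lower_bound(v.pos.begin(), v.pos.end(), pos) -
    v.pos.begin();
  double w1 = 1.0, w0 = 1.0;
  if (lo > 0) {
    double r = haldane_r(pos - v.pos[lo - 1]);
    if (v.org[lo - 1] == 1) { w1 *= 1 - r; w0 *= r; }
    else                    { w1 *= r; w0 *= 1 - r; }
  }
  if (lo < k) {
    double r = haldane_r(v.pos[lo] - pos);
    if (v.org[lo] == 1) { w1 *= 1 - r; w0 *= r; }
    else                { w1 *= r; w0 *= 1 - r; }
  }
  double p = w1 / (w0 + w1);
  if (p < 1e-12) p = 1e-12;
  if (p > 1 - 1e-12) p = 1 - 1e-12;
  return p;
}

struct Qtl {
  int lg;
  double pos, a, s2a, f;
  std::vector<int> baseall;  // n_base
  std::vector<int> hap;      // n*2
  std::vector<int> seg;      // n*2, valid where meio >= 0
  std::vector<int> w;        // n
  std::vector<double> p1;    // M: P(seg = 1) at the current position
};

struct Prior {
  double lambda, a_shape, a_scale, e_shape, e_scale, beta_a, beta_b;
};

static void fill_p1(const Engine& E, Qtl& q) {
  q.p1.resize(E.M);
  for (int m = 0; m < E.M; m++) q.p1[m] = prob_org1(E, m, q.lg, q.pos);
}

static void compute_geno(const Engine& E, Qtl& q) {
  for (int i = 0; i < E.n; i++) {
    for (int s = 0; s < 2; s++) {
      int p = E.par[i * 2 + s];
      if (p < 0) q.hap[i * 2 + s] = q.baseall[E.base[i * 2 + s]];
      else q.hap[i * 2 + s] = q.hap[p * 2 + q.seg[i * 2 + s]];
    }
    q.w[i] = q.hap[i * 2] + q.hap[i * 2 + 1] - 1;
  }
}

// homolog slots whose allele toggles when slot (i,s) toggles
static void collect_cascade(const Engine& E, const Qtl& q, int slot,
                            std::vector<int>& slots) {
  slots.clear();
  std::vector<int> stack{slot};
  while (!stack.empty()) {
    int cur = stack.back();
    stack.pop_back();
    slots.push_back(cur);
    int ci = cur / 2;
    for (const auto& ch : E.children[ci]) {
      if (q.seg[ch.first * 2 + ch.second] == (cur & 1))
        stack.push_back(ch.first * 2 + ch.second);
    }
  }
}

// per-individual dosage change implied by toggling `slots`
static void aggregate_dw(const Qtl& q, const std::vector<int>& slots,
                         std::vector<std::pair<int, int>>& agg) {
  agg.clear();
  for (int slot : slots) {
    int ind = slot / 2;
    int dw = q.hap[slot] ? -1 : 1;
    bool found = false;
    for (auto& pr : agg)
      if (pr.first == ind) { pr.second += dw; found = true; break; }
    if (!found) agg.emplace_back(ind, dw);
  }
}

static double toggle_dll(const std::vector<std::pair<int, int>>& agg,
                         const std::vector<double>& resid,
                         const std::vector<char>& has_y, double a,
                         double se2) {
  double dll = 0;
  for (const auto& pr : agg) {
    if (!has_y[pr.first]) continue;
    double r = resid[pr.first], d = a * pr.second;
    dll -= ((r - d) * (r - d) - r * r) / (2 * se2);
  }
  return dll;
}

static void apply_toggle(Qtl& q, const std::vector<int>& slots,
                         const std::vector<std::pair<int, int>>& agg,
                         std::vector<double>& resid,
                         const std::vector<char>& has_y) {
  for (int slot : slots) q.hap[slot] ^= 1;
  for (const auto& pr : agg) {
    q.w[pr.first] += pr.second;
    if (has_y[pr.first]) resid[pr.first] -= q.a * pr.second;
  }
}

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

static Engine build_engine(List eng) {
  Engine E;
  E.n = as<int>(eng["n"]);
  E.n_base = as<int>(eng["n_base"]);
  E.M = as<int>(eng["M"]);
  E.n_lg = as<int>(eng["n_lg"]);
  IntegerVector par = eng["par"], base = eng["base"], meio = eng["meio"];
  E.par.assign(par.begin(), par.end());
  E.base.assign(base.begin(), base.end());
  E.meio.assign(meio.begin(), meio.end());
  E.base_owner.assign(E.n_base, -1);
  E.meio_owner.assign(E.M, -1);
  E.children.assign(E.n, {});
  for (int i = 0; i < E.n; i++) {
    for (int s = 0; s < 2; s++) {
      int slot = i * 2 + s;
      if (E.par[slot] >= 0) {
        E.children[E.par[slot]].emplace_back(i, s);
        E.meio_owner[E.meio[slot]] = slot;
      } else {
        E.base_owner[E.base[slot]] = slot;
      }
    }
  }
  NumericVector ll = eng["lg_len"];
  E.lg_len.assign(ll.begin(), ll.end());
  // io flattened: offsets (M*n_lg+1), positions, origins
  IntegerVector off = eng["io_off"], org = eng["io_org"];
  NumericVector pos = eng["io_pos"];
  E.io.resize((size_t)E.M * E.n_lg);
  for (size_t c = 0; c < E.io.size(); c++) {
    for (int j = off[c]; j < off[c + 1]; j++) {
      E.io[c].pos.push_back(pos[j]);
      E.io[c].org.push_back(org[j]);
    }
  }
  return E;
}

static Qtl born_from_prior(const Engine& E, const Prior& P, double total_len) {
  Qtl q;
  double u = R::unif_rand() * total_len, acc = 0;
  q.lg = E.n_lg - 1;
  for (int g = 0; g < E.n_lg; g++) {
    acc += E.lg_len[g];
    if (u <= acc) { q.lg = g; break; }
  }
  q.pos = R::unif_rand() * E.lg_len[q.lg];
  q.f = R::rbeta(P.beta_a, P.beta_b);
  q.s2a = rinvgamma(P.a_shape, P.a_scale);
  q.a = R::norm_rand() * std::sqrt(q.s2a);
  q.baseall.resize(E.n_base);
  for (int b = 0; b < E.n_base; b++)
    q.baseall[b] = (R::unif_rand() < q.f) ? 1 : 0;
  q.hap.assign(E.n * 2, 0);
  q.seg.assign(E.n * 2, 0);
  q.w.assign(E.n, 0);
  fill_p1(E, q);
  for (int m = 0; m < E.M; m++)
    q.seg[E.meio_owner[m]] = (R::unif_rand() < q.p1[m]) ? 1 : 0;
  compute_geno(E, q);
  return q;
}

// [[Rcpp::export]]
List rjmcmc_cpp(List eng, NumericVector y, List prior, List settings) {
  Engine E = build_engine(eng);
  Prior P;
  P.lambda = as<double>(prior["lambda"]);
  P.a_shape = as<double>(prior["a_shape"]);
  P.a_scale = as<double>(prior["a_scale"]);
  P.e_shape = as<double>(prior["e_shape"]);
  P.e_scale = as<double>(prior["e_scale"]);
  P.beta_a = as<double>(prior["beta_a"]);
  P.beta_b = as<double>(prior["beta_b"]);
  int n_iter = as<int>(settings["n_iter"]);
  int n_store = as<int>(settings["n_store"]);
  int burnin = as<int>(settings["burnin"]);
  double pos_step = as<double>(settings["pos_step"]);
  bool flat = as<bool>(settings["flat_likelihood"]);
  int max_qtl = as<int>(settings["max_qtl"]);
  bool store_w = as<bool>(settings["store_w"]);

  double total_len = 0;
  for (double l : E.lg_len) total_len += l;

  std::vector<char> has_y(E.n, 0);
  int n_phen = 0;
  for (int i = 0; i < E.n; i++)
    if (!NumericVector::is_na(y[i])) { has_y[i] = 1; n_phen++; }

  double mu = 0, se2 = 1;
  if (!flat) {
    double s = 0;
    for (int i = 0; i < E.n; i++) if (has_y[i]) s += y[i];
    mu = s / std::max(n_phen, 1);
    double ss = 0;
    for (int i = 0; i < E.n; i++)
      if (has_y[i]) ss += (y[i] - mu) * (y[i] - mu);
    se2 = std::max(ss / std::max(n_phen - 1, 1), 1e-8);
  }
  std::vector<Qtl> qtls;
  std::vector<double> resid(E.n, 0);
  for (int i = 0; i < E.n; i++) if (has_y[i]) resid[i] = y[i] - mu;

  int store_every = std::max((n_iter - burnin) / std::max(n_store, 1), 1);
  std::vector<int> st_count;
  std::vector<double> st_mu, st_se2;
  std::vector<int> st_sample, st_lg;
  std::vector<double> st_pos, st_a, st_s2a, st_f;
  std::vector<int> st_w;  // row-major per stored QTL entry
  long acc_birth = 0, try_birth = 0, acc_death = 0, try_death = 0,
    acc_pos = 0, try_pos = 0;

  std::vector<int> slots;
  std::vector<std::pair<int, int>> agg;

  for (int it = 0; it < n_iter; it++) {
    // ---- per-QTL updates -------------------------------------------------
    for (size_t k = 0; k < qtls.size(); k++) {
      Qtl& q = qtls[k];
      // segregation indicators, single-site Gibbs
      for (int m = 0; m < E.M; m++) {
        int slot = E.meio_owner[m];
        int cur = q.seg[slot];
        double p1 = q.p1[m];
        double lpr = cur == 1 ? std::log((1 - p1) / p1)
                              : std::log(p1 / (1 - p1));
        int parent = E.par[slot];
        int new_allele = q.hap[parent * 2 + (1 - cur)];
        double logit;
        if (new_allele == q.hap[slot]) {
          logit = lpr;  // genotype unchanged; prior only
          if (R::unif_rand() < 1.0 / (1.0 + std::exp(-logit)))
            q.seg[slot] ^= 1;
        } else {
          collect_cascade(E, q, slot, slots);
          aggregate_dw(q, slots, agg);
          double dll = flat ? 0.0 :
            toggle_dll(agg, resid, has_y, q.a, se2);
          logit = lpr + dll;
          if (R::unif_rand() < 1.0 / (1.0 + std::exp(-logit))) {
            apply_toggle(q, slots, agg, resid, has_y);
            q.seg[slot] ^= 1;
          }
        }
      }
      // base (founder) alleles, single-site Gibbs
      for (int b = 0; b < E.n_base; b++) {
        int slot = E.base_owner[b];
        int cur = q.baseall[b];
        double lpr = cur == 1 ? std::log((1 - q.f) / q.f)
                              : std::log(q.f / (1 - q.f));
        collect_cascade(E, q, slot, slots);
        aggregate_dw(q, slots, agg);
        double dll = flat ? 0.0 : toggle_dll(agg, resid, has_y, q.a, se2);
        if (R::unif_rand() < 1.0 / (1.0 + std::exp(-(lpr + dll)))) {
          apply_toggle(q, slots, agg, resid, has_y);
          q.baseall[b] ^= 1;
        }
      }
      // founder allele frequency, conjugate Beta
      {
        int c1 = 0;
        for (int b = 0; b < E.n_base; b++) c1 += q.baseall[b];
        q.f = R::rbeta(P.beta_a + c1, P.beta_b + E.n_base - c1);
        if (q.f < 1e-9) q.f = 1e-9;
        if (q.f > 1 - 1e-9) q.f = 1 - 1e-9;
      }
      // additive effect, conjugate normal
      if (flat) {
        q.a = R::norm_rand() * std::sqrt(q.s2a);
      } else {
        double sxx = 0, sxy = 0;
        for (int i = 0; i < E.n; i++) {
          if (!has_y[i] || q.w[i] == 0) continue;
          double rk = resid[i] + q.a * q.w[i];
          sxx += (double)q.w[i] * q.w[i];
          sxy += q.w[i] * rk;
        }
        double prec = sxx / se2 + 1.0 / q.s2a;
        double mean = (sxy / se2) / prec;
        double a_new = mean + R::norm_rand() / std::sqrt(prec);
        double da = a_new - q.a;
        for (int i = 0; i < E.n; i++)
          if (has_y[i] && q.w[i] != 0) resid[i] -= da * q.w[i];
        q.a = a_new;
      }
      // per-QTL variance, conjugate inverse-gamma
      q.s2a = rinvgamma(P.a_shape + 0.5, P.a_scale + 0.5 * q.a * q.a);
      // position, random-walk Metropolis within the linkage group
      {
        try_pos++;
        double L = E.lg_len[q.lg];
        double p2 = q.pos + R::norm_rand() * pos_step;
        for (int guard = 0; guard < 64 && (p2 < 0 || p2 > L); guard++)
          p2 = p2 < 0 ? -p2 : 2 * L - p2;
        if (p2 >= 0 && p2 <= L) {
          double lr = 0;
          std::vector<double> p1new(E.M);
          for (int m = 0; m < E.M; m++) {
            int slot = E.meio_owner[m];
            p1new[m] = prob_org1(E, m, q.lg, p2);
            lr += q.seg[slot] == 1
              ? std::log(p1new[m] / q.p1[m])
              : std::log((1 - p1new[m]) / (1 - q.p1[m]));
          }
          if (std::log(R::unif_rand()) < lr) {
            q.pos = p2;
            q.p1.swap(p1new);
            acc_pos++;
          }
        }
      }
    }
    // ---- intercept and residual variance ---------------------------------
    if (!flat && n_phen > 0) {
      double s = 0;
      for (int i = 0; i < E.n; i++) if (has_y[i]) s += resid[i] + mu;
      double mu_new = s / n_phen + R::norm_rand() * std::sqrt(se2 / n_phen);
      for (int i = 0; i < E.n; i++) if (has_y[i]) resid[i] += mu - mu_new;
      mu = mu_new;
      double ssr = 0;
      for (int i = 0; i < E.n; i++) if (has_y[i]) ssr += resid[i] * resid[i];
      se2 = rinvgamma(P.e_shape + 0.5 * n_phen, P.e_scale + 0.5 * ssr);
    } else if (flat) {
      se2 = rinvgamma(P.e_shape, P.e_scale);
    }
    // ---- reversible jump: birth / death ----------------------------------
    if (R::unif_rand() < 0.5) {
      if ((int)qtls.size() < max_qtl) {
        try_birth++;
        Qtl q = born_from_prior(E, P, total_len);
        double dll = 0;
        if (!flat) {
          for (int i = 0; i < E.n; i++) {
            if (!has_y[i] || q.w[i] == 0) continue;
            double r = resid[i], d = q.a * q.w[i];
            dll -= ((r - d) * (r - d) - r * r) / (2 * se2);
          }
        }
        double logA = dll + std::log(P.lambda / (qtls.size() + 1.0));
        if (std::log(R::unif_rand()) < logA) {
          acc_birth++;
          if (!flat)
            for (int i = 0; i < E.n; i++)
              if (has_y[i] && q.w[i] != 0) resid[i] -= q.a * q.w[i];
          qtls.push_back(std::move(q));
        }
      }
    } else if (!qtls.empty()) {
      try_death++;
      int k = std::min((int)(R::unif_rand() * qtls.size()),
                       (int)qtls.size() - 1);
      Qtl& q = qtls[k];
      double dll = 0;
      if (!flat) {
        for (int i = 0; i < E.n; i++) {
          if (!has_y[i] || q.w[i] == 0) continue;
          double r = resid[i], d = q.a * q.w[i];
          dll -= ((r + d) * (r + d) - r * r) / (2 * se2);
        }
      }
      double logA = dll + std::log(qtls.size() / P.lambda);
      if (std::log(R::unif_rand()) < logA) {
        acc_death++;
        if (!flat)
          for (int i = 0; i < E.n; i++)
            if (has_y[i] && q.w[i] != 0) resid[i] += q.a * q.w[i];
        qtls.erase(qtls.begin() + k);
      }
    }
    // ---- storage ----------------------------------------------------------
    if (it >= burnin && (it - burnin) % store_every == 0 &&
        (int)st_count.size() < n_store) {
      st_count.push_back((int)qtls.size());
      st_mu.push_back(mu);
      st_se2.push_back(se2);
      int samp = (int)st_count.size();
      for (const Qtl& q : qtls) {
        st_sample.push_back(samp);
        st_lg.push_back(q.lg + 1);
        st_pos.push_back(q.pos);
        st_a.push_back(q.a);
        st_s2a.push_back(q.s2a);
        st_f.push_back(q.f);
        if (store_w)
          for (int i = 0; i < E.n; i++) st_w.push_back(q.w[i]);
      }
    }
  }

  IntegerMatrix Wm(store_w ? (int)st_sample.size() : 0, store_w ? E.n : 0);
  if (store_w)
    for (size_t r = 0; r < st_sample.size(); r++)
      for (int i = 0; i < E.n; i++)
        Wm(r, i) = st_w[r * E.n + i];
  return List::create(
    _["count"] = wrap(st_count), _["mu"] = wrap(st_mu),
    _["se2"] = wrap(st_se2), _["sample"] = wrap(st_sample),
    _["lg"] = wrap(st_lg), _["pos"] = wrap(st_pos), _["a"] = wrap(st_a),
    _["s2a"] = wrap(st_s2a), _["f"] = wrap(st_f), _["W"] = Wm,
    _["accept"] = NumericVector::create(
      _["birth"] = try_birth ? (double)acc_birth / try_birth : NA_REAL,
      _["death"] = try_death ? (double)acc_death / try_death : NA_REAL,
      _["position"] = try_pos ? (double)acc_pos / try_pos : NA_REAL));
}

// Fixed-design Gibbs sampler used to validate the conjugate updates: with
// the QTL genotype design W held fixed, draws a | se2 and/or se2 | a with
// exactly the conditionals used by the full sampler.
// [[Rcpp::export]]
List gibbs_fixed_cpp(NumericVector y, NumericMatrix W, NumericVector s2a,
                     double mu, double se2_init, double e_shape,
                     double e_scale, int n_draws, bool update_a,
                     bool update_se2, NumericVector a_init) {
  int n = y.size(), K = W.ncol();
  std::vector<double> a(a_init.begin(), a_init.end());
  double se2 = se2_init;
  std::vector<double> resid(n);
  for (int i = 0; i < n; i++) {
    double f = mu;
    for (int k = 0; k < K; k++) f += a[k] * W(i, k);
    resid[i] = y[i] - f;
  }
  NumericMatrix a_draws(n_draws, K);
  NumericVector se2_draws(n_draws);
  for (int it = 0; it < n_draws; it++) {
    if (update_a) {
      for (int k = 0; k < K; k++) {
        double sxx = 0, sxy = 0;
        for (int i = 0; i < n; i++) {
          double rk = resid[i] + a[k] * W(i, k);
          sxx += W(i, k) * W(i, k);
          sxy += W(i, k) * rk;
        }
        double prec = sxx / se2 + 1.0 / s2a[k];
        double mean = (sxy / se2) / prec;
        double a_new = mean + R::norm_rand() / std::sqrt(prec);
        for (int i = 0; i < n; i++) resid[i] -= (a_new - a[k]) * W(i, k);
        a[k] = a_new;
      }
    }
    if (update_se2) {
      double ssr = 0;
      for (int i = 0; i < n; i++) ssr += resid[i] * resid[i];
      se2 = 1.0 / R::rgamma(e_shape + 0.5 * n,
                            1.0 / (e_scale + 0.5 * ssr));
    }
    for (int k = 0; k < K; k++) a_draws(it, k) = a[k];
    se2_draws[it] = se2;
  }
  return List::create(_["a"] = a_draws, _["se2"] = se2_draws);
}
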