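// Individual-based simulator of range expansion under a dispersal-foraging
// trade-off. Consumers live on a linear landscape of patches with
// Beverton-Holt resource growth; each generation is
// resource growth -> sequential foraging (randomized order) ->
// Poisson reproduction with mutation -> natal dispersal.
// Uses R's RNG throughout so runs are reproducible via set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// trait layout per individual: f_d, f_a, f_invb, [f_e if four-way], f_else
// (f_else is always the last column)

static inline double pow_theta(double f, double theta) {
  return theta == 1.0 ? f : std::pow(f, theta);
}

// mutate child traits inherited from parent; per-value mutation with
// probability p_mut, Normal(0, sd) increments, negatives reset to zero,
// then renormalization to the unit simplex. An all-zero vector after
// clipping triggers a redraw of the whole mutation.
static void mutate_inherit(const double *parent, double *child, int ntr,
                           double p_mut, double sd) {
  for (;;) {
    bool any = false;
    double sum = 0.0;
    for (int j = 0; j < ntr; ++j) {
      double v = parent[j];
      if (p_mut > 0.0 && unif_rand() < p_mut) {
        v += norm_rand() * sd;
        any = true;
        if (v < 0.0) v = 0.0;
      }
      child[j] = v;
      sum += v;
    }
    if (!any) return; // exact inheritance, parent already on the simplex
    if (sum > 0.0) {
      for (int j = 0; j < ntr; ++j) child[j] /= sum;
      return;
    }
    // all values clipped to zero: redraw
  }
}

// sequential foraging within one patch: residents (rows of tr listed in
// ord) harvest in order, updating available resources after each intake.
// Returns final available level; intakes written per individual.
static double forage_sequential(const std::vector<int> &ord,
                                const double *tr, int ntr,
                                double avail, double a_max, double invb_max,
                                double theta, std::vector<double> &intake) {
  for (size_t k = 0; k < ord.size(); ++k) {
    int i = ord[k];
    double in = 0.0;
    if (avail > 0.0) {
      double a_i = pow_theta(tr[(size_t)i * ntr + 1], theta) * a_max;
      double invb_i = pow_theta(tr[(size_t)i * ntr + 2], theta) * invb_max;
      if (invb_i > 0.0) {
        double b_i = 1.0 / invb_i;
        in = a_i * avail / (avail + b_i);
        if (in > avail) in = avail;
      }
    }
    intake[i] = in;
    avail -= in;
  }
  return avail;
}

extern "C" SEXP C_mutate_traits(SEXP traitsSEXP, SEXP pmutSEXP, SEXP sdSEXP) {
  BEGIN_RCPP
  RNGScope rngscope;
  NumericMatrix traits(traitsSEXP);
  double p_mut = as<double>(pmutSEXP), sd = as<double>(sdSEXP);
  int n = traits.nrow(), ntr = traits.ncol();
  NumericMatrix out(n, ntr);
  std::vector<double> parent(ntr), child(ntr);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < ntr; ++j) parent[j] = traits(i, j);
    mutate_inherit(parent.data(), child.data(), ntr, p_mut, sd);
    for (int j = 0; j < ntr; ++j) out(i, j) = child[j];
  }
  return out;
  END_RCPP
}

extern "C" SEXP C_forage_patch(SEXP traitsSEXP, SEXP NSEXP, SEXP amaxSEXP,
                               SEXP invbmaxSEXP, SEXP thetaSEXP,
                               SEXP refugeKSEXP) {
  BEGIN_RCPP
  RNGScope rngscope;
  NumericMatrix traits(traitsSEXP);
  double N0 = as<double>(NSEXP), a_max = as<double>(amaxSEXP);
  double invb_max = as<double>(invbmaxSEXP), theta = as<double>(thetaSEXP);
  double refugeK = as<double>(refugeKSEXP);
  int n = traits.nrow(), ntr = traits.ncol();
  std::vector<double> tr((size_t)n * ntr);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < ntr; ++j) tr[(size_t)i * ntr + j] = traits(i, j);
  // uniform random foraging order (Fisher-Yates with R's RNG)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int k = (int)(unif_rand() * (i + 1));
    if (k > i) k = i;
    std::swap(ord[i], ord[k]);
  }
  std::vector<double> intake(n, 0.0);
  double avail = N0 - refugeK;
  if (avail < 0.0) avail = 0.0;
  double left = forage_sequential(ord, tr.data(), ntr, avail, a_max,
                                  invb_max, theta, intake);
  double N_after = left + std::min(N0, refugeK);
  IntegerVector ordR(n);
  for (int i = 0; i < n; ++i) ordR[i] = ord[i] + 1; // 1-based for R
  return List::create(_["intakes"] = NumericVector(intake.begin(), intake.end()),
                      _["N_after"] = N_after, _["order"] = ordR);
  END_RCPP
}

extern "C" SEXP C_run_sim(SEXP cfgSEXP, SEXP traits0SEXP, SEXP patch0SEXP,
                          SEXP NinitSEXP) {
  BEGIN_RCPP
  RNGScope rngscope;
  List cfg(cfgSEXP);
  const int n_patches = as<int>(cfg["n_patches"]);
  const int n_core = as<int>(cfg["n_core"]);
  const int burn_in = as<int>(cfg["burn_in"]);
  const int max_gen = as<int>(cfg["max_gen"]);
  const double K = as<double>(cfg["K"]);
  const double lam0 = as<double>(cfg["lambda0"]);
  const double mu = as<double>(cfg["mu"]);
  const double d_max = as<double>(cfg["d_max"]);
  const double a_max = as<double>(cfg["a_max"]);
  const double invb_max = as<double>(cfg["invb_max"]);
  const double e_fix = as<double>(cfg["e"]);
  const double e_max = as<double>(cfg["e_max"]);
  const double p_mut = as<double>(cfg["p_mut"]);
  const double mut_sd = as<double>(cfg["mut_sd"]);
  const double theta = as<double>(cfg["tradeoff_exponent"]);
  const double inflow = as<double>(cfg["inflow"]);
  const double refuge = as<double>(cfg["refuge"]);
  const bool four_way = as<bool>(cfg["four_way"]);
  const int record_every = as<int>(cfg["record_every"]);
  const double alpha = (lam0 - 1.0) / K;
  const double refugeK = refuge * K;

  NumericMatrix traits0(traits0SEXP);
  IntegerVector patch0(patch0SEXP);
  NumericVector Ninit(NinitSEXP);
  const int ntr = traits0.ncol();

  std::vector<double> tr, otr;
  std::vector<int> pat, opat;
  {
    int n0 = traits0.nrow();
    tr.resize((size_t)n0 * ntr);
    pat.resize(n0);
    for (int i = 0; i < n0; ++i) {
      for (int j = 0; j < ntr; ++j) tr[(size_t)i * ntr + j] = traits0(i, j);
      pat[i] = patch0[i];
    }
  }
  std::vector<double> N(Ninit.begin(), Ninit.end());

  // per-generation records (flattened rows: gen, patch, count, mean_d,
  // mean_invb, resource)
  std::vector<double> rec;
  std::vector<int> fronts;
  std::vector<double> census;
  bool extinct = false, completed = false;
  int gens_run = 0;

  std::vector<int> counts(n_patches), offs(n_patches + 1), fill(n_patches);
  std::vector<int> ordall;
  std::vector<double> intake;

  const int total_max = burn_in + max_gen;
  const size_t POP_GUARD = 20000000; // refuse runs that would exhaust memory

  auto record_state = [&](int gen) {
    std::vector<double> cnt(n_patches, 0.0), sd_(n_patches, 0.0),
        sib(n_patches, 0.0);
    size_t n = pat.size();
    for (size_t i = 0; i < n; ++i) {
      int x = pat[i];
      cnt[x] += 1.0;
      double d_i = pow_theta(tr[i * ntr], theta) * d_max;
      if (d_i > 1.0) d_i = 1.0;
      sd_[x] += d_i;
      sib[x] += pow_theta(tr[i * ntr + 2], theta) * invb_max;
    }
    for (int x = 0; x < n_patches; ++x) {
      rec.push_back((double)gen);
      rec.push_back((double)x);
      rec.push_back(cnt[x]);
      rec.push_back(cnt[x] > 0 ? sd_[x] / cnt[x] : NA_REAL);
      rec.push_back(cnt[x] > 0 ? sib[x] / cnt[x] : NA_REAL);
      rec.push_back(N[x]);
    }
  };

  record_state(0);
  fronts.push_back(pat.empty() ? -1 : *std::max_element(pat.begin(), pat.end()));
  census.push_back((double)pat.size());

  for (int gen = 1; gen <= total_max; ++gen) {
    const bool burn = gen <= burn_in;
    gens_run = gen;

    // 1) resource growth (Beverton-Holt), optional inflow capped at K
    for (int x = 0; x < n_patches; ++x) {
      double v = lam0 * N[x] / (1.0 + alpha * N[x]);
      if (inflow > 0.0 && v < K) v = std::min(v + inflow * K, K);
      N[x] = v;
    }

    size_t n = pat.size();

    // 2) foraging: group by patch, randomize local order, harvest
    std::fill(counts.begin(), counts.end(), 0);
    for (size_t i = 0; i < n; ++i) counts[pat[i]]++;
    offs[0] = 0;
    for (int x = 0; x < n_patches; ++x) offs[x + 1] = offs[x] + counts[x];
    std::copy(offs.begin(), offs.end() - 1, fill.begin());
    ordall.resize(n);
    for (size_t i = 0; i < n; ++i) ordall[fill[pat[i]]++] = (int)i;
    intake.assign(n, 0.0);
    for (int x = 0; x < n_patches; ++x) {
      int lo = offs[x], hi = offs[x + 1];
      int m = hi - lo;
      if (m == 0) continue;
      for (int i = m - 1; i > 0; --i) { // shuffle segment
        int k = (int)(unif_rand() * (i + 1));
        if (k > i) k = i;
        std::swap(ordall[lo + i], ordall[lo + k]);
      }
      std::vector<int> seg(ordall.begin() + lo, ordall.begin() + hi);
      double avail = N[x] - refugeK;
      if (avail < 0.0) avail = 0.0;
      double left = forage_sequential(seg, tr.data(), ntr, avail, a_max,
                                      invb_max, theta, intake);
      N[x] = left + std::min(N[x], refugeK);
    }

    // 3) reproduction (parents die) with inheritance + mutation
    otr.clear();
    opat.clear();
    for (size_t i = 0; i < n; ++i) {
      double e_i = four_way ? pow_theta(tr[i * ntr + 3], theta) * e_max : e_fix;
      double lambda = e_i * intake[i];
      int noff = lambda > 0.0 ? (int)R::rpois(lambda) : 0;
      if (noff == 0) continue;
      if (opat.size() + noff > POP_GUARD)
        stop("population exceeded %d individuals; check configuration",
             (int)POP_GUARD);
      for (int k = 0; k < noff; ++k) {
        size_t at = otr.size();
        otr.resize(at + ntr);
        mutate_inherit(&tr[i * ntr], &otr[at], ntr, p_mut, mut_sd);
        opat.push_back(pat[i]);
      }
    }

    // 4) natal dispersal; ring over the core during burn-in, reflecting
    //    boundaries afterwards; dispersal mortality mu
    {
      size_t m = opat.size(), keep = 0;
      for (size_t i = 0; i < m; ++i) {
        double d_i = pow_theta(otr[i * ntr], theta) * d_max;
        if (d_i > 1.0) d_i = 1.0;
        int x = opat[i];
        bool alive = true;
        if (d_i > 0.0 && unif_rand() < d_i) {
          if (mu > 0.0 && unif_rand() < mu) {
            alive = false;
          } else {
            int dir = unif_rand() < 0.5 ? -1 : 1;
            int target = x + dir;
            if (burn) {
              target = (target + n_core) % n_core;
            } else {
              if (target < 0) target = 1;
              if (target >= n_patches) target = n_patches - 2;
            }
            x = target;
          }
        }
        if (alive) {
          if (keep != i)
            std::copy(&otr[i * ntr], &otr[i * ntr] + ntr, &otr[keep * ntr]);
          opat[keep] = x;
          ++keep;
        }
      }
      otr.resize(keep * ntr);
      opat.resize(keep);
    }
    tr.swap(otr);
    pat.swap(opat);

    int front = pat.empty() ? -1 : *std::max_element(pat.begin(), pat.end());
    fronts.push_back(front);
    census.push_back((double)pat.size());
    if (pat.empty()) extinct = true;
    if (!burn && front == n_patches - 1) completed = true;
    if (extinct || completed || gen == total_max ||
        gen % record_every == 0 || gen == burn_in) {
      record_state(gen);
    }
    if (extinct || completed) break;
  }

  // pack records
  size_t nrow = rec.size() / 6;
  NumericMatrix recM((int)nrow, 6);
  for (size_t r = 0; r < nrow; ++r)
    for (int cidx = 0; cidx < 6; ++cidx) recM((int)r, cidx) = rec[r * 6 + cidx];

  size_t nfin = pat.size();
  NumericMatrix trFin((int)nfin, ntr);
  IntegerVector patFin((int)nfin);
  for (size_t i = 0; i < nfin; ++i) {
    for (int j = 0; j < ntr; ++j) trFin((int)i, j) = tr[i * ntr + j];
    patFin[(int)i] = pat[i];
  }

  return List::create(
      _["records"] = recM,
      _["front"] = IntegerVector(fronts.begin(), fronts.end()),
      _["census"] = NumericVector(census.begin(), census.end()),
      _["final_traits"] = trFin, _["final_patch"] = patFin,
      _["final_resource"] = NumericVector(N.begin(), N.end()),
      _["extinct"] = extinct, _["completed"] = completed,
      _["generations"] = gens_run);
  END_RCPP
}
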