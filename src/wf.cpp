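// Forward-time diploid Wright-Fisher engine for a radiating species complex.
//
// The population is a set of lineages related by split events.  Each lineage
// holds a vector of haplotypes; a haplotype is a sorted vector of derived
// mutation coordinates (infinite sites on [0, L)) plus a flag for the allele
// carried at a single optionally-selected site.  Mutations fixed within a
// lineage are periodically moved to a per-lineage "fixed" list so haplotype
// vectors stay proportional to the within-lineage segregating load.
//
// Selection regimes are piecewise-constant per lineage:
//   0 = neutral, 1 = overdominance (het advantage s),
//   2 = positive selection for the derived allele (s, h),
//   3 = positive selection for the ancestral allele (s, h).
//
// Determinism: all randomness flows from one std::mt19937_64 seeded by the
// caller, so runs are byte-identical for a fixed seed on a given platform.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <limits>
#include <random>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Hap {
  std::vector<double> mut;  // sorted derived mutation positions
  uint8_t sel = 0;          // allele at the selected site (0 ancestral)
};

struct Lineage {
  bool active = false;
  int size = 0;                   // diploid size
  std::vector<Hap> pop;           // 2*size haplotypes
  std::vector<double> fixed;      // sorted positions fixed within lineage
};

struct Regime {
  int start;  // first generation at which this regime applies
  int code;   // 0 neutral, 1 overdom, 2 pos derived, 3 pos ancestral
  double s, h;
};

struct Engine {
  std::mt19937_64 rng;
  double L, mu, rec;
  double supp_center, supp_radius, supp_factor;
  double sel_pos;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  int regime_code(const std::vector<Regime>& sched, int gen, double* s,
                  double* h) const {
    int code = 0;
    *s = 0.0;
    *h = 0.5;
    for (const Regime& r : sched) {
      if (r.start <= gen) {
        code = r.code;
        *s = r.s;
        *h = r.h;
      }
    }
    return code;
  }

  // Crossover breakpoints: homogeneous Poisson thinned inside the
  // suppression window (models locally reduced recombination, e.g. an
  // inversion spanning an old balanced polymorphism).
  void breakpoints(std::vector<double>& bp) {
    bp.clear();
    if (rec <= 0.0) return;
    std::poisson_distribution<int> pois(rec * L);
    int k = pois(rng);
    for (int i = 0; i < k; ++i) {
      double u = unif(rng) * L;
      if (supp_radius > 0.0 && std::abs(u - supp_center) < supp_radius &&
          unif(rng) >= supp_factor)
        continue;
      bp.push_back(u);
    }
    std::sort(bp.begin(), bp.end());
  }

  // Build one gamete from a parent's pair of haplotypes.
  void gamete(const Hap& a, const Hap& b, Hap& out) {
    static thread_local std::vector<double> bp;
    breakpoints(bp);
    out.mut.clear();
    int cur = (unif(rng) < 0.5) ? 0 : 1;
    int sel_src = cur;
    double lo = 0.0;
    for (size_t i = 0; i <= bp.size(); ++i) {
      double hi = (i < bp.size()) ? bp[i]
                                  : std::numeric_limits<double>::infinity();
      const std::vector<double>& src = (cur == 0) ? a.mut : b.mut;
      auto itlo = std::lower_bound(src.begin(), src.end(), lo);
      auto ithi = std::lower_bound(src.begin(), src.end(), hi);
      out.mut.insert(out.mut.end(), itlo, ithi);
      if (sel_pos >= lo && sel_pos < hi) sel_src = cur;
      cur = 1 - cur;
      lo = hi;
    }
    out.sel = (sel_src == 0) ? a.sel : b.sel;
    // new mutations
    if (mu > 0.0) {
      std::poisson_distribution<int> pois(mu * L);
      int m = pois(rng);
      if (m > 0) {
        size_t old = out.mut.size();
        for (int i = 0; i < m; ++i) out.mut.push_back(unif(rng) * L);
        std::sort(out.mut.begin() + old, out.mut.end());
        std::inplace_merge(out.mut.begin(), out.mut.begin() + old,
                           out.mut.end());
      }
    }
  }
};

// Move mutations carried by every haplotype of the lineage to lin.fixed.
void prune_fixed(Lineage& lin) {
  if (lin.pop.empty()) return;
  const size_t n = lin.pop.size();
  std::unordered_map<double, size_t> count;
  count.reserve(lin.pop[0].mut.size() * 2 + 16);
  for (const Hap& h : lin.pop)
    for (double p : h.mut) ++count[p];
  std::vector<double> fixed;
  for (const auto& kv : count)
    if (kv.second == n) fixed.push_back(kv.first);
  if (fixed.empty()) return;
  std::sort(fixed.begin(), fixed.end());
  for (Hap& h : lin.pop) {
    std::vector<double> keep;
    keep.reserve(h.mut.size() - fixed.size());
    std::set_difference(h.mut.begin(), h.mut.end(), fixed.begin(), fixed.end(),
                        std::back_inserter(keep));
    h.mut.swap(keep);
  }
  std::vector<double> merged;
  merged.reserve(lin.fixed.size() + fixed.size());
  std::merge(lin.fixed.begin(), lin.fixed.end(), fixed.begin(), fixed.end(),
             std::back_inserter(merged));
  lin.fixed.swap(merged);
}

int sel_count(const Lineage& lin) {
  int c = 0;
  for (const Hap& h : lin.pop) c += h.sel;
  return c;
}

}  // namespace

// [[Rcpp::export]]
List wf_simulate_cpp(IntegerVector lin_parent, IntegerVector lin_create,
                     IntegerVector lin_size, IntegerMatrix resize,
                     IntegerVector sample_n, int n_gen, double L, double mu,
                     double rec, double supp_center, double supp_radius,
                     double supp_factor, int sel_mode, double sel_pos,
                     double init_freq, int introduce_gen, int introduce_lineage,
                     NumericMatrix regimes, double stop_at_freq,
                     int sgv_guard_gen, int max_retries, double seed) {
  const int nl = lin_parent.size();
  Engine eng;
  eng.rng.seed(static_cast<uint64_t>(seed));
  eng.L = L;
  eng.mu = mu;
  eng.rec = rec;
  eng.supp_center = supp_center;
  eng.supp_radius = supp_radius;
  eng.supp_factor = supp_factor;
  eng.sel_pos = sel_pos;

  std::vector<std::vector<Regime>> sched(nl);
  for (int i = 0; i < regimes.nrow(); ++i) {
    Regime r;
    int l = static_cast<int>(regimes(i, 0));
    r.start = static_cast<int>(regimes(i, 1));
    r.code = static_cast<int>(regimes(i, 2));
    r.s = regimes(i, 3);
    r.h = regimes(i, 4);
    sched[l].push_back(r);
  }
  for (auto& s : sched)
    std::sort(s.begin(), s.end(),
              [](const Regime& a, const Regime& b) { return a.start < b.start; });

  auto init_root = [&](std::vector<Lineage>& lins) {
    lins.assign(nl, Lineage());
    lins[0].active = true;
    lins[0].size = lin_size[0];
    lins[0].pop.assign(2 * lin_size[0], Hap());
    for (int l = 1; l < nl; ++l) lins[l].size = lin_size[l];
    if ((sel_mode == 2 || sel_mode == 0) && init_freq > 0.0) {
      int ncopies =
          static_cast<int>(std::lround(init_freq * 2.0 * lin_size[0]));
      std::vector<int> idx(2 * lin_size[0]);
      for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
      std::shuffle(idx.begin(), idx.end(), eng.rng);
      for (int i = 0; i < ncopies; ++i) lins[0].pop[idx[i]].sel = 1;
    }
  };

  std::vector<Lineage> lins;
  init_root(lins);

  // snapshot for de-novo establishment retries
  std::vector<Lineage> snapshot;
  int snapshot_gen = -1;
  int retries = 0;
  bool failed = false;
  int end_gen = n_gen;

  int g = 1;
  while (g <= n_gen) {
    // resize events apply to the generation being produced
    for (int i = 0; i < resize.nrow(); ++i)
      if (resize(i, 0) == g) lins[resize(i, 1)].size = resize(i, 2);

    // reproduce every lineage that exists at generation g
    std::vector<std::vector<Hap>> next(nl);
    for (int l = 0; l < nl; ++l) {
      bool creating = (lin_create[l] == g && l != 0);
      if (!lins[l].active && !creating) continue;
      int src = creating ? lin_parent[l] : l;
      const std::vector<Hap>& pool = lins[src].pop;
      const int np = static_cast<int>(pool.size()) / 2;
      double s, h;
      int code = eng.regime_code(sched[l], g, &s, &h);
      std::vector<Hap>& out = next[l];
      out.resize(2 * lins[l].size);
      if (code == 0 || sel_mode == -1) {
        std::uniform_int_distribution<int> pick(0, np - 1);
        for (int i = 0; i < lins[l].size; ++i) {
          int pa = pick(eng.rng), pb = pick(eng.rng);
          eng.gamete(pool[2 * pa], pool[2 * pa + 1], out[2 * i]);
          eng.gamete(pool[2 * pb], pool[2 * pb + 1], out[2 * i + 1]);
        }
      } else {
        std::vector<double> w(np);
        for (int i = 0; i < np; ++i) {
          int d = pool[2 * i].sel + pool[2 * i + 1].sel;
          double fit = 1.0;
          if (code == 1) {
            if (d == 1) fit += s;
          } else if (code == 2) {
            fit += (d == 2) ? s : (d == 1 ? h * s : 0.0);
          } else if (code == 3) {
            fit += (d == 0) ? s : (d == 1 ? h * s : 0.0);
          }
          w[i] = fit;
        }
        std::discrete_distribution<int> pick(w.begin(), w.end());
        for (int i = 0; i < lins[l].size; ++i) {
          int pa = pick(eng.rng), pb = pick(eng.rng);
          eng.gamete(pool[2 * pa], pool[2 * pa + 1], out[2 * i]);
          eng.gamete(pool[2 * pb], pool[2 * pb + 1], out[2 * i + 1]);
        }
      }
    }
    for (int l = 0; l < nl; ++l) {
      if (!next[l].empty()) {
        lins[l].pop.swap(next[l]);
        if (lin_create[l] == g && l != 0) {
          lins[l].active = true;
          lins[l].fixed = lins[lin_parent[l]].fixed;  // inherit fixed set
        }
      }
    }

    // de-novo sweep: introduce the selected mutation, retry on loss
    if (sel_mode == 1) {
      if (g == introduce_gen) {
        snapshot = lins;
        snapshot_gen = g;
        std::uniform_int_distribution<int> pick(
            0, static_cast<int>(lins[introduce_lineage].pop.size()) - 1);
        lins[introduce_lineage].pop[pick(eng.rng)].sel = 1;
      } else if (g > introduce_gen) {
        int tot = 0;
        for (int l = 0; l < nl; ++l)
          if (lins[l].active) tot += sel_count(lins[l]);
        if (tot == 0) {
          if (++retries > max_retries) {
            failed = true;
            break;
          }
          lins = snapshot;
          g = snapshot_gen;
          std::uniform_int_distribution<int> pick(
              0, static_cast<int>(lins[introduce_lineage].pop.size()) - 1);
          lins[introduce_lineage].pop[pick(eng.rng)].sel = 1;
          ++g;
          continue;
        }
        if (stop_at_freq > 0.0) {
          const Lineage& tl = lins[introduce_lineage];
          if (tl.active &&
              sel_count(tl) >=
                  stop_at_freq * static_cast<double>(tl.pop.size())) {
            end_gen = g;
            break;
          }
        }
      }
    }

    // SGV: the balanced polymorphism must survive in the root lineage until
    // the guard generation (the onset of the focal radiation)
    if (sel_mode == 2 && g <= sgv_guard_gen) {
      int c = sel_count(lins[0]);
      if (c == 0 || c == static_cast<int>(lins[0].pop.size())) {
        if (++retries > max_retries) {
          failed = true;
          break;
        }
        init_root(lins);
        g = 1;
        continue;
      }
    }

    if (g % 32 == 0)
      for (int l = 0; l < nl; ++l)
        if (lins[l].active) prune_fixed(lins[l]);
    ++g;
  }

  if (failed) {
    return List::create(Named("ok") = false, Named("retries") = retries);
  }

  // --- sampling ---
  std::vector<int> hap_lin, hap_ind;
  std::vector<std::vector<double>> hapmut;
  std::vector<int> hapsel;
  for (int l = 0; l < nl; ++l) {
    if (sample_n[l] <= 0) continue;
    if (!lins[l].active)
      stop("lineage %d not alive at sampling time", l + 1);
    int ns = sample_n[l];
    int np = static_cast<int>(lins[l].pop.size()) / 2;
    if (ns > np) stop("sample size exceeds lineage size");
    std::vector<int> idx(np);
    for (int i = 0; i < np; ++i) idx[i] = i;
    std::shuffle(idx.begin(), idx.end(), eng.rng);
    for (int i = 0; i < ns; ++i) {
      for (int k = 0; k < 2; ++k) {
        const Hap& h = lins[l].pop[2 * idx[i] + k];
        std::vector<double> full;
        full.reserve(lins[l].fixed.size() + h.mut.size());
        std::merge(lins[l].fixed.begin(), lins[l].fixed.end(), h.mut.begin(),
                   h.mut.end(), std::back_inserter(full));
        hapmut.push_back(std::move(full));
        hapsel.push_back(h.sel);
        hap_lin.push_back(l);
        hap_ind.push_back(i);
      }
    }
  }
  const int nh = static_cast<int>(hapmut.size());

  // union of derived positions, dropping sites derived in every haplotype
  std::vector<std::pair<double, int>> occ;
  for (int j = 0; j < nh; ++j)
    for (double p : hapmut[j]) occ.emplace_back(p, j);
  std::sort(occ.begin(), occ.end());
  std::vector<double> pos;
  std::vector<std::pair<size_t, size_t>> runs;
  size_t i0 = 0;
  while (i0 < occ.size()) {
    size_t i1 = i0;
    while (i1 < occ.size() && occ[i1].first == occ[i0].first) ++i1;
    size_t n = i1 - i0;
    if (n < static_cast<size_t>(nh)) {
      pos.push_back(occ[i0].first);
      runs.emplace_back(i0, i1);
    }
    i0 = i1;
  }
  // selected site, if polymorphic among sampled haplotypes
  int selc = 0;
  for (int v : hapsel) selc += v;
  bool sel_poly = (sel_mode >= 0 && selc > 0 && selc < nh);

  const int ns_sites = static_cast<int>(pos.size()) + (sel_poly ? 1 : 0);
  IntegerMatrix alle(ns_sites, nh);
  NumericVector positions(ns_sites);
  IntegerVector is_sel(ns_sites);
  {
    // interleave the selected site into sorted order
    int row = 0;
    size_t k = 0;
    bool sel_done = !sel_poly;
    while (k < pos.size() || !sel_done) {
      bool take_sel =
          !sel_done && (k >= pos.size() || sel_pos < pos[k]);
      if (take_sel) {
        positions[row] = sel_pos;
        is_sel[row] = 1;
        for (int j = 0; j < nh; ++j) alle(row, j) = hapsel[j];
        sel_done = true;
      } else {
        positions[row] = pos[k];
        for (size_t t = runs[k].first; t < runs[k].second; ++t)
          alle(row, occ[t].second) = 1;
        ++k;
      }
      ++row;
    }
  }

  NumericVector selfreq(nl), linsz(nl);
  for (int l = 0; l < nl; ++l) {
    if (lins[l].active && !lins[l].pop.empty()) {
      selfreq[l] = sel_count(lins[l]) / static_cast<double>(lins[l].pop.size());
      linsz[l] = lins[l].pop.size() / 2.0;
    } else {
      selfreq[l] = NA_REAL;
      linsz[l] = 0;
    }
  }

  return List::create(
      Named("ok") = true, Named("positions") = positions,
      Named("alleles") = alle, Named("hap_lineage") = IntegerVector(hap_lin.begin(), hap_lin.end()),
      Named("hap_individual") = IntegerVector(hap_ind.begin(), hap_ind.end()),
      Named("is_selected_site") = is_sel, Named("sel_freq") = selfreq,
      Named("lineage_sizes") = linsz, Named("retries") = retries,
      Named("end_gen") = end_gen, Named("sel_poly_in_sample") = sel_poly);
}
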