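// Forward-in-time diploid Wright-Fisher engine.
//
// State: per-deme pools of haplotypes, each haplotype a vector of mutation
// ids sorted by genomic position (positions are unique under the
// infinite-sites rule, so position order is a total order). Fitness is
// multiplicative across loci; the balanced allele's coefficient
// S = f_eq - F is recomputed once per generation from parental frequencies.
// Reproduction: each offspring draws a source deme from its migration row,
// then two parents independently with probability proportional to fitness
// (selfing allowed). Gametes get Poisson crossovers and Poisson new
// mutations at rate-map-weighted positions. Fixed mutations move to a
// substitution record; lost mutations are dropped.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Mut {
  int pos;
  double s;
  double h;
  int kind;  // 0 neutral, 1 deleterious, 2 balanced, 3 beneficial
  int origin_gen;
};

struct Sub { int pos; int gen; int kind; };

struct RateMapC {
  std::vector<int> starts, ends;
  std::vector<double> cum;  // cumulative rate mass (rate * block length)
  double total = 0.0;

  void init(const IntegerVector& s, const IntegerVector& e,
            const NumericVector& r) {
    int nb = s.size();
    starts.assign(s.begin(), s.end());
    ends.assign(e.begin(), e.end());
    cum.resize(nb);
    double acc = 0.0;
    for (int i = 0; i < nb; ++i) {
      acc += r[i] * (double)(ends[i] - starts[i] + 1);
      cum[i] = acc;
    }
    total = acc;
  }

  // rate-weighted random position (1-based bp)
  int draw_pos() const {
    double u = unif_rand() * total;
    int b = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (b >= (int)cum.size()) b = (int)cum.size() - 1;
    int len = ends[b] - starts[b] + 1;
    int off = (int)(unif_rand() * len);
    if (off >= len) off = len - 1;
    return starts[b] + off;
  }
};

struct Event {
  int gen;
  int kind;  // 0 size_change, 1 split, 2 set_migration
  int a;     // deme index (size_change) / source deme (split)
  int b;     // new size (size_change, split)
  std::vector<double> mat;  // flattened migration matrix (set_migration)
};

struct Population {
  int L = 0;
  int generation = 0;
  std::vector<std::vector<std::vector<int>>> demes;  // demes[d][hap][mut id]
  std::vector<int> target_sizes;                     // diploid N per deme
  std::vector<Mut> reg;
  std::vector<int> active_ids;
  std::vector<int> counts;
  std::unordered_set<int> occupied;  // positions of active muts + substitutions
  std::vector<Sub> subs;
  std::vector<std::vector<double>> mig;  // backward migration rows
  RateMapC mu, rec;
  std::vector<unsigned char> cls;  // site class per position, size L
  bool has_dfe = false;
  double dfe_p[4] = {0, 0, 0, 0};
  double dfe_edges[5] = {0, 0, 0, 0, 0};
  double dfe_h = 0.5;
  double dfe_2N = 0.0;
  int focal_id = -1;
  double feq = -1.0;   // <0: no frequency dependence (beneficial/neutral)
  std::vector<Event> events;
  size_t event_idx = 0;

  int total_2N() const {
    int t = 0;
    for (const auto& d : demes) t += (int)d.size();
    return t;
  }

  double focal_freq() const {
    if (focal_id < 0) return NA_REAL;
    if (focal_id >= (int)counts.size()) return 0.0;
    return (double)counts[focal_id] / (double)total_2N();
  }
};

double draw_dfe_s(Population& P) {
  double u = unif_rand();
  int c = 0;
  double acc = 0.0;
  for (int i = 0; i < 4; ++i) {
    acc += P.dfe_p[i];
    if (u <= acc) { c = i; break; }
    c = i;
  }
  double scaled = P.dfe_edges[c] +
                  unif_rand() * (P.dfe_edges[c + 1] - P.dfe_edges[c]);
  double s = scaled / P.dfe_2N;
  return s > 1.0 ? 1.0 : s;
}

struct PosLess {
  const std::vector<Mut>& reg;
  bool operator()(int id, int pos) const { return reg[id].pos < pos; }
};

// fitness of an individual (pair of haplotypes); Sbp is this generation's
// balanced-allele coefficient
double individual_fitness_cpp(const Population& P, const std::vector<int>& A,
                              const std::vector<int>& B, double Sbp) {
  double w = 1.0;
  size_t ia = 0, ib = 0;
  while (ia < A.size() || ib < B.size()) {
    int id;
    bool hom = false;
    if (ia < A.size() && ib < B.size()) {
      int pa = P.reg[A[ia]].pos, pb = P.reg[B[ib]].pos;
      if (pa == pb) { id = A[ia]; hom = true; ++ia; ++ib; }
      else if (pa < pb) { id = A[ia]; ++ia; }
      else { id = B[ib]; ++ib; }
    } else if (ia < A.size()) { id = A[ia]; ++ia; }
    else { id = B[ib]; ++ib; }
    const Mut& m = P.reg[id];
    switch (m.kind) {
      case 0: break;
      case 1: w *= hom ? (1.0 - m.s) : (1.0 - m.h * m.s); break;
      case 2: w *= hom ? (1.0 + Sbp) : (1.0 + m.h * Sbp); break;
      case 3: w *= hom ? (1.0 + m.s) : (1.0 + m.h * m.s); break;
    }
  }
  return w < 0.0 ? 0.0 : w;
}

// build one gamete from parent individual (haps 2p, 2p+1) in deme d
std::vector<int> make_gamete(Population& P, int d, int p) {
  const std::vector<int>& h0 = P.demes[d][2 * p];
  const std::vector<int>& h1 = P.demes[d][2 * p + 1];
  std::vector<int> child;

  int nx = (P.rec.total > 0.0) ? (int)R::rpois(P.rec.total) : 0;
  bool first = unif_rand() < 0.5;
  if (nx == 0) {
    child = first ? h0 : h1;
  } else {
    std::vector<int> bks(nx);
    for (int i = 0; i < nx; ++i) bks[i] = P.rec.draw_pos();
    std::sort(bks.begin(), bks.end());
    bks.push_back(P.L + 1);
    const std::vector<int>* cur = first ? &h0 : &h1;
    const std::vector<int>* oth = first ? &h1 : &h0;
    int seg_start = 1;
    child.reserve(std::max(h0.size(), h1.size()) + 2);
    for (int bi = 0; bi <= nx; ++bi) {
      int seg_end = bks[bi];  // segment [seg_start, seg_end)
      if (seg_end > seg_start) {
        PosLess cmp{P.reg};
        auto lo = std::lower_bound(cur->begin(), cur->end(), seg_start, cmp);
        auto hi = std::lower_bound(cur->begin(), cur->end(), seg_end, cmp);
        child.insert(child.end(), lo, hi);
      }
      seg_start = seg_end;
      std::swap(cur, oth);
    }
  }

  int nm = (P.mu.total > 0.0) ? (int)R::rpois(P.mu.total) : 0;
  for (int i = 0; i < nm; ++i) {
    int pos = -1;
    for (int tries = 0; tries < 1000; ++tries) {
      int cand = P.mu.draw_pos();
      if (!P.occupied.count(cand)) { pos = cand; break; }
    }
    if (pos < 0) continue;  // region saturated; skip this mutation
    Mut m;
    m.pos = pos;
    m.origin_gen = P.generation;
    if (P.has_dfe && P.cls[pos - 1] == 1) {
      m.kind = 1; m.s = draw_dfe_s(P); m.h = P.dfe_h;
    } else {
      m.kind = 0; m.s = 0.0; m.h = 0.5;
    }
    int id = (int)P.reg.size();
    P.reg.push_back(m);
    P.occupied.insert(pos);
    P.active_ids.push_back(id);
    PosLess cmp{P.reg};
    auto it = std::lower_bound(child.begin(), child.end(), pos, cmp);
    child.insert(it, id);
  }
  return child;
}

void tally(Population& P) {
  P.counts.resize(P.reg.size(), 0);
  for (int id : P.active_ids) P.counts[id] = 0;
  for (const auto& d : P.demes)
    for (const auto& h : d)
      for (int id : h) P.counts[id]++;

  int tot = P.total_2N();
  std::unordered_set<int> fixed;
  std::vector<int> keep;
  keep.reserve(P.active_ids.size());
  for (int id : P.active_ids) {
    int c = P.counts[id];
    if (c == 0) {
      P.occupied.erase(P.reg[id].pos);
      if (id == P.focal_id) P.focal_id = -1;
    } else if (c == tot) {
      Sub s;
      s.pos = P.reg[id].pos; s.gen = P.generation; s.kind = P.reg[id].kind;
      P.subs.push_back(s);
      fixed.insert(id);
      // position stays occupied: a substituted site cannot re-mutate
      if (id == P.focal_id) P.focal_id = -1;
    } else {
      keep.push_back(id);
    }
  }
  P.active_ids.swap(keep);
  if (!fixed.empty()) {
    for (auto& d : P.demes)
      for (auto& h : d)
        h.erase(std::remove_if(h.begin(), h.end(),
                               [&](int id) { return fixed.count(id) > 0; }),
                h.end());
  }
}

void apply_events(Population& P) {
  while (P.event_idx < P.events.size() &&
         P.events[P.event_idx].gen <= P.generation) {
    const Event& ev = P.events[P.event_idx];
    if (ev.kind == 0) {
      P.target_sizes[ev.a] = ev.b;
    } else if (ev.kind == 1) {
      // split: new deme seeded by copying random individuals from source
      int src = ev.a, Nnew = ev.b;
      std::vector<std::vector<int>> pool;
      pool.reserve(2 * Nnew);
      int Nsrc = (int)P.demes[src].size() / 2;
      for (int i = 0; i < Nnew; ++i) {
        int pick = (int)(unif_rand() * Nsrc);
        if (pick >= Nsrc) pick = Nsrc - 1;
        pool.push_back(P.demes[src][2 * pick]);
        pool.push_back(P.demes[src][2 * pick + 1]);
      }
      P.demes.push_back(std::move(pool));
      P.target_sizes.push_back(Nnew);
      // extend migration matrix with an isolated row/column
      size_t nd = P.demes.size();
      for (auto& row : P.mig) row.push_back(0.0);
      std::vector<double> row(nd, 0.0);
      row[nd - 1] = 1.0;
      P.mig.push_back(row);
      tally(P);
    } else if (ev.kind == 2) {
      size_t nd = P.demes.size();
      P.mig.assign(nd, std::vector<double>(nd, 0.0));
      for (size_t i = 0; i < nd; ++i)
        for (size_t j = 0; j < nd; ++j)
          P.mig[i][j] = ev.mat[i * nd + j];
    }
    P.event_idx++;
  }
}

void step(Population& P) {
  apply_events(P);
  int nd = (int)P.demes.size();
  double F = (P.focal_id >= 0 && P.feq >= 0.0) ? P.focal_freq() : 0.0;
  double Sbp = (P.feq >= 0.0) ? (P.feq - F) : 0.0;

  // fitness and cumulative weights per deme
  std::vector<std::vector<double>> cumw(nd);
  for (int d = 0; d < nd; ++d) {
    int N = (int)P.demes[d].size() / 2;
    cumw[d].resize(N);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      acc += individual_fitness_cpp(P, P.demes[d][2 * i], P.demes[d][2 * i + 1],
                                    Sbp);
      cumw[d][i] = acc;
    }
    if (acc <= 0.0) stop("deme %d has total fitness 0", d + 1);
  }

  std::vector<std::vector<std::vector<int>>> next(nd);
  for (int d = 0; d < nd; ++d) {
    int Nnew = P.target_sizes[d];
    if (Nnew < 1) stop("deme %d went extinct", d + 1);
    next[d].reserve(2 * Nnew);
    for (int i = 0; i < Nnew; ++i) {
      // source deme by migration row
      int src = d;
      if (nd > 1) {
        double u = unif_rand(), acc = 0.0;
        for (int j = 0; j < nd; ++j) {
          acc += P.mig[d][j];
          if (u <= acc) { src = j; break; }
        }
      }
      const std::vector<double>& cw = cumw[src];
      double tw = cw.back();
      auto draw_parent = [&]() {
        double u = unif_rand() * tw;
        int p = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
        if (p >= (int)cw.size()) p = (int)cw.size() - 1;
        return p;
      };
      int p1 = draw_parent();
      int p2 = draw_parent();
      next[d].push_back(make_gamete(P, src, p1));
      next[d].push_back(make_gamete(P, src, p2));
    }
  }
  P.demes.swap(next);
  P.generation++;
  tally(P);
}

Population* get(SEXP xp) {
  Rcpp::XPtr<Population> p(xp);
  return p.get();
}

}  // namespace

// [[Rcpp::export]]
SEXP wf_create(int L, IntegerVector cls, IntegerVector mu_starts,
               IntegerVector mu_ends, NumericVector mu_rates,
               IntegerVector rec_starts, IntegerVector rec_ends,
               NumericVector rec_rates, IntegerVector deme_sizes,
               NumericMatrix mig, List dfe, List events) {
  Population* P = new Population();
  P->L = L;
  P->cls.assign(cls.begin(), cls.end());
  P->mu.init(mu_starts, mu_ends, mu_rates);
  P->rec.init(rec_starts, rec_ends, rec_rates);
  int nd = deme_sizes.size();
  P->demes.resize(nd);
  P->target_sizes.resize(nd);
  for (int d = 0; d < nd; ++d) {
    P->target_sizes[d] = deme_sizes[d];
    P->demes[d].assign(2 * deme_sizes[d], std::vector<int>());
  }
  P->mig.assign(nd, std::vector<double>(nd, 0.0));
  for (int i = 0; i < nd; ++i)
    for (int j = 0; j < nd; ++j) P->mig[i][j] = mig(i, j);
  if (dfe.size() > 0) {
    P->has_dfe = true;
    NumericVector p = dfe["class_probs"], e = dfe["class_bounds_2Ns"];
    for (int i = 0; i < 4; ++i) P->dfe_p[i] = p[i];
    for (int i = 0; i < 5; ++i) P->dfe_edges[i] = e[i];
    P->dfe_h = as<double>(dfe["h"]);
    P->dfe_2N = 2.0 * as<double>(dfe["N_ancestral"]);
  }
  int ne = events.size();
  for (int i = 0; i < ne; ++i) {
    List ev = events[i];
    Event E;
    E.gen = as<int>(ev["gen"]);
    std::string k = as<std::string>(ev["kind"]);
    if (k == "size_change") {
      E.kind = 0; E.a = as<int>(ev["deme"]) - 1; E.b = as<int>(ev["N"]);
    } else if (k == "split") {
      E.kind = 1; E.a = as<int>(ev["deme"]) - 1; E.b = as<int>(ev["N"]);
    } else if (k == "set_migration") {
      E.kind = 2;
      NumericVector m = ev["matrix"];
      E.mat.assign(m.begin(), m.end());
      E.a = 0; E.b = 0;
    } else {
      stop("unknown event kind: %s", k.c_str());
    }
    P->events.push_back(E);
  }
  std::stable_sort(P->events.begin(), P->events.end(),
                   [](const Event& a, const Event& b) { return a.gen < b.gen; });
  return Rcpp::XPtr<Population>(P, true);
}

// [[Rcpp::export]]
SEXP wf_clone_cpp(SEXP xp) {
  Population* P = get(xp);
  Population* C = new Population(*P);
  return Rcpp::XPtr<Population>(C, true);
}

// [[Rcpp::export]]
void wf_evolve(SEXP xp, int ngen) {
  Population* P = get(xp);
  for (int g = 0; g < ngen; ++g) step(*P);
}

// Evolve until the focal allele's frequency leaves (stop_low, stop_high),
// or max_gen generations elapse. Returns status: "low", "high", "maxgen",
// or "nofocal" (focal absent or lost via fixation bookkeeping).
// [[Rcpp::export]]
List wf_evolve_track(SEXP xp, int max_gen, double stop_low, double stop_high) {
  Population* P = get(xp);
  int g = 0;
  std::string status = "maxgen";
  while (g < max_gen) {
    step(*P);
    ++g;
    if (P->focal_id < 0) { status = "nofocal"; break; }
    double f = P->focal_freq();
    if (f <= stop_low) { status = "low"; break; }
    if (f >= stop_high) { status = "high"; break; }
  }
  return List::create(_["gens"] = g, _["status"] = status,
                      _["freq"] = P->focal_id >= 0 ? P->focal_freq() : 0.0);
}

// Place a variant on `copies` distinct random chromosomes (metapopulation).
// kind: 0 neutral, 1 deleterious, 2 balanced, 3 beneficial.
// For kind 2, s_or_feq is the equilibrium frequency; otherwise it is s.
// [[Rcpp::export]]
int wf_introduce(SEXP xp, int pos, int copies, int kind, double s_or_feq,
                 double h, bool focal) {
  Population* P = get(xp);
  if (P->occupied.count(pos))
    stop("position %d is already occupied by an active mutation or substitution",
         pos);
  int tot = P->total_2N();
  if (copies < 1 || copies > tot) stop("copies out of range");
  Mut m;
  m.pos = pos; m.h = h; m.origin_gen = P->generation;
  if (kind == 2) { m.kind = 2; m.s = 0.0; P->feq = s_or_feq; }
  else { m.kind = kind; m.s = s_or_feq; }
  int id = (int)P->reg.size();
  P->reg.push_back(m);
  P->occupied.insert(pos);
  P->active_ids.push_back(id);
  if (focal) P->focal_id = id;

  // sample `copies` distinct chromosomes (partial Fisher-Yates)
  std::vector<int> idx(tot);
  for (int i = 0; i < tot; ++i) idx[i] = i;
  for (int i = 0; i < copies; ++i) {
    int j = i + (int)(unif_rand() * (tot - i));
    if (j >= tot) j = tot - 1;
    std::swap(idx[i], idx[j]);
  }
  for (int i = 0; i < copies; ++i) {
    int flat = idx[i];
    for (auto& d : P->demes) {
      if (flat < (int)d.size()) {
        PosLess cmp{P->reg};
        auto it = std::lower_bound(d[flat].begin(), d[flat].end(), pos, cmp);
        d[flat].insert(it, id);
        break;
      }
      flat -= (int)d.size();
    }
  }
  tally(*P);
  return id;
}

// [[Rcpp::export]]
double wf_focal_freq(SEXP xp) { return get(xp)->focal_freq(); }

// [[Rcpp::export]]
double wf_mut_freq(SEXP xp, int id) {
  Population* P = get(xp);
  if (id < 0 || id >= (int)P->counts.size()) return 0.0;
  return (double)P->counts[id] / (double)P->total_2N();
}

// [[Rcpp::export]]
List wf_status(SEXP xp) {
  Population* P = get(xp);
  IntegerVector sizes((int)P->demes.size());
  for (int d = 0; d < (int)P->demes.size(); ++d)
    sizes[d] = (int)P->demes[d].size() / 2;
  return List::create(_["generation"] = P->generation,
                      _["deme_sizes"] = sizes,
                      _["n_active"] = (int)P->active_ids.size(),
                      _["n_substitutions"] = (int)P->subs.size(),
                      _["focal_freq"] = P->focal_id >= 0 ? P->focal_freq()
                                                         : NA_REAL);
}

// Mean expected heterozygosity 2p(1-p) over active sites (diagnostics).
// [[Rcpp::export]]
NumericVector wf_site_freqs(SEXP xp) {
  Population* P = get(xp);
  int tot = P->total_2N();
  NumericVector out((int)P->active_ids.size());
  for (int i = 0; i < (int)P->active_ids.size(); ++i)
    out[i] = (double)P->counts[P->active_ids[i]] / (double)tot;
  return out;
}

// Sample n_per_deme[i] chromosomes without replacement from deme_idx[i]
// (1-based). Returns the 0/1 matrix over sample-polymorphic sites (columns
// sorted by position), derived counts, substitution records (population
// fixations with gen >= min_sub_gen, plus sample-fixed columns), and the
// focal column position if present.
// [[Rcpp::export]]
List wf_sample(SEXP xp, IntegerVector deme_idx, IntegerVector n_per_deme,
               int min_sub_gen) {
  Population* P = get(xp);
  std::vector<const std::vector<int>*> picked;
  std::vector<int> picked_deme;
  for (int k = 0; k < deme_idx.size(); ++k) {
    int d = deme_idx[k] - 1;
    int m = (int)P->demes[d].size();
    int n = n_per_deme[k];
    if (n > m) stop("cannot sample %d chromosomes from deme of %d", n, m);
    std::vector<int> idx(m);
    for (int i = 0; i < m; ++i) idx[i] = i;
    for (int i = 0; i < n; ++i) {
      int j = i + (int)(unif_rand() * (m - i));
      if (j >= m) j = m - 1;
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < n; ++i) {
      picked.push_back(&P->demes[d][idx[i]]);
      picked_deme.push_back(d + 1);
    }
  }
  int n = (int)picked.size();

  // count derived alleles among sampled chromosomes
  std::vector<int> scount(P->reg.size(), 0);
  for (const auto* h : picked)
    for (int id : *h) scount[id]++;

  std::vector<int> poly, samp_fixed;
  for (int id : P->active_ids) {
    if (scount[id] > 0 && scount[id] < n) poly.push_back(id);
    else if (scount[id] == n) samp_fixed.push_back(id);
  }
  std::sort(poly.begin(), poly.end(),
            [&](int a, int b) { return P->reg[a].pos < P->reg[b].pos; });

  int S = (int)poly.size();
  IntegerMatrix mat(n, S);
  std::vector<int> col_of(P->reg.size(), -1);
  for (int j = 0; j < S; ++j) col_of[poly[j]] = j;
  for (int i = 0; i < n; ++i)
    for (int id : *picked[i])
      if (col_of[id] >= 0) mat(i, col_of[id]) = 1;

  IntegerVector pos(S), kvec(S);
  for (int j = 0; j < S; ++j) {
    pos[j] = P->reg[poly[j]].pos;
    kvec[j] = scount[poly[j]];
  }

  std::vector<int> sp, sg, sk;
  for (const Sub& s : P->subs) {
    if (s.gen >= min_sub_gen) { sp.push_back(s.pos); sg.push_back(s.gen);
                                sk.push_back(s.kind); }
  }
  for (int id : samp_fixed) {
    sp.push_back(P->reg[id].pos);
    sg.push_back(P->generation);
    sk.push_back(P->reg[id].kind);
  }

  int focal_pos = P->focal_id >= 0 ? P->reg[P->focal_id].pos : NA_INTEGER;
  return List::create(
      _["matrix"] = mat, _["positions"] = pos, _["k"] = kvec,
      _["sub_pos"] = wrap(sp), _["sub_gen"] = wrap(sg), _["sub_kind"] = wrap(sk),
      _["deme_of_row"] = wrap(picked_deme), _["focal_pos"] = focal_pos,
      _["generation"] = P->generation);
}

// Fitness vector of a deme's individuals under the current state (tests).
// [[Rcpp::export]]
NumericVector wf_fitness_vector(SEXP xp, int deme) {
  Population* P = get(xp);
  int d = deme - 1;
  double F = (P->focal_id >= 0 && P->feq >= 0.0) ? P->focal_freq() : 0.0;
  double Sbp = (P->feq >= 0.0) ? (P->feq - F) : 0.0;
  int N = (int)P->demes[d].size() / 2;
  NumericVector w(N);
  for (int i = 0; i < N; ++i)
    w[i] = individual_fitness_cpp(*P, P->demes[d][2 * i], P->demes[d][2 * i + 1],
                                  Sbp);
  return w;
}
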