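// Backward-time coalescent engine with piecewise population-size epochs
// (constant or exponential), population merges, admixture pulses, symmetric
// or asymmetric migration, infinite-sites mutation, and (sequence mode)
// Hudson-style ancestral recombination.
//
// Two entry points:
//   cpp_coalescent_sfs: n_sims independent single-site genealogies; tabulates
//     expected branch length and Poisson mutation counts per joint
//     derived-allele-count class across populations.  No cap on sample size.
//   cpp_coalescent_seq: replicates of a length-L sequence with recombination;
//     returns segregating-site positions and 0/1 haplotypes.  Descendant sets
//     are tracked as 64-bit masks, so at most 64 haplotypes.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Epochs {
  // per population: rows (start, N, g); N(t) = N * exp(g * (t - start))
  std::vector<std::vector<double>> start, N, g;
};

// population size at time t (t >= last start <= t)
inline double pop_size_at(const Epochs &ep, int p, double t) {
  const std::vector<double> &st = ep.start[p];
  size_t k = st.size() - 1;
  while (k > 0 && st[k] > t) --k;
  double gg = ep.g[p][k];
  double n0 = ep.N[p][k];
  return (gg == 0.0) ? n0 : n0 * std::exp(gg * (t - st[k]));
}

inline double epoch_growth_at(const Epochs &ep, int p, double t) {
  const std::vector<double> &st = ep.start[p];
  size_t k = st.size() - 1;
  while (k > 0 && st[k] > t) --k;
  return ep.g[p][k];
}

// next epoch boundary strictly after t for pop p (Inf if none)
inline double next_epoch_start(const Epochs &ep, int p, double t) {
  for (double s : ep.start[p]) if (s > t + 1e-12) return s;
  return R_PosInf;
}

// waiting time to coalescence for `pairs` pairs in pop p, from time t,
// valid until the next rate discontinuity (caller caps the result)
inline double coal_wait(const Epochs &ep, int p, double t, double pairs,
                        std::exponential_distribution<double> &rexp,
                        std::mt19937_64 &rng) {
  if (pairs <= 0.0) return R_PosInf;
  double Nt = pop_size_at(ep, p, t);
  double B = pairs / (2.0 * Nt);       // hazard at t
  double gg = epoch_growth_at(ep, p, t);
  double E = rexp(rng);
  if (gg == 0.0) return E / B;
  // hazard(t + w) = B * exp(-gg * w); H(w) = B (1 - exp(-gg w)) / gg
  double arg = 1.0 - gg * E / B;
  if (arg <= 0.0) return R_PosInf;
  return -std::log(arg) / gg;
}

struct Sched {
  // merge: type 0 (a=from, b=to); admix: type 1 (a=target, b=src1, c=src2, alpha)
  std::vector<double> time;
  std::vector<int> type, a, b, c;
  std::vector<double> alpha;
};

} // namespace

// ---------------------------------------------------------------------------
// SFS mode
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_coalescent_sfs(IntegerVector n_samp, List epochs_r, NumericMatrix events,
                        NumericMatrix mig, double theta_site, int n_sims,
                        double seed_) {
  int npop = n_samp.size();
  Epochs ep;
  ep.start.resize(npop); ep.N.resize(npop); ep.g.resize(npop);
  for (int p = 0; p < npop; ++p) {
    NumericMatrix m = epochs_r[p];
    for (int r = 0; r < m.nrow(); ++r) {
      ep.start[p].push_back(m(r, 0));
      ep.N[p].push_back(m(r, 1));
      ep.g[p].push_back(m(r, 2));
    }
  }
  Sched sc;
  for (int r = 0; r < events.nrow(); ++r) {
    sc.time.push_back(events(r, 0));
    sc.type.push_back((int)events(r, 1));
    sc.a.push_back((int)events(r, 2));
    sc.b.push_back((int)events(r, 3));
    sc.c.push_back((int)events(r, 4));
    sc.alpha.push_back(events(r, 5));
  }

  // class index dims: prod over pops of (n_k + 1), column-major
  std::vector<int> dim(npop), str(npop);
  long ncls = 1;
  for (int p = 0; p < npop; ++p) { dim[p] = n_samp[p] + 1; str[p] = ncls; ncls *= dim[p]; }
  std::vector<double> acc_len((size_t)ncls, 0.0);
  std::vector<double> acc_cnt((size_t)ncls, 0.0);
  double tree_len_sum = 0.0;

  std::mt19937_64 rng((uint64_t)seed_);
  std::exponential_distribution<double> rexp(1.0);
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  // lineage: pop + per-pop descendant counts (flattened class index cached).
  // A lineage's class is fixed over its lifetime, so branch length and
  // mutations are accumulated once, at its death.
  std::vector<int> lpop;                 // population of lineage
  std::vector<std::array<int, 8>> lcnt;  // per-pop descendant counts
  std::vector<long> lcls;
  std::vector<double> lbirth;            // time the lineage came into being
  if (npop > 8) stop("at most 8 populations supported");
  std::vector<int> npl(npop, 0);
  std::vector<size_t> idx;
  idx.reserve(256);
  auto close_out = [&](size_t i, double t_death) {
    double life = t_death - lbirth[i];
    if (life <= 0) return;
    acc_len[lcls[i]] += life;
    tree_len_sum += life;
    if (theta_site > 0) {
      std::poisson_distribution<int> rpois(theta_site * life);
      int k = rpois(rng);
      if (k) acc_cnt[lcls[i]] += k;
    }
  };

  bool any_mig = false;
  for (int i = 0; i < mig.nrow(); ++i)
    for (int j = 0; j < mig.ncol(); ++j) if (mig(i, j) > 0) any_mig = true;

  for (int sim = 0; sim < n_sims; ++sim) {
    lpop.clear(); lcnt.clear(); lcls.clear(); lbirth.clear();
    for (int p = 0; p < npop; ++p)
      for (int k = 0; k < n_samp[p]; ++k) {
        lpop.push_back(p);
        std::array<int, 8> cnt{}; cnt[p] = 1;
        lcnt.push_back(cnt);
        lcls.push_back(str[p]); // count 1 in pop p
        lbirth.push_back(0.0);
      }
    std::vector<bool> active(npop, true);
    double t = 0.0;
    size_t ev = 0;
    long guard = 0;

    while (lpop.size() > 1) {
      if (++guard > 100000000L) stop("coalescent did not complete; model may be disconnected");
      // counts per pop
      std::fill(npl.begin(), npl.end(), 0);
      for (int pp : lpop) npl[pp]++;
      // next scheduled boundary: event times + epoch starts
      double t_next = R_PosInf; int next_kind = -1; // 0 event, 1 epoch start
      if (ev < sc.time.size()) { t_next = sc.time[ev]; next_kind = 0; }
      for (int p = 0; p < npop; ++p) {
        double s = next_epoch_start(ep, p, t);
        if (s < t_next) { t_next = s; next_kind = 1; }
      }
      // propose coalescence per pop
      double w_best = R_PosInf; int p_best = -1;
      for (int p = 0; p < npop; ++p) {
        double pairs = 0.5 * (double)npl[p] * (npl[p] - 1);
        double w = coal_wait(ep, p, t, pairs, rexp, rng);
        if (w < w_best) { w_best = w; p_best = p; }
      }
      // migration
      double w_mig = R_PosInf;
      if (any_mig) {
        double tot = 0.0;
        for (int p = 0; p < npop; ++p) {
          if (!npl[p] || !active[p]) continue;
          double rp = 0.0;
          for (int q = 0; q < npop; ++q) if (active[q]) rp += mig(p, q);
          tot += npl[p] * rp;
        }
        if (tot > 0) w_mig = rexp(rng) / tot;
      }
      double w = std::min(w_best, w_mig);
      if (t + w >= t_next) {
        t = t_next;
        if (next_kind == 0) {
          // apply scheduled demographic event
          int ty = sc.type[ev];
          if (ty == 0) { // merge a -> b
            int from = sc.a[ev], to = sc.b[ev];
            for (size_t i = 0; i < lpop.size(); ++i) if (lpop[i] == from) lpop[i] = to;
            active[from] = false;
          } else {       // admixture pulse: target lineages -> src1 w.p. alpha
            int tg = sc.a[ev], s1 = sc.b[ev], s2 = sc.c[ev];
            double al = sc.alpha[ev];
            for (size_t i = 0; i < lpop.size(); ++i)
              if (lpop[i] == tg) lpop[i] = (runif(rng) < al) ? s1 : s2;
            active[tg] = false;
          }
          ++ev;
        }
        continue;
      }
      t += w;
      if (w_mig < w_best) {
        // pick migrating lineage uniformly among those with positive out-rate
        std::vector<double> outr(npop, 0.0);
        for (int p = 0; p < npop; ++p) {
          if (!active[p]) continue;
          for (int q = 0; q < npop; ++q) if (active[q]) outr[p] += mig(p, q);
        }
        double tot = 0.0;
        for (size_t i = 0; i < lpop.size(); ++i) tot += outr[lpop[i]];
        double u = runif(rng) * tot;
        size_t pick = 0;
        for (size_t i = 0; i < lpop.size(); ++i) {
          u -= outr[lpop[i]];
          if (u <= 0) { pick = i; break; }
        }
        int from = lpop[pick];
        double u2 = runif(rng) * outr[from];
        int dest = from;
        for (int q = 0; q < npop; ++q) {
          if (!active[q]) continue;
          u2 -= mig(from, q);
          if (u2 <= 0) { dest = q; break; }
        }
        lpop[pick] = dest;
      } else {
        // coalesce two lineages in p_best
        idx.clear();
        for (size_t i = 0; i < lpop.size(); ++i) if (lpop[i] == p_best) idx.push_back(i);
        size_t i1 = (size_t)(runif(rng) * idx.size()); if (i1 >= idx.size()) i1 = idx.size() - 1;
        size_t i2 = (size_t)(runif(rng) * (idx.size() - 1)); if (i2 >= idx.size() - 1) i2 = idx.size() - 2;
        if (i2 >= i1) ++i2;
        size_t a = idx[i1], b = idx[i2];
        if (a > b) std::swap(a, b);
        close_out(a, t);
        close_out(b, t);
        bool at_root = true;
        for (int p = 0; p < npop; ++p)
          if (lcnt[a][p] + lcnt[b][p] != n_samp[p]) at_root = false;
        if (at_root) {
          // grand MRCA: remove both
          lpop.erase(lpop.begin() + b); lpop.erase(lpop.begin() + a);
          lcnt.erase(lcnt.begin() + b); lcnt.erase(lcnt.begin() + a);
          lcls.erase(lcls.begin() + b); lcls.erase(lcls.begin() + a);
          lbirth.erase(lbirth.begin() + b); lbirth.erase(lbirth.begin() + a);
        } else {
          long cls = 0;
          for (int p = 0; p < npop; ++p) {
            lcnt[a][p] += lcnt[b][p];
            cls += (long)lcnt[a][p] * str[p];
          }
          lcls[a] = cls;
          lbirth[a] = t;
          lpop.erase(lpop.begin() + b);
          lcnt.erase(lcnt.begin() + b);
          lcls.erase(lcls.begin() + b);
          lbirth.erase(lbirth.begin() + b);
        }
      }
    }
  }

  return List::create(_["len"] = NumericVector(acc_len.begin(), acc_len.end()),
                      _["cnt"] = NumericVector(acc_cnt.begin(), acc_cnt.end()),
                      _["dim"] = IntegerVector(dim.begin(), dim.end()),
                      _["tree_len_mean"] = tree_len_sum / n_sims);
}

// ---------------------------------------------------------------------------
// Sequence mode (<= 64 haplotypes)
// ---------------------------------------------------------------------------

namespace {

struct Seg { double a, b; uint64_t mask; };

struct SeqLin {
  int pop;
  std::vector<Seg> segs;
  double tot, lo, hi;
  double birth;
  void refresh() {
    tot = 0.0;
    if (segs.empty()) { lo = hi = 0.0; return; }
    lo = segs.front().a; hi = segs.back().b;
    for (const Seg &s : segs) tot += s.b - s.a;
  }
};

// merge two ancestral segment lists; pieces reaching `full` are dropped
std::vector<Seg> merge_segs(const std::vector<Seg> &A, const std::vector<Seg> &B,
                            uint64_t full) {
  std::vector<Seg> out;
  size_t i = 0, j = 0;
  double ca = (i < A.size()) ? A[i].a : 0.0;
  double cb = (j < B.size()) ? B[j].a : 0.0;
  while (i < A.size() || j < B.size()) {
    if (j >= B.size()) { out.push_back({ca, A[i].b, A[i].mask}); ++i; if (i < A.size()) ca = A[i].a; continue; }
    if (i >= A.size()) { out.push_back({cb, B[j].b, B[j].mask}); ++j; if (j < B.size()) cb = B[j].a; continue; }
    if (A[i].b <= cb) { out.push_back({ca, A[i].b, A[i].mask}); ++i; if (i < A.size()) ca = A[i].a; continue; }
    if (B[j].b <= ca) { out.push_back({cb, B[j].b, B[j].mask}); ++j; if (j < B.size()) cb = B[j].a; continue; }
    // overlap
    if (ca < cb) { out.push_back({ca, cb, A[i].mask}); ca = cb; continue; }
    if (cb < ca) { out.push_back({cb, ca, B[j].mask}); cb = ca; continue; }
    double e = std::min(A[i].b, B[j].b);
    uint64_t m = A[i].mask | B[j].mask;
    if (m != full) out.push_back({ca, e, m});
    ca = e; cb = e;
    if (e >= A[i].b) { ++i; if (i < A.size()) ca = A[i].a; }
    if (e >= B[j].b) { ++j; if (j < B.size()) cb = B[j].a; }
  }
  // coalesce adjacent pieces with identical masks
  std::vector<Seg> cmp;
  for (const Seg &s : out) {
    if (s.b - s.a <= 0) continue;
    if (!cmp.empty() && cmp.back().mask == s.mask && std::abs(cmp.back().b - s.a) < 1e-12)
      cmp.back().b = s.b;
    else cmp.push_back(s);
  }
  return cmp;
}

} // namespace

// [[Rcpp::export]]
List cpp_coalescent_seq(IntegerVector n_samp, List epochs_r, NumericMatrix events,
                        NumericMatrix mig, double L, double mu, double rec,
                        int n_rep, double seed_) {
  int npop = n_samp.size();
  int n_hap = 0;
  for (int p = 0; p < npop; ++p) n_hap += n_samp[p];
  if (n_hap > 64) stop("sequence mode supports at most 64 haplotypes");
  uint64_t full = (n_hap == 64) ? ~0ULL : ((1ULL << n_hap) - 1ULL);

  Epochs ep;
  ep.start.resize(npop); ep.N.resize(npop); ep.g.resize(npop);
  for (int p = 0; p < npop; ++p) {
    NumericMatrix m = epochs_r[p];
    for (int r = 0; r < m.nrow(); ++r) {
      ep.start[p].push_back(m(r, 0));
      ep.N[p].push_back(m(r, 1));
      ep.g[p].push_back(m(r, 2));
    }
  }
  Sched sc;
  for (int r = 0; r < events.nrow(); ++r) {
    sc.time.push_back(events(r, 0));
    sc.type.push_back((int)events(r, 1));
    sc.a.push_back((int)events(r, 2));
    sc.b.push_back((int)events(r, 3));
    sc.c.push_back((int)events(r, 4));
    sc.alpha.push_back(events(r, 5));
  }
  bool any_mig = false;
  for (int i = 0; i < mig.nrow(); ++i)
    for (int j = 0; j < mig.ncol(); ++j) if (mig(i, j) > 0) any_mig = true;

  std::mt19937_64 rng((uint64_t)seed_);
  std::exponential_distribution<double> rexp(1.0);
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  List reps(n_rep);

  for (int rep = 0; rep < n_rep; ++rep) {
    std::vector<SeqLin> lin;
    int h = 0;
    for (int p = 0; p < npop; ++p)
      for (int k = 0; k < n_samp[p]; ++k, ++h) {
        SeqLin l; l.pop = p; l.birth = 0.0;
        l.segs.push_back({0.0, L, 1ULL << h});
        l.refresh();
        lin.push_back(l);
      }
    std::vector<bool> active(npop, true);
    std::vector<double> mpos;          // mutation positions
    std::vector<uint64_t> mmask;       // derived carriers
    double t = 0.0;
    size_t ev = 0;
    long guard = 0;
    // mutations accrue over a lineage's whole lifetime (its ancestral
    // segments are fixed between birth and death), dropped at death
    auto drop_mutations = [&](const SeqLin &l, double t_death) {
      if (mu <= 0 || l.tot <= 0) return;
      double life = t_death - l.birth;
      if (life <= 0) return;
      std::poisson_distribution<int> rpois(mu * life * l.tot);
      int k = rpois(rng);
      for (int x = 0; x < k; ++x) {
        double u = runif(rng) * l.tot;
        for (const Seg &s : l.segs) {
          double w2 = s.b - s.a;
          if (u < w2) { mpos.push_back(s.a + u); mmask.push_back(s.mask); break; }
          u -= w2;
        }
      }
    };

    while (lin.size() > 1) {
      if (++guard > 50000000L) stop("coalescent did not complete; model may be disconnected");
      std::vector<int> npl(npop, 0);
      for (const SeqLin &l : lin) npl[l.pop]++;
      double t_next = R_PosInf; int next_kind = -1;
      if (ev < sc.time.size()) { t_next = sc.time[ev]; next_kind = 0; }
      for (int p = 0; p < npop; ++p) {
        double s = next_epoch_start(ep, p, t);
        if (s < t_next) { t_next = s; next_kind = 1; }
      }
      double w_best = R_PosInf; int p_best = -1;
      for (int p = 0; p < npop; ++p) {
        double pairs = 0.5 * (double)npl[p] * (npl[p] - 1);
        double w = coal_wait(ep, p, t, pairs, rexp, rng);
        if (w < w_best) { w_best = w; p_best = p; }
      }
      // recombination: rate rec per bp on each lineage's breakable span
      double w_rec = R_PosInf, span_tot = 0.0;
      if (rec > 0) {
        for (const SeqLin &l : lin) span_tot += (l.hi - l.lo);
        if (span_tot > 0) w_rec = rexp(rng) / (rec * span_tot);
      }
      double w_mig = R_PosInf;
      if (any_mig) {
        double tot = 0.0;
        for (int p = 0; p < npop; ++p) {
          if (!npl[p] || !active[p]) continue;
          double rp = 0.0;
          for (int q = 0; q < npop; ++q) if (active[q]) rp += mig(p, q);
          tot += npl[p] * rp;
        }
        if (tot > 0) w_mig = rexp(rng) / tot;
      }
      double w = std::min({w_best, w_rec, w_mig});
      if (t + w >= t_next) {
        t = t_next;
        if (next_kind == 0) {
          int ty = sc.type[ev];
          if (ty == 0) {
            int from = sc.a[ev], to = sc.b[ev];
            for (SeqLin &l : lin) if (l.pop == from) l.pop = to;
            active[from] = false;
          } else {
            int tg = sc.a[ev], s1 = sc.b[ev], s2 = sc.c[ev];
            double al = sc.alpha[ev];
            for (SeqLin &l : lin) if (l.pop == tg) l.pop = (runif(rng) < al) ? s1 : s2;
            active[tg] = false;
          }
          ++ev;
        }
        continue;
      }
      t += w;
      if (w == w_rec) {
        double u = runif(rng) * span_tot;
        size_t pick = 0;
        for (size_t i = 0; i < lin.size(); ++i) {
          double sp = lin[i].hi - lin[i].lo;
          if (u < sp) { pick = i; break; }
          u -= sp;
          pick = i;
        }
        SeqLin &l = lin[pick];
        double x = l.lo + runif(rng) * (l.hi - l.lo);
        SeqLin left, right;
        left.pop = right.pop = l.pop;
        left.birth = right.birth = t;
        for (const Seg &s : l.segs) {
          if (s.b <= x) left.segs.push_back(s);
          else if (s.a >= x) right.segs.push_back(s);
          else { left.segs.push_back({s.a, x, s.mask}); right.segs.push_back({x, s.b, s.mask}); }
        }
        if (left.segs.empty() || right.segs.empty()) continue; // breakpoint outside ancestral material
        drop_mutations(l, t);
        left.refresh(); right.refresh();
        lin[pick] = left;
        lin.push_back(right);
      } else if (w == w_mig && any_mig) {
        std::vector<double> outr(npop, 0.0);
        for (int p = 0; p < npop; ++p) {
          if (!active[p]) continue;
          for (int q = 0; q < npop; ++q) if (active[q]) outr[p] += mig(p, q);
        }
        double tot = 0.0;
        for (const SeqLin &l : lin) tot += outr[l.pop];
        double u = runif(rng) * tot;
        size_t pick = 0;
        for (size_t i = 0; i < lin.size(); ++i) {
          u -= outr[lin[i].pop];
          if (u <= 0) { pick = i; break; }
          pick = i;
        }
        int from = lin[pick].pop;
        double u2 = runif(rng) * outr[from];
        int dest = from;
        for (int q = 0; q < npop; ++q) {
          if (!active[q]) continue;
          u2 -= mig(from, q);
          if (u2 <= 0) { dest = q; break; }
        }
        lin[pick].pop = dest;
      } else {
        std::vector<size_t> idx;
        for (size_t i = 0; i < lin.size(); ++i) if (lin[i].pop == p_best) idx.push_back(i);
        size_t i1 = (size_t)(runif(rng) * idx.size()); if (i1 >= idx.size()) i1 = idx.size() - 1;
        size_t i2 = (size_t)(runif(rng) * (idx.size() - 1)); if (i2 >= idx.size() - 1) i2 = idx.size() - 2;
        if (i2 >= i1) ++i2;
        size_t a = idx[i1], b = idx[i2];
        if (a > b) std::swap(a, b);
        drop_mutations(lin[a], t);
        drop_mutations(lin[b], t);
        SeqLin merged;
        merged.pop = p_best;
        merged.birth = t;
        merged.segs = merge_segs(lin[a].segs, lin[b].segs, full);
        merged.refresh();
        lin.erase(lin.begin() + b);
        if (merged.segs.empty()) lin.erase(lin.begin() + a);
        else lin[a] = merged;
      }
      // purge empty lineages (fully coalesced material)
      for (size_t i = lin.size(); i-- > 0; )
        if (lin[i].segs.empty()) lin.erase(lin.begin() + i);
    }

    // order mutations by position, build haplotype matrix
    std::vector<size_t> ord(mpos.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](size_t x, size_t y) { return mpos[x] < mpos[y]; });
    NumericVector pos((int)ord.size());
    IntegerMatrix H(n_hap, (int)ord.size());
    for (size_t k = 0; k < ord.size(); ++k) {
      pos[k] = mpos[ord[k]];
      uint64_t m = mmask[ord[k]];
      for (int hh = 0; hh < n_hap; ++hh) H(hh, (int)k) = (int)((m >> hh) & 1ULL);
    }
    reps[rep] = List::create(_["pos"] = pos, _["haps"] = H);
  }
  return reps;
}
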