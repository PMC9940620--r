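// Bidirectional wavefront alignment: alternating forward/reverse searches
// retaining only scope wavefronts per direction, breakpoint detection with
// the p-score window and the gap-open correction, antidiagonal pruning,
// and the recursive assembly of the full alignment in O(s) working memory.
#include <Rcpp.h>

#include <array>
#include <cstdlib>

#include "wfa_engine.h"

namespace wfa {

struct Bp {
  bool valid = false;
  long long total = 0;
  int sf = 0, sr = 0, k = 0, off = 0;
  Comp comp = CM;
};

// Antidiagonal of a cell is v + h = 2*offset - k: a cheap progress measure.
static long long anti_max(const WF& w) {
  long long best = LLONG_MIN;
  for (int c = 0; c < 3; ++c) {
    const Band& b = w.c[c];
    for (int k = b.lo; k <= b.hi; ++k) {
      int off = b.get(k, NULL_F);
      if (off != NULL_F && off < NULL_R)
        best = std::max(best, 2LL * off - k);
    }
  }
  return best;
}
static long long anti_min(const WF& w) {
  long long best = LLONG_MAX;
  for (int c = 0; c < 3; ++c) {
    const Band& b = w.c[c];
    for (int k = b.lo; k <= b.hi; ++k) {
      int off = b.get(k, NULL_R);
      if (off != NULL_R && off > NULL_F)
        best = std::min(best, 2LL * off - k);
    }
  }
  return best;
}

static void consider(Bp& best, long long total, int sf, int sr, int k, int off,
                     Comp comp, int n, int m) {
  int v = off - k;
  if (off < 0 || off > m || v < 0 || v > n) return;
  if (!best.valid || total < best.total) {
    best.valid = true;
    best.total = total;
    best.sf = sf;
    best.sr = sr;
    best.k = k;
    best.off = off;
    best.comp = comp;
  }
}

// Overlap test between one forward and one reverse wavefront: on every
// shared diagonal, M overlaps when M-> >= M<-, I when I-> >= I<-, D when
// D-> >= D<-. Candidate totals are sf+sr for M and sf+sr-o for I/D (both
// directions pay the open of the gap the breakpoint sits in). The split
// cell is taken from the reverse offsets (the reverse farthest-reaching
// point lies on an optimal traceback), nudged to the nearest cell where
// the flanking sub-alignments remain realisable (h >= 1 for I, v >= 1
// for D; both within reach of the forward offsets).
static void overlap_pair(const WF& f, int sf, const WF& r, int sr,
                         const Pen& pen, int n, int m, Bp& best) {
  if (std::abs(sf - sr) > pen.scope()) return;
  int lo = INT_MAX, hi = INT_MIN;
  for (int c = 0; c < 3; ++c) {
    if (!f.c[c].empty() && !r.c[c].empty()) {
      lo = std::min(lo, std::max(f.c[c].lo, r.c[c].lo));
      hi = std::max(hi, std::min(f.c[c].hi, r.c[c].hi));
    }
  }
  for (int k = lo; k <= hi; ++k) {
    int fm = f.c[CM].get(k, NULL_F), rm = r.c[CM].get(k, NULL_R);
    if (fm != NULL_F && rm != NULL_R && fm >= rm)
      consider(best, static_cast<long long>(sf) + sr, sf, sr, k, rm, CM, n, m);
    int fi = f.c[CI].get(k, NULL_F), ri = r.c[CI].get(k, NULL_R);
    if (fi != NULL_F && ri != NULL_R && fi >= ri)
      consider(best, static_cast<long long>(sf) + sr - pen.o, sf, sr, k,
               std::max(ri, 1), CI, n, m);
    int fd = f.c[CD].get(k, NULL_F), rd = r.c[CD].get(k, NULL_R);
    if (fd != NULL_F && rd != NULL_R && fd >= rd)
      consider(best, static_cast<long long>(sf) + sr - pen.o, sf, sr, k,
               std::max(rd, k + 1), CD, n, m);
  }
}

// Alternating bidirectional search (W->1, W<-1, W->2, W<-2, ...) keeping
// only scope wavefronts per direction. After the first candidate overlap
// the search continues until no future round can yield a strictly lower
// total (any breakpoint found later scores at least sf + sr - o - p + 1).
Bp find_bp(const char* q, int n, const char* t, int m, const Pen& pen,
           Comp begin, Comp end, bool use_skip, Stats& st) {
  int p = pen.scope();
  Ring fw(p), rv(p);
  Bp best;
  long long fmax_anti = LLONG_MIN, rmin_anti = LLONG_MAX;

  WF f0 = base_forward(begin);
  extend_forward(f0, q, n, t, m);
  st.cells_computed += static_cast<long long>(f0.cells());
  fmax_anti = std::max(fmax_anti, anti_max(f0));
  WF r0 = base_reverse(end, n, m);
  extend_reverse(r0, q, n, t, m);
  seed_reverse_end(r0, 0, pen, end, n, m);
  st.cells_computed += static_cast<long long>(r0.cells());
  rmin_anti = std::min(rmin_anti, anti_min(r0));
  if (!use_skip || fmax_anti >= rmin_anti) {
    ++st.overlap_calls;
    overlap_pair(f0, 0, r0, 0, pen, n, m, best);
  } else {
    ++st.overlap_skipped;
  }
  fw.put(0, std::move(f0));
  rv.put(0, std::move(r0));
  st.peak_live_cells = std::max(st.peak_live_cells,
                                static_cast<long long>(fw.cells() + rv.cells()));
  st.peak_live_wavefronts =
      std::max(st.peak_live_wavefronts, std::max(fw.live(), rv.live()));

  long long cap = score_cap(pen, n, m);
  auto fget = [&](int s) { return fw.get(s); };
  auto rget = [&](int s) { return rv.get(s); };
  int sf = 0, sr = 0;
  while (true) {
    // forward round
    if (best.valid &&
        best.total < static_cast<long long>(sf + 1) + sr - pen.o - p + 1)
      break;
    ++sf;
    if (sf > cap)
      Rcpp::stop("breakpoint search exceeded its score bound (internal error)");
    {
      WF w = next_forward(fget, sf, pen, n, m);
      extend_forward(w, q, n, t, m);
      st.cells_computed += static_cast<long long>(w.cells());
      fmax_anti = std::max(fmax_anti, anti_max(w));
      if (!w.empty()) {
        if (!use_skip || fmax_anti >= rmin_anti) {
          ++st.overlap_calls;
          for (int s2 = sr; s2 > sr - p && s2 >= 0; --s2) {
            const WF* r = rv.get(s2);
            if (r) overlap_pair(w, sf, *r, s2, pen, n, m, best);
          }
        } else {
          ++st.overlap_skipped;
        }
      }
      fw.put(sf, std::move(w));
    }
    st.peak_live_cells = std::max(
        st.peak_live_cells, static_cast<long long>(fw.cells() + rv.cells()));
    st.peak_live_wavefronts =
        std::max(st.peak_live_wavefronts, std::max(fw.live(), rv.live()));

    // reverse round
    if (best.valid &&
        best.total < static_cast<long long>(sf) + (sr + 1) - pen.o - p + 1)
      break;
    ++sr;
    {
      WF w = next_reverse(rget, sr, pen, n, m);
      extend_reverse(w, q, n, t, m);
      seed_reverse_end(w, sr, pen, end, n, m);
      st.cells_computed += static_cast<long long>(w.cells());
      rmin_anti = std::min(rmin_anti, anti_min(w));
      if (!w.empty()) {
        if (!use_skip || fmax_anti >= rmin_anti) {
          ++st.overlap_calls;
          for (int s2 = sf; s2 > sf - p && s2 >= 0; --s2) {
            const WF* f = fw.get(s2);
            if (f) overlap_pair(*f, s2, w, sr, pen, n, m, best);
          }
        } else {
          ++st.overlap_skipped;
        }
      }
      rv.put(sr, std::move(w));
    }
    st.peak_live_cells = std::max(
        st.peak_live_cells, static_cast<long long>(fw.cells() + rv.cells()));
    st.peak_live_wavefronts =
        std::max(st.peak_live_wavefronts, std::max(fw.live(), rv.live()));
  }
  if (!best.valid)
    Rcpp::stop("bidirectional search found no breakpoint (internal error)");
  return best;
}

static void solve_node_full(const char* q, int n, const char* t, int m,
                            const Pen& pen, Comp begin, Comp end, Stats& st,
                            std::string& ops) {
  Stats sub;
  FullResult r = wfa_full(q, n, t, m, pen, begin, end, true, sub);
  st.cells_computed += sub.cells_computed;
  st.peak_live_cells = std::max(st.peak_live_cells, sub.peak_live_cells);
  ops += r.ops;
}

// Recursive assembly: split the problem at the breakpoint cell, recurse
// with boundary components matching the breakpoint component, then check
// that the assembled piece reproduces the breakpoint total. All wavefront
// structures of a node are discarded before its recursive calls run.
static void biwfa_rec(const char* q, int n, const char* t, int m,
                      const Pen& pen, Comp begin, Comp end, int depth,
                      bool use_skip, Stats& st, std::string& ops,
                      std::vector<std::array<long long, 5>>& nodes) {
  st.max_depth = std::max(st.max_depth, depth);
  if (n == 0 && m == 0) return;
  int p = pen.scope();
  if (std::min(n, m) == 0 || n + m <= 64) {
    solve_node_full(q, n, t, m, pen, begin, end, st, ops);
    return;
  }
  Bp bp = find_bp(q, n, t, m, pen, begin, end, use_skip, st);
  int v = bp.off - bp.k, h = bp.off;
  if (bp.total <= 2 * p || (v == 0 && h == 0) || (v == n && h == m)) {
    solve_node_full(q, n, t, m, pen, begin, end, st, ops);
    return;
  }
  nodes.push_back({static_cast<long long>(depth), static_cast<long long>(bp.sf),
                   static_cast<long long>(bp.sr), bp.total,
                   static_cast<long long>(bp.comp)});
  size_t mark = ops.size();
  biwfa_rec(q, v, t, h, pen, begin, bp.comp, depth + 1, use_skip, st, ops, nodes);
  biwfa_rec(q + v, n - v, t + h, m - h, pen, bp.comp, end, depth + 1, use_skip,
            st, ops, nodes);
  long long got = score_of_ops(ops.substr(mark), pen, begin);
  if (got != bp.total) {
    // Defensive: a degenerate split failed to reproduce the optimal total;
    // redo this node directly (memory cost is bounded by the node size).
    ++st.fallbacks;
    ops.resize(mark);
    solve_node_full(q, n, t, m, pen, begin, end, st, ops);
  }
}

static Rcpp::List bp_to_list(const Bp& bp, const Stats& st) {
  const char* comps[3] = {"M", "I", "D"};
  return Rcpp::List::create(
      Rcpp::Named("sf") = bp.sf, Rcpp::Named("sr") = bp.sr,
      Rcpp::Named("k") = bp.k, Rcpp::Named("offset") = bp.off,
      Rcpp::Named("component") = std::string(comps[bp.comp]),
      Rcpp::Named("total") = static_cast<double>(bp.total),
      Rcpp::Named("stats") = stats_to_list(st));
}

}  // namespace wfa

using namespace wfa;

// [[Rcpp::export(name = ".cpp_find_breakpoint")]]
Rcpp::List cpp_find_breakpoint(std::string q, std::string t, int x, int o,
                               int e, int begin, int end, bool antidiag_skip) {
  Pen pen = pen_from(x, o, e);
  int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
  if (n + m == 0) Rcpp::stop("breakpoint search requires a non-empty instance");
  Stats st;
  Bp bp = find_bp(q.data(), n, t.data(), m, pen, comp_from_int(begin),
                  comp_from_int(end), antidiag_skip, st);
  return bp_to_list(bp, st);
}

// [[Rcpp::export(name = ".cpp_biwfa_score")]]
Rcpp::List cpp_biwfa_score(std::string q, std::string t, int x, int o, int e,
                           bool antidiag_skip) {
  Pen pen = pen_from(x, o, e);
  int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
  Stats st;
  long long total = 0;
  if (n + m > 0) {
    Bp bp = find_bp(q.data(), n, t.data(), m, pen, CM, CM, antidiag_skip, st);
    total = bp.total;
  }
  return Rcpp::List::create(Rcpp::Named("score") = static_cast<double>(total),
                            Rcpp::Named("stats") = stats_to_list(st));
}

// [[Rcpp::export(name = ".cpp_biwfa_align")]]
Rcpp::List cpp_biwfa_align(std::string q, std::string t, int x, int o, int e,
                           bool antidiag_skip) {
  Pen pen = pen_from(x, o, e);
  int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
  Stats st;
  std::string ops;
  std::vector<std::array<long long, 5>> nodes;
  biwfa_rec(q.data(), n, t.data(), m, pen, CM, CM, 0, antidiag_skip, st, ops,
            nodes);
  long long score = score_of_ops(ops, pen, CM);

  size_t nn = nodes.size();
  Rcpp::IntegerVector nd(nn), nsf(nn), nsr(nn), ncomp(nn);
  Rcpp::NumericVector ntot(nn);
  for (size_t i = 0; i < nn; ++i) {
    nd[i] = static_cast<int>(nodes[i][0]);
    nsf[i] = static_cast<int>(nodes[i][1]);
    nsr[i] = static_cast<int>(nodes[i][2]);
    ntot[i] = static_cast<double>(nodes[i][3]);
    ncomp[i] = static_cast<int>(nodes[i][4]);
  }
  return Rcpp::List::create(
      Rcpp::Named("score") = static_cast<double>(score),
      Rcpp::Named("cigar") = rle_cigar(ops),
      Rcpp::Named("stats") = stats_to_list(st),
      Rcpp::Named("nodes") = Rcpp::List::create(
          Rcpp::Named("depth") = nd, Rcpp::Named("sf") = nsf,
          Rcpp::Named("sr") = nsr, Rcpp::Named("total") = ntot,
          Rcpp::Named("component") = ncomp));
}
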