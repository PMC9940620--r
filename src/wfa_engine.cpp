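// Unidirectional wavefront alignment: greedy LCP/LCS diagonal extension,
// the full O(s^2)-memory WFA with traceback, and the windowed score-only
// WFA that retains only the last scope wavefronts.
#include <Rcpp.h>

#include "wfa_engine.h"

namespace wfa {

// Advance every reachable M offset by the longest common prefix of the
// remaining suffixes of q (from offset - k) and t (from offset).
void extend_forward(WF& w, const char* q, int n, const char* t, int m) {
  Band& M = w.c[CM];
  for (int k = M.lo; k <= M.hi; ++k) {
    int off = M.get(k, NULL_F);
    if (off == NULL_F) continue;
    while (off < m && off - k < n && q[off - k] == t[off]) ++off;
    M.set(k, off);
  }
}

// Pull every reachable reverse M offset back by the longest common suffix
// of the prefixes q[0, offset-k-1] and t[0, offset-1].
void extend_reverse(WF& w, const char* q, int n, const char* t, int m) {
  (void)n;
  (void)m;
  Band& M = w.c[CM];
  for (int k = M.lo; k <= M.hi; ++k) {
    int off = M.get(k, NULL_R);
    if (off == NULL_R) continue;
    while (off > 0 && off - k > 0 && q[off - k - 1] == t[off - 1]) --off;
    M.set(k, off);
  }
}

// Forward base case X_{0,0} = 0; beginning at I or D places the score-0
// seed in that component instead (the gap open is already paid on the
// other side of the breakpoint), and the gap may close at no cost.
WF base_forward(Comp begin) {
  WF w;
  if (begin != CM) {
    w.c[begin].init(0, 0, NULL_F);
    w.c[begin].set(0, 0);
  }
  w.c[CM].init(0, 0, NULL_F);
  w.c[CM].set(0, 0);
  return w;
}

// Reverse base case X_{0,m-n} = m when the alignment ends at M. An
// alignment ending at I or D instead ends with at least one gap column
// whose open this piece pays: the reverse direction charges opens at the
// right end of a gap, so the indel seed enters at score o (see
// seed_reverse_end), and no M base exists at score 0.
WF base_reverse(Comp end, int n, int m) {
  WF w;
  int k = m - n;
  if (end == CM) {
    w.c[CM].init(k, k, NULL_R);
    w.c[CM].set(k, m);
  }
  return w;
}

// Inject the end-at-I/D reverse seed into the wavefront of score o. The
// seed is added after X/M of this score were computed so that a
// zero-column trailing gap (which would contradict ending at an indel)
// cannot close for free at the seed itself.
void seed_reverse_end(WF& w, int s, const Pen& pen, Comp end, int n, int m) {
  if (end == CM || s != pen.o) return;
  int k = m - n;
  Band& b = w.c[end];
  if (b.empty()) {
    b.init(k, k, NULL_R);
    b.set(k, m);
  } else {
    if (k < b.lo || k > b.hi) {
      Band nb;
      nb.init(std::min(k, b.lo), std::max(k, b.hi), NULL_R);
      for (int kk = b.lo; kk <= b.hi; ++kk) nb.set(kk, b.get(kk, NULL_R));
      nb.set(k, m);
      b = std::move(nb);
    } else {
      b.set(k, std::min(b.get(k, NULL_R), m));
    }
  }
}

// Safe upper bound on any attainable score; exceeding it means a bug.
long long score_cap(const Pen& pen, int n, int m) {
  return static_cast<long long>(pen.o) + static_cast<long long>(pen.e) * (n + m) +
         static_cast<long long>(pen.x) * std::min(n, m) + pen.scope() + 2;
}

bool end_reached(const WF& w, Comp end, int n, int m, int null_v) {
  int off = w.c[end].get(m - n, null_v);
  return off != null_v && off >= m;
}

Comp comp_from_int(int c) {
  if (c < 0 || c > 2) Rcpp::stop("component must be 0 (M), 1 (I) or 2 (D)");
  return static_cast<Comp>(c);
}

Pen pen_from(int x, int o, int e) {
  if (x <= 0 || e <= 0 || o < 0) Rcpp::stop("penalties require x > 0, e > 0, o >= 0");
  return Pen{x, o, e};
}

// ---- full WFA with traceback -------------------------------------------
// Retains every wavefront; the recursion base case and the reference
// unidirectional mode.
FullResult wfa_full(const char* q, int n, const char* t, int m, const Pen& pen,
                    Comp begin, Comp end, bool keep_traceback, Stats& st) {
  FullResult res;
  if (n == 0 && m == 0) return res;

  std::vector<WF> all;
  auto get = [&](int s) -> const WF* {
    if (s < 0 || s >= static_cast<int>(all.size())) return nullptr;
    return &all[static_cast<size_t>(s)];
  };

  long long cap = score_cap(pen, n, m);
  int s_final = -1;
  for (int s = 0;; ++s) {
    if (s > cap) Rcpp::stop("wavefront score exceeded its safety bound (internal error)");
    WF w = s == 0 ? base_forward(begin) : next_forward(get, s, pen, n, m);
    extend_forward(w, q, n, t, m);
    st.cells_computed += static_cast<long long>(w.cells());
    all.push_back(std::move(w));
    if (end_reached(all.back(), end, n, m, NULL_F)) {
      s_final = s;
      break;
    }
  }
  long long total = 0;
  for (const auto& w : all) total += static_cast<long long>(w.cells());
  st.peak_live_cells = std::max(st.peak_live_cells, total);
  st.peak_live_wavefronts = std::max(st.peak_live_wavefronts, static_cast<int>(all.size()));
  res.score = s_final;
  if (!keep_traceback) return res;

  // Backtrace as a checked walk: a stored offset dominates every cell
  // behind it on its diagonal (reachable at no greater score), so each
  // step only requires the predecessor's stored offset to cover the cell
  // the path came from. Preference: match, then mismatch, then I, then D
  // (and gap-open before gap-extend). A shallow backtracking stack copes
  // with the rare boundary-clamped offsets whose slack could strand a
  // purely greedy walk.
  std::string ops;
  struct TB {
    int s, k, off;
    Comp c;
    int opt;         // next option to try at this state
    size_t ops_len;  // ops length on entry (for rollback)
  };
  std::vector<TB> stack;
  auto getoff = [&](int ss, Comp cc, int kk) -> int {
    const WF* w = get(ss);
    return w ? w->c[cc].get(kk, NULL_F) : NULL_F;
  };
  stack.push_back(TB{s_final, m - n, m, end, 0, 0});
  long long guard = 0;
  bool done = false;
  while (!stack.empty()) {
    if (++guard > 64LL * (n + m + s_final + 8))
      Rcpp::stop("traceback exceeded its step bound (internal error)");
    const TB cur = stack.back();
    ops.resize(cur.ops_len);
    const int s = cur.s, k = cur.k, off = cur.off;
    const int v = off - k;
    if (s == 0 && k == 0 && off == 0 && cur.c == begin) {
      done = true;  // reached the origin in the begin component
      break;
    }
    // Enumerate this state's predecessor options in preference order:
    // match, mismatch, close-I, close-D for M; open before extend for
    // gaps. `opt` remembers how far we got for backtracking.
    TB nxt{};
    char emit = 0;
    bool moved = false;
    int opt = cur.opt;
    int n_opts = cur.c == CM ? 4 : 2;
    for (; opt < n_opts && !moved; ++opt) {
      if (cur.c == CM) {
        switch (opt) {
          case 0:  // match
            if (off >= 1 && v >= 1 && q[v - 1] == t[off - 1] &&
                getoff(s, CM, k) >= off - 1) {
              emit = '=';
              nxt = TB{s, k, off - 1, CM, 0, 0};
              moved = true;
            }
            break;
          case 1:  // mismatch
            if (off >= 1 && v >= 1 && q[v - 1] != t[off - 1] && s >= pen.x &&
                getoff(s - pen.x, CM, k) >= off - 1) {
              emit = 'X';
              nxt = TB{s - pen.x, k, off - 1, CM, 0, 0};
              moved = true;
            }
            break;
          case 2:  // close I at no cost
            if (off >= 1 && getoff(s, CI, k) >= off) {
              nxt = TB{s, k, off, CI, 0, 0};
              moved = true;
            }
            break;
          case 3:  // close D at no cost
            if (v >= 1 && getoff(s, CD, k) >= off) {
              nxt = TB{s, k, off, CD, 0, 0};
              moved = true;
            }
            break;
        }
        // beginning inside a gap: the origin lives in the I/D component
        if (!moved && opt == 3 && begin != CM && s == 0 && k == 0 && off == 0) {
          nxt = TB{0, 0, 0, begin, 0, 0};
          moved = true;
        }
      } else if (cur.c == CI) {
        if (opt == 0) {  // gap open
          if (off >= 1 && s >= pen.o + pen.e &&
              getoff(s - pen.o - pen.e, CM, k - 1) >= off - 1) {
            emit = comp_to_cigar_op(CI);
            nxt = TB{s - pen.o - pen.e, k - 1, off - 1, CM, 0, 0};
            moved = true;
          }
        } else {  // gap extend
          if (off >= 1 && s >= pen.e && getoff(s - pen.e, CI, k - 1) >= off - 1) {
            emit = comp_to_cigar_op(CI);
            nxt = TB{s - pen.e, k - 1, off - 1, CI, 0, 0};
            moved = true;
          }
        }
      } else {
        if (opt == 0) {  // gap open
          if (v >= 1 && s >= pen.o + pen.e &&
              getoff(s - pen.o - pen.e, CM, k + 1) >= off) {
            emit = comp_to_cigar_op(CD);
            nxt = TB{s - pen.o - pen.e, k + 1, off, CM, 0, 0};
            moved = true;
          }
        } else {  // gap extend
          if (v >= 1 && s >= pen.e && getoff(s - pen.e, CD, k + 1) >= off) {
            emit = comp_to_cigar_op(CD);
            nxt = TB{s - pen.e, k + 1, off, CD, 0, 0};
            moved = true;
          }
        }
      }
    }
    if (moved) {
      stack.back().opt = opt;  // resume after this option on backtrack
      if (emit) ops.push_back(emit);
      nxt.ops_len = ops.size();
      stack.push_back(nxt);
    } else {
      stack.pop_back();  // dead end: the parent tries its next option
    }
  }
  if (!done) Rcpp::stop("traceback found no valid path (internal error)");
  std::reverse(ops.begin(), ops.end());
  res.ops = std::move(ops);
  return res;
}

// ---- windowed score-only WFA --------------------------------------------
long long wfa_score_windowed(const char* q, int n, const char* t, int m,
                             const Pen& pen, Comp begin, Comp end, Stats& st) {
  if (n == 0 && m == 0) return 0;
  int p = pen.scope();
  Ring ring(p);
  auto get = [&](int s) -> const WF* { return ring.get(s); };
  long long cap = score_cap(pen, n, m);
  for (int s = 0;; ++s) {
    if (s > cap) Rcpp::stop("wavefront score exceeded its safety bound (internal error)");
    WF w = s == 0 ? base_forward(begin) : next_forward(get, s, pen, n, m);
    extend_forward(w, q, n, t, m);
    st.cells_computed += static_cast<long long>(w.cells());
    bool done = end_reached(w, end, n, m, NULL_F);
    ring.put(s, std::move(w));
    st.peak_live_cells = std::max(st.peak_live_cells, static_cast<long long>(ring.cells()));
    st.peak_live_wavefronts = std::max(st.peak_live_wavefronts, ring.live());
    if (done) return s;
  }
}

Rcpp::List stats_to_list(const Stats& st) {
  return Rcpp::List::create(
      Rcpp::Named("cells_computed") = static_cast<double>(st.cells_computed),
      Rcpp::Named("peak_live_cells") = static_cast<double>(st.peak_live_cells),
      Rcpp::Named("peak_live_wavefronts") = st.peak_live_wavefronts,
      Rcpp::Named("overlap_calls") = static_cast<double>(st.overlap_calls),
      Rcpp::Named("overlap_skipped") = static_cast<double>(st.overlap_skipped),
      Rcpp::Named("max_depth") = st.max_depth,
      Rcpp::Named("fallbacks") = st.fallbacks);
}

}  // namespace wfa

using namespace wfa;

// [[Rcpp::export(name = ".cpp_wfa_align")]]
Rcpp::List cpp_wfa_align(std::string q, std::string t, int x, int o, int e,
                         int begin, int end, bool traceback) {
  Pen pen = pen_from(x, o, e);
  Stats st;
  FullResult r = wfa_full(q.data(), static_cast<int>(q.size()), t.data(),
                          static_cast<int>(t.size()), pen, comp_from_int(begin),
                          comp_from_int(end), traceback, st);
  return Rcpp::List::create(Rcpp::Named("score") = static_cast<double>(r.score),
                            Rcpp::Named("cigar") = rle_cigar(r.ops),
                            Rcpp::Named("stats") = stats_to_list(st));
}

// [[Rcpp::export(name = ".cpp_wfa_score")]]
Rcpp::List cpp_wfa_score(std::string q, std::string t, int x, int o, int e,
                         int begin, int end) {
  Pen pen = pen_from(x, o, e);
  Stats st;
  long long s = wfa_score_windowed(q.data(), static_cast<int>(q.size()), t.data(),
                                   static_cast<int>(t.size()), pen,
                                   comp_from_int(begin), comp_from_int(end), st);
  return Rcpp::List::create(Rcpp::Named("score") = static_cast<double>(s),
                            Rcpp::Named("stats") = stats_to_list(st));
}

// Low-level single-step exports used by unit tests -------------------------

// [[Rcpp::export(name = ".cpp_wf_extend_forward")]]
Rcpp::IntegerVector cpp_wf_extend_forward(std::string q, std::string t, int lo,
                                          Rcpp::IntegerVector offsets) {
  int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
  WF w;
  w.c[CM].init(lo, lo + static_cast<int>(offsets.size()) - 1, NULL_F);
  for (int i = 0; i < offsets.size(); ++i)
    if (offsets[i] != NA_INTEGER) w.c[CM].off[static_cast<size_t>(i)] = offsets[i];
  extend_forward(w, q.data(), n, t.data(), m);
  Rcpp::IntegerVector out(offsets.size(), NA_INTEGER);
  for (int i = 0; i < offsets.size(); ++i) {
    int v = w.c[CM].off[static_cast<size_t>(i)];
    if (v != NULL_F) out[i] = v;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_wf_extend_reverse")]]
Rcpp::IntegerVector cpp_wf_extend_reverse(std::string q, std::string t, int lo,
                                          Rcpp::IntegerVector offsets) {
  int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
  WF w;
  w.c[CM].init(lo, lo + static_cast<int>(offsets.size()) - 1, NULL_R);
  for (int i = 0; i < offsets.size(); ++i)
    if (offsets[i] != NA_INTEGER) w.c[CM].off[static_cast<size_t>(i)] = offsets[i];
  extend_reverse(w, q.data(), n, t.data(), m);
  Rcpp::IntegerVector out(offsets.size(), NA_INTEGER);
  for (int i = 0; i < offsets.size(); ++i) {
    int v = w.c[CM].off[static_cast<size_t>(i)];
    if (v != NULL_R) out[i] = v;
  }
  return out;
}

static Rcpp::List band_to_list(const Band& b, int null_v) {
  if (b.empty())
    return Rcpp::List::create(Rcpp::Named("lo") = NA_INTEGER,
                              Rcpp::Named("hi") = NA_INTEGER,
                              Rcpp::Named("offset") = Rcpp::IntegerVector(0));
  Rcpp::IntegerVector off(b.hi - b.lo + 1, NA_INTEGER);
  for (int k = b.lo; k <= b.hi; ++k) {
    int v = b.get(k, null_v);
    if (v != null_v) off[k - b.lo] = v;
  }
  return Rcpp::List::create(Rcpp::Named("lo") = b.lo, Rcpp::Named("hi") = b.hi,
                            Rcpp::Named("offset") = off);
}

static Rcpp::List wf_to_list(const WF& w, int null_v) {
  return Rcpp::List::create(Rcpp::Named("M") = band_to_list(w.c[CM], null_v),
                            Rcpp::Named("I") = band_to_list(w.c[CI], null_v),
                            Rcpp::Named("D") = band_to_list(w.c[CD], null_v));
}

// All forward wavefronts 0..s_final (or up to max_score); for tests of the
// recurrences, monotonicity and base cases.
// [[Rcpp::export(name = ".cpp_wavefronts_forward")]]
Rcpp::List cpp_wavefronts_forward(std::string q, std::string t, int x, int o,
                                  int e, int begin, int end, int max_score) {
  Pen pen = pen_from(x, o, e);
  int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
  Comp bc = comp_from_int(begin), ec = comp_from_int(end);
  std::vector<WF> all;
  auto get = [&](int s) -> const WF* {
    if (s < 0 || s >= static_cast<int>(all.size())) return nullptr;
    return &all[static_cast<size_t>(s)];
  };
  long long cap = score_cap(pen, n, m);
  Rcpp::List out;
  for (int s = 0;; ++s) {
    if (s > cap) Rcpp::stop("wavefront score exceeded its safety bound (internal error)");
    WF w = s == 0 ? base_forward(bc) : next_forward(get, s, pen, n, m);
    extend_forward(w, q.data(), n, t.data(), m);
    all.push_back(std::move(w));
    out.push_back(wf_to_list(all.back(), NULL_F));
    if (end_reached(all.back(), ec, n, m, NULL_F)) break;
    if (max_score >= 0 && s >= max_score) break;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_wavefronts_reverse")]]
Rcpp::List cpp_wavefronts_reverse(std::string q, std::string t, int x, int o,
                                  int e, int begin, int end, int max_score) {
  Pen pen = pen_from(x, o, e);
  int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
  Comp bc = comp_from_int(begin), ec = comp_from_int(end);
  std::vector<WF> all;
  auto get = [&](int s) -> const WF* {
    if (s < 0 || s >= static_cast<int>(all.size())) return nullptr;
    return &all[static_cast<size_t>(s)];
  };
  long long cap = score_cap(pen, n, m);
  Rcpp::List out;
  for (int s = 0;; ++s) {
    if (s > cap) Rcpp::stop("wavefront score exceeded its safety bound (internal error)");
    WF w = s == 0 ? base_reverse(ec, n, m) : next_reverse(get, s, pen, n, m);
    extend_reverse(w, q.data(), n, t.data(), m);
    seed_reverse_end(w, s, pen, ec, n, m);
    all.push_back(std::move(w));
    out.push_back(wf_to_list(all.back(), NULL_R));
    // The reverse search reaches the alignment start at the begin component.
    int off = all.back().c[bc].get(0, NULL_R);
    if (off != NULL_R && off <= 0) break;
    if (max_score >= 0 && s >= max_score) break;
  }
  return out;
}
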