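// Shared types for the wavefront engines (forward/reverse WFA, BiWFA).
// The Gotoh oracle in gotoh.cpp deliberately does NOT use this header.
#pragma once

#include <algorithm>
#include <climits>
#include <cstddef>
#include <string>
#include <vector>

namespace wfa {

// Unreachable sentinels: strictly outside any legal offset range.
constexpr int NULL_F = INT_MIN / 2;  // forward direction (offsets maximised)
constexpr int NULL_R = INT_MAX / 2;  // reverse direction (offsets minimised)

// Wavefront components. CI advances the text only (diagonal k-1 -> k at
// offset+1); CD advances the query only (k+1 -> k, same offset). The
// CIGAR mapping to SAM-style I/D ops lives in comp_to_cigar_op() below.
enum Comp { CM = 0, CI = 1, CD = 2 };

struct Pen {
  int x, o, e;
  int scope() const { return std::max(x, o + e); }
};

// One component of a wavefront: offsets over the diagonal range [lo, hi].
struct Band {
  int lo = 0, hi = -1;
  std::vector<int> off;

  bool empty() const { return hi < lo; }
  int get(int k, int null_v) const {
    return (k < lo || k > hi) ? null_v : off[k - lo];
  }
  void init(int lo_, int hi_, int null_v) {
    lo = lo_;
    hi = hi_;
    off.assign(hi < lo ? 0 : static_cast<size_t>(hi - lo + 1), null_v);
    if (hi < lo) { lo = 0; hi = -1; }
  }
  void set(int k, int v) { off[k - lo] = v; }
  // Drop unreachable diagonals at both ends (keeps ranges tight on
  // degenerate inputs).
  void trim(int null_v) {
    while (lo <= hi && off[hi - lo] == null_v) --hi;
    int drop = 0;
    while (lo + drop <= hi && off[drop] == null_v) ++drop;
    if (hi < lo + drop) {
      off.clear();
      lo = 0;
      hi = -1;
    } else {
      if (drop > 0) off.erase(off.begin(), off.begin() + drop);
      lo += drop;
      off.resize(static_cast<size_t>(hi - lo + 1));
    }
  }
  size_t cells() const { return off.size(); }
};

// A full wavefront W_s = (M, I, D) for one score in one direction.
struct WF {
  Band c[3];
  size_t cells() const { return c[0].cells() + c[1].cells() + c[2].cells(); }
  bool empty() const { return c[0].empty() && c[1].empty() && c[2].empty(); }
};

// Ring buffer retaining the last scope+1 wavefronts of one direction:
// the O(s)-space working set of the bidirectional search.
struct Ring {
  int p;
  std::vector<WF> buf;
  std::vector<int> sc;

  explicit Ring(int p_) : p(p_), buf(static_cast<size_t>(p_ + 1)), sc(static_cast<size_t>(p_ + 1), -1) {}

  void put(int s, WF&& w) {
    size_t i = static_cast<size_t>(s % (p + 1));
    buf[i] = std::move(w);
    sc[i] = s;
  }
  // Scores older than the retained window look absent; the recurrences
  // only ever reach back scope scores, so a miss here means "unreachable".
  const WF* get(int s) const {
    if (s < 0) return nullptr;
    size_t i = static_cast<size_t>(s % (p + 1));
    return sc[i] == s ? &buf[i] : nullptr;
  }
  size_t cells() const {
    size_t t = 0;
    for (const auto& w : buf) t += w.cells();
    return t;
  }
  int live() const {
    int t = 0;
    for (int s : sc)
      if (s >= 0) ++t;
    return t;
  }
};

// Instrumentation counters (cheap, always on).
struct Stats {
  long long cells_computed = 0;
  long long peak_live_cells = 0;
  int peak_live_wavefronts = 0;  // per direction
  long long overlap_calls = 0;
  long long overlap_skipped = 0;
  int max_depth = 0;
  int fallbacks = 0;
};

// The single place where wavefront components become CIGAR ops.
// CI consumes text only -> 'D' (deletion from the query, SAM convention
// with the query as the read); CD consumes query only -> 'I'.
inline char comp_to_cigar_op(Comp c) { return c == CI ? 'D' : 'I'; }

// Run-length encode an expanded op string ("==XX" -> "2=2X").
inline std::string rle_cigar(const std::string& ops) {
  std::string out;
  size_t i = 0;
  while (i < ops.size()) {
    size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out += ops[i];
    i = j;
  }
  return out;
}

// Gap-affine score of an expanded op string. A leading gap run whose op
// matches `begin` waives the gap-open o: a sub-alignment that starts
// inside a gap has the open accounted for on the other side of the
// breakpoint. A trailing gap of an end-at-I/D sub-alignment keeps its
// open (the piece containing a gap's start pays its open).
inline long long score_of_ops(const std::string& ops, const Pen& pen,
                              Comp begin = CM) {
  long long s = 0;
  size_t nops = ops.size();
  size_t i = 0;
  while (i < nops) {
    size_t j = i;
    while (j < nops && ops[j] == ops[i]) ++j;
    long long len = static_cast<long long>(j - i);
    char op = ops[i];
    if (op == 'X') {
      s += len * pen.x;
    } else if (op == 'I' || op == 'D') {
      s += pen.o + len * pen.e;
      if (i == 0 && begin != CM && comp_to_cigar_op(begin) == op) s -= pen.o;
    }
    i = j;
  }
  return s;
}

}  // namespace wfa
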