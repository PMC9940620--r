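// Wavefront step primitives shared by the unidirectional engine and the
// bidirectional search: legality clamps, LCP/LCS extension, the next-
// wavefront recurrences, base cases and the full/windowed drivers.
#pragma once

#include <Rcpp.h>

#include "wfa_core.h"

namespace wfa {

// Forward offsets grow; a computed offset that would leave the matrix is
// clamped to the boundary cell of its diagonal, which is always reachable
// with at most the same score (the farthest-reaching predecessor may sit
// pinned on the boundary while a cell behind it on the same diagonal
// continues the alignment). Cell is (v, h) = (offset - k, offset),
// v in [0,n], h in [0,m].
inline int fclamp(int v, int k, int n, int m) {
  if (v == NULL_F) return NULL_F;
  return std::min(v, std::min(m, n + k));
}
// Reverse offsets shrink; clamp to the first cell of the diagonal.
inline int rclamp(int v, int k, int n, int m) {
  (void)n;
  (void)m;
  if (v == NULL_R) return NULL_R;
  return std::max(v, std::max(0, k));
}

inline int max3(int a, int b, int c) { return std::max(a, std::max(b, c)); }
inline int min3(int a, int b, int c) { return std::min(a, std::min(b, c)); }

void extend_forward(WF& w, const char* q, int n, const char* t, int m);
void extend_reverse(WF& w, const char* q, int n, const char* t, int m);
WF base_forward(Comp begin);
WF base_reverse(Comp end, int n, int m);
void seed_reverse_end(WF& w, int s, const Pen& pen, Comp end, int n, int m);
long long score_cap(const Pen& pen, int n, int m);
bool end_reached(const WF& w, Comp end, int n, int m, int null_v);

// Compute W_s from W_{s-x}, W_{s-e}, W_{s-o-e}:
//   I_{s,k} = max(M_{s-o-e,k-1}+1, I_{s-e,k-1}+1)
//   D_{s,k} = max(M_{s-o-e,k+1},   D_{s-e,k+1})
//   X_{s,k} = max(M_{s-x,k}+1, I_{s,k}, D_{s,k})
// X is materialised transiently into the M band; the caller extends it.
template <class Get>
WF next_forward(Get&& get, int s, const Pen& pen, int n, int m) {
  const WF* wx = get(s - pen.x);
  const WF* we = get(s - pen.e);
  const WF* wo = get(s - pen.o - pen.e);
  const Band* mo = wo ? &wo->c[CM] : nullptr;
  const Band* mx = wx ? &wx->c[CM] : nullptr;
  const Band* ie = we ? &we->c[CI] : nullptr;
  const Band* de = we ? &we->c[CD] : nullptr;

  WF out;
  int ilo = INT_MAX, ihi = INT_MIN;
  if (mo && !mo->empty()) { ilo = std::min(ilo, mo->lo + 1); ihi = std::max(ihi, mo->hi + 1); }
  if (ie && !ie->empty()) { ilo = std::min(ilo, ie->lo + 1); ihi = std::max(ihi, ie->hi + 1); }
  int dlo = INT_MAX, dhi = INT_MIN;
  if (mo && !mo->empty()) { dlo = std::min(dlo, mo->lo - 1); dhi = std::max(dhi, mo->hi - 1); }
  if (de && !de->empty()) { dlo = std::min(dlo, de->lo - 1); dhi = std::max(dhi, de->hi - 1); }
  int xlo = std::min(ilo, dlo), xhi = std::max(ihi, dhi);
  if (mx && !mx->empty()) { xlo = std::min(xlo, mx->lo); xhi = std::max(xhi, mx->hi); }

  // Diagonals outside [-n, m] can never hold a legal cell.
  ilo = std::max(ilo, -n); ihi = std::min(ihi, m);
  dlo = std::max(dlo, -n); dhi = std::min(dhi, m);
  xlo = std::max(xlo, -n); xhi = std::min(xhi, m);

  if (ilo <= ihi) {
    out.c[CI].init(ilo, ihi, NULL_F);
    for (int k = ilo; k <= ihi; ++k) {
      int a = mo ? mo->get(k - 1, NULL_F) : NULL_F;
      int b = ie ? ie->get(k - 1, NULL_F) : NULL_F;
      if (a != NULL_F) ++a;
      if (b != NULL_F) ++b;
      out.c[CI].set(k, fclamp(std::max(a, b), k, n, m));
    }
    out.c[CI].trim(NULL_F);
  }
  if (dlo <= dhi) {
    out.c[CD].init(dlo, dhi, NULL_F);
    for (int k = dlo; k <= dhi; ++k) {
      int a = mo ? mo->get(k + 1, NULL_F) : NULL_F;
      int b = de ? de->get(k + 1, NULL_F) : NULL_F;
      out.c[CD].set(k, fclamp(std::max(a, b), k, n, m));
    }
    out.c[CD].trim(NULL_F);
  }
  if (xlo <= xhi) {
    out.c[CM].init(xlo, xhi, NULL_F);
    for (int k = xlo; k <= xhi; ++k) {
      int a = mx ? mx->get(k, NULL_F) : NULL_F;
      if (a != NULL_F) a = fclamp(a + 1, k, n, m);
      int x = max3(a, out.c[CI].get(k, NULL_F), out.c[CD].get(k, NULL_F));
      out.c[CM].set(k, x);
    }
    out.c[CM].trim(NULL_F);
  }
  return out;
}

// Mirror of next_forward with min in place of max:
//   I_{s,k} = min(M_{s-o-e,k+1}-1, I_{s-e,k+1}-1)
//   D_{s,k} = min(M_{s-o-e,k-1},   D_{s-e,k-1})
//   X_{s,k} = min(M_{s-x,k}-1, I_{s,k}, D_{s,k})
template <class Get>
WF next_reverse(Get&& get, int s, const Pen& pen, int n, int m) {
  const WF* wx = get(s - pen.x);
  const WF* we = get(s - pen.e);
  const WF* wo = get(s - pen.o - pen.e);
  const Band* mo = wo ? &wo->c[CM] : nullptr;
  const Band* mx = wx ? &wx->c[CM] : nullptr;
  const Band* ie = we ? &we->c[CI] : nullptr;
  const Band* de = we ? &we->c[CD] : nullptr;

  WF out;
  int ilo = INT_MAX, ihi = INT_MIN;
  if (mo && !mo->empty()) { ilo = std::min(ilo, mo->lo - 1); ihi = std::max(ihi, mo->hi - 1); }
  if (ie && !ie->empty()) { ilo = std::min(ilo, ie->lo - 1); ihi = std::max(ihi, ie->hi - 1); }
  int dlo = INT_MAX, dhi = INT_MIN;
  if (mo && !mo->empty()) { dlo = std::min(dlo, mo->lo + 1); dhi = std::max(dhi, mo->hi + 1); }
  if (de && !de->empty()) { dlo = std::min(dlo, de->lo + 1); dhi = std::max(dhi, de->hi + 1); }
  int xlo = std::min(ilo, dlo), xhi = std::max(ihi, dhi);
  if (mx && !mx->empty()) { xlo = std::min(xlo, mx->lo); xhi = std::max(xhi, mx->hi); }

  ilo = std::max(ilo, -n); ihi = std::min(ihi, m);
  dlo = std::max(dlo, -n); dhi = std::min(dhi, m);
  xlo = std::max(xlo, -n); xhi = std::min(xhi, m);

  if (ilo <= ihi) {
    out.c[CI].init(ilo, ihi, NULL_R);
    for (int k = ilo; k <= ihi; ++k) {
      int a = mo ? mo->get(k + 1, NULL_R) : NULL_R;
      int b = ie ? ie->get(k + 1, NULL_R) : NULL_R;
      if (a != NULL_R) --a;
      if (b != NULL_R) --b;
      out.c[CI].set(k, rclamp(std::min(a, b), k, n, m));
    }
    out.c[CI].trim(NULL_R);
  }
  if (dlo <= dhi) {
    out.c[CD].init(dlo, dhi, NULL_R);
    for (int k = dlo; k <= dhi; ++k) {
      int a = mo ? mo->get(k - 1, NULL_R) : NULL_R;
      int b = de ? de->get(k - 1, NULL_R) : NULL_R;
      out.c[CD].set(k, rclamp(std::min(a, b), k, n, m));
    }
    out.c[CD].trim(NULL_R);
  }
  if (xlo <= xhi) {
    out.c[CM].init(xlo, xhi, NULL_R);
    for (int k = xlo; k <= xhi; ++k) {
      int a = mx ? mx->get(k, NULL_R) : NULL_R;
      if (a != NULL_R) a = rclamp(a - 1, k, n, m);
      int x = min3(a, out.c[CI].get(k, NULL_R), out.c[CD].get(k, NULL_R));
      out.c[CM].set(k, x);
    }
    out.c[CM].trim(NULL_R);
  }
  return out;
}

struct FullResult {
  long long score = 0;
  std::string ops;  // expanded op string over {=, X, I, D}
};

FullResult wfa_full(const char* q, int n, const char* t, int m, const Pen& pen,
                    Comp begin, Comp end, bool keep_traceback, Stats& st);
long long wfa_score_windowed(const char* q, int n, const char* t, int m,
                             const Pen& pen, Comp begin, Comp end, Stats& st);

Comp comp_from_int(int c);
Pen pen_from(int x, int o, int e);
Rcpp::List stats_to_list(const Stats& st);

}  // namespace wfa
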