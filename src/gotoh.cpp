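// Independent ground-truth aligner: the classical Gotoh three-matrix
// dynamic program for gap-affine penalties, O(nm) time and memory.
// Deliberately self-contained — it shares no code with the wavefront
// engines so that agreement between the two is meaningful evidence.
//
// States: M ends in a match/mismatch (or a gap closed at no extra cost),
// I ends in a text-consuming gap column (CIGAR 'D'), D ends in a
// query-consuming gap column (CIGAR 'I'). Begin/end components follow the
// same semantics as the wavefront engines: beginning at I or D means the
// gap open is already paid; ending at I or D selects that matrix at (n,m).
#include <Rcpp.h>

#include <string>
#include <vector>

namespace {

const int INF = INT_MAX / 4;

struct Tables {
  int n, m;
  std::vector<int> M, I, D;  // (n+1) x (m+1), row-major
  int& at(std::vector<int>& T, int i, int j) { return T[static_cast<size_t>(i) * (m + 1) + j]; }
};

int comp_code(const std::string& c) {
  if (c == "M") return 0;
  if (c == "I") return 1;
  if (c == "D") return 2;
  Rcpp::stop("component must be \"M\", \"I\" or \"D\"");
}

Tables fill_tables(const std::string& q, const std::string& t, int x, int o,
                   int e, int begin) {
  int n = static_cast<int>(q.size()), m = static_cast<int>(t.size());
  Tables tb;
  tb.n = n;
  tb.m = m;
  tb.M.assign(static_cast<size_t>(n + 1) * (m + 1), INF);
  tb.I.assign(static_cast<size_t>(n + 1) * (m + 1), INF);
  tb.D.assign(static_cast<size_t>(n + 1) * (m + 1), INF);

  if (begin == 0) tb.at(tb.M, 0, 0) = 0;
  if (begin == 1) tb.at(tb.I, 0, 0) = 0;
  if (begin == 2) tb.at(tb.D, 0, 0) = 0;
  // closing a zero-length boundary gap is free
  tb.at(tb.M, 0, 0) =
      std::min(tb.at(tb.M, 0, 0), std::min(tb.at(tb.I, 0, 0), tb.at(tb.D, 0, 0)));

  for (int j = 1; j <= m; ++j) {
    int open = tb.at(tb.M, 0, j - 1) >= INF ? INF : tb.at(tb.M, 0, j - 1) + o + e;
    int ext = tb.at(tb.I, 0, j - 1) >= INF ? INF : tb.at(tb.I, 0, j - 1) + e;
    tb.at(tb.I, 0, j) = std::min(open, ext);
    tb.at(tb.M, 0, j) = tb.at(tb.I, 0, j);
  }
  for (int i = 1; i <= n; ++i) {
    int open = tb.at(tb.M, i - 1, 0) >= INF ? INF : tb.at(tb.M, i - 1, 0) + o + e;
    int ext = tb.at(tb.D, i - 1, 0) >= INF ? INF : tb.at(tb.D, i - 1, 0) + e;
    tb.at(tb.D, i, 0) = std::min(open, ext);
    tb.at(tb.M, i, 0) = tb.at(tb.D, i, 0);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int iopen = tb.at(tb.M, i, j - 1) >= INF ? INF : tb.at(tb.M, i, j - 1) + o + e;
      int iext = tb.at(tb.I, i, j - 1) >= INF ? INF : tb.at(tb.I, i, j - 1) + e;
      tb.at(tb.I, i, j) = std::min(iopen, iext);
      int dopen = tb.at(tb.M, i - 1, j) >= INF ? INF : tb.at(tb.M, i - 1, j) + o + e;
      int dext = tb.at(tb.D, i - 1, j) >= INF ? INF : tb.at(tb.D, i - 1, j) + e;
      tb.at(tb.D, i, j) = std::min(dopen, dext);
      int sub = q[static_cast<size_t>(i - 1)] == t[static_cast<size_t>(j - 1)] ? 0 : x;
      int diag = tb.at(tb.M, i - 1, j - 1) >= INF ? INF : tb.at(tb.M, i - 1, j - 1) + sub;
      tb.at(tb.M, i, j) =
          std::min(diag, std::min(tb.at(tb.I, i, j), tb.at(tb.D, i, j)));
    }
  }
  return tb;
}

std::string rle(const std::string& ops) {
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

}  // namespace

// [[Rcpp::export(name = ".cpp_gotoh_align")]]
Rcpp::List cpp_gotoh_align(std::string q, std::string t, int x, int o, int e,
                           std::string begin, std::string end) {
  if (x <= 0 || e <= 0 || o < 0) Rcpp::stop("penalties require x > 0, e > 0, o >= 0");
  int bc = comp_code(begin), ec = comp_code(end);
  Tables tb = fill_tables(q, t, x, o, e, bc);
  int n = tb.n, m = tb.m;
  int score = ec == 0 ? tb.at(tb.M, n, m) : (ec == 1 ? tb.at(tb.I, n, m) : tb.at(tb.D, n, m));
  if (score >= INF)
    Rcpp::stop("no alignment satisfies the requested boundary components");

  // Traceback; ties prefer the diagonal move, then I, then D.
  std::string ops;
  int i = n, j = m, st = ec;
  while (true) {
    if (st == 0) {
      if (i == 0 && j == 0) {
        if (bc == 0) break;
        if (bc == 1 && tb.at(tb.M, 0, 0) == tb.at(tb.I, 0, 0)) { st = 1; continue; }
        if (bc == 2 && tb.at(tb.M, 0, 0) == tb.at(tb.D, 0, 0)) { st = 2; continue; }
        Rcpp::stop("oracle traceback lost at the origin (internal error)");
      }
      int cur = tb.at(tb.M, i, j);
      if (i > 0 && j > 0) {
        int sub = q[static_cast<size_t>(i - 1)] == t[static_cast<size_t>(j - 1)] ? 0 : x;
        if (tb.at(tb.M, i - 1, j - 1) < INF && tb.at(tb.M, i - 1, j - 1) + sub == cur) {
          ops.push_back(sub == 0 ? '=' : 'X');
          --i;
          --j;
          continue;
        }
      }
      if (cur == tb.at(tb.I, i, j)) { st = 1; continue; }
      if (cur == tb.at(tb.D, i, j)) { st = 2; continue; }
      Rcpp::stop("oracle traceback lost in M (internal error)");
    } else if (st == 1) {
      if (i == 0 && j == 0 && bc == 1) break;
      int cur = tb.at(tb.I, i, j);
      ops.push_back('D');  // text-consuming gap column
      if (tb.at(tb.M, i, j - 1) < INF && tb.at(tb.M, i, j - 1) + o + e == cur)
        st = 0;
      --j;
    } else {
      if (i == 0 && j == 0 && bc == 2) break;
      int cur = tb.at(tb.D, i, j);
      ops.push_back('I');  // query-consuming gap column
      if (tb.at(tb.M, i - 1, j) < INF && tb.at(tb.M, i - 1, j) + o + e == cur)
        st = 0;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return Rcpp::List::create(Rcpp::Named("score") = static_cast<double>(score),
                            Rcpp::Named("cigar") = rle(ops));
}

// [[Rcpp::export(name = ".cpp_gotoh_matrices")]]
Rcpp::List cpp_gotoh_matrices(std::string q, std::string t, int x, int o,
                              int e, std::string begin) {
  if (x <= 0 || e <= 0 || o < 0) Rcpp::stop("penalties require x > 0, e > 0, o >= 0");
  Tables tb = fill_tables(q, t, x, o, e, comp_code(begin));
  int n = tb.n, m = tb.m;
  auto to_mat = [&](std::vector<int>& T) {
    Rcpp::IntegerMatrix M(n + 1, m + 1);
    for (int i = 0; i <= n; ++i)
      for (int j = 0; j <= m; ++j) {
        int v = tb.at(T, i, j);
        M(i, j) = v >= INF ? NA_INTEGER : v;
      }
    return M;
  };
  return Rcpp::List::create(Rcpp::Named("M") = to_mat(tb.M),
                            Rcpp::Named("I") = to_mat(tb.I),
                            Rcpp::Named("D") = to_mat(tb.D));
}
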