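#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// End-to-end affine-gap alignment of amplicon reads against one reference,
// with traceback to gapped strings. Gap of length k costs open + k * ext
// (both positive). Tie-break during traceback: diagonal, then deletion
// (gap in the read), then insertion — deterministic; indel events are
// left-normalized downstream, so pattern identity does not depend on it.

static const int NEG = -(1 << 28);

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(CharacterVector reads, std::string ref,
                    double match, double mismatch,
                    double gap_open, double gap_ext) {
  const int m = ref.size();
  const int sm = (int)(match * 2), sx = (int)(mismatch * 2);
  const int go = (int)(gap_open * 2), ge = (int)(gap_ext * 2);
  int nr = reads.size();
  CharacterVector out_p(nr), out_s(nr);
  NumericVector out_score(nr);

  for (int r = 0; r < nr; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int n = read.size();
    // state matrices: 0 = M (diag), 1 = X (gap in read, consumes ref),
    // 2 = Y (gap in ref, consumes read)
    std::vector<int> M((n + 1) * (m + 1), NEG), X(M), Y(M);
    auto at = [m](int i, int j) { return i * (m + 1) + j; };
    M[at(0, 0)] = 0;
    for (int j = 1; j <= m; ++j) X[at(0, j)] = -(go + j * ge);
    for (int i = 1; i <= n; ++i) Y[at(i, 0)] = -(go + i * ge);
    for (int i = 1; i <= n; ++i) {
      char rc = read[i - 1];
      for (int j = 1; j <= m; ++j) {
        bool ok = rc == ref[j - 1] && rc != 'N';
        int s = ok ? sm : sx;
        int d = std::max(M[at(i - 1, j - 1)],
                         std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
        if (d > NEG) M[at(i, j)] = d + s;
        int x = std::max(M[at(i, j - 1)] - go - ge,
                         std::max(X[at(i, j - 1)] - ge,
                                  Y[at(i, j - 1)] - go - ge));
        if (x > NEG / 2) X[at(i, j)] = x;
        int y = std::max(M[at(i - 1, j)] - go - ge,
                         std::max(X[at(i - 1, j)] - go - ge,
                                  Y[at(i - 1, j)] - ge));
        if (y > NEG / 2) Y[at(i, j)] = y;
      }
    }
    int i = n, j = m, st;
    int best = std::max(M[at(n, m)], std::max(X[at(n, m)], Y[at(n, m)]));
    st = (M[at(n, m)] == best) ? 0 : (X[at(n, m)] == best ? 1 : 2);
    out_score[r] = best / 2.0;
    std::string ap, as_;
    ap.reserve(n + m); as_.reserve(n + m);
    while (i > 0 || j > 0) {
      if (st == 0) {
        ap.push_back(read[i - 1]); as_.push_back(ref[j - 1]);
        bool ok = read[i - 1] == ref[j - 1] && read[i - 1] != 'N';
        int s = ok ? sm : sx;
        int v = M[at(i, j)] - s;
        --i; --j;
        if (i == 0 && j == 0) break;
        st = (M[at(i, j)] == v) ? 0 : (X[at(i, j)] == v ? 1 : 2);
      } else if (st == 1) {
        ap.push_back('-'); as_.push_back(ref[j - 1]);
        int v = X[at(i, j)];
        --j;
        if (X[at(i, j)] == v + ge) st = 1;
        else if (M[at(i, j)] == v + go + ge) st = 0;
        else st = 2;
      } else {
        ap.push_back(read[i - 1]); as_.push_back('-');
        int v = Y[at(i, j)];
        --i;
        if (Y[at(i, j)] == v + ge) st = 2;
        else if (M[at(i, j)] == v + go + ge) st = 0;
        else st = 1;
      }
    }
    std::reverse(ap.begin(), ap.end());
    std::reverse(as_.begin(), as_.end());
    out_p[r] = ap; out_s[r] = as_;
  }
  return List::create(_["pattern"] = out_p, _["subject"] = out_s,
                      _["score"] = out_score);
}
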