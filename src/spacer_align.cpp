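#include <Rcpp.h>
using namespace Rcpp;

// Off-target candidate evaluation: constrained global alignment of a spacer
// against PAM-anchored genomic windows, with exact counts of DNA bulges
// (extra protospacer base = gap in the spacer) and RNA bulges (skipped
// spacer base = gap in the protospacer). Bulges are internal only: never
// before the first or after the last spacer base, and a spacer end base is
// never skipped. The canonical alignment minimizes, lexicographically,
// (mismatches + bulge bases, bulge bases, DNA-bulge bases, sum of bulge
// positions); within a fixed (d, r) this reduces to minimizing
// mm * 64 + position-sum, which the DP tracks as a single additive value.

static const int BIG = 1 << 28;

// IUPAC bitmasks; an unknown genome base (N or other) matches only a rule 'N'.
static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4;
    case 'W': return 1|8; case 'K': return 4|8; case 'M': return 1|2;
    case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8;
    case 'V': return 1|2|4; case 'N': return 1|2|4|8;
    default: return 0;
  }
}
static int base_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
    default: return 0; // N or anything else: concrete-base mask empty
  }
}

// 0-based start positions (of the PAM) at which `rule` matches `genome`.
// A genome N fails every class except the rule's own N.
// [[Rcpp::export(name = ".pam_scan_cpp")]]
IntegerVector pam_scan_cpp(std::string genome, std::string rule) {
  int n = genome.size(), p = rule.size();
  std::vector<int> hits;
  for (int a = 0; a + p <= n; ++a) {
    bool ok = true;
    for (int k = 0; k < p; ++k) {
      char g = genome[a + k], r = rule[k];
      if (g == 'N' || base_mask(g) == 0) {
        if (r != 'N') { ok = false; break; }
      } else if (!(base_mask(g) & iupac_mask(r))) { ok = false; break; }
    }
    if (ok) hits.push_back(a);
  }
  return wrap(hits);
}

// DP for one window with exactly one contiguous bulge of `nb` bases
// (dna_bulge selects the type; nb == 0 means ungapped). The flag dimension
// enforces contiguity: 0 = bulge not started, 1 = bulge in progress,
// 2 = bulge closed. Returns mm*64 + possum, or BIG when no layout exists.
static int window_dp(const std::string& g, int p, int glen,
                     const std::string& s, int L, int nb, bool dna_bulge) {
  int W = L + (dna_bulge ? nb : -nb);
  if (W < 1 || p + W > glen) return BIG;
  int val[31][3][3];  // [spacer consumed][bulge bases used][flag]
  for (int i = 0; i <= L; ++i)
    for (int b = 0; b <= nb; ++b)
      for (int f = 0; f < 3; ++f) val[i][b][f] = BIG;
  val[0][0][0] = 0;
  for (int i = 0; i <= L; ++i) {
    for (int b = 0; b <= nb; ++b) {
      for (int f = 0; f < 3; ++f) {
        int v = val[i][b][f];
        if (v >= BIG) continue;
        int j = i + (dna_bulge ? b : -b); // window bases consumed
        // diagonal (closes an open bulge)
        if (i < L && j >= 0 && j < W) {
          char gc = g[p + j];
          int mm = (base_mask(gc) && gc == s[i]) ? 0 : 1;
          int nf = (f == 1) ? 2 : f;
          int& t = val[i + 1][b][nf];
          if (v + 64 * mm < t) t = v + 64 * mm;
        }
        // extend/open the bulge (internal only, contiguous)
        if (b < nb && f != 2) {
          if (dna_bulge) {
            // extra window base after spacer base i
            if (j < W && i >= 1 && i <= L - 1) {
              int& t = val[i][b + 1][1];
              if (v + i < t) t = v + i;
            }
          } else {
            // skip spacer base i+1 (1-based)
            if (i >= 1 && i <= L - 2) {
              int& t = val[i + 1][b + 1][1];
              if (v + (i + 1) < t) t = v + (i + 1);
            }
          }
        }
      }
    }
  }
  int best = val[L][nb][nb == 0 ? 0 : 2];
  return best;
}

// For each PAM-anchored protospacer start, the canonical best feasible
// alignment across all (d, r) with d + r <= max_bulge and mm <= max_mm.
// [[Rcpp::export(name = ".spacer_align_anchors_cpp")]]
DataFrame spacer_align_anchors_cpp(std::string genome, IntegerVector proto_starts,
                                   std::string spacer, int max_mm, int max_bulge) {
  int glen = genome.size(), L = spacer.size(), n = proto_starts.size();
  if (L < 1 || L > 30) stop("spacer length must be within 1..30");
  if (max_bulge > 2) stop("bulge budgets above 2 are not supported");
  LogicalVector feasible(n);
  IntegerVector mm(n), dbu(n), rbu(n), span(n), possum(n);
  for (int k = 0; k < n; ++k) {
    int p = proto_starts[k];
    int best = BIG, bmm = NA_INTEGER, bd = 0, br = 0, bps = 0;
    for (int nb = 0; nb <= max_bulge; ++nb) {
      for (int type = 0; type < (nb == 0 ? 1 : 2); ++type) {
        bool dna = type == 0;
        int d = dna ? nb : 0, r = dna ? 0 : nb;
        int v = window_dp(genome, p, glen, spacer, L, nb, dna);
        if (v >= BIG) continue;
        int vm = v >> 6, ps = v & 63;
        if (vm > max_mm) continue;
        int cost = vm + nb;
        int score = (((cost * 64) + nb) * 8 + d) * 64 + ps;
        if (score < best) {
          best = score; bmm = vm; bd = d; br = r; bps = ps;
        }
      }
    }
    feasible[k] = best < BIG;
    mm[k] = bmm; dbu[k] = bd; rbu[k] = br; possum[k] = bps;
    span[k] = L + bd - br;
  }
  return DataFrame::create(_["proto_start"] = proto_starts,
                           _["feasible"] = feasible, _["mismatches"] = mm,
                           _["dna_bulge"] = dbu, _["rna_bulge"] = rbu,
                           _["span"] = span, _["possum"] = possum);
}
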