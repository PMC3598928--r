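#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Cost sentinel for pruned / unreachable cells.  Large enough that one more
// addition cannot overflow an int, absorbing in practice because every
// increment is <= 1 and matrices are < 2^20 cells.
static const int BIG = 1 << 28;

static inline int addc(int a, int b) { return (a >= BIG) ? BIG : a + b; }

// Banded semi-global Needleman-Wunsch with unit costs.
// Conventions (shared with the block engine so the two routes agree):
//   S(0,j) = j   leading read gaps (insertions) are charged,
//   S(i,0) = i   leading reference gaps are charged inside the window,
//   result  = min over the last column j = n, rows i in 1..m (within band):
//             trailing reference bases are free (semi-global).
// band < 0 disables the band (full matrix).
// [[Rcpp::export]]
List nw_band_cpp(IntegerVector read, IntegerVector ref, int band) {
  const int n = read.size(), m = ref.size();
  if (n < 1) stop("empty read");
  if (m < 1) stop("empty reference window");
  const bool banded = band >= 0;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int i = 0; i <= m; ++i)
    prev[i] = (banded && i > band) ? BIG : i;
  for (int j = 1; j <= n; ++j) {
    const int lo = banded ? std::max(1, j - band) : 1;
    const int hi = banded ? std::min(m, j + band) : m;
    for (int i = 0; i <= m; ++i) cur[i] = BIG;
    cur[0] = j;  // boundary row S(0,j) = j
    for (int i = lo; i <= hi; ++i) {
      const int dlt = (ref[i - 1] == read[j - 1]) ? 0 : 1;
      int best = BIG;
      best = std::min(best, addc(prev[i - 1], dlt));  // diagonal
      best = std::min(best, addc(prev[i], 1));        // read gap (insertion)
      best = std::min(best, addc(cur[i - 1], 1));     // reference gap (deletion)
      cur[i] = best;
    }
    std::swap(prev, cur);
  }
  int bestScore = BIG, bestRow = NA_INTEGER;
  const int lo = banded ? std::max(1, n - band) : 1;
  const int hi = banded ? std::min(m, n + band) : m;
  for (int i = lo; i <= hi; ++i)
    if (prev[i] < bestScore) { bestScore = prev[i]; bestRow = i; }
  return List::create(
      _["score"] = (bestScore >= BIG) ? R_PosInf : (double)bestScore,
      _["ref_end"] = bestRow);
}

// One column step of the band-diagonal state machine.  State s = (u, m, l)
// holds the best path costs at cells (j-1, j), (j, j), (j+1, j).
// j is the 1-based read column, m_ref the reference window length.
// initial == true marks the block that starts at read column 1, where the
// u cell of column 1 is the DP boundary S(0,1) reached by a charged
// insertion (no diagonal predecessor exists there).
static inline void block_step(int s[3], int j, const int *read, int n,
                              const int *ref, int m_ref, bool initial) {
  const int iu = j - 1, im = j, il = j + 1;
  int nu, nm, nl;
  if (iu >= 1 && iu <= m_ref) {
    const int du = (ref[iu - 1] == read[j - 1]) ? 0 : 1;
    nu = std::min(addc(s[0], du), addc(s[1], 1));
  } else if (iu == 0 && initial) {
    nu = addc(s[1], 1);  // boundary S(0,1) = 1
  } else {
    nu = BIG;
  }
  if (im >= 1 && im <= m_ref) {
    const int dm = (ref[im - 1] == read[j - 1]) ? 0 : 1;
    nm = std::min(std::min(addc(s[1], dm), addc(s[2], 1)), addc(nu, 1));
  } else {
    nm = BIG;
  }
  if (il >= 1 && il <= m_ref) {
    const int dl = (ref[il - 1] == read[j - 1]) ? 0 : 1;
    nl = std::min(addc(s[2], dl), addc(nm, 1));
  } else {
    nl = BIG;
  }
  s[0] = nu; s[1] = nm; s[2] = nl;
}

// Initial-segment exit scores: run the boundary DP over read columns
// 1..h_end.  Entry state is the column-0 boundary (x, 0, 1): origin on the
// main diagonal, a charged leading reference gap on the lower one.
static void initial_vector(const int *read, int n, const int *ref, int m_ref,
                           int h_end, int v[3]) {
  v[0] = BIG; v[1] = 0; v[2] = (m_ref >= 1) ? 1 : BIG;
  for (int j = 1; j <= h_end; ++j) block_step(v, j, read, n, ref, m_ref, true);
}

// 3x3 transfer table of one later block spanning read columns j0..j1:
// T[e][x] = best within-block path cost from entry diagonal e (cell at
// column j0-1) to exit diagonal x (cell at column j1).
static void block_transfer(const int *read, int n, const int *ref, int m_ref,
                           int j0, int j1, int T[3][3]) {
  for (int e = 0; e < 3; ++e) {
    int s[3] = {BIG, BIG, BIG};
    s[e] = 0;
    for (int j = j0; j <= j1; ++j) block_step(s, j, read, n, ref, m_ref, false);
    for (int x = 0; x < 3; ++x) T[e][x] = s[x];
  }
}

// Block-decomposed banded alignment.
//   exact mode: min-plus composition of full 3x3 transfer tables; equals
//     the banded DP (band = 1) by construction.
//   heuristic mode: each block is summarised as three exit scores with the
//     set of minimising entry diagonals (the BlockScore summary), and
//     the chain adds the predecessor score of a labelled entry diagonal.
// Scores exceeding `threshold` are pruned to x (Inf).  Increments are
// non-negative, so intermediate pruning never changes a surviving score.
// [[Rcpp::export]]
double block_align_cpp(IntegerVector read, IntegerVector ref, int head_width,
                       int block_width, double threshold, bool exact) {
  const int n = read.size(), m = ref.size();
  if (n < 1) stop("empty read");
  if (block_width < 1) stop("block_width must be >= 1");
  const int thr = (threshold == R_PosInf || threshold >= BIG)
                      ? BIG - 1 : (int)threshold;
  const int *rd = INTEGER(read), *rf = INTEGER(ref);
  int h_end = (head_width > 0) ? std::min(head_width, n)
                               : std::min(block_width, n);
  int v[3];
  initial_vector(rd, n, rf, m, h_end, v);
  for (int x = 0; x < 3; ++x) if (v[x] > thr) v[x] = BIG;
  // labels as bitmasks (bit 0 = u, 1 = m, 2 = l); initial segment starts at
  // the origin, labelled m throughout.
  int lab[3] = {2, 2, 2};
  int j0 = h_end + 1;
  while (j0 <= n) {
    const int j1 = std::min(n, j0 + block_width - 1);
    int T[3][3];
    block_transfer(rd, n, rf, m, j0, j1, T);
    int nv[3], nlab[3];
    for (int x = 0; x < 3; ++x) {
      if (exact) {
        int best = BIG;
        for (int e = 0; e < 3; ++e) best = std::min(best, addc(v[e], T[e][x]));
        nv[x] = best;
        nlab[x] = 0;
      } else {
        // per-exit block score and its entry-diagonal label set
        int bs = BIG, mask = 0;
        for (int e = 0; e < 3; ++e) {
          if (T[e][x] < bs) { bs = T[e][x]; mask = 1 << e; }
          else if (T[e][x] == bs && bs < BIG) mask |= 1 << e;
        }
        if (bs >= BIG) { nv[x] = BIG; nlab[x] = 0; continue; }
        int add = BIG, lmask = 0;
        for (int e = 0; e < 3; ++e) {
          if (!(mask & (1 << e))) continue;
          if (v[e] < add) { add = v[e]; lmask = lab[e]; }
          else if (v[e] == add && add < BIG) lmask |= lab[e];
        }
        nv[x] = addc(bs, add);
        nlab[x] = lmask;
      }
      if (nv[x] > thr) { nv[x] = BIG; nlab[x] = 0; }
    }
    for (int x = 0; x < 3; ++x) { v[x] = nv[x]; lab[x] = nlab[x]; }
    j0 = j1 + 1;
  }
  int best = std::min(std::min(v[0], v[1]), v[2]);
  return (best >= BIG || best > thr) ? R_PosInf : (double)best;
}

// Expose the initial exit triple and the per-block 3x3 transfer tables so
// the R-level concatenation algebra can be cross-checked against this
// engine and composed in arbitrary association orders.
// [[Rcpp::export]]
List block_transfers_cpp(IntegerVector read, IntegerVector ref, int head_width,
                         int block_width) {
  const int n = read.size(), m = ref.size();
  if (n < 1) stop("empty read");
  const int *rd = INTEGER(read), *rf = INTEGER(ref);
  int h_end = (head_width > 0) ? std::min(head_width, n)
                               : std::min(block_width, n);
  int v[3];
  initial_vector(rd, n, rf, m, h_end, v);
  NumericVector init(3);
  for (int x = 0; x < 3; ++x) init[x] = (v[x] >= BIG) ? R_PosInf : v[x];
  List transfers;
  int j0 = h_end + 1;
  while (j0 <= n) {
    const int j1 = std::min(n, j0 + block_width - 1);
    int T[3][3];
    block_transfer(rd, n, rf, m, j0, j1, T);
    NumericMatrix M(3, 3);
    for (int e = 0; e < 3; ++e)
      for (int x = 0; x < 3; ++x)
        M(e, x) = (T[e][x] >= BIG) ? R_PosInf : T[e][x];
    transfers.push_back(M);
    j0 = j1 + 1;
  }
  return List::create(_["initial"] = init, _["transfers"] = transfers);
}

// Plain full-matrix Smith-Waterman local alignment with traceback, used by
// the paired-end mate rescue.  Returns the best local score, the 1-based
// coordinates of the aligned segment on both sequences, and the number of
// matched bases along the optimal path.
// [[Rcpp::export]]
List sw_local_cpp(IntegerVector read, IntegerVector ref, int match,
                  int mismatch, int gap) {
  const int n = read.size(), m = ref.size();
  if (n < 1 || m < 1) stop("empty input");
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> P((size_t)(n + 1) * (m + 1), 0);  // 1 diag 2 up 3 left
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int sc = (ref[i - 1] == read[j - 1]) ? match : mismatch;
      const size_t k = (size_t)i * (n + 1) + j;
      int d = H[k - (n + 1) - 1] + sc;
      int u = H[k - (n + 1)] + gap;
      int l = H[k - 1] + gap;
      int h = std::max(std::max(d, std::max(u, l)), 0);
      H[k] = h;
      P[k] = (h == 0) ? 0 : (h == d ? 1 : (h == u ? 2 : 3));
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, nmatch = 0, ri0 = bi, rj0 = bj;
  while (i > 0 && j > 0) {
    const size_t k = (size_t)i * (n + 1) + j;
    if (P[k] == 0) break;
    if (P[k] == 1) {
      if (ref[i - 1] == read[j - 1]) ++nmatch;
      ri0 = i; rj0 = j; --i; --j;
    } else if (P[k] == 2) {
      ri0 = i; --i;
    } else {
      rj0 = j; --j;
    }
  }
  return List::create(_["score"] = best, _["ref_start"] = ri0,
                      _["ref_end"] = bi, _["read_start"] = rj0,
                      _["read_end"] = bj, _["n_match"] = nmatch);
}
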