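#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Semi-global alignment: the full query must align against any substring of
// the reference (ends-free in the reference only). Affine gaps: a gap run of
// length g costs gap_open + g * gap_ext. Gotoh three-state DP with a
// deterministic traceback:
//   - final column: highest score, ties broken by smallest ref end;
//   - final state: M preferred over query-gap state;
//   - within cells: M > ref-consuming gap (D) > query-consuming gap (I).
// Reported stats (mismatches, max/total indel run length) describe the single
// alignment chosen by this traceback; its score is the true optimum.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_semiglobal_cpp")]]
List align_semiglobal_cpp(std::string q, std::string r,
                          double match, double mismatch,
                          double gap_open, double gap_ext) {
  const int m = (int)q.size(), n = (int)r.size();
  if (m < 1 || n < 1) stop("query and reference must be non-empty");
  const double open1 = gap_open + gap_ext; // cost of the first gap base

  // M[i][j]: q[0..i) vs r[?..j), last op aligns q[i-1] to r[j-1]
  // Ix[i][j]: last op consumes a query base against a gap (insertion in query)
  // Iy[i][j]: last op consumes a ref base against a gap (deletion)
  std::vector<std::vector<double>> M(m + 1, std::vector<double>(n + 1, NEG_INF)),
      Ix(m + 1, std::vector<double>(n + 1, NEG_INF)),
      Iy(m + 1, std::vector<double>(n + 1, NEG_INF));

  for (int j = 0; j <= n; ++j) M[0][j] = 0.0; // free leading reference

  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      // query-consuming gap (vertical)
      double best = M[i - 1][j] - open1;
      double alt = Iy[i - 1][j] - open1;
      if (alt > best) best = alt;
      alt = Ix[i - 1][j] - gap_ext;
      if (alt > best) best = alt;
      Ix[i][j] = best;
      if (j >= 1) {
        // diagonal
        double sub = (q[i - 1] == r[j - 1]) ? match : mismatch;
        double d = M[i - 1][j - 1];
        if (Ix[i - 1][j - 1] > d) d = Ix[i - 1][j - 1];
        if (Iy[i - 1][j - 1] > d) d = Iy[i - 1][j - 1];
        M[i][j] = (d == NEG_INF) ? NEG_INF : d + sub;
        // ref-consuming gap (horizontal); leading deletions are excluded by
        // the ends-free initialization, internal ones start from M/Ix
        best = M[i][j - 1] - open1;
        alt = Ix[i][j - 1] - open1;
        if (alt > best) best = alt;
        alt = Iy[i][j - 1] - gap_ext;
        if (alt > best) best = alt;
        Iy[i][j] = best;
      }
    }
  }

  // ends-free trailing reference: best over columns of M / Ix at row m
  double bestScore = NEG_INF;
  int bestJ = 0, bestState = 0; // 0 = M, 1 = Ix
  for (int j = 0; j <= n; ++j) {
    if (M[m][j] > bestScore) { bestScore = M[m][j]; bestJ = j; bestState = 0; }
    if (Ix[m][j] > bestScore) { bestScore = Ix[m][j]; bestJ = j; bestState = 1; }
  }

  // traceback
  int i = m, j = bestJ, state = bestState;
  int mm = 0;
  const double eps = 1e-9;
  std::string ops;
  while (i > 0) {
    if (state == 0) { // M
      if (q[i - 1] != r[j - 1]) ++mm;
      ops.push_back('M');
      double sub = (q[i - 1] == r[j - 1]) ? match : mismatch;
      double prev = M[i][j] - sub;
      if (std::abs(M[i - 1][j - 1] - prev) < eps) state = 0;
      else if (std::abs(Ix[i - 1][j - 1] - prev) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) { // Ix: query base vs gap
      ops.push_back('I');
      double v = Ix[i][j];
      if (std::abs(M[i - 1][j] - (v + open1)) < eps) state = 0;
      else if (std::abs(Iy[i - 1][j] - (v + open1)) < eps) state = 2;
      else state = 1;
      --i;
    } else { // Iy: ref base vs gap
      ops.push_back('D');
      double v = Iy[i][j];
      if (std::abs(M[i][j - 1] - (v + open1)) < eps) state = 0;
      else if (std::abs(Ix[i][j - 1] - (v + open1)) < eps) state = 1;
      else state = 2;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // gap-run statistics: maximal stretches of a single gap type ('I' or 'D');
  // adjacent runs of different types are distinct runs
  int maxRun = 0, totRun = 0, nRuns = 0, curRun = 0;
  char curOp = 'M';
  for (size_t k = 0; k <= ops.size(); ++k) {
    char c = (k < ops.size()) ? ops[k] : 'M';
    if (c == curOp && c != 'M') {
      ++curRun;
    } else {
      if (curRun > 0) { if (curRun > maxRun) maxRun = curRun; totRun += curRun; ++nRuns; }
      curRun = (c != 'M') ? 1 : 0;
      curOp = c;
    }
  }

  return List::create(
      _["score"] = bestScore,
      _["ref_start"] = j,     // 0-based
      _["ref_end"] = bestJ,   // half-open
      _["mismatches"] = mm,
      _["max_indel_len"] = maxRun,
      _["total_indel_len"] = totRun,
      _["n_gap_runs"] = nRuns,
      _["ops"] = ops);
}
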