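#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap costs.
//
// Scoring: +match per matching column, -mismatch per mismatching column,
// -ins_cost per query base aligned to a gap (extra base in the read),
// -del_cost per target base aligned to a gap (base missing from the read).
// Gap penalty is linear in gap length (no open/extend distinction).
//
// Traceback preference on ties: diagonal > deletion (gap in query) >
// insertion (gap in target); the optimum cell is the first maximum in
// row-major order. Both rules make results deterministic.

struct SWResult {
  int score;
  int q_start, q_end;   // 0-based half-open on query
  int t_start, t_end;   // 0-based half-open on target
  int matches, mismatches, insertions, deletions, aligned_cols;
  std::string ref_aligned; // query bases projected onto [t_start, t_end);
                           // '-' where the target base is deleted in the read
};

static SWResult sw_align_core(const std::string &q, const std::string &t,
                              int match, int mismatch, int ins_cost,
                              int del_cost, bool traceback) {
  const int n = q.size(), m = t.size();
  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<unsigned char> dir; // 0 stop, 1 diag, 2 del(gap in query), 3 ins(gap in target)
  if (traceback) dir.assign((n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = (q[i - 1] == t[j - 1]) ? match : -mismatch;
      int d = H[(i - 1) * (m + 1) + (j - 1)] + sub;
      int up = H[(i - 1) * (m + 1) + j] - ins_cost;   // consume query base
      int lf = H[i * (m + 1) + (j - 1)] - del_cost;   // consume target base
      int v = std::max(0, std::max(d, std::max(lf, up)));
      unsigned char dv = 0;
      if (v > 0) dv = (d == v) ? 1 : ((lf == v) ? 2 : 3);
      H[i * (m + 1) + j] = v;
      if (traceback) dir[i * (m + 1) + j] = dv;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  SWResult r;
  r.score = best;
  r.matches = r.mismatches = r.insertions = r.deletions = r.aligned_cols = 0;
  r.q_start = r.q_end = r.t_start = r.t_end = 0;
  if (best == 0 || !traceback) {
    if (best > 0) { r.q_end = bi; r.t_end = bj; }
    return r;
  }
  int i = bi, j = bj;
  std::string proj; // built backwards over target positions
  while (i > 0 && j > 0) {
    unsigned char dv = dir[i * (m + 1) + j];
    if (dv == 0) break;
    if (dv == 1) {
      if (q[i - 1] == t[j - 1]) r.matches++; else r.mismatches++;
      proj.push_back(q[i - 1]);
      --i; --j;
    } else if (dv == 2) { // gap in query: target base deleted in read
      r.deletions++;
      proj.push_back('-');
      --j;
    } else {             // gap in target: extra read base, not projected
      r.insertions++;
      --i;
    }
    r.aligned_cols++;
  }
  r.q_start = i; r.q_end = bi;
  r.t_start = j; r.t_end = bj;
  std::reverse(proj.begin(), proj.end());
  r.ref_aligned = proj;
  return r;
}

static List sw_as_list(const SWResult &r) {
  return List::create(
      _["score"] = r.score, _["matches"] = r.matches,
      _["mismatches"] = r.mismatches, _["insertions"] = r.insertions,
      _["deletions"] = r.deletions, _["aligned_cols"] = r.aligned_cols,
      _["q_start"] = r.q_start, _["q_end"] = r.q_end,
      _["t_start"] = r.t_start, _["t_end"] = r.t_end,
      _["ref_aligned"] = r.ref_aligned);
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string target, int match,
                  int mismatch, int ins_cost, int del_cost) {
  return sw_as_list(
      sw_align_core(query, target, match, mismatch, ins_cost, del_cost, true));
}

// Align one query against a set of targets; returns a stats matrix plus the
// per-target projection strings needed for consensus building.
// [[Rcpp::export(name = ".sw_batch_cpp")]]
List sw_batch_cpp(std::string query, CharacterVector targets, int match,
                  int mismatch, int ins_cost, int del_cost) {
  const int k = targets.size();
  IntegerMatrix stats(k, 10);
  colnames(stats) = CharacterVector::create(
      "score", "matches", "mismatches", "insertions", "deletions",
      "aligned_cols", "q_start", "q_end", "t_start", "t_end");
  CharacterVector proj(k);
  for (int s = 0; s < k; ++s) {
    SWResult r = sw_align_core(query, as<std::string>(targets[s]), match,
                               mismatch, ins_cost, del_cost, true);
    stats(s, 0) = r.score; stats(s, 1) = r.matches; stats(s, 2) = r.mismatches;
    stats(s, 3) = r.insertions; stats(s, 4) = r.deletions;
    stats(s, 5) = r.aligned_cols; stats(s, 6) = r.q_start; stats(s, 7) = r.q_end;
    stats(s, 8) = r.t_start; stats(s, 9) = r.t_end;
    proj[s] = r.ref_aligned;
  }
  return List::create(_["stats"] = stats, _["ref_aligned"] = proj);
}
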