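#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Single rule application at a 0-based position. Returns NA_STRING when the
// lhs does not match (or does not fit) -- the modelled "invalid application".
// [[Rcpp::export]]
String apply_rule_cpp(const std::string& state, const std::string& lhs,
                      const std::string& rhs, const int pos) {
  const int n = (int)state.size(), m = (int)lhs.size();
  if (pos < 0 || pos > n - 1) stop("position out of range");
  if (pos + m > n) return NA_STRING;
  if (state.compare(pos, m, lhs) != 0) return NA_STRING;
  std::string out;
  out.reserve(n - m + rhs.size());
  out.append(state, 0, pos);
  out.append(rhs);
  out.append(state, pos + m, std::string::npos);
  return String(out);
}

// All valid (rule, position) applications from `state`.
// Returns parallel vectors: rule index (1-based), position (0-based), result.
// [[Rcpp::export]]
List successors_cpp(const std::string& state, const CharacterVector& lhs,
                    const CharacterVector& rhs) {
  const int n = (int)state.size();
  std::vector<int> rule_idx, pos_idx;
  std::vector<std::string> to;
  for (int r = 0; r < lhs.size(); ++r) {
    const std::string l = as<std::string>(lhs[r]);
    const std::string rr = as<std::string>(rhs[r]);
    const int m = (int)l.size();
    for (int p = 0; p + m <= n; ++p) {
      if (state.compare(p, m, l) == 0) {
        std::string out;
        out.reserve(n - m + rr.size());
        out.append(state, 0, p);
        out.append(rr);
        out.append(state, p + m, std::string::npos);
        rule_idx.push_back(r + 1);
        pos_idx.push_back(p);
        to.push_back(out);
      }
    }
  }
  return List::create(_["rule"] = wrap(rule_idx), _["pos"] = wrap(pos_idx),
                      _["to"] = wrap(to));
}

// [[Rcpp::export]]
int edit_distance_cpp(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      const int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int lcs_length_cpp(const std::string& a, const std::string& b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }
  return prev[m];
}

static void run_stats(const std::string& s, int& longest, int& shortest,
                      int& collapsed) {
  longest = 0; shortest = 0; collapsed = 0;
  const int n = (int)s.size();
  if (n == 0) return;
  longest = 1; shortest = n; collapsed = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && s[j] == s[i]) ++j;
    const int len = j - i;
    if (len > longest) longest = len;
    if (len < shortest) shortest = len;
    ++collapsed;
    i = j;
  }
}

// The 13-feature representation of a (state, goal) string pair:
//  f1  proportion of state positions matching the goal (denominator |state|;
//      positions past the shorter string are mismatches)
//  f2  |state| - |goal|
//  f3  unique-symbol count difference (state - goal)
//  f4  LCS(state, goal) / |goal|
//  f5, f6   lengths of state, goal
//  f7, f8   longest run of a repeated symbol in state, goal
//  f9, f10  shortest run in state, goal
//  f11, f12 lengths after collapsing consecutive repeats
//  f13 Levenshtein edit distance
// [[Rcpp::export]]
NumericVector feature_vector_cpp(const std::string& s, const std::string& g) {
  const int n = (int)s.size(), m = (int)g.size();
  if (n == 0 || m == 0) stop("state and goal must be non-empty");
  NumericVector f(13);
  int match = 0;
  for (int i = 0; i < std::min(n, m); ++i)
    if (s[i] == g[i]) ++match;
  f[0] = (double)match / n;
  f[1] = n - m;
  bool seen_s[256] = {false}, seen_g[256] = {false};
  int us = 0, ug = 0;
  for (int i = 0; i < n; ++i) {
    unsigned char c = s[i];
    if (!seen_s[c]) { seen_s[c] = true; ++us; }
  }
  for (int i = 0; i < m; ++i) {
    unsigned char c = g[i];
    if (!seen_g[c]) { seen_g[c] = true; ++ug; }
  }
  f[2] = us - ug;
  f[3] = (double)lcs_length_cpp(s, g) / m;
  f[4] = n; f[5] = m;
  int lo, sh, co;
  run_stats(s, lo, sh, co);
  f[6] = lo; f[8] = sh; f[10] = co;
  run_stats(g, lo, sh, co);
  f[7] = lo; f[9] = sh; f[11] = co;
  f[12] = edit_distance_cpp(s, g);
  return f;
}

// Feature matrix for many (state, goal) pairs; rows align with inputs.
// [[Rcpp::export]]
NumericMatrix feature_matrix_cpp(const CharacterVector& states,
                                 const CharacterVector& goals) {
  const int n = states.size();
  if (goals.size() != n) stop("states and goals must have equal length");
  NumericMatrix out(n, 13);
  for (int i = 0; i < n; ++i) {
    NumericVector f = feature_vector_cpp(as<std::string>(states[i]),
                                         as<std::string>(goals[i]));
    for (int j = 0; j < 13; ++j) out(i, j) = f[j];
  }
  return out;
}
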