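#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match +1, mismatch -1 and a
// linear gap penalty of -2 per gap position. Returns identity
// (matches / alignment columns along one optimal path; ties prefer
// diagonal, then up, then left) and the optimal score.

// [[Rcpp::export(name = ".nw_identity_batch")]]
List nw_identity_batch(CharacterVector a, CharacterVector b) {
  const double GAP = -2.0;
  int n = a.size();
  NumericVector identity(n), score(n);
  for (int t = 0; t < n; t++) {
    std::string s1 = as<std::string>(a[t]);
    std::string s2 = as<std::string>(b[t]);
    int m = s1.size(), k = s2.size();
    std::vector<double> prev(k + 1), cur(k + 1);
    std::vector<unsigned char> dir((size_t)(m + 1) * (k + 1));
    for (int j = 0; j <= k; j++) { prev[j] = GAP * j; dir[j] = 2; }
    dir[0] = 0;
    for (int i = 1; i <= m; i++) {
      cur[0] = GAP * i;
      dir[(size_t)i * (k + 1)] = 1;
      for (int j = 1; j <= k; j++) {
        double sc = (s1[i - 1] == s2[j - 1]) ? 1.0 : -1.0;
        double d = prev[j - 1] + sc;
        double u = prev[j] + GAP;
        double l = cur[j - 1] + GAP;
        double best = d; unsigned char bd = 0;
        if (u > best) { best = u; bd = 1; }
        if (l > best) { best = l; bd = 2; }
        cur[j] = best;
        dir[(size_t)i * (k + 1) + j] = bd;
      }
      std::swap(prev, cur);
    }
    score[t] = prev[k];
    int i = m, j = k, matches = 0, cols = 0;
    while (i > 0 || j > 0) {
      unsigned char d = dir[(size_t)i * (k + 1) + j];
      if (i > 0 && j > 0 && d == 0) {
        if (s1[i - 1] == s2[j - 1]) matches++;
        i--; j--;
      } else if (i > 0 && (j == 0 || d == 1)) {
        i--;
      } else {
        j--;
      }
      cols++;
    }
    identity[t] = cols > 0 ? (double)matches / cols : 1.0;
  }
  return List::create(_["identity"] = identity, _["score"] = score);
}
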