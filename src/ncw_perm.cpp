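#include <Rcpp.h>
using namespace Rcpp;

// One block of column-wise permutations of a label grid.
//
// Each elementary permutation independently shuffles every column's observed
// labels among that column's observed positions (missing positions fixed),
// recomputes the pairwise co-clustering counts, and increments exceed(i,j)
// for every co-observed pair whose permuted count is >= the observed count.
// Because missing positions never move, the co-observation denominator is
// permutation-invariant, so comparing counts is identical to comparing CW
// ratios.
//
// Uses R's RNG (RNGScope via Rcpp attributes): set.seed() before the call
// makes the block reproducible. Shuffling the *positions* and then handing
// out labels in fixed label-group order induces the same uniform
// distribution over arrangements as shuffling the labels themselves.
//
// labels: n x R integer grid, NA for missing.
// together_obs: n x n observed co-clustering counts.
// observed: n x n co-observation counts (pairs with 0 are skipped).
// Returns an n x n integer matrix of exceedance counts (upper triangle
// filled, symmetrised in R).
// [[Rcpp::export]]
IntegerMatrix perm_exceed_block(IntegerMatrix labels, IntegerMatrix together_obs,
                                IntegerMatrix observed, int nperm) {
  const int n = labels.nrow();
  const int R = labels.ncol();

  // Precompute per column: observed positions and label-group sizes.
  std::vector<std::vector<int> > pos(R);
  std::vector<std::vector<int> > grp(R);  // group sizes, arbitrary fixed order
  for (int j = 0; j < R; ++j) {
    std::map<int, int> counts;
    for (int i = 0; i < n; ++i) {
      int v = labels(i, j);
      if (v != NA_INTEGER) {
        pos[j].push_back(i);
        counts[v] += 1;
      }
    }
    for (std::map<int, int>::iterator it = counts.begin(); it != counts.end(); ++it)
      grp[j].push_back(it->second);
  }

  std::vector<int> tog(static_cast<size_t>(n) * n);
  IntegerMatrix exceed(n, n);

  for (int p = 0; p < nperm; ++p) {
    std::fill(tog.begin(), tog.end(), 0);
    for (int j = 0; j < R; ++j) {
      std::vector<int>& pj = pos[j];
      const int m = static_cast<int>(pj.size());
      // Fisher-Yates on positions
      for (int i = m - 1; i > 0; --i) {
        int k = static_cast<int>(unif_rand() * (i + 1));
        if (k > i) k = i;  // guard against unif_rand() == 1.0 edge
        std::swap(pj[i], pj[k]);
      }
      // consecutive ranges of shuffled positions form the label groups
      int offset = 0;
      for (size_t g = 0; g < grp[j].size(); ++g) {
        const int gs = grp[j][g];
        for (int a = 0; a < gs; ++a) {
          const int ia = pj[offset + a];
          for (int b = a + 1; b < gs; ++b) {
            const int ib = pj[offset + b];
            if (ia < ib) tog[static_cast<size_t>(ia) * n + ib] += 1;
            else         tog[static_cast<size_t>(ib) * n + ia] += 1;
          }
        }
        offset += gs;
      }
    }
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (observed(i, j) > 0 &&
            tog[static_cast<size_t>(i) * n + j] >= together_obs(i, j)) {
          exceed(i, j) += 1;
        }
      }
    }
  }
  return exceed;
}
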