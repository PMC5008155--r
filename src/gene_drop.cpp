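#include <Rcpp.h>
using namespace Rcpp;

// Monte Carlo gene dropping through a topologically ordered pedigree.
//
// Each founder (and each missing parent side, treated as a private founder)
// carries unique allele labels. One allele per parent is transmitted uniformly
// at random per replicate. Identity of labels within an individual estimates F;
// label matches between individuals estimate coancestry.
//
// dam, sire: 0-based indices into the topological order, -1 = unknown.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export(name = ".gene_drop_cpp")]]
List gene_drop_cpp(IntegerVector dam, IntegerVector sire, int n_rep) {
  const int n = dam.size();
  std::vector<int> a1(n), a2(n);
  std::vector<double> ibd(n, 0.0);
  NumericMatrix S(n, n);  // sum over replicates of allele-label matches (4 comparisons/pair)

  // fixed unique allele labels for founder / missing-parent sides
  std::vector<int> fa1(n), fa2(n);
  int next_allele = 0;
  for (int i = 0; i < n; ++i) {
    fa1[i] = next_allele++;
    fa2[i] = next_allele++;
  }

  for (int rep = 0; rep < n_rep; ++rep) {
    for (int i = 0; i < n; ++i) {
      int d = dam[i], s = sire[i];
      a1[i] = (d < 0) ? fa1[i] : (unif_rand() < 0.5 ? a1[d] : a2[d]);
      a2[i] = (s < 0) ? fa2[i] : (unif_rand() < 0.5 ? a1[s] : a2[s]);
      if (a1[i] == a2[i]) ibd[i] += 1.0;
    }
    for (int i = 0; i < n; ++i) {
      const int x1 = a1[i], x2 = a2[i];
      for (int j = 0; j <= i; ++j) {
        const int y1 = a1[j], y2 = a2[j];
        S(i, j) += (x1 == y1) + (x1 == y2) + (x2 == y1) + (x2 == y2);
      }
    }
  }

  // symmetrize
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < i; ++j)
      S(j, i) = S(i, j);

  return List::create(_["ibd_count"] = wrap(ibd), _["match_sum"] = S);
}
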