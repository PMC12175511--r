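#include <Rcpp.h>
using namespace Rcpp;

// Sample an index from a cumulative probability vector (binary search).
static inline int sample_cum(const std::vector<double> &cum) {
  double u = unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

//' Moran-type neutral local community simulator.
//'
//' One update = one random individual dies and is replaced either by an
//' immigrant drawn from the metacommunity (probability m) or by the
//' offspring of a random local individual (probability 1 - m). One
//' generation = j such updates. Community size j is conserved exactly.
//' Uses R's RNG, so results are reproducible under set.seed().
//'
//' @keywords internal
// [[Rcpp::export]]
IntegerVector moran_local_cpp(NumericVector meta_p, IntegerVector init,
                              double m, int generations) {
  const int S = meta_p.size();
  std::vector<double> cum(S);
  double acc = 0.0;
  for (int i = 0; i < S; ++i) { acc += meta_p[i]; cum[i] = acc; }

  // individual -> species
  std::vector<int> ind;
  for (int s = 0; s < S; ++s)
    for (int k = 0; k < init[s]; ++k) ind.push_back(s);
  const int J = (int)ind.size();
  if (J < 1) stop("local community is empty");

  const long long steps = (long long)generations * (long long)J;
  for (long long t = 0; t < steps; ++t) {
    int dead = (int)(unif_rand() * J);
    if (dead >= J) dead = J - 1;
    int repl;
    if (unif_rand() < m) {
      repl = sample_cum(cum);
    } else {
      int parent = (int)(unif_rand() * J);
      if (parent >= J) parent = J - 1;
      repl = ind[parent];
    }
    ind[dead] = repl;
  }

  IntegerVector out(S);
  for (int k = 0; k < J; ++k) out[ind[k]] += 1;
  return out;
}

// Mean nearest-taxon distance for a member set, using rows of a
// distance matrix with neighbour indices presorted by distance
// (ord is n x (n-1), 1-based tip indices, nearest first).
static double mntd_scan(const NumericMatrix &D, const IntegerMatrix &ord,
                        const std::vector<char> &member,
                        const std::vector<int> &idx) {
  const int k = (int)idx.size();
  const int ncol = ord.ncol();
  double tot = 0.0;
  for (int a = 0; a < k; ++a) {
    int i = idx[a];
    for (int c = 0; c < ncol; ++c) {
      int j = ord(i, c) - 1;
      if (member[j]) { tot += D(i, j); break; }
    }
  }
  return tot / k;
}

//' MNTD of an observed community via presorted neighbour scan.
//' @keywords internal
// [[Rcpp::export]]
double mntd_obs_cpp(NumericMatrix D, IntegerMatrix ord, IntegerVector members) {
  const int n = D.nrow();
  std::vector<char> member(n, 0);
  std::vector<int> idx;
  for (int a = 0; a < members.size(); ++a) {
    int i = members[a] - 1;
    member[i] = 1;
    idx.push_back(i);
  }
  return mntd_scan(D, ord, member, idx);
}

//' Null distribution of MNTD under the taxa-shuffle null: communities of
//' size k drawn uniformly without replacement from the n-taxon pool
//' (equivalent to shuffling tip labels across the pool).
//' @keywords internal
// [[Rcpp::export]]
NumericVector mntd_null_cpp(NumericMatrix D, IntegerMatrix ord, int k,
                            int n_null) {
  const int n = D.nrow();
  if (k < 2 || k > n) stop("community size must be in [2, pool size]");
  NumericVector out(n_null);
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<char> member(n, 0);
  std::vector<int> idx(k);
  for (int r = 0; r < n_null; ++r) {
    // partial Fisher-Yates draw of k indices
    for (int a = 0; a < k; ++a) {
      int b = a + (int)(unif_rand() * (n - a));
      if (b >= n) b = n - 1;
      std::swap(pool[a], pool[b]);
      idx[a] = pool[a];
      member[pool[a]] = 1;
    }
    out[r] = mntd_scan(D, ord, member, idx);
    for (int a = 0; a < k; ++a) member[idx[a]] = 0;
  }
  return out;
}
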