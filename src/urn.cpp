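#include <Rcpp.h>
using namespace Rcpp;

// Discrete urn for local community dynamics: one death plus one replacement
// per event. The replacement is an immigrant drawn from the (fitness
// weighted) metacommunity with probability m, otherwise the offspring of a
// parent chosen among the N-1 surviving residents, weighted by per-taxon
// fitness. Selection acts on birth and immigration only; death is uniform.
// Uses R's RNG, so the R-side seed governs reproducibility.
//
// When all fitness values are equal the resident parent is picked as a
// uniform surviving individual (O(1) per event); otherwise a linear scan
// over fitness-weighted counts is used.

// [[Rcpp::export(name = ".urnSample")]]
IntegerVector urnSample(IntegerVector init, NumericVector immWeight,
                        NumericVector fitness, double m, double nSteps) {
  const int S = init.size();
  const long long steps = (long long) nSteps;

  std::vector<double> cumImm(S);
  double tot = 0.0;
  for (int i = 0; i < S; ++i) { tot += immWeight[i]; cumImm[i] = tot; }
  if (tot <= 0.0) stop("immigration weights sum to zero");
  for (int i = 0; i < S; ++i) cumImm[i] /= tot;

  std::vector<int> counts(init.begin(), init.end());
  long long N = 0;
  for (int i = 0; i < S; ++i) {
    if (counts[i] < 0) stop("negative initial count");
    N += counts[i];
  }
  if (N < 2) stop("community size must be at least 2");

  bool uniformW = true;
  for (int i = 1; i < S; ++i)
    if (fitness[i] != fitness[0]) { uniformW = false; break; }

  std::vector<int> ind((size_t) N);
  { size_t k = 0;
    for (int i = 0; i < S; ++i)
      for (int j = 0; j < counts[i]; ++j) ind[k++] = i; }

  if (uniformW) {
    for (long long t = 0; t < steps; ++t) {
      long long dead = (long long)(unif_rand() * N);
      if (dead >= N) dead = N - 1;
      int repl;
      if (unif_rand() < m) {
        double u = unif_rand();
        repl = (int)(std::lower_bound(cumImm.begin(), cumImm.end(), u) -
                     cumImm.begin());
        if (repl >= S) repl = S - 1;
      } else {
        long long par = (long long)(unif_rand() * (N - 1));
        if (par >= N - 1) par = N - 2;
        if (par >= dead) ++par;  // uniform over the N-1 survivors
        repl = ind[(size_t) par];
      }
      ind[(size_t) dead] = repl;
    }
    std::fill(counts.begin(), counts.end(), 0);
    for (long long j = 0; j < N; ++j) counts[ind[(size_t) j]]++;
  } else {
    std::vector<double> wc(S);
    double W = 0.0;
    for (int i = 0; i < S; ++i) { wc[i] = counts[i] * fitness[i]; W += wc[i]; }
    for (long long t = 0; t < steps; ++t) {
      long long dead = (long long)(unif_rand() * N);
      if (dead >= N) dead = N - 1;
      int di = ind[(size_t) dead];
      // remove the dying individual before choosing a resident parent
      counts[di]--; wc[di] -= fitness[di]; W -= fitness[di];
      int repl;
      if (unif_rand() < m) {
        double u = unif_rand();
        repl = (int)(std::lower_bound(cumImm.begin(), cumImm.end(), u) -
                     cumImm.begin());
        if (repl >= S) repl = S - 1;
      } else {
        double u = unif_rand() * W;
        double acc = 0.0; repl = S - 1;
        for (int i = 0; i < S; ++i) {
          acc += wc[i];
          if (u <= acc) { repl = i; break; }
        }
      }
      counts[repl]++; wc[repl] += fitness[repl]; W += fitness[repl];
      ind[(size_t) dead] = repl;
    }
  }
  return IntegerVector(counts.begin(), counts.end());
}
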