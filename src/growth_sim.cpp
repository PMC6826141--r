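#include <Rcpp.h>
using namespace Rcpp;

// Exact division-event simulation of fitness-proportional population growth.
//
// The population starts with `founders` mutant cells and B - founders
// wild-type cells. At each event one cell divides; a mutant divides with
// probability (1+s)*m / ((1+s)*m + (n-m)) where m is the current mutant
// count and n the current population size. Growth stops at n = n_final.
// This is the embedded jump chain of two independent Yule processes with
// rates (1+s) and 1, i.e. the "modified Moran" growth realization.
//
// Uses R's RNG so that set.seed() in R makes runs reproducible.
// [[Rcpp::export]]
NumericVector urn_growth_sim_cpp(int founders, int bottleneck, double n_final,
                                 double s, int replicates) {
  if (founders < 0 || founders > bottleneck)
    stop("founders must lie in [0, bottleneck]");
  if (s < -1.0 || s > 1.0)
    stop("selection coefficient must lie in [-1, 1]");
  if (n_final < bottleneck)
    stop("final population size must be >= bottleneck size");
  double events = (n_final - bottleneck) * (double)replicates;
  if (events > 6e9)
    stop("event-level simulation too large; use the asymptotic sampler");

  const double a = 1.0 + s;
  const long long nf = (long long)n_final;
  NumericVector out(replicates);

  for (int r = 0; r < replicates; ++r) {
    long long m = founders;
    if (founders == 0) { out[r] = 0.0; continue; }
    if (founders == bottleneck) { out[r] = 1.0; continue; }
    for (long long n = bottleneck; n < nf; ++n) {
      double wm = a * (double)m;
      double p = wm / (wm + (double)(n - m));
      if (unif_rand() < p) ++m;
    }
    out[r] = (double)m / n_final;
  }
  return out;
}
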