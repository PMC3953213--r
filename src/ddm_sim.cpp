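#include <Rcpp.h>
using namespace Rcpp;

//' Euler-Maruyama simulation of a two-boundary Wiener process.
//'
//' Paths start at z between absorbing boundaries 0 and a and evolve as
//' dX = v dt + s dW. Uses R's RNG so set.seed() controls reproducibility.
//' Trials that fail to absorb before max_t are flagged (rt = NA).
//'
//' @noRd
// [[Rcpp::export]]
List ddm_simulate_cpp(int n, double v, double a, double z, double t0,
                      double s, double dt, double max_t) {
  NumericVector rt(n);
  IntegerVector upper(n);
  double sd = s * std::sqrt(dt);
  long max_steps = (long)std::ceil(max_t / dt);
  for (int i = 0; i < n; ++i) {
    double x = z;
    long step = 0;
    int hit = -1;
    while (step < max_steps) {
      x += v * dt + sd * norm_rand();
      ++step;
      if (x >= a) { hit = 1; break; }
      if (x <= 0.0) { hit = 0; break; }
    }
    if (hit < 0) {
      rt[i] = NA_REAL;
      upper[i] = NA_INTEGER;
    } else {
      rt[i] = step * dt + t0;
      upper[i] = hit;
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = upper);
}
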