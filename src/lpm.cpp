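#include <Rcpp.h>
using namespace Rcpp;

// Local pivotal method, variant 1 (LPM1), equal inclusion probabilities n/N.
//
// Repeatedly: pick a random unresolved unit, walk to its nearest unresolved
// neighbour until a mutually-nearest pair is found, then transfer inclusion
// probability within the pair at random. Each update resolves the pair's
// joint probability towards {0, 1}; the loop ends when every unit is
// resolved. Uses R's RNG so draws are reproducible via set.seed().
//
// Nearest-neighbour queries are linear scans over the unresolved set; the
// frame sizes used for site selection and evaluation-point spreads (up to a
// few tens of thousands of candidates) stay well within budget.

// [[Rcpp::export(name = ".lpm1_cpp")]]
IntegerVector lpm1_cpp(NumericVector x, NumericVector y, int n) {
  const int N = x.size();
  if (n < 0 || n > N) stop("sample size out of range");
  std::vector<double> p(N, (double)n / N);
  std::vector<int> alive(N);          // indices of unresolved units
  for (int i = 0; i < N; ++i) alive[i] = i;
  std::vector<int> pos(N);            // position of unit in `alive`
  for (int i = 0; i < N; ++i) pos[i] = i;
  const double eps = 1e-12;

  GetRNGstate();

  auto resolve = [&](int u) {
    // remove u from the alive set (swap with last)
    int pu = pos[u];
    int last = alive.back();
    alive[pu] = last;
    pos[last] = pu;
    alive.pop_back();
  };

  auto nearest = [&](int u) -> int {
    double best = R_PosInf;
    int bj = -1;
    for (size_t k = 0; k < alive.size(); ++k) {
      int j = alive[k];
      if (j == u) continue;
      double dx = x[j] - x[u], dy = y[j] - y[u];
      double d = dx * dx + dy * dy;
      if (d < best) { best = d; bj = j; }
    }
    return bj;
  };

  while (alive.size() > 1) {
    int i = alive[(int)(unif_rand() * alive.size()) % alive.size()];
    // walk until a mutually nearest pair is found
    int j = nearest(i);
    int guard = 0;
    while (++guard < (int)alive.size() + 2) {
      int k = nearest(j);
      if (k == i) break;
      i = j;
      j = k;
    }
    double pi = p[i], pj = p[j], s = pi + pj;
    double u = unif_rand();
    if (s < 1.0) {
      if (u < pj / s) { p[i] = 0.0; p[j] = s; }
      else            { p[i] = s;   p[j] = 0.0; }
    } else {
      if (u < (1.0 - pj) / (2.0 - s)) { p[i] = 1.0; p[j] = s - 1.0; }
      else                            { p[i] = s - 1.0; p[j] = 1.0; }
    }
    if (p[i] < eps || p[i] > 1.0 - eps) resolve(i);
    if (p[j] < eps || p[j] > 1.0 - eps) resolve(j);
  }
  // at most one unit left with a fractional probability (floating point):
  if (alive.size() == 1) {
    int u = alive[0];
    p[u] = (unif_rand() < p[u]) ? 1.0 : 0.0;
  }
  PutRNGstate();

  std::vector<int> sel;
  sel.reserve(n);
  for (int i = 0; i < N; ++i)
    if (p[i] > 0.5) sel.push_back(i + 1);  // 1-based ids
  return wrap(sel);
}
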