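#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Maximum signed CDF deviation for a group of distinct sorted ranks r
// (1-based) out of a universe of n ranks. Candidate evaluation points are
// each member rank r_i and the grid point r_i - 1 just below it; between
// members the deviation only drifts down, so these cover the extremes.
static double max_signed_dev(const std::vector<int> &r, int n) {
  const int k = (int)r.size();
  if (k == 0) return 0.0;
  double best = 0.0, besta = -1.0;
  for (int i = 0; i < k; ++i) {
    const double d1 = (double)(i + 1) / k - (double)r[i] / n;
    const double d0 = (double)i / k - (double)(r[i] - 1) / n;
    if (std::fabs(d0) > besta) { besta = std::fabs(d0); best = d0; }
    if (std::fabs(d1) > besta) { besta = std::fabs(d1); best = d1; }
  }
  return best;
}

//' Null distribution of the combined signed KS statistic
//'
//' Draws \code{nperm} random sign-preserving memberships (\code{ku} up and
//' \code{kd} down regulatees sampled jointly without replacement from a
//' universe of \code{n} ranks) and returns the combined statistic
//' \code{(ku*du - kd*dd) / (ku + kd)} for each draw. Uses R's RNG, so
//' \code{set.seed()} governs reproducibility.
//'
//' @param n universe size.
//' @param ku number of up-regulatees.
//' @param kd number of down-regulatees.
//' @param nperm number of permutations.
//' @return numeric vector of length \code{nperm}.
//' @keywords internal
// [[Rcpp::export]]
NumericVector ks_null_dupdown(int n, int ku, int kd, int nperm) {
  const int k = ku + kd;
  if (k < 1) stop("ku + kd must be >= 1");
  if (k > n) stop("ku + kd exceeds the universe size");
  NumericVector out(nperm);
  std::vector<int> ru(ku), rd(kd);
  for (int b = 0; b < nperm; ++b) {
    IntegerVector s = sample(n, k, false);
    for (int i = 0; i < ku; ++i) ru[i] = s[i];
    for (int i = 0; i < kd; ++i) rd[i] = s[ku + i];
    std::sort(ru.begin(), ru.end());
    std::sort(rd.begin(), rd.end());
    const double du = max_signed_dev(ru, n);
    const double dd = max_signed_dev(rd, n);
    out[b] = (ku * du - kd * dd) / (double)k;
  }
  return out;
}
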