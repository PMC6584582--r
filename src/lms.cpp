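#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sign-Data LMS adaptive canceller. Per sample k (0-based):
//   yhat[k] = w' x[k],  x[k] = (ref[k], ref[k-1], ..., ref[k-n_weights+1])
//   e[k]    = received[k] - yhat[k]
//   w      += mu * e[k] * sign(x[k]) / n_weights   (elementwise; sign(0)=0)
// The tap vector is normalized by (running peak of |ref|) * n_weights so
// the predicted-output swing of one sign-data update is bounded by
// mu * |e| regardless of playback level or filter length; this keeps the
// stated step size inside the stability region. Weights start at zero.
// [[Rcpp::export]]
List lms_sign_data(NumericVector received, NumericVector ref,
                   int n_weights, double mu) {
  int n = received.size();
  NumericVector w(n_weights), cleaned(n);
  double peak = 0.0;
  double nw = static_cast<double>(n_weights);
  for (int k = 0; k < n; ++k) {
    double a = std::fabs(ref[k]);
    if (a > peak) peak = a;
    double yhat = 0.0;
    int taps = (k + 1 < n_weights) ? k + 1 : n_weights;
    if (peak > 0.0) {
      double scale = 1.0 / (peak * nw);
      for (int j = 0; j < taps; ++j) yhat += w[j] * (ref[k - j] * scale);
    }
    double e = received[k] - yhat;
    cleaned[k] = e;
    if (peak > 0.0 && mu != 0.0) {
      double step = mu * e;
      for (int j = 0; j < taps; ++j) {
        double xj = ref[k - j];
        if (xj > 0.0)      w[j] += step;
        else if (xj < 0.0) w[j] -= step;
      }
    }
  }
  return List::create(_["cleaned"] = cleaned, _["weights"] = w);
}
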