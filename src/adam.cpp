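#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update with L2 weight decay folded into the gradient.
// Updates vec, m and v directly; the flattened parameter/state vectors are
// private to the optimizer loop, so in-place mutation is safe and avoids
// re-allocating ~10 full-size temporaries per step.
//
// The update equals the textbook form
//   m <- beta1 m + (1-beta1) g;  v <- beta2 v + (1-beta2) g^2
//   vec <- vec - lr * (m / bc1) / (sqrt(v / bc2) + eps)
// with the bias corrections bc1 = 1-beta1^t, bc2 = 1-beta2^t folded into
// scalar factors.
// [[Rcpp::export]]
void adam_update_inplace(NumericVector vec, NumericVector grad,
                         NumericVector m, NumericVector v, int t,
                         double lr, double weight_decay,
                         double beta1, double beta2, double eps) {
  const R_xlen_t n = vec.size();
  if (grad.size() != n || m.size() != n || v.size() != n)
    stop("adam_update_inplace: length mismatch");
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double sbc2 = std::sqrt(1.0 - std::pow(beta2, t));
  const double step = lr * sbc2 / bc1;
  const double eps_s = eps * sbc2;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = grad[i] + weight_decay * vec[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * g;
    v[i] = beta2 * v[i] + (1.0 - beta2) * g * g;
    vec[i] -= step * m[i] / (std::sqrt(v[i]) + eps_s);
  }
}
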