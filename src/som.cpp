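#include <Rcpp.h>
using namespace Rcpp;

// Online self-organizing map training loop.
//
// X:         n x d data matrix (rows are samples).
// codebook:  k x d initial prototypes (modified copy returned).
// node_pos:  k x 2 node coordinates in map space (1-D chain: (i, 0)).
// order:     0-based row indices, one per presentation step (seeded in R,
//            so determinism lives entirely on the R side).
// lr_start/lr_end: linear decay over all steps.
// radius_start/radius_end: linear decay over the first radius_frac of the
// steps (ordering phase); afterwards the radius stays at radius_end
// (winner-only fine-tuning when radius_end is 0).
//
// Best-matching unit by squared Euclidean distance; ties break to the lowest
// node index (strict <). Neighborhood is Gaussian in node-coordinate space;
// radius below ~0 collapses to winner-only competitive learning.
// Returns the trained codebook and the mean BMU distance per pass
// (a running quantization-error trace).
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix X, NumericMatrix codebook,
                   NumericMatrix node_pos, IntegerVector order,
                   double lr_start, double lr_end,
                   double radius_start, double radius_end,
                   double radius_frac, int steps_per_pass) {
  int n = X.nrow(), d = X.ncol(), k = codebook.nrow();
  NumericMatrix W = clone(codebook);
  long nsteps = order.size();
  int npass = steps_per_pass > 0 ? (int)(nsteps / steps_per_pass) : 1;
  NumericVector qe_trace(npass > 0 ? npass : 1);
  double qe_acc = 0.0; int qe_cnt = 0, pass = 0;

  for (long s = 0; s < nsteps; ++s) {
    double frac = nsteps > 1 ? (double)s / (double)(nsteps - 1) : 0.0;
    double lr = lr_start + (lr_end - lr_start) * frac;
    double rphase = radius_frac > 0 ? frac / radius_frac : 1.0;
    if (rphase > 1.0) rphase = 1.0;
    double radius = radius_start + (radius_end - radius_start) * rphase;
    int i = order[s];

    // best-matching unit
    int bmu = 0; double best = R_PosInf;
    for (int j = 0; j < k; ++j) {
      double dist = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - W(j, c);
        dist += diff * diff;
      }
      if (dist < best) { best = dist; bmu = j; }
    }
    qe_acc += std::sqrt(best); qe_cnt++;

    if (radius <= 1e-12) {
      for (int c = 0; c < d; ++c)
        W(bmu, c) += lr * (X(i, c) - W(bmu, c));
    } else {
      double twoSig2 = 2.0 * radius * radius;
      for (int j = 0; j < k; ++j) {
        double dx = node_pos(j, 0) - node_pos(bmu, 0);
        double dy = node_pos(j, 1) - node_pos(bmu, 1);
        double h = std::exp(-(dx * dx + dy * dy) / twoSig2);
        if (h < 1e-12) continue;
        double lh = lr * h;
        for (int c = 0; c < d; ++c)
          W(j, c) += lh * (X(i, c) - W(j, c));
      }
    }

    if (steps_per_pass > 0 && (s + 1) % steps_per_pass == 0 && pass < npass) {
      qe_trace[pass++] = qe_acc / qe_cnt;
      qe_acc = 0.0; qe_cnt = 0;
    }
  }
  if (steps_per_pass <= 0 && qe_cnt > 0) qe_trace[0] = qe_acc / qe_cnt;
  return List::create(_["codebook"] = W, _["qe_trace"] = qe_trace);
}

// Nearest-prototype assignment (squared Euclidean, ties to lowest index).
// Returns 1-based cluster indices and the mean Euclidean BMU distance.
// [[Rcpp::export]]
List som_assign_cpp(NumericMatrix X, NumericMatrix W) {
  int n = X.nrow(), d = X.ncol(), k = W.nrow();
  IntegerVector assign(n);
  double qe = 0.0;
  for (int i = 0; i < n; ++i) {
    int bmu = 0; double best = R_PosInf;
    for (int j = 0; j < k; ++j) {
      double dist = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - W(j, c);
        dist += diff * diff;
      }
      if (dist < best) { best = dist; bmu = j; }
    }
    assign[i] = bmu + 1;
    qe += std::sqrt(best);
  }
  return List::create(_["assignments"] = assign,
                      _["quantization_error"] = n > 0 ? qe / n : NA_REAL);
}
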