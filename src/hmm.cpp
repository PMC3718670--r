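#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over one chain.  logB is T x I (log emissions);
// per step the emissions are rescaled by their row maximum before the
// classic Rabiner scaling, so the per-step log scale factor is
// log(c_t) + max_i logB(t, i) and the chain log-likelihood is their sum.
// gamma rows and xi slices are renormalized explicitly, which makes the
// posterior identities exact to machine precision.  An independently
// scaled backward recursion provides a second log-likelihood for
// cross-checking.
// [[Rcpp::export(name = ".fb_chain")]]
List fb_chain(NumericMatrix logB, NumericVector pi, NumericMatrix A) {
  const int T = logB.nrow(), I = logB.ncol();
  if (T < 1) stop("empty chain");
  NumericMatrix B(T, I);
  NumericVector m(T);
  for (int t = 0; t < T; ++t) {
    double mx = R_NegInf;
    for (int i = 0; i < I; ++i) mx = std::max(mx, logB(t, i));
    if (!R_FINITE(mx))
      stop("all-zero emission row at position %d", t + 1);
    m[t] = mx;
    for (int i = 0; i < I; ++i) B(t, i) = std::exp(logB(t, i) - mx);
  }

  NumericMatrix alpha(T, I), beta(T, I), gamma(T, I);
  NumericVector log_scale(T);
  // forward
  {
    double c = 0.0;
    for (int i = 0; i < I; ++i) { alpha(0, i) = pi[i] * B(0, i); c += alpha(0, i); }
    if (c <= 0.0) stop("zero forward mass at position 1");
    for (int i = 0; i < I; ++i) alpha(0, i) /= c;
    log_scale[0] = std::log(c) + m[0];
    for (int t = 1; t < T; ++t) {
      c = 0.0;
      for (int j = 0; j < I; ++j) {
        double s = 0.0;
        for (int i = 0; i < I; ++i) s += alpha(t - 1, i) * A(i, j);
        alpha(t, j) = s * B(t, j);
        c += alpha(t, j);
      }
      if (c <= 0.0) stop("zero forward mass at position %d", t + 1);
      for (int j = 0; j < I; ++j) alpha(t, j) /= c;
      log_scale[t] = std::log(c) + m[t];
    }
  }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += log_scale[t];

  // backward, scaled per step by its own row sum (independent of forward)
  double loglik_b;
  {
    std::vector<double> bscale(T, 0.0);
    for (int i = 0; i < I; ++i) beta(T - 1, i) = 1.0;
    bscale[T - 1] = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      double c = 0.0;
      for (int i = 0; i < I; ++i) {
        double s = 0.0;
        for (int j = 0; j < I; ++j) s += A(i, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, i) = s;
        c += s;
      }
      if (c <= 0.0) stop("zero backward mass at position %d", t + 1);
      for (int i = 0; i < I; ++i) beta(t, i) /= c;
      bscale[t] = c;
    }
    double acc = 0.0;
    for (int t = 0; t < T - 1; ++t) acc += std::log(bscale[t]);
    for (int t = 1; t < T; ++t) acc += m[t];
    double s0 = 0.0;
    for (int i = 0; i < I; ++i) s0 += pi[i] * B(0, i) * beta(0, i);
    loglik_b = acc + std::log(s0) + m[0];
  }

  // posteriors
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int i = 0; i < I; ++i) { gamma(t, i) = alpha(t, i) * beta(t, i); s += gamma(t, i); }
    if (s <= 0.0) stop("zero posterior mass at position %d", t + 1);
    for (int i = 0; i < I; ++i) gamma(t, i) /= s;
  }
  NumericMatrix xi(std::max(T - 1, 0), I * I);  // row t: xi_t(i,j), j fastest
  for (int t = 0; t + 1 < T; ++t) {
    double s = 0.0;
    for (int i = 0; i < I; ++i)
      for (int j = 0; j < I; ++j) {
        double v = alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j);
        xi(t, i * I + j) = v;
        s += v;
      }
    if (s <= 0.0) stop("zero transition posterior mass at position %d", t + 1);
    for (int k = 0; k < I * I; ++k) xi(t, k) /= s;
  }

  return List::create(_["alpha"] = alpha, _["beta"] = beta,
                      _["log_scale"] = log_scale, _["gamma"] = gamma,
                      _["xi"] = xi, _["loglik"] = loglik,
                      _["loglik_backward"] = loglik_b);
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// [[Rcpp::export(name = ".viterbi_chain")]]
List viterbi_chain(NumericMatrix logB, NumericVector pi, NumericMatrix A) {
  const int T = logB.nrow(), I = logB.ncol();
  if (T < 1) stop("empty chain");
  NumericMatrix d(T, I);
  IntegerMatrix psi(T, I);
  for (int i = 0; i < I; ++i) d(0, i) = std::log(pi[i]) + logB(0, i);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < I; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < I; ++i) {
        double v = d(t - 1, i) + std::log(A(i, j));
        if (v > best) { best = v; arg = i; }
      }
      d(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int i = 0; i < I; ++i)
    if (d(T - 1, i) > best) { best = d(T - 1, i); arg = i; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states
  return List::create(_["path"] = path, _["log_prob"] = best);
}
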