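// Euler-Maruyama steppers for the bundled model families. Kept in C++
// because the validation experiments integrate ~1e6-1e7 steps per run;
// noise is drawn from R's RNG so set.seed() in R makes runs
// bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rosenzweig-MacArthur metacommunity right-hand side.
// params order: r, K, a, h, eps, m, g, delta_b, delta_c
// state layout species-fastest: (b_1, c_1, b_2, c_2, ...)
static void rm_rhs(int P, const double* x, const double* pr,
                   const NumericMatrix& A, double* out) {
  const double r = pr[0], K = pr[1], a = pr[2], h = pr[3], eps = pr[4],
               m = pr[5], g = pr[6], db = pr[7], dc = pr[8];
  for (int p = 0; p < P; ++p) {
    const double b = x[2 * p], c = x[2 * p + 1];
    const double fr = a * b / (1.0 + a * h * b);
    out[2 * p] = r * b * (1.0 - b / K) - fr * c;
    out[2 * p + 1] = eps * fr * c - m * c - g * c * c;
  }
  for (int p = 0; p < P; ++p) {
    double fb = 0.0, fc = 0.0;
    for (int q = 0; q < P; ++q) {
      if (A(p, q) != 0.0) {
        fb += x[2 * q] - x[2 * p];
        fc += x[2 * q + 1] - x[2 * p + 1];
      }
    }
    out[2 * p] += db * fb;
    out[2 * p + 1] += dc * fc;
  }
}

// [[Rcpp::export]]
List em_native(std::string kind, List native_data, NumericVector x0,
               double dt, int n_samples, int stride, int burn_in,
               NumericVector sigma, bool multiplicative,
               int ramp_index, double ramp_from, double ramp_to,
               double floor_val) {
  const int N = x0.size();
  NumericMatrix values(n_samples, N);
  NumericVector ptrace(ramp_index >= 0 ? n_samples : 0);

  std::vector<double> x(x0.begin(), x0.end()), f(N, 0.0);
  NumericMatrix J, A;
  std::vector<double> pr;
  int P = 0;
  const bool linear = (kind == "linear");
  if (linear) {
    J = as<NumericMatrix>(native_data["jacobian"]);
  } else if (kind == "rm") {
    NumericVector p0 = as<NumericVector>(native_data["params"]);
    pr.assign(p0.begin(), p0.end());
    A = as<NumericMatrix>(native_data["adjacency"]);
    P = N / 2;
  } else {
    stop("unknown native model kind '%s'", kind.c_str());
  }

  const double sdt = std::sqrt(dt);
  const long total = (long)burn_in + (long)n_samples * stride;
  const double denom = std::max(1.0, (double)n_samples * stride - 1.0);
  long k = 0;

  for (long t = 0; t < total; ++t) {
    if (ramp_index >= 0) {
      double frac = t < burn_in ? 0.0 : (double)(t - burn_in) / denom;
      pr[ramp_index] = ramp_from + frac * (ramp_to - ramp_from);
    }
    if (linear) {
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int j = 0; j < N; ++j) acc += J(i, j) * x[j];
        f[i] = acc;
      }
    } else {
      rm_rhs(P, x.data(), pr.data(), A, f.data());
    }
    bool bad = false, low = false;
    for (int i = 0; i < N; ++i) {
      const double s = multiplicative ? sigma[i] * x[i] : sigma[i];
      x[i] += f[i] * dt + s * sdt * norm_rand();
      if (!std::isfinite(x[i])) bad = true;
      if (x[i] < floor_val) low = true;
    }
    if (bad || low) {
      return List::create(_["status"] = bad ? 2 : 1,
                          _["step"] = (double)(t + 1),
                          _["values"] = values, _["param_trace"] = ptrace);
    }
    if (t >= burn_in && (t - burn_in + 1) % stride == 0) {
      for (int i = 0; i < N; ++i) values(k, i) = x[i];
      if (ramp_index >= 0) ptrace[k] = pr[ramp_index];
      ++k;
    }
  }
  return List::create(_["status"] = 0, _["step"] = -1.0,
                      _["values"] = values, _["param_trace"] = ptrace);
}
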