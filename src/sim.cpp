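#include <Rcpp.h>
using namespace Rcpp;

// Exact-transition OU simulation with threshold/reset.  The membrane
// potential follows the AR(1) recursion u <- a*u + s*z at internal step dt
// (a = exp(-dt/tau), s = sigma*sqrt((1-a^2)/2)), which is the exact
// transition density of the process; crossings are checked every dt and the
// potential restarts at u_reset.  Samples are recorded every `thin` steps.
// [[Rcpp::export]]
List oup_reset_cpp(double tau, double theta, double u_reset, double sigma,
                   double duration, double dt, int thin, double u0) {
  const double a = std::exp(-dt / tau);
  const double s = sigma * std::sqrt((1.0 - a * a) / 2.0);
  const long nstep = (long)std::floor(duration / dt + 0.5);
  const long nsamp = nstep / thin + 1;
  NumericVector samples(nsamp);
  std::vector<double> spikes;
  double u = u0;
  samples[0] = u;
  long isamp = 1;
  for (long i = 1; i <= nstep; ++i) {
    u = a * u + s * norm_rand();
    if (u >= theta) {
      spikes.push_back(i * dt);
      u = u_reset;
    }
    if (i % thin == 0 && isamp < nsamp) samples[isamp++] = u;
  }
  return List::create(_["samples"] = samples,
                      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
}

// Event-driven Stein-model simulation: exact exponential decay between
// Poisson arrival events, an instantaneous jump w_k per arrival, and
// threshold/reset.  The trace is sampled on the grid k*epsilon.
// [[Rcpp::export]]
List stein_cpp(NumericVector weights, NumericVector rates, double tau,
               double theta, double u_reset, double duration, double epsilon,
               double u0) {
  const int N = weights.size();
  double total = 0.0;
  std::vector<double> cum(N);
  for (int k = 0; k < N; ++k) { total += rates[k]; cum[k] = total; }
  const long nsamp = (long)std::floor(duration / epsilon) + 1;
  NumericVector samples(nsamp);
  std::vector<double> spikes;
  double u = u0, t = 0.0;
  long isamp = 0;
  samples[isamp++] = u;  // t = 0
  while (true) {
    double tev = (total > 0.0) ? t + exp_rand() / total : duration + 1.0;
    // fill samples strictly before the event (pure decay from (t, u))
    while (isamp < nsamp) {
      double ts = isamp * epsilon;
      if (ts >= tev || ts > duration) break;
      samples[isamp++] = u * std::exp(-(ts - t) / tau);
    }
    if (tev > duration) break;
    // advance to the event and apply the jump
    u = u * std::exp(-(tev - t) / tau);
    t = tev;
    double x = unif_rand() * total;
    int k = (int)(std::lower_bound(cum.begin(), cum.end(), x) - cum.begin());
    if (k >= N) k = N - 1;
    u += weights[k];
    if (u >= theta) {
      spikes.push_back(t);
      u = u_reset;
    }
  }
  return List::create(_["samples"] = samples,
                      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
}
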