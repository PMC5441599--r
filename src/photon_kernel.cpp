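// Brownian-dynamics photon-proposal kernel.
//
// Each particle performs Gaussian steps in a periodic box centered on the
// focus; within a step the detection weight
// W = exp(-2(x^2+y^2)/w^2 - 2 z^2/(p w)^2) is held constant and proposal
// photons are drawn as Poisson counts with rate brightness * W, uniformly
// placed inside the step. Binary triplet/quench acceptance and
// antibunching are applied afterwards in R at the proposed times.
//
// Multi-resolution stepping: while a particle sits where W <= wmin it
// advances by `coarse` fine steps at once (step s.d. scaled by
// sqrt(coarse)); the Gaussian marginal is exact and no emission is lost
// beyond the negligible rate brightness * wmin. The coarse displacement
// is kept far smaller than the distance from the W = wmin shell to any
// region of appreciable weight, so grazing traversals are not missed.
//
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap(double x, double L) {
  // into [-L/2, L/2)
  return x - L * std::floor(x / L + 0.5);
}

// [[Rcpp::export]]
List photon_proposals_cpp(NumericMatrix pos0, int n_steps, double dt,
                          double sigma_step, NumericVector L, double w2,
                          double wz2, double brightness, double wmin,
                          int coarse) {
  const int n_part = pos0.nrow();
  if (coarse < 1) coarse = 1;
  const double sig_c = sigma_step * std::sqrt((double) coarse);
  std::vector<double> times;
  std::vector<int> particle;
  times.reserve(1024);
  particle.reserve(1024);
  for (int ip = 0; ip < n_part; ++ip) {
    double x = pos0(ip, 0), y = pos0(ip, 1), z = pos0(ip, 2);
    double W = std::exp(-2.0 * (x * x + y * y) / w2 - 2.0 * z * z / wz2);
    if (sigma_step > 0.0) {
      int s = 0;
      while (s < n_steps) {
        if (W > wmin) {
          x = wrap(x + norm_rand() * sigma_step, L[0]);
          y = wrap(y + norm_rand() * sigma_step, L[1]);
          z = wrap(z + norm_rand() * sigma_step, L[2]);
          W = std::exp(-2.0 * (x * x + y * y) / w2 - 2.0 * z * z / wz2);
          if (W > wmin) {
            int n = (int) R::rpois(brightness * W * dt);
            for (int j = 0; j < n; ++j) {
              times.push_back((s + unif_rand()) * dt);
              particle.push_back(ip + 1);
            }
          }
          ++s;
        } else {
          int k = std::min(coarse, n_steps - s);
          double f = (k == coarse) ? sig_c
                                   : sigma_step * std::sqrt((double) k);
          x = wrap(x + norm_rand() * f, L[0]);
          y = wrap(y + norm_rand() * f, L[1]);
          z = wrap(z + norm_rand() * f, L[2]);
          W = std::exp(-2.0 * (x * x + y * y) / w2 - 2.0 * z * z / wz2);
          s += k;
        }
      }
    } else {
      if (W <= wmin) continue;
      for (int s = 0; s < n_steps; ++s) {
        int n = (int) R::rpois(brightness * W * dt);
        for (int j = 0; j < n; ++j) {
          times.push_back((s + unif_rand()) * dt);
          particle.push_back(ip + 1);
        }
      }
    }
  }
  return List::create(_["time_s"] = NumericVector(times.begin(), times.end()),
                      _["particle"] = IntegerVector(particle.begin(),
                                                    particle.end()));
}
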