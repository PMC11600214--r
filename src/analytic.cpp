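// Well-tempered metadynamics of a single particle in an analytic
// quasi-1D double well V(x, y) = b (x^2 - 1)^2 + ky y^2.  The particle
// coordinates serve directly as the two collective variables, so this
// fixture exercises the hill-deposition and FES-estimation machinery
// against a landscape whose barrier (b, at the saddle (0, 0)) is known
// exactly.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double KB = 0.008314;

// [[Rcpp::export]]
List cpp_metad_double_well(double barrier, double ky, int n_steps,
                           double dt, double temperature, double gamma,
                           int seed, int stride, double height0,
                           double width, double bias_factor, double mass) {
  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double x = -1.0, y = 0.0; // start in the left basin
  double v0 = std::sqrt(KB * temperature / mass);
  double vx = v0 * gauss(rng), vy = v0 * gauss(rng);
  double kbdT = KB * (bias_factor - 1.0) * temperature;
  double iw2 = 1.0 / (width * width);

  std::vector<double> hc1, hc2, hh, hstep;
  std::vector<double> txs, tys;

  auto bias_grad = [&](double s1, double s2, double* g1, double* g2) {
    double v = 0.0, d1 = 0.0, d2 = 0.0;
    for (size_t k = 0; k < hh.size(); ++k) {
      double u1 = s1 - hc1[k], u2 = s2 - hc2[k];
      double e = hh[k] * std::exp(-0.5 * (u1 * u1 + u2 * u2) * iw2);
      v += e;
      d1 += -e * u1 * iw2;
      d2 += -e * u2 * iw2;
    }
    if (g1) *g1 = d1;
    if (g2) *g2 = d2;
    return v;
  };

  auto force = [&](double px, double py, double* fx, double* fy) {
    // physical force
    *fx = -4.0 * barrier * px * (px * px - 1.0);
    *fy = -2.0 * ky * py;
    double g1, g2;
    bias_grad(px, py, &g1, &g2);
    *fx -= g1;
    *fy -= g2;
  };

  double fx, fy;
  force(x, y, &fx, &fy);
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * KB * temperature / mass);

  for (int step = 1; step <= n_steps; ++step) {
    vx += 0.5 * dt * fx / mass; vy += 0.5 * dt * fy / mass;
    x += 0.5 * dt * vx; y += 0.5 * dt * vy;
    vx = c1 * vx + c2 * gauss(rng);
    vy = c1 * vy + c2 * gauss(rng);
    x += 0.5 * dt * vx; y += 0.5 * dt * vy;
    if (step % stride == 0) {
      double vb = bias_grad(x, y, nullptr, nullptr);
      double h = height0 * std::exp(-vb / kbdT);
      hc1.push_back(x); hc2.push_back(y); hh.push_back(h);
      hstep.push_back(step);
    }
    force(x, y, &fx, &fy);
    vx += 0.5 * dt * fx / mass; vy += 0.5 * dt * fy / mass;
    if (step % 100 == 0) { txs.push_back(x); tys.push_back(y); }
    if (step % 50000 == 0) Rcpp::checkUserInterrupt();
  }

  arma::mat hills(hh.size(), 6);
  for (size_t k = 0; k < hh.size(); ++k) {
    hills(k, 0) = hstep[k];
    hills(k, 1) = hc1[k];
    hills(k, 2) = hc2[k];
    hills(k, 3) = width;
    hills(k, 4) = width;
    hills(k, 5) = hh[k];
  }
  return List::create(_["hills"] = wrap(hills),
                      _["cv1"] = wrap(txs), _["cv2"] = wrap(tys));
}
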