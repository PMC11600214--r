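// Pathway search on a gridded 2D free-energy surface: nudged elastic
// band with randomly initialized beads, and a Metropolis-accepted
// stochastic walk over grid cells.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Bilinear interpolation of a grid field at (x, y); grid nodes at
// xg[i], yg[j]; F is n1 x n2 with rows indexing xg.  Points are
// clamped to the domain.
static double bilin(const arma::mat& F, const arma::vec& xg,
                    const arma::vec& yg, double x, double y) {
  const int n1 = F.n_rows, n2 = F.n_cols;
  double dx = xg(1) - xg(0), dy = yg(1) - yg(0);
  double u = (x - xg(0)) / dx, v = (y - yg(0)) / dy;
  u = std::min(std::max(u, 0.0), double(n1 - 1) - 1e-9);
  v = std::min(std::max(v, 0.0), double(n2 - 1) - 1e-9);
  int i = int(u), j = int(v);
  double fu = u - i, fv = v - j;
  return F(i, j) * (1 - fu) * (1 - fv) + F(i + 1, j) * fu * (1 - fv) +
         F(i, j + 1) * (1 - fu) * fv + F(i + 1, j + 1) * fu * fv;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix Fg, NumericVector xg,
                           NumericVector yg, NumericVector x,
                           NumericVector y) {
  arma::mat F(Fg.begin(), Fg.nrow(), Fg.ncol());
  arma::vec xv(xg.begin(), xg.size()), yv(yg.begin(), yg.size());
  int n = x.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = bilin(F, xv, yv, x[k], y[k]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_neb(NumericMatrix Fg, NumericVector xg, NumericVector yg,
                      double sx, double sy, double ex, double ey,
                      double k_spring, int n_beads, int iters, int seed) {
  arma::mat F(Fg.begin(), Fg.nrow(), Fg.ncol());
  arma::vec xv(xg.begin(), xg.size()), yv(yg.begin(), yg.size());
  const int n1 = F.n_rows, n2 = F.n_cols;
  double dx = xv(1) - xv(0), dy = yv(1) - yv(0);
  double cell = std::min(dx, dy);

  // gradient fields by central differences
  arma::mat Gx(n1, n2), Gy(n1, n2);
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j) {
      int im = std::max(i - 1, 0), ip = std::min(i + 1, n1 - 1);
      int jm = std::max(j - 1, 0), jp = std::min(j + 1, n2 - 1);
      Gx(i, j) = (F(ip, j) - F(im, j)) / ((ip - im) * dx);
      Gy(i, j) = (F(i, jp) - F(i, jm)) / ((jp - jm) * dy);
    }
  double f0 = arma::mean(arma::mean(arma::abs(Gx))) +
              arma::mean(arma::mean(arma::abs(Gy))) + k_spring * cell;
  f0 = std::max(f0, 1e-8);

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> ux(xv(0), xv(n1 - 1));
  std::uniform_real_distribution<double> uy(yv(0), yv(n2 - 1));
  arma::mat B(n_beads, 2);
  B(0, 0) = sx; B(0, 1) = sy;
  B(n_beads - 1, 0) = ex; B(n_beads - 1, 1) = ey;
  for (int b = 1; b < n_beads - 1; ++b) {
    B(b, 0) = ux(rng);
    B(b, 1) = uy(rng);
  }

  arma::mat Fnew = B;
  for (int it = 0; it < iters; ++it) {
    // step budget: full 0.25-cell steps for the first half, then
    // a linear decay so beads settle
    double eta = 0.25 * cell;
    if (it > iters / 2)
      eta *= std::max(0.05, 1.0 - double(it - iters / 2) /
                                double(iters / 2 + 1));
    for (int b = 1; b < n_beads - 1; ++b) {
      double gx = bilin(Gx, xv, yv, B(b, 0), B(b, 1));
      double gy = bilin(Gy, xv, yv, B(b, 0), B(b, 1));
      double tx = B(b + 1, 0) - B(b - 1, 0);
      double ty = B(b + 1, 1) - B(b - 1, 1);
      double tn = std::sqrt(tx * tx + ty * ty);
      if (tn > 1e-12) { tx /= tn; ty /= tn; }
      // landscape force perpendicular to the path
      double gpar = gx * tx + gy * ty;
      double fx = -(gx - gpar * tx);
      double fy = -(gy - gpar * ty);
      // plain springs (straighten kinked paths on flat regions)
      fx += k_spring * (B(b + 1, 0) - 2 * B(b, 0) + B(b - 1, 0));
      fy += k_spring * (B(b + 1, 1) - 2 * B(b, 1) + B(b - 1, 1));
      double fn = std::sqrt(fx * fx + fy * fy);
      double lr = eta / std::max(fn, f0);
      double nx = B(b, 0) + lr * fx;
      double ny = B(b, 1) + lr * fy;
      Fnew(b, 0) = std::min(std::max(nx, xv(0)), xv(n1 - 1));
      Fnew(b, 1) = std::min(std::max(ny, yv(0)), yv(n2 - 1));
    }
    B = Fnew;
  }
  return wrap(B);
}

// Metropolis-accepted random walk over 4-connected grid cells from
// (si, sj) to (ei, ej); returns the loop-pruned path of 0-based cell
// indices, or a 0 x 2 matrix when the end is not reached.
// [[Rcpp::export]]
IntegerMatrix cpp_walk(NumericMatrix Fg, int si, int sj, int ei, int ej,
                       double kT, int max_steps, int seed) {
  arma::mat F(Fg.begin(), Fg.nrow(), Fg.ncol());
  const int n1 = F.n_rows, n2 = F.n_cols;
  std::mt19937_64 rng(seed);
  std::uniform_int_distribution<int> u4(0, 3);
  std::uniform_real_distribution<double> u01(0.0, 1.0);
  const int di[4] = {1, -1, 0, 0};
  const int dj[4] = {0, 0, 1, -1};

  // current loop-free path + on-path position index per cell
  std::vector<int> pi, pj;
  arma::imat onpath(n1, n2);
  onpath.fill(-1);
  pi.push_back(si); pj.push_back(sj);
  onpath(si, sj) = 0;
  int ci = si, cj = sj;
  bool found = (si == ei && sj == ej);

  for (int step = 0; step < max_steps && !found; ++step) {
    int m = u4(rng);
    int ni = ci + di[m], nj = cj + dj[m];
    if (ni < 0 || ni >= n1 || nj < 0 || nj >= n2) continue;
    double dG = F(ni, nj) - F(ci, cj);
    if (dG > 0.0 && u01(rng) >= std::exp(-dG / kT)) continue;
    // accepted
    if (onpath(ni, nj) >= 0) {
      // revisit: truncate the loop
      int pos = onpath(ni, nj);
      for (size_t t = pos + 1; t < pi.size(); ++t)
        onpath(pi[t], pj[t]) = -1;
      pi.resize(pos + 1);
      pj.resize(pos + 1);
    } else {
      pi.push_back(ni); pj.push_back(nj);
      onpath(ni, nj) = int(pi.size()) - 1;
    }
    ci = ni; cj = nj;
    if (ci == ei && cj == ej) found = true;
  }
  if (!found) return IntegerMatrix(0, 2);
  IntegerMatrix out(pi.size(), 2);
  for (size_t t = 0; t < pi.size(); ++t) {
    out(t, 0) = pi[t];
    out(t, 1) = pj[t];
  }
  return out;
}
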