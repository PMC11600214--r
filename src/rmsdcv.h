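#ifndef PATHCG_RMSDCV_H
#define PATHCG_RMSDCV_H

#include <RcppArmadillo.h>

// Best-fit (Kabsch) RMSD between coords X (N x 3) and a reference
// (N x 3), plus the analytic gradient dRMSD/dX evaluated at the
// optimal superposition (rotation/centroid derivative terms vanish
// there).  Coordinates in nm.
inline double kabsch_rmsd_grad(const arma::mat& X, const arma::mat& ref,
                               arma::mat* grad) {
  const arma::uword n = X.n_rows;
  arma::rowvec cx = arma::mean(X, 0);
  arma::rowvec cr = arma::mean(ref, 0);
  arma::mat Xc = X.each_row() - cx;
  arma::mat Rc = ref.each_row() - cr;
  arma::mat H = Rc.t() * Xc;            // 3 x 3
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U) * arma::det(V) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat rot = U * D * V.t();        // rotates Xc frame: Rc * rot' ?
  // fitted reference in the frame of X: Rc_rot = Rc * (U D V^T) maps ref->X
  arma::mat Rfit = Rc * rot;
  arma::mat diff = Xc - Rfit;
  double msd = arma::accu(arma::square(diff)) / double(n);
  double rmsd = std::sqrt(std::max(msd, 0.0));
  if (grad) {
    if (rmsd > 1e-12) {
      *grad = diff / (double(n) * rmsd);
    } else {
      grad->zeros(n, 3);
    }
  }
  return rmsd;
}

#endif
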