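// Kabsch-superposed RMSD kernels.
//
// Frames are passed as an n_frames x (3 * n_atoms) matrix, each row holding
// (x1, y1, z1, x2, y2, z2, ...) of one frame in nm. Every RMSD is computed
// after optimal least-squares rigid-body superposition (Kabsch): with
// centered 3 x n coordinate blocks A, B and the SVD of A B^T,
// msd = (tr A^T A + tr B^T B - 2 (s1 + s2 +/- s3)) / n_atoms,
// the sign of s3 flipping when the optimal rotation would be improper.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Center each frame and return per-frame 3 x n blocks plus their squared
// norms.
static void prepare(const arma::mat& X, std::vector<arma::mat>& blocks,
                    arma::vec& ssq) {
  const arma::uword nf = X.n_rows;
  const arma::uword na = X.n_cols / 3;
  blocks.resize(nf);
  ssq.set_size(nf);
  for (arma::uword f = 0; f < nf; ++f) {
    arma::mat A(3, na);
    for (arma::uword a = 0; a < na; ++a) {
      A(0, a) = X(f, 3 * a);
      A(1, a) = X(f, 3 * a + 1);
      A(2, a) = X(f, 3 * a + 2);
    }
    A.each_col() -= arma::mean(A, 1);
    blocks[f] = A;
    ssq(f) = arma::accu(A % A);
  }
}

static double kabsch_msd(const arma::mat& A, double ga, const arma::mat& B,
                         double gb) {
  arma::mat H = A * B.t();
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in RMSD kernel");
  double sign = (arma::det(U) * arma::det(V) < 0.0) ? -1.0 : 1.0;
  double best = s(0) + s(1) + sign * s(2);
  double msd = (ga + gb - 2.0 * best) / A.n_cols;
  return msd > 0.0 ? msd : 0.0;
}

// [[Rcpp::export]]
double rmsd_pair_cpp(const arma::rowvec& a, const arma::rowvec& b) {
  arma::mat X = arma::join_cols(arma::mat(a), arma::mat(b));
  std::vector<arma::mat> blocks;
  arma::vec ssq;
  prepare(X, blocks, ssq);
  return std::sqrt(kabsch_msd(blocks[0], ssq(0), blocks[1], ssq(1)));
}

// [[Rcpp::export]]
arma::mat rmsd_pairwise_cpp(const arma::mat& X) {
  std::vector<arma::mat> blocks;
  arma::vec ssq;
  prepare(X, blocks, ssq);
  const arma::uword n = X.n_rows;
  arma::mat D(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i + 1 < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      double r = std::sqrt(kabsch_msd(blocks[i], ssq(i), blocks[j], ssq(j)));
      D(i, j) = r;
      D(j, i) = r;
    }
  }
  return D;
}

// [[Rcpp::export]]
arma::mat rmsd_cross_cpp(const arma::mat& X, const arma::mat& Y) {
  if (X.n_cols != Y.n_cols) Rcpp::stop("atom-count mismatch");
  std::vector<arma::mat> bx, by;
  arma::vec sx, sy;
  prepare(X, bx, sx);
  prepare(Y, by, sy);
  arma::mat D(X.n_rows, Y.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    for (arma::uword j = 0; j < Y.n_rows; ++j) {
      D(i, j) = std::sqrt(kabsch_msd(bx[i], sx(i), by[j], sy(j)));
    }
  }
  return D;
}

// RMSD only for requested (i, j) index pairs (1-based), for pivot-pruned
// single linkage at larger frame counts.
// [[Rcpp::export]]
arma::vec rmsd_pairs_cpp(const arma::mat& X, const arma::uvec& i,
                         const arma::uvec& j) {
  if (i.n_elem != j.n_elem) Rcpp::stop("index length mismatch");
  std::vector<arma::mat> blocks;
  arma::vec ssq;
  prepare(X, blocks, ssq);
  arma::vec out(i.n_elem);
  for (arma::uword k = 0; k < i.n_elem; ++k) {
    arma::uword a = i(k) - 1, b = j(k) - 1;
    if (a >= X.n_rows || b >= X.n_rows) Rcpp::stop("index out of range");
    out(k) = std::sqrt(kabsch_msd(blocks[a], ssq(a), blocks[b], ssq(b)));
  }
  return out;
}
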