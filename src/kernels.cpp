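// Numerical kernels: Gaussian-bead Fourier transforms, the grid-approximated
// orientation-marginalized likelihood with backpropagation, and a dense
// linear-assignment solver. All hot loops of the package live here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// rho_hat(k) = h * exp(-|k|^2 / (2 w^2)) * sum_i exp(+i k . y_i)
// K: P x 3 (A^-1), Y: m x 3 (A). Sign convention: exp(+i k.y).
// [[Rcpp::export]]
arma::cx_vec cpp_structure_factor(const arma::mat& K, const arma::mat& Y,
                                  double h, double w) {
  const uword P = K.n_rows, m = Y.n_rows;
  vec k2 = sum(square(K), 1);
  vec env = h * exp(-k2 / (2.0 * w * w));
  vec Sr(P, fill::zeros), Si(P, fill::zeros);
  for (uword i = 0; i < m; ++i) {
    vec ph = K * Y.row(i).t();
    Sr += cos(ph);
    Si += sin(ph);
  }
  return cx_vec(env % Sr, env % Si);
}

// [[Rcpp::export]]
arma::vec cpp_intensity(const arma::mat& K, const arma::mat& Y,
                        double h, double w) {
  cx_vec F = cpp_structure_factor(K, Y, h, w);
  return square(abs(F));
}

// rho(r) = sum_i h (w/sqrt(2 pi))^3 exp(-w^2 |r - y_i|^2 / 2)
// [[Rcpp::export]]
arma::vec cpp_density(const arma::mat& R, const arma::mat& Y,
                      double h, double w) {
  const uword P = R.n_rows, m = Y.n_rows;
  const double pref = h * std::pow(w / std::sqrt(2.0 * M_PI), 3);
  vec out(P, fill::zeros);
  for (uword i = 0; i < m; ++i) {
    vec d2(P, fill::zeros);
    for (uword d = 0; d < 3; ++d)
      d2 += square(R.col(d) - Y(i, d));
    out += exp(-0.5 * w * w * d2);
  }
  return pref * out;
}

// Adjoint of the intensity map: given per-point weights g_p, accumulate
// sum_p g_p dI(k_p)/dy_i with dI/dy_i = -2 env(k) Im(conj(F) e^{i k.y_i}) k.
// Returns m x 3.
// [[Rcpp::export]]
arma::mat cpp_grad_intensity_adjoint(const arma::mat& K, const arma::mat& Y,
                                     double h, double w, const arma::vec& g) {
  const uword m = Y.n_rows;
  vec k2 = sum(square(K), 1);
  vec env = h * exp(-k2 / (2.0 * w * w));
  cx_vec F = cpp_structure_factor(K, Y, h, w);
  vec Fr = real(F), Fi = imag(F);
  mat grad(m, 3, fill::zeros);
  for (uword i = 0; i < m; ++i) {
    vec ph = K * Y.row(i).t();
    // Im(conj(F) e^{i ph}) = Fr sin(ph) - Fi cos(ph)
    vec t = g % env % (Fr % sin(ph) - Fi % cos(ph));
    for (uword d = 0; d < 3; ++d)
      grad(i, d) = -2.0 * dot(t, K.col(d));
  }
  return grad;
}

// Orientation-marginalized log-likelihood of a batch of photon-list images on
// precomputed intensity maps, with optional backpropagated adjoint dL/dI.
//
//   L_j = log sum_{l,s'} exp( log w_l - I0 lambda_l - log n_s
//                             + sum_i log I(r_i, s_i (+) s', l) )
//
// I: cube (n_r x n_s x n_R); a: n_r x n_s cell areas; photons of image j are
// pr/ps[ptr[j] .. ptr[j+1]-1], 0-based cell indices. Zero intensity cells give
// -Inf terms; an image whose every (l, s') term is -Inf yields L_j = -Inf and
// grad_ok = FALSE (the corresponding responsibilities are zero elsewhere, so
// no flooring is needed: zero-responsibility terms are skipped exactly).
// [[Rcpp::export]]
List cpp_batch_loglik(const arma::cube& I, const arma::vec& logw,
                      const arma::vec& lambda, double I0, const arma::mat& a,
                      const arma::ivec& pr, const arma::ivec& ps,
                      const arma::ivec& ptr, bool want_grad) {
  const uword n_r = I.n_rows, n_s = I.n_cols, nR = I.n_slices;
  const uword N = ptr.n_elem - 1;
  if (logw.n_elem != nR || lambda.n_elem != nR)
    stop("quadrature size mismatch with intensity maps");
  cube logI = log(I);  // -Inf where I == 0, by design
  vec base = logw - I0 * lambda - std::log((double)n_s);
  vec per(N);
  double total = 0.0;
  bool grad_ok = true;
  cube G;
  if (want_grad) G.zeros(n_r, n_s, nR);
  vec gsum_l(nR, fill::zeros);
  mat T(n_s, nR);  // T(s', l); column l contiguous
  for (uword j = 0; j < N; ++j) {
    const sword lo = ptr[j], hi = ptr[j + 1];
    for (uword l = 0; l < nR; ++l) T.col(l).fill(base[l]);
    for (sword idx = lo; idx < hi; ++idx) {
      const uword r = pr[idx], s = ps[idx];
      for (uword l = 0; l < nR; ++l) {
        const double* sl = logI.slice_memptr(l) + r;  // stride n_r over s
        double* Tc = T.colptr(l);
        uword c = s;
        for (uword sp = 0; sp < n_s; ++sp) {
          Tc[sp] += sl[n_r * c];
          if (++c == n_s) c = 0;
        }
      }
    }
    const double M = T.max();
    if (!std::isfinite(M)) {
      per[j] = -datum::inf;
      total = -datum::inf;
      grad_ok = false;
      continue;
    }
    // single exp pass, in place; terms below exp(-36) are lost to double
    // rounding in the sum anyway, so skipping them is exact to roundoff
    double Z = 0.0;
    double* Tm = T.memptr();
    const uword nel = T.n_elem;
    for (uword e = 0; e < nel; ++e) {
      const double d = Tm[e] - M;
      const double v = (d > -36.0) ? std::exp(d) : 0.0;
      Tm[e] = v;  // T now holds unnormalized responsibilities
      Z += v;
    }
    const double Lj = M + std::log(Z);
    per[j] = Lj;
    total += Lj;
    if (want_grad) {
      for (sword idx = lo; idx < hi; ++idx) {
        const uword r = pr[idx], s = ps[idx];
        for (uword l = 0; l < nR; ++l) {
          const double* Tc = T.colptr(l);
          const double* Isl = I.slice_memptr(l) + r;
          double* Gsl = G.slice_memptr(l) + r;
          uword c = s;
          for (uword sp = 0; sp < n_s; ++sp) {
            const double g = Tc[sp];
            if (g > 0.0) Gsl[n_r * c] += g / (Z * Isl[n_r * c]);
            if (++c == n_s) c = 0;
          }
        }
      }
      gsum_l += sum(T, 0).t() / Z;
    }
  }
  if (want_grad) {
    for (uword l = 0; l < nR; ++l)
      G.slice(l) -= I0 * gsum_l[l] * a;
    if (!grad_ok) G.reset();
  }
  return List::create(_["total"] = total, _["per_image"] = per,
                      _["G"] = G, _["grad_ok"] = grad_ok);
}

// Dense min-cost perfect matching (Jonker-Volgenant style shortest augmenting
// paths with potentials, O(n^3)). Returns 1-based column for each row.
// [[Rcpp::export]]
List cpp_lap(const arma::mat& cost) {
  const int n = cost.n_rows;
  if ((int)cost.n_cols != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector match(n);
  double tot = 0.0;
  for (int j = 1; j <= n; ++j) {
    match[p[j] - 1] = j;
    tot += cost(p[j] - 1, j - 1);
  }
  return List::create(_["assignment"] = match, _["cost"] = tot);
}
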