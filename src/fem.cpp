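// Invertible tetrahedral FEM kernels: rotation-invariant SVD stress,
// element energy / internal force / stiffness assembly (CSR), and a
// Jacobi-preconditioned conjugate gradient solver.
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Constitutive evaluation floor on stretches: small enough that the
// volumetric log barrier still grows steeply before the floor engages,
// so crushed/inverted elements always push back via the linear
// extrapolation below it.
static const double SIG_CLAMP = 1e-4;

// F = U diag(s) V^T with det(U) = det(V) = +1; at most one negative
// singular value, placed last (invertible-FEM convention).
static void svd_rv(const arma::mat& F, arma::mat& U, arma::vec& s, arma::mat& V) {
  arma::svd(U, s, V, F, "std");
  if (arma::det(U) < 0.0) { U.col(2) *= -1.0; s(2) *= -1.0; }
  if (arma::det(V) < 0.0) { V.col(2) *= -1.0; s(2) *= -1.0; }
}

// [[Rcpp::export]]
List svd_rv_cpp(NumericMatrix Fm) {
  arma::mat F(Fm.begin(), 3, 3, true);
  arma::mat U, V; arma::vec s;
  svd_rv(F, U, s, V);
  return List::create(_["U"] = U, _["d"] = s, _["V"] = V);
}

// Energy, principal-stress gradient g_i = dPsi/ds_i and Hessian
// A_ij = d2Psi/ds_i ds_j of the compressible energy
//   Psi_dev(s) - mu_v ln J + lam/2 (ln J)^2 + [J<1] k (1-J)^3
// code: 0 = NH (p1 = mu), 1 = MR (p1 = C1, p2 = C2), 2 = Ogden1
// (p1 = mu1, p2 = alpha1). Stretches floored at SIG_CLAMP so inverted
// or collapsed elements still produce finite extrapolated stresses.
static void psi_principal(int code, double p1, double p2, double mu_v,
                          double lam, double kcomp, const arma::vec& s_in,
                          double& psi, arma::vec& g, arma::mat& A) {
  arma::vec s(3);
  for (int i = 0; i < 3; ++i) s(i) = std::max(s_in(i), SIG_CLAMP);
  g.zeros(3); A.zeros(3, 3);
  psi = 0.0;
  if (code == 0) { // neo-Hookean
    psi = 0.5 * p1 * (arma::dot(s, s) - 3.0);
    for (int i = 0; i < 3; ++i) { g(i) = p1 * s(i); A(i, i) = p1; }
  } else if (code == 1) { // Mooney-Rivlin
    arma::vec s2 = arma::square(s);
    double I1 = arma::accu(s2);
    double I2 = s2(0) * s2(1) + s2(1) * s2(2) + s2(2) * s2(0);
    psi = p1 * (I1 - 3.0) + p2 * (I2 - 3.0);
    for (int i = 0; i < 3; ++i) {
      double other = I1 - s2(i);
      g(i) = 2.0 * p1 * s(i) + 2.0 * p2 * s(i) * other;
      A(i, i) = 2.0 * p1 + 2.0 * p2 * other;
      for (int j = 0; j < 3; ++j) if (j != i) A(i, j) = 4.0 * p2 * s(i) * s(j);
    }
  } else { // one-term Ogden
    double a = p2;
    psi = p1 / a * (std::pow(s(0), a) + std::pow(s(1), a) + std::pow(s(2), a) - 3.0);
    for (int i = 0; i < 3; ++i) {
      g(i) = p1 * std::pow(s(i), a - 1.0);
      A(i, i) = p1 * (a - 1.0) * std::pow(s(i), a - 2.0);
    }
  }
  double J = s(0) * s(1) * s(2);
  double lnJ = std::log(J);
  psi += -mu_v * lnJ + 0.5 * lam * lnJ * lnJ;
  for (int i = 0; i < 3; ++i) {
    g(i) += (-mu_v + lam * lnJ) / s(i);
    A(i, i) += (mu_v - lam * lnJ) / (s(i) * s(i));
    for (int j = 0; j < 3; ++j) A(i, j) += lam / (s(i) * s(j));
  }
  if (kcomp > 0.0 && J < 1.0) {
    double om = 1.0 - J;
    psi += kcomp * om * om * om;
    for (int i = 0; i < 3; ++i) {
      g(i) += -3.0 * kcomp * om * om * J / s(i);
      A(i, i) += 3.0 * kcomp * om * om * J / (s(i) * s(i));
      for (int j = 0; j < 3; ++j)
        A(i, j) += -3.0 * kcomp * om * (1.0 - 3.0 * J) * J / (s(i) * s(j));
    }
  }
  // linear energy extrapolation below the stretch floor keeps the
  // potential consistent with the (constant) extrapolated stress there
  for (int i = 0; i < 3; ++i)
    if (s_in(i) < SIG_CLAMP) psi += g(i) * (s_in(i) - SIG_CLAMP);
}

// [[Rcpp::export]]
List psi_principal_cpp(int code, double p1, double p2, double mu_v,
                       double lam, double kcomp, NumericVector s) {
  arma::vec sv(s.begin(), 3, true);
  double psi; arma::vec g; arma::mat A;
  psi_principal(code, p1, p2, mu_v, lam, kcomp, sv, psi, g, A);
  return List::create(_["psi"] = psi, _["g"] = g, _["A"] = A);
}

// [[Rcpp::export]]
NumericMatrix first_pk_cpp(int code, double p1, double p2, double mu_v,
                           double lam, double kcomp, NumericMatrix Fm) {
  arma::mat F(Fm.begin(), 3, 3, true);
  arma::mat U, V; arma::vec s;
  svd_rv(F, U, s, V);
  double psi; arma::vec g; arma::mat A;
  psi_principal(code, p1, p2, mu_v, lam, kcomp, s, psi, g, A);
  arma::mat P = U * arma::diagmat(g) * V.t();
  return wrap(P);
}

// ---------------------------------------------------------------- setup
// [[Rcpp::export]]
List fem_setup_cpp(NumericMatrix nodes, IntegerMatrix tets) {
  int n = nodes.nrow(), m = tets.nrow();
  NumericMatrix Bm(m, 9);
  NumericVector vol(m);
  for (int e = 0; e < m; ++e) {
    arma::mat Dm(3, 3);
    int i0 = tets(e, 0) - 1;
    for (int c = 0; c < 3; ++c) {
      int ic = tets(e, c + 1) - 1;
      for (int r = 0; r < 3; ++r) Dm(r, c) = nodes(ic, r) - nodes(i0, r);
    }
    double det = arma::det(Dm);
    if (det <= 0.0) stop("element %d is degenerate or inverted at rest", e + 1);
    vol[e] = det / 6.0;
    arma::mat B = arma::inv(Dm);
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) Bm(e, 3 * r + c) = B(r, c);
  }
  // block sparsity over node pairs
  std::vector<long long> pairs;
  pairs.reserve((size_t)m * 16);
  for (int e = 0; e < m; ++e)
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b)
        pairs.push_back((long long)(tets(e, a) - 1) * n + (tets(e, b) - 1));
  std::vector<long long> uniq(pairs);
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  int nnzb = (int)uniq.size();
  IntegerVector brow_ptr(n + 1), bcol(nnzb), blk_row(nnzb), blk_pos(nnzb);
  {
    int k = 0;
    for (int i = 0; i < n; ++i) {
      brow_ptr[i] = k;
      int start = k;
      while (k < nnzb && uniq[k] / n == i) {
        bcol[k] = (int)(uniq[k] % n);
        blk_row[k] = i;
        blk_pos[k] = k - start;
        ++k;
      }
    }
    brow_ptr[n] = nnzb;
  }
  // per-element map to block ids
  IntegerVector map16(m * 16);
  for (int e = 0; e < m; ++e)
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        long long key = (long long)(tets(e, a) - 1) * n + (tets(e, b) - 1);
        int id = (int)(std::lower_bound(uniq.begin(), uniq.end(), key) - uniq.begin());
        map16[e * 16 + 4 * a + b] = id;
      }
  // scalar CSR layout
  int N = 3 * n, nnz = 9 * nnzb;
  IntegerVector row_ptr(N + 1), col_ind(nnz), row_of(nnz);
  for (int i = 0; i < n; ++i) {
    int nb = brow_ptr[i + 1] - brow_ptr[i];
    for (int a = 0; a < 3; ++a) row_ptr[3 * i + a + 1] = 3 * nb;
  }
  for (int r = 0; r < N; ++r) row_ptr[r + 1] += row_ptr[r];
  for (int bi = 0; bi < nnzb; ++bi) {
    int i = blk_row[bi], k = blk_pos[bi], j = bcol[bi];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        int idx = row_ptr[3 * i + a] + 3 * k + b;
        col_ind[idx] = 3 * j + b;
        row_of[idx] = 3 * i + a;
      }
  }
  IntegerVector diag_idx(N);
  for (int r = 0; r < N; ++r) {
    diag_idx[r] = -1;
    for (int idx = row_ptr[r]; idx < row_ptr[r + 1]; ++idx)
      if (col_ind[idx] == r) { diag_idx[r] = idx; break; }
  }
  return List::create(_["Bm"] = Bm, _["vol"] = vol, _["map16"] = map16,
                      _["blk_row"] = blk_row, _["blk_pos"] = blk_pos,
                      _["row_ptr"] = row_ptr, _["col_ind"] = col_ind,
                      _["row_of"] = row_of, _["diag_idx"] = diag_idx,
                      _["n"] = n, _["m"] = m);
}

// ------------------------------------------------------------- assembly
// [[Rcpp::export]]
List fem_assemble_cpp(List setup, NumericMatrix nodes, IntegerMatrix tets,
                      NumericVector u, IntegerVector matcode,
                      NumericMatrix matpars, bool clamp, bool want_K) {
  NumericMatrix Bm = setup["Bm"];
  NumericVector vol = setup["vol"];
  IntegerVector map16 = setup["map16"];
  IntegerVector blk_row = setup["blk_row"], blk_pos = setup["blk_pos"];
  IntegerVector row_ptr = setup["row_ptr"];
  int n = setup["n"], m = setup["m"];
  int nnz = 9 * blk_row.size();
  NumericVector grad(3 * n), Kvals(want_K ? nnz : 0);
  double energy = 0.0;

  arma::mat U, V; arma::vec s;
  for (int e = 0; e < m; ++e) {
    int idx[4];
    for (int a = 0; a < 4; ++a) idx[a] = tets(e, a) - 1;
    arma::mat B(3, 3);
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) B(r, c) = Bm(e, 3 * r + c);
    arma::mat Ds(3, 3);
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        Ds(r, c) = (nodes(idx[c + 1], r) + u[3 * idx[c + 1] + r]) -
                   (nodes(idx[0], r) + u[3 * idx[0] + r]);
    arma::mat F = Ds * B;
    svd_rv(F, U, s, V);
    int code = matcode[e];
    double psi; arma::vec g; arma::mat A;
    psi_principal(code, matpars(e, 0), matpars(e, 1), matpars(e, 2),
                  matpars(e, 3), matpars(e, 4), s, psi, g, A);
    double ve = vol[e];
    energy += ve * psi;
    arma::mat P = U * arma::diagmat(g) * V.t();
    arma::mat H = ve * P * B.t(); // columns: dE/dx for nodes 1..3
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) {
        grad[3 * idx[c + 1] + r] += H(r, c);
        grad[3 * idx[0] + r] -= H(r, c);
      }
    if (!want_K) continue;

    // shape-row vectors W_p (dF = e_b outer W_p for node p, coord b)
    arma::mat W(4, 3);
    for (int q = 0; q < 3; ++q) W.row(q + 1) = B.row(q);
    W.row(0) = -(B.row(0) + B.row(1) + B.row(2));

    // pairwise coefficients in the diagonal frame
    double asym[3][3], brot[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = i + 1; j < 3; ++j) {
        double e_sym, e_rot;
        double ds = s(i) - s(j);
        if (std::fabs(ds) > 1e-6 * std::max(1.0, std::fabs(s(i))))
          e_sym = (g(i) - g(j)) / ds;
        else
          e_sym = A(i, i) - A(i, j); // limit for coincident stretches
        double sum = s(i) + s(j);
        if (std::fabs(sum) < 1e-8) sum = (sum >= 0 ? 1e-8 : -1e-8);
        e_rot = (g(i) + g(j)) / sum;
        if (clamp) { e_sym = std::max(e_sym, 0.0); e_rot = std::max(e_rot, 0.0); }
        asym[i][j] = 0.5 * (e_sym + e_rot);
        brot[i][j] = 0.5 * (e_sym - e_rot);
      }
    arma::mat Ac = A;
    if (clamp) { // project the diagonal 3x3 block to PSD
      arma::vec eval; arma::mat evec;
      arma::eig_sym(eval, evec, 0.5 * (A + A.t()));
      for (int i = 0; i < 3; ++i) eval(i) = std::max(eval(i), 0.0);
      Ac = evec * arma::diagmat(eval) * evec.t();
    }

    // 12x12 element stiffness, column by column
    double Ke[12][12];
    for (int p = 0; p < 4; ++p)
      for (int b = 0; b < 3; ++b) {
        // dFhat = (U^T e_b) outer (W_p V)
        arma::vec ub = U.row(b).t();
        arma::rowvec wv = W.row(p) * V;
        arma::mat dFh = ub * wv;
        arma::mat dPh(3, 3, arma::fill::zeros);
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) dPh(i, i) += Ac(i, j) * dFh(j, j);
        for (int i = 0; i < 3; ++i)
          for (int j = i + 1; j < 3; ++j) {
            dPh(i, j) = asym[i][j] * dFh(i, j) + brot[i][j] * dFh(j, i);
            dPh(j, i) = brot[i][j] * dFh(i, j) + asym[i][j] * dFh(j, i);
          }
        arma::mat dP = U * dPh * V.t();
        for (int r = 0; r < 4; ++r) {
          arma::vec col = ve * (dP * W.row(r).t());
          for (int a = 0; a < 3; ++a) Ke[3 * r + a][3 * p + b] = col(a);
        }
      }
    // scatter into CSR
    for (int a4 = 0; a4 < 4; ++a4)
      for (int b4 = 0; b4 < 4; ++b4) {
        int bid = map16[e * 16 + 4 * a4 + b4];
        int i = blk_row[bid], k = blk_pos[bid];
        for (int a = 0; a < 3; ++a) {
          int base = row_ptr[3 * i + a] + 3 * k;
          for (int b = 0; b < 3; ++b)
            Kvals[base + b] += Ke[3 * a4 + a][3 * b4 + b];
        }
      }
  }
  return List::create(_["energy"] = energy, _["grad"] = grad,
                      _["Kvals"] = Kvals);
}

// ------------------------------------------------------------- solvers
// [[Rcpp::export]]
NumericVector csr_matvec_cpp(IntegerVector row_ptr, IntegerVector col_ind,
                             NumericVector vals, NumericVector x) {
  int N = row_ptr.size() - 1;
  NumericVector y(N);
  for (int r = 0; r < N; ++r) {
    double acc = 0.0;
    for (int idx = row_ptr[r]; idx < row_ptr[r + 1]; ++idx)
      acc += vals[idx] * x[col_ind[idx]];
    y[r] = acc;
  }
  return y;
}

// Conjugate gradient with a block-Jacobi (3x3 per node) preconditioner;
// falls back to scalar Jacobi for any singular diagonal block.
// [[Rcpp::export]]
List pcg_cpp(IntegerVector row_ptr, IntegerVector col_ind, NumericVector vals,
             NumericVector b, NumericVector x0, double tol, int maxit) {
  int N = row_ptr.size() - 1;
  int nb = N / 3;
  arma::vec x(x0.begin(), N), bb(b.begin(), N);
  // gather 3x3 diagonal blocks and invert
  std::vector<arma::mat33> Binv(nb);
  for (int q = 0; q < nb; ++q) {
    arma::mat33 B; B.zeros();
    for (int a = 0; a < 3; ++a) {
      int r = 3 * q + a;
      for (int idx = row_ptr[r]; idx < row_ptr[r + 1]; ++idx) {
        int c = col_ind[idx] - 3 * q;
        if (c >= 0 && c < 3) B(a, c) = vals[idx];
      }
    }
    arma::mat33 Bi;
    bool ok = arma::inv_sympd(Bi, arma::symmatu(B));
    if (!ok) {
      Bi.zeros();
      for (int a = 0; a < 3; ++a)
        Bi(a, a) = (std::fabs(B(a, a)) > 1e-300) ? 1.0 / B(a, a) : 1.0;
    }
    Binv[q] = Bi;
  }
  auto precond = [&](const arma::vec& r) {
    arma::vec z(N);
    for (int q = 0; q < nb; ++q) {
      arma::vec3 rq = {r(3 * q), r(3 * q + 1), r(3 * q + 2)};
      arma::vec3 zq = Binv[q] * rq;
      z(3 * q) = zq(0); z(3 * q + 1) = zq(1); z(3 * q + 2) = zq(2);
    }
    return z;
  };
  auto matvec = [&](const arma::vec& v) {
    arma::vec y(N);
    for (int r = 0; r < N; ++r) {
      double acc = 0.0;
      for (int idx = row_ptr[r]; idx < row_ptr[r + 1]; ++idx)
        acc += vals[idx] * v(col_ind[idx]);
      y(r) = acc;
    }
    return y;
  };
  double bnorm = arma::norm(bb);
  if (bnorm == 0.0)
    return List::create(_["x"] = NumericVector(N), _["iters"] = 0,
                        _["resid"] = 0.0, _["converged"] = true);
  arma::vec r = bb - matvec(x);
  arma::vec z = precond(r);
  arma::vec p = z;
  double rz = arma::dot(r, z);
  int it = 0;
  double rn = arma::norm(r) / bnorm;
  while (rn > tol && it < maxit) {
    arma::vec Ap = matvec(p);
    double alpha = rz / arma::dot(p, Ap);
    x += alpha * p;
    r -= alpha * Ap;
    rn = arma::norm(r) / bnorm;
    z = precond(r);
    double rz_new = arma::dot(r, z);
    p = z + (rz_new / rz) * p;
    rz = rz_new;
    ++it;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iters"] = it, _["resid"] = rn,
                      _["converged"] = rn <= tol);
}
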