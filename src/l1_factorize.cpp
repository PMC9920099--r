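#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve, for every row u of the target, the weighted least-squares problem
//   min_{beta >= 0} sum_k w_uk (x_uk - D_k. beta)^2
// where D (n x f) is the fixed factor matrix, Wt (m x n) holds the IRLS
// weights for the m row-problems and Xt (m x n) the corresponding data rows.
// The normal matrices B' diag(w_u) B are assembled for all rows at once from
// the matrix product Wt * U, with U the n x f(f+1)/2 matrix of columnwise
// products of D; only the small f x f solves remain in the loop.
static mat rowwise_wls(const mat& D, const mat& Wt, const mat& Xt,
                       const double ridge) {
  const uword m = Wt.n_rows;
  const uword f = D.n_cols;
  const uword npair = f * (f + 1) / 2;

  mat U(D.n_rows, npair);
  uword k = 0;
  for (uword p = 0; p < f; ++p)
    for (uword q = p; q < f; ++q)
      U.col(k++) = D.col(p) % D.col(q);

  const mat M   = Wt * U;          // m x npair packed normal matrices
  const mat RHS = (Wt % Xt) * D;   // m x f right-hand sides

  mat out(m, f);
  mat Mi(f, f);
  mat L(f, f);
  vec sol(f);
  for (uword i = 0; i < m; ++i) {
    k = 0;
    double tr = 0.0;
    for (uword p = 0; p < f; ++p)
      for (uword q = p; q < f; ++q) {
        Mi(p, q) = M(i, k);
        Mi(q, p) = M(i, k);
        if (p == q) tr += M(i, k);
        ++k;
      }
    // small ridge keeps dead factors / exact-fit weight blowups solvable
    const double lam = ridge * (tr / f + 1.0);
    for (uword p = 0; p < f; ++p) Mi(p, p) += lam;

    // in-place Cholesky; the systems are tiny, so a hand-rolled solve beats
    // the generic LAPACK dispatch by a wide margin
    bool ok = true;
    for (uword p = 0; p < f && ok; ++p) {
      double d = Mi(p, p);
      for (uword q = 0; q < p; ++q) d -= L(p, q) * L(p, q);
      if (d <= 0.0) { ok = false; break; }
      const double dp = std::sqrt(d);
      L(p, p) = dp;
      for (uword r = p + 1; r < f; ++r) {
        double s = Mi(r, p);
        for (uword q = 0; q < p; ++q) s -= L(r, q) * L(p, q);
        L(r, p) = s / dp;
      }
    }
    if (ok) {
      for (uword p = 0; p < f; ++p) {
        double s = RHS(i, p);
        for (uword q = 0; q < p; ++q) s -= L(p, q) * sol(q);
        sol(p) = s / L(p, p);
      }
      for (uword pp = f; pp-- > 0;) {
        double s = sol(pp);
        for (uword q = pp + 1; q < f; ++q) s -= L(q, pp) * sol(q);
        sol(pp) = s / L(pp, pp);
      }
    } else if (!solve(sol, Mi, RHS.row(i).t())) {
      sol = pinv(Mi) * RHS.row(i).t();
    }
    for (uword p = 0; p < f; ++p) out(i, p) = sol(p) > 0.0 ? sol(p) : 0.0;
  }
  return out;
}

static double l1_objective(const mat& X, const mat& A, const mat& B) {
  return accu(abs(X - A * B.t()));
}

// Alternating IRLS for  min_{A,B >= 0} || X - A B' ||_1 .
// One reweighting per factor matrix per outer sweep; the iterate with the
// lowest objective seen is returned, so the result can never be worse than
// the initialization.
// [[Rcpp::export(name = ".l1nn_core")]]
Rcpp::List l1nn_core(const arma::mat& X, const arma::mat& A0,
                     const arma::mat& B0, const double tol,
                     const int max_iter, const double eps_w) {
  mat A = A0;
  mat B = B0;

  double obj = l1_objective(X, A, B);
  std::vector<double> trace_v;
  trace_v.reserve(max_iter + 1);
  trace_v.push_back(obj);

  mat bestA = A, bestB = B;
  double best = obj;
  int stall = 0;
  int iters = 0;

  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;

    mat R = X - A * B.t();
    mat W = 1.0 / clamp(abs(R), eps_w, datum::inf);
    A = rowwise_wls(B, W, X, 1e-10);

    R = X - A * B.t();
    W = 1.0 / clamp(abs(R), eps_w, datum::inf);
    B = rowwise_wls(A, W.t(), X.t(), 1e-10);

    const double obj_new = l1_objective(X, A, B);
    trace_v.push_back(obj_new);

    if (obj_new < best) {
      best = obj_new;
      bestA = A;
      bestB = B;
      stall = 0;
    } else if (++stall >= 50) {
      break;
    }
    if (std::abs(obj - obj_new) <= tol * std::max(obj, 1e-12)) {
      obj = obj_new;
      break;
    }
    obj = obj_new;
  }

  return Rcpp::List::create(
      Rcpp::Named("A") = bestA,
      Rcpp::Named("B") = bestB,
      Rcpp::Named("objective") = best,
      Rcpp::Named("objective_trace") = trace_v,
      Rcpp::Named("iterations") = iters);
}

// Multiplicative reweighted updates for the same objective: each sweep
// majorizes the L1 loss by the IRLS-weighted quadratic and applies the
// multiplicative (Lee-Seung type) update of that quadratic,
//   A <- A * ((W % X) B) / ((W % (A B')) B)
// and symmetrically for B. Iterates stay strictly positive, so
// non-negativity never needs an explicit projection.
// [[Rcpp::export(name = ".l1nn_mu_core")]]
Rcpp::List l1nn_mu_core(const arma::mat& X, const arma::mat& A0,
                        const arma::mat& B0, const double tol,
                        const int max_iter, const double eps_w) {
  mat A = A0;
  mat B = B0;
  const uword I = X.n_rows, S = X.n_cols;
  const uword n = I * S;

  // preallocated work buffers; one fused pass computes the objective and
  // the IRLS-weighted copies of the data and the reconstruction
  mat R(I, S), WX(I, S), WR(I, S);
  mat num, den;
  const double tiny = 1e-300;

  auto weigh = [&](double& obj_out) {
    double o = 0.0;
    const double* x = X.memptr();
    const double* r = R.memptr();
    double* wx = WX.memptr();
    double* wr = WR.memptr();
    for (uword k = 0; k < n; ++k) {
      const double d = x[k] - r[k];
      const double ad = d < 0 ? -d : d;
      o += ad;
      const double w = 1.0 / (ad > eps_w ? ad : eps_w);
      wx[k] = w * x[k];
      wr[k] = w * r[k];
    }
    obj_out = o;
  };

  double obj;
  R = A * B.t();
  weigh(obj);
  std::vector<double> trace_v;
  trace_v.reserve(max_iter + 1);
  trace_v.push_back(obj);

  mat bestA = A, bestB = B;
  double best = obj;
  int stall = 0;
  int iters = 0;
  double obj_prev = obj;

  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;

    // A step uses the weights already computed for the current iterate
    num = WX * B;
    den = WR * B;
    A %= num / clamp(den, tiny, datum::inf);

    R = A * B.t();
    weigh(obj);
    num = WX.t() * A;
    den = WR.t() * A;
    B %= num / clamp(den, tiny, datum::inf);

    R = A * B.t();
    weigh(obj);
    trace_v.push_back(obj);

    if (obj < best) {
      best = obj;
      bestA = A;
      bestB = B;
      stall = 0;
    } else if (++stall >= 50) {
      break;
    }
    if (std::abs(obj_prev - obj) <= tol * std::max(obj_prev, 1e-12)) {
      break;
    }
    obj_prev = obj;
  }

  return Rcpp::List::create(
      Rcpp::Named("A") = bestA,
      Rcpp::Named("B") = bestB,
      Rcpp::Named("objective") = best,
      Rcpp::Named("objective_trace") = trace_v,
      Rcpp::Named("iterations") = iters);
}
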