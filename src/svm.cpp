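// Primal L2-regularized squared-hinge linear SVM (damped Newton), plus the
// inner-CV scoring loop used by sequential forward selection. These live in
// C++ because nested feature selection evaluates tens of thousands of small
// fits per cross-validation run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Z: n x (d+1) design with trailing intercept column. y in {-1,+1}.
// cw: per-row cost weights. Minimizes
//   0.5 * ||w||^2 + C * sum_i cw_i * max(0, 1 - y_i * z_i . theta)^2
// (intercept near-unregularized). Convex; damped Newton with halving
// line search converges in a handful of iterations at these sizes.
static vec fit_newton(const mat& Z, const vec& y, const vec& cw, double C,
                      int max_iter = 60, double tol = 1e-9) {
  const uword d = Z.n_cols;
  vec theta(d, fill::zeros);
  vec reg(d, fill::ones);
  reg(d - 1) = 1e-8;

  auto objective = [&](const vec& th) {
    vec r = 1.0 - y % (Z * th);
    r.transform([](double v) { return v > 0.0 ? v : 0.0; });
    return 0.5 * dot(reg % th, th) + C * dot(cw, r % r);
  };

  double obj = objective(theta);
  for (int it = 0; it < max_iter; ++it) {
    vec s = Z * theta;
    vec r = 1.0 - y % s;
    uvec A = find(r > 0.0);
    vec g = reg % theta;
    mat H = diagmat(reg);
    if (!A.is_empty()) {
      mat ZA = Z.rows(A);
      vec cA = cw(A);
      g -= 2.0 * C * (ZA.t() * (cA % y(A) % r(A)));
      H += 2.0 * C * (ZA.t() * (ZA.each_col() % cA));
    }
    if (norm(g, "inf") < tol) break;
    vec step;
    if (!solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
      step = g;  // fall back to gradient descent direction
    }
    double t = 1.0;
    bool moved = false;
    for (int ls = 0; ls < 40; ++ls) {
      vec th2 = theta - t * step;
      double obj2 = objective(th2);
      if (obj2 <= obj - 1e-14) {
        theta = th2;
        obj = obj2;
        moved = true;
        break;
      }
      t *= 0.5;
    }
    if (!moved) break;
  }
  return theta;
}

// [[Rcpp::export(name = ".svm_fit_cpp")]]
Rcpp::List svm_fit_cpp(const arma::mat& X, const arma::vec& y,
                       double C, const arma::vec& cw) {
  mat Z = join_rows(X, ones<vec>(X.n_rows));
  vec theta = fit_newton(Z, y, cw, C);
  return Rcpp::List::create(
      Rcpp::Named("w") = theta.head(X.n_cols),
      Rcpp::Named("b") = theta(X.n_cols));
}

// balanced accuracy of sign predictions
static double balanced_acc(const vec& score, const vec& y) {
  double tp = 0, fn = 0, tn = 0, fp = 0;
  for (uword i = 0; i < y.n_elem; ++i) {
    if (y(i) > 0) {
      if (score(i) > 0) tp++; else fn++;
    } else {
      if (score(i) <= 0) tn++; else fp++;
    }
  }
  double sens = (tp + fn) > 0 ? tp / (tp + fn) : 0.5;
  double spec = (tn + fp) > 0 ? tn / (tn + fp) : 0.5;
  return 0.5 * (sens + spec);
}

// Mean inner-CV balanced accuracy of the feature set
// [selected, candidate_j] for every candidate j. Standardization
// (population sd) is fit on each inner-training fold only; constant
// columns are dropped. fold: 1-based inner fold id per row.
// [[Rcpp::export(name = ".sfs_score_cpp")]]
arma::vec sfs_score_cpp(const arma::mat& X, const arma::vec& y,
                        const arma::uvec& selected,   // 1-based, may be empty
                        const arma::uvec& candidates, // 1-based
                        const arma::uvec& fold, double C) {
  const int k = fold.max();
  const uword nsel = selected.n_elem;
  vec out(candidates.n_elem, fill::zeros);

  // cache per-fold row indices and class weights
  std::vector<uvec> tr_rows(k), va_rows(k);
  std::vector<vec> cws(k);
  for (int f = 0; f < k; ++f) {
    tr_rows[f] = find(fold != (uword)(f + 1));
    va_rows[f] = find(fold == (uword)(f + 1));
    vec ytr = y(tr_rows[f]);
    double npos = accu(ytr > 0), nneg = accu(ytr < 0), n = ytr.n_elem;
    vec cw(ytr.n_elem);
    for (uword i = 0; i < ytr.n_elem; ++i)
      cw(i) = ytr(i) > 0 ? n / (2.0 * npos) : n / (2.0 * nneg);
    cws[f] = cw;
  }

  for (uword c = 0; c < candidates.n_elem; ++c) {
    uvec cols(nsel + 1);
    for (uword j = 0; j < nsel; ++j) cols(j) = selected(j) - 1;
    cols(nsel) = candidates(c) - 1;
    double acc = 0.0;
    int used = 0;
    for (int f = 0; f < k; ++f) {
      mat Xtr = X.submat(tr_rows[f], cols);
      mat Xva = X.submat(va_rows[f], cols);
      vec ytr = y(tr_rows[f]), yva = y(va_rows[f]);
      if (accu(ytr > 0) == 0 || accu(ytr < 0) == 0) continue;
      vec muv = mean(Xtr, 0).t();
      vec sdv = sqrt(mean(square(Xtr.each_row() - muv.t()), 0)).t();
      uvec keep = find(sdv > 0);
      if (keep.is_empty()) continue;
      mat Ztr = Xtr.cols(keep);
      Ztr.each_row() -= muv(keep).t();
      Ztr.each_row() /= sdv(keep).t();
      mat Zva = Xva.cols(keep);
      Zva.each_row() -= muv(keep).t();
      Zva.each_row() /= sdv(keep).t();
      mat Ztr1 = join_rows(Ztr, ones<vec>(Ztr.n_rows));
      vec theta = fit_newton(Ztr1, ytr, cws[f], C);
      vec sva = join_rows(Zva, ones<vec>(Zva.n_rows)) * theta;
      acc += balanced_acc(sva, yva);
      used++;
    }
    out(c) = used > 0 ? acc / used : -1.0;
  }
  return out;
}
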