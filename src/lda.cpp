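// Pooled-covariance linear discriminant classification.
//
// Equal class priors; an observation is assigned to the class whose mean
// minimizes the Mahalanobis distance under the pooled within-class
// covariance (ties broken by smallest class index). A fold whose pooled
// covariance is singular yields prediction -1; callers score such
// observations as misclassified. These loops sit inside the permutation
// tests (thousands of refits), hence C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static bool pooled_fit(const arma::mat& X, const arma::ivec& y,
                       const arma::uvec& train, int K,
                       arma::mat& means, arma::uvec& present,
                       arma::mat& Sinv) {
  const arma::uword p = X.n_cols;
  arma::mat sums(p, K, arma::fill::zeros);
  arma::vec counts(K, arma::fill::zeros);
  arma::mat scatter(p, p, arma::fill::zeros);
  for (arma::uword t = 0; t < train.n_elem; ++t) {
    const arma::uword i = train[t];
    const int c = y[i];
    sums.col(c) += X.row(i).t();
    counts[c] += 1.0;
  }
  present = arma::find(counts > 0);
  const int Kp = present.n_elem;
  if (Kp < 2) return false;
  means.set_size(p, Kp);
  for (int k = 0; k < Kp; ++k)
    means.col(k) = sums.col(present[k]) / counts[present[k]];
  for (arma::uword t = 0; t < train.n_elem; ++t) {
    const arma::uword i = train[t];
    int k = 0;
    while (present[k] != (arma::uword)y[i]) ++k;
    const arma::vec d = X.row(i).t() - means.col(k);
    scatter += d * d.t();
  }
  const double df = (double)train.n_elem - Kp;
  if (df < 1.0) return false;
  scatter /= df;
  return arma::inv_sympd(Sinv, scatter);
}

static int classify_one(const arma::vec& x, const arma::mat& means,
                        const arma::uvec& present, const arma::mat& Sinv) {
  int best = -1;
  double best_d = arma::datum::inf;
  for (arma::uword k = 0; k < present.n_elem; ++k) {
    const arma::vec d = x - means.col(k);
    const double dist = arma::as_scalar(d.t() * Sinv * d);
    if (dist < best_d) {  // strict: ties keep the smallest class index
      best_d = dist;
      best = (int)present[k];
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_lda_train_predict(const arma::mat& X,
                                    const arma::ivec& y,
                                    const arma::uvec& train,
                                    const arma::uvec& test,
                                    int K) {
  arma::mat means, Sinv;
  arma::uvec present;
  IntegerVector out(test.n_elem, -1);
  if (!pooled_fit(X, y, train, K, means, present, Sinv)) return out;
  for (arma::uword t = 0; t < test.n_elem; ++t)
    out[t] = classify_one(X.row(test[t]).t(), means, present, Sinv);
  return out;
}

// partial Fisher-Yates using R's RNG: first n_take entries of a random
// permutation of v (caller holds RNGScope via Rcpp attributes)
static void take_random(std::vector<int>& v, int n_take) {
  const int n = v.size();
  for (int i = 0; i < n_take; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(v[i], v[j]);
  }
}

// mean percentage of correctly cross-classified elements over balanced
// selections; cells = 1-based row indices per (subject x level) cell,
// n_train of each cell go to training, the rest to the cross-set
// [[Rcpp::export]]
double cpp_ncce_crossed(const arma::mat& X, const arma::ivec& y,
                        const List& cells, int n_train, int K,
                        int n_selections) {
  std::vector<std::vector<int>> cs;
  for (int c = 0; c < cells.size(); ++c) {
    IntegerVector v = cells[c];
    cs.emplace_back(v.begin(), v.end());
  }
  double mean_prop = 0.0;
  std::vector<int> train, cross;
  for (int s = 0; s < n_selections; ++s) {
    train.clear(); cross.clear();
    for (auto& cell : cs) {
      take_random(cell, n_train);
      for (size_t i = 0; i < cell.size(); ++i)
        (i < (size_t)n_train ? train : cross).push_back(cell[i] - 1);
    }
    arma::uvec tr(train.size()), cx(cross.size());
    for (size_t i = 0; i < train.size(); ++i) tr[i] = train[i];
    for (size_t i = 0; i < cross.size(); ++i) cx[i] = cross[i];
    arma::mat means, Sinv; arma::uvec present;
    int correct = 0;
    if (pooled_fit(X, y, tr, K, means, present, Sinv))
      for (arma::uword t = 0; t < cx.n_elem; ++t)
        if (classify_one(X.row(cx[t]).t(), means, present, Sinv) == y[cx[t]])
          ++correct;
    mean_prop += (double)correct / cross.size();
  }
  return 100.0 * mean_prop / n_selections;
}

// nested variant: level_units[l] is a list of per-subject 1-based call
// index vectors for test level l; n_train_units whole subjects per level
// go to training, the remaining subjects' calls form the cross-set
// [[Rcpp::export]]
double cpp_ncce_nested(const arma::mat& X, const arma::ivec& y,
                       const List& level_units, int n_train_units, int K,
                       int n_selections) {
  std::vector<std::vector<std::vector<int>>> lv;
  for (int l = 0; l < level_units.size(); ++l) {
    List subs = level_units[l];
    std::vector<std::vector<int>> u;
    for (int s = 0; s < subs.size(); ++s) {
      IntegerVector v = subs[s];
      u.emplace_back(v.begin(), v.end());
    }
    lv.push_back(u);
  }
  double mean_prop = 0.0;
  std::vector<int> train, cross, order;
  for (int s = 0; s < n_selections; ++s) {
    train.clear(); cross.clear();
    for (auto& units : lv) {
      order.resize(units.size());
      for (size_t i = 0; i < units.size(); ++i) order[i] = i;
      take_random(order, n_train_units);
      for (size_t i = 0; i < order.size(); ++i) {
        auto& dst = (i < (size_t)n_train_units ? train : cross);
        for (int ix : units[order[i]]) dst.push_back(ix - 1);
      }
    }
    arma::uvec tr(train.size()), cx(cross.size());
    for (size_t i = 0; i < train.size(); ++i) tr[i] = train[i];
    for (size_t i = 0; i < cross.size(); ++i) cx[i] = cross[i];
    arma::mat means, Sinv; arma::uvec present;
    int correct = 0;
    if (pooled_fit(X, y, tr, K, means, present, Sinv))
      for (arma::uword t = 0; t < cx.n_elem; ++t)
        if (classify_one(X.row(cx[t]).t(), means, present, Sinv) == y[cx[t]])
          ++correct;
    mean_prop += (double)correct / cross.size();
  }
  return 100.0 * mean_prop / n_selections;
}

// [[Rcpp::export]]
IntegerVector cpp_lda_loocv(const arma::mat& X, const arma::ivec& y, int K) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  IntegerVector out(n, -1);
  // totals, downdated per left-out observation
  arma::mat sums(p, K, arma::fill::zeros);
  arma::vec counts(K, arma::fill::zeros);
  std::vector<arma::mat> cross(K, arma::mat(p, p, arma::fill::zeros));
  for (arma::uword i = 0; i < n; ++i) {
    const arma::vec x = X.row(i).t();
    sums.col(y[i]) += x;
    counts[y[i]] += 1.0;
    cross[y[i]] += x * x.t();
  }
  for (arma::uword i = 0; i < n; ++i) {
    const arma::vec xi = X.row(i).t();
    const int c = y[i];
    sums.col(c) -= xi;
    counts[c] -= 1.0;
    cross[c] -= xi * xi.t();

    arma::uvec present = arma::find(counts > 0);
    const int Kp = present.n_elem;
    const double df = (double)(n - 1) - Kp;
    if (Kp >= 2 && df >= 1.0) {
      arma::mat means(p, Kp);
      arma::mat scatter(p, p, arma::fill::zeros);
      for (int k = 0; k < Kp; ++k) {
        const arma::uword cl = present[k];
        means.col(k) = sums.col(cl) / counts[cl];
        scatter += cross[cl] - counts[cl] * means.col(k) * means.col(k).t();
      }
      scatter /= df;
      arma::mat Sinv;
      if (arma::inv_sympd(Sinv, scatter))
        out[i] = classify_one(xi, means, present, Sinv);
    }
    sums.col(c) += xi;
    counts[c] += 1.0;
    cross[c] += xi * xi.t();
  }
  return out;
}
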