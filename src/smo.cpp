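// Soft-margin kernel SVM (C-SVC) trained by SMO with maximal-violating-pair
// working-set selection, plus kernel evaluation and a first-order Markov
// chain sequence sampler. The dual solved here is the standard
//   min 0.5 a'Qa - e'a  s.t.  y'a = 0, 0 <= a_t <= C_t,
// with Q_st = y_s y_t K(x_s, x_t) and per-example box C_t: positives get
// C * cost_ratio (the SVM_light "-j" convention), negatives C.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TAU = 1e-12;

// kernel codes: 0 = linear, 1 = polynomial (x.y + 1)^d, 2 = rbf
static arma::mat kernel_cross_mat(const arma::mat& X, const arma::mat& Y,
                                  int type, double degree, double gamma) {
  arma::mat G = X * Y.t();
  switch (type) {
  case 0:
    return G;
  case 1:
    return arma::pow(G + 1.0, degree);
  case 2: {
    arma::colvec xn = arma::sum(arma::square(X), 1);
    arma::colvec yn = arma::sum(arma::square(Y), 1);
    arma::mat D = arma::repmat(xn, 1, Y.n_rows) +
                  arma::repmat(yn.t(), X.n_rows, 1) - 2.0 * G;
    D.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    return arma::exp(-gamma * D);
  }
  default:
    stop("unknown kernel code");
  }
}

// [[Rcpp::export(name = ".kernel_cross")]]
arma::mat kernel_cross(const arma::mat& X, const arma::mat& Y,
                       int type, double degree, double gamma) {
  return kernel_cross_mat(X, Y, type, degree, gamma);
}

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(const arma::mat& X, const arma::vec& y,
               double C, double cost_ratio,
               int type, double degree, double gamma,
               double tol, int max_iter) {
  const int n = X.n_rows;
  arma::mat K = kernel_cross_mat(X, X, type, degree, gamma);
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n);
  G.fill(-1.0); // gradient of the dual at alpha = 0
  arma::vec Cbox(n);
  for (int t = 0; t < n; ++t) Cbox[t] = y[t] > 0 ? C * cost_ratio : C;

  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    // working-set selection: first order for i, second order for j
    int i = -1, j = -1;
    double m_up = -std::numeric_limits<double>::infinity();
    double m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up = (y[t] > 0 && alpha[t] < Cbox[t]) || (y[t] < 0 && alpha[t] > 0);
      if (in_up && v > m_up) { m_up = v; i = t; }
    }
    double best_gain = 0.0;
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] < 0 && alpha[t] < Cbox[t]) || (y[t] > 0 && alpha[t] > 0);
      if (!in_low) continue;
      double v = -y[t] * G[t];
      if (v < m_low) m_low = v;
      double b = m_up - v; // violation of the pair (i, t)
      if (b > 0 && i >= 0) {
        double a = K(i, i) + K(t, t) - 2.0 * y[i] * y[t] * K(i, t);
        if (a <= 0) a = TAU;
        double gain = b * b / a;
        if (gain > best_gain) { best_gain = gain; j = t; }
      }
    }
    if (i < 0 || j < 0 || m_up - m_low < tol) { converged = true; break; }

    double old_ai = alpha[i], old_aj = alpha[j];
    double Ci = Cbox[i], Cj = Cbox[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > Ci - Cj) { if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = Ci - diff; } }
      else                { if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = Cj + diff; } }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > Ci) { if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = sum - Ci; } }
      else          { if (alpha[j] < 0)  { alpha[j] = 0;  alpha[i] = sum; } }
      if (sum > Cj) { if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = sum - Cj; } }
      else          { if (alpha[i] < 0)  { alpha[i] = 0;  alpha[j] = sum; } }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
    ++iter;
  }

  // bias: f(x) = sum alpha_t y_t K(x_t, x) - rho
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0.0; int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= Cbox[t] - 1e-12) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++n_free; sum_free += yG;
    }
  }
  double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  arma::uvec sv = arma::find(alpha > 1e-12);
  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["sv_index"] = IntegerVector(sv.begin(), sv.end()), // 0-based
    _["rho"] = rho,
    _["iterations"] = iter,
    _["converged"] = converged);
}

// First-order Markov chain sampler over a 20-letter alphabet.
// init_cdf: cumulative initial distribution (length 20); trans_cdf: 20 x 20,
// row r = cumulative distribution of the successor of state r. Uses R's RNG
// so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".sample_chains")]]
CharacterVector sample_chains(NumericVector init_cdf, NumericMatrix trans_cdf,
                              IntegerVector lengths, CharacterVector alphabet) {
  const int K = init_cdf.size();
  const int n = lengths.size();
  std::vector<std::string> letters(K);
  for (int k = 0; k < K; ++k) letters[k] = as<std::string>(alphabet[k]);
  CharacterVector out(n);
  for (int s = 0; s < n; ++s) {
    int L = lengths[s];
    std::string seq;
    seq.reserve(L);
    int state = 0;
    double u = unif_rand();
    while (state < K - 1 && u > init_cdf[state]) ++state;
    seq += letters[state];
    for (int pos = 1; pos < L; ++pos) {
      u = unif_rand();
      int next = 0;
      while (next < K - 1 && u > trans_cdf(state, next)) ++next;
      seq += letters[next];
      state = next;
    }
    out[s] = seq;
  }
  return out;
}
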