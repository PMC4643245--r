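#include <Rcpp.h>
using namespace Rcpp;

// Counting-process Cox partial likelihood with Efron tie handling.
//
// Rows are (start, stop] intervals with an event flag and a case weight.
// The risk set at an event time t is {i : start_i < t <= stop_i}.  Event
// times are processed in decreasing order with two pointers: rows enter
// the tracked risk set when stop_i >= t (ord_add = rows sorted by stop
// descending) and leave when start_i >= t (ord_rem = rows sorted by start
// descending), so each row is added and removed exactly once.
//
// want = 0: loglik only; 1: + gradient and information; 2: + per-row
// score residuals (Efron-consistent, summing to the gradient), needed for
// the cluster-robust sandwich variance.
//
// Case weights on event rows use the weighted-Efron convention: the d
// tied deaths at a time generate d pseudo-events of weight mean(w_death),
// with denominators S0 - (j/d) * D0.
//
// [[Rcpp::export]]
List cox_engine_cpp(NumericMatrix X, NumericVector start, NumericVector stop,
                    IntegerVector event, NumericVector weight,
                    NumericVector beta,
                    IntegerVector ord_add, IntegerVector ord_rem,
                    IntegerVector death_ord, int want) {
  const int n = X.nrow(), p = X.ncol();
  const int nd = death_ord.size();

  // linear predictor, centered for numerical stability (loglik invariant)
  std::vector<double> eta(n), rw(n);
  double eta_mean = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
    eta[i] = s;
    eta_mean += s;
  }
  eta_mean /= std::max(n, 1);
  for (int i = 0; i < n; ++i) {
    eta[i] -= eta_mean;
    rw[i] = weight[i] * std::exp(eta[i]);
  }

  std::vector<double> S1(p, 0.0), S2(p * p, 0.0), G1(p, 0.0);
  double S0 = 0.0, G0 = 0.0;
  std::vector<double> D1(p), D2(p * p), M(p), c1(p), Msum(p);
  std::vector<char> in_set(n, 0);
  std::vector<double> a0, E0;
  NumericMatrix a1, E1, resid;
  if (want >= 2) {
    a0.assign(n, 0.0);
    E0.assign(n, 0.0);
    a1 = NumericMatrix(n, p);
    E1 = NumericMatrix(n, p);
    resid = NumericMatrix(n, p);
  }

  double loglik = 0.0;
  NumericVector grad(p);
  NumericMatrix info(p, p);
  int ia = 0, ir = 0, idp = 0, n_event_times = 0;
  double n_events = 0.0;

  while (idp < nd) {
    const double t = stop[death_ord[idp]];
    // admit rows with stop >= t
    while (ia < n && stop[ord_add[ia]] >= t) {
      const int i = ord_add[ia];
      in_set[i] = 1;
      S0 += rw[i];
      for (int j = 0; j < p; ++j) {
        S1[j] += rw[i] * X(i, j);
        for (int k = j; k < p; ++k) S2[j * p + k] += rw[i] * X(i, j) * X(i, k);
      }
      if (want >= 2) {
        a0[i] = G0;
        for (int j = 0; j < p; ++j) a1(i, j) = G1[j];
      }
      ++ia;
    }
    // retire rows with start >= t (no longer at risk)
    while (ir < n && start[ord_rem[ir]] >= t) {
      const int i = ord_rem[ir];
      if (in_set[i]) {
        in_set[i] = 0;
        S0 -= rw[i];
        for (int j = 0; j < p; ++j) {
          S1[j] -= rw[i] * X(i, j);
          for (int k = j; k < p; ++k) S2[j * p + k] -= rw[i] * X(i, j) * X(i, k);
        }
        if (want >= 2) {
          E0[i] += G0 - a0[i];
          for (int j = 0; j < p; ++j) E1(i, j) += G1[j] - a1(i, j);
        }
      }
      ++ir;
    }
    // collect the tied deaths at time t
    const int first_death = idp;
    double D0 = 0.0, sumw = 0.0;
    std::fill(D1.begin(), D1.end(), 0.0);
    std::fill(D2.begin(), D2.end(), 0.0);
    while (idp < nd && stop[death_ord[idp]] == t) {
      const int i = death_ord[idp];
      D0 += rw[i];
      sumw += weight[i];
      for (int j = 0; j < p; ++j) {
        D1[j] += rw[i] * X(i, j);
        for (int k = j; k < p; ++k) D2[j * p + k] += rw[i] * X(i, j) * X(i, k);
      }
      loglik += weight[i] * eta[i];
      for (int j = 0; j < p; ++j) grad[j] += weight[i] * X(i, j);
      ++idp;
    }
    const int d = idp - first_death;
    const double meanwt = sumw / d;
    n_events += sumw;
    ++n_event_times;

    double c0 = 0.0;
    std::fill(c1.begin(), c1.end(), 0.0);
    std::fill(Msum.begin(), Msum.end(), 0.0);
    for (int jj = 0; jj < d; ++jj) {
      const double f = (double)jj / d;
      const double R = S0 - f * D0;
      if (!(R > 0.0))
        Rcpp::stop("empty or degenerate risk set at event time %f", t);
      for (int j = 0; j < p; ++j) M[j] = (S1[j] - f * D1[j]) / R;
      loglik -= meanwt * std::log(R);
      for (int j = 0; j < p; ++j) {
        grad[j] -= meanwt * M[j];
        Msum[j] += meanwt * M[j];
      }
      if (want >= 1) {
        for (int j = 0; j < p; ++j)
          for (int k = j; k < p; ++k)
            info(j, k) += meanwt * ((S2[j * p + k] - f * D2[j * p + k]) / R -
                                    M[j] * M[k]);
      }
      if (want >= 2) {
        G0 += meanwt / R;
        c0 += f * meanwt / R;
        for (int j = 0; j < p; ++j) {
          G1[j] += meanwt * M[j] / R;
          c1[j] += f * meanwt * M[j] / R;
        }
      }
    }
    if (want >= 2) {
      // event part of the score residual, plus the Efron discount
      // correction to the exposure of the tied deaths themselves
      for (int q = first_death; q < idp; ++q) {
        const int i = death_ord[q];
        for (int j = 0; j < p; ++j)
          resid(i, j) += weight[i] * X(i, j) - Msum[j] / d +
            rw[i] * (c0 * X(i, j) - c1[j]);
      }
    }
  }

  if (want >= 2) {
    // flush exposure accumulated by rows still in the risk set, then
    // assemble resid = eventpart - rw * (E0 * x - E1)
    for (int i = 0; i < n; ++i) {
      if (in_set[i]) {
        E0[i] += G0 - a0[i];
        for (int j = 0; j < p; ++j) E1(i, j) += G1[j] - a1(i, j);
      }
      for (int j = 0; j < p; ++j)
        resid(i, j) -= rw[i] * (E0[i] * X(i, j) - E1(i, j));
    }
  }

  // mirror the symmetric information matrix
  if (want >= 1)
    for (int j = 0; j < p; ++j)
      for (int k = 0; k < j; ++k) info(j, k) = info(k, j);

  List out = List::create(_["loglik"] = loglik, _["grad"] = grad,
                          _["info"] = info, _["n_events"] = n_events,
                          _["n_event_times"] = n_event_times);
  if (want >= 2) out["resid"] = resid;
  return out;
}
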