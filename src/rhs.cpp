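#include <Rcpp.h>
using namespace Rcpp;

// Mass-action flux vector and state derivative for a reaction network.
// Sparse layout: for reaction r, reactant entries occupy [rptr[r], rptr[r+1])
// in (ridx, rcoef); likewise products in (pptr, pidx, pcoef). Indices 0-based.
// flux_r = kf_r * prod(y[reactants]^coef) - kr_r * prod(y[products]^coef);
// dy = S * flux with clamped species held at zero derivative.

static inline double powi(double base, double coef) {
  if (coef == 1.0) return base;
  if (coef == 2.0) return base * base;
  return std::pow(base, coef);
}

// [[Rcpp::export]]
NumericVector rhs_mass_action_cpp(NumericVector y,
                                  NumericVector kf, NumericVector kr,
                                  IntegerVector rptr, IntegerVector ridx,
                                  NumericVector rcoef,
                                  IntegerVector pptr, IntegerVector pidx,
                                  NumericVector pcoef,
                                  LogicalVector clamped) {
  const int nr = kf.size();
  const int ns = y.size();
  NumericVector dy(ns);
  for (int r = 0; r < nr; ++r) {
    double fwd = kf[r];
    if (fwd != 0.0)
      for (int j = rptr[r]; j < rptr[r + 1]; ++j) fwd *= powi(y[ridx[j]], rcoef[j]);
    double rev = kr[r];
    if (rev != 0.0)
      for (int j = pptr[r]; j < pptr[r + 1]; ++j) rev *= powi(y[pidx[j]], pcoef[j]);
    const double v = fwd - rev;
    if (v == 0.0) continue;
    for (int j = rptr[r]; j < rptr[r + 1]; ++j) dy[ridx[j]] -= rcoef[j] * v;
    for (int j = pptr[r]; j < pptr[r + 1]; ++j) dy[pidx[j]] += pcoef[j] * v;
  }
  for (int i = 0; i < ns; ++i)
    if (clamped[i]) dy[i] = 0.0;
  return dy;
}

// [[Rcpp::export]]
NumericVector flux_mass_action_cpp(NumericVector y,
                                   NumericVector kf, NumericVector kr,
                                   IntegerVector rptr, IntegerVector ridx,
                                   NumericVector rcoef,
                                   IntegerVector pptr, IntegerVector pidx,
                                   NumericVector pcoef) {
  const int nr = kf.size();
  NumericVector v(nr);
  for (int r = 0; r < nr; ++r) {
    double fwd = kf[r];
    if (fwd != 0.0)
      for (int j = rptr[r]; j < rptr[r + 1]; ++j) fwd *= powi(y[ridx[j]], rcoef[j]);
    double rev = kr[r];
    if (rev != 0.0)
      for (int j = pptr[r]; j < pptr[r + 1]; ++j) rev *= powi(y[pidx[j]], pcoef[j]);
    v[r] = fwd - rev;
  }
  return v;
}

// Analytic Jacobian of the mass-action RHS: J[i][j] = d(dy_i)/d(y_j).
// For reaction r with forward rate kf*prod(y^a): d(fwd)/dy_j =
// kf * a_j * y_j^(a_j-1) * prod_{k!=j} y_k^a_k (zero when y_j = 0 and
// a_j > 1); likewise for the reverse term over products. Clamped species
// contribute zero rows.
// [[Rcpp::export]]
NumericMatrix jac_mass_action_cpp(NumericVector y,
                                  NumericVector kf, NumericVector kr,
                                  IntegerVector rptr, IntegerVector ridx,
                                  NumericVector rcoef,
                                  IntegerVector pptr, IntegerVector pidx,
                                  NumericVector pcoef,
                                  LogicalVector clamped) {
  const int nr = kf.size();
  const int ns = y.size();
  NumericMatrix J(ns, ns);
  for (int r = 0; r < nr; ++r) {
    // forward partials
    if (kf[r] != 0.0) {
      for (int j = rptr[r]; j < rptr[r + 1]; ++j) {
        const int sj = ridx[j];
        double d = kf[r] * rcoef[j];
        if (rcoef[j] != 1.0) d *= powi(y[sj], rcoef[j] - 1.0);
        for (int k = rptr[r]; k < rptr[r + 1]; ++k) {
          if (k == j) continue;
          d *= powi(y[ridx[k]], rcoef[k]);
        }
        if (d == 0.0) continue;
        for (int k = rptr[r]; k < rptr[r + 1]; ++k)
          J(ridx[k], sj) -= rcoef[k] * d;
        for (int k = pptr[r]; k < pptr[r + 1]; ++k)
          J(pidx[k], sj) += pcoef[k] * d;
      }
    }
    // reverse partials (flux enters with minus sign)
    if (kr[r] != 0.0) {
      for (int j = pptr[r]; j < pptr[r + 1]; ++j) {
        const int sj = pidx[j];
        double d = kr[r] * pcoef[j];
        if (pcoef[j] != 1.0) d *= powi(y[sj], pcoef[j] - 1.0);
        for (int k = pptr[r]; k < pptr[r + 1]; ++k) {
          if (k == j) continue;
          d *= powi(y[pidx[k]], pcoef[k]);
        }
        if (d == 0.0) continue;
        for (int k = rptr[r]; k < rptr[r + 1]; ++k)
          J(ridx[k], sj) += rcoef[k] * d;
        for (int k = pptr[r]; k < pptr[r + 1]; ++k)
          J(pidx[k], sj) -= pcoef[k] * d;
      }
    }
  }
  for (int i = 0; i < ns; ++i)
    if (clamped[i])
      for (int j = 0; j < ns; ++j) J(i, j) = 0.0;
  return J;
}
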