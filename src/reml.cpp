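// REML criterion and analytic gradient for the two longitudinal models.
//
// Both models have block-diagonal (by subject) marginal covariance and a
// fixed-effect design profiled out by generalized least squares:
//
//   volume model:  y_ijk = alpha_i + (beta + b_i) t_ij + d_ij + e_ijk
//     V_i = sb2 * t t' + sd2 * [same visit] + se2 * I
//     X   = per-subject intercepts + common slope t  (arrow-structured X'V^-1 X)
//
//   direct-change model:  c_p = (beta + b_i) dt_p - u_start + u_end
//                               - v_start + v_end + w_p
//     V_i = sb2 * dt dt' + su2 * Su Su' + sv2 * Sv Sv' + sw2 * I
//     X   = dt (single slope column)
//
// The criterion is -2 * restricted log-likelihood:
//   sum_i log|V_i| + log|X'V^-1 X| + r'V^-1 r + (n - p) log(2 pi)
// and its gradient w.r.t. a variance component s2 (with dV the derivative
// of V) is  tr(P dV) - (Py)' dV (Py),  P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1,
// evaluated blockwise.

#include <RcppArmadillo.h>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// [[Rcpp::export]]
List volume_reml_cpp(List subjects, double sb2, double sd2, double se2) {
  const int m = subjects.size();
  double logdetV = 0.0, s_tt = 0.0, b_slope = 0.0, yVy = 0.0;
  double sum_log_a = 0.0, sum_c2a = 0.0, sum_cba = 0.0, sum_b2a = 0.0;
  int n = 0;

  arma::vec a(m), cc(m), ba(m);
  arma::field<arma::mat> Vinv_f(m), W_f(m);

  for (int i = 0; i < m; ++i) {
    List sub = subjects[i];
    arma::vec t = sub["t"];
    arma::ivec vis = sub["visit"];
    arma::vec y = sub["y"];
    const int ni = t.n_elem;
    n += ni;

    arma::mat V = sb2 * (t * t.t());
    for (int r = 0; r < ni; ++r) {
      for (int c = 0; c <= r; ++c) {
        if (vis[r] == vis[c]) { V(r, c) += sd2; if (r != c) V(c, r) += sd2; }
      }
      V(r, r) += se2;
    }

    arma::mat L;
    if (!arma::chol(L, V, "lower")) return List::create(Named("ok") = false);
    logdetV += 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat Vinv = arma::inv_sympd(V);

    arma::mat B(ni, 3);
    B.col(0).ones(); B.col(1) = t; B.col(2) = y;
    arma::mat W = Vinv * B;
    Vinv_f(i) = Vinv; W_f(i) = W;

    const double ai = arma::dot(B.col(0), W.col(0));
    const double ci = arma::dot(B.col(0), W.col(1));
    const double bi = arma::dot(B.col(0), W.col(2));
    if (ai <= 0.0) return List::create(Named("ok") = false);
    a[i] = ai; cc[i] = ci; ba[i] = bi;
    s_tt += arma::dot(B.col(1), W.col(1));
    b_slope += arma::dot(B.col(1), W.col(2));
    yVy += arma::dot(B.col(2), W.col(2));
    sum_log_a += std::log(ai);
    sum_c2a += ci * ci / ai;
    sum_cba += ci * bi / ai;
    sum_b2a += bi * bi / ai;
  }

  const double D = s_tt - sum_c2a; // Schur complement for the slope
  if (!(D > 0.0)) return List::create(Named("ok") = false);
  const double beta = (b_slope - sum_cba) / D;
  const double logdetA = sum_log_a + std::log(D);
  const double quad = yVy - sum_b2a - D * beta * beta;
  const int p = m + 1;
  const double crit = logdetV + logdetA + quad + (n - p) * LOG2PI;

  // gradient pass: per-subject traces and quadratic forms
  arma::vec alpha(m), grad(3, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    alpha[i] = (ba[i] - cc[i] * beta) / a[i];

    List sub = subjects[i];
    arma::vec t = sub["t"];
    arma::ivec vis = sub["visit"];
    const arma::mat& Vinv = Vinv_f(i);
    const arma::mat& W = W_f(i);
    arma::vec q1 = W.col(0), q2 = W.col(1);
    arma::vec vr = W.col(2) - alpha[i] * q1 - beta * q2; // V^-1 residual

    // 2x2 block of (X'V^-1 X)^-1 for (alpha_i, beta)
    const double A11 = 1.0 / a[i] + cc[i] * cc[i] / (a[i] * a[i] * D);
    const double A12 = -cc[i] / (a[i] * D);
    const double A22 = 1.0 / D;

    // tr(P dV) terms need, for each dV, the forms x'V^-1 dV V^-1 x for
    // x in {1, t} and tr(V^-1 dV).
    // dV = t t' (sb2):
    {
      const double tq1 = arma::dot(t, q1), tq2 = arma::dot(t, q2);
      const double trV = tq2; // tr(V^-1 t t') = t' V^-1 t
      const double red = A11 * tq1 * tq1 + 2.0 * A12 * tq1 * tq2 +
                         A22 * tq2 * tq2;
      const double qf = std::pow(arma::dot(t, vr), 2);
      grad[0] += trV - red - qf;
    }
    // dV = same-visit indicator blocks (sd2): sum over visits j of z_j z_j'
    {
      double trV = 0.0, red = 0.0, qf = 0.0;
      arma::ivec uv = arma::unique(vis);
      for (arma::uword j = 0; j < uv.n_elem; ++j) {
        arma::uvec ix = arma::find(vis == uv[j]);
        trV += arma::accu(Vinv.submat(ix, ix));
        const double z1 = arma::accu(q1.elem(ix));
        const double z2 = arma::accu(q2.elem(ix));
        red += A11 * z1 * z1 + 2.0 * A12 * z1 * z2 + A22 * z2 * z2;
        const double zr = arma::accu(vr.elem(ix));
        qf += zr * zr;
      }
      grad[1] += trV - red - qf;
    }
    // dV = I (se2):
    {
      const double trV = arma::trace(Vinv);
      const double red = A11 * arma::dot(q1, q1) +
                         2.0 * A12 * arma::dot(q1, q2) +
                         A22 * arma::dot(q2, q2);
      const double qf = arma::dot(vr, vr);
      grad[2] += trV - red - qf;
    }
  }

  return List::create(Named("ok") = true, Named("crit") = crit,
                      Named("grad") = grad, Named("beta") = beta,
                      Named("se_beta") = std::sqrt(1.0 / D),
                      Named("alpha") = alpha,
                      Named("n") = n, Named("p") = p);
}

// [[Rcpp::export]]
List direct_reml_cpp(List subjects, double sb2, double su2, double sv2,
                     double sw2) {
  const int m = subjects.size();
  double logdetV = 0.0, s = 0.0, b = 0.0, yVy = 0.0;
  int n = 0;
  arma::field<arma::mat> Vinv_f(m);
  arma::field<arma::vec> q1_f(m), q2_f(m);

  for (int i = 0; i < m; ++i) {
    List sub = subjects[i];
    arma::vec dt = sub["dt"];
    arma::mat Su = sub["Su"]; // n_pairs x n_visits signed incidence
    arma::mat Sv = sub["Sv"]; // n_pairs x n_scans signed incidence
    arma::vec y = sub["y"];
    const int ni = dt.n_elem;
    n += ni;

    arma::mat V = sb2 * (dt * dt.t()) + su2 * (Su * Su.t()) +
                  sv2 * (Sv * Sv.t());
    V.diag() += sw2;

    arma::mat L;
    if (!arma::chol(L, V, "lower")) return List::create(Named("ok") = false);
    logdetV += 2.0 * arma::accu(arma::log(L.diag()));
    arma::mat Vinv = arma::inv_sympd(V);
    arma::vec q1 = Vinv * dt, q2 = Vinv * y;
    Vinv_f(i) = Vinv; q1_f(i) = q1; q2_f(i) = q2;

    s += arma::dot(dt, q1);
    b += arma::dot(dt, q2);
    yVy += arma::dot(y, q2);
  }

  if (!(s > 0.0)) return List::create(Named("ok") = false);
  const double beta = b / s;
  const double quad = yVy - b * b / s;
  const double crit = logdetV + std::log(s) + quad + (n - 1) * LOG2PI;

  arma::vec grad(4, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    List sub = subjects[i];
    arma::vec dt = sub["dt"];
    arma::mat Su = sub["Su"];
    arma::mat Sv = sub["Sv"];
    const arma::mat& Vinv = Vinv_f(i);
    const arma::vec& q1 = q1_f(i);
    arma::vec vr = q2_f(i) - beta * q1;

    // dV = dt dt'
    {
      const double dq1 = arma::dot(dt, q1);
      grad[0] += dq1 - dq1 * dq1 / s - std::pow(arma::dot(dt, vr), 2);
    }
    // dV = Su Su'
    {
      arma::mat SuV = Su.t() * Vinv * Su; // small: visits x visits
      arma::vec su_q1 = Su.t() * q1, su_vr = Su.t() * vr;
      grad[1] += arma::trace(SuV) - arma::dot(su_q1, su_q1) / s -
                 arma::dot(su_vr, su_vr);
    }
    // dV = Sv Sv'
    {
      arma::mat SvV = Sv.t() * Vinv * Sv;
      arma::vec sv_q1 = Sv.t() * q1, sv_vr = Sv.t() * vr;
      grad[2] += arma::trace(SvV) - arma::dot(sv_q1, sv_q1) / s -
                 arma::dot(sv_vr, sv_vr);
    }
    // dV = I
    grad[3] += arma::trace(Vinv) - arma::dot(q1, q1) / s - arma::dot(vr, vr);
  }

  return List::create(Named("ok") = true, Named("crit") = crit,
                      Named("grad") = grad, Named("beta") = beta,
                      Named("se_beta") = std::sqrt(1.0 / s),
                      Named("n") = n, Named("p") = 1);
}
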