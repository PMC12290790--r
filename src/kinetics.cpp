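// Analytic compartment-model solutions on a uniform time grid, frame
// averaging, and the Metropolis sweep over per-TAC latent log-parameters
// used by the hierarchical sampler. The input function is treated as
// piecewise linear between grid points; the exponential convolution
// I(t) = [cp (x) exp(-theta t)](t) is then exact per segment
// (exponential-integrator recursion), and its running time-integral is
// obtained exactly from the identity dI/dt = cp - theta I, i.e.
// int_0^T I = (int_0^T cp - I(T)) / theta. Frame averages computed from
// these running integrals are therefore exact for the piecewise-linear
// input: accuracy is limited only by how well the grid sampling
// represents the input curve itself.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// cumulative trapezoid: exact integral of the piecewise-linear curve
static arma::vec cumint_linear(const arma::vec& x, double dt) {
  const int n = x.n_elem;
  arma::vec F(n, arma::fill::zeros);
  for (int i = 1; i < n; ++i)
    F[i] = F[i - 1] + 0.5 * dt * (x[i] + x[i - 1]);
  return F;
}

// I(t_i) and its exact running integral CI(t_i)
static void conv_exp2(const arma::vec& cp, const arma::vec& Fcp, double dt,
                      double theta, arma::vec& I, arma::vec& CI) {
  const int n = cp.n_elem;
  I.zeros(n);
  CI.zeros(n);
  double E, J0, J1;
  const double x = theta * dt;
  if (x < 1e-9) {          // series limit, avoids 0/0
    E = std::exp(-x);
    J0 = dt * (1.0 - 0.5 * x);
    J1 = 0.5 * dt * dt * (1.0 - x / 3.0);
  } else {
    E = std::exp(-x);
    J0 = -std::expm1(-x) / theta;
    J1 = (dt - J0) / theta;
  }
  for (int i = 1; i < n; ++i) {
    const double a = cp[i - 1];
    const double b = (cp[i] - cp[i - 1]) / dt;
    I[i] = I[i - 1] * E + a * J0 + b * J1;
  }
  if (theta > 1e-12) {
    for (int i = 1; i < n; ++i) CI[i] = (Fcp[i] - I[i]) / theta;
  } else {
    // theta ~ 0: I ~ running integral of cp, CI its second integral
    CI = cumint_linear(I, dt);
  }
}

// frame averages from a curve and its exact running integral; frame
// boundaries that do not fall on grid nodes are handled by local
// trapezoid interpolation of the partial segment
static arma::vec frames_from_integral(const arma::vec& curve,
                                      const arma::vec& F, double dt,
                                      const arma::vec& fstart,
                                      const arma::vec& fdur) {
  const int n = curve.n_elem;
  const double tmax = (n - 1) * dt;
  auto Fat = [&](double t) -> double {
    if (t <= 0.0) return 0.0;
    if (t >= tmax) return F[n - 1];
    const double g = t / dt;
    int i = (int)std::floor(g + 1e-9);
    double fr = g - i;
    if (fr < 1e-9) return F[i];
    const double c0 = curve[i], c1 = curve[i + 1];
    const double ct = c0 + fr * (c1 - c0);
    return F[i] + 0.5 * fr * dt * (c0 + ct);
  };
  const int nf = fstart.n_elem;
  arma::vec out(nf);
  for (int f = 0; f < nf; ++f) {
    const double a = fstart[f], b = fstart[f] + fdur[f];
    out[f] = (Fat(b) - Fat(a)) / fdur[f];
  }
  return out;
}

struct Tcm2Sol {
  arma::vec curve, F;
};

static Tcm2Sol tcm2_solve(double K1, double k2, double k3, double k4,
                          double vB, const arma::vec& cp,
                          const arma::vec& Fcp, const arma::vec& wb,
                          const arma::vec& Fwb, double dt) {
  const double sum = k2 + k3 + k4;
  double disc = sum * sum - 4.0 * k2 * k4;
  if (disc < 0.0) disc = 0.0;           // impossible for positive rates; guard
  double root = std::sqrt(disc);
  if (root < 1e-12 * sum + 1e-300) root = 1e-12 * sum + 1e-300;
  const double th1 = 0.5 * (sum + root);
  const double th2 = 0.5 * (sum - root);
  const double phi1 = K1 * (th1 - k3 - k4) / root;
  const double phi2 = K1 * (k3 + k4 - th2) / root;
  arma::vec I1, CI1, I2, CI2;
  conv_exp2(cp, Fcp, dt, th1, I1, CI1);
  conv_exp2(cp, Fcp, dt, th2, I2, CI2);
  Tcm2Sol s;
  s.curve = (1.0 - vB) * (phi1 * I1 + phi2 * I2) + vB * wb;
  s.F = (1.0 - vB) * (phi1 * CI1 + phi2 * CI2) + vB * Fwb;
  return s;
}

// [[Rcpp::export]]
arma::vec tcm2_curve_cpp(double K1, double k2, double k3, double k4,
                         double vB, const arma::vec& cp,
                         const arma::vec& wb, double dt) {
  Tcm2Sol s = tcm2_solve(K1, k2, k3, k4, vB, cp, cumint_linear(cp, dt),
                         wb, cumint_linear(wb, dt), dt);
  return s.curve;
}

// [[Rcpp::export]]
arma::vec tcm2_frames_rates_cpp(double K1, double k2, double k3,
                                double k4, double vB, const arma::vec& cp,
                                const arma::vec& wb, double dt,
                                const arma::vec& fstart,
                                const arma::vec& fdur) {
  Tcm2Sol s = tcm2_solve(K1, k2, k3, k4, vB, cp, cumint_linear(cp, dt),
                         wb, cumint_linear(wb, dt), dt);
  return frames_from_integral(s.curve, s.F, dt, fstart, fdur);
}

// pars = (K1, VND, BP, k4, vB) on natural scale; variant 1: BP = BPND
// (k3 = BP*k4), variant 2: BP = BPP-like (k3 = BP*k4/VND).
// [[Rcpp::export]]
arma::vec tcm2_frames_cpp(const arma::vec& pars, int variant,
                          const arma::vec& cp, const arma::vec& wb,
                          double dt, const arma::vec& fstart,
                          const arma::vec& fdur) {
  const double K1 = pars[0], VND = pars[1], BP = pars[2], k4 = pars[3],
               vB = pars[4];
  const double k2 = K1 / VND;
  const double k3 = (variant == 1) ? BP * k4 : BP * k4 / VND;
  return tcm2_frames_rates_cpp(K1, k2, k3, k4, vB, cp, wb, dt, fstart,
                               fdur);
}

// [[Rcpp::export]]
arma::vec frame_avg_cpp(const arma::vec& curve, double dt,
                        const arma::vec& fstart, const arma::vec& fdur) {
  return frames_from_integral(curve, cumint_linear(curve, dt), dt, fstart,
                              fdur);
}

// [[Rcpp::export]]
arma::vec srtm_curve_cpp(double R1, double k2prime, double bpnd,
                         const arma::vec& ref, double dt) {
  const double k2 = R1 * k2prime;
  const double k2a = k2 / (1.0 + bpnd);
  arma::vec I, CI;
  conv_exp2(ref, cumint_linear(ref, dt), dt, k2a, I, CI);
  return R1 * ref + (k2 - R1 * k2a) * I;
}

// [[Rcpp::export]]
arma::vec srtm_frames_cpp(double R1, double k2prime, double bpnd,
                          const arma::vec& ref, double dt,
                          const arma::vec& fstart,
                          const arma::vec& fdur) {
  const double k2 = R1 * k2prime;
  const double k2a = k2 / (1.0 + bpnd);
  arma::vec Fref = cumint_linear(ref, dt);
  arma::vec I, CI;
  conv_exp2(ref, Fref, dt, k2a, I, CI);
  arma::vec curve = R1 * ref + (k2 - R1 * k2a) * I;
  arma::vec F = R1 * Fref + (k2 - R1 * k2a) * CI;
  return frames_from_integral(curve, F, dt, fstart, fdur);
}

static double tac_loglik(const arma::rowvec& y, const arma::rowvec& w,
                         const arma::rowvec& u, double s,
                         const arma::vec& mu) {
  double ll = 0.0;
  const double inv_s2 = 1.0 / (s * s);
  for (arma::uword f = 0; f < y.n_elem; ++f) {
    const double z = (y[f] - mu[f]) * w[f];
    ll -= 0.5 * z * z * u[f] * inv_s2;
  }
  return ll;
}

// One Metropolis sweep over all TACs' latent log-parameter vectors.
// lambda, base: T x 5; y, w, u: T x F; s: length T; cp, wb: G x S grids;
// subj: 0-based subject index per TAC; step: per-TAC proposal scale;
// pstep: per-parameter relative proposal scale.
// [[Rcpp::export]]
List simba_sweep_cpp(arma::mat lambda, const arma::mat& base,
                     const arma::vec& sd_gamma, const arma::mat& y,
                     const arma::mat& w, const arma::mat& u,
                     const arma::vec& s, const arma::mat& cp,
                     const arma::mat& wb, const arma::ivec& subj,
                     double dt, const arma::vec& fstart,
                     const arma::vec& fdur, int variant,
                     const arma::vec& step, const arma::vec& pstep,
                     int nrep) {
  const int T = lambda.n_rows, P = lambda.n_cols;
  arma::mat preds(T, y.n_cols);
  arma::vec acc(T, arma::fill::zeros), ll_out(T);
  const double lo = -12.0, hi = 7.0, hi_vb = std::log(0.9);

  // per-subject cumulative input integrals, shared across TACs
  const int S = cp.n_cols;
  arma::mat Fcp(cp.n_rows, S), Fwb(wb.n_rows, S);
  for (int si = 0; si < S; ++si) {
    Fcp.col(si) = cumint_linear(cp.col(si), dt);
    Fwb.col(si) = cumint_linear(wb.col(si), dt);
  }
  auto frames_for = [&](const arma::rowvec& lam, int si) -> arma::vec {
    const double K1 = std::exp(lam[0]), VND = std::exp(lam[1]),
                 BP = std::exp(lam[2]), k4 = std::exp(lam[3]),
                 vB = std::exp(lam[4]);
    const double k2 = K1 / VND;
    const double k3 = (variant == 1) ? BP * k4 : BP * k4 / VND;
    Tcm2Sol sol = tcm2_solve(K1, k2, k3, k4, vB, cp.col(si), Fcp.col(si),
                             wb.col(si), Fwb.col(si), dt);
    return frames_from_integral(sol.curve, sol.F, dt, fstart, fdur);
  };

  for (int t = 0; t < T; ++t) {
    const int si = subj[t];
    arma::rowvec lam = lambda.row(t);
    arma::vec mu = frames_for(lam, si);
    double ll = tac_loglik(y.row(t), w.row(t), u.row(t), s[t], mu);
    double lp = 0.0;
    for (int p = 0; p < P; ++p) {
      const double z = (lam[p] - base(t, p)) / sd_gamma[p];
      lp -= 0.5 * z * z;
    }
    for (int r = 0; r < nrep; ++r) {
      arma::rowvec prop = lam;
      for (int p = 0; p < P; ++p)
        prop[p] += step[t] * pstep[p] * R::norm_rand();
      bool ok = true;
      for (int p = 0; p < P; ++p) {
        const double cap = (p == 4) ? hi_vb : hi;
        if (prop[p] < lo || prop[p] > cap) { ok = false; break; }
      }
      if (!ok) continue;
      arma::vec mu_p = frames_for(prop, si);
      double ll_p = tac_loglik(y.row(t), w.row(t), u.row(t), s[t], mu_p);
      double lp_p = 0.0;
      for (int p = 0; p < P; ++p) {
        const double z = (prop[p] - base(t, p)) / sd_gamma[p];
        lp_p -= 0.5 * z * z;
      }
      if (std::log(R::unif_rand()) < (ll_p + lp_p) - (ll + lp)) {
        lam = prop; mu = mu_p; ll = ll_p; lp = lp_p;
        acc[t] += 1.0;
      }
    }
    lambda.row(t) = lam;
    preds.row(t) = mu.t();
    ll_out[t] = ll;
  }
  return List::create(_["lambda"] = lambda, _["preds"] = preds,
                      _["accept"] = acc / nrep, _["loglik"] = ll_out);
}

// total likelihood and predictions for a full latent matrix (used by
// global translation moves)
// [[Rcpp::export]]
List simba_eval_cpp(const arma::mat& lambda, const arma::mat& y,
                    const arma::mat& w, const arma::mat& u,
                    const arma::vec& s, const arma::mat& cp,
                    const arma::mat& wb, const arma::ivec& subj,
                    double dt, const arma::vec& fstart,
                    const arma::vec& fdur, int variant) {
  const int T = lambda.n_rows;
  const int S = cp.n_cols;
  arma::mat Fcp(cp.n_rows, S), Fwb(wb.n_rows, S);
  for (int si = 0; si < S; ++si) {
    Fcp.col(si) = cumint_linear(cp.col(si), dt);
    Fwb.col(si) = cumint_linear(wb.col(si), dt);
  }
  arma::mat preds(T, y.n_cols);
  arma::vec ll(T);
  for (int t = 0; t < T; ++t) {
    const int si = subj[t];
    const arma::rowvec lam = lambda.row(t);
    const double K1 = std::exp(lam[0]), VND = std::exp(lam[1]),
                 BP = std::exp(lam[2]), k4 = std::exp(lam[3]),
                 vB = std::exp(lam[4]);
    const double k2 = K1 / VND;
    const double k3 = (variant == 1) ? BP * k4 : BP * k4 / VND;
    Tcm2Sol sol = tcm2_solve(K1, k2, k3, k4, vB, cp.col(si), Fcp.col(si),
                             wb.col(si), Fwb.col(si), dt);
    arma::vec mu = frames_from_integral(sol.curve, sol.F, dt, fstart,
                                        fdur);
    preds.row(t) = mu.t();
    ll[t] = tac_loglik(y.row(t), w.row(t), u.row(t), s[t], mu);
  }
  return List::create(_["loglik"] = ll, _["preds"] = preds);
}
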