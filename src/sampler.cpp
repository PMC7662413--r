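#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the hierarchical spatio-temporal
// Poisson model. Cells are indexed c = i + I*j + I*J*t (column-major).
// Each scalar update touches only the cells its component element enters,
// exploiting that the likelihood factorises over cells; the running mean
// vector mu = E * exp(eta) is maintained incrementally so a proposal costs
// one exp() plus a sum over the element's cell set.

static inline double rw1_prior_delta(const std::vector<double>& x, int k,
                                     double vnew, double tau) {
  double v = x[k], d = 0.0;
  int n = x.size();
  if (k > 0) {
    double a = vnew - x[k - 1], b = v - x[k - 1];
    d += a * a - b * b;
  }
  if (k < n - 1) {
    double a = vnew - x[k + 1], b = v - x[k + 1];
    d += a * a - b * b;
  }
  return -0.5 * tau * d;
}

struct Accept {
  long att = 0, acc = 0;
  void add(bool a) { ++att; if (a) ++acc; }
  double rate() const { return att ? (double)acc / att : 0.0; }
  void reset() { att = acc = 0; }
};

// [[Rcpp::export]]
List stm_sampler(NumericVector y, NumericVector E, int I, int J, int T,
                 int D, IntegerVector decile0, List nb0,
                 int burnin, int keep, int thin,
                 double tau_shape, double tau_rate, double a0_var,
                 double target_accept) {
  RNGScope scope;
  const int ncell = I * J * T;
  const int NCOMP = 9;  // a0, alpha, gamma, zeta, phi, omega, delta, kappa, nu

  std::vector<std::vector<int>> nb(I);
  for (int i = 0; i < I; ++i) {
    IntegerVector v = nb0[i];
    nb[i].assign(v.begin(), v.end());
  }
  std::vector<std::vector<int>> dec_areas(D);
  for (int i = 0; i < I; ++i) dec_areas[decile0[i]].push_back(i);

  // state
  double ysum = 0.0, esum = 0.0;
  for (int c = 0; c < ncell; ++c) { ysum += y[c]; esum += E[c]; }
  double a0 = std::log((ysum + 0.5) / (esum + 1e-12));
  std::vector<double> alpha(J, 0.0), gamma(I, 0.0), zeta(T, 0.0),
      phi(D, 0.0);
  std::vector<double> omega(I * T, 0.0), delta(I * J, 0.0),
      kappa(J * T, 0.0), nu(D * T, 0.0);
  std::vector<double> tau(8, 10.0);
  // tau index: 0 alpha, 1 gamma, 2 zeta, 3 phi, 4 omega, 5 delta,
  //            6 kappa, 7 nu

  std::vector<double> mu(ncell);
  for (int c = 0; c < ncell; ++c) mu[c] = E[c] * std::exp(a0);

  // precomputed y-sums per component element
  std::vector<double> Ya(J, 0.0), Yg(I, 0.0), Yz(T, 0.0), Yp(D, 0.0);
  std::vector<double> Yom(I * T, 0.0), Yd(I * J, 0.0), Yk(J * T, 0.0),
      Yn(D * T, 0.0);
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < I; ++i) {
        double yy = y[i + I * j + I * J * t];
        int d = decile0[i];
        Ya[j] += yy; Yg[i] += yy; Yz[t] += yy; Yp[d] += yy;
        Yom[i + I * t] += yy; Yd[i + I * j] += yy;
        Yk[j + J * t] += yy; Yn[d + D * t] += yy;
      }

  std::vector<double> step(NCOMP, 0.1);
  std::vector<Accept> batch(NCOMP), post(NCOMP);
  const int BATCH = 50;

  // output
  NumericVector out_a0(keep);
  NumericMatrix out_alpha(keep, J), out_gamma(keep, I), out_zeta(keep, T),
      out_phi(keep, D), out_omega(keep, I * T), out_delta(keep, I * J),
      out_kappa(keep, J * T), out_nu(keep, D * T), out_tau(keep, 8);

  auto mh_accept = [&](double dlog) -> bool {
    if (!std::isfinite(dlog)) return false;
    if (dlog >= 0) return true;
    return std::log(unif_rand()) < dlog;
  };

  int total = burnin + keep * thin;
  int stored = 0;
  for (int it = 0; it < total; ++it) {
    bool adapting = it < burnin;

    // ---- a0 (all cells, vague normal prior) ----
    {
      double msum = 0.0;
      for (int c = 0; c < ncell; ++c) msum += mu[c];
      double dv = norm_rand() * step[0];
      double dlog = dv * ysum - (std::exp(dv) - 1.0) * msum
        - ((a0 + dv) * (a0 + dv) - a0 * a0) / (2.0 * a0_var);
      bool ok = mh_accept(dlog);
      if (ok) {
        double f = std::exp(dv);
        a0 += dv;
        for (int c = 0; c < ncell; ++c) mu[c] *= f;
      }
      batch[0].add(ok); if (!adapting) post[0].add(ok);
    }

    // ---- alpha_j (RW1) ----
    for (int j = 0; j < J; ++j) {
      double msum = 0.0;
      for (int t = 0; t < T; ++t) {
        int base = I * j + I * J * t;
        for (int i = 0; i < I; ++i) msum += mu[base + i];
      }
      double dv = norm_rand() * step[1];
      double vnew = alpha[j] + dv;
      double dlog = dv * Ya[j] - (std::exp(dv) - 1.0) * msum
        + rw1_prior_delta(alpha, j, vnew, tau[0]);
      bool ok = mh_accept(dlog);
      if (ok) {
        double f = std::exp(dv);
        alpha[j] = vnew;
        for (int t = 0; t < T; ++t) {
          int base = I * j + I * J * t;
          for (int i = 0; i < I; ++i) mu[base + i] *= f;
        }
      }
      batch[1].add(ok); if (!adapting) post[1].add(ok);
    }

    // ---- gamma_i (ICAR) ----
    for (int i = 0; i < I; ++i) {
      double msum = 0.0;
      for (int t = 0; t < T; ++t)
        for (int j = 0; j < J; ++j) msum += mu[i + I * j + I * J * t];
      double dv = norm_rand() * step[2];
      double v = gamma[i], vnew = v + dv, dprior = 0.0;
      for (int k : nb[i]) {
        double a = vnew - gamma[k], b = v - gamma[k];
        dprior += a * a - b * b;
      }
      double dlog = dv * Yg[i] - (std::exp(dv) - 1.0) * msum
        - 0.5 * tau[1] * dprior;
      bool ok = mh_accept(dlog);
      if (ok) {
        double f = std::exp(dv);
        gamma[i] = vnew;
        for (int t = 0; t < T; ++t)
          for (int j = 0; j < J; ++j) mu[i + I * j + I * J * t] *= f;
      }
      batch[2].add(ok); if (!adapting) post[2].add(ok);
    }

    // ---- zeta_t (RW1) ----
    for (int t = 0; t < T; ++t) {
      double msum = 0.0;
      int base = I * J * t;
      for (int c = 0; c < I * J; ++c) msum += mu[base + c];
      double dv = norm_rand() * step[3];
      double vnew = zeta[t] + dv;
      double dlog = dv * Yz[t] - (std::exp(dv) - 1.0) * msum
        + rw1_prior_delta(zeta, t, vnew, tau[2]);
      bool ok = mh_accept(dlog);
      if (ok) {
        double f = std::exp(dv);
        zeta[t] = vnew;
        for (int c = 0; c < I * J; ++c) mu[base + c] *= f;
      }
      batch[3].add(ok); if (!adapting) post[3].add(ok);
    }

    // ---- phi_d (RW1 over deciles) ----
    for (int d = 0; d < D; ++d) {
      double msum = 0.0;
      for (int i : dec_areas[d])
        for (int t = 0; t < T; ++t)
          for (int j = 0; j < J; ++j) msum += mu[i + I * j + I * J * t];
      double dv = norm_rand() * step[4];
      double vnew = phi[d] + dv;
      double dlog = dv * Yp[d] - (std::exp(dv) - 1.0) * msum
        + rw1_prior_delta(phi, d, vnew, tau[3]);
      bool ok = mh_accept(dlog);
      if (ok) {
        double f = std::exp(dv);
        phi[d] = vnew;
        for (int i : dec_areas[d])
          for (int t = 0; t < T; ++t)
            for (int j = 0; j < J; ++j) mu[i + I * j + I * J * t] *= f;
      }
      batch[4].add(ok); if (!adapting) post[4].add(ok);
    }

    // ---- omega_it (exchangeable) ----
    for (int t = 0; t < T; ++t)
      for (int i = 0; i < I; ++i) {
        int e = i + I * t;
        double msum = 0.0;
        for (int j = 0; j < J; ++j) msum += mu[i + I * j + I * J * t];
        double dv = norm_rand() * step[5];
        double v = omega[e], vnew = v + dv;
        double dlog = dv * Yom[e] - (std::exp(dv) - 1.0) * msum
          - 0.5 * tau[4] * (vnew * vnew - v * v);
        bool ok = mh_accept(dlog);
        if (ok) {
          double f = std::exp(dv);
          omega[e] = vnew;
          for (int j = 0; j < J; ++j) mu[i + I * j + I * J * t] *= f;
        }
        batch[5].add(ok); if (!adapting) post[5].add(ok);
      }

    // ---- delta_ij (exchangeable) ----
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < I; ++i) {
        int e = i + I * j;
        double msum = 0.0;
        for (int t = 0; t < T; ++t) msum += mu[i + I * j + I * J * t];
        double dv = norm_rand() * step[6];
        double v = delta[e], vnew = v + dv;
        double dlog = dv * Yd[e] - (std::exp(dv) - 1.0) * msum
          - 0.5 * tau[5] * (vnew * vnew - v * v);
        bool ok = mh_accept(dlog);
        if (ok) {
          double f = std::exp(dv);
          delta[e] = vnew;
          for (int t = 0; t < T; ++t) mu[i + I * j + I * J * t] *= f;
        }
        batch[6].add(ok); if (!adapting) post[6].add(ok);
      }

    // ---- kappa_jt (RW1 over t within age row j) ----
    for (int j = 0; j < J; ++j)
      for (int t = 0; t < T; ++t) {
        int e = j + J * t;
        double msum = 0.0;
        int base = I * j + I * J * t;
        for (int i = 0; i < I; ++i) msum += mu[base + i];
        double dv = norm_rand() * step[7];
        double v = kappa[e], vnew = v + dv, dprior = 0.0;
        if (t > 0) {
          double a = vnew - kappa[j + J * (t - 1)],
                 b = v - kappa[j + J * (t - 1)];
          dprior += a * a - b * b;
        }
        if (t < T - 1) {
          double a = vnew - kappa[j + J * (t + 1)],
                 b = v - kappa[j + J * (t + 1)];
          dprior += a * a - b * b;
        }
        double dlog = dv * Yk[e] - (std::exp(dv) - 1.0) * msum
          - 0.5 * tau[6] * dprior;
        bool ok = mh_accept(dlog);
        if (ok) {
          double f = std::exp(dv);
          kappa[e] = vnew;
          for (int i = 0; i < I; ++i) mu[base + i] *= f;
        }
        batch[7].add(ok); if (!adapting) post[7].add(ok);
      }

    // ---- nu_dt (RW1 over t within decile row d) ----
    for (int d = 0; d < D; ++d)
      for (int t = 0; t < T; ++t) {
        int e = d + D * t;
        double msum = 0.0;
        for (int i : dec_areas[d])
          for (int j = 0; j < J; ++j) msum += mu[i + I * j + I * J * t];
        double dv = norm_rand() * step[8];
        double v = nu[e], vnew = v + dv, dprior = 0.0;
        if (t > 0) {
          double a = vnew - nu[d + D * (t - 1)], b = v - nu[d + D * (t - 1)];
          dprior += a * a - b * b;
        }
        if (t < T - 1) {
          double a = vnew - nu[d + D * (t + 1)], b = v - nu[d + D * (t + 1)];
          dprior += a * a - b * b;
        }
        double dlog = dv * Yn[e] - (std::exp(dv) - 1.0) * msum
          - 0.5 * tau[7] * dprior;
        bool ok = mh_accept(dlog);
        if (ok) {
          double f = std::exp(dv);
          nu[e] = vnew;
          for (int i : dec_areas[d])
            for (int j = 0; j < J; ++j) mu[i + I * j + I * J * t] *= f;
        }
        batch[8].add(ok); if (!adapting) post[8].add(ok);
      }

    // ---- re-centring; eta (hence mu) is left invariant by transferring
    //      removed means into the intercept / main effects ----
    {
      // omega: double-centred; area means -> gamma, year means -> zeta
      {
        std::vector<double> rmi(I, 0.0), cmt(T, 0.0);
        double om = 0.0;
        for (int t = 0; t < T; ++t)
          for (int i = 0; i < I; ++i) {
            double v = omega[i + I * t];
            rmi[i] += v; cmt[t] += v; om += v;
          }
        for (int i = 0; i < I; ++i) rmi[i] /= T;
        for (int t = 0; t < T; ++t) cmt[t] /= I;
        om /= (double)I * T;
        for (int t = 0; t < T; ++t)
          for (int i = 0; i < I; ++i)
            omega[i + I * t] -= rmi[i] + cmt[t] - om;
        for (int i = 0; i < I; ++i) gamma[i] += rmi[i] - om;
        for (int t = 0; t < T; ++t) zeta[t] += cmt[t] - om;
        a0 += om;
      }
      // delta: double-centred; area means -> gamma, age means -> alpha
      {
        std::vector<double> rmi(I, 0.0), cmj(J, 0.0);
        double om = 0.0;
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < I; ++i) {
            double v = delta[i + I * j];
            rmi[i] += v; cmj[j] += v; om += v;
          }
        for (int i = 0; i < I; ++i) rmi[i] /= J;
        for (int j = 0; j < J; ++j) cmj[j] /= I;
        om /= (double)I * J;
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < I; ++i)
            delta[i + I * j] -= rmi[i] + cmj[j] - om;
        for (int i = 0; i < I; ++i) gamma[i] += rmi[i] - om;
        for (int j = 0; j < J; ++j) alpha[j] += cmj[j] - om;
        a0 += om;
      }

      // kappa: double-centred; row means -> alpha, column means -> zeta
      std::vector<double> rm(J, 0.0), cm(T, 0.0);
      double om = 0.0;
      for (int t = 0; t < T; ++t)
        for (int j = 0; j < J; ++j) {
          double v = kappa[j + J * t];
          rm[j] += v; cm[t] += v; om += v;
        }
      for (int j = 0; j < J; ++j) rm[j] /= T;
      for (int t = 0; t < T; ++t) cm[t] /= J;
      om /= (J * T);
      for (int t = 0; t < T; ++t)
        for (int j = 0; j < J; ++j)
          kappa[j + J * t] -= rm[j] + cm[t] - om;
      for (int j = 0; j < J; ++j) alpha[j] += rm[j] - om;
      for (int t = 0; t < T; ++t) zeta[t] += cm[t] - om;
      a0 += om;

      // nu: double-centred; row means -> phi, column means -> zeta
      std::vector<double> rmd(D, 0.0), cmt(T, 0.0);
      om = 0.0;
      for (int t = 0; t < T; ++t)
        for (int d = 0; d < D; ++d) {
          double v = nu[d + D * t];
          rmd[d] += v; cmt[t] += v; om += v;
        }
      for (int d = 0; d < D; ++d) rmd[d] /= T;
      for (int t = 0; t < T; ++t) cmt[t] /= D;
      om /= (D * T);
      for (int t = 0; t < T; ++t)
        for (int d = 0; d < D; ++d)
          nu[d + D * t] -= rmd[d] + cmt[t] - om;
      for (int d = 0; d < D; ++d) phi[d] += rmd[d] - om;
      for (int t = 0; t < T; ++t) zeta[t] += cmt[t] - om;
      a0 += om;

      // main effects -> intercept
      auto center_into_a0 = [&](std::vector<double>& x) {
        double mm = 0.0;
        for (double v : x) mm += v;
        mm /= x.size();
        for (double& v : x) v -= mm;
        a0 += mm;
      };
      center_into_a0(alpha);
      center_into_a0(gamma);
      center_into_a0(zeta);
      center_into_a0(phi);
    }

    // ---- Gibbs updates for the precisions ----
    {
      auto rw1_quad = [](const std::vector<double>& x) {
        double q = 0.0;
        for (size_t k = 1; k < x.size(); ++k) {
          double d = x[k] - x[k - 1];
          q += d * d;
        }
        return q;
      };
      auto gibbs = [&](double q, double rank) {
        return R::rgamma(tau_shape + 0.5 * rank,
                         1.0 / (tau_rate + 0.5 * q));
      };
      tau[0] = gibbs(rw1_quad(alpha), J - 1);
      double qg = 0.0;
      for (int i = 0; i < I; ++i)
        for (int k : nb[i])
          if (k > i) {
            double d = gamma[i] - gamma[k];
            qg += d * d;
          }
      tau[1] = gibbs(qg, I - 1);
      tau[2] = gibbs(rw1_quad(zeta), T - 1);
      tau[3] = gibbs(rw1_quad(phi), D - 1);
      double qo = 0.0;
      for (double v : omega) qo += v * v;
      tau[4] = gibbs(qo, (double)(I - 1) * (T - 1));
      double qd = 0.0;
      for (double v : delta) qd += v * v;
      tau[5] = gibbs(qd, (double)(I - 1) * (J - 1));
      double qk = 0.0;
      for (int j = 0; j < J; ++j)
        for (int t = 1; t < T; ++t) {
          double d = kappa[j + J * t] - kappa[j + J * (t - 1)];
          qk += d * d;
        }
      tau[6] = gibbs(qk, (double)(J - 1) * (T - 1));
      double qn = 0.0;
      for (int d = 0; d < D; ++d)
        for (int t = 1; t < T; ++t) {
          double dd = nu[d + D * t] - nu[d + D * (t - 1)];
          qn += dd * dd;
        }
      tau[7] = gibbs(qn, (double)(D - 1) * (T - 1));
    }

    // ---- step-size adaptation, burn-in only ----
    if (adapting && (it + 1) % BATCH == 0) {
      for (int k = 0; k < NCOMP; ++k) {
        double r = batch[k].rate();
        step[k] *= std::exp(r - target_accept);
        if (step[k] < 1e-4) step[k] = 1e-4;
        if (step[k] > 5.0) step[k] = 5.0;
        batch[k].reset();
      }
    }

    // ---- storage ----
    if (it >= burnin && (it - burnin) % thin == 0 && stored < keep) {
      out_a0[stored] = a0;
      for (int j = 0; j < J; ++j) out_alpha(stored, j) = alpha[j];
      for (int i = 0; i < I; ++i) out_gamma(stored, i) = gamma[i];
      for (int t = 0; t < T; ++t) out_zeta(stored, t) = zeta[t];
      for (int d = 0; d < D; ++d) out_phi(stored, d) = phi[d];
      for (int e = 0; e < I * T; ++e) out_omega(stored, e) = omega[e];
      for (int e = 0; e < I * J; ++e) out_delta(stored, e) = delta[e];
      for (int e = 0; e < J * T; ++e) out_kappa(stored, e) = kappa[e];
      for (int e = 0; e < D * T; ++e) out_nu(stored, e) = nu[e];
      for (int k = 0; k < 8; ++k) out_tau(stored, k) = tau[k];
      ++stored;
    }
  }

  NumericVector acc(NCOMP);
  for (int k = 0; k < NCOMP; ++k) acc[k] = post[k].rate();

  return List::create(
      _["a0"] = out_a0, _["alpha"] = out_alpha, _["gamma"] = out_gamma,
      _["zeta"] = out_zeta, _["phi"] = out_phi, _["omega"] = out_omega,
      _["delta"] = out_delta, _["kappa"] = out_kappa, _["nu"] = out_nu,
      _["tau"] = out_tau, _["accept"] = acc);
}
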