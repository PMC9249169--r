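// Hamiltonian (No-U-Turn) sampler for the per-feature hierarchical model:
//   X_i ~ N(mu, Sigma(sigma1, sigma2, rho)) latent bivariate state,
//   y1_i ~ ZIP(s_i * exp(X_i1); pi)      (expression counts),
//   y2_i ~ Binomial(n_i, Phi(X_i2))      (methylation / accessibility).
// Sampling happens on the unconstrained scale:
//   theta = (mu1, mu2, log sigma1, log sigma2, atanh rho, logit pi)
// followed by the latent states X_11..X_I1, X_12..X_I2 sampled directly
// (centred): per-cell counts and coverages are typically large here, so
// the likelihood pins each X_i tightly and the centred geometry with a
// per-coordinate (diagonal) mass is the efficient one. Jacobians of the
// theta transforms are included in the target. Uses R's RNG stream so
// set.seed() gives bitwise reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct ModelData {
  std::vector<double> y1, y2, n, s, log_s, lgam_y1, lchoose_ny2;
  int I;
  bool zi;
  // hyper-parameters
  double a, b, m1, m2, c1, c2, d1, d2;
  double Hi11, Hi12, Hi22;  // inverse of the 2x2 prior covariance H
  int dim;                  // 5 + zi + 2 I
};

inline double log1pexp(double x) {
  // log(1 + e^x), stable
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log Phi(x) and log(1 - Phi(x)) via erfc (both tails computed directly,
// no cancellation); falls back to R's pnorm in the extreme tails where
// erfc underflows.
inline void lpnorm_pair(double x, double& lF, double& lS) {
  if (x > -35.0 && x < 35.0) {
    lF = std::log(0.5 * std::erfc(-x * M_SQRT1_2));
    lS = std::log(0.5 * std::erfc(x * M_SQRT1_2));
  } else {
    lF = R::pnorm(x, 0.0, 1.0, 1, 1);
    lS = R::pnorm(x, 0.0, 1.0, 0, 1);
  }
}

// Log posterior (up to an additive constant) and gradient on the
// unconstrained scale. Returns -Inf for numerically hopeless states.
double logpost_grad(const ModelData& D, const std::vector<double>& q,
                    std::vector<double>* grad) {
  const int I = D.I;
  const int off = 5 + (D.zi ? 1 : 0);
  const double mu1 = q[0], mu2 = q[1];
  const double ls1 = q[2], ls2 = q[3], t = q[4];
  if (ls1 > 300 || ls2 > 300) return R_NegInf;
  const double s1 = std::exp(ls1), s2 = std::exp(ls2);
  const double rho = std::tanh(t);
  const double w2 = std::max(1.0 - rho * rho, 1e-300);
  double lpit = 0.0, pi = 0.0, lpi = R_NegInf, l1mpi = 0.0;
  if (D.zi) {
    lpit = q[5];
    pi = 1.0 / (1.0 + std::exp(-lpit));
    lpi = lpit - log1pexp(lpit);    // log pi
    l1mpi = -log1pexp(lpit);        // log (1 - pi)
  }

  double lp = 0.0;
  if (grad) std::fill(grad->begin(), grad->end(), 0.0);

  for (int i = 0; i < I; ++i) {
    const double x1 = q[off + i], x2 = q[off + I + i];

    // --- expression: zero-inflated Poisson, rate s_i exp(x1) ---
    double llam = D.log_s[i] + x1;
    if (llam > 690.0) llam = 690.0;  // keeps lam finite; such states diverge anyway
    const double lam = std::exp(llam);
    double g1 = 0.0, gpi = 0.0;
    if (D.y1[i] > 0.0) {
      lp += l1mpi + D.y1[i] * llam - lam - D.lgam_y1[i];
      g1 = D.y1[i] - lam;
      gpi = -pi;
    } else {
      if (D.zi) {
        const double a1 = lpi, a2 = l1mpi - lam;
        const double M = std::max(a1, a2);
        const double l0 = M + std::log1p(std::exp(std::min(a1, a2) - M));
        lp += l0;
        g1 = -std::exp(a2 - l0) * lam;
        // d l0 / d logit(pi) = pi (1 - pi) (1 - e^{-lam}) / exp(l0)
        gpi = pi * (1.0 - pi) * (-std::expm1(-lam)) * std::exp(-l0);
      } else {
        lp += -lam;
        g1 = -lam;
      }
    }
    if (grad) {
      (*grad)[off + i] += g1;
      if (D.zi) (*grad)[5] += gpi;
    }

    // --- epigenome: Binomial(n, Phi(x2)); n = 0 is vacuous ---
    if (D.n[i] > 0.0) {
      double lF, lS;
      lpnorm_pair(x2, lF, lS);
      lp += D.y2[i] * lF + (D.n[i] - D.y2[i]) * lS + D.lchoose_ny2[i];
      if (grad) {
        const double ld = -0.918938533204672742 - 0.5 * x2 * x2;  // log dnorm
        (*grad)[off + I + i] += D.y2[i] * std::exp(ld - lF) -
                               (D.n[i] - D.y2[i]) * std::exp(ld - lS);
      }
    }

    // --- bivariate Gaussian prior on the latent pair ---
    const double z1 = (x1 - mu1) / s1, z2 = (x2 - mu2) / s2;
    const double qf = (z1 * z1 - 2.0 * rho * z1 * z2 + z2 * z2) / w2;
    lp += -ls1 - ls2 - 0.5 * std::log(w2) - 0.5 * qf;
    if (grad) {
      const double u1 = (z1 - rho * z2) / w2, u2 = (z2 - rho * z1) / w2;
      (*grad)[off + i] += -u1 / s1;
      (*grad)[off + I + i] += -u2 / s2;
      (*grad)[0] += u1 / s1;
      (*grad)[1] += u2 / s2;
      (*grad)[2] += -1.0 + u1 * z1;
      (*grad)[3] += -1.0 + u2 * z2;
      (*grad)[4] += rho + z1 * z2 - rho * qf;
    }
  }

  // --- priors on theta (Jacobians of the transforms included) ---
  const double dm1 = mu1 - D.m1, dm2 = mu2 - D.m2;
  lp += -0.5 * (dm1 * (D.Hi11 * dm1 + D.Hi12 * dm2) +
                dm2 * (D.Hi12 * dm1 + D.Hi22 * dm2));
  lp += -D.c1 * ls1 - D.c2 / s1;  // inv-gamma on sigma1 + log-Jacobian
  lp += -D.c1 * ls2 - D.c2 / s2;
  lp += D.d1 * std::log1p(rho) + D.d2 * std::log1p(-rho);  // scaled beta + Jacobian
  if (D.zi) lp += D.a * lpi + D.b * l1mpi;                 // beta + Jacobian
  if (grad) {
    (*grad)[0] -= D.Hi11 * dm1 + D.Hi12 * dm2;
    (*grad)[1] -= D.Hi12 * dm1 + D.Hi22 * dm2;
    (*grad)[2] += -D.c1 + D.c2 / s1;
    (*grad)[3] += -D.c1 + D.c2 / s2;
    (*grad)[4] += D.d1 * (1.0 - rho) - D.d2 * (1.0 + rho);
    if (D.zi) (*grad)[5] += D.a - (D.a + D.b) * pi;
  }

  if (!std::isfinite(lp)) return R_NegInf;
  return lp;
}

// Exact observation log-likelihood (all constants kept), conditional on
// the latent states. Used for the deviance of the DIC.
double obs_loglik(const ModelData& D, const std::vector<double>& q) {
  const int I = D.I;
  const int off = 5 + (D.zi ? 1 : 0);
  double lpi = R_NegInf, l1mpi = 0.0;
  if (D.zi) {
    lpi = q[5] - log1pexp(q[5]);
    l1mpi = -log1pexp(q[5]);
  }
  double ll = 0.0;
  for (int i = 0; i < I; ++i) {
    const double x1 = q[off + i], x2 = q[off + I + i];
    double llam = D.log_s[i] + x1;
    if (llam > 690.0) llam = 690.0;
    const double lam = std::exp(llam);
    if (D.y1[i] > 0.0) {
      ll += l1mpi + D.y1[i] * llam - lam - D.lgam_y1[i];
    } else if (D.zi) {
      const double a1 = lpi, a2 = l1mpi - lam;
      const double M = std::max(a1, a2);
      ll += M + std::log1p(std::exp(std::min(a1, a2) - M));
    } else {
      ll += -lam;
    }
    if (D.n[i] > 0.0) {
      double lF, lS;
      lpnorm_pair(x2, lF, lS);
      ll += D.y2[i] * lF + (D.n[i] - D.y2[i]) * lS + D.lchoose_ny2[i];
    }
  }
  return ll;
}

struct State {
  std::vector<double> q, p, grad;
  double lp;
};

// Diagonal mass matrix: `im` holds the inverse mass (posterior variance
// estimates), adapted during the first part of burn-in.
void leapfrog(const ModelData& D, State& z, double eps,
              const std::vector<double>& im) {
  const int d = D.dim;
  for (int k = 0; k < d; ++k) z.p[k] += 0.5 * eps * z.grad[k];
  for (int k = 0; k < d; ++k) z.q[k] += eps * im[k] * z.p[k];
  z.lp = logpost_grad(D, z.q, &z.grad);
  if (!std::isfinite(z.lp)) return;  // divergent; caller checks
  for (int k = 0; k < d; ++k) z.p[k] += 0.5 * eps * z.grad[k];
}

inline double hamiltonian(const State& z, const std::vector<double>& im) {
  double k = 0.0;
  for (size_t i = 0; i < z.p.size(); ++i) k += im[i] * z.p[i] * z.p[i];
  return z.lp - 0.5 * k;
}

inline bool no_uturn(const State& zm, const State& zp,
                     const std::vector<double>& im) {
  double a = 0.0, b = 0.0;
  const int d = (int)zm.q.size();
  for (int k = 0; k < d; ++k) {
    const double dq = zp.q[k] - zm.q[k];
    a += dq * im[k] * zm.p[k];
    b += dq * im[k] * zp.p[k];
  }
  return a >= 0.0 && b >= 0.0;
}

struct Tree {
  State zm, zp;               // leftmost / rightmost states
  std::vector<double> qprop;  // proposal
  double lp_prop;
  double n;                   // number of valid states
  bool ok;                    // subtree free of U-turns / divergences
  double alpha;               // accept-stat accumulator
  int nalpha;
  bool divergent;
};

void build_tree(const ModelData& D, const State& z, double logu, int dir,
                int depth, double eps, double H0, const std::vector<double>& im,
                Tree& out) {
  if (depth == 0) {
    State z1 = z;
    leapfrog(D, z1, dir * eps, im);
    double H1 = std::isfinite(z1.lp) ? hamiltonian(z1, im) : R_NegInf;
    out.zm = z1;
    out.zp = z1;
    out.qprop = z1.q;
    out.lp_prop = z1.lp;
    out.n = (logu <= H1) ? 1.0 : 0.0;
    out.divergent = !(logu < H1 + 1000.0);
    out.ok = !out.divergent;
    double da = H1 - H0;
    out.alpha = std::isfinite(da) ? std::min(1.0, std::exp(da)) : 0.0;
    out.nalpha = 1;
    return;
  }
  build_tree(D, z, logu, dir, depth - 1, eps, H0, im, out);
  if (!out.ok) return;
  Tree t2;
  if (dir == -1) {
    build_tree(D, out.zm, logu, dir, depth - 1, eps, H0, im, t2);
    out.zm = t2.zm;
  } else {
    build_tree(D, out.zp, logu, dir, depth - 1, eps, H0, im, t2);
    out.zp = t2.zp;
  }
  if (t2.n > 0.0 &&
      unif_rand() < t2.n / std::max(out.n + t2.n, 1.0)) {
    out.qprop = t2.qprop;
    out.lp_prop = t2.lp_prop;
  }
  out.n += t2.n;
  out.alpha += t2.alpha;
  out.nalpha += t2.nalpha;
  out.divergent = out.divergent || t2.divergent;
  out.ok = t2.ok && no_uturn(out.zm, out.zp, im);
}

double find_epsilon(const ModelData& D, const State& z0,
                    const std::vector<double>& im) {
  double eps = 0.1;
  State z = z0;
  for (int k = 0; k < (int)z.p.size(); ++k)
    z.p[k] = norm_rand() / std::sqrt(im[k]);
  const double H0 = hamiltonian(z, im);
  State z1 = z;
  leapfrog(D, z1, eps, im);
  double H1 = std::isfinite(z1.lp) ? hamiltonian(z1, im) : R_NegInf;
  double dH = H1 - H0;
  const double dir = (std::isfinite(dH) && dH > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    eps *= std::pow(2.0, dir);
    State zt = z;
    leapfrog(D, zt, eps, im);
    double Ht = std::isfinite(zt.lp) ? hamiltonian(zt, im) : R_NegInf;
    dH = Ht - H0;
    if (!std::isfinite(dH)) dH = R_NegInf;
    if (dir * dH <= dir * std::log(0.5)) break;
  }
  return std::max(eps, 1e-8);
}

ModelData make_model(NumericVector y1, NumericVector y2, NumericVector n,
                     NumericVector s, List hyper, bool zero_inflated) {
  ModelData D;
  D.I = y1.size();
  D.zi = zero_inflated;
  D.dim = 5 + (D.zi ? 1 : 0) + 2 * D.I;
  D.y1.assign(y1.begin(), y1.end());
  D.y2.assign(y2.begin(), y2.end());
  D.n.assign(n.begin(), n.end());
  D.s.assign(s.begin(), s.end());
  D.log_s.resize(D.I);
  D.lgam_y1.resize(D.I);
  D.lchoose_ny2.resize(D.I);
  for (int i = 0; i < D.I; ++i) {
    D.log_s[i] = std::log(D.s[i]);
    D.lgam_y1[i] = std::lgamma(D.y1[i] + 1.0);
    D.lchoose_ny2[i] = D.n[i] > 0.0 ? R::lchoose(D.n[i], D.y2[i]) : 0.0;
  }
  D.a = as<double>(hyper["a"]);
  D.b = as<double>(hyper["b"]);
  NumericVector m = hyper["m"];
  D.m1 = m[0];
  D.m2 = m[1];
  D.c1 = as<double>(hyper["c1"]);
  D.c2 = as<double>(hyper["c2"]);
  D.d1 = as<double>(hyper["d1"]);
  D.d2 = as<double>(hyper["d2"]);
  NumericMatrix H = hyper["H"];
  const double det = H(0, 0) * H(1, 1) - H(0, 1) * H(1, 0);
  D.Hi11 = H(1, 1) / det;
  D.Hi22 = H(0, 0) / det;
  D.Hi12 = -H(0, 1) / det;
  return D;
}

}  // namespace

// [[Rcpp::export]]
double logpost_cpp(NumericVector q, NumericVector y1, NumericVector y2,
                   NumericVector n, NumericVector s, List hyper,
                   bool zero_inflated) {
  ModelData D = make_model(y1, y2, n, s, hyper, zero_inflated);
  std::vector<double> qv(q.begin(), q.end());
  if ((int)qv.size() != D.dim) stop("parameter vector has wrong length");
  return logpost_grad(D, qv, nullptr);
}

// [[Rcpp::export]]
NumericVector logpost_grad_cpp(NumericVector q, NumericVector y1,
                               NumericVector y2, NumericVector n,
                               NumericVector s, List hyper,
                               bool zero_inflated) {
  ModelData D = make_model(y1, y2, n, s, hyper, zero_inflated);
  std::vector<double> qv(q.begin(), q.end());
  if ((int)qv.size() != D.dim) stop("parameter vector has wrong length");
  std::vector<double> g(D.dim);
  logpost_grad(D, qv, &g);
  return wrap(g);
}

// [[Rcpp::export]]
List nuts_sample_cpp(NumericVector y1, NumericVector y2, NumericVector n,
                     NumericVector s, List hyper, bool zero_inflated,
                     int n_samples, int n_burnin, double target_accept,
                     int max_treedepth, NumericVector q_init,
                     bool store_latent) {
  ModelData D = make_model(y1, y2, n, s, hyper, zero_inflated);
  const int I = D.I, d = D.dim;
  const int off = 5 + (D.zi ? 1 : 0);
  if (q_init.size() != d) stop("initial state has wrong length");
  const int kept = n_samples - n_burnin;

  State z;
  z.q.assign(q_init.begin(), q_init.end());
  z.p.assign(d, 0.0);
  z.grad.assign(d, 0.0);
  z.lp = logpost_grad(D, z.q, &z.grad);
  if (!std::isfinite(z.lp)) stop("log posterior not finite at initial state");

  // Diagonal inverse mass (posterior variances), adapted over doubling
  // windows during burn-in as in Stan: an initial step-size-only buffer,
  // variance-estimation windows of doubling length (mass and step size
  // reset at each window end), and a terminal step-size-only buffer.
  // The initial mass comes from the observed curvature: a count y pins
  // its log-rate to variance ~1/y, coverage n pins its probit state to
  // variance ~1/(0.6 n); global parameters concentrate at rate 1/I.
  std::vector<double> im(d, 1.0);
  im[0] = 9.0 / I;                     // mu1 (prior-scale latent sd ~3)
  im[1] = 4.0 / I;                     // mu2
  im[2] = im[3] = 2.0 / I;             // log sigmas
  im[4] = std::max(2.0 / I, 0.02);     // atanh rho
  if (D.zi) im[5] = std::max(4.0 / I, 0.05);  // logit pi
  for (int i = 0; i < I; ++i) {
    im[off + i] = 1.0 / (D.y1[i] + 1.0 / 9.0);
    im[off + I + i] = 1.0 / (0.6 * D.n[i] + 0.25);
  }
  std::vector<double> wm(d, 0.0), ws(d, 0.0);
  long wn = 0;
  int init_buf = 75, term_buf = 50, base_window = 25;
  if (n_burnin < 200) {  // scale the schedule down for short runs
    init_buf = n_burnin / 8 + 1;
    term_buf = n_burnin / 10 + 1;
    base_window = std::max(n_burnin / 8, 5);
  }
  std::vector<int> window_ends;
  {
    int start = init_buf, wlen = base_window;
    while (start + wlen < n_burnin - term_buf) {
      if (start + wlen + 2 * wlen >= n_burnin - term_buf) {
        window_ends.push_back(n_burnin - term_buf);  // extend terminal window
        start = n_burnin - term_buf;
      } else {
        window_ends.push_back(start + wlen);
        start += wlen;
      }
      wlen *= 2;
    }
  }
  size_t next_window = 0;

  // dual averaging toward the target acceptance statistic
  double eps = find_epsilon(D, z, im);
  double mu_da = std::log(10.0 * eps);
  double logeps = std::log(eps), logepsbar = 0.0, Hbar = 0.0;
  int da_m = 0;  // dual-averaging iteration counter (restarts with the mass)
  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;

  NumericMatrix draws(kept, 6);
  NumericVector loglik(kept);
  NumericVector accept(kept);
  NumericMatrix Xmean(I, 2);
  NumericMatrix X1d, X2d;
  if (store_latent) {
    X1d = NumericMatrix(kept, I);
    X2d = NumericMatrix(kept, I);
  }
  int n_divergent = 0;

  for (int m = 1; m <= n_samples; ++m) {
    eps = std::exp(m <= n_burnin ? logeps : logepsbar);
    for (int k = 0; k < d; ++k) z.p[k] = norm_rand() / std::sqrt(im[k]);
    const double H0 = hamiltonian(z, im);
    const double logu = H0 - exp_rand();

    State zm = z, zp = z;
    double nacc = 1.0;
    bool ok = true, div = false;
    double alpha_sum = 0.0;
    int nalpha = 0;
    for (int depth = 0; depth < max_treedepth && ok; ++depth) {
      const int dir = unif_rand() < 0.5 ? -1 : 1;
      Tree t;
      if (dir == -1) {
        build_tree(D, zm, logu, dir, depth, eps, H0, im, t);
        zm = t.zm;
      } else {
        build_tree(D, zp, logu, dir, depth, eps, H0, im, t);
        zp = t.zp;
      }
      alpha_sum += t.alpha;
      nalpha += t.nalpha;
      div = div || t.divergent;
      if (t.ok && t.n > 0.0 && unif_rand() < t.n / nacc) {
        z.q = t.qprop;
        z.lp = t.lp_prop;
      }
      nacc += t.n;
      ok = t.ok && no_uturn(zm, zp, im);
    }
    logpost_grad(D, z.q, &z.grad);  // refresh gradient at accepted state
    const double astat = nalpha > 0 ? alpha_sum / nalpha : 0.0;

    if (m <= n_burnin) {
      ++da_m;
      const double eta = 1.0 / (da_m + t0);
      Hbar = (1.0 - eta) * Hbar + eta * (target_accept - astat);
      logeps = mu_da - std::sqrt((double)da_m) / gamma_da * Hbar;
      const double xi = std::pow((double)da_m, -kappa);
      logepsbar = xi * logeps + (1.0 - xi) * logepsbar;

      if (m > init_buf && next_window < window_ends.size()) {
        ++wn;  // accumulate posterior variances for the current window
        for (int k = 0; k < d; ++k) {
          const double delta = z.q[k] - wm[k];
          wm[k] += delta / wn;
          ws[k] += delta * (z.q[k] - wm[k]);
        }
        if (m == window_ends[next_window]) {
          if (wn > 4) {  // switch to the estimated mass, restart step size
            for (int k = 0; k < d; ++k) {
              const double v = ws[k] / (wn - 1);
              im[k] = std::max(
                  v * wn / (wn + 5.0) + 1e-3 * 5.0 / (wn + 5.0), 1e-10);
            }
            eps = find_epsilon(D, z, im);
            mu_da = std::log(10.0 * eps);
            logeps = std::log(eps);
            logepsbar = 0.0;
            Hbar = 0.0;
            da_m = 0;
          }
          std::fill(wm.begin(), wm.end(), 0.0);
          std::fill(ws.begin(), ws.end(), 0.0);
          wn = 0;
          ++next_window;
        }
      }
    } else {
      const int r = m - n_burnin - 1;
      draws(r, 0) = z.q[0];
      draws(r, 1) = z.q[1];
      draws(r, 2) = std::exp(z.q[2]);
      draws(r, 3) = std::exp(z.q[3]);
      draws(r, 4) = std::tanh(z.q[4]);
      draws(r, 5) = D.zi ? 1.0 / (1.0 + std::exp(-z.q[5])) : 0.0;
      loglik[r] = obs_loglik(D, z.q);
      accept[r] = astat;
      if (div) ++n_divergent;
      for (int i = 0; i < I; ++i) {
        const double x1 = z.q[off + i], x2 = z.q[off + I + i];
        Xmean(i, 0) += x1 / kept;
        Xmean(i, 1) += x2 / kept;
        if (store_latent) {
          X1d(r, i) = x1;
          X2d(r, i) = x2;
        }
      }
    }
  }

  List out = List::create(
      _["draws"] = draws, _["loglik"] = loglik, _["accept"] = accept,
      _["X_mean"] = Xmean, _["step_size"] = std::exp(logepsbar),
      _["n_divergent"] = n_divergent);
  if (store_latent) {
    out["X1_draws"] = X1d;
    out["X2_draws"] = X2d;
  }
  return out;
}
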