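// No-U-Turn sampler (binary doubling with slice acceptance, dual-averaging
// step-size adaptation, diagonal mass matrix estimated during warmup) over
// the unnormalized log posteriors of the three model families.
//
// Parameterization on the unconstrained scale: regression coefficients as-is,
// positive parameters (precision/dispersion phi, residual sd sigma, spline sd
// tau) as logs with the log-Jacobian added to the target density.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// model definitions
// ---------------------------------------------------------------------------

struct Prior {
  double intercept_scale;
  double slope_scale;
  double disp_df;
  double disp_scale;
  double spline_df;     // seasonal only
  double spline_scale;  // seasonal only
};

// log density of a half-Student-t(df, 0, scale) evaluated at x > 0, up to the
// additive constant that does not involve x
static inline double half_t_lpdf(double x, double df, double scale) {
  return -0.5 * (df + 1.0) * std::log1p((x / scale) * (x / scale) / df);
}
// d/dx of the above
static inline double half_t_grad(double x, double df, double scale) {
  return -(df + 1.0) * x / (df * scale * scale + x * x);
}

// fast digamma: shift into the asymptotic regime, then the standard series
static inline double fast_digamma(double x) {
  double r = 0.0;
  while (x < 6.0) {
    r -= 1.0 / x;
    x += 1.0;
  }
  double f = 1.0 / (x * x);
  return r + std::log(x) - 0.5 / x -
         f * (1.0 / 12 - f * (1.0 / 120 - f * (1.0 / 252 -
              f * (1.0 / 240 - f * (1.0 / 132)))));
}

class Model {
 public:
  virtual ~Model() {}
  virtual int dim() const = 0;
  // returns log posterior; writes gradient into grad (length dim())
  virtual double lp_grad(const std::vector<double>& th,
                         std::vector<double>* grad) const = 0;
};

// shared: gaussian priors on coefficients; intercept first when present
static double coef_prior(const std::vector<double>& th, int p,
                         bool has_intercept, const Prior& pr,
                         std::vector<double>* grad) {
  double lp = 0.0;
  for (int j = 0; j < p; ++j) {
    double s = (has_intercept && j == 0) ? pr.intercept_scale : pr.slope_scale;
    lp += -0.5 * th[j] * th[j] / (s * s) - std::log(s);
    (*grad)[j] += -th[j] / (s * s);
  }
  return lp;
}

class BetaRegModel : public Model {
 public:
  NumericMatrix X;
  NumericVector y;
  Prior pr;
  bool has_intercept;
  int n, p;
  BetaRegModel(NumericMatrix X_, NumericVector y_, Prior pr_, bool ic)
      : X(X_), y(y_), pr(pr_), has_intercept(ic), n(y_.size()), p(X_.ncol()) {}
  int dim() const { return p + 1; }
  double lp_grad(const std::vector<double>& th,
                 std::vector<double>* grad) const {
    std::fill(grad->begin(), grad->end(), 0.0);
    double lphi = th[p];
    if (lphi > 30.0 || lphi < -30.0) return R_NegInf;
    double phi = std::exp(lphi);
    double lp = 0.0;
    double dldphi = 0.0;
    for (int i = 0; i < n; ++i) {
      double eta = 0.0;
      for (int j = 0; j < p; ++j) eta += X(i, j) * th[j];
      if (eta > 35.0 || eta < -35.0) return R_NegInf;
      double mu = 1.0 / (1.0 + std::exp(-eta));
      double a = mu * phi, b = (1.0 - mu) * phi;
      double ly = std::log(y[i]), l1y = std::log1p(-y[i]);
      lp += std::lgamma(phi) - std::lgamma(a) - std::lgamma(b) +
            (a - 1.0) * ly + (b - 1.0) * l1y;
      double dldmu = phi * (-fast_digamma(a) + fast_digamma(b) + ly - l1y);
      double w = dldmu * mu * (1.0 - mu);
      for (int j = 0; j < p; ++j) (*grad)[j] += w * X(i, j);
      dldphi += fast_digamma(phi) - mu * fast_digamma(a) -
                (1.0 - mu) * fast_digamma(b) + mu * ly + (1.0 - mu) * l1y;
    }
    if (!std::isfinite(lp)) return R_NegInf;
    lp += coef_prior(th, p, has_intercept, pr, grad);
    lp += half_t_lpdf(phi, pr.disp_df, pr.disp_scale) + lphi;  // + Jacobian
    (*grad)[p] =
        phi * (dldphi + half_t_grad(phi, pr.disp_df, pr.disp_scale)) + 1.0;
    return lp;
  }
};

class NegbinRegModel : public Model {
 public:
  NumericMatrix X;
  NumericVector y;
  Prior pr;
  bool has_intercept;
  int n, p;
  NegbinRegModel(NumericMatrix X_, NumericVector y_, Prior pr_, bool ic)
      : X(X_), y(y_), pr(pr_), has_intercept(ic), n(y_.size()), p(X_.ncol()) {}
  int dim() const { return p + 1; }
  double lp_grad(const std::vector<double>& th,
                 std::vector<double>* grad) const {
    std::fill(grad->begin(), grad->end(), 0.0);
    double lphi = th[p];
    if (lphi > 30.0 || lphi < -30.0) return R_NegInf;
    double phi = std::exp(lphi);
    double lp = 0.0, dldphi = 0.0;
    for (int i = 0; i < n; ++i) {
      double eta = 0.0;
      for (int j = 0; j < p; ++j) eta += X(i, j) * th[j];
      if (eta > 30.0 || eta < -30.0) return R_NegInf;
      double mu = std::exp(eta);
      // NB2 pmf: C(y+phi) with mean mu, variance mu + mu^2/phi
      lp += std::lgamma(y[i] + phi) - std::lgamma(phi) -
            std::lgamma(y[i] + 1.0) + phi * (lphi - std::log(phi + mu)) +
            y[i] * (eta - std::log(phi + mu));
      double dldeta = mu * (y[i] / mu - (y[i] + phi) / (phi + mu));
      for (int j = 0; j < p; ++j) (*grad)[j] += dldeta * X(i, j);
      dldphi += fast_digamma(y[i] + phi) - fast_digamma(phi) + lphi -
                std::log(phi + mu) + 1.0 - (y[i] + phi) / (phi + mu);
    }
    if (!std::isfinite(lp)) return R_NegInf;
    lp += coef_prior(th, p, has_intercept, pr, grad);
    lp += half_t_lpdf(phi, pr.disp_df, pr.disp_scale) + lphi;
    (*grad)[p] =
        phi * (dldphi + half_t_grad(phi, pr.disp_df, pr.disp_scale)) + 1.0;
    return lp;
  }
};

// log(y) ~ Normal(Xf beta + Z b, sigma^2); b ~ N(0, tau^2) iid;
// tau, sigma ~ half-t. theta = (beta[pf], b[q], log tau, log sigma)
class SeasonalModel : public Model {
 public:
  NumericMatrix Xf, Z;
  NumericVector logy;
  Prior pr;
  int n, pf, q;
  SeasonalModel(NumericMatrix Xf_, NumericMatrix Z_, NumericVector logy_,
                Prior pr_)
      : Xf(Xf_), Z(Z_), logy(logy_), pr(pr_), n(logy_.size()), pf(Xf_.ncol()),
        q(Z_.ncol()) {}
  int dim() const { return pf + q + 2; }
  double lp_grad(const std::vector<double>& th,
                 std::vector<double>* grad) const {
    std::fill(grad->begin(), grad->end(), 0.0);
    double ltau = th[pf + q], lsig = th[pf + q + 1];
    if (ltau > 30.0 || ltau < -30.0 || lsig > 30.0 || lsig < -30.0)
      return R_NegInf;
    double tau = std::exp(ltau), sig = std::exp(lsig);
    double lp = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double eta = 0.0;
      for (int j = 0; j < pf; ++j) eta += Xf(i, j) * th[j];
      for (int k = 0; k < q; ++k) eta += Z(i, k) * th[pf + k];
      double r = logy[i] - eta;
      ss += r * r;
      double w = r / (sig * sig);
      for (int j = 0; j < pf; ++j) (*grad)[j] += w * Xf(i, j);
      for (int k = 0; k < q; ++k) (*grad)[pf + k] += w * Z(i, k);
    }
    lp += -0.5 * n * std::log(2.0 * M_PI) - n * lsig - 0.5 * ss / (sig * sig);
    lp += coef_prior(th, pf, true, pr, grad);
    // spline coefficients ~ N(0, tau)
    double sb2 = 0.0;
    for (int k = 0; k < q; ++k) {
      sb2 += th[pf + k] * th[pf + k];
      (*grad)[pf + k] += -th[pf + k] / (tau * tau);
    }
    lp += -0.5 * sb2 / (tau * tau) - q * ltau;
    lp += half_t_lpdf(tau, pr.spline_df, pr.spline_scale) + ltau;
    lp += half_t_lpdf(sig, pr.disp_df, pr.disp_scale) + lsig;
    if (!std::isfinite(lp)) return R_NegInf;
    (*grad)[pf + q] = (sb2 / (tau * tau) - q) +
                      tau * half_t_grad(tau, pr.spline_df, pr.spline_scale) +
                      1.0;
    (*grad)[pf + q + 1] = (ss / (sig * sig) - n) +
                          sig * half_t_grad(sig, pr.disp_df, pr.disp_scale) +
                          1.0;
    return lp;
  }
};

static Prior make_prior(List prior) {
  Prior pr;
  pr.intercept_scale = as<double>(prior["intercept_scale"]);
  pr.slope_scale = as<double>(prior["slope_scale"]);
  pr.disp_df = as<double>(prior["dispersion_df"]);
  pr.disp_scale = as<double>(prior["dispersion_scale"]);
  pr.spline_df = prior.containsElementNamed("spline_df")
                     ? as<double>(prior["spline_df"])
                     : 3.0;
  pr.spline_scale = prior.containsElementNamed("spline_scale")
                        ? as<double>(prior["spline_scale"])
                        : 2.0;
  return pr;
}

static Model* make_model(const std::string& family, List data, List prior) {
  Prior pr = make_prior(prior);
  bool ic = as<bool>(data["includes_intercept"]);
  if (family == "beta") {
    return new BetaRegModel(as<NumericMatrix>(data["X"]),
                            as<NumericVector>(data["y"]), pr, ic);
  } else if (family == "negbin") {
    return new NegbinRegModel(as<NumericMatrix>(data["X"]),
                              as<NumericVector>(data["y"]), pr, ic);
  } else if (family == "seasonal_trend") {
    return new SeasonalModel(as<NumericMatrix>(data["Xf"]),
                             as<NumericMatrix>(data["Z"]),
                             as<NumericVector>(data["logy"]), pr);
  }
  stop("unknown family: " + family);
  return 0;
}

// exposed for cross-checking the C++ target against the R-level
// loglik + log_prior (+ log-scale Jacobians)
// [[Rcpp::export]]
double cf_log_posterior(std::string family, List data, List prior,
                        NumericVector theta) {
  Model* m = make_model(family, data, prior);
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> g(m->dim());
  double lp = m->lp_grad(th, &g);
  delete m;
  return lp;
}

// [[Rcpp::export]]
NumericVector cf_log_posterior_grad(std::string family, List data, List prior,
                                    NumericVector theta) {
  Model* m = make_model(family, data, prior);
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> g(m->dim());
  m->lp_grad(th, &g);
  delete m;
  return wrap(g);
}

// ---------------------------------------------------------------------------
// NUTS
// ---------------------------------------------------------------------------

// ---------------------------------------------------------------------------
// NUTS with a dense metric
//
// The metric S approximates the posterior covariance (estimated from the
// middle warmup window). Momenta are drawn r ~ N(0, S^-1) via the Cholesky
// factor of S; position updates use the velocity v = S r. A dense metric
// matters here because interaction designs make the coefficient posterior
// strongly correlated.
// ---------------------------------------------------------------------------

struct Point {
  std::vector<double> th, r, grad;
  double lp;
};

class Metric {
 public:
  int d;
  std::vector<double> S;  // d x d, row-major; posterior covariance estimate
  std::vector<double> L;  // lower Cholesky of S
  Metric(int d_) : d(d_), S(d_ * d_, 0.0), L(d_ * d_, 0.0) {}

  void set_diagonal(const std::vector<double>& v) {
    std::fill(S.begin(), S.end(), 0.0);
    for (int j = 0; j < d; ++j) S[j * d + j] = v[j];
    chol();
  }

  // returns false if the matrix is not positive definite
  bool chol() {
    std::fill(L.begin(), L.end(), 0.0);
    for (int i = 0; i < d; ++i) {
      for (int j = 0; j <= i; ++j) {
        double s = S[i * d + j];
        for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
        if (i == j) {
          if (s <= 0.0) return false;
          L[i * d + i] = std::sqrt(s);
        } else {
          L[i * d + j] = s / L[j * d + j];
        }
      }
    }
    return true;
  }

  // r = L^-T z gives r ~ N(0, S^-1) for z ~ N(0, I)
  void sample_momentum(std::vector<double>* r) const {
    std::vector<double> z(d);
    for (int j = 0; j < d; ++j) z[j] = R::norm_rand();
    for (int i = d - 1; i >= 0; --i) {
      double s = z[i];
      for (int k = i + 1; k < d; ++k) s -= L[k * d + i] * (*r)[k];
      (*r)[i] = s / L[i * d + i];
    }
  }

  void velocity(const std::vector<double>& r, std::vector<double>* v) const {
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) s += S[i * d + j] * r[j];
      (*v)[i] = s;
    }
  }

  double kinetic(const std::vector<double>& r) const {
    std::vector<double> v(d);
    velocity(r, &v);
    double k = 0.0;
    for (int j = 0; j < d; ++j) k += r[j] * v[j];
    return 0.5 * k;
  }
};

class Nuts {
 public:
  const Model* model;
  int d;
  Metric metric;
  double eps;
  int max_td;
  long n_grad;
  int n_divergent;

  Nuts(const Model* m, const std::vector<double>& diag0)
      : model(m), d(m->dim()), metric(m->dim()), eps(0.1), max_td(10),
        n_grad(0), n_divergent(0) {
    metric.set_diagonal(diag0);
  }

  void leapfrog(Point* z, double step) {
    std::vector<double> v(d);
    for (int j = 0; j < d; ++j) z->r[j] += 0.5 * step * z->grad[j];
    metric.velocity(z->r, &v);
    for (int j = 0; j < d; ++j) z->th[j] += step * v[j];
    z->lp = model->lp_grad(z->th, &z->grad);
    ++n_grad;
    for (int j = 0; j < d; ++j) z->r[j] += 0.5 * step * z->grad[j];
  }

  double joint(const Point& z) const {
    double h = z.lp - metric.kinetic(z.r);
    return std::isfinite(h) ? h : R_NegInf;
  }

  // heuristic for an initial step size (double/halve until the acceptance
  // probability of one leapfrog step crosses 1/2)
  void init_stepsize(const Point& start) {
    Point z = start;
    metric.sample_momentum(&z.r);
    double h0 = joint(z);
    eps = 0.1;
    Point z1 = z;
    leapfrog(&z1, eps);
    double h1 = joint(z1);
    double a = (h1 - h0 > std::log(0.5)) ? 1.0 : -1.0;
    for (int it = 0; it < 100; ++it) {
      z1 = z;
      leapfrog(&z1, eps * std::pow(2.0, a));
      h1 = joint(z1);
      if (!(a * (h1 - h0) > -a * std::log(2.0))) break;
      eps *= std::pow(2.0, a);
      if (eps > 1e6 || eps < 1e-10) break;
    }
  }

  struct Tree {
    Point minus, plus, prop;
    double n;      // slice-acceptable states in the subtree
    bool ok;       // no u-turn, no divergence
    double alpha;  // sum of acceptance statistics
    int n_alpha;
  };

  bool no_uturn(const Point& minus, const Point& plus) const {
    std::vector<double> vm(d), vp(d);
    metric.velocity(minus.r, &vm);
    metric.velocity(plus.r, &vp);
    double smin = 0.0, splus = 0.0;
    for (int j = 0; j < d; ++j) {
      double dth = plus.th[j] - minus.th[j];
      smin += dth * vm[j];
      splus += dth * vp[j];
    }
    return smin >= 0.0 && splus >= 0.0;
  }

  void build_tree(const Point& z, double logu, int v, int depth, double h0,
                  Tree* out) {
    if (depth == 0) {
      Point z1 = z;
      leapfrog(&z1, v * eps);
      double h = joint(z1);
      out->minus = z1;
      out->plus = z1;
      out->prop = z1;
      out->n = (logu <= h) ? 1.0 : 0.0;
      bool diverged = (h - logu) < -1000.0 || !std::isfinite(h);
      if (diverged) ++n_divergent;
      out->ok = !diverged;
      double da = h - h0;
      out->alpha = da > 0.0 ? 1.0 : std::exp(da);
      if (!std::isfinite(out->alpha)) out->alpha = 0.0;
      out->n_alpha = 1;
      return;
    }
    build_tree(z, logu, v, depth - 1, h0, out);
    if (!out->ok) return;
    Tree t2;
    if (v == -1) {
      build_tree(out->minus, logu, v, depth - 1, h0, &t2);
      out->minus = t2.minus;
    } else {
      build_tree(out->plus, logu, v, depth - 1, h0, &t2);
      out->plus = t2.plus;
    }
    if (t2.ok && t2.n > 0.0 && R::unif_rand() < t2.n / (out->n + t2.n))
      out->prop = t2.prop;
    out->n += t2.n;
    out->ok = t2.ok && no_uturn(out->minus, out->plus);
    out->alpha += t2.alpha;
    out->n_alpha += t2.n_alpha;
  }

  // one transition; returns the mean acceptance statistic for dual averaging
  double transition(Point* cur) {
    Point z = *cur;
    z.r.resize(d);
    metric.sample_momentum(&z.r);
    double h0 = joint(z);
    double logu = h0 - R::exp_rand();
    Point zm = z, zp = z, prop = z;
    double n_good = 1.0;
    bool ok = true;
    double alpha = 1.0;
    int n_alpha = 1;
    for (int depth = 0; ok && depth < max_td; ++depth) {
      int v = (R::unif_rand() < 0.5) ? -1 : 1;
      Tree t;
      if (v == -1) {
        build_tree(zm, logu, v, depth, h0, &t);
        zm = t.minus;
      } else {
        build_tree(zp, logu, v, depth, h0, &t);
        zp = t.plus;
      }
      if (t.ok && t.n > 0.0 && R::unif_rand() < t.n / n_good) prop = t.prop;
      n_good += t.n;
      ok = t.ok && no_uturn(zm, zp);
      alpha = t.alpha;
      n_alpha = t.n_alpha;
    }
    *cur = prop;
    return alpha / n_alpha;
  }
};

// [[Rcpp::export]]
List nuts_run(std::string family, List data, List prior, NumericVector init,
              NumericVector inv_mass0, int n_iter, int n_warmup,
              int max_treedepth, double target_accept) {
  Model* model = make_model(family, data, prior);
  int d = model->dim();
  if (init.size() != d) {
    delete model;
    stop("init has length %d but model dimension is %d", (int)init.size(), d);
  }
  Nuts nuts(model, std::vector<double>(inv_mass0.begin(), inv_mass0.end()));
  nuts.max_td = max_treedepth;

  Point cur;
  cur.th.assign(init.begin(), init.end());
  cur.r.assign(d, 0.0);
  cur.grad.assign(d, 0.0);
  cur.lp = model->lp_grad(cur.th, &cur.grad);
  if (!std::isfinite(cur.lp)) {
    delete model;
    stop("non-finite log posterior at the initial point");
  }

  RNGScope scope;
  nuts.init_stepsize(cur);

  // dual averaging of the step size
  double mu_da = std::log(10.0 * nuts.eps);
  double log_eps_bar = 0.0, h_bar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // covariance estimation window (Welford, full matrix)
  int w_start = (int)(0.25 * n_warmup), w_end = (int)(0.75 * n_warmup);
  std::vector<double> vm(d, 0.0), cov(d * d, 0.0), delta(d);
  long vn = 0;

  int n_keep = n_iter - n_warmup;
  NumericMatrix draws(n_keep, d);
  NumericVector lp_keep(n_keep);

  for (int it = 1; it <= n_iter; ++it) {
    double accept = nuts.transition(&cur);
    if (it <= n_warmup) {
      ++da_count;
      h_bar = (1.0 - 1.0 / (da_count + t0)) * h_bar +
              (target_accept - accept) / (da_count + t0);
      double log_eps = mu_da - std::sqrt((double)da_count) / gamma * h_bar;
      double w = std::pow((double)da_count, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      nuts.eps = std::exp(log_eps);
      if (it > w_start && it <= w_end) {
        ++vn;
        for (int j = 0; j < d; ++j) {
          delta[j] = cur.th[j] - vm[j];
          vm[j] += delta[j] / vn;
        }
        for (int i = 0; i < d; ++i)
          for (int j = 0; j <= i; ++j)
            cov[i * d + j] += delta[i] * (cur.th[j] - vm[j]);
      }
      if (it == w_end && vn > 10) {
        // regularized covariance, shrunk towards a small multiple of the
        // initial (scale-aware) diagonal so raw-scale predictors with tiny
        // coefficient variances are not swamped
        double wn = vn / (vn + 5.0);
        for (int i = 0; i < d; ++i) {
          for (int j = 0; j <= i; ++j) {
            double c = cov[i * d + j] / (vn - 1.0) * wn;
            if (i == j) c += 1e-3 * (5.0 / (vn + 5.0)) * inv_mass0[i];
            nuts.metric.S[i * d + j] = c;
            nuts.metric.S[j * d + i] = c;
          }
        }
        if (!nuts.metric.chol()) {
          // fall back to the diagonal if the estimate is not PD
          std::vector<double> dg(d);
          for (int j = 0; j < d; ++j) dg[j] = nuts.metric.S[j * d + j];
          nuts.metric.set_diagonal(dg);
        }
        nuts.init_stepsize(cur);
        mu_da = std::log(10.0 * nuts.eps);
        log_eps_bar = 0.0;
        h_bar = 0.0;
        da_count = 0;
      }
      if (it == n_warmup) nuts.eps = std::exp(log_eps_bar);
    } else {
      int row = it - n_warmup - 1;
      for (int j = 0; j < d; ++j) draws(row, j) = cur.th[j];
      lp_keep[row] = cur.lp;
    }
  }

  delete model;
  return List::create(_["draws"] = draws, _["lp"] = lp_keep,
                      _["step_size"] = nuts.eps,
                      _["n_divergent"] = nuts.n_divergent,
                      _["n_grad"] = nuts.n_grad);
}
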