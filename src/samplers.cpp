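// Log-posterior gradients for the four spatio-temporal Poisson models and
// the NUTS / random-walk Metropolis samplers. Parameters are handled on
// unconstrained scales (logit for correlation parameters, log for
// variances) with the corresponding Jacobian terms included, so priors
// here match the natural-scale R reference up to those Jacobians.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double LOG2PI = 1.837877066409345483560659472811;

typedef std::function<double(const vec&, vec&)> LpGrad;

struct ModelData {
  int model, N, T, p, dim;
  mat y, off, mask, X, LW, LZ;
  vec lW, lZ, tc;
  double ig_a, ig_b, llconst;
};

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Leroux CAR log density of phi (unconstrained s = log k2), with gradient
// contributions. gphi is added in place; grho and gs accumulate d/d rho and
// d/d s (before any transform chain rule).
static double car_term(const vec& phi, double rho, double s,
                       const mat& L, const vec& l,
                       vec& gphi, double& grho, double& gs) {
  const int n = phi.n_elem;
  vec Lphi = L * phi;
  double q1 = arma::dot(phi, Lphi), q0 = arma::dot(phi, phi);
  double ldet = 0.0, trt = 0.0;
  for (int j = 0; j < n; ++j) {
    double e = rho * l[j] + 1.0 - rho;
    ldet += std::log(e);
    trt += (l[j] - 1.0) / e;
  }
  double ek = std::exp(-s);
  gphi -= ek * (rho * Lphi + (1.0 - rho) * phi);
  grho += 0.5 * trt - 0.5 * ek * (q1 - q0);
  gs += -0.5 * n + 0.5 * ek * (rho * q1 + (1.0 - rho) * q0);
  return -0.5 * n * (LOG2PI + s) + 0.5 * ldet - 0.5 * ek * (rho * q1 + (1.0 - rho) * q0);
}

// inverse-gamma prior on k2 = exp(s), including the log-scale Jacobian
static double ig_term(double s, double a, double b, double& gs) {
  gs += -a + b * std::exp(-s);
  return a * std::log(b) - std::lgamma(a) - a * s - b * std::exp(-s);
}

// uniform(0,1) prior on rho = sigmoid(r): only the Jacobian survives.
// grho holds accumulated d lp / d rho; converts to d/d r in place.
static double rho_finalize(double r, double rho, double& grho_to_gr) {
  grho_to_gr = grho_to_gr * rho * (1.0 - rho) + (1.0 - 2.0 * rho);
  return std::log(rho) + std::log1p(-rho);
}

static double model_lp_grad(const ModelData& D, const vec& th, vec& g) {
  g.zeros(D.dim);
  const int N = D.N, T = D.T, p = D.p;
  vec beta = th.subvec(0, p - 1);
  mat eta = arma::reshape(D.X * beta, N, T) + D.off;
  double lp = D.llconst;

  if (D.model == 1) { // SPLTM
    const int iw1 = p, iw2 = p + 1, ia = p + 2, ib = p + 2 + N;
    const int ir1 = p + 2 + 2 * N, ir2 = ir1 + 1, is1 = ir1 + 2, is2 = ir1 + 3;
    vec a = th.subvec(ia, ia + N - 1), b = th.subvec(ib, ib + N - 1);
    double w1 = th[iw1], w2 = th[iw2];
    double rho1 = sigmoid(th[ir1]), rho2 = sigmoid(th[ir2]);
    double s1 = th[is1], s2 = th[is2];
    mat lmu = eta;
    lmu.each_col() += a + w1;
    lmu += (w2 + b) * D.tc.t(); // (w2 + b_i) * tc_t
    mat mu = arma::exp(lmu);
    lp += arma::accu(D.mask % (D.y % lmu - mu));
    mat R = D.mask % (D.y - mu);
    g.subvec(0, p - 1) = D.X.t() * arma::vectorise(R);
    vec rowR = arma::sum(R, 1);
    vec Rtc = R * D.tc;
    g[iw1] = arma::accu(rowR);
    g[iw2] = arma::accu(Rtc);
    vec ga = rowR, gb = Rtc;
    double gr1 = 0, gr2 = 0, gs1 = 0, gs2 = 0;
    lp += car_term(a, rho1, s1, D.LW, D.lW, ga, gr1, gs1);
    lp += car_term(b, rho2, s2, D.LW, D.lW, gb, gr2, gs2);
    lp += ig_term(s1, D.ig_a, D.ig_b, gs1);
    lp += ig_term(s2, D.ig_a, D.ig_b, gs2);
    lp += rho_finalize(th[ir1], rho1, gr1);
    lp += rho_finalize(th[ir2], rho2, gr2);
    g.subvec(ia, ia + N - 1) = ga;
    g.subvec(ib, ib + N - 1) = gb;
    g[ir1] = gr1; g[ir2] = gr2; g[is1] = gs1; g[is2] = gs2;

  } else if (D.model == 2) { // SPAM
    const int ia = p, ib = p + N, ic = p + N + T;
    const int irs = ic + N * T, irT = irs + 1, iss = irs + 2, isT = irs + 3, isI = irs + 4;
    vec a = th.subvec(ia, ia + N - 1), b = th.subvec(ib, ib + T - 1);
    vec c = th.subvec(ic, ic + N * T - 1);
    double rs = sigmoid(th[irs]), rT = sigmoid(th[irT]);
    double ss = th[iss], sT = th[isT], sI = th[isI];
    mat lmu = eta + arma::reshape(c, N, T);
    lmu.each_col() += a;
    lmu.each_row() += b.t();
    mat mu = arma::exp(lmu);
    lp += arma::accu(D.mask % (D.y % lmu - mu));
    mat R = D.mask % (D.y - mu);
    g.subvec(0, p - 1) = D.X.t() * arma::vectorise(R);
    vec ga = arma::sum(R, 1);
    vec gb = arma::sum(R, 0).t();
    double grs = 0, grT = 0, gss = 0, gsT = 0, gsI = 0;
    lp += car_term(a, rs, ss, D.LW, D.lW, ga, grs, gss);
    lp += car_term(b, rT, sT, D.LZ, D.lZ, gb, grT, gsT);
    double ekI = std::exp(-sI), cc = arma::dot(c, c);
    lp += -0.5 * N * T * (LOG2PI + sI) - 0.5 * ekI * cc;
    gsI += -0.5 * N * T + 0.5 * ekI * cc;
    g.subvec(ic, ic + N * T - 1) = arma::vectorise(R) - ekI * c;
    lp += ig_term(ss, D.ig_a, D.ig_b, gss);
    lp += ig_term(sT, D.ig_a, D.ig_b, gsT);
    lp += ig_term(sI, D.ig_a, D.ig_b, gsI);
    lp += rho_finalize(th[irs], rs, grs);
    lp += rho_finalize(th[irT], rT, grT);
    g.subvec(ia, ia + N - 1) = ga;
    g.subvec(ib, ib + T - 1) = gb;
    g[irs] = grs; g[irT] = grT; g[iss] = gss; g[isT] = gsT; g[isI] = gsI;

  } else if (D.model == 3) { // STSM
    const int ia = p, ib = p + N * T;
    const int irs = p + N * T + T, irT = irs + 1, ist = irs + 2, is0 = irs + 2 + T;
    mat A = arma::reshape(th.subvec(ia, ia + N * T - 1), N, T);
    vec b = th.subvec(ib, ib + T - 1);
    double rs = sigmoid(th[irs]), rT = sigmoid(th[irT]), s0 = th[is0];
    mat lmu = eta + A;
    lmu.each_row() += b.t();
    mat mu = arma::exp(lmu);
    lp += arma::accu(D.mask % (D.y % lmu - mu));
    mat R = D.mask % (D.y - mu);
    g.subvec(0, p - 1) = D.X.t() * arma::vectorise(R);
    mat gA = R;
    double grs = 0, grT = 0, gs0 = 0;
    for (int t = 0; t < T; ++t) {
      vec at = A.col(t), gat = gA.col(t);
      double gst = 0;
      lp += car_term(at, rs, th[ist + t], D.LW, D.lW, gat, grs, gst);
      lp += ig_term(th[ist + t], D.ig_a, D.ig_b, gst);
      gA.col(t) = gat;
      g[ist + t] = gst;
    }
    vec gb = arma::sum(R, 0).t();
    lp += car_term(b, rT, s0, D.LZ, D.lZ, gb, grT, gs0);
    lp += ig_term(s0, D.ig_a, D.ig_b, gs0);
    lp += rho_finalize(th[irs], rs, grs);
    lp += rho_finalize(th[irT], rT, grT);
    g.subvec(ia, ia + N * T - 1) = arma::vectorise(gA);
    g.subvec(ib, ib + T - 1) = gb;
    g[irs] = grs; g[irT] = grT; g[is0] = gs0;

  } else { // TMS
    const int ia = p, irs = p + N * T, irT = irs + 1, is0 = irs + 2;
    mat A = arma::reshape(th.subvec(ia, ia + N * T - 1), N, T);
    double rs = sigmoid(th[irs]), rT = sigmoid(th[irT]), s0 = th[is0];
    mat lmu = eta + A;
    mat mu = arma::exp(lmu);
    lp += arma::accu(D.mask % (D.y % lmu - mu));
    mat R = D.mask % (D.y - mu);
    g.subvec(0, p - 1) = D.X.t() * arma::vectorise(R);
    mat gA = R;
    double ldet = 0.0, trt = 0.0;
    for (arma::uword j = 0; j < D.lW.n_elem; ++j) {
      double e = rs * D.lW[j] + 1.0 - rs;
      ldet += std::log(e);
      trt += (D.lW[j] - 1.0) / e;
    }
    double ek = std::exp(-s0);
    double grs = 0, grT = 0, gs0 = 0, qsum = 0, dq = 0;
    for (int t = 0; t < T; ++t) {
      vec e = (t == 0) ? vec(A.col(0)) : vec(A.col(t) - rT * A.col(t - 1));
      vec Le = D.LW * e;
      double q1 = arma::dot(e, Le), q0 = arma::dot(e, e);
      qsum += rs * q1 + (1.0 - rs) * q0;
      dq += q1 - q0;
      vec u = rs * Le + (1.0 - rs) * e;
      gA.col(t) -= ek * u;
      if (t > 0) {
        gA.col(t - 1) += rT * ek * u;
        grT += ek * arma::dot(A.col(t - 1), u);
      }
    }
    lp += T * (-0.5 * N * (LOG2PI + s0) + 0.5 * ldet) - 0.5 * ek * qsum;
    grs += 0.5 * T * trt - 0.5 * ek * dq;
    gs0 += -0.5 * N * T + 0.5 * ek * qsum;
    lp += ig_term(s0, D.ig_a, D.ig_b, gs0);
    lp += rho_finalize(th[irs], rs, grs);
    lp += rho_finalize(th[irT], rT, grT);
    g.subvec(ia, ia + N * T - 1) = arma::vectorise(gA);
    g[irs] = grs; g[irT] = grT; g[is0] = gs0;
  }

  if (!std::isfinite(lp)) { lp = -arma::datum::inf; }
  return lp;
}

static ModelData build_model_data(List cd) {
  ModelData D;
  D.model = as<int>(cd["model"]);
  D.N = as<int>(cd["N"]); D.T = as<int>(cd["T"]); D.p = as<int>(cd["p"]);
  D.dim = as<int>(cd["dim"]);
  D.y = as<mat>(cd["y"]); D.off = as<mat>(cd["off"]); D.mask = as<mat>(cd["mask"]);
  D.X = as<mat>(cd["X"]);
  D.LW = as<mat>(cd["LW"]); D.lW = as<vec>(cd["lW"]);
  D.LZ = as<mat>(cd["LZ"]); D.lZ = as<vec>(cd["lZ"]);
  D.tc = as<vec>(cd["tc"]);
  D.ig_a = as<double>(cd["ig_a"]); D.ig_b = as<double>(cd["ig_b"]);
  D.llconst = as<double>(cd["llconst"]);
  return D;
}

// [[Rcpp::export]]
List cpp_lp_grad(List cdata, arma::vec theta) {
  ModelData D = build_model_data(cdata);
  vec g(D.dim);
  double lp = model_lp_grad(D, theta, g);
  return List::create(_["value"] = lp, _["grad"] = g);
}

// ---- samplers ---------------------------------------------------------------

static vec draw_momentum(int dim, const vec& minv) {
  vec r(dim);
  for (int i = 0; i < dim; ++i) r[i] = norm_rand() / std::sqrt(minv[i]);
  return r;
}

static inline double kinetic(const vec& r, const vec& minv) {
  return 0.5 * arma::dot(r % r, minv);
}

static void leapfrog(const LpGrad& f, vec& th, vec& r, vec& g, double& lp,
                     double eps, const vec& minv) {
  r += 0.5 * eps * g;
  th += eps * (minv % r);
  lp = f(th, g);
  r += 0.5 * eps * g;
}

struct BT {
  vec thm, rm, gm, thp, rp, gp, thpr, gpr;
  double lppr;
  long n;
  bool s;
  double alpha;
  long nalpha;
};

static const double DELTA_MAX = 1000.0;

static BT build_tree(const LpGrad& f, vec th, vec r, vec g, double logu,
                     int v, int j, double eps, const vec& minv,
                     double joint0, int& divergences) {
  BT out;
  if (j == 0) {
    double lp;
    leapfrog(f, th, r, g, lp, v * eps, minv);
    double joint = lp - kinetic(r, minv);
    out.thm = th; out.rm = r; out.gm = g;
    out.thp = th; out.rp = r; out.gp = g;
    out.thpr = th; out.gpr = g; out.lppr = lp;
    out.n = (logu <= joint) ? 1 : 0;
    out.s = (logu < joint + DELTA_MAX);
    if (!out.s) ++divergences;
    double d = joint - joint0;
    out.alpha = (d > 0) ? 1.0 : std::exp(d);
    if (!std::isfinite(out.alpha)) out.alpha = 0.0;
    out.nalpha = 1;
    return out;
  }
  out = build_tree(f, th, r, g, logu, v, j - 1, eps, minv, joint0, divergences);
  if (out.s) {
    BT o2;
    if (v == -1) {
      o2 = build_tree(f, out.thm, out.rm, out.gm, logu, v, j - 1, eps, minv,
                      joint0, divergences);
      out.thm = o2.thm; out.rm = o2.rm; out.gm = o2.gm;
    } else {
      o2 = build_tree(f, out.thp, out.rp, out.gp, logu, v, j - 1, eps, minv,
                      joint0, divergences);
      out.thp = o2.thp; out.rp = o2.rp; out.gp = o2.gp;
    }
    if (o2.n > 0 && unif_rand() < (double)o2.n / (double)(out.n + o2.n)) {
      out.thpr = o2.thpr; out.gpr = o2.gpr; out.lppr = o2.lppr;
    }
    vec dth = out.thp - out.thm;
    bool noturn = (arma::dot(dth, minv % out.rm) >= 0) &&
                  (arma::dot(dth, minv % out.rp) >= 0);
    out.s = o2.s && noturn;
    out.n += o2.n;
    out.alpha += o2.alpha;
    out.nalpha += o2.nalpha;
  }
  return out;
}

static double find_eps(const LpGrad& f, const vec& th0, const vec& minv) {
  double eps = 0.1;
  vec g0(th0.n_elem);
  double lp0 = f(th0, g0);
  vec r0 = draw_momentum(th0.n_elem, minv);
  double joint0 = lp0 - kinetic(r0, minv);
  vec th = th0, r = r0, g = g0;
  double lp;
  leapfrog(f, th, r, g, lp, eps, minv);
  double joint = lp - kinetic(r, minv);
  if (!std::isfinite(joint)) {
    while (!std::isfinite(joint) && eps > 1e-10) {
      eps *= 0.5;
      th = th0; r = r0; g = g0;
      leapfrog(f, th, r, g, lp, eps, minv);
      joint = lp - kinetic(r, minv);
    }
    return eps;
  }
  double a = (joint - joint0 > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    if (a * (joint - joint0) <= -a * std::log(2.0)) break;
    eps *= std::pow(2.0, a);
    th = th0; r = r0; g = g0;
    leapfrog(f, th, r, g, lp, eps, minv);
    joint = lp - kinetic(r, minv);
    if (!std::isfinite(joint)) { eps *= 0.5; break; }
  }
  return eps;
}

static List run_nuts(const LpGrad& f, vec th, int n_total, int burn_in, int thin,
                     double delta, int max_treedepth, bool adapt_mass) {
  const int dim = th.n_elem;
  vec minv(dim, arma::fill::ones);
  vec g(dim);
  double lp = f(th, g);
  if (!std::isfinite(lp)) stop("non-finite log posterior at initial state");

  double eps = find_eps(f, th, minv);
  double mu = std::log(10.0 * eps), Hbar = 0.0, logebar = std::log(eps);
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int awin = 0;

  const int n_keep = (n_total - burn_in) / thin;
  arma::mat draws(n_keep, dim);
  int kept = 0, divergences = 0;
  double alpha_sum = 0.0;
  long alpha_n = 0;

  const int w_lo = burn_in / 4, w_hi = burn_in / 2;
  arma::running_stat_vec<vec> rs;

  for (int h = 1; h <= n_total; ++h) {
    vec r0 = draw_momentum(dim, minv);
    double joint0 = lp - kinetic(r0, minv);
    double logu = joint0 - exp_rand();
    vec thm = th, thp = th, rm = r0, rp = r0, gm = g, gp = g;
    long n = 1;
    bool s = true;
    double alpha = 0;
    long nalpha = 1;
    int j = 0;
    while (s && j < max_treedepth) {
      int v = (unif_rand() < 0.5) ? -1 : 1;
      BT o;
      if (v == -1) {
        o = build_tree(f, thm, rm, gm, logu, v, j, eps, minv, joint0, divergences);
        thm = o.thm; rm = o.rm; gm = o.gm;
      } else {
        o = build_tree(f, thp, rp, gp, logu, v, j, eps, minv, joint0, divergences);
        thp = o.thp; rp = o.rp; gp = o.gp;
      }
      if (o.s && o.n > 0 && unif_rand() < std::min(1.0, (double)o.n / (double)n)) {
        th = o.thpr; g = o.gpr; lp = o.lppr;
      }
      n += o.n;
      alpha = o.alpha; nalpha = o.nalpha;
      vec dth = thp - thm;
      s = o.s && (arma::dot(dth, minv % rm) >= 0) && (arma::dot(dth, minv % rp) >= 0);
      ++j;
    }

    if (h <= burn_in) {
      ++awin;
      double adapt_stat = delta - alpha / (double)nalpha;
      Hbar = (1.0 - 1.0 / (awin + t0)) * Hbar + adapt_stat / (awin + t0);
      double logeps = mu - std::sqrt((double)awin) / gamma * Hbar;
      double etaw = std::pow((double)awin, -kappa);
      logebar = etaw * logeps + (1.0 - etaw) * logebar;
      eps = std::exp(logeps);
      if (adapt_mass && h >= w_lo && h < w_hi) rs(th);
      if (adapt_mass && h == w_hi && rs.count() > 10) {
        vec v2 = rs.var();
        for (int i = 0; i < dim; ++i) minv[i] = std::max(v2[i], 1e-8);
        eps = find_eps(f, th, minv);
        mu = std::log(10.0 * eps);
        Hbar = 0.0; logebar = std::log(eps); awin = 0;
      }
      if (h == burn_in) eps = std::exp(logebar);
    } else {
      alpha_sum += alpha / (double)nalpha;
      ++alpha_n;
      if ((h - burn_in) % thin == 0 && kept < n_keep)
        draws.row(kept++) = th.t();
    }
  }
  return List::create(
    _["draws"] = draws.rows(0, std::max(kept - 1, 0)),
    _["accept_rate"] = alpha_n ? alpha_sum / alpha_n : NA_REAL,
    _["step_size"] = eps,
    _["divergences"] = divergences);
}

static List run_rwm(const LpGrad& f, vec th, int n_total, int burn_in, int thin,
                    double scale0) {
  const int dim = th.n_elem;
  vec g(dim);
  double lp = f(th, g);
  if (!std::isfinite(lp)) stop("non-finite log posterior at initial state");
  double lsc = std::log(scale0 > 0 ? scale0 : 2.38 / std::sqrt((double)dim));
  const int n_keep = (n_total - burn_in) / thin;
  arma::mat draws(n_keep, dim);
  int kept = 0;
  long acc = 0, tries = 0;
  for (int h = 1; h <= n_total; ++h) {
    vec prop = th;
    double sc = std::exp(lsc);
    for (int i = 0; i < dim; ++i) prop[i] += sc * norm_rand();
    vec gdummy;
    double lpp = f(prop, gdummy);
    double a = std::exp(std::min(0.0, lpp - lp));
    bool ok = (unif_rand() < a);
    if (ok) { th = prop; lp = lpp; }
    if (h <= burn_in) {
      lsc += (a - 0.234) / std::pow((double)h, 0.6);
    } else {
      acc += ok; ++tries;
      if ((h - burn_in) % thin == 0 && kept < n_keep)
        draws.row(kept++) = th.t();
    }
  }
  if (tries > 0 && acc == 0) stop("random-walk chain rejected every proposal");
  return List::create(
    _["draws"] = draws.rows(0, std::max(kept - 1, 0)),
    _["accept_rate"] = tries ? (double)acc / tries : NA_REAL,
    _["step_size"] = std::exp(lsc),
    _["divergences"] = 0);
}

// [[Rcpp::export]]
List cpp_sample(List cdata, Nullable<Function> cb, arma::vec init,
                int n_total, int burn_in, int thin, std::string sampler,
                double target_accept, int max_treedepth, bool adapt_mass,
                double rwm_scale) {
  LpGrad f;
  ModelData D;
  if (cb.isNotNull()) {
    Function fn(cb);
    f = [fn](const vec& th, vec& g) -> double {
      List res = fn(NumericVector(th.begin(), th.end()));
      g = as<vec>(res["grad"]);
      return as<double>(res["value"]);
    };
  } else {
    D = build_model_data(cdata);
    f = [&D](const vec& th, vec& g) -> double { return model_lp_grad(D, th, g); };
  }
  if (burn_in >= n_total) stop("burn_in must be smaller than n_total");
  if (thin < 1) stop("thin must be >= 1");
  if (sampler == "nuts")
    return run_nuts(f, init, n_total, burn_in, thin, target_accept,
                    max_treedepth, adapt_mass);
  return run_rwm(f, init, n_total, burn_in, thin, rwm_scale);
}
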