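// Shot-noise Cox process core: likelihood with window-grid quadrature and
// the birth-death MCMC sampler. The intensity is
//   lambda(x) = eps + sum_j w_j * phi(x; c_j, Sigma_j)
// on a lung window W (set of grid cells), and the Poisson log likelihood is
//   sum_i log lambda(x_i) - [eps*|W| + sum_j w_j * mass_j],
// mass_j being the Gaussian mass inside W computed by mid-point quadrature
// over window cells. Kernel evaluation is truncated beyond 6 standard
// deviations of the widest axis (relative mass outside < 1e-7).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Cov2 {
  double s11, s12, s22;
  double det() const { return s11 * s22 - s12 * s12; }
  bool pd() const { return s11 > 0.0 && s22 > 0.0 && det() > 1e-12; }
  double lmax() const {
    double t = 0.5 * (s11 + s22);
    double d = std::sqrt(0.25 * (s11 - s22) * (s11 - s22) + s12 * s12);
    return t + d;
  }
};

struct Window {
  const int *cells_i;  // 1-based column/row indices of window cells
  const int *cells_j;
  int n_cells;
  const int *grid;     // nx*ny indicator (column-major)
  int nx, ny;
  double dx, dy, cell_area;
  double area() const { return n_cells * cell_area; }
  bool inside(double x, double y) const {
    int ix = (int)std::ceil(x / dx);
    int iy = (int)std::ceil(y / dy);
    if (ix < 1 || ix > nx || iy < 1 || iy > ny) return false;
    return grid[(ix - 1) + (iy - 1) * nx] != 0;
  }
};

// Gaussian density contributions of one cluster at all data points.
static void cluster_point_dens(const std::vector<double> &px,
                               const std::vector<double> &py,
                               double cx, double cy, const Cov2 &S,
                               std::vector<double> &out) {
  double det = S.det();
  double i11 = S.s22 / det, i22 = S.s11 / det, i12 = -S.s12 / det;
  double norm = 1.0 / (2.0 * M_PI * std::sqrt(det));
  size_t n = px.size();
  for (size_t i = 0; i < n; ++i) {
    double ux = px[i] - cx, uy = py[i] - cy;
    double q = i11 * ux * ux + 2.0 * i12 * ux * uy + i22 * uy * uy;
    out[i] = (q > 72.0) ? 0.0 : norm * std::exp(-0.5 * q);
  }
}

// Mid-point quadrature of the Gaussian over window cells within 6 sd.
static double window_mass(const Window &W, double cx, double cy,
                          const Cov2 &S) {
  double det = S.det();
  double i11 = S.s22 / det, i22 = S.s11 / det, i12 = -S.s12 / det;
  double norm = 1.0 / (2.0 * M_PI * std::sqrt(det));
  double r = 6.0 * std::sqrt(S.lmax());
  int ilo = std::max(1, (int)std::floor((cx - r) / W.dx) + 1);
  int ihi = std::min(W.nx, (int)std::ceil((cx + r) / W.dx));
  int jlo = std::max(1, (int)std::floor((cy - r) / W.dy) + 1);
  int jhi = std::min(W.ny, (int)std::ceil((cy + r) / W.dy));
  double m = 0.0;
  for (int j = jlo; j <= jhi; ++j) {
    double gy = (j - 0.5) * W.dy - cy;
    for (int i = ilo; i <= ihi; ++i) {
      if (!W.grid[(i - 1) + (j - 1) * W.nx]) continue;
      double gx = (i - 0.5) * W.dx - cx;
      double q = i11 * gx * gx + 2.0 * i12 * gx * gy + i22 * gy * gy;
      if (q <= 72.0) m += norm * std::exp(-0.5 * q);
    }
  }
  return m * W.cell_area;
}

static Window make_window(const IntegerMatrix &grid, double dx, double dy,
                          const IntegerVector &ci, const IntegerVector &cj) {
  Window W;
  W.grid = grid.begin();
  W.nx = grid.nrow();
  W.ny = grid.ncol();
  W.dx = dx;
  W.dy = dy;
  W.cell_area = dx * dy;
  W.cells_i = ci.begin();
  W.cells_j = cj.begin();
  W.n_cells = 0;
  for (int k = 0; k < W.nx * W.ny; ++k)
    if (W.grid[k]) ++W.n_cells;
  return W;
}

// [[Rcpp::export(name = ".sncp_window_mass_cpp")]]
NumericVector sncp_window_mass_cpp(IntegerMatrix grid, double dx, double dy,
                                   NumericMatrix centers, NumericMatrix covs) {
  IntegerVector dummy(0);
  Window W = make_window(grid, dx, dy, dummy, dummy);
  int K = centers.nrow();
  NumericVector out(K);
  for (int j = 0; j < K; ++j) {
    Cov2 S{covs(j, 0), covs(j, 1), covs(j, 2)};
    if (!S.pd()) stop("covariance %d is not positive definite", j + 1);
    out[j] = window_mass(W, centers(j, 0), centers(j, 1), S);
  }
  return out;
}

// [[Rcpp::export(name = ".sncp_loglik_cpp")]]
double sncp_loglik_cpp(NumericVector px, NumericVector py,
                       IntegerMatrix grid, double dx, double dy,
                       NumericMatrix centers, NumericVector weights,
                       NumericMatrix covs, double eps) {
  IntegerVector dummy(0);
  Window W = make_window(grid, dx, dy, dummy, dummy);
  int n = px.size(), K = centers.nrow();
  std::vector<double> pxv(px.begin(), px.end()), pyv(py.begin(), py.end());
  std::vector<double> S(n, 0.0), tmp(n);
  double integral = eps * W.area();
  for (int j = 0; j < K; ++j) {
    Cov2 Sg{covs(j, 0), covs(j, 1), covs(j, 2)};
    if (!Sg.pd()) stop("covariance %d is not positive definite", j + 1);
    cluster_point_dens(pxv, pyv, centers(j, 0), centers(j, 1), Sg, tmp);
    for (int i = 0; i < n; ++i) S[i] += weights[j] * tmp[i];
    integral += weights[j] * window_mass(W, centers(j, 0), centers(j, 1), Sg);
  }
  double ll = -integral;
  for (int i = 0; i < n; ++i) ll += std::log(eps + S[i]);
  return ll;  // -Inf when eps = 0 and some point gets zero cluster intensity
}

// ---- sampler ----------------------------------------------------------

struct Cluster {
  double cx, cy, w;
  Cov2 S;
  double mass;                  // Gaussian mass in window
  std::vector<double> dens;     // phi_ij at data points (unweighted)
};

struct Priors {
  double kappa;     // Poisson mean for K
  int kmax;
  double w_shape, w_rate;
  double iw_df, iw_scale;   // inverse-Wishart(df, scale * I)
  double eps_shape, eps_rate;
};

static double log_iw_prior(const Cov2 &S, const Priors &pr) {
  // p=2: |Sigma|^{-(df+3)/2} exp(-0.5 * scale * tr(Sigma^{-1}))
  double det = S.det();
  double tr_inv = (S.s11 + S.s22) / det;
  return -0.5 * (pr.iw_df + 3.0) * std::log(det) - 0.5 * pr.iw_scale * tr_inv;
}

static Cov2 riw_draw(const Priors &pr) {
  // Sigma ~ IW(df, scale*I)  <=>  Sigma = (scale^{-1} * Wish(df, I))^{-1}
  // Bartlett: W = A A' with a11=sqrt(chisq_df), a22=sqrt(chisq_{df-1}),
  // a21 ~ N(0,1); then Sigma = scale * W^{-1}.
  double a11 = std::sqrt(R::rchisq(pr.iw_df));
  double a22 = std::sqrt(R::rchisq(pr.iw_df - 1.0));
  double a21 = R::rnorm(0.0, 1.0);
  double w11 = a11 * a11;
  double w21 = a11 * a21;
  double w22 = a21 * a21 + a22 * a22;
  double det = w11 * w22 - w21 * w21;
  Cov2 S;
  S.s11 = pr.iw_scale * w22 / det;
  S.s22 = pr.iw_scale * w11 / det;
  S.s12 = -pr.iw_scale * w21 / det;
  return S;
}

// [[Rcpp::export(name = ".sncp_mcmc_cpp")]]
List sncp_mcmc_cpp(NumericVector px, NumericVector py,
                   IntegerMatrix grid, double dx, double dy,
                   List priors, List init, List chain,
                   bool constant_lik = false) {
  IntegerVector win_i, win_j;
  {
    std::vector<int> wi, wj;
    for (int j = 0; j < grid.ncol(); ++j)
      for (int i = 0; i < grid.nrow(); ++i)
        if (grid(i, j)) { wi.push_back(i + 1); wj.push_back(j + 1); }
    win_i = wrap(wi);
    win_j = wrap(wj);
  }
  Window W = make_window(grid, dx, dy, win_i, win_j);
  if (W.n_cells == 0) stop("empty window");
  double area = W.area();

  Priors pr;
  pr.kappa = as<double>(priors["kappa"]);
  pr.kmax = as<int>(priors["k_max"]);
  pr.w_shape = as<double>(priors["w_shape"]);
  pr.w_rate = as<double>(priors["w_rate"]);
  pr.iw_df = as<double>(priors["iw_df"]);
  pr.iw_scale = as<double>(priors["iw_scale"]);
  pr.eps_shape = as<double>(priors["eps_shape"]);
  pr.eps_rate = as<double>(priors["eps_rate"]);

  int n_iter = as<int>(chain["n_iter"]);
  int burn_in = as<int>(chain["burn_in"]);
  int thin = as<int>(chain["thin"]);
  double step_center = as<double>(chain["step_center"]);
  double step_logw = as<double>(chain["step_logw"]);
  double step_sigma = as<double>(chain["step_sigma"]);
  double step_logeps = as<double>(chain["step_logeps"]);
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  size_t n = px.size();
  std::vector<double> pxv(px.begin(), px.end()), pyv(py.begin(), py.end());

  // state
  std::vector<Cluster> cl;
  double eps = as<double>(init["eps"]);
  if (eps <= 0.0) stop("initial eps must be positive");
  {
    NumericMatrix c0 = init["centers"];
    NumericVector w0 = init["weights"];
    NumericMatrix s0 = init["covs"];
    for (int j = 0; j < c0.nrow(); ++j) {
      Cluster c;
      c.cx = c0(j, 0); c.cy = c0(j, 1); c.w = w0[j];
      c.S = Cov2{s0(j, 0), s0(j, 1), s0(j, 2)};
      if (!c.S.pd()) stop("initial covariance %d not positive definite", j + 1);
      c.dens.resize(n);
      cluster_point_dens(pxv, pyv, c.cx, c.cy, c.S, c.dens);
      c.mass = window_mass(W, c.cx, c.cy, c.S);
      cl.push_back(c);
    }
  }

  std::vector<double> Ssum(n, 0.0);
  double total_wm = 0.0;
  for (auto &c : cl) {
    for (size_t i = 0; i < n; ++i) Ssum[i] += c.w * c.dens[i];
    total_wm += c.w * c.mass;
  }
  auto point_term = [&](double e) {
    double s = 0.0;
    for (size_t i = 0; i < n; ++i) s += std::log(e + Ssum[i]);
    return s;
  };
  double log_pt = constant_lik ? 0.0 : point_term(eps);

  // storage
  int n_keep = (n_iter - burn_in + thin - 1) / thin;
  IntegerVector out_k(n_keep);
  NumericVector out_eps(n_keep), out_ll(n_keep);
  List out_states(n_keep);
  int stored = 0;
  int acc_birth = 0, prop_birth = 0, acc_death = 0, prop_death = 0;
  int acc_center = 0, prop_center = 0, acc_w = 0, prop_w = 0;
  int acc_sig = 0, prop_sig = 0, acc_eps = 0, prop_eps = 0;

  std::vector<double> new_dens(n);

  for (int iter = 0; iter < n_iter; ++iter) {
    int K = cl.size();
    // --- birth/death ---
    double p_b = (K == 0) ? 1.0 : (K >= pr.kmax ? 0.0 : 0.5);
    bool do_birth = R::runif(0.0, 1.0) < p_b;
    if (do_birth) {
      ++prop_birth;
      int cell = (int)std::floor(R::runif(0.0, 1.0) * W.n_cells);
      if (cell >= W.n_cells) cell = W.n_cells - 1;
      double cx = (W.cells_i[cell] - 1 + R::runif(0.0, 1.0)) * W.dx;
      double cy = (W.cells_j[cell] - 1 + R::runif(0.0, 1.0)) * W.dy;
      double w = R::rgamma(pr.w_shape, 1.0 / pr.w_rate);
      Cov2 S = riw_draw(pr);
      double dll = 0.0, mass = 0.0, new_pt = log_pt;
      if (!constant_lik) {
        cluster_point_dens(pxv, pyv, cx, cy, S, new_dens);
        mass = window_mass(W, cx, cy, S);
        new_pt = 0.0;
        for (size_t i = 0; i < n; ++i)
          new_pt += std::log(eps + Ssum[i] + w * new_dens[i]);
        dll = (new_pt - log_pt) - w * mass;
      }
      double p_d_new = (K + 1 >= pr.kmax) ? 1.0 : 0.5;
      double log_acc = dll + std::log(pr.kappa / (K + 1)) +
                       std::log(p_d_new / p_b);
      if (std::log(R::runif(0.0, 1.0)) < log_acc) {
        ++acc_birth;
        Cluster c;
        c.cx = cx; c.cy = cy; c.w = w; c.S = S; c.mass = mass;
        if (!constant_lik) {
          c.dens = new_dens;
          for (size_t i = 0; i < n; ++i) Ssum[i] += w * new_dens[i];
          total_wm += w * mass;
          log_pt = new_pt;
        } else {
          c.dens.assign(n, 0.0);
        }
        cl.push_back(c);
      }
    } else if (K > 0) {
      ++prop_death;
      int j = (int)std::floor(R::runif(0.0, 1.0) * K);
      if (j >= K) j = K - 1;
      double dll = 0.0, new_pt = log_pt;
      if (!constant_lik) {
        new_pt = 0.0;
        for (size_t i = 0; i < n; ++i)
          new_pt += std::log(eps + Ssum[i] - cl[j].w * cl[j].dens[i]);
        dll = (new_pt - log_pt) + cl[j].w * cl[j].mass;
      }
      double p_d = 1.0 - p_b;  // death prob at current K
      double p_b_new = (K - 1 == 0) ? 1.0 : 0.5;
      double log_acc = dll + std::log(K / pr.kappa) + std::log(p_b_new / p_d);
      if (std::log(R::runif(0.0, 1.0)) < log_acc) {
        ++acc_death;
        if (!constant_lik) {
          for (size_t i = 0; i < n; ++i) Ssum[i] -= cl[j].w * cl[j].dens[i];
          total_wm -= cl[j].w * cl[j].mass;
          log_pt = new_pt;
        }
        cl.erase(cl.begin() + j);
      }
    }

    // --- per-cluster updates ---
    K = cl.size();
    for (int j = 0; j < K; ++j) {
      Cluster &c = cl[j];
      // center random walk (uniform-on-window prior)
      ++prop_center;
      {
        double cx = c.cx + R::rnorm(0.0, step_center);
        double cy = c.cy + R::rnorm(0.0, step_center);
        if (W.inside(cx, cy)) {
          double dll = 0.0, new_pt = log_pt, mass = c.mass;
          if (!constant_lik) {
            cluster_point_dens(pxv, pyv, cx, cy, c.S, new_dens);
            mass = window_mass(W, cx, cy, c.S);
            new_pt = 0.0;
            for (size_t i = 0; i < n; ++i)
              new_pt += std::log(eps + Ssum[i] +
                                 c.w * (new_dens[i] - c.dens[i]));
            dll = (new_pt - log_pt) - c.w * (mass - c.mass);
          }
          if (std::log(R::runif(0.0, 1.0)) < dll) {
            ++acc_center;
            if (!constant_lik) {
              for (size_t i = 0; i < n; ++i) {
                Ssum[i] += c.w * (new_dens[i] - c.dens[i]);
                c.dens[i] = new_dens[i];
              }
              total_wm += c.w * (mass - c.mass);
              log_pt = new_pt;
            }
            c.cx = cx; c.cy = cy; c.mass = mass;
          }
        }
      }
      // weight log random walk (Gamma prior; includes Jacobian)
      ++prop_w;
      {
        double w_new = c.w * std::exp(step_logw * R::rnorm(0.0, 1.0));
        double dlp = pr.w_shape * std::log(w_new / c.w) -
                     pr.w_rate * (w_new - c.w);
        double dll = 0.0, new_pt = log_pt;
        if (!constant_lik) {
          new_pt = 0.0;
          for (size_t i = 0; i < n; ++i)
            new_pt += std::log(eps + Ssum[i] + (w_new - c.w) * c.dens[i]);
          dll = (new_pt - log_pt) - (w_new - c.w) * c.mass;
        }
        if (std::log(R::runif(0.0, 1.0)) < dll + dlp) {
          ++acc_w;
          if (!constant_lik) {
            for (size_t i = 0; i < n; ++i)
              Ssum[i] += (w_new - c.w) * c.dens[i];
            total_wm += (w_new - c.w) * c.mass;
            log_pt = new_pt;
          }
          c.w = w_new;
        }
      }
      // covariance random walk in (log sd1, log sd2, atanh rho);
      // prior term includes the change-of-variables Jacobian
      // |d Sigma / d theta| = 4 sd1^3 sd2^3 (1 - rho^2).
      ++prop_sig;
      {
        double sd1 = std::sqrt(c.S.s11), sd2 = std::sqrt(c.S.s22);
        double rho = c.S.s12 / (sd1 * sd2);
        rho = std::max(-0.999999, std::min(0.999999, rho));
        double t1 = std::log(sd1) + step_sigma * R::rnorm(0.0, 1.0);
        double t2 = std::log(sd2) + step_sigma * R::rnorm(0.0, 1.0);
        double z = std::atanh(rho) + step_sigma * R::rnorm(0.0, 1.0);
        double nsd1 = std::exp(t1), nsd2 = std::exp(t2), nrho = std::tanh(z);
        Cov2 Snew{nsd1 * nsd1, nrho * nsd1 * nsd2, nsd2 * nsd2};
        if (Snew.pd()) {
          double dlp = log_iw_prior(Snew, pr) - log_iw_prior(c.S, pr) +
                       3.0 * (std::log(nsd1 * nsd2) - std::log(sd1 * sd2)) +
                       std::log1p(-nrho * nrho) - std::log1p(-rho * rho);
          double dll = 0.0, new_pt = log_pt, mass = c.mass;
          if (!constant_lik) {
            cluster_point_dens(pxv, pyv, c.cx, c.cy, Snew, new_dens);
            mass = window_mass(W, c.cx, c.cy, Snew);
            new_pt = 0.0;
            for (size_t i = 0; i < n; ++i)
              new_pt += std::log(eps + Ssum[i] +
                                 c.w * (new_dens[i] - c.dens[i]));
            dll = (new_pt - log_pt) - c.w * (mass - c.mass);
          }
          if (std::log(R::runif(0.0, 1.0)) < dll + dlp) {
            ++acc_sig;
            if (!constant_lik) {
              for (size_t i = 0; i < n; ++i) {
                Ssum[i] += c.w * (new_dens[i] - c.dens[i]);
                c.dens[i] = new_dens[i];
              }
              total_wm += c.w * (mass - c.mass);
              log_pt = new_pt;
            }
            c.S = Snew; c.mass = mass;
          }
        }
      }
    }

    // --- noise intensity (log random walk, Gamma prior + Jacobian) ---
    ++prop_eps;
    {
      double e_new = eps * std::exp(step_logeps * R::rnorm(0.0, 1.0));
      double dlp = pr.eps_shape * std::log(e_new / eps) -
                   pr.eps_rate * (e_new - eps);
      double dll = 0.0, new_pt = log_pt;
      if (!constant_lik) {
        new_pt = point_term(e_new);
        dll = (new_pt - log_pt) - (e_new - eps) * area;
      }
      if (std::log(R::runif(0.0, 1.0)) < dll + dlp) {
        ++acc_eps;
        eps = e_new;
        log_pt = new_pt;
      }
    }

    // --- store ---
    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      int Kc = cl.size();
      NumericMatrix centers(Kc, 2), covs(Kc, 3);
      NumericVector weights(Kc), masses(Kc);
      for (int j = 0; j < Kc; ++j) {
        centers(j, 0) = cl[j].cx; centers(j, 1) = cl[j].cy;
        covs(j, 0) = cl[j].S.s11; covs(j, 1) = cl[j].S.s12;
        covs(j, 2) = cl[j].S.s22;
        weights[j] = cl[j].w;
        masses[j] = cl[j].mass;
      }
      out_k[stored] = Kc;
      out_eps[stored] = eps;
      out_ll[stored] = constant_lik ? NA_REAL
                                    : (log_pt - eps * area - total_wm);
      out_states[stored] = List::create(_["centers"] = centers,
                                        _["weights"] = weights,
                                        _["covs"] = covs,
                                        _["masses"] = masses);
      ++stored;
    }
  }

  return List::create(
      _["k"] = out_k, _["eps"] = out_eps, _["log_lik"] = out_ll,
      _["states"] = out_states,
      _["counters"] = List::create(
          _["birth"] = IntegerVector::create(acc_birth, prop_birth),
          _["death"] = IntegerVector::create(acc_death, prop_death),
          _["center"] = IntegerVector::create(acc_center, prop_center),
          _["weight"] = IntegerVector::create(acc_w, prop_w),
          _["sigma"] = IntegerVector::create(acc_sig, prop_sig),
          _["eps"] = IntegerVector::create(acc_eps, prop_eps)));
}
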