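// Compiled kernels for the Epileptor network model:
//  - Heun integration of the 5D data-generating model (plus the auxiliary
//    convolution state u, so the state is 6 blocks of length N)
//  - RK4 integration of the 2D reduction used as the latent prior
//  - discrete adjoint of the RK4 chain, giving exact gradients of any
//    functional of the latent x-trajectory w.r.t. (x_init, z_init, x0, K, tau0)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// 2D Epileptor vector field on a connectome-coupled network.
// fx_i = 1 - x_i^3 - 2 x_i^2 - z_i + I1
// fz_i = (4 (x_i - x0_i) - z_i - K * sum_j C_ij (x_j - x_i)) / tau0
static void f2d(const vec& x, const vec& z, const vec& x0, double K,
                const mat& C, const vec& rsum, double tau0, double I1,
                vec& fx, vec& fz, vec& coup) {
  fx = 1.0 - x % x % x - 2.0 * square(x) - z + I1;
  coup = C * x - rsum % x;
  fz = (4.0 * (x - x0) - z - K * coup) / tau0;
}

// Jacobian-transpose product of the 2D field.
static void jt2d(const vec& x, const vec& vx, const vec& vz, const vec& x0,
                 double K, const mat& C, const vec& rsum, double tau0,
                 vec& gx, vec& gz) {
  gx = vx % (-3.0 * square(x) - 4.0 * x) + (vz % (4.0 + K * rsum)) / tau0
       - (K / tau0) * (C.t() * vz);
  gz = -vx - vz / tau0;
}

struct ThetaGrad {
  vec x0;
  double K;
  double tau0;
  ThetaGrad(int n) : x0(n, fill::zeros), K(0.0), tau0(0.0) {}
};

// Parameter-transpose product: accumulate (df/dtheta)^T vz.
static void pt2d(const vec& vz, const vec& coup, const vec& fz, double tau0,
                 ThetaGrad& g) {
  g.x0 += (-4.0 / tau0) * vz;
  g.K += dot(vz, -coup / tau0);
  g.tau0 += dot(vz, -fz / tau0);
}

// One classical RK4 step; stores the four stage states for reuse.
struct RK4Stages {
  vec x1, z1, x2, z2, x3, z3, x4, z4;   // stage evaluation points
  vec k1x, k1z, k2x, k2z, k3x, k3z, k4x, k4z;
};

static void rk4_step(const vec& x, const vec& z, const vec& x0, double K,
                     const mat& C, const vec& rsum, double tau0, double I1,
                     double dt, vec& xn, vec& zn, RK4Stages* st) {
  vec coup(x.n_elem);
  vec k1x, k1z, k2x, k2z, k3x, k3z, k4x, k4z;
  f2d(x, z, x0, K, C, rsum, tau0, I1, k1x, k1z, coup);
  vec x2 = x + 0.5 * dt * k1x, z2 = z + 0.5 * dt * k1z;
  f2d(x2, z2, x0, K, C, rsum, tau0, I1, k2x, k2z, coup);
  vec x3 = x + 0.5 * dt * k2x, z3 = z + 0.5 * dt * k2z;
  f2d(x3, z3, x0, K, C, rsum, tau0, I1, k3x, k3z, coup);
  vec x4 = x + dt * k3x, z4 = z + dt * k3z;
  f2d(x4, z4, x0, K, C, rsum, tau0, I1, k4x, k4z, coup);
  xn = x + (dt / 6.0) * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
  zn = z + (dt / 6.0) * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
  if (st) {
    st->x1 = x;  st->z1 = z;  st->x2 = x2; st->z2 = z2;
    st->x3 = x3; st->z3 = z3; st->x4 = x4; st->z4 = z4;
    st->k1x = k1x; st->k1z = k1z; st->k2x = k2x; st->k2z = k2z;
    st->k3x = k3x; st->k3z = k3z; st->k4x = k4x; st->k4z = k4z;
  }
}

// Integrate the latent 2D system over T observation intervals (nsub RK4
// substeps of size dt per interval). Returns x,z at t_1..t_T (the initial
// state t_0 is a model parameter, not part of the latent matrix).
// [[Rcpp::export(name = ".latent_rk4_cpp")]]
Rcpp::List latent_rk4_cpp(const arma::mat& C, const arma::vec& x0, double K,
                          double tau0, double I1, const arma::vec& x_init,
                          const arma::vec& z_init, double dt, int nsub,
                          int T, double bound) {
  const int N = x0.n_elem;
  vec rsum = sum(C, 1);
  mat X(N, T), Z(N, T);
  vec x = x_init, z = z_init, xn, zn;
  for (int j = 0; j < T; ++j) {
    for (int s = 0; s < nsub; ++s) {
      rk4_step(x, z, x0, K, C, rsum, tau0, I1, dt, xn, zn, nullptr);
      x = xn; z = zn;
    }
    if (!x.is_finite() || !z.is_finite() ||
        std::max(abs(x).max(), abs(z).max()) > bound) {
      return Rcpp::List::create(Rcpp::Named("diverged") = true,
                                Rcpp::Named("step") = j + 1,
                                Rcpp::Named("X") = X, Rcpp::Named("Z") = Z);
    }
    X.col(j) = x; Z.col(j) = z;
  }
  return Rcpp::List::create(Rcpp::Named("diverged") = false,
                            Rcpp::Named("step") = T,
                            Rcpp::Named("X") = X, Rcpp::Named("Z") = Z);
}

// Discrete adjoint of the RK4 chain above. dLdX (N x T) holds the gradient of
// the objective w.r.t. the latent x at every observation instant (the
// likelihood does not touch z). Returns gradients w.r.t. x_init, z_init,
// x0, K, tau0. Substep states are recomputed from the stored y_{j-1}.
// [[Rcpp::export(name = ".latent_adjoint_cpp")]]
Rcpp::List latent_adjoint_cpp(const arma::mat& C, const arma::vec& x0,
                              double K, double tau0, double I1,
                              const arma::vec& x_init, const arma::vec& z_init,
                              double dt, int nsub, const arma::mat& X,
                              const arma::mat& Z, const arma::mat& dLdX) {
  const int N = x0.n_elem;
  const int T = X.n_cols;
  vec rsum = sum(C, 1);
  ThetaGrad g(N);
  vec lx(N, fill::zeros), lz(N, fill::zeros);
  std::vector<RK4Stages> stages(nsub);
  vec coup(N), fz(N), gx(N), gz(N);

  for (int j = T - 1; j >= 0; --j) {
    lx += dLdX.col(j);
    // recompute the substep chain from y_{j-1}
    vec x = (j == 0) ? x_init : vec(X.col(j - 1));
    vec z = (j == 0) ? z_init : vec(Z.col(j - 1));
    std::vector<vec> xs(nsub + 1), zs(nsub + 1);
    xs[0] = x; zs[0] = z;
    for (int s = 0; s < nsub; ++s) {
      vec xn, zn;
      rk4_step(xs[s], zs[s], x0, K, C, rsum, tau0, I1, dt, xn, zn, &stages[s]);
      xs[s + 1] = xn; zs[s + 1] = zn;
    }
    // backward through the substeps
    for (int s = nsub - 1; s >= 0; --s) {
      const RK4Stages& st = stages[s];
      vec by_x = lx, by_z = lz;
      vec bk1x = (dt / 6.0) * lx, bk1z = (dt / 6.0) * lz;
      vec bk2x = (dt / 3.0) * lx, bk2z = (dt / 3.0) * lz;
      vec bk3x = (dt / 3.0) * lx, bk3z = (dt / 3.0) * lz;
      vec bk4x = (dt / 6.0) * lx, bk4z = (dt / 6.0) * lz;
      // k4 = f(y4), y4 = y + dt*k3
      jt2d(st.x4, bk4x, bk4z, x0, K, C, rsum, tau0, gx, gz);
      coup = C * st.x4 - rsum % st.x4;
      fz = (4.0 * (st.x4 - x0) - st.z4 - K * coup) / tau0;
      pt2d(bk4z, coup, fz, tau0, g);
      by_x += gx; by_z += gz;
      bk3x += dt * gx; bk3z += dt * gz;
      // k3 = f(y3), y3 = y + dt/2*k2
      jt2d(st.x3, bk3x, bk3z, x0, K, C, rsum, tau0, gx, gz);
      coup = C * st.x3 - rsum % st.x3;
      fz = (4.0 * (st.x3 - x0) - st.z3 - K * coup) / tau0;
      pt2d(bk3z, coup, fz, tau0, g);
      by_x += gx; by_z += gz;
      bk2x += 0.5 * dt * gx; bk2z += 0.5 * dt * gz;
      // k2 = f(y2), y2 = y + dt/2*k1
      jt2d(st.x2, bk2x, bk2z, x0, K, C, rsum, tau0, gx, gz);
      coup = C * st.x2 - rsum % st.x2;
      fz = (4.0 * (st.x2 - x0) - st.z2 - K * coup) / tau0;
      pt2d(bk2z, coup, fz, tau0, g);
      by_x += gx; by_z += gz;
      bk1x += 0.5 * dt * gx; bk1z += 0.5 * dt * gz;
      // k1 = f(y)
      jt2d(st.x1, bk1x, bk1z, x0, K, C, rsum, tau0, gx, gz);
      coup = C * st.x1 - rsum % st.x1;
      fz = (4.0 * (st.x1 - x0) - st.z1 - K * coup) / tau0;
      pt2d(bk1z, coup, fz, tau0, g);
      by_x += gx; by_z += gz;
      lx = by_x; lz = by_z;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("x_init") = lx, Rcpp::Named("z_init") = lz,
      Rcpp::Named("x0") = g.x0, Rcpp::Named("K") = g.K,
      Rcpp::Named("tau0") = g.tau0);
}

// 5D Epileptor vector field with auxiliary convolution state u
// (g(x1) of the model is realized as 0.002*u with du/dt = x1 - gamma*u).
static void f5d(const vec& x1, const vec& y1, const vec& z, const vec& x2,
                const vec& y2, const vec& u, const vec& x0, double K,
                const mat& C, const vec& rsum, double tau0, double tau2,
                double I1, double I2, double gamma,
                vec& dx1, vec& dy1, vec& dz, vec& dx2, vec& dy2, vec& du) {
  const int N = x1.n_elem;
  vec f1(N);
  for (int i = 0; i < N; ++i) {
    if (x1(i) < 0.0)
      f1(i) = x1(i) * x1(i) * x1(i) - 3.0 * x1(i) * x1(i);
    else
      f1(i) = (x2(i) - 0.6 * std::pow(z(i) - 4.0, 2)) * x1(i);
  }
  dx1 = y1 - f1 - z + I1;
  dy1 = 1.0 - 5.0 * square(x1) - y1;
  dz = (4.0 * (x1 - x0) - z - K * (C * x1 - rsum % x1)) / tau0;
  vec f2v(N);
  for (int i = 0; i < N; ++i)
    f2v(i) = (x2(i) < -0.25) ? 0.0 : 6.0 * (x2(i) + 0.25);
  dx2 = -y2 + x2 - x2 % x2 % x2 + I2 + 0.002 * u - 0.3 * (z - 3.5);
  dy2 = (-y2 + f2v) / tau2;
  du = x1 - gamma * u;
}

// Heun (explicit trapezoidal) integration of the 5D network. The state is
// recorded every `record_every` steps, including the initial state.
// `noise_sd` > 0 adds independent Gaussian increments of SD noise_sd*sqrt(dt)
// to the intermediate subsystem (x2, y2) after each step (additive dynamic
// noise as in stochastic Heun network simulations); draws come from R's RNG
// so seeding via set.seed() is reproducible.
// On divergence an R error is raised carrying the failing step index.
// [[Rcpp::export(name = ".heun_5d_cpp")]]
Rcpp::List heun_5d_cpp(const arma::mat& C, const arma::vec& x0, double K,
                       double tau0, double tau2, double I1, double I2,
                       double gamma, const arma::mat& init, double dt,
                       int nsteps, int record_every, double bound,
                       double noise_sd = 0.0) {
  const int N = x0.n_elem;
  vec rsum = sum(C, 1);
  vec x1 = init.col(0), y1 = init.col(1), z = init.col(2),
      x2 = init.col(3), y2 = init.col(4), u = init.col(5);
  const int nrec = nsteps / record_every + 1;
  mat X1(N, nrec), Y1(N, nrec), Zm(N, nrec), X2(N, nrec), Y2(N, nrec),
      U(N, nrec);
  vec times(nrec);
  int rec = 0;
  X1.col(0) = x1; Y1.col(0) = y1; Zm.col(0) = z;
  X2.col(0) = x2; Y2.col(0) = y2; U.col(0) = u;
  times(0) = 0.0; rec = 1;
  vec k1[6], k2[6];
  vec px1, py1, pz, px2, py2, pu;
  for (int s = 1; s <= nsteps; ++s) {
    f5d(x1, y1, z, x2, y2, u, x0, K, C, rsum, tau0, tau2, I1, I2, gamma,
        k1[0], k1[1], k1[2], k1[3], k1[4], k1[5]);
    px1 = x1 + dt * k1[0]; py1 = y1 + dt * k1[1]; pz = z + dt * k1[2];
    px2 = x2 + dt * k1[3]; py2 = y2 + dt * k1[4]; pu = u + dt * k1[5];
    f5d(px1, py1, pz, px2, py2, pu, x0, K, C, rsum, tau0, tau2, I1, I2, gamma,
        k2[0], k2[1], k2[2], k2[3], k2[4], k2[5]);
    x1 += 0.5 * dt * (k1[0] + k2[0]);
    y1 += 0.5 * dt * (k1[1] + k2[1]);
    z  += 0.5 * dt * (k1[2] + k2[2]);
    x2 += 0.5 * dt * (k1[3] + k2[3]);
    y2 += 0.5 * dt * (k1[4] + k2[4]);
    u  += 0.5 * dt * (k1[5] + k2[5]);
    if (noise_sd > 0.0) {
      const double s = noise_sd * std::sqrt(dt);
      for (int i = 0; i < N; ++i) {
        x2(i) += s * R::norm_rand();
        y2(i) += s * R::norm_rand();
      }
    }
    double m = std::max({abs(x1).max(), abs(y1).max(), abs(z).max(),
                         abs(x2).max(), abs(y2).max(), abs(u).max()});
    if (!std::isfinite(m) || m > bound)
      Rcpp::stop("integration diverged at step %d", s);
    if (s % record_every == 0) {
      X1.col(rec) = x1; Y1.col(rec) = y1; Zm.col(rec) = z;
      X2.col(rec) = x2; Y2.col(rec) = y2; U.col(rec) = u;
      times(rec) = s * dt;
      ++rec;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("times") = times, Rcpp::Named("x1") = X1,
      Rcpp::Named("y1") = Y1, Rcpp::Named("z") = Zm,
      Rcpp::Named("x2") = X2, Rcpp::Named("y2") = Y2, Rcpp::Named("u") = U);
}
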