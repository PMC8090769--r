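// Streamline propagation core: bidirectional marching through a diffusion
// tensor field with principal-direction (DTI) or tensor-deflection (TEND)
// steps and optional Gaussian perturbation of the direction.
//
// Geometry conventions match the R side: world mm coordinates, 0-based
// voxel indices, world = affine * (index, 1). Tensor component order is
// (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz). Random draws use R's global RNG so that
// set.seed() on the R side makes tracking fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Termination codes, mirrored by term_reason() in R/tracking.R.
enum Term {
  TERM_RUNNING = 0,
  TERM_MASK = 1,       // left the tracking mask (or the interpolable grid)
  TERM_MAXSTEPS = 2,   // per-half step budget exhausted
  TERM_ANGLE = 3,      // turning angle above threshold
  TERM_LOWFA = 4,      // fractional anisotropy below floor
  TERM_UNDEF = 5,      // propagation direction undefined
  TERM_SEED = 6        // seed voxel itself invalid
};

struct TensorGrid {
  const double* D;     // (nx, ny, nz, 6) column-major
  const int* mask;     // (nx, ny, nz)
  int nx, ny, nz;
  arma::mat33 R;       // world -> voxel linear part
  arma::vec3 t;        // world -> voxel offset
  bool nearest;        // nearest-voxel instead of trilinear interpolation

  arma::vec3 to_voxel(const arma::vec3& p) const { return R * p + t; }

  bool in_mask_world(const arma::vec3& p) const {
    arma::vec3 v = to_voxel(p);
    int i = (int)std::lround(v[0]);
    int j = (int)std::lround(v[1]);
    int k = (int)std::lround(v[2]);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      return false;
    return mask[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] != 0;
  }

  // Sample the tensor at a world point; returns false when the point is
  // outside the grid's interpolable region.
  bool sample(const arma::vec3& p, arma::mat33& out) const {
    arma::vec3 v = to_voxel(p);
    double comp[6];
    size_t nvox = (size_t)nx * ny * nz;
    if (nearest) {
      int i = (int)std::lround(v[0]);
      int j = (int)std::lround(v[1]);
      int k = (int)std::lround(v[2]);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
        return false;
      size_t base = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
      for (int c = 0; c < 6; ++c) comp[c] = D[base + c * nvox];
    } else {
      const double tol = 1e-6;  // snap boundary rounding noise
      int dims[3] = {nx, ny, nz};
      for (int a = 0; a < 3; ++a) {
        if (v[a] < 0 && v[a] > -tol) v[a] = 0;
        if (v[a] > dims[a] - 1 && v[a] < dims[a] - 1 + tol)
          v[a] = dims[a] - 1;
      }
      if (v[0] < 0 || v[1] < 0 || v[2] < 0 ||
          v[0] > nx - 1 || v[1] > ny - 1 || v[2] > nz - 1)
        return false;
      int x0 = std::min((int)std::floor(v[0]), nx > 1 ? nx - 2 : 0);
      int y0 = std::min((int)std::floor(v[1]), ny > 1 ? ny - 2 : 0);
      int z0 = std::min((int)std::floor(v[2]), nz > 1 ? nz - 2 : 0);
      double fx = v[0] - x0, fy = v[1] - y0, fz = v[2] - z0;
      for (int c = 0; c < 6; ++c) comp[c] = 0.0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                       (dz ? fz : 1 - fz);
            if (w == 0.0) continue;
            int xi = std::min(x0 + dx, nx - 1);
            int yi = std::min(y0 + dy, ny - 1);
            int zi = std::min(z0 + dz, nz - 1);
            size_t base = (size_t)xi +
                          (size_t)nx * ((size_t)yi + (size_t)ny * zi);
            for (int c = 0; c < 6; ++c) comp[c] += w * D[base + c * nvox];
          }
    }
    out(0, 0) = comp[0]; out(0, 1) = comp[1]; out(0, 2) = comp[2];
    out(1, 0) = comp[1]; out(1, 1) = comp[3]; out(1, 2) = comp[4];
    out(2, 0) = comp[2]; out(2, 1) = comp[4]; out(2, 2) = comp[5];
    return true;
  }
};

static double fa_of(const arma::mat33& D) {
  arma::vec3 lam;
  if (!arma::eig_sym(lam, D)) return 0.0;
  double ss = arma::dot(lam, lam);
  if (ss <= 0.0) return 0.0;
  double m = arma::mean(lam);
  double num = 0.0;
  for (int i = 0; i < 3; ++i) num += (lam[i] - m) * (lam[i] - m);
  return std::sqrt(1.5 * num / ss);
}

// Leading eigenvector with the degenerate-eigenspace tie-break:
// lambda1 - lambda2 < 1e-9 * trace flags degeneracy.
static bool leading_eigvec(const arma::mat33& D, arma::vec3& out,
                           bool& degenerate) {
  arma::vec3 lam;
  arma::mat33 V;
  if (!arma::eig_sym(lam, V, D)) return false;  // ascending order
  double tr = arma::trace(D);
  degenerate = (tr <= 0.0) || (lam[2] - lam[1] < 1e-9 * tr);
  out = V.col(2);
  return true;
}

// Model step: proposed direction given local tensor and incoming unit
// direction. model 0 = DTI principal direction, 1 = TEND deflection.
static bool model_dir(int model, const arma::mat33& D, const arma::vec3& vin,
                      arma::vec3& out) {
  if (model == 1) {
    arma::vec3 w = D * vin;
    double nw = arma::norm(w);
    double scale = arma::norm(D, "fro");
    if (!std::isfinite(nw) || nw <= scale * 1e-14 || nw == 0.0)
      return false;
    out = w / nw;
    if (arma::dot(out, vin) < 0) out = -out;
    return true;
  }
  bool degenerate = false;
  arma::vec3 e;
  if (!leading_eigvec(D, e, degenerate)) return false;
  if (degenerate) { out = vin; return true; }  // keep incoming direction
  if (arma::dot(e, vin) < 0) e = -e;
  out = e;
  return true;
}

static arma::vec3 perturb(const arma::vec3& v, double s) {
  if (s <= 0.0) return v;
  for (;;) {
    arma::vec3 w = v;
    w[0] += s * norm_rand();
    w[1] += s * norm_rand();
    w[2] += s * norm_rand();
    double n = arma::norm(w);
    if (n > 0.0) return w / n;
  }
}

// March one half-streamline from x0 along v0; appends accepted points
// (excluding x0) to pts and returns the termination code.
static int track_half(const TensorGrid& g, const arma::vec3& x0,
                      const arma::vec3& v0, int model, double alpha,
                      double s, int max_steps, double cos_thresh,
                      double fa_floor, std::vector<double>& pts) {
  arma::vec3 x = x0, vprev = v0;
  arma::mat33 D;
  for (int n = 0; n < max_steps; ++n) {
    if (!g.sample(x, D)) return TERM_MASK;
    arma::vec3 d;
    if (!model_dir(model, D, vprev, d)) return TERM_UNDEF;
    d = perturb(d, s);
    if (arma::dot(d, vprev) < cos_thresh) return TERM_ANGLE;
    arma::vec3 xn = x + alpha * d;
    if (!g.in_mask_world(xn)) return TERM_MASK;
    arma::mat33 Dn;
    if (!g.sample(xn, Dn)) return TERM_MASK;
    if (fa_of(Dn) < fa_floor) return TERM_LOWFA;
    pts.push_back(xn[0]); pts.push_back(xn[1]); pts.push_back(xn[2]);
    x = xn;
    vprev = d;
  }
  return TERM_MAXSTEPS;
}

// [[Rcpp::export]]
List cpp_propagate(NumericVector seed, NumericVector tensors,
                   IntegerVector mask, IntegerVector grid_dim,
                   NumericMatrix world_to_voxel_mat, int model,
                   double alpha, double s, int max_steps,
                   double cos_thresh, double fa_floor, bool nearest) {
  TensorGrid g;
  g.D = REAL(tensors);
  g.mask = INTEGER(mask);
  g.nx = grid_dim[0]; g.ny = grid_dim[1]; g.nz = grid_dim[2];
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) g.R(i, j) = world_to_voxel_mat(i, j);
    g.t[i] = world_to_voxel_mat(i, 3);
  }
  g.nearest = nearest;

  RNGScope rng;
  arma::vec3 x0 = {seed[0], seed[1], seed[2]};

  auto single_point = [&](int code) {
    NumericMatrix P(1, 3);
    P(0, 0) = x0[0]; P(0, 1) = x0[1]; P(0, 2) = x0[2];
    return List::create(_["points"] = P, _["seed_index"] = 1,
                        _["term_backward"] = code, _["term_forward"] = code);
  };

  arma::mat33 D0;
  if (!g.in_mask_world(x0) || !g.sample(x0, D0))
    return single_point(TERM_SEED);
  if (fa_of(D0) < fa_floor)
    return single_point(TERM_LOWFA);

  bool degenerate = false;
  arma::vec3 v0;
  if (!leading_eigvec(D0, v0, degenerate) || degenerate)
    return single_point(TERM_UNDEF);
  // deterministic sign: largest-magnitude component positive
  int imax = 0;
  for (int i = 1; i < 3; ++i)
    if (std::fabs(v0[i]) > std::fabs(v0[imax])) imax = i;
  if (v0[imax] < 0) v0 = -v0;

  std::vector<double> fwd, bwd;
  int term_f = track_half(g, x0, v0, model, alpha, s, max_steps,
                          cos_thresh, fa_floor, fwd);
  int term_b = track_half(g, x0, -v0, model, alpha, s, max_steps,
                          cos_thresh, fa_floor, bwd);

  size_t nb = bwd.size() / 3, nf = fwd.size() / 3;
  NumericMatrix P(nb + nf + 1, 3);
  for (size_t i = 0; i < nb; ++i) {        // backward half, reversed
    size_t src = nb - 1 - i;
    P(i, 0) = bwd[3 * src]; P(i, 1) = bwd[3 * src + 1];
    P(i, 2) = bwd[3 * src + 2];
  }
  P(nb, 0) = x0[0]; P(nb, 1) = x0[1]; P(nb, 2) = x0[2];
  for (size_t i = 0; i < nf; ++i) {
    P(nb + 1 + i, 0) = fwd[3 * i]; P(nb + 1 + i, 1) = fwd[3 * i + 1];
    P(nb + 1 + i, 2) = fwd[3 * i + 2];
  }
  return List::create(_["points"] = P, _["seed_index"] = (int)(nb + 1),
                      _["term_backward"] = term_b,
                      _["term_forward"] = term_f);
}
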