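// Deterministic streamline tractography on the principal-eigenvector
// field of a diffusion tensor volume. Fourth-order Runge-Kutta
// integration, trilinear component-wise tensor interpolation, FA cutoff,
// turning-angle bound and length window. Coordinates: stepping happens in
// world mm; tensors are sampled in continuous 0-based voxel coordinates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct TensorField {
  const double *D;   // nx*ny*nz*6
  int nx, ny, nz;
  arma::mat33 vox2world_R, world2vox_R;
  arma::vec3 vox2world_t, world2vox_t;

  arma::vec3 to_vox(const arma::vec3 &p) const {
    return world2vox_R * p + world2vox_t;
  }

  long idx(int i, int j, int k, int c) const {
    return i + (long)nx * (j + (long)ny * (k + (long)nz * c));
  }

  // Trilinear interpolation of the 6 unique components at continuous
  // voxel coordinates v. Returns false when v is outside the volume.
  bool interp(const arma::vec3 &v, double out[6]) const {
    if (v[0] < 0 || v[1] < 0 || v[2] < 0 ||
        v[0] > nx - 1 || v[1] > ny - 1 || v[2] > nz - 1) return false;
    int i0 = (int)std::floor(v[0]), j0 = (int)std::floor(v[1]),
        k0 = (int)std::floor(v[2]);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = v[0] - i0, fy = v[1] - j0, fz = v[2] - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double w000 = (1 - fx) * (1 - fy) * (1 - fz);
    double w100 = fx * (1 - fy) * (1 - fz);
    double w010 = (1 - fx) * fy * (1 - fz);
    double w110 = fx * fy * (1 - fz);
    double w001 = (1 - fx) * (1 - fy) * fz;
    double w101 = fx * (1 - fy) * fz;
    double w011 = (1 - fx) * fy * fz;
    double w111 = fx * fy * fz;
    for (int c = 0; c < 6; ++c) {
      out[c] = w000 * D[idx(i0, j0, k0, c)] + w100 * D[idx(i1, j0, k0, c)] +
               w010 * D[idx(i0, j1, k0, c)] + w110 * D[idx(i1, j1, k0, c)] +
               w001 * D[idx(i0, j0, k1, c)] + w101 * D[idx(i1, j0, k1, c)] +
               w011 * D[idx(i0, j1, k1, c)] + w111 * D[idx(i1, j1, k1, c)];
      if (!std::isfinite(out[c])) return false;
    }
    return true;
  }
};

arma::mat33 sym33(const double t[6]) {
  arma::mat33 m;
  m(0, 0) = t[0]; m(0, 1) = t[1]; m(0, 2) = t[2];
  m(1, 0) = t[1]; m(1, 1) = t[3]; m(1, 2) = t[4];
  m(2, 0) = t[2]; m(2, 1) = t[4]; m(2, 2) = t[5];
  return m;
}

// eigenvalues ascending from eig_sym; principal = last column
bool principal_dir(const double t[6], arma::vec3 &dir, double *fa_out) {
  arma::vec eigval;
  arma::mat eigvec;
  if (!arma::eig_sym(eigval, eigvec, sym33(t))) return false;
  arma::vec3 ev = {std::max(eigval[0], 0.0), std::max(eigval[1], 0.0),
                   std::max(eigval[2], 0.0)};
  double md = (ev[0] + ev[1] + ev[2]) / 3.0;
  double den = arma::dot(ev, ev);
  double fa = 0.0;
  if (den > 0) {
    double num = 0.0;
    for (int i = 0; i < 3; ++i) num += (ev[i] - md) * (ev[i] - md);
    fa = std::sqrt(1.5 * num / den);
    if (fa > 1.0) fa = 1.0;
  }
  if (fa_out) *fa_out = fa;
  dir = eigvec.col(2);
  double n = arma::norm(dir);
  if (n <= 0) return false;
  dir /= n;
  return true;
}

// Sample the field at world point p: principal direction sign-aligned with
// `ref`, and FA of the interpolated tensor. Returns false outside volume
// or on a degenerate tensor.
bool sample(const TensorField &f, const arma::vec3 &p, const arma::vec3 &ref,
            arma::vec3 &dir, double &fa) {
  double t[6];
  if (!f.interp(f.to_vox(p), t)) return false;
  if (!principal_dir(t, dir, &fa)) return false;
  if (arma::dot(dir, ref) < 0) dir = -dir;
  return true;
}

enum Term { TERM_NONE = 0, TERM_FA = 1, TERM_VOLUME = 2, TERM_ANGLE = 3,
            TERM_MAXSTEPS = 4 };

// One branch of bidirectional propagation; appends points after the seed.
Term propagate(const TensorField &f, const arma::vec3 &seed,
               const arma::vec3 &init_dir, double step, double cos_max,
               double fa_cutoff, int max_steps,
               std::vector<arma::vec3> &pts) {
  arma::vec3 p = seed;
  arma::vec3 d_prev = init_dir;
  bool first = true;
  for (int s = 0; s < max_steps; ++s) {
    arma::vec3 k1, k2, k3, k4;
    double fa;
    if (!sample(f, p, d_prev, k1, fa)) return TERM_VOLUME;
    if (!sample(f, p + (step / 2) * k1, d_prev, k2, fa)) return TERM_VOLUME;
    if (!sample(f, p + (step / 2) * k2, d_prev, k3, fa)) return TERM_VOLUME;
    if (!sample(f, p + step * k3, d_prev, k4, fa)) return TERM_VOLUME;
    arma::vec3 v = (k1 + 2 * k2 + 2 * k3 + k4) / 6.0;
    double n = arma::norm(v);
    if (n <= 0) return TERM_FA;
    v /= n;
    arma::vec3 cand = p + step * v;
    arma::vec3 dir_at;
    double fa_cand;
    if (!sample(f, cand, v, dir_at, fa_cand)) return TERM_VOLUME;
    if (fa_cand < fa_cutoff) return TERM_FA;
    if (!first && arma::dot(v, d_prev) < cos_max) return TERM_ANGLE;
    pts.push_back(cand);
    p = cand;
    d_prev = v;
    first = false;
  }
  return TERM_MAXSTEPS;
}

}  // namespace

// Principal direction of the interpolated tensor at a world point,
// sign-aligned with `incoming`. Returns list(ok, direction, fa).
// [[Rcpp::export]]
List cpp_direction_field(NumericVector D, IntegerVector dims,
                         NumericMatrix affine, NumericVector point,
                         NumericVector incoming) {
  TensorField f;
  f.D = REAL(D);
  f.nx = dims[0]; f.ny = dims[1]; f.nz = dims[2];
  arma::mat A(affine.begin(), 4, 4);
  arma::mat Ainv = arma::inv(A);
  f.world2vox_R = Ainv.submat(0, 0, 2, 2);
  f.world2vox_t = Ainv.submat(0, 3, 2, 3);
  arma::vec3 p = {point[0], point[1], point[2]};
  arma::vec3 ref = {incoming[0], incoming[1], incoming[2]};
  arma::vec3 dir;
  double fa;
  if (!sample(f, p, ref, dir, fa)) {
    return List::create(_["ok"] = false);
  }
  return List::create(_["ok"] = true,
                      _["direction"] = NumericVector::create(dir[0], dir[1], dir[2]),
                      _["fa"] = fa);
}

// Track from each seed (rows of `seeds`, world mm). Returns accepted
// streamlines plus per-seed status codes:
// 0 accepted, 1 seed below FA cutoff / outside, 2 too short, 3 too long,
// 4 degenerate (no step in either direction).
// [[Rcpp::export]]
List cpp_track_seeds(NumericVector D, IntegerVector dims,
                     NumericMatrix affine, NumericMatrix seeds,
                     double step_size, double max_angle_deg,
                     double min_length, double max_length,
                     double fa_cutoff, bool truncate_long) {
  TensorField f;
  f.D = REAL(D);
  f.nx = dims[0]; f.ny = dims[1]; f.nz = dims[2];
  arma::mat A(affine.begin(), 4, 4);
  arma::mat Ainv = arma::inv(A);
  f.world2vox_R = Ainv.submat(0, 0, 2, 2);
  f.world2vox_t = Ainv.submat(0, 3, 2, 3);

  double cos_max = std::cos(max_angle_deg * M_PI / 180.0);
  int max_steps = (int)std::ceil(max_length / step_size) + 2;
  int nseeds = seeds.nrow();

  std::vector<NumericMatrix> tracks;
  std::vector<int> seed_of, term_a, term_b;
  std::vector<double> lengths;
  IntegerVector status(nseeds);

  for (int s = 0; s < nseeds; ++s) {
    arma::vec3 seed = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    arma::vec3 dir0;
    double fa0;
    arma::vec3 ref = {1, 0, 0};
    if (!sample(f, seed, ref, dir0, fa0) || fa0 < fa_cutoff) {
      status[s] = 1;
      continue;
    }
    std::vector<arma::vec3> fwd, bwd;
    Term tf = propagate(f, seed, dir0, step_size, cos_max, fa_cutoff,
                        max_steps, fwd);
    Term tb = propagate(f, seed, -dir0, step_size, cos_max, fa_cutoff,
                        max_steps, bwd);
    if (fwd.empty() && bwd.empty()) {
      status[s] = 4;
      continue;
    }
    size_t npts = bwd.size() + 1 + fwd.size();
    double len = step_size * (npts - 1);
    if (len < min_length) {
      status[s] = 2;
      continue;
    }
    if (len > max_length) {
      if (!truncate_long) {
        status[s] = 3;
        continue;
      }
      // drop points evenly from both ends until within the window
      while (len > max_length && (bwd.size() + fwd.size()) > 0) {
        if (bwd.size() >= fwd.size() && !bwd.empty()) bwd.pop_back();
        else fwd.pop_back();
        npts--;
        len = step_size * (npts - 1);
      }
    }
    NumericMatrix m(npts, 3);
    size_t r = 0;
    for (size_t i = bwd.size(); i-- > 0; ++r)
      for (int c = 0; c < 3; ++c) m(r, c) = bwd[i][c];
    for (int c = 0; c < 3; ++c) m(r, c) = seed[c];
    ++r;
    for (size_t i = 0; i < fwd.size(); ++i, ++r)
      for (int c = 0; c < 3; ++c) m(r, c) = fwd[i][c];
    tracks.push_back(m);
    seed_of.push_back(s + 1);
    lengths.push_back(len);
    term_a.push_back((int)tb);
    term_b.push_back((int)tf);
    status[s] = 0;
  }

  List out_tracks(tracks.size());
  for (size_t i = 0; i < tracks.size(); ++i) out_tracks[i] = tracks[i];
  return List::create(_["streamlines"] = out_tracks,
                      _["seed_index"] = wrap(seed_of),
                      _["length_mm"] = wrap(lengths),
                      _["term_backward"] = wrap(term_a),
                      _["term_forward"] = wrap(term_b),
                      _["status"] = status);
}
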