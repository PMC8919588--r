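// Metropolis-within-Gibbs sampler for twilight-based track refinement
// ("Estelle"-style model): per-twilight locations with a one-sided
// log-normal twilight-error density, a gamma prior on great-circle flight
// speed between consecutive twilights, a Gaussian SST match against a
// gridded weekly field, and a land mask (hard zero, or a soft penalty
// during the relaxed burn-in stage). Called from refine_track_mcmc().
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double EARTH_R = 6371.0;
const double D2R = M_PI / 180.0;

struct Model {
  int K;
  // twilight terms: r = A + q*4*lon + 4*H(lat)
  std::vector<double> A, q, sindec, cosdec;
  double cosz;
  double meanlog, sdlog;
  // movement
  std::vector<double> dt_h; // K-1, hours between consecutive twilights
  double shape, rate;
  // SST
  std::vector<double> sst_obs; // NaN = none
  std::vector<int> wk;         // 0-based week layer
  const double *temp;
  double lon0, dlon, lat0, dlat;
  int nlon, nlat;
  double sst_sd;
  // mask
  std::vector<double> px, py;
  std::vector<int> ring_start, ring_len;
  bool mask_hard;
  double mask_penalty;

  bool on_land(double lon, double lat) const {
    bool inside = false;
    for (size_t r = 0; r < ring_start.size(); ++r) {
      int s = ring_start[r], L = ring_len[r];
      bool hit = false;
      for (int k = 0, j = L - 1; k < L; j = k++) {
        double xi = px[s + k], yi = py[s + k], xj = px[s + j], yj = py[s + j];
        if (((yi > lat) != (yj > lat)) &&
            (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)) hit = !hit;
      }
      if (hit) { inside = true; break; }
    }
    return inside;
  }

  double sst_field_at(double lon, double lat, int w) const {
    double fx = (lon - lon0) / dlon, fy = (lat - lat0) / dlat;
    if (fx < 0) fx = 0; if (fx > nlon - 1.000001) fx = nlon - 1.000001;
    if (fy < 0) fy = 0; if (fy > nlat - 1.000001) fy = nlat - 1.000001;
    int i = (int)fx, j = (int)fy;
    double tx = fx - i, ty = fy - j;
    const double *lay = temp + (size_t)w * nlon * nlat;
    double v00 = lay[i + j * nlon], v10 = lay[i + 1 + j * nlon];
    double v01 = lay[i + (j + 1) * nlon], v11 = lay[i + 1 + (j + 1) * nlon];
    return (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
           (1 - tx) * ty * v01 + tx * ty * v11;
  }

  // location-specific terms (twilight + SST + mask)
  double loc_ll(int k, double lon, double lat) const {
    if (lat <= -89 || lat >= 89) return R_NegInf;
    double ll = 0;
    // mask
    if (on_land(lon, lat)) {
      if (mask_hard) return R_NegInf;
      ll -= mask_penalty;
    }
    // twilight
    double phi = lat * D2R;
    double cosha = (cosz - std::sin(phi) * sindec[k]) / (std::cos(phi) * cosdec[k]);
    if (cosha < -1.0 || cosha > 1.0) return R_NegInf;
    double H = std::acos(cosha) / D2R; // degrees
    double r = A[k] + q[k] * 4.0 * lon + 4.0 * H; // minutes of shading delay
    if (r <= 0) return R_NegInf;
    double z = (std::log(r) - meanlog) / sdlog;
    ll += -std::log(r) - std::log(sdlog) - 0.5 * z * z - 0.918938533204672742;
    // SST
    if (R_finite(sst_obs[k])) {
      double d = sst_obs[k] - sst_field_at(lon, lat, wk[k]);
      ll += -0.5 * d * d / (sst_sd * sst_sd) - std::log(sst_sd) - 0.918938533204672742;
    }
    return ll;
  }

  // movement term between location k and k+1
  double pair_ll(int k, double lon1, double lat1, double lon2, double lat2) const {
    double p1 = lat1 * D2R, p2 = lat2 * D2R;
    double sdp = std::sin((p2 - p1) / 2), sdl = std::sin((lon2 - lon1) * D2R / 2);
    double aa = sdp * sdp + std::cos(p1) * std::cos(p2) * sdl * sdl;
    if (aa > 1) aa = 1;
    double dist = 2 * EARTH_R * std::asin(std::sqrt(aa));
    double s = dist / dt_h[k];
    if (s <= 0) s = 1e-8; // coincident positions: vanishing but finite speed
    return shape * std::log(rate) - std::lgamma(shape) +
           (shape - 1) * std::log(s) - rate * s;
  }
};

} // namespace

// [[Rcpp::export(name = ".estelle_run")]]
List estelle_run(NumericVector lon, NumericVector lat,
                 NumericVector A, NumericVector q,
                 NumericVector dec_rad, double zenith,
                 double meanlog, double sdlog,
                 NumericVector dt_h, double shape, double rate,
                 NumericVector sst_obs, IntegerVector week0,
                 NumericVector field_temp, NumericVector field_grid,
                 double sst_sd,
                 NumericVector mask_px, NumericVector mask_py,
                 IntegerVector ring_start, IntegerVector ring_len,
                 bool mask_hard, double mask_penalty,
                 NumericVector scales, int n_iter,
                 bool adapt, bool collect, int thin) {
  RNGScope rngscope;
  const int K = lon.size();
  Model M;
  M.K = K;
  M.A.assign(A.begin(), A.end());
  M.q.assign(q.begin(), q.end());
  M.sindec.resize(K); M.cosdec.resize(K);
  for (int k = 0; k < K; ++k) { M.sindec[k] = std::sin(dec_rad[k]); M.cosdec[k] = std::cos(dec_rad[k]); }
  M.cosz = std::cos(zenith * D2R);
  M.meanlog = meanlog; M.sdlog = sdlog;
  M.dt_h.assign(dt_h.begin(), dt_h.end());
  M.shape = shape; M.rate = rate;
  M.sst_obs.assign(sst_obs.begin(), sst_obs.end());
  M.wk.assign(week0.begin(), week0.end());
  M.temp = field_temp.begin();
  M.lon0 = field_grid[0]; M.dlon = field_grid[1]; M.nlon = (int)field_grid[2];
  M.lat0 = field_grid[3]; M.dlat = field_grid[4]; M.nlat = (int)field_grid[5];
  M.sst_sd = sst_sd;
  M.px.assign(mask_px.begin(), mask_px.end());
  M.py.assign(mask_py.begin(), mask_py.end());
  M.ring_start.assign(ring_start.begin(), ring_start.end());
  M.ring_len.assign(ring_len.begin(), ring_len.end());
  M.mask_hard = mask_hard; M.mask_penalty = mask_penalty;

  std::vector<double> x(lon.begin(), lon.end()), y(lat.begin(), lat.end());
  std::vector<double> sc(scales.begin(), scales.end());
  std::vector<double> cur_loc(K);
  for (int k = 0; k < K; ++k) cur_loc[k] = M.loc_ll(k, x[k], y[k]);
  std::vector<int> acc(K, 0), acc_win(K, 0);

  if (thin < 1) thin = 1;
  NumericMatrix lon_s(collect ? n_iter : 0, collect ? K : 0);
  NumericMatrix lat_s(collect ? n_iter : 0, collect ? K : 0);
  const int sweeps = n_iter * thin;

  for (int it = 0; it < sweeps; ++it) {
    for (int parity = 0; parity < 2; ++parity) {
      for (int k = parity; k < K; k += 2) {
        double nx = x[k] + sc[k] * norm_rand();
        double ny = y[k] + sc[k] * norm_rand();
        double new_loc = M.loc_ll(k, nx, ny);
        double dll;
        if (new_loc == R_NegInf) {
          continue;
        } else if (cur_loc[k] == R_NegInf) {
          dll = R_PosInf;
        } else {
          dll = new_loc - cur_loc[k];
          if (k > 0)
            dll += M.pair_ll(k - 1, x[k - 1], y[k - 1], nx, ny) -
                   M.pair_ll(k - 1, x[k - 1], y[k - 1], x[k], y[k]);
          if (k < K - 1)
            dll += M.pair_ll(k, nx, ny, x[k + 1], y[k + 1]) -
                   M.pair_ll(k, x[k], y[k], x[k + 1], y[k + 1]);
        }
        if (dll >= 0 || std::log(unif_rand()) < dll) {
          x[k] = nx; y[k] = ny; cur_loc[k] = new_loc;
          ++acc[k]; ++acc_win[k];
        }
      }
    }
    if (adapt && ((it + 1) % 50 == 0)) {
      for (int k = 0; k < K; ++k) {
        double rate_k = acc_win[k] / 50.0;
        sc[k] *= std::exp(rate_k - 0.3);
        if (sc[k] < 1e-3) sc[k] = 1e-3;
        if (sc[k] > 20) sc[k] = 20;
        acc_win[k] = 0;
      }
    }
    if (collect && ((it + 1) % thin == 0)) {
      int row = (it + 1) / thin - 1;
      for (int k = 0; k < K; ++k) { lon_s(row, k) = x[k]; lat_s(row, k) = y[k]; }
    }
  }

  return List::create(
    _["lon"] = NumericVector(x.begin(), x.end()),
    _["lat"] = NumericVector(y.begin(), y.end()),
    _["scales"] = NumericVector(sc.begin(), sc.end()),
    _["acc_rate"] = NumericVector::create(),
    _["acc"] = IntegerVector(acc.begin(), acc.end()),
    _["lon_samples"] = lon_s,
    _["lat_samples"] = lat_s,
    _["n_iter"] = sweeps);
}
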