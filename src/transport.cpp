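// Weighted Monte Carlo photon transport in a layered slab geometry.
//
// Geometry: z = 0 at the top surface, increasing downward. Layers are
// homogeneous infinite slabs; ambient media above/below enter only through
// their refractive indices. Uses R's RNG (unif_rand), so results are
// reproducible with set.seed() and independent of compiler RNG libraries.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// Unpolarized Fresnel reflection probability for a ray crossing from index
// n_i into n_t with incidence cosine cos_ai. Analytic limits replace the
// singular endpoints: normal incidence -> ((n_i-n_t)/(n_i+n_t))^2, at or
// beyond the critical angle -> 1.
// [[Rcpp::export(name = ".cpp_fresnel")]]
double cpp_fresnel(double n_i, double n_t, double cos_ai) {
  if (n_i == n_t) return 0.0;
  if (cos_ai > 1.0) cos_ai = 1.0;
  if (cos_ai < 0.0) cos_ai = 0.0;
  if (cos_ai > 1.0 - 1e-12) {
    double r = (n_i - n_t) / (n_i + n_t);
    return r * r;
  }
  double sin_ai = std::sqrt(1.0 - cos_ai * cos_ai);
  double sin_at = n_i / n_t * sin_ai;
  if (sin_at >= 1.0) return 1.0;  // total internal reflection
  if (cos_ai < 1e-6) return 1.0;  // grazing limit
  double cos_at = std::sqrt(1.0 - sin_at * sin_at);
  // sin/cos of (ai -/+ at) via addition formulas (avoids acos round trips)
  double sap = sin_ai * cos_at + cos_ai * sin_at;  // sin(ai + at)
  double sam = sin_ai * cos_at - cos_ai * sin_at;  // sin(ai - at)
  double cap = cos_ai * cos_at - sin_ai * sin_at;  // cos(ai + at)
  double cam = cos_ai * cos_at + sin_ai * sin_at;  // cos(ai - at)
  double rs = sam * sam / (sap * sap);
  double rp = (sam * cap) * (sam * cap) / ((sap * cam) * (sap * cam));
  double R = 0.5 * (rs + rp);
  if (R > 1.0) R = 1.0;
  return R;
}

// Henyey-Greenstein deflection cosine for one uniform deviate xi.
// [[Rcpp::export(name = ".cpp_hg_cosine")]]
double cpp_hg_cosine(double g, double xi) {
  if (g == 0.0) return 2.0 * xi - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

struct Accum {
  // per-photon contributions for standard errors of the totals
  double sum = 0.0, sum2 = 0.0;
  void add(double x) { sum += x; sum2 += x * x; }
};

// Full simulation. Layer vectors are ordered top -> bottom. flesh_layer is
// 0-based; pass -1 for "no flesh layer" (detection metrics then stay 0).
// Returns raw accumulators; normalization happens in R.
// [[Rcpp::export(name = ".cpp_run_mc")]]
List cpp_run_mc(NumericVector layer_n, NumericVector layer_mua,
                NumericVector layer_mus, NumericVector layer_g,
                NumericVector layer_d, double n_above, double n_below,
                int n_photons, double w_th, double roulette_m,
                double dr, double dz, int nr, int nz, int na,
                int flesh_layer) {
  const int nl = layer_n.size();
  if (nl < 1) stop("at least one layer is required");

  std::vector<double> zb(nl + 1);  // boundary depths
  zb[0] = 0.0;
  for (int i = 0; i < nl; ++i) zb[i + 1] = zb[i] + layer_d[i];
  std::vector<double> mut(nl);
  for (int i = 0; i < nl; ++i) {
    mut[i] = layer_mua[i] + layer_mus[i];
    if (mut[i] <= 0.0) stop("each layer needs mu_a + mu_s > 0");
  }

  const double rsp = cpp_fresnel(n_above, layer_n[0], 1.0);
  const double w0 = 1.0 - rsp;
  const double da = (PI_ / 2.0) / na;

  NumericMatrix refl_r_alpha(nr, na);
  NumericMatrix absorb_r_z(nr, nz);
  NumericVector below_r(nr);
  NumericVector eff_weight_r(nr), total_weight_r(nr);
  NumericVector eff_count_r(nr), total_count_r(nr);
  NumericVector flesh_path_r(nr), total_path_r(nr);
  NumericVector a_layer(nl);
  double t_below = 0.0, rd_total = 0.0, lost_roulette = 0.0;
  double refl_overflow = 0.0;

  Accum acc_rd, acc_below;
  std::vector<Accum> acc_a(nl);

  RNGScope scope;
  std::vector<double> path(nl);
  std::vector<double> a_ph(nl);
  const long max_events = 10000000L;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = w0;
    int layer = 0;
    bool flesh_flag = false;
    double sleft = 0.0;  // dimensionless residual step
    std::fill(path.begin(), path.end(), 0.0);
    std::fill(a_ph.begin(), a_ph.end(), 0.0);
    double ph_rd = 0.0, ph_below = 0.0;
    bool alive = true;
    long events = 0;

    while (alive) {
      if (++events > max_events)
        stop("runaway photon: event cap exceeded (photon %d)", ip + 1);

      double s;  // geometric step in current layer
      if (sleft > 0.0) {
        s = sleft / mut[layer];
        sleft = 0.0;
      } else {
        double xi = unif_rand();
        while (xi <= 0.0) xi = unif_rand();
        s = -std::log(xi) / mut[layer];
      }

      // distance to the boundary along the flight direction
      double db = R_PosInf;
      bool down = uz > 0.0;
      if (uz > 1e-12) db = (zb[layer + 1] - z) / uz;
      else if (uz < -1e-12) db = (zb[layer] - z) / uz;
      if (db < 0.0) db = 0.0;

      if (db <= s) {
        // hit the boundary: move there, bank the unused dimensionless path
        x += ux * db; y += uy * db; z += uz * db;
        path[layer] += db;
        sleft = (s - db) * mut[layer];

        double n_i = layer_n[layer];
        double n_t = down ? (layer == nl - 1 ? n_below : layer_n[layer + 1])
                          : (layer == 0 ? n_above : layer_n[layer - 1]);
        double cos_ai = std::fabs(uz);
        double R = cpp_fresnel(n_i, n_t, cos_ai);
        if (unif_rand() < R) {
          uz = -uz;  // internal reflection
          z = down ? zb[layer + 1] : zb[layer];
          continue;
        }
        // refract (Snell): transverse components scale by n_i/n_t
        double ratio = n_i / n_t;
        double sin_ai = std::sqrt(std::max(0.0, 1.0 - cos_ai * cos_ai));
        double sin_at = ratio * sin_ai;
        double cos_at = std::sqrt(std::max(0.0, 1.0 - sin_at * sin_at));
        if (!down && layer == 0) {
          // escapes into the ambient medium above: score and terminate
          double r = std::sqrt(x * x + y * y);
          int ir = (int)(r / dr);
          bool over = ir >= nr;
          if (over) { ir = nr - 1; refl_overflow += w; }
          double alpha = std::acos(std::min(1.0, cos_at));
          int ia = (int)(alpha / da);
          if (ia >= na) ia = na - 1;
          refl_r_alpha(ir, ia) += w;
          total_weight_r[ir] += w;
          total_count_r[ir] += 1.0;
          double lt = 0.0;
          for (int i = 0; i < nl; ++i) lt += path[i];
          total_path_r[ir] += w * lt;
          if (flesh_flag) {
            eff_weight_r[ir] += w;
            eff_count_r[ir] += 1.0;
          }
          if (flesh_layer >= 0) flesh_path_r[ir] += w * path[flesh_layer];
          rd_total += w;
          ph_rd += w;
          alive = false;
        } else if (down && layer == nl - 1) {
          // crosses into the medium below (core): absorbed there, terminates
          double r = std::sqrt(x * x + y * y);
          int ir = (int)(r / dr);
          if (ir >= nr) ir = nr - 1;
          below_r[ir] += w;
          t_below += w;
          ph_below += w;
          alive = false;
        } else {
          layer += down ? 1 : -1;
          ux *= ratio; uy *= ratio;
          uz = down ? cos_at : -cos_at;
          z = down ? zb[layer] : zb[layer + 1];
        }
        continue;
      }

      // interaction inside the layer: move, deposit, spin
      x += ux * s; y += uy * s; z += uz * s;
      path[layer] += s;
      double dw = w * layer_mua[layer] / mut[layer];
      if (dw > 0.0) {
        double r = std::sqrt(x * x + y * y);
        int ir = (int)(r / dr); if (ir >= nr) ir = nr - 1;
        int iz = (int)(z / dz); if (iz >= nz) iz = nz - 1; if (iz < 0) iz = 0;
        absorb_r_z(ir, iz) += dw;
        a_layer[layer] += dw;
        a_ph[layer] += dw;
        w -= dw;
      }
      if (layer == flesh_layer) flesh_flag = true;

      double ct = cpp_hg_cosine(layer_g[layer], unif_rand());
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double psi = 2.0 * PI_ * unif_rand();
      double cp = std::cos(psi), sp = std::sin(psi);
      if (std::fabs(uz) > 1.0 - 1e-5) {
        ux = st * cp;
        uy = st * sp;
        uz = (uz >= 0.0 ? 1.0 : -1.0) * ct;
      } else {
        double tmp = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / tmp + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / tmp + uy * ct;
        double nuz = -st * cp * tmp + uz * ct;
        ux = nux; uy = nuy; uz = nuz;
      }
      double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;

      if (w < w_th && alive) {
        if (unif_rand() < 1.0 / roulette_m) {
          w *= roulette_m;
        } else {
          lost_roulette += w;
          alive = false;
        }
      }
    }

    acc_rd.add(ph_rd);
    acc_below.add(ph_below);
    for (int i = 0; i < nl; ++i) acc_a[i].add(a_ph[i]);
  }

  NumericVector a_sum(nl), a_sum2(nl);
  for (int i = 0; i < nl; ++i) { a_sum[i] = acc_a[i].sum; a_sum2[i] = acc_a[i].sum2; }

  return List::create(
    _["rsp"] = rsp,
    _["refl_r_alpha"] = refl_r_alpha,
    _["absorb_r_z"] = absorb_r_z,
    _["below_r"] = below_r,
    _["eff_weight_r"] = eff_weight_r,
    _["total_weight_r"] = total_weight_r,
    _["eff_count_r"] = eff_count_r,
    _["total_count_r"] = total_count_r,
    _["flesh_path_r"] = flesh_path_r,
    _["total_path_r"] = total_path_r,
    _["a_layer"] = a_layer,
    _["rd_total"] = rd_total,
    _["t_below"] = t_below,
    _["lost_roulette"] = lost_roulette,
    _["refl_overflow"] = refl_overflow,
    _["rd_sum"] = acc_rd.sum, _["rd_sum2"] = acc_rd.sum2,
    _["below_sum"] = acc_below.sum, _["below_sum2"] = acc_below.sum2,
    _["a_sum"] = a_sum, _["a_sum2"] = a_sum2);
}
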