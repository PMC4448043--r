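// Monte Carlo photon transport in layered slab geometries with lateral
// cylindrical bounds, Henyey-Greenstein scattering, Fresnel/TIR boundary
// optics and track-length fluence tallies on a cylindrical (r,z) grid.
//
// All randomness comes from a counter-based generator keyed by
// (seed, photon index) so that photon histories are reproducible, order
// independent, and replayable one deviate at a time from R (the scalar
// reference engine consumes the identical substreams).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// glibc sincos, used explicitly wherever both the sine and cosine of an
// angle are needed so the choice of primitive does not depend on
// compiler fusion heuristics (the R-side reference engine calls the
// same function through .libm_sincos)
extern "C" void sincos(double x, double *sinx, double *cosx);


static const double STEP_EPS = 1e-12;   // boundary distances below this are the surface we sit on

// ---------------------------------------------------------------- RNG -----

static inline uint64_t mix64(uint64_t z) {
  z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 27; z *= 0x94D049BB133111EBULL;
  z ^= z >> 31;
  return z;
}

static inline uint64_t photon_key(uint64_t seed, uint64_t idx) {
  return mix64(mix64(seed + 0x9E3779B97F4A7C15ULL) ^
               (0xD1B54A32D192ED03ULL * (idx + 1ULL)));
}

// k-th uniform deviate of a photon substream, strictly inside (0, 1)
static inline double u_at(uint64_t key, uint64_t k) {
  uint64_t x = mix64(key + 0x9E3779B97F4A7C15ULL * (k + 1ULL));
  return ((double)(x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

struct Stream {
  uint64_t key;
  uint64_t k;
  double draw() { return u_at(key, k++); }
};

//' @name rng_substream
// [[Rcpp::export(name = ".rng_substream")]]
NumericVector rng_substream_cpp(double seed, double photon_index,
                                double from, int n) {
  uint64_t key = photon_key((uint64_t)(int64_t)seed,
                            (uint64_t)(int64_t)photon_index);
  NumericVector out(n);
  uint64_t k0 = (uint64_t)(int64_t)from;
  for (int i = 0; i < n; i++) out[i] = u_at(key, k0 + (uint64_t)i);
  return out;
}

// ------------------------------------------------------- optics kernels ---

static inline double fresnel_R(double n1, double n2, double cosi) {
  if (n1 == n2) return 0.0;
  double sini2 = 1.0 - cosi * cosi;
  if (sini2 < 0.0) sini2 = 0.0;
  double sint = n1 * std::sqrt(sini2) / n2;
  if (sint >= 1.0) return 1.0;               // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

static inline double hg_cos(double g, double u) {
  if (g == 0.0) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

static inline void rotate_dir(double &ux, double &uy, double &uz,
                              double ct, double phi) {
  double st2 = 1.0 - ct * ct;
  if (st2 < 0.0) st2 = 0.0;
  double st = std::sqrt(st2);
  double sp, cp;
  sincos(phi, &sp, &cp);
  double nx, ny, nz;
  if (std::fabs(uz) > 1.0 - 1e-9) {          // near-pole branch
    double sgn = (uz >= 0.0) ? 1.0 : -1.0;
    nx = st * cp;
    ny = sgn * st * sp;
    nz = sgn * ct;
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    nx = st * (ux * uz * cp - uy * sp) / tmp + ux * ct;
    ny = st * (uy * uz * cp + ux * sp) / tmp + uy * ct;
    nz = -st * cp * tmp + uz * ct;
  }
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / nrm; uy = ny / nrm; uz = nz / nrm;
}

// R's trig/log can differ from the C library's by one ulp on some
// builds; the scalar reference engine calls these wrappers so that both
// engines use the identical transcendental primitives.
// [[Rcpp::export(name = ".libm_sincos")]]
NumericVector libm_sincos(double x) {
  double s, c;
  sincos(x, &s, &c);
  return NumericVector::create(c, s);
}
// [[Rcpp::export(name = ".libm_log")]]
double libm_log(double x) { return std::log(x); }


// ----------------------------------------------------------- geometry -----

struct Layer {
  double z0, z1;     // z interval, z0 < z1
  int inner;         // medium index (0-based) for r < r_lat
  double r_lat;      // lateral radius of the inner zone
  int outer;         // medium index for r >= r_lat (== inner if none)
  bool blocked;      // top plane of the inner zone is an opaque contact
};

enum SurfaceType { SURF_NONE = -1, SURF_ZUP = 0, SURF_ZDOWN = 1,
                   SURF_LATERAL = 2, SURF_EDGE = 3 };

struct Scene {
  std::vector<double> med_n, med_mua, med_mus, med_g, med_mut;
  std::vector<Layer> layers;
  double domain_radius;
  double backplane_refl;
  // source: 0 disc, 1 fiber, 2 pencil
  int src_type;
  double src_z, src_radius, src_sigma, src_cosmax;
  bool src_collimated;
  // grid
  double gz0, gdz, gdr;
  int gnz, gnr;
  // run
  double n_photons_d;
  uint64_t seed;
  double rr_threshold, rr_survival;
  bool strict_term;
  int step_cap;
};

struct Hit { double t; int type; };

static inline Hit dist_boundary(const Scene &S, int li, bool inner,
                                double x, double y, double z,
                                double dx, double dy, double dz) {
  const Layer &L = S.layers[li];
  double best = 1e30;
  int type = SURF_NONE;
  if (dz > 0.0) {
    double t = (L.z1 - z) / dz;
    if (t > STEP_EPS && t < best) { best = t; type = SURF_ZDOWN; }
  } else if (dz < 0.0) {
    double t = (L.z0 - z) / dz;
    if (t > STEP_EPS && t < best) { best = t; type = SURF_ZUP; }
  }
  double a = dx * dx + dy * dy;
  if (a > 0.0) {
    double b = 2.0 * (x * dx + y * dy);
    double c = x * x + y * y;
    if (inner) {
      bool spans = (L.r_lat >= S.domain_radius);
      double Rc = spans ? S.domain_radius : L.r_lat;
      double disc = b * b - 4.0 * a * (c - Rc * Rc);
      if (disc > 0.0) {
        double t = (-b + std::sqrt(disc)) / (2.0 * a);
        if (t > STEP_EPS && t < best) {
          best = t; type = spans ? SURF_EDGE : SURF_LATERAL;
        }
      }
    } else {
      double disc = b * b - 4.0 * a * (c - L.r_lat * L.r_lat);
      if (disc > 0.0) {
        double t1 = (-b - std::sqrt(disc)) / (2.0 * a);
        if (t1 > STEP_EPS && t1 < best) { best = t1; type = SURF_LATERAL; }
      }
      double disc2 = b * b - 4.0 * a * (c - S.domain_radius * S.domain_radius);
      if (disc2 > 0.0) {
        double t2 = (-b + std::sqrt(disc2)) / (2.0 * a);
        if (t2 > STEP_EPS && t2 < best) { best = t2; type = SURF_EDGE; }
      }
    }
  }
  Hit h; h.t = best; h.type = type;
  return h;
}

// ----------------------------------------------------- track deposition ---

struct GridAcc {
  int nr, nz;
  double dr, dz, z0;
  std::vector<double> v;           // nr x nz, column major: v[ir + nr*iz]
  double outside;                  // weight*length falling outside the grid
};

static void deposit_seg(GridAcc &G, std::vector<double> &ts,
                        double x0, double y0, double z0,
                        double x1, double y1, double z1, double w) {
  double ddx = x1 - x0, ddy = y1 - y0, ddz = z1 - z0;
  double L = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
  if (L <= 0.0 || w <= 0.0) return;

  double ta = 0.0, tb = 1.0;
  double zlo = G.z0, zhi = G.z0 + G.nz * G.dz;
  if (ddz != 0.0) {
    double t_lo = (zlo - z0) / ddz, t_hi = (zhi - z0) / ddz;
    double tmn = std::min(t_lo, t_hi), tmx = std::max(t_lo, t_hi);
    if (tmn > ta) ta = tmn;
    if (tmx < tb) tb = tmx;
  } else if (z0 < zlo || z0 >= zhi) {
    G.outside += w * L;
    return;
  }

  double a = ddx * ddx + ddy * ddy;
  double b = 2.0 * (x0 * ddx + y0 * ddy);
  double c = x0 * x0 + y0 * y0;
  double Rg = G.nr * G.dr;
  if (a > 0.0) {
    double disc = b * b - 4.0 * a * (c - Rg * Rg);
    if (disc <= 0.0) {
      if (c >= Rg * Rg) { G.outside += w * L; return; }
    } else {
      double s = std::sqrt(disc);
      double t1 = (-b - s) / (2.0 * a), t2 = (-b + s) / (2.0 * a);
      if (t1 > ta) ta = t1;
      if (t2 < tb) tb = t2;
    }
  } else if (c >= Rg * Rg) {
    G.outside += w * L;
    return;
  }
  if (ta >= tb) { G.outside += w * L; return; }
  G.outside += w * L * (1.0 - (tb - ta));

  ts.clear();
  ts.push_back(ta);
  ts.push_back(tb);

  if (ddz != 0.0) {
    double za = z0 + ta * ddz, zb = z0 + tb * ddz;
    double zmn = std::min(za, zb), zmx = std::max(za, zb);
    int jlo = (int)std::floor((zmn - G.z0) / G.dz) + 1;
    int jhi = (int)std::floor((zmx - G.z0) / G.dz);
    if (jlo < 0) jlo = 0;
    if (jhi > G.nz) jhi = G.nz;
    for (int j = jlo; j <= jhi; j++) {
      double plane = G.z0 + j * G.dz;
      if (plane > zmn && plane < zmx) ts.push_back((plane - z0) / ddz);
    }
  }

  if (a > 0.0) {
    double tstar = -b / (2.0 * a);
    auto shells = [&](double p, double q, bool increasing) {
      double rp2 = a * p * p + b * p + c;
      double rq2 = a * q * q + b * q + c;
      if (rp2 < 0.0) rp2 = 0.0;
      if (rq2 < 0.0) rq2 = 0.0;
      double rp = std::sqrt(rp2), rq = std::sqrt(rq2);
      double rlo = std::min(rp, rq), rhi = std::max(rp, rq);
      int klo = (int)std::floor(rlo / G.dr) + 1;
      int khi = (int)std::floor(rhi / G.dr);
      if (klo < 1) klo = 1;
      for (int k = klo; k <= khi; k++) {
        double re = k * G.dr;
        double d2 = b * b - 4.0 * a * (c - re * re);
        if (d2 <= 0.0) continue;
        double s = std::sqrt(d2);
        double t = increasing ? (-b + s) / (2.0 * a) : (-b - s) / (2.0 * a);
        if (t > p && t < q) ts.push_back(t);
      }
    };
    if (tstar > ta && tstar < tb) {
      shells(ta, tstar, false);
      shells(tstar, tb, true);
    } else if (tstar <= ta) {
      shells(ta, tb, true);
    } else {
      shells(ta, tb, false);
    }
  }

  std::sort(ts.begin(), ts.end());
  for (size_t i = 0; i + 1 < ts.size(); i++) {
    double t0 = ts[i], t1 = ts[i + 1];
    double dt = t1 - t0;
    if (dt <= 0.0) continue;
    double tm = 0.5 * (t0 + t1);
    double xm = x0 + tm * ddx, ym = y0 + tm * ddy, zm = z0 + tm * ddz;
    double rm = std::sqrt(xm * xm + ym * ym);
    int ir = (int)(rm / G.dr);
    int iz = (int)((zm - G.z0) / G.dz);
    if (ir >= 0 && ir < G.nr && iz >= 0 && iz < G.nz) {
      G.v[ir + (size_t)G.nr * iz] += w * dt * L;
    } else {
      G.outside += w * dt * L;
    }
  }
}

// --------------------------------------------------------------- engine ---

static Scene parse_scene(const List &scene) {
  Scene S;
  NumericMatrix media = scene["media"];
  int nm = media.nrow();
  for (int i = 0; i < nm; i++) {
    S.med_n.push_back(media(i, 0));
    S.med_mua.push_back(media(i, 1));
    S.med_mus.push_back(media(i, 2));
    S.med_g.push_back(media(i, 3));
    S.med_mut.push_back(media(i, 1) + media(i, 2));
  }
  NumericMatrix lay = scene["layers"];
  for (int i = 0; i < lay.nrow(); i++) {
    Layer L;
    L.z0 = lay(i, 0); L.z1 = lay(i, 1);
    L.inner = (int)lay(i, 2) - 1;
    L.r_lat = lay(i, 3);
    L.outer = (int)lay(i, 4) - 1;
    L.blocked = lay(i, 5) != 0.0;
    S.layers.push_back(L);
  }
  S.domain_radius = as<double>(scene["domain_radius"]);
  S.backplane_refl = as<double>(scene["backplane_reflectivity"]);
  NumericVector src = scene["source"];
  S.src_type = (int)src[0];
  S.src_z = src[1];
  S.src_radius = src[2];
  S.src_sigma = src[3];
  S.src_cosmax = src[4];
  S.src_collimated = src[5] != 0.0;
  NumericVector grid = scene["grid"];
  S.gz0 = grid[0]; S.gdz = grid[1]; S.gnz = (int)grid[2];
  S.gdr = grid[3]; S.gnr = (int)grid[4];
  List run = scene["run"];
  S.n_photons_d = as<double>(run["n_photons"]);
  S.seed = (uint64_t)(int64_t)as<double>(run["seed"]);
  S.rr_threshold = as<double>(run["roulette_threshold"]);
  S.rr_survival = as<double>(run["roulette_survival"]);
  S.strict_term = as<bool>(run["strict_termination"]);
  S.step_cap = (int)as<double>(run["step_cap"]);
  return S;
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(List scene, bool record_events = false) {
  Scene S = parse_scene(scene);
  int nlay = (int)S.layers.size();
  int nmed = (int)S.med_n.size();

  GridAcc G;
  G.nr = S.gnr; G.nz = S.gnz; G.dr = S.gdr; G.dz = S.gdz; G.z0 = S.gz0;
  G.v.assign((size_t)G.nr * G.nz, 0.0);
  G.outside = 0.0;

  std::vector<double> absorbed(nmed, 0.0);
  double escaped = 0.0, back_plane = 0.0, edge = 0.0;
  double roulette_net = 0.0, capped = 0.0;
  double n_capped = 0.0;
  // per-photon partial sums, folded into the global tallies once per
  // photon (matching the reference engine's summation order exactly)
  std::vector<double> abs_loc(nmed, 0.0);
  std::vector<double> ev;   // photon,x0,y0,z0,x1,y1,z1,w,medium

  // launch layer: the layer whose z interval contains src_z (half open)
  int launch_layer = -1;
  for (int i = 0; i < nlay; i++) {
    if (S.src_z >= S.layers[i].z0 && S.src_z < S.layers[i].z1) {
      launch_layer = i;
      break;
    }
  }
  if (launch_layer < 0) stop("source plane lies outside the layered geometry");

  std::vector<double> ts_buf;
  ts_buf.reserve(64);

  double N = S.n_photons_d;
  for (double pd = 0.0; pd < N; pd += 1.0) {
    uint64_t pidx = (uint64_t)pd;
    Stream rng; rng.key = photon_key(S.seed, pidx); rng.k = 0;

    // ---- launch
    double x, y, z, dx, dy, dz;
    z = S.src_z;
    if (S.src_type == 0) {                       // Lambertian / collimated disc
      double u1 = rng.draw(), u2 = rng.draw();
      double rr = (S.src_radius) * std::sqrt(u1);
      double ph = 2.0 * M_PI * u2;
      double sph, cph;
      sincos(ph, &sph, &cph);
      x = rr * cph; y = rr * sph;
      if (S.src_collimated) {
        dx = 0.0; dy = 0.0; dz = 1.0;
      } else {
        double u3 = rng.draw(), u4 = rng.draw();
        double ct = std::sqrt(1.0 - u3);
        double st = std::sqrt(u3);
        double ph2 = 2.0 * M_PI * u4;
        double sph2, cph2;
        sincos(ph2, &sph2, &cph2);
        dx = st * cph2; dy = st * sph2; dz = ct;
      }
    } else if (S.src_type == 1) {                // fiber aperture
      double rad;
      do {
        double u = rng.draw();
        rad = S.src_sigma * std::sqrt(-2.0 * std::log(u));
      } while (rad > S.src_radius);
      double u2 = rng.draw();
      double ph = 2.0 * M_PI * u2;
      double sph, cph;
      sincos(ph, &sph, &cph);
      x = rad * cph; y = rad * sph;
      double u3 = rng.draw(), u4 = rng.draw();
      double ct = 1.0 - u3 * (1.0 - S.src_cosmax);
      double st = std::sqrt(1.0 - ct * ct);
      double ph2 = 2.0 * M_PI * u4;
      double sph2, cph2;
      sincos(ph2, &sph2, &cph2);
      dx = st * cph2; dy = st * sph2; dz = ct;
    } else {                                     // pencil beam
      x = 0.0; y = 0.0; dx = 0.0; dy = 0.0; dz = 1.0;
    }

    int li = launch_layer;
    bool inner = std::sqrt(x * x + y * y) < S.layers[li].r_lat;
    int mi = inner ? S.layers[li].inner : S.layers[li].outer;
    double w = 1.0;
    bool alive = true;
    int steps = 0;

    std::fill(abs_loc.begin(), abs_loc.end(), 0.0);
    double esc_loc = 0.0, back_loc = 0.0, edge_loc = 0.0;
    double rnet_loc = 0.0, cap_loc = 0.0, ncap_loc = 0.0;

    while (alive) {
      steps++;
      if (steps > S.step_cap) {
        cap_loc += w; ncap_loc += 1.0; alive = false;
        break;
      }
      double mut = S.med_mut[mi];
      double s;
      if (mut > 0.0) {
        double u = rng.draw();
        s = -std::log(u) / mut;
      } else {
        s = R_PosInf;
      }
      Hit h = dist_boundary(S, li, inner, x, y, z, dx, dy, dz);

      if (s < h.t) {
        // ---- interaction: move, deposit, absorb, scatter, roulette
        double nx = x + s * dx, ny = y + s * dy, nz = z + s * dz;
        if (record_events) {
          ev.push_back(pd + 1.0);
          ev.push_back(x); ev.push_back(y); ev.push_back(z);
          ev.push_back(nx); ev.push_back(ny); ev.push_back(nz);
          ev.push_back(w); ev.push_back(mi + 1.0);
        }
        deposit_seg(G, ts_buf, x, y, z, nx, ny, nz, w);
        x = nx; y = ny; z = nz;
        double neww = w * (S.med_mus[mi] / mut);
        abs_loc[mi] += w - neww;
        w = neww;
        if (w <= 0.0) { alive = false; break; }
        double u1 = rng.draw();
        double ct = hg_cos(S.med_g[mi], u1);
        double u2 = rng.draw();
        rotate_dir(dx, dy, dz, ct, 2.0 * M_PI * u2);
        if (w < S.rr_threshold) {
          if (S.strict_term) {
            rnet_loc += w; alive = false;
          } else {
            double ur = rng.draw();
            if (ur < S.rr_survival) {
              double nw = w / S.rr_survival;
              rnet_loc += w - nw;
              w = nw;
            } else {
              rnet_loc += w; alive = false;
            }
          }
        }
      } else {
        // ---- boundary: move, deposit, resolve surface
        double nx = x + h.t * dx, ny = y + h.t * dy, nz = z + h.t * dz;
        if (record_events) {
          ev.push_back(pd + 1.0);
          ev.push_back(x); ev.push_back(y); ev.push_back(z);
          ev.push_back(nx); ev.push_back(ny); ev.push_back(nz);
          ev.push_back(w); ev.push_back(mi + 1.0);
        }
        deposit_seg(G, ts_buf, x, y, z, nx, ny, nz, w);
        x = nx; y = ny; z = nz;

        if (h.type == SURF_EDGE) {
          edge_loc += w; alive = false;
        } else if (h.type == SURF_ZUP || h.type == SURF_ZDOWN) {
          const Layer &L = S.layers[li];
          double zp = (h.type == SURF_ZUP) ? L.z0 : L.z1;
          z = zp;                                 // snap to the plane
          int lj = (h.type == SURF_ZUP) ? li - 1 : li + 1;
          if (lj < 0) {
            back_loc += w; alive = false;
          } else if (lj >= nlay) {
            esc_loc += w; alive = false;
          } else {
            double r_hit = std::sqrt(x * x + y * y);
            // opaque p-contact: leaving the blocked layer's inner zone
            // upward, or entering it from the layer above
            bool blk;
            if (h.type == SURF_ZUP) {
              blk = L.blocked && inner;
            } else {
              blk = S.layers[lj].blocked && (r_hit < S.layers[lj].r_lat);
            }
            if (blk) {
              if (S.backplane_refl > 0.0) {
                double u = rng.draw();
                if (u < S.backplane_refl) {
                  dz = -dz;                       // specular contact
                } else {
                  back_loc += w; alive = false;
                }
              } else {
                back_loc += w; alive = false;
              }
            } else {
              bool inner_j = r_hit < S.layers[lj].r_lat;
              int mj = inner_j ? S.layers[lj].inner : S.layers[lj].outer;
              double n1 = S.med_n[mi], n2 = S.med_n[mj];
              double cosi = std::fabs(dz);
              double R = fresnel_R(n1, n2, cosi);
              double u = rng.draw();
              if (u < R) {
                dz = -dz;                         // reflect (incl. TIR)
              } else {
                double nzn = (dz > 0.0) ? -1.0 : 1.0;  // normal opposing d
                double eta = n1 / n2;
                double sint2 = eta * eta * (1.0 - cosi * cosi);
                double cost = std::sqrt(std::max(0.0, 1.0 - sint2));
                double tx = eta * dx;
                double ty = eta * dy;
                double tz = eta * dz + (eta * cosi - cost) * nzn;
                double nrm = std::sqrt(tx * tx + ty * ty + tz * tz);
                dx = tx / nrm; dy = ty / nrm; dz = tz / nrm;
                li = lj; inner = inner_j; mi = mj;
              }
            }
          }
        } else {                                  // SURF_LATERAL
          const Layer &L = S.layers[li];
          double Rc = L.r_lat;
          double r_hit = std::sqrt(x * x + y * y);
          if (r_hit > 0.0) {                      // snap onto the cylinder
            double f = Rc / r_hit;
            x *= f; y *= f;
          }
          double rx = x / Rc, ry = y / Rc;
          int mj = inner ? L.outer : L.inner;
          double n1 = S.med_n[mi], n2 = S.med_n[mj];
          double ddotn = dx * rx + dy * ry;
          double cosi = std::fabs(ddotn);
          double R = fresnel_R(n1, n2, cosi);
          double u = rng.draw();
          if (u < R) {
            dx = dx - 2.0 * ddotn * rx;
            dy = dy - 2.0 * ddotn * ry;
          } else {
            double sgn = (ddotn > 0.0) ? -1.0 : 1.0;  // normal opposing d
            double nxn = sgn * rx, nyn = sgn * ry;
            double eta = n1 / n2;
            double sint2 = eta * eta * (1.0 - cosi * cosi);
            double cost = std::sqrt(std::max(0.0, 1.0 - sint2));
            double fac = eta * cosi - cost;
            double tx = eta * dx + fac * nxn;
            double ty = eta * dy + fac * nyn;
            double tz = eta * dz;
            double nrm = std::sqrt(tx * tx + ty * ty + tz * tz);
            dx = tx / nrm; dy = ty / nrm; dz = tz / nrm;
            inner = !inner; mi = mj;
          }
        }
      }
    }

    for (int i = 0; i < nmed; i++) absorbed[i] += abs_loc[i];
    escaped += esc_loc;
    back_plane += back_loc;
    edge += edge_loc;
    roulette_net += rnet_loc;
    capped += cap_loc;
    n_capped += ncap_loc;
  }

  NumericMatrix values(G.nr, G.nz);
  std::copy(G.v.begin(), G.v.end(), values.begin());

  List tallies = List::create(
    _["launched"] = N,
    _["absorbed"] = NumericVector(absorbed.begin(), absorbed.end()),
    _["escaped_domain"] = escaped,
    _["back_plane_loss"] = back_plane,
    _["edge_loss"] = edge,
    _["roulette_net"] = roulette_net,
    _["capped"] = capped,
    _["n_capped"] = n_capped,
    _["outside_grid_track"] = G.outside);

  List out = List::create(_["values"] = values, _["tallies"] = tallies);
  if (record_events) {
    int nev = (int)(ev.size() / 9);
    NumericMatrix em(nev, 9);
    for (int i = 0; i < nev; i++)
      for (int j = 0; j < 9; j++) em(i, j) = ev[(size_t)i * 9 + j];
    colnames(em) = CharacterVector::create("photon", "x0", "y0", "z0",
                                           "x1", "y1", "z1", "weight",
                                           "medium");
    out["events"] = em;
  }
  return out;
}
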