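#include <Rcpp.h>
#include <cmath>
#include <vector>

// Movement/detection engine for the encounter simulator.
//
// Animals move on a torus (width W, height H) in straight lines or as a
// correlated random walk, at constant speed. Each camera owns a sector-shaped
// detection zone (radius r, full angle theta about its heading). An
// independent event is emitted when an animal's path segment enters a zone it
// was not already inside; a pass-through within one time step (enter and exit
// between samples) still counts as one event. Entry detection is exact
// segment-sector intersection, so straight-line movers carry no
// discretisation bias in the event count.
//
// Optional placement-bias mechanism: during day hours (06-18 local clock),
// each free-moving animal relocates with per-step probability q*dt to the
// nearest camera ("shade tree") and rests inside its zone for rest_h hours;
// the relocation triggers an entry event unless the animal was already inside
// that zone. Night movement is always unbiased.

struct Interval {
  double lo, hi;
  bool empty() const { return lo > hi; }
};

static inline Interval seg_disc(double px, double py, double dx, double dy,
                                double r2) {
  // t in [0,1] with |p + t d|^2 <= r2
  double a = dx * dx + dy * dy;
  double b = 2.0 * (px * dx + py * dy);
  double c = px * px + py * py - r2;
  if (a < 1e-300) {
    if (c <= 0) return Interval{0.0, 1.0};
    return Interval{1.0, -1.0};
  }
  double disc = b * b - 4.0 * a * c;
  if (disc < 0) return Interval{1.0, -1.0};
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / (2.0 * a);
  double t2 = (-b + sq) / (2.0 * a);
  return Interval{std::max(t1, 0.0), std::min(t2, 1.0)};
}

static inline Interval seg_halfplane(double px, double py, double dx,
                                     double dy, double nx, double ny) {
  // t in [0,1] with (p + t d) . n >= 0
  double g0 = px * nx + py * ny;
  double g1 = dx * nx + dy * ny;
  if (std::fabs(g1) < 1e-300) {
    if (g0 >= 0) return Interval{0.0, 1.0};
    return Interval{1.0, -1.0};
  }
  double tc = -g0 / g1;
  if (g1 > 0) return Interval{std::max(tc, 0.0), 1.0};
  return Interval{0.0, std::min(tc, 1.0)};
}

static inline Interval isect(const Interval& a, const Interval& b) {
  return Interval{std::max(a.lo, b.lo), std::min(a.hi, b.hi)};
}

// Earliest parameter t in [0,1] at which segment p0 + t*(dx,dy) (p0 relative
// to the camera) lies inside the sector; empty interval if never.
static Interval seg_sector(double px, double py, double dx, double dy,
                           double phi, double r, double theta) {
  Interval idisc = seg_disc(px, py, dx, dy, r * r);
  if (idisc.empty()) return idisc;
  double beta = theta / 2.0;
  if (beta >= M_PI - 1e-12) return idisc;  // full circle
  if (theta <= M_PI) {
    // convex wedge: two half-planes through the apex
    double nux = std::cos(phi + beta - M_PI_2);
    double nuy = std::sin(phi + beta - M_PI_2);
    double nlx = std::cos(phi - beta + M_PI_2);
    double nly = std::sin(phi - beta + M_PI_2);
    Interval i = isect(idisc, seg_halfplane(px, py, dx, dy, nux, nuy));
    return isect(i, seg_halfplane(px, py, dx, dy, nlx, nly));
  }
  // reflex wedge: complement of the convex back-cone (half-angle pi - beta
  // about -heading); the wedge is the union of two half-planes
  double alpha = M_PI - beta;
  double psi = phi + M_PI;  // back direction
  double m1x = std::cos(psi + alpha - M_PI_2);
  double m1y = std::sin(psi + alpha - M_PI_2);
  double m2x = std::cos(psi - alpha + M_PI_2);
  double m2y = std::sin(psi - alpha + M_PI_2);
  Interval ia = isect(idisc, seg_halfplane(px, py, dx, dy, -m1x, -m1y));
  Interval ib = isect(idisc, seg_halfplane(px, py, dx, dy, -m2x, -m2y));
  if (ia.empty()) return ib;
  if (ib.empty()) return ia;
  return Interval{std::min(ia.lo, ib.lo), std::max(ia.hi, ib.hi)};
}

static inline bool in_sector(double px, double py, double phi, double r,
                             double theta) {
  double d2 = px * px + py * py;
  if (d2 > r * r) return false;
  if (d2 <= 0) return true;
  double proj = px * std::cos(phi) + py * std::sin(phi);
  return proj >= std::cos(theta / 2.0) * std::sqrt(d2);
}

static inline double wrap0(double v, double L) {
  // floor-based remainder in [0, L); avoids fmod, whose symbol version in
  // this toolchain is newer than the runtime libm provides
  return v - L * std::floor(v / L);
}

static inline double min_image(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_seg_sector(double p0x, double p0y, double p1x,
                                   double p1y, double camx, double camy,
                                   double phi, double r, double theta) {
  Interval i = seg_sector(p0x - camx, p0y - camy, p1x - p0x, p1y - p0y, phi,
                          r, theta);
  if (i.empty()) return Rcpp::NumericVector(0);
  return Rcpp::NumericVector::create(i.lo, i.hi);
}

// [[Rcpp::export]]
Rcpp::List cpp_simulate(int n_animals, double W, double H,
                        Rcpp::NumericVector cam_x, Rcpp::NumericVector cam_y,
                        Rcpp::NumericVector cam_head, double r, double theta,
                        double speed, double duration_h, double dt_h,
                        double turning_sd, double bias_q, double bias_rest_h,
                        double t0_clock) {
  int n_cam = cam_x.size();
  int n_steps = (int)std::llround(duration_h / dt_h);
  double step_len = speed * dt_h;

  // spatial hash over cameras; cell edge must cover zone radius + one step,
  // so every camera detectable from a segment starting in a cell lies in the
  // cell's 3x3 neighbourhood. The neighbourhood camera lists are precomputed
  // per cell (CSR layout): the per-step cost for animals far from any camera
  // is a single lookup.
  double reach = r + step_len + 1e-9;
  int nxc = std::max(1, std::min((int)std::floor(W / reach), 256));
  int nyc = std::max(1, std::min((int)std::floor(H / reach), 256));
  double cw = W / nxc, ch = H / nyc;
  std::vector<std::vector<int>> nb_cams(nxc * nyc);
  for (int c = 0; c < n_cam; ++c) {
    int ix = std::min((int)(wrap0(cam_x[c], W) / cw), nxc - 1);
    int iy = std::min((int)(wrap0(cam_y[c], H) / ch), nyc - 1);
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        int j = ((iy + oy + nyc) % nyc) * nxc + (ix + ox + nxc) % nxc;
        bool seen = false;
        for (int k : nb_cams[j])
          if (k == c) { seen = true; break; }
        if (!seen) nb_cams[j].push_back(c);
      }
  }
  std::vector<int> cell_off(nxc * nyc + 1, 0);
  for (int j = 0; j < nxc * nyc; ++j)
    cell_off[j + 1] = cell_off[j] + (int)nb_cams[j].size();
  std::vector<int> cell_cam(cell_off[nxc * nyc]);
  for (int j = 0; j < nxc * nyc; ++j)
    std::copy(nb_cams[j].begin(), nb_cams[j].end(),
              cell_cam.begin() + cell_off[j]);

  std::vector<double> x(n_animals), y(n_animals), head(n_animals),
      vx(n_animals), vy(n_animals), rest_until(n_animals, -1.0);
  std::vector<int> inside(n_animals, -1);

  for (int i = 0; i < n_animals; ++i) {
    x[i] = R::unif_rand() * W;
    y[i] = R::unif_rand() * H;
    head[i] = R::unif_rand() * 2.0 * M_PI;
    vx[i] = step_len * std::cos(head[i]);
    vy[i] = step_len * std::sin(head[i]);
  }
  // initial containment: being born inside a zone is not an entry event
  for (int i = 0; i < n_animals; ++i) {
    int ix = std::min((int)(x[i] / cw), nxc - 1);
    int iy = std::min((int)(y[i] / ch), nyc - 1);
    int j = iy * nxc + ix;
    for (int k = cell_off[j]; k < cell_off[j + 1]; ++k) {
      int c = cell_cam[k];
      double px = min_image(x[i] - cam_x[c], W);
      double py = min_image(y[i] - cam_y[c], H);
      if (in_sector(px, py, cam_head[c], r, theta)) {
        inside[i] = c;
        break;
      }
    }
  }

  std::vector<int> ev_cam;
  std::vector<double> ev_time;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt_h;
    double clock = wrap0(t0_clock + t, 24.0);
    bool is_day = (clock >= 6.0 && clock < 18.0);

    for (int i = 0; i < n_animals; ++i) {
      if (rest_until[i] >= 0.0) {
        if (t < rest_until[i]) continue;  // resting at the shade tree
        rest_until[i] = -1.0;  // wake and resume the interrupted route
      }

      if (bias_q > 0.0 && is_day) {
        if (R::unif_rand() < bias_q * dt_h) {
          // divert to the nearest camera's shade tree: one entry event is
          // logged there and the animal pauses, then resumes its own route.
          // Pausing in place (rather than relocating the animal) keeps the
          // night-time spatial distribution uniform: a literal relocation
          // truncates the natural path and casts an encounter "shadow" of
          // several hours that depresses night rates well after 18:00.
          int best = -1;
          double bestd = 0.0;
          for (int c = 0; c < n_cam; ++c) {
            double px = min_image(x[i] - cam_x[c], W);
            double py = min_image(y[i] - cam_y[c], H);
            double d2 = px * px + py * py;
            if (best < 0 || d2 < bestd) {
              best = c;
              bestd = d2;
            }
          }
          if (best >= 0) {
            ev_cam.push_back(best);
            ev_time.push_back(t);
            rest_until[i] = t + bias_rest_h;
            continue;
          }
        }
      }

      if (turning_sd > 0.0) {
        head[i] += R::norm_rand() * turning_sd;
        vx[i] = step_len * std::cos(head[i]);
        vy[i] = step_len * std::sin(head[i]);
      }
      double p0x = x[i], p0y = y[i];
      double dx = vx[i], dy = vy[i];
      x[i] = wrap0(p0x + dx, W);
      y[i] = wrap0(p0y + dy, H);

      int ix = std::min((int)(p0x / cw), nxc - 1);
      int iy = std::min((int)(p0y / ch), nyc - 1);
      int j = iy * nxc + ix;
      for (int k = cell_off[j]; k < cell_off[j + 1]; ++k) {
        int c = cell_cam[k];
        double px = min_image(p0x - cam_x[c], W);
        double py = min_image(p0y - cam_y[c], H);
        bool in1 = in_sector(px + dx, py + dy, cam_head[c], r, theta);
        if (inside[i] == c) {
          if (!in1) inside[i] = -1;
          continue;
        }
        Interval iv = seg_sector(px, py, dx, dy, cam_head[c], r, theta);
        if (iv.empty()) continue;
        bool in0 = (iv.lo <= 1e-12);
        if (!in0) {
          ev_cam.push_back(c);
          ev_time.push_back(t + iv.lo * dt_h);
        }
        if (in1) inside[i] = c;
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("camera") = Rcpp::IntegerVector(ev_cam.begin(), ev_cam.end()),
      Rcpp::Named("time_h") = Rcpp::NumericVector(ev_time.begin(), ev_time.end()));
}
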