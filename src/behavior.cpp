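// Schooling / feeding behavior core.
//
// All positions are metres, velocities m/s, fork length (FL) centimetres,
// body mass grams.  The per-step loop is O(n^2) in the number of fish and
// O(n_fish * n_pellets) for encounter detection, which is why it lives in
// C++: one behavioral day is 2400 steps at dt = 0.05 s.
//
// Randomness goes through R's RNG (unif_rand) so set.seed() in R makes a
// whole behavioral day bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static inline double nrm3(double x, double y, double z) {
  return std::sqrt(x * x + y * y + z * z);
}

// Uniform draw on [-1, 1]^3, normalized; all-zero draws are redrawn.
static void rand_unit(double &x, double &y, double &z) {
  do {
    x = R::unif_rand() * 2.0 - 1.0;
    y = R::unif_rand() * 2.0 - 1.0;
    z = R::unif_rand() * 2.0 - 1.0;
  } while (x == 0.0 && y == 0.0 && z == 0.0);
  double s = nrm3(x, y, z);
  x /= s; y /= s; z /= s;
}

// Is point (tx,ty,tz) visible from a fish at (sx,sy,sz) moving with
// velocity (vx,vy,vz)?  Visible = inside the FOV sphere of radius fov_r
// and not inside the backward "dead space" cone of half-angle
// acos(cos_dead) about -v.  A stationary fish has no dead space.
static bool visible_from(double sx, double sy, double sz,
                         double vx, double vy, double vz,
                         double tx, double ty, double tz,
                         double fov_r, double cos_dead) {
  double dx = tx - sx, dy = ty - sy, dz = tz - sz;
  double d = nrm3(dx, dy, dz);
  if (d > fov_r) return false;
  if (d == 0.0) return true;
  double sp = nrm3(vx, vy, vz);
  if (sp == 0.0) return true;
  double cosang = -(dx * vx + dy * vy + dz * vz) / (d * sp);
  return cosang <= cos_dead; // strictly inside the cone -> hidden
}

// [[Rcpp::export(name = ".cpp_neighbors_in_fov")]]
IntegerVector cpp_neighbors_in_fov(int i, NumericMatrix pos, NumericMatrix vel,
                                   NumericVector fl_cm, double fov_mult,
                                   double dead_half_deg) {
  int n = pos.nrow();
  if (i < 1 || i > n) stop("agent index out of range");
  int a = i - 1;
  double fov_r = fov_mult * fl_cm[a] / 100.0;
  double cos_dead = std::cos(dead_half_deg * M_PI / 180.0);
  std::vector<int> out;
  for (int j = 0; j < n; ++j) {
    if (j == a) continue;
    if (visible_from(pos(a, 0), pos(a, 1), pos(a, 2),
                     vel(a, 0), vel(a, 1), vel(a, 2),
                     pos(j, 0), pos(j, 1), pos(j, 2), fov_r, cos_dead))
      out.push_back(j + 1);
  }
  return wrap(out);
}

// Closest of: radial projection on the wall, floor (z=0), surface (z=depth).
static void nearest_boundary(double x, double y, double z,
                             double R, double depth,
                             double &bx, double &by, double &bz) {
  double r = std::sqrt(x * x + y * y);
  double ux, uy;
  if (r > 0.0) { ux = x / r; uy = y / r; }
  else { // on the axis: wall direction undefined, pick a random azimuth
    double th = R::unif_rand() * 2.0 * M_PI;
    ux = std::cos(th); uy = std::sin(th);
  }
  double dwall = R - r, dfloor = z, dsurf = depth - z;
  if (dwall <= dfloor && dwall <= dsurf) { bx = ux * R; by = uy * R; bz = z; }
  else if (dfloor <= dsurf) { bx = x; by = y; bz = 0.0; }
  else { bx = x; by = y; bz = depth; }
}

// [[Rcpp::export(name = ".cpp_nearest_boundary_point")]]
NumericVector cpp_nearest_boundary_point(NumericVector p, double radius,
                                         double depth) {
  double bx, by, bz;
  nearest_boundary(p[0], p[1], p[2], radius, depth, bx, by, bz);
  return NumericVector::create(bx, by, bz);
}

static inline void cap_vel(double &vx, double &vy, double &vz, double vmax) {
  double s = nrm3(vx, vy, vz);
  if (s > vmax && s > 0.0) {
    double f = vmax / s;
    vx *= f; vy *= f; vz *= f;
  }
}

// [[Rcpp::export(name = ".cpp_cap_velocity")]]
NumericVector cpp_cap_velocity(NumericVector v, double tl_cm, double c_maxvel) {
  double vx = v[0], vy = v[1], vz = v[2];
  cap_vel(vx, vy, vz, c_maxvel * tl_cm / 100.0);
  return NumericVector::create(vx, vy, vz);
}

// Project a position that left the tank back to 1 mm inside and zero the
// outward velocity component.
static inline void contain(double &x, double &y, double &z,
                           double &vx, double &vy, double &vz,
                           double R, double depth) {
  const double m = 1e-3;
  double r = std::sqrt(x * x + y * y);
  if (r > R - m) {
    double ux = 1.0, uy = 0.0;
    if (r > 0.0) { ux = x / r; uy = y / r; }
    x = ux * (R - m); y = uy * (R - m);
    double vr = vx * ux + vy * uy;
    if (vr > 0.0) { vx -= vr * ux; vy -= vr * uy; }
  }
  if (z < m)        { z = m;         if (vz < 0.0) vz = 0.0; }
  if (z > depth - m) { z = depth - m; if (vz > 0.0) vz = 0.0; }
}

// [[Rcpp::export(name = ".cpp_step_kinematics")]]
List cpp_step_kinematics(NumericVector p, NumericVector v, NumericVector F,
                         double mass_g, double dt, double tl_cm,
                         double c_maxvel, double radius, double depth) {
  double vx = v[0] + F[0] / mass_g * dt;
  double vy = v[1] + F[1] / mass_g * dt;
  double vz = v[2] + F[2] / mass_g * dt;
  cap_vel(vx, vy, vz, c_maxvel * tl_cm / 100.0);
  double x = p[0] + vx * dt, y = p[1] + vy * dt, z = p[2] + vz * dt;
  contain(x, y, z, vx, vy, vz, radius, depth);
  return List::create(_["position"] = NumericVector::create(x, y, z),
                      _["velocity"] = NumericVector::create(vx, vy, vz));
}

// Resolve pellet-fish encounters.  Pellets are scanned in id order; each
// active pellet within capture_mult * FL of an eligible fish (one whose
// intake can still grow by a whole pellet without crossing S_max) is
// credited to the nearest such fish, ties to the lower fish id, and
// deactivated.  Returns the number consumed in this call.
static int do_encounters(const std::vector<double> &fx,
                         const std::vector<double> &fy,
                         const std::vector<double> &fz,
                         const std::vector<double> &fl_m,
                         std::vector<double> &intake, std::vector<int> &nf,
                         const std::vector<double> &smax,
                         std::vector<double> &px, std::vector<double> &py,
                         std::vector<double> &pz, std::vector<char> &active,
                         double capture_mult, double w_f) {
  int consumed = 0;
  int n = (int)fx.size(), np = (int)px.size();
  const double eps = 1e-12;
  for (int p = 0; p < np; ++p) {
    if (!active[p]) continue;
    int best = -1;
    double bestd = 0.0;
    for (int a = 0; a < n; ++a) {
      if (intake[a] + w_f > smax[a] + eps) continue;
      double d = nrm3(px[p] - fx[a], py[p] - fy[a], pz[p] - fz[a]);
      if (d <= capture_mult * fl_m[a]) {
        if (best < 0 || d < bestd) { best = a; bestd = d; }
      }
    }
    if (best >= 0) {
      active[p] = 0;
      nf[best] += 1;
      intake[best] += w_f;
      ++consumed;
    }
  }
  return consumed;
}

// [[Rcpp::export(name = ".cpp_detect_encounters")]]
List cpp_detect_encounters(NumericMatrix pos, NumericVector fl_cm,
                           NumericVector intake_g, NumericVector smax_g,
                           IntegerVector nf, NumericMatrix pellets,
                           LogicalVector active, double capture_mult,
                           double w_f) {
  int n = pos.nrow(), np = pellets.nrow();
  std::vector<double> fx(n), fy(n), fz(n), fl_m(n), in(n), sm(n);
  std::vector<int> nfc(n);
  for (int a = 0; a < n; ++a) {
    fx[a] = pos(a, 0); fy[a] = pos(a, 1); fz[a] = pos(a, 2);
    fl_m[a] = fl_cm[a] / 100.0;
    in[a] = intake_g[a]; sm[a] = smax_g[a]; nfc[a] = nf[a];
  }
  std::vector<double> px(np), py(np), pz(np);
  std::vector<char> act(np);
  for (int p = 0; p < np; ++p) {
    px[p] = pellets(p, 0); py[p] = pellets(p, 1); pz[p] = pellets(p, 2);
    act[p] = active[p] ? 1 : 0;
  }
  int consumed = do_encounters(fx, fy, fz, fl_m, in, nfc, sm,
                               px, py, pz, act, capture_mult, w_f);
  LogicalVector act_out(np);
  for (int p = 0; p < np; ++p) act_out[p] = act[p] != 0;
  return List::create(_["nf"] = wrap(nfc), _["intake_g"] = wrap(in),
                      _["active"] = act_out, _["consumed"] = consumed);
}

// One full behavioral day: steps all fish at dt for behavior_duration
// seconds, releases floor(total_feed_g / pellet_w_g) pellets at the
// surface at feed_drop_time, sinks pellets, resolves encounters, and
// returns per-fish pellet counts plus bookkeeping diagnostics.
// [[Rcpp::export(name = ".cpp_behavior_day")]]
List cpp_behavior_day(NumericMatrix pos, NumericMatrix vel,
                      NumericVector mass_g, NumericVector fl_cm,
                      double total_feed_g, double pellet_w_g, List par) {
  int n = pos.nrow();
  const double w_sep  = par["w_separation"],  w_coh = par["w_cohesion"];
  const double w_ali  = par["w_alignment"],   w_bnd = par["w_bound"];
  const double w_ine  = par["w_inertia"],     w_rnd = par["w_random"];
  const double w_feed_feeding  = par["w_feed_feeding"];
  const double w_feed_standard = par["w_feed_standard"];
  const double c_std  = par["c_maxvel_standard"];
  const double c_feed = par["c_maxvel_feeding"];
  const double dt = par["dt"];
  const double fov_mult = par["fov_radius_multiplier"];
  const double dead_deg = par["dead_space_half_angle"];
  const double capture_mult = par["capture_radius_multiplier"];
  const double sink = par["pellet_sink_speed"];
  const double duration = par["behavior_duration"];
  const double drop_time = par["feed_drop_time"];
  const double tl_over_fl = par["tl_over_fl"];
  const double feed_area_r = par["feed_area_radius"];
  const double R = par["tank_radius"], depth = par["tank_depth"];
  const double cos_dead = std::cos(dead_deg * M_PI / 180.0);

  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fl_m(n), fov_r(n), vmax_std(n), vmax_feed(n), smax(n);
  std::vector<double> intake(n, 0.0);
  std::vector<int> nf(n, 0);
  for (int a = 0; a < n; ++a) {
    x[a] = pos(a, 0); y[a] = pos(a, 1); z[a] = pos(a, 2);
    vx[a] = vel(a, 0); vy[a] = vel(a, 1); vz[a] = vel(a, 2);
    fl_m[a] = fl_cm[a] / 100.0;
    fov_r[a] = fov_mult * fl_m[a];
    double tl_m = tl_over_fl * fl_m[a];
    vmax_std[a] = c_std * tl_m;
    vmax_feed[a] = c_feed * tl_m;
    smax[a] = 0.04 * mass_g[a];
  }

  // tiny epsilon so an exact multiple of the pellet weight is not lost
  // to floating-point division (e.g. 15.264 g / 0.072 g = 212 pellets)
  int n_release = (total_feed_g > 0.0 && pellet_w_g > 0.0)
    ? (int)std::floor(total_feed_g / pellet_w_g + 1e-9) : 0;
  std::vector<double> px, py, pz;
  std::vector<char> active;
  bool released = false;
  int n_active = 0, consumed = 0, expired = 0;

  int nsteps = (int)std::lround(duration / dt);
  std::vector<double> Fx(n), Fy(n), Fz(n);
  std::vector<char> feeding(n, 0);
  double max_speed_excess = R_NegInf, max_intake_excess = R_NegInf;
  double max_contain_excess = R_NegInf;

  for (int s = 0; s < nsteps; ++s) {
    double t = s * dt;
    if (!released && t >= drop_time - 1e-9) {
      released = true;
      px.resize(n_release); py.resize(n_release); pz.resize(n_release);
      active.assign(n_release, 1);
      for (int p = 0; p < n_release; ++p) {
        double r = feed_area_r * std::sqrt(R::unif_rand());
        double th = R::unif_rand() * 2.0 * M_PI;
        px[p] = r * std::cos(th); py[p] = r * std::sin(th); pz[p] = depth;
      }
      n_active = n_release;
    }

    // behavioral mode for this step
    for (int a = 0; a < n; ++a)
      feeding[a] = (n_active > 0 && intake[a] < smax[a]) ? 1 : 0;

    // forces from the state at time t (synchronous update)
    for (int a = 0; a < n; ++a) {
      double fxx = 0.0, fyy = 0.0, fzz = 0.0;
      int m = 0, nearest = -1;
      double neard = 0.0, sx = 0.0, sy = 0.0, sz = 0.0;
      double svx = 0.0, svy = 0.0, svz = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == a) continue;
        if (!visible_from(x[a], y[a], z[a], vx[a], vy[a], vz[a],
                          x[j], y[j], z[j], fov_r[a], cos_dead)) continue;
        double d = nrm3(x[j] - x[a], y[j] - y[a], z[j] - z[a]);
        if (nearest < 0 || d < neard) { nearest = j; neard = d; }
        sx += x[j]; sy += y[j]; sz += z[j];
        svx += vx[j]; svy += vy[j]; svz += vz[j];
        ++m;
      }
      if (m > 0) {
        // separation: away from the nearest visible neighbor
        double dx = x[a] - x[nearest], dy = y[a] - y[nearest],
               dz = z[a] - z[nearest];
        double d = nrm3(dx, dy, dz);
        if (d == 0.0) rand_unit(dx, dy, dz);
        else { dx /= d; dy /= d; dz /= d; }
        fxx += w_sep * dx; fyy += w_sep * dy; fzz += w_sep * dz;
        // cohesion: toward the centroid of visible neighbors
        double cx = sx / m - x[a], cy = sy / m - y[a], cz = sz / m - z[a];
        double cd = nrm3(cx, cy, cz);
        if (cd > 0.0) {
          fxx += w_coh * cx / cd; fyy += w_coh * cy / cd;
          fzz += w_coh * cz / cd;
        }
        // alignment: toward the mean neighbor velocity
        double axv = svx / m - vx[a], ayv = svy / m - vy[a],
               azv = svz / m - vz[a];
        double ad = nrm3(axv, ayv, azv);
        if (ad > 0.0) {
          fxx += w_ali * axv / ad; fyy += w_ali * ayv / ad;
          fzz += w_ali * azv / ad;
        }
      }
      // boundary avoidance, gated on the FOV sphere
      double bx, by, bz;
      nearest_boundary(x[a], y[a], z[a], R, depth, bx, by, bz);
      double bd = nrm3(x[a] - bx, y[a] - by, z[a] - bz);
      if (bd <= fov_r[a] && bd > 0.0) {
        fxx += w_bnd * (x[a] - bx) / bd;
        fyy += w_bnd * (y[a] - by) / bd;
        fzz += w_bnd * (z[a] - bz) / bd;
      }
      // inertia
      double sp = nrm3(vx[a], vy[a], vz[a]);
      if (sp > 0.0) {
        fxx += w_ine * vx[a] / sp; fyy += w_ine * vy[a] / sp;
        fzz += w_ine * vz[a] / sp;
      }
      // approach feed: nearest active pellet in the FOV
      double w_feed = feeding[a] ? w_feed_feeding : w_feed_standard;
      if (w_feed != 0.0 && n_active > 0) {
        int bestp = -1; double bestd = 0.0;
        for (int p = 0; p < (int)px.size(); ++p) {
          if (!active[p]) continue;
          if (!visible_from(x[a], y[a], z[a], vx[a], vy[a], vz[a],
                            px[p], py[p], pz[p], fov_r[a], cos_dead))
            continue;
          double d = nrm3(px[p] - x[a], py[p] - y[a], pz[p] - z[a]);
          if (bestp < 0 || d < bestd) { bestp = p; bestd = d; }
        }
        if (bestp >= 0 && bestd > 0.0) {
          fxx += w_feed * (px[bestp] - x[a]) / bestd;
          fyy += w_feed * (py[bestp] - y[a]) / bestd;
          fzz += w_feed * (pz[bestp] - z[a]) / bestd;
        }
      }
      // random walk
      double rx, ry, rz;
      rand_unit(rx, ry, rz);
      fxx += w_rnd * rx; fyy += w_rnd * ry; fzz += w_rnd * rz;
      Fx[a] = fxx; Fy[a] = fyy; Fz[a] = fzz;
    }

    // kinematic update (symplectic Euler: v then x), cap, contain
    for (int a = 0; a < n; ++a) {
      vx[a] += Fx[a] / mass_g[a] * dt;
      vy[a] += Fy[a] / mass_g[a] * dt;
      vz[a] += Fz[a] / mass_g[a] * dt;
      double vmax = feeding[a] ? vmax_feed[a] : vmax_std[a];
      cap_vel(vx[a], vy[a], vz[a], vmax);
      x[a] += vx[a] * dt; y[a] += vy[a] * dt; z[a] += vz[a] * dt;
      contain(x[a], y[a], z[a], vx[a], vy[a], vz[a], R, depth);
      double exc = nrm3(vx[a], vy[a], vz[a]) - vmax;
      if (exc > max_speed_excess) max_speed_excess = exc;
      double rr = std::sqrt(x[a] * x[a] + y[a] * y[a]) - R;
      if (rr > max_contain_excess) max_contain_excess = rr;
      double zz = std::max(z[a] - depth, -z[a]);
      if (zz > max_contain_excess) max_contain_excess = zz;
    }

    // pellets sink; those reaching the floor expire
    if (n_active > 0) {
      for (int p = 0; p < (int)px.size(); ++p) {
        if (!active[p]) continue;
        pz[p] -= sink * dt;
        if (pz[p] <= 0.0) { active[p] = 0; ++expired; --n_active; }
      }
    }

    // encounters
    if (n_active > 0) {
      int c = do_encounters(x, y, z, fl_m, intake, nf, smax,
                            px, py, pz, active, capture_mult, pellet_w_g);
      consumed += c;
      n_active -= c;
      for (int a = 0; a < n; ++a) {
        double exc = intake[a] - smax[a];
        if (exc > max_intake_excess) max_intake_excess = exc;
      }
    }
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int a = 0; a < n; ++a) {
    pos_out(a, 0) = x[a]; pos_out(a, 1) = y[a]; pos_out(a, 2) = z[a];
    vel_out(a, 0) = vx[a]; vel_out(a, 1) = vy[a]; vel_out(a, 2) = vz[a];
  }
  return List::create(
    _["nf"] = wrap(nf), _["intake_g"] = wrap(intake),
    _["position"] = pos_out, _["velocity"] = vel_out,
    _["released"] = n_release, _["consumed"] = consumed,
    _["expired"] = expired, _["remaining"] = n_active,
    _["max_speed_excess"] = max_speed_excess,
    _["max_intake_excess"] = max_intake_excess,
    _["max_containment_excess"] = max_contain_excess);
}
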