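#include <Rcpp.h>
#include <cmath>
#include <deque>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// planar segment geometry
// ---------------------------------------------------------------------------

static inline double point_seg_dist(double px, double py,
                                    double ax, double ay,
                                    double bx, double by) {
  double ux = bx - ax, uy = by - ay;
  double len2 = ux * ux + uy * uy;
  if (len2 <= 1e-24) {
    double dx = px - ax, dy = py - ay;
    return std::sqrt(dx * dx + dy * dy);
  }
  double t = ((px - ax) * ux + (py - ay) * uy) / len2;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  double dx = px - (ax + t * ux), dy = py - (ay + t * uy);
  return std::sqrt(dx * dx + dy * dy);
}

// minimum distance between segments P1P2 and Q1Q2 (clamped parametric form)
static double seg_seg_dist(double p1x, double p1y, double p2x, double p2y,
                           double q1x, double q1y, double q2x, double q2y) {
  double ux = p2x - p1x, uy = p2y - p1y;
  double vx = q2x - q1x, vy = q2y - q1y;
  double a = ux * ux + uy * uy;
  double c = vx * vx + vy * vy;
  if (a <= 1e-24 && c <= 1e-24) {
    double dx = p1x - q1x, dy = p1y - q1y;
    return std::sqrt(dx * dx + dy * dy);
  }
  if (a <= 1e-24) return point_seg_dist(p1x, p1y, q1x, q1y, q2x, q2y);
  if (c <= 1e-24) return point_seg_dist(q1x, q1y, p1x, p1y, p2x, p2y);

  double wx = p1x - q1x, wy = p1y - q1y;
  double b = ux * vx + uy * vy;
  double d = ux * wx + uy * wy;
  double e = vx * wx + vy * wy;
  double D = a * c - b * b;
  double s, t;
  if (D <= 1e-12 * a * c) {
    // near-parallel: fix s = 0, then clamp both ways via endpoint projections
    double d1 = point_seg_dist(p1x, p1y, q1x, q1y, q2x, q2y);
    double d2 = point_seg_dist(p2x, p2y, q1x, q1y, q2x, q2y);
    double d3 = point_seg_dist(q1x, q1y, p1x, p1y, p2x, p2y);
    double d4 = point_seg_dist(q2x, q2y, p1x, p1y, p2x, p2y);
    double m = d1;
    if (d2 < m) m = d2;
    if (d3 < m) m = d3;
    if (d4 < m) m = d4;
    return m;
  }
  s = (b * e - c * d) / D;
  t = (a * e - b * d) / D;
  if (s < 0.0) s = 0.0; else if (s > 1.0) s = 1.0;
  // re-solve t for clamped s, then clamp and re-solve s
  t = (b * s + e) / c;
  if (t < 0.0) { t = 0.0; s = -d / a; }
  else if (t > 1.0) { t = 1.0; s = (b - d) / a; }
  if (s < 0.0) s = 0.0; else if (s > 1.0) s = 1.0;
  double dx = (p1x + s * ux) - (q1x + t * vx);
  double dy = (p1y + s * uy) - (q1y + t * vy);
  return std::sqrt(dx * dx + dy * dy);
}

// Minimum distance per frame between two 2-segment body polylines
// (nose -> centre -> tail base). A, B: n x 6 matrices with columns
// nose_x, nose_y, center_x, center_y, tail_x, tail_y.
// [[Rcpp::export]]
NumericVector polyline_pair_dist_cpp(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow();
  if (B.nrow() != n) stop("pose matrices must have equal row counts");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double d = R_PosInf;
    // segments of A: (0,1)-(2,3) and (2,3)-(4,5); same for B
    for (int sa = 0; sa < 2; ++sa) {
      int ja = sa * 2;
      for (int sb = 0; sb < 2; ++sb) {
        int jb = sb * 2;
        double dd = seg_seg_dist(A(i, ja), A(i, ja + 1), A(i, ja + 2), A(i, ja + 3),
                                 B(i, jb), B(i, jb + 1), B(i, jb + 2), B(i, jb + 3));
        if (dd < d) d = dd;
      }
    }
    out[i] = d;
  }
  return out;
}

// ---------------------------------------------------------------------------
// agent-based cage stepper
// ---------------------------------------------------------------------------

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// Advance 4 (or n) correlated-random-walk agents with reflective walls,
// soft mutual avoidance, and scheduled social episodes during which the
// initiator approaches a body point of its target and holds contact.
//
// Pre-drawn per-mouse randomness (heading increments, per-frame free speed,
// elongation jitter) comes in as n_frames x n_mice matrices so that each
// mouse consumes its own reproducible substream.
//
// Episode types: 0 nose-nose, 1 nose-anogenital, 2 side-side.
// Returns pose arrays and the realized episode table (frames at which body
// contact was actually achieved / released).
// [[Rcpp::export]]
List sim_core_cpp(int n_frames, int n_mice, double dt,
                  double lo, double hi,
                  NumericMatrix x0, NumericVector heading0,
                  NumericMatrix dheading, NumericMatrix speed,
                  NumericMatrix elong,
                  double nose_off, double tail_off,
                  double avoid_radius, double avoid_gain,
                  IntegerVector ep_initiator, IntegerVector ep_target,
                  IntegerVector ep_type, IntegerVector ep_start_frame,
                  NumericVector ep_dur_frames,
                  double contact_reach, double approach_speed,
                  double max_step, int timeout_frames,
                  double gt_dist, int depart_frames,
                  int queue_wait_frames) {
  const int FREE = 0, APPROACH = 1, HOLD = 2, DEPART = 3;
  int n_ep = ep_initiator.size();

  NumericMatrix cx(n_frames, n_mice), cy(n_frames, n_mice);
  NumericMatrix nx(n_frames, n_mice), ny(n_frames, n_mice);
  NumericMatrix tx(n_frames, n_mice), ty(n_frames, n_mice);

  std::vector<double> px(n_mice), py(n_mice), hd(n_mice);
  std::vector<double> ox(n_mice), oy(n_mice), oh(n_mice); // frame-start state
  std::vector<int> mode(n_mice, FREE), my_ep(n_mice, -1);
  std::vector<int> depart_until(n_mice, -1);
  std::vector<std::deque<int> > queued(n_mice);
  std::vector<int> ep_contact_frame(n_ep, -1), ep_end_frame(n_ep, -1);
  // ground-truth bounds: first/last frame with body distance <= gt_dist
  std::vector<int> ep_first_le(n_ep, -1), ep_last_le(n_ep, -1);
  std::vector<int> ep_state(n_ep, 0); // 0 pending, 1 active, 2 done, 3 dropped
  // pairwise episode exclusion (no avoidance between engaged partners)
  std::vector<char> engaged(n_mice * n_mice, 0);

  for (int i = 0; i < n_mice; ++i) {
    px[i] = x0(i, 0);
    py[i] = x0(i, 1);
    hd[i] = heading0[i];
  }

  int next_ep = 0;
  for (int f = 0; f < n_frames; ++f) {
    // queue episodes whose time has come; a busy initiator serves its
    // queue when free again, dropping episodes that waited too long
    while (next_ep < n_ep && ep_start_frame[next_ep] <= f) {
      queued[ep_initiator[next_ep]].push_back(next_ep);
      ++next_ep;
    }
    for (int i = 0; i < n_mice; ++i) {
      if (mode[i] != FREE) continue;
      while (!queued[i].empty()) {
        int e = queued[i].front();
        queued[i].pop_front();
        if (f - ep_start_frame[e] > queue_wait_frames) {
          ep_state[e] = 3; // waited too long: dropped
          continue;
        }
        mode[i] = APPROACH;
        my_ep[i] = e;
        ep_state[e] = 1;
        int j = ep_target[e];
        engaged[i * n_mice + j] = engaged[j * n_mice + i] = 1;
        break;
      }
    }
    // all within-frame decisions read start-of-frame positions so that
    // the result does not depend on mouse iteration order
    for (int i = 0; i < n_mice; ++i) {
      ox[i] = px[i]; oy[i] = py[i]; oh[i] = hd[i];
    }
    // engagement flags released this frame are cleared only after all
    // mice have moved, keeping the update order-independent
    std::vector<int> clear_i, clear_j;

    for (int i = 0; i < n_mice; ++i) {
      double stepx = 0.0, stepy = 0.0;
      if (mode[i] == DEPART) {
        int e = my_ep[i];
        int j = ep_target[e];
        double h = std::atan2(oy[i] - oy[j], ox[i] - ox[j]);
        hd[i] = h;
        stepx = approach_speed * dt * std::cos(h);
        stepy = approach_speed * dt * std::sin(h);
        if (f >= depart_until[i]) {
          mode[i] = FREE;
          my_ep[i] = -1;
        }
      } else if (mode[i] == FREE) {
        double h = wrap_pi(hd[i] + dheading(f, i));
        // soft avoidance of the nearest non-engaged cage-mate
        double dmin = R_PosInf;
        int jmin = -1;
        for (int j = 0; j < n_mice; ++j) {
          if (j == i || engaged[i * n_mice + j]) continue;
          double dx = ox[i] - ox[j], dy = oy[i] - oy[j];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d < dmin) { dmin = d; jmin = j; }
        }
        double sp = speed(f, i);
        if (jmin >= 0 && dmin < avoid_radius) {
          double away = std::atan2(oy[i] - oy[jmin], ox[i] - ox[jmin]);
          h = wrap_pi(h + avoid_gain * wrap_pi(away - h));
          // displaced mice keep moving until clear of the neighbour
          double evade = 0.5 * approach_speed;
          if (sp < evade) sp = evade;
        }
        hd[i] = h;
        stepx = sp * dt * std::cos(h);
        stepy = sp * dt * std::sin(h);
      } else {
        int e = my_ep[i];
        int j = ep_target[e];
        // body point on the target depending on episode type
        double uxj = std::cos(oh[j]), uyj = std::sin(oh[j]);
        double gx, gy;
        if (ep_type[e] == 0) {            // target nose
          gx = ox[j] + nose_off * uxj; gy = oy[j] + nose_off * uyj;
        } else if (ep_type[e] == 1) {     // target tail base
          gx = ox[j] - tail_off * uxj; gy = oy[j] - tail_off * uyj;
        } else {                          // target flank (centre)
          gx = ox[j]; gy = oy[j];
        }
        // my own nose should reach the goal point
        double mynx = px[i] + nose_off * std::cos(hd[i]);
        double myny = py[i] + nose_off * std::sin(hd[i]);
        double dx = gx - mynx, dy = gy - myny;
        double d = std::sqrt(dx * dx + dy * dy);
        double h = (d > 1e-9) ? std::atan2(dy, dx) : hd[i];
        hd[i] = h;
        if (mode[i] == APPROACH) {
          if (d <= contact_reach) {
            mode[i] = HOLD;
            ep_contact_frame[e] = f;
          } else if (f - ep_start_frame[e] > timeout_frames) {
            // never caught the target: abandon
            ep_state[e] = 3;
            mode[i] = FREE;
            my_ep[i] = -1;
            clear_i.push_back(i); clear_j.push_back(j);
          }
        }
        if (mode[i] == HOLD &&
            f - ep_contact_frame[e] >= (int)ep_dur_frames[e]) {
          ep_state[e] = 2;
          ep_end_frame[e] = f;
          mode[i] = DEPART; // turn away so the pair separates promptly
          depart_until[i] = f + depart_frames;
          clear_i.push_back(i); clear_j.push_back(j);
        }
        if (mode[i] == APPROACH || mode[i] == HOLD) {
          double sp = (mode[i] == HOLD) ? std::min(approach_speed, d / dt)
                                        : approach_speed;
          stepx = sp * dt * std::cos(h);
          stepy = sp * dt * std::sin(h);
        } else if (mode[i] == DEPART) {
          double ha = std::atan2(oy[i] - oy[j], ox[i] - ox[j]);
          hd[i] = ha;
          stepx = approach_speed * dt * std::cos(ha);
          stepy = approach_speed * dt * std::sin(ha);
        } else {
          stepx = 0.0; stepy = 0.0;
        }
      }
      // cap displacement, move, reflect at walls
      double sl = std::sqrt(stepx * stepx + stepy * stepy);
      if (sl > max_step) { stepx *= max_step / sl; stepy *= max_step / sl; }
      double nxp = px[i] + stepx, nyp = py[i] + stepy;
      if (nxp < lo) { nxp = 2.0 * lo - nxp; hd[i] = wrap_pi(M_PI - hd[i]); }
      else if (nxp > hi) { nxp = 2.0 * hi - nxp; hd[i] = wrap_pi(M_PI - hd[i]); }
      if (nyp < lo) { nyp = 2.0 * lo - nyp; hd[i] = wrap_pi(-hd[i]); }
      else if (nyp > hi) { nyp = 2.0 * hi - nyp; hd[i] = wrap_pi(-hd[i]); }
      px[i] = nxp; py[i] = nyp;

      double el = elong(f, i);
      double ux = std::cos(hd[i]), uy = std::sin(hd[i]);
      cx(f, i) = px[i]; cy(f, i) = py[i];
      nx(f, i) = px[i] + nose_off * el * ux;
      ny(f, i) = py[i] + nose_off * el * uy;
      tx(f, i) = px[i] - tail_off * el * ux;
      ty(f, i) = py[i] - tail_off * el * uy;
    }
    for (size_t k = 0; k < clear_i.size(); ++k) {
      engaged[clear_i[k] * n_mice + clear_j[k]] = 0;
      engaged[clear_j[k] * n_mice + clear_i[k]] = 0;
    }
    // ground-truth bookkeeping: actual body-polyline distance of engaged
    // pairs against the annotation threshold
    for (int i = 0; i < n_mice; ++i) {
      int e = my_ep[i];
      if (e < 0 || ep_initiator[e] != i) continue;
      int j = ep_target[e];
      double dmin = R_PosInf;
      for (int sa = 0; sa < 2; ++sa) {
        double a1x = sa ? cx(f, i) : nx(f, i);
        double a1y = sa ? cy(f, i) : ny(f, i);
        double a2x = sa ? tx(f, i) : cx(f, i);
        double a2y = sa ? ty(f, i) : cy(f, i);
        for (int sb = 0; sb < 2; ++sb) {
          double b1x = sb ? cx(f, j) : nx(f, j);
          double b1y = sb ? cy(f, j) : ny(f, j);
          double b2x = sb ? tx(f, j) : cx(f, j);
          double b2y = sb ? ty(f, j) : cy(f, j);
          double dd = seg_seg_dist(a1x, a1y, a2x, a2y, b1x, b1y, b2x, b2y);
          if (dd < dmin) dmin = dd;
        }
      }
      if (dmin <= gt_dist) {
        if (ep_first_le[e] < 0) ep_first_le[e] = f;
        ep_last_le[e] = f;
      }
    }
  }
  // close out episodes still holding at session end
  for (int e = 0; e < n_ep; ++e) {
    if (ep_state[e] == 1 && ep_contact_frame[e] >= 0) {
      ep_state[e] = 2;
      ep_end_frame[e] = n_frames;
    }
  }
  return List::create(
    _["cx"] = cx, _["cy"] = cy, _["nx"] = nx, _["ny"] = ny,
    _["tx"] = tx, _["ty"] = ty,
    _["ep_state"] = IntegerVector(ep_state.begin(), ep_state.end()),
    _["ep_contact_frame"] = IntegerVector(ep_contact_frame.begin(), ep_contact_frame.end()),
    _["ep_end_frame"] = IntegerVector(ep_end_frame.begin(), ep_end_frame.end()),
    _["ep_first_le"] = IntegerVector(ep_first_le.begin(), ep_first_le.end()),
    _["ep_last_le"] = IntegerVector(ep_last_le.begin(), ep_last_le.end()));
}
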