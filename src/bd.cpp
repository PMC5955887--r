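#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) dynamics of two orientable point
// protomers in a periodic membrane plane.  State: positions x1, x2 (nm, in a
// periodic L x L box) and in-plane orientations th1, th2 (rad).  The
// interaction potential lives on the collective variables
//   d  = minimal-image |x2 - x1|
//   a1 = unsigned angle between protomer 1's orientation axis and the vector
//        to protomer 2 (in [0, pi])
//   a2 = same with the protomers swapped
// and is a sum of Gaussian wells plus an optional harmonic umbrella bias.
// Energies are in kT (reduced units); mobilities are D/kT = D.

static inline double wrap_box(double x, double L) {
  return x - L * std::floor(x / L);
}

// signed angular difference wrapped to (-pi, pi]
static inline double wrap_pi(double a) {
  a -= 2.0 * M_PI * std::round(a / (2.0 * M_PI));
  if (a <= -M_PI) a += 2.0 * M_PI;
  if (a > M_PI) a -= 2.0 * M_PI;
  return a;
}

struct CVState {
  double d, a1, a2;     // collective variables
  double s1, s2;        // sign(d alpha / d theta) for the two angles
  double ex, ey;        // unit vector x1 -> x2 (minimal image)
};

static CVState eval_cvs(double x1x, double x1y, double x2x, double x2y,
                        double th1, double th2, double L) {
  CVState s;
  double rx = x2x - x1x, ry = x2y - x1y;
  rx -= L * std::round(rx / L);
  ry -= L * std::round(ry / L);
  s.d = std::sqrt(rx * rx + ry * ry);
  double phi = std::atan2(ry, rx);          // azimuth of x1 -> x2
  double d1 = wrap_pi(th1 - phi);           // a1 = |d1|
  double d2 = wrap_pi(th2 - (phi + M_PI));  // a2 = |d2|
  s.a1 = std::fabs(d1);
  s.a2 = std::fabs(d2);
  s.s1 = (d1 >= 0.0) ? 1.0 : -1.0;
  s.s2 = (d2 >= 0.0) ? 1.0 : -1.0;
  if (s.d > 0.0) { s.ex = rx / s.d; s.ey = ry / s.d; }
  else { s.ex = 1.0; s.ey = 0.0; }
  return s;
}

// potential energy and its partial derivatives w.r.t. (d, a1, a2)
struct PotGrad { double U, dU_dd, dU_da1, dU_da2; };

static PotGrad well_potential(const CVState &s, const NumericMatrix &wells,
                              const NumericVector &wall) {
  PotGrad g; g.U = 0.0; g.dU_dd = 0.0; g.dU_da1 = 0.0; g.dU_da2 = 0.0;
  if (wall.size() == 3 && wall[0] > 0.0) {
    // exponential steric wall h * exp(-(d - c)/w): unbounded at short range
    double u = wall[0] * std::exp(-(s.d - wall[1]) / wall[2]);
    g.U += u;
    g.dU_dd += -u / wall[2];
  }
  for (int w = 0; w < wells.nrow(); ++w) {
    double dc = wells(w, 0), a1c = wells(w, 1), a2c = wells(w, 2);
    double depth = wells(w, 3), wd = wells(w, 4), wa = wells(w, 5);
    double ud = (s.d - dc) / wd;
    double u1 = (s.a1 - a1c) / wa;
    double u2 = (s.a2 - a2c) / wa;
    double e = -depth * std::exp(-0.5 * (ud * ud + u1 * u1 + u2 * u2));
    g.U += e;
    g.dU_dd  += -e * ud / wd;
    g.dU_da1 += -e * u1 / wa;
    g.dU_da2 += -e * u2 / wa;
  }
  return g;
}

static inline void add_bias(PotGrad &g, const CVState &s, double d0,
                            double a10, double a20, double kd, double ka) {
  g.U += 0.5 * kd * (s.d - d0) * (s.d - d0)
       + 0.5 * ka * ((s.a1 - a10) * (s.a1 - a10) +
                     (s.a2 - a20) * (s.a2 - a20));
  g.dU_dd  += kd * (s.d - d0);
  g.dU_da1 += ka * (s.a1 - a10);
  g.dU_da2 += ka * (s.a2 - a20);
}

// [[Rcpp::export(name = ".bd_simulate_cpp")]]
NumericMatrix bd_simulate_cpp(NumericMatrix wells, NumericVector wall,
                              double L, double D_trans, double D_rot,
                              int n_steps, double dt, int stride,
                              NumericVector bias, // length 0 or 5: d0,a10,a20,kd,ka
                              NumericVector start) { // length 0 or 6
  const bool biased = bias.size() == 5;
  double x1x, x1y, x2x, x2y, th1, th2;
  if (start.size() == 6) {
    x1x = start[0]; x1y = start[1]; x2x = start[2]; x2y = start[3];
    th1 = start[4]; th2 = start[5];
  } else {
    x1x = unif_rand() * L; x1y = unif_rand() * L;
    x2x = unif_rand() * L; x2y = unif_rand() * L;
    th1 = unif_rand() * 2.0 * M_PI; th2 = unif_rand() * 2.0 * M_PI;
  }
  const double sig_t = std::sqrt(2.0 * D_trans * dt);
  const double sig_r = std::sqrt(2.0 * D_rot * dt);
  const int n_frames = n_steps / stride;
  NumericMatrix out(n_frames, biased ? 5 : 4);
  int row = 0;
  for (int step = 1; step <= n_steps; ++step) {
    CVState s = eval_cvs(x1x, x1y, x2x, x2y, th1, th2, L);
    PotGrad g = well_potential(s, wells, wall);
    if (biased) add_bias(g, s, bias[0], bias[1], bias[2], bias[3], bias[4]);
    if (!std::isfinite(g.U) || !std::isfinite(g.dU_dd))
      stop("non-finite potential encountered (degenerate well parameters?)");
    // chain rule: r = x2 - x1; dd/dr = e; dphi/dr = (-ry, rx)/d^2 and
    // da1/dphi = -s1, da2/dphi = -s2 (a_i = |th_i - phi_i| with phi2 = phi+pi)
    double d_eff = std::max(s.d, 1e-8);
    double px = -s.ey / d_eff, py = s.ex / d_eff; // dphi/dr
    double gang = g.dU_da1 * (-s.s1) + g.dU_da2 * (-s.s2);
    double dU_drx = g.dU_dd * s.ex + gang * px;
    double dU_dry = g.dU_dd * s.ey + gang * py;
    // forces on positions (dU/dx1 = -dU/dr, dU/dx2 = +dU/dr)
    x1x += D_trans * dU_drx * dt + sig_t * norm_rand();
    x1y += D_trans * dU_dry * dt + sig_t * norm_rand();
    x2x += -D_trans * dU_drx * dt + sig_t * norm_rand();
    x2y += -D_trans * dU_dry * dt + sig_t * norm_rand();
    th1 += -D_rot * g.dU_da1 * s.s1 * dt + sig_r * norm_rand();
    th2 += -D_rot * g.dU_da2 * s.s2 * dt + sig_r * norm_rand();
    x1x = wrap_box(x1x, L); x1y = wrap_box(x1y, L);
    x2x = wrap_box(x2x, L); x2y = wrap_box(x2y, L);
    if (step % stride == 0) {
      CVState sr = eval_cvs(x1x, x1y, x2x, x2y, th1, th2, L);
      out(row, 0) = step * dt;
      out(row, 1) = sr.d;
      out(row, 2) = sr.a1;
      out(row, 3) = sr.a2;
      if (biased) {
        PotGrad gb; gb.U = 0; gb.dU_dd = 0; gb.dU_da1 = 0; gb.dU_da2 = 0;
        add_bias(gb, sr, bias[0], bias[1], bias[2], bias[3], bias[4]);
        out(row, 4) = gb.U;
      }
      ++row;
    }
  }
  return out;
}
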