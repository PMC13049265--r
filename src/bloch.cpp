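#include <Rcpp.h>
using namespace Rcpp;

// Hard-pulse Bloch integration: one rotation per RF raster sample about the
// effective field in the rotating frame. Relaxation-free (T1 = T2 = Inf).
//
// b1re/b1im : RF waveform in Hz (nutation frequency, gamma*B1/2pi)
// raster    : s per sample
// df        : per-position static offset in Hz (gradient*y + off-resonance)
// minit     : 3 x P initial magnetization (rows Mx, My, Mz)
//
// Convention: left-handed rotation about the effective field
// omega = 2*pi*(b1x, b1y, df), i.e. rotation angle -|omega|*dt, so that a
// real positive b1 tips +z towards +y with transverse phase 0 on resonance.
// [[Rcpp::export]]
NumericMatrix bloch_hard_pulse(NumericVector b1re, NumericVector b1im,
                               double raster, NumericVector df,
                               NumericMatrix minit) {
  const int S = b1re.size();
  const int P = df.size();
  if (minit.nrow() != 3 || minit.ncol() != P)
    stop("initial magnetization must be a 3 x P matrix");
  NumericMatrix M = clone(minit);
  const double twopi = 2.0 * M_PI;

  for (int s = 0; s < S; ++s) {
    const double wx = twopi * b1re[s];
    const double wy = twopi * b1im[s];
    for (int p = 0; p < P; ++p) {
      const double wz = twopi * df[p];
      const double w2 = wx * wx + wy * wy + wz * wz;
      if (w2 == 0.0) continue;
      const double wn = std::sqrt(w2);
      const double th = -wn * raster;
      const double ct = std::cos(th), st = std::sin(th);
      const double nx = wx / wn, ny = wy / wn, nz = wz / wn;
      const double mx = M(0, p), my = M(1, p), mz = M(2, p);
      const double dot = nx * mx + ny * my + nz * mz;
      const double cx = ny * mz - nz * my;
      const double cy = nz * mx - nx * mz;
      const double cz = nx * my - ny * mx;
      const double omc = 1.0 - ct;
      M(0, p) = mx * ct + cx * st + nx * dot * omc;
      M(1, p) = my * ct + cy * st + ny * dot * omc;
      M(2, p) = mz * ct + cz * st + nz * dot * omc;
    }
  }
  return M;
}
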