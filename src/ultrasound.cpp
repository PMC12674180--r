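// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Plane-wave point-target RF synthesis for one transmit.
// Geometry: elements on the x axis at z = 0; scatterers at (x, y, z) mm with
// z the depth. Transmit delay (z cos th + x sin th)/c, receive delay is the
// exact element-to-point distance over c (the y offset lengthens the path;
// there is no elevation weighting). Pulse: Gaussian-enveloped cosine at f0,
// truncated at +/- 4 sigma. Units inside: mm, us, MHz; c in mm/us.
// [[Rcpp::export(name = ".cpp_simulate_rf")]]
NumericMatrix cpp_simulate_rf(const arma::mat &pos, const arma::vec &amp,
                              const arma::vec &elem_x, double angle_rad,
                              double c_mm_us, double f0_mhz, double sigma_us,
                              double fs_mhz, double t0_us, int n_samples) {
  const int ns = pos.n_rows, ne = elem_x.n_elem;
  NumericMatrix rf(n_samples, ne);
  const double two_pi_f0 = 2.0 * M_PI * f0_mhz;
  const double half_support = 4.0 * sigma_us;
  const double inv2s2 = 1.0 / (2.0 * sigma_us * sigma_us);
  const double st = std::sin(angle_rad), ct = std::cos(angle_rad);
  for (int e = 0; e < ne; ++e) {
    double *col = &rf(0, e);
    double xe = elem_x[e];
    for (int s = 0; s < ns; ++s) {
      double x = pos(s, 0), y = pos(s, 1), z = pos(s, 2);
      double tau_tx = (z * ct + x * st) / c_mm_us;
      double dx = x - xe;
      double tau_rx = std::sqrt(dx * dx + y * y + z * z) / c_mm_us;
      double tau = tau_tx + tau_rx;
      int i0 = (int)std::ceil((tau - half_support - t0_us) * fs_mhz);
      int i1 = (int)std::floor((tau + half_support - t0_us) * fs_mhz);
      if (i0 < 0) i0 = 0;
      if (i1 >= n_samples) i1 = n_samples - 1;
      double a = amp[s];
      for (int i = i0; i <= i1; ++i) {
        double dt = t0_us + i / fs_mhz - tau;
        col[i] += a * std::exp(-dt * dt * inv2s2) * std::cos(two_pi_f0 * dt);
      }
    }
  }
  return rf;
}

// Delay-and-sum beamforming of baseband (IQ) channel data onto a pixel
// grid with a constant-F-number receive aperture (half-width z / (2 F#),
// never narrower than one element). Fractional delays by linear
// interpolation of the complex samples plus phase rotation at f0.
// [[Rcpp::export(name = ".cpp_das_iq")]]
List cpp_das_iq(const arma::mat &iq_re, const arma::mat &iq_im,
                const arma::vec &elem_x, double angle_rad, double c_mm_us,
                double f0_mhz, double fs_mhz, double t0_us,
                const arma::vec &px, const arma::vec &pz, double fnum,
                int apod) {
  const int nsamp = iq_re.n_rows, ne = elem_x.n_elem;
  const int nx = px.n_elem, nz = pz.n_elem;
  arma::mat out_re(nz, nx, arma::fill::zeros), out_im(nz, nx, arma::fill::zeros);
  const double st = std::sin(angle_rad), ct = std::cos(angle_rad);
  const double two_pi_f0 = 2.0 * M_PI * f0_mhz;
  // element pitch for "at least one element" fallback
  double pitch = ne > 1 ? std::abs(elem_x[1] - elem_x[0]) : 1.0;
  for (int jx = 0; jx < nx; ++jx) {
    double x = px[jx];
    for (int jz = 0; jz < nz; ++jz) {
      double z = pz[jz];
      double tau_tx = (z * ct + x * st) / c_mm_us;
      double half_ap = fnum > 0 ? z / (2.0 * fnum) : 1e30;
      if (half_ap < 0.51 * pitch) half_ap = 0.51 * pitch;
      double acc_re = 0.0, acc_im = 0.0;
      for (int e = 0; e < ne; ++e) {
        double dx = x - elem_x[e];
        if (std::abs(dx) > half_ap) continue;
        double wa = 1.0;
        if (apod == 1)  // Hann over the receive aperture
          wa = 0.5 + 0.5 * std::cos(M_PI * dx / half_ap);
        double tau = tau_tx + std::sqrt(dx * dx + z * z) / c_mm_us;
        double fi = (tau - t0_us) * fs_mhz;
        if (fi < 0 || fi > nsamp - 1) continue;
        int i0 = (int)fi;
        if (i0 >= nsamp - 1) i0 = nsamp - 2;
        double w = fi - i0;
        double sr = (1 - w) * iq_re(i0, e) + w * iq_re(i0 + 1, e);
        double si = (1 - w) * iq_im(i0, e) + w * iq_im(i0 + 1, e);
        // undo the baseband phase of the delayed echo
        double ph = two_pi_f0 * tau;
        double cp = std::cos(ph), sp = std::sin(ph);
        acc_re += wa * (sr * cp - si * sp);
        acc_im += wa * (sr * sp + si * cp);
      }
      out_re(jz, jx) = acc_re;
      out_im(jz, jx) = acc_im;
    }
  }
  return List::create(_["re"] = out_re, _["im"] = out_im);
}
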