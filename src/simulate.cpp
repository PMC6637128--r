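#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Spectral-domain OCT forward model.
//
// For the A-scan at lateral position (x_j, y_b), frame m, spectral sample k_i:
//
//   I_m(k_i) = E(k_i) * | 1 + sum_s c_s exp(i [2 k_i z_s + phi_s + dphi_{s,m}
//                                             + a2 (k_i-k0)^2 + a3 (k_i-k0)^3]) |^2
//
// with c_s = a_s T_s w(d_s), w a Gaussian lateral amplitude weight whose
// intensity FWHM is `fwhm_um`, T_s the vessel transmission folded into `amps`
// by the caller, phi_s a fixed scatterer phase and dphi_{s,m} the diffuser
// perturbation of frame m. The sample-arm dispersion phase is common to all
// scatterers, so it factors out of the sum as a unit phasor D(k_i).
//
// Scatterers must be sorted by x so each A-scan sees a contiguous window.
// Work is factored as U (K x n, per A-scan geometry phasors, computed once)
// times P (n x M diffuser phasors), so the per-frame cost is one complex
// matrix product instead of fresh trigonometry.
//
// [[Rcpp::export]]
NumericVector simulate_frames_cpp(const arma::vec& xs,
                                  const arma::vec& ys,
                                  const arma::vec& zs,
                                  const arma::vec& amps,
                                  const arma::vec& phi0,
                                  const arma::mat& dphi,
                                  const arma::vec& kvec,
                                  const arma::vec& env,
                                  const arma::vec& xpos,
                                  const arma::vec& ypos,
                                  double fwhm_um,
                                  double cutoff_um,
                                  double a2,
                                  double a3,
                                  double k0) {
  const arma::uword K = kvec.n_elem;
  const arma::uword A = xpos.n_elem;
  const arma::uword B = ypos.n_elem;
  const arma::uword M = dphi.n_cols;
  const arma::uword n_s = xs.n_elem;
  // amplitude-weight coefficient so that the intensity weight w^2 has the
  // requested FWHM: w = exp(-2 ln2 d^2 / FWHM^2)
  const double cc = 2.0 * std::log(2.0) / (fwhm_um * fwhm_um);
  const double cut2 = cutoff_um * cutoff_um;

  // dispersion phasor D(k)
  arma::cx_vec D(K);
  for (arma::uword i = 0; i < K; ++i) {
    double dk = kvec[i] - k0;
    double ph = a2 * dk * dk + a3 * dk * dk * dk;
    D[i] = std::complex<double>(std::cos(ph), std::sin(ph));
  }

  // diffuser phasors for every scatterer and frame
  arma::cx_mat P(n_s, M);
  for (arma::uword m = 0; m < M; ++m)
    for (arma::uword s = 0; s < n_s; ++s)
      P(s, m) = std::complex<double>(std::cos(dphi(s, m)), std::sin(dphi(s, m)));

  NumericVector out(static_cast<R_xlen_t>(K) * A * B * M);
  double* optr = REAL(out);

  for (arma::uword b = 0; b < B; ++b) {
    const double yb = ypos[b];
    // scatterers within the lateral cutoff of this B-scan plane
    arma::uvec sel = arma::find(arma::square(ys - yb) <= cut2);
    const arma::uword nb = sel.n_elem;
    arma::vec xs_b(nb), zs_b(nb), c_b(nb), p0_b(nb);
    for (arma::uword t = 0; t < nb; ++t) {
      arma::uword s = sel[t];
      double dy = ys[s] - yb;
      xs_b[t] = xs[s];
      zs_b[t] = zs[s];
      c_b[t] = amps[s] * std::exp(-cc * dy * dy);
      p0_b[t] = phi0[s];
    }
    arma::cx_mat P_b = P.rows(sel); // nb x M, preserves x-sorted order

    for (arma::uword j = 0; j < A; ++j) {
      Rcpp::checkUserInterrupt();
      const double xj = xpos[j];
      // contiguous x-window [lo, hi)
      const double* xb0 = xs_b.memptr();
      arma::uword lo = std::lower_bound(xb0, xb0 + nb, xj - cutoff_um) - xb0;
      arma::uword hi = std::upper_bound(xb0, xb0 + nb, xj + cutoff_um) - xb0;
      const arma::uword n = hi - lo;

      if (n == 0) {
        for (arma::uword m = 0; m < M; ++m) {
          double* o = optr + K * (j + A * (b + B * m));
          for (arma::uword i = 0; i < K; ++i) o[i] = env[i];
        }
        continue;
      }

      arma::cx_mat U(K, n);
      for (arma::uword t = 0; t < n; ++t) {
        const arma::uword s = lo + t;
        const double dx = xs_b[s] - xj;
        const double w = c_b[s] * std::exp(-cc * dx * dx);
        const double z2 = 2.0 * zs_b[s];
        const double p0 = p0_b[s];
        std::complex<double>* u = U.colptr(t);
        for (arma::uword i = 0; i < K; ++i) {
          const double ang = z2 * kvec[i] + p0;
          u[i] = std::complex<double>(w * std::cos(ang), w * std::sin(ang));
        }
      }

      arma::cx_mat F = U * P_b.rows(lo, hi - 1); // K x M

      for (arma::uword m = 0; m < M; ++m) {
        double* o = optr + K * (j + A * (b + B * m));
        const std::complex<double>* f = F.colptr(m);
        for (arma::uword i = 0; i < K; ++i) {
          const std::complex<double> fd = D[i] * f[i];
          o[i] = env[i] * (1.0 + 2.0 * fd.real() + std::norm(f[i]));
        }
      }
    }
  }

  out.attr("dim") = IntegerVector::create(static_cast<int>(K),
                                          static_cast<int>(A),
                                          static_cast<int>(B),
                                          static_cast<int>(M));
  return out;
}

// Explicit 6-neighbour Perona-Malik anisotropic diffusion with exponential
// conductance c(g) = exp(-(g/kappa)^2) and zero-flux boundaries. Fluxes are
// antisymmetric between voxel pairs, so the global mean is conserved to
// round-off and the scheme obeys an extremum principle for dt <= 1/6.
//
// [[Rcpp::export]]
NumericVector anisodiff3_cpp(NumericVector vol, int nz, int nx, int ny,
                             int n_iter, double kappa, double dt) {
  const R_xlen_t n = static_cast<R_xlen_t>(nz) * nx * ny;
  std::vector<double> v(vol.begin(), vol.end());
  std::vector<double> upd(n);
  const double ik2 = 1.0 / (kappa * kappa);
  const R_xlen_t sz = 1, sx = nz, sy = static_cast<R_xlen_t>(nz) * nx;

  auto flux = [&](double a, double b) {
    const double g = b - a;
    return std::exp(-g * g * ik2) * g;
  };

  for (int it = 0; it < n_iter; ++it) {
    std::fill(upd.begin(), upd.end(), 0.0);
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t base = sx * x + sy * y;
        for (int z = 0; z < nz; ++z) {
          const R_xlen_t i = base + z;
          const double vi = v[i];
          double acc = 0.0;
          if (z + 1 < nz) acc += flux(vi, v[i + sz]);
          if (z > 0)      acc -= flux(v[i - sz], vi);
          if (x + 1 < nx) acc += flux(vi, v[i + sx]);
          if (x > 0)      acc -= flux(v[i - sx], vi);
          if (y + 1 < ny) acc += flux(vi, v[i + sy]);
          if (y > 0)      acc -= flux(v[i - sy], vi);
          upd[i] = acc;
        }
      }
    }
    for (R_xlen_t i = 0; i < n; ++i) v[i] += dt * upd[i];
  }

  NumericVector out(v.begin(), v.end());
  out.attr("dim") = IntegerVector::create(nz, nx, ny);
  return out;
}
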