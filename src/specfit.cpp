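#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Per-window spectral model fit: robust aperiodic (offset, exponent) fit,
// iterative Gaussian peak detection with bounded Levenberg-Marquardt joint
// refit, peak pruning, and a final aperiodic refit on the peak-removed
// spectrum. One implementation backs both the single-window R interface
// and the batched per-recording loop.

// ---- Gaussian peak model -------------------------------------------------

static arma::vec gauss_model(const arma::vec& f, const arma::vec& theta) {
  const arma::uword K = theta.n_elem / 3;
  arma::vec m(f.n_elem, arma::fill::zeros);
  for (arma::uword k = 0; k < K; ++k) {
    double c = theta[3 * k], a = theta[3 * k + 1], w = theta[3 * k + 2];
    arma::vec u = (f - c) / w;
    m += a * arma::exp(-0.5 * arma::square(u));
  }
  return m;
}

static arma::mat gauss_jac(const arma::vec& f, const arma::vec& theta) {
  const arma::uword K = theta.n_elem / 3;
  arma::mat J(f.n_elem, 3 * K);
  for (arma::uword k = 0; k < K; ++k) {
    double c = theta[3 * k], a = theta[3 * k + 1], w = theta[3 * k + 2];
    arma::vec u = (f - c) / w;
    arma::vec e = arma::exp(-0.5 * arma::square(u));
    J.col(3 * k) = a * e % u / w;
    J.col(3 * k + 1) = e;
    J.col(3 * k + 2) = a * e % arma::square(u) / w;
  }
  return J;
}

// Bounded LM with parameter clipping; returns packed theta.
static arma::vec lm_refit(const arma::vec& freqs, const arma::vec& flat,
                          arma::vec theta, const arma::vec& tlo,
                          const arma::vec& thi, int max_iter,
                          double ftol) {
  theta = arma::max(arma::min(theta, thi), tlo);
  arma::vec r = flat - gauss_model(freqs, theta);
  double cost = arma::dot(r, r);
  double lambda = 1e-3;
  for (int it = 0; it < max_iter; ++it) {
    arma::mat J = gauss_jac(freqs, theta);
    arma::mat JtJ = J.t() * J;
    arma::vec g = J.t() * r;
    if (arma::norm(g, "inf") < 1e-10) break;
    bool accepted = false;
    for (int tries = 0; tries < 8; ++tries) {
      arma::mat A = JtJ;
      A.diag() += lambda * (JtJ.diag() + 1e-12);
      arma::vec delta;
      if (arma::solve(delta, A, g, arma::solve_opts::no_approx)) {
        arma::vec cand = arma::max(arma::min(theta + delta, thi), tlo);
        arma::vec rc = flat - gauss_model(freqs, cand);
        double cc = arma::dot(rc, rc);
        if (cc < cost) {
          double rel = (cost - cc) / std::max(cost, 1e-300);
          theta = cand;
          r = rc;
          cost = cc;
          lambda = std::max(lambda / 3.0, 1e-12);
          accepted = true;
          if (rel < ftol) it = max_iter; // converged
          break;
        }
      }
      lambda *= 4.0;
      if (lambda > 1e10) break;
    }
    if (!accepted) break;
  }
  return theta;
}

// Bounded joint refit of K Gaussians (columns c, a, w); R-facing.
// [[Rcpp::export]]
List gauss_refit_cpp(const arma::vec& freqs, const arma::vec& flat,
                     const arma::mat& guess, const arma::mat& lo,
                     const arma::mat& hi, int max_iter = 60,
                     double ftol = 1e-9) {
  const arma::uword K = guess.n_rows;
  arma::vec theta(3 * K), tlo(3 * K), thi(3 * K);
  for (arma::uword k = 0; k < K; ++k)
    for (arma::uword j = 0; j < 3; ++j) {
      theta[3 * k + j] = guess(k, j);
      tlo[3 * k + j] = lo(k, j);
      thi[3 * k + j] = hi(k, j);
    }
  arma::vec out = lm_refit(freqs, flat, theta, tlo, thi, max_iter, ftol);
  arma::mat pk(K, 3);
  for (arma::uword k = 0; k < K; ++k)
    for (arma::uword j = 0; j < 3; ++j) pk(k, j) = out[3 * k + j];
  arma::vec r = flat - gauss_model(freqs, out);
  return List::create(_["peaks"] = pk, _["converged"] = true,
                      _["cost"] = arma::dot(r, r));
}

// ---- aperiodic fit -------------------------------------------------------

// OLS of y ~ b - x * log10(f) over the rows where mask is true.
static arma::vec2 aperiodic_ols(const arma::vec& neglogf, const arma::vec& y,
                                const arma::uvec& mask) {
  double n = 0, Sx = 0, Sxx = 0, Sy = 0, Sxy = 0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    if (!mask[i]) continue;
    double u = neglogf[i], v = y[i];
    n += 1; Sx += u; Sxx += u * u; Sy += v; Sxy += u * v;
  }
  double det = n * Sxx - Sx * Sx;
  arma::vec2 out;
  if (det <= 0 || n < 2) { out[0] = NA_REAL; out[1] = NA_REAL; return out; }
  double slope = (n * Sxy - Sx * Sy) / det;   // coefficient on -log10(f)
  double intercept = (Sy - slope * Sx) / n;
  out[0] = intercept; // offset b
  out[1] = slope;     // exponent x
  return out;
}

// type-7 quantile of v (matches R's default)
static double quantile7(arma::vec v, double p) {
  v = arma::sort(v);
  const arma::uword n = v.n_elem;
  if (n == 1) return v[0];
  double h = (n - 1) * p;
  arma::uword lo = (arma::uword)std::floor(h);
  double frac = h - lo;
  if (lo + 1 >= n) return v[n - 1];
  return v[lo] * (1 - frac) + v[lo + 1] * frac;
}

static arma::vec2 aperiodic_fit(const arma::vec& neglogf, const arma::vec& y,
                                bool robust, double percentile) {
  arma::uvec all(y.n_elem, arma::fill::ones);
  arma::vec2 cf = aperiodic_ols(neglogf, y, all);
  if (robust && cf.is_finite()) {
    arma::vec r = y - (cf[0] + cf[1] * neglogf);
    arma::vec rz = arma::clamp(r, 0.0, arma::datum::inf);
    double thr = quantile7(rz, percentile);
    arma::uvec keep = rz <= thr;
    if (arma::accu(keep) >= 4) cf = aperiodic_ols(neglogf, y, keep);
  }
  return cf;
}

// ---- peak detection + refit ---------------------------------------------

struct PeakSettings {
  int max_n;
  double min_h;   // log10 units
  double thr_sd;
  double wlo, whi;
  double prox;
};

// returns K x 3 matrix (c, a, w)
static arma::mat peak_fit(const arma::vec& freqs, const arma::vec& flat,
                          const PeakSettings& S, int lm_iter = 14) {
  const arma::uword F = freqs.n_elem;
  const double fmin = freqs[0], fmax = freqs[F - 1];
  const double df = freqs[1] - freqs[0];
  arma::vec flat_iter = flat;
  std::vector<arma::vec3> guesses;

  while ((int)guesses.size() < S.max_n) {
    arma::uword imax = flat_iter.index_max();
    double h = flat_iter[imax];
    double sd = arma::stddev(flat_iter);
    if (h < std::max(S.min_h, S.thr_sd * sd)) break;
    double c0 = freqs[imax];
    double half = h / 2;
    int l = -1, rgt = -1;
    for (int i = (int)imax; i >= 0; --i)
      if (flat_iter[i] < half) { l = (int)imax - i; break; }
    for (arma::uword i = imax; i < F; ++i)
      if (flat_iter[i] < half) { rgt = (int)(i - imax); break; }
    double hw_bins;
    if (l < 0 && rgt < 0) hw_bins = 2;
    else if (l < 0) hw_bins = rgt;
    else if (rgt < 0) hw_bins = l;
    else hw_bins = 0.5 * (l + rgt); // both sides: average extent
    double fwhm = 2.0 * hw_bins * df;
    double w0 = std::min(std::max(fwhm / 2.355, S.wlo), S.whi);
    arma::vec3 g = {c0, h, w0};
    guesses.push_back(g);
    arma::vec u = (freqs - c0) / w0;
    flat_iter -= h * arma::exp(-0.5 * arma::square(u));
  }
  // drop overlapping guesses (keep the taller) before the joint refit:
  // a shoulder guess refit jointly with its parent drags the parent's
  // centre toward the shoulder even if the shoulder is pruned afterwards
  {
    std::vector<bool> gkeep(guesses.size(), true);
    for (size_t a = 0; a < guesses.size(); ++a) {
      if (!gkeep[a]) continue;
      for (size_t b = 0; b < guesses.size(); ++b) {
        if (b == a || !gkeep[b] || guesses[b][1] > guesses[a][1]) continue;
        if (b < a && guesses[b][1] == guesses[a][1]) continue;
        if (std::abs(guesses[a][0] - guesses[b][0]) <
            S.prox * (guesses[a][2] + guesses[b][2])) gkeep[b] = false;
      }
    }
    std::vector<arma::vec3> kept;
    for (size_t a = 0; a < guesses.size(); ++a)
      if (gkeep[a]) kept.push_back(guesses[a]);
    guesses = kept;
  }
  const arma::uword K = guesses.size();
  if (K == 0) return arma::mat(0, 3);

  arma::vec theta(3 * K), tlo(3 * K), thi(3 * K);
  for (arma::uword k = 0; k < K; ++k) {
    double c0 = guesses[k][0], h = guesses[k][1], w0 = guesses[k][2];
    theta[3 * k] = c0; theta[3 * k + 1] = h; theta[3 * k + 2] = w0;
    tlo[3 * k] = std::max(fmin, c0 - 2 * w0);
    thi[3 * k] = std::min(fmax, c0 + 2 * w0);
    tlo[3 * k + 1] = 1e-6; thi[3 * k + 1] = arma::datum::inf;
    tlo[3 * k + 2] = S.wlo; thi[3 * k + 2] = S.whi;
  }
  // restrict the refit to bins within 5 SD of any candidate: beyond that
  // the Gaussians' gradients vanish and the bins cannot move the solution
  arma::uvec sel(F, arma::fill::zeros);
  for (arma::uword k = 0; k < K; ++k)
    for (arma::uword i = 0; i < F; ++i)
      if (std::abs(freqs[i] - theta[3 * k]) <= 5.0 * theta[3 * k + 2])
        sel[i] = 1;
  arma::uvec idx = arma::find(sel);
  arma::vec out = lm_refit(freqs.elem(idx), flat.elem(idx), theta, tlo,
                           thi, lm_iter, 3e-6);

  std::vector<arma::vec3> pk;
  for (arma::uword k = 0; k < K; ++k) {
    arma::vec3 p = {out[3 * k], out[3 * k + 1], out[3 * k + 2]};
    pk.push_back(p);
  }
  std::vector<bool> keep(K, true);
  for (arma::uword k = 0; k < K; ++k) {
    if (pk[k][0] - fmin < S.prox * pk[k][2] ||
        fmax - pk[k][0] < S.prox * pk[k][2]) keep[k] = false;
    if (pk[k][1] < S.min_h / 2) keep[k] = false; // collapsed during refit
  }
  for (arma::uword a = 0; a < K; ++a) {
    if (!keep[a]) continue;
    for (arma::uword b = 0; b < K; ++b) {
      if (b == a || !keep[b] || pk[b][1] > pk[a][1]) continue;
      if (pk[b][1] == pk[a][1] && b < a) continue; // tie: keep first
      if (std::abs(pk[a][0] - pk[b][0]) <
          S.prox * (pk[a][2] + pk[b][2])) keep[b] = false;
    }
  }
  std::vector<arma::uword> ord;
  for (arma::uword k = 0; k < K; ++k) if (keep[k]) ord.push_back(k);
  std::sort(ord.begin(), ord.end(), [&](arma::uword i, arma::uword j) {
    return pk[i][0] < pk[j][0];
  });
  arma::mat res(ord.size(), 3);
  for (arma::uword i = 0; i < ord.size(); ++i) {
    res(i, 0) = pk[ord[i]][0];
    res(i, 1) = pk[ord[i]][1];
    res(i, 2) = pk[ord[i]][2];
  }
  return res;
}

static PeakSettings make_settings(int max_n, double min_h, double thr_sd,
                                  double wlo, double whi, double prox) {
  PeakSettings S;
  S.max_n = max_n; S.min_h = min_h; S.thr_sd = thr_sd;
  S.wlo = wlo; S.whi = whi; S.prox = prox;
  return S;
}

// Iterative detection + joint refit of peaks on a flattened spectrum.
// [[Rcpp::export]]
arma::mat fit_peaks_cpp(const arma::vec& freqs, const arma::vec& flat,
                        int max_n, double min_h, double thr_sd, double wlo,
                        double whi, double prox) {
  return peak_fit(freqs, flat, make_settings(max_n, min_h, thr_sd, wlo,
                                             whi, prox));
}

struct WindowFitOut {
  arma::vec2 ap;
  arma::mat peaks;
  double mse, r2;
};

// One flatten -> peak-fit -> peak-removed aperiodic refit cycle.
static void fit_cycle(const arma::vec& freqs, const arma::vec& neglogf,
                      const arma::vec& y, const PeakSettings& S,
                      const arma::vec2& ap_flatten, arma::mat& peaks,
                      arma::vec& pm, arma::vec2& ap_final,
                      double robust_percentile, int lm_iter = 14) {
  arma::vec flat = y - (ap_flatten[0] + ap_flatten[1] * neglogf);
  peaks = peak_fit(freqs, flat, S, lm_iter);
  pm.zeros(y.n_elem);
  if (peaks.n_rows > 0) {
    arma::vec theta(3 * peaks.n_rows);
    for (arma::uword k = 0; k < peaks.n_rows; ++k)
      for (arma::uword j = 0; j < 3; ++j) theta[3 * k + j] = peaks(k, j);
    pm = gauss_model(freqs, theta);
  }
  ap_final = aperiodic_fit(neglogf, y - pm, false, robust_percentile);
}

static WindowFitOut window_fit_one(const arma::vec& freqs,
                                   const arma::vec& neglogf,
                                   const arma::vec& y,
                                   const PeakSettings& S,
                                   double robust_percentile) {
  WindowFitOut o;
  // pass 1: peak-resistant (robust) flatten, biased slightly steep when a
  // large peak is present
  arma::vec2 ap0 = aperiodic_fit(neglogf, y, true, robust_percentile);
  arma::mat peaks1;
  arma::vec pm;
  arma::vec2 ap1;
  fit_cycle(freqs, neglogf, y, S, ap0, peaks1, pm, ap1, robust_percentile,
            5);
  // pass 2: re-flatten with the peak-removed (unbiased) aperiodic and
  // refit the peaks; removes the centre-frequency tilt the robust
  // flatten induces under broad peaks
  if (ap1.is_finite()) {
    fit_cycle(freqs, neglogf, y, S, ap1, o.peaks, pm, o.ap,
              robust_percentile);
  } else {
    o.peaks = peaks1;
    o.ap = ap1;
  }
  arma::vec model = (o.ap[0] + o.ap[1] * neglogf) + pm;
  arma::vec r = y - model;
  o.mse = arma::dot(r, r) / y.n_elem;
  double mu = arma::mean(y);
  double vy = arma::dot(y - mu, y - mu) / y.n_elem;
  o.r2 = vy > 0 ? 1 - o.mse / vy : NA_REAL;
  return o;
}

// Full single-window fit (robust aperiodic -> peaks -> final aperiodic).
// [[Rcpp::export]]
List fit_window_cpp(const arma::vec& freqs, const arma::vec& y, int max_n,
                    double min_h, double thr_sd, double wlo, double whi,
                    double prox, double robust_percentile) {
  arma::vec neglogf = -arma::log10(freqs);
  WindowFitOut o = window_fit_one(freqs, neglogf, y,
                                  make_settings(max_n, min_h, thr_sd, wlo,
                                                whi, prox),
                                  robust_percentile);
  return List::create(_["aperiodic"] = NumericVector::create(o.ap[0], o.ap[1]),
                      _["peaks"] = o.peaks, _["mse"] = o.mse,
                      _["r_squared"] = o.r2);
}

// Batched per-recording loop over the columns of a log10-power matrix.
// Returns windows x 8: offset, exponent, alpha cf/amp/width (NA when no
// in-band peak), mse, r_squared.
// [[Rcpp::export]]
arma::mat fit_windows_batch_cpp(const arma::vec& freqs, const arma::mat& Y,
                                int max_n, double min_h, double thr_sd,
                                double wlo, double whi, double prox,
                                double robust_percentile, double band_lo,
                                double band_hi) {
  arma::vec neglogf = -arma::log10(freqs);
  PeakSettings S = make_settings(max_n, min_h, thr_sd, wlo, whi, prox);
  const arma::uword W = Y.n_cols;
  arma::mat out(W, 8);
  out.fill(NA_REAL);
  for (arma::uword w = 0; w < W; ++w) {
    WindowFitOut o = window_fit_one(freqs, neglogf, Y.col(w), S,
                                    robust_percentile);
    if (!o.ap.is_finite()) continue;
    out(w, 0) = o.ap[0];
    out(w, 1) = o.ap[1];
    // alpha peak: largest amplitude inside the band
    double best_a = -1;
    for (arma::uword k = 0; k < o.peaks.n_rows; ++k) {
      if (o.peaks(k, 0) >= band_lo && o.peaks(k, 0) <= band_hi &&
          o.peaks(k, 1) > best_a) {
        best_a = o.peaks(k, 1);
        out(w, 2) = o.peaks(k, 0);
        out(w, 3) = o.peaks(k, 1);
        out(w, 4) = o.peaks(k, 2);
      }
    }
    out(w, 5) = o.mse;
    out(w, 6) = o.r2;
    out(w, 7) = o.peaks.n_rows;
  }
  return out;
}
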