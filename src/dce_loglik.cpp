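#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Simulated log-likelihood for binary panel choice data with optional
// random coefficients, data-source scale parameters, and an ICLV block
// (structural latent variable + binary/ordered measurement equations).
//
// Utility difference for observation m of respondent n at draw r:
//   dV = lambda_n * ( dX_m'beta + sum_k sigma_k xi_{nkr} dX_{m,rc_k}
//                     + LV_nr * sum_k tau_k dX_{m,tc_k} )
//   LV_nr = Z_n'gamma + eta_{nr},  lambda_n = exp(scale_load_n' loglam)
// Choice probability P = plogis(y_m * dV), y = +1/-1.
// Measurement: binary k ~ Bernoulli(plogis(alpha_k + zeta_k LV)),
// ordered count ~ ordered logit with cutpoints kappa and loading zeta_s.
// Per-respondent likelihood averages exp(choice + measurement loglik) over
// draws (panel product inside the average). Gradients are analytic.
//
// Cutpoints are parameterised as kappa_1 = c_1, kappa_j = kappa_{j-1} +
// exp(c_j), keeping them strictly increasing.

// [[Rcpp::export]]
List dce_loglik_cpp(NumericVector par,
                    NumericMatrix dX, NumericVector y, IntegerVector resp_start,
                    NumericVector w, NumericMatrix scale_load,
                    IntegerVector rand_cols, IntegerVector tau_cols,
                    NumericMatrix Z, NumericMatrix B, IntegerVector Sord,
                    int L, NumericVector xi, NumericMatrix eta, int R,
                    bool want_scores) {
  const int M = dX.nrow(), K = dX.ncol();
  const int N = resp_start.size() - 1;
  const int Krand = rand_cols.size();
  const int S = scale_load.ncol();
  const int Ktau = tau_cols.size();
  const int p = Z.ncol();
  const int Kb = B.ncol();
  const bool has_latent = (p > 0) || (Kb > 0) || (L > 0) || (Ktau > 0);
  const double *dXp = REAL(dX);
  const double *yp = REAL(y);

  // --- unpack parameters ---------------------------------------------------
  int off = 0;
  const double *beta = &par[off];        off += K;
  const double *sigma = (Krand > 0) ? &par[off] : nullptr; off += Krand;
  const double *loglam = (S > 0) ? &par[off] : nullptr;    off += S;
  const double *tau = (Ktau > 0) ? &par[off] : nullptr;    off += Ktau;
  const double *gamma = (p > 0) ? &par[off] : nullptr;     off += p;
  const double *alpha = (Kb > 0) ? &par[off] : nullptr;    off += Kb;
  const double *zeta  = (Kb > 0) ? &par[off] : nullptr;    off += Kb;
  double zeta_s = 0.0;
  if (L > 0) { zeta_s = par[off]; off += 1; }
  std::vector<double> kappa(L), craw(L);
  if (L > 0) {
    for (int j = 0; j < L; ++j) craw[j] = par[off + j];
    kappa[0] = craw[0];
    for (int j = 1; j < L; ++j) kappa[j] = kappa[j - 1] + std::exp(craw[j]);
    off += L;
  }
  const int P = off;
  if (P != par.size()) stop("parameter vector length mismatch");
  if (R < 1) stop("number of draws must be >= 1");

  // --- precompute -----------------------------------------------------------
  std::vector<double> dxb(M, 0.0);       // dX * beta
  for (int j = 0; j < K; ++j) {
    const double bj = beta[j];
    const double *col = dXp + (size_t)j * M;
    if (bj != 0.0) for (int m = 0; m < M; ++m) dxb[m] += col[m] * bj;
  }
  std::vector<double> tdot(M, 0.0);      // sum_k tau_k dX[, tc_k]
  if (Ktau > 0)
    for (int k = 0; k < Ktau; ++k) {
      const double *col = dXp + (size_t)tau_cols[k] * M;
      for (int m = 0; m < M; ++m) tdot[m] += tau[k] * col[m];
    }
  std::vector<double> lam(N, 1.0);
  for (int n = 0; n < N; ++n) {
    double s = 0.0;
    for (int c = 0; c < S; ++c) s += scale_load(n, c) * loglam[c];
    lam[n] = std::exp(s);
  }
  std::vector<double> gz(N, 0.0);
  if (p > 0)
    for (int n = 0; n < N; ++n) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += Z(n, j) * gamma[j];
      gz[n] = s;
    }
  // reorder xi draws so each respondent's block is contiguous: xl[k + Krand*(r + R*n)]
  std::vector<double> xiloc;
  if (Krand > 0) {
    xiloc.resize((size_t)N * R * Krand);
    const double *xip = REAL(xi);
    for (int n = 0; n < N; ++n)
      for (int r = 0; r < R; ++r)
        for (int k = 0; k < Krand; ++k)
          xiloc[(size_t)Krand * (r + (size_t)R * n) + k] =
            xip[(size_t)n + (size_t)N * (k + (size_t)Krand * r)];
  }

  double LL = 0.0;
  NumericVector grad(P);
  NumericMatrix scores(want_scores ? N : 0, want_scores ? P : 0);

  int Tmax = 0;
  for (int n = 0; n < N; ++n) Tmax = std::max(Tmax, resp_start[n + 1] - resp_start[n]);
  std::vector<double> Pbuf((size_t)Tmax * R), DVbuf((size_t)Tmax * R);
  std::vector<double> pan(R), omg(R), LVv(R);
  std::vector<double> pbin((size_t)std::max(Kb, 1) * R);
  std::vector<double> ord_flo(R), ord_fhi(R), ord_P(R);
  std::vector<double> gloc(P);
  std::vector<double> xr((size_t)Tmax * std::max(Krand, 1));  // dX on random cols
  std::vector<double> fk(std::max(Krand, 1));
  const bool need_dv = (S > 0);

  for (int n = 0; n < N; ++n) {
    const int r0 = resp_start[n], r1 = resp_start[n + 1];
    const int Tn = r1 - r0;
    const double ln = lam[n];
    const int s_n = (L > 0) ? Sord[n] : NA_INTEGER;
    const bool has_ord = (L > 0) && (s_n != NA_INTEGER);
    for (int t = 0; t < Tn; ++t)
      for (int k = 0; k < Krand; ++k)
        xr[(size_t)t * Krand + k] = dXp[(size_t)rand_cols[k] * M + (r0 + t)];
    const double *xln = Krand ? &xiloc[(size_t)Krand * (size_t)R * n] : nullptr;

    for (int r = 0; r < R; ++r) {
      double LV = 0.0;
      if (has_latent) LV = gz[n] + ((eta.ncol() > 0) ? eta(n, r) : 0.0);
      LVv[r] = LV;
      double cll = 0.0;
      const double *xl = Krand ? xln + (size_t)Krand * r : nullptr;
      for (int t = 0; t < Tn; ++t) {
        const int m = r0 + t;
        double a = dxb[m];
        const double *xrt = &xr[(size_t)t * Krand];
        for (int k = 0; k < Krand; ++k) a += sigma[k] * xl[k] * xrt[k];
        if (Ktau > 0) a += LV * tdot[m];
        const double dv = ln * a;
        const double u = yp[m] * dv;
        // stable P and log P from one exp
        double Pm, lp;
        if (u > 0) { const double e = std::exp(-u); lp = -log1p(e); Pm = 1.0 / (1.0 + e); }
        else { const double e = std::exp(u); lp = u - log1p(e); Pm = e / (1.0 + e); }
        Pbuf[(size_t)t * R + r] = Pm;
        if (need_dv) DVbuf[(size_t)t * R + r] = dv;
        cll += lp;
      }
      double mll = 0.0;
      for (int k = 0; k < Kb; ++k) {
        const double bv = B(n, k);
        if (ISNAN(bv)) { pbin[(size_t)k * R + r] = NA_REAL; continue; }
        const double s = alpha[k] + zeta[k] * LV;
        const double e = std::exp(-std::fabs(s));
        const double pk = (s > 0) ? 1.0 / (1.0 + e) : 1.0 - 1.0 / (1.0 + e);
        pbin[(size_t)k * R + r] = pk;
        mll += (bv > 0.5) ? ((s > 0) ? -log1p(e) : s - log1p(e))
                          : ((s > 0) ? -s - log1p(e) : -log1p(e));
      }
      if (has_ord) {
        const double mlv = zeta_s * LV;
        double Flo = 0.0, flo = 0.0, Fhi = 1.0, fhi = 0.0;
        if (s_n > 0) {
          const double e = kappa[s_n - 1] - mlv;
          Flo = 1.0 / (1.0 + std::exp(-e)); flo = Flo * (1.0 - Flo);
        }
        if (s_n < L) {
          const double e = kappa[s_n] - mlv;
          Fhi = 1.0 / (1.0 + std::exp(-e)); fhi = Fhi * (1.0 - Fhi);
        }
        double Po = Fhi - Flo;
        if (Po < 1e-300) Po = 1e-300;
        ord_flo[r] = flo; ord_fhi[r] = fhi; ord_P[r] = Po;
        mll += std::log(Po);
      }
      pan[r] = cll + mll;
    }

    // log-mean-exp over draws
    double mx = pan[0];
    for (int r = 1; r < R; ++r) mx = std::max(mx, pan[r]);
    double se = 0.0;
    for (int r = 0; r < R; ++r) { omg[r] = std::exp(pan[r] - mx); se += omg[r]; }
    const double Ln = mx + std::log(se) - std::log((double)R);
    for (int r = 0; r < R; ++r) omg[r] /= se;  // draw weights, sum to 1
    LL += w[n] * Ln;

    // --- gradient ------------------------------------------------------------
    std::fill(gloc.begin(), gloc.end(), 0.0);
    for (int t = 0; t < Tn; ++t) {
      const int m = r0 + t;
      const double *Pt = &Pbuf[(size_t)t * R];
      double e_m = 0.0, h_m = 0.0, d_m = 0.0;
      std::fill(fk.begin(), fk.end(), 0.0);
      if (Krand > 0) {
        for (int r = 0; r < R; ++r) {
          const double tt = omg[r] * (1.0 - Pt[r]);
          e_m += tt;
          const double *xl = xln + (size_t)Krand * r;
          for (int k = 0; k < Krand; ++k) fk[k] += tt * xl[k];
        }
      } else {
        for (int r = 0; r < R; ++r) e_m += omg[r] * (1.0 - Pt[r]);
      }
      if (need_dv) {
        const double *Dt = &DVbuf[(size_t)t * R];
        for (int r = 0; r < R; ++r) d_m += omg[r] * (1.0 - Pt[r]) * Dt[r];
      }
      if (has_latent && Ktau > 0)
        for (int r = 0; r < R; ++r) h_m += omg[r] * (1.0 - Pt[r]) * LVv[r];
      const double base = yp[m] * ln;
      for (int j = 0; j < K; ++j) gloc[j] += base * e_m * dXp[(size_t)j * M + m];
      const double *xrt = &xr[(size_t)t * Krand];
      for (int k = 0; k < Krand; ++k) gloc[K + k] += base * fk[k] * xrt[k];
      for (int c = 0; c < S; ++c)
        gloc[K + Krand + c] += scale_load(n, c) * yp[m] * d_m;
      for (int k = 0; k < Ktau; ++k)
        gloc[K + Krand + S + k] += base * h_m * dXp[(size_t)tau_cols[k] * M + m];
    }
    // latent + measurement part
    if (has_latent) {
      double gLV = 0.0;  // sum_r omg_r d(pan_r)/dLV
      const int oG = K + Krand + S + Ktau;
      const int oA = oG + p, oZ = oA + Kb;
      const int oZs = oZ + Kb, oC = oZs + (L > 0 ? 1 : 0);
      for (int r = 0; r < R; ++r) {
        double dp = 0.0;
        if (Ktau > 0) {
          for (int t = 0; t < Tn; ++t) {
            const int m = r0 + t;
            dp += (1.0 - Pbuf[(size_t)t * R + r]) * yp[m] * ln * tdot[m];
          }
        }
        for (int k = 0; k < Kb; ++k) {
          const double pk = pbin[(size_t)k * R + r];
          if (ISNAN(pk)) continue;
          const double res = B(n, k) - pk;
          gloc[oA + k] += omg[r] * res;
          gloc[oZ + k] += omg[r] * res * LVv[r];
          dp += zeta[k] * res;
        }
        if (has_ord) {
          const double df = (ord_fhi[r] - ord_flo[r]) / ord_P[r];
          gloc[oZs] += omg[r] * (-LVv[r]) * df;
          dp += -zeta_s * df;
          // d kappa_j / d c_1 = 1 (all j); d kappa_j / d c_i = exp(c_i), j >= i
          const double ghi = (s_n < L) ? omg[r] * ord_fhi[r] / ord_P[r] : 0.0;
          const double glo = (s_n > 0) ? -omg[r] * ord_flo[r] / ord_P[r] : 0.0;
          if (s_n < L) {
            gloc[oC] += ghi;
            for (int i = 1; i <= s_n; ++i) gloc[oC + i] += ghi * std::exp(craw[i]);
          }
          if (s_n > 0) {
            gloc[oC] += glo;
            for (int i = 1; i <= s_n - 1; ++i) gloc[oC + i] += glo * std::exp(craw[i]);
          }
        }
        gLV += omg[r] * dp;
      }
      for (int j = 0; j < p; ++j) gloc[oG + j] += gLV * Z(n, j);
    }
    for (int j = 0; j < P; ++j) {
      const double v = w[n] * gloc[j];
      grad[j] += v;
      if (want_scores) scores(n, j) = v;
    }
  }

  List out = List::create(Named("ll") = LL, Named("grad") = grad);
  if (want_scores) out["scores"] = scores;
  return out;
}
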