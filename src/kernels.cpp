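#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pulse-echo simulation of one diverging-wave transmit.
// Each scatterer contributes an echo of a Gaussian-enveloped cosine pulse at
// t = (|p_s - p_src| - s_min)/c + |p_s - p_e|/c on every receive element.
// s_min is the minimum source-to-active-element distance (t = 0 is the instant
// the earliest element fires; the diverging wavefront convention shared with
// the beamformer).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_rf(NumericMatrix scat, NumericVector refl,
                              NumericMatrix elem, NumericVector src,
                              double s_min, double sos, double fs, int n_t,
                              double f0, double sigma_t, bool spreading) {
  const int N = scat.nrow(), E = elem.nrow();
  NumericMatrix rf(n_t, E);
  const double half = 3.5 * sigma_t;
  const double w0 = 2.0 * M_PI * f0;
  const double inv2s2 = 1.0 / (2.0 * sigma_t * sigma_t);
  // pulse lookup table at 1/32-sample resolution over [-half, half]
  const double tab_dt = 1.0 / (32.0 * fs);
  const int n_tab = (int)(2.0 * half / tab_dt) + 2;
  std::vector<double> tab(n_tab);
  for (int i = 0; i < n_tab; ++i) {
    const double dt = -half + i * tab_dt;
    tab[i] = std::exp(-dt * dt * inv2s2) * std::cos(w0 * dt);
  }
  const double inv_tab_dt = 1.0 / tab_dt;
  for (int s = 0; s < N; ++s) {
    const double sx = scat(s, 0), sy = scat(s, 1), sz = scat(s, 2);
    const double dxs = sx - src[0], dys = sy - src[1], dzs = sz - src[2];
    const double d_tx = std::sqrt(dxs * dxs + dys * dys + dzs * dzs);
    const double t_tx = (d_tx - s_min) / sos;
    const double a0 = refl[s];
    for (int e = 0; e < E; ++e) {
      const double dx = sx - elem(e, 0), dy = sy - elem(e, 1), dz = sz - elem(e, 2);
      const double d_rx = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double t0 = t_tx + d_rx / sos;
      double amp = a0;
      if (spreading) amp /= (d_tx * d_rx + 1e-12);
      int n0 = (int)std::ceil((t0 - half) * fs);
      int n1 = (int)std::floor((t0 + half) * fs);
      if (n0 < 0) n0 = 0;
      if (n1 > n_t - 1) n1 = n_t - 1;
      double *col = &rf(0, e);
      for (int n = n0; n <= n1; ++n) {
        const double ft = (n / fs - t0 + half) * inv_tab_dt;
        const int i0 = (int)ft;
        if (i0 >= 0 && i0 < n_tab - 1) {
          const double w = ft - i0;
          col[n] += amp * ((1.0 - w) * tab[i0] + w * tab[i0 + 1]);
        }
      }
    }
  }
  return rf;
}

// Delay-and-sum for one transmit: sum over elements of the RF trace sampled at
// forward + backward delay, linear interpolation in fast time, out-of-range
// samples contribute zero, no apodization.
// [[Rcpp::export]]
NumericVector cpp_das(NumericMatrix rf, NumericMatrix elem, NumericVector src,
                      double s_min, double sos, double fs,
                      NumericVector px, NumericVector py, NumericVector pz) {
  const int n_t = rf.nrow(), E = elem.nrow();
  const int P = px.size();
  NumericVector out(P);
  std::vector<double> tfwd(P);
  const double *xp = px.begin(), *yp = py.begin(), *zp = pz.begin();
  double *op = out.begin();
  const double inv_c = 1.0 / sos;
  for (int p = 0; p < P; ++p) {
    const double dxs = xp[p] - src[0], dys = yp[p] - src[1], dzs = zp[p] - src[2];
    tfwd[p] = (std::sqrt(dxs * dxs + dys * dys + dzs * dzs) - s_min) * inv_c;
  }
  for (int e = 0; e < E; ++e) {
    const double ex = elem(e, 0), ey = elem(e, 1), ez = elem(e, 2);
    const double *col = &rf(0, e);
    for (int p = 0; p < P; ++p) {
      const double dx = xp[p] - ex, dy = yp[p] - ey, dz = zp[p] - ez;
      const double d_rx = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double ts = (tfwd[p] + d_rx * inv_c) * fs;
      const int i0 = (int)ts;
      if (ts >= 0.0 && i0 < n_t - 1) {
        const double w = ts - i0;
        op[p] += (1.0 - w) * col[i0] + w * col[i0 + 1];
      }
    }
  }
  return out;
}

// Zero-normalized 1-D cross-correlation tracking of all windows of all lines
// of a volume pair. v0/v1 are n_depth x n_lines matrices; starts are 0-based
// window start indices. Windows whose +/- max_lag search segment would leave
// the recording are flagged (flag 3) and skipped. Flags: 0 ok, 1 zero
// variance, 2 peak on search boundary (no subsample refinement), 3 search out
// of range. subsample: 0 none, 1 parabolic, 2 cosine.
// [[Rcpp::export]]
List cpp_track(NumericMatrix v0, NumericMatrix v1, IntegerVector starts,
               int wlen, int max_lag, int subsample) {
  const int n_d = v0.nrow(), L = v0.ncol(), W = starts.size();
  NumericMatrix lag(W, L), peak(W, L);
  IntegerMatrix flag(W, L);
  std::vector<double> c(2 * max_lag + 1);
  // prefix sums of the search volume per line: O(1) window mean / energy
  std::vector<double> S1(n_d + 1), S2(n_d + 1);
  for (int l = 0; l < L; ++l) {
    const double *a = &v0(0, l);
    const double *b = &v1(0, l);
    S1[0] = S2[0] = 0.0;
    for (int i = 0; i < n_d; ++i) {
      S1[i + 1] = S1[i] + b[i];
      S2[i + 1] = S2[i] + b[i] * b[i];
    }
    for (int w = 0; w < W; ++w) {
      const int s0 = starts[w];
      if (s0 - max_lag < 0 || s0 + wlen - 1 + max_lag > n_d - 1) {
        lag(w, l) = NA_REAL; peak(w, l) = 0.0; flag(w, l) = 3;
        continue;
      }
      double sa = 0.0, sa2 = 0.0;
      for (int i = 0; i < wlen; ++i) {
        sa += a[s0 + i];
        sa2 += a[s0 + i] * a[s0 + i];
      }
      const double mr = sa / wlen;
      const double vr = sa2 - wlen * mr * mr;
      if (vr <= 0.0) {
        lag(w, l) = 0.0; peak(w, l) = 0.0; flag(w, l) = 1;
        continue;
      }
      int best = 0;
      double bestc = -2.0;
      for (int g = -max_lag; g <= max_lag; ++g) {
        const int t0 = s0 + g;
        const double ms = (S1[t0 + wlen] - S1[t0]) / wlen;
        const double vs = (S2[t0 + wlen] - S2[t0]) - wlen * ms * ms;
        double dot = 0.0;
        const double *ap = a + s0, *bp = b + t0;
        for (int i = 0; i < wlen; ++i) dot += ap[i] * bp[i];
        const double num = dot - wlen * mr * ms;
        const double cc = (vs > 0.0) ? num / std::sqrt(vr * vs) : 0.0;
        c[g + max_lag] = cc;
        if (cc > bestc) { bestc = cc; best = g; }
      }
      double sub = 0.0;
      int fl = 0;
      if (best == -max_lag || best == max_lag) {
        fl = 2;
      } else if (bestc >= 1.0 - 1e-12) {
        // exact match: refinement would only amplify round-off
      } else if (subsample == 1) {
        const double cm = c[best - 1 + max_lag], c0 = c[best + max_lag],
                     cp = c[best + 1 + max_lag];
        const double den = cm - 2.0 * c0 + cp;
        if (den < 0.0) sub = 0.5 * (cm - cp) / den;
      } else if (subsample == 2) {
        const double cm = c[best - 1 + max_lag], c0 = c[best + max_lag],
                     cp = c[best + 1 + max_lag];
        const double arg = (cm + cp) / (2.0 * c0);
        if (c0 != 0.0 && std::fabs(arg) < 1.0) {
          const double om = std::acos(arg);
          if (om > 1e-12) {
            const double th = std::atan((cm - cp) / (2.0 * c0 * std::sin(om)));
            sub = -th / om;
          }
        }
      }
      lag(w, l) = best + sub;
      peak(w, l) = bestc;
      flag(w, l) = fl;
    }
  }
  return List::create(_["lag"] = lag, _["peak"] = peak, _["flag"] = flag);
}
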