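#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Filters are represented as cascades of second-order sections (biquads),
// the numerically robust realization for the order-8 band-pass designs
// used on 50-sample windows: rows of `sos` are (b0, b1, b2, 1, a1, a2).

struct Sos {
  std::vector<double> b0, b1, b2, a1, a2;
  // steady-state unit-step delay states per section, cumulative-gain scaled
  std::vector<double> zi0, zi1;
  int ns;
};

static Sos make_sos(const NumericMatrix& sos) {
  Sos s;
  s.ns = sos.nrow();
  s.b0.resize(s.ns); s.b1.resize(s.ns); s.b2.resize(s.ns);
  s.a1.resize(s.ns); s.a2.resize(s.ns);
  s.zi0.resize(s.ns); s.zi1.resize(s.ns);
  double scale = 1.0;
  for (int j = 0; j < s.ns; ++j) {
    double b0 = sos(j, 0), b1 = sos(j, 1), b2 = sos(j, 2);
    double a1 = sos(j, 4), a2 = sos(j, 5);
    s.b0[j] = b0; s.b1[j] = b1; s.b2[j] = b2; s.a1[j] = a1; s.a2[j] = a2;
    // biquad steady state for a unit step: solve
    //   (1 + a1) z0 - z1 = b1 - a1 b0
    //        a2 z0 + z1 = b2 - a2 b0
    double m00 = 1.0 + a1, m01 = -1.0, m10 = a2, m11 = 1.0;
    double r0 = b1 - a1 * b0, r1 = b2 - a2 * b0;
    double det = m00 * m11 - m01 * m10;
    s.zi0[j] = scale * (r0 * m11 - m01 * r1) / det;
    s.zi1[j] = scale * (m00 * r1 - r0 * m10) / det;
    scale *= (b0 + b1 + b2) / (1.0 + a1 + a2);  // section DC gain
  }
  return s;
}

// Cascaded direct-form II transposed filtering, states seeded with
// `x0` times the steady-state step response.
static void sos_filter(const Sos& s, const double* x, double* y, int n,
                       double x0) {
  std::vector<double> z0(s.ns), z1(s.ns);
  for (int j = 0; j < s.ns; ++j) {
    z0[j] = s.zi0[j] * x0;
    z1[j] = s.zi1[j] * x0;
  }
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    for (int j = 0; j < s.ns; ++j) {
      double w = s.b0[j] * v + z0[j];
      z0[j] = s.b1[j] * v + z1[j] - s.a1[j] * w;
      z1[j] = s.b2[j] * v - s.a2[j] * w;
      v = w;
    }
    y[i] = v;
  }
}

// Zero-phase (forward-backward) cascade filtering with end padding of
// length `padlen`. Pad types: 0 = odd-symmetric reflection (zero-mean
// signals), 1 = even-symmetric reflection, 2 = constant (nonnegative
// envelopes). Requires padlen < n.
static void sos_filtfilt(const Sos& s, const double* x, double* out, int n,
                         int padlen, int padtype) {
  int m = n + 2 * padlen;
  std::vector<double> ext(m), tmp(m);
  for (int i = 0; i < padlen; ++i) {
    double pre, post;
    if (padtype == 0) {
      pre = 2.0 * x[0] - x[padlen - i];
      post = 2.0 * x[n - 1] - x[n - 2 - i];
    } else if (padtype == 1) {
      pre = x[padlen - i];
      post = x[n - 2 - i];
    } else {
      pre = x[0];
      post = x[n - 1];
    }
    ext[i] = pre;
    ext[padlen + n + i] = post;
  }
  for (int i = 0; i < n; ++i)
    ext[padlen + i] = x[i];
  sos_filter(s, ext.data(), tmp.data(), m, ext[0]);
  std::reverse(tmp.begin(), tmp.end());
  sos_filter(s, tmp.data(), ext.data(), m, tmp[0]);
  std::reverse(ext.begin(), ext.end());
  for (int i = 0; i < n; ++i) out[i] = ext[padlen + i];
}

// [[Rcpp::export]]
NumericMatrix cpp_sos_filtfilt(NumericMatrix x, NumericMatrix sos,
                               int padlen, int padtype = 0) {
  int n = x.nrow(), nc = x.ncol();
  if (padlen >= n) stop("padlen must be smaller than the signal length");
  Sos s = make_sos(sos);
  NumericMatrix out(n, nc);
  std::vector<double> col(n), res(n);
  for (int c = 0; c < nc; ++c) {
    for (int i = 0; i < n; ++i) col[i] = x(i, c);
    sos_filtfilt(s, col.data(), res.data(), n, padlen, padtype);
    for (int i = 0; i < n; ++i) out(i, c) = res[i];
  }
  return out;
}

// EEG per-window pipeline: common average reference -> zero-phase band-pass
// -> per-channel within-window z-score (sd = 0 maps to zeros) -> mean over
// the trailing `block` samples. Returns windows x channels.
// [[Rcpp::export]]
NumericMatrix cpp_eeg_features(NumericMatrix x, IntegerVector starts, int w,
                               int block, NumericMatrix sos, int padlen) {
  int nc = x.ncol(), nw = starts.size();
  if (nc < 2) stop("common average reference requires at least 2 channels");
  if (padlen >= w) stop("padlen must be smaller than the window length");
  Sos s = make_sos(sos);
  NumericMatrix out(nw, nc);
  std::vector<std::vector<double> > win(nc, std::vector<double>(w));
  std::vector<double> filt(w);
  for (int k = 0; k < nw; ++k) {
    int s0 = starts[k] - 1;
    // CAR: subtract the instantaneous cross-channel mean
    double in_scale = 0.0;  // raw window magnitude, for the sd floor
    for (int i = 0; i < w; ++i) {
      double m = 0.0;
      for (int c = 0; c < nc; ++c) {
        double v = x(s0 + i, c);
        m += v;
        if (std::fabs(v) > in_scale) in_scale = std::fabs(v);
      }
      m /= nc;
      for (int c = 0; c < nc; ++c) win[c][i] = x(s0 + i, c) - m;
    }
    for (int c = 0; c < nc; ++c) {
      sos_filtfilt(s, win[c].data(), filt.data(), w, padlen, 0);
      double mu = 0.0;
      for (int i = 0; i < w; ++i) mu += filt[i];
      mu /= w;
      double ss = 0.0;
      for (int i = 0; i < w; ++i) ss += (filt[i] - mu) * (filt[i] - mu);
      double sd = (w > 1) ? std::sqrt(ss / (w - 1)) : 0.0;
      // degenerate windows (constant, or pure rounding residue of the
      // CAR on identical channels) yield zero features, not amplified
      // numerical dust
      double acc = 0.0;
      if (sd > 1e-10 * in_scale && sd > 0.0) {
        for (int i = w - block; i < w; ++i) acc += (filt[i] - mu) / sd;
      }
      out(k, c) = acc / block;
    }
  }
  return out;
}

// EMG per-window pipeline: zero-phase band-pass (odd padding) -> rectify
// -> zero-phase low-pass envelope (constant padding, appropriate for a
// nonnegative signal) -> mean over the trailing `block` samples.
// [[Rcpp::export]]
NumericMatrix cpp_emg_features(NumericMatrix x, IntegerVector starts, int w,
                               int block, NumericMatrix sos_bp,
                               NumericMatrix sos_lp, int pad_bp,
                               int pad_lp) {
  int nc = x.ncol(), nw = starts.size();
  if (pad_bp >= w || pad_lp >= w)
    stop("padlen must be smaller than the window length");
  Sos sbp = make_sos(sos_bp), slp = make_sos(sos_lp);
  NumericMatrix out(nw, nc);
  std::vector<double> win(w), f1(w), f2(w);
  for (int k = 0; k < nw; ++k) {
    int s0 = starts[k] - 1;
    for (int c = 0; c < nc; ++c) {
      for (int i = 0; i < w; ++i) win[i] = x(s0 + i, c);
      sos_filtfilt(sbp, win.data(), f1.data(), w, pad_bp, 0);
      for (int i = 0; i < w; ++i) f1[i] = std::fabs(f1[i]);
      sos_filtfilt(slp, f1.data(), f2.data(), w, pad_lp, 2);
      double acc = 0.0;
      for (int i = w - block; i < w; ++i) acc += f2[i];
      out(k, c) = acc / block;
    }
  }
  return out;
}
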