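#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// xoshiro256++ (public-domain algorithm) seeded by splitmix64, feeding a
// ziggurat normal sampler. Self-contained so generated sessions are
// bit-reproducible across platforms and library versions.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

// Marsaglia-Tsang ziggurat for the standard normal (128 layers); tail and
// wedge cases fall back to exact exponential/log sampling.
struct ZigguratNormal {
  Xoshiro rng;
  uint32_t kn[128];
  double wn[128], fn[128];
  bool have32 = false;
  uint64_t cache = 0;

  explicit ZigguratNormal(uint64_t seed) : rng(seed) {
    const double m1 = 2147483648.0;
    const double vn = 9.91256303526217e-3;
    double dn = 3.442619855899, tn = dn;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  uint32_t next32() {
    if (have32) { have32 = false; return (uint32_t)(cache >> 32); }
    cache = rng.next();
    have32 = true;
    return (uint32_t)cache;
  }
  double draw() {
    for (;;) {
      int32_t hz = (int32_t)next32();
      uint32_t iz = hz & 127u;
      uint32_t az = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (az < kn[iz]) return hz * wn[iz];
      const double r = 3.442619855899;
      if (iz == 0) {                       // base-strip tail
        double x, y;
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * wn[iz];              // wedge
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

}  // namespace

// Early-exit finiteness check (validity of large voltage matrices).
// [[Rcpp::export(name = ".cpp_all_finite")]]
bool cpp_all_finite(NumericVector x) {
  const double* p = REAL(x);
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (!std::isfinite(p[i])) return false;
  return true;
}

// Vector of standard-normal deviates; deterministic for a given seed.
// [[Rcpp::export(name = ".cpp_rnorm")]]
NumericVector cpp_rnorm(double n, double seed) {
  R_xlen_t len = (R_xlen_t)n;
  NumericVector out(len);
  ZigguratNormal z((uint64_t)seed);
  for (R_xlen_t i = 0; i < len; ++i) out[i] = z.draw();
  return out;
}

// Gaussian noise matrix scaled by sd, filled in place (one allocation,
// not zero-initialized when it will be overwritten).
// [[Rcpp::export(name = ".cpp_noise_mat")]]
NumericVector cpp_noise_mat(int nr, int nc, double sd, double seed) {
  R_xlen_t len = (R_xlen_t)nr * nc;
  if (sd == 0.0) {
    NumericVector out(len);        // zeros
    out.attr("dim") = IntegerVector::create(nr, nc);
    return out;
  }
  NumericVector out(no_init(len));
  ZigguratNormal z((uint64_t)seed);
  double* p = REAL(out);
  for (R_xlen_t i = 0; i < len; ++i) p[i] = sd * z.draw();
  out.attr("dim") = IntegerVector::create(nr, nc);
  return out;
}

// vol[rows[j], offset + k*segS + s] += W(j, s) * S(j, k): adds
// per-electrode evoked waveforms (identical across pulses up to a
// per-pulse scale) into the trace matrix. W may be wider than one segment
// so template tails continue across segment boundaries; columns beyond
// the trace are clipped.
// [[Rcpp::export(name = ".cpp_add_evoked")]]
void cpp_add_evoked(NumericMatrix vol, IntegerVector rows, NumericMatrix W,
                    NumericMatrix S, int segS, int offset) {
  int nAct = rows.size();
  int nPulse = S.ncol();
  if (W.nrow() != nAct || S.nrow() != nAct)
    stop("row mismatch in evoked accumulation");
  double* pv = REAL(vol);
  int nr = vol.nrow();
  int nc = vol.ncol();
  for (int k = 0; k < nPulse; ++k) {
    for (int s = 0; s < W.ncol(); ++s) {
      int c = offset + k * segS + s;
      if (c >= nc) break;
      double* col = pv + (R_xlen_t)c * nr;
      for (int j = 0; j < nAct; ++j)
        col[rows[j]] += W(j, s) * S(j, k);
    }
  }
}

// Cascaded biquads (direct-form II transposed), each initialized to its
// step-response steady state scaled by the first sample it sees (the
// lfilter_zi construction), which suppresses startup transients.
// Fused cascade: all sections advance per sample, state in registers.
static void sos_cascade(const std::vector<double>& coef, int ns,
                        std::vector<double>& z, double* x, int n) {
  // initialize each section's state to its step steady state, scaled by the
  // input the section actually sees (the previous sections' DC response)
  double x0 = x[0];
  for (int s = 0; s < ns; ++s) {
    const double* c = &coef[6 * s];
    double b0 = c[0], b1 = c[1], b2 = c[2], a1 = c[4], a2 = c[5];
    double den = 1.0 + a1 + a2;
    double G = den != 0.0 ? (b0 + b1 + b2) / den : 0.0;
    z[2 * s] = (b1 + b2 - (a1 + a2) * G) * x0;
    z[2 * s + 1] = (b2 - a2 * G) * x0;
    x0 = b0 * x0 + z[2 * s];   // first output sample feeds the next section
  }
  for (int i = 0; i < n; ++i) {
    double u = x[i];
    for (int s = 0; s < ns; ++s) {
      const double* c = &coef[6 * s];
      double yi = c[0] * u + z[2 * s];
      z[2 * s] = c[1] * u + z[2 * s + 1] - c[4] * yi;
      z[2 * s + 1] = c[2] * u - c[5] * yi;
      u = yi;
    }
    x[i] = u;
  }
}

// Zero-phase (forward-backward) filtering along rows of a matrix with a
// second-order-section cascade, odd reflection padding of `pad` samples and
// steady-state initialization. Rows are processed in cache-friendly blocks.
// [[Rcpp::export(name = ".cpp_sosfiltfilt_rows")]]
NumericMatrix cpp_sosfiltfilt_rows(NumericMatrix x, NumericMatrix sos, int pad) {
  int nr = x.nrow(), nc = x.ncol();
  if (sos.ncol() != 6) stop("sos must have 6 columns");
  if (pad >= nc) pad = nc - 1;
  if (pad < 0) pad = 0;
  NumericVector outv(no_init((R_xlen_t)nr * nc));
  outv.attr("dim") = IntegerVector::create(nr, nc);
  NumericMatrix out(outv);
  const int m = nc + 2 * pad;
  const int B = 32;                       // rows per block
  std::vector<double> buf((size_t)B * m);
  const double* px = REAL(x);
  double* po = REAL(out);
  const int ns = sos.nrow();
  std::vector<double> coef(6 * ns), zst(2 * ns);
  for (int s = 0; s < ns; ++s)
    for (int j = 0; j < 6; ++j) coef[6 * s + j] = sos(s, j) / sos(s, 3);
  for (int r0 = 0; r0 < nr; r0 += B) {
    int nb = std::min(B, nr - r0);
    // gather block, walking columns once
    for (int i = 0; i < nc; ++i) {
      const double* colp = px + (R_xlen_t)i * nr + r0;
      for (int j = 0; j < nb; ++j) buf[(size_t)j * m + pad + i] = colp[j];
    }
    for (int j = 0; j < nb; ++j) {
      double* rowb = &buf[(size_t)j * m];
      double x0 = rowb[pad], xn = rowb[pad + nc - 1];
      for (int i = 0; i < pad; ++i) {
        rowb[i] = 2.0 * x0 - rowb[pad + pad - i];
        rowb[pad + nc + i] = 2.0 * xn - rowb[pad + nc - 2 - i];
      }
      sos_cascade(coef, ns, zst, rowb, m);
      std::reverse(rowb, rowb + m);
      sos_cascade(coef, ns, zst, rowb, m);
      std::reverse(rowb, rowb + m);
    }
    // scatter back
    for (int i = 0; i < nc; ++i) {
      double* colp = po + (R_xlen_t)i * nr + r0;
      for (int j = 0; j < nb; ++j) colp[j] = buf[(size_t)j * m + pad + i];
    }
  }
  return out;
}

// centred 5-sample moving average (shorter at the edges); the 20-80% span
// is determined on the smoothed waveform so threshold crossings are not
// flipped by single-sample noise, while fits use the raw samples
static void smooth_ma5(const double* x, double* out, int n) {
  for (int i = 0; i < n; ++i) {
    int lo = std::max(i - 2, 0), hi = std::min(i + 2, n - 1);
    double s = 0;
    for (int j = lo; j <= hi; ++j) s += x[j];
    out[i] = s / (hi - lo + 1);
  }
}

// fEPSP slope per row: least-squares fit over the 20-80% amplitude span of
// the rising phase toward the global absolute extremum after the blank
// window (span located on the smoothed waveform). Mirrors the documented
// definition of fepspSlope().
// 20-80% rising-span indices (in post-blank space) located on the
// smoothed waveform; returns false for a flat waveform
static bool select_span(const std::vector<double>& post,
                        std::vector<int>& sel) {
  int npost = (int)post.size();
  std::vector<double> sm(npost);
  smooth_ma5(post.data(), sm.data(), npost);
  int pk = 0; double A = 0.0;
  for (int i = 0; i < npost; ++i) {
    double v = std::fabs(sm[i]);
    if (v > A) { A = v; pk = i; }
  }
  if (A == 0.0) return false;
  int i20 = -1;
  for (int i = pk; i >= 0; --i)
    if (std::fabs(sm[i]) < 0.2 * A) { i20 = i; break; }
  sel.clear();
  for (int i = i20 + 1; i <= pk; ++i) {
    double av = std::fabs(sm[i]);
    if (av >= 0.2 * A && av <= 0.8 * A) sel.push_back(i);
  }
  if ((int)sel.size() < 2) {    // fall back to the last two rising samples
    sel.clear();
    if (pk >= 1) { sel.push_back(pk - 1); sel.push_back(pk); }
    else return false;
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_slope_rows")]]
NumericVector cpp_slope_rows(NumericMatrix x, NumericVector timeMs,
                             double blankMs) {
  int nr = x.nrow(), nc = x.ncol();
  int i0 = 0;
  while (i0 < nc && timeMs[i0] <= blankMs) ++i0;
  int npost = nc - i0;
  NumericVector out(nr, 0.0);
  if (npost < 2) return out;
  std::vector<double> post(npost);
  std::vector<int> sel;
  for (int r = 0; r < nr; ++r) {
    for (int i = 0; i < npost; ++i) post[i] = x(r, i0 + i);
    if (!select_span(post, sel)) continue;
    double sx = 0, sy = 0, sxx = 0, sxy = 0;
    int n = (int)sel.size();
    for (int j = 0; j < n; ++j) {
      double t = timeMs[i0 + sel[j]], v = post[sel[j]];
      sx += t; sy += v; sxx += t * t; sxy += t * v;
    }
    double den = sxx - sx * sx / n;
    if (den > 0) out[r] = std::fabs((sxy - sx * sy / n) / den);
  }
  return out;
}

// Mean evoked waveform plus the across-trial activity statistic in one
// pass over the epoch array: returns the mean waveform, the per-electrode
// max-z statistic (|mean| / SE from the across-trial variance smoothed
// along time), and the post-blank extremum of the mean waveform.
// [[Rcpp::export(name = ".cpp_activity_stat")]]
List cpp_activity_stat(NumericVector arr, IntegerVector dims,
                       NumericVector timeMs, double blankMs, int smoothW) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  R_xlen_t plane = (R_xlen_t)d1 * d2;
  const double* p = REAL(arr);
  NumericMatrix mw(d1, d3);
  for (int s = 0; s < d3; ++s) {
    double* col = REAL(mw) + (R_xlen_t)s * d1;
    for (int k = 0; k < d2; ++k) {
      const double* ps = p + (R_xlen_t)s * plane + (R_xlen_t)k * d1;
      for (int e = 0; e < d1; ++e) col[e] += ps[e];
    }
    for (int e = 0; e < d1; ++e) col[e] /= d2;
  }
  int i0 = 0;
  while (i0 < d3 && timeMs[i0] <= blankMs) ++i0;
  int npost = d3 - i0;
  NumericVector ext(d1, 0.0), maxStat(d1, 0.0);
  IntegerVector pkIdx(d1, i0 + 1);
  for (int i = 0; i < npost; ++i) {
    const double* col = REAL(mw) + (R_xlen_t)(i0 + i) * d1;
    for (int e = 0; e < d1; ++e)
      if (std::fabs(col[e]) > std::fabs(ext[e])) {
        ext[e] = col[e]; pkIdx[e] = i0 + i + 1;
      }
  }
  if (d2 >= 2 && npost > 0) {
    // across-trial variance per (electrode, post sample)
    std::vector<double> var((size_t)d1 * npost);
    for (int i = 0; i < npost; ++i) {
      const double* mcol = REAL(mw) + (R_xlen_t)(i0 + i) * d1;
      double* vcol = &var[(size_t)i * d1];
      for (int k = 0; k < d2; ++k) {
        const double* ps = p + (R_xlen_t)(i0 + i) * plane + (R_xlen_t)k * d1;
        for (int e = 0; e < d1; ++e) {
          double dlt = ps[e] - mcol[e];
          vcol[e] += dlt * dlt;
        }
      }
      for (int e = 0; e < d1; ++e) vcol[e] /= (d2 - 1);
    }
    // centred moving average along time (shorter at the edges)
    int half = (smoothW - 1) / 2;
    std::vector<double> acc(d1), stat(d1);
    for (int e = 0; e < d1; ++e) stat[e] = 0.0;
    // prefix sums per electrode over sample index
    std::vector<double> pre((size_t)d1 * (npost + 1), 0.0);
    for (int i = 0; i < npost; ++i) {
      const double* vcol = &var[(size_t)i * d1];
      double* a = &pre[(size_t)(i + 1) * d1];
      const double* b = &pre[(size_t)i * d1];
      for (int e = 0; e < d1; ++e) a[e] = b[e] + vcol[e];
    }
    for (int i = 0; i < npost; ++i) {
      int lo = std::max(i - half, 0);
      int hi = std::min(i + (smoothW - 1 - half), npost - 1);
      double inv = 1.0 / (hi - lo + 1);
      const double* a = &pre[(size_t)(hi + 1) * d1];
      const double* b = &pre[(size_t)lo * d1];
      const double* mcol = REAL(mw) + (R_xlen_t)(i0 + i) * d1;
      for (int e = 0; e < d1; ++e) {
        double vs = (a[e] - b[e]) * inv;
        if (vs > 0) {
          double z = std::fabs(mcol[e]) / std::sqrt(vs / d2);
          if (z > stat[e]) stat[e] = z;
        } else if (std::fabs(mcol[e]) > 0) {
          stat[e] = R_PosInf;
        }
      }
    }
    for (int e = 0; e < d1; ++e) maxStat[e] = stat[e];
  }
  return List::create(_["mw"] = mw, _["maxStat"] = maxStat,
                      _["pkIdx"] = pkIdx, _["ext"] = ext);
}

// Fused epoch extraction + artifact blanking + pre-stimulus centering:
// one allocation, one pass. Semantics identical to extractEpochs() followed
// by blankAndCenter() (asserted by tests).
// [[Rcpp::export(name = ".cpp_extract_blank_center")]]
NumericVector cpp_extract_blank_center(NumericMatrix vol, IntegerVector onset,
                                       int preS, int postS,
                                       NumericVector timeMs, double blankMs) {
  int nr = vol.nrow(), nEv = onset.size(), len = preS + postS + 1;
  NumericVector arr(no_init((R_xlen_t)nr * nEv * len));
  double* pa = REAL(arr);
  const double* pv = REAL(vol);
  for (int s = 0; s < len; ++s)
    for (int k = 0; k < nEv; ++k) {
      int srcCol = onset[k] - 1 - preS + s;
      if (srcCol < 0 || srcCol >= vol.ncol())
        stop("epoch window outside the recorded trace");
      std::copy(pv + (R_xlen_t)srcCol * nr, pv + (R_xlen_t)srcCol * nr + nr,
                pa + ((R_xlen_t)s * nEv + k) * nr);
    }
  // blank: linear interpolation over samples with 0 < t <= blankMs
  if (blankMs > 0) {
    int iz = preS;                 // t = 0 sample
    int i1 = iz;
    while (i1 < len && timeMs[i1] <= blankMs) ++i1;
    if (i1 >= len) stop("no sample beyond the blank window");
    R_xlen_t plane = (R_xlen_t)nr * nEv;
    for (int j = iz + 1; j < i1; ++j) {
      double w = (timeMs[j] - timeMs[iz]) / (timeMs[i1] - timeMs[iz]);
      double* pj = pa + (R_xlen_t)j * plane;
      const double* p0 = pa + (R_xlen_t)iz * plane;
      const double* p1 = pa + (R_xlen_t)i1 * plane;
      for (R_xlen_t q = 0; q < plane; ++q)
        pj[q] = p0[q] * (1.0 - w) + p1[q] * w;
    }
  }
  // centre on the pre-stimulus (t < 0) mean per epoch per electrode
  if (preS > 0) {
    R_xlen_t plane = (R_xlen_t)nr * nEv;
    std::vector<double> mu(plane, 0.0);
    int npre = 0;
    for (int s = 0; s < len; ++s) {
      if (!(timeMs[s] < 0)) continue;
      const double* ps = pa + (R_xlen_t)s * plane;
      for (R_xlen_t q = 0; q < plane; ++q) mu[q] += ps[q];
      ++npre;
    }
    if (npre > 0) {
      for (R_xlen_t q = 0; q < plane; ++q) mu[q] /= npre;
      for (int s = 0; s < len; ++s) {
        double* ps = pa + (R_xlen_t)s * plane;
        for (R_xlen_t q = 0; q < plane; ++q) ps[q] -= mu[q];
      }
    }
  }
  arr.attr("dim") = IntegerVector::create(nr, nEv, len);
  return arr;
}

// Per-pulse fEPSP slopes with the fit window fixed per electrode from the
// mean evoked waveform: the 20-80% amplitude span of the rising phase
// toward the mean waveform's global absolute extremum. Fitting each pulse
// over a fixed window keeps the estimator unbiased under additive noise
// (window selection on noisy single epochs attenuates slopes).
// arr is the [electrodes x pulses x samples] epoch array.
// [[Rcpp::export(name = ".cpp_epoch_slopes")]]
NumericMatrix cpp_epoch_slopes(NumericVector arr, IntegerVector dims,
                               IntegerVector channels, NumericVector timeMs,
                               double blankMs) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int i0 = 0;
  while (i0 < d3 && timeMs[i0] <= blankMs) ++i0;
  int npost = d3 - i0;
  NumericMatrix out(channels.size(), d2);
  if (npost < 2) return out;
  const double* p = REAL(arr);
  std::vector<double> m(npost);
  std::vector<int> sel;
  for (int c = 0; c < channels.size(); ++c) {
    R_xlen_t e = channels[c] - 1;
    for (int i = 0; i < npost; ++i) {
      double s = 0;
      for (int k = 0; k < d2; ++k)
        s += p[e + (R_xlen_t)k * d1 + (R_xlen_t)(i0 + i) * d1 * d2];
      m[i] = s / d2;
    }
    if (!select_span(m, sel)) continue;
    int n = (int)sel.size();
    double sx = 0, sxx = 0;
    for (int j = 0; j < n; ++j) {
      double t = timeMs[i0 + sel[j]];
      sx += t; sxx += t * t;
    }
    double den = sxx - sx * sx / n;
    if (den <= 0) continue;
    for (int k = 0; k < d2; ++k) {
      double sy = 0, sxy = 0;
      for (int j = 0; j < n; ++j) {
        double v = p[e + (R_xlen_t)k * d1 + (R_xlen_t)(i0 + sel[j]) * d1 * d2];
        sy += v; sxy += timeMs[i0 + sel[j]] * v;
      }
      out(c, k) = std::fabs((sxy - sx * sy / n) / den);
    }
  }
  return out;
}

// Row-wise min and max over a column range.
// [[Rcpp::export(name = ".cpp_row_minmax")]]
List cpp_row_minmax(NumericMatrix x, int from, int to) {
  int nr = x.nrow();
  NumericVector mn(nr, R_PosInf), mx(nr, R_NegInf);
  for (int i = from - 1; i < to; ++i) {
    const double* col = REAL(x) + (R_xlen_t)i * nr;
    for (int r = 0; r < nr; ++r) {
      if (col[r] < mn[r]) mn[r] = col[r];
      if (col[r] > mx[r]) mx[r] = col[r];
    }
  }
  return List::create(_["min"] = mn, _["max"] = mx);
}

// Global absolute extremum (and its index) per row over a column range;
// used for peak scans over large epoch matrices.
// [[Rcpp::export(name = ".cpp_row_extremum")]]
List cpp_row_extremum(NumericMatrix x, int from, int to) {
  int nr = x.nrow();
  NumericVector val(nr, 0.0);
  IntegerVector idx(nr, from);
  for (int i = from - 1; i < to; ++i) {
    const double* col = REAL(x) + (R_xlen_t)i * nr;
    for (int r = 0; r < nr; ++r) {
      if (std::fabs(col[r]) > std::fabs(val[r])) {
        val[r] = col[r];
        idx[r] = i + 1;
      }
    }
  }
  return List::create(_["value"] = val, _["index"] = idx);
}
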