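#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Volumes are R arrays dim = c(n1, n2, n3), column-major:
// linear index = i + n1*j + n1*n2*k for 0-based (i, j, k).
// Axis 1 is the axial (slice) axis. Physical position of voxel (i,j,k) is
// origin + voxel_mm * (i, j, k) (voxel-center convention).

static inline R_xlen_t lin(int i, int j, int k, int n1, int n2) {
  return (R_xlen_t)i + (R_xlen_t)n1 * ((R_xlen_t)j + (R_xlen_t)n2 * (R_xlen_t)k);
}

// ---- trilinear / nearest sampling ------------------------------------------

static bool sample_tri(const double* v, const int* ok, int n1, int n2, int n3,
                       double u1, double u2, double u3, bool nearest,
                       double* out) {
  if (nearest) {
    int i = (int)std::lround(u1), j = (int)std::lround(u2), k = (int)std::lround(u3);
    if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) return false;
    R_xlen_t id = lin(i, j, k, n1, n2);
    if (ok && !ok[id]) return false;
    *out = v[id];
    return true;
  }
  int i0 = (int)std::floor(u1), j0 = (int)std::floor(u2), k0 = (int)std::floor(u3);
  if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + 1 >= n1 || j0 + 1 >= n2 || k0 + 1 >= n3) {
    // allow exact top boundary
    if (u1 >= 0 && u2 >= 0 && u3 >= 0 &&
        u1 <= n1 - 1 && u2 <= n2 - 1 && u3 <= n3 - 1) {
      i0 = std::min(i0, n1 - 2); j0 = std::min(j0, n2 - 2); k0 = std::min(k0, n3 - 2);
      if (i0 < 0 || j0 < 0 || k0 < 0) return false;
    } else return false;
  }
  double f1 = u1 - i0, f2 = u2 - j0, f3 = u3 - k0;
  double acc = 0.0;
  for (int di = 0; di < 2; ++di)
    for (int dj = 0; dj < 2; ++dj)
      for (int dk = 0; dk < 2; ++dk) {
        double w = (di ? f1 : 1 - f1) * (dj ? f2 : 1 - f2) * (dk ? f3 : 1 - f3);
        R_xlen_t id = lin(i0 + di, j0 + dj, k0 + dk, n1, n2);
        if (ok && !ok[id]) {
          if (w > 1e-12) return false; // collapsing weights tolerate invalid corner
          continue;
        }
        acc += w * v[id];
      }
  *out = acc;
  return true;
}

// Resample a moving volume onto a target grid. The mapping fixed->moving is the
// affine x = A %*% y + b (physical mm), i.e. the inverse of the moving->fixed
// rigid transform, precomputed in R.
// [[Rcpp::export]]
List cpp_resample_rigid(NumericVector mov, LogicalVector movValid,
                        IntegerVector mdim, NumericVector morigin,
                        IntegerVector fdim, NumericVector forigin,
                        double voxel, NumericMatrix A, NumericVector b,
                        bool nearest, double fill) {
  int m1 = mdim[0], m2 = mdim[1], m3 = mdim[2];
  int f1 = fdim[0], f2 = fdim[1], f3 = fdim[2];
  R_xlen_t nout = (R_xlen_t)f1 * f2 * f3;
  NumericVector out(nout);
  LogicalVector outv(nout);
  const double* v = REAL(mov);
  const int* ok = LOGICAL(movValid);
  double a11 = A(0,0), a12 = A(0,1), a13 = A(0,2);
  double a21 = A(1,0), a22 = A(1,1), a23 = A(1,2);
  double a31 = A(2,0), a32 = A(2,1), a33 = A(2,2);
  R_xlen_t id = 0;
  for (int k = 0; k < f3; ++k) {
    double y3 = forigin[2] + voxel * k;
    for (int j = 0; j < f2; ++j) {
      double y2 = forigin[1] + voxel * j;
      for (int i = 0; i < f1; ++i, ++id) {
        double y1 = forigin[0] + voxel * i;
        double x1 = a11*y1 + a12*y2 + a13*y3 + b[0];
        double x2 = a21*y1 + a22*y2 + a23*y3 + b[1];
        double x3 = a31*y1 + a32*y2 + a33*y3 + b[2];
        double u1 = (x1 - morigin[0]) / voxel;
        double u2 = (x2 - morigin[1]) / voxel;
        double u3 = (x3 - morigin[2]) / voxel;
        double val;
        if (sample_tri(v, ok, m1, m2, m3, u1, u2, u3, nearest, &val)) {
          out[id] = val; outv[id] = true;
        } else {
          out[id] = fill; outv[id] = false;
        }
      }
    }
  }
  return List::create(_["data"] = out, _["valid"] = outv);
}

// Normalized cross-correlation between fixed values at given physical points
// and the moving volume sampled at the mapped points x = A y + b.
// Returns c(ncc, n_valid_points).
// [[Rcpp::export]]
NumericVector cpp_ncc_points(NumericVector mov, LogicalVector movValid,
                             IntegerVector mdim, NumericVector morigin,
                             double voxel, NumericMatrix pts,
                             NumericVector fvals, NumericMatrix A,
                             NumericVector b) {
  int m1 = mdim[0], m2 = mdim[1], m3 = mdim[2];
  const double* v = REAL(mov);
  const int* ok = LOGICAL(movValid);
  double a11 = A(0,0), a12 = A(0,1), a13 = A(0,2);
  double a21 = A(1,0), a22 = A(1,1), a23 = A(1,2);
  double a31 = A(2,0), a32 = A(2,1), a33 = A(2,2);
  int n = pts.nrow();
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  int m = 0;
  for (int p = 0; p < n; ++p) {
    double y1 = pts(p,0), y2 = pts(p,1), y3 = pts(p,2);
    double x1 = a11*y1 + a12*y2 + a13*y3 + b[0];
    double x2 = a21*y1 + a22*y2 + a23*y3 + b[1];
    double x3 = a31*y1 + a32*y2 + a33*y3 + b[2];
    double val;
    if (!sample_tri(v, ok, m1, m2, m3,
                    (x1 - morigin[0]) / voxel,
                    (x2 - morigin[1]) / voxel,
                    (x3 - morigin[2]) / voxel, false, &val)) continue;
    double f = fvals[p];
    sx += f; sy += val; sxx += f*f; syy += val*val; sxy += f*val;
    ++m;
  }
  if (m < 10) return NumericVector::create(-1.0, (double)m);
  double vx = sxx - sx*sx/m, vy = syy - sy*sy/m, cv = sxy - sx*sy/m;
  double denom = std::sqrt(vx * vy);
  double ncc = (denom > 1e-12) ? cv / denom : 0.0;
  return NumericVector::create(ncc, (double)m);
}

// ---- constrained Gaussian filter -------------------------------------------

// Gaussian of width sigma truncated to a cube of half-width `radius` voxels,
// renormalized over the valid, in-bounds neighborhood of each voxel so that
// invalid voxels contribute neither weight nor value.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, LogicalVector valid,
                         IntegerVector dim, double sigma, int radius) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  const double* v = REAL(vol);
  const int* ok = LOGICAL(valid);
  int w = 2 * radius + 1;
  std::vector<double> kern((size_t)w * w * w);
  for (int dk = -radius; dk <= radius; ++dk)
    for (int dj = -radius; dj <= radius; ++dj)
      for (int di = -radius; di <= radius; ++di)
        kern[(size_t)(di + radius) + w * ((size_t)(dj + radius) + w * (size_t)(dk + radius))] =
          std::exp(-0.5 * (di*di + dj*dj + dk*dk) / (sigma * sigma));
  R_xlen_t id = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++id) {
        double acc = 0, wsum = 0;
        for (int dk = -radius; dk <= radius; ++dk) {
          int kk = k + dk; if (kk < 0 || kk >= n3) continue;
          for (int dj = -radius; dj <= radius; ++dj) {
            int jj = j + dj; if (jj < 0 || jj >= n2) continue;
            for (int di = -radius; di <= radius; ++di) {
              int ii = i + di; if (ii < 0 || ii >= n1) continue;
              R_xlen_t q = lin(ii, jj, kk, n1, n2);
              if (!ok[q]) continue;
              double kw = kern[(size_t)(di + radius) + w * ((size_t)(dj + radius) + w * (size_t)(dk + radius))];
              acc += kw * v[q]; wsum += kw;
            }
          }
        }
        out[id] = (wsum > 0) ? acc / wsum : v[id];
      }
  return out;
}

// ---- morphology ------------------------------------------------------------

// Chebyshev-ball (cube) dilation/erosion via separable 1D running max/min.
// [[Rcpp::export]]
LogicalVector cpp_morph_box(LogicalVector mask, IntegerVector dim, int r,
                            bool dilate) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> a(n), bbuf(n);
  for (R_xlen_t t = 0; t < n; ++t) a[t] = mask[t] ? 1 : 0;
  char ident = dilate ? 0 : 1;
  // pass along each axis
  for (int axis = 0; axis < 3; ++axis) {
    int len = (axis == 0) ? n1 : (axis == 1) ? n2 : n3;
    R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)n1 : (R_xlen_t)n1 * n2;
    R_xlen_t nlines = n / len;
    for (R_xlen_t L = 0; L < nlines; ++L) {
      // compute base offset of this line
      R_xlen_t base;
      if (axis == 0) {
        base = L * n1;
      } else if (axis == 1) {
        R_xlen_t i = L % n1, k = L / n1;
        base = i + (R_xlen_t)n1 * n2 * k;
      } else {
        base = L;
      }
      for (int p = 0; p < len; ++p) {
        char acc = ident;
        int lo = std::max(0, p - r), hi = std::min(len - 1, p + r);
        for (int q = lo; q <= hi; ++q) {
          char val = a[base + (R_xlen_t)q * stride];
          if (dilate) { if (val) { acc = 1; break; } }
          else { if (!val) { acc = 0; break; } }
        }
        bbuf[base + (R_xlen_t)p * stride] = acc;
      }
    }
    std::swap(a, bbuf);
  }
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = a[t] != 0;
  return out;
}

// ---- connected components --------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int conn) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n); // zero-initialized
  std::vector<R_xlen_t> stack;
  int next = 0;
  std::vector<int> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (conn == 6 && manh != 1) continue;
        offs.push_back(di); offs.push_back(dj); offs.push_back(dk);
      }
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur % n1);
      int j = (int)((cur / n1) % n2);
      int k = (int)(cur / ((R_xlen_t)n1 * n2));
      for (size_t o = 0; o < offs.size(); o += 3) {
        int ii = i + offs[o], jj = j + offs[o+1], kk = k + offs[o+2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3) continue;
        R_xlen_t q = lin(ii, jj, kk, n1, n2);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Slice-wise (axis 1 fixed) hole fill: complement voxels in each (j,k) plane
// not 4-connected to the plane border are filled.
// [[Rcpp::export]]
LogicalVector cpp_fill_slices(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = mask[t];
  std::vector<char> reach((size_t)n2 * n3);
  std::vector<std::pair<int,int>> stack;
  for (int i = 0; i < n1; ++i) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int j = 0; j < n2; ++j)
      for (int k = 0; k < n3; ++k) {
        if (j == 0 || k == 0 || j == n2 - 1 || k == n3 - 1) {
          if (!mask[lin(i, j, k, n1, n2)] && !reach[(size_t)j + (size_t)n2 * k]) {
            reach[(size_t)j + (size_t)n2 * k] = 1;
            stack.push_back({j, k});
          }
        }
      }
    while (!stack.empty()) {
      auto [j, k] = stack.back(); stack.pop_back();
      const int dj[4] = {1, -1, 0, 0}, dk[4] = {0, 0, 1, -1};
      for (int o = 0; o < 4; ++o) {
        int jj = j + dj[o], kk = k + dk[o];
        if (jj < 0 || kk < 0 || jj >= n2 || kk >= n3) continue;
        if (mask[lin(i, jj, kk, n1, n2)]) continue;
        if (reach[(size_t)jj + (size_t)n2 * kk]) continue;
        reach[(size_t)jj + (size_t)n2 * kk] = 1;
        stack.push_back({jj, kk});
      }
    }
    for (int j = 0; j < n2; ++j)
      for (int k = 0; k < n3; ++k)
        if (!mask[lin(i, j, k, n1, n2)] && !reach[(size_t)j + (size_t)n2 * k])
          out[lin(i, j, k, n1, n2)] = true;
  }
  return out;
}

// ---- remodeling planting ---------------------------------------------------

// Greedy planting of formation/resorption events against the *filtered*
// volume. Seeds are visited in the given (pre-shuffled) order; around each
// seed a small patch of eligible voxels (inside `zone`) is tentatively set
// to the new density, the filtered values of the affected window are
// recomputed, and the patch is committed only if the local threshold-
// crossing changes are admissible:
//   - patch members must cross the target threshold in the intended
//     direction;
//   - any other voxel may change crossing status only where no *other*
//     planting event is targeted: `protmask` carries, per voxel, a bitmask
//     of the events whose measurement cell contains it, and
//     `event_thresholds` their target thresholds; a crossing at another
//     event's (cell, threshold) rejects the patch, as does re-crossing of an
//     already-committed (touched) voxel at the current target;
//   - crossings at the current event's (cell, threshold) are genuine
//     remodeling the measurement will see: they count toward n_target, and
//     the running count may never exceed it.
// This makes planted counts exactly recoverable by the threshold-difference
// measurement on noise-free, motion-free volumes.
// [[Rcpp::export]]
List cpp_plant(NumericVector vol, NumericVector filt, IntegerVector dim,
               NumericVector event_thresholds, int cur_event, double targetT,
               int n_target, double new_density, bool formation,
               double sigma, int radius, IntegerVector candidates,
               LogicalVector zone, IntegerVector protmask,
               LogicalVector touched, int patch_max) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector raw = clone(vol);
  NumericVector W = clone(filt);
  LogicalVector touch = clone(touched);
  int w = 2 * radius + 1;
  std::vector<double> kern((size_t)w * w * w);
  for (int dk = -radius; dk <= radius; ++dk)
    for (int dj = -radius; dj <= radius; ++dj)
      for (int di = -radius; di <= radius; ++di)
        kern[(size_t)(di + radius) + w * ((size_t)(dj + radius) + w * (size_t)(dk + radius))] =
          std::exp(-0.5 * (di*di + dj*dj + dk*dk) / (sigma * sigma));
  int ne = event_thresholds.size();
  std::vector<R_xlen_t> planted;
  int n_flipped = 0;

  auto filt_at = [&](int qi, int qj, int qk) {
    double acc = 0, wsum = 0;
    for (int ek = -radius; ek <= radius; ++ek) {
      int rk = qk + ek; if (rk < 0 || rk >= n3) continue;
      for (int ej = -radius; ej <= radius; ++ej) {
        int rj = qj + ej; if (rj < 0 || rj >= n2) continue;
        for (int ei = -radius; ei <= radius; ++ei) {
          int ri = qi + ei; if (ri < 0 || ri >= n1) continue;
          double kw = kern[(size_t)(ei + radius) + w * ((size_t)(ej + radius) + w * (size_t)(ek + radius))];
          acc += kw * raw[lin(ri, rj, rk, n1, n2)];
          wsum += kw;
        }
      }
    }
    return acc / wsum;
  };

  auto eligible = [&](R_xlen_t q) {
    if (!zone[q] || touch[q]) return false;
    return formation ? (W[q] < targetT) : (W[q] >= targetT);
  };

  std::vector<R_xlen_t> patch;
  std::vector<double> old_raw;
  std::vector<R_xlen_t> win;
  std::vector<double> winW;
  std::vector<R_xlen_t> flips;

  for (int c = 0; c < candidates.size() && n_flipped < n_target; ++c) {
    R_xlen_t p = (R_xlen_t)candidates[c];
    if (!eligible(p)) continue;
    int pi = (int)(p % n1), pj = (int)((p / n1) % n2), pk = (int)(p / ((R_xlen_t)n1 * n2));
    int remaining = n_target - n_flipped;

    for (int want = std::min(patch_max, remaining); want >= 1;
         want = (want > 1 ? 1 : 0)) {
      patch.clear(); old_raw.clear();
      patch.push_back(p);
      if (want > 1) {
        for (int dk = -1; dk <= 1 && (int)patch.size() < want; ++dk) {
          int qk = pk + dk; if (qk < 0 || qk >= n3) continue;
          for (int dj = -1; dj <= 1 && (int)patch.size() < want; ++dj) {
            int qj = pj + dj; if (qj < 0 || qj >= n2) continue;
            for (int di = -1; di <= 1 && (int)patch.size() < want; ++di) {
              int qi = pi + di; if (qi < 0 || qi >= n1) continue;
              if (di == 0 && dj == 0 && dk == 0) continue;
              R_xlen_t q = lin(qi, qj, qk, n1, n2);
              if (eligible(q)) patch.push_back(q);
            }
          }
        }
      }
      for (R_xlen_t q : patch) { old_raw.push_back(raw[q]); raw[q] = new_density; }

      // evaluate the patch; members that fail to cross are trimmed away and
      // the remainder re-evaluated, so patches shrink to their supported core
      int wr = 1 + radius;
      bool ok = true;
      int step_flips = 0;
      while (true) {
        win.clear(); winW.clear(); flips.clear();
        ok = true;
        step_flips = 0;
        std::vector<size_t> failing;
        for (int dk = -wr; dk <= wr && ok; ++dk) {
          int qk = pk + dk; if (qk < 0 || qk >= n3) continue;
          for (int dj = -wr; dj <= wr && ok; ++dj) {
            int qj = pj + dj; if (qj < 0 || qj >= n2) continue;
            for (int di = -wr; di <= wr && ok; ++di) {
              int qi = pi + di; if (qi < 0 || qi >= n1) continue;
              R_xlen_t q = lin(qi, qj, qk, n1, n2);
              double nv = filt_at(qi, qj, qk);
              int patch_pos = -1;
              for (size_t pp = 0; pp < patch.size(); ++pp)
                if (patch[pp] == q) { patch_pos = (int)pp; break; }
              if (patch_pos >= 0) {
                // must cross the target in the intended direction
                if (formation ? (nv < targetT) : (nv >= targetT)) {
                  failing.push_back((size_t)patch_pos);
                } else {
                  ++step_flips;
                  flips.push_back(q);
                  // crossings at another event's (cell, threshold) are vetoed
                  for (int e = 0; e < ne && ok; ++e) {
                    if (e == cur_event) continue;
                    double t = event_thresholds[e];
                    if (((protmask[q] >> e) & 1) &&
                        (W[q] >= t) != (nv >= t)) ok = false;
                  }
                }
              } else {
                for (int e = 0; e < ne && ok; ++e) {
                  double t = event_thresholds[e];
                  if ((W[q] >= t) == (nv >= t)) continue; // no crossing there
                  if (!((protmask[q] >> e) & 1)) continue; // not that event's cell
                  if (e != cur_event || touch[q]) { ok = false; break; }
                  ++step_flips;
                  flips.push_back(q);
                }
              }
              win.push_back(q); winW.push_back(nv);
            }
          }
        }
        if (ok && !failing.empty() && patch.size() > 1) {
          std::sort(failing.begin(), failing.end());
          for (auto it = failing.rbegin(); it != failing.rend(); ++it) {
            raw[patch[*it]] = old_raw[*it];
            patch.erase(patch.begin() + *it);
            old_raw.erase(old_raw.begin() + *it);
          }
          if (patch.empty()) { ok = false; break; }
          continue;
        }
        if (!failing.empty()) ok = false;
        if (ok && (n_flipped + step_flips) > n_target && patch.size() > 1) {
          // overshoot: shed a member and retry
          raw[patch.back()] = old_raw.back();
          patch.pop_back(); old_raw.pop_back();
          continue;
        }
        break;
      }
      if (ok && (n_flipped + step_flips) > n_target) ok = false;
      if (ok && step_flips == 0) ok = false;
      if (!ok) {
        for (size_t t = 0; t < patch.size(); ++t) raw[patch[t]] = old_raw[t];
        continue; // retry with a singleton patch, or give up on this seed
      }
      for (size_t t = 0; t < win.size(); ++t) W[win[t]] = winW[t];
      for (R_xlen_t q : patch) touch[q] = true;
      for (R_xlen_t q : flips) {
        touch[q] = true;
        planted.push_back(q);
      }
      n_flipped += step_flips;
      break;
    }
  }
  IntegerVector out_idx(planted.size());
  for (size_t t = 0; t < planted.size(); ++t) out_idx[t] = (int)planted[t];
  return List::create(_["vol"] = raw, _["filt"] = W, _["planted"] = out_idx,
                      _["touched"] = touch,
                      _["n_planted"] = n_flipped);
}
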