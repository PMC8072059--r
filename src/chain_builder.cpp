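// Monte-Carlo growth of peptide backbones from binned Ramachandran coil
// statistics, with CA-level clash avoidance and incremental rejection
// against Gaussian distance restraints evaluated at surrogate label
// positions. All randomness comes from R's RNG (unif_rand), so runs are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;
// ideal backbone geometry (trans peptide)
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329,
                    B_C_O = 1.231;
static const double A_N_CA_C = 111.0 * DEG, A_CA_C_N = 116.6 * DEG,
                    A_C_N_CA = 121.7 * DEG, A_CA_C_O = 120.8 * DEG;
static const double TET = 110.0 * DEG; // N-CA-label-direction angle

struct Vec3 { double x, y, z; };

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 add(const Vec3 &a, const Vec3 &b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
static inline Vec3 scale(const Vec3 &a, double s) {
  return {a.x * s, a.y * s, a.z * s};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }
static inline Vec3 unit(const Vec3 &a) {
  double n = norm(a);
  return {a.x / n, a.y / n, a.z / n};
}
static inline double dist(const Vec3 &a, const Vec3 &b) {
  Vec3 d = sub(a, b);
  return norm(d);
}

// natural extension reference frame: place D bonded to C, with bond length
// r, angle B-C-D = theta, torsion A-B-C-D = chi
static Vec3 nerf(const Vec3 &A, const Vec3 &B, const Vec3 &C,
                 double r, double theta, double chi) {
  Vec3 bc = unit(sub(C, B));
  Vec3 n = unit(cross(sub(B, A), bc));
  Vec3 m = cross(n, bc);
  double d2 = r * std::sin(theta);
  Vec3 d = {-r * std::cos(theta),
            d2 * std::cos(chi),
            d2 * std::sin(chi)};
  return {C.x + d.x * bc.x + d.y * m.x + d.z * n.x,
          C.y + d.x * bc.y + d.y * m.y + d.z * n.y,
          C.z + d.x * bc.z + d.y * m.z + d.z * n.z};
}

// direction of an ideal tetrahedral pseudo-CB from the local N, CA, C frame;
// the sign of the out-of-plane component selects the L-configuration
static Vec3 label_direction(const Vec3 &N, const Vec3 &CA, const Vec3 &C) {
  Vec3 d1 = unit(sub(N, CA));
  Vec3 d2 = unit(sub(C, CA));
  double c = dot(d1, d2);
  double a = std::cos(TET) / (1.0 + c);
  double rest = 1.0 - a * a * (2.0 + 2.0 * c);
  if (rest < 0) rest = 0;
  double b = std::sqrt(rest / (1.0 - c * c));
  Vec3 u = add(scale(add(d1, d2), a), scale(cross(d1, d2), b));
  return unit(u);
}

// sample a joint (phi, psi) bin from a per-class CDF over nb x nb bins of
// width bw degrees, with uniform jitter inside the bin
static void sample_phipsi(const NumericMatrix &cdf, int cls, int nb,
                          double bw, double &phi, double &psi) {
  double u = unif_rand();
  int lo = 0, hi = nb * nb - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf(cls, mid) < u) lo = mid + 1; else hi = mid;
  }
  int iphi = lo / nb, ipsi = lo % nb;
  phi = (-180.0 + (iphi + unif_rand()) * bw) * DEG;
  psi = (-180.0 + (ipsi + unif_rand()) * bw) * DEG;
}

// [[Rcpp::export]]
List cpp_build_conformers(int n_conf, int n_res, IntegerVector cls,
                          NumericMatrix cdf, int n_bins, double bin_width,
                          NumericMatrix restraints, double threshold,
                          double label_offset,
                          NumericMatrix anchor_frame,  // 3 x 3 (N, CA, C) or 0-row
                          NumericMatrix anchor_ca,     // m x 3 anchor CA coords
                          NumericMatrix anchor_labels, // k x 4: site, x, y, z
                          int res_offset,              // numbering offset of res 1
                          double clash_ca, double clash_anchor,
                          int max_attempts) {
  const bool tethered = anchor_frame.nrow() == 3;
  const int n_restr = restraints.nrow();
  NumericVector coords(static_cast<R_xlen_t>(n_conf) * n_res * 4 * 3);
  IntegerVector attempts_out(n_conf);
  LogicalVector success(n_conf);

  std::vector<Vec3> N(n_res), CA(n_res), C(n_res), O(n_res);
  std::vector<Vec3> lab(n_res);
  std::vector<bool> lab_ok(n_res);

  // anchor-site label positions indexed by construct residue number
  std::vector<int> anc_site(anchor_labels.nrow());
  std::vector<Vec3> anc_pos(anchor_labels.nrow());
  for (int i = 0; i < anchor_labels.nrow(); ++i) {
    anc_site[i] = static_cast<int>(anchor_labels(i, 0));
    anc_pos[i] = {anchor_labels(i, 1), anchor_labels(i, 2),
                  anchor_labels(i, 3)};
  }

  for (int ic = 0; ic < n_conf; ++ic) {
    bool done = false;
    int att = 0;
    while (!done && att < max_attempts) {
      ++att;
      std::fill(lab_ok.begin(), lab_ok.end(), false);
      double logp = 0.0;
      bool dead = false;
      Vec3 prevN, prevCA, prevC;
      double psi_prev = 0.0; // psi of the residue preceding the current one
      if (tethered) {
        prevN = {anchor_frame(0, 0), anchor_frame(0, 1), anchor_frame(0, 2)};
        prevCA = {anchor_frame(1, 0), anchor_frame(1, 1), anchor_frame(1, 2)};
        prevC = {anchor_frame(2, 0), anchor_frame(2, 1), anchor_frame(2, 2)};
        double dum_phi;
        sample_phipsi(cdf, cls[0], n_bins, bin_width, dum_phi, psi_prev);
      }

      for (int i = 0; i < n_res && !dead; ++i) {
        double phi, psi;
        sample_phipsi(cdf, cls[i], n_bins, bin_width, phi, psi);
        if (i == 0 && !tethered) {
          // seed frame: virtual previous carbonyl fixes phi's reference
          Vec3 vC = {-0.56, 1.23, 0.0};
          N[0] = {0.0, 0.0, 0.0};
          CA[0] = {B_N_CA, 0.0, 0.0};
          C[0] = nerf(vC, N[0], CA[0], B_CA_C, A_N_CA_C, phi);
          O[0] = nerf(N[0], CA[0], C[0], B_C_O, A_CA_C_O, psi + M_PI);
        } else {
          Vec3 pN = (i == 0) ? prevN : N[i - 1];
          Vec3 pCA = (i == 0) ? prevCA : CA[i - 1];
          Vec3 pC = (i == 0) ? prevC : C[i - 1];
          // N_i from the previous residue's psi, then trans omega
          N[i] = nerf(pN, pCA, pC, B_C_N, A_CA_C_N, psi_prev);
          CA[i] = nerf(pCA, pC, N[i], B_N_CA, A_C_N_CA, M_PI);
          C[i] = nerf(pC, N[i], CA[i], B_CA_C, A_N_CA_C, phi);
          O[i] = nerf(N[i], CA[i], C[i], B_C_O, A_CA_C_O, psi + M_PI);
        }
        psi_prev = psi;

        // clash checks on CA_i
        for (int j = 0; j <= i - 3; ++j) {
          if (dist(CA[i], CA[j]) < clash_ca) { dead = true; break; }
        }
        if (!dead && tethered) {
          for (int j = 0; j < anchor_ca.nrow(); ++j) {
            Vec3 a = {anchor_ca(j, 0), anchor_ca(j, 1), anchor_ca(j, 2)};
            if (dist(CA[i], a) < clash_anchor) { dead = true; break; }
          }
        }
        if (dead) break;

        // label position for residue i is available once C_i is placed
        lab[i] = add(CA[i], scale(label_direction(N[i], CA[i], C[i]),
                                  label_offset));
        lab_ok[i] = true;

        // evaluate restraints whose second-completed site is residue i
        if (n_restr > 0) {
          int site_now = res_offset + i + 1;
          for (int m = 0; m < n_restr && !dead; ++m) {
            int si = static_cast<int>(restraints(m, 0));
            int sj = static_cast<int>(restraints(m, 1));
            int hi_site = si > sj ? si : sj;
            if (hi_site != site_now) continue;
            int lo_site = si < sj ? si : sj;
            Vec3 p1, p2 = lab[i];
            bool have = false;
            if (lo_site > res_offset) {
              int k = lo_site - res_offset - 1;
              if (k >= 0 && lab_ok[k]) { p1 = lab[k]; have = true; }
            } else {
              for (size_t k = 0; k < anc_site.size(); ++k) {
                if (anc_site[k] == lo_site) { p1 = anc_pos[k]; have = true; }
              }
            }
            if (!have) continue;
            double d = dist(p1, p2);
            double mu = restraints(m, 2), s = restraints(m, 3);
            logp += -(d - mu) * (d - mu) / (2.0 * s * s);
            if (logp < std::log(threshold)) { dead = true; }
          }
        }
      }
      if (!dead) {
        done = true;
        R_xlen_t base = static_cast<R_xlen_t>(ic) * n_res * 4 * 3;
        for (int i = 0; i < n_res; ++i) {
          const Vec3 *at[4] = {&N[i], &CA[i], &C[i], &O[i]};
          for (int a = 0; a < 4; ++a) {
            R_xlen_t k = base + (static_cast<R_xlen_t>(i) * 4 + a) * 3;
            coords[k] = at[a]->x;
            coords[k + 1] = at[a]->y;
            coords[k + 2] = at[a]->z;
          }
        }
      }
    }
    attempts_out[ic] = att;
    success[ic] = done;
    if (ic % 64 == 0) Rcpp::checkUserInterrupt();
  }

  coords.attr("dim") = IntegerVector::create(3, 4 * n_res, n_conf);
  return List::create(_["coords"] = coords, _["attempts"] = attempts_out,
                      _["success"] = success);
}
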