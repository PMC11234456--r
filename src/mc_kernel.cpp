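// White Monte Carlo photon transport in a two-layer slab.
//
// The two layers share the scattering coefficient and anisotropy, so with
// zero absorption the transport medium is homogeneous; the epidermis/dermis
// boundary at z = t_epi only partitions each photon's pathlength for the
// Beer-Lambert absorption step applied afterwards. Photons are launched as a
// pencil beam normally into the surface at z = 0 (z grows downward); all
// photons exiting the top surface are detected regardless of position and
// angle. Fresnel reflection at the tissue-air boundary is handled
// probabilistically; specular reflection of the incident beam is excluded
// (the photon starts inside the medium).

#include <Rcpp.h>
using namespace Rcpp;

static inline double path_in_epi(double z1, double z2, double seg, double t_epi) {
  // length of the segment z1 -> z2 (geometric length seg) lying in [0, t_epi]
  double lo = z1 < z2 ? z1 : z2, hi = z1 < z2 ? z2 : z1;
  if (hi == lo) return (z1 < t_epi) ? seg : 0.0;
  double a = lo > 0.0 ? lo : 0.0;
  double b = hi < t_epi ? hi : t_epi;
  if (b <= a) return 0.0;
  return seg * (b - a) / (hi - lo);
}

static inline double hg_cos(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline void scatter(double &ux, double &uy, double &uz, double g) {
  double ct = hg_cos(g);
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -st * cp * den + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
}

// [[Rcpp::export]]
List cpp_white_mc(double t_epi, double mu_s, double g, int n_photons,
                  double n_rel, double max_path) {
  std::vector<double> p_epi, p_derm;
  p_epi.reserve(n_photons);
  p_derm.reserve(n_photons);
  int truncated = 0;
  const double crit_sin = (n_rel > 1.0) ? 1.0 / n_rel : 2.0;

  for (int i = 0; i < n_photons; ++i) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double le = 0.0, ld = 0.0, total = 0.0;
    bool alive = true, detected = false;

    while (alive) {
      double s = -std::log(unif_rand()) / mu_s;
      double z2 = z + uz * s;
      if (z2 < 0.0) {
        // hits the top surface: advance to the boundary, then Fresnel
        double sb = -z / uz;  // uz < 0 here
        double zb = 0.0;
        double de = path_in_epi(z, zb, sb, t_epi);
        le += de; ld += sb - de; total += sb;
        x += ux * sb; y += uy * sb; z = 0.0;
        if (total > max_path) { truncated++; break; }
        double ci = -uz;  // cosine of incidence against surface normal
        bool exits;
        if (n_rel <= 1.0) {
          exits = true;
        } else {
          double si = std::sqrt(1.0 - ci * ci);
          if (si >= crit_sin) {
            exits = false;  // total internal reflection
          } else {
            double st = n_rel * si;
            double ctr = std::sqrt(1.0 - st * st);
            double rs = (n_rel * ci - ctr) / (n_rel * ci + ctr);
            double rp = (n_rel * ctr - ci) / (n_rel * ctr + ci);
            double R = 0.5 * (rs * rs + rp * rp);
            exits = (unif_rand() >= R);
          }
        }
        if (exits) {
          detected = true;
          alive = false;
        } else {
          uz = -uz;  // specular internal reflection, continue
        }
      } else {
        double de = path_in_epi(z, z2, s, t_epi);
        le += de; ld += s - de; total += s;
        x += ux * s; y += uy * s; z = z2;
        if (total > max_path) { truncated++; break; }
        scatter(ux, uy, uz, g);
      }
    }
    if (detected) {
      p_epi.push_back(le);
      p_derm.push_back(ld);
    }
  }

  NumericMatrix rec(p_epi.size(), 3);
  for (size_t i = 0; i < p_epi.size(); ++i) {
    rec(i, 0) = p_epi[i];
    rec(i, 1) = p_derm[i];
    rec(i, 2) = 1.0;
  }
  colnames(rec) = CharacterVector::create("path_epi", "path_derm", "weight");
  return List::create(_["records"] = rec, _["n_launched"] = n_photons,
                      _["n_truncated"] = truncated);
}

// Beer-Lambert post-hoc absorption over a grid of (mu_a,epi, mu_a,derm)
// values. Factorizes exp(-a*pe - b*pd) = exp(-a*pe) * exp(-b*pd), so the
// exponentials are evaluated once per photon per axis node.
// [[Rcpp::export]]
NumericMatrix cpp_absorption_grid(NumericVector path_epi, NumericVector path_derm,
                                  NumericVector weight, double n_launched,
                                  NumericVector mua_epi, NumericVector mua_derm) {
  int np = path_epi.size();
  int na = mua_epi.size(), nb = mua_derm.size();
  std::vector<double> ea((size_t)np * na), eb((size_t)np * nb);
  for (int a = 0; a < na; ++a)
    for (int i = 0; i < np; ++i)
      ea[(size_t)a * np + i] = weight[i] * std::exp(-mua_epi[a] * path_epi[i]);
  for (int b = 0; b < nb; ++b)
    for (int i = 0; i < np; ++i)
      eb[(size_t)b * np + i] = std::exp(-mua_derm[b] * path_derm[i]);
  NumericMatrix T(na, nb);
  for (int a = 0; a < na; ++a) {
    const double *pa = &ea[(size_t)a * np];
    for (int b = 0; b < nb; ++b) {
      const double *pb = &eb[(size_t)b * np];
      double acc = 0.0;
      for (int i = 0; i < np; ++i) acc += pa[i] * pb[i];
      T(a, b) = acc / n_launched;
    }
  }
  return T;
}

// Henyey-Greenstein deflection cosines, for distribution checks.
// [[Rcpp::export]]
NumericVector cpp_hg_sample(int n, double g) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g);
  return out;
}
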