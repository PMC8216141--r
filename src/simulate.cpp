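#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// One-dimensional two-layer elasto-visco-plastic update.
//
// Prandtl layer: spring E_pr in series with a plastic slider whose yield
// stress hardens with accumulated plastic strain kappa following a Voce
// saturation law  sigY(kappa) = sigma_u - (sigma_u - sigma_y) * exp(-p*kappa).
// Return mapping solves, for the plastic increment dg >= 0,
//   |sig_trial| - E_pr*dg = sigY(kappa + dg)
// which has a unique root because the left side is strictly decreasing in dg
// and the right side is non-decreasing.
//
// Maxwell layer: spring E_mx in series with dashpot eta; backward-Euler
// update  sig_mx' = (sig_mx + E_mx*deps) / (1 + E_mx*dt/eta), which is
// unconditionally stable.
//
// All stresses and moduli in MPa, times in s, strains dimensionless.

static double voce_yield(double kappa, double sigma_y, double sigma_u, double p) {
    return sigma_u - (sigma_u - sigma_y) * std::exp(-p * kappa);
}

// [[Rcpp::export]]
List cpp_simulate_forward(NumericVector time, NumericVector strain,
                          double E_pr, double sigma_y, double p,
                          double sigma_u, double E_mx, double eta,
                          int substeps) {
    const R_xlen_t n = time.size();
    if (strain.size() != n)
        stop("time and strain must have equal length");
    if (substeps < 1) substeps = 1;

    NumericVector stress(n), kappa_out(n), epsp_out(n);

    double eps_p = 0.0, kappa = 0.0, sig_mx = 0.0;
    const bool maxwell_on = (E_mx > 0.0 && eta > 0.0);

    // first sample: assume virgin state at the recorded strain (records
    // start at zero strain in practice)
    {
        double sig_pr = E_pr * (strain[0] - eps_p);
        double sY = voce_yield(kappa, sigma_y, sigma_u, p);
        if (std::fabs(sig_pr) > sY) {
            // degenerate: record starts beyond yield; return-map once
            double sgn = (sig_pr > 0) ? 1.0 : -1.0;
            double dg = 0.0, f;
            for (int it = 0; it < 100; ++it) {
                f = std::fabs(sig_pr) - E_pr * dg - voce_yield(kappa + dg, sigma_y, sigma_u, p);
                double df = -E_pr - p * (sigma_u - sigma_y) * std::exp(-p * (kappa + dg));
                double step = f / df;
                dg -= step;
                if (dg < 0) dg = 0;
                if (std::fabs(step) < 1e-14) break;
            }
            eps_p += sgn * dg;
            kappa += dg;
            sig_pr = E_pr * (strain[0] - eps_p);
        }
        stress[0] = sig_pr;  // dashpot carries no stress at t0
        kappa_out[0] = kappa;
        epsp_out[0] = eps_p;
    }

    for (R_xlen_t i = 1; i < n; ++i) {
        const double dt_full = time[i] - time[i - 1];
        if (!(dt_full > 0.0))
            stop("time must be strictly increasing");
        const double deps_full = strain[i] - strain[i - 1];
        const double dt = dt_full / substeps;
        const double deps = deps_full / substeps;
        double eps = strain[i - 1];

        for (int s = 0; s < substeps; ++s) {
            eps += deps;

            if (maxwell_on)
                sig_mx = (sig_mx + E_mx * deps) / (1.0 + E_mx * dt / eta);
            else
                sig_mx = 0.0;

            double sig_tr = E_pr * (eps - eps_p);
            double sY = voce_yield(kappa, sigma_y, sigma_u, p);
            if (std::fabs(sig_tr) > sY) {
                const double sgn = (sig_tr > 0) ? 1.0 : -1.0;
                const double R = sigma_u - sigma_y;
                double dg = 0.0;
                // Newton with bisection safeguard on
                // g(dg) = |sig_tr| - E_pr*dg - sigY(kappa+dg), g(0) > 0
                double lo = 0.0, hi = std::fabs(sig_tr) / E_pr;
                for (int it = 0; it < 100; ++it) {
                    double g = std::fabs(sig_tr) - E_pr * dg -
                               voce_yield(kappa + dg, sigma_y, sigma_u, p);
                    if (std::fabs(g) < 1e-12 * (1.0 + sigma_u)) break;
                    if (g > 0) lo = dg; else hi = dg;
                    double dgdx = -E_pr - p * R * std::exp(-p * (kappa + dg));
                    double next = dg - g / dgdx;
                    dg = (next > lo && next < hi) ? next : 0.5 * (lo + hi);
                }
                eps_p += sgn * dg;
                kappa += dg;
            }
            // recompute Prandtl stress from the (possibly updated) state
            // (done after loop via eps at sample point)
        }

        stress[i] = E_pr * (strain[i] - eps_p) + sig_mx;
        kappa_out[i] = kappa;
        epsp_out[i] = eps_p;
    }

    return List::create(_["stress"] = stress,
                        _["kappa"] = kappa_out,
                        _["plastic_strain"] = epsp_out);
}
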