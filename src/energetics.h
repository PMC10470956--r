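#ifndef SONARPCOD_ENERGETICS_H
#define SONARPCOD_ENERGETICS_H

#include <Rcpp.h>
#include <cmath>
#include <algorithm>

// Dynamic-energy-budget parameter set. Units: days, cm, kg, MJ.
struct EBParams {
  // growth
  double L0, Linf, k;          // von Bertalanffy (cm, cm, 1/day)
  double omega1, omega2;       // structural mass S = omega1 * L^omega2 (kg)
  // feeding
  double rho_f, eta;           // feeding-level target condition and steepness
  double assim;                // assimilation efficiency of prey
  double Imax_coef;            // max ingestion per structural surface (MJ/d/cm^2)
  double R_half;               // half-saturation prey density (type II)
  // milk
  double milk_coef;            // assimilated milk per calf surface (MJ/d/cm^2)
  double Tw;                   // weaning age (days)
  double Tn;                   // age at which milk intake starts declining (days)
  double rho_milk_full;        // mother condition giving full provisioning
  // metabolism and costs
  double sigma_M, theta_F;     // FMR scalar (MJ/d/kg^0.75), reserve discount
  double sigma_G;              // cost of structural growth (MJ/kg)
  double Tg;                   // gestation period (days)
  double sigma_L;              // lactation efficiency
  double eps_plus, eps_minus;  // anabolic / catabolic efficiency
  double rho_E;                // energy density of reserves (MJ/kg)
  // reproduction and survival
  double F_preg;               // reserve-mass threshold for pregnancy (kg)
  double rho_s, mu_s;          // starvation threshold and hazard scalar (1/day)
  double siler_a1, siler_b1, siler_a2, siler_a3, siler_b3;  // 1/day
  double male_hazard;          // constant hazard of weaned males (1/day)
  double nu_conception;        // conception rate of receptive females (1/day)
  double rho_birth;            // body condition of a neonate
};

inline EBParams eb_params_from_list(const Rcpp::List& p) {
  EBParams q;
  q.L0 = p["L0"]; q.Linf = p["Linf"]; q.k = p["k"];
  q.omega1 = p["omega1"]; q.omega2 = p["omega2"];
  q.rho_f = p["rho_f"]; q.eta = p["eta"]; q.assim = p["assim"];
  q.Imax_coef = p["Imax_coef"]; q.R_half = p["R_half"];
  q.milk_coef = p["milk_coef"]; q.Tw = p["Tw"]; q.Tn = p["Tn"];
  q.rho_milk_full = p["rho_milk_full"];
  q.sigma_M = p["sigma_M"]; q.theta_F = p["theta_F"]; q.sigma_G = p["sigma_G"];
  q.Tg = p["Tg"]; q.sigma_L = p["sigma_L"];
  q.eps_plus = p["eps_plus"]; q.eps_minus = p["eps_minus"]; q.rho_E = p["rho_E"];
  q.F_preg = p["F_preg"]; q.rho_s = p["rho_s"]; q.mu_s = p["mu_s"];
  q.siler_a1 = p["siler_a1"]; q.siler_b1 = p["siler_b1"];
  q.siler_a2 = p["siler_a2"]; q.siler_a3 = p["siler_a3"];
  q.siler_b3 = p["siler_b3"];
  q.male_hazard = p["male_hazard"]; q.nu_conception = p["nu_conception"];
  q.rho_birth = p["rho_birth"];
  return q;
}

namespace eb {

inline double clamp01(double x) { return std::min(1.0, std::max(0.0, x)); }

// structural length at age a (days); fetal ages in [-Tg, 0] allowed
inline double length(double a, const EBParams& p) {
  double L = p.Linf - (p.Linf - p.L0) * std::exp(-p.k * a);
  return std::max(L, 0.0);
}

inline double smass(double L, const EBParams& p) {
  return p.omega1 * std::pow(L, p.omega2);
}

// dS/da via the chain rule (kg/day)
inline double smass_growth(double a, const EBParams& p) {
  double L = length(a, p);
  if (L <= 0.0) return 0.0;
  double dL = p.k * (p.Linf - L);
  return p.omega2 * p.omega1 * std::pow(L, p.omega2 - 1.0) * dL;
}

inline double condition(double F, double S) {
  double W = S + F;
  return W > 0.0 ? F / W : 0.0;
}

// decreasing sigmoid (Hill form), value 0.5 at rho = rho_f
inline double feeding_level(double rho, const EBParams& p) {
  if (rho <= 0.0) return 1.0;
  return 1.0 / (1.0 + std::pow(rho / p.rho_f, p.eta));
}

// age ramp of solid-prey feeding: 0 at birth to 1 at weaning age
inline double solid_ramp(double a, const EBParams& p) {
  return clamp01(a / p.Tw);
}

// type-II functional response term given shared prey density R and the
// area-specific attack-rate multiplier phi
inline double type2(double R, double phi, const EBParams& p) {
  double x = phi * R;
  return x / (x + p.R_half);
}

// ingested (pre-assimilation) solid-prey energy rate (MJ/day)
inline double ingestion(double rho, double L, double a, double R, double phi,
                        const EBParams& p) {
  return feeding_level(rho, p) * p.Imax_coef * L * L * type2(R, phi, p) *
         solid_ramp(a, p);
}

// assimilated solid-prey energy rate (MJ/day)
inline double intake(double rho, double L, double a, double R, double phi,
                     const EBParams& p) {
  return p.assim * ingestion(rho, L, a, R, phi, p);
}

// age factor of milk intake: 1 up to Tn, declining linearly to 0 at weaning
inline double milk_age_factor(double a, const EBParams& p) {
  if (a >= p.Tw) return 0.0;
  if (a <= p.Tn) return 1.0;
  return (p.Tw - a) / (p.Tw - p.Tn);
}

// provisioning willingness of the mother: 0 at/below the starvation
// threshold, 1 at/above rho_milk_full
inline double provisioning(double rho_mother, const EBParams& p) {
  return clamp01((rho_mother - p.rho_s) / (p.rho_milk_full - p.rho_s));
}

// assimilated milk energy rate of a calf (MJ/day)
inline double milk_intake(double rho_calf, double L_calf, double a_calf,
                          double rho_mother, const EBParams& p) {
  return p.milk_coef * L_calf * L_calf * feeding_level(rho_calf, p) *
         milk_age_factor(a_calf, p) * provisioning(rho_mother, p);
}

// field metabolic rate from maintenance mass (MJ/day); S_fetus = 0 unless
// the whale is pregnant
inline double fmr(double S, double F, double S_fetus, const EBParams& p) {
  double m = S + p.theta_F * F + S_fetus;
  return p.sigma_M * std::pow(std::max(m, 0.0), 0.75);
}

// reserve-mass rate of change from a net energy balance (kg/day)
inline double reserves_rate(double net, const EBParams& p) {
  if (net >= 0.0) return p.eps_plus * net / p.rho_E;
  return net / (p.eps_minus * p.rho_E);
}

inline double siler(double a, const EBParams& p) {
  return p.siler_a1 * std::exp(-p.siler_b1 * a) + p.siler_a2 +
         p.siler_a3 * std::exp(p.siler_b3 * a);
}

// natural (non-starvation) hazard; weaned males have a constant rate
inline double background_hazard(double a, bool male, bool weaned,
                                const EBParams& p) {
  if (male && weaned) return p.male_hazard;
  return siler(a, p);
}

inline double starvation_hazard(double rho, const EBParams& p) {
  if (rho >= p.rho_s) return 0.0;
  double r = std::max(rho, 1e-6);
  return p.mu_s * (p.rho_s / r - 1.0);
}

}  // namespace eb

#endif
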