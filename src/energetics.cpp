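#include "energetics.h"
using namespace Rcpp;

// Thin vectorized exports of the energy-budget rate functions. The R-level
// API (R/bioenergetics.R) and the simulation engine (engine.cpp) both call
// the inline functions in energetics.h, so there is a single definition of
// every rate.

// [[Rcpp::export(name = ".eb_length")]]
NumericVector eb_length_cpp(NumericVector a, List params) {
  EBParams p = eb_params_from_list(params);
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) out[i] = eb::length(a[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_smass")]]
NumericVector eb_smass_cpp(NumericVector L, List params) {
  EBParams p = eb_params_from_list(params);
  NumericVector out(L.size());
  for (R_xlen_t i = 0; i < L.size(); ++i) out[i] = eb::smass(L[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_smass_growth")]]
NumericVector eb_smass_growth_cpp(NumericVector a, List params) {
  EBParams p = eb_params_from_list(params);
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) out[i] = eb::smass_growth(a[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_feeding_level")]]
NumericVector eb_feeding_level_cpp(NumericVector rho, List params) {
  EBParams p = eb_params_from_list(params);
  NumericVector out(rho.size());
  for (R_xlen_t i = 0; i < rho.size(); ++i) out[i] = eb::feeding_level(rho[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_intake")]]
NumericVector eb_intake_cpp(NumericVector rho, NumericVector L, NumericVector a,
                            double R, double phi, List params) {
  EBParams p = eb_params_from_list(params);
  R_xlen_t n = rho.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = eb::intake(rho[i], L[i], a[i], R, phi, p);
  return out;
}

// [[Rcpp::export(name = ".eb_milk_intake")]]
NumericVector eb_milk_intake_cpp(NumericVector rho_calf, NumericVector L_calf,
                                 NumericVector a_calf, NumericVector rho_mother,
                                 List params) {
  EBParams p = eb_params_from_list(params);
  R_xlen_t n = rho_calf.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = eb::milk_intake(rho_calf[i], L_calf[i], a_calf[i], rho_mother[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_fmr")]]
NumericVector eb_fmr_cpp(NumericVector S, NumericVector F, NumericVector S_fetus,
                         List params) {
  EBParams p = eb_params_from_list(params);
  R_xlen_t n = S.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = eb::fmr(S[i], F[i], S_fetus[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_reserves_rate")]]
NumericVector eb_reserves_rate_cpp(NumericVector net, List params) {
  EBParams p = eb_params_from_list(params);
  NumericVector out(net.size());
  for (R_xlen_t i = 0; i < net.size(); ++i) out[i] = eb::reserves_rate(net[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_background_hazard")]]
NumericVector eb_background_hazard_cpp(NumericVector a, LogicalVector male,
                                       LogicalVector weaned, List params) {
  EBParams p = eb_params_from_list(params);
  R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = eb::background_hazard(a[i], male[i], weaned[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_starvation_hazard")]]
NumericVector eb_starvation_hazard_cpp(NumericVector rho, List params) {
  EBParams p = eb_params_from_list(params);
  NumericVector out(rho.size());
  for (R_xlen_t i = 0; i < rho.size(); ++i)
    out[i] = eb::starvation_hazard(rho[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_milk_age_factor")]]
NumericVector eb_milk_age_factor_cpp(NumericVector a, List params) {
  EBParams p = eb_params_from_list(params);
  NumericVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = eb::milk_age_factor(a[i], p);
  return out;
}

// [[Rcpp::export(name = ".eb_provisioning")]]
NumericVector eb_provisioning_cpp(NumericVector rho, List params) {
  EBParams p = eb_params_from_list(params);
  NumericVector out(rho.size());
  for (R_xlen_t i = 0; i < rho.size(); ++i) out[i] = eb::provisioning(rho[i], p);
  return out;
}
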