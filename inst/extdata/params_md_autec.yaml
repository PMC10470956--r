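# Blainville's beaked whale (Mesoplodon densirostris) around AUTEC.
# Units: days, cm, kg, MJ. See params_zc_soar.yaml for provenance tags.
species: Md
location: AUTEC
energetics:
  L0: 190.0        # neonate length, cm [assumed]
  Linf: 450.0      # asymptotic length, cm [assumed]
  k: 5.0e-4        # von Bertalanffy rate, 1/day [assumed]
  omega1: 1.0e-5   # length-mass coefficient, kg/cm^omega2 [assumed]
  omega2: 3.0
  rho_f: 0.3
  eta: 5.0
  assim: 0.9
  Imax_coef: 2.2e-3
  R_half: 0.3
  milk_coef: 1.2e-3
  Tw: 640.0        # weaning age, days [assumed]
  Tn: 200.0
  rho_milk_full: 0.25
  sigma_M: 0.6
  theta_F: 0.2
  sigma_G: 30.0
  Tg: 365.0
  sigma_L: 0.86
  eps_plus: 0.9
  eps_minus: 0.9
  rho_E: 25.0
  F_preg: 290.0    # reserve-mass threshold for pregnancy, kg [assumed]
  rho_s: 0.1
  mu_s: 0.05
  siler_a1: 4.0e-4
  siler_b1: 3.3e-3
  siler_a2: 5.5e-5
  siler_a3: 1.5e-6
  siler_b3: 3.3e-4
  male_hazard: 7.0e-5
  nu_conception: 0.05
  rho_birth: 0.2
prey:
  R_max: 0.144     # [calibrated to ~40 whales undisturbed]
  delta: 0.1
  kappa: 2.0e-6
areas: autec
phi_high: 5.0      # attack-rate ratio 6.0/1.2 [prey survey]
dose_response:
  z_min: 0.29      # foraging activity at maximal sonar use (1 - 0.71) [acoustic]
target_abundance: 40
sonar:
  fraction: 0.029
  mean_area: 0.537
  mean_area_east: 0.411
  correlation: 0.848
  record_hours: 16400
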