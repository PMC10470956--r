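# Cuvier's beaked whale (Ziphius cavirostris) around SOAR.
# Units throughout: days, cm, kg, MJ.
# provenance tags: [telemetry] = estimated from tagging/acoustic data and
# printed in the package's movement fixtures; [assumed] = package default
# chosen from general odontocete literature and the predecessor pilot-whale
# energy-budget model; [calibrated] = tuned so the undisturbed population is
# stationary near the target abundance.
species: Zc
location: SOAR
energetics:
  L0: 250.0        # neonate length, cm [assumed]
  Linf: 590.0      # asymptotic length, cm [assumed]
  k: 5.0e-4        # von Bertalanffy rate, 1/day [assumed]
  omega1: 1.07e-5  # length-mass coefficient, kg/cm^omega2 [assumed]
  omega2: 3.0      # length-mass exponent [assumed]
  rho_f: 0.3       # target body condition (feeding level = 0.5) [assumed]
  eta: 5.0         # feeding-level steepness [assumed]
  assim: 0.9       # assimilation efficiency of prey energy [assumed]
  Imax_coef: 2.2e-3  # max ingestion per structural surface, MJ/d/cm^2 [assumed]
  R_half: 0.3      # half-saturation prey density (dimensionless) [assumed]
  milk_coef: 1.2e-3  # assimilated milk per calf surface, MJ/d/cm^2 [assumed]
  Tw: 730.0        # weaning age, days [assumed]
  Tn: 200.0        # calf age at which milk intake starts declining [assumed]
  rho_milk_full: 0.25  # mother condition giving full milk provisioning [assumed]
  sigma_M: 0.6     # field metabolic scalar, MJ/d/kg^0.75 (~2x Kleiber) [assumed]
  theta_F: 0.2     # reserve-mass discount in maintenance mass [assumed]
  sigma_G: 30.0    # cost of structural growth, MJ/kg [assumed]
  Tg: 365.0        # gestation period, days [assumed]
  sigma_L: 0.86    # lactation efficiency [assumed]
  eps_plus: 0.9    # anabolic efficiency [assumed]
  eps_minus: 0.9   # catabolic efficiency [assumed]
  rho_E: 25.0      # energy density of reserves, MJ/kg [assumed]
  F_preg: 700.0    # reserve-mass threshold for pregnancy, kg [assumed]
  rho_s: 0.1       # starvation condition threshold [assumed]
  mu_s: 0.05       # starvation hazard scalar, 1/day [assumed]
  siler_a1: 4.0e-4   # Siler juvenile term, 1/day [assumed]
  siler_b1: 3.3e-3   # Siler juvenile decay, 1/day [assumed]
  siler_a2: 5.5e-5   # Siler constant adult hazard, 1/day (~2%/y) [assumed]
  siler_a3: 1.5e-6   # Siler senescent term, 1/day [assumed]
  siler_b3: 3.3e-4   # Siler senescent rate, 1/day [assumed]
  male_hazard: 7.0e-5  # constant hazard of weaned males, 1/day [assumed]
  nu_conception: 0.05  # conception rate while receptive, 1/day [assumed]
  rho_birth: 0.2   # neonate body condition [assumed]
prey:
  R_max: 0.494     # max prey density without whale foraging [calibrated to ~100 whales undisturbed]
  delta: 0.1       # prey replenishment rate, 1/day [assumed]
  kappa: 2.0e-6    # prey depletion per MJ ingested, 1/MJ [assumed]
areas: soar
phi_high: 13.333333  # attack-rate ratio 20/1.5 [telemetry/prey survey]
dose_response:
  z_min: 0.47      # foraging activity at maximal sonar use (1 - 0.53) [acoustic]
target_abundance: 100  # undisturbed abundance target [survey]
sonar:
  fraction: 0.084      # fraction of hours with sonar [acoustic]
  mean_area: 0.384     # mean standardized sonar area, western, hours with sonar
  mean_area_east: 0.456  # same, eastern unit
  correlation: 0.863   # east-west hourly sonar correlation [acoustic]
  record_hours: 11925  # length of the acoustic record
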