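# Published input parameters for the multiple-path particle dosimetry
# (MPPD) aerosol deposition model of combustible-cigarette smoke.
# Retained as fixture metadata only: this package computes no deposition
# physics; these inputs are ready for a future MPPD integration.
smoking_topography:
  puff_withdrawal_time_s: 1.62
  mouth_hold_time_s: 0.5
  inhalation_time_s: 1
  pause_lung_hold_time_s: 0
  exhalation_time_s: 1.62
  puff_volume_mL: 58.5
  inhaled_mass_mg: 3.854
  dilution_volume_mL: 400
aerosol_properties:
  droplet_number_concentration_per_cm3: 1.0e9
  droplet_median_diameter_um: 0.2
  total_mass_inhaled_mg: 3.850
  droplet_temperature_C: 24.55
respiratory_tract_properties:
  oral_urt_volume_mL: 50
  functional_residual_capacity_mL: 3000
  oral_humidity_pct: 80
  lung_humidity_pct: 99.9
  oral_interface_temperature_C: 20
  lung_temperature_C: 37
constituent_properties:
  units:
    density: g/cm3
    vapor_pressure: kPa
    diff_coeff_air: cm2/s
    molar_mass: g/mol
    diff_coeff_h2o: cm2/s
    latent_heat: kJ/kg
    specific_heat: J/g/K
    activity_coeff: dimensionless
    surface_tension: dyn/cm
    partition_coeff: dimensionless
    clearance_rate: 1/s
    fraction: dimensionless
  water:
    density: 1.009250
    vapor_pressure: 6.330000
    diff_coeff_air: 0.2000
    molar_mass: 18.02
    diff_coeff_h2o: 9.6e-6
    latent_heat: 36.81
    specific_heat: 4.200000
    activity_coeff: 1.02629
    surface_tension: 70.34
    partition_coeff: 233045188905.7
    clearance_rate: 1.0e-4
    fraction: 0.7486
  nicotine:
    density: 0.990059
    vapor_pressure: 0.043400
    diff_coeff_air: 0.0670
    molar_mass: 162.23
    diff_coeff_h2o: 9.6e-6
    latent_heat: 2414.05
    specific_heat: 4.177000
    activity_coeff: 1.84998
    surface_tension: 27.00
    partition_coeff: 22139.739659
    clearance_rate: 1.0e-4
    fraction: 0.0913
  propylene_glycol:
    density: 1.023380
    vapor_pressure: 0.049000
    diff_coeff_air: 0.1030
    molar_mass: 76.09
    diff_coeff_h2o: 9.6e-6
    latent_heat: 871.65
    specific_heat: 2.578000
    activity_coeff: 1.99576
    surface_tension: 34.33
    partition_coeff: 545847.197167
    clearance_rate: 1.0e-4
    fraction: 0.0379
  glycerine:
    density: 1.250260
    vapor_pressure: 9.0e-5
    diff_coeff_air: 0.0958
    molar_mass: 92.09
    diff_coeff_h2o: 9.6e-6
    latent_heat: 961.42
    specific_heat: 2.471000
    activity_coeff: 0.73771
    surface_tension: 62.25
    partition_coeff: 347536324.256485
    clearance_rate: 1.0e-4
    fraction: 0.0779
  triacetin:
    density: 1.143000
    vapor_pressure: 0.001141
    diff_coeff_air: 0.0605
    molar_mass: 218.20
    diff_coeff_h2o: 9.6e-6
    latent_heat: 360.97
    specific_heat: 1.694410
    activity_coeff: 119.359
    surface_tension: 34.88
    partition_coeff: 511445.020496
    clearance_rate: 1.0e-4
    fraction: 0.0363
  toluene:
    density: 0.853000
    vapor_pressure: 6.860000
    diff_coeff_air: 110.6000
    molar_mass: 92.14
    diff_coeff_h2o: 9.6e-6
    latent_heat: 404.99
    specific_heat: 1.733000
    activity_coeff: 1327.94
    surface_tension: 26.50
    partition_coeff: 13.760748
    clearance_rate: 1.0e-4
    fraction: 0.0037
  hydroquinone:
    density: 1.297240
    vapor_pressure: 1.54e-4
    diff_coeff_air: 0.0857
    molar_mass: 110.11
    diff_coeff_h2o: 9.6e-6
    latent_heat: 747.49
    specific_heat: 2.098160
    activity_coeff: 0.06011
    surface_tension: 55.61
    partition_coeff: 8819905.873238
    clearance_rate: 1.0e-4
    fraction: 0.0020
  catechol:
    density: 1.220000
    vapor_pressure: 0.009700
    diff_coeff_air: 0.0861
    molar_mass: 110.11
    diff_coeff_h2o: 9.6e-6
    latent_heat: 576.28
    specific_heat: 1.400000
    activity_coeff: 0.06011
    surface_tension: 44.30
    partition_coeff: 83113.753584
    clearance_rate: 1.0e-4
    fraction: 0.0023
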