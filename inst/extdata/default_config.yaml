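# Default configuration: reference operating parameters for Z. bungeanum
# drying simulations. Keys mirror the arguments of material_properties(),
# pulsation_schedule() and simulation_config(); omitted keys take the
# package defaults.
properties:
  density: 1030                    # kg/m^3
  specific_heat: 1569              # J/(kg C)
  thermal_conductivity: 0.55       # W/(m C)
  latent_heat: 2.32e+06              # J/kg
  liquid_water_concentration: 707.61   # kg/m^3
  evaporation_rate_constant: 1.0e-06
  absorption_coefficient: 0.9
  radiation_intensity: 6.54e+03      # W/m^2
  microwave_frequency: 2.45        # GHz (metadata)
  dielectric_constant: 40          # metadata
  dielectric_loss: 17              # metadata
  antoine_A: 7.8087
  antoine_B: 1007.839
  antoine_C: -166.3583
  diffusivity_scale: 1.0e-09        # m^2 K (r^2 in the diffusivity correlation)
  power_density: 8                 # W/g nominal microwave power (MVD)
  absorbed_fraction: 0.01          # eta, refined by calibration
  ir_penetration_depth: 2.0e-03     # m (Beer-Lambert decay length, PVD)
schedule:
  vacuum_duration: 900             # s (15 min vacuum phase)
  atmospheric_duration: 300        # s (5 min atmospheric phase)
  vacuum_pressure: 10              # kPa absolute
  atmospheric_pressure: 101.325    # kPa absolute
  transition_width: 0.08           # fraction of the cycle period
simulation:
  mode: MVD
  air_temperature: 50              # C
  geometry: slab
  characteristic_size: 0.01        # m (slab half-thickness)
  n_nodes: 30
  t_end: 21600                     # s
  max_step: 60                     # s
  rel_tol: 0.01
  abs_tol: 0.001
  initial_temperature: 20          # C
  initial_moisture: 2.03           # kg/kg dry basis
  target_moisture: 0.11            # kg/kg dry basis (safe level)
  equilibrium_moisture: 0.01       # kg/kg dry basis
  heat_transfer_coeff: 25          # W/(m^2 C)
  mass_transfer_coeff: 0.025       # m/s
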