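# Rat virtual population: 191 individuals, same variability structure as
# the human population.
n_individuals: 191
seed: 20141
variability:
  - {parameter_path: transporters.BSEP.vmax, distribution: lognormal, location: 0, scale: 0.2, lower_bound: 0.2, upper_bound: 5}
  - {parameter_path: transporters.NTCP.vmax, distribution: lognormal, location: 0, scale: 0.2, lower_bound: 0.2, upper_bound: 5}
  - {parameter_path: transporters.BASOLATERAL.vmax, distribution: lognormal, location: 0, scale: 0.25, lower_bound: 0.2, upper_bound: 5}
  - {parameter_path: physiology.ba_synthesis, distribution: lognormal, location: 0, scale: 0.15, lower_bound: 0.3, upper_bound: 3}
acceptance_ranges:
  liver_ba_uM: [0.05, 12]
  serum_ba_uM: [0.005, 12]
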