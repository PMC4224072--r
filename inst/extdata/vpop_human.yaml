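# Human virtual population: 331 individuals with lognormal variability in
# bile acid transport capacity and synthesis. Acceptance keeps candidates
# whose drug-free baseline liver and serum toxic bile acid concentrations
# are physiologically plausible.
n_individuals: 331
seed: 20140
variability:
  - {parameter_path: transporters.BSEP.vmax, distribution: lognormal, location: 0, scale: 0.2, lower_bound: 0.2, upper_bound: 5}
  - {parameter_path: transporters.NTCP.vmax, distribution: lognormal, location: 0, scale: 0.2, lower_bound: 0.2, upper_bound: 5}
  - {parameter_path: transporters.BASOLATERAL.vmax, distribution: lognormal, location: 0, scale: 0.25, lower_bound: 0.2, upper_bound: 5}
  - {parameter_path: physiology.ba_synthesis, distribution: lognormal, location: 0, scale: 0.15, lower_bound: 0.3, upper_bound: 3}
acceptance_ranges:
  liver_ba_uM: [0.2, 12]
  serum_ba_uM: [0.02, 12]
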