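# Rat physiology and baseline parameter set (250 g animal).
# The rat bile acid pool is dominated by non-toxic species (cholic and
# muricholic acids); only a small share is CDCA/LCA-class, and the rat
# additionally hydroxylates LCA to non-toxic products -- both captured
# here and responsible for the species difference in simulated toxicity.
species: rat
bodyweight_kg: 0.25
liver_volume_L: 0.010
blood_volume_L: 0.016
portal_volume_L: 0.003
hepatic_blood_flow_L_per_h: 0.9
ba_synthesis_umol_per_h: 2.0
toxic_pool_fraction: 0.06
lca_hydroxylation_cl_L_per_h: 0.005
gut_conversion_k_per_h: 0.005
conjugation_k_per_h: 1.0
sulfation_k_per_h: 0.3
gut_transit_k_per_h: 0.6
fecal_loss_fraction: 0.2
gallbladder_empty_fraction: 0.75
meal_times_h: [0, 8, 16]
baseline_atp_mM: 2.0
transporters:
  NTCP:
    vmax_umol_per_h: 8
    km_uM: 5
  BSEP:
    vmax_umol_per_h: 12
    km_uM: 4
  BASOLATERAL:
    vmax_umol_per_h: 0.6
    km_uM: 10
toxicity:
  vmax_s: [10, 10]
  km_s_uM: [40, 10]
  hill: [2.5, 2.5]
  tau_per_h: [0.3, 0.3]
  k_atp_mM_per_h: 0.6
injury:
  atp_death_threshold_mM: 1.0
  k_necrosis_max_per_h: 0.1
  necrosis_hill: 2
  alt_content_fold_per_fraction: 300
  k_alt_clear_per_h: 0.02
  k_bili_base_clear_per_h: 0.1
  k_regen_per_h: 0.005
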