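# Human physiology and baseline parameter set for the bile acid / DILI model.
# Reference adult (70 kg). Bile acid values describe the toxic
# (CDCA/LCA-class) share of the pool only; transporter kinetics are
# whole-liver lumped values calibrated so that (a) the drug-free baseline
# reaches a periodic steady state with liver toxic bile acid concentration
# of ~1-2 uM (well below the toxicity Km), (b) recirculating toxic bile
# acid flux is ~250-300 umol/h with ~6% fecal loss per pass balancing
# synthesis.
species: human
bodyweight_kg: 70
liver_volume_L: 1.8
blood_volume_L: 5.4
portal_volume_L: 1.0
hepatic_blood_flow_L_per_h: 90
# total primary bile acid synthesis ~50 umol/h (~470 mg/day cholic +
# chenodeoxycholic equivalents); 35% enters the CDCA/LCA (toxic) pool
ba_synthesis_umol_per_h: 50
toxic_pool_fraction: 0.35
lca_hydroxylation_cl_L_per_h: 0        # pathway absent in human
gut_conversion_k_per_h: 0.005          # CDCA -> LCA by gut flora
conjugation_k_per_h: 1.0
sulfation_k_per_h: 0.3
gut_transit_k_per_h: 0.35
fecal_loss_fraction: 0.15
gallbladder_empty_fraction: 0.75
meal_times_h: [0, 8, 16]
baseline_atp_mM: 4.2
transporters:
  NTCP:
    vmax_umol_per_h: 600
    km_uM: 5
  BSEP:
    vmax_umol_per_h: 650
    km_uM: 4
  BASOLATERAL:
    vmax_umol_per_h: 60
    km_uM: 10
toxicity:
  # Hill signal per class (CDCA-like, LCA-like); calibrated, not the
  # original in-vitro fit (which is not in the public record)
  vmax_s: [10, 10]
  km_s_uM: [40, 10]
  hill: [2.5, 2.5]
  tau_per_h: [0.3, 0.3]
  k_atp_mM_per_h: 1.2
injury:
  atp_death_threshold_mM: 2.2
  k_necrosis_max_per_h: 0.1
  necrosis_hill: 2
  alt_content_fold_per_fraction: 300
  k_alt_clear_per_h: 0.02
  k_bili_base_clear_per_h: 0.1
  k_regen_per_h: 0.005
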