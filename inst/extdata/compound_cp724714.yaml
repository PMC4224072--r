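# CP-724,714, human parameterization.
# Rapid hepatic metabolism (single lumped metabolite compartment in the
# liver); parent inhibits BSEP competitively (Ki approximated by the
# vesicle-assay IC50, 7.45 uM). Metabolite BSEP/ETC activity and biliary
# clearance are hypothesis flags applied by the scenario registry, not
# part of the baseline compound.
name: cp724714
molecular_weight_g_per_mol: 469.5
ka_per_h: 0.8
f_abs: 0.6
uptake_vmax_umol_per_h_per_kg075: 8
uptake_km_uM: 10
passive_cl_L_per_h: 1.0
biliary_cl_mL_per_h_per_kg075: 50
renal_cl_L_per_h: 0
v_central_L_per_kg: 0.5
v_peripheral_L_per_kg: 1.0
q_peripheral_L_per_h: 10
inhibitions:
  - {transporter: BSEP, ki_uM: 7.45, mode: competitive}
metabolites:
  # the BSEP/ETC-active metabolite is a minor share of CP-724,714's
  # (otherwise unmodeled) hepatic metabolism; cleared into bile only, so
  # its hepatic exposure is controlled by its biliary clearance alone
  - product_name: cp724714_metabolite
    vmax_formation_umol_per_h: 1.5
    km_formation_uM: 15
    product_biliary_cl_mL_per_h_per_kg075: 50
    product_passive_cl_L_per_h: 0
    product_inhibitions: []
default_regimen: {amount_mg: 250, interval_h: 8, n_doses: 90, route: oral}
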