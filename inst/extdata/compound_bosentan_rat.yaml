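# Bosentan, rat parameterization (synthetic stand-in for non-public
# in-vivo rat PK data; see the methods vignette). Dosing convention is
# mg/kg once daily, oral by default (an IV regimen can be passed instead).
# Rat-specific inhibition constants: BSEP as in human (rat-vesicle data),
# NTCP far more potent and noncompetitive in rat.
name: bosentan
molecular_weight_g_per_mol: 551.6
ka_per_h: 0.9
f_abs: 0.5
uptake_vmax_umol_per_h_per_kg075: 10
uptake_km_uM: 10
passive_cl_L_per_h: 0.05
biliary_cl_mL_per_h_per_kg075: 300
renal_cl_L_per_h: 0
v_central_L_per_kg: 1.0
v_peripheral_L_per_kg: 1.0
q_peripheral_L_per_h: 0.2
induction:
  targets: [uptake_vmax, metabolism_vmax]
  fold_max: 2.0
  k_ind_per_h: 0.01
inhibitions:
  - {transporter: BSEP, ki_uM: 12, mode: noncompetitive}
  - {transporter: NTCP, ki_uM: 0.23, mode: noncompetitive}
metabolites:
  - product_name: bosentan_major_metabolite
    vmax_formation_umol_per_h: 8
    km_formation_uM: 20
    product_biliary_cl_mL_per_h_per_kg075: 40
    product_passive_cl_L_per_h: 0.02
    product_inhibitions: []
  - product_name: bosentan_minor_metabolite
    vmax_formation_umol_per_h: 2.6
    km_formation_uM: 20
    product_biliary_cl_mL_per_h_per_kg075: 40
    product_passive_cl_L_per_h: 0.02
    product_inhibitions:
      - {transporter: BSEP, ki_uM: 8.5, mode: noncompetitive}
default_regimen: {amount_mg: 50, interval_h: 24, n_doses: 30, route: oral, per_kg: true}
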