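#' Bile acid species tracked by the model
#'
#' Two primary toxic bile acids (chenodeoxycholic acid, CDCA, and
#' lithocholic acid, LCA) and their conjugates. Conjugates inherit the
#' toxicity class of their parent acid.
#'
#' @return tibble with columns `species`, `toxicity_class`.
#' @export
ba_species_table <- function() {
  tibble::tibble(
    species = c("CDCA", "CDCA_amide", "LCA", "LCA_amide", "LCA_sulfate"),
    toxicity_class = c("CDCA-like", "CDCA-like",
                       "LCA-like", "LCA-like", "LCA-like"))
}

BA_SPECIES <- c("CDCA", "CDCA_amide", "LCA", "LCA_amide", "LCA_sulfate")
BA_CLASS <- c(1L, 1L, 2L, 2L, 2L)          # 1 = CDCA-like, 2 = LCA-like
BA_COMPARTMENTS <- c("liver_intracellular", "gallbladder", "gut_lumen",
                     "portal_blood", "systemic_blood")

#' Species physiology
#'
#' Whole-body parameters of the simulated species (human or rat) governing
#' bile acid synthesis, enterohepatic cycling, meals, and hepatic energy
#' state. All rates are whole-body values in the stated units.
#'
#' @param species `"human"` or `"rat"`.
#' @param bodyweight kg.
#' @param liver_volume L.
#' @param blood_volume total blood volume, L (portal + systemic).
#' @param portal_volume portal blood volume, L.
#' @param hepatic_blood_flow portal/hepatic blood flow, L/h.
#' @param ba_synthesis total primary bile acid synthesis, umol/h.
#' @param toxic_pool_fraction share of synthesis entering the toxic
#'   (CDCA/LCA-class) pool; the model tracks only this share.
#' @param lca_hydroxylation_cl hepatic clearance of unconjugated LCA to
#'   non-toxic hydroxylated products, L/h (rodent pathway; 0 in human).
#' @param gut_conversion_k first-order CDCA -> LCA conversion by gut flora
#'   in the gut lumen, 1/h.
#' @param conjugation_k first-order hepatic amidation of CDCA and LCA, 1/h.
#' @param sulfation_k first-order hepatic sulfation of LCA, 1/h.
#' @param gut_transit_k first-order outflow of bile acids from the gut
#'   lumen, 1/h; a fraction `fecal_loss_fraction` of the outflow is lost in
#'   feces, the remainder is reabsorbed to portal blood.
#' @param fecal_loss_fraction fraction of gut outflow lost per pass.
#' @param gallbladder_empty_fraction fraction of gallbladder content
#'   discharged to the gut lumen at each meal.
#' @param meal_times meal clock times within a day, h (3/day).
#' @param baseline_atp hepatocellular ATP setpoint, mM.
#' @return a `species_physiology` list.
#' @export
species_physiology <- function(species = c("human", "rat"),
                               bodyweight, liver_volume, blood_volume,
                               portal_volume, hepatic_blood_flow,
                               ba_synthesis, toxic_pool_fraction,
                               lca_hydroxylation_cl = 0,
                               gut_conversion_k, conjugation_k, sulfation_k,
                               gut_transit_k, fecal_loss_fraction,
                               gallbladder_empty_fraction,
                               meal_times = c(0, 8, 16),
                               baseline_atp) {
  species <- match.arg(species)
  stopifnot(bodyweight > 0, liver_volume > 0, blood_volume > portal_volume,
            portal_volume > 0, hepatic_blood_flow > 0, ba_synthesis >= 0,
            toxic_pool_fraction >= 0, toxic_pool_fraction <= 1,
            lca_hydroxylation_cl >= 0,
            gut_conversion_k >= 0, conjugation_k >= 0, sulfation_k >= 0,
            gut_transit_k >= 0,
            fecal_loss_fraction >= 0, fecal_loss_fraction <= 1,
            gallbladder_empty_fraction >= 0, gallbladder_empty_fraction <= 1,
            length(meal_times) >= 1, baseline_atp > 0)
  if (species == "human" && lca_hydroxylation_cl != 0)
    stop("lca_hydroxylation_cl must be 0 for human physiology")
  structure(list(species = species, bodyweight = bodyweight,
                 liver_volume = liver_volume, blood_volume = blood_volume,
                 portal_volume = portal_volume,
                 hepatic_blood_flow = hepatic_blood_flow,
                 ba_synthesis = ba_synthesis,
                 toxic_pool_fraction = toxic_pool_fraction,
                 lca_hydroxylation_cl = lca_hydroxylation_cl,
                 gut_conversion_k = gut_conversion_k,
                 conjugation_k = conjugation_k, sulfation_k = sulfation_k,
                 gut_transit_k = gut_transit_k,
                 fecal_loss_fraction = fecal_loss_fraction,
                 gallbladder_empty_fraction = gallbladder_empty_fraction,
                 meal_times = meal_times, baseline_atp = baseline_atp),
            class = "species_physiology")
}

#' Bile acid transporter kinetics
#'
#' Whole-liver Michaelis-Menten parameters per transporter and bile acid
#' species. NTCP moves bile acids from portal blood into the hepatocyte,
#' BSEP from hepatocyte into canalicular bile (gallbladder), and the lumped
#' basolateral efflux transporter (MRP3/4-like) from hepatocyte to systemic
#' blood.
#'
#' @param vmax named list (`NTCP`, `BSEP`, `BASOLATERAL`), each a numeric
#'   vector of length 5 (order of [ba_species_table()]), umol/h.
#' @param km same shape, uM.
#' @return a `transporter_params` list.
#' @export
transporter_params <- function(vmax, km) {
  tr <- c("NTCP", "BSEP", "BASOLATERAL")
  stopifnot(all(tr %in% names(vmax)), all(tr %in% names(km)))
  vmax <- lapply(vmax[tr], function(v) {
    v <- as.numeric(v)
    if (length(v) == 1) v <- rep(v, 5)
    stopifnot(length(v) == 5, all(v >= 0)); v
  })
  km <- lapply(km[tr], function(v) {
    v <- as.numeric(v)
    if (length(v) == 1) v <- rep(v, 5)
    stopifnot(length(v) == 5, all(v > 0)); v
  })
  structure(list(vmax = vmax, km = km), class = "transporter_params")
}

#' Bile acid toxicity parameters
#'
#' Parameters of the ATP-decline model: per toxicity class, a Hill-type
#' signal S = 1 / (1 + vmax_s * X^H / (km_s^H + X^H)) driven by the delayed
#' intracellular bile acid concentration X, and globally the ATP turnover
#' rate and baseline. ATP follows
#' d(ATP)/dt = k_synth * S * etc - k_usage * ATP / baseline_atp,
#' with k_synth = k_usage = `k_atp` so that the drug-free steady state is
#' `baseline_atp`.
#'
#' @param vmax_s,km_s,hill,tau numeric length-2 vectors (CDCA-like,
#'   LCA-like): maximal signal denominator (unitless), Michaelis constant
#'   (uM), Hill coefficient (>= 1), delay rate (1/h).
#' @param k_atp ATP turnover rate, mM/h.
#' @param baseline_atp baseline hepatic ATP, mM.
#' @return a `tox_params` list.
#' @export
tox_params <- function(vmax_s, km_s, hill, tau, k_atp, baseline_atp) {
  rep2 <- function(x) if (length(x) == 1) rep(x, 2) else x
  vmax_s <- rep2(vmax_s); km_s <- rep2(km_s)
  hill <- rep2(hill); tau <- rep2(tau)
  stopifnot(length(vmax_s) == 2, all(vmax_s >= 0), all(km_s > 0),
            all(hill >= 1), all(tau > 0), k_atp > 0, baseline_atp > 0)
  structure(list(vmax_s = vmax_s, km_s = km_s, hill = hill, tau = tau,
                 k_atp = k_atp, baseline_atp = baseline_atp),
            class = "tox_params")
}

#' Hepatocyte injury and biomarker parameters
#'
#' Links ATP depletion to hepatocyte necrosis and serum biomarkers.
#' Necrosis hazard is `k_necrosis_max * (max(0, thr - ATP)/thr)^necrosis_hill`
#' with `thr = atp_death_threshold`; ALT (fold of baseline) is released in
#' proportion to the necrosed fraction and cleared first order; bilirubin
#' fold relaxes toward `1/viable_fraction` (reduced clearance as hepatocyte
#' mass is lost); the viable fraction regrows logistically.
#'
#' @param atp_death_threshold mM (< baseline ATP).
#' @param k_necrosis_max maximal necrosis hazard, 1/h.
#' @param necrosis_hill exponent of the sub-threshold response.
#' @param alt_content serum ALT fold released per unit necrosed liver
#'   fraction.
#' @param k_alt_clear first-order serum ALT clearance, 1/h.
#' @param k_bili_base_clear bilirubin relaxation rate, 1/h.
#' @param k_regen hepatocyte regeneration rate, 1/h.
#' @return an `injury_params` list.
#' @export
injury_params <- function(atp_death_threshold, k_necrosis_max, necrosis_hill,
                          alt_content, k_alt_clear, k_bili_base_clear,
                          k_regen) {
  stopifnot(atp_death_threshold > 0, k_necrosis_max > 0, necrosis_hill > 0,
            alt_content > 0, k_alt_clear > 0, k_bili_base_clear > 0,
            k_regen > 0)
  structure(list(atp_death_threshold = atp_death_threshold,
                 k_necrosis_max = k_necrosis_max,
                 necrosis_hill = necrosis_hill, alt_content = alt_content,
                 k_alt_clear = k_alt_clear,
                 k_bili_base_clear = k_bili_base_clear, k_regen = k_regen),
            class = "injury_params")
}
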