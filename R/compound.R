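#' Transporter inhibition specification
#'
#' Describes reversible inhibition of one transporter (or of mitochondrial
#' ATP synthesis via the electron transport chain) by a drug species.
#' Competitive inhibition scales the apparent Michaelis constant by
#' `(1 + I/Ki)`; noncompetitive inhibition divides the maximal rate by the
#' same factor. ETC inhibition always acts as a capacity (noncompetitive-
#' like) factor on ATP synthesis.
#'
#' @param transporter one of `"BSEP"`, `"NTCP"`, `"BASOLATERAL"`, `"ETC"`.
#' @param ki inhibition constant, uM (> 0).
#' @param mode `"competitive"` or `"noncompetitive"`; ignored for ETC.
#' @return an `inhibition_spec` list.
#' @export
inhibition_spec <- function(transporter, ki, mode = "noncompetitive") {
  transporter <- match.arg(transporter, c("BSEP", "NTCP", "BASOLATERAL", "ETC"))
  mode <- match.arg(mode, c("competitive", "noncompetitive"))
  stopifnot(is.numeric(ki), length(ki) == 1, ki > 0)
  structure(list(transporter = transporter, ki = ki, mode = mode),
            class = "inhibition_spec")
}

#' Metabolite formation pathway
#'
#' A saturable (Michaelis-Menten) hepatic metabolism route from the parent
#' drug to one metabolite, with the metabolite's own biliary clearance and
#' transporter inhibition profile.
#'
#' @param product_name metabolite name.
#' @param vmax_formation maximal formation rate, umol/h (whole liver).
#' @param km_formation Michaelis constant, uM (> 0).
#' @param product_biliary_cl metabolite biliary clearance, mL/h/kg^0.75.
#' @param product_inhibitions list of [inhibition_spec()] for the metabolite.
#' @param product_passive_cl liver-blood bidirectional passive clearance of
#'   the metabolite, L/h (default 0 keeps the metabolite hepatic).
#' @param product_renal_cl metabolite renal clearance from blood, L/h.
#' @return a `metabolite_path` list.
#' @export
metabolite_path <- function(product_name, vmax_formation, km_formation,
                            product_biliary_cl = 0,
                            product_inhibitions = list(),
                            product_passive_cl = 0,
                            product_renal_cl = 0) {
  stopifnot(vmax_formation >= 0, km_formation > 0,
            product_biliary_cl >= 0, product_passive_cl >= 0,
            product_renal_cl >= 0)
  structure(list(product_name = product_name,
                 vmax_formation = vmax_formation,
                 km_formation = km_formation,
                 product_biliary_cl = product_biliary_cl,
                 product_inhibitions = product_inhibitions,
                 product_passive_cl = product_passive_cl,
                 product_renal_cl = product_renal_cl),
            class = "metabolite_path")
}

#' Autoinduction specification
#'
#' First-order approach of an induction multiplier from 1 to `fold_max`
#' with rate `k_ind`, applied to hepatic uptake Vmax and/or metabolism Vmax
#' from the start of dosing. Captures compounds (e.g. bosentan) that induce
#' their own uptake and metabolism on repeated dosing.
#'
#' @param targets character subset of `c("uptake_vmax", "metabolism_vmax")`.
#' @param fold_max plateau multiplier (>= 1).
#' @param k_ind first-order rate of approach to plateau, 1/h (> 0).
#' @return an `induction_spec` list.
#' @export
induction_spec <- function(targets = c("uptake_vmax", "metabolism_vmax"),
                           fold_max, k_ind) {
  targets <- match.arg(targets, c("uptake_vmax", "metabolism_vmax"),
                       several.ok = TRUE)
  stopifnot(fold_max >= 1, k_ind > 0)
  structure(list(targets = targets, fold_max = fold_max, k_ind = k_ind),
            class = "induction_spec")
}

#' Drug disposition model
#'
#' Parameterization of one compound and its metabolites for the minimal
#' PBPK model: gut lumen -> portal blood -> liver <-> systemic blood <->
#' peripheral tissue, with saturable hepatic uptake, passive liver-blood
#' exchange, Michaelis-Menten metabolite formation in the liver, biliary
#' and renal clearance, and optional autoinduction.
#'
#' @param name compound name.
#' @param molecular_weight g/mol.
#' @param ka first-order oral absorption rate, 1/h.
#' @param f_abs fraction absorbed, in `[0, 1]`.
#' @param uptake_vmax maximal active hepatic uptake, umol/h/kg^0.75
#'   (allometrically scaled by bodyweight^0.75 at simulation time).
#' @param uptake_km uptake Michaelis constant, uM.
#' @param passive_cl bidirectional passive liver-blood clearance, L/h.
#' @param biliary_cl biliary clearance of parent from liver, mL/h/kg^0.75.
#' @param renal_cl renal clearance from systemic blood, L/h.
#' @param v_central central (plasma) distribution volume, L/kg.
#' @param v_peripheral peripheral volume, L/kg.
#' @param q_peripheral central-peripheral distribution clearance, L/h.
#' @param metabolites list of [metabolite_path()] (at most 2).
#' @param induction an [induction_spec()] or `NULL`.
#' @param inhibitions list of [inhibition_spec()] for the parent.
#' @return a `compound_model` list.
#' @export
compound_model <- function(name, molecular_weight, ka, f_abs,
                           uptake_vmax = 0, uptake_km = 1,
                           passive_cl = 0, biliary_cl = 0, renal_cl = 0,
                           v_central = 0.25, v_peripheral = 0,
                           q_peripheral = 0,
                           metabolites = list(), induction = NULL,
                           inhibitions = list()) {
  stopifnot(molecular_weight > 0, ka >= 0, f_abs >= 0, f_abs <= 1,
            uptake_vmax >= 0, uptake_km > 0, passive_cl >= 0,
            biliary_cl >= 0, renal_cl >= 0, v_central > 0,
            v_peripheral >= 0, q_peripheral >= 0,
            length(metabolites) <= 2)
  structure(list(name = name, molecular_weight = molecular_weight,
                 ka = ka, f_abs = f_abs,
                 uptake_vmax = uptake_vmax, uptake_km = uptake_km,
                 passive_cl = passive_cl, biliary_cl = biliary_cl,
                 renal_cl = renal_cl, v_central = v_central,
                 v_peripheral = v_peripheral, q_peripheral = q_peripheral,
                 metabolites = metabolites, induction = induction,
                 inhibitions = inhibitions),
            class = "compound_model")
}

#' Dosing regimen
#'
#' @param amount dose, mg (or mg/kg when `per_kg = TRUE`, the usual rat
#'   convention).
#' @param interval dosing interval, h.
#' @param n_doses number of doses (>= 1).
#' @param route `"oral"` (dose enters gut lumen) or `"iv"` (bolus into
#'   systemic blood).
#' @param per_kg interpret `amount` as mg/kg bodyweight.
#' @return a `dose_regimen` list.
#' @export
dose_regimen <- function(amount, interval = 24, n_doses = 1,
                         route = c("oral", "iv"), per_kg = FALSE) {
  route <- match.arg(route)
  stopifnot(amount >= 0, interval > 0, n_doses >= 1)
  structure(list(amount = amount, interval = interval,
                 n_doses = as.integer(n_doses), route = route,
                 per_kg = per_kg),
            class = "dose_regimen")
}

#' Dose event times of a regimen
#' @param regimen a [dose_regimen()].
#' @return numeric vector of dose times, h (first dose at 0).
#' @export
dose_times <- function(regimen) {
  regimen$interval * (seq_len(regimen$n_doses) - 1)
}

#' Scale metabolite formation capacity (impaired-metabolism variant)
#'
#' Multiplies the formation Vmax of every metabolite pathway by `factor`,
#' leaving all other parameters (including uptake Vmax) untouched. Used to
#' represent a metabolic polymorphism, e.g. a 10-fold reduction in
#' bosentan metabolism.
#'
#' @param compound a [compound_model()].
#' @param factor multiplicative factor, in `(0, 1]`.
#' @return a modified copy of `compound`.
#' @export
apply_impaired_metabolism <- function(compound, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    stop("`factor` must be a single value in (0, 1]")
  compound$metabolites <- lapply(compound$metabolites, function(m) {
    m$vmax_formation <- m$vmax_formation * factor
    m
  })
  compound
}

#' Names of all drug species in a compound model (parent first)
#' @param compound a [compound_model()].
#' @return character vector.
#' @export
compound_species <- function(compound) {
  c(compound$name,
    vapply(compound$metabolites, `[[`, "", "product_name"))
}
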