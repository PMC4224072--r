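#' Load a species configuration (physiology, transporters, toxicity, injury)
#'
#' Reads the packaged YAML parameter file for a species (or a user file of
#' the same schema). Keys carry explicit units (e.g. `ba_synthesis_umol_per_h`).
#'
#' @param species `"human"`, `"rat"`, or a path to a YAML file.
#' @return list with elements `physiology`, `transporters`, `tox`, `injury`.
#' @export
load_species_config <- function(species = "human") {
  path <- if (file.exists(species)) species else
    system.file("extdata", paste0("physiology_", species, ".yaml"),
                package = "biletox")
  if (!nzchar(path) || !file.exists(path))
    stop("no configuration found for species '", species, "'")
  y <- yaml::read_yaml(path)
  phys <- species_physiology(
    species = y$species,
    bodyweight = y$bodyweight_kg,
    liver_volume = y$liver_volume_L,
    blood_volume = y$blood_volume_L,
    portal_volume = y$portal_volume_L,
    hepatic_blood_flow = y$hepatic_blood_flow_L_per_h,
    ba_synthesis = y$ba_synthesis_umol_per_h,
    toxic_pool_fraction = y$toxic_pool_fraction,
    lca_hydroxylation_cl = y$lca_hydroxylation_cl_L_per_h,
    gut_conversion_k = y$gut_conversion_k_per_h,
    conjugation_k = y$conjugation_k_per_h,
    sulfation_k = y$sulfation_k_per_h,
    gut_transit_k = y$gut_transit_k_per_h,
    fecal_loss_fraction = y$fecal_loss_fraction,
    gallbladder_empty_fraction = y$gallbladder_empty_fraction,
    meal_times = as.numeric(y$meal_times_h),
    baseline_atp = y$baseline_atp_mM)
  tr <- transporter_params(
    vmax = lapply(y$transporters, function(t) t$vmax_umol_per_h),
    km = lapply(y$transporters, function(t) t$km_uM))
  tox <- tox_params(
    vmax_s = as.numeric(y$toxicity$vmax_s),
    km_s = as.numeric(y$toxicity$km_s_uM),
    hill = as.numeric(y$toxicity$hill),
    tau = as.numeric(y$toxicity$tau_per_h),
    k_atp = y$toxicity$k_atp_mM_per_h,
    baseline_atp = y$baseline_atp_mM)
  inj <- injury_params(
    atp_death_threshold = y$injury$atp_death_threshold_mM,
    k_necrosis_max = y$injury$k_necrosis_max_per_h,
    necrosis_hill = y$injury$necrosis_hill,
    alt_content = y$injury$alt_content_fold_per_fraction,
    k_alt_clear = y$injury$k_alt_clear_per_h,
    k_bili_base_clear = y$injury$k_bili_base_clear_per_h,
    k_regen = y$injury$k_regen_per_h)
  list(physiology = phys, transporters = tr, tox = tox, injury = inj)
}

parse_inhibitions <- function(lst) {
  lapply(lst, function(i)
    inhibition_spec(i$transporter, i$ki_uM,
                    mode = i$mode %||% "noncompetitive"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a compound model from a packaged or user YAML file
#'
#' @param name a packaged compound name (e.g. `"bosentan"`,
#'   `"bosentan_rat"`, `"telmisartan"`, `"cp724714"`) or a YAML path.
#' @return a [compound_model()] with attribute `default_regimen`.
#' @export
load_compound <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("compound_", name, ".yaml"),
                package = "biletox")
  if (!nzchar(path) || !file.exists(path))
    stop("no compound configuration named '", name, "'")
  y <- yaml::read_yaml(path)
  mets <- lapply(y$metabolites %||% list(), function(m)
    metabolite_path(
      product_name = m$product_name,
      vmax_formation = m$vmax_formation_umol_per_h,
      km_formation = m$km_formation_uM,
      product_biliary_cl = m$product_biliary_cl_mL_per_h_per_kg075 %||% 0,
      product_inhibitions = parse_inhibitions(m$product_inhibitions %||% list()),
      product_passive_cl = m$product_passive_cl_L_per_h %||% 0,
      product_renal_cl = m$product_renal_cl_L_per_h %||% 0))
  ind <- NULL
  if (!is.null(y$induction))
    ind <- induction_spec(targets = unlist(y$induction$targets),
                          fold_max = y$induction$fold_max,
                          k_ind = y$induction$k_ind_per_h)
  cm <- compound_model(
    name = y$name, molecular_weight = y$molecular_weight_g_per_mol,
    ka = y$ka_per_h, f_abs = y$f_abs,
    uptake_vmax = y$uptake_vmax_umol_per_h_per_kg075 %||% 0,
    uptake_km = y$uptake_km_uM %||% 1,
    passive_cl = y$passive_cl_L_per_h %||% 0,
    biliary_cl = y$biliary_cl_mL_per_h_per_kg075 %||% 0,
    renal_cl = y$renal_cl_L_per_h %||% 0,
    v_central = y$v_central_L_per_kg,
    v_peripheral = y$v_peripheral_L_per_kg %||% 0,
    q_peripheral = y$q_peripheral_L_per_h %||% 0,
    metabolites = mets, induction = ind,
    inhibitions = parse_inhibitions(y$inhibitions %||% list()))
  if (!is.null(y$default_regimen)) {
    r <- y$default_regimen
    attr(cm, "default_regimen") <- dose_regimen(
      amount = r$amount_mg, interval = r$interval_h, n_doses = r$n_doses,
      route = r$route %||% "oral", per_kg = isTRUE(r$per_kg))
  }
  cm
}

#' Load the packaged virtual-population specification for a species
#'
#' @param species `"human"` or `"rat"`, or a YAML path.
#' @return list with `n`, `seed`, `specs` (list of [variability_spec()])
#'   and `acceptance_ranges`.
#' @export
load_vpop_config <- function(species = "human") {
  path <- if (file.exists(species)) species else
    system.file("extdata", paste0("vpop_", species, ".yaml"),
                package = "biletox")
  if (!nzchar(path) || !file.exists(path))
    stop("no population configuration for '", species, "'")
  y <- yaml::read_yaml(path)
  specs <- lapply(y$variability, function(v)
    variability_spec(parameter_path = v$parameter_path,
                     distribution = v$distribution,
                     location = v$location, scale = v$scale,
                     lower_bound = v$lower_bound %||% -Inf,
                     upper_bound = v$upper_bound %||% Inf))
  acc <- lapply(y$acceptance_ranges, function(r) as.numeric(unlist(r)))
  list(n = y$n_individuals, seed = y$seed, specs = specs, acceptance_ranges = acc)
}
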