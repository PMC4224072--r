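# Compound modifiers used by the scenario registry -------------------------

modify_specs <- function(specs, transporter, fn) {
  lapply(specs, function(s) {
    if (s$transporter == transporter) fn(s) else s
  })
}

#' Scenario-level compound modifications
#'
#' Helpers that build hypothesis variants of a compound: override an
#' inhibition constant or mode, add an inhibition, or change a metabolite's
#' biliary clearance.
#'
#' @param compound a [compound_model()].
#' @param transporter transporter name.
#' @param ki new inhibition constant, uM.
#' @param mode `"competitive"` or `"noncompetitive"`.
#' @param where `"parent"`, `"metabolite"` (all), or `"all"`.
#' @param spec an [inhibition_spec()] to add.
#' @param j metabolite index.
#' @param value new biliary clearance, mL/h/kg^0.75.
#' @return the modified compound.
#' @name scenario_modifiers
NULL

#' @rdname scenario_modifiers
#' @export
override_ki <- function(compound, transporter, ki, where = "all") {
  f <- function(s) { s$ki <- ki; s }
  if (where %in% c("parent", "all"))
    compound$inhibitions <- modify_specs(compound$inhibitions, transporter, f)
  if (where %in% c("metabolite", "all"))
    compound$metabolites <- lapply(compound$metabolites, function(m) {
      m$product_inhibitions <- modify_specs(m$product_inhibitions,
                                            transporter, f)
      m
    })
  compound
}

#' @rdname scenario_modifiers
#' @export
set_inhibition_mode <- function(compound, transporter, mode,
                                where = "all") {
  mode <- match.arg(mode, c("competitive", "noncompetitive"))
  f <- function(s) { s$mode <- mode; s }
  if (where %in% c("parent", "all"))
    compound$inhibitions <- modify_specs(compound$inhibitions, transporter, f)
  if (where %in% c("metabolite", "all"))
    compound$metabolites <- lapply(compound$metabolites, function(m) {
      m$product_inhibitions <- modify_specs(m$product_inhibitions,
                                            transporter, f)
      m
    })
  compound
}

#' @rdname scenario_modifiers
#' @export
add_inhibition <- function(compound, spec, where = "parent") {
  if (where %in% c("parent", "all"))
    compound$inhibitions <- c(compound$inhibitions, list(spec))
  if (where %in% c("metabolite", "all"))
    compound$metabolites <- lapply(compound$metabolites, function(m) {
      m$product_inhibitions <- c(m$product_inhibitions, list(spec))
      m
    })
  compound
}

#' @rdname scenario_modifiers
#' @export
set_metabolite_biliary_cl <- function(compound, j, value) {
  stopifnot(j <= length(compound$metabolites), value >= 0)
  compound$metabolites[[j]]$product_biliary_cl <- value
  compound
}

# Scenario registry ---------------------------------------------------------

#' Build a registered simulation scenario
#'
#' A scenario bundles a species, a compound variant (hypothesis flags
#' applied) and a dosing regimen. [list_scenarios()] enumerates the
#' registry.
#'
#' @param name registered scenario name.
#' @param cp_dose_mg CP-724,714 dose for its scenarios, mg (three times
#'   daily).
#' @param basolateral_ki exploratory bosentan basolateral efflux Ki, uM
#'   (not established experimentally; exposed as a knob).
#' @param etc_ki_parent,etc_ki_metabolite CP-724,714 electron transport
#'   chain inhibition constants, uM (scenario parameters).
#' @return a `scenario` list: `name`, `species`, `compound`, `regimen`,
#'   `pk_variability`, `description`.
#' @export
scenario <- function(name, cp_dose_mg = 250, basolateral_ki = 4,
                     etc_ki_parent = 100, etc_ki_metabolite = 5) {
  reg <- scenario_table()
  if (!name %in% reg$name)
    stop("unknown scenario '", name, "'; available: ",
         paste(reg$name, collapse = ", "))
  species <- reg$species[reg$name == name]
  desc <- reg$description[reg$name == name]
  pkvar <- FALSE
  if (startsWith(name, "bosentan_rat")) {
    cm <- load_compound("bosentan_rat")
    regn <- attr(cm, "default_regimen")
    if (name == "bosentan_rat_no_uptake_inhibition")
      cm <- override_ki(cm, "NTCP", 1e10)
  } else if (startsWith(name, "bosentan")) {
    cm <- load_compound("bosentan")
    regn <- attr(cm, "default_regimen")
    if (name == "bosentan_human_pk_variability") pkvar <- TRUE
    if (name == "bosentan_human_impaired_metabolism")
      cm <- apply_impaired_metabolism(cm, 0.1)
    if (name == "bosentan_human_basolateral")
      cm <- add_inhibition(cm, inhibition_spec("BASOLATERAL",
                                               ki = basolateral_ki,
                                               mode = "noncompetitive"))
  } else if (startsWith(name, "telmisartan")) {
    cm <- load_compound("telmisartan")
    regn <- attr(cm, "default_regimen")
    dose <- as.numeric(strsplit(name, "_")[[1]][2])
    regn$amount <- dose
    mode <- if (grepl("noncompetitive", name)) "noncompetitive"
      else "competitive"
    cm <- set_inhibition_mode(cm, "BSEP", mode)
  } else if (startsWith(name, "cp724714")) {
    cm <- load_compound("cp724714")
    regn <- attr(cm, "default_regimen")
    regn$amount <- cp_dose_mg
    # baseline assumptions: parent-only competitive BSEP, no ETC
    if (name %in% c("cp724714_metabolite_inhibition",
                    "cp724714_poor_clearance", "cp724714_noncompetitive",
                    "cp724714_etc"))
      cm <- add_inhibition(cm,
                           inhibition_spec("BSEP",
                                           ki = cm$inhibitions[[1]]$ki,
                                           mode = "competitive"),
                           where = "metabolite")
    if (name %in% c("cp724714_poor_clearance", "cp724714_noncompetitive",
                    "cp724714_etc"))
      cm <- set_metabolite_biliary_cl(cm, 1, cm$biliary_cl * 0.1)
    if (name == "cp724714_noncompetitive")
      cm <- set_inhibition_mode(cm, "BSEP", "noncompetitive")
    if (name == "cp724714_etc") {
      cm <- add_inhibition(cm, inhibition_spec("ETC", ki = etc_ki_parent),
                           where = "parent")
      cm <- add_inhibition(cm,
                           inhibition_spec("ETC", ki = etc_ki_metabolite),
                           where = "metabolite")
    }
  }
  structure(list(name = name, species = species, compound = cm,
                 regimen = regn, pk_variability = pkvar,
                 description = desc),
            class = "scenario")
}

scenario_table <- function() {
  tibble::tribble(
    ~name, ~species, ~description,
    "bosentan_human_baseline", "human",
    "bosentan 500 mg q12h x 30 d, noncompetitive BSEP (parent Ki 12 uM, minor metabolite 8.5 uM), competitive NTCP (Ki 18 uM)",
    "bosentan_human_pk_variability", "human",
    "baseline bosentan with normal PK variability layered on absorption, uptake Vmax and both metabolite formation Vmax",
    "bosentan_human_impaired_metabolism", "human",
    "bosentan with both metabolite formation Vmax at 10% of baseline (slow-metabolizer polymorphism)",
    "bosentan_human_basolateral", "human",
    "bosentan with exploratory basolateral efflux inhibition added",
    "bosentan_rat", "rat",
    "bosentan 50 mg/kg once daily in rat, noncompetitive BSEP and NTCP (Ki 0.23 uM)",
    "bosentan_rat_no_uptake_inhibition", "rat",
    "rat bosentan with NTCP inhibition eliminated (Ki 1e10 uM)",
    "telmisartan_50_competitive", "human",
    "telmisartan 50 mg once daily x 30 d, competitive BSEP Ki 16 uM",
    "telmisartan_50_noncompetitive", "human",
    "telmisartan 50 mg once daily x 30 d, noncompetitive BSEP Ki 16 uM",
    "telmisartan_3000_noncompetitive", "human",
    "telmisartan 3000 mg once daily, noncompetitive",
    "telmisartan_12000_noncompetitive", "human",
    "telmisartan 12000 mg once daily, noncompetitive",
    "cp724714_baseline", "human",
    "CP-724,714 q8h, parent-only competitive BSEP Ki 7.45 uM, no ETC inhibition",
    "cp724714_metabolite_inhibition", "human",
    "metabolite also inhibits BSEP with the parent Ki",
    "cp724714_poor_clearance", "human",
    "metabolite inhibition + metabolite biliary clearance at 10% of parent",
    "cp724714_noncompetitive", "human",
    "poor clearance variant with all BSEP inhibition noncompetitive",
    "cp724714_etc", "human",
    "poor clearance variant + electron transport chain inhibition by parent and metabolite")
}

#' List registered scenarios
#' @return tibble `name`, `species`, `description`.
#' @export
list_scenarios <- function() scenario_table()

#' Run a scenario end to end
#'
#' Single-individual mode (default) simulates the baseline individual of
#' the scenario's species; population mode runs a supplied or freshly
#' generated virtual population. Outputs can be written as tidy CSV plus a
#' summary JSON.
#'
#' @param x a scenario name or [scenario()] object.
#' @param population a `simpops`, `"default"` to generate the packaged
#'   population (331 human / 191 rat), or `NULL` for the single baseline
#'   individual.
#' @param seed integer seed (population generation and PK variability).
#' @param days override simulated duration, days.
#' @param out_dir if non-`NULL`, write `<name>_results.csv` and
#'   `<name>_summary.json` there.
#' @param engine `"C"` or `"R"`.
#' @param ... passed to [scenario()] when `x` is a name.
#' @return single mode: list `sim` (a `dili_sim`) and `summary` (tibble);
#'   population mode: list `results` (per-individual tibble), `incidence`,
#'   `summary`.
#' @export
run_scenario <- function(x, population = NULL, seed = 1L, days = NULL,
                         out_dir = NULL, engine = "C", ...) {
  sc <- if (inherits(x, "scenario")) x else scenario(x, ...)
  cfg <- load_species_config(sc$species)
  if (is.null(days))
    days <- ceiling(sc$regimen$n_doses * sc$regimen$interval / 24)
  if (is.null(population)) {
    bl <- solve_baseline(cfg$physiology, cfg$transporters, cfg$tox,
                         cfg$injury, engine = engine)
    sim <- simulate_dili(cfg$physiology, cfg$transporters, cfg$tox,
                         cfg$injury, compound = sc$compound,
                         regimen = sc$regimen, days = days,
                         init = bl$state, engine = engine)
    summary <- dplyr::bind_cols(
      tibble::tibble(scenario = sc$name, species = sc$species),
      summarize_individual(sim, days))
    out <- list(scenario = sc, sim = sim, summary = summary)
  } else {
    if (identical(population, "default")) {
      vp <- load_vpop_config(sc$species)
      population <- generate_simpops(vp$n, vp$specs, cfg$physiology,
                                     cfg$transporters, cfg$tox, cfg$injury,
                                     seed = if (is.null(seed)) vp$seed else seed,
                                     acceptance_ranges = vp$acceptance_ranges,
                                     engine = engine)
    }
    if (sc$pk_variability)
      population <- add_pk_variability(population, default_pk_specs(),
                                       seed = seed + 1L)
    results <- run_population(population, sc, days = days, engine = engine)
    inc <- incidence(results)
    summary <- dplyr::bind_cols(
      tibble::tibble(scenario = sc$name, species = sc$species), inc,
      tibble::tibble(median_min_atp_mM = median(results$min_atp_mM,
                                                na.rm = TRUE)))
    out <- list(scenario = sc, results = results, incidence = inc,
                summary = summary)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$results))
      write.csv(out$results,
                file.path(out_dir, paste0(sc$name, "_results.csv")),
                row.names = FALSE)
    jsonlite::write_json(
      c(as.list(out$summary), list(seed = seed)),
      file.path(out_dir, paste0(sc$name, "_summary.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Default PK variability specification (4 parameters, normal factors)
#' @return list of 4 [variability_spec()].
#' @export
default_pk_specs <- function() {
  mk <- function(path) variability_spec(path, "normal", location = 1,
                                        scale = 0.25, lower_bound = 0.3,
                                        upper_bound = 2.5)
  list(mk("compound.ka"), mk("compound.uptake_vmax"),
       mk("compound.metabolites.1.vmax_formation"),
       mk("compound.metabolites.2.vmax_formation"))
}

#' Peak ALT fold as a function of metabolite biliary clearance
#'
#' Repeats the CP-724,714 combined-mechanism simulation (competitive BSEP
#' inhibition by parent and metabolite plus ETC inhibition) at a fixed dose
#' while sweeping the metabolite biliary clearance, which is unconstrained
#' by parent plasma pharmacokinetics.
#'
#' @param cl_values metabolite biliary clearances, mL/h/kg^0.75 (> 0).
#' @param cp_dose_mg dose, mg (three times daily).
#' @param days duration, days.
#' @param engine `"C"` or `"R"`.
#' @return tibble `metabolite_biliary_cl`, `peak_alt_fold`,
#'   `peak_norm_lft`, `min_atp_mM`.
#' @export
metabolite_clearance_sweep <- function(cl_values = c(1, 2, 5, 10, 20, 50),
                                       cp_dose_mg = 400, days = 30,
                                       engine = "C") {
  stopifnot(all(cl_values > 0))
  cfg <- load_species_config("human")
  bl <- solve_baseline(cfg$physiology, cfg$transporters, cfg$tox,
                       cfg$injury, engine = engine)
  purrr::map_dfr(cl_values, function(cl) {
    sc <- scenario("cp724714_etc", cp_dose_mg = cp_dose_mg)
    sc$compound <- set_metabolite_biliary_cl(sc$compound, 1, cl)
    sim <- simulate_dili(cfg$physiology, cfg$transporters, cfg$tox,
                         cfg$injury, compound = sc$compound,
                         regimen = sc$regimen, days = days,
                         init = bl$state, engine = engine)
    s <- summarize_individual(sim, days)
    tibble::tibble(metabolite_biliary_cl = cl,
                   peak_alt_fold = s$peak_alt_fold,
                   peak_norm_lft = s$peak_norm_lft,
                   min_atp_mM = s$min_atp_mM)
  })
}

#' Normalized LFT elevation versus steady-state exposure
#'
#' For each dose, runs the named CP-724,714 hypothesis scenario in the
#' baseline human and reports the day-22 AUC(0-24) of parent plasma
#' exposure together with the peak normalized LFT over the whole
#' simulation.
#'
#' @param scenario_names registered CP-724,714 scenario names.
#' @param doses doses, mg.
#' @param days duration, days (>= 22).
#' @param engine `"C"` or `"R"`.
#' @return tibble `scenario`, `dose_mg`, `auc24_day22_uM_h`,
#'   `peak_norm_lft`.
#' @export
lft_vs_auc_table <- function(scenario_names = c("cp724714_baseline",
                                                "cp724714_etc"),
                             doses = c(100, 250, 400, 650),
                             days = 30, engine = "C") {
  if (days < 22) stop("regimen must span at least 22 days")
  cfg <- load_species_config("human")
  bl <- solve_baseline(cfg$physiology, cfg$transporters, cfg$tox,
                       cfg$injury, engine = engine)
  grid <- expand.grid(scenario = scenario_names, dose_mg = doses,
                      stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sc <- scenario(grid$scenario[i], cp_dose_mg = grid$dose_mg[i])
    sim <- simulate_dili(cfg$physiology, cfg$transporters, cfg$tox,
                         cfg$injury, compound = sc$compound,
                         regimen = sc$regimen, days = days,
                         init = bl$state, engine = engine)
    curve <- sim_tidy(sim, "drug")
    class(curve) <- c("pk_curve", class(curve))
    alt <- sim$state[, IDX_ALT]; bili <- sim$state[, IDX_BILI]
    tibble::tibble(scenario = grid$scenario[i], dose_mg = grid$dose_mg[i],
                   auc24_day22_uM_h = auc(curve, sc$compound$name,
                                          21 * 24, 22 * 24),
                   peak_norm_lft = max(normalized_lft(alt, bili)))
  })
}
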