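#' Parameter variability specification
#'
#' One sampled dimension of a virtual population. Samples are
#' multiplicative factors applied to the baseline value addressed by
#' `parameter_path` (`"transporters.<T>.vmax"`, `"physiology.ba_synthesis"`,
#' `"compound.ka"`, `"compound.uptake_vmax"`,
#' `"compound.metabolites.<j>.vmax_formation"`).
#'
#' @param parameter_path target parameter (see above).
#' @param distribution `"lognormal"` (location/scale on the log scale) or
#'   `"normal"`.
#' @param location,scale distribution parameters (scale > 0).
#' @param lower_bound,upper_bound truncation bounds for the factor.
#' @return a `variability_spec` list.
#' @export
variability_spec <- function(parameter_path,
                             distribution = c("lognormal", "normal"),
                             location = 0, scale, lower_bound = -Inf,
                             upper_bound = Inf) {
  distribution <- match.arg(distribution)
  stopifnot(scale > 0, lower_bound < upper_bound)
  structure(list(parameter_path = parameter_path,
                 distribution = distribution, location = location,
                 scale = scale, lower_bound = lower_bound,
                 upper_bound = upper_bound),
            class = "variability_spec")
}

sample_spec <- function(spec) {
  repeat {
    x <- if (spec$distribution == "lognormal")
      rlnorm(1, spec$location, spec$scale)
    else rnorm(1, spec$location, spec$scale)
    if (x >= spec$lower_bound && x <= spec$upper_bound && x > 0) return(x)
  }
}

#' Apply multiplicative overrides to model components
#'
#' @param overrides named numeric vector (names are parameter paths).
#' @param physiology,transporters,compound components to modify; only
#'   those addressed by the overrides need be non-`NULL`.
#' @return list with the modified `physiology`, `transporters`, `compound`.
#' @export
apply_overrides <- function(overrides, physiology = NULL,
                            transporters = NULL, compound = NULL) {
  for (path in names(overrides)) {
    v <- overrides[[path]]
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (parts[1] == "transporters") {
      transporters$vmax[[parts[2]]] <- transporters$vmax[[parts[2]]] * v
    } else if (parts[1] == "physiology") {
      physiology[[parts[2]]] <- physiology[[parts[2]]] * v
    } else if (parts[1] == "compound") {
      sub <- paste(parts[-1], collapse = ".")
      if (!is.null(compound))
        compound <- set_param(compound, sub,
                              get_param(compound, sub) * v)
    } else stop("unknown parameter path: ", path)
  }
  list(physiology = physiology, transporters = transporters,
       compound = compound)
}

#' Baseline observables of a solved drug-free state
#' @keywords internal
baseline_observables <- function(state, physiology) {
  liv <- sum(state[IDX_BA(1:5, 1L)]) / physiology$liver_volume
  serum <- sum(state[IDX_BA(1:5, 5L)]) /
    (physiology$blood_volume - physiology$portal_volume)
  c(liver_ba_uM = liv, serum_ba_uM = serum, atp_mM = state[[IDX_ATP]])
}

#' Generate a seeded virtual population
#'
#' Rejection-samples parameter multipliers from the variability specs,
#' solves each candidate's drug-free periodic baseline, and accepts
#' candidates whose baseline observables (liver and serum total toxic bile
#' acid concentration, uM) fall within the plausibility ranges, until `n`
#' individuals are accepted. Fully reproducible from `seed`.
#'
#' @param n number of individuals (human populations mirroring the study
#'   use 331, rat 191; any n >= 1 is supported).
#' @param specs list of [variability_spec()].
#' @param physiology,transporters,tox,injury baseline model configuration.
#' @param seed integer seed.
#' @param acceptance_ranges named list of `c(lo, hi)` per observable
#'   (`liver_ba_uM`, `serum_ba_uM`); `NULL` accepts every candidate.
#' @param baseline_days per-candidate baseline re-solve horizon, days
#'   (warm-started from the reference baseline).
#' @param engine `"C"` or `"R"`.
#' @return a `simpops` object.
#' @export
generate_simpops <- function(n, specs, physiology, transporters, tox,
                             injury, seed = 1L, acceptance_ranges = NULL,
                             baseline_days = 14, engine = "C") {
  stopifnot(n >= 1, length(specs) >= 1)
  ref <- solve_baseline(physiology, transporters, tox, injury,
                        days = 30, engine = engine)
  set.seed(seed)
  individuals <- vector("list", n)
  accepted <- 0L; tried <- 0L
  while (accepted < n) {
    tried <- tried + 1L
    if (tried > 200L && accepted / tried < 0.01)
      stop("population acceptance rate below 1% (", accepted, "/", tried,
           " accepted); check acceptance_ranges against the baseline ",
           "observables of the sampled parameter space")
    overrides <- vapply(specs, sample_spec, 0)
    names(overrides) <- vapply(specs, `[[`, "", "parameter_path")
    mod <- apply_overrides(overrides, physiology, transporters)
    bl <- solve_baseline(mod$physiology, mod$transporters, tox, injury,
                         days = baseline_days, init = ref$state,
                         must_converge = FALSE, engine = engine)
    obs <- baseline_observables(bl$state, mod$physiology)
    ok <- bl$converged
    if (ok && !is.null(acceptance_ranges)) {
      for (nm in names(acceptance_ranges)) {
        r <- acceptance_ranges[[nm]]
        if (obs[[nm]] < r[1] || obs[[nm]] > r[2]) { ok <- FALSE; break }
      }
    }
    if (ok) {
      accepted <- accepted + 1L
      individuals[[accepted]] <- list(id = accepted, overrides = overrides,
                                      baseline_state = bl$state,
                                      baseline_summary = obs)
    }
  }
  structure(list(species = physiology$species, individuals = individuals,
                 seed = as.integer(seed), specs = specs,
                 acceptance_ranges = acceptance_ranges,
                 n_tried = tried,
                 physiology = physiology, transporters = transporters,
                 tox = tox, injury = injury),
            class = "simpops")
}

#' @export
print.simpops <- function(x, ...) {
  cat("<simpops>", length(x$individuals), x$species, "individuals, seed",
      x$seed, "(", x$n_tried, "candidates tried )\n")
  invisible(x)
}

#' Layer pharmacokinetic variability onto a population
#'
#' Adds seeded multiplicative overrides on exactly four PK parameters (oral
#' absorption coefficient, hepatic uptake Vmax, and the two metabolite
#' formation Vmax values) on top of the existing transport variability.
#'
#' @param pop a `simpops`.
#' @param pk_specs list of 4 [variability_spec()] whose paths are
#'   `compound.ka`, `compound.uptake_vmax`,
#'   `compound.metabolites.1.vmax_formation`,
#'   `compound.metabolites.2.vmax_formation`.
#' @param seed integer seed for the PK layer.
#' @return the population with per-individual `pk_overrides`.
#' @export
add_pk_variability <- function(pop, pk_specs, seed = 1L) {
  stopifnot(inherits(pop, "simpops"))
  need <- c("compound.ka", "compound.uptake_vmax",
            "compound.metabolites.1.vmax_formation",
            "compound.metabolites.2.vmax_formation")
  got <- sort(vapply(pk_specs, `[[`, "", "parameter_path"))
  if (!identical(got, sort(need)))
    stop("pk_specs must target exactly: ", paste(need, collapse = ", "))
  set.seed(seed)
  for (i in seq_along(pop$individuals)) {
    ov <- vapply(pk_specs, sample_spec, 0)
    names(ov) <- vapply(pk_specs, `[[`, "", "parameter_path")
    pop$individuals[[i]]$pk_overrides <- ov
  }
  pop$pk_seed <- as.integer(seed)
  pop
}

summarize_individual <- function(sim, days) {
  alt <- sim$state[, IDX_ALT]; bili <- sim$state[, IDX_BILI]
  out <- tibble::tibble(
    min_atp_mM = min(sim$state[, IDX_ATP]),
    peak_alt_fold = max(alt),
    peak_bili_fold = max(bili),
    peak_norm_lft = max(normalized_lft(alt, bili)),
    min_viable_fraction = min(sim$state[, IDX_VIABLE]),
    peak_liver_ba_uM = max(rowSums(
      sim$state[, IDX_BA(1:5, 1L), drop = FALSE])) /
      sim$physiology$liver_volume)
  if (!is.null(sim$compound)) {
    curve <- sim_tidy(sim, "drug")
    class(curve) <- c("pk_curve", class(curve))
    out$auc24_day1_uM_h <- auc(curve, sim$compound$name, 0,
                               min(24, max(sim$times)))
    out$auc24_day22_uM_h <- if (max(sim$times) >= 22 * 24)
      auc(curve, sim$compound$name, 21 * 24, 22 * 24) else NA_real_
  }
  out
}

#' Run a scenario over a virtual population
#'
#' Simulates every individual from its own solved baseline and summarizes
#' the outcome. Individual integration failures are recorded (`status`
#' column) and do not stop the run. Results are independent of execution
#' order.
#'
#' @param pop a `simpops` from [generate_simpops()].
#' @param scenario a [scenario()] (or `NULL` for a drug-free run).
#' @param days simulated duration, days (defaults to the scenario regimen
#'   span).
#' @param engine `"C"` or `"R"`.
#' @return tibble, one row per individual: outcome summaries plus `id` and
#'   `status`.
#' @export
run_population <- function(pop, scenario = NULL, days = NULL,
                           engine = "C") {
  stopifnot(inherits(pop, "simpops"))
  compound <- scenario$compound
  regimen <- scenario$regimen
  if (!is.null(scenario) && !identical(scenario$species, pop$species))
    stop("scenario species '", scenario$species,
         "' does not match population species '", pop$species, "'")
  if (is.null(days))
    days <- if (!is.null(regimen))
      ceiling(regimen$n_doses * regimen$interval / 24) else 30
  purrr::map_dfr(pop$individuals, function(ind) {
    mod <- apply_overrides(ind$overrides, pop$physiology,
                           pop$transporters, compound)
    cm <- mod$compound
    if (!is.null(ind$pk_overrides) && !is.null(cm))
      cm <- apply_overrides(ind$pk_overrides, compound = cm)$compound
    res <- tryCatch({
      sim <- simulate_dili(mod$physiology, mod$transporters, pop$tox,
                           pop$injury, compound = cm, regimen = regimen,
                           days = days, init = ind$baseline_state,
                           engine = engine)
      dplyr::bind_cols(tibble::tibble(id = ind$id, status = "ok"),
                       summarize_individual(sim, days))
    }, error = function(e) {
      tibble::tibble(id = ind$id, status = paste("error:",
                                                 conditionMessage(e)))
    })
    res
  })
}

#' ALT elevation incidence in population results
#'
#' @param results tibble from [run_population()].
#' @param alt_fold_threshold fold-of-baseline threshold (default 3).
#' @return tibble `n`, `n_elevated`, `percentage`.
#' @export
incidence <- function(results, alt_fold_threshold = 3) {
  stopifnot(nrow(results) > 0)
  ok <- results[results$status == "ok", ]
  n <- nrow(ok)
  cnt <- sum(ok$peak_alt_fold > alt_fold_threshold)
  tibble::tibble(n = n, n_elevated = cnt, percentage = 100 * cnt / n)
}

#' Export a population manifest as JSON
#'
#' Records the seed, variability specs, acceptance ranges and per-individual
#' overrides so a population is auditable and reproducible.
#'
#' @param pop a `simpops`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_population_manifest <- function(pop, path) {
  manifest <- list(
    species = pop$species, n = length(pop$individuals), seed = pop$seed,
    pk_seed = pop$pk_seed,
    specs = lapply(pop$specs, unclass),
    acceptance_ranges = pop$acceptance_ranges,
    individuals = lapply(pop$individuals, function(i)
      c(list(id = i$id), as.list(i$overrides),
        if (!is.null(i$pk_overrides)) as.list(i$pk_overrides),
        as.list(i$baseline_summary))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
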