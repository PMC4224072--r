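null_transporters <- function() {
  transporter_params(vmax = list(NTCP = 0, BSEP = 0, BASOLATERAL = 0),
                     km = list(NTCP = 1, BSEP = 1, BASOLATERAL = 1))
}

null_tox <- function(physiology) {
  tox_params(vmax_s = 0, km_s = 1, hill = 1, tau = 1, k_atp = 1,
             baseline_atp = physiology$baseline_atp)
}

null_injury <- function(physiology) {
  injury_params(atp_death_threshold = physiology$baseline_atp / 2,
                k_necrosis_max = 1e-12, necrosis_hill = 1, alt_content = 1,
                k_alt_clear = 0.02, k_bili_base_clear = 0.1,
                k_regen = 0.001)
}

#' Simulate plasma and liver drug exposure
#'
#' Runs the PBPK part of the model alone (the bile acid and toxicity
#' modules are inert) and returns tidy concentration-time curves for the
#' parent and every metabolite. Doses are instantaneous amounts added to
#' the gut lumen (oral) or systemic blood (IV) at each scheduled time.
#'
#' @param compound a [compound_model()].
#' @param regimen a [dose_regimen()].
#' @param physiology a [species_physiology()].
#' @param days duration; defaults to the regimen span plus one interval.
#' @param dt_out output resolution, h.
#' @param engine `"C"` or `"R"`.
#' @return a `pk_curve` tibble (`time_h`, `species`, `compartment`,
#'   `conc_uM`) with the full simulation attached as attribute `sim`.
#' @export
simulate_pk <- function(compound, regimen, physiology, days = NULL,
                        dt_out = 0.25, engine = "C") {
  stopifnot(inherits(compound, "compound_model"),
            inherits(regimen, "dose_regimen"))
  if (is.null(days))
    days <- (regimen$n_doses * regimen$interval) / 24
  sim <- simulate_dili(physiology, null_transporters(),
                       null_tox(physiology), null_injury(physiology),
                       compound = compound, regimen = regimen, days = days,
                       engine = engine, dt_out = dt_out, meals = FALSE)
  curve <- sim_tidy(sim, "drug")
  class(curve) <- c("pk_curve", class(curve))
  attr(curve, "sim") <- sim
  curve
}

#' Area under the plasma concentration curve
#'
#' Trapezoidal AUC of the plasma concentration of one drug species over
#' `[t_start, t_end]`, with linear interpolation at the interval ends.
#'
#' @param curve a `pk_curve` tibble from [simulate_pk()].
#' @param species drug species name (default: first present).
#' @param t_start,t_end integration bounds, h.
#' @return AUC, uM*h.
#' @export
auc <- function(curve, species = NULL, t_start = NULL, t_end = NULL) {
  sub <- curve[curve$compartment == "plasma", ]
  if (is.null(species)) species <- sub$species[1]
  if (!species %in% sub$species)
    stop("species '", species, "' not present in the curve")
  sub <- sub[sub$species == species, ]
  tt <- sub$time_h; cc <- sub$conc_uM
  if (is.null(t_start)) t_start <- min(tt)
  if (is.null(t_end)) t_end <- max(tt)
  if (!(t_start < t_end) || t_start < min(tt) - 1e-9 || t_end > max(tt) + 1e-9)
    stop("[t_start, t_end] must be an increasing interval within the curve")
  grid <- sort(unique(c(t_start, tt[tt > t_start & tt < t_end], t_end)))
  vals <- approx(tt, cc, xout = grid, ties = "ordered")$y
  sum(diff(grid) * (head(vals, -1) + tail(vals, -1)) / 2)
}

#' Drug mass balance audit
#'
#' Checks, at every output time, that administered drug equals the sum of
#' all compartment amounts plus cumulative elimination sinks: for the
#' parent, gut + portal + blood + liver + peripheral + fecal + renal +
#' biliary + cumulative metabolized; for each metabolite, cumulative formed
#' equals compartments plus its sinks.
#'
#' @param sim a `dili_sim` with a compound (or a `pk_curve`, whose attached
#'   simulation is used).
#' @return tibble per drug species: `species`, `max_rel_error`.
#' @export
drug_mass_balance <- function(sim) {
  if (inherits(sim, "pk_curve")) sim <- attr(sim, "sim")
  stopifnot(inherits(sim, "dili_sim"), !is.null(sim$compound))
  sp <- compound_species(sim$compound)
  tm <- sim$times
  sched <- sim$schedule
  # reported states at an event time are pre-event, except the t = 0 dose
  # which is folded into the initial state
  administered <- vapply(tm, function(t)
    sum(sched$dose_umol * (sched$dose_times < t - 1e-9 |
                             sched$dose_times == 0)), 0)
  out <- vector("list", length(sp))
  ref <- max(administered, 1e-12)
  for (e in seq_along(sp)) {
    ie <- IDX_ENT(e)
    tot <- rowSums(sim$state[, ie + 1:9, drop = FALSE])
    if (e == 1L) {
      err <- abs(tot - administered) / ref
    } else {
      formed <- sim$state[, ie + 9L]
      present <- rowSums(sim$state[, ie + c(1:8), drop = FALSE])
      err <- abs(present - formed) / ref
    }
    out[[e]] <- tibble::tibble(species = sp[e], max_rel_error = max(err))
  }
  dplyr::bind_rows(out)
}

#' Bile acid mole balance audit
#'
#' Verifies d(total moles)/dt = synthesis - fecal loss - hydroxylation:
#' total bile acid moles at every time must equal the initial total plus
#' synthesized minus the cumulative sinks.
#'
#' @param sim a `dili_sim`.
#' @return maximum relative error over the run.
#' @export
ba_mole_balance <- function(sim) {
  syn <- sim$physiology$ba_synthesis * sim$physiology$toxic_pool_fraction
  tot <- rowSums(sim$state[, 1:25, drop = FALSE])
  expected <- tot[1] + syn * (sim$times - sim$times[1]) +
    (sim$state[1, IDX_FECAL] - sim$state[, IDX_FECAL]) +
    (sim$state[1, IDX_HYD] - sim$state[, IDX_HYD])
  max(abs(tot - expected) / max(tot))
}

#' Solve the drug-free periodic baseline
#'
#' Integrates the bile acid model without drug under the meal schedule
#' until a periodic steady state: the day-over-day change of every
#' compartment total must fall below `tol` (default 0.5%).
#'
#' @param physiology,transporters,tox,injury model configuration.
#' @param days integration horizon, days (>= 2).
#' @param init optional warm-start state vector.
#' @param tol day-over-day relative change tolerance.
#' @param must_converge error (with trajectory summary) on non-convergence.
#' @param engine `"C"` or `"R"`.
#' @return list: `state` (final state vector, a valid `init` for
#'   [simulate_dili()]), `converged`, `max_daily_change`, `sim`.
#' @export
solve_baseline <- function(physiology, transporters, tox, injury,
                           days = 30, init = NULL, tol = 0.005,
                           must_converge = TRUE, engine = "C") {
  stopifnot(days >= 2)
  sim <- simulate_dili(physiology, transporters, tox, injury,
                       days = days, init = init, engine = engine,
                       dt_out = 1)
  i_end <- length(sim$times)
  i_prev <- which.min(abs(sim$times - (sim$times[i_end] - 24)))
  comp_tot <- function(i)
    vapply(1:5, function(c) sum(sim$state[i, IDX_BA(1:5, c)]), 0)
  a <- comp_tot(i_prev); b <- comp_tot(i_end)
  scale <- max(sum(b), 1e-9)
  chg <- max(abs(b - a) / pmax(abs(a), 0.001 * scale))
  converged <- chg < tol
  if (!converged && must_converge)
    stop("baseline did not reach a periodic steady state (max daily ",
         "change ", signif(chg, 3), "); compartment totals: ",
         paste(signif(b, 4), collapse = ", "))
  state <- sim$state[i_end, ]
  list(state = state, converged = converged, max_daily_change = chg,
       sim = sim)
}
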