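#' Apparent transporter kinetics under reversible inhibition
#'
#' Competitive inhibition multiplies the apparent Michaelis constant by
#' `(1 + I/Ki)`; noncompetitive inhibition divides the maximal rate by the
#' same factor. Multiple inhibitors of one transporter multiply their
#' factors.
#'
#' @param vmax maximal transport rate, umol/h.
#' @param km Michaelis constant, uM.
#' @param inhibitor_conc inhibitor concentration(s), uM (one per spec).
#' @param specs a single [inhibition_spec()] or a list of them.
#' @return list with `vmax_app`, `km_app`.
#' @export
apply_inhibition <- function(vmax, km, inhibitor_conc, specs) {
  if (inherits(specs, "inhibition_spec")) specs <- list(specs)
  stopifnot(length(inhibitor_conc) == length(specs),
            all(inhibitor_conc >= 0))
  f_comp <- 1; f_noncomp <- 1
  for (i in seq_along(specs)) {
    fac <- 1 + inhibitor_conc[i] / specs[[i]]$ki
    if (specs[[i]]$mode == "competitive") f_comp <- f_comp * fac
    else f_noncomp <- f_noncomp * fac
  }
  list(vmax_app = vmax / f_noncomp, km_app = km * f_comp)
}

#' Delayed bile acid sensing
#'
#' Rate of change of the delayed intracellular bile acid concentration:
#' `tau * (conc - delayed)`. The delayed concentration relaxes toward the
#' instantaneous one with time constant `1/tau`.
#'
#' @param ba_liver_conc instantaneous liver intracellular concentration, uM.
#' @param ba_delayed delayed concentration, uM.
#' @param tau delay rate, 1/h (> 0).
#' @return d(delayed)/dt, uM/h.
#' @export
delay_update <- function(ba_liver_conc, ba_delayed, tau) {
  stopifnot(all(tau > 0))
  tau * (ba_liver_conc - ba_delayed)
}

#' ATP synthesis inhibition signal
#'
#' Hill-type signal per toxicity class,
#' `S_c = 1 / (1 + vmax_s * X^H / (km_s^H + X^H))` with X the class
#' delayed bile acid concentration; the combined signal is the product over
#' classes (independent-hit assumption). S = 1 with no bile acid burden and
#' tends to `1/(1 + vmax_s)` per class at saturating concentrations.
#'
#' @param ba_delayed numeric length-2 (CDCA-like, LCA-like class delayed
#'   concentrations, uM).
#' @param params a [tox_params()].
#' @return list with `S` (combined) and `per_class` (length 2).
#' @export
synthesis_signal <- function(ba_delayed, params) {
  stopifnot(length(ba_delayed) == 2, all(ba_delayed >= 0))
  x <- ba_delayed
  frac <- ifelse(x > 0,
                 x^params$hill / (params$km_s^params$hill + x^params$hill),
                 0)
  per_class <- 1 / (1 + params$vmax_s * frac)
  list(S = prod(per_class), per_class = per_class)
}

#' ATP turnover under synthesis inhibition
#'
#' `d(ATP)/dt = k_synth * S * etc_factor - k_usage * ATP / baseline_atp`
#' with `k_synth = k_usage = k_atp`, so the unperturbed steady state is
#' `baseline_atp` and a sustained signal S moves the steady state to
#' `S * etc_factor * baseline_atp`.
#'
#' @param atp current ATP, mM.
#' @param S synthesis inhibition signal in `(0, 1]`.
#' @param etc_factor electron-transport-chain capacity factor in `(0, 1]`.
#' @param params a [tox_params()].
#' @return d(ATP)/dt, mM/h.
#' @export
atp_dynamics <- function(atp, S, etc_factor, params) {
  stopifnot(atp >= 0, S > 0, S <= 1, etc_factor > 0, etc_factor <= 1)
  params$k_atp * S * etc_factor - params$k_atp * atp / params$baseline_atp
}

#' Electron transport chain inhibition factor
#'
#' Capacity factor on ATP synthesis from direct mitochondrial inhibitors:
#' the product of `1 / (1 + I/Ki_ETC)` over compounds, 1 when none are
#' present.
#'
#' @param inhibitor_liver_conc liver concentrations, uM.
#' @param ki_etc matching ETC inhibition constants, uM.
#' @return factor in `(0, 1]`.
#' @export
etc_inhibition_factor <- function(inhibitor_liver_conc, ki_etc) {
  stopifnot(length(inhibitor_liver_conc) == length(ki_etc),
            all(inhibitor_liver_conc >= 0), all(ki_etc > 0))
  if (!length(ki_etc)) return(1)
  prod(1 / (1 + inhibitor_liver_conc / ki_etc))
}

#' Hepatocyte loss and serum biomarker dynamics
#'
#' Necrosis hazard is zero above the ATP death threshold and rises as
#' `k_necrosis_max * ((thr - ATP)/thr)^necrosis_hill` below it. Serum ALT
#' fold is driven by `alt_content` times the necrosis rate and cleared
#' first order back to 1; bilirubin fold relaxes toward `1/viable_fraction`;
#' the viable fraction regrows logistically toward 1.
#'
#' @param atp mM.
#' @param viable_fraction in `(0, 1]`.
#' @param alt_fold,bili_fold current serum folds of baseline.
#' @param params an [injury_params()].
#' @return list of derivatives `d_viable`, `d_alt`, `d_bili` (per hour) and
#'   the instantaneous `hazard` (1/h).
#' @export
injury_dynamics <- function(atp, viable_fraction, alt_fold, bili_fold,
                            params) {
  thr <- params$atp_death_threshold
  deficit <- max(0, (thr - atp) / thr)
  hz <- params$k_necrosis_max * deficit^params$necrosis_hill
  d_v <- -hz * viable_fraction +
    params$k_regen * viable_fraction * (1 - viable_fraction)
  d_alt <- params$k_alt_clear * (1 - alt_fold) +
    params$alt_content * hz * viable_fraction
  v_eff <- max(viable_fraction, 0.05)
  d_bili <- params$k_bili_base_clear * (1 / v_eff - bili_fold)
  list(d_viable = d_v, d_alt = d_alt, d_bili = d_bili, hazard = hz)
}

#' Normalized liver function test elevation
#'
#' Composite statistic `max(alt_fold/5, bili_fold/3)` used to compare
#' simulated injury to clinical LFT elevations on a common scale.
#'
#' @param alt_fold serum ALT fold of baseline (>= 0).
#' @param bili_fold serum bilirubin fold of baseline (>= 0).
#' @return unitless, vectorized.
#' @export
normalized_lft <- function(alt_fold, bili_fold) {
  if (any(alt_fold < 0) || any(bili_fold < 0))
    stop("fold elevations must be non-negative")
  pmax(alt_fold / 5, bili_fold / 3)
}
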