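#' Measurement noise model
#'
#' @param kind `"proportional"` (CV of the signal), `"additive"` (constant
#'   SD) or `"combined"`.
#' @param cv coefficient of variation for the proportional part.
#' @param sd standard deviation for the additive part.
#' @param seed integer seed.
#' @return a `noise_model` list.
#' @export
noise_model <- function(kind = c("proportional", "additive", "combined"),
                        cv = 0.05, sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(cv >= 0, sd >= 0)
  structure(list(kind = kind, cv = cv, sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(x, noise) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(noise$seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    expr
  }
  withr_seed({
    out <- x
    if (noise$kind %in% c("proportional", "combined"))
      out <- out * (1 + noise$cv * rnorm(length(x)))
    if (noise$kind %in% c("additive", "combined"))
      out <- out + noise$sd * rnorm(length(x))
    pmax(out, 0)
  })
}

#' Generate noisy plasma concentration-time observations
#'
#' Simulates the PBPK model from known (true) parameters, samples it at the
#' requested times, and applies seeded measurement noise. Stands in for
#' digitized literature curves when testing parameter recovery.
#'
#' @param true_compound a [compound_model()] (ground truth).
#' @param regimen,physiology dosing and species context.
#' @param sample_times observation times, h.
#' @param noise a [noise_model()].
#' @param species_names which drug species to observe (default parent only).
#' @return tibble `time_h`, `species`, `compartment`, `conc_uM` with the
#'   truth attached as attributes `truth` (compound) and `clean` (noise-free
#'   values).
#' @export
gen_plasma_pk <- function(true_compound, regimen, physiology, sample_times,
                          noise = noise_model(),
                          species_names = true_compound$name) {
  curve <- simulate_pk(true_compound, regimen, physiology,
                       days = max(sample_times) / 24 + 1e-9)
  curve <- curve[curve$compartment == "plasma" &
                   curve$species %in% species_names, ]
  obs <- purrr::map_dfr(species_names, function(sp) {
    sub <- curve[curve$species == sp, ]
    tibble::tibble(time_h = sample_times, species = sp,
                   compartment = "plasma",
                   conc_uM = approx(sub$time_h, sub$conc_uM,
                                    xout = sample_times,
                                    ties = "ordered")$y)
  })
  clean <- obs$conc_uM
  obs$conc_uM <- apply_noise(clean, noise)
  attr(obs, "truth") <- true_compound
  attr(obs, "clean") <- clean
  obs
}

#' Generate in-vitro ATP time courses at fixed bile acid exposures
#'
#' Emulates the hepatocyte experiment used to parameterize the toxicity
#' model: cells are held at measured intracellular bile acid concentrations
#' and ATP (% of control) is recorded over time, with seeded noise.
#'
#' @param true_tox a [tox_params()] (ground truth).
#' @param ba_class `"CDCA-like"` or `"LCA-like"`.
#' @param exposure_levels intracellular concentrations, uM (>= 2 levels).
#' @param times sampling times, h.
#' @param noise a [noise_model()].
#' @return tibble `exposure_uM`, `time_h`, `atp_pct`, truth attached as
#'   attributes `truth` and `clean`.
#' @export
gen_invitro_atp <- function(true_tox, ba_class = "CDCA-like",
                            exposure_levels, times,
                            noise = noise_model()) {
  stopifnot(length(exposure_levels) >= 1)
  out <- simulate_invitro_atp(true_tox, ba_class, exposure_levels, times)
  clean <- out$atp_pct
  out$atp_pct <- apply_noise(clean, noise)
  attr(out, "truth") <- true_tox
  attr(out, "clean") <- clean
  out
}

#' Generate a synthetic vesicle inhibition plate
#'
#' Logistic inhibition of net transporter-mediated probe uptake plus an
#' AMP background, in duplicate, over a serial dilution. The default
#' dilution series is the packaged protocol's stock series; in-well
#' concentrations are 1% of nominal.
#'
#' @param true_ic50 in-well IC50, uM.
#' @param true_hill Hill slope.
#' @param max_inhibition maximal inhibition, % (bottom plateau =
#'   `(100 - max_inhibition)%` of control).
#' @param dilution_series nominal stock concentrations, uM, decreasing.
#' @param noise a [noise_model()] (applied per well).
#' @param top control (uninhibited) net signal.
#' @param background mean AMP background signal.
#' @param n_replicates wells per condition.
#' @return a [vesicle_plate()] with attribute `truth`.
#' @export
gen_vesicle_assay <- function(true_ic50, true_hill = 1,
                              max_inhibition = 100,
                              dilution_series = c(30000, 10000, 3160, 1000,
                                                  316, 100, 31.6, 10),
                              noise = noise_model(cv = 0.03),
                              top = 100, background = 20,
                              n_replicates = 2) {
  stopifnot(true_ic50 > 0, all(diff(dilution_series) < 0))
  conc_well <- dilution_series * 0.01
  bottom <- top * (1 - max_inhibition / 100)
  net <- bottom + (top - bottom) / (1 + (conc_well / true_ic50)^true_hill)
  n <- length(conc_well)
  atp_clean <- matrix(rep(net + background, n_replicates), ncol = n_replicates)
  amp_clean <- matrix(background, n, n_replicates)
  all_clean <- c(atp_clean, amp_clean)
  noisy <- apply_noise(all_clean, noise)
  plate <- vesicle_plate(dilution_series,
                         matrix(noisy[seq_len(n * n_replicates)], n),
                         matrix(noisy[-seq_len(n * n_replicates)], n))
  attr(plate, "truth") <- list(ic50 = true_ic50, hill = true_hill,
                               max_inhibition = max_inhibition, top = top,
                               background = background)
  plate
}
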