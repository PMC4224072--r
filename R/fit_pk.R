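# Parameter paths address numeric fields of a compound_model, e.g. "ka",
# "uptake_vmax", "metabolites.1.vmax_formation".
get_param <- function(compound, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "metabolites") {
    compound$metabolites[[as.integer(parts[2])]][[parts[3]]]
  } else compound[[parts[1]]]
}

set_param <- function(compound, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (parts[1] == "metabolites") {
    compound$metabolites[[as.integer(parts[2])]][[parts[3]]] <- value
  } else compound[[parts[1]]] <- value
  compound
}

#' Fit PBPK parameters to observed concentration-time data
#'
#' Weighted least-squares estimation (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) of selected compound parameters against observed
#' plasma (and optionally liver) concentrations. Deterministic given the
#' starting values in `free_params`.
#'
#' @param observed tibble with `time_h`, `species`, `compartment`,
#'   `conc_uM` (as written by [simulate_pk()] / [gen_plasma_pk()]).
#' @param compound_template a [compound_model()] providing fixed parameters
#'   and structure.
#' @param regimen,physiology dosing and species context of the data.
#' @param free_params named numeric vector of starting values; names are
#'   parameter paths (e.g. `c(ka = 0.5, renal_cl = 2)`).
#' @param lower,upper bounds, recycled to `length(free_params)`.
#' @param weighting `"proportional"` (residuals scaled by predicted
#'   concentration) or `"absolute"`.
#' @param dt_out simulation output resolution used for prediction, h.
#' @return a `pk_fit` object with elements `compound` (fitted),
#'   `estimates`, `convergence` (`"converged"`, `"boundary"` or
#'   `"non-convergence"`), `rss`, `info`, `message`.
#' @export
fit_pk <- function(observed, compound_template, regimen, physiology,
                   free_params, lower = 1e-8, upper = Inf,
                   weighting = c("proportional", "absolute"),
                   dt_out = 0.25) {
  weighting <- match.arg(weighting)
  paths <- names(free_params)
  stopifnot(length(paths) > 0, !is.null(paths))
  obs <- observed[observed$compartment == "plasma", ]
  if (nrow(obs) < 2 * length(free_params))
    stop("need at least 2x more observations than free parameters")
  lower <- rep_len(lower, length(free_params))
  upper <- rep_len(upper, length(free_params))
  days <- max(obs$time_h) / 24 + 1e-9

  predict_at <- function(theta) {
    cm <- compound_template
    for (i in seq_along(paths)) cm <- set_param(cm, paths[i], theta[i])
    curve <- simulate_pk(cm, regimen, physiology, days = days,
                         dt_out = dt_out)
    curve <- curve[curve$compartment == "plasma", ]
    vapply(seq_len(nrow(obs)), function(k) {
      sub <- curve[curve$species == obs$species[k], ]
      approx(sub$time_h, sub$conc_uM, xout = obs$time_h[k],
             ties = "ordered")$y
    }, 0)
  }
  resid_fun <- function(theta) {
    pred <- predict_at(theta)
    r <- obs$conc_uM - pred
    if (weighting == "proportional")
      r <- r / pmax(pred, 0.01 * max(obs$conc_uM, 1e-12))
    r
  }
  fit <- minpack.lm::nls.lm(par = unname(free_params), lower = lower,
                            upper = upper, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-10, ptol = 1e-10))
  est <- setNames(fit$par, paths)
  at_bound <- any(abs(fit$par - lower) < 1e-10 * pmax(1, abs(lower))) ||
    any(is.finite(upper) & abs(fit$par - upper) < 1e-10 * pmax(1, abs(upper)))
  convergence <- if (fit$info %in% 1:3 && !at_bound) "converged"
    else if (at_bound) "boundary" else "non-convergence"
  cm <- compound_template
  for (i in seq_along(paths)) cm <- set_param(cm, paths[i], est[i])
  structure(list(compound = cm, estimates = est, start = free_params,
                 convergence = convergence, rss = sum(fit$fvec^2),
                 info = fit$info, message = fit$message,
                 n_obs = nrow(obs)),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit>", x$convergence, "| rss", signif(x$rss, 4), "\n")
  print(signif(x$estimates, 5))
  invisible(x)
}

#' @export
tidy.pk_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 start = unname(x$start))
}

#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, convergence = x$convergence,
                 info = x$info, n_obs = x$n_obs,
                 n_par = length(x$estimates))
}
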