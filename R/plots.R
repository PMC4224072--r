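#' Plot drug concentration-time curves
#'
#' @param curve a `pk_curve` from [simulate_pk()].
#' @param log_y log-scale the concentration axis.
#' @return a ggplot.
#' @export
plot_pk <- function(curve, log_y = FALSE) {
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$time_h, y = .data$conc_uM,
                                    colour = .data$species,
                                    linetype = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (uM)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.pk_curve <- function(object, ...) plot_pk(object, ...)

#' Plot biomarker and ATP trajectories of a simulation
#'
#' @param sim a `dili_sim`.
#' @return a ggplot (facetted: hepatic ATP, viable fraction, ALT and
#'   bilirubin folds).
#' @export
plot_biomarkers <- function(sim) {
  df <- sim_tidy(sim, "biomarkers")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h / 24,
                                   y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dili_sim <- function(object, ...) plot_biomarkers(object)

#' Strip plot of per-individual minimum hepatic ATP in a population
#'
#' Reproduces the population-level view that separates toxic from non-toxic
#' transporter inhibitors: each point is one simulated individual's minimum
#' hepatic ATP over the scenario.
#'
#' @param results one or more [run_population()] tibbles; a named list
#'   facets by scenario.
#' @param baseline_atp reference line, mM.
#' @return a ggplot.
#' @export
plot_population_atp <- function(results, baseline_atp = NULL) {
  if (is.data.frame(results)) results <- list(scenario = results)
  df <- dplyr::bind_rows(results, .id = "scenario")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario,
                                        y = .data$min_atp_mM)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "minimum hepatic ATP (mM)") +
    ggplot2::theme_minimal()
  if (!is.null(baseline_atp))
    p <- p + ggplot2::geom_hline(yintercept = baseline_atp,
                                 linetype = "dashed")
  p
}

#' Plot a metabolite-clearance sweep
#'
#' @param sweep tibble from [metabolite_clearance_sweep()].
#' @return a ggplot.
#' @export
plot_clearance_sweep <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$metabolite_biliary_cl,
                               y = .data$peak_alt_fold)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "metabolite biliary clearance (mL/h/kg^0.75)",
                  y = "peak ALT fold of baseline") +
    ggplot2::theme_minimal()
}

#' Plot an IC50 fit over its data
#'
#' @param fit an `ic50_fit`.
#' @param net the `conc_uM`/`net_signal` data it was fitted to.
#' @return a ggplot.
#' @export
plot_ic50 <- function(fit, net) {
  grid <- tibble::tibble(conc_uM = exp(seq(log(min(net$conc_uM[net$conc_uM > 0])),
                                           log(max(net$conc_uM)),
                                           length.out = 100)))
  grid$net_signal <- fit$bottom + (fit$top - fit$bottom) /
    (1 + (grid$conc_uM / fit$ic50)^fit$hill)
  ggplot2::ggplot(net, ggplot2::aes(x = .data$conc_uM,
                                    y = .data$net_signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inhibitor (uM, in-well)",
                  y = "ATP-dependent uptake") +
    ggplot2::theme_minimal()
}
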