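#' Membrane vesicle inhibition plate
#'
#' Probe-substrate uptake signals measured at a serial dilution of the
#' inhibitor, in the presence of ATP (transport + passive) and with AMP
#' replacing ATP (passive background), in replicate.
#'
#' @param inhibitor_conc inhibitor concentrations, uM, strictly decreasing
#'   from stock.
#' @param uptake_atp,uptake_amp signal matrices or vectors
#'   (concentration x replicate); vectors are treated as one replicate.
#' @param dilution_factor factor from nominal (stock-well) to in-well
#'   concentration; the packaged assay protocol adds inhibitor as 1% of the
#'   incubation volume, i.e. 0.01.
#' @param in_well if `TRUE`, `inhibitor_conc` is already the in-well
#'   concentration and no dilution factor is applied.
#' @return a `vesicle_plate` list.
#' @export
vesicle_plate <- function(inhibitor_conc, uptake_atp, uptake_amp,
                          dilution_factor = 0.01, in_well = FALSE) {
  to_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1)
  uptake_atp <- to_mat(uptake_atp); uptake_amp <- to_mat(uptake_amp)
  stopifnot(all(diff(inhibitor_conc) < 0),
            nrow(uptake_atp) == length(inhibitor_conc),
            all(dim(uptake_atp) == dim(uptake_amp)),
            all(uptake_atp >= 0), all(uptake_amp >= 0))
  conc_well <- if (in_well) inhibitor_conc else
    inhibitor_conc * dilution_factor
  structure(list(inhibitor_conc = inhibitor_conc, conc_well = conc_well,
                 uptake_atp = uptake_atp, uptake_amp = uptake_amp),
            class = "vesicle_plate")
}

#' ATP-dependent (transporter-mediated) uptake
#'
#' Subtracts the AMP background (passive diffusion into the vesicles) from
#' the +ATP signal, floors at zero, and averages replicates.
#'
#' @param plate a [vesicle_plate()].
#' @return tibble `conc_uM` (in-well), `net_signal`.
#' @export
atp_dependent_uptake <- function(plate) {
  stopifnot(inherits(plate, "vesicle_plate"))
  net <- pmax(plate$uptake_atp - plate$uptake_amp, 0)
  tibble::tibble(conc_uM = plate$conc_well, net_signal = rowMeans(net))
}

#' Four-parameter logistic IC50 fit
#'
#' Fits `y = bottom + (top - bottom) / (1 + (x/ic50)^hill)` on log
#' concentration to net transporter-mediated uptake, with the bottom
#' bounded at >= 0. Flags a failure when the data show no transition in
#' the tested range.
#'
#' @param net tibble `conc_uM`, `net_signal` from [atp_dependent_uptake()],
#'   or a `vesicle_plate`.
#' @return an `ic50_fit`: `ic50` (uM, in-well scale), `hill`,
#'   `max_inhibition_pct`, `top`, `bottom`, `converged`, `flag`, `se_log_ic50`.
#' @export
fit_ic50 <- function(net) {
  if (inherits(net, "vesicle_plate")) net <- atp_dependent_uptake(net)
  x <- net$conc_uM; y <- net$net_signal
  stopifnot(length(x) >= 5)
  span <- diff(range(y))
  if (span < 0.1 * max(abs(y), 1e-12)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_,
                          max_inhibition_pct = NA_real_, top = max(y),
                          bottom = min(y), converged = FALSE,
                          flag = "no transition in tested range",
                          se_log_ic50 = NA_real_),
                     class = "ic50_fit"))
  }
  top0 <- max(y); bot0 <- max(min(y), 0)
  ic0 <- exp(mean(log(range(x[x > 0]))))
  resid_fun <- function(th) {
    top <- th[1]; bot <- th[2]; lic <- th[3]; hill <- th[4]
    y - (bot + (top - bot) / (1 + (x / exp(lic))^hill))
  }
  fit <- minpack.lm::nls.lm(
    par = c(top0, bot0, log(ic0), 1),
    lower = c(0, 0, log(min(x[x > 0]) / 100), 0.2),
    upper = c(Inf, Inf, log(max(x) * 100), 8),
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  th <- fit$par
  cov <- tryCatch(solve(fit$hessian) * 2 * fit$deviance /
                    max(length(x) - 4, 1),
                  error = function(e) NULL)
  se <- if (!is.null(cov)) sqrt(abs(cov[3, 3])) else NA_real_
  ic50 <- exp(th[3])
  in_range <- ic50 > min(x[x > 0]) / 10 && ic50 < max(x) * 10
  structure(list(ic50 = ic50, hill = th[4],
                 max_inhibition_pct = 100 * (th[1] - th[2]) / th[1],
                 top = th[1], bottom = th[2],
                 converged = fit$info %in% 1:3 && in_range,
                 flag = if (in_range) "ok" else "IC50 outside tested range",
                 se_log_ic50 = se),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("<ic50_fit> IC50", signif(x$ic50, 4), "uM | hill",
      signif(x$hill, 3), "| max inhibition",
      signif(x$max_inhibition_pct, 4), "% |", x$flag, "\n")
  invisible(x)
}

#' @export
tidy.ic50_fit <- function(x, ...) {
  tibble::tibble(term = c("ic50", "hill", "top", "bottom"),
                 estimate = c(x$ic50, x$hill, x$top, x$bottom))
}

#' @export
glance.ic50_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, hill = x$hill,
                 max_inhibition_pct = x$max_inhibition_pct,
                 converged = x$converged, flag = x$flag)
}

#' Approximate an inhibition constant from an IC50
#'
#' Returns the IC50 unchanged as the Ki estimate (the working convention
#' when the inhibition mode and probe occupancy are undetermined), with a
#' provenance note attached.
#'
#' @param ic50 uM (> 0).
#' @return Ki, uM, with attribute `provenance`.
#' @export
ki_from_ic50 <- function(ic50) {
  stopifnot(all(ic50 > 0))
  structure(ic50,
            provenance = "Ki approximated as IC50 (mode undetermined)")
}

#' Read / write a vesicle plate as long-format CSV
#'
#' Columns: `well`, `conc_uM` (nominal), `atp_flag` (1 = +ATP, 0 = AMP
#' background), `replicate`, `signal`.
#'
#' @param plate a [vesicle_plate()].
#' @param path CSV path.
#' @param ... passed to [vesicle_plate()] (e.g. `dilution_factor`).
#' @return `write_plate_csv`: the path, invisibly; `read_plate_csv`: a
#'   `vesicle_plate`.
#' @export
write_plate_csv <- function(plate, path) {
  n <- length(plate$inhibitor_conc); r <- ncol(plate$uptake_atp)
  df <- data.frame(
    well = rep(seq_len(n), times = 2 * r),
    conc_uM = rep(plate$inhibitor_conc, times = 2 * r),
    atp_flag = rep(c(1, 0), each = n * r),
    replicate = rep(rep(seq_len(r), each = n), times = 2),
    signal = c(as.vector(plate$uptake_atp), as.vector(plate$uptake_amp)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path, ...) {
  df <- read.csv(path)
  conc <- sort(unique(df$conc_uM), decreasing = TRUE)
  reps <- sort(unique(df$replicate))
  get <- function(flag) {
    m <- matrix(NA_real_, length(conc), length(reps))
    sub <- df[df$atp_flag == flag, ]
    m[cbind(match(sub$conc_uM, conc), match(sub$replicate, reps))] <-
      sub$signal
    if (anyNA(m)) stop("unmatched +ATP/background wells in plate file")
    m
  }
  vesicle_plate(conc, get(1), get(0), ...)
}
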