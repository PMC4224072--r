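#' Read and write concentration-time curves as tidy CSV
#'
#' Columns: `time_h`, `species`, `compartment`, `conc_uM`.
#'
#' @param curve a `pk_curve` tibble.
#' @param path CSV path.
#' @return `write_pk_csv`: the path invisibly; `read_pk_csv`: a `pk_curve`
#'   tibble.
#' @export
write_pk_csv <- function(curve, path) {
  write.csv(curve[, c("time_h", "species", "compartment", "conc_uM")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pk_csv
#' @export
read_pk_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("time_h", "species", "compartment", "conc_uM") %in%
                  names(df)))
  class(df) <- c("pk_curve", class(df))
  df
}

#' Write a bile acid state snapshot as tidy CSV
#'
#' Columns: `time_h`, `species`, `compartment`, `amount_umol`.
#'
#' @param sim a `dili_sim`.
#' @param path CSV path.
#' @param times subset of output times to keep (default all).
#' @return the path, invisibly.
#' @export
write_ba_csv <- function(sim, path, times = NULL) {
  df <- sim_tidy(sim, "bile_acids")
  if (!is.null(times)) df <- df[df$time_h %in% times, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
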