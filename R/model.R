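# Combined ODE model: state layout and parameter flattening shared by the
# R reference right-hand side and the compiled C right-hand side.
#
# State vector (length 64):
#   1..25   bile acid amounts, species-major: (s-1)*5 + compartment
#           (liver, gallbladder, gut_lumen, portal_blood, systemic_blood)
#   26..30  delayed liver bile acid concentrations (uM), per species
#   31      cumulative fecal bile acid loss (umol)
#   32      cumulative LCA hydroxylation loss (umol)
#   33      hepatic ATP (mM)
#   34      viable hepatocyte fraction
#   35      serum ALT fold of baseline
#   36      serum bilirubin fold of baseline
#   37      autoinduction multiplier
#   38..64  drug entities (3 slots x 9): gut, portal, systemic blood,
#           liver, peripheral, fecal sink, renal sink, biliary sink,
#           converted (parent: cumulative metabolized; metabolite:
#           cumulative formed), all umol

N_STATE <- 64L
IDX_BA <- function(s, c) (s - 1L) * 5L + c
IDX_DELAY <- 26:30
IDX_FECAL <- 31L; IDX_HYD <- 32L
IDX_ATP <- 33L; IDX_VIABLE <- 34L; IDX_ALT <- 35L; IDX_BILI <- 36L
IDX_IND <- 37L
IDX_ENT <- function(e) 37L + (e - 1L) * 9L   # base; fields +1..+9
N_PARMS <- 135L

#' Flatten a model configuration to the numeric parameter vector used by
#' the ODE right-hand sides
#' @keywords internal
flatten_model <- function(physiology, transporters, tox, injury,
                          compound = NULL) {
  p <- numeric(N_PARMS)
  ph <- physiology
  p[1] <- ph$liver_volume
  p[2] <- ph$portal_volume
  p[3] <- ph$blood_volume - ph$portal_volume
  p[4] <- ph$hepatic_blood_flow
  p[5] <- ph$ba_synthesis * ph$toxic_pool_fraction
  p[6] <- ph$gut_transit_k
  p[7] <- ph$fecal_loss_fraction
  p[8] <- ph$gut_conversion_k
  p[9] <- ph$conjugation_k
  p[10] <- ph$sulfation_k
  p[11] <- ph$lca_hydroxylation_cl
  p[12] <- ph$baseline_atp
  for (T in 1:3) {
    tr <- c("NTCP", "BSEP", "BASOLATERAL")[T]
    for (s in 1:5) {
      base <- 13L + ((T - 1L) * 5L + (s - 1L)) * 2L
      p[base] <- transporters$vmax[[tr]][s]
      p[base + 1L] <- transporters$km[[tr]][s]
    }
  }
  p[43:50] <- c(tox$vmax_s[1], tox$km_s[1], tox$hill[1], tox$tau[1],
                tox$vmax_s[2], tox$km_s[2], tox$hill[2], tox$tau[2])
  p[51] <- tox$k_atp
  p[52:58] <- c(injury$atp_death_threshold, injury$k_necrosis_max,
                injury$necrosis_hill, injury$alt_content,
                injury$k_alt_clear, injury$k_bili_base_clear,
                injury$k_regen)
  p[59] <- 1; p[60] <- 0; p[61] <- 0; p[62] <- 0
  p[63] <- 0
  if (!is.null(compound)) {
    bw75 <- ph$bodyweight^0.75
    if (!is.null(compound$induction)) {
      p[59] <- compound$induction$fold_max
      p[60] <- compound$induction$k_ind
      p[61] <- as.numeric("uptake_vmax" %in% compound$induction$targets)
      p[62] <- as.numeric("metabolism_vmax" %in% compound$induction$targets)
    }
    nmet <- length(compound$metabolites)
    p[63] <- 1 + nmet
    fill_inh <- function(base, specs) {
      # +15 ki_N, +16 mode_N, +17 ki_B, +18 mode_B, +19 ki_Bl, +20 mode_Bl,
      # +21 ki_ETC, +22 etc_flag ; mode: 0 none, 1 competitive, 2 noncomp
      for (s in specs) {
        off <- switch(s$transporter, NTCP = 15L, BSEP = 17L,
                      BASOLATERAL = 19L, ETC = 21L)
        p[base + off] <<- s$ki
        if (s$transporter == "ETC") p[base + 22L] <<- 1
        else p[base + off + 1L] <<-
            if (s$mode == "competitive") 1 else 2
      }
    }
    base1 <- 64L
    p[base1] <- 1                         # present
    p[base1 + 1L] <- compound$ka
    p[base1 + 2L] <- compound$f_abs
    p[base1 + 3L] <- compound$v_central * ph$bodyweight
    p[base1 + 4L] <- compound$v_peripheral * ph$bodyweight
    p[base1 + 5L] <- if (compound$v_peripheral > 0) compound$q_peripheral else 0
    p[base1 + 6L] <- compound$passive_cl
    p[base1 + 7L] <- compound$renal_cl
    p[base1 + 8L] <- compound$biliary_cl * bw75 / 1000
    p[base1 + 9L] <- compound$uptake_vmax * bw75
    p[base1 + 10L] <- compound$uptake_km
    for (j in seq_len(nmet)) {
      m <- compound$metabolites[[j]]
      p[base1 + 11L + (j - 1L) * 2L] <- m$vmax_formation
      p[base1 + 12L + (j - 1L) * 2L] <- m$km_formation
      baseM <- 64L + j * 24L
      p[baseM] <- 1
      p[baseM + 3L] <- compound$v_central * ph$bodyweight
      p[baseM + 6L] <- m$product_passive_cl
      p[baseM + 7L] <- m$product_renal_cl
      p[baseM + 8L] <- m$product_biliary_cl * bw75 / 1000
      p[baseM + 10L] <- 1
      p[baseM + 23L] <- 1                 # is metabolite
      fill_inh(baseM, m$product_inhibitions)
    }
    fill_inh(base1, compound$inhibitions)
  }
  p
}

#' Default (pre-dose, pre-baseline-solve) state vector
#' @keywords internal
init_state <- function(physiology) {
  y <- numeric(N_STATE)
  y[IDX_ATP] <- physiology$baseline_atp
  y[IDX_VIABLE] <- 1
  y[IDX_ALT] <- 1
  y[IDX_BILI] <- 1
  y[IDX_IND] <- 1
  names(y) <- state_names()
  y
}

state_names <- function() {
  ba <- as.vector(t(outer(BA_SPECIES, BA_COMPARTMENTS, paste, sep = ".")))
  ent <- as.vector(t(outer(paste0("ent", 1:3),
                           c("gut", "portal", "blood", "liver", "periph",
                             "fecal", "renal", "biliary", "conv"),
                           paste, sep = ".")))
  c(ba, paste0("delay.", BA_SPECIES), "fecal_ba", "hyd_sink",
    "atp", "viable", "alt_fold", "bili_fold", "induction", ent)
}

# Reference right-hand side, composed from the module-level functions.
# Used for small runs and as the oracle for the compiled C version.
make_rhs_r <- function(physiology, transporters, tox, injury,
                       compound = NULL) {
  ph <- physiology
  pflat <- flatten_model(physiology, transporters, tox, injury, compound)
  n_ent <- as.integer(pflat[63])
  inh_specs <- list()
  if (!is.null(compound)) {
    inh_specs[[1]] <- compound$inhibitions
    for (j in seq_along(compound$metabolites))
      inh_specs[[j + 1]] <- compound$metabolites[[j]]$product_inhibitions
  }
  tau_sp <- tox$tau[BA_CLASS]

  function(t, y, parms) {
    dy <- numeric(N_STATE)
    A <- matrix(y[1:25], nrow = 5, byrow = TRUE,
                dimnames = list(BA_SPECIES, BA_COMPARTMENTS))
    # drug entities
    ind <- y[IDX_IND]
    inhibitors <- list()
    ent_liver_conc <- numeric(n_ent)
    if (n_ent > 0) {
      for (e in seq_len(n_ent)) {
        ent_liver_conc[e] <- y[IDX_ENT(e) + 4L] / ph$liver_volume
        inhibitors[[e]] <- list(conc = ent_liver_conc[e],
                                inhibitions = inh_specs[[e]])
      }
      base1 <- 64L
      ka <- pflat[base1 + 1L]; fab <- pflat[base1 + 2L]
      VC <- pflat[base1 + 3L]; VT <- pflat[base1 + 4L]
      qp <- pflat[base1 + 5L]; CLp <- pflat[base1 + 6L]
      ren <- pflat[base1 + 7L]; bil <- pflat[base1 + 8L]
      vmu <- pflat[base1 + 9L]; kmu <- pflat[base1 + 10L]
      ind_u <- if (pflat[61] > 0) ind else 1
      ind_m <- if (pflat[62] > 0) ind else 1
      i1 <- IDX_ENT(1L)
      Gd <- y[i1 + 1L]; Pd <- y[i1 + 2L]; Bd <- y[i1 + 3L]
      Ld <- y[i1 + 4L]; Td <- y[i1 + 5L]
      C_Pd <- Pd / ph$portal_volume; C_Bd <- Bd / VC
      C_Ld <- Ld / ph$liver_volume
      C_Td <- if (VT > 0) Td / VT else 0
      upt <- ind_u * vmu * C_Pd / (kmu + C_Pd) + CLp * C_Pd
      met <- numeric(2)
      for (j in seq_len(n_ent - 1L)) {
        vmf <- ind_m * pflat[base1 + 11L + (j - 1L) * 2L]
        kmf <- pflat[base1 + 12L + (j - 1L) * 2L]
        met[j] <- vmf * C_Ld / (kmf + C_Ld)
      }
      Q <- ph$hepatic_blood_flow
      dy[i1 + 1L] <- -ka * Gd
      dy[i1 + 2L] <- ka * fab * Gd + Q * (C_Bd - C_Pd) - upt
      dy[i1 + 3L] <- Q * (C_Pd - C_Bd) + CLp * C_Ld - ren * C_Bd -
        qp * (C_Bd - C_Td)
      dy[i1 + 4L] <- upt - CLp * C_Ld - bil * C_Ld - sum(met)
      dy[i1 + 5L] <- qp * (C_Bd - C_Td)
      dy[i1 + 6L] <- ka * (1 - fab) * Gd
      dy[i1 + 7L] <- ren * C_Bd
      dy[i1 + 8L] <- bil * C_Ld
      dy[i1 + 9L] <- sum(met)
      for (j in seq_len(n_ent - 1L)) {
        e <- j + 1L; ie <- IDX_ENT(e); baseM <- 64L + j * 24L
        CLpM <- pflat[baseM + 6L]; renM <- pflat[baseM + 7L]
        bilM <- pflat[baseM + 8L]; VCM <- pflat[baseM + 3L]
        LdM <- y[ie + 4L]; BdM <- y[ie + 3L]
        C_LM <- LdM / ph$liver_volume; C_BM <- BdM / VCM
        exch <- CLpM * (C_LM - C_BM)
        dy[ie + 4L] <- met[j] - bilM * C_LM - exch
        dy[ie + 3L] <- exch - renM * C_BM
        dy[ie + 7L] <- renM * C_BM
        dy[ie + 8L] <- bilM * C_LM
        dy[ie + 9L] <- met[j]
      }
      dy[IDX_IND] <- pflat[60] * (pflat[59] - ind)
    }
    # bile acids
    st <- list(amount = A)
    fl <- ba_fluxes(st, transporters, ph, inhibitors)
    dy[1:25] <- as.vector(t(fl$d_amount))
    dy[IDX_FECAL] <- fl$d_fecal
    dy[IDX_HYD] <- fl$d_hydroxylation
    # delayed concentrations and toxicity
    C_L <- A[, 1] / ph$liver_volume
    D <- y[IDX_DELAY]
    dy[IDX_DELAY] <- delay_update(C_L, D, tau_sp)
    X <- c(sum(D[BA_CLASS == 1L]), sum(D[BA_CLASS == 2L]))
    S <- synthesis_signal(pmax(X, 0), tox)$S
    etc <- inhibition_factors(inhibitors)$etc
    atp <- max(y[IDX_ATP], 0)
    dy[IDX_ATP] <- atp_dynamics(atp, S, etc, tox)
    inj <- injury_dynamics(atp, y[IDX_VIABLE], y[IDX_ALT], y[IDX_BILI],
                           injury)
    dy[IDX_VIABLE] <- inj$d_viable
    dy[IDX_ALT] <- inj$d_alt
    dy[IDX_BILI] <- inj$d_bili
    list(dy)
  }
}

# Event schedule: meals (gallbladder emptying) and doses.
build_events <- function(physiology, regimen = NULL, days,
                         dose_umol = 0, meals = TRUE) {
  meal_t <- numeric(0)
  if (meals && length(physiology$meal_times))
    meal_t <- as.vector(outer(physiology$meal_times, 24 * (seq_len(ceiling(days)) - 1), "+"))
  meal_t <- meal_t[meal_t < days * 24]
  dose_t <- if (!is.null(regimen)) dose_times(regimen) else numeric(0)
  dose_t <- dose_t[dose_t < days * 24]
  list(meal_times = sort(meal_t), dose_times = sort(dose_t),
       dose_umol = dose_umol,
       route = if (!is.null(regimen)) regimen$route else "oral",
       gb_fraction = physiology$gallbladder_empty_fraction)
}

make_event_fun <- function(ev) {
  tol <- 1e-9
  function(t, y, parms) {
    if (any(abs(ev$meal_times - t) < tol)) {
      gb <- IDX_BA(1:5, 2L); gut <- IDX_BA(1:5, 3L)
      moved <- ev$gb_fraction * y[gb]
      y[gb] <- y[gb] - moved
      y[gut] <- y[gut] + moved
    }
    if (length(ev$dose_times) && any(abs(ev$dose_times - t) < tol)) {
      tgt <- if (ev$route == "oral") IDX_ENT(1L) + 1L else IDX_ENT(1L) + 3L
      y[tgt] <- y[tgt] + ev$dose_umol
    }
    y
  }
}

apply_events_at0 <- function(y, ev) {
  tol <- 1e-9
  f0 <- make_event_fun(ev)
  if (any(abs(ev$meal_times - 0) < tol) ||
      (length(ev$dose_times) && any(abs(ev$dose_times - 0) < tol)))
    y <- f0(0, y, NULL)
  y
}

#' Simulate the coupled drug / bile acid / hepatotoxicity model
#'
#' Integrates the full system (drug disposition, bile acid enterohepatic
#' recirculation under transporter inhibition, delayed bile-acid-driven ATP
#' decline, hepatocyte loss and serum biomarkers) with meal-triggered
#' gallbladder emptying and dosing implemented as state increments.
#'
#' @param physiology a [species_physiology()].
#' @param transporters a [transporter_params()].
#' @param tox a [tox_params()].
#' @param injury an [injury_params()].
#' @param compound a [compound_model()] or `NULL` for drug-free runs.
#' @param regimen a [dose_regimen()] or `NULL`.
#' @param days simulated duration, days.
#' @param init initial state vector (from [solve_baseline()]) or `NULL`
#'   for the naive empty state.
#' @param engine `"C"` (compiled, default) or `"R"` (reference).
#' @param dt_out output resolution, h.
#' @param meals include meal-triggered gallbladder emptying.
#' @param rtol,atol solver tolerances.
#' @return a `dili_sim` object: list with `times` (h), `state` (matrix,
#'   one row per output time), `schedule`, and the model configuration.
#' @export
simulate_dili <- function(physiology, transporters, tox, injury,
                          compound = NULL, regimen = NULL, days = 30,
                          init = NULL, engine = c("C", "R"), dt_out = 1,
                          meals = TRUE, rtol = 1e-8, atol = 1e-10) {
  engine <- match.arg(engine)
  stopifnot(days > 0)
  dose_umol <- 0
  if (!is.null(compound) && !is.null(regimen)) {
    amt_mg <- regimen$amount * if (regimen$per_kg) physiology$bodyweight else 1
    dose_umol <- amt_mg / compound$molecular_weight * 1000
  }
  ev <- build_events(physiology, regimen, days, dose_umol, meals)
  y0 <- if (is.null(init)) init_state(physiology) else init
  names(y0) <- state_names()
  y0 <- apply_events_at0(y0, ev)
  times <- seq(0, days * 24, by = dt_out)
  evt <- sort(unique(c(ev$meal_times, ev$dose_times)))
  evt <- evt[evt > 0]
  times <- sort(unique(c(times, evt)))
  pflat <- flatten_model(physiology, transporters, tox, injury, compound)
  events <- if (length(evt))
    list(func = make_event_fun(ev), time = evt) else NULL
  if (engine == "C") {
    out <- deSolve::lsoda(y0, times, func = "dili_derivs",
                          parms = pflat, dllname = "biletox",
                          initfunc = "dili_init", nout = 0,
                          events = events, rtol = rtol, atol = atol,
                          maxsteps = 50000)
  } else {
    rhs <- make_rhs_r(physiology, transporters, tox, injury, compound)
    out <- deSolve::lsoda(y0, times, func = function(t, y, p) rhs(t, y, p),
                          parms = NULL, events = events,
                          rtol = rtol, atol = atol, maxsteps = 50000)
  }
  di <- attr(out, "istate")
  if (!is.null(di) && di[1] < 0)
    stop("ODE integration failed (istate = ", di[1], ")")
  state <- out[, -1, drop = FALSE]
  colnames(state) <- state_names()
  neg <- min(state)
  if (neg < -1e-6 * max(abs(state)))
    stop("negative state beyond tolerance in ",
         colnames(state)[which(state == neg, arr.ind = TRUE)[1, 2]])
  n_clip <- sum(state < 0)
  state[state < 0] <- 0
  structure(list(times = out[, 1], state = state, schedule = ev,
                 physiology = physiology, compound = compound,
                 regimen = regimen, n_clipped = n_clip),
            class = "dili_sim")
}

#' @export
print.dili_sim <- function(x, ...) {
  cat("<dili_sim>", length(x$times), "time points,",
      if (is.null(x$compound)) "drug-free" else x$compound$name,
      "| min ATP", signif(min(x$state[, IDX_ATP]), 3), "mM",
      "| peak ALT fold", signif(max(x$state[, IDX_ALT]), 3), "\n")
  invisible(x)
}

#' Tidy time series of a simulation
#'
#' @param sim a `dili_sim`.
#' @param what `"biomarkers"` (ATP, viable fraction, ALT/bilirubin folds),
#'   `"bile_acids"` (amounts per species/compartment) or `"drug"`
#'   (plasma/liver concentrations per drug species).
#' @return a tibble in long format.
#' @export
sim_tidy <- function(sim, what = c("biomarkers", "bile_acids", "drug")) {
  what <- match.arg(what)
  tm <- sim$times
  if (what == "biomarkers") {
    tibble::tibble(
      time_h = rep(tm, 4),
      variable = rep(c("hepatic_atp_mM", "viable_fraction",
                       "alt_fold", "bili_fold"), each = length(tm)),
      value = c(sim$state[, IDX_ATP], sim$state[, IDX_VIABLE],
                sim$state[, IDX_ALT], sim$state[, IDX_BILI]))
  } else if (what == "bile_acids") {
    grid <- expand.grid(compartment = BA_COMPARTMENTS,
                        species = BA_SPECIES, stringsAsFactors = FALSE)
    purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      s <- match(grid$species[i], BA_SPECIES)
      c <- match(grid$compartment[i], BA_COMPARTMENTS)
      tibble::tibble(time_h = tm, species = grid$species[i],
                     compartment = grid$compartment[i],
                     amount_umol = sim$state[, IDX_BA(s, c)])
    })
  } else {
    if (is.null(sim$compound)) stop("drug-free simulation has no drug series")
    sp <- compound_species(sim$compound)
    VC <- sim$compound$v_central * sim$physiology$bodyweight
    purrr::map_dfr(seq_along(sp), function(e) {
      ie <- IDX_ENT(e)
      tibble::tibble(
        time_h = rep(tm, 2), species = sp[e],
        compartment = rep(c("plasma", "liver"), each = length(tm)),
        conc_uM = c(sim$state[, ie + 3L] / VC,
                    sim$state[, ie + 4L] / sim$physiology$liver_volume))
    })
  }
}

#' Extract the bile acid state at a simulation time
#' @param sim a `dili_sim`.
#' @param t time, h (defaults to the final time).
#' @return a [ba_state()].
#' @export
sim_ba_state <- function(sim, t = max(sim$times)) {
  i <- which.min(abs(sim$times - t))
  ba_state(amount = matrix(sim$state[i, 1:25], nrow = 5, byrow = TRUE),
           delayed = sim$state[i, IDX_DELAY])
}

#' Liver intracellular toxic bile acid concentration over time
#' @param sim a `dili_sim`.
#' @param by_class split into CDCA-like / LCA-like classes.
#' @return tibble `time_h`, (`toxicity_class`,) `conc_uM`.
#' @export
liver_ba_conc <- function(sim, by_class = FALSE) {
  liv <- sim$state[, IDX_BA(1:5, 1L), drop = FALSE] /
    sim$physiology$liver_volume
  if (by_class) {
    tibble::tibble(
      time_h = rep(sim$times, 2),
      toxicity_class = rep(c("CDCA-like", "LCA-like"),
                           each = length(sim$times)),
      conc_uM = c(rowSums(liv[, BA_CLASS == 1L, drop = FALSE]),
                  rowSums(liv[, BA_CLASS == 2L, drop = FALSE])))
  } else {
    tibble::tibble(time_h = sim$times, conc_uM = rowSums(liv))
  }
}
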