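#' Bile acid state container
#'
#' Molar amounts of each tracked bile acid species in each anatomical
#' compartment, plus the delayed liver intracellular concentration used by
#' the toxicity signal.
#'
#' @param amount 5 x 5 numeric matrix (species x compartments, in the order
#'   of [ba_species_table()] and `liver_intracellular`, `gallbladder`,
#'   `gut_lumen`, `portal_blood`, `systemic_blood`), umol. Scalars recycle.
#' @param delayed length-5 numeric, delayed liver concentrations, uM.
#' @return a `ba_state` list.
#' @export
ba_state <- function(amount = 0, delayed = 0) {
  m <- matrix(amount, nrow = 5, ncol = 5,
              dimnames = list(BA_SPECIES, BA_COMPARTMENTS))
  stopifnot(all(m >= 0))
  d <- rep_len(delayed, 5); names(d) <- BA_SPECIES
  structure(list(amount = m, delayed = d), class = "ba_state")
}

#' Combined inhibition factors over all circulating drug species
#'
#' @param inhibitors list of `list(conc = uM, inhibitions = list of
#'   inhibition_spec)`, one element per drug species present.
#' @return list per transporter (`NTCP`, `BSEP`, `BASOLATERAL`) of
#'   `f_comp`/`f_noncomp` multipliers, plus `etc` (ATP-synthesis capacity
#'   factor in (0,1]).
#' @keywords internal
inhibition_factors <- function(inhibitors) {
  out <- list(NTCP = c(1, 1), BSEP = c(1, 1), BASOLATERAL = c(1, 1))
  etc <- 1
  for (inh in inhibitors) {
    for (spec in inh$inhibitions) {
      fac <- 1 + inh$conc / spec$ki
      if (spec$transporter == "ETC") {
        etc <- etc / fac
      } else if (spec$mode == "competitive") {
        out[[spec$transporter]][1] <- out[[spec$transporter]][1] * fac
      } else {
        out[[spec$transporter]][2] <- out[[spec$transporter]][2] * fac
      }
    }
  }
  list(factors = out, etc = etc)
}

#' Bile acid compartment fluxes
#'
#' Net rate of change of every bile acid species in every compartment:
#' Michaelis-Menten NTCP uptake (portal blood -> liver), BSEP export
#' (liver -> gallbladder), basolateral efflux (liver -> systemic blood);
#' first-order hepatic conjugation/sulfation, gut-flora CDCA -> LCA
#' conversion, gut outflow with fractional fecal loss and reabsorption to
#' portal blood, portal-systemic blood exchange at hepatic blood flow,
#' constant CDCA synthesis into the liver, and (rodent) hepatic LCA
#' hydroxylation. Drug inhibition modulates the three transporters via
#' [apply_inhibition()] kinetics.
#'
#' @param state a [ba_state()].
#' @param transporters a [transporter_params()].
#' @param physiology a [species_physiology()].
#' @param inhibitors list of `list(conc, inhibitions)` per drug species
#'   (liver concentrations, uM); empty for drug-free dynamics.
#' @return list: `d_amount` (5 x 5 matrix, umol/h), `d_fecal`,
#'   `d_hydroxylation` (sink rates, umol/h), `synthesis` (umol/h).
#' @export
ba_fluxes <- function(state, transporters, physiology, inhibitors = list()) {
  p <- physiology
  A <- state$amount
  C_L <- A[, 1] / p$liver_volume
  C_P <- A[, 4] / p$portal_volume
  C_B <- A[, 5] / (p$blood_volume - p$portal_volume)

  f <- inhibition_factors(inhibitors)$factors
  mm <- function(tr, conc) {
    vmax <- transporters$vmax[[tr]] / f[[tr]][2]
    km <- transporters$km[[tr]] * f[[tr]][1]
    vmax * conc / (km + conc)
  }
  J_ntcp <- mm("NTCP", C_P)
  J_bsep <- mm("BSEP", C_L)
  J_baso <- mm("BASOLATERAL", C_L)

  syn <- p$ba_synthesis * p$toxic_pool_fraction
  k_conj <- p$conjugation_k; k_sulf <- p$sulfation_k
  J_hyd <- p$lca_hydroxylation_cl * C_L[3]       # unconjugated LCA only
  gut_out <- p$gut_transit_k * A[, 3]
  J_conv <- p$gut_conversion_k * A[1, 3]         # CDCA -> LCA in gut lumen
  Q <- p$hepatic_blood_flow

  dA <- matrix(0, 5, 5, dimnames = dimnames(A))
  # liver
  dA[, 1] <- J_ntcp - J_bsep - J_baso
  dA[1, 1] <- dA[1, 1] + syn - k_conj * A[1, 1]
  dA[2, 1] <- dA[2, 1] + k_conj * A[1, 1]
  dA[3, 1] <- dA[3, 1] - (k_conj + k_sulf) * A[3, 1] - J_hyd
  dA[4, 1] <- dA[4, 1] + k_conj * A[3, 1]
  dA[5, 1] <- dA[5, 1] + k_sulf * A[3, 1]
  # gallbladder (meal emptying is an event, not a flux)
  dA[, 2] <- J_bsep
  # gut lumen
  dA[, 3] <- -gut_out
  dA[1, 3] <- dA[1, 3] - J_conv
  dA[3, 3] <- dA[3, 3] + J_conv
  # portal blood
  dA[, 4] <- (1 - p$fecal_loss_fraction) * gut_out - J_ntcp +
    Q * (C_B - C_P)
  # systemic blood
  dA[, 5] <- J_baso - Q * (C_B - C_P)

  list(d_amount = dA,
       d_fecal = sum(p$fecal_loss_fraction * gut_out),
       d_hydroxylation = unname(J_hyd),
       synthesis = syn)
}

#' Gallbladder emptying at a meal
#'
#' Transfers `gallbladder_empty_fraction` of each species' gallbladder
#' content to the gut lumen; total moles are conserved exactly.
#'
#' @param state a [ba_state()].
#' @param physiology a [species_physiology()].
#' @return the updated `ba_state`.
#' @export
gallbladder_empty <- function(state, physiology) {
  f <- physiology$gallbladder_empty_fraction
  moved <- f * state$amount[, 2]
  state$amount[, 2] <- state$amount[, 2] - moved
  state$amount[, 3] <- state$amount[, 3] + moved
  state
}
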