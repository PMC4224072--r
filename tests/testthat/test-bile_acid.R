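test_that("competitive and noncompetitive inhibition follow their definitions", {
  comp <- inhibition_spec("BSEP", ki = 2, mode = "competitive")
  out <- apply_inhibition(100, 5, inhibitor_conc = 2, comp)
  expect_equal(out$km_app, 10)
  expect_equal(out$vmax_app, 100)

  noncomp <- inhibition_spec("BSEP", ki = 2, mode = "noncompetitive")
  out <- apply_inhibition(100, 5, inhibitor_conc = 2, noncomp)
  expect_equal(out$vmax_app, 50)
  expect_equal(out$km_app, 5)

  # an astronomically large Ki leaves kinetics untouched to machine precision
  off <- inhibition_spec("NTCP", ki = 1e10, mode = "noncompetitive")
  out <- apply_inhibition(100, 5, inhibitor_conc = 50, off)
  expect_equal(out$vmax_app, 100, tolerance = 1e-8)

  # multiple inhibitors multiply their factors
  both <- list(noncomp, noncomp)
  out <- apply_inhibition(100, 5, c(2, 2), both)
  expect_equal(out$vmax_app, 25)
})

test_that("ba_fluxes from an empty state is pure synthesis", {
  cfg <- human_cfg()
  fl <- ba_fluxes(ba_state(0), cfg$transporters, cfg$physiology)
  syn <- cfg$physiology$ba_synthesis * cfg$physiology$toxic_pool_fraction
  expect_equal(fl$d_amount["CDCA", "liver_intracellular"], syn)
  expect_equal(sum(abs(fl$d_amount)), syn)
  expect_equal(fl$d_fecal, 0)
  expect_equal(fl$d_hydroxylation, 0)
})

test_that("flux balance: total change equals synthesis minus sinks", {
  cfg <- human_cfg()
  st <- ba_state(matrix(runif(25, 0, 50), 5, 5))
  fl <- ba_fluxes(st, cfg$transporters, cfg$physiology)
  expect_equal(sum(fl$d_amount),
               fl$synthesis - fl$d_fecal - fl$d_hydroxylation,
               tolerance = 1e-10)
})

test_that("losing BSEP capacity raises the liver derivative", {
  cfg <- human_cfg()
  st <- sim_ba_state(human_baseline()$sim)
  base <- ba_fluxes(st, cfg$transporters, cfg$physiology)
  tr0 <- cfg$transporters
  tr0$vmax$BSEP <- rep(0, 5)
  nob <- ba_fluxes(st, tr0, cfg$physiology)
  expect_gt(sum(nob$d_amount[, "liver_intracellular"]),
            sum(base$d_amount[, "liver_intracellular"]))
})

test_that("gallbladder emptying conserves moles exactly", {
  cfg <- human_cfg()
  st <- ba_state(100)
  out <- gallbladder_empty(st, cfg$physiology)
  f <- cfg$physiology$gallbladder_empty_fraction
  expect_equal(unname(out$amount[, "gallbladder"]), rep(100 * (1 - f), 5))
  expect_equal(unname(out$amount[, "gut_lumen"]), rep(100 * (1 + f), 5))
  expect_equal(sum(out$amount), sum(st$amount))

  p0 <- cfg$physiology; p0$gallbladder_empty_fraction <- 0
  expect_equal(gallbladder_empty(st, p0)$amount, st$amount)
  empty <- ba_state(0)
  expect_equal(gallbladder_empty(empty, cfg$physiology)$amount,
               empty$amount)
})

test_that("drug-free baselines converge to a periodic steady state", {
  bl <- human_baseline()
  expect_true(bl$converged)
  expect_lt(bl$max_daily_change, 0.005)
  st <- sim_ba_state(bl$sim)
  expect_true(all(rowSums(st$amount) > 0))
  expect_lt(ba_mole_balance(bl$sim), 1e-6)

  # washout: without synthesis everything decays toward zero
  cfg <- human_cfg()
  p0 <- cfg$physiology; p0$ba_synthesis <- 0
  sim <- simulate_dili(p0, cfg$transporters, cfg$tox, cfg$injury,
                       days = 60, init = bl$state)
  expect_lt(sum(sim$state[nrow(sim$state), 1:25]),
            0.02 * sum(sim$state[1, 1:25]))
})

test_that("rat baseline carries less liver toxic bile acid than human", {
  h <- sim_ba_state(human_baseline()$sim)
  r <- sim_ba_state(rat_baseline()$sim)
  h_conc <- sum(h$amount[, "liver_intracellular"]) /
    human_cfg()$physiology$liver_volume
  r_conc <- sum(r$amount[, "liver_intracellular"]) /
    rat_cfg()$physiology$liver_volume
  expect_lt(r_conc, h_conc)
})

test_that("noncompetitive BSEP inhibition accumulates at least as much liver bile acid as competitive", {
  cfg <- human_cfg()
  bl <- human_baseline()
  cm <- load_compound("bosentan")
  reg <- dose_regimen(500, 12, 10)
  peak <- function(mode) {
    cmx <- set_inhibition_mode(cm, "BSEP", mode)
    sim <- simulate_dili(cfg$physiology, cfg$transporters, cfg$tox,
                         cfg$injury, compound = cmx, regimen = reg,
                         days = 5, init = bl$state)
    max(liver_ba_conc(sim)$conc_uM)
  }
  expect_gte(peak("noncompetitive"), peak("competitive"))
})

test_that("peak liver bile acid is non-decreasing in inhibitor dose", {
  cfg <- human_cfg()
  bl <- human_baseline()
  cm <- load_compound("bosentan")
  peaks <- vapply(c(125, 500, 2000), function(dose) {
    sim <- simulate_dili(cfg$physiology, cfg$transporters, cfg$tox,
                         cfg$injury, compound = cm,
                         regimen = dose_regimen(dose, 12, 10),
                         days = 5, init = bl$state)
    max(liver_ba_conc(sim)$conc_uM)
  }, 0)
  expect_true(all(diff(peaks) >= -1e-9))
})

test_that("mole balance holds under drug at 1e-6", {
  cfg <- human_cfg()
  cm <- load_compound("bosentan")
  sim <- simulate_dili(cfg$physiology, cfg$transporters, cfg$tox,
                       cfg$injury, compound = cm,
                       regimen = dose_regimen(500, 12, 10), days = 5,
                       init = human_baseline()$state)
  expect_lt(ba_mole_balance(sim), 1e-6)
  expect_true(all(drug_mass_balance(sim)$max_rel_error < 1e-6))
})
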