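test_that("dose schedules and degenerate regimens behave", {
  reg <- dose_regimen(500, interval = 12, n_doses = 60)
  expect_length(dose_times(reg), 60)
  expect_equal(max(dose_times(reg)), 29.5 * 24)

  # zero dose: all drug concentrations identically zero
  cm <- bateman_compound()
  curve <- simulate_pk(cm, dose_regimen(0, 24, 1), bateman_physiology(),
                       days = 1)
  expect_true(all(curve$conc_uM == 0))
})

test_that("linear-regime plasma curve matches the Bateman solution", {
  ka <- 0.8; cl <- 3
  cm <- bateman_compound(ka, cl)
  phys <- bateman_physiology()
  dose_umol <- 100 / cm$molecular_weight * 1000
  curve <- simulate_pk(cm, dose_regimen(100, 24, 1), phys, days = 1,
                       dt_out = 0.25)
  pl <- curve[curve$compartment == "plasma" & curve$time_h >= 0.5, ]
  expected <- bateman_conc(pl$time_h, dose_umol, ka,
                           cl, cm$v_central * phys$bodyweight, cm$f_abs)
  expect_lt(max(abs(pl$conc_uM - expected) / expected), 1e-3)
})

test_that("drug mass is conserved across compartments and sinks", {
  cfg <- human_cfg()
  cm <- load_compound("bosentan")
  sim <- simulate_pk(cm, dose_regimen(500, 12, 6), cfg$physiology,
                     days = 3)
  mb <- drug_mass_balance(sim)
  expect_true(all(mb$max_rel_error < 1e-6))
})

test_that("doubling the dose doubles AUC in the linear uptake regime", {
  cfg <- human_cfg()
  cm <- load_compound("bosentan")
  # tiny doses keep hepatic uptake far below saturation
  a1 <- auc(simulate_pk(cm, dose_regimen(0.5, 24, 1), cfg$physiology,
                        days = 1.5), "bosentan")
  a2 <- auc(simulate_pk(cm, dose_regimen(1, 24, 1), cfg$physiology,
                        days = 1.5), "bosentan")
  expect_equal(a2 / a1, 2, tolerance = 0.01)
})

test_that("autoinduction lowers the late trough below the first-day trough", {
  cfg <- human_cfg()
  cm <- load_compound("bosentan")
  curve <- simulate_pk(cm, dose_regimen(500, 12, 56), cfg$physiology,
                       days = 28, dt_out = 0.25)
  pl <- curve[curve$species == "bosentan" & curve$compartment == "plasma", ]
  trough1 <- pl$conc_uM[which.min(abs(pl$time_h - 11.75))]
  trough28 <- pl$conc_uM[which.min(abs(pl$time_h - 671.75))]
  expect_lte(trough28, trough1)
})

test_that("apply_impaired_metabolism scales only metabolite formation", {
  cm <- load_compound("bosentan")
  out <- apply_impaired_metabolism(cm, 0.1)
  expect_equal(out$metabolites[[1]]$vmax_formation,
               cm$metabolites[[1]]$vmax_formation * 0.1)
  expect_equal(out$metabolites[[2]]$vmax_formation,
               cm$metabolites[[2]]$vmax_formation * 0.1)
  expect_equal(out$uptake_vmax, cm$uptake_vmax)
  expect_equal(apply_impaired_metabolism(cm, 1), cm)
  half <- apply_impaired_metabolism(cm, 0.5)
  expect_equal(vapply(half$metabolites, `[[`, 0, "vmax_formation"),
               vapply(cm$metabolites, `[[`, 0, "vmax_formation") / 2)
  expect_error(apply_impaired_metabolism(cm, 0))
  expect_error(apply_impaired_metabolism(cm, -1))
})

test_that("auc matches simple geometry", {
  flat <- tibble::tibble(time_h = seq(0, 24, 4), species = "x",
                         compartment = "plasma", conc_uM = 2)
  expect_equal(auc(flat, "x", 0, 24), 48)
  zero <- dplyr::mutate(flat, conc_uM = 0)
  expect_equal(auc(zero, "x", 0, 24), 0)
  tri <- tibble::tibble(time_h = c(0, 12, 24), species = "x",
                        compartment = "plasma", conc_uM = c(0, 10, 0))
  expect_equal(auc(tri, "x", 0, 24), 120)
  expect_error(auc(flat, "nope"), "not present")
  expect_error(auc(flat, "x", 10, 5), "increasing")
})

test_that("fit_pk recovers parameters from its own data", {
  phys <- bateman_physiology()
  truth <- bateman_compound(ka = 0.8, cl = 3)
  reg <- dose_regimen(100, 24, 1)
  times <- c(0.5, 1, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24)

  # noise-free self-consistency
  obs0 <- gen_plasma_pk(truth, reg, phys, times, noise_model(cv = 0))
  fit0 <- fit_pk(obs0, truth, reg, phys,
                 free_params = c(ka = 0.5, renal_cl = 5),
                 lower = c(0.05, 0.1), upper = c(5, 50))
  expect_equal(fit0$convergence, "converged")
  expect_lt(abs(fit0$estimates[["ka"]] - 0.8) / 0.8, 1e-3)
  expect_lt(abs(fit0$estimates[["renal_cl"]] - 3) / 3, 1e-3)

  # 5% proportional noise: within 15% of truth
  obs <- gen_plasma_pk(truth, reg, phys, times,
                       noise_model(cv = 0.05, seed = 7))
  fit <- fit_pk(obs, truth, reg, phys,
                free_params = c(ka = 0.5, renal_cl = 5),
                lower = c(0.05, 0.1), upper = c(5, 50))
  expect_lt(abs(fit$estimates[["ka"]] - 0.8) / 0.8, 0.15)
  expect_lt(abs(fit$estimates[["renal_cl"]] - 3) / 3, 0.15)
})

test_that("fit_pk flags degenerate all-zero observations", {
  phys <- bateman_physiology()
  truth <- bateman_compound()
  reg <- dose_regimen(100, 24, 1)
  obs <- tibble::tibble(time_h = seq(1, 24, 2), species = "probe",
                        compartment = "plasma", conc_uM = 0)
  fit <- fit_pk(obs, truth, reg, phys,
                free_params = c(ka = 0.5, renal_cl = 5),
                lower = c(0.05, 0.1), upper = c(5, 500))
  expect_true(fit$convergence %in% c("boundary", "non-convergence"))
})

test_that("pk curves round-trip through tidy CSV", {
  cm <- bateman_compound()
  curve <- simulate_pk(cm, dose_regimen(100, 24, 1), bateman_physiology(),
                       days = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_csv(curve, path)
  back <- read_pk_csv(path)
  expect_equal(back$conc_uM, curve$conc_uM, tolerance = 1e-12)
  expect_s3_class(back, "pk_curve")
})
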