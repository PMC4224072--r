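test_that("ATP-dependent uptake subtracts background and averages replicates", {
  conc <- c(1000, 100, 10, 1, 0.1)
  pl <- vesicle_plate(conc, uptake_atp = cbind(rep(5, 5), rep(5, 5)),
                      uptake_amp = cbind(rep(5, 5), rep(5, 5)))
  expect_true(all(atp_dependent_uptake(pl)$net_signal == 0))

  pl2 <- vesicle_plate(conc, uptake_atp = rep(8, 5), uptake_amp = rep(0, 5))
  expect_true(all(atp_dependent_uptake(pl2)$net_signal == 8))

  pl3 <- vesicle_plate(conc, uptake_atp = cbind(rep(10, 5), rep(12, 5)),
                       uptake_amp = matrix(0, 5, 2))
  expect_true(all(atp_dependent_uptake(pl3)$net_signal == 11))
})

test_that("IC50 is recovered from synthetic plates", {
  # noise-free: essentially exact
  pl0 <- gen_vesicle_assay(true_ic50 = 7.45, true_hill = 1,
                           max_inhibition = 97,
                           noise = noise_model(cv = 0))
  fit0 <- fit_ic50(pl0)
  expect_true(fit0$converged)
  expect_lt(abs(fit0$ic50 - 7.45) / 7.45, 1e-3)
  expect_lt(abs(fit0$max_inhibition_pct - 97) / 97, 0.02)

  # 3% proportional noise: within 15%
  pl <- gen_vesicle_assay(true_ic50 = 7.45, true_hill = 1,
                          max_inhibition = 97,
                          noise = noise_model(cv = 0.03, seed = 3))
  fit <- fit_ic50(pl)
  expect_lt(abs(fit$ic50 - 7.45) / 7.45, 0.15)
})

test_that("a flat plate is flagged, not fitted", {
  conc <- c(30000, 10000, 3160, 1000, 316, 100, 31.6, 10)
  pl <- vesicle_plate(conc, uptake_atp = rep(100, 8), uptake_amp = rep(0, 8))
  fit <- fit_ic50(pl)
  expect_false(fit$converged)
  expect_match(fit$flag, "no transition")
  expect_true(is.na(fit$ic50))
})

test_that("fit_ic50 is scale-equivariant in concentration", {
  pl <- gen_vesicle_assay(true_ic50 = 5, true_hill = 1.2,
                          max_inhibition = 98, noise = noise_model(cv = 0))
  net <- atp_dependent_uptake(pl)
  f1 <- fit_ic50(net)
  net10 <- dplyr::mutate(net, conc_uM = conc_uM * 10)
  f10 <- fit_ic50(net10)
  expect_equal(f10$ic50 / f1$ic50, 10, tolerance = 1e-3)
})

test_that("Ki adopts the IC50 value with provenance", {
  expect_equal(as.numeric(ki_from_ic50(16)), 16)
  expect_equal(as.numeric(ki_from_ic50(7.45)), 7.45)
  expect_equal(as.numeric(ki_from_ic50(1)), 1)
  expect_match(attr(ki_from_ic50(1), "provenance"), "IC50")
  expect_error(ki_from_ic50(0))
})

test_that("plates round-trip through long-format CSV", {
  pl <- gen_vesicle_assay(true_ic50 = 7.45, noise = noise_model(cv = 0.03,
                                                                seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(pl, path)
  back <- read_plate_csv(path)
  expect_equal(back$uptake_atp, pl$uptake_atp, tolerance = 1e-12)
  expect_equal(back$conc_well, pl$conc_well)
})

test_that("unmatched wells are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(well = 1:5, conc_uM = c(1000, 316, 100, 31.6, 10),
                   atp_flag = 1, replicate = 1, signal = 50)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_plate_csv(path), "unmatched")
})
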