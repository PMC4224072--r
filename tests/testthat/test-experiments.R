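test_that("the scenario registry builds every registered scenario", {
  tab <- list_scenarios()
  expect_gt(nrow(tab), 10)
  for (nm in tab$name) {
    sc <- scenario(nm)
    expect_s3_class(sc, "scenario")
    expect_true(sc$species %in% c("human", "rat"))
  }
  expect_error(scenario("not_a_scenario"), "unknown scenario")
})

test_that("scenario definitions encode their hypothesis flags", {
  # telmisartan 50 mg: 30 once-daily doses
  sc <- scenario("telmisartan_50_competitive")
  expect_equal(sc$regimen$amount, 50)
  expect_equal(sc$regimen$interval, 24)
  expect_length(dose_times(sc$regimen), 30)
  expect_equal(sc$compound$inhibitions[[1]]$mode, "competitive")
  expect_equal(scenario("telmisartan_50_noncompetitive")$
                 compound$inhibitions[[1]]$mode, "noncompetitive")

  # rat uptake-inhibition knockout: NTCP Ki pushed to 1e10
  sc2 <- scenario("bosentan_rat_no_uptake_inhibition")
  ntcp <- Filter(function(s) s$transporter == "NTCP",
                 sc2$compound$inhibitions)
  expect_equal(ntcp[[1]]$ki, 1e10)

  # poor metabolite clearance: 10% of the parent biliary clearance
  sc3 <- scenario("cp724714_poor_clearance")
  expect_equal(sc3$compound$metabolites[[1]]$product_biliary_cl,
               sc3$compound$biliary_cl * 0.1)

  # ETC hypothesis adds ETC inhibition to parent and metabolite
  sc4 <- scenario("cp724714_etc")
  has_etc <- function(specs) any(vapply(specs, function(s)
    s$transporter == "ETC", TRUE))
  expect_true(has_etc(sc4$compound$inhibitions))
  expect_true(has_etc(sc4$compound$metabolites[[1]]$product_inhibitions))

  # impaired metabolism: both formation Vmax at 10%
  sc5 <- scenario("bosentan_human_impaired_metabolism")
  base <- scenario("bosentan_human_baseline")
  expect_equal(vapply(sc5$compound$metabolites, `[[`, 0, "vmax_formation"),
               vapply(base$compound$metabolites, `[[`, 0,
                      "vmax_formation") * 0.1)
})

test_that("zero dose yields zero exposure and baseline normalized LFT", {
  tab <- lft_vs_auc_table("cp724714_baseline", doses = 0, days = 22)
  expect_equal(tab$auc24_day22_uM_h, 0)
  expect_equal(tab$peak_norm_lft, 1 / 3, tolerance = 1e-3)
  expect_error(lft_vs_auc_table(doses = 100, days = 10), "22 days")
})

test_that("the metabolite clearance sweep is monotone and saturates", {
  sw <- metabolite_clearance_sweep(cl_values = c(5, 20, 200, 200),
                                   cp_dose_mg = 400)
  # duplicate clearance values give identical outputs
  expect_equal(sw$peak_alt_fold[3], sw$peak_alt_fold[4])
  # peak ALT fold is monotone non-increasing in clearance
  expect_true(all(diff(sw$peak_alt_fold[1:3]) <= 1e-9))
  # very large clearance: no metabolite accumulation, no ALT signal
  expect_lt(sw$peak_alt_fold[3], 1.05)
})

test_that("run_scenario writes a results bundle", {
  dir <- withr::local_tempdir()
  out <- run_scenario("telmisartan_50_competitive", days = 2,
                      out_dir = dir)
  expect_true(file.exists(file.path(
    dir, "telmisartan_50_competitive_summary.json")))
  expect_s3_class(out$sim, "dili_sim")
  expect_equal(out$summary$peak_alt_fold, 1, tolerance = 1e-6)
})
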