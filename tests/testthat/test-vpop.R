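small_specs <- function(scale = 0.2) {
  list(variability_spec("transporters.BSEP.vmax", "lognormal", 0, scale,
                        0.2, 5),
       variability_spec("physiology.ba_synthesis", "lognormal", 0, scale,
                        0.3, 3))
}

small_pop <- function(n = 4, seed = 5, scale = 0.2) {
  cfg <- human_cfg()
  generate_simpops(n, small_specs(scale), cfg$physiology, cfg$transporters,
                   cfg$tox, cfg$injury, seed = seed)
}

test_that("population generation is bit-reproducible from its seed", {
  p1 <- small_pop(4, seed = 5)
  p2 <- small_pop(4, seed = 5)
  ov <- function(p) lapply(p$individuals, `[[`, "overrides")
  expect_identical(ov(p1), ov(p2))
  expect_identical(lapply(p1$individuals, `[[`, "baseline_state"),
                   lapply(p2$individuals, `[[`, "baseline_state"))
  p3 <- small_pop(4, seed = 6)
  expect_false(identical(ov(p1), ov(p3)))
})

test_that("near-zero variance collapses the population onto the baseline", {
  pop <- small_pop(3, seed = 2, scale = 1e-6)
  for (ind in pop$individuals)
    expect_equal(unname(ind$overrides), c(1, 1), tolerance = 1e-4)
  bl <- human_baseline()
  expect_equal(pop$individuals[[1]]$baseline_summary[["atp_mM"]],
               bl$state[["atp"]], tolerance = 1e-3)
})

test_that("an impossible acceptance range aborts with diagnostics", {
  cfg <- human_cfg()
  expect_error(
    generate_simpops(3, small_specs(), cfg$physiology, cfg$transporters,
                     cfg$tox, cfg$injury, seed = 1,
                     acceptance_ranges = list(liver_ba_uM = c(500, 600))),
    "acceptance rate")
})

test_that("drug-free population runs stay at each individual's baseline ATP", {
  pop <- small_pop(4, seed = 3)
  res <- run_population(pop, scenario = NULL, days = 5)
  expect_true(all(res$status == "ok"))
  base_atp <- vapply(pop$individuals, function(i)
    i$baseline_summary[["atp_mM"]], 0)
  expect_true(all(abs(res$min_atp_mM - base_atp) / base_atp < 0.01))
})

test_that("duplicated individuals give identical results (order-independent)", {
  pop <- small_pop(2, seed = 4)
  pop$individuals <- list(pop$individuals[[1]], pop$individuals[[2]],
                          pop$individuals[[1]])
  pop$individuals[[3]]$id <- 3L
  sc <- scenario("telmisartan_50_noncompetitive")
  res <- run_population(pop, sc, days = 3)
  expect_equal(dplyr::select(res[3, ], -id), dplyr::select(res[1, ], -id))
})

test_that("incidence arithmetic matches reported percentages", {
  fake <- function(n, k)
    tibble::tibble(status = "ok",
                   peak_alt_fold = c(rep(10, k), rep(1, n - k)))
  expect_equal(incidence(fake(331, 1))$percentage, 0.302, tolerance = 0.002)
  expect_equal(incidence(fake(331, 8))$percentage, 2.42, tolerance = 0.002)
  expect_equal(incidence(fake(50, 0))$percentage, 0)
  expect_equal(incidence(fake(331, 1))$n_elevated, 1)
})

test_that("PK variability layer validates its parameter set and reproduces", {
  pop <- small_pop(3, seed = 7)
  bad <- list(variability_spec("compound.ka", "normal", 1, 0.2, 0.2, 3))
  expect_error(add_pk_variability(pop, bad), "exactly")

  p1 <- add_pk_variability(pop, default_pk_specs(), seed = 11)
  p2 <- add_pk_variability(pop, default_pk_specs(), seed = 11)
  expect_identical(lapply(p1$individuals, `[[`, "pk_overrides"),
                   lapply(p2$individuals, `[[`, "pk_overrides"))

  # (near-)zero variance leaves outcomes unchanged
  tiny <- lapply(default_pk_specs(), function(s) {
    s$scale <- 1e-9; s })
  p0 <- add_pk_variability(pop, tiny, seed = 11)
  sc <- scenario("bosentan_human_baseline")
  r_base <- run_population(pop, sc, days = 4)
  r_tiny <- run_population(p0, sc, days = 4)
  expect_equal(r_tiny$min_atp_mM, r_base$min_atp_mM, tolerance = 1e-6)
})

test_that("PK variability widens the outcome distribution", {
  pop <- small_pop(12, seed = 8, scale = 0.1)
  sc <- scenario("bosentan_human_baseline")
  r0 <- run_population(pop, sc, days = 6)
  r1 <- run_population(add_pk_variability(pop, default_pk_specs(),
                                          seed = 21), sc, days = 6)
  expect_gt(sd(r1$min_atp_mM), sd(r0$min_atp_mM))
})

test_that("population manifests serialize to JSON", {
  pop <- small_pop(2, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_population_manifest(pop, path)
  m <- jsonlite::read_json(path)
  expect_equal(m$n, 2)
  expect_equal(m$seed, 9)
  expect_length(m$individuals, 2)
})
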