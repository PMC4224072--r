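test_that("delayed sensing matches its exponential solution", {
  expect_equal(delay_update(5, 5, 0.3), 0)

  # constant input: gap closes by 63.2% after one time constant
  tau <- 0.4
  sol <- deSolve::lsoda(c(d = 0), seq(0, 1 / tau, length.out = 5),
                        function(t, y, p) list(delay_update(10, y, tau)),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[nrow(sol), "d"]), 10 * (1 - exp(-1)),
               tolerance = 1e-6)

  # very fast tau: delayed value tracks the input closely
  expect_gt(delay_update(10, 9.99, 1000), 0)
  sol2 <- deSolve::lsoda(c(d = 0), c(0, 0.05),
                         function(t, y, p) list(delay_update(10, y, 200)),
                         parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol2[2, "d"]), 10, tolerance = 1e-3)
})

test_that("synthesis signal has the Hill form and limits", {
  tox <- tox_params(vmax_s = c(10, 6), km_s = c(40, 10), hill = 2.5,
                    tau = 0.3, k_atp = 1.2, baseline_atp = 4.2)
  expect_equal(synthesis_signal(c(0, 0), tox)$S, 1)

  # half-saturation: per-class S = 1/(1 + vmax_s/2)
  s <- synthesis_signal(c(40, 0), tox)
  expect_equal(s$per_class[1], 1 / (1 + 10 / 2))
  s2 <- synthesis_signal(c(0, 10), tox)
  expect_equal(s2$per_class[2], 1 / (1 + 6 / 2))

  # saturating concentration: per-class floor 1/(1 + vmax_s)
  s3 <- synthesis_signal(c(1e9, 1e9), tox)
  expect_equal(s3$per_class, c(1 / 11, 1 / 7), tolerance = 1e-6)
  expect_equal(s3$S, prod(s3$per_class), tolerance = 1e-6)

  # combined signal is the product over classes, bounded in (0, 1]
  s4 <- synthesis_signal(c(20, 5), tox)
  expect_equal(s4$S, prod(s4$per_class))
  expect_true(s4$S > prod(1 / (1 + tox$vmax_s)) && s4$S <= 1)
})

test_that("ATP turnover is calibrated to its baseline fixed point", {
  tox <- tox_params(vmax_s = 10, km_s = 40, hill = 2.5, tau = 0.3,
                    k_atp = 1.2, baseline_atp = 4.2)
  expect_equal(atp_dynamics(4.2, 1, 1, tox), 0)
  # S = 0.5 moves the steady state to half baseline
  expect_equal(atp_dynamics(0.5 * 4.2, 0.5, 1, tox), 0)
  expect_lt(atp_dynamics(4.2, 0.5, 1, tox), 0)
})

test_that("drug-free human and rat simulations hold their baseline ATP", {
  h <- human_baseline()$sim
  expect_equal(tail(h$state[, "atp"], 1), 4.2, tolerance = 0.02)
  r <- rat_baseline()$sim
  expect_equal(tail(r$state[, "atp"], 1), 2.0, tolerance = 0.02)
})

test_that("ETC inhibition multiplies per-compound factors", {
  expect_equal(etc_inhibition_factor(numeric(0), numeric(0)), 1)
  expect_equal(etc_inhibition_factor(5, 5), 0.5)
  expect_equal(etc_inhibition_factor(c(5, 5), c(5, 5)), 0.25)
})

test_that("injury model: no necrosis above threshold, ALT decays first order", {
  inj <- injury_params(atp_death_threshold = 1.9, k_necrosis_max = 0.05,
                       necrosis_hill = 3, alt_content = 150,
                       k_alt_clear = 0.02, k_bili_base_clear = 0.1,
                       k_regen = 0.005)
  # at or above threshold nothing happens
  out <- injury_dynamics(3, 1, 1, 1, inj)
  expect_equal(out$hazard, 0)
  expect_equal(out$d_viable, 0)
  expect_equal(out$d_alt, 0)

  # after an ALT impulse the fold relaxes to 1 at rate k_alt_clear
  out2 <- injury_dynamics(3, 1, 2, 1, inj)
  expect_equal(out2$d_alt, inj$k_alt_clear * (1 - 2))

  # a 1% necrosis step releases alt_content/100 fold equivalents
  out3 <- injury_dynamics(0, 1, 1, 1, inj)
  expect_equal(out3$hazard, inj$k_necrosis_max)
  expect_equal(out3$d_alt, inj$alt_content * inj$k_necrosis_max)

  # sustained zero ATP: viable fraction strictly decreasing
  for (v in c(1, 0.8, 0.5, 0.2))
    expect_lt(injury_dynamics(0, v, 1, 1, inj)$d_viable, 0)

  # bilirubin steady state is 1/viable_fraction
  expect_equal(injury_dynamics(3, 0.5, 1, 2, inj)$d_bili, 0)
})

test_that("normalized LFT follows max(ALT/5, bilirubin/3)", {
  expect_equal(normalized_lft(5, 3), 1)
  expect_equal(normalized_lft(15, 1), 3)
  expect_equal(normalized_lft(0, 0), 0)
  expect_equal(normalized_lft(1, 1), 1 / 3)
  expect_error(normalized_lft(-1, 0), "non-negative")
})

test_that("conjugates inherit their parent acid's toxicity class", {
  tab <- ba_species_table()
  expect_equal(tab$toxicity_class[tab$species == "CDCA_amide"], "CDCA-like")
  expect_equal(tab$toxicity_class[tab$species == "LCA_amide"], "LCA-like")
  expect_equal(tab$toxicity_class[tab$species == "LCA_sulfate"], "LCA-like")
})

test_that("toxicity parameters are recoverable from in-vitro ATP data", {
  truth <- tox_params(vmax_s = 10, km_s = 40, hill = 2.5, tau = 0.3,
                      k_atp = 1.2, baseline_atp = 4.2)
  exposures <- c(5, 10, 20, 40, 80, 160)
  times <- seq(2, 48, 4)

  clean <- gen_invitro_atp(truth, "CDCA-like", exposures, times,
                           noise_model(cv = 0))
  fit0 <- fit_tox_params(clean, k_atp = 1.2, baseline_atp = 4.2)
  expect_equal(fit0$convergence, "converged")
  tru <- c(vmax_s = 10, km_s = 40, hill = 2.5, tau = 0.3)
  expect_true(all(abs(fit0$estimates - tru) / tru < 1e-3))

  noisy <- gen_invitro_atp(truth, "CDCA-like", exposures, times,
                           noise_model(cv = 0.05, seed = 11))
  fit <- fit_tox_params(noisy, k_atp = 1.2, baseline_atp = 4.2)
  expect_true(all(abs(fit$estimates - tru) / tru < 0.20))
})

test_that("a toxicity-free ATP dataset pins vmax_s near zero", {
  flat <- tidyr::expand_grid(exposure_uM = c(10, 50, 200),
                             time_h = seq(2, 48, 4))
  flat$atp_pct <- 100
  fit <- fit_tox_params(flat, k_atp = 1.2, baseline_atp = 4.2)
  expect_lt(fit$estimates[["vmax_s"]], 0.05)
})

test_that("single-exposure designs raise the identifiability warning", {
  truth <- tox_params(vmax_s = 10, km_s = 40, hill = 2.5, tau = 0.3,
                      k_atp = 1.2, baseline_atp = 4.2)
  one <- gen_invitro_atp(truth, "CDCA-like", 40, seq(2, 48, 4),
                         noise_model(cv = 0))
  expect_warning(fit <- fit_tox_params(one, k_atp = 1.2,
                                       baseline_atp = 4.2),
                 "identifiable")
  expect_false(fit$identifiable)
})
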