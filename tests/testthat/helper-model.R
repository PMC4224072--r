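# Shared fixtures. Heavy objects (species configs, solved baselines,
# virtual populations) are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

human_cfg <- function() cached("human_cfg", load_species_config("human"))
rat_cfg <- function() cached("rat_cfg", load_species_config("rat"))

human_baseline <- function() cached("human_baseline", {
  cfg <- human_cfg()
  solve_baseline(cfg$physiology, cfg$transporters, cfg$tox, cfg$injury)
})

rat_baseline <- function() cached("rat_baseline", {
  cfg <- rat_cfg()
  solve_baseline(cfg$physiology, cfg$transporters, cfg$tox, cfg$injury)
})

human_pop <- function() cached("human_pop", {
  cfg <- human_cfg()
  vp <- load_vpop_config("human")
  generate_simpops(vp$n, vp$specs, cfg$physiology, cfg$transporters,
                   cfg$tox, cfg$injury, seed = vp$seed,
                   acceptance_ranges = vp$acceptance_ranges)
})

rat_pop <- function() cached("rat_pop", {
  cfg <- rat_cfg()
  vp <- load_vpop_config("rat")
  generate_simpops(vp$n, vp$specs, cfg$physiology, cfg$transporters,
                   cfg$tox, cfg$injury, seed = vp$seed,
                   acceptance_ranges = vp$acceptance_ranges)
})

pop_result <- function(scenario_name) {
  key <- paste0("res_", scenario_name)
  cached(key, {
    sc <- scenario(scenario_name)
    pop <- if (sc$species == "human") human_pop() else rat_pop()
    run_population(pop, sc)
  })
}

# A deliberately simple one-compartment-like compound: oral absorption into
# a fast-transit portal, renal elimination only; liver is bypassed.
bateman_compound <- function(ka = 0.8, cl = 3) {
  compound_model(name = "probe", molecular_weight = 400, ka = ka,
                 f_abs = 0.9, uptake_vmax = 0, uptake_km = 1,
                 passive_cl = 0, biliary_cl = 0, renal_cl = cl,
                 v_central = 0.3, v_peripheral = 0, q_peripheral = 0)
}

# physiology with a near-instantaneous portal transit so the model
# collapses to the one-compartment oral-absorption system
bateman_physiology <- function() {
  p <- human_cfg()$physiology
  p$portal_volume <- 0.004
  p$hepatic_blood_flow <- 400
  p
}

bateman_conc <- function(t, dose_umol, ka, cl, v, f_abs) {
  ke <- cl / v
  f_abs * dose_umol * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}
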