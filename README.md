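# biletox

Mechanistic simulation of bile acid-mediated drug-induced liver injury
(DILI) caused by inhibition of hepatic bile acid transporters, for
toxicologists and pharmacometricians who want to ask *whether* — and in
*which individuals* — a BSEP inhibitor will raise serum ALT, rather than
rank compounds by IC50 alone.

## What it models

Four coupled layers, integrated as one ODE system:

1. **Drug disposition** — a minimal PBPK model (gut lumen -> portal blood
   -> liver <-> systemic blood <-> peripheral tissue) with saturable
   hepatic uptake, up to two explicit metabolites, biliary/renal
   clearance, and autoinduction. Doses are discrete events (oral or IV;
   mg/kg for rat).
2. **Bile acid enterohepatic circulation** — chenodeoxycholic and
   lithocholic acid and their conjugates, synthesized in liver, exported
   by BSEP into the gallbladder, discharged into the gut at meals,
   recycled through portal blood by NTCP, with a lumped basolateral
   escape route. Drugs inhibit these transporters competitively
   (apparent Km x (1 + I/Ki)) or noncompetitively (Vmax / (1 + I/Ki)).
3. **Hepatotoxicity** — delayed liver bile acid concentrations drive a
   Hill-type ATP-synthesis-inhibition signal S per toxicity class;
   d(ATP)/dt = k_synth·S·E − k_usage·ATP/ATP0, where E is an optional
   electron-transport-chain inhibition factor; ATP below a death
   threshold produces hepatocyte necrosis, serum ALT and bilirubin
   elevations, and the normalized LFT statistic
   max(ALT fold/5, bilirubin fold/3).
4. **Virtual populations** — seeded rejection-sampled variability in
   transport capacity and bile acid synthesis (331 humans / 191 rats by
   default), per-individual baselines, and ALT > 3x incidence.

The packaged calibration reproduces the headline discriminations of this
model class: bosentan produces a small number of ALT elevations in the
human population but none in the rat; telmisartan produces none at
clinical doses under either inhibition mode; CP-724,714 hepatotoxicity
requires metabolite accumulation plus mitochondrial (ETC) inhibition, and
is insensitive to dose under competitive-only assumptions.

It also ships analysis tools: vesicle-assay IC50 fitting (4-parameter
logistic on ATP-dependent uptake, Ki taken as IC50), PBPK parameter
estimation from concentration-time data, in-vitro ATP time-course fitting
for the toxicity constants, and synthetic-data generators with known
ground truth for all three.

## A worked example

```r
library(biletox)

run <- run_scenario("bosentan_human_baseline")
run$summary
#> # A tibble: 1 x 10
#>   scenario                species min_atp_mM peak_alt_fold peak_bili_fold
#>   <chr>                   <chr>        <dbl>         <dbl>          <dbl>
#> 1 bosentan_human_baseline human         3.47          1.00           1.00
#> # peak_norm_lft 0.333, peak_liver_ba_uM 33.0, auc24_day1_uM_h 18.7, ...
```

The typical (baseline) human tolerates bosentan: hepatic ATP dips visibly
(3.5 mM against the 4.2 mM baseline, driven by liver bile acid rising from
~1 to ~30 uM after doses) but stays above the necrosis threshold, so ALT
never moves. Toxicity is a population phenomenon:

```r
cfg <- load_species_config("human")
vp  <- load_vpop_config("human")
pop <- generate_simpops(vp$n, vp$specs, cfg$physiology, cfg$transporters,
                        cfg$tox, cfg$injury, seed = vp$seed,
                        acceptance_ranges = vp$acceptance_ranges)
res <- run_population(pop, scenario("bosentan_human_baseline"))
incidence(res)
#> # A tibble: 1 x 3
#>       n n_elevated percentage
#>   <int>      <int>      <dbl>
#> 1   331          7       2.11
```

A few individuals — low BSEP capacity, high synthesis — cross into
sustained ATP depletion and ALT elevation; the same population under
telmisartan 50 mg (`scenario("telmisartan_50_noncompetitive")`) yields 0
of 331, and the rat population under 50 mg/kg bosentan 0 of 191.
`plot_population_atp()` shows the per-individual minimum-ATP pattern that
separates these regimens more sharply than the counts.

Scenario registry: `list_scenarios()` enumerates all bosentan,
telmisartan and CP-724,714 hypothesis variants;
`metabolite_clearance_sweep()` and `lft_vs_auc_table()` reproduce the
dose-response and metabolite-clearance analyses. A thin CLI wraps these:
`Rscript inst/cli/simulate run <scenario> --seed 1 --out DIR` (also
`list-scenarios`, `population`, `sweep-clearance`).

## Documentation

The methods vignette (`vignettes/biletox-methods.Rmd`) describes the
model equations and assumptions, every calibrated default and why it was
chosen, what the synthetic-data generators do and do not emulate, and the
package's known limitations.
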