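# marinedisp

Displacement analysis of marine top predators — seabirds and small
cetaceans — around offshore developments, from boat-based line-transect
surveys.

Environmental monitoring of offshore wind farms commonly surveys a study
area along parallel transects across three development phases
(preconstruction, construction, operation) and asks: did relative
abundance inside the development footprint change between phases?
`marinedisp` implements the full analysis pipeline for that question,
aimed at ecological statisticians and impact-assessment practitioners:

1. **Survey ingestion and segmentation** — GPS tracks, timestamped
   sightings and Beaufort sea-state logs are combined into a per-segment
   modelling table: transects are projected to UTM (zone 30N, in-package
   Krüger-series transverse Mercator), divided by along-track chainage
   into 600 m (seabird) or 1 km (cetacean) segments, and each segment
   gets a summed count, an effort length, a good/poor sea-state class
   and a development phase.
2. **Hierarchical Bayesian count GAMMs** — counts per segment are
   modelled with a log link as

   `log mu = beta_phase + f_phase(x, y) + b_survey + b_transect + log(effort/L)`

   with a distinct low-rank thin-plate spatial smooth per phase, nested
   random effects, and either a negative binomial response
   (`Var = mu + mu^2/theta`; seabird) or a zero-inflated Poisson whose
   extra-zero probability depends on survey conditions
   (`logit pi0 = gamma0 + gamma_cond [poor]`; cetacean). Models are fit
   by an in-package Hamiltonian-Monte-Carlo-within-Gibbs sampler with
   non-centred scales, seeded and exactly reproducible, with R-hat/ESS
   diagnostics.
3. **Displacement maps** — per-phase posterior prediction surfaces
   (relative abundance per segment at population level), SD/mean
   uncertainty maps, and pairwise-phase change maps that flag a cell
   when the two phases' 95% credible intervals do not overlap, plus
   footprint-wide posterior summaries.
4. **Synthetic surveys with known truth** — `scenario_config()` /
   `simulate_surveys()` emulate the monitored design (ten 18-km
   transects 2 km apart over 360 km², ~13 km² footprint, Markov-chain
   sea state, NB/ZIP counts over Gaussian-process intensity surfaces,
   optional footprint displacement), so parameter recovery and
   displacement detection are testable end to end.

The methods vignette (`vignettes/displacement-methods.Rmd`) documents
the models, priors, sampler and design decisions.

## Worked example

Simulate a small survey programme (two surveys per phase, 9-km
transects), build the seabird segment table and fit the NB GAMM:

```r
library(marinedisp)

cfg <- scenario_config(transect_length = 9000, surveys_per_phase = 2,
                       seed = 42)
sim <- simulate_surveys(cfg)
seg <- build_segments(sim, "guillemot")

fit <- fit_gamm(seg, model_spec("NB", knots = 12, chains = 3,
                                warmup = 800, draws = 500, seed = 7))
fit
print(render_parameter_table(fit), digits = 2)
```

```
NB GAMM fit: 1500 draws x 108 parameters (3 chains)
converged: TRUE (max monitored R-hat 1.053)
                            parameter raw_est raw_lower raw_upper resp_est resp_lower resp_upper significant
1 Preconstruction versus construction   -0.22     -0.85      0.49      0.8       0.43        1.6          No
2       Construction versus operation    0.31     -0.40      1.04      1.4       0.67        2.8          No
3    Preconstruction versus operation    0.09     -0.55      0.75      1.1       0.58        2.1          No
```

The rows are the pairwise phase contrasts of expected counts per
segment, on the log (raw) and count (response) scales. The generating
construction contrast in this scenario is `-0.5` on the log scale: the
95% credible interval covers it, and with only two surveys per phase no
contrast is (correctly) flagged significant by the CrI rule.
`truth_report(sim$truth, "guillemot")` prints the full generating
parameter set for such comparisons.

Per-phase prediction surfaces and the construction-phase change map:

```r
grid <- make_grid(fit, 600)                       # 0.36 km^2 cells
pre  <- predict_surface(fit, grid, "preconstruction")
con  <- predict_surface(fit, grid, "construction")
cm   <- change_map(pre, con)                      # CrI non-overlap rule
fp   <- project_to_utm(sim$footprint[, "lon"], sim$footprint[, "lat"])
footprint_summary(pre, as.matrix(fp))$mean        # 0.99 birds/segment
sum(cm$significant)                               # 0 of 420 cells
```

One call runs everything (segments, fit, surfaces, change maps, effort
and parameter tables, manifest) into an artifact directory:

```r
d <- tempfile(); write_scenario(sim, d)
res <- run_pipeline(run_config(input = d, species = "guillemot",
                               out = "run1", seed = 1))
verify_run("run1")   # re-derives the tables from stored draws: TRUE
```

A thin command-line wrapper with `simulate`, `run` and `verify`
subcommands is installed at `inst/scripts/marinedisp-cli.R`.

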