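# scatdiet

Quantitative dietary ecology from carnivore scat samples, built around the
sympatric snow leopard / Himalayan wolf system of the Nepalese
trans-Himalaya. For ecologists analysing scat-based diet data, the package
covers the full chain from per-scat prey records to:

- **Diet profiles** — relative frequency of occurrence
  (RFO_i = O_i / ΣO) and relative biomass via linear feeding-trial
  correction factors Y = a + bX (RB_i ∝ FO_i·Y_i), with wild/domestic
  aggregates and scat-level composition summaries;
- **Pianka's dietary overlap** DO = ΣP_ij P_ik / √(ΣP_ij² ΣP_ik²);
- **Levins niche breadth** B = 1/Σp², with cluster-bootstrap percentile
  CIs (resampling whole scats) and a permutation test for an
  interspecific breadth difference;
- **Prey selection** — G-test of use vs availability
  (G = 2ΣO ln(O/E), df = k−1) and Manly selection ratios w_i = o_i/π_i
  with Bonferroni-adjusted simultaneous confidence intervals and
  preference/avoidance classification;
- a **seeded synthetic scat generator** stating the reference study's
  conditions (98/54 scats, published per-scat richness distributions),
  so every stage is testable without any download.

The published diet summary table ships as a plain-text fixture
(`load_reference_diet()`); a deliberately **synthetic** prey-mass table is
included for biomass demos and must be replaced with sourced masses for
real analyses.

## Worked example

```r
library(scatdiet)
run_demo()   # recompute the published headline statistics from the fixture
```

```
PASS  Pianka overlap (biomass basis)         got    0.937  expected    0.937
PASS  Levins breadth, snow leopard (RFO)     got    6.451  expected    6.450
PASS  Levins breadth, wolf (RFO)             got    5.983  expected    5.980
PASS  Snow leopard wild diet share (RFO %)   got   55.274  expected   55.280
PASS  Wolf domestic diet share (RFO %)       got   67.890  expected   67.890
```

The overlap of 0.937 (on the biomass basis; 0.863 on the RFO basis) says
the two predators' diets are nearly proportional — strong potential for
exploitative competition. Breadths of 6.45 and 5.98 mean both spread their
diet over the equivalent of ~6 equally-used prey out of 11.

A synthetic end-to-end run:

```r
sim <- generate_dataset(default_generator_config(seed = 42))
bootstrap_breadth_ci(sim$dataset, "snow_leopard", n_boot = 2000, seed = 42)
#> Levins niche breadth for snow_leopard: 6.41 (95% bootstrap CI 5.33-7.13, 2000 reps)
breadth_difference_test(sim$dataset, "snow_leopard", "wolf",
                        n_perm = 999, seed = 42)
#> Breadth difference snow_leopard vs wolf: |6.41 - 6.20| = 0.213, p = 0.7850 (999 permutations)
g_test(occurrence_counts(sim$dataset, "wolf"), sim$availability)
#> G-test of use vs availability: G = 46.05, df = 10, p = 1.405e-06
```

Both predators were simulated from the same kind of diet, so the breadth
difference is non-significant (p = 0.785); use still deviates from the
availability weights (small p in the G-test) because the simulated diets
are not proportional to availability.

The full pipeline (files in, JSON + markdown report out):

```r
cfg <- analysis_config(paths = list(scats = "scats.csv",
                                    availability = "availability.csv",
                                    attributes = "attributes.csv"),
                       seed = 1)
report <- run_full_analysis(cfg, out = "analysis_out")
```

or from the shell: `Rscript -e 'scatdiet::scatdiet_main()' run --scats ...`
(subcommands `demo`, `simulate`, `run`).

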