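# gpcrdimer

Analysis stack for G protein-coupled receptor (GPCR) di/oligomerization
and beta-arrestin recruitment studies. It is written for groups that
combine single-molecule localization microscopy, rigid-body docking of
receptor complexes, and BRET plate-reader assays, and need the
quantification steps between raw outputs and figures to be explicit,
tested and reproducible.

The package covers three stages, plus a ground-truth simulator:

1. **Oligomer census from localization maps.** Localizations within a
   7 x 7 um ROI are deduplicated (points strictly within 20 nm of a
   survivor are discounted as re-blinks), then assigned to complexes by
   fixed-radius neighborhood analysis (50 nm search radius): a seed
   receptor collects its unassigned neighbors and the group is retired
   from further searches, preventing double counting. The census reports
   complexes by size as a percentage of total receptors (% monomeric,
   % associated), and stratifies ROIs by receptor density
   (high: > 100 receptors/um^2). A single-linkage mode ships for
   sensitivity analysis.

2. **Membrane-topology post-processing of docking poses.** For poses
   `x -> R x + t` of a probe protomer against a membrane-framed target:
   tilt = `acos((R z)·z)` and z-offset of the Calpha centroid along the
   membrane normal; filtering keeps the best 4000 solutions by score and
   discards poses with tilt > 0.4 rad or |z-offset| > 6.0 A; survivors
   are leader-clustered under a 3-A Calpha RMSD cutoff (no
   re-superposition — the target fixes the frame). Also: interface
   contacts (min heavy-atom distance <= 4.5 A per residue pair),
   receptor-arrestin anchor filtering (Calpha distance R132 to
   finger-loop residue 71), Tilt/Rot orientation indices, and heavy-atom
   clash counting for 2:1 vs 2:2 stoichiometry checks.

3. **BRET quantification.** Net BRET = mean(535/475 ratio) minus the
   donor-only control; saturation curves fit one-site-specific binding
   `y = BRETmax·x/(BRET50 + x)`; ligand-induced recruitment traces fit
   one-phase association `y = plateau·(1 − e^(−kt))` with derived
   halftime `ln(2)/k` and initial rate `k·span`; dose-response curves
   fit a Hill-slope-1 logistic reported as −log10 EC50; pathway bias is
   `Emax/EC50` as fold change versus a reference condition.

The simulators (`simulate_localizations()`, `simulate_poses()`,
`simulate_bret()`) generate labelled inputs for each stage with known
composition, tilt/z-offset, or curve parameters, so every procedure is
validated against ground truth and independent brute-force oracles.

## Worked example

```r
library(gpcrdimer)

# simulate a 7x7 um map with known composition, then run the census
sim <- simulate_localizations(palm_sim_config(
  c("1" = 50, "2" = 30, "3" = 15, "5" = 5),
  cluster_radius_nm = 10, loc_error_sd_nm = 5, blink_rate = 0,
  min_center_sep_nm = 300, seed = 11))
census(assign_complexes(sim$map), sim$map)
#> <oligomer_census> 180 receptors in 100 complexes | monomer 27.8% / associated 72.2% | 3.7 receptors/um^2 (low)
#>  size n_complexes pct_receptors
#>     1          50         27.78
#>     2          30         33.33
#>     3          15         25.00
#>     5           5         13.89

# recruitment kinetics: fitted k and plateau give halftime and initial rate
t <- seq(3, 300, by = 3)
fit_kinetics(data.frame(time_s = t,
                        y = 0.05012 * (1 - exp(-1.999e-2 * t))))
#> <kinetics_fit> k 0.01999 /s, plateau 0.05012, halftime 34.67 s, initial rate 0.001002 /s (converged)
```

The census recovers the configured composition exactly (50 monomers, 30
dimers, 15 trimers, 5 pentamers = 180 receptors; 27.78% monomeric). The
kinetics fit recovers the rate constant and plateau of the noise-free
trace; halftime and initial rate are exact functions of the fitted
parameters (`ln(2)/k` and `k·plateau`).

The numbered scripts under `analysis/` run the full workflow in order —
simulation, census (with dedup under blinking and density
stratification), pose filtering/clustering/contacts/clash checks, BRET
fits with bias factors, and the end-to-end pipeline driver
(`run_pipeline()` on `inst/extdata/demo_run.json`) — writing their
tables under `results/`.

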