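---
title: "Methods: oligomer census, pose topology and BRET quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oligomer census, pose topology and BRET quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gpcrdimer implements the computational stack used to study G
protein-coupled receptor (GPCR) di/oligomerization and its consequences
for beta-arrestin recruitment: (i) a single-molecule localization census
that counts receptors in monomers, dimers and higher oligomers; (ii)
membrane-topology post-processing of rigid-body docking poses for a
two-protomer complex, including arrestin anchor filtering, orientation
indices and stoichiometry clash checks; and (iii) BRET curve
quantification (saturation, recruitment kinetics, dose-response and
Emax/EC50 bias factors). A synthetic-data generator provides
ground-truth-labelled inputs for every stage, so the whole stack is
testable without microscopy, docking or plate-reader output.

This vignette records the models, the conventions chosen where the
procedures are usually described only loosely, and what the synthetic
tests do and do not demonstrate about real data.

## 1. Localization census

**Input.** A table of 2D localizations (nm) from sub-pixel particle
localization of PALM/TIRF movies, restricted to a rectangular region of
interest — by convention a 7 x 7 um window, treated as the half-open
rectangle `[0, w) x [0, h)` so a point is counted in exactly one ROI when
windows tile.

**Duplicate discounting.** Photoactivatable dyes re-blink, so one
receptor can appear as several localizations. Points strictly within
20 nm of a surviving point are discounted. The survivor rule had to be
fixed by us: points are visited in a canonical order (frame, then x, then
y, then input index) and each survivor removes all not-yet-visited points
strictly within the radius. This keeps retained points actual detections
(no centroid merging), is deterministic, and makes the result independent
of input row order. The pass is deliberately non-transitive: a chain at
0, 15 and 30 nm keeps the points at 0 and 30 — discounted points do not
themselves discount others.

A consequence worth stating plainly: the 20 nm rule cannot distinguish a
re-blink from a second receptor of the same tight complex. When receptors
are placed within a 10 nm-radius disc, two members of a dimer are often
closer than 20 nm, and dedup merges them. The dedup stage is therefore an
artefact-removal step for blinking data, not an unconditional
preprocessing step; the census of a blink-free simulated map is run
without it, and count-recovery claims for blinking data are made against
the *resolvable* receptor set (the true positions passed through the same
rule).

**Complex assignment.** Neighborhood analysis with a fixed 50 nm search
radius assigns every (deduplicated) localization to exactly one complex.
The published description — a receptor is discounted from further
searches once assigned, to prevent double-counting — reads as greedy
seeded aggregation rather than transitive linkage, so `greedy_seed` is
the default: points are visited in canonical order; each unassigned point
seeds a complex and absorbs every still-unassigned point within the
radius (inclusive). Whether the original interpreter grows complexes
transitively is not documented, so `single_linkage` (connected components
of the within-radius graph) ships as a labelled alternative for
sensitivity analysis rather than a guess at a single intent. Single
linkage can only merge what greedy seeding splits, never the reverse, so
its complex count is never larger. Both modes are verified against
independently coded brute-force implementations on thousands of random
point sets.

**Census and density.** Counts per oligomer size are reported on the
receptor basis (receptors in complexes of size s over all receptors),
with sizes at or above 10 pooled — the pooling point matches the typical
granularity of oligomer heat maps and is configurable. Receptor surface
density is total receptors over the full ROI area, with no edge
correction (none is applied in the field procedure this mirrors); ROIs
above 100 receptors/um^2 (strictly) are classed high-density, all others
low. The same dedup radius is used for treated and untreated ROIs.

## 2. Synthetic localization maps

The generator places complex centers uniformly over the ROI (optionally
with a minimum pairwise separation, enforced by bounded rejection), then
places the s receptors of each complex uniformly in a disc of radius
10 nm by default — small enough that all intra-complex distances stay
below the 50 nm search radius, which is the property the census needs;
no generative model of true receptor arrangements is published. Each
receptor emits one primary localization with Gaussian error (default sd
10 nm, a stand-in consistent with sub-10 nm localization precision — the
actual precision of the dye/instrument pairing is not published and this
default is flagged as such) plus a Poisson number of blink duplicates
with their own spread. Emissions falling outside the ROI are re-drawn so
density remains count/area. All randomness flows from one seeded
generator per call; identical configuration and seed give bit-identical
output.

What passing tests show: with no noise and well-separated complexes the
census recovers the configured composition exactly, and with 5 nm error
and 300 nm center separation it still does. What they do not show: real
membranes have receptor density gradients, drift residuals, variable
labeling efficiency and dye photophysics far richer than a Poisson blink
count; recovery rates on this generator are upper bounds, not estimates,
for real data.

## 3. Docking pose topology

Poses are rigid transforms (proper rotation + translation, Angstrom) of a
probe protomer docked against a fixed target kept in its membrane frame
(z axis = membrane normal, membrane center at z = 0), each carrying a
docking score.

**Topology filter.** The best 4000 solutions by score are retained
(ties broken by pose id), then poses are discarded whose tilt —
`acos` of the (3,3) element of the rotation, i.e. the angle between the
rotated z axis and the membrane normal — exceeds 0.4 rad, or whose
z-offset — displacement of the probe Calpha geometric center along z —
exceeds 6.0 A in absolute value. The threshold on |z| rather than signed
z is our reading; a signed threshold would pass arbitrarily deep
insertions on one side. The filter is exact arithmetic on the transform,
so the simulator (which constructs rotations as a spin about z composed
with a tilt about a random in-plane axis, and solves the translation's z
component for the target offset) can label every pose with its true
tilt/z-offset, and the test demands the filtered set equal the labelled
set exactly.

**Clustering.** Survivors are grouped by greedy leader clustering under a
3-A Calpha RMSD cutoff: the best-scored unclustered pose becomes a
center and absorbs everything within the cutoff. RMSD is computed on
transformed probe Calpha coordinates *without* re-superposition — the
target fixes the frame, so pose differences are physical displacements
and a pure translation by d has RMSD exactly d. The published procedure
follows clustering with visual inspection of centers; that step is
inherently manual, so the artifact instead reports centers ranked by
score with their cluster sizes.

**Contacts, arrestin filter, indices, clashes.** Interface contacts list
residue pairs whose minimum heavy-atom distance is at most 4.5 A (the
cutoff is ours; the value is conventional for heavy-atom contacts, and
configurable). Receptor-arrestin poses are filtered on the Calpha
distance between the receptor's conserved DRY arginine (residue 132) and
the arrestin finger-loop anchor (residue 71); the rule is published
without a numeric cutoff, so the default of 12 A — wide enough to admit
finger-loop engagement geometries — is prominently configurable and
attached to every retained pose. The orientation of a docked arrestin is
summarized by a Tilt index (angle between the arrestin's dominant
Calpha principal component, sign-fixed towards the N-domain centroid,
and the membrane normal) and a Rot index (signed angle about +z between
the xy-projections of that axis and of the receptor reference vector,
anchor residue 132 towards the receptor centroid). These conventions make
values self-consistent across poses within this package; they are one
explicit operationalization of the indices used in the structural
literature and are not guaranteed to match other implementations
numerically. Stoichiometry clash checks count heavy-atom pairs strictly
closer than 2.5 A between effector copies (and copies vs the receptor
dimer); more than 10 such pairs marks an arrangement as clashing. Both
numbers are configurable — published clash analyses are qualitative.
Hydrogens are ignored in every distance operation.

## 4. BRET quantification

**Net BRET.** Per cycle, the acceptor/donor emission ratio (535/475 nm);
per condition, the cycle mean minus the mean ratio of the donor-only
control. Net acceptor expression subtracts the donor-only acceptor
fluorescence analogously. Rows with non-positive donor emission are
rejected and counted.

**Saturation.** One-site-specific binding, `y = BRETmax * x /
(BRET50 + x)` with x the net acceptor/donor expression ratio, fitted by
bounded Levenberg-Marquardt least squares (non-negative parameters;
initialization BRETmax at max(y), BRET50 at the x nearest half-max;
parameter tolerance 1e-8, at most 1000 iterations). BRETmax reports
protomer proximity, BRET50 protomer-protomer affinity.

**Kinetics.** Ligand-induced traces (post-agonist ratio minus mean basal
ratio, optionally vehicle-subtracted) are fitted to one-phase
association `y = plateau * (1 - exp(-k t))` with the intercept fixed at
0 — the subtraction construction forces the curve through the origin; a
free-intercept variant exists for raw ratios. Halftime `ln(2)/k`, span
`plateau - y0` and initial rate `k * span` are computed exactly from the
fitted parameters, never re-estimated, so the identities hold to machine
precision by construction. Fits on fewer than 8 points, or traces
spanning less than two fitted halftimes, warn.

**Dose-response and bias.** `y = baseline + (Emax - baseline) /
(1 + EC50/conc)`, EC50 fitted on the log10 scale, Hill slope fixed at 1
by default since the published analysis does not state a slope model; a
variable-slope flag exists. Potency is reported as -log10 EC50. The
per-pathway bias factor is Emax/EC50, compared across conditions as fold
change versus a designated reference; it is defined only for converged
fits. When several biological replicates exist the intended averaging
order is fit-per-replicate, then summarize — matching how kinetic tables
are usually presented — though pooled fits are possible by
concatenation.

## 5. Pipeline, seeds and problem sizes

`run_pipeline()` ties the stages together from a JSON configuration
(shipped demo: `inst/extdata/demo_run.json`), validating every block
before execution and reporting all violations, not just the first. A
single global seed fans out to per-stage child seeds via `stage_seed()`
(a Lehmer step on the seed plus a position-weighted hash of the stage
name, modulo 2^31 - 1), so any stage can be re-run in isolation with the
stream it would see in the full run. Identical configuration and seed
give byte-identical data outputs; the report echoes the configuration
and records package and R versions.

Simulation sizes used throughout the tests and the analysis scripts were
chosen to make the statistical checks decisive at desk scale: 1000-pose
sets for the topology filter (expected acceptance 25% under uniform
tilt/z sampling), 1000 random point sets of up to 12 points for the
assignment oracles, 100-seed recovery studies for the curve fits
(kinetics: k 0.02 /s, plateau 0.05, 3 s sampling over 300 s, noise sd
0.002; saturation: BRETmax 0.3, BRET50 0.05, 12 titration points, noise
sd 0.01 — all at the scale of typical published fits), and 7 x 7 um
maps of 180-400 localizations. The biological percentages and potencies
measured on cells are properties of those cells; nothing at desk scale
reproduces them, and the package makes no attempt to — its claims are
about the correctness of the procedures.

## 6. Known limitations

- The census has no drift correction, frame linking or edge correction,
  and no spatial statistics beyond the fixed-radius rule (no Ripley/L(r)
  analysis).
- Blink modelling is a Poisson count with Gaussian spread; real dye
  photophysics (long dark states, bursts) is richer, so dedup
  performance on real data must be validated against controls.
- The pose stage post-processes transforms; it does not dock, score,
  minimize or estimate affinities.
- Tilt/Rot index values are convention-dependent; compare only within a
  convention.
- Dose-response fits assume a monotone logistic; biphasic curves are out
  of scope.

## Worked example

```{r, eval = FALSE}
library(gpcrdimer)

sim <- simulate_localizations(palm_sim_config(
  c("1" = 50, "2" = 30, "3" = 15, "5" = 5),
  cluster_radius_nm = 10, loc_error_sd_nm = 5, blink_rate = 0,
  min_center_sep_nm = 300, seed = 11))
census(assign_complexes(sim$map), sim$map)

t <- seq(3, 300, by = 3)
fit_kinetics(data.frame(time_s = t,
                        y = 0.05012 * (1 - exp(-1.999e-2 * t))))
```

The numbered scripts under `analysis/` run the full workflow
(simulation, census, pose filtering/clustering, BRET fits, end-to-end
pipeline) and write their tables under `results/`.
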