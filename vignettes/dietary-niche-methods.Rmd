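---
title: "Methods: scat-based dietary niche analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scat-based dietary niche analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatdiet)
```

## The problem

Sympatric apex predators — here the snow leopard (*Panthera uncia*) and the
Himalayan wolf (*Canis lupus chanco*) in the Nepalese trans-Himalaya — may
compete for prey, and both may depredate livestock. Scat (fecal) samples
identify what each predator ate: prey remains (mainly hair) in each scat are
assigned to species, giving a per-scat set of prey. From these sets the
package computes diet profiles, interspecific dietary overlap, niche
breadth with uncertainty, and prey selection relative to availability.

## Data model

The sampling unit is the **scat**. A prey species contributes at most one
occurrence per scat (presence/absence): hair abundance within a scat is an
artifact of slide subsampling, not of intake, so within-scat multiplicity
carries no signal. A dataset is a long-format table, one row per
(scat, prey item); occurrences within a scat are dependent, which drives
two later choices (cluster bootstrap, scat-level permutation).

The packaged reference table (`load_reference_diet()`) carries the
published per-predator relative frequency of occurrence (FO, %) and
relative biomass (RB, %) for 11 prey species. The mountain weasel was never
found in wolf scats; its wolf cells are structural zeros, not missing data,
so wolf tables carry 10 entries and the species enters joint statistics as
a zero proportion.

## Diet profiles

For predator $j$, the relative frequency of occurrence of prey $i$ is

$$\mathrm{RFO}_{ij} = \frac{O_{ij}}{\sum_k O_{kj}},$$

with $O_{ij}$ the number of scats of predator $j$ containing prey $i$. The
denominator is the total number of prey-item occurrences (the summed
per-scat richness), not the number of scats, so RFO sums to 1 across prey.

Occurrence frequencies overestimate small prey (more hairs per unit body
mass). Feeding-trial regressions convert one scat's worth of prey into
kilograms consumed, $Y = a + bX$ with $X$ the prey's mean body mass (kg):
$Y = 1.980 + 0.035X$ (felid trials) for the snow leopard and
$Y = 0.439 + 0.008X$ (wolf trials) for the wolf. Relative biomass is

$$\mathrm{RB}_i = 100 \cdot \frac{\mathrm{FO}_i Y_i}{\sum_j \mathrm{FO}_j Y_j},$$

which is invariant to rescaling FO (counts and percent columns give the
same answer) and collapses to RFO when all $Y_i$ are equal. Mean prey
masses were not published for the reference study; the package ships an
explicitly synthetic, editable mass table
(`inst/extdata/prey_masses_synthetic.csv`) with a provenance column and
treats masses strictly as user input. The published RB columns are
therefore fixture data, used as-is, never "re-derived" from invented
masses.

## Overlap and breadth

Pianka's dietary overlap between predators $j$ and $k$ is

$$DO = \frac{\sum_i P_{ij} P_{ik}}
           {\sqrt{\sum_i P_{ij}^2 \, \sum_i P_{ik}^2}},$$

the cosine similarity of the two proportion vectors over the union of prey
(0 = disjoint diets, 1 = identical). The headline overlap is computed on
the relative-biomass basis, which reproduces the published 0.937; the RFO
basis gives 0.863 and is always reported alongside, with the basis an
explicit parameter.

Levins niche breadth is the unstandardized $B = 1/\sum_i p_i^2$, ranging
from 1 (specialist) to $k$ (uniform use of $k$ prey). This form reproduces
the published 6.45 (snow leopard) and 5.98 (wolf) from the FO columns; the
standardized $B_A = (B-1)/(k-1)$ is available as an option.

**Uncertainty.** Confidence intervals for $B$ use a cluster bootstrap:
whole scats are resampled with replacement (10,000 replicates by default)
and $B$ recomputed from each replicate's RFO profile; the interval is the
percentile interval. The scat is the resampling unit because occurrences
within a scat are dependent. The interspecific breadth difference
$|B_a - B_b|$ is tested by pooling all scats and permuting predator labels
with group sizes fixed (9,999 permutations by default), with the add-one
convention $p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$ so $p$ is never 0.
The published interval endpoints and $p = 0.923$ are **not** reproduction
targets: they depend on unpublished scat-level data and an unstated
resampling scheme (the published intervals are far wider than a scat-level
cluster bootstrap produces).

## Use versus availability

With availability proportions $\pi_i$ (census-style, treated as known) and
$n$ total occurrences, the G-test of proportional use is

$$G = 2 \sum_{i: O_i > 0} O_i \ln\!\frac{O_i}{n \pi_i},
  \qquad df = k - 1,$$

with the p-value from the upper $\chi^2$ tail. Selection ratios follow the
Manly design-I form: $w_i = o_i/\pi_i$ with $o_i = O_i/n$,
$se(w_i) = \sqrt{o_i(1-o_i)/(n\pi_i^2)}$, and simultaneous Bonferroni
intervals $w_i \pm z_{1-\alpha/(2k)}\,se(w_i)$, truncated below at 0.
Classification: preference when the lower limit exceeds 1, avoidance when
the upper limit is below 1, otherwise neutral; lowering $\alpha$ can only
widen intervals, so it never creates new preference/avoidance calls. Prey
with zero observed use get $w = 0$ with a degenerate $[0,0]$ interval and
an explicit warning rather than an ad-hoc continuity correction. The
published G statistics (88.62, 32.91) are not reproducible because the
availability counts behind them were never printed; the package instead
validates this stage against its closed form and by simulation (below).

## Sample sufficiency

The reference study asserts (without stating a method) that sample sizes
sufficed. The package implements the field-standard randomized
accumulation curve: mean cumulative prey richness over random scat
orderings, which is monotone, bounded by the registry size, and plateaus
when further scats stop adding species. This choice cannot be verified
against the study's own (unpublished) sufficiency analysis.

## The synthetic world

`default_generator_config()` states the study conditions as a stochastic
world: 98 snow-leopard and 54 wolf scats; per-scat richness distributions
(0.54, 0.42, 0.04) over 1–3 prey and (0.5374, 0.37, 0.0741, 0.0185) over
1–4 prey (the published wolf percentages sum to 100.26 from rounding; the
one-item mass is set to one minus the rest); true diets equal to the
reference FO columns, normalized. Per scat, richness $k$ is drawn first,
then $k$ *distinct* prey sequentially without replacement with
probabilities proportional to the diet — a scat cannot contain a species
twice, matching the presence/absence unit.

Two defaults are free parameters the study never published, fixed once:

* **Availability weights** (π): a plausible census mix for the study
  area — livestock herds and small mammals abundant, mustelids scarce
  (goat 0.25, blue sheep / marmot / pika 0.15 each, sheep 0.10, yak 0.05,
  least weasel 0.04, horse / mountain weasel / stone marten 0.03, dog
  0.02). Total availability defaults to 1,000 sightings.
* **Seeding**: one seed per configuration; every draw flows from it, so
  identical seeds give byte-identical datasets.

**What the generator does not emulate:** spatial transect structure, scat
detection/decay, prey misidentification, and seasonal diet shifts. A green
test therefore establishes statistical correctness of the estimators under
the stated sampling model, not robustness to field artifacts.

**A known distortion, kept deliberately.** Sequential without-replacement
draws within multi-prey scats flatten the occurrence distribution relative
to the nominal diet (dominant prey are slightly under-represented:
asymptotic max absolute RFO deviation ≈ 0.011 at the default
configuration; asymptotic Levins 6.65 against the nominal 6.45). This is a
property of presence/absence sampling itself, not a bug, so parameter
recovery is asserted with this distortion included. Calibration studies
that need an exactly identified estimand (bootstrap coverage) use a
single-prey-per-scat world, where the RFO estimator is exactly multinomial
and the nominal diet's Levins is the estimator's own population value.

## Numerical and testing choices

* Probability-vector validation at $10^{-9}$; reported tables rounded to
  2 dp, full precision kept internally.
* The G-test type-I calibration draws use from availability itself at
  $n = 147$ occurrences in a world with all expected counts
  $\ge 5$ (uniform availability), the regime in which the $\chi^2$
  reference for G is claimed. With rare categories (expected counts
  below ~5, as under the default availability weights) G is known to be
  anti-conservative (measured ≈6% at nominal 5%); the package does not
  hide this, it simply does not claim calibration there.
* Simulation harnesses draw per-dataset seeds from a single master stream
  rather than consecutive integers.
* Permutation and bootstrap computations are vectorized (multinomial
  weight matrices and one `crossprod` per batch), keeping the full
  acceptance suite under half a minute on one CPU.

## Limitations

* Morphological scat identification, micro-histology, and genetic
  confirmation are upstream of this package and out of scope.
* The published bootstrap interval endpoints, breadth-difference p-value,
  G statistics, and numeric selection ratios are unreproducible in
  principle from the published summaries alone; the package reproduces the
  five desk-scale headline statistics exactly and validates everything
  else by oracle equivalence and simulation.
* Percentile bootstrap intervals for Levins breadth undercover mildly at
  moderate sample sizes (≈94% at $n = 500$ single-prey scats against a
  nominal 95%), consistent with the plug-in estimator's small negative
  bias.
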