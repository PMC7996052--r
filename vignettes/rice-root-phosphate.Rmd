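---
title: "Simulating the upland-rice root system and its phosphate economy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the upland-rice root system and its phosphate economy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rhizoP simulates the root system of the phosphorus-efficient upland rice
genotype DJ123 in three dimensions, attaches explicit root-hair cohorts to
every root segment, computes phosphate uptake with a radial
advection--diffusion--reaction solver, and evaluates the phosphorus economy
of each root class.  This vignette explains the model, its assumptions, the
parameters that matter, and the numerical and design choices behind the
implementation.

## The root architecture model

Six root classes are simulated: the primary root, three nodal (crown) root
classes -- branched, fast-elongating, and tiller-borne -- and two lateral
classes, the larger L-type and the rice-specific short S-type.  The system
is a growing set of axes; each axis carries a tip position and a unit
heading, and lays fixed segments behind the tip as it elongates
(`grow_root_system()`, `advance()`).

**Elongation.**  Every class has a peak elongation rate and a maximum length
(for DJ123: 2.19/46 for the primary, 1.46/35 and 2.14/45 cm for branched and
fast nodal roots, 0.73/14.6 for L-types, 0.14/1.08 cm day^-1^/cm for
S-types).  Rates ramp up over the first two days of axis age (power-law
emergence ramp, exponent 0.15), reaching the peak at day 2.  Main axes then
hold the peak until they saturate at their maximum length; the published
2.14 cm day^-1^ for fast nodal roots is the 45 cm maximum length divided by
an estimated 21-day age, and with this curve a fast nodal axis accumulates
44.4 cm in 21 days (within 1.5% of 45 cm).  Any curve bounded by that peak
cannot reach 45.0 cm exactly in 21 days (45/2.14 = 21.03 d), which is why
the ramp is deliberately short and the plateau long.  Lateral classes
instead decline exponentially after the ramp, with the time constant solved
so that the lifetime growth integral equals the class maximum length; this
makes a "length" perturbation (see sensitivity below) stretch the decline
phase while leaving the peak rate untouched.  Each axis draws a lognormal
growth multiplier (median 1, sigma 0.3, truncated to [0.25, 2.5]) scaling
both its rate and its maximum length, so final lateral lengths vary.

**Branching.**  Lateral primordia are placed by inter-branching distances
(IBD) drawn per parent/child class pair from truncated normal distributions;
faster-growing parents therefore branch more per unit time.  Fast nodal
roots double their sampled IBD during the first two weeks of system
development and branch more sparsely away from the base afterwards.  Laterals
emerge perpendicular to the parent at a uniformly random radial angle; the
`cannotgrowup` rule flattens any upward-pointing lateral heading to
horizontal, which on its own reproduces the observed preference of L-types
for the lower flank of shallow nodal roots.

**Emergence and tropism.**  Nodal roots emerge from the hypocotyl at a rapid
rate until day 13 and half a root per day thereafter, which makes the
cumulative count concave as observed; the fast class appears only after day
10 and its share grows as the system matures.  Tillers (days 12, 16, 20 by
default; the source data give no tillering schedule) each start a slow
nodal stream.  Nodal growth angles are drawn from a scaled Beta(1.25, 2)
distribution on 8--90 degrees from the soil surface, giving a mode near 24
degrees and 62% of angles at or below 45 degrees, as measured in the field.
Headings evolve by gravitropism (strong for the primary root, -0.065 cm/cm
of the printed -0.115 to -0.015 range; negligible -0.0001 for crown roots)
plus a bounded random impedance perturbation; depth is positive downward
and no axis grows above the soil surface.

**Calibrated quantities.**  The IBD distributions, growth-multiplier spread,
and nodal emission rates come from unavailable source tables, so their
defaults were calibrated once against the published day-31 architecture:
total root length 60--70 m with class length shares of roughly 51% S-type,
32% L-type and 16% nodal+primary, and hair-length shares of 29% (S-type)
and 36% (L-type).  They are labelled calibrated in the config export and
were frozen after calibration.

## Root hairs

Hairs are explicit cylinder cohorts: every segment carries
`density(age) * length` hairs of class-specific length (0.02 cm primary,
0.015 nodal/L-type, 0.012 cm S-type) and 5 um diameter.  Density starts at
the class ceiling (1,400 hairs cm^-1^ on main axes, 700 on L-types, 400 on
S-types) and declines linearly with host age following the published
reference decline (full density on a 3-day-old root to 55% on a 40-day-old
root, i.e. -1.216% of the age-3 value per day), the same relative shape for
every class.  Cohort totals (count x identical cylinder) are exact because
all hairs of a cohort share geometry.  Setting densities to zero reproduces
the bald-root system exactly.

## Phosphate uptake

Each root cohort owns a radial soil domain from its surface radius r~0~ to
an outer no-flux radius r~1~, governed by the buffered cylindrical
diffusion--advection equation

$$ b \frac{\partial C}{\partial t} = \frac{1}{r} \frac{\partial}{\partial r}
   \left( r\, b\, D_e \frac{\partial C}{\partial r} + r\, v(r)\, C \right),
   \qquad v(r) = v_0 r_0 / r , $$

with Michaelis--Menten influx
$I_{max}(C - C_{min})/(K_m + C - C_{min})$ at r~0~ and zero flux (or a fixed
concentration, for verification) at r~1~.  The soil constants are the
measured buffer power b = 6,000 and effective diffusivity
D~e~ = 9.227x10^-6^ cm^2^ day^-1^; v~0~ defaults to 0 (no transpiration is
modelled).  Dividing by b gives a conservation law for the solution
concentration; b re-enters through the boundary sink and the mass
accounting.

**Discretization.**  Finite volumes on logarithmically spaced nodes (25 by
default, dense near the root where the depletion length
$\sqrt{D_e t} \approx 0.016$ cm at 28 days must be resolved), implicit Euler
in time (maximum step 0.2 days), and Newton iteration on the nonlinear
boundary flux to an absolute tolerance of 10^-10^ on the surface
concentration.  The scheme is discretely conservative: for every domain the
soil P lost equals the cumulative flux through r~0~ to the Newton tolerance
(observed ~10^-14^ relative), and the transient solution was verified
against an independent uniform-grid method-of-lines reference and against
the closed-form steady cylindrical solution with a linear (Robin) boundary
to within 0.5%.

**Cohorts and outer radii.**  Segments of equal class, birth day and outer
radius share one domain, because the soil is homogeneous; this pools roughly
10^5^ segments into a few hundred domains and makes all members of a cohort
exactly exchangeable.  All segments of a cohort are treated as born at the
cohort's length-weighted mean birth time (at 1-day cohort width this
misplaces a segment by at most half a day and keeps the global mass balance
exact).  The outer radius is half the local mean inter-root distance,
estimated from the root-length density accumulated in the segment's 1 cm^3^
voxel at its birth (floored at 0.2 cm, capped at 2 cm and quantized to
seven bins).  Hairs draw from independent domains with r~0~ equal to the
hair radius and r~1~ the half mean spacing between hairs inside the hair
shell at ceiling density (~0.006--0.009 cm, so neighbouring hairs compete).
A hair does not compete with its own host surface; this independent-domain
design overestimates the hair contribution -- in the calibrated runs hairs
take roughly 45% of the total uptake, against about 16% reported for the
original model -- and is quantified rather than hidden (the depletion-zone
overlap diagnostic reports the length fraction of intersecting zones,
about 0.1 at day 21).

**Calibration.**  The measured soil solution concentration (83 nM)
underestimates measured plant P several-fold, so -- as in the source study
-- the working concentration is 540 nM.  The Michaelis--Menten constants
are not public; defaults are rice-literature
placeholders (I~max~ = 0.0864 umol cm^-2^ day^-1^, K~m~ = 5.8x10^-3^
umol mL^-1^, C~min~ = 10^-5^ umol mL^-1^) and `calibrate_imax()` adjusts the
single I~max~ scalar (monotone, log-space secant) so that day-31 plant P
matches the measured 774.3 ug; the calibrated value is ~0.4 umol cm^-2^
day^-1^.  Plant P content is cumulative influx times the molar mass of P
(30.97 ug umol^-1^); simulation day 31 corresponds to 28 days after
emergence.

## Cost--benefit analysis

Root weight uses the cost-analysis tissue densities 0.06 (nodal and
primary), 0.07 (L-type) and 0.1 g cm^-3^ (S-type and hairs); the growth
section of the source implies an alternative 0.08/0.09/0.1 set, noted in
the config comments.  Cost is weight times the tissue P concentration of
0.8 ug P per mg root; efficiencies and benefit-to-cost ratios are exact
quotients of each ledger row.  The primary root is folded into the nodal
row.  Three cost-recovery scenarios are provided: Case 1 divides class cost
by the class's current daily uptake (both static at day 31); Cases 2 and 3
simulate a continuously growing single-class system -- one axis elongating
along its class curve and re-initiating at its maximum length, placed in
otherwise root-free soil -- with and without hairs, and report the first day
cumulative uptake covers cumulative construction cost.  The single-axis
construction is a deliberate, config-exposed choice; the source does not
specify how its hypothetical single-class systems were built.

A known, quantified discrepancy: the published per-class table prints a
nodal weight (399.9 mg for 10.8 m of root at <= 0.065 cm diameter) that is
not reproducible from any stated diameter/density combination -- it implies
either ~0.11 g cm^-3^ or a 0.089 cm diameter.  At the stated values the
nodal cost is ~0.16 ug P per cm, about half the printed table's implicit
0.30 ug cm^-1^, and at that cost a hairless nodal-only system in this model
recovers its cost around day 12--15 instead of "never".  The ledger
implements the stated formulas and reports what follows from them; it does
not tune weights to reproduce the printed table.

## Sensitivity analysis

`run_scan()` perturbs two soil parameters (solution concentration; buffer
power with D~e~ rescaled to hold D~e~b constant) and six root parameters
(L-/S-type length and IBD, hair length and density) by factor levels 0.25 to
4, with replicate seeds shared across parameters and levels (paired design).
"Length" factors scale the class maximum length and peak rate jointly, so
the achieved root length at every age -- and the lifetime growth integral --
scale exactly by the factor; IBD factors scale mean, sd and truncation
bounds; hair factors scale the trait on every class.  Responses are reported
as percent of the mean baseline.  The joint scaling was a deliberate design
revision: under the published peak rates laterals need about 20 days to
complete their growth, so scaling the maximum length alone (with a
stretched decline phase) changes the *realized* day-31 lengths by only a
few percent and cannot reproduce the observed sensitivity structure; with
joint scaling the scan reproduces it closely -- soil P strictly monotone
and near-linear (x4 gives ~396% of baseline), hair length dominating hair
density (x4: ~260% vs ~146%), L-type length the most influential root
parameter (x4: ~216%, helped by the knock-on S-types that longer L-types
carry) ahead of S-type length (~166%), and all responses weaker to
proportional decreases than to increases.

## What the generator does and does not emulate

The synthetic architecture reproduces the statistical structure the model
assumes: truncated-normal IBDs, truncated-lognormal growth multipliers, the
measured growth-angle distribution, the age-declining hair density, and the
piecewise nodal emission schedule.  It does not emulate soil mechanical
heterogeneity, senescence, carbon limitation, mycorrhizal uptake, root
exudation or P solubilization (the 540 nM working concentration stands in
for the latter), nor container effects; passing tests therefore demonstrate
internal consistency with the published architecture summaries, not
field-level prediction.

## Problem sizes and tolerances used by the test suite

The test suite grows day-31 systems (~4,000--10,000 axes, ~10^5^ segments,
~3 s each), solves uptake on 25 radial nodes at 0.2-day steps (~1.5 s), and
runs the reduced sensitivity scan at 15 radial nodes with 3 replicates.
Mass-balance assertions use 10^-6^ relative tolerance (observed ~10^-14^);
oracle comparisons use 0.5%; stochastic envelopes use the spreads stated in
the tests.  Seeds are fixed wherever randomness is involved; identical seeds
give bit-identical runs.

## Known limitations

Hair uptake is overestimated by the independent-domain design (above);
inter-root competition acts only through voxel-local outer radii, not
through shared domains; hair cost ignores the density decline (hairs are
not refunded); segment geometry within a time step is straight; and the
economics ledger inherits every published-value inconsistency it refuses to
tune away (nodal weight, the 6.9x hair/root length ratio -- this model's
ratio is ~8.7 and the report prints it).
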