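---
title: "Phytomer-based 3D canopy photosynthesis and the decomposition of heterosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phytomer-based 3D canopy photosynthesis and the decomposition of heterosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

A maize hybrid out-yields its parental inbreds through two distinct
routes: a larger, differently arranged canopy that captures more
photosynthetically active radiation (PAR), and leaves that fix more
carbon per photon. Field measurements entangle the two. This package
separates them *in silico*: it builds three-dimensional canopies from
per-phytomer morphological descriptors, computes facet-level PAR
interception hour by hour, integrates leaf photosynthesis to canopy
biomass over a fixed 60-day post-silking window, and then re-runs the
simulation with the hybrid's canopy structure and its parents'
photosynthetic parameters swapped in all combinations. The relative
change in simulated yield (accumulated above-ground biomass, Mg ha^-1^)
and radiation use efficiency (RUE, g MJ^-1^) attributes the
hybrid-parent gap to structure and to photosynthesis.

The seven scenarios combine the hybrid JNK728 with its male parent
J2416 and female parent JMC01: the three pure cultivars, A1/A2
(parental structure, hybrid photosynthesis) and B1/B2 (hybrid
structure, parental photosynthesis). With $Y$ either yield or RUE, the
structure and photosynthesis contributions against, e.g., the male
parent are

$$C_{c,J2416} = \frac{Y_{JNK728} - Y_{A1}}{Y_{JNK728} - Y_{J2416}} \times 100,
\qquad
C_{p,J2416} = \frac{Y_{JNK728} - Y_{B1}}{Y_{JNK728} - Y_{J2416}} \times 100.$$

The two need not sum to 100; the package additionally reports the
residual $100 - C_c - C_p$ as an interaction term (an extension beyond
the standard decomposition, labelled as such in the output).

## Plant and canopy geometry

Each leaf is reduced to the descriptors of its midrib: length `LL`
(cm), collar height `HLBase`, the rises of the highest midrib point
(`HDBTop`) and of the tip (`HDBTip`, negative for tips drooping below
the collar), and the horizontal projections from the collar to the
highest point (`Ltop`) and to the tip (`Ltip`). `build_midrib()` fits a
planar cubic Bezier in the leaf's vertical azimuth plane whose control
parameters (including the collar-arm length and a softly regularized
collar tangent angle) are solved by weighted Levenberg-Marquardt. The
arc length and the two rises form the heavily weighted tier and are met
to within 0.5% of `LL`; the two horizontal projections form the
least-squares tier, met to within 2% for feasible descriptor sets. The
tiering matters because descriptor sets can be mutually infeasible —
whenever the collar-to-top-to-tip path length exceeds `LL`, no curve
can satisfy all five values, and the solver then resolves the conflict
in favour of arc length and rises.

The blade is a ruled surface around the midrib with a beta-shaped width
profile peaking at 30% of the midrib length (maize blades widen
quickly and taper long; the field study reports no width profile, so
this is a package choice). Tessellation is area-preserving: ring widths
are rescaled so that the triangle mesh area equals the analytic blade
area $\text{LL} \cdot w_{\max} \int_0^1 f(s)\,ds$ at any segment count,
removing the chord-versus-arc deficit that otherwise makes coarse
meshes systematically small.

`assemble_canopy()` replicates plants on a row grid (0.6 m rows,
within-row spacing $1/(\text{PD} \cdot 0.6)$ for plant density PD = 6
plants m^-2^), assigns distichous leaf azimuths (alternating sides of
the row with seeded +-15 degree jitter), and registers an opaque
virtual wall around the stand footprint at 60% of plant height, which
emulates the optical closure of a surrounding field. Interception
records are collected over a central focal block of interior plants.

## Radiation

Solar position uses standard declination (Spencer series) and
hour-angle astronomy on local solar time. Each daylight integer hour
from ceiling(sunrise) to floor(sunset) is simulated.

A facet is *sunlit* when it faces the beam (its normal makes more than
90 degrees with the sun-to-ground ray direction) **and** the ray from
its centroid to the sun is unobstructed by other facets or the wall.
Orientation alone would count beam-shaded facets as sunlit; the
occlusion-aware definition is the default, and the orientation-only
variant remains available via `occlusion_aware = FALSE`. Sunlit facets
receive $(I_{dir}/\cos\theta_z)\,|\cos(\mathbf{n},\mathbf{s})|$; shaded
facets receive no direct light (black-leaf, single-interception — no
scattering, no penumbra).

The production occlusion algorithm projects all triangles
orthographically along the beam, bins them into a uniform 2D grid, and
tests each focal facet's centroid ray exactly (Moller-Trumbore) against
the candidates in its cell. It therefore makes *identical* decisions to
the brute-force all-pairs oracle while scaling linearly, and the test
suite asserts flag-for-flag equality on random scenes. A rasterized
depth buffer was considered and rejected: pixel quantization cannot
guarantee that exact agreement.

Diffuse sky radiation uses an equal-solid-angle hemisphere
discretization (46 sectors by default, Fibonacci layout) under a
uniform-radiance sky, each sector treated as a directional source with
weight proportional to the cosine of its zenith angle. Sector
visibility is independent of time of day, so the per-facet diffuse
factor is computed once per canopy and reused across all hours of a
season. The incident direct/diffuse split is an input; the weather
generator offers a constant fraction (default 0.2, a clear-sky value)
or a Spitters-type clearness-index partition.

Energy conservation is asserted against the beam power through the
beam-projected bounding box of the scene. The naive "incident PAR times
ground footprint" bound holds only when all light enters from above; at
low sun the beam tube also enters the small simulated stands laterally
above the wall, and measured interception exceeds the naive bound by up
to 15% while staying well under the rigorous one (`beam_power_bound()`).

## Leaf photosynthesis

Net photosynthesis follows Ye's light-response model

$$A(Q) = \alpha\,\frac{1 - \beta Q}{1 + \gamma Q}\,Q - R_d,$$

with initial slope $\alpha$, photoinhibition $\beta$, saturation
$\gamma$ and dark respiration $R_d$. Its maximum has the closed form
$A_{\max} = \alpha\left(\frac{\sqrt{\beta + \gamma} -
\sqrt{\beta}}{\gamma}\right)^2 - R_d$, verified in the tests against
grid-search maximization. `fit_light_response()` estimates the four
parameters by bounded Levenberg-Marquardt least squares from eight
start points, with physiological bounds ($\alpha \le 0.15$,
$\beta \le 10^{-2}$, $\gamma \le 0.1$, $R_d \le 10$).

Published parameter tables print only ($\alpha$, $A_{\max}$, $R_d$) per
cultivar and canopy layer; `solve_beta_gamma()` completes them by
fixing a small $\beta$ (default $5\times10^{-5}$) and inverting the
closed form for $\gamma$. The three measured layers (third leaf above
the ear, ear leaf, third below) are mapped onto ranks as upper (ranks
above ear+1), middle (ear +-1) and lower (below ear-1), with no
within-layer heterogeneity — the only join consistent with both the
measurement protocol and the canopy layering.

## Canopy integration

Per leaf and hour, intercepted photons `IPP` (umol leaf^-1^ h^-1^)
convert back to a leaf-level PPFD as $\text{IPP}/3600/(\text{LA}\cdot
10^{-4})$; the Ye model evaluated at that PPFD, summed over leaves and
focal plants and divided by the focal ground area $M/\text{PD}$, gives
the instantaneous canopy rate. Daily assimilation integrates hourly
values times 3600 s; biomass applies the CO~2~ molar mass and a fixed
CO~2~-to-dry-mass efficiency, $DM = 44 \cdot (A_{canDAY} \cdot 10^{-6})
\cdot 0.41$ g m^-2^ d^-1^ (the explicit umol-to-mol factor keeps the
chain dimensionally consistent); intercepted energy divides photons by
4.55 umol J^-1^. Accumulated biomass and interception over exactly 60
post-silking days give yield ($ADM \times 10^{-2}$ Mg ha^-1^) and RUE
($ADM/AIPAR$). The canopy snapshot is static over the window — leaf
senescence and stay-green dynamics are deliberately outside scope.

Because radiation depends only on canopy structure,
`run_all_scenarios()` computes interception once per distinct structure
source and reuses it across the scenarios sharing it. Two identities
then hold bitwise and are tested: a trait self-swap reproduces the pure
cultivar, and swapping only photosynthesis leaves AIPAR unchanged.

## The synthetic generator as study conditions

No digitized canopies are distributed with the study, so the generator
stands in for them. Its defaults are the study conditions: 19 phytomers
per plant; ear at rank 13 (hybrid, male parent) or 12 (female parent);
plant heights 266.37 / 187.50 / 251.68 cm; ear heights 106.85 / 74.29 /
67.42 cm; one-sided leaf areas 0.72 / 0.46 / 0.58 m^2^; leaf
inclination ~66 degrees; rank profiles of `HDBTop` peaking at rank 14
(67.68 / 60.43 / 74.96 cm) and the reported `Ltop`/`Ltip` peak
value-rank pairs. Descriptors follow scaled-beta unimodal curves
through those peaks; collar heights follow a power curve anchored at
the ear height. Leaf-length peaks and tip rises are reported only
graphically in the study, so they are package choices consistent with
the stated peaks; where the raw curves would make a leaf's highest
point unreachable within its length, the repair pass *raises leaf
length* to the collar-top-tip path length rather than moving the
quantitatively anchored peaks, and per-rank maximum widths are then
back-solved so the 19-leaf area sum hits the cultivar target.

A-Q observations are Ye-model evaluations at the 12 chamber PPFD set
points (2000 down to 0 umol m^-2^ s^-1^) plus Gaussian noise; recovery
statistics are quoted for fits to three replicate curves, matching the
three replicate field plots of the protocol. Weather is a sinusoidal
diurnal PAR course truncated at sunrise/sunset with a 2000 umol m^-2^
s^-1^ clear-day noon peak, optional lognormal day-to-day cloudiness,
and a configurable diffuse split.

What the generator does **not** emulate: measured leaf-length curves
rank by rank (only the in-text peaks are anchored), organ growth and
the 2-day digitization cadence, senescence, row-orientation effects,
and the study site's actual cloudy-season radiation. The synthetic
weather is brighter than a Beijing field season, so simulated canopies
sit deeper in light saturation and absolute RUE values (~2.2 g MJ^-1^
on the reduced stand) fall below the published field-scale values
(~4 g MJ^-1^). Passing tests therefore demonstrate the *mechanics* —
interception accounting, the integration chain, orderings among
cultivars, and the exact worked-example arithmetic — not a reproduction
of field magnitudes, which would require the original digitized
canopies and weather records.

## Numerical choices and problem sizes

* Midrib solver: 192-point curve sampling, up to 6 Levenberg-Marquardt
  starts with Nelder-Mead polish and an escalation pass for stubborn
  fits; typical residuals are far inside the 0.5%/2% tiers.
* Occlusion: 5 cm grid cells, ray epsilon 10^-3^ cm (shared by
  production and oracle so their decisions coincide); facet normals are
  oriented upward, and ties in orientation resolve deterministically.
* Tessellation defaults: 8-12 longitudinal segments, 2 width strips;
  area is exact by construction, so the segment count only affects the
  spatial resolution of shading.
* The packaged studies and tests run on reduced stands (3x5 plants with
  one interior focal plant for the season runs; 5x5 plants with the
  3x3 interior focal block for the cultivar-ordering study; 10-60 day
  windows), chosen so the full workflow stays interactive; the geometry,
  radiation and integration code paths are identical at the study's full
  10x15 size.
* Degenerate inputs: chord-equals-arc descriptors produce exact straight
  midribs; zero-light seasons raise an error on the undefined RUE
  quotient rather than returning NaN; a zero hybrid-parent gap flags the
  decomposition as undefined instead of propagating division by zero.

## Worked example

```{r example}
library(maizecanopy)
pub <- published_scenario_values()
contributions(pub$yield_Mg_ha)   # 70/36 vs J2416, 42/74 vs JMC01
contributions(pub$RUE_g_MJ)      # 21/87 vs J2416, 5/116 vs JMC01
heterosis_ratios(pub$RUE_g_MJ[c("JNK728", "J2416", "JMC01")])  # 13%, 17%
```

## Known limitations

Leaf-level PPFD averaging (one PPFD per leaf per hour) smooths the
within-leaf light distribution before the nonlinear light response is
applied; with the concave Ye model this slightly overestimates leaf
photosynthesis relative to facet-level integration. The static canopy,
absent senescence, fixed conversion efficiency, and the black-leaf
(no-scattering) radiation treatment are all deliberate simplifications
inherited from the modelling framework the package implements.
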