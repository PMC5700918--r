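---
title: "Methods: larval dispersal of fall armyworm on Bt cotton"
author: "spodsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: larval dispersal of fall armyworm on Bt cotton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spodsim)
```

## The problem

Neonate larvae of the fall armyworm, *Spodoptera frugiperda*, disperse
between plants within a cotton field. When Bt and non-Bt plants are
interleaved — deliberately as refuge, or accidentally through seed
contamination — this movement shapes how quickly resistance to Bt toxins
evolves. `spodsim` bundles the two computational halves of that question:

1. **Behavioural bioassay statistics.** Host-acceptance bioassays release
   a fixed number of neonates on caged plants and later classify each
   larva by position (on/off the plant) and feeding evidence. The package
   computes the behavioural proportions from such tables, fits the
   survival-over-time logistic regression, runs the Box-Cox factorial
   ANOVA with Tukey–Kramer comparisons, the correlation-matrix PCA with
   Kaiser retention, and the UPGMA clustering of treatments.
2. **A lattice individual-based model (IBM)** of immatures and adult
   females on a Bt/non-Bt landscape, in which the larval dispersal kernel
   depends on the crop of the current cell — the mechanism suggested by
   video-tracking assays in which Cry1F-resistant neonates moved roughly
   three times farther on Bt than on non-Bt cotton.

No raw insect data are distributed; a synthetic generator reproduces the
statistical structure the analyses assume, so the whole pipeline is
testable offline and can ingest real data as tidy CSV of the same shape.

## The synthetic bioassay generator

The generator emulates a randomized-block factorial: 4 blocks × strains
(susceptible SS, Cry1F-resistant RR) × cotton varieties (WideStrike
`BT_WS`, TwinLink `BT_TL`, non-Bt isoline `NONBT`) × exposure intervals
(6, 12, 18, 24 h), with 20 neonates per plant. Each plant's larvae are
assigned to the five mutually exclusive fates — on-plant fed, on-plant
not fed, off-plant fed, off-plant not fed, unrecovered — by a **single
multinomial draw**, which makes the count-conservation identity exact by
construction rather than by bookkeeping.

The category probabilities follow a fate chain:

* recovered alive with probability $s(t) = \mathrm{logit}^{-1}(b_0 + b_1 t)$,
  using the fitted per-strain models as defaults
  ($b_0 = 2.7690$, $b_1 = -0.1470$ for SS; $b_0 = 1.1089$, $b_1 = -0.0483$
  for RR, logit units and logit/h);
* found on the plant with the observed per-strain, per-interval mean
  on-plant percentages as defaults (e.g. 64.83% for SS at 0–6 h);
* fed conditional on position, per strain × variety. These last
  probabilities have no printed source values; the defaults are invented
  and encode only the qualitative pattern (more feeding on than off the
  plant, higher on-plant feeding for RR on Bt, more post-feeding
  dispersal on non-Bt). They are free parameters of
  `bioassay_params()`.

"Unrecovered" absorbs death and escape jointly, because the bioassay
design cannot distinguish them; *survival* throughout the package means
*recovered alive*. The per-interval unrecovered fraction can be set
freely through the `survival_prob` override, which replaces the logistic
model by arbitrary per-interval probabilities.

Video-tracking endpoints (distance moved in cm, mean velocity in cm/s,
continuous mobility period in s) are drawn log-normally around group
means: positive support and right skew are typical of movement data, and
the mean-parameterization makes every group's expected value equal its
nominal mean for any dispersion, with the zero-dispersion limit exactly
deterministic. The default distance means put RR on non-Bt at one third
of RR on Bt (30 vs 90 cm), the key observed contrast; four replicates
per treatment mirrors the tracking design, but `n_per_group` is free.

What the generator does **not** emulate: plant architecture, leaf
position, within-plant movement, time-correlated tracking noise, or any
block-level random effect (blocks differ only by sampling noise).
Passing tests therefore demonstrate correctness of the estimators on
data satisfying the model's assumptions, not robustness to the
violations real assays exhibit.

## Behavioural metrics and their denominators

For each plant, with $R$ released and $r$ recovered alive:

* survival $= r / R$ — always on the released denominator;
* host acceptance $=$ (on-plant recovered)$/r$;
* dispersal rate $=$ (off-plant recovered)$/r$;
* PFD (post-feeding dispersal) $=$ (off-plant fed)$/r$;
* IFP $=$ (on-plant fed)$/r$.

The source assays never state the denominators; recovered-alive is used
because it keeps host acceptance and dispersal complementary (they sum
to 1 whenever $r > 0$) and matches the "percentage of larvae recovered
from the plants" phrasing of such assays. A `denominator_mode` switch
provides the released-based alternative. A plant with $r = 0$ yields
missing metrics, never 0/0.

## Survival regression and ANOVA

Survival counts are overdispersed binomial, so the regression of
recovered-alive/released on exposure time uses a quasi-binomial GLM with
logit link; standard errors are scaled by the method-of-moments
dispersion estimate, and Wald 95% intervals are reported. Complete
separation (infinite or extreme coefficients) is flagged with a warning
rather than silently returned. A half-normal plot of absolute deviance
residuals with a simulated envelope (99 refitted simulations by default)
is returned as coordinates, not a rendered figure.

The proportion metrics go through a Box-Cox transform before the
factorial ANOVA. $\lambda$ is estimated by profile log-likelihood on the
grid $[-2, 2]$ in steps of 0.01 — fine enough that the reported
$\lambda$ is grid-exact while keeping the search instantaneous. Zero
proportions must be lifted by an explicit `offset` (recommended
$0.5/n$ with $n$ the count denominator); the function refuses silently
transforming non-positive data. With $\lambda = 1$ the transform is
affine and the F table equals the untransformed analysis — a convenient
internal consistency check. The default model is the randomized-block
factorial `block + variety * strain * interval_h` with sequential
(type I) sums of squares, the classical presentation for balanced
designs; interval-wise letters use the pooled error term.

Pairwise comparisons use the studentized range with the Tukey–Kramer
standard error $\sqrt{\mathrm{MSE}/2\,(1/n_i + 1/n_j)}$, valid for
unequal group sizes and reducing to Tukey's HSD for balanced ones. The
compact letter display is built by insert-and-absorb: start from one
column holding all groups, split any column containing a significantly
different pair, absorb columns contained in others, and letter the
columns in the order of their best-ranked member; groups are ranked by
descending mean.

## PCA and clustering

PCA standardizes each variable (centre by mean, scale by standard
deviation) and eigendecomposes the correlation matrix of the four
behavioural proportions (survival, dispersal rate, PFD, IFP). Retention
follows the Kaiser criterion (eigenvalue $> 1$); variance explained by
component $k$ is $\lambda_k / p \times 100$ since the eigenvalues sum to
the number of variables. Which "dispersal" variant enters the PCA is the
caller's choice — any four-column selection is accepted — because
pre- versus post-feeding inclusion is a design question, not a numerical
one.

Treatment clustering is agglomerative with unweighted average linkage
(UPGMA) on Euclidean distances between the proportion vectors
(the natural metric for points in $[0,1]^4$; the source analyses say
only "distance matrix based on proportion data"). Average linkage on a
metric is monotone, so merge heights are non-decreasing and a horizontal
cut — e.g. near 1.15, which separates the early-exposure Bt treatments
from the rest in data of this shape — yields a unique grouping. The
dendrogram exports to Newick with heights as branch lengths.

## The lattice model

State: a `height × width` lattice (default 100 × 100) carrying one crop
label per cell, a 0/1 immature-occupancy grid, and an adult-female count
grid capped at the carrying capacity $K = 10$ per cell. Immatures and
adults occupy the same cell without interacting. Contamination switches
exactly `round(fraction × cells)` cells (half away from zero) to the
opposite crop, placed uniformly without replacement.

Each time step applies, in a fixed documented order:

1. **demographic transitions** — per-larva mortality; metamorphosis
   (larva removed, one female added to the same cell if below $K$, lost
   otherwise); per-female mortality; oviposition (each female converts
   the empty immature slot of *her own* cell with the oviposition
   probability, at most one egg per cell per step);
2. **larval dispersal** — larvae in random order each draw one uniform
   candidate within the Chebyshev ball of their cell's crop radius
   (default 3 on Bt, a 7 × 7 region; 1 on non-Bt, a 3 × 3 region) and
   move iff the destination is empty at that moment;
3. **adult dispersal** — females in random order each draw one uniform
   candidate within Chebyshev radius 35 and move iff the destination is
   below $K$.

Design choices where the source description is silent: the lattice is
bounded with clipped neighbourhoods (a torus would make "distance from
the centre of the distribution" ill-defined); "a region of 7 × 7 cells
(radius 3)" is read as a Chebyshev ball, and the adult radius the same
way for consistency; event order and sequential random-order updates
resolve collisions and are fully seeded; metamorphosis produces one
female immediately (no pupal delay, only females modelled); oviposition
is own-cell only; movement is the only crop-dependent process — no
mortality difference on Bt versus non-Bt cells, which isolates the
dispersal mechanism. The initial population is a centred 20 × 20 block
of larvae and no adults: a compact inoculum makes the expansion endpoint
interpretable.

The demographic probabilities are **calibration placeholders**, not
measured rates: immature mortality 0.02, metamorphosis 0.05, adult
mortality 0.05, oviposition 0.30 per female per step, chosen only so
populations persist over a 300-step run. The probability functions of
the original C implementation this model descends from are defined in a
supplement that is not redistributed here; the `transition_rates()`
slots accept any per-step constants.

Endpoints, per replicate after 300 steps: the mean Euclidean distance of
occupied larval cells to their centroid (cell units), and larval density
(occupied cells / total cells). The six study scenarios are Bt-dominant
(`a1`–`a3`) and non-Bt-dominant (`b1`–`b3`) landscapes at 0/10/20%
contamination, 50 replicates each, compared endpoint-wise with the
Tukey–Kramer test at $P = 0.05$.

### A known limitation of the placeholder rates

With the shipped demographic placeholders the population is strongly
supercritical (each immature has probability $0.05/0.07 \approx 0.71$ of
reaching adulthood, and each adult lays several eggs over a ~20-step
lifetime), and adults jump up to 35 cells per step. The test suite's
full-battery run shows the consequence: the population reaches
lattice-wide occupancy (density ≈ 0.8) well before step 300 in every
scenario, at which point the distance-to-centroid endpoint measures the
lattice rather than larval movement, and the crop contrast between
Bt-dominant and non-Bt-dominant scenarios is erased (all six scenarios
share a Tukey letter). The crop-dependent kernel itself behaves
correctly — in the movement-only regime (all transition rates zero) the
radius-3 kernel spreads significantly farther than the radius-1 kernel,
which the suite verifies — so recovering crop-level contrasts at the
whole-population scale is a question of demographic calibration, i.e. of
replacing the placeholders with the original probability functions.

## Randomness and reproducibility

All randomness flows through R's RNG, including the compiled core, so a
single `set.seed()` reproduces any trajectory. Batch runs derive one
child seed per replicate from the master seed by seeding the RNG with
the master and drawing integers (`derive_seeds()`); any replicate can
therefore be reproduced in isolation from its recorded child seed.
Every command wrapper writes a JSON manifest with the config snapshot,
seed, package version and output list, and re-running with the same
config and seed reproduces the CSV payloads byte-identically.

## Problem sizes used by the test suite

Unit tests run on deliberately small designs (single blocks, 10–30-cell
lattices, 5–40 steps) so the suite stays fast; the calibration test uses
$10^5$ larvae per design cell, the regression-recovery tests 250 plants
× 20 larvae per time point (the published fitting scale), and the
battery check runs the full study conditions (100 × 100 lattice, 300
steps, 50 replicates × 6 scenarios). Property checks (conservation,
occupancy bounds, kernel support, determinism) sweep 100 seeds on small
grids, where a violation would be as visible as on large ones.

## Known limitations

* The demographic placeholders above; scenario-level endpoint contrasts
  should not be interpreted until they are replaced by calibrated
  functions.
* The generator draws blocks independently; block effects in the
  factorial ANOVA therefore reflect sampling noise only.
* The compact letter display is unique up to letter naming but, like all
  CLDs, can understate the ordering information in the underlying
  pairwise table; the full comparison table is always returned alongside.
* Quasi-binomial Wald intervals are first-order; at very small plant
  counts profile intervals would be preferable.
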