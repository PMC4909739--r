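---
title: "Partitioning plant P uptake by soil 32P labeling: model, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning plant P uptake by soil 32P labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracerpart)
```

## The problem

When a P fertilizer is applied to soil, the P a plant takes up comes from
three pools: the native plant-available soil P, the P remobilized from the
sown seeds, and the fertilizer itself. Chemical analysis of the plant cannot
tell these apart. The indirect (soil-labeling) isotope-dilution method can:
the soil's plant-available P pool is labeled with carrier-free ^32^PO~4~
ions *before* fertilization, so soil-derived P carries the tracer while
fertilizer- and seed-derived P do not. The dilution of the tracer in the
plant then reveals how much unlabeled P entered through each route.

`tracerpart` implements this accounting for the classic design: an
unfertilized control, a water-soluble reference fertilizer (triple super
phosphate, TSP), and a test product (here a thermally conditioned sewage
sludge, TCSS), grown in labeled pots with repeated shoot harvests ("cuts").

## The model

For every treatment, cumulative shoot P uptake decomposes as

$$Pt = Pseed + Psoil + Pfert,$$

with all quantities in mg P per kg soil ($Pfert \equiv 0$ in the control).
The observable tracer quantity is the fraction of the introduced activity
$R$ recovered in shoots, $r/R$ (percent). Three steps turn these into a
partition:

1. **Decay correction.** ^32^P decays about 5% per day (half-life
   14.276 d), so counts measured on different dates are first referred to
   the labeling date: $A_0 = A \cdot 2^{t/T_{1/2}}$ (`decay_correct()`).
   The correction is exactly invertible, which the tests exploit as a
   round-trip property.
2. **Seed correction.** The seed contribution is measured in an unlabeled
   side experiment as sown-seed P minus residual-seed P, allocated to
   shoots by the shoot share of whole-plant P (`seed_p_allocated()`). Seed
   reserves are depleted after the first regrowth cycle, so the default
   allocates seed P to cut 1 only (`seed_cuts = 1`).
3. **Isotope dilution.** The control anchors the isotopic composition of
   soil-derived P, $IC_0 = r_0 / (Pt_0 - Pseed_0)$. Assuming the
   plant-available soil pool has the *same* specific activity under every
   treatment, a fertilized treatment's soil-derived uptake is
   $Psoil = (Pt_0 - Pseed_0)\, r_f / r_0$, and the fertilizer-derived
   uptake is the residual $Pfert = Pt - Pseed - Psoil$.

Derived quantities: $Pdff = 100\,Pfert/Pt$ (percent of nutrition derived
from the fertilizer), $CPU = 100\,Pfert/\text{dose}$ (fertilizer P
recovery), the specific activity $SA = (r/R)/Pt$ and its reciprocal the
L-value $L = Pt/(r/R)$, a plant estimate of the isotopically exchangeable,
plant-available soil P. Agronomic effectiveness compares a test product
with the reference either through $Pfert$ ($AE_{CPU}$) or through $Pdff$
($AE_{Pdff}$); the latter is less sensitive to conditions that depress
soil- and fertilizer-derived uptake in the same proportion (e.g. microbial
competition).

## Computation modes

The fitting function `partition_p32()` partitions **per cut and per pot**:
each pot's per-cut recovery is compared with the control's per-cut means,
and the per-cut partitions are then summed per pot (`cumulate_cuts()`
recomputes Pdff, CPU, SA and L from the sums — ratios are never averaged).
This is the arithmetic that supports replicate-level SE and letter
statistics. A second, clearly labeled **aggregate mode**
(`partition_aggregate()`) runs the same chain on cumulated treatment
means; it is useful at the desk and for teaching, but whenever tracer
recovery varies across cuts its Psoil/Pfert differ from the per-replicate
cumulation, while the ratio quantities (SA, L) are identical. The shipped
published summary reflects exactly this gap: its Psoil/Pfert columns come
from per-replicate cumulation of unpublished per-cut values and are treated
as *inputs*, not as recomputable outputs.

Negative Pfert or Psoil estimates (possible under measurement noise) are
retained and flagged, never clipped, so treatment means stay unbiased.

## Worked example

```{r example}
sim <- simulate_pot_experiment(default_sim_config(seed = 42, cv = 0.10))
fit <- partition_p32(sim$observations, sim$labeling,
                     doses = c(TSP = 50, TCSS = 50),
                     seed_budgets = sim$seed_budgets, reference = "TSP")
fit
summary(fit, variables = c("Pt", "Pfert", "Pdff"))
```

## The synthetic generator

`simulate_pot_experiment()` draws the experiment the analysis assumes:
three treatments by default (control, TSP, TCSS at 50 mg P kg^-1^), five
pots each, cuts at 27/38/59 days after sowing, soil labeled with
3.7 MBq kg^-1^. Its default true magnitudes are calibrated once to the
published cumulative means — shoot P uptake 4.6/19.7/12.5 mg P kg^-1^,
seed allocation 0.62/0.89/0.67 mg P kg^-1^, true Pdff 0.55/0.56, and
first-cut soil-derived uptakes 1.11/3.13/1.14 mg P kg^-1^ — under the
equal-SA assumption, with a slightly decreasing soil-pool isotopic
composition over cuts (3.3/3.0/2.75 % of R per mg P) that reproduces the
control's cumulative recovery of ~11.9%. A consequence worth knowing: the
published triple (r/R, Psoil, Pfert) for the fertilized treatments is not
mutually consistent with the equal-SA model at the aggregate level, so the
generator prioritizes Pt, Pdff and the seed and first-cut soil values; the
TSP truth then implies a cumulative recovery near 24% rather than the
printed 20.1%.

The noise model is multiplicative lognormal (mean-preserving) on dry
matter and on the soil- and fertilizer-derived uptake components
(biological variation, CV 10% by default) and additive Gaussian on counts
relative to activity (simplified counting error, CV 10%). Activities are
written out *decayed* to the count dates, so any correct analysis must
decay-correct them. Seed budgets are emitted so that `seed_p_allocated()`
returns the configured allocation exactly — the generator and analysis are
exact inverses on noise-free data, which is the basis of the consistency
tests. What the generator does **not** emulate: root-uptake kinetics,
sorption chemistry, within-pot spatial heterogeneity, counting dead-time
or quench effects, and any mechanistic microbial P dynamics. The
"assumption violation" mode is a phenomenological multiplier on a
treatment's soil-pool specific activity; the induced bias is exactly
$(m-1) \cdot Psoil$, which the tests assert. Passing tests therefore
validate the algebra and the statistical behaviour of the estimator under
its stated assumptions — not the assumptions themselves in any particular
real soil.

The incubation generator uses a two-pool respiration model, basal rate
plus exponentially decaying flush, $f(t) = b + A e^{-kt}$, integrated
exactly over the standard 1–63 day sampling schedule and inverted into
back-titration volumes (5 mL of 0.5 M NaOH trap, 0.1 N HCl, 6 mg C per
meq at the phenolphthalein endpoint convention). Defaults
(control $b$=1.85, $A$=48; TSP $b$=2.0, $A$=52; TCSS $b$=1.9, $A$=65; all
$k$=0.5 d^-1^) put the TCSS day-1 flux near 53 mg C kg^-1^ d^-1^ and its
63-day cumulative near 250 mg C kg^-1^, inside the published 214–255
envelope; the envelope is a calibration check, not an equality, because
the raw titration data behind the published curves are unavailable.

## Statistical reporting

`anova_one_way()` delegates the classical decomposition to `stats::aov()`;
`snk_letters()` implements the Student–Newman–Keuls step-down directly
from the studentized-range distribution so the letter logic is testable in
isolation: ranges spanning $p$ ordered means are tested against
$q_{1-\alpha,p,df}$, ranges inside a non-significant range are protected,
and the compact letter display is built from the maximal non-significant
intervals (groups sharing no letter differ at $\alpha$). Unequal group
sizes use the harmonic mean (flagged); ties in means are broken stably by
group label. Reconstructing the published p-values from printed mean ± SE
pairs is deliberately not attempted — the raw replicates are unavailable
and display rounding makes it unverifiable.

## Numerical and design choices

* All P quantities are mg P per kg soil; radioactivity is carried as
  percent of introduced R after decay correction to the labeling date.
* The L-value is computed as $Pt/(r/R)$ without seed subtraction, which
  reproduces the published values (39, 98); a seed-corrected variant can
  be had by passing `Pt - Pseed` explicitly.
* Half-life default 14.276 d; whether the original counts were
  decay-corrected is unstated in the source, so the correction is this
  package's own convention (it is a no-op when all counts share one date).
* Error dispersion is reported as SE throughout.
* Percent outputs are kept at full precision; rounding to display
  precision happens only in reports.
* Problem sizes in the test-suite simulations (5 pots, 3 cuts, 200
  Monte-Carlo replicates for the bias check) match the design the package
  targets; the bias criterion is |mean recovered − truth| < 2 Monte-Carlo
  SEs.

## Known limitations

* The equal-SA assumption is untestable from a single labeled experiment;
  the violation mode quantifies the resulting bias direction but cannot
  detect it in real data.
* Seed allocation uses one whole-plant split per treatment (from the
  unlabeled side experiment), not per pot.
* The aggregate mode's Psoil/Pfert should not be compared against
  replicate-cumulated values from the same data — the difference is a
  property of the arithmetic, not an error.
* Heavy-metal compliance is a static concentration check against limit
  values; no soil fate modeling.
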