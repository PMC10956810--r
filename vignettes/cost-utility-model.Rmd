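---
title: "A three-state Markov cost-utility model for unresectable hepatocellular carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov cost-utility model for unresectable hepatocellular carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hccmarkov)
library(dplyr)
```

## The decision problem

Patients with unresectable hepatocellular carcinoma (uHCC, BCLC stage C)
who are ineligible for surgery or loco-regional therapy face a choice, in
settings where checkpoint-inhibitor combinations are not yet reimbursed,
between best supportive care (BSC) and systemic therapy with atezolizumab
plus bevacizumab (A+B).  `hccmarkov` implements a societal-perspective
cost-utility analysis of that choice for a Thai cohort entering treatment
at age 50, together with a five-year governmental budget-impact
projection for listing A+B on a national formulary.

## Model structure

The disease is represented by a Markov cohort model with three states:
*progression-free* (PF), *progression*, and *death*, evaluated on a
one-month cycle over a lifetime horizon (600 cycles by default, ample for
a cohort whose survival is measured in months).  The whole cohort enters
progression-free.  Each cycle, a patient in PF either progresses, dies,
or stays; the two exits are treated as mutually exclusive per-cycle
probabilities, so the staying probability is the complement of their sum.
A patient in the progression state either dies or stays.  Death is
absorbing.

Disease-specific mortality applies identically from both alive states.
This structural choice is what reproduces the model's internal validation
anchor — a median overall survival of 4 months on BSC — because if death
were reachable only after progression, median survival roughly doubles.
Background (other-cause) mortality is combined with disease mortality as
independent competing probabilities,
$p_{death} = 1-(1-p_{disease})(1-p_{background})$, with the cohort aging
1/12 year per cycle for the life-table lookup.  At the disease-death
rates in this model (0.10–0.17 per month) the background correction is
negligible, a property the test suite verifies directly by re-running the
whole analysis with background mortality switched off and checking that
neither arm's median moves and the ICER shifts by under 2%.

## Transition probabilities

The BSC arm's monthly probabilities are model inputs, piecewise constant:

* progression: 0.29 for months 1–6, then 0.24;
* disease death: 0.17 for months 1–12, then 0.10.

The A+B arm applies treatment-effect hazard ratios to the BSC
probabilities on the rate scale,

$$p' = 1 - (1 - p)^{HR},$$

with $HR_{PFS} = 0.34$ (SE 0.06) on progression and $HR_{OS} = 0.40$
(SE 0.07) on disease death, both lognormally distributed.  With the
hazard ratios at their means this yields the model's other validation
anchor, a 10-month median overall survival on A+B.

For users starting from landmark survival proportions rather than
per-cycle probabilities, `survival_to_cycle_prob()` converts a cumulative
probability $P$ at time $T$ months into a per-cycle probability.  Two
readings of the time denominator circulate for this conversion — rate per
month versus rate per year ($t = T/12$) — and both are implemented;
they disagree by a factor of twelve in the rate.  The base case does not
depend on the choice because the monthly probabilities above are inputs,
not derived quantities.

## Costs, utilities and discounting

Costs are 2023 USD (34 THB/USD, recorded as metadata only) from a
societal perspective.  While progression-free, the A+B arm accrues the
monthly drug acquisition cost (\$6,135), administration (\$21), and
monitoring: four laboratory tests (\$34 total) every cycle, a CT scan
(\$218) every second cycle and a chest scan (\$76) every third.  Periodic
items charge on cycles divisible by their period, so the CT first charges
at cycle 2 — the inputs state only the frequencies, and this convention
is the natural one for tests ordered at the end of each interval.  After
progression, A+B patients move to supportive care (\$489/month, the same
bundled estimate that covers the BSC arm in both alive states).  Direct
non-medical costs (travel \$5 + food \$2 + caregiver productivity
\$3 = \$10/month) accrue in every alive state on both arms, reflecting a
monthly hospital visit.  An optional one-off adverse-event management
cost at model entry is supported for the A+B arm
(`settings$ae_cost_oneoff`); its default is zero because no usable
estimate for the grade-3/4 events (hypertension, AST elevation) is
available in the model's published inputs, and the item is small relative
to the drug cost it accompanies.

Utilities are 0.89 (PF) and 0.58 (progression), beta-distributed.  QALYs
accrue as occupancy-weighted utility divided by 12 per cycle.

Two accounting conventions deserve explicit statement:

* **Start-of-cycle occupancy.**  Costs and QALYs for cycle $c$ are paid
  on the state occupancy at the start of the cycle; an event during the
  cycle pays the destination state from the next cycle onward.  No
  half-cycle correction is applied by default — the integer-month median
  validation anchors match the uncorrected trace — but
  `settings$half_cycle_correction` averages start- and end-of-cycle
  occupancy for sensitivity.  The trace summary `state_time()`, by
  contrast, sums the stored end-of-cycle occupancies; the two views
  differ by at most one cycle of full occupancy.
* **Annual-step discounting with the first year exempt.**  Both costs
  and outcomes discount at 3% per year *beyond* year one:
  cycles 1–12 carry factor 1 and every cycle of year $y$ carries
  $(1.03)^{-(y-1)}$.  A per-cycle compounding switch
  (`settings$discounting = "per_cycle"`) exists for sensitivity.

## Parameter uncertainty

Every uncertain parameter is published as a distribution family with a
mean and SE only, so distribution parameters are recovered by matching
moments on the natural scale (`moment_match()`): gamma via
shape $=\mu^2/\sigma^2$, scale $=\sigma^2/\mu$; beta via the method of
moments; lognormal via $\sigma_{\log}^2 = \log(1+(\sigma/\mu)^2)$,
$\mu_{\log} = \log\mu - \sigma_{\log}^2/2$.  For the lognormal hazard
ratios the printed mean is thus the natural-scale mean; the common
alternative that treats the printed mean as the median
(`lognormal_parametrization = "naive"`) is available behind a switch,
since the source table does not state which was intended — its columns
are labelled Mean/SE, which is what the default honours.

One-way sensitivity sweeps each non-fixed parameter across
$\mu \pm 1.96\sigma$ truncated to the family's support (the source never
states how its confidence bounds were formed; the normal approximation is
the conventional default), plus the discount rate over 0% and 6%.  The
probabilistic analysis (`run_psa()`) draws 5,000 independent parameter
sets, re-runs both arms per draw, and summarises as the ratio of mean
incremental cost to mean incremental QALY, with the cost-effectiveness
acceptability curve defined by strictly positive incremental net monetary
benefit $\lambda \Delta E - \Delta C > 0$ at each willingness-to-pay
$\lambda$ (ties, a measure-zero event, count as not cost-effective).
Infeasible draws (per-cycle exit probabilities exceeding one) would be
redrawn and counted; in this model's parameter space they cannot occur,
because only hazard ratios below one touch the fixed BSC probabilities.
The run is reproducible from its seed alone: the full iteration-by-
parameter draw matrix is generated up front from one seeded generator,
so any iteration can be reconstructed exactly.

```{r psa-small}
cfg <- default_config()
lt <- make_life_table()
psa <- run_psa(cfg, lt, iterations = 200, seed = 1)
glance(psa)
ceac(psa, wtp = cfg$settings$wtp_thresholds)
```

(The bundled configuration uses 5,000 iterations; the examples here use
200 to keep the vignette light.)

## Budget impact

The eligible population funnels the annual national incidence of liver
and intrahepatic bile-duct cancer (27,394) through the HCC share (50%)
and the BCLC-C share (11.2%), giving 1,534 candidates per year.  Uptake
ramps linearly from 14.6% by 6.5 points per year.  Patient counts per
year default to the published 224/324/425/525/625; note that re-deriving
them as `round(eligible × access)` gives 423 and 623 in years 3 and 5 —
the published counts appear to carry internal rounding — so the override
is the default and the derivation remains available.

Yearly cost is undiscounted direct medical cost only (drug,
administration, monitoring, post-progression supportive care; no
non-medical costs).  Under the default *initiation-year* attribution each
starting cohort's full lifetime cost is booked in its start year; this is
the convention that reconciles with a first-year budget of order
224 × per-patient lifetime cost.  A *calendar-year* mode spreads each
cohort's cost stream over calendar years with carry-over; over an
extended window the two modes book identical totals (a conservation
property in the test suite).  Which convention the published projection
used is not stated, and its year-5 figure is not reproduced by either
mode, so the fifth-year value should be read as indicative only.

```{r budget}
project_budget(cfg, lt)
```

## The synthetic life table

Age-specific background mortality is the one model input with no usable
published values, so the package generates a clearly-labelled synthetic
stand-in (`make_life_table()`): Gompertz-shaped annual mortality
$q(a) = \min(q_{50} \cdot 2^{(a-50)/d},\ 0.99)$ with $q_{50} = 0.005$ and
doubling time $d = 8$ years — the order of magnitude and age-doubling
behaviour of adult national life tables.  It makes no claim to match the
Thai table.  This is defensible precisely because the model is insensitive
to it: disease mortality dominates background mortality by two orders of
magnitude at every cycle, and the test suite quantifies the insensitivity
(medians unchanged, ICER shift < 2% against a zero-mortality table).
Consequently, passing tests say nothing about the accuracy of any real
life table — only that no plausible one can matter here.

## Verification strategy

Three independent routes check the engine:

* a **closed-form geometric benchmark**: with equal death probabilities
  from both alive states the alive fraction is an explicit geometric
  product, compared to machine precision;
* an **individual-level microsimulation** (`microsim()`) with the same
  event conventions, compared to the cohort trace within three binomial
  standard errors at every cycle (200,000 patients in the acceptance
  property, 20,000 in the unit test);
* a **dual accumulation route**: the fast vectorised engine behind
  `run_psa()` and `one_way_sa()` is checked against the fully tabular
  `run_trace()` + `cost_schedule()` + `accumulate_costs()` pipeline on
  random draws.

Moment matching is verified by sampling round trips (10^6 draws per
parameter in the acceptance property), and metamorphic tests perturb all
parameter means by ±20% (`perturbed_config()`) and assert that
conservation, validity and monotonicity survive.

## Known limitations

* The printed monthly transition probabilities bound BSC mean survival
  near 6.3 person-months (start-of-cycle accounting), and therefore bound
  the lifetime QALYs both arms can accumulate.  Published QALY totals for
  this comparison imply roughly 20% more person-time than those same
  probabilities generate; no documented model feature closes that gap,
  and this package deliberately does not add undocumented ones.  The
  package reports what the stated inputs produce.
* Treatment discontinuation for toxicity, dose modification and
  individual heterogeneity (e.g. weight-based dosing) are not modelled.
* The hazard ratios are consumed as inputs; the network meta-analysis
  that produced them, and any currency/CPI adjustment, are out of scope.
* The one-way sensitivity sweep applies the same ±1.96 SE rule to every
  uncertain parameter, including the drug unit cost, whose swing under
  this rule is of the same order as the PFS hazard ratio's; rankings
  below the dominant OS hazard ratio are sensitive to that convention.
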