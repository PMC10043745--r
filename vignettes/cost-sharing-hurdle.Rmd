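---
title: "Inferring plan cost-sharing mechanisms and modelling follow-on breast imaging"
author: "costshare package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring plan cost-sharing mechanisms and modelling follow-on breast imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costshare)
```

## The problem

Screening mammography carries no patient cost-sharing for most commercially
insured women, but the diagnostic work-up that follows an abnormal screen —
diagnostic mammography, breast ultrasound, breast MRI, biopsy — does.  If
expected out-of-pocket costs (OOPCs) deter women from completing recommended
follow-on testing, the policy goal of free screening is partly undone.
Studying this from administrative claims requires three ingredients that this
package provides as a connected pipeline:

1. **Episodes of care** anchored on a screening mammogram, built from raw
   claims with explicit inclusion, exclusion and termination rules.
2. **Plan-type inference**: claims reveal what patients paid, not the
   cost-sharing design printed on their insurance card; the design is
   inferred from the claims of *all* enrollees in each plan and the plans are
   classified as balanced, copay-dominant, coinsurance-dominant or
   deductible-dominant.
3. **A two-part hurdle model** relating plan type to the number of follow-on
   services, with delta-method average marginal effects.

Because the claims databases used for such studies are proprietary, the
package ships a synthetic claims generator with full ground truth; every
stage is validated against planted parameters rather than against data that
cannot be redistributed.

## Episodes of care

The index event is a patient's earliest screening mammography claim
(CPT G0202 / 77057 / 77063 by default) in the index year.  The episode runs
over the half-open window $(\text{index}, \min(\text{index}+365\text{d},
\text{first breast-cancer diagnosis claim})]$; the index claim itself never
counts as a subsequent service.  Patients enter the cohort if they are
female, at least 40 years old at the start of the study period, continuously
enrolled in a single plan across the whole period, alive at its end, and
free of breast-cancer diagnoses (ICD-9 174.x, ICD-10 C50.x, prefix match
with dots retained) in the 365 days before the index.  Exclusions are
reason-coded and logged.

Design choices a user should know:

* **Age is evaluated twice.**  Eligibility uses age at the study-period
  start; the age-group covariate uses age at the index date.  The two rules
  are deliberately distinct.
* **Same-day duplicate claims count separately** by default (service counts
  are claim-line counts); a `dedup` switch pools same patient/day/CPT lines.
* **Comorbidity** is a prospective Charlson score over the 365 days before
  the index, computed from a configurable ICD-prefix-to-weight map.  The
  shipped default uses standard categories and classical weights with a
  severity hierarchy (complicated diabetes supersedes uncomplicated,
  moderate/severe liver disease supersedes mild, metastatic disease
  supersedes localised malignancy).  Scores are binned 0 / 1 / 2 / 3+.
* **Death ascertainment** uses an optional `death_date` enrollment column;
  without one, patients are assumed alive.

## Plan mechanism inference

Each plan is summarised by a triplet: the mode copay over all its claims,
the mode of the per-claim coinsurance-to-allowed ratio, and the maximum over
enrollees of the annual sum of deductible payments.  Two numerical
conventions make the triplet well defined: coinsurance ratios are rounded to
two decimals before taking the mode (coinsurance rates are quoted in whole
percents), and mode ties break toward the smaller value.  Claims with zero
allowed amount are skipped in the ratio; a flag can exclude zero-cost-share
claims entirely.

Triplets are min-max scaled component-wise.  The default orientation is

$$s = \frac{\max - x}{\max - \min},$$

under which the plan attaining the global maximum of a component scales to
0.  This inverted orientation is kept as the default for fidelity to the
procedure the pipeline reproduces; the conventional orientation
$s = (x-\min)/(\max-\min)$ is available as `orientation = "standard"`
because the intent of the origin-seeded cluster (below) differs between the
two readings, and the ambiguity cannot be resolved from the description
alone.

Clustering uses Lloyd's algorithm with exactly four centers: three drawn
uniformly at random in the unit cube and one placed deterministically at the
origin.  Points are assigned to the exactly nearest center (Euclidean; ties
to the lowest center index), all four centers are then recomputed as
assigned-point means (the origin center is *not* pinned; a `pin_origin` flag
pins it), and iteration stops when assignments no longer change.  An empty
cluster is re-seeded to the point farthest from its nearest live center; if
re-seeding cannot help because every point coincides with a center, the
cluster is left empty.  One run per seed is performed, matching the
procedure being reproduced; multi-restart is deliberately not the default.

Clusters are labelled by re-expressing centers so that larger always means
more cost-sharing (undoing the inverted orientation if needed): the center
with the smallest across-dimension range is `balanced`; the rest take the
label of their largest dimension, with conflicts resolved deterministically
(larger coordinate wins, the loser takes its largest unclaimed dimension).
Finally plan types are ranked by the unweighted mean over plans of the mean
annual OOPC of each plan's enrollees; rank 1 is the cheapest type and
becomes the reference level of the regression.

**Known limitation.**  A single Lloyd run from random initial centers finds
a local optimum.  On planted four-type universes dominated by one large
type, a minority of seeds converge to a solution that splits the largest
cluster and merges two small ones; when this happens a substantial share of
labels is wrong.  The package keeps the single-run default for fidelity and
exposes the behaviour rather than papering over it; users who want the
global optimum should use several seeds and keep the run with the smallest
final SSE (the fitted object records `sse_path`).

## The two-part hurdle model

Most screened women have zero follow-on services, so the count outcome is
modelled in two parts.  Part 1 is a logistic regression (IRLS via `glm`) for
$P(Y_i > 0)$ over the full cohort.  Part 2 models the positive counts with a
zero-truncated negative binomial in the NB2 parameterisation
($\mathrm{Var} = \mu + \alpha\mu^2$, chosen as the ecosystem default):

$$\log L_2 = \sum_{i: y_i \ge 1} \left[ \log f(y_i;\mu_i,\alpha) -
\log\{1 - f(0;\mu_i,\alpha)\} \right], \qquad \mu_i = \exp(x_i^\top\beta),$$

maximised by BFGS over $(\beta, \log\alpha)$ with the analytic score;
everything is computed in log space (`log1p`, `expm1`) so small $\alpha$ and
large $\mu$ are stable.  Line-search excursions that overflow the likelihood
are treated as barriers, and an underflowing $\alpha$ is clamped at
$10^{-12}$.  Convergence requires the relative log-likelihood change of the
quasi-Newton iteration to fall below $10^{-12}$ and is verified against the
score norm; a second polish run is started if the score norm is loose.
Standard errors come from the observed information, obtained as a central
finite-difference Jacobian of the analytic score; the same quantity computed
from function values only is used as a cross-check in the test suite.

Marginal effects for plan type are **average marginal effects conditional on
any use**: the mean over the part-2 estimation sample of the difference in
the truncated mean $m(\mu,\alpha)=\mu/\{1-f(0;\mu,\alpha)\}$ when every
patient is switched from the reference (lowest-OOPC) type to the contrast
type.  This matches an analysis of utilisation *among patients undergoing
subsequent testing*; the unconditional two-part effect
$P(\text{any}) \times m$ is available via `conditional = FALSE`.  Standard
errors propagate the part-2 parameter covariance (and, unconditionally, the
part-1 covariance) through the AME by the delta method with a numerical
gradient; intervals and p-values use the normal reference appropriate to
maximum-likelihood asymptotics at these sample sizes.

**Duan smearing** is implemented as a multiplicative retransformation of
$\hat\mu$ by the mean of the exponentiated log-scale residuals among
positives, $S = \tfrac1n \sum y_i/\hat\mu_i$, held fixed in the delta-method
variance.  Smearing is a retransformation device for log-scale regressions,
and its exact recipe for a zero-truncated count MLE is a convention rather
than a settled formula; it is ON by default to mirror the reproduced
analysis and documented here as a sensitivity knob (`smearing = FALSE`
reports unsmeared effects; the factor itself is reported alongside every
effect).

Region enters the adjustment as fixed-effect indicators, not clustered
standard errors.  In the regression the age covariate uses three levels
(40–64, 65–74, 75+): the two oldest descriptive strata are far too thin in a
screening population to support their own indicators, and the reproduced
adjustment set itself pools them.  The pipeline additionally pools any
adjustment level with fewer than five positive outcomes into the reference
level before fitting; without this, desk-scale runs would fail on empty
count-part cells.

## The synthetic claims generator

The generator is first-class, tested code and defines the study conditions:

* **Plan universe.**  Four plan types with mixture defaulting to the exact
  count ratios of the emulated plan universe (balanced 4736, copay 13310,
  coinsurance 1881, deductible 2901 out of 22828 — the three-decimal shares
  0.207/0.583/0.082/0.127 sum to 0.999 and are rejected by the sum-to-1
  validation).  Counts are apportioned by largest remainder.  Dominant
  components sit in narrow bands (copay \$55–65 per visit, coinsurance
  20–28%, deductible \$1000–1400 per year); balanced plans have all three
  components non-trivial (\$8–12, 5–8%, \$280–380); background components
  are near zero and shrink with the `separation` factor.  The bands were
  chosen once so that (a) at `separation >= 2` the scaled triplets form
  well-separated type clusters and (b) the expected annual OOPC ordering is
  coinsurance < balanced < copay < deductible, matching the ordering the
  pipeline is expected to recover.  Deductibles are set low enough that
  typical annual spending exhausts them, otherwise the annual cap would not
  be observable from claims.
* **Claims.**  Allowed amounts are log-normal (median \$150, log-sd 0.8):
  claims costs are right-skewed and the exact shape is immaterial to the
  inference being tested.  Cost-sharing follows the plan's true mechanism
  through a per-enrollee annual deductible accumulator (deductible portion
  first, coinsurance on the remainder, copay capped so the patient never
  pays more than the allowed amount).  The accumulator resets each calendar
  year.  Screening mammogram claims carry zero cost-sharing and do not
  advance the accumulator.
* **Outcomes.**  Any-test indicators are Bernoulli with logit-linear
  probability; positive counts are zero-truncated NB2 drawn by inverse-CDF.
  Default parameters give a subsequent-testing rate near 11% (reference
  coinsurance plans highest at 12.1%), a mean of about 1.95 services among
  testers, dispersion $\alpha = 0.1$, and small negative plan-type effects
  on the count scale (balanced $-0.0064$, copay $-0.0219$, deductible
  $-0.0146$) sized to yield conditional AMEs of a few hundredths of a
  service per tester.  Covariates (age group, race/ethnicity, Charlson
  category, five regions standing in for state) are drawn with the
  descriptive shares of the emulated cohort.
* **Study simulation.**  `simulate_study()` adds screening claims in the
  index year (some women screen twice, exercising the earliest-claim rule),
  planted Charlson condition claims in the lookback year, prior-cancer
  claims (about 1% of screened women, excluded downstream), post-index
  cancer diagnoses (about 1.5%, terminating episodes early), and subsequent
  service claims split multinomially over diagnostic mammography,
  ultrasound, MRI and biopsy (0.45/0.46/0.05/0.04).  A ground-truth sidecar
  records plan specs, outcome parameters, the expected cohort and planted
  per-category counts.  All randomness flows from one master seed through
  named substreams, so stages are bit-reproducible in isolation.

What the generator does **not** emulate: claim adjudication edge cases
(coordination of benefits, denials), realistic CPT/ICD ontologies beyond the
codes the pipeline consumes, out-of-pocket maxima, family-level deductibles,
benefit-year (rather than calendar-year) accumulators, and selection of
patients into plans on unobservables.  Passing tests therefore demonstrate
that the pipeline's logic and estimators are correct under a known
mechanism, not that any particular real-world estimate is reproduced.

## Numerical conventions

* Percentages in tables are rounded half-up to one decimal (matching how the
  printed percentages recompute from printed counts), and every emitted
  table self-checks that its percentages recompute from its own counts to
  within 0.05.
* Mode ties break toward the smaller value; k-means assignment ties break
  toward the lower cluster index; OOPC rank ties break by first occurrence.
* Degenerate min-max components (max = min) scale to 0 with a warning.
* The hurdle fit refuses all-zero or all-positive outcomes, detects probable
  separation in the logistic part (a fitted logit coefficient beyond ±30),
  and reports a rank-deficiency error naming the empty count-part cells.

## Problem sizes

The test suite exercises fits at up to 50 000 patients (coefficient
recovery within three standard errors of planted truth), clustering
universes of 2 000 plans over 20 seeds, confidence-interval coverage over
200 replications of 1 500 patients, and exact oracle comparisons (brute-force
Lloyd; brute-force truncated-pmf summation) on small instances.  These sizes
were chosen to make Monte-Carlo error small relative to the assertions while
keeping the default check fast on a laptop.  `scripts/acceptance.R` re-runs
the same computations from scratch for an arbitrary seed.
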