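---
title: "Quantifying vocal efficiency in call sequences: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vocal efficiency in call sequences: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocaleff)
```

`vocaleff` tests whether animal call sequences obey the
Menzerath–Altmann law — longer sequences are built from shorter calls —
and how individual and social factors modulate that relationship. This
vignette is the package's account of the science: the models it fits,
the assumptions they make, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices underneath.

## The law and its statistical form

The parametric law relates element duration $y$ to sequence size $x$:

$$y = a\,x^{b}\,e^{cx},$$

with scale $a > 0$, power exponent $b$, and exponential rate $c$.
`fit_menzerath_nonlinear()` estimates all three by least squares on the
log scale, where the model is linear in its parameters:
$\ln y = \ln a + b \ln x + c x$. Setting $c = 0$ and taking logs gives
the linearised form used by essentially all comparative work,
$\ln y = \ln a + b \ln x$, and that linear form is what the
hierarchical models estimate. Adherence to the law is a negative $b$
whose confidence interval excludes zero.

Two modelling commitments follow the current best practice in this
literature:

* **Full-distribution responses.** Every call contributes its own
  duration as a response row, with a random intercept per sequence,
  instead of regressing sequence-mean durations on length. Sequence
  means manufacture a spurious negative slope under regression to the
  mean and discard within-sequence variance; the full distribution
  avoids both.
* **Singleton exclusion.** Length-1 sequences are removed before
  fitting. Isolated single calls are known to depart from the law
  (they behave more like independent signals than sequence elements),
  and with only one length value they contribute nothing to a slope
  anyway.

## From annotations to sequences

The pipeline starts from time annotations (Audacity label tracks or
Raven Pro selection tables), not waveforms; call detection and caller
identification are upstream, human tasks. Two ingest conventions
matter:

* Caller identity is supplied per label file (observers typically name
  the caller on the recording, and exports are per focal individual); a
  label of the form `id:NAME` overrides it per call, and `unknown`
  marks the call for exclusion.
* Times are parsed with a decimal point only — a decimal comma is a
  parse error, never a silent zero — and are kept at full input
  precision.

**Segmentation rule.** A sequence is a run of same-individual calls on
one recording in which every silent interval (next onset minus previous
offset) is at most the gap threshold; a silence *strictly greater* than
the threshold starts a new sequence. The default threshold is 1.0 s,
the convention for corvid calls, and the strict inequality means a gap
of exactly 1.000 s does not split. The gap is silence, not
onset-to-onset time, because "inter-call interval" most naturally reads
as the pause the listener hears. Sequences never span recordings or
individuals. Overlapping same-individual calls are physically
impossible for one syrinx and indicate an annotation or attribution
problem: both calls are flagged, and the affected sequence is excluded
rather than silently merged.

**Exclusion cascade.** `apply_exclusions()` drops whole sequences in a
fixed order — unknown caller, overlapping calls, incomplete recording
context, then singletons — and reports a count per rule, so the audit
reconstructs the filter cascade exactly. The kept set is
order-invariant (the rules are applied to disjoint remainders); only
the tallies depend on the documented order. Sequence completeness
cannot be inferred from timestamps alone, so the package honours an
explicit `incomplete_context` flag set at annotation time rather than
guessing.

## Social covariates

Two per-individual covariates are derived from focal-observation logs.

**Elo rating** (dominance). Agonistic interactions are processed in
date order (ties keep input order — the process is deliberately free of
randomness). Before each bout the expected probability that the
eventual winner wins is logistic in the rating gap,
$p = 1/(1 + e^{-(r_w - r_l)/s})$, and the winner then takes
$k(1 - p)$ points from the loser, so updates are zero-sum and upsets
move ratings most. Defaults: initial rating 0, $k = 100$, and
steepness $s = 400/\ln 10 \approx 173.7$, the classical Elo logistic in
which a 200-point gap predicts a ~0.76 win probability. The sequential
update rule itself is standard; all three constants are arguments, and
individuals never observed interacting keep the initial rating of 0.

**CSI** (composite sociality index, affiliation). For each co-housed
dyad and each affiliative behaviour category (allopreening and contact
sitting), the interaction rate is events per dyadic observation time;
the dyadic CSI is the mean over categories of each rate normalised by
its across-dyad mean, so the population mean of dyadic CSI is exactly 1
and a value of 2 means "twice as affiliative as the average dyad". An
individual's CSI is its mean over dyads. Dyadic observation time is
approximated as the *smaller* of the two individuals' focal time
(five-minute focals are the unit in the intended use) — exact when
co-housed birds are observed in the same sessions, conservative
otherwise. A category with no events anywhere has an undefined
normalisation and is dropped with a warning rather than propagating a
division by zero.

**Effort correction.** Raw Elo and CSI both grow mechanically with how
often an individual was observed. Both are therefore reported raw and
as the residual from an OLS regression of the index on per-individual
observation count; the corrected index is mean-zero and exactly
orthogonal to effort. With fewer than 3 individuals the regression is
meaningless (error); with constant effort it is degenerate and the
mean-centred index is returned with a warning.

## The hierarchical models

All models are Gaussian on the log-duration scale.

* **Simple** (`fit_simple()`), applied separately per subspecies:
  `ln_dur ~ ln_len + (1 | individual/sequence_id)`. The nested
  intercepts absorb stable individual differences in call duration and
  the shared deviation of calls within a sequence. Fitting subspecies
  separately, rather than pooling with a subspecies fixed effect, is
  deliberate: with grossly unbalanced samples a pooled model invites
  conclusions about *relative* law strength that the data cannot
  support, so the package only assesses presence per subspecies.
* **Complex ladder** (`fit_complex()`), for the focal, well-sampled
  subspecies, with covariates sex, group size, age, Elo and CSI:
  `eq4` adds their main effects and deepens the intercepts to
  `(1 | population/group/individual/sequence_id)`; `eq5` additionally
  interacts every covariate with `ln_len`, letting them modulate the
  law itself; `eq6` adds `(0 + ln_len | population:group:individual)`,
  a nested random slope with no intercept at that level, capturing
  individual variation in the law beyond the covariates. The three are
  nested in the likelihood-ratio sense.

Conventions, each recorded in the fitted object:

* **Standardisation.** Continuous covariates are z-scored before
  fitting (centre and scale stored for back-transformation). Raw Elo
  spans hundreds of points; without standardisation its coefficient
  would be per-point and numerically tiny, and the covariates would be
  on wildly different scales. Effects are therefore per standard
  deviation. Sex is coded with female as reference, so `ln_len` is the
  female slope and `ln_len:sexM` the male offset.
* **Age and group size.** Age is recording year minus hatch year;
  unknown hatch years receive the mean age of the known individuals.
  Group size at the recording date is derived from membership
  intervals when dates are available, otherwise from the group roster.
* **Estimation.** Maximum likelihood by default, because AIC and LRT
  comparisons across fixed-effect structures require it; REML is
  available and recorded. Wald 95% intervals are estimate ± 1.96 se —
  with thousands of calls the normal quantile is indistinguishable
  from any small-sample correction — and an interval excluding zero is
  flagged a strong effect. A covariate with zero variance in the data
  is dropped with an explicit message, never silently.
* **Model choice.** `compare_models()` tabulates AIC (recomputed as
  $2k - 2\ell$), flags the lowest, notes whether its lead exceeds 2
  units, and runs likelihood-ratio tests along the nested ladder only;
  it refuses LRTs across non-nested pairs, different data, or REML
  fits.

## Numerical choices

* Variance components are bounded at zero; boundary (singular) fits
  are legal outcomes, recorded but not warned into noise.
* The eq6 likelihood surface can trap a single optimizer in a local
  optimum below the nested eq5 optimum. `fit_complex()` therefore fits
  with both of lme4's standard optimizers (nloptwrap, then bobyqa with
  an enlarged evaluation budget) and keeps the better likelihood.
  Log-likelihood nesting along the ladder is asserted in the tests to
  a 1e-6 tolerance: at a boundary optimum the two models agree only to
  optimizer precision (~1e-12), and bit-exact ordering is not
  meaningful.
* Convergence status is carried per fit (`$converged`), so
  non-convergence is an explicit reported state rather than a dropped
  replicate; `recovery_experiment()` counts failures instead of
  discarding them.
* `fit_simple(zero_variance = TRUE)` evaluates the mixed model with
  every random-effect variance pinned at 0 — the boundary where
  generalised least squares coincides with OLS — which the tests
  compare against the closed-form normal-equations solution to 1e-8.
  A constant response (zero total variance) degenerates the Gaussian
  likelihood; the limiting fit (zero slope, exact interpolation) is
  returned with a warning.

## The synthetic-data generator

`generate_dataset()` draws a full study with known truth: populations,
groups of varying size, individuals with sex, age, and latent
dominance/affiliation covariates; per-call log-durations

$$\ln y = \ln a + \big(b + \beta_{\text{int}}^\top z_i + u_i^{(s)}\big)\ln x
  + c\,x + \beta_{\text{main}}^\top z_i + u_{\text{pop}} + u_{\text{grp}}
  + u_{\text{ind}} + u_{\text{seq}} + \varepsilon,$$

i.e. exactly the generative reading of the eq6 model; calls are then
laid on a timeline (default 0.3 s of silence within sequences, 3 s
between — safely above the 1 s threshold so segmentation inverts the
generator exactly) and optionally written out as Audacity label files,
so ingest and segmentation are exercised end to end, not just the
model code. `generate_interactions()` supplies matching focal logs: a
winner drawn with logistic probability in the latent rank gap, and
Poisson affiliative events per dyad.

Defaults describe a realistic captive-corvid study and are fixed once:
2 populations, 6 groups, 30 individuals, 120 sequences each, singleton
fraction 0.15, multi-call sequence lengths 2 + Geometric with mean
3.25 calls (matching the roughly 12,000-calls-over-3,700-sequences
scale of a multi-year study of this kind), $a = 1$, $b = -0.5$,
$c = 0$, and log-scale standard deviations 0.1 (population), 0.1
(group), 0.2 (individual), 0.1 (sequence), 0.3 (residual). Durations
get a 1 ms floor so logs stay finite under extreme noise draws; label
files carry nine decimal places so the text round trip preserves
durations to 1e-9 s. A single integer seed drives one random stream in
a fixed draw order, so outputs are byte-identical across runs.

What the generator does *not* emulate — and therefore what passing
tests cannot certify about real data: acoustic measurement error in
the annotations themselves, call-type structure (all calls are drawn
from one law), observer effects on when recordings happen,
autocorrelation of duration within a sequence beyond the shared
intercept, and non-Gaussian duration tails. Recovery results say the
estimator is correct under its own model, at realistic scale; they are
not evidence that any particular species obeys the law.

## Validation design

The test suite ties every stage to an independent oracle: hand-built
label files for the readers; the generator's own bookkeeping for
segmentation (exact partition equality, including the
exactly-at-threshold boundary case); an in-test re-implementation of
the sequential update for Elo; closed-form results for CSI
normalisation; the normal equations for every OLS limit. At study
scale (30 individuals, ~3,600 generated sequences per replicate) the
package runs 100-replicate recovery and null-control experiments: the
slope estimator shows |bias| < 0.02 with Wald coverage inside
[0.89, 0.99], and with $b = 0$ the interval excludes zero in no more
than 10% of replicates. Problem sizes in the routine tests are scaled
to what those checks need, not more: segmentation properties on
~1,000-call datasets, model-structure checks on ~500–1,700-call
datasets, the two 100-replicate experiments at full study scale.

## Known limitations

* The complex models assume the covariates are constant within an
  individual over the analysis window (or supplied per recording date
  via membership intervals); rapidly changing group compositions are
  only captured if the call table carries session dates.
* Elo here is the plain sequential rating: no randomised-order
  repeatability, no hierarchy-steepness diagnostics.
* The CSI dyadic-time approximation (minimum of the two focal times)
  biases rates upward for very unevenly observed dyads; supply true
  dyadic observation times when they exist.
* Cross-subspecies comparison of law strength is out of scope by
  design; the simple model is fit per subspecies and no pooled
  contrast is offered.
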