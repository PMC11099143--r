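---
title: "Modeling approach-avoidance arbitration under threat with bradycardia states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling approach-avoidance arbitration under threat with bradycardia states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patsim)
```

## The task and the scientific question

In an approach-avoidance conflict task, a player decides on every trial
whether to approach a target that carries both a potential monetary reward
(1--5 euros) and a potential threat (1--5 electrical shocks). Approaching is
risky but potentially profitable: it yields the money with probability 0.40,
the shocks with probability 0.40, and nothing otherwise. Avoiding is safe
but unprofitable: nothing with probability 0.80, money or shocks with
probability 0.10 each. A third factor, the *action context*, manipulates
whether approaching requires a button press (active context) or withholding
one (passive context), crossing the value question with a motor one.

While a player anticipates the target, threat typically induces a
freezing-like state marked by heart-rate deceleration (*bradycardia*). The
question this package operationalizes is whether that transient cardiac
state relates, trial by trial, to how reward and threat are weighed in the
approach-avoidance decision -- and how to build fMRI regressors that can
localize such state-value interactions.

Because real recordings of this task are access-restricted, everything here
runs on a generative simulator whose structure mirrors the task design. The
simulator is first-class, tested code: the package's empirical claims are
claims about *recovery* -- that the analysis chain retrieves the parameters
the generator used.

## The decision-value model family

Choices are modeled through a trial-wise decision value $DV$, mapped to an
approach probability by the logistic function
$p(\text{approach}) = 1/(1 + e^{-DV})$. The base model is

$$DV = \beta_0 + \beta_m m + \beta_s s + \beta_{m:s}\, m s + \beta_{ac}\, ac
 + \beta_{hr}\, \Delta hr + \beta_{m:ac}\, m\, ac + \beta_{s:ac}\, s\, ac,$$

where $m$ and $s$ are the standardized money and shock levels, $ac$ is the
sum-coded action context ($-1$ active, $+1$ passive) and $\Delta hr$ is the
standardized bradycardia index. Three *freezing* variants add exactly one
interaction with $\Delta hr$:

* **AV** (aversive value): $\beta_{s:hr}\, s\, \Delta hr$ -- bradycardia
  modulates threat sensitivity;
* **VC** (value comparison): $\beta_{ms:hr}\, \Delta ms\, \Delta hr$ with
  $\Delta ms = m - s$ computed on the raw levels before standardization --
  bradycardia modulates the reward-threat comparison;
* **AI** (action invigoration): $\beta_{ac:hr}\, ac\, \Delta hr$ --
  bradycardia modulates the tendency to respond actively.

`pat_group_params()` ships the group-level coefficient rows used to
parameterize simulation agents and regressors, e.g.

```{r}
pat_group_params("av")
```

Because each variant differs from the base model by one term, their DV
vectors are nearly collinear (per-subject rank correlations around 0.998 at
these coefficients). The model-based regressor module therefore works with
difference scores $DV_{diff} = DV_{base} - DV_{freezing}$, which isolate the
added interaction and decorrelate the regressors (mean $|\rho|$ well below
0.1 when $\Delta hr$ is independent of the conditions).

## The bradycardia index

`simulate_cardiac()` draws a latent trial-wise deceleration
$\delta_{it} \sim N(\bar\delta + u_i, \sigma_{trial})$, with
$u_i \sim N(0, \sigma_{subject})$, independent of the trial conditions, and
renders it as beat times: the instantaneous rate sits at the subject's
baseline before the anticipation onset, ramps linearly to baseline
$+\, \delta_{it}$ over the first 5 s of the anticipation window, and stays
flat thereafter. Defaults: $\bar\delta = -1.77$ BPM,
$\sigma_{subject} = 1$ BPM, $\sigma_{trial} = 2$ BPM, baseline
$70 \pm 7$ BPM. The 5 s ramp-to-plateau shape is a modeling choice: the
cardiac response is known to develop slowly, which is also why only trials
with long (6--7 s) anticipation intervals enter analyses.

Preprocessing inverts this: inter-beat intervals become BPM ($60/IBI$,
timestamped at the interval's second beat, linearly interpolated to a 10 Hz
grid), and the index is

$$\Delta hr = \overline{BPM}_{[5,7]\,\text{s after onset}} -
  \overline{BPM}_{[-1,0]\,\text{s before onset}}.$$

The second-beat timestamp convention lags the true instantaneous rate by up
to one beat, so a noiseless round trip recovers $\delta_{it}$ to about
0.03 BPM rather than exactly; the generator assigns each inter-beat interval
from the rate at the interval midpoint specifically to keep this
discretization bias small. Tests assert recovery within 0.1 BPM.

Quality control flags trials whose windows are uncovered or whose IBIs fall
outside $[0.33, 2]$ s; since every IBI is also the gap between consecutive
BPM samples, that single bound covers both artifact criteria. Exclusions
drop short-anticipation trials, flagged trials, and active responses faster
than 200 ms.

## Standardization conventions

All continuous predictors are mean-centered and scaled *across* subjects on
the pooled post-exclusion analysis set, using the population SD (so balanced
1--5 levels map onto $\{\pm 1.414, \pm 0.707, 0\}$ exactly). $\Delta ms$ is
differenced on raw levels first, then standardized; the across-vs-within
subject pooling and the after-differencing choice are design decisions,
frozen as an attribute so regressor construction reuses the identical
transform. The simulator standardizes its own bradycardia input the same
way, which makes generator and fitter scales consistent by construction.

## Fitting, inference, and comparison

The default fitter is pooled maximum likelihood: one Bernoulli/logit
likelihood over all trials of all subjects, maximized by iteratively
reweighted least squares, with probabilities clamped at $10^{-12}$ inside
the log-likelihood and quasi-separation flagged (estimates clamped at
$\pm 25$ on the logit scale, never silently). Uncertainty comes from a
nonparametric bootstrap over subjects (default 500 resamples). A
hierarchical alternative (`method = "hierarchical"`) fits the same fixed
effects with per-subject random intercepts and uncorrelated slopes via
`lme4::glmer`, drawing approximate posterior samples from the asymptotic
normal; it is held to reproduce pooled point estimates within bootstrap
uncertainty on data generated without random effects. Maximal
random-effect correlation structures are out of scope.

Interval inference follows highest-density-interval conventions: the HDI is
the narrowest contiguous window containing the requested mass of the
samples; an effect is *significant* when the 95% HDI excludes zero and
*marginally significant* when only the 90% HDI does. Model comparison uses
AIC for pooled fits, with parameter-count tie-breaks.

The response-time model is a shifted log-normal,
$RT = \text{shift} + e^{N(\mu, \sigma)}$, with $\mu$ linear in the full
money $\times$ shocks $\times$ choice $\times$ $\Delta hr$ interaction set,
fitted only on trials with an active response. With a known shift the
location coefficients are exact least squares on $\log(RT - \text{shift})$;
an unknown shift is profiled over a 50-point grid on $[0, \min RT)$. The
heart-rate condition model is a Gaussian linear model of $\Delta hr$ on the
money $\times$ shocks $\times$ context set; with balanced sum-coded
predictors its intercept estimates the grand anticipatory deceleration.

## What the generator does and does not emulate

The generator reproduces the *statistical structure* the analysis assumes:
factorial balance (each run holds the full 5$\times$5$\times$2 factorial of
long trials once, plus 12 short fillers drawn without replacement from the
factorial cells, preserving marginal balance), the outcome contingencies,
condition-independent bradycardia, logistic choices, and log-normal RTs.
Generator defaults not fixed by the task design are package choices:
per-subject random coefficient deviations default to SD
$= 0.5\,|\text{group coefficient}|$ (recovery experiments switch them off),
the RT shift defaults to 0.2 s with $\sigma = 0.25$ on the log scale, and
the RT location slopes default to the reported group effects.

It does *not* emulate raw photoplethysmogram waveforms, MR or respiratory
artifacts, visual rendering, skin conductance or pupil channels, serial
dependencies across trials, or any misspecification between the choice
model and the data-generating process. Passing recovery tests therefore
demonstrates the internal consistency and statistical correctness of the
analysis chain -- not that the model family is the true model of any real
dataset.

## Model-based regressor construction

`build_design_matrix()` works at a 0.1 s microtime resolution: boxcars over
the event durations, each parametric modulator demeaned across its events
(the orthogonalization with respect to the unmodulated regressor -- there
is deliberately *no* serial orthogonalization among modulators, so shared
variance is attributed to the error term), convolution with the canonical
double-gamma HRF (response delay 6 s, undershoot delay 16 s, dispersions
1 s, undershoot ratio 1/6, unit peak; implemented peak at 5.0 s),
downsampling to the TR = 1.5 s grid, and a discrete-cosine drift set up to
the 1/128 Hz high-pass cutoff. Demeaning happens per run; per-subject
demeaning is a plausible alternative the package does not implement.
AR(1) noise modeling is omitted -- synthetic-BOLD recovery uses ordinary
least squares, which is exact at zero noise and unbiased under the white
noise the simulator produces.

Sign-splitting of a difference regressor assigns strictly positive and
strictly negative trials to separate modulators; exactly-zero scores join
neither (the boundary assignment is a package decision). Correlation
diagnostics use Spearman rank correlations per subject throughout,
averaged across subjects.

## Numerical choices and degenerate inputs

* Probability clamping at $10^{-12}$; logit estimates clamped at $\pm 25$
  only when separation is detected, with a warning.
* IRLS convergence at $10^{-10}$ on the max coefficient change, 100
  iteration cap; weights floored at $10^{-10}$.
* HDIs require at least 100 samples; constant samples give a zero-width
  interval.
* Empty analysis sets are legal for the exclusion report (everything
  excluded) but an error for the fitters.
* All simulator entry points require an explicit seed; the pipeline derives
  per-stage seeds from one root seed, making bundles bit-identical under
  identical configuration.

## Problem sizes

Unit tests run on small designs (tens of subjects, 100--150 trials).
Recovery experiments use 300 subjects $\times$ 150 trials per replicate for
choice and RT models, averaging estimates over 5 replicates in the
acceptance script to damp simulation noise at fixed design size, and 58
subjects $\times$ 150 trials for the heart-rate model and regressor
diagnostics -- the scale of the study the task design comes from. These
sizes are the package's chosen trade-off between Monte-Carlo error and
runtime.

## Known limitations

* Pooled maximum likelihood ignores between-subject heterogeneity; on data
  with strong random effects its interval coverage degrades (the bootstrap
  over subjects mitigates, not removes, this). The hierarchical method is
  the antidote but is slower and only loosely mirrors a fully Bayesian
  treatment.
* The bradycardia trace model is a deterministic ramp plus white beat
  noise; real cardiac dynamics include respiratory sinus arrhythmia and
  slow drifts the quality rules can only partially stand in for.
* AIC-based comparison of the freezing models is a stand-in metric; with
  the small printed interaction coefficients the four models fit simulated
  data nearly equally well, so comparison results on realistic effect
  sizes are expected to be close calls, and ranking claims on real data
  are not made.
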