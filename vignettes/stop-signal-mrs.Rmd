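---
title: "Modelling response inhibition and its neurochemical correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling response inhibition and its neurochemical correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In the stop-signal task a participant prepares a left/right choice response
to an arrow and must occasionally cancel it when the arrow changes colour
after a variable stop-signal delay (SSD). The latency of the covert
cancellation process — the stop-signal reaction time (SSRT) — indexes
response inhibition and rises in disinhibited clinical populations such as
behavioural-variant frontotemporal dementia and progressive supranuclear
palsy. `stopsig` implements a complete analysis chain for studies that
relate SSRT to neurochemistry measured by MR spectroscopy (MRS): task
simulation, hierarchical Bayesian estimation of a race model, CRLB-weighted
covariate correction of metabolite concentrations, and a Bayesian
correlation decision procedure.

# The race model

Every trial is a race between three independent runners with ex-Gaussian
finishing times (Normal(mu, sigma) + Exponential(tau)):

* a go runner **matching** the stimulus,
* a go runner **mismatching** the stimulus (choice errors),
* a **stop** runner that starts at the SSD on stop trials (and at delay
  zero on no-go trials).

Two attentional failure mixtures complete the model: with probability
`p_gf` the go processes fail to start (producing omissions on any trial),
and with probability `p_tf` the stop process fails to start ("trigger
failure"), in which case a stop trial cannot be inhibited. A response is
emitted by the first go runner to finish unless the stop runner finishes
first. That gives 11 free parameters per participant. SSRT is defined as
`mu_stop + tau_stop`, the mean finishing time of the stop process, so the
model yields a full posterior distribution of SSRT rather than a point
estimate, uncontaminated by attentional failures.

The likelihood of each observed trial outcome is in `loglik_trials()`; the
only non-closed-form piece is the probability that the stop runner beats
both go runners,
`integral f_stop(u - d) S_match(u) S_mismatch(u) du`,
which we evaluate by Gauss–Legendre quadrature over the effective
support of the stop runner (`mu - 10 sigma` to `mu + 15 (sigma + tau)`):
64 nodes in the exported likelihood functions (error about 1e-9 in the
log-likelihood against adaptive quadrature) and 32 nodes inside the
sampler (error about 1e-5, far below posterior Monte-Carlo error); the
mass outside the truncation is below 3e-7. The normal CDF is computed via
`erfc` with an asymptotic log-tail expansion, and underflowing
intermediates are flushed to zero — subnormal arithmetic is both
meaningless here and disproportionately slow. Per-trial probabilities that underflow are floored at
log = -745 and counted (`n_floor`), so the sampler never sees non-finite
values. Responses with RT at or below the SSD are legal: the stop-survival
factor evaluates to one there. Omissions on go trials are attributed
entirely to go failure — the simulator has no response deadline, so
simulation and likelihood describe the same generative process.

# Task engine

The default session is five blocks of 120 trials: 450 go, 51 no-go and 99
stop trials, the first 20 trials of every block being go trials used only
to initialise the staircase (they are excluded from the likelihood, as is
the 20-trial practice block). The SSD follows a one-up-one-down staircase
targeting 50% cumulative stop accuracy. Design choices the task
description leaves open, fixed here once:

* staircase step 0.05 s on bounds [0, 1.5] s — the standard 50%-tracking
  configuration;
* the starting SSD of each block is the mean of the block's
  initialisation-go RTs minus 0.25 s (clipped to the bounds), which places
  the first stop signal comfortably inside the go RT distribution; if all
  20 trials were omitted the default 0.25 s is used with a warning;
* the staircase restarts each block (the per-block initialisation trials
  imply a per-block restart); no-go trials carry SSD 0 and do not move it;
* left/right stimuli are balanced within one trial and assigned by a
  seeded shuffle; stop and no-go trials also carry a balanced stimulus
  side, which the likelihood needs to tell matching from mismatching
  responses (the session TSV therefore includes a `stimulus` column).

# Hierarchical estimation

Participant-level parameters are modelled as draws from group-level
truncated-normal distributions (normal on the probit scale for the two
failure probabilities), fitted separately per diagnostic group. Location
priors are weakly informative, with means of 1.5 s for the go runners' mu
and 1.0 s for the stop runner's mu — deliberately slow, appropriate for
older and clinical cohorts — 0.1 s and 0.2 s for sigma and tau, and -1.5
(probit) for the failure probabilities. Group scales have half-normal(0.5)
priors truncated to [0.01, 3]: group SDs under 10 ms (or 0.01 probit) are
below any meaningful resolution of the task and degenerate the hierarchy.
The exact prior scales are configurable and logged with every fit.

Sampling is differential-evolution MCMC: 33 chains by default (three per
parameter), thinning of every 10th sample, and a 5% per-iteration
probability of a migration sweep that cyclically swaps whole states among
a random subset of chains. Crossover proposals
`x* = x + gamma (x_a - x_b) + eps` use `gamma = 2.38 / sqrt(2 d)` scaled
by a uniform(0.5, 1) factor. Four additions keep the ensemble healthy,
all standard remedies for Metropolis samplers of hierarchical
evidence-accumulation models:

* chains start at each participant's penalised maximum a posteriori point
  (a short Nelder–Mead run of the session likelihood with a very weak pull
  to the prior locations), jittered at roughly the posterior scale;
* a 15% mixture of random-walk moves whose step sizes do not depend on the
  ensemble spread, so the population can never collapse into a state where
  all crossover proposals are degenerate;
* dedicated "ridge" moves: with limited stop trials each runner's mu and
  tau are only weakly identified along `mu + tau = const`, so proposals
  include anti-correlated (mu, tau) components, the group locations get
  joint (loc_mu down, loc_tau up) blocks, and an occasional global move
  shifts a runner's mu/tau for every participant and the group location
  together. Without these the sampler equilibrates extremely slowly along
  that ridge, biasing the mu/tau split (although not their sum, the SSRT);
* the two failure probabilities are sampled non-centred: participants
  carry standardised deviations `z` with `probit(p) = loc + scale * z`,
  and the group (location, scale) pair moves in a joint block with the
  likelihood re-evaluated. This removes the hierarchical funnel for the
  two parameters the data inform least.

Burn-in proceeds in blocks gated by the split-chain potential scale
reduction statistic R-hat (< 1.1 for every group- and participant-level
parameter), replacing visual inspection of trace plots; trace plots remain
available via `autoplot(fit, type = "trace")`. After the gate passes, 500
thinned iterations per chain (by default) form the posterior. An
adaptation phase precedes burn-in: participants first differentiate under
a broad fixed group level, after which group locations and scales are
re-seeded from the realised participant spread.

Model adequacy is checked with `posterior_predictive()`: sessions are
re-simulated from random retained draws through the full task engine and
compared with the observed go RT deciles, stop accuracy (overall and by
SSD band) and error/omission rates.

# MRS correction and group comparison

Water-scaled metabolite concentrations are corrected per (region,
metabolite) with a weighted linear model — age (centred), sex (single
indicator) and tissue fractions; grey and white matter for glutamate, grey
matter for GABA — weighted by `1 / CRLB^2`, reading the Cramér–Rao lower
bound as a percent standard deviation (a `1 / CRLB` option is provided).
Diagnostic group is deliberately excluded from the design so that group
differences survive in the residuals, which carry all further analysis.
The model is fitted per region (pooling regions is a switchable
alternative; per-region is the default because voxel composition and
spectral quality differ systematically between regions). Constant
covariates are dropped, in which case the correction degrades gracefully
to subtracting the weighted mean. A two-sided single-outlier Grubbs test
(`grubbs_outlier()`) screens each cell at alpha = 0.05.

Group comparison uses a mixed ANOVA with region as the within-subject
factor and diagnosis between subjects, Tukey-adjusted pairwise contrasts,
and simple main effects of diagnosis per region as one-way F tests.

# Brain–behaviour association

For each retained SSRT posterior draw, `posterior_correlation()` computes
the Spearman correlation across participants between that draw and the
corrected metabolite level, giving a posterior distribution of plausible
correlation values (one correlation per retained draw). It is summarised
by the 95% highest density interval — the sample-based shortest interval,
ties broken toward the earlier window — and a region of practical
equivalence (ROPE) of Spearman R in (-0.1, 0.1), a small effect size. The
null is rejected when HDI and ROPE do not overlap; an HDI inside the ROPE
is practical equivalence; anything else is undecided. The association is
computed within the patient group by default (the study design reports the
control analysis separately as null); the same machinery runs specificity
screens against trigger-failure draws and any other metabolites present.

A caution that the package's own calibration experiments make explicit:
the HDI/ROPE rule on a correlation posterior of this kind is **not** a
frequentist test. The spread of the correlation distribution reflects the
SSRT posterior uncertainty, not primarily the sampling variability of a
correlation at the study's n, so with tight SSRT posteriors and ~30
participants the rule rejects a true null appreciably more often than 5%.
The package reproduces the published decision procedure; interpret
verdicts accordingly.

# The synthetic cohort

Because no participant-level data are distributable, `cohort_spec()`
defines a generator that emulates the study's statistical structure; it is
the ground truth for every end-to-end test. Defaults, chosen once:

* 33 patients, 20 controls; ages ~N(66, 7) and balanced sex, identical
  across groups (age- and sex-matched by construction);
* race parameters drawn from group truncated normals with a slower, more
  variable stop runner and more frequent attentional failures in patients
  (group-mean SSRT 0.40 s vs 0.25 s, spanning published patient/control
  values for these tasks);
* metabolite concentrations built from a baseline plus age, sex and
  tissue-fraction effects, a patient deficit confined to right inferior
  frontal gyrus GABA, and negative coupling
  between frontal metabolite levels and the **true** SSRT within patients
  only (point Spearman near -0.5), so that recovery error is attributable
  to inference, not the generator; the occipital control region gets
  neither deficit nor coupling;
* CRLB values drawn per group/region/metabolite around published
  spectral-quality means (frontal GABA ~9.4% in controls vs ~12.3% in
  patients), with residual noise scaled by each record's CRLB — making the
  inverse-CRLB-squared weighting of the correction efficient by
  construction; patients get lower grey-matter fractions (atrophy).

The frontal GABA deficit (0.38 concentration units) is calibrated so that
the *post-correction* group effect size at n = 53 sits at about d = 0.9,
inside the range the published evidence implies: the pooled F(1) statistic
of 8.67 at these group sizes corresponds to d of about 0.84, and the
subgroup comparisons (t of 2.9 and 2.4 at smaller n) to d up to about 1.0.
The upper part of that range is used so that the deficit is detected
stably rather than with coin-flip power at the study's sample size. The
calibration must be done on corrected values: because patients have lower
grey-matter fractions, the pooled tissue-fraction coefficient absorbs a
substantial share of any injected raw deficit (the same type-II-error
concern the partial-volume literature raises for this correction), and the
CRLB-scaled noise makes patient residuals more variable than controls'.

What the generator does **not** emulate: RT sequential effects
(post-error slowing, fatigue), response deadlines, within-session
parameter drift, non-ex-Gaussian contamination, voxel misregistration, or
correlated metabolite panels. Passing tests therefore demonstrate that the
estimation machinery recovers the structure this model family assumes —
not that real clinical data satisfy those assumptions.

`apply_exclusions()` mirrors the study's handling: participants with fewer
than 50 analysable stop trials leave the behavioural analyses but remain
in the metabolite group comparison, with every exclusion logged.

# Problem sizes and presets

`run_study()` wires the stages together behind three presets. `paper` is
the configuration the method is described with (full cohort and task, 33
chains, thinning 10, 500 retained draws) and is CPU-hours heavy; `demo`
keeps the full cohort and task but a lighter schedule (13 chains, thinning
2, 300 retained draws) sized to finish in minutes, which leaves the
scientific pattern intact because the verdicts depend on posterior
location and spread, not on draw count beyond a few hundred; `ci` is an
8 + 8 cohort with 300-trial sessions for smoke tests.

The packaged parameter-recovery study uses 8 participants x 300-trial
sessions that keep the full design's number of stop trials (100 per
participant; only go trials are reduced), 13 chains and a schedule of a
few thousand iterations per replicate. Its results are instructive about
the model rather than flattering to it: each participant's SSRT and the
group-level SSRT location are recovered well, but the mu/tau split of the
stop runner is volume- and prior-dominated at feasible trial counts — even
fully converged reference runs place the group mu_stop location below its
generating value while tau_stop absorbs the difference. Studies needing
the split itself (rather than SSRT) would need far more stop trials or
informative priors on tau_stop. The slowest-mixing coordinates (the
failure probabilities and the stop runner's mu/tau ridge) also keep the
split-chain R-hat above 1.1 at short schedules even when the SSRT-level
summaries are stable.

The `pipeline` surface is the exported functions plus
`scripts/acceptance.R`; there is no separate shell tool because the
package's users drive it from R.

# Known limitations

* The mu/tau decomposition of the stop runner needs many stop trials; at
  ~50 per participant only their sum (SSRT) is sharply identified.
* The ROPE decision rule is not calibrated as a frequentist test (above).
* The sampler is a single-CPU R/C++ implementation; very large cohorts
  call for the `demo`-style schedules rather than the `paper` one.
* Group-level scales are bounded below at 0.01 as a modelling choice;
  studies of truly homogeneous populations would need to revisit it.
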