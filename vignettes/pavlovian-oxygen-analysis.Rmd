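---
title: "Modelling Pavlovian learning and its haemodynamic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Pavlovian learning and its haemodynamic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pavlovo2` implements a complete, reproducible analysis pipeline for
probabilistic Pavlovian conditioning experiments in which tissue-oxygen
(T~O2~) amperometry signals are recorded from nucleus accumbens (NAc) and
orbitofrontal cortex (OFC) while rats learn that two auditory cues predict
reward with different probabilities. This vignette explains the models and
procedures, the assumptions behind them, and the choices made where a
published description leaves the design open.

```{r setup, message = FALSE}
library(pavlovo2)
library(dplyr)
```

## The task and its simulator

Each session presents 56 ten-second auditory cues: 28 CS~High~ trials
rewarded on exactly 75% (21/28) and 28 CS~Low~ trials rewarded on exactly
25% (7/28), with the outcome (pellet delivery or omission) at cue offset
and inter-trial intervals drawn uniformly from 30–60 s (mean 45 s).
Training runs for nine sessions; session 9 doubles as the pre-drug
reference day and session 10 is an acute drug challenge (vehicle or an
amphetamine-like treatment). Cue identity is counterbalanced: in group
CL1–T2 the clicker is the CS~High~, in group T1–C2 the tone is.

Two points are worth flagging as our own choices:

* **Exact-proportion rewards.** A "75% rewarded" cue could be implemented
  per-trial (Bernoulli) or per-session (exactly 21 of 28). We enforce
  exact per-session counts so that every downstream quantity that depends
  on reward frequency is deterministic given a seed; a Bernoulli variant
  would only add between-session variance without changing any estimand.
* **ITI law.** Only the mean (45 s) and range (30–60 s) are specified;
  we use the uniform distribution on that range, the maximum-entropy
  choice consistent with both.

```{r schedule}
sched <- generate_schedule(1, "CL1_T2", "training", seed = 7)
table(sched$cue, sched$rewarded)
```

## The generative learning agent

Behaviour is simulated by a Rescorla–Wagner agent that mirrors the richest
model in the fitted grid. The value of the presented cue is updated each
trial by

$$V \leftarrow V + \alpha\,\beta_{\mathrm{sound}}\,(r - V),$$

with $\beta_{\mathrm{tone}} \equiv 1$ and $\beta_{\mathrm{clicker}}$ a
salience multiplier (clickers are typically more arousing than pure
tones, and the agent's population defaults make clicker salience and
clicker unconditioned responding larger than the tone's). Values start at
0 for both cues — naive animals — and carry across sessions.

The emitted cue-period head-entry rate is

$$\mathrm{rate}(t) = \max\{0,\; g\,V_{\mathrm{cue}}(t) + k_{\mathrm{sound}}
  + b(t) + \varepsilon_t\},$$

where $g$ is a response gain, $k$ a cue-specific unconditioned responding
constant, $b(t)$ a recency-weighted smooth of the pre-cue rates
($b(t) = \gamma b(t-1) + (1-\gamma)\,\mathrm{rate}_{\mathrm{pre}}(t-1)$),
and $\varepsilon_t$ Gaussian noise truncated so rates stay non-negative.
Pre-cue rates come from a stationary truncated-Gaussian baseline process.
A continuous truncated-Gaussian emission (rather than Poisson counts) was
chosen to match the Gaussian likelihood used in fitting; nothing in the
pipeline depends on the emission being integer-valued.

On an amphetamine session, cue discrimination collapses: expressed values
are shrunk toward the two cues' mean by the fraction `drug_effect`
($V_{\mathrm{eff}} = \bar V + (1-d)(V - \bar V)$), applied to both the
behavioural gain term and the neural event amplitudes, and CS~Low~
outcome amplitudes are additionally blunted toward zero by the same
fraction. Learning itself is left intact — the drug alters expression,
not the stored associations — which is sufficient to abolish behavioural
and neural discrimination at $d$ near 1 while keeping the simulator
simple.

## The simulated oxygen signal

Each electrode's trace is a linear event-related model:

$$y(t) = \sum_{e} a_e\, h(t - t_e) + \text{drift} + \eta(t),$$

where $h$ is a gamma-shaped haemodynamic response function with unit peak
at 4 s, 4-s FWHM and 25-s support (rodent haemodynamics peak faster than
the canonical human BOLD response), sampled at 1 Hz; $\eta$ is AR(1)
noise. Cue events carry amplitude $w_{\mathrm{cue}} V(t)$. Outcome-event
amplitudes differ by region profile:

* **NAc profile** — a signed reward prediction error,
  $a_{\mathrm{outcome}} = r(t) - V(t)$ (positive outcome weight, equal
  and opposite value weight);
* **OFC profile** — an unsigned prediction error plus positive value,
  $a_{\mathrm{outcome}} = |r(t) - V(t)| + 0.5\,r(t) + 0.5\,V(t)$.

These profiles encode the two regional hypotheses the regressions are
designed to distinguish; simulating both from shared value latents also
induces a positive cross-region correlation of cue responses, which
`cross_region_correlation()` measures.

What the simulator deliberately does **not** emulate: electrode drift and
calibration chemistry, movement artefacts, session-boundary
non-stationarities, and any nonlinearity of neurovascular coupling.
Passing the recovery tests therefore shows that the analysis pipeline is
correct and well-powered under its own assumptions — not that those
assumptions hold for any particular in-vivo recording.

## The fitted model grid

`model_grid()` contains the one-parameter standard learner, each
single-component extension, and the full model:

| component | parameters added |
|---|---|
| cue salience | $\beta_{\mathrm{clicker}}$ (tone fixed at 1) |
| split learning rates | $\alpha_{pos}, \alpha_{neg}$ (replacing $\alpha$) |
| unconditioned responding | $k$ shared, or $k_{\mathrm{clicker}}, k_{\mathrm{tone}}$ |
| pre-cue baseline | trial-specific rate, or recency smoother ($\gamma$), each with a weight $w_b$ |

All 2×2×3×3 flag combinations are constructible with `model_spec()`.
Observed cue-period rates are fitted with a Gaussian likelihood with free
$\sigma$; $\sigma$ is profiled analytically inside the optimiser (its MLE
is $\sqrt{RSS/n}$) but reported and counted as a free parameter, as are
the gain and, for baseline modes, $w_b$. The published description of
this model family does not state its likelihood or normalisation; the
Gaussian choice is ours, selected as the simplest likelihood for a
continuous non-negative rate, and the parameter count convention is
stated here precisely because BIC comparisons depend on it:

$$\mathrm{BIC} = k \ln n - 2 \ln \hat L, \qquad n = 56 \times
  \text{sessions fitted}.$$

Fitting uses bounded L-BFGS-B from 20 Latin-hypercube restarts (bounds:
$\alpha, \gamma \in (0.001, 0.999)$, $\beta \in (0.01, 10]$,
$k, g, w_b \in [0, 20]$); the restart with the lowest NLL wins, and the
whole fit is deterministic given its seed. Model comparison breaks exact
BIC ties toward the spec with fewer parameters, then grid order; the
population-preferred model minimises the summed BIC.

```{r fit, eval = FALSE}
cohort <- simulate_cohort(8, cohort_config(), seed = 1)
training <- filter(cohort$trials, session <= 9)
cmp <- compare_models(training, model_grid(), n_restarts = 20, seed = 1)
autoplot(cmp)
```

## Event-locked analyses

`cohort_auc()` applies the two model-free response measures:

* **cue window** — AUC of the baseline-corrected signal 5–10 s after cue
  onset, baselined to the mean of the 5 s before the cue. The published
  analyses do not state the baseline window; 5 s is long enough to
  average over noise yet shorter than the minimum gap to the previous
  outcome's response.
* **outcome window** — AUC over the 30 s after the outcome, normalised to
  the signal value at outcome time (so the measure is a change from the
  moment of outcome, as the outcome analyses require).

Integration is trapezoidal on the native 1-Hz grid; windows snap to
samples and no interpolation is ever used. Trials whose 30-s outcome
window would cross the next cue onset are excluded and logged (possible
only at the minimum 30-s ITI). Sessions 1–9 are partitioned into three
equal training stages (1–3, 4–6, 7–9); published analyses refer to
early/mid/late without boundaries, and an equal split is the only
symmetric choice.

## Trial-by-trial regressions

For each electrode, per-trial AUCs are regressed on latents from that
animal's fitted learning model. Response and regressors are z-scored
within each electrode–session before stacking, so coefficients are
standardized effect sizes and slow between-session drifts cannot
masquerade as trial-by-trial coding. The designs are:

* `cue_value`: cue AUC on $V(t)$;
* `outcome_rpe`: outcome AUC on $r(t)$ and $V(t-1)$ — the two components
  of the reward prediction error, with signs reported as fitted;
* `outcome_unsigned`: outcome AUC on $|r(t) - V(t-1)|$.

A signal qualifies as a reward prediction error when, across electrodes
(the unit of analysis, matching how such data are reported), three
criteria hold at the group level: a positive value effect on cue-locked
signals, a positive outcome effect, and a negative value effect on
outcome-locked signals. `rpe_criteria_check()` applies a two-sided
one-sample t-test across electrodes to each.

One definitional subtlety: the trial-level prediction error is
$\delta(t) = r(t) - V(t-1)$, but a printed composite form
$V(t) + r(t) - V(t-1)$ also circulates. The regressions use the
two-component decomposition ($r$ and $V$ as separate regressors), which
is what the criteria require; the composite form is available as the
`outcome_rpe_printed` design for anyone wanting it, and we deliberately
do not guess at which was intended where the two disagree.

`value_vs_behaviour_comparison()` asks whether model-derived value or the
animal's raw head-entry rate better predicts the cue signal, by BIC of
the two single-regressor models per electrode.

## The drug contrast

Mixed ANOVAs on real data are replaced here by a permutation
difference-of-differences test, which preserves the cue × session × drug
interaction logic while being exactly specifiable and assumption-free:
the statistic is $[\Delta\mathrm{index}]_{\mathrm{amph}} -
[\Delta\mathrm{index}]_{\mathrm{veh}}$, where the discrimination index is
mean(CS~High~) − mean(CS~Low~) and $\Delta$ is drug-session minus
pre-drug. The null permutes drug-group labels across animals; with
$\binom{n}{n_a} \le$ `n_perm` all assignments are enumerated and the
p-value is exact (for eight animals, 70 assignments, the smallest
achievable p is 1/70). The follow-up pairwise-correction procedure used
with the original ANOVAs is unspecified; the permutation framework
sidesteps it rather than guessing.

## Numerical choices and degenerate inputs

* All randomness flows from one integer master seed through
  `child_seed()`, a polynomial string hash: every animal, session,
  electrode and permutation stream is independently reproducible, and
  adding animals does not shift other streams.
* The value recursion is implemented once in C++ and shared by the
  simulator and every fitted variant; tests hold it to a plain-R loop at
  1e-12.
* Effective learning rates $\alpha\beta$ are clipped into (0, 1] so the
  salience multiplier cannot push an update out of range.
* Constant regressors (e.g. an all-rewarded session), singular designs,
  windows outside the trace, missing cues, and undersized groups all
  raise typed errors naming the problem; the pipeline driver converts
  undersized-group errors into an insufficient-n note rather than
  failing a whole run.
* With fewer than two trials in an integration window, AUC refuses
  rather than extrapolating.

## Problem sizes used by the test-suite studies

The packaged replication studies run at: 20 animals for parameter
recovery (grid of 8 models, 20 restarts); 20 seeded cohorts of 8 animals
(one NAc and one OFC electrode each, 6 restarts for the latent fits) for
the prediction-error criteria; 20 cohorts for drug-contrast power and 500
null cohorts for its size. These sizes give stable pass/fail behaviour
for the properties being checked while keeping a full run in the minutes
range on a single core.

## Known limitations

* The Gaussian rate likelihood is a modelling convenience; a count
  likelihood (Poisson emission is available in the simulator's design
  space) would be more literal for small head-entry counts.
* No hierarchical pooling across animals: each animal is fitted
  independently, as in the original analysis style.
* The drug model collapses expression of value, not learning; dissecting
  those would require a richer pharmacological model than the data this
  pipeline targets could constrain.
* Electrode exclusion, calibration and artefact handling for real
  recordings are out of scope; `read_trace()` validates structure, not
  signal quality.
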