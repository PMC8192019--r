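---
title: "The sn-Plast navigation model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sn-Plast navigation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

snplastr simulates reward-based spatial learning in a circular open field
with a spiking network whose feedforward synapses follow *sequentially
neuromodulated plasticity* (sn-Plast): during exploration, tonic
acetylcholine (ACh) turns every pre/post spike coincidence into an immediate
synaptic depression; when the agent finds the reward, a phasic dopamine (DA)
pulse retroactively potentiates recently active synapses through a decaying
eligibility trace. The package also implements the analysis pipeline that
surrounds the model: the two-stage initial/reversal protocol, grid-search
fitting of per-subject learning curves, parameter recovery, synthetic
behavioural cohorts, and trial-outcome statistics.

This vignette is the package's own account of the model and of every design
decision that was genuinely open.

## The network

**Place cells.** 121 input neurons tile the arena on an 11 × 11 square
lattice with spacing σ = 0.4 a.u., spanning [−2, 2] per axis. Cell *i* fires
as an inhomogeneous Poisson process with rate

$$\lambda_i(\mathbf{x}) = \bar\lambda\,
  e^{-\lVert \mathbf{x} - \mathbf{x}_i \rVert^2 / \sigma^2},
  \qquad \bar\lambda = 400\ \mathrm{Hz}.$$

The lattice is the unique regular construction that yields the stated count
of 121 cells at the stated spacing; the alternative phrasing of the grid as
lying on a circle of radius 6.1 a.u. is dimensionally inconsistent with
these two constraints (121 cells at 0.4 spacing span 4 a.u., and every task
coordinate has norm ≤ 2), so the arena wall is fixed at radius 2.0 — the
exact norm of both start positions — and the 6.1 figure is not used.
Whether the original lattice was clipped to a circular mask is immaterial at
this σ and is not done here.

**Action ring.** 40 output neurons each prefer a movement direction
$\mathbf{a}_j = a_0(\sin\theta_j, \cos\theta_j)$, $\theta_j = 2j\pi/N$,
$a_0 = 0.08$. They are simplified Spike Response Model neurons: the membrane
potential is a sum of EPSP kernels
$\epsilon(t) = \frac{\epsilon_0}{\tau_m - \tau_s}(e^{-t/\tau_m} -
e^{-t/\tau_s})$ over afferent spikes arriving after the neuron's own last
spike, plus a refractory kernel $\chi e^{-(t - \hat t)/\tau_m}$ with
χ = −5 mV. Spiking is stochastic with escape rate
$\lambda(u) = \lambda_0 e^{(u - \theta)/\Delta u}$ (λ₀ = 60 Hz, θ = 16 mV,
Δu = 2 mV). A neuron's own spike clears its EPSP accumulators, which
implements the "only arrivals after the last spike" summation bound online.

**Lateral connectivity.** The ring is fixed (never plastic):
$w^{lat}_{jk} = w_-/N + w_+ f(j,k)/N$ with $w_- = -300$, $w_+ = 100$, and a
symmetric similarity profile $f$ that excites neighbours and inhibits
dissimilar directions, producing a soft winner-take-all bump. The raw von
Mises profile $e^{\psi\cos\Delta\theta}$ with ψ = 20 spans nine orders of
magnitude and would produce lateral weights around 10⁹ — incompatible with
millivolt-scale membrane constants (θ = 16 mV). `build_lateral_weights()`
therefore row-normalises the profile to mean one,
$f = N e^{\psi\cos\Delta\theta} / \sum_k e^{\psi\cos\Delta\theta}$, which
preserves the stated $w_\pm$ scales, the symmetry, and the
excite-similar/inhibit-dissimilar structure, and concentrates net excitation
on roughly the two nearest neighbours each side. The raw profile remains
available via `normalise = FALSE`. This is the one place where the printed
constants could not be taken simultaneously literally; the normalisation is
the package's resolution and the winner-take-all property is tested rather
than assumed.

**Action selection and navigation.** Each neuron's firing rate is estimated
online by filtering its spike train with the normalised kernel
$\gamma(t) = (e^{-t/\tau_\gamma} - e^{-t/\nu_\gamma})/(\tau_\gamma -
\nu_\gamma)$ (τγ = 50 ms, νγ = 20 ms), so ρ is in spikes per unit time. The
displacement per time step is the population vector
$\mathbf{a}(t) = \frac1N \sum_j \rho_j \mathbf{a}_j$, applied without
further dt scaling (the printed update rule has none). At the wall the
radial component of the step is reflected; reflection preserves step length,
and floating-point overshoot is projected back onto the boundary. Synapses
from place cells within one lattice spacing of the wall onto actions
pointing outward at that cell (positive radial component, strictly) are held
at zero and excluded from plasticity — the stated boundary-effect guard,
with the boundary set taken as the minimal one-ring interpretation since no
definition is printed.

## The plasticity rule

Every pre/post spike pair contributes a coincidence mass
$W(\Delta t) = e^{-|\Delta t|/\tau}$ (τ = 10 ms), symmetric in spike order:
the neuromodulator, not the timing, sets the sign. The pairing is all-pairs
with exponential discounting, maintained online by per-neuron traces; a
simultaneous pair counts exactly once with W(0) = 1. Summed over a raster
this equals the explicit double sum over spike pairs, which the test suite
verifies to 1e−9.

With ACh present (the entire exploration phase), each step's mass is applied
immediately as depression, $\Delta w = -\eta_{ACh}\,m$. Independently, all
mass accumulates into a per-synapse eligibility trace decaying with
τₑ = 2 s. At reward, dopamine performs a single retroactive update
$\Delta w = +\eta_{DA}\, e$, then the trace is cleared. The α flag in the
eligibility definition is read literally: ACh acts instantaneously (α = 0
makes the trace factor unity), DA reads the 2-second memory (α = 1). Weights
start at $w_{in} = 2$ and are clipped to [1, 3] after every update, so the
state is always valid; masked boundary synapses stay at exactly 0 as a
documented exception to the lower bound. With η_ACh = 0 (full cholinergic
silencing) weights freeze during exploration but eligibility still
accumulates, so reward-driven learning continues.

Eligibility is cleared at trial end whether or not dopamine fired: the
inter-trial interval resets all activity but not the weights, and with
τₑ = 2 s any carryover across the interval would be physically negligible.
Dopamine is a one-shot, fixed-amplitude pulse — no reward-prediction-error
dynamics, no negative feedback on omission; those are documented extensions
of the rule, not part of it.

## The task protocol

A session is 8 days × 10 trials with well 1 at (−0.43, 0.43) baited, then
12 days × 10 trials with well 2 at (0.43, −0.43) baited (well radius 0.3).
Trials start on the wall at (−1.6, −1.2) or (1.6, 1.2), five from each side
per day in random order with at most three consecutive same-side starts
(the mouse protocol's pseudo-randomisation; a flag disables the run-length
constraint). A trial ends at reward detection plus a 300 ms consummatory
pause with place-cell activity silenced, immediately on wrong-well contact
(unrewarded), or at T_max = 15 s. Detection is evaluated once per time step
on the updated position, and additionally on the start position itself so a
trial that begins on a well terminates at t = 0. Weights persist across
trials and the stage switch; spike traces, eligibility, and all activity
reset between trials. One master seed spawns an independent substream per
trial, so any trial is reproducible in isolation.

## Units and numerical choices

* All dynamics use dt = 1 ms; kernels have 5–50 ms constants. Rates are
  converted to spikes/ms once, centrally (λ₀ = 0.06/ms internally), and the
  Bernoulli step probability at the 400 Hz place-field peak is 0.4.
* Poisson spiking is the per-step Bernoulli approximation; probabilities
  above 1 in the action layer are clipped with a saturation warning.
* The compiled trial loop truncates place-field support at 3σ, where the
  rate is below 10⁻⁴ of peak (≈ 0.05 Hz); the R-level `place_rates()` is
  exact.
* Eligibility decay in the compiled loop is maintained in a lazily rescaled
  form (one multiplication per step instead of a 121 × 40 sweep); the test
  suite pins it to the reference implementation at 1e−8.
* IRLS for the trial-outcome logistic regression converges on the
  log-likelihood at 1e−8, at most 100 iterations, with classed errors for
  rank deficiency and perfect separation (detected as degenerate fitted
  probabilities, naming the diverging column).
* Grid-fit ties are broken to the lowest η_ACh, then the lowest η_DA —
  deterministic, and conservative about cholinergic effect sizes.
* `days_to_criterion()` is reach-and-maintain: the earliest day from which
  every remaining day meets the threshold; never-reaching subjects are
  censored at stage length + 1, the worst rank for downstream rank tests.

## Fitting and its desk-scale defaults

The production grid varies η_DA over 7.5e−4 … 2.75e−3 in steps of 2e−4 and
the ratio η_ACh/η_DA over 0 … 1 in steps of 0.02 — 561 combinations — with
100 simulations per point. A simulation bank is computed once per grid and
shared by all subjects of a cohort; per iteration, the best point by RMSE on
the 20-day success curve is selected, and winners are averaged across
iterations to give the estimate and the fitted curve. Whether the original
procedure shared one bank across mice or regenerated it per mouse is not
stated; sharing is statistically equivalent and cheaper.

The package's own recovery checks run at desk scale: `reduced_grid()` keeps
every fifth ratio level and every second dopamine level (66 points) with 10
iterations, and recovery uses 20 simulated agents. These sizes were chosen
once as the scale a single workstation handles comfortably; the full
561 × 100 bank is available through `grid_spec()` defaults.

Group-level draws for power analyses use axis-aligned rectangles in
(η_DA, ratio) space. The study reports its group regions only graphically,
so the defaults are honest qualitative stand-ins: controls draw from ratios
0.10–0.55, the ACh-suppressed group from 0–0.45, over the same η_DA span.
They were calibrated once, by construction (draws only, no simulation), so
that the group difference in true η_ACh is real in expectation but a single
cohort's Kruskal–Wallis test reaches significance in only about half of the
draws — the partial-power phenomenon the original analysis reports — and
the test suite asserts that fraction stays strictly inside (0.2, 0.9).

## The synthetic cohorts, and what the tests do not show

`generate_mechanistic_cohort()` simulates subjects from region-drawn
parameters; `generate_glm_cohort()` draws trial outcomes from the
fixed-effects logistic model with Gaussian per-subject intercepts and trial
slopes. The subject-effect spreads default to sd(b₀) = 0.5 and
sd(b₄) = 0.01 — the study fits but does not print these variances, and the
defaults were picked so synthetic per-subject curves span the range seen in
individual-fit figures. The statistical calibration checks generate with the
spreads at zero, so the fixed-effects refit is correctly specified and Wald
coverage is interpretable.

Both generators emulate the *structure* of the behavioural data: the schema,
the group sizes (8/16/21), the protocol, the direction and rough size of
group effects. They do not emulate real mice: no odour cues, maze rotations,
stationarity removals, day-one handling effects, or individually
idiosyncratic strategies (the original study itself notes subjects whose
reversal behaviour the model does not explain). Passing tests therefore
demonstrate internal consistency of model + pipeline and qualitative
reproduction of the published effects, not quantitative agreement with any
animal's data. The simulated agent also differs visibly from mice in its
baseline: with two symmetric wells and wrong-well termination, a naive
agent succeeds on roughly half its trials, whereas mice start much lower —
so simulated learning curves compress the early acquisition phase.

## Emergent spontaneous activity

The action ring is a self-sustaining attractor. At rest (u = 0) the escape
rate is λ₀e^(−θ/Δu) ≈ 0.02 Hz per neuron — about 0.8 Hz across the ring —
so a spontaneous spike typically arrives within a second or two of trial
start; lateral excitation then ignites a travelling activity bump that moves
the agent even with all feedforward synapses at zero. This is a direct
consequence of the printed escape function and lateral structure, not of the
normalisation choice (the raw profile ignites far more violently). It means
"no feedforward drive" does not imply "no movement": a strict no-drive
control — used when verifying that an agent that never reaches a well times
out at exactly T_max — must silence the lateral ring as well.

## Known limitations

* The Eq-5-scale question above: the lateral profile normalisation is a
  package decision, and absolute firing-rate levels in the ring (hence
  trial latencies) depend on it. All qualitative claims tested — selective
  reversal impairment under reduced ACh, monotone ACh/reversal-speed
  relation, recovery of generating parameters, policy maps pointing at the
  learned well — are robust to it in the tested range.
* Trial-number coding in the logistic design is a running index within each
  stage by default; the decimal day.trial coding is available behind a flag
  and changes the trial coefficient's scale, not its sign.
* Mixed-effects (subject-level) estimation is deliberately out of scope:
  `subject_model_frame()` exports a model frame for lme4-style tools.
* η_DA identifiability at desk scale is limited by curve saturation; the
  recovery check's rank correlations are the honest measure of it.
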