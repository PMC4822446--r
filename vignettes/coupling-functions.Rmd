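---
title: "Inferring cross-frequency coupling functions from phase dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cross-frequency coupling functions from phase dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`oscouple` reconstructs and analyses *coupling functions* between oscillatory
physiological rhythms — cortical EEG bands (δ, θ, α, γ), respiration and the
cardiac main mode — in the phase–phase sense. This vignette is the package's
account of its model, its defaults, and the choices behind them.

## The model

Each pair of rhythms is described by two coupled stochastic phase equations

$$\dot\phi_i \;=\; \omega_i \;+\; q_i(\phi_i, \phi_j) \;+\; \xi_i(t),
\qquad i \ne j \in \{1, 2\},$$

where $\omega_i$ is the natural frequency, $q_i$ the deterministic coupling
function and $\xi_i$ Gaussian white noise with
$\langle \xi_i(t)\,\xi_j(\tau)\rangle = \delta(t-\tau) D_{ij}$. Because
$q_i$ is $2\pi$-periodic in both arguments it is expanded in a truncated
Fourier basis, $\sin(k\phi_i + l\phi_j)$ and $\cos(k\phi_i + l\phi_j)$ with
$|k|, |l| \le K$ and one representative per $\pm(k,l)$ sign pair
($k > 0$, or $k = 0, l > 0$). The default order $K = 2$ gives 25 terms per
equation. The constant term carries $\omega_i$. The enumeration order
(constant first, lexicographic $(k,l)$, sin before cos) is arbitrary but
frozen, so parameter indices are stable across runs and serialisations; any
complete order-$K$ set up to sign equivalence spans the same space.

Every trigonometric term has exactly one role in the equation of the target
oscillator $i$:

* **self** ($l = 0$): dependence on the target's own phase;
* **direct** ($k = 0$): unidirectional driving by the other phase alone;
* **indirect** ($k \ne 0, l \ne 0$): joint ("common") dependence, including
  diffusive phase-difference terms such as $\sin(\phi_j - \phi_i)$.

The conceptual motivation for the direct/indirect split is the factorisation
of a coupling function into a phase response curve and a perturbation
function: a constant phase-response component yields pure direct driving,
while any phase dependence of the response yields joint terms. The package
implements the split as an orthogonal partition of basis terms, not as a
function factorisation — the two subsets are disjoint, so the Euclidean
norms satisfy $\|{\rm net}\|^2 = \|{\rm direct}\|^2 + \|{\rm indirect}\|^2$
exactly.

## Phase extraction

Raw channels (EEG, thorax respiration, ECG) are turned into invariant phases
band by band:

1. **Zero-phase FIR band-pass** (`bandpass()`): windowed-sinc (Hamming)
   design applied forward and backward, so no phase lag is introduced.
   Published pipelines rarely state a filter order; here it is
   tied to the slow band edge, $\lceil 3 \cdot \text{rate} / f_{lo} \rceil$
   taps (capped at 10% of the signal length), which keeps at least three
   cycles of the slowest passband component inside the impulse response.
   Band boundaries are preloaded in `band_registry()`: δ 0.8–4, θ 4–7.5,
   α 7.5–14, β 14–22, γ 22–100, respiration 0.145–0.6, cardiac 0.6–2 Hz.
   The cardiac phase is obtained by band-filtering the ECG around the
   ~1 Hz main oscillation mode rather than by R-peak detection: this keeps
   intra-cycle phase resolution, at the cost of discarding slow heart-rate
   variability, which is not the object here.
2. **Hilbert protophase** (`hilbert_protophase()`): the unwrapped angle of
   the FFT-based analytic signal.
3. **Protophase-to-phase transformation** (`protophase_to_phase()`): the
   protophase depends on the observable; the invariant phase is obtained by
   the monotone circle map built from the Fourier coefficients
   $S_n = \langle e^{-in\theta}\rangle$ of the wrapped protophase
   distribution,
   $\phi(\theta)=\theta+2\sum_{n=1}^{N_F}
   \mathrm{Re}[S_n(e^{in\theta}-1)/(in)]$,
   which makes the phase density uniform. $N_F = 24$ harmonics by default —
   enough to resolve realistic protophase distortions while keeping the
   map smooth; it is configurable. Because the correction is
   $2\pi$-periodic, cycle counts are preserved exactly.
4. **Edge trimming**: $\lceil 2 / f_{lo}\rceil$ seconds are dropped at each
   end after the Hilbert transform, where filter and analytic-signal
   transients live. For the respiration band this is 14 s per end, so
   recordings should exceed the analysis windows by at least half a minute.

`extract_phase()` chains all four steps. For inference, each pair of phases
is linearly interpolated onto a common grid at 10× the faster band's centre
frequency, capped at 120 Hz (`run_config(pair_rate_cap = )`). The cap keeps
the design matrices tractable; for γ-band pairs it undersamples the fastest
basis terms, so γ couplings are estimated conservatively (attenuated rather
than inflated) — a deliberate trade-off, and the reason γ-heavy analyses
should raise the cap when computing time allows.

## Dynamical Bayesian inference

`infer_window()` fits both phase equations jointly. Phase velocities are
two-point finite differences with the basis evaluated at midpoint phases
(consistent with the Stratonovich drift correction, which enters through the
$-\tfrac h2 \sum_n \partial\Phi/\partial\phi$ term). With a multivariate
normal prior $(c^{(0)}, \Xi^{(0)})$ the posterior follows from alternating
two closed-form updates until the parameters and the 2×2 noise matrix both
change by less than `tol` (default 1e-6 relative, `max_iter = 100`):

$$D = \frac hN \sum_n \big(\dot\phi_n - c\,\Phi_n\big)
      \big(\dot\phi_n - c\,\Phi_n\big)^{\!\top}, \qquad
  \Xi = \Xi^{(0)} + h\,\Phi^{\!\top} D^{-1} \Phi, \qquad
  c = \Xi^{-1} r,$$

with $r = \Xi^{(0)} c^{(0)} + h\,\Phi^{\!\top} D^{-1}\dot\phi -
\tfrac h2 \textstyle\sum_n \partial\Phi/\partial\phi$. On noise-free data
this reduces to ordinary least squares (verified against an independent OLS
oracle in the test suite). Numerical safeguards: eigenvalues of $D$ are
floored at 1e-12 so that noise-free data do not produce a singular weight
matrix; a singular concentration matrix triggers ridge regularisation with a
warning; non-convergence returns the last iterate, flagged.

The flat prior is zero mean with concentration $10^{-8} I$ — numerically
safe and dominated by any realistic data term.

**Windows and time evolution.** `infer_sequence()` splits a recording into
non-overlapping windows (default 50 s: ≥ 40 cycles of the slowest cortical
rhythm, short enough to follow drifting physiology) and propagates each
posterior into the next prior with
$\Sigma^{\rm prior} = \Sigma^{\rm post} + p_w^2\,{\rm diag}(c^2)$
(default $p_w = 0.2$). $p_w = 0$ is full memory; large $p_w$ makes windows
effectively independent. The tests verify that a coupling ramping from 0.1
to 0.5 across ten windows is tracked with at most one window of lag.

**Noise convention.** The Euler–Maruyama increment is
$\sqrt{dt \cdot D}\,\mathcal N(0,1)$, which makes the inferred $D$ estimate
the generator's `noise_strength` directly — fixing the estimator's target
removes a factor-of-two ambiguity between conventions.

## Coupling quantities

From a posterior, `coupling_function_grid()` evaluates the selected terms on
a uniform $2\pi \times 2\pi$ grid (default 100 × 100 — smooth rendering for
$K = 2$ surfaces); `coupling_strength()` is the Euclidean norm of the
selected coefficient subvector; `similarity_rho()` is the Pearson
correlation of two coupling-coefficient vectors — a scale-free measure of
similarity of *form*. ρ is computed over the coupling terms only
($l \ne 0$), excluding the constant and self terms, because the similarity
of interest concerns the coupling surface, which those terms do not shape;
this is a declared choice where conventions differ.

`subject_summary()` aggregates windows by the **median** (robust to
transient non-convergence; the choice is exposed) and reports both
directions, flagging the *predominant* one — the direction with the larger
median net strength — since the weaker direction is usually not
interpretable on its own.

## Surrogates and statistics

Whether an inferred coupling is genuine is decided against surrogate data:

* **Intra-subject surrogates** (`intra_surrogate()`): the driver phase is
  split into whole cycles at its $2\pi$ crossings, the cycles are permuted
  uniformly at random and rejoined with offsets that are exact multiples of
  $2\pi$. This preserves the rhythm's cycle-duration multiset and wrapped
  distribution exactly while destroying temporal alignment with the
  response. For an almost-periodic driver the surrogate stays partially
  aligned — permutation can only exploit the driver's own cycle-to-cycle
  variability, whose misalignment variance grows like $D\,T/3$ over a
  recording of length $T$. Detection of genuine coupling therefore improves
  with longer recordings and with physiologically realistic frequency
  variability; perfectly metronomic drivers cannot be surrogate-tested this
  way (nor by any method that preserves the rhythm's own statistics).
* **Inter-subject surrogates** (`inter_surrogate()`): the response is paired
  with the same band's phase from other subjects.

The default significance rule is *genuine > surrogate mean + 2 SD*
(`significance_vs_surrogates()`, with a percentile alternative). For gating,
the genuine and surrogate strengths are computed by the *same* estimator — a
single flat-prior fit over the whole overlap — so the finite-sample
inflation of a 20-dimensional parameter norm cancels in the comparison;
mixing estimators with different window lengths would bias the gate.
100 surrogates by default; 19 is the minimum accepted (the classical
one-sided 5% rank argument).

Group contrasts use the Wilcoxon test (`group_compare()`): unpaired rank-sum
for different-subject groups, the paired signed-rank variant (a flag) for
same-subject awake-versus-anaesthetised designs — the literature is usually
silent on which is meant. Tests are two-sided at α = 0.05 with **no**
multiplicity correction, matching the practice of assessing each coupling
relationship independently. Descriptives are the boxplot five numbers.

## The synthetic cohort generator

No recordings ship with the package; `make_cohort()` generates cohorts that
emulate the study design the pipeline targets: three groups (awake-like,
propofol-like, sevoflurane-like), 15 subjects per group by default, 20-min
recordings, with six band oscillators rendered into three channels (`eeg` =
δ + θ + α + γ, `resp`, `ecg`) plus Gaussian measurement noise. Defaults are
300 Hz sampling (the full clinical 1200 Hz is a config away and changes
nothing structurally), inter-subject strength spread 0.05 (no literature
value exists for inter-subject coupling variability; this makes groups
separated by ≥ 0.2 clearly distinct at n = 15 while keeping within-group
overlap realistic) and 2% natural-frequency jitter.

Oscillator noise strengths (`default_oscillators()`) are set so each rhythm
shows realistic cycle-to-cycle variability rather than metronomic
regularity: broadband cortical rhythms (δ 0.3, θ 0.3, α 0.2, γ 0.5 rad²/s)
wander noticeably within their bands, respiration (0.1) has a period CV
around 15%, the heartbeat (0.05) a few percent. This matters beyond realism:
surrogate testing *relies* on rhythm variability (see above), and phase
recovery accuracy degrades gracefully with it (circular RMS ≈ 0.03 rad at
$D = 0.02$, ≈ 0.11 rad at $D = 0.3$ for the δ band — the module-level
fidelity check is run at $D = 0.1$, within the regime where the chain is
expected to be accurate).

What the generator does **not** emulate: ECG morphology (QRS complexes),
1/f EEG background, artefacts, amplitude dynamics, and non-stationary
band power. Passing tests therefore demonstrate correctness of the phase
pipeline under its model assumptions, not robustness to every feature of
clinical recordings; artefact handling is expected upstream.

Euler–Maruyama integration uses $dt = 1/(40 f_{\max})$ (40 steps per cycle
of the fastest oscillator), refined to an exact integer subdivision of the
requested output rate; a step with $dt\,\omega > 0.5$ rad is refused.

## Problem sizes in the shipped tests

The test-suite and acceptance-script runs use desk-scale versions of the
study conditions, chosen once: parameter recovery uses 400-s records at
40 Hz; surrogate calibration uses 100 simulated subjects with 900-s records
at 12 Hz and 19 surrogates each (900 s gives the cycle-permutation
surrogates enough driver variability, $DT/3 \approx 3$ rad², to decorrelate
fully at $D = 0.01$); the end-to-end cohort uses 3 × 10 subjects, 240-s
recordings at 100 Hz with δ, θ, α oscillators and planted δ→α strengths
0.1 / 0.35 / 0.6 — the qualitative ordering (awake weak, anaesthetised
strong, sevoflurane strongest) reported for that coupling.

## Known limitations

* γ-band couplings are estimated at a capped 120 Hz pair rate; the fastest
  basis terms are undersampled there and strengths are attenuated. Raise
  `pair_rate_cap` for γ-focused work.
* The surrogate gate is conservative for rhythms with little frequency
  variability (see above); near-metronomic drivers require longer records.
* Inference assumes a pairwise phase model; couplings routed through a
  third oscillator appear as indirect components, not as network edges.
* The decomposition is orthogonal by construction; it does not recover the
  multiplicative phase-response-curve factorisation itself.
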