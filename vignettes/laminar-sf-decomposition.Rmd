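---
title: "Decomposing laminar spatial-frequency processing in V1: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing laminar spatial-frequency processing in V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Primary visual cortex receives spatial-frequency (SF) information through two
parallel geniculate streams: the magnocellular (M) pathway, terminating in
L4Cα and preferring low SFs, and the parvocellular (P) pathway, terminating
in L4Cβ and preferring higher SFs. How the output layers (L2/3) combine these
feedforward drives with local recurrent processing — and whether a cortical
column *suppresses* or *amplifies* its input at high SFs — is the question
this package's analysis chain addresses.

The chain has five stages, each usable on its own:

1. **Reverse correlation** (`reverse_correlate()`, `smooth_response()`,
   `compute_ser()`, `select_sites()`): dynamic responses
   `Resp(orientation, delay)` from spikes and a randomized 20-ms
   flashed-grating sequence.
2. **Laminar geometry** (`compute_csd()`, `assign_relative_depth()`,
   `build_laminar_pattern()`).
3. **SF tuning** (`fit_sf_tuning()`, `cutoff_sf()`, `relative_cutoff_sf()`,
   `select_sf_conditions()`).
4. **Group structure** (`output_input_activation()`, `bootstrap_classify()`,
   `dip_test_calibrated()`, `cluster_placements()`).
5. **Connectivity and mechanism** (`fit_var()`,
   `pairwise_conditional_gc()`, `aggregate_connections()`, `fit_model()`,
   `laminar_activation_patterns()`, `contributions()`, `mp_index()`).

# The response model

All dynamic responses live on a 2-ms (500 Hz) grid of delays from −20 to
+150 ms; model fitting uses the causal window t ∈ [0, 150] ms (76 samples
per SF condition).

The **FF model** predicts the response of site *i* at every SF as

$$\hat R_i(sf, t) = w_m \, (R_m(sf,\cdot) * K_m)(t)
                  + w_p \, (R_p(sf,\cdot) * K_p)(t),$$

where $R_m$, $R_p$ are the layer-mean dynamic responses of the L4Cα and
L4Cβ sites of the same placement (orientation-averaged; the model is fit per
SF, not per orientation) and each temporal kernel is a difference of two
log-normal lobes,

$$K(t) = e^{-(\ln t - \Delta t_1)^2 / 2\sigma_1^2}
       - g\, e^{-(\ln t - \Delta t_2)^2 / 2\sigma_2^2}, \qquad t > 0 .$$

The **FF & Rec model** adds an SF-dependent recurrent component
$w_{rec}(sf)\, R_{rec}(t)$ whose time course is a single unit-peak
log-normal bump (default peak 65 ms, after the ~52-ms feedforward drive
peak). Kernel parameters are shared across SFs; only $w_{rec}$ varies per
SF. The FF variant has 12 free parameters; FF & Rec has 14 + one recurrent
weight per SF condition.

## Kernel normalisation (a deliberate deviation)

Weights are only meaningful relative to a kernel scale. Fixing the kernels
to unit *peak* makes the weights structurally non-identifiable: when a
kernel is narrow relative to the smooth input drive, the convolution output
depends on the parameters almost only through $w \cdot \sum_t K(t)$, so a
near-delta kernel with a large weight reproduces the data of a broad kernel
with a small weight (we observed a fitted $\sigma = 0.05$ delta kernel
matching the data at raw gof 0.9999978 with the weight off by a factor of
four). The package therefore normalises the feedforward kernels to unit
**net area**: the weight is then the DC transfer amplitude of the pathway —
a quantity the data constrain directly — and the kernel shape only controls
temporal smearing. The recurrent course is unit-peak (it enters without
convolution, so its peak is directly constrained; $w_{rec}$ is the
component's peak amplitude in spikes/s). `lognormal_kernel()` exposes all
three conventions; `normalize = "none"` returns the raw formula.

## Fitting

`fit_model()` minimises the summed squared error jointly over all SF
conditions of one site. The linear parameters ($w_m$, $w_p$, $w_{rec}(sf)$)
are profiled out by nonnegativity-constrained least squares (Lawson–Hanson
on the normal equations) inside a bounded multi-start L-BFGS-B search over
the nonlinear kernel parameters; the best restart is then polished by
alternating Nelder–Mead and L-BFGS-B rounds, because the SSE surface has
narrow curved valleys in the kernel parameters. Everything is deterministic
(fixed start grid, no RNG). Bounds: log-time centres in [ln 10, ln 140]
(peaks 10–140 ms), widths σ ∈ [0.05, 1.5], subtractive gains g ∈ [0, 1],
weights ≥ 0. Convergence tolerances: `factr = 10` (≈ 2·10⁻¹⁵ relative) in
the polish, `reltol = 1e-14` for the simplex.

Model comparison uses the adjusted goodness of fit
$1 - (N-1)(1-gof_{raw})/(N-P-1)$ with $N$ = time bins × SF conditions and
$P$ the free-parameter count; the decomposition stage keeps only fits with
raw gof > 0.8.

## Contributions

`laminar_activation_patterns()` splits a fitted FF & Rec prediction into its
M, P and recurrent components (which sum to the prediction pointwise).
Placement-level contributions per SF are variance-explained-style scores of
each single component against the data; raw scores can be negative and are
floored at zero before normalising the triple to sum to one (the floor is
needed because a component that explains nothing can have arbitrarily
negative raw score, which would make "fractions" meaningless). Per-site
contributions use the maximum over time of each component instead. The MP
index $(C_p - C_m)/(C_p + C_m)$ summarises the relative feedforward
contribution of the two streams.

# What the synthetic world states — and what it does not

`simulate_placement()` draws a 24-channel column spanning relative depth
0–1 with layer boundaries at 0.15/0.35/0.45/0.55/0.65/0.80
(L2|L3|L4B|L4Cα|L4Cβ|L5|L6 — standard macaque V1 proportions). Input-layer
sites carry the drives; all other sites are the FF & Rec forward model
evaluated with ground-truth parameters shipped as versioned JSON packs
(`inst/extdata/ffrec_params_group*.json`), with per-site log-normal weight
jitter (SD 0.15) and i.i.d. Gaussian response noise (default SD
2 spikes/s).

Choices the source protocol does not fix quantitatively, made once:

* **SF ladder** 0.625, 1.25, 2.5, 5, 7.5, 10, 15 c/deg — seven conditions
  inside the protocol's 0.5–20 c/deg range, lowest 0.625.
* **Drive SF gains**: log-Gaussian, M peaked at 1 c/deg (1.2 octave SD,
  amplitude 40 spikes/s), P at 6 c/deg (1.4 octave SD, 35 spikes/s). These
  are qualitative stand-ins; no quantitative L4C gain data exist to emulate.
* **Drive kinetics**: unit-peak log-normal time courses, M peaking at 46 ms
  and P at 57 ms so the pooled input-layer drive peaks near 52 ms. The M/P
  timing difference reflects the faster magnocellular conduction and is also
  what makes the two pathways separable from a single placement — with
  identical kinetics only the SF profiles distinguish them.
* **Ground-truth kernels**: mildly biphasic (main lobe at 14–20 ms, σ ≈ 0.4;
  subtractive lobe at 38–48 ms, σ = 0.3, g = 0.2–0.25), giving clearly
  positive net area. Pack weights were solved so that the noiseless
  output/input activation is ≈ 0.55–0.78 for group 1 at every SF (pure
  suppression) and, for group 2, rises through 1 near 6 c/deg to ≈ 1.3–2.0
  at the high SFs (recurrent amplification); L2/3 recurrent weights increase
  monotonically with SF in group 2 and are zero in group 1.
* **Spike front end**: inhomogeneous Poisson at 10 spikes/s baseline with a
  unimodal circular orientation gain (baseline 0.2, peak 1, 30° width) —
  needed only so reverse correlation has structure to recover.

A green test on this world establishes that the *operators* are correct and
that the qualitative group signatures follow from the stated mechanism. It
does **not** emulate: eye movements, burst/refractory spiking, correlated
noise across channels or bins, electrode drift, layer-boundary uncertainty,
or any quantitative match to recorded monkey response amplitudes.

# Statistical components

**Bootstrap group classification.** The observed high-SF output/input
activation is compared with 1000 resamples (with replacement) of the
placement's low-SF activation distribution (per-site L2/3 activations at
the low SF). The reported p is the *upper-tail* fraction of resamples at
least as large as the observed index, and p < 0.05 labels the placement
amplification-dominated. The literal count-below formulation
(`tail = "literal"`, p = 1 − K/n with K the count of resamples exceeding
the observation) is retained for reference but reverses the tail: taken at
face value it would assign large p to strongly amplified placements,
contradicting its own use as an amplification test, so the upper-tail
reading is the default. No plus-one correction is applied to the raw
proportion.

**Dip test.** No dip-statistic implementation exists in the environment, so
the statistic is computed from first principles (C++): the dip is the
smallest band half-width d such that a nondecreasing convex-then-concave
CDF (an atom is allowed at the mode) fits between the empirical CDF ± d;
feasibility is checked with greatest-convex-minorant / least-concave-
majorant constructions and the dip is found by bisection. The test suite
verifies exact known values (uniform grids give 1/(2n); two balanced point
masses give 1/4) and agreement with an independent brute-force oracle. The
"calibrated" p-value is Monte-Carlo against a unimodal normal null with
matched mean and SD; since the dip is location/scale invariant the null
distribution depends only on n and is cached per session
(`dip_null_distribution()`).

**Granger causality.** The full VAR (order 15 = 30 ms at 500 Hz) is fit by
least squares with trials pooled; its autocovariance sequence is obtained
from the companion-form Lyapunov equation (doubling iteration) and extended
by the Yule–Walker recursion until it has decayed below 10⁻⁸ of its initial
norm. Each restricted model (one source channel removed) is solved from
that autocovariance sequence by Whittle's forward/backward recursion rather
than refit to data, so full and restricted models are mutually consistent
and the GC values ln(Σ_restricted/Σ_full) are nonnegative up to numerical
tolerance (tiny negatives are clamped to zero). Significance, where needed,
comes from circular-shift surrogates. All ordered layer pairs enter the
feedforward/recurrent aggregation (no distance-based exclusion: the source
protocol states none).

**SER scale.** The stimulus-driven energy ratio is computed on the raw
firing rate: the blank-triggered baseline rate is added back before
squaring. On baseline-*subtracted* responses the pre-onset energy is pure
noise energy, which makes the ratio scale-free and heavy-tailed (its 95th
percentile for noise-only sites is ≈ 5 regardless of the noise SD), so the
">3 selects visually driven sites" rule only behaves as described on the
raw-rate scale. Blank subtraction is kept for the dynamic responses
themselves, so unresponsive sites have responses near zero downstream.

# Numerical conventions and edge rules

* Smoothing: rectangular, width 20 ms = 10 samples; at the edges the window
  shrinks (no zero padding), so pre-onset bins are not suppressed.
* Argmax ties (peak time): earliest delay wins.
* Site selection: strictly greater than the SER threshold (SER = 3.0 is
  excluded).
* CSD: exactly the negative second difference; edge channels are `NA` (no
  Vaknin padding), keeping the operator the literal formula.
* Depth boundaries: a channel exactly on a boundary belongs to the deeper
  layer; the depth grid step is 0.02 (the window length 0.1 is stated, the
  step is not).
* Tuning fits are on the raw SF axis (not log-SF); the 50% and 90% response
  rules are implemented as ≥ on the dense evaluation grid (0.1–25 c/deg,
  1000 log-spaced points), where grid quantisation dominates the
  distinction between > and ≥. The "high SF at or above 6 c/deg" clause is
  read as a constraint on the SF, not on the response threshold.
* Discrete convolution carries no bin-width factor; the weights absorb the
  constant.

A related numerical point: for strongly amplified columns at the high SF the
*normalized* recurrent share saturates at exactly 1 (both feedforward raw
scores are negative and floored at zero), so analyses that need graded
recurrent strength — such as the correlation between recurrent contribution
and activation across placements — should use the raw variance-explained
contribution, which stays smooth and monotone.

# Known limitations

* **Weight recovery under noise.** With per-SF free recurrent weights, the
  recurrent bump (peak 65 ms) is nearly collinear with the feedforward
  components (input drives peaking at 46/57 ms, smeared ~10–15 ms by the
  kernels). At a response SNR of 10 the maximum-likelihood fit routinely
  attains a *lower* SSE than the generating parameters while placing
  weights 30%+ away from them: the error is estimator variance along a
  near-degenerate ridge, not an optimisation failure. Noiseless recovery is
  accurate to <1%; noisy weight estimates should be treated as ensemble
  quantities (their cohort-level averages and trends are stable), not
  per-site point estimates. The corresponding acceptance check on noisy
  per-site recovery fails by construction and is left failing.
* The laminar alignment is metadata-driven; the earliest-sink heuristic is
  advisory only.
* No frequency-domain or state-space GC; no per-orientation or
  trial-by-trial model fitting; no biophysical spiking model.
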