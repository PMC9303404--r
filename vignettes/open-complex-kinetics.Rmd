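---
title: "Methods: dwell-time kinetics of open-complex dynamics on supercoiled DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dwell-time kinetics of open-complex dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opendwell)
```

# The kinetic model and its observables

A supercoiled DNA tether held at low force reports promoter opening as a
discrete drop of its end-to-end extension: unwinding $n$ base pairs removes
$n/\mathrm{pitch}$ turns of twist, which the conserved linking number
converts into writhe, shortening the tether by
$(n/\mathrm{pitch})\,\Delta z$ (with $\Delta z \approx 60$ nm of extension
per turn in the plectonemic regime). The recorded signal is therefore a
two-level telegraph process. Its *closed state* (CS) lumps the free
promoter and the closed complex $\mathrm{RP_C}$; its *open state* (OS)
lumps the open intermediate $\mathrm{RP_I}$ and the stable open complex
$\mathrm{RP_O}$, which render at the same extension level because any
bubble-size difference between them is below the assay's resolution.

The full scheme is

$$\mathrm{R}+\mathrm{P}
  \underset{k_{-1}}{\overset{k_1[R]}{\rightleftharpoons}} \mathrm{RP_C}
  \xrightarrow{k_2} \mathrm{RP_I}
  \underset{k_{-3}}{\overset{k_3}{\rightleftharpoons}} \mathrm{RP_O},
  \qquad \mathrm{RP_I} \xrightarrow{k_5} \mathrm{R}+\mathrm{P},
  \qquad \mathrm{RP_O} \xrightarrow{k_4} \mathrm{R}+\mathrm{P}.$$

Each observable dwell is a *first-passage time* of the corresponding
transient sub-chain, i.e. a phase-type random variable with density
$f(t) = \pi_0^\top e^{Qt} a$, where $Q$ is the generator over the
transient states, $a = -Q\mathbf{1}$ the absorption rates and $\pi_0$ the
entry distribution. `build_scheme()` assembles this triple for the ladder
of candidate OS models (reversed pathway `M1`, parallel pathways `M2`,
dissociation from RP$_\mathrm{O}$ `M3` in both entry conventions, and
dissociation from RP$_\mathrm{I}$ `M4` with its three solvable
assumptions) plus the CS binding chain.

Two structural facts drive model discrimination, and `pdf_shape()` encodes
the first: a scheme whose entry states carry no direct absorption has
$f(0^+) = \pi_0^\top a = 0$, so its density *rises* from zero ("peaked",
gamma-like) instead of being a positive mixture of decaying exponentials.
Observed OS dwell histograms are maximal at short times, which eliminates
the peaked candidates. Note one wrinkle in the candidate ladder: with entry
in RP$_\mathrm{O}$ and absorption from RP$_\mathrm{O}$ (case 1 of `M3`),
$f(0) = k_4 > 0$, so that case is mathematically a positive mixture even
though it is often described informally as peaked; the package reports
shapes strictly from $\pi_0^\top a$. With entry in RP$_\mathrm{I}$ and
absorption only from RP$_\mathrm{O}$ (case 2), the density is a
*difference* of exponentials — double-exponential in algebraic form but
vanishing at the origin — and `pdf_shape()` classifies it as peaked.

## Conversion relations

The accepted model (`M4_A3`: $k_4 = 0$) has generator
$Q = \begin{pmatrix}-(k_5+k_3) & k_3\\ k_{-3} & -k_{-3}\end{pmatrix}$ with
absorption $(k_5, 0)$ and entry in RP$_\mathrm{I}$. Its density is exactly
the two-exponential mixture
$f(t) = p_+k_+e^{-k_+t} + p_-k_-e^{-k_-t}$, where $-k_\pm$ are the
eigenvalues of $Q$. Inverting the eigensystem gives the closed-form map
used throughout:

$$k_5 = p_+k_+ + p_-k_-,\qquad
  k_3 = \frac{p_+p_-(k_+-k_-)^2}{k_5},\qquad
  k_{-3} = \frac{k_+k_-}{k_5},$$

all strictly positive whenever $0 \le p_+ \le 1$ and $k_\pm > 0$.
`micro_to_fit()` is the exact inverse (quadratic eigenvalue roots; the
weight is computed as $(k_+-k_5)/(k_+-k_-)$ directly, which is
better-conditioned than $1-p_+$ when $p_-$ is tiny). The measure-zero
repeated-eigenvalue boundary is returned as the single-exponential limit
with $p_+ = 1$, where the map is otherwise undefined. Uncertainties of the
fitted $(k_+, k_-, p_-)$ are pushed through this map by the delta method,
with partial derivatives taken by central finite differences at relative
step $10^{-6}$ — a step size that balances truncation against round-off
for these smooth rational functions (`propagate_errors()`; agreement with
analytic partials is tested to $10^{-4}$).

# The synthetic-data generator

No public raw traces exist for this assay, so the package ships a
generator that is itself first-class, tested code. `simulate_trajectory()`
is an exact Gillespie simulation of the full scheme (exponential waiting
times at the total exit rate, branching proportional to the competing
rates, pseudo-first-order binding at $k_1[R]$). `render_trace()` maps the
lumped state to a two-level signal (CS level `z_CS`, OS level
`z_CS - jump`, with the 73 nm jump for positive and the 42 nm jump for
negative supercoiling), samples it at 58 Hz at the state occupied at each
timestamp, adds linear drift and i.i.d. Gaussian noise, and block-averages
by the decimation factor (default 10, giving 5.8 Hz effective).

Default study conditions: rates of the order of the 150 mM potassium
acetate condition at 34 °C —
$k_5 = 0.0385$, $k_3 = 0.0525$, $k_{-3} = 0.0389\ \mathrm{s^{-1}}$,
$K_D = 17$ nM with $k_2 = 0.16\ \mathrm{s^{-1}}$ at 5 nM holoenzyme
(binding split as $k_1 = 0.1\ \mathrm{nM^{-1}s^{-1}}$,
$k_{-1} = 1.7\ \mathrm{s^{-1}}$, fast against $k_2$ so that the
rapid-pre-equilibration description of the opening rate holds). The raw
noise SD defaults to 25 nm, chosen so that the 73 nm jump has SNR ≈ 9
after 10× averaging, visually consistent with published traces; the true
instrument noise amplitude and drift spectrum are not published, so these
are stated choices, not inferences.

What the generator deliberately does *not* emulate: bead Brownian dynamics
and camera/tracking physics (its noise is white, where real traces have an
Ornstein–Uhlenbeck-like correlation at $t_c \approx 45$ ms), torque
dependence of the rates, plectoneme dynamics, and sub-sample state changes
(each sample takes the instantaneous state at its timestamp; dwells below
one effective sample are invisible anyway). Passing tests therefore
validate the *analysis chain* under realistic amplitude and rate
conditions; they cannot certify behaviour against correlated tracking
noise beyond what the Allan-deviation diagnostics characterize.

# Segmentation

`detect_changepoints()` implements bottom-up merging with an L1 cost: the
series is cut into blocks of `min_size` samples (default 2), and the
adjacent pair whose merge increases the total cost least is merged while
that increase stays below the penalty. The cost of a segment is the sum of
absolute deviations from its median — robust to the heavy tails that
brief excursions produce. Two implementation details matter:

- **Penalty units.** The raw L1 cost scales with the data units, so a
  fixed penalty would mean different things at different noise levels.
  The package standardizes the series by a robust noise scale (median
  absolute first difference / $\sqrt2$) before costing, making the
  penalty a dimensionless noise-unit quantity; the default `penalty = 1`
  then transfers across conditions. Larger penalties can only remove
  breakpoints: the greedy merge order is penalty-independent, so the
  number of detected transitions is non-increasing in the penalty (a
  tested invariant).
- **Cost evaluation.** Any point between the two central order statistics
  minimizes the L1 sum equally, so a single partial-sort order statistic
  replaces the full median with no loss of exactness.

Spurious low-gain breakpoints inside a level are tolerated at this stage:
`label_segments()` classifies segment medians by length-weighted 1-D
2-means (the lower-extension cluster is the OS, since opening shortens the
tether), merges same-label neighbours — which absorbs the spurious splits
— and falls back to all-CS when the two centers are closer than 4 noise
scales (a trace with no opening events has no second level to find).

`extract_dwells()` converts segment lengths to durations at the effective
sampling rate, flags the first and last dwell as censored (their
boundaries are set by the recording, not by transitions), and discards
dwells shorter than `t_min` while merging their flanking same-label
neighbours. The default `t_min` = 90 ms is twice the typical correlation
time of the assay ($t_c \approx 45$ ms), i.e. the stated spatiotemporal
resolution. `correlation_time()` estimates $t_c$ as the lag at which the
autocorrelation falls to $1/e$ — a stand-in estimator validated on
synthetic AR(1) noise, since how $t_c$ is read off an Allan-deviation
curve in practice is not standardized. Linear drift is removed by a Tukey
resistant line, and only when the fitted slope exceeds 0.5 nm/s, so that
genuine two-level structure is never "corrected" away.

# Dwell-time likelihoods

Censored boundary dwells are excluded from all fits. Retained dwells are
left-truncated at `t_min`, and the likelihood is renormalized on
$[t_\min, \infty)$; whether and how short-dwell truncation entered
published analyses is not stated, so truncation-renormalization is this
package's explicit choice (with `t_min = 0` it reduces to the plain
likelihood).

- Single exponential: the truncated MLE is closed-form,
  $\hat k = 1/(\bar\tau - t_\min)$; the numerical optimum agrees to
  $10^{-8}$ (tested).
- Double exponential: bounded quasi-Newton (L-BFGS-B) over
  $(\ln k_+, \ln k_-, \operatorname{logit} p_-)$ with an analytic
  gradient written in terms of per-observation component
  responsibilities, which keeps it finite when one component's density
  underflows. Eight initializations by default (one moment-based, the
  rest stratified random); label switching is resolved by relabelling so
  $k_+ \ge k_-$. The log/logit coordinates make the box constraints
  simple positivity/interval bounds.

Model choice uses $\mathrm{BIC} = m\ln N - 2\ln\hat L$ with $m = 1$ or 3;
ties go to the single exponential. Parameter errors come from $n$-out-of-$n$
bootstrap resampling (1000 replicates by default; replicates that fail to
refit are dropped, and more than 20% failures raises an error). One
bootstrap SD is reported, matching the convention in which propagated
errors are quoted; doubling for two-SD error bars is the caller's choice.

**Sample-size guidance.** With the study-condition rates the two OS
exponentials are separated only ~9-fold with $p_+ \approx 0.25$, and the
sampling SD of the derived $k_3$ is ≈ 24% at 1000 dwells (≈ 8% at 9000).
Excluding censored dwells also length-biases the retained sample short by
roughly $\mathbb{E}[\tau^2]/(\mathbb{E}[\tau]\,T)$ per trace of length
$T$ — about 10% at $T = 1500$ s and 2.5% at $T = 6000$ s for a 61 s mean
OS dwell. The package's validation therefore uses ensembles of 120 traces
of 6000 s (~7700 dwells of each state), sized so that the 15% recovery
tolerance sits at roughly two sampling SDs of the worst parameter; the
worked example in the README (24 traces) illustrates the larger
uncertainties of a session-sized data set.

# Condition-dependence fits

- **Binding** (`fit_binding`): weighted nonlinear least squares of
  $k_\mathrm{open} = k_2[R]/(K_D+[R])$, started from the linearized
  double-reciprocal form. Identifiability note: over a 0.2–10 nM design
  with $K_D = 17$ nM the curve never saturates, so $K_D$ carries ~3.5× the
  per-point relative noise; rate series intended to recover $K_D$ within
  20% need per-point errors of ≲ 3%, i.e. ≳ 1000 dwells per
  concentration. The shipped fixture series uses 2% relative noise — the
  standard error of a rate estimated from ~2000 dwells — for exactly this
  reason.
- **Arrhenius** (`fit_arrhenius`): linear least squares of $\ln k$ versus
  $1/T$ (temperatures accepted in °C, converted to K;
  $R_\mathrm{gas} = 1.98720425\times10^{-3}$ kcal mol⁻¹ K⁻¹; energies
  echoed in kJ/mol via 4.184). Negative activation energies are permitted
  and meaningful: they indicate a non-elementary step proceeding through a
  stabilizing intermediate.
- **Coupled binding–Arrhenius** (`fit_kopen_temperature`): nonlinear least
  squares of
  $k_\mathrm{open}(T) = k_2^0e^{-\Delta E_2/k_BT}[R] /
  (K_D^0e^{-\Delta E_\mathrm{diff}/k_BT} + [R])$, unweighted (matching the
  generic least-squares practice for such curves). The Arrhenius factors
  are internally anchored at the mean inverse temperature, which
  decorrelates prefactors from energies — the naive $K_D^0$ at infinite
  temperature is astronomically large ($\sim e^{175}$ for
  $\Delta E_\mathrm{diff} = 107$ kcal/mol) and would be hopeless as a
  direct optimization variable. A grid of energy starts makes the fit
  robust to the sign and size of the turnover; when
  $\Delta E_\mathrm{diff} > \Delta E_2$ the fitted curve is non-monotonic
  with an interior maximum (isomerization-limited at low temperature,
  dissociation-limited at high).
- **Salt sensitivity** (`salt_sensitivity`): defined here as the log–log
  slope $S = d\ln k/d\ln[\mathrm{salt}]$, the natural dimensionless
  power-law exponent; a published $S$ without an explicit definition is
  assumed to be this quantity.

# Supercoiling geometry

`bubble_and_bend()` inverts the jump arithmetic: opening shortens the
tether by the twist-conversion term $n\,\Delta z/\mathrm{pitch}$ *plus*
the bent/wrapped length $L$ on positively supercoiled DNA, and by the
twist term *minus* $L$ on negatively supercoiled DNA, so
$n = \mathrm{pitch}(J_+ + J_-)/(2\Delta z)$ and $L = (J_+-J_-)/2$.
Reported values are rounded to the nearest bp/nm (half away from zero)
with the raw values retained; `expected_jump()` is the exact inverse on
the raw values. `twist_shift()` locates each rotation-extension curve's
apex by a parabola fit to the points within 90% of the maximal extension
(how curve centers are located is not standardized; a local parabola is
the minimal smooth model) and reports the apex displacement in turns and
in °/kb.

# Population kinetics

`simulate_populations()` integrates the linear master equation over the
four species from an all-free initial condition using the eigendecomposition
of the generator (exact for a linear system; scaling-and-squaring fallback
for defective or complex spectra). `analytic_steady_state()` — the
normalized null vector of the generator — serves as an independent oracle,
and averaged Gillespie occupancy provides a stochastic cross-check.

One qualitative observation: the open intermediate overshoots (peaks and
then declines toward equilibrium) only when opening is fast relative to
the filling of RP$_\mathrm{O}$, i.e. roughly $k_\mathrm{open} \gg
k_3 + k_{-3}$; at the default study rates the RP$_\mathrm{I}$ occupancy
rises monotonically instead. The tested overshoot fixture uses
$k_2 = 0.5$, $k_3 = 0.005$, $k_{-3} = 0.002$, $k_5 = 0.02\ \mathrm{s^{-1}}$.
The published per-temperature population figures (free-promoter fractions
of 0.25/0.70/0.58 and RP$_\mathrm{O}$/RP$_\mathrm{I}$ ratios of
1.05/2.42/1.85) derive from per-temperature rate tables in supplementary
material that is not publicly deposited, so they are not reproducible
here; the module validates against its analytic and stochastic oracles
instead.

# Degenerate inputs and numerical conventions

- Matrix exponentials by eigendecomposition where the spectrum is real and
  well-conditioned, `Matrix::expm` (scaling-and-squaring) otherwise.
- A scheme with all absorption rates zero has no first passage and errors
  out; a Gillespie configuration with no exit anywhere errors as
  absorbing.
- `micro_to_fit` with $k_3 = 0$ returns the no-RP$_\mathrm{O}$ limit
  $(k_+ = k_5, k_- = k_{-3}, p_- = 0)$ by convention.
- Constant extension series segment to zero breakpoints; an all-CS trace
  labels as a single cluster rather than forcing two levels.
- Mean dwell ≤ `t_min` is degenerate data and errors rather than returning
  an infinite rate.
- All simulation randomness is routed through integer seeds; identical
  seeds give bit-identical trajectories and traces, and `run_pipeline`
  derives per-stage seeds from the single run seed.

# Known limitations

- Two-level segmentation only; no >2-state level detection, no online
  detection, no interval-censored likelihoods beyond left truncation, and
  no mixtures beyond two exponentials.
- White rendering noise understates the difficulty of segmenting
  correlated tracking noise; penalties may need retuning (0.2–5 in noise
  units is the practical range) on real instruments.
- The binding split $k_1, k_{-1}$ behind a given $K_D$ is not identifiable
  from dwell data alone; only their ratio and $k_2$ are.
- Boundary-censoring length bias is mitigated by long traces, not
  corrected in the likelihood.
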