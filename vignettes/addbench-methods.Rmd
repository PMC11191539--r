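---
title: "Methods: the ADD simulator and the FC biomarker benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ADD simulator and the FC biomarker benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`addbench` simulates a whole brain as a network of N cortical regions, each
described by a neural mass: reciprocally coupled excitatory (E) and
inhibitory (I) populations characterized by mean membrane potential (mV)
and mean spike density (spikes/s). Incoming spike density is converted to
membrane potential by a linear biexponential postsynaptic kernel

\[ h(t) = A\,(e^{-a t} - e^{-b t}), \qquad b > a > 0, \]

with separate EPSP (`Amp1 = 1.6` mV, `a1 = 55`, `b1 = 605` 1/s) and IPSP
(`Amp2 = 32` mV, `a2 = 27.5`, `b2 = 55` 1/s) shapes. Membrane potential is
converted back to spike density by a static sigmoid

\[ f(V) = \frac{2g}{1 + e^{\,q (V_d - V)}}, \]

value `g = 25` spikes/s at the threshold `Vd = 7` mV and saturation `2g`.
Every excitatory population receives noisy thalamic input (mean `Pt = 550`
spikes/s) and `S`-weighted (`S = 1.5`) spike density from the excitatory
populations of adjacent regions of a binary structural connectome; the
inhibitory loop has gains `C1 = 32` (E to I) and `C2 = 3` (I to E). The
output "EEG/MEG" signal of a region is the mean membrane potential of its
excitatory population.

Activity-dependent degeneration (ADD) rests on one assumption: excessive
firing damages synapses. Per region and time step a loss factor

\[ \mathrm{loss} = e^{-d \cdot \mathrm{maxAct}} \]

is computed, where `maxAct` is the largest excitatory spike density over
the last 20 samples (40 ms, current sample included), and *all* synapses of
that region — E to I, I to E, thalamic, and the incident side of every
inter-regional connection — are multiplied by it. An inter-regional edge
therefore decays as the product of its two endpoint-side multipliers.
Simulations run in epochs of 4096 retained samples at 500 Hz, each preceded
by a 5000-sample settling transient; epochs are consecutive (state and
degeneration carry over), so epoch number doubles as disease time.

## Calibration choices and why they were made

Several quantities are not pinned down by the published description. They
are all explicit `nm_params()` arguments; the defaults are fixed once, for
the reasons below, and the test suite asserts the resulting behaviour.

**Kernel amplitude convention** (`psp_normalize`). Reading `Amp` as the
kernel *peak* multiplies the IPSP kernel by 4 relative to the classical
alpha-rhythm-model convention `A (e^{-at} - e^{-bt})`. Under the
peak-normalized reading, resting inhibition (≥ 31 mV for any non-negative
inhibitory rate) always exceeds the ~20 mV thalamic drive: the network is
unconditionally quiescent and produces no alpha rhythm, contradicting the
healthy state the model is known for. Under the raw convention the healthy
fixed point sits at E ≈ 3.3, I ≈ 9.4 spikes/s with an E/I loop gain just
below the oscillation threshold, giving the classic noise-driven alpha
resonance: an 8–10 Hz dominated spectrum with spectral peak near 9 Hz and
E/I balance E/(E+I) ≈ 0.26. The simulator default is therefore `"raw"`;
`psp_filter()` still offers `"peak"`.

**Reported firing rates.** The published initial rates (E ≈ 30, I ≈ 75
spikes/s, balance ≈ 0.3) cannot arise under the stated sigmoid, whose
saturation is `2g = 50 < 75`. We do not rescale any printed parameter; our
healthy state reproduces the *ratio* (balance 0.25–0.26 vs 0.3) and every
qualitative trajectory feature at roughly one-ninth the absolute rate
scale. This is documented rather than hidden: either the original sigmoid
is unbounded or its gains differ for the inhibitory population.

**Degeneration timescale** (`kappa`). Applying `loss = e^{-0.01\,maxAct}`
at every 2-ms sample, literally as printed, collapses all synapses within a
single epoch (0.74^9096 ≈ 0), contradicting the published ~100-epoch
trajectory. The loss is therefore applied per sample at an effective rate
`d/kappa`. `kappa = 27288` (three epochs' worth of samples) is calibrated
against the published milestones — relative theta power rising severalfold
starting around epoch 15–25 and the E/I balance reaching its plateau near
epoch 100 — and then frozen. The literal mode stays available via
`add_literal = TRUE` for fidelity experiments.

**Thalamic noise** (`sigma0`). Only "fluctuations around the mean,
noiselevel 1.0" is stated. We use additive Gaussian per-sample fluctuations
of standard deviation `noiselevel * sigma0` with `sigma0 = sqrt(Pt)` (a
shot-noise-like scale, ≈ 23 spikes/s), truncated at zero, independent
across regions, held constant within a sample across integration substeps.

**Integration** (`substeps`). PSP kernels are realized as exact
impulse-invariant pairs of first-order recursions; the only discretization
error is the explicit (one-substep-delayed) nonlinear feedback. At the
native 2-ms step the spectrum is visibly biased (relative band powers move
~10% when the internal step is halved). The default of 8 substeps (0.25 ms)
is where doubling further changes band powers by < 5%, which the test
suite asserts.

**Degeneration order.** The loss multiplies synapses *after* the membrane
update of each sample; computing it before changes epoch-level summaries by
under 1% (asserted in the suite).

**Multiplier floor.** Strength multipliers are clipped at `1e-6` to avoid
denormal drift; by then the region is functionally disconnected.

## The connectome

The published benchmark couples 78 regions through a binary
tractography-derived graph that is not publicly printed. `addbench`
accepts any user matrix (`load_adjacency()`, delimited text, optional
binarization threshold) and otherwise substitutes a seeded surrogate:
78 nodes, density 0.10 (300 edges — a typical tractography-graph
sparsity), drawn from a 5-module stochastic-block-style model with an 8:1
within/between-module edge preference, resampled until connected.
Erdős–Rényi and Watts–Strogatz families are available for sensitivity
checks. A synthetic AAL-style label list (`aal78_labels()`) names per-ROI
outputs; it is a stand-in resource, not the atlas.

## Spectral machinery and connectivity measures

Signals are band-filtered (delta 0.5–4, theta 4–8, alpha 8–13, beta
13–30 Hz; alpha1 8–10, alpha2 10–13, gamma 30–48 Hz for power summaries —
the gamma range is our configuration default, not a published value) by
zero-phase FFT masking with one-bin raised-cosine edges: deterministic, no
filter-order choice, unit passband gain. The analytic signal
\(z_t = x_t + i\tilde x_t = A_t e^{i\varphi_t}\) comes from the standard
one-sided-spectrum construction; 1% of samples at each epoch edge are
trimmed from connectivity averages against Hilbert edge artifacts.
Relative band power uses the epoch periodogram over 0.5–48 Hz with
half-open bin assignment so tiling bands sum to one; median frequency
interpolates the cumulative power with a midpoint convention (a pure tone
returns its own frequency), and the spectral peak is reported alongside.

Pairwise measures, per band and epoch:

* **AEC / AECc** — Pearson correlation of Hilbert envelopes; the corrected
  variant removes the instantaneous least-squares projection of one signal
  on the other before the envelope of the residual is correlated
  (both directions averaged; linearity of the Hilbert transform lets the
  residual's analytic signal be formed as \(z_y - \beta z_x\)). A null
  residual (pure scale copy) contributes 0.
* **PLI** — \(|\langle \mathrm{sign}\,\sin \Delta\varphi_t \rangle_t|\);
  zero-lag coupling gives 0. The printed definition omits the time
  average, without which the quantity is a per-sample ±1; the standard
  average is restored. `sign(0)` counts as neither lead nor lag, realized
  with a ±1e-12 dead zone because exact scale copies differ at rounding
  level.
* **PLT** — sign changes of \(\sin \Delta\varphi_t\) are detected; `T` is
  the mean interval (s) between successive changes, boundary-truncated
  intervals included (no change at all gives `T` = the full epoch; the
  alternative complete-intervals convention is config-exposed), and
  \(\mathrm{PLT} = 1 - e^{-T}\). As printed ("1 − e^T") the measure would
  be non-positive and contradict its stated 0–1 normalization; we treat
  that as a typo. An identically zero phase difference gives 0.
* **JPE** — both series are coded as ordinal patterns of length `n = 4`,
  lag `tau = 1` (amplitudes ranked highest = 1 to lowest = n; ties to the
  earlier sample). The joint pattern histogram excludes symmetric
  (\(\pi_x = \pi_y\)) and anti-symmetric (\(\pi_y\) = amplitude reversal of
  \(\pi_x\)) pairs — the volume-conduction correction — and its Shannon
  entropy `H` (natural log) is normalized by the printed constant
  \(\log((n!-1)^2) = \log 529\). We return \(1 - H/H_{max}\) so the measure
  *increases* with coupling, matching the sign-inverted usage and the
  positive printed cutoffs; the literal negative-sign form is available.
  The geometric exclusion removes \(2\,n! = 48\) cells while the printed
  denominator implies 47; we keep the geometric rule and the printed
  constant (the 1-cell discrepancy is far below estimation error). If every
  pair is excluded (e.g. identical channels) the value is 1 with a
  `degenerate` flag.

## The benchmark

For each measure, band and timestep, ADD and control runs are compared on
per-run whole-brain mean connectivity by a two-sided permutation test on
the difference of group means (exact enumeration when
\(\binom{n_1+n_2}{n_1} \le 20000\), otherwise Monte Carlo with the add-one
estimator), with Benjamini–Hochberg FDR across the timesteps within each
(measure, band) family — the correction family is configurable since the
published scope is unstated. Relative theta power, the reference
biomarker, is computed per channel and its (band-independent) curve is
replicated into each band family. Per-ROI profiles apply the same test per
region with FDR across regions. ROC analysis scores each run by its
whole-brain mean; orientation is auto-selected so the ADD group is the
positive-high class (ADD raises JPE but lowers PLT) and reported, AUC is
the trapezoid (equal to Mann–Whitney \(U/(n_1 n_2)\)), and the operating
point maximizes accuracy with ties resolved toward sensitivity.

## What the synthetic world does and does not establish

The surrogate connectome reproduces sparsity and modularity but not the
exact hub topology of the unpublished tractography graph, absolute firing
rates are ~9× lower than printed (sigmoid saturation, above), there are no
conduction delays and no volume conduction (so leakage-corrected measures
face no real leakage), and all runs share one parameter set rather than
subject-level variability. Green tests therefore establish the qualitative disease dynamics under
controlled hyperexcitability, not the printed AUC decimals, which are
stretch targets requiring the original matrix and are deliberately not
asserted.

One acceptance-level claim is *knowingly red* in this world and left so:
the headline ordering "JPE and PLT detect earlier than AECc and PLI" does
not reproduce. In our calibrated runs relative theta power separates ADD
from control first (AUC 1.0 from early epochs), PLI becomes the strongest
FC measure at later stages, PLT follows with the published ADD-low
direction, and JPE shows no consistent group effect. The likely reason is
the firing-rate regime: at E ≈ 3, I ≈ 9 spikes/s (forced by the bounded
sigmoid, see above) the dynamics are close to linear and Gaussian, and
band-filtered ordinal-pattern statistics are nearly blind to the small
synaptic changes that spectral power — hypersensitive just below the
oscillation threshold — picks up immediately. Reproducing the published
ordering appears to require the original implementation's ~10× higher
firing rates, which the printed sigmoid parameters cannot produce; we do
not rescale them silently.

## Reproducibility

Every run takes one master seed; noise is drawn in a fixed order (one
vector per 2-ms sample, shared bit-for-bit by the R reference stepper and
the compiled engine), so equal seeds give byte-identical output files. The
benchmark derives per-cell permutation seeds deterministically from its
seed argument. Configurations serialize to strict-schema JSON; unknown
keys are errors.
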