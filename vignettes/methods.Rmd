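---
title: "Estimating left-ventricular end-systolic elastance from a brachial pressure wave: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating left-ventricular end-systolic elastance from a brachial pressure wave: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

End-systolic elastance $E_{es}$ — the slope of the left ventricle's
end-systolic pressure–volume relation — is the canonical load-insensitive
index of cardiac contractility. Measuring it requires invasive
pressure–volume loops, so it is rarely available at the bedside. `pulsees`
implements an in silico pipeline that asks: how much of $E_{es}$ can be read
off a single non-invasive brachial pressure waveform? A hemodynamic
simulator with a known ground-truth $E_{es}$ generates a virtual population
of pressure waves; small one-dimensional convolutional networks are trained
to regress $E_{es}$ from the wave (and its time derivative); agreement and
noise robustness are then quantified.

## The ventricle

The heart is a time-varying elastance model,

$$P_{LV}(t) = E(t)\,\bigl(V_{LV}(t) - V_d\bigr), \qquad
  E(t) = E_{ed} + (E_{es}-E_{ed})\,e_n(t),$$

with dead volume $V_d$ and a dimensionless activation $e_n(t)\in[0,1]$.
The literature the sampling distributions are drawn from does not pin down
a specific activation curve, so the package uses the simplest form that
honors the one timing parameter that is sampled (the time of maximal
elastance $t_{es}$): a piecewise raised cosine rising over $[0, t_{es}]$,
relaxing over a relaxation time $t_r = t_{es}/2$, and zero for the rest of
the cycle. It is continuous, peaks at exactly 1 at $t=t_{es}$, and is
trivially testable. Parameter sets whose systole $t_{es}+t_r$ would exceed
the cardiac cycle are rejected.

Filling and ejection pass through ideal-diode valves with small series
resistances ($R_{ven} = 0.003$, $R_{valve} = 0.006$ mmHg·s/ml): inflow
$Q_{in} = \max(0,(P_{fill}-P_{LV})/R_{ven})$, outflow
$Q_{out} = \max(0,(P_{LV}-P_{root})/R_{valve})$. There is no regurgitation
and no inertial valve dynamics.

## The arterial tree

The arterial network is a reduced-order surrogate: twelve tapered segments
(ascending aorta, two arch pieces, thoracic and abdominal aorta, an iliac
terminal, the brachiocephalic / right-subclavian branch, the left carotid,
and the left subclavian / axillary / brachial run) shipped as an editable
YAML configuration. Each segment is discretized into lumped
$\Pi$-elements: Poiseuille resistance $R = 128\mu l/(\pi d^4)$, inertance
$L = 4\rho l/(\pi d^2)$ and compliance $C = D\,A\,l$ evaluated at the local
tapered diameter, with constant (pressure-independent) distensibility $D$.
Leaves carry three-element Windkessel loads. This linearized ladder keeps
the features that carry contractility information — wave propagation,
reflection, brachial pulse-pressure amplification — while remaining stable
and fast on a desk machine. It deliberately omits cerebral and coronary
sub-networks, pressure-dependent compliance, Womersley wall shear and
venous return.

Per-segment distensibility is the aortic value times a packaged
stiffness-ratio map (peripheral segments 0.35–0.6 of the aortic
distensibility), so the sampled "aortic distensibility" parameter sets the
aortic reference and the rest of the tree follows the fixed ratios.
Terminal peripheral resistances keep fixed ratios between vascular beds and
are rescaled so that the parallel total of each bed's $R_c + R_p$ equals
the sampled total peripheral resistance exactly; characteristic resistances
are 5% of each bed's peripheral resistance; terminal compliances split a
0.35 ml/mmHg pool and scale together with distensibility.

The coupled ODE system is integrated with a fixed-step explicit RK4 scheme
(default $dt = 10^{-4}$ s, all quantities internally SI, clinical units at
every interface with 1 mmHg = 133.322 Pa). Nodes start at 80 mmHg with zero
flows and the ventricle at its end-diastolic equilibrium volume
$V_d + P_{fill}/E_{ed}$; cycles are integrated until the maximum
cycle-to-cycle node-pressure change drops below 0.5 mmHg (at most 20
cycles), and the final cycle is resampled to 200 points. Divergence aborts
with the offending parameter set; non-convergence is reported as a flag and
treated as a rejection by the cohort generator. Two to three spatial
elements per segment keep a single subject near 50 ms; finer discretization
sharpens wave features slightly but roughly doubles the cost, and the
packaged default favors cohort throughput.

## The virtual population

Nine parameters are sampled as independent Gaussians (means and SDs from
the literature): $E_{es}$ 2.3±1, $E_{ed}$ 0.2±0.11 mmHg/ml, filling
pressure 15±5.4 mmHg, $t_{es}$ 327±39 ms, heart rate 63.7±9.5 bpm, aortic
distensibility 5.86±3.23 ($10^{-3}$/mmHg), total peripheral resistance
1.28±0.31 mmHg·s/ml, aortic diameter 33.2±4.1 mm and height 169.2±8.9 cm.
The diameter figure is sometimes printed in centimetres, which is
anatomically impossible; the package treats it as millimetres. No
inter-parameter dependencies are modelled (there are no data to inform
them). Draws outside physiologically defensible truncation bounds (for
example $E_{es} \in [0.3, 6]$) are redrawn, keeping the marginals
near-Gaussian; draws with $E_{es} \le E_{ed}$ or with a systole longer than
the cycle are recorded as rejected subjects.

Heights scale all segment lengths relative to the 180 cm reference subject;
the sampled aortic diameter scales all diameters uniformly (there are no
data for differential scaling); distensibility and terminal compliance move
together.

Each simulated subject is screened against normative brachial and aortic
blood-pressure values: all eight of SBP, DBP, MAP and PP at both sites must
lie within mean ± 2.807 SD (a 99.5% normal band, inclusive at the
boundary). The reference table shipped with the package (brachial
123/76/92/47, aortic 112/77/92/35 mmHg, with SDs of 10–15 mmHg) encodes
plausible literature norms; the filter mechanism, not the particular
constants, is the methodological point, and the table is an editable
argument. Because the exact normative values behind the original 37%
acceptance rate are not published, the acceptance rate of this surrogate
(about 20% under the defaults) is a soft, qualitative check only. As in
the original study population, the filter selects upward in heart rate and
filling pressure and the accepted population has a mean ejection fraction
near 47%.

## Preprocessing and learning

Accepted subjects' left-brachial waves (200 samples per cycle) are split
60/20/20 into training/validation/test by a seeded permutation. The time
derivative is computed with central differences, $f'[n] =
(f[n+1]-f[n-1])/(2\tau)$, $\tau = T/200$, with periodic wrap-around at the
endpoints since the wave is one full cycle. Both channels are min–max
normalized per time point; scalers are fitted on the training rows only and
applied unchanged to validation and test rows (no clipping), and the
derivative channel gets its own scaler so the two channels stay
commensurate. Targets remain in native mmHg/ml.

The two regressors are the published small architectures: four conv1d
stages (kernel 5, stride 2, padding 2), each followed by a ReLU, filter
counts 2/4/8/16 (one-channel) or 8/16/18/24 (two-channel), then a single
max-pool (kernel 3, stride 2), flatten (widths 96 and 144), and one affine
output unit. Training minimizes the MSE with Adam at learning rate 0.001.
Hyperparameter tuning follows the published grid — batch sizes {32, 64,
128} and epochs 1–400 — implemented as per-epoch validation checkpointing,
which evaluates every epoch candidate at one training cost and restores the
weights of the argmin-validation epoch. Weight initialization is seeded
uniform scaled by fan-in; convolution biases start slightly positive
because the min–max-normalized inputs are non-negative and an unlucky
symmetric initialization of the very small first layers (two filters) can
otherwise leave every rectified unit silent. The engine is single-threaded
C++, so fixed seeds reproduce training curves bit for bit.

## Noise robustness

Measurement error is emulated by adding white Gaussian noise to the raw
test-set pressure waves at SNRs of 70/60/50/40/30 dB, with the
measured-power convention ($\sigma^2 = P_{sig}/10^{SNR/10}$, $P_{sig}$ the
per-subject mean square). Noise is applied only to the test set, after
training; for the two-channel model the derivative is recomputed from the
noisy pressure so corruption propagates through the derivative, and both
channels are renormalized with the frozen training scalers.

## Metrics

Agreement is summarized by the regression line of estimates on truth,
Pearson's r with a t-distribution p-value, RMSE, range-normalized RMSE
(percent of the reference max–min), Bland–Altman bias with 1.96 SD limits
of agreement (differences are estimate minus reference, SDs use the n−1
denominator), the predicted-population mean and SD, and fractions of
absolute errors below 0.05 and 0.5 mmHg/ml (strict inequality). Every
statistic is tested against a brute-force formula oracle.

## What the synthetic data do and do not show

The generator emulates the study conditions: the parameter distributions,
the geometry scaling, the plausibility screen, the 200-sample single-cycle
format, and the preprocessing/training recipe. It does not reproduce the
original high-fidelity arterial model: the surrogate's smoother, lower
dimensional waveforms carry measurably less information about $E_{es}$
than the original model's (pressure level and pulse alone are strongly
confounded by the unobserved ventricular volumes), so test-set agreement
under the surrogate sits below the published headline numbers, and results
here quantify the method under the reduced-order physics rather than
certify clinical performance. Passing tests demonstrate that the pipeline
is implemented faithfully and reproducibly — not that a brachial cuff
waveform clinically determines contractility.

## Problem sizes

The shipped evaluation runs use a cohort of at least 2,000 accepted
subjects (roughly 10,000 sampled at the default acceptance rate), the
60/20/20 split, both architectures over the full batch-size grid with up to
400 epochs, and the five-level noise sweep; unit tests use a 600-waveform
analytic toy substrate and 25–40 subject micro-cohorts.
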