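---
title: "Methods: simultaneous PET-MR myocardial blood flow quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous PET-MR myocardial blood flow quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfquant)
```

perfquant implements ROI-level myocardial blood flow (MBF) quantification
for simultaneously acquired dynamic contrast-enhanced MR and ¹³N-ammonia
PET, together with a digital perfusion phantom used to validate both
quantification arms by parameter recovery. This vignette is the package's
account of the science: the models, their assumptions, the parameters that
matter, the numerical choices, and what the validation does and does not
demonstrate.

## The digital phantom

The phantom emulates a flow circuit in which a bolus-shaped arterial input
feeds a single well-mixed "myocardial" compartment:

$$V_d \frac{dC_m}{dt} = Q\,(C_a - C_m), \qquad Q = F \cdot m,$$

with $F$ the perfusion rate (mL/g/min), $m$ the tissue-equivalent mass (g)
and $V_d$ the dispersion (mixing) volume at the sampling site (mL). The
impulse response is the exponential $(Q/V_d)\,e^{-(Q/V_d)t}$; knowing
$V_d/m$ calibrates measured rates into mL/g/min in both arms, which is
what makes the two modalities commensurable on the phantom.

Boluses are peak-normalized gamma variates
$g(t) = d\,\big((t-t_a)/\alpha\beta\big)^\alpha e^{\alpha-(t-t_a)/\beta}$
(defaults $\alpha = 3$, $\beta = 4$ s), the standard first-pass shape; the
protocol is a dilute contrast bolus (dose ratio 1:10) followed 120 s later
by the neat bolus, with the PET tracer co-injected with the neat bolus. MR
samples one dynamic per heartbeat (heart rate 60, so 1 s) for 240
dynamics; PET frames run 60 × 3 s + 8 × 15 s from injection.

Key generator defaults, chosen once where the protocol leaves them open:

| parameter | default | rationale |
|---|---|---|
| $V_d$, $m$ | 15 mL, 45 g | see "Compartment geometry" below |
| neat arterial peak Gd | 0.3 mmol/L | keeps phantom signals in the quasi-linear range of the long-T1 saline compartment (the regime the dual-bolus design targets); tissue peaks stay below ~0.25 mmol/L |
| dilute arrival | 12 s | a few samples of pre-contrast baseline beyond the 8 baseline dynamics |
| PET arterial peak | 100 kBq/mL | activity scale cancels in the kinetic model |
| MR noise sd | 0.05 a.u. (M0 = 1000) | ROI-mean noise for large uniform phantom chambers (AIF enhancement SNR ≈ 50) |
| PET frame cv | $0.05/\sqrt{\Delta t}$ | count-statistics scaling: longer frames are quieter |

**Compartment geometry.** $m/V_d = 3$ makes the washout rate $3F$ per
minute (time constant 20 s at 1 mL/g/min). A unit-ratio compartment
($V_d = m$) would washout with a 60-s time constant at the lowest flow, so
the 240-dynamic acquisition would truncate roughly a fifth of the
myocardial indicator mass — and the integral-matching AIF normalization
(below) would inherit that as a +20% flow error. A compact mixing chamber
keeps the washout inside the printed acquisition window; physically it
corresponds to sampling close to a small, well-stirred dispersion volume
while the mass calibration describes the full perfused equivalent.

**What the phantom does not emulate.** No recirculation, no vascular
transit-time distribution (the impulse response is purely exponential), no
contrast extravasation or tracer trapping, no T2* effects, no spatially
resolved signal, Gaussian rather than Poisson/Rician noise. Passing the
recovery tests therefore shows the estimators are correct for a
single-compartment system under the stated noise models — not that they
are unbiased on real myocardium, where the impulse response has a vascular
plateau and the noise is structured.

## The CMR arm

### Signal model and the dual-bolus AIF

The saturation-recovery FLASH signal is modelled analytically as
$S = M_0 \sin\alpha\,(1 - e^{-TI \cdot R_1})$ with
$R_1 = 1/T_{10} + r_1 c$. This preserves the saturating
signal-concentration relationship that motivates the dual-bolus protocol
while remaining closed-form and exactly invertible; the readout-train
correction of a full Bloch simulation is an extension point, not
implemented. Defaults: phantom protocol TI 100 ms / flip 10° / saline
T10 3000 ms; volunteer protocol TI 115 ms / flip 14° / blood T10 1900 ms,
myocardium 1200 ms; gadobutrol relaxivity 5.0 L mmol⁻¹ s⁻¹ at 3 T
(configurable — the agent is specified, its relaxivity is a literature
convention).

The AIF is measured from the dilute bolus, where signal is quasi-linear,
then scaled by the dose ratio and shifted to the neat arrival. Two
pipeline decisions matter here:

* **Shift by the known inter-bolus delay.** `assemble_dual_bolus_aif()`
  aligns the dilute bolus foot (first sample above 5% of peak) with a
  target arrival; the pipeline passes *detected foot + injection delay*,
  which reproduces the neat bolus timing exactly since both boluses share
  one injection apparatus. Aligning the foot with the neat *onset* instead
  leaves the surrogate several seconds early and biases the delay search.
* **Gamma-variate denoising** (`smooth_aif = TRUE`). The AIF enters the
  deconvolution as a regressor, so AIF noise acts as an
  errors-in-variables problem: it attenuates the fitted amplitude (about
  −3% at the default noise level) and inflates its variance. Fitting the
  measured dilute curve with a parametric gamma variate — standard
  first-pass practice — removes both effects.

### Phantom-mode normalization

Phantom analyses run on baseline-corrected *signal* curves (native T1 of
the phantom fluid is treated as unknown, so no lookup-table conversion is
attempted; the modest saturation left at the default concentration
calibration costs 1–2% of flow). The AIF scale is then fixed by indicator
conservation: with complete washout, $\int C_m = \int C_a$, so the AIF is
rescaled by $\int myo / \int aif$. Both integrals are evaluated **over the
neat-bolus window only** (from 10 s before the neat arrival): the full
acquisition also contains the dilute bolus' own tissue response, which
would inflate the myocardial integral by the reciprocal dose ratio (~10%)
and depress MBF by the same amount. In volunteer mode the lookup-table
conversion replaces integral matching, and the tissue-density convention
(1.05 g/mL) replaces the geometric calibration.

### Fermi deconvolution

The impulse response is constrained to a Fermi function, parameterized by
its height at onset:

$$R(t) = A\,\frac{1 + e^{-k\tau_0}}{1 + e^{k(t - \tau_d - \tau_0)}},
\qquad \text{MBF} = A \cdot 60 \cdot \text{calibration}.$$

A deliberate design choice is that $\tau_0$, the inflection position, may
be **negative**. For $\tau_0 > 0$ the response has the classic
plateau-then-decay shape that fits real myocardium (vascular transit
plateau). For $\tau_0 \ll 0$ the same formula degenerates smoothly to
$A e^{-kt}$ — the exact impulse response of a well-mixed compartment. If
$\tau_0$ is forced non-negative, the best Fermi approximation to an
exponential response carries a shoulder, and its onset height
underestimates flow by 20–37% across the 1–5 mL/g/min grid (we verified
this is the global optimum by grid search). That constrained behaviour
reproduces the systematic CMR-below-PET bias reported for physical
single-compartment phantoms; the unconstrained family removes it, and the
sign convention keeps MBF = $R(\tau_d)$ = the amplitude parameter in both
regimes. Both branches are evaluated in overflow-safe forms.

Optimization: bounded Levenberg–Marquardt (minpack.lm) on
(amplitude, $k$, $\tau_0$) with bounds $A \in [0, 100 A_0]$,
$k \in [10^{-4}, 5]$ s⁻¹, $\tau_0 \in [-600, 300]$ s; deterministic
multistarts (amplitude at twice the central-volume ratio
$\max C_t / \int C_a$; $k \in \{0.05, 0.2\}$ s⁻¹; $\tau_0$ at the tissue
time-to-peak and at −30 s); the onset delay is searched on whole samples
(0–2 plus the AIF-to-tissue foot lag) and fixed within each fit, keeping
the objective smooth. Best RSS wins; ties go to the smaller parameter
norm. Convergence: ftol 10⁻¹⁰, max 300 iterations; a fit that converges
from no start returns `converged = FALSE` with `NA` MBF rather than a
silent zero.

**Quadrature.** The model convolution uses trapezoidal weights on a grid
upsampled 4× from the 1-s dynamics (linear AIF interpolation, read back at
the sample times). At the highest phantom flow the response e-folds in
4 s, and 1-s trapezoid convolution alone leaves a ~4% flow bias; 4×
upsampling reduces the quadrature error below 1%. The simulator itself
integrates the exponential kernel *exactly* against piecewise-linear
inputs, so simulator and fitter never share discretization errors.

## The PET arm

Frame means are exact time-averages of the piecewise-linear fine curve
(`bin_frames()`), and decay correction multiplies by the exact
frame-average factor $\lambda\Delta t / (e^{-\lambda t_1}(1 -
e^{-\lambda\Delta t}))$ — not the midpoint factor — so a constant source
measured under decay is restored to machine precision (`expm1` guards the
near-stable limit). The default half-life is the ¹³N value, 9.96 min, and
correcting twice is a state error.

The one-tissue compartment model
$C_t = (1-V_b) K_1 (C_a \ast e^{-k_2 t}) + V_b C_a$ is fitted to the
frames whose midpoints fall within the first 240 s (the 4-min window that
limits metabolite effects in vivo; 180/240/300-s fits are reported
together when `diagnostics = TRUE`). Weights are proportional to frame
duration. The model is evaluated on a 0.25-s grid and frame-averaged with
the same quadrature as `bin_frames()`, so binning the model and binning
the data commute. The fine-grid AIF is reconstructed from its frame means
by a monotone Hyman spline through the cumulative frame integrals — the
reconstruction reproduces every frame mean exactly; midpoint
interpolation, by contrast, clips the 3-s-frame bolus peak and leaves a
~6% $K_1$ bias at high flow. $V_b$ is fixed at 0 in phantom mode (no
arterial signal inside the sampled chamber) and fitted in $[0, 0.5]$ in
vivo. MBF is read as $K_1$ (DeGrado convention); an extraction-fraction
correction (¹³N extraction ~85% in vivo) is a configuration hook left off
by default to match the implemented model.

## Agreement statistics

`bland_altman()` uses differences CMR − PET (so CMR underestimation is a
negative bias) and limits ±1.96·SD with the $n-1$ denominator and no
small-sample correction. `icc21()` is ICC(2,1) — two-way random effects,
absolute agreement, single measure — computed from the ANOVA mean squares;
absolute agreement is the defensible form when the same coefficient
grades test–retest repeatability and cross-modality agreement. Pearson r
and its two-tailed p come from the t transform with $n-2$ df. The AHA
16-segment map assigns LAD {1,2,7,8,13,14}, RCA {3,4,9,10,15},
LCX {5,6,11,12,16}; territory and global MBF are unweighted segment means.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle
(closed forms for the compartment, an $O(n^2)$ direct-sum convolution, an
ANOVA-based ICC, analytic decay) and the pipeline end-to-end by parameter
recovery: noise-free recovery within 5% at every flow of the 1–5 mL/g/min
grid for both arms, monotonicity in true flow, cross-arm correlation
above 0.99, and — under the default noise models — bias within 5% and
coefficient of variation under 10% per flow per arm over 50 replicates
(250 simulated studies, a few minutes of compute). Reproducibility is
part of the contract: one integer seed drives all noise, identical
configurations give byte-identical artifacts, and wall-clock timing stays
out of written reports.

## Known limitations

* The Fermi and one-compartment models are fitted to ROI curves only; no
  pixel-wise mapping, no multi-compartment (two-tissue) PET model, no
  model-based CMR tracer kinetics.
* The analytic SR-FLASH equation ignores the readout train; absolute
  lookup-table accuracy against a full Bloch simulation is not asserted.
* Phantom-mode accuracy leans on indicator conservation within the
  acquisition window; flows well below 1 mL/g/min (washout slower than
  the acquisition) would reintroduce truncation bias.
* In vivo agreement numbers (correlations, biases between modalities)
  depend on real acquisitions and are outside what the digital phantom
  can reproduce; the package only demonstrates internal consistency of
  the comparison machinery on simulated cohorts.
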