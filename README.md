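# perfquant

Quantification of myocardial blood flow (MBF) from **simultaneous PET–MR
perfusion imaging**: Fermi-constrained deconvolution for dynamic
contrast-enhanced CMR, the DeGrado one-tissue compartment model for
¹³N-ammonia PET, and the agreement statistics used to compare the two
modalities — plus a digital perfusion phantom that generates matched MR and
PET curves at known flows so the whole pipeline is testable by parameter
recovery.

It is aimed at researchers working with ROI-level perfusion curves (an
arterial input region plus one or more myocardial regions), not with raw
scanner data: image reconstruction, attenuation/motion correction and
segmentation happen upstream.

## The models

**CMR arm.** First-pass gadolinium kinetics obey the central volume
principle: the myocardial concentration curve is the convolution of the
arterial input function (AIF) with a tissue impulse response whose initial
height equals flow,

```
C_myo(t) = (C_a ⊛ R)(t),    MBF = R(τ_d) · 60 · calibration .
```

`R` is constrained to a Fermi function

```
R(t) = A · (1 + e^{-kτ₀}) / (1 + e^{k(t - τ_d - τ₀)}) ,  t ≥ τ_d ,
```

parameterized so the amplitude `A = R(τ_d)` is read directly as MBF. The
inflection position τ₀ may be negative, in which case the response
degenerates smoothly to the exponential `A·e^{-kt}` of a well-mixed
compartment — essential for phantom data, where the tissue volume *is* a
single mixing chamber. The fit is bounded Levenberg–Marquardt least squares
with deterministic multistarts and an integer-sample delay search.

Because MR signal is a saturating function of concentration
(`S = M0 sinα (1 − e^{−TI·R1})`, `R1 = 1/T10 + r1·c`), the AIF is measured
from a **dilute pre-bolus** (dose ratio 1:10), rescaled and shifted onto the
neat bolus by the known inter-bolus delay. In phantom mode the residual
scale is fixed by matching the AIF time-integral to the myocardial curve
(indicator conservation); in volunteer mode signal is converted to
concentration through a lookup table of the signal model.

**PET arm.** Frame-binned time–activity curves (60 × 3 s + 8 × 15 s) are
decay-corrected with exact frame-average factors (¹³N half-life 9.96 min)
and fitted with the one-tissue compartment model

```
C_t(t) = (1 − V_b)·K1 ∫ C_a(u) e^{−k2(t−u)} du + V_b·C_a(t) ,   MBF = K1 ,
```

over the first 4 min after injection, with the fine-grid AIF reconstructed
from frame means by a monotone spline through cumulative frame integrals.

**Agreement.** `pearson_agreement()`, `icc21()` (ICC(2,1), two-way random
effects, absolute agreement), `bland_altman()` (differences CMR − PET,
limits ±1.96 SD), `territory_aggregate()` (AHA 16-segment → LAD/LCX/RCA +
global), and `agreement_report()` combining them.

## Worked example

Simulate one dual-bolus phantom run at 3 mL/g/min with realistic noise and
quantify it with both arms:

```r
library(perfquant)

ds  <- simulate_protocol(phantom_config(flow = 3, seed = 7))
quantify_cmr_phantom(ds)
#> Fermi-constrained deconvolution fit
#>   MBF: 2.947 mL/g/min  (amplitude 0.1473 s^-1, calibration 0.3333)
#>   decay_k 0.1473 s^-1, width_tau0 -283.5 s, delay 0 s
#>   rss 0.4937, converged TRUE (8 iter)
quantify_pet_phantom(ds)
#> One-tissue-compartment (DeGrado) fit
#>   MBF (= K1): 2.933 mL/g/min, k2 8.853 min^-1, Vb 0
#>   window 240 s, rss 0.1796, converged TRUE (9 iter)
```

Both arms recover the true flow of 3 mL/g/min within ~2%. The very negative
`width_tau0` says the fitted impulse response is in its quasi-exponential
regime, as expected for a well-mixed compartment; `k2 ≈ 8.85 min⁻¹` tracks
the compartment washout rate `flow × mass / V_d = 9 min⁻¹`.

A full flow-grid study with the cross-modality comparison:

```r
study <- run_phantom_study(flows = 1:5, n_replicates = 2, seed = 42)
agreement_report(study, x = mbf_cmr, y = mbf_pet)
#>       n pearson_r     pearson_p   icc    bias loa_low loa_high
#> 1    10     0.996 0.00000000103 0.995 -0.0582  -0.338    0.221
```

The two arms correlate at r = 0.996 with a small negative bias (CMR slightly
below PET) — the same qualitative picture as physical phantom experiments,
where CMR tends to underestimate PET. `autoplot()` works on fits,
curves, TACs and agreement reports; `tidy()`/`glance()` give tibble views
of every fit object.

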