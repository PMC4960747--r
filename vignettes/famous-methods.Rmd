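---
title: "Methods: macromolecule-suppressed glutamate editing with famousr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macromolecule-suppressed glutamate editing with famousr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famousr)
```

## The measurement problem

Glutamate (Glu) is the brain's principal excitatory neurotransmitter. Its
C4 proton resonance at 2.35 ppm is a J-coupled multiplet sitting on a broad
background of short-T1 macromolecule (MM) resonances, flanked by NAA
(2.01 ppm) and creatine (3.03 ppm). Quantifying it from a single-voxel 7T
proton spectrum therefore needs three things at once: isolation of the
2.35 ppm signal, removal of the MM background, and an absolute reference.

The five-spectrum scheme implemented here (FAMOUS SVGS) solves all three
within one acquisition:

1. **Water reference** — no suppression; used for eddy-current correction,
   coil combination weights, automated phasing and absolute referencing.
2. **Control1 / Selinv1** — water-suppressed acquisitions with a
   frequency-selective inversion (FSI) pulse applied at 7.05 ppm (mirrored
   about water) and at 2.35 ppm respectively. Their difference retains
   only resonances inside the FSI band.
3. **Control2 / Selinv2** — the same pair with a double inversion recovery
   (DIR) preparation that nulls metabolite magnetization (T1 1-2 s) while
   letting short-T1 MM signal (~0.3 s) recover. The second difference pair
   contains the *MM-only* edited signal.

The in-vivo edited spectrum is `(Control1 - Selinv1) - (Control2 -
Selinv2)`: MM signal is edited identically in both pairs and cancels;
metabolite signal, absent from the nulled pair, survives. For phantoms
(no MM) the plain difference `Control1 - Selinv1` suffices.

## Sequence physics

### The FSI pulse

The editing pulse is a truncated-Gaussian amplitude-modulated inversion
calibrated to *50% inversion* at band center — we read this as inversion
depth `(1 - Mz)/2 = 0.5`, i.e. Mz driven from +1 to 0 (saturation). The
alternative reading (Mz to -0.5) is available by raising
`target_inversion`; because the editing efficiency used in quantification
is computed from the same Bloch profile, the pipeline is self-consistent
under either convention.

`design_fsi_pulse()` finds, by bisection with the on-resonance amplitude
recalibrated at every trial, the longest (most selective) duration whose
inversion depth stays within 10% of target across the requested band
(default 60 Hz: the 14 Hz triplet span plus ~45 Hz shim margin). The 10%
band tolerance is a deliberate choice: a Gaussian profile cannot be flat
to 1% across +/-30 Hz while also decaying below 0.05 depth beyond three
bandwidths — those two requirements meet at roughly the 10% level, and
the resulting duration (10.3 ms for the default band) sits in the
expected 10-40 ms range for this pulse class. Bloch integration uses 512
piecewise-constant segments with rotation-matrix updates and no
relaxation during the pulse (pulse << T1, T2); the profile of an AM pulse
is evaluated on |offset| so its even symmetry is exact in floating point.

### Metabolite nulling

For two instantaneous inversions followed by exponential recovery (full
recovery before the first inversion assumed),

$$M_z/M_0 = 1 - 2e^{-TI_2/T_1} + 2e^{-(TI_1+TI_2)/T_1}.$$

`optimize_double_ir_delays()` minimizes the worst-case |Mz/M0| over T1 in
[1, 2] s by coarse grid search plus two local refinements (ties broken
toward the shorter total delay). The optimum (~2.13 s / ~0.59 s) leaves a
worst-case metabolite residual of ~0.025 — an order of magnitude better
than the best single inversion (~0.24). The model ignores TR saturation:
at TR 3 s a 2 s T1 is only ~78% recovered, so absolute nulling depths in
a real scan would differ somewhat; this is a documented limitation, not
modeled, because the quantification only needs the *relative* bookkeeping
below. MM magnetization at T1 0.3 s retains Mz ~ 0.72 under these delays,
so the second difference pair removes ~72% of the in-band MM signal —
about a 3.6x reduction, the figure the package's tests assert.

### What the editing keeps

A line partially inverted to Mz keeps the fraction `(1 + Mz)/2` of its
equilibrium observable signal; the difference spectrum therefore retains
`kappa = (1 - Mz)/2` of it — 0.5 at the 50%-inversion design point.
`editing_efficiency()` computes kappa as the amplitude-weighted mean over
the edited 1:2:1 triplet from the designed profile (~0.4986 by default),
and `quantify_glu()` uses that same number, so acquisition and
quantification cannot drift apart under configuration changes. In in-vivo
mode the edited amplitude additionally carries the known factor
`1 - Mz_DIR(T1_met)` from the subtracted nulled pair; quantification
divides it out at the configured nominal metabolite T1 (1.4 s).

## The synthetic acquisition

`simulate_acquisition()` generates the five labelled multi-channel FID
sets of one scan. Each channel's stored FID is the *sum* over averages
(scanner convention) of

$$\sum_\text{lines} w_\ell\, A_\ell\, g_c\,
  e^{i(\phi_\ell + \theta_c)}\, e^{2\pi i f_\ell t}\, e^{-\pi W_\ell t}\,
  e^{i\phi_\text{eddy}(t)} + \text{noise},$$

with the per-line, per-block weight $w_\ell$ from the state table above,
amplitudes in mM-proton units (concentration x proton count; water
carries 2 x 55510 x water-fraction), and complex Gaussian noise of SD
$\sigma\sqrt{n_\text{avg}}$. Defaults and their rationale:

* **Protocol**: TR 3000 ms, TE 21 ms, 4096 points, 6000 Hz, 4 dummies,
  8 water / 32 suppressed averages — the published phantom and in-vivo
  protocols (252 s and 468 s total).
* **Linewidth 15 Hz** for water and metabolites: the de-shimmed phantom
  condition chosen to mimic in vivo. T2/TE decay is absorbed into the
  linewidths (TE is short and no relaxation correction is applied
  downstream either).
* **Eddy transient** `1.0 rad x 5 ms + 0.3 rad x 50 ms`, identical across
  blocks and channels — representative decaying gradient transients; the
  shared-transient assumption is exactly what makes water-referenced
  correction exact.
* **Residual water 1/140**: the suppression factor the sequence achieves;
  the water-suppression pulse train itself is represented only by this
  factor, since its purpose and achieved performance, not its flip
  angles, are what matter spectrally.
* **Four receiver channels** with fixed gains/phases — enough to exercise
  the combination math; a 32-channel array adds nothing testable.
* **Noise sigma 4.0** (mM-proton units per sample per shot per channel):
  yields ~1% single-scan concentration precision at protocol averages,
  typical of a well-shimmed 7T editing study. The published in-vivo CoV
  of 6.6% is then dominated by physiological/positioning variance, as it
  should be.
* **Brain composition**: Glu 9.57 mM (the published mean) as a 1:2:1
  pseudo-triplet at +/-7 Hz; MM line at 2.30 ppm, 4 mM-protons, 40 Hz,
  T1 0.3 s (~15% contamination of the edited band when not nulled); NAA
  12 mM and Cr 8 mM singlets (3 protons each, T1 1.7/1.6 s); 80% tissue
  water. Glutamine (~2.44 ppm) is not modeled by default.

The pseudo-triplet replaces full density-matrix J-evolution: only the
line positions, relative amplitudes and total proton count matter to the
editing and integration bookkeeping being tested. Likewise there is no
spatial localization, no frequency drift across averages, and no motion.
Passing tests therefore demonstrate the correctness of the processing
and quantification chain under its own stated signal model — not
robustness to lineshape distortion, drift or lipid artifacts in real
scanner data.

## Automated processing

`preprocess_set()` applies, identically to every block: division by the
stored average count; coherent channel combination with matched-filter
weights from the conjugate first water-reference sample (unit power,
reused across blocks so inter-block ratios survive); Klose eddy-current
correction `fid * exp(-i arg(water))`; 7 Hz exponential apodization;
Fourier transform; and a single zero-order phase chosen in closed form to
maximize the real water integral, applied to all five spectra. Numerical
choices worth noting:

* **First-point scaling**: the t = 0 FID sample is halved before the FFT.
  The rectangle rule applied to a one-sided signal otherwise adds a flat
  baseline of `dwell x s(0)/2` across the spectrum — small, but large
  enough to bias a 0.2 ppm band integral by a percent.
* **No zero-filling, no first-order phase**: 4096 points suffice, and
  eddy correction plus on-resonance acquisition leave no linear phase in
  this model (documented limitation for real data).
* ECC and apodization are pointwise multiplications and commute; a
  regression test asserts this so the step order stays a free choice.

## Quantification

The edited band integral (2.25-2.45 ppm, trapezoid on the native grid,
closed interval, no interpolation) is converted to concentration by

$$C = \frac{I_\text{Glu}/(\kappa\, n_\text{met})}
           {I_\text{water}/n_\text{water}}
      \times f_\text{water} \times 55510\ \text{mM},$$

with the water integral taken from the *analytic* area of a
Levenberg-Marquardt Lorentzian fit of the water reference (so window
truncation cannot bias the denominator), proton counts 2/2, and water
fraction 1.0 (phantom) or 0.8 (brain). No relaxation correction is
applied by default; a multiplicative hook exists.

Two bookkeeping factors are applied to the numerator and reported in the
diagnostics:

* **Band-truncation correction.** A 22 Hz edited line (15 Hz + 7 Hz
  broadening) leaves ~23% of its Lorentzian area outside the +/-29.7 Hz
  band. The captured fraction is computed in closed form (Lorentzian CDF
  of the edited triplet, per-line depths from the FSI profile, linewidth
  from the water fit — water and metabolites share the shim) and divided
  out. Without it, recovered concentrations would run ~0.77x true and
  the phantom linearity slope could not approach 1.
* **DIR residual factor** `1 - Mz_DIR(T1 nominal)` in in-vivo mode, as
  above.

In phantom mode a Lorentzian fit of the difference peak is also reported
(the band integral stays the primary number). The Levenberg-Marquardt
fits run on the residual function directly; the conventional
`nls`-object route fails on symmetric lines, where the phase and
center-frequency gradients become collinear.

Noise-free end-to-end recovery is 8.96 mM at 9 mM truth (-0.4%,
dominated by band-edge discretization of the closed-interval trapezoid);
the four-phantom series regresses with slope ~1.01 and R-squared > 0.999
at default noise. In-vivo recovery with the default MM and NAA
contamination is within 5% of truth, versus ~15% high when the same data
are processed phantom-style — the quantitative case for the metabolite
nulling. The residual in-vivo bias is real physics of this configuration:
~72% MM retention under the optimized delays and the NAA Lorentzian tail
entering the band through the 10 ms pulse's transition wings.

## Calibration and statistics

`reference_voltage()` inverts the stimulated-echo two-voltage
calibration: a STEAM signal scales as sin^3(theta), so
`S2/S1 = 8 cos^3(theta)` identifies the flip angle at 100 V and
`B1 = 9000 / theta_deg`. Noise-negative S2 is clamped to zero with a
warning (the 180-degree null is approached at high ratio); S2 >= 8 S1 is
a domain error.

`icc_oneway()` is the one-way random single-measures intraclass
correlation `(MSB - MSW)/(MSB + (k-1) MSW)` with the classical exact-F
two-sided interval — the only form that reproduces both published bounds
(0.745, 0.996) from the packaged 5 x 2 table. Mean +/- SD and CoV use
the sample (n-1) SD, required to reproduce 0.63 and 6.6% from the same
ten values. A simulation test checks the interval's coverage at ICC 0.9
(93-97% over 2000 replicates).

```{r stats}
glance(retest_summary(glu_retest_example()))
```

## Problem sizes and determinism

All simulations in the tests and the acceptance script run at the full
protocol size (4096 points, 4 channels, 3 or 5 blocks); one simulated
scan plus quantification takes well under a second, so no scaling down
was needed. Every stochastic step takes an explicit seed
(`artifact_model(seed = )`), and a seeded acquisition is bit-reproducible.
Grid searches (pulse bisection, delay optimization) are deterministic.

## Known limitations

* Single-voxel amplitude model only: no localization physics, chemical
  shift displacement, drift or motion.
* Pseudo-triplet Glu, singlet neighbors, single MM line: compositions are
  configurable but make no claim of spectral fidelity.
* Full TR recovery assumed in the DIR model; steady-state saturation at
  TR 3 s is not modeled.
* No first-order phase or baseline correction (the method's premise is
  that the difference spectrum needs neither).
* Whether an empirical scanner calibration would absorb kappa rather than
  apply it explicitly cannot be decided from published absolute values
  alone; the package makes the physically explicit choice.
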