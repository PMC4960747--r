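# famousr

Macromolecule-suppressed glutamate editing for 7T single-voxel proton MR
spectroscopy, implemented end to end: sequence physics, synthetic
acquisition, automated processing, absolute quantification and
test–retest statistics.

## The problem and the method

Glutamate's C4 resonance at 2.35 ppm sits on a broad short-T1
macromolecule (MM) background, next to NAA and creatine. The five-spectrum
FAMOUS SVGS scheme isolates it with a frequency-selective inversion (FSI)
pulse and removes the MM background with a double inversion recovery
(DIR): one scan acquires a water reference plus two control/inversion
pairs, the second pair with metabolite magnetization nulled. The edited
spectrum is

```
phantom:  Control1 − Selinv1
in vivo: (Control1 − Selinv1) − (Control2 − Selinv2)
```

so only resonances inside the FSI band survive, and MM signal — edited
identically in both pairs because its short T1 defeats the nulling —
cancels. The edited band integral I_Glu (2.25–2.45 ppm) becomes an
absolute concentration by water referencing:

```
C = [ I_Glu / (κ·n_met) ] / [ I_water / n_water ] × f_water × 55510 mM
```

with κ the editing efficiency computed from the Bloch profile of the
designed FSI pulse (≈0.5 at the 50%-inversion design point), I_water the
analytic area of a Lorentzian fit of the water reference, and f_water the
tissue water content (1.0 phantom, 0.8 brain). The package authors the
whole chain: Bloch simulation of the shaped pulse, minimax optimization
of the nulling delays, a multi-channel acquisition simulator with eddy
current/coil/noise artifacts, the automated processing chain (matched
filter coil combination, Klose eddy-current correction, 7 Hz apodization,
FT with first-point scaling, water-referenced auto-phasing), the
quantification above, the two-voltage STEAM B1 calibration, and one-way
random ICC test–retest statistics with exact-F confidence intervals.

## Worked example

```r
library(famousr)

fsi <- design_fsi_pulse()           # 60 Hz band, 50% inversion
ir  <- optimize_double_ir_delays()  # null T1 in [1, 2] s
fsi
#> <fsi_pulse> 10.34 ms Gaussian, target depth 0.5 over 60 Hz at 2.35 ppm
ir
#> <double_ir_delays> ti1 2132.1 ms, ti2 591.9 ms; worst |Mz| 0.0247 over T1 1 - 2 s

# simulate a 9 mM phantom scan, process and quantify it
q <- famous_pipeline(9, mode = "phantom", seed = 1, fsi = fsi, ir = ir)
q
#> <famous_quant> phantom mode: Glu 8.848 mM (kappa 0.4986 )
```

The 10.3 ms Gaussian pulse saturates the 2.35 ppm triplet (κ ≈ 0.4986 of
the Glu signal survives in the difference); the optimized delays leave at
most 2.5% residual metabolite magnetization across T1 1–2 s; and the
simulated 9 mM phantom is recovered at 8.85 mM (noise at the default
level contributes ~1% scatter; the noise-free recovery is 8.96 mM).

Repeatability statistics from the packaged five-subject, two-scan
example table:

```r
glance(retest_summary(glu_retest_example()))
#> # A tibble: 1 × 10
#>       n     k  mean    sd cov_percent   icc icc_ci_low icc_ci_high    icc_p max_abs_diff
#>   <int> <int> <dbl> <dbl>       <dbl> <dbl>      <dbl>       <dbl>    <dbl>        <dbl>
#> 1     5     2  9.57 0.632        6.60 0.961      0.745       0.996 0.000311         0.25
```

Mean 9.57 ± 0.63 mM, CoV 6.6%, ICC(1,1) 0.961 with 95% CI (0.745,
0.996), and a maximal between-scan change of 0.25 mM.

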