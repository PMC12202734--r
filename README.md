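# vfadesign

SAR-constrained design of variable flip-angle (VFA) refocusing trains for
3D fast-spin-echo (FSE/TSE) MRI with very long echo trains, for sequence
developers and MR physicists working at high field.

In 3D FSE, a single excitation is followed by hundreds of refocusing
pulses; the signal decays along the train, so each phase-encoding line is
weighted by a different amplitude (the modulation transfer function, MTF).
The Fourier transform of the MTF is the point-spread function (PSF), whose
side bands are T2 blurring. Variable flip angles can store magnetisation
longitudinally and flatten the MTF -- but the classical design is a
heuristic, built for one tissue, and the RF power budget (relative SAR,
`rSAR(α) = mean((α_i/180°)²)`) caps what any train can do.

`vfadesign` poses the train as the solution of a constrained optimisation:

    α* = argmin_α  w·L_PSF(α) + (1 − w)·L1(cTRG·I_TRG, I_FSE(α)) + λ_R·R(α)
         subject to  rSAR(α) = c_SAR

where `L_PSF` penalises PSF side bands of every tissue (on unit-mean MTFs),
`L1` is the mean absolute deviation of the simulated FSE image from a
scaled spin-echo target image, and `R` is the total variation of the train.
All trains with `rSAR = c_SAR` live on a hypersphere of radius
`180°·sqrt(c_SAR·ETL)`, so the constraint is kept exactly by rescaling
after each ADAM step (projected gradient descent). Gradients flow
analytically through the full physics chain: an extended-phase-graph (EPG)
echo-train simulation with forward-mode Jacobian propagation in compiled
code (optionally with inversion preparation for FLAIR), linear k-space
assembly through the view-ordering table, and the image/PSF losses.
Setting `w = 1` yields sharpness-optimised trains, `w = 0`
SNR/contrast-optimised ones, intermediate `w` the trade-off.

The package also provides the classical prospective three-part-target VFA
baseline (SAR-matched by bisection, for fair comparison at equal SAR), a
seeded synthetic 2D brain phantom (WM/GM/CSF with disjoint masks and
optional zero-signal "vessels"), and quantification tools: the PSF
residual error against the uniform-signal reference, pseudo-replica
Monte-Carlo SNR maps with pre-whitening, and ROI contrast-to-noise ratios.

## A worked example

Optimise a PSF-flavoured train for a T2-weighted 7 T protocol (ETL 200,
ESP 3.8 ms, TE_eff 380 ms, 9% relative SAR) and compare its blurring
against the SAR-matched standard VFA:

```r
library(vfadesign)

pre <- preset_t2w(w = 1)       # PSF-optimised flavour
res <- run_preset(pre)         # ~2 min on one CPU
print(res)
#> VFA optimisation: 400 iterations (iteration cap), final total=0.264857, rel.SAR=0.0900
#>   flip angles: 1.0..170.8 deg (mean 38.1)

std <- standard_vfa_train(pre$protocol, c_SAR = 0.09)
err_std <- psf_error(simulate_unencoded_signal(pre$descr, std$alpha,
                                               pre$protocol, TI = 1800),
                     pre$psf_table)
err_opt <- psf_error(simulate_unencoded_signal(pre$descr, res$alpha,
                                               pre$protocol, TI = 1800),
                     pre$psf_table)
sprintf("ERR std = %.4f  ERR psf-opt = %.4f  reduction = %.1f %%",
        err_std, err_opt, 100 * (1 - err_opt / err_std))
#> "ERR std = 1.7787  ERR psf-opt = 1.0154  reduction = 42.9 %"
```

The returned train sits on the SAR constraint to machine precision
(`relative_sar(res$alpha)` is 0.09), and its dark-fluid WM/GM-averaged PSF
keeps 43% less of its mass in side bands than the standard scheme at the
same SAR. The numbers to read: `ERR` is the fraction of point-spread mass
displaced from the central voxel (0 = no blurring, 2 = none of it in the
centre), computed from the tissue-averaged echo-train signal with CSF
attenuated by a TI = 1800 ms inversion-recovery weight.

`cmd_evaluate()` scores any train (including externally supplied plain-text
VFA lists, one angle in degrees per line):

```r
ev <- cmd_evaluate(res$alpha, list(
  protocol = list(ETL = 200, ESP = 3.8, TR = 3200, TE_eff = 380),
  phantom = list(shape = c(64, 200), seed = 1),
  optimizer = list(c_SAR = 0.09)), n_rep = 50)
print(ev)
#> VFA evaluation: ETL=200, rel.SAR=0.0900
#>   PSF residual error (dark-fluid tissue average): 1.0154
#>   PSF side-band sums: WM=0.0004185, GM=0.0005235, CSF=0.003563
#>   median pseudo-replica SNR: 1.92
```

A thin command-line front-end wrapping these functions (subcommands
`optimize`, `evaluate`, `baseline`, `phantom`, YAML configuration) ships
at `inst/cli/vfa.R`.

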