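---
title: "Designing SAR-constrained variable flip-angle trains for 3D FSE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing SAR-constrained variable flip-angle trains for 3D FSE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

3D fast-spin-echo (FSE/TSE) sequences acquire very long trains of spin
echoes -- two hundred and more -- after a single excitation. The transverse
magnetisation decays along the train, so the k-space lines sampled by late
echoes carry less signal than early ones. This per-line amplitude weighting
is the *modulation transfer function* (MTF); its Fourier transform, the
*point-spread function* (PSF), describes how a point of tissue is smeared
along the phase-encoding direction. A strongly non-uniform MTF means heavy
T2 blurring. Variable refocusing flip angles (VFA) counteract the decay by
storing magnetisation longitudinally and releasing it later, producing
pseudo-steady states -- but the classical VFA design is heuristic, tuned to
a single tissue, and blind to the sampling scheme and the spatial content
of the object. At 7 T the problem sharpens: T2 times are shorter, the RF
power ceiling (SAR) is lower, and both blurring and SAR scale unfavourably.

`vfadesign` treats the flip-angle train as the free parameter of a
constrained optimisation: minimise a weighted combination of a PSF
side-band penalty (sharpness), an L1 contrast-fidelity term against a
simulated spin-echo target image (SNR/contrast), and a smoothness
regularizer, subject to a hard relative-SAR equality constraint, with
gradients propagated analytically through the entire physics chain.

## The model, piece by piece

### EPG signal simulation

The echo-train signal of one tissue (T1, T2, M0) is simulated with the
extended phase graph (EPG) formalism: configuration states $F^+_k$,
$F^-_k$, $Z_k$ up to truncation order $K$, with the standard RF mixing
matrix, relaxation split into half-echo-spacing intervals, regrowth of
$Z_0$, and one unit of crusher dephasing per half interval. The CPMG
condition is realised as a $90^\circ$ excitation about $+y$ with refocusing
pulses about $+x$. An optional ideal inversion (for dark-fluid/FLAIR
contrast) negates $Z$ and recovers for a delay TI before the excitation;
transverse coherences are assumed spoiled during TI.

Choices the formalism leaves open, and what this package does:

* **Truncation order** `K = ETL + 1` by default -- exact for `ETL`
  refocusing intervals; configurable, and verified in the tests to leave
  echo amplitudes unchanged beyond `1e-10` when raised.
* **Relaxation split**: half-ESP halves around each pulse (the standard
  FSE-EPG convention).
* **Single-shot simulation from thermal equilibrium**: one excitation per
  TR and per partition; no inter-TR steady state is modelled.
* **Gradients**: the Jacobian $\partial S_i / \partial \alpha_j$ is
  propagated in forward mode through every EPG operator in compiled code
  (all operators are real-linear in the state, so derivative columns evolve
  under the same maps, plus one injection of $\partial T(\alpha_i) /
  \partial \alpha_i$ at pulse $i$). The unit tests pin this against central
  finite differences at relative `1e-4`, and the simulation itself against
  a 20 000-spin isochromat (Bloch-rotation) ensemble at relative `1e-3`.

### Image formation and the target

An object descriptor holds per-tissue parameters and disjoint masks on a
2D grid whose second axis is phase encoding. For each echo, the composite
amplitude image $\sum_T S_T[e]\,\mathrm{mask}_T$ is transformed to
k-space; a linear view-ordering table assigns each PE line the echo that
samples it (echo $i$ samples line $\mathrm{centre} + (i -
\mathrm{centre\ echo}) \cdot R$; unsampled lines inherit the nearest
sampled line's echo, ties to the lower index); the combined k-space is
inverse-transformed and the magnitude taken. All transforms are unitary
and centred, with the k-space centre and the PSF centre at index
$\lfloor N_y/2 \rfloor$ (0-based). Because the model is linear in the
per-echo amplitudes, the combined k-space is simply each mask's k-space
weighted per line by the tissue's MTF -- which is also how the loss
gradient is pulled back onto the signals with two FFTs per iteration.

The contrast target is a mono-exponential spin-echo image: voxel value
$M_0 (1 - e^{-TR/T_1}) e^{-TE/T_2}$ (the saturation factor can be
disabled), with TE = 45 ms and TR = 6000 ms by default -- chosen to keep
T1 influence small at 7 T -- scaled by $c_{TRG} = 0.65$. For FLAIR the CSF
compartment of the target is zeroed.

### The objective

For a train $\alpha$ with per-tissue signals $S_T(\alpha)$:

$$ \mathcal{L}(\alpha) = w\,L_{PSF}(\alpha) + (1 - w)\,L_1(\alpha)
   + \lambda_R R(\alpha), \qquad \text{s.t. } \mathrm{rSAR}(\alpha) = c_{SAR} $$

* $L_1$: mean absolute deviation of the simulated FSE image from the
  scaled target.
* $L_{PSF}$: for each tissue, the mean absolute PSF amplitude outside the
  central voxel, weighted by $c_T \in [0, 1]$. The MTF of each tissue is
  normalised to unit mean before the transform, so the penalty measures
  the *shape* of the blurring. This normalisation matters: an
  amplitude-carrying PSF penalty has a degenerate global optimum at zero
  signal (the PSF scales linearly with the signal), and an optimizer will
  find it -- the pure-sharpness problem is only well posed on the
  normalised MTF.
* $R$: the L1 total variation $\sum_i |\alpha_{i+1} - \alpha_i|$ in
  degrees, preventing discontinuous trains. Its natural scale (hundreds of
  degrees) is far from the image losses' (fractions of unity), so it
  carries a weight $\lambda_R$; the presets use $\lambda_R =
  1/(1800\,\mathrm{ETL})$, which keeps the regularizer near 5-10% of the
  converged objective -- small enough not to flatten genuine structure
  such as the centre-echo peak of SNR-optimised trains, large enough to
  suppress echo-to-echo ripple.
* $\mathrm{rSAR}(\alpha) = \frac{1}{ETL} \sum_i (\alpha_i/180^\circ)^2$:
  all feasible trains lie on a hypersphere of radius $180^\circ
  \sqrt{c_{SAR}\,ETL}$, so the constraint is enforced by rescaling --
  projected gradient descent.

### The optimizer

ADAM ($\beta_1 = 0.9$, $\beta_2 = 0.999$) on the analytic gradient,
followed each step by a clamp to $[0^\circ, 180^\circ]$ and the projection
onto the SAR sphere; every iterate is feasible to $10^{-9}$. The
initialisation is the constant feasible train $\alpha_i = 180^\circ
\sqrt{c_{SAR}}$ (54° at 9% SAR). Iteration stops when the change in total
loss stays below `c_STOP` for `patience` consecutive iterations (the
patience window exists because ADAM's momentum warm-up produces near-zero
first steps that a single-iteration check mistakes for convergence), or at
`max_iterations`.

Two budget choices are deliberate package defaults rather than universal
constants. The generic `optimizer_config()` default step size is 0.001 (in
radians of flip angle, the scale on which the loss is differentiated); on
the reduced problems the presets ship with, the loss surface is shallow
enough that this step never leaves the initialisation within a realistic
budget, so `preset_t2w()`/`preset_flair()` use a step of 0.02 rad and 400
iterations -- the total loss plateaus by iteration ~300 on both presets,
which is how these numbers were fixed.

### The heuristic baseline

The comparison standard is the classical prospective VFA design: a
three-part target signal (exponential approach from the natural first-echo
amplitude to a pseudo-steady-state plateau, constant plateau until the
k-space-centre echo, then a linear flip-angle ramp to `max_fa` = 120°),
tracked echo by echo with a 1D root search on the forward EPG step; when
the target is unreachable the amplitude-maximising angle is used. The
approach constant is 2 echoes: the entry must drop to the plateau quickly,
because every echo spent demanding near-maximal signal burns transverse
magnetisation that the plateau needs back. Because all comparisons are
made *at equal relative SAR*, the plateau level is not chosen by hand: it
is bisected until the finished train's relative SAR equals the prescribed
level (9% for the T2-weighted protocol).

### Quantification

* **PSF residual error**: the signal (simulated here as the dark-fluid,
  TI = 1800 ms, voxel-fraction- and IR-weighted WM/GM tissue average, so
  fluid contributes little) is normalised to unit mean, mapped to the MTF,
  transformed; the error is the L1 distance to the reference PSF of an
  all-ones signal, with both PSFs compared as unit-L1 profiles. This
  bounded form (error $\le 2$) measures the fraction of point-spread mass
  sitting in side bands; it is the scale on which the reference
  measurements this package is calibrated against are expressed, and it is
  invariant to the arbitrary amplitude of a measured signal. The
  amplitude-carrying comparison remains available via `normalize = "none"`.
* **Pseudo-replica SNR**: k-space (optionally pre-whitened by the channel
  noise covariance) is perturbed `n_rep` times with unit complex Gaussian
  noise (SD 1 per real/imaginary component), each replica reconstructed by
  unitary inverse FFT (root-sum-of-squares over channels), and SNR =
  mean/SD per voxel. With unitary transforms, a constant image of value
  $c$ gives median SNR $\approx c$, which the tests verify to $3/\sqrt{n_{rep}}$.
* **CNR**: $(\bar S_A - \bar S_B)/\sigma_A$ with $\sigma_A$ from the
  pseudo-replica SD map.

## The synthetic phantom, and what it does not emulate

`make_synthetic_brain()` builds a seeded, deterministic 2D head phantom:
nested jittered ellipses giving an outer CSF rim, a grey-matter ribbon, a
white-matter core, two CSF ventricles, and a few one-voxel zero-signal
"vessels". Default 7 T parameters: WM 1500/50 ms (the values the VFA
design itself is calibrated for), GM 2000/55 ms, CSF 4500/2000 ms, M0
0.75/0.85/1.0 -- all overridable, since only the WM pair is canonical.

The preset optimisations run the phantom at 64 voxels readout by the
protocol's full PE matrix (200 or 220 lines, one per echo). The PE axis is
kept full-size deliberately: with a shortened PE axis only the sampled
window of echoes reaches the image loss, and the SNR-optimised train
degenerates (three quarters of the train become invisible to the
objective). The readout axis carries no sequence physics and is safe to
shrink.

What passing tests on this phantom do *not* show: behaviour under B1+
transmit inhomogeneity (no B1 maps are modelled), magnetisation-transfer
effects, multi-coil sensitivity encoding or parallel-imaging
reconstruction beyond regular undersampling with nearest-echo fill,
partition-direction (second PE axis) blurring, or the amplitude statistics
of measured in-vivo echo trains -- the simulated standard baseline shows a
sharper initial transient relative to its plateau than coil-averaged
in-vivo signals do, which inflates its absolute PSF-error figure relative
to measured values.

## Numerical choices and degenerate inputs

* Centred unitary FFTs throughout; k-space centre and PSF centre at
  $\lfloor N_y/2 \rfloor$ (0-based). The centre line of the view ordering
  carries the centre echo exactly, so TE$_{eff}$ = centre echo × ESP.
* Magnitude (not real-part) PSFs and images everywhere; the magnitude's
  non-differentiability at zero is handled by a zero subgradient.
* L1-type losses use sign subgradients, as their reference
  implementations do.
* The all-zero train cannot be projected onto the SAR sphere
  (degenerate-input error); all-zero signals are rejected by the PSF-error
  metric.
* Nearest-echo fill ties resolve to the lower line index; echoes that fall
  outside the PE range are dropped and their lines filled from the nearest
  sampled neighbour.
* The stopping criterion compares absolute loss change by default
  (`stop_mode = "relative"` available), with a 10-iteration patience.

## Known limitations

* The FLAIR protocol's 220 echoes cannot all map into a 220-line single
  PE axis when the centre echo is 75: echoes beyond 184 encode partitions
  in the real 3D sequence and are unused by the 2D image model here.
* The smoothness weight and the optimizer budget are calibrated for the
  shipped presets; substantially different grids, ETLs or tissue sets may
  need re-tuning of `lambda_R` and `max_iterations` (inspect the loss
  history).
* The degeneracy analysis above applies to `w = 1` exactly; for `w`
  slightly below 1 the contrast term re-anchors the amplitude, and results
  interpolate between the two regimes.

## A worked run

```{r, eval = FALSE}
library(vfadesign)
pre <- preset_t2w(w = 1)           # PSF-optimised, 9% SAR, ETL 200
res <- run_preset(pre)
print(res)
relative_sar(res$alpha)            # 0.09 to machine precision

std <- standard_vfa_train(pre$protocol, c_SAR = 0.09)
ph <- pre$descr
tab <- pre$psf_table
err_std <- psf_error(simulate_unencoded_signal(ph, std$alpha, pre$protocol,
                                               TI = 1800), tab)
err_opt <- psf_error(simulate_unencoded_signal(ph, res$alpha, pre$protocol,
                                               TI = 1800), tab)
100 * (1 - err_opt / err_std)      # percent blurring reduction
```
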