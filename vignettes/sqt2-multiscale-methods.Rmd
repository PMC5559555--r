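---
title: "Multi-scale modelling of the SQT2 KCNQ1 V307L mutation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale modelling of the SQT2 KCNQ1 V307L mutation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sqtsim)
```

`sqtsim` reconstructs, at desk scale, a multi-scale in-silico study of the
short-QT-syndrome-2 (SQT2) KCNQ1 V307L gain-of-function mutation: a Markov
chain model of the slow delayed-rectifier potassium current (IKs), embedded
in a human ventricular myocyte model and in 1D/2D monodomain tissue. This
vignette explains the science and every consequential design decision; the
README shows the user-facing workflow.

## The IKs Markov chain

IKs is carried by tetrameric KCNQ1+KCNE1 channels. The channel model has 15
closed states and two open states. Each of the four voltage sensors makes
two sequential transitions, resting → intermediate (rates $\alpha$, $\beta$)
and intermediate → activated ($\gamma$, $\delta$); with all four sensors
activated the channel opens (C15 → O1 at $\theta$, back at $\eta$) and the
open channel interconverts between two open states (O1 ↔ O2 at $\psi$,
$\omega$). Aggregating subunit configurations yields the 15 closed
macrostates. Every transition class follows a single-exponential voltage
dependence,

$$ r(V) = a\, e^{bV}, $$

with prefactor $a$ (1/ms) and sensitivity $b$ (1/mV); this is the standard
parameterisation for this scheme, and all mutant effects are expressed
through the fitted coefficients. The current law is ohmic,

$$ I_{Ks} = g_{Ks}\,(1-\text{block})\, \textstyle\sum_p w_p\, s_p\,
   (O1_p + O2_p)\,(V - E_{Ks}), $$

with population weights $w_p$ (a single population for homozygotes; an
exact 50:50 mixture of independent WT and mutant populations for the
heterozygote, each population evolving under its own rates but the shared
membrane potential) and relative-amplitude scales $s_p$ (below).
Pharmacological block is pure conductance scaling.

Numerics: `advanceChannel()` integrates $\dot p = Q(V)p$ with classical RK4
and adaptive sub-stepping, and is validated against the exact matrix
exponential; fixed-voltage clamp segments are propagated exactly with the
matrix exponential per segment. Inside cell and tissue steps a midpoint-rule
variant with the same sub-step control is used; transition rates are capped
at 50/ms — transitions faster than that equilibrate within microseconds of
the 0.02-ms step and the cap only binds at potentials where the affected
state's occupancy is negligible (it is part of the rate law, applied
identically in every code path). Antisymmetric flow accounting preserves
the probability sum to roundoff; occupancies are clamped non-negative and
renormalised.

## Fitting the genotype presets

The experimental activation and kinetics data behind the WT and V307L
channels are not published as tables, so the package ships a fixture
generator (`generateFixtures()`) emulating the reported constraints:

* Boltzmann-shaped normalised activation I-V targets, WT
  $V_{1/2} = +20$ mV, slope $k = 12$ mV (typical of KCNQ1+KCNE1 at
  physiological temperature), measured as end-of-3-s-step currents of the
  standard protocol (hold −80 mV, 50 ms pre-step to −40 mV, 3-s test steps
  −70..+60 mV in 10-mV increments, 5-s tails at −40 mV);
* the mutant target identical in shape but shifted exactly −36 mV;
* WT kinetic anchors: tail-deactivation time constant 185 ms at the −40 mV
  tail and time-to-half-activation 1200 ms at +20 mV, together with
  voltage-sensor reset rates at −80 mV — all taken from the classic cardiac
  IKs Markov parameterisation at 37 °C, which pins quantities the
  activation curve and tail leave unidentified (notably the diastolic reset
  that controls beat-to-beat IKs accumulation);
* mutant kinetic factors: tail deactivation 2× slower than WT (a
  conservative twofold slow-down consistent with the qualitative report of
  slowed deactivation), activation 7× faster (time-to-half at +20 mV, the
  value a pure −36 mV translation of the WT gating scheme implies — the
  parsimonious single-mechanism reading of left-shifted, accelerated
  activation). The mutant fit is
  additionally penalised if its closed-state return at −80 mV is faster
  than WT's (slowed deactivation must extend to the deep closed states, or
  the mutant would paradoxically reset faster between beats).

`fitParams()` minimises the weighted sum of squared I-V residuals plus the
squared kinetic penalties with the Nelder-Mead simplex (`stats::optim`,
relative tolerance 1e-10, iteration cap and deterministic restarts from the
incumbent), prefactors on a log scale, plus a monotonicity penalty on the
steady-state activation curve and a penalty on resting open probability at
−80 mV above 1%. Fitting is fully deterministic. The shipped presets
(`iksParams("WT")`, `iksParams("V307L")`, mirrored in
`inst/extdata/iks_params_*.txt`) are the result of this workflow: the WT
fit starts from the classic parameterisation, the mutant fit from voltage
translations of the fitted WT (`translateParams()`).

Relative amplitude: normalised I-V fits constrain only the shape per
genotype. The mutant's amplitude scale $s$ is set by `saturationScale()` so
that its saturating (end-of-step, +60 mV) open probability carries the same
current as WT's — equal channel expression and unitary conductance, with
all gain-of-function arising from gating. The AP-clamp peak-ratio operation
(`apClampScaleFactor()`) is available for scaling against an experimentally
observed peak ratio instead; with no observed ratio the saturation anchor is
the package default.

Fitted presets measured through the public clamp route: activation shift
−35.8 mV, tail-deactivation ratio 1.94, activation speed-up 7.0.

## Host myocyte and conductance calibration

The host is the 2006 human ventricular AP model of ten Tusscher and
Panfilov (epicardial, mid-myocardial, endocardial variants), transcribed
equation-for-equation, with the native Hodgkin-Huxley IKs gate replaced by
the Markov model's open probability; the host's IKs reversal-potential
formula is kept, as is the host's transmural IKs expression gradient
(mid-myocardial cells carry 25% of the epicardial conductance — removing
this with the gate replacement would collapse the mid-myocardial phenotype
entirely). Integration uses Rush-Larsen updates for the host gates
(steady-state/decay-factor lookup tables at 0.05-mV resolution), forward
updates for concentrations, explicit membrane-potential updates, Δt = 0.02
ms (0.03 ms for the 2D sheet), and reversal potentials refreshed every 0.5
ms. Stimuli are −52 pA/pF for 1 ms (2 ms in tissue).

$g_{Ks}$ is calibrated once, by bisection, so that the WT epicardial cell
paced at 1 Hz (50 beats) gives APD90 = 325.6 ms; the calibrated value is
0.0824 nS/pF. Every other cellular and tissue output — mutant APDs, QT
intervals, refractory periods, titration fractions — is a genuine
prediction of the fitted kinetics.

Protocols: APD90 is measured from maximal upstroke velocity to 90%
repolarisation of that beat's amplitude, with linear interpolation of the
crossing. ERP uses an S1 steady-pacing train followed by a single S2,
bisected at 1-ms resolution; capture requires overshoot above 0 mV and at
least 80% of the S1 amplitude (the source study prints no criterion; this
is the conventional, testable choice). APD restitution uses a 10-beat S1
train at 1000 ms and one S2 per diastolic interval; ERP restitution paces
dynamically at each cycle length. Block titration brackets and bisects the
smallest block fraction whose steady-state APD90 (30 conditioning beats per
evaluation) matches the reference within 1 ms.

## 1D strand and pseudo-ECG

The transmural strand is a 15-mm monodomain cable at 0.2-mm resolution with
no-flux ends, stimulated at the ENDO end; nodes start from single-cell 1-Hz
steady states and are conditioned in tissue for two beats before the
recorded one. The diffusion coefficient (0.1457 mm²/ms) is calibrated once
for a planar conduction velocity of 70 cm/s. Composition, ordered from the
stimulated end, is 25% ENDO, 35% MIDDLE, 40% EPI: the source study states
its proportions were chosen to produce a positive T wave, and with this
implementation's coupled repolarisation profile the EPI-weighted
arrangement is what achieves that (the ENDO-weighted arrangement yields a
negative T wave); the choice was made on T-wave polarity only.

The pseudo-ECG is the standard unipolar far-field integral of the membrane
potential gradient against the gradient of $1/r$, evaluated 2 cm beyond the
EPI end on the strand axis. QT runs from the onset of the depolarisation
deflection (2% of the R amplitude) to the T end, defined as the return of
the potential to within 2% of the T amplitude above baseline; the T peak is
the largest absolute deflection after depolarisation completes. The T-end
rule is declared rather than inherited (the source prints none); the 2%
threshold catches the late tail of repolarisation, so QT values here run
systematically long compared to tangent-style rules by roughly 10 ms.

The vulnerable window launches a conditioning wave from the ENDO end and
applies a 3-node premature stimulus 5 mm from the EPI end at 1-ms-scanned
delivery times, classifying each outcome by whether new wavefronts pass
sentinel nodes on each side of the site (bidirectional block /
unidirectional conduction / bidirectional conduction); the window is the
span of unidirectional outcomes. Strand block titration bisects on the
pseudo-ECG QT with a 2-ms matching tolerance.

## 2D sheet

The sheet is an idealised isotropic monodomain rectangle (default
60×60 mm; the packaged experiments use 40×20 mm at 0.2 mm, Δt = 0.03 ms),
uniform epicardial tissue or transmurally layered bands. S1 is a planar
wave from one edge; S2 covers the half of the sheet behind the S1 wavetail
and fires adaptively when the centroid of the region has repolarised below
−80 mV while tissue farther along the propagation direction is still
refractory — the premature front is then blocked on its refractory flank
and its free end can curl and re-enter. Re-entry lifespan is the time from
S2 to the last recorded upstroke anywhere; the dominant frequency is the
peak of a Hann-windowed, zero-padded periodogram of the whole-field mean
potential (band 0.5–20 Hz, grid ≤ 0.2 Hz), optionally after subtracting a
running mean to suppress the slow envelope of transient episodes. Once all
activity is extinguished after S2 the integration stops and the mean signal
is padded with its resting value (a quiescent monodomain sheet stays
quiescent).

At these domain sizes the excitation wavelength (APD × CV, roughly 23 cm
for WT and 14 cm for the homozygous mutant) far exceeds the domain, so
re-entry is transient in every genotype and only the direction of effect —
longer lifespan and higher dominant frequency under the mutation — is
meaningful. The source study's sustained re-entry lives in
anatomically realistic 2D/3D geometries outside this package's scope.

## What the fixtures do and do not establish

The synthetic fixtures encode exactly the constraints the source reports:
the −36 mV activation shift, slower deactivation, faster activation, and
Boltzmann-shaped activation curves. They do not reproduce the unpublished
experimental I-V tables, the digitised AP-clamp command, or the authors'
fitted coefficients. Consequently the package's WT-anchored predictions
track the published cellular/tissue values closely for the homozygote
(EPI/ENDO APDs within ~2%) but shorten the heterozygote and mid-myocardial
mutants less than published (10–20%), need correspondingly smaller
normalising block fractions, and widen the vulnerable window less. These
deviations move together — they all reflect a mutant whose plateau current
gain, relative to WT, is somewhat smaller than the original model's — and
are sensitive chiefly to the unpublished deactivation slow-down factor and
relative-amplitude scaling. Passing tests therefore establish the method
chain and the direction and approximate magnitude of every effect, not
digit-level agreement with the original coefficients.

## Known limitations

* Combinatorial WT/mutant subunit stoichiometries are not modelled; the
  heterozygote is the stated 50:50 population mixture.
* No temperature scaling, no stochastic single-channel behaviour, no
  state-dependent drug kinetics (block is conductance scaling).
* The 2D sheet is idealised; anatomical geometries, anisotropy and 3D
  scroll-wave dynamics are out of scope.
* Deterministic throughout: identical configurations give bit-identical
  results; there is no sampling noise to average over.
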