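---
title: "Quantifying ocular dominance plasticity from periodic-stimulus intrinsic-signal imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ocular dominance plasticity from periodic-stimulus intrinsic-signal imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odimaps)
```

## The measurement model

Intrinsic-signal optical imaging records tiny stimulus-driven changes in
cortical light reflectance — on the order of $10^{-4}$ fractional change
— through the skull. In the periodic-stimulus (Fourier) variant, a
drifting bar sweeps the visual field cyclically at a fixed temporal
frequency $f$ (0.125 Hz in the standard protocol), so each cortical
pixel responding to a given visual-field position modulates its
reflectance sinusoidally at $f$ with a phase determined by when the bar
crosses that position. The forward model for a pixel $x$ is

$$ r_x(t) = A(x)\,\cos\!\bigl(2\pi f t + \theta(x)\bigr) + \varepsilon_x(t), $$

where $A(x)$ is the response amplitude ("V1-activation") and
$\theta(x) = 2\pi\,\phi(x)/E$ maps the visual-field position $\phi(x)$
(degrees) onto temporal phase over one stimulus cycle of extent $E$
degrees (70° for the full-field bar stimulus).

`extractComponent()` estimates the complex response per pixel as

$$ \hat c(x) = \frac{2}{T}\sum_{k=0}^{T-1} r_x(t_k)\, e^{-2\pi i f t_k}, $$

after truncating to a whole number of stimulus cycles and subtracting
each pixel's temporal mean. The $2/T$ calibration makes
$|\hat c| = A$ for a pure sinusoid, so recovered magnitudes are directly
comparable to injected amplitudes and are reported in the conventional
$\times 10^{-4}$ display units. Our sign convention is
$\arg\hat c = +\theta$ for $\cos(2\pi f t + \theta)$; the simulator and
`toRetinotopy()` share it, so position $= E\,(\arg\hat c \bmod 2\pi)/2\pi$
inverts the forward model exactly.

Numerical choices worth stating:

* Incomplete trailing cycles are dropped, never zero-padded, keeping $f$
  exactly on a DFT bin (no leakage).
* DC removal cannot change the stimulus bin for whole cycles; it is
  applied anyway as protection against truncation effects in real data,
  implemented directly on the two quadrature projections.
* Temporal binning (`binFrames()`, 30 Hz to 7.5 Hz by averaging fours)
  attenuates the stimulus component by the aperture factor
  $\frac{\sin(2\pi f m/2f_s)}{m \sin(2\pi f/2f_s)} \approx 1 - 4\times10^{-4}$
  and delays the phase by half a bin ($\approx 0.44°$ of visual field at
  the defaults). Both effects are properties of binning itself, are
  identical for the two eyes (hence cancel exactly in the ODI ratio),
  and shift retinotopy by a constant (hence leave map scatter
  untouched). Consistency checks at $10^{-6}$ tolerance therefore
  extract at the native frame rate.

## Ocular dominance scoring

The ocular dominance index of a pixel with contralateral- and
ipsilateral-eye response magnitudes $C$ and $I$ is

$$ \mathrm{ODI} = \frac{C - I}{C + I} \in [-1, +1], $$

positive for contralateral dominance. `blockOdi()` applies the standard
scoring chain to a block of (by default) four consecutive runs per eye:

1. average each eye's magnitude maps over the block's runs;
2. smooth both averaged maps with a 5×5 uniform kernel (shot-noise
   reduction). The protocol text mentions smoothing the ipsilateral
   map; we smooth both, because a per-pixel ratio of one filtered and
   one unfiltered operand is not meaningful. Borders use reflect
   padding so edge magnitudes are not dragged toward zero.
3. threshold the smoothed ipsilateral map at 30% of its peak to define
   the responsive region (the literal rule; `maskFrom = "both"` or
   `"contra"` are available for sensitivity analyses);
4. include the block only if each eye's mean magnitude over its own
   responsive mask reaches $10^{-4}$. The summary used for this rule is
   not defined more precisely in the protocol; we use the mean over the
   responsive mask, which matches how activation values are reported;
5. average pixel ODIs over the mask; `animalSummary()` then averages
   the included blocks (typically 3–5 per animal), unweighted.

Scale invariance ($\alpha C, \alpha I$), antisymmetry (swapping eyes),
and the $[-1,1]$ bounds are exact algebraic properties and are enforced
by tests. Because the smoothing kernel is applied identically to both
eyes, a scene whose ipsilateral map is a scalar multiple of the
contralateral map has an exactly uniform pixel ODI, which the noiseless
pipeline recovers to $10^{-6}$; this is the basis of the
parameter-recovery tests.

Run blocks are assembled from consecutive runs in acquisition order; a
trailing partial block is dropped (no remainder rule is stated in the
protocol, and a partial block would mix inclusion statistics).

## Retinotopic map quality (scatter)

For each pixel of the most responsive area whose full 5×5 neighbourhood
lies inside that area, we compute the difference between its
visual-field position and the mean position of its 24 surrounding
pixels; the scatter index is the standard deviation of these
differences, in degrees. A linear retinotopic gradient has zero scatter
(a symmetric neighbourhood mean equals the centre), so the index
measures local map roughness, not slope. For i.i.d. positional jitter
of standard deviation $\sigma$ the index converges to
$\sigma\sqrt{25/24}$, which the tests verify to 5%.

The responsive area is selected by applying the 30%-of-peak threshold
and keeping the top $n$ pixels by magnitude — 20,000 at the full
512×512 acquisition; `scaledAreaPixels()` preserves that areal fraction
(≈7.6%) at other image sizes. Positions within one cycle are treated as
linear: the analysed area spans far less than a cycle, and pixels whose
neighbourhood straddles the wrap are skipped and counted.

## Optomotor behavior

Optomotor spatial-frequency thresholds (cyc/deg, at full contrast) and
contrast thresholds (percent, at six fixed spatial frequencies: 0.031,
0.064, 0.092, 0.103, 0.192, 0.272 cyc/deg) are analysed from daily
tests over days 0–7. A percent threshold is interpreted as the
Michelson contrast of the grating at threshold, and contrast
sensitivity is its reciprocal ($100\% \to 1$, $50\% \to 2$). The exact
percent-to-Michelson calibration of a specific optomotor apparatus is
exposed as a pluggable `convert` function because published tables show
floor/ceiling values (≈3.5 at the extreme frequencies) that imply
apparatus limits no formula in our hands could reproduce; the default
identity interpretation is only validated for internal consistency.

Spatial-frequency improvement is computed per animal as
$100\,(d_7 - d_0)/d_0$ and then averaged, because a group SEM requires
per-animal values; the mean per-animal percentage is generally not the
ratio of group means (0.37 → 0.46 gives 24.3% per animal).

## Statistics battery

The analysis battery mirrors the study design: Shapiro–Wilk normality
and pairwise variance-ratio F-tests are reported as advisory checks
(no branching on their outcome — the published analyses use t/ANOVA
regardless, and we preserve that behaviour rather than switching to
nonparametric tests); two-tailed pooled-variance t-tests for two
groups; one-way ANOVA followed by all pairwise comparisons with
Bonferroni correction (raw $p$ × number of comparisons, capped at 1);
and for time courses a two-way repeated-measures ANOVA (between factor
group, within factor day, subject as blocking factor) with
Bonferroni-corrected cellwise comparisons. Sphericity is not corrected,
and that is flagged in every result's notes. Stars follow the
conventional levels (* $p<0.05$, ** $p<0.01$, *** $p<0.001$). Under
null simulations the t-test holds its nominal 5% rate and the
Bonferroni family stays at or below it (Bonferroni is conservative by
construction).

## The synthetic-data generator

The generator exists so that every stage is testable against known
ground truth; it emulates exactly the structure the analysis assumes:

* a responsive zone (model binocular V1) with uniform eye-specific
  amplitudes chosen by inverting the ODI formula, so the designed mean
  ODI is exact (`makeOdScene()`);
* a linear retinotopic gradient across the zone (`makeLinearRetinotopy()`);
* stimulus-locked sinusoidal reflectance at 0.125 Hz riding on
  i.i.d. Gaussian pixel noise plus an optional slow global drift
  sinusoid at a non-stimulus frequency (`renderMovie()`);
* behavioral cohorts whose deprived groups ramp linearly from day-0 to
  day-7 values and whose controls stay flat, with additive Gaussian
  measurement noise (`simulateBehaviorCohort()`; presets follow the
  published group means, e.g. 0.37 → 0.46 cyc/deg for deprived
  controls and the corresponding contrast-sensitivity tables).

What it deliberately does *not* model: vascular artifacts, eye
movements, spatially correlated (hemodynamic) noise, photon/camera
physics, or a psychophysical staircase for the optomotor task. Passing
recovery tests therefore demonstrates correctness of the analysis
chain, not robustness to every artifact of real recordings. In
particular, no hemodynamic phase lag is simulated or corrected: the
protocol this package follows does not state how (or whether) the lag
was removed, so absolute retinotopic positions are untestable against
published values and only relative properties (gradients, scatter) are
asserted.

## Default parameters and problem sizes

| parameter | default | meaning |
|---|---|---|
| acquisition rate | 30 Hz | camera frame rate |
| binned rate | 7.5 Hz | after averaging fours |
| stimulus frequency | 0.125 Hz | drifting-bar cycle rate |
| cycle extent | 70° | visual field per stimulus cycle |
| binocular span | −5° … +15° azimuth | stimulus window for OD runs |
| smoothing kernel | 5×5 uniform | shot-noise reduction |
| responsive threshold | 30% of peak | background elimination |
| block inclusion | ≥ 1×10⁻⁴ | mean responsive magnitude per eye |
| block size | 4 runs | ODI scoring unit |
| scatter area | 20,000 px at 512×512 | most responsive area |

Simulated recovery studies run at 64×64 pixels with 4 stimulus cycles
per run and movies rendered directly at the binned 7.5 Hz rate —
binning is verified separately, and rendering at 30 Hz would only
rescale every magnitude by the same aperture factor. Per-pixel-frame
noise in recovery runs is 20% of the contralateral amplitude
($4\times10^{-5}$), which leaves single-run magnitude errors near 2%
(the $\sigma\sqrt{2/T}$ law) — comfortably inside the $10^{-4}$
inclusion rule, as in the published recordings. The full 512×512
geometry is supported by the same code paths.

## A worked example

```{r example, eval = FALSE}
scene <- makeOdScene(0.25, contraPeak = 2e-4, shape = c(64, 64))
acq <- acquisitionConfig(acquisitionRate = 7.5, binnedRate = 7.5,
                         nCycles = 4L, imageSize = c(64L, 64L))
animal <- simulateOdAnimal(scene, acq, noiseSd = 4e-5, seed = 11)
animal
#> Animal 'animal' (group): 1 included block(s), ODI 0.2476
```

The designed ODI of 0.25 is recovered to well within the ±0.02 band the
recovery tests enforce across 20-animal cohorts.

## Known limitations

* The scoring chain follows the stated protocol where it is explicit
  and documents its choices where the protocol is silent (mask source,
  inclusion summary, border handling, block remainders); alternative
  conventions would shift absolute ODIs slightly but not the group
  contrasts the statistics operate on.
* Retinotopic positions are reported within a single stimulus cycle;
  no bidirectional-stimulus delay cancellation is implemented.
* TIFF map/stack files store samples rescaled to [0, 1] with the
  affine restore parameters in a YAML sidecar; round-trips are exact to
  the 32-bit sample quantisation of the value range.
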