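---
title: "Models and methods behind spotlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spotlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spotlink)
```

spotlink analyzes single-molecule fluorescence movies in four stages —
photon correction, candidate detection, sub-pixel refinement, and track
linking — followed by evaluation, super-resolution rendering and diffusion
analysis. This vignette explains the models each stage assumes, the
parameters that matter, what the built-in simulator does and does not
emulate, and the numerical choices that were genuinely open.

## Image formation model

A fluorophore at sub-pixel position $(\mu_x, \mu_y)$ produces an expected
photon count per pixel of

$$\mu_k = N\,\Delta E_x(k)\,\Delta E_y(k) + b,$$

where $\Delta E$ is the integral of a normalized 1D Gaussian of width
$\sigma$ over the pixel's extent (a difference of error functions at the
pixel edges $\pm\tfrac12$ px around the pixel center), $N$ is the total
signal in photons and $b$ the background in photons per pixel. The
*pixel-integrated* Gaussian matters at $\sigma \approx 1$ px: a sampled
Gaussian misattributes up to several percent of the flux per pixel. For
astigmatic imaging the pixel-center coordinates are rotated by $\theta$
into the PSF frame and each axis integrated with its own width
($\sigma_x$, $\sigma_y$); this separable treatment of rotated pixels is an
approximation, exact at $\theta \in \{0, \pi/2\}$. Camera counts relate to
photons through gain and offset (`convert_to_photons()`); the Poisson
likelihood below is only valid after that conversion. Negative corrected
pixels are clipped to zero (a Poisson mean cannot be negative) and the
clip count is reported.

The PSF width defaults to the Gaussian–Airy approximation
$\sigma = 0.21\,\lambda/\mathrm{NA}$ (`psf_sigma_from_optics()`): 1.005 px
for 670 nm emission at NA 1.4 and 100 nm pixels. It is a parameter
everywhere — a measured bead calibration should override it when
available.

## Candidate detection

Three score filters are provided. The band-pass filter subtracts a
large-scale Gaussian smoothing (background) from a small-scale one
(spots); both kernels are normalized so constant offsets score exactly
zero. Normalized cross-correlation scores each window against the
integrated-Gaussian template; scores live in $[-1, 1]$, are invariant
under additive offsets, and zero-variance patches are defined to score 0
rather than 0/0. The à-trous wavelet filter applies the undecimated
B3-spline kernel $(1,4,6,4,1)/16$ with $2^{j-1}-1$ holes at level $j$;
detail planes plus the final smooth plane reconstruct the input exactly,
and the second detail plane — whose scale matches diffraction-limited
spots — is the score. Its threshold is $k_\sigma$ times a robust noise
estimate, $\mathrm{median}(|d_1|)/0.6745$, from the finest plane. The
choice of plane 2 and the default $k_\sigma = 2$ are conventions, both
exposed as parameters.

All convolutions use mirror boundary padding, which avoids spurious edge
maxima. Candidates are 3×3 local maxima strictly above threshold;
non-maximum suppression keeps no two candidates within `min_distance` px,
ties broken towards smaller $(y, x)$ for determinism; candidates within
half a fit window of the border are dropped so refinement is total.
Coordinates are 0-based pixel indices with $x$ = column, $y$ = row;
multiplying by the pixel size gives nm.

## Refinement

`fit_mle()` minimizes the Poisson negative log-likelihood
$\sum_k (\mu_k - y_k \log \mu_k)$ over a square window by Levenberg-damped
Fisher scoring. $N$, $b$ and the widths are fitted in log space, which
enforces positivity without constrained-solver machinery. A step is
accepted only if the cost decreases, so the cost is non-increasing by
construction; iteration stops when the largest (log-scale) parameter
change drops below `tol` ($10^{-6}$ by default, `max_iter` 100) or when an
accepted step no longer improves the cost measurably.

Two guardrails address the known failure modes of dim-spot fitting: the
position is constrained to the fit window, and the width to
`sigma_bounds` (default $[0.5, 3] \times$ the initial width) — an in-focus
PSF narrower than half a pixel is a noise artifact, the classic collapse
mode. A solution pinned at any of these bounds is not an interior maximum
likelihood estimate; it is flagged `at_bound` and the built-in refinement
plugin discards such rows along with non-converged ones.

Initialization: position from the candidate pixel, background from the
window-border median, $N$ from the background-subtracted window sum,
width from the optics. The default window is 11 px; for $\sigma \approx
1$ px the conventional $2\lceil 3\sigma\rceil + 1 = 7$ px is tighter
against neighboring spots.

Localization precision is the Cramér–Rao lower bound of the same model at
the fitted parameters (square root of the inverse Fisher information,
position block), numerically evaluated and reported in nm. A closed-form
(Thompson/Mortensen-style) expression is deliberately not used: the
numerical CRLB stays consistent with whatever model variant was fitted
and is directly testable by Monte-Carlo refitting. One caveat the test
suite quantifies: at very low photon budgets (50 signal photons on 10
background, peak SNR ≈ 1.8) the maximum-likelihood estimator itself no
longer attains the bound — a few percent of realizations have their
global likelihood optimum on a noise blob 1–3 px away, inflating the
empirical scatter roughly 20% above the CRLB even for an exhaustive
global search. From about 200 signal photons the bound is attained within
a few percent. The signal-to-background ratio attached to each fit is the
expected signal density in the pixel containing the fitted position
divided by the fitted background, which makes the customary 0.8 cutoff
scale-free.

`radial_symmetry_center()` is the non-iterative alternative: image
gradients on the half-pixel dual grid define lines through the spot
center; the weighted least-squares intersection is closed-form, exact for
noiseless radially symmetric spots, and needs no photon calibration. Its
photometry columns ($N$, $b$, $\sigma$) are moment estimates, good enough
for filtering but not for quantitative use.

## Tracking

Per frame, open track ends and new localizations are paired by a
minimum-total-distance one-to-one assignment restricted to pairs within
the linking radius, solved as a maximum-weight bipartite matching in
which an offset makes cardinality dominate cost. Optimal assignment
rather than greedy matching was chosen because greedy results depend on
point order and are ambiguous under ties; the optimal pairing is
order-independent and is verified in the tests against an exhaustive
brute-force oracle. Blinking emitters are handled by gap closing: a track
may claim a localization up to `max_gap` frames later within radius
`max_dist`·√gap — the diffusive scaling, conservative for both stationary
dSTORM emitters and Brownian particles. Tracks shorter than `min_length`
are discarded. Track ids are assigned in order of track start (frame,
then $y$, $x$).

## The simulator

The simulator is first-class, tested code; it defines the conditions the
acceptance checks run under.

*Geometry.* Emitters are placed uniformly inside the "on" sectors of an
n-arm Siemens star (alternating angular sectors of width $\pi/n$)
inscribed in the grid, by rejection sampling; positions are continuous.
The stated density $\rho = 7.5$ px$^{-1}$ has ambiguous dimensions for an
areal process; spotlink reads it against the linear grid extent, drawing
the emitter count Poisson with mean $\rho \cdot \mathrm{grid}$ (1920
expected at 256 px). Under the kinetics below this yields ~45
simultaneously active emitters on a 256 px frame initially — a plausible
dSTORM activation density — decaying as emitters bleach. Both $\rho$ and
the absolute count are parameters.

*Kinetics.* Each emitter alternates exponentially distributed dark
(rate $k_\mathrm{on}$) and active (rate $k_\mathrm{deactivate} =
k_\mathrm{off} + k_\mathrm{bleach}$) periods in continuous time; after
each active period it bleaches with probability $p_\mathrm{bleach} =
k_\mathrm{bleach}/k_\mathrm{deactivate}$, making the number of
activations geometric. Defaults: $k_\mathrm{off} = 1$,
$k_\mathrm{bleach} = 0.15$ frame$^{-1}$, $k_\mathrm{on} =
k_\mathrm{off}/(5\rho)$. "Active state durations drawn from a Poissonian
distribution" is interpreted as exponential dwell times — the two-state
telegraph model consistent with the rate identities
$1/k_\mathrm{active} = 1/k_\mathrm{deactivate} + 1/k_\mathrm{on}$; a
literally Poisson-distributed duration has no continuous-time meaning.
The per-frame active fraction $A \in (0, 1]$ is the overlap of the active
intervals with each unit frame interval.

*Rendering and noise.* Expected images are $b + \sum_i A_i N g(\mu_i)$
with $g$ the integrated Gaussian; pixel values are Poisson draws. The SNR
of an emitter instance is defined in the shot-noise form $s/\sqrt{s+b}$
with $s$ its peak-pixel expected signal; "normalizing to an average SNR"
rescales $N$ globally so the mean over active instances hits the target.
Because many instances are partial-frame (small $A$), the rescaled $N$
for a movie at nominal SNR 2 makes fully active emitters brighter than
the nominal figure — the definition is exposed and the scale factor
returned. The grid preset renders one expected frame of 16×16 emitters
and re-draws the Poisson noise for each of the 3500 duplicated frames;
duplicating noisy frames would make repeated detection trivial. Brownian
movies use per-axis Gaussian steps of variance $2 D t_a$ with reflection
at the borders, and return the true trajectories as a tracking table.

*What it does not emulate:* sCMOS pixel-dependent noise, EMCCD excess
noise, sample drift, axial defocus, motion blur within a frame, and
multi-emitter overlap handling. Passing tests on these movies therefore
demonstrate correctness of the algorithms under ideal shot-noise-limited
conditions, not robustness to every camera artifact of real data.

## Evaluation

Localizations are scored against ground truth per frame with the same
optimal-assignment machinery (radius default $2\sigma_\mathrm{PSF}$, the
common convention in localization-microscopy scoring); the Jaccard index
is $TP/(TP+FN+FP)$ and RMSE the root mean squared pair distance. When
both sets are empty the Jaccard index is defined as 1 and RMSE reported
as 0 with a degenerate flag.

Fourier ring correlation bins both sets into 2D histograms at `super_px`
nm, correlates their Fourier transforms per radial frequency ring, and
reports the inverse of the first frequency where the curve — smoothed
with a 3-ring moving average to suppress spurious single-ring dips —
falls below 1/7 of its maximum, refined by linear interpolation between
rings. The super-pixel must oversample the expected resolution (bins of
8–12 nm resolve resolutions down to ~2× that); the curve is returned so
a missing crossing is visible rather than silent. For simulations the two
sets are ground truth and observations; for experimental data, split one
localization set into random halves.

## Post-processing

The dSTORM quality chain keeps fits with SBR > 0.8 and width within
1.42 ± 0.4 px (inclusive edges, with a $10^{-9}$ slack so representable
boundary values pass), then removes localizations on tracks longer than
25 frames — persistent emitters are fluorophore clusters, not single
switching molecules. Super-resolution rendering is either a plain 2D
histogram or precision-weighted splatting, where each localization enters
as a unit-integral Gaussian of width equal to its CRLB precision; both
modes conserve the localization count as the image integral.

For diffusion, displacements between track points $k$ frames apart are
pooled across tracks per lag; $x$ and $y$ components are pooled into one
1D sample (isotropy), and intervals spanning a bridged gap are excluded
because their effective time base differs. The per-lag variance is the
closed-form Gaussian MLE (mean of squares); a least-squares fit of a
Gaussian bell to the normalized displacement histogram is available and
agrees asymptotically. The variances, in µm², are regressed on lag time
with ordinary least squares over lags 1..5 by default (longer lags are
noise-dominated): $\sigma^2 = 2 D\,k t_a + \varepsilon$ per axis, so the
slope halves to $D$ and the intercept absorbs static localization error.
The per-axis convention with factor $2D\Delta t$ (rather than radial
$4D\Delta t$) is fixed here and used consistently. A negative slope is
reported with a flag, never silently clipped.

## Persistence and provenance

Every analysis returns a bundle: the three stage tables plus the plugin
name and every parameter value of every executed stage, sufficient to
re-run the identical analysis. Bundles persist as a single hierarchical
JSON file — open and language-neutral — with doubles serialized as
17-significant-digit strings, which reproduces every finite IEEE double
bit-exactly (plain JSON number emission does not guarantee this). CSV
export per table is provided for interoperability.

## Problem sizes used by the tests

The test-bed sizes are chosen so the whole suite runs on a laptop-class
machine in a few minutes while keeping every statistical check
well-powered: kinetics identities at $10^4$ emitters; CRLB Monte-Carlo at
1000 refits; the SNR sweep on 100-frame, 128 px star movies at SNR 2/3/5
with the generator's default density; diffusion recovery on 200 particles
for 200 frames at 950 Hz on a 384 px field, where the reflection bias on
$D$ (≈3% at 256 px) is comfortably below the recovery tolerance; oracle
equivalence on 200 random instances of up to 6 points per side.

## Known limitations

Overlapping emitters are fitted one at a time — crowded scenes bias
positions and inflate RMSE tails; multi-emitter fitting is out of scope.
The CRLB-based precision is a lower bound: below ~100 signal photons the
reported precision understates the true scatter (see above). The tracker
has no motion model; fast directed motion with close encounters favors a
Kalman-style linker. Drift is neither simulated nor corrected.
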