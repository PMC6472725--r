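---
title: "Phase-space measures of pedalling-force variability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-space measures of pedalling-force variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedalphase)
```

## The problem

The tangential force a cyclist applies to the crank traces a quasi-sinusoidal
curve once per pedal revolution. Linear summaries of that curve (means,
coefficients of variation) are often blind to changes in its *shape* — where
the peak sits, how long the downstroke stays above the mean, how noisy the
recovery minimum is. This package implements a non-linear alternative: each
terrain sector's force series is standardized and embedded in a
two-dimensional delay phase space, where a perfectly repeating cycle traces a
closed limit-cycle orbit centered on the origin. Deviations of the orbit's
*location* — not its size — then quantify shape changes of the pedalling
pattern, and a planned contrast tests whether those deviations follow the
terrain's inclination profile.

## Pipeline and model

For one subject, one session, one terrain sector:

1. **Segmentation.** Cycles are cut at upward zero crossings of the force:
   the first sample at or above zero whose predecessor is negative. No
   sub-sample interpolation is attempted — boundaries stay on the 64 Hz
   grid, so revolution times are exact multiples of the sample period.
   Crossings closer than `min_cycle_samples` (default 16 samples, i.e. a
   240 rpm ceiling) to the previous accepted crossing are treated as
   noise-induced double crossings and dropped. Partial cycles at the sector
   edges are discarded: they would distort the segment statistics.
2. **Time normalization.** Each cycle is linearly interpolated to
   `interp_points = 100` samples, removing cadence differences within and
   between subjects.
3. **Standardization.** The reassembled sector series is z-scored with its
   own mean and sample standard deviation (divisor $n-1$), removing
   amplitude differences. Standardization happens after interpolation,
   matching the pipeline's stated order of operations; because
   interpolation is linear and cycles are near-periodic, the difference
   from z-scoring raw samples is negligible for realistic cadences.
4. **Embedding.** The delay embedding pairs the series with itself shifted
   by $\tau = 0.25$ cycles: $P_i = (z_i, z_{i+\tau})$. On the normalized
   grid $\tau$ is exactly 25 samples, which is the only reading under which
   a fractional-cycle delay is well defined after normalization. The series
   is truncated, never wrapped: wrap-around would pair the last cycle with
   the first and fabricate continuity the recording does not guarantee. A
   pure sinusoid embeds onto a circle of radius $\sqrt{2}$ (its z-scored
   amplitude), centered on the origin.
5. **Measures.** Five outcome variables per sector:
   - $L_R$: Euclidean distance from the origin (the cloud's arithmetic
     center after z-scoring) to the center of the best geometric regression
     circle, fitted by Levenberg–Marquardt minimization of
     $\sum_i (\sqrt{(x_i-x_c)^2+(y_i-y_c)^2}-r)^2$ starting from the
     algebraic (Kåsa) solution.
   - $\lVert M_c \rVert$: norm of the componentwise median of the cloud.
   - $\lVert M_{L1} \rVert$: norm of the geometric (L1) median, computed by
     Weiszfeld iteration with the Vardi–Zhang correction when an iterate
     lands on a data point.
   - RevTimeCV: $100\, s_{\mathrm{RevTime}} / \bar{x}_{\mathrm{RevTime}}$,
     the percent coefficient of variation of revolution times.
   - HR: the mean of all 1 Hz heart-rate samples inside the sector window.

For a symmetric limit cycle all three location measures vanish; waveform
asymmetries move them away from zero together, but they weight the cloud
differently ($L_R$ through the fitted orbit, $M_c$ marginally per
coordinate, $M_{L1}$ through robust multivariate location).

The medians are reported as norms because the contrast analysis needs one
number per sector; the vector components are retained in the measures table
for inspection. Note that norms are non-negative, so their sampling
distribution near a symmetric attractor is folded — one reason the
prerequisite checks are attached to every contrast row.

## Contrast analysis

Let $\lambda_j$ be the z-scored inclinations of the analysis sectors
(4–11). For each subject the sector values of one outcome variable collapse
to a contrast score $L_i = \sum_j \lambda_j v_{ij}$; the hypothesis that
the outcome pattern follows the inclination pattern is the one-sample,
one-tailed (upper) t test of the $L_i$ against zero with $df = n-1$:

$$ t = \frac{\bar{L}}{s_L/\sqrt{n}}, \qquad
   p = P(T_{n-1} > t), \qquad
   g = \frac{\bar{L}}{s_L} = \frac{t}{\sqrt{n}}. $$

The effect size $g$ is the standardized mean contrast score with **no**
small-sample correction: the uncorrected ratio reproduces every published
$(t, g)$ pair of the reference study's contrast table, whereas the usual
$df$-based correction factor ($\approx 0.914$ at $df = 9$) is incompatible
with all of them. Likewise the one-tailed upper reading of $p$ is adopted
because it is the only convention consistent with every published
$(t, p)$ pair, including the negative-$t$ row ($t = -0.453 \to p = 0.669$).

Prerequisites — Shapiro–Wilk on the $n$ contrast scores, Bartlett across the
sector-wise groups — are computed and reported with every row but are never
fatal: the original analysis reports that they were tested, not that rows
were dropped. Which data the checks were applied to is not documented
upstream; applying Shapiro–Wilk to the scores (the quantity actually
t-tested) and Bartlett to the sector groups is this package's documented
choice. $\alpha = 0.01$ is applied per test with no multiplicity
correction, matching the original design; the flag in the output is purely
decorative — $t$, $p$, $g$ never depend on it.

## The synthetic session generator

No raw recordings are published for this kind of study, so the package
ships a generator that emulates the *statistical structure* the analysis
assumes, making every stage testable end to end.

**Waveform.** One cycle is $A\,\sin(2\pi g(\phi)) + \varepsilon(\phi)$ with
the monotone phase warp

$$ g(\phi) = \phi - \beta\,\frac{\sin(2\pi\phi) +
   \tfrac{1}{2}(1-\cos(2\pi\phi))}{2\pi},
   \qquad \beta = \beta_0 + \kappa\,\cdot\text{inclination}. $$

The sine term delays the force peak into the second quadrant of the cycle;
the cosine term moves the mid-cycle zero crossing later, prolonging the
above-mean downstroke. The cosine term is essential and deliberate: a pure
sine warp satisfies $g(\phi + \tfrac12) = g(\phi) + \tfrac12$, which makes
the waveform antisymmetric over half a cycle and its value distribution
symmetric about zero — the componentwise median of the embedded cloud would
then be identically $(0,0)$ no matter how strong the warp, and the
generator could never exercise that measure. Warp strengths are kept below
$|\beta| = 0.5$, comfortably inside the monotonicity bound
$|\beta| < 2/\sqrt{5}$.

$\varepsilon(\phi)$ is zero-mean Gaussian with SD
$\sigma_0 + \sigma_1 \max(0, \text{incl}) \, v(\phi)$, where $v$ is a unit
Gaussian bump (width 0.06 cycles) centered on the waveform minimum:
variability concentrates around the recovery-phase minimum on climbs.

**Sessions.** Per-cycle periods are $60/\text{cadence} \times
(1 + N(0, \text{jitter CV}))$, sampled at 64 Hz — cadence jitter is
deliberately inclination-free, so RevTimeCV is independent of terrain by
construction and serves as the pipeline's built-in negative control. In
NO_SHIFT sessions (fixed gear) the warp, the amplitude and the valley noise
couple to inclination; in SHIFT sessions (free gear) all three couplings
are zero — gearing absorbs the load — while heart rate still responds, at
half the gain. Heart rate follows a noisy first-order lag (time constant
30 s) toward $\text{hr}_\text{rest} + \text{hr}_\text{gain}\cdot
\text{incl}$.

**Defaults.** 10 subjects, 13 contiguous sectors of 180 s (sectors 4–11
analyzed, inclinations 0, 2, 4, 1, −2, −4, 3, 6 % — a mixed profile with a
downhill stretch followed by the steepest climb; the originating study
shows its terrain only graphically, so these values are this package's
choice of a realistic mixed course), cadence 77 rpm with 3 % jitter,
amplitude 150 N, $\beta_0 = 0.08$, $\kappa = 0.035$ per % grade
(so $\beta \le 0.29$ at 6 %), $\sigma_0 = 4$ N, $\sigma_1 = 1.5$ N per %
grade, heart rate 95 bpm rest + 7 bpm per % grade. Between-subject
heterogeneity (CV 10 % on cadence, coupling and heart-rate gain) keeps
contrast t values finite and realistic rather than astronomically large.
One global seed streams every session; the stream depends on subject only,
so a subject's SHIFT and NO_SHIFT sessions share cadence and noise draws
and differ exactly where the couplings act.

**What the generator does and does not emulate.** It reproduces the
qualitative structure the analysis targets — attractor location measures
and heart rate tracking inclination under fixed gearing, decoupling under
free gearing, terrain-independent cycle-time variability. It does not
attempt biomechanical realism: no two-leg interaction, no fatigue drift, no
rolling resistance or trainer control dynamics, no inter-cycle serial
correlation beyond the waveform itself. Passing the end-to-end tests
therefore demonstrates that the pipeline detects the intended class of
waveform-shape changes at realistic noise levels — not that real riders
produce exactly this waveform family.

## Numerical choices

- **Circle fit**: Kåsa algebraic initialization (fallback: origin with RMS
  radius when the design matrix is singular); damped Gauss–Newton with
  multiplicative damping adaptation; convergence when the step norm falls
  below $10^{-10}$, capped at 100 iterations; non-convergence is reported
  in the `converged` flag, not thrown. Collinear clouds are rejected.
- **Geometric median**: Weiszfeld from the componentwise median, stop when
  successive iterates move less than $10^{-8}$, cap 1000 iterations;
  Vardi–Zhang step at coincidences, with the optimality test
  $\lVert R \rVert \le \eta$ for early exit. Two points return the midpoint
  (any point of the segment minimizes; the midpoint is the symmetric,
  deterministic choice).
- **Zero-variance guards**: constant segments cannot be z-scored; identical
  sector patterns give contrast scores of pure rounding noise, detected
  with a relative threshold rather than exact zero.
- **Sector assignment**: terrain windows are half-open $[start, end)$ on
  the session time axis; a cycle belongs to the sector containing its
  starting boundary. Distance-based terrain definitions must be converted
  to time upstream, since force is recorded against time.
- **Clock alignment**: the 64 Hz force clock and the 1 Hz heart-rate clock
  are assumed to share time zero; how the original hardware aligned them is
  not documented beyond "synced".

## Problem sizes used in the shipped analyses

The shipped analysis scripts and the end-to-end tests run the full
10-subject, 2-session, 13-sector study with 180 s sectors (roughly 230
cycles per sector, 3 × 10^6 force samples in total), which completes in
well under a minute; property-style tests use 30–60 s sectors, which
preserve ≥ 30 cycles per sector — enough for stable medians and circle
fits — while keeping the suite fast.

## Known limitations

- The location measures are reported as norms, so they cannot distinguish
  the *direction* of attractor displacement; the vector components are kept
  in the measures table for that purpose.
- The contrast is directional (upper-tailed). A variable that tracked
  inclination *inversely* would produce a large negative $t$ and a $p$
  near 1, not a detection.
- Segmentation assumes the force signal crosses zero every cycle. Recordings
  with a strictly positive tangential force (e.g. heavy flywheel drag
  compensation) would need re-referencing before segmentation.
- With integer-sample boundaries, revolution-time quantization contributes
  up to one sample period of jitter to RevTimeCV at 64 Hz; at ~50 samples
  per cycle this is a floor of roughly 0.5 % CV, negligible against the
  3 % cadence jitter simulated here.
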