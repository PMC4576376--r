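---
title: "Methods: from raw tag channels to annotated movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw tag channels to annotated movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ddtag` processes high-rate multi-sensor tag logs in a fixed chain of
modular steps. This vignette explains the model behind each step, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-deployment tests do and do not show
about real data.

## The data model

A deployment is a `sensor_table`: an ordered set of samples with a typed
channel schema. Five time fields (day, hour, minute, second, millisecond)
combine into the millisecond time index as
`day·86400000 + h·3600000 + min·60000 + s·1000 + ms`. The combination is
*not* re-based to zero, so positional fixes stamped on the same clock align
exactly at merge time. Fix merging is an exact-timestamp join — a fix
between two samples stays unmatched (no interpolation) unless an explicit
nearest-neighbour tolerance is enabled, which is off by default because a
silent tolerance can hide clock desynchronisation. Missing values are `NA`
and are skipped, not imputed, by every windowed computation downstream.
Row indexing is 1-based throughout, R's native convention; exported files
carry timestamps, never indices, so no off-by-one ambiguity leaves the
package.

## Magnetometer calibration

An error-free magnetometer swung through all orientations traces a sphere
centred at the origin. A hard-iron bias *b* displaces it; soft-iron
distortion maps it to an ellipsoid. `fit_ellipsoid()` fits the general
quadric `x'Ax + 2b'x = 1` to the sample cloud by linear least squares,
completes the square to get the centre (the hard-iron offset) and shape
matrix, and takes the SPD matrix square root as the correction *W*, so
`corrected(x) = W(x − b)` lies on a sphere. This algebraic fit was chosen
over an iterative adaptive estimator because it is closed-form,
deterministic and — as the tests verify — recovers the generating offset
and (up to global scale) the distortion matrix to ~1e-6 on noise-free data.
Heading is invariant to the global scale of *W*, which is therefore fixed
cosmetically so the mean corrected norm is exactly 1; the reported field
magnitude is the geometric mean of the fitted semi-axes in raw units, and
fit quality is reported as the coefficient of variation (CV) of the
corrected norms.

One consequence worth knowing: the correction maps sensor noise through
*W*, so the corrected-norm CV is roughly the noise sigma scaled by the
distortion's spectrum (relative to the field magnitude). The noisy-recovery
tests use a mild ~10% soft-iron distortion — the realistic case for a
device-mounted sensor — where sigma = 1% of the field yields a CV just
under 1%. A pathological distortion with eigenvalues far above 1 would
amplify noise beyond that figure without any defect in the fit.

Degenerate clouds (fewer than 10 samples, rank-deficient/near-planar
geometry, or a non-ellipsoidal fitted quadric) are rejected with an
"insufficient orientation coverage" error rather than returning a garbage
model.

## Attitude and heading

Raw acceleration is split into static and dynamic parts by a centred
moving average with truncated edges (`running_mean`). The window is a
required user parameter: it must be odd (so the window is centred) and
should span roughly the animal's stride period or above — about 2 s is a
common starting point; window 1 disables smoothing entirely. The split is
exact by construction: dynamic is defined as `raw − static`.

Pitch and roll use the standard accelerometer-tilt equations
(`pitch = atan2(−sx, √(sy²+sz²))`, `roll = atan2(sy, sz)`) for a tag whose
z axis reads +1 g when level. The sign conventions are internally
consistent and validated by rotation-oracle recovery in the tests; other
tools may differ in sign. At gimbal lock (|pitch| → 90°) roll is 0 by the
`atan2(0, 0) = 0` convention, and the heading is set to `NA` when the
level-frame horizontal magnetometer component falls below 1e-9 of the
vector norm, since a compass direction is undefined there.

Tilt compensation rotates each magnetometer vector by roll about x, then
pitch about y, bringing its x–y plane level. The compass equation
`H = atan2(m_y, −m_x)` is evaluated with the two-argument arctangent so all
four quadrants resolve while agreeing with the single-argument ratio where
defined; declination (a single user-supplied constant for the study site,
in degrees) is added modulo 360. Angles are degrees at every interface and
radians only internally.

Sensor-frame alignment (magnetometer vs accelerometer axes, and the
device's discrete mounting orientation) is expressed as signed permutation
matrices; applying a map and then its inverse restores the input exactly.

## Energetics and speed

Per-axis dynamic acceleration is the absolute residual about the running
mean, `DA = |raw − running mean|`; `VeDBA = √(ΣDA²)` and `ODBA = ΣDA`.
The alternative reading — a running mean *of* absolute residuals — was
rejected: with it a static signal would not give exactly zero VeDBA, the
identity the package treats as definitional. The norm inequality
`ODBA/√3 ≤ VeDBA ≤ ODBA` holds samplewise and is tested as a property.
The same window is used for the attitude and DBA splits by default, but
they are independent parameters.

Speed is `s = VeDBA·m + c` when `VeDBA > t` (strictly; at `VeDBA = t` the
speed is 0) and 0 otherwise, with no hysteresis or smoothing added. The
coefficients m, c and threshold t come from external calibration
(treadmill/VO₂ studies) and are taken as given. For volant species VeDBA
does not track airspeed, so a constant-speed mode returns a fixed value to
be refined later by fix correction.

## Dead-reckoning and fix correction

Integration advances one sample per update: the speed over the sample
interval becomes the angular distance `q = s·Δt/R` with R = 6.371×10⁶ m
(spherical earth; no ellipsoid), and the destination-point equations update
latitude and longitude along the heading. Δt enters because speed is in
m/s — dimensional consistency forces the per-sample interval into q. Steps
with `q = 0` or missing heading/speed leave the position unchanged, which
is what makes sub-threshold speeds "park" the track. Starting at a pole
with nonzero motion is an error (longitude undefined).

The segment bearing between two points uses the standard initial-bearing
two-argument-arctangent formula, constrained by the round-trip property
that one dead-reckoning step of the matching distance along that bearing
lands on the target point to < 1e-9°; distance is the haversine form. The
correction loop treats the bearing/distance between a segment's endpoints —
not per-sample quantities — as the thing to match: per segment between
consecutive fixes it adds `hC = gpsHeading − drHeading` (wrapped to
(−180, 180]) to every sample heading and multiplies every sample speed by
`sC = gpsDistance/drDistance`, re-integrates, and repeats until the updates
fall below tolerance (defaults: max 10 iterations, 0.1° heading, 0.1%
speed — the loop typically converges in one or two iterations because a
constant rotation/scaling of a short spherical segment is almost exactly
what the endpoint mismatch measures). `sC` scales `q` uniformly, the only
reading under which `sC` makes the segment length equal the fix-to-fix
distance. Each segment is re-anchored exactly at its opening fix, resetting
accumulated error; the track start is the first fix. Samples after the last
fix reuse the last segment's coefficients, on the assumption that the
systematic error they estimate persists; samples before the first fix keep
their dead-reckoned shape translated to end at the first fix. A segment
with no dead-reckoned movement but moving fixes cannot be fixed by scaling
(`sC` undefined): it is flagged and a constant-speed fallback spreads the
fix-to-fix distance uniformly across the segment. Fix errors themselves are
not modelled — fixes are trusted as ground truth.

## Behaviour classification

Classification is query-by-example search: one positive example (any
channels — accelerometer for gaits, magnetometer for thermalling, pressure
for dives) slides along the series, and normalized cross-correlation scores
shape similarity at each position. Each channel's template and window are
zero-meaned and unit-normed, so gain and offset shifts do not affect the
score; the per-channel correlations are averaged (unweighted — no channel
is privileged a priori) and mapped to percent as `(r + 1)/2·100`, making
100% an exact shape match and 0% a perfect anti-match. The sliding products
are computed in frequency space, which the tests verify agrees with the
direct sliding dot product to 1e-10; windows with zero variance score 0
(no shape to match), and windows touching missing data score `NA`. An
unnormalized mode returns the raw amplitude-sensitive correlation for the
cases where amplitude *is* the signal.

Matches are positions strictly above the threshold, reduced by non-maximum
suppression so accepted windows do not overlap (highest similarity wins,
ties to the earliest start); suppression is configurable off since some
workflows want the raw crossings. The default threshold of 80% comes from
the planted-motif benchmark geometry: at 6 dB SNR a true motif scores about
95% while the maximum noise-window score over thousands of positions stays
near 70%, so 80 splits the two populations with margin on both sides.
Boosting pools the candidate matches of several templates of the same
behaviour and suppresses overlaps jointly, so the boosted count is never
below the best single template's. Rational-factor resampling (interpolate
by p, decimate by q) searches for the same behaviour at a different speed;
it is implemented as zero-stuffing plus a linear-phase FIR low-pass with
the group delay compensated and first-derivative edge reflection, which
keeps a sine's 2/1-then-1/2 round trip under 0.1% RMS — an uncompensated
polyphase filter would shift the waveform by half the filter length and
break template alignment.

The accept/reject loop is modelled without a GUI: matches enter a pending
queue, decisions move them into classes (`provenance = "matched"`) or into
a rejection record that prevents identical intervals from being re-proposed
by later searches; manual labels override rejections (the expert outranks
the bookkeeping). Class codes are integers assigned in creation order with
0 reserved for unlabelled rows; overlapping labels of the same class are
unioned, overlaps across classes are an error because a sample cannot
carry two codes in the exported file. Templates persist in a plain-text
store (one file per template plus a JSON index) keyed animal → behaviour.

## The synthetic-deployment generator

`simulate_deployment()` emulates the full sensor constellation with every
generating parameter retained: attitude programmes rotate gravity into the
accelerometer, the magnetic field (magnitude, inclination) is rotated into
the device frame and pushed through the *inverse* calibration
(`A⁻¹m + b`), fixes are truth-track positions at a fixed interval plus
noise, and gait is an amplitude-modulated sine whose amplitude tracks truth
speed — making the VeDBA–speed proxy exactly linear by construction, so
the speed model is recoverable by regression. Systematic errors enter the
way they do in the field: a heading bias rotates the *sensor* frame while
the animal moves along the truth heading, and a speed scale distorts the
observed speed channel.

Default conditions describe a modest terrestrial deployment: 40 Hz, 0.5
m/s, smooth heading wander (0.5°/sample random walk), ±35°/±50°
pitch/roll oscillation (enough orientation coverage for ellipsoid
calibration), unit field at 60° inclination, a ~10–30% soft-iron
distortion with offset (0.2, −0.1, 0.3), and fixes every 60 s. The
noise-free end-to-end scenario uses an attitude window of 1 sample —
static = raw is exact for a gravity-only accelerometer under any attitude
programme — a constant-speed model, and behaviour motifs planted on the
pressure channel so the accelerometer stays gravity-only; these are the
conditions under which sub-microdegree recovery of truth headings and
track is attainable and meaningful. Problem sizes in the test suite
(10⁴-step oracle walks, 10³ round-trip pairs, 500-point calibration
clouds, 240–300 s deployments at 10–20 Hz, a 4000-sample motif benchmark)
were chosen once as the smallest sizes at which the asymptotic behaviour
is visible.

What passing these tests shows: the derivation chain is internally exact
and the correction/classification machinery recovers planted truth under
the stated conditions. What it does not show: performance on real animals —
real gait is not a sine, real attitude is not smooth, magnetic
interference varies in time, GPS fixes err, and behaviours vary in duration
and shape far beyond an additive motif. The generator is a correctness
instrument, not an animal model.

## Known limitations

Vertical movement (pressure-derived depth/altitude) is not integrated into
the track; the earth is spherical, not an ellipsoid; declination is a
single constant per deployment; fix error is unmodelled; template matching
assumes the behaviour's duration is within the reach of rational
resampling; and the suite's evenly-spaced fix schedule is kinder than the
gappy fixes of real deployments.
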