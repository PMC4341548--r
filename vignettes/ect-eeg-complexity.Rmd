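---
title: "Tracking EEG complexity across an ECT course: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking EEG complexity across an ECT course: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectmse)
```

## The problem

Electroconvulsive therapy (ECT) produces clinical change whose
neurophysiological correlates are poorly understood. One candidate marker is
the *complexity* of the resting EEG: not its power in fixed frequency bands,
but the irregularity of its fluctuations across temporal scales. This
package implements a complete analysis of that idea for a longitudinal
single-subject design: repeated resting-state EEG sessions before, during,
and after an ECT course (plus a benzodiazepine comparison phase), each
reduced to multiscale entropy (MSE) curves and conventional power spectra,
then summarized into scale-band-by-region scalars that can be tracked over
the treatment course and related to a clinical severity score (the
Bush-Francis Catatonia Rating Scale, BFCRS) and serum BDNF.

## Sample entropy and the multiscale curve

The central estimator is sample entropy. For a series
$\{x_1, \dots, x_N\}$, embedding dimension $m$ and tolerance $r$,

$$\mathrm{SampEn}(m, r, N) = -\ln \frac{A}{B},$$

where $B$ is the number of ordered pairs $(i, j)$, $i \neq j$, of
$m$-point templates whose Chebyshev distance is strictly below $r$, and $A$
is the number of those pairs still within $r$ when the templates are
extended to $m + 1$ points. Both counts are taken over the $N - m$ templates
that can be extended, so $A/B$ is a genuine conditional probability:
*given that two stretches of signal looked alike for $m$ samples, how often
do they still look alike one sample later?* Perfectly predictable signals
give $A = B$ and entropy 0; for iid Gaussian noise the conditional
probability tends to $2\Phi(r/\sqrt{2}\,\sigma) - 1$, so at the default
$r = 0.2\,\mathrm{SD}$ the estimator should approach
$-\ln(2\Phi(0.2/\sqrt 2) - 1) \approx 2.19$ — a closed-form limit the test
suite checks at full segment length.

Defaults are $m = 2$ and $r = 0.2$ times the segment's standard deviation,
the usual choices for short noisy physiological series. Self-matches
($i = j$) are excluded; the tolerance comparison is strict (`< r`),
following the definition above. Counting is implemented in C++ with a
sorted first-component scan that prunes candidate pairs without changing
which pairs are counted; the suite verifies exact count equality against an
exhaustive $O(N^2)$ scan.

The multiscale curve applies SampEn to coarse-grained copies of the
segment: at scale factor $\tau$, non-overlapping windows of $\tau$ samples
are replaced by their means, giving a series of length
$\lfloor N/\tau \rfloor$. Scale factors run from 1 to 40 — the analysis
bands (below) need scales 1-5 and 31-40, and 40 keeps a 30 s segment's
coarsest series at 375 points, still comfortably long enough for $m = 2$
estimation.

Two conventions deserve comment because the MSE literature varies:

* **Tolerance across scales.** By default $r$ is fixed from the
  scale-factor-1 segment's SD and held constant across $\tau$
  (`r_mode = "fixed"`). Coarse-graining shrinks a white-noise signal's SD
  like $1/\sqrt\tau$, so with a fixed tolerance its entropy *decreases*
  with scale, while long-range-correlated ($1/f$-like) signals stay nearly
  flat — the classic signature separating "complex" from "merely random"
  signals, which the suite tests as a Monte-Carlo trend. A
  `"per_scale"` mode that recomputes $r$ from each coarse series is
  provided for comparison.
* **Undefined values.** When no template pair matches (tiny tolerance,
  short coarse series), the conditional probability is undefined. This is
  represented as a tagged missing value (`NA`) and propagated — band
  summaries skip such entries and report how many were skipped — rather
  than raised as an error mid-pipeline.

## The recording protocol the analysis assumes

Each session contributes two continuous, artifact-free 30 s eyes-closed
segments (15,000 samples at 500 Hz) per channel over an eight-electrode
10-20 montage (F3, F4, C3, C4, P3, P4, O1, O2). MSE is computed per
segment and the two curves averaged per channel. No software filtering,
re-referencing or artifact correction is applied on read: filtering can
distort the nonlinear temporal structure the entropy estimator measures,
so the acquisition bandpass is treated as a property of the data. Two
automated stand-ins replace procedures that are visual in practice:

* an amplitude/gradient artifact flag (defaults 100 µV and 50 µV/sample,
  both configurable) replaces visual segment rejection;
* a posterior alpha-dominance check (mean alpha power above the mean of
  the flanking theta and beta bands in both O1 and O2) replaces visual
  confirmation of eyes-closed wakefulness.

Segment positions within the recording are an explicit input (markers in
the session manifest), not inferred: windows are half-open in seconds with
0-based sample indexing, and extraction is sample-exact.

## Spectral comparison analysis

The conventional comparison splits each 30 s segment into fifteen 2 s
epochs (0.5 Hz resolution), applies a Hanning taper per epoch, averages
one-sided absolute power across epochs, and log-transforms (base 10) last.
Power is compensated for the taper's power loss so a white-noise spectrum
is flat and total power matches the signal's mean square. Band edges are
not part of the protocol being emulated, so the standard clinical bands
(theta 4-8, alpha 8-13, beta 13-30, gamma 30-60 Hz, half-open) are adopted
as configurable defaults; directional band-power conclusions should be
robust to these edges, and tests only assert constructions that are.

## Course summaries and associations

Each session collapses to two scalars: the mean SampEn over scale factors
1-5 across F3/F4/C3/C4 (**frontocentral fine-scale complexity**, 20
values) and over scale factors 31-40 across O1/O2 (**occipital
coarse-scale complexity**, 20 values). P3/P4 are computed but enter no
summary, since the tracked bands are defined on the frontocentral and
occipital regions only. Condition means average these scalars over each
phase's sessions.

Between-segment reproducibility is quantified per region (frontal F3/F4,
central C3/C4, occipital O1/O2): each session and segment is reduced to
the region's mean SampEn over channels and all scale factors, and the
Pearson correlation between segment-1 and segment-2 scalars is taken
across sessions. The protocol this emulates did not specify the exact
quantity correlated; the region-mean-over-all-scales reduction is this
package's interpretation, chosen because it uses every scale the curves
contain and matches the per-region reporting convention. Under a shared
session effect with independent segment noise the expected correlation is
the variance ratio $\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$, which the
suite verifies against simulation.

Clinical association is deliberately descriptive: Pearson r (with the
number of points) between each complexity summary and BFCRS or BDNF,
computed over all sessions and with the lorazepam phase excluded. The
exclusion variant exists because a sedative can improve the clinical score
without changing EEG complexity, which dilutes the association; comparing
the two variants makes that dissociation visible. No p-values or
multiple-comparison machinery are attached — with two dozen dependent
sessions from one subject, inferential statistics would suggest a rigor
the design cannot support. BDNF is sparse serum data and is used only
where measured, never interpolated.

## The synthetic study generator

No EEG from the emulated protocol is publicly deposited, so the package
ships a generator that produces a complete surrogate study at the same
geometry: 24 sessions (3 pre-ECT, 7 during-ECT, 8 after-ECT, 6 lorazepam),
two 30 s segments per session and channel at 500 Hz. Each channel signal
is built from:

* a $1/f^\beta$ Gaussian background (spectral shaping of white noise,
  $\beta = 1$ by default — the broadband slope of resting EEG);
* an amplitude-modulated alpha oscillation, strongest occipitally
  (relative amplitude 1.2 at O1/O2 falling to 0.1 at F3/F4), so generated
  signals pass the alpha-dominance check where real eyes-closed EEG would;
* a **fine-scale regularity injection**: a fraction $\lambda_f$ of a
  moving-average-smoothed copy of the background is mixed in, making the
  signal locally more predictable and lowering SampEn at scale factors
  1-5 (applied frontocentrally);
* a **coarse-scale variability injection**: an additive band-limited
  (0.3-6 Hz) standardized slow stochastic component scaled by
  $\lambda_c$, which survives coarse-graining and raises SampEn at scale
  factors 31-40 (applied occipitally). An additive slow component was
  chosen over a multiplicative slow envelope because modulating a
  zero-mean background perturbs coarse-grained window means only at
  second order and does not reliably move coarse-scale entropy.

Both effects are injected *mechanistically*, through signal construction,
never by targeting entropy values — so the entropy estimator remains an
honest measurement of the generated dynamics. Condition defaults encode
the direction of the treatment effects being emulated (fine-scale
frontocentral complexity falls during ECT and partially reverts after;
coarse-scale occipital complexity rises and partially reverts; lorazepam
resembles the pre-treatment state), with magnitudes chosen once as
plausible for a clearly-visible single-subject effect — published figures
give direction but no numeric effect sizes. Per-session jitter on the
lambdas (SD 0.04), shared by a session's two segments, gives realistic
between-session variability and keeps between-segment reproducibility
below 1. The BFCRS trajectory falls from around 28 during ECT to around 6,
relapses partway after, and falls again under lorazepam; BDNF rises with
ECT and is observed at only four sessions to emulate sparse serum
sampling. The ECT course table is packaged verbatim via
`table1_fixture()` (eight stimulations, one failed seizure).

What the generator does **not** emulate: eye-blink/EMG artifacts, drowsiness
episodes, electrode drift, medication effects other than the condition map,
and any true neural-mass dynamics. Passing tests on synthetic data
therefore demonstrate that the pipeline measures what it claims to measure
under controlled dynamics, not that real patient EEG would show these
effects.

## Numerical and design choices

* Coarse-graining discards the trailing partial window; windows never
  overlap.
* Chebyshev (max-component) distance for template matching, per the
  SampEn literature.
* Natural logarithm for entropy; log10 for spectra (figure-axis
  convention of standard EEG analyzers; switchable).
* EDF physical units are normalized to µV on read; matrix CSVs are
  assumed µV. The EDF writer quantizes to 16 bits, so EDF round trips are
  exact only to the physical span divided by $2^{16}$; matrix CSV round
  trips are bitwise for integer-representable data.
* Zero-variance segments are an error at entropy time (the tolerance
  degenerates), not silently 0.
* All randomness in generation flows from a single integer seed;
  identical seed and configuration reproduce a study byte-for-byte.

## Problem sizes used by the shipped checks

The package's own verification scripts run the full canonical geometry
where the quantity demands it (30 s / 15,000-sample segments for the iid
limit, the entropy-versus-scale signatures, and the synthetic-course
recovery runs, the latter over 20 generator seeds with entropy evaluated
on the scale bands the summaries need), and reduced geometries (4 s
segments, one session per condition) where only plumbing is under test.
These sizes are stated here as the package's reference configuration for
its own regression checks.

## Known limitations

* The design is a single-subject treatment course: associations are
  descriptive, and nothing here supports population-level claims.
* SampEn measures irregularity, not "complexity" in a physiological
  sense; the multiscale profile mitigates but does not resolve this.
* The maximum scale factor (40) and the band edges are defaults of this
  package, configurable where the emulated protocol is silent.
* The reproducibility reduction (region mean over all scales) is an
  interpretation; other reductions (per-scale correlation, ICC) would be
  defensible.
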