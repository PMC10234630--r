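---
title: "Quantifying temporal individuality in developing C. elegans"
author: "roamdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal individuality in developing C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roamdev)
library(S4Vectors)
```

## The problem

Isogenic *C. elegans* individuals raised in identical environments still
behave differently, and those differences can persist across the whole of
development. On food, a worm alternates between two locomotor states:
*roaming* (fast, relatively straight runs that cover a large area) and
*dwelling* (slow movement with frequent reorientations). Tracking single
worms continuously from hatching through the four larval stages into
adulthood produces, for each individual, a long behavioral trajectory whose
roaming content varies both with developmental time and between individuals.

`roamdev` implements the full analysis chain from a frame-level centroid
trajectory to population-level statements about *individuality dimensions*:

1. rolling kinematics and two-state classification of every frame,
2. segmentation of a recording into stages at lethargus midpoints and
   age normalization into a fixed number of bins per stage,
3. a rank/bias transform that places each individual relative to its
   experiment at every developmental time window,
4. weighted-covariance PCA of the bias matrix, whose leading components are
   temporal individuality dimensions,
5. shuffle-null significance for components and permutation tests for
   differences in score dispersion between conditions, and
6. a synthetic cohort/trajectory generator that plants known structure so
   every step is testable without any recordings.

## From trajectory to binned behavior

**Kinematics.** Per-frame speed is the centroid displacement times the frame
rate (3 fps by default); the heading is the direction of the displacement
vector, and angular velocity the absolute wrapped heading change per second.
Both are averaged over a centered 10 s rolling window (30 frames at 3 fps).
Edge frames with truncated windows are flagged rather than dropped. A
stationary frame has no heading; its angular velocity is defined as zero.
Non-uniform sampling is an error naming the offending frames — gaps are
never silently interpolated.

**Two-state classification.** Roaming and dwelling separate in the joint
distribution of speed and angular velocity. The classifier works in the
units of a 50 x 50 reference histogram (speed bin 7.59 um/s, angular
velocity bin 3.6 deg/s) and draws a per-stage diagonal through it: a frame
in stage $s$ is roaming when

$$\frac{v}{7.59} > m_s \cdot \frac{\omega}{3.6},$$

with slopes $m_s$ = 5, 2.5, 2.3, 2, 1.5 for L1, L2, L3, L4 and adulthood. A
larger slope is a stricter roaming criterion, so the roaming set shrinks
monotonically as a slope grows. Frames exactly on the diagonal, and frames
in the zeroth speed bin (speed below one bin width), are dwelling. Because
the diagonal is linear, applying the inequality per frame is identical to
the histogram-lookup formulation and needs no binning. The axis orientation
and the on-diagonal assignment are conventions of this package (fast +
straight = roaming); they are stated here because the field's verbal
descriptions do not pin them down.

**Stage segmentation.** Between larval stages the worm is quiescent
(lethargus). The rolling speed is further smoothed with a 300-frame running
mean; quiescent spans are runs where the smoothed speed is at or below the
0.05 quantile of the individual's own smoothed-speed distribution, lasting
at least 20 minutes. The four longest spans are the lethargus periods, and
their midpoints define the stage boundaries. The quantile and the minimum
duration are exposed parameters; only the smoothing window is canonical.
The comparison is "at or below" the quantile value: with strictly-below, a
recording whose quiescent spans have near-constant speed equal to the
quantile value would yield an empty quiescent set, and a numerically tiny
tolerance (1e-6 um/s) absorbs running-mean round-off in that same
degenerate case.

**Age normalization.** Each stage's frame span is divided into a fixed
number of equal-duration windows: 75 per stage (375 fine bins) for
visualization and population statistics, 10 per stage (50 bins) for the
rank-based analysis. The two binnings are computed independently from the
frame labels (75/10 is not an integer ratio, so the coarse matrix is not an
aggregate of the fine one). The per-bin roaming fraction counts roaming
frames over roaming + dwelling frames; quiescent frames are excluded from
numerator and denominator, and empty bins are missing, not zero.

## Ranks, biases and individuality dimensions

Within each experiment and each of the 50 bins, individuals are ranked by
roaming fraction (ascending; ties get fractional ranks, so values 0.1, 0.3,
0.3, 0.9 rank as 1, 2.5, 2.5, 4). Ranks become biases through

$$b_{i,k} = \frac{2}{n_i}\left(r_{i,k} - \tfrac12\right) - 1,$$

where $n_i$ is the size of individual $i$'s experiment. Biases live in
$(-1, 1)$, the experiment median maps to 0, the extremes to
$\pm(1 - 1/n)$, and every per-bin, per-experiment mean bias is exactly zero
— including under ties, which is why no mean term is needed in the
decomposition below.

Each individual's bias vector is decomposed as
$b_i = \sum_k t_{i,k} w_k$ with $t_{i,k} = b_i \cdot w_k$, where the
components $w_k$ are eigenvectors of the *weighted* second-moment matrix
$M = \sum_i w_i\, b_i b_i^\top / \sum_i w_i$. The weight $w_i$ is the
inverse of the number of individuals in $i$'s condition (strain x
treatment), so every condition contributes equally no matter how large it
is; with a single condition this reduces to ordinary (uncentered) PCA. Note
the two groupings: ranking is within *experiment*, weighting is within
*condition*; the data object carries both labels. No mean is subtracted by
default (a centering toggle exists for sensitivity checks). Component signs
are fixed so each component's largest-magnitude entry is positive, and
correlations with components are therefore reported as absolute values.

The leading components have interpretable shapes: a same-sign component
captures individuals that consistently roam more (or less) than their
population across all of development; a component that flips sign once near
mid-development captures individuals that switch their bias during L3; a
twice-flipping component captures individuals whose L1/adult bias opposes
their mid-larval bias.

**Significance by shuffling.** Each bin's ranks are permuted independently
within each experiment (500 replicates by default), which preserves every
per-bin rank multiset while destroying temporal structure. Two comparisons
are made, following the two published variants: (1) *own space* — the
shuffled data get their own weighted PCA and the same-numbered eigenvalue
is recorded; (2) *original space* — the shuffled biases are projected onto
the real components and the weighted score variance along each is recorded.
The exceedance of a component is the fraction of replicates at or above the
observed value. Under a structure-free null the observed eigenvalue is
exchangeable with the own-space replicates, so the own-space test is
exactly calibrated; the original-space comparison is the sharper contrast
for display but is conservative/anti-conservative by construction depending
on the component, and is not used as a calibration reference.

**Dispersion comparisons.** Inter-individual variance of scores along one
dimension (population variance, denominator $n$ — with the uncentered,
weighted decomposition this makes the per-component score variances sum to
the total bias variance) is the dispersal parameter compared between
conditions with a permutation test: individuals are reassigned to two
groups of the original sizes, the two-sided statistic is
$|\mathrm{var}_A - \mathrm{var}_B|$, and
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$ with 1000
permutations by default, so p-values are bounded below by $1/(n+1)$ and
valid. The same procedure circulates under the name "bootstrapping" in
figure legends; `bootstrapVarianceTest()` is an alias. Across components
and condition pairs, p-values are adjusted by Benjamini-Hochberg.

**Consistency index.** The classic summary of homogeneous individuality is
$\log_2(A/B)$ where $A$ and $B$ count the bins in which an individual is
above resp. below the within-experiment per-bin median. Bins tied with the
median are excluded from both counts (this preserves the index's
antisymmetry under reflection about the median), and a zero count is
replaced by 0.5, bounding the index at $\pm\log_2(100)$ for 50 bins. On
cohorts with a planted same-sign dimension, the index correlates with the
first component's scores at $|r| > 0.9$ while the later components stay
near zero — the unsupervised analysis recovers the pre-defined notion of
consistency without being told about it.

## The synthetic generator

The generator defines the conditions under which the machinery is
validated.

**Matrix level.** A cohort's roaming fraction in bin $k$ is

$$p_{i,k} = \mathrm{logistic}\!\left(\beta_k + \sqrt{K} \sum_d c_{i,d}\,
a_d[k] + \varepsilon_{i,k}\right),$$

with orthonormal archetypes $a_d$ over the $K = 50$ bins (built-ins:
homogeneous, single switch at the L3 midpoint, double switch at the L1/L2
and L4/adult boundaries, orthogonalized in order), individual coefficients
$c_{i,d} \sim N(0, \text{strength}_d)$ and per-bin noise
$\varepsilon \sim N(0, \sigma)$. The $\sqrt{K}$ factor makes a strength the
per-bin signal amplitude in units of the per-bin noise SD (a sign-pattern
archetype has entries of magnitude $1/\sqrt K$); without it a "strength"
would shrink with the number of bins, and planted dimensions of order-one
strength would be undetectable in principle. The logistic link keeps
fractions in $[0,1]$; any monotone link would do for a rank-based analysis,
and the logistic is chosen for symmetry. The baseline stage propensities
$\mathrm{logistic}(\beta)$ default to (0.40, 0.50, 0.55, 0.50, 0.35) —
moderate roaming, highest mid-development. Stress profiles multiply the
stage propensity on the fraction scale inside the logit, so a factor of 0.3
suppresses a stage's mean roaming to roughly 0.3 of the unstressed level
and the ratio of condition means recovers the factor. Individuals are
assigned to experiments round-robin, and one root seed expands into
per-individual substreams, so cohorts are bit-reproducible.

**Trajectory level.** Within a stage, roam/dwell episodes alternate with
exponential durations; per-frame speed is drawn from the state's truncated
normal and the heading performs a random walk with the state's
heading-change SD. Between stages, a lethargus span of constant near-zero
speed (0.3 um/s, below the 1 um/s quiescence scale) gives the detector an
unambiguous target. The kinematic defaults are fixtures, not estimates:
roam episodes of 90 s and dwell episodes of 135 s (minutes-scale episodes,
long-run roaming fraction 0.4), per-stage roam speeds rising from 80 to 170
um/s against dwell speeds of 6-15 um/s, heading-change SD 2 deg/frame while
roaming and 40 deg/frame while dwelling. Episode durations matter: a 10 s
rolling window mixes states near episode edges, and with the strict L1
slope a window containing more than a few percent dwell frames classifies
as dwelling, so second-scale episodes would bias roaming fractions low by
more than 0.1. With minute-scale episodes the classify-and-bin round trip
recovers the generating per-stage fractions within 0.1 (measured maximum
error 0.073 across seeds and stages).

**Frame level.** For the size module, a synthetic cropped frame (151 x 151
by default) places a single connected blob of exactly the requested pixel
count (the pixels nearest the center — an approximate disc) at a dark gray
level on a uniform background, with optional additive noise, together with
its matching background frame.

What the generator does *not* emulate: posture, omega turns and reversals
as discrete events, within-stage developmental trends in speed, tracking
dropouts, or arena-boundary effects. Passing the round-trip tests therefore
shows the pipeline is self-consistent under a plausible two-state model,
not that the classifier is optimal for real recordings.

## Worm size

A frame is normalized against a background estimate (the pixel-wise mean of
8 equally spaced frames) as $\tilde f = (f - b + 100)/256$, so background
pixels sit near $100/256 \approx 0.39$ and the darker worm falls below the
fixed threshold 0.34. The area is the number of pixels enclosed by the
single closed iso-contour at that threshold — exactly one connected dark
blob not touching the border; zero or multiple blobs, or a border-cut blob,
yield a missing value. Enclosed counting is interior-inclusive (holes are
filled; boundary pixels count). Area series are smoothed with a centered
301-frame running median (10 min at 3 fps) that ignores missing frames;
edges use truncated windows. Size-matched comparisons run over 20 windows
of width 10% of the pooled size range, centers evenly spaced over
$[\min + w/2, \max - w/2]$, comparing groups within each window by rank-sum
test with BH adjustment across windows.

The per-video background bookkeeping of multi-hour rigs (each video
normalized against the background of a later chunk) is deliberately out of
scope: `normalizeFrame()` takes an explicit background argument and callers
supply whichever estimate applies.

## Numerical choices and degenerate inputs

* Fractional ranks use midranks (`ties.method = "average"`); with all
  values equal every rank is $(n+1)/2$ and every bias 0.
* Eigenvalues are clipped at zero (rank-deficient bias matrices are legal;
  trailing components span the null space and explain nothing).
* The permutation p-value convention $(1 + m)/(1 + n)$ avoids zero
  p-values; exceedances, by contrast, may be exactly 0 and are reported as
  observed.
* Rank-sum tests fall back to $p = 1$ when the pooled values of a unit are
  constant.
* `detectStages()` fails loudly (an error naming the count of qualifying
  spans) when fewer than four quiescent spans exist; such individuals are
  excluded by callers, never patched.
* All Monte Carlo entry points take explicit integer seeds; per-individual
  and per-stage substreams are derived deterministically from the root
  seed, so regenerating any single individual reproduces its data.

## Validation problem sizes

The shipped test suite validates the machinery at sizes chosen to keep a
full run around half a minute: cohorts of 456 individuals for planted
three-dimension recovery (strengths 1.5, 1.0, 0.7, noise 1), 1000 for the
consistency/PC agreement bounds, 200 structure-free cohorts of 24
individuals with 100-replicate shuffle nulls for the exact calibration
check of the own-space significance test, and trajectory round-trips of
five 0.5 h stages separated by 0.5 h lethargus gaps at 3 fps (about 48,600
frames each). Stress-profile recovery uses 200 + 200 individuals at
moderate dispersion (strength 0.5, noise 0.5), where the fraction-scale
ratio estimator is accurate to a few percent.

## Known limitations

* The classifier's diagonal orientation and on-diagonal assignment are
  conventions; recordings whose roaming is slow but straight would need a
  different boundary.
* Angular velocity is computed from displacement headings, not body
  orientation; at very low speeds the heading is noise-dominated, which is
  why the zeroth speed bin is assigned to dwelling.
* The shuffle null preserves per-bin marginals but not within-individual
  autocorrelation under the alternative; it tests "no temporal structure",
  not "no individuality".
* The original-space shuffle comparison has no exact calibration guarantee;
  use the own-space mode when a calibrated test is needed.
* With very small experiments (n < ~10) the bias grid is coarse and score
  variances are noisy; the permutation test remains valid but has little
  power.
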