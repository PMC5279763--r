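---
title: "Quantifying balance from center-of-pressure trajectories"
author: "copbalance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying balance from center-of-pressure trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(copbalance)
```

## The problem

During dynamic balance exercises — here, game-like lateral weight shifting
on a force plate — the center of pressure (CoP) traces a planar path
$\gamma(t_i) = (ML(t_i), AP(t_i))$. Classical posturographic summaries
(whole-trial RMS, mean velocity, path length) collapse the entire trial into
one number and therefore cannot track balance *as it evolves*, which is what
an adaptive exergame or a real-time assessment needs. `copbalance`
implements a family of short-window measures that can be evaluated over a
fraction of a second, together with the statistical battery used to judge
which of them separate age groups.

## The measures

All measures derive from three per-sample primitives:

* **Fluctuation from the mean** $FM(t_i) = \lVert \gamma(t_i) - \bar\gamma
  \rVert$, the distance from the trial-mean position;
* **Instantaneous speed** $v(t_i) = \lVert \gamma(t_i) - \gamma(t_{i-1})
  \rVert / (t_i - t_{i-1})$, with $v(t_1) = 0$ by definition;
* **Discrete curvature** $\kappa(t_i) = 4\triangle_{abc} / (abc)$, the
  curvature of the circle through three consecutive samples, with the
  triangle area from Heron's formula.

A sliding window of $s = 2n + 1$ samples centered at $t_k$ then yields, for
$k = n+1, \dots, N-n$:

* $SD(t_k)$, $RMS(t_k)$, $CoV(t_k)$ — the local (population-form) standard
  deviation, root mean square and coefficient of variation of $FM$;
* $SD'(t_k) = SD(t_k)/d(t_k)$ and likewise $RMS'$, $CoV'$ — the same
  statistics divided by $d(t_k)$, the path length travelled inside the
  window, so that two movers with equal dispersion but different speeds are
  distinguished;
* $I(t_k)$ — the turbulence intensity, the local coefficient of variation of
  speed; and $I'(t_k)$, the variant normalized by the local mean of
  *squared* speed instead of the mean.

Each trial is summarized by the median of each series over its valid range,
plus the arithmetic mean of curvature ($\bar\kappa$) alongside its median —
the mean is kept deliberately because it, unlike the median, responds to
rare extreme samples. That gives eleven numbers per trial
(`SD, RMS, CoV, SDp, RMSp, CoVp, I, Ip, Speed, kappa_median, kappa_mean`).

### Index-range and formula conventions

Three typographic ambiguities in the source formulas had to be resolved;
the package's readings are:

* the backward-difference speed is computed for $i = 2, \dots, N$ (the
  difference is well defined at $i = N$; medians are insensitive to the one
  extra sample);
* $SD$, $RMS$ and $I$ numerators are root-mean quantities (the square root
  of the window average), consistent with their names, with the population
  divisor $1/s$;
* $d(t_k)$ sums the $2n$ segments lying fully inside the window
  ($i = k-n, \dots, k+n-1$), so every windowed measure shares one valid
  range $[n+1, N-n]$ with exactly $N - 2n$ defined samples.

Useful identities, asserted in the test suite: $RMS^2 = SD^2 + \bar{FM}^2$
at every valid index; translating the trajectory changes nothing (every
measure is either differential or referenced to the trial mean); scaling
coordinates by $a$ multiplies $Speed$, $SD$, $RMS$, $d$ by $a$, divides
$\kappa$ and $I'$ by $a$, and leaves $CoV$, $SD'$, $RMS'$, $I$ unchanged.
Note that $\kappa$ and $I'$ carry a unit (1/length): their magnitudes
depend on whether coordinates are in mm, cm or m, which is why the unit is
carried as trajectory metadata.

### Window size

The window must be shorter than half a sway cycle or transitions smear out.
With a maximum sway frequency of about 0.65 Hz, half a cycle is 0.77 s; the
default window is $n = 25$, $s = 51$ samples = 0.3 s at 170 Hz.
`compute_features()` warns when the configured window violates the
constraint.

## Preprocessing

Force plates deliver non-uniform sample times, so each trial is first
interpolated onto a uniform 170 Hz grid with a cubic spline through all
samples (anchored at the first timestamp — reproducible without knowledge of
the acquisition clock), then 6 s are trimmed from each end to drop setup and
wind-down movement; a 48 s trial leaves 36 s of analyzable signal. The
pipeline never smooths: an interpolating spline passes through its knots,
and no low-pass option is offered, because filtering removes exactly the
sample-scale irregularity that curvature and the turbulence measures
quantify. Out-of-plate outlier samples are *kept* for feature computation
(medians absorb them; the curvature mean deliberately does not) and are
excluded only from plots.

## The synthetic cohort

The only deposited data for this kind of study is a trial-by-measure
matrix; raw recordings are not public. The generator therefore produces
cohorts with the qualitative structure real recordings show, so every
downstream stage is testable without any download:

* **ML**: a tanh-smoothed square wave $A \tanh(\beta \sin(2\pi f t +
  \phi))/\tanh(\beta)$ — long dwells under each foot with fast transitions;
  the sharpness $\beta$ sets how square (fast, smooth) the transition is.
* **AP**: a smooth band-limited wander, a sum of eight random sinusoids in
  0.5–2.5 Hz. Smoothness matters: a differentiable wander adds sustained
  speed without adding sample-scale roughness.
* **Tremor**: small white jitter on both coordinates. At 170 Hz white
  position noise dominates the *discrete geometry* of the path: it adds
  roughly $300 \cdot sd$ cm/s of apparent speed and bends consecutive
  chords, so it controls curvature and $I'$, most strongly where motion is
  slow.
* **Sampling**: a 170 Hz grid plus zero-mean timestamp jitter kept strictly
  increasing; rare (< 0.05%) samples replaced by far out-of-plate outliers.

Per-participant amplitude and frequency are drawn once and shared across
that participant's trials. Default profiles (the study conditions; 20
participants per group, 10 trials of 48 s each):

| parameter | older | younger |
|---|---|---|
| amplitude mean ± sd (cm) | 8 ± 2 | 12 ± 2.5 |
| sway frequency mean ± sd (Hz) | 0.30 ± 0.06 | 0.45 ± 0.08 |
| transition sharpness β | 3 | 8 |
| tremor sd (cm) | 0.020 | 0.008 |
| AP wander sd (cm) | 0.4 | 1.5 |
| outlier probability | 2e-4 | 2e-4 |

The choices encode: younger movers sway wider, faster, with squarer
transitions and livelier smooth wander; older movers are slower and carry
*more broadband tremor relative to their speed*. The last point is the
subtle one. Because discrete curvature scales like
$8 \cdot \text{sagitta}/\text{chord}^2$, irregularity is relative: the same
tremor raises curvature far more when chords are short (slow movement).
An early model iteration that injected large white tremor into the older
group made them *faster* (noise speed swamps sway speed) and made the
smoother group's curvature *higher* (small chords, $\kappa \sim
1/\text{noise}$) — both directions backwards. The present parameters give
the empirically observed directions with wide margins: younger higher
median speed, lower median $\kappa$, lower median $I'$ (Mann–Whitney
$p \ll 0.01$ at 200 trials per group, stable across seeds).

What the generator does **not** emulate: condition-specific dynamics (the
five instructed task variants are emitted as labels only), postural
physiology (no inverted-pendulum model, no forces or moments), fatigue or
learning across trials, and the long-tailed participant heterogeneity of
real cohorts. Passing the direction-of-effect tests therefore shows the
*pipeline* recovers planted group structure — not that real older adults
behave like the model.

## Statistics

Measures are z-scored (pooled mean and sample SD) before all multivariate
work. For each measure, Shapiro–Wilk decides per group whether a Welch
t-test (unequal variances, fractional df) or a Mann–Whitney U test compares
the groups; Bonferroni multiplies raw p by the number of measures (11).
Distribution overlap is quantified by the overlapping coefficient
$OVL = \int \min(\hat f_1, \hat f_2)\,dx \in [0,1]$, computed from Gaussian
KDEs with Silverman bandwidths on a shared 512-point grid. The grid is
padded by 6 bandwidths: with shorter padding the truncated kernel tails
alone cost ~1e-5 of mass and identical samples would not score 1 to the
advertised 1e-6. Bandwidth, grid size and padding are exposed because OVL
values in the 0.6–0.85 range move by a few points under different KDE
settings.

PCA runs on the z-scored matrix (equivalently the correlation matrix of the
raw measures); component signs are fixed so each component's
largest-magnitude loading is positive; squared loadings × 100 give
per-variable percentage contributions (each component sums to 100, mean
reference 100/11 ≈ 9.09). Group confidence ellipses are normal-theory
ellipses with semi-axes $\sqrt{\lambda_j \chi^2_2(0.95)}$. Pairwise Pearson
correlations are reported together with the *computed* t-based critical
$|r|$ at the chosen alpha (≈ 0.098 at $n = 400$, $\alpha = 0.05$) — a fixed
printed threshold is never hard-coded.

## Worked example

```{r pipeline}
cfg <- cohort_config(n_participants_per_group = 5, trials_per_participant = 4,
                     trial_duration = 24, seed = 42)
cohort <- preprocess(generate_cohort(cfg))
features <- extract_features(cohort)
cmp <- compare_groups(features)
cmp
balance_pca(features)
```

```{r violins, fig.height = 5}
overlapping_violins(features, cmp)
```

```{r biplot}
pca_biplot(balance_pca(features))
```

## Numerical choices and degenerate inputs

* All denominators ($\bar{FM}_k$, $d$, $\mu$, $\mu'$, $\Delta t$) are
  guarded by a configurable epsilon (default 1e-12 in trajectory units);
  failures yield undefined samples, excluded from medians and means, never
  zeros or infinities.
* Coincident consecutive points give $\kappa = 0$ and are flagged; a
  negative Heron radicand from floating-point cancellation is clamped to 0.
  Heron's formula is used as written (no numerically stabilized variant); a
  circumcircle-fit oracle in the tests bounds its error at the scales the
  pipeline sees.
* Repeated timestamps raise an error naming the offending index rather than
  dividing by zero.
* Trials too short for the window are skipped with a warning during cohort
  extraction; single-trial functions raise errors instead.
* Test problem sizes: oracle sweeps use 100 trajectories of 60–140 samples;
  cohort-level checks use the full 400-trial design across 5 seeds;
  byte-determinism uses a 16-trial cohort (determinism is size-independent).

## Limitations

* The synthetic cohort is a phenomenological model; effect *sizes* on it
  are not calibrated to any real population, only effect directions.
* $\kappa$ and $I'$ magnitudes depend on the coordinate unit; comparisons
  across datasets require a consistent unit (the trajectory carries it as
  metadata).
* The Mann–Whitney route reports the U statistic without a distributional
  effect size; OVL fills that role here.
* No frequency-domain, entropy or recurrence measures are included — the
  scope is short-window geometry and dispersion.
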