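---
title: "Quantifying one-sided mating postures and bilateral asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying one-sided mating postures and bilateral asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matingasym)
library(dplyr)
```

## The scientific problem

Most animals with internal fertilisation mate with bilaterally symmetric
postures, and most genitalia are symmetric. In the cactophilic
*Drosophila nannoptera* species group, both rules break: *D. pachea*
males mate one-sidedly, riding the female abdomen shifted toward her
right, *D. nannoptera* males tilt strongly to the female's right during
copulation, and the intromittent organ (aedeagus/phallus) of *D. pachea*
and *D. acanthoptera* is strikingly left-right asymmetric. This package
implements a reusable pipeline for the comparative analysis behind such
observations:

1. **Timeline curation** — annotated behavioural events (courtship
   start, copulation start, settling, copulation end) are validated,
   converted to durations, and filtered by explicit exclusion reasons
   with exact accounting.
2. **Posture geometry** — signed mating angles are computed from three
   manually placed landmarks per video frame, in a dorsal (top) view
   (P1 female head tip, P2 female scutellum tip, P3 male head) or a
   frontal view (P4 female head dorsal edge, P5 proboscis, P6 male head
   dorsal edge), with two-point (Bookstein) registration for overlay
   displays.
3. **Posture statistics** — per-species directional contrasts against a
   zero (symmetric) mean angle, a copulation-duration ANOVA,
   repeatability of landmark placement, and per-minute interval
   summaries of the frontal tilt.
4. **Bilateral asymmetry** — a classifier separating directional
   asymmetry (consistent side bias, DA) from fluctuating asymmetry
   (random zero-mean deviations, FA) in paired left/right structure
   lengths.
5. **Character mapping** — small-parsimony (Fitch/Sankoff)
   reconstruction of discrete sexual characters on the group cladogram,
   including exhaustive enumeration of equally parsimonious
   gain/loss scenarios.
6. **Synthetic data** — a generator emulating the statistical structure
   of the original video recordings, so the full pipeline runs and is
   testable without any video material.

## The signed mating angle

All coordinates are pixel coordinates with the y axis pointing **down**,
the native convention of extracted video frames. In the top view, let
$u = P_2 - P_1$ be the female midline (head to scutellum) and
$v = P_3 - P_2$ the vector from the scutellum to the male head. The
canonical statistic is the *deviation angle*

$$\theta = -\operatorname{atan2}(u \times v,\; u \cdot v),$$

the signed deviation of the male head from the posterior extension of
the female midline. A male sitting directly behind the female scores
$0°$; the sign convention makes $\theta > 0$ mean "male on the female's
right" in both views (in the frontal view the female faces the camera,
so her right is the viewer's left; the identical formula applied to
$u = P_4 - P_5$, $v = P_6 - P_5$ yields that reading automatically).
Note this is the deviation from a straight-behind position (equivalently
$180°$ minus the interior landmark angle, signed): aligned couples score
near zero, which is the scale on which per-species distributions are
compared and displayed.

Two properties are load-bearing and are property-tested to $10^{-9}$
degrees: $\theta$ is invariant under any orientation-preserving
similarity transform of the landmark set (rotation, translation,
positive uniform scaling — i.e. under arbitrary camera pose), and it
flips sign under reflection. Because of the first property, the angle
can be measured before or after registration with identical results;
because of the second, left/right conclusions are meaningful. Oblique
(non-orthogonal) camera views bias the *magnitude* of the measured
angle in ways no planar statistic can undo; as in the underlying
experimental design, only the sign and the consistency of the per-species
distribution are treated as reliable.

Registration itself maps each frame by the unique orientation-preserving
similarity sending $P_1 \to (0,0)$ and $P_2 \to (0,1)$ (in complex
coordinates, $z \mapsto i\,(z - p_1)/(p_2 - p_1)$ — never a reflection).
Frames whose baseline $|P_1P_2|$ is shorter than 1 pixel are rejected
rather than warned about, since the rotation is then numerically
meaningless.

## Timeline rules

* A mounting event counts as a copulation start only when the male
  stays mounted at least **15 s** (inclusive at the boundary).
* Courtship runs from courtship start to copulation start; copulation
  to the male's complete descent. Durations are stored in seconds and
  reported in minutes; a missing event yields a missing duration, never
  zero.
* Postures are compared across species at the **settling time point**
  (first invariant posture of the mounted male) and the **10% stable
  copulation time point**, at 10% of the elapsed time between settling
  and copulation end. For species with mean copulation duration
  $> 2.5$, $> 15$ or $> 60$ minutes, a periodic grid at 2.5, 5 or 10
  minute steps is added. The thresholds are strict ($>$); the grid is
  anchored at the settling time point (the natural origin of the stable
  copulation period) and stops at copulation end; a grid point within
  1 s of the 10% point is dropped as a duplicate. When schedule times
  must be matched to discrete frame times, ties snap to the earlier
  frame.
* Exclusion reasons form a closed vocabulary; per-analysis usability is
  derived from it, and the accounting table satisfies the exact
  partition identity retained + discarded = total, with mixed-reason
  records tallied once under `multiple`.

## Statistical choices

**Directional angle test.** A one-way gaussian linear model without
intercept (`angle ~ species - 1`) is fitted to the per-experiment angles
at a fixed time point; each species mean is tested against zero with a
Wald $z$ statistic using the pooled residual sd, matching the standard
GLM-contrast machinery (the unit tests cross-check estimates, $z$ and
raw p-values against `glm()` + `multcomp::glht()`). p-values are
Bonferroni-corrected with an **explicit** family size (default in the
pipeline: $m = 10$, the ten species tested at one time point); the
family size is never inferred silently. $z$-based rather than $t$-based
p-values are used deliberately — the familywise type-I error under a
symmetric generator at the study sample sizes is verified by simulation
to stay below the nominal level.

**Repeatability.** Duplicate landmark acquisitions are analysed with a
single additive two-way fixed-effects fit `angle ~ image + replicate`,
each factor tested against the residual; placement is repeatable when
the replicate factor is negligible ($p > 0.05$). The layout must be
complete (every image measured once per acquisition round). Quoted
repeatability analyses of this design sometimes report per-factor
residual degrees of freedom that cannot arise from one additive fit
(they suggest two sequential one-factor fits); we do not guess at that
and expose both factor tests from the one well-defined additive model.
A factor whose sum of squares is zero relative to the total (below
$10^{-12}$ of it) gets $F = 0$ exactly, so that "replicate 2 identical
to replicate 1" behaves as expected even when the residual sum of
squares is itself numerically zero.

**Interval summary.** Frontal tilt angles are binned into one-minute
intervals after copulation start. Within an experiment, multiple
measurements in a bin are averaged *first*; the reported mean and sd
are across experiments, and the sd is missing (not zero) when a single
experiment contributes.

**DA/FA classifier.** Paired lengths give the signed difference
$L - R$ (µm) and the normalized index $2(L-R)/(L+R)$. Published
descriptions of such data are often qualitative ("consistently
longer"); we adopt an explicit, conservative rule: a **directional**
verdict requires *both* the exact two-sided binomial sign test on
non-tied signs *and* the two-sided one-sample $t$ test on the
differences to fall below $\alpha = 0.05$, with the majority sign
agreeing with the mean. Differences below 0.5 µm (measurement
resolution) are ties and leave the sign test. Fewer than five specimens
returns `insufficient`, because the two-sided sign test cannot reach
$p < 0.05$ below $n = 6$. Requiring both tests keeps the null
rejection rate well under $\alpha$ (verified over 2000 simulated null
datasets) while retaining essentially full power at a true index of
0.2 with sd 0.05 and $n = 10$.

**Parsimony.** Minimum change counts use the Sankoff dynamic program
with unit costs, which is exact on polytomies (the group cladogram is
deliberately usable either with the resolved topology or with the
*nannoptera*-group trichotomy). Leaves coded `nd` (not determined)
impose no constraint. The dynamic program is verified against a
brute-force enumeration of all internal labelings on hundreds of random
trees; `enumerate_scenarios()` exposes that enumeration to users so
that equally parsimonious histories (e.g. two independent gains of
right-sided mating vs a single gain followed by a loss) can be listed
explicitly. Gains and losses are not weighted differently — no
biological claim would support an asymmetric cost here.

## What the synthetic generator emulates — and what it does not

`simulate_study()` is a first-class module, not a test fixture. Its
defaults are the study conditions: per-species copulation and courtship
duration distributions (truncated normals within each species' observed
range — the true distributional shape is unknown, only mean, sd and
range being available, and truncation doubles as the $\ge 15$ s validity
rule), the per-species sample sizes of the duration analysis, and true
mean top-view angles of +21.4° (*D. pachea*), +32.5° (*D. nannoptera*)
and exactly 0° for the eight species concluded to mate symmetrically,
with a between-experiment sd of 12°. Setting the symmetric species to a
true zero (rather than to their small, non-significant fitted means)
makes the generator encode the study's conclusions, so that sidedness
classification — right-sided vs none — has a well-defined truth. Within an experiment,
posture persists over time: a random experiment-level intercept
(default sd 5°, a component of the 12°) induces the autocorrelation
visible when measurements of one couple are connected over time.
Landmarks are emitted for an ideal couple under a random camera pose —
rotation uniform on $[0, 2\pi)$, uniform scale on $[0.5, 2]$,
translation within an 800 × 600 pixel frame, matching the recording
resolution — with Gaussian per-replicate landmark noise (default 2 px).
With zero noise the measured angle reproduces the true angle to
numerical precision, which pins the whole geometry chain.
`simulate_frontal()` generates frontal-view trials whose true tilt
follows a per-minute trajectory (default: the *D. nannoptera*
rise-then-plateau trajectory), and `simulate_bilateral()` draws paired
lengths $L = b(1 + d/2)$, $R = b(1 - d/2)$ with
$d \sim N(\text{true index}, \text{sd})$, so the realized index equals
$d$ exactly.

The generator does **not** emulate: pixel images (landmarks are exact
up to Gaussian noise, whereas human placement error is
image-content-dependent), oblique-view magnitude bias (poses are planar
similarities, so simulated angles are unbiased — real camera obliquity
compresses magnitudes), behavioural sequences within courtship, or
correlations between exclusion reasons and species. Passing
parameter-recovery tests therefore demonstrates the correctness of the
statistical machinery under the stated model, not robustness to those
unmodelled features of real video data.

The canonical 315-trial exclusion structure
(`study_accounting_records()`) is a synthetic fixture reproducing the
published accounting exactly: 204 courtship discards
(4 + 43 + 27 + 129 + 1 mixed), 169 copulation discards
(4 + 7 + 27 + 129 + 2 mixed), 22 posture discards for invisible
landmarks and one further trial unusable at the 10% time point — giving
111, 146, 124 and 123 usable trials respectively.

## Numerical and testing choices

Test problem sizes are chosen to give tight Monte-Carlo error at
desk scale: 1000 random poses for the $10^{-9}$-degree invariance
bound; 200 random trees (≤ 6 leaves, ≤ 3 states) against the
brute-force parsimony oracle; 1000 replicates for the familywise
type-I error of the angle test; 200 independent synthetic studies for
the 2-standard-error recovery of the *D. nannoptera* mean angle
(+32.53° at $n = 21$), passed in well over 90% of seeds; 2000 null and
1000 alternative datasets for the DA/FA classifier. Blinding codes are
drawn without replacement from 1 000 000–9 999 999, guaranteeing seven
digits and injectivity; all stochastic components consume one explicit
seed and reproduce byte-identically.

## Known limitations

* Angle magnitudes from oblique views are biased toward zero; only
  signs and within-species consistency should be interpreted.
* Angles are treated linearly, not circularly — appropriate because
  observed postural deviations are far from ±180°, but wrong for
  hypothetical near-inverted postures.
* The DA/FA classifier tests only a location shift; shape asymmetry and
  size-corrected asymmetry are out of scope.
* Parsimony counts are minima under unit costs; they bound, but do not
  estimate, the number of evolutionary transitions.
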