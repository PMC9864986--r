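---
title: "Adaptive weighting and trust discounting for Dempster–Shafer multi-sensor fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive weighting and trust discounting for Dempster–Shafer multi-sensor fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsfusion)
```

## The problem

Wearable activity recognition fuses heterogeneous sensors — accelerometer,
gyroscope, heart rate — at the decision level. Each sensor's reading is turned
into a *basic probability assignment* (BPA) over the activity classes, and the
BPAs are combined with Dempster's rule. Two pathologies corrupt this scheme:

* **conflict** — one sensor points away from the consensus (its evidence has a
  large Jousselme distance to the others), and
* **fuzziness** — a sensor spreads its mass nearly uniformly because its
  class prototypes are close together, so it contributes little information.

The classical fixes reweight each evidence by a conflict score, a clarity
(inverse-fuzziness) score, their product, or their mean, then *discount* each
BPA toward an uninformative distribution before combining. All four naive
combinations share a failure mode: a sensor that is sharply wrong — high
clarity, high conflict — buys enough weight with its clarity to flip the fused
decision. `dsfusion` implements an adaptive weight that damps exactly this
case, plus the surrounding machinery and baselines needed to compare schemes.

## The model

Let $\Theta = \{\theta_1,\dots,\theta_n\}$ be the frame and
$m_1,\dots,m_N$ singleton-only BPAs from the $N$ sensors.

**Conflict.** The Jousselme distance
$d_J(m_i,m_j) = \sqrt{\tfrac12 (v_i-v_j)^\top D (v_i-v_j)}$ uses the Jaccard
matrix $D_{AB} = |A\cap B|/|A\cup B|$ over all non-empty subsets. Per-evidence
similarity is $\mathrm{Sim}(m_i) = \sum_{j\neq i} (1 - d_J(m_i, m_j))$, in
$[0, N-1]$, rescaled by default so the scores sum to $N-1$ (preserving
ratios); a mean normalization is available.

**Clarity.** Each evidence's distance to the uniform (maximum-entropy)
distribution $\mathrm{Unif} = (1/n,\dots,1/n)$. The default metric treats the
classes as unit-spaced points in frame order and computes the 1-D
Wasserstein-1 distance by the CDF closed form
$\sum_k |\sum_{l\le k}(m(\theta_l) - 1/n)|$; total-variation and Euclidean
alternates sit behind `clarity_metric`. Clarity scores are normalized to sum
to 1. Höhle and Deng entropies are provided as diagnostics but do not enter
the default weight.

**Adaptive weight.** With normalized scores $s_i$ and $c_i$,
$$W(m_i) = \tfrac12\left(s_i + c_i\, e^{-\left|c_i - s_i\right|}\right).$$
When clarity and similarity agree ($c_i = s_i$) the weight is just $s_i$;
when they disagree the exponential damps the clarity term, so sharp-but-wrong
evidence cannot dominate. An `amplifying` mode ($e^{+|c_i-s_i|}$) exists for
sensitivity analysis only.

**Trust discount.** Each BPA is reallocated toward indifference in proportion
to its distrust:
$$\mathrm{NewBpa}(\theta) = m(\theta)\,W + \frac{1-W}{c}\,(1 - m(\theta)).$$
With $c = n-1$ (the default) the output sums to exactly 1 with no
renormalization — an algebraic identity, since
$W + \frac{1-W}{n-1}(n-1) = 1$. The alternative `literal_two` mode fixes
$c = 2$ and renormalizes; because Dempster's rule cancels per-evidence scale
factors, the modes differ in reallocation shape only. Note that for $n = 2$
the discount at $W < 1/2$ moves mass past uniform toward the *complement* of
each hypothesis; this is the formula's stated behavior and is kept.

Discounted BPAs are combined pairwise by Dempster's rule and the fused argmax
is the decision (ties broken by frame order, with a warning).

## The pipeline and its tunables

| parameter | default | meaning |
|---|---|---|
| `weight_scheme` | `proposed` | adaptive weight; `ds` skips weighting, four baselines for comparison |
| `sim_normalization` | `sum` | similarity scores rescaled to sum to $N-1$ (unitless) |
| `clarity_metric` | `index_w1` | CDF-closed-form Wasserstein-1 on unit-spaced class indices (unitless) |
| `exponent_mode` | `damping` | exponential divides the clarity term |
| `divisor_mode` | `frame_minus_one` | self-normalizing discount divisor $c = n-1$ |

BPA generation from a scalar sensor reading uses inverse-distance
normalization against per-class prototype means:
$m(\theta_c) \propto 1/\max(|x - \mu_{s,c}|, 10^{-12})$. This choice (rather
than, say, a softmax of negative distances) reproduces the package's embedded
reference evidence rows from the prototype table to within one unit in the
third decimal, which is how it was selected. The $10^{-12}$ clip makes an
exact prototype hit yield essentially a point mass instead of dividing by
zero.

## Design choices where the design was open

* **Jousselme quadratic form.** The distance is computed on the *difference*
  of the mass vectors. Any reading that evaluates the form on the pair itself
  fails the identity-of-indiscernibles axiom, so the difference form is the
  only defensible one.
* **Which scores feed the weight.** Normalized similarity and clarity (both
  sub-unit) enter the weight; raw scores can exceed 1 and would break the
  $W \in [0,1]$ guarantee.
* **Discount divisor.** The literal divisor 2 yields an unnormalized BPA for
  $n \neq 3$; the $n-1$ divisor is self-normalizing and preserves the
  qualitative behavior, so it is the default and the literal mode is retained
  for fidelity.
* **Clarity ground metric.** No ground metric over categorical activity
  classes is canonical. Unit-spaced indices in frame order give a closed form
  and make clarity sensitive to *where* mass concentrates; total-variation
  and Euclidean alternates are one flag away, and for 2-class frames all
  three agree up to scale.
* **Interpretation bands.** Kappa is annotated with the conventional labels
  in steps of 0.2 ("slight" through "almost perfect"); values at or below 0
  are labeled "poor".

## Numerical conventions

Mass functions are validated to sum to 1 within $10^{-9}$; masses below
$10^{-15}$ after combination are pruned and the result renormalized. Total
conflict is declared at $k > 1 - 10^{-12}$ and raises a typed error rather
than returning an undefined division. Subsets are bitmasks over the ordered
frame (size cap 20); the dense Jaccard matrix is materialized only for frames
of size $\le 10$, with an identity fast path for singleton-only BPAs.

## What the synthetic generator does and does not emulate

`generate_dataset()` draws class-conditional Gaussian features around the
per-class prototype means — the simplest model consistent with
prototypes-as-means. Default noise levels (ACC 0.6 m/s², GYRO 0.25 rad/s,
BPM 6 beats/min) were chosen once: they keep within-class spread small
against most between-class separations while leaving the nearly degenerate
accelerometer prototypes of the sedentary activities (within 0.06 m/s² of
each other) heavily overlapping, which is precisely the conflict-and-fuzziness
regime the method targets. Heart-rate values are not rounded to integers.

The generator does **not** model temporal correlation, sensor drift, activity
transitions, or the feature-extraction step of a real deployment. A green
test on synthetic data therefore establishes that the *fusion mathematics*
behaves as specified — not that any particular accuracy will be achieved on a
real corpus. Accuracies on external datasets are explicitly outside the test
surface; the pipeline will consume any feature CSV of the right shape via
`cmd_fit()` / `cmd_evaluate()`.

`conflict_scenario()` generalizes the two-class counterexample: a majority
cluster peaking on one class with peak mass
$1 - \mathrm{fuzziness}\cdot(1 - 1/n)$ and one dissenter interpolated between
the majority BPA and a point mass on another class by the conflict level, so
zero conflict and zero fuzziness give identical, certain evidences.

## Known limitations

* The adaptive weight is *not* monotone in the conflict level of a dissenting
  evidence: a near-uniform dissenter is penalized through clarity, a sharp
  one through similarity, and the weight dips and recovers at the crossover.
  The test suite asserts the monotonicity that does hold (the dissenter's
  similarity score) and the end-to-end decision behavior, not a monotone
  weight.
* Trust discounting and clarity are defined for singleton-only BPAs, the
  pipeline regime; compound focal sets are supported by the mass/combination
  layer and the entropy diagnostics only.
* One scalar feature per sensor per window; multi-feature sensors are out of
  scope.
* Alternative combination rules (Yager, PCR) are out of scope.

## Worked example

```{r demo}
res <- classify(example_reading(), activity_prototypes(), fusion_config())
res
res$weights
```

The full comparison across schemes, including the two-class counterexample
where classical fusion and clarity-only weighting side with the sharp
dissenter while the adaptive weight restores the majority, is printed by
`cmd_demo_worked_example()`.
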