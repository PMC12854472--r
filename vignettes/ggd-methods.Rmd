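---
title: "Drift tests and retrospective selection gradients on a phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift tests and retrospective selection gradients on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggdrift)
```

## The question the package answers

Given a rooted phylogeny with branch lengths, specimen-level
measurements of p continuous traits for its tip taxa, and per-node
demographic parameters (effective population size Ne, divergence time,
generation length), `ggdrift` asks, branch by branch: *is the amount of
multivariate morphological change compatible with genetic drift alone?*
Where drift is rejected in the upper tail (too much change), it then
asks *what pattern of selection would have produced the change*, and
whether each trait moved because selection acted on it directly or
because it covaries with other selected traits.

## The drift test

For a branch from ancestor i to descendant j with trait mean vectors
$z_i, z_j$, the test statistic is the generalized genetic distance

$$\mathrm{GGD} = \frac{N_e}{t}\,(z_i - z_j)' W^{-1} (z_i - z_j),$$

a squared Mahalanobis distance $D^2$ scaled by effective population
size over generations since divergence ($t$ = divergence time /
generation length). Under neutral divergence of a multivariate trait
with additive-genetic covariance $G$, the between-lineage divergence
after $t$ generations is $(t/N_e)\,G$; standardizing the observed
difference by $W \approx G$ and scaling by $N_e/t$ therefore yields a
chi-square statistic with df = p. Small values indicate stabilizing
selection (less divergence than drift predicts), large values
directional selection.

Because a true $G$ is unattainable for museum samples, the pooled
within-group *phenotypic* covariance stands in for it (Cheverud's
conjecture), scaled by a heritability constant, default $h^2 = 0.4$
(the average reported for primate craniometric traits). The
substitution is conservative for the upper tail: assuming full
heritability would inflate GGD. Downstream, every $D^2$ and every
gradient scales exactly by $1/h^2$; with $h^2 = 0.4$ the GGD is 2.5
times its $h^2 = 1$ value.

### Rate regimes and the tail convention

`classify_rate()` cuts the GGD at chi-square quantiles
$\{q_{\alpha_2}, q_{\alpha_1}, q_{1-\alpha_1}, q_{1-\alpha_2}\}$,
defaults $\{0.001, 0.05, 0.95, 0.999\}$, giving five ordered labels:
`very_slow < slow < neutral < fast < very_fast`. "Two-tailed at the
95% and 99.9% levels" is ambiguous between this convention and
$\{\alpha/2, 1-\alpha/2\}$; the default is the $\{\alpha, 1-\alpha\}$
pair because, with df = 46, it reproduces the published shading of the
hominoid branch-rate table that this pipeline's report mirrors (e.g.
31.15 classifies *slow* against $q_{0.05}(46) = 31.44$ while 36.34 is
*neutral*; 59.82 *neutral* against $q_{0.95}(46) = 62.83$ while 69.79
is *fast*). The other convention is available via
`tail_convention = "alpha_half"`. Intervals are left-closed: a value
exactly at a lower quantile belongs to the faster side, which only
matters on sets of measure zero.

Reports also emit a `ggd_*_2dp` column computed from the
2-dp-rounded Ne/t, because published tables print rounded ratios and
the two products can differ in the second decimal.

## Ancestral state reconstruction

Each trait is reconstructed independently under single-rate Brownian
motion. For fixed tip values, maximizing the joint likelihood over all
internal-node values is equivalent to minimizing
$\sum_{\text{branches}} (\Delta z)^2 / v$ (branch length $v$), a
quadratic problem solved exactly as a linear system on the
$1/v$-weighted graph Laplacian: the internal block satisfies
$L_{II} \hat z_I = -L_{IT} z_T$. This equals the GLS reconstruction
and, as the unit suite verifies, agrees with both an independent
brute-force likelihood optimizer and `ape::ace(method = "ML")` on
small trees.

Confidence intervals use the conditional normal variance of each
internal node given the tips, $\sigma^2 [L_{II}^{-1}]_{aa}$, with
$\sigma^2$ the per-trait ML (not REML) Brownian rate estimated from
the tip covariance matrix. Two consequences worth knowing:

* Point estimates are convex combinations of tip means (they always
  lie inside the tip range) and are equivariant under adding a
  constant to all tips.
* Rescaling all branch lengths by a common factor changes *nothing*,
  CIs included: only the product $\sigma^2 v$ is identified, so the ML
  rate absorbs the rescaling. (A natural first guess is that CIs
  should widen; they do not.)

Zero-length branches are perturbed to $10^{-8} \times$ tree height
with a warning rather than failing. Internal nodes are reported in
preorder from the root, stable across runs. CIs are reported but point
estimates drive the GGD and gradient stages; propagating ancestral
uncertainty into those stages is a known limitation, flagged here
deliberately.

## The covariance matrix

Sex and taxon structure would inflate a naive covariance, so specimens
are centered on their (taxon x sex) cell means — identical to the
residuals of a MANOVA with sex and taxon (and their interaction) as
predictors, as the unit suite checks against `lm()`. The pooled
within-group matrix divides the residual cross-product by $N - g$
(unbiased; a divisor-$N$ switch exists, the source convention being
unstated). Samples below 40 pooled specimens trigger a warning, 40
being the conventional adequacy threshold for phenotypic-for-genetic
substitution.

The default pooling rule, `"descendants"`, pools the extant taxa
descending from each branch's ancestral node (the worked convention of
the source analysis: a branch inside one genus uses that genus's
specimens); `"all"` pools every taxon once, and an explicit per-node
taxon list can override either. Whether the original analysis pooled
the whole sample or the descendant clade for deep internal branches is
not recoverable from its text; both are supported and the default is
documented.

Inversion is exact while the condition number allows; below a
reciprocal-condition threshold of $10^{-10}$ a Moore–Penrose
pseudo-inverse is used with a warning and the condition number is
recorded in the run manifest. With p = 46 traits and pooled samples as
small as 61 this fallback is a practical necessity, not an edge case.

## Selection gradients

For a flagged branch, $\beta = W^{-1}(z_{desc} - z_{anc})$: the
descendant-minus-ancestor difference premultiplied by the inverse
covariance, i.e. the retrospective differential selection gradient.
Signs read as selection *for increase* (positive) or *decrease*
(negative).

Uncertainty comes from a specimen-level bootstrap: descendant
specimens are resampled with replacement, the taxon mean and gradient
recomputed B times (default 1000), and per-trait 95% percentile
intervals taken. The ancestral estimate is held fixed — it is a model
quantity, not a sample — so the CI reflects descendant sampling error
only; that is the simplest design consistent with "resampled vectors
of trait means", and the one implemented. Percentile (not BCa)
intervals are used for the same reason. Resampling is deterministic
given a seed and leaves the global RNG stream untouched.

Each trait is then classified:

* `none` if the CI contains zero (negligible gradient);
* `direct_increase` / `direct_decrease` if the gradient is significant
  and the realized response has the same sign;
* `indirect` if significant but opposed in sign — the trait's change
  is then a correlated response to selection on traits it covaries
  with, the "spandrel" pattern. An exactly zero response with a
  significant gradient is classified `indirect`; it cannot arise from
  continuous data and is flagged if constructed.

Responses are reported as percent change. The default scale is
*geometric*: for logged traits,
$100\,(e^{z_{desc}} - e^{z_{anc}})/e^{z_{anc}}$, a ratio statement
about the raw measurement. The alternative `"logged"` scale
($100\,\Delta z / z_{anc}$) is also emitted; it is undefined at
$z_{anc}=0$ and less interpretable, but published tables do not state
which was used, so both are available.

## The synthetic world

`simulation_scenario()` states a world in which every stage has known
truth. Defaults, chosen once: a balanced 8-tip tree, p = 6 traits,
compound-symmetric phenotypic covariance (variance 1, covariance 0.3
— trait integration without near-singularity), $h^2 = 0.4$ matching
the analysis default, 50 specimens per taxon (a realistic museum-series
size that keeps covariance estimates stable), and Ne = 10 000,
divergence 250 000 years, generation length 25 years at every node, so
Ne/t = 1 and nothing hides behind the demographic scaling.

Drift increments per branch are drawn from
$\mathcal{N}(0, (t/N_e)\,G)$ — the keystone consistency choice: with
the true $W = G$ and true Ne/t, the GGD of a neutral branch is
chi-square(p) *by construction*, which is exactly the null the test
assumes. The calibration experiment verifies the two-sided rejection
rate at $\alpha = 0.05$ per tail (nominal 0.10) and a
Kolmogorov–Smirnov match to chi-square(6). Branch lengths enter only
the reconstruction weights; drift variance is parameter-driven, so the
simulator can hold variance fixed while varying reconstruction
geometry.

Directional selection is injected on one branch as a deterministic
shift $c\,G\,\beta^*$ — the expected response to an aggregate gradient
$c\,\beta^*$ under the breeder's equation. The strong-signal setting
uses $c = 6$, fixed a priori from the expected-GGD algebra
($\mathbb{E}[\mathrm{GGD}] \approx p + c^2 \beta^{*\prime} G \beta^*
\approx 89$ against $q_{0.999}(6) = 22.5$), not tuned after running.

Specimen simulation adds multivariate-normal noise with covariance
$P$ around tip means, assigns half of each taxon to each sex, and can
add a sex effect to one sex; the suite verifies that the MANOVA-residual
covariance removes it while the naive covariance inflates.

### What the estimation pipeline does to the signal

Two systematic effects, both visible in the experiments and worth
understanding before reading results:

* *Attenuation*: the reconstructed ancestor of a shifted tip is pulled
  toward that tip, shrinking the estimated branch change. Tip-branch
  GGD from the full estimation pipeline is therefore *deflated*
  relative to truth (the estimated-W calibration variant records
  this; it is reported, not asserted), and weak selection signals
  lose power.
* *Leakage*: the same pull displaces the shared ancestor relative to
  the *sister* lineage, so a strongly selected tip can drag its sister
  branch over the fast threshold on a balanced tree. The end-to-end
  fixture that asserts "exactly the selected branch is flagged"
  therefore places the selected tip on a long terminal branch, where
  the ancestor is dominated by the unshifted taxa; with the balanced
  default tree the acceptance criterion asserts only that the *true*
  branch is flagged.

A green synthetic suite therefore establishes internal consistency of
the statistics and the estimation machinery under the stated world. It
does not establish robustness to what real specimen data add: unequal
and small per-taxon samples, measurement error, covariance structure
that differs across taxa (the conserved-covariance assumption), p
comparable to n (hence the pseudo-inverse fallback), or
misspecified Ne and generation times.

### Bootstrap coverage design

Coverage of a "true zero gradient" is only well defined when the
ancestor used in the gradient is the descendant's true mean; drift
alone would otherwise displace the two and the CI, which reflects
specimen sampling only, would correctly *not* cover zero. The coverage
experiment therefore holds the ancestor at the known truth and centers
the descendant on it, isolating the bootstrap's claim. Percentile
intervals at n = 50 run slightly anti-conservative (~94% observed),
as expected.

## Pipeline orchestration

`run_pipeline()` runs read/validate, tip means, ancestral
reconstruction, covariance, rates, gradients — in that order, failing
with the stage name on error. Gradients are computed only for branches
whose *mean*-Ne/t regime is `fast` or `very_fast` (the workflow's
gate), with `all_branches = TRUE` as override; each gradient block is
annotated with whether the lower- and upper-bound regimes agree, since
conclusions that hold only under the mean and upper Ne bounds deserve
the caveat. Flagged branches ending in an internal node have no
specimens to resample and are listed in the manifest instead of being
bootstrapped. Reruns with identical inputs and seed produce
byte-identical outputs; the manifest records input hashes, settings,
seed, package version, timings and all warnings.

## Numerical choices, collected

| Choice | Value | Why |
|---|---|---|
| Log base for traits | natural | convention; base-10 switch for sensitivity |
| Chi-square tail convention | $\{\alpha, 1-\alpha\}$ | reproduces the published shading; `alpha_half` available |
| Covariance divisor | $N - g$ | unbiased pooled-within; `"n"` switch |
| Small-sample warning | $N < 40$ | substitution adequacy threshold |
| Pseudo-inverse rcond | $10^{-10}$ | p close to n in realistic data |
| Zero-length branches | $+10^{-8}\times$ height | proceed with warning, not fail |
| Bootstrap CI | percentile, B = 1000 | simplest consistent with the stated 95% CIs |
| Response scale | geometric | ratio statement for logged traits; logged also emitted |
| Heritability | 0.4 | reported primate craniometric average; conservative upward |
| Strong-signal shift | $c = 6$ | fixed a priori from expected-GGD algebra |

## Known limitations

Single-rate univariate Brownian motion only (no OU, no branch-specific
rates, no fossil constraints); ancestral CIs not propagated into GGD
or gradients; the conserved-covariance assumption is taken, not
tested; tree inference is out of scope (the tree is an input); and
published per-trait gradient values for the hominoid dataset require
the raw specimen data, which this package does not ship — it computes
the analogous tables from any conforming input.
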