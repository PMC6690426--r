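---
title: "Exact permutation log-rank tests: model, schemes and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact permutation log-rank tests: model, schemes and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permlogrank)
```

## The model and its assumptions

The data are per-patient triples $(t_i, \delta_i, g_i)$: a non-negative
follow-up time, an event indicator ($\delta_i = 1$ if the event was
observed, $0$ if the patient was right-censored at $t_i$), and one of $K
\ge 2$ group labels. The null hypothesis is that all $K$ groups share the
same survival function. The test is rank-based: only the ordering of
times matters (the statistic is invariant under strictly increasing time
transforms), and the package assumes non-informative right censoring.
Left truncation, interval censoring and competing risks are out of scope.

At each distinct event time the test conditions on the at-risk
configuration: with $d_i$ events among $n_i$ at risk ($d_{ij}$, $n_{ij}$
in group $j$),

$$O_j = \sum_i d_{ij}, \qquad E_j = \sum_i d_i\,n_{ij}/n_i,$$

$$V_{jl} = \sum_i \frac{d_i\,(n_i - d_i)}{n_i - 1}\,
   \frac{n_{ij}}{n_i}\Bigl(\delta_{jl} - \frac{n_{il}}{n_i}\Bigr),$$

the hypergeometric variance with the ties correction
$(n_i - d_i)/(n_i - 1)$; a time with $n_i = 1$ contributes zero. The
statistic is $T = z^\top \hat V^{-1} z$ with $z = O - E$ and $\hat V$
restricted to the first $K - 1$ groups, and the asymptotic p-value (AP)
is the upper chi-square tail on $K - 1$ degrees of freedom.

**Tie convention.** At a tied time, events are ranked before censorings:
a patient censored exactly at an event time is still at risk there. This
is the convention of all mainstream implementations (the test suite
cross-checks `survival::survdiff` on tied data to $10^{-8}$), and the
package's risk tables, Kaplan–Meier curves and permutation schemes all
share it. Time zero is allowed and enters the first risk set rather than
being silently dropped.

**Degenerate covariance.** When $\hat V$ is rank-deficient (typically a
group whose entire at-risk period misses every event time), the package
uses the Moore–Penrose pseudo-inverse, reports the rank as the degrees of
freedom, and warns. It does not try to guess what any particular other
tool would do in this corner; the behaviour is documented and
deterministic, and a silent failure inside a permutation loop is the
outcome being avoided. The degrees of freedom otherwise stay $K - 1$
based on the group count of the dataset, whether or not every group
experienced events.

## The exact p-value

The permutation p-value replaces the chi-square reference with the
permutation distribution of $T$. With $b$ of $B$ resampled statistics at
least as large as the observed one (floating-point ties count as
extreme, the conservative choice), the estimator is the add-one form

$$EP = \frac{b + 1}{B + 1},$$

which can never report zero and yields a valid test at any $B$. The
attached 95% interval is Clopper–Pearson on the exceedance probability;
exact binomial intervals are the natural choice for a tail proportion
estimated from few exceedances, where normal approximations fail in
precisely the cases of interest.

Two resampling schemes are provided.

**Label permutation** permutes the group labels across patients. It is
exact when censoring is identically distributed across groups, which
covers the clustering-evaluation use case (a partition independent of
survival is tested against fixed survival data).

**Follow-up-conditioned permutation** (after Heinze and co-workers)
handles unequal censoring between groups by conditioning on each group's
observed follow-up structure. One imputation draws, for every censored
patient, a latent event time from the pooled Kaplan–Meier estimate
$\hat S$ conditional on exceeding the observed time, and for every event
patient a latent follow-up time from the pooled reverse Kaplan–Meier
estimate $\hat G$ conditional on being at least the observed time. Each
resample then permutes the latent event times across patient slots while
every slot keeps its group label and latent follow-up time, and
re-censors (observed time = min, event flag = "event first"). The
multiset of follow-up times within each group is therefore identical in
every resample. With no censored observations the scheme collapses to
plain label permutation.

Design choices in this scheme that were genuinely open:

* **Kaplan–Meier tail.** When the largest observation is censored,
  $\hat S$ retains mass; that mass is placed at the largest observed
  time — the simplest proper distribution. The choice is isolated in one
  helper so that, e.g., an exponential tail could be substituted. The
  same rule applies to $\hat G$.
* **Imputation count.** The default is $M = 10$ independent imputations.
  Rather than averaging the $M$ per-imputation add-one estimators, the
  package pools the exceedance counts over all $M \times B$ resamples and
  reports $EP = (b + 1)/(MB + 1)$; the two differ by $O(1/B)$ and pooling
  preserves both the add-one validity guarantee and the invariant
  $EP = (b+1)/(B+1)$ with $B$ the total resample count, which every
  output object satisfies exactly.
* **Degenerate inputs.** A resample with zero events yields $T = 0$ (no
  information, never counted as extreme unless $T_{obs} = 0$); a dataset
  with no censoring makes $\hat G$ degenerate at the largest time, which
  is exactly the label-permutation limit.

For small samples `logrank_enumeration()` evaluates every distinct
assignment of the observed group sizes (multiset permutations, not all
$n!$ orderings) and returns the exact tail proportion; it is the gold
standard the sampled EP is tested against, capped by default at $10^6$
assignments.

## The synthetic generator and what it emulates

`generate_dataset()` draws latent event times from per-group exponential
distributions and latent censoring times from a per-group model (none,
exponential, uniform, or administrative cutoff); the observation is the
minimum, with the event winning exact ties. Exponential event times were
chosen because every summary is checkable in closed form (mean
$1/\lambda$, censoring fraction $\lambda_c/(\lambda_e + \lambda_c)$
under exponential censoring); a Weibull hook would be the natural
extension. Equal hazards define the null.

The generator emulates the *structure* that drives the chi-square
approximation's failure — group sizes, event counts, censoring imbalance
— but not features of real cohorts such as non-proportional hazards,
cured fractions, covariate-dependent censoring or batch effects in
follow-up. Passing calibration tests on these data therefore shows that
the implementation is correct and that the inflation phenomenon is real
in the stated regimes; it does not certify behaviour on any particular
real cohort.

## Calibration diagnostics

Three reusable procedures quantify when the AP misleads:

* `type1_error()` — rejection fraction at level $\alpha$ over simulated
  null replicates, for AP, label-EP or conditional-EP, with exact
  binomial intervals. Tolerances throughout the package are expressed in
  multiples of the Monte Carlo standard error, so checks are invariant
  to the replicate count.
* `ap_null_distribution()` — the APs of uniformly permuted labels of one
  solution on one cohort; under the null this should be Uniform(0, 1),
  and the fraction $\le \alpha$ measures anti-conservatism. Setting
  $\alpha$ to an observed AP turns the same primitive into the
  "fraction of permutations at least as significant" diagnostic for a
  reported p-value.
* `fpr_curve()` — for each $k$, random partitions into $k - 1$ clusters
  of fixed small size (default 10) plus one large cluster, and the
  fraction declared significant. For the AP this fraction rises well
  above $\alpha$ as $k$ grows; an exact test stays at or below $\alpha$
  up to Monte Carlo noise.

## Problem sizes used by the shipped checks

The package's own test suite and `scripts/acceptance.R` run at sizes
chosen to give stable Monte Carlo estimates while keeping a desk run
short: 2,000 null replicates for the valid-regime calibration (two
balanced groups of 200, exponential censoring leaving about two-thirds
events); 1,000 replicates for the AP arm and 400 for the conditional-EP
arm ($B = 199$, $M = 2$) of the unequal-follow-up scenario; 2,000 random
partitions per $k$ for the AP false-positive curve on a 621-patient null
cohort and 100 partitions for the conditional-EP spot check at $k = 20$;
50 datasets of $n \le 8$ for the enumeration-agreement check at
$B = 20{,}000$. The unequal-follow-up scenario itself — a small fully
followed group (5 patients, administrative cutoff 3) against a large
early-truncated group (200 patients, cutoff 0.02), equal unit hazards —
was fixed a priori as a realistic caricature of comparing a small
long-followed cohort with a large recent one; it concentrates the two
drivers of the approximation's failure, few events and imbalance, in one
design.

```{r example}
d <- generate_dataset(scenario_config(c(150, 150),
        censoring = censoring_model("exponential", rate = 0.33)),
      seed = 99)
labels <- random_clustering_labels(d$n, k = 4, small_size = 10)
logrank_permutation_test(
  survival_dataset(d$time, d$event, labels), B = 999, seed = 1)
```

## Known limitations

* Weighted log-rank variants (Fleming–Harrington, Wilcoxon), trend and
  stratified tests are not implemented.
* The exact p-value is estimated by sampling, not by the network
  algorithm; for very small tail probabilities the cost grows as $1/p$.
* The conditional scheme's imputation follows the published Heinze-style
  construction for two or more groups; other multi-group extensions of
  the follow-up-conditioned idea exist and are not reproduced here.
* Power is low when survival curves cross, and the multi-group null is
  rejected when any single group deviates — both reasons to always
  inspect the Kaplan–Meier curves (`plot_km()`) alongside any p-value,
  exact or asymptotic.
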