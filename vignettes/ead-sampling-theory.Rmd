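---
title: "Sampling theory for phylogenetic diversity via the edge-length abundance distribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling theory for phylogenetic diversity via the edge-length abundance distribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eadiv)
```

## The model

A metacommunity is a rooted phylogenetic tree whose tips are *individuals*
(e.g. individual 16S reads), and a local community is a random subset of
those tips.  Write $l_e$ for the length of edge $e$ and $n_e$ for the
number of tips descended through it.  The package's central object is the
**edge-length abundance distribution**

$$L(n) \;=\; \sum_{e:\, n_e = n} l_e,$$

the phylogenetic analogue of a species abundance distribution: it answers
"how much branch length is carried by rare clades versus common clades?"
while forgetting everything else about the topology.

A *sampling scheme* enters only through its presence probability
$P(n)$ — the chance that at least one of a clade's $n$ tips is sampled:

* **binomial**, intensity $p \in [0,1]$ (probability each individual is
  sampled): $P(n) = 1-(1-p)^n$;
* **poisson**, intensity $p \ge 0$ (mean count per tip, sampling with
  replacement): $P(n) = 1-e^{-pn}$;
* **negbinom**, intensity $p \ge 0$ and clustering $\varepsilon$:
  $P(n) = 1-(1+\varepsilon p n)^{-1/\varepsilon}$.

The negative-binomial scheme has a concrete generative story used
throughout the package: a single community-wide factor
$g \sim \mathrm{Gamma}(\text{mean}=1, \text{var}=\varepsilon)$ multiplies
every tip's Poisson intensity.  Conditional on $g$ tips are independent;
marginally, nearby tips co-occur.  $\varepsilon \to 0$ recovers Poisson;
$\varepsilon < 0$ (overdispersed, more even sampling than random) is an
analytic continuation valid while $1+\varepsilon p n > 0$ for every class
in use — `presence_probability()` raises a domain error otherwise, naming
the offending class.

Because every edge is present in the sampled subtree exactly when its
clade is represented,

$$\mathbb{E}[\mathrm{PD}] = \sum_n L(n)\,P(n),$$

and analogous sums give the expected shared and union branch length of
two independent samples and hence an expected UniFrac.  This is the whole
trick: one pass over the tree to get $L(n)$, then every scheme, intensity
and sample size is a cheap sum.

### The rooted PD convention

`induced_pd()` counts every edge with at least one sampled descendant,
which connects the sample to the root.  This convention is forced by the
expectation formula above, which sums over *all* edges; software using
the MRCA-spanning (unrooted) convention will report smaller PD for small
samples, and comparisons should account for that.  The root edge is an
ordinary edge of abundance class $N$; when the newick supplies no root
edge its length is 0, so the convention costs nothing on such trees.

### Variance of sampled PD

With $I_e$ the presence indicator of edge $e$,

$$\mathrm{Var}(\mathrm{PD}) = \sum_e l_e^2 P_e(1-P_e)
 \;+\; 2\!\!\sum_{a \prec d}\! l_a l_d\,\mathrm{Cov}(I_a, I_d)
 \;+\; 2\!\!\sum_{a \parallel d}\! l_a l_d\,\mathrm{Cov}(I_a, I_d),$$

split over nested pairs ($a$ a strict ancestor of $d$) and disjoint pairs.
Descendant presence implies ancestor presence in *any* scheme, so for
nested pairs $\mathrm{Cov} = P_d(1-P_a)$ exactly.  Under binomial and
Poisson sampling tips are independent and disjoint edges are
uncorrelated, and the nested sum is accumulated in a single post-order
pass ($O(\text{edges})$).  Under the negative-binomial scheme the shared
gamma factor correlates disjoint edges too:
by inclusion–exclusion, with $q(n) = (1+\varepsilon p n)^{-1/\varepsilon}$
the absence probability,
$\mathrm{Cov}(I_a,I_d) = q(n_a{+}n_d) - q(n_a)q(n_d)$ for disjoint pairs
(their clades are disjoint, so absences multiply conditional on $g$).
That term is aggregated over abundance-class pairs, not edge pairs, so
the cost stays modest; nested pairs are then corrected by an
ancestor-chain walk.  Omitting the disjoint term is not a small error —
for clustered sampling the between-clade correlation dominates the
variance on trees of a few hundred tips, which the Monte-Carlo agreement
tests would immediately expose.

Degenerate cases behave as they must: $p=0$ and binomial $p=1$ give zero
variance; for $\varepsilon<0$, $q$ is continued by 0 where its base hits
zero (absence impossible), which is exact for
$\varepsilon = -1/m$, $m$ integer, where the scheme coincides with $m$
multinomial draws.  For $\varepsilon<0$ there is no generative sampler in
the package (`draw_sample()` refuses), so that branch of the variance is
validated against an independently derived pairwise-covariance oracle
rather than simulation — a documented limitation.

### Matching a null to an observed sample

To place an observed community with $T$ distinct tips on a theory curve,
`solve_intensity()` inverts the expected number of distinct tips
$\mathbb{E}[T] = N\,P(1)$ — the only quantity that is both observable and
analytic in all three families (moment matching).  All three inversions
are closed forms (binomial $p = T/N$; poisson $p = -\log(1-T/N)$;
negbinom $p = ((1-T/N)^{-\varepsilon}-1)/\varepsilon$), so no iterative
root-finding is involved; Poisson and negbinom cannot reach $T=N$ at
finite intensity and say so.  `classify_sample()` then labels the sample
by a two-sided band $\mathbb{E}[\mathrm{PD}] \pm z_{1-\alpha/2}\,\sigma$
(normal approximation; a distribution-free Chebyshev band
$\pm\sigma/\sqrt{\alpha}$ is available via `conf = "chebyshev"` when the
normal approximation is in doubt, at the price of power).  The normal
band's calibration is itself tested: random binomial samples from a
300-tip simulated metacommunity are labeled `random` in well over 90% of
200 seeded replicates.

### Expected UniFrac and unequal sample sizes

`expected_unifrac()` is the *ratio of expectations*
$1 - \mathbb{E}[\text{shared}]/\mathbb{E}[\text{union}]$, not the
expectation of the per-pair ratio.  The two differ by a Jensen-type bias;
`mc_beta()` reports both (`unifrac_of_means` vs `mean_unifrac`) so the
bias is measurable rather than hidden.  The practical use is
normalization: an observed UniFrac between samples of different sizes is
divided by the expected UniFrac of two random samples of exactly those
sizes (`normalize_unifrac()`), avoiding the common workaround of
rarefying every community down to the smallest one.

## Octave binning and power-law fitting

`bin_ead()` groups abundance classes into half-open Preston octaves
$[2^k, 2^{k+1})$ — half-open so boundary classes are never double
counted; bins jointly cover $[1, N]$.  `fit_power_law()` runs ordinary
least squares on the log-log binned distribution and negates the slope.

One choice here matters and is easy to get silently wrong.  On a *tree*,
the number of edges with $n$ descendants falls roughly like $n^{-2}$, so
octaves at large $n$ contain only a handful of occupied classes; raw
octave mass (or mass per unit bin width) then under-represents those
octaves and biases the exponent upward by a large margin.  The default
therefore regresses **mass per occupied abundance class**, which is an
unbiased estimate of the mean $L(n)$ in the bin whatever the occupancy;
`normalize = "width"` and `"none"` are provided for compatibility with
other plotting conventions, and the regression abscissa (lower bin edge
vs geometric midpoint) is likewise a documented option.  At least three
positive bins are required; fewer is an error, not a silent fit.

## Synthetic generators: what they emulate

* `fixture_tree()` — the four-tip worked example
  `((A:1,B:2):2,(C:1,D:1):1);`, chosen so that every closed form in the
  package can be recomputed by hand (its EAD is $\{1\!:5,\ 2\!:3,\ 4\!:0\}$
  and it contains a length-2 edge with exactly two descendant tips).  It
  is a pedagogical stand-in, not a tree from any empirical dataset.
* `yule_tree()` — pure-birth topology with i.i.d. exponential branch
  lengths (mean `length_scale`, default 1).  Used as a neutral topology
  for property tests; real microbiome trees are *not* Yule (their EADs
  are closer to power laws, their branch lengths are correlated with
  depth), so passing tests on Yule trees demonstrates correctness of the
  algebra, not realism of the null.
* `powerlaw_tree()` — random coalescent-style merge topology whose edge
  lengths are assigned per abundance class so the EAD equals
  $L(n) = \text{scale}\cdot n^{-\alpha}$ *exactly* on occupied classes
  (the root edge is the lone class-$N$ member).  Exactness makes
  downstream round-trip tests sharp: any exponent-recovery error is
  attributable to binning and occupancy, not generator noise.  What this
  generator does not emulate: real trees' correlation between clade size
  and edge length within a class, and any deviation from power law.

All generators are seeded and bit-reproducible; the Monte-Carlo engine
draws replicates as one vectorized block under a single `set.seed`
stream (restored on exit), so a summary is a pure function of
(tree, scheme, reps, seed).

## Numerical choices

* Presence/absence probabilities use `log1p`/`expm1` throughout, so
  $p \to 1$, tiny $\varepsilon$ (the Poisson limit is met to $10^{-6}$
  relative at $\varepsilon = 10^{-8}$ over $n$ up to $10^3$) and large
  $n$ do not lose precision.
* EAD conservation ($\sum_n L(n)$ = total branch length) holds to
  floating-point roundoff; tests assert $10^{-9}$ relative and observe
  $\sim 10^{-16}$.
* Analytic mean and variance agree with exhaustive $2^N$ enumeration to
  $10^{-12}$ absolute on trees of up to 8 tips.
* Missing branch lengths parse to 0 with a warning; negative lengths are
  an error; zero-length edges and multifurcations (including basal ones)
  pass through untouched, as FastTree-style trees require.
* Average-linkage clustering of distance matrices sorts labels
  lexicographically before linkage, so equal-distance merges resolve
  deterministically to the smallest label pair.
* Degenerate nulls (sd = 0, e.g. a full binomial sample) label `random`
  when observed equals expected and warn otherwise.

## Problem sizes used by the test-suite

The suite validates at sizes where every oracle is exact or its Monte
Carlo error is well below the effect being measured: exhaustive
enumeration up to $2^8$ outcomes × 100 trees; conservation over 1000
Yule trees of 50–500 tips; $10^4$-replicate Monte Carlo on a 100-tip
tree (3-standard-error agreement bands); confidence-band calibration
with 200 replicates on a 300-tip metacommunity; exponent recovery on
1024-tip power-law trees for $\alpha \in \{0.8, 1.0, 1.2\}$ (within
0.15).  Theory curves use a power-law EAD with $\alpha = 1.05$ and
$n_{\max} = 2^{12}$: the exponent is set slightly above 1 because at
$\alpha = 1$ exactly the expected-PD curve carries a logarithmic
correction and is not a clean power law in sample size; just above 1 the
log–log curve is linear to $R^2 > 0.99$ across two decades, and
clustered (negbinom, $\varepsilon \in \{0.5, 2\}$) curves lie at or
below the Poisson curve at every matched sample size.

## Known limitations

* Fixed-size sampling (hypergeometric/multinomial conditioning on the
  exact number of reads) is not implemented; sample size is matched in
  expectation only.
* Overdispersed ($\varepsilon < 0$) schemes have no sampler, only
  analytics.
* `fit_power_law()` is OLS on binned data, deliberately mirroring how
  such plots are usually made; it is not a maximum-likelihood power-law
  estimator and inherits the usual small-sample biases of binned fits.
* Expected UniFrac is a ratio of expectations; for very small samples
  the per-pair ratio's mean can differ noticeably (use `mc_beta()` to
  quantify).
* Weighted UniFrac, ordination, and trait-based null models are out of
  scope.
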