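---
title: "Methods: comparing isolated plant populations with isopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing isolated plant populations with isopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`isopop` implements the complete statistical workflow of a two-region
comparative study of isolated plant populations: dominant-marker
genetic diversity and differentiation, isolation by distance, Bayesian
comparison of population traits between regions, a hierarchical model
of seed-germination trials, and a correlation screen linking
population structure, reproduction and genetic variation.  This
vignette is the package's account of the underlying models, the
choices that were genuinely open, and what the bundled simulations can
and cannot show about real data.

## The data model

The genetic input is a binary individuals-by-loci matrix of dominant
marker scores (AFLP-style band presence/absence), with each individual
assigned to a population and each population to a region.  Version 1
deliberately rejects missing genotype codes: in dominant-marker
practice, samples without a clean banding pattern are rescored or
excluded before analysis, and a silent missing-data policy tends to
hide scoring problems.  Scoring reproducibility is summarised by
`genotyping_error_rate()`, defined as discordant calls divided by
(pairs x loci).  Discordance could alternatively be normalised per
reproducible band; the pair-locus denominator was chosen because it
needs no phenotype-frequency bookkeeping and is the stricter of the
two (it counts concordant absent-absent calls in the denominator),
and it is flagged here because published error rates do not always
state which normalisation they use.

## Diversity statistics for dominant markers

Within a population, each locus contributes through its band frequency
$f$.  Because dominant markers hide heterozygotes, allele frequencies
must be estimated; the default is the Hardy-Weinberg square-root
estimator $q = \sqrt{1 - f}$, $p = 1 - q$ (the convention of the
classic dominant-marker software), with a band-as-allele alternative
($p = f$) available for sensitivity analysis.  From $(p, q)$ the
package reports, averaged over loci:

* Nei's gene diversity $H_e = 1 - p^2 - q^2$,
* Shannon's information index $I = -(p \ln p + q \ln q)$,
* the percentage of polymorphic loci (band frequency strictly between
  0 and 1; no rare-allele cutoff is applied, since none is standard
  for within-population dominant data).

The Shannon index is implemented with its conventional positive sign;
the literal expression $\sum p_i \ln p_i$ sometimes printed in methods
sections is negative-valued and cannot match tabulated positive
values.  The percentage of polymorphic loci is independent of the
allele-frequency estimator; $H_e$ and $I$ are zero exactly when no
locus is polymorphic.

## AMOVA and Phi statistics

Analysis of molecular variance decomposes squared inter-individual
distances.  For binary band vectors the package uses the squared
Euclidean distance, which equals the count of mismatched loci — the
standard AMOVA input for dominant data (the choice is stated here
because method sections often name only the software).  With total sum
of squares $SS_T = \sum_{i<j} d_{ij} / N$ and the analogous
within-group sums, the one-level decomposition gives

$$\sigma^2_w = MS_w, \qquad
  \sigma^2_a = \frac{MS_a - MS_w}{n_0}, \qquad
  n_0 = \frac{N - \sum_k n_k^2 / N}{K - 1},$$

and $\Phi_{PT} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)$.  The
three-stratum design (regions / populations / individuals) uses the
classical unequal-sample-size coefficients $n$, $n'$, $n''$ and
reports $\Phi_{RT}$, $\Phi_{PR}$ and $\Phi_{PT}$.  Negative variance
components are truncated to zero for percentages and Phi statistics
(the convention of the established AMOVA software); the raw estimates
are kept in the result for diagnostics.  `components_from_summary()`
runs the identical algebra starting from a printed (df, SS) table plus
sample sizes, which makes published AMOVA tables re-analysable without
the raw data.

Significance uses permutation schemes matched to each statistic:
individuals among populations for $\Phi_{PT}$, individuals among
populations within their region for $\Phi_{PR}$, whole populations
among regions for $\Phi_{RT}$.  P-values use the $(b+1)/(m+1)$
estimator so a permutation p can never be exactly zero, with 999
permutations by default.  Because band distances are integers, the
permutation distribution is discrete and ties against the observed
statistic are counted as exceedances, which makes small-data tests
slightly conservative; the test suite therefore calibrates type-I
error at 60 loci with 199 permutations, where the discreteness is
negligible.

## Isolation by distance

`mantel_test()` correlates the off-diagonal entries of the pairwise
$\Phi_{PT}$ matrix (population-level differentiation, not individual
distances) with geographic distances, one-tailed for a positive
association, since isolation by distance is a directional hypothesis.
Geographic distances are great-circle (haversine, sphere radius
6371 km) for field coordinates and planar Euclidean for the
simulator's km grid.  For up to eight populations the test can
enumerate all $n!$ permutations and return the exact p-value; the
Monte Carlo version uses the same $(b+1)/(m+1)$ correction as the
AMOVA tests.

## Bayesian two-group comparison of traits

Region contrasts of per-population traits use the robust
Bayesian two-group model: group-specific locations $\mu_k$ and scales
$\sigma_k$ with a common Student-t degrees-of-freedom parameter
$\nu$, priors $\mu_k \sim \mathrm{N}(\bar y, 1000\, s_y)$,
$\sigma_k \sim \mathrm{U}(s_y/1000,\ 1000\, s_y)$,
$\nu - 1 \sim \mathrm{Exp}(1/29)$ — the established robust-estimation
defaults, adopted because the study design calls only for
"uninformed" priors.  Habitat area, strictly positive and strongly
right-skewed, uses a gamma likelihood (shape/rate per group, vague
gamma hyperpriors) with the difference reported on the original
scale.  Traits that need variance stabilisation can be square-root
transformed; the reported difference is then on the transformed scale
with a back-transformed difference of squared locations also
returned, because the original scale of a transformed-mean difference
is ambiguous and both readings are defensible.

Sampling is componentwise adaptive random-walk Metropolis (step sizes
tuned to 44% acceptance during warmup), four chains by default, run
lengths chosen so the reported parameters reach an effective sample
size of 10,000 and split-chain $\hat R < 1.01$; shortfalls attach a
warning rather than an error so that reduced settings remain usable in
simulation studies.  The sampler is cross-checked in the test suite
against a JAGS fit of the same model.  The summary reports the
posterior mode of the pooled difference draws (kernel-density argmax —
the "most credible difference"), its highest density interval
(shortest contiguous interval of the requested mass), the credibility
flag (HDI excludes zero), and the standardized effect size
$d = (\mu_1 - \mu_2) / \sqrt{(\sigma_1^2 + \sigma_2^2)/2}$ converted
to $r = d / \sqrt{d^2 + 4}$; this conversion reproduces the effect
sizes printed in comparative studies of this design, whose effect-size
definition is otherwise undocumented.

## The germination model

Germination trials are modelled as a Bayesian analogue of a two-way
logistic ANOVA.  Each dish's germination probability $\pi$ is beta
distributed around its treatment-by-region cell mode $\omega$ with a
single concentration $\kappa$ shared by all cells,

$$\pi \sim \mathrm{Beta}\!\big(\omega(\kappa - 2) + 1,\
  (1 - \omega)(\kappa - 2) + 1\big), \qquad
  y \sim \mathrm{Binomial}(n_{\text{sown}}, \pi),$$

and the cell mode is an inverse-logit of grand mean plus treatment,
region and interaction deflections, each family constrained to sum to
zero with $\mathrm{N}(0, \sigma)$ priors and vague gamma priors on the
precisions and on $\kappa - 2$.  The mode-concentration
parameterisation keeps "equal concentration between cells" literal and
guarantees $\kappa > 2$ (a unimodal beta).  Dish probabilities and
deflection-scale precisions have conjugate Gibbs updates; cell
parameters and $\log(\kappa - 2)$ use adaptive random-walk Metropolis.
Any setting that reaches the ESS and convergence targets is
acceptable — acceptance is diagnostic-based, not step-count-based, so
the package does not hard-code the long production chains of the
original software stack.

Marginal contrasts average the cell modes over the other factor on the
probability scale and decide credibility by the 95% HDI excluding
zero, consistent with the trait comparisons.  The compact letter
display uses the standard insert-and-absorb algorithm, so levels share
a letter exactly when their difference is not credible.

## The synthetic study

`simulate_aflp()` generates the genetic data from an island model:
ancestral band frequencies uniform on (0.05, 0.95), then
Balding-Nichols beta steps
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ per region
(`f_between = 0.14`) and per population (`f_within = 0.30` and `0.37`
in the two default regions), chosen as the simplest generator whose
differentiation parameter is directly comparable to a Phi statistic.
The defaults mirror the motivating study's scale — 2 regions x 10
populations x 15 individuals x 308 loci — and run in seconds.

One design decision deserves emphasis.  Applying the beta step to the
frequency of a dominant allele and then emitting phenotypes under
Hardy-Weinberg dominance ($P(\text{band}) = 1 - (1-p)^2$) inflates
phenotype-level $\Phi_{PT}$ well above the allelic $F$ (measured bias
about +0.07 at $F = 0.3$), because dominance stretches frequency
differences.  A generator whose parameter does not mean what its name
says is a poor calibration tool, so by default the beta step acts on
the band-presence frequency itself, making $F$ recoverable by AMOVA
essentially without bias; `dominance = TRUE` switches to the explicit
diploid mechanism for stress-testing the square-root estimator against
its own generative assumption, with the documented caveat about
inflated Phi.

For the isolation-by-distance region, populations sit on a line 10 km
apart and the beta steps accumulate along the chain; the per-step $F$
is calibrated from the mean pairwise lag so that the region's average
differentiation still matches `f_within`.  Trait tables draw each
trait from a location-scale t (30 df, rescaled to the target sd) or a
moment-matched gamma at region-specific means mirroring the bundled
example table; population density and fruit set are then derived, not
drawn, so the derived-trait identities hold in simulated data by
construction.  Germination data are drawn from exactly the likelihood
the model fits.

What the simulations do *not* emulate: linkage between loci, mutation
or coalescent depth, spatial structure within populations, scoring
error, and trait covariance beyond the density identities.  Passing
recovery tests therefore shows the estimators are correct for their
own assumptions, not that those assumptions hold in any field system.

## Numerical and test-design choices

* HDIs are computed by the sorted-window method and require at least
  100 draws; degenerate draw vectors return a zero-width interval.
* The posterior mode uses a 2048-point kernel density over the pooled
  draws; the median is the fallback for tiny draw counts.
* Effective sample sizes use the spectral estimator summed over
  chains; convergence uses split-chain $\hat R$.
* Spearman correlations use mid-ranks and the t approximation with
  $n - 2$ df (the convention of the common desktop statistics
  packages), with exact permutation p-values available up to $n = 8$;
  full enumeration beyond that is impractical and Monte Carlo p-values
  would silently change the published-value comparisons.  No
  multiple-testing correction is applied anywhere in the correlation
  screen — deliberately, matching the analysis style the package
  reproduces — so users should expect roughly 5% spuriously starred
  cells under independence.
* When reproducing printed tables, correlations are compared at
  ±0.01 and summary means at one unit in the last printed digit,
  because the fixture carries values at printed precision while the
  original computations used unrounded data.
* Region-level fruit set is reported as the ratio of means (mean
  capsules / mean flowers), which is what printed region rows of this
  table family contain; the mean of per-population ratios is available
  trivially and differs whenever flower counts vary across
  populations — both definitions are implemented.

The test suite runs every stochastic check at "desk scale": 500
replicates for permutation type-I calibration (60 loci, 199
permutations), 50 replicates for island-model recovery at the full
study scale, 20 simulation-based-calibration replicates for the
germination model with truth drawn from the model's own prior
structure (drawing cell modes independently of the hierarchical prior
creates deliberate prior-data conflict and is not a calibration
check), and reduced MCMC settings wherever the quantity under test is
a posterior mean rather than a tail.  At eight dishes of ten seeds the
per-cell sampling noise is 0.03-0.05 sd, so germination recovery is
asserted on the mean absolute error across cells rather than the worst
cell, which no estimator could bound tightly at that sample size.

## Known limitations

* No missing-genotype support; no codominant markers.
* AMOVA is limited to three strata; no sequence-based distances.
* No partial Mantel tests or Mantel correlograms.
* The two-group module compares exactly two groups; model comparison
  and Bayes factors are out of scope.
* The random-walk samplers are adequate for these low-dimensional
  posteriors but are not a general-purpose MCMC engine; for other
  models, use a dedicated probabilistic-programming system.
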