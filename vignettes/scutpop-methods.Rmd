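---
title: "Methods: population and landscape genetics of two insular skullcap taxa"
author: "scutpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population and landscape genetics of two insular skullcap taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scutpop)
```

# The scientific problem

Two closely related skullcap (*Scutellaria*) taxa on a subtropical island —
a widespread progenitor ("bar") and a narrowly distributed putative endemic
("tpe") — show almost no genetic differentiation at neutral markers despite
being named as distinct species. `scutpop` implements, as one tested
pipeline, the analyses needed to ask (i) whether the endemic is an old
lineage that met the progenitor again (secondary contact) or a recent
founder offshoot; (ii) whether its populations arose once or repeatedly; and
(iii) whether local climate, rather than geography, structures the neutral
genetic variation among populations.

The markers are 11 polymorphic microsatellite loci (diploid, integer repeat
scores) and two concatenated chloroplast fragments treated as one haploid
locus. Nine populations are involved: six of the progenitor and three of the
derived taxon, with the site coordinates and six bioclimatic variables
(bio2, bio8, bio9 in °C; bio13, bio18, bio19 in mm) shipped as a packaged
fixture.

# Sequence diversity and neutrality

For an alignment of $n$ haploid sequences with $S$ segregating sites
(complete-site deletion of columns containing gaps or `N`), the package
reports the mean number of pairwise differences $\pi$ and Watterson's
estimator $\theta_W = S / a_{n-1}$, $a_{n-1} = \sum_{i=1}^{n-1} 1/i$, both
*per locus* (summed over sites). The per-locus convention is forced by the
values this pipeline reproduces: $\theta_W = 0.314$ for $n = 14$, $S = 1$ is
exactly $1/a_{13}$, which a per-site convention cannot produce.

Tajima's $D$ uses the standard constants $(a_1, a_2, b_1, b_2, c_1, c_2,
e_1, e_2)$. Two p-values are reported: the beta-distribution approximation,
and a coalescent p from simulating neutral genealogies of $n$ tips
conditioned on $S$ by dropping $S$ mutations on branches with probability
proportional to branch length ($p = \Pr(|D_{null}| \ge |D_{obs}|)$,
two-sided). The conditional null for small $n$ is slightly left-skewed,
which the tests check as a sign property. For $S = 1$ the observed singleton
configuration is the *minimum* of the conditional null, so mildly negative
$D$ values near $-1.1$ are unremarkable (their simulated p-values sit far
above any rejection level).

Microsatellite diversity per deme follows the standard indices: number of
different and effective alleles ($N_e = 1/\sum p^2$), Shannon's
$I = -\sum p \ln p$, expected heterozygosity $H_e = 1 - \sum p^2$
(uncorrected; the bias-corrected variant cannot be discriminated from the
reproduced table and the uncorrected form is the default), and private
alleles (alleles seen in exactly one deme over the whole table), each
averaged over loci with a standard error across loci. Allele frequencies use
non-missing gene copies only (pairwise deletion), matching the default
behaviour of the field's standard toolchain.

# The structured-coalescent simulator

The simulator (C++ core) traces sampled gene copies backward through a set
of demes. Waiting times are exponential with total rate
$\sum_i k_i(k_i-1)/2 \cdot 1/N_i$ (coalescence; $N_i$ in gene copies — $2N$
for nuclear loci, $N$ for the haploid chloroplast) plus
$k \cdot (d_{open}-1) \cdot m$ (migration; $m$ is the backward per-pair
per-generation rate, island-style symmetric among open demes). Demographic
events — size changes, deme merges (founding events viewed backward),
migration-rate changes — interrupt the exponential clock at fixed times in
generations; tied event times are applied in list order. Mutations are laid
on the realized genealogy: Poisson($\mu \ell$) per branch of length $\ell$,
stepwise $\pm 1$ with equal probability for microsatellites (strict SMM, no
range constraint) and one new segregating column per mutation for sequences
(infinite sites). The R RNG drives everything, so a single `set.seed` makes
whole datasets bit-identical.

Design choices worth stating: time is counted in generations only (any
years-per-generation mapping is a reporting convention); microsatellites are
simulated as $2n$ gene copies per diploid individual and paired into
genotypes; migration in founder scenarios is symmetric (the reproduced
analyses report only a scalar rate); there is no recombination, selection,
or indel process. The simulator's correctness is pinned by closed forms:
$E[T_2] = 2N$ for a sampled pair, $E[S] = \theta\, a_{n-1}$ under infinite
sites, and identity-in-state probability $1/\sqrt{1+2\theta}$ at SMM
equilibrium, all checked in the test suite at 1,500–2,000 replicates with
Monte-Carlo tolerances (four standard errors).

## Demographic scenarios

Four scenario families are built in, differing in how the derived demes
attach to the progenitor:

* **Secondary contact** — ancient split from an ancestor, independent
  bottlenecks in each taxon, migration active only more recently than the
  contact onset (onset must postdate the split).
* **Founder** — the progenitor passes $N_A \to N_{B'} \to N_B$ (bottleneck
  and recovery); the derived taxon buds off at $T_2 < T_1$ with size $N_T$
  and continuous symmetric migration since. The recovery time of the
  bottleneck is not identified by the reproduced analysis, so the package
  defaults it to the founding epoch ($t_{recover} = T_2$), exposed as a
  parameter.
* **Multiple origins** — three derived demes founded independently from the
  progenitor at free times $T_1, T_2, T_3$.
* **Single origin** — one founding followed by splits within the derived
  lineage, splits constrained to be more recent than the founding.

A constant-size island model (used by the outlier scan) closes the set.

# ABC model choice

Summary statistics per dataset: per-deme mean allele number and mean
$H_e$, global $F_{IS}/F_{ST}/F_{IT}$ (Nei formulation, for which
$(1-F_{IT}) = (1-F_{IS})(1-F_{ST})$ holds exactly), mean and standard
deviation of Nei pairwise $F_{ST}$, total allele count, and mean per-locus
variance of allele size. The exact summary list of the original workflow is
open-ended, so it is config-exposed here; the pairwise-$F_{ST}$ spread is
included by default because it is the natural discriminant between
heterogeneous (multiple-origin) and shared (single-origin) founding
histories — the mean alone cannot see the difference.

Priors are log-uniform envelopes (the reproduced study prints only
posteriors): $N \in [10, 10^4]$ individuals (founder sizes capped at
$10^3$), $T \in [1, 10^5]$ generations, $\mu \in [10^{-5}, 10^{-3}]$ per
locus per generation, and $m \in [10^{-6}, 10^{-2}]$ per pair per
generation. The migration envelope ends at $10^{-2}$ because the posterior
summaries being emulated report $m < 0.01$ and $m < 0.001$; per-pair rates
of order $0.1$ would make the nine-deme system effectively panmictic and
are outside the biology of these markers. Order constraints ($T_2 < T_1$,
splits before founding) are enforced by rejection at draw time.

Rejection retains the `retain_k` simulations closest to the observed vector
in Euclidean distance on summaries standardized by the simulation-wide
median absolute deviation (robust to the heavy tails of log-uniform priors;
zero-MAD statistics are excluded; ties break by simulation index so the
retained set is reproducible). For model choice the MAD is pooled across
candidate tables so all models share one metric. The marginal density of a
model is computed from the retained set by a general-linear-model
adjustment: a multivariate-normal regression of retained summaries on
retained parameters, with the observed vector's density averaged over the
retained parameter sample (a mixture evaluation, deterministic given the
retained set; singular covariances are ridge-regularized). Posterior model
probabilities are normalized densities; Bayes factors are density ratios
and chain transitively to numerical precision. An optional NIPALS PLS
compression of the summaries (components maximizing covariance with the
parameters) is available but off by default — the statistic set is small.

**Scale.** The original workflow runs $10^6$ simulations retaining 5,000.
This package's defaults are desk scale: reference tables of 10,000 draws per
scenario with the best 500 retained, and recovery experiments at per-deme
sample sizes of 24 (progenitor) and 12 (each derived deme) — the study's
order of magnitude, sized so the two reference tables build in about five
minutes on one CPU. At that scale the test suite verifies that data
simulated under the multiple-origins prior is assigned highest posterior to
the generating family in at least 70% of 30 replicates (measured: 90%), and
that equal-tailed 95% intervals for the founder size $N_T$ cover the truth
in at least 90% of 50 replicates.

# Structure statistics

AMOVA decomposes allele-identity variance over gene copies (two per diploid
individual) among groups (species), among demes within groups, and within
demes, with the classical nested sums-of-squares and unbalanced-design
coefficients. With the 0/1 identity metric, all sums of squares reduce to
allele counts, and the tests verify the decomposition against an
independent oracle that expands copies to one-hot indicators and runs a
plain nested ANOVA. Negative variance components are reported untruncated —
a grouping at odds with the real structure legitimately produces them. The
identity distance (an $F_{ST}$-like AMOVA) is the default; squared
repeat-size differences ($R_{ST}$-like, `metric = "repeat_size"`) are also
implemented because the reproduced table does not say which mode was used —
identity is the conservative choice.
Permutation schemes follow the statistic: individuals among all demes for
$F_{ST}$, individuals among demes within groups for $F_{SC}$, whole demes
among groups for $F_{CT}$; p-values use the add-one convention.

Pairwise genetic distance is Nei's $G_{ST} = (H_T - H_S)/H_T$ per locus
(unweighted mean frequencies for $H_T$), averaged over loci polymorphic in
the pair, then Rousset-linearized $F_{ST}/(1-F_{ST})$ for the matrix tests;
entries at or above 0.999 clamp to 999 to avoid infinities on fixed pairs.

# The F_ST outlier scan

Each locus's (total $H_e$, multi-deme $G_{ST}$) pair is compared to a null
envelope simulated under a finite island model with the same deme count and
sample sizes, deme size 500, and a per-pair migration rate calibrated
iteratively (400-locus batches) until the realized mean $F_{ST}$ matches the
observed multilocus mean within 0.01. Null loci draw their mutation rate
log-uniformly over $[10^{-5}, 5\times10^{-3}]$ so the envelope spans the
observed heterozygosity range. Simulated loci are sorted into 20 equal-count
$H_e$ bins; the 2.5/50/97.5% quantiles per bin are interpolated at each
observed $H_e$. The binning of the original method is unpublished, so
equal-count bins with interpolation are this package's choice. Calibration
is verified by construction: 400 loci simulated wholly under the island
model are flagged at 5% ± 2% by the 95% envelope, and a locus fixed for
different alleles in every deme is flagged high. No multiple-testing
correction is applied to the per-locus flags (none is applied in the
analysis being reproduced).

# Matrix association tests

Geographic distance defaults to a physically meaningful mode: longitude and
latitude projected to kilometres by a local equirectangular projection,
altitude in kilometres, 3-D Euclidean. A `paper_raw` mode reproduces the
mixing of decimal degrees with metres that published pipelines sometimes
use; both exist because the reproduced correlation values depend on this
unstated choice. Environmental distance is Euclidean over the six
bioclimatic variables, standardized by default (also unstated in the
original; flag-controlled).

The Mantel statistic is the Spearman correlation of row-major upper
triangles; the null jointly permutes rows and columns of one matrix;
p-values are one-tailed (positive association) with the add-one convention,
9,999 permutations by default. The partial Mantel uses the first-order
partial correlation of rank vectors, with significance from permuting the
matrix of residuals of the response ranks on the conditioner ranks. MMRR is
ordinary least squares on standardized unfolded matrices with coefficients
tested two-tailed against row/column permutations of the response. Exact
identities pin the implementations: single-predictor MMRR equals the
Pearson Mantel coefficient to $10^{-10}$, the permutation p on a
4-population problem matches the exhaustive 24-permutation null, and the
statistics are invariant to joint relabeling. The Spearman statistic and
its permutation p are also cross-checked against the independent vegan
implementation.

# Climate ordination

Collinear climate variables are pruned by iteratively dropping the largest
variance inflation factor ($VIF_j = 1/(1-R_j^2)$) until all fall below 10;
perfect collinearity maps to infinite VIF and is dropped first (ties resolve
in column order). Climate PCA is correlation-matrix PCA with deterministic
loading signs (largest-magnitude loading positive).

"Genetic components" are interpreted as the first five principal
coordinates (metric PCoA) of the individual-level allele-sharing distance
$d_{ij} = 1 - \tfrac{1}{L}\sum_\ell s_\ell/2$ ($s_\ell$ = shared alleles at
locus $\ell$); the original phrasing does not name the distance, so metric
and axis count are configurable. The partial dbRDA constrains these axes by
the six climate variables conditioning on latitude and longitude —
individuals carry their population's site values, which is forced by an
individual-level response with site-level predictors. The constrained
ordination, its inertia partition (conditional + constrained +
unconstrained = total, asserted to $10^{-9}$ on every input), and marginal
per-term permutation tests (999 permutations of residuals) are delegated to
vegan's `rda`/`anova.cca`. Per-variable GLMs on ordination axes 1–2 report
per-axis t statistics, adjusted $R^2$ and the overall F. Raw p-values are
reported throughout (the reproduced analysis applies no correction).

# The synthetic nine-deme dataset

`analysis/02_simulate_dataset.R` generates the repository's stand-in for
the unpublished genotypes: nine demes named after the sampling sites, the
study's per-population sample sizes (12, 4, 22, 9, 12, 21 progenitor;
12, 23, 40 derived), 11 microsatellite loci at the estimated per-locus rate
$5.274\times10^{-4}$, one haploid sequence locus, founder demes with
$N < 100$ founded under 100 generations ago, a bottleneck-recovery history
anchored at the point estimates ($N_A \approx 597$, $N_{B'} \approx 199$,
$N_B \approx 683$), and per-pair migration $5\times10^{-4}$ (the emulated
posteriors report $m$ below $10^{-2}$–$10^{-3}$). What it does *not*
emulate: allele-size range constraints, null alleles, genotyping error,
linkage, and the (unknown) true He level of the real loci — with the
printed sizes and mutation rate, simulated heterozygosity runs higher than
the published per-deme values, which is a visible inconsistency of the
printed point estimates, not a dial to adjust. Passing tests on this
generator therefore demonstrate correctness of the estimators and the
inference machinery under known truth, not agreement with the unpublished
genotypes.

# Numerical conventions and limitations

Missing genotypes must be missing in both allele slots; statistics drop
them per locus. Distance matrices are validated symmetric to $10^{-9}$ with
zero diagonals; only linearized-$F_{ST}$ matrices may carry negative
entries. Permutation p-values can never be below $1/(P+1)$. The coalescent
event loop has a hard guard of $2\times10^8$ events. Known limitations: no
recombination or selection in the simulator; the GLM marginal density is a
local mixture approximation whose absolute value is less trustworthy than
the model *ranking* it induces; Fdist envelopes at extreme observed
heterozygosity rely on edge-bin interpolation; and the dbRDA treats
site-level climate as constant within demes.
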