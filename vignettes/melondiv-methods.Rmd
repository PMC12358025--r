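---
title: "Methods: marker-based diversity analysis with melondiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based diversity analysis with melondiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melondiv)
```

## The problem

Crop germplasm collections — the melon (*Cucumis melo*) collections that
motivated this package being a typical case — are still routinely genotyped
with small mixed marker panels: a dozen dominant presence/absence markers
(RAPD) alongside a handful of codominant multi-allelic microsatellites
(SSR), plus a few chloroplast CAPS markers that type the maternal lineage.
melondiv implements the full analysis chain for such panels: band-sharing
similarity, diversity statistics, tree building and ordination, Bayesian
admixture clustering with model selection, cytoplasm typing, and seed/trait
classification — together with a synthetic-data generator that provides
ground truth for every stage.

## Genotype model

Dominant markers are stored exactly as they are scored in practice: the
pseudo-homozygote codes 1/1 (band present) and 0/0 (band absent). A
dominant heterozygote is unrepresentable by construction, and every
downstream statistic consumes this two-state coding directly — no
Hardy–Weinberg back-estimation of allele frequencies is attempted, because
with a dozen loci and strong population structure that estimation is
unreliable and the coded-phenotype frequencies are what the classical
band-sharing literature actually uses. Codominant calls are unordered
allele pairs with alleles labelled by fragment-size rank (1 = smallest);
`"7/3"` and `"3/7"` load to the same call.

## Band-sharing similarity

For two accessions, genetic similarity is

$$GS = \frac{N_{11} + N_{00}}{n},$$

where $N_{11}$ accumulates shared positive bands, $N_{00}$ counts shared
dominant-band absences, and $n$ is the number of mutually non-missing
markers (19 for a complete 12 RAPD + 7 SSR panel). Codominant sharing is
fractional: the score between genotypes with distinct-allele sets $A$ and
$B$ is $|A \cap B| / \max(|A|, |B|)$, which gives the classical 0.5 for a
homozygote 2/2 against a heterozygote 2/3, and extends the rule to every
heterozygote-heterozygote case (2/3 vs 2/4 scores 0.5, 2/3 vs 4/5 scores
0). Genetic distance is $GD = 1 - GS$. Under missing data the denominator
is the pairwise-complete marker count; with complete data the published
constant denominator is recovered.

Diversity statistics follow the standard estimators: Botstein's PIC for
codominant markers, the two-state form $2p(1-p)$ (maximum 0.5) for
dominant ones; gene diversity $D$ as the across-locus mean of
$1 - \sum_i p_i^2$ (the plug-in estimator by default; the $m/(m-1)$
small-sample correction is available behind `unbiased = TRUE`); and Nei's
1972 standard distance $D = -\ln\, J_{xy}/\sqrt{J_x J_y}$ between group
frequency profiles.

## Trees and ordination

`upgma()` is a direct implementation of size-weighted average-linkage
agglomeration with node heights at half the merge distance, so leaves sit
at height zero and the tree is exactly ultrametric. Ties in the minimum
distance are broken by merging the pair whose cluster labels (each
cluster represented by its lexicographically smallest leaf) sort first;
this makes results invariant to input row order, and `to_newick()` orders
children canonically so equal trees serialize identically. On tie-free
matrices the algorithm coincides with `stats::hclust(method = "average")`,
which the test suite uses as an independent oracle.

`pcoa()` wraps classical metric scaling (Gower double-centering,
`stats::cmdscale`): axes are eigenvectors scaled by the square root of
their eigenvalues. Band-sharing GD is not guaranteed Euclidean, so
negative eigenvalues can occur; they are reported but excluded, and
explained variance is taken over the sum of positive eigenvalues only.
Morphological traits are column-standardized (mean 0, sd 1 with the
$n-1$ convention) before Euclidean distances, UPGMA clustering, or PCA
(`stats::prcomp` on the pre-standardized matrix), because fruit weight
otherwise dominates every axis. A zero-variance trait is an error rather
than a silent drop. The trait dendrogram uses standardized Euclidean
distance with UPGMA linkage — a documented assumption chosen to match the
genetic side, since classical workflows rarely state the linkage used.

## The admixture model

`run_admixture()` is a Gibbs sampler for the standard admixture model:
each gene copy of individual $i$ at locus $l$ originates from cluster $k$
with probability $q_{ik}$ and is then an allele draw from that cluster's
frequency vector $p_{kl\cdot}$. One sweep alternates:

1. cluster-of-origin assignment for every gene copy, sampled from
   $\Pr(z = k) \propto q_{ik}\, p_{kla}$;
2. frequency updates $p_{kl\cdot} \sim \mathrm{Dir}(\text{prior} +
   \text{counts})$. Under the correlated-frequency (F-) model the prior is
   $p^A_{l\cdot}(1-F_k)/F_k$ around ancestral frequencies $p^A$, giving
   the drift interpretation of $F_k$; the ancestral frequencies get a
   Metropolis update with a Dirichlet proposal centred on the current
   value (flat Dirichlet prior), and each $F_k$ a random-walk Metropolis
   update with a uniform prior on (0, 0.5). The independent model uses a
   flat Dirichlet prior instead;
3. ancestry updates $q_{i\cdot} \sim \mathrm{Dir}(\alpha + \text{counts})$,
   followed by a random-walk Metropolis update of the symmetric Dirichlet
   parameter $\alpha$ itself (uniform prior on (0, 10)).

Alpha inference matters and is on by default. With $\alpha$ fixed at 1
the prior is uniform over the ancestry simplex and the posterior-mean $Q$
of even a completely unadmixed individual is pulled noticeably toward the
centre, visibly inflating the $|\hat{Q} - Q_{\text{true}}|$ recovery
error on small panels. Letting the data drive $\alpha$ small (as the
reference implementations of this model do by default) restores sharp
assignments; `infer_alpha = FALSE` gives the fixed-alpha variant for
comparison.

Dominant markers enter the likelihood as their 1/1 / 0/0 coding, i.e. as
two-allele loci with both copies observed — mirroring how such data are
entered in practice rather than modelling dominance with a recessive null
allele. The log data probability of a run is estimated from the collected
sweeps as $\overline{\ln L} - \tfrac{1}{2}\mathrm{var}(\ln L)$; the
harmonic-mean estimator is avoided for its notorious instability.

Model selection uses the Evanno statistic
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / s_K$ over
replicate runs, undefined at the endpoints of the scanned range and
reported as $+\infty$ with a flag when $s_K = 0$. Replicate runs are
aligned by the column permutation minimizing the summed squared
difference to the run with the highest $\ln P(D)$ (exhaustive over $K!$
for $K \le 8$, greedy column matching beyond); the consensus $Q$ is the
mean of the aligned matrices. Accessions with a maximum membership
strictly above 0.6 are assigned to that population; all others are
labelled admixed by their two largest components ("Pop3/4"-style, in
descending membership order — the two-largest convention is our
assumption, as the 0.6 rule alone does not define admixed classes).

## Cytoplasm typing

Chloroplast CAPS markers are consumed as observed digestion-pattern
labels. A user-supplied key (YAML) maps each pattern to a haplotype
letter per marker and each complete letter tuple to a cytoplasm type
(Ia/Ib/Ic/III). Classification is a pure lookup: a tuple missing from
the key yields `"unclassified"` (with the reason recorded), while a
pattern label unknown to the key is an error, since it indicates a
mis-keyed dataset rather than a new lineage. The packaged three-marker
key emitted by the generator is synthetic — it has the shape of a real
diagnostic key, not its published fragment sizes. Heteroplasmy is not
modelled.

## The synthetic-data generator

`sim_spec()` fixes the study conditions; its defaults are the conditions
under which the sampler's recovery properties are validated: two
ancestral populations of 50 accessions each, 100 dominant + 20 codominant
loci, drift $F = 0.05$, pure (unadmixed) ancestry. Ancestral frequencies
come from a flat Dirichlet, population frequencies from the same
Balding–Nichols-style drift model the sampler assumes, codominant
genotypes from two independent allele draws through the ancestry mixture,
and dominant markers from a single two-state draw recorded as 1/1 or 0/0.
Cytoplasm follows majority ancestry deterministically (a mixing-rate knob
exists but defaults to 0) — the simplest structure that makes
geography-by-lineage crosstabs exactly checkable. Seed lengths are
Gaussian per class with defaults of 11.0 ± 1.0 mm (large) and 6.0 ± 1.0
mm (small), straddling the 9.0 mm classification cut as real large- and
small-seeded melon groups do; fruit weight is constructed to a target
correlation of 0.823 with seed length, the magnitude reported for African
melon accessions. Everything derives deterministically from
`master_seed` (the three emitters use fixed offsets of that seed so each
table is reproducible independently of call order).

What the generator does *not* emulate: linkage between nuclear loci,
mutation processes, genotyping error, maternal introgression independent
of nuclear ancestry, and missing data patterns. Passing recovery tests on
these simulations therefore demonstrates correctness of the estimators
under their own model assumptions, not robustness to the full messiness
of real germplasm data.

## Numerical choices and problem sizes

Sampler state is clamped away from the simplex boundary (frequencies at
$10^{-12}$) so Dirichlet log-densities stay finite; Metropolis proposal
scales are 50 (Dirichlet concentration, ancestral frequencies), 0.05
(drift random walk) and 0.05 (alpha random walk). The validation suite
runs the sampler at reduced but honest problem sizes: ancestry recovery
uses the default two-population spec with 5 runs of 500 + 500 sweeps,
asserting a consensus error below 0.1 against the generating ancestry;
the ΔK replicate study uses 15 accessions per population,
50 + 10 loci, $F = 0.25$ (well-separated populations), scanning
$K = 1 \ldots K_{\text{true}}+2$ with 3 runs of 250 + 350 sweeps. For
real analyses the defaults remain the classical protocol: $K = 1$–10, 20
runs per $K$, 5000/5000 sweeps.

## Limitations

- The sampler has no linkage model, no prior-population information, and
  no parallel tempering; very weakly differentiated populations
  ($F \lesssim 0.02$ on small panels) will not be resolved.
- $\Delta K$ is undefined at the endpoints of the scanned range and, like
  all second-difference criteria, cannot select $K = K_{\min}$ or
  $K_{\max}$.
- Band-sharing GD is not metric in general; PCoA may shed genuinely
  negative eigenvalues, and the reported variance fractions then refer to
  the positive part of the spectrum only.
- The dominant-marker PIC and diversity values are statistics of the
  band-phenotype coding, not of underlying allele frequencies; they are
  comparable across datasets scored the same way, but not to
  codominant-marker values.
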