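---
title: "Methods: microsatellite panel power and maximum-likelihood kinship"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite panel power and maximum-likelihood kinship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatkin)
```

This vignette is the package's own account of its statistical methods: the
models, the estimators, the simulation machinery, the numerical choices,
and the places where the design was genuinely open. It states no empirical
result that the test suite or the acceptance script does not itself
compute.

## The setting

Small captive populations — here motivated by *ex situ* breeding of the
Harpy Eagle, but the machinery is generic — are genotyped at a panel of
roughly ten codominant microsatellite loci with 2–8 alleles each and
moderate diversity (mean expected heterozygosity near 0.45). Managers need
three things from such data: per-locus diversity summaries, a measure of
how much discriminatory power the panel has (for identifying individuals
and for excluding candidate parents), and pairwise relatedness estimates
conservative enough to base pairing decisions on.

## Genotype handling

A `genotype_table` stores unordered diploid allele pairs (homozygotes
repeat the label) for individuals x loci; allele labels are opaque
positive integers, and nothing downstream assumes any ordering or
stepwise-mutation structure on them — every statistic in the package is
allele-identity based. Missing genotypes are wholly missing (the file code
is `0` in each allele column, the GenAlEx convention); half-missing cells
are treated as parse errors rather than data.

Sequence-derived alleles can be encoded four ways (`encode_alleles`):
total sequence length (`FullLength`, equivalent to classical fragment
analysis), target-repeat length only (`RepeatFocused`), the tuple of all
annotated repeat lengths (`SSRs`), or the full sequence string (`CAT`,
where SNPs and indels also distinguish alleles). The two tuple/string
schemes map distinct keys to integer codes in first-appearance order
within each locus, which keeps the encoding deterministic and
file-representable. `CAT` refines `FullLength` by construction: equal
sequences have equal lengths. Repeat annotations travel in a BED-like TSV
whose first column names the FASTA record (`individual|locus|copy`);
because alleles of one locus differ in length, intervals must be
per-record rather than per-locus, and an explicit `target` flag marks the
target microsatellite.

The missing-data filter removes loci above the threshold (default 10%)
first, then recomputes individual missingness over the retained loci and
removes individuals still above it. The order matters: an individual whose
gaps are concentrated in discarded loci survives. The reverse order is
available but non-default; with either order a single pass is a fixpoint
on data of this shape, which the suite checks by applying the filter
twice.

## Diversity statistics

Expected heterozygosity uses Nei's unbiased estimator
$\hat H_E = \frac{2n}{2n-1}\bigl(1 - \sum_i p_i^2\bigr)$ with plain
sample-proportion allele frequencies. The choice is pinned by the worked
configurations of the two biallelic reference loci (43:1 and 38:6 allele
counts in 22 individuals), which the biased estimator does not reproduce
at 4-decimal precision.

The Hardy–Weinberg test is the conditional exact test: given the observed
allele counts, the probability of a genotype configuration with $h$
heterozygotes and genotype counts $n_g$ is proportional to
$2^h / \prod_g n_g!$, and the p-value sums the probabilities of all
configurations at most as probable as the observed one (probability
ordering, the classical choice). Complete enumeration is used when the
configuration count is within `max_configs` (default $10^6$); otherwise a
Monte-Carlo version re-pairs the pooled allele vector at random, with the
add-one estimator $(b+1)/(N+1)$ so that p-values are never zero. The two
paths are required to agree within Monte-Carlo error in the suite.
Monomorphic loci return $p = 1$ with a degeneracy flag rather than an
error, so panel-wide summaries do not fall over on uninformative loci.

Linkage disequilibrium between two loci uses the log-likelihood-ratio
statistic $G$ of the two-locus genotype contingency table, with a null
distribution obtained by permuting one locus's single-locus genotypes
among individuals — this conditions on both single-locus genotype
distributions and tests only association. The permutation count (default
10,000) bounds the smallest attainable p-value at $1/(N+1)$.

## Panel power

The default exclusion probability Q is the *parent-pair* case: the chance
that a random Hardy–Weinberg couple is genetically incompatible as the
parental pair of a random offspring,
$$Q = 1 + 4a_4 - 4a_5 - 3a_6 - 8a_2^2 + 8a_2a_3 + 2a_3^2, \qquad
  a_k = \sum_i p_i^k.$$
The verbal definition of exclusion ("excluding a random individual as a
potential parent") names a single candidate, but only the parent-pair
polynomial reproduces the reference panel's printed per-locus values at
both reconstructible loci (the one-parent-known polynomial gives 0.0217
where 0.0420 is printed), so the parent-pair case is the default and the
single-candidate cases (`one_parent_known`, `no_known_parent`) sit behind
an argument. The normative definition of all three cases is the
brute-force enumeration over offspring and candidate genotypes
(`exclusion_probability_bruteforce`); the polynomials are accepted only
because the suite verifies them against it to $10^{-10}$ on randomized
frequency vectors.

Identity probability is $I = \sum_i p_i^4 + \sum_{i<j}(2p_ip_j)^2 =
2a_2^2 - a_4$, the collision probability of Hardy–Weinberg genotypes.
Joint values assume independent loci: $QC = 1 - \prod_l (1-Q_l)$,
$IC = \prod_l I_l$. Frequencies feeding Q and I are plain sample
proportions with no small-sample correction — again pinned by exact
agreement with the reconstructible loci.

Minimal-panel selection is greedy (decreasing Q or increasing I until the
joint criterion is met), which reproduces the reference panel's four-locus
subset and scales to larger panels; an exhaustive mode over all subsets is
provided for panels of at most 15 loci.

## The kinship model

At one locus, a non-inbred pair shares 0, 1 or 2 alleles identical by
descent with probabilities $(k_0, k_1, k_2)$, and the joint probability of
the observed unordered genotype pair is the mixture
$k_0 S_0 + k_1 S_1 + k_2 S_2$: $S_0$ is the product of Hardy–Weinberg
genotype probabilities, $S_2$ is the genotype probability when the two
genotypes are identical (zero otherwise), and $S_1$ averages, over the
first genotype's two alleles, the probability of the second genotype given
one IBD allele. Log-likelihoods sum over jointly genotyped loci; loci
missing in either member are skipped. A configuration impossible under the
hypothesis (for instance no shared allele under parent–offspring, where
exactly one parental allele must appear in the offspring) yields a
log-likelihood of $-\infty$, represented by a sentinel that loses every
comparison and never produces `NaN`.

The canonical hypotheses are U $(1,0,0)$, HS $(0.5,0.5,0)$, FS
$(0.25,0.5,0.25)$ and PO $(0,1,0)$, with relatedness
$r = k_2 + k_1/2$. `ml_relatedness` maximises over the full simplex by a
0.01-step grid followed by a 0.001-step local refinement — deterministic,
boundary-exact (estimates like $r = 0.5$ at the PO vertex are reported
exactly), and resolving flat-likelihood ties towards the least related
point. `ml_relationship` compares the four canonical hypotheses, breaking
ties in the order U, HS, FS, PO: when the data cannot distinguish, the
less alarming label is preferred, consonant with the pipeline's
conservative stance. Allele frequencies for all likelihoods are estimated
from the complete filtered data set including the focal pair; the
alternative (leave-pair-out frequencies) changes results little at these
sample sizes and would make results depend on which pair is being
examined.

## Confidence sets, classification and disambiguation

For each candidate hypothesis $R$, the observed statistic is
$\lambda_{obs} = \ln L(\text{best hypothesis}) - \ln L(R)$. Pairs are
simulated under $R$ at the observed loci (the pair's missing pattern is
preserved by simulating only jointly typed loci) and the same statistic is
computed for each, re-maximising over hypotheses per simulated pair; $R$
is retained when the add-one tail proportion exceeds $\alpha$. Whether the
re-maximising or fixed-hypothesis construction is intended by the
originating software is not documented; the re-maximising one is adopted
because it makes $\lambda \ge 0$ by construction, guarantees the ML
hypothesis is always in its own set, and is the more conservative of the
two. The conservative classification rule then reads: *related* only if U
is excluded, *unrelated* only if the set is exactly $\{U\}$, *ambiguous*
otherwise. Coverage of the true relationship is slightly above the nominal
level because of the add-one estimator; the suite checks $\ge 93\%$ at
$\alpha = 0.05$.

Ambiguous pairs are re-tested: the top hypothesis against each alternative
in the pair's set, simulating under the alternative, with small p-values
eliminating the alternative. The default Bonferroni correction counts all
tests across all ambiguous pairs in the run, as the procedure description
prescribes ("the significance threshold varies with the total number of
tests performed"). That correction is deliberately and severely strict:
pairs are ambiguous precisely because their likelihood ratios are
borderline, so their raw p-values cluster just below the uncorrected
threshold and rarely survive any multiplication — with run-wide
correction, most ambiguous pairs stay ambiguous, which matches the
reference study's experience that the majority of its ambiguities
persisted. A per-pair correction mode (`m_mode = "per_pair"`) is provided
for the variant in which roughly half of the unrelated-leaning ambiguities
resolve; the suite exercises both.

## The synthetic-data generator

The generator reproduces the statistical structure the analysis assumes —
and nothing more. Founders are independent Hardy–Weinberg draws;
offspring receive one uniformly chosen allele per parent per locus;
`simulate_pair` draws the IBD-sharing count per locus and fills non-IBD
alleles from the frequencies. The same batch engine backs the confidence
sets and likelihood-ratio tests, so the suite's cross-check that empirical
pair frequencies match the $S_0/S_1/S_2$ mixture simultaneously validates
the sampler and the likelihood. All generators take explicit seeds and
share R's global generator; there is no hidden state.

`random_panel_frequencies` emulates the reference panel's shape: 10 loci,
allele counts drawn from 2–8 with weights centred near 4, and per-locus
gene diversity targeted uniformly in $[0.30, 0.60]$ (truncated at
$0.95\,(1-1/m)$ for loci with few alleles) by mixing a random simplex
point towards either a point mass or the uniform vector and solving the
mixing weight — giving skewed, dominant-allele profiles whose panel-mean
expected heterozygosity lands near 0.45, the level observed for the real
markers. Allele labels are plausible fragment lengths on a dinucleotide
ladder. What the generator deliberately omits: mutation, genotyping error
and stutter, null alleles, inbred founders, and population structure.
Passing tests on this synthetic material therefore validate the
estimators under their own model assumptions — they do not certify
robustness to Wahlund-type heterozygote deficits or genotyping artifacts,
which real captive panels must screen for upstream.

## Problem sizes and numerical choices

The package defaults follow the reference procedure (100,000 simulations
per confidence-set candidate and per likelihood-ratio test); the test
suite and the bundled analyses scale the Monte-Carlo sizes down (400–10,000
simulations, 200-pair recovery studies, 10 loci x 8 equifrequent alleles
for the informative-locus designs) — sizes chosen so the whole suite runs
in well under a minute of simulation work while keeping Monte-Carlo error
an order of magnitude below every asserted tolerance. `pairwise_analysis`
shares null simulations between pairs with the same jointly-typed-locus
pattern, so a complete table costs one batch per hypothesis rather than
one per pair; results remain deterministic given the seed.

Two boundary effects deserve note. First, because IBD coefficients live on
the simplex, $\hat r \ge 0$: for truly unrelated pairs only upward errors
survive, so the mean $\hat r$ over unrelated pairs sits slightly above
zero (bounded near 0.08 at the 10-locus, 8-allele design) rather than
centring on it. Second, relatedness above 0.5 — parents who are themselves
related — makes PO and FS statistically interchangeable, since both imply
$r = 0.5$ and differ only in whether allele sharing is obligatory; the
family-recovery test therefore asserts the related/unrelated
classification, not the exact label.

## Known limitations

Likelihoods assume non-inbred pairs, no null alleles and no genotyping
error (the originating software's null-allele option is out of scope).
Pairwise inference is not pedigree reconstruction: triads, sibship
partitions and parentage assignment need dedicated tools. Exclusion and
identity combinations assume independent loci, so panels with linked or
duplicated markers overstate QC and understate IC.
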