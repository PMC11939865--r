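---
title: "Allele correlation networks and bloc discovery with blocnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele correlation networks and bloc discovery with blocnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blocnet)
```

## The problem

Haplotypes — runs of nucleotides inherited together — carry more
information about protein variation and its regulation than single
SNPs, but conventional haplotype inference phases *every* variant in a
window, forcing recent and neutral mutations into the inferred pair of
haplotypes. `blocnet` instead extracts *blocs*: partial haplotypes
containing only strongly co-inherited alleles, found as connected
components of an allele-level correlation network built from unphased
genotypes. Blocs are then screened for case/control association by
carrier odds ratio and profiled across populations.

This vignette documents the model, its assumptions, the tunable
parameters, the numerical conventions, and what the synthetic data used
throughout validation does and does not establish.

## The allele co-occurrence coefficient

Every biallelic SNP contributes two network nodes, one per allele,
because a single scalar correlation per SNP pair averages over allele
pairings and loses signals confined to cohort subgroups. For SNPs $i$
and $j$ and alleles $a$, $b$, the package computes, over the $n_2$
samples non-missing at both SNPs,

$$\hat p_a = \frac{\sum d_a}{2 n_2}, \qquad
  \hat p_{ab} = \frac{\sum d_a d_b}{4 n_2}, \qquad
  w_{ab} = \frac{\hat p_{ab} - \hat p_a \hat p_b}
               {\min(\hat p_a, \hat p_b) - \hat p_a \hat p_b},$$

where $d_a \in \{0,1,2\}$ is the sample's allele count. $w_{ab}$ is set
to 0 when the co-occurrence excess is non-positive (or its maximum is
0) and clipped to $[0,1]$. The numerator is the composite linkage
disequilibrium of the allele pair estimated from dosage products —
never from inferred phase — and the denominator is its maximum given
the two allele frequencies, so $w_{ab} = 1$ indicates co-occurrence at
its frequency-permitted ceiling. Four values are produced per SNP pair
(REF/ALT $\times$ REF/ALT).

Assumptions and consequences worth knowing:

* **Unphased composite counting.** With heterozygote pairs the product
  $d_a d_b / 4$ undercounts same-chromosome co-occurrence relative to
  the (unobservable) haplotype frequency, so even a perfect copy of a
  SNP scores below 1 when heterozygotes are present. This is a
  deliberate property of staying phase-free; weights remain monotone in
  the underlying co-inheritance, which is what edge *ranking* needs.
* The kernel is isolated in one internal function (`.cccFromSums`) so
  an alternative correlation can be swapped in without touching the
  network machinery.
* Intra-SNP edges are excluded: the two alleles of one SNP are
  structurally anti-correlated and would waste the degree budget below.

Pairs with fewer than two complete samples are skipped with a warning.
All accumulation is in double precision, and the vectorized network
path (`buildNetwork`, three BLAS cross-products) is tested to $10^{-12}$
against per-pair enumeration.

## Edge selection and bloc extraction

`thresholdToMeanDegree` keeps the
$\lfloor |V| \cdot t / 2 \rfloor$ highest-weight edges, with
$|V| = 2 \times$ (number of SNPs) *including* singleton nodes and
default target $t = 1$: sparse enough that surviving components are
tight LD structures, dense enough that real blocs stay connected. Two
numerical conventions matter here:

* **Zero weights are non-edges.** A floored weight of 0 means no
  positive co-occurrence excess; such entries are never candidates for
  retention even when the candidate list runs short of the requested
  count (the function then keeps all positive edges and warns).
* **Ties are broken deterministically** by (weight descending, first
  node id, second node id), so edge selection — and everything
  downstream — is bit-reproducible regardless of input order.

Components are found by breadth-first search; a union-find oracle in
the test suite confirms the partition on a thousand random graphs.
Components with more than 10 nodes (strict inequality, i.e. $\ge 11$)
become blocs, ordered genomically. A component containing *both*
alleles of one SNP is not forbidden by the model; the package keeps the
allele with the larger summed incident weight (tie: REF), flags the
bloc `multiAllelic`, and preserves the original node count for the
size screen, so users can inspect such cases rather than having them
silently dropped.

## Carrier calls, odds ratios, and the three-trial cascade

A sample **carries** a bloc when it has at least one copy of the bloc
allele at every bloc SNP where it is genotyped; samples missing more
than 30% of the bloc's SNPs are excluded from both numerator and
denominator. Missing genotypes at retained samples count as
*compatible*: the resulting frequencies are therefore upper bounds, and
adding the missing data back can only lower them — a monotonicity that
the test suite exercises directly on nested blocs (with the exclusion
rule disabled, since changing the evaluated set as SNPs are added can
move the denominator in either direction; the monotonicity statement is
about a fixed evaluated set).

Association uses the cross-product odds ratio with the Woolf
(log-scale) interval,
$\exp(\ln \text{OR} \pm z \sqrt{1/a + 1/b + 1/c + 1/d})$, applying the
Haldane–Anscombe $+0.5$ correction (flagged) when a cell is empty. Two
conventions are deliberate:

* $z$ is the conventional two-decimal critical value ($1.96$ at the
  0.95 level). The package's reference three-trial results reproduce
  to all printed decimals only under this convention.
* The $p$-value is the two-sided normal test on
  $\ln \text{OR} / \text{SE}$, consistent with the interval. No
  multiple-testing correction is applied: selection is controlled by
  design, through independent Validation and Replication stages.

`screenBlocs` runs the cascade: every $>10$-node bloc significant on
Discovery (CI excluding 1) is re-tested on Validation; the most
significant Validation survivor (smallest $p$; ties by larger lower CI
bound, then lexicographic bloc id — the ranking criterion is otherwise
underdetermined, so it is fixed and recorded in the audit trail) is
tested once on Replication. MCI samples inform the blind network build
but never the 2×2 tables. Cohort splits are caller-provided input; the
package performs no randomization of real samples.

## Population profiling with partial SNP overlap

Reference panels rarely genotype every bloc SNP. `profilePopulations`
intersects the bloc with each panel's SNPs (data-driven, not
hard-coded), applies the same carrier rule and 30% exclusion, and
reports carriers over evaluated samples. The packaged 23-SNP bloc
(`thop1Bloc()`) ships with its real SNP ids and pattern alleles;
its coordinates are placeholder spacings (synthetic), sufficient for
ordering only. The companion `syntheticPopulationPanel()` is a
deterministic synthetic stand-in for an 11-population reference panel
— *not* real genotypes — whose per-population sample sizes, SNP subsets
(12–15 of 23) and carrier counts are construction parameters; it
exists so the profiling code path, including exclusions and platform
overlap, runs against known truth.

## The synthetic-data generator

`generateGenotypes(SyntheticScenario(...))` emulates the structure of a
case/control genotype study: diploid biallelic genotypes; per-genotype
missingness; CASE/MCI/CONTROL labels; three cohort splits; one planted
multi-SNP pattern. Each chromosome of each individual carries the
planted haplotype with probability `hapFreqCase` or `hapFreqControl`
(MCI at control frequency, since intermediate diagnoses are never
association-tested); pattern chromosomes mutate away from the bloc
allele per SNP with probability `patternDecay`; everything else draws
independent alleles at background MAFs uniform on
`backgroundMafRange`.

Default conditions — the study conditions used by the acceptance
checks — are 500 SNPs, a contiguous centered 23-SNP planted bloc,
2,000 cases and 2,000 controls, frequencies 0.6/0.3, decay 0.01,
missingness 0.01, splits 0.45/0.18/0.37. The split proportions mirror
a realistic three-trial partition of a cohort of this size; background
MAFs span 0.05–0.5, the usual post-QC range for array data. Carrier
probability follows the Hardy–Weinberg closed form
$q = 1 - (1 - f)^2$, which the tests verify empirically at $n = 5000$.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: background LD between non-planted SNPs
(an AR(1)-style option was considered and left out to keep null
calibration clean; background SNPs are mutually independent),
population structure and admixture, genotyping batch effects,
coalescent realism, and recombination within the planted pattern beyond
i.i.d. per-SNP decay. Null-scenario calibration (the Discovery screen's
false-survivor rate matching the nominal 5% CI-exclusion level) is
therefore a statement about independent backgrounds, the easiest case.

Reproducibility: one documented generator (R's Mersenne-Twister via
`set.seed`) drives all randomness; the same scenario seed yields
byte-identical datasets across platforms.

## Problem sizes and degenerate inputs

The validation suite runs at desk scale by choice: networks of 500
SNPs (~125k SNP pairs, seconds via BLAS cross-products), null
calibration over 500 replicates of a 23-SNP, 4,000-sample scenario,
and 1,000-graph component oracles. Memory for the network build grows
as the square of the SNP count (several dense SNP×SNP matrices); a
`maxPairDistance` window restricts candidate pairs for larger inputs.
Degenerate inputs are defined rather than accidental: an empty genotype
matrix yields an empty network; an all-zero 2×2 table is an error
(single zero cells are Haldane-corrected); a population with zero bloc
overlap yields a flagged `NA` row while the run continues; monomorphic
SNPs get a deterministic placeholder alternate allele at PLINK load.

## Known limitations

* Carrier status demands the bloc allele at *every* observed bloc SNP;
  there is no tolerance parameter for near-carriers, matching the
  strict definition the screening statistics assume.
* PLINK ped/map round-trips re-derive minor-allele orientation at
  load (the format stores nucleotides only); VCF round-trips are exact.
  On an in-sample frequency tie the lexicographically later nucleotide
  becomes the alternate allele.
* The two-node-per-SNP design doubles the pair computation relative to
  scalar-LD methods; this is the price of allele-specific resolution.
* Blocs are connected components, not communities: a single
  high-weight bridge edge merges two LD structures. The per-bloc
  `sourceComponentSize` and the edge list let users audit such merges.
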