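---
title: "Unguided SNP-based parentage analysis: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unguided SNP-based parentage analysis: model, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snparent)
```

## The problem

Given a population genotyped at bi-allelic SNPs — a germplasm collection, a
breeding program, a natural stand — which individuals are the parents of
which others? Most parentage tools require a priori structure: who is an
adult, who is an offspring, which sexes the adults are. `snparent` implements
a strategy that needs none of that. Every individual may simultaneously be
tested as a potential mother, father, and offspring, and the amount of
guiding information is controlled entirely by a five-level class key per
individual (`Mo`, `Fa`, `Pa`, `Off`, `All`).

The method makes no assumptions about ploidy: genotype calls are collapsed
to three states (first-allele homozygote, heterozygote of any dosage,
second-allele homozygote) plus missing, which is exactly the information a
collapsed SNP call provides for any even ploidy.

## The triad test

For a candidate parent pair $(i, j)$, the genotype of any offspring they
could produce — the *expected progeny* $EP_{ij}$ — is fully determined at
every locus where **both parents are homozygous**: two like homozygotes fix
the homozygote, two opposite homozygotes fix the heterozygote. All other loci
are treated as missing in $EP_{ij}$.

The expected progeny is compared with every potential offspring $PO_k$ using
the Gower dissimilarity over loci $l = 1, \dots, n$:

$$
GD_{ij|k} \;=\; 1 - \frac{\sum_l s_l\, w_l}{\sum_l w_l},
$$

where $s_l = 1$ for identical states, $s_l = 0.5$ when the states differ by
one allele (heterozygote vs homozygote), $s_l = 0$ for opposite homozygotes,
and $w_l = 1$ only when both states are non-missing ($w_l = 0$ otherwise).
$GD = 0$ is perfect identity; $GD = 1$ is opposite homozygosity at every
comparable locus. If $i$ and $j$ truly are $k$'s parents, $GD_{ij|k}$ is zero
up to genotyping error; for false triads it reflects the background
relatedness of the population (typically 0.2–0.3 in an outbred panel).

Ordering all $GD_{ij|k}$ values exposes a characteristic gap between the
cluster of true triads near zero and everything else. The analysis:

1. **Gap location.** Among GD values below the `max_ident` ceiling (default
   0.1 — larger values cannot be true triads and are ignored during
   significance testing, though they remain in the full output table), find
   the largest difference between adjacent ordered values. The midpoint of
   that gap is the declaration threshold. Ties resolve to the lower-GD gap
   (the conservative, smaller declared set).
2. **Gap significance.** The largest gap is tested as an outlying maximum
   among all adjacent-gap lengths in the scanned region, with a Dixon ratio
   test. If the gap is not significant at `alpha`, nothing is declared.
3. **Per-triad significance.** Each below-threshold triad is pooled with the
   `comparison_sample` (default 30) smallest GD values above the gap — the
   most closely related spurious triads — and tested as an outlying minimum
   of that set with a Dixon test. The triad is declared true iff
   $p \le \alpha$.
4. **One parent pair per offspring.** If several below-threshold triads for
   the same offspring pass their individual tests, only the lowest-GD (then
   lowest-$p$) triad is declared. Parent-pair allocation assigns each
   offspring at most one pair, and simultaneous declaration of two pairs for
   one offspring is self-contradictory. In simulation the only competing
   hypotheses are (parent, full-sib) pairs of the same family, which have
   structurally small but non-zero GD (≈ 0.03–0.06) and always lose to the
   true triad.

Triads whose "offspring" is one of its own putative parents arise whenever
an individual is keyed `All`; they are enumerated and scored — the unguided
triad space for $n$ individuals holds exactly $n^2 (n-1)/2$ triads — but can
never be declared.

### Dixon tests by Monte Carlo

The Dixon ratio variants follow sample size: $r_{10}$ for $n \le 7$,
$r_{11}$ for $8 \le n \le 10$, $r_{21}$ for $11 \le n \le 13$, $r_{22}$ for
$n \ge 14$. Published critical-value tables stop near $n = 30$, while the
gap test here may involve thousands of adjacent gaps, so p-values are
computed by Monte-Carlo simulation of the null (standard-normal samples of
the same size; 10,000 replicates by default; a fixed, user-settable seed;
null distributions cached per sample size). At table sizes the simulated
null reproduces the classical one-sided critical values (e.g. $r_{10}$ with
$n = 5$: 0.642 at $p = 0.05$, 0.821 at $p = 0.005$) to Monte-Carlo
precision, and the p-value is uniform under the null. A constant sample
returns $p = 1$; fewer than three values is an error.

## The dyad test

A triad can only be declared when both parents are genotyped. When one
parent is absent, the *dyad* analysis attempts to identify the remaining
parent for each unresolved offspring $k$. It is a two-stage procedure over
all candidate parents $i$, built from the same expected-progeny
dissimilarities:

* **Stage 1 (GDM).** $GDM_{i|k}$ is the mean of $GD_{ij|k}$ over all
  co-parents $j$. An individual is more closely related to a population of
  its (hypothetical) siblings than to random progenies, so a true parent's
  GDM is depressed. The GDM values of all candidates for offspring $k$ are
  treated as a normal distribution; candidates whose normal score falls
  below the lower bound of the two-sided confidence interval (default 99%,
  i.e. $z < -2.576$) are flagged.
* **Stage 2 (GDCV).** $\sigma_{GD}$ is the sample standard deviation
  (divisor $j - 1$) of the per-co-parent GDs, re-expressed in units of the
  direct parent–offspring Gower dissimilarity:
  $GDCV_{i|k} = \sigma_{GD} / GD_{i|k}$. Variability is higher between an
  individual and a population of its siblings than between an individual
  and the progenies of its siblings, and the direct distance $GD_{i|k}$ of
  a true parent is small, so a true parent's GDCV is an upper outlier. The
  GDCV normal scores are computed over **all** candidates (a stable null),
  and flagged pairs whose score exceeds the upper bound are reported, with a
  cumulative p-value defined as the product of the stage-1 lower-tail and
  stage-2 upper-tail normal probabilities (the paper-style "cumulative"
  value is otherwise undefined; the product of the two one-sided tail
  probabilities is the simplest composition and is documented as exactly
  that).

### Why co-parents range over the whole population

The decisive design choice in the dyad analysis is the co-parent set. For
candidate $i$ and offspring $k$, co-parents $j$ range over the **entire
genotyped population except $i$** — including $k$ itself and $k$'s
relatives — not merely over the labelled parent candidates. Two reasons:

1. The true co-parent is, by hypothesis, absent from or unlabelled in the
   population, so there is no principled restriction of the hypothetical
   co-parent set; the triad space "involving parent $i$" includes every
   pairing of $i$, also with individuals keyed as offspring.
2. The stage-2 signal lives in exactly those pairings. $EP_{ik}$ — the
   expected progeny of the candidate with the offspring itself — is nearly
   identical to $k$ precisely when $i$ is a true parent (at loci where both
   are homozygous, $k$ carries $i$'s allele), and $EP_{i,\text{sib}(k)}$ is
   nearly a sibling of $k$. These co-parents produce the strong downward
   spikes in the per-co-parent GD set that inflate a true parent's
   $\sigma_{GD}$.

In panmictic simulations, restricting co-parents to labelled parent
candidates (as a literal reading of the candidate-set symmetry would
suggest) leaves a true parent's $\sigma_{GD}$ at about $0.56\times$ that of
false candidates — the ratio of single- to double-difference per-locus
variance — which cancels the boost from the small $GD_{i|k}$ denominator and
makes stage 2 essentially powerless (0 of 15 removed-parent cases
recovered). With population-wide co-parents the same scenario recovers
15 of 15 with no spurious pair in most seeds. Class keys therefore restrict
who can be *reported* as a parent, never who can serve as a hypothetical
co-parent.

By default the dyad analysis runs only for offspring with no declared triad
(`dyad = "auto"`), the regime in which it is meaningful; `"always"` and
`"never"` are available.

## The pedigree simulator

`simulate_population()` generates populations with known truth so that the
whole pipeline is testable without external data. Its defaults emulate the
validation design the method was originally assessed on:

| parameter | default | meaning |
|---|---|---|
| `n_founders` | 62 | unrelated founders, Hardy–Weinberg genotypes |
| `n_families` × `sibs_per_family` | 5 × 3 | full-sib families; parents drawn from founders without replacement, so full-sib confounders exist by construction |
| `n_loci` | 1000 | bi-allelic SNPs, independent loci |
| `allele_freq_range` | (0.05, 0.95) | uniform founder allele frequencies; yields ≈ 36.5% expected heterozygosity, matching the ≈ 36.6% of the validation data |
| `missing_rate` | 0.118 | independent per-call missingness |
| `error_rate` | 0.01 | per-call state perturbation: homozygote → heterozygote, heterozygote → either homozygote with equal probability |

Offspring are produced by call-level Mendelian transmission: homozygous
parents transmit deterministically (so with zero error and missingness every
true trio has $GD_{ij|k}$ exactly 0, matching the expected-progeny
construction), heterozygous parents transmit either allele with probability
one half. One seed fixes all randomness; the same seed reproduces the table
bit for bit.

What the simulator deliberately does **not** model: linkage and LD between
loci, population structure or relatedness among founders beyond the planted
families, dosage-resolved polyploid genotypes (the analysed method only ever
sees collapsed three-state calls), and read-level sequencing artefacts
(error is a symmetric per-call state perturbation). Passing tests on these
simulations therefore demonstrate the statistical machinery under the
stated design — they do not guarantee performance on a structured germplasm
collection, where background relatedness raises the spurious-GD floor and
relatives of a missing parent can strengthen (or, as confounders, complicate)
the dyad signal.

## Numerical and operational choices

* **Genotype encoding.** Allele order within a locus is lexicographic; GD is
  invariant to the choice, and determinism aids testing. Loci with more than
  two observed alleles or no non-missing calls are dropped with a warning.
  Monomorphic loci are retained by default (they always match and only
  dilute contrasts, never flip them); `drop_monomorphic = TRUE` removes
  them.
* **Undefined GD.** A comparison with zero comparable loci yields `NA` —
  never a silent 0 — and the triad or dyad is excluded from ranking with a
  warning.
* **Gap edge cases.** Fewer than three GD values below `max_ident`, or fewer
  than three adjacent gaps, make the gap undeterminable: the run completes
  with zero declared triads rather than failing.
* **Dyad edge cases.** Fewer than three candidate parents is an error
  (normal scores would be meaningless). A zero direct distance $GD_{i|k}$
  marks a duplicate sample, not a parent: the pair's GDCV is undefined and
  excluded with a warning, as are candidates with fewer than two defined
  co-parent GDs. A zero-spread GDM or GDCV set flags nothing, with a
  warning.
* **Defaults.** `max_ident = 0.1`, `alpha = 0.01` (99% confidence, the level
  used in the original validation), `dyad_confidence = 0.99`,
  `comparison_sample = 30` (keeps the per-triad Dixon test in its classical
  operating range while sampling the near-gap neighbourhood).
* **QC.** The fit records each individual's mean GD and mean usable-locus
  count over all triads it takes part in, and flags individuals more than
  3 standard deviations below the population mean on either metric —
  operationalising the recommendation to cull such individuals, for which no
  published cutoff exists.

## Problem sizes used in the test suite

The packaged tests and the acceptance script run the full validation design
(77 individuals, 225,302 triads, 1000 loci) in a few seconds per seed on one
CPU; sweeps use 20 seeds. Property tests for the Gower kernel use random
10 × 10 state matrices against a brute-force per-locus oracle; Dixon
calibration uses 200–400 simulated null samples. These sizes were chosen to
exercise every code path at the study's own scale while keeping a complete
run of the suite short.

## Known limitations

* The gap heuristic needs spurious triads below `max_ident` to anchor the
  above-gap side; in a population with no low-GD spurious structure the gap
  degenerates and nothing is declared (a conservative failure).
* The per-triad Dixon test measures isolation from the above-gap sample
  only; its Type-I control near the threshold is inherited from the gap
  location, which is why the one-pair-per-offspring rule matters.
* Unguided dyad analysis (relatives among the candidates) retains the
  method's known confusion mode: a full sib of the offspring can outscore
  the true parent at stage 2. Supplying generational labels removes sibs
  from the candidate set and, in the emulated design, restores exact
  recovery.
* The two-stage dyad bounds are two-sided quantiles of the stated
  confidence level; near-threshold true parents (GDCV score just below the
  upper bound) are missed conservatively rather than traded against
  spurious reports.
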