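---
title: "Coverage planning for amplicon genotyping: model and methods"
author: "ampcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage planning for amplicon genotyping: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampcov)
```

## The problem

Targeted amplicon sequencing reads single DNA molecules, so every error
introduced during PCR-based library preparation — polymerase
misincorporations, homopolymer slippage, and chimeras formed when a
partially extended strand primes on a related allele — surfaces as a read
with a wrong sequence. The proportion of *correct* reads (reads identical to
a true allele of the sampled individual) varies enormously with the
polymerase used, and it determines how many reads one must sequence before a
genotype can be called with confidence. `ampcov` implements that accounting:
it measures per-enzyme correct-read proportions from demultiplexed reads and
turns them into minimum-coverage recommendations.

## The recovery model

Reads from one amplicon are modelled as independent draws over $m + 1$
categories. With per-read correct probability $p$ and positive amplification
weights $w_1, \dots, w_m$ over the $m$ true alleles, a read is a correct
copy of allele $i$ with probability

$$q_i = p \, \frac{w_i}{\sum_j w_j},$$

and erroneous with probability $1 - p$. A genotype is considered safely
recoverable from $n$ reads when every allele is seen in at least $k$
identical correct copies (default $k = 3$; a variant supported by a single
read is indistinguishable from an error, and two reads still leave an
appreciable chance of coincidence). The recovery probability

$$R(n) = \Pr\{X_1 \ge k, \dots, X_m \ge k\}, \qquad
  (X_1, \dots, X_m, E) \sim \mathrm{Multinomial}(n; q_1, \dots, q_m, 1 - {\textstyle\sum_i} q_i)$$

is computed exactly by inclusion–exclusion over the failure events
$\{X_i < k\}$: each joint term is an explicit multinomial sum over count
vectors below $k$, evaluated in log space (`lgamma`) so large $n$ does not
overflow. For $m = 1$ this reduces to the binomial upper tail, which the
test suite uses as an independent closed-form check; a brute-force
enumeration over all multinomial outcomes and a Monte Carlo sampler
(`mc_recovery`) provide two further independent routes that the tests
compare against the inclusion–exclusion path.

`min_coverage` returns the smallest $n$ with $R(n) \ge c$ (default
$c = 0.999$). $R(n)$ is nondecreasing in $n$, so the search brackets the
threshold by doubling from $mk$ and finishes by bisection; the result is
exact, not approximate. With the defaults, $p = 0.88$ gives a haplotype
coverage of `r min_coverage(allele_profile(0.88))$n_min` reads and
$p = 0.53$ gives `r min_coverage(allele_profile(0.53))$n_min` — a
low-fidelity enzyme more than doubles the required coverage even in the
simplest possible marker system.

### Amplification bias

Unequal allele amplification is common in multi-allele PCR. The phrase "one
allele amplifies half as well as the other" is modelled by weights
$(2, 1)$: correct reads split between alleles in proportion to the weights,
so the weaker allele receives $q_2 = p/3$ per read. This is the simplest
convention consistent with a per-read category model; observed per-allele
read frequencies can be plugged in directly as weights when available,
which is the recommended practice for planning a real experiment. Under any
fixed $p$ and $k$, biased weights can only increase the minimum coverage —
a pattern the test suite asserts across $p$ values.

`consistent_p_interval` inverts the map: given a printed or desired
coverage, it reports the interval of $p$ values whose minimum coverage
equals it (the map $p \mapsto n_{\min}$ is non-increasing, so the preimage
is an interval, located on a grid with step 0.001 by default).

## The read-processing chain

**Demultiplexing.** Reads follow the two-round tailed-amplicon
architecture: adaptor (ending in a 4 bp platform key), a 10 bp MID barcode,
the universal M13 tail, the locus-specific primer, the insert, and the
mirror of that structure reverse-complemented at the other end. A read is
assigned iff, in either orientation, it contains the complete MID + tail +
primer structure at both ends with the *same* sheet MID, and the trimmed
insert length falls in the design's range. Matching is exact and
mismatch-free — the filter is deterministic and conservative, mirroring
barcode extractors that demand complete MID and primer sequences — with one
deliberate exception: IUPAC degeneracy codes in the locus primers (the
bundled MHC II primers contain Y, K, M, W, S) match any base of their set.
MIDs and tails match literally. A read matching two different sheet entries
is rejected as `ambiguous_mid`; this cannot occur with barcode sets of
pairwise distance ≥ 3 (which `generate_mids` enforces) but is defined for
safety. Rejected reads are returned with a reason (`no_mid`,
`incomplete_primer`, `length_out_of_range`, `ambiguous_mid`), never
silently dropped, so assigned + rejected always equals the input count.

**Classification.** A read is correct iff its trimmed insert is
character-identical to a reference allele of its individual, on either
strand. Identity includes length: a single substitution or homopolymer
indel makes a read incorrect. Correct reads are attributed to the matching
allele (ties broken by allele-id sort order; they cannot arise when alleles
are distinct, as the panel validator enforces). Per experimental unit —
the (system, enzyme, PCR condition, individual) tuple — the proportion
correct is $\hat p = n_\text{correct}/n_\text{reads}$, and a unit enters
downstream statistics only when it has **more than 10 reads** (strictly
greater, as the inclusion rule is stated). `pool_stats` pools by summing
counts, never by averaging proportions.

**Reporting.** `build_coverage_table` pools the included units per enzyme —
the simple system alone for the haplotype column; both PCR conditions
combined for the biallelic columns — and computes minimum coverage under
weights $1$, $(1,1)$ and $(2,1)$. An enzyme with no units for a system is
flagged `n.a.` (did not amplify); an enzyme whose data cannot support a
coverage estimate — no unit above 10 reads, or zero correct reads (a finite
coverage does not exist at $\hat p = 0$) — is flagged `i.d.`.

**Condition comparison.** The effect of modified cycling conditions on
$\hat p$ is assessed with a stratified permutation test
(`compare_conditions`): within each enzyme × individual stratum, condition
labels are randomly reassigned across units; the statistic is the
read-weighted mean of within-stratum differences in pooled proportions. We
chose a permutation test over a mixed-model fit deliberately: it is exact
under the null, self-contained, and its calibration is verified in the test
suite (type-I error within [0.03, 0.07] at $\alpha = 0.05$ over 1000 null
datasets; power above 0.9 against a 7.5-point shift with 10 strata of 2000
reads). Note the granularity: with $S$ one-vs-one strata only $2^S$ label
configurations exist, so attainable p-values are bounded below by roughly
$2^{1-S}$; the test emits `(1 + \#\{|T^*| \ge |T|\})/(reps + 1)`, which is
never exactly zero.

## The synthetic read generator

`simulate_unit` emulates the study conditions so the whole chain is
testable without a sequencing run. Each read draws a template allele in
proportion to the profile's allele weights, then passes through three
mechanistic error channels:

* **Chimeras** (probability `chimera_fraction`): the insert is replaced by a
  single-crossover hybrid of two distinct alleles at a uniformly chosen
  internal breakpoint — the partial-extension mechanism. Multi-crossover
  chimeras are out of scope.
* **Substitutions**: each insert base mutates with probability
  `substitution_rate` to a uniformly chosen different base.
* **Homopolymer indels**: each run of ≥ 3 identical bases gains or loses
  one base with probability `homopolymer_indel_rate` (the platform's
  characteristic error mode; reference alleles are generated with runs
  capped at 5 bp).

The insert is then wrapped in the full tailed structure (degenerate primer
positions realised per read, so the demultiplexer's IUPAC handling is
exercised) and emitted in a random orientation. Correctness is judged *post
hoc* on the emitted sequence — a back-mutation that regenerates a reference
allele counts as correct, keeping the generator's truth table and the
classifier's identity rule consistent by construction. Output is
deterministic for a fixed seed.

`calibrate_profile` makes `target_p_correct` exact in expectation: read
survival factorises as
$(1-\text{chimera})\,(1-\text{sub})^{L}\,(1-\text{indel})^{H}$ per allele
($L$ length, $H$ homopolymer sites), and the substitution rate is solved in
closed form when allele lengths agree, by root finding otherwise. An
infeasible target (e.g. chimera fraction alone exceeding the allowed error)
is an error, not a silent clamp. Per-enzyme fidelity differences are thus
reproduced by a single dial, spanning the empirically observed range of
roughly 0.02–0.92 correct reads.

What the generator does **not** emulate: flowgram-specific noise beyond the
homopolymer knob, quality scores, emulsion-PCR duplication, primer-site
errors (errors are confined to the insert), and coverage imbalance between
units. Passing calibration tests therefore show that the pipeline recovers
the proportions the generator encodes — they do not certify error rates of
any particular platform or enzyme.

## Numerical and design choices

* Sequences are plain upper-case text; coordinates are 0-based half-open
  internally; inputs are case-insensitive.
* Exact inclusion–exclusion is the default for $m \le 4$ alleles (term
  count grows as $k^m$); `mc_recovery` covers larger $m$ or serves as a
  cross-check, with a binomial standard error and a fixed seed.
* Probabilities are clamped to $[0,1]$ after summation; the m = 1 path
  agrees with `pbinom` to better than $10^{-12}$ absolutely (the
  alternating sum cancels catastrophically only below that scale).
* The coverage search never evaluates $R$ outside $[mk - 1, 2\,n_{\min}]$;
  ties are impossible by monotonicity.
* Degenerate inputs: $p = 0$ makes the confidence unreachable and is an
  error in `min_coverage`; empty read sets and empty stats pools return
  empty results, not errors; a chimera fraction with a single template
  allele is a validation error.
* Test problem sizes: calibration tests use 2000-read units over 30 seeds
  and targets $p \in \{0.1, 0.5, 0.9\}$ (standard errors of the mean
  ≈ 0.002, comfortably inside the asserted 0.02 band); the exhaustive
  enumeration check covers all $n \le 15$, $m \le 3$, $k \le 3$; Monte
  Carlo comparisons use $10^5$ replicates.

## Known limitations

* The identity rule cannot distinguish a true allele absent from the panel
  from an error; the package assumes the reference genotypes are complete
  and correct for each individual.
* The bias convention (weights over correct reads) is one of several
  possible formalisations of unequal amplification; coverage values for
  biased loci published under a different convention will differ. The
  weights are exposed precisely so users can substitute observed per-allele
  frequencies.
* The permutation comparison tests a mean shift in proportions; it does not
  model unit-level overdispersion within a stratum beyond what
  stratification absorbs.
* Demultiplexing is exact-match by design: reads with sequencing errors in
  the MID, tails or primers are discarded, which understates usable
  coverage when such errors are common — a conservative bias consistent
  with the completeness filter it reproduces.
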