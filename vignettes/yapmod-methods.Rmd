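---
title: "Reconstructing condition-specific transcriptional modules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing condition-specific transcriptional modules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yapmod)
```

## The problem

Yeast AP-1 transcription factors (Yap1p in *S. cerevisiae*, Cgap1p in
*C. glabrata*, Cap1p in *C. albicans*) drive the transcriptional response to
oxidative stress. A *condition-specific transcriptional module* is the set of
genes a factor activates under one defined stimulus — here, benomyl-induced
stress. No single assay defines such a module reliably: expression arrays
show response but not causation, deletion-mutant transcriptomes show
dependence but include indirect targets, and ChIP-chip shows binding but not
regulation. `yapmod` implements an integrative reconstruction that requires
convergent evidence, plus the downstream analyses such modules support:
cross-species comparison through orthology, de-novo cis-regulatory motif
discovery, and protein–DNA contact analysis on a structural model of the
factor–DNA complex.

Every stage is driven by a synthetic-data generator with recorded ground
truth, so the full pipeline is testable offline; the generator's defaults are
fixed study conditions, not tuning knobs.

## Module reconstruction

Four steps, each with its own evidence stream:

1. **Condition response.** Genes significantly up-regulated under the
   stimulus, called by 2-of-3 consensus over three callers with deliberately
   different variance models (below).
2. **Factor dependence.** The same consensus applied to the
   deletion-mutant vs wild-type benomyl response. Polarity is a flag
   (`direction` in `consensus_vote()`); the default follows the convention
   that the planted group of interest is tested for up-regulation.
3. **Promoter binding.** Probes classified by a two-component mixture of
   regressions of IP on INPUT, intersected at gene level with consensus
   enrichment of replicate log(IP/INPUT) ratios.
4. **Integration.** A gene joins the module iff
   `step1 AND (step2 OR step3)`. The universe is the expression matrix; the
   rule is Boolean and fully specified, so `build_btm()` is tested against
   exhaustive truth-table evaluation.

### Three variance-modelling strategies

The point of consensus calling is robustness to the variance model, so the
three callers are genuinely different, not three wrappers around one test:

* `moderated_t()` — empirical-Bayes shrinkage of the pooled per-gene
  variance, `s~² = (d0·s0² + dg·sg²)/(d0+dg)`. The prior degrees of freedom
  `d0` are estimated by method of moments on `log s²` (excess of `var(log s²)`
  over `trigamma(dg/2)`, inverted through `trigamma`); when the excess is
  non-positive the prior falls back to `d0 = 4`, a weakly-informative default.
  Two-sided p on `d0 + dg` df, call at p < 0.05.
* `permutation_d()` — a variance-stabilized `d = Δmean/(s + s0)` with `s0`
  the median per-gene standard error (the classic exchangeability offset);
  null distribution by label permutation, pooled across genes; FDR as the
  expected null exceedance count over the observed count, forced monotone in
  |d|; call at FDR < 0.05.
* `groupwise_variance_t()` — Welch-type statistic on per-group variances,
  each shrunk toward its group's own prior, with Welch–Satterthwaite degrees
  of freedom augmented by the prior df; call at p < 0.05.

All three use pairwise-complete observations and drop a gene (call = NA)
when fewer than two finite values remain in a group. The ratio-enrichment
stage reuses the same voting scheme in a one-sample form (sign-flip
permutations replace label permutations; the third caller becomes the plain
per-gene one-sample t, keeping three distinct variance strategies).

P-values of individual callers are deliberately uncorrected for multiplicity
— the 2-of-3 vote is the false-positive control, which is the design's
premise. On a 2000-gene null, each caller's fraction below 0.05 stays in
[0.03, 0.07] and the consensus false-positive rate never exceeds the worst
single caller (asserted in the test suite).

## The ChIP mixture model

For probe intensities on log2 scale, the IP signal is modelled conditional
on the INPUT signal as a two-component mixture of linear regressions:
unbound probes follow `ip = a0 + b0·input + ε`, bound probes
`ip = a1 + b1·input + ε`, with shared residual sd σ (homoscedastic by
default: stable on small sets; a heteroscedastic variant would double the
variance parameters without changing the contract) and bound weight π. The
EM uses random-split initialization with per-component weighted least
squares, tolerance 1e-6 on the log-likelihood, at most 500 iterations and 10
restarts; components are relabelled so `b1 ≥ b0`.

A fit is *degenerate* when a component vanishes (π < 1e-3), the slopes
collapse (|b1−b0| < 1e-3), or the mixture fails a likelihood-ratio
comparison against a single regression (2·Δloglik < 20). The last rule is
needed because EM on single-line data happily reports a spurious split of
the residual cloud (observed gain ≈ 3 log-lik units, against ≈ 10³ for a
genuine mixture); without it, noise could masquerade as binding evidence.

Probes are declared bound when the posterior probability of being unbound is
at most α = 0.05 — the natural mixture-model reading of "risk α". Posteriors
are clamped to (0, 1) so that α = 0 selects nothing. Gene-level binding
requires both methodologies (mixture AND ratio enrichment) to hit at least
one promoter probe of the gene — the conservative reading that minimizes
false positives, since the evidence types have independent failure modes.

One identifiability caveat, documented because it bounds what parameter
recovery can show: with INPUT centred at 8 on log2 scale, the fitted
intercepts extrapolate eight units outside the data, so their sampling error
(≈ σ·√((1+x̄²/s²ₓ)/nπ) ≈ 0.05 at n = 5000, π = 0.2, σ = 0.2) is an order of
magnitude larger than the slopes'. Slopes, σ and π are the quantities to
trust; the test suite verifies the EM optimum against a grid-search oracle
rather than pretending the intercept is sharply estimated.

## Motif discovery

Promoters are the −800..−1 regions upstream of the translation start,
strand-aware and truncated at neighboring annotated features. Three
algorithms cover complementary motif classes:

* `discover_words()` — exact k-mer census (k ∈ {7, 8, 9} by default,
  spanning the 7–8 bp YRE lengths plus one), scored by hypergeometric
  enrichment of per-promoter presence;
* `discover_degenerate()` — greedy generalization of the top words to
  two-base IUPAC codes while the enrichment p improves, stopping before a
  fourth ambiguous column;
* `discover_pwm()` — a zero-or-one-site-per-sequence EM against an order-0
  background, seeded from the most frequent module words (a standard
  subsequence-seeding heuristic; random-window seeding finds local optima),
  converted to IUPAC by including every base with column frequency ≥ 0.25.

Enrichment is always per-promoter presence (not occurrence counts), both
strands, with a motif and its reverse complement collapsed to one canonical
form — so a palindrome is never counted twice, and two variants that are
reverse complements of each other (e.g. TTACTAA/TTAGTAA) are a single motif
by construction. The universe N is the whole promoter collection including
the module. The tail probability is computed in log space
(`logsumexp` over `lchoose` terms) and is verified against exhaustive
enumeration for all N ≤ 25.

The filter cascade retains candidates with length ≥ 7, at most 3
uncharacterized (non-ACGT) columns, p < 1e-5, and support from ≥ 2 distinct
algorithms; two motifs "match" when some ungapped offset on either strand
gives ≥ 7 overlapping columns whose IUPAC sets all intersect (7 being the
minimum retained length). Discovery p-values are not multiplicity-corrected;
the 1e-5 operating point is the stringency control, and on null modules no
word reaches it (the per-word p-values are conservative; with ~3·10⁴ words
tested the *minimum* p is expected below 1e-4 about once per run, which is
multiplicity, not miscalibration).

Retained candidates are grouped by the same matching rule (transitively) and
merged: members align at their best offset to the group's most significant
member, columns are merged by IUPAC union over the members covering them, a
column is kept only when ≥ 50% of members cover it (interior low-coverage
columns become N, flanking ones are trimmed). The union rule means the
merged consensus can be wider than a short member; on such extensions the
member-match ⊆ consensus-match inclusion holds on the jointly covered core,
not in the flanks — the price of reporting a single consensus the way the
field's logo figures do. Coverage is the fraction of module promoters with
at least one match to the merged consensus.

## Cross-species comparison

Homology links come from all-vs-all local alignment (BLOSUM62, affine gaps
11/1) with E-values from extreme-value statistics scaled by the search-space
size; a link requires E < 1e-2, aligned length > 100 aa and identity > 25%
simultaneously. An adapter ingests standard 12-column tabular alignment
output for real data. One-to-one orthologs are reciprocal best hits with
lexicographic tie-breaking. Module overlap is the number of ortholog pairs
spanning the two modules; its percentage uses the smaller module as
denominator, and significance is reported both by permutation (independent
same-size shuffles within each universe, 10⁴ by default) and by an analytic
hypergeometric on the ortholog-pair space — on fully paired universes the
two nulls coincide exactly, which the tests exploit. Annotation-transfer
error rates are FP = |predicted∖reference|/|predicted| and
FN = |reference∖predicted|/|reference|, with the alternative FP denominator
(|reference|) also reported since either convention is defensible.

## Protein–DNA contacts

Structures are read from PDB format (altloc duplicates resolved to the
highest-occupancy copy); chains are classified by residue-name vocabulary.
Candidate contacts are polar/charged protein atoms (N/O) against DNA N/O
atoms inside a 2–5 Å outer window. A salt bridge is a charged side-chain
atom (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2, Asp OD1/OD2, Glu OE1/OE2) against
a phosphate oxygen anywhere in the outer window; a hydrogen bond is any N/O
pair inside the geometric window 2.4–3.5 Å (no hydrogens are assumed;
donors/acceptors are inferred from heavy atoms); precedence salt bridge >
hydrogen bond, one record per atom pair. Waters within 3.5 Å of both sides
add water-mediated records for pairs not in direct contact. All thresholds
are arguments, because geometric H-bond criteria differ between tools and a
real-structure analysis may need the window adjusted within the outer 2–5 Å
range. Conservation of contacting residues is evaluated on an explicit
basic-region alignment: a residue is conserved iff all aligned sequences
carry the identical amino acid at its column.

## The synthetic-data generator

The generator emulates the study conditions at desk scale, chosen once:
5000-gene matrices (the study's arrays covered ~5000–6200 genes) with 7
arrays per group (the step-1 compendium is ~14 arrays per species), planted
effect 1.0 log2 units against noise sd 0.25; 5000 IP/INPUT probes (the real
platforms had 14k–67k) from the mixture (0, 1, 1, 1.5), σ = 0.2, π = 0.2,
with INPUT log-normal (mean 8, sd 1 on log2 scale); 2000 promoters of 800 nt
at GC 0.38 (yeast-like), the planted IUPAC motif carried by 70% of module
promoters (the reported consensus coverage); proteomes mutated by
substitutions only at rate 0.05 so identity is analytic; toy complexes with
atoms spaced so the planted contact list is provably the only one inside the
search window. It does **not** emulate array spatial artifacts, dye bias,
probe-sequence effects, correlated gene expression, promoter composition
heterogeneity (order-0 background only), indels, or real nucleic-acid
geometry — so green tests demonstrate algorithmic correctness and
statistical calibration under the stated model, not robustness to every
artifact of real arrays.

Determinism: every generator is a pure function of its `sim_config`; each
uses a fixed offset from the config seed and restores the caller's RNG
state, so reruns are byte-identical and stages cannot perturb each other.

## Problem sizes and numerical choices

Tests and the acceptance script run the sizes above or smaller (the
end-to-end smoke runs use 400 genes, 600 probes, 250 promoters of 300 nt),
which keeps the full suite comfortably within a coffee break on one CPU
while leaving every statistical property measurable. Other numerical
choices: EM tolerances are absolute 1e-6 (mixture) and relative 1e-4 (PWM)
on the log-likelihood; posterior and mixing-weight floors at 1e-6–1e-12
avoid log-of-zero without affecting estimates; permutation p-values use the
add-one convention (1+exceed)/(1+total); best-hit ties in the ortholog
search are broken lexicographically and logged; hypergeometric tails cap at
1 after exponentiation.

## Known limitations

* The three DE callers share decision contracts with the tools they stand in
  for, not their numerics; no attempt is made to replicate any external
  tool's exact output.
* The homology E-value uses fixed extreme-value parameters for gapped
  BLOSUM62 (λ = 0.267, K = 0.041) rather than per-search estimation; at the
  stringent link thresholds this affects no decision in the tested regimes.
* Gene-level binding intersection (AND of any-probe hits) is one defensible
  reading; probe-level intersection would be stricter still and is not
  implemented.
* Gapped/dyad motifs and higher-order backgrounds are out of scope; the
  order-0 background is a config-level extension point.
* Real-structure contact analysis depends on the chosen H-bond window;
  reproducing any particular published contact list may require adjusting it
  within the outer 2–5 Å window.
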