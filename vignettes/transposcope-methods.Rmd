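---
title: "Methods: hierarchical TE classification, annotation statistics and event detection"
author: "transposcope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical TE classification, annotation statistics and event detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transposcope)
```

This vignette documents the models and procedures in `transposcope`, the
parameters that matter, the numerical conventions chosen where several were
defensible, and the limits of what the synthetic-data tests demonstrate.

## The taxonomy and its label space

Transposon classes are organised as a rooted tree of slash-separated
integer codes. Class 1 covers retrotransposons (LTR superfamilies Copia,
Gypsy, ERV, BelPao; non-LTR LINEs and SINEs), class 2 the DNA transposons
(TIR superfamilies Tc1-Mariner, hAT, CMC, Sola, Zator, Novosib, plus
Helitrons and MITEs). A virtual root sits above `1` and `2` but is never
emitted as a label, which matches the usual convention of hierarchical
metrics that exclude the universal root. The taxonomy is a runtime
configuration (`parse_taxonomy()`), because published classification
schemes disagree in their deeper levels; the shipped default covers the
superfamilies named above and is prefix-closed by construction. Sibling
order is ascending numeric everywhere, which also fixes all decoding
tie-breaks deterministically.

```{r}
tax <- default_taxonomy()
tax_children(tax, "1/1")
tax_ancestors(tax, "2/1/6")
```

## Features

Each sequence is encoded as 336 relative k-mer frequencies (k = 2, 3, 4)
plus 169 binary protein-domain indicators.

**Relative k-mer frequency.** The count of a k-mer is normalised by the
number of times the k-mer would occur if the sequence consisted of that
k-mer alone — its own periodic tiling truncated to the sequence length.
We read this definition literally with overlapping occurrence counts on
both sides of the ratio. Under that reading both homopolymers
(`AA` in `AAAA...`: count L−1, tiling count L−1) and non-self-overlapping
k-mers (`CG` in `CGCG...`) normalise to at most 1, which is the property
that makes the features comparable across k-mers of different internal
periodicity. Whether occurrences should be counted with overlap is not
fixed by the definition alone; we chose overlap counting and verify the
implementation against a brute-force substring scan in the test suite. The
denominator has a closed form: for a k-mer whose set of self-rotation
shifts is $S \subseteq \{0,\dots,k-1\}$,
$\mathrm{count}(w,\mathrm{tile}(w,L)) = \sum_{s \in S,\, s \le L-k}
\lfloor (L-k-s)/k \rfloor + 1$.

Non-ACGT characters (ambiguity codes, `N`) are handled conservatively: a
window containing one matches no k-mer, while the denominator still uses
the full sequence length. Lowercase (soft-masked) input is uppercased
first, since masked sequence is common in TE libraries. Sequences shorter
than k yield 0 with a warning.

**Domain indicators.** An entry is 1 when the hit table contains a hit for
that sequence and domain at e-value ≤ 5.0. The boundary is inclusive, the
conventional reading of hit filters. The domain list is data, not
algorithm: the shipped 169-entry list (`domains_synthetic.txt`) is a
synthetic stand-in built from transposon-associated conserved-domain
families and placeholders, and should be replaced by a curated list for
production use. The feature layout (column names) is stored inside every
trained model and checked at prediction time, so a model can never be
silently applied to differently laid-out features.

## The hierarchical classifier

`te_classifier()` supports the cross product of two model structures, two
training strategies and five base learners; the default — random forest,
selective, binary (RFSB) — is the recommended configuration.

**Binary structure.** One probabilistic yes/no scorer per taxonomy node.
Node $c$'s positives are the training samples whose ancestor-augmented
label set contains $c$; its negatives are the remainder of the
strategy-determined pool. Decoding starts at the root and repeatedly
descends to the child with maximal node probability until reaching a leaf.
Probabilities of sibling scorers are compared directly without
recalibration; per-step probabilities are exposed so callers can truncate
paths at a confidence threshold if they wish — the default always descends
to a leaf.

**Multilabel structure.** One multiclass scorer per internal node over its
children plus a reserved return label `-1`. Since only the name of the
return class is fixed by the design, its training set was an open choice:
we use the pool samples that do not belong to the parent's subtree,
subsampled to the mean child-class size so the return class does not
dominate the priors. Decoding ranks candidates by probability (ties:
ascending code, `-1` last); when `-1` outranks all remaining children, the
decoder backtracks one level and resumes with that level's next-best
unvisited child. A root-level return with no alternatives yields an
explicit "unclassified" result rather than a forced guess.

**Strategies.** *all* trains every node on the full training set;
*selective* trains each node on the samples activated by its parent — the
samples whose true lineage passes through the parent node. Selective pools
are therefore nested along every root-to-leaf chain, a property asserted
in the tests. A side effect worth knowing: a node that is its parent's
only populated child has no negatives in its selective pool and degenerates
to a constant scorer with prior 1, which the model records in
`fallback_nodes`.

**Base learners.** Random forest (default, 100 trees — the hyperparameter
is recorded in the model and adjustable via `learner_params`), multinomial
logistic regression, SVM with probability outputs, Gaussian naive Bayes,
and a SAMME-style boosted-stump AdaBoost implemented on `rpart` trees.
Nodes with fewer than `min_node_examples` (default 2) positives fall back
to a constant-prior scorer instead of aborting the fit.

## Evaluation

Three perspectives, matching how hierarchical classifiers are usually
reported:

1. **Hierarchical precision/recall/F1** on ancestor-augmented sets
   $\hat T_i = \{t_i\} \cup \mathrm{anc}(t_i)$ and the predicted path
   $\hat P_i$: $hP = \sum_i |\hat P_i \cap \hat T_i| / \sum_i |\hat P_i|$,
   $hR$ analogously over $|\hat T_i|$, $hF1$ the harmonic mean. Micro
   pooling (summing before dividing) is the default because it is the
   standard definition of these metrics; a per-sample macro variant is
   available via `average = "macro"`. Unclassified predictions contribute
   an empty $\hat P_i$, penalising recall but not precision.
2. **Per-level metrics**: codes truncated to a depth, samples whose truth
   is shallower excluded (padding would invent labels), macro
   precision/recall/F1 over the classes observed at that depth.
3. **Per-class F1 and MCC**, one-vs-rest on augmented sets, with undefined
   MCC (zero denominator) reported as 0.

`cross_validate()` stratifies folds by leaf label under a fixed seed and
averages arithmetically across folds, retaining per-fold reports. Classes
with fewer samples than folds trigger a warning and are simply spread as
far as they go.

## Curation rules

`curate_sequences()` applies, in a fixed order that makes reports
deterministic: category exclusion (keyword match on free-text tags, since
source databases label fragments/contigs/satellites/RNA heterogeneously),
label unification (raw names through a user-extensible synonym map; the
shipped map covers common RepBase/Wicker-style names), the strict
length bound (> 100 bp kept, exactly 100 bp dropped), the requirement that
all four nucleotides occur at least once, and finally exact full-sequence
deduplication (case-insensitive; first occurrence kept). "Duplicate" means
exact string identity — similarity-based clustering is an external-tool
step, not part of the curation rules. The report reconciles exactly:
kept + dropped + duplicates = input, and curation is idempotent.

## Annotation statistics

Coordinates are GFF3-style 1-based inclusive at the interfaces; interval
arithmetic is delegated to `IRanges`/`GenomicRanges` internally. The
transposon region mask is the per-chromosome interval union, with
book-ended intervals coalesced. Two content definitions coexist
deliberately: overall TE content uses the union mask (a base pair under
three overlapping annotations counts once), while per-class content sums
raw annotation lengths (overlapping copies count separately) — so per-class
contents can sum to more than the mask-based total, which the tests assert
on an overlapping fixture. Length distributions use type-7 (linear
interpolation) percentiles, with whisker positions at quartile ± 1.5×IQR.
Density tracks tile from position 1; an annotation spanning a window
boundary is counted in its start window while its covered base pairs are
split across windows. Tool overlap is bp-based and asymmetric (share of
tool *i*'s mask covered by tool *j*); a count-based variant was considered
and rejected as more sensitive to fragmented annotations. Conflicting
class labels from overlapping annotations of different tools are kept, not
resolved.

## Event detection

The pipeline applies three rules with these conventions:

* **Length filter**: keep 50 bp ≤ svlen ≤ 0.01 × genome. Both bounds are
  boundary-inclusive on the keep side (a 50 bp variant survives).
* **Duplicate merging**: the duplicate criterion itself was an open
  choice; we follow conventional SV-merging practice — same chromosome and
  type, reciprocal overlap ≥ 0.8 (configurable), insertions instead by
  breakpoint proximity (±100 bp) plus min/max length ratio ≥ 0.5.
  Relations are closed transitively; each group collapses to the longest
  variant (ties: smallest position). Merging is idempotent.
* **Matching**: intersection ≥ 10 % of the *shorter* of SV and annotation,
  and min/max length ratio ≥ 0.5. The 10 % reference interval is
  genuinely ambiguous; we measure against the shorter element because the
  matching philosophy weights length similarity above overlap, and the
  shorter-element reference is the laxer, consistent choice. It is
  configurable. Insertions have no reference span and match by breakpoint
  within the annotation ± 100 bp plus the same length test. Whether one SV
  may be reported against several TEs affects event totals and is not
  fixed a priori, so both views are emitted: all qualifying pairs, plus a
  unique best-match flag per SV (largest intersection, ties to the longest
  annotation). Summary statistics use best matches.

Relative activity of class $c$ is its bp share among events divided by its
bp share among annotations; weighted by annotation shares these average to
1 over classes present in both sets, which serves as an internal
consistency check. The event-vs-phylogenetic-distance relationship is an
OLS fit with Pearson correlation; patristic distances come from
`ape::cophenetic.phylo()`.

## Synthetic data: what it shows and what it does not

The generators mirror the two real feature families: classes differ by an
order-1 Markov compositional bias (strength 0.6 by default, enough to
separate four classes without making them trivially orthogonal) and by
class-private pseudo-domains hit with probability 0.9 below the e-value
threshold. Genome simulation plants non-overlapping copies with exact
base-pair accounting (so a planted 21 % yields a 21.0 % mask identically),
and the SV generator emits planted events with optional jitter, sub-50 bp
decoys and duplicate caller copies.

Default scales are deliberately small — 4 leaf classes × 200 sequences of
300–800 bp for recovery experiments, 100 kb genomes with tens of planted
copies — so the whole suite runs in about a minute while still exercising
every code path. What a passing recovery test shows is that the
implementation correctly propagates class signal from both feature blocks
through hierarchical training and decoding; it does not show that real TE
superfamilies are separable at these accuracies. Real libraries contain
degraded, truncated and nested copies, shared domains across superfamilies
and strongly imbalanced classes, none of which the generators emulate (no
substitution models, no nesting, no fragmentation). The negative control
(identical bias, no domains) verifies the other direction: without signal,
held-out hierarchical F1 drops to chance levels (≈ 0.3–0.5 on the
four-class taxonomy, depending on the prior structure of the decoder).

## Numerical and degenerate-input conventions

* Empty taxonomies, empty annotation sets, empty masks and zero-TE
  simulations are all valid and return empty results, not errors.
* A k-mer frequency with zero denominator (sequence shorter than the
  k-mer) is 0 with a warning.
* Ties in decoding resolve by ascending code order; ties in duplicate-group
  collapse by smallest position; best-match ties by longest annotation.
* MCC and correlation with zero variance are reported as 0 rather than NA,
  so downstream aggregation never propagates missingness.
* All stochastic functions take an explicit integer seed and are pure
  functions of their arguments: same seed, byte-identical output.

## Known limitations

* The shipped domain list is a synthetic stand-in; classification quality
  on real data depends on a curated list and real RPSTBLASTN hits.
* Binary-structure sibling probabilities come from independently trained
  scorers and are compared uncalibrated.
* The package consumes the standard outputs of annotation tools and SV
  callers; it does not run them, build sequence-level consensus, or
  reconstruct nested/fragmented elements.
* Short-read SV calls are out of scope; the matching rules assume the
  breakpoint quality of long-read callers.
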