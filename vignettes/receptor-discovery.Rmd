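---
title: "Classifying scavenger receptors and TSR proteins and nominating plastid-recognition candidates"
author: "kleptorecept"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying scavenger receptors and TSR proteins and nominating plastid-recognition candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kleptorecept)
```

## The problem

Sacoglossan sea slugs such as *Elysia timida*, *E. cornigera* and
*E. chlorotica* steal chloroplasts from their algal food and keep them
photosynthetically active inside their own cells ("functional
kleptoplasty"). How the slug's innate immune system recognizes a
chloroplast as a symbiont rather than a pathogen is unknown, but in
photosymbiotic cnidarians two pattern-recognition receptor groups dominate
that process: scavenger receptors (SRs) and thrombospondin-type-1-repeat
(TSR) superfamily proteins. `kleptorecept` implements a desk-scale,
fully testable version of the receptor-discovery analysis for such systems:

1. read the standard annotation artifacts produced upstream (translated
   proteome FASTA, a Pfam per-domain table, transmembrane predictions,
   tabular homology hits with a taxonomy map);
2. assemble each protein's ordered domain architecture;
3. classify architectures into SR classes and TSR families with an explicit
   arrangement grammar;
4. scan TSP1 domain segments for their diagnostic binding motifs and build
   sequence-logo matrices;
5. select candidate recognition genes from raw count matrices with TMM
   normalization and an all-comparisons log2-fold-change rule.

A synthetic-data module generates every input with planted truth, so each
stage is testable end to end without any download.

## Annotation inputs and filters

All coordinates, in files and internally, are 1-based inclusive — the
convention of the emitting tools. Domain hits take their extent from the
*envelope* coordinates of the per-domain table, not the narrower alignment
coordinates: envelopes bound the region the domain plausibly occupies,
which is what arrangement adjacency should see, at the cost of slightly
wider extents.

Three thresholds gate the inputs (`pipeline_config()`):

| parameter              | default | role                                        |
|------------------------|---------|---------------------------------------------|
| `blast_evalue_max`     | 1e-10   | homology annotation E-value ceiling          |
| `domain_ievalue_max`   | 1e-5    | per-domain independent E-value ceiling       |
| `min_protein_length`   | 150 aa  | protein-level length floor                   |

The length filter applies to the protein, not the domain region. Homology
records are additionally restricted to Metazoa via a two-column
subject-to-group taxonomy map; records without a mapping are dropped with a
reported count, and by default only the best (lowest-E-value) hit per
protein is considered (`best_hit_only = FALSE` keeps all hits — the choice
is exposed because annotation pipelines differ on it and neither convention
is universal). Proteins referenced by hit or TM files but absent from the
FASTA are a hard error rather than a warning: that situation always means
mismatched inputs, and silently intersecting them would fabricate a
proteome nobody assembled.

## From hits to architectures

Profile-HMM scans routinely emit several overlapping family hits over one
stretch of sequence. `resolve_overlaps()` admits hits greedily by evidence
strength — ascending independent E-value, ties broken by descending bit
score, then ascending start, end and family name so the outcome is
independent of input order — and keeps a hit only while its overlap with
every admitted hit stays at or below `max_overlap_frac` (default 0.25) of
the shorter of the two. The default tolerates the modest envelope overlap
of genuinely adjacent domains while rejecting rival assignments of the same
region.

Transmembrane helices are merged in afterwards with two rules:

* TM regions never compete with Pfam hits during overlap resolution;
* a helix overlapped by a retained Pfam domain over more than half of the
  helix is suppressed from the arrangement string — a helix inside a domain
  is topology, not arrangement, and keeping it would fragment arrangement
  strings that the literature writes as e.g. `TM + CD36 + TM`.

Repeated identical adjacent domains are kept as repeats (a properdin-like
protein really is `TSP1 + TSP1 + ...`), never collapsed.

## The classification grammar

Rules are written against *concepts* (CD36, CTLD, SRCR, TSP1, ...), and a
shipped, editable vocabulary maps Pfam family names onto concepts
(`default_domain_vocabulary()`); the receptor literature names concepts,
not Pfam accessions, and the mapping is the one place that binding is made.
Evaluation is strictly first-match-wins, SR rules before TSR rules,
specific before generic (see `?default_ruleset` for the full ordered list).
Three choices deserve justification:

* **SR-E-like requires exactly one CTLD and exactly one TM.** Published
  assignments place both two-CTLD membrane proteins *and* single-CTLD
  proteins flanked by two TMs (e.g. Collectin-12-like sequences) among
  generic C-type lectins; "a transmembrane region with a single C-type
  lectin domain" is read literally on both counts. Only "SR-E-like" is
  ever emitted: SR-E proper requires experimentally demonstrated scavenging
  activity, which no annotation can establish.
* **SR-B flanking is positional, not merely count-based**: at least one TM
  starting before the CD36 domain and one ending after it, with no other
  Pfam domain between either TM and the CD36 domain — the extracellular
  loop reading of the class definition.
* **SR-A relies on collagen + C-terminal SRCR + TM only.** The canonical
  definition also names an α-helical coiled coil, but no detection method
  for it is part of the input artifacts; since surveys of these slugs find
  no SR-A at all, the rule is exercised only on synthetic data.

On the TSR side, thrombospondin/COMP recognition requires at least one
type-3 repeat plus the C-terminal lectin-like domain rather than a literal
count of 13 repeats — repeat counts in per-domain tables are fragmentary.
ADAMTS-like membership is evidence-based on domain content (TSP1 with an
ADAMTS spacer, metalloproteinase-family domain or PLAC domain); no signal
peptide or prodomain detection is attempted. An ADAMTS spacer alone, with
no TSP1, still reports as ADAMTS-like but carries a "no TSP1" flag in the
matched rule, so downstream users can exclude it. Unknown domain labels
never match any rule; they can only demote a protein from the
TSP1-only categories to the mixed `TSR_other` group, which is exactly the
published reading of "new domain arrangements".

## TSP1 motifs and the logo matrix

A canonical TSP1 repeat carries six conserved cysteines, the tryptophan
glycosaminoglycan-binding tract `WXXWXXW`, and the CD36/SR-B binding
motifs `CSVTCG` and `GVQTRXR`, followed by an `RXR` tract of polar
residues. `scan_motifs()` reports each motif exactly and — for the two
CD36-binding motifs — in a one-mismatch-tolerant mode, because divergent
repeats are described as carrying motifs *similar* to `CSVTCG`; one
mismatch over the fixed positions is the default reading of "similar" and
both columns are reported so neither is silently preferred. The `RXR`
tract accepts arginine, lysine or glutamine at the R positions by default
(the polar-residue reading); `strict_rxr = TRUE` demands arginine.

"Six cysteines" is operationalized two ways: the per-segment raw count
(reported per segment) and the consensus-level count of C-majority
alignment columns (`conserved_cysteine_count()`), because the claim is
about the domain consensus, not every instance.

`build_logo_matrix()` computes per-column residue frequencies with
optional pseudocount smoothing, `(count + pc) / (n + 20 pc)`, and the
information content `log2(20) - H` with `H` the column Shannon entropy in
bits, no small-sample correction. A pure column therefore carries
`log2(20) ≈ 4.32` bits and a uniform column 0 — both asserted analytically
in the tests. Alignment itself is out of scope: the module accepts
pre-aligned segments and only columnizes trivially when all segments share
one length (which the generator guarantees); shipping an MSA algorithm
would duplicate mature tools without adding anything to the analysis.

## Expression: normalization and the selection rule

Counts are raw; a gene survives the low-count filter iff at least
`min_samples_at_count` (2) samples reach `min_raw_count` (100) reads.
TMM normalization is implemented in the package: against a reference
sample (automatically the one whose 75th count-fraction percentile is
closest to the mean), genes zero in either sample are excluded, per-gene
log2 ratios `M` and average abundances `A` are doubly trimmed (30% of M at
each tail, 5% of A — the canonical trim fractions), and the factor is
`2^(Σ w M / Σ w)` with first-order delta-method precision weights; factors
are rescaled to geometric mean 1. Identical columns yield factors of
exactly 1, a pure depth difference is absorbed by library size, and on
planted-shift simulations the factors agree with the established reference
implementation within 2% (asserted in the tests, which use that
implementation only as a cross-check oracle).

Fold changes are `log2((mean CPM_A + c) / (mean CPM_B + c))` on CPM over
effective library sizes (library size × factor), with `prior_count`
`c = 0.5` keeping ratios finite at zero counts (the exact value is
inconsequential away from zero and configurable). For the triplicated
design, group CPMs are averaged after normalization; pooling before
normalization would let one deep replicate dominate its group.

Significance is the threshold rule alone: a gene is differentially
expressed iff |L2FC| > 1 (twofold). No dispersion estimation, exact test
or p-value is computed — two of the three target designs have no
replicates, so the threshold *is* the inference rule, and reproducing a
replicate-based test machinery here would imply an error model the data
cannot support. Selection then depends on the design:

* `fed_vs_starvation` (unreplicated adults): a candidate must exceed the
  threshold in **every** fed-vs-starved comparison;
* `staged_juvenile` (triplicates): per-stage up/down calls are made for
  the initial (fed5 vs aposymbiotic), transient (fed7 vs fed5) and stable
  (fed10 vs fed7) comparisons, and the candidate set is the initial-phase
  upregulated set.

### Detection boundary of unreplicated designs

With negative-binomial dispersion φ = 0.1, a single-sample log2 ratio has
standard deviation ≈ `sqrt(2 φ) / ln 2` ≈ 0.65, so a planted twofold
effect (L2FC 2) clears the threshold margin of 1 by only ~1.5 standard
deviations per comparison — an intrinsic limit of unreplicated designs, not
of the implementation. The quantitative recovery properties (sensitivity
≥ 0.95, false-selection ≤ 0.05) are therefore asserted on the replicated
staged design, where averaging triplicates shrinks the noise enough to
clear the margin comfortably; the unreplicated design is exercised with a
planted log2 effect of 3 (recovering ≥ 19 of 20 planted genes) and with a
null effect (false selections ≤ 5%).

## What the generator emulates — and what it does not

`generate_proteome()` plants, per receptor category, the defining
arrangement at non-overlapping coordinates, writes the same file dialects
the parsers consume (round-trip contract), samples real-hit independent
E-values below 1e-5 and distractor-hit E-values in 1e-4..1e-2. Distractors
may carry rule-relevant family names: they change nothing downstream if and
only if the E-value filter works, which is exactly what the
distractor-invariance test asserts. Amino-acid backgrounds are uniform
random — the pipeline never re-detects domains from sequence, so sequence
realism buys nothing here.

`generate_counts()` draws negative-binomial counts around log-normal
per-gene baselines scaled to the planned depth (1e6 by default), with the
planted genes up-shifted in the fed (or fed5) samples. Planted genes are
drawn from the expressed half of the baseline distribution: a gene below
the low-count filter's floor could never be selected regardless of its
true effect, so planting there would probe the filter, not the selection
rule — and any real candidate gene necessarily passed the count filter.

For the worked-example checks against the published candidate tables, the
reported per-gene fold changes are embedded among decoy genes up to the
reported per-class totals. Decoys emulate the genes reported as *not*
selected, so their values are drawn from a null spread (`N(0, 0.5)`) and
any decoy that would pass the selection rule is redrawn — a passing decoy
would contradict the reported outcome it stands in for.

What the generator does **not** emulate: fragmented or partial domain
hits, overlapping true architectures, non-uniform residue composition,
sequencing-depth heterogeneity beyond a global scale, count correlation
between samples, or mapping ambiguity. Passing tests therefore demonstrate
the correctness of the rules and computations under clean planted truth,
not robustness to every artifact of real annotation pipelines.

## Numerical and degenerate-input choices

* Overlap resolution tie-breaks: E-value, then bit score, start, end,
  family name — total order, so results are permutation-invariant.
* Empty architectures classify as `unclassified` with an empty matched
  rule; empty inputs yield empty outputs everywhere rather than errors.
* An all-zero sample is a hard error for TMM (no ratio is defined);
  a comparison with an empty group is a hard error in the design
  constructor.
* Logo columns with no standard residue are an error; residues outside the
  20-letter alphabet (X, gaps) are ignored in counts.
* Problem sizes in the shipped tests: 1,001-protein proteomes (77 per
  category) for classifier recovery, 2,000-gene matrices for TMM and DE
  recovery, 500 random segments for the motif oracle — sizes at which
  every property is stable while the whole suite stays fast.

## Known limitations

* The classifier sees only what the vocabulary maps; receptor families
  defined by domains absent from the default vocabulary require extending
  it (by design, but a silent gap if forgotten).
* TSP1 segment extraction trusts envelope coordinates; truncated repeats
  at protein ends are reported as-is.
* The threshold-only selection rule inherits the limits discussed above:
  for unreplicated designs it is a fold-change screen, not a statistical
  test, and should be read as such.
* The pipeline consumes upstream tool outputs; it does not run HMMER,
  TMHMM, BLAST, read mapping or abundance estimation, and inherits
  whatever biases those tools introduced.
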