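---
title: "Screening for composite TE-derived enhancer candidates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for composite TE-derived enhancer candidates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Transposable elements (TEs) are a major raw material for new *cis*-regulatory
DNA: a TE copy that lands near a developmental gene can, over tens of
millions of years, be domesticated into an enhancer. Classically each
co-opted enhancer traces back to a single TE. A more recent idea is
*composite* enhancers: several TEs of unrelated origin inserted side-by-side
inside one conserved non-coding element (CNE), each contributing part of the
regulatory activity, with the full activity assembled stepwise as successive
TEs integrated during evolution.

`coopte` implements the in-silico side of that research programme as a
reusable, fully testable pipeline:

1. **Screen** — find every TE annotation that overlaps strongly conserved
   sequence ("TE-derived CNEs").
2. **Cluster** — chain proximal TE-derived CNEs into candidate composite
   loci and quantify how often a focal TE family has conserved companions.
3. **Consensus identity** — quantify each sub-element's decay by local
   alignment against its subfamily consensus.
4. **Phylogeny** — date each sub-element's integration by mapping ortholog
   presence/absence onto a rooted species tree under single-gain (Dollo)
   logic, and derive the relative integration order.
5. **Simulate** — generate all inputs with known ground truth so that every
   stage, and the pipeline end to end, is verifiable without external
   downloads.

# The screen

A repeat annotation (one RepeatMasker `.out` row) qualifies as a TE-derived
CNE when the total overlap between its genomic interval and conserved
elements whose log-odds (LOD) conservation score is **strictly greater than
100** is **strictly greater than 30 bp**. Both thresholds are exposed
(`min_lod`, `min_overlap`) with those defaults, and both are read as strict
inequalities — the boundary cases (exactly 30 bp, exactly LOD 100) are
excluded, which the test suite pins down explicitly.

Three choices here were genuinely open and are worth recording:

* **Overlap is summed per repeat across conserved elements.** Conservation
  tracks fragment arbitrarily; a TE whose conserved portion is split across
  two adjacent elements of 20 bp each is biologically one 40-bp conserved
  TE. The unit of the screen is the TE, so the per-element overlaps are
  summed. `per_element = TRUE` switches to requiring a single element to
  exceed the threshold, for sensitivity analysis.
* **Per-fragment, not per-insertion, by default.** RepeatMasker splits one
  insertion into several rows sharing a join ID. The native unit of the
  `.out` format is the row, so overlap is computed per row by default;
  `merge_joins = TRUE` first merges fragments sharing a join ID and scores
  the insertion as a unit.
* **Strand is ignored**: conservation tracks are unstranded.

Simple repeats, low-complexity runs, satellites and structural RNAs are
parsed but tagged non-TE and excluded from the screen — they are not
transposable elements, and counting them would inflate every downstream
statistic. An optional `exclude` BED (e.g. exons) can be subtracted from the
conserved track first, since "conserved non-coding" strictly implies exon
exclusion; this is off by default because the upstream conserved-element
lists used in practice are usually already non-coding-filtered, and
subtraction requires an annotation the user must supply.

Interval overlap itself is delegated to `GenomicRanges`/`IRanges`; the test
suite checks the screen against an independent quadratic all-pairs oracle
and the overlap primitive against per-base set intersection.

# Clustering into composite loci

Two TE-derived CNEs belong to the same candidate locus when the gap between
their repeat intervals is **strictly below 600 bp** (`max_gap`), and
chaining is transitive (single linkage). A locus may therefore span more
than 600 bp overall; that is intentional — the motivating pattern is an
ordered run of three TEs inside a ~1.2-kb CNE, which a pairwise-only rule
could split. Distances are measured between the repeat intervals by
default; `distance_on = "elements"` measures between the hulls of the
conserved elements instead, since either reading of "proximal" is
defensible.

`companion_stats()` then reports, for a focal family, how many of its
conserved copies sit in a locus that also contains a member of a
*different* subfamily. Two fragments of the same subfamily never count as
companions. The percentage is rounded **half-up to one decimal** (base R's
banker's rounding would turn e.g. 8.65 into 8.6); with 626 focal copies of
which 54 are accompanied this convention prints 8.6%, which the acceptance
suite verifies through the module itself.

# Consensus identity

`align_to_consensus()` performs local (Smith–Waterman) alignment with
affine gaps, implemented in C++ for speed, with defaults match = +2,
mismatch = −3, gap open = −5, gap extend = −2 (a gap of length L costs
open + (L−1)·extend). Local alignment is the right model because anciently
decayed relics often match only an internal slice of their consensus — the
motivating example matches positions 391–501 of a >500-nt consensus.
Both orientations are tried by default (`strand_mode = "both"`), ties going
to the forward strand.

Percent identity is `100 · n_matches / n_columns` rounded half-up to one
decimal, where `n_columns` counts **all** alignment columns including gap
columns. This is the conservative convention; gaps are failures to match.
`identity_denominator = "aligned-bases"` divides by non-gap columns
instead, which approximates RepeatMasker's `100 − %div` accounting.
`N` never counts as a match, in either the score or the identity.
Determinism: among equal-scoring alignments the end cell preferring longer
alignments and then smaller consensus coordinates is chosen, and traceback
prefers substitution over vertical over horizontal moves.

`identity_summary()` separates partial-consensus matches from effectively
full-length ones: a match is flagged full-length when it covers at least
90% of the consensus (configurable), so a 111-nt match to a 550-nt
consensus (coverage ≈ 0.20) is reported as partial while a 407/420-nt
match is reported as full-length.

**Known estimator bias.** Local alignment trims terminal columns whose
cumulative score is negative, preferentially discarding mismatch-rich ends.
The recovered identity of a copy evolved at per-site substitution
probability *p* therefore sits slightly *above* the naive expectation
100·(1−p): at p = 0.30 on a 500-nt consensus the mean recovered identity is
about 71.7% rather than 70.0% (about +1.7 points; an independent local
aligner shows the same offset, so this is intrinsic to local alignment at
these scoring parameters, not an artefact of this implementation). Users
comparing recovered identities to substitution rates should expect this
small upward offset; the test suite documents it.

# Integration branch and order

`infer_gain()` assumes a TE insertion at an orthologous site arises once
and can only be lost (Dollo logic) — TE insertions are effectively
homoplasy-free characters, which is the standard premise for using them as
phylogenetic markers. The gain node is the MRCA of all species carrying the
ortholog; `n_losses` is the minimal number of branches below it whose
removal explains every absent descendant, computed bottom-up (count of
maximal all-absent subtrees). The MRCA is provably the unique
loss-minimising gain placement, and the suite checks node and loss count
against exhaustive enumeration on random trees.

An element absent everywhere is an error, not a root gain: an unobservable
character carries no placement information and silently defaulting would
fabricate one.

`integration_order()` sorts gain assignments oldest-first by strict clade
nesting: `a` precedes `b` only when `a`'s gain node is a proper ancestor of
`b`'s. Equal or incomparable gain nodes share a rank (a tie group) and are
never silently ordered — an integration-order claim rests on strict
nesting, and fabricating an order under ties would overstate the evidence.
Ranks count ancestor gain nodes, so the output is a total preorder
consistent with the partial order.

Presence calls, when made from ortholog percent identities
(`call_presence_from_identity()`), use a **60% identity threshold by
default**. No field-standard cutoff exists; 60% sits comfortably above the
~50–55% identity floor at which two unrelated sequences of this
composition can be locally aligned, while retaining deeply decayed true
orthologs in the low-60s. The threshold is deliberately surfaced as a
prominent argument, and presence is monotone non-increasing in it.

# The synthetic data generator

`simulate_dataset()` writes the real on-disk formats — FASTA, RepeatMasker
`.out`, BED, newick, TSV — rather than handing in-memory objects to the
pipeline, because format dialects (1-based vs 0-based, the C-strand
consensus column order, the `lod=` name field) are the pipeline's main
practical failure mode and must be exercised end to end.

The default configuration is the package's fixed study scenario:

* three consensus families of 550, 420 and 310 nt whose integrations are
  planted on the nested clades Mammalia, Theria and Eutheria of an
  8-species mammal tree;
* 24 composite insertions of all three side-by-side (the middle family
  full-length, the oldest family as a 391–501 consensus slice mirroring
  the motivating locus), with inter-member gaps drawn uniformly from
  0–550 bp — inside the 600-bp chaining window;
* standalone insertions of each family (conserved with probability 0.8)
  plus a few simple repeats, which must be ignored by the screen;
* per-copy divergence 0.27, placing recovered identities in the low 70s —
  the decay level typical of such anciently exapted relics;
* conserved elements covering every conserved planted TE with LOD drawn
  lognormal around 300, plus 40 background elements with LOD around 50, so
  both screening thresholds separate signal from background;
* presence rows drawn by the single-gain model with per-edge loss
  probability 0.1.

Planted units are separated by at least 1500 bp, well above the chaining
window, so distinct planted units never chain into accidental composites
and "false composite" is unambiguous in ground truth. Background DNA is
uniform random; the generator deliberately does **not** model nucleotide
composition, CpG decay, per-branch sequence evolution along the tree, or
nested/overlapping insertions. Passing tests therefore demonstrate
correctness of the *computational procedure* under the generative model,
not robustness to every property of real genomes — on real data, repeat
fragmentation, segmental duplications and alignment-track artefacts all add
noise the simulation does not emulate.

With default settings the whole scenario (400-kb genome, 112 planted
annotations) simulates, screens, clusters, aligns and infers in a few
seconds; the oracle-equivalence test batteries use hundreds of random
instances with up to 500 repeats × 200 elements per instance, sizes chosen
so the full suite completes in a few minutes on one core.

# Numerical and degenerate-input conventions

* All internal coordinates are 0-based half-open; conversion happens only
  at I/O boundaries (RepeatMasker and consensus spans are 1-based
  inclusive externally).
* Empty screens, empty clusters and a focal family with zero copies are
  defined results (empty tables, `NA` percentage), not errors.
* Percentages are rounded half away from zero at one decimal throughout.
* `chain_proximal()` breaks a chain when the gap to the running maximum
  end reaches `max_gap`; because inputs are sorted by start, this is
  exactly single linkage (verified against union-find).
* Seeds: every stochastic component (generator, pipeline, tests) is
  seeded; the same configuration reproduces byte-identical output files.

# Limitations

* The headline genome-wide numbers of the motivating study (hundreds of
  focal-family CNEs, of which ~9% have conserved companions) depend on a
  specific human assembly, conservation track, repeat library and consensus
  database; reproducing them requires those external resources and is an
  integration exercise, not something this package's tests claim.
* The Dollo model hard-codes a single gain; parallel integration at
  orthologous sites, while rare, would be mis-dated.
* When losses eliminate an entire child clade of the true gain branch, the
  MRCA estimator necessarily shifts the gain one or more nodes crownward —
  recovery is only identified while every child clade retains a surviving
  presence, and the suite asserts recovery exactly in that regime.
* The aligner is designed for locus-scale inputs (up to a few kb against a
  consensus); it allocates full traceback matrices and is not a
  whole-genome aligner.
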