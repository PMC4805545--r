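---
title: "Designing tagged fosmid clones and validating them by pooled mate-pair sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tagged fosmid clones and validating them by pooled mate-pair sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fostag)
```

# The problem

C-terminal tagging of genes on genomic fosmid clones keeps the endogenous
promoter, UTRs and stop codon intact, so the fusion protein is expressed
from its native regulatory context. Engineering thousands of such clones in
96-well liquid cultures is efficient, but every clone must be verified:
oligonucleotide synthesis errors end up in the homology arms, imprecise
cassette exchange leaves errors at the arm/cassette junctions, and in a
small fraction of clones the Flp-mediated excision of the selection operon
fails, leaving an "un-flipped" cassette that breaks the reading frame.

Sequencing each clone individually does not scale. The pooled design
sequences each 96-well plate as 8 row pools and 12 column pools of barcoded
mate-pair libraries (~3 kb fragments, 100 bp reads). Two properties make
this identifiable:

* every fosmid carries a unique genomic insert, so the *genomic* mate of a
  pair pins the pair to one clone even though the tag cassette itself is
  identical across all clones ("tag-anchored" pairs);
* each clone appears in exactly one row pool and one column pool, so any
  observation can be required to replicate across two independently
  prepared libraries of the same culture (cross-pool confirmation).

# The engineering model

`tag_fosmid()` runs the two-step tagging pipeline in silico:

1. `tag_site()` places the tag at the *most commonly used C-terminus* over
   the gene's isoforms — the stop-codon position shared by the largest
   number of isoforms. On ties the 3'-most stop with respect to strand is
   chosen and the gene is flagged (`tie = TRUE`); the tie rule is a package
   decision, made so that ties never silently truncate the longest isoform.
2. `design_homology_arms()` takes the 50 bp upstream and downstream of the
   stop codon in coding orientation. `insert_pretag()` models the
   recombination: the arm sequences of the oligo (including synthesis
   errors within a tolerance of 2 substitutions per arm — errors beyond
   that fail the step, errors within it are incorporated into the clone)
   replace the genomic homology regions and the pre-tagging cassette lands
   between the last sense codon and the stop codon.
3. `exchange_tag()` swaps the pre-tag marker for the full tagging cassette
   through the epitope flanks shared by the pre-tag and every cassette, and
   `flip_out()` excises the FRT-flanked selection operon, leaving a single
   in-frame FRT.
4. `verify_frame()` asserts the four properties a correct construct must
   have: insert length ≡ 0 (mod 3), no in-frame stop inside the insert, the
   endogenous stop codon immediately downstream of the tag, and a 3'-UTR
   identical to the base fosmid.

Constructs carry an ordered edit log; replaying it on the base fosmid
reproduces the construct, and deleting the tag interval restores the base
fosmid byte-exactly. Both properties are asserted in the test suite, on
plus- and minus-strand genes.

**Cassette sequences are configuration data.** Real tagging cassettes are
specified by element order, not full sequence, so the shipped registry uses
synthetic stand-in segments with the correct structural properties: element
order 2xTY1 – sGFP – V5 – protease sites – BLRP – FRT[operon]FRT – 3xFLAG;
every coding segment a multiple of 3 and stop-free; the canonical 34-nt FRT
core embedded in a 36-nt in-frame unit whose pad bases are chosen so the
unit contains no stop codon in frame (the bare core read in frame 0
contains TAG); a 714-nt fluorophore segment (sGFP-sized); and a 1500-nt
selection operon. The operon length matters: the un-flipped form is 1534 nt
longer than the flipped form, which exceeds the 1500-nt width of the
concordant insert window, so a mate pair can never appear concordant under
both the flipped and the un-flipped interpretation. This mirrors the size
of a real rpsL-neo operon and was fixed before any validation experiments.
`validate_cassette()` re-checks all structural invariants at registry
construction.

# The synthetic data generator

`synth_locus()` builds a 12-kb random-sequence fosmid with one embedded
gene whose CDS (stop-free sense codons ending in TAA) ends near position
4000. The geometry is chosen so the mutation region of interest
(tag ± 1 kb) plus the longest plausible fragment (3000 + 3·1000 bp) fits
inside the tagged construct on either strand. A 96-well scenario
(`make_validation_scenario()`) tags every clone and injects a *designed*
defect set with exact ground truth: clones with known arm substitutions,
clones left un-flipped, and a clone with a 2-bp junction deletion.
`apply_defects()` is the random counterpart: per-base substitution rates
stratified into homology arms (the dominant error class, from oligo
synthesis), ±10 bp junction zones (imprecise exchange resolution, including
short indels) and the cassette body; the strata are disjoint so the rates
compose additively, and the arm stratum spans the full 50 bp of each arm.

Three simulator decisions matter for interpreting results:

* **Defects are drawn once per clone, before pooling.** Both pools receive
  aliquots of the same culture; this is what makes cross-pool confirmation
  informative rather than circular.
* **`depth` is mean read-base coverage over the ROI.** Fragment starts are
  uniform over the window of all starts whose reads can touch the ROI, and
  the pair count is `depth × window / (2 × read_len)`. Realized per-clone
  depth is not reported for the original libraries, so the 50× default is a
  configuration choice, not a claim.
* **Duplicates come from an independent RNG stream.** PCR duplicates are
  exact copies of original pairs, flagged in the truth tables and drawn
  from a stream separate from fragment and error draws — raising `dup_rate`
  adds copies without changing anything else, which turns the
  duplicate-robustness property (verdicts invariant between 20% and 50%
  duplication) into an exact identity rather than a statistical one.

Reads are emitted in the mate-pair reverse-forward (outward) orientation:
read 1 is the reverse complement of the fragment's leftmost 100 bases,
read 2 its rightmost 100 bases. Quality strings are constant; sequencing
error is folded into a per-base substitution rate, because the validator's
score model consumes counts, not base qualities.

What the simulator does **not** emulate: chimeric mate-pair artefacts, GC
or positional coverage bias, quality-score error profiles, barcode read
errors (barcodes are opaque labels), and adapter contamination (real-data
mode assumes pre-trimmed input). Passing tests therefore demonstrate the
correctness of the pooling/anchoring/confirmation logic under the stated
library geometry, not robustness to every artefact of a real sequencing
run.

# The validation pipeline

## Mapping and pair resolution

The built-in mapper (`map_pairs()`, Rcpp) is a deliberately simple
functional equivalent of the external aligner used for the original
libraries: exact 21-mer seeding over all references, ungapped extension,
and an affine-gap dynamic-programming fallback (mismatch 2, gap open 3, gap
extend 2) with full traceback, accepting alignments up to 6 edits. The
affine penalties make a contiguous 2-bp gap strictly cheaper than two split
1-bp gaps, so all reads covering the same deletion report the same event; a
unit-cost scheme ties between those representations and breaks variant
aggregation. Real-data mode ingests standard SAM records instead
(`ingest_sam()`), dropping secondary/supplementary records, and the
internal alignments can be exported as SAM (`export_sam()`); the round trip
is exact.

Because the cassette is common to all clones, a read inside it would hit
every construct. The mapper reports such reads once, against shared
cassette references (flipped and un-flipped forms), and suppresses the
per-construct copies; `resolve_pairs()` translates cassette hits into clone
coordinates when pairing them with a clone-specific genomic mate. A pair is
kept when exactly one clone admits a concordant placement — reverse-forward
orientation and implied insert inside the window — and classified as
`tag_anchored`, `genomic_only` or `unflipped_evidence`; cross-clone ties
are discarded as ambiguous, mirroring the unique-concordant-only mapping
of the original analysis.

* **Insert window.** The default [2200, 3700] follows the explicit mapping
  parameters used for the original libraries; the looser prose estimate
  (3000 ± 1000 → [2000, 4000]) is selectable via
  `validator_config(insert_window =)`. The narrow window accepts a strict
  subset of the wide one.
* **Un-flipped evidence** requires the cassette-side mate to overlap the
  selection operon *proper* — exclusive of the FRT cores and pad bases,
  which are shared with the flipped form and carry no flip-state
  information — by at least 20 aligned bases, mirroring the tag-anchoring
  threshold. A shorter overlap can be manufactured by a forced gapped
  alignment of a flipped-clone read within the 6-edit budget; ≥ 20
  genuinely un-flipped-specific bases cannot.
* At equal edit distance the flipped-space interpretation of a pair is
  preferred over un-flipped evidence, and a direct construct alignment over
  a translated cassette alignment; both tie-breaks are deterministic.

## Duplicates, coverage, variants, verdicts

`remove_duplicates()` keeps one pair per (pool, clone, both mates'
position and strand); it is idempotent. `anchored_coverage()` counts a pair
only if its tag-side mate overlaps the tag by ≥ 20 aligned bases (exactly
20 counts), and reports per-base ROI coverage plus the fraction of tag
bases covered at least once over the union of the clone's two pools.

`call_variants()` forms a pileup from the deduplicated concordant pairs of
one pool, aggregates events by (position, ref, alt), and scores each
candidate with the phred-scaled binomial tail
`-10·log10 P(X ≥ k | n, e)`; calls with score < 20 are dropped. The
error-rate null `e` defaults to 0.01 and should be set to the library's
expected error rate. Indels are left-normalized against the reference
(VCF-style) before comparison, and the scenario scorer normalizes its truth
tables the same way, so representation differences cannot masquerade as
calls. `cross_confirm()` then requires the identical variant in both pools
with ≥ 3 *variant-supporting deduplicated reads* each. This is the stricter
of the two readings of "coverage of 3 or more reads" — the one under which
the duplicate-robustness property is meaningful, since duplicates may not
manufacture support; the site-depth reading is available via
`confirm_mode = "site_depth"`.

Clones flagged as un-flipped are not analysed further for mutations:
reads from an un-flipped cassette forced onto the flipped reference would
otherwise produce artifactual calls clustered at the FRT scar. Verdict
precedence is `no_data` (no tag-anchored pairs and no un-flipped evidence
in either pool) > `unflipped` > `mutated` (≥ 1 confirmed variant) >
`mutation_free_full` (tag coverage fraction 1) > `mutation_free_partial`.
By default the un-flipped flag itself requires evidence in **both** pools,
symmetric with variant confirmation; the original rule flagged on any
single read, and that single-read mode is available
(`require_both_pools_unflipped = FALSE`). Every run log records which mode
was used. Summary percentages are rounded half-up to one decimal, matching
how printed library tables report (e.g. 9580 of 10995 → 87.1%).

# Parameters at a glance

| parameter | default | unit | rationale |
|---|---|---|---|
| `arm_len` | 50 | bp | homology-arm length of the engineering protocol |
| `min_flank` | 2500 | bp | clone must extend this far beyond the gene on both sides |
| `insert_mean`, `insert_sd` | 3000, 1000 | bp | mate-pair size selection |
| `read_len` | 100 | bp | library read length |
| `insert_window` | [2200, 3700] | bp | concordant-mapping parameters; [2000, 4000] selectable |
| `min_anchor` | 20 | aligned bp | tag-anchoring threshold for coverage |
| `min_cov` | 3 | reads/pool | cross-pool confirmation threshold |
| `min_score` | 20 | phred | variant score cutoff |
| `error_rate` | 0.01 | /base | binomial null for the score |
| `depth` | 50 | × over ROI | simulation default; a config choice, not a claim |
| `k`, `max_edits`, `band` | 21, 6, 8 | — | mapper seeding, edit budget, max indel span |

# Problem sizes and what the tests show

The test suite exercises the full pipeline at the study's plate geometry: a
96-clone designed-defect plate at 50× per pool (~350k pairs) for parameter
recovery and duplicate robustness, a 24-clone defect-free plate for the
null pipeline (no calls, all clones fully covered), the same 96-clone plate
at 1× to demonstrate the sensitivity/coverage coupling of the ≥3-support
rule (expected per-pool support ~1 < 3, so nothing is confirmed and the
affected clones degrade to mutation-free categories), and exhaustive
deconvolution over all 96 wells. Statistical oracles (binomial counts for
the defect and oligo-error models, the insert-size mean, the score
arithmetic) are checked against closed forms at 3σ.

# Known limitations

* The mapper is a simplified functional equivalent: unique-best concordant
  placement, edits ≤ 6, indels up to the band width (8 bp). Structural
  variants beyond short indels, and clones whose genomic inserts genuinely
  overlap (possible in a real library when neighbouring fosmids share
  sequence), are out of scope; overlapping-insert reads would be discarded
  as cross-clone-ambiguous rather than misassigned.
* Variant calling is count-based; there are no base-quality-aware genotype
  likelihoods. Only the score < 20 filter of the original pipeline is
  reproduced; its caller's additional "standard filters" are not
  enumerated anywhere and are not modelled.
* Genome-scale figures from the original resource (gene coverage of the
  real fosmid library, library-wide mutation-free rates) depend on the
  external annotation and undeposited raw data; the package validates the
  operations on synthetic annotations and reproduces the printed
  percentages only as arithmetic of the summary reporter.
* Pools never span plates; plate identity is part of the barcode
  namespace. Whether the original study pooled across plates is not
  specified; per-plate pooling is assumed and configurable upstream.
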