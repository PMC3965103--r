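---
title: "Classifying microRNA loci from read-stack evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying microRNA loci from read-stack evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstack)
```

## The problem

Small RNA deep sequencing has made it cheap to propose new microRNA
loci, and correspondingly easy to annotate fragments of other
transcripts — rRNA, snoRNA, degradation products — as microRNAs. A
genuine, canonically processed microRNA leaves a characteristic
footprint in sequencing data: Drosha and Dicer excise a defined duplex
from the precursor hairpin, so reads pile up in two tight stacks, one
per arm, whose most abundant members pair in the hairpin structure with
a 2-nt 3' overhang at both duplex ends. `mirstack` evaluates that
footprint. Given hairpin precursors, mature annotations and one or more
read sets, it builds a per-arm read stack (counts summed across
datasets) and asks whether the pattern supports canonical processing,
contradicts it, or is simply too sparse to judge.

## The five criteria

A locus is called **high confidence** only if all five of the following
hold (all thresholds are fields of `thresholds()` and can be
overridden; the defaults below are the conventional published values):

1. **Read depth** — at least 10 reads map with zero mismatches to each
   of the two possible mature products (`min_reads_per_arm = 10`,
   inclusive).
2. **Duplex overhang** — the most abundant read from each arm, taken as
   the observed mature pair, must pair in the hairpin structure with a
   3' overhang of 0–4 nt at both duplex ends (`overhang_min = 0`,
   `overhang_max = 4`, inclusive).
3. **5'-end homogeneity** — at least 50% of the reads on each arm share
   the modal 5' end (`min_modal5p_fraction = 0.5`, inclusive). Drosha
   and Dicer cut precisely; ragged 5' ends are a hallmark of
   degradation fragments.
4. **Folding energy** — the hairpin's folding free energy must be
   strictly below −0.2 kcal/mol/nt (`max_energy_per_nt = -0.2`). This
   is the one strict inequality among the five: a locus at exactly
   −0.2 fails.
5. **Mature pairing** — at least 60% of the bases in the mature
   sequences are paired in the hairpin structure
   (`min_mature_paired_fraction = 0.6`, inclusive), counted over the
   union of the mature intervals.

The verdict maps the booleans to four outcomes, judged in the order
insufficiency before inconsistency:

* `HIGH_CONFIDENCE` — all five criteria hold;
* `INSUFFICIENT_EVIDENCE` — criterion 1 fails (by far the most common
  outcome on real collections: most annotations simply lack reads on
  one arm);
* `PATTERN_INCONSISTENT` — reads are plentiful but the overhang or
  homogeneity pattern (criteria 2–3) contradicts canonical processing;
* `STRUCTURE_FAIL` — the read pattern is canonical but the structure
  criteria (4–5) fail. This fourth verdict is our own extension: a
  well-read locus on a badly folding precursor fits none of the three
  read-pattern assertions, and collapsing it into either
  `PATTERN_INCONSISTENT` or `INSUFFICIENT_EVIDENCE` would misstate the
  evidence. It is flagged as such in reports.

Branched (multiloop) precursor structures are analyzed — the branch
carrying the most base pairs is treated as the microRNA hairpin — but
are never promoted to `HIGH_CONFIDENCE`; the demotion is recorded in
the call's notes rather than inventing a rejection rule for a case the
criteria do not address.

## Design choices in the geometry

**Coordinates.** All coordinates are 1-based inclusive, the native R
and GFF convention, both internally and in reports.

**Arm assignment.** The criteria speak of reads "mapping to" an arm
without defining it. A read counts toward an arm when it overlaps that
arm's mature locus by at least half the read's length
(`mature_overlap_fraction = 0.5`). This tolerates the templated 3'
trimming and tailing ubiquitous in small RNA data while excluding loop
fragments; reads spanning the whole terminal loop are tracked
separately and count toward neither arm.

**Summed counts.** The 10-read threshold is evaluated on counts summed
across all datasets, matching the convention of displaying one stack
with summed counts per locus. A per-dataset interpretation would make
the verdict depend on how a collection happens to be partitioned into
GEO/SRA accessions. For users who want the stricter reading, a
`per_dataset` flag requires the depth threshold to be met on both arms
within at least one single dataset; it is off by default.

**Star inference.** When only one arm carries an annotation, the
partner required by criterion 1 is inferred from the structure by
inverting the canonical duplex geometry: the star's 5' end is the
partner of the base 2 nt inside the mature's 3' end, and its 3' end
lies 2 nt beyond the partner of the mature's 5' end, walking inward
over unpaired bases before taking partners. On a perfectly paired stem
this construction returns a duplex with exactly (2, 2) overhangs —
a closed-form identity the test suite checks. Without inference, every
single-arm annotation would fail criterion 1 vacuously.

**Overhang arithmetic on imperfect duplexes.** Real duplex ends are
often unpaired. The overhang computation anchors each product's 5' end
on the nearest paired base walking 3'-ward, at most
`overhang_walk_limit = 5` nt, and folds the walked distance into the
overhang; if no paired base exists within the limit the overhang is
undefined and criterion 2 fails, with the reason recorded.

**Which duplex for criterion 2?** Annotated matures and observed reads
can disagree. The criterion is evaluated on the most-abundant-read
pair — the wording of the criterion refers to the most abundant reads,
and the reads are the evidence being judged — while the annotated-pair
geometry is computed and reported alongside
(`annotated_overhang_5p/3p` columns).

**Ties.** Modal 5' starts and most-abundant reads tie-break to the
smaller start, then the lexicographically smaller sequence, making
every verdict deterministic.

**Folding.** Structure input takes precedence over de novo folding
(`refold` forces recomputation); folding is delegated to `RNAfold`
(ViennaRNA) at its default temperature and parameter set, with the
engine version recorded in the run log. `energy_per_nt()` is the plain
ratio MFE/length.

## The synthetic locus generator

`locus_spec()` / `make_hairpin()` / `make_read_stack()` generate loci
with exactly controlled properties: a seeded, GC-controlled 5' arm; a
3' arm that is its reverse complement (a perfect stem); a poly-A loop
that stays unpaired under any reasonable model; matures placed so the
annotated duplex realizes requested overhangs exactly; and read stacks
with requested depth and modal 5' fraction, the non-modal remainder
spread round-robin over distinct offsets so no single off-modal start
can outweigh the modal one whenever the requested fraction is at least
0.5. Ground-truth structures are constructed, not folded, so
structure-dependent tests are independent of any folding engine; the
generator assigns a nominal stacking-style energy (−3.4 kcal/mol per GC
pair, −2.0 per AU) as a bookkeeping value, and a single test exercises
the real folding path separately.

`make_case()` produces the three read-pattern archetypes: `SUPPORTED`
(deep stacks on both arms, 2-nt overhangs), `ONE_ARM_ONLY` (reads on a
single arm) and `BAD_OVERHANG` (deep stacks pairing with a 7-nt
overhang). Defaults are a 35-bp stem, 6-nt loop, 80% GC, 22-nt matures,
100 reads per expressed arm at 90% 5' homogeneity with ±2 nt offset
noise — an idealization of a well-expressed, cleanly processed animal
microRNA.

What the generator does **not** emulate: sequencing error, adapter
contamination, cross-mapping between paralogous loci, expression
dynamics, and non-canonical biogenesis (mirtrons, Dicer-independent
loci such as mir-451 — which are expected to fail these criteria by
construction). Passing tests on synthetic loci therefore demonstrate
that the arithmetic and the decision logic are correct, not that the
thresholds are optimal for any particular real collection.

```{r archetypes}
cs <- make_case("SUPPORTED", seed = 1)
res <- analyze_locus(cs$hairpin, cs$matures, cs$read_sets)
res$call
```

## Problem sizes used in validation

The test suite validates against independent oracles at deliberately
modest scale: exact mapping against a naive all-offsets scan (500 reads
by 50 hairpins), pair tables against a recursive matcher (1,000 random
structures), archetype recovery over 100 seeds per archetype, and
1,000 randomized monotone-support perturbations — sizes at which the
brute-force oracles remain exact and the full suite runs in well under
a minute per file.

## Known limitations

* Only sense-strand, mismatch-free mapping is performed; the criteria
  define mapping as exact, so SNVs or editing sites in reads are
  invisible (such reads simply do not count).
* Cross-hairpin multi-mappers count at every locus they match, which
  can inflate support for paralogous families; within-hairpin
  multi-hits are flagged (`multi_hit`) in the report.
* The energy criterion inherits the folding engine's model; supplying
  structures folded under a different parameter set will move loci near
  the −0.2 kcal/mol/nt boundary.
* No multi-level confidence score is computed — the verdict is
  categorical, with manual overrides available through the override
  table.
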