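---
title: "Methods: consensus-based bHLH family characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-based bHLH family characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhlhfamily)
library(dplyr)
```

## The problem

Basic helix-loop-helix (bHLH) proteins form one of the largest plant
transcription-factor families. Family membership, DNA-binding potential and
gene structure are all read off one ~60-residue domain with four regions: a
basic region of about 17 residues, two amphipathic helices, and a loop of
variable length (most often six residues) between them. `bhlhfamily`
implements a complete desk pipeline for characterizing such a family from a
protein FASTA, a GTF annotation and a seed alignment of domain sequences:
domain detection under a consensus-mismatch criterion, residue-rule
classification of DNA-binding categories, intron-pattern taxonomy within
the domain's coding region, conservation statistics, and family-level
summaries with expression-threshold filters. A synthetic family generator
with recorded ground truth makes every stage testable without genome
downloads.

## Consensus profile and domain scan

`build_consensus()` reduces a seed alignment to one modal residue and one
conservation fraction per column. Columns at or above the threshold
(default 0.5 — a residue carried by at least half the seed domains) become
*consensus positions*; only these are compared during scanning, because
non-conserved columns carry no consensus residue to mismatch against. Two
denominator conventions exist for the fraction: the consensus builder
excludes gaps by default (the modal residue among aligned residues) while
`column_conservation()` counts gap rows in the denominator by default,
since a statement like "conserved in at least half the domains" counts
domains, not non-gap characters. Both functions expose both conventions
through `gap_denominator`.

`locate_domain()` scans every start offset and every loop length in
`loop_range` (default 5–15). The loop is treated as elastic: consensus
loop positions are compared against the first `min(candidate, consensus)`
loop residues and surplus residues are uncounted, so a 9-residue loop is
not penalized merely for being long. The placement minimizing total
mismatches at consensus positions wins; ties are resolved by smaller
deviation of the loop from its mode (6), then smaller start, then smaller
loop length — the last key added because two loop lengths can tie at equal
deviation (5 and 7) at the same start, and every tie must break
deterministically. `X` and gap characters never match.

Acceptance uses the low-stringency family-membership rule: a candidate is a
family member when its total mismatch count is at most `max_mismatches`
(default 12). The budget is applied to the whole domain, with per-region
counts always reported; optional `per_region_caps` lets users bound
regions individually, since published descriptions of region-wise counting
leave either reading open.

The packaged seed (`toy_seed_alignment()`, 8 rows × 60 columns) is fully
synthetic. Its HLH block is strongly conserved — 41 of 43 columns at or
above threshold, three of them exactly at 0.5 and two just below, so the
threshold boundary is exercised — while every basic-region column is
variable. Consensus matching therefore reads the HLH consensus only,
matching the membership criterion's intent and leaving the basic region
free to vary with binding category. Users with a real domain alignment
(for example a full-family supplementary alignment) can pass it to
`build_consensus()` unchanged; the published full-family profile is not
redistributable here, so no claim is made that the toy seed reproduces
per-gene published calls.

## Binding classification

`classify_binding()` reads the located basic region (domain positions
1–17). The rules, stated on 1-based domain coordinates:

* at least 5 basic residues → DNA binder; fewer → tentative non-binder;
* Glu-13 and Arg-16 → E-box recognition;
* His/Lys-9 and Arg-17 (in addition) → G-box specificity;
* below 5 basic residues, the same motifs rescue a domain as a
  *potential* G-box or E-box binder.

This yields six mutually exclusive categories (`G_binder`, `E_non_G`,
`non_E_binder`, `potential_E_box`, `potential_G_box`, `non_binder`) that
nest as G binders ⊆ E-box binders ⊆ DNA binders. The basic set is
{Arg, Lys, His}; His is included because the G-box rule itself treats
His-9 as functional, and the set is configurable. The ≥5 threshold has no
upper cap: observed ranges of 5–11 in real families describe data, not the
rule. A non-standard residue at a rule position counts as a non-match and
is logged.

## Intron patterns

Intron positions and phases are recovered from the GTF alone. For each
junction between consecutive CDS pieces (taken in transcription order, so
strand handling is automatic), the number of coding nucleotides upstream
of the intron is intersected with the domain's CDS interval
(`3*(start-1)+1 .. 3*end`). Interior junctions become events
`(domain_codon, phase)` with phase = nucleotides of the interrupted codon
lying 5′ of the intron (0 = between codons). A junction carrying zero
domain nucleotides on one side (an intron exactly at either domain
boundary) is not an interior event; reporting it would place an intron at
codon 0 or beyond the last codon, so the implementation requires at least
one domain nucleotide on each side.

`assign_patterns()` normalizes event positions onto a 60-residue scale and
matches them against a registry: same intron count, equal phases, every
position within ±2 residues (configurable). Unmatched signatures found new
entries labelled `A`, `B`, … in first-encounter order over
lexicographically sorted transcript ids, making labels independent of
input order; intronless domains take the reserved `intronless` label.
Registry letters are local to a run — published pattern letters for a
specific family can be aliased onto them but are not themselves
recoverable without that family's per-gene data. Domains of different
lengths normalize the same codon to slightly different scaled positions,
so a blueprint planted across length variants can legitimately split into
neighbouring registry entries; truth-recovery checks therefore compare raw
`(codon, phase)` signatures, while the registry is checked for determinism
and tolerance behaviour.

`gene_structure_stats()` adds exon counts, intronless flags (one
CDS-bearing exon) and symmetric phase-zero exons (internal CDS exons
flanked by two phase-0 introns, the configuration favouring exon
shuffling).

## Family summaries and expression filters

`genome_fraction()`, `chromosome_distribution()`,
`tabulate_categories()`/`derive_aggregates()` and
`pattern_distribution()` produce the family-level tables. All printed
percentages round half-up to two decimals (`round_half_up()`), matching
the conventional printed style; base R's half-to-even rounding would
differ on exact halves.

`select_representative()` picks one transcript per gene: fewest consensus
mismatches, then longest protein, then smallest transcript id.

`expression_filter()` keeps the deliberately mixed boundary semantics of
the conventional thresholds: strictly greater than 10 for TPM, at least 5
for FPKM/RPKM. `select_degs()` uses fold change ≥ 2 — interpreted as
|log2FC| ≥ 1 in either direction, since up- and down-regulated sets are
both reported under the single cutoff — with adjusted p ≤ 0.05, both
boundaries inclusive. The pipeline consumes precomputed expression and DE
tables; count-model fitting is out of scope.

## The synthetic generator

`generate_family()` emulates the statistical structure the analysis
assumes, with defaults chosen once as the study conditions:

* binding-category mix proportional to the wheat contingency row
  (291/85/84/8/3/100 over 571);
* subgenome fractions proportional to 176/193/183 with a 19/571 scaffold
  fraction;
* loop lengths over 5–15 with mode 6 at 64%, giving the 60-residue domain
  mode;
* intron blueprints covering an intronless class (20%), a single phase-0
  loop intron (35%, the most common observed pattern type), three phase-0
  introns (20%), and two rarer signatures (a phase-1 helix-1 intron and a
  phase-2/phase-0 pair); intron lengths uniform 60–300 nt, since observed
  lengths vary even at one position and only positions and phases matter
  downstream;
* expression classes 35% tissue-specific / 45% broad / 20% silent over a
  five-organ panel.

The basic region is constructed per category: rule residues are planted,
extra basic residues are added at free positions to a target drawn from
the category's feasible range, and impossible requests (a G-box category
with fewer basic residues than its own forced residues) fail before
generation. Substitution noise applies to the helix1/loop/helix2 block and
never to the basic region or rule positions, so the recorded category is
consistent with the emitted residues at every noise level; degradation
under noise enters through domain mislocation, which is what the mismatch
criterion governs. Back-translation uses the lexicographically first codon
per amino acid — a fixed slice of the genetic code — so gene models are
reproducible without a genome; the stop codon is excluded from the CDS,
one documented choice among GTF dialects. Gene models carry UTRs on the
terminal exons, mixed strands (minus-strand models are mirrored layouts),
and GTF frames computed from cumulative coding length.

`generate_expression()` builds values whose classes are separable by
construction: tissue-specific genes exceed 10 units only in their tissue
(elsewhere below 5), broad genes exceed 10 everywhere, silent genes stay
below 5 everywhere; log-normal spread sits on top of those floors. The DE
table carries true log2 fold changes plus Gaussian noise (`dispersion`,
default 0.15) and adjusted-p placeholders consistent with effect
direction. This generated table stands in for a fitted count model
deliberately: downstream filters only read thresholds.

What passing tests on this generator do **not** show: recovery on real
proteomes with degenerate domains, multi-domain proteins, alternative
transcripts per gene in the GTF, alignment gaps in candidate domains
(candidates are compared ungapped), or realistic expression dispersion.
The generator fixes one domain backbone; real families vary outside rule
positions far more.

## Numerical and degenerate-input choices

* All randomness flows through a single integer seed per generator call;
  identical spec + seed reproduces files byte-for-byte.
* All-gap alignment columns are retained with a sentinel residue and zero
  fraction and carry no ungapped coordinate; all-gap rows are accepted
  with a warning.
* Proteins shorter than the minimal domain (basic + helix1 + loop_min +
  helix2) yield no hit rather than an error.
* Empty accepted-hit sets produce empty (not missing) distribution tables.
* Report assembly (`assemble_report()`) writes no timestamps, so bundles
  are byte-deterministic and re-runs can be diffed.

## Problem sizes used in the tests

The test-suite and the acceptance script use synthetic families of 10–200
genes, 50 proteins for the brute-force placement cross-check, the
exhaustive 60 × 3 codon-phase round-trip, and 100 seeded replicates for
fold-change recovery. These sizes make every property check exact or
tightly bounded while keeping a full run around a minute and a half.

## Known limitations

* The scanner performs ungapped comparison against the consensus; a single
  indel inside a real domain shifts downstream positions and inflates
  mismatches. Profile-HMM scoring is explicitly out of scope.
* Registry letters are corpus-relative; comparisons across runs require
  carrying the registry forward (`assign_patterns(registry = ...)`).
* Published per-gene catalogs, full-family conserved-position counts and
  published pattern letter assignments require the original genome
  releases and supplementary alignments, which this package does not
  redistribute; the package reproduces the published summary arithmetic
  and validates the mechanisms on ground-truthed synthetic data instead.
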