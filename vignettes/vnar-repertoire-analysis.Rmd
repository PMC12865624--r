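---
title: "Characterizing vNAR repertoires: annotation, typing, diversity and biopanning analysis"
author: "vnartools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing vNAR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnartools)
```

## The problem

The variable domain of the shark new antigen receptor (vNAR) is a ~12 kDa
single-domain antibody with two antigen-contacting loops (CDR1 and CDR3 —
vNARs lack CDR2) and two additional hypervariable loops (HV2, HV4) on an
Ig-fold scaffold stapled by a canonical disulfide between two conserved
cysteines near positions 22 and 83. Naive vNAR phage-display libraries are
characterized by (i) how many cloned inserts are complete and in frame,
(ii) how the repertoire distributes over the classical vNAR types I-IV,
defined by noncanonical cysteine patterns in CDR1/CDR3, (iii) CDR3 length
and cysteine diversity, and (iv) how biopanning enriches binders round by
round. `vnartools` implements that characterization as a tested pipeline:

1. `read_sequences()` / `translate_repertoire()` — parse FASTA/FASTQ,
   locate the NcoI/NotI cloning flanks, translate, and flag defective
   ("bald") clones;
2. `annotate_repertoire()` — delimit FR1/CDR1/FR2/HV2/FR3a/HV4/FR3b/CDR3/FR4;
3. `classify_repertoire()` — assign types I/IIa/IIb/III/IV;
4. `summarize_repertoire()`, `unique_cdr3_partition()`,
   `cdr3_length_stats()` — diversity statistics;
5. `call_positive()`, `summarize_round()`, `summarize_antigen()`,
   `enrichment_trajectory()` — ELISA/biopanning screening arithmetic;
6. `generate_library()` / `generate_panning_dataset()` — seeded synthetic
   data with ground-truth labels for validating every stage.

## Insert quality control

Cloned inserts are expected to carry the NcoI site (`CCATGG`) at the 5'
end and the NotI site (`GCGGCCGC`) at the 3' end; the ATG embedded in
`CCATGG` is the initiator codon. `detect_flanks()` searches both motifs
exactly (no mismatches: library screening is done by colony PCR/digest,
and the synthetic generator controls defects explicitly). When a motif
repeats, the first 5' occurrence is paired with the last downstream 3'
occurrence, which maximizes the recovered insert. Both motifs are
palindromes, so strand orientation is decided by which strand carries a
valid 5'-then-3' arrangement, not by motif presence alone; reads
recovered on the reverse strand are recorded as such.

`translate_repertoire()` translates from that ATG to the last full codon
before the 3' flank under the standard genetic code and sets
`premature_stop`, `frameshift` (coding length not a multiple of 3),
`untranslatable` (no ATG under the flank policy), `missing_5p_flank` /
`missing_3p_flank`, and `too_short`. A protein is reported only when none
of the fatal flags fire; `too_short` (default minimum 80 aa, against a
~100-115 aa domain) keeps the protein but marks the record. Reads lacking
a flank are excluded from annotation and all downstream statistics by
default (`complete_only = TRUE`) while remaining countable in QC reports —
how such reads were handled in the original NGS analysis is not
documented, so the exclusion is this package's explicit policy. FASTQ
qualities are summarized (mean Phred) but never used for filtering.

## Region annotation by cysteine anchoring

Published vNAR structures give fixed coordinates on a 112-residue frame:
CDR1 25-33, HV2 44-51, HV4 60-65, CDR3 87-96, with the canonical
disulfide Cys22-Cys83. No IMGT/Kabat-style renumbering is in common use
for these domains, so `annotate_repertoire()` generalizes the fixed
coordinates by *anchor offsets*: each canonical cysteine is located as
the Cys nearest its reference position (windows 22±3 and 83±6,
configurable; equidistant ties go N-terminal), and every boundary is an
offset from an anchor — FR1 ends at `cys1 + 2`, CDR1 is the next 9
residues (fixed width; indels are pushed into FR2 because CDR1 diversity
is limited), HV2/HV4 are fixed offsets from `cys1`, FR3b ends at
`cys2 + 3`, CDR3 starts at `cys2 + 4`, and FR4 starts at the first match
of the framework anchor motif `[YW]G.G` at or after the CDR3 start (the
literature states no canonical FR4 motif; the default is the
`YGAGTVLTVN`-style framework tail pattern and is configurable). This
anchor-offset scheme is a reconstruction — the original repertoire
analysis does not state how CDR3 was delimited on length-variant reads —
and is therefore exercised hard by the test suite: on every defect-free
synthetic clone the scheme must recover the generator's ground-truth
CDR3 span exactly, and the nine spans must tile `1..length` with no gaps
or overlaps.

Clones missing an anchor or the FR4 motif get `annotation_status =
"no_anchor"`; clones whose anchors imply incoherent spans (any empty
region other than CDR3, broken contiguity, or CDR3 length outside 4-34)
get `"atypical_spacing"`. Both are excluded from typing and diversity
statistics but are retained for QC accounting.

## Type classification

Types are assigned from loop cysteines, in strict precedence:

| order | label | evidence |
|---|---|---|
| 1 | III | CDR1 has Cys at scheme position 29 *and* Trp at 30 |
| 2 | IIa | >=1 Cys in CDR1 and >=1 Cys in CDR3 (interloop pair) |
| 3 | I | Cys-free CDR1, even CDR3 Cys count >= 2 |
| 4 | IIb | Cys in exactly one loop |
| 5 | IV | no noncanonical Cys in either loop |

The textual definitions of the types overlap (a clone with cysteines in
both loops and an even CDR3 count satisfies both the type-I and type-IIa
descriptions); the precedence resolves every overlap in favor of the
interloop-capable interpretation, matching the description of IIa as the
"typical" type II. Three further decisions are documented toggles: a
lone CDR1 Cys with Trp at 30 but not at 29 is *not* type III (the rule
requires both positions); odd CDR3 counts with a Cys-free CDR1 are IIb
(type I's even count is what enables paired linkages); CDR1 cysteines
are counted anywhere in 25-33, not only at 29 — whether the original
analysis restricted the position is unstated. The canonical Cys22/Cys83
never enter the counts (they lie in framework spans), and HV2/HV4
cysteines are ignored for typing but raise a warning. A property test
enumerates the full evidence space (CDR1 Cys configurations × Trp30 ×
CDR3 counts 0-5) and checks that exactly one rule fires and that the
label agrees with an independent restatement of the rules.

## Diversity statistics

Uniqueness is defined on the full translated protein (the repertoire
figure of merit is unique *protein* sequences, not nucleotide variants).
`unique_cdr3_partition()` splits unique clones into those whose CDR3
occurs in exactly one clone versus those sharing a CDR3 but differing in
FR/CDR1/HV regions. Percentages are computed by *round-half-up* at the
printed precision (one decimal for type shares, integer for CDR3
statistics): this matches most published values, though printed numbers
of this kind are sometimes truncated instead (e.g. 23.95 printed as
23.9), so the convention is explicit in `round_half_up()` and used
consistently. The CDR3 cysteine histogram is computed over *distinct*
CDR3 strings, matching the usual "proportion of CDR3 sequences"
presentation. `cdr1_variability_pct` is the share of clones whose CDR1
differs from the modal CDR1 string — the literature's "~6% CDR1
diversity" has no operational definition, so this one is stated and
testable; note that on synthetic libraries every type-IIa/III clone
carries an engineered CDR1 cysteine and thus differs from the modal
CDR1, so this statistic is structurally larger there than in real data.

## Biopanning and ELISA analysis

A clone is phage-ELISA positive when its antigen OD is at least four
times the *maximum* negative-control OD (BSA, milk, unrelated antigen);
the maximum is the most conservative reading of "compared to negative
antigens", and whether the original rule used mean or max is unstated
(configurable). The threshold is inclusive (`fold >= 4`). Consistency
across replicate assays is required via `min_replicates` (default 3,
matching triplicate confirmation). Positive clones are binned by mean
antigen OD: high (> 1.0), medium (0.5-1.0, with 1.0 assigned to medium
because "high" is defined as strictly above 1.0), low (< 0.5).
`enrichment_trajectory()` reports — but never enforces — the expected
pattern of nondecreasing positivity and nonincreasing uniqueness across
rounds. One published screening sentence ("~1% of clones were
antigen-positive (3/30)") is arithmetically inconsistent with its own
counts; the package always reports the count-derived percentage (3/30 =
10%).

## The synthetic repertoire generator

No sequence data for the characterized library is deposited, so the
generator is the pipeline's test bed. It emulates the *statistical
structure* of a naive vNAR library, not its sequence content:

* **Scaffold.** A single fixed framework (canonical Cys at 22/83, Leu31
  in CDR1, FR4 tail `YGAGTVLTVN`) with a per-position substitution rate
  (default 0.005) over non-anchor framework/HV positions, from an
  alphabet excluding Cys and Trp so that typing evidence is never
  perturbed. No framework consensus for the source library is available,
  so a learned position-specific profile is out of reach; this is the
  generator's main departure from real data, and passing tests
  demonstrate pipeline correctness, not biological realism of the
  framework.
* **Composition.** Type proportions default to the sequenced naive
  library's composition; per-type counts are fixed by largest-remainder
  apportionment rather than multinomial sampling, so small libraries
  match their spec exactly and composition-recovery tests are exact. The
  `fig3a_spec()` preset encodes the published per-type counts (36,256 I /
  57,112 IIa / 98,849 IIb / 8 III / 46,190 IV) for scaled replication.
* **CDR3.** Lengths are drawn from a discretized normal on 6-28 centred
  at 15.5 with sd 1.483, chosen once so the 15-16 band carries ~50% of
  the mass — the published range and modal band are the only quantitative
  constraints available, the rest of the shape is this package's choice.
  Residues are uniform over the 19 non-Cys amino acids; label-required
  cysteines (and Cys29/Trp30 for type III) are placed explicitly, and any
  CDR3 that would contain the FR4 anchor pattern (including across the
  CDR3/FR4 junction) is resampled so annotation is exact on defect-free
  clones. CDR1 carries Leu31 with probability 0.95 and one substitution
  with probability 0.06.
* **Defects and duplicates** are applied by count (half-up of
  `rate × n`), on disjoint clones, after construction: `missing_flank`
  deletes one cloning site and scrubs accidental motif occurrences (both
  motifs are palindromic, so forward-strand scrubbing covers the reverse
  complement too); `premature_stop` rewrites one mid-insert codon to a
  stop; `frameshift` deletes a single nucleotide. Defaults (3% / 2% / 1%)
  are consistent with >97% complete inserts and >90% functional clones in
  a well-built library; the `fig3a_spec()` preset is defect-free because
  it models already-QC'ed unique protein sequences.
* **Nucleotides.** Proteins are reverse-translated with uniformly sampled
  synonymous codons; the initiator ATG plus a fixed Ala codon (GCN)
  reconstitute the NcoI site. PCR amplification bias, polymerase error
  spectra and phage growth competition are not modeled.
* **Randomness.** One seed drives every draw via a local RNG scope
  (`.Random.seed` is restored), so generation is byte-reproducible and
  never disturbs the caller's RNG stream.

The ELISA generator plants binders by count per round, draws negative
controls uniform on [0.04, 0.12], binder antigen ODs from N(1.08, 0.15)
truncated below at four times the well's largest negative (so planted
truth and the four-fold rule agree by construction), and non-binder ODs
strictly below that threshold. The binder OD model puts ~70% of binders
above 1.0 OD, the high-OD share characteristic of a late panning round.

## Numerical choices and degenerate inputs

Half-up rounding throughout (`floor(x·10^d + 0.5)/10^d`); anchor ties go
N-terminal; empty inputs raise errors rather than returning NaN
(`completeness_rate()`, `summarize_round()`, `cdr3_length_stats()`,
`leu31_fraction()`); an all-zero negative-control well leaves the fold
undefined and the record flagged, never positive; duplicate FASTA ids
are an error naming the id. Largest-remainder ties are broken by input
order.

## Problem sizes

The test suite exercises libraries of 50-10,000 clones and the
full-pipeline composition check runs the tenth-scale preset (23,841
clones, ~10 s); these sizes give exact count-apportionment checks and
3-standard-error windows for the stochastic ones while keeping the suite
fast. The same tenth-scale run is what `scripts/acceptance.R` reports.

```{r pipeline, eval = FALSE}
lib <- generate_library(fig3a_spec(scale = 0.1, seed = 1))
records <- translate_repertoire(lib)
maps <- annotate_repertoire(records)
calls <- classify_repertoire(maps)
summarize_repertoire(calls, maps)
```

## Known limitations

* The anchor-offset region scheme is a documented reconstruction; clones
  with unusual anchor spacing are set aside rather than force-fitted.
* The fixed-scaffold generator cannot probe robustness to framework
  indels or to libraries whose anchors drift outside the search windows.
* CDR1 width is fixed at 9; true CDR1 length variants would surface as
  FR2 differences.
* No rarefaction or diversity indices (Shannon, Chao1) — the
  characterization summarized here does not use them.
* BLI kinetics, phylogenetics and structural analysis are out of scope.
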