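---
title: "Screening mitochondrial genomes for candidate pathogenic tRNA mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening mitochondrial genomes for candidate pathogenic tRNA mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

## The problem

Human mitochondrial DNA (mtDNA) is a 16,569 bp circular genome inherited
strictly through the maternal line, usually homoplasmically: every copy in
a carrier's cells bears the same allele, and every child of a carrier
mother is a carrier. When a phenotype — here, obesity segregating among
matrilineal relatives of a pediatric proband — tracks the maternal line,
complete mtDNA sequencing of the proband against the revised Cambridge
Reference Sequence (rCRS) typically yields a few dozen differences, almost
all of them benign lineage (haplogroup) markers. The analytic task is to
separate a plausible candidate mutation from that background. `mitoscreen`
implements the whole desk-side part of such a screen as tested,
deterministic code.

## The screening model

A proband genome is compared with the circular reference by an anchored
two-pointer scan (`extract_variants()`), yielding point variants in
heavy-strand coordinates (`m.<pos><ref>><alt>`). Each variant is annotated
against a bundled gene map; for genes encoded on the light strand (such as
the tRNA-Cys gene MT-TC), alleles are complemented, so the heavy-strand
`5802 T>C` reads `m.5802A>G` in gene notation. Coding substitutions are
translated under the vertebrate mitochondrial genetic code (stop-affecting
changes are classed `other`; the study data contain none).

Candidates must then pass three criteria, each a strict inequality with
configurable thresholds defaulting to the screen's definitions:

1. **Rarity** — carried by fewer than 1% of matched controls
   (`control_frequency()`, here a 106-subject cohort).
2. **Conservation** — a conservation index (CI) above 75%. For a tRNA
   position the CI is the percentage of non-human species in a
   multi-species alignment whose base equals the human wild-type base
   (`conservation_index()`).
3. **Structural potential** — the position lies where a change can disturb
   the cloverleaf: a paired stem position or the anticodon loop
   (`structural_flag()`). The argument for the screened variant is the
   disrupted 30–40 anticodon-stem pair.

A variant is a `candidate` only if all three hold; a variant failing any
present criterion is `not_candidate`; if a criterion's input is absent
(e.g. no structural model outside tRNAs) and nothing already fails, the
verdict is `indeterminate`. This encodes, rather than hides, the fact that
the structural criterion is only defined for tRNA screening. Differences
in carrier frequency can be tested with `fisher_exact()`, a two-sided
Fisher's exact test computed by hypergeometric enumeration (sum of tables
no more probable than the observed one); the test suite checks it against
`stats::fisher.test()` over every 2×2 table with margins ≤ 12.

## Coordinates, strands and the cloverleaf

All genome coordinates are 1-based, inclusive, heavy-strand, and wrap
modulo the genome length; the control region (16024..576) is the only
bundled feature that wraps the origin. Overlapping annotations (e.g.
MT-ATP8/MT-ATP6) are resolved deterministically — tRNA > rRNA >
protein-coding > control region, then smaller start — so every position
maps to exactly one gene, as a published variant table assumes.

tRNA positions use canonical cloverleaf numbering (anticodon 34–36,
discriminator 73). The alignment dialect is block-structured: fixed-width
stem blocks anchored at canonical positions 1, 8, 10, 22, 26, 27, 32, 39,
44, 49, 61, 66 and 73, and ragged loop blocks that we treat as
left-aligned. Mapping a genome position into this numbering walks the
human row of the alignment (`genome_to_trna_position()`): genome 5802,
the 25th base of the 66 nt tRNA-Cys gene read on the light strand, lands
on canonical position 30 because the human D-loop block holds only 3 of
its 8 canonical slots.

Gap policy: a gap in a non-human row counts as a mismatch (the row is in
the denominator); a gap in the human row makes the CI undefined there,
since the index is anchored on the human wild-type base. The denominator
is the non-human rows by default (configurable to include the human row).
With no comparison rows at all the CI is reported as 100 (vacuously
conserved) — the single-species edge case.

### A surfaced discrepancy

Computed from the bundled 17-species alignment exactly as printed, the CI
at position 30 is 93.75% (15 of 16 non-human rows; the *Lemur catta*
anticodon-stem block reads `TTGGA`, whose fourth column is G where the
human base is A). Prose accounts of this alignment sometimes state 100%
conservation at this site. The package computes from the data and reports
93.75; the screening conclusion is unchanged because the criterion is
`> 75%`. We deliberately do not force the rounder number.

## The synthetic data, and what it does not show

Every input the pipeline consumes can be generated (`sim_config()` and
the `generate_*()` functions), so all stages are testable offline. The
defaults are the study's conditions: a 16,569 bp genome; a 47-variant
proband (the published table shipped as a fixture); a 106-subject control
cohort in which the candidate variant is absent (carrier frequency 0) and
the haplogroup backbone is common (each control carries it with
probability 0.5 — a deliberate, realistic choice for same-region controls
that also guarantees every backbone variant fails the <1% criterion); and
a 17-species alignment. One master seed derives an independent stream per
sub-generator, so generators are bit-reproducible and mutually
independent.

The reference the simulations use is a **synthetic surrogate**, not the
true rCRS, which is not redistributed here.
`generate_surrogate_reference()` pins, at every position the variant
table touches, the printed reference allele; for coding substitutions it
solves for a whole codon (on the gene's strand) consistent with the
printed silent/missense annotation — e.g. positions 13753/13754 share the
Ser473 codon `TC(T/C)`, and 13775/13776 share the `ACA` Thr480 codon, so
one codon must satisfy both constraints at once. Everything else is
random. Classification is always *computed* from this sequence; nothing
is looked up from the table at test time. What passing tests therefore
show is that the machinery (strand logic, codon indexing, mitochondrial
code, partition bookkeeping) reproduces the published classification on a
genome consistent with the published table — not that we have re-derived
the annotations from the true rCRS. Supplying a genuine `NC_012920`
FASTA to `load_reference()` runs the identical analysis on the real
genome.

Similarly, the pedigree, the child BMI percentile cutoffs and the
haplogroup marker database are clearly-labelled demo fixtures: the
published pedigree figure is not machine-readable, the national BMI
reference tables are cited but not reprinted, and the defining markers of
haplogroup D4 are not enumerated in the source. Analyses over these files
demonstrate the operations, not clinical values. The simulators also do
not model heteroplasmy, read-level data, back-mutation, or mutation-rate
processes.

## Numerical and design choices

* **Variant extraction** is an anchored scan, not pairwise alignment:
  indels (≤ 5 bp) must re-anchor on 10 exact matching bases, while
  substitutions may cluster (the published table contains adjacent pairs
  such as 13753/13754). A run of more than 15 in-register mismatches
  aborts with an "ambiguous region" error rather than guessing. Indel
  calls are left-aligned by construction because scanning stops at the
  first divergent base.
* **BMI** is weight/height² reported to one decimal with
  half-away-from-zero rounding, matching clinical tables (base `round()`
  is banker's rounding and would give 20.2 for 20.25).
* **Obesity classes** use strict inequalities ("more than the 95th/99th
  percentile"); a child whose age/sex band is missing from the cutoff
  table is an error, never a silent default. Adults fall back to the
  Chinese adult convention (overweight > 24, obese > 28 kg/m²), which
  classes a BMI of 25.7 as overweight.
* **Haplogroup matching** is flat marker-set concordance (fraction of a
  haplogroup's defining markers present), ranked with lexicographic
  tie-breaks — sufficient for a backbone-coincidence claim, and honestly
  far short of phylogenetic haplogroup calling.
* **Matrilineal summaries** follow mother links only; the matriline is
  everyone whose maternal chain reaches the proband's founding matriarch,
  males included (they carry but do not transmit). Cycles are rejected,
  and carrier sets violating strict maternal transmission are rejected at
  pedigree construction.

## Problem sizes

The test suite and the analysis scripts run at the study's own scale: one
16.6 kb proband genome, 106 control genomes, a 17 × 15-block alignment.
Property suites use 200 random 2 kb genomes for round-trip identity,
every 2×2 table with margins ≤ 12 for the exact test, three match
probabilities (0.5/0.75/0.9) for CI parameter recovery, and 100 random
pedigrees for transmission — sizes chosen to exercise the invariants
densely while staying desk-scale.

## Known limitations

Heteroplasmy is carried as a flag, never quantified; there is no
read-level (FASTQ/BAM) support and no structural-variant handling. The
structural criterion is membership in a stem or the anticodon loop — a
deliberate, computable stand-in for biophysical evidence such as
molecular-dynamics simulation, which is out of scope. Non-tRNA variants
receive an `indeterminate` verdict when they pass rarity and
conservation, encoding the screen's silence about their structural
assessment rather than inventing one.
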