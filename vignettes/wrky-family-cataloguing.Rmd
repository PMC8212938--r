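---
title: "Cataloguing a WRKY transcription factor family in an allohexaploid proteome"
author: "wrkycatalog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing a WRKY transcription factor family in an allohexaploid proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkycatalog)
```

## The problem

WRKY transcription factors form one of the largest regulatory families in
plants. A WRKY protein is defined by a ~60-residue DNA-binding domain that
opens with the heptapeptide **WRKYGQK** and closes with a zinc-finger motif;
it binds the W-box element (C/T)TGAC(T/C) in target promoters. The family
divides structurally into group I (two WRKY domains), group II (one domain
plus a **C2H2** zinc finger, with subgroups IIa–IIe) and group III (one
domain plus a **C2HC**, also written CCHC, zinc finger).

Bread wheat (*Triticum aestivum*) is allohexaploid: three diverged diploid
subgenomes (A, B and D) coexist, organised into seven homeologous
chromosome complements (1A/1B/1D … 7A/7B/7D). A wheat "gene" in the
family-catalogue sense is therefore a **homeolog group**: up to three
corresponding copies, at most one per subgenome, all on one complement. A
complete set is a triad (type A:B:D); gene loss leaves pairs (A:B, A:D,
B:D) or singletons (A, B, D). Cataloguing the family means: find all
members in the proteome, collapse splice isoforms, infer which copies are
homeologs of one another, name the genes systematically, classify them into
WRKY groups, and summarise homeolog retention.

`wrkycatalog` implements that workflow end to end, together with a seeded
simulator of allohexaploid proteomes so that every stage can be exercised
and validated without any external download, plus small expression
utilities (log2-TPM transformation, a multi-stress responsiveness filter,
and qPCR quantification by the 2^−ΔΔCt method).

## Domain detection: a deterministic motif scanner

Published family surveys typically locate the WRKY domain with a profile
HMM (hmmsearch against the Pfam WRKY model) followed by a conserved-domain
check. `find_wrky_domains()` replaces that stochastic scoring stack with a
deterministic motif scanner, which we prefer here because its behaviour is
exactly specifiable and testable:

* **Heptapeptide.** All non-overlapping, left-to-right occurrences of an
  allowed heptapeptide. The default set is `WRKYGQK` plus the common
  natural variants `WRKYGKK` and `WRKYGEK`; a strict mode restricts to the
  canonical `WRKYGQK`. The simulator only ever plants `WRKYGQK`, so results
  on synthetic data are identical in both modes.
* **Zinc finger.** Downstream of each heptapeptide the scanner looks for
  C2H2 (`C-x(4,5)-C-x(22,23)-H-x-H`) or C2HC (`C-x(7)-C-x(23)-H-x-C`). The
  first cysteine must lie within `max_zf_gap` residues of the heptapeptide
  end; the default of 60 matches the span of the canonical ~60-aa domain.
  If both patterns match, the one starting nearer the heptapeptide wins,
  with exact ties going to C2H2. A domain with no finger in range is
  reported with type `none` rather than dropped.

This is a surrogate for, not a reproduction of, HMM scoring: no E-values
are computed, and borderline degenerate domains that a profile HMM would
score past a threshold are out of scope.

Classification (`call_major_group()`) then follows the structural rule
table — two or more domains → group I; one domain + C2HC → group III; one
domain + C2H2 → group II. When a protein's domains disagree on finger type,
the C-terminal domain decides, because the C-terminal domain is the
classifying one in two-domain proteins. Group II subgroups are resolved
separately (`resolve_subgroup()`) as the label of the nearest labelled
reference protein by patristic distance in a joint tree, with exact ties
broken alphabetically — a deterministic stand-in for the usual visual clade
assignment against an *Arabidopsis* reference panel, which remains a user
input since no canonical panel is bundled.

## Isoform collapse

Annotation releases list one protein per splice isoform
(`accession.1`, `accession.2`, …). `collapse_isoforms()` keeps, per gene
accession, the record with the smallest isoform index — the "first isoform"
convention of family surveys — and orders the result by complement,
subgenome and start coordinate. The operation is idempotent and refuses
duplicated (gene, isoform) pairs.

## Alignment and tree

The phylogenetic engine is written for exact testability rather than raw
speed, with the inner dynamic programs in C++:

* `pairwise_global_align()` is Needleman–Wunsch/Gotoh affine-gap global
  alignment. A gap of length L costs `gap_open + (L−1)·gap_extend`
  (defaults −10/−1 with BLOSUM62; the original analyses do not state their
  parameters, so these widely used defaults are a package decision).
  Traceback ties prefer diagonal, then vertical, then horizontal moves, so
  alignments are fully deterministic. The test suite checks optimality
  against exhaustive enumeration of every alignment for short sequences and
  against an independent implementation for longer ones.
* `progressive_msa()` is guide-tree progressive alignment: UPGMA (average
  linkage) on 3-mer cosine distances for the guide tree, then
  profile–profile alignment where a column pair scores the mean of all
  residue-pair substitution scores, gap pairs scoring zero. Degapping any
  row returns the input sequence unchanged.
* `distance_from_alignment()` offers the p-distance (mismatches over
  comparable columns, pairwise deletion of gapped columns) and its Poisson
  correction −ln(1−p). p-distance is the default, as in the common NJ
  desktop tools. A pair with no comparable column is an error by default;
  the pipeline and the bootstrap instead assign such saturated pairs the
  maximal distance 1, since in a family-wide alignment they only ever arise
  between unrelated members.
* `neighbor_joining()` is canonical NJ on the Q criterion
  `Q(i,j) = (n−2)·d(i,j) − R_i − R_j`. Ties on Q break to the smallest
  index pair; negative branch lengths are clamped to zero with the deficit
  moved to the sister branch so the joined path length is preserved; the
  last three nodes form the customary trifurcating root of the unrooted
  topology. On additive matrices NJ is exact, which the tests verify to
  1e-9 against randomly generated trees, alongside per-join agreement with
  an exhaustive Q-scan.
* `bootstrap_support()` resamples alignment columns with replacement,
  rebuilds distance + NJ per replicate, and reports for each internal edge
  the percentage of replicates containing the same leaf bipartition
  (canonicalised so rooting is irrelevant). The default is 100 replicates,
  which is ample for the well-separated synthetic families here; 1000
  mirrors common published practice and is a config switch. A single seed
  governs all resampling.

## Homeolog grouping

`infer_groups()` partitions the tree's leaves into homeolog groups. A
candidate group is the leaf set on **either side of a tree edge** — both
sides are considered because the trifurcating root is an artifact of NJ's
final join and can land inside a true group, which would break a naive
rooted-clade traversal. A candidate qualifies when

1. it has at most three leaves, none without a placed complement;
2. all leaves share one chromosome complement (translocated copies would
   violate complement-based naming, so cross-complement candidates are
   split — a deliberate policy, since the naming scheme is
   complement-based);
3. no subgenome appears twice;
4. it is compact: the largest leaf-to-leaf path distance in the tree does
   not exceed `max_within_distance`.

Candidates are accepted largest-first; anything left over becomes a
singleton. The compactness bound exists because NJ gives *every* leaf a
cherry partner, so two unrelated singleton genes that happen to sit on the
same complement with different subgenomes would otherwise merge. Grouping
is well-posed when within-group divergence (≤ 0.3 substitutions/site) is
separated from between-gene divergence (≥ 0.6); the default bound, 0.45,
is the midpoint of those regimes. Set it to `Inf` to recover the purely
topological rule.

## Nomenclature

`assign_names()` numbers genes 1..G across chromosome complements 1→7.
Within a complement, the *reference subgenome* is the one carrying the most
family copies there (ties A > B > D); groups with a copy on the reference
subgenome come first, ordered by that copy's start coordinate, and the
remaining groups follow ordered by their highest-priority subgenome and its
start. Copies are named `prefix + serial + "-" + subgenome`, e.g.
`TaWRKY75-A`. Published descriptions of within-complement ordering are
ambiguous ("physical location and number of gene copies"); the
reference-subgenome reading implemented here is one consistent
interpretation, and all type-level and complement-level statistics are
invariant to it. Groups without a placed complement (unplaced scaffolds)
are excluded from the positional order and numbered last, by gene id.

## Summary statistics

`type_groups()` and `summary_stats()` produce the catalogue bookkeeping:
copies and genes per homeolog type, gene percentages, copies and
percentages per subgenome, genes per complement, and copy-count fold ratios
against comparator family sizes in other species. Percentages are rounded
half-up to two decimals, matching how such tables are conventionally
printed (75/124 → 60.48). Note that half-up rounding can differ in the
last digit from a table rounded by other means (15/124 = 12.0967 prints
here as 12.10).

## Expression utilities

`relative_expression()` implements the Livak 2^−ΔΔCt method:
ΔCt = Ct(target) − Ct(reference) within each sample,
ΔΔCt = ΔCt(treated) − ΔCt(control), fold change 2^−ΔΔCt. Replicate cycles
are averaged (arithmetic mean of Ct) before subtraction, the common
practice when triplicate wells are reported without an aggregation rule.
`log2_transform()` applies log2(TPM + pseudocount), pseudocount 1 by
default. `stress_response_filter()` classes a gene as `multi_stress` when
it is detected (TPM ≥ threshold) under at least two of cold, drought, heat
and PEG, and `non_responsive` otherwise; the detection threshold defaults
to 0.5 TPM, a deliberate choice since public expression browsers do not
state their cutoff. Raising the threshold can only demote genes — the
filter is monotone, which the tests assert property-style.

## The synthetic proteome generator

`simulate_proteome()` exists so the whole pipeline can be validated against
a known truth. Its default configuration *is* the study condition the
package targets: 124 genes in 294 copies (75 triads, 1 A:B, 12 A:D, 7 B:D,
10 A, 4 B, 15 D), 24 genes on complement 1 and 5 on complement 6 with the
remaining 95 spread evenly (19 each) over complements 2, 3, 4, 5 and 7, a
group plan of 52 group-I / 148 group-II / 94 group-III copies, 47 copies
carrying 59 extra splice isoforms for 353 family records, and 500
motif-free background proteins. Ancestral protein lengths are drawn
uniformly from 120–300 residues, a deliberately compact range that keeps
the full catalogue (an 853-protein scan, a 294-sequence alignment and tree)
running in seconds while leaving the family architecture untouched.

Design points worth knowing when interpreting results:

* **One independent ancestor per gene.** Copies of a gene diverge from
  their ancestor by substitutions at `within_triad_divergence`
  (default 0.15/site; pairwise within-triad divergence is therefore about
  twice that, minus coincident hits). Distinct genes are unrelated draws,
  so between-gene divergence sits near saturation; the configured
  `between_gene_divergence` acts as the declared lower bound of that
  regime. A corollary: group II *subgroups* have no phylogenetic signal in
  synthetic data — subgroup structure would require subfamily ancestors —
  so planting and recovery of group labels operate at the major-group
  level, and nearest-reference subgroup resolution is validated on
  purpose-built reference trees instead.
* **Cassettes are inviolate.** Motif cassettes (heptapeptide, spacer, zinc
  finger) are never mutated, and non-cassette family residues are drawn
  from the 17 amino acids excluding W, C and H, so no spurious
  heptapeptide or zinc-finger pattern can arise. Scanner recall on
  synthetic data is therefore 1 *by construction* — a generator property,
  not a biological claim. Background proteins are uniform over all 20
  amino acids with accidental heptapeptides rejected and resampled.
* **No indels by default.** An indel mode exists (`indel_rate`) but is off,
  keeping copies of a gene colinear and the alignment trivially checkable.
  Real proteomes have indels, domain truncations, heptapeptide variants
  and annotation noise; passing on synthetic data demonstrates the
  pipeline's internal correctness, not robustness to those artefacts.

`score_recovery()` closes the loop: exact-match rates for isoform
collapse, grouping, homeolog types and group labels, all 1.0 under default
settings.

## One reproducible run

`run_pipeline()` chains everything, fills unset parameters from
`default_pipeline_config()`, records every default it applied in the run
manifest, and is deterministic given the seed. Problem sizes at the default
study scale — 853 input records, 294 aligned copies, bootstrap off — keep a
full run under ten seconds; bootstrap at 100 replicates adds about a
minute and is enabled with `n_boot`.

```{r pipeline, eval = FALSE}
catalog <- run_pipeline(list(simulate = TRUE, seed = 1), output_dir = "run1")
catalog
summary(catalog)
score_recovery(catalog$simulation$truth, catalog)
```

## Known limitations

* The motif scanner is deterministic and pattern-based; it will miss family
  members whose heptapeptide deviates beyond the allowed set or whose zinc
  finger violates the spacer ranges, cases a profile HMM can score.
* Homeology is inferred from tree proximity plus chromosome metadata only;
  no synteny or Ks evidence is used, and translocated homeologs are
  deliberately split.
* Within-complement name order is one reading of an ambiguous convention;
  serial numbers of individual genes are not comparable across tools that
  read it differently.
* The simulator does not emulate codon-level evolution, length variation
  between homeologs (without `indel_rate`), realistic residue frequencies,
  or expression counts.
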