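# wrkycatalog

Cataloguing the WRKY transcription factor family in an allohexaploid
(bread-wheat-like) proteome: motif-based member detection, splice-isoform
collapse, phylogeny-driven homeolog triad inference, systematic
nomenclature, WRKY group classification, homeolog-retention statistics, and
stress-expression utilities — all validated against a seeded synthetic
proteome generator with planted ground truth.

## The science in brief

WRKY proteins carry a ~60-residue DNA-binding domain: the heptapeptide
**WRKYGQK** followed by a zinc finger, either C2H2
(`C-x(4,5)-C-x(22,23)-H-x-H`) or C2HC (`C-x(7)-C-x(23)-H-x-C`). The family
classifies structurally as

* group I — two WRKY domains,
* group II — one domain + C2H2 finger (subgroups IIa–IIe),
* group III — one domain + C2HC finger.

Bread wheat is allohexaploid (subgenomes A, B, D over chromosome
complements 1–7), so one *gene* is a **homeolog group** of up to three
subgenome copies. The pipeline detects all family members, keeps the first
isoform per accession, aligns them (progressive MSA: UPGMA guide tree on
3-mer cosine distances, profile–profile affine-gap alignment under
BLOSUM62), builds a neighbor-joining tree on p-distances
(`Q(i,j) = (n−2)·d(i,j) − R_i − R_j`, optional column-bootstrap supports),
partitions the leaves into homeolog groups (same complement, distinct
subgenomes, compact in the tree), numbers genes along complements 1→7 with
subgenome suffixes (`TaWRKY75-A`), classifies every copy by domain count
and zinc-finger type, and tabulates homeolog retention. qPCR fold changes
use the Livak method, 2^−ΔΔCt.

Because the raw proteome of the original wheat survey is not bundled, the
package ships a first-class simulator: a seeded allohexaploid proteome with
planted motif cassettes, configurable per-subgenome gene loss, splice
isoforms and motif-free background proteins, whose default configuration
reproduces the catalogued family architecture (124 genes, 294 copies, 353
records, 52/148/94 group plan).

## Worked example

```r
library(wrkycatalog)
catalog <- run_pipeline(list(simulate = TRUE, seed = 1))
catalog
```

```
WRKY family catalog
  input records:      853
  candidate records:  353
  gene copies:        294
  genes (groups):     124
  WRKY groups:        I = 52  II = 148  III = 94
```

853 simulated proteins were scanned; 353 carry a WRKY domain, collapsing
to 294 gene copies (the first isoform of each accession), which the tree
partitions into 124 genes. `summary()` gives the retention bookkeeping:

```r
summary(catalog)
```

```
Family catalog: 124 genes, 294 gene copies

Homeolog types:
 homeolog_type copies genes pct_genes
         A:B:D    225    75     60.48
           A:B      2     1      0.81
           A:D     24    12      9.68
           B:D     14     7      5.65
             A     10    10      8.06
             B      4     4      3.23
             D     15    15     12.10

Copies per subgenome:
 subgenome copies pct_copies
         A     98      33.33
         B     87      29.59
         D    109      37.07

Genes per chromosome complement:
 complement genes
          1    24
          2    19
          3    19
          4    19
          5    19
          6     5
          7    19

Copy-count fold ratio vs comparators:
 rice maize
 2.85  2.47
```

Reading it: 75 genes (60.48%) retain a full A:B:D triad; exactly one gene
lost its D homeolog (0.81%); subgenome D carries the most copies (109,
37.07%) and B the fewest (87, 29.59%); the 294 copies are 2.85- and
2.47-fold the comparator family sizes in rice (103) and maize (119).
Per-copy calls and names are in `catalog_table(catalog)`:

```r
head(catalog_table(catalog)[, c("name", "gene_id", "homeolog_type", "group")], 3)
```

```
       name gene_id homeolog_type group
1 TaWRKY2-A  g2_c1A         A:B:D   III
2 TaWRKY3-A  g3_c1A         A:B:D    II
3 TaWRKY4-A  g4_c1A         A:B:D     I
```

Recovery of the planted truth is exact on every axis:

```r
score_recovery(catalog$simulation$truth, catalog)
#> recovery rates: isoform collapse 1 | grouping 1 | homeolog types 1 | group labels 1
```

A YAML-driven command-line wrapper over the same function lives at
`inst/cli/familymap.R`. See the vignette
(`vignettes/wrky-family-cataloguing.Rmd`) for the model, parameter and
design discussion.

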