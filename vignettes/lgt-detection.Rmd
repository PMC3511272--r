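---
title: "Detecting lateral gene transfers in root-knot nematode genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lateral gene transfers in root-knot nematode genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtscan)
```

## The model

`lgtscan` asks, for each protein-coding gene of a root-knot nematode
(*Meloidogyne incognita*, *M. hapla*), whether its history is better
explained by lateral acquisition from a non-metazoan donor than by vertical
descent. The evidence is combined in three successive filters, each of which
only ever narrows the candidate set:

1. **Ortholog restriction.** A gene clustering with any other metazoan
   species in an ortholog group (OrthoMCL-style input) is treated as
   vertically inherited and removed. What survives are nematode-restricted
   groups and unclustered singletons. One representative per group — the
   longest *M. incognita* member, else the longest *M. hapla* member — is
   carried forward, which avoids re-testing in-paralogs separately.
2. **BLAST vote.** The representative is compared against a broad protein
   database. The vote asks whether the gene's closest relatives are
   predominantly non-metazoan: among the ten best hits (after quality
   filters and after setting aside hits to plant-parasitic nematodes, which
   are uninformative about the transfer because the transfer may predate
   their radiation), a non-metazoan fraction of at least one half makes the
   gene a candidate. Near-identical non-metazoan hits are better explained
   by contamination of the assembly than by ancient transfer and are
   removed.
3. **Tree topology.** A rooted gene tree supports the transfer when a node
   *A* joins a receiver clade of plant-parasitic nematode sequences
   (containing the focal species) with a donor clade free of eumetazoans,
   and the rest of the tree contains no plant-parasitic nematode. If the
   parent node *B* is inferred to be a duplication node — which happens
   exactly when the external clade also contains a non-metazoan — the
   nematode sequences are nested inside non-metazoan diversity, and the
   direction of transfer is unambiguous: support A+B.

The assumptions are those of the underlying inputs: ortholog groups reflect
homology, the BLAST database's taxonomy labels are correct, and the gene
trees are rooted such that the receiver/donor/external decomposition is
meaningful. Tree inference itself (and BLAST, clustering, domain scanning,
TE annotation) is out of scope: the package consumes those tools' standard
outputs.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| BLAST e-value cut-off | 0.01 | — | minimal hit significance |
| query coverage | 0.30 | fraction of query aa | excludes domain-only matches |
| vote window | 10 | hits | the "ten best hits" rule |
| vote threshold | 0.50 | fraction (inclusive) | "at least 50% non-metazoan" |
| contamination | id > 80 and cov > 0.5 | %, fraction (strict) | near-identity over most of the protein |
| duplication thresholds | ≥ 3 Minc or ≥ 2 Mhap | copies | corrects the 2-copy Minc genome structure |
| cluster rule | ≥ 3 genes, gap < 50,000 | genes, bp (strict) | genomic clusters of LGT genes |
| TE windows | 200/500/1000/2000 | bp per flank | flanking-density profile |
| mobile screen | e < 0.001; id ≥ 30, qcov ≥ 0.5, scov ≥ 0.5 | —, %, fraction | loose then strict stage |
| PPN lineages | 6300, 211184, 211225 | NCBI taxids | Tylenchida, Triplonchida, Dorylaimina |
| metazoan anchor | 6072 | NCBI taxid | Eumetazoa |

All are carried in `lgt_pipeline_config()` and can be overridden; the
defaults are the study conditions and are what the tests exercise.

## Decisions where the procedure was genuinely open

* **PPN hits and the vote window.** Whether the ten-best window is taken
  before or after removing plant-parasitic-nematode hits changes the
  denominator. The default removes them first (`ppn_mode = "skip"`), so the
  vote is over ten informative hits whenever ten exist and cannot be starved
  by self-hits; `ppn_mode = "window"` gives the alternative reading.
* **Fewer than ten surviving hits.** The vote is computed over the available
  survivors (at least one required); queries with none are `no_hit` and
  leave the analysis, mirroring how trees cannot be built from too few hits.
* **Ties.** Equal e-values rank by descending bitscore then subject id;
  equal lengths (representatives, dedup survivors) break to the
  lexicographically smallest id. Purely for reproducibility.
* **Node B at the root.** When node *A* is a child of the root, *B* is the
  root; when *A* is the root there is no *B* and support stays A.
* **Multifurcations.** A node qualifies when its child clades split cleanly
  into receiver-valid and donor-valid sets with no mixed child — collapsed
  low-support edges should not manufacture or destroy calls.
* **Several calls in one tree.** All are reported; per-tree outputs use the
  best call (support grade, then most focal copies, then node id). Tree
  counts count trees, not calls.
* **Before-split duplication.** A duplication node "prior to the speciation"
  is read as a node with both focal species below it on at least two child
  clades; the species-overlap rule alone labels duplication nodes inside
  receiver subtrees.
* **The df = 1 chi-square.** The TE-density test is reported with one degree
  of freedom, which pins the table to a 2×2; the package contrasts gene
  class against TE presence/absence in the flanks, without continuity
  correction, with a count-total alternative behind `method =
  "count_total"`. Reproduced statistics on real genomes are therefore not
  asserted anywhere — only the direction and significance structure are, on
  synthetic data.
* **Mobile-element cut-off.** Sources disagree between e < 0.001 and
  e < 0.01; the default is 0.001, configurable.
* **GO slim mapping.** Default is the most-specific slim ancestor set
  (`mode = "most_specific"`); bucket-style mapping to all slim ancestors is
  available (`mode = "all"`). Percentages are always over proteins annotated
  in the namespace, never whole proteomes.
* **Rounding.** Printed percentages use half-up rounding (two decimals for
  proteome shares, integers for cohort percentages), matching how the
  headline values are conventionally printed; base `round()` half-even would
  differ at exact halves.

## What the generator emulates — and what it does not

`simulate_lgt_study()` plants, per gene, a class (LGT, vertical,
contaminant), a donor division drawn from the observed donor-clade mix
(Bacteria : Protist : Fungi : Plant : Archaea = 72 : 51 : 21 : 19 : 4), copy
numbers and duplication timing at the observed rates (92/141 of LGT trees
contain both nematodes; 83% of those duplicated; 79% of duplications started
before the species split; 72% of those continued after), strong-support
topologies at 52/141, genomic clusters, a 2× TE enrichment in 2 kb flanks,
CDS with a codon profile perturbed by ~0.02 in within-amino-acid fractions,
domain/GO fixtures with an enrichment of carbohydrate/protein-metabolism
flavors among LGT genes, and mobile-element hits at the 146/609 and 32/146
stage rates. BLAST tables are synthesized from the truth labels rather than
computed by alignment, and trees are built directly as topologies: the
package tests the decision logic, not alignment or tree inference.
Consequently, passing tests demonstrate that the filters and pattern
matcher implement their rules exactly and recover planted signal with zero
false positives under clean conditions — they do not demonstrate robustness
to noisy orthology, wrong rooting, or taxonomically mislabelled databases,
which real data can exhibit.

Degenerate inputs are defined rather than rejected: CDS lengths not
divisible by three are trimmed with a warning; codons containing N are
skipped and tallied; empty sequences error; negative inter-gene gaps
(overlapping models) clamp to zero; a TE touching both flanks of a short
gene counts once; identical TE-count distributions yield a chi-square
statistic of exactly 0 and p = 1; amino acids absent from a CDS set get an
undefined (NA) fraction rather than 0.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the generator at the small
study scale — 50 planted LGT genes, 200 vertical genes, 10 contaminants —
plus 500 twelve-leaf random trees for the pattern-matcher equivalence check,
10 × 500 trees for duplication-rate recovery, and 100 replicate genomes
(200 genes per class) for the TE-density power check. Rate-recovery checks
pool estimates over the 10 seeds because a single 500-tree replicate carries
a binomial standard error of about two percentage points on the before-split
rate; each individual seed is additionally required to stay within three
binomial standard errors.

## Known limitations

* Transfers between metazoans, or from nematodes outward, are invisible by
  construction (the pattern requires a non-eumetazoan donor clade).
* A gene transferred independently into another metazoan lineage would be
  discarded at the ortholog-restriction stage.
* The taxonomy walk is exact but assumes every BLAST subject and tree leaf
  resolves to a taxid in the supplied table; unknown taxa are reported as
  errors rather than guessed.
* `Protist` is a paraphyletic catch-all (eukaryotes that are not metazoan,
  fungal or plant); viruses and other unanchored taxa are `Other`.
* Scaffold-end statistics use gene midpoints; genes longer than a scaffold
  half are summarized coarsely.
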