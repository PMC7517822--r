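---
title: "Detecting diversity-generating retroelements with dgrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diversity-generating retroelements with dgrscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biology and the statistic

Diversity-generating retroelements (DGRs) are bacterial loci that rewrite a
short *variable region* (VR) inside a target gene from a nearby non-coding
*template repeat* (TR). The rewrite is carried out by an error-prone reverse
transcriptase (RT) that misincorporates specifically opposite template
adenines, so the TR and VR copies are near-identical except for mismatches
with two diagnostic properties:

1. **Adenine specificity** — at mismatch columns, the TR base is
   predominantly `A` (the detector requires strictly more than 80% of
   mismatches at TR adenines).
2. **Codon-position bias** — because the diversified positions encode
   ligand-binding residues while synonymous variation is not selected for,
   VR mismatches sit predominantly at 1st/2nd codon positions of the target
   ORF (the detector requires at least 2/3).

A cassette is an RT gene plus one TR plus one or more VR-bearing target
genes, typically spanning 5–10 kbp. Variable proteins (VPs) usually carry the
VR inside a C-terminal C-type-lectin-like (CLec) fold, and additional
*remote* targets — CLec genes elsewhere in the genome whose 3' region shows
at least 50% nucleotide identity to a TR — point to dispersal of diversified
modules. Genes with CLec domains below 50% TR identity are *VP homologs*.

`dgrscan` implements this discovery procedure end to end:

* `scan_rt_candidates()` — translate every CDS and score it against an RT
  consensus (local alignment, BLOSUM62, gaps −11/−1), reporting RT motif
  blocks.
* `find_near_repeats()` — search the RT ±5 kbp window for near-identical
  repeat pairs in either orientation.
* `assign_tr_vr()` / `mutagenesis_signature()` / `is_near_3prime()` — orient
  each pair, test the two-part signature, and localize the VR within its
  target gene.
* `assemble_cassettes()`, `find_remote_targets()`, `greedy_cluster()`,
  `neighborhood_report()` — assemble cassettes, map dispersed targets,
  cluster paralogs CD-HIT-style and inventory mobile-element annotations
  within ±10 kbp.
* `generate_genome()` — plant all of the above, with decoys, into a synthetic
  genome with a machine-readable truth table.
* `run_pipeline()` — QC → detection → remote targets → neighborhoods →
  pooled clustering → summaries, as diffable plain-text reports.

## A worked example

```{r, eval = FALSE}
library(dgrscan)

sim <- generate_genome(synth_params(), seed = 3)
det <- detect_dgrs(sim$genome, sim$genes)
length(det$cassettes)        # 2 planted, 2 found
det$cassettes[[1]]$vrs[, c("target_gene", "n_mismatch",
                           "adenine_fraction", "codon12_fraction")]

res <- run_pipeline(list(g1 = list(genome = sim$genome, genes = sim$genes,
                                   domains = sim$domains)), "run_out")
res$summaries
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_bp` | 5000 | bases scanned on each side of the RT gene (the 10-kbp proximal region) |
| `min_repeat_len`, `max_repeat_len` | 80, 250 | accepted repeat copy lengths (bp); cassette repeats are typically 100–200 bp |
| `near_identity_range` | [0.75, 0.995] | identity regarded as "near-identical"; exact repeats are retained but cannot pass the mismatch floor |
| `adenine_fraction_min` | 0.8 | adenine criterion; the pass is strict `>` because the rule is "more than 80%" |
| `codon12_fraction_min` | 2/3 | codon criterion; `>=`, set at the uniform expectation as a permissive default |
| `min_mismatches` | 4 | below this a fraction is statistically vacuous; exact duplications therefore never pass |
| `three_prime_fraction` | 0.25 | terminal fraction of the CDS counted as "near the 3' terminus" (boundary inclusive) |
| `seed_k` | 8 | exact seed length of the repeat search |
| `rt_min_score` | 200 | RT candidacy floor (local BLOSUM62 score versus the consensus); planted RTs at 90% amino-acid identity score ≈1500, random CDS < 100 |
| `remote_identity_min` | 0.5 | remote-VP designation threshold, inclusive (`>=`) |
| qc `max_scaffolds` | 50 | draft assemblies with more scaffolds are excluded |

Clustering thresholds follow the field conventions: RT de-replication at
0.99 identity, RT families at 0.95 identity / 0.9 coverage, CLec families at
0.30 / 0.3, all with the CD-HIT "shorter-sequence" identity denominator.
Consensus building uses a 75% per-column threshold.

## Design choices

**Seed length.** Repeat search is seed-and-extend: exact `k`-mer seeds are
chained per diagonal (substitution-driven repeats keep all seeds on one exact
diagonal; small indels split a repeat across neighboring diagonals, whose
padded realignments converge and are de-duplicated). The default is `k = 8`
rather than a longer seed: at the hardest planted condition (repeat length
≈100 bp at 90% identity, ≈10 mismatches), the chance that no exact 12-mer
survives between mismatches is several percent per pair, which is too lossy
for a detector expected to recover every cassette; with `k = 8` plus
chaining, a miss requires an (essentially never observed) 120-bp stretch
without any 8-mer run. Random 8-mer seed pairs in a 12-kbp window number only
about a thousand and are removed by the chain-span filter and realignment.

**Boundary-robust counting.** Local realignment of a candidate pair can
extend a few bases into flanking sequence that is similar by chance, and a
couple of foreign mismatches can then push a genuine cassette below the
strict 80% adenine rule. Conversely, restricting counting to a seed-anchored
core (between the first and last run of `seed_k` consecutive matches) can
chop genuine terminal mismatches when they cluster more densely than
`seed_k`, which again can drag the measured fraction to the boundary. The
two errors are complementary, so the signature is evaluated on both supports
— the full alignment and its seed-anchored core — and a pair is accepted
when the criteria hold on either; the reported counts come from the support
that passed (the full alignment when both do). Gap columns and columns
adjacent to a gap are always excluded.

**Remote identity is ungapped.** Mutagenic retrohoming substitutes bases
without changing length, and any optimal *gapped* alignment of ~40%-identical
DNA inflates a gap-free-columns identity well above 50% (gaps are free of
the denominator). The remote scan therefore uses a permissive local
alignment only to *locate* the homologous region and then reports the
ungapped identity of the full TR laid on the best nearby diagonal (anchors
from both ends of the local hit, ±3). This cleanly separates planted 70%
remote VPs from 40% homologs; for genuinely indel-containing homology it
will undercall identity, which is the conservative direction for the
designation rule.

**Role assignment.** The copy inside a CDS is the VR. When both or neither
copy is coding, the copy with the higher adenine fraction at mismatch
positions becomes the TR if the margin is at least 0.2; otherwise the pair
is flagged ambiguous and kept out of cassettes (exact duplications always
land here — they have no mismatches to orient them).

**Windows and conventions.** All internal coordinates are 0-based half-open;
GFF3 conversion happens only at file boundaries. The proximal window is
measured from the RT gene boundaries. Repeat windows containing more than
10% `N` are skipped. The TR is compared in both orientations and the
best-scoring one is kept.

## The synthetic benchmark

`generate_genome()` plants, on an i.i.d. background at 45% GC: per cassette
an RT CDS (consensus mutated to ~90% amino-acid identity), a non-coding TR
(100–200 bp, codon-clean so the VR can sit in frame), and target CDS whose
3'-terminal VR copies the TR with `round(10%·L)` mismatches; dispersed
remote VPs (70% TR identity) and VP homologs (40%); transposase-annotated
CDS within 10 kbp of a cassette; unrelated filler genes; and three decoy
classes — an exact duplication inside an RT window (no mismatches, cannot be
oriented), a near-repeat whose mismatches avoid adenines (fails the adenine
rule), and a true-looking near-repeat placed more than 5 kbp from any RT
(never scanned). A truth table records every planted interval together with
realized mismatch statistics, which `realized_signature()` recomputes
directly from the emitted FASTA, independently of the detection code.

Mismatch placement draws the number of adenine-sited and codon-1/2-sited
mismatches binomially at `p_A = 0.95` and `p_12 = 0.9`; because a planted
cassette is meant to be a *true positive*, each draw is conditioned on
clearing the corresponding signature threshold with a small margin (an
unconditioned draw leaves a few percent of pairs below the strict 80% rule,
which would make "recover every planted cassette" unattainable by
construction rather than by detector fault). The pooled realized fractions
remain inside the 99% binomial band of `p_A` and `p_12`, which the test
suite checks over seeds 1–20.

A single pseudo-random stream is keyed by (seed, item index), so adding
decoys or remote targets never perturbs cassette sequences, and identical
parameters and seed give byte-identical output.

**What passing these benchmarks does not show.** The generator emulates
locus architecture and the mutagenesis statistic, not real genomes: no
codon-usage structure, no operons, no repeat families or mobile-element
sequence (transposases are annotations on random CDS), no sequencing error,
no phylogenetic correlation between genomes, and the bundled RT/CLec
consensus files are synthetic stand-ins (`inst/extdata/*_synthetic.faa`).
Recovery on real assemblies additionally depends on annotation quality and
on supplying a genuine RT consensus via the `consensus` argument.

## Problem sizes and numerics

The test suite and the acceptance script run entirely on synthetic data:
20 genomes of 200 kbp (two cassettes each) for recovery and generator
statistics, an 8-genome cohort for the end-to-end pipeline, exhaustive
alignment-oracle checks on all binary-alphabet pairs up to length 4 plus
sampled pairs to length 6, 1000 random pairs for the signature recount, 50
random sets for the clustering oracle and 50 random 5–8-taxon trees for
neighbor joining. Pairwise alignment is delegated to
`Biostrings::pairwiseAlignment` (a gap run of length *L* costs
`gap_open + L·gap_extend`); scores and identities are what the package
guarantees, while traceback tie-breaks follow Biostrings' deterministic
choice. Default schemes: DNA +2/−3 with gaps −5/−2 (BLAST-like), protein
BLOSUM62 with gaps −11/−1, and a +1/−1 scheme for remote-homology location
whose expected local score is positive exactly above 50% identity.

## Known limitations

* Only complete CDS annotations are considered as targets; pseudogenes and
  partial CDS are not scanned (CDS whose length is not a multiple of three
  are translated after trimming and flagged, not rejected).
* Accessory DGR genes (avd-like), prophage assignment and profile-HMM domain
  calling are out of scope; domain evidence enters via an annotation table
  or the bundled consensus fallback.
* The neighbor-joining utility (`nj_tree()`, wrapping `ape::nj`) is
  lightweight plumbing, not a substitute for maximum-likelihood
  phylogenetics.
* Neighborhood counts are reported both with and without de-duplication of
  features shared between overlapping neighborhoods; which convention a
  given published count used may differ.
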