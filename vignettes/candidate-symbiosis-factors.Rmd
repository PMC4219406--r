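---
title: "Screening bacterial genomes for candidate symbiosis factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening bacterial genomes for candidate symbiosis factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Bacteria cultured from an animal gut often have close relatives — sometimes
conspecifics — living freely in fermenting plant material, food, or soil.
When host-associated isolates differ functionally from their free-living
relatives, the genetic basis of that difference is a natural place to look
for *candidate symbiosis factors*: genes whose presence, or whose sequence
history, distinguishes the host-associated genomes. `symbioscreen`
implements the comparative-genomics side of that search for sets of draft
bacterial genomes, such as *Acetobacter* and *Lactobacillus* isolates from
the *Drosophila* gut compared against their non-fly relatives. It asks three
questions:

1. **Gene content.** Which gene families (clusters of orthologous groups,
   COGs) are shared or unique between genome pairs, and which are present in
   *every* host-associated genome but absent from *all* free-living ones?
2. **Gene history.** For families present in both groups, in which ones are
   the host-associated sequences *more similar to each other* than to any
   other genome's — i.e. monophyletic — suggesting shared ancestry or
   horizontal exchange tied to the shared niche?
3. **Genome identity.** How similar are the genomes overall (average percent
   nucleotide identity, APNI), and which isolates fall within the
   conventional 95% same-species boundary?

The phylogenomic screen (question 2) is the package's core. Because its
statistical behaviour cannot be validated on real genomes — there is no
ground truth — the package ships a seeded simulator that emits complete
synthetic datasets with known planted signal, and every claim the package
makes about its own sensitivity and false-positive rate is computed against
that truth.

## The screen, step by step

**Orthology.** All proteins from all genomes are compared all-vs-all by
Smith–Waterman local alignment (BLOSUM62, affine gaps 11/1). E-values follow
the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with fixed gapped
constants ($\lambda = 0.267$, $K = 0.041$); fixing the constants keeps
E-values reproducible without a database-composition fit. Pairs with
$E \le 10^{-5}$ and coverage $\ge 0.5$ of the shorter sequence become edges
weighted by $-\log_{10} E$ (capped at 300 so that underflowing E-values stay
finite). Within-genome edges are kept only for in-paralogs — pairs scoring
above either partner's best between-genome hit — and weights are normalized
per genome pair, following the OrthoMCL scheme. Markov clustering (MCL) with
inflation 1.5 then partitions the graph into COGs; inflation 1.5 is the
granularity conventional for ortholog clustering at genus scale.

**Per-family trees.** Each eligible COG (at least three sequences, all
designated in-group genomes represented) is aligned by progressive MSA:
a UPGMA guide tree over fractional-common-3-mer distances, then
profile–profile global alignment with mean-of-pairs BLOSUM62 scoring and the
same 11/1 gap costs. Children are visited in sorted-id order, so alignments
are independent of input order. Distances are Poisson-corrected p-distances
($d = -\ln(1-p)$, pairwise deletion, $p$ capped at 0.95 so saturated pairs
stay finite), and trees are canonical Saitou–Nei neighbor joining. Negative
NJ branch estimates are clamped to zero with the deficit moved to a sister
branch, preserving path lengths through the shared node.

**The exclusivity test.** "The in-group forms a clade" is formalized on the
*unrooted* tree: some edge's removal must yield a leaf side whose genomes
are all in-group members and which covers every member at least once.
Rooting an NJ tree is arbitrary, and this bipartition criterion is
rooting-invariant. Paralogous in-group leaves outside the clade do not
disqualify a family — the clade must contain the group, not exhaust it.

**Bootstrap.** First-round-exclusive families (only those; support for
clear negatives would be wasted computation) are re-tested on alignments
whose columns are resampled with replacement. Support is the fraction of
replicates in which the exclusive bipartition recurs; hits at or above 0.80
are retained — the conventional support threshold for this kind of screen,
with at least 100 replicates (the package default is 1000; the synthetic
study conditions use 100). Validation here is by NJ bootstrap throughout: a
maximum-likelihood second round was considered and rejected as out of scope,
since the acceptance surface is planted-signal recovery, not likelihood
values.

**Loci.** Retained hits are mapped onto a reference genome (by default the
first in-group member) and chained into loci: hits on one contig with at
most 5 intervening genes between consecutive members share a locus label
("A", "B", … by descending size then leftmost coordinate; singletons are
"lone"). The threshold is invented — locus diagrams in the source material
are drawn, not computed — so it is configurable and echoed in the run
manifest.

## The simulator: what it emulates, and what it does not

`sim_config()` fixes the study conditions. The defaults are the conditions
under which the package's recovery claims are computed:

| parameter | default | why |
|---|---|---|
| `n_genomes` | 8 | desk-scale stand-in for the 33-genome pool |
| `in_group` | g1–g3 | three host-associated isolates, as in the motivating system |
| `n_cogs` | 200 | enough families for stable rate estimates at desk scale |
| `plant_fraction` | 0.1 | planted monophyletic families (the alternative hypothesis) |
| `presence_prob` | 0.9 | the screen targets broadly shared families; draft-genome absence is modest |
| `protein_length` | 300 aa | typical bacterial protein |
| `subst_rate` | 0.5 /site/unit branch | keeps ortholog identities in the 60–95% range seen among congeners; higher rates push planted families into the alignment twilight zone, which the source data do not show |
| `group_separation` | 0.5 | stem length of the planted clade |
| `branch_mean` | 0.1 | exponential species-tree branch lengths |
| `genome_divergence` | 0.01/0.05/0.10 | APNI recovery grid |

Monophyly is planted by clade re-grafting: the in-group's induced subtree is
detached and re-attached on a fresh stem of length `group_separation`. This
gives exact ground truth without modelling an explicit transfer process
whose rates nothing in the source system constrains. The species tree is
rejection-sampled so that the in-group is *not* monophyletic — and, when at
least three out-group taxa exist, stays non-monophyletic after removal of
any single out-group leaf. The screen's null hypothesis requires a
polyphyletic in-group (host-associated isolates interleaved among
free-living relatives, as in the motivating system); without the rejection
step the alternative would be true for every family and the false-positive
rate undefined.

Proteins evolve by a per-branch substitution channel (each site substitutes
with probability $1 - e^{-r b}$, new residue uniform over the other 19).
Composed over a path with branch lengths $b_1, \dots, b_k$, the expected
fraction of differing sites is
$\frac{19}{20}\bigl(1 - \prod_i \frac{20 e^{-r b_i} - 1}{19}\bigr)$,
which the tests verify by simulation at length 10,000. Genes are
back-translated with uniform synonymous codon choice and concatenated with
200-bp random spacers into contigs; planted genes are placed in adjacent
blocks (up to 7 genes) in in-group genomes so the locus machinery has
something to find, and each genome carries a small accessory contig of
mobile-element-annotated genes for the keyword scan.

What the simulator does **not** model: indels (alignments of simulated
orthologs are gap-free, so the screen's gap handling is exercised only by
hand-built cases), rate heterogeneity across sites, codon usage bias, genome
rearrangement, gene duplication (no paralogs are emitted; paralog handling
of the exclusivity test is covered by constructed trees in the unit tests),
and contamination or fragmentation artifacts of real draft assemblies.
Passing the recovery tests therefore shows the pipeline is correct and
well-calibrated *under these conditions*, not that real screens share its
error rates.

## APNI

Whole-genome identity uses the fragment convention (ANIb): the query genome
is cut into 1020-bp windows (terminal remainders of at least half a window
are kept), each fragment is aligned to the subject genome with blastn
(match +1 / mismatch −1, gap open 5 / extend 2, both strands), and fragments
are retained when identity ≥ 30% over ≥ 70% of the fragment. A direction's
ANI is the mean identity of retained fragments; APNI is the mean of the two
directions, making the statistic symmetric by construction. Fragments that
are mostly N are discarded before alignment, and N never counts as a match.
A pair with no retained fragments reports "no alignment", never 0. Against
simulated pairs with per-site divergence $d \in \{0.01, 0.05, 0.10\}$ over
1 Mb the estimator recovers $100(1-d)$ within half a percentage point
(the acceptance suite recomputes this). The 95% species cutoff is a
reporting convention, not a fitted threshold.

## Numerical and design choices

- **Deterministic everything.** All stochastic operations take explicit
  seeds; datasets re-emitted under the same configuration are byte-identical,
  cluster ids are assigned by descending size with lexicographic tie-breaks,
  ties in representative selection go to the smallest protein id, and MCL
  iterates to a $10^{-6}$ column-change tolerance with pruning at $10^{-5}$.
- **k-mer prefilter on by default.** The all-vs-all stage only aligns pairs
  sharing at least 4 distinct 4-mers. Two unrelated 300-aa sequences share
  about 0.5 such 4-mers in expectation, while homologs detectable at the
  screen's E-value cutoff share dozens, so the filter removes the quadratic
  bulk of hopeless alignments without changing the surviving graph — a
  property the test suite asserts by building the graph both ways on a
  simulated dataset.
- **Ambiguity codes.** U/B/Z/J map to X on input; X scores via the BLOSUM62
  X column in alignments and contributes zero in profile scoring.
- **Degenerate inputs.** Single-sequence "alignments" are returned as
  1-row matrices; a bootstrap replicate whose resampled columns leave a
  sequence pair with no comparable sites counts as a non-supporting
  replicate; a COG whose members all come from in-group genomes with one
  leaf per genome has no separating edge and is (correctly) not a hit.
- **Recovery metrics.** Sensitivity is computed against *all* planted
  families — a planted family lost to cluster splitting or merging counts
  as a miss, not as out-of-denominator. The false-positive rate is the
  fraction of screened non-planted families yielding a retained hit.

## Problem sizes

The shipped validation uses: 50 random additive matrices ($n \le 12$) for
NJ exactness; 1000 random trees ($n \le 10$) against brute-force bipartition
enumeration; 100 random graphs ($\le 8$ nodes) against an independently
coded reference MCL; 100 random presence matrices for the content
identities; 1-Mb genome pairs for APNI recovery; and the full default
synthetic dataset (8 genomes, 200 families, 100 bootstrap replicates) for
end-to-end screen recovery. These sizes give stable pass/fail behaviour at
desk scale; all scale linearly (or for the all-vs-all stage, quadratically
with the prefilter's large constant-factor reduction) for larger runs.

## Limitations

Full-scale replication of a real genus-wide screen additionally requires
downloading public assemblies and tolerating version drift in alignment
statistics; COG counts at that scale are sensitive to the E-value cutoff
and coverage filter, which the original tooling did not document. The
screen's second round here is NJ bootstrap, not maximum likelihood; the
mobile-element scan replaces manual contig inspection with a configurable
keyword-fraction rule; and BLASTn search against relatives' plasmids is out
of scope.
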