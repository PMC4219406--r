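# symbioscreen

Comparative and phylogenomic screening for **candidate symbiosis factors**
in host-associated bacteria.

Gut isolates of *Acetobacter* and *Lactobacillus* from *Drosophila* — and
host-associated bacteria generally — often have free-living conspecifics or
close relatives. Genes that distinguish the host-associated genomes are
natural candidates for symbiosis function. `symbioscreen` implements the
comparative side of that search for a panel of (draft) genomes:

- **Orthology**: all-vs-all Smith–Waterman protein similarity (BLOSUM62,
  affine gaps 11/1, Karlin–Altschul E-values), an OrthoMCL-style weighted
  ortholog graph, and Markov clustering (inflation 1.5) into clusters of
  orthologous groups (COGs), with profile-based representative and
  annotation selection per cluster.
- **Phylogenomic screen** (the core): per-COG progressive alignment →
  Poisson distances → neighbor-joining tree → a rooting-invariant test for a
  clade occupied *exclusively* by a designated taxon group (e.g. the fly
  isolates), followed by column-bootstrap support; hits with support ≥ 80%
  are retained and chained into genomic loci on a reference genome.
- **Gene content**: genome × COG presence/absence matrix, pairwise
  shared/unique counts, group-exclusive COGs, and a keyword scan for
  putative plasmid/prophage contigs.
- **APNI**: fragment-based (ANIb) average percent nucleotide identity
  between assemblies, with the conventional 95% same-species benchmark.
- **Simulator**: a seeded generator that emits complete synthetic datasets
  (proteomes, genomes, GFF3, annotations) with a planted fraction of
  group-monophyletic families and known ground truth, so every stage's
  sensitivity and false-positive rate is measurable.

The screen's formal statistic: for a gene tree $T$ with leaves mapped to
genomes and a group $G$, the group is *exclusively monophyletic* when some
edge of the unrooted $T$ defines a bipartition whose one side contains only
leaves from members of $G$ and covers every member of $G$. Bootstrap
support is the fraction of column-resampled replicate trees in which such
an edge recurs; the screen retains COGs with support $\ge 0.80$ over at
least 100 replicates.

## Worked example

The `analysis/` directory is a five-stage narrative workflow over the
package (each script prints what it found and writes tables under
`results/`):

```sh
Rscript analysis/01_simulate.R     # emit the synthetic study dataset
Rscript analysis/02_cluster.R      # ortholog graph + Markov clustering
Rscript analysis/03_screen.R       # the phylogenomic screen
Rscript analysis/04_gene_content.R # presence/absence comparisons
Rscript analysis/05_apni.R         # whole-genome identity
```

With the default study conditions (8 genomes, in-group g1–g3, 200 gene
families, 10% planted monophyly, seed 11) the run prints:

```
families: 200, planted monophyletic: 23
1509 proteins -> 248 COGs (4662 edges in the ortholog graph)
exact family recovery vs truth: 1.000
<screen_result> group 'in_group': 164 COGs screened, 23 first-round hits, 23 retained at support >= 0.8
sensitivity vs planted truth: 1.000  (FPR 0.000 over 141 null families)
locus assignment of retained hits:
 A B C D
 7 7 7 2
pair d05: APNI 94.944 (expected 95.0, realized divergence 0.0507)
```

Reading: all 23 families planted with in-group monophyly were recovered as
bootstrap-supported hits, none of the 141 screened null families was called
(the clustering stage reconstructed every simulated family exactly), the
hits chain into three 7-gene loci plus a 2-gene locus — mirroring the
adjacent placement the generator used — and the APNI estimator recovers a
5%-divergent genome pair at 94.9% identity. The same functions
(`cluster_proteins()`, `screen_cogs()`, `compute_apni()`, …) run unchanged
on real per-genome protein FASTA + genome FASTA + GFF3 inputs via
`load_dataset()`.

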