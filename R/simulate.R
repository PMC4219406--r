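#' Configuration for the synthetic genome-family simulator
#'
#' The generator emits a set of related genomes descended from one species
#' tree, per-gene families with variable presence/absence, a planted fraction
#' of families in which the designated in-group is monophyletic by
#' construction (mimicking niche-specific shared ancestry), nucleotide
#' genomes with controlled pairwise divergence for APNI recovery, and
#' annotation strings including mobile-element keywords.
#'
#' @param n_genomes Number of genomes (>= 4).
#' @param in_group Genome ids of the designated group (>= 2 when planting).
#' @param n_cogs Number of gene families.
#' @param plant_fraction Fraction of families with planted group monophyly.
#' @param presence_prob Per-genome presence probability of a family (the
#'   screen targets broadly shared families, so the default is high).
#' @param protein_length Mean protein length (aa).
#' @param subst_rate Site substitution rate per unit branch length.
#' @param group_separation Stem branch length attached to the planted
#'   in-group clade (the extra divergence separating group from non-group).
#' @param genome_divergence Per-site substitution probabilities for the
#'   emitted nucleotide genome pairs (APNI recovery inputs).
#' @param mobile_cog_fraction Fraction of families given mobile-element
#'   keyword annotations.
#' @param planted_locus_size Maximum planted genes placed adjacently per
#'   genomic locus in in-group genomes.
#' @param spacer_length Length of the random intergenic spacers (bp).
#' @param branch_mean Mean of the exponential species-tree branch lengths.
#' @param seed Mandatory RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 8L,
                       in_group = c("g1", "g2", "g3"),
                       n_cogs = 200L,
                       plant_fraction = 0.1,
                       presence_prob = 0.9,
                       protein_length = 300L,
                       subst_rate = 0.5,
                       group_separation = 0.5,
                       genome_divergence = c(0.01, 0.05, 0.10),
                       mobile_cog_fraction = 0.05,
                       planted_locus_size = 7L,
                       spacer_length = 200L,
                       branch_mean = 0.1,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  probs <- c(plant_fraction, presence_prob, mobile_cog_fraction)
  stopifnot(all(probs >= 0), all(probs <= 1), n_genomes >= 4,
            protein_length >= 50, subst_rate >= 0, group_separation >= 0,
            all(genome_divergence >= 0), all(genome_divergence <= 1))
  genomes <- paste0("g", seq_len(n_genomes))
  stopifnot(all(in_group %in% genomes))
  if (plant_fraction > 0 && length(in_group) < 2L)
    stop("planting requires an in_group of at least 2 genomes")
  structure(list(n_genomes = as.integer(n_genomes), genomes = genomes,
                 in_group = in_group, n_cogs = as.integer(n_cogs),
                 plant_fraction = plant_fraction,
                 presence_prob = presence_prob,
                 protein_length = as.integer(protein_length),
                 subst_rate = subst_rate,
                 group_separation = group_separation,
                 genome_divergence = genome_divergence,
                 mobile_cog_fraction = mobile_cog_fraction,
                 planted_locus_size = as.integer(planted_locus_size),
                 spacer_length = as.integer(spacer_length),
                 branch_mean = branch_mean,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random species tree
#'
#' Random bifurcating topology drawn uniformly over labelled topologies,
#' exponential branch lengths. Deterministic for a fixed seed.
#'
#' @param n Number of leaves (>= 4).
#' @param seed RNG seed.
#' @param branch_mean Mean branch length.
#' @param labels Optional tip labels (default g1..gn).
#' @return An unrooted `phylo` with 2n-3 positive branch lengths.
#' @export
simulate_species_tree <- function(n, seed, branch_mean = 0.1, labels = NULL) {
  if (n < 4L) stop("need at least 4 leaves")
  labels <- labels %||% paste0("g", seq_len(n))
  with_seed(seed, {
    tr <- ape::rtopology(n, rooted = FALSE,
                         br = function(k) rexp(k, rate = 1 / branch_mean))
    tr$tip.label <- labels[as.integer(sub("^t", "", tr$tip.label))]
    tr
  })
}

# TRUE when `members` form an exclusive clade on an unrooted tree with one
# leaf per genome (plain monophyly on bipartitions).
.is_group_clade <- function(tree, members) {
  tips <- tree$tip.label
  if (!all(members %in% tips)) return(FALSE)
  if (length(setdiff(tips, members)) < 1L) return(TRUE)
  res <- find_exclusive_group_bipartition(
    tree, stats::setNames(tips, tips), members)
  res$found
}

# Independent sub-seeds for the simulator's stages, all derived from the one
# mandatory config seed: [1] species tree, [2] cog set, [3] emission,
# [4] divergence pairs.
.sim_seeds <- function(config) derive_seeds(config$seed, 4L)

# Species tree for a dataset: rejection-sample topologies until the in-group
# is non-monophyletic, and stays so after removal of any single out-group
# leaf. The screen's null hypothesis requires a polyphyletic in-group (as for
# gut isolates interleaved among free-living relatives); without this the
# alternative would be true for every family.
.robust_species_tree <- function(config, max_tries = 1000L) {
  seeds <- derive_seeds(.sim_seeds(config)[1L], max_tries)
  out_taxa <- setdiff(config$genomes, config$in_group)
  for (t in seq_len(max_tries)) {
    tr <- simulate_species_tree(config$n_genomes, seeds[t],
                                config$branch_mean, config$genomes)
    bad <- .is_group_clade(tr, config$in_group)
    # single-deletion robustness is only meaningful while at least two
    # out-group taxa remain (with one, exclusivity is trivially true)
    if (!bad && length(out_taxa) >= 3L) {
      for (drop in out_taxa) {
        sub <- ape::drop.tip(tr, drop)
        if (.is_group_clade(sub, config$in_group)) { bad <- TRUE; break }
      }
    }
    if (!bad) return(tr)
  }
  stop("could not find a species tree with a polyphyletic in-group")
}

# Root a small unrooted tree at the midpoint of its first edge so it can be
# grafted as a clade.
.as_rooted_clade <- function(tree, tips, D) {
  if (length(tips) == 2L) {
    d <- D[tips[1], tips[2]]
    txt <- sprintf("(%s:%g,%s:%g);", tips[1], d / 2, tips[2], d / 2)
    return(ape::read.tree(text = txt))
  }
  hc <- stats::hclust(stats::as.dist(D[tips, tips] / 2), method = "average")
  ape::as.phylo(hc)
}

#' Simulate gene trees, presence design and ground truth for a COG set
#'
#' Presence is sampled per genome; for planted families every in-group genome
#' is forced present. A non-planted family's gene tree is the species tree
#' pruned to the present genomes. For a planted family the in-group leaves
#' are detached and re-attached as a single clade on a fresh stem branch of
#' length `group_separation`, making the group monophyletic by construction.
#'
#' @param species_tree Species `phylo` whose tips are the genome ids.
#' @param config A [sim_config()].
#' @return List with `cogs` (per family: `tree`, `present`, `planted`),
#'   `presence` (logical matrix families x genomes) and `truth` data.frame.
#' @export
simulate_cog_set <- function(species_tree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$plant_fraction > 0 && length(config$in_group) < 2L)
    stop("planting requires an in_group of at least 2 genomes")
  genomes <- species_tree$tip.label
  D <- ape::cophenetic.phylo(species_tree)
  with_seed(.sim_seeds(config)[2L], {
    n <- config$n_cogs
    planted <- runif(n) < config$plant_fraction
    presence <- matrix(runif(n * length(genomes)) < config$presence_prob,
                       nrow = n, dimnames = list(NULL, genomes))
    presence[planted, config$in_group] <- TRUE
    cogs <- vector("list", n)
    for (k in seq_len(n)) {
      present <- genomes[presence[k, ]]
      tr <- NULL
      if (!planted[k]) {
        if (length(present) >= 2L)
          tr <- ape::keep.tip(species_tree, present)
      } else {
        ing <- intersect(present, config$in_group)
        outg <- setdiff(present, config$in_group)
        clade <- .as_rooted_clade(species_tree, ing, D)
        clade$root.edge <- config$group_separation
        if (length(outg) >= 2L) {
          rest <- ape::keep.tip(species_tree, outg)
          host_edge <- sample.int(nrow(rest$edge), 1L)
          pos <- runif(1L, 0, rest$edge.length[host_edge])
          tr <- ape::bind.tree(rest, clade,
                               where = rest$edge[host_edge, 2L],
                               position = pos)
        } else if (length(outg) == 1L) {
          txt <- sub(";$", "", ape::write.tree(clade))
          stem <- config$group_separation
          txt <- sprintf("(%s:%g,%s);",
                         outg, stem, txt)
          tr <- ape::read.tree(text = txt)
        } else {
          tr <- if (length(ing) >= 2L) clade else NULL
        }
      }
      cogs[[k]] <- list(tree = tr, present = present, planted = planted[k])
    }
    truth <- data.frame(cog = sprintf("fam%04d", seq_len(n)),
                        planted = planted,
                        n_present = rowSums(presence),
                        stringsAsFactors = FALSE)
    names(cogs) <- truth$cog
    list(cogs = cogs, presence = presence, truth = truth)
  })
}

#' Evolve protein sequences down a gene tree
#'
#' The root sequence is uniform over the 20 amino acids; along each branch a
#' site substitutes with probability 1 - exp(-rate * branch_length), the new
#' residue uniform over the other 19. Deterministic for a fixed seed.
#'
#' @param gene_tree A `phylo` (its tip labels name the output sequences).
#' @param length Protein length (>= 50).
#' @param rate Substitution rate per unit branch length.
#' @param seed RNG seed.
#' @return Named character vector of amino-acid sequences, one per tip.
#' @export
evolve_proteins <- function(gene_tree, length, rate, seed) {
  if (length < 50L) stop("protein length must be >= 50")
  with_seed(seed, {
    if (is.null(gene_tree)) stop("gene_tree is NULL")
    n_tip <- base::length(gene_tree$tip.label)
    if (n_tip == 1L) {
      s <- paste(sample(AA20, length, replace = TRUE), collapse = "")
      return(stats::setNames(s, gene_tree$tip.label))
    }
    tr <- ape::reorder.phylo(gene_tree, "cladewise")
    n_node <- n_tip + tr$Nnode
    seqs <- matrix(NA_integer_, nrow = n_node, ncol = length)
    root <- tr$edge[1L, 1L]
    seqs[root, ] <- sample.int(20L, length, replace = TRUE)
    root_edge <- tr$root.edge %||% 0
    if (root_edge > 0) {
      p <- 1 - exp(-rate * root_edge)
      mut <- runif(length) < p
      if (any(mut)) {
        shift <- sample.int(19L, sum(mut), replace = TRUE)
        seqs[root, mut] <- 1L + (seqs[root, mut] - 1L + shift) %% 20L
      }
    }
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      s <- seqs[parent, ]
      p <- 1 - exp(-rate * tr$edge.length[e])
      mut <- runif(length) < p
      if (any(mut)) {
        # adding a uniform nonzero shift mod 20 yields a uniform draw over
        # the 19 residues different from the current one
        shift <- sample.int(19L, sum(mut), replace = TRUE)
        s[mut] <- 1L + (s[mut] - 1L + shift) %% 20L
      }
      seqs[child, ] <- s
    }
    out <- vapply(seq_len(n_tip), function(i)
      paste(AA20[seqs[i, ]], collapse = ""), character(1))
    stats::setNames(out, tr$tip.label)
  })
}

# Codon table: amino acid -> codons, from the standard genetic code.
.codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons
}

# Back-translate a protein with uniform synonymous codon choice (RNG state
# of the caller is consumed; call inside with_seed).
.back_translate <- function(protein) {
  codons <- .codon_table()
  res <- strsplit(protein, "")[[1]]
  picked <- vapply(res, function(a) {
    opts <- codons[[a]]
    opts[sample.int(base::length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
  paste(picked, collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a pair of genomes at a controlled per-site divergence
#'
#' A random genome of the requested length and a copy in which each site is
#' substituted (to a different base) with probability `d`.
#'
#' @param length Genome length (bp).
#' @param d Per-site substitution probability.
#' @param seed RNG seed.
#' @return List with contigs `a` and `b` (named character vectors) and the
#'   realized divergence `realized_d`.
#' @export
simulate_divergent_pair <- function(length, d, seed) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    a <- sample.int(4L, length, replace = TRUE)
    mut <- runif(length) < d
    b <- a
    if (any(mut)) {
      shift <- sample.int(3L, sum(mut), replace = TRUE)
      b[mut] <- 1L + (b[mut] - 1L + shift) %% 4L
    }
    list(a = c(contig1 = paste(bases[a], collapse = "")),
         b = c(contig1 = paste(bases[b], collapse = "")),
         realized_d = mean(a != b))
  })
}

# Annotation vocabulary for simulated families.
.GENERIC_ANNOTATIONS <- c(
  "aldehyde dehydrogenase", "FAD-dependent pyridine nucleotide-disulfide oxidoreductase",
  "transcriptional regulator, TetR-like", "2-alkenal reductase",
  "RND efflux system, membrane fusion protein", "organic hydroperoxide resistance protein",
  "ABC transporter ATP-binding protein", "glycosyltransferase",
  "aminotransferase class I", "hypothetical protein",
  "sugar phosphotransferase system EIIA component", "thioredoxin reductase",
  "riboflavin biosynthesis protein RibD", "superoxide dismutase",
  "outer membrane efflux lipoprotein", "LysR-family transcriptional regulator")
.MOBILE_ANNOTATIONS <- c(
  "phage integrase", "plasmid replication protein RepA",
  "ParA family partition protein", "phage terminase large subunit",
  "plasmid mobilization protein MobA", "replication initiation protein")

#' Emit a complete synthetic dataset to disk
#'
#' Writes, per genome, a protein FASTA, a nucleotide genome FASTA (proteins
#' back-translated with uniform synonymous codons and concatenated with
#' random spacers; planted-family genes placed adjacently in in-group
#' genomes so loci are detectable), a GFF3 of CDS coordinates and a small
#' accessory contig of mobile-element-annotated genes; plus an annotation
#' table, nucleotide genome pairs at the configured divergences, and ground
#' truth tables covering every emitted gene. Output is byte-identical across
#' runs with the same config.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param overwrite Allow writing into an existing nonempty directory.
#' @return Invisibly, a list with the emitted `paths`, the in-memory
#'   `proteins`, `truth` tables and the species tree.
#' @export
emit_dataset <- function(config, outdir, overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite)
    stop("output directory exists and is not empty: ", outdir,
         " (use overwrite = TRUE)")
  for (sub in c("proteins", "genomes", "annotation", "truth", "apni"))
    dir.create(file.path(outdir, sub), recursive = TRUE, showWarnings = FALSE)

  species_tree <- .robust_species_tree(config)
  cogset <- simulate_cog_set(species_tree, config)
  n <- config$n_cogs
  fam_ids <- cogset$truth$cog
  seeds <- derive_seeds(.sim_seeds(config)[3L], n + 2L)

  # per-family lengths, sequences, annotations
  fam_seqs <- vector("list", n)
  with_seed(seeds[n + 1L], {
    fam_len <- pmax(50L, round(rgamma(n, shape = 25,
                                      scale = config$protein_length / 25)))
    is_mobile_fam <- runif(n) < config$mobile_cog_fraction
    fam_ann <- ifelse(is_mobile_fam,
                      sample(.MOBILE_ANNOTATIONS, n, replace = TRUE),
                      sample(.GENERIC_ANNOTATIONS, n, replace = TRUE))
  })
  for (k in seq_len(n)) {
    cg <- cogset$cogs[[k]]
    if (is.null(cg$tree)) {
      if (length(cg$present) == 1L) {
        fam_seqs[[k]] <- evolve_proteins(structure(
          list(tip.label = cg$present, edge = matrix(0L, 0, 2), Nnode = 0L),
          class = "phylo"), fam_len[k], config$subst_rate, seeds[k])
      } else fam_seqs[[k]] <- character(0)
    } else {
      fam_seqs[[k]] <- evolve_proteins(cg$tree, fam_len[k],
                                       config$subst_rate, seeds[k])
    }
  }

  proteins <- list(); truth_genes <- list(); paths <- list()
  ann_rows <- list()
  with_seed(seeds[n + 2L], {
    for (g in config$genomes) {
      fams <- which(vapply(fam_seqs, function(s) g %in% names(s), logical(1)))
      planted_here <- fams[cogset$truth$planted[fams]]
      other <- setdiff(fams, planted_here)
      order_other <- sample(other)
      if (g %in% config$in_group && length(planted_here)) {
        # planted genes in adjacent blocks to create detectable loci: each
        # block is inserted whole at a random gap among the other genes
        blocks <- split(planted_here,
                        ceiling(seq_along(planted_here) /
                                  config$planted_locus_size))
        gaps <- sort(sample.int(length(order_other) + 1L,
                                min(length(blocks),
                                    length(order_other) + 1L)))
        items <- c(as.list(order_other), blocks)
        key <- c(seq_along(order_other), gaps[seq_along(blocks)] - 0.5)
        gene_order <- unlist(items[order(key)])
      } else {
        gene_order <- sample(fams)
      }
      # main contig
      contig_id <- paste0(g, "_c1")
      seq_parts <- character(0)
      pos <- 0L
      grows <- list()
      for (idx in seq_along(gene_order)) {
        k <- gene_order[idx]
        prot <- fam_seqs[[k]][[g]]
        nt <- .back_translate(prot)
        spacer <- .random_dna(config$spacer_length)
        start <- pos + config$spacer_length + 1L
        end <- start + nchar(nt) - 1L
        pos <- end
        seq_parts <- c(seq_parts, spacer, nt)
        pid <- sprintf("%s_p%04d", g, idx)
        proteins[[length(proteins) + 1L]] <- data.frame(
          genome_id = g, protein_id = pid, residues = prot,
          annotation = fam_ann[k], stringsAsFactors = FALSE)
        grows[[length(grows) + 1L]] <- data.frame(
          protein_id = pid, genome_id = g, cog = fam_ids[k],
          contig_id = contig_id, start = start, end = end, strand = "+",
          ordinal = idx, planted = cogset$truth$planted[k],
          mobile = is_mobile_fam[k], annotation = fam_ann[k],
          stringsAsFactors = FALSE)
      }
      main_contig <- paste(c(seq_parts, .random_dna(config$spacer_length)),
                           collapse = "")
      # accessory mobile contig (< 60 kb by construction)
      acc_id <- paste0(g, "_mob")
      acc_parts <- character(0)
      pos <- 0L
      for (ai in seq_len(6L)) {
        prot <- paste(sample(AA20, 150L, replace = TRUE), collapse = "")
        nt <- .back_translate(prot)
        spacer <- .random_dna(config$spacer_length)
        start <- pos + config$spacer_length + 1L
        end <- start + nchar(nt) - 1L
        pos <- end
        acc_parts <- c(acc_parts, spacer, nt)
        pid <- sprintf("%s_m%02d", g, ai)
        ann <- .MOBILE_ANNOTATIONS[1L + (ai - 1L) %% length(.MOBILE_ANNOTATIONS)]
        proteins[[length(proteins) + 1L]] <- data.frame(
          genome_id = g, protein_id = pid, residues = prot,
          annotation = ann, stringsAsFactors = FALSE)
        grows[[length(grows) + 1L]] <- data.frame(
          protein_id = pid, genome_id = g, cog = NA_character_,
          contig_id = acc_id, start = start, end = end, strand = "+",
          ordinal = ai, planted = FALSE, mobile = TRUE, annotation = ann,
          stringsAsFactors = FALSE)
      }
      acc_contig <- paste(c(acc_parts, .random_dna(config$spacer_length)),
                          collapse = "")
      gdf <- do.call(rbind, grows)
      truth_genes[[g]] <- gdf
      ann_rows[[g]] <- gdf[, c("protein_id", "genome_id", "contig_id",
                               "annotation")]

      # write per-genome files
      pdf <- do.call(rbind, proteins[vapply(proteins, function(d)
        d$genome_id == g, logical(1))])
      aa <- Biostrings::AAStringSet(stats::setNames(
        pdf$residues, paste(pdf$protein_id, pdf$annotation)))
      fp <- file.path(outdir, "proteins", paste0(g, ".faa"))
      Biostrings::writeXStringSet(aa, fp)
      contigs <- c(main_contig, acc_contig)
      names(contigs) <- c(contig_id, acc_id)
      dna <- Biostrings::DNAStringSet(contigs)
      fg <- file.path(outdir, "genomes", paste0(g, ".fna"))
      Biostrings::writeXStringSet(dna, fg)
      gff <- file.path(outdir, "annotation", paste0(g, ".gff3"))
      .write_gff3(gdf, contigs, gff)
      paths[[g]] <- c(proteins = fp, genome = fg, gff = gff)
    }
  })

  proteins <- do.call(rbind, proteins)
  truth_genes <- do.call(rbind, truth_genes)
  rownames(truth_genes) <- NULL
  write_table(do.call(rbind, ann_rows),
              file.path(outdir, "annotation", "annotations.tsv"),
              sort_by = c("genome_id", "protein_id"))
  write_table(cogset$truth, file.path(outdir, "truth", "truth_cogs.tsv"),
              sort_by = "cog")
  write_table(truth_genes, file.path(outdir, "truth", "truth_genes.tsv"),
              sort_by = c("genome_id", "contig_id", "ordinal"))
  ape::write.tree(species_tree, file.path(outdir, "truth", "species_tree.nwk"))

  # nucleotide pairs at controlled divergence for APNI recovery
  div_rows <- list()
  div_seeds <- derive_seeds(.sim_seeds(config)[4L],
                            length(config$genome_divergence))
  base_len <- 200000L
  for (i in seq_along(config$genome_divergence)) {
    d <- config$genome_divergence[i]
    pair <- simulate_divergent_pair(base_len, d, div_seeds[i])
    tag <- sprintf("d%02d", round(100 * d))
    pa <- file.path(outdir, "apni", paste0("base_", tag, ".fna"))
    pb <- file.path(outdir, "apni", paste0("derived_", tag, ".fna"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(pair$a), pa)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(pair$b), pb)
    div_rows[[i]] <- data.frame(pair = tag, nominal_d = d,
                                realized_d = pair$realized_d,
                                length = base_len, stringsAsFactors = FALSE)
  }
  write_table(do.call(rbind, div_rows),
              file.path(outdir, "truth", "divergence.tsv"), sort_by = "pair")
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))

  invisible(list(paths = paths, proteins = proteins,
                 truth_cogs = cogset$truth, truth_genes = truth_genes,
                 species_tree = species_tree, outdir = outdir))
}

# Minimal deterministic GFF3 writer for simulated CDS features.
.write_gff3 <- function(genes, contigs, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (cg in names(contigs))
    writeLines(sprintf("##sequence-region %s 1 %d", cg, nchar(contigs[[cg]])),
               con)
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  writeLines(sprintf("%s\tsymbioscreen_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$contig_id, genes$start, genes$end, genes$strand,
                     genes$protein_id), con)
  invisible(path)
}
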