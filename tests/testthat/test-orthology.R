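# Hand-built protein tables for graph construction.
make_proteins <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(genome_id = r[[1]], protein_id = r[[2]], residues = r[[3]],
               annotation = "", stringsAsFactors = FALSE)))
}

test_that("a reciprocal strong hit between two genomes yields one edge", {
  set.seed(3)
  s <- random_protein(150)
  pr <- make_proteins(list("g1", "a1", s), list("g2", "b1", s))
  g <- build_ortholog_graph(pr, cluster_params(kmer_prefilter = FALSE))
  expect_equal(nrow(g$edges), 1L)
  al <- pairwise_local_align(s, s)
  expect_equal(g$edges$raw_weight, min(-al$log10_evalue, 300))
  # single between-genome edge normalizes to 1 (its own pair mean)
  expect_equal(g$edges$weight, 1.0)
})

test_that("an E-value underflowing to zero is capped at weight 300", {
  set.seed(4)
  s <- random_protein(700)
  pr <- make_proteins(list("g1", "a1", s), list("g2", "b1", s))
  g <- build_ortholog_graph(pr, cluster_params(kmer_prefilter = FALSE))
  expect_equal(g$edges$raw_weight, 300)
  expect_equal(g$edges$evalue, 0)
})

test_that("a planted orthologous triple clusters together, unrelated protein isolates", {
  set.seed(5)
  base <- random_protein(200)
  mutate <- function(s, n) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), n)
    for (i in idx) v[i] <- sample(setdiff(AA <- c("A","R","N","D","C","Q","E",
      "G","H","I","L","K","M","F","P","S","T","W","Y","V"), v[i]), 1)
    paste(v, collapse = "")
  }
  pr <- make_proteins(list("g1", "a1", mutate(base, 20)),
                      list("g2", "b1", mutate(base, 20)),
                      list("g3", "c1", mutate(base, 20)),
                      list("g1", "a2", random_protein(200)))
  g <- build_ortholog_graph(pr, cluster_params(kmer_prefilter = FALSE))
  # oracle: expected adjacency from direct all-pairs alignment
  ids <- pr$protein_id
  expected <- character(0)
  for (i in 1:3) for (j in (i + 1):4) {
    al <- pairwise_local_align(pr$residues[i], pr$residues[j])
    if (al$evalue <= 1e-5 && al$coverage >= 0.5)
      expected <- c(expected, paste(sort(c(ids[i], ids[j])), collapse = "-"))
  }
  got <- sort(paste(pmin(g$edges$p1, g$edges$p2),
                    pmax(g$edges$p1, g$edges$p2), sep = "-"))
  expect_equal(got, sort(expected))
  cogs <- mcl_cluster(g)
  sizes <- table(cogs$cog_id)
  expect_equal(sort(as.integer(sizes)), c(1L, 3L))
  triple <- cogs$cog_id[match(c("a1", "b1", "c1"), cogs$protein_id)]
  expect_equal(length(unique(triple)), 1L)
})

test_that("the k-mer prefilter leaves the surviving graph unchanged", {
  set.seed(6)
  cfg <- sim_config(n_genomes = 4, in_group = c("g1", "g2"), n_cogs = 8,
                    plant_fraction = 0, seed = 91)
  tr <- simulate_species_tree(4, 12, labels = cfg$genomes)
  cs <- simulate_cog_set(tr, cfg)
  prot <- list()
  for (k in seq_along(cs$cogs)) {
    cg <- cs$cogs[[k]]
    if (is.null(cg$tree)) next
    seqs <- evolve_proteins(cg$tree, 120, 0.5, seed = 100 + k)
    for (g in names(seqs))
      prot[[length(prot) + 1L]] <- data.frame(
        genome_id = g, protein_id = paste0(g, "_f", k), residues = seqs[[g]],
        annotation = "", stringsAsFactors = FALSE)
  }
  prot <- do.call(rbind, prot)
  g_on <- build_ortholog_graph(prot, cluster_params(kmer_prefilter = TRUE))
  g_off <- build_ortholog_graph(prot, cluster_params(kmer_prefilter = FALSE))
  key <- function(g) {
    e <- g$edges
    o <- order(e$p1, e$p2)
    list(p = paste(e$p1, e$p2)[o], w = e$weight[o])
  }
  expect_equal(key(g_on)$p, key(g_off)$p)
  expect_equal(key(g_on)$w, key(g_off)$w)
})

test_that("within-genome edges require the in-paralog condition", {
  set.seed(8)
  base <- random_protein(150)
  # a1/a2 are recent in-paralogs (identical), b1 a diverged ortholog
  v <- strsplit(base, "")[[1]]
  idx <- sample(length(v), 60)
  v[idx] <- sample(c("A","G","S","T","P","K","R","E"), 60, replace = TRUE)
  far <- paste(v, collapse = "")
  pr <- make_proteins(list("g1", "a1", base), list("g1", "a2", base),
                      list("g2", "b1", far))
  g <- build_ortholog_graph(pr, cluster_params(kmer_prefilter = FALSE))
  within <- g$edges[g$edges$within, ]
  expect_equal(nrow(within), 1L)     # a1-a2 retained: stronger than any between hit
  # now make the within pair weaker than the between hits: a2 close to b1
  pr2 <- make_proteins(list("g1", "a1", far), list("g1", "a2", base),
                       list("g2", "b1", base))
  g2 <- build_ortholog_graph(pr2, cluster_params(kmer_prefilter = FALSE))
  expect_false(any(g2$edges$within))
})
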