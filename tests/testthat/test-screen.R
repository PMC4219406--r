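make_members <- function(cog, genome, protein) {
  data.frame(cog_id = cog, genome_id = genome, protein_id = protein,
             stringsAsFactors = FALSE)
}

test_that("ineligible COGs are skipped with a stated reason", {
  set.seed(1)
  prot <- data.frame(
    genome_id = c("g1", "g2", "g3", "g1", "g2", "g1", "g1", "g3"),
    protein_id = paste0("p", 1:8),
    residues = replicate(8, random_protein(60)),
    annotation = "", stringsAsFactors = FALSE)
  cm <- make_members(
    c("C1", "C1", "C1",      # eligible
      "C2", "C2",            # two sequences only
      "C3", "C3", "C3"),     # no g2 member -> group not co-present
    prot$genome_id, prot$protein_id)
  grp <- taxon_group("grp", c("g1", "g2"))
  res <- screen_cogs(prot, cm, grp, screen_params(n_bootstrap = 5), seed = 1)
  expect_equal(res$n_screened, 1L)
  expect_equal(res$skipped$reason[res$skipped$cog_id == "C2"],
               "fewer than 3 sequences")
  expect_equal(res$skipped$reason[res$skipped$cog_id == "C3"],
               "group not co-present")
})

test_that("a planted group-monophyletic COG is exclusive with high support", {
  cfg <- sim_config(n_genomes = 6, in_group = c("g1", "g2"), n_cogs = 1,
                    plant_fraction = 1, presence_prob = 1, seed = 77)
  tr <- simulate_species_tree(6, 5, labels = cfg$genomes)
  cs <- simulate_cog_set(tr, cfg)
  seqs <- evolve_proteins(cs$cogs[[1]]$tree, 300, cfg$subst_rate, seed = 6)
  prot <- data.frame(genome_id = names(seqs),
                     protein_id = paste0(names(seqs), "_p1"),
                     residues = unname(seqs), annotation = "",
                     stringsAsFactors = FALSE)
  cm <- make_members("C1", prot$genome_id, prot$protein_id)
  grp <- taxon_group("grp", cfg$in_group)
  res <- screen_cogs(prot, cm, grp, screen_params(n_bootstrap = 100), seed = 2)
  expect_equal(nrow(res$hits), 1L)
  expect_true(res$hits$first_round_exclusive)
  expect_gte(res$hits$support, 0.8)
  expect_true(res$hits$retained)
})

test_that("every retained hit meets the support threshold and ordering is stable", {
  # synthesizing the invariant directly on the hits frame after a tiny run
  cfg <- sim_config(n_genomes = 6, in_group = c("g1", "g2"), n_cogs = 10,
                    plant_fraction = 0.3, seed = 13)
  out <- emit_dataset(cfg, withr::local_tempdir())
  cl <- cluster_proteins(out$proteins)
  grp <- taxon_group("grp", cfg$in_group)
  res <- screen_cogs(out$proteins, cl$cog_members, grp,
                     screen_params(n_bootstrap = 30), seed = 3)
  if (nrow(res$hits)) {
    expect_true(all(res$hits$support[res$hits$retained] >= 0.8))
    expect_true(all(diff(res$hits$support) <= 0))
    expect_true(all(res$hits$support >= 0 & res$hits$support <= 1))
  }
  expect_error(screen_cogs(out$proteins, cl$cog_members,
                           structure(list(name = "x", members = "g1"),
                                     class = "taxon_group")),
               "at least 2")
})

test_that("locus assignment chains nearby genes and labels by size then position", {
  # 18 hits shaped like a 7-gene locus, a 4-gene locus and 7 dispersed genes
  hits <- data.frame(
    cog_id = sprintf("H%02d", 1:18), group = "grp",
    first_round_exclusive = TRUE, support = 1, retained = TRUE,
    n_seqs = 3L, n_taxa = 3L, group_members_present = "g1,g2",
    stringsAsFactors = FALSE)
  cm <- make_members(hits$cog_id, "g1", sprintf("g1_%02d", 1:18))
  ords <- c(10:16,            # locus of 7 adjacent genes
            40:43,            # locus of 4 adjacent genes
            seq(60, 120, 10)) # 7 dispersed genes
  coords <- data.frame(protein_id = sprintf("g1_%02d", 1:18),
                       contig_id = "c1", start = ords * 1000L,
                       end = ords * 1000L + 900L, strand = "+",
                       ordinal = ords, stringsAsFactors = FALSE)
  out <- assign_loci(hits, cm, coords, reference_genome = "g1")
  expect_equal(sum(out$locus_label == "A"), 7L)
  expect_equal(sum(out$locus_label == "B"), 4L)
  expect_equal(sum(out$locus_label == "lone"), 7L)
  expect_equal(out$locus_label[1:7], rep("A", 7))
})

test_that("locus chaining respects the intervening-gene threshold and contigs", {
  hits <- data.frame(
    cog_id = c("Ha", "Hb", "Hc"), group = "grp",
    first_round_exclusive = TRUE, support = 1, retained = TRUE,
    n_seqs = 3L, n_taxa = 3L, group_members_present = "g1,g2",
    stringsAsFactors = FALSE)
  cm <- make_members(hits$cog_id, "g1", c("pa", "pb", "pc"))
  coords <- data.frame(protein_id = c("pa", "pb", "pc"),
                       contig_id = c("c1", "c1", "c2"),
                       start = c(1000, 1200, 500), end = c(1100, 1300, 600),
                       strand = "+", ordinal = c(10L, 12L, 3L),
                       stringsAsFactors = FALSE)
  out <- assign_loci(hits, cm, coords, reference_genome = "g1")
  expect_equal(out$locus_label[out$cog_id == "Ha"],
               out$locus_label[out$cog_id == "Hb"])   # 1 intervening gene
  expect_equal(out$locus_label[out$cog_id == "Hc"], "lone")  # other contig
  # a hit without coordinates is labelled lone with a warning
  cm2 <- make_members(hits$cog_id, "g1", c("pa", "pb", "missing"))
  expect_warning(out2 <- assign_loci(hits, cm2, coords[1:2, ],
                                     reference_genome = "g1"),
                 "lone")
  expect_equal(out2$locus_label[out2$cog_id == "Hc"], "lone")
})

test_that("the summary report formats supports and handles empty input", {
  empty <- summarize_screen(data.frame())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("locus", "predicted_function", "n_taxa_with_cog",
                    "bootstrap_confidence_pct") %in% names(empty)))
  hits <- data.frame(
    cog_id = c("C1", "C2"), group = "grp", first_round_exclusive = TRUE,
    support = c(1.0, 0.97), retained = TRUE, n_seqs = c(5L, 2L),
    n_taxa = c(33L, 2L), group_members_present = c("g1,g2", "g1,g2"),
    locus_label = c("A", "lone"), ref_ordinal = c(1L, 5L),
    stringsAsFactors = FALSE)
  grp <- taxon_group("grp", c("g1", "g2"))
  rep <- summarize_screen(hits, c(C1 = "oxidoreductase"), grp)
  expect_equal(rep$bootstrap_confidence_pct[rep$cog_id == "C1"], "100")
  # a COG present only in group genomes prints n/a
  expect_equal(rep$bootstrap_confidence_pct[rep$cog_id == "C2"], "n/a")
  expect_equal(rep$predicted_function[rep$cog_id == "C1"], "oxidoreductase")
  expect_equal(rep$n_taxa_with_cog[rep$cog_id == "C1"], 33L)
})
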