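test_that("species tree simulation is seeded, bifurcating and positive", {
  t1 <- simulate_species_tree(6, seed = 1)
  t2 <- simulate_species_tree(6, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$edge.length), 2 * 6 - 3)   # unrooted binary tree
  expect_true(all(t1$edge.length > 0))
  expect_error(simulate_species_tree(3, seed = 1), "at least 4")
  t3 <- simulate_species_tree(6, seed = 2)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
})

test_that("plant_fraction 0 prunes the species tree; 1 makes every family monophyletic", {
  cfg0 <- sim_config(n_genomes = 6, in_group = c("g1", "g2"), n_cogs = 20,
                     plant_fraction = 0, seed = 31)
  tr <- simulate_species_tree(6, 99, labels = cfg0$genomes)
  cs0 <- simulate_cog_set(tr, cfg0)
  expect_false(any(cs0$truth$planted))
  for (cg in cs0$cogs) {
    if (is.null(cg$tree)) next
    expect_identical(
      ape::write.tree(cg$tree),
      ape::write.tree(ape::keep.tip(tr, cg$present)))
  }
  cfg1 <- sim_config(n_genomes = 6, in_group = c("g1", "g2"), n_cogs = 20,
                     plant_fraction = 1, presence_prob = 1, seed = 32)
  cs1 <- simulate_cog_set(tr, cfg1)
  expect_true(all(cs1$truth$planted))
  for (cg in cs1$cogs) {
    gmap <- stats::setNames(cg$tree$tip.label, cg$tree$tip.label)
    expect_true(oracle_exclusive(cg$tree, gmap, c("g1", "g2")))
  }
})

test_that("planted flags equal brute-force monophyly counts over a family set", {
  cfg <- sim_config(n_genomes = 8, in_group = c("g1", "g2", "g3"),
                    n_cogs = 60, plant_fraction = 0.15, seed = 11)
  ds <- emit_dataset(cfg, withr::local_tempdir())
  cs <- simulate_cog_set(ds$species_tree, cfg)
  mono <- vapply(cs$cogs, function(cg) {
    if (is.null(cg$tree) || length(cg$tree$tip.label) < 3) return(NA)
    present_in <- intersect(cg$present, cfg$in_group)
    if (length(present_in) < 2) return(NA)
    gmap <- stats::setNames(cg$tree$tip.label, cg$tree$tip.label)
    oracle_exclusive(cg$tree, gmap, present_in)
  }, logical(1))
  planted <- cs$truth$planted
  # every planted family is monophyletic by construction ...
  expect_true(all(mono[planted], na.rm = TRUE))
  # ... and on this dataset no unplanted family is monophyletic by chance,
  # so the counts coincide
  expect_equal(sum(mono, na.rm = TRUE), sum(planted))
})

test_that("protein evolution matches its closed-form divergence", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.5);")
  seqs <- evolve_proteins(tr, 10000, rate = 0.6, seed = 4)
  obs <- mean(strsplit(seqs[["a"]], "")[[1]] != strsplit(seqs[["b"]], "")[[1]])
  expd <- oracle_expected_diff(c(0.3, 0.5), 0.6)
  se <- sqrt(expd * (1 - expd) / 10000)
  expect_lt(abs(obs - expd), 3 * se)
  # rate 0 transmits the root unchanged
  s0 <- evolve_proteins(tr, 100, rate = 0, seed = 4)
  expect_identical(s0[["a"]], s0[["b"]])
  # same seed, same output
  expect_identical(evolve_proteins(tr, 200, 0.6, seed = 8),
                   evolve_proteins(tr, 200, 0.6, seed = 8))
  expect_error(evolve_proteins(tr, 10, 0.6, seed = 1), ">= 50")
})

test_that("emitted datasets have the stated file inventory and coherent truth", {
  cfg <- sim_config(n_genomes = 6, in_group = c("g1", "g2"), n_cogs = 25,
                    plant_fraction = 0.2, seed = 55)
  td <- withr::local_tempdir()
  out <- emit_dataset(cfg, td)
  expect_equal(length(list.files(file.path(td, "proteins"))), 6L)
  expect_equal(length(list.files(file.path(td, "genomes"))), 6L)
  expect_equal(length(list.files(file.path(td, "annotation"), "gff3$")), 6L)
  expect_true(file.exists(file.path(td, "truth", "truth_cogs.tsv")))
  # genes per genome in truth equal the presence design
  cs <- simulate_cog_set(out$species_tree, cfg)
  fam_genes <- out$truth_genes[!is.na(out$truth_genes$cog), ]
  expect_equal(unname(table(fam_genes$genome_id)[cfg$genomes]),
               unname(table(factor(rep(cfg$genomes,
                                       times = colSums(cs$presence)),
                                   levels = cfg$genomes))))
  # planted genes sit at consecutive ordinals in in-group genomes
  for (g in cfg$in_group) {
    pg <- fam_genes[fam_genes$genome_id == g & fam_genes$planted, ]
    pg <- pg[order(pg$ordinal), ]
    runs <- split(pg$ordinal, cumsum(c(1, diff(pg$ordinal) != 1)))
    # blocks are adjacent by construction (adjacent insertion gaps can fuse
    # two blocks, so runs may only be longer than the block size)
    expect_gte(max(lengths(runs)), min(nrow(pg), cfg$planted_locus_size))
  }
  # refusal to overwrite
  expect_error(emit_dataset(cfg, td), "overwrite")
})

test_that("emission is byte-identical for a fixed config and seed", {
  cfg <- sim_config(n_genomes = 5, in_group = c("g1", "g2"), n_cogs = 12,
                    plant_fraction = 0.25, seed = 21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_dataset(cfg, d1)
  emit_dataset(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_equal(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_equal(h1, h2)
})

test_that("divergent pair simulation hits its nominal rate", {
  p <- simulate_divergent_pair(50000, 0.05, seed = 44)
  expect_equal(nchar(p$a[[1]]), 50000L)
  expect_lt(abs(p$realized_d - 0.05), 0.005)
  p0 <- simulate_divergent_pair(1000, 0, seed = 44)
  expect_identical(p0$a, p0$b)
})
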