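aln_mat <- function(x) {
  m <- do.call(rbind, strsplit(unname(x), ""))
  rownames(m) <- names(x)
  m
}

test_that("pairwise distances follow the Poisson closed form with pairwise deletion", {
  aln <- aln_mat(c(a = paste(rep("A", 10), collapse = ""),
                   b = paste(c(rep("A", 9), "K"), collapse = "")))
  D <- pairwise_distances(aln)
  expect_equal(D["a", "b"], -log(0.9))          # p = 0.1
  expect_equal(D["a", "a"], 0)
  Dp <- pairwise_distances(aln, model = "p")
  expect_equal(Dp["a", "b"], 0.1)
  # gap columns excluded per pair
  aln2 <- aln_mat(c(a = "AA-", b = "AAG"))
  expect_equal(pairwise_distances(aln2, model = "p")["a", "b"], 0)
  aln3 <- aln_mat(c(a = "AAC", b = "AAG"))
  expect_equal(pairwise_distances(aln3, model = "p")["a", "b"], 1 / 3)
  # saturation capped before the log
  aln4 <- aln_mat(c(a = "AAAA", b = "KKKK"))
  expect_equal(pairwise_distances(aln4)["a", "b"], -log(1 - 0.95))
  # no comparable sites is an error naming the pair
  aln5 <- aln_mat(c(a = "A-", b = "-G"))
  expect_error(pairwise_distances(aln5), "a and b")
})

test_that("three taxa give the closed-form star tree", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  pd <- path_dist(tr)
  expect_equal(pd[rownames(D), colnames(D)], D)
  b <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(b["a"]), (3 + 5 - 6) / 2)
  expect_equal(unname(b["b"]), (3 + 6 - 5) / 2)
  expect_equal(unname(b["c"]), (5 + 6 - 3) / 2)
})

test_that("an additive 4-taxon matrix is recovered exactly (least-squares oracle)", {
  # known tree: ((a:1,b:2):5,c:3,d:4)
  tr0 <- ape::read.tree(text = "((a:1,b:2):5,c:3,d:4);")
  D <- path_dist(tr0)[c("a", "b", "c", "d"), c("a", "b", "c", "d")]
  tr <- neighbor_joining(D)
  expect_equal(path_dist(tr)[rownames(D), colnames(D)], D, tolerance = 1e-12)
  # oracle: of the 3 unrooted quartets, only ab|cd fits with zero residual
  rss <- oracle_quartet_ls(D)
  expect_equal(which.min(rss), 1L)
  expect_lt(rss[1], 1e-18)
  expect_gt(min(rss[2:3]), 1e-6)
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))
})

test_that("NJ reproduces ultrametric path distances to numerical precision", {
  set.seed(10)
  hc <- stats::hclust(dist(matrix(rnorm(24), 8)), method = "average")
  tr0 <- ape::as.phylo(hc)
  D <- path_dist(tr0)
  tr <- neighbor_joining(D)
  expect_lt(max(abs(path_dist(tr)[rownames(D), colnames(D)] - D)), 1e-9)
})

test_that("negative branch estimates are clamped with the deficit moved to a sister", {
  D <- matrix(c(0, 2, 3, 3.2,
                2, 0, 3.1, 3,
                3, 3.1, 0, 0.4,
                3.2, 3, 0.4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("the exclusive-bipartition test handles the contract cases", {
  gmap <- c(a = "G1", b = "G2", c = "X", d = "Y")
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_true(find_exclusive_group_bipartition(tr, gmap, c("G1", "G2"))$found)
  expect_false(find_exclusive_group_bipartition(tr, gmap, c("G1", "X"))$found)
  # paralogs outside the clade do not disqualify
  gmap2 <- c(a1 = "A", a2 = "A", b = "B", c = "C", d = "D")
  tr2 <- ape::read.tree(text = "((a1:1,b:1):1,(a2:1,(c:1,d:1):1):1);")
  expect_true(find_exclusive_group_bipartition(tr2, gmap2, c("A", "B"))$found)
  # group = entire leaf set: no internal edge separates it
  gmap3 <- c(a = "A", b = "B", c = "C")
  tr3 <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_false(find_exclusive_group_bipartition(tr3, gmap3,
                                                c("A", "B", "C"))$found)
  # absent member is found = FALSE with a reason, not an error
  res <- find_exclusive_group_bipartition(tr, gmap, c("G1", "Z"))
  expect_false(res$found)
  expect_match(res$reason, "absent")
})

test_that("bootstrap support is 1 for a cleanly separated group and reproducible", {
  set.seed(20)
  core <- random_protein(120)
  v <- strsplit(core, "")[[1]]
  idx <- sample(120, 70)
  v[idx] <- sample(c("A","R","N","D","C","Q","E","G","H","I"), 70, TRUE)
  far <- paste(v, collapse = "")
  v2 <- strsplit(far, "")[[1]]
  idx2 <- sample(120, 30)
  v2[idx2] <- sample(c("L","K","M","F","P","S","T","W","Y","V"), 30, TRUE)
  far2 <- paste(v2, collapse = "")
  aln <- aln_mat(c(p1 = core, p2 = core, q1 = far, q2 = far2))
  gmap <- c(p1 = "G1", p2 = "G2", q1 = "O1", q2 = "O2")
  s1 <- bootstrap_group_support(aln, gmap, c("G1", "G2"), n_reps = 100, seed = 7)
  expect_equal(s1, 1.0)
  s2 <- bootstrap_group_support(aln, gmap, c("G1", "G2"), n_reps = 100, seed = 7)
  expect_identical(s1, s2)
  expect_warning(
    s3 <- bootstrap_group_support(aln, gmap, c("G1", "ZZ"), n_reps = 10, seed = 1),
    "missing")
  expect_equal(s3, 0)
  expect_error(bootstrap_group_support(aln, gmap, c("G1", "G2"), n_reps = 0),
               "n_reps")
})

test_that("bootstrap support grows with group separation on a two-block family", {
  set.seed(21)
  L <- 150
  make_aln <- function(delta) {
    jitter <- function(s, k) {
      i <- sample(L, k); s[i] <- sample(c("A","G","S","T"), k, TRUE); s
    }
    # two blocks around two cores whose separation delta is the internal
    # branch of the generating tree
    core_g <- strsplit(random_protein(L), "")[[1]]
    core_o <- jitter(core_g, round(delta * L))
    rbind(p1 = jitter(core_g, 3), p2 = jitter(core_g, 3),
          q1 = jitter(core_o, 3), q2 = jitter(core_o, 3))
  }
  gmap <- c(p1 = "G1", p2 = "G2", q1 = "O1", q2 = "O2")
  supports <- vapply(c(0.05, 0.2, 0.5), function(d)
    bootstrap_group_support(make_aln(d), gmap, c("G1", "G2"),
                            n_reps = 60, seed = 33), numeric(1))
  expect_true(all(diff(supports) >= 0))
  expect_true(all(supports >= 0 & supports <= 1))
})
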