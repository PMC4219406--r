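# Independent reference implementations used as oracles. These are written
# from the definitions, deliberately plain (dense loops, no pruning, no reuse
# of package internals), so they stay independent of the code paths they
# check.

# -- exhaustive affine-gap dynamic programming ------------------------------

# Global alignment score over an arbitrary position-score matrix S
# (gap of length L costs open + ext * L), plain R.
oracle_nw_score <- function(S, open = 11, ext = 1) {
  n <- nrow(S); m <- ncol(S); NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + S[i, j]
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Smith-Waterman local score for two residue strings under a substitution
# matrix, plain R.
oracle_sw_score <- function(a, b, submat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e30
  M <- matrix(0, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- X
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) +
                                  submat[A[i], B[j]])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Score a 2-row gapped alignment under substitution matrix + affine gaps.
oracle_score_pair_alignment <- function(rowA, rowB, submat, open = 11, ext = 1) {
  stopifnot(length(rowA) == length(rowB))
  sc <- 0; gapA <- FALSE; gapB <- FALSE
  for (k in seq_along(rowA)) {
    a <- rowA[k]; b <- rowB[k]
    if (a == "-" && b == "-") next
    if (a == "-") {
      sc <- sc - ext - if (gapA) 0 else open
      gapA <- TRUE; gapB <- FALSE
    } else if (b == "-") {
      sc <- sc - ext - if (gapB) 0 else open
      gapB <- TRUE; gapA <- FALSE
    } else {
      sc <- sc + submat[a, b]
      gapA <- gapB <- FALSE
    }
  }
  sc
}

# -- reference MCL iteration ------------------------------------------------

# Unoptimized dense Markov clustering, explicit column loops, no pruning.
oracle_mcl <- function(W, inflation = 1.5, max_iter = 200, tol = 1e-6) {
  n <- nrow(W)
  for (i in seq_len(n)) {
    mx <- max(W[i, ])
    W[i, i] <- if (mx > 0) mx else 1
  }
  M <- W
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    E <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      E[i, j] <- sum(M[i, ] * M[, j])
    I <- E ^ inflation
    for (j in seq_len(n)) I[, j] <- I[, j] / sum(I[, j])
    delta <- max(abs(I - M))
    M <- I
    if (delta < tol) break
  }
  A <- (M > 1e-5) | t(M > 1e-5)
  # clusters = components of the attractor structure, by hand-rolled BFS
  seen <- rep(FALSE, n); comp <- integer(n); k <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    k <- k + 1L; queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; comp[v] <- k
      nb <- which(A[v, ] & !seen)
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
  }
  unname(split(seq_len(n), comp))
}

# Canonical form of a partition (for set comparison).
partition_key <- function(parts) {
  sort(vapply(parts, function(p) paste(sort(p), collapse = ","), character(1)))
}

# -- brute-force exclusive-bipartition test ---------------------------------

# For every edge: delete it, recover the two leaf sides as graph components,
# and test the exclusivity condition directly.
oracle_exclusive <- function(tree, genome_map, members) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  edges <- tree$edge
  all_nodes <- sort(unique(as.vector(edges)))
  for (e in seq_len(nrow(edges))) {
    rest <- edges[-e, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(rest[, 1]),
                 to = as.character(rest[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(all_nodes)))
    comp <- igraph::components(g)$membership
    side1_nodes <- as.integer(names(comp)[comp == comp[[as.character(edges[e, 2])]]])
    side1 <- side1_nodes[side1_nodes <= n_tip]
    for (side in list(side1, setdiff(seq_len(n_tip), side1))) {
      if (!length(side) || length(side) == n_tip) next
      gg <- genome_map[tips[side]]
      if (all(gg %in% members) && all(members %in% gg)) return(TRUE)
    }
  }
  FALSE
}

# -- trees and distances ----------------------------------------------------

# Random tree with strictly positive branch lengths; cophenetic distances of
# such a tree form an additive matrix.
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.2, 2))
  ape::unroot(tr)
}

# Least-squares fit of a 4-taxon topology: returns the residual sum of
# squares of the best nonnegative edge fit for each of the 3 unrooted
# topologies (taxa in the order a,b,c,d of dimnames(D)).
oracle_quartet_ls <- function(D) {
  taxa <- rownames(D)
  pairs <- t(combn(4, 2))
  d <- apply(pairs, 1, function(ij) D[ij[1], ij[2]])
  # edge order: pendant 1..4, internal 5; design rows follow `pairs`
  design_for <- function(split) {
    # split: the pair grouped together, e.g. c(1,2) for ((1,2),(3,4))
    t(apply(pairs, 1, function(ij) {
      x <- numeric(5)
      x[ij[1]] <- 1; x[ij[2]] <- 1
      same <- (ij[1] %in% split) == (ij[2] %in% split)
      if (!same) x[5] <- 1
      x
    }))
  }
  vapply(list(c(1, 2), c(1, 3), c(1, 4)), function(sp) {
    A <- design_for(sp)
    fit <- qr.solve(A, d)
    sum((A %*% fit - d)^2)
  }, numeric(1))
}

# Closed-form expected fraction of differing sites between two tips of a
# gene tree, for the generator's per-branch substitution channel:
# along each branch b the channel is q_b * I + (1 - q_b) * (J - I)/19 with
# q_b = exp(-rate * b); composing over the path multiplies the coefficients
# alpha_b = (20 q_b - 1) / 19, giving
# P(differ) = (19/20) * (1 - prod alpha_b).
oracle_expected_diff <- function(path_lengths, rate) {
  alpha <- (20 * exp(-rate * path_lengths) - 1) / 19
  (19 / 20) * (1 - prod(alpha))
}

# -- misc -------------------------------------------------------------------

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}

b62 <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Patristic (path-length) distances of a phylo tree; explicit method call so
# the tests do not depend on S3 registration order.
path_dist <- function(tree) ape::cophenetic.phylo(tree)
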