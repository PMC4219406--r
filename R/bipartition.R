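# Tip indices below the child node of every edge, by postorder accumulation.
.edge_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  # map back to the original edge order
  lapply(seq_len(nrow(tree$edge)), function(e) below[[tree$edge[e, 2L]]])
}

#' Test whether a tree has a clade occupied exclusively by a taxon group
#'
#' Operates on the unrooted tree's bipartitions: the group forms an exclusive
#' clade when some edge's removal yields a leaf side whose genomes (i) are all
#' group members and (ii) include every group member at least once. Paralogous
#' leaves of group genomes outside the clade do not disqualify. When the
#' group's leaves are the entire leaf set (one leaf per genome), no internal
#' edge can separate it and the result is `FALSE`.
#'
#' @param tree A `phylo` tree with protein-id tip labels.
#' @param genome_map Named character vector mapping protein id -> genome id.
#' @param group A [taxon_group()] or character vector of genome ids.
#' @return List with `found` (logical), `edges` (indices of qualifying edges
#'   in `tree$edge`) and `reason` (set when a group member is absent).
#' @export
find_exclusive_group_bipartition <- function(tree, genome_map, group) {
  members <- if (inherits(group, "taxon_group")) group$members else group
  tips <- tree$tip.label
  genomes <- unname(genome_map[tips])
  if (anyNA(genomes)) stop("genome_map lacks entries for some tips")
  absent <- setdiff(members, genomes)
  if (length(absent))
    return(list(found = FALSE, edges = integer(0),
                reason = paste0("group member(s) absent from tree: ",
                                paste(absent, collapse = ", "))))
  n_tip <- length(tips)
  sets <- .edge_tip_sets(tree)
  hit <- logical(nrow(tree$edge))
  for (e in seq_along(sets)) {
    for (side in list(sets[[e]], setdiff(seq_len(n_tip), sets[[e]]))) {
      if (length(side) == 0L || length(side) == n_tip) next
      g <- genomes[side]
      if (all(g %in% members) && all(members %in% g)) {
        hit[e] <- TRUE
        break
      }
    }
  }
  list(found = any(hit), edges = which(hit), reason = NULL)
}

#' Bootstrap support for group exclusivity
#'
#' Resamples alignment columns with replacement; for each replicate the
#' distance matrix and neighbor-joining tree are rebuilt and the exclusive
#' bipartition test applied. Support is the fraction of replicates in which
#' the group forms an exclusive clade. Reproducible for a fixed seed.
#'
#' @param aln Character matrix alignment (rows = protein ids).
#' @param genome_map Named vector protein id -> genome id.
#' @param group A [taxon_group()] or character vector of genome ids.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return Support value in [0, 1].
#' @export
bootstrap_group_support <- function(aln, genome_map, group, n_reps = 1000L,
                                    seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  members <- if (inherits(group, "taxon_group")) group$members else group
  genomes <- unname(genome_map[rownames(aln)])
  if (length(setdiff(members, genomes))) {
    warning("group member(s) missing from alignment; support is 0")
    return(0)
  }
  if (nrow(aln) < 3L) return(0)
  L <- ncol(aln)
  with_seed(seed, {
    ok <- 0L
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      found <- tryCatch({
        D <- pairwise_distances(aln[, cols, drop = FALSE])
        tr <- neighbor_joining(D)
        find_exclusive_group_bipartition(tr, genome_map, members)$found
      }, error = function(e) FALSE)
      if (isTRUE(found)) ok <- ok + 1L
    }
    ok / n_reps
  })
}
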