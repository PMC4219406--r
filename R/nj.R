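#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei neighbor joining (Studier-Keppler Q-criterion).
#' Negative estimated branch lengths are clamped to zero with the deficit
#' transferred to the sister branch, preserving path lengths through the
#' shared node; any residual negatives after redistribution are set to zero.
#'
#' @param D Symmetric distance matrix (n >= 3, zero diagonal, finite,
#'   non-negative) with row/column names.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", 1:n)
  tr <- if (n == 3L) {
    # closed form: star tree with b_i = (d_ij + d_ik - d_jk) / 2
    lab <- rownames(D)
    b <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
           (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
           (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    structure(list(edge = cbind(rep(4L, 3L), 1:3),
                   edge.length = b, tip.label = lab, Nnode = 1L),
              class = "phylo", order = "cladewise")
  } else {
    ape::nj(D)
  }
  clamp_negative_branches(tr)
}

# Zero out negative branch lengths, moving each deficit onto a sister branch
# (another edge sharing the same parent node, smallest child index first).
clamp_negative_branches <- function(tree) {
  el <- tree$edge.length
  for (rep_i in seq_len(length(el) + 1L)) {
    neg <- which(el < 0)
    if (!length(neg)) break
    e <- neg[which.min(el[neg])]
    deficit <- el[e]
    el[e] <- 0
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sisters)) {
      s <- sisters[order(tree$edge[sisters, 2L])][1L]
      el[s] <- el[s] + deficit
    }
  }
  tree$edge.length <- pmax(el, 0)
  tree
}
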