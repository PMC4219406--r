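# Column frequency matrix (20 x L) of an alignment block; frequencies are
# over non-gap, standard residues, so all-gap columns give a zero vector.
.block_freq <- function(aln) {
  L <- ncol(aln)
  F <- matrix(0, nrow = 20L, ncol = L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    col <- aln[, j]
    col <- col[col %in% AA20]
    if (length(col)) {
      tab <- tabulate(match(col, AA20), nbins = 20L)
      F[, j] <- tab / length(col)
    }
  }
  F
}

# Merge two alignment blocks by profile-profile global alignment: score of a
# column pair is the mean-of-pairs expected BLOSUM62 score, gaps affine 11/1.
.merge_blocks <- function(alnA, alnB, gap_open = 11, gap_ext = 1) {
  B62 <- blosum62()[AA20, AA20]
  FA <- .block_freq(alnA); FB <- .block_freq(alnB)
  S <- t(FA) %*% B62 %*% FB
  path <- .nw_affine_path(S, gap_open, gap_ext)
  ncolM <- length(path$a)
  out <- matrix("-", nrow = nrow(alnA) + nrow(alnB), ncol = ncolM)
  rownames(out) <- c(rownames(alnA), rownames(alnB))
  ia <- path$a > 0L; ib <- path$b > 0L
  out[seq_len(nrow(alnA)), ia] <- alnA[, path$a[ia], drop = FALSE]
  out[nrow(alnA) + seq_len(nrow(alnB)), ib] <- alnB[, path$b[ib], drop = FALSE]
  out
}

# Fractional-common-kmer distance used for the guide tree.
.kmer_dist <- function(seqs, k = 3L) {
  n <- length(seqs)
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character(0)))
    table(substring(s, seq_len(L - k + 1L), k:L))
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      common <- intersect(names(km[[i]]), names(km[[j]]))
      shared <- sum(pmin(as.integer(km[[i]][common]),
                         as.integer(km[[j]][common])))
      denom <- min(nchar(seqs[[i]]), nchar(seqs[[j]])) - k + 1L
      f <- if (denom > 0) shared / denom else 0
      D[i, j] <- D[j, i] <- 1 - min(f, 1)
    }
  }
  D
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from fractional-common-3-mer distances by UPGMA, then
#' profile-profile global alignment (mean-of-pairs BLOSUM62, affine gaps
#' 11/1) at each internal node. Sequences are processed in sorted-id order so
#' the result is independent of input order.
#'
#' @param seqs Named character vector of amino-acid sequences (names = ids).
#' @return Character matrix alignment, rows in sorted-id order; removing the
#'   gaps from any row reproduces that input sequence.
#' @export
progressive_msa <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  seqs <- seqs[order(names(seqs))]
  if (length(seqs) == 1L) {
    m <- matrix(strsplit(seqs[[1]], "")[[1]], nrow = 1L)
    rownames(m) <- names(seqs)
    return(m)
  }
  blocks <- lapply(seq_along(seqs), function(i) {
    m <- matrix(strsplit(seqs[[i]], "")[[1]], nrow = 1L)
    rownames(m) <- names(seqs)[i]
    m
  })
  if (length(seqs) == 2L) {
    merged <- .merge_blocks(blocks[[1]], blocks[[2]])
  } else {
    D <- .kmer_dist(seqs)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    for (r in seq_len(nrow(hc$merge))) {
      pick <- function(x) if (x < 0) blocks[[-x]] else nodes[[x]]
      left <- pick(hc$merge[r, 1]); right <- pick(hc$merge[r, 2])
      # canonical operand order: block holding the smallest id goes first
      if (min(rownames(left)) > min(rownames(right))) {
        tmp <- left; left <- right; right <- tmp
      }
      nodes[[r]] <- .merge_blocks(left, right)
    }
    merged <- nodes[[nrow(hc$merge)]]
  }
  merged[order(rownames(merged)), , drop = FALSE]
}
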