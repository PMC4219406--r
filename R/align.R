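#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under BLOSUM62 with affine gaps (a gap of length L
#' costs `gap_open + gap_ext * L`). The expectation value follows the
#' Karlin-Altschul form E = K m n exp(-lambda S) with fixed gapped BLOSUM62
#' constants, so E-values are reproducible without a database composition fit.
#'
#' @param seqA,seqB Nonempty amino-acid strings.
#' @param gap_open,gap_ext Affine gap penalties (BLAST convention 11/1).
#' @param lambda,K Karlin-Altschul gapped constants.
#' @return A list with `score`, `evalue`, `log10_evalue`, `identity` (matches /
#'   alignment columns on the optimal traceback) and `coverage` (aligned
#'   fraction of the shorter sequence).
#' @export
pairwise_local_align <- function(seqA, seqB, gap_open = 11, gap_ext = 1,
                                 lambda = 0.267, K = 0.041) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB), type = "local",
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_ext)
  s <- Biostrings::score(pa)
  aln_len <- nchar(as.character(Biostrings::pattern(pa)))
  identity <- if (aln_len > 0) Biostrings::nmatch(pa) / aln_len else 0
  m <- nchar(seqA); n <- nchar(seqB)
  spanA <- Biostrings::end(Biostrings::pattern(pa)) -
    Biostrings::start(Biostrings::pattern(pa)) + 1L
  spanB <- Biostrings::end(Biostrings::subject(pa)) -
    Biostrings::start(Biostrings::subject(pa)) + 1L
  coverage <- if (m <= n) spanA / m else spanB / n
  log10e <- log10(K * m * n) - lambda * s / log(10)
  list(score = s, evalue = 10^log10e, log10_evalue = log10e,
       identity = identity, coverage = min(coverage, 1))
}

# Unique k-mers of one sequence.
.seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

# Candidate pairs sharing at least `min_shared` distinct k-mers: an inverted
# index from k-mer to sequence, then pair counts accumulated per bucket.
# Cheap screen that removes the vast majority of unrelated pairs before the
# quadratic alignment stage.
shared_kmer_pairs <- function(seqs, k = 4L, min_shared = 4L) {
  n <- length(seqs)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0)))
  km <- lapply(seqs, .seq_kmers, k = k)
  idx <- rep.int(seq_len(n), lengths(km))
  buckets <- split(idx, unlist(km, use.names = FALSE))
  buckets <- buckets[lengths(buckets) >= 2L]
  counts <- new.env(parent = emptyenv(), size = 4096L)
  for (b in buckets) {
    b <- sort.int(b)
    nb <- length(b)
    for (x in seq_len(nb - 1L)) {
      for (y in (x + 1L):nb) {
        key <- paste0(b[x], "_", b[y])
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(counts)
  if (!length(keys)) return(data.frame(i = integer(0), j = integer(0)))
  cnt <- vapply(keys, function(kk) counts[[kk]], integer(1))
  keep <- keys[cnt >= min_shared]
  ij <- do.call(rbind, strsplit(keep, "_", fixed = TRUE))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
  out[order(out$i, out$j), , drop = FALSE]
}
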