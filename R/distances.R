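#' Pairwise evolutionary distances from a protein alignment
#'
#' Sites where either row carries a gap are excluded per pair (pairwise
#' deletion). The p-distance is the mismatch fraction over the used sites;
#' the Poisson-corrected distance is -ln(1 - p) with p capped at 0.95 before
#' the log so saturated pairs stay finite.
#'
#' @param aln Character matrix alignment with at least two rows.
#' @param model `"poisson"` (default) or `"p"`.
#' @return Symmetric numeric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  stopifnot(is.matrix(aln))
  n <- nrow(aln)
  if (n < 2L) stop("alignment needs at least 2 rows")
  ids <- rownames(aln) %||% as.character(seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  gap <- aln == "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      used <- sum(ok)
      if (used == 0L)
        stop("no comparable sites between ", ids[i], " and ", ids[j])
      p <- sum(aln[i, ok] != aln[j, ok]) / used
      d <- if (model == "p") p else -log(1 - min(p, 0.95))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}
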