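#' Parameters for ortholog graph construction and Markov clustering
#'
#' @param evalue_cutoff Maximum expectation value for a similarity edge.
#' @param min_coverage Minimum aligned fraction of the shorter sequence.
#' @param inflation MCL inflation exponent (granularity; the screen uses 1.5).
#' @param mcl_max_iter,mcl_tol,mcl_prune MCL iteration controls.
#' @param kmer_prefilter Whether to restrict the all-vs-all alignment stage to
#'   pairs sharing at least `min_shared_kmers` distinct 4-mers. Unrelated
#'   random proteins essentially never pass the filter, while detectable
#'   homologs share many 4-mers, so the surviving graph is unchanged.
#' @param min_shared_kmers Shared 4-mer threshold for the prefilter.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(evalue_cutoff = 1e-5, min_coverage = 0.5,
                           inflation = 1.5, mcl_max_iter = 100L,
                           mcl_tol = 1e-6, mcl_prune = 1e-5,
                           kmer_prefilter = TRUE, min_shared_kmers = 4L) {
  stopifnot(evalue_cutoff > 0, min_coverage > 0, min_coverage <= 1,
            inflation > 1, mcl_max_iter >= 1, mcl_tol > 0, mcl_prune >= 0)
  structure(list(evalue_cutoff = evalue_cutoff, min_coverage = min_coverage,
                 inflation = inflation, mcl_max_iter = as.integer(mcl_max_iter),
                 mcl_tol = mcl_tol, mcl_prune = mcl_prune,
                 kmer_prefilter = isTRUE(kmer_prefilter),
                 min_shared_kmers = as.integer(min_shared_kmers)),
            class = "cluster_params")
}

#' Build the weighted ortholog graph from all-vs-all protein similarity
#'
#' Every candidate protein pair is locally aligned; edges are kept when the
#' E-value is at or below the cutoff and coverage of the shorter sequence
#' meets `min_coverage`. Edge weight is -log10(E) capped at 300.
#' Within-genome edges are retained only for in-paralogs: pairs that score
#' better than either partner's best between-genome hit. Between-genome edge
#' weights are then normalized by the mean between-genome weight of that
#' genome pair, and in-paralog weights by the genome's mean in-paralog weight,
#' following the OrthoMCL weighting scheme.
#'
#' @param proteins Protein table as from [read_protein_fasta()] (rows from at
#'   least two genomes, `protein_id` unique).
#' @param params A [cluster_params()] object.
#' @return An `ortholog_graph`: list with `edges` (data.frame `p1`, `p2`,
#'   `weight`, `raw_weight`, `evalue`, `within`), `proteins` (ids) and
#'   `genome_map` (named vector protein -> genome).
#' @export
build_ortholog_graph <- function(proteins, params = cluster_params()) {
  stopifnot(is.data.frame(proteins),
            all(c("genome_id", "protein_id", "residues") %in% names(proteins)))
  if (anyDuplicated(proteins$protein_id))
    stop("protein_id values must be unique across the input set")
  if (length(unique(proteins$genome_id)) < 2L)
    stop("need proteins from at least 2 genomes")
  ord <- order(proteins$protein_id)
  proteins <- proteins[ord, , drop = FALSE]
  seqs <- stats::setNames(proteins$residues, proteins$protein_id)
  gmap <- stats::setNames(proteins$genome_id, proteins$protein_id)
  n <- length(seqs)

  if (params$kmer_prefilter) {
    cand <- shared_kmer_pairs(seqs, k = 4L,
                              min_shared = params$min_shared_kmers)
  } else {
    cand <- expand.grid(i = seq_len(n), j = seq_len(n))
    cand <- cand[cand$i < cand$j, , drop = FALSE]
  }
  ss_log("aligning ", nrow(cand), " candidate pairs of ", n, " proteins")

  keep_i <- integer(0); keep_j <- integer(0)
  keep_w <- numeric(0); keep_e <- numeric(0)
  if (nrow(cand)) {
    # batch alignments by the j side to amortize call overhead
    for (jj in unique(cand$j)) {
      ii <- cand$i[cand$j == jj]
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(seqs[ii]), Biostrings::AAString(seqs[[jj]]),
        type = "local", substitutionMatrix = blosum62(),
        gapOpening = 11, gapExtension = 1)
      s <- Biostrings::score(pa)
      m <- nchar(seqs[ii]); nn <- nchar(seqs[[jj]])
      spanA <- Biostrings::end(Biostrings::pattern(pa)) -
        Biostrings::start(Biostrings::pattern(pa)) + 1L
      spanB <- Biostrings::end(Biostrings::subject(pa)) -
        Biostrings::start(Biostrings::subject(pa)) + 1L
      cov <- ifelse(m <= nn, spanA / m, spanB / nn)
      log10e <- log10(0.041 * m * nn) - 0.267 * s / log(10)
      ok <- log10e <= log10(params$evalue_cutoff) & cov >= params$min_coverage
      if (any(ok)) {
        keep_i <- c(keep_i, ii[ok]); keep_j <- c(keep_j, rep.int(jj, sum(ok)))
        keep_w <- c(keep_w, pmin(-log10e[ok], 300))
        keep_e <- c(keep_e, 10^log10e[ok])
      }
    }
  }

  edges <- data.frame(p1 = names(seqs)[keep_i], p2 = names(seqs)[keep_j],
                      raw_weight = keep_w, evalue = keep_e,
                      stringsAsFactors = FALSE)
  edges$within <- gmap[edges$p1] == gmap[edges$p2]

  # in-paralog rule: keep a within-genome edge only when it outscores both
  # partners' best between-genome hits
  if (any(edges$within)) {
    between <- edges[!edges$within, , drop = FALSE]
    best_between <- rep(-Inf, n)
    names(best_between) <- names(seqs)
    if (nrow(between)) {
      for (col in c("p1", "p2")) {
        agg <- tapply(between$raw_weight, between[[col]], max)
        best_between[names(agg)] <- pmax(best_between[names(agg)], agg)
      }
    }
    win <- edges$within
    ok_par <- edges$raw_weight >= best_between[edges$p1] &
      edges$raw_weight >= best_between[edges$p2]
    drop <- win & !ok_par
    if (any(drop)) edges <- edges[!drop, , drop = FALSE]
  }

  # OrthoMCL-style weight normalization
  edges$weight <- edges$raw_weight
  if (nrow(edges)) {
    pairkey <- ifelse(edges$within,
                      paste0("W|", gmap[edges$p1]),
                      paste0("B|", pmin(gmap[edges$p1], gmap[edges$p2]), "|",
                             pmax(gmap[edges$p1], gmap[edges$p2])))
    mean_w <- tapply(edges$raw_weight, pairkey, mean)
    edges$weight <- edges$raw_weight / as.numeric(mean_w[pairkey])
  }
  if (!nrow(edges)) ss_log("no edges survived the similarity filters")
  rownames(edges) <- NULL
  structure(list(edges = edges, proteins = names(seqs), genome_map = gmap),
            class = "ortholog_graph")
}

#' @export
print.ortholog_graph <- function(x, ...) {
  cat("<ortholog_graph> ", length(x$proteins), " proteins, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}
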