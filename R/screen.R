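#' Parameters for the phylogenomic screen
#'
#' @param support_threshold Minimum bootstrap support (inclusive) for a hit to
#'   be retained; the screen's convention is 0.80.
#' @param n_bootstrap Number of bootstrap replicates for first-round hits.
#' @param min_taxa_in_cog Minimum number of distinct genomes in an eligible COG.
#' @param locus_max_intervening_genes Maximum genes between consecutive hits
#'   assigned to one genomic locus.
#' @param locus_same_contig_required Whether one locus may not span contigs.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(support_threshold = 0.80, n_bootstrap = 1000L,
                          min_taxa_in_cog = 2L,
                          locus_max_intervening_genes = 5L,
                          locus_same_contig_required = TRUE) {
  stopifnot(support_threshold > 0, support_threshold <= 1, n_bootstrap >= 1)
  structure(list(support_threshold = support_threshold,
                 n_bootstrap = as.integer(n_bootstrap),
                 min_taxa_in_cog = as.integer(min_taxa_in_cog),
                 locus_max_intervening_genes = as.integer(locus_max_intervening_genes),
                 locus_same_contig_required = isTRUE(locus_same_contig_required)),
            class = "screen_params")
}

#' Screen COGs for exclusive taxon-group clades with bootstrap support
#'
#' For every eligible COG (at least three sequences, spanning at least
#' `min_taxa_in_cog` genomes, with every group member present) the COG is
#' aligned (unless an alignment is supplied), Poisson distances and a
#' neighbor-joining tree are computed, and the exclusive-bipartition test is
#' applied. Bootstrap support is computed only for first-round-positive COGs
#' (cost control); a hit is flagged retained when support meets the
#' threshold.
#'
#' @param proteins Protein table covering all COG members.
#' @param cog_members COG membership data.frame (`cog_id`, `genome_id`,
#'   `protein_id`) as from [mcl_cluster()].
#' @param group A [taxon_group()].
#' @param params A [screen_params()].
#' @param seed Master seed for the bootstrap RNG.
#' @param alignments Optional named list of precomputed alignments by cog_id.
#' @return A `screen_result`: list with `hits` (data.frame sorted by
#'   descending support then cog_id), `skipped` (cog_id + reason),
#'   `n_screened`, `trees` and `alignments` (named lists for hits), and the
#'   echoed parameters.
#' @export
screen_cogs <- function(proteins, cog_members, group, params = screen_params(),
                        seed = 1L, alignments = NULL) {
  stopifnot(inherits(group, "taxon_group"), is.data.frame(cog_members))
  if (length(group$members) < 2L) stop("group needs at least 2 members")
  seq_by_id <- stats::setNames(proteins$residues, proteins$protein_id)
  gmap <- stats::setNames(cog_members$genome_id, cog_members$protein_id)
  cogs <- split(cog_members$protein_id, cog_members$cog_id)
  cog_ids <- names(cogs)
  cog_seeds <- derive_seeds(seed, length(cogs))

  hits <- list(); skipped <- list(); trees <- list(); alns <- list()
  n_screened <- 0L
  for (k in seq_along(cogs)) {
    cid <- cog_ids[k]
    members <- cogs[[k]]
    genomes <- unique(unname(gmap[members]))
    if (length(members) < 3L) {
      skipped[[cid]] <- "fewer than 3 sequences"
      next
    }
    if (length(genomes) < params$min_taxa_in_cog) {
      skipped[[cid]] <- "fewer taxa than min_taxa_in_cog"
      next
    }
    if (!all(group$members %in% genomes)) {
      skipped[[cid]] <- "group not co-present"
      next
    }
    n_screened <- n_screened + 1L
    aln <- alignments[[cid]] %||% progressive_msa(seq_by_id[members])
    D <- pairwise_distances(aln)
    tr <- neighbor_joining(D)
    first <- find_exclusive_group_bipartition(tr, gmap, group)
    if (!first$found) next
    support <- bootstrap_group_support(aln, gmap, group,
                                       n_reps = params$n_bootstrap,
                                       seed = cog_seeds[k])
    hits[[cid]] <- data.frame(
      cog_id = cid, group = group$name, first_round_exclusive = TRUE,
      support = support, retained = support >= params$support_threshold,
      n_seqs = length(members), n_taxa = length(genomes),
      group_members_present = paste(sort(intersect(genomes, group$members)),
                                    collapse = ","),
      stringsAsFactors = FALSE)
    trees[[cid]] <- tr
    alns[[cid]] <- aln
  }
  hits_df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(cog_id = character(0), group = character(0),
               first_round_exclusive = logical(0), support = numeric(0),
               retained = logical(0), n_seqs = integer(0),
               n_taxa = integer(0), group_members_present = character(0))
  if (nrow(hits_df)) {
    hits_df <- hits_df[order(-hits_df$support, hits_df$cog_id), , drop = FALSE]
    rownames(hits_df) <- NULL
  }
  skipped_df <- data.frame(cog_id = names(skipped),
                           reason = unlist(skipped) %||% character(0),
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(hits = hits_df, skipped = skipped_df,
                 n_screened = n_screened, trees = trees, alignments = alns,
                 group = group, params = params, seed = seed),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> group '", x$group$name, "': ", x$n_screened,
      " COGs screened, ", nrow(x$hits), " first-round hits, ",
      sum(x$hits$retained), " retained at support >= ",
      x$params$support_threshold, "\n", sep = "")
  invisible(x)
}

#' Assign genomic locus labels to screen hits
#'
#' Hits whose genes lie on the same contig of the reference genome with at
#' most `locus_max_intervening_genes` genes between consecutive members form
#' one locus. Multi-gene loci are labelled "A", "B", ... by descending gene
#' count then leftmost coordinate; singleton loci are labelled "lone".
#'
#' @param hits Hits data.frame from [screen_cogs()] (component `hits`).
#' @param cog_members COG membership table.
#' @param gene_coords Coordinate table from [read_gff3_genes()] for the
#'   reference genome.
#' @param reference_genome Genome id whose coordinates anchor the loci
#'   (default: first group member named in the hits).
#' @param params A [screen_params()].
#' @return The hits data.frame with `locus_label`, `ref_contig`,
#'   `ref_ordinal` and `ref_start` columns added.
#' @export
assign_loci <- function(hits, cog_members, gene_coords,
                        reference_genome = NULL, params = screen_params()) {
  stopifnot(is.data.frame(hits))
  if (is.null(reference_genome)) {
    present <- strsplit(hits$group_members_present[1] %||% "", ",")[[1]]
    reference_genome <- sort(present)[1]
  }
  if (nrow(hits) == 0L) {
    hits$locus_label <- character(0)
    hits$ref_contig <- character(0)
    hits$ref_ordinal <- integer(0)
    hits$ref_start <- integer(0)
    return(hits)
  }
  ref_members <- cog_members[cog_members$genome_id == reference_genome, ,
                             drop = FALSE]
  hits$ref_contig <- NA_character_
  hits$ref_ordinal <- NA_integer_
  hits$ref_start <- NA_integer_
  for (r in seq_len(nrow(hits))) {
    pids <- ref_members$protein_id[ref_members$cog_id == hits$cog_id[r]]
    rows <- gene_coords[gene_coords$protein_id %in% pids, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rows[order(rows$ordinal), , drop = FALSE]
    hits$ref_contig[r] <- rows$contig_id[1]
    hits$ref_ordinal[r] <- rows$ordinal[1]
    hits$ref_start[r] <- rows$start[1]
  }
  if (any(is.na(hits$ref_ordinal)))
    warning(sum(is.na(hits$ref_ordinal)),
            " hit(s) without coordinates in ", reference_genome,
            "; labelled 'lone'")
  # chain hits on one contig when the ordinal gap stays within the threshold
  cluster_id <- rep(NA_integer_, nrow(hits))
  next_cluster <- 0L
  ord <- order(hits$ref_contig, hits$ref_ordinal, na.last = TRUE)
  prev <- NULL
  for (r in ord) {
    if (is.na(hits$ref_ordinal[r])) next
    if (!is.null(prev) &&
        identical(hits$ref_contig[r], hits$ref_contig[prev]) &&
        (hits$ref_ordinal[r] - hits$ref_ordinal[prev] - 1L) <=
          params$locus_max_intervening_genes) {
      cluster_id[r] <- cluster_id[prev]
    } else {
      next_cluster <- next_cluster + 1L
      cluster_id[r] <- next_cluster
    }
    prev <- r
  }
  hits$locus_label <- "lone"
  multi <- table(cluster_id)
  multi <- multi[multi >= 2L]
  if (length(multi)) {
    left <- vapply(as.integer(names(multi)), function(cl)
      min(hits$ref_start[which(cluster_id == cl)]), numeric(1))
    rank <- order(-as.integer(multi), left)
    labels <- stats::setNames(LETTERS[seq_along(multi)],
                              names(multi)[rank])
    for (cl in names(labels))
      hits$locus_label[which(cluster_id == as.integer(cl))] <- labels[[cl]]
  }
  hits$reference_genome <- reference_genome
  hits
}

#' Summarize screen hits as a report table
#'
#' One row per hit in the layout of the screen's report: locus, predicted
#' function (the representative's annotation), number of taxa possessing the
#' COG, group members present, and bootstrap support as a percentage
#' ("n/a" when the COG occurs only in group genomes, where support is
#' trivial). Rows are ordered by locus label then reference coordinate.
#'
#' @param hits Hits data.frame after [assign_loci()].
#' @param annotations Named character vector cog_id -> annotation (e.g. from
#'   [select_representatives()]); missing entries print as "".
#' @param group A [taxon_group()] (used for the "n/a" rule).
#' @return A report data.frame.
#' @export
summarize_screen <- function(hits, annotations = NULL, group = NULL) {
  if (nrow(hits) == 0L)
    return(data.frame(locus = character(0), predicted_function = character(0),
                      n_taxa_with_cog = integer(0),
                      group_members_with_cog = character(0),
                      bootstrap_confidence_pct = character(0),
                      cog_id = character(0)))
  members <- if (!is.null(group)) group$members else character(0)
  ann <- if (is.null(annotations)) rep("", nrow(hits)) else
    unname(annotations[hits$cog_id])
  ann[is.na(ann)] <- ""
  only_group <- vapply(seq_len(nrow(hits)), function(r) {
    present <- strsplit(hits$group_members_present[r], ",")[[1]]
    hits$n_taxa[r] <= length(present) && length(members) > 0
  }, logical(1))
  pct <- ifelse(only_group, "n/a",
                formatC(round(hits$support * 100), format = "d"))
  out <- data.frame(locus = hits$locus_label,
                    predicted_function = ann,
                    n_taxa_with_cog = hits$n_taxa,
                    group_members_with_cog = hits$group_members_present,
                    bootstrap_confidence_pct = pct,
                    cog_id = hits$cog_id,
                    stringsAsFactors = FALSE)
  lab <- out$locus
  lab_rank <- ifelse(lab == "lone", "ZZZ", lab)
  out <- out[order(lab_rank, hits$ref_ordinal, out$cog_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the per-hit gene trees as Newick files
#'
#' @param screen A `screen_result` from [screen_cogs()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_hit_trees <- function(screen, dir) {
  stopifnot(inherits(screen, "screen_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cid in names(screen$trees)) {
    p <- file.path(dir, paste0(cid, ".nwk"))
    ape::write.tree(screen$trees[[cid]], file = p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
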