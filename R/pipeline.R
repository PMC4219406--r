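#' Load all per-genome inputs of an emitted or real dataset
#'
#' Expects the layout written by [emit_dataset()]: `proteins/<genome>.faa`,
#' `genomes/<genome>.fna`, `annotation/<genome>.gff3`.
#'
#' @param dir Dataset directory.
#' @param genomes Optional genome ids (default: every `.faa` file found).
#' @return List with `proteins` (one table), `coords` (one table, with
#'   `genome_id`), `assemblies` (named list) and `genomes`.
#' @export
load_dataset <- function(dir, genomes = NULL) {
  if (is.null(genomes)) {
    genomes <- sort(sub("\\.faa$", "",
                        list.files(file.path(dir, "proteins"), "\\.faa$")))
  }
  if (!length(genomes)) stop("no genomes found under ", dir)
  proteins <- do.call(rbind, lapply(genomes, function(g)
    read_protein_fasta(file.path(dir, "proteins", paste0(g, ".faa")), g)))
  coords <- do.call(rbind, lapply(genomes, function(g) {
    co <- read_gff3_genes(file.path(dir, "annotation", paste0(g, ".gff3")))
    co$genome_id <- g
    co
  }))
  assemblies <- lapply(genomes, function(g)
    read_genome_fasta(file.path(dir, "genomes", paste0(g, ".fna")), g))
  names(assemblies) <- genomes
  list(proteins = proteins, coords = coords, assemblies = assemblies,
       genomes = genomes)
}

#' Cluster a protein set into COGs
#'
#' All-vs-all similarity, ortholog graph, Markov clustering; optionally the
#' per-COG profile representative and annotation.
#'
#' @param proteins Protein table.
#' @param params A [cluster_params()].
#' @param representatives One of `"none"`, `"all"`: whether to run the
#'   profile-based representative selection over every COG (quadratic in pool
#'   size; [select_representatives()] can be run later on a subset).
#' @return List with `graph`, `cog_members` and (optionally) `cogs` summary.
#' @export
cluster_proteins <- function(proteins, params = cluster_params(),
                             representatives = c("none", "all")) {
  representatives <- match.arg(representatives)
  graph <- build_ortholog_graph(proteins, params)
  cog_members <- mcl_cluster(graph, params)
  cogs <- NULL
  if (representatives == "all")
    cogs <- select_representatives(cog_members, proteins)
  list(graph = graph, cog_members = cog_members, cogs = cogs)
}

#' Select profile representatives and annotations for COGs
#'
#' Aligns each COG, builds its profile and scans the whole taxon pool for the
#' best-scoring sequence (see [select_representative()]).
#'
#' @param cog_members COG membership table.
#' @param proteins Protein table (the taxon pool).
#' @param cog_ids Optional subset of COG ids (default all).
#' @return Data.frame `cog_id`, `representative`, `annotation`.
#' @export
select_representatives <- function(cog_members, proteins, cog_ids = NULL) {
  seq_by_id <- stats::setNames(proteins$residues, proteins$protein_id)
  cogs <- split(cog_members$protein_id, cog_members$cog_id)
  if (!is.null(cog_ids)) cogs <- cogs[intersect(names(cogs), cog_ids)]
  rows <- lapply(names(cogs), function(cid) {
    members <- cogs[[cid]]
    aln <- progressive_msa(seq_by_id[members])
    prof <- build_profile(aln)
    rep <- select_representative(members, prof, proteins)
    data.frame(cog_id = cid, representative = rep$protein_id,
               annotation = rep$annotation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$cog_id), , drop = FALSE]
}

#' Run the full phylogenomic screen over a clustered dataset
#'
#' Screens COGs for exclusive group clades, computes bootstrap support,
#' assigns genomic locus labels against the reference genome, selects
#' representatives for the hits and builds the summary report.
#'
#' @param proteins Protein table.
#' @param cog_members COG membership table.
#' @param group A [taxon_group()].
#' @param coords Coordinate table (with `genome_id`) for locus assignment.
#' @param params A [screen_params()].
#' @param seed Bootstrap seed.
#' @param reference_genome Genome anchoring the locus labels (default first
#'   group member).
#' @return List with `screen` (the `screen_result`), `hits` (with loci),
#'   `report` (summary table) and `annotations`.
#' @export
run_screen <- function(proteins, cog_members, group, coords = NULL,
                       params = screen_params(), seed = 1L,
                       reference_genome = NULL) {
  scr <- screen_cogs(proteins, cog_members, group, params, seed)
  hits <- scr$hits
  ann <- NULL
  if (nrow(hits)) {
    if (!is.null(coords)) {
      ref <- reference_genome %||% sort(group$members)[1]
      ref_coords <- coords[coords$genome_id == ref, , drop = FALSE]
      hits <- assign_loci(hits, cog_members, ref_coords,
                          reference_genome = ref, params = params)
    } else {
      hits$locus_label <- "lone"
      hits$ref_ordinal <- NA_integer_
    }
    reps <- select_representatives(cog_members, proteins, hits$cog_id)
    ann <- stats::setNames(reps$annotation, reps$cog_id)
  }
  report <- summarize_screen(hits, ann, group)
  list(screen = scr, hits = hits, report = report, annotations = ann)
}

#' Compare recovered screen hits against simulator ground truth
#'
#' Maps each COG to the simulated family all its members belong to ("mixed"
#' if members span families). Sensitivity is the fraction of all planted
#' families recovered by a retained hit (a planted family lost to cluster
#' splitting or merging counts as a miss); the false-positive rate is the
#' fraction of screened non-planted families that yield a retained hit.
#'
#' @param screen_result A `screen_result` (or the list from [run_screen()]).
#' @param truth_genes Truth gene table from [emit_dataset()].
#' @param truth_cogs Truth family table from [emit_dataset()].
#' @param cog_members COG membership table.
#' @return List with `sensitivity`, `fpr`, counts, and the hit-to-family map.
#' @export
evaluate_screen <- function(screen_result, truth_genes, truth_cogs,
                            cog_members) {
  scr <- if (inherits(screen_result, "screen_result")) screen_result
         else screen_result$screen
  fam_of_protein <- stats::setNames(truth_genes$cog, truth_genes$protein_id)
  cogs <- split(cog_members$protein_id, cog_members$cog_id)
  fam_of_cog <- vapply(cogs, function(members) {
    fams <- unique(unname(fam_of_protein[members]))
    fams <- fams[!is.na(fams)]
    if (length(fams) == 1L) fams else if (!length(fams)) NA_character_
    else "mixed"
  }, character(1))
  screened <- setdiff(names(cogs), scr$skipped$cog_id)
  screened_fams <- fam_of_cog[screened]
  planted_fams <- truth_cogs$cog[truth_cogs$planted]
  retained <- scr$hits$cog_id[scr$hits$retained]
  retained_fams <- unname(fam_of_cog[retained])
  tp_fams <- intersect(retained_fams, planted_fams)
  planted_screened <- intersect(planted_fams, screened_fams)
  nonplanted_screened <- setdiff(screened_fams[!is.na(screened_fams)],
                                 c(planted_fams, "mixed"))
  fp <- setdiff(retained_fams[!is.na(retained_fams)], planted_fams)
  sensitivity <- if (length(planted_fams))
    length(tp_fams) / length(planted_fams)
  else NA_real_
  fpr <- if (length(nonplanted_screened))
    length(intersect(fp, nonplanted_screened)) / length(nonplanted_screened)
  else 0
  list(sensitivity = sensitivity, fpr = fpr,
       n_planted = length(planted_fams),
       n_planted_screened = length(planted_screened),
       n_nonplanted_screened = length(nonplanted_screened),
       n_first_round = nrow(scr$hits), n_retained = length(retained),
       true_positives = sort(tp_fams), false_positives = sort(fp),
       cog_family_map = fam_of_cog)
}

#' Exact-recovery rate of simulated families by the clustering stage
#'
#' A family counts as exactly recovered when some COG contains all of the
#' family's emitted proteins and nothing else.
#'
#' @param cog_members COG membership table.
#' @param truth_genes Truth gene table.
#' @return Fraction of simulated families recovered exactly.
#' @export
cog_recovery_rate <- function(cog_members, truth_genes) {
  fams <- split(truth_genes$protein_id, truth_genes$cog)
  cogs <- split(cog_members$protein_id, cog_members$cog_id)
  keys <- vapply(cogs, function(m) paste(sort(m), collapse = "|"),
                 character(1))
  hit <- vapply(fams, function(m)
    paste(sort(m), collapse = "|") %in% keys, logical(1))
  mean(hit)
}

#' Write a run manifest
#'
#' Records the configuration echo, seeds, package version, and an md5
#' checksum for every output file, so runs are auditable and reruns
#' comparable.
#'
#' @param path Manifest path (YAML).
#' @param config Named list echoed verbatim.
#' @param outputs Character vector of output file paths to checksum.
#' @param extra Optional named list of additional fields (e.g. skip logs).
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, config, outputs = character(0),
                           extra = list()) {
  existing <- outputs[file.exists(outputs)]
  manifest <- c(list(
    tool = "symbioscreen",
    version = as.character(utils::packageVersion("symbioscreen")),
    config = config,
    outputs = if (length(existing))
      as.list(stats::setNames(unname(tools::md5sum(existing)), existing))
    else list()),
    extra)
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}
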