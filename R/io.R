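#' Read a protein FASTA file into a protein record table
#'
#' Headers are split on whitespace: the first token is the protein identifier,
#' the remainder (if any) is kept as the annotation string. Residues are
#' uppercased and the ambiguity codes U, B, Z and J are mapped to X so that
#' downstream scoring matrices stay total.
#'
#' @param path Path to an amino-acid FASTA file.
#' @param genome_id Genome identifier attached to every record.
#' @return A data.frame with columns `genome_id`, `protein_id`, `residues`,
#'   `annotation`.
#' @export
read_protein_fasta <- function(path, genome_id) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  ann <- sub("^\\S+\\s*", "", headers)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein_id in ", path, ": ", paste(dup, collapse = ", "))
  res <- toupper(as.character(aa))
  res <- sub("\\*+$", "", res)  # trailing stop codons
  n_amb <- sum(lengths(regmatches(res, gregexpr("[UBZJ]", res))))
  if (n_amb > 0L) {
    ss_log(n_amb, " ambiguous residues (U/B/Z/J) mapped to X in ", path)
    res <- gsub("[UBZJ]", "X", res)
  }
  if (any(!nzchar(res))) stop("empty sequence in ", path)
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X]"), res)
  if (any(bad))
    stop("invalid residues in ", path, " for: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  data.frame(genome_id = genome_id, protein_id = unname(ids),
             residues = unname(res), annotation = unname(ann),
             stringsAsFactors = FALSE)
}

#' Read a nucleotide genome assembly FASTA
#'
#' @param path Path to a nucleotide FASTA file.
#' @param genome_id Genome identifier.
#' @param group_tag One of `"in_group"`, `"out_group"`, `"other"` marking the
#'   genome's role in a screen (e.g. fly vs non-fly isolates).
#' @return An object of class `genome_assembly`: a list with `genome_id`,
#'   `group_tag` and a named character vector `contigs`.
#' @export
read_genome_fasta <- function(path, genome_id,
                              group_tag = c("other", "in_group", "out_group")) {
  group_tag <- match.arg(group_tag)
  if (!file.exists(path)) stop("file does not exist: ", path)
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("empty FASTA file: ", path)
  contigs <- toupper(as.character(dna))
  names(contigs) <- vapply(strsplit(names(dna), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(contigs))) stop("empty contig in ", path)
  genome_assembly(genome_id, contigs, group_tag)
}

#' Construct a genome assembly object
#'
#' @param genome_id Genome identifier.
#' @param contigs Named character vector of contig sequences (A/C/G/T/N).
#' @param group_tag Group membership tag.
#' @return A `genome_assembly` object.
#' @export
genome_assembly <- function(genome_id, contigs,
                            group_tag = c("other", "in_group", "out_group")) {
  group_tag <- match.arg(group_tag)
  stopifnot(length(contigs) >= 1L, all(nzchar(contigs)),
            !is.null(names(contigs)))
  structure(list(genome_id = genome_id, group_tag = group_tag,
                 contigs = contigs, contig_lengths = nchar(contigs)),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", x$genome_id, " (", x$group_tag, "): ",
      length(x$contigs), " contig(s), ", sum(x$contig_lengths), " bp\n",
      sep = "")
  invisible(x)
}

#' Read gene coordinates from a GFF3 file
#'
#' Parses CDS (or gene) features and returns one row per feature keyed by its
#' ID attribute, with 1-based inclusive coordinates and an `ordinal` giving the
#' rank of the gene along its contig (ascending start, ties broken by
#' protein_id).
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `protein_id`, `contig_id`, `start`,
#'   `end`, `strand`, `ordinal`.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    nf <- length(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (nf != 9L)
      stop("malformed GFF3 line ", i, " in ", path, ": expected 9 fields, got ", nf)
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (!is.na(s) && !is.na(e) && s > e)
      stop("start > end on GFF3 line ", i, " in ", path)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  ids <- as.character(gr$ID)
  no_id <- is.na(ids) | !nzchar(ids)
  if (any(no_id)) {
    warning(sum(no_id), " feature(s) without an ID attribute skipped in ", path)
    gr <- gr[!no_id]; ids <- ids[!no_id]
  }
  df <- data.frame(protein_id = ids,
                   contig_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$contig_id, df$start, df$protein_id), ]
  df$ordinal <- stats::ave(seq_len(nrow(df)), df$contig_id,
                           FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Write a report table as TSV
#'
#' Writes a UTF-8 tab-separated file with a header line. Tabs embedded in
#' character fields are replaced by spaces. Rows can be sorted by a stated key
#' so reports are deterministic and diffable.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @param sort_by Optional character vector of column names to sort rows by.
#' @return Invisibly, the (possibly sanitized and sorted) data.frame written.
#' @export
write_table <- function(rows, path, sort_by = NULL) {
  stopifnot(is.data.frame(rows))
  if (!is.null(sort_by) && nrow(rows)) {
    missing_keys <- setdiff(sort_by, names(rows))
    if (length(missing_keys))
      stop("sort_by column(s) not present: ", paste(missing_keys, collapse = ", "))
    rows <- rows[do.call(order, rows[sort_by]), , drop = FALSE]
  }
  for (cn in names(rows)) {
    if (is.character(rows[[cn]]) && any(grepl("\t", rows[[cn]], fixed = TRUE))) {
      ss_log("tabs replaced by spaces in column '", cn, "'")
      rows[[cn]] <- gsub("\t", " ", rows[[cn]], fixed = TRUE)
    }
  }
  ok <- tryCatch({
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok))
  rownames(rows) <- NULL
  invisible(rows)
}

#' Read a TSV report table
#'
#' @param path Path to a TSV file written by [write_table()].
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Define a taxon group for the phylogenomic screen
#'
#' @param name Group name.
#' @param members Character vector of at least two genome ids.
#' @return A `taxon_group` object.
#' @export
taxon_group <- function(name, members) {
  members <- unique(as.character(members))
  if (length(members) < 2L)
    stop("a taxon group needs at least 2 member genomes")
  structure(list(name = name, members = members), class = "taxon_group")
}

#' Read taxon group definitions from a YAML file
#'
#' The file maps group names to lists of genome ids, e.g.
#' `fly_acetobacter: [g1, g2]`.
#'
#' @param path Path to the YAML file.
#' @param genomes Optional character vector of loaded genome ids; if given,
#'   group members must be a subset.
#' @return A named list of [taxon_group()] objects.
#' @export
read_taxon_groups <- function(path, genomes = NULL) {
  defs <- yaml::read_yaml(path)
  out <- lapply(names(defs), function(nm) {
    g <- taxon_group(nm, unlist(defs[[nm]]))
    if (!is.null(genomes)) {
      unknown <- setdiff(g$members, genomes)
      if (length(unknown))
        stop("group '", nm, "' names unknown genome(s): ",
             paste(unknown, collapse = ", "))
    }
    g
  })
  stats::setNames(out, names(defs))
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param aln Character matrix (rows = sequences, rownames = ids).
#' @param path Output path.
#' @export
write_msa_fasta <- function(aln, path) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  seqs <- apply(aln, 1L, paste, collapse = "")
  xs <- Biostrings::AAStringSet(seqs)
  names(xs) <- rownames(aln)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read an aligned FASTA into an alignment matrix
#'
#' @param path Path to an aligned FASTA file.
#' @return Character matrix with one row per sequence.
#' @export
read_msa_fasta <- function(path) {
  xs <- Biostrings::readAAStringSet(path)
  if (length(xs) == 0L) stop("empty alignment file: ", path)
  w <- unique(Biostrings::width(xs))
  if (length(w) != 1L) stop("rows of ", path, " differ in length")
  m <- do.call(rbind, strsplit(as.character(xs), ""))
  rownames(m) <- vapply(strsplit(names(xs), "\\s+"), `[`, character(1), 1L)
  m
}
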