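#' Parameters for fragment-based average nucleotide identity (APNI)
#'
#' The ANIb convention: the query genome is cut into fragments
#' (default 1020 bp), each fragment is aligned to the subject genome, and
#' fragments are retained when identity and coverage pass the filters.
#'
#' @param fragment_length Fragment window length (bp, >= 100).
#' @param min_fragment_identity Minimum fragment identity for retention.
#' @param min_fragment_coverage Minimum aligned fraction of the fragment.
#' @param species_cutoff Same-species benchmark, percent (conventionally 95).
#' @return A list of class `apni_params`.
#' @export
apni_params <- function(fragment_length = 1020L, min_fragment_identity = 0.30,
                        min_fragment_coverage = 0.70, species_cutoff = 95.0) {
  stopifnot(fragment_length >= 100,
            min_fragment_identity > 0, min_fragment_identity <= 1,
            min_fragment_coverage > 0, min_fragment_coverage <= 1)
  structure(list(fragment_length = as.integer(fragment_length),
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_coverage = min_fragment_coverage,
                 species_cutoff = species_cutoff),
            class = "apni_params")
}

#' Cut a genome assembly into consecutive non-overlapping fragments
#'
#' Windows of length L per contig; a terminal remainder of at least L/2 is
#' kept as a short fragment, shorter remainders are dropped.
#'
#' @param assembly A `genome_assembly` or named character vector of contigs.
#' @param L Fragment length.
#' @return Named character vector of fragments ("contig:start-end", 1-based).
#' @export
fragment_genome <- function(assembly, L = 1020L) {
  contigs <- if (inherits(assembly, "genome_assembly")) assembly$contigs
             else assembly
  if (is.null(contigs) || length(contigs) == 0L) stop("empty assembly")
  frags <- character(0)
  for (cg in names(contigs)) {
    n <- nchar(contigs[[cg]])
    starts <- seq.int(1L, n, by = L)
    for (s in starts) {
      e <- min(s + L - 1L, n)
      if (e - s + 1L < L && e - s + 1L < L / 2) next
      frags[[paste0(cg, ":", s, "-", e)]] <- substr(contigs[[cg]], s, e)
    }
  }
  frags
}

.require_blast <- function() {
  for (tool in c("blastn", "makeblastdb")) {
    if (!nzchar(Sys.which(tool)))
      stop(tool, " not found on PATH; it is required for APNI computation")
  }
}

# One direction of ANIb: fragments of `query` aligned to `subject` with
# blastn (match +1 / mismatch -1, gap open 5 / extend 2, both strands);
# best HSP per fragment, filtered by identity and fragment coverage.
.apni_direction <- function(query_contigs, subject_contigs, params) {
  frags <- fragment_genome(query_contigs, params$fragment_length)
  # fragments that are mostly ambiguous never align informatively
  n_frac <- vapply(frags, function(s)
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s),
    numeric(1))
  frags <- frags[n_frac <= 0.5]
  total <- length(frags)
  if (total == 0L)
    return(list(ani = NA_real_, used = 0L, total = 0L))
  td <- tempfile("apni")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "frags.fna"); sf <- file.path(td, "subject.fna")
  qx <- Biostrings::DNAStringSet(frags)
  names(qx) <- names(frags)
  Biostrings::writeXStringSet(qx, qf)
  sx <- Biostrings::DNAStringSet(subject_contigs)
  names(sx) <- names(subject_contigs)
  Biostrings::writeXStringSet(sx, sf)
  db <- file.path(td, "db")
  st <- system2("makeblastdb", c("-in", sf, "-dbtype", "nucl", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed")
  out <- file.path(td, "hits.tsv")
  st <- system2("blastn",
                c("-task", "blastn", "-query", qf, "-db", db,
                  "-reward", "1", "-penalty", "-1",
                  "-gapopen", "5", "-gapextend", "2",
                  "-evalue", "1e-15", "-dust", "no",
                  "-xdrop_gap_final", "150",
                  "-outfmt", shQuote("6 qseqid pident length qlen bitscore"),
                  "-out", out),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastn failed")
  if (!file.size(out))
    return(list(ani = NA_real_, used = 0L, total = total))
  hits <- read.delim(out, header = FALSE,
                     col.names = c("qseqid", "pident", "length", "qlen",
                                   "bitscore"),
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$qseqid, -hits$bitscore), , drop = FALSE]
  hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  keep <- hits$pident / 100 >= params$min_fragment_identity &
    hits$length >= params$min_fragment_coverage * hits$qlen
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(list(ani = NA_real_, used = 0L, total = total))
  list(ani = mean(hits$pident), used = nrow(hits), total = total)
}

#' Average percent nucleotide identity between two genome assemblies
#'
#' Reciprocal fragment-based ANI (ANIb): each genome's fragments are aligned
#' to the other genome; a direction's ANI is the mean identity of retained
#' fragments, and APNI is the mean of the two directions. When no fragment is
#' retained in either direction the APNI is undefined (flagged, not zero).
#'
#' @param genomeA,genomeB `genome_assembly` objects (or named contig vectors).
#' @param params An [apni_params()].
#' @return An `apni_result`: genome pair, `apni` (percent, or NA with status
#'   "no alignment"), per-direction fragment counts, `same_species`.
#' @export
compute_apni <- function(genomeA, genomeB, params = apni_params()) {
  .require_blast()
  getc <- function(g) if (inherits(g, "genome_assembly")) g$contigs else g
  getid <- function(g, default) if (inherits(g, "genome_assembly"))
    g$genome_id else default
  ca <- getc(genomeA); cb <- getc(genomeB)
  if (!length(ca) || !length(cb)) stop("empty assembly")
  ab <- .apni_direction(ca, cb, params)
  ba <- .apni_direction(cb, ca, params)
  vals <- c(ab$ani, ba$ani)
  apni <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  structure(list(genome_A = getid(genomeA, "A"), genome_B = getid(genomeB, "B"),
                 apni = apni,
                 status = if (is.na(apni)) "no alignment" else "ok",
                 fragments_used = c(AvsB = ab$used, BvsA = ba$used),
                 fragments_total = c(AvsB = ab$total, BvsA = ba$total),
                 same_species = !is.na(apni) && apni >= params$species_cutoff,
                 params = params),
            class = "apni_result")
}

#' @export
print.apni_result <- function(x, ...) {
  cat("<apni_result> ", x$genome_A, " vs ", x$genome_B, ": APNI = ",
      ifelse(is.na(x$apni), "undefined (no alignment)",
             formatC(x$apni, format = "f", digits = 2)),
      if (!is.na(x$apni)) paste0("  same_species = ", x$same_species) else "",
      "\n", sep = "")
  invisible(x)
}

#' Pairwise APNI table for a set of assemblies
#'
#' @param assemblies Named list of `genome_assembly` objects.
#' @param params An [apni_params()].
#' @return Data.frame with one row per unordered pair (lower-triangle order).
#' @export
apni_matrix <- function(assemblies, params = apni_params()) {
  ids <- names(assemblies)
  stopifnot(length(ids) >= 2L)
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      r <- compute_apni(assemblies[[i]], assemblies[[j]], params)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_A = ids[i], genome_B = ids[j], apni = r$apni,
        same_species = r$same_species, status = r$status,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
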