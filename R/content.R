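#' Build the genome-by-COG presence/absence matrix
#'
#' @param cog_members COG membership table (`cog_id`, `genome_id`,
#'   `protein_id`); singleton COGs included. Paralogous members collapse to a
#'   single presence bit.
#' @param genomes Optional character vector of genome ids expected in the
#'   matrix; a listed genome contributing zero proteins is an error.
#' @return Logical matrix, rows = genomes, columns = COG ids.
#' @export
build_content_matrix <- function(cog_members, genomes = NULL) {
  stopifnot(is.data.frame(cog_members),
            all(c("cog_id", "genome_id") %in% names(cog_members)))
  seen <- sort(unique(cog_members$genome_id))
  if (is.null(genomes)) genomes <- seen
  missing_g <- setdiff(genomes, seen)
  if (length(missing_g))
    stop("genome(s) with zero proteins: ", paste(missing_g, collapse = ", "))
  cogs <- sort(unique(cog_members$cog_id))
  m <- matrix(FALSE, nrow = length(genomes), ncol = length(cogs),
              dimnames = list(genomes, cogs))
  keep <- cog_members$genome_id %in% genomes
  m[cbind(cog_members$genome_id[keep], cog_members$cog_id[keep])] <- TRUE
  m
}

#' Shared and unique COG counts for a genome pair
#'
#' Counts are computed against the pair only: a COG "unique to A" is present
#' in A and absent from B regardless of other genomes.
#'
#' @param matrix Presence matrix from [build_content_matrix()].
#' @param A,B Distinct genome ids (rows of the matrix).
#' @return List with `shared`, `unique_A`, `unique_B` counts and sorted COG
#'   id lists `shared_cogs`, `unique_A_cogs`, `unique_B_cogs`.
#' @export
pairwise_content <- function(matrix, A, B) {
  if (identical(A, B)) stop("A and B must differ")
  stopifnot(A %in% rownames(matrix), B %in% rownames(matrix))
  a <- matrix[A, ]; b <- matrix[B, ]
  list(shared = sum(a & b),
       unique_A = sum(a & !b),
       unique_B = sum(!a & b),
       shared_cogs = sort(colnames(matrix)[a & b]),
       unique_A_cogs = sort(colnames(matrix)[a & !b]),
       unique_B_cogs = sort(colnames(matrix)[!a & b]))
}

#' COGs present in every in-group genome and absent from every out-group genome
#'
#' Genomes outside both sets are ignored.
#'
#' @param matrix Presence matrix.
#' @param in_group,out_group Disjoint, nonempty genome id vectors.
#' @return Sorted character vector of COG ids.
#' @export
group_exclusive_cogs <- function(matrix, in_group, out_group) {
  if (!length(in_group) || !length(out_group))
    stop("in_group and out_group must be nonempty")
  if (length(intersect(in_group, out_group)))
    stop("in_group and out_group overlap")
  stopifnot(all(c(in_group, out_group) %in% rownames(matrix)))
  in_all <- colSums(matrix[in_group, , drop = FALSE]) == length(in_group)
  out_none <- colSums(matrix[out_group, , drop = FALSE]) == 0L
  sort(colnames(matrix)[in_all & out_none])
}

#' Parameters for the mobile-element annotation scan
#'
#' @param keywords Annotation keywords indicating plasmid/prophage origin.
#' @param contig_review_length Contigs shorter than this (bp) are listed for
#'   review regardless of keyword content.
#' @param flag_fraction Fraction of a contig's genes that must match a
#'   keyword for the contig to be flagged putative mobile.
#' @return A list of class `mobile_scan_params`.
#' @export
mobile_scan_params <- function(keywords = c("plasmid", "par", "phage",
                                            "replication"),
                               contig_review_length = 60000L,
                               flag_fraction = 0.5) {
  if (!length(keywords)) stop("keywords must be nonempty")
  structure(list(keywords = keywords,
                 contig_review_length = as.integer(contig_review_length),
                 flag_fraction = flag_fraction),
            class = "mobile_scan_params")
}

# Case-insensitive word match; "par" additionally matches gene-name style
# tokens like ParA/parB but never arbitrary words containing "par".
.matches_mobile <- function(annotation, keywords) {
  tokens <- strsplit(annotation, "[^A-Za-z0-9]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  for (kw in keywords) {
    if (kw == "par") {
      if (any(tolower(tokens) == "par") ||
          any(grepl("^[Pp]ar[A-Z][0-9]*$", tokens)))
        return(TRUE)
    } else if (any(tolower(tokens) == tolower(kw))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Scan contigs for putative plasmids and prophage
#'
#' A contig is flagged "putative mobile" when at least `flag_fraction` of its
#' annotated genes match a mobile-element keyword (case-insensitive word
#' match; "par" matches standalone or as a ParA-style gene name). Contigs
#' shorter than `contig_review_length` are additionally listed for review
#' regardless of their keyword fraction. Output is deterministic and
#' independent of gene input order.
#'
#' @param annotations Data.frame with `protein_id`, `contig_id`, `annotation`.
#' @param contig_lengths Named numeric vector contig id -> length (bp).
#' @param params A [mobile_scan_params()].
#' @return Data.frame per contig: gene counts, keyword fraction, `flagged`
#'   and `for_review`, sorted by contig id.
#' @export
mobile_element_scan <- function(annotations, contig_lengths,
                                params = mobile_scan_params()) {
  stopifnot(is.data.frame(annotations),
            all(c("contig_id", "annotation") %in% names(annotations)))
  hits <- vapply(annotations$annotation, .matches_mobile, logical(1),
                 keywords = params$keywords, USE.NAMES = FALSE)
  contigs <- sort(unique(c(annotations$contig_id, names(contig_lengths))))
  n_genes <- vapply(contigs, function(cg)
    sum(annotations$contig_id == cg), integer(1))
  n_mobile <- vapply(contigs, function(cg)
    sum(hits[annotations$contig_id == cg]), integer(1))
  frac <- ifelse(n_genes > 0, n_mobile / n_genes, 0)
  len <- unname(contig_lengths[contigs])
  data.frame(contig_id = contigs,
             length_bp = len,
             n_genes = unname(n_genes),
             n_mobile = unname(n_mobile),
             mobile_fraction = unname(frac),
             flagged = unname(n_genes > 0 & frac >= params$flag_fraction),
             for_review = unname(!is.na(len) &
                                   len < params$contig_review_length),
             stringsAsFactors = FALSE, row.names = NULL)
}
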