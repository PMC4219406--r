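#' Build a position-specific profile from a multiple alignment
#'
#' Columns with more than 50% gaps are marked as insert columns and excluded
#' from match scoring. Match-column scores are amino-acid log-odds against a
#' uniform background with add-one pseudocounts.
#'
#' @param aln Character matrix alignment (rows = sequences).
#' @return A `cog_profile`: list with `log_odds` (20 x n_match matrix),
#'   `match_cols` (alignment column indices), `consensus` (character vector)
#'   and `n_rows`.
#' @export
build_profile <- function(aln) {
  if (is.character(aln) && !is.matrix(aln) && length(aln) == 1L)
    aln <- matrix(strsplit(aln, "")[[1]], nrow = 1L)
  stopifnot(is.matrix(aln))
  if (nrow(aln) == 0L || ncol(aln) == 0L) stop("empty alignment")
  gap_frac <- colMeans(aln == "-")
  match_cols <- which(gap_frac <= 0.5)
  counts <- matrix(0L, nrow = 20L, ncol = length(match_cols),
                   dimnames = list(AA20, NULL))
  for (k in seq_along(match_cols)) {
    col <- aln[, match_cols[k]]
    tab <- table(factor(col[col %in% AA20], levels = AA20))
    counts[, k] <- as.integer(tab)
  }
  n_obs <- colSums(counts)
  freq <- sweep(counts + 1, 2L, n_obs + 20, "/")
  log_odds <- log(freq) - log(1 / 20)
  consensus <- AA20[apply(counts, 2L, which.max)]
  structure(list(log_odds = log_odds, match_cols = match_cols,
                 insert_cols = setdiff(seq_len(ncol(aln)), match_cols),
                 consensus = consensus, n_rows = nrow(aln)),
            class = "cog_profile")
}

# Global profile-to-sequence alignment score under the profile's log-odds,
# affine gaps. Residues outside the 20-letter alphabet (X) contribute 0.
.profile_seq_score <- function(profile, seq, gap_open = 11, gap_ext = 1) {
  res <- strsplit(seq, "")[[1]]
  idx <- match(res, AA20)
  n_match <- ncol(profile$log_odds)
  S <- matrix(0, nrow = n_match, ncol = length(res))
  known <- !is.na(idx)
  if (any(known))
    S[, known] <- t(profile$log_odds)[, idx[known], drop = FALSE]
  .nw_affine_score(S, gap_open, gap_ext)
}

#' Select the representative sequence and annotation for a COG
#'
#' Scores every sequence in the taxon pool against the COG's profile
#' (global profile-to-sequence alignment with affine gaps) and returns the
#' best scorer; ties are broken by the lexicographically smallest protein id.
#' The representative may lie outside the COG if a pool sequence scores
#' higher, in which case this is logged; its annotation becomes the cluster
#' annotation.
#'
#' @param cog Character vector of the COG's member protein ids.
#' @param profile A [build_profile()] result for the COG's alignment.
#' @param taxon_pool Protein table for the whole run (the pool searched).
#' @return List with `protein_id` and `annotation`.
#' @export
select_representative <- function(cog, profile, taxon_pool) {
  stopifnot(inherits(profile, "cog_profile"), is.data.frame(taxon_pool))
  if (nrow(taxon_pool) == 0L) stop("empty taxon pool")
  pool <- taxon_pool[order(taxon_pool$protein_id), , drop = FALSE]
  best_score <- -Inf; best_id <- NA_character_
  for (r in seq_len(nrow(pool))) {
    sc <- .profile_seq_score(profile, pool$residues[r])
    if (sc > best_score) {
      best_score <- sc
      best_id <- pool$protein_id[r]
    }
  }
  if (!(best_id %in% cog))
    ss_log("representative ", best_id, " lies outside its COG")
  ann <- pool$annotation[match(best_id, pool$protein_id)] %||% ""
  list(protein_id = best_id, annotation = ann, score = best_score)
}
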