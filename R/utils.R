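#' @useDynLib symbioscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats hclust as.dist rexp runif rbinom setNames
#' @importFrom utils write.table read.delim combn head
NULL

# Evaluate `code` under a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a vector of independent sub-seeds from one master seed. Keeps every
# derived seed strictly below 2^31 so they remain valid R integers.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

ss_log <- function(..., verbose = getOption("symbioscreen.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[symbioscreen] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# BLOSUM62 substitution matrix, cached once per session.
.pkg_cache <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}
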