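#' @useDynLib nrgcat, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of sub-seeds from a master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + 1000003 * seq_len(n)) %% 2147483647
}

#' Reverse complement of DNA strings
#'
#' Strict \{A,C,G,T,N\} alphabet; N maps to N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Validate a DNA sequence vector against the strict alphabet.
is_valid_dna <- function(x) {
  grepl("^[ACGTN]+$", x)
}

# Exact decimal serialization for provenance round-trips.
num_to_chr <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
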