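#' Catalog build parameters
#'
#' Bundles the thresholds of the clustering step and the filter cascade.
#' Defaults follow the published pipeline: clustering at 95% identity over
#' 90% of the shorter sequence with a word size of 8 (the `cd-hit-est -n 8
#' -c 0.95 -aS 0.9` convention), host screening at >= 75% identity over
#' >= 50% of the gene, containment deduplication at 100 bp exact matches,
#' and a robust-z cutoff of 5 for the anomaly screen.
#'
#' @param identity_threshold minimum clustering identity, as a fraction of
#'   the shorter sequence's length.
#' @param overlap_threshold minimum aligned fraction of the shorter sequence.
#' @param word_size prefilter word length in bases (4--12).
#' @param host_identity minimum local-alignment identity for host removal.
#' @param host_coverage minimum fraction of the gene covered by the host hit.
#' @param containment_min minimum exact shared substring (bp) for
#'   containment deduplication.
#' @param anomaly_z robust z-score cutoff for the anomaly screen.
#' @param anomaly_min_genes minimum genes per species for the anomaly screen.
#' @param strand_mode `"FORWARD"` clusters oriented coding sequences;
#'   `"BOTH"` also tries the reverse complement.
#' @return an object of class `build_params`.
#' @export
build_params <- function(identity_threshold = 0.95,
                         overlap_threshold = 0.90,
                         word_size = 8L,
                         host_identity = 0.75,
                         host_coverage = 0.50,
                         containment_min = 100L,
                         anomaly_z = 5.0,
                         anomaly_min_genes = 20L,
                         strand_mode = c("FORWARD", "BOTH")) {
  strand_mode <- match.arg(strand_mode)
  frac_ok <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x > 0 && x <= 1
  if (!frac_ok(identity_threshold)) stop("identity_threshold must be in (0, 1]")
  if (!frac_ok(overlap_threshold)) stop("overlap_threshold must be in (0, 1]")
  if (!frac_ok(host_identity)) stop("host_identity must be in (0, 1]")
  if (!frac_ok(host_coverage)) stop("host_coverage must be in (0, 1]")
  word_size <- as.integer(word_size)
  if (is.na(word_size) || word_size < 4L || word_size > 12L) {
    stop("word_size must be an integer in [4, 12]")
  }
  containment_min <- as.integer(containment_min)
  if (is.na(containment_min) || containment_min < 1L) {
    stop("containment_min must be >= 1")
  }
  if (!is.numeric(anomaly_z) || anomaly_z <= 0) stop("anomaly_z must be > 0")
  p <- list(identity_threshold = identity_threshold,
            overlap_threshold = overlap_threshold,
            word_size = word_size,
            host_identity = host_identity,
            host_coverage = host_coverage,
            containment_min = containment_min,
            anomaly_z = anomaly_z,
            anomaly_min_genes = as.integer(anomaly_min_genes),
            strand_mode = strand_mode)
  class(p) <- "build_params"
  p
}

#' @export
print.build_params <- function(x, ...) {
  cat("Catalog build parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, x[[nm]]))
  invisible(x)
}
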