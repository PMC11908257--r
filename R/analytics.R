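# Catalog- and profile-level statistics: gene accumulation curves,
# threshold-based species counting, compositional co-occurrence with a hard
# correlation threshold, and single-feature ROC AUC.

#' Gene accumulation curve
#'
#' For each of `n_orders` seeded random sample orders, computes the
#' cumulative number of distinct features (columns) observed as samples
#' (rows) are added, and reports the per-position mean and standard
#' deviation.  Each per-order curve is monotone nondecreasing.
#'
#' @param presence samples x features matrix (logical, or numeric treated
#'   as present when `> 0`); row names are sample ids.
#' @param n_orders number of random orders to average over.
#' @param seed integer seed.
#' @return data.table with `position`, `mean`, `sd`.
#' @export
accumulation_curve <- function(presence, n_orders = 100L, seed = 1L) {
  m <- presence > 0
  if (!is.matrix(m) || nrow(m) < 1L) {
    stop("presence must be a matrix with at least one sample", call. = FALSE)
  }
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m))) {
    stop("duplicate sample ids in presence matrix", call. = FALSE)
  }
  n <- nrow(m)
  curves <- with_seed(seed, {
    vapply(seq_len(n_orders), function(o) {
      ord <- sample.int(n)
      first <- apply(m[ord, , drop = FALSE], 2L, function(col) {
        w <- which(col)
        if (length(w) == 0L) NA_integer_ else w[1]
      })
      cumsum(tabulate(first[!is.na(first)], nbins = n))
    }, numeric(n))
  })
  curves <- matrix(curves, nrow = n)
  data.table(position = seq_len(n),
             mean = rowMeans(curves),
             sd = apply(curves, 1L, stats::sd))
}

#' Count taxa above a detection threshold
#'
#' Counts the listed taxa whose relative abundance is strictly greater than
#' `threshold` (1% by default -- the conservative detection threshold used
#' for counting co-occurring congeneric species).
#'
#' @param composition a `composition_profile` from [compose()].
#' @param taxa character vector of taxon names to consider.
#' @param threshold detection threshold (strict).
#' @return integer count.
#' @export
count_species_over_threshold <- function(composition, taxa,
                                         threshold = 0.01) {
  sum(composition$taxon %in% taxa & composition$share > threshold)
}

clr_transform <- function(x, pseudocount = NULL) {
  # x: samples x taxa relative abundances; per-sample pseudocount defaults
  # to half the smallest nonzero share of that sample
  t(apply(x, 1L, function(row) {
    pc <- pseudocount %||% (min(row[row > 0]) / 2)
    lx <- log(row + pc)
    lx - mean(lx)
  }))
}

#' Compositional co-occurrence with a hard correlation threshold
#'
#' CLR-transforms a samples x taxa abundance matrix (per-sample pseudocount:
#' half the smallest nonzero share), then computes pairwise Pearson
#' correlations over the samples where at least one of the pair is
#' detected.  Coefficients with `|r| < hard_threshold` or with a
#' correlation-test p-value `>= alpha` are set to zero.  This is a stated
#' simplification of sparse compositional correlation machinery: the
#' thresholded-Pearson-on-CLR core, without its bias-correction step.
#'
#' @param abundance samples x taxa numeric matrix of relative abundances.
#' @param hard_threshold absolute-correlation floor (coefficients below it
#'   report as 0).
#' @param alpha significance level for the correlation t-test.
#' @param pseudocount optional fixed pseudocount for the CLR transform.
#' @return symmetric taxa x taxa coefficient matrix with unit diagonal;
#'   attribute `flagged` names taxa with undefined (constant) columns.
#' @export
cooccurrence <- function(abundance, hard_threshold = 0.3, alpha = 0.001,
                         pseudocount = NULL) {
  if (nrow(abundance) < 10L) {
    stop("cooccurrence requires at least 10 samples", call. = FALSE)
  }
  if (ncol(abundance) < 2L) {
    stop("cooccurrence requires at least 2 taxa", call. = FALSE)
  }
  clr <- clr_transform(abundance, pseudocount)
  p <- ncol(abundance)
  taxa <- colnames(abundance) %||% paste0("t", seq_len(p))
  r <- diag(1, p)
  dimnames(r) <- list(taxa, taxa)
  flagged <- character(0)
  for (i in seq_len(p - 1L)) {
    for (j in seq.int(i + 1L, p)) {
      use <- abundance[, i] > 0 | abundance[, j] > 0
      n <- sum(use)
      val <- 0
      if (n >= 3L) {
        xi <- clr[use, i]; xj <- clr[use, j]
        if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
          flagged <- c(flagged, taxa[i], taxa[j])
        } else {
          rv <- stats::cor(xi, xj)
          tt <- rv * sqrt((n - 2) / max(1 - rv^2, .Machine$double.eps))
          pval <- 2 * stats::pt(-abs(tt), df = n - 2)
          if (abs(rv) >= hard_threshold && pval < alpha) val <- rv
        }
      }
      r[i, j] <- r[j, i] <- val
    }
  }
  attr(r, "flagged") <- unique(flagged)
  r
}

#' Single-feature ROC AUC
#'
#' `AUC = P(value_pos > value_neg) + 0.5 P(tie)` over all positive-negative
#' pairs, computed via the rank (Mann-Whitney) identity.
#'
#' @param values per-sample feature values (e.g. relative abundances).
#' @param labels binary labels (logical, or coercible; `TRUE` = positive).
#' @return AUC as a fraction in `[0, 1]`.
#' @export
auc_single_feature <- function(values, labels) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auc_single_feature requires both classes to be non-empty",
         call. = FALSE)
  }
  rk <- rank(values)  # midranks handle ties
  (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
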