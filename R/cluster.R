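# Greedy incremental clustering of coding sequences into non-redundant gene
# clusters: sort by length descending, first-fit against existing
# representatives, with a shared-word prefilter ahead of each alignment.
# Identity is counted over the shorter sequence (the CD-HIT -c convention
# used together with -aS).

# Substitution matrix over the strict alphabet; N never matches anything
# (conservative: an N column is a mismatch even against another N).
dna_submat <- function(match = 1L, mismatch = -1L) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

# Matching columns and aligned pattern span of a pairwiseAlignment result.
# pattern()/subject() return the aligned region only, with gaps, at equal
# length.
aln_stats <- function(pa) {
  p <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  matches <- sum(p == s & p != "-" & p != "N")
  list(matches = matches,
       aligned_span = sum(p != "-"),
       columns = length(p))
}

#' Semi-global alignment of two sequences
#'
#' Aligns the shorter sequence against the longer with free end gaps on both
#' (overlap alignment).  Identity is matching columns divided by the length
#' of the shorter sequence; coverage is the aligned span of the shorter
#' sequence divided by its length.  With `strand_mode = "BOTH"` the reverse
#' complement of the shorter sequence is also tried and the better identity
#' wins.
#'
#' @param a,b DNA strings (non-empty).
#' @param params a [build_params()] object.
#' @return list with `identity`, `shorter_coverage`, and `aligned` (`TRUE`
#'   when both clustering thresholds are met).
#' @export
align_pair <- function(a, b, params = build_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  shorter <- if (nchar(a) <= nchar(b)) a else b
  longer <- if (nchar(a) <= nchar(b)) b else a
  one <- function(q) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = q, subject = longer, type = "overlap",
      substitutionMatrix = dna_submat(), gapOpening = 5, gapExtension = 2)
    st <- aln_stats(pa)
    list(identity = st$matches / nchar(q),
         shorter_coverage = st$aligned_span / nchar(q))
  }
  res <- one(shorter)
  if (params$strand_mode == "BOTH") {
    alt <- one(revcomp(shorter))
    if (alt$identity > res$identity) res <- alt
  }
  res$aligned <- res$identity >= params$identity_threshold &&
    res$shorter_coverage >= params$overlap_threshold
  res
}

# Admissible shared-word threshold for a query of length lq: a sequence
# within the identity threshold (substitution-only) destroys at most
# word_size words per substitution, so a true match shares at least
# (lq - w + 1) - w * floor((1 - identity) * lq) words.
prefilter_threshold <- function(lq, params) {
  w <- params$word_size
  max(1L, (lq - w + 1L) -
        w * floor((1 - params$identity_threshold) * lq))
}

#' Shared-word prefilter for a candidate pair
#'
#' Returns `FALSE` only when the number of query word positions whose word
#' occurs in the candidate falls below the admissible bound, so a true match
#' under substitution-only divergence is never rejected.
#'
#' @param query the shorter sequence.
#' @param candidate the longer sequence (`nchar(query) <= nchar(candidate)`).
#' @param params a [build_params()] object.
#' @return logical: could this pair satisfy the clustering thresholds?
#' @export
kmer_prefilter <- function(query, candidate, params = build_params()) {
  stopifnot(nchar(query) <= nchar(candidate))
  qc <- .kmer_codes(query, params$word_size)
  cand <- sort(unique(.kmer_codes(candidate, params$word_size)))
  hits <- .prefilter_hits(qc, list(cand), params$word_size,
                          prefilter_threshold(nchar(query), params))
  length(hits) > 0L
}

#' Greedy incremental gene clustering
#'
#' Genes are sorted by length descending (ties: lexicographically smallest
#' `gene_id` first) and assigned first-fit to the earliest existing
#' representative whose alignment meets the identity and overlap thresholds;
#' otherwise the gene founds a new cluster.  Representatives are therefore a
#' longest member of their cluster and mutually non-redundant.
#'
#' @param genes gene table (columns `gene_id`, `sequence`, `length`).
#' @param params a [build_params()] object.
#' @return data.table with one row per gene: `gene_id`, `nrg_id` (the
#'   representative's `gene_id`), `is_representative`.
#' @export
cluster_genes <- function(genes, params = build_params()) {
  if (nrow(genes) == 0L) stop("cluster_genes: empty input", call. = FALSE)
  ord <- order(-genes$length, genes$gene_id)
  ids <- genes$gene_id[ord]
  seqs <- genes$sequence[ord]
  lens <- genes$length[ord]
  w <- params$word_size
  rep_idx <- integer(0)        # indices (into ord) of representatives
  rep_codes <- list()          # sorted unique word codes per representative
  assign_to <- integer(length(ids))
  for (i in seq_along(ids)) {
    qc <- .kmer_codes(seqs[i], w)
    hit <- 0L
    if (length(rep_idx) > 0L) {
      thr <- prefilter_threshold(lens[i], params)
      cand <- .prefilter_hits(qc, rep_codes, w, thr)
      for (r in cand) {
        al <- align_pair(seqs[i], seqs[rep_idx[r]], params)
        if (al$aligned) { hit <- r; break }
      }
    }
    if (hit > 0L) {
      assign_to[i] <- rep_idx[hit]
    } else {
      rep_idx <- c(rep_idx, i)
      rep_codes[[length(rep_idx)]] <- sort(unique(qc))
      assign_to[i] <- i
    }
  }
  data.table(gene_id = ids, nrg_id = ids[match(assign_to, seq_along(ids))],
             is_representative = assign_to == seq_along(ids))[order(gene_id)]
}

#' Summarize clusters
#'
#' @param cluster_map output of [cluster_genes()].
#' @return data.table with `cluster_id` (= representative gene id),
#'   `representative_id`, `size`.
#' @export
cluster_summary <- function(cluster_map) {
  cluster_map[, .(representative_id = nrg_id[1], size = .N),
              by = .(cluster_id = nrg_id)][order(cluster_id)]
}
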