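# The four-stage filter cascade applied to non-redundant genes after
# clustering, in fixed order: host screen -> N filter -> exact-substring
# containment deduplication -> anomaly screen.  Each stage returns the kept
# and removed gene tables plus a removal log.

filter_result <- function(nrgs, removed_ids, stage, statistic = NA_character_) {
  removed <- nrgs[nrg_id %in% removed_ids]
  log <- if (length(removed_ids) > 0L) {
    data.table(nrg_id = removed_ids, stage = stage, statistic = statistic)
  } else {
    data.table(nrg_id = character(0), stage = character(0),
               statistic = character(0))
  }
  list(kept = nrgs[!nrg_id %in% removed_ids], removed = removed, log = log)
}

#' Screen genes against a host (or other unwanted) genome
#'
#' A gene is removed when some local alignment against a host sequence
#' reaches `host_identity` identity over at least `host_coverage` of the
#' gene's length.  Both strands are searched.  Identity is matching columns
#' over alignment columns (the blastn percent-identity convention); coverage
#' is the aligned gene span over the gene length.
#'
#' @param nrgs gene table with `nrg_id`, `sequence`, `length`.
#' @param host_sequences character vector of host sequences (a no-op when
#'   empty or `NULL`).
#' @param params a [build_params()] object.
#' @return list of `kept`, `removed`, `log`.
#' @export
screen_against_host <- function(nrgs, host_sequences, params = build_params()) {
  if (is.null(host_sequences) || length(host_sequences) == 0L) {
    return(filter_result(nrgs, character(0), "host"))
  }
  mat <- dna_submat(match = 2L, mismatch = -1L)
  hit <- function(g) {
    for (h in host_sequences) {
      for (q in c(g, revcomp(g))) {
        pa <- Biostrings::pairwiseAlignment(
          pattern = q, subject = h, type = "local",
          substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
        st <- aln_stats(pa)
        if (st$columns == 0L) next
        identity <- st$matches / st$columns
        coverage <- st$aligned_span / nchar(g)
        if (identity >= params$host_identity &&
            coverage >= params$host_coverage) {
          return(sprintf("identity=%.4f;coverage=%.4f", identity, coverage))
        }
      }
    }
    NA_character_
  }
  stat <- vapply(nrgs$sequence, hit, character(1), USE.NAMES = FALSE)
  removed_ids <- nrgs$nrg_id[!is.na(stat)]
  res <- filter_result(nrgs, removed_ids, "host")
  if (length(removed_ids) > 0L) res$log$statistic <- stat[!is.na(stat)]
  res
}

#' Remove genes containing ambiguous bases
#'
#' Removes exactly the genes whose sequence contains at least one `N`.
#'
#' @inheritParams screen_against_host
#' @return list of `kept`, `removed`, `log`.
#' @export
drop_n_genes <- function(nrgs) {
  removed_ids <- nrgs$nrg_id[grepl("N", nrgs$sequence, fixed = TRUE)]
  filter_result(nrgs, removed_ids, "n_filter", "contains_N")
}

#' Containment deduplication
#'
#' For every pair of genes sharing an exact common substring of at least
#' `containment_min` bases, the shorter gene is removed (ties on length:
#' the lexicographically larger id is removed).  Removal is evaluated
#' against the original input set in a single pass, so an already-removed
#' gene still witnesses the removal of others.  A shared substring of
#' length >= L exists iff the pair shares an L-mer, which is how the scan is
#' implemented.
#'
#' @inheritParams screen_against_host
#' @return list of `kept`, `removed`, `log`.
#' @export
containment_dedup <- function(nrgs, params = build_params()) {
  L <- params$containment_min
  eligible <- which(nrgs$length >= L)
  if (length(eligible) < 2L) {
    return(filter_result(nrgs, character(0), "containment"))
  }
  km <- rbindlist(lapply(eligible, function(i) {
    starts <- seq_len(nrgs$length[i] - L + 1L)
    data.table(kmer = unique(substring(nrgs$sequence[i], starts,
                                       starts + L - 1L)),
               idx = i)
  }))
  shared <- km[, if (.N > 1L) .(idx = list(idx)), by = kmer]
  removed <- character(0)
  witness <- character(0)
  if (nrow(shared) > 0L) {
    pairs <- unique(rbindlist(lapply(shared$idx, function(ix) {
      cmb <- utils::combn(sort(ix), 2L)
      data.table(i = cmb[1, ], j = cmb[2, ])
    })))
    li <- nrgs$length[pairs$i]; lj <- nrgs$length[pairs$j]
    ii <- nrgs$nrg_id[pairs$i]; ij <- nrgs$nrg_id[pairs$j]
    loser <- fifelse(li > lj, ij,
                     fifelse(lj > li, ii, pmax(ii, ij)))
    winner <- fifelse(loser == ij, ii, ij)
    keep1 <- !duplicated(loser)
    removed <- loser[keep1]
    witness <- winner[keep1]
  }
  res <- filter_result(nrgs, removed, "containment")
  if (length(removed) > 0L) {
    res$log$statistic <- sprintf("contained_in=%s", witness)
  }
  res
}

cosine_dist <- function(m, centroid) {
  num <- as.vector(m %*% centroid)
  den <- sqrt(rowSums(m^2)) * sqrt(sum(centroid^2))
  1 - num / pmax(den, .Machine$double.eps)
}

robust_z <- function(x) {
  med <- stats::median(x)
  madv <- stats::mad(x)
  if (madv < .Machine$double.eps) {
    z <- rep(0, length(x))
    z[x != med] <- Inf * sign(x[x != med] - med)
    return(z)
  }
  (x - med) / madv
}

#' Anomaly screen on composition, abundance and prevalence
#'
#' For every species-annotated gene, three statistics are computed within
#' its species: (i) cosine distance of the gene's tetranucleotide frequency
#' vector to the species centroid, (ii) log10 median depth across the
#' samples containing the species, and (iii) the gene's prevalence among
#' those samples.  Each statistic is converted to a robust z-score
#' (median/MAD) within species, and a gene is removed when any |z| exceeds
#' `anomaly_z`.  Species with fewer than `anomaly_min_genes` genes are
#' skipped, as are genes without a species-level taxon.  Without a presence
#' table only the tetramer statistic is used (with a warning).
#'
#' @param nrgs gene table with `nrg_id`, `sequence`, `length`, and a
#'   `species` column (`NA`/empty for genes without species-level taxonomy).
#' @param presence optional long table of per-sample depth:
#'   `nrg_id`, `sample_id`, `depth`.
#' @param params a [build_params()] object.
#' @return list of `kept`, `removed`, `log`, and `scores` (all per-gene
#'   statistics and z-scores, for re-thresholding).
#' @export
anomaly_filter <- function(nrgs, presence = NULL, params = build_params()) {
  if (!"species" %in% names(nrgs)) {
    stop("anomaly_filter requires a species column", call. = FALSE)
  }
  use_presence <- !is.null(presence) && nrow(presence) > 0L
  if (!use_presence) {
    warning("no per-sample presence table: anomaly screen runs in ",
            "tetramer-only mode", call. = FALSE)
  }
  sp <- nrgs$species
  sp[is.na(sp)] <- ""
  counts <- table(sp[nzchar(sp)])
  active_sp <- names(counts)[counts >= params$anomaly_min_genes]
  scores <- data.table(nrg_id = character(0), species = character(0),
                       tetramer_dist = numeric(0), log_depth = numeric(0),
                       prevalence = numeric(0), z_tetramer = numeric(0),
                       z_depth = numeric(0), z_prevalence = numeric(0))
  removed_ids <- character(0)
  stat <- character(0)
  for (s in active_sp) {
    idx <- which(sp == s)
    seqs <- Biostrings::DNAStringSet(nrgs$sequence[idx])
    tf <- Biostrings::oligonucleotideFrequency(seqs, width = 4L)
    tf <- tf / pmax(rowSums(tf), 1L)
    centroid <- colMeans(tf)
    d_tet <- cosine_dist(tf, centroid)
    z_tet <- robust_z(d_tet)
    if (use_presence) {
      ids <- nrgs$nrg_id[idx]
      pres <- presence[nrg_id %in% ids]
      sp_samples <- unique(pres$sample_id[pres$depth > 0])
      n_s <- length(sp_samples)
      if (n_s > 0L) {
        wide <- dcast(pres[sample_id %in% sp_samples],
                      nrg_id ~ sample_id, value.var = "depth", fill = 0,
                      fun.aggregate = sum)
        depth_mat <- matrix(0, nrow = length(ids), ncol = n_s,
                            dimnames = list(ids, sp_samples))
        if (nrow(wide) > 0L) {
          m <- as.matrix(wide[, -1, drop = FALSE])
          depth_mat[wide$nrg_id, colnames(m)] <- m
        }
        med_depth <- apply(depth_mat, 1L, stats::median)
        l_dep <- log10(med_depth + 1e-6)
        prev <- rowMeans(depth_mat > 0)
      } else {
        l_dep <- rep(NA_real_, length(idx))
        prev <- rep(NA_real_, length(idx))
      }
    } else {
      l_dep <- rep(NA_real_, length(idx))
      prev <- rep(NA_real_, length(idx))
    }
    z_dep <- if (all(is.na(l_dep))) rep(NA_real_, length(idx)) else robust_z(l_dep)
    z_prev <- if (all(is.na(prev))) rep(NA_real_, length(idx)) else robust_z(prev)
    zmat <- cbind(z_tet, z_dep, z_prev)
    bad <- apply(zmat, 1L, function(z) any(abs(z) > params$anomaly_z,
                                           na.rm = TRUE))
    scores <- rbind(scores, data.table(
      nrg_id = nrgs$nrg_id[idx], species = s, tetramer_dist = d_tet,
      log_depth = l_dep, prevalence = prev, z_tetramer = z_tet,
      z_depth = z_dep, z_prevalence = z_prev))
    if (any(bad)) {
      removed_ids <- c(removed_ids, nrgs$nrg_id[idx][bad])
      stat <- c(stat, sprintf("z_tet=%.2f;z_depth=%.2f;z_prev=%.2f",
                              z_tet[bad], z_dep[bad], z_prev[bad]))
    }
  }
  res <- filter_result(nrgs, removed_ids, "anomaly")
  if (length(removed_ids) > 0L) res$log$statistic <- stat
  res$scores <- scores
  res
}
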