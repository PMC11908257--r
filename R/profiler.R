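# Catalog-based profiling of metagenome/metatranscriptome reads: end-to-end
# mapping against the NRG sequences, multi-mapping resolution by equal
# fractional split among best-score alignments, gene-length-corrected
# coverage ("depth"), taxon relative abundance, and TPM.

#' Map reads end-to-end against a catalog
#'
#' Candidate genes are found through exact (mismatch-free) seed matches of
#' length `seed_len` taken at every read offset; each candidate placement is
#' scored by full-length, gap-free end-to-end comparison.  Reads whose best
#' alignment identity falls below `min_identity` are dropped (unaligned reads
#' are never reported); up to `k` best-score alignments are reported per
#' read.
#'
#' @param reads a character vector of read sequences, a data.table with
#'   `id`/`sequence` columns (as from [read_fastq()]), or a FASTQ path.
#' @param catalog an `nrg_catalog`, or any table with `nrg_id` and
#'   `sequence` columns.
#' @param seed_len exact-seed length in bases.
#' @param k maximum number of reported alignments per read.
#' @param min_identity minimum end-to-end identity for a reported alignment.
#' @param both_strands also try the reverse complement of each read.
#' @param seed_stride spacing between seed offsets along the read; at the
#'   default `seed_len / 2` every base is covered by two seed windows, so a
#'   placement is guaranteed to be found for reads with up to
#'   `floor((len - seed_len + 1) / seed_stride / 2)` substitutions.
#' @return alignment table: `read_id`, `nrg_id`, `pos` (1-based), `strand`
#'   (+1/-1), `mismatches`, `aln_len`, `score` (matching bases), `read_seq`;
#'   attribute `n_reads` holds the input read count.
#' @export
map_reads <- function(reads, catalog, seed_len = 20L, k = 10L,
                      min_identity = 0.90, both_strands = TRUE,
                      seed_stride = max(1L, seed_len %/% 2L)) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.data.frame(reads)) {
    read_ids <- reads$id
    read_seqs <- reads$sequence
  } else {
    read_seqs <- reads
    read_ids <- names(reads) %||% sprintf("read%07d", seq_along(reads))
    if (is.null(names(reads)) == FALSE && any(!nzchar(read_ids))) {
      read_ids <- sprintf("read%07d", seq_along(reads))
    }
  }
  ref <- if (inherits(catalog, "nrg_catalog")) catalog$entries else catalog
  if (nrow(ref) == 0L) stop("catalog has no entries", call. = FALSE)
  hit <- .map_reads(read_seqs, ref$sequence, as.integer(seed_len),
                    as.integer(k), min_identity, both_strands,
                    as.integer(seed_stride))
  if (hit$n_too_short > 0L) {
    warning(hit$n_too_short, " read(s) shorter than the seed length were ",
            "counted as unmapped", call. = FALSE)
  }
  aln <- data.table(read_id = read_ids[hit$read],
                    nrg_id = ref$nrg_id[hit$gene],
                    pos = hit$pos, strand = hit$strand,
                    mismatches = hit$mismatches, aln_len = hit$len,
                    score = hit$len - hit$mismatches,
                    read_seq = read_seqs[hit$read])
  setattr(aln, "n_reads", length(read_seqs))
  aln
}

#' Quantify per-gene coverage from alignments
#'
#' Every read contributes total weight 1, split equally among its best-score
#' alignments.  `bases` is the weighted aligned length and `depth` (gene
#' coverage) is `bases / gene length` -- the gene-length correction applied
#' before computing relative abundances.  Genes with zero mapped reads are
#' omitted.
#'
#' @param aln alignment table from [map_reads()] or [read_sam()].
#' @param catalog an `nrg_catalog` (or a table with `nrg_id` and `length`).
#' @param sample_id label stored on the profile.
#' @return a `gene_profile` data.table: `nrg_id`, `reads`, `bases`, `depth`.
#' @export
quantify <- function(aln, catalog, sample_id = "sample") {
  ref <- if (inherits(catalog, "nrg_catalog")) catalog$entries else catalog
  empty <- data.table(nrg_id = character(0), reads = numeric(0),
                      bases = numeric(0), depth = numeric(0))
  if (nrow(aln) == 0L) {
    prof <- empty
  } else {
    unknown <- setdiff(unique(aln$nrg_id), ref$nrg_id)
    if (length(unknown) > 0L) {
      stop("alignment references unknown NRG: ", unknown[1], call. = FALSE)
    }
    a <- copy(aln)
    a[, best := score == max(score), by = read_id]
    a <- a[best == TRUE]
    a[, weight := 1 / .N, by = read_id]
    prof <- a[, .(reads = sum(weight), bases = sum(weight * aln_len)),
              by = nrg_id]
    prof <- merge(prof, ref[, .(nrg_id, length)], by = "nrg_id")
    prof[, depth := bases / length]
    prof[, length := NULL]
    prof <- prof[order(nrg_id)]
  }
  setattr(prof, "sample_id", sample_id)
  setattr(prof, "class", c("gene_profile", class(prof)))
  prof[]
}

#' Taxon relative abundance from a gene profile
#'
#' The share of a taxon is the sum of depths (gene coverages) of its genes
#' divided by the total depth.  Species- and genus-level labels are separate
#' buckets; `MULTIGENERA` and `UNASSIGNED` are their own buckets.
#'
#' @param profile a `gene_profile` from [quantify()].
#' @param taxonomy taxonomy table (`nrg_id`, `rank`, `name`) -- typically
#'   `catalog$entries`.
#' @return a `composition_profile` data.table (`taxon`, `rank`, `share`)
#'   with attributes `total_depth` and `empty` (flagged `TRUE` when nothing
#'   mapped, instead of dividing by zero).
#' @export
compose <- function(profile, taxonomy) {
  tx <- as.data.table(taxonomy)[, .(nrg_id, rank, name)]
  miss <- setdiff(profile$nrg_id, tx$nrg_id)
  if (length(miss) > 0L) {
    stop("taxonomy does not cover NRG: ", miss[1], call. = FALSE)
  }
  m <- merge(profile, tx, by = "nrg_id")
  m[, taxon := fifelse(rank %in% c("SPECIES", "GENUS"), name, rank)]
  comp <- m[, .(depth = sum(depth)), by = .(taxon, rank)]
  total <- sum(comp$depth)
  if (total <= 0 || nrow(comp) == 0L) {
    out <- data.table(taxon = character(0), rank = character(0),
                      share = numeric(0))
    setattr(out, "total_depth", 0)
    setattr(out, "empty", TRUE)
  } else {
    out <- comp[, .(taxon, rank, share = depth / total)][order(-share)]
    setattr(out, "total_depth", total)
    setattr(out, "empty", FALSE)
  }
  setattr(out, "sample_id", attr(profile, "sample_id"))
  setattr(out, "class", c("composition_profile", class(out)))
  out[]
}

#' Transcripts per million
#'
#' `rate_g = reads_g / (length_g / 1000)`; TPM is the rate rescaled to sum
#' to one million over all mapped genes.
#'
#' @param profile a `gene_profile` from [quantify()].
#' @param catalog an `nrg_catalog` (or table with `nrg_id`, `length`).
#' @return an `expression_profile` data.table (`nrg_id`, `tpm`); attribute
#'   `empty` is `TRUE` when no reads mapped.
#' @export
tpm <- function(profile, catalog) {
  ref <- if (inherits(catalog, "nrg_catalog")) catalog$entries else catalog
  if (nrow(profile) == 0L || sum(profile$reads) <= 0) {
    out <- data.table(nrg_id = character(0), tpm = numeric(0))
    setattr(out, "empty", TRUE)
  } else {
    m <- merge(profile, ref[, .(nrg_id, length)], by = "nrg_id")
    m[, rate := reads / (length / 1000)]
    out <- m[, .(nrg_id, tpm = rate / sum(rate) * 1e6)][order(nrg_id)]
    setattr(out, "empty", FALSE)
  }
  setattr(out, "sample_id", attr(profile, "sample_id"))
  setattr(out, "class", c("expression_profile", class(out)))
  out[]
}
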