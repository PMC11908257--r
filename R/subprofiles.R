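# Sub-profiles derived from a sample's gene or expression profile: the
# fungal fraction (mycobiome), the bacteriophage fraction and its
# virulent:temperate ratio, the acceptance filter for predicted phage
# contigs, per-species transcriptome extraction, and CAZy-family expression
# matrices with taxon contributions.

#' Mycobiome sub-profile
#'
#' The mycobiome is "detected" when the total fungal relative abundance is
#' strictly above `threshold` (default 1e-4).  Within-fungi shares are
#' renormalized to sum to one over the fungal species.
#'
#' @param composition a `composition_profile` from [compose()].
#' @param fungal_species character vector of fungal species names.
#' @param threshold detection threshold on the total fungal share.
#' @return list with `total_share`, `detected`, and `within` (data.table
#'   `taxon`, `share` renormalized over fungi).
#' @export
mycobiome <- function(composition, fungal_species, threshold = 1e-4) {
  stopifnot(length(fungal_species) > 0L)
  fun <- composition[rank == "SPECIES" & taxon %in% fungal_species]
  total <- sum(fun$share)
  within <- if (total > 0) {
    fun[, .(taxon, share = share / total)][order(-share)]
  } else {
    data.table(taxon = character(0), share = numeric(0))
  }
  list(total_share = total, detected = total > threshold, within = within)
}

#' Phageome sub-profile
#'
#' The phage share is the summed depth of phage-annotated genes over the
#' total depth; the lifestyle ratio is the summed coverage of virulent
#' genes divided by that of temperate genes (flagged undefined when the
#' temperate depth is zero).
#'
#' @param profile a `gene_profile` from [quantify()].
#' @param phage_table phage annotation table (`nrg_id`, `lifestyle`,
#'   `family`, `host_genus`).
#' @return list with `phage_share`, `virulent_temperate_ratio`,
#'   `ratio_defined`, `by_host`, `by_family` (depth per host genus/family).
#' @export
phageome <- function(profile, phage_table) {
  ph <- merge(profile, as.data.table(phage_table), by = "nrg_id")
  total <- sum(profile$depth)
  share <- if (total > 0) sum(ph$depth) / total else 0
  vir <- sum(ph$depth[ph$lifestyle == "VIRULENT"])
  tem <- sum(ph$depth[ph$lifestyle == "TEMPERATE"])
  list(phage_share = share,
       virulent_temperate_ratio = if (tem > 0) vir / tem else NA_real_,
       ratio_defined = tem > 0,
       by_host = ph[, .(depth = sum(depth)), by = host_genus][order(-depth)],
       by_family = ph[, .(depth = sum(depth)), by = family][order(-depth)])
}

#' Acceptance filter for predicted phage contigs
#'
#' A candidate contig is accepted iff it has more than one known viral gene,
#' is not predicted to be a prophage, has fewer than 10 bacterial host
#' genes, and a completeness estimate strictly above 90%.  A host genus is
#' recorded only when the host-prediction score is at least 1400.
#'
#' @param candidates data.table with columns `contig_id`,
#'   `viral_gene_count`, `is_prophage` (logical), `host_gene_count`,
#'   `completeness`; optional `host_genus` and `host_score`.
#' @param min_host_score score threshold for accepting a host prediction.
#' @return data.table of accepted contigs (`contig_id`, `host_genus` --
#'   empty when the score was below threshold or absent).
#' @export
phage_contig_filter <- function(candidates, min_host_score = 1400) {
  cand <- as.data.table(candidates)
  req <- c("contig_id", "viral_gene_count", "is_prophage",
           "host_gene_count", "completeness")
  miss <- setdiff(req, names(cand))
  if (length(miss) > 0L) {
    stop("phage candidate table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ok <- cand$viral_gene_count > 1 &
    !as.logical(cand$is_prophage) &
    cand$host_gene_count < 10 &
    cand$completeness > 90
  acc <- cand[ok]
  host <- if ("host_genus" %in% names(acc)) acc$host_genus else
    rep("", nrow(acc))
  if ("host_score" %in% names(acc)) {
    host[is.na(acc$host_score) | acc$host_score < min_host_score] <- ""
  }
  data.table(contig_id = acc$contig_id,
             host_genus = fifelse(is.na(host), "", host))
}

#' Extract one species' transcriptome
#'
#' Refuses (returning the observed count) when the number of reads mapped
#' to the species' genes is not strictly greater than `min_reads`;
#' otherwise emits the whole-sample TPM values restricted to the species'
#' genes plus a species-renormalized variant (TPM recomputed over the
#' species' genes only).
#'
#' @param profile a `gene_profile` from [quantify()].
#' @param catalog an `nrg_catalog`.
#' @param species species name (must exist in the catalog taxonomy).
#' @param min_reads minimum species-mapped reads; the published pipeline
#'   used 100000 for sample selection and 250000 in the corresponding
#'   figure, so both are supported through this parameter.
#' @return list with `emitted`, `species_reads`, and (when emitted) `table`
#'   (`nrg_id`, `tpm_whole_sample`, `tpm_species`).
#' @export
species_transcriptome <- function(profile, catalog, species,
                                  min_reads = 100000) {
  tx <- catalog$entries
  sp_genes <- tx[rank == "SPECIES" & name == species, nrg_id]
  if (length(sp_genes) == 0L) {
    stop("species not found in catalog taxonomy: ", species, call. = FALSE)
  }
  sp_prof <- profile[nrg_id %in% sp_genes]
  n <- sum(sp_prof$reads)
  if (!(n > min_reads)) {
    return(list(emitted = FALSE, species_reads = n))
  }
  whole <- tpm(profile, catalog)
  sub <- whole[nrg_id %in% sp_genes]
  within <- tpm(sp_prof, catalog)
  tbl <- merge(sub[, .(nrg_id, tpm_whole_sample = tpm)],
               within[, .(nrg_id, tpm_species = tpm)], by = "nrg_id")
  list(emitted = TRUE, species_reads = n, table = tbl[order(nrg_id)])
}

#' CAZy-family expression matrix and taxon contributions
#'
#' Sums TPM per CAZy family and sample; a gene annotated with several
#' families contributes its full TPM to each of them (families are analyzed
#' marginally; TPM is never double-counted within a family).  The
#' contribution of a taxon to a family is its share of the family's TPM in
#' that sample.
#'
#' @param expressions named list of `expression_profile` objects (names are
#'   sample ids).
#' @param cazy_table annotation table (`nrg_id`, `label`) of CAZy families,
#'   or a catalog `annotations` table (rows with `scheme == "CAZy"` used).
#' @param taxonomy taxonomy table (`nrg_id`, `rank`, `name`).
#' @return list with `matrix` (samples x families, TPM) and `contributions`
#'   (long data.table `sample_id`, `family`, `taxon`, `fraction`).
#' @export
cazy_matrix <- function(expressions, cazy_table, taxonomy) {
  cz <- as.data.table(cazy_table)
  if ("scheme" %in% names(cz)) cz <- cz[scheme == "CAZy"]
  cz <- cz[, .(nrg_id, family = label)]
  tx <- as.data.table(taxonomy)[, .(nrg_id, rank, name)]
  tx[, taxon := fifelse(rank %in% c("SPECIES", "GENUS"), name, rank)]
  long <- rbindlist(lapply(names(expressions), function(s) {
    e <- merge(expressions[[s]], cz, by = "nrg_id", allow.cartesian = TRUE)
    if (nrow(e) == 0L) return(NULL)
    e <- merge(e, tx[, .(nrg_id, taxon)], by = "nrg_id")
    e[, sample_id := s]
    e
  }))
  fams <- sort(unique(cz$family))
  samples <- names(expressions)
  mat <- matrix(0, nrow = length(samples), ncol = length(fams),
                dimnames = list(samples, fams))
  contrib <- data.table(sample_id = character(0), family = character(0),
                        taxon = character(0), fraction = numeric(0))
  if (nrow(long) > 0L) {
    fam_tot <- long[, .(tpm = sum(tpm)), by = .(sample_id, family)]
    for (i in seq_len(nrow(fam_tot))) {
      mat[fam_tot$sample_id[i], fam_tot$family[i]] <- fam_tot$tpm[i]
    }
    contrib <- long[, .(tpm = sum(tpm)), by = .(sample_id, family, taxon)]
    contrib <- merge(contrib,
                     fam_tot[, .(sample_id, family, total = tpm)],
                     by = c("sample_id", "family"))
    contrib <- contrib[, .(sample_id, family, taxon,
                           fraction = tpm / total)]
    setorder(contrib, sample_id, family, -fraction)
  }
  list(matrix = mat, contributions = contrib)
}
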