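# Catalog assembly: clustering, the filter cascade, taxonomy propagation,
# annotation joins, and the on-disk layout (one FASTA plus numbered TSVs,
# mirroring the distributed-file family of published gene catalogs).

#' Build a non-redundant gene catalog
#'
#' Runs the full pipeline: greedy clustering, then the filter cascade in
#' fixed order (host screen, N filter, containment deduplication, anomaly
#' screen), then taxonomy propagation over the surviving clusters.  The
#' anomaly screen needs species labels, so a provisional propagation over
#' the post-containment clusters feeds it; final labels are recomputed on
#' the surviving set.
#'
#' @param genes gene table from [load_genes()] or [cds_from_genomes()].
#' @param params a [build_params()] object.
#' @param host_sequences optional character vector of host/contaminant
#'   genome sequences.
#' @param presence optional per-sample depth table for the anomaly screen
#'   (`nrg_id`, `sample_id`, `depth`).
#' @param annotations optional annotation table (`nrg_id`, `scheme`,
#'   `label`), e.g. CAZy families.
#' @param phage optional phage annotation table (`nrg_id`, `lifestyle`
#'   (`TEMPERATE`/`VIRULENT`), `family`, `host_genus`).
#' @param seed integer recorded in provenance (the build itself is
#'   deterministic).
#' @return an object of class `nrg_catalog`: `entries` (nrg_id, sequence,
#'   length, rank, name, genus), `cluster_map`, `annotations`, `phage`,
#'   `removal_log`, `report` (per-stage gene counts), `rule_summary`,
#'   `provenance`.
#' @export
build_catalog <- function(genes, params = build_params(),
                          host_sequences = NULL, presence = NULL,
                          annotations = NULL, phage = NULL, seed = 0L) {
  stopifnot(nrow(genes) >= 1L)
  if (!all(is_valid_dna(genes$sequence))) {
    stop("gene sequences must be over {A,C,G,T,N}", call. = FALSE)
  }
  cluster_map <- cluster_genes(genes, params)
  nrgs <- merge(cluster_map[is_representative == TRUE, .(nrg_id)],
                genes[, .(nrg_id = gene_id, sequence, length)],
                by = "nrg_id")
  report <- c(input_genes = nrow(genes), clusters = nrow(nrgs))

  st_host <- screen_against_host(nrgs, host_sequences, params)
  report["after_host_screen"] <- nrow(st_host$kept)
  st_n <- drop_n_genes(st_host$kept)
  report["after_n_filter"] <- nrow(st_n$kept)
  st_cont <- containment_dedup(st_n$kept, params)
  report["after_containment"] <- nrow(st_cont$kept)

  surviving_map <- cluster_map[nrg_id %in% st_cont$kept$nrg_id]
  prov_tax <- propagate_taxonomy(surviving_map, genes)
  with_sp <- merge(st_cont$kept, prov_tax[, .(nrg_id, rank, name)],
                   by = "nrg_id")
  with_sp[, species := fifelse(rank == "SPECIES", name, NA_character_)]
  st_anom <- anomaly_filter(
    with_sp[, .(nrg_id, sequence, length, species)], presence, params)
  report["after_anomaly"] <- nrow(st_anom$kept)

  final_map <- cluster_map[nrg_id %in% st_anom$kept$nrg_id]
  taxonomy <- propagate_taxonomy(final_map, genes)
  entries <- merge(st_anom$kept[, .(nrg_id, sequence, length)],
                   taxonomy[, .(nrg_id, rank, name, genus)], by = "nrg_id")

  ann <- if (is.null(annotations)) {
    data.table(nrg_id = character(0), scheme = character(0),
               label = character(0))
  } else as.data.table(annotations)[nrg_id %in% entries$nrg_id]
  ph <- if (is.null(phage)) {
    data.table(nrg_id = character(0), lifestyle = character(0),
               family = character(0), host_genus = character(0))
  } else as.data.table(phage)[nrg_id %in% entries$nrg_id]

  removal_log <- rbindlist(list(st_host$log, st_n$log, st_cont$log,
                                st_anom$log))
  # genes whose cluster was filtered out, with the stage and (for
  # containment removals) the witness gene that caused the removal --
  # reads of a contained gene still map to its witness, so downstream
  # expectation models need this
  filtered_map <- merge(cluster_map[!nrg_id %in% st_anom$kept$nrg_id],
                        removal_log, by = "nrg_id")
  filtered_map[, witness := fifelse(
    stage == "containment", sub("^contained_in=", "", statistic), "")]
  filtered_map <- filtered_map[, .(gene_id, nrg_id, stage,
                                   witness)][order(gene_id)]
  cat <- list(entries = entries[order(nrg_id)],
              cluster_map = final_map[order(gene_id)],
              filtered_map = filtered_map,
              annotations = ann,
              phage = ph,
              removal_log = removal_log,
              report = report,
              rule_summary = attr(taxonomy, "rule_summary"),
              anomaly_scores = st_anom$scores,
              provenance = c(
                lapply(unclass(params), identity),
                list(seed = as.integer(seed),
                     n_input_genes = nrow(genes),
                     genes_md5 = md5_of(paste(genes$gene_id, genes$sequence,
                                              collapse = ";")))))
  class(cat) <- "nrg_catalog"
  cat
}

md5_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' @export
print.nrg_catalog <- function(x, ...) {
  cat("Non-redundant gene catalog:", nrow(x$entries), "NRGs\n")
  cat("  taxonomy:",
      sum(x$entries$rank == "SPECIES"), "species-level,",
      sum(x$entries$rank == "GENUS"), "genus-level,",
      sum(x$entries$rank == "MULTIGENERA"), "multi-genera,",
      sum(x$entries$rank == "UNASSIGNED"), "unassigned\n")
  cat("  pipeline:", paste(names(x$report), x$report, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Write a catalog to a directory
#'
#' Layout: `0.NRG.fasta` (representative sequences), `1.taxonomy.txt`,
#' `2.cluster_map.txt`, `3.removals.txt`, `8.annotations.txt` (long form,
#' all schemes; CAZy labels use scheme `CAZy`), `10.phage.txt`, and
#' `provenance.txt`.  A write/read round trip reproduces the catalog's
#' entries, cluster map, annotations and provenance exactly.
#'
#' @param catalog an `nrg_catalog`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create catalog directory: ", dir, call. = FALSE)
  }
  write_fasta(catalog$entries$nrg_id, catalog$entries$sequence,
              file.path(dir, "0.NRG.fasta"))
  write_tsv(catalog$entries[, .(nrg_id, rank, name, genus)],
            file.path(dir, "1.taxonomy.txt"))
  write_tsv(catalog$cluster_map, file.path(dir, "2.cluster_map.txt"))
  write_tsv(catalog$removal_log, file.path(dir, "3.removals.txt"))
  write_tsv(catalog$filtered_map, file.path(dir, "4.filtered_map.txt"))
  write_tsv(catalog$annotations, file.path(dir, "8.annotations.txt"))
  write_tsv(catalog$phage, file.path(dir, "10.phage.txt"))
  prov <- catalog$provenance
  prov_chr <- vapply(prov, function(v) {
    if (is.numeric(v) && !is.integer(v)) num_to_chr(v) else as.character(v)
  }, character(1))
  write_tsv(data.table(field = names(prov), value = prov_chr,
                       type = vapply(prov, function(v) class(v)[1],
                                     character(1))),
            file.path(dir, "provenance.txt"))
  write_tsv(data.table(stage = names(catalog$report),
                       genes = as.integer(catalog$report)),
            file.path(dir, "build_report.txt"))
  write_tsv(data.table(rule = names(catalog$rule_summary),
                       clusters = as.integer(catalog$rule_summary)),
            file.path(dir, "rule_summary.txt"))
  invisible(dir)
}

#' Read a catalog written by [write_catalog()]
#'
#' @param dir catalog directory.
#' @return an `nrg_catalog`.
#' @export
read_catalog <- function(dir) {
  fa <- read_fasta(file.path(dir, "0.NRG.fasta"))
  tax <- read_tsv(file.path(dir, "1.taxonomy.txt"))
  for (col in c("rank", "name", "genus")) {
    set(tax, j = col, value = fifelse(is.na(as.character(tax[[col]])), "",
                                      as.character(tax[[col]])))
  }
  entries <- merge(data.table(nrg_id = fa$id, sequence = fa$sequence,
                              length = nchar(fa$sequence)),
                   tax, by = "nrg_id")
  cm <- read_tsv(file.path(dir, "2.cluster_map.txt"))
  cm[, is_representative := as.logical(is_representative)]
  rl <- read_tsv(file.path(dir, "3.removals.txt"))
  if (nrow(rl) > 0L) {
    rl[, `:=`(nrg_id = as.character(nrg_id), stage = as.character(stage),
              statistic = as.character(statistic))]
  } else {
    rl <- data.table(nrg_id = character(0), stage = character(0),
                     statistic = character(0))
  }
  fm <- read_tsv(file.path(dir, "4.filtered_map.txt"))
  if (nrow(fm) > 0L) {
    fm[, `:=`(gene_id = as.character(gene_id), nrg_id = as.character(nrg_id),
              stage = as.character(stage),
              witness = fifelse(is.na(as.character(witness)), "",
                                as.character(witness)))]
  } else {
    fm <- data.table(gene_id = character(0), nrg_id = character(0),
                     stage = character(0), witness = character(0))
  }
  ann <- read_tsv(file.path(dir, "8.annotations.txt"))
  if (nrow(ann) == 0L) {
    ann <- data.table(nrg_id = character(0), scheme = character(0),
                      label = character(0))
  }
  ph <- read_tsv(file.path(dir, "10.phage.txt"))
  if (nrow(ph) == 0L) {
    ph <- data.table(nrg_id = character(0), lifestyle = character(0),
                     family = character(0), host_genus = character(0))
  }
  provt <- read_tsv(file.path(dir, "provenance.txt"))
  prov <- Map(function(v, ty) {
    switch(ty, integer = as.integer(v), numeric = as.numeric(v),
           as.character(v))
  }, provt$value, provt$type)
  names(prov) <- provt$field
  rep_t <- read_tsv(file.path(dir, "build_report.txt"))
  report <- stats::setNames(as.integer(rep_t$genes), rep_t$stage)
  rs_t <- read_tsv(file.path(dir, "rule_summary.txt"))
  rs <- stats::setNames(as.integer(rs_t$clusters), rs_t$rule)
  cat <- list(entries = entries[order(nrg_id)], cluster_map = cm,
              filtered_map = fm,
              annotations = ann, phage = ph, removal_log = rl,
              report = report, rule_summary = rs,
              anomaly_scores = NULL, provenance = prov)
  class(cat) <- "nrg_catalog"
  cat
}
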