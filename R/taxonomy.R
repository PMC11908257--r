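# Propagation of member taxonomy to gene clusters via a five-rule decision
# tree: (1) uniform species-level taxonomy -> that species; (2) a strict
# majority (>50%) of one species -> that species; (3) no species majority
# but a strict genus majority -> that genus; (4) no genus majority ->
# MultiGenera; (5) no taxonomic information at all -> unassigned.
# Majorities are computed over the members that carry taxonomy at the
# relevant rank (untaxed members abstain); exactly 50% is not a majority.

#' Tally member taxonomy of one cluster
#'
#' @param species character vector of member species labels (`NA`/empty when
#'   the member has no species-level call).
#' @param genus matching genus labels (`NA`/empty when absent; a member with
#'   genus but no species contributes a genus-only vote).
#' @return a `taxonomy_tally` list: `n_members`, `species_counts`,
#'   `genus_counts`, `species_genus` (genus of each counted species),
#'   `n_genus_only`, `n_untaxed`.
#' @export
tally_members <- function(species, genus) {
  stopifnot(length(species) == length(genus))
  species[is.na(species)] <- ""
  genus[is.na(genus)] <- ""
  if (any(nzchar(species) & !nzchar(genus))) {
    stop("species-level member without a genus", call. = FALSE)
  }
  has_sp <- nzchar(species)
  has_gn <- nzchar(genus)
  sp_counts <- table(species[has_sp])
  gn_counts <- table(genus[has_gn])  # species votes also vote their genus
  sp_genus <- tapply(genus[has_sp], species[has_sp], `[[`, 1L)
  t <- list(n_members = length(species),
            species_counts = as.list(sp_counts),
            genus_counts = as.list(gn_counts),
            species_genus = as.list(sp_genus),
            n_genus_only = sum(has_gn & !has_sp),
            n_untaxed = sum(!has_gn))
  class(t) <- "taxonomy_tally"
  t
}

#' Assign cluster taxonomy from a member tally
#'
#' Applies the five rules in order and reports which rule fired.
#'
#' @param tally a `taxonomy_tally` from [tally_members()].
#' @return list with `rank` (`"SPECIES"`, `"GENUS"`, `"MULTIGENERA"` or
#'   `"UNASSIGNED"`), `name` (empty for the last two), `genus` (genus of the
#'   assigned species, or the assigned genus), and `rule` (1--5).
#' @export
assign_cluster_taxonomy <- function(tally) {
  stopifnot(inherits(tally, "taxonomy_tally"), tally$n_members >= 1L)
  sp <- unlist(tally$species_counts)
  gn <- unlist(tally$genus_counts)
  n_taxed <- sum(gn)  # every taxed member carries at least a genus
  if (n_taxed == 0L) {
    return(list(rank = "UNASSIGNED", name = "", genus = "", rule = 5L))
  }
  if (length(sp) > 0L) {
    n_sp_votes <- sum(sp)
    # rule 1: uniform species-level taxonomy across all taxed members
    if (length(sp) == 1L && tally$n_genus_only == 0L) {
      s <- names(sp)[1]
      return(list(rank = "SPECIES", name = s,
                  genus = tally$species_genus[[s]], rule = 1L))
    }
    # rule 2: strict majority of one species among species voters
    top <- which.max(sp)
    if (sp[top] / n_sp_votes > 0.5) {
      s <- names(sp)[top]
      return(list(rank = "SPECIES", name = s,
                  genus = tally$species_genus[[s]], rule = 2L))
    }
  }
  # rule 3: strict genus majority among all taxed members
  top <- which.max(gn)
  if (gn[top] / n_taxed > 0.5) {
    return(list(rank = "GENUS", name = names(gn)[top],
                genus = names(gn)[top], rule = 3L))
  }
  # rule 4: no genus majority
  list(rank = "MULTIGENERA", name = "", genus = "", rule = 4L)
}

#' Propagate member taxonomy to all clusters
#'
#' @param cluster_map output of [cluster_genes()] (`gene_id`, `nrg_id`).
#' @param genes gene table with `gene_id`, `species`, `genus`.
#' @return data.table with one row per cluster: `nrg_id`, `rank`, `name`,
#'   `genus`, `rule`; attribute `rule_summary` holds the count per rule
#'   branch (length 5).
#' @export
propagate_taxonomy <- function(cluster_map, genes) {
  missing <- setdiff(cluster_map$gene_id, genes$gene_id)
  if (length(missing) > 0L) {
    stop("cluster member without a gene record: ", missing[1], call. = FALSE)
  }
  members <- merge(cluster_map[, .(gene_id, nrg_id)],
                   genes[, .(gene_id, species, genus)], by = "gene_id")
  res <- members[, {
    a <- assign_cluster_taxonomy(tally_members(species, genus))
    .(rank = a$rank, name = a$name, genus = a$genus, rule = a$rule)
  }, by = nrg_id]
  res <- res[order(nrg_id)]
  summary <- vapply(1:5, function(r) sum(res$rule == r), integer(1))
  names(summary) <- paste0("rule", 1:5)
  setattr(res, "rule_summary", summary)
  res
}
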