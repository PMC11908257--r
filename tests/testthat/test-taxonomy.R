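# Independent rule evaluator used as the enumeration oracle: a direct,
# self-contained restatement of the five-rule tree over explicit vote
# vectors, written without reference to the package internals.
oracle_assign <- function(species, genus) {
  species[is.na(species)] <- ""
  genus[is.na(genus)] <- ""
  taxed <- which(nzchar(genus) | nzchar(species))
  if (length(taxed) == 0L) return(list(rank = "UNASSIGNED", name = "", rule = 5L))
  sp_votes <- species[nzchar(species)]
  if (length(sp_votes) > 0L) {
    if (length(unique(sp_votes)) == 1L && length(sp_votes) == length(taxed)) {
      return(list(rank = "SPECIES", name = sp_votes[1], rule = 1L))
    }
    tab <- sort(table(sp_votes), decreasing = TRUE)
    if (tab[1] * 2 > length(sp_votes)) {
      return(list(rank = "SPECIES", name = names(tab)[1], rule = 2L))
    }
  }
  gn_votes <- genus[taxed]
  tab <- sort(table(gn_votes), decreasing = TRUE)
  if (tab[1] * 2 > length(gn_votes)) {
    return(list(rank = "GENUS", name = names(tab)[1], rule = 3L))
  }
  list(rank = "MULTIGENERA", name = "", rule = 4L)
}

assign_from_votes <- function(species, genus) {
  assign_cluster_taxonomy(tally_members(species, genus))
}

test_that("the five published rule examples resolve as stated", {
  # rule 1: uniform species
  a <- assign_from_votes(rep("spX", 3), rep("G1", 3))
  expect_equal(a[c("rank", "name", "rule")],
               list(rank = "SPECIES", name = "spX", rule = 1L))
  # rule 2: strict species majority (2/3), different genera
  a <- assign_from_votes(c("spX", "spX", "spY"), c("G1", "G1", "G2"))
  expect_equal(a[c("rank", "name", "rule")],
               list(rank = "SPECIES", name = "spX", rule = 2L))
  # rule 3: species tie within one genus
  a <- assign_from_votes(c("spX", "spY"), c("G1", "G1"))
  expect_equal(a[c("rank", "name", "rule")],
               list(rank = "GENUS", name = "G1", rule = 3L))
  # rule 4: species tie across genera
  a <- assign_from_votes(c("spX", "spY"), c("G1", "G2"))
  expect_equal(a[c("rank", "rule")], list(rank = "MULTIGENERA", rule = 4L))
  # rule 5: no taxonomy at all
  a <- assign_from_votes(c(NA, NA), c(NA, NA))
  expect_equal(a[c("rank", "rule")], list(rank = "UNASSIGNED", rule = 5L))
})

test_that("exactly 50% is not a majority", {
  # 2 vs 2 same genus: no species majority, genus unanimous -> GENUS
  a <- assign_from_votes(c("spX", "spX", "spY", "spY"), rep("G1", 4))
  expect_equal(a$rule, 3L)
  # 2 vs 2 across genera: genus split 50/50 -> MULTIGENERA
  a <- assign_from_votes(c("spX", "spX", "spY", "spY"),
                         c("G1", "G1", "G2", "G2"))
  expect_equal(a$rule, 4L)
  # 3 of 6 species votes is not a species majority
  a <- assign_from_votes(c("spX", "spX", "spX", "spY", "spY", "spZ"),
                         c("G1", "G1", "G1", "G1", "G1", "G1"))
  expect_equal(a$rule, 3L)
})

test_that("genus-only votes count at genus rank, abstain at species rank", {
  # one species vote + one same-genus-only vote: not uniform (rule 1 needs
  # all taxed members at species rank), but 1/1 species majority -> rule 2
  a <- assign_from_votes(c("spX", NA), c("G1", "G1"))
  expect_equal(a[c("rank", "name", "rule")],
               list(rank = "SPECIES", name = "spX", rule = 2L))
  # untaxed members abstain entirely
  a <- assign_from_votes(c("spX", "spX", NA), c("G1", "G1", NA))
  expect_equal(a$rule, 1L)
})

test_that("decision tree equals the enumeration oracle over all small tallies", {
  # all member vote vectors with <= 6 members over 3 species (sp1,sp2 in
  # genus GA; sp3 in genus GB), genus-only votes for GA/GB, and untaxed
  cats <- data.frame(
    species = c("sp1", "sp2", "sp3", NA, NA, NA),
    genus = c("GA", "GA", "GB", "GA", "GB", NA),
    stringsAsFactors = FALSE)
  n_checked <- 0L
  for (n in 1:6) {
    combos <- utils::combn(n + 5L, 5L)  # compositions of n over 6 categories
    for (ci in seq_len(ncol(combos))) {
      bars <- combos[, ci]
      counts <- diff(c(0L, bars, n + 6L)) - 1L
      stopifnot(sum(counts) == n)
      species <- rep(cats$species, counts)
      genus <- rep(cats$genus, counts)
      got <- assign_from_votes(species, genus)
      want <- oracle_assign(species, genus)
      expect_equal(got$rank, want$rank,
                   info = paste("counts:", paste(counts, collapse = ",")))
      expect_equal(got$rule, want$rule,
                   info = paste("counts:", paste(counts, collapse = ",")))
      if (got$rank %in% c("SPECIES", "GENUS")) {
        expect_equal(got$name, want$name,
                     info = paste("counts:", paste(counts, collapse = ",")))
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 900L)  # full enumeration actually ran
})

test_that("propagate_taxonomy summarizes rule branches and checks integrity", {
  genes <- gene_table(
    withr::with_seed(101, replicate(6, random_dna(200))),
    ids = sprintf("g%d", 1:6),
    species = c("sp1", "sp1", "sp2", "sp3", NA, NA),
    genus = c("GA", "GA", "GA", "GB", "GA", NA))
  cm <- data.table::data.table(
    gene_id = sprintf("g%d", 1:6),
    nrg_id = c("g1", "g1", "g3", "g4", "g3", "g6"),
    is_representative = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  tax <- propagate_taxonomy(cm, genes)
  # four clusters: g1 {g1,g2}, g3 {g3,g5}, g4 {g4}, g6 {g6}
  expect_equal(nrow(tax), 4L)
  expect_equal(tax[nrg_id == "g1", rank], "SPECIES")  # uniform sp1
  expect_equal(tax[nrg_id == "g3", rank], "SPECIES")  # sp2 majority over
  expect_equal(tax[nrg_id == "g3", rule], 2L)         # one genus-only vote
  expect_equal(tax[nrg_id == "g4", rule], 1L)         # uniform singleton
  expect_equal(tax[nrg_id == "g6", rank], "UNASSIGNED")
  expect_equal(sum(attr(tax, "rule_summary")), 4L)
  # missing gene record -> integrity error
  cm2 <- rbind(cm, data.table::data.table(gene_id = "ghost", nrg_id = "g1",
                                          is_representative = FALSE))
  expect_error(propagate_taxonomy(cm2, genes), "ghost")
})

test_that("sister species at 2% produce genus-level clusters in a mock build", {
  specs <- list(
    species_spec("sis A", "SisterGenus", genome_length = 10000L, n_genes = 10L),
    species_spec("sis B", "SisterGenus", genome_length = 10000L, n_genes = 10L,
                 divergence_from_parent = 0.02, parent = "sis A"),
    species_spec("solo C", "SoloGenus", genome_length = 10000L, n_genes = 10L))
  genes <- cds_from_genomes(make_genomes(specs, seed = 7))
  cm <- cluster_genes(genes, build_params())
  tax <- propagate_taxonomy(cm, genes)
  rs <- attr(tax, "rule_summary")
  expect_gt(rs[["rule3"]], 0L)  # shared clusters labeled at genus level
  expect_equal(tax[rank == "GENUS", unique(name)], "SisterGenus")
  # the un-paired species stays species-level via rule 1
  expect_true(all(tax[name == "solo C", rule] == 1L))
})
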