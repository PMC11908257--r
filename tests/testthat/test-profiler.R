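test_that("error-free reads map uniquely to their source gene", {
  genes <- withr::with_seed(110, replicate(4, random_dna(500)))
  cat <- toy_catalog(genes)
  reads <- substring(genes[2], c(1, 101, 201), c(100, 200, 300))
  aln <- map_reads(reads, cat)
  expect_equal(nrow(aln), 3L)
  expect_true(all(aln$nrg_id == "nrg02"))
  expect_true(all(aln$mismatches == 0L))
  expect_equal(aln$pos, c(1L, 101L, 201L))
})

test_that("a read from a gene shared verbatim by two NRGs reports both", {
  g <- random_dna(400, seed = 111)
  cat <- toy_catalog(c(g, g, random_dna(400, seed = 112)))
  aln <- map_reads(substring(g, 51, 150), cat)
  expect_equal(sort(aln$nrg_id), c("nrg01", "nrg02"))
  expect_equal(aln$score[1], aln$score[2])
})

test_that("reverse-complement reads map on the minus strand", {
  g <- random_dna(400, seed = 113)
  cat <- toy_catalog(g)
  aln <- map_reads(revcomp(substring(g, 101, 200)), cat)
  expect_equal(aln$strand, -1L)
  expect_equal(aln$pos, 101L)
  expect_equal(nrow(map_reads(revcomp(substring(g, 101, 200)), cat,
                              both_strands = FALSE)), 0L)
})

test_that("reads below min_identity are dropped; short reads warn", {
  g <- random_dna(400, seed = 114)
  cat <- toy_catalog(g)
  read <- substring(g, 1, 100)
  bad <- withr::with_seed(115, mutate_fixed(read, 11))  # identity 0.89
  ok <- withr::with_seed(116, mutate_fixed(read, 10))   # identity 0.90
  aln <- map_reads(c(bad, ok), cat, seed_stride = 1L)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$mismatches, 10L)
  expect_warning(map_reads("ACGTACGT", cat), "shorter than the seed")
})

test_that("mapper equals the exhaustive-alignment oracle", {
  # error-free reads at default stride; error-bearing reads at stride 1
  # (the stride guarantee covers up to floor(n_windows/2) substitutions)
  genes <- withr::with_seed(120, replicate(5, random_dna(300)))
  genes[2] <- paste0(substring(genes[1], 1, 150),
                     random_dna(150, seed = 121))  # shared 150 bp prefix
  cat <- toy_catalog(genes)
  # 100 bp reads, 20 bp seeds: 81 seed windows; e substitutions destroy at
  # most 20 e windows, so any placement with <= 3 errors is guaranteed found
  # at stride 1 (and error-free placements at any stride)
  for (err in c(0, 3)) {
    reads <- withr::with_seed(122 + err, {
      g <- sample(5, 400, replace = TRUE)
      st <- sample(200, 400, replace = TRUE)
      r <- substring(genes[g], st, st + 99)
      if (err > 0) r <- vapply(r, function(x)
        mutate_fixed(x, sample(0:err, 1)), character(1), USE.NAMES = FALSE)
      # mix in some reverse-complement reads
      flip <- sample(c(TRUE, FALSE), 400, replace = TRUE)
      ifelse(flip, revcomp(r), r)
    })
    aln <- map_reads(reads, cat, seed_stride = if (err == 0) 10L else 1L)
    got <- data.frame(read = match(aln$read_id,
                                   sprintf("read%07d", seq_along(reads))),
                      gene = match(aln$nrg_id, cat$entries$nrg_id),
                      pos = aln$pos, strand = aln$strand,
                      mismatches = aln$mismatches)
    got <- got[order(got$read, got$gene, got$pos, -got$strand), ]
    want <- oracle_map(reads, genes)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("quantify splits ties, corrects for gene length, validates ids", {
  g1 <- random_dna(1000, seed = 130)
  cat <- toy_catalog(c(g1, random_dna(500, seed = 131)))
  # 10 unique 100 bp reads on a 1000 bp gene -> depth 1.0
  reads <- substring(g1, seq(1, 901, by = 100), seq(100, 1000, by = 100))
  prof <- quantify(map_reads(reads, cat), cat)
  expect_equal(prof$reads, 10)
  expect_equal(prof$depth, 1.0)

  # a tied read splits 0.5/0.5
  g <- random_dna(400, seed = 132)
  cat2 <- toy_catalog(c(g, g))
  prof2 <- quantify(map_reads(substring(g, 1, 100), cat2), cat2)
  expect_equal(prof2$reads, c(0.5, 0.5))

  fake <- data.table::data.table(read_id = "r", nrg_id = "nope", pos = 1L,
                                 strand = 1L, mismatches = 0L,
                                 aln_len = 100L, score = 100L,
                                 read_seq = strrep("A", 100))
  expect_error(quantify(fake, cat), "unknown NRG")
})

test_that("compose normalizes shares per bucket and flags empty profiles", {
  seqs <- withr::with_seed(133, replicate(4, random_dna(500)))
  cat <- toy_catalog(seqs,
                     rank = c("SPECIES", "SPECIES", "GENUS", "UNASSIGNED"),
                     name = c("sp a", "sp b", "gen c", ""),
                     genus = c("gen a", "gen b", "gen c", ""))
  prof <- data.table::data.table(nrg_id = cat$entries$nrg_id,
                                 reads = c(10, 10, 5, 5),
                                 bases = c(1000, 1000, 500, 500),
                                 depth = c(2, 2, 1, 1))
  comp <- compose(prof, cat$entries)
  expect_equal(sum(comp$share), 1, tolerance = 1e-12)
  expect_equal(comp[taxon == "sp a", share], 1 / 3)
  expect_equal(comp[taxon == "gen c", share], 1 / 6)
  expect_equal(comp[taxon == "UNASSIGNED", share], 1 / 6)

  empty <- quantify(map_reads(character(0), cat), cat)
  ecomp <- compose(empty, cat$entries)
  expect_true(attr(ecomp, "empty"))
  expect_equal(nrow(ecomp), 0L)
})

test_that("tpm follows the closed form and sums to 1e6", {
  seqs <- c(random_dna(1000, seed = 134), random_dna(2000, seed = 135))
  cat <- toy_catalog(seqs)
  prof <- data.table::data.table(nrg_id = c("nrg01", "nrg02"),
                                 reads = c(50, 50),
                                 bases = c(5000, 5000), depth = c(5, 2.5))
  e <- tpm(prof, cat)
  expect_equal(sum(e$tpm), 1e6, tolerance = 1e-3)
  expect_equal(e$tpm, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # single mapped gene -> 1e6
  e1 <- tpm(prof[1], cat)
  expect_equal(e1$tpm, 1e6)
})

test_that("SAM import and internal mapper give identical profiles", {
  genes <- withr::with_seed(136, replicate(3, random_dna(400)))
  cat <- toy_catalog(genes)
  reads <- withr::with_seed(137, {
    g <- sample(3, 200, replace = TRUE)
    st <- sample(300, 200, replace = TRUE)
    substring(genes[g], st, st + 79)
  })
  aln <- map_reads(reads, cat)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, stats::setNames(cat$entries$length, cat$entries$nrg_id), f)
  p1 <- quantify(aln, cat)
  p2 <- quantify(read_sam(f), cat)
  expect_equal(as.data.frame(p1), as.data.frame(p2), ignore_attr = TRUE)
})

test_that("mock-community depths are recovered within 5%", {
  specs <- list(
    species_spec("A", "gA", genome_length = 20000L, n_genes = 20L),
    species_spec("B", "gB", genome_length = 20000L, n_genes = 20L),
    species_spec("C", "gC", genome_length = 20000L, n_genes = 20L))
  gen <- make_genomes(specs, seed = 140)
  genes <- cds_from_genomes(gen)
  catalog <- suppressWarnings(build_catalog(genes, seed = 140))
  comm <- c(A = 0.5, B = 0.25, C = 0.25)  # depth ratios 2:1:1
  truth <- simulate_reads(gen, comm, n_reads = 60000, read_length = 100,
                          error_rate = 0, seed = 141)
  prof <- quantify(map_reads(truth$reads, catalog), catalog)
  obs <- compose(prof, catalog$entries)
  for (sp in names(comm)) {
    expect_lt(abs(obs[taxon == sp, share] - comm[[sp]]) / comm[[sp]], 0.05)
  }
})
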