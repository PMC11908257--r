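nrg_table <- function(seqs, ids = sprintf("n%03d", seq_along(seqs)),
                      species = NA_character_) {
  data.table::data.table(nrg_id = ids, sequence = seqs,
                         length = nchar(seqs),
                         species = rep_len(species, length(seqs)))
}

test_that("host screen removes hits above both thresholds, keeps the rest", {
  p <- build_params()
  host <- random_dna(3000, seed = 60)

  # gene equal to a host segment -> removed
  g_exact <- substring(host, 501, 800)
  # gene with ~70% identity over its whole length -> kept (below 75%)
  g_low <- withr::with_seed(61, mutate_fixed(substring(host, 1001, 1300), 90))
  # 80% identity but only over 40% of the gene -> kept (below 50% coverage)
  part <- withr::with_seed(62, mutate_fixed(substring(host, 2001, 2120), 24))
  g_part <- paste0(part, random_dna(180, seed = 63))
  # reverse-complement hit -> removed (both strands searched)
  g_rc <- revcomp(substring(host, 1501, 1800))
  # unrelated gene -> kept
  g_none <- random_dna(300, seed = 64)

  nrgs <- nrg_table(c(g_exact, g_low, g_part, g_rc, g_none))
  res <- screen_against_host(nrgs, host, p)
  expect_setequal(res$removed$nrg_id, c("n001", "n004"))
  expect_setequal(res$kept$nrg_id, c("n002", "n003", "n005"))
  expect_equal(res$log$stage, rep("host", 2))

  # empty host set is a no-op
  res0 <- screen_against_host(nrgs, NULL, p)
  expect_equal(nrow(res0$removed), 0L)
  expect_equal(res0$kept, nrgs)
})

test_that("N filter removes exactly the N-containing genes", {
  nrgs <- nrg_table(c("ACGTNACGT", strrep("ACGT", 5), "NNNN"))
  res <- drop_n_genes(nrgs)
  expect_setequal(res$removed$nrg_id, c("n001", "n003"))
  expect_equal(res$kept$nrg_id, "n002")
  res0 <- drop_n_genes(nrg_table(character(0)))
  expect_equal(nrow(res0$kept), 0L)
  expect_equal(nrow(res0$removed), 0L)
})

test_that("containment dedup boundary: 100 bp removes, 99 bp keeps", {
  p <- build_params()
  block100 <- random_dna(100, seed = 70)
  block99 <- random_dna(99, seed = 71)
  # embed blocks with distinct flanks so the shared run is exactly the block
  a <- paste0(random_dna(400, seed = 72), block100, random_dna(400, seed = 73))
  b <- paste0(random_dna(200, seed = 74), block100, random_dna(200, seed = 75))
  # flank the 99 bp block with differing bases so the run cannot extend
  c_ <- paste0(random_dna(199, seed = 76), "A", block99, "A",
               random_dna(200, seed = 77))
  d <- paste0(random_dna(149, seed = 78), "C", block99, "C",
              random_dna(150, seed = 79))
  nrgs <- nrg_table(c(a, b, c_, d))
  # guard the fixture: intended shared runs at/below the boundary
  expect_gte(lcs_length(a, b), 100)
  expect_equal(lcs_length(c_, d), 99)
  res <- containment_dedup(nrgs, p)
  expect_equal(res$removed$nrg_id, "n002")  # shorter of the 100 bp pair
  expect_setequal(res$kept$nrg_id, c("n001", "n003", "n004"))
})

test_that("containment dedup chain removes against the original set", {
  p <- build_params()
  blockAB <- random_dna(120, seed = 80)
  blockBC <- random_dna(120, seed = 81)
  a <- paste0(random_dna(390, seed = 82), blockAB, random_dna(390, seed = 83))
  b <- paste0(random_dna(130, seed = 84), blockAB, random_dna(130, seed = 85),
              blockBC)
  c_ <- paste0(random_dna(90, seed = 86), blockBC, random_dna(90, seed = 87))
  nrgs <- nrg_table(c(a, b, c_))  # lengths 900 > 500 > 300
  expect_lt(lcs_length(a, c_), 100)
  res <- containment_dedup(nrgs, p)
  # B loses to A; C loses to B even though B is itself removed (single pass
  # against the original set)
  expect_setequal(res$removed$nrg_id, c("n002", "n003"))
  expect_equal(res$kept$nrg_id, "n001")
})

test_that("containment dedup equals the brute-force LCS oracle", {
  p <- build_params()
  seeds <- 1:12
  for (s in seeds) {
    inst <- withr::with_seed(900 + s, {
      n <- sample(8:16, 1)
      seqs <- replicate(n, random_dna(sample(150:300, 1)))
      # plant some shared blocks
      for (q in seq_len(sample(0:3, 1))) {
        i <- sample(n, 2)
        blk_len <- sample(c(95, 100, 120, 160), 1)
        src <- seqs[[i[1]]]
        start <- sample(nchar(src) - blk_len + 1L, 1)
        blk <- substring(src, start, start + blk_len - 1L)
        tgt <- seqs[[i[2]]]
        at <- sample(nchar(tgt) - blk_len + 1L, 1)
        substr(tgt, at, at + blk_len - 1L) <- blk
        seqs[[i[2]]] <- tgt
      }
      seqs
    })
    nrgs <- nrg_table(inst)
    res <- containment_dedup(nrgs, p)
    # oracle: all ordered pairs with LCS >= 100 remove the shorter
    # (tie: lexicographically larger id)
    removed <- character(0)
    n <- nrow(nrgs)
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        if (lcs_length(nrgs$sequence[i], nrgs$sequence[j]) >=
            p$containment_min) {
          li <- nrgs$length[i]; lj <- nrgs$length[j]
          loser <- if (li > lj) nrgs$nrg_id[j]
          else if (lj > li) nrgs$nrg_id[i]
          else max(nrgs$nrg_id[i], nrgs$nrg_id[j])
          removed <- union(removed, loser)
        }
      }
    }
    expect_setequal(res$removed$nrg_id, removed)
  }
})

test_that("anomaly filter flags a composition outlier, spares normal genes", {
  p <- build_params()
  genes <- withr::with_seed(95, replicate(30, random_dna(600)))
  repeatgene <- strrep("AC", 300)  # pure 2-mer repeat: tetramer outlier
  nrgs <- nrg_table(c(genes, repeatgene), species = "sp x")
  res <- suppressWarnings(anomaly_filter(nrgs, NULL, p))
  expect_equal(res$removed$nrg_id, "n031")
  expect_equal(nrow(res$scores), 31L)
  expect_gt(res$scores[nrg_id == "n031", abs(z_tetramer)], p$anomaly_z)

  # homogeneous set: no removals at z = 5
  res2 <- suppressWarnings(anomaly_filter(nrg_table(genes, species = "sp x"),
                                          NULL, p))
  expect_equal(nrow(res2$removed), 0L)

  # species below the support guard is untouched
  few <- nrg_table(c(replicate(9, random_dna(300)), strrep("AC", 150)),
                   species = "sp y")
  res3 <- suppressWarnings(anomaly_filter(few, NULL, p))
  expect_equal(nrow(res3$removed), 0L)
  expect_equal(nrow(res3$scores), 0L)
})

test_that("anomaly filter uses depth and prevalence when presence is given", {
  p <- build_params()
  genes <- withr::with_seed(96, replicate(25, random_dna(600)))
  nrgs <- nrg_table(genes, species = "sp x")
  samples <- sprintf("s%02d", 1:12)
  presence <- data.table::CJ(nrg_id = nrgs$nrg_id, sample_id = samples)
  presence[, depth := 1.0]
  # one gene present in a single sample at huge depth: prevalence and
  # abundance outlier
  presence[nrg_id == "n001" & sample_id != "s01", depth := 0]
  presence[nrg_id == "n001" & sample_id == "s01", depth := 500]
  res <- anomaly_filter(nrgs, presence, p)
  expect_true("n001" %in% res$removed$nrg_id)
  expect_false(any(setdiff(nrgs$nrg_id, "n001") %in% res$removed$nrg_id))
  sc <- res$scores[nrg_id == "n001"]
  expect_gt(abs(sc$z_prevalence), p$anomaly_z)
})
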