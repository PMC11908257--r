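# Shared fixture builders.  All fixtures are generated in code under fixed
# seeds; nothing is read from disk except what a test writes itself.

random_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Substitute exactly `k` positions of `seq` (chosen without replacement)
# with a different base.  Deterministic given the RNG state.
mutate_fixed <- function(seq, k, positions = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- positions %||% sample(length(ch), k)
  bases <- c("A", "C", "G", "T")
  cur <- match(ch[pos], bases)
  shift <- sample.int(3L, length(pos), replace = TRUE)
  ch[pos] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  paste(ch, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent Hamming distance (R-level oracle).
ham <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# A small gene table around `n` random genes of length `len`.
gene_table <- function(seqs, ids = sprintf("g%03d", seq_along(seqs)),
                       species = NA_character_, genus = NA_character_) {
  data.table::data.table(
    gene_id = ids, sequence = seqs, length = nchar(seqs),
    source_type = "ISOLATE", source_id = "src", sample_id = "",
    species = rep_len(species, length(seqs)),
    genus = rep_len(genus, length(seqs)))
}

# Planted-family instance: n_fam random ancestor sequences (~75% divergent
# from one another), each spawning `per_fam` members whose pairwise
# within-family divergence is ~`within` (each member mutates at within/2
# from the ancestor).  Returns the gene table plus the true family labels.
planted_families <- function(n_fam = 4L, per_fam = 10L, len = 450L,
                             within = 0.02, seed = 1L) {
  withr::with_seed(seed, {
    anc <- replicate(n_fam, random_dna(len))
    seqs <- character(0)
    fam <- integer(0)
    for (f in seq_len(n_fam)) {
      for (m in seq_len(per_fam)) {
        k <- rbinom(1L, len, within / 2)
        seqs <- c(seqs, mutate_fixed(anc[f], k))
        fam <- c(fam, f)
      }
    }
    ids <- sprintf("f%02dm%03d", fam, seq_along(seqs))
    list(genes = gene_table(seqs, ids), family = fam)
  })
}

# Tiny catalog straight from entry sequences (bypasses the build pipeline).
toy_catalog <- function(seqs, ids = sprintf("nrg%02d", seq_along(seqs)),
                        rank = "SPECIES", name = paste0("sp", seq_along(seqs)),
                        genus = paste0("gen", seq_along(seqs))) {
  entries <- data.table::data.table(
    nrg_id = ids, sequence = seqs, length = nchar(seqs),
    rank = rep_len(rank, length(seqs)), name = rep_len(name, length(seqs)),
    genus = rep_len(genus, length(seqs)))
  cat <- list(entries = entries,
              cluster_map = data.table::data.table(
                gene_id = ids, nrg_id = ids, is_representative = TRUE),
              annotations = data.table::data.table(
                nrg_id = character(0), scheme = character(0),
                label = character(0)),
              phage = data.table::data.table(
                nrg_id = character(0), lifestyle = character(0),
                family = character(0), host_genus = character(0)),
              removal_log = NULL, report = NULL, rule_summary = NULL,
              anomaly_scores = NULL,
              provenance = list(seed = 0L))
  class(cat) <- "nrg_catalog"
  cat
}

# Brute-force longest common substring length via the suffix-match DP,
# vectorized over anti-diagonals (independent of the package's k-mer scan).
lcs_length <- function(a, b) {
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  na <- length(x); nb <- length(y)
  best <- 0L
  for (k in (-(nb - 1L)):(na - 1L)) {  # diagonal offset i - j = k
    i <- max(1L, 1L + k):min(na, nb + k)
    j <- i - k
    eq <- x[i] == y[j]
    if (!any(eq)) next
    r <- rle(eq)
    best <- max(best, max(r$lengths[r$values]))
  }
  best
}

# Exhaustive end-to-end alignment oracle: all (gene, offset, strand)
# placements of each read, Hamming-scored in R.
oracle_map <- function(read_seqs, gene_seqs, min_identity = 0.90,
                       both_strands = TRUE) {
  res <- list()
  for (r in seq_along(read_seqs)) {
    rs <- read_seqs[r]
    len <- nchar(rs)
    maxmm <- floor((1 - min_identity) * len + 1e-9)
    hits <- list()
    strands <- if (both_strands) c(1L, -1L) else 1L
    for (st in strands) {
      q <- if (st == 1L) rs else nrgcat::revcomp(rs)
      qv <- utf8ToInt(q)
      for (g in seq_along(gene_seqs)) {
        gv <- utf8ToInt(gene_seqs[g])
        gl <- length(gv)
        if (len > gl) next
        for (off in 0:(gl - len)) {
          mm <- sum(qv != gv[(off + 1L):(off + len)])
          if (mm <= maxmm) {
            hits[[length(hits) + 1L]] <-
              data.frame(read = r, gene = g, pos = off + 1L, strand = st,
                         mismatches = mm)
          }
        }
      }
    }
    if (length(hits) == 0L) next
    h <- do.call(rbind, hits)
    h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    res[[length(res) + 1L]] <- h
  }
  if (length(res) == 0L) {
    return(data.frame(read = integer(0), gene = integer(0),
                      pos = integer(0), strand = integer(0),
                      mismatches = integer(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$read, out$gene, out$pos, -out$strand), , drop = FALSE]
}
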