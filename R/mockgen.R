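# Seeded generator of synthetic species genomes, known-proportion mock
# communities, and substitution-error short reads.  This is the package's
# stand-in for simulator-based validation: root genomes are uniform-random
# DNA, child genomes are parent copies with Poisson-placed substitutions, and
# genes tile each genome as fixed-length non-overlapping windows so the
# cluster-level ground truth is known exactly.

#' Describe a synthetic species
#'
#' @param species species name.
#' @param genus genus name.
#' @param genome_length genome length in bases.
#' @param n_genes number of tiled gene windows.
#' @param divergence_from_parent substitutions per site relative to `parent`
#'   (0--0.3); ignored for root species.
#' @param parent name of the parent species, or `NA` for a root.
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(species, genus, genome_length = 50000L,
                         n_genes = 50L, divergence_from_parent = 0,
                         parent = NA_character_) {
  if (!is.numeric(divergence_from_parent) || divergence_from_parent < 0 ||
      divergence_from_parent > 0.3) {
    stop("divergence_from_parent must be in [0, 0.3]", call. = FALSE)
  }
  s <- list(species = species, genus = genus,
            genome_length = as.integer(genome_length),
            n_genes = as.integer(n_genes),
            divergence_from_parent = divergence_from_parent,
            parent = parent)
  class(s) <- "species_spec"
  s
}

random_genome <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

mutate_genome <- function(genome, rate) {
  L <- nchar(genome)
  n_sub <- min(stats::rpois(1L, L * rate), L)
  if (n_sub == 0L) return(genome)
  pos <- sample.int(L, n_sub)
  ch <- strsplit(genome, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  # substitute with one of the three other bases, uniformly
  cur <- match(ch[pos], bases)
  shift <- sample.int(3L, n_sub, replace = TRUE)
  ch[pos] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  paste(ch, collapse = "")
}

#' Generate synthetic species genomes
#'
#' Root genomes are uniform-random DNA; each child is a copy of its parent
#' with `Poisson(L * divergence)` substitutions at uniform positions.  Gene
#' coordinates tile each genome with fixed-length non-overlapping windows.
#' Fully deterministic given `seed`.
#'
#' @param specs list of [species_spec()] objects; parents must appear before
#'   their children.
#' @param seed integer seed.
#' @param gene_length gene window length in bases.
#' @param spacer gap between consecutive gene windows in bases.
#' @return named list (by species) of `list(genome, coords, spec)` where
#'   `coords` is a data.table of `start`/`end` gene windows.
#' @export
make_genomes <- function(specs, seed, gene_length = 900L, spacer = 100L) {
  stopifnot(length(specs) >= 1L)
  names(specs) <- vapply(specs, `[[`, "", "species")
  with_seed(seed, {
    out <- list()
    for (sp in specs) {
      need <- sp$n_genes * (gene_length + spacer) - spacer
      if (need > sp$genome_length) {
        stop("species ", sp$species, ": ", sp$n_genes, " genes of ",
             gene_length, " bp (+", spacer, " bp spacers) exceed the ",
             sp$genome_length, " bp genome", call. = FALSE)
      }
      if (is.na(sp$parent)) {
        g <- random_genome(sp$genome_length)
      } else {
        if (!sp$parent %in% names(out)) {
          stop("parent species ", sp$parent,
               " must be listed before its child ", sp$species,
               call. = FALSE)
        }
        g <- mutate_genome(out[[sp$parent]]$genome, sp$divergence_from_parent)
      }
      starts <- 1L + (seq_len(sp$n_genes) - 1L) * (gene_length + spacer)
      out[[sp$species]] <- list(
        genome = g,
        coords = data.table(start = starts, end = starts + gene_length - 1L),
        spec = sp)
    }
    out
  })
}

#' Extract tiled gene windows as gene records
#'
#' Emits each gene window as a forward-strand gene record carrying the
#' species' taxonomy (source type `ISOLATE`).
#'
#' @param genomes output of [make_genomes()].
#' @return a gene table as produced by [load_genes()].
#' @export
cds_from_genomes <- function(genomes) {
  recs <- lapply(genomes, function(g) {
    if (nrow(g$coords) == 0L) return(NULL)
    tag <- gsub("[^A-Za-z0-9]+", "_", g$spec$species)
    seqs <- substring(g$genome, g$coords$start, g$coords$end)
    data.table(gene_id = sprintf("%s|g%04d", tag, seq_len(nrow(g$coords))),
               sequence = seqs, length = nchar(seqs),
               source_type = "ISOLATE", source_id = g$spec$species,
               sample_id = "", species = g$spec$species,
               genus = g$spec$genus)
  })
  out <- rbindlist(recs)
  if (nrow(out) == 0L) {
    out <- data.table(gene_id = character(0), sequence = character(0),
                      length = integer(0), source_type = character(0),
                      source_id = character(0), sample_id = character(0),
                      species = character(0), genus = character(0))
  }
  out[]
}

#' Simulate substitution-error shotgun reads from a mock community
#'
#' Species are sampled with probability proportional to
#' `proportion * genome_length`, so a species' expected per-base sequencing
#' depth share equals its stated proportion.  Read start positions are
#' uniform on the forward strand; substitution errors are i.i.d. per base;
#' quality scores are constant.  Deterministic given `seed`.
#'
#' @param genomes output of [make_genomes()].
#' @param proportions named numeric vector of community proportions (must sum
#'   to 1 within 1e-9); names must be species in `genomes`.
#' @param n_reads number of reads.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return a `mock_truth` list: `reads` (data.table `id`, `sequence`,
#'   `qual`), `provenance` (`read_id`, `species`, `start`), `proportions`,
#'   `read_length`, `error_rate`, `seed`.
#' @export
simulate_reads <- function(genomes, proportions, n_reads,
                           read_length = 150L, error_rate = 0,
                           seed) {
  if (!is.numeric(n_reads) || n_reads <= 0) {
    stop("n_reads must be positive", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", sum(proportions), ")",
         call. = FALSE)
  }
  if (is.null(names(proportions)) ||
      !all(names(proportions) %in% names(genomes))) {
    stop("proportions must be named by species present in `genomes`",
         call. = FALSE)
  }
  glen <- vapply(genomes[names(proportions)],
                 function(g) nchar(g$genome), integer(1))
  if (read_length > min(glen)) {
    stop("read_length exceeds the shortest genome", call. = FALSE)
  }
  with_seed(seed, {
    w <- proportions * glen
    counts <- as.vector(stats::rmultinom(1L, n_reads, w / sum(w)))
    names(counts) <- names(proportions)
    seqs <- character(0)
    prov_sp <- character(0)
    prov_start <- integer(0)
    for (sp in names(counts)) {
      k <- counts[[sp]]
      if (k == 0L) next
      starts <- sample.int(glen[[sp]] - read_length + 1L, k, replace = TRUE)
      seqs <- c(seqs, substring(genomes[[sp]]$genome, starts,
                                starts + read_length - 1L))
      prov_sp <- c(prov_sp, rep(sp, k))
      prov_start <- c(prov_start, starts)
    }
    if (error_rate > 0) {
      total <- length(seqs) * read_length
      n_err <- stats::rbinom(1L, total, error_rate)
      if (n_err > 0L) {
        idx <- sample.int(total, n_err)
        rd <- (idx - 1L) %/% read_length + 1L
        ps <- (idx - 1L) %% read_length + 1L
        shift <- sample.int(3L, n_err, replace = TRUE)
        bases <- c("A", "C", "G", "T")
        ord <- order(rd)
        rd <- rd[ord]; ps <- ps[ord]; shift <- shift[ord]
        for (grp in split(seq_along(rd), rd)) {
          i <- rd[grp[1]]
          ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
          cur <- match(ch[ps[grp]], bases)
          ch[ps[grp]] <- bases[((cur - 1L + shift[grp]) %% 4L) + 1L]
          seqs[i] <- paste(ch, collapse = "")
        }
      }
    }
    ids <- sprintf("read%07d", seq_along(seqs))
    truth <- list(
      reads = data.table(id = ids, sequence = seqs,
                         qual = strrep("I", read_length)),
      provenance = data.table(read_id = ids, species = prov_sp,
                              start = prov_start),
      proportions = proportions,
      read_length = as.integer(read_length),
      error_rate = error_rate,
      seed = seed)
    class(truth) <- "mock_truth"
    truth
  })
}

#' @export
print.mock_truth <- function(x, ...) {
  cat("Mock community:", nrow(x$reads), "reads of", x$read_length,
      "bp, substitution error", x$error_rate, "\n")
  p <- sort(x$proportions, decreasing = TRUE)
  cat(paste(sprintf("  %-30s %6.3f", names(p), p), collapse = "\n"), "\n")
  invisible(x)
}

#' Default synthetic species panel
#'
#' Eight species in six genera, including one sister pair at 2% divergence
#' (orthologs merge at the 95% clustering threshold, so their clusters are
#' labeled at genus level) and one at 6% (orthologs mostly stay distinct).
#'
#' @param genome_length genome length per species, in bases.
#' @param n_genes number of 900 bp gene windows per genome.
#' @return list of [species_spec()] objects.
#' @export
default_mock_species <- function(genome_length = 50000L, n_genes = 50L) {
  sp <- function(...) species_spec(..., genome_length = genome_length,
                                   n_genes = n_genes)
  list(
    sp("Mockibacterium alpha", "Mockibacterium"),
    sp("Mockibacterium beta", "Mockibacterium",
       divergence_from_parent = 0.02, parent = "Mockibacterium alpha"),
    sp("Fictibacillus gamma", "Fictibacillus"),
    sp("Fictibacillus delta", "Fictibacillus",
       divergence_from_parent = 0.06, parent = "Fictibacillus gamma"),
    sp("Synthetica epsilon", "Synthetica"),
    sp("Imaginella zeta", "Imaginella"),
    sp("Artificia eta", "Artificia"),
    sp("Fabricatus theta", "Fabricatus"))
}

#' Default mock community designs
#'
#' Ten proportion vectors over the eight default species: three
#' single-dominant communities, one even community, three sister-pair
#' gradients over the 2% pair, one gradient over the 6% pair, and two seeded
#' random assortments with every species at >= 1%.
#'
#' @param species character vector of the eight species names, in the order
#'   of [default_mock_species()].
#' @param seed integer seed for the random assortments.
#' @return named list of named proportion vectors, each summing to 1.
#' @export
default_mock_communities <- function(species, seed) {
  stopifnot(length(species) == 8L)
  v <- function(x) { names(x) <- species; x / sum(x) }
  dom <- function(i) { p <- rep(0.03, 8L); p[i] <- 0.79; v(p) }
  pair <- function(i, j, pi, pj) {
    p <- rep((1 - pi - pj) / 6, 8L); p[i] <- pi; p[j] <- pj; v(p)
  }
  comm <- list(
    c01_dominant_epsilon = dom(5L),
    c02_dominant_alpha = dom(1L),
    c03_even = v(rep(0.125, 8L)),
    c04_sister2pc_75_25 = pair(1L, 2L, 0.45, 0.15),
    c05_sister2pc_50_50 = pair(1L, 2L, 0.30, 0.30),
    c06_sister2pc_25_75 = pair(1L, 2L, 0.15, 0.45),
    c07_sister6pc_67_33 = pair(3L, 4L, 0.40, 0.20))
  rnd <- with_seed(seed, replicate(3L, stats::rexp(8L), simplify = FALSE))
  for (i in seq_along(rnd)) {
    p <- rnd[[i]] / sum(rnd[[i]])
    comm[[sprintf("c%02d_random", 7L + i)]] <- v(0.01 + 0.92 * p)
  }
  comm
}
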