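# Readers and writers for the plain-text formats the package consumes and
# emits: FASTA/FASTQ (gzip transparent), tab-separated tables, and a minimal
# SAM subset.  Sequences are normalized to upper case, U -> T, and validated
# against the strict {A,C,G,T,N} alphabet.

#' Read a FASTA file
#'
#' Strict reader: sequences are upper-cased, RNA `U` is converted to `T`, and
#' any character outside `{A,C,G,T,N}` is a parse error naming the offending
#' line.  Gzip-compressed files are read transparently.
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @return a [data.table::data.table] with columns `id` (header token up to
#'   the first whitespace) and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) {
    stop("FASTA parse error at line 1: no header found in ", path,
         call. = FALSE)
  }
  pre <- lines[seq_len(hdr[1] - 1L)]
  if (any(nzchar(trimws(pre)))) {
    bad <- which(nzchar(trimws(pre)))[1]
    stop("FASTA parse error at line ", bad, ": sequence before first header",
         call. = FALSE)
  }
  seq_lines <- lines
  seq_lines[hdr] <- ""
  norm <- gsub("U", "T", toupper(seq_lines), fixed = TRUE)
  bad <- which(nzchar(norm) & !is_valid_dna(norm))
  if (length(bad) > 0L) {
    stop("FASTA parse error at line ", bad[1],
         ": invalid character in sequence (alphabet is A,C,G,T,N)",
         call. = FALSE)
  }
  grp <- cumsum(startsWith(lines, ">"))
  seqs <- vapply(split(norm, grp), paste, character(1), collapse = "")
  ids <- sub("^>([^ \t]*).*$", "\\1", lines[hdr])
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0L) {
    stop("FASTA parse error at line ", hdr[empty[1]],
         ": record '", ids[empty[1]], "' has an empty sequence",
         call. = FALSE)
  }
  if (any(!nzchar(ids))) {
    stop("FASTA parse error at line ", hdr[which(!nzchar(ids))[1]],
         ": empty record id", call. = FALSE)
  }
  data.table(id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param ids record identifiers.
#' @param sequences DNA strings.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, sequences, path, width = 80L) {
  stopifnot(length(ids) == length(sequences))
  wrap <- function(s) {
    if (nchar(s) <= width) return(s)
    starts <- seq(1L, nchar(s), by = width)
    paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
          collapse = "\n")
  }
  out <- character(2L * length(ids))
  out[c(TRUE, FALSE)] <- paste0(">", ids)
  out[c(FALSE, TRUE)] <- vapply(sequences, wrap, character(1), USE.NAMES = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Minimal four-line-record FASTQ reader (gzip transparent).  Sequence
#' normalization matches [read_fasta()].
#'
#' @param path path to a FASTQ file.
#' @return a data.table with columns `id`, `sequence`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error: ", path, " has ", length(lines),
         " lines (not a multiple of 4)", call. = FALSE)
  }
  n <- length(lines) %/% 4L
  ids <- lines[seq(1L, by = 4L, length.out = n)]
  if (any(!startsWith(ids, "@"))) {
    bad <- which(!startsWith(ids, "@"))[1]
    stop("FASTQ parse error at line ", (bad - 1L) * 4L + 1L,
         ": record does not start with '@'", call. = FALSE)
  }
  seqs <- gsub("U", "T", toupper(lines[seq(2L, by = 4L, length.out = n)]),
               fixed = TRUE)
  bad <- which(!is_valid_dna(seqs))
  if (length(bad) > 0L) {
    stop("FASTQ parse error at line ", (bad[1] - 1L) * 4L + 2L,
         ": invalid character in read sequence", call. = FALSE)
  }
  data.table(id = sub("^@([^ \t]*).*$", "\\1", ids),
             sequence = seqs,
             qual = lines[seq(4L, by = 4L, length.out = n)])
}

#' Write reads to a FASTQ file
#'
#' @param ids read identifiers.
#' @param sequences read sequences.
#' @param quals quality strings; a single string is recycled per read.
#' @param path output path (a `.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, sequences, quals, path) {
  n <- length(ids)
  stopifnot(length(sequences) == n)
  if (length(quals) == 1L && n > 1L) {
    quals <- vapply(nchar(sequences),
                    function(l) strrep(substr(quals, 1L, 1L), l), character(1))
  }
  out <- character(4L * n)
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", ids)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- sequences
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- quals
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

# Thin TSV wrappers: tab-separated, header row, no quoting, UTF-8.
read_tsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "", colClasses = NULL, ...)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "",
                     eol = "\n")
  invisible(path)
}

#' Read a gene-source manifest
#'
#' One row per source FASTA with its provenance and taxonomy.  Required
#' columns: `fasta_path`, `source_type` (one of `MAG`, `UNBINNED`,
#' `ISOLATE`), `source_id`, `sample_id`, `species`, `genus`.  `species` and
#' `genus` may be empty (gene carries no taxonomy); a species without a genus
#' is a configuration error.
#'
#' @param path path to the manifest TSV.
#' @param base_dir directory against which relative `fasta_path` entries are
#'   resolved; defaults to the manifest's directory.
#' @return the manifest as a data.table with resolved `fasta_path`.
#' @export
read_source_manifest <- function(path, base_dir = dirname(path)) {
  m <- read_tsv(path)
  req <- c("fasta_path", "source_type", "source_id", "sample_id",
           "species", "genus")
  miss <- setdiff(req, names(m))
  if (length(miss) > 0L) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in req) set(m, j = col, value = as.character(m[[col]]))
  for (col in req) set(m, j = col, value = fifelse(is.na(m[[col]]), "", m[[col]]))
  bad <- setdiff(unique(m$source_type), c("MAG", "UNBINNED", "ISOLATE"))
  if (length(bad) > 0L) {
    stop("unknown source_type token(s): ", paste(bad, collapse = ", "),
         " (expected MAG, UNBINNED or ISOLATE)", call. = FALSE)
  }
  orphan <- nzchar(m$species) & !nzchar(m$genus)
  if (any(orphan)) {
    stop("manifest row ", which(orphan)[1],
         ": species is set but genus is empty (genus is required for ",
         "species-level taxonomy)", call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$fasta_path)
  m[rel, fasta_path := file.path(base_dir, fasta_path)]
  m[]
}

#' Load gene records from a manifest
#'
#' Reads every source FASTA named in a manifest and attaches the source's
#' provenance and taxonomy to each gene.
#'
#' @param manifest a manifest table from [read_source_manifest()], or a path.
#' @return a gene table with columns `gene_id`, `sequence`, `length`,
#'   `source_type`, `source_id`, `sample_id`, `species`, `genus`.
#' @export
load_genes <- function(manifest) {
  if (is.character(manifest)) manifest <- read_source_manifest(manifest)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    fa <- read_fasta(manifest$fasta_path[i])
    data.table(gene_id = fa$id, sequence = fa$sequence,
               length = nchar(fa$sequence),
               source_type = manifest$source_type[i],
               source_id = manifest$source_id[i],
               sample_id = manifest$sample_id[i],
               species = manifest$species[i],
               genus = manifest$genus[i])
  })
  genes <- rbindlist(recs)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene_id across sources: ", dup[1], call. = FALSE)
  }
  genes[]
}

# ---- minimal SAM subset ----------------------------------------------------
# The internal mapper is gap-free and end-to-end, so CIGAR is always <len>M.
# Mismatch count travels in NM:i and alignment score (matches) in AS:i.
# Rsamtools only reads BAM (a binary format), hence this small text reader.

#' Write alignments as SAM
#'
#' @param aln alignment table from [map_reads()] (columns `read_id`, `nrg_id`,
#'   `pos`, `strand`, `mismatches`, `aln_len`, `score`, `read_seq`).
#' @param ref_lengths named integer vector of reference gene lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(ref_lengths), "\tLN:", ref_lengths))
  if (nrow(aln) > 0L) {
    first <- !duplicated(aln$read_id)
    flag <- ifelse(aln$strand < 0, 16L, 0L) + ifelse(first, 0L, 256L)
    seqs <- ifelse(aln$strand < 0, revcomp(aln$read_seq), aln$read_seq)
    body <- paste(aln$read_id, flag, aln$nrg_id, aln$pos, 255L,
                  paste0(aln$aln_len, "M"), "*", 0L, 0L, seqs, "*",
                  paste0("NM:i:", aln$mismatches),
                  paste0("AS:i:", aln$score), sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from a SAM file
#'
#' Supports the subset written by [write_sam()]: single-segment, gap-free
#' CIGAR (`<n>M`), `NM:i` mismatch tags.  Unmapped records (FLAG 0x4) are
#' skipped.
#'
#' @param path path to a SAM file.
#' @return alignment table compatible with [quantify()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "@")]
  empty <- data.table(read_id = character(0), nrg_id = character(0),
                      pos = integer(0), strand = integer(0),
                      mismatches = integer(0), aln_len = integer(0),
                      score = integer(0), read_seq = character(0))
  if (length(body) == 0L) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short) > 0L) {
    stop("SAM parse error: record ", short[1], " has fewer than 11 fields",
         call. = FALSE)
  }
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  fields <- fields[mapped]
  flag <- flag[mapped]
  if (length(fields) == 0L) return(empty)
  cigar <- vapply(fields, `[[`, "", 6L)
  if (!all(grepl("^[0-9]+M$", cigar))) {
    stop("SAM import supports gap-free CIGAR (<n>M) records only",
         call. = FALSE)
  }
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0L) NA_integer_ else as.integer(sub("^NM:i:", "", tag[1]))
  }, integer(1))
  if (anyNA(nm)) stop("SAM import requires NM:i tags", call. = FALSE)
  len <- as.integer(sub("M$", "", cigar))
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, -1L, 1L)
  seqs <- vapply(fields, `[[`, "", 10L)
  seqs <- ifelse(strand < 0L & seqs != "*", revcomp(seqs), seqs)
  data.table(read_id = vapply(fields, `[[`, "", 1L),
             nrg_id = vapply(fields, `[[`, "", 3L),
             pos = as.integer(vapply(fields, `[[`, "", 4L)),
             strand = strand,
             mismatches = nm,
             aln_len = len,
             score = len - nm,
             read_seq = seqs)
}
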