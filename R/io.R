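#' Read a FASTA genome
#'
#' Reads a multi-record FASTA file into a named [Biostrings::DNAStringSet].
#' Sequences are uppercased and multi-line records concatenated; record
#' order is preserved. Record names are the first whitespace-delimited
#' token of each header.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop_format("%s: empty FASTA file", path)
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop_format("%s: line %d: sequence data before any '>' header", path, first)
  }
  headers <- which(startsWith(lines, ">"))
  bad <- headers[!nzchar(trimws(substring(lines[headers], 2)))]
  if (length(bad)) stop_format("%s: line %d: malformed empty header", path, bad[1])
  ends <- c(headers[-1] - 1L, length(lines))
  for (i in seq_along(headers)) {
    body <- lines[seq.int(headers[i] + 1L, length.out = max(0L, ends[i] - headers[i]))]
    if (sum(nchar(trimws(body))) == 0L) {
      stop_format("%s: line %d: record with empty sequence", path, headers[i])
    }
  }
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(x) <- sub("\\s.*$", "", names(x))
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  x
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_genome_chars(seqs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Parses Sanger (Phred+33) FASTQ into a read set. Each record must occupy
#' four lines and carry a quality string of the same length as its
#' sequence.
#'
#' @param path path to a FASTQ file.
#' @return a list with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (length(lines) == 0L) {
    return(list(id = character(0), seq = character(0), qual = character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    stop_format("%s: truncated FASTQ record near line %d", path,
                4L * (length(lines) %/% 4L) + 1L)
  }
  idx <- seq(1L, length(lines), by = 4L)
  if (any(!startsWith(lines[idx], "@"))) {
    stop_format("%s: line %d: expected '@' header", path, idx[which(!startsWith(lines[idx], "@"))[1]])
  }
  if (any(!startsWith(lines[idx + 2L], "+"))) {
    stop_format("%s: line %d: expected '+' separator", path,
                (idx + 2L)[which(!startsWith(lines[idx + 2L], "+"))[1]])
  }
  seq <- toupper(lines[idx + 1L])
  qual <- lines[idx + 3L]
  if (any(nchar(qual) != nchar(seq))) {
    bad <- which(nchar(qual) != nchar(seq))[1]
    stop_format("%s: line %d: quality length differs from sequence length",
                path, idx[bad] + 3L)
  }
  list(id = sub("^@", "", sub("\\s.*$", "", lines[idx])), seq = seq, qual = qual)
}

#' Write reads to FASTQ
#'
#' @param reads list with `id`, `seq` and optional `qual` (defaults to "I",
#'   Phred 40, for every base).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seq <- as.character(reads$seq)
  id <- as.character(reads$id %||% paste0("read", seq_along(seq)))
  qual <- reads$qual %||% vapply(nchar(seq), function(n) strrep("I", n), "")
  if (any(nchar(qual) != nchar(seq))) {
    stop_validation("quality length differs from sequence length")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Imports `exon` features of a GTF2.2 file (1-based inclusive
#' coordinates) into the exon table used throughout the package: 0-based
#' half-open coordinates, exons grouped by transcript and sorted by start.
#' Only `gene_id` and `transcript_id` attributes are required; an optional
#' `gene_biotype` attribute ("coding"/"lncRNA") defaults to "coding".
#'
#' @param path path to a GTF file.
#' @return a `data.frame` with columns `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`, `exon_number`, `biotype`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop_format("%s: %s", path, conditionMessage(e)))
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) == 0L) stop_format("%s: no exon features", path)
  if (is.null(df$transcript_id) || anyNA(df$transcript_id)) {
    stop_format("%s: exon feature without transcript_id", path)
  }
  if (is.null(df$gene_id) || anyNA(df$gene_id)) {
    stop_format("%s: exon feature without gene_id", path)
  }
  if (any(!as.character(df$strand) %in% c("+", "-"))) {
    stop_format("%s: exon feature without '+'/'-' strand", path)
  }
  ann <- data.frame(
    gene_id = as.character(df$gene_id),
    transcript_id = as.character(df$transcript_id),
    chrom = as.character(df$seqnames),
    start = df$start - 1L,       # to 0-based half-open
    end = df$end,
    strand = as.character(df$strand),
    biotype = if (!is.null(df$gene_biotype)) {
      ifelse(is.na(df$gene_biotype), "coding", as.character(df$gene_biotype))
    } else "coding",
    stringsAsFactors = FALSE
  )
  if (any(ann$end <= ann$start)) stop_format("%s: exon with end <= start", path)
  ann <- ann[order(ann$transcript_id, ann$start), , drop = FALSE]
  ann$exon_number <- stats::ave(ann$start, ann$transcript_id,
                                FUN = seq_along)
  validate_annotation(ann)
  rownames(ann) <- NULL
  ann
}

#' Write gene models to GTF
#'
#' @param annotation exon table as produced by [read_gtf()] or
#'   [generate_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  validate_annotation(annotation)
  a <- annotation[order(annotation$gene_id, annotation$transcript_id, annotation$start), ]
  lines <- sprintf(
    "%s\tcircscan\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; exon_number \"%d\"; gene_biotype \"%s\";",
    a$chrom, a$start + 1L, a$end, a$strand, a$gene_id, a$transcript_id,
    as.integer(a$exon_number), a$biotype %||% "coding")
  writeLines(lines, path)
  invisible(path)
}

# Exon-table invariants: positive widths, per-transcript exons sorted and
# non-overlapping, one chrom/strand per transcript.
validate_annotation <- function(ann) {
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(ann))) {
    stop_validation("annotation lacks columns: %s",
                    paste(setdiff(need, names(ann)), collapse = ", "))
  }
  if (any(ann$end <= ann$start)) stop_validation("exon with end <= start")
  if (any(!ann$strand %in% c("+", "-"))) stop_validation("exon strand must be '+'/'-'")
  for (tx in split(ann, ann$transcript_id)) {
    if (length(unique(tx$chrom)) > 1L || length(unique(tx$strand)) > 1L) {
      stop_validation("transcript %s mixes chrom/strand", tx$transcript_id[1])
    }
    o <- order(tx$start)
    if (any(tx$end[o][-nrow(tx)] > tx$start[o][-1L])) {
      stop_validation("transcript %s has overlapping exons", tx$transcript_id[1])
    }
  }
  invisible(ann)
}

circ_table_columns <- c("chrom", "start", "end", "strand", "circ_id",
                        "n_unique_reads", "srpbm", "cr5", "cr3",
                        "category", "host_gene")

validate_circ_rows <- function(rows) {
  missing_cols <- setdiff(circ_table_columns, names(rows))
  if (length(missing_cols)) {
    stop_validation("circ table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  bad <- which(rows$end <= rows$start |
                 rows$n_unique_reads < 0 |
                 rows$srpbm < 0 |
                 (!is.na(rows$cr5) & (rows$cr5 < 0 | rows$cr5 > 1)) |
                 (!is.na(rows$cr3) & (rows$cr3 < 0 | rows$cr3 > 1)))
  if (length(bad)) {
    stop_validation("invalid circ table row(s): %s",
                    paste(utils::head(bad, 5L), collapse = ", "))
  }
  invisible(rows)
}

#' Write a circRNA table
#'
#' Writes per-circRNA records either as a header-bearing TSV with the
#' package's fixed column order, or as BED6 (0-based half-open; the score
#' column holds the unique-read count capped at 1000).
#'
#' @param rows `data.frame` of circRNA records.
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"bed6plus"`.
#' @return `path`, invisibly.
#' @export
write_circ_table <- function(rows, path, dialect = c("tsv", "bed6plus")) {
  dialect <- match.arg(dialect)
  if (nrow(rows)) validate_circ_rows(rows) else {
    for (col in setdiff(circ_table_columns, names(rows))) rows[[col]] <- logical(0)
  }
  if (dialect == "tsv") {
    out <- rows[, circ_table_columns, drop = FALSE]
    out$srpbm <- signif(out$srpbm, 6)
    out$cr5 <- signif(out$cr5, 6)
    out$cr3 <- signif(out$cr3, 6)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(rows$chrom, rows$start, rows$end, rows$circ_id,
                      pmin(rows$n_unique_reads, 1000L), rows$strand)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a circRNA table written by [write_circ_table()]
#'
#' @param path path to the TSV.
#' @return `data.frame` of circRNA records.
#' @export
read_circ_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  rows <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(circ_table_columns %in% names(rows))) {
    stop_format("%s: not a circscan circRNA table", path)
  }
  if (nrow(rows)) validate_circ_rows(rows)
  rows
}
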