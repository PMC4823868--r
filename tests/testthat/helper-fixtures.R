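# Shared fixtures and independent oracles, built in code at test time.

DNA <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

# Brute-force anchor oracle: all exact occurrences of `anchor` (and of its
# reverse complement, reported as '-') by plain substring scan.
brute_anchor_scan <- function(anchor, genome) {
  hits <- NULL
  scan1 <- function(pat, chrom, seq, strand) {
    p <- 1L
    out <- integer(0)
    repeat {
      m <- regexpr(pat, substr(seq, p, nchar(seq)), fixed = TRUE)
      if (m < 0) break
      out <- c(out, p + m - 2L)  # 0-based
      p <- p + m
    }
    if (length(out)) data.frame(chrom = chrom, pos = out, strand = strand,
                                stringsAsFactors = FALSE)
  }
  for (ch in names(genome)) {
    hits <- rbind(hits, scan1(anchor, ch, genome[[ch]], "+"),
                  scan1(revcomp(anchor), ch, genome[[ch]], "-"))
  }
  if (is.null(hits)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$chrom, hits$pos, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Independent local-alignment score oracle (full dynamic program).
sw_oracle_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  sc <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE),
    gapOpening = 0, gapExtension = -gap, scoreOnly = TRUE)
  as.numeric(sc)
}

count_mismatch_str <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# A small hand-built two-gene annotation used by host/classification tests:
#   gene gA ('+', coding): tA1 exons [100,200) [300,400) [500,650)
#                          tA2 exons [100,200) [300,400) [500,900)
#   gene gB ('-', lncRNA): tB1 exons [2000,2150) [2300,2400)
toy_annotation <- function() {
  data.frame(
    gene_id = c(rep("gA", 6), rep("gB", 2)),
    transcript_id = c(rep("tA1", 3), rep("tA2", 3), rep("tB1", 2)),
    chrom = "chr1",
    start = c(100, 300, 500, 100, 300, 500, 2000, 2300),
    end = c(200, 400, 650, 200, 400, 900, 2150, 2400),
    strand = c(rep("+", 6), rep("-", 2)),
    exon_number = c(1:3, 1:3, 2:1),
    biotype = c(rep("coding", 6), rep("lncRNA", 2)),
    stringsAsFactors = FALSE)
}

# Build a genome string carrying a single-exon circle with canonical
# flanks: ...AG [exon] GT...  Returns 0-based exon coordinates.
genome_with_circle <- function(exon_len = 200, pad = 400, strand = "+",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  left <- rand_dna(pad)
  exon <- rand_dna(exon_len)
  right <- rand_dna(pad)
  if (strand == "+") {
    substr(left, pad - 1, pad) <- "AG"
    substr(right, 1, 2) <- "GT"
  } else {
    substr(left, pad - 1, pad) <- "AC"
    substr(right, 1, 2) <- "CT"
  }
  g <- c(chr1 = paste0(left, exon, right))
  list(genome = g, start = pad, end = pad + exon_len, exon = exon,
       strand = strand)
}
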