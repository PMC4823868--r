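#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce a genome (named character vector or DNAStringSet) to a named
# uppercase character vector; names are required and must be unique.
as_genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- toupper(genome)
  } else {
    stop_validation("genome must be a named character vector or DNAStringSet")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))) || anyDuplicated(names(seqs))) {
    stop_validation("genome sequences must carry unique non-empty names")
  }
  if (any(nchar(seqs) < 1L)) stop_validation("empty chromosome sequence")
  seqs
}

# Coerce reads (character vector, DNAStringSet, or read_fastq() result) to
# a character vector of sequences.
as_read_chars <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.list(reads) && !is.null(reads$seq)) return(as.character(reads$seq))
  if (is.data.frame(reads) && !is.null(reads$seq)) return(as.character(reads$seq))
  if (is.character(reads)) return(reads)
  stop_validation("reads must be a character vector, DNAStringSet or read set")
}

draw_range <- function(n, range) {
  if (length(range) == 1L) range <- c(range, range)
  if (range[1] > range[2]) stop_config("invalid range [%s, %s]", range[1], range[2])
  if (isTRUE(all.equal(range[1], round(range[1]))) &&
      isTRUE(all.equal(range[2], round(range[2])))) {
    sample.int(range[2] - range[1] + 1L, n, replace = TRUE) + range[1] - 1L
  } else {
    runif(n, range[1], range[2])
  }
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
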