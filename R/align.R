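#' Build an exact-match k-mer seed index of a genome
#'
#' Indexes every k-mer of the forward strand of each chromosome; queries
#' return occurrences on both strands (a minus-strand hit for query `q` at
#' position `p` means the reverse complement of `q` occurs at `p` on the
#' forward sequence). K-mers containing N are not indexed and never
#' queried. The index lives in memory and backs both contiguous read
#' placement and the 20-nt anchor lookups of the junction caller.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param k k-mer length (default 20, the anchor length).
#' @return a `seed_index` object.
#' @export
build_index <- function(genome, k = 20L) {
  seqs <- as_genome_chars(genome)
  if (k < 4L) stop_config("k must be >= 4")
  if (k > min(nchar(seqs))) {
    stop_config("k = %d exceeds the shortest chromosome (%d nt)",
                k, min(nchar(seqs)))
  }
  ptr <- cpp_build_index(unname(seqs), names(seqs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k),
                 chrom = names(seqs), chrom_length = unname(nchar(seqs))),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: k=%d, %d chromosome(s), %s nt total\n",
              x$k, length(x$chrom), format(sum(x$chrom_length), big.mark = ",")))
  invisible(x)
}

chrom_name <- function(index, chrom_idx) index$chrom[chrom_idx]

#' Look up all exact occurrences of an anchor
#'
#' @param anchor_seq character scalar of length `index$k`.
#' @param index a [build_index()] object.
#' @param side optional label ("5'"/"3'") recording which read end the
#'   anchor came from; carried through to the result.
#' @return `data.frame` with `chrom`, `pos` (0-based forward start),
#'   `strand`, `side`, in deterministic (chrom, pos, strand) order.
#' @export
map_anchor <- function(anchor_seq, index, side = NA_character_) {
  stopifnot(inherits(index, "seed_index"))
  if (nchar(anchor_seq) != index$k) {
    stop_validation("anchor length %d != k = %d", nchar(anchor_seq), index$k)
  }
  hits <- cpp_map_anchor(index$ptr, toupper(anchor_seq))
  data.frame(chrom = chrom_name(index, hits$chrom_idx), pos = hits$pos,
             strand = hits$strand, side = rep(side, nrow(hits)),
             stringsAsFactors = FALSE)
}

#' Place reads contiguously on the genome
#'
#' Seeds each read with its first k-mer (last k-mer as fallback) on both
#' strands and verifies a full-length gapless extension with at most
#' `max_mismatch` substitutions. The hit with fewest mismatches wins;
#' ties break deterministically by (chrom, pos, '+' first). Reads without
#' a qualifying placement are reported unmapped (NA row), not an error.
#'
#' @param reads character vector / `DNAStringSet` / read set.
#' @param index a [build_index()] object.
#' @param max_mismatch mismatch budget (default 2).
#' @return `data.frame` with one row per read: `chrom`, `pos`, `strand`,
#'   `n_mismatches`; NA entries mean unmapped.
#' @export
map_contiguous <- function(reads, index, max_mismatch = 2L) {
  stopifnot(inherits(index, "seed_index"))
  reads <- toupper(as_read_chars(reads))
  hits <- cpp_map_contiguous(index$ptr, reads, as.integer(max_mismatch))
  data.frame(chrom = chrom_name(index, hits$chrom_idx), pos = hits$pos,
             strand = hits$strand, n_mismatches = hits$n_mismatches,
             stringsAsFactors = FALSE)
}
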