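#' Split a read into its two terminal anchors
#'
#' The junction caller reduces each contiguously unmappable read to a
#' 20-nt anchor from each end; anchor placements in head-to-tail
#' orientation flag candidate back-splice junctions.
#'
#' @param read character scalar.
#' @param anchor_len anchor length (default 20).
#' @return list with `left` and `right` anchors, or `NULL` (skip signal)
#'   when the read is shorter than `2 * anchor_len`.
#' @export
split_anchors <- function(read, anchor_len = 20L) {
  L <- nchar(read)
  if (L < 2L * anchor_len) return(NULL)
  list(left = substr(read, 1L, anchor_len),
       right = substr(read, L - anchor_len + 1L, L))
}

#' Resolve the breakpoint between two anchor placements
#'
#' Enumerates every split position `s` in `[anchor_len, len(read) -
#' anchor_len]` such that `read[1:s]` extends the left-anchor placement
#' and `read[(s+1):len]` extends the right-anchor placement with at most
#' `max_mismatch` substitutions in total, keeping only splits whose
#' genomic breakpoints are flanked by strand-aware canonical splice
#' dinucleotides (GT donor / AG acceptor; CT / AC on the forward strand
#' for minus-strand junctions). The junction's strand is the one whose
#' motif matches — the hit pair's strand only selects whether the read or
#' its reverse complement aligns forward, since the library contains both
#' orientations of every fragment. Placements in genomically forward
#' order give a linear junction; reversed (head-to-tail) order gives a
#' back-splice. Among acceptable splits the deterministic tie-break is:
#' fewest mismatches, linear over back-splice, split nearest the read
#' midpoint, then smallest `acceptor_start`.
#'
#' `acceptor_start` / `donor_end` are geometric forward-strand
#' boundaries: a back-splice call spans the circle
#' `[acceptor_start, donor_end)`.
#'
#' @param read character scalar.
#' @param left_hit,right_hit single anchor hits (rows of [map_anchor()]
#'   output, or lists with `chrom`, `pos`, `strand`) for the read's first
#'   and last anchor respectively; must share chrom and strand.
#' @param index a [build_index()] object (carries the genome).
#' @param max_mismatch mismatch budget (default 2).
#' @param all_candidates return every acceptable split instead of the best.
#' @return `data.frame` of calls (`chrom`, `strand`, `acceptor_start`,
#'   `donor_end`, `jtype`, `n_mismatches`, `split`); zero rows when no
#'   split is acceptable.
#' @export
resolve_breakpoint <- function(read, left_hit, right_hit, index,
                               max_mismatch = 2L, all_candidates = FALSE) {
  stopifnot(inherits(index, "seed_index"))
  if (left_hit$chrom != right_hit$chrom || left_hit$strand != right_hit$strand) {
    stop_validation("anchor hits must share chrom and strand")
  }
  ci <- match(left_hit$chrom, index$chrom)
  if (is.na(ci)) stop_validation("unknown chromosome %s", left_hit$chrom)
  res <- cpp_resolve_breakpoint(index$ptr, toupper(read), ci,
                                as.integer(left_hit$pos), ci,
                                as.integer(right_hit$pos),
                                as.character(left_hit$strand),
                                index$k, as.integer(max_mismatch),
                                isTRUE(all_candidates))
  data.frame(chrom = chrom_name(index, res$chrom_idx), strand = res$strand,
             acceptor_start = res$acceptor_start, donor_end = res$donor_end,
             jtype = res$jtype, n_mismatches = res$n_mismatches,
             split = res$split, stringsAsFactors = FALSE)
}

#' Default junction-caller parameters
#'
#' @param anchor_len terminal anchor length in nt.
#' @param max_mismatch substitution budget per read (0 inside splice
#'   dinucleotides, which the read never covers).
#' @param max_span maximum genomic distance between the two anchor hits.
#' @param max_anchor_hits anchors with more occurrences are treated as
#'   repeat-derived and their reads skipped.
#' @param min_unique_backsplice evidence threshold: back-splice junctions
#'   need at least this many distinct supporting read sequences.
#' @return named list of parameters.
#' @export
junction_params <- function(anchor_len = 20L, max_mismatch = 2L,
                            max_span = 1e6, max_anchor_hits = 10L,
                            min_unique_backsplice = 2L) {
  list(anchor_len = as.integer(anchor_len),
       max_mismatch = as.integer(max_mismatch),
       max_span = as.numeric(max_span),
       max_anchor_hits = as.integer(max_anchor_hits),
       min_unique_backsplice = as.integer(min_unique_backsplice))
}

#' Call linear and back-splice junctions from a read set
#'
#' Per read: attempt contiguous placement; if that fails, split into
#' terminal anchors, look up both anchors, and resolve a breakpoint for
#' every same-chromosome, same-strand hit pair within `max_span`, keeping
#' the single best call per read under the deterministic tie-break.
#' Support is then aggregated per junction key over **distinct read
#' sequences** (`n_unique`, which deduplicates PCR copies) as well as raw
#' spanning reads (`n_reads`, the count the circular-ratio and SRPBM
#' formulas use). All linear junctions are reported; back-splice
#' junctions require `n_unique >= min_unique_backsplice`.
#'
#' @param reads character vector / `DNAStringSet` / read set.
#' @param index a [build_index()] object of the reference genome.
#' @param params see [junction_params()].
#' @return list with
#'   * `junctions`: `data.frame` (`chrom`, `strand`, `acceptor_start`,
#'     `donor_end`, `jtype`, `n_reads`, `n_unique`), ordered by
#'     coordinates;
#'   * `summary`: total, contiguously mapped, junction-mapped (linear and
#'     back-spliced), unmapped and skipped read counts plus
#'     `n_mapped_reads` (contiguous + linear-spliced + back-spliced, the
#'     SRPBM denominator);
#'   * `read_calls`: the per-read assignment table.
#' @export
call_junctions <- function(reads, index, params = junction_params()) {
  stopifnot(inherits(index, "seed_index"))
  reads <- toupper(as_read_chars(reads))
  n <- length(reads)
  empty <- data.frame(chrom = character(0), strand = character(0),
                      acceptor_start = integer(0), donor_end = integer(0),
                      jtype = character(0), n_reads = integer(0),
                      n_unique = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(junctions = empty,
                summary = data.frame(n_total = 0L, n_contiguous = 0L,
                                     n_linear = 0L, n_backsplice = 0L,
                                     n_unmapped = 0L, n_skipped = 0L,
                                     n_mapped_reads = 0L),
                read_calls = NULL))
  }
  res <- cpp_call_reads(index$ptr, reads, params$anchor_len,
                        params$max_mismatch, params$max_span,
                        params$max_anchor_hits)
  calls <- data.frame(status = res$status, chrom_idx = res$chrom_idx,
                      strand = res$strand, acceptor_start = res$acceptor_start,
                      donor_end = res$donor_end, n_mismatches = res$n_mismatches,
                      stringsAsFactors = FALSE)
  jn <- which(calls$status %in% c(1L, 2L))
  if (length(jn)) {
    key <- paste(calls$chrom_idx[jn], calls$strand[jn],
                 calls$acceptor_start[jn], calls$donor_end[jn],
                 calls$status[jn], sep = "\r")
    # order-invariant aggregation: tabulate reads and distinct sequences
    n_reads <- tapply(rep(1L, length(jn)), key, sum)
    n_uni <- tapply(reads[jn], key, function(s) length(unique(s)))
    parts <- do.call(rbind, strsplit(names(n_reads), "\r", fixed = TRUE))
    jx <- data.frame(chrom = chrom_name(index, as.integer(parts[, 1])),
                     strand = parts[, 2],
                     acceptor_start = as.integer(parts[, 3]),
                     donor_end = as.integer(parts[, 4]),
                     jtype = ifelse(parts[, 5] == "1", "linear", "backsplice"),
                     n_reads = as.integer(n_reads),
                     n_unique = as.integer(n_uni),
                     stringsAsFactors = FALSE)
    keep <- jx$jtype == "linear" |
      jx$n_unique >= params$min_unique_backsplice
    jx <- jx[keep, , drop = FALSE]
    jx <- jx[order(jx$chrom, jx$acceptor_start, jx$donor_end, jx$strand,
                   jx$jtype), , drop = FALSE]
    rownames(jx) <- NULL
  } else {
    jx <- empty
  }
  n_contig <- sum(calls$status == 0L)
  n_lin <- sum(calls$status == 1L)
  n_bs <- sum(calls$status == 2L)
  list(junctions = jx,
       summary = data.frame(n_total = n, n_contiguous = n_contig,
                            n_linear = n_lin, n_backsplice = n_bs,
                            n_unmapped = sum(calls$status == 3L),
                            n_skipped = sum(calls$status == 4L),
                            n_mapped_reads = n_contig + n_lin + n_bs),
       read_calls = calls)
}
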