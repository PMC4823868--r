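# Host-gene assignment, genomic-origin classification, spliced length,
# flanking introns and inverted-repeat scoring.

tx_index <- function(annotation) {
  a <- annotation[order(annotation$start), , drop = FALSE]
  split(a, a$transcript_id)
}

#' Assign the host gene of a circRNA
#'
#' Among same-strand transcripts in which `circ$start` equals some exon
#' start and `circ$end` equals the end of the same or a later exon,
#' selects the transcript whose matched exon run has the longest spliced
#' length (ties by lexicographically smallest transcript id); the host
#' gene is that transcript's gene. Boundary matching is exact.
#'
#' @param circ list or one-row `data.frame` with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param annotation exon table (see [read_gtf()]).
#' @return list: `circ_id` (if present on `circ`), `gene_id`,
#'   `transcript_id`, `exon_from`, `exon_to` (1-based geometric exon
#'   indices within the transcript), `spliced_length`; the gene and
#'   transcript are `NA` when no transcript matches both ends.
#' @export
assign_host_gene <- function(circ, annotation) {
  cand <- annotation[annotation$chrom == circ$chrom &
                       annotation$strand == circ$strand, , drop = FALSE]
  none <- list(circ_id = circ$circ_id %||% NA_character_,
               gene_id = NA_character_, transcript_id = NA_character_,
               exon_from = NA_integer_, exon_to = NA_integer_,
               spliced_length = NA_integer_)
  if (nrow(cand) == 0L) return(none)
  best <- NULL
  for (tx in tx_index(cand)) {
    i <- which(tx$start == circ$start)
    j <- which(tx$end == circ$end)
    if (length(i) == 0L || length(j) == 0L) next
    i <- i[1]; j <- j[length(j)]
    if (j < i) next
    len <- sum(tx$end[i:j] - tx$start[i:j])
    if (is.null(best) || len > best$spliced_length ||
        (len == best$spliced_length && tx$transcript_id[1] < best$transcript_id)) {
      best <- list(circ_id = circ$circ_id %||% NA_character_,
                   gene_id = tx$gene_id[1], transcript_id = tx$transcript_id[1],
                   exon_from = i, exon_to = j, spliced_length = len)
    }
  }
  best %||% none
}

#' Spliced length of a circRNA on its host transcript
#'
#' Sum of the matched exon lengths, introns excluded.
#'
#' @param circ as in [assign_host_gene()].
#' @param annotation exon table.
#' @param transcript_id transcript whose exons must match both circle ends.
#' @return integer length in nt.
#' @export
spliced_length <- function(circ, annotation, transcript_id) {
  tx <- annotation[annotation$transcript_id == transcript_id, , drop = FALSE]
  tx <- tx[order(tx$start), , drop = FALSE]
  i <- which(tx$start == circ$start)
  j <- which(tx$end == circ$end)
  if (length(i) == 0L || length(j) == 0L || j[length(j)] < i[1]) {
    stop_domain("circle ends do not both match exon boundaries of %s",
                transcript_id)
  }
  i <- i[1]; j <- j[length(j)]
  sum(tx$end[i:j] - tx$start[i:j])
}

#' Classify the genomic origin of a circRNA
#'
#' Priority order (categories form a partition): both ends match coding
#' exon boundaries on the same strand -> `"coding-exonic"`; both ends
#' match lncRNA exon boundaries -> `"lncRNA"`; contained within an intron
#' of a same-strand transcript -> `"intronic"`; overlapping annotation on
#' the opposite strand only -> `"antisense"`; otherwise `"unannotated"`.
#'
#' @param circ as in [assign_host_gene()].
#' @param annotation exon table with a `biotype` column
#'   (`"coding"`/`"lncRNA"`).
#' @return category string.
#' @export
classify_circ <- function(circ, annotation) {
  if (is.null(annotation$biotype)) annotation$biotype <- "coding"
  for (bt in c("coding", "lncRNA")) {
    hit <- assign_host_gene(circ, annotation[annotation$biotype == bt, ,
                                             drop = FALSE])
    if (!is.na(hit$gene_id)) {
      return(if (bt == "coding") "coding-exonic" else "lncRNA")
    }
  }
  sense <- annotation[annotation$chrom == circ$chrom &
                        annotation$strand == circ$strand, , drop = FALSE]
  if (nrow(sense)) {
    for (tx in tx_index(sense)) {
      if (nrow(tx) < 2L) next
      istart <- tx$end[-nrow(tx)]
      iend <- tx$start[-1L]
      if (any(circ$start >= istart & circ$end <= iend)) return("intronic")
    }
  }
  overlaps <- function(d) any(d$chrom == circ$chrom &
                                d$start < circ$end & d$end > circ$start)
  gene_span <- do.call(rbind, lapply(split(annotation, annotation$gene_id),
    function(g) data.frame(chrom = g$chrom[1], start = min(g$start),
                           end = max(g$end), strand = g$strand[1],
                           stringsAsFactors = FALSE)))
  same <- gene_span[gene_span$strand == circ$strand, , drop = FALSE]
  opp <- gene_span[gene_span$strand != circ$strand, , drop = FALSE]
  if (!overlaps(same) && overlaps(opp)) return("antisense")
  "unannotated"
}

#' Flanking introns of a circRNA
#'
#' Returns the intron immediately 5' of the first matched exon and
#' immediately 3' of the last matched exon, in transcript orientation
#' (for minus-strand hosts the upstream intron is the genomically
#' rightward one). A side whose matched exon is terminal has no flanking
#' intron and is reported `NULL`.
#'
#' @param circ as in [assign_host_gene()].
#' @param assignment result of [assign_host_gene()].
#' @param annotation exon table.
#' @param genome named character vector or `DNAStringSet` (optional; when
#'   given, intron sequences are attached, forward-strand orientation).
#' @return list with `upstream` and `downstream`, each `NULL` or a list
#'   `(chrom, start, end, length, seq)`.
#' @export
flanking_introns <- function(circ, assignment, annotation, genome = NULL) {
  if (is.na(assignment$transcript_id)) {
    stop_domain("circRNA has no host assignment")
  }
  tx <- annotation[annotation$transcript_id == assignment$transcript_id, ,
                   drop = FALSE]
  tx <- tx[order(tx$start), , drop = FALSE]
  seqs <- if (!is.null(genome)) as_genome_chars(genome)
  intron <- function(k) { # intron between geometric exons k and k+1
    if (k < 1L || k >= nrow(tx)) return(NULL)
    s <- tx$end[k]; e <- tx$start[k + 1L]
    list(chrom = tx$chrom[1], start = s, end = e, length = e - s,
         seq = if (!is.null(seqs)) substr(seqs[[tx$chrom[1]]], s + 1L, e)
               else NA_character_)
  }
  left <- intron(assignment$exon_from - 1L)
  right <- intron(assignment$exon_to)
  if (circ$strand == "+") {
    list(upstream = left, downstream = right)
  } else {
    list(upstream = right, downstream = left)
  }
}

#' Best inverted repeat between two flanking introns
#'
#' Smith-Waterman local alignment (match +1, mismatch -1, -2 per gap
#' column, linear gaps) of the upstream intron against the reverse
#' complement of the downstream intron: a high-identity hit is a pair of
#' reverse-complementary segments of the kind (inverted Alu repeats) that
#' promotes back-splicing by bringing the circle's splice sites together.
#' Identity counts matched columns over all alignment columns including
#' gaps. Deterministic tie-break: smallest upstream start, then smallest
#' downstream start.
#'
#' @param upstream_intron,downstream_intron character scalars (nonempty).
#' @param match,mismatch,gap scoring parameters.
#' @return list: `score`, `identity`, `length` (alignment columns),
#'   `n_matches`, `upstream` and `downstream` segment coordinates
#'   (0-based half-open within each intron), and the aligned strings. A
#'   score of 0 means no positive-scoring alignment.
#' @export
best_inverted_repeat <- function(upstream_intron, downstream_intron,
                                 match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(upstream_intron) || !nzchar(downstream_intron)) {
    stop_validation("introns must be nonempty")
  }
  b_rc <- revcomp(downstream_intron)
  al <- cpp_smith_waterman(toupper(upstream_intron), toupper(b_rc),
                           match, mismatch, gap)
  if (al$score <= 0) {
    return(list(score = 0, identity = NA_real_, length = 0L, n_matches = 0L,
                upstream = NULL, downstream = NULL,
                a_aligned = "", b_aligned = ""))
  }
  nd <- nchar(downstream_intron)
  list(score = al$score, identity = al$identity, length = al$length,
       n_matches = al$n_matches,
       upstream = c(start = al$a_start, end = al$a_end),
       # map reverse-complement coordinates back onto the downstream intron
       downstream = c(start = nd - al$b_end, end = nd - al$b_start),
       a_aligned = al$a_aligned, b_aligned = al$b_aligned)
}

#' Flanking-intron length contrast between two circRNA sets
#'
#' Compares flanking-intron lengths (the maximum of a circle's two sides)
#' between a high-abundance set and the remaining circles with the
#' rank-sum test.
#'
#' @param high_lengths,other_lengths numeric vectors of per-circle
#'   flanking-intron lengths.
#' @return list: `median_high`, `median_other`, `statistic` (U for the
#'   high set), `p.value`; an `insufficient` flag when a set is empty.
#' @export
intron_length_contrast <- function(high_lengths, other_lengths) {
  if (length(high_lengths) == 0L || length(other_lengths) == 0L) {
    return(list(median_high = NA_real_, median_other = NA_real_,
                statistic = NA_real_, p.value = NA_real_,
                insufficient = TRUE))
  }
  rs <- rank_sum_test(high_lengths, other_lengths)
  list(median_high = median(high_lengths),
       median_other = median(other_lengths),
       statistic = rs$statistic, p.value = rs$p.value, insufficient = FALSE)
}

#' Annotate circRNA records against gene models
#'
#' Fills `host_gene`, `category` and `spliced_length` for each record and
#' computes flanking-intron lengths and (optionally) the best
#' inverted-repeat hit per circle.
#'
#' @param records circRNA records from [quantify_circs()].
#' @param annotation exon table.
#' @param genome optional genome (enables inverted-repeat scoring).
#' @param score_repeats also run [best_inverted_repeat()] per circle
#'   (default `FALSE`; quadratic in intron length).
#' @return `records` with `host_gene`, `category`, `spliced_length`,
#'   `flank_up_len`, `flank_down_len`, `flank_max_len` and, when scoring,
#'   `ir_identity`, `ir_length`, `ir_score` columns.
#' @export
annotate_circs <- function(records, annotation, genome = NULL,
                           score_repeats = FALSE) {
  n <- nrow(records)
  records$host_gene <- NA_character_
  records$category <- NA_character_
  records$spliced_length <- NA_integer_
  records$flank_up_len <- NA_integer_
  records$flank_down_len <- NA_integer_
  records$flank_max_len <- NA_integer_
  if (score_repeats) {
    records$ir_identity <- NA_real_
    records$ir_length <- NA_integer_
    records$ir_score <- NA_real_
  }
  for (i in seq_len(n)) {
    circ <- records[i, ]
    asg <- assign_host_gene(circ, annotation)
    records$host_gene[i] <- asg$gene_id
    records$spliced_length[i] <- asg$spliced_length
    records$category[i] <- classify_circ(circ, annotation)
    if (!is.na(asg$transcript_id)) {
      fl <- flanking_introns(circ, asg, annotation, genome)
      records$flank_up_len[i] <- fl$upstream$length %||% NA_integer_
      records$flank_down_len[i] <- fl$downstream$length %||% NA_integer_
      both <- c(records$flank_up_len[i], records$flank_down_len[i])
      if (!all(is.na(both))) records$flank_max_len[i] <- max(both, na.rm = TRUE)
      if (score_repeats && !is.null(genome) &&
          !is.null(fl$upstream) && !is.null(fl$downstream)) {
        ir <- best_inverted_repeat(fl$upstream$seq, fl$downstream$seq)
        records$ir_identity[i] <- ir$identity
        records$ir_length[i] <- ir$length
        records$ir_score[i] <- ir$score
      }
    }
  }
  records
}
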