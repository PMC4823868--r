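#' Spliced reads per billion mapped (SRPBM)
#'
#' `SRPBM = n_circ_reads / (n_mapped_reads / 1e9) / read_length`: the
#' back-spliced read count normalized by sample depth (in billions of
#' mapped reads) and read length, so abundance is comparable across
#' RNA-seq runs.
#'
#' @param n_circ_reads reads spanning the back-splice junction (vectorized).
#' @param n_mapped_reads total mapped reads in the sample (> 0).
#' @param read_length read length in nt (> 0).
#' @return numeric SRPBM values.
#' @export
srpbm <- function(n_circ_reads, n_mapped_reads, read_length) {
  if (any(n_mapped_reads <= 0)) stop_domain("n_mapped_reads must be > 0")
  if (any(read_length <= 0)) stop_domain("read_length must be > 0")
  n_circ_reads / (n_mapped_reads / 1e9) / read_length
}

#' Circular ratio
#'
#' `CR = c / (c + l)`: the fraction of junction-informative reads at a
#' circle boundary that are back-spliced rather than linearly spliced.
#' Undefined (NA) when both counts are zero.
#'
#' @param n_circ_reads back-spliced read count(s).
#' @param n_linear_reads linearly spliced read count(s) at the same boundary.
#' @return numeric in `[0, 1]`, or NA where both inputs are zero.
#' @export
circular_ratio <- function(n_circ_reads, n_linear_reads) {
  if (any(n_circ_reads < 0) || any(n_linear_reads < 0)) {
    stop_domain("read counts must be nonnegative")
  }
  tot <- n_circ_reads + n_linear_reads
  ifelse(tot == 0, NA_real_, n_circ_reads / tot)
}

#' Circular ratios at both boundaries of each called circle
#'
#' For each back-splice junction, the 5' (acceptor-side) circular ratio
#' divides its spanning reads by those plus the spanning reads of linear
#' junctions sharing the circle's `acceptor_start`; the 3' (donor-side)
#' ratio uses linear junctions sharing the circle's `donor_end`. A
#' boundary with no matching linear junction yields CR = 1 (linearly
#' spliced products absent). For minus-strand circles the 5'/3' labels
#' refer to the genomic left/right boundary.
#'
#' @param junctions junction table from [call_junctions()].
#' @return the back-splice subset with `cr5` and `cr3` columns added.
#' @export
compute_cr_ends <- function(junctions) {
  bs <- junctions[junctions$jtype == "backsplice", , drop = FALSE]
  lin <- junctions[junctions$jtype == "linear", , drop = FALSE]
  if (nrow(bs) == 0L) {
    bs$cr5 <- numeric(0); bs$cr3 <- numeric(0)
    return(bs)
  }
  acc_key <- function(d) paste(d$chrom, d$strand, d$acceptor_start, sep = "\r")
  don_key <- function(d) paste(d$chrom, d$strand, d$donor_end, sep = "\r")
  l5 <- tapply(lin$n_reads, acc_key(lin), sum)
  l3 <- tapply(lin$n_reads, don_key(lin), sum)
  lin5 <- unname(l5[acc_key(bs)]); lin5[is.na(lin5)] <- 0
  lin3 <- unname(l3[don_key(bs)]); lin3[is.na(lin3)] <- 0
  bs$cr5 <- circular_ratio(bs$n_reads, lin5)
  bs$cr3 <- circular_ratio(bs$n_reads, lin3)
  rownames(bs) <- NULL
  bs
}

#' Assemble per-sample circRNA records
#'
#' Turns a junction-calling result into one record per back-splice
#' junction with SRPBM (from raw spanning-read counts and the sample's
#' own mapped-read total) and boundary circular ratios. `category` and
#' `host_gene` are filled by [annotate_circs()].
#'
#' @param called result of [call_junctions()].
#' @param read_length read length used for SRPBM (default 100).
#' @param sample_id optional sample label.
#' @return `data.frame` of circRNA records (`chrom`, `start`, `end`,
#'   `strand`, `circ_id`, `n_reads`, `n_unique_reads`, `srpbm`, `cr5`,
#'   `cr3`, `category`, `host_gene`, `sample_id`).
#' @export
quantify_circs <- function(called, read_length = 100L, sample_id = NA_character_) {
  bs <- compute_cr_ends(called$junctions)
  n_mapped <- called$summary$n_mapped_reads
  out <- data.frame(
    chrom = bs$chrom, start = bs$acceptor_start, end = bs$donor_end,
    strand = bs$strand,
    circ_id = sprintf("circ_%s_%d_%d_%s", bs$chrom, bs$acceptor_start,
                      bs$donor_end, bs$strand),
    n_reads = bs$n_reads, n_unique_reads = bs$n_unique,
    srpbm = if (nrow(bs)) srpbm(bs$n_reads, n_mapped, read_length) else numeric(0),
    cr5 = bs$cr5, cr3 = bs$cr3,
    category = rep(NA_character_, nrow(bs)),
    host_gene = rep(NA_character_, nrow(bs)),
    sample_id = rep(sample_id, nrow(bs)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' High-abundance circRNA screen
#'
#' Keeps circRNAs whose boundary circular ratios and SRPBM clear strict
#' thresholds (defaults 0.2 and 1). Mode `"both"` demands both boundary
#' ratios exceed `cr_min`; mode `"max"` takes the maximum of the two
#' ratios as representative. Records with a missing CR fail the screen in
#' `"both"` mode (the screen demands positive evidence); in `"max"` mode
#' a single observed boundary suffices.
#'
#' @param records circRNA records carrying `cr5`, `cr3`, `srpbm`.
#' @param cr_min circular-ratio threshold (strict, default 0.2).
#' @param srpbm_min SRPBM threshold (strict, default 1).
#' @param mode `"both"` (default) or `"max"`.
#' @return the qualifying subset of `records`.
#' @export
high_abundance_screen <- function(records, cr_min = 0.2, srpbm_min = 1.0,
                                  mode = c("both", "max")) {
  mode <- match.arg(mode)
  if (mode == "both") {
    ok <- !is.na(records$cr5) & !is.na(records$cr3) &
      records$cr5 > cr_min & records$cr3 > cr_min
  } else {
    crmax <- pmax(records$cr5, records$cr3, na.rm = TRUE)
    crmax[is.na(records$cr5) & is.na(records$cr3)] <- NA_real_
    ok <- !is.na(crmax) & crmax > cr_min
  }
  out <- records[ok & records$srpbm > srpbm_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag the predominant circRNA isoform per host gene
#'
#' Within each host gene producing at least two circRNAs, the top
#' circRNA by SRPBM is predominant when its SRPBM is at least `fold`
#' times the second highest. Genes with a single circRNA are excluded.
#'
#' @param records circRNA records with `host_gene` and `srpbm`.
#' @param fold fold-change requirement (default 2).
#' @return `data.frame` per multi-circRNA gene: `host_gene`, `n_circ`,
#'   `top_circ_id`, `top_srpbm`, `second_srpbm`, `predominant`.
#' @export
predominant_isoform <- function(records, fold = 2.0) {
  r <- records[!is.na(records$host_gene), , drop = FALSE]
  res <- lapply(split(r, r$host_gene), function(g) {
    if (nrow(g) < 2L) return(NULL)
    o <- order(-g$srpbm, g$circ_id)
    data.frame(host_gene = g$host_gene[1], n_circ = nrow(g),
               top_circ_id = g$circ_id[o[1]], top_srpbm = g$srpbm[o[1]],
               second_srpbm = g$srpbm[o[2]],
               predominant = g$srpbm[o[1]] >= fold * g$srpbm[o[2]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(host_gene = character(0), n_circ = integer(0),
                      top_circ_id = character(0), top_srpbm = numeric(0),
                      second_srpbm = numeric(0), predominant = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Build an SRPBM expression matrix from per-sample records
#'
#' @param record_list list of [quantify_circs()] outputs (one per sample),
#'   each with a distinct `sample_id`.
#' @return numeric matrix, rows = circ_id, columns = sample_id.
#' @export
expression_matrix <- function(record_list) {
  all <- do.call(rbind, record_list)
  ids <- sort(unique(all$circ_id))
  samples <- unique(all$sample_id)
  if (anyNA(samples)) stop_validation("records need sample_id for a matrix")
  m <- matrix(0, length(ids), length(samples),
              dimnames = list(ids, samples))
  m[cbind(match(all$circ_id, ids), match(all$sample_id, samples))] <- all$srpbm
  m
}
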