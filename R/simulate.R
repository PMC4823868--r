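#' Simulation configuration
#'
#' Parameters of the synthetic genome/read generator. The defaults define
#' the package's reference scene: a 5 Mb genome (5 chromosomes of 1 Mb)
#' carrying 200 multi-exon genes of which a fifth circularize one
#' internal exon at a circular fraction drawn from `[0.2, 0.9]`,
#' sequenced to 200,000 error-free 100-nt single-end reads — the scale of
#' a desk-size ribominus RNA-seq experiment with known ground truth.
#' Paired-end mates would be processed as independent reads, so the
#' simulator emits single-end reads directly.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in nt.
#' @param n_genes number of genes (one transcript each).
#' @param exons_per_gene integer range of exon counts (min 3 for genes
#'   that circularize, so the circularized exon is internal).
#' @param exon_length integer range of exon lengths (nt).
#' @param intron_length integer range of intron lengths (nt, >= 4 so
#'   every intron can carry GT..AG).
#' @param intergenic integer range of intergenic gap lengths (nt).
#' @param circ_gene_fraction fraction of genes with a circularized exon.
#' @param circ_fraction range of the circular fraction `f` (circular
#'   molecules over all molecules at the locus).
#' @param circ_exons integer range of the number of consecutive exons per
#'   circle (default a single exon).
#' @param expr_sigma log-normal sigma of per-gene expression.
#' @param read_length read length in nt (>= 40, i.e. two 20-nt anchors).
#' @param n_reads total reads to draw.
#' @param error_rate per-base substitution rate in `[0, 1)`.
#' @param planted_ir `NULL`, or `list(length =, identity =)` to plant a
#'   reverse-complementary segment pair in the flanking introns of every
#'   circularized exon.
#' @param seed RNG seed; one stream drawn in the order genome ->
#'   expression -> reads.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chroms = 5L, chrom_length = 1e6, n_genes = 200L,
                       exons_per_gene = c(3L, 8L), exon_length = c(150L, 400L),
                       intron_length = c(200L, 1500L), intergenic = c(200L, 2000L),
                       circ_gene_fraction = 0.2, circ_fraction = c(0.2, 0.9),
                       circ_exons = c(1L, 1L), expr_sigma = 1,
                       read_length = 100L, n_reads = 200000L, error_rate = 0,
                       planted_ir = NULL, seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), exons_per_gene = exons_per_gene,
              exon_length = exon_length, intron_length = intron_length,
              intergenic = intergenic, circ_gene_fraction = circ_gene_fraction,
              circ_fraction = circ_fraction, circ_exons = circ_exons,
              expr_sigma = expr_sigma, read_length = as.integer(read_length),
              n_reads = as.integer(n_reads), error_rate = error_rate,
              planted_ir = planted_ir, seed = seed)
  if (cfg$read_length < 40L) stop_config("read_length must be >= 40 (two 20-nt anchors)")
  if (cfg$intron_length[1] < 4L) stop_config("intron_length must be >= 4")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) stop_config("error_rate must be in [0, 1)")
  if (cfg$circ_gene_fraction < 0 || cfg$circ_gene_fraction > 1) {
    stop_config("circ_gene_fraction must be in [0, 1]")
  }
  if (max(cfg$exon_length) < cfg$read_length && cfg$circ_gene_fraction > 0) {
    stop_config("exon_length range cannot accommodate a circularized exon >= read_length")
  }
  if (!is.null(cfg$planted_ir)) {
    if (max(cfg$intron_length) < cfg$planted_ir$length + 4L) {
      stop_config("intron_length range too short for the planted repeat")
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# A back-splice junction [A, D) is shift-ambiguous when the same reads
# admit a second zero-mismatch GT/AG (or CT/AC) interpretation at
# [A-d, D-d) or [A+d, D+d): the d boundary-adjacent bases repeat on both
# sides and the shifted breakpoints also carry splice motifs. Such a
# context makes the truth coordinates unidentifiable from reads (any
# caller must guess), so the generator breaks each one by rewriting a
# single base of the shifted motif, preferring a position outside every
# true splice signal. Shifts 1-3 are impossible (the motifs would have
# to overlap incompatibly); splits live >= anchor_len from the read
# ends, so shifts beyond read_length are irrelevant.
deambiguate_circle <- function(ch, A, D, prev_end, next_start,
                               max_shift = 60L) {
  protected <- c(prev_end + 1L, prev_end + 2L, A - 1L, A,
                 D + 1L, D + 2L, next_start - 1L, next_start)
  motifs <- list(c("A", "G", "G", "T"), c("A", "C", "C", "T"))
  flip_first <- c(A = "C", C = "A", G = "A", T = "C")  # breaks AG/AC/GT/CT
  repeat {
    changed <- FALSE
    for (d in 4:max_shift) {
      # leftward shift: acceptor A-d, donor D-d
      if (A - d - 1L >= 1L && all(ch[(A - d + 1L):A] == ch[(D - d + 1L):D])) {
        for (m in motifs) {
          if (all(ch[(A - d - 1L):(A - d)] == m[1:2]) &&
              all(ch[(D - d + 1L):(D - d + 2L)] == m[3:4])) {
            p <- if (!(A - d - 1L) %in% protected) A - d - 1L else D - d + 1L
            ch[p] <- flip_first[[ch[p]]]
            changed <- TRUE
          }
        }
      }
      # rightward shift: acceptor A+d, donor D+d
      if (D + d + 2L <= length(ch) && all(ch[(A + 1L):(A + d)] == ch[(D + 1L):(D + d)])) {
        for (m in motifs) {
          if (all(ch[(A + d - 1L):(A + d)] == m[1:2]) &&
              all(ch[(D + d + 1L):(D + d + 2L)] == m[3:4])) {
            p <- if (!(D + d + 1L) %in% protected) D + d + 1L else A + d - 1L
            ch[p] <- flip_first[[ch[p]]]
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  ch
}

# Mutate a sequence to a target per-base identity (substitutions only).
mutate_to_identity <- function(seq, identity) {
  n <- nchar(seq)
  n_sub <- round((1 - identity) * n)
  if (n_sub == 0L) return(seq)
  pos <- sample.int(n, n_sub)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic genome with gene models and circle ground truth
#'
#' Lays non-overlapping genes onto random-sequence chromosomes. Every
#' intron carries canonical splice dinucleotides on its gene's strand (GT
#' ..AG, appearing as CT..AC on the forward sequence of minus-strand
#' genes). A configured fraction of genes designates one internal exon
#' (or run of exons, each >= read_length so single-exon circles can carry
#' junction-spanning reads) as circularized with a drawn circular
#' fraction `f`. Optionally a reverse-complementary segment pair of
#' configured length and identity is planted in the two flanking introns
#' of every circle.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default the config's; `NULL` continues the
#'   current stream).
#' @return list with `genome` (named character vector), `annotation`
#'   (exon table) and `truth` (circle skeleton: `circ_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `true_f`, `exon_from`, `exon_to`,
#'   `circle_length`, `flank_up_len`, `flank_down_len`).
#' @export
generate_genome <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  n_circ <- round(cfg$circ_gene_fraction * cfg$n_genes)
  circ_genes <- if (n_circ > 0) sort(sample.int(cfg$n_genes, n_circ)) else integer(0)
  gene_chrom <- rep(seq_len(cfg$n_chroms), length.out = cfg$n_genes)

  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chroms <- lapply(seq_len(cfg$n_chroms), function(i) {
    sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
  })
  cursor <- rep(0L, cfg$n_chroms)

  ann <- vector("list", cfg$n_genes)
  truth <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    ci <- gene_chrom[g]
    is_circ <- g %in% circ_genes
    strand <- sample(c("+", "-"), 1L)
    k_lo <- if (is_circ) max(3L, cfg$exons_per_gene[1]) else cfg$exons_per_gene[1]
    k <- draw_range(1L, c(k_lo, max(k_lo, cfg$exons_per_gene[2])))
    exon_len <- draw_range(k, cfg$exon_length)
    intron_len <- if (k > 1L) draw_range(k - 1L, cfg$intron_length) else integer(0)

    ef <- et <- NA_integer_
    if (is_circ) {
      run <- min(draw_range(1L, cfg$circ_exons), k - 2L)
      ef <- if (k - 1L - run >= 2L) sample(2:(k - run), 1L) else 2L
      et <- ef + run - 1L
      # circularized exons must fit a full read
      lo <- max(cfg$exon_length[1], cfg$read_length)
      if (cfg$exon_length[2] < lo) stop_config("exon_length cannot fit read_length")
      exon_len[ef:et] <- draw_range(et - ef + 1L, c(lo, cfg$exon_length[2]))
      if (!is.null(cfg$planted_ir)) {
        lo_i <- cfg$planted_ir$length + 6L
        if (cfg$intron_length[2] < lo_i) stop_config("introns too short for planted repeat")
        intron_len[c(ef - 1L, et)] <- draw_range(2L, c(max(cfg$intron_length[1], lo_i),
                                                       cfg$intron_length[2]))
      }
    }

    gap <- draw_range(1L, cfg$intergenic)
    span <- sum(exon_len) + sum(intron_len)
    if (cursor[ci] + gap + span > cfg$chrom_length) {
      stop_config("chromosome %s too short for gene %d (need %d more nt)",
                  chrom_names[ci], g, cursor[ci] + gap + span - cfg$chrom_length)
    }
    gstart <- cursor[ci] + gap   # 0-based gene start
    cursor[ci] <- gstart + span

    # exon coordinates (geometric order along the forward strand)
    starts <- integer(k); ends <- integer(k)
    p <- gstart
    for (e in seq_len(k)) {
      starts[e] <- p
      ends[e] <- p + exon_len[e]
      p <- ends[e] + if (e < k) intron_len[e] else 0L
    }
    # splice dinucleotides on the gene's strand
    ch <- chroms[[ci]]
    for (e in seq_len(k - 1L)) {
      s <- ends[e]; e2 <- starts[e + 1L]      # intron [s, e2)
      if (strand == "+") {
        ch[(s + 1L):(s + 2L)] <- c("G", "T")
        ch[(e2 - 1L):e2] <- c("A", "G")
      } else {
        ch[(s + 1L):(s + 2L)] <- c("C", "T")
        ch[(e2 - 1L):e2] <- c("A", "C")
      }
    }
    # plant an inverted repeat in the two flanking introns of the circle
    if (is_circ && !is.null(cfg$planted_ir)) {
      L <- cfg$planted_ir$length
      up_s <- ends[ef - 1L]; up_e <- starts[ef]       # upstream intron
      dn_s <- ends[et]; dn_e <- starts[et + 1L]       # downstream intron
      u0 <- up_s + 3L  # keep clear of the splice dinucleotides
      seg <- paste(ch[(u0 + 1L):(u0 + L)], collapse = "")
      d0 <- dn_s + 3L
      planted <- mutate_to_identity(revcomp(seg), cfg$planted_ir$identity)
      ch[(d0 + 1L):(d0 + L)] <- strsplit(planted, "")[[1]]
    }
    if (is_circ) {
      ch <- deambiguate_circle(ch, starts[ef], ends[et],
                               ends[ef - 1L], starts[et + 1L])
    }
    chroms[[ci]] <- ch

    gid <- sprintf("g%04d", g)
    ann[[g]] <- data.frame(
      gene_id = gid, transcript_id = sprintf("t%04d", g),
      chrom = chrom_names[ci], start = starts, end = ends, strand = strand,
      exon_number = if (strand == "+") seq_len(k) else rev(seq_len(k)),
      biotype = "coding", stringsAsFactors = FALSE)
    if (is_circ) {
      truth[[g]] <- data.frame(
        circ_id = sprintf("circ_%s_%d_%d_%s", chrom_names[ci], starts[ef],
                          ends[et], strand),
        gene_id = gid, chrom = chrom_names[ci],
        start = starts[ef], end = ends[et], strand = strand,
        true_f = draw_range(1L, cfg$circ_fraction),
        exon_from = ef, exon_to = et,
        circle_length = sum(exon_len[ef:et]),
        flank_up_len = intron_len[ef - 1L], flank_down_len = intron_len[et],
        stringsAsFactors = FALSE)
    }
  }
  genome <- vapply(chroms, paste, "", collapse = "")
  names(genome) <- chrom_names
  truth_df <- do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
  if (is.null(truth_df)) {
    truth_df <- data.frame(circ_id = character(0), gene_id = character(0),
                           chrom = character(0), start = integer(0),
                           end = integer(0), strand = character(0),
                           true_f = numeric(0), exon_from = integer(0),
                           exon_to = integer(0), circle_length = integer(0),
                           flank_up_len = integer(0), flank_down_len = integer(0),
                           stringsAsFactors = FALSE)
  }
  list(genome = genome, annotation = do.call(rbind, ann), truth = truth_df)
}

# Junction positions (RNA coordinates) of a spliced sequence assembled
# from geometric exon lengths; for '-' transcripts the RNA is the reverse
# complement, so junctions mirror.
rna_junctions <- function(exon_len, strand) {
  if (length(exon_len) < 2L) return(numeric(0))
  b <- cumsum(exon_len)[-length(exon_len)]
  if (strand == "+") b else sum(exon_len) - rev(b)
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in sample.int(length(ch), n_err[i])) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate reads from a synthetic genome, with ground truth
#'
#' Assembles each gene's linear transcript (exon concatenation, reverse
#' complemented for minus-strand genes) and, for circularized loci, the
#' circle transcript. Per-gene molecule abundance is log-normal; at a
#' circle locus a fraction `f` of molecules is circular. Reads start
#' uniformly along molecules (on circles the start wraps across the
#' back-splice junction), are emitted in either orientation with equal
#' probability, and carry i.i.d. substitution errors. Ground truth
#' tallies, per circle, the reads that genuinely span the back-splice
#' junction and the two boundary linear junctions — both by >= 1 nt on
#' each side and in "callable" form (>= anchor_len nt on each side and
#' crossing no other junction, the geometry the junction caller can
#' recover), callable back-splice support also as distinct sequences.
#'
#' @param genome,annotation,truth output of [generate_genome()].
#' @param config the same [sim_config()].
#' @param seed RNG seed (`NULL` continues the current stream).
#' @param anchor_len anchor length used for the callable tallies.
#' @return list with
#'   * `reads`: list(`id`, `seq`, `qual`);
#'   * `truth`: the skeleton plus columns `bs_reads`, `bs_callable`,
#'     `bs_unique_callable`, `lin5_reads`, `lin3_reads`, `lin5_callable`,
#'     `lin3_callable`;
#'   * `read_log`: per-read provenance (`gene_id`, `molecule`
#'     ("linear"/"circle"), `start` (1-based RNA coordinate), `flipped`).
#' @export
simulate_reads <- function(genome, annotation, truth, config,
                           seed = NULL, anchor_len = 20L) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  R <- cfg$read_length
  genome <- as_genome_chars(genome)

  genes <- unique(annotation$gene_id)
  n_genes <- length(genes)
  abundance <- rlnorm(n_genes, 0, cfg$expr_sigma)
  names(abundance) <- genes

  ann_sorted <- annotation[order(annotation$start), , drop = FALSE]
  ann_by_gene <- split(ann_sorted, ann_sorted$gene_id)
  truth_by_gene <- if (nrow(truth)) split(truth, truth$gene_id) else list()

  # one entry per molecule species (linear transcript or circle)
  species <- list()
  for (g in genes) {
    ex <- ann_by_gene[[g]]
    strand <- ex$strand[1]
    fwd <- paste(substring(genome[[ex$chrom[1]]], ex$start + 1L, ex$end),
                 collapse = "")
    rna <- if (strand == "+") fwd else revcomp(fwd)
    tr <- truth_by_gene[[g]]
    f <- if (!is.null(tr)) tr$true_f[1] else 0
    a <- abundance[[g]]
    Tlen <- nchar(rna)
    if (Tlen >= R) {
      species[[length(species) + 1L]] <- list(
        gene = g, kind = "linear", seq = rna, len = Tlen,
        weight = a * (1 - f) * (Tlen - R + 1L),
        exon_len = ex$end - ex$start, strand = strand)
    }
    if (!is.null(tr)) {
      ef <- tr$exon_from[1]; et <- tr$exon_to[1]
      cfwd <- paste(substring(genome[[ex$chrom[1]]], ex$start[ef:et] + 1L,
                              ex$end[ef:et]), collapse = "")
      crna <- if (strand == "+") cfwd else revcomp(cfwd)
      C <- nchar(crna)
      if (C < R) stop_config("circle %s shorter than read_length", tr$circ_id[1])
      species[[length(species) + 1L]] <- list(
        gene = g, kind = "circle", seq = crna, len = C,
        weight = a * f * C,
        exon_len = (ex$end - ex$start)[ef:et], strand = strand)
    }
  }
  w <- vapply(species, `[[`, 0, "weight")
  if (all(w <= 0)) stop_config("no expressible molecules")
  counts <- as.vector(stats::rmultinom(1L, cfg$n_reads, w))

  seq_out <- vector("list", length(species))
  log_out <- vector("list", length(species))
  for (i in seq_along(species)) {
    m <- counts[i]
    if (m == 0L) next
    sp <- species[[i]]
    if (sp$kind == "linear") {
      starts <- sample.int(sp$len - R + 1L, m, replace = TRUE)
      seqs <- substring(sp$seq, starts, starts + R - 1L)
    } else {
      starts <- sample.int(sp$len, m, replace = TRUE)
      doubled <- paste0(sp$seq, substr(sp$seq, 1L, R - 1L))
      seqs <- substring(doubled, starts, starts + R - 1L)
    }
    flip <- runif(m) < 0.5
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    seq_out[[i]] <- seqs
    log_out[[i]] <- data.frame(gene_id = sp$gene, molecule = sp$kind,
                               start = starts, flipped = flip,
                               stringsAsFactors = FALSE)
  }
  seqs <- unlist(seq_out)
  if (is.null(seqs)) seqs <- character(0)
  seqs <- apply_errors(seqs, cfg$error_rate)
  read_log <- do.call(rbind, log_out)
  if (is.null(read_log)) {
    read_log <- data.frame(gene_id = character(0), molecule = character(0),
                           start = integer(0), flipped = logical(0))
  }
  ids <- sprintf("r%07d", seq_along(seqs))
  read_log$id <- ids
  rownames(read_log) <- NULL

  # ground-truth junction tallies
  zero <- rep(0L, nrow(truth))
  truth$bs_reads <- truth$bs_callable <- truth$bs_unique_callable <- zero
  truth$lin5_reads <- truth$lin3_reads <- zero
  truth$lin5_callable <- truth$lin3_callable <- zero
  if (nrow(truth)) {
    for (r in seq_len(nrow(truth))) {
      g <- truth$gene_id[r]
      ex <- ann_by_gene[[g]]
      strand <- ex$strand[1]
      ef <- truth$exon_from[r]; et <- truth$exon_to[r]
      exon_len <- ex$end - ex$start
      C <- truth$circle_length[r]

      sel_c <- which(read_log$gene_id == g & read_log$molecule == "circle")
      if (length(sel_c)) {
        u <- read_log$start[sel_c]
        before <- C - u + 1L            # nt before the wrap junction
        spans <- before >= 1L & before <= R - 1L
        # RNA-order exon lengths of the circle
        clens <- if (strand == "+") exon_len[ef:et] else rev(exon_len[ef:et])
        callable <- spans & before >= anchor_len & before <= R - anchor_len &
          before <= clens[length(clens)] & (R - before) <= clens[1L]
        truth$bs_reads[r] <- sum(spans)
        truth$bs_callable[r] <- sum(callable)
        truth$bs_unique_callable[r] <- length(unique(seqs[sel_c][callable]))
      }
      # boundary linear junctions on the linear transcript (RNA coords)
      sel_l <- which(read_log$gene_id == g & read_log$molecule == "linear")
      if (length(sel_l)) {
        v <- read_log$start[sel_l]
        Tlen <- sum(exon_len)
        jall <- sort(rna_junctions(exon_len, strand))
        bL <- sum(exon_len[seq_len(ef - 1L)])        # geometric left boundary
        bR <- sum(exon_len[seq_len(et)])             # geometric right boundary
        jL <- if (strand == "+") bL else Tlen - bL
        jR <- if (strand == "+") bR else Tlen - bR
        tally <- function(j) {
          prev <- max(c(0, jall[jall < j]))
          nxt <- min(c(Tlen, jall[jall > j]))
          before <- j - v + 1L
          spans <- before >= 1L & before <= R - 1L
          callable <- spans & before >= anchor_len & before <= R - anchor_len &
            before <= (j - prev) & (R - before) <= (nxt - j)
          c(sum(spans), sum(callable))
        }
        tL <- tally(jL); tR <- tally(jR)
        truth$lin5_reads[r] <- tL[1]; truth$lin5_callable[r] <- tL[2]
        truth$lin3_reads[r] <- tR[1]; truth$lin3_callable[r] <- tR[2]
      }
    }
  }
  list(reads = list(id = ids, seq = seqs,
                    qual = rep(strrep("I", R), length(seqs))),
       truth = truth, read_log = read_log)
}

#' Generate a complete synthetic dataset
#'
#' Seeds one RNG stream and draws, in order, the genome, the per-gene
#' expression and the reads.
#'
#' @param config a [sim_config()].
#' @param seed overrides the config's seed.
#' @return list merging [generate_genome()] and [simulate_reads()]
#'   output: `genome`, `annotation`, `truth`, `reads`, `read_log`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  set.seed(seed)
  gg <- generate_genome(config, seed = NULL)
  sim <- simulate_reads(gg$genome, gg$annotation, gg$truth, config, seed = NULL)
  list(genome = gg$genome, annotation = gg$annotation, truth = sim$truth,
       reads = sim$reads, read_log = sim$read_log)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `models.gtf`, `reads.fastq` and `truth.tsv` under
#' `dir`.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$genome, file.path(dir, "genome.fa"))
  write_gtf(dataset$annotation, file.path(dir, "models.gtf"))
  write_fastq(dataset$reads, file.path(dir, "reads.fastq"))
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
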