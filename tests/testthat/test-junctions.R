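test_that("split_anchors tiles the read ends and signals short reads", {
  r100 <- rand_dna(100)
  a <- split_anchors(r100)
  expect_equal(a$left, substr(r100, 1, 20))
  expect_equal(a$right, substr(r100, 81, 100))

  r40 <- rand_dna(40)
  a40 <- split_anchors(r40)
  expect_equal(paste0(a40$left, a40$right), r40)

  expect_null(split_anchors(rand_dna(39)))
})

test_that("a head-to-tail read across an AG|exon|GT context is a back-splice", {
  for (strand in c("+", "-")) {
    fx <- genome_with_circle(exon_len = 200, strand = strand, seed = 77)
    exon_rna <- if (strand == "+") fx$exon else revcomp(fx$exon)
    read <- paste0(substr(exon_rna, 151, 200), substr(exon_rna, 1, 50))
    idx <- build_index(fx$genome)
    anch <- split_anchors(read)
    hl <- map_anchor(anch$left, idx)
    hr <- map_anchor(anch$right, idx)
    expect_equal(nrow(hl), 1)
    expect_equal(nrow(hr), 1)
    call <- resolve_breakpoint(read, hl[1, ], hr[1, ], idx)
    expect_equal(nrow(call), 1)
    expect_equal(call$jtype, "backsplice")
    expect_equal(call$strand, strand)
    expect_equal(call$acceptor_start, fx$start)
    expect_equal(call$donor_end, fx$end)
    expect_equal(call$n_mismatches, 0)
  }
})

test_that("breakpoint resolution matches a brute-force split enumeration", {
  fx <- genome_with_circle(exon_len = 180, strand = "+", seed = 33)
  read <- paste0(substr(fx$exon, 121, 180), substr(fx$exon, 1, 40))
  idx <- build_index(fx$genome)
  anch <- split_anchors(read)
  hl <- map_anchor(anch$left, idx)
  hr <- map_anchor(anch$right, idx)
  calls <- resolve_breakpoint(read, hl[1, ], hr[1, ], idx,
                              all_candidates = TRUE)
  calls <- calls[calls$jtype == "backsplice" & calls$strand == "+", ,
                 drop = FALSE]
  # oracle: try every split of the read at both placements
  g <- fx$genome[[1]]
  found <- NULL
  for (s in 20:80) {
    pref <- substr(read, 1, s)
    suff <- substr(read, s + 1, 100)
    b1 <- hl$pos + s
    b2 <- hr$pos + 20 - (100 - s)
    mm <- count_mismatch_str(pref, substr(g, hl$pos + 1, hl$pos + s)) +
      count_mismatch_str(suff, substr(g, b2 + 1, b2 + (100 - s)))
    if (mm > 2) next
    if (b1 - b2 < 1) next
    if (substr(g, b1 + 1, b1 + 2) == "GT" && substr(g, b2 - 1, b2) == "AG") {
      found <- rbind(found, data.frame(acceptor_start = b2, donor_end = b1,
                                       n_mismatches = mm))
    }
  }
  expect_equal(nrow(calls), nrow(found))
  expect_setequal(paste(calls$acceptor_start, calls$donor_end),
                  paste(found$acceptor_start, found$donor_end))
})

test_that("a canonical exon1|exon2 read is a linear junction call", {
  set.seed(55)
  e1 <- rand_dna(300); e2 <- rand_dna(300); intr <- rand_dna(200)
  substr(intr, 1, 2) <- "GT"
  substr(intr, 199, 200) <- "AG"
  g <- c(chr1 = paste0(rand_dna(150), e1, intr, e2, rand_dna(150)))
  read <- paste0(substr(e1, 251, 300), substr(e2, 1, 50))
  idx <- build_index(g)
  res <- call_junctions(read, idx)
  lin <- res$junctions
  expect_equal(nrow(lin), 1)
  expect_equal(lin$jtype, "linear")
  expect_equal(lin$donor_end, 150 + 300)          # end of exon1
  expect_equal(lin$acceptor_start, 150 + 300 + 200)  # start of exon2

  # mutate the donor dinucleotide: no call at all
  g2 <- g
  substr(g2[[1]], 451, 452) <- "GG"
  idx2 <- build_index(g2)
  res2 <- call_junctions(read, idx2)
  expect_equal(nrow(res2$junctions), 0)
})

test_that("duplicate read sequences collapse to one unique read", {
  fx <- genome_with_circle(exon_len = 200, strand = "+", seed = 21)
  read <- paste0(substr(fx$exon, 151, 200), substr(fx$exon, 1, 50))
  idx <- build_index(fx$genome)
  res <- call_junctions(c(read, read, read), idx,
                        junction_params(min_unique_backsplice = 1))
  bs <- res$junctions[res$junctions$jtype == "backsplice", ]
  expect_equal(bs$n_reads, 3)
  expect_equal(bs$n_unique, 1)

  # under the default evidence threshold the same input yields no call
  res2 <- call_junctions(c(read, read, read), idx)
  expect_equal(nrow(res2$junctions), 0)
})

test_that("the caller recovers every adequately covered simulated circle", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 250000, n_genes = 20,
                    exons_per_gene = c(3, 6), exon_length = c(150, 350),
                    intron_length = c(100, 500), circ_gene_fraction = 0.4,
                    circ_fraction = c(0.5, 0.5), n_reads = 50000,
                    seed = 1)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$truth), 8)
  idx <- build_index(ds$genome)
  res <- call_junctions(ds$reads, idx)
  bs <- res$junctions[res$junctions$jtype == "backsplice", ]
  called <- paste(bs$chrom, bs$strand, bs$acceptor_start, bs$donor_end)
  truth_all <- paste(ds$truth$chrom, ds$truth$strand, ds$truth$start, ds$truth$end)
  eligible <- ds$truth$bs_unique_callable >= 2
  expect_true(all(truth_all[eligible] %in% called))    # recall, coordinates exact
  expect_true(all(called %in% truth_all))              # precision
  m <- merge(ds$truth, bs,
             by.x = c("chrom", "strand", "start", "end"),
             by.y = c("chrom", "strand", "acceptor_start", "donor_end"))
  expect_equal(m$n_reads, m$bs_callable)
  expect_equal(m$n_unique, m$bs_unique_callable)
})

test_that("calls are invariant under read input order", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 100000, n_genes = 8,
                    exons_per_gene = c(3, 4), exon_length = c(150, 250),
                    intron_length = c(80, 300), circ_gene_fraction = 0.5,
                    n_reads = 10000, seed = 6)
  ds <- simulate_dataset(cfg)
  idx <- build_index(ds$genome)
  a <- call_junctions(ds$reads, idx)
  set.seed(99)
  perm <- sample(length(ds$reads$seq))
  b <- call_junctions(ds$reads$seq[perm], idx)
  expect_equal(a$junctions, b$junctions)
  expect_equal(a$summary, b$summary)
})

test_that("every reported call re-validates against the genome", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 100000, n_genes = 8,
                    exons_per_gene = c(3, 4), exon_length = c(150, 250),
                    intron_length = c(80, 300), circ_gene_fraction = 0.5,
                    n_reads = 10000, error_rate = 0.002, seed = 14)
  ds <- simulate_dataset(cfg)
  idx <- build_index(ds$genome)
  res <- call_junctions(ds$reads, idx)
  g <- ds$genome[[1]]
  j <- res$junctions
  expect_gt(nrow(j), 0)
  for (i in seq_len(nrow(j))) {
    right <- substr(g, j$donor_end[i] + 1, j$donor_end[i] + 2)
    left <- substr(g, j$acceptor_start[i] - 1, j$acceptor_start[i])
    if (j$strand[i] == "+") {
      expect_equal(right, "GT")
      expect_equal(left, "AG")
    } else {
      expect_equal(right, "CT")
      expect_equal(left, "AC")
    }
    if (j$jtype[i] == "backsplice") {
      expect_lt(j$acceptor_start[i], j$donor_end[i])
    } else {
      expect_lte(j$donor_end[i], j$acceptor_start[i])
    }
  }
})

test_that("an empty read set yields an empty table", {
  fx <- genome_with_circle(seed = 2)
  idx <- build_index(fx$genome)
  res <- call_junctions(character(0), idx)
  expect_equal(nrow(res$junctions), 0)
  expect_equal(res$summary$n_total, 0)
})
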