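test_that("host genes are assigned by exact boundary matching", {
  ann <- toy_annotation()
  # exactly exon 2 of tA1/tA2 (shared): single-exon fragment
  circ <- list(chrom = "chr1", start = 300, end = 400, strand = "+")
  asg <- assign_host_gene(circ, ann)
  expect_equal(asg$gene_id, "gA")
  expect_equal(asg$spliced_length, 100)
  expect_equal(asg$transcript_id, "tA1")  # equal fragments: smallest id

  # both transcripts match exons 2..3 but tA2's fragment is longer
  circ2 <- list(chrom = "chr1", start = 300, end = 900, strand = "+")
  asg2 <- assign_host_gene(circ2, ann)
  expect_equal(asg2$transcript_id, "tA2")
  expect_equal(asg2$spliced_length, 100 + 400)

  # start matches but no exon end does: unassigned
  circ3 <- list(chrom = "chr1", start = 300, end = 410, strand = "+")
  expect_true(is.na(assign_host_gene(circ3, ann)$gene_id))

  # wrong strand: unassigned
  circ4 <- list(chrom = "chr1", start = 300, end = 400, strand = "-")
  expect_true(is.na(assign_host_gene(circ4, ann)$gene_id))
})

test_that("host assignment ignores transcript input order", {
  ann <- toy_annotation()
  circ <- list(chrom = "chr1", start = 300, end = 900, strand = "+")
  set.seed(3)
  for (i in 1:5) {
    shuffled <- ann[sample(nrow(ann)), ]
    expect_equal(assign_host_gene(circ, shuffled)$transcript_id, "tA2")
  }
})

test_that("spliced length sums matched exons and excludes introns", {
  ann <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                    start = c(1000, 7000), end = c(1200, 7300),
                    strand = "+", exon_number = 1:2, biotype = "coding",
                    stringsAsFactors = FALSE)
  circ <- list(chrom = "chr1", start = 1000, end = 7300, strand = "+")
  expect_equal(spliced_length(circ, ann, "t"), 500)   # 200 + 300, 5.8 kb intron out

  ann2 <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                     start = 500, end = 1599, strand = "+", exon_number = 1,
                     biotype = "coding", stringsAsFactors = FALSE)
  circ2 <- list(chrom = "chr1", start = 500, end = 1599, strand = "+")
  expect_equal(spliced_length(circ2, ann2, "t"), 1099)

  expect_error(spliced_length(circ, ann2, "t"), class = "circscan_domain_error")
})

test_that("genomic-origin categories form the expected partition", {
  ann <- toy_annotation()
  expect_equal(classify_circ(list(chrom = "chr1", start = 300, end = 400,
                                  strand = "+"), ann), "coding-exonic")
  expect_equal(classify_circ(list(chrom = "chr1", start = 2000, end = 2150,
                                  strand = "-"), ann), "lncRNA")
  # wholly inside intron 1 of tA1, same strand
  expect_equal(classify_circ(list(chrom = "chr1", start = 210, end = 290,
                                  strand = "+"), ann), "intronic")
  # over gB but on the opposite strand
  expect_equal(classify_circ(list(chrom = "chr1", start = 2010, end = 2100,
                                  strand = "+"), ann), "antisense")
  expect_equal(classify_circ(list(chrom = "chr1", start = 5000, end = 5400,
                                  strand = "+"), ann), "unannotated")
})

test_that("classification is exhaustive over random intervals", {
  ann <- toy_annotation()
  set.seed(6)
  cats <- vapply(1:60, function(i) {
    s <- sample(0:5000, 1)
    classify_circ(list(chrom = "chr1", start = s,
                       end = s + sample(50:600, 1),
                       strand = sample(c("+", "-"), 1)), ann)
  }, "")
  expect_true(all(cats %in% c("coding-exonic", "lncRNA", "intronic",
                              "antisense", "unannotated")))
})

test_that("flanking introns follow transcript orientation", {
  ann <- toy_annotation()
  circ <- list(chrom = "chr1", start = 300, end = 400, strand = "+")
  asg <- assign_host_gene(circ, ann)
  fl <- flanking_introns(circ, asg, ann)
  expect_equal(fl$upstream$start, 200)
  expect_equal(fl$upstream$end, 300)
  expect_equal(fl$upstream$length, 100)
  expect_equal(fl$downstream$start, 400)
  expect_equal(fl$downstream$end, 500)

  # first exon: no upstream intron on a plus-strand host
  circ2 <- list(chrom = "chr1", start = 100, end = 200, strand = "+")
  asg2 <- assign_host_gene(circ2, ann)
  fl2 <- flanking_introns(circ2, asg2, ann)
  expect_null(fl2$upstream)
  expect_equal(fl2$downstream$length, 100)

  # minus-strand host: the genomically rightward intron is upstream
  circb <- list(chrom = "chr1", start = 2000, end = 2150, strand = "-")
  asgb <- assign_host_gene(circb, ann)
  flb <- flanking_introns(circb, asgb, ann)
  expect_equal(flb$upstream$start, 2150)
  expect_equal(flb$upstream$end, 2300)
  expect_null(flb$downstream)
})

test_that("an exact planted inverted repeat scores identity 1 over its length", {
  set.seed(41)
  seg <- rand_dna(269)
  hit <- best_inverted_repeat(seg, revcomp(seg))
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$length, 269L)
  expect_equal(hit$score, 269)
  expect_equal(unname(hit$upstream), c(0, 269))
  expect_equal(unname(hit$downstream), c(0, 269))

  # embedded in longer introns the exact copy is still found; the local
  # alignment may pick up a few lucky flanking matches beyond it
  up <- rand_dna(1000)
  seg2 <- substr(up, 301, 569)
  down <- paste0(rand_dna(400), revcomp(seg2), rand_dna(300))
  hit2 <- best_inverted_repeat(up, down)
  expect_gte(hit2$score, 269)
  expect_gte(hit2$identity, 0.97)
  expect_lte(hit2$length, 285)
  expect_lte(hit2$upstream["start"], 300)
  expect_gte(hit2$upstream["end"], 569)
  # the reported segments are mutually reverse-complementary up to the
  # few flanking columns
  dseg <- substr(down, hit2$downstream["start"] + 1, hit2$downstream["end"])
  useg <- substr(up, hit2$upstream["start"] + 1, hit2$upstream["end"])
  expect_true(grepl(seg2, useg, fixed = TRUE))
  expect_true(grepl(revcomp(seg2), dseg, fixed = TRUE))
})

test_that("a degraded planted repeat reports the planted identity regime", {
  set.seed(42)
  up <- rand_dna(1200)
  seg <- substr(up, 401, 669)
  rc <- revcomp(seg)
  n_mut <- round(0.17 * 269)
  pos <- sample(269, n_mut)
  ch <- strsplit(rc, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  down <- paste0(rand_dna(350), paste(ch, collapse = ""), rand_dna(350))
  hit <- best_inverted_repeat(up, down)
  expect_lt(abs(hit$identity - 0.83), 0.02)
  expect_lt(abs(hit$length - 269), 15)
})

test_that("alignment scores equal the independent dynamic-programming oracle", {
  set.seed(43)
  cases <- list(
    list(a = rand_dna(300), b = rand_dna(300)),
    list(a = rand_dna(2000), b = rand_dna(2000)))
  # planted mid-identity case
  up <- rand_dna(800)
  down <- paste0(rand_dna(200), revcomp(substr(up, 101, 400)), rand_dna(200))
  cases <- c(cases, list(list(a = up, b = down)))
  for (cs in cases) {
    hit <- best_inverted_repeat(cs$a, cs$b)
    oracle <- sw_oracle_score(cs$a, revcomp(cs$b))
    expect_equal(hit$score, oracle)
  }
})

test_that("inverted-repeat scoring is symmetric in its two introns", {
  set.seed(44)
  up <- rand_dna(600)
  down <- paste0(rand_dna(100), revcomp(substr(up, 201, 420)), rand_dna(80))
  h1 <- best_inverted_repeat(up, down)
  h2 <- best_inverted_repeat(down, up)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$identity, h2$identity)
  expect_equal(h1$length, h2$length)
})

test_that("random introns score far below a planted repeat", {
  set.seed(45)
  up <- rand_dna(1000)
  down <- rand_dna(1000)
  rnd <- best_inverted_repeat(up, down)
  planted <- best_inverted_repeat(
    up, paste0(rand_dna(300), revcomp(substr(up, 101, 369)), rand_dna(300)))
  expect_lt(rnd$score, planted$score / 3)
})

test_that("intron length contrast separates a tenfold planted effect", {
  set.seed(46)
  high <- rlnorm(30, log(10000), 0.3)
  other <- rlnorm(60, log(1000), 0.3)
  res <- intron_length_contrast(high, other)
  expect_lt(res$p.value, 0.01)
  expect_gt(res$median_high, res$median_other)

  same <- intron_length_contrast(other, other)
  expect_gt(same$p.value, 0.9)

  tiny <- intron_length_contrast(5000, c(400, 300))  # exact enumeration path
  expect_lte(tiny$p.value, 1)
  expect_gte(tiny$p.value, 0)

  expect_true(intron_length_contrast(numeric(0), other)$insufficient)
})

test_that("annotate_circs fills host, category and flank columns end to end", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 120000, n_genes = 10,
                    exons_per_gene = c(3, 5), exon_length = c(150, 300),
                    intron_length = c(80, 300), circ_gene_fraction = 0.5,
                    n_reads = 20000, seed = 7)
  ds <- simulate_dataset(cfg)
  idx <- build_index(ds$genome)
  res <- call_junctions(ds$reads, idx)
  q <- quantify_circs(res, read_length = cfg$read_length)
  ann <- annotate_circs(q, ds$annotation, ds$genome)
  expect_true(all(!is.na(ann$host_gene)))
  expect_true(all(ann$category == "coding-exonic"))
  m <- merge(ann, ds$truth, by = c("chrom", "start", "end", "strand"))
  expect_equal(m$flank_up_len.x,
               ifelse(m$strand == "+", m$flank_up_len.y, m$flank_down_len.y))
  expect_equal(m$spliced_length, m$circle_length)
})
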