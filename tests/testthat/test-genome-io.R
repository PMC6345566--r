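test_that("FASTA reading normalises case, joins lines and masks ambiguity", {
  p <- write_lines_tmp(c(">c1", "acgt"), ".fa")
  expect_equal(unclass(read_genome_fasta(p))[["c1"]], "ACGT")

  p <- write_lines_tmp(c(">c1", "AC", "GT"), ".fa")
  expect_equal(unclass(read_genome_fasta(p))[["c1"]], "ACGT")

  p <- write_lines_tmp(c(">c1", "ACRT"), ".fa")
  expect_equal(unclass(read_genome_fasta(p))[["c1"]], "ACNT")

  p <- write_lines_tmp(c(">c1", "ACGT", ">c1", "GGGG"), ".fa")
  expect_error(read_genome_fasta(p), "duplicate")

  p <- write_lines_tmp(character(0), ".fa")
  expect_error(read_genome_fasta(p))
})

test_that("genome_fetch is 0-based half-open and errors out of range", {
  g <- genome_seq(c(c1 = "ACGTACGT"))
  expect_equal(genome_fetch(g, "c1", 0, 4), "ACGT")
  expect_equal(nchar(genome_fetch(g, "c1", 2, 7)), 5L)
  expect_equal(genome_fetch(g, "c1", 0, 4, strand = "-"), "ACGT")
  expect_error(genome_fetch(g, "c1", 0, 9), "out-of-range")
  expect_error(genome_fetch(g, "c2", 0, 2), "absent")
})

test_that("GTF reading converts coordinates and derives the junction set", {
  gtf <- c(
    'c1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";')
  g <- read_annotation_gtf(write_lines_tmp(gtf, ".gtf"))
  expect_equal(nrow(g$junctions), 1L)
  expect_equal(g$junctions$start, 100L)
  expect_equal(g$junctions$end, 200L)

  gtf1 <- 'c1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  g1 <- read_annotation_gtf(write_lines_tmp(gtf1, ".gtf"))
  expect_equal(nrow(g1$junctions), 0L)
})

test_that("a junction shared by two transcripts appears once", {
  exons <- data.frame(
    gene_id = "g1",
    transcript_id = rep(c("t1", "t2"), each = 2L),
    chrom = "c1",
    start = c(0L, 200L, 50L, 200L),
    end = c(100L, 300L, 100L, 350L),
    strand = "+")
  g <- splice_graph(exons)
  # brute-force oracle: enumerate consecutive-exon pairs per transcript
  oracle <- unique(do.call(rbind, lapply(c("t1", "t2"), function(tid) {
    e <- exons[exons$transcript_id == tid, ]
    e <- e[order(e$start), ]
    data.frame(start = e$end[-nrow(e)], end = e$start[-1L])
  })))
  expect_equal(nrow(g$junctions), nrow(oracle))
  expect_equal(nrow(g$junctions), 1L)
})

test_that("splice_graph validates geometry", {
  bad <- data.frame(gene_id = "g", transcript_id = "t", chrom = "c1",
                    start = 10L, end = 10L, strand = "+")
  expect_error(splice_graph(bad), "end <= start")
  two_chrom <- data.frame(gene_id = "g", transcript_id = "t",
                          chrom = c("c1", "c2"),
                          start = c(0L, 200L), end = c(100L, 300L),
                          strand = "+")
  expect_error(splice_graph(two_chrom), "multiple chromosomes")
})

test_that("exon lengths plus intron lengths equal the genomic span", {
  g <- fixture_graph()
  for (tid in g$transcripts$transcript_id) {
    e <- g$exons[g$exons$transcript_id == tid, ]
    e <- e[order(e$start), ]
    exon_sum <- sum(e$end - e$start)
    intron_sum <- if (nrow(e) > 1L) sum(e$start[-1L] - e$end[-nrow(e)]) else 0L
    expect_equal(exon_sum + intron_sum, max(e$end) - min(e$start))
  }
})

test_that("GTF round trip reproduces transcripts and junctions", {
  g <- fixture_graph()
  path <- tempfile(fileext = ".gtf")
  write_annotation_gtf(g, path)
  g2 <- read_annotation_gtf(path)
  expect_equal(g2$exons[order(g2$exons$transcript_id, g2$exons$start),
                        c("transcript_id", "start", "end", "strand")],
               g$exons[order(g$exons$transcript_id, g$exons$start),
                       c("transcript_id", "start", "end", "strand")],
               ignore_attr = TRUE)
  expect_equal(g2$junctions, g$junctions)
  expect_equal(g2$transcripts$cds_start, g$transcripts$cds_start)
})

test_that("junction dinucleotides are strand-aware and flag GC donors", {
  g <- genome_seq(c(c1 = paste0("AAAA", "GTAAG", strrep("C", 10), "TTCAG",
                                "AAAA")))
  # + strand intron [4, 24): starts GT..., ends ..AG
  j <- data.frame(chrom = "c1", start = 4L, end = 24L, strand = "+")
  d <- junction_dinucleotides(j, g)
  expect_equal(d$donor, "GT")
  expect_equal(d$acceptor, "AG")
  expect_true(d$canonical)

  gc <- genome_seq(c(c1 = paste0("AAAA", "GCAAG", strrep("C", 10), "TTCAG",
                                 "AAAA")))
  dgc <- junction_dinucleotides(j, gc)
  expect_equal(dgc$donor, "GC")
  expect_true(dgc$gc_donor)
  expect_false(dgc$canonical)
})

test_that("minus-strand dinucleotides match a reverse-complement oracle", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_dna(60)
    g <- genome_seq(c(c1 = s))
    start <- sample(5:20, 1L); end <- start + sample(10:30, 1L)
    jm <- data.frame(chrom = "c1", start = start, end = end, strand = "-")
    got <- junction_dinucleotides(jm, g)
    # oracle: mirror the junction onto the reverse-complemented genome and
    # read it as a + strand junction
    L <- nchar(s)
    grc <- genome_seq(c(c1 = revcomp(s)))
    jp <- data.frame(chrom = "c1", start = L - end, end = L - start,
                     strand = "+")
    oracle <- junction_dinucleotides(jp, grc)
    expect_equal(got$donor, oracle$donor)
    expect_equal(got$acceptor, oracle$acceptor)
  }
})

test_that("BED reading preserves half-open coordinates and defaults strand", {
  p <- write_lines_tmp("c1\t10\t11\t.\t0\t+", ".bed")
  b <- read_bed(p)
  expect_equal(b, data.frame(chrom = "c1", start = 10L, end = 11L,
                             strand = "+"))
  p3 <- write_lines_tmp("c1\t5\t9", ".bed")
  expect_equal(read_bed(p3)$strand, "+")
  pm <- write_lines_tmp("c1\t5\t9\tname\t0\t-", ".bed")
  expect_equal(read_bed(pm)$strand, "-")
  expect_error(read_bed(write_lines_tmp("c1\t5", ".bed")), "malformed")
  expect_error(read_bed(write_lines_tmp("c1\t9\t5", ".bed")), "start >= end")
})

test_that("transcript mRNA assembly and coordinate mapping agree", {
  g <- fixture_graph()
  gen <- fixture_genome()
  m <- transcript_mrna(g, "gA.t1", gen)
  expect_equal(nchar(m), 300L + 400L + 400L)
  # position at start of middle exon maps just after exon 1
  expect_equal(genomic_to_tx(g, "gA.t1", 700L), 300L)
  expect_error(genomic_to_tx(g, "gA.t1", 500L), "not exonic")
  # minus strand: first mRNA base is the highest genomic exon base
  gm <- fixture_graph(strand = "-")
  expect_equal(genomic_to_tx(gm, "gA.t1", 1799L), 0L)
})
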