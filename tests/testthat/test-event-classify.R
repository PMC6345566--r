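test_that("de-novo flags distinguish annotated junctions and sites", {
  graph <- fixture_graph()
  ann <- data.frame(chrom = "c1", start = 400L, end = 700L, strand = "+")
  expect_equal(unlist(flag_de_novo(ann, graph)),
               c(junction_annotated = TRUE, donor_annotated = TRUE,
                 acceptor_annotated = TRUE))
  # annotated donor spliced to a novel acceptor inside the intron
  novel_acc <- data.frame(chrom = "c1", start = 400L, end = 600L,
                          strand = "+")
  expect_equal(unname(unlist(flag_de_novo(novel_acc, graph))),
               c(FALSE, TRUE, FALSE))
  # exon-internal junction: fully novel
  exitron_j <- data.frame(chrom = "c1", start = 800L, end = 1000L,
                          strand = "+")
  expect_equal(unname(unlist(flag_de_novo(exitron_j, graph))),
               c(FALSE, FALSE, FALSE))
})

test_that("asymmetry ratio follows the worked junction-count example", {
  expect_equal(junction_asymmetry_ratio(140, 10), 14)
  expect_equal(junction_asymmetry_ratio(10, 10), 1)
  expect_equal(junction_asymmetry_ratio(5, 0), Inf)
  expect_error(junction_asymmetry_ratio(0, 0), "undefined")
})

# genome with AATAAA planted a fixed distance after an exon end
terminal_fixture <- function(polya_at = 60L, incl = 140L, sout = 10L) {
  set.seed(8)
  s <- strsplit(random_dna(2000), "", fixed = TRUE)[[1]]
  exon <- list(chrom = "c1", start = 500L, end = 600L, strand = "+")
  # scrub accidental signals downstream, then plant one
  reg <- paste(s[601:1200], collapse = "")
  reg <- gsub("AATAAA", "AACAAA", reg)
  s[601:1200] <- strsplit(reg, "", fixed = TRUE)[[1]]
  if (!is.na(polya_at)) {
    s[(600L + polya_at + 1L):(600L + polya_at + 6L)] <-
      c("A", "A", "T", "A", "A", "A")
  }
  g <- genome_seq(c(c1 = paste(s, collapse = "")))
  j <- data.frame(chrom = "c1", start = c(400L, 600L),
                  end = c(500L, 800L), strand = "+")
  tab <- fixture_table(j, c(incl, sout), c(incl, sout))
  list(genome = g, exon = exon, table = tab)
}

test_that("terminal-exon evidence needs asymmetry plus a polyA signal", {
  fx <- terminal_fixture(polya_at = 60L, incl = 70L, sout = 5L)
  ev <- detect_terminal_exon(fx$exon, fx$table, fx$genome, min_ratio = 5)
  expect_equal(ev$asymmetry_ratio, 14)
  expect_equal(ev$inclusion_count, 140L)   # both samples pooled
  expect_equal(ev$polya$offset, 60L)
  expect_equal(ev$polya$signal, "AATAAA")
  expect_equal(ev$polya$genomic_start, 660L)

  # symmetric junction reads: no evidence even with a signal present
  fs <- terminal_fixture(polya_at = 60L, incl = 10L, sout = 10L)
  expect_null(detect_terminal_exon(fs$exon, fs$table, fs$genome,
                                   min_ratio = 5))

  # no signal in the window: no evidence despite infinite asymmetry
  fn <- terminal_fixture(polya_at = NA, incl = 100L, sout = 0L)
  expect_null(detect_terminal_exon(fn$exon, fn$table, fn$genome,
                                   min_ratio = 5))
})

test_that("classification follows the taxonomy's worked geometries", {
  graph <- fixture_graph()
  genome <- fixture_genome()

  # exitron: single junction strictly inside the middle exon
  exi <- classify_event(
    data.frame(chrom = "c1", start = 800L, end = 1000L, strand = "+"),
    NULL, graph, genome)
  expect_equal(exi$class, "exitron")
  expect_equal(exi$delta_length, -200L)

  # alternative 3'SS 1353 nt into the exon-extension direction:
  # shared donor, novel intronic acceptor upstream of the annotated one
  wide <- splice_graph(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c1",
    start = c(100L, 2000L), end = c(300L, 2400L), strand = "+"),
    cds = data.frame(transcript_id = "t", cds_start = 150L,
                     cds_end = 2350L))
  gwide <- genome_seq(c(c1 = random_dna(3000)))
  ref <- data.frame(chrom = "c1", start = 300L, end = 2000L, strand = "+")
  gm <- classify_event(
    data.frame(chrom = "c1", start = 300L, end = 2000L - 1353L,
               strand = "+"),
    ref, wide, gwide)
  expect_equal(gm$class, "alt3ss_extension")
  expect_equal(gm$delta_length, 1353L)
})

test_that("alt 5'SS truncation reports the signed removed length", {
  wide <- splice_graph(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c1",
    start = c(100L, 3700L), end = c(1700L, 4000L), strand = "+"))
  gwide <- genome_seq(c(c1 = random_dna(4200)))
  ref <- data.frame(chrom = "c1", start = 1700L, end = 3700L, strand = "+")
  al <- classify_event(
    data.frame(chrom = "c1", start = 1700L - 1407L, end = 3700L,
               strand = "+"),
    ref, wide, gwide)
  expect_equal(al$class, "alt5ss_truncation")
  expect_equal(al$delta_length, -1407L)
  expect_equal(al$region_end - al$region_start, 1407L)
})

test_that("cassette pairs split into annotated vs cryptic by site novelty", {
  graph <- fixture_graph()
  genome <- fixture_genome()
  # two junctions delimiting the annotated middle exon [700,1100)
  chg_ann <- data.frame(chrom = "c1", start = c(400L, 1100L),
                        end = c(700L, 1400L), strand = "+")
  ev_ann <- classify_event(chg_ann,
                           data.frame(chrom = "c1", start = 400L,
                                      end = 1400L, strand = "+"),
                           graph, genome)
  expect_equal(ev_ann$class, "annotated_cassette")
  expect_equal(ev_ann$delta_length, 400L)

  # novel exon [800,900) inside the t2 skipping intron
  chg_cr <- data.frame(chrom = "c1", start = c(400L, 900L),
                       end = c(800L, 1400L), strand = "+")
  ev_cr <- classify_event(chg_cr,
                          data.frame(chrom = "c1", start = 400L,
                                     end = 1400L, strand = "+"),
                          graph, genome)
  expect_equal(ev_cr$class, "cryptic_internal_exon")
  expect_equal(ev_cr$delta_length, 100L)

  expect_error(classify_event(
    data.frame(chrom = "c1", start = c(400L, 900L), end = c(800L, 1400L),
               strand = c("+", "-")),
    NULL, graph, genome), "mixed strands")
})

test_that("classification is strand-symmetric", {
  L <- 3000L
  set.seed(33)
  s <- random_dna(L)
  mk <- function(strand, genome, flip) {
    iv <- function(s, e) {
      if (flip) list(start = L - e, end = L - s) else
        list(start = s, end = e)
    }
    e1 <- iv(100L, 300L); e2 <- iv(2000L, 2400L)
    exons <- data.frame(gene_id = "g", transcript_id = "t", chrom = "c1",
                        start = c(e1$start, e2$start),
                        end = c(e1$end, e2$end), strand = strand)
    graph <- splice_graph(exons)
    r <- iv(300L, 2000L); c <- iv(300L, 1900L)
    classify_event(
      data.frame(chrom = "c1", start = c$start, end = c$end,
                 strand = strand),
      data.frame(chrom = "c1", start = r$start, end = r$end,
                 strand = strand),
      graph, genome)
  }
  plus <- mk("+", genome_seq(c(c1 = s)), flip = FALSE)
  minus <- mk("-", genome_seq(c(c1 = revcomp(s))), flip = TRUE)
  expect_equal(plus$class, "alt3ss_extension")
  expect_equal(minus$class, plus$class)
  expect_equal(abs(minus$delta_length), abs(plus$delta_length))
})

test_that("event-type proportions sum to 100 with stable ordering", {
  p <- summarize_event_types(c("exitron", "exitron", "alt5ss_truncation",
                               "alt5ss_truncation"))
  expect_equal(p$percent, c(50, 50))
  expect_equal(p$class, c("alt5ss_truncation", "exitron"))

  expect_equal(nrow(summarize_event_types(character(0))), 0L)

  p3 <- summarize_event_types(c("exitron", "alt5ss_extension",
                                "cryptic_internal_exon"))
  expect_equal(sum(p3$percent), 100, tolerance = 1e-9)
  expect_equal(p3$percent, rep(100 / 3, 3), tolerance = 1e-9)
})
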