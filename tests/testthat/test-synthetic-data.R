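small_cfg <- function(...) {
  simulation_config(seed = 17, events_per_class = 2, clip_n_sites = 30, ...)
}

test_that("the generator is deterministic given the seed", {
  r1 <- generate_reference(small_cfg())
  r2 <- generate_reference(small_cfg())
  expect_identical(unclass(r1$genome), unclass(r2$genome))
  expect_identical(r1$truth$events, r2$truth$events)
  expect_identical(r1$truth$crosslinks$sites, r2$truth$crosslinks$sites)
  t1 <- simulate_junction_counts(r1, small_cfg())
  t2 <- simulate_junction_counts(r2, small_cfg())
  expect_identical(t1$counts, t2$counts)
  # and a different seed changes the data
  r3 <- generate_reference(simulation_config(seed = 18,
                                             events_per_class = 2,
                                             clip_n_sites = 30))
  expect_false(identical(unclass(r1$genome), unclass(r3$genome)))
})

test_that("truth-manifest coordinates resolve against the annotation", {
  ref <- generate_reference(small_cfg())
  roles <- ref$truth$junction_roles
  expect_true(all(roles$chrom %in% names(ref$genome)))
  # every junction interval lies inside its chromosome and is >= 4 nt
  for (i in seq_len(nrow(roles))) {
    expect_gte(roles$end[i] - roles$start[i], 4L)
    expect_lte(roles$end[i], nchar(ref$genome[[roles$chrom[i]]]))
  }
  # annotated (skip/constitutive) junctions are in the graph's set
  ann <- roles[roles$role %in% c("constitutive", "skip"), ]
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  expect_true(all(key(ann) %in% key(ref$graph$junctions)))
  # cryptic junctions are not annotated
  cr <- roles[roles$role %in% c("cryptic_single", "incl_left"), ]
  cr <- cr[!ref$truth$events$class[match(cr$event,
                                         ref$truth$events$event)] %in%
             "annotated_cassette", ]
  expect_false(any(key(cr) %in% key(ref$graph$junctions)))
})

test_that("planted splice sites carry the expected dinucleotides", {
  ref <- generate_reference(small_cfg())
  roles <- ref$truth$junction_roles
  events <- ref$truth$events
  cls <- events$class[match(roles$event, events$event)]
  dn <- junction_dinucleotides(roles, ref$genome)
  # every planted junction is GT-AG except the configured GC-donor exitron
  expect_true(all(dn$canonical | dn$gc_donor))
  gc_rows <- which(dn$gc_donor)
  expect_length(gc_rows, small_cfg()$gc_donor_exitrons)
  expect_true(all(cls[gc_rows] == "exitron"))
})

test_that("terminal-exon plants put AATAAA only at the configured offset", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  ev <- ref$truth$events
  te <- ev[ev$class == "cryptic_terminal_exon", ]
  expect_gt(nrow(te), 0L)
  for (i in seq_len(nrow(te))) {
    e <- te[i, ]
    down <- if (e$strand == "+") {
      genome_fetch(ref$genome, e$chrom, e$region_end, e$region_end + 500L)
    } else {
      genome_fetch(ref$genome, e$chrom, e$region_start - 500L,
                   e$region_start, strand = "-")
    }
    hits <- gregexpr("AATAAA", down, fixed = TRUE)[[1]]
    expect_equal(as.integer(hits[1]) - 1L, cfg$polya_offset)
  }
})

test_that("count allocation follows the planted PSI", {
  # degenerate PSI: no cryptic reads in A, all cryptic reads in B
  cfg <- simulation_config(seed = 19, events_per_class = 1,
                           classes = "alt5ss_extension", psi_a = 0,
                           psi_b = 1, clip_n_sites = 5)
  ref <- generate_reference(cfg)
  tab <- simulate_junction_counts(ref, cfg, exact = TRUE)
  roles <- ref$truth$junction_roles
  cr <- which(roles$role == "cryptic_single")
  sk <- which(!is.na(roles$event) & roles$role == "skip")
  a_cols <- tab$samples$condition == "A"
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  cr_i <- match(key(roles[cr, ]), key(tab$junctions))
  sk_i <- match(key(roles[sk, ]), key(tab$junctions))
  expect_true(all(tab$counts[cr_i, a_cols] == 0L))
  expect_true(all(tab$counts[sk_i, !a_cols] == 0L))

  # stochastic mean: cryptic counts average depth * psi over replicates
  cfg2 <- simulation_config(seed = 23, events_per_class = 1,
                            classes = "alt5ss_extension", psi_a = 0.5,
                            psi_b = 0.5, replicates = 150L,
                            clip_n_sites = 5)
  ref2 <- generate_reference(cfg2)
  tab2 <- simulate_junction_counts(ref2, cfg2)
  cr2 <- match(key(ref2$truth$junction_roles[
    ref2$truth$junction_roles$role == "cryptic_single", ]),
    key(tab2$junctions))
  m <- mean(tab2$counts[cr2, ])
  expect_equal(m, 50, tolerance = 0.1 * 50)
})

test_that("emitted files round-trip through the package readers", {
  cfg <- small_cfg()
  dir <- tempfile("sim")
  ref <- simulate_study(cfg, dir, exact = TRUE)
  expect_true(all(file.exists(unlist(ref$paths))))

  genome <- read_genome_fasta(ref$paths$genome)
  expect_identical(unclass(genome), unclass(ref$genome))
  graph <- read_annotation_gtf(ref$paths$gtf)
  expect_equal(graph$junctions, ref$graph$junctions)
  tab <- read_sj_samples(ref$paths$sample_sheet, graph)
  # zero-count junctions are omitted from the files; compare the rest
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  idx <- match(key(tab$junctions), key(ref$table$junctions))
  expect_true(all(tab$counts == ref$table$counts[idx, , drop = FALSE]))
  truth <- jsonlite::read_json(ref$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$events$class, ref$truth$events$class)

  # rerunning the study writes byte-identical artifacts
  dir2 <- tempfile("sim")
  simulate_study(cfg, dir2, exact = TRUE)
  for (f in c("genome.fa", "annotation.gtf", "crosslinks.bed",
              file.path("sj", "A1.tab"))) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("crosslink plants appear in the configured window fraction", {
  cfg <- simulation_config(seed = 29, events_per_class = 2,
                           clip_n_sites = 60, clip_plant_fraction = 1)
  ref <- generate_reference(cfg)
  sites <- simulate_crosslinks(ref, cfg)
  w <- extract_windows(sites, ref$genome)
  hit <- vapply(w, function(x) grepl("TGAAG", x, fixed = TRUE), logical(1))
  expect_true(all(hit))

  cfg0 <- simulation_config(seed = 29, events_per_class = 2,
                            clip_n_sites = 60, clip_plant_fraction = 0)
  ref0 <- generate_reference(cfg0)
  w0 <- extract_windows(simulate_crosslinks(ref0, cfg0), ref0$genome)
  hit0 <- mean(vapply(w0, function(x) grepl("TGAAG", x, fixed = TRUE),
                      logical(1)))
  # analytic background: ~97 positions at rate p(T)p(G)p(A)^2p(G)
  p <- 97 * 0.3 * 0.2 * 0.3 * 0.3 * 0.2
  expect_lt(abs(hit0 - p), 0.15)
})
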