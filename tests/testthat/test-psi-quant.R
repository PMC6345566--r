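sj_line <- function(chrom, s1, e1, code, uniq) {
  sprintf("%s\t%d\t%d\t%d\t1\t1\t%d\t0\t50", chrom, s1, e1, code, uniq)
}

test_that("SJ tables convert coordinates and resolve strand codes", {
  p <- write_lines_tmp(sj_line("c1", 101, 200, 1, 140), ".tab")
  d <- read_sj_table(p)
  expect_equal(d, data.frame(chrom = "c1", start = 100L, end = 200L,
                             strand = "+", count = 140L))

  graph <- splice_graph(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c1",
    start = c(0L, 200L), end = c(100L, 300L), strand = "+"))
  p0 <- write_lines_tmp(c(sj_line("c1", 101, 200, 0, 9),
                          sj_line("c1", 501, 600, 0, 4)), ".tab")
  expect_warning(d0 <- read_sj_table(p0, graph), "dropped")
  expect_equal(nrow(d0), 1L)
  expect_equal(d0$strand, "+")

  pneg <- write_lines_tmp(sj_line("c1", 101, 200, 1, -5), ".tab")
  expect_error(read_sj_table(pneg), "negative")
})

test_that("LSVs form at shared anchors with enough support", {
  graph <- fixture_graph()
  j <- data.frame(chrom = "c1",
                  start = c(400L, 400L, 2000L),
                  end = c(700L, 1400L, 2400L),
                  strand = "+")
  tab <- fixture_table(j, c(10L, 10L, 50L), c(10L, 10L, 50L))
  lsvs <- define_lsvs(graph, tab, min_total = 10L)
  expect_length(lsvs, 1L)
  expect_equal(lsvs[[1]]$side, "source")
  expect_equal(nrow(lsvs[[1]]$junctions), 2L)
  # below the support threshold: no LSV
  tab_low <- fixture_table(j, c(2L, 2L, 1L), c(2L, 2L, 1L))
  expect_length(define_lsvs(graph, tab_low, min_total = 10L), 0L)
})

test_that("exitron fixtures anchor into LSVs as a brute-force scan predicts", {
  graph <- fixture_graph()
  # exitron inside middle exon [700,1100): internal donor 800, acceptor 1000;
  # companion junction from the upstream exon donor to the internal acceptor
  j <- data.frame(chrom = "c1",
                  start = c(400L, 400L, 800L),
                  end = c(700L, 1000L, 1000L),
                  strand = "+")
  tab <- fixture_table(j, c(50L, 40L, 5L), c(50L, 10L, 40L))
  lsvs <- define_lsvs(graph, tab, min_total = 10L)
  # brute-force oracle: count anchors shared by >= 2 junctions
  donor_anchors <- table(j$start)
  target_anchors <- table(j$end)
  expected_n <- sum(donor_anchors >= 2L) + sum(target_anchors >= 2L)
  expect_length(lsvs, expected_n)
  sides <- vapply(lsvs, `[[`, character(1), "side")
  anchors <- vapply(lsvs, `[[`, numeric(1), "anchor")
  expect_true(any(sides == "target" & anchors == 1000))
})

test_that("E(PSI) matches the closed-form Dirichlet mean", {
  graph <- fixture_graph()
  j <- data.frame(chrom = "c1", start = c(400L, 400L),
                  end = c(700L, 1400L), strand = "+")

  cases <- list(list(a = c(5L, 5L), want = c(0.5, 0.5)),
                list(a = c(0L, 0L), want = c(0.5, 0.5)),
                list(a = c(140L, 10L), want = c(141, 11) / 152))
  for (cs in cases) {
    tab <- fixture_table(j, cs$a, cs$a)
    lsv <- define_lsvs(graph, tab, min_total = 0L)[[1]]
    est <- estimate_psi(lsv, tab, "A", alpha = 1)
    expect_equal(unname(est$e_psi), cs$want, tolerance = 1e-9)
    expect_equal(sum(est$e_psi), 1, tolerance = 1e-9)
  }
})

test_that("multi-replicate E(PSI) is the replicate mean, not the pool", {
  graph <- fixture_graph()
  j <- data.frame(chrom = "c1", start = c(400L, 400L),
                  end = c(700L, 1400L), strand = "+")
  sj <- list(A1 = cbind(j, count = c(90L, 10L)),
             A2 = cbind(j, count = c(10L, 90L)),
             B1 = cbind(j, count = c(50L, 50L)))
  tab <- junction_count_table(sj, c("A", "A", "B"))
  lsv <- define_lsvs(graph, tab, min_total = 0L)[[1]]
  est <- estimate_psi(lsv, tab, "A", alpha = 1)
  expect_equal(unname(est$e_psi[1]), mean(c(91 / 102, 11 / 102)),
               tolerance = 1e-9)
})

test_that("delta-PSI calling matches a Monte-Carlo oracle and is seeded", {
  graph <- fixture_graph()
  j <- data.frame(chrom = "c1", start = c(400L, 400L),
                  end = c(700L, 1400L), strand = "+")

  # symmetric counts: no change
  tab0 <- fixture_table(j, c(50L, 50L), c(50L, 50L))
  lsv <- define_lsvs(graph, tab0, min_total = 0L)[[1]]
  d0 <- delta_psi(lsv, tab0, seed = 5L)
  expect_lt(max(abs(d0$e_dpsi)), 0.05)
  expect_equal(d0$tier, c("none", "none"))

  # complete switch: confident V20 call
  tab1 <- fixture_table(j, c(100L, 0L), c(0L, 100L))
  d1 <- delta_psi(lsv, tab1, seed = 5L)
  expect_true(all(d1[["p_ge_0.2"]] > 0.99))
  expect_equal(d1$tier, c("V20", "V20"))

  # modest shift: |E(dPSI)| ~ 0.098 (independent closed form), tier < V20
  tab2 <- fixture_table(j, c(50L, 50L), c(60L, 40L))
  d2 <- delta_psi(lsv, tab2, seed = 5L)
  closed <- 61 / 102 - 51 / 102
  expect_equal(d2$e_dpsi[1], closed, tolerance = 0.02)
  expect_false(any(d2$tier == "V20"))
  # the V-threshold probabilities are nested
  expect_true(all(d2[["p_ge_0.2"]] <= d2[["p_ge_0.1"]]))

  # seed determinism: bit-identical results
  expect_identical(delta_psi(lsv, tab2, seed = 9L),
                   delta_psi(lsv, tab2, seed = 9L))
})

# builds a table of n binary source-LSVs with given per-condition psi
many_lsv_table <- function(n, psi_a, psi_b, depth = 100L, reps = 3L,
                           seed = 1L) {
  set.seed(seed)
  j <- data.frame(chrom = "c1",
                  start = rep(seq_len(n) * 1000L, each = 2L),
                  end = rep(seq_len(n) * 1000L, each = 2L) +
                    rep(c(200L, 400L), n),
                  strand = "+")
  sj <- list()
  conds <- rep(c("A", "B"), each = reps)
  for (s in seq_along(conds)) {
    psi <- if (conds[s] == "A") psi_a else psi_b
    c1 <- stats::rbinom(n, depth, psi)
    cnt <- as.vector(rbind(c1, depth - c1))
    sj[[sprintf("%s%d", conds[s], ((s - 1L) %% reps) + 1L)]] <-
      cbind(j, count = cnt)
  }
  junction_count_table(sj, conds)
}

many_lsv_graph <- function(n) {
  splice_graph(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "c1",
    start = c(0L, (n + 2L) * 1000L), end = c(100L, (n + 2L) * 1000L + 100L),
    strand = "+"))
}

test_that("null data yields few V20 calls; calls increase with true dPSI", {
  n <- 60L
  graph <- many_lsv_graph(n)
  set.seed(21)
  psis <- stats::runif(n, 0.2, 0.8)
  # null: both conditions from the same per-LSV multinomial
  sjnull <- list()
  conds <- rep(c("A", "B"), each = 3L)
  j <- data.frame(chrom = "c1",
                  start = rep(seq_len(n) * 1000L, each = 2L),
                  end = rep(seq_len(n) * 1000L, each = 2L) +
                    rep(c(200L, 400L), n),
                  strand = "+")
  for (s in seq_along(conds)) {
    c1 <- stats::rbinom(n, 100L, psis)
    sjnull[[paste0(conds[s], s)]] <- cbind(j, count = as.vector(
      rbind(c1, 100L - c1)))
  }
  tabnull <- junction_count_table(sjnull, conds)
  calls <- call_delta_psi(graph, tabnull, seed = 13L)
  expect_lt(mean(calls$tier == "V20"), 0.05)

  # monotonicity of the V20 fraction in the true effect size
  frac <- vapply(c(0, 0.25, 0.5), function(d) {
    tab <- many_lsv_table(40L, 0.2, 0.2 + d, seed = 31L)
    cl <- call_delta_psi(many_lsv_graph(40L), tab, seed = 17L)
    mean(cl$tier == "V20")
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], 0.9)
})
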