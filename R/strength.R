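.PWM_WIDTH <- c(donor = 9L, acceptor = 23L)

#' Train a splice-site position weight matrix
#'
#' Builds per-position nucleotide frequencies (with pseudocount) from a set
#' of aligned site windows and converts them to log2-odds against background
#' frequencies. Donor windows are 9 nt (3 exonic + 6 intronic), acceptor
#' windows 23 nt (20 intronic + 3 exonic, covering the polypyrimidine
#' tract); the exon/intron boundary sits between the exonic and intronic
#' blocks.
#'
#' @param sites Character vector of aligned windows, all of the fixed length
#'   for \code{site_kind}, alphabet ACGT.
#' @param site_kind "donor" or "acceptor".
#' @param pseudocount Added per nucleotide per position (default 0.5).
#' @param background Named vector of background frequencies (default uniform
#'   0.25).
#' @return A \code{pwm_model}: list with \code{site_kind}, \code{width},
#'   \code{log_odds} (4 x width matrix, rows ACGT), \code{pseudocount}.
#' @export
train_pwm <- function(sites, site_kind = c("donor", "acceptor"),
                      pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  site_kind <- match.arg(site_kind)
  w <- .PWM_WIDTH[[site_kind]]
  if (length(sites) == 0L) stop("empty training set")
  if (any(nchar(sites) != w)) {
    stop(site_kind, " windows must be exactly ", w, " nt")
  }
  if (any(grepl("[^ACGT]", sites))) stop("training windows must be ACGT only")
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- apply(mat, 2L, function(col) {
    table(factor(col, levels = c("A", "C", "G", "T")))
  })
  freqs <- sweep(counts + pseudocount, 2L,
                 colSums(counts + pseudocount), "/")
  lo <- log2(sweep(freqs, 1L, background[rownames(freqs)], "/"))
  structure(list(site_kind = site_kind, width = w, log_odds = lo,
                 pseudocount = pseudocount),
            class = "pwm_model")
}

#' Score a window with a PWM
#'
#' @param pwm A \code{pwm_model}.
#' @param window Character scalar of the PWM's width. Windows containing
#'   any non-ACGT character (e.g. N) get \code{NA}: they are excluded from
#'   percentile referencing rather than scored on fabricated content.
#' @return Sum of per-position log2-odds, or \code{NA_real_}.
#' @export
score_window <- function(pwm, window) {
  if (nchar(window) != pwm$width) {
    stop("window length ", nchar(window), " != PWM width ", pwm$width)
  }
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T"))) return(NA_real_)
  sum(pwm$log_odds[cbind(match(chars, rownames(pwm$log_odds)),
                         seq_along(chars))])
}

#' Extract the fixed splice-site window around a junction side
#'
#' Strand-aware: the returned window is in transcript orientation, so the
#' donor window always reads exon|GT-intron and the acceptor window
#' intron-AG|exon regardless of genomic strand.
#'
#' @param genome A \code{genome_seq}.
#' @param junction One-row data.frame / list: \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (intron, 0-based half-open).
#' @param side "donor" or "acceptor".
#' @return Character scalar (9 nt donor / 23 nt acceptor window).
#' @export
site_window <- function(genome, junction, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  j <- as.list(junction)
  if (side == "donor") {
    if (j$strand == "+") {
      genome_fetch(genome, j$chrom, j$start - 3L, j$start + 6L)
    } else {
      genome_fetch(genome, j$chrom, j$end - 6L, j$end + 3L, strand = "-")
    }
  } else {
    if (j$strand == "+") {
      genome_fetch(genome, j$chrom, j$end - 20L, j$end + 3L)
    } else {
      genome_fetch(genome, j$chrom, j$start - 3L, j$start + 20L, strand = "-")
    }
  }
}

#' Score a splice site of a junction
#'
#' @param pwm A \code{pwm_model} matching \code{side}.
#' @param genome A \code{genome_seq}.
#' @param junction One-row junction data.frame / list.
#' @param side "donor" or "acceptor".
#' @return Raw log2-odds score, or \code{NA} if the window contains N.
#' @export
score_site <- function(pwm, genome, junction, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  if (pwm$site_kind != side) stop("PWM kind does not match requested side")
  score_window(pwm, site_window(genome, junction, side))
}

#' Percentile rank of a score against a reference distribution
#'
#' Midrank convention: 100 * (#\{ref < score\} + 0.5 * #\{ref == score\}) / n,
#' matching the percentile-of-alternative-exon framing used for splice-site
#' strength reporting. Monotone non-decreasing in the score; every member of
#' a reference set ranks strictly inside (0, 100) against that set, and the
#' mean of those ranks is 50.
#'
#' @param score Raw score (NA gives NA).
#' @param reference_scores Non-empty numeric vector (NAs dropped).
#' @return Percentile in [0, 100].
#' @export
percentile_rank <- function(score, reference_scores) {
  reference_scores <- reference_scores[!is.na(reference_scores)]
  if (length(reference_scores) == 0L) stop("empty reference score set")
  if (is.na(score)) return(NA_real_)
  100 * (sum(reference_scores < score) +
           0.5 * sum(reference_scores == score)) / length(reference_scores)
}

#' Read an ESE hexamer list
#'
#' @param path Plain-text file, one hexamer per line; blank lines and lines
#'   starting with '#' are ignored.
#' @return Uppercase character vector of hexamers.
#' @export
read_ese_list <- function(path) {
  x <- readLines(path)
  x <- toupper(trimws(x))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (any(nchar(x) != 6L)) stop("ESE entries must be hexamers")
  unique(x)
}

#' Exonic splicing enhancer density
#'
#' Overlapping hexamer hits per 100 nt of exon sequence: hits * 100 /
#' (length - 5).
#'
#' @param exon_seq Uppercase exon sequence (transcript orientation),
#'   length >= 6.
#' @param ese_set Character vector of hexamers.
#' @return Density per 100 nt.
#' @export
ese_density <- function(exon_seq, ese_set) {
  n <- nchar(exon_seq)
  if (n < 6L) stop("exon sequence shorter than 6 nt")
  windows <- substring(exon_seq, seq_len(n - 5L), seq_len(n - 5L) + 5L)
  100 * sum(windows %in% ese_set) / (n - 5L)
}

#' Reference splice-site scores from the annotation
#'
#' Scores every annotated junction's donor and acceptor with the supplied
#' PWMs; these annotated-site score sets are the default reference
#' distributions for percentile ranking.
#'
#' @param graph A \code{splice_graph}.
#' @param genome A \code{genome_seq}.
#' @param pwm_donor,pwm_acceptor \code{pwm_model}s.
#' @return List with numeric vectors \code{donor} and \code{acceptor}.
#' @export
reference_site_scores <- function(graph, genome, pwm_donor, pwm_acceptor) {
  j <- graph$junctions
  donor <- vapply(seq_len(nrow(j)), function(i)
    score_site(pwm_donor, genome, j[i, ], "donor"), numeric(1))
  acceptor <- vapply(seq_len(nrow(j)), function(i)
    score_site(pwm_acceptor, genome, j[i, ], "acceptor"), numeric(1))
  list(donor = donor[!is.na(donor)], acceptor = acceptor[!is.na(acceptor)])
}

#' Train donor/acceptor PWMs from the annotated junctions
#'
#' @param graph A \code{splice_graph}.
#' @param genome A \code{genome_seq}.
#' @param pseudocount Passed to \code{\link{train_pwm}}.
#' @return List with \code{donor} and \code{acceptor} \code{pwm_model}s.
#' @export
train_annotation_pwms <- function(graph, genome, pseudocount = 0.5) {
  j <- graph$junctions
  dw <- aw <- character(0)
  for (i in seq_len(nrow(j))) {
    d <- site_window(genome, j[i, ], "donor")
    a <- site_window(genome, j[i, ], "acceptor")
    if (!grepl("[^ACGT]", d)) dw <- c(dw, d)
    if (!grepl("[^ACGT]", a)) aw <- c(aw, a)
  }
  list(donor = train_pwm(dw, "donor", pseudocount),
       acceptor = train_pwm(aw, "acceptor", pseudocount))
}

#' Compare cryptic exons with their downstream annotated exons
#'
#' For every cryptic internal exon event, scores the cryptic exon's 5' and
#' 3' splice sites as percentiles of the reference score sets, measures its
#' ESE hexamer density, and does the same for the immediately downstream
#' annotated exon of the host gene. Reports per-event rows, cohort means and
#' paired two-sided t-tests (cryptic minus downstream) for the 3' splice-site
#' percentile, the 5' splice-site percentile and the ESE density.
#'
#' @param events data.frame from \code{\link{classify_events}}; rows with
#'   class \code{cryptic_internal_exon} (and \code{cryptic_terminal_exon})
#'   are used.
#' @param graph A \code{splice_graph}.
#' @param genome A \code{genome_seq}.
#' @param pwms List with \code{donor}/\code{acceptor} \code{pwm_model}s
#'   (default: trained from the annotation).
#' @param ese_set Character vector of ESE hexamers.
#' @param reference Optional list of reference score vectors
#'   (\code{donor}, \code{acceptor}); default: annotated-site scores.
#' @return List with \code{per_event} data.frame and \code{tests}
#'   data.frame (statistic, p-value, means per measure).
#' @export
compare_cryptic_vs_downstream <- function(events, graph, genome,
                                          pwms = NULL, ese_set,
                                          reference = NULL) {
  if (is.null(pwms)) pwms <- train_annotation_pwms(graph, genome)
  if (is.null(reference)) {
    reference <- reference_site_scores(graph, genome, pwms$donor,
                                       pwms$acceptor)
  }
  use <- events$class %in% c("cryptic_internal_exon", "cryptic_terminal_exon")
  ev <- events[use, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    # cryptic exon = the inserted region; its acceptor is the upstream
    # junction's 3' end, its donor the downstream junction's 5' start
    # (transcript orientation via strand)
    cr_exon <- list(chrom = e$chrom, start = e$region_start,
                    end = e$region_end, strand = e$strand)
    # junction-like intervals flanking the cryptic exon, for window cutting:
    up_j <- list(chrom = e$chrom, strand = e$strand,
                 start = e$region_start - 10L, end = e$region_start)
    dn_j <- list(chrom = e$chrom, strand = e$strand,
                 start = e$region_end, end = e$region_end + 10L)
    if (e$strand == "+") {
      cr_acc_j <- up_j; cr_don_j <- dn_j
    } else {
      cr_acc_j <- dn_j; cr_don_j <- up_j
    }
    dn_exon <- .downstream_exon(graph, cr_exon)
    if (is.null(dn_exon)) {
      warning("event ", e$event_id, " has no downstream annotated exon; skipped")
      next
    }
    dn_acc_j <- if (dn_exon$strand == "+") {
      list(chrom = dn_exon$chrom, strand = "+",
           start = dn_exon$start - 10L, end = dn_exon$start)
    } else {
      list(chrom = dn_exon$chrom, strand = "-",
           start = dn_exon$end, end = dn_exon$end + 10L)
    }
    dn_don_j <- if (dn_exon$strand == "+") {
      list(chrom = dn_exon$chrom, strand = "+",
           start = dn_exon$end, end = dn_exon$end + 10L)
    } else {
      list(chrom = dn_exon$chrom, strand = "-",
           start = dn_exon$start - 10L, end = dn_exon$start)
    }
    p <- function(j, side) {
      percentile_rank(score_site(pwms[[side]], genome, j, side),
                      reference[[side]])
    }
    cr_seq <- genome_fetch(genome, cr_exon$chrom, cr_exon$start, cr_exon$end,
                           strand = cr_exon$strand)
    dn_seq <- genome_fetch(genome, dn_exon$chrom, dn_exon$start, dn_exon$end,
                           strand = dn_exon$strand)
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = e$event_id, gene_id = e$gene_id,
      cryptic_acceptor_pct = p(cr_acc_j, "acceptor"),
      cryptic_donor_pct = p(cr_don_j, "donor"),
      cryptic_ese_density = ese_density(cr_seq, ese_set),
      downstream_acceptor_pct = p(dn_acc_j, "acceptor"),
      downstream_donor_pct = p(dn_don_j, "donor"),
      downstream_ese_density = ese_density(dn_seq, ese_set))
  }
  per_event <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character())
  tests <- NULL
  if (length(rows) >= 2L) {
    tt <- function(a, b) {
      ok <- !is.na(a) & !is.na(b)
      t <- stats::t.test(a[ok], b[ok], paired = TRUE)
      c(mean_cryptic = mean(a[ok]), mean_downstream = mean(b[ok]),
        statistic = unname(t$statistic), p_value = t$p.value)
    }
    tests <- rbind(
      acceptor_pct = tt(per_event$cryptic_acceptor_pct,
                        per_event$downstream_acceptor_pct),
      donor_pct = tt(per_event$cryptic_donor_pct,
                     per_event$downstream_donor_pct),
      ese_density = tt(per_event$cryptic_ese_density,
                       per_event$downstream_ese_density))
    tests <- data.frame(measure = rownames(tests), tests, row.names = NULL)
  }
  list(per_event = per_event, tests = tests)
}

# nearest annotated exon downstream (transcript orientation) of an interval
.downstream_exon <- function(graph, exon) {
  ex <- graph$exons
  if (exon$strand == "+") {
    cand <- ex[ex$chrom == exon$chrom & ex$strand == "+" &
                 ex$start >= exon$end, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand <- cand[which.min(cand$start), ]
  } else {
    cand <- ex[ex$chrom == exon$chrom & ex$strand == "-" &
                 ex$end <= exon$start, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand <- cand[which.max(cand$end), ]
  }
  list(chrom = cand$chrom, start = cand$start, end = cand$end,
       strand = cand$strand)
}

#' Export / import a PWM as a TSV matrix
#'
#' @param pwm A \code{pwm_model}.
#' @param path TSV path.
#' @return Invisibly \code{path}; \code{read_pwm} returns a
#'   \code{pwm_model}.
#' @export
write_pwm <- function(pwm, path) {
  hdr <- sprintf("# site_kind=%s pseudocount=%g", pwm$site_kind,
                 pwm$pseudocount)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(pwm$log_odds, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @param path TSV path written by \code{write_pwm}.
#' @export
read_pwm <- function(path) {
  hdr <- readLines(path, n = 1L)
  kind <- sub(".*site_kind=(\\w+).*", "\\1", hdr)
  pc <- as.numeric(sub(".*pseudocount=([0-9.eE+-]+).*", "\\1", hdr))
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L,
                                   row.names = 1L))
  colnames(m) <- NULL
  structure(list(site_kind = kind, width = ncol(m), log_odds = m,
                 pseudocount = pc),
            class = "pwm_model")
}
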