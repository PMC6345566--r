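#' Extract crosslink-site windows
#'
#' Cuts the strand-aware window position +/- flank (101 nt at the default
#' flank of 50, avoiding crosslinking bias at the site itself) around every
#' crosslink site. Windows truncated by a chromosome end, and windows
#' containing N, are dropped with a message reporting the count.
#'
#' @param sites data.frame with \code{chrom}, \code{start} (0-based site
#'   position; for 1-bp BED intervals this is the base), \code{strand}.
#' @param genome A \code{genome_seq}.
#' @param flank Half-window (default 50).
#' @return Character vector of window sequences in transcript orientation.
#' @export
extract_windows <- function(sites, genome, flank = 50L) {
  stopifnot(flank > 0L)
  out <- character(0)
  dropped_edge <- dropped_n <- 0L
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]; pos <- sites$start[i]
    if (!chrom %in% names(genome)) { dropped_edge <- dropped_edge + 1L; next }
    L <- nchar(genome[[chrom]])
    s <- pos - flank; e <- pos + flank + 1L
    if (s < 0L || e > L) { dropped_edge <- dropped_edge + 1L; next }
    w <- genome_fetch(genome, chrom, s, e, strand = sites$strand[i])
    if (grepl("N", w, fixed = TRUE)) { dropped_n <- dropped_n + 1L; next }
    out <- c(out, w)
  }
  if (dropped_edge + dropped_n > 0L) {
    message(dropped_edge, " window(s) dropped at chromosome ends, ",
            dropped_n, " containing N")
  }
  out
}

#' Fraction of windows containing each k-mer
#'
#' Presence/absence statistic: each k-mer is counted at most once per window
#' regardless of how many times it occurs there, and the fraction is
#' windows-containing / total windows.
#'
#' @param windows Non-empty character vector of window sequences.
#' @param k k-mer size (default 5: pentamers).
#' @return Named numeric vector of fractions for every k-mer observed in at
#'   least one window.
#' @export
kmer_window_fractions <- function(windows, k = 5L) {
  if (length(windows) == 0L) stop("empty window list")
  stopifnot(k >= 1L)
  per_window <- lapply(windows, function(w) {
    n <- nchar(w)
    if (n < k) return(character(0))
    unique(substring(w, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
  })
  tab <- table(unlist(per_window))
  frac <- as.numeric(tab) / length(windows)
  names(frac) <- names(tab)
  # k-mers containing N carry no motif information
  frac[!grepl("N", names(frac), fixed = TRUE)]
}

#' Pentamer enrichment vs control windows
#'
#' Corrects observed per-window k-mer fractions for their average occurrence
#' in control windows: enrichment = log2((f_obs + pseudo) / (f_ctrl +
#' pseudo)). A two-proportion normal z-score is reported alongside. Rows are
#' ranked by enrichment descending with lexicographic tie-breaking, and each
#' k-mer is flagged for containing the AA dinucleotide.
#'
#' @param obs_fractions Named fractions from observed windows.
#' @param ctrl_fractions Named fractions from control windows.
#' @param pseudo Pseudocount on the fraction scale; default
#'   1 / \code{n_obs}.
#' @param n_obs,n_ctrl Window counts behind each fraction set (for the
#'   z-score and the default pseudocount).
#' @return data.frame: \code{kmer}, \code{f_obs}, \code{f_ctrl},
#'   \code{log2_enrichment}, \code{z}, \code{rank}, \code{contains_AA},
#'   sorted by rank.
#' @export
enrichment_vs_control <- function(obs_fractions, ctrl_fractions,
                                  pseudo = NULL, n_obs, n_ctrl) {
  ko <- names(obs_fractions); kc <- names(ctrl_fractions)
  if (length(ko) && length(kc) &&
      length(unique(nchar(c(ko, kc)))) != 1L) {
    stop("observed and control fractions have mismatched k")
  }
  if (is.null(pseudo)) pseudo <- 1 / n_obs
  stopifnot(pseudo > 0)
  kmers <- sort(union(ko, kc))
  f_obs <- ifelse(kmers %in% ko, obs_fractions[kmers], 0)
  f_ctrl <- ifelse(kmers %in% kc, ctrl_fractions[kmers], 0)
  enr <- log2((f_obs + pseudo) / (f_ctrl + pseudo))
  pool <- (f_obs * n_obs + f_ctrl * n_ctrl) / (n_obs + n_ctrl)
  se <- sqrt(pool * (1 - pool) * (1 / n_obs + 1 / n_ctrl))
  z <- ifelse(se > 0, (f_obs - f_ctrl) / se, 0)
  ord <- order(-enr, kmers)
  out <- data.frame(kmer = kmers, f_obs = unname(f_obs),
                    f_ctrl = unname(f_ctrl),
                    log2_enrichment = unname(enr), z = unname(z),
                    contains_AA = grepl("AA", kmers, fixed = TRUE))[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Altschul-Erickson walk: uniform random Eulerian re-arrangement of the
# dinucleotide multigraph, preserving every dinucleotide count and the
# first/last characters exactly
.dinucleotide_shuffle_one <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n <= 2L || length(unique(chars)) == 1L) return(s)
  from <- chars[-n]; to <- chars[-1L]
  verts <- unique(chars)
  last <- chars[n]
  out_edges <- split(to, factor(from, levels = verts))

  # choose one "last out-edge" per non-terminal vertex so that the chosen
  # edges form a tree directed toward the terminal vertex
  nonterm <- setdiff(verts[lengths(out_edges) > 0L], last)
  repeat {
    pick <- vapply(nonterm, function(v) {
      e <- out_edges[[v]]
      e[[sample.int(length(e), 1L)]]
    }, character(1))
    ok <- TRUE
    for (v in nonterm) {
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen || !(cur %in% nonterm)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- pick[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }

  # permute the remaining out-edges, appending the chosen last edge
  lists <- lapply(verts, function(v) {
    e <- out_edges[[v]]
    if (is.null(e) || length(e) == 0L) return(character(0))
    if (v %in% nonterm) {
      i <- match(pick[[v]], e)
      rest <- e[-i]
      c(if (length(rest)) rest[sample.int(length(rest))], e[i])
    } else {
      e[sample.int(length(e))]
    }
  })
  names(lists) <- verts

  res <- character(n)
  res[1L] <- chars[1L]
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  cur <- chars[1L]
  for (i in 2L:n) {
    nxt <- lists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Build control windows
#'
#' Default mode is a dinucleotide-preserving shuffle of each observed window
#' (Altschul-Erickson Eulerian walk), giving composition-matched controls;
#' alternatively windows are cut from user-supplied regions.
#'
#' @param windows Observed window sequences (shuffle mode).
#' @param mode "dinucleotide_shuffle" or "supplied_bed".
#' @param seed Integer seed (shuffles are deterministic given the seed).
#' @param n_shuffles Shuffle rounds per observed window (shuffle mode);
#'   more rounds tighten the control fraction estimates.
#' @param bed,genome,flank For \code{supplied_bed}: regions data.frame (as
#'   from \code{\link{read_bed}}), genome, and half-window; a window is cut
#'   around each region midpoint.
#' @return Character vector of control windows.
#' @export
control_windows <- function(windows, mode = c("dinucleotide_shuffle",
                                              "supplied_bed"),
                            seed = 1L, n_shuffles = 1L, bed = NULL,
                            genome = NULL, flank = 50L) {
  mode <- match.arg(mode)
  if (mode == "dinucleotide_shuffle") {
    set.seed(seed)
    vapply(rep(windows, n_shuffles), .dinucleotide_shuffle_one,
           character(1), USE.NAMES = FALSE)
  } else {
    if (is.null(bed) || is.null(genome)) {
      stop("supplied_bed mode needs bed and genome")
    }
    mid <- (bed$start + bed$end) %/% 2L
    extract_windows(data.frame(chrom = bed$chrom, start = mid,
                               strand = bed$strand), genome, flank)
  }
}

#' Annotate the genomic region of crosslink sites
#'
#' Strand-matched overlap with the annotation, resolved by priority
#' CDS > 5' UTR > 3' UTR > ncRNA exon > intron > intergenic.
#'
#' @param sites data.frame with \code{chrom}, \code{start}, \code{strand}.
#' @param graph A \code{splice_graph}.
#' @return Character vector of region labels, one per site.
#' @export
annotate_region <- function(sites, graph) {
  prio <- c(CDS = 1L, `5UTR` = 2L, `3UTR` = 3L, ncRNA_exon = 4L,
            intron = 5L, intergenic = 6L)
  tx <- graph$transcripts
  ex <- graph$exons
  vapply(seq_len(nrow(sites)), function(i) {
    chrom <- sites$chrom[i]; pos <- sites$start[i]
    strand <- sites$strand[i]
    hit_tx <- tx[tx$chrom == chrom & tx$strand == strand &
                   tx$start <= pos & pos < tx$end, , drop = FALSE]
    if (nrow(hit_tx) == 0L) return("intergenic")
    labs <- vapply(seq_len(nrow(hit_tx)), function(k) {
      t1 <- hit_tx[k, ]
      e <- ex[ex$transcript_id == t1$transcript_id, , drop = FALSE]
      exonic <- any(e$start <= pos & pos < e$end)
      if (!exonic) return("intron")
      if (is.na(t1$cds_start)) return("ncRNA_exon")
      if (pos >= t1$cds_start && pos < t1$cds_end) return("CDS")
      before_cds <- if (strand == "+") pos < t1$cds_start else
        pos >= t1$cds_end
      if (before_cds) "5UTR" else "3UTR"
    }, character(1))
    names(prio)[min(prio[labs])]
  }, character(1))
}

#' Positional motif map around junction sets
#'
#' For each junction the window covers \code{exon_extent} exonic and
#' \code{intron_extent} intronic nucleotides around the donor (5' splice
#' site) anchor, in transcript orientation. Each track records, per
#' position, the fraction of windows in which any query k-mer occurrence
#' overlaps that position, smoothed by a centred running mean; the
#' regulated/control ratio track is included.
#'
#' @param junction_sets Named list of junction data.frames; must contain
#'   \code{regulated} and \code{control}.
#' @param genome A \code{genome_seq}.
#' @param query_kmers Character vector of query k-mers (equal length).
#' @param exon_extent,intron_extent Window extents in nt (> 0).
#' @param smooth Running-mean width (odd; default 5).
#' @return A \code{motif_map}: list with \code{position} (relative to the
#'   exon/intron boundary, exonic negative), per-set smoothed fraction
#'   tracks, and \code{ratio}.
#' @export
motif_position_map <- function(junction_sets, genome, query_kmers,
                               exon_extent = 50L, intron_extent = 100L,
                               smooth = 5L) {
  stopifnot(exon_extent > 0L, intron_extent > 0L,
            all(c("regulated", "control") %in% names(junction_sets)))
  k <- unique(nchar(query_kmers))
  if (length(k) != 1L) stop("query k-mers must share one length")
  width <- exon_extent + intron_extent
  tracks <- lapply(junction_sets, function(jset) {
    if (nrow(jset) == 0L) stop("empty junction set")
    cov <- matrix(0, nrow = 0, ncol = width)
    for (i in seq_len(nrow(jset))) {
      j <- jset[i, ]
      w <- tryCatch({
        if (j$strand == "+") {
          genome_fetch(genome, j$chrom, j$start - exon_extent,
                       j$start + intron_extent)
        } else {
          genome_fetch(genome, j$chrom, j$end - intron_extent,
                       j$end + exon_extent, strand = "-")
        }
      }, error = function(e) NULL)
      if (is.null(w) || grepl("N", w, fixed = TRUE)) next
      hit <- rep(0, width)
      starts <- seq_len(width - k + 1L)
      occ <- starts[substring(w, starts, starts + k - 1L) %in% query_kmers]
      for (o in occ) hit[o:(o + k - 1L)] <- 1
      cov <- rbind(cov, hit)
    }
    if (nrow(cov) == 0L) stop("no usable windows in a junction set")
    colMeans(cov)
  })
  sm <- function(x) {
    half <- smooth %/% 2L
    vapply(seq_along(x), function(i) {
      mean(x[max(1L, i - half):min(length(x), i + half)])
    }, numeric(1))
  }
  reg <- sm(tracks$regulated); ctl <- sm(tracks$control)
  eps <- 1e-6
  structure(list(position = seq(-exon_extent, intron_extent - 1L),
                 regulated = reg, control = ctl,
                 ratio = (reg + eps) / (ctl + eps),
                 query_kmers = query_kmers, smooth = smooth),
            class = "motif_map")
}

#' @export
print.motif_map <- function(x, ...) {
  cat(sprintf("motif_map: %d positions [%d..%d], query %s; peak ratio %.2f at %+d\n",
              length(x$position), min(x$position), max(x$position),
              paste(x$query_kmers, collapse = ","),
              max(x$ratio), x$position[which.max(x$ratio)]))
  invisible(x)
}

#' Write an enrichment table or motif map as TSV
#'
#' @param x data.frame (enrichment table) or \code{motif_map}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_clip_tsv <- function(x, path) {
  if (inherits(x, "motif_map")) {
    x <- data.frame(position = x$position, regulated = x$regulated,
                    control = x$control, ratio = x$ratio)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
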