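#' Event classes recognised by the classifier, in stable report order
#' @export
EVENT_CLASSES <- c("annotated_cassette", "cryptic_internal_exon",
                   "alt5ss_extension", "alt5ss_truncation",
                   "alt3ss_extension", "alt3ss_truncation",
                   "exitron", "cryptic_terminal_exon", "complex")

.annotated_site_sets <- function(graph) {
  j <- graph$junctions
  anc <- .anchor_coords(j)
  list(junction = junction_key(j),
       donor = paste(j$chrom, j$strand, anc$donor),
       acceptor = paste(j$chrom, j$strand, anc$acceptor))
}

#' Flag de-novo junctions and splice sites
#'
#' A junction is annotated iff its intron 4-tuple is in the splice graph's
#' annotated junction set; each splice site is annotated iff that coordinate
#' is the donor (or acceptor) of any annotated junction on the same strand.
#' Splice sites never seen in the annotation are "de-novo" (cryptic
#' candidates).
#'
#' @param junctions data.frame of junction rows (\code{chrom}, \code{start},
#'   \code{end}, \code{strand}).
#' @param graph A \code{splice_graph}.
#' @return data.frame with logical columns \code{junction_annotated},
#'   \code{donor_annotated}, \code{acceptor_annotated}.
#' @export
flag_de_novo <- function(junctions, graph) {
  sets <- .annotated_site_sets(graph)
  anc <- .anchor_coords(junctions)
  data.frame(
    junction_annotated = junction_key(junctions) %in% sets$junction,
    donor_annotated = paste(junctions$chrom, junctions$strand, anc$donor) %in%
      sets$donor,
    acceptor_annotated = paste(junctions$chrom, junctions$strand,
                               anc$acceptor) %in% sets$acceptor)
}

#' Junction-read asymmetry ratio
#'
#' Ratio of reads on the junction splicing *into* an exon to reads on the
#' junction splicing *out* of it. A large ratio (the worked testis case shows
#' 14-fold) indicates transcripts that enter the exon but terminate rather
#' than splice on — the signature of a terminal exon. Returns \code{Inf} when
#' there are inclusion reads but no splice-out reads; errors when both counts
#' are zero (the ratio is undefined, not 0 or 1).
#'
#' @param inclusion_count Reads on the inclusion junction.
#' @param splice_out_count Reads on the splice-out junction.
#' @return Numeric ratio (possibly \code{Inf}).
#' @export
junction_asymmetry_ratio <- function(inclusion_count, splice_out_count) {
  stopifnot(inclusion_count >= 0, splice_out_count >= 0)
  if (inclusion_count == 0 && splice_out_count == 0) {
    stop("asymmetry ratio undefined: both junction counts are zero")
  }
  if (splice_out_count == 0) return(Inf)
  inclusion_count / splice_out_count
}

# pooled count of reads on junctions matching (chrom, coord-at, strand);
# side = "end" matches junction end == coord, "start" matches start == coord
.junction_reads_at <- function(table, chrom, coord, strand, side) {
  j <- table$junctions
  hit <- j$chrom == chrom & j$strand == strand &
    (if (side == "end") j$end == coord else j$start == coord)
  if (!any(hit)) 0L else sum(table$counts[hit, , drop = FALSE])
}

#' Detect terminal-exon evidence for a candidate exon
#'
#' Evidence requires (a) junction-read asymmetry: reads splicing into the
#' exon outnumber reads splicing out of it by at least \code{min_ratio}
#' (splice-out count 0 counts as infinite asymmetry), and (b) a
#' polyadenylation signal hexamer (default exactly AATAAA) on the transcribed
#' strand within \code{window_nt} downstream of the exon's 3' end; the most
#' proximal hit is reported.
#'
#' @param exon List or one-row data.frame with \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (0-based half-open).
#' @param table A \code{junction_counts}.
#' @param genome A \code{genome_seq}.
#' @param window_nt Search window downstream of the exon 3' end (default
#'   500).
#' @param signal_set Uppercase polyA signal hexamers (default "AATAAA").
#' @param min_ratio Minimum asymmetry ratio (default 5).
#' @return List with \code{exon}, \code{inclusion_count},
#'   \code{splice_out_count}, \code{asymmetry_ratio} and \code{polya}
#'   (signal, offset downstream, genomic start), or \code{NULL} when the
#'   evidence requirements are not met.
#' @export
detect_terminal_exon <- function(exon, table, genome, window_nt = 500L,
                                 signal_set = "AATAAA", min_ratio = 5) {
  stopifnot(window_nt > 0L, length(signal_set) >= 1L,
            all(signal_set == toupper(signal_set)))
  exon <- as.list(exon)
  L <- nchar(genome[[exon$chrom]])
  if (is.null(L) || exon$start < 0L || exon$end > L) {
    stop("exon outside genome bounds")
  }
  plus <- exon$strand == "+"
  incl <- .junction_reads_at(table, exon$chrom,
                             if (plus) exon$start else exon$end,
                             exon$strand, if (plus) "end" else "start")
  sout <- .junction_reads_at(table, exon$chrom,
                             if (plus) exon$end else exon$start,
                             exon$strand, if (plus) "start" else "end")
  if (incl == 0L && sout == 0L) return(NULL)
  ratio <- junction_asymmetry_ratio(incl, sout)
  if (ratio < min_ratio) return(NULL)

  # downstream window in transcript orientation, truncated at the chromosome
  if (plus) {
    w_end <- min(L, exon$end + window_nt)
    if (w_end - exon$end < 6L) return(NULL)
    seq <- genome_fetch(genome, exon$chrom, exon$end, w_end)
  } else {
    w_start <- max(0L, exon$start - window_nt)
    if (exon$start - w_start < 6L) return(NULL)
    seq <- genome_fetch(genome, exon$chrom, w_start, exon$start, strand = "-")
  }
  offs <- vapply(signal_set, function(s) {
    m <- regexpr(s, seq, fixed = TRUE)
    if (m < 0L) NA_integer_ else as.integer(m) - 1L
  }, integer(1))
  if (all(is.na(offs))) return(NULL)
  best <- which.min(offs)
  off <- offs[best]
  gpos <- if (plus) exon$end + off else exon$start - off - 6L
  list(exon = exon[c("chrom", "start", "end", "strand")],
       inclusion_count = incl, splice_out_count = sout,
       asymmetry_ratio = ratio,
       polya = list(signal = signal_set[best], offset = unname(off),
                    genomic_start = unname(gpos)))
}

.site_annotated <- function(graph, chrom, coord, strand, kind) {
  sets <- .annotated_site_sets(graph)
  paste(chrom, strand, coord) %in% sets[[kind]]
}

# which splice-site kind sits at a junction's genomic start/end
.kind_at <- function(strand, side) {
  if (side == "start") { if (strand == "+") "donor" else "acceptor" }
  else                 { if (strand == "+") "acceptor" else "donor" }
}

#' Classify one splicing event
#'
#' Applies the cryptic-event taxonomy to a set of changing junctions plus a
#' reference junction, in fixed rule order: (1) exitron — a single changing
#' junction lying strictly inside one annotated exon; (2) cassette-type — two
#' changing junctions delimiting an exon-sized interval, promoted to
#' cryptic_terminal_exon when terminal-exon evidence (read asymmetry plus a
#' downstream polyA signal) is found, otherwise cryptic_internal_exon if
#' either internal splice site is de-novo, else annotated_cassette;
#' (3) alt 5' splice site — changing and reference share the acceptor;
#' (4) alt 3' splice site — they share the donor; extension when the
#' alternative site is intronic relative to the annotated exon (mRNA grows),
#' truncation when exonic (mRNA shrinks); (5) complex otherwise.
#' delta_length is the signed change in mature mRNA length.
#'
#' @param changing data.frame of one or two changing junctions.
#' @param reference One-row data.frame: the reference junction (annotated
#'   member with the highest pooled count), or NULL.
#' @param graph A \code{splice_graph}.
#' @param genome A \code{genome_seq}.
#' @param table Optional \code{junction_counts} (needed for terminal-exon
#'   evidence).
#' @param terminal_cfg List of \code{window_nt}, \code{signal_set},
#'   \code{min_ratio} passed to \code{\link{detect_terminal_exon}}.
#' @return List describing the event: \code{class}, \code{chrom},
#'   \code{strand}, \code{junctions}, \code{reference}, \code{de_novo},
#'   \code{dinucleotides}, \code{delta_length}, \code{region_start},
#'   \code{region_end} (the inserted or removed genomic interval),
#'   \code{noncanonical_gc_donor} and optional \code{terminal_evidence}.
#' @export
classify_event <- function(changing, reference, graph, genome, table = NULL,
                           terminal_cfg = list(window_nt = 500L,
                                               signal_set = "AATAAA",
                                               min_ratio = 5)) {
  stopifnot(nrow(changing) %in% c(1L, 2L))
  allj <- rbind(changing[, c("chrom", "start", "end", "strand")],
                if (!is.null(reference))
                  reference[, c("chrom", "start", "end", "strand")])
  if (length(unique(allj$strand)) > 1L || length(unique(allj$chrom)) > 1L) {
    stop("event junctions on mixed strands or chromosomes")
  }
  strand <- allj$strand[1L]; chrom <- allj$chrom[1L]
  dn <- flag_de_novo(changing, graph)
  dinu <- junction_dinucleotides(changing, genome)
  ev <- list(chrom = chrom, strand = strand, junctions = changing,
             reference = reference, de_novo = dn, dinucleotides = dinu,
             noncanonical_gc_donor = any(dinu$gc_donor))

  if (nrow(changing) == 1L) {
    j <- changing[1L, ]
    # (1) exitron: both splice sites strictly inside one annotated exon
    ex <- graph$exons
    inside <- ex$chrom == chrom & ex$strand == strand &
      ex$start < j$start & j$end < ex$end
    if (any(inside)) {
      ev$class <- "exitron"
      ev$delta_length <- -(j$end - j$start)
      ev$region_start <- j$start; ev$region_end <- j$end
      return(ev)
    }
    # (3)/(4) alternative splice sites against the reference junction
    if (!is.null(reference)) {
      r <- reference[1L, ]
      share_start <- j$start == r$start
      share_end <- j$end == r$end
      if (xor(share_start, share_end)) {
        shared_side <- if (share_start) "start" else "end"
        shared_kind <- .kind_at(strand, shared_side)
        # shared donor => the acceptor differs (alt 3'SS) and vice versa
        alt_kind <- if (shared_kind == "donor") "alt3ss" else "alt5ss"
        delta <- (r$end - r$start) - (j$end - j$start)
        ev$class <- paste0(alt_kind,
                           if (delta > 0) "_extension" else "_truncation")
        diffc <- if (share_start) c(j$end, r$end) else c(j$start, r$start)
        ev$delta_length <- delta
        ev$region_start <- min(diffc); ev$region_end <- max(diffc)
        return(ev)
      }
    }
    ev$class <- "complex"
    ev$delta_length <- NA_integer_
    ev$region_start <- NA_integer_; ev$region_end <- NA_integer_
    return(ev)
  }

  # two changing junctions: cassette-type geometry
  chg <- changing[order(changing$start), , drop = FALSE]
  j1 <- chg[1L, ]; j2 <- chg[2L, ]
  if (j1$end < j2$start) {
    exon <- list(chrom = chrom, start = j1$end, end = j2$start,
                 strand = strand)
    ev$region_start <- exon$start; ev$region_end <- exon$end
    ev$delta_length <- exon$end - exon$start
    if (!is.null(table)) {
      tev <- detect_terminal_exon(exon, table, genome,
                                  terminal_cfg$window_nt,
                                  terminal_cfg$signal_set,
                                  terminal_cfg$min_ratio)
      if (!is.null(tev)) {
        ev$class <- "cryptic_terminal_exon"
        ev$terminal_evidence <- tev
        return(ev)
      }
    }
    # internal boundary sites: j1's site at its end, j2's site at its start
    s1 <- .site_annotated(graph, chrom, j1$end, strand,
                          .kind_at(strand, "end"))
    s2 <- .site_annotated(graph, chrom, j2$start, strand,
                          .kind_at(strand, "start"))
    ev$class <- if (s1 && s2) "annotated_cassette" else "cryptic_internal_exon"
    return(ev)
  }
  ev$class <- "complex"
  ev$delta_length <- NA_integer_
  ev$region_start <- NA_integer_; ev$region_end <- NA_integer_
  ev
}

# reference junction of an LSV: annotated member with highest pooled count,
# ties broken by leftmost coordinate; falls back to highest-count member
.reference_junction <- function(members, graph, table) {
  idx <- match(junction_key(members), junction_key(table$junctions))
  pooled <- rowSums(table$counts[idx, , drop = FALSE])
  ann <- flag_de_novo(members, graph)$junction_annotated
  cand <- if (any(ann)) which(ann) else seq_len(nrow(members))
  cand[order(-pooled[cand], members$start[cand], members$end[cand])][1L]
}

#' Group high-confidence calls into events and classify them
#'
#' Takes the per-junction delta-PSI calls, keeps junctions at the requested
#' confidence tier, selects per LSV the changing junction (largest
#' E(delta-PSI), i.e. the junction gaining usage) and the reference junction,
#' merges the two LSVs of a cassette-type exon via their shared reference
#' (skip) junction — searching the count table for the partner inclusion
#' junction when only one side reaches the tier — and classifies each
#' resulting event.
#'
#' @param calls data.frame from \code{\link{call_delta_psi}}.
#' @param graph A \code{splice_graph}.
#' @param genome A \code{genome_seq}.
#' @param table A \code{junction_counts}.
#' @param tier Confidence tier required (default "V20"; "V10" accepts both).
#' @param terminal_cfg Passed to \code{\link{classify_event}}.
#' @return data.frame with one row per event (class, coordinates, de-novo
#'   flags, dinucleotides, delta_length, E(delta-PSI), tier); the full event
#'   objects are attached as attribute \code{"details"}.
#' @export
classify_events <- function(calls, graph, genome, table, tier = "V20",
                            terminal_cfg = list(window_nt = 500L,
                                                signal_set = "AATAAA",
                                                min_ratio = 5)) {
  want <- if (tier == "V10") c("V10", "V20") else "V20"
  hc <- calls[calls$tier %in% want, , drop = FALSE]
  recs <- list()
  for (id in unique(hc$lsv_id)) {
    mem <- calls[calls$lsv_id == id, , drop = FALSE]
    hcm <- hc[hc$lsv_id == id, , drop = FALSE]
    chg <- hcm[which.max(hcm$e_dpsi), , drop = FALSE]
    if (chg$e_dpsi <= 0) next  # the gaining junction sits in another LSV
    ref_i <- .reference_junction(mem, graph, table)
    ref <- mem[ref_i, , drop = FALSE]
    if (junction_key(ref) == junction_key(chg)) next
    recs[[length(recs) + 1L]] <- list(chg = chg, ref = ref)
  }
  if (length(recs) == 0L) {
    return(structure(.empty_events_df(), details = list()))
  }

  refkeys <- vapply(recs, function(r) junction_key(r$ref), character(1))
  chgkeys <- vapply(recs, function(r) junction_key(r$chg), character(1))
  used <- rep(FALSE, length(recs))
  events <- list()
  for (i in seq_along(recs)) {
    if (used[i]) next
    partner <- which(!used & refkeys == refkeys[i] & chgkeys != chgkeys[i])
    partner <- setdiff(partner, i)
    if (length(partner) >= 1L) {
      p <- partner[1L]
      used[c(i, p)] <- TRUE
      changing <- unique(rbind(
        recs[[i]]$chg[, c("chrom", "start", "end", "strand")],
        recs[[p]]$chg[, c("chrom", "start", "end", "strand")]))
      primary <- if (recs[[i]]$chg$e_dpsi >= recs[[p]]$chg$e_dpsi)
        recs[[i]]$chg else recs[[p]]$chg
      events[[length(events) + 1L]] <-
        list(changing = changing, reference = recs[[i]]$ref, call = primary)
      next
    }
    used[i] <- TRUE
    chg <- recs[[i]]$chg
    ref <- recs[[i]]$ref
    changing <- chg[, c("chrom", "start", "end", "strand")]
    # exitron junctions classify alone; never pair them into a cassette
    ex <- graph$exons
    is_exitron <- any(ex$chrom == chg$chrom & ex$strand == chg$strand &
                        ex$start < chg$start & chg$end < ex$end)
    # single-sided cassette: look in the table for the partner inclusion
    # junction sharing the reference's other anchor across an exon-sized gap
    share_start <- chg$start == ref$start
    share_end <- chg$end == ref$end
    if (!is_exitron && xor(share_start, share_end)) {
      tj <- table$junctions
      if (share_start) {
        cand <- tj$chrom == chg$chrom & tj$strand == chg$strand &
          tj$end == ref$end & tj$start > chg$end
      } else {
        cand <- tj$chrom == chg$chrom & tj$strand == chg$strand &
          tj$start == ref$start & tj$end < chg$start
      }
      cand <- cand & junction_key(tj) != junction_key(ref)
      if (any(cand)) {
        part <- tj[which(cand)[1L], , drop = FALSE]
        changing <- rbind(changing, part[, c("chrom", "start", "end",
                                             "strand")])
      }
    }
    events[[length(events) + 1L]] <-
      list(changing = changing, reference = ref, call = chg)
  }

  details <- vector("list", length(events))
  rows <- vector("list", length(events))
  for (k in seq_along(events)) {
    e <- events[[k]]
    cl <- classify_event(e$changing, e$reference, graph, genome, table,
                         terminal_cfg)
    cl$event_id <- sprintf("EV%04d", k)
    cl$gene_id <- .locate_gene(graph, cl$chrom, cl$strand,
                               min(e$changing$start), max(e$changing$end))
    cl$e_dpsi <- e$call$e_dpsi
    cl$tier <- e$call$tier
    details[[k]] <- cl
    rows[[k]] <- data.frame(
      event_id = cl$event_id, gene_id = cl$gene_id, class = cl$class,
      chrom = cl$chrom, strand = cl$strand,
      junctions = paste(junction_key(cl$junctions), collapse = ";"),
      reference = if (is.null(cl$reference)) NA_character_ else
        junction_key(cl$reference),
      any_de_novo = !all(cl$de_novo$junction_annotated),
      donor_dinuc = cl$dinucleotides$donor[1L],
      acceptor_dinuc = cl$dinucleotides$acceptor[1L],
      noncanonical_gc_donor = cl$noncanonical_gc_donor,
      delta_length = cl$delta_length,
      region_start = cl$region_start, region_end = cl$region_end,
      e_dpsi = cl$e_dpsi, tier = cl$tier)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, details = details)
}

.locate_gene <- function(graph, chrom, strand, start, end) {
  tx <- graph$transcripts
  hit <- tx$chrom == chrom & tx$strand == strand &
    tx$start <= start & end <= tx$end
  if (!any(hit)) return(NA_character_)
  tx$gene_id[which(hit)[1L]]
}

.empty_events_df <- function() {
  data.frame(event_id = character(), gene_id = character(),
             class = character(), chrom = character(), strand = character(),
             junctions = character(), reference = character(),
             any_de_novo = logical(), donor_dinuc = character(),
             acceptor_dinuc = character(), noncanonical_gc_donor = logical(),
             delta_length = integer(), region_start = integer(),
             region_end = integer(), e_dpsi = numeric(), tier = character())
}

#' Event-class proportion table
#'
#' @param events data.frame from \code{\link{classify_events}} (or anything
#'   with a \code{class} column), or a character vector of classes.
#' @return data.frame with \code{class}, \code{n}, \code{percent} (summing
#'   to 100), classes in stable taxonomy order; empty input gives an empty
#'   table.
#' @export
summarize_event_types <- function(events) {
  cls <- if (is.character(events)) events else events$class
  if (length(cls) == 0L) {
    return(data.frame(class = character(), n = integer(),
                      percent = numeric()))
  }
  tab <- table(factor(cls, levels = EVENT_CLASSES))
  tab <- tab[tab > 0L]
  data.frame(class = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(cls),
             row.names = NULL)
}
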