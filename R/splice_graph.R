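#' Build a splice graph from exon and CDS tables
#'
#' The splice graph is the package's coordinate model of the annotation:
#' transcripts with ordered exons, optional CDS bounds, and the set of
#' annotated splice junctions (introns) derivable from consecutive exons of
#' any transcript. All coordinates are 0-based half-open. A junction is keyed
#' by its intron interval plus strand, not by its flanking exons, so a
#' junction shared by several transcripts appears once.
#'
#' @param exons data.frame with columns \code{gene_id}, \code{transcript_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} (0-based
#'   half-open).
#' @param cds Optional data.frame with \code{transcript_id}, \code{cds_start},
#'   \code{cds_end} (genomic 0-based half-open bounds of the coding region).
#' @return A \code{splice_graph} object: list with \code{exons},
#'   \code{transcripts} and \code{junctions} data.frames.
#' @export
splice_graph <- function(exons, cds = NULL) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "start", "end",
                  "strand") %in% names(exons)))
  if (any(exons$end <= exons$start)) stop("exon with end <= start")
  if (!all(exons$strand %in% c("+", "-"))) stop("exon strand must be + or -")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  tx_ids <- unique(exons$transcript_id)
  tx_rows <- lapply(tx_ids, function(tid) {
    e <- exons[exons$transcript_id == tid, , drop = FALSE]
    if (length(unique(e$chrom)) > 1L || length(unique(e$strand)) > 1L) {
      stop("transcript spans multiple chromosomes or strands: ", tid)
    }
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
      stop("overlapping exons in transcript: ", tid)
    }
    data.frame(transcript_id = tid, gene_id = e$gene_id[1L],
               chrom = e$chrom[1L], strand = e$strand[1L],
               start = min(e$start), end = max(e$end),
               cds_start = NA_integer_, cds_end = NA_integer_)
  })
  transcripts <- do.call(rbind, tx_rows)
  rownames(transcripts) <- transcripts$transcript_id

  if (!is.null(cds) && nrow(cds) > 0L) {
    idx <- match(cds$transcript_id, transcripts$transcript_id)
    if (anyNA(idx)) stop("CDS for unknown transcript")
    transcripts$cds_start[idx] <- cds$cds_start
    transcripts$cds_end[idx] <- cds$cds_end
    bad <- !is.na(transcripts$cds_start) &
      (transcripts$cds_start < transcripts$start |
         transcripts$cds_end > transcripts$end)
    if (any(bad)) stop("CDS bounds outside transcript span")
  }

  jl <- lapply(tx_ids, function(tid) {
    e <- exons[exons$transcript_id == tid, , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    data.frame(chrom = e$chrom[1L],
               start = e$end[-nrow(e)], end = e$start[-1L],
               strand = e$strand[1L])
  })
  junctions <- unique(do.call(rbind, c(jl, list(
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character())))))
  junctions <- junctions[order(junctions$chrom, junctions$start,
                               junctions$end, junctions$strand), , drop = FALSE]
  rownames(junctions) <- NULL
  if (nrow(junctions) && any(junctions$end - junctions$start < 4L)) {
    stop("intron shorter than 4 nt (no room for donor and acceptor)")
  }

  structure(list(exons = exons, transcripts = transcripts,
                 junctions = junctions),
            class = "splice_graph")
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("splice_graph: %d gene(s), %d transcript(s), %d exon(s), %d annotated junction(s)\n",
              length(unique(x$transcripts$gene_id)), nrow(x$transcripts),
              nrow(x$exons), nrow(x$junctions)))
  invisible(x)
}

#' Read a GTF annotation into a splice graph
#'
#' Exon (and, when present, CDS) features carrying \code{gene_id} and
#' \code{transcript_id} attributes are converted from GTF 1-based inclusive
#' coordinates to the internal 0-based half-open convention, and the full
#' annotated junction set is derived from consecutive exons.
#'
#' @param path Path to a GTF file.
#' @return A \code{splice_graph}.
#' @export
read_annotation_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file does not exist: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stop("GTF contains no exon features")
  df <- data.frame(
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GTF 1-based -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  if (any(!df$strand %in% c("+", "-"))) stop("feature without +/- strand")
  exons <- df[df$type == "exon", c("gene_id", "transcript_id", "chrom",
                                   "start", "end", "strand")]
  cds_feats <- df[df$type == "CDS", , drop = FALSE]
  cds <- NULL
  if (nrow(cds_feats) > 0L) {
    cds <- do.call(rbind, lapply(split(cds_feats, cds_feats$transcript_id),
                                 function(e) {
      data.frame(transcript_id = e$transcript_id[1L],
                 cds_start = min(e$start), cds_end = max(e$end))
    }))
  }
  splice_graph(exons, cds)
}

#' Write a splice graph back to GTF
#'
#' Emits exon features (and CDS features for coding transcripts, trimmed to
#' the exon structure) with \code{gene_id}/\code{transcript_id} attributes.
#' Internal 0-based half-open coordinates are converted back to GTF 1-based
#' inclusive, so a read/write round trip reproduces the transcripts and the
#' junction set exactly.
#'
#' @param graph A \code{splice_graph}.
#' @param path Output GTF path.
#' @return Invisibly, \code{path}.
#' @export
write_annotation_gtf <- function(graph, path) {
  ex <- graph$exons
  rows <- list(data.frame(
    chrom = ex$chrom, src = "crypticsplice", type = "exon",
    start = ex$start + 1L, end = ex$end, strand = ex$strand,
    gene_id = ex$gene_id, transcript_id = ex$transcript_id))
  tx <- graph$transcripts
  coding <- tx[!is.na(tx$cds_start), , drop = FALSE]
  if (nrow(coding) > 0L) {
    cds_rows <- do.call(rbind, lapply(seq_len(nrow(coding)), function(i) {
      t1 <- coding[i, ]
      e <- ex[ex$transcript_id == t1$transcript_id, , drop = FALSE]
      s <- pmax(e$start, t1$cds_start)
      en <- pmin(e$end, t1$cds_end)
      keep <- s < en
      data.frame(chrom = e$chrom[keep], src = "crypticsplice", type = "CDS",
                 start = s[keep] + 1L, end = en[keep], strand = e$strand[keep],
                 gene_id = e$gene_id[keep],
                 transcript_id = e$transcript_id[keep])
    }))
    rows <- c(rows, list(cds_rows))
  }
  d <- do.call(rbind, rows)
  lines <- sprintf(
    "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    d$chrom, d$src, d$type, d$start, d$end, d$strand, d$gene_id,
    d$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Donor and acceptor dinucleotides of splice junctions
#'
#' Extracts the first and last two intronic bases of each junction in
#' transcript orientation: the donor is always the 5' splice-site side and
#' the acceptor the 3' side, so a canonical intron reads GT..AG on either
#' strand. GC donors (the minor spliceosomal variant seen at, e.g., exitron
#' donors) are flagged as non-canonical-GC rather than rejected.
#'
#' @param junctions data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (intron interval, 0-based half-open).
#' @param genome A \code{genome_seq}.
#' @return data.frame with \code{donor}, \code{acceptor}, \code{canonical}
#'   (GT-AG), \code{gc_donor} (GC-AG) columns aligned with the input rows.
#' @export
junction_dinucleotides <- function(junctions, genome) {
  n <- nrow(junctions)
  donor <- acceptor <- character(n)
  for (i in seq_len(n)) {
    j <- junctions[i, ]
    left <- genome_fetch(genome, j$chrom, j$start, j$start + 2L)
    right <- genome_fetch(genome, j$chrom, j$end - 2L, j$end)
    if (j$strand == "+") {
      donor[i] <- left; acceptor[i] <- right
    } else {
      donor[i] <- revcomp(right); acceptor[i] <- revcomp(left)
    }
  }
  data.frame(donor = donor, acceptor = acceptor,
             canonical = donor == "GT" & acceptor == "AG",
             gc_donor = donor == "GC" & acceptor == "AG")
}

#' Spliced transcript (mRNA) sequence
#'
#' @param graph A \code{splice_graph}.
#' @param transcript_id Transcript identifier.
#' @param genome A \code{genome_seq}.
#' @return Character scalar: the mature mRNA sequence in transcript
#'   orientation.
#' @export
transcript_mrna <- function(graph, transcript_id, genome) {
  e <- graph$exons[graph$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(e) == 0L) stop("unknown transcript: ", transcript_id)
  parts <- vapply(seq_len(nrow(e)), function(i) {
    genome_fetch(genome, e$chrom[i], e$start[i], e$end[i])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (e$strand[1L] == "-") revcomp(s) else s
}

#' Map a genomic position to a transcript (mRNA) offset
#'
#' @param graph A \code{splice_graph}.
#' @param transcript_id Transcript identifier.
#' @param pos Genomic position (0-based). Must fall in an exon of the
#'   transcript.
#' @return 0-based offset of that base in the mature mRNA.
#' @export
genomic_to_tx <- function(graph, transcript_id, pos) {
  e <- graph$exons[graph$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(e) == 0L) stop("unknown transcript: ", transcript_id)
  e <- e[order(e$start), , drop = FALSE]
  hit <- which(pos >= e$start & pos < e$end)
  if (length(hit) != 1L) stop("position ", pos, " not exonic in ", transcript_id)
  if (e$strand[1L] == "+") {
    off <- pos - e$start[hit]
    if (hit > 1L) off <- off + sum(e$end[seq_len(hit - 1L)] - e$start[seq_len(hit - 1L)])
  } else {
    off <- e$end[hit] - 1L - pos
    if (hit < nrow(e)) {
      rest <- seq(hit + 1L, nrow(e))
      off <- off + sum(e$end[rest] - e$start[rest])
    }
  }
  as.integer(off)
}
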