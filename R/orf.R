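#' Is a length change frame-preserving?
#'
#' A splicing event preserves the reading frame iff the signed change it
#' makes to the mature mRNA is a multiple of 3 (e.g. the 1407-nt and 1263-nt
#' in-frame deletions seen at long meiotic exons).
#'
#' @param delta_length Signed nucleotide change to the mRNA.
#' @return Logical.
#' @export
is_frame_preserving <- function(delta_length) {
  stopifnot(is.numeric(delta_length), delta_length == as.integer(delta_length))
  delta_length %% 3L == 0L
}

#' Codons affected by a frame-preserving event
#'
#' @param delta_length Frame-preserving signed nucleotide change.
#' @return \code{|delta_length| / 3} (e.g. a 1407-nt in-frame deletion
#'   removes coding information for 469 amino acids).
#' @export
codons_affected <- function(delta_length) {
  if (!is_frame_preserving(delta_length)) {
    stop("delta_length is not a multiple of 3: ", delta_length)
  }
  as.integer(abs(delta_length) %/% 3L)
}

#' Does an inserted sequence introduce a stop codon?
#'
#' Scans the inserted sequence, in transcript orientation, for an in-frame
#' stop. \code{phase} is the offset of the first complete codon within the
#' insertion (0, 1 or 2): the first \code{phase} bases complete the codon
#' interrupted at the insertion point and are not scanned as a codon start.
#' Incomplete trailing triplets are ignored.
#'
#' @param seq Uppercase insertion sequence, transcript orientation.
#' @param phase Offset of the first complete codon, in \{0, 1, 2\}.
#' @return Logical: TRUE iff any in-frame triplet is TAA, TAG or TGA.
#' @export
inserted_sequence_has_stop <- function(seq, phase) {
  if (!phase %in% 0:2) stop("phase out of range: ", phase)
  n <- nchar(seq)
  starts <- seq.int(phase + 1L, by = 3L,
                    length.out = max(0L, (n - phase) %/% 3L))
  if (length(starts) == 0L) return(FALSE)
  codons <- substring(seq, starts, starts + 2L)
  any(codons %in% c("TAA", "TAG", "TGA"))
}

# spliced coding sequence of a transcript, transcript orientation
.cds_sequence <- function(graph, tx_row, genome) {
  mrna <- transcript_mrna(graph, tx_row$transcript_id, genome)
  if (tx_row$strand == "+") {
    a <- genomic_to_tx(graph, tx_row$transcript_id, tx_row$cds_start)
    b <- genomic_to_tx(graph, tx_row$transcript_id, tx_row$cds_end - 1L)
  } else {
    a <- genomic_to_tx(graph, tx_row$transcript_id, tx_row$cds_end - 1L)
    b <- genomic_to_tx(graph, tx_row$transcript_id, tx_row$cds_start)
  }
  substr(mrna, a + 1L, b + 1L)
}

# number of coding nucleotides of the transcript strictly 5' of a genomic
# position that is the transcript-orientation start of an event region
.coding_nt_before <- function(graph, tx_row, pos) {
  e <- graph$exons[graph$exons$transcript_id == tx_row$transcript_id, ,
                   drop = FALSE]
  e <- e[order(e$start), , drop = FALSE]
  cs <- tx_row$cds_start; ce <- tx_row$cds_end
  tot <- 0L
  for (i in seq_len(nrow(e))) {
    s <- max(e$start[i], cs); en <- min(e$end[i], ce)
    if (s >= en) next
    if (tx_row$strand == "+") {
      tot <- tot + max(0L, min(en, pos) - s)
    } else {
      tot <- tot + max(0L, en - max(s, pos))
    }
  }
  as.integer(tot)
}

#' Assess the reading-frame impact of a splicing event
#'
#' Classifies the event's consequence for the protein: events whose affected
#' genomic region lies outside the CDS bounds (for instance a cryptic
#' terminal exon within the 5' UTR) are \code{noncoding}; otherwise the event
#' is \code{disruptive} when its length change breaks the frame or, for
#' insertions, when the inserted sequence carries an in-frame stop codon, and
#' \code{tolerated} otherwise. The phase at the insertion point is recomputed
#' from the annotated CDS start by walking the spliced transcript; GTF frame
#' attributes are never consulted.
#'
#' @param event An event list from \code{\link{classify_event}} (or a list
#'   with \code{chrom}, \code{strand}, \code{delta_length},
#'   \code{region_start}, \code{region_end} and \code{class}).
#' @param graph A \code{splice_graph}.
#' @param transcript_id Transcript to assess against; defaults to the
#'   longest-CDS transcript of the gene overlapping the event.
#' @param genome A \code{genome_seq}.
#' @return A one-row data.frame: \code{event_id}, \code{transcript_id},
#'   \code{delta_length}, \code{frame_preserving}, \code{introduces_stop},
#'   \code{codons_affected} (NA unless frame-preserving) and
#'   \code{disruption} in \{disruptive, tolerated, noncoding\}.
#' @export
assess_event <- function(event, graph, genome, transcript_id = NULL) {
  if (is.null(transcript_id)) {
    tx <- graph$transcripts
    cand <- tx$chrom == event$chrom & tx$strand == event$strand &
      tx$start <= event$region_start & event$region_end <= tx$end
    cand_tx <- tx[cand, , drop = FALSE]
    if (nrow(cand_tx) == 0L) stop("no transcript overlaps the event")
    cds_len <- ifelse(is.na(cand_tx$cds_start), -1L,
                      cand_tx$cds_end - cand_tx$cds_start)
    transcript_id <- cand_tx$transcript_id[which.max(cds_len)]
  }
  tx_row <- graph$transcripts[graph$transcripts$transcript_id ==
                                transcript_id, , drop = FALSE]
  if (nrow(tx_row) == 0L) stop("unknown transcript: ", transcript_id)
  tx_row <- as.list(tx_row[1L, ])
  ev_id <- if (!is.null(event$event_id)) event$event_id else NA_character_
  dl <- as.integer(event$delta_length)

  no_cds <- is.na(tx_row$cds_start)
  outside <- no_cds ||
    event$region_end <= tx_row$cds_start ||
    event$region_start >= tx_row$cds_end
  if (outside) {
    return(data.frame(event_id = ev_id, transcript_id = transcript_id,
                      delta_length = dl, frame_preserving = NA,
                      introduces_stop = NA, codons_affected = NA_integer_,
                      disruption = "noncoding"))
  }

  fp <- is_frame_preserving(dl)
  stop_hit <- FALSE
  pos5 <- if (event$strand == "+") event$region_start else event$region_end
  before <- .coding_nt_before(graph, tx_row, pos5)
  r <- before %% 3L
  cds_seq <- .cds_sequence(graph, tx_row, genome)
  if (dl > 0) {
    # insertion: scan every codon that contains inserted bases, including
    # the codons spanning the two splice boundaries, by extending the
    # insert with the partial reference codons on each side
    ins_seq <- genome_fetch(genome, event$chrom, event$region_start,
                            event$region_end, strand = event$strand)
    prefix <- if (r > 0L) substr(cds_seq, before - r + 1L, before) else ""
    need <- (3L - (r + dl) %% 3L) %% 3L
    suffix <- if (need > 0L) substr(cds_seq, before + 1L, before + need)
      else ""
    stop_hit <- inserted_sequence_has_stop(paste0(prefix, ins_seq, suffix),
                                           0L)
  } else if (dl < 0 && fp && r > 0L) {
    # frame-preserving deletion: the joined codon straddling the new
    # junction can itself become a stop
    removed <- event$region_end - event$region_start
    junction_codon <- paste0(
      substr(cds_seq, before - r + 1L, before),
      substr(cds_seq, before + removed + 1L, before + removed + 3L - r))
    stop_hit <- junction_codon %in% c("TAA", "TAG", "TGA")
  }
  disruption <- if (!fp || stop_hit) "disruptive" else "tolerated"
  data.frame(event_id = ev_id, transcript_id = transcript_id,
             delta_length = dl, frame_preserving = fp,
             introduces_stop = stop_hit,
             codons_affected = if (fp) codons_affected(dl) else NA_integer_,
             disruption = disruption)
}

#' Assess a whole event table
#'
#' @param events data.frame from \code{\link{classify_events}} (with
#'   attribute \code{"details"}).
#' @param graph A \code{splice_graph}.
#' @param genome A \code{genome_seq}.
#' @return data.frame, one row per event with a defined region.
#' @export
assess_events <- function(events, graph, genome) {
  details <- attr(events, "details")
  rows <- list()
  for (d in details) {
    if (is.na(d$region_start)) next
    rows[[length(rows) + 1L]] <- assess_event(d, graph, genome)
  }
  if (length(rows) == 0L) {
    return(data.frame(event_id = character(), transcript_id = character(),
                      delta_length = integer(), frame_preserving = logical(),
                      introduces_stop = logical(),
                      codons_affected = integer(), disruption = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
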