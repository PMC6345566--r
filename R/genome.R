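#' Read a genome FASTA into a genome_seq object
#'
#' Loads a (multi-record) FASTA file, uppercases every sequence and masks any
#' character outside the ACGTN alphabet to \code{N}. Ambiguity codes are
#' deliberately not expanded: any window containing \code{N} is later excluded
#' from motif and splice-site statistics rather than contributing fabricated
#' sequence content.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of chromosome sequences with class
#'   \code{genome_seq}.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  names(seqs) <- nm
  genome_seq(seqs)
}

#' Construct a genome_seq from named sequences
#'
#' @param seqs Named character vector, one uppercase ACGTN string per
#'   chromosome.
#' @return A \code{genome_seq} object.
#' @export
genome_seq <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome names")
  structure(seqs, class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq with", length(x), "chromosome(s):\n")
  for (nm in names(x)) cat(sprintf("  %s: %d bp\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Fetch genomic sequence by 0-based half-open interval
#'
#' All internal coordinates in this package are 0-based half-open, so
#' \code{genome_fetch(g, "c1", 0, 4)} returns the first four bases and the
#' returned string always has length \code{end - start}. Out-of-range access
#' is an error, never silently truncated.
#'
#' @param genome A \code{genome_seq}.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds.
#' @param strand If \code{"-"}, the reverse complement is returned.
#' @return A character scalar of length \code{end - start}.
#' @export
genome_fetch <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("chromosome absent from genome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (start < 0 || end > L || start >= end) {
    stop(sprintf("out-of-range access %s:[%d,%d) on chromosome of length %d",
                 chrom, start, end, L))
  }
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s) else s
}

#' Reverse complement of a DNA string (N-preserving)
#'
#' @param x Character scalar over ACGTN.
#' @return Reverse complement string.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read crosslink or region intervals from BED3/BED6
#'
#' BED coordinates are already 0-based half-open and pass through unchanged.
#' BED3 records default to the + strand; a \code{.} strand is also treated
#' as +.
#'
#' @param path Path to a BED3 or BED6 file.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf == 3L | nf >= 6L)) {
    stop("malformed BED: expected 3 or >=6 tab-separated columns, got ",
         paste(unique(nf[nf != 3L & nf < 6L]), collapse = ","), " columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.integer(vapply(fields, `[[`, character(1), 2L))
  end <- as.integer(vapply(fields, `[[`, character(1), 3L))
  if (anyNA(start) || anyNA(end)) stop("malformed BED: non-integer coordinates")
  if (any(start >= end)) stop("malformed BED: start >= end")
  strand <- rep("+", length(lines))
  has6 <- nf >= 6L
  if (any(has6)) {
    s6 <- vapply(fields[has6], `[[`, character(1), 6L)
    s6[!s6 %in% c("+", "-")] <- "+"
    strand[has6] <- s6
  }
  data.frame(chrom = chrom, start = start, end = end, strand = strand)
}

#' Write intervals as BED6
#'
#' @param x data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (0-based half-open).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_bed <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, x$start, x$end,
                   if (!is.null(x$name)) x$name else ".", x$strand)
  writeLines(lines, path)
  invisible(path)
}
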