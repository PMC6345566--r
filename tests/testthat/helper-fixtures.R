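# shared fixture builders (all fixtures are built in code at test time)

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a single-gene two-transcript graph on a 3-kb chromosome:
#   t1: exons [100,400) [700,1100) [1400,1800), CDS 150..1700
#   t2: exons [100,400) [1400,1800)  (skips the middle exon)
fixture_graph <- function(strand = "+") {
  exons <- data.frame(
    gene_id = "gA",
    transcript_id = rep(c("gA.t1", "gA.t2"), c(3L, 2L)),
    chrom = "c1",
    start = c(100L, 700L, 1400L, 100L, 1400L),
    end = c(400L, 1100L, 1800L, 400L, 1800L),
    strand = strand)
  cds <- data.frame(transcript_id = "gA.t1", cds_start = 150L,
                    cds_end = 1700L)
  splice_graph(exons, cds)
}

# genome for fixture_graph with canonical GT..AG introns
fixture_genome <- function(seed = 42L) {
  set.seed(seed)
  s <- strsplit(random_dna(3000), "", fixed = TRUE)[[1]]
  for (d in c(400L, 1100L)) s[(d + 1L):(d + 2L)] <- c("G", "T")
  for (a in c(700L, 1400L)) s[(a - 1L):a] <- c("A", "G")
  genome_seq(c(c1 = paste(s, collapse = "")))
}

# junction_counts with one sample per condition from simple count vectors
fixture_table <- function(junctions, counts_a, counts_b) {
  sj <- list(
    A1 = cbind(junctions, count = counts_a),
    B1 = cbind(junctions, count = counts_b))
  junction_count_table(sj, c("A", "B"))
}

dinuc_census <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) return(table(character(0)))
  table(paste0(chars[-length(chars)], chars[-1L]))
}

# independent oracle: translate reference and mutant CDS from the annotated
# start and ask whether the mutant still ends with the reference's tail
translate_oracle <- function(ref_cds, mut_cds) {
  aa <- function(x) {
    x <- substr(x, 1L, nchar(x) - nchar(x) %% 3L)
    p <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAString(x),
                            if.fuzzy.codon = "solve")))
    sub("\\*.*$", "", p)
  }
  refp <- aa(ref_cds)
  mutp <- aa(mut_cds)
  tail_len <- 8L
  ref_tail <- substr(refp, nchar(refp) - tail_len + 1L, nchar(refp))
  !endsWith(mutp, ref_tail)
}
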