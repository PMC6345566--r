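#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a two-genotype
#' design with three biological replicates per condition, planted cryptic
#' splicing events of every class switching from a low wild-type PSI to a
#' high knockout PSI (delta-PSI 0.5 by default), negative-binomial read
#' depth per local splicing variation with multinomial allocation, weak
#' cryptic splice sites (two mismatches from the consensus), equal planted
#' ESE density in cryptic and downstream exons, polyA signals at a fixed
#' distance downstream of terminal-exon plants, and a crosslink cohort in
#' which a configured fraction of windows carries a planted AA-containing
#' pentamer over a 40 percent GC background.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param events_per_class Planted events per class (default 20).
#' @param classes Event classes to plant.
#' @param psi_a,psi_b Cryptic-junction PSI in conditions A and B.
#' @param depth_mean Mean LSV read depth (default 100).
#' @param depth_dispersion Negative-binomial dispersion (default 0.1;
#'   variance = mu + dispersion * mu^2).
#' @param replicates Replicates per condition (default 3).
#' @param exon_len,intron_len Length ranges for ordinary exons/introns.
#' @param cryptic_exon_len Length range for planted cryptic exons.
#' @param weak_mismatches Mismatches from the splice-site consensus planted
#'   at cryptic internal-exon sites (default 2).
#' @param frame_disruptive_fraction Fraction of cryptic internal exons
#'   planted as frame-breaking or stop-containing (default 0.84).
#' @param ese_hexamers Planted ESE hexamer set.
#' @param ese_per_100nt Planted ESE hexamer density (default 3 per 100 nt).
#' @param polya_offset Distance from a terminal exon's 3' end to the planted
#'   AATAAA (default 60).
#' @param terminal_asymmetry Inclusion / splice-out read ratio planted at
#'   terminal exons (default 14, the worked testis case).
#' @param gc_donor_exitrons How many exitron plants get a GC (rather than
#'   GT) donor (default 1).
#' @param clip_n_sites,clip_pentamers,clip_plant_fraction,clip_background_gc
#'   Crosslink cohort: number of sites, planted pentamer(s) (every planted
#'   window receives each of them), fraction of windows carrying a plant,
#'   background GC content.
#' @param motif_map_offset Intronic offset at which the pentamer is planted
#'   downstream of each regulated (cryptic) donor (default 10).
#' @return A \code{sim_config} list.
#' @export
simulation_config <- function(seed = 1L,
                              events_per_class = 20L,
                              classes = c("cryptic_internal_exon",
                                          "annotated_cassette",
                                          "exitron",
                                          "alt5ss_extension",
                                          "alt5ss_truncation",
                                          "alt3ss_extension",
                                          "alt3ss_truncation",
                                          "cryptic_terminal_exon"),
                              psi_a = 0.05, psi_b = 0.55,
                              depth_mean = 100, depth_dispersion = 0.1,
                              replicates = 3L,
                              exon_len = c(150L, 250L),
                              intron_len = c(400L, 700L),
                              cryptic_exon_len = c(80L, 150L),
                              weak_mismatches = 2L,
                              frame_disruptive_fraction = 0.84,
                              ese_hexamers = c("GAAGAA", "AAGGAC"),
                              ese_per_100nt = 3,
                              polya_offset = 60L,
                              terminal_asymmetry = 14,
                              gc_donor_exitrons = 1L,
                              clip_n_sites = 600L,
                              clip_pentamers = "TGAAG",
                              clip_plant_fraction = 0.6,
                              clip_background_gc = 0.4,
                              motif_map_offset = 10L) {
  stopifnot(psi_a >= 0, psi_a <= 1, psi_b >= 0, psi_b <= 1,
            clip_plant_fraction >= 0, clip_plant_fraction <= 1,
            depth_mean > 0, replicates >= 1L)
  structure(as.list(environment()), class = "sim_config")
}

.rand_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# stop-free exon interior: T-free alphabet, so no TAA/TAG/TGA can arise in
# any frame or from plant boundaries
.rand_exon_dna <- function(n) {
  paste(sample(c("A", "C", "G"), n, replace = TRUE,
               prob = c(0.4, 0.3, 0.3)), collapse = "")
}

.overwrite <- function(seqv, pos0, s) {
  # pos0: 0-based start within character vector seqv
  seqv[(pos0 + 1L):(pos0 + nchar(s))] <- strsplit(s, "", fixed = TRUE)[[1]]
  seqv
}

# donor: exonic CAG | intronic GTAAGT starting at intron start d (0-based).
# exonic_safe keeps the exonic CAG exact (variation and weak mismatches go
# to intronic positions only), so codons spanning a planted exon boundary
# can never become stop codons
.place_donor <- function(seqv, d, weak_mm = 0L, gc_donor = FALSE,
                         exonic_safe = FALSE) {
  win <- c("C", "A", "G", "G", "T", "A", "A", "G", "T")  # -3..+6
  if (gc_donor) win[5L] <- "C"  # GT -> GC, minor-class donor
  mutable <- if (exonic_safe) 6:9 else c(1:3, 6:9)  # never the GT/GC
  if (weak_mm > 0L) {
    at <- sample(mutable, weak_mm)
    for (i in at) {
      win[i] <- sample(setdiff(c("A", "C", "G", "T"), win[i]), 1L)
    }
  } else if (!exonic_safe) {
    # annotated sites: small natural variation outside the GT
    for (i in mutable) {
      if (stats::runif(1) < 0.15) {
        win[i] <- sample(setdiff(c("A", "C", "G", "T"), win[i]), 1L)
      }
    }
  }
  .overwrite(seqv, d - 3L, paste(win, collapse = ""))
}

# acceptor: 17-nt polypyrimidine tract + CAG ending the intron at e (0-based
# half-open end); exonic bases are left as-is
.place_acceptor <- function(seqv, e, weak_mm = 0L) {
  tract <- sample(c("C", "T"), 17L, replace = TRUE, prob = c(0.35, 0.65))
  win <- c(tract, "C", "A", "G")
  if (weak_mm > 0L) {
    at <- sample(1:17, weak_mm)
    win[at] <- sample(c("A", "G"), weak_mm, replace = TRUE)
  }
  .overwrite(seqv, e - 20L, paste(win, collapse = ""))
}

# remove accidental polyA signals from a region so planted ones are the only
# hits a search can find
.scrub_motif <- function(seqv, start0, end0, motifs) {
  s <- paste(seqv[(start0 + 1L):end0], collapse = "")
  for (m in motifs) {
    repeat {
      hit <- regexpr(m, s, fixed = TRUE)
      if (hit < 0L) break
      substr(s, hit + 2L, hit + 2L) <- "C"
    }
  }
  .overwrite(seqv, start0, s)
}

.plant_ese <- function(seqv, ex_start, ex_end, hexamers, per_100nt) {
  len <- ex_end - ex_start
  n <- max(1L, floor(len * per_100nt / 100))
  usable <- seq(ex_start + 5L, ex_end - 11L, by = 1L)
  if (length(usable) < n * 7L) n <- max(1L, length(usable) %/% 12L)
  # evenly spread, non-overlapping plants
  at <- ex_start + 5L + floor((seq_len(n) - 0.5) / n * (len - 16L))
  for (p in at) {
    seqv <- .overwrite(seqv, p, sample(hexamers, 1L))
  }
  seqv
}

.flip_iv <- function(start, end, L) list(start = L - end, end = L - start)

#' Generate a synthetic reference with planted cryptic events
#'
#' Builds one gene per chromosome (strands alternating), each with four
#' constitutive exons flanked by canonical splice sites (CAG|GTAAGT donors,
#' polypyrimidine + CAG acceptors) and an annotated CDS, and embeds one
#' planted event per gene according to the event plan: weak-site cryptic
#' internal exons carrying planted ESE hexamers, annotated cassette exons,
#' exon-internal donor/acceptor pairs (exitrons, optionally with a GC
#' donor), intronic or exonic alternative donors/acceptors at recorded
#' offsets, and cryptic terminal exons with an AATAAA planted at a fixed
#' downstream distance. Crosslink positions (with a fraction of windows
#' carrying the planted pentamer) and motif-map plants near regulated donors
#' are embedded in the same pass. Deterministic given the seed.
#'
#' @param config A \code{sim_config}.
#' @return List with \code{genome} (\code{genome_seq}), \code{graph}
#'   (\code{splice_graph}), \code{truth} (manifest list: \code{events}
#'   data.frame, \code{junction_roles} data.frame, \code{crosslinks},
#'   \code{motif}, \code{config} echo).
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  plan <- data.frame(
    class = rep(config$classes, each = config$events_per_class),
    stringsAsFactors = FALSE)
  n_genes <- nrow(plan)
  disruptive <- rep(FALSE, n_genes)
  ci <- which(plan$class == "cryptic_internal_exon")
  n_dis <- round(config$frame_disruptive_fraction * length(ci))
  disruptive[ci[seq_len(n_dis)]] <- TRUE
  # half of the disruptive plants break frame by length, half carry a stop
  stop_based <- rep(FALSE, n_genes)
  stop_based[ci[seq_len(n_dis %/% 2L)]] <- TRUE

  gc_left <- config$gc_donor_exitrons
  seqs <- list()
  exon_rows <- list(); cds_rows <- list(); role_rows <- list()
  event_rows <- list(); reg_junc <- list(); ctrl_junc <- list()
  clip_zone <- list()  # per gene: interval safe for crosslink plants

  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("g%03d", g)
    cls <- plan$class[g]
    strand <- if (g %% 2L == 0L) "-" else "+"

    E <- function() sample(seq(config$exon_len[1], config$exon_len[2]), 1L)
    I <- function() sample(seq(config$intron_len[1], config$intron_len[2]), 1L)
    e_len <- c(E(), E(), if (cls == "exitron") 900L else E(), E())
    # intron 3 is kept long: it hosts the crosslink-site cohort, which
    # needs room for well-separated +/-50 nt windows
    i_len <- c(I(), I(), sample(1500:1900, 1L))
    pad5 <- 200L; pad3 <- 700L

    # sense-orientation coordinates (0-based)
    e1s <- pad5; e1e <- e1s + e_len[1]
    e2s <- e1e + i_len[1]; e2e <- e2s + e_len[2]
    e3s <- e2e + i_len[2]; e3e <- e3s + e_len[3]
    e4s <- e3e + i_len[3]; e4e <- e4s + e_len[4]
    L <- e4e + pad3
    seqv <- strsplit(.rand_dna(L, config$clip_background_gc), "",
                     fixed = TRUE)[[1]]

    # constitutive splice sites
    for (d in c(e1e, e2e, e3e)) seqv <- .place_donor(seqv, d)
    for (a in c(e2s, e3s, e4s)) seqv <- .place_acceptor(seqv, a)
    # downstream comparison exon interior (stop-free, ESE-planted)
    seqv <- .overwrite(seqv, e3s + 3L, .rand_exon_dna(e3e - e3s - 6L))
    seqv <- .plant_ese(seqv, e3s, e3e, config$ese_hexamers,
                       config$ese_per_100nt)

    tx <- sprintf("%s.t1", gene_id)
    ex_tpl <- data.frame(gene_id = gene_id, transcript_id = tx,
                         chrom = gene_id,
                         start = c(e1s, e2s, e3s, e4s),
                         end = c(e1e, e2e, e3e, e4e), strand = "+")
    # terminal-exon genes start their CDS in exon 2, so the cryptic exon
    # planted in intron 1 sits in the 5' UTR (noncoding impact)
    cds_tpl <- data.frame(
      transcript_id = tx,
      cds_start = if (cls == "cryptic_terminal_exon") e2s + 10L else
        e1s + 10L,
      cds_end = e4e - 10L)
    const_j <- data.frame(start = c(e1e, e2e, e3e),
                          end = c(e2s, e3s, e4s))
    roles <- data.frame(start = const_j$start, end = const_j$end,
                        role = "constitutive", event = NA_character_)
    ev <- NULL
    extra_exons <- NULL; extra_cds <- NULL

    if (cls %in% c("cryptic_internal_exon", "annotated_cassette",
                   "cryptic_terminal_exon")) {
      terminal <- cls == "cryptic_terminal_exon"
      host_s <- if (terminal) e1e else e2e   # intron 1 (5' UTR) or intron 2
      host_e <- if (terminal) e2s else e3s
      cx_len <- sample(seq(config$cryptic_exon_len[1],
                           config$cryptic_exon_len[2]), 1L)
      if (cls == "cryptic_internal_exon") {
        if (disruptive[g] && !stop_based[g]) {
          if (cx_len %% 3L == 0L) cx_len <- cx_len + 1L
        } else {
          cx_len <- cx_len - cx_len %% 3L
        }
      }
      cxs <- host_s + ((host_e - host_s - cx_len) %/% 2L)
      cxe <- cxs + cx_len
      seqv <- .overwrite(seqv, cxs, .rand_exon_dna(cx_len))
      seqv <- .plant_ese(seqv, cxs, cxe, config$ese_hexamers,
                         config$ese_per_100nt)
      if (terminal) {
        # the comparison exon immediately downstream of a 5'-UTR terminal
        # plant is exon 2: give it the same planted ESE density
        seqv <- .plant_ese(seqv, e2s, e2e, config$ese_hexamers,
                           config$ese_per_100nt)
      }
      if (cls == "cryptic_internal_exon" && stop_based[g]) {
        # in-frame stop at a codon boundary of the insertion
        before <- (e1e - cds_tpl$cds_start) + (e2e - e2s)
        phase <- (3L - before %% 3L) %% 3L
        seqv <- .overwrite(seqv, cxs + phase + 9L, "TAA")
      }
      weak <- if (cls == "annotated_cassette") 0L else config$weak_mismatches
      seqv <- .place_acceptor(seqv, cxs, weak_mm = weak)
      seqv <- .place_donor(seqv, cxe, weak_mm = weak,
                           exonic_safe = cls == "cryptic_internal_exon")
      if (cls == "cryptic_internal_exon") {
        # keep the upstream exon's terminal codon bases stop-safe so the
        # planted tolerated/disruptive status survives boundary codons
        seqv <- .place_donor(seqv, host_s, exonic_safe = TRUE)
      }
      if (terminal) {
        win_end <- min(L, cxe + 500L)
        seqv <- .scrub_motif(seqv, cxe, win_end, "AATAAA")
        seqv <- .overwrite(seqv, cxe + config$polya_offset, "AATAAA")
      }
      if (cls == "annotated_cassette") {
        tx2 <- sprintf("%s.t2", gene_id)
        extra_exons <- data.frame(
          gene_id = gene_id, transcript_id = tx2, chrom = gene_id,
          start = c(e1s, e2s, cxs, e3s, e4s),
          end = c(e1e, e2e, cxe, e3e, e4e), strand = "+")
        extra_cds <- data.frame(transcript_id = tx2,
                                cds_start = e1s + 10L, cds_end = e4e - 10L)
      }
      roles <- rbind(roles, data.frame(
        start = c(host_s, cxe), end = c(cxs, host_e),
        role = c("incl_left", "incl_right"), event = gene_id))
      roles$role[roles$start == host_s & roles$end == host_e] <- "skip"
      roles$event[roles$role == "skip"] <- gene_id
      reg_junc[[gene_id]] <- data.frame(start = cxe, end = host_e)
      ev <- data.frame(region_start = cxs, region_end = cxe,
                       delta_length = cx_len)
    } else if (cls == "exitron") {
      # internal donor/acceptor pair inside the long exon 3; removed
      # segment a multiple of 3 (frame-preserving deletion)
      d_int <- e3s + 150L
      rm_len <- 501L
      a_int <- d_int + rm_len
      gc_don <- gc_left > 0L
      if (gc_don) gc_left <- gc_left - 1L
      seqv <- .place_donor(seqv, d_int, gc_donor = gc_don)
      seqv <- .place_acceptor(seqv, a_int)
      roles <- rbind(roles, data.frame(
        start = c(d_int, e2e), end = c(a_int, a_int),
        role = c("cryptic_single", "companion"), event = gene_id))
      reg_junc[[gene_id]] <- data.frame(start = d_int, end = a_int)
      ev <- data.frame(region_start = d_int, region_end = a_int,
                       delta_length = -rm_len)
    } else if (cls %in% c("alt5ss_extension", "alt5ss_truncation",
                          "alt3ss_extension", "alt3ss_truncation")) {
      delta <- 3L * sample(20:45, 1L) +
        sample(0:2, 1L, prob = c(0.4, 0.3, 0.3))
      if (cls == "alt5ss_extension") {        # donor moved into intron 2
        site <- e2e + delta
        seqv <- .place_donor(seqv, site, weak_mm = config$weak_mismatches)
        jx <- c(site, e3s); region <- c(e2e, site); dl <- delta
      } else if (cls == "alt5ss_truncation") { # donor inside exon 2
        site <- e2e - delta
        seqv <- .place_donor(seqv, site, weak_mm = config$weak_mismatches)
        jx <- c(site, e3s); region <- c(site, e2e); dl <- -delta
      } else if (cls == "alt3ss_extension") {  # acceptor moved into intron 2
        site <- e3s - delta
        seqv <- .place_acceptor(seqv, site, weak_mm = config$weak_mismatches)
        jx <- c(e2e, site); region <- c(site, e3s); dl <- delta
      } else {                                 # acceptor inside exon 3
        site <- e3s + delta
        seqv <- .place_acceptor(seqv, site, weak_mm = config$weak_mismatches)
        jx <- c(e2e, site); region <- c(e3s, site); dl <- -delta
      }
      roles <- rbind(roles, data.frame(
        start = jx[1], end = jx[2], role = "cryptic_single",
        event = gene_id))
      roles$role[roles$start == e2e & roles$end == e3s] <- "skip"
      roles$event[roles$role == "skip"] <- gene_id
      reg_junc[[gene_id]] <- data.frame(start = jx[1], end = jx[2])
      ev <- data.frame(region_start = region[1], region_end = region[2],
                       delta_length = dl)
    }
    ctrl_junc[[gene_id]] <- data.frame(start = e3e, end = e4s)
    # motif-map plant at a fixed intronic offset downstream of the
    # regulated (cryptic) donor, clear of the donor consensus itself
    if (!is.null(reg_junc[[gene_id]])) {
      seqv <- .overwrite(seqv,
                         reg_junc[[gene_id]]$start[1L] + 6L +
                           config$motif_map_offset,
                         config$clip_pentamers[1L])
    }
    zone <- c(e3e + 160L, e4s - 80L)

    # strand flip: reverse-complement the chromosome, mirror coordinates
    if (strand == "-") {
      seqs[[gene_id]] <- revcomp(paste(seqv, collapse = ""))
      flip <- function(df) {
        iv <- .flip_iv(df$start, df$end, L)
        df$start <- iv$start; df$end <- iv$end
        df
      }
      ex_tpl <- flip(ex_tpl); ex_tpl$strand <- "-"
      if (!is.null(extra_exons)) {
        extra_exons <- flip(extra_exons); extra_exons$strand <- "-"
      }
      civ <- .flip_iv(cds_tpl$cds_start, cds_tpl$cds_end, L)
      cds_tpl$cds_start <- civ$start; cds_tpl$cds_end <- civ$end
      if (!is.null(extra_cds)) {
        civ <- .flip_iv(extra_cds$cds_start, extra_cds$cds_end, L)
        extra_cds$cds_start <- civ$start; extra_cds$cds_end <- civ$end
      }
      roles <- flip(roles)
      reg_junc[[gene_id]] <- flip(reg_junc[[gene_id]])
      ctrl_junc[[gene_id]] <- flip(ctrl_junc[[gene_id]])
      if (!is.null(ev)) {
        iv <- .flip_iv(ev$region_start, ev$region_end, L)
        ev$region_start <- iv$start; ev$region_end <- iv$end
      }
      zone <- c(L - zone[2L], L - zone[1L])
    } else {
      seqs[[gene_id]] <- paste(seqv, collapse = "")
    }
    clip_zone[[gene_id]] <- zone

    roles$chrom <- gene_id; roles$strand <- strand; roles$gene <- gene_id
    reg_junc[[gene_id]]$chrom <- gene_id
    reg_junc[[gene_id]]$strand <- strand
    ctrl_junc[[gene_id]]$chrom <- gene_id
    ctrl_junc[[gene_id]]$strand <- strand
    exon_rows[[g]] <- rbind(ex_tpl, extra_exons)
    cds_rows[[g]] <- rbind(cds_tpl, extra_cds)
    role_rows[[g]] <- roles
    if (!is.null(ev)) {
      event_rows[[g]] <- cbind(
        data.frame(event = gene_id, gene_id = gene_id, class = cls,
                   chrom = gene_id, strand = strand,
                   psi_a = config$psi_a, psi_b = config$psi_b,
                   frame_disruptive = if (cls == "cryptic_internal_exon")
                     disruptive[g] else NA),
        ev)
    }
  }

  genome <- genome_seq(unlist(seqs))
  graph <- splice_graph(do.call(rbind, exon_rows), do.call(rbind, cds_rows))
  junction_roles <- do.call(rbind, role_rows)
  rownames(junction_roles) <- NULL

  # crosslink cohort: intronic sites, a fraction of whose +/-50 windows
  # carry every configured pentamer
  flank <- 50L
  pents <- config$clip_pentamers
  k <- unique(nchar(pents))
  if (length(k) != 1L) stop("clip pentamers must share one length")
  n_plant <- round(config$clip_n_sites * config$clip_plant_fraction)
  cl_rows <- list()
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  # round-robin over genes, with sites spread evenly through each gene's
  # zone so windows do not pile up on the same sequence
  gene_of <- rep(gene_ids, length.out = config$clip_n_sites)
  pos_pool <- list()
  for (gid in unique(gene_of)) {
    zone <- clip_zone[[gid]]
    lo <- zone[1L] + flank; hi <- zone[2L] - flank
    m <- sum(gene_of == gid)
    stride <- (hi - lo) / m
    p <- lo + round((seq_len(m) - 0.5) * stride) +
      sample(-10:10, m, replace = TRUE)
    pos_pool[[gid]] <- as.integer(pmin(hi, pmax(lo, p)))
  }
  used <- stats::setNames(rep(0L, length(unique(gene_of))), unique(gene_of))
  for (i in seq_len(config$clip_n_sites)) {
    gid <- gene_of[i]
    gl <- nchar(genome[[gid]])
    gstrand <- if (match(gid, gene_ids) %% 2L == 0L) "-" else "+"
    used[[gid]] <- used[[gid]] + 1L
    pos <- pos_pool[[gid]][used[[gid]]]
    planted <- i <= n_plant
    if (planted) {
      # plant one contiguous cassette: with several pentamers they are
      # joined by AA spacers, so every k-mer the cassette contributes
      # (including the bridges) still carries the AA dinucleotide when the
      # pentamers themselves start and end with A
      cassette <- paste(pents, collapse = if (length(pents) > 1L) "AA"
                        else "")
      cl <- nchar(cassette)
      off <- sample(seq(-flank + 2L, flank - 1L - cl), 1L)
      s <- if (gstrand == "+") pos + off else pos - off - cl
      genome[[gid]] <- paste0(substr(genome[[gid]], 1L, s),
                              if (gstrand == "+") cassette else
                                revcomp(cassette),
                              substr(genome[[gid]], s + cl + 1L, gl))
    }
    cl_rows[[i]] <- data.frame(chrom = gid, start = pos, end = pos + 1L,
                               strand = gstrand, planted = planted)
  }
  crosslink_sites <- do.call(rbind, cl_rows)

  truth <- list(
    events = do.call(rbind, event_rows),
    junction_roles = junction_roles,
    crosslinks = list(pentamers = config$clip_pentamers,
                      plant_fraction = config$clip_plant_fraction,
                      sites = crosslink_sites),
    motif = list(pentamer = config$clip_pentamers[1L],
                 intron_offset = config$motif_map_offset + 6L,
                 regulated = do.call(rbind, reg_junc),
                 control = do.call(rbind, ctrl_junc)),
    config = unclass(config))
  rownames(truth$events) <- NULL
  rownames(truth$motif$regulated) <- NULL
  rownames(truth$motif$control) <- NULL
  list(genome = genome, graph = graph, truth = truth)
}

#' Simulate junction counts for the planted design
#'
#' Per planted event and replicate: total LSV reads are drawn
#' negative-binomially (or fixed at the mean when \code{exact}) and
#' allocated to member junctions multinomially using the condition's planted
#' PSI; condition A uses PSI_A, condition B PSI_B. Constitutive junctions
#' get independent depth draws. Terminal-exon splice-out counts follow the
#' planted asymmetry ratio.
#'
#' @param reference List from \code{\link{generate_reference}}.
#' @param config The same \code{sim_config}.
#' @param exact Logical: if TRUE, use expected counts (noise-free) instead
#'   of random draws.
#' @return A \code{junction_counts} object with samples A1..An, B1..Bn.
#' @export
simulate_junction_counts <- function(reference, config, exact = FALSE) {
  set.seed(config$seed + 104729L)
  roles <- reference$truth$junction_roles
  events <- reference$truth$events
  size <- 1 / config$depth_dispersion
  mu <- config$depth_mean
  draw_T <- function() {
    if (exact) as.integer(round(mu)) else
      stats::rnbinom(1L, size = size, mu = mu)
  }
  draw_I <- function(T, p) {
    if (exact) as.integer(round(T * p)) else stats::rbinom(1L, T, p)
  }

  sample_ids <- c(paste0("A", seq_len(config$replicates)),
                  paste0("B", seq_len(config$replicates)))
  conditions <- rep(c("A", "B"), each = config$replicates)
  sj_list <- list()
  for (s in seq_along(sample_ids)) {
    psi <- if (conditions[s] == "A") config$psi_a else config$psi_b
    cnt <- integer(nrow(roles))
    for (eid in unique(stats::na.omit(roles$event))) {
      idx <- which(!is.na(roles$event) & roles$event == eid)
      r <- roles[idx, , drop = FALSE]
      cls <- events$class[events$event == eid]
      T <- draw_T()
      if (all(c("incl_left", "incl_right", "skip") %in% r$role)) {
        I <- draw_I(T, psi)
        left <- I
        right <- if (cls == "cryptic_terminal_exon") {
          as.integer(round(I / config$terminal_asymmetry))
        } else I
        cnt[idx[r$role == "incl_left"]] <- left
        cnt[idx[r$role == "incl_right"]] <- right
        cnt[idx[r$role == "skip"]] <- T - I
      } else {
        # binary LSV: cryptic junction vs its partner (annotated skip for
        # alt-SS events, companion junction for exitrons)
        cj <- draw_I(T, psi)
        cnt[idx[r$role == "cryptic_single"]] <- cj
        other <- idx[r$role %in% c("skip", "companion")]
        cnt[other] <- T - cj
      }
    }
    for (i in which(roles$role == "constitutive" & is.na(roles$event))) {
      cnt[i] <- draw_T()
    }
    sj_list[[sample_ids[s]]] <-
      data.frame(chrom = roles$chrom, start = roles$start, end = roles$end,
                 strand = roles$strand, count = cnt)
  }
  junction_count_table(sj_list, conditions)
}

#' Simulate the crosslink-site BED
#'
#' Materialises the crosslink cohort embedded by
#' \code{\link{generate_reference}}: single-base sites within gene bodies, a
#' configured fraction of whose +/- flank windows carry the planted
#' pentamer.
#'
#' @param reference List from \code{\link{generate_reference}}.
#' @param config The same \code{sim_config}.
#' @return data.frame of BED6-style sites (\code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{planted}).
#' @export
simulate_crosslinks <- function(reference, config) {
  reference$truth$crosslinks$sites
}

#' Write a complete simulated study to disk
#'
#' Emits \code{genome.fa}, \code{annotation.gtf}, \code{sj/<sample>.tab}
#' (SJ dialect), \code{crosslinks.bed}, \code{truth.json} and
#' \code{sample_sheet.tsv} under \code{dir}. Byte-identical across reruns
#' with the same config.
#'
#' @param config A \code{sim_config}.
#' @param dir Output directory (created if needed).
#' @param exact Noise-free counts (see
#'   \code{\link{simulate_junction_counts}}).
#' @return Invisibly, the reference list with \code{table} and \code{paths}
#'   added.
#' @export
simulate_study <- function(config, dir, exact = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "sj"), showWarnings = FALSE)
  ref <- generate_reference(config)
  table <- simulate_junction_counts(ref, config, exact = exact)

  fa <- Biostrings::DNAStringSet(unclass(ref$genome))
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fa"), width = 80L)
  write_annotation_gtf(ref$graph, file.path(dir, "annotation.gtf"))

  sheet <- data.frame(sample_id = table$samples$sample_id,
                      path = file.path("sj", paste0(table$samples$sample_id,
                                                    ".tab")),
                      condition = table$samples$condition)
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    cnt <- table$counts[, sid]
    keep <- cnt > 0L
    j <- table$junctions[keep, , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                     j$chrom, j$start + 1L, j$end,
                     ifelse(j$strand == "+", 1L, 2L),
                     1L, 1L, cnt[keep], 0L, 50L)
    writeLines(lines, file.path(dir, sheet$path[i]))
  }
  utils::write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- simulate_crosslinks(ref, config)
  write_bed(cl, file.path(dir, "crosslinks.bed"))
  jsonlite::write_json(ref$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  ref$table <- table
  ref$paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    crosslinks = file.path(dir, "crosslinks.bed"),
    truth = file.path(dir, "truth.json"))
  invisible(ref)
}
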