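# junction identity is the (chrom, intron_start, intron_end, strand) 4-tuple
junction_key <- function(j) {
  paste(j$chrom, j$start, j$end, j$strand, sep = ":")
}

#' Read one STAR-style splice-junction count table
#'
#' Parses the nine-column SJ.out.tab dialect (chrom, 1-based intron start,
#' 1-based inclusive intron end, strand code 0/1/2, motif code, annotated
#' flag, unique reads, multimapping reads, max overhang). Intron coordinates
#' are converted to 0-based half-open and the unique-read column is used as
#' the junction count. Strand code 0 rows are kept when the intron interval
#' matches an annotated junction (strand taken from the annotation),
#' otherwise dropped with a warning.
#'
#' @param path Path to the TSV.
#' @param graph Optional \code{splice_graph} used to resolve strand code 0.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{count}.
#' @export
read_sj_table <- function(path, graph = NULL) {
  if (!file.exists(path)) stop("SJ table does not exist: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", rep("integer", 8L)),
                         col.names = c("chrom", "start1", "end1", "strand_code",
                                       "motif", "annotated", "unique", "multi",
                                       "overhang"))
  if (any(d$unique < 0L)) stop("negative junction counts in ", path)
  if (!all(d$strand_code %in% 0:2)) stop("unparseable strand codes in ", path)
  out <- data.frame(chrom = d$chrom, start = d$start1 - 1L, end = d$end1,
                    strand = c("0", "+", "-")[d$strand_code + 1L],
                    count = d$unique)
  unk <- out$strand == "0"
  if (any(unk)) {
    if (!is.null(graph) && nrow(graph$junctions) > 0L) {
      ann <- graph$junctions
      akey <- paste(ann$chrom, ann$start, ann$end)
      m <- match(paste(out$chrom[unk], out$start[unk], out$end[unk]), akey)
      out$strand[unk][!is.na(m)] <- ann$strand[m[!is.na(m)]]
    }
    drop <- out$strand == "0"
    if (any(drop)) {
      warning(sum(drop), " undetermined-strand junction(s) without an ",
              "annotation match dropped from ", basename(path))
      out <- out[!drop, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Assemble a junction count table across samples
#'
#' @param sj_list Named list of per-sample data.frames as returned by
#'   \code{\link{read_sj_table}}; names are sample ids.
#' @param conditions Character vector (one per sample) of condition labels,
#'   e.g. \code{"A"}/\code{"B"}.
#' @return A \code{junction_counts} object: \code{junctions} data.frame,
#'   \code{samples} data.frame and a junction x sample integer \code{counts}
#'   matrix (missing junctions zero-filled).
#' @export
junction_count_table <- function(sj_list, conditions) {
  stopifnot(length(sj_list) == length(conditions), !is.null(names(sj_list)))
  all_j <- unique(do.call(rbind, lapply(sj_list, function(d)
    d[, c("chrom", "start", "end", "strand")])))
  all_j <- all_j[order(all_j$chrom, all_j$start, all_j$end, all_j$strand), ,
                 drop = FALSE]
  rownames(all_j) <- NULL
  key <- junction_key(all_j)
  counts <- matrix(0L, nrow = nrow(all_j), ncol = length(sj_list),
                   dimnames = list(key, names(sj_list)))
  for (s in names(sj_list)) {
    d <- sj_list[[s]]
    counts[match(junction_key(d), key), s] <- as.integer(d$count)
  }
  if (any(counts < 0L)) stop("negative counts")
  structure(list(junctions = all_j,
                 samples = data.frame(sample_id = names(sj_list),
                                      condition = conditions),
                 counts = counts),
            class = "junction_counts")
}

#' Read a sample sheet and its SJ tables
#'
#' @param sheet_path TSV with header columns \code{sample_id}, \code{path},
#'   \code{condition}; relative paths are resolved against the sheet's
#'   directory.
#' @param graph Optional \code{splice_graph} for strand resolution.
#' @return A \code{junction_counts} object.
#' @export
read_sj_samples <- function(sheet_path, graph = NULL) {
  sheet <- utils::read.table(sheet_path, sep = "\t", header = TRUE,
                             colClasses = "character")
  stopifnot(all(c("sample_id", "path", "condition") %in% names(sheet)))
  paths <- ifelse(file.exists(sheet$path), sheet$path,
                  file.path(dirname(sheet_path), sheet$path))
  sj <- lapply(paths, read_sj_table, graph = graph)
  names(sj) <- sheet$sample_id
  junction_count_table(sj, sheet$condition)
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts: %d junction(s) x %d sample(s) (%s)\n",
              nrow(x$junctions), nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$condition)),
                            table(x$samples$condition)), collapse = ", ")))
  invisible(x)
}

# strand-aware donor/acceptor anchor coordinates of junction rows
.anchor_coords <- function(j) {
  donor <- ifelse(j$strand == "+", j$start, j$end)
  acceptor <- ifelse(j$strand == "+", j$end, j$start)
  list(donor = donor, acceptor = acceptor)
}

#' Define local splicing variations (LSVs)
#'
#' An LSV is the set of junctions sharing one splice-site anchor: a common
#' donor coordinate forms a source LSV, a common acceptor a target LSV. Every
#' anchor with at least two junctions whose summed count across samples
#' reaches \code{min_total} yields one LSV; a junction may belong to both a
#' source and a target LSV.
#'
#' @param graph A \code{splice_graph} (chromosome sanity check only; LSVs are
#'   defined from observed junctions).
#' @param table A \code{junction_counts}.
#' @param min_total Minimum summed read count over all members and samples
#'   (default 10).
#' @return List of LSVs; each has \code{lsv_id}, \code{chrom}, \code{strand},
#'   \code{anchor}, \code{side} and a \code{junctions} data.frame of members.
#' @export
define_lsvs <- function(graph, table, min_total = 10L) {
  j <- table$junctions
  if (nrow(j) == 0L) return(list())
  if (!all(j$chrom %in% c(graph$exons$chrom, graph$junctions$chrom))) {
    stop("junction table contains chromosomes absent from the splice graph")
  }
  totals <- rowSums(table$counts)
  anc <- .anchor_coords(j)
  out <- list()
  for (side in c("source", "target")) {
    coord <- if (side == "source") anc$donor else anc$acceptor
    grp <- split(seq_len(nrow(j)), paste(j$chrom, j$strand, coord))
    for (g in grp) {
      if (length(g) < 2L) next
      if (sum(totals[g]) < min_total) next
      mem <- j[g, , drop = FALSE]
      mem <- mem[order(mem$start, mem$end), , drop = FALSE]
      lsv <- list(lsv_id = sprintf("%s:%s:%d:%s", mem$chrom[1L], mem$strand[1L],
                                   coord[g[1L]], side),
                  chrom = mem$chrom[1L], strand = mem$strand[1L],
                  anchor = coord[g[1L]], side = side, junctions = mem)
      out[[lsv$lsv_id]] <- lsv
    }
  }
  if (length(out) == 0L) return(list())
  out[order(names(out))]
}

.lsv_counts <- function(lsv, table) {
  idx <- match(junction_key(lsv$junctions), junction_key(table$junctions))
  if (anyNA(idx)) stop("LSV junction absent from count table")
  table$counts[idx, , drop = FALSE]
}

#' Posterior expected PSI within one condition
#'
#' Per replicate r the posterior over the LSV's junction proportions is
#' Dirichlet(c_rj + alpha); E(PSI_j) for the condition is the mean over
#' replicates of (c_rj + alpha) / (sum_k c_rk + J * alpha), where J is the
#' number of member junctions. Replicates are combined as an equal-weight
#' mixture, never pooled, preserving between-replicate variability.
#'
#' @param lsv One LSV from \code{\link{define_lsvs}}.
#' @param table A \code{junction_counts}.
#' @param condition Condition label.
#' @param alpha Dirichlet prior pseudocount (> 0, default 1).
#' @return List with \code{lsv_id}, \code{condition}, per-replicate
#'   \code{dirichlet} parameter matrix and \code{e_psi} (named numeric,
#'   sums to 1).
#' @export
estimate_psi <- function(lsv, table, condition, alpha = 1) {
  stopifnot(alpha > 0)
  sel <- table$samples$condition == condition
  if (!any(sel)) stop("condition has zero samples: ", condition)
  cts <- .lsv_counts(lsv, table)[, sel, drop = FALSE]
  par <- cts + alpha
  psi_rep <- sweep(par, 2L, colSums(par), "/")
  e_psi <- rowMeans(psi_rep)
  names(e_psi) <- junction_key(lsv$junctions)
  list(lsv_id = lsv$lsv_id, condition = condition, dirichlet = par,
       e_psi = e_psi)
}

#' Monte-Carlo delta-PSI with high-confidence tiers
#'
#' For each member junction, PSI is drawn \code{n_draws} times per condition:
#' each draw picks a replicate uniformly and samples that replicate's
#' Dirichlet posterior. delta-PSI = PSI_B - PSI_A. The call reports
#' E(delta-PSI) and P(|delta-PSI| >= V) for each V, and assigns the
#' confidence tier V20 (or V10) when that probability reaches
#' \code{threshold} at V = 0.2 (or 0.1). Deterministic given \code{seed}.
#'
#' @param lsv One LSV.
#' @param table A \code{junction_counts} with conditions A and B.
#' @param v_set Thresholds V (default c(0.1, 0.2)).
#' @param n_draws Monte-Carlo draws (>= 1000; default 10000).
#' @param alpha Dirichlet prior (default 1).
#' @param threshold Posterior probability required for a tier (default 0.95).
#' @param seed Integer seed.
#' @param conditions Length-2 character vector naming conditions (A, B).
#' @return data.frame, one row per member junction: \code{lsv_id},
#'   junction coordinates, \code{e_psi_a}, \code{e_psi_b}, \code{e_dpsi},
#'   one \code{p_ge_<V>} column per V, and \code{tier} in
#'   \{none, V10, V20\}.
#' @export
delta_psi <- function(lsv, table, v_set = c(0.1, 0.2), n_draws = 10000L,
                      alpha = 1, threshold = 0.95, seed = 1L,
                      conditions = c("A", "B")) {
  stopifnot(n_draws >= 1000L, alpha > 0)
  set.seed(seed)
  cts <- .lsv_counts(lsv, table)
  J <- nrow(cts)
  draws <- lapply(conditions, function(cond) {
    sel <- which(table$samples$condition == cond)
    if (length(sel) == 0L) stop("condition has zero samples: ", cond)
    par <- cts[, sel, drop = FALSE] + alpha
    rep_pick <- sample.int(length(sel), n_draws, replace = TRUE)
    g <- matrix(stats::rgamma(J * n_draws, shape = par[, rep_pick]),
                nrow = J)
    sweep(g, 2L, colSums(g), "/")
  })
  dpsi <- draws[[2L]] - draws[[1L]]

  psi_a <- estimate_psi(lsv, table, conditions[1L], alpha)$e_psi
  psi_b <- estimate_psi(lsv, table, conditions[2L], alpha)$e_psi
  out <- cbind(data.frame(lsv_id = lsv$lsv_id), lsv$junctions,
               data.frame(e_psi_a = unname(psi_a), e_psi_b = unname(psi_b),
                          e_dpsi = rowMeans(dpsi)))
  v_set <- sort(v_set)
  for (v in v_set) {
    out[[sprintf("p_ge_%g", v)]] <- rowMeans(abs(dpsi) >= v)
  }
  tier <- rep("none", J)
  if (0.1 %in% v_set) tier[out[["p_ge_0.1"]] >= threshold] <- "V10"
  if (0.2 %in% v_set) tier[out[["p_ge_0.2"]] >= threshold] <- "V20"
  out$tier <- tier
  rownames(out) <- NULL
  out
}

#' Quantify delta-PSI for every LSV in a table
#'
#' Convenience wrapper: defines LSVs and runs \code{\link{delta_psi}} on each
#' with a per-LSV seed derived deterministically from \code{seed}.
#'
#' @inheritParams delta_psi
#' @param graph A \code{splice_graph}.
#' @param min_total LSV read-support filter (see \code{\link{define_lsvs}}).
#' @return data.frame of per-junction calls across all LSVs.
#' @export
call_delta_psi <- function(graph, table, v_set = c(0.1, 0.2),
                           n_draws = 10000L, alpha = 1, threshold = 0.95,
                           seed = 1L, min_total = 10L,
                           conditions = c("A", "B")) {
  lsvs <- define_lsvs(graph, table, min_total)
  if (length(lsvs) == 0L) {
    return(data.frame(lsv_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), e_psi_a = numeric(),
                      e_psi_b = numeric(), e_dpsi = numeric(),
                      tier = character()))
  }
  res <- lapply(seq_along(lsvs), function(i) {
    delta_psi(lsvs[[i]], table, v_set, n_draws, alpha, threshold,
              seed = (seed + i) %% .Machine$integer.max,
              conditions = conditions)
  })
  do.call(rbind, res)
}
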