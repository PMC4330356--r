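#' Classify a control/d0/d21 methylation trajectory
#'
#' Threshold re-expression of the four demethylation/remethylation
#' patterns observed for single-copy loci, extended with STABLE, HYPER
#' and UNCLASSIFIED so that every trajectory receives exactly one
#' label.  Rules, in order:
#' \itemize{
#'   \item HYPER: `m_d21 >= m_control + 0.20` (a net methylation gain;
#'     checked first so that gains from a low starting level are not
#'     absorbed by the stability rule);
#'   \item STABLE: no quantifiable loss at d0
#'     (`m_control - m_d0 < 0.20`) and d21 within `recover_tol` of
#'     control;
#'   \item otherwise loss occurred; with recovery defined as
#'     `m_control - m_d21 < recover_tol`:
#'     P1 (full de-/re-methylation): `m_d0 < low` and recovered;
#'     P2 (partial demethylation/full remethylation):
#'     `low <= m_d0 <= partial_hi` and recovered;
#'     P3 (loss, no recovery): `m_d0 < low` and `m_d21 < low`;
#'     P4 (loss, incomplete recovery): not recovered, not P3;
#'     UNCLASSIFIED otherwise.
#' }
#'
#' @param m_control,m_d0,m_d21 Methylation fractions in \[0, 1\]
#'   (vectorised).
#' @param low Low-methylation threshold (default 0.20).
#' @param partial_hi Upper bound of partial demethylation at d0
#'   (default 0.75).
#' @param recover_tol Recovery tolerance on `m_control - m_d21`
#'   (default 0.20).
#' @return Factor with levels P1_full_de_re, P2_partial_de_full_re,
#'   P3_loss_no_recovery, P4_loss_incomplete_recovery, STABLE, HYPER,
#'   UNCLASSIFIED.
#' @export
classify_trajectory <- function(m_control, m_d0, m_d21, low = 0.20,
                                partial_hi = 0.75, recover_tol = 0.20) {
  stopifnot(all(m_control >= 0 & m_control <= 1),
            all(m_d0 >= 0 & m_d0 <= 1),
            all(m_d21 >= 0 & m_d21 <= 1))
  n <- max(length(m_control), length(m_d0), length(m_d21))
  mc <- rep_len(m_control, n); m0 <- rep_len(m_d0, n)
  m21 <- rep_len(m_d21, n)
  out <- rep("UNCLASSIFIED", n)
  hyper <- m21 >= mc + 0.20
  stable <- !hyper & (mc - m0 < 0.20) & (m21 >= mc - recover_tol)
  rest <- !hyper & !stable
  recovered <- (mc - m21) < recover_tol
  p1 <- rest & recovered & m0 < low
  p2 <- rest & recovered & m0 >= low & m0 <= partial_hi
  p3 <- rest & !recovered & m0 < low & m21 < low
  p4 <- rest & !recovered & !p3
  out[hyper] <- "HYPER"
  out[stable] <- "STABLE"
  out[p1] <- "P1_full_de_re"
  out[p2] <- "P2_partial_de_full_re"
  out[p3] <- "P3_loss_no_recovery"
  out[p4] <- "P4_loss_incomplete_recovery"
  factor(out, levels = c("P1_full_de_re", "P2_partial_de_full_re",
                         "P3_loss_no_recovery",
                         "P4_loss_incomplete_recovery",
                         "STABLE", "HYPER", "UNCLASSIFIED"))
}

#' Trajectory calls for every tile of a tile matrix
#'
#' @param tm A `"tile_matrix"` with control, d0 and d21 groups.
#' @param ... Thresholds passed to [classify_trajectory()].
#' @return data.frame: tile coordinates, the three group means and the
#'   `pattern` factor.
#' @export
tile_trajectories <- function(tm, ...) {
  stopifnot(inherits(tm, "tile_matrix"),
            all(c("control", "d0", "d21") %in% colnames(tm$meth_group)))
  res <- cbind(tm$tiles,
               data.frame(m_control = tm$meth_group[, "control"],
                          m_d0 = tm$meth_group[, "d0"],
                          m_d21 = tm$meth_group[, "d21"],
                          row.names = NULL))
  res$pattern <- classify_trajectory(res$m_control, res$m_d0,
                                     res$m_d21, ...)
  res
}

#' Rank candidate genes by fractional methylation loss at d21
#'
#' Per tile, the percentage of the original (control) methylation lost
#' by d21 is `100 * (m_control - m_d21) / m_control`; per gene, losses
#' of the gene's annotated tiles are averaged (the "average of
#' methylation averages of tiles associated to unique gene IDs").
#' Genes are returned in decreasing loss order with a loss bin label
#' (top bin `[85,100]`) and an imprinted flag.
#'
#' @param tiles data.frame with `tile_id`, `m_control` and `m_d21`
#'   columns (e.g. a [test_tile_ttest()] result renamed, or
#'   [tile_trajectories()] output).
#' @param annotation data.frame with `tile_id` and `gene_id` (see
#'   [annotate_tiles()]); tiles without a gene are ignored.
#' @param imprinted_genes Character vector of known imprinted gene ids.
#' @param breaks Loss-percentage bin boundaries.
#' @return data.frame of class `"candidate_rank"`: `gene_id`,
#'   `n_tiles`, `loss_pct`, `bin`, `imprinted_flag`, sorted by
#'   decreasing `loss_pct`.
#' @export
rank_candidates <- function(tiles, annotation,
                            imprinted_genes = character(),
                            breaks = c(-Inf, 0, 25, 50, 75, 85, 100)) {
  stopifnot(all(c("tile_id", "m_control", "m_d21") %in% names(tiles)),
            all(c("tile_id", "gene_id") %in% names(annotation)))
  x <- merge(tiles[c("tile_id", "m_control", "m_d21")],
             annotation[c("tile_id", "gene_id")], by = "tile_id")
  x <- x[!is.na(x$gene_id), , drop = FALSE]
  zero <- x$m_control == 0
  if (any(zero)) {
    gone <- setdiff(unique(x$gene_id[zero]),
                    unique(x$gene_id[!zero]))
    if (length(gone))
      message(length(gone), " gene(s) excluded: all tiles have zero ",
              "control methylation")
    x <- x[!zero, , drop = FALSE]
  }
  if (!nrow(x)) {
    return(structure(data.frame(gene_id = character(),
                                n_tiles = integer(),
                                loss_pct = numeric(), bin = character(),
                                imprinted_flag = logical()),
                     class = c("candidate_rank", "data.frame")))
  }
  x$loss_pct <- 100 * (x$m_control - x$m_d21) / x$m_control
  agg <- stats::aggregate(loss_pct ~ gene_id, data = x, FUN = mean)
  nt <- stats::aggregate(tile_id ~ gene_id, data = x, FUN = length)
  res <- merge(agg, nt, by = "gene_id")
  names(res)[names(res) == "tile_id"] <- "n_tiles"
  res <- res[order(-res$loss_pct, res$gene_id), , drop = FALSE]
  lab <- c("<=0%", "(0,25)%", "[25,50)%", "[50,75)%", "[75,85)%",
           "[85,100]%")
  res$bin <- as.character(cut(res$loss_pct, breaks = breaks,
                              labels = lab, right = FALSE,
                              include.lowest = TRUE))
  res$bin[res$loss_pct <= 0] <- lab[1]
  res$imprinted_flag <- res$gene_id %in% imprinted_genes
  rownames(res) <- NULL
  res <- res[c("gene_id", "n_tiles", "loss_pct", "bin",
               "imprinted_flag")]
  class(res) <- c("candidate_rank", "data.frame")
  res
}

#' Merge tiles into consecutive regions
#'
#' Single linear pass merging tiles (per chromosome) whose gap is at
#' most `max_gap` bp into unique consecutive regions; the 500 bp
#' default reproduces the "separated by a maximum of 500 bp" rule, with
#' an inclusive comparison (a gap of exactly 500 bp is merged).  The
#' operation is idempotent and independent of input order.
#'
#' @param tiles data.frame with `chrom`, `start`, `end` (and optionally
#'   `tile_id`).
#' @param max_gap Maximum gap merged, in bp (default 500).
#' @return data.frame: `region_id`, `chrom`, `start`, `end`,
#'   `n_tiles`, and comma-separated `tile_ids`.
#' @export
merge_tiles <- function(tiles, max_gap = 500L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(tiles)))
  if (!nrow(tiles)) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_tiles = integer(), tile_ids = character()))
  }
  ids <- if ("tile_id" %in% names(tiles)) tiles$tile_id else
    paste0(tiles$chrom, ":", tiles$start)
  gr <- GenomicRanges::GRanges(
    tiles$chrom, IRanges::IRanges(tiles$start + 1L, tiles$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  hits <- GenomicRanges::findOverlaps(gr, red,
                                      maxgap = 0L)
  memb <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_tiles = as.integer(table(factor(memb, seq_along(red)))),
    tile_ids = vapply(seq_along(red), function(i)
      paste(sort(unique(ids[memb == i])), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("R%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
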