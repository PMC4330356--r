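granges_from <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Assign a single genomic feature to each tile
#'
#' Any-overlap annotation with a fixed priority:
#' promoter-TSS > TTS > 5UTR > 3UTR > exon > intron > noncoding >
#' intergenic.  Promoter and TTS windows are the TSS/TTS +/- 1 kb
#' (configurable); the remaining features come from the gene model
#' intervals.  Ties within a feature class are broken by the longest
#' overlap.
#'
#' @param tiles data.frame with `tile_id`, `chrom`, `start`, `end`.
#' @param features Gene feature intervals: `chrom`, `start`, `end`,
#'   `gene_id`, `strand`, `feature` (labels among 5UTR, exon, intron,
#'   3UTR, noncoding).
#' @param promoter_flank,tts_flank Half-window around the TSS/TTS in bp
#'   (default 1000).  Within the promoter-TSS and TTS classes, equal
#'   overlaps are further tie-broken by distance of the tile midpoint
#'   to the anchoring TSS/TTS (nearest wins).
#' @return data.frame: `tile_id`, `feature`, `gene_id` (NA iff
#'   intergenic).
#' @export
assign_feature <- function(tiles, features, promoter_flank = 1000L,
                           tts_flank = 1000L) {
  stopifnot(all(c("tile_id", "chrom", "start", "end") %in% names(tiles)))
  out <- data.frame(tile_id = tiles$tile_id,
                    feature = "intergenic", gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.null(features) || nrow(features) == 0 || nrow(tiles) == 0) {
    return(out)
  }
  genes <- gene_bounds(features)
  feat_w <- features[c("chrom", "start", "end", "gene_id", "feature")]
  feat_w$anchor <- NA_real_
  windows <- rbind(
    data.frame(chrom = genes$chrom,
               start = pmax(0L, genes$tss - promoter_flank),
               end = genes$tss + promoter_flank,
               gene_id = genes$gene_id, feature = "promoter-TSS",
               anchor = genes$tss, stringsAsFactors = FALSE),
    data.frame(chrom = genes$chrom,
               start = pmax(0L, genes$tts - tts_flank),
               end = genes$tts + tts_flank,
               gene_id = genes$gene_id, feature = "TTS",
               anchor = genes$tts, stringsAsFactors = FALSE),
    feat_w)
  tile_mid <- (tiles$start + tiles$end) / 2
  tile_gr <- granges_from(tiles)
  unassigned <- rep(TRUE, nrow(tiles))
  for (feat in setdiff(feature_vocabulary(), "intergenic")) {
    if (!any(unassigned)) break
    w <- windows[windows$feature == feat, , drop = FALSE]
    if (!nrow(w)) next
    w_gr <- granges_from(w)
    hits <- GenomicRanges::findOverlaps(tile_gr[unassigned], w_gr)
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ow <- GenomicRanges::width(IRanges::pintersect(
      tile_gr[unassigned][q], w_gr[s]))
    adist <- abs(tile_mid[unassigned][q] - w$anchor[s])
    adist[is.na(adist)] <- Inf
    ord <- order(q, -ow, adist)
    first <- !duplicated(q[ord])
    qi <- which(unassigned)[q[ord][first]]
    out$feature[qi] <- feat
    out$gene_id[qi] <- w$gene_id[s[ord][first]]
    unassigned[qi] <- FALSE
  }
  out
}

#' Repeat-element context of tiles
#'
#' For each tile: the class of the overlapping repeat (longest overlap
#' on ties; none if no overlap), the distance in bp to the nearest
#' repeat (0 iff overlapping), and whether a repeat lies within
#' `proximity` bp (inclusive).
#'
#' @param tiles data.frame with `tile_id`, `chrom`, `start`, `end`.
#' @param repeats data.frame with `chrom`, `start`, `end` and a repeat
#'   class column (`extra` as read by [read_bed()], or
#'   `repeat_class`).
#' @param proximity Proximity threshold in bp (default 1000).
#' @return data.frame: `tile_id`, `repeat_overlap` (class or NA),
#'   `repeat_within_1kb`, `distance_to_nearest_repeat` (NA when the
#'   chromosome has no repeat).
#' @export
repeat_context <- function(tiles, repeats, proximity = 1000L) {
  stopifnot(all(c("tile_id", "chrom", "start", "end") %in% names(tiles)))
  cls_col <- intersect(c("repeat_class", "extra", "class"),
                       names(repeats))[1]
  out <- data.frame(tile_id = tiles$tile_id,
                    repeat_overlap = NA_character_,
                    repeat_within_1kb = FALSE,
                    distance_to_nearest_repeat = NA_real_,
                    stringsAsFactors = FALSE)
  if (is.null(repeats) || nrow(repeats) == 0 || nrow(tiles) == 0)
    return(out)
  if (is.na(cls_col)) stop("repeats need a class column")
  tile_gr <- granges_from(tiles)
  rep_gr <- granges_from(repeats)
  # suppress the benign seqlevel-union notice for chromosomes present
  # in only one of the two sets
  near <- suppressWarnings(
    GenomicRanges::distanceToNearest(tile_gr, rep_gr))
  qi <- S4Vectors::queryHits(near)
  out$distance_to_nearest_repeat[qi] <-
    as.numeric(S4Vectors::mcols(near)$distance)
  hits <- GenomicRanges::findOverlaps(tile_gr, rep_gr)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ow <- GenomicRanges::width(IRanges::pintersect(tile_gr[q],
                                                   rep_gr[s]))
    ord <- order(q, -ow)
    first <- !duplicated(q[ord])
    out$repeat_overlap[q[ord][first]] <-
      repeats[[cls_col]][s[ord][first]]
  }
  out$repeat_within_1kb <- !is.na(out$distance_to_nearest_repeat) &
    out$distance_to_nearest_repeat <= proximity
  out
}

#' Full tile annotation
#'
#' Combines [assign_feature()], CpG-island membership (any overlap of
#' at least 1 bp) and [repeat_context()] into one record per tile.
#'
#' @param tiles data.frame with `tile_id`, `chrom`, `start`, `end`.
#' @param features Gene feature intervals (see [assign_feature()]).
#' @param cgis CpG-island intervals (`chrom`, `start`, `end`), or NULL.
#' @param repeats Repeat intervals with a class column, or NULL.
#' @param promoter_flank,tts_flank,proximity See the component
#'   functions.
#' @return data.frame with columns `tile_id`, `feature`, `gene_id`,
#'   `cgi`, `repeat_overlap`, `repeat_within_1kb`,
#'   `distance_to_nearest_repeat`.
#' @export
annotate_tiles <- function(tiles, features, cgis = NULL, repeats = NULL,
                           promoter_flank = 1000L, tts_flank = 1000L,
                           proximity = 1000L) {
  fe <- assign_feature(tiles, features, promoter_flank, tts_flank)
  fe$cgi <- FALSE
  if (!is.null(cgis) && nrow(cgis) && nrow(tiles)) {
    hits <- GenomicRanges::findOverlaps(granges_from(tiles),
                                        granges_from(cgis))
    fe$cgi[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  rc <- repeat_context(tiles, if (is.null(repeats))
    data.frame(chrom = character(), start = integer(),
               end = integer(), repeat_class = character()) else repeats,
    proximity)
  cbind(fe, rc[, -1, drop = FALSE])
}

#' Chi-square test on genomic composition counts
#'
#' Pearson chi-square (no continuity correction) comparing two
#' per-class count vectors, e.g. repeat-class composition of
#' hypomethylated versus stable tiles.  Classes with a zero expected
#' count are pooled into an "other" class with a warning.
#'
#' @param counts1,counts2 Named integer vectors over the same classes.
#' @return List: `statistic`, `df`, `p.value`, and the `table` tested.
#' @export
composition_chi2 <- function(counts1, counts2) {
  if (!is.null(names(counts1)) && !is.null(names(counts2))) {
    all_cls <- union(names(counts1), names(counts2))
    counts1 <- stats::setNames(
      ifelse(is.na(counts1[all_cls]), 0, counts1[all_cls]), all_cls)
    counts2 <- stats::setNames(
      ifelse(is.na(counts2[all_cls]), 0, counts2[all_cls]), all_cls)
  }
  if (length(counts1) != length(counts2) || length(counts1) < 2)
    stop("need counts over the same >= 2 classes")
  tab <- rbind(group1 = counts1, group2 = counts2)
  exp_zero <- colSums(tab) == 0
  if (any(exp_zero)) {
    warning("pooling ", sum(exp_zero), " empty class(es)")
    tab <- tab[, !exp_zero, drop = FALSE]
    if (ncol(tab) < 2) stop("fewer than 2 non-empty classes")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, table = tab)
}

#' Wilcoxon rank-sum test for a per-feature methylation shift
#'
#' Two-sided rank-sum test between the control and d21 methylation
#' values of one feature class: exact null distribution when both
#' groups have at most `exact_max` values (and no ties), normal
#' approximation otherwise.  Completely tied data give `p = 1`.
#'
#' @param x,y Methylation values of the two groups.
#' @param exact_max Largest group size for the exact test (default 10).
#' @return Two-sided p-value.
#' @export
feature_shift_test <- function(x, y, exact_max = 10L) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (all(c(x, y) == c(x, y)[1])) return(1)
  exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Per-feature methylation shift tests across two groups
#'
#' @param values data.frame with columns `feature`, `m_control`,
#'   `m_d21` (one row per tile).
#' @param adjust Multiple-testing adjustment method (default "BH").
#' @return data.frame: `feature`, group medians, `n`, `p`, `p_adj`.
#' @export
feature_shift_tests <- function(values, adjust = "BH") {
  stopifnot(all(c("feature", "m_control", "m_d21") %in% names(values)))
  sp <- split(values, values$feature)
  out <- do.call(rbind, lapply(names(sp), function(f) {
    v <- sp[[f]]
    data.frame(feature = f, n = nrow(v),
               median_control = stats::median(v$m_control),
               median_d21 = stats::median(v$m_d21),
               p = feature_shift_test(v$m_control, v$m_d21),
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- stats::p.adjust(out$p, adjust)
  rownames(out) <- NULL
  out
}
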