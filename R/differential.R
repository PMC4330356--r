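#' Welch two-sample t test (single tile)
#'
#' Thin wrapper around [stats::t.test()] handling the degenerate
#' zero-variance cases of tile methylation data: identical constant
#' groups give `p = 1`; distinct constant groups are flagged and given
#' `p = 0` (their significance is then decided by the effect-size gate
#' alone).
#'
#' @param a,b Replicate methylation fractions for the two groups.
#' @return List with `diff` (mean(b) - mean(a)), `p`, and `flag`
#'   (TRUE when the test was degenerate).
#' @export
welch_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  d <- mean(b) - mean(a)
  va <- stats::var(a); vb <- stats::var(b)
  if ((is.na(va) || va == 0) && (is.na(vb) || vb == 0)) {
    return(list(diff = d, p = if (d == 0) 1 else 0, flag = d != 0))
  }
  p <- tryCatch(stats::t.test(b, a)$p.value,
                error = function(e) NA_real_)
  if (is.na(p)) return(list(diff = d, p = if (d == 0) 1 else 0,
                            flag = TRUE))
  list(diff = d, p = p, flag = FALSE)
}

# status factor from significance + effect-size gate
call_status <- function(diff, significant, min_diff) {
  status <- rep("stable", length(diff))
  status[significant & diff <= -min_diff] <- "hypo"
  status[significant & diff >= min_diff] <- "hyper"
  factor(status, levels = c("hypo", "hyper", "stable"))
}

#' Per-tile Welch t test between two groups
#'
#' Replicate-level two-group comparison: a tile is called hypo- or
#' hypermethylated only when the Welch t test is significant
#' (`p < alpha`) AND the absolute difference of group means reaches
#' `min_diff` (the +/- >= 20 percentage-point effect-size gate).
#'
#' @param tm A `"tile_matrix"`.
#' @param group_a,group_b Timepoint labels (reference first; `diff` is
#'   `mean_b - mean_a`).
#' @param alpha Raw p-value threshold (default 0.05).
#' @param min_diff Minimum absolute group-mean difference (default 0.20).
#' @return data.frame of class `"differential_result"`: tile
#'   coordinates, group means, `diff`, `p`, BH `q`, `status`
#'   (hypo/hyper/stable) and a `flag` column marking degenerate
#'   zero-variance tests.
#' @export
test_tile_ttest <- function(tm, group_a = "control", group_b = "d21",
                            alpha = 0.05, min_diff = 0.20) {
  stopifnot(inherits(tm, "tile_matrix"),
            group_a %in% names(tm$groups), group_b %in% names(tm$groups))
  A <- tm$meth[, tm$groups[[group_a]], drop = FALSE]
  B <- tm$meth[, tm$groups[[group_b]], drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2)
    stop("need >= 2 replicates per group for the t test")
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  d <- mb - ma
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, d / sqrt(se2), NA_real_)
  dfw <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), dfw)
  flag <- se2 == 0 & d != 0
  p[se2 == 0 & d == 0] <- 1
  p[flag] <- 0
  res <- cbind(tm$tiles,
               data.frame(mean_a = ma, mean_b = mb, diff = d, p = p,
                          q = stats::p.adjust(p, "BH"),
                          flag = flag, row.names = NULL))
  res$status <- call_status(res$diff, res$p < alpha, min_diff)
  attr(res, "method") <- "ttest"
  attr(res, "groups") <- c(a = group_a, b = group_b)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Per-tile Fisher exact test on pooled counts
#'
#' Pools methylated/unmethylated read counts across replicates within
#' each group and applies a two-sided Fisher exact test to the 2x2
#' table per tile, with Benjamini-Hochberg correction across all tested
#' tiles.  A tile is called hypo-/hypermethylated only when
#' `q < q_threshold` AND the absolute group-mean difference reaches
#' `min_diff`.  Tiles with zero total reads in either group are skipped
#' (reported via the `skipped` attribute).
#'
#' @param tm A `"tile_matrix"` built by [make_tiles()] (pooled counts
#'   required).
#' @param group_a,group_b Timepoint labels.
#' @param q_threshold BH-adjusted significance threshold (default 0.01).
#' @param min_diff Minimum absolute group-mean difference (default 0.20).
#' @return data.frame of class `"differential_result"` as in
#'   [test_tile_ttest()], with pooled count columns.
#' @export
test_tile_counts <- function(tm, group_a = "control", group_b = "d21",
                             q_threshold = 0.01, min_diff = 0.20) {
  stopifnot(inherits(tm, "tile_matrix"),
            group_a %in% names(tm$groups), group_b %in% names(tm$groups))
  if (is.null(tm$meth_counts))
    stop("tile matrix carries no pooled counts")
  sa <- tm$groups[[group_a]]; sb <- tm$groups[[group_b]]
  meth_a <- rowSums(tm$meth_counts[, sa, drop = FALSE])
  tot_a <- rowSums(tm$total_counts[, sa, drop = FALSE])
  meth_b <- rowSums(tm$meth_counts[, sb, drop = FALSE])
  tot_b <- rowSums(tm$total_counts[, sb, drop = FALSE])
  keep <- tot_a > 0 & tot_b > 0
  if (any(!keep))
    message(sum(!keep), " tile(s) skipped: zero total reads in a group")
  p <- rep(NA_real_, length(meth_a))
  p[keep] <- vapply(which(keep), function(i)
    stats::fisher.test(matrix(c(meth_a[i], tot_a[i] - meth_a[i],
                                meth_b[i], tot_b[i] - meth_b[i]),
                              2, 2))$p.value,
    numeric(1))
  ma <- rowMeans(tm$meth[, sa, drop = FALSE])
  mb <- rowMeans(tm$meth[, sb, drop = FALSE])
  res <- cbind(tm$tiles,
               data.frame(mean_a = ma, mean_b = mb, diff = mb - ma,
                          meth_a = meth_a, unmeth_a = tot_a - meth_a,
                          meth_b = meth_b, unmeth_b = tot_b - meth_b,
                          p = p, row.names = NULL))
  res <- res[keep, , drop = FALSE]
  res$q <- stats::p.adjust(res$p, "BH")
  res$status <- call_status(res$diff, res$q < q_threshold, min_diff)
  attr(res, "method") <- "counts"
  attr(res, "groups") <- c(a = group_a, b = group_b)
  attr(res, "skipped") <- tm$tiles$tile_id[!keep]
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Classify methylation levels into high/intermediate/low states
#'
#' @param x Methylation fractions in \[0, 1\].
#' @return Factor with levels HIGH (> 0.80), INTERMEDIATE (\[0.20,
#'   0.80\], boundaries inclusive) and LOW (< 0.20) -- an exhaustive
#'   partition of \[0, 1\].
#' @export
classify_state <- function(x) {
  stopifnot(all(x >= 0 & x <= 1, na.rm = TRUE))
  factor(ifelse(x > 0.80, "HIGH", ifelse(x < 0.20, "LOW",
                                         "INTERMEDIATE")),
         levels = c("HIGH", "INTERMEDIATE", "LOW"))
}

#' Fraction of tiles per methylation state in a group
#'
#' @param tm A `"tile_matrix"`.
#' @param group Timepoint label.
#' @return Named numeric vector (HIGH, INTERMEDIATE, LOW) summing to 1.
#' @export
state_fractions <- function(tm, group) {
  stopifnot(inherits(tm, "tile_matrix"),
            group %in% colnames(tm$meth_group))
  st <- classify_state(tm$meth_group[, group])
  table(st) / length(st)
}

#' Retention calls at d0 relative to control
#'
#' Applies the two-stage retention rule: a tile must have lost at least
#' `loss_min` (0.20) absolute methylation between control and d0, and
#' is then classed by the fraction of its original methylation still
#' present at d0 (`m_d0 / m_control` > 0.20 / > 0.40).  The absolute
#' d0 methylation reading is also reported, including a flag for tiles
#' retaining 40--74\% absolute methylation.  Tiles with zero control
#' methylation are excluded (retained fraction undefined).
#'
#' @param tm A `"tile_matrix"` with control and d0 groups.
#' @param control,d0 Group labels.
#' @param loss_min Minimum absolute loss to enter the retention
#'   analysis.
#' @return data.frame: tile coordinates, `m_control`, `m_d0`, `lost`,
#'   `retained_frac`, `retained_gt20`, `retained_gt40`, `class`
#'   (retained>40\% within retained>20\%), `retained_abs` and
#'   `abs_40_74`.
#' @export
retention_calls <- function(tm, control = "control", d0 = "d0",
                            loss_min = 0.20) {
  stopifnot(inherits(tm, "tile_matrix"),
            all(c(control, d0) %in% colnames(tm$meth_group)))
  mc <- tm$meth_group[, control]
  m0 <- tm$meth_group[, d0]
  drop <- mc == 0
  if (any(drop))
    message(sum(drop),
            " tile(s) excluded: control methylation 0, retained ",
            "fraction undefined")
  res <- cbind(tm$tiles,
               data.frame(m_control = mc, m_d0 = m0, row.names = NULL))
  res <- res[!drop, , drop = FALSE]
  res$lost <- (res$m_control - res$m_d0) >= loss_min
  res$retained_frac <- res$m_d0 / res$m_control
  res$retained_gt20 <- res$lost & res$retained_frac > 0.20
  res$retained_gt40 <- res$lost & res$retained_frac > 0.40
  res$class <- ifelse(!res$lost, "not_lost",
                      ifelse(res$retained_gt40, "retained>40%",
                             ifelse(res$retained_gt20, "retained>20%",
                                    "not_retained")))
  res$retained_abs <- res$m_d0
  res$abs_40_74 <- res$lost & res$m_d0 >= 0.40 & res$m_d0 <= 0.74
  res
}
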