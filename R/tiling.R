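#' @keywords internal
new_tile_matrix <- function(tiles, meth, cov, n_cpg, meth_counts,
                            total_counts, manifest) {
  groups <- split(manifest$sample_id, manifest$timepoint)
  meth_group <- vapply(groups, function(s)
    rowMeans(meth[, s, drop = FALSE]), numeric(nrow(tiles)))
  if (nrow(tiles) == 1) meth_group <- matrix(meth_group, nrow = 1,
                                             dimnames = list(tiles$tile_id,
                                                             names(groups)))
  structure(list(tiles = tiles, meth = meth, cov = cov, n_cpg = n_cpg,
                 meth_counts = meth_counts, total_counts = total_counts,
                 meth_group = meth_group, groups = groups,
                 manifest = manifest),
            class = "tile_matrix")
}

# Collapse minus-strand calls onto the C position of the CpG on the plus
# strand (pos - 1) and sum counts with any plus-strand call there.
collapse_strands <- function(calls) {
  if (!any(calls$strand == "-")) return(calls)
  calls$pos <- ifelse(calls$strand == "-", calls$pos - 1L, calls$pos)
  key <- paste(calls$chrom, calls$pos)
  agg <- rowsum(cbind(coverage = calls$coverage, n_meth = calls$n_meth),
                key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(chrom = calls$chrom[first], pos = calls$pos[first],
                    strand = "+", coverage = agg[, "coverage"],
                    n_meth = agg[, "n_meth"], stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Aggregate CpG calls into 100 bp tiles
#'
#' Builds fixed-width, non-overlapping tiles aligned to multiples of
#' `tile_width` and computes per-sample tile methylation as the
#' unweighted mean of the per-CpG methylated fractions in the tile.
#' A tile is retained only if, in every sample, it contains at least
#' `min_cpg` covered CpGs and the mean per-CpG read coverage is at
#' least `min_cov` (set `cov_mode = "each"` to require every CpG to
#' reach `min_cov` instead).  Calls on the minus strand are collapsed
#' onto the plus-strand C before tiling.
#'
#' @param calls Named list of call data.frames (one per sample;
#'   see [read_calls()]) or an `"rrbs_experiment"`.
#' @param manifest Sample manifest (ignored when `calls` is an
#'   experiment).
#' @param tile_width Tile width in bp (default 100).
#' @param min_cpg Minimum covered CpGs per tile per sample.
#' @param min_cov Minimum CpG coverage per tile per sample.
#' @param cov_mode `"mean"` (default): tile mean CpG coverage must reach
#'   `min_cov`; `"each"`: every CpG must.
#' @return A `"tile_matrix"`: tile coordinates, per-sample methylation,
#'   mean-coverage, CpG-count and pooled-count matrices, and group
#'   (timepoint) mean methylation.
#' @export
make_tiles <- function(calls, manifest = NULL, tile_width = 100L,
                       min_cpg = 1L, min_cov = 20,
                       cov_mode = c("mean", "each")) {
  cov_mode <- match.arg(cov_mode)
  if (inherits(calls, "rrbs_experiment")) {
    manifest <- calls$manifest
    calls <- calls$calls
  }
  stopifnot(is.list(calls), !is.null(manifest),
            all(manifest$sample_id %in% names(calls)))
  samples <- manifest$sample_id

  per_sample <- lapply(samples, function(s) {
    x <- collapse_strands(calls[[s]])
    x <- x[x$coverage > 0, , drop = FALSE]
    if (!nrow(x)) {
      return(data.frame(key = character(), n_cpg = numeric(),
                        mean_cov = numeric(), meth = numeric(),
                        meth_ct = numeric(), tot_ct = numeric(),
                        each_ok = logical(), stringsAsFactors = FALSE))
    }
    bin <- (x$pos %/% tile_width) * tile_width
    key <- paste0(x$chrom, ":", bin)
    frac <- x$n_meth / x$coverage
    ok <- if (cov_mode == "each") x$coverage >= min_cov else
      rep(TRUE, nrow(x))
    agg <- rowsum(cbind(n = 1, cov = x$coverage, frac = frac,
                        meth_ct = x$n_meth, tot_ct = x$coverage,
                        all_ok = as.numeric(ok)),
                  key, reorder = FALSE)
    data.frame(key = rownames(agg), n_cpg = agg[, "n"],
               mean_cov = agg[, "cov"] / agg[, "n"],
               meth = agg[, "frac"] / agg[, "n"],
               meth_ct = agg[, "meth_ct"], tot_ct = agg[, "tot_ct"],
               each_ok = agg[, "all_ok"] == agg[, "n"],
               stringsAsFactors = FALSE)
  })
  names(per_sample) <- samples

  keys <- Reduce(intersect, lapply(per_sample, `[[`, "key"))
  if (length(keys)) {
    get <- function(col) vapply(per_sample, function(d)
      d[[col]][match(keys, d$key)], numeric(length(keys)))
    n_cpg <- get("n_cpg"); mean_cov <- get("mean_cov")
    if (length(keys) == 1) {
      n_cpg <- matrix(n_cpg, 1, dimnames = list(keys, samples))
      mean_cov <- matrix(mean_cov, 1, dimnames = list(keys, samples))
    }
    pass <- rowSums(n_cpg >= min_cpg) == length(samples)
    if (cov_mode == "mean") {
      pass <- pass & rowSums(mean_cov >= min_cov) == length(samples)
    } else {
      each <- get("each_ok")
      if (length(keys) == 1) each <- matrix(each, 1)
      pass <- pass & rowSums(each == 1) == length(samples)
    }
    keys <- keys[pass]
  }
  if (!length(keys))
    stop("no tiles pass filters (min_cpg = ", min_cpg, ", min_cov = ",
         min_cov, ") in every sample")

  grab <- function(col) {
    m <- vapply(per_sample, function(d) d[[col]][match(keys, d$key)],
                numeric(length(keys)))
    if (length(keys) == 1) m <- matrix(m, 1)
    dimnames(m) <- list(keys, samples)
    m
  }
  meth <- grab("meth"); cov <- grab("mean_cov"); n_cpg <- grab("n_cpg")
  meth_counts <- grab("meth_ct"); total_counts <- grab("tot_ct")

  chrom <- sub(":[^:]*$", "", keys)
  start <- as.integer(sub("^.*:", "", keys))
  ord <- order(chrom, start)
  tiles <- data.frame(tile_id = keys, chrom = chrom, start = start,
                      end = start + tile_width,
                      stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(tiles) <- NULL
  reord <- function(m) m[ord, , drop = FALSE]
  new_tile_matrix(tiles, reord(meth), reord(cov), reord(n_cpg),
                  reord(meth_counts), reord(total_counts), manifest)
}

#' @export
print.tile_matrix <- function(x, ...) {
  cat("Tile matrix:", nrow(x$tiles), "tiles x", ncol(x$meth),
      "samples\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(x$groups),
                                 lengths(x$groups)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pairwise Pearson correlation between samples
#'
#' Per-tile methylation correlations between all sample pairs, with an
#' average-linkage hierarchical clustering on `1 - r`.
#'
#' @param tm A `"tile_matrix"` with at least 2 tiles.
#' @return List with the symmetric correlation matrix `r`, the
#'   `hclust` object `clustering`, and the leaf `order`.
#' @export
sample_correlations <- function(tm) {
  stopifnot(inherits(tm, "tile_matrix"))
  if (nrow(tm$meth) < 2) stop("need at least 2 tiles")
  sds <- apply(tm$meth, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance sample(s): ",
            paste(colnames(tm$meth)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(tm$meth))
  ok <- sds > 0
  cl <- NULL
  ord <- seq_len(ncol(r))
  if (sum(ok) >= 2) {
    cl <- stats::hclust(stats::as.dist(1 - r[ok, ok]),
                        method = "average")
    ord <- which(ok)[cl$order]
  }
  list(r = r, clustering = cl, order = ord)
}

#' Methylation metaprofile around transcription start sites
#'
#' Mean group methylation of tiles by strand-oriented distance from the
#' nearest-gene TSS bin: a tile contributes to every gene whose TSS lies
#' within `flank` bp of the tile midpoint, at the signed (upstream
#' negative) distance.
#'
#' @param tm A `"tile_matrix"`.
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `tss`
#'   (e.g. the `genes` element of a synthetic genome, or derived from a
#'   features BED via [gene_bounds()]).
#' @param flank Half-window around the TSS in bp (default 4000).
#' @param bin Bin width in bp (default 200).
#' @return data.frame: bin start/mid and one mean-methylation column per
#'   timepoint group, plus the contributing pair count `n`.
#' @export
tss_profile <- function(tm, genes, flank = 4000L, bin = 200L) {
  stopifnot(inherits(tm, "tile_matrix"))
  if (is.null(genes) || nrow(genes) == 0) {
    warning("no genes supplied; empty TSS profile")
    out <- data.frame(bin_start = integer(), bin_mid = integer(),
                      n = integer())
    for (g in names(tm$groups)) out[[g]] <- numeric()
    return(out)
  }
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(genes)))
  mid <- tm$tiles$start + (tm$tiles$end - tm$tiles$start) %/% 2
  tile_gr <- GenomicRanges::GRanges(tm$tiles$chrom,
                                    IRanges::IRanges(mid, width = 1))
  win_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(0, genes$tss - flank), genes$tss + flank))
  hits <- GenomicRanges::findOverlaps(tile_gr, win_gr)
  if (!length(hits)) {
    warning("no tiles within ", flank, " bp of any TSS")
  }
  ti <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  d <- mid[ti] - genes$tss[gi]
  d <- ifelse(genes$strand[gi] == "-", -d, d)
  keep <- abs(d) <= flank
  ti <- ti[keep]; d <- d[keep]
  idx <- pmin(floor((d + flank) / bin), (2 * flank) %/% bin - 1)
  bins <- seq(-flank, flank - bin, by = bin)
  out <- data.frame(bin_start = bins, bin_mid = bins + bin / 2,
                    n = as.integer(tabulate(idx + 1, length(bins))))
  for (g in names(tm$groups)) {
    v <- tm$meth_group[ti, g]
    s <- rowsum(v, idx, reorder = TRUE)
    col <- rep(NA_real_, length(bins))
    col[as.integer(rownames(s)) + 1] <- s / tabulate(idx + 1,
                                                     length(bins))[
      as.integer(rownames(s)) + 1]
    out[[g]] <- col
  }
  out
}

#' Derive gene bounds and TSS/TTS from a feature table
#'
#' @param features data.frame with chrom, start, end, gene_id, strand
#'   (e.g. read from a genes BED with [read_bed()], renaming `name` to
#'   `gene_id` and `extra` to `feature`).
#' @return data.frame gene_id, chrom, start, end, strand, tss, tts.
#' @export
gene_bounds <- function(features) {
  stopifnot(all(c("chrom", "start", "end", "gene_id", "strand") %in%
                  names(features)))
  sp <- split(features, features$gene_id)
  out <- do.call(rbind, lapply(sp, function(f) {
    data.frame(gene_id = f$gene_id[1], chrom = f$chrom[1],
               start = min(f$start), end = max(f$end),
               strand = f$strand[1], stringsAsFactors = FALSE)
  }))
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out$tts <- ifelse(out$strand == "+", out$end, out$start)
  rownames(out) <- NULL
  out
}
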