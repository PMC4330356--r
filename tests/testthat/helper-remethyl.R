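# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written from first principles (enumeration,
# brute force) and never call the code paths they check.

# --- fixtures ---------------------------------------------------------

# Calls for one sample: every listed tile gets `n_cpg` CpGs at fixed
# coverage with methylated counts reproducing the requested fractions.
calls_for_tiles <- function(fracs, chrom = "chr1", tile_width = 100L,
                            n_cpg = 2L, coverage = 100L) {
  rows <- lapply(seq_along(fracs), function(i) {
    start <- (i - 1L) * tile_width
    data.frame(chrom = chrom,
               pos = start + seq(10L, by = 20L, length.out = n_cpg),
               strand = "+", coverage = coverage,
               n_meth = as.integer(round(fracs[i] * coverage)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# tile_matrix whose group means are exactly the rows of `level_mat`
# (tiles x groups), with `reps` replicates per group.
fixture_tile_matrix <- function(level_mat,
                                groups = colnames(level_mat),
                                reps = c(3L, 3L, 4L)[seq_along(groups)],
                                coverage = 100L, n_cpg = 2L) {
  manifest <- do.call(rbind, lapply(seq_along(groups), function(g) {
    data.frame(sample_id = sprintf("%s_r%d", groups[g], seq_len(reps[g])),
               timepoint = groups[g], replicate = seq_len(reps[g]),
               path = NA_character_, stringsAsFactors = FALSE)
  }))
  calls <- lapply(manifest$timepoint, function(tp)
    calls_for_tiles(level_mat[, tp], coverage = coverage,
                    n_cpg = n_cpg))
  names(calls) <- manifest$sample_id
  make_tiles(calls, manifest, min_cov = 1)
}

# Cached default pipeline run (shared by the end-to-end tests).
default_run_cache <- new.env()
get_default_run <- function(seed = 1L) {
  key <- paste0("run", seed)
  if (is.null(default_run_cache[[key]]))
    default_run_cache[[key]] <- run_pipeline(default_config(seed = seed))
  default_run_cache[[key]]
}

# Map pipeline tiles to their true simulated locus class.
tile_truth_classes <- function(run) {
  cpg <- run$genome$cpgs
  key <- paste0(cpg$chrom, ":", (cpg$pos %/% 100L) * 100L)
  cls <- tapply(cpg$class, key, function(x) x[1])
  unname(cls[run$tiles$tiles$tile_id])
}

withr_like_tempdir <- function() {
  d <- tempfile("remethyl")
  dir.create(d)
  d
}

# --- independent oracles ----------------------------------------------

# Two-sided Fisher exact p by full enumeration over the hypergeometric
# support with fixed margins (table = a, b / c, d).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact rank-sum p by enumerating all group assignments.
wilcox_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Region merging by union-find on all tile pairs.
merge_bruteforce <- function(tiles, max_gap = 500L) {
  n <- nrow(tiles)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || tiles$chrom[i] != tiles$chrom[j]) next
    gap <- max(tiles$start[j] - tiles$end[i],
               tiles$start[i] - tiles$end[j], 0)
    overlap <- tiles$start[j] < tiles$end[i] &&
      tiles$start[i] < tiles$end[j]
    if (overlap || gap <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  regs <- lapply(split(seq_len(n), root), function(idx)
    c(start = min(tiles$start[idx]), end = max(tiles$end[idx])))
  out <- data.frame(chrom = tiles$chrom[as.integer(names(regs))],
                    start = vapply(regs, `[[`, numeric(1), "start"),
                    end = vapply(regs, `[[`, numeric(1), "end"))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Benjamini-Hochberg rejection set by the hand rule:
# reject all p up to the largest i with p_(i) <= i * q / m.
bh_reject_enum <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# Brute-force tile aggregation: unweighted mean of per-CpG fractions
# per (chrom, 100 bp bin), counting only covered CpGs.
aggregate_bruteforce <- function(calls, tile_width = 100L) {
  calls <- calls[calls$coverage > 0, , drop = FALSE]
  bin <- (calls$pos %/% tile_width) * tile_width
  key <- paste0(calls$chrom, ":", bin)
  out <- lapply(split(seq_len(nrow(calls)), key), function(idx) {
    fr <- calls$n_meth[idx] / calls$coverage[idx]
    c(n = length(idx), meth = mean(fr),
      mean_cov = mean(calls$coverage[idx]))
  })
  res <- do.call(rbind, out)
  data.frame(key = rownames(res), res, row.names = NULL,
             stringsAsFactors = FALSE)
}
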