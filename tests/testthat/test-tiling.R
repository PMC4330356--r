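two_sample_manifest <- function(tps = c("s1", "s2")) {
  data.frame(sample_id = tps, timepoint = tps, replicate = 1L,
             path = NA_character_, stringsAsFactors = FALSE)
}

test_that("tile methylation is the unweighted mean of CpG fractions", {
  calls <- data.frame(chrom = "chr1", pos = c(10L, 40L, 90L),
                      strand = "+", coverage = c(10L, 100L, 1000L),
                      n_meth = c(8L, 60L, 400L))
  man <- two_sample_manifest("s1")
  tm <- make_tiles(list(s1 = calls), man, min_cov = 1)
  # fractions 0.8, 0.6, 0.4 -> unweighted mean 0.6 despite coverage
  expect_equal(unname(tm$meth[1, "s1"]), 0.6)
  expect_equal(unname(tm$n_cpg[1, "s1"]), 3)
})

test_that("a tile failing the 20x filter in one sample drops everywhere", {
  c1 <- data.frame(chrom = "chr1", pos = c(10L, 110L), strand = "+",
                   coverage = c(30L, 30L), n_meth = c(15L, 15L))
  c2 <- data.frame(chrom = "chr1", pos = c(10L, 110L), strand = "+",
                   coverage = c(19L, 25L), n_meth = c(5L, 5L))
  tm <- make_tiles(list(s1 = c1, s2 = c2), two_sample_manifest(),
                   min_cov = 20)
  expect_equal(nrow(tm$tiles), 1L)
  expect_equal(tm$tiles$start, 100L)
})

test_that("tiles without covered CpGs are never emitted", {
  c1 <- data.frame(chrom = "chr1", pos = c(10L, 210L), strand = "+",
                   coverage = c(30L, 0L), n_meth = c(15L, 0L))
  tm <- make_tiles(list(s1 = c1), two_sample_manifest("s1"),
                   min_cov = 1)
  expect_equal(tm$tiles$start, 0L)   # the zero-coverage 200-tile is gone
  expect_error(
    make_tiles(list(s1 = c1[2, ]), two_sample_manifest("s1")),
    "no tiles pass")
})

test_that("per-CpG coverage mode is stricter than tile-mean mode", {
  c1 <- data.frame(chrom = "chr1", pos = c(10L, 40L), strand = "+",
                   coverage = c(10L, 40L), n_meth = c(5L, 20L))
  man <- two_sample_manifest("s1")
  tm_mean <- make_tiles(list(s1 = c1), man, min_cov = 20,
                        cov_mode = "mean")
  expect_equal(nrow(tm_mean$tiles), 1L)   # mean coverage 25 passes
  expect_error(make_tiles(list(s1 = c1), man, min_cov = 20,
                          cov_mode = "each"),
               "no tiles pass")
})

test_that("raising the coverage filter never adds tiles", {
  set.seed(1)
  calls <- data.frame(chrom = "chr1",
                      pos = sort(sample.int(5000, 200)), strand = "+",
                      coverage = rnbinom(200, size = 5, mu = 30))
  calls$n_meth <- rbinom(200, calls$coverage, 0.5)
  calls <- calls[calls$coverage > 0, ]
  man <- two_sample_manifest("s1")
  kept <- lapply(c(1, 10, 20, 30), function(mc) {
    tryCatch(make_tiles(list(s1 = calls), man,
                        min_cov = mc)$tiles$tile_id,
             error = function(e) character())
  })
  for (i in 2:4)
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})

test_that("tile aggregation equals brute-force recomputation", {
  set.seed(42)
  man <- two_sample_manifest("s1")
  for (rep in 1:300) {
    n <- sample(3:25, 1)
    calls <- data.frame(chrom = sample(c("c1", "c2"), n, TRUE),
                        pos = sample.int(1200, n), strand = "+",
                        coverage = sample(0:60, n, TRUE))
    calls$n_meth <- rbinom(n, calls$coverage, runif(1))
    calls <- calls[!duplicated(calls[c("chrom", "pos")]), ]
    if (!any(calls$coverage > 0)) next
    tm <- make_tiles(list(s1 = calls), man, min_cov = 0)
    oracle <- aggregate_bruteforce(calls)
    oracle <- oracle[match(tm$tiles$tile_id, oracle$key), ]
    expect_equal(unname(tm$meth[, "s1"]), oracle$meth)
    expect_equal(unname(tm$n_cpg[, "s1"]), oracle$n)
    expect_equal(unname(tm$cov[, "s1"]), oracle$mean_cov)
  }
})

test_that("minus-strand calls collapse onto the plus-strand C", {
  calls <- data.frame(chrom = "chr1", pos = c(10L, 11L), strand = c("+", "-"),
                      coverage = c(10L, 30L), n_meth = c(10L, 0L))
  man <- two_sample_manifest("s1")
  tm <- make_tiles(list(s1 = calls), man, min_cov = 1)
  expect_equal(unname(tm$n_cpg[1, "s1"]), 1)       # one CpG after collapse
  expect_equal(unname(tm$meth[1, "s1"]), 10 / 40)  # counts pooled
})

test_that("sample correlations: duplicates, anticorrelation, hand value", {
  lv <- cbind(a = c(0.1, 0.4, 0.6, 0.9), b = c(0.1, 0.4, 0.6, 0.9),
              c = c(0.2, 0.3, 0.7, 0.8), d = c(0.9, 0.6, 0.4, 0.1))
  tm <- fixture_tile_matrix(lv, reps = rep(1L, 4))
  sc <- sample_correlations(tm)
  expect_equal(unname(diag(sc$r)), rep(1, 4))
  expect_equal(sc$r, t(sc$r))
  expect_equal(sc$r["a_r1", "b_r1"], 1.0)
  expect_equal(sc$r["a_r1", "d_r1"], -1.0)
  # hand Pearson for (0.1,0.4,0.6,0.9) vs (0.2,0.3,0.7,0.8)
  expect_equal(sc$r["a_r1", "c_r1"], 0.28 / sqrt(0.34 * 0.26),
               tolerance = 1e-12)
  expect_s3_class(sc$clustering, "hclust")
})

test_that("zero-variance samples yield NA correlations with a warning", {
  lv <- cbind(a = c(0.1, 0.9), b = c(0.5, 0.5))
  tm <- fixture_tile_matrix(lv, reps = c(1L, 1L))
  expect_warning(sc <- sample_correlations(tm), "zero-variance")
  expect_true(is.na(sc$r["a_r1", "b_r1"]))
})

test_that("TSS metaprofile: flat input gives a flat profile", {
  calls <- calls_for_tiles(rep(0.7, 40))
  man <- two_sample_manifest("s1")
  tm <- make_tiles(list(s1 = calls), man, min_cov = 1)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 2000L)
  pr <- tss_profile(tm, genes, flank = 2000, bin = 200)
  vals <- pr$s1[pr$n > 0]
  expect_true(all(abs(vals - 0.7) < 1e-12))
})

test_that("TSS metaprofile shows a promoter dip, strand-oriented", {
  # methylation 0 within 400 bp of the TSS, 0.8 elsewhere
  tss <- 2000L
  fr <- ifelse(abs(seq(0, 3900, by = 100) + 50 - tss) <= 400, 0, 0.8)
  calls <- calls_for_tiles(fr)
  man <- two_sample_manifest("s1")
  tm <- make_tiles(list(s1 = calls), man, min_cov = 1)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
                      tss = tss)
  pr <- tss_profile(tm, genes, flank = 1600, bin = 400)
  centre <- pr$s1[pr$bin_mid %in% c(-200, 200)]
  edge <- pr$s1[abs(pr$bin_mid) > 800]
  expect_true(all(centre < 0.2))
  expect_true(all(edge[!is.na(edge)] > 0.6))
})

test_that("empty gene set warns and returns an empty profile", {
  calls <- calls_for_tiles(c(0.5, 0.5))
  tm <- make_tiles(list(s1 = calls), two_sample_manifest("s1"),
                   min_cov = 1)
  expect_warning(pr <- tss_profile(tm, NULL), "no genes")
  expect_equal(nrow(pr), 0L)
})
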