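simple_features <- function() {
  # gene gA on +: TSS 5000, exons/introns to a TTS at 9000
  data.frame(chrom = "chr1",
             start = c(5000L, 5200L, 5500L, 6200L, 6500L, 8800L),
             end = c(5200L, 5500L, 6200L, 6500L, 8800L, 9000L),
             gene_id = "gA", strand = "+",
             feature = c("5UTR", "exon", "intron", "exon", "intron",
                         "3UTR"),
             stringsAsFactors = FALSE)
}

tile_df <- function(starts, chrom = "chr1") {
  data.frame(tile_id = paste0(chrom, ":", starts), chrom = chrom,
             start = starts, end = starts + 100L,
             stringsAsFactors = FALSE)
}

test_that("tiles overlapping nothing are intergenic", {
  res <- assign_feature(tile_df(100L), simple_features())
  expect_equal(res$feature, "intergenic")
  expect_true(is.na(res$gene_id))
})

test_that("priority: promoter-TSS beats intron of another gene", {
  feats <- rbind(simple_features(),
                 data.frame(chrom = "chr1", start = 4000L, end = 4800L,
                            gene_id = "gB", strand = "+",
                            feature = "intron"))
  # tile at 4500 overlaps gA's promoter window (TSS 5000 +/- 1000)
  # and gB's intron: promoter wins
  res <- assign_feature(tile_df(4500L), feats)
  expect_equal(res$feature, "promoter-TSS")
  expect_equal(res$gene_id, "gA")
})

test_that("a tile fully inside an exon is exonic; TTS window beats UTR", {
  # exon at 6200-6500 is beyond the promoter window (TSS 5000 + 1 kb)
  res <- assign_feature(tile_df(6300L), simple_features())
  expect_equal(res$feature, "exon")
  # 3'UTR at 8800-9000 lies inside the TTS +/- 1 kb window: TTS wins
  res2 <- assign_feature(tile_df(8850L), simple_features())
  expect_equal(res2$feature, "TTS")
  res3 <- assign_feature(tile_df(6700L), simple_features())
  expect_equal(res3$feature, "intron")
})

test_that("feature assignment partitions the tile set", {
  set.seed(8)
  tiles <- tile_df(seq(0L, 12000L, by = 100L))
  res <- assign_feature(tiles, simple_features())
  expect_equal(nrow(res), nrow(tiles))
  expect_equal(sum(table(res$feature)), nrow(tiles))
  expect_true(all(res$feature %in% feature_vocabulary()))
  expect_true(all(is.na(res$gene_id) == (res$feature == "intergenic")))
})

test_that("repeat context: overlap, proximity and exact distances", {
  reps <- data.frame(chrom = "chr1", start = c(50L, 900L),
                     end = c(150L, 1200L),
                     repeat_class = c("LINE", "SINE"))
  res <- repeat_context(tile_df(c(0L, 0L)), reps[1, ])
  expect_equal(res$repeat_overlap[1], "LINE")
  expect_equal(res$distance_to_nearest_repeat[1], 0)

  res <- repeat_context(tile_df(0L), reps[2, ])
  expect_true(is.na(res$repeat_overlap))
  expect_equal(res$distance_to_nearest_repeat, 800)
  expect_true(res$repeat_within_1kb)

  far <- data.frame(chrom = "chr1", start = 1101L, end = 1400L,
                    repeat_class = "IAP")
  res <- repeat_context(tile_df(0L), far)    # gap 1001
  expect_equal(res$distance_to_nearest_repeat, 1001)
  expect_false(res$repeat_within_1kb)
  at <- data.frame(chrom = "chr1", start = 1100L, end = 1400L,
                   repeat_class = "IAP")     # gap exactly 1000
  expect_true(repeat_context(tile_df(0L), at)$repeat_within_1kb)
})

test_that("overlap class ties break by longest overlap", {
  reps <- data.frame(chrom = "chr1", start = c(0L, 60L),
                     end = c(30L, 200L),
                     repeat_class = c("SINE", "LINE"))
  res <- repeat_context(tile_df(0L), reps)
  expect_equal(res$repeat_overlap, "LINE")   # 30 bp vs 40 bp overlap
  reps2 <- data.frame(chrom = "chr1", start = c(0L, 30L),
                      end = c(20L, 200L),
                      repeat_class = c("SINE", "LINE"))
  expect_equal(repeat_context(tile_df(0L), reps2)$repeat_overlap,
               "LINE")                       # 20 bp vs 70 bp
})

test_that("repeat context equals a brute-force all-pairs scan", {
  set.seed(13)
  for (i in 1:30) {
    nt <- sample(1:20, 1); nr <- sample(1:15, 1)
    tiles <- tile_df(sample(seq(0L, 4000L, by = 100L), nt))
    reps <- data.frame(chrom = "chr1",
                       start = sample.int(4000L, nr),
                       stringsAsFactors = FALSE)
    reps$end <- reps$start + sample(50:300, nr, replace = TRUE)
    reps$repeat_class <- sample(c("LINE", "SINE"), nr, TRUE)
    got <- repeat_context(tiles, reps)
    for (j in seq_len(nt)) {
      gaps <- pmax(reps$start - tiles$end[j], tiles$start[j] - reps$end,
                   0)
      expect_equal(got$distance_to_nearest_repeat[j], min(gaps))
      expect_equal(got$repeat_within_1kb[j], min(gaps) <= 1000)
      expect_equal(is.na(got$repeat_overlap[j]), min(gaps) > 0)
    }
  }
})

test_that("tiles without repeats on their chromosome report no distance", {
  reps <- data.frame(chrom = "chr2", start = 0L, end = 100L,
                     repeat_class = "LINE")
  res <- repeat_context(tile_df(0L, chrom = "chr1"), reps)
  expect_true(is.na(res$distance_to_nearest_repeat))
  expect_false(res$repeat_within_1kb)
})

test_that("CGI membership is any overlap of at least 1 bp", {
  cgis <- data.frame(chrom = "chr1", start = 99L, end = 300L)
  ann <- annotate_tiles(tile_df(c(0L, 400L)), simple_features(),
                        cgis = cgis)
  expect_equal(ann$cgi, c(TRUE, FALSE))
})

test_that("composition chi-square matches the hand formula", {
  same <- composition_chi2(c(a = 10, b = 20), c(a = 10, b = 20))
  expect_equal(same$statistic, 0)
  r <- composition_chi2(c(x = 30, y = 70), c(x = 60, y = 40))
  expect_equal(r$statistic, 2 * 225 / 45 + 2 * 225 / 55,
               tolerance = 1e-9)
  expect_equal(r$statistic, 18.18, tolerance = 0.005)
  expect_equal(r$df, 1)
  expect_warning(composition_chi2(c(a = 5, b = 0, c = 5),
                                  c(a = 2, b = 0, c = 8)),
                 "empty class")
})

test_that("wilcoxon shift test matches exact enumeration", {
  p <- feature_shift_test(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_equal(p, 0.1)   # most extreme of C(6,3) = 20 orderings
  expect_equal(p, wilcox_enum_p(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9)))
  expect_equal(feature_shift_test(c(0.5, 0.5), c(0.5, 0.5)), 1)
  set.seed(4)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(runif(n1), 6); y <- round(runif(n2), 6)
    if (anyDuplicated(c(x, y))) next
    expect_equal(feature_shift_test(x, y), wilcox_enum_p(x, y),
                 tolerance = 1e-12, label = paste("case", i))
  }
})

test_that("per-feature shift table adjusts p-values", {
  set.seed(6)
  vals <- data.frame(feature = rep(c("exon", "intron"), each = 8),
                     m_control = runif(16, 0.6, 0.9))
  vals$m_d21 <- vals$m_control - ifelse(vals$feature == "exon", 0.4, 0)
  res <- feature_shift_tests(vals)
  expect_equal(nrow(res), 2L)
  expect_lt(res$p[res$feature == "exon"], 0.01)
  expect_true(all(res$p_adj >= res$p - 1e-12))
})
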