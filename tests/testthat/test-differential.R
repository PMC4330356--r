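# tile_matrix with per-replicate methylation set per group
replicate_tile_matrix <- function(a_rows, b_rows, groups = c("control",
                                                             "d21")) {
  stopifnot(nrow(a_rows) == nrow(b_rows))
  manifest <- rbind(
    data.frame(sample_id = paste0(groups[1], "_r", seq_len(ncol(a_rows))),
               timepoint = groups[1], replicate = seq_len(ncol(a_rows)),
               path = NA_character_),
    data.frame(sample_id = paste0(groups[2], "_r", seq_len(ncol(b_rows))),
               timepoint = groups[2], replicate = seq_len(ncol(b_rows)),
               path = NA_character_))
  calls <- c(lapply(seq_len(ncol(a_rows)), function(j)
    calls_for_tiles(a_rows[, j], coverage = 100L)),
    lapply(seq_len(ncol(b_rows)), function(j)
      calls_for_tiles(b_rows[, j], coverage = 100L)))
  names(calls) <- manifest$sample_id
  make_tiles(calls, manifest, min_cov = 1)
}

test_that("welch test handles identical, separated and constant groups", {
  r <- welch_test(c(0.8, 0.8, 0.8), c(0.8, 0.8, 0.8))
  expect_equal(r$p, 1)
  expect_equal(r$diff, 0)
  r <- welch_test(c(0.8, 0.8, 0.8), c(0.3, 0.3, 0.3))
  expect_equal(r$p, 0)
  expect_true(r$flag)
  # textbook Welch oracle
  a <- c(0.9, 0.88, 0.92); b <- c(0.15, 0.1, 0.2)
  se2 <- var(a) / 3 + var(b) / 3
  tstat <- (mean(b) - mean(a)) / sqrt(se2)
  dfw <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(welch_test(a, b)$p, 2 * pt(-abs(tstat), dfw),
               tolerance = 1e-12)
})

test_that("t-test recipe calls hypo only past both gates", {
  A <- rbind(c(0.80, 0.80, 0.80),   # identical in both groups
             c(0.90, 0.88, 0.92),   # strong loss
             c(0.50, 0.50, 0.50))   # significant but small effect
  B <- rbind(c(0.80, 0.80, 0.80),
             c(0.15, 0.10, 0.20),
             c(0.31, 0.31, 0.31))
  tm <- replicate_tile_matrix(A, B)
  res <- test_tile_ttest(tm, "control", "d21")
  expect_equal(as.character(res$status), c("stable", "hypo", "stable"))
  # |diff| = 0.19 with an arbitrarily small p stays stable
  expect_lt(res$p[3], 1e-6)
  expect_equal(res$diff[3], -0.19)
})

test_that("conservation: hypo + hyper + stable = tiles tested", {
  set.seed(3)
  A <- matrix(runif(60, 0.2, 0.9), 20, 3)
  B <- matrix(pmin(1, pmax(0, A + rnorm(60, -0.2, 0.2))), 20, 3)
  tm <- replicate_tile_matrix(A, B)
  res <- test_tile_ttest(tm, "control", "d21")
  expect_equal(sum(table(res$status)), nrow(res))
  res2 <- test_tile_counts(tm, "control", "d21")
  expect_equal(sum(table(res2$status)), nrow(res2))
})

test_that("fisher p equals full-margin enumeration (totals <= 60)", {
  set.seed(7)
  for (i in 1:150) {
    tot_a <- sample(1:30, 1); tot_b <- sample(1:30, 1)
    a <- sample(0:tot_a, 1); c_ <- sample(0:tot_b, 1)
    got <- fisher.test(matrix(c(a, tot_a - a, c_, tot_b - c_), 2))$p.value
    want <- fisher_enum_p(a, tot_a - a, c_, tot_b - c_)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("pooled-count recipe: identical tables are stable, tails exact", {
  A <- rbind(c(0.5, 0.5, 0.5), c(0.9, 0.9, 0.9))
  B <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  tm <- replicate_tile_matrix(A, B)
  res <- test_tile_counts(tm, "control", "d21")
  expect_equal(as.character(res$status[1]), "stable")
  expect_equal(res$p[1], 1)
  # tile 2 pools to (270, 30) vs (150, 150) over 3 replicates of 100x
  expect_equal(res$p[2],
               fisher_enum_p(res$meth_a[2], res$unmeth_a[2],
                             res$meth_b[2], res$unmeth_b[2]),
               tolerance = 1e-9)
  expect_equal(as.character(res$status[2]), "hypo")
})

test_that("single pooled 2x2 example matches the hypergeometric tail", {
  # counts (90 meth, 10 unmeth) vs (50, 50)
  p <- fisher.test(matrix(c(90, 10, 50, 50), 2))$p.value
  expect_equal(p, fisher_enum_p(90, 10, 50, 50), tolerance = 1e-9)
})

test_that("BH rejections follow the hand rule and are stable under permutation", {
  p <- c(0.001, 0.002, 0.03, 0.8)
  expect_equal(bh_reject_enum(p, 0.01), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(p.adjust(p, "BH") < 0.01, bh_reject_enum(p, 0.01))
  set.seed(1)
  for (i in 1:25) {
    pv <- runif(12)^2
    q <- 0.05
    ref <- bh_reject_enum(pv, q)
    expect_equal(p.adjust(pv, "BH") < q, ref)
    perm <- sample.int(12)
    expect_equal((p.adjust(pv[perm], "BH") < q)[order(perm)], ref)
    # q monotone in p
    qv <- p.adjust(pv, "BH")
    expect_true(all(diff(qv[order(pv)]) >= -1e-12))
  }
})

test_that("state classes partition [0,1] with inclusive boundaries", {
  x <- c(0, 0.19999, 0.2, 0.5, 0.8, 0.80001, 1)
  st <- classify_state(x)
  expect_equal(as.character(st),
               c("LOW", "LOW", "INTERMEDIATE", "INTERMEDIATE",
                 "INTERMEDIATE", "HIGH", "HIGH"))
  expect_false(anyNA(classify_state(seq(0, 1, by = 0.001))))
})

test_that("state fractions sum to one and match constructed input", {
  lv <- cbind(control = c(0.95, 0.85, 0.5, 0.1),
              d0 = c(0.95, 0.5, 0.1, 0.1))
  tm <- fixture_tile_matrix(lv, reps = c(1L, 1L))
  fr <- state_fractions(tm, "control")
  expect_equal(sum(fr), 1)
  expect_equal(as.numeric(fr), c(2, 1, 1) / 4)
  lv2 <- cbind(control = rep(0.95, 3), d0 = rep(0.95, 3))
  tm2 <- fixture_tile_matrix(lv2, reps = c(1L, 1L))
  expect_equal(as.numeric(state_fractions(tm2, "control")), c(1, 0, 0))
})

test_that("retention rule: two-stage thresholds and exclusions", {
  lv <- cbind(control = c(0.9, 0.9, 0.9, 0.9, 0),
              d0 = c(0.5, 0.85, 0.05, 0.25, 0))
  tm <- fixture_tile_matrix(lv, reps = c(1L, 1L))
  expect_message(res <- retention_calls(tm, "control", "d0"),
                 "excluded")
  expect_equal(nrow(res), 4L)          # m_control = 0 dropped
  expect_equal(res$class,
               c("retained>40%", "not_lost", "not_retained",
                 "retained>20%"))
  expect_equal(res$retained_frac[1], 0.5 / 0.9, tolerance = 1e-9)
  # retained>40% is a subset of retained>20%
  expect_true(all(!res$retained_gt40 | res$retained_gt20))
  expect_true(res$abs_40_74[1])        # absolute 0.5 in [0.40, 0.74]
})
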