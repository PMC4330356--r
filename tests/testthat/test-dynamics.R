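test_that("single-division recurrence matches hand evaluation", {
  # passive halving per division
  expect_equal(step_methylation(0.8, 0, 0, TRUE), 0.4)
  expect_equal(step_methylation(0.8, 0, 0, FALSE), 0.4)
  # perfect maintenance is a fixed point
  expect_equal(step_methylation(1.0, 1, 0, TRUE), 1.0)
  # hand evaluation with de novo active
  expect_equal(step_methylation(0.9, 0, 0.25, TRUE),
               (0.9 + 0.9 * 0.25 + 0.1 * 0.25) / 2)
  expect_equal(step_methylation(0.9, 0, 0.25, TRUE), 0.575)
})

test_that("recurrence maps [0,1] to [0,1] over a parameter grid", {
  grid <- seq(0, 1, by = 0.25)
  for (m in grid) for (rho in grid) for (delta in grid)
    for (gate in c(TRUE, FALSE)) {
      m2 <- step_methylation(m, rho, delta, gate)
      expect_true(m2 >= 0 && m2 <= 1,
                  info = sprintf("m=%g rho=%g delta=%g", m, rho, delta))
    }
})

test_that("maintenance-off trajectory follows the closed form", {
  # m_t = delta + (m0 - delta)/2^t, via an explicit iteration oracle
  tl <- timeline(c("control", "d0"), divisions_off = 3)
  p <- list(m0 = 0.9, rho_on = 0, delta = 0.25, delta_recovery = 0.25,
            theta = 0, alleles = 1L)
  tr <- expected_trajectory(p, tl)
  expect_equal(unname(tr[["d0"]]), 0.25 + 0.65 / 8)
  expect_equal(unname(tr[["d0"]]), 0.33125)
  # iteration oracle, independent of allele bookkeeping
  m <- 0.9
  for (i in 1:3) m <- (m + 0.25) / 2
  expect_equal(unname(tr[["d0"]]), m)
})

test_that("unmethylated loci with no de novo stay at zero forever", {
  p <- list(m0 = 0, rho_on = 0.7, delta = 0, delta_recovery = 0,
            theta = 0.05, alleles = 1L)
  expect_true(all(expected_trajectory(p, timeline()) == 0))
})

test_that("trajectories are non-increasing with the gate closed", {
  tl <- timeline()
  for (rho in c(0, 0.4, 0.9)) for (m0 in c(0.3, 0.9)) {
    p <- list(m0 = m0, rho_on = rho, delta = 0.5, delta_recovery = 0.5,
              theta = 1.01, alleles = 1L)   # gate can never open
    tr <- expected_trajectory(p, tl)
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("repeat-class de novo rates set the d0 retention plateau", {
  tl <- timeline()
  for (delta in c(0.22, 0.28, 0.35)) {
    p <- list(m0 = 0.9, rho_on = 1, delta = delta,
              delta_recovery = delta, theta = 0.05, alleles = 1L)
    tr <- expected_trajectory(p, tl)
    expect_equal(unname(tr[["d0"]]), delta, tolerance = 0.02)
  }
})

test_that("simulated pooled means track the expected trajectory", {
  g <- build_genome(genome_spec(c(chr1 = 5e5), rng_seed = 2),
                    class_counts = c(GDMD_LIKE = 30L),
                    hyper_prone_n = 0)
  tl <- timeline(c("control", "d0", "d21"))
  # noise off: fixed deterministic coverage comes from pooling many CpGs
  ex <- simulate_experiment(g, tl = tl,
                            noise = noise_params(site_jitter_sd = 0),
                            n_replicates = c(control = 1L, d0 = 1L,
                                             d21 = 1L),
                            seed = 9)
  want <- expected_trajectory(default_dynamics_params()["GDMD_LIKE", ],
                              tl)
  for (i in seq_len(nrow(ex$manifest))) {
    d <- ex$calls[[ex$manifest$sample_id[i]]]
    tot <- sum(d$coverage)
    phat <- sum(d$n_meth) / tot
    mu <- want[[ex$manifest$timepoint[i]]]
    se <- sqrt(max(mu * (1 - mu), 1e-12) / tot)
    expect_lt(abs(phat - mu), max(3 * se, 1e-4))
  }
})

test_that("imprinted gDMDs average their alleles and never recover", {
  g <- build_genome(genome_spec(c(chr1 = 3e5), rng_seed = 4),
                    class_counts = c(IMPRINTED_GDMD = 15L),
                    hyper_prone_n = 0)
  tl <- timeline(c("control", "d0", "d21"))
  ex <- simulate_experiment(g, tl = tl,
                            noise = noise_params(site_jitter_sd = 0),
                            n_replicates = c(control = 2L, d0 = 2L,
                                             d21 = 2L), seed = 5)
  pooled <- vapply(seq_len(nrow(ex$manifest)), function(i) {
    d <- ex$calls[[i]]
    sum(d$n_meth) / sum(d$coverage)
  }, numeric(1))
  names(pooled) <- ex$manifest$timepoint
  expect_equal(unname(pooled[names(pooled) == "control"][1]), 0.5,
               tolerance = 0.02)
  expect_true(all(pooled[names(pooled) == "d21"] < 0.05))
})

test_that("simulation is deterministic under a fixed seed", {
  g <- build_genome(genome_spec(c(chr1 = 1e5), rng_seed = 1),
                    class_counts = c(INTERGENIC = 5L),
                    hyper_prone_n = 0)
  tl <- timeline(c("control", "d0", "d21"))
  e1 <- simulate_experiment(g, tl = tl, seed = 7,
                            n_replicates = c(control = 1L, d0 = 1L,
                                             d21 = 1L))
  e2 <- simulate_experiment(g, tl = tl, seed = 7,
                            n_replicates = c(control = 1L, d0 = 1L,
                                             d21 = 1L))
  expect_identical(e1$calls, e2$calls)
})

test_that("default-noise pooled means stay within 3 SE of the model", {
  # full sampling law per CpG: coverage C ~ NB, site p ~ Beta(mean mu),
  # reads ~ Binomial(C, p); the pooled estimator sum(meth)/sum(cov) is
  # unbiased for mu with variance derived from the law itself
  g <- build_genome(genome_spec(c(chr1 = 2e6), rng_seed = 3),
                    class_counts = c(RE_SINE = 250L, GENIC_BODY = 100L,
                                     IMPRINTED_GDMD = 15L),
                    hyper_prone_n = 0)
  tl <- timeline(c("control", "d0", "d21"))
  noise <- noise_params()
  ex <- simulate_experiment(g, tl = tl, noise = noise,
                            n_replicates = c(control = 1L, d0 = 1L,
                                             d21 = 1L), seed = 21)
  traj <- ex$truth$class_trajectories
  s_beta <- 0.25 / noise$site_jitter_sd^2 - 1
  for (i in seq_len(nrow(ex$manifest))) {
    d <- ex$calls[[i]]
    tp <- ex$manifest$timepoint[i]
    for (cl in unique(ex$truth$cpg_class)) {
      idx <- ex$truth$cpg_class == cl
      mu <- traj[cl, tp]
      tot <- sum(d$coverage[idx])
      if (tot == 0) next
      phat <- sum(d$n_meth[idx]) / tot
      v_site <- mu * (1 - mu) / (s_beta + 1)
      # per-read variance + extra-binomial site term across CpGs
      v <- mu * (1 - mu) / tot +
        v_site * sum(d$coverage[idx]^2) / tot^2
      expect_lt(abs(phat - mu), 3 * sqrt(v) + 1e-6,
                label = paste(cl, tp))
    }
  }
})
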