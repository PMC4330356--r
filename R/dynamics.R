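#' One replication step of the methylation inheritance model
#'
#' Strand-averaged semiconservative recurrence for the methylation
#' fraction of a region across one cell division.  The old strand keeps
#' its methylation; the new strand is methylated by maintenance activity
#' (probability `rho`, given a methylated template) or by de novo
#' activity (probability `delta`); unmethylated dyads can gain
#' methylation de novo only while the gate is open:
#'
#' \deqn{m' = [\, m + m(\rho + (1-\rho)\delta) + (1-m)\,\delta I \,]/2}
#'
#' with \eqn{I = 1} if `gate_open`, else 0.  With `rho = delta = 0` this
#' is passive demethylation (halving per division); with `rho = 1`,
#' `delta = 0` methylation is perfectly maintained; with `rho = 0` and
#' the gate open the trajectory decays towards the plateau `delta`.
#'
#' @param m Current methylation fraction(s) in \[0, 1\].
#' @param rho Maintenance efficiency in \[0, 1\].
#' @param delta De novo methylation probability per division in \[0, 1\].
#' @param gate_open Logical; whether de novo activity can act on
#'   unmethylated dyads (regional methylation at or above the gate
#'   threshold).
#' @return Methylation fraction(s) after one division, in \[0, 1\].
#' @export
step_methylation <- function(m, rho, delta, gate_open = TRUE) {
  stopifnot(all(m >= 0 & m <= 1), all(rho >= 0 & rho <= 1),
            all(delta >= 0 & delta <= 1))
  i <- as.numeric(gate_open)
  (m + m * (rho + (1 - rho) * delta) + (1 - m) * delta * i) / 2
}

# Iterate the recurrence for one allele over the division schedule of a
# timeline, recording the methylation fraction at each sampled timepoint.
# The gate is re-evaluated before every division against the allele's
# current methylation.
allele_trajectory <- function(m0, rho_on, delta, delta_recovery, theta,
                              tl) {
  sched <- timeline_divisions(tl)
  max_off <- max(sched$n_off)
  max_on <- max(sched$n_on)
  traj_off <- numeric(max_off + 1)
  m <- m0
  traj_off[1] <- m
  for (k in seq_len(max_off)) {
    m <- step_methylation(m, rho = 0, delta = delta,
                          gate_open = m >= theta)
    traj_off[k + 1] <- m
  }
  traj_on <- numeric(max_on + 1)
  traj_on[1] <- m
  for (k in seq_len(max_on)) {
    m <- step_methylation(m, rho = rho_on, delta = delta_recovery,
                          gate_open = m >= theta)
    traj_on[k + 1] <- m
  }
  ifelse(sched$n_on > 0 | sched$timepoint == "d0",
         traj_on[sched$n_on + 1],
         traj_off[sched$n_off + 1])
}

#' Expected methylation trajectory of one locus class
#'
#' Iterates [step_methylation()] over the timeline's division schedule:
#' `divisions_off` divisions with maintenance off (control to d0), then
#' `divisions_per_day_on` divisions per recovery day with maintenance
#' restored.  Two-allele classes are simulated per allele and averaged.
#' With `rho = 0` and the gate open the closed form
#' \eqn{m_t = \delta + (m_0 - \delta)/2^t} holds; with `rho = 1` and
#' `delta = 0` the trajectory is constant.
#'
#' @param params One-row data.frame (or coercible list) with fields
#'   `m0`, `rho_on`, `delta`, `delta_recovery`, `theta`, `alleles`, and
#'   for two-allele classes `m0_allele1`/`m0_allele2` (see
#'   [default_dynamics_params()]).
#' @param tl A [timeline()].
#' @return Named numeric vector: expected methylation fraction at each
#'   timepoint.
#' @export
expected_trajectory <- function(params, tl = timeline()) {
  stopifnot(inherits(tl, "timeline"))
  p <- as.list(params)
  if (is.null(p$delta_recovery) || is.na(p$delta_recovery))
    p$delta_recovery <- p$delta
  if (is.null(p$alleles) || is.na(p$alleles)) p$alleles <- 1L
  if (p$alleles == 2L) {
    tr <- (allele_trajectory(p$m0_allele1, p$rho_on, p$delta,
                             p$delta_recovery, p$theta, tl) +
           allele_trajectory(p$m0_allele2, p$rho_on, p$delta,
                             p$delta_recovery, p$theta, tl)) / 2
  } else {
    tr <- allele_trajectory(p$m0, p$rho_on, p$delta, p$delta_recovery,
                            p$theta, tl)
  }
  stats::setNames(tr, tl$timepoints)
}

#' Expected trajectories for every locus class
#'
#' @param params Parameter table as [default_dynamics_params()].
#' @param tl A [timeline()].
#' @return Matrix classes x timepoints.
#' @export
class_trajectories <- function(params = default_dynamics_params(),
                               tl = timeline()) {
  validate_dynamics_params(params)
  t(vapply(seq_len(nrow(params)),
           function(i) expected_trajectory(params[i, ], tl),
           numeric(length(tl$timepoints)))) ->
    m
  rownames(m) <- params$class
  m
}

# Mean-preserving site-level jitter: Beta draw around m with sd
# `sd` at m = 0.5 (precision s = 0.25/sd^2 - 1); degenerate at 0/1.
jitter_beta <- function(m, sd) {
  if (sd <= 0) return(m)
  s <- 0.25 / sd^2 - 1
  out <- m
  mid <- m > 0 & m < 1
  if (any(mid))
    out[mid] <- stats::rbeta(sum(mid), m[mid] * s, (1 - m[mid]) * s)
  out
}

#' Simulate an RRBS time-course experiment
#'
#' Generates per-sample methylation call tables for every CpG of a
#' synthetic genome across the requested timepoints and replicates.
#' Each CpG follows its locus class's expected trajectory (two alleles
#' averaged for imprinted gDMDs; hypermethylation-prone loci use
#' [hyper_prone_params()]); per CpG and sample a read coverage is drawn
#' from a negative binomial and the methylated read count from a
#' binomial around the (jittered) trajectory value.
#'
#' @param genome A `"synthetic_genome"` from [build_genome()].
#' @param params Class parameter table ([default_dynamics_params()]).
#' @param tl A [timeline()].
#' @param noise A [noise_params()].
#' @param n_replicates Named integer vector, replicates per sampled
#'   timepoint; default `c(control = 3, d0 = 3, d21 = 4)` matching the
#'   RRBS design.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return List of class `"rrbs_experiment"`: `calls` (named list of
#'   call data.frames, one per sample), `manifest`, `truth` (class
#'   trajectory matrix and per-CpG expected fractions), and the inputs.
#' @export
simulate_experiment <- function(genome,
                                params = default_dynamics_params(),
                                tl = timeline(),
                                noise = noise_params(),
                                n_replicates = c(control = 3L, d0 = 3L,
                                                 d21 = 4L),
                                seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(tl, "timeline"), inherits(noise, "noise_params"),
            all(n_replicates >= 1))
  validate_dynamics_params(params)
  tp <- names(n_replicates)
  if (!all(tp %in% tl$timepoints))
    stop("n_replicates names must be timeline timepoints")
  missing_cls <- setdiff(unique(genome$cpgs$class), params$class)
  if (length(missing_cls))
    stop("no dynamics parameters for class: ",
         paste(missing_cls, collapse = ", "))

  traj <- class_trajectories(params, tl)
  htraj <- expected_trajectory(hyper_prone_params(), tl)

  cpg <- genome$cpgs
  hyper <- genome$loci$locus_id[genome$loci$hyper_prone]
  is_h <- cpg$locus_id %in% hyper

  manifest <- do.call(rbind, lapply(tp, function(t) {
    data.frame(sample_id = sprintf("%s_r%d", t, seq_len(n_replicates[[t]])),
               timepoint = t, replicate = seq_len(n_replicates[[t]]),
               path = NA_character_, stringsAsFactors = FALSE)
  }))

  with_seed(seed, {
    calls <- vector("list", nrow(manifest))
    names(calls) <- manifest$sample_id
    for (i in seq_len(nrow(manifest))) {
      t <- manifest$timepoint[i]
      m <- traj[cpg$class, t]
      if (any(is_h)) m[is_h] <- htraj[[t]]
      p_site <- jitter_beta(m, noise$site_jitter_sd)
      cov <- stats::rnbinom(nrow(cpg), size = noise$coverage_dispersion,
                            mu = noise$mean_coverage)
      n_meth <- stats::rbinom(nrow(cpg), cov, p_site)
      calls[[i]] <- data.frame(chrom = cpg$chrom, pos = cpg$pos,
                               strand = "+", coverage = cov,
                               n_meth = n_meth, stringsAsFactors = FALSE)
    }
    structure(list(calls = calls, manifest = manifest,
                   truth = list(class_trajectories = traj,
                                hyper_trajectory = htraj,
                                cpg_class = cpg$class,
                                cpg_locus = cpg$locus_id,
                                hyper_loci = hyper),
                   genome = genome, params = params, timeline = tl,
                   noise = noise, seed = seed),
              class = "rrbs_experiment")
  })
}

#' @export
print.rrbs_experiment <- function(x, ...) {
  cat("Simulated RRBS experiment:", length(x$calls), "samples,",
      nrow(x$calls[[1]]), "CpGs each\n")
  print(table(x$manifest$timepoint))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' One call TSV per sample plus a `manifest.tsv`.
#'
#' @param experiment An `"rrbs_experiment"`.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "rrbs_experiment"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  man <- experiment$manifest
  man$path <- file.path(dir, paste0(man$sample_id, ".calls.tsv"))
  for (i in seq_len(nrow(man)))
    write_calls(experiment$calls[[man$sample_id[i]]], man$path[i])
  write_manifest(man, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}
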