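#' Default run configuration
#'
#' All tunables of every stage, with defaults equal to the study's
#' stated analysis settings: 100 bp tiles, 1 CpG minimum, 20x coverage
#' per tile per sample, +/- 20 percentage-point effect gate, q = 0.01
#' (Fisher/BH recipe) or p = 0.05 (t-test recipe), 500 bp region
#' merging, 1 kb promoter/TTS windows and repeat proximity, and the
#' control/d0/d21 design with 3/3/4 replicates.
#'
#' @param seed Integer seed for genome construction and simulation.
#' @return Nested list of class `"remethyl_config"`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    genome = list(chromosomes = c(chr1 = 5e6, chr2 = 5e6),
                  class_counts = as.list(default_class_counts()),
                  cpg_density = as.list(default_cpg_density()),
                  hyper_prone_n = 8L),
    timeline = list(timepoints = c("control", "d0", "d3", "d5", "d7",
                                   "d10", "d14", "d21"),
                    divisions_off = 8L, divisions_per_day_on = 2L),
    noise = list(mean_coverage = 30, coverage_dispersion = 5,
                 site_jitter_sd = 0.05),
    replicates = list(control = 3L, d0 = 3L, d21 = 4L),
    tiling = list(tile_width = 100L, min_cpg = 1L, min_cov = 20,
                  cov_mode = "mean"),
    differential = list(method = "counts", alpha = 0.05,
                        q_threshold = 0.01, min_diff = 0.20),
    trajectory = list(low = 0.20, partial_hi = 0.75,
                      recover_tol = 0.20),
    annotation = list(promoter_flank = 1000L, tts_flank = 1000L,
                      proximity = 1000L),
    merge = list(max_gap = 500L),
    tss = list(flank = 4000L, bin = 200L),
    report = list(decimals = 0L)),
    class = "remethyl_config")
}

#' Read a run configuration from YAML
#'
#' Values found in the file override the defaults; everything else
#' keeps its default.
#'
#' @param path YAML file.
#' @param seed Default seed if the file sets none.
#' @return A `"remethyl_config"`.
#' @export
read_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config(seed)), user)
  class(cfg) <- "remethyl_config"
  cfg
}

#' Percentage with half-away-from-zero rounding
#'
#' Formats `100 * numerator / denominator` rounded half away from zero
#' to `decimals` places, the convention reproducing the study's printed
#' ratios (e.g. 5063/7423 -> "68\%"; 3688/9884 at one decimal ->
#' "37.3\%").
#'
#' @param numerator,denominator Counts; `denominator > 0`.
#' @param decimals Decimal places (default 0).
#' @return Percentage string, e.g. `"68\%"`.
#' @export
pct <- function(numerator, denominator, decimals = 0L) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  p <- 100 * numerator / denominator
  r <- round_half_away(p, decimals)
  paste0(formatC(r, format = "f", digits = decimals), "%")
}

#' @keywords internal
round_half_away <- function(x, digits = 0L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Complement of a reduced-tile count
#'
#' Given the total number of changed tiles and the number with reduced
#' methylation, returns the number with increased methylation.
#'
#' @param total_changed,reduced Counts with `reduced <= total_changed`.
#' @return `total_changed - reduced`.
#' @export
diff_counts <- function(total_changed, reduced) {
  if (any(reduced > total_changed))
    stop("reduced count exceeds total")
  total_changed - reduced
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes the stages in order: simulate (genome + RRBS counts), tile,
#' differential tests (control vs d0 and control vs d21), trajectory
#' classification, region merging of d0-hypomethylated tiles,
#' annotation, candidate ranking, and the summary report.  The run is
#' deterministic given the configuration seed.
#'
#' @param config A `"remethyl_config"` (see [default_config()]).
#' @param seed Overrides `config$seed` when given.
#' @return List of class `"remethyl_run"` with every stage output and
#'   `report`, a consistency-checked [summary] of counts and
#'   percentages; `log` records per-stage in/out counts.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL) {
  stopifnot(inherits(config, "remethyl_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, message = msg,
                                          stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  genome <- stage("simulate", {
    spec <- genome_spec(unlist(config$genome$chromosomes),
                        rng_seed = config$seed)
    build_genome(spec,
                 class_counts = unlist(config$genome$class_counts),
                 cpg_density = unlist(config$genome$cpg_density),
                 hyper_prone_n = config$genome$hyper_prone_n)
  })
  note("simulate", sprintf("genome: %d loci, %d CpGs",
                           nrow(genome$loci), nrow(genome$cpgs)))
  tl <- do.call(timeline, config$timeline)
  experiment <- stage("simulate", simulate_experiment(
    genome, tl = tl, noise = do.call(noise_params, config$noise),
    n_replicates = unlist(config$replicates), seed = config$seed + 1L))
  note("simulate", sprintf("%d samples simulated",
                           length(experiment$calls)))

  tm <- stage("tile", make_tiles(
    experiment, tile_width = config$tiling$tile_width,
    min_cpg = config$tiling$min_cpg, min_cov = config$tiling$min_cov,
    cov_mode = config$tiling$cov_mode))
  note("tile", sprintf("%d tiles pass filters in all %d samples",
                       nrow(tm$tiles), ncol(tm$meth)))

  correlations <- stage("tile", sample_correlations(tm))
  tssp <- stage("tile", tss_profile(tm, genome$genes,
                                    flank = config$tss$flank,
                                    bin = config$tss$bin))

  dcfg <- config$differential
  test_fun <- if (dcfg$method == "ttest") {
    function(a, b) test_tile_ttest(tm, a, b, alpha = dcfg$alpha,
                                   min_diff = dcfg$min_diff)
  } else {
    function(a, b) suppressMessages(
      test_tile_counts(tm, a, b, q_threshold = dcfg$q_threshold,
                       min_diff = dcfg$min_diff))
  }
  diff_d0 <- stage("diff", test_fun("control", "d0"))
  diff_d21 <- stage("diff", test_fun("control", "d21"))
  note("diff", sprintf("control vs d0: %d hypo / %d hyper of %d",
                       sum(diff_d0$status == "hypo"),
                       sum(diff_d0$status == "hyper"), nrow(diff_d0)))
  note("diff", sprintf("control vs d21: %d hypo / %d hyper of %d",
                       sum(diff_d21$status == "hypo"),
                       sum(diff_d21$status == "hyper"),
                       nrow(diff_d21)))

  states <- vapply(names(tm$groups),
                   function(g) as.numeric(state_fractions(tm, g)),
                   numeric(3))
  rownames(states) <- c("HIGH", "INTERMEDIATE", "LOW")
  retention <- stage("diff", suppressMessages(retention_calls(tm)))

  traj <- stage("classify", tile_trajectories(
    tm, low = config$trajectory$low,
    partial_hi = config$trajectory$partial_hi,
    recover_tol = config$trajectory$recover_tol))
  note("classify", paste(utils::capture.output(
    print(table(traj$pattern)))[2], collapse = " "))

  hypo_d0 <- diff_d0[diff_d0$status == "hypo", , drop = FALSE]
  regions <- stage("merge", merge_tiles(hypo_d0,
                                        max_gap = config$merge$max_gap))
  note("merge", sprintf("%d hypo tiles at d0 -> %d regions",
                        nrow(hypo_d0), nrow(regions)))

  cgis <- genome$loci[genome$loci$cgi_flag,
                      c("chrom", "start", "end"), drop = FALSE]
  repeats <- genome$loci[!is.na(genome$loci$repeat_class),
                         c("chrom", "start", "end", "repeat_class"),
                         drop = FALSE]
  annot <- stage("annotate", annotate_tiles(
    tm$tiles, genome$features, cgis = cgis, repeats = repeats,
    promoter_flank = config$annotation$promoter_flank,
    tts_flank = config$annotation$tts_flank,
    proximity = config$annotation$proximity))
  note("annotate", sprintf("%d/%d tiles genic",
                           sum(annot$feature != "intergenic"),
                           nrow(annot)))

  hypo_tiles <- diff_d21[diff_d21$status == "hypo", , drop = FALSE]
  rank_in <- data.frame(tile_id = hypo_tiles$tile_id,
                        m_control = hypo_tiles$mean_a,
                        m_d21 = hypo_tiles$mean_b,
                        stringsAsFactors = FALSE)
  imprinted <- unique(stats::na.omit(
    genome$loci$gene_id[genome$loci$class == "IMPRINTED_GDMD"]))
  candidates <- stage("rank", suppressMessages(
    rank_candidates(rank_in, annot, imprinted_genes = imprinted)))
  note("rank", sprintf("%d candidate genes; %d in top bin",
                       nrow(candidates),
                       sum(candidates$bin == "[85,100]%")))

  shift <- stage("annotate", feature_shift_tests(
    data.frame(feature = annot$feature,
               m_control = tm$meth_group[, "control"],
               m_d21 = tm$meth_group[, "d21"])))

  report <- build_report(tm, diff_d0, diff_d21, states, retention,
                         traj, regions, annot, candidates,
                         decimals = config$report$decimals)

  structure(list(config = config, genome = genome,
                 experiment = experiment, tiles = tm,
                 correlations = correlations, tss_profile = tssp,
                 diff_d0 = diff_d0, diff_d21 = diff_d21,
                 state_fractions = states, retention = retention,
                 trajectories = traj, regions = regions,
                 annotation = annot, candidates = candidates,
                 feature_shift = shift, report = report,
                 log = do.call(rbind, log)),
            class = "remethyl_run")
}

# Summary report: every percentage is derived from its printed
# numerator/denominator pair by pct() and re-checked at build time.
build_report <- function(tm, diff_d0, diff_d21, states, retention,
                         traj, regions, annot, candidates,
                         decimals = 0L) {
  n_tiles <- nrow(tm$tiles)
  genic <- annot$feature != "intergenic"
  hypo21 <- diff_d21$status == "hypo"
  an21 <- annot[match(diff_d21$tile_id, annot$tile_id), ]
  ret20 <- retention$retained_gt20
  an_ret <- annot[match(retention$tile_id, annot$tile_id), ]

  sections <- list(
    tiles = list(total = n_tiles),
    differential_d0 = count_section(
      c(hypo = sum(diff_d0$status == "hypo"),
        hyper = sum(diff_d0$status == "hyper"),
        stable = sum(diff_d0$status == "stable")),
      nrow(diff_d0), decimals),
    differential_d21 = count_section(
      c(hypo = sum(hypo21), hyper = sum(diff_d21$status == "hyper"),
        stable = sum(diff_d21$status == "stable")),
      nrow(diff_d21), decimals),
    state_fractions = states,
    retention = count_section(
      c(retained_gt20 = sum(ret20),
        retained_gt40 = sum(retention$retained_gt40),
        abs_40_74 = sum(retention$abs_40_74)),
      nrow(retention), decimals),
    retention_gt20_context = if (any(ret20)) count_section(
      c(genic = sum(an_ret$feature[ret20] != "intergenic"),
        re_overlap = sum(!is.na(an_ret$repeat_overlap[ret20])),
        re_within_1kb = sum(is.na(an_ret$repeat_overlap[ret20]) &
                              an_ret$repeat_within_1kb[ret20])),
      sum(ret20), decimals) else NULL,
    hypo_d21_context = if (any(hypo21)) count_section(
      c(genic = sum(an21$feature[hypo21] != "intergenic"),
        re_overlap = sum(!is.na(an21$repeat_overlap[hypo21])),
        cgi = sum(an21$cgi[hypo21])),
      sum(hypo21), decimals) else NULL,
    patterns = table(traj$pattern),
    regions = list(n_regions = nrow(regions),
                   n_member_tiles = sum(regions$n_tiles)),
    candidate_bins = table(candidates$bin))
  validate_report(sections)
  structure(sections, class = "remethyl_report")
}

count_section <- function(counts, total, decimals = 0L) {
  list(counts = counts, total = total,
       pct = stats::setNames(
         vapply(counts, function(k) pct(k, total, decimals),
                character(1)),
         names(counts)))
}

# internal consistency: each printed percentage must be reproducible
# from its count/total pair
validate_report <- function(sections) {
  for (s in sections) {
    if (is.list(s) && !is.null(s$counts)) {
      again <- vapply(s$counts, function(k) pct(k, s$total, 0L),
                      character(1))
      dec <- nchar(sub("^[^.]*\\.?", "", sub("%$", "", s$pct[1])))
      again <- vapply(s$counts, function(k) pct(k, s$total, dec),
                      character(1))
      if (!all(again == s$pct))
        stop("internal report inconsistency")
    }
  }
  invisible(TRUE)
}

#' @export
print.remethyl_report <- function(x, ...) {
  cat("== Summary report ==\n")
  cat("Tiles quantified:", x$tiles$total, "\n")
  pr <- function(name, s) {
    if (is.null(s)) return()
    cat(name, ":\n", sep = "")
    for (k in names(s$counts))
      cat(sprintf("  %-15s n = %6d  (%s of %d)\n", k, s$counts[[k]],
                  s$pct[[k]], s$total))
  }
  pr("Control vs d0", x$differential_d0)
  pr("Control vs d21", x$differential_d21)
  cat("State fractions (rows HIGH/INTERMEDIATE/LOW):\n")
  print(round(x$state_fractions, 3))
  pr("d0 retention (lost >=20% yet retained)", x$retention)
  pr("Retained>20% tiles", x$retention_gt20_context)
  pr("Hypomethylated-at-d21 tiles", x$hypo_d21_context)
  cat("Trajectory patterns:\n"); print(x$patterns)
  cat("Merged hypo-at-d0 regions:", x$regions$n_regions, "regions /",
      x$regions$n_member_tiles, "tiles\n")
  cat("Candidate loss bins:\n"); print(x$candidate_bins)
  invisible(x)
}

#' @export
print.remethyl_run <- function(x, ...) {
  cat("remethyl pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat(" ", nrow(x$genome$loci), "loci;", nrow(x$tiles$tiles),
      "tiles;", length(x$experiment$calls), "samples\n")
  cat("  stages: simulate -> tile -> diff -> classify -> merge -> ",
      "annotate -> rank -> report\n", sep = "")
  invisible(x)
}

#' @export
summary.remethyl_run <- function(object, ...) object$report
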