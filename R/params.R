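#' Locus class vocabulary
#'
#' The nine sequence categories distinguished by the simulator: imprinted
#' germline DMDs (gDMDs), gDMD-like single-copy loci, four repeat-element
#' classes, generic gene bodies, intergenic background and unmethylated
#' CpG-island promoters.
#'
#' @return Character vector of the nine class identifiers.
#' @export
locus_classes <- function() {
  c("IMPRINTED_GDMD", "GDMD_LIKE", "RE_LINE", "RE_SINE", "RE_IAP",
    "RE_SATELLITE", "GENIC_BODY", "INTERGENIC", "CGI_PROMOTER_UNMETH")
}

#' Repeat class labels used in BED output
#'
#' Fixed mapping from repeat locus classes to the class strings written in
#' (and read back from) the repeats BED file.
#'
#' @return Named character vector, names are locus classes.
#' @export
repeat_class_labels <- function() {
  c(RE_LINE = "LINE", RE_SINE = "SINE", RE_IAP = "IAP",
    RE_SATELLITE = "Satellite")
}

#' Genomic feature vocabulary
#'
#' The eight single-label genomic features a tile can be assigned, in
#' decreasing annotation priority.
#'
#' @return Character vector of length 8.
#' @export
feature_vocabulary <- function() {
  c("promoter-TSS", "TTS", "5UTR", "3UTR", "exon", "intron",
    "noncoding", "intergenic")
}

#' Per-class methylation inheritance parameters
#'
#' One row per locus class. `m0` is the initial (pre-treatment) methylation
#' fraction; `rho_on` the maintenance efficiency when DNMT1 is present
#' (probability that the daughter site of a methylated CpG dyad is
#' methylated at replication); `delta` the de novo methylation probability
#' per division during the suppression phase; `delta_recovery` the de novo
#' probability during recovery (defaults to `delta`); `theta` the de novo
#' gate threshold: de novo methylation acts only while the current regional
#' methylation is at least `theta`, making fully unmethylated regions
#' immune to remethylation; `alleles` is 1 or 2, with two-allele classes
#' (the imprinted gDMDs) carrying per-allele starting values `m0_allele1`
#' and `m0_allele2`.
#'
#' Defaults encode the behaviour of each class under transient DNMT1 loss:
#' imprinted gDMDs start at 50\% (one fully methylated, one fully
#' unmethylated allele) and never regain methylation; gDMD-like loci are
#' highly methylated, fall below the gate during suppression and stay
#' unmethylated; LINE-like repeats lose nearly all methylation at d0 but
#' are efficiently remethylated; SINE/IAP/satellite repeats plateau at
#' their de novo rate (22--35\%) and recover; gene bodies and intergenic
#' background retain intermediate methylation and recover; unmethylated
#' CpG-island promoters stay at zero throughout.
#'
#' @return data.frame keyed by `class`.
#' @export
default_dynamics_params <- function() {
  p <- data.frame(
    class = locus_classes(),
    m0    = c(0.50, 0.90, 0.95, 0.90, 0.95, 0.90, 0.85, 0.85, 0.00),
    rho_on = c(1, 1, 1, 1, 1, 1, 1, 1, 1),
    delta  = c(0.00, 0.02, 0.02, 0.30, 0.25, 0.33, 0.25, 0.15, 0.00),
    delta_recovery = c(0.00, 0.02, 0.15, 0.30, 0.25, 0.33, 0.25, 0.15, 0.00),
    theta  = c(0.05, 0.05, 0.00, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
    alleles = c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    m0_allele1 = c(1, NA, NA, NA, NA, NA, NA, NA, NA),
    m0_allele2 = c(0, NA, NA, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  rownames(p) <- p$class
  validate_dynamics_params(p)
  p
}

#' @keywords internal
validate_dynamics_params <- function(p) {
  stopifnot(is.data.frame(p),
            all(c("class", "m0", "rho_on", "delta", "delta_recovery",
                  "theta", "alleles") %in% names(p)))
  num <- c("m0", "rho_on", "delta", "delta_recovery", "theta")
  for (col in num) {
    v <- p[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("dynamics parameter '", col, "' must lie in [0, 1]")
  }
  if (!all(p$alleles %in% c(1L, 2L)))
    stop("'alleles' must be 1 or 2")
  two <- p$alleles == 2L
  if (any(two & (is.na(p$m0_allele1) | is.na(p$m0_allele2))))
    stop("two-allele classes need m0_allele1 and m0_allele2")
  invisible(p)
}

#' Simulation parameters for a hypermethylation-prone locus
#'
#' A small set of low-methylation intergenic loci is flagged
#' `hyper_prone` by the genome generator and simulated with these
#' parameters: an elevated de novo rate confined to the recovery phase
#' drives their methylation above the starting level by d21, exercising
#' the hypermethylation branch of the pipeline.  The mechanism is a
#' modelling placeholder, not a biological claim.
#'
#' @return One-row data.frame in the [default_dynamics_params()] layout.
#' @export
hyper_prone_params <- function() {
  data.frame(class = "INTERGENIC", m0 = 0.10, rho_on = 1,
             delta = 0.01, delta_recovery = 0.05, theta = 0,
             alleles = 1L, m0_allele1 = NA_real_, m0_allele2 = NA_real_,
             stringsAsFactors = FALSE)
}

#' Experiment timeline
#'
#' Sampled timepoints of the suppression/recovery time course, together
#' with the cell-division schedule: `divisions_off` divisions occur with
#' maintenance methylation off (between control and d0), then
#' `divisions_per_day_on` divisions per recovery day with maintenance
#' restored.
#'
#' @param timepoints Ordered character vector; `"control"` then `"d0"`
#'   then recovery days `"d<k>"`.
#' @param divisions_off Cell divisions with DNMT1 absent (default 8).
#' @param divisions_per_day_on Divisions per recovery day (default 2).
#' @return An object of class `"timeline"`.
#' @export
timeline <- function(timepoints = c("control", "d0", "d3", "d5", "d7",
                                    "d10", "d14", "d21"),
                     divisions_off = 8L,
                     divisions_per_day_on = 2L) {
  stopifnot(length(timepoints) >= 2, timepoints[1] == "control",
            timepoints[2] == "d0", divisions_off >= 0,
            divisions_per_day_on >= 0)
  days <- timepoint_days(timepoints)
  if (is.unsorted(days[-1], strictly = TRUE))
    stop("recovery timepoints must be strictly increasing days")
  structure(list(timepoints = timepoints,
                 days = days,
                 divisions_off = as.integer(divisions_off),
                 divisions_per_day_on = as.integer(divisions_per_day_on)),
            class = "timeline")
}

#' @keywords internal
timepoint_days <- function(tp) {
  days <- rep(NA_real_, length(tp))
  days[tp == "control"] <- NA
  d <- grepl("^d[0-9]+$", tp)
  days[d] <- as.numeric(sub("^d", "", tp[d]))
  if (any(!d & tp != "control"))
    stop("timepoint labels must be 'control' or 'd<day>'")
  days
}

#' Division schedule of a timeline
#'
#' @param tl A [timeline()].
#' @return data.frame with one row per timepoint: cumulative
#'   maintenance-off divisions (`n_off`) and maintenance-on recovery
#'   divisions (`n_on`) experienced by that timepoint.
#' @export
timeline_divisions <- function(tl) {
  stopifnot(inherits(tl, "timeline"))
  n_off <- ifelse(tl$timepoints == "control", 0L, tl$divisions_off)
  n_on <- ifelse(is.na(tl$days), 0L,
                 as.integer(tl$days * tl$divisions_per_day_on))
  data.frame(timepoint = tl$timepoints, n_off = n_off, n_on = n_on,
             stringsAsFactors = FALSE)
}

#' @export
print.timeline <- function(x, ...) {
  cat("Timeline:", paste(x$timepoints, collapse = " -> "), "\n")
  cat("  divisions with maintenance off:", x$divisions_off, "\n")
  cat("  recovery divisions per day:    ", x$divisions_per_day_on, "\n")
  invisible(x)
}

#' RRBS count-noise parameters
#'
#' Per-CpG read coverage is drawn from a negative binomial with mean
#' `mean_coverage` and size (dispersion) `coverage_dispersion`; the
#' per-CpG methylation probability is drawn from a mean-preserving Beta
#' distribution around the class trajectory whose standard deviation at
#' a methylation level of 0.5 is `site_jitter_sd` (0 disables jitter).
#'
#' @param mean_coverage Mean reads per CpG (default 30, so most tiles
#'   clear the 20x filter).
#' @param coverage_dispersion Negative-binomial size parameter.
#' @param site_jitter_sd Site-level biological variability.
#' @return An object of class `"noise_params"`.
#' @export
noise_params <- function(mean_coverage = 30, coverage_dispersion = 5,
                         site_jitter_sd = 0.05) {
  stopifnot(mean_coverage > 0, coverage_dispersion > 0,
            site_jitter_sd >= 0, site_jitter_sd < 0.5)
  structure(list(mean_coverage = mean_coverage,
                 coverage_dispersion = coverage_dispersion,
                 site_jitter_sd = site_jitter_sd),
            class = "noise_params")
}

# Run `code` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}
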