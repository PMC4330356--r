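#' Read per-CpG methylation calls
#'
#' Reads a tab-separated methylation call table with columns
#' `chrom`, `pos`, `strand`, `coverage`, `n_meth` (a superset of the
#' bismark coverage dialect, with 0-based positions and counts rather
#' than percentages).  Rows are validated (`0 <= n_meth <= coverage`,
#' no duplicate `(chrom, pos, strand)`) and returned sorted by
#' `(chrom, pos)`.
#'
#' @param path File path.
#' @return data.frame of methylation calls.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "character"),
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "coverage", "n_meth")
  if (!identical(names(df), need))
    stop("call file must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), coverage = integer(),
                      n_meth = integer()))
  }
  for (col in c("pos", "coverage", "n_meth")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("malformed value in column '", col, "' at line ",
           bad[1] + 1L, " of ", path)
    df[[col]] <- v
  }
  validate_calls(df, path)
}

#' @keywords internal
validate_calls <- function(df, what = "calls") {
  bad <- which(df$n_meth > df$coverage | df$n_meth < 0 | df$coverage < 0)
  if (length(bad))
    stop("invalid counts (n_meth > coverage or negative) in ", what,
         " at row ", bad[1], ": chrom=", df$chrom[bad[1]],
         " pos=", df$pos[bad[1]])
  if (!all(df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*' in ", what)
  dup <- duplicated(df[c("chrom", "pos", "strand")])
  if (any(dup))
    stop("duplicate (chrom, pos, strand) in ", what, ": chrom=",
         df$chrom[which(dup)[1]], " pos=", df$pos[which(dup)[1]])
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write per-CpG methylation calls
#'
#' @param calls data.frame with columns chrom, pos, strand, coverage,
#'   n_meth.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_calls <- function(calls, path) {
  need <- c("chrom", "pos", "strand", "coverage", "n_meth")
  stopifnot(all(need %in% names(calls)))
  utils::write.table(calls[need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated table with columns `sample_id`, `timepoint`,
#' `replicate`, `path`.  Sample ids must be unique; file existence is
#' checked when `check_files` is TRUE.
#'
#' @param path Manifest path.
#' @param check_files Verify that each listed call file exists.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "timepoint", "replicate", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  validate_manifest(df[need], check_files = check_files)
}

#' @keywords internal
validate_manifest <- function(df, check_files = FALSE) {
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest")
  if (any(table(df$timepoint) < 1))
    stop("every timepoint needs at least one replicate")
  if (check_files) {
    missing <- df$path[!file.exists(df$path)]
    if (length(missing))
      stop("manifest refers to missing file(s): ",
           paste(missing, collapse = ", "))
  }
  df
}

#' Write a sample manifest
#'
#' @param manifest data.frame with sample_id, timepoint, replicate, path.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED interval file
#'
#' Supports three dialects: `"bed4"` (chrom, start, end, name), `"bed6"`
#' (+ score, strand) and `"bed6+1"` (one extra annotation column, e.g. a
#' gene feature or repeat class).  Intervals are 0-based half-open and
#' returned sorted within chromosome; `start >= end` is rejected.
#'
#' @param path BED path.
#' @param dialect One of "bed4", "bed6", "bed6+1".
#' @return data.frame of intervals (`extra` column for bed6+1).
#' @export
read_bed <- function(path, dialect = c("bed6+1", "bed6", "bed4")) {
  dialect <- match.arg(dialect)
  ncols <- switch(dialect, bed4 = 4L, bed6 = 6L, `bed6+1` = 7L)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "extra")[seq_len(ncols)]
  info <- file.info(path)
  if (is.na(info$size)) stop("no such file: ", path)
  if (info$size == 0) {
    df <- as.data.frame(stats::setNames(
      rep(list(character()), ncols), cols), stringsAsFactors = FALSE)
    df$start <- integer(); df$end <- integer()
    return(df)
  }
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) != ncols)
    stop("expected ", ncols, " columns for ", dialect, ", found ",
         ncol(df), " in ", path)
  names(df) <- cols
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end)))
    stop("non-numeric interval bounds in ", path)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("invalid interval (start >= end) at line ", bad[1], " of ", path)
  if (any(df$start < 0)) stop("negative start in ", path)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a BED interval file
#'
#' @param intervals data.frame with the dialect's columns (see
#'   [read_bed()]).
#' @param path Output path.
#' @param dialect One of "bed4", "bed6", "bed6+1".
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path,
                      dialect = c("bed6+1", "bed6", "bed4")) {
  dialect <- match.arg(dialect)
  ncols <- switch(dialect, bed4 = 4L, bed6 = 6L, `bed6+1` = 7L)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "extra")[seq_len(ncols)]
  stopifnot(all(cols %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop("invalid interval (start >= end)")
  ok <- tryCatch({
    utils::write.table(intervals[cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Write a tile matrix as TSV
#'
#' Columns: tile_id, chrom, start, end, n_cpg (minimum across samples),
#' then one methylation and one mean-coverage column per sample
#' (`meth.<sample>`, `cov.<sample>`).
#'
#' @param tm A `"tile_matrix"` (see [make_tiles()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tile_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "tile_matrix"))
  df <- tm$tiles
  df$n_cpg <- apply(tm$n_cpg, 1, min)
  meth <- as.data.frame(tm$meth)
  names(meth) <- paste0("meth.", colnames(tm$meth))
  cov <- as.data.frame(tm$cov)
  names(cov) <- paste0("cov.", colnames(tm$cov))
  utils::write.table(cbind(df, meth, cov), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tile matrix TSV
#'
#' Reconstructs a reduced `"tile_matrix"` (methylation and coverage
#' matrices; pooled counts are not stored in the TSV form).
#'
#' @param path Path written by [write_tile_matrix()].
#' @param manifest Optional manifest restoring timepoint groups.
#' @return A `"tile_matrix"` object.
#' @export
read_tile_matrix <- function(path, manifest = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  mcols <- grep("^meth\\.", names(df), value = TRUE)
  ccols <- grep("^cov\\.", names(df), value = TRUE)
  samples <- sub("^meth\\.", "", mcols)
  meth <- as.matrix(df[mcols]); colnames(meth) <- samples
  cov <- as.matrix(df[ccols]); colnames(cov) <- samples
  rownames(meth) <- rownames(cov) <- df$tile_id
  tiles <- df[c("tile_id", "chrom", "start", "end")]
  if (is.null(manifest))
    manifest <- data.frame(sample_id = samples,
                           timepoint = sub("_r[0-9]+$", "", samples),
                           replicate = NA_integer_, path = NA_character_,
                           stringsAsFactors = FALSE)
  new_tile_matrix(tiles, meth, cov,
                  n_cpg = matrix(df$n_cpg, nrow(df), length(samples),
                                 dimnames = list(df$tile_id, samples)),
                  meth_counts = NULL, total_counts = NULL,
                  manifest = manifest)
}
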