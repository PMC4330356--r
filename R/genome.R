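#' Genome specification
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param rng_seed Integer seed controlling locus and CpG placement.
#' @return An object of class `"genome_spec"`.
#' @export
genome_spec <- function(chromosomes = c(chr1 = 5e6, chr2 = 5e6),
                        rng_seed = 1L) {
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosomes must have unique names")
  if (any(chromosomes <= 0)) stop("chromosome lengths must be positive")
  structure(list(chromosomes = chromosomes,
                 rng_seed = as.integer(rng_seed)),
            class = "genome_spec")
}

#' Default locus-class counts
#'
#' The default synthetic genome carries 15 imprinted gDMDs (the number of
#' confirmed imprinted genes recovered by the tile analysis), a few dozen
#' gDMD-like loci, four repeat classes, and a genic/intergenic/CGI-promoter
#' background, for roughly 4,000 loci in total.
#'
#' @return Named integer vector over [locus_classes()].
#' @export
default_class_counts <- function() {
  c(IMPRINTED_GDMD = 15L, GDMD_LIKE = 40L, RE_LINE = 600L, RE_SINE = 600L,
    RE_IAP = 300L, RE_SATELLITE = 200L, GENIC_BODY = 1100L,
    INTERGENIC = 950L, CGI_PROMOTER_UNMETH = 200L)
}

#' Default CpG sites per locus, by class
#'
#' CpGs are laid down in dense clusters (about 7 CpGs per 100 bp patch in
#' CGI-like loci and 4 elsewhere, mirroring typical RRBS tile densities)
#' so that 100 bp tiles carry several CpGs each.
#'
#' @return Named integer vector over [locus_classes()].
#' @export
default_cpg_density <- function() {
  c(IMPRINTED_GDMD = 21L, GDMD_LIKE = 21L, RE_LINE = 8L, RE_SINE = 4L,
    RE_IAP = 8L, RE_SATELLITE = 8L, GENIC_BODY = 12L, INTERGENIC = 8L,
    CGI_PROMOTER_UNMETH = 14L)
}

# Locus lengths (bp) by class; internal sizing constants chosen so the
# default genome is ~60% locus-covered, leaving realistic inter-locus
# gaps for the promoter/TTS annotation windows.
locus_lengths <- function() {
  c(IMPRINTED_GDMD = 1200L, GDMD_LIKE = 1200L, RE_LINE = 1500L,
    RE_SINE = 300L, RE_IAP = 1000L, RE_SATELLITE = 1000L,
    GENIC_BODY = 2500L, INTERGENIC = 1500L, CGI_PROMOTER_UNMETH = 1000L)
}

cgi_like_classes <- function() {
  c("IMPRINTED_GDMD", "GDMD_LIKE", "CGI_PROMOTER_UNMETH")
}

#' Build a synthetic annotated genome
#'
#' Places non-overlapping loci of the requested classes on the
#' specification's chromosomes (coordinates only, no nucleotide sequence)
#' and scatters clustered CpG sites inside each locus.  Gene-bearing
#' classes (imprinted gDMDs, gDMD-like loci, gene bodies, unmethylated
#' CGI promoters) receive unique gene identifiers and gene models:
#' promoter-centred loci sit on the TSS of a short single-exon gene,
#' while gene bodies carry a 5'UTR/exon/intron/3'UTR structure.
#' All coordinates are 0-based half-open.
#'
#' @param spec A [genome_spec()].
#' @param class_counts Named integer vector of loci per class.
#' @param cpg_density CpG sites per locus; a scalar or a named per-class
#'   vector.
#' @param hyper_prone_n Number of intergenic loci flagged as
#'   hypermethylation-prone (see [hyper_prone_params()]).
#' @param min_gap Minimum gap between adjacent loci, in bp.
#' @return A list of class `"synthetic_genome"` with elements `loci`,
#'   `cpgs`, `features` (gene sub-feature intervals), `genes`, and `spec`.
#' @export
build_genome <- function(spec = genome_spec(),
                         class_counts = default_class_counts(),
                         cpg_density = default_cpg_density(),
                         hyper_prone_n = 8L, min_gap = 200L) {
  stopifnot(inherits(spec, "genome_spec"))
  if (any(class_counts < 0)) stop("class counts must be >= 0")
  bad <- setdiff(names(class_counts), locus_classes())
  if (length(bad)) stop("unknown locus class: ", paste(bad, collapse = ", "))
  if (length(cpg_density) == 1 && is.null(names(cpg_density))) {
    cpg_density <- stats::setNames(rep(as.integer(cpg_density),
                                       length(locus_classes())),
                                   locus_classes())
  }
  if (any(cpg_density < 1)) stop("cpg_density must be >= 1")
  if (sum(class_counts) == 0) return(empty_genome(spec))

  with_seed(spec$rng_seed, {
    cls <- rep(names(class_counts), class_counts)
    n <- length(cls)
    len <- locus_lengths()[cls]
    chrom <- sample(names(spec$chromosomes), n, replace = TRUE,
                    prob = spec$chromosomes / sum(spec$chromosomes))

    loci <- vector("list", length(spec$chromosomes))
    names(loci) <- names(spec$chromosomes)
    for (ch in names(spec$chromosomes)) {
      idx <- which(chrom == ch)
      if (!length(idx)) next
      idx <- idx[sample.int(length(idx))]   # random order along the chromosome
      total <- sum(len[idx]) + (length(idx) + 1) * min_gap
      clen <- spec$chromosomes[[ch]]
      if (total > clen)
        stop("chromosome ", ch, " too small for requested loci (needs ",
             total, " bp, has ", clen, ")")
      # gaps: minimum spacing plus a random split of the free space
      w <- stats::runif(length(idx) + 1)
      gaps <- min_gap + floor(w / sum(w) * (clen - total))
      start <- cumsum(c(0, len[idx])) [seq_along(idx)] + cumsum(gaps)[seq_along(idx)]
      loci[[ch]] <- data.frame(chrom = ch, start = start,
                               end = start + len[idx],
                               class = cls[idx],
                               stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, loci)
    loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
    rownames(loci) <- NULL
    loci$locus_id <- sprintf("L%05d", seq_len(nrow(loci)))
    loci$strand <- sample(c("+", "-"), nrow(loci), replace = TRUE)

    # gene identifiers per gene-bearing class
    loci$gene_id <- NA_character_
    gene_prefix <- c(IMPRINTED_GDMD = "Imp", GDMD_LIKE = "Gdl",
                     GENIC_BODY = "Gene", CGI_PROMOTER_UNMETH = "CgiP")
    for (cl in names(gene_prefix)) {
      i <- which(loci$class == cl)
      if (length(i))
        loci$gene_id[i] <- sprintf("%s%04d", gene_prefix[[cl]], seq_along(i))
    }
    loci$cgi_flag <- loci$class %in% c("IMPRINTED_GDMD", "CGI_PROMOTER_UNMETH")
    loci$repeat_class <- unname(repeat_class_labels()[loci$class])
    loci$hyper_prone <- FALSE
    ig <- which(loci$class == "INTERGENIC")
    if (hyper_prone_n > 0 && length(ig))
      loci$hyper_prone[sample(ig, min(hyper_prone_n, length(ig)))] <- TRUE

    features <- build_gene_models(loci, spec)
    cpgs <- place_cpgs(loci, cpg_density)

    structure(list(loci = loci, cpgs = cpgs,
                   features = features$features, genes = features$genes,
                   spec = spec),
              class = "synthetic_genome")
  })
}

#' @keywords internal
empty_genome <- function(spec) {
  structure(list(
    loci = data.frame(chrom = character(), start = integer(),
                      end = integer(), class = character(),
                      locus_id = character(), strand = character(),
                      gene_id = character(), cgi_flag = logical(),
                      repeat_class = character(), hyper_prone = logical()),
    cpgs = data.frame(chrom = character(), pos = integer(),
                      locus_id = character(), class = character()),
    features = data.frame(chrom = character(), start = integer(),
                          end = integer(), gene_id = character(),
                          strand = character(), feature = character()),
    genes = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), tss = integer(),
                       tts = integer()),
    spec = spec), class = "synthetic_genome")
}

# Gene models:
#  - promoter-centred classes (gDMD, gDMD-like, CGI promoter): the locus
#    midpoint is the TSS of a 1.5 kb single-exon gene running downstream;
#  - gene bodies: 5'UTR (200 bp), alternating exons (300) / introns (700),
#    3'UTR (200), oriented by strand.
build_gene_models <- function(loci, spec) {
  feats <- list()
  genes <- list()
  promo <- loci$class %in% c("IMPRINTED_GDMD", "GDMD_LIKE",
                             "CGI_PROMOTER_UNMETH")
  if (any(promo)) {
    g <- loci[promo, , drop = FALSE]
    mid <- floor((g$start + g$end) / 2)
    glen <- 1500L
    clen <- spec$chromosomes[g$chrom]
    gstart <- ifelse(g$strand == "+", mid, pmax(0, mid - glen))
    gend <- ifelse(g$strand == "+", pmin(clen, mid + glen), mid)
    feats[[length(feats) + 1]] <- data.frame(
      chrom = g$chrom, start = gstart, end = gend, gene_id = g$gene_id,
      strand = g$strand, feature = "exon", stringsAsFactors = FALSE)
    genes[[length(genes) + 1]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, start = gstart, end = gend,
      strand = g$strand, stringsAsFactors = FALSE)
  }
  body <- which(loci$class == "GENIC_BODY")
  if (length(body)) {
    g <- loci[body, , drop = FALSE]
    tmpl <- gene_body_template(locus_lengths()[["GENIC_BODY"]])
    per <- nrow(tmpl)
    rel_start <- rep(tmpl$start, times = nrow(g))
    rel_end <- rep(tmpl$end, times = nrow(g))
    feat <- rep(tmpl$feature, times = nrow(g))
    gs <- rep(g$start, each = per)
    ge <- rep(g$end, each = per)
    strand <- rep(g$strand, each = per)
    # flip the template for minus-strand genes so the 5'UTR is 3'-ward
    start <- ifelse(strand == "+", gs + rel_start, ge - rel_end)
    end <- ifelse(strand == "+", gs + rel_end, ge - rel_start)
    feats[[length(feats) + 1]] <- data.frame(
      chrom = rep(g$chrom, each = per), start = start, end = end,
      gene_id = rep(g$gene_id, each = per), strand = strand,
      feature = feat, stringsAsFactors = FALSE)
    genes[[length(genes) + 1]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
      strand = g$strand, stringsAsFactors = FALSE)
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    empty_genome(genome_spec())$features
  genes <- if (length(genes)) do.call(rbind, genes) else
    empty_genome(genome_spec())$genes[, 1:5]
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  features <- features[order(features$chrom, features$start), , drop = FALSE]
  rownames(features) <- rownames(genes) <- NULL
  list(features = features, genes = genes)
}

gene_body_template <- function(len) {
  utr5 <- 200L; utr3 <- 200L; exon <- 300L; intron <- 700L
  parts <- data.frame(start = 0L, end = utr5, feature = "5UTR",
                      stringsAsFactors = FALSE)
  at <- utr5
  repeat {
    if (at + exon + utr3 > len) break
    parts <- rbind(parts, data.frame(start = at, end = at + exon,
                                     feature = "exon"))
    at <- at + exon
    if (at + intron + exon + utr3 > len) break
    parts <- rbind(parts, data.frame(start = at, end = at + intron,
                                     feature = "intron"))
    at <- at + intron
  }
  rbind(parts, data.frame(start = len - utr3, end = len, feature = "3UTR"))
}

# Clustered CpG placement: CpGs fall in ~100 bp patches of `patch` sites
# each (7 for CGI-like loci, 4 elsewhere), at unique sorted positions.
place_cpgs <- function(loci, cpg_density) {
  if (!nrow(loci)) return(empty_genome(genome_spec())$cpgs)
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    n <- cpg_density[[loci$class[i]]]
    patch <- if (loci$class[i] %in% cgi_like_classes()) 7L else 4L
    npatch <- max(1L, ceiling(n / patch))
    width <- loci$end[i] - loci$start[i]
    span <- min(90L, width - 1L)
    centers <- loci$start[i] +
      sort(sample.int(max(1L, width - span), npatch, replace = TRUE)) - 1L
    sizes <- diff(round(seq(0, n, length.out = npatch + 1)))
    pos <- unlist(lapply(seq_len(npatch), function(k) {
      centers[k] + sample.int(span + 1L, min(sizes[k], span + 1L)) - 1L
    }))
    pos <- sort(unique(pmin(pos, loci$end[i] - 1L)))
    if (!length(pos)) pos <- loci$start[i]
    out[[i]] <- data.frame(chrom = loci$chrom[i], pos = pos,
                           locus_id = loci$locus_id[i],
                           class = loci$class[i],
                           stringsAsFactors = FALSE)
  }
  cpgs <- do.call(rbind, out)
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos), , drop = FALSE]
  cpgs <- cpgs[!duplicated(cpgs[c("chrom", "pos")]), , drop = FALSE]
  rownames(cpgs) <- NULL
  cpgs
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome:", length(x$spec$chromosomes), "chromosome(s),",
      sum(x$spec$chromosomes), "bp\n")
  cat(" ", nrow(x$loci), "loci,", nrow(x$cpgs), "CpG sites\n")
  if (nrow(x$loci)) print(table(x$loci$class))
  invisible(x)
}

#' Write genome annotation as BED files
#'
#' Writes three BED dialects: gene features as BED6 plus a feature column
#' (`genes.bed`), CpG islands as BED4 (`cgi.bed`) and repeats as BED6 plus
#' a repeat-class column (`repeats.bed`).  Coordinates are 0-based
#' half-open, as in the BED standard.
#'
#' @param genome A `"synthetic_genome"` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_annotation <- function(genome, dir) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  paths <- c(genes = file.path(dir, "genes.bed"),
             cgi = file.path(dir, "cgi.bed"),
             repeats = file.path(dir, "repeats.bed"))
  f <- genome$features
  write_bed(data.frame(chrom = f$chrom, start = f$start, end = f$end,
                       name = f$gene_id, score = rep(0L, nrow(f)),
                       strand = f$strand, extra = f$feature,
                       stringsAsFactors = FALSE),
            paths["genes"], dialect = "bed6+1")
  cg <- genome$loci[genome$loci$cgi_flag, , drop = FALSE]
  write_bed(data.frame(chrom = cg$chrom, start = cg$start, end = cg$end,
                       name = cg$locus_id, stringsAsFactors = FALSE),
            paths["cgi"], dialect = "bed4")
  rp <- genome$loci[!is.na(genome$loci$repeat_class), , drop = FALSE]
  write_bed(data.frame(chrom = rp$chrom, start = rp$start, end = rp$end,
                       name = rp$locus_id, score = rep(0L, nrow(rp)),
                       strand = rp$strand, extra = rp$repeat_class,
                       stringsAsFactors = FALSE),
            paths["repeats"], dialect = "bed6+1")
  invisible(paths)
}
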