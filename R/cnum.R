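#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps
NULL

# Peaks travel as tibbles (chrom, start, end, ...) in BED convention
# (0-based, half-open); GRanges (1-based, closed) only internally.
peaks_to_granges <- function(peaks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) abort("peak start must be < end")
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

#' Read a narrowPeak (or BED) peak file
#'
#' narrowPeak files carry the MACS signal value in column 7, used as the
#' peak `score`; plain BED files fall back to the BED score column when
#' present.
#'
#' @param path path to a narrowPeak / BED file.
#' @return a tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score` (narrowPeak signalValue where available).
#' @export
read_narrowpeak <- function(path) {
  first <- readLines(path, n = 1)
  ncol <- length(strsplit(first, "\t")[[1]])
  if (ncol >= 10) {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(signalValue = "numeric",
                                            pValue = "numeric",
                                            qValue = "numeric",
                                            peak = "integer"))
    score <- gr$signalValue
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    score <- if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = score
  )
}

#' Write peaks as a narrowPeak file
#'
#' @param peaks a peak tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    chrom = peaks$chrom,
    start = peaks$start,
    end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name else
      paste0("peak_", seq_len(nrow(peaks))),
    score = 0L,
    strand = ".",
    signalValue = if ("score" %in% names(peaks)) peaks$score else 0,
    pValue = -1,
    qValue = -1,
    peak = -1L
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count the clusters in which each peak is present
#'
#' `cnum` of a union peak is the number of cell clusters whose peak set
#' contains at least one peak overlapping it by `min_overlap` bases or more;
#' constitutive peaks reach the maximal cnum (present in every cluster),
#' cluster-specific peaks have cnum 1.
#'
#' @param union_peaks a peak tibble (typically the union peak set called on
#'   all nuclei).
#' @param clusters a named list of peak tibbles, one per cell cluster.
#' @param min_overlap minimum overlap in bases (default 1).
#' @return `union_peaks` with an added integer `cnum` column.
#' @export
assign_cnum <- function(union_peaks, clusters, min_overlap = 1) {
  if (length(clusters) == 0) abort("at least one cluster peak set required")
  gr <- peaks_to_granges(union_peaks)
  hits <- purrr::map(clusters, function(p) {
    suppressWarnings(  # disjoint seqlevels are a legitimate zero-overlap case
      IRanges::overlapsAny(gr, peaks_to_granges(p), minoverlap = min_overlap)
    )
  })
  dplyr::mutate(as_tibble(union_peaks),
                cnum = as.integer(Reduce(`+`, hits)))
}

#' Attach bulk peak intensities to single-cell peaks
#'
#' Each record receives the maximum `score` among bulk peaks it overlaps
#' (at least one base); records overlapping no bulk peak keep `bulk_score`
#' NA and are excluded from downstream intensity analysis.
#'
#' @param records a peak tibble (e.g. from [assign_cnum()]).
#' @param bulk_peaks a peak tibble with a `score` column (bulk intensities).
#' @return `records` with an added `bulk_score` column; the number of
#'   overlapping records is available as `attr(, "n_overlapping")`.
#' @export
attach_bulk <- function(records, bulk_peaks) {
  if (!"score" %in% names(bulk_peaks) || all(is.na(bulk_peaks$score))) {
    abort("bulk peaks must carry scores")
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(peaks_to_granges(records),
                                peaks_to_granges(bulk_peaks))
  )
  best <- tibble(
    i = S4Vectors::queryHits(hits),
    score = bulk_peaks$score[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::group_by(.data$i) |>
    dplyr::summarise(bulk_score = max(.data$score), .groups = "drop")
  out <- dplyr::mutate(as_tibble(records), bulk_score = NA_real_)
  out$bulk_score[best$i] <- best$bulk_score
  attr(out, "n_overlapping") <- nrow(best)
  out
}

#' Split a bimodal intensity distribution into low and high groups
#'
#' Fits a deterministic two-component Gaussian mixture ([fit_gmm2()]) to
#' `log(score)` and places the threshold at the posterior crossover (the
#' smallest score whose high-component posterior exceeds 0.5). The density
#' dip (antimode) between the fitted means is reported as a bimodality
#' diagnostic. Intended for the constitutive (maximal-cnum) peak group,
#' whose bulk intensities separate into stochastic (low) and constant
#' (high) open-chromatin regions.
#'
#' @param scores positive intensity vector (at least 100 values unless
#'   `manual_threshold` is given).
#' @param manual_threshold optional fixed threshold overriding the mixture
#'   fit.
#' @return an object of class `intensity_split`: `threshold`,
#'   `labels` (factor `"low"`/`"high"` along `scores`), `fit` (the `gmm2`,
#'   log scale), `dip` (antimode location and density, log scale).
#' @export
dichotomize_intensity <- function(scores, manual_threshold = NULL) {
  if (any(is.na(scores)) || any(scores <= 0)) {
    abort("scores must be positive and non-missing")
  }
  if (is.null(manual_threshold)) {
    if (length(scores) < 100) {
      abort("fewer than 100 scores: supply manual_threshold")
    }
    if (diff(range(scores)) == 0) {
      abort("degenerate (all equal) scores: supply manual_threshold")
    }
    lx <- log(scores)
    fit <- fit_gmm2(lx)
    grid <- sort(unique(lx))
    post <- posterior_high(fit, grid)
    hit <- which(post > 0.5)
    thr_log <- if (length(hit) == 0) max(grid) + 1e-9 else grid[hit[1]]
    threshold <- exp(thr_log)
    dip <- gmm2_dip(fit)
  } else {
    threshold <- manual_threshold
    fit <- NULL
    dip <- NULL
  }
  structure(
    list(
      threshold = threshold,
      labels = factor(ifelse(scores >= threshold, "high", "low"),
                      levels = c("low", "high")),
      fit = fit,
      dip = dip
    ),
    class = "intensity_split"
  )
}

#' @export
print.intensity_split <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<intensity_split> threshold %.4g: %d low, %d high\n",
              x$threshold, tab["low"], tab["high"]))
  if (!is.null(x$dip)) {
    cat(sprintf("density dip at log-score %.3f (density %.4g)\n",
                x$dip$at, x$dip$density))
  }
  invisible(x)
}

#' @exportS3Method
tidy.intensity_split <- function(x, ...) {
  tibble(intensity_group = x$labels)
}

#' @exportS3Method
glance.intensity_split <- function(x, ...) {
  tab <- table(x$labels)
  tibble(threshold = x$threshold,
         n_low = as.integer(tab["low"]), n_high = as.integer(tab["high"]),
         dip_at = if (is.null(x$dip)) NA_real_ else x$dip$at)
}

#' Annotate peaks with genomic features from a gene model
#'
#' Each peak is classified by its midpoint with the precedence
#' promoter > 5' UTR > 3' UTR > exon > intron > intergenic. Promoters are
#' TSS +/- `promoter_window` bases (strand-aware TSS); introns are
#' transcript bases not covered by exons. Peaks on chromosomes absent from
#' the gene model are intergenic, with a warning.
#'
#' @param records a peak tibble.
#' @param gene_model path to a GTF file, or a `GRanges` imported from one
#'   (feature types `transcript`, `exon`, `five_prime_utr`,
#'   `three_prime_utr` are used).
#' @param promoter_window half-width of the promoter window around the TSS
#'   in bases (default 2000).
#' @return `records` with an added `feature` factor column (levels
#'   `promoter`, `utr5`, `utr3`, `exon`, `intron`, `intergenic`).
#' @export
annotate_features <- function(records, gene_model, promoter_window = 2000) {
  gtf <- if (is.character(gene_model)) {
    rtracklayer::import(gene_model, format = "gtf")
  } else {
    gene_model
  }
  type <- as.character(gtf$type)
  tx <- gtf[type == "transcript"]
  if (length(tx) == 0) tx <- gtf[type == "gene"]
  exons <- gtf[type == "exon"]
  utr5 <- gtf[type %in% c("five_prime_utr", "5UTR")]
  utr3 <- gtf[type %in% c("three_prime_utr", "3UTR")]

  tss <- GenomicRanges::resize(tx, width = 1, fix = "start")
  prom <- suppressWarnings(
    GenomicRanges::resize(tss, width = 2 * promoter_window + 1, fix = "center")
  )
  prom <- GenomicRanges::trim(prom)
  introns <- GenomicRanges::setdiff(GenomicRanges::reduce(tx, ignore.strand = TRUE),
                                    GenomicRanges::reduce(exons, ignore.strand = TRUE))

  mid <- floor((records$start + records$end) / 2)
  mid_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  known <- as.character(GenomicRanges::seqnames(mid_gr)) %in%
    as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(gtf)))
  if (any(!known)) {
    warn(sprintf("%d peak(s) on chromosomes absent from the gene model: intergenic",
                 sum(!known)))
  }
  ov <- function(subject) {
    if (length(subject) == 0) rep(FALSE, length(mid_gr))
    else suppressWarnings(IRanges::overlapsAny(mid_gr, subject,
                                               ignore.strand = TRUE))
  }
  feature <- rep("intergenic", nrow(records))
  feature[ov(introns)] <- "intron"
  feature[ov(exons)] <- "exon"
  feature[ov(utr3)] <- "utr3"
  feature[ov(utr5)] <- "utr5"
  feature[ov(prom)] <- "promoter"
  dplyr::mutate(as_tibble(records),
                feature = factor(feature,
                                 levels = c("promoter", "utr5", "utr3",
                                            "exon", "intron", "intergenic")))
}

#' Fraction of query peaks overlapping a subject peak set
#'
#' @param query,subject peak tibbles (both non-empty).
#' @param min_overlap minimum overlap in bases (default 1).
#' @return a one-row tibble: `n_query`, `n_overlap`, `pct` (one decimal,
#'   half-up).
#' @export
overlap_fraction <- function(query, subject, min_overlap = 1) {
  if (nrow(query) == 0) abort("empty query peak set")
  hit <- suppressWarnings(
    IRanges::overlapsAny(peaks_to_granges(query), peaks_to_granges(subject),
                         minoverlap = min_overlap)
  )
  tibble(n_query = nrow(query), n_overlap = sum(hit),
         pct = percent_of(sum(hit), nrow(query), 1))
}

#' Compare two overlap fractions by chi-squared test
#'
#' Builds the 2x2 overlap / non-overlap contingency table for two query
#' groups against the same subject set and applies Pearson's chi-squared
#' without continuity correction.
#'
#' @param query1,query2 peak tibbles for the two groups.
#' @param subject the common subject peak set.
#' @param min_overlap minimum overlap in bases (default 1).
#' @return a one-row tibble with both percentages, the chi-squared
#'   statistic, df and p value.
#' @export
compare_overlap_fractions <- function(query1, query2, subject,
                                      min_overlap = 1) {
  f1 <- overlap_fraction(query1, subject, min_overlap)
  f2 <- overlap_fraction(query2, subject, min_overlap)
  tab <- rbind(
    c(f1$n_overlap, f1$n_query - f1$n_overlap),
    c(f2$n_overlap, f2$n_query - f2$n_overlap)
  )
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(pct1 = f1$pct, pct2 = f2$pct,
         chi2_stat = unname(ct$statistic),
         chi2_df = unname(ct$parameter),
         chi2_p = ct$p.value)
}

#' Distance from each peak midpoint to the nearest anchor position
#'
#' @param query a peak tibble.
#' @param anchors a tibble with columns `chrom`, `pos` (0-based positions,
#'   e.g. transcription start sites); non-empty.
#' @return `query` with an added `distance` column (absolute base distance
#'   from the peak midpoint to the nearest same-chromosome anchor; NA for
#'   peaks on chromosomes without anchors).
#' @export
distance_to_nearest <- function(query, anchors) {
  if (nrow(anchors) == 0) abort("empty anchor set")
  mid <- floor((query$start + query$end) / 2)
  mid_gr <- GenomicRanges::GRanges(query$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  anchor_gr <- GenomicRanges::GRanges(anchors$chrom,
                                      IRanges::IRanges(anchors$pos + 1L,
                                                       anchors$pos + 1L))
  idx <- suppressWarnings(GenomicRanges::nearest(mid_gr, anchor_gr))
  distance <- abs(mid - anchors$pos[idx])  # NA where no same-chrom anchor
  dplyr::mutate(as_tibble(query), distance = as.numeric(distance))
}
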