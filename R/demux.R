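#' Filter nuclei by total read depth
#'
#' Retains nuclei with at least `min_reads` total reads (inclusive), the
#' depth filter applied before demultiplexing accuracy assessment.
#'
#' @param records a tibble with a `total_reads` column (one row per nucleus).
#' @param min_reads minimum total read count (default 10000).
#' @return the retained rows (possibly none).
#' @export
filter_nuclei <- function(records, min_reads = 10000) {
  stopifnot("total_reads" %in% names(records))
  dplyr::filter(records, .data$total_reads >= min_reads)
}

#' Quality-control filter for nuclei
#'
#' Drops a nucleus when any enabled condition is met: fraction of reads in
#' peaks below `min_frip_pct` percent; fragments aligned to peaks below
#' `min_fragments_in_peaks`; blacklist read ratio above
#' `max_blacklist_ratio`; or nucleosome signal outside
#' `nucleosome_bounds` (exclusive bounds: a record is dropped when the
#' signal is below the lower or above the upper bound). Pass `NULL` for any
#' threshold to disable that predicate.
#'
#' @param records a tibble with columns `frip_pct`, `fragments_in_peaks`,
#'   `blacklist_ratio`, `nucleosome_signal` as required by the enabled
#'   predicates.
#' @param min_frip_pct minimum percent of reads in peaks (default 15).
#' @param min_fragments_in_peaks minimum fragments in peaks (default 2000).
#' @param max_blacklist_ratio maximum blacklist ratio (default 0.05).
#' @param nucleosome_bounds length-2 numeric, keep records strictly inside
#'   (default `c(0.2, 4)`).
#' @return the surviving rows.
#' @export
qc_filter_nuclei <- function(records,
                             min_frip_pct = 15,
                             min_fragments_in_peaks = 2000,
                             max_blacklist_ratio = 0.05,
                             nucleosome_bounds = c(0.2, 4)) {
  need <- function(col, enabled) {
    if (enabled && !col %in% names(records)) {
      abort(sprintf("qc predicate enabled but column `%s` is missing", col))
    }
  }
  need("frip_pct", !is.null(min_frip_pct))
  need("fragments_in_peaks", !is.null(min_fragments_in_peaks))
  need("blacklist_ratio", !is.null(max_blacklist_ratio))
  need("nucleosome_signal", !is.null(nucleosome_bounds))

  drop <- rep(FALSE, nrow(records))
  if (!is.null(min_frip_pct)) drop <- drop | records$frip_pct < min_frip_pct
  if (!is.null(min_fragments_in_peaks)) {
    drop <- drop | records$fragments_in_peaks < min_fragments_in_peaks
  }
  if (!is.null(max_blacklist_ratio)) {
    drop <- drop | records$blacklist_ratio > max_blacklist_ratio
  }
  if (!is.null(nucleosome_bounds)) {
    drop <- drop | records$nucleosome_signal < nucleosome_bounds[1] |
      records$nucleosome_signal > nucleosome_bounds[2]
  }
  records[!drop, , drop = FALSE]
}

# Normalize hash-count input (hash_count_matrix, matrix, or long tibble with
# cell_barcode/sample_id/n_umi) to a cells x samples integer matrix.
as_count_matrix <- function(counts) {
  if (inherits(counts, "hash_count_matrix")) return(counts$counts)
  if (is.matrix(counts)) return(counts)
  stopifnot(all(c("cell_barcode", "sample_id") %in% names(counts)))
  val <- if ("n_umi" %in% names(counts)) "n_umi" else "count"
  wide <- tidyr::pivot_wider(counts[, c("cell_barcode", "sample_id", val)],
                             names_from = "sample_id", values_from = val,
                             values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cell_barcode
  m
}

#' Derive per-sample count cutoffs from a bimodal count distribution
#'
#' For each sample, fits a deterministic two-component Gaussian mixture
#' ([fit_gmm2()]) to `log1p(count)` over nuclei; the cutoff is the smallest
#' count at which the posterior probability of the high (signal) component
#' exceeds 0.5. When the fitted means are closer than one log unit the
#' distribution is treated as unimodal and the fixed `fallback` cutoff is
#' used instead.
#'
#' @param counts a `hash_count_matrix`, a cells x samples matrix, or a long
#'   tibble with `cell_barcode`, `sample_id`, `n_umi`.
#' @param fallback fixed cutoff used when no bimodality is detected
#'   (default 10).
#' @param min_nuclei minimum nuclei required to attempt a mixture fit
#'   (default 50); fewer is an error instructing fixed-cutoff use.
#' @return a tibble with columns `sample_id`, `cutoff`, `method`
#'   (`"mixture"` or `"fallback"`), `mu_low`, `mu_high` (log1p scale).
#' @export
auto_cutoff <- function(counts, fallback = 10, min_nuclei = 50) {
  m <- as_count_matrix(counts)
  if (nrow(m) < min_nuclei) {
    abort(sprintf(
      "only %d nuclei (< %d): too few for mixture cutoffs, use a fixed cutoff",
      nrow(m), min_nuclei
    ))
  }
  purrr::map_dfr(colnames(m), function(s) {
    x <- log1p(m[, s])
    fit <- fit_gmm2(x)
    if (diff(fit$mu) < 1) {
      return(tibble(sample_id = s, cutoff = fallback, method = "fallback",
                    mu_low = fit$mu[1], mu_high = fit$mu[2]))
    }
    cand <- 1:max(m[, s])
    post <- posterior_high(fit, log1p(cand))
    hit <- which(post > 0.5)
    cutoff <- if (length(hit) == 0) fallback else cand[hit[1]]
    tibble(sample_id = s, cutoff = as.numeric(cutoff), method = "mixture",
           mu_low = fit$mu[1], mu_high = fit$mu[2])
  })
}

# Named cutoff vector from tibble / named vector / scalar.
cutoff_vector <- function(cutoffs, samples) {
  if (is.data.frame(cutoffs)) {
    v <- setNames(cutoffs$cutoff, cutoffs$sample_id)
  } else if (length(cutoffs) == 1 && is.null(names(cutoffs))) {
    v <- setNames(rep(as.numeric(cutoffs), length(samples)), samples)
  } else {
    v <- cutoffs
  }
  if (!all(samples %in% names(v))) {
    abort("cutoffs do not cover all samples in the count matrix")
  }
  if (any(v[samples] <= 0)) abort("cutoffs must be positive")
  v[samples]
}

#' Classify nuclei from hash counts by the count-cutoff quadrant rule
#'
#' A nucleus is a singlet of sample `s` when `s` is the only sample whose
#' count reaches its cutoff, a multiplet when two or more samples reach
#' their cutoffs, and negative when none does (insufficient hash counts).
#'
#' @param counts a `hash_count_matrix`, matrix, or long tibble (see
#'   [auto_cutoff()]).
#' @param cutoffs an [auto_cutoff()] tibble, a named per-sample numeric
#'   vector, or a single cutoff applied to every sample.
#' @return a tibble with columns `cell_barcode`, `label` (`"singlet"`,
#'   `"multiplet"`, `"negative"`), `sample_id` (the assigned sample for
#'   singlets, else NA) and `n_above`.
#' @export
#' @examples
#' m <- rbind(c(500, 3), c(500, 400), c(2, 3))
#' dimnames(m) <- list(c("c1", "c2", "c3"), c("S1", "S2"))
#' classify_hash(m, cutoffs = 10)
classify_hash <- function(counts, cutoffs) {
  m <- as_count_matrix(counts)
  cut <- cutoff_vector(cutoffs, colnames(m))
  above <- sweep(m, 2, cut, `>=`)
  n_above <- unname(rowSums(above))
  tibble(
    cell_barcode = rownames(m),
    label = ifelse(n_above == 1, "singlet",
                   ifelse(n_above >= 2, "multiplet", "negative")),
    sample_id = ifelse(n_above == 1,
                       colnames(m)[max.col(above, ties.method = "first")],
                       NA_character_),
    n_above = as.integer(n_above)
  )
}

#' Centered log-ratio transform of a hash count matrix
#'
#' `clr(x_i) = log(x_i + 1) - mean(log(x + 1))` across the samples of each
#' cell.
#'
#' @param counts a `hash_count_matrix`, matrix, or long tibble.
#' @return a cells x samples numeric matrix of CLR values.
#' @export
clr_normalize <- function(counts) {
  m <- as_count_matrix(counts)
  lx <- log1p(m)
  sweep(lx, 1, rowMeans(lx))
}

#' Classify nuclei by CLR normalization and per-sample quantile thresholds
#'
#' Alternative to the count-cutoff quadrant rule, following the cell-hashing
#' convention: counts are CLR-normalized, and for each sample a threshold is
#' set at the `neg_quantile` quantile of the CLR values of its negative
#' cluster (cells whose highest count lies elsewhere). Cells above threshold
#' for exactly one sample are singlets, two or more multiplets, none
#' negative.
#'
#' @param counts a `hash_count_matrix`, matrix, or long tibble.
#' @param neg_quantile quantile of the negative-cluster CLR distribution
#'   (default 0.99).
#' @return a calls tibble as in [classify_hash()].
#' @export
classify_hash_clr <- function(counts, neg_quantile = 0.99) {
  m <- as_count_matrix(counts)
  cl <- clr_normalize(m)
  top <- max.col(m, ties.method = "first")
  above <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    neg <- which(top != j)
    thr <- if (length(neg) >= 2) quantile(cl[neg, j], neg_quantile) else -Inf
    above[, j] <- cl[, j] > thr
  }
  n_above <- unname(rowSums(above))
  tibble(
    cell_barcode = rownames(m),
    label = ifelse(n_above == 1, "singlet",
                   ifelse(n_above >= 2, "multiplet", "negative")),
    sample_id = ifelse(n_above == 1,
                       colnames(m)[max.col(above, ties.method = "first")],
                       NA_character_),
    n_above = as.integer(n_above)
  )
}

#' Summarize hash calls into per-label counts and percentages
#'
#' @param calls a calls tibble from [classify_hash()] (column `label`), or a
#'   named numeric vector of per-label counts.
#' @param digits decimals for the reported percentages (half-up, default 2).
#' @return a tibble with columns `label`, `n`, `pct`; `pct` sums to 100
#'   within rounding.
#' @export
#' @examples
#' summarize_calls(c(singlet = 9144, multiplet = 1251, negative = 179))
summarize_calls <- function(calls, digits = 2) {
  if (is.numeric(calls)) {
    counts <- calls
  } else {
    stopifnot(nrow(calls) >= 1)
    lv <- intersect(c("singlet", "multiplet", "negative"),
                    unique(c(calls$label, "singlet", "multiplet", "negative")))
    counts <- table(factor(calls$label, levels = lv))
    counts <- setNames(as.numeric(counts), names(counts))
  }
  tibble(
    label = names(counts),
    n = unname(counts),
    pct = percent_of(unname(counts), sum(counts), digits)
  )
}
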