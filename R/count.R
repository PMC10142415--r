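#' Collapse UMIs within cell x sample groups
#'
#' Within each (cell barcode, sample) group, identical UMIs are first
#' deduplicated; with `method = "directional"` a UMI `b` is then absorbed
#' into a UMI `a` when their Hamming distance is 1 and
#' `reads(a) >= 2 * reads(b) - 1` (the directional adjacency network used for
#' sequencing-error-tolerant UMI deduplication). The collapsed count of a
#' group is the number of surviving UMI clusters. `method = "exact"` stops
#' after the identical-UMI step.
#'
#' @param triples a tibble with columns `cell_barcode`, `sample_id`, `umi`
#'   (one row per valid read).
#' @param method `"directional"` (default) or `"exact"`.
#' @return a tibble with columns `cell_barcode`, `sample_id`, `n_umi`
#'   (collapsed count) and `n_reads` (raw reads in the group), with
#'   `n_umi <= n_reads` everywhere.
#' @export
#' @examples
#' collapse_umis(tibble::tibble(
#'   cell_barcode = "AAAA", sample_id = "S1",
#'   umi = c(rep("AAAA", 3), "AAAT")
#' ))
collapse_umis <- function(triples, method = c("directional", "exact")) {
  method <- match.arg(method)
  stopifnot(all(c("cell_barcode", "sample_id", "umi") %in% names(triples)))
  if (nrow(triples) == 0) {
    return(tibble(cell_barcode = character(), sample_id = character(),
                  n_umi = integer(), n_reads = integer()))
  }
  per_umi <- dplyr::count(triples, .data$cell_barcode, .data$sample_id,
                          .data$umi, name = "reads")
  per_umi <- dplyr::arrange(per_umi, .data$cell_barcode, .data$sample_id)
  grp <- dplyr::group_by(per_umi, .data$cell_barcode, .data$sample_id)
  gid <- dplyr::group_indices(grp)

  keys <- dplyr::distinct(per_umi, .data$cell_barcode, .data$sample_id)
  if (method == "exact") {
    n_umi <- as.integer(table(gid))
  } else {
    n_umi <- .directional_collapse_groups(per_umi$umi, per_umi$reads, gid)
  }
  reads_tot <- as.integer(tapply(per_umi$reads, gid, sum))
  dplyr::tibble(keys, n_umi = n_umi, n_reads = reads_tot)
}

new_hash_count_matrix <- function(counts, raw_read_counts, parse_stats) {
  stopifnot(identical(dim(counts), dim(raw_read_counts)))
  structure(
    list(counts = counts, raw_read_counts = raw_read_counts,
         parse_stats = parse_stats),
    class = "hash_count_matrix"
  )
}

#' Build a UMI-collapsed hash count matrix from FASTQ
#'
#' Runs the full hash-counting pipeline: reads the three record-synchronized
#' FASTQ streams (biological mates plus the 16 nt cell-barcode index read),
#' parses each record against the design (trying read 1, then the reverse
#' complement of read 2, then read 2 as sequenced; the first parse reaching
#' the furthest stage wins), corrects cell barcodes against the whitelist,
#' and collapses UMIs per (cell, sample) group.
#'
#' @param fastq_r1 path to the first biological read FASTQ (optionally
#'   gzipped).
#' @param fastq_index path to the index-read FASTQ carrying the cell barcode.
#' @param fastq_r2 optional path to the second biological read FASTQ.
#' @param whitelist path to a plain-text whitelist (one barcode per line) or
#'   a character vector of valid cell barcodes.
#' @param design a [hash_design()].
#' @param umi_collapse `"directional"` (default) or `"exact"`, see
#'   [collapse_umis()].
#' @param index_rc reverse-complement the index read before whitelist
#'   matching (i5 orientation differs between sequencers). Default `FALSE`.
#' @return a `hash_count_matrix`: UMI-collapsed `counts` and pre-collapse
#'   `raw_read_counts` matrices (valid cells x samples) plus `parse_stats`,
#'   a named tally over parse statuses summing to the records processed.
#' @export
count_hashes <- function(fastq_r1, fastq_index, fastq_r2 = NULL,
                         whitelist, design,
                         umi_collapse = c("directional", "exact"),
                         index_rc = FALSE) {
  umi_collapse <- match.arg(umi_collapse)
  r1 <- Biostrings::readDNAStringSet(fastq_r1, format = "fastq")
  idx <- Biostrings::readDNAStringSet(fastq_index, format = "fastq")
  r2 <- if (!is.null(fastq_r2)) Biostrings::readDNAStringSet(fastq_r2, format = "fastq")
  check_synchronized(r1, idx, r2)

  if (is.character(whitelist) && length(whitelist) == 1 && file.exists(whitelist)) {
    whitelist <- readLines(whitelist)
  }
  whitelist <- whitelist[nzchar(whitelist)]

  index_seq <- as.character(idx)
  if (index_rc) index_seq <- reverse_complement(index_seq)
  index_seq <- substr(index_seq, 1, design$cell_barcode_len)
  cc <- correct_cell_barcodes(index_seq, whitelist, design$cell_mismatch_tol)

  attempts <- list(as.character(r1))
  if (!is.null(r2)) {
    attempts <- c(attempts, list(reverse_complement(as.character(r2)),
                                 as.character(r2)))
  }
  ah <- anchor_hash_parse(attempts[[1]], design)
  if (length(attempts) > 1) {
    rank0 <- anchor_hash_rank(ah)
    for (alt in attempts[-1]) {
      retry <- which(rank0 < 3L)
      if (length(retry) == 0) break
      ah_alt <- anchor_hash_parse(alt[retry], design)
      better <- anchor_hash_rank(ah_alt) > rank0[retry]
      if (any(better)) {
        ah[retry[better], ] <- ah_alt[better, ]
        rank0[retry[better]] <- anchor_hash_rank(ah_alt)[better]
      }
    }
  }
  parsed <- combine_parse(ah, cc)

  valid <- parsed[parsed$status == "valid", ]
  groups <- collapse_umis(
    tibble(cell_barcode = valid$corrected_cell_barcode,
           sample_id = valid$sample_id, umi = valid$umi),
    method = umi_collapse
  )

  cells <- whitelist[whitelist %in% groups$cell_barcode]
  samples <- design$barcodes$sample_id
  counts <- matrix(0L, nrow = length(cells), ncol = length(samples),
                   dimnames = list(cells, samples))
  raw <- counts
  ij <- cbind(match(groups$cell_barcode, cells), match(groups$sample_id, samples))
  counts[ij] <- groups$n_umi
  raw[ij] <- groups$n_reads

  stats <- table(parsed$status)
  parse_stats <- setNames(as.integer(stats), names(stats))
  parse_stats <- c(parse_stats, total = length(r1))
  new_hash_count_matrix(counts, raw, parse_stats)
}

# 3 = anchor + hash both parsed, 2 = anchor found, 1 = no anchor.
anchor_hash_rank <- function(ah) {
  ifelse(!ah$anchor_ok, 1L, ifelse(ah$hash_status == "ok", 3L, 2L))
}

check_synchronized <- function(r1, idx, r2 = NULL) {
  ids <- function(x) sub("\\s.*$", "", names(x))
  if (length(r1) != length(idx) ||
      (!is.null(r2) && length(r2) != length(r1))) {
    abort("FASTQ streams are desynchronized: record counts differ")
  }
  if (!is.null(names(r1)) && !is.null(names(idx)) &&
      !identical(ids(r1), ids(idx))) {
    abort("FASTQ streams are desynchronized: record ids differ")
  }
  if (!is.null(r2) && !is.null(names(r2)) && !identical(ids(r1), ids(r2))) {
    abort("FASTQ streams are desynchronized: record ids differ")
  }
  invisible(TRUE)
}

#' @export
print.hash_count_matrix <- function(x, ...) {
  cat(sprintf("<hash_count_matrix> %d cells x %d samples, %d UMIs total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  cat("parse_stats:", paste(names(x$parse_stats), x$parse_stats,
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.hash_count_matrix <- function(x, ...) x$counts

#' @export
dim.hash_count_matrix <- function(x) dim(x$counts)

#' Long-format view of a hash count matrix
#'
#' @param x a `hash_count_matrix` from [count_hashes()].
#' @param ... unused.
#' @return a tibble with columns `cell_barcode`, `sample_id`, `n_umi`,
#'   `n_reads` (zero entries omitted).
#' @exportS3Method
tidy.hash_count_matrix <- function(x, ...) {
  keep <- which(x$raw_read_counts > 0, arr.ind = TRUE)
  tibble(
    cell_barcode = rownames(x$counts)[keep[, 1]],
    sample_id = colnames(x$counts)[keep[, 2]],
    n_umi = x$counts[keep],
    n_reads = x$raw_read_counts[keep]
  ) |> dplyr::arrange(.data$cell_barcode, .data$sample_id)
}

#' One-row summary of a hash counting run
#'
#' @param x a `hash_count_matrix`.
#' @param ... unused.
#' @return a one-row tibble: cells, samples, total reads, valid reads,
#'   total collapsed UMIs, and the overall duplication rate.
#' @exportS3Method
glance.hash_count_matrix <- function(x, ...) {
  valid <- unname(x$parse_stats["valid"])
  tibble(
    n_cells = nrow(x$counts),
    n_samples = ncol(x$counts),
    total_reads = unname(x$parse_stats["total"]),
    valid_reads = valid,
    total_umis = sum(x$counts),
    dup_rate = if (valid > 0) 1 - sum(x$counts) / valid else NA_real_
  )
}

#' Write a hash count matrix to disk
#'
#' Writes the UMI-collapsed counts as MatrixMarket (`matrix.mtx` with
#' `barcodes.tsv` / `samples.tsv` sidecars), a wide TSV (`counts.tsv`, rows =
#' cell barcodes) and the parse tallies as `parse_stats.json`.
#'
#' @param x a `hash_count_matrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hash_counts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "samples.tsv"))
  wide <- data.frame(cell_barcode = rownames(x$counts), x$counts,
                     check.names = FALSE)
  write.table(wide, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(x$parse_stats),
                       file.path(dir, "parse_stats.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a hash count matrix written by [write_hash_counts()]
#'
#' @param dir directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `samples.tsv` and optionally `parse_stats.json`.
#' @return a `hash_count_matrix` (raw read counts unavailable on re-read are
#'   set equal to the collapsed counts).
#' @export
read_hash_counts <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "barcodes.tsv")),
                      readLines(file.path(dir, "samples.tsv")))
  stats_path <- file.path(dir, "parse_stats.json")
  stats <- if (file.exists(stats_path)) {
    unlist(jsonlite::read_json(stats_path))
  } else {
    c(total = sum(m))
  }
  new_hash_count_matrix(m, m, stats)
}
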