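#' Assign species from per-genome fragment counts (barnyard designs)
#'
#' For each nucleus, let `f` be the fraction of fragments aligned to the
#' best genome. A nucleus is a singlet of that genome when `f >= purity`, a
#' doublet when `f < purity` and the minor genome carries at least
#' `min_minor` fragments, and undetermined otherwise (including zero total).
#'
#' @param genome_counts a long tibble with columns `cell_barcode`,
#'   `genome_id`, `fragment_count` covering at least two genomes.
#' @param purity major-genome fraction required for a singlet call
#'   (default 0.9).
#' @param min_minor minimum minor-genome fragments to call a doublet
#'   (default 100).
#' @return a tibble with columns `cell_barcode`, `label` (`"singlet"`,
#'   `"doublet"`, `"undetermined"`), `genome_id` (the assigned genome for
#'   singlets), `total_fragments`, `major_frac`.
#' @export
#' @examples
#' assign_species(tibble::tibble(
#'   cell_barcode = c("c1", "c1", "c2", "c2"),
#'   genome_id = c("human", "mouse", "human", "mouse"),
#'   fragment_count = c(5000, 50, 2000, 1800)
#' ))
assign_species <- function(genome_counts, purity = 0.9, min_minor = 100) {
  stopifnot(all(c("cell_barcode", "genome_id", "fragment_count") %in%
                  names(genome_counts)))
  if (length(unique(genome_counts$genome_id)) < 2) {
    abort("species assignment needs at least two genomes")
  }
  genome_counts |>
    dplyr::group_by(.data$cell_barcode) |>
    dplyr::summarise(
      total_fragments = sum(.data$fragment_count),
      major = max(.data$fragment_count),
      minor = sum(.data$fragment_count) - max(.data$fragment_count),
      genome_top = .data$genome_id[which.max(.data$fragment_count)],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      major_frac = ifelse(.data$total_fragments > 0,
                          .data$major / .data$total_fragments, NA_real_),
      label = dplyr::case_when(
        .data$total_fragments == 0 ~ "undetermined",
        .data$major_frac >= purity ~ "singlet",
        .data$minor >= min_minor ~ "doublet",
        TRUE ~ "undetermined"
      ),
      genome_id = ifelse(.data$label == "singlet", .data$genome_top,
                         NA_character_)
    ) |>
    dplyr::select("cell_barcode", "label", "genome_id", "total_fragments",
                  "major_frac")
}

#' Per-nucleus genome fragment counts from a fragments file
#'
#' Counts fragments per (cell barcode, genome) from a 10x-style fragments
#' table (`chrom start end barcode count`, BED-like 0-based half-open,
#' optionally gzipped), assigning each fragment to a genome by its
#' chromosome-name prefix as in combined-reference alignments (e.g.
#' `GRCh38_chr1`, `mm10_chr1`).
#'
#' @param path path to the fragments TSV (no header; comment lines starting
#'   `#` ignored).
#' @param genome_prefixes named character vector mapping genome_id to the
#'   chromosome prefix, e.g. `c(human = "GRCh38_", mouse = "mm10_")`.
#' @return a tibble `cell_barcode`, `genome_id`, `fragment_count` (every
#'   barcode x genome combination present, zero-filled).
#' @export
genome_counts_from_fragments <- function(path, genome_prefixes) {
  frag <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                     col.names = c("chrom", "start", "end", "barcode", "count"),
                     colClasses = c("character", "integer", "integer",
                                    "character", "integer"))
  genome <- rep(NA_character_, nrow(frag))
  for (g in names(genome_prefixes)) {
    genome[startsWith(frag$chrom, genome_prefixes[[g]])] <- g
  }
  keep <- !is.na(genome)
  tibble(cell_barcode = frag$barcode[keep], genome_id = genome[keep],
         n = frag$count[keep]) |>
    dplyr::group_by(.data$cell_barcode, .data$genome_id) |>
    dplyr::summarise(fragment_count = sum(.data$n), .groups = "drop") |>
    tidyr::complete(.data$cell_barcode, genome_id = names(genome_prefixes),
                    fill = list(fragment_count = 0L))
}
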