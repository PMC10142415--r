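# Expand a genome x sample confusion matrix into matching call tibbles.
calls_from_confusion <- function(confusion, extra_hash = c(multiplet = 0,
                                                           negative = 0)) {
  genomes <- rownames(confusion)
  samples <- colnames(confusion)
  rows <- list()
  k <- 0
  for (g in genomes) for (s in samples) {
    n <- confusion[g, s]
    if (n > 0) {
      rows[[length(rows) + 1]] <-
        tibble::tibble(cell_barcode = sprintf("bc%07d", k + seq_len(n)),
                       genome = g, sample = s)
      k <- k + n
    }
  }
  both <- dplyr::bind_rows(rows)
  hash <- tibble::tibble(cell_barcode = both$cell_barcode, label = "singlet",
                         sample_id = both$sample)
  for (lab in names(extra_hash)) {
    n <- extra_hash[[lab]]
    if (n > 0) {
      hash <- dplyr::bind_rows(hash, tibble::tibble(
        cell_barcode = sprintf("x%s%06d", lab, seq_len(n)),
        label = lab, sample_id = NA_character_
      ))
    }
  }
  species <- tibble::tibble(cell_barcode = both$cell_barcode,
                            label = "singlet", genome_id = both$genome)
  extra_bc <- setdiff(hash$cell_barcode, species$cell_barcode)
  species <- dplyr::bind_rows(species, tibble::tibble(
    cell_barcode = extra_bc, label = "doublet", genome_id = NA_character_
  ))
  list(hash = hash, species = species)
}

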