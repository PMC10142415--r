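#' Describe the structure of a hashing oligonucleotide experiment
#'
#' A hash design records everything needed to parse a hashing read: the set of
#' sample barcodes, the two UMI lengths flanking the barcode, the constant
#' anchor sequences at either end of the insert (remnants of the sequencing
#' adapters), the cell-barcode length of the index read, and the mismatch
#' tolerances used during parsing. The layout of a hashing read is
#' `anchor5 - UMI1 - sample barcode - UMI2 - anchor3`.
#'
#' Barcode sets must be unambiguous under the hash mismatch tolerance: the
#' minimum pairwise Hamming distance must be at least
#' `2 * hash_mismatch_tol + 1`, so no read can sit within tolerance of two
#' different barcodes.
#'
#' @param barcodes a tibble/data.frame with columns `sample_id`, `sequence`
#'   and optionally `species` (genome label for barnyard designs), or a named
#'   character vector of sequences.
#' @param umi1_len,umi2_len lengths (bases) of the UMIs before and after the
#'   sample barcode. Their sum must be positive.
#' @param anchor5,anchor3 constant sequences flanking the variable region.
#'   Empty strings are allowed (pre-extracted hash reads).
#' @param cell_barcode_len length of the cell (index-read) barcode.
#' @param hash_mismatch_tol,cell_mismatch_tol,anchor_mismatch_tol maximum
#'   Hamming mismatches tolerated when matching the sample barcode, the cell
#'   barcode and each anchor.
#' @return an object of class `hash_design`.
#' @export
#' @examples
#' hash_design(c(S1 = "ACGTACGT", S2 = "TGCATGCA"))
hash_design <- function(barcodes,
                        umi1_len = 8, umi2_len = 8,
                        anchor5 = "", anchor3 = "",
                        cell_barcode_len = 16,
                        hash_mismatch_tol = 1,
                        cell_mismatch_tol = 1,
                        anchor_mismatch_tol = 2) {
  if (is.character(barcodes)) {
    if (is.null(names(barcodes))) abort("barcode vector must be named by sample_id")
    barcodes <- tibble(sample_id = names(barcodes), sequence = unname(barcodes))
  }
  barcodes <- as_tibble(barcodes)
  if (!all(c("sample_id", "sequence") %in% names(barcodes))) {
    abort("`barcodes` needs columns sample_id and sequence")
  }
  if (!"species" %in% names(barcodes)) barcodes$species <- NA_character_
  barcodes <- barcodes[, c("sample_id", "sequence", "species")]

  design <- structure(
    list(
      barcodes = barcodes,
      umi1_len = as.integer(umi1_len),
      umi2_len = as.integer(umi2_len),
      anchor5 = toupper(anchor5),
      anchor3 = toupper(anchor3),
      cell_barcode_len = as.integer(cell_barcode_len),
      hash_mismatch_tol = as.integer(hash_mismatch_tol),
      cell_mismatch_tol = as.integer(cell_mismatch_tol),
      anchor_mismatch_tol = as.integer(anchor_mismatch_tol)
    ),
    class = "hash_design"
  )
  validate_hash_design(design)
}

validate_hash_design <- function(design) {
  bc <- design$barcodes
  if (nrow(bc) < 1) abort("design must contain at least one barcode")
  if (anyDuplicated(bc$sample_id)) abort("duplicate sample_id in design")
  if (any(!nzchar(bc$sequence))) abort("empty barcode sequence")
  if (length(unique(nchar(bc$sequence))) != 1) {
    abort("all barcodes in a design must have equal length")
  }
  bad <- grepl("[^ACGT]", toupper(c(bc$sequence,
                                    design$anchor5, design$anchor3)))
  if (any(bad)) abort("sequences must be over the alphabet {A,C,G,T}")
  bc$sequence <- toupper(bc$sequence)
  design$barcodes <- bc
  if (design$umi1_len < 0 || design$umi2_len < 0 ||
      design$umi1_len + design$umi2_len == 0) {
    abort("umi1_len + umi2_len must be positive")
  }
  tols <- c(design$hash_mismatch_tol, design$cell_mismatch_tol,
            design$anchor_mismatch_tol)
  if (any(tols < 0)) abort("mismatch tolerances must be >= 0")
  if (nrow(bc) >= 2) {
    dmin <- min_pairwise_hamming(design)
    need <- 2L * design$hash_mismatch_tol + 1L
    if (dmin < need) {
      abort(sprintf(
        "minimum pairwise barcode Hamming distance %d < %d required for hash_mismatch_tol %d",
        dmin, need, design$hash_mismatch_tol
      ))
    }
  }
  design
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' @param design a [hash_design()] (or character vector of equal-length
#'   sequences) with at least two barcodes.
#' @return the smallest Hamming distance over all unordered barcode pairs.
#' @export
#' @examples
#' min_pairwise_hamming(c(a = "ACGT", b = "ACGA"))
min_pairwise_hamming <- function(design) {
  seqs <- if (inherits(design, "hash_design")) design$barcodes$sequence else unname(design)
  if (length(seqs) < 2) {
    abort("pairwise distance undefined for fewer than two barcodes")
  }
  pairs <- utils::combn(length(seqs), 2)
  min(apply(pairs, 2, function(p) hamming(seqs[p[1]], seqs[p[2]])))
}

#' Read a hash design from a YAML file
#'
#' The file holds `barcodes` (map sample_id -> `{sequence, species}`),
#' `umi1_len`, `umi2_len`, `anchor5`, `anchor3`, `cell_barcode_len` and an
#' optional `tolerances` map with keys `hash`, `cell`, `anchor` (defaults
#' 1, 1, 2).
#'
#' @param path path to the YAML design file.
#' @return a validated [hash_design()].
#' @export
read_hash_design <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$barcodes) || length(y$barcodes) == 0) {
    abort("design file has no barcodes")
  }
  bc <- purrr::imap_dfr(y$barcodes, function(v, id) {
    if (is.character(v)) v <- list(sequence = v)
    tibble(sample_id = id,
           sequence = v$sequence,
           species = v$species %||% NA_character_)
  })
  tol <- y$tolerances %||% list()
  hash_design(
    bc,
    umi1_len = y$umi1_len %||% 8,
    umi2_len = y$umi2_len %||% 8,
    anchor5 = y$anchor5 %||% "",
    anchor3 = y$anchor3 %||% "",
    cell_barcode_len = y$cell_barcode_len %||% 16,
    hash_mismatch_tol = tol$hash %||% 1,
    cell_mismatch_tol = tol$cell %||% 1,
    anchor_mismatch_tol = tol$anchor %||% 2
  )
}

#' Write a hash design to a YAML file
#'
#' `read_hash_design(write_hash_design(design, path))` restores every field.
#'
#' @param design a [hash_design()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hash_design <- function(design, path) {
  bc <- design$barcodes
  barcodes <- purrr::map(seq_len(nrow(bc)), function(i) {
    out <- list(sequence = bc$sequence[i])
    if (!is.na(bc$species[i])) out$species <- bc$species[i]
    out
  })
  names(barcodes) <- bc$sample_id
  yaml::write_yaml(list(
    barcodes = barcodes,
    umi1_len = design$umi1_len,
    umi2_len = design$umi2_len,
    anchor5 = design$anchor5,
    anchor3 = design$anchor3,
    cell_barcode_len = design$cell_barcode_len,
    tolerances = list(hash = design$hash_mismatch_tol,
                      cell = design$cell_mismatch_tol,
                      anchor = design$anchor_mismatch_tol)
  ), path)
  invisible(path)
}

# Expected read layout length from anchor5 through anchor3.
design_layout_length <- function(design) {
  nchar(design$anchor5) + design$umi1_len +
    nchar(design$barcodes$sequence[1]) + design$umi2_len + nchar(design$anchor3)
}

# Map sample_id -> species label (NA where unset).
design_species_map <- function(design) {
  setNames(design$barcodes$species, design$barcodes$sample_id)
}

#' @export
print.hash_design <- function(x, ...) {
  cat(sprintf(
    "<hash_design> %d barcode(s), %d nt; layout %s-UMI%d-BC-UMI%d-%s; cell barcode %d nt\n",
    nrow(x$barcodes), nchar(x$barcodes$sequence[1]),
    if (nzchar(x$anchor5)) x$anchor5 else "(none)",
    x$umi1_len, x$umi2_len,
    if (nzchar(x$anchor3)) x$anchor3 else "(none)",
    x$cell_barcode_len
  ))
  cat(sprintf("tolerances: hash %d, cell %d, anchor %d\n",
              x$hash_mismatch_tol, x$cell_mismatch_tol, x$anchor_mismatch_tol))
  print(x$barcodes, ...)
  invisible(x)
}

#' @exportS3Method
tidy.hash_design <- function(x, ...) {
  x$barcodes
}
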