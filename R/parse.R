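#' Correct raw cell barcodes against a whitelist
#'
#' Exact whitelist members are kept as-is; otherwise the unique whitelist
#' member within `tol` mismatches is substituted. A tie between two or more
#' whitelist members is ambiguous and yields no correction, as does a barcode
#' with no member in range.
#'
#' @param raw character vector of raw (sequenced) cell barcodes.
#' @param whitelist character vector of valid cell barcodes (equal width).
#' @param tol maximum Hamming distance for correction (default 1).
#' @return a tibble with columns `raw`, `corrected` (NA when uncorrectable)
#'   and `cell_status` (`"valid"`, `"ambiguous_cell"` or `"unknown_cell"`).
#' @export
#' @examples
#' correct_cell_barcodes(c("AAAA", "AAAT", "CCCC"),
#'                       whitelist = c("AAAA", "GGGG"), tol = 1)
correct_cell_barcodes <- function(raw, whitelist, tol = 1) {
  if (length(whitelist) == 0) abort("whitelist is empty")
  corrected <- whitelist[match(raw, whitelist)]
  status <- ifelse(is.na(corrected), "unknown_cell", "valid")

  todo <- is.na(corrected) & nchar(raw) == nchar(whitelist[1])
  if (tol >= 1 && any(todo)) {
    uniq <- unique(raw[todo])
    if (tol == 1) {
      nb <- hamming1_neighbours(uniq)
      nb[nb == uniq] <- NA_character_  # skip no-op substitutions
      inwl <- matrix(nb %in% whitelist, nrow = nrow(nb))
      nhit <- rowSums(inwl)
      first <- max.col(inwl, ties.method = "first")
      hits <- purrr::map(seq_along(uniq), function(i) {
        if (nhit[i] == 0) character(0)
        else if (nhit[i] == 1) nb[i, first[i]]
        else unique(nb[i, inwl[i, ]])
      })
    } else {
      wl_codes <- char_code_matrix(whitelist, nchar(whitelist[1]))
      hits <- purrr::map(uniq, function(r) {
        d <- rowSums(wl_codes != matrix(utf8ToInt(r), nrow = nrow(wl_codes),
                                        ncol = ncol(wl_codes), byrow = TRUE))
        whitelist[d <= tol & d > 0]
      })
    }
    fix <- purrr::map_chr(hits, function(h) if (length(h) == 1) h else NA_character_)
    stat <- purrr::map_chr(hits, function(h) {
      if (length(h) == 1) "valid" else if (length(h) > 1) "ambiguous_cell" else "unknown_cell"
    })
    idx <- match(raw[todo], uniq)
    corrected[todo] <- fix[idx]
    status[todo] <- stat[idx]
  }
  tibble(raw = raw, corrected = corrected, cell_status = status)
}

# Locate anchors and slice the layout for one orientation of the hash read.
# Returns per-read offset, anchor pass/fail, UMI and barcode fields, and the
# hash-match outcome ("ok", "ambiguous_hash", "unknown_hash").
anchor_hash_parse <- function(reads, design, offset_window = 3L) {
  n <- length(reads)
  a5 <- design$anchor5
  a3 <- design$anchor3
  u1 <- design$umi1_len
  u2 <- design$umi2_len
  bcw <- nchar(design$barcodes$sequence[1])
  need <- design_layout_length(design) + offset_window
  padded <- stringr::str_pad(toupper(reads), width = need, side = "right", pad = "N")

  offsets <- 0:offset_window
  a5len <- nchar(a5)
  a3len <- nchar(a3)
  a3start <- a5len + u1 + bcw + u2  # relative to offset
  mm <- matrix(0L, nrow = n, ncol = length(offsets))
  for (j in seq_along(offsets)) {
    o <- offsets[j]
    m5 <- if (a5len > 0) {
      mismatches_to(substr(padded, o + 1, o + a5len), a5)
    } else 0L
    m3 <- if (a3len > 0) {
      mismatches_to(substr(padded, o + a3start + 1, o + a3start + a3len), a3)
    } else 0L
    mm[, j] <- m5 + m3
    if (a5len == 0 && a3len == 0) break
  }
  pass <- mm <= design$anchor_mismatch_tol * ((a5len > 0) + (a3len > 0))
  # per-anchor tolerance: re-check individually at the candidate offset below
  best_j <- max.col(-mm, ties.method = "first")
  anchor_ok <- pass[cbind(seq_len(n), best_j)]
  if (a5len > 0 && a3len > 0) {
    # both anchors must individually satisfy the tolerance
    o <- offsets[best_j]
    m5 <- mismatches_to(substr(padded, o + 1, o + a5len), a5)
    m3 <- mismatches_to(substr(padded, o + a3start + 1, o + a3start + a3len), a3)
    anchor_ok <- m5 <= design$anchor_mismatch_tol & m3 <= design$anchor_mismatch_tol
  }
  o <- offsets[best_j]

  fs <- o + a5len  # field start (0-based) of UMI1
  umi1 <- substr(padded, fs + 1, fs + u1)
  bc_field <- substr(padded, fs + u1 + 1, fs + u1 + bcw)
  umi2 <- substr(padded, fs + u1 + bcw + 1, fs + u1 + bcw + u2)

  seqs <- design$barcodes$sequence
  dmat <- vapply(seqs, function(s) mismatches_to(bc_field, s), integer(n))
  if (n == 1) dmat <- matrix(dmat, nrow = 1)
  dmin <- do.call(pmin, as.data.frame(dmat))
  nmin <- rowSums(dmat == dmin)
  win <- max.col(-dmat, ties.method = "first")
  hash_status <- ifelse(dmin > design$hash_mismatch_tol, "unknown_hash",
                        ifelse(nmin > 1, "ambiguous_hash", "ok"))
  sample_id <- ifelse(hash_status == "ok", design$barcodes$sample_id[win], NA_character_)
  tibble(
    offset = o,
    anchor_ok = anchor_ok,
    umi = paste0(umi1, umi2),
    sample_id = sample_id,
    hash_status = hash_status
  )
}

#' Parse structured hashing reads
#'
#' Applies the fixed read layout `anchor5 - UMI1 - sample barcode - UMI2 -
#' anchor3` to each read. The 5' anchor is located within a 0-3 base
#' start-offset window allowing up to `anchor_mismatch_tol` mismatches per
#' anchor; the cell barcode from the index read is corrected against the
#' whitelist; the sample barcode is matched against the design with the
#' unique-winner rule. Failures are encoded in `status` by the first failing
#' stage (anchor, then cell, then hash), never as errors.
#'
#' @param reads character vector (or `DNAStringSet`) of hash-read sequences.
#' @param index character vector of index-read (cell barcode) sequences,
#'   parallel to `reads`.
#' @param design a [hash_design()].
#' @param whitelist character vector of valid cell barcodes.
#' @return a tibble with one row per read: `raw_cell_barcode`,
#'   `corrected_cell_barcode`, `sample_id`, `umi` (UMI1 and UMI2
#'   concatenated) and `status`, one of `valid`, `no_anchor`,
#'   `ambiguous_cell`, `unknown_cell`, `ambiguous_hash`, `unknown_hash`.
#'   `status == "valid"` exactly when both `corrected_cell_barcode` and
#'   `sample_id` are present.
#' @export
parse_hash_reads <- function(reads, index, design, whitelist) {
  reads <- as.character(reads)
  index <- as.character(index)
  if (length(reads) != length(index)) {
    abort("reads and index must have equal length")
  }
  ah <- anchor_hash_parse(reads, design)
  cc <- correct_cell_barcodes(index, whitelist, design$cell_mismatch_tol)
  combine_parse(ah, cc)
}

parse_status_levels <- c("valid", "no_anchor", "ambiguous_cell",
                         "unknown_cell", "ambiguous_hash", "unknown_hash")

# Merge anchor/hash outcome with the cell-correction outcome, applying the
# anchor -> cell -> hash failure precedence.
combine_parse <- function(ah, cc) {
  status <- ifelse(!ah$anchor_ok, "no_anchor",
            ifelse(cc$cell_status != "valid", cc$cell_status,
            ifelse(ah$hash_status != "ok", ah$hash_status, "valid")))
  valid <- status == "valid"
  tibble(
    raw_cell_barcode = cc$raw,
    corrected_cell_barcode = ifelse(valid | cc$cell_status == "valid",
                                    cc$corrected, NA_character_),
    sample_id = ifelse(valid, ah$sample_id, NA_character_),
    umi = ifelse(valid, ah$umi, NA_character_),
    status = factor(status, levels = parse_status_levels)
  )
}
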