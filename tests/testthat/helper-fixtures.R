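# Shared fixtures, built in code.

# The reference 4-barcode design shipped with the package.
ref_design <- function() {
  read_hash_design(system.file("extdata", "reference_design.yml",
                               package = "snhash"))
}

# Assemble an error-free hash read for a design.
make_read <- function(design, sample_id, umi1 = NULL, umi2 = NULL,
                      offset = 0, pad_to = 50) {
  bc <- design$barcodes$sequence[design$barcodes$sample_id == sample_id]
  umi1 <- umi1 %||% strrep("A", design$umi1_len)
  umi2 <- umi2 %||% strrep("C", design$umi2_len)
  core <- paste0(design$anchor5, umi1, bc, umi2, design$anchor3)
  read <- paste0(strrep("G", offset), core)
  if (nchar(read) < pad_to) read <- paste0(read, strrep("T", pad_to - nchar(read)))
  read
}

# Substitute bases at given 1-based positions.
mutate_at <- function(seq, positions) {
  for (p in positions) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  seq
}

`%||%` <- rlang::`%||%`

# Write a 4-line-record FASTQ (optionally gzipped by extension).
write_test_fastq <- function(seqs, path, ids = sprintf("r%05d", seq_along(seqs))) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), con)
  path
}

# A 2-plex clean-simulation config: tight hash-depth dispersion so that no
# nucleus lacks hash reads entirely (zero-read nuclei are unrecoverable by
# construction and would confound recovery checks).
clean_config <- function(n = 60, seed = 1) {
  sim_config(
    samples = tibble::tibble(sample_id = c("S1", "S2"),
                             species = c("human", "mouse"),
                             n_nuclei = c(as.integer(n), as.integer(n))),
    doublet_rate = 0, ambient_fraction = 0, base_error_rate = 0,
    hash_depth_mean = 100, hash_depth_dispersion = 10,
    seed = seed
  )
}
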