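#' Configuration for a synthetic hashing experiment
#'
#' Defaults follow the `paper-like` preset of a 2-plex barnyard run: an
#' overdispersed (negative binomial) hash depth so a small tail of nuclei
#' has too few hash reads to classify, a doublet rate around twelve percent,
#' a few percent ambient hash contamination, and sequencing depth around
#' 27,000 reads per nucleus so most nuclei clear a 10,000-read filter.
#'
#' @param samples tibble with columns `sample_id`, `species`, `n_nuclei`
#'   (default: a 2-plex human/mouse barnyard, 500 nuclei each).
#' @param doublet_rate fraction of nuclei that are doublets (two samples in
#'   one droplet).
#' @param hash_depth_mean,hash_depth_dispersion negative-binomial mean and
#'   size for hash reads per nucleus.
#' @param ambient_fraction fraction of a nucleus's hash reads carrying a
#'   wrong (ambient) sample barcode.
#' @param base_error_rate per-base substitution probability applied i.i.d.
#'   to every synthetic read (both mates and the index read).
#' @param genome_depth_mean,genome_depth_dispersion negative-binomial mean
#'   and size for aligned fragments per nucleus.
#' @param cross_species_noise fraction of a singlet's fragments assigned to
#'   the wrong genome (mapping noise).
#' @param total_reads_meanlog,total_reads_sdlog lognormal parameters for
#'   total sequenced reads per nucleus (drives the depth filter).
#' @param read_length length of the synthetic biological reads.
#' @param seed integer seed; all outputs are pure functions of
#'   (config, design, seed).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(samples = tibble(
                         sample_id = c("S1", "S2"),
                         species = c("human", "mouse"),
                         n_nuclei = c(500L, 500L)
                       ),
                       doublet_rate = 0.12,
                       hash_depth_mean = 300,
                       hash_depth_dispersion = 3,
                       ambient_fraction = 0.03,
                       base_error_rate = 0.005,
                       genome_depth_mean = 2000,
                       genome_depth_dispersion = 2,
                       cross_species_noise = 0.02,
                       total_reads_meanlog = log(27000),
                       total_reads_sdlog = 0.45,
                       read_length = 50L,
                       seed = 1L) {
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "species", "n_nuclei") %in% names(samples)))
  fracs <- c(doublet_rate, ambient_fraction, base_error_rate,
             cross_species_noise)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (hash_depth_mean <= 0 || genome_depth_mean <= 0) abort("depths must be > 0")
  if (hash_depth_dispersion <= 0) abort("dispersion must be > 0")
  structure(
    list(samples = samples, doublet_rate = doublet_rate,
         hash_depth_mean = hash_depth_mean,
         hash_depth_dispersion = hash_depth_dispersion,
         ambient_fraction = ambient_fraction,
         base_error_rate = base_error_rate,
         genome_depth_mean = genome_depth_mean,
         genome_depth_dispersion = genome_depth_dispersion,
         cross_species_noise = cross_species_noise,
         total_reads_meanlog = total_reads_meanlog,
         total_reads_sdlog = total_reads_sdlog,
         read_length = as.integer(read_length),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Evaluate `code` under `seed`, restoring the caller's RNG state after.
with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# i.i.d. per-base substitution errors on equal-width sequences.
inject_errors <- function(seqs, p) {
  if (p <= 0 || length(seqs) == 0) return(seqs)
  w <- nchar(seqs[1])
  n <- length(seqs)
  k <- rbinom(1, n * w, p)
  if (k == 0) return(seqs)
  pos <- sample.int(n * w, k)
  read_i <- ((pos - 1) %% n) + 1
  base_i <- ((pos - 1) %/% n) + 1
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(k)) {
    i <- read_i[j]; b <- base_i[j]
    cur <- substr(seqs[i], b, b)
    substr(seqs[i], b, b) <- sample(setdiff(bases, cur), 1)
  }
  seqs
}

write_fastq_gz <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), con)
  invisible(path)
}

#' Simulate a complete barnyard hashing experiment with ground truth
#'
#' Generates record-synchronized hash-read FASTQ triplets (read 1 carries
#' the hashing layout, read 2 its reverse complement, the index read the
#' cell barcode), a cell-barcode whitelist ten times the nucleus count, a
#' per-nucleus per-genome fragment count table, and a truth table naming
#' each nucleus's sample(s) and species. Doublets receive hash reads from
#' both constituent samples and, when the samples differ in species,
#' fragments from both genomes. Ambient hash reads carry a barcode drawn
#' uniformly from the other samples; substitution errors are injected
#' i.i.d. per base. All outputs are deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param design a [hash_design()] whose barcodes cover
#'   `config$samples$sample_id`.
#' @param out_dir output directory (default: a fresh temporary directory).
#' @return a list with `files` (paths: `r1`, `r2`, `index`, `whitelist`,
#'   `genome_counts`, `truth`, `config`), `truth` (tibble: `cell_barcode`,
#'   `sample_id`, `sample_id2`, `species`, `species2`, `is_doublet`,
#'   `n_hash_reads`, `total_reads`), `genome_counts` (long tibble) and
#'   `whitelist`.
#' @export
simulate_experiment <- function(config, design, out_dir = tempfile("sim")) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "hash_design"))
  if (!all(config$samples$sample_id %in% design$barcodes$sample_id)) {
    abort("design barcodes do not cover all configured samples")
  }
  if (design_layout_length(design) > config$read_length) {
    abort("read_length shorter than the hashing layout")
  }
  n_total <- sum(config$samples$n_nuclei)
  if (n_total > 4^design$cell_barcode_len / 100) {
    abort("too many nuclei for the cell-barcode space (collision risk)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  with_sim_seed(config$seed, {
    smp <- config$samples
    species_of <- setNames(smp$species, smp$sample_id)

    # whitelist and cell barcodes
    whitelist <- unique(random_dna(10 * n_total, design$cell_barcode_len))
    while (length(whitelist) < 10 * n_total) {
      whitelist <- unique(c(whitelist,
                            random_dna(10 * n_total - length(whitelist),
                                       design$cell_barcode_len)))
    }
    cells <- sample(whitelist, n_total)

    # truth: primary sample, doublet flag, secondary sample
    primary <- sample(rep(smp$sample_id, smp$n_nuclei))
    is_doublet <- rep(FALSE, n_total)
    n_doub <- round(config$doublet_rate * n_total)
    if (n_doub > 0) is_doublet[sample.int(n_total, n_doub)] <- TRUE
    secondary <- rep(NA_character_, n_total)
    if (any(is_doublet) && nrow(smp) > 1) {
      secondary[is_doublet] <- vapply(primary[is_doublet], function(s) {
        sample(setdiff(smp$sample_id, s), 1)
      }, character(1))
    }

    # hash reads
    n_hash <- rnbinom(n_total, size = config$hash_depth_dispersion,
                      mu = config$hash_depth_mean)
    nuc_of_read <- rep.int(seq_len(n_total), n_hash)
    n_reads <- length(nuc_of_read)
    src <- primary[nuc_of_read]
    doub_read <- is_doublet[nuc_of_read] & runif(n_reads) < 0.5
    src[doub_read] <- secondary[nuc_of_read][doub_read]
    if (config$ambient_fraction > 0 && nrow(smp) > 1) {
      amb <- runif(n_reads) < config$ambient_fraction
      if (any(amb)) {
        src[amb] <- vapply(src[amb], function(s) {
          sample(setdiff(smp$sample_id, s), 1)
        }, character(1))
      }
    }
    bc_seq <- setNames(design$barcodes$sequence, design$barcodes$sample_id)
    umi1 <- random_dna(n_reads, design$umi1_len)
    umi2 <- random_dna(n_reads, design$umi2_len)
    layout <- paste0(design$anchor5, umi1, unname(bc_seq[src]), umi2,
                     design$anchor3)
    pad_w <- config$read_length - nchar(layout[1])
    full <- if (pad_w > 0) paste0(layout, random_dna(n_reads, pad_w)) else layout
    r1 <- inject_errors(full, config$base_error_rate)
    r2 <- inject_errors(reverse_complement(full), config$base_error_rate)
    idx <- inject_errors(cells[nuc_of_read], config$base_error_rate)

    # genome fragments
    genomes <- unique(smp$species)
    frags <- rnbinom(n_total, size = config$genome_depth_dispersion,
                     mu = config$genome_depth_mean)
    sp1 <- unname(species_of[primary])
    sp2 <- unname(species_of[secondary])
    gc <- matrix(0L, nrow = n_total, ncol = length(genomes),
                 dimnames = list(NULL, genomes))
    to_primary <- frags
    cross_doub <- is_doublet & !is.na(sp2) & sp2 != sp1
    if (any(cross_doub)) {
      half <- rbinom(sum(cross_doub), frags[cross_doub], 0.5)
      gc[cbind(which(cross_doub), match(sp2[cross_doub], genomes))] <- half
      to_primary[cross_doub] <- frags[cross_doub] - half
    }
    gc[cbind(seq_len(n_total), match(sp1, genomes))] <-
      gc[cbind(seq_len(n_total), match(sp1, genomes))] + to_primary
    if (config$cross_species_noise > 0 && length(genomes) > 1) {
      for (g in seq_along(genomes)) {
        move <- rbinom(n_total, gc[, g], config$cross_species_noise)
        tgt <- if (length(genomes) == 2) (3 - g) else {
          sample(setdiff(seq_along(genomes), g), n_total, replace = TRUE)
        }
        gc[, g] <- gc[, g] - move
        gc[cbind(seq_len(n_total), tgt)] <- gc[cbind(seq_len(n_total), tgt)] + move
      }
    }
    total_reads <- pmax(round(rlnorm(n_total, config$total_reads_meanlog,
                                     config$total_reads_sdlog)),
                        rowSums(gc))

    truth <- tibble(
      cell_barcode = cells,
      sample_id = primary,
      sample_id2 = secondary,
      species = sp1,
      species2 = sp2,
      is_doublet = is_doublet,
      n_hash_reads = as.integer(n_hash),
      total_reads = as.integer(total_reads)
    )
    genome_counts <- tibble(
      cell_barcode = rep(cells, each = length(genomes)),
      genome_id = rep(genomes, times = n_total),
      fragment_count = as.integer(t(gc))
    )

    ids <- sprintf("read%07d", seq_len(n_reads))
    files <- list(
      r1 = file.path(out_dir, "hash_R1.fastq.gz"),
      r2 = file.path(out_dir, "hash_R2.fastq.gz"),
      index = file.path(out_dir, "hash_I2.fastq.gz"),
      whitelist = file.path(out_dir, "whitelist.txt"),
      genome_counts = file.path(out_dir, "genome_counts.tsv"),
      truth = file.path(out_dir, "truth.tsv"),
      config = file.path(out_dir, "config.yml")
    )
    write_fastq_gz(ids, r1, files$r1)
    write_fastq_gz(ids, r2, files$r2)
    write_fastq_gz(ids, idx, files$index)
    writeLines(whitelist, files$whitelist)
    write.table(genome_counts, files$genome_counts, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cfg <- unclass(config)
    cfg$samples <- purrr::transpose(as.list(smp))
    yaml::write_yaml(cfg, files$config)

    list(files = files, truth = truth, genome_counts = genome_counts,
         whitelist = whitelist)
  })
}

#' Simulate a cluster/bulk peak fixture with known cnum and intensity truth
#'
#' Lays non-overlapping union peaks along a synthetic chromosome, assigns
#' each a true cluster-presence count (cnum), materializes per-cluster peak
#' sets accordingly, and draws bulk intensities whose log-mean increases
#' with cnum; the maximal-cnum group is drawn from an explicit
#' two-component log-scale mixture (stochastic vs constant open regions).
#'
#' @param n_peaks number of union peaks.
#' @param n_clusters number of cell clusters (>= 2).
#' @param cnum_weights sampling weights for true cnum 1..n_clusters
#'   (recycled/normalized; default skewed toward constitutive peaks).
#' @param bulk_overlap_prob probability a union peak has a matching bulk
#'   peak.
#' @param intensity_base,intensity_slope log-scale intercept and per-cnum
#'   slope of bulk intensity for non-maximal groups.
#' @param mix_meanlog,mix_sdlog,mix_prop_low two-component lognormal mixture
#'   for the maximal-cnum group (low/high means, common sd, low-component
#'   weight).
#' @param peak_width,peak_spacing geometry of the synthetic peaks (bases).
#' @param seed integer seed.
#' @return a list: `union_peaks` (tibble), `clusters` (named list of peak
#'   tibbles), `bulk_peaks` (tibble with `score`), `truth` (tibble `name`,
#'   `true_cnum`, `true_component`).
#' @export
simulate_cnum_fixture <- function(n_peaks = 2000, n_clusters = 4,
                                  cnum_weights = NULL,
                                  bulk_overlap_prob = 0.9,
                                  intensity_base = 0.5,
                                  intensity_slope = 0.5,
                                  mix_meanlog = c(1, 4), mix_sdlog = 0.4,
                                  mix_prop_low = 0.4,
                                  peak_width = 400, peak_spacing = 1000,
                                  seed = 1L) {
  if (n_clusters < 2) abort("need at least two clusters")
  if (is.null(cnum_weights)) {
    cnum_weights <- c(rep(1, n_clusters - 1), 2)
  }
  with_sim_seed(seed, {
    starts <- (seq_len(n_peaks) - 1L) * as.integer(peak_spacing)
    union_peaks <- tibble(
      chrom = "chrS",
      start = starts,
      end = starts + as.integer(peak_width),
      name = sprintf("peak_%05d", seq_len(n_peaks))
    )
    true_cnum <- sample(seq_len(n_clusters), n_peaks, replace = TRUE,
                        prob = cnum_weights)
    membership <- purrr::map(true_cnum, function(k) {
      sample.int(n_clusters, k)
    })
    cluster_ids <- paste0("cluster_", LETTERS[seq_len(n_clusters)])
    clusters <- purrr::map(seq_len(n_clusters), function(j) {
      keep <- purrr::map_lgl(membership, function(m) j %in% m)
      union_peaks[keep, ]
    })
    names(clusters) <- cluster_ids

    has_bulk <- runif(n_peaks) < bulk_overlap_prob
    is_max <- true_cnum == n_clusters
    comp_low <- is_max & runif(n_peaks) < mix_prop_low
    meanlog <- ifelse(is_max,
                      ifelse(comp_low, mix_meanlog[1], mix_meanlog[2]),
                      intensity_base + intensity_slope * true_cnum)
    score <- rlnorm(n_peaks, meanlog, mix_sdlog)
    bulk_peaks <- dplyr::mutate(union_peaks[has_bulk, ], score = score[has_bulk])

    truth <- tibble(
      name = union_peaks$name,
      true_cnum = as.integer(true_cnum),
      true_component = dplyr::case_when(
        !is_max | !has_bulk ~ NA_character_,
        comp_low ~ "low",
        TRUE ~ "high"
      )
    )
    list(union_peaks = union_peaks, clusters = clusters,
         bulk_peaks = bulk_peaks, truth = truth)
  })
}
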