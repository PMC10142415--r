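test_that("the read-depth filter is inclusive at the boundary", {
  rec <- tibble::tibble(cell_barcode = c("a", "b", "c"),
                        total_reads = c(9999, 10000, 20000))
  expect_equal(filter_nuclei(rec)$cell_barcode, c("b", "c"))
  expect_equal(filter_nuclei(rec, min_reads = 0), rec)
})

test_that("qc predicates drop on any violated condition", {
  rec <- tibble::tibble(
    cell_barcode = paste0("c", 1:6),
    frip_pct = c(14.9, 20, 20, 20, 20, 20),
    fragments_in_peaks = c(5000, 1999, 5000, 5000, 5000, 5000),
    blacklist_ratio = c(0.01, 0.01, 0.06, 0.01, 0.01, 0.01),
    nucleosome_signal = c(1, 1, 1, 0.1, 5, 2.0)
  )
  out <- qc_filter_nuclei(rec)
  expect_equal(out$cell_barcode, "c6")  # nucleosome 2.0 is inside (0.2, 4)
})

test_that("qc predicates are individually toggleable and checked", {
  rec <- tibble::tibble(cell_barcode = "c1", frip_pct = 5,
                        fragments_in_peaks = 10, blacklist_ratio = 0.5,
                        nucleosome_signal = 9)
  out <- qc_filter_nuclei(rec, min_frip_pct = NULL,
                          min_fragments_in_peaks = NULL,
                          max_blacklist_ratio = NULL,
                          nucleosome_bounds = NULL)
  expect_equal(nrow(out), 1)
  expect_error(qc_filter_nuclei(dplyr::select(rec, -"nucleosome_signal")),
               "nucleosome_signal")
})

test_that("qc survivors equal the brute-force application of the predicates", {
  set.seed(13)
  rec <- tibble::tibble(
    cell_barcode = paste0("c", 1:200),
    frip_pct = runif(200, 0, 40),
    fragments_in_peaks = rpois(200, 2500),
    blacklist_ratio = runif(200, 0, 0.1),
    nucleosome_signal = runif(200, 0, 5)
  )
  keep <- !(rec$frip_pct < 15 | rec$fragments_in_peaks < 2000 |
              rec$blacklist_ratio > 0.05 |
              rec$nucleosome_signal < 0.2 | rec$nucleosome_signal > 4)
  expect_equal(qc_filter_nuclei(rec), rec[keep, ])
})

test_that("mixture cutoffs separate ambient from signal counts", {
  set.seed(11)
  n <- 500
  truth <- rep(c("ambient", "signal"), each = n)
  counts <- c(rpois(n, 2), rnbinom(n, size = 4, mu = 300))
  m <- cbind(S1 = counts)
  rownames(m) <- paste0("c", seq_len(2 * n))
  cut <- auto_cutoff(m)
  expect_equal(cut$method, "mixture")
  expect_gte(cut$cutoff, 10)
  expect_lte(cut$cutoff, 60)
  called_signal <- counts >= cut$cutoff
  expect_gte(mean(called_signal == (truth == "signal")), 0.99)
})

test_that("degenerate counts fall back to the fixed cutoff", {
  m <- cbind(S1 = rep(5, 100))
  rownames(m) <- paste0("c", 1:100)
  cut <- auto_cutoff(m)
  expect_equal(cut$method, "fallback")
  expect_equal(cut$cutoff, 10)
})

test_that("scaling all counts shifts the mixture threshold into the scaled gap", {
  set.seed(12)
  ambient <- rpois(300, 2)
  signal <- rnbinom(300, size = 4, mu = 300)
  m1 <- cbind(S1 = c(ambient, signal)); rownames(m1) <- paste0("c", 1:600)
  m10 <- m1 * 10L
  c1 <- auto_cutoff(m1)$cutoff
  c10 <- auto_cutoff(m10)$cutoff
  expect_gt(c10, c1)
  # the unscaled threshold sits in the between-cluster gap
  expect_gt(c1, max(ambient))
  expect_lte(c1, min(signal))
  # the scaled threshold clears the scaled ambient cluster and tracks the
  # 10x scaling (the exact crossover moves with the log1p grid, so the
  # ratio is approximate)
  expect_gt(c10, 10 * max(ambient))
  expect_gt(c10 / c1, 5)
  expect_lt(c10 / c1, 20)
})

test_that("too few nuclei for mixture fitting is an instructive error", {
  m <- cbind(S1 = rpois(20, 5)); rownames(m) <- paste0("c", 1:20)
  expect_error(auto_cutoff(m), "fixed cutoff")
})

test_that("the quadrant rule classifies singlets, multiplets and negatives", {
  m <- rbind(c1 = c(500, 3), c2 = c(500, 400), c3 = c(2, 3))
  colnames(m) <- c("S1", "S2")
  calls <- classify_hash(m, cutoffs = 10)
  expect_equal(calls$label, c("singlet", "multiplet", "negative"))
  expect_equal(calls$sample_id, c("S1", NA, NA))
  # counts equal to the cutoff score as above it (inclusive)
  calls2 <- classify_hash(rbind(c1 = c(10, 0)) |>
                            `colnames<-`(c("S1", "S2")), cutoffs = 10)
  expect_equal(calls2$label, "singlet")
})

test_that("classification is invariant to sample order and silent samples", {
  set.seed(14)
  m <- matrix(rnbinom(300, size = 2, mu = 50), ncol = 3,
              dimnames = list(paste0("c", 1:100), c("S1", "S2", "S3")))
  cuts <- tibble::tibble(sample_id = c("S1", "S2", "S3"), cutoff = 10)
  a <- classify_hash(m, cuts)
  b <- classify_hash(m[, c(3, 1, 2)], cuts)
  expect_equal(a$label, b$label)
  expect_equal(a$sample_id, b$sample_id)
  # an extra all-zero sample below cutoff changes nothing
  m4 <- cbind(m, S4 = 0L)
  cuts4 <- dplyr::bind_rows(cuts, tibble::tibble(sample_id = "S4", cutoff = 10))
  c4 <- classify_hash(m4, cuts4)
  expect_equal(c4$label, a$label)
  expect_equal(c4$sample_id, a$sample_id)
})

test_that("CLR-quantile demultiplexing recovers well-separated singlets", {
  set.seed(15)
  n <- 300
  own <- rnbinom(n, size = 6, mu = 400)
  other <- rpois(n, 3)
  m <- cbind(S1 = c(own, other), S2 = c(other, own))
  rownames(m) <- paste0("c", 1:(2 * n))
  calls <- classify_hash_clr(m)
  truth <- rep(c("S1", "S2"), each = n)
  ok <- calls$label == "singlet" & calls$sample_id == truth
  expect_gte(mean(ok), 0.95)
})

test_that("species assignment applies purity and minor-count rules", {
  gc <- tibble::tibble(
    cell_barcode = rep(c("c1", "c2", "c3", "c4"), each = 2),
    genome_id = rep(c("human", "mouse"), 4),
    fragment_count = c(5000, 50,   # f ~ 0.99 -> human singlet
                       2000, 1800, # f ~ 0.53 -> doublet
                       300, 50,    # f ~ 0.86, minor 50 < 100 -> undetermined
                       0, 0)       # empty -> undetermined
  )
  out <- assign_species(gc)
  expect_equal(out$label[out$cell_barcode == "c1"], "singlet")
  expect_equal(out$genome_id[out$cell_barcode == "c1"], "human")
  expect_equal(out$label[out$cell_barcode == "c2"], "doublet")
  expect_equal(out$label[out$cell_barcode == "c3"], "undetermined")
  expect_equal(out$label[out$cell_barcode == "c4"], "undetermined")
})

test_that("species calls recover simulated barnyard truth at depth", {
  d <- ref_design()
  cfg <- sim_config(
    samples = tibble::tibble(sample_id = c("S1", "S2"),
                             species = c("human", "mouse"),
                             n_nuclei = c(250L, 250L)),
    doublet_rate = 0.1, seed = 3
  )
  sim <- simulate_experiment(cfg, d, out_dir = withr::local_tempdir())
  calls <- assign_species(sim$genome_counts)
  rec <- dplyr::inner_join(calls, sim$truth, by = "cell_barcode")
  rec <- rec[rec$total_fragments >= 2000, ]
  cross <- rec$is_doublet & !is.na(rec$species2) & rec$species2 != rec$species
  ok <- ifelse(cross, rec$label == "doublet",
               rec$label == "singlet" & rec$genome_id == rec$species)
  expect_gte(mean(ok), 0.98)
})

test_that("genome counts can be derived from a fragments file", {
  dir <- withr::local_tempdir()
  frag <- file.path(dir, "fragments.tsv")
  writeLines(c(
    "# comment line",
    "GRCh38_chr1\t100\t200\tAAAA\t2",
    "GRCh38_chr2\t100\t200\tAAAA\t1",
    "mm10_chr1\t100\t200\tAAAA\t5",
    "mm10_chr1\t300\t400\tCCCC\t4"
  ), frag)
  out <- genome_counts_from_fragments(frag, c(human = "GRCh38_", mouse = "mm10_"))
  expect_equal(out$fragment_count[out$cell_barcode == "AAAA" &
                                    out$genome_id == "human"], 3L)
  expect_equal(out$fragment_count[out$cell_barcode == "AAAA" &
                                    out$genome_id == "mouse"], 5L)
  expect_equal(out$fragment_count[out$cell_barcode == "CCCC" &
                                    out$genome_id == "human"], 0L)
})

test_that("call summaries reproduce printed two-decimal percentages", {
  s <- summarize_calls(c(singlet = 9144, multiplet = 1251, negative = 179))
  expect_equal(s$pct, c(86.48, 11.83, 1.69))
  one <- summarize_calls(tibble::tibble(label = "singlet"))
  expect_equal(one$pct[one$label == "singlet"], 100)
})

test_that("summary percentages always sum to 100 within rounding", {
  set.seed(16)
  for (i in 1:20) {
    counts <- setNames(sample(0:5000, 3), c("singlet", "multiplet", "negative"))
    if (sum(counts) == 0) next
    s <- summarize_calls(counts)
    expect_lte(abs(sum(s$pct) - 100), 0.02)
  }
})
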