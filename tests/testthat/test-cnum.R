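peak_tbl <- function(chrom, start, end, score = NA_real_) {
  tibble::tibble(chrom = chrom, start = start, end = end, score = score)
}

test_that("cnum counts the clusters a peak overlaps", {
  union <- peak_tbl("chr1", c(100, 500), c(200, 700))
  clusters <- list(
    A = peak_tbl("chr1", 150, 260),   # overlaps peak 1
    B = peak_tbl("chr1", 900, 1000),  # overlaps none
    C = peak_tbl("chr1", c(120, 480), c(180, 520)),  # peaks 1 and 2
    D = peak_tbl("chr1", 699, 800)    # 1 base with peak 2
  )
  out <- assign_cnum(union, clusters)
  expect_equal(out$cnum, c(2L, 2L))
  # peak present in every cluster reaches the maximum
  everywhere <- assign_cnum(peak_tbl("chr1", 0, 1000), clusters)
  expect_equal(everywhere$cnum, 4L)  # overlaps a peak in every cluster
})

test_that("half-open intervals do not overlap at a shared endpoint", {
  union <- peak_tbl("chr1", 100, 200)
  clusters <- list(A = peak_tbl("chr1", 200, 300))
  expect_equal(assign_cnum(union, clusters)$cnum, 0L)
  expect_equal(assign_cnum(union, list(A = peak_tbl("chr1", 199, 300)))$cnum, 1L)
})

test_that("cnum matches the quadratic all-pairs oracle on random intervals", {
  set.seed(21)
  for (rep in 1:5) {
    union <- peak_tbl(sample(c("chr1", "chr2"), 80, replace = TRUE),
                      s <- sample(1:5000, 80), s + sample(50:300, 80, replace = TRUE))
    clusters <- lapply(1:4, function(j) {
      peak_tbl(sample(c("chr1", "chr2"), 40, replace = TRUE),
               s2 <- sample(1:5000, 40), s2 + sample(50:300, 40, replace = TRUE))
    })
    names(clusters) <- paste0("cl", 1:4)
    out <- assign_cnum(union, clusters)
    expect_equal(out$cnum, as.integer(oracle_cnum(union, clusters)))
  }
})

test_that("group sizes partition the union peak set", {
  set.seed(22)
  union <- peak_tbl("chr1", s <- sample(1:10000, 120), s + 100)
  clusters <- lapply(1:4, function(j) {
    keep <- sample(c(TRUE, FALSE), 120, replace = TRUE)
    union[keep, ]
  })
  names(clusters) <- paste0("cl", 1:4)
  out <- assign_cnum(union, clusters)
  expect_equal(sum(table(out$cnum)), nrow(union))
  # growing a cluster's peak set never decreases any cnum
  clusters2 <- clusters
  clusters2[[2]] <- union
  out2 <- assign_cnum(union, clusters2)
  expect_true(all(out2$cnum >= out$cnum))
})

test_that("bulk attachment takes the maximum score over overlaps", {
  rec <- peak_tbl("chr1", c(100, 1000), c(300, 1200))
  bulk <- peak_tbl("chr1", c(90, 250, 5000), c(150, 350, 5100),
                   score = c(5, 9, 100))
  out <- attach_bulk(rec, bulk)
  expect_equal(out$bulk_score, c(9, NA))
  expect_equal(attr(out, "n_overlapping"), 1L)
  expect_error(attach_bulk(rec, peak_tbl("chr1", 1, 2)), "scores")
})

test_that("bulk overlap counts match a brute-force oracle", {
  set.seed(24)
  rec <- peak_tbl("chr1", s <- sample(1:20000, 150), s + 150)
  bulk <- peak_tbl("chr1", s2 <- sample(1:20000, 60), s2 + 200,
                   score = runif(60, 1, 50))
  out <- attach_bulk(rec, bulk)
  expected <- vapply(seq_len(nrow(rec)), function(i) {
    any(oracle_overlaps(rec$start[i], rec$end[i], bulk$start, bulk$end))
  }, logical(1))
  expect_equal(!is.na(out$bulk_score), expected)
  expect_equal(attr(out, "n_overlapping"), sum(expected))
})

test_that("intensity dichotomization recovers a simulated bimodal mixture", {
  set.seed(5)
  comp <- rep(c("low", "high"), each = 1000)
  scores <- c(rlnorm(1000, 1, 0.4), rlnorm(1000, 4, 0.4))
  split <- dichotomize_intensity(scores)
  expect_gte(mean(as.character(split$labels) == comp), 0.95)
  expect_true(split$threshold > exp(1) && split$threshold < exp(4))
  expect_false(is.null(split$dip))
})

test_that("a manual threshold splits clearly separated scores", {
  scores <- c(1, 1, 1, 1000, 1000, 1000)
  split <- dichotomize_intensity(scores, manual_threshold = 10)
  expect_equal(as.character(split$labels),
               rep(c("low", "high"), each = 3))
})

test_that("labels are invariant under monotone scaling of the scores", {
  set.seed(26)
  scores <- c(rlnorm(500, 1, 0.4), rlnorm(500, 4, 0.4))
  a <- dichotomize_intensity(scores)
  b <- dichotomize_intensity(scores * 37)
  expect_equal(a$labels, b$labels)
  expect_equal(b$threshold / a$threshold, 37, tolerance = 1e-6)
})

test_that("degenerate or tiny score vectors are informative errors", {
  expect_error(dichotomize_intensity(rep(2, 200)), "manual_threshold")
  expect_error(dichotomize_intensity(runif(20) + 1), "manual_threshold")
  expect_error(dichotomize_intensity(c(-1, rep(2, 199))), "positive")
})

test_that("feature annotation follows the midpoint precedence rules", {
  gtf <- system.file("extdata", "toy_genes.gtf", package = "snhash")
  # gene g1: chr1 + strand, tx 10000-20000 (0-based), TSS 10000,
  #   exons 10000-10500 / 14000-14500 / 19500-20000,
  #   utr5 10000-10100, utr3 19800-20000, promoter 8000-12001
  # gene g2: chr1 - strand, tx 30000-40000, TSS 39999 -> promoter 37999-42000
  # gene g3: chr2 + strand, single exon tx 5000-8000
  mk <- function(chrom, mid) peak_tbl(chrom, mid - 50, mid + 50)
  peaks <- dplyr::bind_rows(
    mk("chr1", 9500),    # 500 upstream of g1 TSS -> promoter
    mk("chr1", 10050),   # utr5 region but inside promoter window -> promoter
    mk("chr1", 14250),   # exon 2 of g1, outside promoter -> exon
    mk("chr1", 13000),   # between exons, inside tx -> intron
    mk("chr1", 19900),   # utr3 of g1 -> utr3
    mk("chr1", 25000),   # between genes -> intergenic
    mk("chr1", 39950),   # utr5 of g2 (minus strand) but promoter window -> promoter
    mk("chr1", 30050),   # utr3 of g2 -> utr3
    mk("chr1", 35000),   # intron of g2 (no exons there) -> intron
    mk("chr2", 7500),    # exon of g3, outside promoter window -> exon
    mk("chr2", 5050)     # utr5 of g3 inside promoter window -> promoter
  )
  out <- annotate_features(peaks, gtf)
  expect_equal(as.character(out$feature),
               c("promoter", "promoter", "exon", "intron", "utr3",
                 "intergenic", "promoter", "utr3", "intron", "exon",
                 "promoter"))
  # utr5 wins once outside the promoter window
  out2 <- annotate_features(mk("chr2", 5050), gtf, promoter_window = 10)
  expect_equal(as.character(out2$feature), "utr5")
})

test_that("peaks on chromosomes absent from the gene model are intergenic", {
  gtf <- system.file("extdata", "toy_genes.gtf", package = "snhash")
  expect_warning(out <- annotate_features(peak_tbl("chrUn", 100, 200), gtf),
                 "absent")
  expect_equal(as.character(out$feature), "intergenic")
})

test_that("every peak receives exactly one feature", {
  gtf <- system.file("extdata", "toy_genes.gtf", package = "snhash")
  set.seed(27)
  peaks <- peak_tbl("chr1", s <- sample(1:45000, 100), s + 200)
  out <- annotate_features(peaks, gtf)
  expect_false(any(is.na(out$feature)))
  expect_equal(nrow(out), 100)
})

test_that("overlap fractions report one-decimal percentages", {
  q <- peak_tbl("chr1", seq(0, 9000, by = 1000), seq(100, 9100, by = 1000))
  s <- peak_tbl("chr1", c(0, 1000, 2000, 3000), c(150, 1150, 2150, 3050))
  out <- overlap_fraction(q, s)
  expect_equal(out$pct, 40.0)
  expect_equal(out$n_overlap, 4)
  disjoint <- overlap_fraction(q, peak_tbl("chr2", 0, 100))
  expect_equal(disjoint$pct, 0)
  expect_error(overlap_fraction(q[0, ], s), "empty")
})

test_that("overlap-fraction comparison uses the oracle-tested chi-squared", {
  set.seed(28)
  q1 <- peak_tbl("chr1", s1 <- sample(1:50000, 120), s1 + 100)
  q2 <- peak_tbl("chr1", s2 <- sample(1:50000, 150), s2 + 100)
  subj <- peak_tbl("chr1", s3 <- sample(1:50000, 80), s3 + 400)
  out <- compare_overlap_fractions(q1, q2, subj)
  f1 <- overlap_fraction(q1, subj)
  f2 <- overlap_fraction(q2, subj)
  tab <- rbind(c(f1$n_overlap, f1$n_query - f1$n_overlap),
               c(f2$n_overlap, f2$n_query - f2$n_overlap))
  expect_equal(out$chi2_stat, oracle_chi2(tab), tolerance = 1e-10)
})

test_that("anchor distances are measured midpoint-to-position per chromosome", {
  q <- dplyr::bind_rows(
    peak_tbl("chr1", 950, 1050),   # midpoint 1000, anchor at 1000 -> 0
    peak_tbl("chr1", 2450, 2550),  # midpoint 2500, nearest anchor 4000 -> 1500
    peak_tbl("chr3", 100, 200)     # no anchors on chr3 -> NA
  )
  anchors <- tibble::tibble(chrom = c("chr1", "chr1"), pos = c(1000, 4000))
  out <- distance_to_nearest(q, anchors)
  expect_equal(out$distance, c(0, 1500, NA))
  expect_error(distance_to_nearest(q, anchors[0, ]), "empty")
})

test_that("nearest-anchor distances match a linear-scan oracle", {
  set.seed(29)
  q <- peak_tbl("chr1", s <- sample(1:100000, 200), s + 100)
  anchors <- tibble::tibble(chrom = "chr1", pos = sample(1:100000, 30))
  out <- distance_to_nearest(q, anchors)
  mids <- floor((q$start + q$end) / 2)
  expected <- vapply(mids, function(m) min(abs(m - anchors$pos)), numeric(1))
  expect_equal(out$distance, expected)
})

test_that("narrowPeak files round-trip through the readers", {
  dir <- withr::local_tempdir()
  peaks <- peak_tbl("chr1", c(100, 900), c(400, 1400), score = c(7.5, 12))
  path <- file.path(dir, "peaks.narrowPeak")
  write_narrowpeak(peaks, path)
  back <- read_narrowpeak(path)
  expect_equal(back$start, peaks$start)
  expect_equal(back$end, peaks$end)
  expect_equal(back$score, peaks$score)
})
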