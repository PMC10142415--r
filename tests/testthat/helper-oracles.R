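# Independent brute-force oracles used across the suite. These deliberately
# use plain loops and closed forms, never the package's own code paths.

# Hamming distance, character by character.
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Minimum pairwise Hamming distance by exhaustive pairs.
oracle_min_pairwise <- function(seqs) {
  best <- Inf
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i < j) best <- min(best, oracle_hamming(seqs[i], seqs[j]))
    }
  }
  best
}

# All barcodes within `tol` mismatches of `field` (neighbourhood enumeration).
oracle_barcode_matches <- function(field, barcodes, tol) {
  names(barcodes)[vapply(barcodes, function(b) oracle_hamming(field, b) <= tol,
                         logical(1))]
}

# Directional UMI network size, slow R version: repeatedly take the
# highest-count unassigned UMI as a cluster seed and absorb reachable nodes
# along edges a -> b with Hamming 1 and reads(a) >= 2*reads(b) - 1.
oracle_directional_count <- function(umis, reads) {
  n <- length(umis)
  if (n == 0) return(0L)
  assigned <- rep(FALSE, n)
  clusters <- 0L
  repeat {
    open <- which(!assigned)
    if (length(open) == 0) break
    seed <- open[which.max(reads[open])]
    clusters <- clusters + 1L
    frontier <- seed
    assigned[seed] <- TRUE
    while (length(frontier) > 0) {
      a <- frontier[1]
      frontier <- frontier[-1]
      for (b in which(!assigned)) {
        if (oracle_hamming(umis[a], umis[b]) == 1 &&
            reads[a] >= 2 * reads[b] - 1) {
          assigned[b] <- TRUE
          frontier <- c(frontier, b)
        }
      }
    }
  }
  clusters
}

# Textbook Pearson chi-squared statistic, sum((O - E)^2 / E).
oracle_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Quadratic interval-overlap test (0-based half-open).
oracle_overlaps <- function(s1, e1, s2, e2, min_overlap = 1) {
  pmin(e1, e2) - pmax(s1, s2) >= min_overlap
}

# cnum by all-pairs overlap against each cluster.
oracle_cnum <- function(peaks, clusters, min_overlap = 1) {
  vapply(seq_len(nrow(peaks)), function(i) {
    sum(vapply(clusters, function(cl) {
      any(cl$chrom == peaks$chrom[i] &
            oracle_overlaps(peaks$start[i], peaks$end[i],
                            cl$start, cl$end, min_overlap))
    }, logical(1)))
  }, numeric(1))
}
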