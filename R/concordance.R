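#' Concordance between hash-based and alignment-based classifications
#'
#' Restricted to nuclei called singlet under both schemes, builds the
#' genome-singlet x hash-singlet confusion matrix; a nucleus is concordant
#' when the species of its assigned hash sample equals its assigned genome.
#' Association is tested with Pearson's chi-squared on the confusion matrix
#' (no continuity correction); when any expected cell count is below 5 the
#' statistic is flagged unreliable rather than switching tests. Percentages
#' of singlet / multiplet / negative hash calls over all classified nuclei
#' are reported alongside.
#'
#' @param hash_calls a calls tibble from [classify_hash()] (`cell_barcode`,
#'   `label`, `sample_id`).
#' @param species_calls a calls tibble from [assign_species()]
#'   (`cell_barcode`, `label`, `genome_id`).
#' @param sample_to_species named character vector mapping each sample_id to
#'   its genome_id, or a [hash_design()] carrying species labels.
#' @return an object of class `concordance_report` with elements
#'   `confusion` (genomes x samples matrix), `n_concordant`, `n_discordant`,
#'   `discordance_pct` (half-up, two decimals), `chi2_stat`, `chi2_df`,
#'   `chi2_p`, `chi2_unreliable`, and `summary` (the [summarize_calls()]
#'   tibble of the hash calls on the shared barcodes).
#' @export
concordance <- function(hash_calls, species_calls, sample_to_species) {
  if (inherits(sample_to_species, "hash_design")) {
    sample_to_species <- design_species_map(sample_to_species)
  }
  shared <- dplyr::inner_join(
    hash_calls, species_calls,
    by = "cell_barcode", suffix = c("_hash", "_species")
  )
  if (nrow(shared) == 0) {
    abort("no shared cell barcodes between hash and species calls")
  }
  both <- dplyr::filter(shared, .data$label_hash == "singlet",
                        .data$label_species == "singlet")
  genomes <- sort(unique(unname(sample_to_species)))
  samples <- names(sample_to_species)
  confusion <- table(
    factor(both$genome_id, levels = genomes),
    factor(both$sample_id, levels = samples)
  )
  confusion <- matrix(as.integer(confusion), nrow = length(genomes),
                      dimnames = list(genome = genomes, sample = samples))
  concord_mask <- outer(genomes, samples,
                        function(g, s) unname(sample_to_species[s]) == g)
  n_concordant <- sum(confusion[concord_mask])
  n_discordant <- sum(confusion) - n_concordant

  keep <- rowSums(confusion) > 0
  keepc <- colSums(confusion) > 0
  test_mat <- confusion[keep, keepc, drop = FALSE]
  if (all(dim(test_mat) >= 2)) {
    ct <- suppressWarnings(chisq.test(test_mat, correct = FALSE))
    unreliable <- any(ct$expected < 5)
    chi2 <- list(stat = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, unreliable = unreliable)
  } else {
    chi2 <- list(stat = NA_real_, df = NA_integer_, p = NA_real_,
                 unreliable = NA)
  }

  structure(
    list(
      confusion = confusion,
      n_concordant = n_concordant,
      n_discordant = n_discordant,
      discordance_pct = percent_of(n_discordant, max(sum(confusion), 1), 2),
      chi2_stat = chi2$stat,
      chi2_df = chi2$df,
      chi2_p = chi2$p,
      chi2_unreliable = chi2$unreliable,
      summary = summarize_calls(dplyr::rename(shared, label = "label_hash"))
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  print(x$confusion)
  cat(sprintf("concordant %d, discordant %d (%.2f%%)\n",
              x$n_concordant, x$n_discordant, x$discordance_pct))
  if (!is.na(x$chi2_stat)) {
    cat(sprintf("chi-squared = %.4g, df = %d, p %s%s\n",
                x$chi2_stat, x$chi2_df,
                if (x$chi2_p < 2.2e-16) "< 2.2e-16" else sprintf("= %.3g", x$chi2_p),
                if (isTRUE(x$chi2_unreliable)) " (expected count < 5: unreliable)" else ""))
  }
  cat("hash-call summary over classified nuclei:\n")
  print(x$summary)
  invisible(x)
}

#' Long-format confusion matrix of a concordance report
#'
#' @param x a `concordance_report`.
#' @param ... unused.
#' @return a tibble `genome`, `sample`, `n`, `concordant`.
#' @exportS3Method
tidy.concordance_report <- function(x, ...) {
  df <- as.data.frame.table(x$confusion, responseName = "n",
                            stringsAsFactors = FALSE)
  as_tibble(df)
}

#' One-row summary of a concordance report
#'
#' @param x a `concordance_report`.
#' @param ... unused.
#' @return a one-row tibble with the headline concordance numbers.
#' @exportS3Method
glance.concordance_report <- function(x, ...) {
  tibble(
    n_both_singlet = sum(x$confusion),
    n_concordant = x$n_concordant,
    n_discordant = x$n_discordant,
    discordance_pct = x$discordance_pct,
    chi2_stat = x$chi2_stat,
    chi2_df = x$chi2_df,
    chi2_p = x$chi2_p,
    chi2_unreliable = x$chi2_unreliable
  )
}
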