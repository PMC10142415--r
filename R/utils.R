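#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages in hashing
#' summaries follow the conventional half-up rule (86.475 -> 86.48).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(2.25, 86.475), 1:2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a count over a total
#'
#' @param n count (numerator).
#' @param total denominator.
#' @param digits decimals to report (half-up).
#' @return numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' percent_of(9144, 10574)      # 86.48
#' percent_of(51, 2266, 1)      # 2.3
percent_of <- function(n, total, digits = 2) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, digits)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("Hamming distance requires equal lengths")
  sum(charToRaw(a) != charToRaw(b))
}

# n x width integer matrix of character codes for equal-width strings;
# vectorized workhorse behind anchor/barcode matching.
char_code_matrix <- function(x, width) {
  matrix(utf8ToInt(paste(x, collapse = "")), ncol = width, byrow = TRUE)
}

# Mismatch count of each string in `x` (equal width) against one `pattern`.
mismatches_to <- function(x, pattern) {
  w <- nchar(pattern)
  if (length(x) == 0) return(integer(0))
  m <- char_code_matrix(x, w)
  p <- utf8ToInt(pattern)
  as.integer(rowSums(m != matrix(p, nrow = nrow(m), ncol = w, byrow = TRUE)))
}

# All single-base substitution variants of each barcode, as an
# n x (4 * width) character matrix (entries equal to the input where the
# substituted base matches the original; callers filter those).
hamming1_neighbours <- function(x) {
  w <- nchar(x[1])
  bases <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(x), ncol = 4 * w)
  k <- 0
  for (pos in seq_len(w)) {
    for (b in bases) {
      k <- k + 1
      v <- x
      substr(v, pos, pos) <- b
      out[, k] <- v
    }
  }
  out
}

random_dna <- function(n, width) {
  if (n == 0) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
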