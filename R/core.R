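DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide one-letter codes (DNA); U accepted and mapped to T in
# non-strict mode before this set is consulted.
IUPAC_DNA <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Ordered component names of the 18-dimensional PCNV
#'
#' Layout: four nucleotide counts, four positional means (kappa), four
#' positional variances (D-squared), six pairwise positional covariances.
#'
#' @return Character vector of length 18.
#' @export
pcnv_components <- function() {
  c("nA", "nC", "nG", "nT",
    "kA", "kC", "kG", "kT",
    "D2A", "D2C", "D2G", "D2T",
    "covAC", "covAG", "covAT", "covCG", "covCT", "covGT")
}

# Signal an invalid-input condition; the CLI maps this class to exit code 2.
abort_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("pcnv_input_error", "error")))
}

# Normalize a raw sequence string: uppercase, optional U->T, validate
# against the IUPAC DNA alphabet. Returns the cleaned string.
normalize_sequence <- function(seq, strict = FALSE, id = NULL) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    abort_input("sequence must be a single character string")
  s <- toupper(seq)
  if (nchar(s) == 0L)
    abort_input("empty sequence%s", if (is.null(id)) "" else sprintf(" for record '%s'", id))
  if (!strict) s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  allowed <- if (strict) DNA_BASES else IUPAC_DNA
  bad <- which(!(chars %in% allowed))
  if (length(bad) > 0L) {
    abort_input("invalid character '%s' at position %d%s",
                chars[bad[1L]], bad[1L],
                if (is.null(id)) "" else sprintf(" in record '%s'", id))
  }
  s
}

#' Extract 1-based occurrence positions of each nucleotide
#'
#' Returns, for each of A, C, G, T, the strictly increasing list of 1-based
#' positions at which that base occurs. Ambiguous IUPAC letters (N, R, Y, ...)
#' occupy their position — they never shift the coordinates of later
#' characters — but join no nucleotide's list. With `strict = TRUE` any
#' non-ACGT character is rejected instead.
#'
#' @param seq A single DNA string (case-insensitive; `U` is read as `T`
#'   unless `strict`).
#' @param strict Reject ambiguous IUPAC characters instead of skipping them.
#' @return Named list with elements `A`, `C`, `G`, `T`, each an integer
#'   vector of positions, plus attribute `N` (sequence length).
#' @examples
#' extract_positions("ACTGGCAAT")$A  # 1 7 8
#' @export
extract_positions <- function(seq, strict = FALSE) {
  s <- normalize_sequence(seq, strict = strict)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- lapply(DNA_BASES, function(b) which(chars == b))
  names(out) <- DNA_BASES
  attr(out, "N") <- length(chars)
  out
}

#' Positional distribution of one nucleotide
#'
#' The length-N step function U(i) derived from the occurrence positions:
#' zero before the first occurrence, then within each block between
#' consecutive occurrences p_j and p_{j+1} the constant p_j / (p_{j+1} - p_j),
#' and from the last occurrence p_n to the end the constant
#' p_n / (N - (p_n - 1)). An absent nucleotide yields all zeros.
#'
#' Built from the closed-form block structure in O(n) block operations; the
#' literal per-position scan lives in the test suite as an independent oracle.
#'
#' @param positions Strictly increasing integer vector of 1-based occurrence
#'   positions (possibly empty).
#' @param N Sequence length, a positive integer.
#' @return Numeric vector of length `N`.
#' @examples
#' positional_distribution(c(2L, 6L), 9L)  # 0, 1/2 x4, 3/2 x4
#' @export
positional_distribution <- function(positions, N) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) abort_input("N must be a positive integer")
  n <- length(positions)
  if (n == 0L) return(numeric(N))
  positions <- as.integer(positions)
  if (any(positions < 1L) || any(positions > N))
    abort_input("positions must lie in [1, N]")
  if (n > 1L && any(diff(positions) <= 0L))
    abort_input("positions must be strictly increasing")
  head_zeros <- numeric(positions[1L] - 1L)
  mid <- if (n > 1L) {
    widths <- diff(positions)
    rep(positions[-n] / widths, widths)
  } else numeric(0L)
  tail_width <- N - (positions[n] - 1L)
  tail_block <- rep(positions[n] / tail_width, tail_width)
  c(head_zeros, mid, tail_block)
}

#' Average positional distribution (kappa)
#'
#' Sum of the positional distribution divided by the occurrence count; this
#' equals the arithmetic mean of the occurrence positions. Defined as 0 for
#' an absent nucleotide.
#'
#' @param u Positional distribution values (length N).
#' @param n Occurrence count of the nucleotide.
#' @return A single numeric value.
#' @export
positional_mean <- function(u, n) {
  if (n == 0L) return(0)
  sum(u) / n
}

#' Positional covariance of two nucleotides
#'
#' cov(alpha, beta) = sum_i (U_a(i) - Ubar_a)(U_b(i) - Ubar_b) / (n_a * n_b),
#' where Ubar is the mean of the positional distribution over all N
#' positions. Note the denominator is the product of the two occurrence
#' counts, not N. Defined as 0 when either count is 0.
#'
#' @param ua,ub Positional distributions of the two nucleotides (equal length).
#' @param na,nb Their occurrence counts.
#' @return A single numeric value; symmetric in (ua, na) vs (ub, nb).
#' @export
positional_covariance <- function(ua, ub, na, nb) {
  if (length(ua) != length(ub))
    abort_input("positional distributions have different lengths (%d vs %d)",
                length(ua), length(ub))
  if (na == 0L || nb == 0L) return(0)
  sum((ua - mean(ua)) * (ub - mean(ub))) / (na * nb)
}

#' Positional variance (D-squared)
#'
#' The covariance of a positional distribution with itself,
#' sum_i (U(i) - Ubar)^2 / n^2; always nonnegative, 0 for an absent
#' nucleotide.
#'
#' @param u Positional distribution values.
#' @param n Occurrence count.
#' @return A single nonnegative numeric value.
#' @export
positional_variance <- function(u, n) {
  positional_covariance(u, u, n, n)
}

#' Compute the 18-dimensional PCNV of a DNA sequence
#'
#' Assembles, in fixed order, the four nucleotide counts, the four positional
#' means, the four positional variances and the six pairwise positional
#' covariances (AC, AG, AT, CG, CT, GT). Components involving an absent
#' nucleotide are 0.
#'
#' @inheritParams extract_positions
#' @param id Optional record identifier, stored as attribute `source_id`.
#' @return Named numeric vector of length 18 (names from
#'   [pcnv_components()]), with attributes `source_id` and `source_length`.
#' @examples
#' v <- compute_pcnv("ACTGGCAAT")
#' round(v[["covAC"]], 4)  # 1.4769
#' @export
compute_pcnv <- function(seq, id = NULL, strict = FALSE) {
  pos <- extract_positions(seq, strict = strict)
  N <- attr(pos, "N")
  counts <- vapply(pos, length, integer(1L))
  U <- lapply(pos, positional_distribution, N = N)
  kappa <- mapply(positional_mean, U, counts)
  d2 <- mapply(positional_variance, U, counts)
  pair_idx <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                   c(2L, 3L), c(2L, 4L), c(3L, 4L))
  covs <- vapply(pair_idx, function(p) {
    positional_covariance(U[[p[1L]]], U[[p[2L]]], counts[p[1L]], counts[p[2L]])
  }, numeric(1L))
  v <- c(counts, kappa, d2, covs)
  names(v) <- pcnv_components()
  attr(v, "source_id") <- id
  attr(v, "source_length") <- N
  v
}

#' PCNV matrix for a set of sequences
#'
#' @param x A [pcnv_dataset] or a named character vector of DNA sequences.
#' @param strict Passed to [compute_pcnv()].
#' @return Numeric matrix, one row per sequence (rownames = ids), 18 columns
#'   named as in [pcnv_components()].
#' @export
compute_pcnv_matrix <- function(x, strict = FALSE) {
  seqs <- if (inherits(x, "pcnv_dataset")) x$records else x
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    abort_input("sequences must be named by record id")
  mat <- t(vapply(seq_along(seqs), function(i) {
    as.numeric(compute_pcnv(seqs[[i]], id = names(seqs)[i], strict = strict))
  }, numeric(18L)))
  dimnames(mat) <- list(names(seqs), pcnv_components())
  mat
}
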