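#' Parameters of the hybrid distance
#'
#' @param k word (k-mer) length in bases; default 6, the value used by the
#'   established windowed word-count clustering tools.
#' @param window window length in bases for the local distance; default 100.
#' @param weight_local weight A on the normalized local (windowed d2)
#'   distance; default 0.9.
#' @param weight_global weight B on the global relative-entropy distance;
#'   default 0.1. A + B must equal 1.
#' @return a list of class `hybrid_params`.
#' @export
hybrid_params <- function(k = 6, window = 100,
                          weight_local = 0.9, weight_global = 0.1) {
  k <- as.integer(k)
  window <- as.integer(window)
  if (is.na(k) || k < 1 || k > 12) stop("k must be an integer in [1, 12]")
  if (is.na(window) || window < k) stop("window must be >= k")
  if (weight_local < 0 || weight_local > 1 ||
      weight_global < 0 || weight_global > 1)
    stop("weights must lie in [0, 1]")
  if (abs(weight_local + weight_global - 1) > 1e-12)
    stop("weight_local + weight_global must equal 1")
  structure(list(k = k, window = window,
                 weight_local = weight_local,
                 weight_global = weight_global),
            class = "hybrid_params")
}

#' Named local/global weight combinations
#'
#' The six weightings used in the parameter study, CB1..CB6: local weight
#' from 0.95 down to 0.70 in steps of 0.05, global weight the complement.
#'
#' @return data.frame with columns `combo`, `weight_local`, `weight_global`.
#' @export
weight_combos <- function() {
  data.frame(combo = paste0("CB", 1:6),
             weight_local = seq(0.95, 0.70, by = -0.05),
             weight_global = seq(0.05, 0.30, by = 0.05))
}

# k-mer codes (0-based 2-bit encoding, -1 where the word leaves A/C/G/T)
# for every start position of seq
kmer_codes <- function(seq, k) kmer_codes_cpp(seq, as.integer(k))

decode_kmer <- function(code, k) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(code))
  for (i in seq_along(code)) {
    v <- code[i]
    w <- character(k)
    for (j in k:1) { w[j] <- bases[v %% 4 + 1]; v <- v %/% 4 }
    out[i] <- paste(w, collapse = "")
  }
  out
}

#' Count k-words in a sequence
#'
#' Counts every length-`k` substring composed only of A/C/G/T; words
#' containing any other character (N, ambiguity codes) are excluded.
#'
#' @param seq a single DNA string.
#' @param k word length.
#' @return named integer vector of counts (only observed words); empty if
#'   the sequence is shorter than `k` or has no valid word.
#' @export
count_words <- function(seq, k) {
  codes <- kmer_codes(seq, k)
  codes <- codes[codes >= 0]
  if (length(codes) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(codes)
  stats::setNames(as.integer(tab), decode_kmer(as.integer(names(tab)), k))
}

#' k-word frequency vector of a whole sequence
#'
#' Frequencies are counts divided by the total number of valid k-words in
#' the entire sequence (the global feature is never windowed).
#'
#' @inheritParams count_words
#' @return named numeric vector summing to 1.
#' @export
word_freqs <- function(seq, k) {
  cnt <- count_words(seq, k)
  if (length(cnt) == 0)
    stop("sequence contains no valid k-word (k = ", k, ")")
  cnt / sum(cnt)
}

#' Windowed word-count (d2) distance between two sequences
#'
#' The d2 distance between two windows is the sum over all k-words of the
#' squared difference in occurrence counts. Both sequences are scanned with
#' a sliding window (step 1 base); the reported distance is the minimum d2
#' over all window pairs, so two sequences are close as soon as any pair of
#' their subsequences is close. A sequence shorter than the window
#' contributes its whole length as the single window.
#'
#' @param p,q DNA strings.
#' @param params a [hybrid_params] object (only `k` and `window` are used).
#' @param rc also compare against the reverse complement of `q` and return
#'   the smaller distance (for unoriented ESTs); default FALSE.
#' @return non-negative integer-valued distance; 0 for identical sequences.
#' @export
d2_distance <- function(p, q, params = hybrid_params(), rc = FALSE) {
  k <- params$k
  if (nchar(p) < k || nchar(q) < k)
    stop("sequence shorter than word length k = ", k, ": no words to compare")
  v <- d2_min_cpp(kmer_codes(p, k), kmer_codes(q, k), k, params$window)
  if (rc) {
    vrc <- d2_min_cpp(kmer_codes(p, k), kmer_codes(revcomp(q), k),
                      k, params$window)
    v <- min(v, vrc)
  }
  v
}

#' Global relative-entropy (gred) distance between two sequences
#'
#' A symmetric, bounded relative-entropy divergence between the
#' whole-sequence k-word frequency vectors of the two sequences, computed
#' as the Jensen-Shannon divergence with logarithm base 2. It is 0 exactly
#' when the two frequency vectors are identical and 1 exactly when their
#' word supports are disjoint (no shared k-word).
#'
#' @param p,q DNA strings, each containing at least one valid k-word.
#' @param k word length; default 6.
#' @param rc also compare against the reverse complement of `q` and return
#'   the smaller distance; default FALSE.
#' @return distance in \[0, 1\].
#' @export
gred_distance <- function(p, q, k = 6, rc = FALSE) {
  k <- as.integer(k)
  v <- gred_pair_cpp(kmer_codes(p, k), kmer_codes(q, k))
  if (rc) v <- min(v, gred_pair_cpp(kmer_codes(p, k),
                                    kmer_codes(revcomp(q), k)))
  v
}

#' Reverse complement of a DNA string
#'
#' @param x a DNA string (A/C/G/T/N and IUPAC codes).
#' @return the reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

dist_mat <- function(values, ids, kind) {
  dimnames(values) <- list(ids, ids)
  attr(values, "kind") <- kind
  values
}

#' Min-max normalization of a raw d2 distance matrix
#'
#' Linearly rescales the off-diagonal entries to \[0, 1\] using their
#' minimum and maximum, preserving the rank order of all distances. The
#' diagonal stays 0. If all off-diagonal entries are equal the matrix
#' degenerates to all zeros, with a warning.
#'
#' @param m square symmetric matrix (kind `raw_d2`), n >= 2.
#' @return matrix of kind `normalized_d2` with entries in \[0, 1\].
#' @export
minmax_normalize <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2)
    stop("m must be a square matrix with n >= 2")
  off <- m[row(m) != col(m)]
  lo <- min(off); hi <- max(off)
  out <- m
  if (hi == lo) {
    warning("all off-diagonal distances are equal; normalized matrix is all zero")
    out[] <- 0
  } else {
    out <- (m - lo) / (hi - lo)
    diag(out) <- 0
  }
  attr(out, "kind") <- "normalized_d2"
  dimnames(out) <- dimnames(m)
  out
}

seq_codes <- function(ds, k) {
  lapply(ds$seq, kmer_codes, k = k)
}

#' Pairwise raw d2 matrix for a dataset
#'
#' @param ds an [est_set] with n >= 2 sequences, all at least `k` long.
#' @param params a [hybrid_params].
#' @param rc compare each pair also against the reverse complement and keep
#'   the minimum; default FALSE.
#' @return symmetric matrix of kind `raw_d2`, zero diagonal.
#' @export
d2_matrix <- function(ds, params = hybrid_params(), rc = FALSE) {
  check_dataset_for_k(ds, params$k)
  codes <- seq_codes(ds, params$k)
  m <- d2_matrix_cpp(codes, params$k, params$window)
  if (rc) {
    codes_rc <- lapply(vapply(ds$seq, revcomp, ""), kmer_codes, k = params$k)
    m <- pmin(m, d2_matrix_cpp(codes, params$k, params$window, codes_rc))
  }
  dist_mat(m, ds$id, "raw_d2")
}

#' Pairwise gred matrix for a dataset
#'
#' @inheritParams d2_matrix
#' @param k word length for the global feature; default 6.
#' @return symmetric matrix of kind `gred`, entries in \[0, 1\].
#' @export
gred_matrix <- function(ds, k = 6, rc = FALSE) {
  k <- as.integer(k)
  check_dataset_for_k(ds, k)
  codes <- seq_codes(ds, k)
  m <- gred_matrix_cpp(codes)
  if (rc) {
    codes_rc <- lapply(vapply(ds$seq, revcomp, ""), kmer_codes, k = k)
    m <- pmin(m, gred_matrix_cpp(codes, codes_rc))
  }
  dist_mat(m, ds$id, "gred")
}

check_dataset_for_k <- function(ds, k) {
  stopifnot(inherits(ds, "est_set"))
  if (length(ds) < 2) stop("dataset must contain at least 2 sequences")
  nvalid <- vapply(ds$seq, function(s) sum(kmer_codes(s, k) >= 0), 0L)
  if (any(nvalid == 0))
    stop("sequence(s) without a valid k-word (k = ", k, "): ",
         paste(ds$id[nvalid == 0], collapse = ", "))
  invisible(TRUE)
}

#' Combine normalized local and global matrices at given weights
#'
#' The hybrid distance is linear in its two components, so a precomputed
#' pair of matrices can be re-weighted exactly (used by [sweep_weights()]).
#'
#' @param norm_d2 matrix of kind `normalized_d2`.
#' @param gred matrix of kind `gred`.
#' @param weight_local,weight_global weights A and B, A + B = 1.
#' @return matrix of kind `hybrid`.
#' @export
combine_matrices <- function(norm_d2, gred, weight_local, weight_global) {
  if (abs(weight_local + weight_global - 1) > 1e-12)
    stop("weights must sum to 1")
  if (!identical(dim(norm_d2), dim(gred)))
    stop("component matrices differ in shape")
  out <- weight_local * norm_d2 + weight_global * gred
  attr(out, "kind") <- "hybrid"
  out
}

#' Hybrid distance matrix for a dataset
#'
#' Runs the full four-step procedure: (1) windowed d2 for all pairs,
#' (2) gred for all pairs, (3) min-max normalization of the d2 matrix,
#' (4) weighted combination `A * d2'' + B * gred`. The result lies in
#' \[0, 1\] with 0 meaning identical ESTs.
#'
#' @inheritParams d2_matrix
#' @return symmetric matrix of kind `hybrid`, zero diagonal, entries in
#'   \[0, 1\].
#' @export
hybrid_matrix <- function(ds, params = hybrid_params(), rc = FALSE) {
  local <- minmax_normalize(d2_matrix(ds, params, rc = rc))
  if (params$weight_global == 0) {
    out <- local
    attr(out, "kind") <- "hybrid"
    return(out)
  }
  global <- gred_matrix(ds, k = params$k, rc = rc)
  combine_matrices(local, global, params$weight_local, params$weight_global)
}
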