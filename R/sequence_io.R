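#' Construct an EST dataset
#'
#' An `est_set` holds named nucleotide sequences in a fixed order; the order
#' defines the row/column order of every distance matrix computed from it.
#'
#' @param ids character vector of unique, non-empty sequence identifiers.
#' @param seqs character vector of IUPAC-DNA sequences (same length as `ids`).
#'   Sequences are uppercased; characters outside A/C/G/T are retained but
#'   k-words containing them never enter word counting.
#' @return an object of class `est_set`: a list with elements `id` and `seq`.
#' @export
est_set <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (any(!nzchar(ids)) || anyNA(ids))
    stop("sequence ids must be non-empty")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) < 1))
    stop("all sequences must have length >= 1")
  structure(list(id = ids, seq = seqs), class = "est_set")
}

#' @export
length.est_set <- function(x) length(x$id)

#' @export
print.est_set <- function(x, ...) {
  cat(sprintf("est_set with %d sequences (lengths %d-%d)\n",
              length(x), min(nchar(x$seq)), max(nchar(x$seq))))
  invisible(x)
}

#' Read a multi-FASTA file of EST/mRNA sequences
#'
#' Sequences are uppercased on read. Records shorter than `min_len` are
#' dropped (the standard dataset-cleaning step removes everything under
#' 100 bp); the number dropped is reported via [message()].
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param min_len minimum sequence length to keep; default 0 keeps all.
#' @return an [est_set].
#' @export
read_fasta <- function(path, min_len = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  # Biostrings silently tolerates leading junk; enforce the FASTA contract
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  first <- which(nzchar(trimws(head_lines)))[1]
  if (!is.na(first) && !startsWith(trimws(head_lines[first]), ">"))
    stop("malformed FASTA in ", path, ": sequence data before first header at line ",
         first)
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  keep <- nchar(seqs) >= min_len
  if (any(!keep))
    message(sum(!keep), " record(s) shorter than ", min_len, " bp dropped")
  if (!any(keep)) {
    return(structure(list(id = character(0), seq = character(0)),
                     class = "est_set"))
  }
  est_set(ids[keep], seqs[keep])
}

#' Write an EST dataset to FASTA
#'
#' @param x an [est_set].
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "est_set"))
  ss <- Biostrings::DNAStringSet(x$seq)
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a ground-truth label table
#'
#' Two-column TSV mapping sequence id to gene/cluster label; a header row
#' `id<TAB>label` is optional. Whitespace around fields is trimmed.
#'
#' @param path path to the TSV file.
#' @return named character vector: `labels[id] == label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty label table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) stop("label table ", path, ": line ", bad[1],
                        " does not have two tab-separated columns")
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  labs <- trimws(vapply(parts, `[[`, "", 2L))
  if (tolower(ids[1]) == "id" && tolower(labs[1]) == "label") {
    ids <- ids[-1]; labs <- labs[-1]
  }
  if (length(ids) == 0) stop("empty label table: ", path)
  if (anyDuplicated(ids)) {
    for (i in unique(ids[duplicated(ids)])) {
      if (length(unique(labs[ids == i])) > 1)
        stop("conflicting labels for id '", i, "' in ", path)
    }
    keep <- !duplicated(ids)
    ids <- ids[keep]; labs <- labs[keep]
  }
  stats::setNames(labs, ids)
}

#' Write a label table (id, label) as TSV
#'
#' @param labels named vector (names = ids); cluster labels or gene names.
#' @param path output path.
#' @param header write an `id\\tlabel` header row (default TRUE).
#' @export
write_labels <- function(labels, path, header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("id\tlabel", con)
  writeLines(paste(names(labels), as.character(labels), sep = "\t"), con)
  invisible(path)
}

#' Distance-matrix TSV round trip
#'
#' Square symmetric matrices travel as TSV: the first row lists the n ids;
#' each following row is `id<TAB>v1<TAB>...<TAB>vn` with values printed to
#' at least 8 significant digits, so `read_matrix(write_matrix(m))`
#' reproduces `m` to well under 1e-6 per entry.
#'
#' @param m numeric matrix with identical rownames and colnames, symmetric,
#'   zero diagonal. A `kind` attribute (e.g. "hybrid") is preserved in memory
#'   but not serialized.
#' @param path file path.
#' @return `read_matrix` returns the matrix with dimnames set to the ids.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  ids <- rownames(m)
  if (is.null(ids)) stop("matrix must carry ids as rownames")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix must be symmetric")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(ids[i], paste(sprintf("%.10g", m[i, ]), collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("not a distance-matrix file: ", path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(ids)
  if (length(lines) != n + 1)
    stop("matrix file ", path, ": expected ", n, " data rows, found ",
         length(lines) - 1)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != n + 1)
      stop("matrix file ", path, ": row ", i, " has ", length(f) - 1,
           " values, expected ", n)
    if (f[1] != ids[i])
      stop("matrix file ", path, ": row id '", f[1],
           "' does not match header id '", ids[i], "'")
    m[i, ] <- as.numeric(f[-1])
  }
  if (anyNA(m)) stop("matrix file ", path, ": non-numeric entries")
  m
}
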