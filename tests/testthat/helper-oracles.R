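# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with R/ or src/.

rand_dna <- function(n, p_n = 0) {
  alphabet <- c("A", "C", "G", "T")
  x <- sample(alphabet, n, replace = TRUE)
  if (p_n > 0) {
    hit <- which(runif(n) < p_n)
    x[hit] <- "N"
  }
  paste(x, collapse = "")
}

# all k-words of a sequence as strings, NA where the word leaves A/C/G/T
oracle_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, 1:(n - k + 1), k:n)
  w[grepl("[^ACGT]", w)] <- NA_character_
  w
}

# naive windowed-minimum d2: enumerate every window pair explicitly.
# Count vectors per window are built independently with table(); the
# cross-distance matrix uses the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab.
oracle_d2 <- function(p, q, k, window) {
  kp <- oracle_kmers(p, k)
  kq <- oracle_kmers(q, k)
  lev <- sort(unique(stats::na.omit(c(kp, kq))))
  win_counts <- function(words, seq_len_) {
    m <- min(window, seq_len_) - k + 1       # words per window
    nw <- length(words) - m + 1              # window start positions
    out <- matrix(0L, nw, length(lev))
    for (s in seq_len(nw)) {
      tab <- table(factor(words[s:(s + m - 1)], levels = lev))
      out[s, ] <- as.integer(tab)
    }
    out
  }
  A <- win_counts(kp, nchar(p))
  B <- win_counts(kq, nchar(q))
  D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  min(D)
}

# direct evaluation of the base-2 Jensen-Shannon divergence between the
# whole-sequence word-frequency tables
oracle_gred <- function(p, q, k) {
  fp <- table(stats::na.omit(oracle_kmers(p, k)))
  fq <- table(stats::na.omit(oracle_kmers(q, k)))
  fp <- fp / sum(fp); fq <- fq / sum(fq)
  words <- union(names(fp), names(fq))
  a <- ifelse(words %in% names(fp), as.numeric(fp[words]), 0)
  b <- ifelse(words %in% names(fq), as.numeric(fq[words]), 0)
  m <- (a + b) / 2
  term <- function(x) ifelse(x > 0, x * log2(x / m), 0)
  sum(term(a) + term(b)) / 2
}

# brute-force density-reachability closure replicating the sequential
# scan's labelling: clusters are the connected components of the graph on
# core points (edges at distance <= eps); components are numbered by the
# dataset index of their first core point; a non-core point with a core
# neighbor joins the earliest such cluster, everything else is noise (-1)
oracle_dbscan <- function(m, eps, min_points) {
  n <- nrow(m)
  nb <- lapply(seq_len(n), function(i) setdiff(which(m[i, ] <= eps), i))
  core <- vapply(nb, length, 1L) >= min_points
  labels <- rep(-1L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cid <- cid + 1L
    comp <- i
    repeat {
      grow <- setdiff(unique(unlist(nb[comp])), comp)
      grow <- grow[core[grow]]
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    labels[comp] <- cid
  }
  for (i in seq_len(n)) {
    if (core[i] || !length(nb[[i]])) next
    cn <- nb[[i]][core[nb[[i]]]]
    cand <- labels[cn]
    cand <- cand[cand >= 1]
    if (length(cand)) labels[i] <- min(cand)
  }
  as.integer(labels)
}

# canonical form of a partition-with-noise: noise items become singleton
# blocks; blocks compared as unordered sets of member indices
canonical_partition <- function(labels) {
  lab <- as.character(labels)
  noise <- labels == -1
  lab[noise] <- paste0("s", which(noise))
  blocks <- split(seq_along(labels), lab)
  blocks <- lapply(blocks, sort)
  unname(blocks[order(vapply(blocks, `[`, 1L, 1))])
}

same_partition <- function(a, b) {
  identical(canonical_partition(a), canonical_partition(b))
}

# Jaccard components by exhaustive enumeration of all unordered pairs;
# predicted -1 labels are singletons (never co-clustered)
oracle_jaccard <- function(pred, truth) {
  n <- length(pred)
  a <- b <- cc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_c <- pred[i] != -1 && pred[j] != -1 && pred[i] == pred[j]
      same_p <- truth[i] == truth[j]
      if (same_c && same_p) a <- a + 1
      else if (same_c) b <- b + 1
      else if (same_p) cc <- cc + 1
    }
  }
  list(index = if (a + b + cc == 0) 1 else a / (a + b + cc),
       a = a, b = b, c = cc)
}

# random symmetric matrix in [0,1] with zero diagonal, with enough mass
# near zero that clusters actually form at small eps
rand_unit_matrix <- function(n, ids = sprintf("s%02d", seq_len(n))) {
  m <- matrix(0, n, n)
  v <- runif(n * (n - 1) / 2)^2
  m[upper.tri(m)] <- v
  m <- m + t(m)
  dimnames(m) <- list(ids, ids)
  m
}

# random partition labels over n items (some -1 noise)
rand_partition <- function(n, k = sample(2:6, 1), p_noise = 0.15) {
  lab <- sample(seq_len(k), n, replace = TRUE)
  lab[runif(n) < p_noise] <- -1L
  as.integer(lab)
}
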