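#' Jaccard index of a clustering against a reference partition
#'
#' Counts unordered pairs of ESTs: `a` co-clustered in both the predicted
#' clustering C and the reference partition, `b` co-clustered in C only,
#' `c` co-clustered in the reference only; the index is `a / (a + b + c)`,
#' 1 when the two structures are identical. Every predicted label -1 is
#' treated as its own singleton cluster — two noise ESTs never count as
#' co-clustered. If no pair is co-clustered on either side the index is
#' defined as 1 (both structures are all singletons).
#'
#' @param pred an `est_clustering` (or named integer vector of labels,
#'   -1 = singleton).
#' @param truth named vector mapping the same ids to reference labels.
#' @return list with `index`, and pair counts `a`, `b`, `c`.
#' @export
jaccard_index <- function(pred, truth) {
  p <- if (inherits(pred, "est_clustering")) pred$labels else pred
  if (is.null(names(p)) || is.null(names(truth)))
    stop("pred and truth must be named by sequence id")
  missing_in_truth <- setdiff(names(p), names(truth))
  missing_in_pred <- setdiff(names(truth), names(p))
  if (length(missing_in_truth) || length(missing_in_pred))
    stop("id sets differ; missing in truth: ",
         paste(missing_in_truth, collapse = ", "),
         "; missing in pred: ",
         paste(missing_in_pred, collapse = ", "))
  truth <- truth[names(p)]
  plab <- as.character(p)
  noise <- p == -1
  plab[noise] <- paste0(".noise.", seq_len(sum(noise))) # distinct singletons
  tab <- table(plab, as.character(truth))
  ch2 <- function(x) x * (x - 1) / 2
  a <- sum(ch2(tab))
  pairs_pred <- sum(ch2(rowSums(tab)))
  pairs_truth <- sum(ch2(colSums(tab)))
  b <- pairs_pred - a
  cc <- pairs_truth - a
  idx <- if (a + b + cc == 0) 1 else a / (a + b + cc)
  list(index = idx, a = a, b = b, c = cc)
}

#' Weight-by-eps parameter sweep
#'
#' Evaluates the hybrid distance over a grid of local/global weightings
#' and neighborhood radii. The d2 and gred matrices are computed once and
#' re-weighted per combination — exact, because the hybrid distance is
#' linear in its two components at fixed weights.
#'
#' @param ds an [est_set].
#' @param truth named reference labels covering all ids in `ds`.
#' @param combos data.frame with columns `combo`, `weight_local`,
#'   `weight_global`; default [weight_combos()] (CB1..CB6).
#' @param eps_grid neighborhood radii to test; default 0.05 to 0.30 in
#'   steps of 0.05.
#' @param method "dbscan" or "hier".
#' @param k,window word length and window size for the distance.
#' @param min_points DBSCAN minimum neighbors; default 2.
#' @param rc reverse-complement-aware comparison; default FALSE.
#' @return long-format data.frame: combo, weight_local, weight_global,
#'   eps, jaccard, n_clusters — one row per (combo, eps).
#' @export
sweep_weights <- function(ds, truth, combos = weight_combos(),
                          eps_grid = seq(0.05, 0.30, by = 0.05),
                          method = c("dbscan", "hier"),
                          k = 6, window = 100, min_points = 2, rc = FALSE) {
  method <- match.arg(method)
  base <- hybrid_params(k = k, window = window)
  local <- minmax_normalize(d2_matrix(ds, base, rc = rc))
  global <- gred_matrix(ds, k = k, rc = rc)
  rows <- vector("list", nrow(combos) * length(eps_grid))
  r <- 0L
  for (i in seq_len(nrow(combos))) {
    m <- combine_matrices(local, global,
                          combos$weight_local[i], combos$weight_global[i])
    for (eps in eps_grid) {
      cl <- if (method == "dbscan") dbscan_est(m, eps = eps,
                                               min_points = min_points)
            else hierarchical_est(m, cut = eps)
      jc <- jaccard_index(cl, truth)
      r <- r + 1L
      rows[[r]] <- data.frame(combo = combos$combo[i],
                              weight_local = combos$weight_local[i],
                              weight_global = combos$weight_global[i],
                              eps = eps,
                              jaccard = jc$index,
                              n_clusters = cl$n_clusters)
    }
  }
  do.call(rbind, rows)
}
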