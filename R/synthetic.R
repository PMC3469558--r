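#' Configuration for the gene-family EST simulator
#'
#' Describes a family of paralogous genes and an EST library sampled from
#' them. Each paralog is derived from one ancestral gene: designated
#' shared blocks (exon-like regions) stay near-identical across paralogs
#' (mutated at `shared_block_divergence`), while the rest of each gene
#' diverges independently at `inter_gene_divergence`. ESTs are contiguous
#' fragments with uniform position and length, plus per-base substitution
#' sequencing errors.
#'
#' @param n_genes number of paralogous genes (>= 2).
#' @param gene_len gene length in bases.
#' @param n_exons number of shared blocks per gene (0 = unrelated genes).
#' @param shared_block_len length of each shared block; blocks of at least
#'   the comparison window (100 bases) defeat a purely window-based
#'   distance.
#' @param inter_gene_divergence per-base substitution probability applied
#'   to non-shared regions of each paralog.
#' @param shared_block_divergence per-base substitution probability inside
#'   shared blocks (small, e.g. <= 0.02).
#' @param ests_per_gene ESTs sampled per gene: a single count or a
#'   (min, max) range.
#' @param est_len_range EST length range in bases; default c(200, 800),
#'   the typical EST length span. Must lie within \[100, gene_len\].
#' @param error_rate per-base substitution probability of the sequencing
#'   error model (substitution-only; no indels).
#' @param block_jitter maximum per-gene shift (bases) of each shared block
#'   offset; 0 (default) places blocks at identical offsets in all genes.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return a list of class `family_config`.
#' @export
family_config <- function(n_genes = 10, gene_len = 3000,
                          n_exons = 1, shared_block_len = 150,
                          inter_gene_divergence = 0.25,
                          shared_block_divergence = 0.01,
                          ests_per_gene = 40,
                          est_len_range = c(200, 800),
                          error_rate = 0.005,
                          block_jitter = 0,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), gene_len = as.integer(gene_len),
              n_exons = as.integer(n_exons),
              shared_block_len = as.integer(shared_block_len),
              inter_gene_divergence = inter_gene_divergence,
              shared_block_divergence = shared_block_divergence,
              ests_per_gene = as.integer(ests_per_gene),
              est_len_range = as.integer(est_len_range),
              error_rate = error_rate,
              block_jitter = as.integer(block_jitter),
              seed = as.integer(seed))
  if (cfg$n_genes < 2) stop("n_genes must be >= 2")
  if (length(cfg$est_len_range) == 1)
    cfg$est_len_range <- rep(cfg$est_len_range, 2)
  if (cfg$est_len_range[1] < 100 || cfg$est_len_range[2] > cfg$gene_len ||
      cfg$est_len_range[1] > cfg$est_len_range[2])
    stop("est_len_range must be ordered and lie within [100, gene_len]")
  for (p in c("inter_gene_divergence", "shared_block_divergence", "error_rate"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  if (cfg$n_exons > 0 &&
      cfg$n_exons * cfg$shared_block_len > cfg$gene_len)
    stop("shared blocks exceed gene length: infeasible geometry")
  if (any(is.na(cfg$ests_per_gene)) || any(cfg$ests_per_gene < 1))
    stop("ests_per_gene must be a positive count or range")
  class(cfg) <- "family_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

# substitute each position independently with prob `rate`, always to a
# different base
mutate_chars <- function(x, rate) {
  if (rate <= 0) return(x)
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit)) {
    shift <- sample.int(3, length(hit), replace = TRUE)
    x[hit] <- BASES[(match(x[hit], BASES) - 1 + shift) %% 4 + 1]
  }
  x
}

# evenly spaced block start offsets that keep blocks disjoint and in range
block_offsets <- function(gene_len, n_exons, block_len) {
  if (n_exons == 0) return(integer(0))
  centers <- round((seq_len(n_exons) - 0.5) * gene_len / n_exons)
  starts <- pmax(1L, pmin(gene_len - block_len + 1L,
                          as.integer(centers - floor(block_len / 2))))
  if (n_exons > 1 && any(diff(starts) < block_len))
    stop("shared blocks overlap: infeasible geometry")
  starts
}

#' Simulate a gene-family EST dataset with ground truth
#'
#' @param cfg a [family_config].
#' @return list with `dataset` (an [est_set]) and `truth` (named character
#'   vector id -> source gene). Gene sequences are attached as attribute
#'   `genes` on the result for inspection.
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "family_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(cfg$seed)

  ancestor <- sample(BASES, cfg$gene_len, replace = TRUE)
  starts <- block_offsets(cfg$gene_len, cfg$n_exons, cfg$shared_block_len)
  genes <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    s <- starts
    if (cfg$block_jitter > 0 && length(s)) {
      s <- s + sample(seq(-cfg$block_jitter, cfg$block_jitter),
                      length(s), replace = TRUE)
      s <- pmax(1L, pmin(cfg$gene_len - cfg$shared_block_len + 1L, s))
    }
    in_block <- rep(FALSE, cfg$gene_len)
    for (b in s) in_block[b:(b + cfg$shared_block_len - 1L)] <- TRUE
    gene <- ancestor
    gene[!in_block] <- mutate_chars(ancestor[!in_block],
                                    cfg$inter_gene_divergence)
    gene[in_block] <- mutate_chars(ancestor[in_block],
                                   cfg$shared_block_divergence)
    genes[[g]] <- gene
  }

  ids <- character(0); seqs <- character(0); labs <- character(0)
  for (g in seq_len(cfg$n_genes)) {
    n_est <- if (length(cfg$ests_per_gene) > 1)
      sample(cfg$ests_per_gene[1]:cfg$ests_per_gene[2], 1) else
      cfg$ests_per_gene
    gname <- sprintf("g%02d", g)
    for (e in seq_len(n_est)) {
      len <- sample(cfg$est_len_range[1]:cfg$est_len_range[2], 1)
      pos <- sample.int(cfg$gene_len - len + 1L, 1)
      frag <- genes[[g]][pos:(pos + len - 1L)]
      frag <- mutate_chars(frag, cfg$error_rate)
      ids <- c(ids, sprintf("%s_e%03d", gname, e))
      seqs <- c(seqs, paste(frag, collapse = ""))
      labs <- c(labs, gname)
    }
  }
  ds <- est_set(ids, seqs)
  out <- list(dataset = ds, truth = stats::setNames(labs, ids))
  attr(out, "genes") <- vapply(genes, paste, "", collapse = "")
  out
}

#' Frozen benchmark fixtures
#'
#' `fixture_easy()` simulates well-separated genes (no shared blocks, deep
#' divergence): the default pipeline recovers the true gene partition.
#' `fixture_family()` simulates paralogs sharing a near-identical block
#' longer than the 100-base comparison window, the scenario in which a
#' purely local window-based distance co-clusters ESTs across genes.
#' Both use frozen seeds, so they are byte-identical across runs.
#'
#' @return list with `dataset` and `truth` as in [simulate_family()].
#' @export
fixture_easy <- function() {
  simulate_family(family_config(
    n_genes = 6, gene_len = 2000, n_exons = 0, shared_block_len = 0,
    inter_gene_divergence = 0.35, ests_per_gene = 32,
    est_len_range = c(250, 800), error_rate = 0.005, seed = 4101L))
}

#' @rdname fixture_easy
#' @export
fixture_family <- function() {
  simulate_family(family_config(
    n_genes = 5, gene_len = 2500, n_exons = 1, shared_block_len = 150,
    inter_gene_divergence = 0.25, shared_block_divergence = 0.01,
    ests_per_gene = 55, est_len_range = c(350, 800), error_rate = 0.005,
    seed = 21L))
}
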