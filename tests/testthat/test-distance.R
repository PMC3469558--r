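test_that("count_words counts only valid A/C/G/T words", {
  expect_equal(count_words("AAAT", 1), c(A = 3L, T = 1L))
  expect_equal(count_words("ACGT", 4), c(ACGT = 1L))
  expect_equal(count_words("ANAA", 2), c(AA = 1L))
  expect_equal(length(count_words("ACG", 4)), 0L)  # k > len: empty, no error
  expect_equal(length(count_words("NNNN", 2)), 0L)
})

test_that("word_freqs normalizes whole-sequence counts to 1", {
  expect_equal(word_freqs("AAAT", 1), c(A = 0.75, T = 0.25))
  expect_equal(word_freqs("ACGT", 2), c(AC = 1, CG = 1, GT = 1) / 3)
  expect_error(word_freqs("NNN", 2), "no valid k-word")
  withr::with_seed(7, {
    for (i in 1:20) {
      s <- rand_dna(sample(10:300, 1), p_n = 0.05)
      k <- sample(c(1, 2, 3, 6), 1)
      f <- word_freqs(s, k)
      expect_equal(sum(f), 1)
      expect_true(all(f > 0))
    }
  })
})

test_that("d2_distance matches hand-derived window minima", {
  p1 <- hybrid_params(k = 1, window = 4)
  expect_equal(d2_distance("AAAA", "AAAT", p1), 2)      # (4-3)^2 + (0-1)^2
  p2 <- hybrid_params(k = 1, window = 2)
  expect_equal(d2_distance("AATT", "TTAA", p2), 0)      # window "AA"/"TT" shared
  expect_error(d2_distance("AC", "A", hybrid_params(k = 2, window = 2)),
               "shorter than word length")
})

test_that("d2_distance is symmetric, zero at identity, and oracle-exact", {
  withr::with_seed(11, {
    for (i in 1:40) {
      k <- sample(c(1, 2, 3, 6), 1)
      n1 <- sample(10:150, 1); n2 <- sample(10:150, 1)
      if (min(n1, n2) < k) next
      w <- sample(k:60, 1)
      p <- rand_dna(n1, p_n = 0.03); q <- rand_dna(n2, p_n = 0.03)
      prm <- hybrid_params(k = k, window = w)
      d <- d2_distance(p, q, prm)
      expect_identical(d, d2_distance(q, p, prm))
      expect_identical(d, oracle_d2(p, q, k, w))
      expect_identical(d2_distance(p, p, prm), 0)
    }
  })
})

test_that("gred_distance meets the relative-entropy contract", {
  expect_equal(gred_distance("ACGTACGT", "ACGTACGT", k = 2), 0)
  expect_equal(gred_distance("AAAA", "CCCC", k = 1), 1)   # disjoint supports
  expect_equal(gred_distance("AA", "AC", k = 1), 0.311278124459133,
               tolerance = 1e-12)
  # 0 iff equal frequency vectors: same composition, different order
  expect_equal(gred_distance("ACAC", "CACA", k = 1), 0)
  withr::with_seed(13, {
    for (i in 1:30) {
      p <- rand_dna(sample(10:200, 1)); q <- rand_dna(sample(10:200, 1))
      k <- sample(c(1, 2, 3, 6), 1)
      g <- gred_distance(p, q, k = k)
      expect_gte(g, 0); expect_lte(g, 1)
      expect_equal(g, gred_distance(q, p, k = k))
      expect_equal(g, oracle_gred(p, q, k), tolerance = 1e-12)
    }
  })
})

test_that("minmax_normalize maps endpoints to 0/1 and preserves order", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m["a", "b"] <- m["b", "a"] <- 2
  m["a", "c"] <- m["c", "a"] <- 4
  m["b", "c"] <- m["c", "b"] <- 10
  nm <- minmax_normalize(m)
  expect_equal(nm["a", "b"], 0)
  expect_equal(nm["b", "c"], 1)
  expect_equal(nm["a", "c"], 0.25)   # (4-2)/(10-2)
  expect_equal(diag(nm), c(a = 0, b = 0, c = 0))

  flat <- matrix(5, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  diag(flat) <- 0
  expect_warning(z <- minmax_normalize(flat), "all off-diagonal")
  expect_true(all(z == 0))

  withr::with_seed(17, {
    r <- rand_unit_matrix(12) * 37
    nr <- minmax_normalize(r)
    off <- upper.tri(r)
    expect_equal(order(r[off]), order(nr[off]))  # monotone
    expect_equal(min(nr[off]), 0)
    expect_equal(max(nr[off]), 1)
  })
})

test_that("hybrid matrix is the exact weighted sum of its components", {
  withr::with_seed(19, {
    sim <- simulate_family(family_config(n_genes = 3, gene_len = 600,
                                         n_exons = 0, shared_block_len = 0,
                                         ests_per_gene = 4,
                                         est_len_range = c(100, 200),
                                         error_rate = 0.01, seed = 5))
  })
  ds <- sim$dataset
  prm <- hybrid_params(k = 4, window = 60, weight_local = 0.8,
                       weight_global = 0.2)
  local <- minmax_normalize(d2_matrix(ds, prm))
  global <- gred_matrix(ds, k = 4)
  h <- hybrid_matrix(ds, prm)
  expect_lt(max(abs(h - (0.8 * local + 0.2 * global))), 1e-12)
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(diag(h), stats::setNames(rep(0, length(ds)), ds$id))
  expect_lt(max(abs(h - t(h))), 1e-15)

  # A=1 reproduces the local-only matrix entrywise
  h_loc <- hybrid_matrix(ds, hybrid_params(k = 4, window = 60,
                                           weight_local = 1, weight_global = 0))
  expect_equal(as.numeric(h_loc), as.numeric(local), tolerance = 1e-15)

  # single-pair example: 0.9*0.4 + 0.1*0.8 = 0.44
  expect_equal(0.9 * 0.4 + 0.1 * 0.8, 0.44)
  # identical sequences sit at distance 0 in the hybrid matrix
  ds2 <- est_set(c("u", "v", "w"),
                 c(ds$seq[1], ds$seq[1], ds$seq[5]))
  h2 <- hybrid_matrix(ds2, hybrid_params(k = 4, window = 60))
  expect_equal(h2["u", "v"], 0)
})

test_that("reverse-complement mode takes the orientation minimum", {
  withr::with_seed(23, {
    p <- rand_dna(200)
    q <- rand_dna(200)
  })
  qrc <- revcomp(q)
  prm <- hybrid_params(k = 3, window = 50)
  expect_equal(d2_distance(p, q, prm, rc = TRUE),
               min(d2_distance(p, q, prm), d2_distance(p, qrc, prm)))
  # an EST equal to the reverse complement of another is distance 0 with rc
  expect_equal(d2_distance(p, revcomp(p), prm, rc = TRUE), 0)
  expect_equal(gred_distance(p, revcomp(p), k = 3, rc = TRUE), 0)
})

test_that("hybrid_params validates the weight simplex and window", {
  expect_error(hybrid_params(weight_local = 0.5, weight_global = 0.4),
               "must equal 1")
  expect_error(hybrid_params(k = 6, window = 5), "window")
  expect_error(hybrid_params(k = 0), "k must be")
  wc <- weight_combos()
  expect_equal(wc$combo, paste0("CB", 1:6))
  expect_equal(wc$weight_local + wc$weight_global, rep(1, 6))
  expect_equal(wc$weight_global, seq(0.05, 0.30, by = 0.05))
})
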