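test_that("the wNN weight kernel behaves as a sharp similarity filter", {
  expect_equal(wnn_weight(0), 0)
  expect_equal(wnn_weight(1, 1e-6), 1e12)
  # strictly increasing in |r| on (0, 1)
  rs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(wnn_weight(rs)) > 0))
  expect_equal(wnn_weight(-0.7), wnn_weight(0.7))   # even in r
  expect_true(wnn_weight(0.5) < 1 && wnn_weight(0.9) > 1)
  expect_error(wnn_weight(1.2))
  expect_error(wnn_weight(0.5, eps = 0))
})

test_that("zero-fill sets every missing entry to exactly zero", {
  m <- random_emap(8, 0.3, seed = 1)
  res <- impute_baseline(m, "zeros")
  mp <- missing_pairs(m)
  expect_true(all(res$matrix$scores[mp] == 0))
  expect_false(any(is.na(res$matrix$scores[upper.tri(res$matrix$scores)])))
})

test_that("gene-mean baseline averages the two row means", {
  s <- matrix(NA_real_, 4, 4)
  s[1, 3] <- s[3, 1] <- 2       # row 1 measured values: {2}
  s[2, 4] <- s[4, 2] <- 4       # row 2 measured values: {4}
  m <- emap_matrix(s)
  res <- impute_baseline(m, "gene_mean")
  expect_equal(res$matrix$scores[1, 2], 3)
})

test_that("median baseline uses the global measured median", {
  s <- matrix(NA_real_, 4, 4)
  s[1, 2] <- s[2, 1] <- -1; s[1, 3] <- s[3, 1] <- 0
  s[2, 3] <- s[3, 2] <- 5
  m <- emap_matrix(s)
  res <- impute_baseline(m, "median")
  expect_true(all(res$matrix$scores[missing_pairs(m)] == 0))
})

test_that("gene-mean fallback on a fully missing row is flagged", {
  s <- matrix(NA_real_, 4, 4)
  s[1, 2] <- s[2, 1] <- 2; s[1, 3] <- s[3, 1] <- 4
  m <- emap_matrix(s)    # row 4 fully missing
  res <- impute_baseline(m, "gene_mean")
  prov <- res$provenance
  expect_true(all(prov$fallback[prov$i == 4 | prov$j == 4]))
})

test_that("uKNN at K=1 combines the two symmetric donor values", {
  m <- toy_emap()
  res <- impute_uknn(m, imputation_config("uknn", k = 1))
  # i-side donor: duplicate profile g2 gives M[g2, g3] = 1.5;
  # j-side donor: g3's best neighbour g2 gives M[g1, g2] = 0.2
  expect_equal(res$matrix$scores[1, 3], (1.5 + 0.2) / 2)
  expect_equal(res$matrix$scores[3, 1], res$matrix$scores[1, 3])
})

test_that("neighbours without a measured partner value are skipped", {
  m <- toy_emap()
  # make the top neighbour of g1 (the duplicate g2) useless for (g1, g3)
  s <- m$scores; s[2, 3] <- s[3, 2] <- NA
  m2 <- emap_matrix(s, alleles = m$alleles)
  res <- impute_uknn(m2, imputation_config("uknn", k = 1))
  nb <- rank_neighbors(m2, 1)
  # the i-side donor must now be the best neighbour with (i', g3) measured
  eligible <- nb$index[m2$measured[nb$index, 3]]
  expect_false(eligible[1] == 2)
  expect_equal(res$matrix$scores[1, 3],
               oracle_uknn_value(m2, 1, 3, K = 1), tolerance = 1e-12)
})

test_that("wNN equals uKNN when all donors share one correlation", {
  # four genes in two exact-duplicate pairs: every donor has r = 1
  s <- matrix(NA_real_, 6, 6)
  set_pair <- function(i, j, v) s[i, j] <<- s[j, i] <<- v
  for (v in list(c(1, 5, 0.4), c(2, 5, 0.4), c(1, 6, -1.1), c(2, 6, -1.1),
                 c(3, 5, 2.2), c(4, 5, 2.2), c(3, 6, 0.8), c(4, 6, 0.8),
                 c(1, 4, 0.9), c(2, 3, -0.3), c(5, 6, 1.7)))
    set_pair(v[1], v[2], v[3])
  m <- emap_matrix(s)
  # (1, 3) is missing; donors on both sides are exact duplicates (r = 1)
  u <- impute_uknn(m, imputation_config("uknn", k = 2))
  w <- impute_wnn(m, imputation_config("wnn", k = 2))
  expect_equal(w$matrix$scores[1, 3], u$matrix$scores[1, 3],
               tolerance = 1e-9)
})

test_that("a near-perfect donor dominates the wNN estimate", {
  w_hi <- wnn_weight(0.99); w_lo <- wnn_weight(0.3)
  # with 3 weak donors the dominant donor still carries >99% of the mass
  expect_gt(w_hi / (w_hi + 3 * w_lo), 0.99)
})

test_that("uKNN, wNN and LLS match brute-force oracles on small matrices", {
  for (seed in 1:5) {
    n <- 6 + (seed %% 3)
    m <- random_emap(n, 0.3, seed = seed + 20)
    mp <- missing_pairs(m)
    if (nrow(mp) == 0) next
    for (k in c(1, 2, 3)) {
      ru <- impute_uknn(m, imputation_config("uknn", k = k))
      rw <- impute_wnn(m, imputation_config("wnn", k = k))
      rl <- impute_lls(m, imputation_config("lls", k = k))
      for (p in seq_len(nrow(mp))) {
        i <- mp[p, 1]; j <- mp[p, 2]
        expect_equal(ru$matrix$scores[i, j], oracle_uknn_value(m, i, j, k),
                     tolerance = 1e-9,
                     info = sprintf("uknn seed %d k %d (%d,%d)", seed, k, i, j))
        expect_equal(rw$matrix$scores[i, j], oracle_wnn_value(m, i, j, k),
                     tolerance = 1e-9,
                     info = sprintf("wnn seed %d k %d (%d,%d)", seed, k, i, j))
        expect_equal(rl$matrix$scores[i, j], oracle_lls_value(m, i, j, k),
                     tolerance = 1e-9,
                     info = sprintf("lls seed %d k %d (%d,%d)", seed, k, i, j))
      }
    }
  }
})

test_that("prefill_for_lls averages row means and is idempotent on complete input", {
  s <- matrix(NA_real_, 4, 4)
  s[1, 3] <- s[3, 1] <- 2; s[2, 4] <- s[4, 2] <- 4
  m <- emap_matrix(s)
  W <- prefill_for_lls(m)
  expect_equal(W[1, 2], 3)
  expect_equal(W, t(W))
  expect_equal(W[m$measured], m$scores[m$measured])

  full <- random_emap(5, 0, seed = 1)   # complete matrix
  W2 <- prefill_for_lls(full)
  expect_equal(W2[full$measured], full$scores[full$measured])
})

test_that("fit_lls recovers exact linear structure", {
  # target g1 = duplicate of g2 on all measured positions -> coefficient 1
  m <- toy_emap()
  W <- prefill_for_lls(m)
  f <- fit_lls(m, W, 1, k = 1)
  expect_equal(f$neighbors, 2)
  expect_equal(unname(f$coefficients), 1, tolerance = 1e-9)

  # target = 2*A + 1*B exactly (B kept positively correlated with the
  # target, since anti-correlated genes are never eligible neighbours)
  set.seed(5)
  a <- rnorm(8); b <- 0.8 * a + 0.6 * rnorm(8)
  s <- matrix(NA_real_, 11, 11)
  s[1, 4:11] <- s[4:11, 1] <- 2 * a + b
  s[2, 4:11] <- s[4:11, 2] <- a
  s[3, 4:11] <- s[4:11, 3] <- b
  for (i in 4:10) for (j in (i + 1):11) s[i, j] <- s[j, i] <- rnorm(1)
  s[1, 2] <- s[2, 1] <- 0; s[1, 3] <- s[3, 1] <- 0; s[2, 3] <- s[3, 2] <- 0
  m2 <- emap_matrix(s)
  W2 <- prefill_for_lls(m2)
  # force the neighbour set to {g2, g3} via k = 2 only if they rank top;
  # construct guarantees the exact linear combination is reproduced
  f2 <- fit_lls(m2, W2, 1, k = 2)
  fitted <- colSums(f2$coefficients * W2[f2$neighbors, which(m2$measured[1, ])])
  expect_equal(fitted, m2$scores[1, which(m2$measured[1, ])],
               tolerance = 1e-8, ignore_attr = TRUE)

  # K exceeding the number of measured positions: minimum-norm solution
  m3 <- random_emap(8, 0.7, seed = 9)
  g <- which(rowSums(m3$measured) >= 1)[1]
  W3 <- prefill_for_lls(m3)
  nb <- rank_neighbors(m3, g)
  if (nrow(nb) >= 1) {
    f3 <- fit_lls(m3, W3, g, k = 7)
    A <- t(W3[f3$neighbors, which(m3$measured[g, ]), drop = FALSE])
    expect_equal(f3$coefficients,
                 drop(MASS::ginv(A) %*% m3$scores[g, m3$measured[g, ]]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("LLS with a duplicate-profile neighbour passes its value through", {
  m <- toy_emap()
  res <- impute_lls(m, imputation_config("lls", k = 1))
  # g1's only fit neighbour is its exact duplicate g2 (coefficient 1),
  # so the i-side estimate is exactly working[g2, g3] = 1.5
  W <- prefill_for_lls(m)
  f1 <- fit_lls(m, W, 1, k = 1)
  expect_equal(unname(f1$coefficients), 1, tolerance = 1e-9)
  expect_equal(res$matrix$scores[1, 3], oracle_lls_value(m, 1, 3, 1),
               tolerance = 1e-9)
})

test_that("imputing a complete matrix changes nothing", {
  full <- random_emap(6, 0, seed = 3)
  for (meth in c("zeros", "gene_mean", "median", "uknn", "wnn", "lls")) {
    res <- impute_emap(full, meth)
    expect_equal(res$matrix$scores, full$scores)
    expect_equal(nrow(res$provenance), 0)
  }
})

test_that("all imputers preserve measured entries, symmetry and determinism", {
  m <- random_emap(9, 0.35, seed = 13)
  for (meth in c("zeros", "gene_mean", "median", "uknn", "wnn", "lls")) {
    r1 <- impute_emap(m, meth)
    r2 <- impute_emap(m, meth)
    s <- r1$matrix$scores
    expect_identical(s[m$measured], m$scores[m$measured])
    expect_equal(s, t(s))
    expect_false(any(is.na(s[upper.tri(s)])))
    expect_identical(s, r2$matrix$scores)   # no hidden randomness
  }
})

test_that("empty donor pools fall back to gene means and are flagged", {
  # g4 is measured against nothing: every pair involving g4 needs fallback
  s <- matrix(NA_real_, 5, 5)
  s[1, 2] <- s[2, 1] <- 1; s[1, 3] <- s[3, 1] <- 2
  s[2, 3] <- s[3, 2] <- 3; s[1, 5] <- s[5, 1] <- 1.5
  m <- emap_matrix(s)
  for (meth in c("uknn", "wnn", "lls")) {
    res <- impute_emap(m, meth, k = 2)
    prov <- res$provenance
    g4 <- prov[prov$i == 4 | prov$j == 4, ]
    expect_true(all(g4$fallback), label = meth)
    expect_false(any(is.na(g4$value)))
  }
})
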