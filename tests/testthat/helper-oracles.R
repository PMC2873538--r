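# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (per-pair loops, stats::cor, MASS::ginv) so they
# share no code path with the package implementation.

# small symmetric matrix with controlled missingness
random_emap <- function(n, miss_frac = 0.3, seed = 1, scale = 2) {
  set.seed(seed)
  s <- matrix(stats::rnorm(n * n, sd = scale), n, n)
  s <- (s + t(s)) / 2
  keep <- matrix(TRUE, n, n)
  up <- which(upper.tri(keep), arr.ind = TRUE)
  drop <- up[stats::runif(nrow(up)) < miss_frac, , drop = FALSE]
  keep[drop] <- FALSE
  keep[drop[, c(2, 1), drop = FALSE]] <- FALSE
  diag(keep) <- FALSE
  s[!keep] <- NA_real_
  emap_matrix(s, alleles = sprintf("a%02d", seq_len(n)))
}

oracle_pearson <- function(a, b, min_overlap = 3) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_overlap) return(NA_real_)
  if (length(unique(a[ok])) == 1 || length(unique(b[ok])) == 1)
    return(NA_real_)
  stats::cor(a[ok], b[ok])
}

oracle_rank <- function(m, g, min_overlap = 3) {
  n <- length(m$alleles)
  r <- vapply(seq_len(n), function(k) {
    if (k == g) return(NA_real_)
    oracle_pearson(m$scores[g, ], m$scores[k, ], min_overlap)
  }, numeric(1))
  keep <- which(!is.na(r) & r > 0)
  keep[order(-r[keep], m$alleles[keep])]
}

oracle_rank_r <- function(m, g, min_overlap = 3) {
  idx <- oracle_rank(m, g, min_overlap)
  r <- vapply(idx, function(k)
    oracle_pearson(m$scores[g, ], m$scores[k, ], min_overlap), numeric(1))
  list(idx = idx, r = r)
}

oracle_row_mean <- function(m, g) {
  v <- m$scores[g, ][m$measured[g, ]]
  if (length(v) == 0) NA_real_ else mean(v)
}

oracle_gene_mean_value <- function(m, i, j) {
  rm_ <- vapply(seq_along(m$alleles), function(g) oracle_row_mean(m, g),
                numeric(1))
  ov <- mean(m$scores[m$measured])
  if (is.na(ov) || is.nan(ov)) ov <- 0
  rm_[is.na(rm_)] <- ov
  (rm_[i] + rm_[j]) / 2
}

# donors on one side: gene's ranked neighbours with a measured partner
oracle_donors <- function(m, gene, partner, K, min_overlap = 3) {
  rk <- oracle_rank_r(m, gene, min_overlap)
  keep <- m$measured[rk$idx, partner]
  idx <- rk$idx[keep]; r <- rk$r[keep]
  take <- seq_len(min(K, length(idx)))
  list(idx = idx[take], r = r[take])
}

oracle_uknn_value <- function(m, i, j, K, min_overlap = 3) {
  di <- oracle_donors(m, i, j, K, min_overlap)
  dj <- oracle_donors(m, j, i, K, min_overlap)
  vals <- c(m$scores[di$idx, j], m$scores[dj$idx, i])
  if (length(vals) == 0) return(oracle_gene_mean_value(m, i, j))
  mean(vals)
}

oracle_wnn_value <- function(m, i, j, K, eps = 1e-6, min_overlap = 3) {
  di <- oracle_donors(m, i, j, K, min_overlap)
  dj <- oracle_donors(m, j, i, K, min_overlap)
  vals <- c(m$scores[di$idx, j], m$scores[dj$idx, i])
  if (length(vals) == 0) return(oracle_gene_mean_value(m, i, j))
  w <- (c(di$r, dj$r)^2 / (1 - c(di$r, dj$r)^2 + eps))^2
  sum(w / sum(w) * vals)
}

oracle_prefill <- function(m) {
  n <- length(m$alleles)
  rm_ <- vapply(seq_len(n), function(g) oracle_row_mean(m, g), numeric(1))
  ov <- mean(m$scores[m$measured]); if (is.na(ov)) ov <- 0
  rm_[is.na(rm_)] <- ov
  W <- m$scores
  for (i in seq_len(n)) for (j in seq_len(n))
    if (!m$measured[i, j]) W[i, j] <- (rm_[i] + rm_[j]) / 2
  diag(W) <- 0
  W
}

oracle_lls_side <- function(m, W, gene, partner, K, min_overlap = 3) {
  nb <- oracle_rank(m, gene, min_overlap)
  if (length(nb) == 0) return(NA_real_)
  nb <- nb[seq_len(min(K, length(nb)))]
  pos <- which(m$measured[gene, ])
  if (length(pos) == 0) return(NA_real_)
  A <- t(W[nb, pos, drop = FALSE])
  x <- MASS::ginv(A) %*% m$scores[gene, pos]
  sum(x * W[nb, partner])
}

oracle_lls_value <- function(m, i, j, K, min_overlap = 3) {
  W <- oracle_prefill(m)
  est <- c(oracle_lls_side(m, W, i, j, K, min_overlap),
           oracle_lls_side(m, W, j, i, K, min_overlap))
  gm <- oracle_gene_mean_value(m, i, j)
  if (all(is.na(est))) return(gm)
  est[is.na(est)] <- gm
  mean(est)
}

# one-sided (greater) Fisher p for table rbind(c(a, b), c(c, d)),
# rows = class / background, cols = share / no-share
oracle_fisher_greater <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + c_          # sharers in population
  n1 <- a + b          # class size
  kk <- a:min(n1, K)
  sum(stats::dhyper(kk, K, N - K, n1))
}

# tiny deterministic matrix used across tests: 6 genes, g1/g2 duplicate
# profiles over g4..g6, pair (g1, g3) missing
toy_emap <- function() {
  s <- matrix(NA_real_, 6, 6)
  set_pair <- function(i, j, v) s[i, j] <<- s[j, i] <<- v
  set_pair(1, 2, 0.2)
  set_pair(1, 4, 1.0);  set_pair(1, 5, -2.0); set_pair(1, 6, 0.5)
  set_pair(2, 4, 1.0);  set_pair(2, 5, -2.0); set_pair(2, 6, 0.5)
  set_pair(2, 3, 1.5)                      # (1, 3) left missing
  set_pair(3, 4, 0.7);  set_pair(3, 5, -1.2); set_pair(3, 6, 2.1)
  set_pair(4, 5, 0.3);  set_pair(4, 6, -0.4); set_pair(5, 6, 0.9)
  emap_matrix(s, alleles = paste0("g", 1:6))
}
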