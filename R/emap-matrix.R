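#' Construct an E-MAP interaction matrix
#'
#' An `emap_matrix` holds a symmetric gene-by-gene matrix of quantitative
#' genetic-interaction scores (S-scores) together with a boolean mask of
#' which entries were actually measured. Self-interactions are not data:
#' the diagonal is always flagged unmeasured and its scores set to `NA`.
#'
#' @param scores numeric n x n matrix of interaction scores. Row and column
#'   names, when present, must agree and become the allele identifiers.
#'   Unmeasured entries may be `NA`.
#' @param measured logical n x n mask, `TRUE` where the score was measured.
#'   Defaults to `!is.na(scores)`.
#' @param alleles character vector of unique allele identifiers; defaults
#'   to `rownames(scores)` or `g1..gn`.
#' @return an object of class `emap_matrix` with elements `alleles`,
#'   `scores` (unmeasured entries `NA`) and `measured`.
#' @examples
#' s <- matrix(c(NA, 1, 2, 1, NA, -1, 2, -1, NA), 3, 3)
#' m <- emap_matrix(s, alleles = c("a", "b", "c"))
#' n_measured_pairs(m)
#' @export
emap_matrix <- function(scores, measured = NULL, alleles = NULL) {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores))
    stop("`scores` must be a square matrix")
  n <- nrow(scores)
  if (n < 2) stop("an E-MAP needs at least 2 alleles")
  storage.mode(scores) <- "double"
  if (is.null(alleles)) alleles <- rownames(scores)
  if (is.null(alleles)) alleles <- paste0("g", seq_len(n))
  alleles <- as.character(alleles)
  if (length(alleles) != n) stop("length(alleles) must equal nrow(scores)")
  if (anyDuplicated(alleles)) stop("allele identifiers must be unique")
  if (is.null(measured)) measured <- !is.na(scores)
  if (!is.matrix(measured) || !identical(dim(measured), dim(scores)))
    stop("`measured` must be a logical matrix with the same dimensions as `scores`")
  measured <- measured & !is.na(scores)
  diag(measured) <- FALSE
  if (!isTRUE(all(measured == t(measured))))
    stop("`measured` mask must be symmetric")
  scores[!measured] <- NA_real_
  asym <- which(measured & abs(scores - t(scores)) > 1e-8, arr.ind = TRUE)
  if (nrow(asym) > 0)
    stop(sprintf("scores are not symmetric at measured entry (%s, %s)",
                 alleles[asym[1, 1]], alleles[asym[1, 2]]))
  dimnames(scores) <- dimnames(measured) <- list(alleles, alleles)
  structure(list(alleles = alleles, scores = scores, measured = measured),
            class = "emap_matrix")
}

#' @export
print.emap_matrix <- function(x, ...) {
  n <- length(x$alleles)
  np <- n * (n - 1) / 2
  nm <- n_measured_pairs(x)
  cat(sprintf("E-MAP matrix: %d alleles, %d/%d unordered pairs measured (%.1f%% missing)\n",
              n, nm, np, 100 * (1 - nm / np)))
  invisible(x)
}

#' @export
dim.emap_matrix <- function(x) dim(x$scores)

#' Number of measured unordered off-diagonal pairs
#' @param m an `emap_matrix`
#' @return integer count
#' @export
n_measured_pairs <- function(m) {
  stopifnot(inherits(m, "emap_matrix"))
  sum(m$measured[upper.tri(m$measured)])
}

#' Missing unordered pairs of an E-MAP
#'
#' @param m an `emap_matrix`
#' @return two-column integer matrix of (i, j) indices with i < j for every
#'   unmeasured off-diagonal unordered pair.
#' @export
missing_pairs <- function(m) {
  stopifnot(inherits(m, "emap_matrix"))
  idx <- which(upper.tri(m$measured) & !m$measured, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Measured unordered pairs of an E-MAP
#' @param m an `emap_matrix`
#' @return two-column integer matrix (i < j) of measured pairs
#' @export
measured_pairs <- function(m) {
  stopifnot(inherits(m, "emap_matrix"))
  idx <- which(upper.tri(m$measured) & m$measured, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Imputation configuration
#'
#' Bundles the tuning parameters shared by the neighbour-based imputers.
#'
#' @param method one of `"zeros"`, `"gene_mean"`, `"median"`, `"uknn"`,
#'   `"wnn"`, `"lls"`.
#' @param k neighbour count. Defaults follow the recommended values per
#'   method (uKNN 5, wNN 50, LLS 20) when `NA`.
#' @param eps small positive constant in the wNN weight denominator,
#'   guarding against division by zero at `r = 1`.
#' @param min_overlap minimum number of jointly measured profile positions
#'   for a Pearson correlation to be considered defined. Must be >= 2;
#'   the default 3 is the smallest overlap at which r is not forced to +/-1.
#' @param normalize how wNN normalizes donor weights: `"joint"` pools the
#'   two symmetric donor sides before normalizing to one; `"per_side"`
#'   normalizes each side then averages the two sides.
#' @param seed integer seed recorded for provenance (the imputers
#'   themselves are deterministic).
#' @return a list of class `imputation_config`
#' @export
imputation_config <- function(method = c("wnn", "uknn", "lls", "zeros",
                                         "gene_mean", "median"),
                              k = NA_integer_, eps = 1e-6, min_overlap = 3L,
                              normalize = c("joint", "per_side"),
                              seed = NA_integer_) {
  method <- match.arg(method)
  normalize <- match.arg(normalize)
  if (is.na(k)) k <- switch(method, uknn = 5L, wnn = 50L, lls = 20L, 1L)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0")
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 2) stop("min_overlap must be >= 2")
  structure(list(method = method, k = k, eps = eps,
                 min_overlap = min_overlap, normalize = normalize,
                 seed = seed),
            class = "imputation_config")
}

#' Pearson correlation between two profiles with gaps
#'
#' Computes the correlation over positions where both profiles are
#' observed (pairwise-complete). Returns `NA` ("undefined") when fewer
#' than `min_overlap` joint positions exist or either restricted profile
#' has zero variance.
#'
#' @param a,b numeric vectors of equal length; `NA` marks a gap
#' @param min_overlap minimum joint observations required
#' @return correlation in \[-1, 1\], or `NA` when undefined
#' @export
pairwise_pearson <- function(a, b, min_overlap = 3L) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_overlap) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Rank candidate neighbours of a gene by profile correlation
#'
#' Correlations are computed on measured values only (pairwise-complete),
#' never on imputed values, so neighbour identity does not depend on
#' imputation order. Genes with undefined or non-positive correlation are
#' ineligible: anti-correlated donors would contribute wrong-signed values
#' under squared-correlation weighting, and similarity ranking never makes
#' them "nearest". Ties in r are broken lexicographically by allele name.
#'
#' @param m an `emap_matrix`
#' @param gene integer index or allele name of the query gene
#' @param config an [imputation_config()] (uses `min_overlap`)
#' @return data.frame with columns `index`, `allele`, `r`, `overlap`,
#'   ordered by decreasing r; zero rows when no gene qualifies.
#' @export
rank_neighbors <- function(m, gene, config = imputation_config()) {
  stopifnot(inherits(m, "emap_matrix"))
  gene <- .resolve_gene(m, gene)
  n <- length(m$alleles)
  r <- numeric(n); ov <- integer(n)
  for (g in seq_len(n)) {
    if (g == gene) { r[g] <- NA_real_; next }
    ok <- m$measured[gene, ] & m$measured[g, ]
    ov[g] <- sum(ok)
    r[g] <- pairwise_pearson(m$scores[gene, ], m$scores[g, ],
                             config$min_overlap)
  }
  keep <- which(!is.na(r) & r > 0)
  keep <- keep[order(-r[keep], m$alleles[keep])]
  data.frame(index = keep, allele = m$alleles[keep], r = r[keep],
             overlap = ov[keep], stringsAsFactors = FALSE)
}

#' Mean measured interaction score of a gene
#'
#' Arithmetic mean of the gene's measured off-diagonal entries; `NA` when
#' the gene has no measured interactions.
#'
#' @param m an `emap_matrix`
#' @param gene integer index or allele name
#' @return numeric scalar or `NA`
#' @export
row_mean <- function(m, gene) {
  stopifnot(inherits(m, "emap_matrix"))
  gene <- .resolve_gene(m, gene)
  v <- m$scores[gene, m$measured[gene, ]]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Symmetrize an asymmetric prediction matrix
#'
#' Averages the (i, j) and (j, i) predictions of an imputer that treats
#' rows and columns asymmetrically, yielding a single score per unordered
#' pair. Idempotent on symmetric input.
#'
#' @param asym square numeric matrix
#' @return symmetric matrix of the same dimension
#' @export
symmetrize_predictions <- function(asym) {
  if (!is.matrix(asym) || nrow(asym) != ncol(asym))
    stop("input must be a square matrix")
  (asym + t(asym)) / 2
}

.resolve_gene <- function(m, gene) {
  if (is.character(gene)) {
    i <- match(gene, m$alleles)
    if (is.na(i)) stop(sprintf("unknown allele '%s'", gene))
    return(i)
  }
  gene <- as.integer(gene)
  if (gene < 1 || gene > length(m$alleles)) stop("gene index out of range")
  gene
}

# Full pairwise-complete correlation and overlap tables, plus per-gene
# neighbour rankings (indices ordered by decreasing r, name-lexicographic
# ties, r > 0 only). Shared workhorse for the neighbour-based imputers.
.neighbor_tables <- function(m, config) {
  S <- m$scores
  O <- tcrossprod(m$measured * 1)
  C <- .pairwise_cor_matrix(S, m$measured, O)
  C[O < config$min_overlap] <- NA_real_
  diag(C) <- NA_real_
  n <- nrow(S)
  ranked <- vector("list", n)
  for (g in seq_len(n)) {
    r <- C[g, ]
    keep <- which(!is.na(r) & r > 0)
    ranked[[g]] <- keep[order(-r[keep], m$alleles[keep])]
  }
  list(C = C, O = O, ranked = ranked)
}

# All-pairs pairwise-complete Pearson correlation between the rows of S
# (NA = unobserved), via crossproducts on zero-filled copies. O is the
# joint-observation count matrix. Zero-variance restrictions give NA.
.pairwise_cor_matrix <- function(S, measured, O) {
  X <- S
  X[!measured] <- 0
  M <- measured * 1
  sx <- X %*% t(M)          # sum of row i over joint support with j
  s2 <- (X * X) %*% t(M)    # sum of squares likewise
  sxy <- X %*% t(X)
  num <- O * sxy - sx * t(sx)
  varx <- O * s2 - sx^2               # n^2 * variance over joint support
  degenerate <- varx <= 1e-10 * pmax(O * s2, 1)   # zero-variance guard
  den2 <- varx * t(varx)
  C <- num / sqrt(pmax(den2, .Machine$double.xmin))
  C[degenerate | t(degenerate)] <- NA_real_
  pmin(pmax(C, -1), 1)
}

# Row means with explicit fallback chain: gene mean -> overall measured
# mean -> 0. Returns list(value = numeric vector, fallback = logical).
.row_means_filled <- function(m) {
  rm_ <- vapply(seq_along(m$alleles), function(g) row_mean(m, g), numeric(1))
  overall <- mean(m$scores[m$measured])
  if (is.nan(overall) || is.na(overall)) overall <- 0
  fb <- is.na(rm_)
  rm_[fb] <- overall
  list(value = rm_, fallback = fb)
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring
# the caller's .Random.seed afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
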