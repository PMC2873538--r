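#' Specification for a synthetic E-MAP
#'
#' Describes a module-structured symmetric interaction matrix: genes are
#' partitioned into modules (emulating protein complexes/pathways, whose
#' members share interaction profiles), every unordered module pair --
#' including a module with itself -- carries a latent mean score that is
#' 0 for most pairs and strongly positive/negative for a planted
#' minority, and each gene-pair score is its module-pair mean plus
#' Gaussian noise. Missingness combines the three E-MAP categories:
#' all DAmP-DAmP pairs, all flagged chromosomal-neighbour pairs, and
#' random "other" dropout up to the target fraction.
#'
#' Default rates keep the strong classes below 10% of pairs (strong
#' genetic interactions are rare events) while leaving enough
#' signal variance for neighbour-based imputers to exploit.
#'
#' @param n_genes number of alleles (default 400)
#' @param n_modules number of modules (default 20)
#' @param within_mean,within_sd baseline latent mean and noise sd for
#'   same-module pairs (defaults 0 and 1)
#' @param between_mean,between_sd baseline latent mean and noise sd for
#'   different-module pairs (defaults 0 and 1)
#' @param alleviating_rate,aggravating_rate probability that a pair of
#'   distinct modules is planted strongly alleviating / aggravating
#'   (defaults 0.025 and 0.035)
#' @param within_alleviating_rate,within_aggravating_rate probability
#'   that a module's own internal block is planted strongly alleviating
#'   / aggravating (defaults 0.2 and 0.3): strong epistasis concentrates
#'   within complexes and pathways, which is what makes imputed strong
#'   pairs enriched for shared annotations
#' @param alleviating_value,aggravating_value planted latent means
#'   (defaults +3.2 and -4.0, clearing the 2.0 / -2.5 class thresholds)
#' @param missing_fraction target fraction of unordered pairs missing
#'   (default 0.2; published E-MAPs run 7-35%)
#' @param damp_fraction fraction of genes carrying DAmP alleles
#'   (default 0.1)
#' @param neighbor_pair_fraction fraction of unordered pairs flagged as
#'   chromosomal neighbours (default 0.002)
#' @param seed integer seed
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_genes = 400L, n_modules = 20L,
                           within_mean = 0, within_sd = 1,
                           between_mean = 0, between_sd = 1,
                           alleviating_rate = 0.025,
                           aggravating_rate = 0.035,
                           within_alleviating_rate = 0.2,
                           within_aggravating_rate = 0.3,
                           alleviating_value = 3.2,
                           aggravating_value = -4.0,
                           missing_fraction = 0.2,
                           damp_fraction = 0.1,
                           neighbor_pair_fraction = 0.002,
                           seed = 1L) {
  stopifnot(n_modules <= n_genes, n_genes >= 2,
            within_sd >= 0, between_sd >= 0,
            alleviating_rate >= 0, aggravating_rate >= 0,
            alleviating_rate + aggravating_rate <= 1,
            within_alleviating_rate >= 0, within_aggravating_rate >= 0,
            within_alleviating_rate + within_aggravating_rate <= 1,
            missing_fraction > 0, missing_fraction < 1,
            damp_fraction >= 0, damp_fraction <= 1,
            neighbor_pair_fraction >= 0, neighbor_pair_fraction <= 1,
            alleviating_value > 0, aggravating_value < 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic E-MAP with ground truth
#'
#' Draws a matrix according to a [synthetic_spec()]: module-pair latent
#' means with planted strong interactions, symmetric Gaussian noise,
#' structured missingness (DAmP-DAmP pairs and chromosomal neighbours are
#' entirely missing; random "other" dropout fills up to the target
#' fraction) and allele metadata whose coordinates place exactly the
#' flagged neighbour pairs within the 50 kb window. Measured scores are
#' centred so their mean is 0, matching the near-zero mean of normalized
#' interaction scores. Deterministic per seed.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `matrix` (the incomplete [emap_matrix()]), `truth`
#'   (complete symmetric score matrix, diagonal `NA`), `meta` (allele
#'   metadata data.frame), `modules` (named module assignment) and `spec`
#' @export
generate_emap <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, .generate_emap_impl(spec))
}

.generate_emap_impl <- function(spec) {
  n <- spec$n_genes
  nm <- spec$n_modules
  alleles <- sprintf("g%03d", seq_len(n))
  modules <- sort(rep_len(seq_len(nm), n))
  names(modules) <- alleles

  # latent module-pair means, planted strong interactions included
  L <- matrix(spec$between_mean, nm, nm)
  diag(L) <- spec$within_mean
  for (a in seq_len(nm)) for (b in a:nm) {
    u <- stats::runif(1)
    p_al <- if (a == b) spec$within_alleviating_rate else spec$alleviating_rate
    p_ag <- if (a == b) spec$within_aggravating_rate else spec$aggravating_rate
    if (u < p_al) L[a, b] <- L[b, a] <- spec$alleviating_value
    else if (u < p_al + p_ag) L[a, b] <- L[b, a] <- spec$aggravating_value
  }

  same_mod <- outer(modules, modules, `==`)
  truth <- L[cbind(rep(modules, n), rep(modules, each = n))]
  dim(truth) <- c(n, n)
  noise_sd <- ifelse(same_mod, spec$within_sd, spec$between_sd)
  up <- upper.tri(truth)
  noise <- stats::rnorm(sum(up), 0, noise_sd[up])
  truth[up] <- truth[up] + noise
  truth[lower.tri(truth)] <- t(truth)[lower.tri(truth)]
  diag(truth) <- NA_real_
  dimnames(truth) <- list(alleles, alleles)

  # allele metadata: contiguous chromosome blocks, genes spaced far
  # apart except the planted neighbour pairs
  n_chr <- min(16L, n)
  chr_of <- sort(rep_len(seq_len(n_chr), n))
  pos_in_chr <- stats::ave(seq_len(n), chr_of, FUN = seq_along)
  gene_len <- 1500
  spacing <- 150000
  start <- 1 + (pos_in_chr - 1) * spacing
  end <- start + gene_len - 1

  damp <- rep(FALSE, n)
  n_damp <- round(spec$damp_fraction * n)
  if (n_damp > 0) damp[sample.int(n, n_damp)] <- TRUE

  # neighbour pairs: disjoint same-chromosome adjacent gene pairs (at
  # most one DAmP allele, so categories stay unambiguous), second gene
  # relocated to within 10 kb of the first
  n_pairs_total <- n * (n - 1) / 2
  n_nb <- round(spec$neighbor_pair_fraction * n_pairs_total)
  cand <- which(seq_len(n) %% 2 == 1 & c(chr_of[-n] == chr_of[-1], FALSE) &
                  !(damp & c(damp[-1], TRUE)))
  if (n_nb > length(cand))
    stop("neighbor_pair_fraction infeasible for this gene layout")
  nb_first <- sort(sample(cand, n_nb))
  nb_pairs <- cbind(nb_first, nb_first + 1L)
  if (n_nb > 0) {
    start[nb_pairs[, 2]] <- end[nb_pairs[, 1]] + 10000
    end[nb_pairs[, 2]] <- start[nb_pairs[, 2]] + gene_len - 1
  }

  meta <- data.frame(allele = alleles, gene = toupper(alleles),
                     chromosome = paste0("chr", chr_of),
                     start = start, end = end,
                     perturbation = ifelse(damp, "damp", "deletion"),
                     stringsAsFactors = FALSE)
  rownames(meta) <- alleles

  # structured + random missingness
  up_idx <- which(up, arr.ind = TRUE)
  key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  damp_idx <- which(damp)
  struct_keys <- c(
    if (length(damp_idx) >= 2)
      key(rep(damp_idx, length(damp_idx)),
          rep(damp_idx, each = length(damp_idx)))[
            rep(damp_idx, length(damp_idx)) <
              rep(damp_idx, each = length(damp_idx))],
    if (n_nb > 0) key(nb_pairs[, 1], nb_pairs[, 2]))
  struct_keys <- unique(struct_keys)
  all_keys <- key(up_idx[, 1], up_idx[, 2])
  n_missing <- round(spec$missing_fraction * n_pairs_total)
  if (n_missing < length(struct_keys))
    stop(sprintf(
      "missing_fraction %.3f below structural minimum %.3f (DAmP-DAmP + neighbour pairs)",
      spec$missing_fraction, length(struct_keys) / n_pairs_total))
  pool <- setdiff(all_keys, struct_keys)
  other_keys <- sample(pool, n_missing - length(struct_keys))
  miss <- all_keys %in% c(struct_keys, other_keys)

  measured <- matrix(FALSE, n, n)
  sel <- up_idx[!miss, , drop = FALSE]
  measured[sel] <- TRUE
  measured[sel[, c(2, 1), drop = FALSE]] <- TRUE

  # centre so the measured-score mean is 0
  centre <- mean(truth[measured])
  truth <- truth - centre
  scores <- truth
  scores[!measured] <- NA_real_
  diag(scores) <- NA_real_

  list(matrix = emap_matrix(scores, measured, alleles = alleles),
       truth = truth, meta = meta, modules = modules, spec = spec)
}

#' Generate module-aligned annotations
#'
#' Each module spawns `terms_per_module` terms annotating its members,
#' so that (at `noise = 0`) two genes share a term exactly when they
#' belong to the same module. A `noise` fraction of genes additionally
#' receives one random term from another module.
#'
#' @param modules named module assignment (from [generate_emap()])
#' @param terms_per_module terms spawned per module (default 1)
#' @param noise fraction of genes given a random extra term (default 0)
#' @param seed integer seed
#' @param source label for the resulting map
#' @return an `annotation_map`
#' @export
generate_annotations <- function(modules, terms_per_module = 1L,
                                 noise = 0, seed = 1L,
                                 source = "synthetic_modules") {
  stopifnot(noise >= 0, noise <= 1, terms_per_module >= 0)
  genes <- names(modules)
  if (terms_per_module == 0)
    return(annotation_map(character(0), character(0), source = source))
  g <- rep(genes, terms_per_module)
  t_ <- as.vector(vapply(seq_len(terms_per_module), function(k)
    sprintf("M%02d_T%d", modules, k), character(length(modules))))
  if (noise > 0) {
    extra <- .with_seed(seed, {
      pick <- which(stats::runif(length(genes)) < noise)
      if (length(pick) > 0) {
        other_mod <- vapply(modules[pick], function(mq) {
          opts <- setdiff(unique(modules), mq)
          if (length(opts) == 0) mq else sample(opts, 1)
        }, numeric(1))
        list(g = genes[pick], t = sprintf("M%02d_T1", other_mod))
      } else list(g = character(0), t = character(0))
    })
    g <- c(g, extra$g); t_ <- c(t_, extra$t)
  }
  annotation_map(g, t_, source = source,
                 max_term_size = max(1000L, length(genes)))
}
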