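#' Fraction of gene pairs sharing an annotation
#'
#' A pair "shares" when the two genes' retained term sets intersect;
#' pairs involving an unannotated gene count as non-sharing.
#'
#' @param pairs two-column character matrix or data.frame of gene pairs
#' @param annotations an `annotation_map` (see [read_annotations()])
#' @return list with `fraction`, `n_share`, `n_pairs`
#' @export
shared_annotation_fraction <- function(pairs, annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop("empty pair list")
  g2t <- annotations$gene2terms
  share <- vapply(seq_len(nrow(pairs)), function(p) {
    ta <- g2t[[pairs[p, 1]]]; tb <- g2t[[pairs[p, 2]]]
    !is.null(ta) && !is.null(tb) && length(intersect(ta, tb)) > 0
  }, logical(1))
  list(fraction = mean(share), n_share = sum(share), n_pairs = nrow(pairs))
}

#' Test a class of gene pairs for annotation-sharing enrichment
#'
#' Builds the 2x2 table (class vs background) x (share vs not-share) and
#' applies a one-sided Fisher's exact test of whether class pairs share
#' annotations more often than background pairs. A degenerate table (a
#' zero margin) reports p = 1 with a warning.
#'
#' @param class_pairs,background_pairs two-column gene-pair matrices
#' @param annotations an `annotation_map`
#' @param alpha significance level (default 0.01)
#' @param class_label,category labels carried into the result
#' @return an `enrichment_result`: list with the two sharing fractions,
#'   the 2x2 `counts`, `odds_ratio`, `p_value` and `significant`
#' @export
enrichment_test <- function(class_pairs, background_pairs, annotations,
                            alpha = 0.01, class_label = "class",
                            category = "all") {
  cs <- shared_annotation_fraction(class_pairs, annotations)
  bs <- shared_annotation_fraction(background_pairs, annotations)
  tab <- matrix(c(cs$n_share, cs$n_pairs - cs$n_share,
                  bs$n_share, bs$n_pairs - bs$n_share),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("class", "background"),
                                c("share", "no_share")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    p <- 1; or <- NA_real_
  } else {
    ft <- stats::fisher.test(tab, alternative = "greater")
    p <- ft$p.value; or <- unname(ft$estimate)
  }
  structure(list(class = class_label, category = category,
                 n_pairs = cs$n_pairs, frac_shared = cs$fraction,
                 frac_background = bs$fraction, counts = tab,
                 odds_ratio = or, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s [%s]: %d pairs, %.1f%% share vs %.1f%% background, p = %.3g%s\n",
              x$class, x$category, x$n_pairs, 100 * x$frac_shared,
              100 * x$frac_background, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Annotation enrichment of imputed interaction classes
#'
#' Classifies every imputed pair into alleviating/neutral/aggravating and
#' tests each class for shared-annotation enrichment against the
#' background of all imputed pairs. When a missing-category map is
#' supplied, the chromosomal-neighbour and DAmP-DAmP subsets of each
#' strong class are additionally tested on their own. Classes or subsets
#' with fewer than 2 pairs are skipped with a message (e.g. when almost
#' no DAmP-DAmP pair is predicted alleviating).
#'
#' @param result an `imputation_result`
#' @param annotations an `annotation_map`
#' @param categories optional data.frame from [classify_missing()]
#' @param thresholds a [class_thresholds()]
#' @param alpha significance level
#' @param gene_map optional named character vector mapping allele ids to
#'   gene names used in the annotations; identity by default
#' @param background `"all"` (every imputed pair; the zero-variance limit
#'   of background sampling) or `"sample"` (a seeded random subset of
#'   imputed pairs matched in size to the class)
#' @param seed seed for `background = "sample"`
#' @return list of `enrichment_result`
#' @export
enrich_imputed_classes <- function(result, annotations, categories = NULL,
                                   thresholds = class_thresholds(),
                                   alpha = 0.01, gene_map = NULL,
                                   background = c("all", "sample"),
                                   seed = 1L) {
  stopifnot(inherits(result, "imputation_result"))
  background <- match.arg(background)
  prov <- result$provenance
  if (nrow(prov) == 0) stop("no imputed pairs")
  to_gene <- function(a) if (is.null(gene_map)) a else unname(gene_map[a])
  all_pairs <- cbind(to_gene(prov$allele_i), to_gene(prov$allele_j))
  cls <- as.character(classify_interaction(prov$value, thresholds))
  cat_of <- rep("other", nrow(prov))
  if (!is.null(categories)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    idx <- match(key(prov$allele_i, prov$allele_j),
                 key(categories$allele_i, categories$allele_j))
    cat_of[!is.na(idx)] <- categories$category[idx[!is.na(idx)]]
  }
  subsets <- list(list(label = "all", keep = rep(TRUE, nrow(prov))))
  if (!is.null(categories))
    for (ct in c("chromosomal_neighbor", "damp_damp"))
      if (any(cat_of == ct))
        subsets <- c(subsets, list(list(label = ct, keep = cat_of == ct)))
  out <- list()
  for (sub in subsets) {
    bg <- all_pairs[sub$keep, , drop = FALSE]
    for (cl in c("alleviating", "aggravating", "neutral")) {
      sel <- sub$keep & cls == cl
      if (sum(sel) < 2) {
        message(sprintf("skipping class '%s' [%s]: %d pair(s)",
                        cl, sub$label, sum(sel)))
        next
      }
      this_bg <- bg
      if (background == "sample" && nrow(bg) > sum(sel))
        this_bg <- bg[.with_seed(seed, sample.int(nrow(bg), sum(sel))), ,
                      drop = FALSE]
      out[[paste(cl, sub$label, sep = ".")]] <-
        enrichment_test(all_pairs[sel, , drop = FALSE], this_bg,
                        annotations, alpha = alpha, class_label = cl,
                        category = sub$label)
    }
  }
  out
}

#' Write enrichment results as a TSV
#'
#' @param results list of `enrichment_result`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_enrichment <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(class = r$class, category = r$category, n_pairs = r$n_pairs,
               frac_shared = r$frac_shared,
               frac_background = r$frac_background,
               odds_ratio = r$odds_ratio, p_value = r$p_value,
               significant = r$significant, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
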