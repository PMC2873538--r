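#' Read an E-MAP matrix from a tab-delimited flat file
#'
#' Parses the flat-file format used by published E-MAP studies (and by the
#' Cluster tool): row 1 is a tab followed by the allele names, each later
#' row is an allele name followed by n tab-separated cells. A cell holds a
#' decimal score or a missing token. Published files are sometimes emitted
#' triangular, so when exactly one of (i, j) / (j, i) is present the value
#' is mirrored with a warning; when both are present but disagree beyond
#' `tol` the read fails at that cell.
#'
#' @param path file path
#' @param missing_tokens strings treated as missing; the empty cell is
#'   always missing
#' @param tol maximum tolerated |(i,j) - (j,i)| before raising
#' @return an [emap_matrix()]
#' @export
read_emap <- function(path, missing_tokens = c("", "NA", "NaN", "nan"),
                      tol = 1e-6) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("E-MAP file must have a header and >= 2 rows")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  alleles <- header[-1]
  n <- length(alleles)
  if (n < 2) stop("E-MAP file must list >= 2 alleles in its header")
  if (anyDuplicated(alleles))
    stop(sprintf("duplicate allele name '%s' in header",
                 alleles[duplicated(alleles)][1]))
  if (length(lines) - 1 != n)
    stop(sprintf("non-square table: %d header alleles but %d data rows",
                 n, length(lines) - 1))
  scores <- matrix(NA_real_, n, n, dimnames = list(alleles, alleles))
  for (i in seq_len(n)) {
    cells <- strsplit(lines[[i + 1]], "\t", fixed = TRUE)[[1]]
    # trailing empty cells are dropped by strsplit; pad back
    length(cells) <- n + 1
    cells[is.na(cells)] <- ""
    if (cells[1] != alleles[i])
      stop(sprintf("row %d is labelled '%s' but column %d is '%s'",
                   i + 1, cells[1], i, alleles[i]))
    vals <- cells[-1]
    miss <- vals %in% missing_tokens
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!miss & is.na(parsed))
    if (length(bad) > 0)
      stop(sprintf("unparseable cell '%s' at row '%s', column '%s'",
                   vals[bad[1]], alleles[i], alleles[bad[1]]))
    scores[i, !miss] <- parsed[!miss]
  }
  has <- !is.na(scores)
  both <- has & t(has)
  conflict <- which(both & abs(scores - t(scores)) > tol, arr.ind = TRUE)
  if (nrow(conflict) > 0)
    stop(sprintf("asymmetric scores at (%s, %s): %g vs %g",
                 alleles[conflict[1, 1]], alleles[conflict[1, 2]],
                 scores[conflict[1, 1], conflict[1, 2]],
                 scores[conflict[1, 2], conflict[1, 1]]))
  onesided <- has & !t(has)
  if (any(onesided)) {
    warning(sprintf("%d single-sided entries mirrored to their transpose",
                    sum(onesided)))
    scores[t(onesided)] <- t(scores)[t(onesided)]
  }
  if (any(!is.na(diag(scores)))) {
    warning("diagonal (self-interaction) entries present; ignored")
    diag(scores) <- NA_real_
  }
  emap_matrix(scores, alleles = alleles)
}

#' Write an E-MAP matrix to a tab-delimited flat file
#'
#' Inverse of [read_emap()]: scores are printed with six decimal places
#' and missing entries as empty cells, so a write/read round trip
#' reproduces scores (to 1e-6), mask and allele order.
#'
#' @param m an [emap_matrix()]
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_emap <- function(m, path) {
  stopifnot(inherits(m, "emap_matrix"))
  cells <- matrix("", nrow(m$scores), ncol(m$scores))
  cells[m$measured] <- sprintf("%.6f", m$scores[m$measured])
  lines <- c(paste(c("", m$alleles), collapse = "\t"),
             vapply(seq_along(m$alleles), function(i)
               paste(c(m$alleles[i], cells[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read allele metadata
#'
#' Six-column TSV (`allele`, `gene`, `chromosome`, `start`, `end`,
#' `perturbation`) describing each allele: systematic gene name, genomic
#' interval (1-based inclusive) and perturbation type (`deletion` for a
#' full knockout, `damp` for a hypomorphic DAmP allele of an essential
#' gene). Lines starting with `#` are ignored.
#'
#' @param path file path
#' @return data.frame keyed by `allele`
#' @export
read_allele_meta <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("allele", "gene", "chromosome", "start", "end", "perturbation")
  if (!all(need %in% names(df)))
    stop("metadata file must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (anyDuplicated(df$allele)) stop("duplicate allele in metadata")
  if (any(df$start > df$end) || any(df$start < 1))
    stop("invalid coordinates: need 1 <= start <= end")
  bad <- setdiff(unique(df$perturbation), c("deletion", "damp"))
  if (length(bad) > 0)
    stop("unknown perturbation type(s): ", paste(bad, collapse = ", "))
  rownames(df) <- df$allele
  df
}

#' Classify missing pairs into the three E-MAP missingness categories
#'
#' Missing entries in E-MAPs fall into three categories:
#' `chromosomal_neighbor` (both genes on the same chromosome with an
#' inter-interval gap of at most `window_bp`; such pairs are filtered
#' from screens because recombination between nearby loci fakes a
#' negative interaction), `damp_damp` (both alleles are DAmP
#' perturbations of essential genes, combinations that are rarely
#' assayed), and `other` (everything else, mostly sporadic experimental
#' dropout). A DAmP pair that is also within the window is classed as a
#' neighbour, since the recombination artifact applies regardless of
#' allele type.
#'
#' @param m an [emap_matrix()]
#' @param meta data.frame from [read_allele_meta()]
#' @param window_bp neighbour window in base pairs (default 50 kb)
#' @param strict error (rather than warn and use `other`) when an allele
#'   lacks metadata
#' @return data.frame with columns `allele_i`, `allele_j`, `category`,
#'   one row per missing unordered pair
#' @export
classify_missing <- function(m, meta, window_bp = 50000, strict = FALSE) {
  stopifnot(inherits(m, "emap_matrix"))
  mp <- missing_pairs(m)
  ai <- m$alleles[mp[, 1]]; aj <- m$alleles[mp[, 2]]
  known <- m$alleles %in% rownames(meta)
  if (!all(known)) {
    msg <- sprintf("%d alleles lack metadata; their pairs classed 'other'",
                   sum(!known))
    if (strict) stop(msg) else warning(msg)
  }
  idx_i <- match(ai, rownames(meta)); idx_j <- match(aj, rownames(meta))
  cat_ <- rep("other", nrow(mp))
  ok <- !is.na(idx_i) & !is.na(idx_j)
  if (any(ok)) {
    same_chr <- meta$chromosome[idx_i] == meta$chromosome[idx_j]
    gap <- pmax(0, pmax(meta$start[idx_i], meta$start[idx_j]) -
                     pmin(meta$end[idx_i], meta$end[idx_j]) - 1)
    neighbor <- ok & same_chr & gap <= window_bp
    damp <- ok & meta$perturbation[idx_i] == "damp" &
      meta$perturbation[idx_j] == "damp"
    cat_[damp] <- "damp_damp"
    cat_[neighbor] <- "chromosomal_neighbor"   # takes precedence
  }
  data.frame(allele_i = ai, allele_j = aj, category = cat_,
             stringsAsFactors = FALSE)
}

#' Read a gene-annotation file and apply a term-size ceiling
#'
#' Reads a two-column tab-delimited gene/term file (GO Slim mapping
#' style, or phenotype annotations). Comment lines starting with `!` or
#' `#` are ignored, as in gene_association headers. Terms annotating more
#' than `max_term_size` genes are removed before the maps are built --
#' very broad terms (e.g. 'viable') carry no information about shared
#' function.
#'
#' @param path file path
#' @param source label for this annotation source (e.g. `"go_slim"`,
#'   `"phenotype"`)
#' @param max_term_size ceiling on genes per retained term (the reference
#'   analysis used 1000 for GO Slim and 175 for phenotypes)
#' @return an `annotation_map`: list with `source`, `term2genes`,
#'   `gene2terms` (mutually inverse named lists) and `max_term_size`
#' @export
read_annotations <- function(path, source = "annotations",
                             max_term_size = 1000L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^[!#]", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2
  if (any(!ok))
    warning(sprintf("skipped %d malformed line(s): %s", sum(!ok),
                    paste(utils::head(which(!ok), 5), collapse = ", ")))
  genes <- vapply(parts[ok], `[`, character(1), 1)
  terms <- vapply(parts[ok], `[`, character(1), 2)
  annotation_map(genes, terms, source = source,
                 max_term_size = max_term_size)
}

#' Build an annotation map from gene/term vectors
#'
#' @param genes,terms parallel character vectors (one annotation each)
#' @param source source label
#' @param max_term_size ceiling on genes per retained term
#' @return an `annotation_map` (see [read_annotations()])
#' @export
annotation_map <- function(genes, terms, source = "annotations",
                           max_term_size = 1000L) {
  keep <- !duplicated(paste0(genes, "\r", terms))
  genes <- genes[keep]; terms <- terms[keep]
  sizes <- table(terms)
  retained <- names(sizes)[sizes <= max_term_size]
  keep <- terms %in% retained
  genes <- genes[keep]; terms <- terms[keep]
  if (length(genes) == 0)
    warning("annotation map is empty after term-size filtering")
  obj <- structure(list(
    source = source,
    term2genes = lapply(split(genes, terms), unique),
    gene2terms = lapply(split(terms, genes), unique),
    max_term_size = as.integer(max_term_size)), class = "annotation_map")
  obj
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation map '%s': %d genes, %d terms (ceiling %d)\n",
              x$source, length(x$gene2terms), length(x$term2genes),
              x$max_term_size))
  invisible(x)
}

#' Write a two-column annotation TSV
#' @param ann an `annotation_map`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_map"))
  g <- rep(names(ann$gene2terms), lengths(ann$gene2terms))
  t_ <- unlist(ann$gene2terms, use.names = FALSE)
  writeLines(paste(g, t_, sep = "\t"), path)
  invisible(path)
}

#' Write an allele-metadata TSV
#' @param meta data.frame in [read_allele_meta()] layout
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_allele_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
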