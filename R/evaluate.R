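#' Hide measured values for evaluation
#'
#' Artificially masks a fraction of the measured unordered pairs
#' (selected uniformly at random without replacement, reproducibly per
#' seed) and records their true values, giving a held-out test set for
#' imputation accuracy. Hiding is symmetric: (i, j) and (j, i) are masked
#' together.
#'
#' @param m an [emap_matrix()]
#' @param fraction proportion of measured unordered pairs to hide
#'   (default 0.01); `floor(fraction * n_measured_pairs)` pairs are drawn
#' @param seed integer seed
#' @return a `hidden_set`: list with `masked` (the matrix with those
#'   pairs unmeasured), `pairs` (two-column index matrix) and `answers`
#'   (true values)
#' @export
hide_values <- function(m, fraction = 0.01, seed = 1L) {
  stopifnot(inherits(m, "emap_matrix"), fraction > 0, fraction < 1)
  mp <- measured_pairs(m)
  n_hide <- floor(fraction * nrow(mp))
  if (n_hide < 1)
    stop("fraction yields zero pairs to hide")
  sel <- .with_seed(seed, sample.int(nrow(mp), n_hide))
  pairs <- mp[sort(sel), , drop = FALSE]
  answers <- m$scores[pairs]
  masked <- m
  masked$measured[pairs] <- FALSE
  masked$measured[pairs[, c(2, 1), drop = FALSE]] <- FALSE
  masked$scores[!masked$measured] <- NA_real_
  structure(list(masked = masked, pairs = pairs, answers = answers),
            class = "hidden_set")
}

#' Normalized root mean squared error
#'
#' \deqn{NRMSE = \sqrt{\frac{mean[(guess - answer)^2]}{variance(answer)}}}
#' with the population (divisor-n) variance, so that predicting the mean
#' of zero-mean answers scores exactly 1. Lower is better; 0 is perfect.
#'
#' @param guesses,answers equal-length numeric vectors
#' @return non-negative scalar
#' @export
nrmse <- function(guesses, answers) {
  if (length(guesses) != length(answers)) stop("length mismatch")
  if (length(answers) == 0) stop("empty input")
  v <- mean((answers - mean(answers))^2)
  if (v == 0) stop("answers have zero variance; NRMSE undefined")
  sqrt(mean((guesses - answers)^2) / v)
}

#' Correlation between predictions and true values
#'
#' Pearson correlation, with the convention that a zero-variance vector
#' (e.g. the constant predictions of the zero-fill baseline) yields 0
#' rather than an undefined value.
#'
#' @param guesses,answers equal-length numeric vectors
#' @return correlation in \[-1, 1\]
#' @export
prediction_correlation <- function(guesses, answers) {
  if (length(guesses) != length(answers)) stop("length mismatch")
  if (length(answers) == 0) stop("empty input")
  if (stats::sd(guesses) == 0 || stats::sd(answers) == 0) return(0)
  stats::cor(guesses, answers)
}

#' Interaction-class thresholds
#'
#' Strongly alleviating interactions are scores above `alleviating_gt`
#' (default 2.0) and strongly aggravating ones are scores below
#' `aggravating_lt` (default -2.5); everything else, boundaries
#' included, is neutral.
#'
#' @param alleviating_gt positive threshold
#' @param aggravating_lt negative threshold
#' @return list of class `class_thresholds`
#' @export
class_thresholds <- function(alleviating_gt = 2.0, aggravating_lt = -2.5) {
  stopifnot(aggravating_lt < 0, alleviating_gt > 0)
  structure(list(alleviating_gt = alleviating_gt,
                 aggravating_lt = aggravating_lt),
            class = "class_thresholds")
}

#' Classify interaction scores into three classes
#'
#' @param score numeric score(s)
#' @param thresholds a [class_thresholds()]
#' @return factor with levels alleviating, neutral, aggravating
#' @export
classify_interaction <- function(score, thresholds = class_thresholds()) {
  cls <- ifelse(score > thresholds$alleviating_gt, "alleviating",
                ifelse(score < thresholds$aggravating_lt, "aggravating",
                       "neutral"))
  factor(cls, levels = c("alleviating", "neutral", "aggravating"))
}

#' Per-class precision, recall and F1
#'
#' Standard definitions: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R). Undefined ratios (no predictions, or no actuals, of a
#' class) are reported as 0.
#'
#' @param predicted,actual equal-length vectors of class labels from the
#'   three-class alphabet
#' @return data.frame with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `n_actual`, `n_predicted`, `precision`, `recall`, `f1`
#' @export
classification_report <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  lev <- c("alleviating", "neutral", "aggravating")
  predicted <- factor(as.character(predicted), levels = lev)
  actual <- factor(as.character(actual), levels = lev)
  if (anyNA(predicted) || anyNA(actual))
    stop("labels outside the three-class alphabet")
  out <- do.call(rbind, lapply(lev, function(cl) {
    tp <- sum(predicted == cl & actual == cl)
    fp <- sum(predicted == cl & actual != cl)
    fn <- sum(predicted != cl & actual == cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               n_actual = tp + fn, n_predicted = tp + fp,
               precision = p, recall = r, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Evaluate an imputer by repeated artificial masking
#'
#' Repeats the hide/impute cycle (default 20 times at 1% hiding), pools
#' the (guess, answer) pairs across repetitions, and reports pooled
#' prediction correlation, NRMSE and the three-class
#' precision/recall/F1. Per-repetition seeds are derived from `seed`, so
#' the whole evaluation is reproducible.
#'
#' @param m an [emap_matrix()]
#' @param imputer a method name (see [imputation_config()]) or a
#'   function(masked_matrix, pairs) returning predicted values
#' @param config [imputation_config()] used when `imputer` is a name
#' @param repetitions number of masking repetitions
#' @param fraction hidden fraction per repetition
#' @param seed master seed
#' @param thresholds [class_thresholds()] for the class report
#' @param pool pool pairs across repetitions (default) or average the
#'   per-repetition correlation/NRMSE
#' @return an `evaluation_report`: list with `method`, `correlation`,
#'   `nrmse`, `class_report`, `n_pairs`, `repetitions`, and the pooled
#'   `guesses`/`answers`
#' @export
evaluate_imputer <- function(m, imputer = "wnn",
                             config = NULL,
                             repetitions = 20L, fraction = 0.01,
                             seed = 1L,
                             thresholds = class_thresholds(),
                             pool = TRUE) {
  method <- if (is.function(imputer)) "custom" else imputer
  if (!is.function(imputer) && is.null(config))
    config <- imputation_config(imputer)
  guesses <- answers <- vector("list", repetitions)
  per_rep <- matrix(NA_real_, repetitions, 2)
  for (rep_i in seq_len(repetitions)) {
    hs <- hide_values(m, fraction, seed = seed + rep_i - 1L)
    g <- if (is.function(imputer)) imputer(hs$masked, hs$pairs)
    else .predict_pairs(hs$masked, hs$pairs, config)$value
    guesses[[rep_i]] <- g
    answers[[rep_i]] <- hs$answers
    if (!pool)
      per_rep[rep_i, ] <- c(prediction_correlation(g, hs$answers),
                            nrmse(g, hs$answers))
  }
  g <- unlist(guesses); a <- unlist(answers)
  corr <- if (pool) prediction_correlation(g, a) else mean(per_rep[, 1])
  err <- if (pool) nrmse(g, a) else mean(per_rep[, 2])
  structure(list(method = method,
                 k = if (is.null(config)) NA_integer_ else config$k,
                 correlation = corr, nrmse = err,
                 class_report = classification_report(
                   classify_interaction(g, thresholds),
                   classify_interaction(a, thresholds)),
                 n_pairs = length(g), repetitions = repetitions,
                 guesses = g, answers = a),
            class = "evaluation_report")
}

#' Cross-validated three-class evaluation
#'
#' Strong genetic interactions are rare (under 10% of pairs), so the
#' class report is computed over the entire dataset by k-fold
#' cross-validation: all measured unordered pairs are partitioned into
#' random disjoint folds, each fold is hidden and imputed in turn, and
#' every measured pair contributes exactly one prediction.
#'
#' @inheritParams evaluate_imputer
#' @param folds number of folds (default 20)
#' @return an `evaluation_report` (correlation and NRMSE computed over
#'   the full prediction vector)
#' @export
cross_validate_classes <- function(m, imputer = "wnn", config = NULL,
                                   folds = 20L, seed = 1L,
                                   thresholds = class_thresholds()) {
  stopifnot(folds >= 2)
  mp <- measured_pairs(m)
  if (nrow(mp) < folds) stop("fewer measured pairs than folds")
  if (!is.function(imputer) && is.null(config))
    config <- imputation_config(imputer)
  assignment <- .with_seed(seed, sample(rep(seq_len(folds),
                                            length.out = nrow(mp))))
  guesses <- rep(NA_real_, nrow(mp))
  for (f in seq_len(folds)) {
    idx <- which(assignment == f)
    pairs <- mp[idx, , drop = FALSE]
    masked <- m
    masked$measured[pairs] <- FALSE
    masked$measured[pairs[, c(2, 1), drop = FALSE]] <- FALSE
    masked$scores[!masked$measured] <- NA_real_
    guesses[idx] <- if (is.function(imputer)) imputer(masked, pairs)
    else .predict_pairs(masked, pairs, config)$value
  }
  answers <- m$scores[mp]
  structure(list(method = if (is.function(imputer)) "custom" else imputer,
                 k = if (is.null(config)) NA_integer_ else config$k,
                 correlation = prediction_correlation(guesses, answers),
                 nrmse = nrmse(guesses, answers),
                 class_report = classification_report(
                   classify_interaction(guesses, thresholds),
                   classify_interaction(answers, thresholds)),
                 n_pairs = length(guesses), repetitions = folds,
                 guesses = guesses, answers = answers),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation of '%s': correlation %.3f, NRMSE %.3f over %d pairs (%d repetitions)\n",
              x$method, x$correlation, x$nrmse, x$n_pairs, x$repetitions))
  print(x$class_report[c("class", "n_actual", "precision", "recall", "f1")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an evaluation report as TSV and JSON
#'
#' Emits `<prefix>.tsv` (one row per class with the shared correlation
#' and NRMSE columns) and `<prefix>.json`.
#'
#' @param report an `evaluation_report`
#' @param prefix output path prefix
#' @return invisibly, the two paths
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "evaluation_report"))
  cr <- report$class_report
  df <- data.frame(method = report$method, K = report$k,
                   correlation = report$correlation, nrmse = report$nrmse,
                   class = cr$class, precision = cr$precision,
                   recall = cr$recall, f1 = cr$f1, n = report$n_pairs,
                   stringsAsFactors = FALSE)
  tsv <- paste0(prefix, ".tsv"); js <- paste0(prefix, ".json")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(method = report$method, K = report$k,
         correlation = report$correlation, nrmse = report$nrmse,
         n = report$n_pairs, repetitions = report$repetitions,
         classes = cr[c("class", "n_actual", "precision", "recall", "f1")]),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
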