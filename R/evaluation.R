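#' Stratified k-fold partition
#'
#' Splits instances into `folds` disjoint test sets of near-equal size
#' (differing by at most one instance) while keeping each class's proportion
#' within one instance of its global share.  Stratification uses the true
#' labels — evaluation-side information only; training never sees the truth of
#' masked instances.  The assignment is fully determined by the seed.
#'
#' @param x a `pu_dataset`.
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param stratify stratify on true labels (default `TRUE`); `FALSE` gives a
#'   plain random partition.
#' @return A list of `folds` elements, each a list with integer vectors
#'   `train` and `test` of instance positions.
#' @export
stratified_kfold <- function(x, folds = 10L, seed = 1L, stratify = TRUE) {
  stopifnot(inherits(x, "pu_dataset"))
  n <- length(x$ids)
  folds <- as.integer(folds)
  if (folds < 2 || folds > n)
    stop("'folds' must be between 2 and the number of instances",
         call. = FALSE)
  assign_fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratify) {
      groups <- split(seq_len(n), x$truth)
    } else {
      groups <- list(seq_len(n))
    }
    p <- sample.int(folds, 1) - 1L  # rotate which folds receive remainders
    for (g in groups) {
      g <- g[sample.int(length(g))]
      assign_fold[g] <- (p + seq_along(g) - 1L) %% folds + 1L
      p <- p + length(g)
    }
  })
  lapply(seq_len(folds), function(f)
    list(train = which(assign_fold != f), test = which(assign_fold == f)))
}

#' Confusion matrix of binary predictions
#'
#' @param truth true labels (`"positive"`/`"negative"`).
#' @param predicted predicted labels, same length.
#' @return An object of class `confusion_matrix`: a named integer vector with
#'   `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusion(c("positive", "positive", "negative", "negative"),
#'           c("positive", "negative", "positive", "negative"))
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  truth <- as.character(truth); predicted <- as.character(predicted)
  bad <- setdiff(unique(c(truth, predicted)), CLASS_LEVELS)
  if (length(bad))
    stop("labels must be binary positive/negative; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(c(TP = sum(truth == "positive" & predicted == "positive"),
              TN = sum(truth == "negative" & predicted == "negative"),
              FP = sum(truth == "negative" & predicted == "positive"),
              FN = sum(truth == "positive" & predicted == "negative")),
            class = "confusion_matrix")
}

#' Accuracy, precision, recall and F-measure
#'
#' Derives the four standard metrics from a confusion matrix:
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `PR = TP / (TP + FP)`,
#' `R = TP / (TP + FN)`, `FM = 2 TP / (2 TP + FN + FP)` (the harmonic mean of
#' precision and recall).  A metric whose denominator is zero is reported as 0
#' and flagged in `degenerate`.
#'
#' @param cm a `confusion_matrix` (or named vector with TP/TN/FP/FN).
#' @return A list with `ACC`, `PR`, `R`, `FM` and a character vector
#'   `degenerate` naming any zero-denominator metrics.
#' @examples
#' classification_metrics(confusion(rep("positive", 3), rep("positive", 3)))
#' @export
classification_metrics <- function(cm) {
  tp <- cm[["TP"]]; tn <- cm[["TN"]]; fp <- cm[["FP"]]; fn <- cm[["FN"]]
  total <- tp + tn + fp + fn
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  degenerate <- character(0)
  pr <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- c(degenerate, "PR"); 0 }
  r <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "R"); 0 }
  fm <- if (2 * tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp) else {
    degenerate <- c(degenerate, "FM"); 0 }
  list(ACC = (tp + tn) / total, PR = pr, R = r, FM = fm,
       degenerate = degenerate)
}

#' Cross-validated evaluation of the full PU pipeline
#'
#' Runs the complete method under the standard protocol: the labels of a
#' fully labeled dataset are masked once at `mask_ratio` (seeded), the masked
#' dataset is split into stratified folds, and for each fold the training
#' portion is relabeled by unanimous-vote k-NN on its observed labels, a tree
#' is built on the result, and the held-out fold is predicted and scored
#' against the retained true labels.
#'
#' @param x a `pu_dataset` carrying true labels on every instance.  If fully
#'   labeled, masking is applied at `mask_ratio`; a dataset that already
#'   contains unlabeled instances is used as is (set `mask_ratio = NA`).
#' @param mask_ratio fraction of labels to hide before cross-validation
#'   (default 0.05); 0 skips masking (plain supervised CV); `NA` means the
#'   dataset is already masked.
#' @param k neighbors for the relabeling stage (default 3).
#' @param folds,seed,stratify passed to [stratified_kfold()]; the same seed
#'   also drives the masking draw.
#' @param criterion,min_leaf,max_depth passed to [build_tree()].
#' @param pool,normalization passed to [relabel_unlabeled()].
#' @return A list of class `pu_cv_result`: `per_fold` (data frame of fold
#'   metrics), `means` (mean ACC/PR/R/FM over folds), `confusion` (pooled
#'   counts), and `config` (the resolved settings, including the seed).
#' @examples
#' cv <- run_npulud_cv(toy_fixture("supervised"), mask_ratio = 0.25,
#'                     folds = 5, seed = 7)
#' cv$means["ACC"]
#' @export
run_npulud_cv <- function(x, mask_ratio = 0.05, k = 3L, folds = 10L,
                          seed = 1L, stratify = TRUE,
                          criterion = c("gain_ratio", "gain"),
                          min_leaf = 2L, max_depth = Inf,
                          pool = c("all", "positives"),
                          normalization = c("minmax", "none")) {
  criterion <- match.arg(criterion)
  pool <- match.arg(pool)
  normalization <- match.arg(normalization)
  stopifnot(inherits(x, "pu_dataset"))
  if (any(x$truth == "unknown"))
    stop("evaluation requires true labels on every instance", call. = FALSE)
  if (!is.na(mask_ratio) && mask_ratio > 0)
    x <- mask_labels(x, mask_ratio, seed = seed)
  fold_sets <- stratified_kfold(x, folds = folds, seed = seed,
                                stratify = stratify)
  per_fold <- vector("list", length(fold_sets))
  pooled <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in seq_along(fold_sets)) {
    train <- x[fold_sets[[f]]$train]
    test <- x[fold_sets[[f]]$test]
    if (n_unlabeled(train) > 0)
      train <- relabel_unlabeled(train, k = k, pool = pool,
                                 normalization = normalization)$data
    tree <- build_tree(train, criterion = criterion, min_leaf = min_leaf,
                       max_depth = max_depth)
    pred <- predict(tree, test)
    cm <- confusion(test$truth, pred)
    pooled <- pooled + cm
    m <- classification_metrics(cm)
    per_fold[[f]] <- data.frame(fold = f, n_test = length(test$ids),
                                ACC = m$ACC, PR = m$PR, R = m$R, FM = m$FM)
  }
  per_fold <- do.call(rbind, per_fold)
  means <- colMeans(per_fold[, c("ACC", "PR", "R", "FM")])
  structure(list(per_fold = per_fold, means = means,
                 confusion = structure(pooled, class = "confusion_matrix"),
                 config = list(mask_ratio = mask_ratio, k = as.integer(k),
                               folds = as.integer(folds),
                               seed = as.integer(seed), stratify = stratify,
                               criterion = criterion,
                               min_leaf = as.integer(min_leaf),
                               max_depth = max_depth, pool = pool,
                               normalization = normalization)),
            class = "pu_cv_result")
}

#' @export
print.pu_cv_result <- function(x, ...) {
  cat(sprintf("pu_cv_result: %d folds, mask_ratio = %s, k = %d, seed = %d\n",
              x$config$folds, format(x$config$mask_ratio), x$config$k,
              x$config$seed))
  cat(sprintf("mean ACC %.4f  PR %.4f  R %.4f  FM %.4f\n",
              x$means[["ACC"]], x$means[["PR"]], x$means[["R"]],
              x$means[["FM"]]))
  invisible(x)
}

#' Accuracy across label-masking ratios
#'
#' Repeats [run_npulud_cv()] at each masking ratio with a shared fold seed,
#' reporting the mean cross-validated accuracy per ratio — the robustness
#' check of the pipeline against the share of hidden labels.
#'
#' @param x a fully labeled `pu_dataset`.
#' @param ratios masking ratios to sweep (default `c(0.05, 0.10, 0.15, 0.20)`).
#' @param ... further arguments passed to [run_npulud_cv()].
#' @inheritParams run_npulud_cv
#' @return A data frame with columns `ratio` and `mean_acc`.
#' @export
ratio_sweep <- function(x, ratios = c(0.05, 0.10, 0.15, 0.20), k = 3L,
                        folds = 10L, seed = 1L, ...) {
  rows <- lapply(ratios, function(r) {
    cv <- run_npulud_cv(x, mask_ratio = r, k = k, folds = folds, seed = seed,
                        ...)
    data.frame(ratio = r, mean_acc = cv$means[["ACC"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired per-dataset scores.  Differences
#' `b - a` equal to zero are discarded; the absolute differences receive
#' midranks, and the statistic is `W = min(W+, W-)`, the smaller of the two
#' signed rank sums.  For `n_effective <= 25` the two-sided p-value is exact,
#' computed from the null distribution of `W+` over all sign assignments of
#' the observed (possibly tied) ranks; larger samples use the normal
#' approximation with tie-corrected variance.
#'
#' @param a,b paired score vectors of equal length (at least 6).
#' @return A list with `statistic` (W), `w_plus`, `w_minus`, `p_value`,
#'   `n_effective`, and `method` (`"exact"` or `"normal"`).  When every
#'   difference is zero the result is degenerate: `n_effective = 0` and
#'   `p_value = NA`.
#' @examples
#' acc <- benchmark_fixture("accuracy_dt_vs_npulud")
#' wilcoxon_signed_rank(acc$dt, acc$npulud)$p_value
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must be paired", call. = FALSE)
  if (length(a) < 6) stop("need at least 6 pairs", call. = FALSE)
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, w_plus = NA_real_, w_minus = NA_real_,
                p_value = NA_real_, n_effective = 0L, method = "degenerate"))
  r <- rank(abs(d))          # midranks for ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= 25) {
    p <- exact_signed_rank_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    # variance with tie correction over the midranks
    sigma2 <- sum(r^2) / 4
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, w_plus = w_plus, w_minus = w_minus, p_value = p,
       n_effective = as.integer(n), method = method)
}

# Exact two-sided p for W = min(W+, W-) conditional on the observed midranks:
# all 2^n sign assignments equally likely.  Ranks are doubled so midranks
# (*.5) become integers; the subset-sum distribution is built by dynamic
# programming, and symmetry of W+ about sum(r)/2 gives the two-sided value.
exact_signed_rank_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  p_le <- sum(counts[seq_len(as.integer(round(2 * w)) + 1)]) / 2^length(ranks)
  min(1, 2 * p_le)
}
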