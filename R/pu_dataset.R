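#' Construct a positive-unlabeled dataset
#'
#' A `pu_dataset` holds a tabular binary-classification problem in the
#' positive-unlabeled (PU) setting: feature columns (numeric or categorical),
#' an observed label per instance in `{positive, negative, unlabeled}`, and an
#' optional hidden true label in `{positive, negative, unknown}` retained so
#' that evaluation can score predictions on instances whose observed label has
#' been masked.  The observed labels partition the data as D = P_L + U: the
#' labeled part and the unlabeled part.
#'
#' @param features data frame of feature columns; numeric columns are treated
#'   as numeric features, everything else as categorical. `NA` marks a missing
#'   value.
#' @param observed character or factor of observed labels, values in
#'   `c("positive", "negative", "unlabeled")`.
#' @param truth optional true labels, values in
#'   `c("positive", "negative", "unknown")`. Defaults to `observed` for
#'   labeled instances and `"unknown"` for unlabeled ones.
#' @param ids integer instance identifiers, unique; default `1:n`.
#' @param positive_class the raw label value that was mapped to "positive"
#'   (kept for round-tripping files).
#' @param check_consistency verify that each observed label agrees with the
#'   retained true label (default `TRUE`).  Relabeling output disables the
#'   check: an assigned label may legitimately contradict the hidden truth,
#'   and that disagreement is what evaluation measures.
#'
#' @return An object of class `pu_dataset` with components `features`,
#'   `specs` (per-feature kind, categories and observed numeric range),
#'   `observed`, `truth`, `ids`, `positive_class`.
#' @examples
#' d <- pu_dataset(data.frame(x = c(1, 2, 10)),
#'                 observed = c("positive", "unlabeled", "unlabeled"))
#' n_unlabeled(d)
#' @export
pu_dataset <- function(features, observed, truth = NULL,
                       ids = seq_len(nrow(features)),
                       positive_class = "positive",
                       check_consistency = TRUE) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  n <- nrow(features)
  observed <- as.character(observed)
  if (length(observed) != n)
    stop("'observed' must have one label per instance", call. = FALSE)
  bad <- setdiff(unique(observed), c("positive", "negative", "unlabeled"))
  if (length(bad))
    stop("invalid observed label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(truth)) {
    truth <- ifelse(observed == "unlabeled", "unknown", observed)
  } else {
    truth <- as.character(truth)
    if (length(truth) != n)
      stop("'truth' must have one label per instance", call. = FALSE)
    bad <- setdiff(unique(truth), c("positive", "negative", "unknown"))
    if (length(bad))
      stop("invalid true label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    mism <- check_consistency &
      observed != "unlabeled" & truth != "unknown" & truth != observed
    if (any(mism))
      stop("observed label contradicts true label for instance(s): ",
           paste(utils::head(ids[mism]), collapse = ", "), call. = FALSE)
  }
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("instance ids must be unique", call. = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (j in seq_along(features)) {
    if (is.factor(features[[j]])) features[[j]] <- as.character(features[[j]])
    if (is.logical(features[[j]])) features[[j]] <- as.character(features[[j]])
    if (is.integer(features[[j]])) features[[j]] <- as.numeric(features[[j]])
  }
  structure(list(features = features,
                 specs = feature_specs(features),
                 observed = observed,
                 truth = truth,
                 ids = ids,
                 positive_class = positive_class),
            class = "pu_dataset")
}

# Infer per-feature metadata: kind, category codes, observed numeric range.
feature_specs <- function(features) {
  lapply(stats::setNames(names(features), names(features)), function(nm) {
    x <- features[[nm]]
    if (is.numeric(x)) {
      ok <- !is.na(x)
      rng <- if (any(ok)) range(x[ok]) else c(NA_real_, NA_real_)
      list(name = nm, kind = "numeric", range = rng)
    } else {
      cats <- sort(unique(x[!is.na(x)]))
      list(name = nm, kind = "categorical", categories = cats)
    }
  })
}

#' @export
print.pu_dataset <- function(x, ...) {
  tab <- table(factor(x$observed, c("positive", "negative", "unlabeled")))
  kinds <- vapply(x$specs, `[[`, "", "kind")
  cat(sprintf("pu_dataset: %d instances, %d features (%d numeric, %d categorical)\n",
              length(x$ids), length(x$specs),
              sum(kinds == "numeric"), sum(kinds == "categorical")))
  cat(sprintf("observed labels: %d positive, %d negative, %d unlabeled\n",
              tab[["positive"]], tab[["negative"]], tab[["unlabeled"]]))
  invisible(x)
}

#' Subset a PU dataset by instance position
#'
#' @param x a `pu_dataset`.
#' @param i integer positions (not ids) of the instances to keep.
#' @param ... ignored.
#' @return A `pu_dataset` with the selected instances; ids are preserved and
#'   numeric feature ranges are recomputed over the subset.
#' @export
`[.pu_dataset` <- function(x, i, ...) {
  pu_dataset(x$features[i, , drop = FALSE],
             observed = x$observed[i], truth = x$truth[i],
             ids = x$ids[i], positive_class = x$positive_class,
             check_consistency = FALSE)
}

#' Instance counts by observed label
#'
#' `n_positive()`, `n_negative()` and `n_unlabeled()` count instances whose
#' observed label is positive, negative, or unlabeled (the sizes of P_L's
#' positive part, the labeled negatives, and U).
#'
#' @param x a `pu_dataset`.
#' @return An integer count.
#' @export
n_positive <- function(x) sum(x$observed == "positive")

#' @rdname n_positive
#' @export
n_negative <- function(x) sum(x$observed == "negative")

#' @rdname n_positive
#' @export
n_unlabeled <- function(x) sum(x$observed == "unlabeled")

#' The worked 20-instance example dataset
#'
#' A small two-feature dataset (weight, count) of 20 instances used throughout
#' the documentation and tests.  The `supervised` variant carries the full
#' labels (11 positive, 9 negative).  The `pu` variant keeps 8 instances
#' labeled positive and marks the remaining 12 unlabeled, while retaining the
#' supervised labels as hidden truth, so that relabeling can be checked
#' exactly.
#'
#' @param variant `"supervised"` (all labels observed) or `"pu"` (8 positive,
#'   12 unlabeled).
#' @return A `pu_dataset` of 20 instances.
#' @examples
#' toy <- toy_fixture("pu")
#' which(toy$observed == "positive")
#' @export
toy_fixture <- function(variant = c("pu", "supervised")) {
  variant <- match.arg(variant)
  feats <- data.frame(
    weight = c(1, 1, 2, 2, 2, 3, 4, 4, 4, 6, 6, 7, 8, 8, 8, 10, 10, 10, 11, 12),
    count  = c(6, 9, 1, 3, 10, 4, 2, 6, 7, 4, 11, 10, 2, 5, 8, 12, 5, 8, 10, 6))
  labels <- c("positive", "positive", "positive", "positive", "positive",
              "positive", "positive", "positive", "positive", "positive",
              "negative", "negative", "positive", "negative", "negative",
              "negative", "negative", "negative", "negative", "negative")
  if (variant == "supervised")
    return(pu_dataset(feats, observed = labels, truth = labels))
  keep <- c(1, 3, 5, 6, 7, 9, 10, 13)
  observed <- rep("unlabeled", 20)
  observed[keep] <- labels[keep]
  pu_dataset(feats, observed = observed, truth = labels)
}

#' Round half away from zero
#'
#' Commercial rounding at a given number of decimal digits: exact halves move
#' up, unlike [round()], which rounds half to even.  Used for the masked-count
#' rule (`round_half_up(ratio * n)` instances are masked) and for presenting
#' benchmark column means at two decimals.
#'
#' @param x numeric vector.
#' @param digits decimal digits to keep (default 0).
#' @return `x` rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(34.5)        # 35 (round() would give 34)
#' round_half_up(86.335, 2)   # 86.34
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # guard against representation error pushing an exact half just below .5
  trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale * sign(x)
}

#' Mask observed labels to simulate the PU setting
#'
#' Hides the labels of a uniformly drawn subset of instances, turning a fully
#' labeled dataset into a positive-unlabeled one.  Exactly
#' `round_half_up(ratio * n)` instances are selected without replacement by the
#' seeded generator regardless of their class; their observed label becomes
#' `"unlabeled"` while the true label is retained for evaluation.  The same
#' seed and ratio always select the same instances.
#'
#' @param x a fully labeled `pu_dataset` (no instance already unlabeled).
#' @param ratio fraction of instances to mask, in `[0, 1]`.
#' @param seed integer seed for the selection.
#' @return A `pu_dataset` with the selected instances unlabeled.
#' @examples
#' masked <- mask_labels(toy_fixture("supervised"), ratio = 0.25, seed = 1)
#' n_unlabeled(masked)
#' @export
mask_labels <- function(x, ratio, seed = 1L) {
  stopifnot(inherits(x, "pu_dataset"))
  if (!is.numeric(ratio) || length(ratio) != 1 || is.na(ratio) ||
      ratio < 0 || ratio > 1)
    stop("'ratio' must be a single number in [0, 1]", call. = FALSE)
  if (any(x$observed == "unlabeled"))
    stop("dataset already contains unlabeled instances", call. = FALSE)
  n <- length(x$ids)
  m <- round_half_up(ratio * n)
  if (m == 0) return(x)
  sel <- withr::with_seed(as.integer(seed), sample.int(n, m))
  observed <- x$observed
  observed[sel] <- "unlabeled"
  pu_dataset(x$features, observed = observed, truth = x$truth,
             ids = x$ids, positive_class = x$positive_class)
}
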