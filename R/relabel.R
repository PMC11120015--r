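#' Heterogeneous Euclidean distance between instances
#'
#' Distance used by the nearest-neighbor stage.  Each numeric feature
#' contributes the squared difference, divided by the feature's observed range
#' under `"minmax"` normalization (a zero-range feature contributes 0); each
#' categorical feature contributes 0 on a match and 1 on a mismatch; any
#' comparison involving a missing value contributes 1.  The distance is the
#' square root of the summed contributions, hence symmetric, non-negative and
#' zero exactly when every contribution is zero.
#'
#' @param x a `pu_dataset`.
#' @param i position of the query instance.
#' @param j position of a second instance, or `NULL` to return the distances
#'   from `i` to every instance (including the zero self-distance).
#' @param normalization `"minmax"` (default) or `"none"` (raw differences).
#' @return A single distance if `j` is given, otherwise a numeric vector of
#'   length `nrow(x$features)`.
#' @examples
#' toy <- toy_fixture("pu")
#' pu_distance(toy, 2, 5, normalization = "none")  # sqrt(2)
#' @export
pu_distance <- function(x, i, j = NULL, normalization = c("minmax", "none")) {
  normalization <- match.arg(normalization)
  d2 <- distance_sq_to_all(x, i, normalization)
  if (is.null(j)) sqrt(d2) else sqrt(d2[j])
}

# squared distances from instance i to all rows, vectorized over features
distance_sq_to_all <- function(x, i, normalization) {
  n <- nrow(x$features)
  acc <- numeric(n)
  for (spec in x$specs) {
    col <- x$features[[spec$name]]
    if (spec$kind == "numeric") {
      diff <- col - col[i]
      if (normalization == "minmax") {
        rng <- spec$range[2] - spec$range[1]
        # zero-range feature contributes nothing, but missingness still does
        diff <- if (is.na(rng) || rng == 0) diff * 0 else diff / rng
      }
      contrib <- diff^2
      contrib[is.na(contrib)] <- 1    # missing on either side
    } else {
      contrib <- as.numeric(col != col[i])
      contrib[is.na(contrib)] <- 1
    }
    acc <- acc + contrib
  }
  acc
}

#' k-nearest neighbors of an instance
#'
#' Finds the `k` instances of the dataset closest to the query under
#' [pu_distance()].  The query instance itself is always excluded from the
#' pool; with `pool = "positives"` the pool is further restricted to instances
#' whose observed label is positive.  Distance ties are broken toward the
#' smaller instance id, making the result deterministic.
#'
#' @param x a `pu_dataset` (the search set D).
#' @param i position of the query instance within `x`.
#' @param k number of neighbors (default 3).
#' @param pool `"all"` (default; all of D) or `"positives"` (labeled
#'   positives only).
#' @param normalization passed to [pu_distance()].
#' @return An object of class `knn_result`: a list with `query_id`, `ids`
#'   (neighbor ids, ascending by distance then id), `distances`, and
#'   `positions` (row positions of the neighbors in `x`).
#' @examples
#' k_nearest(toy_fixture("pu"), i = 2, k = 3)$ids  # 5, 1, 9
#' @export
k_nearest <- function(x, i, k = 3L, pool = c("all", "positives"),
                      normalization = c("minmax", "none")) {
  pool <- match.arg(pool)
  normalization <- match.arg(normalization)
  stopifnot(inherits(x, "pu_dataset"), length(i) == 1)
  k <- as.integer(k)
  if (k < 1) stop("'k' must be at least 1", call. = FALSE)
  cand <- setdiff(seq_along(x$ids), i)
  if (pool == "positives") cand <- cand[x$observed[cand] == "positive"]
  if (length(cand) < k)
    stop("neighbor pool (", length(cand), ") smaller than k = ", k,
         call. = FALSE)
  d <- sqrt(distance_sq_to_all(x, i, normalization))[cand]
  ord <- order(d, x$ids[cand])[seq_len(k)]
  structure(list(query_id = x$ids[i],
                 ids = x$ids[cand][ord],
                 distances = d[ord],
                 positions = cand[ord]),
            class = "knn_result")
}

#' Is an instance a strong positive?
#'
#' An unlabeled instance is a *strong positive instance* when every one of its
#' k nearest neighbors carries an observed positive label — a unanimous vote,
#' as opposed to the majority vote of ordinary k-NN classification.  A single
#' negative or unlabeled neighbor breaks unanimity.
#'
#' @param result a `knn_result` from [k_nearest()].
#' @param x the `pu_dataset` the query was run against.
#' @return `TRUE` if all neighbors are observed positive.
#' @export
is_strong_positive <- function(result, x) {
  stopifnot(inherits(result, "knn_result"), inherits(x, "pu_dataset"))
  all(x$observed[result$positions] == "positive")
}

#' Relabel unlabeled instances by unanimous-vote k-NN
#'
#' Stage 1 of the PU pipeline: each unlabeled instance is assigned the
#' positive class if it is a strong positive instance (all k nearest
#' neighbors in D observed positive) and the negative class otherwise,
#' splitting U into P_UL and N_UL.  The pass uses only the original observed
#' labels of D — assignments never cascade into later neighbor queries — and
#' leaves labeled instances untouched, so the output carries no unlabeled
#' instances and is invariant to instance storage order.
#'
#' @param x a `pu_dataset` with at least one observed positive instance.
#' @inheritParams k_nearest
#' @return A list of class `relabel_result`: `data` (the relabeled
#'   `pu_dataset`), `pul_ids` and `nul_ids` (ids assigned positive and
#'   negative), and `audit` (one `knn_result` per relabeled instance, the
#'   evidence for each decision).
#' @examples
#' res <- relabel_unlabeled(toy_fixture("pu"), k = 3)
#' res$pul_ids  # 2, 4, 8
#' @export
relabel_unlabeled <- function(x, k = 3L, pool = c("all", "positives"),
                              normalization = c("minmax", "none")) {
  pool <- match.arg(pool)
  normalization <- match.arg(normalization)
  stopifnot(inherits(x, "pu_dataset"))
  u <- which(x$observed == "unlabeled")
  if (length(u) == 0)
    return(structure(list(data = x, pul_ids = integer(0),
                          nul_ids = integer(0), audit = list()),
                     class = "relabel_result"))
  if (n_positive(x) < 1)
    stop("relabeling requires at least one observed positive instance",
         call. = FALSE)
  if (pool == "positives" && n_positive(x) < k)
    stop("pool 'positives' requires at least k observed positives",
         call. = FALSE)
  if (length(x$ids) < k + 1)
    stop("dataset must have at least k + 1 instances", call. = FALSE)
  audit <- vector("list", length(u))
  strong <- logical(length(u))
  for (m in seq_along(u)) {
    nb <- k_nearest(x, u[m], k = k, pool = pool, normalization = normalization)
    audit[[m]] <- nb
    strong[m] <- is_strong_positive(nb, x)
  }
  observed <- x$observed
  observed[u] <- ifelse(strong, "positive", "negative")
  out <- pu_dataset(x$features, observed = observed, truth = x$truth,
                    ids = x$ids, positive_class = x$positive_class,
                    check_consistency = FALSE)
  structure(list(data = out,
                 pul_ids = x$ids[u][strong],
                 nul_ids = x$ids[u][!strong],
                 audit = audit),
            class = "relabel_result")
}

#' @export
print.relabel_result <- function(x, ...) {
  cat(sprintf("relabel_result: %d unlabeled -> %d positive (P_UL), %d negative (N_UL)\n",
              length(x$pul_ids) + length(x$nul_ids),
              length(x$pul_ids), length(x$nul_ids)))
  invisible(x)
}
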