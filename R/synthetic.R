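#' Seeded Gaussian PU dataset generator
#'
#' Generates a two-class dataset with known ground truth for exercising the
#' whole pipeline without external data.  Numeric features are drawn from
#' class-conditional isotropic Gaussians whose centroids lie `separation`
#' within-class standard deviations apart; categorical features are drawn
#' from class-conditional category distributions (a skewed three-category
#' multinomial per class).  True labels are retained on every instance and
#' [mask_labels()] is applied at `mask_ratio` from the same seed stream, so
#' the dataset is fully reproducible per seed.
#'
#' @param n instance count (at least 10).
#' @param d_numeric number of numeric features (default 2).
#' @param d_categorical number of categorical features (default 0).
#' @param separation centroid distance in units of the within-class standard
#'   deviation (default 6).
#' @param positive_fraction fraction of positive instances, in (0, 1)
#'   (default 0.5).
#' @param mask_ratio fraction of labels hidden by masking (default 0.05).
#' @param seed integer seed.
#' @return A `pu_dataset` with `n` instances and full hidden truth.
#' @examples
#' d <- generate_gaussian_pu(n = 200, separation = 6, seed = 1)
#' n_unlabeled(d)  # 10
#' @export
generate_gaussian_pu <- function(n = 200L, d_numeric = 2L,
                                 d_categorical = 0L, separation = 6,
                                 positive_fraction = 0.5, mask_ratio = 0.05,
                                 seed = 1L) {
  n <- as.integer(n)
  if (n < 10) stop("'n' must be at least 10", call. = FALSE)
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("'positive_fraction' must be in (0, 1)", call. = FALSE)
  if (d_numeric + d_categorical < 1)
    stop("at least one feature is required", call. = FALSE)
  n_pos <- max(1L, round_half_up(positive_fraction * n))
  truth <- c(rep("positive", n_pos), rep("negative", n - n_pos))
  feats <- withr::with_seed(as.integer(seed), {
    cols <- list()
    if (d_numeric > 0) {
      # centroids +/- separation/2 along the diagonal unit vector
      offset <- separation / (2 * sqrt(d_numeric))
      for (j in seq_len(d_numeric)) {
        mu <- ifelse(truth == "positive", -offset, offset)
        cols[[paste0("x", j)]] <- stats::rnorm(n, mean = mu, sd = 1)
      }
    }
    if (d_categorical > 0) {
      cats <- c("a", "b", "c")
      p_pos <- c(0.6, 0.3, 0.1); p_neg <- c(0.1, 0.3, 0.6)
      for (j in seq_len(d_categorical)) {
        v <- character(n)
        v[truth == "positive"] <- sample(cats, sum(truth == "positive"),
                                         replace = TRUE, prob = p_pos)
        v[truth == "negative"] <- sample(cats, sum(truth == "negative"),
                                         replace = TRUE, prob = p_neg)
        cols[[paste0("c", j)]] <- v
      }
    }
    as.data.frame(cols, stringsAsFactors = FALSE)
  })
  d <- pu_dataset(feats, observed = truth, truth = truth)
  # masking draws from a seed derived from the dataset seed so feature
  # sampling and masking can each be regenerated independently
  if (mask_ratio > 0)
    d <- mask_labels(d, mask_ratio, seed = as.integer(seed) + 1000003L)
  d
}

#' Axis-aligned separable toy generator
#'
#' Produces a two-feature dataset with the threshold structure of the packaged
#' 20-instance example: instances are positive exactly in the low-weight
#' region (`weight <= 5`) or the low-count strip (`count <= 4`), so a depth-2
#' tree recovers the labels.  At `scale = 1` the output is the packaged
#' example itself, coordinates and masked subset included.  Larger scales add
#' `20 * (scale - 1)` seeded jittered copies of the base points (jitter
#' within ±0.1, small against the example's unit grid): copies of labeled
#' positives stay labeled positive, copies of true negatives join the masked
#' subset, preserving both the class balance and the example's geometry.  No
#' point crosses a decision boundary, every masked negative keeps an
#' unlabeled point among its nearest neighbors and every masked positive
#' keeps three labeled positives, so the unanimous-vote rule at `k = 3`
#' recovers all masked labels exactly, at any scale.
#'
#' @param scale size multiplier; the dataset has `20 * scale` instances.
#' @param seed integer seed for the jitter (unused at `scale = 1`).
#' @return A `pu_dataset` with hidden truth on every instance.
#' @export
generate_grid_toy <- function(scale = 1L, seed = 20L) {
  scale <- as.integer(scale)
  if (scale < 1) stop("'scale' must be at least 1", call. = FALSE)
  base <- toy_fixture("pu")
  if (scale == 1) return(base)
  n_extra <- 20L * (scale - 1L)
  labeled_pos <- which(base$observed == "positive")
  true_neg <- which(base$truth == "negative")
  # alternate positive/negative copies to keep the class balance of the base
  src <- integer(n_extra)
  src[seq(1, n_extra, by = 2)] <-
    rep_len(labeled_pos, length(seq(1, n_extra, by = 2)))
  src[seq(2, n_extra, by = 2)] <-
    rep_len(true_neg, length(seq(2, n_extra, by = 2)))
  extra <- withr::with_seed(as.integer(seed), {
    list(w = base$features$weight[src] + stats::runif(n_extra, -0.1, 0.1),
         cnt = base$features$count[src] + stats::runif(n_extra, -0.1, 0.1))
  })
  truth_extra <- base$truth[src]
  observed_extra <- ifelse(truth_extra == "positive", "positive", "unlabeled")
  pu_dataset(data.frame(weight = c(base$features$weight, extra$w),
                        count = c(base$features$count, extra$cnt)),
             observed = c(base$observed, observed_extra),
             truth = c(base$truth, truth_extra))
}

#' Fraction of masked labels recovered by relabeling
#'
#' Convenience wrapper measuring how well the unanimous-vote relabeling stage
#' restores hidden labels: it relabels the unlabeled instances and returns the
#' share whose assigned label equals the retained truth.
#'
#' @param x a `pu_dataset` with unlabeled instances and known truth.
#' @inheritParams relabel_unlabeled
#' @return A number in `[0, 1]` (NA when nothing is unlabeled).
#' @examples
#' recovery_rate(toy_fixture("pu"), k = 3)  # 1 on the worked example
#' @export
recovery_rate <- function(x, k = 3L, pool = c("all", "positives"),
                          normalization = c("minmax", "none")) {
  u <- which(x$observed == "unlabeled")
  if (length(u) == 0) return(NA_real_)
  res <- relabel_unlabeled(x, k = k, pool = match.arg(pool),
                           normalization = match.arg(normalization))
  mean(res$data$observed[u] == x$truth[u])
}
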