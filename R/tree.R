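#' Shannon entropy of class counts
#'
#' Impurity of a node: `-sum(p_i * log2(p_i))` over the class proportions
#' `p_i = counts_i / sum(counts)`, with the convention `0 * log2(0) = 0`.
#' Measured in bits; ranges from 0 (pure node) to `log2(m)` for `m` classes.
#'
#' @param counts non-negative class counts with a positive total.
#' @return Entropy in bits.
#' @examples
#' entropy(c(11, 9))   # 0.99277...
#' entropy(c(5, 5))    # exactly 1 bit
#' @export
entropy <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0)
    stop("'counts' must be non-negative with a positive total", call. = FALSE)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Expected entropy of a partition
#'
#' The size-weighted mean entropy of the child nodes produced by a candidate
#' split: `sum_j (|D_j|/|D|) * entropy(D_j)`.  Always non-negative and never
#' larger than the parent entropy.
#'
#' @param children list of per-child class-count vectors; their element-wise
#'   sum is the parent's counts.
#' @return Expected entropy in bits.
#' @examples
#' expected_entropy(list(c(9, 0), c(2, 9)))  # 0.37622...
#' @export
expected_entropy <- function(children) {
  sizes <- vapply(children, sum, 0)
  total <- sum(sizes)
  if (total <= 0) stop("empty parent", call. = FALSE)
  keep <- sizes > 0
  sum(vapply(children[keep], entropy, 0) * sizes[keep]) / total
}

#' Information gain of a partition
#'
#' Reduction in entropy achieved by splitting the parent into the given
#' children: `entropy(parent) - expected_entropy(children)`.  Non-negative on
#' empirical counts.
#'
#' @param parent class counts of the parent node.
#' @param children list of per-child class-count vectors partitioning
#'   `parent`.
#' @return Gain in bits.
#' @examples
#' information_gain(c(11, 9), list(c(9, 0), c(2, 9)))  # 0.61655...
#' @export
information_gain <- function(parent, children) {
  entropy(parent) - expected_entropy(children)
}

#' Gain ratio of a partition
#'
#' Information gain normalized by the split information (the entropy of the
#' child-size distribution), the C4.5 criterion that penalizes many-way
#' splits.  A partition whose split information is zero (a single non-empty
#' branch) carries no information and yields `NA`, signalling the candidate
#' should be skipped.
#'
#' @inheritParams information_gain
#' @return The gain ratio, or `NA` for a single-branch partition.
#' @examples
#' gain_ratio(c(11, 9), list(c(9, 0), c(2, 9)))  # 0.62104...
#' @export
gain_ratio <- function(parent, children) {
  sizes <- vapply(children, sum, 0)
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2) return(NA_real_)
  split_info <- entropy(sizes)
  if (split_info <= 0) return(NA_real_)
  information_gain(parent, children) / split_info
}

CLASS_LEVELS <- c("positive", "negative")

class_counts <- function(labels) {
  tab <- table(factor(labels, CLASS_LEVELS))
  stats::setNames(as.numeric(tab), CLASS_LEVELS)
}

#' Best split of a set of instances
#'
#' Enumerates every candidate split — for each numeric feature a binary
#' threshold at each midpoint between consecutive distinct sorted values, for
#' each categorical feature one multiway split over its observed categories —
#' and returns the candidate maximizing the criterion.  Under `"gain_ratio"`
#' the usual C4.5 guard applies: the ratio is compared only among candidates
#' whose information gain is at least the average gain of all positive-gain
#' candidates, which prevents near-empty branches with vanishing split
#' information from winning on an inflated ratio.  Ties are broken toward the
#' smaller feature index, then the smaller threshold.  Instances with a
#' missing value for a feature are left out of that feature's gain
#' computation.
#'
#' @param features data frame of feature columns.
#' @param labels class labels (`"positive"`/`"negative"`), one per row.
#' @param criterion `"gain_ratio"` (default, the C4.5 convention) or
#'   `"gain"`.
#' @param exclude names of categorical features already split on along the
#'   current path (each is used at most once per path).
#' @return A list describing the winning candidate (`feature`, `kind`,
#'   `threshold` or `categories`, `gain`, `gain_ratio`, `score`), or `NULL`
#'   when no candidate has positive gain.
#' @examples
#' toy <- toy_fixture("supervised")
#' best_split(toy$features, toy$observed)$threshold  # weight threshold 5
#' @export
best_split <- function(features, labels, criterion = c("gain_ratio", "gain"),
                       exclude = character(0)) {
  criterion <- match.arg(criterion)
  parent <- class_counts(labels)
  if (sum(parent > 0) < 2 || nrow(features) < 2) return(NULL)
  cands <- list()
  for (f in seq_along(features)) {
    nm <- names(features)[f]
    col <- features[[f]]
    ok <- !is.na(col)
    if (sum(ok) < 2) next
    if (is.numeric(col)) {
      vals <- sort(unique(col[ok]))
      if (length(vals) < 2) next
      thresholds <- (vals[-1] + vals[-length(vals)]) / 2
      for (t in thresholds) {
        children <- list(class_counts(labels[ok & col <= t]),
                         class_counts(labels[ok & col > t]))
        cand <- score_candidate(parent, children)
        if (!is.null(cand))
          cands[[length(cands) + 1]] <-
            c(list(feature = nm, index = f, kind = "numeric",
                   threshold = t), cand)
      }
    } else {
      if (nm %in% exclude) next
      cats <- sort(unique(col[ok]))
      if (length(cats) < 2) next
      children <- lapply(cats, function(cg) class_counts(labels[ok & col == cg]))
      cand <- score_candidate(parent, children)
      if (!is.null(cand))
        cands[[length(cands) + 1]] <-
          c(list(feature = nm, index = f, kind = "categorical",
                 categories = cats), cand)
    }
  }
  if (length(cands) == 0) return(NULL)
  if (criterion == "gain") {
    for (i in seq_along(cands)) cands[[i]]$score <- cands[[i]]$gain
  } else {
    # C4.5 guard: rank by gain ratio only among candidates whose gain is at
    # least the average positive gain; skip zero-split-information candidates
    avg_gain <- mean(vapply(cands, `[[`, 0, "gain"))
    cands <- Filter(function(cd) !is.na(cd$gain_ratio) &&
                      cd$gain >= avg_gain - 1e-12, cands)
    if (length(cands) == 0) return(NULL)
    for (i in seq_along(cands)) cands[[i]]$score <- cands[[i]]$gain_ratio
  }
  best <- NULL
  for (cd in cands) best <- better_candidate(best, cd)
  best
}

score_candidate <- function(parent, children) {
  g <- information_gain(parent, children)
  if (g <= 1e-12) return(NULL)            # "no candidate has gain > 0"
  list(gain = g, gain_ratio = gain_ratio(parent, children))
}

# tie-break: higher score, then smaller feature index, then smaller threshold
better_candidate <- function(best, cand) {
  if (is.null(best)) return(cand)
  if (cand$score > best$score + 1e-12) return(cand)
  if (cand$score < best$score - 1e-12) return(best)
  if (cand$index < best$index) return(cand)
  if (cand$index > best$index) return(best)
  tb <- !is.null(cand$threshold) && !is.null(best$threshold) &&
    cand$threshold < best$threshold
  if (tb) cand else best
}

#' Build an entropy-based decision tree
#'
#' Stage 2 of the PU pipeline: grows a classification tree on fully labeled
#' data by recursively applying [best_split()].  A node stops splitting when
#' it is pure, holds fewer than `2 * min_leaf` instances, reaches `max_depth`,
#' or no candidate has positive gain.  Each leaf predicts the majority class
#' of its instances; a tied leaf falls back to its parent's majority and
#' ultimately to the positive class.  During training, instances missing the
#' split feature are routed to the child with the larger non-missing count.
#'
#' @param x a `pu_dataset` with no unlabeled instances (run
#'   [relabel_unlabeled()] first in the PU setting).
#' @param criterion split criterion, `"gain_ratio"` (default) or `"gain"`.
#' @param min_leaf minimum node size worth splitting is `2 * min_leaf`
#'   (default `min_leaf = 2`).
#' @param max_depth maximum tree depth (`Inf` = unlimited; a lone leaf has
#'   depth 0).
#' @return An object of class `pu_tree`.
#' @examples
#' relab <- relabel_unlabeled(toy_fixture("pu"), k = 3)
#' tree <- build_tree(relab$data)
#' mean(predict(tree, relab$data) == relab$data$truth)  # 1 on the toy set
#' @export
build_tree <- function(x, criterion = c("gain_ratio", "gain"),
                       min_leaf = 2L, max_depth = Inf) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(x, "pu_dataset"))
  if (any(x$observed == "unlabeled"))
    stop("training data contains unlabeled instances; relabel first",
         call. = FALSE)
  if (length(x$ids) == 0) stop("empty training set", call. = FALSE)
  root <- grow_node(x$features, x$observed, criterion, min_leaf, max_depth,
                    depth = 0, parent_major = "positive",
                    exclude = character(0))
  structure(list(root = root,
                 specs = x$specs,
                 params = list(criterion = criterion,
                               min_leaf = as.integer(min_leaf),
                               max_depth = max_depth),
                 n_train = length(x$ids)),
            class = "pu_tree")
}

majority_class <- function(counts, parent_major) {
  if (counts[["positive"]] > counts[["negative"]]) return("positive")
  if (counts[["negative"]] > counts[["positive"]]) return("negative")
  parent_major
}

grow_node <- function(features, labels, criterion, min_leaf, max_depth,
                      depth, parent_major, exclude) {
  counts <- class_counts(labels)
  major <- majority_class(counts, parent_major)
  leaf <- list(type = "leaf", counts = counts, class = major)
  if (sum(counts > 0) < 2 || sum(counts) < 2 * min_leaf || depth >= max_depth)
    return(leaf)
  split <- best_split(features, labels, criterion = criterion,
                      exclude = exclude)
  if (is.null(split)) return(leaf)
  col <- features[[split$feature]]
  if (split$kind == "numeric") {
    groups <- ifelse(is.na(col), NA, ifelse(col <= split$threshold, 1L, 2L))
    ngroups <- 2L
  } else {
    groups <- match(col, split$categories)
    ngroups <- length(split$categories)
    exclude <- c(exclude, split$feature)
  }
  # missing (or unseen) values follow the most populated branch
  if (anyNA(groups)) {
    sizes <- tabulate(groups, nbins = ngroups)
    groups[is.na(groups)] <- which.max(sizes)
  }
  children <- lapply(seq_len(ngroups), function(g) {
    idx <- groups == g
    grow_node(features[idx, , drop = FALSE], labels[idx], criterion,
              min_leaf, max_depth, depth + 1, major, exclude)
  })
  list(type = "split", feature = split$feature, kind = split$kind,
       threshold = split$threshold, categories = split$categories,
       gain = split$gain, gain_ratio = split$gain_ratio,
       counts = counts, children = children)
}

#' Predict class labels with a decision tree
#'
#' Routes each instance from the root to a leaf and returns the leaf's class.
#' An instance missing the value tested at a split — or carrying a category
#' unseen in training — follows the child that received the most training
#' instances, so prediction is total: every conforming instance gets a label.
#'
#' @param object a `pu_tree`.
#' @param newdata a `pu_dataset` or a data frame with the training feature
#'   columns.
#' @param ... ignored.
#' @return Character vector of `"positive"`/`"negative"` labels.
#' @export
predict.pu_tree <- function(object, newdata, ...) {
  features <- if (inherits(newdata, "pu_dataset")) newdata$features else
    as.data.frame(newdata)
  missing_cols <- setdiff(names(object$specs), names(features))
  if (length(missing_cols))
    stop("newdata lacks feature column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  vapply(seq_len(nrow(features)), function(i)
    route_instance(object$root, features[i, , drop = FALSE]), "")
}

node_size <- function(node) sum(node$counts)

route_instance <- function(node, row) {
  while (node$type == "split") {
    v <- row[[node$feature]]
    child_id <- if (node$kind == "numeric") {
      if (is.na(v)) NA_integer_ else if (v <= node$threshold) 1L else 2L
    } else {
      if (is.na(v)) NA_integer_ else match(as.character(v), node$categories)
    }
    if (is.na(child_id))
      child_id <- which.max(vapply(node$children, node_size, 0))
    node <- node$children[[child_id]]
  }
  node$class
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(vapply(node$children, tree_depth, 0L))
}

count_nodes <- function(node) {
  if (node$type == "leaf") return(1L)
  1L + sum(vapply(node$children, count_nodes, 0L))
}

#' @export
print.pu_tree <- function(x, ...) {
  cat(sprintf("pu_tree: %d nodes, depth %d, trained on %d instances (%s)\n",
              count_nodes(x$root), tree_depth(x$root), x$n_train,
              x$params$criterion))
  print_node(x$root, indent = "")
  invisible(x)
}

print_node <- function(node, indent) {
  if (node$type == "leaf") {
    cat(sprintf("%sleaf: %s (%d positive / %d negative)\n", indent,
                node$class, node$counts[["positive"]],
                node$counts[["negative"]]))
  } else {
    if (node$kind == "numeric") {
      cat(sprintf("%s%s <= %g:\n", indent, node$feature, node$threshold))
      print_node(node$children[[1]], paste0(indent, "  "))
      cat(sprintf("%s%s > %g:\n", indent, node$feature, node$threshold))
      print_node(node$children[[2]], paste0(indent, "  "))
    } else {
      for (ci in seq_along(node$categories)) {
        cat(sprintf("%s%s = %s:\n", indent, node$feature,
                    node$categories[ci]))
        print_node(node$children[[ci]], paste0(indent, "  "))
      }
    }
  }
}

#' Serialize a decision tree to JSON
#'
#' Writes the full tree — structure, thresholds, class counts, and training
#' metadata — as a JSON document; [tree_from_json()] restores a `pu_tree`
#' whose predictions are identical.
#'
#' @param tree a `pu_tree`.
#' @param path optional file path; with `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "pu_tree"))
  doc <- list(format = "npulud_tree", version = 1L,
              params = tree$params, n_train = tree$n_train,
              specs = unname(tree$specs), root = tree$root)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' Restore a decision tree from JSON
#'
#' @param input a path to a JSON file written by [tree_to_json()], or the
#'   JSON text itself.
#' @return A `pu_tree`.
#' @export
tree_from_json <- function(input) {
  doc <- tryCatch(jsonlite::fromJSON(input, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed tree document: ", conditionMessage(e),
                         call. = FALSE))
  if (!identical(doc$format, "npulud_tree") || is.null(doc$root))
    stop("malformed tree document: not a serialized tree", call. = FALSE)
  specs <- doc$specs
  for (s in seq_along(specs)) {
    specs[[s]]$range <- unlist(specs[[s]]$range)
    specs[[s]]$categories <- unlist(specs[[s]]$categories)
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  params <- doc$params
  if (is.null(params$max_depth)) params$max_depth <- Inf
  structure(list(root = rebuild_node(doc$root), specs = specs,
                 params = params, n_train = doc$n_train),
            class = "pu_tree")
}

rebuild_node <- function(node) {
  node$counts <- unlist(node$counts)
  if (identical(node$type, "split")) {
    node$categories <- unlist(node$categories)
    node$children <- lapply(node$children, rebuild_node)
  }
  node
}
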