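#' Read a PU dataset from a CSV or ARFF file
#'
#' Reads a tabular binary-classification dataset whose label column contains
#' the positive class value, at most one other (negative) value, and an
#' unlabeled marker.  Feature kinds are inferred: a column is numeric when all
#' its non-missing entries parse as numbers, categorical otherwise.  `"?"` and
#' empty cells are treated as missing values and never imputed.
#'
#' @param path path to the file.
#' @param format `"csv"` (comma-separated, header row required) or `"arff"`
#'   (read via [foreign::read.arff()]; nominal attributes map to categorical
#'   features).
#' @param label_column name of the class column.
#' @param positive_class raw label value mapped to `"positive"`.
#' @param unlabeled_token raw label value mapped to `"unlabeled"`
#'   (default `"unlabeled"`).
#' @return A `pu_dataset`.  True labels are set equal to the observed labels
#'   (`"unknown"` for unlabeled rows).
#' @seealso [write_pu_csv()] for the inverse operation.
#' @export
read_pu_table <- function(path, format = c("csv", "arff"), label_column,
                          positive_class, unlabeled_token = "unlabeled") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (format == "csv") {
    if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = c("?", ""), fileEncoding = "UTF-8")
  } else {
    df <- foreign::read.arff(path)
    for (j in seq_along(df))
      if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
    df
  }
  if (nrow(raw) == 0) stop("empty file: ", path, call. = FALSE)
  if (!label_column %in% names(raw))
    stop("label column '", label_column, "' not found", call. = FALSE)
  lab <- as.character(raw[[label_column]])
  feats <- raw[, setdiff(names(raw), label_column), drop = FALSE]
  # numeric inference for character columns (ARFF already types numerics)
  for (j in seq_along(feats)) {
    x <- feats[[j]]
    if (is.character(x)) {
      num <- suppressWarnings(as.numeric(x))
      if (!any(is.na(num) & !is.na(x))) feats[[j]] <- num
    }
  }
  other <- setdiff(unique(lab[!is.na(lab)]), c(positive_class, unlabeled_token))
  if (length(other) > 1)
    stop("label column has more than two classes: ",
         paste(c(positive_class, other), collapse = ", "), call. = FALSE)
  observed <- ifelse(lab == positive_class, "positive",
                     ifelse(lab == unlabeled_token, "unlabeled", "negative"))
  pu_dataset(feats, observed = observed, positive_class = positive_class)
}

#' Write a PU dataset to CSV
#'
#' Writes the feature columns and the observed label column (raw positive
#' class value restored; unlabeled instances written as `unlabeled_token`).
#' With `truth_column` set, the hidden true label is written in an extra
#' column so a masked dataset round-trips losslessly.  Numeric values are
#' written with full precision so that `read_pu_table()` recovers them
#' bit-identically.
#'
#' @param x a `pu_dataset`.
#' @param path output path.
#' @param label_column name for the class column (default `"class"`).
#' @param unlabeled_token value written for unlabeled instances.
#' @param negative_class value written for negative instances (default
#'   `"negative"`).
#' @param truth_column optional name for a true-label column; `NULL` (default)
#'   omits it.
#' @return `path`, invisibly.
#' @export
write_pu_csv <- function(x, path, label_column = "class",
                         unlabeled_token = "unlabeled",
                         negative_class = "negative",
                         truth_column = NULL) {
  stopifnot(inherits(x, "pu_dataset"))
  out <- x$features
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- vapply(out[[j]], function(z)
        if (is.na(z)) NA_character_ else format(z, digits = 17), "")
      out[[j]] <- v
    }
    out[[j]][is.na(out[[j]])] <- "?"
  }
  out[[label_column]] <- ifelse(x$observed == "positive", x$positive_class,
                                ifelse(x$observed == "unlabeled",
                                       unlabeled_token, negative_class))
  if (!is.null(truth_column))
    out[[truth_column]] <- ifelse(x$truth == "positive", x$positive_class,
                                  ifelse(x$truth == "unknown", "?",
                                         negative_class))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Published benchmark summaries shipped with the package
#'
#' Loads one of the reference benchmark tables distributed with the package
#' as plain TSV files: per-dataset accuracies of a plain supervised decision
#' tree versus the PU pipeline on 24 public datasets
#' (`"accuracy_dt_vs_npulud"`), per-dataset PU-pipeline accuracies across
#' label-masking ratios 5--20\% (`"accuracy_by_mask_ratio"`), and per-dataset
#' F-measures of four earlier PU learners alongside the PU pipeline
#' (`"fmeasure_pul_methods"`).  These published values serve as inputs to the
#' aggregation and paired-comparison helpers; they are reference results, not
#' outputs of this package.
#'
#' @param name one of `"accuracy_dt_vs_npulud"`, `"accuracy_by_mask_ratio"`,
#'   `"fmeasure_pul_methods"`.
#' @return A data frame with one row per dataset.
#' @examples
#' acc <- benchmark_fixture("accuracy_dt_vs_npulud")
#' colMeans(acc[, c("dt", "npulud")])
#' @export
benchmark_fixture <- function(name = c("accuracy_dt_vs_npulud",
                                       "accuracy_by_mask_ratio",
                                       "fmeasure_pul_methods")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("benchmark_", name, ".tsv"),
                      package = "npulud", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
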