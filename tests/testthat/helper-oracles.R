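# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals: plain loops over all pairs.

# squared per-feature contributions summed over columns, then sqrt
oracle_distance <- function(d, i, j, normalization = "minmax") {
  total <- 0
  for (nm in names(d$features)) {
    a <- d$features[[nm]][i]; b <- d$features[[nm]][j]
    if (is.na(a) || is.na(b)) { total <- total + 1; next }
    if (is.numeric(d$features[[nm]])) {
      diff <- a - b
      if (normalization == "minmax") {
        rng <- diff(range(d$features[[nm]], na.rm = TRUE))
        diff <- if (rng == 0) 0 else diff / rng
      }
      total <- total + diff^2
    } else {
      total <- total + as.numeric(a != b)
    }
  }
  sqrt(total)
}

# full sort of all pairwise distances, ties toward the smaller id
oracle_knn <- function(d, i, k, pool = "all", normalization = "minmax") {
  cand <- setdiff(seq_along(d$ids), i)
  if (pool == "positives") cand <- cand[d$observed[cand] == "positive"]
  dist <- vapply(cand, function(j) oracle_distance(d, i, j, normalization), 0)
  ord <- order(dist, d$ids[cand])
  list(ids = d$ids[cand][ord][seq_len(k)], distances = dist[ord][seq_len(k)])
}

oracle_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# enumerate every (feature, threshold) binary split and every categorical
# multiway split; return the best criterion value reached by any candidate
oracle_best_score <- function(features, labels, criterion = "gain") {
  parent <- table(factor(labels, c("positive", "negative")))
  hp <- oracle_entropy(as.numeric(parent))
  best <- -Inf
  n <- length(labels)
  for (f in seq_along(features)) {
    col <- features[[f]]
    if (is.numeric(col)) {
      vals <- sort(unique(col))
      if (length(vals) < 2) next
      for (t in (vals[-1] + vals[-length(vals)]) / 2) {
        grp <- col <= t
        sizes <- c(sum(grp), sum(!grp))
        he <- sum(vapply(list(labels[grp], labels[!grp]), function(l)
          oracle_entropy(as.numeric(table(factor(l, c("positive", "negative"))))),
          0) * sizes) / n
        g <- hp - he
        if (g <= 1e-12) next
        score <- if (criterion == "gain") g else g / oracle_entropy(sizes)
        best <- max(best, score)
      }
    } else {
      cats <- sort(unique(col))
      if (length(cats) < 2) next
      sizes <- vapply(cats, function(cg) sum(col == cg), 0)
      he <- sum(vapply(cats, function(cg)
        oracle_entropy(as.numeric(table(factor(labels[col == cg],
                                               c("positive", "negative"))))),
        0) * sizes) / n
      g <- hp - he
      if (g <= 1e-12) next
      score <- if (criterion == "gain") g else g / oracle_entropy(sizes)
      best <- max(best, score)
    }
  }
  if (is.finite(best)) best else NA_real_
}
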