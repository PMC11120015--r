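test_that("entropy, expected entropy, gain and gain ratio match closed forms", {
  # parent split of the worked example: 11 positive, 9 negative
  expect_equal(entropy(c(11, 9)), 0.9927744539878083, tolerance = 1e-12)
  expect_equal(entropy(c(10, 0)), 0)
  expect_equal(entropy(c(5, 5)), 1)
  expect_error(entropy(c(0, 0)), "positive total")

  children <- list(c(9, 0), c(2, 9))      # weight <= 5 on the supervised toy
  expect_equal(expected_entropy(children), 11 / 20 * entropy(c(2, 9)),
               tolerance = 1e-12)
  expect_equal(expected_entropy(children), 0.376221139601473,
               tolerance = 1e-9)
  expect_equal(expected_entropy(list(c(11, 9))), entropy(c(11, 9)))
  expect_equal(information_gain(c(11, 9), children), 0.6165533143863353,
               tolerance = 1e-9)
  expect_equal(information_gain(c(11, 9), list(c(11, 9))), 0)
  # perfect separation recovers the whole parent entropy
  expect_equal(information_gain(c(11, 9), list(c(11, 0), c(0, 9))),
               entropy(c(11, 9)))
  expect_equal(gain_ratio(c(11, 9), children),
               0.6165533143863353 / entropy(c(9, 11)), tolerance = 1e-9)
  expect_equal(gain_ratio(c(11, 9), children), 0.6210406723397688,
               tolerance = 1e-9)
  # 50/50 partition has exactly 1 bit of split information
  expect_equal(gain_ratio(c(6, 6), list(c(6, 0), c(0, 6))), 1)
  expect_true(is.na(gain_ratio(c(5, 5), list(c(5, 5)))))
  # entropy invariant under class permutation, bounded by log2(m)
  for (cnt in list(c(3, 7), c(1, 1, 8), c(2, 5, 9, 4))) {
    expect_equal(entropy(cnt), entropy(rev(cnt)))
    expect_gte(entropy(cnt), 0)
    expect_lte(entropy(cnt), log2(length(cnt)) + 1e-12)
  }
})

test_that("best_split finds the weight threshold of the worked example", {
  sup <- toy_fixture("supervised")
  for (crit in c("gain", "gain_ratio")) {
    bs <- best_split(sup$features, sup$observed, criterion = crit)
    expect_equal(bs$feature, "weight")
    expect_gt(bs$threshold, 4)
    expect_lt(bs$threshold, 6)
  }
  # degenerate inputs
  same <- data.frame(x = rep(1, 6))
  expect_null(best_split(same, rep(c("positive", "negative"), 3)))
  # one feature separating the classes: gain equals parent entropy
  sep <- data.frame(x = c(1, 1, 2, 2))
  bs <- best_split(sep, c("positive", "positive", "negative", "negative"),
                   criterion = "gain")
  expect_equal(bs$threshold, 1.5)
  expect_equal(bs$gain, 1)
})

test_that("best_split under gain matches brute-force enumeration", {
  sets <- list(generate_gaussian_pu(n = 120, d_numeric = 2, d_categorical = 1,
                                    separation = 1.5, mask_ratio = 0,
                                    seed = 3),
               generate_gaussian_pu(n = 200, d_numeric = 3, separation = 0.5,
                                    mask_ratio = 0, seed = 8))
  for (d in sets) {
    bs <- best_split(d$features, d$observed, criterion = "gain")
    ref <- oracle_best_score(d$features, d$observed, criterion = "gain")
    expect_equal(bs$gain, ref, tolerance = 1e-12)
  }
})

test_that("every candidate gain evaluated on random data is non-negative", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(4:40, 1)
      labels <- sample(c("positive", "negative"), n, replace = TRUE)
      feats <- data.frame(x = rnorm(n), g = sample(letters[1:3], n, TRUE))
      parent <- table(factor(labels, c("positive", "negative")))
      if (min(parent) == 0) next
      bs <- best_split(feats, labels, criterion = "gain")
      if (!is.null(bs)) expect_gte(bs$gain, -1e-12)
    }
  })
})

test_that("tree on the relabeled toy set matches the narrative structure", {
  res <- relabel_unlabeled(toy_fixture("pu"), k = 3)
  tree <- build_tree(res$data)
  # root: weight threshold between 4 and 6
  expect_equal(tree$root$feature, "weight")
  expect_gt(tree$root$threshold, 4)
  expect_lt(tree$root$threshold, 6)
  # low-weight branch is a pure positive leaf; high-weight branch splits on
  # count with the count <= 4 side positive and the other side negative
  left <- tree$root$children[[1]]
  expect_equal(left$type, "leaf")
  expect_equal(left$class, "positive")
  right <- tree$root$children[[2]]
  expect_equal(right$feature, "count")
  expect_gt(right$threshold, 4)
  expect_lt(right$threshold, 5)
  expect_equal(right$children[[1]]$class, "positive")
  expect_equal(right$children[[2]]$class, "negative")
  # classifies all 20 training instances correctly
  expect_equal(predict(tree, res$data), res$data$truth)
  # sum of leaf counts equals the training size
  expect_equal(sum(tree$root$counts), 20)
})

test_that("predict follows the narrative rules and handles edge routing", {
  tree <- build_tree(relabel_unlabeled(toy_fixture("pu"), k = 3)$data)
  expect_equal(predict(tree, data.frame(weight = 3, count = 4)), "positive")
  expect_equal(predict(tree, data.frame(weight = 10, count = 8)), "negative")
  expect_equal(predict(tree, data.frame(weight = 10, count = 2)), "positive")
  # missing value at a split follows the largest child (11 of 20 go right)
  expect_equal(predict(tree, data.frame(weight = NA, count = 8)), "negative")
  # single-class training set collapses to one leaf
  pure <- pu_dataset(data.frame(x = 1:5), observed = rep("positive", 5))
  t1 <- build_tree(pure)
  expect_equal(t1$root$type, "leaf")
  expect_equal(predict(t1, data.frame(x = 100)), "positive")
  # contradictory duplicates cannot be split; tie falls back to positive
  dup <- pu_dataset(data.frame(x = c(1, 1)),
                    observed = c("positive", "negative"))
  t2 <- build_tree(dup)
  expect_equal(t2$root$type, "leaf")
  expect_equal(t2$root$class, "positive")
  expect_error(build_tree(toy_fixture("pu")), "unlabeled")
})

test_that("categorical splits are multiway, used once per path, with fallback
           routing for unseen categories", {
  d <- pu_dataset(
    data.frame(color = c("r", "r", "g", "g", "b", "b", "b"),
               x = c(1, 2, 1, 2, 1, 2, 3)),
    observed = c("positive", "positive", "negative", "negative",
                 "positive", "positive", "negative"))
  tree <- build_tree(d, min_leaf = 1)
  expect_equal(tree$root$feature, "color")
  expect_equal(tree$root$kind, "categorical")
  expect_length(tree$root$children, 3)
  # unseen category routes to the largest child ("b", 3 instances)
  expect_equal(predict(tree, data.frame(color = "purple", x = 1)),
               predict(tree, data.frame(color = "b", x = 1)))
})

test_that("unpruned trees reach 100% training accuracy on duplicate-free data", {
  for (seed in c(2, 7)) {
    d <- generate_gaussian_pu(n = 80, d_numeric = 2, separation = 1,
                              mask_ratio = 0, seed = seed)
    tree <- build_tree(d, min_leaf = 1)
    expect_equal(mean(predict(tree, d) == d$observed), 1)
  }
})

test_that("JSON serialization round-trips structure and predictions", {
  res <- relabel_unlabeled(toy_fixture("pu"), k = 3)
  tree <- build_tree(res$data)
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, path)
  back <- tree_from_json(path)
  expect_equal(predict(back, res$data), predict(tree, res$data))
  expect_equal(back$root$threshold, tree$root$threshold)
  expect_equal(back$params$criterion, tree$params$criterion)
  expect_equal(npulud:::count_nodes(back$root), npulud:::count_nodes(tree$root))
  # categorical trees round-trip too
  dc <- pu_dataset(data.frame(g = c("a", "a", "b", "b"), x = c(1, 2, 3, 4)),
                   observed = c("positive", "positive", "negative",
                                "negative"))
  tc <- build_tree(dc, min_leaf = 1)
  bc <- tree_from_json(tree_to_json(tc))
  expect_equal(predict(bc, dc), predict(tc, dc))
  # malformed documents are rejected
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(tree_to_json(tree), 1, 50), bad)
  expect_error(tree_from_json(bad), "malformed")
  writeLines('{"some": "json"}', bad)
  expect_error(tree_from_json(bad), "malformed")
})
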