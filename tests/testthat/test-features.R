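two_feature_table <- function() {
  feature_table(
    list(f1 = c("a", "b"), f2 = "c"),
    matrix(c("10", "11", NA, "1"), 2, 2,
           dimnames = list(c("x", "y"), c("f1", "f2"))))
}

test_that("the hand-worked index values are reproduced", {
  ft <- feature_table(list(f1 = c("a", "b")),
                      matrix(c("10", "11"), 2, 1,
                             dimnames = list(c("x", "y"), "f1")))
  res <- tanimoto_similarity(ft, "x", "y")
  expect_equal(res$numerator, 1)
  expect_equal(res$denominator, 2)
  expect_equal(res$similarity, 0.5)

  # half-known feature adds 0.5 to the denominator only
  res2 <- tanimoto_similarity(two_feature_table(), "x", "y")
  expect_equal(res2$numerator, 1)
  expect_equal(res2$denominator, 2.5)
  expect_equal(res2$similarity, 0.4)
  expect_equal(res2$distance, 0.6)
})

test_that("self-similarity is 1 with all features known; both-unknown features are skipped", {
  ft <- rand_feature_table(4, unknown_rate = 0, seed = 2)
  g <- rownames(ft$values)[1]
  expect_equal(tanimoto_similarity(ft, g, g)$similarity, 1.0)

  both_u <- feature_table(list(f1 = "a", f2 = "b"),
                          matrix(c(NA, NA, "1", "1"), 2, 2,
                                 dimnames = list(c("x", "y"),
                                                 c("f1", "f2"))))
  res <- tanimoto_similarity(both_u, "x", "y")
  expect_equal(res$features_skipped, "f1")
  expect_equal(res$similarity, 1)
})

test_that("the index is symmetric and matches the set-based oracle with unknowns", {
  for (s in 1:20) {
    ft <- rand_feature_table(6, unknown_rate = 0.25, seed = 200 + s)
    gs <- sample(rownames(ft$values), 2)
    o <- oracle_tanimoto(ft, gs[1], gs[2])
    if (is.na(o)) {
      expect_error(tanimoto_similarity(ft, gs[1], gs[2]), "undefined")
    } else {
      expect_equal(tanimoto_similarity(ft, gs[1], gs[2])$similarity, o)
      expect_equal(tanimoto_similarity(ft, gs[2], gs[1])$similarity, o)
    }
  }
})

test_that("with no unknowns and single-bit features the index is classical Jaccard", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      n_feat <- 8
      features <- setNames(as.list(sprintf("s%d", 1:n_feat)),
                           sprintf("f%d", 1:n_feat))
      vx <- rbinom(n_feat, 1, 0.5); vy <- rbinom(n_feat, 1, 0.5)
      if (sum(vx | vy) == 0) vx[1] <- 1
      vals <- rbind(x = as.character(vx), y = as.character(vy))
      colnames(vals) <- names(features)
      ft <- feature_table(features, vals)
      jacc <- sum(vx & vy) / sum(vx | vy)
      expect_equal(tanimoto_similarity(ft, "x", "y")$similarity, jacc)
    }
  })
})

test_that("adding a feature known in exactly one strain dilutes similarity", {
  ft0 <- feature_table(list(f1 = c("a", "b")),
                       matrix(c("11", "11"), 2, 1,
                              dimnames = list(c("x", "y"), "f1")))
  base <- tanimoto_similarity(ft0, "x", "y")$similarity
  ft1 <- feature_table(list(f1 = c("a", "b"), f2 = "c"),
                       matrix(c("11", "11", "1", NA), 2, 2,
                              dimnames = list(c("x", "y"), c("f1", "f2"))))
  expect_lt(tanimoto_similarity(ft1, "x", "y")$similarity, base)
})

test_that("feature distance matrices agree with elementwise recomputation and respect clades", {
  for (s in 1:5) {
    ft <- rand_feature_table(5, unknown_rate = 0.1, seed = 300 + s)
    d <- tryCatch(feature_distance_matrix(ft), error = function(e) NULL)
    if (is.null(d)) next
    g <- rownames(ft$values)
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(d[i, j], 1 - oracle_tanimoto(ft, g[i], g[j]))
  }

  clades <- list(K1 = c("a1", "a2", "a3"), K2 = c("b1", "b2", "b3"))
  gen <- gen_feature_table(clades, unknown_rate = 0, seed = 5)
  d <- feature_distance_matrix(gen$table)
  within <- c(d["a1", "a2"], d["a1", "a3"], d["b1", "b2"])
  between <- c(d["a1", "b1"], d["a2", "b2"], d["a3", "b3"])
  expect_equal(max(within), 0)          # identical fingerprints inside a clade
  expect_gt(mean(between), mean(within))
})

test_that("undefined pairs abort matrix construction unless a substitute is allowed", {
  ft <- feature_table(list(f1 = "a"),
                      matrix(c(NA, NA, "1"), 3, 1,
                             dimnames = list(c("x", "y", "z"), "f1")))
  expect_error(feature_distance_matrix(ft), "x/y")
  d <- feature_distance_matrix(ft, allow_missing = TRUE)
  expect_equal(d["x", "y"], 1)
})

test_that("known-info counts track the unknown mask exactly", {
  ft <- two_feature_table()
  expect_equal(known_info_counts(ft), c(f1 = 2L, f2 = 1L))
  gen <- gen_feature_table(list(K = sprintf("g%d", 1:10)),
                           unknown_rate = 0.3, seed = 6)
  expect_equal(unname(known_info_counts(gen$table)),
               unname(colSums(!gen$truth$unknown_mask)))
})

test_that("feature tables round-trip through the TSV format", {
  ft <- rand_feature_table(5, unknown_rate = 0.2, seed = 9)
  f <- withr::local_tempfile()
  write_feature_table(ft, f)
  back <- read_feature_table(f, ft$features)
  expect_equal(back$values, ft$values)
})

test_that("inference rules fill unknowns explicitly and only unknowns", {
  ft <- feature_table(
    list(morphology = c("unicellular", "filamentous"), heterocysts = "het"),
    matrix(c("10", "01", "10", NA, NA, "1"), 3, 2,
           dimnames = list(c("u1", "f1", "u2"),
                           c("morphology", "heterocysts"))))
  rules <- data.frame(when = "morphology", has = "unicellular",
                      then = "heterocysts", value = "0")
  out <- apply_inference_rules(ft, rules)
  expect_equal(out$values["u1", "heterocysts"], "0")   # filled
  expect_true(is.na(out$values["f1", "heterocysts"])) # rule does not fire
  expect_equal(out$values["u2", "heterocysts"], "1")   # known value untouched
})
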