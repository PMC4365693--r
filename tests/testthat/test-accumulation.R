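test_that("rarefaction endpoints are exact: n=G core equals CORE, n=1 pan is genome CLOG count", {
  g <- gen_pan_genome(pan_genome_spec(6, core_count = 12,
                                      dispensable_count = 30,
                                      unique_rate = 3), seed = 4)
  cls <- classify_clogs(g$table)
  curve <- rarefy(g$table, repetitions = 50, seed = 9)
  expect_true(all(curve$core[["6"]] == cls$counts[["core"]]))
  per_genome <- colSums(cyanopan:::presence_matrix(g$table))
  expect_true(all(curve$pan[["1"]] %in% per_genome))
  expect_true(all(sort(unique(curve$pan[["1"]])) %in% sort(unique(per_genome))))
})

test_that("rarefaction means match exhaustive subset enumeration for small G", {
  tab <- rand_clog_table(6, 40, seed = 21)
  oracle <- oracle_rarefaction_means(tab)
  curve <- rarefy(tab, repetitions = 1000, seed = 1)   # > choose(6,3): exhaustive
  expect_equal(vapply(curve$core, mean, numeric(1)), oracle$core,
               ignore_attr = TRUE)
  expect_equal(vapply(curve$pan, mean, numeric(1)), oracle$pan,
               ignore_attr = TRUE)
})

test_that("nested sampling keeps core non-increasing and pan non-decreasing per replicate", {
  tab <- rand_clog_table(8, 60, seed = 31)
  curve <- rarefy(tab, repetitions = 30, seed = 2, nested = TRUE)
  core_mat <- do.call(cbind, curve$core)
  pan_mat <- do.call(cbind, curve$pan)
  expect_true(all(apply(core_mat, 1, function(v) all(diff(v) <= 0))))
  expect_true(all(apply(pan_mat, 1, function(v) all(diff(v) >= 0))))
})

test_that("new-genes steps obey the pan conservation law per ordering", {
  tab <- rand_clog_table(7, 50, seed = 41)
  nc <- new_genes_per_step(tab, permutations = 40, seed = 3)
  total <- n_clogs(tab)
  # every ordering eventually discovers the whole pan-genome
  expect_true(all(rowSums(nc$new) == total))
})

test_that("new-genes means match exhaustive enumeration of all orderings (G = 5)", {
  tab <- rand_clog_table(5, 30, seed = 51)
  nc <- new_genes_per_step(tab, permutations = 200, seed = 4)  # 120 orderings
  expect_equal(nrow(nc$new), 120)
  expect_equal(nc$mean, oracle_new_genes_means(tab), ignore_attr = TRUE)
})

test_that("degenerate tables give flat or zero new-gene curves", {
  # disjoint genomes: new(n) is always that genome's own CLOG count
  tab <- clog_table(data.frame(
    clog_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
    genome_id = c("A", "A", "B", "B", "B", "C"),
    gene_id = paste0("g", 1:6)))
  nc <- new_genes_per_step(tab, permutations = 10, seed = 5)
  expect_true(all(sort(unique(as.vector(nc$new))) %in% c(1, 2, 3)))
  expect_true(all(rowSums(nc$new) == 6))
  # identical CLOG membership everywhere: new(n) = 0 for n >= 2
  tab2 <- clog_table(data.frame(
    clog_id = rep(c("c1", "c2"), each = 3),
    genome_id = rep(c("A", "B", "C"), 2),
    gene_id = paste0("g", 1:6)))
  nc2 <- new_genes_per_step(tab2, permutations = 10, seed = 6)
  expect_true(all(nc2$new[, -1] == 0))
})

test_that("power-law fit recovers a noiseless exponent exactly", {
  curve <- data.frame(n = 1:20, mean = 100 * (1:20)^-0.5)
  fit <- fit_power_law(curve)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-9)
  expect_equal(fit$kappa, 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$open)
})

test_that("power-law fit drops non-positive points and errors below 3 points", {
  curve <- data.frame(n = 1:4, mean = c(10, 5, 0, 2))
  expect_warning(fit_power_law(curve, n_min = 1), "non-positive")
  expect_error(suppressWarnings(fit_power_law(
    data.frame(n = 1:3, mean = c(4, 0, 1)), n_min = 1)), "fewer than 3")
})

test_that("bootstrap alpha_sd is reproducible and non-negative", {
  g <- gen_pan_genome(pan_genome_spec(10, core_count = 20,
                                      dispensable_count = 100,
                                      unique_rate = 10), seed = 8)
  nc <- new_genes_per_step(g$table, permutations = 50, seed = 9)
  f1 <- fit_power_law(nc, bootstrap = 50, seed = 10)
  f2 <- fit_power_law(nc, bootstrap = 50, seed = 10)
  expect_identical(f1$alpha_sd, f2$alpha_sd)
  expect_gte(f1$alpha_sd, 0)
})

test_that("clade core ratio is 1 for the full universe and detects planted clade cores", {
  clade <- c("G01", "G02", "G03", "G04")
  spec <- pan_genome_spec(8, core_count = 15, dispensable_count = 40,
                          unique_rate = 2,
                          clade_extras = list(list(genomes = clade,
                                                   count = 10)))
  g <- gen_pan_genome(spec, seed = 12)
  curve <- rarefy(g$table, repetitions = 300, seed = 13)
  full <- core_ratio(g$table, g$table$genomes, curve)
  expect_equal(full$ratio, 1.0)
  res <- core_ratio(g$table, clade, curve)
  # direct arithmetic on generator truth: observed core of the clade
  p <- cyanopan:::presence_matrix(g$table)
  obs <- sum(rowSums(p[, clade]) == length(clade))
  expect_equal(res$observed, obs)
  expect_gt(res$ratio, 1)
  expect_error(core_ratio(g$table, "G01", curve), "at least 2")
})
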