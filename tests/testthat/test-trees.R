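test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  pm <- patristic_matrix(tr)
  expect_equal(pm[rownames(d), colnames(d)], d, tolerance = 1e-12)
  lens <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ recovers topology and branch lengths exactly from additive matrices", {
  for (s in 1:15) {
    sim <- rand_additive_matrix(sample(4:20, 1), seed = 400 + s)
    tr <- neighbor_joining(sim$d)
    pm <- patristic_matrix(tr)[rownames(sim$d), colnames(sim$d)]
    expect_lt(max(abs(pm - sim$d)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(sim$tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ agrees with an independent implementation on non-additive matrices", {
  for (s in 1:10) {
    n <- sample(4:12, 1)
    d <- withr::with_seed(500 + s, {
      m <- matrix(stats::runif(n * n, 0.2, 1), n)
      m <- (m + t(m)) / 2; diag(m) <- 0
      dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
      m
    })
    expect_equal(ape::dist.topo(ape::unroot(neighbor_joining(d)),
                                ape::unroot(ape::nj(stats::as.dist(d)))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("equidistant taxa yield a valid binary tree with equal leaf-to-leaf paths", {
  n <- 6
  d <- matrix(1, n, n); diag(d) <- 0
  dimnames(d) <- list(letters[1:n], letters[1:n])
  tr <- neighbor_joining(d)
  expect_true(ape::is.binary(ape::unroot(tr)))
  pm <- patristic_matrix(tr)
  expect_lt(max(abs(upper_vec <- pm[upper.tri(pm)] - 1)), 1e-9)
  expect_true(all(tr$edge.length >= 0))
  # deterministic output under label permutation of an all-ties matrix
  expect_identical(ape::write.tree(tr), ape::write.tree(neighbor_joining(d)))
})

test_that("input validation rejects bad matrices", {
  expect_error(neighbor_joining(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))), "at least 3")
  m <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(m), "symmetric")
})

test_that("patristic distances sum branch lengths along paths", {
  cherry <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
  pm <- patristic_matrix(cherry)
  expect_equal(pm["A", "B"], 3)
  expect_equal(pm["A", "C"], 4.5)
  star <- ape::read.tree(text = "(A:2,B:2,C:2);")
  expect_true(all(patristic_matrix(star)[upper.tri(diag(3))] == 4))
  noblen <- ape::read.tree(text = "((A,B),C);")
  expect_error(patristic_matrix(noblen), "branch lengths")
})

test_that("patristic correlation is 1 for identical trees and scale-invariant", {
  sim <- rand_additive_matrix(8, seed = 601)
  t1 <- neighbor_joining(sim$d)
  expect_equal(patristic_correlation(t1, t1), 1.0)
  t2 <- t1
  t2$edge.length <- t2$edge.length * 7.3
  expect_equal(patristic_correlation(t1, t2), 1.0, tolerance = 1e-12)
  t3 <- neighbor_joining(rand_additive_matrix(8, seed = 602)$d)
  expect_equal(patristic_correlation(t1, t3), patristic_correlation(t3, t1))
  small <- ape::read.tree(text = "(A:1,B:1,Z:1);")
  expect_error(patristic_correlation(t1, small), "fewer than 3")
})

test_that("single-copy core selection requires exactly one gene per genome", {
  tab <- clog_table(data.frame(
    clog_id = c("c1", "c1", "c2", "c2", "c2", "c3", "c3"),
    genome_id = c("A", "B", "A", "A", "B", "A", "B"),
    gene_id = paste0("g", 1:7)), genomes = c("A", "B"))
  cls <- classify_clogs(tab)
  expect_equal(select_single_copy_core(tab, cls), c("c1", "c3"))
})

test_that("AAI identity matches hand-aligned examples and identical sequences give distance 0", {
  tab <- clog_table(data.frame(
    clog_id = c("c1", "c1"), genome_id = c("A", "B"),
    gene_id = c("a1", "b1")), genomes = c("A", "B"))
  seqs <- c(a1 = "ACDEFG", b1 = "ACDEYG")
  res <- aai_matrix(tab, "c1", seqs)
  expect_equal(res$aai["A", "B"], 5 / 6)
  expect_equal(res$distance["A", "B"], 1 / 6)
  res2 <- aai_matrix(tab, "c1", c(a1 = "ACDEFG", b1 = "ACDEFG"))
  expect_equal(res2$aai["A", "B"], 1)
  expect_equal(res2$distance["A", "B"], 0)
  expect_error(aai_matrix(tab, "c1", c(a1 = "ACDEFG")), "missing sequence")
})

test_that("NJ on 1 - AAI recovers the generating topology of simulated proteomes", {
  tree <- ape::read.tree(
    text = "((A:0.15,B:0.15):0.2,(C:0.12,D:0.18):0.15,(E:0.2,F:0.1):0.25);")
  sim <- gen_divergent_proteins(tree, n_clogs = 12, protein_length = 120,
                                seed = 42)
  cls <- classify_clogs(sim$table)
  scc <- select_single_copy_core(sim$table, cls)
  expect_equal(length(scc), 12)
  res <- aai_matrix(sim$table, scc, sim$sequences)
  nj_tree <- neighbor_joining(res$distance)
  expect_equal(ape::dist.topo(ape::unroot(nj_tree), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
})

test_that("p-distances skip gap columns and validate ragged alignments", {
  expect_equal(msa_p_distance(c(x = "ACGT", y = "ACGA"))["x", "y"], 0.25)
  expect_equal(msa_p_distance(c(x = "AC-T", y = "ACGT"))["x", "y"], 0)
  expect_equal(msa_p_distance(c(x = "AAAA", y = "AAAA"))["x", "y"], 0)
  expect_error(msa_p_distance(c(x = "ACGT", y = "ACG")), "ragged")
  expect_error(msa_p_distance(c(x = "--AA", y = "AA--")), "no comparable")
})
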