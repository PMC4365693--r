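sig_table <- function() {
  # feature set {A,B}: c_exact matches exactly; c_super adds C (decoy);
  # c_sub covers only A (support 1); c_out sits outside entirely
  clog_table(data.frame(
    clog_id = c("c_exact", "c_exact", "c_super", "c_super", "c_super",
                "c_sub", "c_out"),
    genome_id = c("A", "B", "A", "B", "C", "A", "C"),
    gene_id = paste0("g", 1:7)), genomes = c("A", "B", "C"))
}

test_that("exact feature CLOGs require full coverage and strict exclusivity", {
  fs <- feature_strain_set("feat", members = c("A", "B"), excluded = "C")
  expect_equal(exact_feature_clogs(sig_table(), fs), "c_exact")
  expect_error(exact_feature_clogs(sig_table(),
    feature_strain_set("none", members = character())), "no member")
})

test_that("relaxed buckets count support and reduce to exact at full support", {
  fs <- feature_strain_set("feat", members = c("A", "B"))
  rel <- relaxed_feature_clogs(sig_table(), fs, min_support = 1)
  expect_equal(rel$buckets[["2"]], "c_exact")
  expect_equal(rel$buckets[["1"]], "c_sub")
  expect_equal(relaxed_feature_clogs(sig_table(), fs, 2)$clog_ids,
               exact_feature_clogs(sig_table(), fs))
  expect_equal(sort(rel$genes), c("g1", "g2", "g6"))
  expect_error(relaxed_feature_clogs(sig_table(), fs, 3), "out of range")
})

test_that("planted exact-feature CLOGs are recovered with perfect precision and recall", {
  for (s in 1:10) {
    spec <- pan_genome_spec(
      10, core_count = 10, dispensable_count = 50, unique_rate = 3,
      signatures = list(list(name = "het",
                             feature_set = c("G02", "G04", "G06"),
                             n_exact = 4, n_decoy_superset = 3,
                             n_decoy_subset = 3)))
    g <- gen_pan_genome(spec, seed = 700 + s)
    fs <- feature_strain_set("het", members = c("G02", "G04", "G06"))
    found <- exact_feature_clogs(g$table, fs)
    planted <- g$truth$clog_id[g$truth$role == "signature"]
    # random dispensable CLOGs may coincide with the exact member set
    coincidental <- g$truth$clog_id[g$truth$role == "dispensable" &
      g$truth$clog_id %in% found]
    expect_true(all(planted %in% found))                      # recall 1
    expect_equal(sort(found), sort(c(planted, coincidental))) # precision 1
    expect_false(any(grepl("decoy", found)))
  }
})

test_that("adding a non-member genome to a CLOG removes it from exact and relaxed results", {
  tab <- sig_table()
  fs <- feature_strain_set("feat", members = c("A", "B"))
  poisoned <- clog_table(rbind(tab$members,
    data.frame(clog_id = "c_exact", genome_id = "C", gene_id = "gX")),
    genomes = tab$genomes)
  expect_false("c_exact" %in% exact_feature_clogs(poisoned, fs))
  expect_false("c_exact" %in% relaxed_feature_clogs(poisoned, fs, 1)$clog_ids)
})

test_that("marker profiles count marker CLOGs per genome and flag incomplete markers", {
  tab <- sig_table()
  classes <- c(A = "positive", B = "positive", C = "negative")
  prof <- marker_profile(tab, c("c_exact", "c_sub"), classes)
  expect_equal(prof$per_genome$n_markers[prof$per_genome$genome_id == "A"], 2)
  expect_equal(prof$per_genome$n_markers[prof$per_genome$genome_id == "C"], 0)
  # c_sub misses positive genome B
  expect_equal(names(prof$incomplete_markers), "c_sub")
  expect_equal(prof$incomplete_markers$c_sub, "B")
  expect_error(marker_profile(tab, "nope", classes), "unknown CLOG")
})

test_that("specificity filter applies inclusive thresholds at the stated boundaries", {
  hits <- data.frame(
    query_id = c("q1", "q1", "q2", "q3"),
    subject_id = c("s1", "s2", "s3", "s4"),
    subject_taxon = c("Viridiplantae", "Bacteria", "Bacteria", "Bacteria"),
    query_coverage = c(0.79, 0.90, 0.80, 0.95),
    e_value = c(1e-30, 1.0e-10, 1e-9, 1e-50),
    stringsAsFactors = FALSE)
  res <- specificity_filter(hits)
  # 0.79 coverage excluded despite strong e-value; e-value exactly 1e-10 included
  expect_equal(res$qualifying$subject_id, c("s2", "s4"))
  expect_equal(res$is_signature,
               c(q1 = FALSE, q2 = TRUE, q3 = FALSE))
  expect_equal(res$taxon_counts$n_hits, c(1, 1))
})

test_that("the filter is monotone in its thresholds and reports both hit counts", {
  hits <- data.frame(
    query_id = rep("q", 6), subject_id = c("s1", "s1", "s2", "s3", "s4", "s5"),
    subject_taxon = rep("Bacteria", 6),
    query_coverage = seq(0.5, 1.0, 0.1),
    e_value = 10^-(seq(5, 30, 5)), stringsAsFactors = FALSE)
  base <- nrow(specificity_filter(hits)$qualifying)
  stricter_cov <- nrow(specificity_filter(hits, min_coverage = 0.95)$qualifying)
  stricter_ev <- nrow(specificity_filter(hits, max_evalue = 1e-25)$qualifying)
  expect_lte(stricter_cov, base)
  expect_lte(stricter_ev, base)
  res <- specificity_filter(hits, min_coverage = 0.5, max_evalue = 1)
  expect_equal(res$taxon_counts$n_hits, 6)
  expect_equal(res$taxon_counts$n_subjects, 5)   # s1 hit twice
})

test_that("feature strain sets parse from +/-/u files and reject overlap", {
  f <- withr::local_tempfile(lines = c("Ana1 +", "Syn1 -", "Osc1 u"))
  fs <- read_feature_strain_set(f, "heterocysts")
  expect_equal(fs$members, "Ana1")
  expect_equal(fs$excluded, "Syn1")
  expect_equal(fs$unknown, "Osc1")
  expect_error(feature_strain_set("x", members = "A", excluded = "A"),
               "disjoint")
})
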