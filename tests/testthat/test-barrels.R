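mk_evidence <- function(votes, phmm, pfam_cov, override, length = 200,
                        clog_id = NA_character_) {
  hits <- if (phmm)
    data.frame(family = "Omp85", start = 10L, end = 150L, evalue = 1e-20,
               bits = 100, stringsAsFactors = FALSE)
  else data.frame(family = character(), start = integer(), end = integer(),
                  evalue = numeric(), bits = numeric())
  iv <- if (pfam_cov) cbind(1, length) else matrix(numeric(0), 0, 2)
  barrel_evidence("p1", "G01", length, list(votes), list(hits), list(iv),
                  clog_id, override)
}

test_that("TMBp consensus needs strictly more than one predictor vote", {
  expect_false(tmbp_consensus(character()))
  expect_false(tmbp_consensus("BOMP"))
  expect_true(tmbp_consensus(c("BOMP", "KNN")))
  expect_true(tmbp_consensus(c("BOMP", "KNN", "TMBetaDisc")))
  expect_error(tmbp_consensus("NotAPredictor"), "roster")
})

test_that("pHMM probability and family labelling follow the best-hit rule", {
  expect_false(phmm_probable(NULL)$probable)
  one <- data.frame(family = "OprB", start = 1L, end = 90L, evalue = 1e-12,
                    bits = 80)
  expect_true(phmm_probable(one)$probable)
  expect_equal(phmm_probable(one)$family, "OprB")
  two <- data.frame(family = c("OprB", "Omp85"), start = c(1L, 5L),
                    end = c(90L, 120L), evalue = c(1e-12, 1e-30),
                    bits = c(80, 200))
  expect_equal(phmm_probable(two)$family, "Omp85")   # lower e-value wins
  tie <- data.frame(family = c("OprB", "Omp85"), start = c(1L, 5L),
                    end = c(90L, 120L), evalue = c(1e-30, 1e-30),
                    bits = c(300, 200))
  expect_equal(phmm_probable(tie)$family, "OprB")    # higher bits breaks tie
})

test_that("Pfam potential applies the longer-than-79-residues uncovered rule", {
  expect_true(pfam_potential(100, matrix(numeric(0), 0, 2)))   # 100 uncovered
  expect_false(pfam_potential(100, cbind(1, 21)))              # 79 uncovered
  expect_true(pfam_potential(101, cbind(1, 21)))               # 80 uncovered
  expect_true(pfam_potential(200, rbind(c(1, 60), c(141, 200)))) # gap 61..140
  expect_false(pfam_potential(200, rbind(c(1, 60), c(140, 200)))) # gap of 79
  expect_false(pfam_potential(79, matrix(numeric(0), 0, 2)))
  expect_true(pfam_potential(80, matrix(numeric(0), 0, 2)))
  # overlapping intervals merge before gap measurement
  expect_false(pfam_potential(150, rbind(c(1, 50), c(30, 80), c(81, 150))))
  expect_error(pfam_potential(100, cbind(50, 120)), "outside")
})

test_that("CLOG vote uses a strict majority over all members of the CLOG", {
  tab <- clog_table(data.frame(
    clog_id = c("c1", "c1", "c1", "c1", "c2", "c2", "c2", "c3"),
    genome_id = rep("G01", 8),
    gene_id = paste0("p", 1:8)), genomes = "G01")
  # c1: 2/4 pass -> 0.5, not > 0.5 -> fails
  res <- clog_detected(tab, paste0("p", 1:8),
                       c("c1", "c1", "c1", "c1", "c2", "c2", "c2", "c3"),
                       c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_false(res$per_clog[["c1"]])
  expect_true(all(!res$per_protein[paste0("p", 1:4)]))
  # c2: 2/3 pass -> passes; only the passing members are flagged
  expect_true(res$per_clog[["c2"]])
  expect_equal(unname(res$per_protein[paste0("p", 5:7)]),
               c(TRUE, TRUE, FALSE))
  # singleton passing CLOG: 1/1 > 0.5
  expect_true(res$per_protein[["p8"]])
})

test_that("members without evidence rows count as non-passing in the denominator", {
  tab <- clog_table(data.frame(
    clog_id = rep("c1", 4), genome_id = rep("G01", 4),
    gene_id = paste0("p", 1:4)), genomes = "G01")
  # evidence covers only 2 of the 4 members, both passing: 2/4 not > 0.5
  res <- clog_detected(tab, c("p1", "p2"), c("c1", "c1"), c(TRUE, TRUE))
  expect_false(res$per_clog[["c1"]])
})

test_that("the 16-combination decision table (x override) is categorized correctly", {
  grid <- expand.grid(tmbp = c(TRUE, FALSE), phmm = c(TRUE, FALSE),
                      pfam = c(TRUE, FALSE), clog = c(TRUE, FALSE),
                      override = c(TRUE, FALSE))
  expected <- with(grid, ifelse(!(tmbp & phmm), "d",
                         ifelse(pfam & clog, "a",
                         ifelse(xor(pfam, clog), "b",
                         ifelse(override, "c", "d")))))
  got <- mapply(cyanopan:::category_from_flags, grid$tmbp, grid$phmm,
                grid$pfam, grid$clog, grid$override)
  expect_equal(unname(got), expected)
  # every input lands in exactly one category
  expect_true(all(got %in% c("a", "b", "c", "d")))
})

test_that("categorize_barrels wires the criteria together on single proteins", {
  tab1 <- clog_table(data.frame(clog_id = "c1", genome_id = "G01",
                                gene_id = "p1"), genomes = "G01")
  all4 <- categorize_barrels(mk_evidence(c("BOMP", "KNN"), TRUE, FALSE,
                                         FALSE, clog_id = "c1"), tab1)
  expect_equal(as.character(all4$category), "a")
  expect_equal(all4$family, "Omp85")

  # majors only + override -> c; without override -> d
  ev_c <- mk_evidence(c("BOMP", "KNN"), TRUE, TRUE, TRUE)
  expect_equal(as.character(categorize_barrels(ev_c)$category), "c")
  ev_d <- mk_evidence(c("BOMP", "KNN"), TRUE, TRUE, FALSE)
  expect_equal(as.character(categorize_barrels(ev_d)$category), "d")

  # single vote fails the majors regardless of minors
  ev_one <- mk_evidence("BOMP", TRUE, FALSE, TRUE, clog_id = NA_character_)
  expect_equal(as.character(categorize_barrels(ev_one)$category), "d")
})

test_that("the noiseless generator yields perfect category recovery", {
  gen <- gen_barrel_evidence(400, prevalence = 0.25,
                             sensitivities = c(BOMP = 1, KNN = 1,
                                               TMBetaDisc = 1),
                             specificities = c(BOMP = 1, KNN = 1,
                                               TMBetaDisc = 1),
                             phmm_sensitivity = 1, phmm_specificity = 1,
                             seed = 77)
  calls <- categorize_barrels(gen$evidence, gen$table)
  expect_true(all(calls$category[gen$truth[calls$protein_id]] == "a"))
  expect_true(all(calls$category[!gen$truth[calls$protein_id]] == "d"))
})

test_that("noisy predictor votes occur at the stated rates", {
  gen <- gen_barrel_evidence(4000, prevalence = 0.5,
                             sensitivities = c(BOMP = 0.8, KNN = 0.9,
                                               TMBetaDisc = 0.7),
                             specificities = c(BOMP = 0.95, KNN = 0.9,
                                               TMBetaDisc = 0.99),
                             seed = 88)
  barrels <- gen$truth[gen$evidence$protein_id]
  bomp_tp <- vapply(gen$evidence$predictor_votes[barrels],
                    function(v) "BOMP" %in% v, logical(1))
  # binomial 99.9% bound around sensitivity 0.8
  p_hat <- mean(bomp_tp)
  se <- sqrt(0.8 * 0.2 / sum(barrels))
  expect_lt(abs(p_hat - 0.8), 3.3 * se + 0.01)
})

test_that("evidence tables round-trip through the TSV format", {
  gen <- gen_barrel_evidence(25, prevalence = 0.4, seed = 5)
  f <- withr::local_tempfile()
  write_barrel_evidence(gen$evidence, f)
  back <- read_barrel_evidence(f)
  expect_equal(back$protein_id, gen$evidence$protein_id)
  expect_equal(back$predictor_votes, gen$evidence$predictor_votes)
  expect_equal(back$clog_id, gen$evidence$clog_id)
  c1 <- categorize_barrels(gen$evidence, gen$table)
  c2 <- categorize_barrels(back, gen$table)
  expect_equal(as.character(c1$category), as.character(c2$category))
})

test_that("family summaries tally strains, orders and sequences", {
  reg <- genome_registry(data.frame(
    genome_id = c("G01", "G02", "G03"),
    species = c("sp1", "sp2", "sp3"),
    order = c("Nostocales", "Nostocales", "Chroococcales")))
  calls <- structure(data.frame(
    protein_id = paste0("p", 1:4),
    genome_id = c("G01", "G01", "G02", "G03"),
    tmbp_probable = TRUE, phmm_probable = TRUE, pfam_potential = TRUE,
    clog_detected = TRUE,
    category = factor(c("a", "a", "a", "d"), levels = letters[1:4]),
    family = c("Omp85", "Omp85", "Omp85", "Omp85"),
    clog_id = NA_character_, stringsAsFactors = FALSE),
    class = c("barrel_calls", "data.frame"))
  fam <- family_summary(calls, reg)
  expect_equal(fam$families$n_strains, 2)   # category d excluded
  expect_equal(fam$families$n_orders, 1)
  expect_equal(fam$families$n_sequences, 3)
})
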