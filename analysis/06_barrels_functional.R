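#!/usr/bin/env Rscript
# Consensus beta-barrel categorization from the synthetic evidence table,
# per-family summaries, and the COG-category profile along a nested clade
# chain.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

ev <- read_barrel_evidence(file.path(IN, "barrel_evidence.tsv"))
btab <- read_clog_table(file.path(IN, "barrel_groups.tsv"), "tsv")
calls <- categorize_barrels(ev, btab)
utils::write.table(calls, file.path(OUT, "barrel_calls.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
say("Category counts: %s",
    paste(sprintf("(%s) %d", names(table(calls$category)),
                  table(calls$category)), collapse = ", "))

truth <- utils::read.delim(file.path(IN, "barrel_truth.tsv"))
is_b <- setNames(truth$is_barrel, truth$protein_id)[calls$protein_id]
say("Detection (category a/b) sensitivity %.2f, specificity %.2f",
    mean(calls$category[is_b] %in% c("a", "b")),
    mean(calls$category[!is_b] == "d"))

breg <- genome_registry(data.frame(
  genome_id = sort(unique(ev$genome_id)),
  species = sort(unique(ev$genome_id)),
  order = rep(c("OrderA", "OrderB"), length.out =
                length(unique(ev$genome_id)))))
fam <- family_summary(calls, breg, btab)
utils::write.table(fam$families, file.path(OUT, "barrel_families.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# functional profile of nested clade cores, projected on genome G01
registry <- read_genome_registry(file.path(IN, "registry.tsv"))
tab <- read_clog_table(file.path(IN, "groups.txt"), "orthomcl_groups",
                       genomes = registry$genomes$genome_id)
ann <- read_annotation_map(file.path(IN, "annotation.tsv"))
g <- tab$genomes
chain <- clade_chain(list(g, g[1:10], g[1:5]), g)
prof <- incremental_profile(tab, chain, "G01", ann)
utils::write.table(
  data.frame(step = rownames(prof$category_counts), prof$category_counts),
  file.path(OUT, "clade_cog_profile.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
say("Core genes per chain step: %s",
    paste(lengths(prof$increments), collapse = " / "))
say("Category classes: %s",
    paste(sprintf("%s=%s", names(prof$category_class),
                  prof$category_class)[!is.na(prof$category_class)],
          collapse = ", "))
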