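#!/usr/bin/env Rscript
# Classify the CLOGs of the synthetic pan-genome into core, dispensable
# and unique, and profile each genome's gene composition.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

registry <- read_genome_registry(file.path(IN, "registry.tsv"))
tab <- read_clog_table(file.path(IN, "groups.txt"), "orthomcl_groups",
                       genomes = registry$genomes$genome_id)
cls <- classify_clogs(tab)
print(cls)

utils::write.table(
  data.frame(clog_id = names(cls$class), class = as.character(cls$class),
             occupancy = unname(cls$occupancy)),
  file.path(OUT, "classification.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

profiles <- t(vapply(tab$genomes, function(g) genome_profile(tab, cls, g),
                     integer(3)))
utils::write.table(data.frame(genome_id = rownames(profiles), profiles),
                   file.path(OUT, "genome_profiles.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

say("Occupancy histogram (genomes per CLOG):")
print(cls$occupancy_histogram)

paralogs <- multi_sequence_unique_clogs(tab, cls)
say("%d unique-class CLOGs hold two or more sequences (putative paralogs)",
    paralogs$count)

# sanity check against the generator's truth labels
truth <- utils::read.delim(file.path(IN, "clog_truth.tsv"))
agree <- all(as.character(cls$class[truth$clog_id]) == truth$class)
say("Classification agrees with generator truth: %s", agree)
stopifnot(agree)
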