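#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a clade-structured pan-genome with
# planted clade cores and signature CLOGs, a matching phenotype feature
# table, divergent protein families along a known tree, beta-barrel
# evidence, and an outgroup homology hit table. Everything is written in
# the same external formats the readers consume, so steps 02-06 exercise
# the full parse-compute-write path.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

say("Simulating with seed %d", SEED)

clades <- split(sprintf("G%02d", 1:20), rep(1:4, each = 5))
names(clades) <- paste0("clade", 1:4)
fset <- c("G03", "G07", "G11", "G15")    # planted 'thermophile' strains

spec <- calibrated_pan_spec(
  clade_extras = lapply(clades, function(g) list(genomes = g, count = 80)),
  signatures = list(list(name = "thermo", feature_set = fset, n_exact = 5,
                         n_decoy_superset = 4, n_decoy_subset = 4)))
pan <- gen_pan_genome(spec, seed = SEED)
write_clog_table(pan$table, file.path(IN, "groups.txt"), "orthomcl_groups")
utils::write.table(pan$truth, file.path(IN, "clog_truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

registry <- genome_registry(data.frame(
  genome_id = pan$table$genomes,
  species = sprintf("Synthetica cyanophila %s", pan$table$genomes),
  order = rep(paste0("Order", 1:4), each = 5),
  stringsAsFactors = FALSE))
write_genome_registry(registry, file.path(IN, "registry.tsv"))

feat <- gen_feature_table(clades, unknown_rate = 0.1, seed = SEED + 1L)
write_feature_table(feat$table, file.path(IN, "features.tsv"))

truth_tree <- ape::read.tree(
  text = "((A:0.15,B:0.15):0.2,(C:0.12,D:0.18):0.15,(E:0.2,F:0.1):0.25);")
ape::write.tree(truth_tree, file.path(IN, "aai_true_tree.nwk"))
prot <- gen_divergent_proteins(truth_tree, n_clogs = 10,
                               protein_length = 120, seed = SEED + 2L)
Biostrings::writeXStringSet(Biostrings::AAStringSet(prot$sequences),
                            file.path(IN, "proteins.faa"))
write_clog_table(prot$table, file.path(IN, "protein_groups.tsv"), "tsv")

barr <- gen_barrel_evidence(2000, seed = SEED + 3L)
write_barrel_evidence(barr$evidence, file.path(IN, "barrel_evidence.tsv"))
write_clog_table(barr$table, file.path(IN, "barrel_groups.tsv"), "tsv")
utils::write.table(
  data.frame(protein_id = names(barr$truth), is_barrel = barr$truth),
  file.path(IN, "barrel_truth.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

# outgroup homology hits for the signature candidates: one candidate has a
# strong plant hit (not a signature), the rest only sub-threshold hits
sig_genes <- pan$table$members$gene_id[
  pan$table$members$clog_id == "sig_thermo_001"][1:2]
hits <- data.frame(
  query = c(sig_genes[1], sig_genes[1], sig_genes[2]),
  subject = c("At1g01010", "EcK12_0001", "EcK12_0002"),
  taxon = c("Viridiplantae", "Bacteria", "Bacteria"),
  coverage = c(92, 45, 79),
  evalue = c(1e-42, 1e-3, 1e-30))
utils::write.table(hits, file.path(IN, "outgroup_hits.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)

# COG-style annotation for the representative genome's genes
ann <- data.frame(
  gene_id = pan$table$members$gene_id,
  categories = rep_len(c("J", "K", "C", "E", "KL", "R", "M", "T", "P", "O"),
                       nrow(pan$table$members)))
utils::write.table(ann, file.path(IN, "annotation.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

say("Synthetic inputs written under %s", IN)
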