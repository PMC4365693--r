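#!/usr/bin/env Rscript
# Distance matrices (CLOG sharing, Tanimoto-like features, AAI) and their
# neighbor-joining trees; patristic correlations between the trees.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

registry <- read_genome_registry(file.path(IN, "registry.tsv"))
tab <- read_clog_table(file.path(IN, "groups.txt"), "orthomcl_groups",
                       genomes = registry$genomes$genome_id)

dclog <- clog_distance_matrix(tab)
write_distance_matrix(dclog, file.path(OUT, "dist_clog.tsv"))
t_clog <- neighbor_joining(dclog)
ape::write.tree(t_clog, file.path(OUT, "tree_clog.nwk"))

feat <- read_feature_table(file.path(IN, "features.tsv"),
                           default_features())
dfeat <- feature_distance_matrix(feat, allow_missing = TRUE)
write_distance_matrix(dfeat, file.path(OUT, "dist_feature.tsv"))
t_feat <- neighbor_joining(dfeat)
ape::write.tree(t_feat, file.path(OUT, "tree_feature.nwk"))

say("CLOG vs feature tree patristic correlation: %.3f",
    patristic_correlation(t_clog, t_feat))

# AAI tree from the simulated protein families
ptab <- read_clog_table(file.path(IN, "protein_groups.tsv"), "tsv")
seqs <- Biostrings::readAAStringSet(file.path(IN, "proteins.faa"))
seqs <- setNames(as.character(seqs), names(seqs))
scc <- select_single_copy_core(ptab, classify_clogs(ptab))
aai <- aai_matrix(ptab, scc, seqs)
write_distance_matrix(aai$distance, file.path(OUT, "dist_aai.tsv"))
t_aai <- neighbor_joining(aai$distance)
ape::write.tree(t_aai, file.path(OUT, "tree_aai.nwk"))

true_tree <- ape::read.tree(file.path(IN, "aai_true_tree.nwk"))
say("AAI tree vs generating tree: correlation %.3f, topology recovered %s",
    patristic_correlation(t_aai, true_tree),
    ape::dist.topo(ape::unroot(t_aai), ape::unroot(true_tree)) == 0)
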