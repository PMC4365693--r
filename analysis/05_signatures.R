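#!/usr/bin/env Rscript
# Mine feature-specific CLOGs (exact and relaxed support), profile marker
# CLOGs across strain classes, and apply the outgroup specificity filter
# that promotes candidates to signature genes.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

registry <- read_genome_registry(file.path(IN, "registry.tsv"))
tab <- read_clog_table(file.path(IN, "groups.txt"), "orthomcl_groups",
                       genomes = registry$genomes$genome_id)
truth <- utils::read.delim(file.path(IN, "clog_truth.tsv"))

fset <- c("G03", "G07", "G11", "G15")
fs <- feature_strain_set("thermo", members = fset,
                         excluded = setdiff(tab$genomes, fset))

exact <- exact_feature_clogs(tab, fs)
planted <- truth$clog_id[truth$role == "signature"]
say("Exact feature-specific CLOGs: %d found, %d planted, %d decoys rejected",
    length(exact), length(planted),
    sum(grepl("decoy", truth$clog_id[truth$role != "signature"])))
stopifnot(setequal(exact, planted))

rel <- relaxed_feature_clogs(tab, fs, min_support = 3)
say("Relaxed support buckets: %s",
    paste(sprintf("%s strains -> %d CLOGs", names(rel$buckets),
                  lengths(rel$buckets)), collapse = "; "))
utils::write.table(
  data.frame(clog_id = rel$clog_ids),
  file.path(OUT, "relaxed_feature_clogs.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

classes <- setNames(ifelse(tab$genomes %in% fset, "positive", "negative"),
                    tab$genomes)
prof <- marker_profile(tab, exact, classes)
utils::write.table(prof$per_genome, file.path(OUT, "marker_profile.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
say("Mean marker count: positives %.1f, negatives %.1f",
    prof$class_summary[["positive"]], prof$class_summary[["negative"]])

hits <- read_hit_table(file.path(IN, "outgroup_hits.tsv"))
candidates <- tab$members$gene_id[tab$members$clog_id %in% exact]
res <- specificity_filter(hits, queries = candidates)
say("Signature status after the outgroup filter: %d of %d candidates kept",
    sum(res$is_signature[candidates]), length(candidates))
utils::write.table(
  data.frame(gene_id = candidates,
             is_signature = unname(res$is_signature[candidates])),
  file.path(OUT, "signature_genes.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
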