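#!/usr/bin/env Rscript
# Core/pan-genome rarefaction by repeated random genome subsampling, the
# new-genes-per-genome curve, and the open-pangenome power-law exponent.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

registry <- read_genome_registry(file.path(IN, "registry.tsv"))
tab <- read_clog_table(file.path(IN, "groups.txt"), "orthomcl_groups",
                       genomes = registry$genomes$genome_id)

curve <- rarefy(tab, repetitions = 200, seed = SEED + 10L)
core_sum <- summary(curve, "core")
pan_sum <- summary(curve, "pan")
utils::write.table(core_sum, file.path(OUT, "rarefaction_core.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(pan_sum, file.path(OUT, "rarefaction_pan.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
say("Core shrinks from %.0f (n=1) to %.0f (n=%d); pan grows to %.0f",
    core_sum$mean[1], core_sum$mean[nrow(core_sum)], nrow(core_sum),
    pan_sum$mean[nrow(pan_sum)])

nc <- new_genes_per_step(tab, permutations = 200, seed = SEED + 11L)
utils::write.table(data.frame(n = seq_along(nc$mean), mean_new = nc$mean,
                              sd_new = nc$sd),
                   file.path(OUT, "new_genes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

fit <- fit_power_law(nc, bootstrap = 100, seed = SEED + 12L)
print(fit)
utils::write.table(
  data.frame(alpha = fit$alpha, alpha_sd = fit$alpha_sd,
             kappa = fit$kappa, r_squared = fit$r_squared,
             open = fit$open),
  file.path(OUT, "power_law_fit.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

# clade core enrichment: planted clade cores make each 5-genome clade's
# core larger than a random 5-genome subset's
for (k in 1:4) {
  clade <- registry$genomes$genome_id[registry$genomes$order ==
                                        paste0("Order", k)]
  r <- core_ratio(tab, clade, curve)
  say("clade %d: core %d vs expected %.1f -> ratio %.2f",
      k, r$observed, r$expected, r$ratio)
}
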