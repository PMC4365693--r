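# Shared setup for the analysis drivers: seed handling and output paths.
# Each numbered script can be run on its own; 01 must run first since it
# writes the synthetic inputs the later steps read back.

suppressPackageStartupMessages(library(cyanopan))

args <- commandArgs(trailingOnly = TRUE)
SEED <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
OUT <- "results"
IN <- file.path(OUT, "synthetic")
dir.create(IN, showWarnings = FALSE, recursive = TRUE)

say <- function(...) message(sprintf(...))
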