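# Shared settings for the analysis workflow.
#
# One simulated full-length transcriptome dataset stands in for the mapped
# FLNC reads of a three-caste survey: 60 genes, three samples
# (queen/worker/drone), realistic end jitter (sd 5 bp) and a 2% intergenic
# mono-exon noise-read rate. Every script reads and writes under results/.

library(isoannot)

SEED <- 101
DATA_DIR <- "results/data"
OUT_DIR <- "results"

pipeline_config <- function() {
  sim_config(seed = SEED, n_genes = 60)
}

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

wtsv <- function(d, f) utils::write.table(
  d, file.path(OUT_DIR, f), sep = "\t", quote = FALSE, row.names = FALSE)
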