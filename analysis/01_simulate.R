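#!/usr/bin/env Rscript
# Generate the simulated dataset: toy genome, truth and reference
# annotations, per-sample full-length read alignments (BED12) and the
# transcript count matrix consumed by the expression analysis.

source("analysis/00_config.R")

cfg <- pipeline_config()
sim <- simulate_genome(cfg)
fl <- simulate_flnc(sim, cfg)

write_annotation(sim$truth_ann, file.path(DATA_DIR, "truth.gff3"))
write_annotation(sim$ref_ann, file.path(DATA_DIR, "reference.gff3"))
Biostrings::writeXStringSet(sim$genome, file.path(DATA_DIR, "genome.fa"))
for (s in cfg$samples) {
  ids <- fl$reads$transcripts$tx_id[fl$reads$transcripts$sample == s]
  write_bed12(subset_tx(fl$reads, ids),
              file.path(DATA_DIR, paste0("reads_", s, ".bed12")))
}
utils::write.table(fl$read_truth, file.path(DATA_DIR, "read_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seed = cfg$seed, n_genes = cfg$n_genes,
       n_transcripts = n_tx(sim$truth_ann$tx),
       n_reads = n_tx(fl$reads),
       n_noise_reads = sum(fl$read_truth$is_noise),
       planted_events = as.list(table(sim$truth$events$type)),
       planted_lnc = as.list(table(
         sim$truth$isoforms$lnc_class[sim$truth$isoforms$kind == "lnc"]))),
  file.path(DATA_DIR, "simulation_manifest.json"),
  auto_unbox = TRUE, pretty = TRUE)

message(sprintf(
  "Simulated %d gene units (%d transcripts) and %d reads (%d noise) across %s.",
  nrow(sim$truth_ann$genes), n_tx(sim$truth_ann$tx), n_tx(fl$reads),
  sum(fl$read_truth$is_noise), paste(cfg$samples, collapse = "/")))
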