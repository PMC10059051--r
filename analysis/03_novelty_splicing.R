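#!/usr/bin/env Rscript
# Compare the collapsed loci/isoforms against the reference annotation
# (known vs novel at both levels) and enumerate alternative-splicing
# events per type, per sample and combined.

source("analysis/00_config.R")

cfg <- pipeline_config()
reads <- do.call(bind_tx, lapply(cfg$samples, function(s)
  read_bed12(file.path(DATA_DIR, paste0("reads_", s, ".bed12")),
             sample = s)))
col <- collapse_reads(reads)
ref <- read_annotation(file.path(DATA_DIR, "reference.gff3"))

nov <- classify_novelty(col, ref)
wtsv(rbind(nov$genes, nov$transcripts), "novelty_calls.tsv")
nf <- novelty_fractions(nov$genes, nov$transcripts)
message(sprintf(
  "Novel: %d/%d loci (%s%%) and %d/%d isoforms (%s%%) relative to the reference.",
  nf$n_novel_genes, nf$n_genes, nf$pct_novel_genes,
  nf$n_novel_transcripts, nf$n_transcripts, nf$pct_novel_transcripts))

ev <- count_events_by_sample(col$isoforms, samples = cfg$samples)
wtsv(ev$events, "as_events.tsv")
wtsv(ev$summary, "as_counts_by_type_and_sample.tsv")
wtsv(as_type_summary(ev$events), "as_type_summary.tsv")
n_as_genes <- length(unique(ev$events$gene_id))
message(sprintf(
  "AS: %d events in %d genes (%s%% of loci); per-sample totals %s; combined >= each.",
  nrow(ev$events), n_as_genes, pct2(n_as_genes, nrow(col$loci)),
  paste(colSums(ev$summary[, cfg$samples, drop = FALSE]), collapse = "/")))
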