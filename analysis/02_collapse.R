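#!/usr/bin/env Rscript
# Collapse the mapped full-length reads into gene loci and non-redundant
# isoforms using the same-direction >20% span / >20% exon overlap rule,
# and tabulate the isoform-per-gene distribution.

source("analysis/00_config.R")

cfg <- pipeline_config()
reads <- do.call(bind_tx, lapply(cfg$samples, function(s)
  read_bed12(file.path(DATA_DIR, paste0("reads_", s, ".bed12")),
             sample = s)))

col <- collapse_reads(reads, same_gene_rule())
write_annotation(annotation(col$isoforms), file.path(OUT_DIR,
                                                     "isoforms.gff3"))
wtsv(col$loci, "loci.tsv")
wtsv(col$read_to_isoform, "read_to_isoform.tsv")
dist <- isoform_distribution(col$isoforms)
wtsv(dist, "isoform_distribution.tsv")
us <- unique_sets(col$isoforms)
wtsv(us$unique, "sample_unique_isoforms.tsv")

message(sprintf(
  "%d reads -> %d loci, %d non-redundant isoforms; %s of genes carry a single isoform.",
  n_tx(reads), nrow(col$loci), n_tx(col$isoforms),
  paste0(dist$pct[dist$bin == "1"], "%")))
message(sprintf("Sample-unique isoforms: %s.",
                paste(sprintf("%s=%d", us$unique$sample, us$unique$n),
                      collapse = ", ")))
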