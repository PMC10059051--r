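#!/usr/bin/env Rscript
# Flag candidate noncoding transcripts with the ORF + hexamer heuristic and
# classify them into the four positional classes relative to the reference
# annotation.

source("analysis/00_config.R")

cfg <- pipeline_config()
reads <- do.call(bind_tx, lapply(cfg$samples, function(s)
  read_bed12(file.path(DATA_DIR, paste0("reads_", s, ".bed12")),
             sample = s)))
col <- collapse_reads(reads)
genome <- Biostrings::readDNAStringSet(file.path(DATA_DIR, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))
ref <- read_annotation(file.path(DATA_DIR, "reference.gff3"))

lnc <- lncrna_calls(col$isoforms, genome, ref)
wtsv(lnc$coding, "coding_potential.tsv")
wtsv(lnc$lncrna, "lncrna_classes.tsv")

lnc_set <- subset_tx(col$isoforms, lnc$lncrna$tx_id)
mrna_ids <- lnc$coding$tx_id[lnc$coding$call == "coding"]
s <- lncrna_summary(lnc$lncrna, known_lnc = NULL, lnc_set = lnc_set,
                    mrna_lengths = spliced_length(
                      subset_tx(col$isoforms, mrna_ids)))
wtsv(data.frame(class = names(s$class_pct),
                n = as.integer(s$class_counts),
                pct = unname(s$class_pct)),
     "lncrna_class_summary.tsv")
message(sprintf(
  "lncRNA: %d candidates (%s); median length %d vs %d nt for mRNAs.",
  s$n,
  paste(sprintf("%s %s%%", names(s$class_pct), s$class_pct),
        collapse = ", "),
  round(s$length_summary$lncrna[["median"]]),
  round(s$length_summary$mrna[["median"]])))
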