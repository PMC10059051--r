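#!/usr/bin/env Rscript
# Cluster read 3' ends into polyA sites per gene, summarise the per-gene
# site-count distribution, and profile nucleotide composition and the
# A10 element around the sites.

source("analysis/00_config.R")

cfg <- pipeline_config()
reads <- do.call(bind_tx, lapply(cfg$samples, function(s)
  read_bed12(file.path(DATA_DIR, paste0("reads_", s, ".bed12")),
             sample = s)))
col <- collapse_reads(reads)
genome <- Biostrings::readDNAStringSet(file.path(DATA_DIR, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))

sites <- polya_sites(col$reads, merge_window = 24, min_site_support = 2)
wtsv(sites, "polya_sites.tsv")
# BED6 of sites (score = support)
bed <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", sites$chrom, sites$position,
               sites$position + 1, sites$gene_id, sites$support,
               sites$strand)
writeLines(bed, file.path(OUT_DIR, "polya_sites.bed"))

apa <- apa_summary(sites)
wtsv(data.frame(sites_per_gene = names(apa$histogram),
                n_genes = as.integer(apa$histogram)),
     "apa_site_count_distribution.tsv")
fp <- flank_profile(sites, genome, flank = 50)
utils::write.table(round(fp$freq, 4), file.path(OUT_DIR,
                                                "polya_flank_composition.tsv"),
                   sep = "\t", quote = FALSE, col.names = NA)
message(sprintf(
  "APA: %d sites over %d genes (mean %.2f/gene; %s%% with 1-9 sites); A10 element in %s%% of flanks.",
  apa$n_sites, apa$n_genes, apa$mean_sites_per_gene,
  apa$bin_shares[["1-9"]], round(100 * fp$hit_fraction, 1)))
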