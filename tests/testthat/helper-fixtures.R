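# small constructors used across the suite

mk_tx <- function(id, exons, chrom = "chr1", strand = "+",
                  sample = NA_character_) {
  exons <- matrix(exons, ncol = 2)
  tx_set(data.frame(tx_id = id, chrom = chrom, strand = strand,
                    sample = sample, stringsAsFactors = FALSE),
         data.frame(tx_id = id, start = exons[, 1], end = exons[, 2],
                    stringsAsFactors = FALSE))
}

# structural identity key: chrom, strand, intron chain, span
struct_key <- function(x)
  sort(paste(intron_chain_key(x), tx_spans(x)$start, tx_spans(x)$end))

# random mapped reads: clustered around `n_centers` locus seeds so that the
# same-gene graph has non-trivial components
rand_reads <- function(n, seed, n_centers = max(2, n %/% 6),
                       chroms = c("chr1", "chr2")) {
  set.seed(seed)
  centers <- data.frame(
    chrom = sample(chroms, n_centers, TRUE),
    strand = sample(c("+", "-"), n_centers, TRUE),
    pos = sample.int(50000, n_centers))
  tr <- NULL; ex <- NULL
  for (i in seq_len(n)) {
    c_i <- sample.int(n_centers, 1)
    start <- centers$pos[c_i] + sample(-400:400, 1)
    n_ex <- sample(1:4, 1)
    lens <- sample(40:250, n_ex, TRUE)
    gaps <- sample(50:200, n_ex, TRUE)
    starts <- start + cumsum(c(0, lens[-n_ex] + gaps[-n_ex]))
    id <- sprintf("r%04d", i)
    tr <- rbind(tr, data.frame(tx_id = id, chrom = centers$chrom[c_i],
                               strand = centers$strand[c_i],
                               stringsAsFactors = FALSE))
    ex <- rbind(ex, data.frame(tx_id = id, start = starts,
                               end = starts + lens,
                               stringsAsFactors = FALSE))
  }
  tx_set(tr, ex)
}

# independent connected-components oracle: scalar same_gene on the
# chrom/strand/span-intersection candidate pairs, then graph components
oracle_components <- function(reads, rule = same_gene_rule()) {
  n <- n_tx(reads)
  sp <- tx_spans(reads)
  singles <- lapply(sp$tx_id, function(id) subset_tx(reads, id))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      if (sp$chrom[i] != sp$chrom[j]) next
      if (sp$start[i] >= sp$end[j] || sp$start[j] >= sp$end[i]) next
      adj[i, j] <- adj[j, i] <- same_gene(singles[[i]], singles[[j]], rule)
    }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# canonical partition signature (set of member-id sets), for comparing
# groupings irrespective of labels
partition_sig <- function(ids, membership)
  unname(sort(vapply(split(ids, membership),
                     function(v) paste(sort(v), collapse = ","),
                     character(1))))
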