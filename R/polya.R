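#' Strand-aware 3' end positions of transcripts
#'
#' The 3' end is the last transcribed coordinate: the span end on `+`, the
#' span start on `-` (both in the 0-based half-open convention, so the `+`
#' value is an exclusive end).
#'
#' @param x a [tx_set()].
#' @return named numeric vector of 3' end positions.
#' @export
three_prime_ends <- function(x) {
  sp <- tx_spans(x)
  stats::setNames(ifelse(sp$strand == "+", sp$end, sp$start), sp$tx_id)
}

#' Cluster 3' end positions into polyA sites
#'
#' Single-linkage clustering on one gene's read 3' ends: positions within
#' `merge_window` of a cluster member join the cluster. The representative
#' position is the support-weighted mode, ties broken toward the most
#' distal position (downstream in transcription direction). Clusters below
#' `min_site_support` are dropped. Sites are returned 5' to 3'.
#'
#' @param ends numeric vector of 3' end positions (one per read).
#' @param strand `"+"` or `"-"`.
#' @param merge_window single-linkage distance (bp); default 24.
#' @param min_site_support minimum reads per retained site; default 2.
#' @return data.frame `position`, `support`, `n_positions` with the member
#'   end positions as an attribute `members` (list of numeric vectors).
#' @export
cluster_polya <- function(ends, strand = "+", merge_window = 24,
                          min_site_support = 2) {
  if (!length(ends))
    return(structure(data.frame(position = numeric(), support = integer(),
                                n_positions = integer()),
                     members = list()))
  o <- order(ends)
  e <- ends[o]
  brk <- c(FALSE, diff(e) > merge_window)
  cl <- cumsum(brk)
  members <- split(e, cl)
  rep_pos <- vapply(members, function(v) {
    tb <- table(v)
    mx <- names(tb)[tb == max(tb)]
    pos <- as.numeric(mx)
    if (strand == "+") max(pos) else min(pos)
  }, numeric(1))
  support <- lengths(members)
  keep <- support >= min_site_support
  members <- members[keep]; rep_pos <- rep_pos[keep]
  support <- support[keep]
  ord <- if (strand == "+") order(rep_pos) else order(-rep_pos)
  structure(data.frame(position = unname(rep_pos[ord]),
                       support = as.integer(unname(support[ord])),
                       n_positions = vapply(members[ord], function(v)
                         length(unique(v)), integer(1)),
                       row.names = NULL),
            members = unname(members[ord]))
}

#' PolyA sites for every gene of a read set
#'
#' @param reads a [tx_set()] with a gene assignment column (`locus_id` or
#'   `gene_id`).
#' @param merge_window,min_site_support see [cluster_polya()].
#' @return data.frame `gene_id`, `chrom`, `strand`, `position`, `support`,
#'   sites ordered 5' to 3' within each gene.
#' @export
polya_sites <- function(reads, merge_window = 24, min_site_support = 2) {
  tr <- reads$transcripts
  gcol <- if ("locus_id" %in% names(tr)) "locus_id" else "gene_id"
  stopifnot(gcol %in% names(tr))
  ends <- three_prime_ends(reads)
  out <- list()
  for (g in unique(tr[[gcol]])) {
    idx <- tr[[gcol]] == g
    strand <- tr$strand[idx][1]
    cl <- cluster_polya(ends[tr$tx_id[idx]], strand, merge_window,
                        min_site_support)
    if (nrow(cl))
      out[[length(out) + 1]] <- data.frame(
        gene_id = g, chrom = tr$chrom[idx][1], strand = strand,
        position = cl$position, support = cl$support,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), position = numeric(),
                      support = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary of per-gene polyA site counts
#'
#' @param site_counts integer vector: number of sites per gene (genes with
#'   at least one site), or the data.frame from [polya_sites()].
#' @return list with `n_genes`, `n_sites`, `mean_sites_per_gene` (2
#'   decimals, round-half-up), `histogram` (site count -> genes) and
#'   `bin_shares`: percentage of genes with 1-9 and with 10 or more sites.
#' @export
apa_summary <- function(site_counts) {
  if (is.data.frame(site_counts))
    site_counts <- as.integer(table(site_counts$gene_id))
  stopifnot(all(site_counts >= 1))
  n_genes <- length(site_counts)
  n_sites <- sum(site_counts)
  hist <- table(site_counts)
  list(n_genes = n_genes, n_sites = n_sites,
       mean_sites_per_gene = round_half_up(n_sites / n_genes, 2),
       histogram = hist,
       bin_shares = c(`1-9` = pct2(sum(site_counts <= 9), n_genes),
                      `10+` = pct2(sum(site_counts >= 10), n_genes)))
}

#' Nucleotide composition and A-element scan around polyA sites
#'
#' For each site, the window covers `flank` bases upstream (the last
#' transcribed bases, offsets `-flank..-1`) and `flank` bases downstream
#' (offsets `0..flank-1`) on the transcribed strand; minus-strand windows
#' are reverse-complemented. Sites too close to a chromosome end are
#' truncated with a mask and masked positions are excluded from the
#' per-position denominators. The element scan reports, per offset, the
#' fraction of sites whose window contains the consensus element starting
#' there, plus the overall fraction of sites with at least one hit.
#'
#' @param sites data.frame from [polya_sites()].
#' @param genome a `DNAStringSet`.
#' @param flank half-window width in bp (default 50).
#' @param element consensus element to scan for (default ten adenines).
#' @return list with `freq` (5 x 2*flank matrix over A,C,G,T,N; columns are
#'   offsets), `offsets`, `element_start_fraction` (per offset),
#'   `hit_fraction` and `n_sites`.
#' @export
flank_profile <- function(sites, genome, flank = 50,
                          element = strrep("A", 10)) {
  stopifnot(nrow(sites) > 0)
  width <- 2 * flank
  seqs <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    chrseq <- genome[[sites$chrom[i]]]
    L <- length(chrseq)
    p <- sites$position[i]
    lo <- p - flank; hi <- p + flank  # 0-based half-open window [lo, hi)
    clo <- max(0, lo); chi <- min(L, hi)
    if (clo > lo || chi < hi)
      warning("flank window truncated at chromosome end for site at ", p)
    s <- as.character(Biostrings::subseq(chrseq, clo + 1, chi))
    s <- paste0(strrep("N", clo - lo), s, strrep("N", hi - chi))
    if (sites$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    seqs[i] <- s
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  bases <- c("A", "C", "G", "T", "N")
  freq <- apply(mat, 2, function(col) {
    real <- col != "N"
    n <- sum(real)
    cnt <- table(factor(col, bases))
    if (n > 0) {
      out <- as.numeric(cnt) / n
      out[5] <- 0 # masked positions excluded from the denominator
      out / max(sum(out), 1e-12)
    } else rep(0, 5)
  })
  rownames(freq) <- bases
  offsets <- seq(-flank, flank - 1)
  colnames(freq) <- offsets
  # overlap-aware scan: a hit at offset j means the element starts there
  k <- nchar(element)
  hit_at <- vapply(seq_len(width - k + 1), function(j)
    substring(seqs, j, j + k - 1) == element, logical(nrow(sites)))
  hit_at <- matrix(hit_at, nrow = nrow(sites))
  list(freq = freq, offsets = offsets,
       element_start_fraction = stats::setNames(colMeans(hit_at),
                                                offsets[seq_len(width - k + 1)]),
       hit_fraction = mean(rowSums(hit_at) > 0),
       n_sites = nrow(sites))
}
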