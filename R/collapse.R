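#' Same-gene grouping rule
#'
#' Two mapped full-length reads belong to the same gene when they map in the
#' same direction, their spans overlap by more than `min_span_overlap_fraction`
#' and at least one exon pair overlaps by more than
#' `min_exon_overlap_fraction`. Overlap fractions are computed on the shorter
#' of the two features (the strictest symmetric choice for nested fragments);
#' both thresholds are strict (`>`).
#'
#' @param min_span_overlap_fraction span-overlap threshold (default 0.20).
#' @param min_exon_overlap_fraction exon-overlap threshold (default 0.20).
#' @param require_same_strand require identical strand (default TRUE).
#' @export
same_gene_rule <- function(min_span_overlap_fraction = 0.20,
                           min_exon_overlap_fraction = 0.20,
                           require_same_strand = TRUE) {
  stopifnot(min_span_overlap_fraction >= 0, min_span_overlap_fraction <= 1,
            min_exon_overlap_fraction >= 0, min_exon_overlap_fraction <= 1)
  structure(list(min_span_overlap_fraction = min_span_overlap_fraction,
                 min_exon_overlap_fraction = min_exon_overlap_fraction,
                 require_same_strand = require_same_strand),
            class = "same_gene_rule")
}

#' Overlap fraction of two intervals
#'
#' `|a intersect b| / min(|a|, |b|)`; 0 when disjoint. Intervals are 0-based
#' half-open `c(start, end)` on the same chromosome.
#'
#' @param a,b numeric length-2 vectors `c(start, end)`.
#' @export
span_overlap_fraction <- function(a, b) {
  if (a[2] <= a[1] || b[2] <= b[1]) stop("empty interval")
  ov <- min(a[2], b[2]) - max(a[1], b[1])
  if (ov <= 0) return(0)
  ov / min(a[2] - a[1], b[2] - b[1])
}

# vectorized overlap fraction on parallel interval columns
.ov_frac <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ifelse(ov <= 0, 0, ov / pmin(e1 - s1, e2 - s2))
}

#' Test whether two transcripts are from the same gene
#'
#' @param t1,t2 single-transcript [tx_set()] objects.
#' @param rule a [same_gene_rule()].
#' @return logical; symmetric in its arguments.
#' @export
same_gene <- function(t1, t2, rule = same_gene_rule()) {
  stopifnot(n_tx(t1) == 1, n_tx(t2) == 1)
  a <- t1$transcripts; b <- t2$transcripts
  if (a$chrom != b$chrom) return(FALSE)
  if (rule$require_same_strand && a$strand != b$strand) return(FALSE)
  s1 <- tx_spans(t1); s2 <- tx_spans(t2)
  f <- span_overlap_fraction(c(s1$start, s1$end), c(s2$start, s2$end))
  if (f <= rule$min_span_overlap_fraction) return(FALSE)
  e1 <- t1$exons; e2 <- t2$exons
  for (i in seq_len(nrow(e1))) {
    fe <- .ov_frac(e1$start[i], e1$end[i], e2$start, e2$end)
    if (any(fe > rule$min_exon_overlap_fraction)) return(TRUE)
  }
  FALSE
}

# union-find with path halving
.uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# all qualifying same-gene edges among reads, vectorized through GRanges
.same_gene_edges <- function(reads, rule) {
  sp <- tx_spans(reads)
  spg <- span_granges(reads)
  hits <- GenomicRanges::findOverlaps(spg,
            ignore.strand = !rule$require_same_strand,
            drop.self = TRUE, drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(matrix(integer(), ncol = 2))
  keep <- .ov_frac(sp$start[qi], sp$end[qi], sp$start[si], sp$end[si]) >
    rule$min_span_overlap_fraction
  qi <- qi[keep]; si <- si[keep]
  if (!length(qi)) return(matrix(integer(), ncol = 2))
  # exon-level qualifying transcript pairs
  eg <- exon_granges(reads)
  eh <- GenomicRanges::findOverlaps(eg,
          ignore.strand = !rule$require_same_strand,
          drop.self = TRUE, drop.redundant = TRUE)
  eq <- S4Vectors::queryHits(eh); es <- S4Vectors::subjectHits(eh)
  ex <- reads$exons
  ekeep <- .ov_frac(ex$start[eq], ex$end[eq], ex$start[es], ex$end[es]) >
    rule$min_exon_overlap_fraction
  tx_idx <- match(ex$tx_id, reads$transcripts$tx_id)
  ta <- tx_idx[eq[ekeep]]; tb <- tx_idx[es[ekeep]]
  exon_pairs <- unique(paste(pmin(ta, tb), pmax(ta, tb)))
  span_pairs <- paste(pmin(qi, si), pmax(qi, si))
  ok <- span_pairs %in% exon_pairs
  cbind(pmin(qi, si)[ok], pmax(qi, si)[ok])
}

#' Group reads into gene loci
#'
#' Loci are the connected components of the graph whose edges are
#' [same_gene()] pairs (transitive closure of the pairwise relation, found by
#' union-find). Locus ids are deterministic, ordered by (chrom, start).
#'
#' @param reads a [tx_set()] of mapped reads.
#' @param rule a [same_gene_rule()].
#' @return list with `loci` (data.frame `locus_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_reads`) and `reads` (the input `tx_set` with a
#'   `locus_id` column added).
#' @export
build_loci <- function(reads, rule = same_gene_rule()) {
  n <- n_tx(reads)
  if (n == 0)
    return(list(loci = data.frame(locus_id = character(), chrom = character(),
                                  strand = character(), start = numeric(),
                                  end = numeric(), n_reads = integer()),
                reads = reads))
  comp <- .uf_components(n, .same_gene_edges(reads, rule))
  sp <- tx_spans(reads)
  cstart <- tapply(sp$start, comp, min)
  cend <- tapply(sp$end, comp, max)
  cchrom <- tapply(sp$chrom, comp, `[`, 1)
  cstrand <- tapply(sp$strand, comp, `[`, 1)
  uc <- as.integer(names(cstart))
  ord <- order(cchrom, cstart, cend)
  locus_id <- sprintf("LOC%05d", seq_along(uc))
  names(locus_id) <- uc[ord]
  loci <- data.frame(locus_id = locus_id,
                     chrom = as.character(cchrom)[ord],
                     strand = as.character(cstrand)[ord],
                     start = as.numeric(cstart)[ord],
                     end = as.numeric(cend)[ord],
                     n_reads = as.integer(table(comp))[ord],
                     stringsAsFactors = FALSE, row.names = NULL)
  reads$transcripts$locus_id <- unname(locus_id[as.character(comp)])
  list(loci = loci, reads = reads)
}

#' Collapse reads of each locus into non-redundant isoforms
#'
#' Multi-exon reads with identical intron chains merge into one isoform whose
#' terminal exon ends are the extreme 5'/3' read ends. Mono-exon reads merge
#' when mutually contained within `mono_end_tol`; containment components are
#' iterated to a fixpoint so that collapsing a collapsed set is a no-op.
#' Each isoform carries `support` (number of merged reads) and `samples`
#' (comma-joined sorted source samples).
#'
#' @param reads a [tx_set()] with a `locus_id` column (see [build_loci()]).
#' @param mono_end_tol end tolerance (bp) for mono-exon containment merging.
#' @param min_support isoforms with fewer supporting reads are dropped
#'   (default 1 = keep all).
#' @return list with `isoforms` (a `tx_set` with `gene_id` = locus id,
#'   `support`, `samples`) and `read_to_isoform` (data.frame `tx_id`,
#'   `isoform_id`, `kept`).
#' @export
collapse_isoforms <- function(reads, mono_end_tol = 20, min_support = 1) {
  stopifnot("locus_id" %in% names(reads$transcripts))
  tr <- reads$transcripts
  sp <- tx_spans(reads)
  nex <- n_exons(reads)
  chains <- intron_chain_key(reads)
  smp <- if ("sample" %in% names(tr)) as.character(tr$sample) else
    rep(NA_character_, nrow(tr))
  ins <- introns(reads)
  iso_tr <- list(); iso_ex <- list(); r2i <- list()
  for (loc in unique(tr$locus_id)) {
    idx <- which(tr$locus_id == loc)
    multi <- idx[nex[idx] > 1]
    mono <- idx[nex[idx] == 1]
    groups <- list()
    if (length(multi))
      groups <- c(groups, unname(split(multi, chains[multi])))
    if (length(mono))
      groups <- c(groups, .mono_groups(sp[mono, , drop = FALSE], mono,
                                       mono_end_tol))
    # deterministic isoform order: by merged start, end, chain
    gstart <- vapply(groups, function(g) min(sp$start[g]), numeric(1))
    gend <- vapply(groups, function(g) max(sp$end[g]), numeric(1))
    gkey <- vapply(groups, function(g) chains[g[1]], character(1))
    groups <- groups[order(gstart, gend, gkey)]
    for (k in seq_along(groups)) {
      g <- groups[[k]]
      iso_id <- sprintf("%s.iso%03d", loc, k)
      first <- g[1]
      if (nex[first] > 1) {
        ichain <- ins[ins$tx_id == tr$tx_id[first], , drop = FALSE]
        bounds <- sort(c(min(sp$start[g]), ichain$start, ichain$end,
                         max(sp$end[g])))
        ex <- data.frame(tx_id = iso_id,
                         start = bounds[seq(1, length(bounds), 2)],
                         end = bounds[seq(2, length(bounds), 2)],
                         stringsAsFactors = FALSE)
      } else {
        ex <- data.frame(tx_id = iso_id, start = min(sp$start[g]),
                         end = max(sp$end[g]), stringsAsFactors = FALSE)
      }
      sams <- sort(unique(smp[g][!is.na(smp[g])]))
      iso_tr[[length(iso_tr) + 1]] <- data.frame(
        tx_id = iso_id, chrom = tr$chrom[first], strand = tr$strand[first],
        gene_id = loc, support = length(g),
        samples = if (length(sams)) paste(sams, collapse = ",") else
          NA_character_,
        stringsAsFactors = FALSE)
      iso_ex[[length(iso_ex) + 1]] <- ex
      r2i[[length(r2i) + 1]] <- data.frame(tx_id = tr$tx_id[g],
                                           isoform_id = iso_id,
                                           stringsAsFactors = FALSE)
    }
  }
  iso_tr <- do.call(rbind, iso_tr)
  keep <- iso_tr$support >= min_support
  map <- do.call(rbind, r2i)
  map$kept <- map$isoform_id %in% iso_tr$tx_id[keep]
  isoforms <- tx_set(iso_tr[keep, , drop = FALSE],
                     do.call(rbind, iso_ex)[
                       do.call(rbind, iso_ex)$tx_id %in% iso_tr$tx_id[keep], ,
                       drop = FALSE])
  list(isoforms = isoforms, read_to_isoform = map)
}

# mono-exon containment components, iterated to fixpoint on interval hulls
.mono_groups <- function(sp_mono, idx, tol) {
  items <- lapply(seq_along(idx), function(i)
    list(start = sp_mono$start[i], end = sp_mono$end[i], members = idx[i]))
  repeat {
    n <- length(items)
    if (n <= 1) break
    st <- vapply(items, `[[`, numeric(1), "start")
    en <- vapply(items, `[[`, numeric(1), "end")
    edges <- NULL
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      contained <- (st[i] >= st[j] - tol & en[i] <= en[j] + tol) |
        (st[j] >= st[i] - tol & en[j] <= en[i] + tol)
      if (any(contained)) edges <- rbind(edges, cbind(i, j[contained]))
    }
    if (is.null(edges)) break
    comp <- .uf_components(n, edges)
    if (length(unique(comp)) == n) break
    items <- lapply(split(seq_len(n), comp), function(g)
      list(start = min(st[g]), end = max(en[g]),
           members = unlist(lapply(items[g], `[[`, "members"))))
  }
  lapply(items, `[[`, "members")
}

#' Collapse mapped reads into loci and non-redundant isoforms
#'
#' Convenience driver: [build_loci()] followed by [collapse_isoforms()].
#'
#' @inheritParams build_loci
#' @inheritParams collapse_isoforms
#' @return list with `loci`, `isoforms`, `read_to_isoform`, `reads` (with
#'   locus assignment).
#' @export
collapse_reads <- function(reads, rule = same_gene_rule(), mono_end_tol = 20,
                           min_support = 1) {
  bl <- build_loci(reads, rule)
  ci <- collapse_isoforms(bl$reads, mono_end_tol, min_support)
  list(loci = bl$loci, isoforms = ci$isoforms,
       read_to_isoform = ci$read_to_isoform, reads = bl$reads)
}
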