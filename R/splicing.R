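#' Alternative-splicing events between two isoforms
#'
#' Compares the intron chains of two same-locus isoforms within the region
#' where their spans overlap. Fully shared introns act as anchors; each
#' maximal segment between anchors where the chains differ is one variant,
#' typed as:
#' \describe{
#'   \item{ES}{exon(s) internal to one chain absent from the other, with the
#'     flanking intron outer boundaries shared.}
#'   \item{IR}{an intron of one chain fully exonic in the other.}
#'   \item{AD}{shared acceptor, differing donor (strand-aware: the donor is
#'     the 5' splice site in transcription direction).}
#'   \item{AA}{shared donor, differing acceptor.}
#'   \item{MEE}{two non-overlapping exons, each present in exactly one
#'     chain, between shared flanking junction boundaries.}
#' }
#' Variants matching none of the five types are labelled `complex`.
#' Terminal-exon end differences are not events (they are TSS/polyA
#' variation), and introns only partly inside the common span region are
#' ignored for the same reason. The result is symmetric in argument order.
#'
#' @param t1,t2 single-transcript [tx_set()] objects on the same chromosome
#'   and strand.
#' @return data.frame with `type`, `region_start`, `region_end`,
#'   `anchor_left`, `anchor_right`, `witness1`, `witness2` (witnesses sorted
#'   so the result is order-independent); zero rows when the isoforms do not
#'   differ within their common region.
#' @export
pairwise_events <- function(t1, t2) {
  stopifnot(n_tx(t1) == 1, n_tx(t2) == 1)
  a <- t1$transcripts; b <- t2$transcripts
  if (a$chrom != b$chrom || a$strand != b$strand)
    stop("pairwise_events requires transcripts on the same chromosome and strand")
  w <- sort(c(a$tx_id, b$tx_id))
  empty <- data.frame(type = character(), region_start = numeric(),
                      region_end = numeric(), anchor_left = numeric(),
                      anchor_right = numeric(), witness1 = character(),
                      witness2 = character(), stringsAsFactors = FALSE)
  s1 <- tx_spans(t1); s2 <- tx_spans(t2)
  r0 <- max(s1$start, s2$start); r1 <- min(s1$end, s2$end)
  if (r1 <= r0) return(empty)
  i1 <- introns(t1); i2 <- introns(t2)
  i1 <- i1[i1$start >= r0 & i1$end <= r1, , drop = FALSE]
  i2 <- i2[i2$start >= r0 & i2$end <= r1, , drop = FALSE]
  key1 <- paste(i1$start, i1$end); key2 <- paste(i2$start, i2$end)
  shared <- i1[key1 %in% key2, , drop = FALSE]
  u1 <- i1[!key1 %in% key2, , drop = FALSE]
  u2 <- i2[!key2 %in% key1, , drop = FALSE]
  if (nrow(u1) + nrow(u2) == 0) return(empty)
  # segment boundaries: region ends plus shared-intron anchors
  aL <- c(r0, shared$end); aR <- c(shared$start, r1)
  ord <- order(aL)
  aL <- aL[ord]; aR <- sort(aR)
  out <- empty
  for (s in seq_along(aL)) {
    g1 <- u1[u1$start >= aL[s] & u1$end <= aR[s], , drop = FALSE]
    g2 <- u2[u2$start >= aL[s] & u2$end <= aR[s], , drop = FALSE]
    if (nrow(g1) + nrow(g2) == 0) next
    ev <- .type_variant(g1, g2, a$strand)
    out <- rbind(out, data.frame(type = ev$type,
                                 region_start = ev$region[1],
                                 region_end = ev$region[2],
                                 anchor_left = aL[s], anchor_right = aR[s],
                                 witness1 = w[1], witness2 = w[2],
                                 stringsAsFactors = FALSE))
  }
  out
}

# type one variant segment from the two chains' unshared introns
.type_variant <- function(g1, g2, strand) {
  if (nrow(g1) < nrow(g2)) { tmp <- g1; g1 <- g2; g2 <- tmp }
  n1 <- nrow(g1); n2 <- nrow(g2)
  g1 <- g1[order(g1$start), , drop = FALSE]
  g2 <- g2[order(g2$start), , drop = FALSE]
  if (n2 == 0 && n1 == 1)
    return(list(type = "IR", region = c(g1$start, g1$end)))
  if (n2 == 1 && n1 >= 2 &&
      g2$start == g1$start[1] && g2$end == g1$end[n1])
    return(list(type = "ES", region = c(g1$end[1], g1$start[n1])))
  if (n1 == 1 && n2 == 1) {
    same_start <- g1$start == g2$start
    same_end <- g1$end == g2$end
    if (same_start != same_end) {
      # strand-aware donor/acceptor: on "+" the donor is the intron start
      if (same_end) {
        ty <- if (strand == "+") "AD" else "AA"
        region <- range(c(g1$start, g2$start))
      } else {
        ty <- if (strand == "+") "AA" else "AD"
        region <- range(c(g1$end, g2$end))
      }
      return(list(type = ty, region = region))
    }
  }
  if (n1 == 2 && n2 == 2 &&
      g1$start[1] == g2$start[1] && g1$end[2] == g2$end[2]) {
    e1 <- c(g1$end[1], g1$start[2])
    e2 <- c(g2$end[1], g2$start[2])
    if (e1[2] <= e2[1] || e2[2] <= e1[1])
      return(list(type = "MEE",
                  region = c(min(e1[1], e2[1]), max(e1[2], e2[2]))))
  }
  all_s <- c(g1$start, g1$end, g2$start, g2$end)
  list(type = "complex", region = range(all_s))
}

#' Deduplicated event set per gene
#'
#' Union of [pairwise_events()] over all isoform pairs of each gene,
#' deduplicated by event key (gene, type, region, anchors). Complex variants
#' are kept in the table but reported separately from the five-type counts.
#'
#' @param isoforms a [tx_set()] with `gene_id`.
#' @return data.frame of events with `gene_id` and the pairwise columns;
#'   `witness1`/`witness2` are from the first pair exhibiting the event.
#' @export
gene_events <- function(isoforms) {
  tr <- isoforms$transcripts
  out <- list()
  for (g in unique(tr$gene_id)) {
    ids <- tr$tx_id[tr$gene_id == g]
    if (length(ids) < 2) next
    evs <- list()
    for (i in seq_len(length(ids) - 1))
      for (j in (i + 1):length(ids)) {
        e <- pairwise_events(subset_tx(isoforms, ids[i]),
                             subset_tx(isoforms, ids[j]))
        if (nrow(e)) evs[[length(evs) + 1]] <- e
      }
    if (!length(evs)) next
    ev <- do.call(rbind, evs)
    key <- paste(ev$type, ev$region_start, ev$region_end,
                 ev$anchor_left, ev$anchor_right)
    ev <- ev[!duplicated(key), , drop = FALSE]
    ev <- cbind(gene_id = g, ev, stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- ev
  }
  if (!length(out))
    return(data.frame(gene_id = character(), type = character(),
                      region_start = numeric(), region_end = numeric(),
                      anchor_left = numeric(), anchor_right = numeric(),
                      witness1 = character(), witness2 = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Event counts per sample and combined
#'
#' Per-sample counts are computed on the sample-restricted isoform sets (an
#' isoform is present in a sample when the sample appears in its `samples`
#' label); the combined count is computed on the full isoform set. The
#' combined count is at least each per-sample count but need not equal their
#' sum: an event witnessed only by isoforms from different samples appears
#' in the combined analysis and in no single sample.
#'
#' @param isoforms a [tx_set()] with `gene_id` and `samples`
#'   (comma-separated sample labels, as produced by [collapse_isoforms()]).
#' @param samples sample labels to report; default: all labels observed.
#' @return list with `events` (the combined event table), `per_sample`
#'   (named list of per-sample event tables) and `summary` (data.frame
#'   type x sample counts, including `combined`, plus a `complex` row).
#' @export
count_events_by_sample <- function(isoforms, samples = NULL) {
  tr <- isoforms$transcripts
  stopifnot("samples" %in% names(tr))
  sample_sets <- strsplit(ifelse(is.na(tr$samples), "", tr$samples), ",")
  if (is.null(samples))
    samples <- sort(unique(unlist(sample_sets)))
  combined <- gene_events(isoforms)
  per_sample <- lapply(samples, function(s) {
    ids <- tr$tx_id[vapply(sample_sets, function(v) s %in% v, logical(1))]
    gene_events(subset_tx(isoforms, ids))
  })
  names(per_sample) <- samples
  types <- c("ES", "IR", "AA", "AD", "MEE", "complex")
  tab <- vapply(c(per_sample, list(combined = combined)), function(e)
    as.integer(table(factor(e$type, types))), integer(length(types)))
  summary <- data.frame(type = types, tab, check.names = FALSE,
                        stringsAsFactors = FALSE)
  list(events = combined, per_sample = per_sample, summary = summary)
}

#' Per-type AS summary for a combined event table
#'
#' @param events data.frame from [gene_events()].
#' @return data.frame `type`, `n_events`, `n_genes` (distinct genes with at
#'   least one event of the type); complex variants listed last.
#' @export
as_type_summary <- function(events) {
  types <- c("ES", "IR", "AA", "AD", "MEE", "complex")
  data.frame(
    type = types,
    n_events = vapply(types, function(t) sum(events$type == t), integer(1)),
    n_genes = vapply(types, function(t)
      length(unique(events$gene_id[events$type == t])), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
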