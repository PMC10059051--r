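#' Classify collapsed gene loci as known or novel
#'
#' A locus is novel when (1) it has no overlap, or overlap not exceeding the
#' rule threshold, with any annotated gene on either strand, or (2) its
#' best-overlapping annotated gene exceeds the threshold but lies on the
#' opposite strand. Otherwise it is known and linked to the best-overlapping
#' same-strand reference gene (ties broken by larger overlap, then smaller
#' reference start). Overlap is the span-overlap fraction of the shorter
#' feature, as in [same_gene_rule()].
#'
#' @param loci data.frame from [build_loci()] (`locus_id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @param ref reference [annotation()].
#' @param rule a [same_gene_rule()]; its span threshold is used.
#' @return data.frame `feature_id`, `level`, `call`, `reason`,
#'   `matched_reference_id`.
#' @export
classify_genes <- function(loci, ref, rule = same_gene_rule()) {
  thr <- rule$min_span_overlap_fraction
  g <- ref$genes
  ggr <- gene_granges(ref)
  lgr <- .gr(loci$chrom, loci$start, loci$end, loci$strand)
  hits <- GenomicRanges::findOverlaps(lgr, ggr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  frac <- .ov_frac(loci$start[qi], loci$end[qi], g$start[si], g$end[si])
  out <- data.frame(feature_id = loci$locus_id, level = "gene",
                    call = "novel", reason = "no_overlap",
                    matched_reference_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(loci))) {
    sel <- which(qi == i)
    if (!length(sel)) next
    fr <- frac[sel]
    best <- sel[order(-fr, g$start[si[sel]])][1]
    if (max(fr) <= thr) {
      out$reason[i] <- "low_overlap"
    } else if (g$strand[si[best]] != loci$strand[i]) {
      out$reason[i] <- "opposite_strand"
      out$matched_reference_id[i] <- g$gene_id[si[best]]
    } else {
      out$call[i] <- "known"; out$reason[i] <- "matched"
      out$matched_reference_id[i] <- g$gene_id[si[best]]
    }
  }
  out
}

#' Classify collapsed isoforms as known or novel transcripts
#'
#' An isoform of a known gene is known when its intron chain equals some
#' reference isoform's intron chain (end differences ignored), or when both
#' it and a reference isoform are single-exon with reciprocal span overlap
#' above the rule threshold. It is novel when it carries a splice site
#' (intron boundary) absent from the reference isoforms of its gene, when
#' its junction combination matches no reference chain, or when exactly one
#' of the pair is single-exon. Isoforms of novel loci are novel by
#' inheritance and carry the locus-level reason.
#'
#' @param isoforms a [tx_set()] of collapsed isoforms with `gene_id` = locus.
#' @param gene_calls data.frame from [classify_genes()].
#' @param ref reference [annotation()].
#' @param rule a [same_gene_rule()].
#' @return data.frame `feature_id`, `level`, `call`, `reason`,
#'   `matched_reference_id`.
#' @export
classify_transcripts <- function(isoforms, gene_calls, ref,
                                 rule = same_gene_rule()) {
  thr <- rule$min_span_overlap_fraction
  tr <- isoforms$transcripts
  sp <- tx_spans(isoforms)
  nex <- n_exons(isoforms)
  ref_gene_of_tx <- ref$tx$transcripts$gene_id
  names(ref_gene_of_tx) <- ref$tx$transcripts$tx_id
  ref_chain <- intron_chain_key(ref$tx)
  ref_sp <- tx_spans(ref$tx)
  ref_nex <- n_exons(ref$tx)
  my_chain <- intron_chain_key(isoforms)
  gmap <- gene_calls$matched_reference_id
  names(gmap) <- gene_calls$feature_id
  greason <- gene_calls$reason
  names(greason) <- gene_calls$feature_id
  gcall <- gene_calls$call
  names(gcall) <- gene_calls$feature_id

  out <- data.frame(feature_id = tr$tx_id, level = "transcript",
                    call = "novel", reason = NA_character_,
                    matched_reference_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tr))) {
    loc <- tr$gene_id[i]
    if (gcall[loc] == "novel") {
      out$reason[i] <- greason[loc]
      next
    }
    rg <- gmap[loc]
    ref_tx_ids <- names(ref_gene_of_tx)[ref_gene_of_tx == rg]
    if (nex[i] > 1) {
      hit <- ref_tx_ids[ref_chain[ref_tx_ids] == my_chain[i]]
      if (length(hit)) {
        out$call[i] <- "known"; out$reason[i] <- "matched"
        out$matched_reference_id[i] <- hit[1]
      } else {
        # a new individual boundary or a new junction combination both mean
        # a splice structure absent from the reference
        out$reason[i] <- "new_splice_site"
      }
    } else {
      mono_ref <- ref_tx_ids[ref_nex[ref_tx_ids] == 1]
      matched <- NA_character_
      for (rt in mono_ref) {
        k <- match(rt, ref_sp$tx_id)
        ov <- min(sp$end[i], ref_sp$end[k]) - max(sp$start[i], ref_sp$start[k])
        if (ov > 0 &&
            ov / (sp$end[i] - sp$start[i]) > thr &&
            ov / (ref_sp$end[k] - ref_sp$start[k]) > thr) {
          matched <- rt; break
        }
      }
      if (!is.na(matched)) {
        out$call[i] <- "known"; out$reason[i] <- "matched"
        out$matched_reference_id[i] <- matched
      } else {
        out$reason[i] <- "single_exon_mismatch"
      }
    }
  }
  out
}

#' Run both novelty levels on a collapse result
#'
#' @param collapse result of [collapse_reads()].
#' @param ref reference [annotation()].
#' @param rule a [same_gene_rule()].
#' @return list with `genes` and `transcripts` call tables.
#' @export
classify_novelty <- function(collapse, ref, rule = same_gene_rule()) {
  gc <- classify_genes(collapse$loci, ref, rule)
  tc <- classify_transcripts(collapse$isoforms, gc, ref, rule)
  list(genes = gc, transcripts = tc)
}
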