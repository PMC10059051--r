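#' Train a hexamer usage model from reference coding sequences
#'
#' The coding model is the 6-mer frequency distribution of the training
#' CDS set (pseudocount 1); the background model is the zeroth-order
#' expectation from the training set's mononucleotide composition. The
#' score of a sequence is the mean log-likelihood ratio (coding vs
#' background) of its overlapping hexamers; coding sequence scores
#' positive, compositionally unstructured sequence scores negative.
#'
#' @param cds a `DNAStringSet` (or character vector) of coding sequences.
#' @return list with `log_ratio` (named vector over the 4096 hexamers) and
#'   `base_freq`.
#' @export
train_hexamer_model <- function(cds) {
  if (length(cds) == 0) stop("empty training set")
  cds <- Biostrings::DNAStringSet(cds)
  hex <- colSums(Biostrings::oligonucleotideFrequency(cds, width = 6,
                                                      step = 1))
  hex <- hex + 1
  p_cod <- hex / sum(hex)
  mono <- colSums(Biostrings::oligonucleotideFrequency(cds, width = 1))
  mono <- (mono + 1) / sum(mono + 1)
  letters6 <- strsplit(names(hex), "")
  p_bg <- vapply(letters6, function(l) prod(mono[l]), numeric(1))
  list(log_ratio = stats::setNames(log(p_cod) - log(p_bg), names(hex)),
       base_freq = mono)
}

# mean hexamer log-likelihood ratio of one or more sequences
.hexamer_score <- function(seqs, model) {
  seqs <- Biostrings::DNAStringSet(seqs)
  cnt <- Biostrings::oligonucleotideFrequency(seqs, width = 6, step = 1)
  tot <- rowSums(cnt)
  sc <- as.numeric(cnt %*% model$log_ratio[colnames(cnt)])
  ifelse(tot > 0, sc / tot, 0)
}

# longest open reading frame (in codons) over the three forward frames;
# an ORF open at the 3' end counts
.longest_orf <- function(seq_char) {
  n <- nchar(seq_char)
  best <- 0L
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 1) next
    cods <- substring(seq_char, frame + 3 * (seq_len(ncod) - 1) + 1,
                      frame + 3 * seq_len(ncod))
    is_start <- cods == "ATG"
    is_stop <- cods %in% c("TAA", "TAG", "TGA")
    open <- -1L
    for (i in seq_len(ncod)) {
      if (is_stop[i]) {
        if (open > 0) best <- max(best, i - open)
        open <- -1L
      } else if (is_start[i] && open < 0) open <- i
    }
    if (open > 0) best <- max(best, ncod - open + 1L)
  }
  as.integer(best)
}

#' Coding-potential heuristic
#'
#' A lightweight ORF-plus-hexamer classifier: a transcript is called
#' noncoding when its longest forward-frame ORF is shorter than
#' `orf_min_codons`, its hexamer score against the training model is below
#' `score_threshold`, and its length is at least `min_lnc_length` (shorter
#' sequences are not lncRNA candidates at all and are flagged ineligible).
#' This heuristic is not equivalent to the dedicated coding-potential tools
#' used in large annotation projects; externally produced calls can be
#' substituted via the `external_calls` argument of [lncrna_calls()].
#'
#' @param seqs named `DNAStringSet` (or character vector) of transcript
#'   sequences (already stranded).
#' @param ref_cds training coding sequences, or a model from
#'   [train_hexamer_model()].
#' @param orf_min_codons ORF threshold in codons (default 100).
#' @param score_threshold hexamer log-ratio threshold (default 0).
#' @param min_lnc_length minimum lncRNA length in nt (default 200).
#' @return data.frame `tx_id`, `length`, `orf_codons`, `hexamer_score`,
#'   `call` (`coding`/`noncoding`), `eligible` (length filter).
#' @export
coding_potential <- function(seqs, ref_cds, orf_min_codons = 100,
                             score_threshold = 0, min_lnc_length = 200) {
  model <- if (is.list(ref_cds) && !is.null(ref_cds$log_ratio)) ref_cds
           else train_hexamer_model(ref_cds)
  seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) == 0)
    return(data.frame(tx_id = character(), length = integer(),
                      orf_codons = integer(), hexamer_score = numeric(),
                      call = character(), eligible = logical(),
                      stringsAsFactors = FALSE))
  chr <- as.character(seqs)
  orf <- vapply(chr, .longest_orf, integer(1), USE.NAMES = FALSE)
  score <- .hexamer_score(seqs, model)
  len <- Biostrings::width(seqs)
  eligible <- len >= min_lnc_length
  noncoding <- orf < orf_min_codons & score < score_threshold & eligible
  data.frame(tx_id = if (is.null(names(seqs)))
               as.character(seq_along(seqs)) else names(seqs),
             length = len, orf_codons = orf, hexamer_score = score,
             call = ifelse(noncoding, "noncoding", "coding"),
             eligible = eligible, stringsAsFactors = FALSE)
}

#' Positional classification of noncoding transcripts
#'
#' Precedence order: (1) `intronic` - the span lies entirely within a single
#' intron of some reference transcript, either strand; (2) `sense` - exons
#' overlap exons of a same-strand reference gene; (3) `antisense` - exons
#' overlap exons of an opposite-strand reference gene; (4) `intergenic` -
#' no overlap with any reference gene span (transcripts that overlap a span
#' without exonic overlap and without full intron containment also fall
#' here). Ties within one precedence class pick the anchor gene with the
#' larger exonic overlap.
#'
#' @param x a [tx_set()] of candidate transcripts.
#' @param ref reference [annotation()].
#' @return data.frame `tx_id`, `class`, `anchor_gene`.
#' @export
classify_position <- function(x, ref) {
  sp <- tx_spans(x)
  ref_ins <- introns(ref$tx)
  ref_tr <- ref$tx$transcripts
  out <- data.frame(tx_id = sp$tx_id, class = "intergenic",
                    anchor_gene = NA_character_, stringsAsFactors = FALSE)
  if (nrow(sp) == 0) return(out)
  # (1) intron containment, either strand
  if (nrow(ref_ins)) {
    igr <- .gr(ref_tr$chrom[match(ref_ins$tx_id, ref_tr$tx_id)],
               ref_ins$start, ref_ins$end)
    sgr <- .gr(sp$chrom, sp$start, sp$end)
    win <- GenomicRanges::findOverlaps(sgr, igr, type = "within",
                                       ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(win)
    host <- ref_tr$gene_id[match(ref_ins$tx_id[S4Vectors::subjectHits(win)],
                                 ref_tr$tx_id)]
    if (length(qi)) {
      first <- !duplicated(qi)
      out$class[qi[first]] <- "intronic"
      out$anchor_gene[qi[first]] <- host[first]
    }
  }
  todo <- out$class == "intergenic"
  if (!any(todo)) return(out)
  # (2)/(3) exonic overlap by strand relation
  eg <- exon_granges(x)
  reg <- exon_granges(ref$tx)
  hits <- GenomicRanges::findOverlaps(eg, reg, ignore.strand = TRUE)
  if (length(hits)) {
    qx <- S4Vectors::mcols(eg)$tx_id[S4Vectors::queryHits(hits)]
    rx <- S4Vectors::mcols(reg)$tx_id[S4Vectors::subjectHits(hits)]
    ovw <- GenomicRanges::width(GenomicRanges::pintersect(
      eg[S4Vectors::queryHits(hits)], reg[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    same <- x$transcripts$strand[match(qx, x$transcripts$tx_id)] ==
      ref_tr$strand[match(rx, ref_tr$tx_id)]
    rgene <- ref_tr$gene_id[match(rx, ref_tr$tx_id)]
    df <- data.frame(tx = qx, gene = rgene, same = same, ov = ovw,
                     stringsAsFactors = FALSE)
    agg <- stats::aggregate(ov ~ tx + gene + same, df, sum)
    for (i in which(todo)) {
      rows <- agg[agg$tx == sp$tx_id[i], , drop = FALSE]
      if (!nrow(rows)) next
      pick <- if (any(rows$same)) rows[rows$same, , drop = FALSE]
              else rows[!rows$same, , drop = FALSE]
      pick <- pick[order(-pick$ov, pick$gene), , drop = FALSE]
      out$class[i] <- if (pick$same[1]) "sense" else "antisense"
      out$anchor_gene[i] <- pick$gene[1]
    }
  }
  out
}

#' Candidate lncRNA calls for a collapsed isoform set
#'
#' Runs [coding_potential()] on the isoform sequences (or applies
#' externally produced calls) and classifies the noncoding transcripts
#' positionally.
#'
#' @param isoforms a [tx_set()].
#' @param genome `DNAStringSet`.
#' @param ref reference [annotation()] (for positional classes and, by
#'   default, the coding training set from its transcript sequences).
#' @param ref_cds optional training sequences or hexamer model; defaults to
#'   the reference transcripts' sequences.
#' @param external_calls optional data.frame `tx_id`, `call`
#'   (`coding`/`noncoding`) replacing the built-in heuristic.
#' @param min_lnc_length,orf_min_codons,score_threshold see
#'   [coding_potential()].
#' @return list with `coding` (the per-transcript coding table) and
#'   `lncrna` (positional classes of the noncoding, length-eligible set).
#' @export
lncrna_calls <- function(isoforms, genome, ref, ref_cds = NULL,
                         external_calls = NULL, min_lnc_length = 200,
                         orf_min_codons = 100, score_threshold = 0) {
  seqs <- tx_sequences(isoforms, genome)
  if (is.null(external_calls)) {
    if (is.null(ref_cds)) ref_cds <- tx_sequences(ref$tx, genome)
    cp <- coding_potential(seqs, ref_cds, orf_min_codons, score_threshold,
                           min_lnc_length)
  } else {
    len <- Biostrings::width(seqs)
    cp <- data.frame(tx_id = names(seqs), length = len,
                     orf_codons = NA_integer_, hexamer_score = NA_real_,
                     call = external_calls$call[
                       match(names(seqs), external_calls$tx_id)],
                     eligible = len >= min_lnc_length,
                     stringsAsFactors = FALSE)
    cp$call[is.na(cp$call)] <- "coding"
  }
  lnc_ids <- cp$tx_id[cp$call == "noncoding" & cp$eligible]
  pos <- classify_position(subset_tx(isoforms, lnc_ids), ref)
  list(coding = cp, lncrna = pos)
}

#' Summary of a lncRNA call set
#'
#' @param classes data.frame from [classify_position()] (the lncRNA set).
#' @param novel logical vector: is each lncRNA absent from the known lncRNA
#'   set? Alternatively supply `known_lnc` to compute it.
#' @param known_lnc optional [tx_set()] of known lncRNAs; a call is known
#'   when a same-strand known transcript shares its intron-chain key and
#'   overlaps its span.
#' @param lnc_set optional [tx_set()] of the called lncRNAs (required when
#'   `known_lnc` is used, and for length summaries).
#' @param mrna_lengths optional numeric vector of mRNA spliced lengths for
#'   the length comparison.
#' @return list with `class_counts`, `class_pct` (2 decimals), `n`,
#'   `novel_n`, `novel_pct`, and `length_summary` when lengths are
#'   available.
#' @export
lncrna_summary <- function(classes, novel = NULL, known_lnc = NULL,
                           lnc_set = NULL, mrna_lengths = NULL) {
  lv <- c("intronic", "sense", "antisense", "intergenic")
  cc <- table(factor(classes$class, lv))
  n <- nrow(classes)
  if (is.null(novel) && !is.null(known_lnc) && !is.null(lnc_set)) {
    kk <- intron_chain_key(known_lnc)
    ks <- tx_spans(known_lnc)
    mk <- intron_chain_key(lnc_set)
    msp <- tx_spans(lnc_set)
    novel <- vapply(seq_len(n_tx(lnc_set)), function(i) {
      cand <- which(kk == mk[i])
      !any(ks$end[cand] > msp$start[i] & ks$start[cand] < msp$end[i])
    }, logical(1))
    novel <- novel[match(classes$tx_id, msp$tx_id)]
  }
  out <- list(class_counts = cc,
              class_pct = stats::setNames(
                vapply(as.integer(cc), pct2, numeric(1), den = max(n, 1)),
                lv),
              n = n)
  if (!is.null(novel)) {
    out$novel_n <- sum(novel)
    out$novel_pct <- pct2(sum(novel), max(n, 1))
  }
  if (!is.null(lnc_set)) {
    ll <- spliced_length(lnc_set)
    out$length_summary <- list(
      lncrna = c(mean = mean(ll), median = stats::median(ll)),
      mrna = if (!is.null(mrna_lengths))
        c(mean = mean(mrna_lengths), median = stats::median(mrna_lengths)))
  }
  out
}
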