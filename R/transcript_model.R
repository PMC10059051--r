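#' Transcript set: the core data model
#'
#' A `tx_set` holds a collection of transcript models as two data frames:
#' `transcripts` (one row per transcript: `tx_id`, `chrom`, `strand`, and
#' optional columns such as `sample`, `gene_id`, `support`, `strandless`) and
#' `exons` (one row per exon: `tx_id`, `start`, `end`). All coordinates are
#' 0-based half-open; 1-based closed coordinates exist only at the GFF3/GTF
#' boundary. Exons of a transcript must be sorted by start, non-overlapping,
#' and separated by gaps of at least 1 bp (the introns).
#'
#' @param transcripts data.frame with at least `tx_id`, `chrom`, `strand`.
#' @param exons data.frame with `tx_id`, `start`, `end` (0-based half-open).
#' @param merge_adjacent merge exons separated by a gap < 1 bp (zero-length
#'   introns are format noise); a warning is emitted when this happens.
#' @return An object of class `tx_set`.
#' @export
tx_set <- function(transcripts, exons, merge_adjacent = TRUE) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  stopifnot(all(c("tx_id", "chrom", "strand") %in% names(transcripts)),
            all(c("tx_id", "start", "end") %in% names(exons)))
  transcripts$tx_id <- as.character(transcripts$tx_id)
  exons$tx_id <- as.character(exons$tx_id)
  if (anyDuplicated(transcripts$tx_id))
    stop("duplicated transcript ids: ",
         paste(unique(transcripts$tx_id[duplicated(transcripts$tx_id)]),
               collapse = ", "))
  if (!all(exons$tx_id %in% transcripts$tx_id))
    stop("exons reference unknown transcript ids")
  if (any(exons$start >= exons$end))
    stop("exon with start >= end (coordinates are 0-based half-open)")
  exons <- exons[order(match(exons$tx_id, transcripts$tx_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  x <- structure(list(transcripts = transcripts, exons = exons),
                 class = "tx_set")
  x <- .validate_exon_chains(x, merge_adjacent)
  x
}

.validate_exon_chains <- function(x, merge_adjacent) {
  ex <- x$exons
  if (nrow(ex) == 0) return(x)
  id <- ex$tx_id
  same <- c(FALSE, id[-1] == id[-length(id)])
  prev_end <- c(NA_real_, ex$end[-nrow(ex)])
  gap <- ex$start - prev_end
  bad <- same & gap < 0
  if (any(bad))
    stop("overlapping exons within transcript(s): ",
         paste(unique(id[bad]), collapse = ", "))
  adj <- same & gap < 1
  if (any(adj)) {
    if (!merge_adjacent)
      stop("adjacent exons (zero-length intron) in: ",
           paste(unique(id[adj]), collapse = ", "))
    warning("merging ", sum(adj), " adjacent exon pair(s) (zero-length introns)")
    # collapse runs of adjacency: group id increments where a new block starts
    grp <- cumsum(!adj)
    ex <- data.frame(tx_id = tapply(ex$tx_id, grp, `[`, 1),
                     start = as.numeric(tapply(ex$start, grp, min)),
                     end   = as.numeric(tapply(ex$end, grp, max)),
                     stringsAsFactors = FALSE)
    ex <- ex[order(match(ex$tx_id, x$transcripts$tx_id), ex$start), ,
             drop = FALSE]
    rownames(ex) <- NULL
    x$exons <- ex
  }
  miss <- setdiff(x$transcripts$tx_id, x$exons$tx_id)
  if (length(miss))
    stop("transcript(s) with no exons: ", paste(miss, collapse = ", "))
  x
}

#' @export
print.tx_set <- function(x, ...) {
  cat("tx_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Number of transcripts in a tx_set
#' @param x a `tx_set`.
#' @export
n_tx <- function(x) nrow(x$transcripts)

#' Genomic spans of the transcripts
#'
#' @param x a `tx_set`.
#' @return data.frame `tx_id`, `chrom`, `strand`, `start`, `end` in the order
#'   of `x$transcripts`; span is `[first exon start, last exon end)`.
#' @export
tx_spans <- function(x) {
  ex <- x$exons
  f <- factor(ex$tx_id, levels = x$transcripts$tx_id)
  data.frame(tx_id = x$transcripts$tx_id,
             chrom = x$transcripts$chrom,
             strand = x$transcripts$strand,
             start = as.numeric(tapply(ex$start, f, min)),
             end = as.numeric(tapply(ex$end, f, max)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exon counts per transcript
#' @param x a `tx_set`.
#' @export
n_exons <- function(x) {
  tab <- table(factor(x$exons$tx_id, levels = x$transcripts$tx_id))
  stats::setNames(as.integer(tab), x$transcripts$tx_id)
}

#' Spliced (mature transcript) lengths
#' @param x a `tx_set`.
#' @export
spliced_length <- function(x) {
  f <- factor(x$exons$tx_id, levels = x$transcripts$tx_id)
  stats::setNames(as.numeric(tapply(x$exons$end - x$exons$start, f, sum)),
                  x$transcripts$tx_id)
}

#' Intron table of a tx_set
#'
#' @param x a `tx_set`.
#' @return data.frame `tx_id`, `start`, `end` of introns (0-based half-open),
#'   i.e. the gaps between consecutive exons.
#' @export
introns <- function(x) {
  ex <- x$exons
  if (nrow(ex) < 2)
    return(data.frame(tx_id = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  id <- ex$tx_id
  same <- id[-1] == id[-length(id)]
  data.frame(tx_id = id[-1][same],
             start = ex$end[-nrow(ex)][same],
             end = ex$start[-1][same],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intron-chain identity keys
#'
#' The intron chain (ordered donor/acceptor coordinates together with
#' chromosome and strand) is the identity key used for isoform collapse.
#' Mono-exon transcripts get the key `"<chrom><strand>:."`.
#'
#' @param x a `tx_set`.
#' @return named character vector, one key per transcript.
#' @export
intron_chain_key <- function(x) {
  tr <- x$transcripts
  ins <- introns(x)
  chain <- rep(".", nrow(tr))
  names(chain) <- tr$tx_id
  if (nrow(ins)) {
    k <- vapply(split(paste0(ins$start, "-", ins$end),
                      factor(ins$tx_id, levels = tr$tx_id)),
                function(v) if (all(is.na(v))) "." else paste(v, collapse = ";"),
                character(1))
    chain <- ifelse(is.na(k) | k == "NA", ".", k)
    names(chain) <- tr$tx_id
  }
  full <- paste0(tr$chrom, tr$strand, ":", chain)
  names(full) <- tr$tx_id
  full
}

#' Subset a tx_set by transcript ids
#' @param x a `tx_set`; @param ids character vector of transcript ids.
#' @export
subset_tx <- function(x, ids) {
  tr <- x$transcripts[x$transcripts$tx_id %in% ids, , drop = FALSE]
  ex <- x$exons[x$exons$tx_id %in% ids, , drop = FALSE]
  rownames(tr) <- rownames(ex) <- NULL
  structure(list(transcripts = tr, exons = ex), class = "tx_set")
}

#' Concatenate tx_sets
#' @param ... `tx_set` objects with disjoint transcript ids.
#' @export
bind_tx <- function(...) {
  xs <- list(...)
  tr <- do.call(rbind, lapply(xs, function(x) {
    t <- x$transcripts
    for (col in c("sample", "gene_id"))
      if (!col %in% names(t)) t[[col]] <- NA_character_
    t[c("tx_id", "chrom", "strand", "sample", "gene_id",
        setdiff(names(t), c("tx_id", "chrom", "strand", "sample", "gene_id")))]
  }))
  common <- Reduce(intersect, lapply(xs, function(x) names(x$transcripts)))
  tr <- tr[, union(c("tx_id", "chrom", "strand"),
                   union(common, c("sample", "gene_id"))), drop = FALSE]
  ex <- do.call(rbind, lapply(xs, `[[`, "exons"))
  tx_set(tr, ex)
}

## ---- GRanges bridges (0-based half-open -> 1-based closed) ----

.gr <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1, end = end),
                         strand = strand)
}

#' Transcript spans as GRanges
#' @param x a `tx_set`.
#' @export
span_granges <- function(x) {
  sp <- tx_spans(x)
  gr <- .gr(sp$chrom, sp$start, sp$end, sp$strand)
  names(gr) <- sp$tx_id
  gr
}

#' Exons as GRanges (with `tx_id` metadata column)
#' @param x a `tx_set`.
#' @export
exon_granges <- function(x) {
  chrom <- x$transcripts$chrom[match(x$exons$tx_id, x$transcripts$tx_id)]
  strand <- x$transcripts$strand[match(x$exons$tx_id, x$transcripts$tx_id)]
  gr <- .gr(chrom, x$exons$start, x$exons$end, strand)
  S4Vectors::mcols(gr)$tx_id <- x$exons$tx_id
  gr
}

## ---- Annotation: gene-grouped transcript set with interval index ----

#' Build an annotation (gene-grouped transcript set)
#'
#' @param tx a `tx_set` whose `transcripts` carry a `gene_id` column.
#' @param genes optional data.frame `gene_id`, `chrom`, `strand`, `start`,
#'   `end`; derived from member transcripts when omitted. Gene span is the
#'   union span of member transcripts.
#' @return object of class `annotation` with elements `genes`, `tx`.
#' @export
annotation <- function(tx, genes = NULL) {
  stopifnot(inherits(tx, "tx_set"), "gene_id" %in% names(tx$transcripts))
  if (is.null(genes)) {
    sp <- tx_spans(tx)
    sp$gene_id <- tx$transcripts$gene_id
    genes <- do.call(rbind, lapply(split(sp, sp$gene_id), function(d) {
      if (length(unique(d$chrom)) != 1 || length(unique(d$strand)) != 1)
        stop("gene ", d$gene_id[1], " mixes chrom or strand")
      data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                 strand = d$strand[1], start = min(d$start), end = max(d$end),
                 stringsAsFactors = FALSE)
    }))
    genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene ids")
  structure(list(genes = genes, tx = tx), class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat("annotation:", nrow(x$genes), "genes,", n_tx(x$tx), "transcripts\n")
  invisible(x)
}

#' Gene spans as a GRanges interval index
#' @param ann an `annotation`.
#' @export
gene_granges <- function(ann) {
  g <- ann$genes
  gr <- .gr(g$chrom, g$start, g$end, g$strand)
  names(gr) <- g$gene_id
  gr
}

#' Query the annotation's interval index
#'
#' Returns the gene ids whose spans intersect the query interval
#' (0-based half-open), optionally restricted to one strand.
#'
#' @param ann an `annotation`.
#' @param chrom,start,end query interval.
#' @param strand optional `"+"`/`"-"`; default any.
#' @export
ann_query <- function(ann, chrom, start, end, strand = NULL) {
  gr <- gene_granges(ann)
  q <- .gr(chrom, start, end, if (is.null(strand)) "*" else strand)
  hits <- GenomicRanges::findOverlaps(q, gr,
            ignore.strand = is.null(strand))
  names(gr)[S4Vectors::subjectHits(hits)]
}

#' Transcripts of one gene as a tx_set
#' @param ann an `annotation`; @param gene_id gene identifier.
#' @export
gene_tx <- function(ann, gene_id) {
  ids <- ann$tx$transcripts$tx_id[ann$tx$transcripts$gene_id %in% gene_id]
  subset_tx(ann$tx, ids)
}
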