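#' Read a reference annotation from GFF3 or GTF
#'
#' Parses a GFF3 (gene/mRNA/exon hierarchy) or GTF (gene_id/transcript_id
#' attributes) file into an [annotation()]. File coordinates (1-based closed)
#' are converted to the internal 0-based half-open convention. Gzip-compressed
#' files are accepted. Strandless (`.`) multi-exon transcripts are an error;
#' strandless single-exon features are kept on `"+"` with `strandless = TRUE`
#' (they never satisfy a same-strand clause against `"-"` features).
#'
#' @param path file path (`.gff3`, `.gff`, `.gtf`, optionally `.gz`).
#' @param format `"auto"` (from extension), `"gff3"` or `"gtf"`.
#' @return an [annotation()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- if (grepl("\\.gtf$", base, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  if (format == "gtf") .ann_from_gtf(gr, path) else .ann_from_gff3(gr, path)
}

.find_line <- function(path, pattern) {
  ln <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  hit <- grep(pattern, ln, fixed = TRUE)
  if (length(hit)) hit[1] else NA_integer_
}

.ann_from_gff3 <- function(gr, path) {
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  is_exon <- type == "exon"
  if (!any(is_exon)) stop("no exon features in ", path)
  ex_parent <- parent[is_exon]
  if (anyNA(ex_parent)) {
    i <- which(is_exon)[which(is.na(ex_parent))[1]]
    stop("exon with no Parent transcript near line ",
         .find_line(path, paste0(GenomicRanges::start(gr)[i] , "\t",
                                 GenomicRanges::end(gr)[i])), " in ", path)
  }
  known_ids <- id[!is_exon & !is.na(id)]
  orphan <- setdiff(unique(ex_parent), known_ids)
  if (length(orphan))
    stop("exon Parent '", orphan[1], "' matches no transcript feature (line ",
         .find_line(path, paste0("Parent=", orphan[1])), ") in ", path)
  # transcript features: anything an exon points at
  tx_idx <- which(!is_exon & id %in% unique(ex_parent))
  tx_gene <- parent[tx_idx]
  tx_gene[is.na(tx_gene)] <- id[tx_idx][is.na(tx_gene)] # orphan tx: own gene
  .assemble_annotation(
    ex_tx = ex_parent,
    ex_start = GenomicRanges::start(gr)[is_exon] - 1,
    ex_end = GenomicRanges::end(gr)[is_exon],
    ex_chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    ex_strand = as.character(BiocGenerics::strand(gr))[is_exon],
    tx2gene = stats::setNames(tx_gene, id[tx_idx]))
}

.ann_from_gtf <- function(gr, path) {
  is_exon <- as.character(gr$type) == "exon"
  if (!any(is_exon)) stop("no exon features in ", path)
  txid <- as.character(gr$transcript_id)[is_exon]
  gid <- as.character(gr$gene_id)[is_exon]
  if (anyNA(txid)) stop("GTF exon without transcript_id in ", path)
  .assemble_annotation(
    ex_tx = txid,
    ex_start = GenomicRanges::start(gr)[is_exon] - 1,
    ex_end = GenomicRanges::end(gr)[is_exon],
    ex_chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    ex_strand = as.character(BiocGenerics::strand(gr))[is_exon],
    tx2gene = stats::setNames(gid, txid)[!duplicated(txid)])
}

.assemble_annotation <- function(ex_tx, ex_start, ex_end, ex_chrom, ex_strand,
                                 tx2gene) {
  ids <- unique(ex_tx)
  chrom <- vapply(split(ex_chrom, factor(ex_tx, ids)), `[`, character(1), 1)
  nex <- table(factor(ex_tx, ids))
  strand <- vapply(split(ex_strand, factor(ex_tx, ids)), `[`, character(1), 1)
  strandless <- strand == "*"
  if (any(strandless & nex > 1))
    stop("strandless multi-exon transcript(s): ",
         paste(ids[strandless & nex > 1], collapse = ", "))
  strand[strandless] <- "+"
  tr <- data.frame(tx_id = ids, chrom = chrom, strand = strand,
                   gene_id = unname(tx2gene[ids]),
                   strandless = unname(strandless),
                   stringsAsFactors = FALSE)
  tx <- tx_set(tr, data.frame(tx_id = ex_tx, start = ex_start, end = ex_end,
                              stringsAsFactors = FALSE))
  annotation(tx)
}

#' Write an annotation as GFF3
#'
#' Deterministic output order (chrom, start, id); `read_annotation()` is the
#' inverse. Extra per-transcript columns `support` and `samples` are written
#' as attributes when present.
#'
#' @param ann an [annotation()].
#' @param path output file path.
#' @export
write_annotation <- function(ann, path) {
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start, ann$genes$gene_id), ]
  tr <- ann$tx$transcripts
  sp <- tx_spans(ann$tx)
  ex <- ann$tx$exons
  esc <- function(x) gsub("[;=&,\t]", "_", as.character(x))
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    lines <- c(lines, sprintf("%s\tisoannot\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom[i], g$start[i] + 1, g$end[i],
                              g$strand[i], esc(gid)))
    memb <- which(tr$gene_id == gid)
    memb <- memb[order(sp$start[memb], tr$tx_id[memb])]
    for (j in memb) {
      attrs <- sprintf("ID=%s;Parent=%s", esc(tr$tx_id[j]), esc(gid))
      if ("support" %in% names(tr) && !is.na(tr$support[j]))
        attrs <- paste0(attrs, ";support=", tr$support[j])
      if ("samples" %in% names(tr) && !is.na(tr$samples[j]))
        attrs <- paste0(attrs, ";samples=", esc(tr$samples[j]))
      lines <- c(lines, sprintf("%s\tisoannot\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
                                sp$chrom[j], sp$start[j] + 1, sp$end[j],
                                sp$strand[j], attrs))
      eidx <- which(ex$tx_id == tr$tx_id[j])
      for (k in seq_along(eidx)) {
        e <- eidx[k]
        lines <- c(lines, sprintf(
          "%s\tisoannot\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          sp$chrom[j], ex$start[e] + 1, ex$end[e], sp$strand[j],
          esc(tr$tx_id[j]), k, esc(tr$tx_id[j])))
      }
    }
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read BED12 transcript models
#'
#' 12-column BED with blocks; BED's 0-based half-open coordinates are the
#' internal convention and are preserved as-is. Gzip input accepted.
#'
#' @param path BED12 file.
#' @param sample optional sample label attached to every transcript.
#' @return a [tx_set()].
#' @export
read_bed12 <- function(path, sample = NA_character_) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- readLines(con, warn = FALSE)
  close(con)
  raw <- raw[nzchar(raw) & !grepl("^(track|browser|#)", raw)]
  if (!length(raw))
    return(tx_set(data.frame(tx_id = character(), chrom = character(),
                             strand = character(), sample = character()),
                  data.frame(tx_id = character(), start = numeric(),
                             end = numeric())))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    stop("line ", which(nf < 12)[1], ": expected 12 BED columns, got ",
         nf[which(nf < 12)[1]])
  m <- do.call(rbind, fields)
  n_blocks <- as.integer(m[, 10])
  sizes <- lapply(strsplit(m[, 11], ","), function(v) as.numeric(v[nzchar(v)]))
  starts <- lapply(strsplit(m[, 12], ","), function(v) as.numeric(v[nzchar(v)]))
  bad <- which(lengths(sizes) != n_blocks | lengths(starts) != n_blocks)
  if (length(bad))
    stop("line ", bad[1], ": blockCount (", n_blocks[bad[1]],
         ") does not match blockSizes/blockStarts lengths")
  tx_id <- m[, 4]
  if (anyDuplicated(tx_id)) tx_id <- make.unique(tx_id, sep = "_dup")
  chromStart <- as.numeric(m[, 2])
  ex <- data.frame(
    tx_id = rep(tx_id, n_blocks),
    start = unlist(starts) + rep(chromStart, n_blocks),
    end = unlist(starts) + unlist(sizes) + rep(chromStart, n_blocks),
    stringsAsFactors = FALSE)
  tr <- data.frame(tx_id = tx_id, chrom = m[, 1], strand = m[, 6],
                   sample = sample, stringsAsFactors = FALSE)
  strandless <- !tr$strand %in% c("+", "-")
  if (any(strandless & n_blocks > 1))
    stop("strandless multi-exon BED record(s): line ",
         which(strandless & n_blocks > 1)[1])
  tr$strand[strandless] <- "+"
  tr$strandless <- strandless
  tx_set(tr, ex)
}

#' Write a tx_set as BED12
#'
#' @param x a [tx_set()].
#' @param path output file path.
#' @export
write_bed12 <- function(x, path) {
  sp <- tx_spans(x)
  ord <- order(sp$chrom, sp$start, sp$tx_id)
  ex_by <- split(x$exons[, c("start", "end")], x$exons$tx_id)
  lines <- vapply(ord, function(i) {
    e <- ex_by[[sp$tx_id[i]]]
    e <- e[order(e$start), , drop = FALSE]
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            sp$chrom[i], sp$start[i], sp$end[i], sp$tx_id[i], sp$strand[i],
            sp$start[i], sp$end[i], nrow(e),
            paste0(paste(e$end - e$start, collapse = ","), ","),
            paste0(paste(e$start - sp$start[i], collapse = ","), ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in transcription order; minus-strand
#' transcripts are reverse-complemented.
#'
#' @param x a [tx_set()].
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @return `DNAStringSet` named by transcript id.
#' @export
tx_sequences <- function(x, genome) {
  tr <- x$transcripts
  ex_by <- split(x$exons[, c("start", "end")], x$exons$tx_id)
  seqs <- vapply(seq_len(nrow(tr)), function(i) {
    e <- ex_by[[tr$tx_id[i]]]
    e <- e[order(e$start), , drop = FALSE]
    chrseq <- genome[[tr$chrom[i]]]
    s <- paste(vapply(seq_len(nrow(e)), function(k)
      as.character(Biostrings::subseq(chrseq, e$start[k] + 1, e$end[k])),
      character(1)), collapse = "")
    if (tr$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tr$tx_id
  out
}
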