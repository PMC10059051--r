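#' Round half up
#'
#' Decimal rounding with ties going away from zero (the convention used for
#' all reported percentages, e.g. 82.525 -> 82.53), unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric; @param digits decimal places (default 2).
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage to two decimals, round-half-up
#'
#' @param num numerator; @param den denominator.
#' @export
pct2 <- function(num, den) round_half_up(100 * num / den, 2)

#' Distribution of isoform counts per gene
#'
#' Bins 1, 2, ..., 10 and >10, with percentages of the total gene count.
#'
#' @param iso_per_gene integer vector of isoform counts per gene, or a
#'   collapsed isoform [tx_set()] (counts derived from `gene_id`).
#' @return data.frame `bin`, `n_genes`, `pct`.
#' @export
isoform_distribution <- function(iso_per_gene) {
  if (inherits(iso_per_gene, "tx_set"))
    iso_per_gene <- as.integer(table(iso_per_gene$transcripts$gene_id))
  stopifnot(all(iso_per_gene >= 1))
  total <- length(iso_per_gene)
  bins <- c(as.character(1:10), ">10")
  n <- c(vapply(1:10, function(k) sum(iso_per_gene == k), integer(1)),
         sum(iso_per_gene > 10))
  data.frame(bin = bins, n_genes = n, pct = pct2(n, total),
             stringsAsFactors = FALSE)
}

#' Novel-feature fractions
#'
#' @param gene_calls,tx_calls call tables from [classify_novelty()] (only
#'   the `call` column is used).
#' @return list with counts and percentages (2 decimals) of novel genes and
#'   novel transcripts.
#' @export
novelty_fractions <- function(gene_calls, tx_calls) {
  ng <- sum(gene_calls$call == "novel"); tg <- nrow(gene_calls)
  nt <- sum(tx_calls$call == "novel"); tt <- nrow(tx_calls)
  list(n_genes = tg, n_novel_genes = ng, pct_novel_genes = pct2(ng, tg),
       n_transcripts = tt, n_novel_transcripts = nt,
       pct_novel_transcripts = pct2(nt, tt))
}

#' Sample-unique and shared isoform sets
#'
#' An isoform is unique to a sample when its supporting reads come from
#' exactly that sample. Shared categories partition the remaining isoforms
#' by their sample-presence pattern.
#'
#' @param isoforms a [tx_set()] with a `samples` column (comma-joined
#'   labels from [collapse_isoforms()]).
#' @return list with `unique` (data.frame `sample`, `n`, `mean_length`:
#'   mean spliced length), `patterns` (table over presence patterns) and
#'   `n_total`.
#' @export
unique_sets <- function(isoforms) {
  tr <- isoforms$transcripts
  stopifnot("samples" %in% names(tr))
  lens <- spliced_length(isoforms)
  pat <- ifelse(is.na(tr$samples), "", tr$samples)
  sets <- strsplit(pat, ",")
  nset <- lengths(sets)
  all_samples <- sort(unique(unlist(sets)))
  uniq <- do.call(rbind, lapply(all_samples, function(s) {
    sel <- nset == 1 & vapply(sets, function(v) identical(v, s), logical(1))
    data.frame(sample = s, n = sum(sel),
               mean_length = if (any(sel)) mean(lens[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(unique = uniq, patterns = table(pat), n_total = nrow(tr))
}

#' Hypergeometric over-representation test for term sets
#'
#' One-sided upper-tail hypergeometric p-value per term, BH-adjusted across
#' terms.
#'
#' @param hits character vector of hit genes (must be inside `universe`).
#' @param universe character vector of all eligible genes.
#' @param term2gene data.frame with columns `term`, `gene`.
#' @param q_threshold report threshold for the `significant` flag.
#' @return data.frame `term`, `n_term`, `n_hit`, `p`, `q`, `significant`.
#' @export
enrich_terms <- function(hits, universe, term2gene, q_threshold = 0.05) {
  hits <- unique(hits); universe <- unique(universe)
  if (!all(hits %in% universe))
    stop("hit(s) outside the universe: ",
         paste(utils::head(setdiff(hits, universe), 5), collapse = ", "))
  if (!nrow(term2gene)) stop("empty term map")
  term2gene <- term2gene[term2gene$gene %in% universe, , drop = FALSE]
  terms <- unique(term2gene$term)
  N <- length(universe); n <- length(hits)
  res <- do.call(rbind, lapply(terms, function(tm) {
    gs <- unique(term2gene$gene[term2gene$term == tm])
    K <- length(gs)
    k <- length(intersect(gs, hits))
    data.frame(term = tm, n_term = K, n_hit = k,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, "BH")
  res$significant <- res$q < q_threshold
  res[order(res$p, res$term), , drop = FALSE]
}

#' Run the full simulated-annotation pipeline
#'
#' Generates data with [simulate_genome()]/[simulate_flnc()], then runs
#' collapse, novelty, splicing, polyA, lncRNA and differential-expression
#' stages, and assembles a dataset-level summary whose every percentage is
#' recomputable from its printed numerator and denominator
#' (see [audit_summary()]). Deterministic given the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @param rule a [same_gene_rule()].
#' @param merge_window,min_site_support polyA clustering parameters.
#' @param out_dir optional output directory: stage outputs (GFF3, BED12,
#'   TSV, JSON manifest) are written there.
#' @return list with per-stage results and `summary`.
#' @export
run_pipeline <- function(cfg = sim_config(), rule = same_gene_rule(),
                         merge_window = 24, min_site_support = 2,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  sim <- stage("simulate", simulate_genome(cfg))
  fl <- stage("simulate", simulate_flnc(sim, cfg))
  if (n_tx(fl$reads) == 0) stop("stage 'collapse' failed: no input reads")
  col <- stage("collapse", collapse_reads(fl$reads, rule))
  nov <- stage("novelty", classify_novelty(col, sim$ref_ann, rule))
  ev <- stage("splice", count_events_by_sample(col$isoforms))
  sites <- stage("polya", polya_sites(col$reads, merge_window,
                                      min_site_support))
  apa <- stage("polya", apa_summary(sites))
  fp <- stage("polya", flank_profile(sites, sim$genome))
  lnc <- stage("lncrna", lncrna_calls(col$isoforms, sim$genome, sim$ref_ann))
  lnc_set <- subset_tx(col$isoforms, lnc$lncrna$tx_id)
  mrna_ids <- lnc$coding$tx_id[lnc$coding$call == "coding"]
  lnc_sum <- stage("lncrna", lncrna_summary(
    lnc$lncrna, known_lnc = sim$known_lnc, lnc_set = lnc_set,
    mrna_lengths = spliced_length(subset_tx(col$isoforms, mrna_ids))))
  tx2gene <- data.frame(tx_id = col$isoforms$transcripts$tx_id,
                        gene_id = col$isoforms$transcripts$gene_id,
                        stringsAsFactors = FALSE)
  sc <- stage("de", simulate_counts(tx2gene, cfg$de_config, cfg$seed))
  groups <- sc$col_data$condition
  det <- stage("de", de_test(sc$counts, groups))
  deg <- stage("de", de_test(gene_counts(sc$counts, tx2gene), groups))
  ov <- stage("de", overlap_report(det, deg, tx2gene))

  nf <- novelty_fractions(nov$genes, nov$transcripts)
  summary <- list(
    totals = list(n_reads = n_tx(fl$reads), n_isoforms = n_tx(col$isoforms),
                  n_loci = nrow(col$loci)),
    novelty = nf,
    isoform_distribution = isoform_distribution(col$isoforms),
    as_summary = ev$summary,
    as_n_events = nrow(ev$events),
    as_n_genes = length(unique(ev$events$gene_id)),
    pct_as_genes = pct2(length(unique(ev$events$gene_id)), nrow(col$loci)),
    apa = apa,
    polya_hit_fraction = fp$hit_fraction,
    lncrna = lnc_sum,
    unique_sets = unique_sets(col$isoforms),
    de = list(n_det = ov$n_det, n_detg = ov$n_detg, n_deg = ov$n_deg,
              overlap = ov))
  res <- list(config = cfg, sim = sim, reads = fl, collapse = col,
              novelty = nov, splicing = ev, polya_sites = sites,
              flank = fp, lncrna = lnc, counts = sc,
              det = det, deg = deg, summary = summary)
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  iso_ann <- annotation(res$collapse$isoforms)
  write_annotation(iso_ann, file.path(out_dir, "isoforms.gff3"))
  write_annotation(res$sim$ref_ann, file.path(out_dir, "reference.gff3"))
  write_bed12(res$reads$reads, file.path(out_dir, "reads.bed12"))
  Biostrings::writeXStringSet(res$sim$genome,
                              file.path(out_dir, "genome.fa"))
  wtsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(rbind(res$novelty$genes, res$novelty$transcripts), "novelty.tsv")
  wtsv(res$splicing$events, "as_events.tsv")
  wtsv(res$splicing$summary, "as_summary.tsv")
  wtsv(res$polya_sites, "polya_sites.tsv")
  wtsv(res$lncrna$coding, "coding_potential.tsv")
  wtsv(res$lncrna$lncrna, "lncrna_classes.tsv")
  wtsv(res$det, "det.tsv")
  wtsv(res$deg, "deg.tsv")
  utils::write.table(res$counts$counts,
                     file.path(out_dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("isoannot")),
    seed = res$config$seed,
    parameters = res$config[setdiff(names(res$config), "de_config")],
    de_parameters = res$config$de_config,
    outputs = vapply(list.files(out_dir, full.names = TRUE), function(f)
      unname(tools::md5sum(f)), character(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Self-consistency audit of a pipeline summary
#'
#' Recomputes every reported percentage from its printed numerator and
#' denominator and checks agreement; returns TRUE invisibly or stops with
#' the first mismatch.
#'
#' @param summary the `summary` element of [run_pipeline()]'s result.
#' @export
audit_summary <- function(summary) {
  chk <- function(lbl, pct, num, den) {
    if (abs(pct - pct2(num, den)) > 1e-9)
      stop("summary audit failed for ", lbl)
  }
  nf <- summary$novelty
  chk("novel genes", nf$pct_novel_genes, nf$n_novel_genes, nf$n_genes)
  chk("novel transcripts", nf$pct_novel_transcripts,
      nf$n_novel_transcripts, nf$n_transcripts)
  d <- summary$isoform_distribution
  total <- sum(d$n_genes)
  for (i in seq_len(nrow(d)))
    chk(paste("isoform bin", d$bin[i]), d$pct[i], d$n_genes[i], total)
  chk("AS genes", summary$pct_as_genes, summary$as_n_genes,
      summary$totals$n_loci)
  ap <- summary$apa
  kc <- as.integer(names(ap$histogram))
  chk("APA 1-9", ap$bin_shares[["1-9"]],
      sum(ap$histogram[kc <= 9]), ap$n_genes)
  chk("APA 10+", ap$bin_shares[["10+"]],
      sum(ap$histogram[kc >= 10]), ap$n_genes)
  if (abs(ap$mean_sites_per_gene -
          round_half_up(ap$n_sites / ap$n_genes, 2)) > 1e-9)
    stop("summary audit failed for APA mean")
  ln <- summary$lncrna
  for (cl in names(ln$class_pct))
    chk(paste("lncRNA", cl), ln$class_pct[[cl]],
        as.integer(ln$class_counts[[cl]]), ln$n)
  if (!is.null(ln$novel_pct))
    chk("novel lncRNA", ln$novel_pct, ln$novel_n, ln$n)
  invisible(TRUE)
}
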