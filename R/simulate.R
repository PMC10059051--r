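#' Simulation configuration
#'
#' Defines the conditions a simulated full-length transcriptome run emulates:
#' multi-isoform genes whose isoforms differ by exactly one planted
#' alternative-splicing event each, multiple 3' cleavage sites per gene with
#' A-rich planted downstream elements, noncoding transcripts in each of the
#' four positional classes, and negative-binomial expression counts with
#' planted fold changes. A single seed fixes every downstream draw.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of protein-coding gene units.
#' @param isoform_dist probabilities over isoform counts 1..k per gene.
#' @param as_event_mix proportions over event types ES, IR, AA, AD, MEE used
#'   when planting the extra isoforms (must sum to 1).
#' @param apa_dist probabilities over the number of polyA sites 1..k per gene.
#' @param polya_flank_A_enrichment probability that each base of the planted
#'   10-bp element immediately downstream of a polyA site is an A.
#' @param n_noncoding named counts of planted noncoding transcripts per
#'   positional class (`intronic`, `sense`, `antisense`, `intergenic`).
#' @param end_jitter_sd standard deviation (bp) of the truncated Normal 5'/3'
#'   end jitter applied to simulated reads; jitter never crosses a splice
#'   site.
#' @param noise_read_rate expected fraction of additional intergenic
#'   mono-exon noise reads relative to the signal reads.
#' @param reads_per_isoform mean reads per isoform per present sample.
#' @param samples sample labels (the three castes by default).
#' @param novel_gene_fraction fraction of coding gene units omitted from the
#'   emitted reference annotation (they become novel genes downstream).
#' @param novel_tx_fraction fraction of non-base isoforms of kept genes
#'   omitted from the reference (novel transcripts downstream).
#' @param known_lnc_fraction fraction of planted noncoding transcripts also
#'   listed in the "known lncRNA" set.
#' @param de_config a [de_config()] list for [simulate_counts()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 50,
                       isoform_dist = c(`1` = 0.60, `2` = 0.18, `3` = 0.10,
                                        `4` = 0.07, `5` = 0.05),
                       as_event_mix = c(ES = 0.20, IR = 0.40, AA = 0.15,
                                        AD = 0.15, MEE = 0.10),
                       apa_dist = c(0.35, 0.22, 0.16, 0.12, 0.09, 0.06),
                       polya_flank_A_enrichment = 0.9,
                       n_noncoding = c(intronic = 6, sense = 4,
                                       antisense = 4, intergenic = 6),
                       end_jitter_sd = 5,
                       noise_read_rate = 0.02,
                       reads_per_isoform = 4,
                       samples = c("queen", "worker", "drone"),
                       novel_gene_fraction = 0.15,
                       novel_tx_fraction = 0.25,
                       known_lnc_fraction = 0.3,
                       de_config = NULL) {
  stopifnot(abs(sum(as_event_mix) - 1) < 1e-8,
            abs(sum(isoform_dist) - 1) < 1e-8,
            all(n_noncoding >= 0), n_genes >= 1, seed == round(seed))
  if (is.null(de_config)) de_config <- isoannot_de_default()
  structure(as.list(environment()), class = "sim_config")
}

#' Differential-expression simulation configuration
#'
#' @param n_replicates replicates per condition (two conditions).
#' @param dispersion NB dispersion (must be > 0).
#' @param planted_log2fc magnitude of the planted log2 fold change for
#'   non-null features (sign drawn at random per feature).
#' @param fraction_null fraction of features with no planted change.
#' @param base_meanlog,base_sdlog lognormal parameters of baseline means.
#' @param n_switch number of isoform-switch genes: two isoforms of one gene
#'   swap means between conditions so the gene total is unchanged.
#' @param switch_means the high/low means swapped in a switch pair.
#' @export
de_config <- function(n_replicates = 3, dispersion = 0.1, planted_log2fc = 2,
                      fraction_null = 0.8, base_meanlog = 4.5,
                      base_sdlog = 1, n_switch = 0,
                      switch_means = c(1000, 100)) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  as.list(environment())
}

.CODONS <- {
  b <- c("T", "C", "A", "G")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# replace codon runs so no reading frame carries an ORF of >= max_codons
.break_orfs <- function(seq_chars, max_codons = 60) {
  n <- length(seq_chars)
  for (frame in 0:2) {
    i <- frame + 1
    open <- -1L
    while (i + 2 <= n) {
      cod <- paste0(seq_chars[i], seq_chars[i + 1], seq_chars[i + 2])
      if (cod %in% c("TAA", "TAG", "TGA")) open <- -1L
      else if (cod == "ATG" && open < 0) open <- i
      if (open > 0 && (i - open) / 3 >= max_codons) {
        seq_chars[i:(i + 2)] <- c("T", "A", "A")
        open <- -1L
      }
      i <- i + 3
    }
  }
  seq_chars
}

.revcomp_chars <- function(x)
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])

unit_ids_all <- function(units) vapply(units, `[[`, character(1), "unit_id")

#' Simulate a toy genome, annotation and ground truth
#'
#' Places gene units left-to-right on one chromosome. Each multi-isoform
#' gene's extra isoforms differ from the base isoform by exactly one planted
#' AS event, each at its own internal exon slot (slots are spaced three exons
#' apart so events of different isoforms never share an anchor region).
#' Protein-coding genes receive a planted ORF with biased codon usage;
#' noncoding transcripts receive ORF-broken random sequence; the 10 bp
#' downstream of every planted polyA site is drawn with the configured
#' A-enrichment.
#'
#' @param cfg a [sim_config()].
#' @return list with `truth_ann` (annotation of all true transcripts),
#'   `ref_ann` (the emitted reference annotation: coding genes minus the
#'   planted novel subset), `genome` (`DNAStringSet`), `known_lnc` (tx_set of
#'   the "known lncRNA" subset) and `truth` (the ground-truth tables).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  chrom <- "chrS"
  n <- cfg$n_genes
  iso_k <- sample(seq_along(cfg$isoform_dist), n, TRUE, cfg$isoform_dist)
  strands <- sample(c("+", "-"), n, TRUE)
  apa_k <- sample(seq_along(cfg$apa_dist), n, TRUE, cfg$apa_dist)
  ev_types <- names(cfg$as_event_mix)

  units <- list()
  gaps <- NULL # free intergenic intervals usable for noise reads
  cursor <- 1000
  n_intergenic <- cfg$n_noncoding[["intergenic"]]
  lnc_after <- if (n_intergenic > 0)
    unique(pmin(n, ceiling(seq_len(n_intergenic) * n / (n_intergenic + 1))))
  else integer(0)
  lnc_int_placed <- 0

  for (g in seq_len(n)) {
    k <- iso_k[g]
    n_extra <- k - 1
    types <- if (n_extra > 0) sample(ev_types, n_extra, TRUE,
                                     cfg$as_event_mix) else character(0)
    n_ex <- if (n_extra > 0) 3 * n_extra + 3 else
      sample(c(1, 2, 3, 4, 5), 1, prob = c(.15, .2, .25, .2, .2))
    slots <- if (n_extra > 0) 3 * seq_len(n_extra) - 1 else integer(0)
    ex_len <- sample(120:300, n_ex, TRUE)
    in_len <- if (n_ex > 1) sample(250:500, n_ex - 1, TRUE) else integer(0)
    # MEE events need room for the alternative exon inside intron `slot`
    for (m in seq_along(types))
      if (types[m] == "MEE") in_len[slots[m]] <- 650
    big_intron <- if (n_ex > 1) n_ex - 1 else NA_integer_
    if (!is.na(big_intron)) in_len[big_intron] <- max(in_len[big_intron], 1400)

    strand <- strands[g]
    ka <- apa_k[g]
    start <- cursor + if (strand == "-") 60 * ka else 0
    starts <- start + c(0, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    base_ex <- data.frame(start = starts, end = ends)
    gene_end <- ends[n_ex]

    unit_id <- sprintf("G%04d", g)
    isoforms <- list(list(tx_id = paste0(unit_id, ".t1"), exons = base_ex))
    events <- NULL
    for (m in seq_along(types)) {
      j <- slots[m]; ty <- types[m]
      ex <- base_ex
      if (ty == "ES") {
        region <- c(ex$start[j], ex$end[j])
        ex <- ex[-j, , drop = FALSE]
      } else if (ty == "IR") {
        region <- c(ex$end[j], ex$start[j + 1])
        ex$end[j] <- ex$end[j + 1]
        ex <- ex[-(j + 1), , drop = FALSE]
      } else if (ty %in% c("AA", "AD")) {
        # intron j boundaries: start = donor on "+", acceptor on "-"
        shift_donor <- (ty == "AD") == (strand == "+")
        if (shift_donor) {
          region <- c(ex$end[j] - 40, ex$end[j])
          ex$end[j] <- ex$end[j] - 40
        } else {
          region <- c(ex$start[j + 1], ex$start[j + 1] + 40)
          ex$start[j + 1] <- ex$start[j + 1] + 40
        }
      } else { # MEE: alternative exon inside intron j
        alt <- c(ex$end[j] + 200, ex$end[j] + 350)
        region <- c(ex$start[j], alt[2])
        ex$start[j] <- alt[1]; ex$end[j] <- alt[2]
      }
      tx_id <- sprintf("%s.t%d", unit_id, m + 1)
      isoforms[[m + 1]] <- list(tx_id = tx_id,
                                exons = ex[order(ex$start), , drop = FALSE])
      events <- rbind(events, data.frame(
        unit_id = unit_id, type = ty, region_start = region[1],
        region_end = region[2], iso_id = tx_id, stringsAsFactors = FALSE))
    }
    sites <- if (strand == "+") gene_end + 60 * (seq_len(ka) - 1)
             else start - 60 * (seq_len(ka) - 1)
    right <- if (strand == "+") gene_end + 60 * ka else gene_end
    units[[length(units) + 1]] <- list(
      unit_id = unit_id, kind = "coding", strand = strand, chrom = chrom,
      isoforms = isoforms, events = events, apa_sites = sites,
      base_ex = base_ex, big_intron = big_intron, lnc_class = NA_character_,
      host = NA_character_)
    gaps <- rbind(gaps, data.frame(start = right + 200,
                                   end = right + 1000))
    cursor <- right + 1200
    # interleave intergenic lncRNA units
    while (lnc_int_placed < length(lnc_after) &&
           g == lnc_after[lnc_int_placed + 1]) {
      lnc_int_placed <- lnc_int_placed + 1
      lid <- sprintf("LNCG%03d", lnc_int_placed)
      lst <- sample(c("+", "-"), 1)
      ex <- data.frame(start = cursor, end = cursor + 500)
      units[[length(units) + 1]] <- list(
        unit_id = lid, kind = "lnc", strand = lst, chrom = chrom,
        isoforms = list(list(tx_id = paste0(lid, ".t1"), exons = ex)),
        events = NULL, apa_sites = if (lst == "+") ex$end else ex$start,
        base_ex = ex, big_intron = NA, lnc_class = "intergenic",
        host = NA_character_)
      gaps <- rbind(gaps, data.frame(start = cursor + 700,
                                     end = cursor + 1500))
      cursor <- cursor + 1700
    }
  }

  coding_idx <- which(vapply(units, function(u) u$kind == "coding",
                             logical(1)))
  # hosts for intronic lncRNAs need a multi-exon gene (its widened intron)
  multi_idx <- coding_idx[vapply(units[coding_idx],
                                 function(u) nrow(u$base_ex) > 1, logical(1))]
  # cycle hosts so each planted lncRNA lands on a distinct gene when the
  # host pool allows; `shift` staggers classes across the pool
  plant_lnc <- function(count, maker, shift = 0) {
    out <- list()
    for (i in seq_len(if (length(multi_idx)) count else 0)) {
      h <- (i - 1 + shift) %% length(multi_idx) + 1
      out[[i]] <- maker(units[[multi_idx[h]]], i)
    }
    out
  }
  nnc <- cfg$n_noncoding
  lnc_units <- list()
  mk <- function(lid, strand, ex, class, host)
    list(unit_id = lid, kind = "lnc", strand = strand, chrom = chrom,
         isoforms = list(list(tx_id = paste0(lid, ".t1"), exons = ex)),
         events = NULL, apa_sites = if (strand == "+") ex$end else ex$start,
         base_ex = ex, big_intron = NA, lnc_class = class, host = host)
  if (nnc[["intronic"]] > 0)
    lnc_units <- c(lnc_units, plant_lnc(nnc[["intronic"]],
      function(u, i) {
        bi <- u$big_intron
        i0 <- u$base_ex$end[bi]
        mk(sprintf("LNCI%03d", i), sample(c("+", "-"), 1),
           data.frame(start = i0 + 300, end = i0 + 800), "intronic",
           u$unit_id)
      }, shift = 0))
  # host exon for sense/antisense planting: exon 3 where it exists, because
  # no planted event removes or spans it (event slots are exons 2, 5, 8, ...),
  # so no isoform's intron can contain a transcript anchored there
  anchor_exon <- function(u) {
    ne <- nrow(u$base_ex)
    u$base_ex[if (ne >= 3) 3 else min(2, ne), ]
  }
  if (nnc[["sense"]] > 0)
    lnc_units <- c(lnc_units, plant_lnc(nnc[["sense"]],
      function(u, i) {
        e <- anchor_exon(u)
        # stop 40 bp short of the host exon end so the lncRNA's own 3' end
        # never falls within a polyA merge window of a host site; extend
        # upstream into the intron to keep the transcript long, but stay
        # strictly inside the intron so no host intron is fully covered
        # (full coverage would be a real intron-retention signature);
        # with an MEE planted in that intron, stay downstream of the
        # alternative exon so no variant isoform's intron is covered either
        prev_end <- max(u$base_ex$end[u$base_ex$end <= e$start])
        lo <- prev_end + 30
        if (!is.null(u$events)) {
          mee_end <- u$events$region_end[u$events$type == "MEE" &
                                           u$events$region_end > prev_end &
                                           u$events$region_end <= e$start]
          if (length(mee_end)) lo <- max(lo, max(mee_end) + 30)
        }
        up <- min(max(80, 440 - (e$end - e$start)), e$start - lo)
        mk(sprintf("LNCS%03d", i), u$strand,
           data.frame(start = e$start - up, end = e$end - 40), "sense",
           u$unit_id)
      }, shift = 11))
  if (nnc[["antisense"]] > 0)
    lnc_units <- c(lnc_units, plant_lnc(nnc[["antisense"]],
      function(u, i) {
        e <- anchor_exon(u)
        mk(sprintf("LNCA%03d", i), if (u$strand == "+") "-" else "+",
           data.frame(start = e$start - 150, end = e$end + 150), "antisense",
           u$unit_id)
      }, shift = 23))
  units <- c(units, lnc_units)

  chrom_len <- cursor + 1000
  genome_chars <- sample(c("A", "C", "G", "T"), chrom_len, TRUE,
                         prob = c(0.33, 0.17, 0.17, 0.33))
  # strongly skewed codon usage gives the coding model a clear hexamer
  # signature, as real transcriptomes do
  codon_w <- (stats::rexp(length(.CODONS)) + 0.05)^2

  write_spliced <- function(ex, strand, spliced_chars) {
    if (strand == "-") spliced_chars <- .revcomp_chars(spliced_chars)
    pos <- unlist(lapply(seq_len(nrow(ex)),
                         function(i) (ex$start[i] + 1):ex$end[i]))
    genome_chars[pos] <<- spliced_chars
  }
  for (u in units) {
    ex <- u$base_ex
    L <- sum(ex$end - ex$start)
    if (u$kind == "coding") {
      n_cod <- max(10, floor((L - 130) / 3))
      cds <- c("A", "T", "G",
               unlist(strsplit(sample(.CODONS, n_cod, TRUE, codon_w), "")),
               "T", "A", "A")
      utr5 <- sample(c("A", "C", "G", "T"), 60, TRUE)
      rest <- L - length(cds) - 60
      utr3 <- sample(c("A", "C", "G", "T"), rest, TRUE)
      write_spliced(ex, u$strand, c(utr5, cds, utr3))
    } else {
      raw <- sample(c("A", "C", "G", "T"), L, TRUE)
      write_spliced(ex, u$strand, .break_orfs(raw))
    }
  }
  # planted A-rich elements downstream of each polyA site
  draw_elem <- function(n) ifelse(stats::runif(n) < cfg$polya_flank_A_enrichment,
                                  "A", sample(c("C", "G", "T"), n, TRUE))
  for (u in units) {
    for (s in u$apa_sites) {
      if (u$strand == "+") {
        idx <- (s + 1):(s + 10)
        genome_chars[idx] <- draw_elem(10)
      } else {
        idx <- (s - 9):s
        genome_chars[idx] <- .revcomp_chars(draw_elem(10))
      }
    }
  }
  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- chrom

  # assemble truth tables and annotations
  tr <- list(); exl <- list(); iso_rows <- list()
  for (u in units) {
    for (is in u$isoforms) {
      tr[[length(tr) + 1]] <- data.frame(
        tx_id = is$tx_id, chrom = u$chrom, strand = u$strand,
        gene_id = u$unit_id, stringsAsFactors = FALSE)
      exl[[length(exl) + 1]] <- data.frame(tx_id = is$tx_id,
                                           start = is$exons$start,
                                           end = is$exons$end,
                                           stringsAsFactors = FALSE)
      iso_rows[[length(iso_rows) + 1]] <- data.frame(
        tx_id = is$tx_id, unit_id = u$unit_id, kind = u$kind,
        lnc_class = u$lnc_class,
        expected_locus = if (!is.na(u$lnc_class) &&
                             u$lnc_class == "sense") u$host else u$unit_id,
        stringsAsFactors = FALSE)
    }
  }
  truth_tx <- tx_set(do.call(rbind, tr), do.call(rbind, exl))
  truth_ann <- annotation(truth_tx)
  iso_df <- do.call(rbind, iso_rows)

  # reference annotation: coding units minus planted novel genes/transcripts;
  # lncRNA host genes stay in the reference so the planted positional
  # classes remain well defined
  hosts <- unique(stats::na.omit(vapply(units, `[[`, character(1), "host")))
  host_idx <- which(unit_ids_all(units) %in% hosts)
  novel_pool <- setdiff(coding_idx, host_idx)
  novel_units <- sample(novel_pool,
                        min(length(novel_pool),
                            round(cfg$novel_gene_fraction *
                                    length(coding_idx))))
  unit_ids <- vapply(units, `[[`, character(1), "unit_id")
  iso_df$unit_in_ref <- !(iso_df$unit_id %in% unit_ids[novel_units]) &
    iso_df$kind == "coding"
  extra <- iso_df$kind == "coding" & iso_df$unit_in_ref &
    !grepl("\\.t1$", iso_df$tx_id)
  omit_tx <- sample(iso_df$tx_id[extra],
                    round(cfg$novel_tx_fraction * sum(extra)))
  iso_df$in_ref <- iso_df$unit_in_ref & !(iso_df$tx_id %in% omit_tx)
  ref_tx <- subset_tx(truth_tx, iso_df$tx_id[iso_df$in_ref])
  ref_ann <- annotation(ref_tx)

  lnc_ids <- iso_df$tx_id[iso_df$kind == "lnc"]
  known_ids <- sample(lnc_ids,
                      round(cfg$known_lnc_fraction * length(lnc_ids)))
  known_lnc <- subset_tx(truth_tx, known_ids)

  apa <- do.call(rbind, lapply(units, function(u)
    data.frame(unit_id = u$unit_id, position = u$apa_sites,
               strand = u$strand, stringsAsFactors = FALSE)))
  events <- do.call(rbind, c(list(NULL),
    lapply(units, function(u) u$events)))
  truth <- list(isoforms = iso_df, events = events, apa = apa,
                gaps = gaps, chrom = chrom, chrom_len = chrom_len,
                known_lnc_ids = known_ids, config = cfg)
  list(truth_ann = truth_ann, ref_ann = ref_ann, genome = genome,
       known_lnc = known_lnc, truth = truth)
}

# default DE configuration used by sim_config (kept separate to avoid a
# self-referencing default argument)
isoannot_de_default <- function() de_config()

#' Isoform set a noise-free collapse is expected to recover
#'
#' The collapsed representative of each true isoform: its own exon chain
#' with the 3' terminal exon extended to the unit's most distal planted
#' polyA site (reads are emitted across all planted sites, and collapse
#' keeps the extreme ends of each intron-chain group).
#'
#' @param sim result of [simulate_genome()].
#' @return a [tx_set()] parallel to `sim$truth_ann$tx`.
#' @export
expected_collapse <- function(sim) {
  tx <- sim$truth_ann$tx
  apa <- sim$truth$apa
  sp <- tx_spans(tx)
  ex <- tx$exons
  for (uid in unique(apa$unit_id)) {
    pos <- apa$position[apa$unit_id == uid]
    ids <- tx$transcripts$tx_id[tx$transcripts$gene_id == uid]
    strand <- tx$transcripts$strand[tx$transcripts$gene_id == uid][1]
    for (id in ids) {
      rows <- which(ex$tx_id == id)
      if (strand == "+") {
        last <- rows[which.max(ex$end[rows])]
        ex$end[last] <- max(c(pos, ex$end[last]))
      } else {
        first <- rows[which.min(ex$start[rows])]
        ex$start[first] <- min(c(pos, ex$start[first]))
      }
    }
  }
  tx_set(tx$transcripts, ex)
}

#' Simulate full-length reads from the planted transcripts
#'
#' Each true isoform is present in a random non-empty subset of samples and
#' emits reads that copy its exon chain. Read 3' ends are assigned to the
#' gene's planted polyA sites (round-robin, so each site is supported when
#' read depth allows); 5'/3' ends then receive truncated Normal jitter that
#' never crosses a splice site. A `noise_read_rate` fraction of intergenic
#' mono-exon reads is added.
#'
#' @param sim result of [simulate_genome()].
#' @param cfg the same [sim_config()].
#' @return list with `reads` (a [tx_set()] with `sample` labels),
#'   `read_truth` (data.frame `read_id`, `tx_id`, `sample`, `is_noise`) and
#'   `presence` (data.frame `tx_id`, `sample`).
#' @export
simulate_flnc <- function(sim, cfg) {
  set.seed(cfg$seed + 1L)
  truth <- sim$truth
  tx <- sim$truth_ann$tx
  sp <- tx_spans(tx)
  ins <- introns(tx)
  iso_df <- truth$isoforms
  samples <- cfg$samples
  rtr <- list(); rex <- list(); rt <- list(); pres <- list()
  read_n <- 0
  jit <- function(n) if (cfg$end_jitter_sd > 0)
    round(stats::rnorm(n, 0, cfg$end_jitter_sd)) else rep(0, n)

  for (uid in unique(iso_df$unit_id)) {
    ids <- iso_df$tx_id[iso_df$unit_id == uid]
    sites <- truth$apa$position[truth$apa$unit_id == uid]
    strand <- sp$strand[match(ids[1], sp$tx_id)]
    # 5'->3' site order; round-robin assignment covers every site
    k_sites <- length(sites)
    per_iso <- lapply(ids, function(id) {
      pp <- sample(samples, sample(length(samples), 1))
      nr <- pmax(1, stats::rpois(length(pp), cfg$reads_per_isoform))
      sm <- rep(pp, nr)
      # every isoform visits every planted site so the collapsed ends are
      # deterministic (the most distal site)
      while (length(sm) < k_sites) sm <- c(sm, sm[1])
      list(tx_id = id, samples = sm)
    })
    total <- sum(vapply(per_iso, function(p) length(p$samples), integer(1)))
    while (total < 2 * k_sites) { # each site needs >= 2 supporting reads
      k <- (total %% length(per_iso)) + 1
      per_iso[[k]]$samples <- c(per_iso[[k]]$samples,
                                per_iso[[k]]$samples[1])
      total <- total + 1
    }
    for (p in per_iso) {
      id <- p$tx_id
      e0 <- tx$exons[tx$exons$tx_id == id, c("start", "end")]
      e0 <- e0[order(e0$start), , drop = FALSE]
      my_introns <- ins[ins$tx_id == id, , drop = FALSE]
      site_i <- 0
      for (sm in p$samples) {
        read_n <- read_n + 1
        site_i <- site_i %% length(sites) + 1
        e <- e0
        n_ex <- nrow(e)
        # 3' end to the assigned polyA site, then jitter within limits
        if (strand == "+") {
          e$end[n_ex] <- sites[site_i]
          e$end[n_ex] <- max(e$start[n_ex] + 20,
                             e$end[n_ex] + jit(1))
          e$start[1] <- min(e$end[1] - 20, max(0, e$start[1] + jit(1)))
        } else {
          e$start[1] <- sites[site_i]
          e$start[1] <- min(e$end[1] - 20, max(0, e$start[1] + jit(1)))
          e$end[n_ex] <- max(e$start[n_ex] + 20, e$end[n_ex] + jit(1))
        }
        rid <- sprintf("read%06d", read_n)
        rtr[[read_n]] <- data.frame(tx_id = rid, chrom = truth$chrom,
                                    strand = strand, sample = sm,
                                    stringsAsFactors = FALSE)
        rex[[read_n]] <- data.frame(tx_id = rid, start = e$start,
                                    end = e$end, stringsAsFactors = FALSE)
        rt[[read_n]] <- data.frame(read_id = rid, tx_id = id, sample = sm,
                                   is_noise = FALSE, stringsAsFactors = FALSE)
      }
      pres[[length(pres) + 1]] <- data.frame(
        tx_id = id, sample = unique(p$samples), stringsAsFactors = FALSE)
    }
  }
  n_signal <- read_n
  n_noise <- stats::rbinom(1, n_signal, cfg$noise_read_rate)
  gaps <- truth$gaps
  for (k in seq_len(n_noise)) {
    read_n <- read_n + 1
    gp <- gaps[(k - 1) %% nrow(gaps) + 1, ]
    len <- sample(250:450, 1)
    st <- gp$start + sample.int(max(1, gp$end - gp$start - len), 1) - 1
    rid <- sprintf("read%06d", read_n)
    rtr[[read_n]] <- data.frame(tx_id = rid, chrom = truth$chrom,
                                strand = sample(c("+", "-"), 1),
                                sample = sample(cfg$samples, 1),
                                stringsAsFactors = FALSE)
    rex[[read_n]] <- data.frame(tx_id = rid, start = st, end = st + len,
                                stringsAsFactors = FALSE)
    rt[[read_n]] <- data.frame(read_id = rid, tx_id = NA_character_,
                               sample = rtr[[read_n]]$sample, is_noise = TRUE,
                               stringsAsFactors = FALSE)
  }
  reads <- tx_set(do.call(rbind, rtr), do.call(rbind, rex))
  list(reads = reads, read_truth = do.call(rbind, rt),
       presence = do.call(rbind, pres))
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Two conditions with `n_replicates` each; counts are
#' NB(mean, dispersion) with the planted log2 fold change applied to
#' condition B of non-null features. Optional isoform-switch genes swap the
#' means of two member transcripts between conditions so the gene-level sum
#' is unchanged.
#'
#' @param tx2gene data.frame with columns `tx_id`, `gene_id`.
#' @param de_cfg a [de_config()].
#' @param seed RNG seed.
#' @return list with `counts` (integer matrix transcripts x samples),
#'   `col_data` (condition/replicate), `truth` (per-transcript planted
#'   log2FC, DE status, switch flag) and `gene_truth` (gene-level DE status:
#'   union of member-transcript statuses).
#' @export
simulate_counts <- function(tx2gene, de_cfg = de_config(), seed = 1) {
  set.seed(seed + 2L)
  if (de_cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (de_cfg$n_replicates < 2) stop("need >= 2 replicates per condition")
  tx2gene <- as.data.frame(tx2gene, stringsAsFactors = FALSE)
  ids <- tx2gene$tx_id
  m <- length(ids)
  nr <- de_cfg$n_replicates
  mu0 <- stats::rlnorm(m, de_cfg$base_meanlog, de_cfg$base_sdlog)
  lfc <- numeric(m)
  non_null <- stats::runif(m) > de_cfg$fraction_null
  lfc[non_null] <- sample(c(-1, 1), sum(non_null), TRUE) *
    de_cfg$planted_log2fc
  is_switch_tx <- rep(FALSE, m)
  muA <- mu0; muB <- mu0 * 2^lfc
  if (de_cfg$n_switch > 0) {
    cnt <- table(tx2gene$gene_id)
    cand <- names(cnt)[cnt >= 2]
    sw <- sample(cand, min(de_cfg$n_switch, length(cand)))
    for (gsw in sw) {
      pair <- which(tx2gene$gene_id == gsw)[1:2]
      muA[pair] <- de_cfg$switch_means
      muB[pair] <- rev(de_cfg$switch_means)
      lfc[pair] <- log2(muB[pair] / muA[pair])
      non_null[pair] <- TRUE
      is_switch_tx[pair] <- TRUE
    }
  } else sw <- character(0)
  depth <- stats::runif(2 * nr, 0.8, 1.2)
  counts <- matrix(0L, m, 2 * nr,
                   dimnames = list(ids, c(paste0("A_", seq_len(nr)),
                                          paste0("B_", seq_len(nr)))))
  size <- 1 / de_cfg$dispersion
  for (j in seq_len(nr))
    counts[, j] <- stats::rnbinom(m, mu = muA * depth[j], size = size)
  for (j in seq_len(nr))
    counts[, nr + j] <- stats::rnbinom(m, mu = muB * depth[nr + j],
                                       size = size)
  col_data <- data.frame(sample = colnames(counts),
                         condition = rep(c("A", "B"), each = nr),
                         replicate = rep(seq_len(nr), 2),
                         depth = depth, stringsAsFactors = FALSE)
  truth <- data.frame(tx_id = ids, gene_id = tx2gene$gene_id,
                      base_mean = mu0, log2fc = lfc, is_de = non_null,
                      is_switch = is_switch_tx, stringsAsFactors = FALSE)
  gene_truth <- do.call(rbind, lapply(split(truth, truth$gene_id),
    function(d) data.frame(gene_id = d$gene_id[1], is_de = any(d$is_de),
                           is_switch = any(d$is_switch),
                           stringsAsFactors = FALSE)))
  rownames(gene_truth) <- NULL
  list(counts = counts, col_data = col_data, truth = truth,
       gene_truth = gene_truth, switch_genes = sw)
}
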