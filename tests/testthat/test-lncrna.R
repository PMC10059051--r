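# deterministic training CDS set with biased codon usage
train_cds <- function(n = 40, n_codons = 220, seed = 99) {
  set.seed(seed)
  b <- c("T", "C", "A", "G")
  codons <- setdiff(as.vector(outer(outer(b, b, paste0), b, paste0)),
                    c("TAA", "TAG", "TGA"))
  w <- (rexp(length(codons)) + 0.05)^2
  vapply(seq_len(n), function(i)
    paste0("ATG", paste(sample(codons, n_codons, TRUE, w), collapse = ""),
           "TAA"),
    character(1))
}

test_that("ORF finder and hexamer call behave at the boundaries", {
  cds <- train_cds()
  # no ATG anywhere -> ORF 0 -> noncoding (length >= 200)
  no_atg <- paste(rep("C", 300), collapse = "")
  cp <- coding_potential(setNames(no_atg, "x"), cds)
  expect_equal(cp$orf_codons, 0L)
  expect_equal(cp$call, "noncoding")
  # a planted 300-codon ORF drawn from the training codon model -> coding
  long_orf <- train_cds(n = 1, n_codons = 300, seed = 12)
  cp2 <- coding_potential(setNames(long_orf, "y"), cds)
  expect_equal(cp2$call, "coding")
  expect_gte(cp2$orf_codons, 300)
  # shorter than the length filter: never eligible as lncRNA
  short <- substr(no_atg, 1, 150)
  cp3 <- coding_potential(setNames(short, "z"), cds)
  expect_false(cp3$eligible)
  expect_error(coding_potential(setNames(no_atg, "x"), character(0)),
               "empty")
})

test_that("ORF length counts codons from ATG, stops close the frame", {
  cds <- train_cds()
  # ATG + 5 codons + TAA embedded in C padding
  s <- paste0(strrep("C", 30), "ATG", "GCTGCTGCTGCTGCT", "TAA",
              strrep("C", 30))
  cp <- coding_potential(setNames(s, "s"), cds, min_lnc_length = 10)
  expect_equal(cp$orf_codons, 6L) # ATG plus five codons
})

test_that("hexamer heuristic separates coding-like from random sequence", {
  cds <- train_cds(n = 60)
  model <- train_hexamer_model(cds)
  set.seed(5)
  # 200 sequences sampled from the training codon model vs 200 uniform
  coding_like <- train_cds(n = 200, n_codons = 160, seed = 6)
  rand <- vapply(seq_len(200), function(i)
    paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
    character(1))
  calls_c <- coding_potential(coding_like, model)$call
  calls_r <- coding_potential(rand, model)$call
  acc <- (sum(calls_c == "coding") + sum(calls_r == "noncoding")) / 400
  expect_gt(acc, 0.9)
})

test_that("positional classes follow the precedence order", {
  # reference gene: two exons, one intron [1200, 2000)
  tr <- data.frame(tx_id = "rt", chrom = "chr1", strand = "+",
                   gene_id = "rg", stringsAsFactors = FALSE)
  ref <- annotation(tx_set(tr, data.frame(tx_id = c("rt", "rt"),
                                          start = c(1000, 2000),
                                          end = c(1200, 2500))))
  inside_intron <- mk_tx("a", rbind(c(1300, 1900)), strand = "-")
  sense_ov <- mk_tx("b", rbind(c(1100, 1400)))
  anti_ov <- mk_tx("c", rbind(c(1100, 1400)), strand = "-")
  nowhere <- mk_tx("d", rbind(c(9000, 9400)))
  x <- bind_tx(inside_intron, sense_ov, anti_ov, nowhere)
  cls <- classify_position(x, ref)
  expect_equal(cls$class, c("intronic", "sense", "antisense", "intergenic"))
  expect_equal(cls$anchor_gene[1:3], rep("rg", 3))
  # intronic outranks sense: a same-strand transcript fully inside the
  # intron is intronic even though the gene is same-strand
  intr_sense <- mk_tx("e", rbind(c(1300, 1900)))
  expect_equal(classify_position(intr_sense, ref)$class, "intronic")
})

test_that("reference gene order never changes positional calls", {
  cfg <- sim_config(seed = 43, n_genes = 20, end_jitter_sd = 0,
                    noise_read_rate = 0)
  sim <- simulate_genome(cfg)
  lncs <- subset_tx(sim$truth_ann$tx,
                    sim$truth$isoforms$tx_id[sim$truth$isoforms$kind == "lnc"])
  ref <- sim$ref_ann
  c1 <- classify_position(lncs, ref)
  set.seed(1)
  perm <- sample(nrow(ref$genes))
  ref2 <- ref
  ref2$genes <- ref$genes[perm, ]
  c2 <- classify_position(lncs, ref2)
  expect_identical(c1, c2)
})

test_that("planted positional classes are recovered exactly", {
  cfg <- sim_config(seed = 47, n_genes = 30, end_jitter_sd = 0,
                    noise_read_rate = 0)
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(sim, cfg)
  col <- collapse_reads(fl$reads)
  kx <- function(x) paste(intron_chain_key(x), tx_spans(x)$start,
                          tx_spans(x)$end)
  exp <- expected_collapse(sim)
  map <- setNames(exp$transcripts$tx_id[match(kx(col$isoforms), kx(exp))],
                  col$isoforms$transcripts$tx_id)
  lnc <- lncrna_calls(col$isoforms, sim$genome, sim$ref_ann)
  iso_df <- sim$truth$isoforms
  planted <- iso_df$tx_id[iso_df$kind == "lnc"]
  called_nc <- map[lnc$coding$tx_id[lnc$coding$call == "noncoding"]]
  expect_true(all(planted %in% called_nc))
  cls <- setNames(lnc$lncrna$class, map[lnc$lncrna$tx_id])
  want <- setNames(iso_df$lnc_class[iso_df$kind == "lnc"], planted)
  expect_equal(cls[names(want)], want)
  # the four classes partition the called set
  expect_equal(sum(table(lnc$lncrna$class)), nrow(lnc$lncrna))
})

test_that("external coding calls replace the heuristic", {
  cfg <- sim_config(seed = 51, n_genes = 8, end_jitter_sd = 0,
                    noise_read_rate = 0)
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(sim, cfg)
  col <- collapse_reads(fl$reads)
  ids <- col$isoforms$transcripts$tx_id
  ext <- data.frame(tx_id = ids,
                    call = rep(c("coding", "noncoding"), length.out =
                                 length(ids)))
  lnc <- lncrna_calls(col$isoforms, sim$genome, sim$ref_ann,
                      external_calls = ext)
  expect_equal(lnc$coding$call,
               ext$call[match(lnc$coding$tx_id, ext$tx_id)])
})

test_that("lncrna_summary computes class shares and novelty", {
  classes <- data.frame(
    tx_id = sprintf("l%02d", 1:10),
    class = c(rep("intronic", 4), rep("sense", 3), rep("antisense", 2),
              "intergenic"),
    anchor_gene = NA_character_, stringsAsFactors = FALSE)
  s <- lncrna_summary(classes, novel = c(rep(TRUE, 9), FALSE))
  expect_equal(unname(s$class_pct["intronic"]), 40)
  expect_equal(s$novel_pct, 90)
  expect_equal(sum(s$class_counts), 10)
})
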