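test_that("canonical variants are typed by definition", {
  # intron retention
  t1 <- mk_tx("t1", rbind(c(0, 100), c(200, 300)))
  t2 <- mk_tx("t2", rbind(c(0, 300)))
  ev <- pairwise_events(t1, t2)
  expect_equal(ev$type, "IR")
  expect_equal(c(ev$region_start, ev$region_end), c(100, 200))
  # exon skipping
  s1 <- mk_tx("s1", rbind(c(0, 100), c(200, 300), c(400, 500)))
  s2 <- mk_tx("s2", rbind(c(0, 100), c(400, 500)))
  ev <- pairwise_events(s1, s2)
  expect_equal(ev$type, "ES")
  expect_equal(c(ev$region_start, ev$region_end), c(200, 300))
  # alternative donor on "+": differing intron start, shared end
  d1 <- mk_tx("d1", rbind(c(0, 100), c(200, 300)))
  d2 <- mk_tx("d2", rbind(c(0, 120), c(200, 300)))
  ev <- pairwise_events(d1, d2)
  expect_equal(ev$type, "AD")
  expect_equal(c(ev$region_start, ev$region_end), c(100, 120))
  # alternative acceptor on "+": shared start, differing end
  a1 <- mk_tx("a1", rbind(c(0, 100), c(200, 300)))
  a2 <- mk_tx("a2", rbind(c(0, 100), c(230, 300)))
  expect_equal(pairwise_events(a1, a2)$type, "AA")
  # mutually exclusive exons
  m1 <- mk_tx("m1", rbind(c(0, 100), c(200, 250), c(500, 600)))
  m2 <- mk_tx("m2", rbind(c(0, 100), c(300, 360), c(500, 600)))
  ev <- pairwise_events(m1, m2)
  expect_equal(ev$type, "MEE")
  expect_equal(c(ev$region_start, ev$region_end), c(200, 360))
})

test_that("AD/AA classification is strand-aware (reflection test)", {
  d1 <- mk_tx("d1", rbind(c(0, 100), c(200, 300)))
  d2 <- mk_tx("d2", rbind(c(0, 120), c(200, 300)))
  expect_equal(pairwise_events(d1, d2)$type, "AD")
  # mirror the structure around 300 and flip the strand: same genomic
  # shapes on "-" must give the mirrored classification
  refl <- function(ex) {
    m <- 300 - ex[, 2:1]
    m[order(m[, 1]), , drop = FALSE]
  }
  r1 <- mk_tx("r1", refl(rbind(c(0, 100), c(200, 300))), strand = "-")
  r2 <- mk_tx("r2", refl(rbind(c(0, 120), c(200, 300))), strand = "-")
  expect_equal(pairwise_events(r1, r2)$type, "AD")
  # and the unmirrored structure on "-" flips AD to AA
  d1m <- mk_tx("d1", rbind(c(0, 100), c(200, 300)), strand = "-")
  d2m <- mk_tx("d2", rbind(c(0, 120), c(200, 300)), strand = "-")
  expect_equal(pairwise_events(d1m, d2m)$type, "AA")
})

test_that("pairwise_events is symmetric and rejects strand mismatches", {
  t1 <- mk_tx("t1", rbind(c(0, 100), c(200, 300), c(400, 500)))
  t2 <- mk_tx("t2", rbind(c(0, 300), c(400, 520)))
  e12 <- pairwise_events(t1, t2)
  e21 <- pairwise_events(t2, t1)
  expect_identical(e12, e21)
  t3 <- mk_tx("t3", rbind(c(0, 100)), strand = "-")
  expect_error(pairwise_events(t1, t3), "strand")
})

test_that("terminal-exon end differences are not events", {
  t1 <- mk_tx("t1", rbind(c(0, 100), c(200, 300)))
  t2 <- mk_tx("t2", rbind(c(10, 100), c(200, 290)))
  expect_equal(nrow(pairwise_events(t1, t2)), 0)
  # an intron hanging off the common region is TSS variation, not AS
  t3 <- mk_tx("t3", rbind(c(-500, -400), c(-200, 100), c(200, 300)))
  t3$exons$start <- t3$exons$start + 1000
  t3$exons$end <- t3$exons$end + 1000
  t4 <- mk_tx("t4", rbind(c(850, 1100), c(1200, 1300)))
  ev <- pairwise_events(t3, t4)
  expect_equal(nrow(ev), 0)
})

test_that("events deduplicate by key across isoform pairs", {
  base <- mk_tx("b", rbind(c(0, 100), c(200, 300), c(400, 500)))
  skip <- mk_tx("k", rbind(c(0, 100), c(400, 500)))
  long3 <- mk_tx("l", rbind(c(0, 100), c(200, 300), c(400, 520)))
  iso <- bind_tx(base, skip, long3)
  iso$transcripts$gene_id <- "g"
  ev <- gene_events(iso)
  # pairs (b,k) and (l,k) both show the same ES; dedup leaves one event
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "ES")
  one <- subset_tx(iso, "b"); one$transcripts$gene_id <- "g"
  expect_equal(nrow(gene_events(one)), 0)
})

test_that("per-sample counts use restricted sets; combined uses the pool", {
  base <- mk_tx("b", rbind(c(0, 100), c(200, 300), c(400, 500)))
  skip <- mk_tx("k", rbind(c(0, 100), c(400, 500)))
  iso <- bind_tx(base, skip)
  iso$transcripts$gene_id <- "g"
  # both AS witnesses only in worker
  iso$transcripts$samples <- c("worker", "worker")
  cnt <- count_events_by_sample(iso, samples = c("queen", "worker", "drone"))
  s <- cnt$summary
  expect_equal(s$worker[s$type == "ES"], 1L)
  expect_equal(s$queen[s$type == "ES"], 0L)
  expect_equal(s$combined[s$type == "ES"], 1L)
  # witnesses split across samples: only the combined analysis sees it
  iso$transcripts$samples <- c("queen", "worker")
  cnt2 <- count_events_by_sample(iso, samples = c("queen", "worker"))
  s2 <- cnt2$summary
  expect_equal(s2$queen[s2$type == "ES"], 0L)
  expect_equal(s2$worker[s2$type == "ES"], 0L)
  expect_equal(s2$combined[s2$type == "ES"], 1L)
  expect_true(all(s2$combined >= pmax(s2$queen, s2$worker)))
})

test_that("simulated loci reproduce the planted event set exactly", {
  for (sd in c(19, 29)) {
    cfg <- sim_config(seed = sd, n_genes = 25, end_jitter_sd = 0,
                      noise_read_rate = 0)
    sim <- simulate_genome(cfg)
    fl <- simulate_flnc(sim, cfg)
    col <- collapse_reads(fl$reads)
    ev <- gene_events(col$isoforms)
    tt <- sim$truth$events
    expect_identical(
      sort(paste(ev$type, ev$region_start, ev$region_end)),
      sort(paste(tt$type, tt$region_start, tt$region_end)))
  }
})

test_that("planted event-type mix is recovered within multinomial bounds", {
  mix <- c(ES = 0.2, IR = 0.4, AA = 0.15, AD = 0.15, MEE = 0.1)
  cfg <- sim_config(seed = 37, n_genes = 120,
                    isoform_dist = c(`1` = 0, `2` = 0.4, `3` = 0.4,
                                     `4` = 0.2),
                    as_event_mix = mix, end_jitter_sd = 0,
                    noise_read_rate = 0,
                    n_noncoding = c(intronic = 0, sense = 0, antisense = 0,
                                    intergenic = 0))
  sim <- simulate_genome(cfg)
  tt <- sim$truth$events
  n <- nrow(tt)
  expect_gte(n, 200)
  obs <- table(factor(tt$type, names(mix)))
  # each observed share within a 99% binomial interval of its target
  for (ty in names(mix)) {
    bounds <- qbinom(c(0.005, 0.995), n, mix[[ty]])
    expect_gte(obs[[ty]], bounds[1])
    expect_lte(obs[[ty]], bounds[2])
  }
})
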