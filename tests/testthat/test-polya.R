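test_that("3' ends are strand-aware", {
  p <- mk_tx("p", rbind(c(0, 100), c(200, 300)))
  m <- mk_tx("m", rbind(c(0, 100), c(200, 300)), strand = "-")
  expect_equal(unname(three_prime_ends(p)), 300)
  expect_equal(unname(three_prime_ends(m)), 0)
})

test_that("single-linkage clustering matches the definition", {
  # all ends identical: one site with full support
  cl <- cluster_polya(rep(500, 7), "+")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$support, 7L)
  expect_equal(cl$position, 500)
  # a gap wider than the window splits clusters
  cl2 <- cluster_polya(c(100, 105, 400, 402), "+", merge_window = 30)
  expect_equal(cl2$support, c(2L, 2L))
  # degenerate window: one site per distinct position
  ends <- c(10, 11, 12, 50, 50)
  cl3 <- cluster_polya(ends, "+", merge_window = 0, min_site_support = 1)
  expect_equal(nrow(cl3), length(unique(ends)))
  # support below min_site_support drops the cluster
  cl4 <- cluster_polya(c(100, 400, 401), "+", min_site_support = 2)
  expect_equal(nrow(cl4), 1)
})

test_that("representative is the weighted mode, ties broken distal", {
  # 300 has higher multiplicity
  cl <- cluster_polya(c(290, 300, 300), "+")
  expect_equal(cl$position, 300)
  # tie: most distal wins, which depends on strand
  expect_equal(cluster_polya(c(290, 290, 300, 300), "+")$position, 300)
  expect_equal(cluster_polya(c(290, 290, 300, 300), "-")$position, 290)
})

test_that("clustering equals a brute-force single-linkage oracle", {
  brute_single_linkage <- function(ends, window) {
    groups <- as.list(ends)
    repeat {
      merged <- FALSE
      for (i in seq_along(groups)) {
        for (j in seq_along(groups)) {
          if (i >= j) next
          if (min(abs(outer(groups[[i]], groups[[j]], "-"))) <= window) {
            groups[[i]] <- c(groups[[i]], groups[[j]])
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) return(groups)
    }
  }
  for (sd in c(3, 5, 9)) {
    set.seed(sd)
    ends <- sample.int(2000, 60, replace = TRUE)
    cl <- cluster_polya(ends, "+", merge_window = 24, min_site_support = 1)
    oracle <- brute_single_linkage(ends, 24)
    expect_equal(sort(cl$support),
                 sort(lengths(oracle)))
    expect_setequal(
      vapply(attr(cl, "members"), function(v) paste(sort(v), collapse = ","),
             character(1)),
      vapply(oracle, function(v) paste(sort(v), collapse = ","),
             character(1)))
  }
})

test_that("site count per gene is non-increasing in the merge window", {
  set.seed(4)
  ends <- sample.int(3000, 80, replace = TRUE)
  prev <- Inf
  for (w in c(0, 10, 24, 50, 200)) {
    n <- nrow(cluster_polya(ends, "+", merge_window = w,
                            min_site_support = 1))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("site supports conserve the gene's read count", {
  reads <- rand_reads(60, 15)
  col <- collapse_reads(reads)
  sites <- polya_sites(col$reads, min_site_support = 1)
  support <- tapply(sites$support, sites$gene_id, sum)
  reads_per_locus <- table(col$reads$transcripts$locus_id)
  expect_equal(as.integer(support[names(reads_per_locus)]),
               as.integer(reads_per_locus))
})

test_that("planted sites are recovered exactly on noise-free simulations", {
  cfg <- sim_config(seed = 41, n_genes = 30, end_jitter_sd = 0,
                    noise_read_rate = 0)
  sim <- simulate_genome(cfg)
  fl <- simulate_flnc(sim, cfg)
  col <- collapse_reads(fl$reads)
  sites <- polya_sites(col$reads)
  expect_identical(sort(paste(sites$strand, sites$position)),
                   sort(paste(sim$truth$apa$strand,
                              sim$truth$apa$position)))
})

test_that("apa_summary reports histogram, mean and bin shares", {
  s <- apa_summary(c(1L, 1L, 3L, 12L))
  expect_equal(s$mean_sites_per_gene, round_half_up(17 / 4, 2))
  expect_equal(unname(s$bin_shares["1-9"]), 75)
  expect_equal(unname(s$bin_shares["10+"]), 25)
  one <- apa_summary(1L)
  expect_equal(one$mean_sites_per_gene, 1)
  expect_equal(unname(one$bin_shares["1-9"]), 100)
})

test_that("flank profile: planted all-A downstream gives frequency 1", {
  genome <- Biostrings::DNAStringSet(c(chrF = paste(
    c(rep("C", 100), rep("A", 60), rep("G", 100)), collapse = "")))
  sites <- data.frame(gene_id = "g", chrom = "chrF", strand = "+",
                      position = 100, support = 5)
  fp <- flank_profile(sites, genome, flank = 50)
  down <- as.character(0:49)
  expect_true(all(fp$freq["A", down] == 1))
  expect_equal(fp$hit_fraction, 1)
  expect_equal(unname(fp$element_start_fraction["0"]), 1)
})

test_that("minus-strand windows are reverse-complemented", {
  set.seed(6)
  seqc <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrR = seqc))
  sp <- data.frame(gene_id = "g", chrom = "chrR", strand = "+",
                   position = 200, support = 2)
  sm <- transform(sp, strand = "-")
  fp <- flank_profile(sp, genome, flank = 20)
  fm <- flank_profile(sm, genome, flank = 20)
  # the minus profile is the plus profile with A<->T, C<->G and offsets
  # reversed
  expect_equal(unname(fm$freq["A", ]), unname(rev(fp$freq["T", ])))
  expect_equal(unname(fm$freq["C", ]), unname(rev(fp$freq["G", ])))
})

test_that("uniform flanks give ~0.25 composition and no A-run excess", {
  set.seed(8)
  seqc <- paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrU = seqc))
  pos <- seq(100, 29800, by = 120)
  sites <- data.frame(gene_id = paste0("g", seq_along(pos)), chrom = "chrU",
                      strand = "+", position = pos, support = 2)
  fp <- flank_profile(sites, genome, flank = 50)
  expect_true(all(abs(fp$freq[c("A", "C", "G", "T"), ] - 0.25) < 0.13))
  # expected fraction of windows containing an A-run of 10 in iid ACGT:
  # bounded above by 91 * 0.25^10 ~ 1e-4
  expect_lte(fp$hit_fraction, 0.01)
})

test_that("sites at chromosome ends are truncated with a warning", {
  genome <- Biostrings::DNAStringSet(c(chrE = strrep("ACGT", 30)))
  sites <- data.frame(gene_id = "g", chrom = "chrE", strand = "+",
                      position = 10, support = 2)
  expect_warning(fp <- flank_profile(sites, genome, flank = 50), "truncated")
  expect_true(all(fp$freq[, as.character(-50:-11)] == 0))
})
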