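test_that("median-of-ratios normalization removes depth scaling", {
  set.seed(2)
  base <- matrix(rpois(500 * 4, 100), ncol = 4,
                 dimnames = list(sprintf("f%03d", 1:500), paste0("s", 1:4)))
  doubled <- base
  doubled[, 2] <- base[, 2] * 2
  nn <- normalize_counts(doubled)
  expect_equal(nn$size_factors[2] / nn$size_factors[1], 2,
               tolerance = 0.02, ignore_attr = TRUE)
  # identical samples: all size factors 1
  same <- cbind(base[, 1], base[, 1], base[, 1])
  expect_equal(unname(normalize_counts(same)$size_factors), rep(1, 3))
  # simulated depth factors recovered within 5%
  t2g <- data.frame(tx_id = rownames(base), gene_id = rownames(base))
  sc <- simulate_counts(t2g, de_config(n_replicates = 4, dispersion = 0.05,
                                       fraction_null = 1,
                                       base_meanlog = 5), seed = 77)
  sf <- normalize_counts(sc$counts)$size_factors
  ratio <- sf / sc$col_data$depth
  expect_true(all(abs(ratio / mean(ratio) - 1) < 0.05))
})

test_that("all-zero fallback warns and uses total counts", {
  m <- matrix(c(0, 5, 0, 10, 0, 7), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_warning(nn <- normalize_counts(m), "total-count")
  expect_equal(length(nn$size_factors), 2)
})

test_that("identical groups give log2FC 0 and no call", {
  m <- matrix(rep(c(50, 80, 120), each = 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  res <- de_test(m, rep(c("A", "B"), each = 3))
  expect_equal(res$log2FC, rep(0, 3))
  expect_false(any(res$call))
})

test_that("group size and zero-row handling", {
  m <- matrix(rpois(40, 50), nrow = 4,
              dimnames = list(letters[1:4], paste0("s", 1:10)))
  expect_error(de_test(m, c(rep("A", 1), rep("B", 9))), "replicates")
  m[2, ] <- 0
  res <- de_test(m, rep(c("A", "B"), each = 5))
  expect_false(res$tested[2])
  expect_true(is.na(res$pvalue[2]))
  expect_false(res$call[2])
  # BH denominator excludes untested rows: padj of tested rows computed
  # over 3 features
  p <- res$pvalue[res$tested]
  expect_equal(sort(res$padj[res$tested]),
               sort(p.adjust(p, "BH")))
})

test_that("planted fold changes are recovered and called", {
  t2g <- data.frame(tx_id = sprintf("t%03d", 1:200),
                    gene_id = sprintf("g%03d", 1:200))
  sc <- simulate_counts(t2g, de_config(n_replicates = 5, dispersion = 0.01,
                                       planted_log2fc = 3,
                                       fraction_null = 0.5,
                                       base_meanlog = log(500),
                                       base_sdlog = 0), seed = 9)
  res <- de_test(sc$counts, sc$col_data$condition)
  de_idx <- sc$truth$is_de
  expect_true(all(res$call[de_idx]))
  expect_true(all(abs(abs(res$log2FC[de_idx]) - 3) < 0.3))
  expect_equal(sum(res$call[!de_idx]), 0)
})

test_that("null simulation keeps p-values uniform and calls rare", {
  t2g <- data.frame(tx_id = sprintf("t%04d", 1:1000),
                    gene_id = sprintf("g%04d", 1:1000))
  sc <- simulate_counts(t2g, de_config(n_replicates = 5, dispersion = 0.1,
                                       fraction_null = 1), seed = 4)
  res <- de_test(sc$counts, sc$col_data$condition)
  p <- res$pvalue[res$tested]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
  expect_lte(mean(res$call), 0.05 + 2 * sqrt(0.05 * 0.95 / length(p)))
})

test_that("BH adjustment is order-invariant and monotone after sorting", {
  t2g <- data.frame(tx_id = sprintf("t%03d", 1:300),
                    gene_id = sprintf("g%03d", 1:300))
  sc <- simulate_counts(t2g, de_config(n_replicates = 3, fraction_null = 0.7),
                        seed = 13)
  res <- de_test(sc$counts, sc$col_data$condition)
  perm <- sample(nrow(sc$counts))
  res_p <- de_test(sc$counts[perm, ], sc$col_data$condition)
  expect_equal(res_p$padj[match(res$feature_id, res_p$feature_id)],
               res$padj)
  srt <- res[res$tested, ]
  srt <- srt[order(srt$pvalue), ]
  expect_true(all(diff(srt$padj) >= -1e-12))
  expect_gte(min(srt$padj), min(srt$pvalue))
})

test_that("gene aggregation sums member transcripts and conserves totals", {
  m <- matrix(c(10, 20, 5, 7, 30, 40, 15, 17), nrow = 4,
              dimnames = list(c("t1", "t2", "t3", "t4"), c("s1", "s2")))
  t2g <- data.frame(tx_id = c("t1", "t2", "t3", "t4"),
                    gene_id = c("g1", "g1", "g2", "g3"))
  g <- gene_counts(m, t2g)
  expect_equal(g["g1", "s1"], 30)
  expect_equal(g["g3", ], m["t4", ]) # single-transcript gene unchanged
  expect_equal(colSums(g), colSums(m))
  expect_error(gene_counts(m, t2g[-1, ]), "no gene")
})

test_that("isoform switches appear at transcript level, not gene level", {
  t2g <- data.frame(tx_id = sprintf("w%03d", 1:100),
                    gene_id = rep(sprintf("sg%02d", 1:50), each = 2))
  sc <- simulate_counts(t2g, de_config(n_replicates = 5, dispersion = 0.005,
                                       fraction_null = 1, n_switch = 20),
                        seed = 5)
  det <- de_test(sc$counts, sc$col_data$condition)
  deg <- de_test(gene_counts(sc$counts, t2g), sc$col_data$condition)
  sw <- sc$switch_genes
  detg <- unique(t2g$gene_id[match(det$feature_id[det$call], t2g$tx_id)])
  expect_gte(mean(sw %in% detg), 0.9)
  expect_lte(mean(sw %in% deg$feature_id[deg$call]), 0.1)
  ov <- overlap_report(det, deg, t2g)
  expect_lte(ov$n_overlap, min(ov$n_detg, ov$n_deg))
})

test_that("overlap report handles empty and full intersections", {
  t2g <- data.frame(tx_id = c("t1", "t2"), gene_id = c("g1", "g2"))
  none <- data.frame(feature_id = c("t1", "t2"), call = c(FALSE, FALSE))
  some_genes <- data.frame(feature_id = c("g1", "g2"),
                           call = c(TRUE, FALSE))
  ov <- overlap_report(none, some_genes, t2g)
  expect_equal(ov$n_det, 0)
  expect_equal(ov$n_overlap, 0)
  both <- data.frame(feature_id = c("t1", "t2"), call = c(TRUE, TRUE))
  allg <- data.frame(feature_id = c("g1", "g2"), call = c(TRUE, TRUE))
  ov2 <- overlap_report(both, allg, t2g)
  expect_equal(ov2$pct_of_deg, 100)
  expect_equal(ov2$pct_of_detg, 100)
})

test_that("calls agree with DESeq2 on strongly separated features", {
  skip_if_not_installed("DESeq2")
  t2g <- data.frame(tx_id = sprintf("t%03d", 1:120),
                    gene_id = sprintf("g%03d", 1:120))
  sc <- simulate_counts(t2g, de_config(n_replicates = 4, dispersion = 0.05,
                                       planted_log2fc = 3,
                                       fraction_null = 0.5,
                                       base_meanlog = 5), seed = 21)
  res <- de_test(sc$counts, sc$col_data$condition)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sc$counts, S4Vectors::DataFrame(condition =
                                        factor(sc$col_data$condition)),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds)
  })
  dcall <- !is.na(dres$padj) & dres$padj < 0.05 & abs(dres$log2FoldChange) > 1
  agree <- mean(res$call == dcall)
  expect_gt(agree, 0.9)
  # fold-change estimates track DESeq2 closely on DE features
  de_idx <- sc$truth$is_de
  expect_lt(stats::median(abs(res$log2FC[de_idx] -
                                dres$log2FoldChange[de_idx])), 0.2)
})
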