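seg <- function(start, end, cn, chrom = "chr1", sample_id = "s1") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             cn = cn, stringsAsFactors = FALSE)
}

test_that("detect_wgd thresholds the length-weighted mean copy number", {
  expect_false(detect_wgd(seg(1, 1e6, 2.0)))
  expect_true(detect_wgd(seg(1, 1e6, 2.6)))
  half <- rbind(seg(1, 5e5, 2), seg(5e5 + 1, 1e6, 4))
  expect_true(detect_wgd(half)) # weighted mean 3.0
  # invariance to segment subdivision
  split_half <- rbind(seg(1, 2.5e5, 2), seg(2.5e5 + 1, 5e5, 2),
                      seg(5e5 + 1, 1e6, 4))
  expect_equal(detect_wgd(half), detect_wgd(split_half))
  expect_error(detect_wgd(seg(1, 10, 2)[0, ]), class = "sgmsig_input_error")
})

test_that("gene_cn takes the minimum qualifying overlapping segment", {
  s <- rbind(seg(1000, 6000, 1.2))
  expect_equal(gene_cn(s, "chr1", 2000, 3000), 1.2)
  s2 <- rbind(seg(1, 5000, 2.1), seg(2000, 3999, 0.8), seg(4000, 9000, 1.5))
  expect_equal(gene_cn(s2, "chr1", 2500, 4500), 0.8)
  # sub-1000 bp segments are ignored
  s3 <- rbind(seg(2000, 2499, 0.1))
  expect_true(is.na(gene_cn(s3, "chr1", 2000, 3000)))
  expect_true(is.na(gene_cn(s, "chr2", 2000, 3000)))
})

test_that("gene_loss applies platform-, WGD- and sex-aware thresholds", {
  expect_true(gene_loss(1.4, "WGS", wgd = FALSE))
  expect_false(gene_loss(1.5, "WGS", wgd = FALSE))
  expect_true(gene_loss(1.9, "WGS", wgd = TRUE))
  expect_false(gene_loss(2.0, "WGS", wgd = TRUE))
  expect_false(gene_loss(1.2, "WGS", wgd = FALSE, chromosome = "X",
                         sex = "male"))
  expect_true(gene_loss(0.9, "WGS", wgd = FALSE, chromosome = "X",
                        sex = "male"))
  expect_true(gene_loss(1.4, "WGS", wgd = TRUE, chromosome = "chrX",
                        sex = "male"))
  expect_true(gene_loss(1.4, "WGS", wgd = FALSE, chromosome = "X",
                        sex = "female"))
  expect_true(gene_loss(-0.5, "TCGA"))
  expect_false(gene_loss(0.0, "TCGA"))
  expect_false(gene_loss(NA_real_, "WGS")) # no CNA data -> no deletion
  expect_warning(gene_loss(1.4, "WGS", chromosome = "X"), "sex unknown")
  # monotone in copy number
  for (wgd in c(TRUE, FALSE)) {
    calls <- vapply(seq(0, 3, 0.1), gene_loss, logical(1),
                    platform = "WGS", wgd = wgd)
    expect_true(all(diff(calls) <= 0))
  }
})

test_that("cooccurrence reproduces simple count arithmetic", {
  sgm <- paste0("s", 1:467)
  loss <- paste0("s", 1:275)
  co <- cooccurrence(sgm, loss)
  expect_equal(co$k, 275)
  expect_equal(co$n, 467)
  expect_equal(round(100 * co$fraction, 1), 58.9)
  co2 <- cooccurrence(paste0("s", 1:29), paste0("s", 1:25))
  expect_equal(round(100 * co2$fraction, 1), 86.2)
  expect_equal(cooccurrence("a", "b")$fraction, 0)
  expect_true(co$fraction >= 0 && co$fraction <= 1 && co$k <= co$n)
})

test_that("motif_test compares SGM and non-SGM motif composition", {
  same <- motif_test(rep(c("YTCA", "other"), 10), rep(c("YTCA", "other"), 20))
  expect_true(all(same$p >= 0.5))
  extreme <- motif_test(rep("YTCA", 15), rep("RTCA", 15))
  expect_equal(extreme[extreme$motif == "YTCA", "p"],
               fisher_oracle_greater(15, 0, 0, 15), tolerance = 1e-12)
  small <- motif_test(c("YTCA", "YTCA", "RTCA"), c("YTCA", "other", "other"))
  expect_equal(small[small$motif == "RTCA", "p"],
               fisher_oracle_greater(1, 2, 0, 3), tolerance = 1e-12)
  expect_error(motif_test(character(0), "YTCA"), class = "sgmsig_input_error")
})

test_that("expression_association dichotomizes at the median with ties to low", {
  counts <- data.frame(sample_id = paste0("s", 1:20),
                       sbs13_sgms = c(rep(5, 10), rep(0, 10)))
  expr <- setNames(c(rep(10, 10), rep(1, 10)), paste0("s", 1:20))
  res <- expression_association(expr, counts)
  expect_equal(res$n_high, 10) # 10 strictly above the median of 5.5
  expect_lt(res$p, 0.001)
  # counts equal to expression rank: minimal attainable p
  expr2 <- setNames(1:12 + 0.5, paste0("t", 1:12))
  counts2 <- data.frame(sample_id = paste0("t", 1:12), c1 = 1:12)
  res2 <- expression_association(expr2, counts2)
  expect_equal(res2$p, wilcox.test(7:12, 1:6, alternative = "greater")$p.value)
  # ties at the median go to the low group
  expr3 <- setNames(c(1, 2, 2, 3, 4, 5), paste0("u", 1:6))
  res3 <- expression_association(expr3,
                                 data.frame(sample_id = paste0("u", 1:6),
                                            c1 = c(1, 1, 1, 9, 9, 9)))
  expect_equal(res3$n_high, 3)
  expect_error(expression_association(expr3[1:3],
                                      data.frame(sample_id = paste0("u", 1:3),
                                                 c1 = 1:3)),
               class = "sgmsig_input_error")
  expect_error(expression_association(setNames(rep(1, 6), paste0("u", 1:6)),
                                      data.frame(sample_id = paste0("u", 1:6),
                                                 c1 = 1:6)),
               class = "sgmsig_degenerate_error")
})

test_that("expression_association is calibrated under the null", {
  withr_seed(33, {
    ps <- vapply(1:200, function(i) {
      n <- 40
      expr <- setNames(rnorm(n), paste0("s", 1:n))
      counts <- data.frame(sample_id = paste0("s", 1:n),
                           c1 = rpois(n, 5))
      expression_association(expr, counts)$p
    }, numeric(1))
    expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  })
})

test_that("smoking_burden runs pairwise rank tests with FDR", {
  withr_seed(17, {
    groups <- rep(c("current", "never", "reformed_long"), each = 20)
    counts <- data.frame(sbs4 = c(rpois(20, 12), rpois(20, 1), rpois(20, 2)),
                         glu = c(rpois(20, 6), rpois(20, 0.5), rpois(20, 1)))
    res <- smoking_burden(groups, counts)
    expect_equal(nrow(res), 6) # 3 pairs x 2 categories
    top <- res[res$category == "sbs4" & res$group1 == "current" &
               res$group2 == "never", ]
    expect_lt(top$fdr, 0.001)
    expect_true(all(res$fdr >= res$p - 1e-12))
    # a single non-empty group yields no tests
    expect_equal(nrow(smoking_burden(rep("never", 10),
                                     data.frame(x = rpois(10, 2)))), 0)
  })
  # null: no pair significant in most replicates
  withr_seed(18, {
    hits <- vapply(1:60, function(i) {
      groups <- sample(rep(c("a", "b", "c", "d"), each = 12))
      res <- smoking_burden(groups, data.frame(x = rpois(48, 4)))
      any(res$fdr < 0.05)
    }, logical(1))
    expect_lte(mean(hits), 0.1)
  })
})

test_that("ko_test detects burden differences via the NB two-model LRT", {
  withr_seed(19, {
    # power: 5-fold lower mean in KO clones, 10 per group
    hits <- vapply(1:40, function(i) {
      clones <- data.frame(group = rep(c("WT", "KO"), each = 10),
                           sgms = c(rnbinom(10, mu = 25, size = 5),
                                    rnbinom(10, mu = 5, size = 5)))
      ko_test(clones, "sgms")$p < 0.01
    }, logical(1))
    expect_gte(mean(hits), 0.9)
    # null calibration: identical distributions
    null_ps <- vapply(1:60, function(i) {
      clones <- data.frame(group = rep(c("WT", "KO"), each = 10),
                           sgms = rnbinom(20, mu = 10, size = 5))
      ko_test(clones, "sgms")$p
    }, numeric(1))
    # df-1 LRT p values are ~uniform under the null: calibrated type-I error
    expect_gt(median(null_ps), 0.25)
    expect_lt(mean(null_ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
  })
  expect_error(ko_test(data.frame(group = c("WT", "WT", "KO"),
                                  sgms = c(1, 2, 3)), "sgms"),
               class = "sgmsig_input_error")
  expect_error(ko_test(data.frame(group = rep(c("WT", "KO"), each = 3),
                                  sgms = rep(0L, 6)), "sgms"),
               class = "sgmsig_degenerate_error")
})
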