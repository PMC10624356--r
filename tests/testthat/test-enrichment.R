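# Minimal labeled-SNV table builder for statistical tests that do not need
# real sequence context.
fake_snvs <- function(signature, class, n, sample_id = "s1",
                      cancer_type = "ct") {
  data.frame(
    sample_id = sample_id, cancer_type = cancer_type,
    functional_class = class, signature_label = signature,
    channel = "T[C>G]A", ref_aa = "S", gene_id = "g",
    stringsAsFactors = FALSE
  )[rep(1, n), , drop = FALSE]
}

test_that("qc_filter applies the exclusion rules in order", {
  md <- data.frame(
    sample_id = c("hyper", "lowwes", "arty", "dupA", "dupB", "lonely",
                  paste0("ok", 1:25)),
    platform = c("WGS", "WES", "WGS", rep("WGS", 2), "WGS", rep("WGS", 25)),
    cancer_type = c(rep("lung", 5), "rare", rep("lung", 25)),
    patient_id = c("p1", "p2", "p3", "p4", "p4", "p5", paste0("q", 1:25)),
    purity = c(0.5, 0.5, 0.5, 0.9, 0.4, 0.5, rep(0.5, 25)),
    stringsAsFactors = FALSE
  )
  mk <- function(id, n, sig = "SBS1") {
    data.frame(sample_id = id, signature_label = sig,
               stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
  }
  muts <- rbind(
    mk("hyper", 90001), mk("lowwes", 19), mk("arty", 79),
    mk("arty", 21, "SBS45"), mk("dupA", 50), mk("dupB", 50), mk("lonely", 50),
    do.call(rbind, lapply(paste0("ok", 1:25), mk, n = 30))
  )
  out <- qc_filter(muts, md, cohort_config())
  rules <- setNames(out$exclusions$rule, out$exclusions$sample_id)
  expect_equal(unname(rules["hyper"]), "hypermutator")
  expect_equal(unname(rules["lowwes"]), "low_snv_count")
  expect_equal(unname(rules["arty"]), "artifact_signatures")
  expect_equal(unname(rules["dupB"]), "duplicate_patient") # lower purity
  expect_equal(unname(rules["lonely"]), "small_cancer_type")
  expect_false("dupA" %in% out$exclusions$sample_id)
  expect_setequal(out$metadata$sample_id, c("dupA", paste0("ok", 1:25)))
  # boundary cases: exactly at threshold is kept
  md2 <- md[md$sample_id %in% c("ok1", paste0("ok", 2:25), "dupA"), ]
  muts2 <- rbind(mk("dupA", 90000), do.call(rbind, lapply(
    paste0("ok", 1:25), mk, n = 30)))
  out2 <- qc_filter(muts2, md2, cohort_config())
  expect_false("dupA" %in% out2$exclusions$sample_id)
  expect_error(qc_filter(muts, md[, -5], cohort_config()),
               class = "sgmsig_format_error")
})

test_that("class_signature_test matches the hypergeometric oracle", {
  # a worked 2x2 plus a sweep of random small tables
  snv_tab <- function(a, b, c_, d) {
    rbind(fake_snvs("SIG", "stop_gain", a), fake_snvs("SIG", "missense", b),
          fake_snvs("OTH", "stop_gain", c_), fake_snvs("OTH", "missense", d))
  }
  r <- class_signature_test(snv_tab(8, 2, 2, 8), "SIG", "stop_gain",
                            cohort_config(), seed = 1)
  expect_equal(r$p, fisher_oracle_greater(8, 2, 2, 8), tolerance = 1e-12)
  expect_equal(r$observed, 8)
  withr_seed(99, {
    for (i in 1:40) {
      tb <- as.vector(stats::rmultinom(1, sample(10:60, 1), rep(0.25, 4)))
      if (tb[1] + tb[2] == 0 || tb[1] + tb[3] == 0) next
      r <- class_signature_test(snv_tab(tb[1], tb[2], tb[3], tb[4]),
                                "SIG", "stop_gain", cohort_config(), seed = 1)
      expect_equal(r$p, fisher_oracle_greater(tb[1], tb[2], tb[3], tb[4]),
                   tolerance = 1e-12,
                   info = paste(tb, collapse = ","))
    }
  })
  # extreme table: all class SNVs carry the signature, none of the rest do
  r2 <- class_signature_test(snv_tab(10, 0, 0, 30), "SIG", "stop_gain",
                             cohort_config(), seed = 1)
  expect_equal(r2$p, fisher_oracle_greater(10, 0, 0, 30), tolerance = 1e-12)
  expect_lt(r2$p, 1e-7)
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  withr_seed(5, {
    for (i in 1:20) {
      p <- runif(sample(3:40, 1))
      q <- p.adjust(p, method = "BH")
      expect_equal(q, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-12))
      expect_true(all(q <= 1))
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-12))
    }
  })
})

test_that("expected_count matches its analytic mean and covers it", {
  e <- expected_count(1000, 0.5, 0.2, iterations = 10000, seed = 1)
  sd_mean <- sqrt(1000 * 0.1 * 0.9) / sqrt(10000)
  expect_lt(abs(e$mean - 100), 3 * sqrt(1000 * 0.1 * 0.9)) # loose sanity
  expect_lt(abs(e$mean - 100), 5 * sd_mean + 1)
  expect_equal(expected_count(1000, 0.5, 0, seed = 1),
               list(mean = 0, ci = c(0, 0)))
  # CI covers the analytic mean in most independent reruns
  hits <- vapply(1:20, function(s) {
    e <- expected_count(500, 0.3, 0.2, iterations = 2000, seed = s)
    e$ci[1] <= 30 && 30 <= e$ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(expected_count(10, 1.5, 0.2, seed = 1),
               class = "sgmsig_input_error")
})

test_that("enrichment_analysis tests eligible pairs with per-family FDR", {
  snvs <- rbind(
    fake_snvs("SBSa", "stop_gain", 30), fake_snvs("SBSa", "missense", 120),
    fake_snvs("SBSb", "stop_gain", 10), fake_snvs("SBSb", "missense", 290),
    fake_snvs("SBSrare", "missense", 40),
    fake_snvs("unassigned", "missense", 50)
  )
  res <- enrichment_analysis(snvs, cohort_config(), seed = 1)
  # SBSrare has < 100 SNVs: not tested
  expect_false("SBSrare" %in% res$signature)
  expect_false("unassigned" %in% res$signature)
  expect_setequal(unique(res$signature), c("SBSa", "SBSb"))
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_equal(res$fdr, ave(res$p, res$cancer_type,
                            FUN = function(p) p.adjust(p, "BH")))
  # artifact signatures are never tested
  snvs2 <- rbind(snvs, fake_snvs("SBS45", "missense", 200))
  res2 <- enrichment_analysis(snvs2, cohort_config(), seed = 1)
  expect_false("SBS45" %in% res2$signature)
})

test_that("amino_acid_test flags the targeted residue in an extreme cohort", {
  sgms <- rbind(fake_snvs("SIG", "stop_gain", 20), fake_snvs("OTH", "stop_gain", 20))
  sgms$ref_aa <- c(rep("S", 20), rep("E", 20)) # SIG hits only serines
  res <- amino_acid_test(sgms, "SIG")
  rs <- res[res$ref_aa == "S", ]
  expect_equal(rs$p, fisher_oracle_greater(20, 0, 0, 20), tolerance = 1e-12)
  expect_true(res[res$ref_aa == "E", "p"] > 0.5)
  expect_true(all(res$fdr >= res$p - 1e-12))
})

test_that("amino-acid enrichment is null-calibrated under label shuffling", {
  withr_seed(21, {
    hits <- vapply(1:40, function(i) {
      n <- 120
      sgms <- fake_snvs("SIG", "stop_gain", n)
      sgms$signature_label <- sample(c("SIG", "OTH"), n, replace = TRUE)
      sgms$ref_aa <- sample(c("S", "E", "G", "Q", "R"), n, replace = TRUE)
      res <- amino_acid_test(sgms, "SIG")
      any(res$fdr < 0.01)
    }, logical(1))
    expect_lte(mean(hits), 0.05)
  })
})

test_that("probabilistic replication is exact for degenerate exposures", {
  m <- tiny_model()
  catalog <- synthetic_catalog()
  cfg <- sim_config(seed = 31, n_genes = 20, n_samples = 8,
                    mean_gene_codons = 100, burden_meanlog = log(60),
                    exposure_prior = c(SBS4like = 1, SBS13like = 1e-9,
                                       SBS18like = 1e-9, SBSflat = 1e-9))
  model <- simulate_coding_model(cfg)
  cohort <- simulate_cohort(model, catalog, cfg)
  ann <- annotate_snvs(cohort$mutations, model)
  # degenerate exposure matrix: everything on one signature
  expo <- matrix(0, cfg$n_samples, 4,
                 dimnames = list(sort(unique(ann$sample_id)),
                                 colnames(catalog)))
  expo[, "SBS4like"] <- 1
  cc <- cohort_config(min_signature_snvs = 10, probabilistic_iterations = 5)
  rep_tab <- probabilistic_replication(ann, expo, catalog, cc, seed = 1)
  expect_equal(length(unique(rep_tab$iteration)), 5L)
  expect_true(all(rep_tab$signature == "SBS4like"))
  # identical across iterations (only one signature can ever be drawn)
  expect_equal(length(unique(rep_tab$p)), 1L)
  ann$signature_label <- "SBS4like"
  top <- class_signature_test(ann, "SBS4like", "stop_gain", cc, seed = 2)
  expect_equal(unique(rep_tab$p), top$p)
})

test_that("pan-cancer pooling equals the single-family analysis on pooled counts", {
  a <- rbind(fake_snvs("SBSa", "stop_gain", 20, cancer_type = "lung"),
             fake_snvs("SBSa", "missense", 100, cancer_type = "lung"),
             fake_snvs("SBSb", "missense", 130, cancer_type = "lung"))
  b <- rbind(fake_snvs("SBSa", "stop_gain", 15, cancer_type = "breast"),
             fake_snvs("SBSa", "missense", 105, cancer_type = "breast"),
             fake_snvs("SBSb", "missense", 130, cancer_type = "breast"))
  pooled <- pan_cancer(rbind(a, b), cohort_config(), seed = 1)
  expect_equal(unique(pooled$cancer_type), "pan-cancer")
  row <- pooled[pooled$signature == "SBSa" & pooled$class == "stop_gain", ]
  expect_equal(row$observed, 35)
  expect_equal(row$n_total, nrow(a) + nrow(b))
  # pooling a single cohort reproduces that cohort's analysis
  single <- enrichment_analysis(a, cohort_config(), seed = 1)
  pan_single <- pan_cancer(a, cohort_config(), seed = 1)
  expect_equal(single$p, pan_single$p)
  expect_equal(single$observed, pan_single$observed)
})
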