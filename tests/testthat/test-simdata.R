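test_that("simulated coding models are valid ORF collections and reproducible", {
  cfg <- sim_config(seed = 11, n_genes = 15, mean_gene_codons = 90)
  m <- simulate_coding_model(cfg)
  expect_equal(length(m$genes), 15L)
  for (g in m$genes) {
    codons <- substring(g$cds, seq(1, nchar(g$cds), 3), seq(3, nchar(g$cds), 3))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    expect_equal(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(aa[-length(aa)] == "*"))
    expect_gte(length(codons), 30L)
  }
  expect_true(any(vapply(m$genes, function(g) g$strand == "-", logical(1))))
  expect_true(any(vapply(m$genes, function(g) length(g$starts) > 1, logical(1))))
  # byte-identical reproducibility
  m2 <- simulate_coding_model(cfg)
  expect_identical(m$genome, m2$genome)
  expect_identical(m$gene_table, m2$gene_table)
  m3 <- simulate_coding_model(sim_config(seed = 12, n_genes = 15))
  expect_false(identical(m$genome, m3$genome))
})

test_that("simulated cohorts follow the configured exposures and contexts", {
  catalog <- synthetic_catalog()
  cfg <- sim_config(seed = 21, n_genes = 25, n_samples = 4,
                    mean_gene_codons = 150, burden_meanlog = log(2500),
                    burden_sdlog = 0.05)
  model <- simulate_coding_model(cfg)
  cohort <- simulate_cohort(model, catalog, cfg)
  muts <- cohort$mutations
  # reference alleles match the genome; channels match the drawn contexts
  expect_true(all(substring(model$genome[muts$chrom], muts$pos, muts$pos) ==
                  muts$ref))
  expect_false(any(duplicated(paste(muts$sample_id, muts$chrom, muts$pos))))
  # per-sample spectrum approximates the exposure-weighted profile mixture
  ann <- annotate_snvs(muts, model)
  for (s in rownames(cohort$exposures)[1:2]) {
    emp <- spectrum(ann$channel[ann$sample_id == s])
    mix <- as.vector(unclass(catalog) %*% cohort$exposures[s, ])
    expect_gt(cosine_similarity(emp, mix), 0.95)
  }
  # reproducibility
  cohort2 <- simulate_cohort(model, catalog, cfg)
  expect_identical(cohort$mutations, cohort2$mutations)
})

test_that("a single-signature prior labels every mutation with that signature", {
  catalog <- synthetic_catalog()
  cfg <- sim_config(seed = 22, n_genes = 10, n_samples = 3,
                    mean_gene_codons = 100,
                    exposure_prior = c(SBS4like = 1, SBS13like = 1e-12,
                                       SBS18like = 1e-12, SBSflat = 1e-12))
  model <- simulate_coding_model(cfg)
  cohort <- simulate_cohort(model, catalog, cfg)
  expect_true(all(cohort$mutations$true_signature == "SBS4like"))
})

test_that("an APOBEC-like cohort truncates more serines and glutamates than a flat one", {
  cfg0 <- sim_config(seed = 23, n_genes = 40, n_samples = 25,
                     mean_gene_codons = 150, burden_meanlog = log(200))
  model <- simulate_coding_model(cfg0)
  catalog <- synthetic_catalog()
  run <- function(prior_sig) {
    prior <- setNames(rep(1e-12, 4), colnames(catalog))
    prior[prior_sig] <- 1
    cfg <- sim_config(seed = 24, n_genes = 40, n_samples = 25,
                      mean_gene_codons = 150, burden_meanlog = log(200),
                      exposure_prior = prior)
    ann <- annotate_snvs(simulate_cohort(model, catalog, cfg)$mutations, model)
    sgm <- ann[ann$functional_class == "stop_gain", ]
    mean(sgm$ref_aa %in% c("S", "E"))
  }
  expect_gt(run("SBS13like"), run("SBSflat"))
  # and the direction agrees with the genetic-code propensity oracle
  d13 <- signature_stop_distribution(catalog[, "SBS13like"], model)
  dfl <- signature_stop_distribution(catalog[, "SBSflat"], model)
  expect_gt(d13[["S"]] + d13[["E"]], dfl[["S"]] + dfl[["E"]])
})

test_that("driver spiking adds the requested stop-gain mutations", {
  catalog <- synthetic_catalog()
  cfg <- sim_config(seed = 25, n_genes = 20, n_samples = 30,
                    mean_gene_codons = 120, burden_meanlog = log(50))
  model <- simulate_coding_model(cfg)
  cohort <- simulate_cohort(model, catalog, cfg)
  n0 <- nrow(cohort$mutations)
  spiked <- spike_driver_sgms(cohort, model, catalog, "gene005", "SBS13like",
                              n_sgms = 12, seed = 7)
  expect_equal(nrow(spiked$mutations), n0 + 12)
  add <- spiked$mutations[spiked$mutations$spiked, ]
  expect_equal(nrow(add), 12)
  expect_equal(length(unique(add$sample_id)), 12) # distinct samples
  ann <- annotate_snvs(add, model)
  expect_true(all(ann$functional_class == "stop_gain"))
  expect_true(all(ann$gene_id == "gene005"))
  # channels compatible with the signature
  expect_true(all(catalog[ann$channel, "SBS13like"] > 0))
  expect_error(spike_driver_sgms(cohort, model, catalog, "gene005",
                                 "SBS13like", n_sgms = 31, seed = 7),
               class = "sgmsig_input_error")
})

test_that("simulated covariates honor their configuration", {
  catalog <- synthetic_catalog()
  cfg <- sim_config(seed = 26, n_genes = 12, n_samples = 20,
                    mean_gene_codons = 80, burden_meanlog = log(40),
                    wgd_fraction = 0, loss_rate = 0)
  model <- simulate_coding_model(cfg)
  cohort <- simulate_cohort(model, catalog, cfg)
  cov <- simulate_covariates(cohort, model, cfg)
  for (s in unique(cov$cn_segments$sample_id)) {
    expect_false(detect_wgd(cov$cn_segments[cov$cn_segments$sample_id == s, ]))
  }
  expect_true(all(cov$cn_segments$cn == 2))
  expect_false(any(cov$wgd))
  expect_equal(dim(cov$expression), c(20L, 12L))
  expect_setequal(unique(cov$clinical$smoking_category),
                  intersect(c("current", "reformed_recent", "reformed_long",
                              "never"), cov$clinical$smoking_category))
  # wgd fraction 1: all samples called WGD
  cfg2 <- sim_config(seed = 26, n_genes = 12, n_samples = 20,
                     mean_gene_codons = 80, burden_meanlog = log(40),
                     wgd_fraction = 1, loss_rate = 0.3)
  cov2 <- simulate_covariates(cohort, model, cfg2)
  for (s in unique(cov2$cn_segments$sample_id)[1:5]) {
    expect_true(detect_wgd(cov2$cn_segments[cov2$cn_segments$sample_id == s, ]))
  }
  # expression link raises the linked gene's expression with SGM burden
  ann <- annotate_snvs(cohort$mutations, model)
  cfg3 <- sim_config(seed = 26, n_genes = 12, n_samples = 20,
                     mean_gene_codons = 80, burden_meanlog = log(40),
                     expr_link_gene = "gene001", expr_link_coef = 2,
                     expr_link_signature = "SBS13like")
  cov3 <- simulate_covariates(list(mutations = ann), model, cfg3)
  burden <- vapply(rownames(cov3$expression), function(s) {
    sum(ann$sample_id == s & ann$true_signature == "SBS13like" &
        ann$functional_class == "stop_gain")
  }, numeric(1))
  if (stats::sd(burden) > 0) {
    expect_gt(cor(burden, log(cov3$expression[, "gene001"]),
                  method = "spearman"), 0)
  }
})
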