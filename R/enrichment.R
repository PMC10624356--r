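#' Cohort QC and enrichment configuration
#'
#' Defaults follow the thresholds used throughout the analysis: hypermutator
#' cutoffs of 90,000 SNVs (WGS) and 1,800 SNVs (WES, ~30 SNVs/Mbp), removal
#' of WES samples with fewer than 20 SNVs, removal of samples with more than
#' 20% of SNVs assigned to sequencing-artifact signatures, at least 25
#' samples per consolidated cancer type, at least 100 SNVs per tested
#' signature, FDR threshold 0.01, 10,000 binomial iterations for expected
#' counts, and 100 probabilistic assignment iterations.
#'
#' @param hypermutator_wgs,hypermutator_wes Per-sample SNV counts above
#'   which a sample is removed as hypermutated.
#' @param min_snvs_wes Minimum SNV count for WES samples.
#' @param artifact_fraction Maximum tolerated fraction of SNVs assigned to
#'   artifact signatures.
#' @param artifact_signatures Labels treated as sequencing artifacts.
#' @param min_samples_per_type Minimum samples per cancer type.
#' @param min_signature_snvs Minimum SNVs for a signature to be tested.
#' @param fdr_threshold Significance cutoff on BH-adjusted p values.
#' @param binomial_iterations Iterations for [expected_count()].
#' @param probabilistic_iterations Iterations for
#'   [probabilistic_replication()].
#' @param fdr_across_types If `TRUE`, the BH family spans cancer types
#'   within a cohort; default is one family per cohort x cancer type.
#' @param gene_test_conditioning `"sgm"` (default) or `"all_mutations"`; see
#'   [gene_test()].
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(hypermutator_wgs = 90000,
                          hypermutator_wes = 1800,
                          min_snvs_wes = 20,
                          artifact_fraction = 0.20,
                          artifact_signatures = c("SBS27", "SBS43",
                                                  paste0("SBS", 45:60)),
                          min_samples_per_type = 25,
                          min_signature_snvs = 100,
                          fdr_threshold = 0.01,
                          binomial_iterations = 10000,
                          probabilistic_iterations = 100,
                          fdr_across_types = FALSE,
                          gene_test_conditioning = c("sgm", "all_mutations")) {
  cfg <- list(
    hypermutator_wgs = hypermutator_wgs, hypermutator_wes = hypermutator_wes,
    min_snvs_wes = min_snvs_wes, artifact_fraction = artifact_fraction,
    artifact_signatures = artifact_signatures,
    min_samples_per_type = min_samples_per_type,
    min_signature_snvs = min_signature_snvs, fdr_threshold = fdr_threshold,
    binomial_iterations = binomial_iterations,
    probabilistic_iterations = probabilistic_iterations,
    fdr_across_types = fdr_across_types,
    gene_test_conditioning = match.arg(gene_test_conditioning)
  )
  num <- cfg[!vapply(cfg, is.character, logical(1)) &
             !vapply(cfg, is.logical, logical(1))]
  if (any(unlist(num) <= 0)) stop_input("config thresholds must be positive")
  structure(cfg, class = "cohort_config")
}

#' Cohort quality-control filter
#'
#' Applies, in order: removal of hypermutated samples (platform-specific
#' thresholds), removal of low-count WES samples, removal of samples with an
#' excess of artifact-signature SNVs (only when a `signature_label` column
#' is present), per-patient deduplication keeping the highest-purity sample,
#' and removal of cancer types left with fewer than the minimum number of
#' samples.
#'
#' @param mutations SNV data frame with `sample_id` (and `signature_label`
#'   for the artifact rule).
#' @param metadata Per-sample data frame with `sample_id`, `platform`
#'   (`WGS`/`WES`), `cancer_type`, `patient_id`, `purity`.
#' @param config A [cohort_config()].
#' @return List with `mutations`, `metadata` (filtered) and `exclusions`
#'   (data frame of `sample_id`, `rule`).
#' @export
qc_filter <- function(mutations, metadata, config = cohort_config()) {
  need <- c("sample_id", "platform", "cancer_type", "patient_id", "purity")
  if (!all(need %in% names(metadata))) {
    stop_format(sprintf("metadata must have columns: %s",
                        paste(need, collapse = ", ")))
  }
  excl <- data.frame(sample_id = character(0), rule = character(0),
                     stringsAsFactors = FALSE)
  drop <- function(ids, rule) {
    if (length(ids) == 0L) return()
    excl <<- rbind(excl, data.frame(sample_id = ids, rule = rule,
                                    stringsAsFactors = FALSE))
    metadata <<- metadata[!metadata$sample_id %in% ids, , drop = FALSE]
    mutations <<- mutations[!mutations$sample_id %in% ids, , drop = FALSE]
  }
  counts <- table(mutations$sample_id)
  n_snv <- function(ids) {
    out <- as.integer(counts[ids]); out[is.na(out)] <- 0L; out
  }
  # 1. hypermutators
  thr <- ifelse(metadata$platform == "WGS", config$hypermutator_wgs,
                config$hypermutator_wes)
  drop(metadata$sample_id[n_snv(metadata$sample_id) > thr], "hypermutator")
  # 2. low-confidence WES samples
  low <- metadata$platform == "WES" &
    n_snv(metadata$sample_id) < config$min_snvs_wes
  drop(metadata$sample_id[low], "low_snv_count")
  # 3. artifact-contaminated samples
  if ("signature_label" %in% names(mutations) && nrow(mutations) > 0) {
    art <- tapply(mutations$signature_label %in% config$artifact_signatures,
                  mutations$sample_id, mean)
    bad <- names(art)[art > config$artifact_fraction]
    drop(intersect(bad, metadata$sample_id), "artifact_signatures")
  }
  # 4. per-patient deduplication by maximum purity (ties: first sample id)
  md <- metadata[order(metadata$patient_id, -metadata$purity,
                       metadata$sample_id), , drop = FALSE]
  dup <- md$sample_id[duplicated(md$patient_id)]
  drop(dup, "duplicate_patient")
  # 5. cancer-type consolidation
  tab <- table(metadata$cancer_type)
  small <- names(tab)[tab < config$min_samples_per_type]
  drop(metadata$sample_id[metadata$cancer_type %in% small], "small_cancer_type")
  list(mutations = mutations, metadata = metadata, exclusions = excl)
}

#' Fold change of observed over expected counts
#'
#' @param observed Observed count.
#' @param expected Expected count (mean under independence); must be > 0.
#' @return `observed / expected`.
#' @export
fold_change <- function(observed, expected) {
  if (any(expected <= 0)) stop_input("expected count must be positive")
  observed / expected
}

#' Expected co-occurrence count by binomial sampling
#'
#' Under independence of signature and class, the number of SNVs carrying
#' both is Binomial(n, p_signature * p_class); the mean and a 95% interval
#' are estimated by Monte Carlo sampling.
#'
#' @param n_total Total number of SNVs.
#' @param p_signature,p_class Marginal probabilities in `[0, 1]`.
#' @param iterations Number of binomial draws (default 10,000).
#' @param seed Integer seed.
#' @return List with `mean` and `ci` (2.5 and 97.5 percentiles).
#' @export
expected_count <- function(n_total, p_signature, p_class,
                           iterations = 10000, seed = 1) {
  if (p_signature < 0 || p_signature > 1 || p_class < 0 || p_class > 1) {
    stop_input("probabilities must be in [0, 1]")
  }
  if (iterations < 1) stop_input("iterations must be >= 1")
  draws <- with_seed(seed, stats::rbinom(iterations, n_total,
                                         p_signature * p_class))
  list(mean = mean(draws),
       ci = unname(stats::quantile(draws, c(0.025, 0.975))))
}

# One-tailed (greater) Fisher's exact p for a 2x2 table given as a,b,c,d.
fisher_greater <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), 2, 2),
                     alternative = "greater")$p.value
}

exonic <- function(snvs) {
  snvs[snvs$functional_class != "noncoding" & !is.na(snvs$channel), ,
       drop = FALSE]
}

#' Test enrichment of a functional class in a signature
#'
#' One-tailed Fisher's exact test on the 2x2 table of exonic SNVs
#' {assigned to `signature` vs other signatures} x {of functional `class` vs
#' other classes}, with binomially sampled expected counts and fold change.
#' Unassigned SNVs are excluded from the table.
#'
#' @param snvs Annotated, signature-labeled SNV data frame.
#' @param signature Signature label to test.
#' @param class Functional class (e.g. `"stop_gain"`).
#' @param config A [cohort_config()].
#' @param seed Seed for the binomial expected-count sampling.
#' @return One-row data frame: `signature`, `class`, `n_total`, `observed`,
#'   `expected_mean`, `expected_lo`, `expected_hi`, `fold_change`, `p`.
#' @export
class_signature_test <- function(snvs, signature, class,
                                 config = cohort_config(), seed = 1) {
  x <- exonic(snvs)
  x <- x[x$signature_label != "unassigned", , drop = FALSE]
  is_sig <- x$signature_label == signature
  is_cls <- x$functional_class == class
  a <- sum(is_sig & is_cls); b <- sum(is_sig & !is_cls)
  c_ <- sum(!is_sig & is_cls); d <- sum(!is_sig & !is_cls)
  n <- a + b + c_ + d
  p_sig <- (a + b) / n
  p_cls <- (a + c_) / n
  exp_ <- expected_count(n, p_sig, p_cls, config$binomial_iterations, seed)
  data.frame(
    signature = signature, class = class, n_total = n, observed = a,
    expected_mean = exp_$mean, expected_lo = exp_$ci[1],
    expected_hi = exp_$ci[2],
    fold_change = if (exp_$mean > 0) a / exp_$mean else NA_real_,
    p = fisher_greater(a, b, c_, d),
    stringsAsFactors = FALSE
  )
}

#' Signature-by-class enrichment analysis of a cohort
#'
#' Runs [class_signature_test()] for every eligible signature x functional
#' class pair, separately per cancer type. A signature is eligible when it
#' has at least `min_signature_snvs` exonic SNVs in the cancer type, is not
#' an artifact signature, and has at least one SNV of the tested class.
#' Related signature labels are merged first (see [merge_labels()]). BH FDR
#' is computed within each cohort x cancer-type family (or across types
#' when `config$fdr_across_types`).
#'
#' @param snvs Annotated, labeled SNV data frame; a `cancer_type` column
#'   splits the analysis (absent: one family `"all"`).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Data frame of enrichment results with `cancer_type` and `fdr`
#'   columns, plus a `"skipped"` attribute logging ineligible tests.
#' @export
enrichment_analysis <- function(snvs, config = cohort_config(), seed = 1) {
  if (!"cancer_type" %in% names(snvs)) snvs$cancer_type <- "all"
  snvs$signature_label <- merge_labels(snvs$signature_label)
  x <- exonic(snvs)
  res <- list(); skipped <- list()
  for (ct in sort(unique(x$cancer_type))) {
    xc <- x[x$cancer_type == ct, , drop = FALSE]
    labeled <- xc[xc$signature_label != "unassigned", , drop = FALSE]
    sig_counts <- table(labeled$signature_label)
    sigs <- setdiff(names(sig_counts)[sig_counts >= config$min_signature_snvs],
                    config$artifact_signatures)
    classes <- intersect(c("missense", "silent", "stop_gain", "stop_loss",
                           "start_loss"), unique(xc$functional_class))
    for (sg in sort(sigs)) {
      for (cl in classes) {
        n_in_class <- sum(labeled$signature_label == sg &
                          labeled$functional_class == cl)
        if (n_in_class < 1) {
          skipped[[length(skipped) + 1L]] <- data.frame(
            cancer_type = ct, signature = sg, class = cl,
            reason = "no SNV of class in signature", stringsAsFactors = FALSE)
          next
        }
        r <- class_signature_test(xc, sg, cl, config, seed)
        r <- cbind(cancer_type = ct, r, stringsAsFactors = FALSE)
        res[[length(res) + 1L]] <- r
      }
    }
  }
  if (length(res) == 0L) {
    out <- data.frame(cancer_type = character(0), signature = character(0),
                      class = character(0), n_total = integer(0),
                      observed = integer(0), expected_mean = numeric(0),
                      expected_lo = numeric(0), expected_hi = numeric(0),
                      fold_change = numeric(0), p = numeric(0),
                      fdr = numeric(0))
  } else {
    out <- do.call(rbind, res)
    if (config$fdr_across_types) {
      out$fdr <- stats::p.adjust(out$p, method = "BH")
    } else {
      out$fdr <- stats::ave(out$p, out$cancer_type,
                            FUN = function(p) stats::p.adjust(p, method = "BH"))
    }
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Amino-acid enrichment among signature-associated stop-gain mutations
#'
#' Among stop-gain SNVs, tests for each reference amino acid whether it
#' co-occurs with `signature` more often than with other signatures
#' (one-tailed Fisher), with BH FDR across amino acids.
#'
#' @param sgms Data frame of stop-gain annotated SNVs (needs `ref_aa`,
#'   `signature_label`).
#' @param signature Signature label to test.
#' @param config A [cohort_config()].
#' @param seed Seed for expected-count sampling.
#' @return Data frame: one row per amino acid, with observed/expected
#'   fractions, fold change, `p` and `fdr`.
#' @export
amino_acid_test <- function(sgms, signature, config = cohort_config(),
                            seed = 1) {
  x <- sgms[sgms$functional_class == "stop_gain" &
            sgms$signature_label != "unassigned", , drop = FALSE]
  if (sum(x$signature_label == signature) < 1) {
    stop_input("no stop-gain SNV carries the tested signature")
  }
  is_sig <- x$signature_label == signature
  res <- lapply(sort(unique(x$ref_aa)), function(aa) {
    is_aa <- x$ref_aa == aa
    a <- sum(is_sig & is_aa); b <- sum(is_sig & !is_aa)
    c_ <- sum(!is_sig & is_aa); d <- sum(!is_sig & !is_aa)
    frac_sig <- a / (a + b)
    frac_other <- if (c_ + d > 0) c_ / (c_ + d) else NA_real_
    data.frame(
      signature = signature, ref_aa = aa, observed = a,
      frac_signature = frac_sig, frac_other = frac_other,
      fold_change = if (is.na(frac_other)) NA_real_
        else if (frac_other > 0) frac_sig / frac_other
        else if (frac_sig > 0) Inf else NA_real_,
      p = fisher_greater(a, b, c_, d), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Probabilistic replication of the stop-gain enrichment analysis
#'
#' Redraws per-SNV signature assignments from the per-sample posterior
#' (multinomial over exposure-weighted profile probabilities) over
#' `config$probabilistic_iterations` iterations, rerunning the stop-gain
#' signature tests each time with BH adjustment within the iteration.
#' Iteration `i` uses seed `seed + i`.
#'
#' @param snvs Annotated SNV data frame (needs `sample_id`, `channel`,
#'   `functional_class`).
#' @param exposures Samples x signatures exposure matrix (e.g. from
#'   [assign_cohort()]).
#' @param catalog An `sbs_catalog`.
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @return Data frame with one row per iteration x tested signature:
#'   `iteration`, `signature`, `observed`, `fold_change`, `p`, `fdr`,
#'   `significant` (FDR < 0.05).
#' @export
probabilistic_replication <- function(snvs, exposures, catalog,
                                      config = cohort_config(), seed = 1) {
  samples <- rownames(exposures)
  sample_idx <- split(seq_len(nrow(snvs)), snvs$sample_id)
  res <- list()
  for (i in seq_len(config$probabilistic_iterations)) {
    lab <- rep("unassigned", nrow(snvs))
    for (s in samples) {
      idx <- sample_idx[[s]]
      if (is.null(idx)) next
      lab[idx] <- sample_assignments(snvs$channel[idx], exposures[s, ],
                                     catalog, seed = seed + i)
    }
    it <- snvs
    it$signature_label <- merge_labels(lab)
    x <- exonic(it)
    labeled <- x[x$signature_label != "unassigned", , drop = FALSE]
    sig_counts <- table(labeled$signature_label)
    sigs <- setdiff(names(sig_counts)[sig_counts >= config$min_signature_snvs],
                    config$artifact_signatures)
    rows <- list()
    for (sg in sort(sigs)) {
      obs <- sum(labeled$signature_label == sg &
                 labeled$functional_class == "stop_gain")
      if (obs < 1) next
      r <- class_signature_test(x, sg, "stop_gain", config, seed = seed + i)
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = i, signature = sg, observed = r$observed,
        fold_change = r$fold_change, p = r$p, stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) next
    tab <- do.call(rbind, rows)
    tab$fdr <- stats::p.adjust(tab$p, method = "BH")
    tab$significant <- tab$fdr < 0.05
    res[[length(res) + 1L]] <- tab
  }
  if (length(res) == 0L) {
    return(data.frame(iteration = integer(0), signature = character(0),
                      observed = integer(0), fold_change = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  }
  do.call(rbind, res)
}

#' Pan-cancer enrichment analysis
#'
#' Pools eligible samples across cancer types within a dataset and reruns
#' the signature-by-class enrichment with a single pooled FDR family.
#'
#' @param snvs Annotated, labeled SNV data frame (its `cancer_type` column,
#'   if any, is collapsed).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Enrichment result data frame with `cancer_type = "pan-cancer"`.
#' @export
pan_cancer <- function(snvs, config = cohort_config(), seed = 1) {
  snvs$cancer_type <- "pan-cancer"
  enrichment_analysis(snvs, config, seed)
}
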