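write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(outdir, subcommand, seed, config, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    config = config[!vapply(config, is.null, logical(1))],
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(outdir, paste0("manifest_",
                                                          subcommand, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the analysis pipeline
#'
#' Config-driven orchestration of the full workflow on an output directory
#' with fixed file names. Subcommands: `simulate` writes a synthetic genome
#' (FASTA), gene model, catalog, mutation, ground-truth and covariate
#' tables; `annotate` adds functional annotations to the mutation table;
#' `assign` fits per-sample exposures and labels each SNV with its top
#' signature; `enrich` runs the signature-by-class enrichment (plus the
#' pan-cancer pooling); `genes` runs the gene-level stop-gain analysis for
#' the most stop-gain-enriched signature; `associations` runs the
#' copy-number co-occurrence and motif analyses; `report` writes summary
#' tables (class composition, per-signature stop-gain counts and amino-acid
#' proportions). `all` runs everything in order. Every subcommand writes a
#' manifest recording the seed, the configuration and md5 sums of its
#' outputs, so reruns are verifiably identical.
#'
#' @param subcommand One of `simulate`, `annotate`, `assign`, `enrich`,
#'   `genes`, `associations`, `report`, `all`.
#' @param outdir Output (and input) directory.
#' @param sim A [sim_config()] (required by `simulate`).
#' @param config A [cohort_config()].
#' @param seed Master integer seed used by the stochastic stages.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(subcommand = c("all", "simulate", "annotate",
                                        "assign", "enrich", "genes",
                                        "associations", "report"),
                         outdir, sim = NULL, config = cohort_config(),
                         seed = 1) {
  subcommand <- match.arg(subcommand)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pf <- function(name) file.path(outdir, name)
  need <- function(name) {
    if (!file.exists(pf(name))) {
      stop_input(sprintf("missing input '%s' in %s; run the earlier stage first",
                         name, outdir))
    }
    pf(name)
  }
  steps <- if (subcommand == "all") {
    c("simulate", "annotate", "assign", "enrich", "genes", "associations",
      "report")
  } else {
    subcommand
  }
  for (step in steps) {
    switch(step,
      simulate = {
        if (is.null(sim)) stop_input("simulate requires a sim_config")
        model <- simulate_coding_model(sim)
        catalog <- synthetic_catalog()
        cohort <- simulate_cohort(model, catalog, sim)
        cov <- simulate_covariates(cohort, model, sim)
        Biostrings::writeXStringSet(
          Biostrings::DNAStringSet(model$genome), pf("genome.fa"))
        write_tsv(model$gene_table, pf("gene_model.tsv"))
        write_catalog(catalog, pf("catalog.tsv"))
        write_tsv(cohort$mutations, pf("mutations.tsv"))
        write_tsv(data.frame(sample_id = rownames(cohort$exposures),
                             cohort$exposures, check.names = FALSE),
                  pf("true_exposures.tsv"))
        write_tsv(cov$cn_segments, pf("cn_segments.tsv"))
        write_tsv(data.frame(sample_id = rownames(cov$expression),
                             cov$expression, check.names = FALSE),
                  pf("expression.tsv"))
        write_tsv(cov$clinical, pf("clinical.tsv"))
        write_manifest(outdir, "simulate", sim$seed, unclass(sim),
                       pf(c("genome.fa", "gene_model.tsv", "catalog.tsv",
                            "mutations.tsv", "true_exposures.tsv",
                            "cn_segments.tsv", "expression.tsv",
                            "clinical.tsv")))
      },
      annotate = {
        model <- build_coding_model(need("genome.fa"), need("gene_model.tsv"))
        muts <- read_maf(need("mutations.tsv"))
        ann <- annotate_snvs(muts, model)
        write_tsv(ann, pf("annotated.tsv"))
        write_manifest(outdir, "annotate", seed, list(), pf("annotated.tsv"))
      },
      assign = {
        ann <- utils::read.delim(need("annotated.tsv"), stringsAsFactors = FALSE)
        catalog <- read_catalog(need("catalog.tsv"))
        fit <- assign_cohort(ann, catalog)
        write_tsv(fit$snvs, pf("labeled.tsv"))
        write_tsv(data.frame(sample_id = rownames(fit$exposures),
                             fit$exposures, check.names = FALSE),
                  pf("fitted_exposures.tsv"))
        write_manifest(outdir, "assign", seed, list(),
                       pf(c("labeled.tsv", "fitted_exposures.tsv")))
      },
      enrich = {
        lab <- utils::read.delim(need("labeled.tsv"), stringsAsFactors = FALSE)
        if (!"signature_label" %in% names(lab)) {
          stop_input("labeled.tsv lacks a signature_label column; run assign first")
        }
        enr <- enrichment_analysis(lab, config, seed)
        write_tsv(enr, pf("enrichment.tsv"))
        pan <- pan_cancer(lab, config, seed)
        write_tsv(pan, pf("enrichment_pan_cancer.tsv"))
        write_manifest(outdir, "enrich", seed, unclass(config),
                       pf(c("enrichment.tsv", "enrichment_pan_cancer.tsv")))
      },
      genes = {
        lab <- utils::read.delim(need("labeled.tsv"), stringsAsFactors = FALSE)
        enr <- utils::read.delim(need("enrichment.tsv"), stringsAsFactors = FALSE)
        sgm <- enr[enr$class == "stop_gain", , drop = FALSE]
        if (nrow(sgm) == 0L) {
          write_tsv(data.frame(), pf("gene_enrichment.tsv"))
        } else {
          top_sig <- sgm$signature[which.min(sgm$p)]
          ge <- gene_enrichment(list(cohort = lab), top_sig,
                                conditioning = config$gene_test_conditioning)
          write_tsv(ge, pf("gene_enrichment.tsv"))
        }
        write_manifest(outdir, "genes", seed, list(), pf("gene_enrichment.tsv"))
      },
      associations = {
        lab <- utils::read.delim(need("labeled.tsv"), stringsAsFactors = FALSE)
        segs <- utils::read.delim(need("cn_segments.tsv"),
                                  stringsAsFactors = FALSE)
        model <- build_coding_model(need("genome.fa"), need("gene_model.tsv"))
        ge_path <- pf("gene_enrichment.tsv")
        genes <- if (file.exists(ge_path)) {
          ge <- utils::read.delim(ge_path, stringsAsFactors = FALSE)
          if (nrow(ge)) utils::head(ge$gene_id[ge$fdr < 0.05], 10) else character(0)
        } else character(0)
        rows <- list()
        for (g in genes) {
          grec <- model$genes[[g]]
          sgm_samples <- unique(lab$sample_id[
            !is.na(lab$gene_id) & lab$gene_id == g &
              lab$functional_class == "stop_gain"])
          loss_samples <- character(0)
          for (s in unique(segs$sample_id)) {
            ss <- segs[segs$sample_id == s, , drop = FALSE]
            cn <- gene_cn(ss, grec$chrom, min(grec$starts), max(grec$ends))
            if (gene_loss(cn, "WGS", detect_wgd(ss), grec$chrom)) {
              loss_samples <- c(loss_samples, s)
            }
          }
          co <- cooccurrence(sgm_samples, loss_samples)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, sgm_samples = co$n, with_loss = co$k,
            fraction = co$fraction, stringsAsFactors = FALSE)
        }
        write_tsv(if (length(rows)) do.call(rbind, rows) else data.frame(),
                  pf("cn_cooccurrence.tsv"))
        sbs13 <- lab[lab$signature_label == "SBS13like" & !is.na(lab$channel), ]
        if (nrow(sbs13) > 0 && any(sbs13$functional_class == "stop_gain") &&
            any(sbs13$functional_class != "stop_gain")) {
          mt <- motif_test(sbs13$motif_class[sbs13$functional_class == "stop_gain"],
                           sbs13$motif_class[sbs13$functional_class != "stop_gain"])
          write_tsv(mt, pf("motif_tests.tsv"))
        }
        write_manifest(outdir, "associations", seed, list(),
                       pf(c("cn_cooccurrence.tsv", "motif_tests.tsv")))
      },
      report = {
        lab <- utils::read.delim(need("labeled.tsv"), stringsAsFactors = FALSE)
        cls <- as.data.frame(table(lab$functional_class),
                             stringsAsFactors = FALSE)
        names(cls) <- c("functional_class", "n")
        cls$fraction <- cls$n / sum(cls$n)
        write_tsv(cls, pf("report_class_composition.tsv"))
        sgm <- lab[lab$functional_class == "stop_gain" &
                   lab$signature_label != "unassigned", , drop = FALSE]
        bysig <- as.data.frame(table(sgm$signature_label),
                               stringsAsFactors = FALSE)
        names(bysig) <- c("signature", "n_sgms")
        write_tsv(bysig, pf("report_sgm_by_signature.tsv"))
        if (nrow(sgm) > 0) {
          aa <- as.data.frame(prop.table(table(sgm$signature_label, sgm$ref_aa),
                                         margin = 1))
          names(aa) <- c("signature", "ref_aa", "proportion")
          write_tsv(aa, pf("report_sgm_amino_acids.tsv"))
        }
        write_manifest(outdir, "report", seed, list(),
                       pf(c("report_class_composition.tsv",
                            "report_sgm_by_signature.tsv",
                            "report_sgm_amino_acids.tsv")))
      }
    )
  }
  invisible(outdir)
}
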