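#' Gene-level enrichment of signature-associated stop-gain mutations
#'
#' Tests whether a gene's stop-gain mutations (SGMs) are biased toward a
#' signature relative to the exome-wide distribution. The default table
#' conditions on SGMs: among all exonic SGMs of the cohort,
#' {in `gene` vs elsewhere} x {assigned to `signature` vs other signatures},
#' one-tailed (greater) Fisher's exact test. The alternative conditioning
#' (`"all_mutations"`) restricts to the signature's exonic mutations and
#' tests {SGM vs non-SGM} x {in gene vs elsewhere}.
#'
#' @param snvs Annotated, labeled SNV data frame for one cohort.
#' @param gene Gene id.
#' @param signature Signature label.
#' @param conditioning `"sgm"` (default) or `"all_mutations"`.
#' @param model Optional `coding_model`; when supplied, a gene absent from
#'   it is an input error.
#' @return One-tailed Fisher p value (`NA` when the gene has no SGM of the
#'   signature, in which case the gene is not eligible for testing).
#' @export
gene_test <- function(snvs, gene, signature,
                      conditioning = c("sgm", "all_mutations"),
                      model = NULL) {
  conditioning <- match.arg(conditioning)
  if (!is.null(model) && !gene %in% names(model$genes)) {
    stop_input(sprintf("gene '%s' absent from coding model", gene))
  }
  x <- exonic(snvs)
  x <- x[x$signature_label != "unassigned", , drop = FALSE]
  in_gene <- !is.na(x$gene_id) & x$gene_id == gene
  is_sig <- x$signature_label == signature
  is_sgm <- x$functional_class == "stop_gain"
  if (sum(in_gene & is_sig & is_sgm) < 1) return(NA_real_)
  if (conditioning == "sgm") {
    u <- is_sgm
    a <- sum(u & in_gene & is_sig); b <- sum(u & in_gene & !is_sig)
    c_ <- sum(u & !in_gene & is_sig); d <- sum(u & !in_gene & !is_sig)
  } else {
    u <- is_sig
    a <- sum(u & in_gene & is_sgm); b <- sum(u & in_gene & !is_sgm)
    c_ <- sum(u & !in_gene & is_sgm); d <- sum(u & !in_gene & !is_sgm)
  }
  fisher_greater(a, b, c_, d)
}

#' Combine per-cohort p values with Brown's method
#'
#' Fisher's combined statistic `-2 * sum(log(p))` referred to a scaled
#' chi-square whose scale and degrees of freedom are derived from the
#' empirical covariance of `-2 log p` across genes tested in every
#' contributing cohort. Negative estimated covariances are clamped at zero
#' so that correlation can only penalize, never inflate, significance. With
#' a single p value the input is returned; with no covariance estimate (or
#' fewer than `min_genes` complete genes) the method reduces to Fisher's.
#'
#' @param p Numeric vector of p values for one gene (one per cohort).
#' @param p_matrix Optional genes x cohorts matrix of p values used to
#'   estimate the covariance (rows with any `NA` are dropped).
#' @param min_genes Minimum number of complete genes required to estimate
#'   the covariance (default 20); below this, Fisher's method is used with a
#'   warning.
#' @return Combined p value.
#' @export
brown_combine <- function(p, p_matrix = NULL, min_genes = 20) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop_input("at least one p value required")
  if (any(p <= 0 | p > 1)) stop_input("p values must be in (0, 1]")
  k <- length(p)
  if (k == 1L) return(p)
  x <- -2 * sum(log(p))
  e <- 2 * k
  v <- 2 * e
  if (!is.null(p_matrix)) {
    pm <- p_matrix[stats::complete.cases(p_matrix), , drop = FALSE]
    if (nrow(pm) >= min_genes && ncol(pm) == k) {
      S <- stats::cov(-2 * log(pm))
      off <- S[upper.tri(S)]
      v <- 4 * k + 2 * sum(pmax(off, 0))
    } else {
      warning("too few genes tested in all cohorts to estimate covariance; ",
              "falling back to Fisher's method", call. = FALSE)
    }
  }
  scale <- v / (2 * e)
  df <- 2 * e^2 / v
  stats::pchisq(x / scale, df = df, lower.tail = FALSE)
}

#' Gene-level driver analysis across cohorts
#'
#' Runs [gene_test()] per gene and cohort (genes are tested in a cohort only
#' if they carry at least one SGM assigned to the signature there), merges
#' per-cohort p values with [brown_combine()] (covariance estimated from
#' genes tested in every cohort), and BH-adjusts the merged p values across
#' all tested genes for the signature.
#'
#' @param cohorts Named list of annotated, labeled SNV data frames.
#' @param signature Signature label.
#' @param conditioning Passed to [gene_test()].
#' @return Data frame: `gene_id`, one `p_<cohort>` column per cohort,
#'   `n_signature_sgms` (summed over cohorts), `brown_p`, `fdr`, sorted by
#'   `fdr`.
#' @export
gene_enrichment <- function(cohorts, signature,
                            conditioning = c("sgm", "all_mutations")) {
  conditioning <- match.arg(conditioning)
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    stop_input("cohorts must be a named list")
  }
  per <- lapply(cohorts, function(snvs) {
    x <- exonic(snvs)
    sg <- x[x$functional_class == "stop_gain" &
            x$signature_label == signature & !is.na(x$gene_id), , drop = FALSE]
    genes <- sort(unique(sg$gene_id))
    p <- vapply(genes, function(g) gene_test(x, g, signature, conditioning),
                numeric(1))
    nsg <- vapply(genes, function(g) sum(sg$gene_id == g), integer(1))
    list(genes = genes, p = p, n = nsg)
  })
  all_genes <- sort(unique(unlist(lapply(per, `[[`, "genes"))))
  if (length(all_genes) == 0L) {
    return(data.frame(gene_id = character(0), brown_p = numeric(0),
                      fdr = numeric(0)))
  }
  pm <- sapply(per, function(z) {
    out <- rep(NA_real_, length(all_genes))
    out[match(z$genes, all_genes)] <- z$p
    out
  })
  pm <- matrix(pm, nrow = length(all_genes),
               dimnames = list(all_genes, names(cohorts)))
  nm <- sapply(per, function(z) {
    out <- rep(0L, length(all_genes))
    out[match(z$genes, all_genes)] <- z$n
    out
  })
  nm <- matrix(nm, nrow = length(all_genes))
  brown <- vapply(seq_along(all_genes), function(i) {
    suppressWarnings(brown_combine(pm[i, ], p_matrix = pm))
  }, numeric(1))
  out <- data.frame(gene_id = all_genes, stringsAsFactors = FALSE)
  for (j in seq_along(cohorts)) out[[paste0("p_", names(cohorts)[j])]] <- pm[, j]
  out$n_signature_sgms <- rowSums(nm)
  out$brown_p <- brown
  out$fdr <- stats::p.adjust(brown, method = "BH")
  out[order(out$fdr, out$brown_p, out$gene_id), , drop = FALSE]
}

#' Overlap of significant genes with known cancer genes
#'
#' One-tailed Fisher's exact test of the 2x2 overlap of a significant gene
#' set with a known-cancer-gene list against a background of all coding
#' genes.
#'
#' @param significant_genes,known_cancer_genes Character vectors, subsets of
#'   `background`.
#' @param background Character vector of all coding genes.
#' @return List with `overlap` (genes in both sets) and `p`.
#' @export
cgc_overlap <- function(significant_genes, known_cancer_genes, background) {
  significant_genes <- unique(significant_genes)
  known_cancer_genes <- unique(known_cancer_genes)
  background <- unique(background)
  if (!all(significant_genes %in% background) ||
      !all(known_cancer_genes %in% background)) {
    stop_input("gene sets must be subsets of the background")
  }
  a <- length(intersect(significant_genes, known_cancer_genes))
  b <- length(setdiff(significant_genes, known_cancer_genes))
  c_ <- length(setdiff(known_cancer_genes, significant_genes))
  d <- length(background) - a - b - c_
  list(overlap = sort(intersect(significant_genes, known_cancer_genes)),
       p = fisher_greater(a, b, c_, d))
}

#' Per-protein amino-acid residue counts of a coding model
#'
#' @param model A `coding_model`.
#' @return Matrix genes x one-letter amino acids of residue counts
#'   (terminal stop excluded).
#' @export
protein_residue_counts <- function(model) {
  aas <- sort(setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*"))
  out <- matrix(0L, length(model$genes), length(aas),
                dimnames = list(names(model$genes), aas))
  for (gid in names(model$genes)) {
    cds <- model$genes[[gid]]$cds
    codons <- substring(cds, seq(1L, nchar(cds) - 3L, 3L),
                        seq(3L, nchar(cds) - 3L, 3L))
    tab <- table(factor(translate_codon(codons), levels = aas))
    out[gid, ] <- as.integer(tab)
  }
  out
}

#' Residue-content test for a gene set
#'
#' One-tailed Mann-Whitney U test asking whether the proteins of `gene_set`
#' contain more residues of `residue` than the remaining proteins of the
#' proteome.
#'
#' @param gene_set Character vector of gene ids (a strict subset of the
#'   proteome).
#' @param residue One-letter amino-acid code (e.g. `"S"`, `"E"`).
#' @param proteome Genes x amino-acids count matrix, e.g. from
#'   [protein_residue_counts()].
#' @return One-tailed p value.
#' @export
residue_content_test <- function(gene_set, residue, proteome) {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L || !all(gene_set %in% rownames(proteome))) {
    stop_input("gene_set must be a non-empty subset of the proteome")
  }
  rest <- setdiff(rownames(proteome), gene_set)
  if (length(rest) == 0L) stop_input("gene_set must not cover the whole proteome")
  if (!residue %in% colnames(proteome)) stop_input("unknown residue")
  suppressWarnings(stats::wilcox.test(proteome[gene_set, residue],
                                      proteome[rest, residue],
                                      alternative = "greater"))$p.value
}

#' Positional skew of stop-gain mutations along a protein
#'
#' Normalizes protein positions to (0, 1] and runs one-tailed one-sample
#' Wilcoxon signed-rank tests against 0.5 in both directions, reporting the
#' direction with the smaller p (N = toward the N terminus, C = toward the
#' C terminus). All positions exactly at the midpoint yield p = 1 by
#' convention.
#'
#' @param positions Integer protein positions (1-based).
#' @param protein_length Protein length in residues.
#' @return List with `direction` (`"N"` or `"C"`) and `p`.
#' @export
positional_skew <- function(positions, protein_length) {
  if (length(positions) < 1L) stop_input("at least one position required")
  if (any(positions < 1L | positions > protein_length)) {
    stop_input("positions must lie within the protein")
  }
  rel <- positions / protein_length
  if (all(rel == 0.5)) return(list(direction = NA_character_, p = 1))
  p_n <- suppressWarnings(stats::wilcox.test(rel, mu = 0.5,
                                             alternative = "less"))$p.value
  p_c <- suppressWarnings(stats::wilcox.test(rel, mu = 0.5,
                                             alternative = "greater"))$p.value
  if (p_n <= p_c) list(direction = "N", p = p_n) else list(direction = "C", p = p_c)
}
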