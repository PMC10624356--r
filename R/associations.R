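#' Whole-genome duplication call from copy-number segments
#'
#' A sample is called WGD when its length-weighted mean copy number across
#' segments exceeds 2.5.
#'
#' @param segments Data frame with `start`, `end` (1-based inclusive) and
#'   `cn` columns for one sample.
#' @return Logical.
#' @export
detect_wgd <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L) {
    stop_input("at least one copy-number segment required")
  }
  w <- segments$end - segments$start + 1
  if (any(w <= 0)) stop_input("segments must have start <= end")
  stats::weighted.mean(segments$cn, w) > 2.5
}

#' Gene-level copy number from segments
#'
#' Among segments overlapping the gene interval and at least
#' `min_segment_length` bps long, returns the minimum copy number; `NA` when
#' no such segment exists (no CNA data; downstream loss calls then default
#' to no loss).
#'
#' @param segments Per-sample segment data frame (`chrom`, `start`, `end`,
#'   `cn`).
#' @param gene_chrom,gene_start,gene_end Gene interval (1-based inclusive).
#' @param min_segment_length Minimum segment length in bps (default 1000).
#' @return Numeric copy number or `NA`.
#' @export
gene_cn <- function(segments, gene_chrom, gene_start, gene_end,
                    min_segment_length = 1000) {
  if (gene_start > gene_end) stop_input("invalid gene interval")
  seg <- segments[segments$chrom == gene_chrom &
                  segments$end >= gene_start & segments$start <= gene_end &
                  (segments$end - segments$start + 1) >= min_segment_length, ,
                  drop = FALSE]
  if (nrow(seg) == 0L) return(NA_real_)
  min(seg$cn)
}

#' Gene-loss call from copy number
#'
#' Platform- and ploidy-aware thresholds: on the relative-call platform
#' (`"TCGA"`), loss is copy number below 0. On absolute WGS calls
#' (`"WGS"`), loss on autosomes (and on X in females) is CN < 1.5 without
#' whole-genome duplication and CN < 2.0 with WGD; on X in males the
#' thresholds are CN < 1.0 and CN < 1.5. A missing sex on chromosome X
#' falls back to the autosome rule with a warning.
#'
#' @param gene_cn Gene copy number (`NA` returns `FALSE`: no CNA data means
#'   no deletion is assumed).
#' @param platform `"TCGA"` (relative calls) or `"WGS"` (absolute calls).
#' @param wgd Logical whole-genome duplication status.
#' @param chromosome Chromosome name; anything matching `X` (e.g. `"X"`,
#'   `"chrX"`) uses the sex-specific rule.
#' @param sex `"female"`, `"male"`, or `NA`.
#' @return Logical loss call.
#' @export
gene_loss <- function(gene_cn, platform = c("WGS", "TCGA"), wgd = FALSE,
                      chromosome = "autosome", sex = NA_character_) {
  platform <- match.arg(platform)
  if (is.na(gene_cn)) return(FALSE)
  if (platform == "TCGA") return(gene_cn < 0)
  is_x <- grepl("^(chr)?X$", chromosome, ignore.case = TRUE)
  male_x <- is_x && !is.na(sex) && tolower(sex) == "male"
  if (is_x && is.na(sex)) {
    warning("sex unknown on chromosome X; using autosome thresholds",
            call. = FALSE)
  }
  thr <- if (male_x) {
    if (wgd) 1.5 else 1.0
  } else {
    if (wgd) 2.0 else 1.5
  }
  gene_cn < thr
}

#' Co-occurrence of stop-gain mutations and copy-number losses
#'
#' @param sgm_samples Character vector of samples carrying a
#'   signature-associated stop-gain mutation in the gene.
#' @param loss_samples Character vector of samples with a copy-number loss
#'   of the gene.
#' @return List with `k` (samples with both), `n` (SGM samples) and
#'   `fraction` = k/n.
#' @export
cooccurrence <- function(sgm_samples, loss_samples) {
  sgm_samples <- unique(sgm_samples)
  n <- length(sgm_samples)
  if (n < 1L) stop_input("at least one SGM sample required")
  k <- length(intersect(sgm_samples, unique(loss_samples)))
  list(k = k, n = n, fraction = k / n)
}

#' Quadnucleotide motif enrichment of stop-gain mutations
#'
#' For each motif class, a one-tailed Fisher's exact test asking whether
#' stop-gain mutations of a signature are more frequent at that motif than
#' the signature's non-stop-gain mutations.
#'
#' @param sgm_motifs Motif classes (`YTCA`/`RTCA`/`other`) of the
#'   signature's stop-gain mutations.
#' @param non_sgm_motifs Motif classes of the signature's other mutations.
#' @return Data frame with one row per motif class: counts, fractions and
#'   `p`.
#' @export
motif_test <- function(sgm_motifs, non_sgm_motifs) {
  if (length(sgm_motifs) == 0L || length(non_sgm_motifs) == 0L) {
    stop_input("both mutation sets must be non-empty")
  }
  motifs <- c("YTCA", "RTCA", "other")
  res <- lapply(motifs, function(m) {
    a <- sum(sgm_motifs == m); b <- sum(sgm_motifs != m)
    c_ <- sum(non_sgm_motifs == m); d <- sum(non_sgm_motifs != m)
    data.frame(motif = m, sgm_count = a, non_sgm_count = c_,
               sgm_fraction = a / (a + b), non_sgm_fraction = c_ / (c_ + d),
               p = fisher_greater(a, b, c_, d), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Expression association with stop-gain mutation burden
#'
#' Median-dichotomizes samples on a gene's expression (values strictly above
#' the median are "high"; ties go to the low group) and compares per-sample
#' mutation counts between the groups with one-tailed Wilcoxon rank-sum
#' tests (alternative: greater burden in the high group), one test per count
#' category, BH-adjusted across categories. Samples without mutations must
#' be included with zero counts.
#'
#' @param expression Named numeric vector of expression values per sample.
#' @param counts Data frame with `sample_id` plus one numeric column per
#'   mutation category, covering the same samples.
#' @return Data frame with `category`, `n_high`, `n_low`, `p`, `fdr`; `NA`
#'   p values where a group is degenerate. Constant expression is an error
#'   of class `sgmsig_degenerate_error` (the test is skipped by callers).
#' @export
expression_association <- function(expression, counts) {
  if (is.null(names(expression))) stop_input("expression must be named by sample")
  common <- intersect(names(expression), counts$sample_id)
  if (length(common) < 4L) stop_input("at least 4 samples with expression required")
  expression <- expression[common]
  counts <- counts[match(common, counts$sample_id), , drop = FALSE]
  if (length(unique(expression)) == 1L) {
    stop_degenerate("constant expression; association test skipped")
  }
  high <- expression > stats::median(expression)
  categories <- setdiff(names(counts), "sample_id")
  res <- lapply(categories, function(cat) {
    x <- counts[[cat]][high]; y <- counts[[cat]][!high]
    p <- if (length(x) < 2L || length(y) < 2L) NA_real_ else
      suppressWarnings(stats::wilcox.test(x, y,
                                          alternative = "greater"))$p.value
    data.frame(category = cat, n_high = sum(high), n_low = sum(!high), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Stop-gain burden across smoking-history categories
#'
#' All pairwise Wilcoxon rank-sum tests of per-sample mutation counts
#' between non-empty smoking-history groups, per count category, with BH
#' adjustment across all pairs and categories.
#'
#' @param groups Factor or character vector of smoking-history categories,
#'   one per sample.
#' @param counts Data frame (or named list) of per-sample count vectors, one
#'   column per category (e.g. signature SGMs and Glu>Stop SGMs).
#' @return Data frame: `category`, `group1`, `group2`, `n1`, `n2`, `p`,
#'   `fdr`; zero rows when fewer than two groups are non-empty.
#' @export
smoking_burden <- function(groups, counts) {
  groups <- as.character(groups)
  counts <- as.data.frame(counts)
  if (nrow(counts) != length(groups)) {
    stop_input("groups and counts must cover the same samples")
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2L) {
    return(data.frame(category = character(0), group1 = character(0),
                      group2 = character(0), n1 = integer(0), n2 = integer(0),
                      p = numeric(0), fdr = numeric(0)))
  }
  pairs <- utils::combn(lev, 2)
  res <- list()
  for (cat in names(counts)) {
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      x <- counts[[cat]][groups == g1]; y <- counts[[cat]][groups == g2]
      p <- suppressWarnings(stats::wilcox.test(x, y))$p.value
      res[[length(res) + 1L]] <- data.frame(
        category = cat, group1 = g1, group2 = g2,
        n1 = length(x), n2 = length(y), p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Knockout-clone mutation-burden test (negative-binomial two-model LRT)
#'
#' Fits negative-binomial regressions of per-clone mutation counts with and
#' without a treatment-group covariate (log link) and compares them with a
#' likelihood-ratio chi-square test on one degree of freedom. When the NB
#' fit does not converge (dispersion in the Poisson limit), the Poisson LRT
#' is used instead and flagged in the result.
#'
#' @param clones Data frame with a `group` column (two levels, e.g.
#'   `WT`/`KO`) and count columns; at least two clones per group.
#' @param category Name of the count column to test.
#' @return List with `p`, `family` (`"negative_binomial"` or `"poisson"`),
#'   and `group_means`.
#' @export
ko_test <- function(clones, category) {
  if (!category %in% names(clones)) stop_input("unknown count category")
  counts <- clones[[category]]
  group <- factor(clones$group)
  if (nlevels(group) != 2L) stop_input("exactly two treatment groups required")
  if (any(table(group) < 2L)) stop_input("at least two clones per group required")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("counts must be non-negative integers")
  }
  if (all(counts == 0)) stop_degenerate("all counts are zero")
  dat <- data.frame(y = counts, group = group)
  family <- "negative_binomial"
  ll <- tryCatch({
    m0 <- suppressWarnings(MASS::glm.nb(y ~ 1, data = dat))
    m1 <- suppressWarnings(MASS::glm.nb(y ~ group, data = dat))
    if (!m0$converged || !m1$converged) stop("no convergence")
    c(stats::logLik(m0), stats::logLik(m1))
  }, error = function(e) {
    family <<- "poisson"
    m0 <- stats::glm(y ~ 1, data = dat, family = stats::poisson())
    m1 <- stats::glm(y ~ group, data = dat, family = stats::poisson())
    c(stats::logLik(m0), stats::logLik(m1))
  })
  lr <- max(0, 2 * (ll[2] - ll[1]))
  list(p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
       family = family,
       group_means = tapply(counts, group, mean))
}
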