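# Approximate human codon usage (frequency per 1000 codons, sense codons
# only), used for "human"-like codon composition of simulated ORFs.
.HUMAN_CODON_USAGE <- c(
  TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9, CTT = 13.2, CTC = 19.6,
  CTA = 7.2, CTG = 39.6, ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
  GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1, TCT = 15.2, TCC = 17.7,
  TCA = 12.2, TCG = 4.4, CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
  ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1, GCT = 18.4, GCC = 27.7,
  GCA = 15.8, GCG = 7.4, TAT = 12.2, TAC = 15.3, CAT = 10.9, CAC = 15.1,
  CAA = 12.3, CAG = 34.2, AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
  GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6, TGT = 10.6, TGC = 12.6,
  TGG = 13.2, CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4, AGT = 12.1,
  AGC = 19.5, AGA = 12.2, AGG = 12.0, GGT = 10.8, GGC = 22.2, GGA = 16.5,
  GGG = 16.5
)

#' Synthetic SBS signature catalog
#'
#' Four synthetic 96-channel profiles with the qualitative shapes of the
#' processes studied here: `SBS4like` (tobacco-smoking-like, C>A rich across
#' contexts), `SBS13like` (APOBEC-like, concentrated on T[C>G]N and T[C>A]N
#' transversions), `SBS18like` (ROS-like, C>A with strong 5'/3' context
#' preferences), and `SBSflat` (featureless clock-like control, uniform over
#' the 96 channels).
#'
#' @param signatures Subset of the four profile names to include.
#' @return An `sbs_catalog`.
#' @export
synthetic_catalog <- function(signatures = c("SBS4like", "SBS13like",
                                             "SBS18like", "SBSflat")) {
  chans <- sbs_channels()
  comp <- parse_channel(chans)
  sub <- paste0(comp$ref, ">", comp$alt)
  profs <- list()
  # smoking-like: dominated by C>A with modest context structure
  w <- rep(0.002, 96)
  ca <- sub == "C>A"
  w[ca] <- 0.045
  w[ca & comp$five_prime %in% c("C", "T")] <- 0.065
  profs$SBS4like <- w / sum(w)
  # APOBEC-like: T[C>G]N heavy plus T[C>A]N, little else
  w <- rep(0.0005, 96)
  w[chans == "T[C>G]A"] <- 0.38
  w[chans == "T[C>G]T"] <- 0.17
  w[chans == "T[C>G]C"] <- 0.07
  w[chans == "T[C>G]G"] <- 0.05
  w[chans == "T[C>A]A"] <- 0.12
  w[chans == "T[C>A]G"] <- 0.06
  w[chans == "T[C>A]T"] <- 0.06
  w[chans == "T[C>A]C"] <- 0.04
  profs$SBS13like <- w / sum(w)
  # ROS-like: C>A with 3' preference away from the smoking-like shape
  w <- rep(0.001, 96)
  w[ca & comp$three_prime %in% c("A", "T")] <- 0.08
  w[ca & comp$five_prime == "G"] <- 0.05
  profs$SBS18like <- w / sum(w)
  # featureless control
  profs$SBSflat <- rep(1 / 96, 96)
  m <- do.call(cbind, profs)
  rownames(m) <- chans
  as_catalog(m[, signatures, drop = FALSE])
}

#' Synthetic-cohort configuration
#'
#' Captures every tunable of the simulator so a cohort is fully reproducible
#' from its configuration (the seed is mandatory). Defaults describe a small
#' but realistic desk-scale cohort: 60 genes of ~180 codons, 50 samples with
#' a log-normal SNV burden around 100 exonic SNVs/sample, symmetric
#' Dirichlet(1) signature exposures over the synthetic catalog, no driver
#' spikes, 15% focal gene-loss rate and 20% WGD fraction.
#'
#' @param n_genes Number of genes.
#' @param mean_gene_codons,sd_log_gene_codons Log-normal gene length law
#'   (codons; minimum 30).
#' @param codon_usage `"uniform"` over sense codons or `"human"`
#'   (human-like usage table).
#' @param intron_prob Fraction of genes given a two-exon structure.
#' @param minus_strand_prob Fraction of genes placed on the minus strand.
#' @param intergenic Intergenic spacer length (bp).
#' @param n_samples Number of samples.
#' @param exposure_prior Named Dirichlet concentration per catalog
#'   signature (`NULL`: symmetric 1 over the catalog).
#' @param burden_meanlog,burden_sdlog Log-normal per-sample SNV burden law.
#' @param flank Flanking bps around CDS eligible for mutation placement.
#' @param cancer_type Cancer-type label stamped on the cohort.
#' @param wgd_fraction Fraction of samples with whole-genome duplication.
#' @param loss_rate Per-gene, per-sample focal copy-number loss rate.
#' @param expr_meanlog,expr_sdlog Log-normal gene-expression law.
#' @param expr_link_gene,expr_link_coef Optional gene whose expression is
#'   tied to the per-sample stop-gain burden of `expr_link_signature` with
#'   strength `expr_link_coef` (log-scale units per standard deviation).
#' @param expr_link_signature Signature whose SGM burden drives the link.
#' @param smoking_link Strength in (0, 1) of the coupling between smoking
#'   category and smoking-signature SGM burden (0 = independent).
#' @param smoking_signature Signature treated as the smoking process.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60, mean_gene_codons = 180,
                       sd_log_gene_codons = 0.25,
                       codon_usage = c("human", "uniform"),
                       intron_prob = 0.3, minus_strand_prob = 0.4,
                       intergenic = 120,
                       n_samples = 50, exposure_prior = NULL,
                       burden_meanlog = log(100), burden_sdlog = 0.4,
                       flank = 2, cancer_type = "synthetic",
                       wgd_fraction = 0.2, loss_rate = 0.15,
                       expr_meanlog = 3, expr_sdlog = 0.5,
                       expr_link_gene = NULL, expr_link_coef = 0,
                       expr_link_signature = "SBS13like",
                       smoking_link = 0, smoking_signature = "SBS4like",
                       seed) {
  if (missing(seed)) stop_input("a seed is mandatory in sim_config")
  cfg <- list(n_genes = n_genes, mean_gene_codons = mean_gene_codons,
              sd_log_gene_codons = sd_log_gene_codons,
              codon_usage = match.arg(codon_usage),
              intron_prob = intron_prob, minus_strand_prob = minus_strand_prob,
              intergenic = intergenic, n_samples = n_samples,
              exposure_prior = exposure_prior,
              burden_meanlog = burden_meanlog, burden_sdlog = burden_sdlog,
              flank = flank, cancer_type = cancer_type,
              wgd_fraction = wgd_fraction, loss_rate = loss_rate,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              expr_link_gene = expr_link_gene, expr_link_coef = expr_link_coef,
              expr_link_signature = expr_link_signature,
              smoking_link = smoking_link,
              smoking_signature = smoking_signature,
              seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$n_samples < 1) stop_input("counts must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d samples, burden ~ lognormal(%.2f, %.2f), seed %d\n",
              x$n_genes, x$n_samples, x$burden_meanlog, x$burden_sdlog, x$seed))
  invisible(x)
}

sample_codons <- function(n, usage) {
  sense <- sense_codons()
  if (usage == "uniform") {
    sample(sense, n, replace = TRUE)
  } else {
    sample(names(.HUMAN_CODON_USAGE), n, replace = TRUE,
           prob = .HUMAN_CODON_USAGE)
  }
}

random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Simulate a coding model
#'
#' Generates a single synthetic chromosome carrying valid ORFs (ATG, sense
#' codons with configurable codon usage, terminal stop codon, no internal
#' stop) separated by random intergenic sequence. A configurable fraction of
#' genes is placed on the minus strand, and a fraction receives a two-exon
#' structure with a short intron, so splicing and strand handling are
#' exercised.
#'
#' @param config A [sim_config()].
#' @return A `coding_model` (its `gene_table` element holds the gene-model
#'   table for serialization).
#' @export
simulate_coding_model <- function(config) {
  with_seed(config$seed, {
    pieces <- character(0)
    cursor <- 1L
    rows <- list()
    for (i in seq_len(config$n_genes)) {
      gid <- sprintf("gene%03d", i)
      n_codons <- max(30L, round(stats::rlnorm(1, log(config$mean_gene_codons),
                                               config$sd_log_gene_codons)))
      body <- sample_codons(n_codons - 2L, config$codon_usage)
      cds <- paste0("ATG", paste(body, collapse = ""),
                    sample(.STOP_CODONS, 1))
      strand <- if (stats::runif(1) < config$minus_strand_prob) "-" else "+"
      gseq <- if (strand == "-") revcomp(cds) else cds
      spacer <- random_seq(config$intergenic)
      pieces <- c(pieces, spacer)
      cursor <- cursor + config$intergenic
      if (stats::runif(1) < config$intron_prob && nchar(gseq) > 60L) {
        # split the genomic CDS footprint in two with a short intron
        cut <- sample(20:(nchar(gseq) - 20L), 1)
        intron_len <- sample(40:80, 1)
        exon1 <- substr(gseq, 1L, cut)
        exon2 <- substr(gseq, cut + 1L, nchar(gseq))
        pieces <- c(pieces, exon1, random_seq(intron_len), exon2)
        s1 <- cursor; e1 <- cursor + nchar(exon1) - 1L
        s2 <- e1 + intron_len + 1L; e2 <- s2 + nchar(exon2) - 1L
        rows[[i]] <- data.frame(gene_id = gid, chrom = "chr1", strand = strand,
                                cds_starts = paste(c(s1, s2), collapse = ","),
                                cds_ends = paste(c(e1, e2), collapse = ","),
                                stringsAsFactors = FALSE)
        cursor <- e2 + 1L
      } else {
        pieces <- c(pieces, gseq)
        rows[[i]] <- data.frame(gene_id = gid, chrom = "chr1", strand = strand,
                                cds_starts = as.character(cursor),
                                cds_ends = as.character(cursor + nchar(gseq) - 1L),
                                stringsAsFactors = FALSE)
        cursor <- cursor + nchar(gseq)
      }
    }
    pieces <- c(pieces, random_seq(config$intergenic))
    genome <- c(chr1 = paste(pieces, collapse = ""))
    coding_model(genome, do.call(rbind, rows))
  })
}

# Index of mutable positions by pyrimidine-normalized trinucleotide context,
# restricted to CDS footprints +/- flank. Cached on the model by attribute.
context_index <- function(model, flank = 2) {
  cache <- attr(model, "context_index")
  if (!is.null(cache) && identical(attr(cache, "flank"), flank)) return(cache)
  pos_by_chrom <- list()
  for (g in model$genes) {
    lo <- pmax(g$starts - flank, 2L)
    hi <- pmin(g$ends + flank, nchar(model$genome[[g$chrom]]) - 1L)
    pos_by_chrom[[g$chrom]] <- c(pos_by_chrom[[g$chrom]],
                                 unlist(Map(seq.int, lo, hi)))
  }
  keys <- character(0); chroms <- character(0); positions <- integer(0)
  for (chrom in names(pos_by_chrom)) {
    p <- sort(unique(pos_by_chrom[[chrom]]))
    tri <- substring(model$genome[[chrom]], p - 1L, p + 1L)
    mid <- substr(tri, 2L, 2L)
    pur <- mid %in% c("A", "G")
    tri[pur] <- revcomp(tri[pur])
    keys <- c(keys, tri); chroms <- c(chroms, rep(chrom, length(p)))
    positions <- c(positions, p)
  }
  idx <- split(data.frame(chrom = chroms, pos = positions,
                          stringsAsFactors = FALSE), keys)
  attr(idx, "flank") <- flank
  idx
}

channel_context_key <- function(channel) {
  comp <- parse_channel(channel)
  paste0(comp$five_prime, comp$ref, comp$three_prime)
}

#' Simulate a signature-driven mutation cohort
#'
#' Per sample, signature exposures are drawn from a Dirichlet prior and the
#' SNV burden from a log-normal law. Each SNV draws its true signature from
#' the exposures and its 96-channel from that signature's profile, and is
#' placed uniformly at a genomic position (CDS +/- flank) whose
#' pyrimidine-normalized trinucleotide context matches the channel, so that
#' annotation, motif and genetic-code analyses see real sequence
#' constraints. No position is mutated twice in the same sample. A channel
#' with no matching genomic site is resampled from the same signature (with
#' one warning).
#'
#' @param model A `coding_model` (typically from [simulate_coding_model()]).
#' @param catalog An `sbs_catalog`.
#' @param config A [sim_config()].
#' @return List with `mutations` (data frame: `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `cancer_type`, `true_signature`) and `exposures` (the
#'   true samples x signatures Dirichlet draws).
#' @export
simulate_cohort <- function(model, catalog, config) {
  idx <- context_index(model, config$flank)
  sigs <- colnames(catalog)
  alpha <- config$exposure_prior
  if (is.null(alpha)) alpha <- stats::setNames(rep(1, length(sigs)), sigs)
  if (!setequal(names(alpha), sigs)) {
    stop_input("exposure_prior must be named by catalog signatures")
  }
  alpha <- alpha[sigs]
  chan_key <- stats::setNames(channel_context_key(sbs_channels()), sbs_channels())
  warned <- FALSE
  with_seed(config$seed, {
    expo <- matrix(0, config$n_samples, length(sigs),
                   dimnames = list(sprintf("s%03d", seq_len(config$n_samples)),
                                   sigs))
    muts <- list()
    for (si in seq_len(config$n_samples)) {
      sid <- rownames(expo)[si]
      w <- stats::rgamma(length(sigs), shape = alpha)
      w <- w / sum(w)
      expo[si, ] <- w
      n <- max(1L, round(stats::rlnorm(1, config$burden_meanlog,
                                       config$burden_sdlog)))
      true_sig <- sample(sigs, n, replace = TRUE, prob = w)
      channel <- character(n)
      for (sg in unique(true_sig)) {
        m <- true_sig == sg
        channel[m] <- sample(sbs_channels(), sum(m), replace = TRUE,
                             prob = catalog[, sg])
      }
      # resample channels that match no genomic context in this model
      for (round in 1:50) {
        missing <- which(!chan_key[channel] %in% names(idx))
        if (length(missing) == 0L) break
        if (!warned) {
          warning("channel with no matching genomic site; resampling",
                  call. = FALSE)
          warned <- TRUE
        }
        for (sg in unique(true_sig[missing])) {
          m <- missing[true_sig[missing] == sg]
          channel[m] <- sample(sbs_channels(), length(m), replace = TRUE,
                               prob = catalog[, sg])
        }
      }
      chrom <- character(n); pos <- integer(n)
      pending <- seq_len(n)
      for (round in 1:25) {
        if (length(pending) == 0L) break
        keys <- chan_key[channel[pending]]
        for (key in unique(keys)) {
          j <- pending[keys == key]
          sites <- idx[[key]]
          r <- sample.int(nrow(sites), length(j), replace = TRUE)
          chrom[j] <- sites$chrom[r]; pos[j] <- sites$pos[r]
        }
        pending <- which(duplicated(paste0(chrom, ":", pos)))
      }
      keep <- !duplicated(paste0(chrom, ":", pos))
      chrom <- chrom[keep]; pos <- pos[keep]
      channel <- channel[keep]; true_sig <- true_sig[keep]
      ref <- substring(model$genome[chrom], pos, pos)
      calt <- parse_channel(channel)$alt
      alt <- ifelse(ref %in% c("C", "T"), calt, comp_base(calt))
      muts[[si]] <- data.frame(sample_id = sid, chrom = chrom, pos = pos,
                               ref = ref, alt = alt,
                               cancer_type = config$cancer_type,
                               true_signature = true_sig,
                               stringsAsFactors = FALSE)
    }
    list(mutations = do.call(rbind, muts), exposures = expo)
  })
}

#' Spike driver stop-gain mutations into a cohort
#'
#' Adds `n_sgms` stop-gain mutations to a gene at stop-reachable sites
#' compatible with the signature's profile (channels with non-zero mass),
#' each in a distinct sample, emulating positive selection of truncating
#' driver mutations. Because such mutations are generated by the mutational
#' process itself, recipient samples are drawn with probability proportional
#' to their true exposure to the signature (uniformly when the cohort
#' carries no exposure matrix), and sites are drawn proportionally to the
#' signature's channel probabilities.
#'
#' @param cohort List from [simulate_cohort()].
#' @param model The `coding_model` used to simulate the cohort.
#' @param catalog The `sbs_catalog` used.
#' @param gene Target gene id.
#' @param signature Signature whose channels the spiked SGMs must use.
#' @param n_sgms Number of SGMs to add.
#' @param seed Integer seed.
#' @return The cohort with augmented `mutations` (spiked rows flagged by a
#'   logical `spiked` column) and a `spiked` element recording ground truth.
#' @export
spike_driver_sgms <- function(cohort, model, catalog, gene, signature,
                              n_sgms, seed) {
  sites <- gene_stop_sites(model, gene)
  if (is.null(sites)) stop_input(sprintf("gene '%s' has no stop-reachable site", gene))
  prof <- catalog[, signature]
  sites <- sites[prof[sites$channel] > 0, , drop = FALSE]
  if (nrow(sites) == 0L) {
    stop_input(sprintf(
      "gene '%s' has no stop-reachable site compatible with %s (deficit: %d)",
      gene, signature, n_sgms))
  }
  samples <- sort(unique(cohort$mutations$sample_id))
  if (n_sgms > length(samples)) {
    stop_input(sprintf("cannot place %d SGMs in %d distinct samples",
                       n_sgms, length(samples)))
  }
  existing <- paste0(cohort$mutations$sample_id, ":", cohort$mutations$chrom,
                     ":", cohort$mutations$pos)
  sample_w <- rep(1, length(samples))
  if (!is.null(cohort$exposures) && signature %in% colnames(cohort$exposures)) {
    w <- cohort$exposures[samples, signature]
    if (sum(w) > 0) sample_w <- w
  }
  with_seed(seed, {
    target <- sample(samples, n_sgms, prob = sample_w)
    rows <- list()
    for (i in seq_len(n_sgms)) {
      for (try in 1:100) {
        r <- sample.int(nrow(sites), 1, prob = prof[sites$channel])
        key <- paste0(target[i], ":", sites$chrom[r], ":", sites$pos[r])
        if (!key %in% existing) break
      }
      existing <- c(existing, key)
      rows[[i]] <- data.frame(
        sample_id = target[i], chrom = sites$chrom[r], pos = sites$pos[r],
        ref = sites$ref[r], alt = sites$alt[r],
        cancer_type = cohort$mutations$cancer_type[1],
        true_signature = signature, stringsAsFactors = FALSE)
    }
    add <- do.call(rbind, rows)
    base <- cohort$mutations
    base$spiked <- FALSE
    add$spiked <- TRUE
    cohort$mutations <- rbind(base, add)
    cohort$spiked <- add
    cohort
  })
}

#' Simulate copy-number, expression and clinical covariates for a cohort
#'
#' Copy number: per sample, one background segment per chromosome at total
#' CN 2 (or 4 for WGD samples) plus focal loss segments over genes drawn at
#' `loss_rate` (CN 0.8 without WGD, 1.8 with WGD). Expression: log-normal
#' per gene and sample, with an optional link adding
#' `expr_link_coef * scale(SGM count)` to the designated gene's log
#' expression. Clinical: four smoking-history categories, optionally coupled
#' to the per-sample burden of the smoking signature, plus sex and purity.
#'
#' @param cohort List from [simulate_cohort()] (annotated or not; stop-gain
#'   burdens are computed from `true_signature` and, when available, the
#'   `functional_class` column of `cohort$mutations`).
#' @param model The `coding_model`.
#' @param config A [sim_config()].
#' @return List with `cn_segments`, `expression` (samples x genes matrix),
#'   `clinical` (sample_id, smoking_category, sex, purity) and `wgd`
#'   (named logical ground truth).
#' @export
simulate_covariates <- function(cohort, model, config) {
  muts <- cohort$mutations
  samples <- sort(unique(muts$sample_id))
  genes <- names(model$genes)
  gene_start <- vapply(model$genes, function(g) min(g$starts), integer(1))
  gene_end <- vapply(model$genes, function(g) max(g$ends), integer(1))
  gene_chrom <- vapply(model$genes, function(g) g$chrom, character(1))
  chromlen <- nchar(model$genome)
  sgm_flag <- if ("functional_class" %in% names(muts)) {
    muts$functional_class == "stop_gain"
  } else {
    rep(TRUE, nrow(muts))
  }
  count_of <- function(sig) {
    vapply(samples, function(s) {
      sum(muts$sample_id == s & muts$true_signature == sig & sgm_flag)
    }, numeric(1))
  }
  with_seed(config$seed + 1L, {
    wgd <- stats::setNames(stats::runif(length(samples)) < config$wgd_fraction,
                           samples)
    segs <- list()
    for (s in samples) {
      base <- if (wgd[[s]]) 4 else 2
      loss_cn <- if (wgd[[s]]) 1.8 else 0.8
      lost <- stats::runif(length(genes)) < config$loss_rate
      for (chrom in names(chromlen)) {
        segs[[length(segs) + 1L]] <- data.frame(
          sample_id = s, chrom = chrom, start = 1L,
          end = unname(chromlen[chrom]), cn = base, stringsAsFactors = FALSE)
      }
      if (any(lost)) {
        segs[[length(segs) + 1L]] <- data.frame(
          sample_id = s, chrom = gene_chrom[lost],
          start = pmax(1L, gene_start[lost] - 200L),
          end = pmin(unname(chromlen[gene_chrom[lost]]), gene_end[lost] + 200L),
          cn = loss_cn, stringsAsFactors = FALSE)
      }
    }
    cn_segments <- do.call(rbind, segs)
    rownames(cn_segments) <- NULL
    expr <- matrix(stats::rlnorm(length(samples) * length(genes),
                                 config$expr_meanlog, config$expr_sdlog),
                   length(samples), length(genes),
                   dimnames = list(samples, genes))
    if (!is.null(config$expr_link_gene) && config$expr_link_coef != 0) {
      burden <- count_of(config$expr_link_signature)
      z <- if (stats::sd(burden) > 0) as.vector(scale(burden)) else burden * 0
      expr[, config$expr_link_gene] <-
        exp(log(expr[, config$expr_link_gene]) + config$expr_link_coef * z)
    }
    levels_ <- c("current", "reformed_recent", "reformed_long", "never")
    if (config$smoking_link > 0) {
      burden <- count_of(config$smoking_signature)
      score <- config$smoking_link * rank(burden, ties.method = "average") /
        length(burden) + (1 - config$smoking_link) * stats::runif(length(burden))
      grp <- cut(score, stats::quantile(score, seq(0, 1, 0.25)),
                 include.lowest = TRUE, labels = rev(levels_))
      smoking <- as.character(grp)
    } else {
      smoking <- sample(levels_, length(samples), replace = TRUE)
    }
    clinical <- data.frame(
      sample_id = samples, smoking_category = smoking,
      sex = sample(c("female", "male"), length(samples), replace = TRUE),
      purity = round(stats::runif(length(samples), 0.3, 0.95), 3),
      stringsAsFactors = FALSE)
    list(cn_segments = cn_segments, expression = expr, clinical = clinical,
         wgd = wgd)
  })
}
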