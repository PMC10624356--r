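# Independent oracles and tiny fixtures used across the suite.

# One-tailed (greater) Fisher p by explicit hypergeometric enumeration:
# margins fixed, probabilities from binomial coefficients.
fisher_oracle_greater <- function(a, b, c, d) {
  m <- a + b
  n_ <- c + d
  k <- a + c
  xs <- max(0, k - n_):min(m, k)
  probs <- exp(lchoose(m, xs) + lchoose(n_, k - xs) - lchoose(m + n_, k))
  sum(probs[xs >= a])
}

# Benjamini-Hochberg by the textbook step-up definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Brute-force stop-path enumeration for one codon: all 9 substitutions,
# membership in the stop set.
stop_paths_oracle <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  hits <- 0L
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), bases[pos])) {
      mutated <- bases
      mutated[pos] <- alt
      if (paste(mutated, collapse = "") %in% c("TAA", "TAG", "TGA")) {
        hits <- hits + 1L
      }
    }
  }
  hits
}

# A handcrafted coding model: one plus-strand gene, one minus-strand gene
# encoding the same protein, and a two-exon plus-strand gene.
tiny_model <- function() {
  # geneA (+): ATG TCA GAA TGG TAA at chr1:4..18
  cdsA <- "ATGTCAGAATGGTAA"
  chr1 <- paste0("CGT", cdsA, "ACGTT")
  # geneB (-): same CDS, reverse complemented, at chr2:5..19
  chr2 <- paste0("AAGC", paste(rev(strsplit(chartr("ACGT", "TGCA", cdsA),
                                            "")[[1]]), collapse = ""), "GG")
  # geneC (+): two exons, ATGGAA | TAA with a 5-bp intron, on chr3
  chr3 <- paste0("TT", "ATGGAA", "GGGCC", "TAA", "AT")
  genome <- c(chr1 = chr1, chr2 = chr2, chr3 = chr3)
  gt <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr2", "chr3"),
    strand = c("+", "-", "+"),
    cds_starts = c("4", "5", "3,14"),
    cds_ends = c("18", "19", "8,16"),
    stringsAsFactors = FALSE
  )
  coding_model(genome, gt)
}

# Plus-strand single-exon model from a vector of codon strings.
model_from_codons <- function(codons, pad = "CGATT") {
  cds <- paste(codons, collapse = "")
  genome <- c(chr1 = paste0(pad, cds, pad))
  gt <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                   cds_starts = as.character(nchar(pad) + 1L),
                   cds_ends = as.character(nchar(pad) + nchar(cds)),
                   stringsAsFactors = FALSE)
  coding_model(genome, gt)
}

# Brute-force amino-acid stop-gain distribution for plus-strand single-exon
# models: scan every CDS position and alternate base on the raw genome
# string, translate the mutated codon, and accumulate profile mass.
stop_dist_oracle <- function(profile, model) {
  stopifnot(length(model$genes) == 1L)
  g <- model$genes[[1]]
  stopifnot(g$strand == "+", length(g$starts) == 1L)
  seqs <- model$genome[[g$chrom]]
  mass <- c()
  for (t in seq_len(nchar(g$cds) - 3L)) { # exclude the terminal stop codon
    gpos <- g$starts + t - 1L
    ref <- substr(seqs, gpos, gpos)
    ci <- (t - 1L) %/% 3L
    codon <- substr(g$cds, ci * 3L + 1L, ci * 3L + 3L)
    aa <- unname(Biostrings::GENETIC_CODE[codon])
    if (aa == "*") next
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      mut <- g$cds
      substr(mut, t, t) <- alt
      ci3 <- ci * 3L
      if (!unname(Biostrings::GENETIC_CODE[substr(mut, ci3 + 1L, ci3 + 3L)]) == "*") next
      ch <- normalize_channel(substr(seqs, gpos - 1L, gpos - 1L), ref, alt,
                              substr(seqs, gpos + 1L, gpos + 1L))
      mass[aa] <- sum(mass[aa], profile[[ch]], na.rm = TRUE)
    }
  }
  mass <- mass[mass > 0]
  mass[order(names(mass))] / sum(mass)
}

# A shuffled codon-balanced CDS: ATG, all 61 sense codons once, TAA.
balanced_codon_model <- function(seed = 42) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  codons <- withr_seed_sample(sense, seed)
  model_from_codons(c("ATG", codons, "TAA"))
}

# Evaluate `code` under a fixed seed, restoring RNG state afterwards.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

withr_seed_sample <- function(x, seed) withr_seed(seed, sample(x))
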