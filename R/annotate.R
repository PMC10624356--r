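#' Construct a coding model from in-memory genome and gene table
#'
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param gene_table Data frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `cds_starts`, `cds_ends` (comma-separated 1-based inclusive
#'   genomic coordinates, ascending).
#' @param on_invalid `"error"` (default) to reject genes whose spliced CDS
#'   is not a clean ORF (length divisible by 3, ATG start, terminal stop, no
#'   internal stop); `"warn"` to warn and keep them (for real-data inputs).
#' @return An object of class `coding_model`: per-gene CDS sequences with
#'   genomic maps, plus the genome and a position index used by
#'   [annotate_snvs()].
#' @export
coding_model <- function(genome, gene_table, on_invalid = c("error", "warn")) {
  on_invalid <- match.arg(on_invalid)
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(names(genome)) || any(names(genome) == "")) {
    stop_format("genome sequences must be named by chromosome")
  }
  need <- c("gene_id", "chrom", "strand", "cds_starts", "cds_ends")
  if (!all(need %in% names(gene_table))) {
    stop_format(sprintf("gene table must have columns: %s",
                        paste(need, collapse = ", ")))
  }
  if (anyDuplicated(gene_table$gene_id)) {
    stop_format("gene ids must be unique (one transcript per gene)")
  }
  genes <- list()
  for (i in seq_len(nrow(gene_table))) {
    gid <- as.character(gene_table$gene_id[i])
    chrom <- as.character(gene_table$chrom[i])
    strand <- as.character(gene_table$strand[i])
    if (!chrom %in% names(genome)) {
      stop_format(sprintf("gene %s: chromosome '%s' not in genome", gid, chrom))
    }
    if (!strand %in% c("+", "-")) {
      stop_format(sprintf("gene %s: strand must be '+' or '-'", gid))
    }
    starts <- as.integer(strsplit(as.character(gene_table$cds_starts[i]), ",")[[1]])
    ends <- as.integer(strsplit(as.character(gene_table$cds_ends[i]), ",")[[1]])
    if (length(starts) != length(ends) || any(is.na(starts)) || any(is.na(ends)) ||
        any(starts > ends)) {
      stop_format(sprintf("gene %s: malformed CDS intervals", gid))
    }
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    if (any(starts[-1] <= ends[-length(ends)])) {
      stop_format(sprintf("gene %s: CDS intervals overlap", gid))
    }
    if (starts[1] < 1L || ends[length(ends)] > nchar(genome[[chrom]])) {
      stop_format(sprintf("gene %s: CDS interval outside chromosome", gid))
    }
    exon_seqs <- substring(genome[[chrom]], starts, ends)
    if (strand == "+") {
      cds <- paste(exon_seqs, collapse = "")
      gmap <- unlist(Map(seq.int, starts, ends), use.names = FALSE)
    } else {
      # transcript order: descending genomic coordinate, reverse complement
      cds <- paste(revcomp(rev(exon_seqs)), collapse = "")
      gmap <- unlist(Map(function(s, e) seq.int(e, s), rev(starts), rev(ends)),
                     use.names = FALSE)
    }
    problems <- character(0)
    if (nchar(cds) %% 3L != 0L) {
      stop_format(sprintf("gene %s: CDS length %d not divisible by 3", gid, nchar(cds)))
    }
    codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
    aa <- translate_codon(codons)
    if (codons[1] != "ATG") problems <- c(problems, "does not start with ATG")
    if (!codons[length(codons)] %in% .STOP_CODONS) {
      problems <- c(problems, "does not end with a stop codon")
    }
    if (any(aa[-length(aa)] == "*")) problems <- c(problems, "internal stop codon")
    if (length(problems) > 0) {
      msg <- sprintf("gene %s: %s", gid, paste(problems, collapse = "; "))
      if (on_invalid == "error") stop_format(msg) else warning(msg, call. = FALSE)
    }
    genes[[gid]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                         starts = starts, ends = ends, cds = cds, gmap = gmap)
  }
  # deterministic alphabetical gene order; also fixes the rule that an SNV
  # hitting overlapping genes is attributed to the alphabetically first one
  genes <- genes[order(names(genes))]
  index <- build_position_index(genes)
  structure(list(genome = genome, genes = genes, index = index,
                 gene_table = gene_table),
            class = "coding_model")
}

build_position_index <- function(genes) {
  if (length(genes) == 0L) {
    return(list(key = character(0), gene_id = character(0), tpos = integer(0)))
  }
  key <- unlist(lapply(genes, function(g) paste0(g$chrom, ":", g$gmap)),
                use.names = FALSE)
  gene_id <- rep(names(genes), vapply(genes, function(g) length(g$gmap), integer(1)))
  tpos <- unlist(lapply(genes, function(g) seq_along(g$gmap)), use.names = FALSE)
  # genes are already alphabetical, so match() on key returns the
  # alphabetically first gene for positions covered by several genes
  list(key = key, gene_id = gene_id, tpos = tpos)
}

#' @export
print.coding_model <- function(x, ...) {
  cat(sprintf("coding_model: %d genes on %d chromosome(s), %d coding bases\n",
              length(x$genes), length(x$genome),
              sum(vapply(x$genes, function(g) nchar(g$cds), integer(1)))))
  invisible(x)
}

#' Build a coding model from FASTA and gene-model files
#'
#' @param genome_fasta Path to a genome FASTA file.
#' @param gene_model_table Path to a tab-separated gene model with columns
#'   `gene_id`, `chrom`, `strand`, `cds_starts`, `cds_ends` (comma-separated
#'   1-based inclusive coordinates).
#' @inheritParams coding_model
#' @return A `coding_model` object.
#' @export
build_coding_model <- function(genome_fasta, gene_model_table,
                               on_invalid = c("error", "warn")) {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gt <- utils::read.delim(gene_model_table, stringsAsFactors = FALSE)
  coding_model(genome, gt, on_invalid = match.arg(on_invalid))
}

#' Read a MAF-like mutation table
#'
#' Tab-separated with header columns `sample_id`, `chrom`, `pos`, `ref`,
#' `alt` (additional columns are kept).
#'
#' @param path File path.
#' @return Data frame of SNVs.
#' @export
read_maf <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x))) {
    stop_format(sprintf("mutation table must have columns: %s",
                        paste(need, collapse = ", ")))
  }
  x$pos <- as.integer(x$pos)
  x
}

#' Annotate somatic SNVs against a coding model
#'
#' Assigns each SNV its functional class by translating the mutated codon
#' (`stop_gain`, `stop_loss`, `start_loss`, `missense`, `silent`, or
#' `noncoding` outside any CDS), the amino-acid change and protein position,
#' the pyrimidine-normalized trinucleotide channel from the +/-1 genomic
#' context, and the quadnucleotide motif class (YTCA/RTCA/other) used for
#' APOBEC analyses. SNVs overlapping several genes are attributed to the
#' alphabetically first gene. Start-loss takes precedence in codon 1 and
#' stop-loss in the terminal codon.
#'
#' @param snvs Data frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt` (1-based genomic coordinates).
#' @param model A `coding_model`.
#' @return The input with columns `gene_id`, `functional_class`, `ref_aa`,
#'   `alt_aa`, `protein_position`, `channel`, `motif_class` appended.
#'   `channel` is `NA` when a flanking base is unavailable (contig edge);
#'   such SNVs are excluded from signature analyses downstream.
#' @export
annotate_snvs <- function(snvs, model) {
  if (!inherits(model, "coding_model")) stop_input("model must be a coding_model")
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snvs))) {
    stop_format(sprintf("snvs must have columns: %s", paste(need, collapse = ", ")))
  }
  n <- nrow(snvs)
  if (n == 0L) {
    snvs[c("gene_id", "functional_class", "ref_aa", "alt_aa", "channel",
           "motif_class")] <- character(0)
    snvs$protein_position <- integer(0)
    return(snvs)
  }
  chrom <- as.character(snvs$chrom)
  pos <- as.integer(snvs$pos)
  ref <- check_bases(snvs$ref, "ref allele")
  alt <- check_bases(snvs$alt, "alt allele")
  if (any(ref == alt)) stop_input("ref and alt alleles must differ")
  if (!all(chrom %in% names(model$genome))) {
    stop_data("SNV on a chromosome absent from the genome")
  }
  chromlen <- nchar(model$genome)[chrom]
  if (any(pos < 1L | pos > chromlen)) stop_data("SNV position outside chromosome")
  genome_ref <- substring(model$genome[chrom], pos, pos)
  if (any(genome_ref != ref)) {
    bad <- which(genome_ref != ref)[1]
    stop_data(sprintf("ref allele mismatch with genome at %s:%d (%s vs %s)",
                      chrom[bad], pos[bad], ref[bad], genome_ref[bad]))
  }
  # trinucleotide channel from genomic context
  has_flank <- pos > 1L & pos < chromlen
  channel <- rep(NA_character_, n)
  if (any(has_flank)) {
    f <- substring(model$genome[chrom[has_flank]], pos[has_flank] - 1L,
                   pos[has_flank] - 1L)
    t3 <- substring(model$genome[chrom[has_flank]], pos[has_flank] + 1L,
                    pos[has_flank] + 1L)
    channel[has_flank] <- normalize_channel(f, ref[has_flank], alt[has_flank], t3)
  }
  # gene lookup (alphabetically first gene wins for overlaps)
  hit <- match(paste0(chrom, ":", pos), model$index$key)
  gene_id <- model$index$gene_id[hit]
  tpos <- model$index$tpos[hit]
  cls <- rep("noncoding", n)
  ref_aa <- rep(NA_character_, n)
  alt_aa <- rep(NA_character_, n)
  prot_pos <- rep(NA_integer_, n)
  coding <- !is.na(gene_id)
  if (any(coding)) {
    gidx <- match(gene_id[coding], names(model$genes))
    strand <- vapply(model$genes, function(g) g$strand, character(1))[gidx]
    cds <- vapply(model$genes, function(g) g$cds, character(1))[gidx]
    minus <- strand == "-"
    talt <- ifelse(minus, comp_base(alt[coding]), alt[coding])
    tp <- tpos[coding]
    ci <- (tp - 1L) %/% 3L            # 0-based codon index
    off <- tp - ci * 3L               # 1..3 within codon
    codon <- substring(cds, ci * 3L + 1L, ci * 3L + 3L)
    mutated <- codon
    substr(mutated, off, off) <- talt
    raa <- translate_codon(codon)
    aaa <- translate_codon(mutated)
    k <- ifelse(aaa == raa, "silent",
         ifelse(ci == 0L, "start_loss",
         ifelse(raa == "*", "stop_loss",
         ifelse(aaa == "*", "stop_gain", "missense"))))
    cls[coding] <- k
    ref_aa[coding] <- raa
    alt_aa[coding] <- aaa
    prot_pos[coding] <- ci + 1L
  }
  snvs$gene_id <- gene_id
  snvs$functional_class <- cls
  snvs$ref_aa <- ref_aa
  snvs$alt_aa <- alt_aa
  snvs$protein_position <- prot_pos
  snvs$channel <- channel
  snvs$motif_class <- quad_motif_class(snvs, model)
  snvs
}

#' Annotate a single SNV
#'
#' Convenience wrapper around [annotate_snvs()] for one variant.
#'
#' @param snv One-row data frame or list with `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param model A `coding_model`.
#' @return One-row annotated data frame.
#' @export
annotate_snv <- function(snv, model) {
  annotate_snvs(as.data.frame(snv, stringsAsFactors = FALSE), model)
}

#' Quadnucleotide APOBEC motif class of mutated cytosines
#'
#' Reads the 4-mer at positions (-2, -1, 0, +1) relative to the mutated base
#' on the strand where that base is a C, and classifies it as `YTCA`
#' (Y = C/T), `RTCA` (R = A/G) or `other`. Mutations whose
#' pyrimidine-normalized reference is T (genomic ref A or T) are classed
#' `other`; a missing flanking base yields `not_applicable`.
#'
#' @param snvs Data frame with `chrom`, `pos`, `ref` columns.
#' @param model A `coding_model` (its genome is used).
#' @return Character vector of motif classes.
#' @export
quad_motif_class <- function(snvs, model) {
  chrom <- as.character(snvs$chrom)
  pos <- as.integer(snvs$pos)
  ref <- toupper(as.character(snvs$ref))
  chromlen <- nchar(model$genome)[chrom]
  out <- rep("other", length(pos))
  isC <- ref == "C"
  isG <- ref == "G"
  ok_c <- isC & pos - 2L >= 1L & pos + 1L <= chromlen
  ok_g <- isG & pos - 1L >= 1L & pos + 2L <= chromlen
  out[(isC & !ok_c) | (isG & !ok_g)] <- "not_applicable"
  if (any(ok_c)) {
    four <- substring(model$genome[chrom[ok_c]], pos[ok_c] - 2L, pos[ok_c] + 1L)
    out[ok_c] <- classify_quad(four)
  }
  if (any(ok_g)) {
    four <- revcomp(substring(model$genome[chrom[ok_g]], pos[ok_g] - 1L,
                              pos[ok_g] + 2L))
    out[ok_g] <- classify_quad(four)
  }
  out
}

classify_quad <- function(four) {
  ifelse(grepl("^[CT]TCA$", four), "YTCA",
         ifelse(grepl("^[AG]TCA$", four), "RTCA", "other"))
}
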