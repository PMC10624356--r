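#' The 96 SBS trinucleotide channels in catalog order
#'
#' Channels are ordered as in the COSMIC SBS catalog: substitution type
#' (C>A, C>G, C>T, T>A, T>C, T>G), then the 5' base (A, C, G, T), then the
#' 3' base (A, C, G, T). The mutated reference base is always a pyrimidine;
#' purine-reference substitutions are represented by their reverse
#' complement (see [normalize_channel()]).
#'
#' @return Character vector of 96 channel strings such as `"A[C>G]T"`.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  as.vector(vapply(subs, function(s) {
    as.vector(t(outer(.BASES, .BASES, function(f, t) paste0(f, "[", s, "]", t))))
  }, character(16)))
}

#' Pyrimidine-normalize a single-base substitution with its context
#'
#' Maps a substitution plus flanking bases onto one of the 96 SBS channels.
#' If the mutated reference base is a pyrimidine (C or T) the channel is the
#' input itself; if it is a purine the whole context is reverse complemented
#' (the flanks swap and complement, reference and alternate bases
#' complement), so that the stored reference base is always C or T.
#'
#' @param five_prime,ref,alt,three_prime Single bases (vectorized) in
#'   `A/C/G/T`; `alt` must differ from `ref`.
#' @return Character vector of channel strings, e.g. `"T[C>A]T"`.
#' @export
#' @examples
#' normalize_channel("T", "C", "G", "A") # unchanged
#' normalize_channel("A", "G", "T", "A") # reverse complemented: T[C>A]T
normalize_channel <- function(five_prime, ref, alt, three_prime) {
  five_prime <- check_bases(five_prime, "5' flank")
  ref <- check_bases(ref, "reference base")
  alt <- check_bases(alt, "alternate base")
  three_prime <- check_bases(three_prime, "3' flank")
  if (any(ref == alt)) stop_input("alt base must differ from ref base")
  purine <- ref %in% c("A", "G")
  f <- ifelse(purine, comp_base(three_prime), five_prime)
  r <- ifelse(purine, comp_base(ref), ref)
  a <- ifelse(purine, comp_base(alt), alt)
  t3 <- ifelse(purine, comp_base(five_prime), three_prime)
  paste0(f, "[", r, ">", a, "]", t3)
}

# Split channel strings into their components (5' flank, ref, alt, 3' flank).
parse_channel <- function(channel) {
  data.frame(
    five_prime = substr(channel, 1L, 1L),
    ref = substr(channel, 3L, 3L),
    alt = substr(channel, 5L, 5L),
    three_prime = substr(channel, 7L, 7L),
    stringsAsFactors = FALSE
  )
}

#' Enumerate single-base substitutions converting a codon to a stop codon
#'
#' For a sense codon of the standard genetic code, lists every single-base
#' substitution that yields one of the stop codons TAA, TAG or TGA. Rows are
#' ordered deterministically by codon position, then alphabetically by the
#' alternate base.
#'
#' @param codon A 3-character string over `A/C/G/T`; must not itself be a
#'   stop codon.
#' @return A data frame with columns `codon`, `position` (1-3), `ref`,
#'   `alt` and `stop_codon`; zero rows when no single substitution reaches a
#'   stop codon.
#' @export
#' @examples
#' stop_paths("TCA") # the serine codon reachable by two transversions
#' stop_paths("ATG") # empty: no single substitution yields a stop codon
stop_paths <- function(codon) {
  if (length(codon) != 1L || is.na(codon) || nchar(codon) != 3L) {
    stop_input("codon must be a single 3-base string")
  }
  codon <- toupper(codon)
  bases <- strsplit(codon, "", fixed = TRUE)[[1]]
  if (!all(bases %in% .BASES)) stop_input("codon contains bases outside A/C/G/T")
  if (codon %in% .STOP_CODONS) stop_domain("codon is already a stop codon")
  rows <- list()
  for (pos in 1:3) {
    for (alt in setdiff(.BASES, bases[pos])) {
      mutated <- bases
      mutated[pos] <- alt
      mut_codon <- paste(mutated, collapse = "")
      if (mut_codon %in% .STOP_CODONS) {
        rows[[length(rows) + 1L]] <- data.frame(
          codon = codon, position = pos, ref = bases[pos], alt = alt,
          stop_codon = mut_codon, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      codon = character(0), position = integer(0), ref = character(0),
      alt = character(0), stop_codon = character(0), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

#' Sense codons one substitution away from a stop codon
#'
#' @return Named integer vector: names are the sense codons with at least
#'   one single-base path to a stop codon, values are the number of such
#'   paths (consistent with [stop_paths()]).
#' @export
#' @examples
#' stop_reachable_codons()[c("TCA", "TCG", "GAA", "GAG")]
stop_reachable_codons <- function() {
  counts <- vapply(sense_codons(), function(cd) nrow(stop_paths(cd)), integer(1))
  counts[counts > 0L]
}

# All stop paths of all sense codons, one table (memoised in the namespace).
.stop_path_env <- new.env(parent = emptyenv())
stop_path_table <- function() {
  if (is.null(.stop_path_env$tab)) {
    tabs <- lapply(sense_codons(), stop_paths)
    .stop_path_env$tab <- do.call(rbind, tabs[vapply(tabs, nrow, integer(1)) > 0])
  }
  .stop_path_env$tab
}

# Enumerate the stop-gain sites of one gene: every CDS position/alt pair that
# converts its codon to a stop codon, with the genomic-context channel.
# Contexts use genomic flanking bases, so substitutions whose trinucleotide
# context spans two adjacent codons (e.g. Glu>Stop via N[G>T]A) are handled
# naturally. Sites at a contig edge (missing flank) are dropped.
gene_stop_sites <- function(model, gene_id) {
  g <- model$genes[[gene_id]]
  if (is.null(g)) stop_input(sprintf("gene '%s' not in coding model", gene_id))
  chromseq <- model$genome[[g$chrom]]
  len <- nchar(g$cds)
  n_codon <- len %/% 3L
  # exclude the terminal stop codon
  codons <- substring(g$cds, seq(1L, len - 3L, by = 3L), seq(3L, len - 3L, by = 3L))
  inst <- data.frame(codon_index = seq_along(codons), codon = codons,
                     stringsAsFactors = FALSE)
  paths <- stop_path_table()
  hits <- merge(inst, paths, by = "codon")
  if (nrow(hits) == 0L) return(NULL)
  tpos <- (hits$codon_index - 1L) * 3L + hits$position
  gpos <- g$gmap[tpos]
  # genomic-strand ref/alt
  minus <- g$strand == "-"
  ref_g <- if (minus) comp_base(hits$ref) else hits$ref
  alt_g <- if (minus) comp_base(hits$alt) else hits$alt
  ok <- gpos > 1L & gpos < nchar(chromseq)
  if (!any(ok)) return(NULL)
  hits <- hits[ok, , drop = FALSE]
  gpos <- gpos[ok]; ref_g <- ref_g[ok]; alt_g <- alt_g[ok]
  five <- substring(chromseq, gpos - 1L, gpos - 1L)
  three <- substring(chromseq, gpos + 1L, gpos + 1L)
  data.frame(
    gene_id = gene_id, chrom = g$chrom, pos = gpos,
    ref = ref_g, alt = alt_g,
    channel = normalize_channel(five, ref_g, alt_g, three),
    ref_aa = translate_codon(hits$codon),
    protein_position = hits$codon_index,
    stringsAsFactors = FALSE
  )
}

#' Expected amino-acid distribution of stop-gain mutations under a signature
#'
#' Given a 96-channel signature profile and a coding model, enumerates every
#' coding-sequence site at which a single-base substitution yields a stop
#' codon, weights each site/substitution by the profile probability of its
#' pyrimidine-normalized genomic-context channel, and aggregates the mass by
#' the amino acid being truncated. Sites are weighted uniformly across the
#' coding model (no per-gene mutation-rate weighting); trinucleotide
#' contexts are read from the genome, so they may span adjacent codons.
#'
#' @param profile Non-negative numeric vector of length 96 summing to 1;
#'   either named by channel strings or given in [sbs_channels()] order.
#' @param model A `coding_model` (see [build_coding_model()]).
#' @return Named numeric vector of probabilities over one-letter amino-acid
#'   codes, summing to 1; amino acids with zero mass are omitted.
#' @export
signature_stop_distribution <- function(profile, model) {
  profile <- as_profile(profile)
  if (!inherits(model, "coding_model") || length(model$genes) == 0L) {
    stop_input("model must be a non-empty coding_model")
  }
  mass <- numeric(0)
  for (gid in names(model$genes)) {
    sites <- gene_stop_sites(model, gid)
    if (is.null(sites)) next
    w <- profile[sites$channel]
    agg <- tapply(w, sites$ref_aa, sum)
    for (aa in names(agg)) {
      mass[aa] <- (if (aa %in% names(mass)) mass[aa] else 0) + agg[[aa]]
    }
  }
  total <- sum(mass)
  if (length(mass) == 0L || total <= 0) {
    stop_degenerate("no stop-reachable site carries profile mass in this coding model")
  }
  out <- mass[mass > 0] / total
  out[order(names(out))]
}

# Validate a 96-channel probability profile; returns it named by channel.
as_profile <- function(profile, tol = 1e-9) {
  chans <- sbs_channels()
  if (is.null(names(profile))) {
    if (length(profile) != 96L) stop_input("profile must have 96 channels")
    names(profile) <- chans
  } else {
    if (!setequal(names(profile), chans)) {
      stop_input("profile names must be the 96 SBS channels")
    }
    profile <- profile[chans]
  }
  if (any(profile < 0)) stop_input("profile must be non-negative")
  if (abs(sum(profile) - 1) > max(tol, 1e-9)) {
    stop_input("profile must sum to 1")
  }
  profile
}
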