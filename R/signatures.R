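#' Construct an SBS signature catalog
#'
#' @param profiles Numeric matrix: 96 rows named by channel strings (any
#'   order; reordered to [sbs_channels()] order), one column per signature.
#'   Columns must be non-negative and sum to 1 within `1e-3`; they are
#'   renormalized to sum exactly 1.
#' @return Object of class `sbs_catalog` (a 96 x k matrix).
#' @export
as_catalog <- function(profiles) {
  profiles <- as.matrix(profiles)
  chans <- sbs_channels()
  if (is.null(rownames(profiles)) || !setequal(rownames(profiles), chans) ||
      nrow(profiles) != 96L) {
    stop_format("catalog must have exactly the 96 SBS channels as row names")
  }
  if (is.null(colnames(profiles)) || anyDuplicated(colnames(profiles))) {
    stop_format("catalog signature names must be present and unique")
  }
  profiles <- profiles[chans, , drop = FALSE]
  if (any(profiles < 0)) stop_format("catalog profiles must be non-negative")
  sums <- colSums(profiles)
  if (any(abs(sums - 1) > 1e-3)) {
    stop_format(sprintf("catalog column(s) %s do not sum to 1",
                        paste(colnames(profiles)[abs(sums - 1) > 1e-3],
                              collapse = ", ")))
  }
  profiles <- sweep(profiles, 2, sums, "/")
  structure(profiles, class = c("sbs_catalog", "matrix"))
}

#' Read an SBS signature catalog from TSV
#'
#' First column holds the 96 channel strings (e.g. `"A[C>G]T"`), remaining
#' columns one signature profile each (COSMIC v3 layout).
#'
#' @param path File path.
#' @return An `sbs_catalog`.
#' @export
read_catalog <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2L) stop_format("catalog must have a channel column and >=1 signature")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop_format("catalog contains non-numeric or missing values")
  as_catalog(m)
}

#' Write an SBS signature catalog to TSV
#'
#' @param catalog An `sbs_catalog`.
#' @param path Output file path.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(channel = rownames(catalog), as.data.frame(unclass(catalog)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Coerce a spectrum (counts or probabilities) to a named 96-vector in
# canonical channel order.
as_spectrum_vector <- function(spectrum) {
  chans <- sbs_channels()
  if (is.null(names(spectrum))) {
    if (length(spectrum) != 96L) stop_input("spectrum must have 96 channels")
    names(spectrum) <- chans
  } else {
    if (!all(names(spectrum) %in% chans)) stop_input("unknown channel in spectrum")
    full <- stats::setNames(numeric(96), chans)
    full[names(spectrum)] <- spectrum
    spectrum <- full
  }
  if (any(spectrum < 0)) stop_input("spectrum must be non-negative")
  spectrum[chans]
}

#' Refit per-sample signature exposures by pruned non-negative least squares
#'
#' A deliberately simple single-sample refitting procedure: the normalized
#' 96-channel spectrum is regressed on the catalog profiles by non-negative
#' least squares, signatures receiving less than `prune` of the total weight
#' are removed, and the fit is repeated until the active set is stable. The
#' returned weights are normalized to sum to 1.
#'
#' @param spectrum 96-channel mutation counts (named by channel or in
#'   catalog order); total must be at least 1.
#' @param catalog An `sbs_catalog`.
#' @param prune Relative weight below which a signature is dropped between
#'   refits (default 0.01).
#' @return Named numeric vector over all catalog signatures (zero for pruned
#'   signatures) summing to 1.
#' @export
fit_exposures <- function(spectrum, catalog, prune = 0.01) {
  spectrum <- as_spectrum_vector(spectrum)
  if (sum(spectrum) < 1) stop_input("spectrum must contain at least one mutation")
  b <- spectrum / sum(spectrum)
  A <- unclass(catalog)
  sigs <- colnames(A)
  active <- sigs
  repeat {
    fit <- pracma::lsqnonneg(A[, active, drop = FALSE], b)
    w <- fit$x
    if (sum(w) <= 0) stop_degenerate("NNLS fit collapsed to zero weights")
    w <- w / sum(w)
    keep <- active[w >= prune]
    if (length(keep) == 0L) keep <- active[which.max(w)]
    if (length(keep) == length(active)) break
    active <- keep
  }
  out <- stats::setNames(numeric(length(sigs)), sigs)
  out[active] <- w
  out / sum(out)
}

# Per-channel posterior over signatures: weight(s) * profile_s(channel).
posterior_matrix <- function(exposures, catalog) {
  A <- unclass(catalog)
  if (is.null(names(exposures)) || !all(names(exposures) %in% colnames(A))) {
    stop_input("exposures must be named by catalog signatures")
  }
  w <- stats::setNames(numeric(ncol(A)), colnames(A))
  w[names(exposures)] <- exposures
  sweep(A, 2, w, "*")
}

#' Assign each SNV its most probable signature
#'
#' The per-SNV posterior is proportional to exposure weight times the
#' signature's profile probability of the SNV's channel. Ties go to the
#' alphabetically smallest signature name; a channel with zero posterior
#' mass under every signature yields `"unassigned"`.
#'
#' @param channels Character vector of SBS channel strings (`NA` allowed;
#'   yields `"unassigned"`).
#' @param exposures Named non-negative weights over catalog signatures.
#' @param catalog An `sbs_catalog`.
#' @return Character vector of signature labels.
#' @export
assign_top <- function(channels, exposures, catalog) {
  M <- posterior_matrix(exposures, catalog)
  M <- M[, order(colnames(M)), drop = FALSE]
  idx <- match(channels, rownames(M))
  out <- rep("unassigned", length(channels))
  ok <- !is.na(idx)
  if (any(ok)) {
    sub <- M[idx[ok], , drop = FALSE]
    best <- max.col(sub, ties.method = "first")
    lab <- colnames(M)[best]
    lab[rowSums(sub) <= 0] <- "unassigned"
    out[ok] <- lab
  }
  out
}

#' Draw one probabilistic signature assignment per SNV
#'
#' Each SNV's signature is drawn from the multinomial distribution with
#' probabilities proportional to exposure weight times profile probability
#' of its channel, reproducibly under `seed`.
#'
#' @inheritParams assign_top
#' @param seed Integer seed.
#' @return Character vector of signature labels (one draw).
#' @export
sample_assignments <- function(channels, exposures, catalog, seed) {
  M <- posterior_matrix(exposures, catalog)
  M <- M[, order(colnames(M)), drop = FALSE]
  idx <- match(channels, rownames(M))
  out <- rep("unassigned", length(channels))
  ok <- !is.na(idx)
  if (!any(ok)) return(out)
  sub <- M[idx[ok], , drop = FALSE]
  tot <- rowSums(sub)
  drawable <- tot > 0
  lab <- rep("unassigned", nrow(sub))
  if (any(drawable)) {
    P <- sub[drawable, , drop = FALSE] / tot[drawable]
    cum <- t(apply(P, 1, cumsum))
    u <- with_seed(seed, stats::runif(nrow(cum)))
    col <- rowSums(cum < u) + 1L
    lab[drawable] <- colnames(M)[col]
  }
  out[ok] <- lab
  out
}

#' Merge related COSMIC signature labels
#'
#' Collapses the clock-like signatures SBS5 and SBS40 to `SBS5/40`, the UV
#' signatures SBS7a-d to `SBS7`, the hypermutation signatures SBS10a/b to
#' `SBS10`, and SBS17a/b to `SBS17`. All other labels are unchanged.
#'
#' @param label Character vector of signature labels.
#' @return Character vector of merged labels.
#' @export
merge_labels <- function(label) {
  map <- c(SBS5 = "SBS5/40", SBS40 = "SBS5/40",
           SBS7a = "SBS7", SBS7b = "SBS7", SBS7c = "SBS7", SBS7d = "SBS7",
           SBS10a = "SBS10", SBS10b = "SBS10",
           SBS17a = "SBS17", SBS17b = "SBS17")
  merged <- unname(map[label])
  ifelse(is.na(merged), label, merged)
}

#' Tabulate a 96-channel mutation spectrum
#'
#' @param channels Character vector of channel strings; `NA` entries
#'   (undefined context) are dropped.
#' @return Named integer vector of counts over the 96 channels in catalog
#'   order.
#' @export
spectrum <- function(channels) {
  tab <- table(factor(channels[!is.na(channels)], levels = sbs_channels()))
  out <- as.integer(tab)
  names(out) <- sbs_channels()
  out
}

#' Cosine similarity of two 96-channel spectra
#'
#' @param spec_a,spec_b Non-negative numeric vectors of equal length with
#'   positive norm.
#' @return Cosine similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(spec_a, spec_b) {
  a <- as.numeric(spec_a); b <- as.numeric(spec_b)
  if (length(a) != length(b)) stop_input("spectra must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_input("spectra must have positive norm")
  sum(a * b) / (na * nb)
}

# Per-sample spectra -> exposures for a cohort of annotated SNVs.
# Returns a samples x signatures matrix.
cohort_exposures <- function(snvs, catalog, prune = 0.01) {
  samples <- sort(unique(snvs$sample_id))
  out <- matrix(0, length(samples), ncol(catalog),
                dimnames = list(samples, colnames(catalog)))
  for (s in samples) {
    sp <- spectrum(snvs$channel[snvs$sample_id == s])
    if (sum(sp) >= 1) out[s, ] <- fit_exposures(sp, catalog, prune = prune)
  }
  out
}

#' Assign top signatures across a cohort
#'
#' Fits per-sample exposures from each sample's own spectrum and labels every
#' SNV with its most probable signature (see [fit_exposures()],
#' [assign_top()]).
#'
#' @param snvs Annotated SNV data frame (needs `sample_id`, `channel`).
#' @param catalog An `sbs_catalog`.
#' @param prune Pruning threshold for [fit_exposures()].
#' @return List with `snvs` (input plus `signature_label` column) and
#'   `exposures` (samples x signatures matrix).
#' @export
assign_cohort <- function(snvs, catalog, prune = 0.01) {
  expo <- cohort_exposures(snvs, catalog, prune = prune)
  lab <- rep("unassigned", nrow(snvs))
  for (s in rownames(expo)) {
    i <- snvs$sample_id == s
    lab[i] <- assign_top(snvs$channel[i], expo[s, ], catalog)
  }
  snvs$signature_label <- lab
  list(snvs = snvs, exposures = expo)
}
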