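#' @keywords internal
"_PACKAGE"

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

abort_sgmsig <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sgmsig_error")))
}

stop_input <- function(msg) abort_sgmsig(msg, "sgmsig_input_error")
stop_format <- function(msg) abort_sgmsig(msg, "sgmsig_format_error")
stop_domain <- function(msg) abort_sgmsig(msg, "sgmsig_domain_error")
stop_degenerate <- function(msg) abort_sgmsig(msg, "sgmsig_degenerate_error")
stop_data <- function(msg) abort_sgmsig(msg, "sgmsig_data_error")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

check_bases <- function(x, what = "base") {
  x <- toupper(as.character(x))
  if (any(is.na(x)) || !all(x %in% .BASES)) {
    stop_input(sprintf("invalid %s: values must be one of A, C, G, T", what))
  }
  x
}

# Vectorized complement / reverse complement on plain character vectors.
comp_base <- function(x) unname(.COMP[x])

revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(unname(.COMP[strsplit(s, "", fixed = TRUE)[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Codon -> one-letter amino acid ("*" for stop), standard genetic code.
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

sense_codons <- function() {
  all64 <- names(Biostrings::GENETIC_CODE)
  setdiff(all64, .STOP_CODONS)
}
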