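# Shared sequence helpers. Coordinates are 0-based, half-open throughout.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split an in-frame ORF into codons
#'
#' @param orf nucleotide string, length divisible by 3.
#' @return character vector of codons.
#' @export
split_codons <- function(orf) {
  orf <- toupper(orf)
  n <- nchar(orf)
  if (n == 0L || n %% 3L != 0L)
    stop("ORF length (", n, ") is not a positive multiple of 3")
  substring(orf, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate an in-frame ORF to protein
#'
#' Standard genetic code; stop codons render as `*`.
#'
#' @param orf nucleotide string, length divisible by 3.
#' @return amino-acid string.
#' @export
translate_orf <- function(orf) {
  if (nchar(orf) %% 3L != 0L) stop("ORF not in frame")
  as.character(Biostrings::translate(Biostrings::DNAString(toupper(orf)),
                                     if.fuzzy.codon = "error"))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

is_stop_codon <- function(codon) toupper(codon) %in% STOP_CODONS

# Count occurrences of a motif on both strands of a sequence.
# A palindromic motif is counted once per site.
count_motif_both_strands <- function(seq, motif) {
  seq <- toupper(seq); motif <- toupper(motif)
  n_fwd <- length(gregexpr(motif, seq, fixed = TRUE)[[1L]])
  if (n_fwd == 1L && gregexpr(motif, seq, fixed = TRUE)[[1L]][1L] == -1L) n_fwd <- 0L
  rc <- revcomp(motif)
  if (rc == motif) return(n_fwd)
  hits <- gregexpr(rc, seq, fixed = TRUE)[[1L]]
  n_rev <- if (hits[1L] == -1L) 0L else length(hits)
  n_fwd + n_rev
}

# 0-based start positions of motif occurrences on the forward strand
motif_starts <- function(seq, motif) {
  hits <- gregexpr(toupper(motif), toupper(seq), fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}

# Derive an independent RNG seed (< 2^31) from a base seed and a string label,
# so that per-sample streams are stable when other samples are added/removed.
derive_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(as.character(label))) h <- (h * 131 + v) %% 2147483587
  as.integer((as.numeric(seed) %% 2147483587 * 7919 + h) %% 2147483587) + 1L
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(name, " must be a single number in [", min, ", ", max, "]")
  x
}
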