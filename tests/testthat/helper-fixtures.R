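# Shared fixtures: all inputs are built in code at test time.

usage_tbl <- read_codon_usage()
SENSE <- usage_tbl[usage_tbl$amino_acid != "*", ]

# Random in-frame ORF: ATG + uniformly sampled sense codons + one stop.
random_orf <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  body <- sample(SENSE$codon, n_codons, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(drscan:::AA_MASS), n, replace = TRUE), collapse = "")
}

# Independent exhaustive pairwise Hamming oracle (plain double loop).
hamming_oracle <- function(umis) {
  best <- Inf
  for (i in seq_along(umis)) {
    for (j in seq_len(i - 1L)) {
      a <- strsplit(umis[i], "")[[1L]]
      b <- strsplit(umis[j], "")[[1L]]
      best <- min(best, sum(a != b))
    }
  }
  best
}

# Independent brute-force minimal-dG window enumeration (mirrors the scan's
# contract, written with naive loops and its own tie-breaking bookkeeping).
dg_scan_bruteforce <- function(protein, coarse_start, coarse_end, flank = 5L,
                               length_range = c(17L, 25L), mode = "full") {
  lo <- max(0L, coarse_start - flank)
  hi <- min(nchar(protein), coarse_end + flank)
  cand <- list()
  for (len in length_range[1L]:length_range[2L]) {
    if (len > hi - lo) next
    for (s in lo:(hi - len)) {
      cand[[length(cand) + 1L]] <- list(
        start = s, end = s + len,
        dg = dg_apparent(substr(protein, s + 1L, s + len), mode = mode))
    }
  }
  dgs <- vapply(cand, `[[`, numeric(1), "dg")
  lens <- vapply(cand, function(c) c$end - c$start, numeric(1))
  starts <- vapply(cand, `[[`, numeric(1), "start")
  ord <- order(dgs, -lens, starts)
  cand[[ord[1L]]]
}
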