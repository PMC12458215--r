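# Barcoded expression-cassette design: Hamming-constrained UMI sets,
# HA-tag insertion, restriction-site silencing and cassette assembly.

#' UMI design constraints
#'
#' Defaults follow the library design used for pooled GPCR scanning:
#' 10-nt barcodes, minimum pairwise Hamming distance 4, maximum homopolymer
#' run 2, GC between 35% and 65%, and no start codon or common Golden-Gate /
#' cloning recognition sites on either strand (BsmBI, BsaI, EcoRI, XhoI,
#' NotI).
#'
#' @param length barcode length in nt.
#' @param min_hamming minimum pairwise Hamming distance within the set.
#' @param max_homopolymer maximum homopolymer run length.
#' @param gc_min,gc_max allowed GC-content fraction bounds.
#' @param forbidden_motifs motifs excluded on both strands.
#' @return object of class `umi_constraints`.
#' @export
umi_constraints <- function(length = 10L, min_hamming = 4L, max_homopolymer = 2L,
                            gc_min = 0.35, gc_max = 0.65,
                            forbidden_motifs = c("ATG", "CGTCTC", "GGTCTC",
                                                 "GAATTC", "CTCGAG", "GCGGCCGC")) {
  length <- as.integer(length)
  if (length <= 0L) stop("length must be > 0")
  if (gc_min < 0 || gc_max > 1 || gc_min > gc_max)
    stop("need 0 <= gc_min <= gc_max <= 1")
  if (min_hamming > length) stop("min_hamming cannot exceed length")
  if (max_homopolymer < 1L) stop("max_homopolymer must be >= 1")
  structure(list(length = length, min_hamming = as.integer(min_hamming),
                 max_homopolymer = as.integer(max_homopolymer),
                 gc_min = gc_min, gc_max = gc_max,
                 forbidden_motifs = toupper(forbidden_motifs)),
            class = "umi_constraints")
}

# Filter a base-index matrix (values 1..4 = A,C,G,T) against the per-sequence
# constraints; returns the surviving sequences as strings, plus a tally of
# how many candidates each filter removed (used in infeasibility errors).
filter_umi_candidates <- function(M, constraints) {
  L <- ncol(M)
  tally <- c(gc = 0L, homopolymer = 0L, motif = 0L)
  gc <- rowSums(M == 2L | M == 3L) / L
  keep <- gc >= constraints$gc_min & gc <= constraints$gc_max
  tally["gc"] <- sum(!keep)
  M <- M[keep, , drop = FALSE]
  if (nrow(M) && constraints$max_homopolymer < L) {
    h <- constraints$max_homopolymer
    run <- matrix(TRUE, nrow(M), L - h)
    for (j in seq_len(h)) run <- run & (M[, 1:(L - h), drop = FALSE] ==
                                        M[, (1 + j):(L - h + j), drop = FALSE])
    bad <- rowSums(run) > 0L
    tally["homopolymer"] <- sum(bad)
    M <- M[!bad, , drop = FALSE]
  }
  if (!nrow(M)) return(list(seqs = character(0), tally = tally))
  seqs <- do.call(paste0, as.data.frame(matrix(BASES[M], nrow(M), L)))
  for (motif in unique(constraints$forbidden_motifs)) {
    for (m in unique(c(motif, revcomp(motif)))) {
      bad <- grepl(m, seqs, fixed = TRUE)
      tally["motif"] <- tally["motif"] + sum(bad)
      seqs <- seqs[!bad]
    }
  }
  list(seqs = seqs, tally = tally)
}

#' Generate a maximally differentiable UMI set
#'
#' Builds `n` barcodes satisfying all per-sequence constraints (GC window,
#' homopolymer cap, forbidden motifs on both strands) and a minimum pairwise
#' Hamming distance. The default `"exhaustive"` method enumerates all 4^L
#' candidates, filters them, then selects greedily in a seeded random order
#' with pairwise-distance rejection; `"greedy"` samples candidates at random
#' instead of enumerating (the scalable path for longer barcodes).
#'
#' @param n number of UMIs requested.
#' @param constraints a [umi_constraints()] object.
#' @param seed RNG seed; the set is bit-reproducible given the seed.
#' @param method `"exhaustive"` (default, feasible to L ~ 12) or `"greedy"`.
#' @param max_tries candidate draws for the greedy method.
#' @return character vector of `n` barcodes.
#' @export
generate_umi_set <- function(n, constraints = umi_constraints(), seed = 1L,
                             method = c("exhaustive", "greedy"),
                             max_tries = 1e6) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  L <- constraints$length
  set.seed(seed)
  if (method == "exhaustive") {
    if (L > 12L) stop("exhaustive enumeration is limited to length <= 12; use method='greedy'")
    M <- as.matrix(expand.grid(rep(list(1:4), L), KEEP.OUT.ATTRS = FALSE))
    res <- filter_umi_candidates(M, constraints)
    pool <- res$seqs
    if (length(pool) < n)
      stop("infeasible request: only ", length(pool), " candidates pass the ",
           "per-sequence filters (removed by GC: ", res$tally["gc"],
           ", homopolymer: ", res$tally["homopolymer"],
           ", motif: ", res$tally["motif"], ")")
    pool <- pool[sample.int(length(pool))]
  } else {
    draws <- matrix(sample.int(4L, max_tries * L, replace = TRUE), ncol = L)
    pool <- filter_umi_candidates(draws, constraints)$seqs
  }
  sel <- matrix(0L, n, L)
  k <- 0L
  for (s in pool) {
    v <- match(strsplit(s, "")[[1L]], BASES)
    if (k > 0L) {
      d <- rowSums(sel[seq_len(k), , drop = FALSE] !=
                   matrix(v, k, L, byrow = TRUE))
      if (any(d < constraints$min_hamming)) next
    }
    k <- k + 1L
    sel[k, ] <- v
    if (k == n) break
  }
  if (k < n)
    stop("infeasible request: pairwise Hamming distance >= ",
         constraints$min_hamming, " is the binding constraint; only ", k,
         " of ", n, " barcodes selected from ", length(pool),
         " filtered candidates")
  do.call(paste0, as.data.frame(matrix(BASES[sel], n, L)))
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' Exhaustive all-pairs computation; the design oracle for generated sets.
#'
#' @param umis character vector of equal-length barcodes.
#' @return smallest pairwise Hamming distance (Inf for a single barcode).
#' @export
min_pairwise_hamming <- function(umis) {
  if (length(umis) < 2L) return(Inf)
  if (length(unique(nchar(umis))) != 1L) stop("barcodes must have equal length")
  M <- do.call(rbind, strsplit(umis, ""))
  best <- Inf
  for (i in seq_len(nrow(M) - 1L)) {
    d <- rowSums(M[(i + 1L):nrow(M), , drop = FALSE] !=
                 matrix(M[i, ], nrow(M) - i, ncol(M), byrow = TRUE))
    best <- min(best, d)
  }
  best
}

# Nucleotide sequence of the influenza HA nonapeptide tag YPYDVPDYA
HA_TAG_NT <- "TACCCATACGATGTTCCAGATTACGCT"

#' Insert an epitope tag after a given codon
#'
#' Inserts `tag_nt` into an ORF after `insertion_codon_index` codons. The
#' default index 2 places the tag after the start codon and the second codon,
#' the rule used for receptors without a cleavable signal peptide (class A
#' and olfactory); for signal-peptide receptors the caller supplies the
#' index derived from the predicted cleavage site.
#'
#' @param orf in-frame nucleotide sequence starting with ATG.
#' @param insertion_codon_index number of leading codons kept before the tag
#'   (in `[1, codon count)`).
#' @param tag_nt in-frame tag sequence (default: HA tag, YPYDVPDYA).
#' @return tagged nucleotide sequence.
#' @export
insert_ha_tag <- function(orf, insertion_codon_index = 2L, tag_nt = HA_TAG_NT) {
  orf <- toupper(orf); tag_nt <- toupper(tag_nt)
  codons <- split_codons(orf)
  if (codons[1L] != "ATG") stop("ORF must start with ATG")
  if (nchar(tag_nt) %% 3L != 0L) stop("tag length must be divisible by 3 (frame-preserving)")
  i <- as.integer(insertion_codon_index)
  if (i < 1L || i >= length(codons))
    stop("insertion_codon_index must be in [1, ", length(codons), ")")
  if (!nzchar(tag_nt)) return(orf)
  paste0(paste(codons[seq_len(i)], collapse = ""), tag_nt,
         paste(codons[(i + 1L):length(codons)], collapse = ""))
}

#' Silence restriction-recognition sites with synonymous substitutions
#'
#' Removes every occurrence of `recognition` (searched on both strands) from
#' an in-frame ORF by recoding codons it spans. At each site the
#' highest-frequency synonymous codon that removes the site (without
#' creating a new one) is chosen; alternatives are tried in descending
#' frequency order, and two-codon edits only when no single edit suffices.
#' The encoded protein is unchanged.
#'
#' @param orf in-frame nucleotide sequence.
#' @param recognition recognition sequence (e.g. BsmBI "CGTCTC").
#' @param usage a [read_codon_usage()] table.
#' @return recoded nucleotide sequence with no recognition site on either
#'   strand.
#' @export
silence_sites <- function(orf, recognition = "CGTCTC",
                          usage = read_codon_usage()) {
  orf <- toupper(orf); recognition <- toupper(recognition)
  if (nchar(orf) %% 3L != 0L) stop("ORF not in frame")
  fam <- split(seq_len(nrow(usage)), usage$amino_acid)
  site_hits <- function(s) {
    hits <- motif_starts(s, recognition)
    rc <- revcomp(recognition)
    if (rc != recognition) hits <- sort(c(hits, motif_starts(s, rc)))
    hits
  }
  for (iter in 1:100) {
    codons <- split_codons(orf)
    hits <- site_hits(orf)
    if (!length(hits)) return(orf)
    pos <- hits[1L]
    span <- (pos %/% 3L + 1L):((pos + nchar(recognition) - 1L) %/% 3L + 1L)
    # candidate synonymous replacements, best (most frequent) first
    cands <- do.call(rbind, lapply(span, function(ci) {
      aa <- usage$amino_acid[usage_lookup(usage, codons[ci])]
      alt <- fam[[aa]]
      alt <- alt[usage$codon[alt] != codons[ci]]
      if (!length(alt)) return(NULL)
      data.frame(ci = ci, codon = usage$codon[alt],
                 freq = usage$freq_per_thousand[alt])
    }))
    edited <- FALSE
    try_edit <- function(edits) {
      new <- codons
      new[edits$ci] <- edits$codon
      s <- paste(new, collapse = "")
      # the edit must remove this site and not increase the total site count
      if (length(site_hits(s)) < length(hits)) s else NULL
    }
    if (!is.null(cands)) {
      cands <- cands[order(-cands$freq), , drop = FALSE]
      for (r in seq_len(nrow(cands))) {
        s <- try_edit(cands[r, , drop = FALSE])
        if (!is.null(s)) { orf <- s; edited <- TRUE; break }
      }
      if (!edited && nrow(cands) > 1L) {
        # pairs of codon edits, ordered by combined frequency
        pr <- expand.grid(a = seq_len(nrow(cands)), b = seq_len(nrow(cands)))
        pr <- pr[cands$ci[pr$a] < cands$ci[pr$b], , drop = FALSE]
        if (nrow(pr)) {
          pr <- pr[order(-(cands$freq[pr$a] + cands$freq[pr$b])), , drop = FALSE]
          for (r in seq_len(nrow(pr))) {
            s <- try_edit(cands[c(pr$a[r], pr$b[r]), , drop = FALSE])
            if (!is.null(s)) { orf <- s; edited <- TRUE; break }
          }
        }
      }
    }
    if (!edited)
      stop("recognition site at 0-based position ", pos,
           " cannot be removed by synonymous substitution (codons ",
           paste(span, collapse = ","), ")")
  }
  stop("site silencing did not converge")
}

#' Replace the native stop with a single glycine codon plus stop
#'
#' Strips all contiguous native C-terminal glycine codons (preventing
#' non-native diglycine motifs), then appends `gly_codon` followed by the
#' ORF's native stop codon, so the encoded protein ends in exactly one Gly.
#'
#' @param orf in-frame nucleotide sequence ending in a stop codon.
#' @param gly_codon glycine codon to append (default GGC, the most frequent
#'   human Gly codon).
#' @return recoded nucleotide sequence.
#' @export
terminal_glycine_swap <- function(orf, gly_codon = "GGC") {
  codons <- split_codons(orf)
  n <- length(codons)
  if (!is_stop_codon(codons[n])) stop("ORF does not end in a stop codon")
  gly_codon <- toupper(gly_codon)
  if (translate_orf(gly_codon) != "G") stop("gly_codon must encode glycine")
  stop_codon <- codons[n]
  body <- codons[-n]
  while (length(body) && translate_orf(body[length(body)]) == "G")
    body <- body[-length(body)]
  paste(c(body, gly_codon, stop_codon), collapse = "")
}

#' Assemble a barcoded expression cassette
#'
#' Concatenates, 5' to 3': enzyme recognition site, UMI, attB recombination
#' site, ORF (already tag-inserted, site-silenced and glycine-swapped) and a
#' 3' enzyme site in reverse orientation. Errors if the junctions introduce
#' extraneous recognition occurrences (the assembled cassette must contain
#' exactly two, counting both strands).
#'
#' @param umi barcode sequence.
#' @param orf processed ORF ending in Gly + stop.
#' @param attb attB recombination site sequence (may be an empty placeholder).
#' @param enzyme_site recognition sequence (default BsmBI "CGTCTC").
#' @return list of class `cassette` with `sequence` and an `elements` data
#'   frame (element, start, end; 0-based half-open, tiling the sequence).
#' @export
assemble_cassette <- function(umi, orf, attb, enzyme_site = "CGTCTC") {
  umi <- toupper(umi); orf <- toupper(orf); attb <- toupper(attb)
  enzyme_site <- toupper(enzyme_site)
  codons <- split_codons(orf)
  if (!is_stop_codon(codons[length(codons)]))
    stop("ORF must end in a stop codon")
  if (sum(is_stop_codon(codons)) != 1L)
    stop("ORF must contain exactly one stop codon (at its 3' end)")
  parts <- c(enzyme_site_5 = enzyme_site, umi = umi, attb = attb, orf = orf,
             enzyme_site_3 = revcomp(enzyme_site))
  seqc <- paste(parts, collapse = "")
  ends <- cumsum(nchar(parts))
  elements <- data.frame(element = names(parts),
                         start = c(0L, head(ends, -1L)), end = ends,
                         row.names = NULL)
  n_sites <- count_motif_both_strands(seqc, enzyme_site)
  if (n_sites != 2L)
    stop("assembled cassette contains ", n_sites,
         " enzyme recognition occurrences (expected exactly 2); ",
         "junction or internal site must be resolved")
  structure(list(sequence = seqc, elements = elements,
                 enzyme_site = enzyme_site), class = "cassette")
}

#' Write cassettes to FASTA and their element maps to BED-like TSV
#'
#' @param cassettes named list of [assemble_cassette()] results.
#' @param fasta_path,map_path output paths.
#' @param config optional [run_config()] for the TSV provenance header.
#' @export
write_cassettes <- function(cassettes, fasta_path, map_path, config = NULL) {
  seqs <- vapply(cassettes, `[[`, character(1), "sequence")
  write_fasta(seqs, fasta_path)
  maps <- do.call(rbind, lapply(names(cassettes), function(id) {
    cbind(cassette = id, cassettes[[id]]$elements)
  }))
  write_tsv(maps, map_path, config)
  invisible(list(fasta = fasta_path, map = map_path))
}
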