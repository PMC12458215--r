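# Per-receptor feature extraction: topology, physicochemistry, transcript
# descriptors and secondary-structure fractions.

# Average residue masses (Da) and Kyte-Doolittle hydropathy values.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                    E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                    M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                    Y = -1.3, V = 4.2)
WATER_MASS <- 18.01524

# Side-chain and terminal pKa values for the Henderson-Hasselbalch pI.
PKA_POS <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEG <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

net_charge_at_ph <- function(counts, ph) {
  pos <- sum(counts[names(PKA_POS)] / (1 + 10^(ph - PKA_POS)))
  neg <- sum(counts[names(PKA_NEG)] / (1 + 10^(PKA_NEG - ph)))
  pos - neg
}

load_diwv <- function() {
  path <- system.file("extdata", "instability_dipeptide_weights.tsv",
                      package = "drscan", mustWork = TRUE)
  df <- read_tsv(path, required_cols = c("first", "second", "weight"))
  m <- matrix(0, 20L, 20L, dimnames = list(sort(unique(df$first)),
                                           sort(unique(df$second))))
  m[cbind(df$first, df$second)] <- df$weight
  m
}
.diwv_cache <- new.env(parent = emptyenv())

#' Physicochemical properties of a protein sequence
#'
#' Molecular weight (average residue masses + one water), isoelectric point
#' (bisection on the Henderson-Hasselbalch net charge with a standard pKa
#' set), aromaticity (fraction of Phe/Trp/Tyr), the dipeptide-composition
#' instability index (published dipeptide weights, scaled by 10/L), and the
#' GRAVY score (mean Kyte-Doolittle hydropathy).
#'
#' @param protein amino-acid string, standard 20-residue alphabet.
#' @return named numeric: mw, pi, aromaticity, instability, gravy.
#' @export
sequence_properties <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  bad <- setdiff(aa, names(AA_MASS))
  if (length(bad)) stop("nonstandard residue(s): ", paste(unique(bad), collapse = ","))
  L <- length(aa)
  counts <- table(factor(aa, levels = names(AA_MASS)))
  grp <- c(Nterm = 1, Cterm = 1, counts[c("K", "R", "H", "D", "E", "C", "Y")])
  names(grp) <- c("Nterm", "Cterm", "K", "R", "H", "D", "E", "C", "Y")
  lo <- 0; hi <- 14
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (net_charge_at_ph(grp, mid) > 0) lo <- mid else hi <- mid
  }
  pi_val <- (lo + hi) / 2
  if (is.null(.diwv_cache$m)) .diwv_cache$m <- load_diwv()
  instab <- if (L >= 2L)
    10 / L * sum(.diwv_cache$m[cbind(aa[-L], aa[-1L])]) else NA_real_
  c(mw = sum(AA_MASS[aa]) + WATER_MASS,
    pi = pi_val,
    aromaticity = mean(aa %in% c("F", "W", "Y")),
    instability = instab,
    gravy = mean(KYTE_DOOLITTLE[aa]))
}

#' Topological feature vector from seven refined TMD segments
#'
#' Emits the fixed 27-feature topological schema: normalized lengths and
#' dG_app of TMD1-7, normalized lengths of the six connecting loops
#' (ICL1, ECL1, ICL2, ECL2, ICL3, ECL3), normalized N-/C-tail lengths,
#' total normalized TMD and loop lengths, mean and minimum TMD dG_app, and
#' the protein length. All length features are divided by the full
#' processed protein length, so TMD + loop + tail features partition to 1.
#'
#' @param protein full amino-acid sequence.
#' @param tmds data.frame with columns `start`, `end` (0-based half-open)
#'   and `dg`, exactly 7 ordered, non-overlapping rows — e.g. from
#'   [dg_scan()] applied to each coarse TMD. Receptors lacking all seven
#'   TMDs are rejected (flag them incomplete upstream).
#' @return named numeric vector of 27 features.
#' @export
topology_feature_vector <- function(protein, tmds) {
  n <- nchar(protein)
  if (nrow(tmds) != 7L)
    stop("exactly 7 TMD segments required (got ", nrow(tmds), "); receptor incomplete")
  if (any(diff(as.vector(rbind(tmds$start, tmds$end))) < 0))
    stop("TMD segments must be ordered and non-overlapping")
  if (tmds$start[1L] < 0L || tmds$end[7L] > n) stop("TMD outside the protein")
  tmd_len <- (tmds$end - tmds$start) / n
  loop_len <- (tmds$start[-1L] - tmds$end[-7L]) / n
  ntail <- tmds$start[1L] / n
  ctail <- (n - tmds$end[7L]) / n
  out <- c(setNames(tmd_len, paste0("tmd", 1:7, "_norm_len")),
           setNames(tmds$dg, paste0("tmd", 1:7, "_dg")),
           setNames(loop_len, c("icl1_norm_len", "ecl1_norm_len",
                                "icl2_norm_len", "ecl2_norm_len",
                                "icl3_norm_len", "ecl3_norm_len")),
           ntail_norm_len = ntail, ctail_norm_len = ctail,
           tmd_total_norm_len = sum(tmd_len),
           loop_total_norm_len = sum(loop_len),
           dg_mean = mean(tmds$dg), dg_min = min(tmds$dg),
           protein_length = n)
  out
}

#' Transcript descriptor vector
#'
#' A fixed, documented descriptor set for an in-frame ORF: length, overall
#' and per-codon-position GC (GC1/GC2/GC3), %MinMax-derived common/rare
#' codon fractions and profile summaries, per-base composition, GC/AT skew,
#' CpG dinucleotide density, 5'-region (first 50 codons) GC and common-codon
#' fraction, and per-base maximum homopolymer runs.
#'
#' @param orf in-frame nucleotide sequence.
#' @param usage a [read_codon_usage()] table.
#' @param window %MinMax window (default 17).
#' @return named numeric vector (stable schema across inputs).
#' @export
transcript_feature_vector <- function(orf, usage = read_codon_usage(),
                                      window = 17L) {
  orf <- toupper(orf)
  codons <- split_codons(orf)
  b <- strsplit(orf, "")[[1L]]
  n <- length(b)
  pos_gc <- function(k) {
    bb <- substr(codons, k, k)
    mean(bb %in% c("G", "C"))
  }
  prof <- minmax_profile(orf, usage, window = min(window, length(codons) -
                           (1 - length(codons) %% 2L)))
  has_windows <- any(!is.na(prof))
  fr <- if (has_windows) codon_class_fractions(prof)
        else c(f_common = NA_real_, f_rare = NA_real_)
  runs <- rle(b)
  maxrun <- vapply(BASES, function(base) {
    r <- runs$lengths[runs$values == base]
    if (length(r)) max(r) else 0L
  }, numeric(1))
  five <- substr(orf, 1L, min(n, 150L))
  five_codons <- min(length(codons), 50L)
  w5 <- min(window, five_codons - (1 - five_codons %% 2L))
  f_common5 <- if (w5 >= 1L && five_codons >= w5)
    tryCatch(codon_class_fractions(
      minmax_profile(substr(orf, 1L, five_codons * 3L), usage, w5))[["f_common"]],
      error = function(e) NA_real_)
  else NA_real_
  gcs <- sum(b == "G") - sum(b == "C")
  ats <- sum(b == "A") - sum(b == "T")
  c(length_nt = n,
    gc = as.numeric(gc_content(orf)),
    gc1 = pos_gc(1L), gc2 = pos_gc(2L), gc3 = pos_gc(3L),
    f_common = fr[["f_common"]], f_rare = fr[["f_rare"]],
    minmax_mean = if (has_windows) mean(prof, na.rm = TRUE) else NA_real_,
    minmax_min = if (has_windows) min(prof, na.rm = TRUE) else NA_real_,
    minmax_max = if (has_windows) max(prof, na.rm = TRUE) else NA_real_,
    frac_a = mean(b == "A"), frac_c = mean(b == "C"),
    frac_g = mean(b == "G"), frac_t = mean(b == "T"),
    gc_skew = if (sum(b %in% c("G", "C"))) gcs / sum(b %in% c("G", "C")) else 0,
    at_skew = if (sum(b %in% c("A", "T"))) ats / sum(b %in% c("A", "T")) else 0,
    cpg_density = length(motif_starts(orf, "CG")) / (n - 1L),
    gc_5prime = as.numeric(gc_content(five)),
    f_common_5prime = f_common5,
    homopolymer_a = maxrun[["A"]], homopolymer_c = maxrun[["C"]],
    homopolymer_g = maxrun[["G"]], homopolymer_t = maxrun[["T"]])
}

SS_CODES <- c("H", "G", "E", "B", "T", "C")

#' Secondary-structure class fractions
#'
#' Per-residue fractions of alpha-helix (H), 3-10 helix (G), extended
#' strand (E), isolated beta-bridge (B), turn (T) and coil (C). Pi-helix
#' (I) is mapped to H.
#'
#' @param assignment character vector (or single string) of one-letter codes.
#' @return named numeric(6), summing to 1.
#' @export
ss_fractions <- function(assignment) {
  if (length(assignment) == 1L && nchar(assignment) > 1L)
    assignment <- strsplit(assignment, "")[[1L]]
  codes <- toupper(assignment)
  codes[codes == "I"] <- "H"
  bad <- setdiff(codes, SS_CODES)
  if (length(bad)) stop("unknown secondary-structure code(s): ",
                        paste(unique(bad), collapse = ","))
  tab <- table(factor(codes, levels = SS_CODES))
  setNames(as.numeric(tab) / length(codes), paste0("ss_", tolower(SS_CODES)))
}
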