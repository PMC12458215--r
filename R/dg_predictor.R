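# Translocon-mediated membrane insertion energetics: the biological
# hydrophobicity scale and the apparent free energy (dG_app) predictor used
# to refine transmembrane-segment boundaries.

# Central (position-independent) per-residue dG_app contributions of the
# biological hydrophobicity scale, kcal/mol (19-residue host segment,
# membrane-center position).
DG_CENTER_SCALE <- c(
  A = 0.11, C = -0.13, D = 3.49, E = 2.68, F = -0.32, G = 0.74, H = 2.06,
  I = -0.60, K = 2.71, L = -0.55, M = -0.10, N = 2.05, P = 2.23, Q = 2.36,
  R = 2.58, S = 0.84, T = 0.52, V = -0.31, W = 0.30, Y = 0.68)

# Position-dependent profile coefficients of the full dG predictor. Each
# residue contributes dg0 * exp(-dg1 * pos^2) at scaled position pos in
# [-9, 9]; the aromatics Trp and Tyr carry an additional symmetric pair of
# interface Gaussians dg2 * (exp(-dg3 (pos - dg4)^2) + exp(-dg3 (pos + dg4)^2)).
DG_PROFILE <- list(
  A = c(0.1267255, 0.0215152),
  C = c(-0.0765051, 0.0994228),
  D = c(1.7939795, 0.0172643),
  E = c(1.4193720, 0.0089351),
  F = c(-0.2766953, 0.0010297),
  G = c(0.4813492, 0.0047210),
  H = c(1.1998590, 0.0080127),
  I = c(-0.4597384, 0.0181495),
  K = c(1.8485768, 0.0218446),
  L = c(-0.4282992, 0.0023804),
  M = c(-0.0774786, 0.0984413),
  N = c(1.3266132, 0.0092375),
  P = c(1.0860888, 0.0100568),
  Q = c(1.3336109, 0.0111996),
  R = c(1.6492534, 0.0512044),
  S = c(0.7023921, 0.0077661),
  T = c(0.5266550, 0.0311973),
  V = c(-0.2447218, 0.0979201),
  W = c(0.2909390, 0.0189282, -0.5479140, 0.0930222, 6.4736619),
  Y = c(0.6275249, 0.0103896, -0.5744404, 0.0947821, 6.9164963))

# Helical hydrophobic-moment coefficient and length-correction polynomial
# of the full predictor.
DG_MU_COEF <- 0.27045
DG_LEN_CORR <- function(L) 9.29 - 0.645 * L + 0.00822 * L^2

# Per-residue position-specific contributions for a segment (internal).
dg_position_contribs <- function(aa, L) {
  pos <- if (L == 1L) 0 else 9 * (2 * (seq_len(L) - 1L) / (L - 1L) - 1)
  vapply(seq_len(L), function(i) {
    p <- DG_PROFILE[[aa[i]]]
    v <- p[1L] * exp(-p[2L] * pos[i]^2)
    if (length(p) == 5L)
      v <- v + p[3L] * (exp(-p[4L] * (pos[i] - p[5L])^2) +
                        exp(-p[4L] * (pos[i] + p[5L])^2))
    v
  }, numeric(1))
}

#' Apparent free energy of translocon-mediated membrane insertion
#'
#' Predicted dG_app (kcal/mol) of a candidate transmembrane segment
#' according to the biological hydrophobicity scale. Negative values mean
#' efficient membrane insertion. The default `"full"` mode sums
#' position-dependent per-residue contributions (Gaussian depth profiles,
#' with interface terms for Trp/Tyr), adds a helical hydrophobic-moment
#' term and a segment-length correction; `"sum"` is the plain sum of the
#' central scale values.
#'
#' @param segment amino-acid string (standard 20-residue alphabet).
#' @param mode `"full"` (default) or `"sum"`.
#' @return dG_app in kcal/mol.
#' @export
dg_apparent <- function(segment, mode = c("full", "sum")) {
  mode <- match.arg(mode)
  aa <- strsplit(toupper(segment), "")[[1L]]
  L <- length(aa)
  if (L < 1L) stop("empty segment")
  bad <- setdiff(aa, names(DG_CENTER_SCALE))
  if (length(bad)) stop("unsupported residue(s): ", paste(unique(bad), collapse = ","))
  if (mode == "sum") return(sum(DG_CENTER_SCALE[aa]))
  g <- dg_position_contribs(aa, L)
  ang <- 100.0 * (seq_len(L) - 1L) * pi / 180
  mu <- sqrt(sum(g * sin(ang))^2 + sum(g * cos(ang))^2)
  sum(g) + DG_MU_COEF * mu + DG_LEN_CORR(L)
}

#' Refine a transmembrane segment by minimal-dG scanning
#'
#' Scans every allowed window within a coarse TMD region (extended by
#' `flank` residues on each side) and returns the segment minimizing
#' [dg_apparent()]. Ties are broken toward the longer window, then the
#' smaller start. Coordinates are 0-based half-open.
#'
#' @param protein full amino-acid sequence.
#' @param coarse_start,coarse_end coarse TMD interval (0-based half-open),
#'   e.g. from a topology predictor.
#' @param flank residues the scan may extend beyond the coarse region
#'   (default 5).
#' @param length_range allowed segment lengths (default 17-25 residues).
#' @param mode passed to [dg_apparent()].
#' @return list of class `tmd_segment`: start, end, dg, sequence.
#' @export
dg_scan <- function(protein, coarse_start, coarse_end, flank = 5L,
                    length_range = c(17L, 25L), mode = "full") {
  n <- nchar(protein)
  if (coarse_start < 0L || coarse_end > n || coarse_start >= coarse_end)
    stop("coarse region must be a non-empty interval within the protein")
  if (flank < 0L) stop("flank must be >= 0")
  lo <- max(0L, coarse_start - as.integer(flank))
  hi <- min(n, coarse_end + as.integer(flank))
  lmin <- as.integer(length_range[1L]); lmax <- as.integer(length_range[2L])
  if (hi - lo < lmin)
    stop("scan region (", hi - lo, " residues) shorter than minimum segment length ", lmin)
  best <- NULL
  for (len in lmin:min(lmax, hi - lo)) {
    for (start in lo:(hi - len)) {
      seg <- substr(protein, start + 1L, start + len)
      dg <- dg_apparent(seg, mode = mode)
      if (is.null(best) || dg < best$dg ||
          (dg == best$dg && (len > best$end - best$start ||
                             (len == best$end - best$start && start < best$start)))) {
        best <- list(start = start, end = start + len, dg = dg, sequence = seg)
      }
    }
  }
  structure(best, class = "tmd_segment")
}
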