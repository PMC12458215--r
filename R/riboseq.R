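# Ribosome-profiling metagene analysis: footprint length gating, 100-bin
# metagene profiles, coverage Z-scores and RNA-Seq mock normalization.

#' Classify ribosome-protected fragments by length
#'
#' Fragments of 28-38 nt are monosomes (a single ribosome), 50-70 nt are
#' disomes (a collided ribosome pair); everything else is discarded. Bounds
#' are inclusive.
#'
#' @param length integer vector of fragment lengths (nt).
#' @param monosome_range,disome_range inclusive length windows.
#' @return character vector: "monosome", "disome" or "discard".
#' @export
classify_footprint <- function(length, monosome_range = c(28L, 38L),
                               disome_range = c(50L, 70L)) {
  if (any(length <= 0)) stop("fragment lengths must be > 0")
  out <- rep("discard", base::length(length))
  out[length >= monosome_range[1L] & length <= monosome_range[2L]] <- "monosome"
  out[length >= disome_range[1L] & length <= disome_range[2L]] <- "disome"
  out
}

#' Metagene profile over 100 relative-position bins
#'
#' Pools footprints of one class across transcripts, assigning each fragment
#' to bin `floor(n_bins * anchor / CDS_length)` (clipped to the last bin),
#' where the anchor is the fragment 5' end plus an optional fixed P-site
#' offset. Bin values are fragments per million mapped fragments per
#' nucleotide, where the per-bin nucleotide span is the mean CDS length of
#' the pooled transcripts divided by `n_bins`, and the per-million
#' denominator is the library total supplied in `total_mapped` (all
#' class-assigned fragments) so that per-class profiles are comparable.
#'
#' @param fragments data.frame with columns `transcript`, `start` (0-based
#'   5' offset in the CDS) and `length` (nt).
#' @param cds_lengths named integer vector of CDS lengths (nt).
#' @param class_filter "monosome" or "disome".
#' @param n_bins number of bins (default 100).
#' @param p_site_offset fixed anchor offset in nt (default 0; no offsetting).
#' @param total_mapped per-million denominator; default = all monosome +
#'   disome fragments in `fragments`.
#' @return data.frame of class `meta_profile` (bin, density) with
#'   attributes: class, n_assigned, n_dropped, total_mapped, bin_span.
#' @export
metagene_profile <- function(fragments, cds_lengths,
                             class_filter = c("monosome", "disome"),
                             n_bins = 100L, p_site_offset = 0L,
                             total_mapped = NULL) {
  class_filter <- match.arg(class_filter)
  stopifnot(all(c("transcript", "start", "length") %in% names(fragments)))
  unknown <- setdiff(unique(fragments$transcript), names(cds_lengths))
  if (length(unknown))
    stop("transcript(s) without a CDS length: ", paste(head(unknown, 5), collapse = ", "))
  cls <- classify_footprint(fragments$length)
  if (is.null(total_mapped)) total_mapped <- sum(cls != "discard")
  if (total_mapped <= 0) stop("no mapped fragments in denominator")
  f <- fragments[cls == class_filter, , drop = FALSE]
  len <- cds_lengths[f$transcript]
  anchor <- f$start + p_site_offset
  ok <- anchor >= 0 & anchor < len
  n_dropped <- sum(!ok)
  f <- f[ok, , drop = FALSE]; anchor <- anchor[ok]; len <- len[ok]
  bin <- pmin(floor(n_bins * anchor / len), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  pooled <- unique(f$transcript)
  bin_span <- if (length(pooled)) mean(cds_lengths[pooled]) / n_bins else NA_real_
  density <- counts / total_mapped * 1e6 / bin_span
  if (!length(pooled)) density <- rep(0, n_bins)
  structure(data.frame(bin = seq_len(n_bins) - 1L, density = density),
            class = c("meta_profile", "data.frame"),
            profile_class = class_filter, n_assigned = nrow(f),
            n_dropped = n_dropped, total_mapped = total_mapped,
            bin_span = bin_span)
}

#' Coverage Z-scores across a transcript set
#'
#' How far above or below average each transcript's coverage is, in
#' population standard deviations: z = (x - mean) / sd, with sd computed
#' with the 1/n convention. Applied independently to Ribo-Seq and RNA-Seq
#' count vectors.
#'
#' @param counts numeric vector (>= 2 transcripts).
#' @return numeric vector of Z-scores, names preserved.
#' @export
coverage_zscores <- function(counts) {
  if (length(counts) < 2L) stop("need at least 2 transcripts")
  mu <- mean(counts)
  sd_pop <- sqrt(mean((counts - mu)^2))
  if (sd_pop == 0) stop("zero variance: all transcript counts are equal")
  (counts - mu) / sd_pop
}

#' Mock-normalize RNA-Seq counts against the parental line
#'
#' Per transcript: mean count across library-expressing replicates minus
#' mean count across parental-line replicates. Negative values are reported
#' as-is and flagged.
#'
#' @param library_counts numeric matrix transcripts x replicates
#'   (recombinant cells expressing the library).
#' @param parental_counts same shape/rownames, parental cell line.
#' @return data.frame: transcript, mock_normalized, negative (flag).
#' @export
mock_normalize <- function(library_counts, parental_counts) {
  library_counts <- as.matrix(library_counts)
  parental_counts <- as.matrix(parental_counts)
  if (!identical(rownames(library_counts), rownames(parental_counts)) ||
      nrow(library_counts) != nrow(parental_counts))
    stop("library and parental tables must cover identical transcripts")
  d <- rowMeans(library_counts) - rowMeans(parental_counts)
  data.frame(transcript = rownames(library_counts) %||%
               as.character(seq_along(d)),
             mock_normalized = d, negative = d < 0, row.names = NULL)
}

#' Adjust transcript abundance for recombined-cell representation
#'
#' Converts a mock-normalized read count to a per-cell-equivalent abundance
#' by dividing by the receptor's fractional representation in the
#' recombined cellular pool (from barcode DNA counts). A zero fraction
#' leaves the value undefined (NA) and flagged.
#'
#' @param rna_norm mock-normalized read count(s).
#' @param dna_fraction fractional pool representation(s), in (0, 1].
#' @return data.frame: adjusted, undefined (flag).
#' @export
abundance_adjust <- function(rna_norm, dna_fraction) {
  stopifnot(length(rna_norm) == length(dna_fraction))
  if (any(dna_fraction < 0, na.rm = TRUE)) stop("dna_fraction must be >= 0")
  undef <- !is.na(dna_fraction) & dna_fraction == 0
  adj <- ifelse(undef, NA_real_, rna_norm / dna_fraction)
  data.frame(adjusted = adj, undefined = undef)
}
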