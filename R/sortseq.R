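# Sort-Seq quantification: read filtering, exact-match UMI counting,
# rarefaction, low-GFP enrichment and bin-weighted intensity estimation.

#' Expected-error read filter
#'
#' Retains reads whose summed per-base error probability sum(10^(-Q/10)) is
#' at most `max_expected_errors` — the standard expected-errors
#' interpretation of discarding reads likely to contain more than one error.
#'
#' @param reads data.frame from [read_fastq()] (columns sequence, quality).
#' @param max_expected_errors threshold (default 1.0).
#' @return the retained rows, order preserved, with an `expected_errors`
#'   column appended; the number discarded is attached as attribute
#'   `n_discarded`.
#' @export
filter_reads <- function(reads, max_expected_errors = 1.0) {
  stopifnot(is.data.frame(reads), all(c("sequence", "quality") %in% names(reads)))
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad)) stop("malformed read record at index ", bad[1L],
                        ": sequence/quality length mismatch")
  ee <- vapply(phred_scores(reads$quality),
               function(q) sum(10^(-q / 10)), numeric(1))
  keep <- ee <= max_expected_errors
  out <- reads[keep, , drop = FALSE]
  out$expected_errors <- ee[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Count exact UMI matches in reads
#'
#' Extracts the barcode at a fixed offset from each read and assigns the
#' read to a receptor only on an exact match against the UMI table; reads
#' with any mismatch are discarded (no error correction), so each read
#' contributes to at most one receptor.
#'
#' @param reads data.frame with a `sequence` column.
#' @param umi_table data.frame with columns `receptor`, `umi` (unique).
#' @param umi_start 0-based offset of the barcode within the read.
#' @return integer count vector named by receptor, with attributes
#'   `n_assigned`, `n_discarded` (assigned + discarded = input reads).
#' @export
count_umis <- function(reads, umi_table, umi_start = 0L) {
  stopifnot(all(c("receptor", "umi") %in% names(umi_table)))
  umis <- toupper(umi_table$umi)
  if (anyDuplicated(umis)) stop("duplicate UMI sequences in table")
  if (anyDuplicated(umi_table$receptor)) stop("duplicate receptor ids in table")
  L <- unique(nchar(umis))
  if (length(L) != 1L) stop("UMIs must have a single common length")
  counts <- setNames(integer(length(umis)), umi_table$receptor)
  n <- nrow(reads)
  if (n > 0L) {
    obs <- toupper(substr(reads$sequence, umi_start + 1L, umi_start + L))
    hit <- match(obs, umis)
    tab <- table(factor(hit[!is.na(hit)], levels = seq_along(umis)))
    counts[] <- as.integer(tab)
  }
  attr(counts, "n_assigned") <- sum(counts)
  attr(counts, "n_discarded") <- n - sum(counts)
  counts
}

# Multivariate hypergeometric draw: subsample `size` reads without
# replacement from category counts x (sequential conditional rhyper).
rmvhyper <- function(x, size) {
  k <- length(x); out <- integer(k)
  remaining <- sum(x)
  for (i in seq_len(k)) {
    if (size <= 0L) break
    if (i == k) { out[i] <- size; break }
    out[i] <- rhyper(1L, x[i], remaining - x[i], size)
    size <- size - out[i]
    remaining <- remaining - x[i]
  }
  out
}

#' Rarefy a count table to a common depth
#'
#' Subsamples every sample, without replacement, down to the smallest sample
#' total (or `depth` if given). Each sample uses an independent RNG stream
#' derived from `(seed, sample id)`, so adding or removing samples never
#' perturbs the others.
#'
#' @param counts integer matrix, receptors x samples (named columns).
#' @param seed base seed.
#' @param depth target depth; default = minimum sample total.
#' @return rarefied integer matrix with equal column totals.
#' @export
rarefy_counts <- function(counts, seed = 1L, depth = NULL) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample(s) with zero total reads: ",
                             paste(colnames(counts)[totals == 0], collapse = ", "))
  depth <- as.integer(depth %||% min(totals))
  if (any(totals < depth)) stop("depth exceeds a sample total")
  out <- counts
  ids <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  for (j in seq_len(ncol(counts))) {
    if (totals[j] == depth) next
    set.seed(derive_seed(seed, ids[j]))
    out[, j] <- rmvhyper(counts[, j], depth)
  }
  out
}

#' Low-GFP enrichment scores with Fisher exact tests
#'
#' For each receptor, the enrichment ratio is its read count in the low-GFP
#' fraction divided by its combined count across the five high-GFP bins;
#' significance is a two-sided Fisher exact test on the 2x2 table (receptor
#' vs all-other reads, low vs combined high). Receptors sampled below
#' `min_freq` in the low fraction or the combined high pool are flagged and
#' left unscored. Inputs should be rarefied.
#'
#' @param low integer count vector (low-GFP), named by receptor.
#' @param high_bins integer matrix receptors x 5 (high-GFP quintile bins),
#'   same receptor order.
#' @param min_freq minimum sampling frequency per subpopulation (default
#'   5e-6, i.e. 0.0005%).
#' @return data.frame: receptor, low, high, ratio, p, q (BH-adjusted),
#'   pass_sampling.
#' @export
lowgfp_enrichment <- function(low, high_bins, min_freq = 5e-6) {
  high_bins <- as.matrix(high_bins)
  if (ncol(high_bins) != 5L) stop("high_bins must have 5 bin columns")
  if (length(low) != nrow(high_bins)) stop("low and high_bins disagree on receptors")
  high <- rowSums(high_bins)
  tot_low <- sum(low); tot_high <- sum(high)
  if (tot_low == 0 || tot_high == 0) stop("empty fraction")
  pass <- (low / tot_low) >= min_freq & (high / tot_high) >= min_freq
  ratio <- ifelse(pass, low / high, NA_real_)
  p <- rep(NA_real_, length(low))
  for (i in which(pass)) {
    tab <- matrix(c(low[i], tot_low - low[i], high[i], tot_high - high[i]), 2L)
    p[i] <- fisher.test(tab, alternative = "two.sided")$p.value
  }
  q <- rep(NA_real_, length(low))
  q[pass] <- p.adjust(p[pass], method = "BH")
  data.frame(receptor = names(low) %||% as.character(seq_along(low)),
             low = as.integer(low), high = as.integer(high),
             ratio = ratio, p = p, q = q, pass_sampling = pass,
             row.names = NULL)
}

#' Bin intensity representatives
#'
#' Validates a vector of five strictly increasing representative
#' fluorescence intensities for the high-GFP quintile bins. When gate
#' boundaries rather than representatives are available, use
#' [bin_intensities_from_gates()].
#'
#' @param intensities numeric(5), strictly increasing, bins 1..5 ascending.
#' @return numeric(5) of class `bin_intensities`.
#' @export
bin_intensities <- function(intensities) {
  intensities <- as.numeric(intensities)
  if (length(intensities) != 5L) stop("need exactly 5 bin intensities")
  if (any(diff(intensities) <= 0)) stop("bin intensities must be strictly increasing")
  if (any(intensities <= 0)) stop("bin intensities must be positive")
  structure(intensities, class = "bin_intensities")
}

#' Representative intensities from gate boundaries
#'
#' Flow intensities are approximately log-distributed, so the representative
#' intensity of each bin defaults to the geometric mean of its gate
#' boundaries.
#'
#' @param gates numeric(6), ascending gate boundaries on the fluorescence
#'   axis (outer boundaries included).
#' @return [bin_intensities()] vector.
#' @export
bin_intensities_from_gates <- function(gates) {
  gates <- as.numeric(gates)
  if (length(gates) != 6L || any(diff(gates) <= 0) || any(gates <= 0))
    stop("gates must be 6 ascending positive boundaries")
  bin_intensities(sqrt(gates[-6L] * gates[-1L]))
}

#' Intensity-weighted surface-expression estimate
#'
#' Per receptor, the immunostaining-intensity-weighted average of its reads
#' across the five high-GFP bins: sum_b c_b I_b / sum_b c_b. Undefined (NA)
#' for receptors with no high-GFP reads or sampled below `min_freq` of the
#' combined high pool.
#'
#' @param bin_counts integer matrix receptors x 5.
#' @param intensities a [bin_intensities()] vector.
#' @param min_freq minimum combined-high sampling frequency (default 5e-6).
#' @return named numeric vector of intensities (NA where undefined).
#' @export
estimate_intensity <- function(bin_counts, intensities, min_freq = 5e-6) {
  bin_counts <- as.matrix(bin_counts)
  if (ncol(bin_counts) != 5L) stop("bin_counts must have 5 bin columns")
  intensities <- bin_intensities(intensities)
  tot <- rowSums(bin_counts)
  est <- as.numeric(bin_counts %*% intensities) / tot
  est[tot == 0 | tot / sum(bin_counts) < min_freq] <- NA_real_
  setNames(est, rownames(bin_counts))
}

#' Normalize replicate intensities and average
#'
#' Scales each replicate by (grand mean of the replicate population means /
#' that replicate's population mean) — correcting day-to-day calibration
#' drift — then averages per receptor over the replicates where the estimate
#' is defined.
#'
#' @param per_replicate numeric matrix receptors x replicates (NA allowed).
#' @param replicate_population_means per-replicate overall population mean
#'   intensity; default = column means of `per_replicate` (NA-removed).
#' @return data.frame: receptor, intensity_rep columns (normalized),
#'   intensity_mean, n_reps.
#' @export
normalize_and_average <- function(per_replicate, replicate_population_means = NULL) {
  per_replicate <- as.matrix(per_replicate)
  if (ncol(per_replicate) < 1L) stop("need at least one replicate")
  mus <- replicate_population_means %||% colMeans(per_replicate, na.rm = TRUE)
  if (length(mus) != ncol(per_replicate)) stop("one population mean per replicate required")
  if (any(!is.finite(mus)) || any(mus == 0)) stop("replicate population means must be finite and non-zero")
  scaled <- sweep(per_replicate, 2L, mean(mus) / mus, `*`)
  n_reps <- rowSums(!is.na(scaled))
  mean_i <- rowMeans(scaled, na.rm = TRUE)
  mean_i[n_reps == 0L] <- NA_real_
  out <- data.frame(receptor = rownames(per_replicate) %||%
                      as.character(seq_len(nrow(per_replicate))),
                    scaled, row.names = NULL, check.names = FALSE)
  names(out)[2L:(1L + ncol(scaled))] <-
    paste0("intensity_rep", seq_len(ncol(scaled)))
  out$intensity_mean <- mean_i
  out$n_reps <- n_reps
  out
}

#' Summarize splice-variant effects against canonical receptors
#'
#' Given per-receptor abundance and surface-intensity values for isoforms
#' and their canonical counterparts, reports the headline isoform
#' comparisons: the fraction of isoform transcripts whose abundance drops by
#' at least `abundance_drop` relative to canonical, the number of isoforms
#' whose surface intensity is at least `gain` above canonical, and the
#' number within `within` of the canonical intensity.
#'
#' @param isoforms data.frame with columns `isoform`, `canonical`,
#'   `abundance_iso`, `abundance_can`, `intensity_iso`, `intensity_can`.
#' @param abundance_drop fractional decrease threshold (default 0.5).
#' @param gain fractional intensity gain threshold (default 0.2).
#' @param within fractional window around canonical intensity (default 0.5).
#' @return list: frac_abundance_drop, n_intensity_gain, n_within_canonical,
#'   n_isoforms, plus the per-isoform ratio table.
#' @export
splice_variant_summary <- function(isoforms, abundance_drop = 0.5,
                                   gain = 0.2, within = 0.5) {
  need <- c("isoform", "canonical", "abundance_iso", "abundance_can",
            "intensity_iso", "intensity_can")
  missing <- setdiff(need, names(isoforms))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  ab_ratio <- isoforms$abundance_iso / isoforms$abundance_can
  in_ratio <- isoforms$intensity_iso / isoforms$intensity_can
  ok_ab <- is.finite(ab_ratio); ok_in <- is.finite(in_ratio)
  list(frac_abundance_drop = mean(ab_ratio[ok_ab] <= (1 - abundance_drop)),
       n_intensity_gain = sum(in_ratio[ok_in] >= (1 + gain)),
       n_within_canonical = sum(abs(in_ratio[ok_in] - 1) <= within),
       n_isoforms = nrow(isoforms),
       ratios = data.frame(isoform = isoforms$isoform,
                           abundance_ratio = ab_ratio,
                           intensity_ratio = in_ratio))
}
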