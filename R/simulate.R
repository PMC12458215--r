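# Seeded generators that emulate every assay stage: receptor libraries with
# controllable codon bias, Sort-Seq bin counts, low/high-GFP stability
# sampling, ribosome footprints and planted-effect feature tables.

# Default class mix of a canonical receptor library (class A, classes B/C/F
# pooled, olfactory, and taste/vomeronasal/other).
DEFAULT_CLASS_MIX <- c(classA = 286, classBCF = 55, olfactory = 393,
                       other = 32) / 766

#' Simulate a receptor library with ground truth
#'
#' Generates random in-frame ORFs (ATG + residues drawn uniformly + stop)
#' with controllable synonymous-codon bias and GC tilt, assigns receptor
#' classes from `class_mix`, and draws latent surface-expression
#' intensities log-normally spanning roughly four decades (the dynamic
#' range seen in receptor surface immunostaining) plus per-receptor
#' transcript-stability factors.
#'
#' @param n receptors (>= 2).
#' @param class_mix named class probabilities (positive, renormalized).
#' @param codon_bias in [0, 1]: probability of forcing the most frequent
#'   synonymous codon (1 = every codon is the family maximum).
#' @param gc_shift codon-weight GC tilt: weights multiplied by
#'   exp(gc_shift * #GC-bases); 0 = plain usage-frequency sampling.
#' @param n_codons protein length range in residues (uniform; default
#'   120-200, excluding the initiator Met and stop).
#' @param intensity_meanlog,intensity_sdlog latent log-normal parameters
#'   (defaults log(500) and log(1e4)/4, i.e. ~4 decades across +-2 sd).
#' @param unstable_frac,unstable_factor fraction of receptors planted as
#'   unstable and their stability multiplier (defaults 0 and 0.1).
#' @param usage a [read_codon_usage()] table.
#' @param seed RNG seed.
#' @return list of class `receptor_set`: `receptors` (data.frame receptor,
#'   class, orf, protein) and `truth` (receptor, latent_intensity,
#'   stability, unstable).
#' @export
simulate_receptor_set <- function(n, class_mix = DEFAULT_CLASS_MIX,
                                  codon_bias = 0, gc_shift = 0,
                                  n_codons = c(120L, 200L),
                                  intensity_meanlog = log(500),
                                  intensity_sdlog = log(1e4) / 4,
                                  unstable_frac = 0, unstable_factor = 0.1,
                                  usage = read_codon_usage(), seed = 1L) {
  if (n < 2L) stop("n must be >= 2")
  if (any(class_mix < 0) || sum(class_mix) <= 0 || is.null(names(class_mix)))
    stop("impossible class mix: need named non-negative weights with positive sum")
  check_number(codon_bias, "codon_bias", 0, 1)
  set.seed(seed)
  cls <- sample(names(class_mix), n, replace = TRUE,
                prob = class_mix / sum(class_mix))
  sense <- usage[usage$amino_acid != "*", , drop = FALSE]
  stops <- usage[usage$amino_acid == "*", , drop = FALSE]
  fam <- split(seq_len(nrow(sense)), sense$amino_acid)
  aa_pool <- names(fam)[names(fam) != "M"]  # Met only at position 1
  pick_codon <- function(aa) {
    idx <- fam[[aa]]
    w <- sense$freq_per_thousand[idx] *
      exp(gc_shift * vapply(sense$codon[idx], function(cd)
        sum(strsplit(cd, "")[[1L]] %in% c("G", "C")), numeric(1)))
    if (codon_bias > 0 && runif(1L) < codon_bias)
      return(sense$codon[idx[which.max(sense$freq_per_thousand[idx])]])
    sense$codon[idx[sample.int(length(idx), 1L, prob = w)]]
  }
  orfs <- proteins <- character(n)
  lens <- n_codons[1L] + sample.int(n_codons[2L] - n_codons[1L] + 1L, n,
                                    replace = TRUE) - 1L
  for (i in seq_len(n)) {
    aas <- sample(aa_pool, lens[i], replace = TRUE)
    body <- vapply(aas, pick_codon, character(1))
    stop_cd <- stops$codon[sample.int(nrow(stops), 1L,
                                      prob = stops$freq_per_thousand)]
    orfs[i] <- paste(c("ATG", body, stop_cd), collapse = "")
    proteins[i] <- paste(c("M", aas), collapse = "")
  }
  ids <- sprintf("R%04d", seq_len(n))
  latent <- rlnorm(n, intensity_meanlog, intensity_sdlog)
  unstable <- runif(n) < unstable_frac
  stability <- ifelse(unstable, unstable_factor, 1)
  structure(list(
    receptors = data.frame(receptor = ids, class = cls, orf = orfs,
                           protein = proteins, stringsAsFactors = FALSE),
    truth = data.frame(receptor = ids, latent_intensity = latent,
                       stability = stability, unstable = unstable)),
    class = "receptor_set")
}

#' Simulate a five-bin Sort-Seq experiment
#'
#' Per receptor, cell-level intensities are log-normal around the latent
#' intensity with coefficient of variation `cell_cv`; cells are gated into
#' five bins at population quintiles; reads are allocated multinomially per
#' bin proportional to each receptor's cell share (and abundance). Bin
#' representatives are the geometric means of the gate boundaries.
#'
#' @param truth ground-truth data.frame (`receptor`, `latent_intensity`,
#'   optionally `stability` as pool-abundance weight).
#' @param reads_per_receptor mean sequencing reads per receptor (default
#'   2000); total reads = n * this, split evenly across bins.
#' @param cells_per_receptor sorted cells per receptor (default 500).
#' @param cell_cv cell-to-cell coefficient of variation (default 0.5).
#' @param seed RNG seed.
#' @return list: `counts` (receptors x bin1..bin5 integer matrix),
#'   `bin_intensities`, `gates` (6 boundaries), `truth`.
#' @export
simulate_sortseq_experiment <- function(truth, reads_per_receptor = 2000,
                                        cells_per_receptor = 500,
                                        cell_cv = 0.5, seed = 1L) {
  n <- nrow(truth)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cell_cv^2))
  cells <- matrix(rlnorm(n * cells_per_receptor,
                         meanlog = rep(log(truth$latent_intensity),
                                       each = cells_per_receptor),
                         sdlog = sdlog),
                  nrow = cells_per_receptor)
  qs <- quantile(cells, probs = seq(0, 1, 0.2), type = 7)
  gates <- as.numeric(qs)
  gates[1L] <- min(cells) * 0.999; gates[6L] <- max(cells) * 1.001
  bin_of <- function(v) pmin(findInterval(v, gates[2:5]) + 1L, 5L)
  share <- t(apply(cells, 2L, function(v) tabulate(bin_of(v), 5L))) /
    cells_per_receptor
  abundance <- truth$stability %||% rep(1, n)
  reads_per_bin <- round(n * reads_per_receptor / 5)
  counts <- matrix(0L, n, 5L,
                   dimnames = list(truth$receptor, paste0("bin", 1:5)))
  for (b in 1:5) {
    w <- abundance * share[, b]
    if (sum(w) == 0) next  # empty bin at extreme parameters
    counts[, b] <- as.integer(rmultinom(1L, reads_per_bin, w))
  }
  list(counts = counts,
       bin_intensities = bin_intensities_from_gates(gates),
       gates = gates, truth = truth)
}

#' Simulate low-GFP / high-GFP stability sampling
#'
#' Receptors with a stability factor below 1 are over-represented in the
#' low-GFP sample proportional to 1/stability; the high-GFP pool is sampled
#' proportional to abundance and split evenly into the five sorting bins.
#' Multinomial sampling at the stated depths.
#'
#' @param truth ground-truth data.frame (`receptor`, `stability`).
#' @param low_depth,high_depth sequencing depths (defaults 1e6 each).
#' @param seed RNG seed.
#' @return list: `low` (named counts), `high_bins` (receptors x 5).
#' @export
simulate_transcript_stability <- function(truth, low_depth = 1e6,
                                          high_depth = 1e6, seed = 1L) {
  if (low_depth <= 0 || high_depth <= 0) stop("depths must be > 0")
  set.seed(seed)
  n <- nrow(truth)
  w_low <- 1 / truth$stability
  w_high <- rep(1, n)
  low <- as.integer(rmultinom(1L, low_depth, w_low))
  names(low) <- truth$receptor
  high_tot <- as.integer(rmultinom(1L, high_depth, w_high))
  high_bins <- t(vapply(high_tot, function(x) {
    if (x == 0) return(integer(5L))
    as.integer(rmultinom(1L, x, rep(1, 5L)))
  }, integer(5L)))
  dimnames(high_bins) <- list(truth$receptor, paste0("bin", 1:5))
  list(low = low, high_bins = high_bins)
}

#' Simulate ribosome-protected fragments
#'
#' Fragment lengths are drawn uniformly from the monosome (28-38 nt) and
#' disome (50-70 nt) windows with mixing fraction `monosome_frac`; 5'
#' anchors are uniform over each CDS except multiplicatively boosted inside
#' a planted pause bin.
#'
#' @param cds_lengths named integer vector of CDS lengths (nt).
#' @param fragments_total total fragments (default 20000).
#' @param monosome_frac monosome mixing fraction in [0, 1] (default 0.92,
#'   disomes being a small minority of footprints).
#' @param pause_bin 0-based 100-bin index of a planted pause site (NULL =
#'   none).
#' @param pause_boost multiplicative occupancy boost inside the pause bin
#'   (1 = flat).
#' @param n_bins bins used to place the pause (default 100).
#' @param seed RNG seed.
#' @return data.frame of footprint records (transcript, start, length).
#' @export
simulate_riboseq <- function(cds_lengths, fragments_total = 20000L,
                             monosome_frac = 0.92, pause_bin = NULL,
                             pause_boost = 1, n_bins = 100L, seed = 1L) {
  check_number(monosome_frac, "monosome_frac", 0, 1)
  set.seed(seed)
  tx <- names(cds_lengths)
  n_per_tx <- as.integer(rmultinom(1L, fragments_total, cds_lengths))
  recs <- vector("list", length(tx))
  for (i in seq_along(tx)) {
    m <- n_per_tx[i]
    if (m == 0L) next
    len <- cds_lengths[[i]]
    w <- rep(1, len)
    if (!is.null(pause_bin) && pause_boost != 1) {
      bins <- pmin(floor(n_bins * (seq_len(len) - 1L) / len), n_bins - 1L)
      w[bins == pause_bin] <- pause_boost
    }
    start <- sample.int(len, m, replace = TRUE, prob = w) - 1L
    mono <- runif(m) < monosome_frac
    flen <- ifelse(mono, sample(28:38, m, replace = TRUE),
                   sample(50:70, m, replace = TRUE))
    recs[[i]] <- data.frame(transcript = tx[i], start = start,
                            length = as.integer(flen))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate a feature table with planted threshold effects
#'
#' Latent log-intensity decreases by `effect_dg_tmd6` when the planted TMD6
#' insertion energy is above 0 kcal/mol (marginal hydrophobicity) and by
#' `effect_sasa` when the planted total SASA is below `sasa_threshold`;
#' remaining features are pure noise. The emitted table is compatible with
#' [labeled_dataset()] / [train_classifier()].
#'
#' The planted feature distributions put roughly a third of receptors above
#' the TMD6 threshold and half below the SASA threshold, so the
#' neither-defect group matches the ~33% high-expression prevalence of a
#' 67th-percentile label cutoff; the default 3-log-unit effects (~20-fold
#' intensity drop per defect) make the planted structure recoverable well
#' above the irreducible label noise.
#'
#' @param n receptors (>= 50).
#' @param effect_dg_tmd6,effect_sasa effect sizes in log-intensity units
#'   (defaults 3 and 3; 0 = null).
#' @param sasa_threshold SASA threshold in Angstrom^2 (default 1900).
#' @param noise_features number of pure-noise feature columns (default 20).
#' @param noise_sd residual log-intensity noise sd (default 1).
#' @param seed RNG seed.
#' @return list: `features` (data.frame incl. tmd6_dg and sasa_total),
#'   `intensity`, `truth` (the planted group indicators).
#' @export
simulate_feature_table <- function(n = 300L, effect_dg_tmd6 = 3,
                                   effect_sasa = 3, sasa_threshold = 1900,
                                   noise_features = 20L, noise_sd = 1,
                                   seed = 1L) {
  if (n < 50L) stop("n must be >= 50")
  set.seed(seed)
  tmd6_dg <- rnorm(n, mean = -0.6, sd = 1.5)
  sasa_total <- rnorm(n, mean = sasa_threshold, sd = 250)
  marginal <- tmd6_dg > 0
  low_sasa <- sasa_total < sasa_threshold
  log_int <- log(3000) - effect_dg_tmd6 * marginal - effect_sasa * low_sasa +
    rnorm(n, sd = noise_sd)
  noise <- matrix(rnorm(n * noise_features), n, noise_features,
                  dimnames = list(NULL, sprintf("noise_%02d", seq_len(noise_features))))
  features <- data.frame(tmd6_dg = tmd6_dg, sasa_total = sasa_total, noise,
                         check.names = FALSE)
  list(features = features, intensity = exp(log_int),
       truth = data.frame(marginal_tmd6 = marginal, low_sasa = low_sasa))
}
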