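# %MinMax codon-usage profiling, GC content and random-reverse-translation
# null distributions.

#' Load a codon usage table
#'
#' Reads a TSV with columns `codon`, `amino_acid`, `freq_per_thousand` and
#' derives, for each codon, its synonymous-family maximum, minimum and mean
#' frequency plus its within-family relative frequency. The bundled human
#' genome-wide table is used when `path` is omitted.
#'
#' Single-codon families (Met, Trp) and stop codons are flagged `excluded`:
#' their family max equals the mean, so sliding-window %MinMax terms would be
#' undefined, and they are left out of window means.
#'
#' @param path TSV path; default = bundled human usage table.
#' @return data.frame of class `codon_usage_table` with one row per codon.
#' @export
read_codon_usage <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "human_codon_usage.tsv", package = "drscan",
                        mustWork = TRUE)
  df <- read_tsv(path, required_cols = c("codon", "amino_acid", "freq_per_thousand"))
  df$codon <- toupper(df$codon)
  if (anyDuplicated(df$codon)) stop("duplicate codons in usage table")
  if (nrow(df) != 64L) stop("usage table must list all 64 codons (got ", nrow(df), ")")
  fam <- split(seq_len(nrow(df)), df$amino_acid)
  df$fam_size <- df$fam_max <- df$fam_min <- df$fam_mean <- df$rel_freq <- NA_real_
  for (idx in fam) {
    f <- df$freq_per_thousand[idx]
    if (sum(f) <= 0) stop("synonymous family with zero total frequency")
    df$fam_size[idx] <- length(idx)
    df$fam_max[idx]  <- max(f)
    df$fam_min[idx]  <- min(f)
    df$fam_mean[idx] <- mean(f)
    df$rel_freq[idx] <- f / sum(f)
  }
  df$excluded <- df$fam_size == 1L | df$amino_acid == "*"
  class(df) <- c("codon_usage_table", "data.frame")
  df
}

usage_lookup <- function(usage, codons) {
  i <- match(codons, usage$codon)
  if (anyNA(i)) stop("unknown codon(s): ",
                     paste(unique(codons[is.na(i)]), collapse = ", "))
  i
}

#' Sliding-window %MinMax codon-usage profile
#'
#' For each window of `window` codons, with Actual/Max/Min/Avg the window
#' means of each codon's usage frequency, its synonymous-family maximum,
#' minimum and mean: %MinMax = 100 (Actual - Avg) / (Max - Avg) when
#' Actual > Avg, else 100 (Actual - Avg) / (Avg - Min). Positive values mean
#' locally common codon choices, negative values locally rare ones; the
#' statistic is bounded in [-100, 100]. Met, Trp and stop codons are excluded
#' from window means (their family max equals the mean).
#'
#' @param orf in-frame nucleotide sequence.
#' @param usage a [read_codon_usage()] table.
#' @param window odd window size in codons (default 17).
#' @param relative use within-family relative frequencies instead of raw
#'   genome-wide frequencies (default FALSE, the cited algorithm's choice).
#' @return object of class `minmax_profile`: numeric vector of per-window
#'   values (length = codons - window + 1, NA where a window holds only
#'   excluded codons), with the window size as an attribute.
#' @export
minmax_profile <- function(orf, usage = read_codon_usage(), window = 17L,
                           relative = FALSE) {
  codons <- split_codons(orf)
  n <- length(codons)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window > n) stop("window (", window, ") exceeds codon count (", n, ")")
  i <- usage_lookup(usage, codons)
  f <- if (relative) usage$rel_freq[i] else usage$freq_per_thousand[i]
  if (relative) {
    fmax <- rep(1, n); fmin <- f * 0; fmean <- f * 0
    fam <- split(seq_len(64L), usage$amino_acid)
    rmax <- rmin <- rmean <- numeric(64L)
    for (idx in fam) {
      rmax[idx] <- max(usage$rel_freq[idx]); rmin[idx] <- min(usage$rel_freq[idx])
      rmean[idx] <- mean(usage$rel_freq[idx])
    }
    fmax <- rmax[i]; fmin <- rmin[i]; fmean <- rmean[i]
  } else {
    fmax <- usage$fam_max[i]; fmin <- usage$fam_min[i]; fmean <- usage$fam_mean[i]
  }
  keep <- !usage$excluded[i]
  # rolling sums over included codons only
  roll <- function(x) {
    cs <- cumsum(c(0, x))
    cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]
  }
  cnt  <- roll(as.numeric(keep))
  act  <- roll(ifelse(keep, f, 0))     / pmax(cnt, 1)
  wmax <- roll(ifelse(keep, fmax, 0))  / pmax(cnt, 1)
  wmin <- roll(ifelse(keep, fmin, 0))  / pmax(cnt, 1)
  wavg <- roll(ifelse(keep, fmean, 0)) / pmax(cnt, 1)
  up <- act > wavg
  val <- ifelse(up,
                100 * (act - wavg) / (wmax - wavg),
                100 * (act - wavg) / (wavg - wmin))
  val[act == wavg] <- 0
  val[cnt == 0] <- NA_real_
  structure(val, window = window, class = "minmax_profile")
}

#' Common/rare codon fractions of a %MinMax profile
#'
#' @param profile a [minmax_profile()] (or numeric vector of window values).
#' @return named numeric `c(f_common, f_rare)`: fractions of (non-NA) windows
#'   with %MinMax > 0 and < 0; exact zeros count in neither.
#' @export
codon_class_fractions <- function(profile) {
  v <- as.numeric(profile)
  v <- v[!is.na(v)]
  if (!length(v)) stop("profile has no defined windows")
  c(f_common = mean(v > 0), f_rare = mean(v < 0))
}

#' Fractional G+C content
#'
#' `N` bases are excluded from both numerator and denominator; the number
#' excluded is attached as attribute `n_excluded`.
#'
#' @param seq nucleotide string (ACGTN).
#' @return fraction in [0, 1].
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  b <- strsplit(toupper(seq), "")[[1L]]
  bad <- !b %in% c(BASES, "N")
  if (any(bad)) stop("non-ACGTN character(s): ", paste(unique(b[bad]), collapse = ","))
  b <- b[b != "N"]
  if (!length(b)) stop("sequence contains only N bases")
  structure(mean(b %in% c("G", "C")),
            n_excluded = sum(toupper(strsplit(seq, "")[[1L]]) == "N"))
}

#' Random reverse translations (RRT) null distributions
#'
#' Samples `n` codon sequences for a protein, one codon per residue with
#' probability proportional to genome-wide usage frequency, and returns the
#' %MinMax common/rare fractions and GC content of each draw — the null
#' model against which an observed transcript's codon bias is judged.
#'
#' @param protein amino-acid string (stop `*` allowed only as final residue).
#' @param usage a [read_codon_usage()] table.
#' @param n number of RRTs (default 200).
#' @param seed RNG seed.
#' @param window %MinMax window (default 17).
#' @return data.frame with columns rrt, f_common, f_rare, gc.
#' @export
random_reverse_translations <- function(protein, usage = read_codon_usage(),
                                        n = 200L, seed = 1L, window = 17L) {
  if (n < 1L) stop("n must be >= 1")
  aa <- strsplit(toupper(protein), "")[[1L]]
  if (!length(aa)) stop("empty protein")
  fam <- split(seq_len(nrow(usage)), usage$amino_acid)
  missing <- setdiff(aa, names(fam))
  if (length(missing))
    stop("residue(s) with no codon in the usage table: ",
         paste(missing, collapse = ","))
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    cods <- vapply(aa, function(a) {
      idx <- fam[[a]]
      usage$codon[idx[sample.int(length(idx), 1L,
                                 prob = usage$freq_per_thousand[idx])]]
    }, character(1))
    orf <- paste(cods, collapse = "")
    fr <- if (length(aa) >= window)
      codon_class_fractions(minmax_profile(orf, usage, window))
    else c(f_common = NA_real_, f_rare = NA_real_)
    out[[k]] <- data.frame(rrt = k, f_common = fr[["f_common"]],
                           f_rare = fr[["f_rare"]], gc = as.numeric(gc_content(orf)))
  }
  do.call(rbind, out)
}

#' Median-split group comparison (Mann-Whitney U)
#'
#' Splits receptors into high/low groups at the median of `split_by` (ties go
#' to the low group) and compares `values` across groups with a two-sided
#' Mann-Whitney U test.
#'
#' @param values numeric vector to compare (e.g. f_common, GC).
#' @param split_by numeric vector defining the split (e.g. high-GFP read
#'   fraction); same length as `values`.
#' @return list with `group` (factor high/low), `p`, `statistic`,
#'   `median_high`, `median_low`.
#' @export
compare_median_groups <- function(values, split_by) {
  stopifnot(length(values) == length(split_by))
  ok <- !is.na(values) & !is.na(split_by)
  values <- values[ok]; split_by <- split_by[ok]
  if (length(values) < 4L) stop("need at least 4 complete observations")
  grp <- factor(ifelse(split_by > median(split_by), "high", "low"),
                levels = c("low", "high"))
  if (length(unique(grp)) < 2L) stop("median split produced a single group")
  wt <- wilcox.test(values[grp == "high"], values[grp == "low"], exact = FALSE)
  list(group = grp, p = wt$p.value, statistic = unname(wt$statistic),
       median_high = median(values[grp == "high"]),
       median_low = median(values[grp == "low"]))
}
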