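make_reads <- function(seqs, quals) {
  data.frame(id = paste0("r", seq_along(seqs)), sequence = seqs,
             quality = quals, stringsAsFactors = FALSE)
}

q_string <- function(qs) intToUtf8(qs + 33L)

test_that("expected-error filter matches per-base summation", {
  reads <- make_reads(
    c(strrep("A", 10), strrep("A", 10), strrep("A", 12)),
    c(q_string(rep(10L, 10)),   # EE = 10 * 0.1  = 1.0  -> kept at 1.0
      q_string(rep(40L, 10)),   # EE = 10 * 1e-4        -> kept
      q_string(rep(c(2L, 30L), 6))))
  out <- filter_reads(reads, max_expected_errors = 1.0)
  ee3 <- sum(10^(-rep(c(2, 30), 6) / 10))
  expect_identical(out$id, c("r1", "r2", if (ee3 <= 1) "r3"))
  expect_equal(out$expected_errors[1], 1.0)
  expect_equal(out$expected_errors[2], 10 * 1e-4)
  expect_identical(attr(out, "n_discarded"), 1L)
  # mixed-quality reads agree with an independent recomputation
  set.seed(1)
  qs <- lapply(1:50, function(i) sample(2:41, 20, replace = TRUE))
  reads <- make_reads(rep(strrep("C", 20), 50), vapply(qs, q_string, ""))
  out <- filter_reads(reads, 0.05)
  oracle_keep <- vapply(qs, function(q) sum(10^(-q / 10)) <= 0.05, logical(1))
  expect_identical(out$id, reads$id[oracle_keep])
  expect_error(filter_reads(make_reads("ACGT", "II")), "mismatch")
})

test_that("UMI counting assigns only exact matches and conserves reads", {
  tab <- data.frame(receptor = c("R1", "R2"), umi = c("ACGTACGTAC", "TTGCAATGGC"))
  reads <- make_reads(c("ACGTACGTACAAAA",    # exact R1
                        "ACGTACGTTCAAAA",    # 1 mismatch -> discarded
                        "TTGCAATGGCTTTT"),   # exact R2
                      rep(q_string(rep(30L, 14)), 3))
  counts <- count_umis(reads, tab, umi_start = 0)
  expect_identical(as.integer(counts), c(1L, 1L))
  expect_identical(attr(counts, "n_assigned") + attr(counts, "n_discarded"),
                   nrow(reads))
  empty <- count_umis(reads[0, ], tab)
  expect_identical(as.integer(empty), c(0L, 0L))
  expect_identical(attr(empty, "n_discarded"), 0L)
  expect_error(count_umis(reads, data.frame(receptor = c("a", "b"),
                                            umi = c("AC", "AC"))), "duplicate")
})

test_that("rarefaction equalizes totals exactly and preserves expectations", {
  m <- cbind(s1 = c(60L, 30L, 10L), s2 = c(10L, 30L, 10L), s3 = c(40L, 30L, 10L))
  rownames(m) <- paste0("R", 1:3)
  r <- rarefy_counts(m, seed = 1)
  expect_equal(unname(colSums(r)), rep(50, 3))
  expect_identical(r[, "s2"], m[, "s2"])          # already at the minimum
  expect_true(all(r <= m))
  expect_identical(rarefy_counts(m, seed = 9), rarefy_counts(m, seed = 9))
  expect_error(rarefy_counts(cbind(a = c(0L, 0L))), "zero total")
  # hypergeometric expectation: receptor at fraction f -> mean f * depth
  big <- cbind(s1 = c(400L, 600L), s2 = c(100L, 100L))
  means <- rowMeans(vapply(1:200, function(s)
    rarefy_counts(big, seed = s)[, "s1"], numeric(2)))
  exp1 <- 200 * 400 / 1000
  se <- sqrt(200 * 0.4 * 0.6 * (1000 - 200) / (1000 - 1)) / sqrt(200)
  expect_lt(abs(means[1] - exp1), 4 * se)
})

test_that("low-GFP enrichment reproduces the exact hypergeometric Fisher p", {
  # fully symmetric table -> p = 1
  low <- c(R1 = 5L, R2 = 5L)
  high <- matrix(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L), 2, 5)
  res <- lowgfp_enrichment(low, high, min_freq = 0)
  expect_equal(res$p[1], 1.0)
  expect_equal(res$ratio, c(1, 1))
  # (30, 1970; 10, 9990): exhaustive two-sided tail summation oracle
  d_obs <- dhyper(30, 40, 11960, 2000)
  p_oracle <- sum(dhyper(0:40, 40, 11960, 2000)[
    dhyper(0:40, 40, 11960, 2000) <= d_obs * (1 + 1e-7)])
  res2 <- lowgfp_enrichment(
    c(A = 30L, B = 1970L),
    cbind(c(2L, 1998L), c(2L, 1998L), c(2L, 1998L), c(2L, 1998L), c(2L, 1998L)),
    min_freq = 0)
  expect_equal(res2$p[1], p_oracle, tolerance = 1e-10)
  # sampling flag: frequency below 0.0005% in combined high -> unscored
  lowc <- setNames(rep(100L, 2), c("A", "B"))
  highc <- rbind(A = rep(1L, 5), B = rep(400000L, 5))
  res3 <- lowgfp_enrichment(lowc, highc)
  expect_false(res3$pass_sampling[1])
  expect_true(is.na(res3$ratio[1]))
  expect_true(res3$pass_sampling[2])
})

test_that("intensity estimation is the read-weighted bin average", {
  I <- bin_intensities(c(1, 2, 3, 4, 5))
  expect_equal(unname(estimate_intensity(rbind(c(0, 0, 0, 0, 10)), I, 0)), 5.0)
  expect_equal(unname(estimate_intensity(rbind(rep(10, 5)), I, 0)), 3.0)
  set.seed(2)
  counts <- matrix(rpois(50, 40), 10, 5)
  est <- estimate_intensity(counts, I, 0)
  oracle <- apply(counts, 1, function(cc) sum(cc * as.numeric(I)) / sum(cc))
  expect_equal(unname(est), oracle)
  expect_true(all(est >= 1 & est <= 5))
  expect_error(bin_intensities(c(1, 2, 2, 4, 5)), "strictly increasing")
  # zero coverage -> undefined
  expect_true(is.na(estimate_intensity(rbind(c(5, 5, 5, 5, 5), rep(0, 5)), I, 0)[2]))
})

test_that("replicate normalization rescales and averages as specified", {
  x <- cbind(rep1 = c(1, 2, 3), rep2 = c(1, 2, 3), rep3 = c(1, 2, 3))
  out <- normalize_and_average(x)
  expect_equal(out$intensity_mean, c(1, 2, 3))
  # globally doubling one replicate is undone by the normalization
  y <- cbind(r1 = c(1, 2, 3), r2 = 2 * c(1, 2, 3))
  outy <- normalize_and_average(y)
  expect_equal(outy$intensity_rep1 / outy$intensity_rep1[1],
               outy$intensity_rep2 / outy$intensity_rep2[1], tolerance = 1e-12)
  # explicit three-replicate oracle with distinct scales
  z <- cbind(a = c(10, 20), b = c(30, 60), c = c(20, 40))
  mus <- c(15, 45, 30)
  outz <- normalize_and_average(z, mus)
  oracle <- sapply(1:2, function(i) mean(z[i, ] * mean(mus) / mus))
  expect_equal(outz$intensity_mean, oracle)
  # NA handling: averaged over the defined subset, support counted
  w <- cbind(c(1, NA), c(3, 4))
  outw <- normalize_and_average(w, c(1, 1))
  expect_identical(outw$n_reps, c(2, 1))
  expect_equal(outw$intensity_mean[2], 4)
  expect_error(normalize_and_average(z, c(0, 1, 2)), "non-zero")
})

test_that("splice-variant summaries match a direct counting oracle", {
  set.seed(3)
  n <- 40
  iso <- data.frame(isoform = paste0("I", 1:n), canonical = paste0("C", 1:n),
                    abundance_iso = runif(n, 0, 100),
                    abundance_can = runif(n, 10, 100),
                    intensity_iso = runif(n, 0, 4000),
                    intensity_can = runif(n, 100, 4000))
  s <- splice_variant_summary(iso)
  ar <- iso$abundance_iso / iso$abundance_can
  ir <- iso$intensity_iso / iso$intensity_can
  expect_equal(s$frac_abundance_drop, mean(ar <= 0.5))
  expect_equal(s$n_intensity_gain, sum(ir >= 1.2))
  expect_equal(s$n_within_canonical, sum(abs(ir - 1) <= 0.5))
  expect_error(splice_variant_summary(iso[, -3]), "missing column")
})

test_that("estimator recovers latent intensities on a small simulated library", {
  rs <- simulate_receptor_set(150, seed = 21)
  sim <- simulate_sortseq_experiment(rs$truth, reads_per_receptor = 2000,
                                     cell_cv = 0.5, seed = 22)
  est <- estimate_intensity(sim$counts, sim$bin_intensities, min_freq = 0)
  rho <- cor(est, rs$truth$latent_intensity, method = "spearman",
             use = "complete.obs")
  expect_gte(rho, 0.9)
})
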