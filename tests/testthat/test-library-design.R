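test_that("generated UMI sets satisfy every per-sequence filter and the pairwise Hamming bound", {
  cons <- umi_constraints()
  umis <- generate_umi_set(100, cons, seed = 7)
  expect_length(umis, 100L)
  expect_false(anyDuplicated(umis) > 0)
  gc <- vapply(strsplit(umis, ""), function(b) mean(b %in% c("G", "C")), numeric(1))
  expect_true(all(gc >= cons$gc_min & gc <= cons$gc_max))
  expect_false(any(grepl("AAA|CCC|GGG|TTT", umis)))
  for (m in cons$forbidden_motifs) {
    expect_false(any(grepl(m, umis, fixed = TRUE)))
    expect_false(any(grepl(revcomp(m), umis, fixed = TRUE)))
  }
  # exhaustive all-pairs oracle, independent of the generator's bookkeeping
  expect_gte(hamming_oracle(umis), cons$min_hamming)
  expect_equal(min_pairwise_hamming(umis), hamming_oracle(umis))
})

test_that("UMI generation is seed-reproducible and handles edge requests", {
  cons <- umi_constraints()
  expect_identical(generate_umi_set(25, cons, seed = 3),
                   generate_umi_set(25, cons, seed = 3))
  other <- generate_umi_set(25, cons, seed = 4)
  expect_gte(hamming_oracle(other), cons$min_hamming)
  one <- generate_umi_set(1, cons, seed = 1)
  expect_length(one, 1L)
  # a 4-nt barcode space cannot host 50 sequences at Hamming >= 4
  tiny <- umi_constraints(length = 4, min_hamming = 4, max_homopolymer = 2,
                          gc_min = 0, gc_max = 1, forbidden_motifs = character(0))
  expect_error(generate_umi_set(50, tiny, seed = 1), "infeasible")
})

test_that("greedy sampling honours the same constraints as enumeration", {
  cons <- umi_constraints()
  umis <- generate_umi_set(40, cons, seed = 11, method = "greedy",
                           max_tries = 2e4)
  expect_length(umis, 40L)
  expect_gte(hamming_oracle(umis), cons$min_hamming)
})

test_that("HA tag insertion preserves frame and lands after the second codon", {
  orf <- "ATGAAACCCTAA"
  out <- insert_ha_tag(orf, 2)
  expect_identical(substr(out, 1, 6), "ATGAAA")
  expect_identical(nchar(out), nchar(orf) + nchar(drscan:::HA_TAG_NT))
  # translate-and-scan: the HA nonapeptide starts at residue 3
  expect_identical(substr(translate_orf(out), 3, 11), "YPYDVPDYA")
  expect_identical(insert_ha_tag(orf, 2, tag_nt = ""), orf)
  expect_error(insert_ha_tag(orf, 0), "insertion_codon_index")
  expect_error(insert_ha_tag(orf, 2, tag_nt = "AC"), "divisible by 3")
  expect_error(insert_ha_tag("CCCAAATAA", 1), "start with ATG")
})

test_that("site silencing removes recognition sites on both strands without touching the protein", {
  # CGTCTC spans codons CGT|CTC
  orf <- paste0("ATG", "CGT", "CTC", "AAA", "TAA")
  out <- silence_sites(orf, "CGTCTC", usage_tbl)
  expect_identical(translate_orf(out), translate_orf(orf))
  expect_identical(drscan:::count_motif_both_strands(out, "CGTCTC"), 0L)
  # zero sites: byte-identical no-op
  clean <- "ATGAAACCCTAA"
  expect_identical(silence_sites(clean, "CGTCTC", usage_tbl), clean)
  # site present only as reverse complement GAGACG
  orf_rc <- paste0("ATG", "GAG", "ACG", "AAA", "TAA")
  out_rc <- silence_sites(orf_rc, "CGTCTC", usage_tbl)
  expect_identical(translate_orf(out_rc), translate_orf(orf_rc))
  expect_identical(drscan:::count_motif_both_strands(out_rc, "CGTCTC"), 0L)
})

test_that("silencing picks the most frequent synonymous codon that works", {
  orf <- paste0("ATG", "CGT", "CTC", "AAA", "TAA")
  out <- silence_sites(orf, "CGTCTC", usage_tbl)
  # one codon changed, and the changed codon is the best-ranked fix:
  # among all single synonymous swaps that remove the site, the chosen one
  # has the maximal genome frequency
  cods_in <- split_codons(orf); cods_out <- split_codons(out)
  changed <- which(cods_in != cods_out)
  expect_length(changed, 1L)
  freq_of <- function(cd) usage_tbl$freq_per_thousand[match(cd, usage_tbl$codon)]
  best <- -Inf
  for (ci in 2:3) {
    aa <- usage_tbl$amino_acid[match(cods_in[ci], usage_tbl$codon)]
    alts <- usage_tbl$codon[usage_tbl$amino_acid == aa]
    for (alt in setdiff(alts, cods_in[ci])) {
      trial <- cods_in; trial[ci] <- alt
      if (drscan:::count_motif_both_strands(paste(trial, collapse = ""),
                                            "CGTCTC") == 0L)
        best <- max(best, freq_of(alt))
    }
  }
  expect_equal(freq_of(cods_out[changed]), best)
})

test_that("protein sequence is invariant under site silencing on random ORFs", {
  set.seed(42)
  for (k in 1:300) {
    orf <- random_orf(sample(20:80, 1))
    out <- silence_sites(orf, "CGTCTC", usage_tbl)
    expect_identical(translate_orf(out), translate_orf(orf))
    expect_identical(drscan:::count_motif_both_strands(out, "CGTCTC"), 0L)
  }
})

test_that("terminal glycine swap yields exactly one Gly before the native stop", {
  expect_identical(terminal_glycine_swap("ATGAAATAA"), "ATGAAAGGCTAA")
  expect_identical(terminal_glycine_swap("ATGAAAGGATAA"), "ATGAAAGGCTAA")
  # trailing diglycine collapses; translated tail is a single Gly
  out <- terminal_glycine_swap("ATGGGAGGTTAA")
  prot <- translate_orf(out)
  expect_identical(prot, "MG*")
  expect_error(terminal_glycine_swap("ATGAAAGGA"), "stop codon")
  # native stop codon is preserved
  expect_identical(terminal_glycine_swap("ATGAAATGA"), "ATGAAAGGCTGA")
})

test_that("cassette assembly orders elements 5'->3' and counts exactly two enzyme sites", {
  orf <- terminal_glycine_swap(silence_sites(random_orf(30, seed = 5),
                                             "CGTCTC", usage_tbl))
  cs <- assemble_cassette(umi = "ACGACGATCG", orf = orf, attb = "TTCGGTTTGTCTGGTCAACCACCGCGGT")
  el <- cs$elements
  expect_identical(el$element, c("enzyme_site_5", "umi", "attb", "orf", "enzyme_site_3"))
  expect_identical(el$start, c(0L, head(el$end, -1)))        # tiling
  expect_identical(el$end[nrow(el)], nchar(cs$sequence))
  expect_identical(drscan:::count_motif_both_strands(cs$sequence, "CGTCTC"), 2L)
  # degenerate empty attB placeholder keeps the order, zero-length interval
  cs2 <- assemble_cassette("ACGACGATCG", orf, attb = "")
  expect_identical(cs2$elements$start[3], cs2$elements$end[3])
  # an extraneous internal site is rejected
  expect_error(assemble_cassette("ACGTCTCGAT", orf, ""), "expected exactly 2")
})

test_that("assembled cassettes round-trip through FASTA", {
  orf <- terminal_glycine_swap("ATGAAACCCGTGTAA")
  cs <- assemble_cassette("ACGACGATCG", orf, "GGTTTGTCTGGTCAACCACC")
  path <- tempfile(fileext = ".fasta")
  write_fasta(c(cassette1 = cs$sequence), path)
  back <- read_fasta(path)
  expect_identical(unname(back["cassette1"]), cs$sequence)
})
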