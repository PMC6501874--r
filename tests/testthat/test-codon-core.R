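cd <- dupsel:::codon_data()

test_that("single-change classification follows the standard code", {
  expect_equal(classify_single_change("TTT", "TTC"), "synonymous")
  expect_equal(classify_single_change("TTT", "TTA"), "nonsynonymous")
  expect_equal(classify_single_change("TGG", "TGA"), "nonsense")
  expect_error(classify_single_change("TTT", "TAA"), "exactly one position")
  expect_error(classify_single_change("AAA", "AAA"), "exactly one position")
})

test_that("pathway counts average over stop-free minimal pathways", {
  id <- pathway_counts("AAA", "AAA")
  expect_equal(c(id$syn, id$nsyn), c(0, 0))
  # both 2-step pathways valid: Ala->Ala->Val (1 syn + 1 nsyn each ordering)
  p <- pathway_counts("GCA", "GTT")
  expect_equal(c(p$syn, p$nsyn), c(1, 1))
  expect_false(p$blocked)
  # TAT -> TGG: the pathway via TAG (stop) is excluded
  p <- pathway_counts("TAT", "TGG")
  expect_equal(c(p$syn, p$nsyn), c(0, 2))
  expect_error(pathway_counts("TAA", "TAT"), "sense")
})

test_that("pathway counts are symmetric and total-preserving over all pairs", {
  pt <- dupsel:::pathway_tables(cd)
  expect_equal(pt$syn, t(pt$syn))
  expect_equal(pt$nsyn, t(pt$nsyn))
  expect_equal(pt$blocked, t(pt$blocked))
  # syn + nsyn equals the Hamming distance for every pair, including the
  # stop-blocked fallback (counts stay total-preserving by design)
  expect_equal(pt$syn + pt$nsyn, cd$ndiff + 0)
  # single-difference pairs agree with classify_single_change
  idx <- which(cd$ndiff == 1L, arr.ind = TRUE)
  some <- idx[seq(1, nrow(idx), by = 7), , drop = FALSE]
  for (r in seq_len(nrow(some))) {
    i <- some[r, 1]; j <- some[r, 2]
    cls <- classify_single_change(cd$codons61[i], cd$codons61[j])
    expect_equal(pt$nsyn[i, j], as.numeric(cls == "nonsynonymous"))
  }
  # under the standard code every sense pair has a stop-free pathway
  expect_false(any(pt$blocked))
})

test_that("fully stop-blocked pairs fall back to nonsynonymous stop steps", {
  # a code with extra stops so that both TAT -> TGG orderings cross a stop
  code <- Biostrings::GENETIC_CODE
  code[["TGT"]] <- "*"
  cdx <- dupsel:::codon_data(code)
  pp <- dupsel:::.pathway_pair("TAT", "TGG", cdx)
  expect_true(pp$blocked)
  expect_equal(pp$syn + pp$nsyn, 2)   # total-preserving fallback
  expect_equal(pp$nsyn, 2)
})

test_that("Nei-Gojobori site counts sum to 3 per codon and 183 in total", {
  x <- ng_site_counts("TTT")
  expect_equal(x$syn_sites, 1 / 3)
  expect_equal(x$nsyn_sites, 8 / 3)
  expect_equal(ng_site_counts("GGG")$syn_sites, 1)
  expect_equal(ng_site_counts("ATG")$syn_sites, 0)
  s <- dupsel:::ng_tables(cd)
  expect_equal(sum(s) + sum(3 - s), 183)
  expect_true(all(s >= 0 & s <= 3))
  expect_error(ng_site_counts("TAA"), "stop")
})

test_that("sequence-level site counts sum over codons and skip gaps", {
  expect_equal(alignment_site_counts("TTTTTT")$syn_sites, 2 / 3)
  expect_equal(alignment_site_counts("")$syn_sites, 0)
  x <- alignment_site_counts("ATGGGG")
  expect_equal(c(x$syn_sites, x$nsyn_sites), c(1, 5))
  # gap codon is excluded, remaining codon still counted
  expect_equal(alignment_site_counts(c(NA, cd$codon_index[["GGG"]]))$syn_sites, 1)
})
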