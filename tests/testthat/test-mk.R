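test_that("polymorphism counting uses minimum-change spanning arrangements", {
  inv <- hap_sample(h1 = "ATGAAA", h2 = "ATGAAA", h3 = "ATGAAA")
  expect_equal(count_polymorphisms(inv)[c("Ps", "Pn")], list(Ps = 0, Pn = 0))
  syn <- hap_sample(h1 = "TTT", h2 = "TTC", h3 = "TTT")
  expect_equal(count_polymorphisms(syn)[c("Ps", "Pn")], list(Ps = 1, Pn = 0))
  # tri-allelic column: spanning tree AAG-AAA-AGA, one syn + one nsyn step
  tri <- hap_sample(h1 = "AAA", h2 = "AAG", h3 = "AGA")
  expect_equal(count_polymorphisms(tri)[c("Ps", "Pn")], list(Ps = 1, Pn = 1))
  # gap alleles are excluded column-wise, not counted
  gap <- hap_sample(h1 = "TTT", h2 = "---", h3 = "TTC")
  expect_equal(count_polymorphisms(gap)$Ps, 1)
  expect_error(count_polymorphisms(hap_sample(h1 = "TTT")), ">= 2")
})

test_that("divergence counts only fixed columns against the reference", {
  s <- hap_sample(h1 = "TTTGCATTC", h2 = "TTTGCATTT")
  # column 3 is polymorphic: contributes nothing to divergence; the two fixed
  # columns give TTT->TTC (1 syn) and GCA->GTT (1 syn + 1 nsyn)
  d <- count_divergence(s, "TTCGTTTTT")
  expect_equal(d$Ds_raw, 2)
  expect_equal(d$Dn_raw, 1)
  expect_equal(d$n_compared, 2)
  expect_error(count_divergence(s, "TTT"), "length")
})

test_that("Jukes-Cantor correction matches the closed form and inflates", {
  expect_equal(jc_correct(0, 100), 0)
  expect_equal(jc_correct(10, 100), -75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(round(jc_correct(10, 100), 3), 10.733)
  for (p in c(0.01, 0.2, 0.5, 0.7))
    expect_gte(jc_correct(p * 50, 50), p * 50)
  expect_error(jc_correct(40, 50), "saturated")
})

test_that("MK tests reproduce the published worked examples", {
  r1 <- mk_test(142.0, 15.0, 5.1, 6.0)
  expect_equal(round(r1$NI, 2), 0.09)
  r2 <- mk_test(86, 12, 899.0, 378.1)
  expect_equal(round(r2$statistic, 1), 13.5)
  expect_lt(r2$p.value, 5e-4)
  # independence: proportional table
  r3 <- mk_test(10, 5, 20, 10)
  expect_equal(r3$NI, 1)
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p.value, 1)
  # zero cells flag NI as undefined rather than infinite
  r4 <- mk_test(10, 5, 0, 10)
  expect_false(r4$ni_defined)
  expect_true(is.na(r4$NI))
  expect_error(mk_test(0, 0, 0, 0), "all-zero")
  expect_output(print(r1), "NI")
})

test_that("MK invariances: transposition, row swap, reciprocal NI", {
  chi <- function(m) {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - E)^2 / E)
  }
  withr::with_seed(7, {
    for (i in 1:10) {
      x <- matrix(runif(4, 1, 100), 2, 2)
      r <- mk_test(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
      expect_equal(r$statistic, chi(t(x)), tolerance = 1e-10)
      swapped <- mk_test(x[2, 1], x[2, 2], x[1, 1], x[1, 2])
      expect_equal(swapped$statistic, r$statistic, tolerance = 1e-10)
      expect_equal(r$NI * swapped$NI, 1, tolerance = 1e-10)
    }
  })
})

test_that("suite aggregation reports conservative bounds", {
  # two synthetic references around a 2-haplotype sample
  base <- random_codon_seq(150, 61)
  smp <- simulate_population_sample(base, 8, 0.05, 0.02, seed = 62)
  ref1 <- simulate_divergence(base, 0.06, 0.02, seed = 63)$seq
  ref2 <- simulate_divergence(base, 0.12, 0.05, seed = 64)$seq
  rng <- mk_vs_reconstruction_suite(smp, list(m1 = ref1, m2 = ref2))
  m1 <- mk_sample_vs_reference(smp, ref1)
  m2 <- mk_sample_vs_reference(smp, ref2)
  expect_equal(rng$NI_max, max(m1$NI, m2$NI))
  expect_equal(rng$chi2_min, min(m1$statistic, m2$statistic))
  expect_equal(rng$ranges$Ds, range(m1$counts$Ds, m2$counts$Ds))
  expect_equal(rng$p_at_chi2_min,
               (if (m1$statistic < m2$statistic) m1 else m2)$p.value)
  # single member: ranges collapse to points
  one <- mk_vs_reconstruction_suite(smp, list(m1 = ref1))
  expect_equal(one$ranges$Ds[1], one$ranges$Ds[2])
  expect_equal(one$NI_max, m1$NI)
  # identical members: zero-width ranges
  two <- mk_vs_reconstruction_suite(smp, list(a = ref1, b = ref1))
  expect_equal(two$ranges$Dn[1], two$ranges$Dn[2])
  expect_output(print(rng), "NI <=")
})

test_that("pairwise MK pools polymorphism and corrects divergence", {
  base <- random_codon_seq(150, 65)
  a <- simulate_population_sample(base, 10, 0.05, 0.02, seed = 66)
  bbase <- simulate_divergence(base, 0.1, 0.04, seed = 67)$seq
  b <- simulate_population_sample(bbase, 6, 0.05, 0.02, seed = 68)
  pw <- pairwise_mk(a, b)
  pa <- count_polymorphisms(a); pb <- count_polymorphisms(b)
  expect_equal(pw$counts$Ps, pa$Ps + pb$Ps)
  expect_equal(pw$counts$Pn, pa$Pn + pb$Pn)
  expect_gte(pw$counts$Ds, pw$counts$Ds_raw)
  expect_gte(pw$counts$Dn, pw$counts$Dn_raw)
  # identical samples: no divergence, test flagged undefined
  same <- pairwise_mk(a, a)
  expect_equal(same$counts$Ds_raw + same$counts$Dn_raw, 0)
  expect_false(same$ni_defined)
  expect_error(pairwise_mk(a, hap_sample(h1 = "TTT", h2 = "TTT")), "length")
})

test_that("published per-gene polymorphism counts pool to the pairwise rows", {
  g <- gss_mk_counts()
  p <- g$polymorphisms
  pool <- function(i, j) c(p$Ps[i] + p$Ps[j], p$Pn[i] + p$Pn[j])
  expect_equal(pool(1, 2), unlist(g$pairwise[1, c("Ps", "Pn")],
                                  use.names = FALSE))
  expect_equal(pool(1, 3), unlist(g$pairwise[2, c("Ps", "Pn")],
                                  use.names = FALSE))
  expect_equal(pool(2, 3), unlist(g$pairwise[3, c("Ps", "Pn")],
                                  use.names = FALSE))
})
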