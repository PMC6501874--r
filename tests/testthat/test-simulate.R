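test_that("alignment simulation is seed-deterministic, byte for byte", {
  tr <- quartet_tree()
  s1 <- simulate_codon_alignment(tr, 50, kappa = 2, omega = 0.5, seed = 71)
  s2 <- simulate_codon_alignment(tr, 50, kappa = 2, omega = 0.5, seed = 71)
  f1 <- tempfile(); f2 <- tempfile()
  write_codon_fasta(s1$alignment, f1)
  write_codon_fasta(s2$alignment, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(s1$site_classes, s2$site_classes)
  s3 <- simulate_codon_alignment(tr, 50, kappa = 2, omega = 0.5, seed = 72)
  expect_false(identical(s1$alignment$codons, s3$alignment$codons))
  unlink(c(f1, f2))
})

test_that("degenerate regimes behave as expected", {
  # zero branch lengths: all tips identical
  trz <- ape::read.tree(text = "(A:0,B:0,C:0,D:0);")
  sz <- simulate_codon_alignment(trz, 30, kappa = 2, omega = 0.7, seed = 73)
  expect_equal(nrow(unique(sz$alignment$codons)), 1)
  # omega = 0: the protein can never change, so every column translates
  # identically across tips (pathway-averaged nsyn counts may still be
  # fractionally positive for synonymous codon pairs in different blocks,
  # e.g. CTC/TTA, both Leu)
  tr <- quartet_tree()
  s0 <- simulate_codon_alignment(tr, 200, kappa = 2, omega = 0, seed = 74)
  cd <- dupsel:::codon_data()
  m <- s0$alignment$codons
  aa <- matrix(cd$aa61[m], nrow(m))
  expect_true(all(apply(aa, 2, function(x) length(unique(x)) == 1)))
})

test_that("omega = 1 yields pathway-counted dN/dS near 1 (kappa = 1)", {
  # unweighted Nei-Gojobori site counts are only unbiased without a
  # transition/transversion asymmetry, hence kappa = 1 here
  tr2 <- ape::read.tree(text = "(A:0.3,B:0.3);")
  s <- simulate_codon_alignment(tr2, 2000, kappa = 1, omega = 1, seed = 75)
  m <- s$alignment$codons
  pt <- dupsel:::pathway_tables(dupsel:::codon_data())
  idx <- cbind(m[1, ], m[2, ])
  ps <- sum(pt$syn[idx]); pn <- sum(pt$nsyn[idx])
  sc1 <- alignment_site_counts(m[1, ]); sc2 <- alignment_site_counts(m[2, ])
  S <- (sc1$syn_sites + sc2$syn_sites) / 2
  N <- (sc1$nsyn_sites + sc2$nsyn_sites) / 2
  ratio <- (pn / N) / (ps / S)
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("population samples respect theta and never contain stops", {
  base <- random_codon_seq(200, 76)
  zero <- simulate_population_sample(base, 10, 0, 0, seed = 77)
  expect_equal(nrow(unique(zero$codons)), 1)
  smp <- simulate_population_sample(base, 12, 0.08, 0.03, seed = 78)
  expect_false(anyNA(smp$codons))        # sense codons everywhere
  # one single-base event per distinct codon position: counts recover truth
  tru <- attr(smp, "truth")
  cnt <- count_polymorphisms(smp)
  expect_equal(cnt$Ps, tru$n_syn)
  expect_equal(cnt$Pn, tru$n_nsyn)
  rep2 <- simulate_population_sample(base, 12, 0.08, 0.03, seed = 78)
  expect_identical(smp$codons, rep2$codons)
})

test_that("counted synonymous polymorphism scales linearly with theta", {
  base <- random_codon_seq(300, 79)
  thetas <- c(0.02, 0.05, 0.1)
  means <- sapply(seq_along(thetas), function(k)
    mean(sapply(1:12, function(i) {
      s <- simulate_population_sample(base, 10, thetas[k], 0.01,
                                      seed = 800 + 20 * k + i)
      count_polymorphisms(s)$Ps
    })))
  S <- alignment_site_counts(base)$syn_sites
  slope <- coef(lm(means ~ thetas))[2]
  expect_equal(unname(slope), S, tolerance = 0.25)
})

test_that("scenario presets encode the four retention regimes", {
  pr <- scenario_presets()
  expect_named(pr, c("neutral", "NF", "EAC", "CN"))
  expect_equal(pr$neutral$params$omega2, 1)
  expect_equal(pr$NF$params$omega2, 4)
  expect_length(pr$EAC$tree$foreground, 2)
  expect_length(pr$NF$tree$foreground, 1)
  sim <- simulate_scenario(pr$CN, seed = 81)
  expect_equal(sim$alignment$n_codons, 300)
  expect_equal(sum(sim$site_classes >= 3) / 300, 0.1, tolerance = 0.5)
  # CN annotation fixture feeds the classifier to a CN verdict by construction
  ann <- pr$CN$annotations
  call <- classify_retention(
    branch_evidence("gss12", 1e-4, ann[["gss12"]]),
    branch_evidence("gss3", 1e-4, ann[["gss3"]]))
  expect_equal(call$mode, "CN")
  # EAC fixture likewise
  ann <- pr$EAC$annotations
  expect_equal(classify_retention(
    branch_evidence("gss12", 1e-4, ann[["gss12"]]),
    branch_evidence("gss3", 1e-3, ann[["gss3"]]))$mode, "EAC")
})
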