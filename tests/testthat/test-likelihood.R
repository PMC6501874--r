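test_that("zero-length tree likelihood reduces to the root frequency", {
  one <- codon_alignment(c(A = "AAA", B = "AAA"))
  trz <- ape::read.tree(text = "(A:0,B:0);")
  expect_equal(tree_log_likelihood(one, trz, "M0", kappa = 2, omega = 0.5,
                                   pi = rep(1 / 61, 61)),
               log(1 / 61))
})

test_that("pruning equals brute-force state enumeration (M0 and branch-site)", {
  tr3 <- triplet_tree()
  sim <- simulate_codon_alignment(tr3, 2, kappa = 2, omega = 0.5, seed = 21)
  expect_equal(
    tree_log_likelihood(sim$alignment, tr3, "M0", kappa = 1.7, omega = 0.35,
                        frequencies = "equal"),
    enumerate_loglik(sim$alignment, tr3, "M0", kappa = 1.7, omega = 0.35,
                     frequencies = "equal"),
    tolerance = 1e-12)

  tr4 <- quartet_tree(fg = "D")
  sim4 <- simulate_codon_alignment(tr4, 2, kappa = 2, omega = 0.5, seed = 22)
  for (frq in c("equal", "f3x4")) {
    expect_equal(
      tree_log_likelihood(sim4$alignment, tr4, "branch_site", kappa = 2.2,
                          omega0 = 0.15, omega2 = 4, p0 = 0.5, p1 = 0.3,
                          frequencies = frq),
      enumerate_loglik(sim4$alignment, tr4, "branch_site", kappa = 2.2,
                       omega0 = 0.15, omega2 = 4, p0 = 0.5, p1 = 0.3,
                       frequencies = frq),
      tolerance = 1e-12)
  }
  # internal foreground branch
  tri <- read_codon_tree(text = "((A:0.2,B:0.3)#1:0.3,C:0.25,D:0.4);")
  expect_equal(
    tree_log_likelihood(sim4$alignment, tri, "branch_site", kappa = 2,
                        omega0 = 0.2, omega2 = 3, p0 = 0.6, p1 = 0.2,
                        frequencies = "equal"),
    enumerate_loglik(sim4$alignment, tri, "branch_site", kappa = 2,
                     omega0 = 0.2, omega2 = 3, p0 = 0.6, p1 = 0.2,
                     frequencies = "equal"),
    tolerance = 1e-12)
})

test_that("likelihood is invariant to root placement (reversibility)", {
  tr <- quartet_tree()
  sim <- simulate_codon_alignment(tr, 40, kappa = 2, omega = 0.5, seed = 23)
  base <- tree_log_likelihood(sim$alignment, tr, "M0", kappa = 2, omega = 0.5,
                              frequencies = "equal")
  for (og in c("A", "C", "D")) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    rr$foreground <- integer(0)
    expect_equal(tree_log_likelihood(sim$alignment, rr, "M0", kappa = 2,
                                     omega = 0.5, frequencies = "equal"),
                 base, tolerance = 1e-8)
  }
})

test_that("likelihood preconditions are enforced", {
  tr <- quartet_tree()
  aln <- codon_alignment(c(A = "ATG", B = "ATG", C = "ATG"))
  expect_error(tree_log_likelihood(aln, tr, "M0", kappa = 2, omega = 1),
               "missing from alignment")
  sim <- simulate_codon_alignment(tr, 5, kappa = 2, omega = 0.5, seed = 2)
  expect_error(tree_log_likelihood(sim$alignment, tr, "branch_site", kappa = 2,
                                   omega0 = .1, omega2 = 2, p0 = .7, p1 = .2),
               "foreground")
})
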