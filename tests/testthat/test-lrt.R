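test_that("Holm-Bonferroni adjustment matches the hand-computed procedure", {
  expect_equal(holm_adjust(c(0.001, 0.02, 0.04)), c(0.003, 0.04, 0.04))
  expect_equal(holm_adjust(0.37), 0.37)
  expect_equal(holm_adjust(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone, never below raw, rank-preserving
  withr::with_seed(99, {
    for (i in 1:20) {
      p <- runif(sample(2:8, 1))
      a <- holm_adjust(p)
      expect_true(all(a >= p))
      expect_true(all(a <= 1))
      expect_equal(order(a[order(p)]), seq_along(p))
    }
  })
})

test_that("branch-site LRT: nesting, boundary and chi-square reference", {
  pr <- scenario_presets(n_codons = 120)
  sim <- simulate_scenario(pr$NF, seed = 41)
  res <- branch_site_lrt(sim$alignment, pr$NF$tree, "gss12", seed = 1)
  expect_s3_class(res, "bs_lrt")
  expect_gte(res$lnL_alt, res$lnL_null - 1e-6)
  expect_gte(res$stat, 0)
  expect_equal(res$df, 1L)
  expect_equal(res$p.value, pchisq(res$stat, 1, lower.tail = FALSE))
  expect_true(res$converged)
  expect_output(print(res), "X2")
  # an invariant alignment carries no information: stat collapses to 0, p = 1
  flat <- codon_alignment(setNames(rep(paste(rep("ATGGGATTA", 4), collapse = ""),
                                       6), pr$NF$tree$tip.label))
  res0 <- branch_site_lrt(flat, pr$NF$tree, "gss12", seed = 1)
  expect_equal(res0$stat, 0, tolerance = 1e-4)
  expect_gt(res0$p.value, 0.99)
})

test_that("branch scans adjust jointly and rank truly selected branches first", {
  pr <- scenario_presets()
  sim <- simulate_scenario(pr$EAC, seed = 42)   # selection on gss12 AND gss3
  sc <- scan_branches(sim$alignment, pr$EAC$tree,
                      c("gss12", "gss3", "gss12x", "YcC"), seed = 1)
  expect_s3_class(sc, "bs_scan")
  expect_equal(sc$branch, c("gss12", "gss3", "gss12x", "YcC"))
  expect_true(all(sc$p_adj >= sc$p_raw - 1e-12))
  # the strongest signal in the scan sits on a truly selected branch (the
  # longer selected stem dominates; the short one carries little power)
  expect_true(sc$branch[which.min(sc$p_raw)] %in% c("gss12", "gss3"))
  expect_lt(min(sc$p_adj[sc$branch %in% c("gss12", "gss3")]),
            min(sc$p_adj[!sc$branch %in% c("gss12", "gss3")]) + 1e-12)
  expect_output(print(sc), "Holm")
  # single-branch scan: Holm with m = 1 is the identity
  one <- scan_branches(sim$alignment, pr$EAC$tree, "gss12", seed = 1)
  expect_equal(one$p_adj, one$p_raw)
})

test_that("site-class posteriors are normalised and prior-like when uninformative", {
  pr <- scenario_presets(n_codons = 100)
  sim <- simulate_scenario(pr$NF, seed = 43)
  fit <- fit_codon_model(sim$alignment, pr$NF$tree, "branch_site",
                         n_starts = 2, seed = 1)
  post <- site_class_posteriors(fit)
  expect_equal(rowSums(post[, c("p0", "p1", "p2a", "p2b")]),
               rep(1, nrow(post)), tolerance = 1e-9)
  expect_true(all(post$p_selected >= 0 & post$p_selected <= 1))
  m0 <- fit_codon_model(sim$alignment, pr$NF$tree, "M0", n_starts = 1, seed = 1)
  expect_error(site_class_posteriors(m0), "branch-site")
  # with omega2 pinned at 1 an invariant column is uninformative about the
  # class, so its posterior equals the prior proportions
  flat <- codon_alignment(setNames(rep(paste(rep("ATGGGATTA", 3), collapse = ""),
                                       6), pr$NF$tree$tip.label))
  fn <- fit_codon_model(flat, pr$NF$tree, "branch_site_null",
                        n_starts = 1, seed = 1)
  pn <- site_class_posteriors(fn)
  expect_equal(unlist(pn[1, c("p0", "p1", "p2a", "p2b")], use.names = FALSE),
               fn$proportions, tolerance = 1e-6)
})
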