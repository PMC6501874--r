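test_that("marginal reconstruction equals brute-force Bayes on 3-taxon cases", {
  tr <- triplet_tree()
  aln <- codon_alignment(c(A = "TTTGGA", B = "TTCGGA", C = "CTTGAA"))
  fit <- fit_codon_model(aln, tr, "M0", frequencies = "equal",
                         n_starts = 1, seed = 1)
  rec <- marginal_reconstruction(fit, 4)
  bf <- enumerate_node_posterior(aln, fit$tree, 4, "M0",
                                 kappa = fit$params$kappa,
                                 omega = fit$params$omega,
                                 pi = rep(1 / 61, 61))
  expect_lt(max(abs(rec$state_posteriors - bf)), 1e-10)
  expect_equal(rowSums(rec$state_posteriors), rep(1, 2), tolerance = 1e-9)
  expect_equal(rec$map_codons,
               colnames(bf)[apply(bf, 1, which.max)])
})

test_that("branch-site reconstruction marginalises classes (oracle check)", {
  tr <- set_foreground(triplet_tree(), "C")
  sim <- simulate_codon_alignment(tr, 20, kappa = 2, omega0 = 0.2, omega2 = 4,
                                  p0 = 0.6, p1 = 0.2, seed = 53)
  aln <- sim$alignment
  fit <- fit_codon_model(aln, tr, "branch_site", frequencies = "equal",
                         n_starts = 1, seed = 1,
                         branch_lengths = c(0.3, 0.2, 0.4))
  rec <- marginal_reconstruction(fit, 4)
  p <- fit$params
  bf <- enumerate_node_posterior(aln, fit$tree, 4, "branch_site",
                                 kappa = p$kappa, omega0 = p$omega0,
                                 omega2 = p$omega2, p0 = p$p0, p1 = p$p1,
                                 pi = rep(1 / 61, 61))
  expect_lt(max(abs(rec$state_posteriors - bf)), 1e-10)
})

test_that("consensus dominance and zero-length-branch identities hold", {
  # star tree, identical tips, short branches: MAP is the shared codon
  star <- ape::read.tree(text = "(A:0.01,B:0.01,C:0.01,D:0.01);")
  aln <- codon_alignment(setNames(rep("TGGATT", 4), c("A", "B", "C", "D")))
  fit <- fit_codon_model(aln, star, "M0", frequencies = "equal", n_starts = 1,
                         seed = 1, branch_lengths = rep(0.01, 4))
  rec <- marginal_reconstruction(fit, 5)
  expect_equal(rec$map_codons, c("TGG", "ATT"))
  expect_true(all(rec$site_posteriors > 0.99))
  # a zero-length internal branch makes parent and child posteriors equal
  tr <- read_codon_tree(text = "((A:0.2,B:0.3)x:0.0,C:0.25,D:0.4);")
  sim <- simulate_codon_alignment(tr, 10, kappa = 2, omega = 0.4, seed = 51)
  pd <- dupsel:::prepare_pruning_data(sim$alignment, tr)
  bl <- pd$el
  internal_edge <- which(pd$edge[, 2] > ape::Ntip(tr))
  bl[internal_edge] <- 1e-9
  f2 <- fit_codon_model(sim$alignment, tr, "M0", frequencies = "equal",
                        n_starts = 1, seed = 1, branch_lengths = bl)
  parent <- ape::Ntip(tr) + 1
  child <- pd$edge[internal_edge, 2]
  ra <- marginal_reconstruction(f2, parent)
  rb <- marginal_reconstruction(f2, child)
  expect_lt(max(abs(ra$state_posteriors - rb$state_posteriors)), 1e-6)
  # tips are refused
  expect_error(marginal_reconstruction(f2, "A"), "tip")
})

test_that("reconstruction suites are labelled, deterministic and complete", {
  pr <- scenario_presets(n_codons = 80)
  sim <- simulate_scenario(pr$NF, seed = 52)
  specs <- list(list(model = "M0"),
                list(model = "branch_site", foreground = "gss12"),
                list(model = "branch_site_null", foreground = "gss12"))
  node <- "gss12"
  s1 <- reconstruction_suite(sim$alignment, pr$NF$tree, node, specs, seed = 3)
  expect_s3_class(s1, "recon_suite")
  expect_length(s1$members, 3)
  expect_equal(s1$members[[1]]$model_label, "M0")
  expect_match(s1$members[[2]]$model_label, "w2>1")
  expect_match(s1$members[[3]]$model_label, "w2=1")
  # identical specs reproduce identical sequences under the same seed
  s2 <- reconstruction_suite(sim$alignment, pr$NF$tree, node, specs, seed = 3)
  expect_equal(as.character(s2$members[[2]]), as.character(s1$members[[2]]))
  # a single-spec suite equals the direct reconstruction
  fit <- fit_codon_model(sim$alignment, pr$NF$tree, "M0", n_starts = 2,
                         seed = 3)
  direct <- marginal_reconstruction(fit, node)
  expect_equal(as.character(s1$members[[1]]), as.character(direct))
})
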