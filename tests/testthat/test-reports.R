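test_that("MK reports follow the published rounding and range conventions", {
  r1 <- mk_test(142.0, 15.0, 5.1, 6.0)
  df <- write_mk_report(list("G1 vs G2" = r1))
  expect_equal(names(df), c("comparison", "Ps", "Pn", "Ds", "Dn", "NI",
                            "chi2", "P"))
  expect_equal(df$NI, "0.09")
  expect_equal(df$chi2, "18.8")
  expect_equal(df$P, "0.000")
  # range results render min-max cells and <= / >= bounds
  base <- random_codon_seq(120, 91)
  smp <- simulate_population_sample(base, 8, 0.05, 0.02, seed = 92)
  refs <- list(m1 = simulate_divergence(base, 0.05, 0.02, seed = 93)$seq,
               m2 = simulate_divergence(base, 0.12, 0.06, seed = 94)$seq)
  rng <- mk_vs_reconstruction_suite(smp, refs)
  dfr <- write_mk_report(list(anc = rng))
  expect_match(dfr$NI, "^<=")
  expect_match(dfr$chi2, "^>=")
  if (abs(diff(rng$ranges$Ds)) >= 0.05) expect_match(dfr$Ds, "-")
  expect_error(write_mk_report(list()), "empty")
})

test_that("TSV and JSON report files are consistent", {
  r <- mk_test(86, 12, 899.0, 378.1)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_mk_report(list(YcC = r), tsv = tsv, json = js)
  tab <- read.delim(tsv, check.names = FALSE, colClasses = "character")
  full <- jsonlite::read_json(js)
  expect_equal(tab$NI, sprintf("%.2f", full$YcC$NI))
  expect_equal(tab$chi2, sprintf("%.1f", full$YcC$chi2))
  expect_equal(full$YcC$Ds, 899.0)
  unlink(c(tsv, js))
})

test_that("scan reports round for display and keep full precision in JSON", {
  pr <- scenario_presets(n_codons = 90)
  sim <- simulate_scenario(pr$NF, seed = 95)
  sc <- scan_branches(sim$alignment, pr$NF$tree, c("gss12", "gss3"), seed = 1)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_scan_report(sc, tsv = tsv, json = js)
  tab <- read.delim(tsv)
  expect_equal(tab$branch, c("gss12", "gss3"))
  full <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(round(full$p_raw, 3), as.numeric(tab$P_raw), tolerance = 1e-9)
  unlink(c(tsv, js))
})

test_that("reconstructed sequences are written with model labels", {
  pr <- scenario_presets(n_codons = 60)
  sim <- simulate_scenario(pr$NF, seed = 96)
  suite <- reconstruction_suite(sim$alignment, pr$NF$tree, "gss12",
                                list(list(model = "M0")), seed = 1)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_reconstruction(suite, fasta = fa, tsv = tsv)
  lines <- readLines(fa)
  expect_match(lines[1], "M0")
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 60)
  expect_true(all(tab$posterior > 0 & tab$posterior <= 1))
  unlink(c(fa, tsv))
})
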