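# ---- operating-characteristic studies ---------------------------------------
# Seeded simulation studies of the package's own tests: null calibration and
# power of the branch-site LRT, M0 parameter recovery, and MK calibration.
# These back the package's validation suite and the reproduction script.

#' Null calibration of the branch-site LRT
#'
#' Simulates replicates under the neutral preset (omega2 = 1 everywhere) and
#' tests the marked daughter branch, returning the raw p-values. With the
#' conservative chi-square(1) convention the rejection rate at alpha = 0.05
#' is expected at or below the nominal level.
#'
#' @param n_rep number of replicates.
#' @param seed integer seed (replicate i uses `seed + i`).
#' @param n_codons codons per simulated alignment.
#' @return numeric vector of p-values.
#' @export
bs_null_calibration <- function(n_rep = 200, seed = 1, n_codons = 300) {
  sc <- scenario_presets(n_codons = n_codons)$neutral
  vapply(seq_len(n_rep), function(i) {
    sim <- simulate_scenario(sc, seed = seed + i)
    branch_site_lrt(sim$alignment, sc$tree, "gss12", seed = 1)$p.value
  }, 0)
}

#' Power of the branch-site LRT under episodic positive selection
#'
#' Simulates replicates under the NF preset (foreground omega2 on one
#' daughter stem) and tests that branch.
#'
#' @inheritParams bs_null_calibration
#' @param omega2 foreground omega of the generating scenario.
#' @return numeric vector of p-values.
#' @export
bs_power_study <- function(n_rep = 100, seed = 1, n_codons = 300, omega2 = 4) {
  sc <- scenario_presets(n_codons = n_codons, omega2 = omega2)$NF
  vapply(seq_len(n_rep), function(i) {
    sim <- simulate_scenario(sc, seed = seed + i)
    branch_site_lrt(sim$alignment, sc$tree, "gss12", seed = 1)$p.value
  }, 0)
}

#' Parameter recovery of the M0 fit
#'
#' Simulates M0 data on a four-taxon tree and refits, returning the
#' maximum-likelihood estimates per replicate.
#'
#' @inheritParams bs_null_calibration
#' @param omega,kappa true generating values.
#' @return data.frame with `omega_hat`, `kappa_hat`, `lnL`, `converged`.
#' @export
m0_recovery_study <- function(n_rep = 20, seed = 1, omega = 0.3, kappa = 2,
                              n_codons = 500) {
  tr <- read_codon_tree(text = "((A:0.2,B:0.3):0.15,C:0.25,D:0.4);")
  out <- lapply(seq_len(n_rep), function(i) {
    sim <- simulate_codon_alignment(tr, n_codons, kappa = kappa, omega = omega,
                                    seed = seed + i)
    f <- fit_codon_model(sim$alignment, tr, "M0", n_starts = 2, seed = 1)
    data.frame(omega_hat = f$params$omega, kappa_hat = f$params$kappa,
               lnL = f$lnL, converged = f$converged)
  })
  do.call(rbind, out)
}

#' Calibration of the MK test on simulated population data
#'
#' Per replicate: a base sequence spawns a within-species haplotype sample
#' (Poisson polymorphism overlay) and a diverged reference; the full MK stack
#' (pathway counting, fixed-column divergence, Jukes-Cantor correction,
#' Pearson chi-square) is run against the reference. `ratio_poly` and
#' `ratio_div` set the nonsynonymous:synonymous per-site intensity ratios of
#' the two processes; with equal ratios the expected Neutrality Index is 1,
#' and in general the mean NI converges to `ratio_poly / ratio_div`.
#'
#' @inheritParams bs_null_calibration
#' @param n_codons base-sequence length.
#' @param n_haplotypes sampled alleles per replicate.
#' @param theta_syn synonymous polymorphism intensity per site.
#' @param d_syn synonymous divergence per site.
#' @param ratio_poly,ratio_div nonsynonymous:synonymous intensity ratios for
#'   polymorphism and divergence.
#' @return data.frame with `NI`, `chi2`, `p`, and the four counts.
#' @export
mk_calibration_study <- function(n_rep = 100, seed = 1, n_codons = 500,
                                 n_haplotypes = 20, theta_syn = 0.12,
                                 d_syn = 0.10, ratio_poly = 1, ratio_div = 1) {
  out <- lapply(seq_len(n_rep), function(i) {
    base <- withr::with_seed(seed + 3L * i, {
      cd61 <- codon_data()$codons61
      paste(sample(cd61, n_codons, replace = TRUE), collapse = "")
    })
    ref <- simulate_divergence(base, d_syn, d_syn * ratio_div,
                               seed = seed + 3L * i + 1L)$seq
    smp <- simulate_population_sample(base, n_haplotypes, theta_syn,
                                      theta_syn * ratio_poly,
                                      seed = seed + 3L * i + 2L)
    r <- mk_sample_vs_reference(smp, ref)
    data.frame(NI = r$NI, chi2 = r$statistic, p = r$p.value,
               Ps = r$counts$Ps, Pn = r$counts$Pn,
               Ds = r$counts$Ds, Dn = r$counts$Dn)
  })
  do.call(rbind, out)
}
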