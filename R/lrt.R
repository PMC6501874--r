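# ---- branch-site likelihood-ratio tests -------------------------------------

#' Branch-site test of episodic positive selection on one branch
#'
#' Fits the branch-site model A alternative (foreground omega2 free, >= 1)
#' and null (omega2 = 1) with the given branch as foreground, and compares
#' them by a likelihood-ratio test with the statistic referred to the
#' chi-square distribution with 1 degree of freedom (a conservative
#' convention relative to the 50:50 boundary mixture).
#'
#' By default branch lengths are estimated once under M0 on the same data and
#' held fixed in both branch-site fits, which makes genome-scale scans and
#' simulation studies tractable; set `branch_lengths = "estimate"` to
#' re-estimate them under each model. The null model is fitted first and its
#' solution seeds the alternative fit, so the nesting inequality
#' `lnL_alt >= lnL_null` holds by construction.
#'
#' @inheritParams fit_codon_model
#' @param foreground the branch to test (tip/node label or node number; see
#'   [set_foreground()]).
#' @param m0_fit optional precomputed M0 [fit_codon_model()] on the same
#'   alignment and tree, reused for the fixed branch lengths.
#' @param branch_lengths `"m0"` (default) or `"estimate"`.
#' @return object of class `bs_lrt`: `stat` (2 delta lnL, clipped at 0),
#'   `df`, `p.value`, the two fits, and the foreground id.
#' @export
branch_site_lrt <- function(aln, tree, foreground, seed = NULL,
                            m0_fit = NULL, branch_lengths = c("m0", "estimate"),
                            frequencies = "f3x4", n_starts = 2,
                            control = list()) {
  branch_lengths <- match.arg(branch_lengths)
  tree <- set_foreground(tree, foreground)
  bl <- "estimate"
  fix_kappa <- NULL
  if (branch_lengths == "m0") {
    if (is.null(m0_fit))
      m0_fit <- fit_codon_model(aln, tree, "M0", frequencies = frequencies,
                                n_starts = 1, seed = seed, control = control)
    bl <- m0_fit$branch_lengths
    fix_kappa <- m0_fit$params$kappa   # kappa profiled under M0
  }
  # the foreground branch length is re-optimised in BOTH branch-site fits, so
  # misfit of the shared M0 lengths on that branch cannot masquerade as omega2
  free_br <- if (branch_lengths == "m0") {
    tr_post <- ape::reorder.phylo(tree, "postorder")
    which(foreground_edges(tr_post))
  }
  null <- fit_codon_model(aln, tree, "branch_site_null",
                          frequencies = frequencies, branch_lengths = bl,
                          free_branches = free_br,
                          fix_kappa = fix_kappa, n_starts = max(1, n_starts - 1),
                          seed = seed, control = control)
  # seed the alternative from the null solution: once with omega2 pushed off
  # the boundary, once at the boundary itself (the latter guarantees
  # lnL_alt >= lnL_null)
  warm <- null$params[c("kappa", "omega0", "p0", "p1")]
  alt_inits <- list(c(warm, list(omega2 = 2.5)),
                    c(warm, list(omega2 = 1 + 1e-4)))
  bl_alt <- if (identical(bl, "estimate")) bl else null$branch_lengths
  alt <- fit_codon_model(aln, tree, "branch_site",
                         frequencies = frequencies, branch_lengths = bl_alt,
                         free_branches = free_br,
                         fix_kappa = fix_kappa, n_starts = n_starts,
                         seed = seed, init = alt_inits, control = control)
  stat <- max(0, 2 * (alt$lnL - null$lnL))
  structure(list(
    foreground = foreground,
    foreground_nodes = tree$foreground,
    stat = stat,
    df = 1L,
    p.value = pchisq(stat, df = 1, lower.tail = FALSE),
    lnL_alt = alt$lnL,
    lnL_null = null$lnL,
    alt = alt,
    null = null,
    converged = alt$converged && null$converged
  ), class = "bs_lrt")
}

#' @export
print.bs_lrt <- function(x, ...) {
  cat("branch-site LRT, foreground:", paste(x$foreground, collapse = ","), "\n")
  cat(sprintf("  lnL(alt) = %.4f  lnL(null) = %.4f\n", x$lnL_alt, x$lnL_null))
  cat(sprintf("  X2(1) = %.2f,  P = %.4g%s\n", x$stat, x$p.value,
              if (x$converged) "" else "  [unconverged fit]"))
  cat(sprintf("  omega2 = %.3f (foreground classes %.3f of sites)\n",
              x$alt$params$omega2, sum(x$alt$proportions[3:4])))
  invisible(x)
}

#' Scan a set of branches for episodic positive selection
#'
#' Runs [branch_site_lrt()] with each listed branch as foreground (one M0
#' fit of the data is shared across tests for the fixed branch lengths) and
#' applies the Holm-Bonferroni correction to the raw p-values.
#'
#' @inheritParams branch_site_lrt
#' @param branches vector of branch identifiers (tip/node labels or node
#'   numbers); the report preserves this order.
#' @param alpha significance level used only for display.
#' @return a `data.frame` of class `bs_scan`: one row per branch with
#'   `stat`, `p_raw`, `p_adj`, `omega2`, and convergence flags. Individual
#'   `bs_lrt` objects are attached as attribute `"tests"`.
#' @export
scan_branches <- function(aln, tree, branches, seed = NULL,
                          frequencies = "f3x4", branch_lengths = c("m0", "estimate"),
                          n_starts = 2, alpha = 0.05, control = list()) {
  branch_lengths <- match.arg(branch_lengths)
  if (!length(branches)) stop("empty branch set")
  m0 <- NULL
  if (branch_lengths == "m0")
    m0 <- fit_codon_model(aln, tree, "M0", frequencies = frequencies,
                          n_starts = max(2, n_starts), seed = seed,
                          control = control)
  tests <- lapply(branches, function(b) {
    tryCatch(branch_site_lrt(aln, tree, b, seed = seed, m0_fit = m0,
                             branch_lengths = branch_lengths,
                             frequencies = frequencies, n_starts = n_starts,
                             control = control),
             error = function(e) e)
  })
  ok <- !vapply(tests, inherits, TRUE, what = "error")
  p_raw <- rep(NA_real_, length(branches))
  p_raw[ok] <- vapply(tests[ok], `[[`, 0, "p.value")
  p_adj <- rep(NA_real_, length(branches))
  p_adj[ok] <- holm_adjust(p_raw[ok])
  out <- data.frame(
    branch = as.character(branches),
    stat = ifelse(ok, vapply(tests, function(t)
      if (inherits(t, "error")) NA_real_ else t$stat, 0), NA_real_),
    df = 1L,
    p_raw = p_raw,
    p_adj = p_adj,
    omega2 = vapply(tests, function(t)
      if (inherits(t, "error")) NA_real_ else t$alt$params$omega2, 0),
    converged = vapply(tests, function(t)
      if (inherits(t, "error")) FALSE else t$converged, TRUE),
    stringsAsFactors = FALSE
  )
  attr(out, "tests") <- tests
  attr(out, "alpha") <- alpha
  class(out) <- c("bs_scan", "data.frame")
  out
}

#' @export
print.bs_scan <- function(x, ...) {
  cat("branch-site scan (", nrow(x), " branches, Holm-adjusted)\n", sep = "")
  df <- as.data.frame(x)
  df$stat <- round(df$stat, 2)
  df$p_raw <- signif(df$p_raw, 3)
  df$p_adj <- signif(df$p_adj, 3)
  df$omega2 <- round(df$omega2, 3)
  df$sig <- ifelse(!is.na(df$p_adj) & df$p_adj <= attr(x, "alpha"), "*", "")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Thin wrapper over [stats::p.adjust()] (`method = "holm"`): adjusted
#' p-values are monotone, never smaller than the raw values, and capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

# ---- site-class posteriors --------------------------------------------------

#' Empirical-Bayes site-class posteriors under a branch-site fit
#'
#' Naive empirical Bayes at the maximum-likelihood estimates: for each codon
#' site the posterior probability of classes \{0, 1, 2a, 2b\} is proportional
#' to the class proportion times the class-conditional site likelihood.
#' Sites in classes 2a/2b on the foreground branch evolve under omega2; the
#' column `p_selected` (posterior of 2a plus 2b) summarises the evidence for
#' positive selection at the site.
#'
#' @param fit a `codon_fit` of model `"branch_site"` (or
#'   `"branch_site_null"`).
#' @param threshold reporting threshold attached to the result.
#' @return `data.frame` with one row per alignment codon column: class
#'   posteriors (`p0`, `p1`, `p2a`, `p2b`, rows summing to 1), `p_selected`,
#'   and `selected` (`p_selected >= threshold`). Gap-excluded columns carry
#'   `NA`.
#' @export
site_class_posteriors <- function(fit, threshold = 0.95) {
  if (fit$model == "M0")
    stop("site-class posteriors need a branch-site fit")
  pr <- fit$params
  cl <- bs_classes(pr$omega0, pr$omega2, pr$p0, pr$p1)
  ll <- class_site_logliks(fit$data, fit$pi, pr$kappa, cl,
                           fit$branch_lengths)
  lw <- sweep(ll, 2, log(pmax(cl$props, 1e-300)), "+")
  M <- apply(lw, 1, max)
  post <- exp(lw - M)
  post <- post / rowSums(post)
  full <- matrix(NA_real_, length(fit$data$pattern_of_site), 4)
  kept <- !is.na(fit$data$pattern_of_site)
  full[kept, ] <- post[fit$data$pattern_of_site[kept], ]
  out <- data.frame(site = seq_len(nrow(full)), p0 = full[, 1], p1 = full[, 2],
                    p2a = full[, 3], p2b = full[, 4])
  out$p_selected <- out$p2a + out$p2b
  out$selected <- !is.na(out$p_selected) & out$p_selected >= threshold
  attr(out, "threshold") <- threshold
  out
}
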