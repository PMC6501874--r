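#' Codon frequency estimation
#'
#' Equilibrium sense-codon frequencies for the substitution model: `equal`
#' (1/61), `f3x4` (products of position-specific nucleotide frequencies,
#' renormalised over sense codons; the usual default), or `f61` (empirical
#' codon frequencies). A small pseudocount keeps all frequencies positive,
#' which the reversible-model machinery requires.
#'
#' @param aln a [codon_alignment()] (unused for `mode = "equal"`).
#' @param mode frequency model.
#' @param pseudocount added per nucleotide (f3x4) or codon (f61) count.
#' @return numeric vector of 61 frequencies summing to 1.
#' @export
codon_frequencies <- function(aln = NULL, mode = c("f3x4", "equal", "f61"),
                              pseudocount = 0.5) {
  mode <- match.arg(mode)
  cd <- codon_data()
  n <- length(cd$codons61)
  if (mode == "equal") return(rep(1 / n, n))
  if (is.null(aln)) stop("mode '", mode, "' needs an alignment")
  idx <- as.vector(aln$codons)
  idx <- idx[!is.na(idx)]
  if (mode == "f61") {
    cnt <- tabulate(idx, n) + pseudocount
    return(cnt / sum(cnt))
  }
  # f3x4
  pi_pos <- matrix(0, 4, 3)
  for (p in 1:3) {
    cnt <- tabulate(cd$nt_idx[idx, p], 4) + pseudocount
    pi_pos[, p] <- cnt / sum(cnt)
  }
  pi <- pi_pos[cd$nt_idx[, 1], 1] * pi_pos[cd$nt_idx[, 2], 2] *
        pi_pos[cd$nt_idx[, 3], 3]
  pi / sum(pi)
}

#' Codon substitution rate matrix
#'
#' Builds the 61x61 generator of the Goldman-Yang-style codon model:
#' instantaneous rates are zero for multi-position changes and stop targets,
#' and otherwise proportional to the target frequency `pi_j`, multiplied by
#' `kappa` for transitions and by `omega` for nonsynonymous changes. The
#' matrix is scaled so that the mean substitution rate at stationarity is 1,
#' i.e. branch lengths are expected substitutions per codon.
#'
#' In site-class mixtures (branch-site models) the classes share one scale
#' factor instead, so that classes with larger omega evolve faster in
#' absolute terms; see the internal `mixture_rate_scale`.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi 61 sense-codon frequencies summing to 1.
#' @param scale rescale to mean rate 1 (set `FALSE` to apply an external
#'   shared scale factor).
#' @return 61x61 generator matrix with `pi` attached as attribute `"pi"`.
#' @export
build_rate_matrix <- function(kappa, omega, pi, scale = TRUE) {
  cd <- codon_data()
  n <- length(cd$codons61)
  if (length(pi) != n || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be ", n, " frequencies summing to 1")
  if (kappa <= 0 || omega < 0) stop("kappa must be > 0 and omega >= 0")
  Q <- matrix(0, n, n)
  Q[cd$single] <- rep(pi, each = n)[cd$single]
  Q[cd$single & cd$ts] <- Q[cd$single & cd$ts] * kappa
  Q[cd$single & cd$nonsyn] <- Q[cd$single & cd$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    r <- -sum(pi * diag(Q))
    if (r > 0) Q <- Q / r
  }
  attr(Q, "pi") <- pi
  dimnames(Q) <- list(cd$codons61, cd$codons61)
  Q
}

# Shared scale factor of a site-class mixture: the expected substitution rate
# per codon of the background process, averaged over class proportions, is
# normalised to 1. Branch lengths are therefore expected substitutions per
# codon on background branches; foreground classes with omega2 > 1 evolve
# proportionally faster.
mixture_rate_scale <- function(kappa, pi, classes, cache = NULL) {
  r <- vapply(unique(classes$bg), function(w) {
    key <- sprintf("r_%.17g_%.17g", kappa, w)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    Q <- build_rate_matrix(kappa, w, pi, scale = FALSE)
    v <- -sum(pi * diag(Q))
    if (!is.null(cache) && w == 1) cache[[key]] <- v
    v
  }, 0)
  names(r) <- sprintf("%.17g", unique(classes$bg))
  sum(classes$props * r[sprintf("%.17g", classes$bg)])
}

# symmetric eigendecomposition of a reversible generator, for fast P(t)
decompose_rate_matrix <- function(Q, pi = attr(Q, "pi")) {
  sp <- sqrt(pi)
  S <- Q * (sp %o% (1 / sp))            # diag(sp) Q diag(1/sp), symmetric
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(U = e$vectors / sp,              # diag(1/sp) V
       V = t(e$vectors * sp),           # t(V) diag(sp)
       lambda = e$values)
}

#' Transition probability matrix
#'
#' `exp(Q t)` via the symmetric eigendecomposition of the reversible
#' generator; rows are clamped to `[0, 1]` and renormalised against rounding
#' noise.
#'
#' @param Q generator from [build_rate_matrix()] (or a precomputed
#'   decomposition from the internal `decompose_rate_matrix`).
#' @param t branch length (>= 0), expected substitutions per codon.
#' @return 61x61 stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("negative branch length")
  dec <- if (is.matrix(Q)) decompose_rate_matrix(Q) else Q
  P <- dec$U %*% (exp(dec$lambda * t) * dec$V)
  P[P < 0] <- 0
  P / rowSums(P)
}
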