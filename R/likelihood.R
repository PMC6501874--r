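# ---- data preparation -------------------------------------------------------

# Compress an alignment against a tree into site patterns, postorder edges and
# foreground flags. Columns with any gap/ambiguity among the tree's tips are
# dropped from the likelihood (the alignments this targets are gap-stripped).
prepare_pruning_data <- function(aln, tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tips <- aln_tip_matrix(aln, tree$tip.label)
  kept <- colSums(is.na(tips)) == 0
  if (!any(kept)) stop("no gap-free alignment columns usable for the tree")
  tm <- tips[, kept, drop = FALSE]
  key <- apply(tm, 2, paste, collapse = ".")
  upat <- !duplicated(key)
  pat_id <- match(key, key[upat])
  w <- as.vector(table(factor(pat_id, levels = seq_len(sum(upat)))))
  tr <- ape::reorder.phylo(tree, "postorder")
  pattern_of_site <- rep(NA_integer_, length(kept))
  pattern_of_site[kept] <- pat_id
  list(tips = tm[, upat, drop = FALSE],
       w = w,
       pattern_of_site = pattern_of_site,
       kept = kept,
       edge = tr$edge,
       el = tr$edge.length,
       fg = foreground_edges(tr),
       n_tip = ape::Ntip(tree),
       n_node = ape::Ntip(tree) + tree$Nnode,
       tip_labels = tree$tip.label)
}

# Branch-site model A class structure: proportions over {0, 1, 2a, 2b} and the
# (background, foreground) omega of each class.
bs_classes <- function(omega0, omega2, p0, p1) {
  s <- p0 + p1
  p2 <- max(0, 1 - s)
  if (s < 1e-12) { w2a <- p2 / 2; w2b <- p2 / 2 }
  else { w2a <- p2 * p0 / s; w2b <- p2 * p1 / s }
  list(props = c(p0, p1, w2a, w2b),
       bg = c(omega0, 1, omega0, 1),
       fg = c(omega0, 1, omega2, omega2))
}

# Per-class cubes of per-edge transition matrices (61 x 61 x n_edge, postorder
# edge order). classes: list(props, bg, fg); bl overrides pd$el when given.
build_class_cubes <- function(pd, pi, kappa, classes, bl = NULL) {
  bl <- bl %||% pd$el
  n_edge <- nrow(pd$edge)
  sc <- mixture_rate_scale(kappa, pi, classes)
  omegas <- sort(unique(c(classes$bg, if (any(pd$fg)) classes$fg)))
  P <- lapply(omegas, function(w) {
    dec <- decompose_rate_matrix(
      build_rate_matrix(kappa, w, pi, scale = FALSE) / sc, pi)
    arr <- array(0, c(length(pi), length(pi), n_edge))
    for (e in seq_len(n_edge)) arr[, , e] <- transition_matrix(dec, bl[e])
    arr
  })
  names(P) <- sprintf("%.17g", omegas)
  lapply(seq_along(classes$props), function(k) {
    cube <- P[[sprintf("%.17g", classes$bg[k])]]
    if (any(pd$fg)) {
      fgP <- P[[sprintf("%.17g", classes$fg[k])]]
      cube[, , pd$fg] <- fgP[, , pd$fg]
    }
    cube
  })
}

# eigendecomposition of the unscaled generator, memoised for recurring
# omegas (the shared mixture scale only divides the eigenvalues)
unscaled_decomp <- function(kappa, omega, pi, cache = NULL) {
  key <- sprintf("d_%.17g_%.17g", kappa, omega)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  d <- decompose_rate_matrix(build_rate_matrix(kappa, omega, pi, scale = FALSE),
                             pi)
  if (!is.null(cache) && omega == 1) cache[[key]] <- d
  d
}

# Per-class per-pattern log-likelihoods (hot path: P-matrix construction and
# pruning consolidated in C++).
class_site_logliks <- function(pd, pi, kappa, classes, bl = NULL,
                               cache = NULL) {
  bl <- bl %||% pd$el
  sc <- mixture_rate_scale(kappa, pi, classes, cache)
  omegas <- sort(unique(c(classes$bg, if (any(pd$fg)) classes$fg)))
  key <- sprintf("%.17g", omegas)
  bg_idx <- match(sprintf("%.17g", classes$bg), key)
  fg_idx <- if (any(pd$fg)) match(sprintf("%.17g", classes$fg), key) else bg_idx
  decs <- lapply(omegas, function(w) unscaled_decomp(kappa, w, pi, cache))
  class_logliks_cpp(pd$edge, pd$tips, pi, pd$n_node, bl,
                    lapply(decs, `[[`, "U"), lapply(decs, `[[`, "V"),
                    lapply(decs, function(d) d$lambda / sc),
                    bg_idx, fg_idx, pd$fg)
}

# mixture log-likelihood: sum_patterns w * log sum_k props_k exp(ll_k)
mix_loglik <- function(ll, props, w) {
  keep <- props > 0
  lw <- sweep(ll[, keep, drop = FALSE], 2, log(props[keep]), "+")
  M <- apply(lw, 1, max)
  sum(w * (M + log(rowSums(exp(lw - M)))))
}

# ---- public likelihood ------------------------------------------------------

#' Codon-model log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over the 61 sense-codon states, with site-pattern
#' compression. Under `model = "branch_site"` each site is a mixture over the
#' four classes \{0, 1, 2a, 2b\} of branch-site model A, with the foreground
#' omega applied on branches marked in the tree (or via `foreground`).
#'
#' @param aln a [codon_alignment()] containing all tree tips.
#' @param tree a `phylo` tree with branch lengths (expected substitutions per
#'   codon).
#' @param model `"M0"` (single omega) or `"branch_site"`.
#' @param kappa transition/transversion ratio.
#' @param omega M0 nonsynonymous/synonymous ratio.
#' @param omega0,omega2,p0,p1 branch-site parameters: background omega in
#'   `[0, 1]`, foreground omega `>= 1`, and the class-0/class-1 proportions.
#' @param frequencies codon frequency mode (see [codon_frequencies()]) used
#'   when `pi` is not given.
#' @param pi optional explicit 61-vector of codon frequencies.
#' @param foreground optional branch marks (see [set_foreground()]).
#' @return the log-likelihood (numeric scalar).
#' @export
tree_log_likelihood <- function(aln, tree, model = c("M0", "branch_site"),
                                kappa, omega = NULL, omega0 = NULL,
                                omega2 = NULL, p0 = NULL, p1 = NULL,
                                frequencies = "f3x4", pi = NULL,
                                foreground = NULL) {
  model <- match.arg(model)
  if (!is.null(foreground)) tree <- set_foreground(tree, foreground)
  pd <- prepare_pruning_data(aln, tree)
  pi <- pi %||% codon_frequencies(aln, frequencies)
  if (model == "M0") {
    if (is.null(omega)) stop("M0 needs omega")
    cl <- list(props = 1, bg = omega, fg = omega)
  } else {
    if (is.null(omega0) || is.null(omega2) || is.null(p0) || is.null(p1))
      stop("branch_site needs omega0, omega2, p0, p1")
    if (!any(foreground_edges(tree)))
      stop("branch_site model needs a non-empty foreground set")
    cl <- bs_classes(omega0, omega2, p0, p1)
  }
  ll <- class_site_logliks(pd, pi, kappa, cl)
  mix_loglik(ll, cl$props, pd$w)
}

#' Brute-force likelihood by state enumeration
#'
#' Reference implementation for validating the pruning algorithm: sums the
#' joint probability over all combinations of internal-node states, with
#' transition matrices computed by [Matrix::expm()]. Exponential in the
#' number of internal nodes; use on toy trees only (<= 4 tips, few codons).
#'
#' @inheritParams tree_log_likelihood
#' @return the log-likelihood (numeric scalar).
#' @export
enumerate_loglik <- function(aln, tree, model = c("M0", "branch_site"),
                             kappa, omega = NULL, omega0 = NULL,
                             omega2 = NULL, p0 = NULL, p1 = NULL,
                             frequencies = "f3x4", pi = NULL,
                             foreground = NULL) {
  model <- match.arg(model)
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("enumerate_loglik needs the Matrix package")
  if (!is.null(foreground)) tree <- set_foreground(tree, foreground)
  pi <- pi %||% codon_frequencies(aln, frequencies)
  cl <- if (model == "M0") list(props = 1, bg = omega, fg = omega)
        else bs_classes(omega0, omega2, p0, p1)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  if (61^nint > 3e6) stop("too many internal nodes for enumeration")
  tips <- aln_tip_matrix(aln, tree$tip.label)
  tips <- tips[, colSums(is.na(tips)) == 0, drop = FALSE]
  fg <- foreground_edges(tree)
  K <- length(cl$props)
  sc <- mixture_rate_scale(kappa, pi, cl)
  Pk <- lapply(seq_len(K), function(k) {
    lapply(seq_len(nrow(tree$edge)), function(e) {
      w <- if (fg[e]) cl$fg[k] else cl$bg[k]
      Q <- build_rate_matrix(kappa, w, pi, scale = FALSE) / sc
      as.matrix(Matrix::expm(Q * tree$edge.length[e]))
    })
  })
  grid <- as.matrix(expand.grid(rep(list(seq_along(pi)), nint)))
  total <- 0
  for (s in seq_len(ncol(tips))) {
    Ls <- 0
    for (k in seq_len(K)) {
      if (cl$props[k] == 0) next
      terms <- pi[grid[, 1]]             # root is node ntip + 1
      for (e in seq_len(nrow(tree$edge))) {
        pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        sp <- grid[, pa - ntip]
        sc <- if (ch <= ntip) rep(tips[ch, s], nrow(grid)) else grid[, ch - ntip]
        terms <- terms * Pk[[k]][[e]][cbind(sp, sc)]
      }
      Ls <- Ls + cl$props[k] * sum(terms)
    }
    total <- total + log(Ls)
  }
  total
}
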