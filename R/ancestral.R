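# ---- marginal ancestral reconstruction --------------------------------------

# inside/outside partials for one class cube; returns list(inside, F, msgs)
# indexed by node, plus the per-pattern site likelihood. No scaling: partial
# products stay far from underflow on the tree sizes this targets.
.in_out <- function(pd, cube, pi) {
  n_pat <- ncol(pd$tips)
  n_edge <- nrow(pd$edge)
  inside <- vector("list", pd$n_node)
  msgs <- vector("list", n_edge)
  for (e in seq_len(n_edge)) {
    ch <- pd$edge[e, 2]
    msg <- if (ch <= pd$n_tip) cube[, , e][, pd$tips[ch, ]]
           else cube[, , e] %*% inside[[ch]]
    msg <- matrix(msg, length(pi), n_pat)
    msgs[[e]] <- msg
    inside[[pd$edge[e, 1]]] <- if (is.null(inside[[pd$edge[e, 1]]])) msg
                               else inside[[pd$edge[e, 1]]] * msg
  }
  root <- pd$edge[n_edge, 1]
  Fout <- vector("list", pd$n_node)
  Fout[[root]] <- matrix(pi, length(pi), n_pat)
  child_edges <- split(seq_len(n_edge), pd$edge[, 1])
  for (e in rev(seq_len(n_edge))) {       # reverse postorder = preorder
    u <- pd$edge[e, 1]; ch <- pd$edge[e, 2]
    if (ch <= pd$n_tip) next
    sibs <- setdiff(child_edges[[as.character(u)]], e)
    sib_prod <- Fout[[u]]
    for (e2 in sibs) sib_prod <- sib_prod * msgs[[e2]]
    Fout[[ch]] <- crossprod(cube[, , e], sib_prod)
  }
  list(inside = inside, Fout = Fout, root = root,
       site_lik = colSums(pi * inside[[root]]))
}

#' Marginal ancestral codon reconstruction at an internal node
#'
#' Per-site posterior distribution over the 61 sense codons at an internal
#' node, given the tips and a fitted codon model: partial likelihoods below
#' the node are combined with the likelihood flow from the rest of the tree;
#' under branch-site models the posterior is marginalised over the four site
#' classes. The maximum-a-posteriori codon is reported per site; exact ties
#' are broken toward the lexicographically smallest codon and flagged.
#' Gap-excluded alignment columns are emitted as `---`.
#'
#' @param fit a converged [fit_codon_model()] object.
#' @param node internal node (ape node number or node label).
#' @return object of class `ancestral_seq`: `node`, `model_label`,
#'   `map_codons` (character vector, `---` at excluded columns),
#'   `site_posteriors` (posterior probability of the MAP state), `tied`
#'   (logical), and `state_posteriors` (site x 61 matrix).
#' @export
marginal_reconstruction <- function(fit, node) {
  if (!fit$converged) stop("fit did not converge; reconstruction refused")
  nd <- node_number(fit$tree, node)
  if (nd <= fit$data$n_tip)
    stop("node ", node, " is a tip; reconstruction targets internal nodes")
  pd <- fit$data
  pr <- fit$params
  cl <- if (fit$model == "M0") list(props = 1, bg = pr$omega, fg = pr$omega)
        else bs_classes(pr$omega0, pr$omega2, pr$p0, pr$p1)
  cubes <- build_class_cubes(pd, fit$pi, pr$kappa, cl, fit$branch_lengths)
  n_pat <- ncol(pd$tips)
  num <- matrix(0, length(fit$pi), n_pat)
  den <- numeric(n_pat)
  for (k in seq_along(cubes)) {
    if (cl$props[k] == 0) next
    io <- .in_out(pd, cubes[[k]], fit$pi)
    num <- num + cl$props[k] * io$inside[[nd]] * io$Fout[[nd]]
    den <- den + cl$props[k] * io$site_lik
  }
  post <- sweep(num, 2, den, "/")                      # 61 x n_pat
  map_idx <- apply(post, 2, which.max)
  map_p <- post[cbind(map_idx, seq_len(n_pat))]
  tied <- vapply(seq_len(n_pat), function(j)
    sum(abs(post[, j] - map_p[j]) < 1e-12) > 1L, TRUE)
  cd <- codon_data()
  n_sites <- length(pd$pattern_of_site)
  codons <- rep("---", n_sites)
  site_p <- rep(NA_real_, n_sites)
  tie_s <- rep(FALSE, n_sites)
  sp <- matrix(NA_real_, n_sites, length(fit$pi),
               dimnames = list(NULL, cd$codons61))
  kept <- !is.na(pd$pattern_of_site)
  pat <- pd$pattern_of_site[kept]
  codons[kept] <- cd$codons61[map_idx[pat]]
  site_p[kept] <- map_p[pat]
  tie_s[kept] <- tied[pat]
  sp[kept, ] <- t(post)[pat, ]
  structure(list(node = nd,
                 model_label = model_label(fit),
                 map_codons = codons,
                 site_posteriors = site_p,
                 tied = tie_s,
                 state_posteriors = sp),
            class = "ancestral_seq")
}

model_label <- function(fit) {
  fg <- fit$tree$foreground %||% integer(0)
  switch(fit$model,
         M0 = "M0",
         branch_site = paste0("BS w2>1 @", paste(fg, collapse = "+")),
         branch_site_null = paste0("BS w2=1 @", paste(fg, collapse = "+")))
}

#' @export
print.ancestral_seq <- function(x, ...) {
  cat("ancestral reconstruction at node", x$node, "under", x$model_label, "\n")
  ok <- !is.na(x$site_posteriors)
  cat(sprintf("  %d sites (%d reconstructed), mean MAP posterior %.3f\n",
              length(x$map_codons), sum(ok), mean(x$site_posteriors[ok])))
  if (any(x$tied)) cat("  MAP ties at", sum(x$tied), "site(s)\n")
  invisible(x)
}

#' @export
as.character.ancestral_seq <- function(x, ...) paste(x$map_codons, collapse = "")

#' Reconstruction under a suite of constrained models
#'
#' Fits each model specification and reconstructs the same internal node
#' under each fit, emulating the practice of bracketing ancestral-state
#' uncertainty with a set of models (e.g. neutral M0 plus branch-site models
#' forcing positive selection, omega2 > 1, or near-neutrality, omega2 = 1,
#' onto key branches).
#'
#' @inheritParams fit_codon_model
#' @param node internal node to reconstruct.
#' @param specs list of model specifications, each a list with elements
#'   `model` (`"M0"`, `"branch_site"`, `"branch_site_null"`), optional
#'   `foreground`, and optional `label`.
#' @return object of class `recon_suite`: `node` and `members` (one
#'   `ancestral_seq` per spec, with its `fit` attached; members whose fit
#'   failed to converge are flagged, not dropped).
#' @export
reconstruction_suite <- function(aln, tree, node, specs, seed = NULL,
                                 frequencies = "f3x4", n_starts = 2,
                                 control = list()) {
  if (!length(specs)) stop("empty model suite")
  members <- lapply(specs, function(sp) {
    fit <- fit_codon_model(aln, tree, sp$model, frequencies = frequencies,
                           foreground = sp$foreground, n_starts = n_starts,
                           seed = seed, control = control)
    if (!fit$converged)
      return(structure(list(node = NA, model_label = sp$label %||% model_label(fit),
                            failed = TRUE, fit = fit), class = "ancestral_seq"))
    rec <- marginal_reconstruction(fit, node)
    if (!is.null(sp$label)) rec$model_label <- sp$label
    rec$fit <- fit
    rec
  })
  structure(list(node = node_number(tree, node), members = members),
            class = "recon_suite")
}

#' @export
print.recon_suite <- function(x, ...) {
  cat("reconstruction suite at node", x$node, "-", length(x$members),
      "member(s)\n")
  for (m in x$members)
    cat("  ", m$model_label,
        if (isTRUE(m$failed)) " [fit not converged]" else "", "\n", sep = "")
  invisible(x)
}

#' Brute-force node posterior by state enumeration
#'
#' Reference implementation for validating [marginal_reconstruction()]:
#' enumerates all internal-node state combinations (transition matrices from
#' [Matrix::expm()]) and sums the joint probabilities per state of the target
#' node. Toy trees only.
#'
#' @inheritParams enumerate_loglik
#' @param node internal node number.
#' @return matrix of posterior probabilities (sites x 61).
#' @export
enumerate_node_posterior <- function(aln, tree, node,
                                     model = c("M0", "branch_site"),
                                     kappa, omega = NULL, omega0 = NULL,
                                     omega2 = NULL, p0 = NULL, p1 = NULL,
                                     frequencies = "f3x4", pi = NULL,
                                     foreground = NULL) {
  model <- match.arg(model)
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("enumerate_node_posterior needs the Matrix package")
  if (!is.null(foreground)) tree <- set_foreground(tree, foreground)
  pi <- pi %||% codon_frequencies(aln, frequencies)
  cl <- if (model == "M0") list(props = 1, bg = omega, fg = omega)
        else bs_classes(omega0, omega2, p0, p1)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  nd <- node_number(tree, node)
  stopifnot(nd > ntip, 61^nint <= 3e6)
  tips <- aln_tip_matrix(aln, tree$tip.label)
  tips <- tips[, colSums(is.na(tips)) == 0, drop = FALSE]
  fg <- foreground_edges(tree)
  K <- length(cl$props)
  sc <- mixture_rate_scale(kappa, pi, cl)
  Pk <- lapply(seq_len(K), function(k)
    lapply(seq_len(nrow(tree$edge)), function(e) {
      w <- if (fg[e]) cl$fg[k] else cl$bg[k]
      as.matrix(Matrix::expm(build_rate_matrix(kappa, w, pi, scale = FALSE) /
                               sc * tree$edge.length[e]))
    }))
  grid <- as.matrix(expand.grid(rep(list(seq_along(pi)), nint)))
  out <- matrix(0, ncol(tips), length(pi))
  for (s in seq_len(ncol(tips))) {
    acc <- numeric(length(pi))
    for (k in seq_len(K)) {
      if (cl$props[k] == 0) next
      terms <- pi[grid[, 1]]
      for (e in seq_len(nrow(tree$edge))) {
        pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        sc <- if (ch <= ntip) rep(tips[ch, s], nrow(grid)) else grid[, ch - ntip]
        terms <- terms * Pk[[k]][[e]][cbind(grid[, pa - ntip], sc)]
      }
      acc <- acc + cl$props[k] *
        vapply(seq_along(pi), function(y) sum(terms[grid[, nd - ntip] == y]), 0)
    }
    out[s, ] <- acc / sum(acc)
  }
  colnames(out) <- codon_data()$codons61
  out
}
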