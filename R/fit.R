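# ---- parameter transforms ---------------------------------------------------
# All free parameters are optimised on unconstrained log / logit scales.

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

# theta layout (free parameters only):
#   [log kappa]  unless kappa is fixed
#   M0:          log omega
#   branch_site: logit omega0, [z2 unless omega2 fixed at 1], a, b
#   [log bl...]  unless branch lengths are fixed
# with omega2 = 1 + exp(z2) and (p0, p1) the additive-logistic image of (a, b).
pack_start <- function(model, ini, fix_omega2 = FALSE, fix_kappa = NULL) {
  th <- if (is.null(fix_kappa)) log(ini$kappa) else numeric(0)
  if (model == "M0") th <- c(th, log(ini$omega))
  else {
    th <- c(th, .logit(ini$omega0))
    if (!fix_omega2) th <- c(th, log(max(ini$omega2 - 1, 1e-4)))
    p2 <- max(1 - ini$p0 - ini$p1, 1e-4)
    th <- c(th, log(ini$p0 / p2), log(ini$p1 / p2))
  }
  th
}

unpack_params <- function(model, th, fix_omega2 = FALSE, fix_kappa = NULL) {
  if (is.null(fix_kappa)) { kappa <- exp(th[1]); i <- 2L }
  else { kappa <- fix_kappa; i <- 1L }
  if (model == "M0")
    return(list(kappa = kappa, omega = exp(th[i]), n = i))
  omega0 <- .inv_logit(th[i]); i <- i + 1L
  if (fix_omega2) omega2 <- 1
  else { omega2 <- 1 + exp(th[i]); i <- i + 1L }
  ea <- exp(th[i]); eb <- exp(th[i + 1])
  s <- 1 + ea + eb
  list(kappa = kappa, omega0 = omega0, omega2 = omega2,
       p0 = ea / s, p1 = eb / s, n = i + 1L)
}

model_classes <- function(model, pr) {
  if (model == "M0") list(props = 1, bg = pr$omega, fg = pr$omega)
  else bs_classes(pr$omega0, pr$omega2, pr$p0, pr$p1)
}

# forward-difference gradient respecting box bounds; pinned dimensions
# (lower == upper) contribute zero. fn memoises its last evaluation, so the
# base value is usually free.
make_grad <- function(fn, lower, upper, eps = 1e-7) {
  function(th) {
    f0 <- fn(th)
    g <- numeric(length(th))
    for (i in seq_along(th)) {
      if (upper[i] - lower[i] < 1e-12) next
      h <- eps * max(1, abs(th[i]))
      if (th[i] + h > upper[i]) h <- -h
      th2 <- th; th2[i] <- th[i] + h
      g[i] <- (fn(th2) - f0) / h
    }
    g
  }
}

# ---- fitting ----------------------------------------------------------------

#' Fit a codon substitution model by maximum likelihood
#'
#' Fits M0 (single omega) or the branch-site model A (alternative, or null
#' with the foreground omega fixed at 1) to a codon alignment on a fixed tree
#' topology, by bounded quasi-Newton (L-BFGS-B) on log/logit-transformed
#' parameters with multiple restarts. Branch lengths are either re-estimated
#' jointly or held fixed at supplied values.
#'
#' @param aln a [codon_alignment()].
#' @param tree `phylo` tree with starting branch lengths; for branch-site
#'   models the foreground branches must be marked (see [set_foreground()])
#'   or passed via `foreground`.
#' @param model `"M0"`, `"branch_site"` (omega2 free, >= 1) or
#'   `"branch_site_null"` (omega2 = 1).
#' @param frequencies codon frequency mode, see [codon_frequencies()].
#' @param foreground optional foreground branch marks.
#' @param branch_lengths `"estimate"` to optimise branch lengths, or a
#'   numeric vector (postorder edge order, as in the fitted object) to hold
#'   them fixed.
#' @param free_branches with fixed `branch_lengths`, indices (postorder) of
#'   edges whose lengths are nevertheless re-optimised (e.g. the foreground
#'   branch in a branch-site test, so that both the null and the alternative
#'   model can adjust it).
#' @param fix_kappa optional value at which to pin the transition/transversion
#'   ratio (used when profiling kappa under a simpler model).
#' @param n_starts number of optimisation starts (first from heuristic
#'   values, the rest jittered; best log-likelihood wins, first start wins
#'   exact ties).
#' @param seed integer seed making the jittered restarts reproducible.
#' @param init optional named list of starting values
#'   (`kappa`, `omega`, `omega0`, `omega2`, `p0`, `p1`).
#' @param control list with optional `factr`, `maxit` for [stats::optim()].
#' @return an object of class `codon_fit` with elements `params`
#'   (maximum-likelihood estimates), `lnL`, `branch_lengths` (postorder),
#'   `tree` (branch lengths replaced by estimates), `converged`, and the
#'   prepared data needed by downstream methods.
#' @seealso [branch_site_lrt()], [site_class_posteriors()],
#'   [marginal_reconstruction()], [simulate.codon_fit()]
#' @export
fit_codon_model <- function(aln, tree,
                            model = c("M0", "branch_site", "branch_site_null"),
                            frequencies = "f3x4", foreground = NULL,
                            branch_lengths = "estimate", free_branches = NULL,
                            fix_kappa = NULL, n_starts = 3, seed = NULL,
                            init = NULL, control = list()) {
  model <- match.arg(model)
  if (!is.null(foreground)) tree <- set_foreground(tree, foreground)
  bs <- model != "M0"
  fix_w2 <- model == "branch_site_null"
  if (bs && !length(tree$foreground %||% integer(0)))
    stop("branch-site models need a non-empty foreground set")
  pd <- prepare_pruning_data(aln, tree)
  pi <- codon_frequencies(aln, frequencies)
  ctl <- modifyList(list(factr = 1e8, maxit = 200), control)
  est_bl <- identical(branch_lengths, "estimate")
  fixed_bl <- if (!est_bl) {
    stopifnot(is.numeric(branch_lengths),
              length(branch_lengths) == nrow(pd$edge))
    branch_lengths
  }
  opt_edges <- if (est_bl) seq_len(nrow(pd$edge))
               else as.integer(free_branches %||% integer(0))
  mkey <- if (bs) "branch_site" else "M0"
  cache <- new.env(parent = emptyenv())

  last_th <- NULL; last_val <- NULL
  negll <- function(th) {
    if (!is.null(last_th) && identical(th, last_th)) return(last_val)
    pr <- unpack_params(mkey, th, fix_w2, fix_kappa)
    bl <- if (est_bl) exp(th[(pr$n + 1):length(th)]) else fixed_bl
    if (!est_bl && length(opt_edges))
      bl[opt_edges] <- exp(th[(pr$n + 1):length(th)])
    cl <- model_classes(mkey, pr)
    v <- tryCatch(mix_loglik(class_site_logliks(pd, pi, pr$kappa, cl, bl,
                                                cache),
                             cl$props, pd$w),
                  error = function(e) -Inf)
    v <- if (!is.finite(v)) 1e12 else -v
    last_th <<- th; last_val <<- v
    v
  }

  bl0 <- pmax(pd$el, 1e-4)
  default_init <- list(kappa = fix_kappa %||% 2, omega = 0.4, omega0 = 0.1,
                       omega2 = 2.5, p0 = 0.7, p1 = 0.2)
  # init: a named list of starting values, or an unnamed list of several
  inits <- if (is.null(init)) list(default_init)
           else if (is.null(names(init)))
             lapply(init, function(x) modifyList(default_init, x))
           else list(modifyList(default_init, init))
  base_init <- inits[[1]]

  make_theta <- function(ini, bl) {
    th <- pack_start(mkey, ini, fix_w2, fix_kappa)
    if (est_bl) c(th, log(bl))
    else if (length(opt_edges)) c(th, log(pmax(fixed_bl[opt_edges], 1e-4)))
    else th
  }
  starts <- lapply(inits, make_theta, bl = bl0)
  n_starts <- max(n_starts, length(starts))
  if (n_starts > length(starts)) {
    jit <- function() {
      ini <- base_init
      ini$kappa <- ini$kappa * exp(runif(1, -0.7, 0.7))
      ini$omega <- exp(runif(1, log(0.05), log(1.5)))
      ini$omega0 <- runif(1, 0.02, 0.6)
      ini$omega2 <- 1 + exp(runif(1, log(0.2), log(4)))
      ini$p0 <- runif(1, 0.4, 0.9)
      ini$p1 <- runif(1, 0.03, min(0.4, 0.95 - ini$p0))
      make_theta(ini, bl0 * exp(runif(length(bl0), -0.5, 0.5)))
    }
    starts <- c(starts, withr::with_seed(seed %||% 1L,
      lapply(seq_len(n_starts - length(starts)), function(i) jit())))
  }

  npar <- length(starts[[1]])
  lower <- rep(-12, npar); upper <- rep(12, npar)
  i <- 1L
  if (is.null(fix_kappa)) { lower[1] <- -5; upper[1] <- 5; i <- 2L }
  if (!bs) { lower[i] <- -10; upper[i] <- 4.6 }          # omega <= ~100
  else if (!fix_w2) { lower[i + 1] <- -15; upper[i + 1] <- 6 }
  nb <- if (est_bl) length(bl0) else length(opt_edges)
  if (nb > 0) {
    ib <- (npar - nb + 1):npar
    lower[ib] <- log(1e-7); upper[ib] <- log(30)
  }
  grad <- make_grad(negll, lower, upper)

  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(st, negll, gr = grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(factr = ctl$factr, maxit = ctl$maxit)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-9) best <- o
  }
  if (is.null(best)) stop("all optimisation starts failed")

  pr <- unpack_params(mkey, best$par, fix_w2, fix_kappa)
  bl_hat <- if (est_bl) exp(best$par[(pr$n + 1):npar]) else fixed_bl
  if (!est_bl && length(opt_edges))
    bl_hat[opt_edges] <- exp(best$par[(pr$n + 1):npar])
  pr$n <- NULL
  tree_hat <- tree
  # map postorder branch lengths back onto the input edge order
  tr_post <- ape::reorder.phylo(tree, "postorder")
  m <- match(paste(tree$edge[, 1], tree$edge[, 2]),
             paste(tr_post$edge[, 1], tr_post$edge[, 2]))
  tree_hat$edge.length <- bl_hat[m]

  structure(list(
    call = match.call(),
    model = model,
    frequencies = frequencies,
    params = pr,
    proportions = if (bs) model_classes(mkey, pr)$props,
    branch_lengths = bl_hat,
    lnL = -best$value,
    converged = best$convergence == 0,
    n_starts_used = n_starts,
    n_free = npar,
    seed = seed,
    pi = pi,
    tree = tree_hat,
    data = pd,
    aln_ids = aln$ids
  ), class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon model fit:", x$model,
      sprintf("(%s frequencies)\n", x$frequencies))
  cat(sprintf("  lnL = %.4f  (%d free parameters%s)\n", x$lnL, x$n_free,
              if (x$converged) "" else "; NOT converged"))
  p <- x$params
  if (x$model == "M0")
    cat(sprintf("  kappa = %.3f  omega = %.4f\n", p$kappa, p$omega))
  else {
    cat(sprintf("  kappa = %.3f  omega0 = %.4f  omega2 = %.4f\n",
                p$kappa, p$omega0, p$omega2))
    cat(sprintf("  class proportions (0,1,2a,2b): %s\n",
                paste(sprintf("%.3f", x$proportions), collapse = ", ")))
  }
  cat(sprintf("  %d sequences, %d patterns, tree length %.3f\n",
              length(x$aln_ids), ncol(x$data$tips), sum(x$branch_lengths)))
  invisible(x)
}

#' @export
coef.codon_fit <- function(object, ...) unlist(object$params)

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$n_free,
            nobs = sum(object$data$w), class = "logLik")
}

#' @export
summary.codon_fit <- function(object, ...) {
  out <- list(fit = object,
              coef = coef(object),
              foreground = object$tree$foreground,
              n_sites = sum(object$data$w))
  class(out) <- "summary.codon_fit"
  out
}

#' @export
print.summary.codon_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$foreground) && length(x$foreground))
    cat("  foreground branch child nodes:",
        paste(x$foreground, collapse = ", "), "\n")
  invisible(x)
}
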