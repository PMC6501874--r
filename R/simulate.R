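# ---- synthetic data: codon alignments and population samples ----------------

#' Simulate a codon alignment along a tree
#'
#' Generative model matched to the branch-site machinery: each site draws a
#' class from the model-A proportions \{0, 1, 2a, 2b\}, root codons are drawn
#' from `pi`, and states evolve down the tree with class- and
#' branch-appropriate omega (foreground branches marked on the tree use the
#' foreground omega of classes 2a/2b). With `omega2 = 1` (or no foreground)
#' this collapses to (mixtures of) site-homogeneous models; a single `omega`
#' gives plain M0.
#'
#' @param tree `phylo` tree with branch lengths (expected substitutions per
#'   codon) and optional foreground marks.
#' @param n_codons number of codon sites.
#' @param kappa transition/transversion ratio.
#' @param omega single M0 omega; alternatively give the branch-site
#'   parameters.
#' @param omega0,omega2,p0,p1 branch-site model A parameters.
#' @param pi codon frequencies (default equal over the 61 sense codons).
#' @param seed integer seed; identical scenarios and seeds reproduce the
#'   alignment exactly.
#' @return list with `alignment` (a [codon_alignment()] over the tree tips)
#'   and `site_classes` (integer truth table, 1..4 = classes 0, 1, 2a, 2b).
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2,
                                     omega = NULL, omega0 = NULL,
                                     omega2 = NULL, p0 = NULL, p1 = NULL,
                                     pi = NULL, seed = NULL) {
  cd <- codon_data()
  pi <- pi %||% rep(1 / 61, 61)
  cl <- if (!is.null(omega)) list(props = 1, bg = omega, fg = omega)
        else bs_classes(omega0, omega2, p0, p1)
  tr <- ape::reorder.phylo(tree, "postorder")
  fg <- foreground_edges(tr)
  # preorder traversal: reverse postorder
  edges <- rev(seq_len(nrow(tr$edge)))
  ntip <- ape::Ntip(tree)
  root <- tr$edge[nrow(tr$edge), 1]
  omegas <- sort(unique(c(cl$bg, if (any(fg)) cl$fg)))
  sc <- mixture_rate_scale(kappa, pi, cl)
  decs <- lapply(omegas, function(w)
    decompose_rate_matrix(build_rate_matrix(kappa, w, pi, scale = FALSE) / sc,
                          pi))
  names(decs) <- sprintf("%.17g", omegas)

  withr::with_seed(seed %||% stop("simulate_codon_alignment needs a seed"), {
    classes <- sample.int(length(cl$props), n_codons, replace = TRUE,
                          prob = cl$props)
    states <- matrix(NA_integer_, ntip + tree$Nnode, n_codons)
    states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
    for (e in edges) {
      pa <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      child <- integer(n_codons)
      for (k in seq_along(cl$props)) {
        idx <- which(classes == k)
        if (!length(idx)) next
        w <- if (fg[e]) cl$fg[k] else cl$bg[k]
        P <- transition_matrix(decs[[sprintf("%.17g", w)]],
                               tr$edge.length[e])
        for (s in unique(states[pa, idx])) {
          at <- idx[states[pa, idx] == s]
          child[at] <- sample.int(61, length(at), replace = TRUE, prob = P[s, ])
        }
      }
      states[ch, ] <- child
    }
    seqs <- vapply(seq_len(ntip), function(i)
      paste(cd$codons61[states[i, ]], collapse = ""), "")
    list(alignment = codon_alignment(seqs, ids = tree$tip.label),
         site_classes = classes)
  })
}

#' Apply random substitutions to a codon sequence
#'
#' Overlays Poisson numbers of synonymous and nonsynonymous single-base
#' substitutions (expected counts `rate * class sites` of the current
#' sequence) at random codon positions, never creating stop codons. Used to
#' manufacture diverged reference sequences for MK calibration studies.
#'
#' @param seq nucleotide string or codon-index vector.
#' @param d_syn,d_nsyn expected substitutions per synonymous/nonsynonymous
#'   site.
#' @param seed integer seed.
#' @return list with `seq` (codon-index vector), `n_syn`, `n_nsyn` applied.
#' @export
simulate_divergence <- function(seq, d_syn, d_nsyn, seed) {
  cd <- codon_data()
  idx <- if (is.character(seq)) codon_indices(seq, cd) else as.integer(seq)
  withr::with_seed(seed, {
    sc <- alignment_site_counts(idx)
    n_syn <- rpois(1, d_syn * sc$syn_sites)
    n_nsyn <- rpois(1, d_nsyn * sc$nsyn_sites)
    for (cls in c(rep("syn", n_syn), rep("nsyn", n_nsyn)))
      idx <- .apply_point_change(idx, cls, cd)
    list(seq = idx, n_syn = n_syn, n_nsyn = n_nsyn)
  })
}

# substitute one random single-base change of the requested class somewhere
# in the sequence (rejection sampling over positions)
.apply_point_change <- function(idx, class, cd, max_try = 1000L) {
  nb <- .single_step_neighbours(cd)
  pool <- if (class == "syn") nb$syn else nb$nsyn
  for (i in seq_len(max_try)) {
    pos <- sample(which(!is.na(idx)), 1)
    cand <- pool[[idx[pos]]]
    if (length(cand)) {
      idx[pos] <- if (length(cand) == 1) cand else sample(cand, 1)
      return(idx)
    }
  }
  stop("could not place a ", class, " change (sequence too constrained)")
}

.single_step_neighbours <- function(cd) {
  if (!is.null(cd$nbr)) return(cd$nbr)
  syn <- lapply(seq_len(61), function(i)
    which(cd$single[i, ] & !cd$nonsyn[i, ]))
  nsyn <- lapply(seq_len(61), function(i)
    which(cd$single[i, ] & cd$nonsyn[i, ]))
  cd$nbr <- list(syn = syn, nsyn = nsyn)
  cd$nbr
}

#' Simulate a within-species haplotype sample
#'
#' Overlays Poisson-distributed single-base polymorphisms on a base sequence
#' (no coalescent genealogy): synonymous events with expectation
#' `theta_syn * synonymous sites`, nonsynonymous with
#' `theta_nsyn * nonsynonymous sites`. Each derived allele lands at a random
#' segregating frequency (uniform on 1..n-1 carriers, so every event is
#' polymorphic, not fixed) at a distinct codon position; no stop codons are
#' created.
#'
#' @param base base (ancestral) sequence: nucleotide string or codon-index
#'   vector.
#' @param n_haplotypes number of sampled alleles (>= 2).
#' @param theta_syn,theta_nsyn expected polymorphisms per synonymous /
#'   nonsynonymous site.
#' @param seed integer seed.
#' @param ids haplotype identifiers.
#' @return a [codon_alignment()] of `n_haplotypes` alleles, with the true
#'   event counts attached as attribute `"truth"`.
#' @export
simulate_population_sample <- function(base, n_haplotypes, theta_syn,
                                       theta_nsyn, seed,
                                       ids = sprintf("hap%02d", seq_len(n_haplotypes))) {
  cd <- codon_data()
  idx <- if (is.character(base)) codon_indices(base, cd) else as.integer(base)
  stopifnot(n_haplotypes >= 2)
  withr::with_seed(seed, {
    sc <- alignment_site_counts(idx)
    n_syn <- rpois(1, theta_syn * sc$syn_sites)
    n_nsyn <- rpois(1, theta_nsyn * sc$nsyn_sites)
    haps <- matrix(rep(idx, each = n_haplotypes), n_haplotypes, length(idx))
    classes <- c(rep("syn", n_syn), rep("nsyn", n_nsyn))
    nb <- .single_step_neighbours(cd)
    avail <- which(!is.na(idx))
    events <- list()
    for (cls in classes) {
      placed <- FALSE
      for (tries in seq_len(1000L)) {
        if (!length(avail)) break
        pos <- if (length(avail) == 1) avail else sample(avail, 1)
        pool <- if (cls == "syn") nb$syn[[idx[pos]]] else nb$nsyn[[idx[pos]]]
        if (length(pool)) {
          derived <- if (length(pool) == 1) pool else sample(pool, 1)
          k <- sample.int(n_haplotypes - 1, 1)
          carriers <- sample.int(n_haplotypes, k)
          haps[carriers, pos] <- derived
          events[[length(events) + 1]] <-
            list(pos = pos, class = cls, derived = derived, carriers = k)
          avail <- setdiff(avail, pos)   # one event per codon position
          placed <- TRUE
          break
        }
        avail <- setdiff(avail, pos)
      }
      if (!placed) break
    }
    cd61 <- cd$codons61
    seqs <- vapply(seq_len(n_haplotypes), function(i) {
      s <- ifelse(is.na(haps[i, ]), "---", cd61[haps[i, ]])
      paste(s, collapse = "")
    }, "")
    out <- codon_alignment(seqs, ids = ids, allow_gaps = TRUE)
    attr(out, "truth") <- list(n_syn = sum(vapply(events, function(e)
      e$class == "syn", TRUE)), n_nsyn = sum(vapply(events, function(e)
      e$class == "nsyn", TRUE)), events = events)
    out
  })
}

#' Ready-made duplication scenarios
#'
#' Four seeded simulation scenarios on a six-tip tree mirroring a duplicated
#' gene family with two paralog clades and an outgroup: `neutral` (no
#' positive selection anywhere), `NF` (foreground omega2 > 1 on one daughter
#' branch only), and `EAC`/`CN` (foreground omega2 > 1 on both daughter
#' branches, distinguished by their function-annotation fixtures). Daughter
#' branches are the stems of the two paralog clades, marked via their crown
#' nodes. Defaults: 300 codons, kappa = 2, omega0 = 0.1, 10% of sites in the
#' foreground classes (p0 = 0.72, p1 = 0.18), omega2 = 4 where selected.
#'
#' @param n_codons codon sites per simulated alignment.
#' @param omega2 foreground omega on selected branches.
#' @return named list of scenarios; each has `tree` (marked foreground =
#'   selected branches), `test_branches` (the two daughter stems, first the
#'   selected one where applicable), `params`, `n_codons`, `annotations`
#'   (function states for the retention classifier) and `seed`.
#' @export
scenario_presets <- function(n_codons = 300, omega2 = 4) {
  base_newick <- paste0(
    "(((PxGSS1:0.08,PxGSS2:0.08)gss12x:0.12,PaGSS12:0.15)gss12:0.70,",
    "(PxGSS3:0.12,PaGSS3:0.12)gss3:0.30,YcC:0.35);")
  tr <- read_codon_tree(text = base_newick)
  params <- list(kappa = 2, omega0 = 0.1, p0 = 0.72, p1 = 0.18)
  mk <- function(fg, omega2_use, annotations, seed)
    list(tree = if (length(fg)) set_foreground(tr, fg) else tr,
         test_branches = c("gss12", "gss3"),
         params = c(params, list(omega2 = omega2_use)),
         n_codons = n_codons,
         annotations = annotations,
         seed = seed)
  list(
    neutral = mk("gss12", 1,
                 c(gss12 = "unknown", gss3 = "unknown"), 101L),
    NF = mk("gss12", omega2,
            c(gss12 = "novel", gss3 = "ancestral"), 102L),
    EAC = mk(c("gss12", "gss3"), omega2,
             c(gss12 = "novel", gss3 = "ancestral"), 103L),
    CN = mk(c("gss12", "gss3"), omega2,
            c(gss12 = "novel", gss3 = "novel-variant"), 104L)
  )
}

#' Simulate one scenario replicate
#'
#' @param scenario an element of [scenario_presets()].
#' @param seed overrides the scenario's fixture seed.
#' @return as [simulate_codon_alignment()].
#' @export
simulate_scenario <- function(scenario, seed = NULL) {
  p <- scenario$params
  simulate_codon_alignment(scenario$tree, scenario$n_codons,
                           kappa = p$kappa, omega0 = p$omega0,
                           omega2 = p$omega2, p0 = p$p0, p1 = p$p1,
                           seed = seed %||% scenario$seed)
}

#' Simulate alignments from a fitted codon model
#'
#' @param object a [fit_codon_model()] result.
#' @param nsim number of alignments.
#' @param seed integer seed (replicate i uses `seed + i - 1`).
#' @param ... unused.
#' @return list of [simulate_codon_alignment()] results (length `nsim`).
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = 1L, ...) {
  p <- object$params
  args <- if (object$model == "M0") list(omega = p$omega)
          else list(omega0 = p$omega0, omega2 = p$omega2, p0 = p$p0, p1 = p$p1)
  lapply(seq_len(nsim), function(i)
    do.call(simulate_codon_alignment,
            c(list(tree = object$tree, n_codons = length(object$data$kept),
                   kappa = p$kappa, pi = NULL, seed = seed + i - 1L), args)))
}
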