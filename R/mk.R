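# ---- McDonald-Kreitman machinery --------------------------------------------

#' Synonymous/nonsynonymous polymorphism counts within a sample
#'
#' Per codon column, the distinct alleles are connected by a minimum-change
#' spanning arrangement (minimum spanning tree under codon Hamming distance,
#' deterministic tie-breaks) and fractional [pathway_counts()] are summed
#' over its edges. Invariant columns contribute nothing; alleles with
#' gap/ambiguity codons are excluded column-wise.
#'
#' @param sample a [codon_alignment()] of within-species haplotypes (>= 2).
#' @return list with `Ps`, `Pn` (fractional counts) and `n_segregating`.
#' @export
count_polymorphisms <- function(sample) {
  if (length(sample$ids) < 2) stop("a population sample needs >= 2 haplotypes")
  cd <- codon_data()
  pt <- pathway_tables(cd)
  Ps <- 0; Pn <- 0; seg <- 0L
  for (j in seq_len(sample$n_codons)) {
    al <- sort(unique(sample$codons[!is.na(sample$codons[, j]), j]))
    if (length(al) < 2) next
    seg <- seg + 1L
    ed <- mst_edges(al, cd)
    Ps <- Ps + sum(pt$syn[ed])
    Pn <- Pn + sum(pt$nsyn[ed])
  }
  list(Ps = Ps, Pn = Pn, n_segregating = seg)
}

# Prim's algorithm on the complete graph of distinct codon states, weighted by
# Hamming distance; ties resolved toward the smallest codon index. Returns a
# 2-column matrix of codon-index pairs.
mst_edges <- function(states, cd) {
  k <- length(states)
  if (k == 2) return(matrix(states, 1, 2))
  D <- cd$ndiff[states, states]
  in_tree <- c(1L, rep(NA_integer_, k - 1))
  edges <- matrix(0L, k - 1, 2)
  used <- 1L
  while (used < k) {
    best <- NULL
    for (i in which(!is.na(in_tree))) for (j in seq_len(k)) {
      if (!is.na(in_tree[j]) || i == j) next
      cand <- c(D[i, j], i, j)
      if (is.null(best) || cand[1] < best[1] ||
          (cand[1] == best[1] && (cand[3] < best[3] ||
                                  (cand[3] == best[3] && cand[2] < best[2]))))
        best <- cand
    }
    edges[used, ] <- states[best[2:3]]
    in_tree[best[3]] <- 1L
    used <- used + 1L
  }
  edges
}

# consensus codon index per column (majority; ties toward the smallest codon
# index); NA where no allele is observed
consensus_sequence <- function(sample) {
  apply(sample$codons, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_integer_)
    tab <- table(col)
    as.integer(names(tab)[which.max(tab)])
  })
}

# columns fixed within the sample (exactly one allele among non-NA rows)
fixed_states <- function(sample) {
  apply(sample$codons, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) && all(col == col[1])) col[1] else NA_integer_
  })
}

#' Raw divergence counts between a sample and a reference sequence
#'
#' Counts substitutions only at columns fixed within the sample (the classic
#' MKT convention; polymorphic columns contribute to polymorphism only),
#' summing fractional [pathway_counts()] between the fixed state and the
#' reference codon.
#'
#' @param sample a [codon_alignment()] of haplotypes.
#' @param reference reference codon sequence: a nucleotide string, or an
#'   integer vector of codon indices (`NA` = excluded column), of the same
#'   codon length as the sample.
#' @return list with `Ds_raw`, `Dn_raw` and the number of compared columns.
#' @export
count_divergence <- function(sample, reference) {
  cd <- codon_data()
  ref <- if (is.character(reference)) codon_indices(reference, cd) else
    as.integer(reference)
  if (length(ref) != sample$n_codons)
    stop("reference length (", length(ref), " codons) does not match sample (",
         sample$n_codons, ")")
  fx <- fixed_states(sample)
  ok <- !is.na(fx) & !is.na(ref)
  pt <- pathway_tables(cd)
  idx <- cbind(fx[ok], ref[ok])
  list(Ds_raw = sum(pt$syn[idx]), Dn_raw = sum(pt$nsyn[idx]),
       n_compared = sum(ok))
}

#' Jukes-Cantor correction of a substitution count
#'
#' Corrects a raw per-class substitution count for multiple hits:
#' `p = raw/sites`, `d = -3/4 log(1 - 4p/3)`, returning `d * sites`.
#' Applied to divergence only (synonymous counts against synonymous sites,
#' nonsynonymous against nonsynonymous sites); polymorphism counts are never
#' corrected.
#'
#' @param raw_count fractional substitution count (>= 0).
#' @param sites fractional site count of the matching class.
#' @return corrected count (>= `raw_count`).
#' @examples
#' jc_correct(10, 100)   # 10.733
#' @export
jc_correct <- function(raw_count, sites) {
  if (raw_count == 0) return(0)
  p <- raw_count / sites
  if (p >= 0.75)
    stop("substitution class saturated (p = ", signif(p, 3),
         " >= 0.75); Jukes-Cantor correction undefined")
  -0.75 * log(1 - 4 * p / 3) * sites
}

#' McDonald-Kreitman test from a 2x2 count table
#'
#' Contrasts within-species polymorphism with between-lineage divergence:
#' Neutrality Index `NI = (Pn/Ps)/(Dn/Ds)`, Pearson chi-square (no continuity
#' correction) on the table `[[Ps, Pn], [Ds, Dn]]`, and the upper chi-square
#' tail probability with 1 df. `NI` is flagged undefined (not infinite) when
#' `Ps`, `Ds` or `Dn` is zero.
#'
#' @param Ps,Pn synonymous/nonsynonymous polymorphism counts.
#' @param Ds,Dn synonymous/nonsynonymous (corrected) divergence counts.
#' @param counts optional list carrying the full [mk_counts()] bookkeeping.
#' @return object of class `mk_test` with `table`, `NI`, `statistic`,
#'   `p.value`, `ni_defined`.
#' @examples
#' mk_test(142, 15, 5.1, 6.0)   # NI = 0.09
#' @export
mk_test <- function(Ps, Pn, Ds, Dn, counts = NULL) {
  if (any(c(Ps, Pn, Ds, Dn) < 0)) stop("negative count")
  tab <- matrix(c(Ps, Pn, Ds, Dn), 2, 2, byrow = TRUE,
                dimnames = list(c("polymorphism", "divergence"),
                                c("syn", "nsyn")))
  tot <- sum(tab)
  if (tot == 0) stop("all-zero MK table")
  ni_defined <- Ps > 0 && Ds > 0 && Dn > 0
  NI <- if (ni_defined) (Pn / Ps) / (Dn / Ds) else NA_real_
  rs <- rowSums(tab); cs <- colSums(tab)
  chi2 <- p <- NA_real_
  if (all(rs > 0) && all(cs > 0)) {
    E <- outer(rs, cs) / tot
    chi2 <- sum((tab - E)^2 / E)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(table = tab, NI = NI, ni_defined = ni_defined,
                 statistic = chi2, df = 1L, p.value = p, counts = counts),
            class = "mk_test")
}

#' @export
print.mk_test <- function(x, ...) {
  cat("McDonald-Kreitman test\n")
  print(round(x$table, 1))
  cat(sprintf("  NI = %s,  X2(1) = %s,  P = %s\n",
              if (x$ni_defined) sprintf("%.2f", x$NI) else "undefined",
              if (is.na(x$statistic)) "NA" else sprintf("%.1f", x$statistic),
              if (is.na(x$p.value)) "NA" else sprintf("%.3f", x$p.value)))
  invisible(x)
}

#' Full MK counting between a sample and a reference sequence
#'
#' Assembles the complete 2x2 machinery: polymorphism counts within the
#' sample, raw divergence counts at fixed columns, Nei-Gojobori site totals
#' (averaged between the sample consensus and the reference), Jukes-Cantor
#' correction of the divergence counts, and the [mk_test()].
#'
#' @inheritParams count_divergence
#' @param correct apply the Jukes-Cantor distance correction to divergence.
#' @return an `mk_test` whose `counts` element records `Ps`, `Pn`, `Ds_raw`,
#'   `Dn_raw`, `Ds`, `Dn`, `syn_sites`, `nsyn_sites`.
#' @export
mk_sample_vs_reference <- function(sample, reference, correct = TRUE) {
  cd <- codon_data()
  ref <- if (is.character(reference)) codon_indices(reference, cd) else
    as.integer(reference)
  pol <- count_polymorphisms(sample)
  div <- count_divergence(sample, ref)
  cons <- consensus_sequence(sample)
  ok <- !is.na(cons) & !is.na(ref)
  sc_s <- alignment_site_counts(cons[ok])
  sc_r <- alignment_site_counts(ref[ok])
  syn_sites <- (sc_s$syn_sites + sc_r$syn_sites) / 2
  nsyn_sites <- (sc_s$nsyn_sites + sc_r$nsyn_sites) / 2
  Ds <- if (correct) jc_correct(div$Ds_raw, syn_sites) else div$Ds_raw
  Dn <- if (correct) jc_correct(div$Dn_raw, nsyn_sites) else div$Dn_raw
  counts <- list(Ps = pol$Ps, Pn = pol$Pn, Ds_raw = div$Ds_raw,
                 Dn_raw = div$Dn_raw, Ds = Ds, Dn = Dn,
                 syn_sites = syn_sites, nsyn_sites = nsyn_sites)
  mk_test(pol$Ps, pol$Pn, Ds, Dn, counts = counts)
}

#' Conservative MK bounds against an ancestral-reconstruction suite
#'
#' Runs [mk_sample_vs_reference()] against each member of a
#' [reconstruction_suite()] (or any list of reference sequences) and
#' aggregates conservatively: per-cell min-max ranges, the largest Neutrality
#' Index (reported as an upper bound, "NI <= max"), the smallest chi-square
#' (reported as a lower bound, "X2 >= min") and the p-value at that smallest
#' chi-square.
#'
#' @param sample a [codon_alignment()] of haplotypes.
#' @param suite a `recon_suite`, or a list of reference sequences (strings or
#'   codon-index vectors).
#' @param correct apply Jukes-Cantor correction per member.
#' @return object of class `mk_range`: `members` (named list of `mk_test`),
#'   `ranges` (min/max per cell), `NI_max`, `chi2_min`, `p_at_chi2_min`.
#' @export
mk_vs_reconstruction_suite <- function(sample, suite, correct = TRUE) {
  refs <- if (inherits(suite, "recon_suite")) {
    keep <- !vapply(suite$members, function(m) isTRUE(m$failed), TRUE)
    setNames(lapply(suite$members[keep], function(m)
      codon_indices(as.character(m), allow_stop = TRUE)),
      vapply(suite$members[keep], `[[`, "", "model_label"))
  } else suite
  if (!length(refs)) stop("no usable suite member")
  if (is.null(names(refs))) names(refs) <- paste0("model", seq_along(refs))
  members <- list()
  for (nm in names(refs)) {
    res <- tryCatch(mk_sample_vs_reference(sample, refs[[nm]], correct),
                    error = function(e) {
                      message("suite member '", nm, "' skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) members[[nm]] <- res
  }
  if (!length(members)) stop("every suite member failed MK counting")
  cell <- function(f) vapply(members, f, 0)
  ranges <- list(Ps = range(cell(function(m) m$counts$Ps)),
                 Pn = range(cell(function(m) m$counts$Pn)),
                 Ds = range(cell(function(m) m$counts$Ds)),
                 Dn = range(cell(function(m) m$counts$Dn)))
  NI <- cell(function(m) if (m$ni_defined) m$NI else NA_real_)
  chi2 <- cell(function(m) m$statistic)
  i_min <- which.min(chi2)
  structure(list(members = members,
                 ranges = ranges,
                 NI_max = if (all(is.na(NI))) NA_real_ else max(NI, na.rm = TRUE),
                 chi2_min = chi2[[i_min]],
                 p_at_chi2_min = members[[i_min]]$p.value),
            class = "mk_range")
}

#' @export
print.mk_range <- function(x, ...) {
  cat("MK test against a reconstruction suite (", length(x$members),
      " member(s))\n", sep = "")
  rng <- function(r) if (abs(r[1] - r[2]) < 1e-9) sprintf("%.1f", r[1])
                     else sprintf("%.1f-%.1f", r[1], r[2])
  cat(sprintf("  Ds %s  Dn %s  Ps %s  Pn %s\n", rng(x$ranges$Ds),
              rng(x$ranges$Dn), rng(x$ranges$Ps), rng(x$ranges$Pn)))
  cat(sprintf("  NI <= %.2f,  X2 >= %.1f,  P = %.3f\n",
              x$NI_max, x$chi2_min, x$p_at_chi2_min))
  invisible(x)
}

#' Pairwise MK test between two population samples
#'
#' Polymorphism cells pool the two samples' within-gene counts; divergence
#' cells are Jukes-Cantor-corrected pathway counts between the two samples at
#' columns fixed in both (site totals averaged between the two consensus
#' sequences).
#'
#' @param sample_a,sample_b [codon_alignment()]s of equal codon length.
#' @param correct apply the Jukes-Cantor correction to the divergence cells.
#' @return an `mk_test` with pooled-count bookkeeping in `counts`.
#' @export
pairwise_mk <- function(sample_a, sample_b, correct = TRUE) {
  if (sample_a$n_codons != sample_b$n_codons)
    stop("samples have different codon lengths")
  cd <- codon_data()
  pa <- count_polymorphisms(sample_a)
  pb <- count_polymorphisms(sample_b)
  Ps <- pa$Ps + pb$Ps; Pn <- pa$Pn + pb$Pn
  fa <- fixed_states(sample_a); fb <- fixed_states(sample_b)
  ok <- !is.na(fa) & !is.na(fb)
  pt <- pathway_tables(cd)
  idx <- cbind(fa[ok], fb[ok])
  Ds_raw <- sum(pt$syn[idx]); Dn_raw <- sum(pt$nsyn[idx])
  ca <- consensus_sequence(sample_a); cb <- consensus_sequence(sample_b)
  both <- !is.na(ca) & !is.na(cb)
  sc_a <- alignment_site_counts(ca[both]); sc_b <- alignment_site_counts(cb[both])
  syn_sites <- (sc_a$syn_sites + sc_b$syn_sites) / 2
  nsyn_sites <- (sc_a$nsyn_sites + sc_b$nsyn_sites) / 2
  Ds <- if (correct) jc_correct(Ds_raw, syn_sites) else Ds_raw
  Dn <- if (correct) jc_correct(Dn_raw, nsyn_sites) else Dn_raw
  counts <- list(Ps = Ps, Pn = Pn, Ps_a = pa$Ps, Pn_a = pa$Pn, Ps_b = pb$Ps,
                 Pn_b = pb$Pn, Ds_raw = Ds_raw, Dn_raw = Dn_raw, Ds = Ds,
                 Dn = Dn, syn_sites = syn_sites, nsyn_sites = nsyn_sites)
  mk_test(Ps, Pn, Ds, Dn, counts = counts)
}
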