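#' Genetic-code lookup tables
#'
#' Internal cache of codon-level lookup structures for the standard genetic
#' code (or an injected alternative): sense codons in lexicographic order,
#' translations, single-step change masks (transition / nonsynonymous), and
#' precomputed pathway and site counts.
#'
#' @param code named character vector mapping all 64 codons to amino-acid
#'   symbols, with `"*"` for stop codons. Defaults to the standard code
#'   ([Biostrings::GENETIC_CODE]).
#' @return an environment with lookup tables (internal).
#' @keywords internal
codon_data <- function(code = NULL) {
  if (is.null(code) && !is.null(.cd$codons61)) return(.cd)
  gc_tab <- code %||% Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  all64 <- sort(as.vector(outer(outer(nts, nts, paste0), nts, paste0)))
  if (!all(all64 %in% names(gc_tab)))
    stop("genetic code table must cover all 64 codons")
  aa64 <- unname(gc_tab[all64])
  sense <- aa64 != "*"
  codons61 <- all64[sense]
  aa61 <- aa64[sense]
  n <- length(codons61)

  nt_idx <- matrix(0L, n, 3L)
  for (p in 1:3) nt_idx[, p] <- match(substr(codons61, p, p), nts)

  # pairwise structure over sense codons
  diffs <- matrix(0L, n, n)
  for (p in 1:3) diffs <- diffs + outer(nt_idx[, p], nt_idx[, p], "!=")
  single <- diffs == 1L
  purine <- c(TRUE, FALSE, TRUE, FALSE)              # A, G
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    dp <- outer(nt_idx[, p], nt_idx[, p], "!=")
    same_type <- outer(purine[nt_idx[, p]], purine[nt_idx[, p]], "==")
    ts <- ts | (single & dp & same_type)
  }
  nonsyn <- outer(aa61, aa61, "!=")

  e <- .cd
  if (!is.null(code)) e <- new.env(parent = emptyenv())
  e$nts <- nts
  e$all64 <- all64
  e$aa64 <- setNames(aa64, all64)
  e$stop_codons <- all64[!sense]
  e$codons61 <- codons61
  e$aa61 <- aa61
  e$codon_index <- setNames(seq_len(n), codons61)
  e$nt_idx <- nt_idx
  e$ndiff <- diffs
  e$single <- single
  e$ts <- ts
  e$nonsyn <- nonsyn
  e$path <- NULL          # filled lazily by pathway_tables()
  e$ng_syn <- NULL        # filled lazily by ng_tables()
  e
}

translate_codon <- function(codon, cd = codon_data()) {
  aa <- cd$aa64[toupper(codon)]
  if (any(is.na(aa))) stop("not a codon over {A,C,G,T}: ", codon[is.na(aa)][1])
  unname(aa)
}

#' Classify a single-nucleotide codon change
#'
#' @param c1,c2 codon strings differing at exactly one position; `c1` must be a
#'   sense codon.
#' @param code optional 64-entry genetic code table (see [codon_data()]).
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`.
#' @examples
#' classify_single_change("TTT", "TTC")  # synonymous
#' classify_single_change("TGG", "TGA")  # nonsense
#' @export
classify_single_change <- function(c1, c2, code = NULL) {
  cd <- codon_data(code)
  a1 <- translate_codon(c1, cd); a2 <- translate_codon(c2, cd)
  nd <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (nd != 1L) stop("codons must differ at exactly one position (got ", nd, ")")
  if (a1 == "*") stop("source codon is a stop codon")
  if (a2 == "*") return("nonsense")
  if (a1 == a2) "synonymous" else "nonsynonymous"
}

# permutations of 1..k for k = 1,2,3
.perms <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# pathway syn/nsyn counts for one ordered pair of codon strings
.pathway_pair <- function(s1, s2, cd) {
  x1 <- strsplit(s1, "")[[1]]; x2 <- strsplit(s2, "")[[1]]
  pos <- which(x1 != x2)
  k <- length(pos)
  if (k == 0L) return(list(syn = 0, nsyn = 0, blocked = FALSE))
  syn_tot <- 0; nsyn_tot <- 0; n_ok <- 0L
  syn_all <- 0; nsyn_all <- 0    # fallback: stop steps counted nonsynonymous
  for (ord in .perms[[k]]) {
    cur <- x1; syn <- 0; nsyn <- 0; ok <- TRUE
    for (p in pos[ord]) {
      nxt <- cur; nxt[p] <- x2[p]
      a_cur <- cd$aa64[paste(cur, collapse = "")]
      a_nxt <- cd$aa64[paste(nxt, collapse = "")]
      if (a_nxt == "*" || a_cur == "*") { ok <- FALSE; nsyn <- nsyn + 1 }
      else if (a_cur == a_nxt) syn <- syn + 1
      else nsyn <- nsyn + 1
      cur <- nxt
    }
    syn_all <- syn_all + syn; nsyn_all <- nsyn_all + nsyn
    if (ok) { syn_tot <- syn_tot + syn; nsyn_tot <- nsyn_tot + nsyn; n_ok <- n_ok + 1L }
  }
  m <- length(.perms[[k]])
  if (n_ok > 0L)
    list(syn = syn_tot / n_ok, nsyn = nsyn_tot / n_ok, blocked = FALSE)
  else
    list(syn = syn_all / m, nsyn = nsyn_all / m, blocked = TRUE)
}

# 61 x 61 matrices of averaged pathway counts, computed once per code
pathway_tables <- function(cd = codon_data()) {
  if (!is.null(cd$path)) return(cd$path)
  n <- length(cd$codons61)
  syn <- matrix(0, n, n); nsyn <- matrix(0, n, n); blocked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || cd$ndiff[i, j] == 1L) {
      # single-step pairs need no enumeration
      if (i != j) { if (cd$nonsyn[i, j]) nsyn[i, j] <- 1 else syn[i, j] <- 1 }
      next
    }
    pc <- .pathway_pair(cd$codons61[i], cd$codons61[j], cd)
    syn[i, j] <- pc$syn; nsyn[i, j] <- pc$nsyn; blocked[i, j] <- pc$blocked
  }
  cd$path <- list(syn = syn, nsyn = nsyn, blocked = blocked)
  cd$path
}

#' Fractional synonymous/nonsynonymous pathway counts between two codons
#'
#' Enumerates all orderings of the differing positions (minimal mutational
#' pathways), discards pathways that pass through a stop codon, and averages
#' the per-pathway synonymous and nonsynonymous step counts. If every pathway
#' is stop-blocked (possible for some triple-difference pairs), the average is
#' taken over all pathways with stop steps counted as nonsynonymous, and the
#' result is flagged.
#'
#' @param c1,c2 sense codon strings.
#' @inheritParams classify_single_change
#' @return list with components `syn`, `nsyn` (fractional counts summing to
#'   the Hamming distance of the codons) and `blocked` (logical flag).
#' @examples
#' pathway_counts("GCA", "GTT")  # both 2-step pathways valid: (1, 1)
#' pathway_counts("TAT", "TGG")  # pathway via the TAG stop excluded: (0, 2)
#' @export
pathway_counts <- function(c1, c2, code = NULL) {
  cd <- codon_data(code)
  i <- cd$codon_index[toupper(c1)]; j <- cd$codon_index[toupper(c2)]
  if (is.na(i) || is.na(j)) stop("both codons must be sense codons")
  pt <- pathway_tables(cd)
  list(syn = pt$syn[i, j], nsyn = pt$nsyn[i, j], blocked = pt$blocked[i, j])
}

ng_tables <- function(cd = codon_data()) {
  if (!is.null(cd$ng_syn)) return(cd$ng_syn)
  n <- length(cd$codons61)
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    x <- strsplit(cd$codons61[i], "")[[1]]
    s <- 0
    for (p in 1:3) for (b in cd$nts[cd$nts != x[p]]) {
      y <- x; y[p] <- b
      tgt <- cd$aa64[paste(y, collapse = "")]
      if (tgt != "*" && tgt == cd$aa61[i]) s <- s + 1
    }
    syn_sites[i] <- s / 3
  }
  cd$ng_syn <- syn_sites
  syn_sites
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for a codon
#'
#' At each of the three codon positions the synonymous-site fraction is the
#' number of the three possible single-base changes that are synonymous,
#' divided by 3; changes to stop codons count as nonsynonymous. The two
#' fractions sum to exactly 3 per codon.
#'
#' @param c1 a sense codon string.
#' @inheritParams classify_single_change
#' @return list with `syn_sites` and `nsyn_sites`.
#' @examples
#' ng_site_counts("TTT")  # (1/3, 8/3)
#' ng_site_counts("ATG")  # Met: (0, 3)
#' @export
ng_site_counts <- function(c1, code = NULL) {
  cd <- codon_data(code)
  i <- cd$codon_index[toupper(c1)]
  if (is.na(i)) stop("stop codon (or non-codon) input: ", c1)
  s <- ng_tables(cd)[i]
  list(syn_sites = s, nsyn_sites = 3 - s)
}

#' Site counts for a codon sequence
#'
#' Sums [ng_site_counts()] over the codons of an in-frame sequence. Codons
#' containing gaps or ambiguity characters are skipped.
#'
#' @param seq nucleotide string (length divisible by 3), or an integer vector
#'   of sense-codon indices (`NA` = skipped).
#' @inheritParams classify_single_change
#' @return list with `syn_sites` and `nsyn_sites`.
#' @export
alignment_site_counts <- function(seq, code = NULL) {
  cd <- codon_data(code)
  idx <- if (is.numeric(seq)) as.integer(seq) else codon_indices(seq, cd)
  idx <- idx[!is.na(idx)]
  s <- sum(ng_tables(cd)[idx])
  list(syn_sites = s, nsyn_sites = 3 * length(idx) - s)
}

# split a nucleotide string into sense-codon indices; NA for gap/ambiguous
# codons; error on internal stop codons unless allow_stop
codon_indices <- function(seq, cd = codon_data(), allow_stop = FALSE,
                          what = "sequence") {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0)
    stop(what, " length (", nchar(seq), ") is not divisible by 3")
  if (nchar(seq) == 0) return(integer(0))
  cods <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  idx <- unname(cd$codon_index[cods])
  is_stop <- cods %in% cd$stop_codons
  if (any(is_stop)) {
    bad <- which(is_stop)
    if (!allow_stop && any(bad < length(cods)))
      stop(what, " contains an internal stop codon at codon ",
           bad[bad < length(cods)][1])
    idx[bad] <- NA_integer_   # terminal stop column excluded from analysis
  }
  idx
}
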