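# ---- duplicate-gene retention-mode classification ---------------------------

#' Evidence bundle for one gene copy
#'
#' @param branch branch identifier (for reporting).
#' @param p_adjusted adjusted p-value of the positive-selection test on the
#'   copy's branch (branch-site LRT and/or MK test).
#' @param function_state `"ancestral"`, `"novel"`, `"novel-variant"` or
#'   `"unknown"` -- an annotation supplied by the user (functional states come
#'   from assays, not from sequence).
#' @param source evidence source, `"branch_site"`, `"mk"` or `"both"`.
#' @return list of class `branch_evidence`.
#' @export
branch_evidence <- function(branch, p_adjusted,
                            function_state = c("unknown", "ancestral",
                                               "novel", "novel-variant"),
                            source = c("branch_site", "mk", "both")) {
  function_state <- match.arg(function_state)
  source <- match.arg(source)
  stopifnot(is.numeric(p_adjusted), p_adjusted >= 0, p_adjusted <= 1)
  structure(list(branch = branch, p_adjusted = p_adjusted,
                 function_state = function_state, source = source),
            class = "branch_evidence")
}

#' Classify the retention mode of a duplicate gene pair
#'
#' Decision table over per-copy selection evidence and function annotations:
#' \itemize{
#'   \item NF (neofunctionalization): exactly one copy under positive
#'     selection, the other copy non-positive with the ancestral function
#'     retained.
#'   \item EAC (escape from adaptive conflict): both copies positive, one
#'     copy's function ancestral.
#'   \item CN (concerted neofunctionalization): both copies positive, both
#'     functions novel (or novel variants).
#'   \item SF-or-ambiguous: everything else, including any `"unknown"`
#'     function annotation (which degrades the call and adds a caveat).
#' }
#' "Positive" means the adjusted p-value is at most `alpha`; the classifier
#' never claims purifying selection affirmatively, only absence of evidence
#' for positive selection. The call is invariant to swapping the daughters.
#'
#' @param daughter_a,daughter_b [branch_evidence()] for the two copies.
#' @param pre_duplication optional [branch_evidence()] for the parent branch
#'   (reported in the evidence summary; the mode is decided by the daughters).
#' @param alpha significance level for calling positive selection.
#' @return object of class `retention_call` with `mode` (`"NF"`, `"EAC"`,
#'   `"CN"` or `"SF-or-ambiguous"`), `evidence` and `caveats`.
#' @examples
#' a <- branch_evidence("GSS1/2", 1e-4, "novel")
#' b <- branch_evidence("GSS3", 1e-4, "novel-variant")
#' classify_retention(a, b)   # CN
#' @export
classify_retention <- function(daughter_a, daughter_b, pre_duplication = NULL,
                               alpha = 0.05) {
  stopifnot(inherits(daughter_a, "branch_evidence"),
            inherits(daughter_b, "branch_evidence"))
  pos <- function(d) d$p_adjusted <= alpha
  caveats <- character(0)
  fs <- c(daughter_a$function_state, daughter_b$function_state)
  if (any(fs == "unknown"))
    caveats <- c(caveats, "function annotation unknown for at least one copy")
  if (!is.null(pre_duplication) && pos(pre_duplication))
    caveats <- c(caveats,
                 "positive selection also detected on the pre-duplication branch")
  novel <- fs %in% c("novel", "novel-variant")
  ancestral <- fs == "ancestral"
  pa <- pos(daughter_a); pb <- pos(daughter_b)
  mode <- if (any(fs == "unknown")) "SF-or-ambiguous"
  else if (xor(pa, pb) && ((pa && ancestral[2] && novel[1]) ||
                           (pb && ancestral[1] && novel[2]))) "NF"
  else if (pa && pb && sum(ancestral) == 1 && sum(novel) == 1) "EAC"
  else if (pa && pb && all(novel)) "CN"
  else "SF-or-ambiguous"
  if (mode == "SF-or-ambiguous" && !length(caveats))
    caveats <- "selection/function pattern matches none of NF, EAC, CN"
  structure(list(mode = mode,
                 evidence = list(daughter_a = daughter_a,
                                 daughter_b = daughter_b,
                                 pre_duplication = pre_duplication),
                 alpha = alpha,
                 caveats = caveats),
            class = "retention_call")
}

#' @export
print.retention_call <- function(x, ...) {
  long <- c(NF = "neofunctionalization",
            EAC = "escape from adaptive conflict",
            CN = "concerted neofunctionalization",
            "SF-or-ambiguous" = "subfunctionalization or ambiguous")
  cat("retention mode:", x$mode, sprintf("(%s)\n", long[[x$mode]]))
  for (nm in c("daughter_a", "daughter_b")) {
    d <- x$evidence[[nm]]
    cat(sprintf("  %s: p_adj = %.3g (%s at alpha = %g), function %s\n",
                d$branch, d$p_adjusted,
                if (d$p_adjusted <= x$alpha) "positive" else "non-positive",
                x$alpha, d$function_state))
  }
  for (cv in x$caveats) cat("  caveat:", cv, "\n")
  invisible(x)
}
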