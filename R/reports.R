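# ---- report assembly --------------------------------------------------------
# Display rounding follows the published-table conventions: NI to 2 decimals,
# chi-square to 1, p-values to 3; ranges rendered "min-max", bounds "<=x"/">=y".

fmt_num <- function(x, digits) ifelse(is.na(x), "-", sprintf(paste0("%.", digits, "f"), x))

fmt_range <- function(lo, hi, digits = 1) {
  ifelse(is.na(lo), "-",
         ifelse(abs(hi - lo) < 10^(-digits) / 2, fmt_num(lo, digits),
                paste0(fmt_num(lo, digits), "-", fmt_num(hi, digits))))
}

mk_row <- function(x, label = "") {
  ct <- x$counts %||% list(Ps = x$table[1, 1], Pn = x$table[1, 2],
                           Ds = x$table[2, 1], Dn = x$table[2, 2])
  data.frame(comparison = label,
             Ps = ct$Ps, Pn = ct$Pn, Ds = ct$Ds, Dn = ct$Dn,
             NI = x$NI, chi2 = x$statistic, P = x$p.value,
             stringsAsFactors = FALSE)
}

#' Write a McDonald-Kreitman report
#'
#' Renders MK results in the layout of the published tables: one row per
#' comparison with syn/nsyn polymorphism and (corrected) divergence counts,
#' `NI` (2 dp), chi-square (1 dp) and `P` (3 dp). `mk_range` results render
#' their cells as `min-max` ranges and their summary statistics as bounds
#' (`<=NI_max`, `>=chi2_min`). A TSV (rounded display values) and a parallel
#' full-precision JSON are written when paths are given.
#'
#' @param results a single `mk_test`/`mk_range` or a (optionally named) list
#'   of them.
#' @param tsv,json optional output paths.
#' @return the display `data.frame`, invisibly when files are written.
#' @export
write_mk_report <- function(results, tsv = NULL, json = NULL) {
  if (inherits(results, c("mk_test", "mk_range"))) results <- list(results)
  if (!length(results)) stop("empty result set; no report written")
  if (is.null(names(results)))
    names(results) <- paste0("comparison", seq_along(results))
  rows <- list(); full <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "mk_test")) {
      r <- mk_row(x, nm)
      rows[[nm]] <- data.frame(comparison = nm,
                               Ps = fmt_num(r$Ps, 1), Pn = fmt_num(r$Pn, 1),
                               Ds = fmt_num(r$Ds, 1), Dn = fmt_num(r$Dn, 1),
                               NI = fmt_num(r$NI, 2),
                               chi2 = fmt_num(r$chi2, 1),
                               P = fmt_num(r$P, 3), stringsAsFactors = FALSE)
      full[[nm]] <- list(Ps = r$Ps, Pn = r$Pn, Ds = r$Ds, Dn = r$Dn,
                         NI = r$NI, chi2 = r$chi2, P = r$P)
    } else if (inherits(x, "mk_range")) {
      rg <- x$ranges
      rows[[nm]] <- data.frame(
        comparison = nm,
        Ps = fmt_range(rg$Ps[1], rg$Ps[2]), Pn = fmt_range(rg$Pn[1], rg$Pn[2]),
        Ds = fmt_range(rg$Ds[1], rg$Ds[2]), Dn = fmt_range(rg$Dn[1], rg$Dn[2]),
        NI = paste0("<=", fmt_num(x$NI_max, 2)),
        chi2 = paste0(">=", fmt_num(x$chi2_min, 1)),
        P = fmt_num(x$p_at_chi2_min, 3), stringsAsFactors = FALSE)
      full[[nm]] <- list(ranges = rg, NI_max = x$NI_max,
                         chi2_min = x$chi2_min, P = x$p_at_chi2_min)
    } else stop("unsupported result type: ", class(x)[1])
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(full, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(tsv) && is.null(json)) df else invisible(df)
}

#' Write a branch-scan report
#'
#' @param scan a [scan_branches()] result.
#' @param tsv,json optional output paths (TSV rounded for display, JSON at
#'   full precision).
#' @return the display `data.frame`, invisibly when files are written.
#' @export
write_scan_report <- function(scan, tsv = NULL, json = NULL) {
  stopifnot(inherits(scan, "bs_scan"))
  df <- data.frame(branch = scan$branch,
                   chi2 = fmt_num(scan$stat, 1),
                   df = scan$df,
                   P_raw = fmt_num(scan$p_raw, 3),
                   P_adjusted = fmt_num(scan$p_adj, 3),
                   omega2 = fmt_num(scan$omega2, 2),
                   converged = scan$converged,
                   stringsAsFactors = FALSE)
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(as.data.frame(scan), json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(tsv) && is.null(json)) df else invisible(df)
}

#' Write reconstructed ancestral sequences
#'
#' FASTA with the model label in the description line, and (optionally) a
#' per-site posterior TSV.
#'
#' @param suite a `recon_suite` or single `ancestral_seq`.
#' @param fasta,tsv output paths.
#' @export
write_reconstruction <- function(suite, fasta = NULL, tsv = NULL) {
  members <- if (inherits(suite, "recon_suite")) suite$members else list(suite)
  members <- members[!vapply(members, function(m) isTRUE(m$failed), TRUE)]
  if (!length(members)) stop("no reconstructed member to write")
  if (!is.null(fasta)) {
    ss <- Biostrings::BStringSet(vapply(members, as.character, ""))
    names(ss) <- vapply(members, function(m)
      paste0("node", m$node, " ", m$model_label), "")
    Biostrings::writeXStringSet(ss, fasta, width = 60L)
  }
  if (!is.null(tsv)) {
    tab <- do.call(rbind, lapply(members, function(m)
      data.frame(model = m$model_label,
                 site = seq_along(m$map_codons),
                 codon = m$map_codons,
                 posterior = m$site_posteriors,
                 tied = m$tied, stringsAsFactors = FALSE)))
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(suite)
}
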