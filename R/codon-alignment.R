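#' In-frame codon alignment
#'
#' Container for an aligned set of protein-coding sequences, stored as a
#' matrix of sense-codon indices (rows = sequences, columns = codon sites).
#' Codons containing gaps or IUPAC ambiguity characters are stored as `NA`
#' and excluded from all downstream counts and likelihoods; a terminal stop
#' codon (if every sequence carries one) is likewise excluded. Internal stop
#' codons are a validation error.
#'
#' @param seqs character vector of equal-length nucleotide strings (lengths
#'   divisible by 3), or a list of such strings.
#' @param ids sequence identifiers; defaults to `names(seqs)`.
#' @param allow_gaps if `FALSE` (strict mode), any gap or ambiguity codon is
#'   an error rather than an excluded column.
#' @return an object of class `codon_alignment` with elements `ids`,
#'   `codons` (integer matrix, `NA` = excluded codon) and `n_codons`.
#' @examples
#' aln <- codon_alignment(c(a = "ATGTTT", b = "ATGTTC"))
#' aln$n_codons
#' @export
codon_alignment <- function(seqs, ids = names(seqs), allow_gaps = FALSE) {
  seqs <- toupper(unlist(seqs))
  if (length(seqs) < 1L) stop("alignment needs at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences have unequal lengths")
  cd <- codon_data()
  mat <- do.call(rbind, lapply(seq_along(seqs), function(i)
    codon_indices(seqs[i], cd, what = paste0("sequence '", ids[i], "'"))))
  rownames(mat) <- ids
  if (!allow_gaps && anyNA(mat)) {
    bad <- which(colSums(is.na(mat)) > 0)[1]
    stop("gap/ambiguity codon at codon column ", bad,
         " (use allow_gaps = TRUE to exclude such columns)")
  }
  structure(list(ids = ids, codons = mat, n_codons = ncol(mat)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment: ", length(x$ids), " sequences x ", x$n_codons,
      " codons\n", sep = "")
  ngap <- sum(colSums(is.na(x$codons)) > 0)
  if (ngap > 0) cat("  columns with gaps/ambiguities:", ngap, "\n")
  cat("  ids:", paste(head(x$ids, 6), collapse = ", "),
      if (length(x$ids) > 6) "...", "\n")
  invisible(x)
}

#' @export
as.character.codon_alignment <- function(x, ...) {
  cd <- codon_data()
  apply(x$codons, 1, function(row) {
    s <- ifelse(is.na(row), "---", cd$codons61[row])
    paste(s, collapse = "")
  })
}

#' Read a codon alignment from FASTA
#'
#' @param path FASTA file; description lines are used as record ids.
#' @inheritParams codon_alignment
#' @return a [codon_alignment()].
#' @export
read_codon_fasta <- function(path, allow_gaps = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  codon_alignment(as.character(ss), ids = names(ss), allow_gaps = allow_gaps)
}

#' Write a codon alignment to FASTA
#'
#' Excluded (gap/ambiguity) codons are written as `---`; lines wrap at 60
#' columns.
#'
#' @param aln a [codon_alignment()].
#' @param path output file.
#' @export
write_codon_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(as.character(aln))
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

# integer codon matrix restricted to (and ordered by) the given tip labels
aln_tip_matrix <- function(aln, tips) {
  miss <- setdiff(tips, aln$ids)
  if (length(miss))
    stop("tree tips missing from alignment: ", paste(miss, collapse = ", "))
  aln$codons[match(tips, aln$ids), , drop = FALSE]
}
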