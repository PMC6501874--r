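# small in-code fixtures shared across tests

quartet_tree <- function(fg = NULL) {
  tr <- read_codon_tree(text = "((A:0.2,B:0.3):0.15,C:0.25,D:0.4);")
  if (!is.null(fg)) tr <- set_foreground(tr, fg) else tr$foreground <- integer(0)
  tr
}

triplet_tree <- function() ape::read.tree(text = "(A:0.3,B:0.2,C:0.4);")

# a deterministic pseudo-random sense-codon sequence
random_codon_seq <- function(n, seed) {
  cd61 <- dupsel:::codon_data()$codons61
  withr::with_seed(seed, paste(sample(cd61, n, replace = TRUE), collapse = ""))
}

# haplotype sample built from explicit per-haplotype codon strings
hap_sample <- function(...) {
  seqs <- c(...)
  codon_alignment(seqs, ids = names(seqs) %||% paste0("h", seq_along(seqs)),
                  allow_gaps = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
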