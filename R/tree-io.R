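#' Read a phylogeny with foreground branch marks
#'
#' Parses a Newick tree (branch lengths, node support labels) and the PAML
#' `#1` branch-tag dialect marking foreground branches. Marks may follow a tip
#' label (`B#1:0.2`) or a closing parenthesis (`)#1:0.1`). The returned object
#' is an [ape::read.tree()] `"phylo"` tree with an extra `foreground` element:
#' the node numbers whose parent edges are marked.
#'
#' @param path file containing one Newick tree.
#' @param text alternatively, the Newick string itself.
#' @return a `phylo` object with a `foreground` integer vector.
#' @examples
#' tr <- read_codon_tree(text = "(A:0.1,B#1:0.2,C:0.3);")
#' foreground_edges(tr)
#' @export
read_codon_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  tagged <- gsub("\\s*#\\s*1", "__FG1__", text)
  tr <- tryCatch(ape::read.tree(text = tagged),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    # locate first parenthesis imbalance for the error message
    bal <- cumsum((strsplit(text, "")[[1]] == "(") -
                  (strsplit(text, "")[[1]] == ")"))
    off <- if (any(bal < 0)) which(bal < 0)[1] else nchar(text)
    stop("malformed Newick near character offset ", off, ": ",
         substr(text, max(1, off - 15), min(nchar(text), off + 5)))
  }
  fg <- integer(0)
  mark <- function(labels, nodes) {
    hit <- grepl("__FG1__", labels %||% character(0), fixed = TRUE)
    fg <<- c(fg, nodes[hit])
    sub("__FG1__", "", labels, fixed = TRUE)
  }
  tr$tip.label <- mark(tr$tip.label, seq_along(tr$tip.label))
  if (!is.null(tr$node.label))
    tr$node.label <- mark(tr$node.label,
                          ape::Ntip(tr) + seq_along(tr$node.label))
  tr$foreground <- sort(fg)
  tr
}

#' Write a phylogeny with foreground branch marks
#'
#' Inverse of [read_codon_tree()]: emits Newick with `#1` appended to the
#' labels of marked nodes.
#'
#' @param tree a `phylo` object, optionally with a `foreground` element.
#' @param path output file; if `NULL` the Newick string is returned.
#' @export
write_codon_tree <- function(tree, path = NULL) {
  fg <- tree$foreground %||% integer(0)
  ntip <- ape::Ntip(tree)
  if (length(fg)) {
    tips <- fg[fg <= ntip]
    tree$tip.label[tips] <- paste0(tree$tip.label[tips], "__FG1__")
    internal <- fg[fg > ntip]
    if (length(internal)) {
      if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
      tree$node.label[internal - ntip] <-
        paste0(tree$node.label[internal - ntip], "__FG1__")
    }
  }
  tree$foreground <- NULL
  nwk <- gsub("__FG1__", "#1", ape::write.tree(tree), fixed = TRUE)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

#' Mark foreground branches on a tree
#'
#' A branch is identified by its child node: a tip label, an internal node
#' label, or an ape node number.
#'
#' @param tree a `phylo` object.
#' @param nodes vector of tip labels, node labels, or node numbers.
#' @return the tree with its `foreground` element replaced.
#' @export
set_foreground <- function(tree, nodes) {
  tree$foreground <- sort(unique(vapply(nodes, node_number, 0L, tree = tree)))
  tree
}

# resolve a tip label / node label / numeric id to an ape node number
node_number <- function(tree, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (x < 1L || x > ape::Ntip(tree) + tree$Nnode)
      stop("node number out of range: ", x)
    return(x)
  }
  i <- match(x, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(x, tree$node.label %||% character(0))
  if (!is.na(j)) return(ape::Ntip(tree) + j)
  stop("no tip or node labelled '", x, "'")
}

#' Foreground indicator over tree edges
#'
#' @param tree a `phylo` object with a `foreground` element (see
#'   [read_codon_tree()], [set_foreground()]).
#' @return logical vector along `tree$edge` rows.
#' @export
foreground_edges <- function(tree) {
  tree$edge[, 2] %in% (tree$foreground %||% integer(0))
}
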