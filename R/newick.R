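# Newick I/O and the dated species tree (chronogram) used for rates and
# simulation. Trees are ape `phylo` objects; a chronogram additionally
# carries class "chronogram" and must be ultrametric with leaf age 0.

#' Read a Newick tree
#'
#' @param path Newick file
#' @param chronogram validate the tree as an ultrametric chronogram (branch
#'   lengths in myr, all root-to-leaf path lengths equal)
#' @param tol relative tolerance for the ultrametricity check
#' @return an ape `phylo`; with `chronogram = TRUE`, classed
#'   `c("chronogram", "phylo")`
#' @export
read_newick <- function(path, chronogram = FALSE, tol = 1e-6) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error in ", path, call. = FALSE)
  if (chronogram) tr <- as_chronogram(tr, tol = tol)
  tr
}

#' Write a tree to Newick
#'
#' Branch lengths are written after `:` and bootstrap support values, when
#' present, as bare internal-node labels.
#'
#' @param tree an ape `phylo`
#' @param path output file
#' @param digits significant digits for branch lengths
#' @export
write_newick <- function(tree, path, digits = 10) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Validate a tree as a chronogram
#'
#' @param tree rooted ape `phylo` with branch lengths in myr
#' @param tol relative ultrametricity tolerance
#' @return the tree with class `c("chronogram", "phylo")`
#' @export
as_chronogram <- function(tree, tol = 1e-6) {
  if (inherits(tree, "chronogram")) return(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("chronogram requires branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("chronogram must be rooted", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_len(ape::Ntip(tree))]
  if (diff(range(tip_depths)) > tol * max(max(tip_depths), 1))
    stop("tree is not ultrametric: root-to-leaf path lengths differ",
         call. = FALSE)
  class(tree) <- c("chronogram", "phylo")
  tree
}

#' Node ages of a chronogram
#'
#' @param tree a chronogram
#' @return numeric vector of ages (mya) indexed by node number (tips first,
#'   ages 0)
#' @export
node_ages <- function(tree) {
  tree <- as_chronogram(tree)
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths[seq_len(ape::Ntip(tree))]) - depths
  ages[seq_len(ape::Ntip(tree))] <- 0
  ages
}

#' Total branch length of a tree
#'
#' For a chronogram this is the summed duration (myr) of all branches, the
#' denominator of the per-100-myr event rates.
#'
#' @param tree an ape `phylo` (or chronogram)
#' @return sum of all branch lengths; 0 for a degenerate single-leaf tree
#' @export
total_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length)
}

#' Packaged 15-species vertebrate chronogram
#'
#' The dated species tree for human plus 14 vertebrates with approximate
#' TimeTree-style node ages scaled by a single factor so that the total
#' branch length equals 2,685 myr. Individual node ages are therefore
#' approximate; dating functions take the calibration time as an explicit
#' argument.
#'
#' @return a chronogram over 15 species tokens (Hosa, Patr, Mamu, Caja,
#'   Mumu, Rano, Bota, Cafa, Modo, Anca, Gaga, Tagu, Xetr, Orla, Dare)
#' @export
cyp_vertebrate_chronogram <- function() {
  read_newick(system.file("extdata", "vertebrate_chronogram.nwk",
                          package = "cypevol", mustWork = TRUE),
              chronogram = TRUE)
}
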