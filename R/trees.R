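# Tree construction and branch-length fitting: neighbor-joining, bootstrap
# support over alignment columns, ordinary-least-squares branch lengths on a
# fixed topology, outgroup rooting and clade queries.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); for an additive input matrix
#' the realized path lengths reproduce the input distances exactly.
#'
#' @param D a `cyp_dist` or symmetric numeric matrix with labels
#' @return an unrooted ape `phylo`
#' @export
nj_build <- function(D) {
  m <- unclass(D)
  if (!all(is.finite(m)))
    stop("distance matrix contains non-finite entries", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 labels for NJ", call. = FALSE)
  tr <- ape::nj(stats::as.dist(m))
  diag <- metricity_diagnostic(m)
  attr(tr, "metricity") <- diag
  tr
}

metricity_diagnostic <- function(m) {
  n <- nrow(m)
  viol <- 0L
  checked <- 0L
  if (n >= 3L) {
    idx <- utils::combn(n, 3)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]; l <- idx[3, k]
      checked <- checked + 1L
      if (m[i, j] > m[i, l] + m[l, j] + 1e-12 ||
          m[i, l] > m[i, j] + m[j, l] + 1e-12 ||
          m[j, l] > m[j, i] + m[i, l] + 1e-12) viol <- viol + 1L
    }
  }
  list(triangle_violations = viol, triples_checked = checked)
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns (codon columns for codon alignments) with
#' replacement, rebuilds an NJ tree per replicate with `distance_fn`, and
#' reports for each internal branch of the original tree the percentage of
#' replicates whose tree contains the same bipartition. Replicates in which
#' `distance_fn` yields non-finite distances are dropped with a warning and
#' the denominator adjusted.
#'
#' @param aln a `cyp_alignment`
#' @param distance_fn function mapping an alignment to a distance matrix,
#'   e.g. `function(a) distance_matrix(a, "p")`
#' @param n_reps number of bootstrap replicates
#' @param seed integer seed (reproducible)
#' @return the original NJ tree with numeric support (percent, full
#'   precision) in `attr(, "support")` and rounded values as `node.label`
#' @export
bootstrap_support <- function(aln, distance_fn, n_reps = 100, seed = 1) {
  stopifnot(n_reps >= 1)
  D0 <- distance_fn(aln)
  tr0 <- nj_build(D0)
  nu <- n_units(aln, aln_type(aln))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  reps <- vector("list", n_reps)
  dropped <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(nu, nu, replace = TRUE)
    sub <- subset_units(aln, idx)
    Dr <- tryCatch(distance_fn(sub), error = function(e) NULL)
    if (is.null(Dr) || !all(is.finite(unclass(Dr)))) {
      dropped <- dropped + 1L
      next
    }
    reps[[r]] <- ape::nj(stats::as.dist(unclass(Dr)))
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (dropped > 0L)
    warning(dropped, " bootstrap replicate(s) dropped (undefined distances)")
  if (length(reps) == 0L)
    stop("all bootstrap replicates dropped", call. = FALSE)
  counts <- ape::prop.clades(tr0, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / length(reps)
  attr(tr0, "support") <- support
  tr0$node.label <- as.character(round(support))
  attr(tr0, "n_effective_reps") <- length(reps)
  tr0
}

subset_units <- function(aln, idx) {
  type <- aln_type(aln)
  cols <- if (type == "codon") {
    as.vector(vapply(idx, function(u) (3L * (u - 1L) + 1L):(3L * u),
                     integer(3)))
  } else idx
  m <- unclass(aln)[, cols, drop = FALSE]
  structure(m, class = c("cyp_alignment", "matrix", "array"),
            type = type, column_map = attr(aln, "column_map")[idx])
}

#' Ordinary-least-squares branch lengths on a fixed topology
#'
#' Each pairwise distance is modelled as the sum of branch lengths on the
#' path connecting the pair; the linear least-squares solution over the
#' path-incidence structure is returned. Negative fitted lengths are
#' clamped to zero with a warning, followed by one refit pass of the
#' remaining branches.
#'
#' @param topology an ape `phylo` whose tip set equals the labels of `D`
#'   (rooted input is unrooted first; the two root branches of a rooted
#'   binary tree are not separately identifiable)
#' @param D a `cyp_dist` or labelled symmetric matrix
#' @return list with `tree` (unrooted topology carrying fitted lengths),
#'   `lengths` (tibble: parent, child, length, clamped), `sse`, and
#'   `n_clamped`
#' @export
ols_branch_lengths <- function(topology, D) {
  m <- unclass(D)
  tr <- topology
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tips <- tr$tip.label
  if (!setequal(tips, rownames(m)))
    stop("topology tip set does not match distance labels", call. = FALSE)
  n <- length(tips)
  prs <- utils::combn(n, 2)
  d <- m[cbind(match(tips[prs[1, ]], rownames(m)),
               match(tips[prs[2, ]], rownames(m)))]
  E <- nrow(tr$edge)
  sides <- edge_tip_sides(tr)
  A <- matrix(0, ncol(prs), E)
  for (e in seq_len(E)) {
    inside <- sides[[e]]
    A[, e] <- as.numeric(xor(prs[1, ] %in% inside, prs[2, ] %in% inside))
  }
  qr_A <- qr(A)
  if (qr_A$rank < E) stop("singular OLS system (degenerate topology)",
                          call. = FALSE)
  beta <- qr.coef(qr_A, d)
  clamped <- beta < 0
  if (any(clamped)) {
    warning(sum(clamped), " negative OLS branch length(s) clamped to 0")
    beta[clamped] <- 0
    free <- !clamped
    if (any(free)) {
      beta2 <- qr.coef(qr(A[, free, drop = FALSE]), d)
      beta2[beta2 < 0] <- 0
      beta[free] <- beta2
    }
  }
  fit <- as.vector(A %*% beta)
  sse <- sum((d - fit)^2)
  tr$edge.length <- beta
  node_name <- function(i) {
    if (i <= n) tips[i] else paste0("node", i)
  }
  lengths <- tibble::tibble(
    parent = vapply(tr$edge[, 1], node_name, character(1)),
    child = vapply(tr$edge[, 2], node_name, character(1)),
    length = beta,
    clamped = clamped
  )
  list(tree = tr, lengths = lengths, sse = sse, n_clamped = sum(clamped))
}

# For each edge, the tip indices on the child side.
edge_tip_sides <- function(tr) {
  n <- ape::Ntip(tr)
  desc <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  ord <- rev(ape::postorder(tr))  # we need children before parents: postorder
  for (e in ape::postorder(tr)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tr$edge)), function(e) desc[[tr$edge[e, 2]]])
}

#' Root a tree with an outgroup
#'
#' Places the root at the midpoint of the branch separating the outgroup
#' from the ingroup.
#'
#' @param tree an ape `phylo`
#' @param outgroup character vector of outgroup tip labels (must be
#'   separable from the ingroup by one branch)
#' @return rooted `phylo`
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!all(outgroup %in% tree$tip.label))
    stop("unknown outgroup tip(s)", call. = FALSE)
  if (setequal(outgroup, tree$tip.label))
    stop("outgroup cannot contain all leaves", call. = FALSE)
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
              edgelabel = TRUE),
    error = function(e) stop("outgroup is not separable: ",
                             conditionMessage(e), call. = FALSE))
  if (!is.null(rooted$edge.length)) {
    root_node <- ape::Ntip(rooted) + 1L
    root_edges <- which(rooted$edge[, 1] == root_node)
    if (length(root_edges) == 2L) {
      s <- sum(rooted$edge.length[root_edges])
      rooted$edge.length[root_edges] <- s / 2
    }
  }
  rooted
}

#' Test a leaf set for monophyly
#'
#' TRUE iff some branch of the tree bipartitions exactly the given set (for
#' a rooted tree: some clade equals the set). The support of the defining
#' branch, when node labels carry support values, is attached as attribute
#' `"support"`.
#'
#' @param tree an ape `phylo`
#' @param leaves character vector of tip labels
#' @return logical with attribute `support`
#' @export
is_monophyletic <- function(tree, leaves) {
  if (!all(leaves %in% tree$tip.label))
    stop("unknown leaf label(s): ",
         paste(setdiff(leaves, tree$tip.label), collapse = ", "),
         call. = FALSE)
  tips <- tree$tip.label
  target <- sort(match(leaves, tips))
  if (length(target) %in% c(1L, length(tips)))
    return(structure(TRUE, support = NA_real_))
  sides <- edge_tip_sides(tree)
  n <- length(tips)
  rooted <- ape::is.rooted(tree)
  for (e in seq_along(sides)) {
    side <- sort(sides[[e]])
    hit <- identical(side, target) ||
      (!rooted && identical(sort(setdiff(seq_len(n), side)), target))
    if (hit) {
      sup <- NA_real_
      child <- tree$edge[e, 2]
      if (!is.null(tree$node.label) && child > n) {
        lab <- tree$node.label[child - n]
        sup <- suppressWarnings(as.numeric(lab))
      }
      return(structure(TRUE, support = sup))
    }
  }
  structure(FALSE, support = NA_real_)
}
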